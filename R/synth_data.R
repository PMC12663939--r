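#' Design of a synthetic measurement campaign
#'
#' Describes the sampling design the generator emulates: xylem water
#' status and evaporative demand varied independently (uniformly and
#' uncorrelated) across plants and days. Defaults mirror a 37-plant,
#' 87-measurement campaign spanning psi_xyl in [-2, 0] MPa and VPD in
#' [2.66, 4.82] kPa.
#'
#' @param n_plants Number of plants.
#' @param n_measurements Number of measurements (>= n_plants; plants are
#'   assigned round-robin across consecutive days, so every plant
#'   contributes at least one record and at most `ceiling(n/n_plants)`).
#' @param psi_xyl_range Range of xylem potentials, MPa.
#' @param vpd_range Range of VPD, kPa.
#' @param T_leaf_C Leaf temperature, deg C (must keep the whole VPD range
#'   below saturation).
#' @param seed Integer seed; all randomness in [generate_campaign()] flows
#'   from it.
#' @return Object of class `campaign_design`.
#' @export
campaign_design <- function(n_plants = 37, n_measurements = 87,
                            psi_xyl_range = c(-2, 0),
                            vpd_range = c(2.66, 4.82),
                            T_leaf_C = 33, seed = 1) {
  stopifnot(
    n_measurements >= n_plants, n_plants >= 1,
    psi_xyl_range[1] < psi_xyl_range[2], vpd_range[1] < vpd_range[2]
  )
  esat <- saturation_vapor_pressure(T_leaf_C + 273.15)
  if (vpd_range[2] > esat) {
    stop(sprintf(
      "vpd_range upper end (%.3g kPa) exceeds e_sat at %.3g degC (%.3g kPa)",
      vpd_range[2], T_leaf_C, esat
    ))
  }
  structure(
    list(
      n_plants = as.integer(n_plants),
      n_measurements = as.integer(n_measurements),
      psi_xyl_range = psi_xyl_range, vpd_range = vpd_range,
      T_leaf_C = T_leaf_C, seed = as.integer(seed)
    ),
    class = "campaign_design"
  )
}

#' Measurement noise model
#'
#' Observation noise applied after the forward model: additive Gaussian on
#' water-potential readings (optical-probe noise), multiplicative
#' lognormal on fluxes (gas-analyser noise). Dispersions of zero give a
#' noise-free campaign.
#'
#' @param psi_sd Standard deviation of potential readings, MPa.
#' @param flux_cv Coefficient of variation of fluxes (lognormal sigma).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(psi_sd = 0.15, flux_cv = 0.05) {
  if (psi_sd < 0 || flux_cv < 0) stop("dispersions must be non-negative")
  structure(list(psi_sd = psi_sd, flux_cv = flux_cv), class = "noise_model")
}

#' Generate a synthetic gas-exchange + nanoreporter campaign
#'
#' Samples (psi_xyl, VPD) independently and uniformly over the design
#' ranges, forward-solves the two-compartment model for every record
#' (with a stomatal-closure schedule so conductance drops near the turgor
#' loss point), and applies the observation-noise model. The returned
#' table follows the campaign CSV schema and carries the noise-free truth
#' in extra `*_true` columns, so analytics can be validated against known
#' ground truth. Physical ordering `psi_ssc <= psi_xyl` is preserved under
#' noise by clipping the substomatal reading just below the xylem reading
#' where noise would invert them.
#'
#' All randomness flows from `design$seed` through one RNG stream in a
#' fixed order (psi draws, VPD draws, then noise), so a given seed yields
#' a byte-identical table.
#'
#' @param design A [campaign_design()].
#' @param net,law,scen Model truth, see [solve_steady_state()].
#' @param schedule Stomatal schedule, a function psi -> total gs
#'   (mmol m-2 s-1); default [gs_schedule()].
#' @param noise A [noise_model()].
#' @param assimilation_per_gs Net assimilation per unit stomatal
#'   conductance, (umol m-2 s-1)/(mmol m-2 s-1); a fixed proportionality
#'   standing in for the carbon side, which this generator does not model.
#' @param P Pressure, kPa.
#' @param constants A [physical_constants()] object.
#' @return Data.frame: campaign schema columns, then
#'   `psi_xyl_true_MPa`, `psi_ssc_true_MPa`, `gs_true`, `g_oxz_true`,
#'   `g_s_true` (truth on the measurement convention: corrected stomatal
#'   conductance computed from noise-free fluxes and mole fractions).
#' @examples
#' camp <- generate_campaign(campaign_design(seed = 42))
#' nrow(camp)
#' @export
generate_campaign <- function(design = campaign_design(),
                              net = leaf_network(), law = membrane_law(),
                              scen = scenario_spec(),
                              schedule = gs_schedule(),
                              noise = noise_model(),
                              assimilation_per_gs = 0.05,
                              P = physical_constants()$atm_pressure,
                              constants = physical_constants()) {
  stopifnot(inherits(design, "campaign_design"), inherits(noise, "noise_model"))
  n <- design$n_measurements
  set.seed(design$seed)
  psi_xyl <- stats::runif(n, design$psi_xyl_range[1], design$psi_xyl_range[2])
  vpd <- stats::runif(n, design$vpd_range[1], design$vpd_range[2])
  plant <- ((seq_len(n) - 1L) %% design$n_plants) + 1L
  day <- ((seq_len(n) - 1L) %/% design$n_plants) + 1L
  T_leaf <- design$T_leaf_C + 273.15
  scale <- psi_scale_mpa(T_leaf, constants)
  w_sat <- saturation_mole_fraction(T_leaf, P)

  E_ad <- E_ab <- psi_ssc <- gs_true <- goxz_true <- gstar_true <-
    numeric(n)
  for (i in seq_len(n)) {
    air <- air_state_from_vpd(vpd[i], T_leaf, P)
    gs_t <- schedule(psi_xyl[i])
    sol <- solve_steady_state(
      net, law, scen,
      boundary_conditions(psi_xyl[i], air, gs_ad = gs_t / 2, gs_ab = gs_t / 2),
      constants
    )
    E_ad[i] <- sol$E_ad
    E_ab[i] <- sol$E_ab
    psi_ssc[i] <- sol$psi_apo[1]
    gs_true[i] <- gs_t
    goxz_true[i] <- sol$g_oxz
    # truth on the measurement convention (corrected stomatal conductance)
    w_i <- w_sat * exp(psi_ssc[i] / scale)
    gstar_true[i] <- (sol$E_ad + sol$E_ab) *
      (1 - (w_i + air$w_a) / 2) / (w_i - air$w_a)
  }
  A_true <- assimilation_per_gs * gs_true

  # observation noise (draw order fixed for reproducibility)
  zf1 <- stats::rnorm(n)
  zf2 <- stats::rnorm(n)
  zf3 <- stats::rnorm(n)
  zp1 <- stats::rnorm(n)
  zp2 <- stats::rnorm(n)
  E_ad_obs <- E_ad * exp(noise$flux_cv * zf1)
  E_ab_obs <- E_ab * exp(noise$flux_cv * zf2)
  A_obs <- A_true * exp(noise$flux_cv * zf3)
  psi_xyl_obs <- psi_xyl + noise$psi_sd * zp1
  psi_ssc_obs <- psi_ssc + noise$psi_sd * zp2
  transpiring <- (E_ad_obs + E_ab_obs) > 0
  clip <- transpiring & psi_ssc_obs > psi_xyl_obs
  psi_ssc_obs[clip] <- psi_xyl_obs[clip] - 1e-6

  data.frame(
    plant_id = sprintf("P%02d", plant),
    day = day,
    E_ad = E_ad_obs, E_ab = E_ab_obs, A = A_obs,
    T_leaf_C = design$T_leaf_C,
    VPD_kPa = vpd,
    psi_xyl_MPa = psi_xyl_obs,
    psi_ssc_MPa = psi_ssc_obs,
    P_kPa = P,
    psi_xyl_true_MPa = psi_xyl,
    psi_ssc_true_MPa = psi_ssc,
    gs_true = gs_true,
    g_oxz_true = goxz_true,
    g_s_true = gstar_true,
    stringsAsFactors = FALSE
  )
}

#' Write a campaign table as CSV with a unit header
#'
#' Columns are documented in `#`-prefixed comment lines so every numeric
#' column carries its units; [read_campaign()] skips them.
#'
#' @param campaign Data.frame from [generate_campaign()] or compatible.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_campaign <- function(campaign, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "# gas-exchange + nanoreporter campaign",
    "# units: E_ad,E_ab mmol/m2/s; A umol/m2/s; T_leaf_C degC;",
    "#        VPD_kPa kPa; psi_* MPa; P_kPa kPa; g_* mmol/m2/s"
  ), con)
  utils::write.csv(campaign, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a synthetic FRET nanosensor image with known ground truth
#'
#' Builds (i) a pixel-wise water-potential field (Gaussian around
#' `psi_mean`, clamped to the calibration's valid range), (ii) a FRET
#' efficiency map through the supplied calibration curve plus pixel noise,
#' and (iii) an autofluorescence channel showing mesophyll cells - smooth
#' rounded disks when turgid, shrunken faceted outlines when not - with
#' elliptical dark substomatal cavities between them. The true potential
#' field and cell layout are stored in the object for validation.
#'
#' @param shape Image dimensions, pixels (rows, cols).
#' @param cells Data.frame with columns `cx`, `cy`, `r` (pixels) and
#'   logical `turgid`; `NULL` lays out a jittered grid of cells.
#' @param n_cells Number of cells for the automatic layout.
#' @param turgid Default turgor state for the automatic layout.
#' @param psi_mean,psi_sd Mean and SD of the potential field, MPa.
#' @param calibration A [calibration_curve()].
#' @param zeta_noise_sd Pixel noise on FRET efficiency (same units as
#'   zeta).
#' @param pixel_size Pixel edge, micrometres.
#' @param seed Integer seed.
#' @return Object of class `fret_image`: list with `zeta_map`,
#'   `autofluorescence`, `pixel_size`, `metadata`, and `truth`
#'   (`psi_map`, `cells`).
#' @examples
#' img <- generate_fret_image(psi_mean = -6, psi_sd = 1, seed = 7)
#' @export
generate_fret_image <- function(shape = c(192, 192), cells = NULL,
                                n_cells = 25, turgid = TRUE,
                                psi_mean = -6, psi_sd = 1,
                                calibration = calibration_curve(),
                                zeta_noise_sd = 0.005,
                                pixel_size = 0.5, seed = 1) {
  set.seed(seed)
  H <- shape[1]
  W <- shape[2]
  if (is.null(cells)) {
    k <- ceiling(sqrt(n_cells))
    step_x <- W / k
    step_y <- H / k
    grid <- expand.grid(gx = seq_len(k), gy = seq_len(k))[seq_len(n_cells), ]
    cells <- data.frame(
      cx = (grid$gx - 0.5) * step_x + stats::runif(n_cells, -2, 2),
      cy = (grid$gy - 0.5) * step_y + stats::runif(n_cells, -2, 2),
      r = 0.30 * min(step_x, step_y) * stats::runif(n_cells, 0.9, 1.1),
      turgid = turgid
    )
  }
  stopifnot(all(c("cx", "cy", "r", "turgid") %in% names(cells)))
  if (any(cells$cx - cells$r < 1 | cells$cx + cells$r > W |
    cells$cy - cells$r < 1 | cells$cy + cells$r > H)) {
    stop("cells must lie fully within the frame")
  }
  if (nrow(cells) > 1) {
    d <- as.matrix(stats::dist(cells[, c("cx", "cy")]))
    rr <- outer(cells$r, cells$r, "+")
    if (any(d[upper.tri(d)] < rr[upper.tri(rr)])) {
      warning("overlapping cells in layout")
    }
  }

  xx <- matrix(rep(seq_len(W), each = H), H, W)
  yy <- matrix(rep(seq_len(H), times = W), H, W)
  auto <- matrix(0, H, W)
  phase <- stats::runif(nrow(cells), 0, 2 * pi)
  for (i in seq_len(nrow(cells))) {
    dx <- xx - cells$cx[i]
    dy <- yy - cells$cy[i]
    rho <- sqrt(dx^2 + dy^2)
    if (isTRUE(cells$turgid[i])) {
      redge <- cells$r[i]
    } else {
      # shrunken, faceted outline: reduced radius with angular lobing
      theta <- atan2(dy, dx)
      redge <- cells$r[i] * 0.72 * (1 + 0.22 * cos(6 * theta + phase[i]))
    }
    auto[rho <= redge] <- 1
  }
  # elliptical dark substomatal cavities in the background
  n_ssc <- max(2L, nrow(cells) %/% 6L)
  ssc <- data.frame(
    cx = stats::runif(n_ssc, 0.1 * W, 0.9 * W),
    cy = stats::runif(n_ssc, 0.1 * H, 0.9 * H),
    a = stats::runif(n_ssc, 4, 8), b = stats::runif(n_ssc, 2, 5),
    ang = stats::runif(n_ssc, 0, pi)
  )
  ssc_mask <- matrix(FALSE, H, W)
  for (i in seq_len(n_ssc)) {
    dx <- xx - ssc$cx[i]
    dy <- yy - ssc$cy[i]
    u <- dx * cos(ssc$ang[i]) + dy * sin(ssc$ang[i])
    v <- -dx * sin(ssc$ang[i]) + dy * cos(ssc$ang[i])
    ssc_mask <- ssc_mask | ((u / ssc$a[i])^2 + (v / ssc$b[i])^2 <= 1)
  }
  auto[ssc_mask & auto == 0] <- 0
  auto <- auto * 0.85 + 0.05
  auto <- pmin(pmax(auto + matrix(stats::rnorm(H * W, 0, 0.02), H, W), 0), 1)

  psi_map <- matrix(stats::rnorm(H * W, psi_mean, psi_sd), H, W)
  rng <- calibration$psi_range
  psi_map <- pmin(pmax(psi_map, rng[1]), rng[2])
  zeta <- cal_apply(calibration, psi_map) +
    matrix(stats::rnorm(H * W, 0, zeta_noise_sd), H, W)

  structure(
    list(
      zeta_map = zeta,
      autofluorescence = auto,
      pixel_size = pixel_size,
      metadata = list(
        psi_mean = psi_mean, psi_sd = psi_sd, seed = seed,
        zeta_noise_sd = zeta_noise_sd
      ),
      truth = list(psi_map = psi_map, cells = cells)
    ),
    class = "fret_image"
  )
}

#' @export
print.fret_image <- function(x, ...) {
  cat(sprintf(
    "FRET image: %d x %d px (%.2g um/px), zeta in [%.3f, %.3f]%s\n",
    nrow(x$zeta_map), ncol(x$zeta_map), x$pixel_size,
    min(x$zeta_map), max(x$zeta_map),
    if (!is.null(x$truth)) ", ground truth attached" else ""
  ))
  invisible(x)
}

#' Write / read a FRET image as a two-page TIFF
#'
#' Page 1 is the FRET-efficiency map, page 2 the autofluorescence channel,
#' both stored as 32-bit float. Ground truth (when present) is written to
#' a JSON sidecar.
#'
#' @param img A `fret_image`.
#' @param path Output TIFF path.
#' @param truth_path Optional path for the ground-truth JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_fret_image <- function(img, path, truth_path = NULL) {
  stopifnot(inherits(img, "fret_image"))
  tiff::writeTIFF(
    list(img$zeta_map, img$autofluorescence),
    path,
    bits.per.sample = 32L, reduce = FALSE
  )
  if (!is.null(truth_path) && !is.null(img$truth)) {
    jsonlite::write_json(
      list(
        psi_mode = unname(psi_histogram(img$truth$psi_map)$mode),
        psi_mean = mean(img$truth$psi_map),
        cells = img$truth$cells,
        pixel_size = img$pixel_size
      ),
      truth_path,
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}

#' @rdname write_fret_image
#' @param pixel_size Pixel edge, micrometres (not stored in the TIFF).
#' @return `read_fret_image`: a `fret_image` without ground truth.
#' @export
read_fret_image <- function(path, pixel_size = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop("expected a two-page TIFF (zeta, autofluorescence)")
  structure(
    list(
      zeta_map = pages[[1]], autofluorescence = pages[[2]],
      pixel_size = pixel_size, metadata = list(source = path), truth = NULL
    ),
    class = "fret_image"
  )
}
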