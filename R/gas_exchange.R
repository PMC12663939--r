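#' Effective outside-xylem-zone conductance
#'
#' g_oxz = (E_ad + E_ab) / (w_xyl - w_ssc_ad): the total transpiration flux
#' divided by the mole-fraction driving force between the xylem-equilibrated
#' apoplasm (both-sides-taped reading) and the substomatal-cavity apoplasm
#' (untaped reading on the adaxial surface). Records with a non-positive
#' driving force are flagged: the conductance is returned as `NA` with a
#' warning, never an error, so a batch analysis survives bad records.
#'
#' @param E_ad,E_ab Adaxial and abaxial transpiration, mmol m-2 s-1.
#' @param w_xyl,w_ssc_ad Vapor mole fractions equivalent to the xylem and
#'   adaxial substomatal-cavity water potentials, mol mol-1.
#' @return Conductance, mmol m-2 s-1 (vectorised; NA where flagged).
#' @examples
#' oxz_conductance(3, 2, 0.0310, 0.0290) # 2500
#' @export
oxz_conductance <- function(E_ad, E_ab, w_xyl, w_ssc_ad) {
  if (any(c(E_ad, E_ab) < 0, na.rm = TRUE)) {
    stop("transpiration fluxes must be non-negative")
  }
  drv <- w_xyl - w_ssc_ad
  bad <- !is.na(drv) & drv <= 0
  if (any(bad)) {
    warning(sprintf(
      "%d record(s) with non-positive driving force w_xyl - w_ssc flagged as NA",
      sum(bad)
    ))
  }
  out <- (E_ad + E_ab) / drv
  out[bad] <- NA_real_
  out
}

#' Stomatal conductance corrected for interior undersaturation
#'
#' Total conductance of the leaf to water vapor from the measured interior
#' mole fraction: g_s = E * (1 - (w_i + w_a)/2) / (w_i - w_a), where w_i is
#' the substomatal mole fraction actually measured (rather than assumed
#' saturated). The (1 - (w_i + w_a)/2) term is the standard mass-flow
#' correction of cuvette gas-exchange systems.
#'
#' @param E Total transpiration, mmol m-2 s-1.
#' @param w_i Interior (substomatal) vapor mole fraction, mol mol-1.
#' @param w_a Ambient vapor mole fraction, mol mol-1.
#' @return Conductance, mmol m-2 s-1 (NA where w_i <= w_a, with warning).
#' @examples
#' stomatal_conductance_corrected(5, 0.029, 0.012) # ~288
#' @export
stomatal_conductance_corrected <- function(E, w_i, w_a) {
  drv <- w_i - w_a
  bad <- !is.na(drv) & drv <= 0
  if (any(bad)) {
    warning(sprintf(
      "%d record(s) with w_i <= w_a flagged as NA", sum(bad)
    ))
  }
  out <- E * (1 - (w_i + w_a) / 2) / drv
  out[bad] <- NA_real_
  out
}

#' Conventional (Gaastra) stomatal conductance
#'
#' The conventional estimate assuming a saturated leaf interior:
#' g_s_sat = E / (w_sat(T_leaf) - w_a). Deliberately carries no mass-flow
#' correction factor, exactly as the classical formula is written, so that
#' the relative-error phenotype delta_gs compares the corrected and
#' conventional forms as they are used in practice.
#'
#' @inheritParams stomatal_conductance_corrected
#' @param w_sat_leaf Saturation mole fraction at leaf temperature, mol mol-1.
#' @return Conductance, mmol m-2 s-1 (NA where w_sat_leaf <= w_a).
#' @export
stomatal_conductance_gaastra <- function(E, w_sat_leaf, w_a) {
  drv <- w_sat_leaf - w_a
  bad <- !is.na(drv) & drv <= 0
  if (any(bad)) {
    warning(sprintf("%d record(s) with w_sat <= w_a flagged as NA", sum(bad)))
  }
  out <- E / drv
  out[bad] <- NA_real_
  out
}

campaign_columns <- c(
  "plant_id", "day", "E_ad", "E_ab", "A", "T_leaf_C", "VPD_kPa",
  "psi_xyl_MPa", "psi_ssc_MPa", "P_kPa"
)

#' Read a measurement-campaign CSV
#'
#' One row per paired gas-exchange + nanoreporter measurement. The schema is
#' `plant_id,day,E_ad,E_ab,A,T_leaf_C,VPD_kPa,psi_xyl_MPa,psi_ssc_MPa,P_kPa`;
#' extra columns are preserved. Leading `#` lines (unit comments) are
#' skipped.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with at least the schema columns.
#' @export
read_campaign <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(campaign_columns, names(df))
  if (length(missing)) {
    stop(
      "campaign CSV is missing required column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  df
}

#' Per-measurement conductances and nonstomatal-control phenotypes
#'
#' Takes a campaign table (see [read_campaign()] for the schema) and appends
#' the derived metrics: mole fractions (`w_sat`, `w_a`, `w_xyl`, `w_ssc`),
#' conductances (`g_oxz`, `g_s`, `g_s_sat`), the phenotypes `delta_w`
#' (relative undersaturation of the substomatal cavity), `delta_gs`
#' (relative error of the conventional conductance estimate), `delta_iwue`
#' (relative gain in intrinsic water-use efficiency), and the resistance
#' ratio `ratio = g_s/g_oxz`.
#'
#' delta_iwue is computed as 1 - E/E_sat with E_sat = g_s (w_sat - w_a),
#' the transpiration a saturated interior would sustain at the same
#' corrected g_s; assimilation cancels from the ratio. Because g_s carries
#' the mass-flow correction, this makes delta_iwue algebraically equal to
#' delta_gs, and within a few percent of delta_w (they coincide exactly
#' when the correction factor is dropped). The alternative convention
#' iWUE = A/g_s is available via `iwue_convention = "A_over_gs"` (there
#' delta_iwue = (g_s_sat - g_s)/g_s_sat, the conductance-based form).
#'
#' @param records Data.frame in the campaign schema.
#' @param constants A [physical_constants()] object.
#' @param formula Saturation vapor pressure formula.
#' @param iwue_convention `"A_over_E"` (default) or `"A_over_gs"`.
#' @return The input data.frame with derived-metric columns appended.
#' @examples
#' camp <- generate_campaign(campaign_design(seed = 1))
#' met <- delta_metrics(camp)
#' summary(met$delta_w)
#' @export
delta_metrics <- function(records, constants = physical_constants(),
                          formula = c("tetens", "buck"),
                          iwue_convention = c("A_over_E", "A_over_gs")) {
  formula <- match.arg(formula)
  iwue_convention <- match.arg(iwue_convention)
  missing <- setdiff(campaign_columns, names(records))
  if (length(missing)) {
    stop("records missing column(s): ", paste(missing, collapse = ", "))
  }
  T_leaf <- records$T_leaf_C + 273.15
  P <- records$P_kPa
  w_sat <- saturation_mole_fraction(T_leaf, P, formula)
  esat <- saturation_vapor_pressure(T_leaf, formula)
  if (any(records$VPD_kPa > esat, na.rm = TRUE)) {
    stop("VPD exceeds saturation vapor pressure at leaf temperature")
  }
  w_a <- (esat - records$VPD_kPa) / P
  w_xyl <- w_sat * psi_to_h(records$psi_xyl_MPa, T_leaf, constants)
  w_ssc <- w_sat * psi_to_h(records$psi_ssc_MPa, T_leaf, constants)

  E <- records$E_ad + records$E_ab
  g_oxz <- oxz_conductance(records$E_ad, records$E_ab, w_xyl, w_ssc)
  g_s <- stomatal_conductance_corrected(E, w_ssc, w_a)
  g_s_sat <- stomatal_conductance_gaastra(E, w_sat, w_a)

  delta_w <- (w_sat - w_ssc) / (w_sat - w_a)
  delta_gs <- (g_s - g_s_sat) / g_s
  E_sat <- g_s * (w_sat - w_a)
  delta_iwue <- switch(iwue_convention,
    A_over_E = 1 - E / E_sat,
    A_over_gs = (g_s_sat - g_s) / g_s_sat
  )
  ratio <- g_s / g_oxz

  cbind(records, data.frame(
    w_sat = w_sat, w_a = w_a, w_xyl = w_xyl, w_ssc = w_ssc,
    g_oxz = g_oxz, g_s = g_s, g_s_sat = g_s_sat,
    delta_w = delta_w, delta_gs = delta_gs, delta_iwue = delta_iwue,
    ratio = ratio
  ))
}

#' Bin campaign metrics by xylem water potential or VPD
#'
#' Reproduces the binning used to summarise campaigns: psi_xyl bins
#' `0 to -0.4, -0.4 to -0.8, -0.8 to -1.2, -1.2 to -1.6, -1.6 to -2` MPa,
#' or VPD bins `2.66-3.25, 3.25-3.75, 3.75-4.25, 4.25-4.82` kPa. Intervals
#' are closed on the low-stress edge (toward zero for psi_xyl, toward the
#' lower VPD), so a record at exactly -0.4 MPa falls in the `0 to -0.4` bin.
#'
#' @param metrics Output of [delta_metrics()].
#' @param axis `"psi_xyl"` or `"vpd"`.
#' @param edges Optional numeric bin edges overriding the defaults.
#' @return Object of class `bin_summary`: data.frame with one row per bin
#'   and columns `bin_low`, `bin_high`, `n`, then `mean_*` and `se_*` for
#'   each derived metric.
#' @export
bin_summarize <- function(metrics, axis = c("psi_xyl", "vpd"), edges = NULL) {
  axis <- match.arg(axis)
  if (is.null(edges)) {
    edges <- switch(axis,
      psi_xyl = c(0, -0.4, -0.8, -1.2, -1.6, -2),
      vpd = c(2.66, 3.25, 3.75, 4.25, 4.82)
    )
  }
  x <- switch(axis, psi_xyl = metrics$psi_xyl_MPa, vpd = metrics$VPD_kPa)
  # Work on increasing stress: for psi_xyl, stress increases as psi falls,
  # so bin k holds edges[k] >= x > edges[k+1]; closed on the low-stress edge.
  vars <- c(
    "g_oxz", "g_s", "g_s_sat", "delta_w", "delta_gs", "delta_iwue", "ratio"
  )
  nb <- length(edges) - 1
  rows <- vector("list", nb)
  for (k in seq_len(nb)) {
    lo <- edges[k]
    hi <- edges[k + 1]
    # shared edges belong to the lower-stress bin: psi bins are (lo, hi]
    # walking downward with the first bin closed at 0; VPD bins are (lo, hi]
    # walking upward with the first bin closed at the lowest VPD
    inbin <- if (axis == "psi_xyl") {
      !is.na(x) & ((x < lo & x >= hi) | (k == 1 & x == lo))
    } else {
      !is.na(x) & ((x > lo & x <= hi) | (k == 1 & x == lo))
    }
    n <- sum(inbin)
    stats <- lapply(vars, function(v) {
      vals <- metrics[[v]][inbin]
      vals <- vals[is.finite(vals)]
      if (length(vals) == 0) {
        c(NA_real_, NA_real_)
      } else {
        c(mean(vals), stats::sd(vals) / sqrt(length(vals)))
      }
    })
    row <- data.frame(bin_low = lo, bin_high = hi, n = n)
    for (i in seq_along(vars)) {
      row[[paste0("mean_", vars[i])]] <- stats[[i]][1]
      row[[paste0("se_", vars[i])]] <- stats[[i]][2]
    }
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  attr(out, "axis") <- axis
  class(out) <- c("bin_summary", "data.frame")
  out
}
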