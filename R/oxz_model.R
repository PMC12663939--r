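#' Discretized two-compartment leaf hydraulic architecture
#'
#' Describes the pseudo-one-dimensional outside-xylem zone: a cell-to-cell
#' (symplasmic) path and an apoplasmic/vapor path running across the leaf
#' thickness, exchanging water through the plasma membrane at every depth.
#' Conductivities are per unit leaf area; the membrane exchange coefficient
#' is per unit symplasm-apoplasm interfacial area and is scaled internally
#' by `a_int` (interfacial area per leaf volume).
#'
#' @param n_layers Number of layers per half-leaf (grid has
#'   `2*n_layers + 1` nodes across the full thickness).
#' @param thickness Leaf thickness, m.
#' @param xylem_position Position of the xylem plane as a fraction of
#'   thickness (0 = adaxial surface).
#' @param k_cc Cell-to-cell hydraulic conductivity, mol m-1 s-1 MPa-1 per
#'   leaf area.
#' @param k_vap Axial apoplasmic (vapor-dominated) conductivity,
#'   mol m-1 s-1 MPa-1 per leaf area.
#' @param a_int Symplasm-apoplasm interfacial area per leaf volume, m2 m-3.
#' @return Object of class `leaf_network`.
#' @examples
#' net <- leaf_network()
#' @export
leaf_network <- function(n_layers = 50, thickness = 2e-4,
                         xylem_position = 0.5, k_cc = 1e-6,
                         k_vap = 3e-7, a_int = 4e4) {
  stopifnot(n_layers >= 1, thickness > 0)
  if (k_cc <= 0 || k_vap <= 0 || a_int <= 0) {
    stop("conductivities and interfacial area must be positive")
  }
  if (xylem_position <= 0 || xylem_position >= 1) {
    stop("xylem_position must lie strictly inside (0, 1)")
  }
  structure(
    list(
      n_layers = as.integer(n_layers), thickness = thickness,
      xylem_position = xylem_position, k_cc = k_cc, k_vap = k_vap,
      a_int = a_int
    ),
    class = "leaf_network"
  )
}

#' @export
print.leaf_network <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Leaf network: %d layers/half, thickness %.3g m, xylem at %.2f\n",
      "  k_cc = %.3g, k_vap = %.3g mol/m/s/MPa; a_int = %.3g m2/m3\n"
    ),
    x$n_layers, x$thickness, x$xylem_position, x$k_cc, x$k_vap, x$a_int
  ))
  invisible(x)
}

#' Sigmoid plasma-membrane conductance law
#'
#' Bounded four-parameter logistic for the plasma-membrane hydraulic
#' conductance as a function of the upstream xylem water potential:
#' kappa(psi) = kappa_min + (kappa_max - kappa_min) /
#' (1 + exp((psi_50 - psi)/slope)). Units of kappa are mol m-2 s-1 MPa-1
#' per unit symplasm-apoplasm interfacial area. The default parameters are
#' the package's calibrated law: the bounds sit within the range measured
#' on maize leaf protoplasts and the midpoint/slope were adjusted so the
#' forward model reproduces the observed decline of outside-xylem
#' conductance with xylem water potential (see the methods vignette).
#'
#' @param kappa_max,kappa_min Upper and lower bounds, mol m-2 s-1 MPa-1
#'   per interfacial area.
#' @param psi_50 Water potential of half-decline, MPa.
#' @param slope Width of the transition, MPa (> 0).
#' @return Object of class `membrane_law`.
#' @examples
#' law <- membrane_law()
#' membrane_conductance(law, -0.85)
#' @export
membrane_law <- function(kappa_max = 2.535e-3, kappa_min = 3.51e-5,
                         psi_50 = -0.184, slope = 0.170) {
  if (!(kappa_max > kappa_min && kappa_min > 0)) {
    stop("need kappa_max > kappa_min > 0")
  }
  if (slope <= 0) stop("slope must be positive")
  structure(
    list(
      kappa_max = kappa_max, kappa_min = kappa_min,
      psi_50 = psi_50, slope = slope
    ),
    class = "membrane_law"
  )
}

#' @export
print.membrane_law <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Membrane law: kappa in [%.3g, %.3g] mol/m2/s/MPa,",
      " psi_50 = %.3g MPa, slope = %.3g MPa\n"
    ),
    x$kappa_min, x$kappa_max, x$psi_50, x$slope
  ))
  invisible(x)
}

#' Evaluate the membrane law at the upstream xylem potential
#'
#' The exchange conductance is controlled by the water status of the source
#' xylem, not the local potential, so the whole through-leaf network shares
#' a single kappa at a given xylem potential and the steady-state system
#' stays linear.
#'
#' @param law A [membrane_law()].
#' @param psi_xyl Xylem water potential, MPa (vectorised).
#' @return Conductance, mol m-2 s-1 MPa-1 per interfacial area.
#' @export
membrane_conductance <- function(law, psi_xyl) {
  law$kappa_min + (law$kappa_max - law$kappa_min) /
    (1 + exp((law$psi_50 - psi_xyl) / law$slope))
}

#' Hydraulic scenario specification
#'
#' Selects one of four competing hydraulic architectures for the
#' outside-xylem zone:
#' \describe{
#'   \item{uniform_membrane}{(preferred) the membrane law applies at every
#'     symplasm-apoplasm interface through the leaf.}
#'   \item{symplasm_conductance}{the membrane stays at `kappa_max`; instead
#'     the cell-to-cell conductivity declines with xylem potential by the
#'     factor `kcc_min_frac + (1 - kcc_min_frac) * logistic`.}
#'   \item{wall_air_layer}{uniform membrane plus an air-filled cell-wall
#'     layer of thickness `air_layer_thickness` added in series at each
#'     interface.}
#'   \item{bundle_sheath_only}{membranes stay at `kappa_max` everywhere;
#'     the membrane law is applied only at the bundle sheath, modelled as a
#'     variable entry conductance `bs_area_per_leaf_area *
#'     membrane_conductance(law, psi_xyl)` between the xylem and the
#'     cell-to-cell path.}
#' }
#'
#' @param kind One of the four scenario names.
#' @param air_layer_thickness Air layer thickness, m (wall_air_layer).
#' @param kcc_min_frac Floor of the cell-to-cell decline factor
#'   (symplasm_conductance).
#' @param bs_area_per_leaf_area Bundle-sheath interfacial area per leaf
#'   area, m2 m-2 (bundle_sheath_only).
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c(
                            "uniform_membrane", "symplasm_conductance",
                            "wall_air_layer", "bundle_sheath_only"
                          ),
                          air_layer_thickness = 200e-9,
                          kcc_min_frac = 0.04,
                          bs_area_per_leaf_area = 10) {
  kind <- match.arg(kind)
  stopifnot(
    air_layer_thickness > 0, kcc_min_frac > 0, kcc_min_frac <= 1,
    bs_area_per_leaf_area > 0
  )
  structure(
    list(
      kind = kind, air_layer_thickness = air_layer_thickness,
      kcc_min_frac = kcc_min_frac,
      bs_area_per_leaf_area = bs_area_per_leaf_area
    ),
    class = "scenario_spec"
  )
}

#' Boundary conditions for the steady-state solve
#'
#' @param psi_xyl Xylem water potential, MPa (<= 0).
#' @param air An [air_state_from_vpd()] object (sets leaf temperature,
#'   ambient mole fraction and pressure).
#' @param gs_ad,gs_ab Stomatal conductance of the adaxial and abaxial
#'   surfaces, mmol m-2 s-1. Zero encodes a taped (non-transpiring)
#'   surface.
#' @return Object of class `boundary_conditions`.
#' @examples
#' bc <- boundary_conditions(-0.85, air_state_from_vpd(4.2, 303.15),
#'   gs_ad = 90, gs_ab = 90
#' )
#' @export
boundary_conditions <- function(psi_xyl, air, gs_ad = 90, gs_ab = 90) {
  if (!inherits(air, "air_state")) stop("air must be an air_state object")
  if (psi_xyl > 0) stop("psi_xyl must be <= 0")
  if (gs_ad < 0 || gs_ab < 0) stop("stomatal conductances must be >= 0")
  structure(
    list(psi_xyl = psi_xyl, air = air, gs_ad = gs_ad, gs_ab = gs_ab),
    class = "boundary_conditions"
  )
}

# Conductance of an air-filled wall layer of thickness t, per interfacial
# area, on a water-potential driving force (mol m-2 s-1 MPa-1). Vapor
# diffusivity D_wv and molar density of air at the boundary temperature.
air_layer_conductance <- function(thickness_m, T, P, w_sat,
                                  constants = physical_constants()) {
  D_wv <- 2.5e-5 * (T / 298.15)^1.8 # m2/s, temperature-scaled
  c_air <- P * 1e3 / (constants$gas_constant * T) # mol/m3
  beta <- w_sat * constants$molar_volume_water * 1e6 / (constants$gas_constant * T)
  D_wv * c_air / thickness_m * beta
}

#' Solve the two-compartment steady state
#'
#' Finite-volume discretization of the coupled cell-to-cell and apoplasmic
#' paths on `2*n_layers + 1` nodes across the leaf thickness. The
#' cell-to-cell path is pinned to `psi_xyl` at the xylem plane (Dirichlet)
#' with no-flux conditions at both epidermes; the apoplasmic path has
#' no-flux internal boundaries except stomatal Robin conditions at each
#' surface, with flux `g_s * (w(psi) - w_a)` using the linearized humidity
#' `w = w_sat * (1 + psi * Vw/(R T))` so the system is linear for fixed
#' xylem potential. Membrane exchange `a_int * kappa * (psi_cc - psi_apo)`
#' couples the compartments layer by layer. Reported substomatal humidities
#' apply the exact Kelvin relation to the solved potentials; the
#' linearization-consistent mole fractions are also returned for
#' verification against the closed-form two-node reduction.
#'
#' @param net A [leaf_network()].
#' @param law A [membrane_law()].
#' @param scen A [scenario_spec()].
#' @param bc A [boundary_conditions()].
#' @param constants A [physical_constants()] object.
#' @return Object of class `profile_solution`: list with node positions
#'   `z` (m), profiles `psi_cc` and `psi_apo` (MPa), surface fluxes `E_ad`,
#'   `E_ab` (mmol m-2 s-1), exact-Kelvin humidities `h_ssc_ad`, `h_ssc_ab`,
#'   the effective conductance `g_oxz` (mmol m-2 s-1, exact-Kelvin mole
#'   fractions) and its linearization-consistent twin `g_oxz_lin`, the
#'   per-node `membrane_exchange` (mol m-3 s-1), and the mole fractions
#'   used.
#' @examples
#' sol <- solve_steady_state(
#'   leaf_network(), membrane_law(), scenario_spec(),
#'   boundary_conditions(-0.85, air_state_from_vpd(4.2, 303.15), 90, 90)
#' )
#' sol$h_ssc_ad
#' @export
solve_steady_state <- function(net, law, scen = scenario_spec(), bc,
                               constants = physical_constants()) {
  stopifnot(
    inherits(net, "leaf_network"), inherits(law, "membrane_law"),
    inherits(scen, "scenario_spec"), inherits(bc, "boundary_conditions")
  )
  T <- bc$air$temperature
  P <- bc$air$P
  w_a <- bc$air$w_a
  w_sat <- saturation_mole_fraction(T, P)
  beta_p <- constants$molar_volume_water * 1e6 / (constants$gas_constant * T) # 1/MPa
  psi_xyl <- bc$psi_xyl

  N <- 2L * net$n_layers + 1L
  dz <- net$thickness / (N - 1)
  z <- (seq_len(N) - 1) * dz
  ix <- round(net$xylem_position * (N - 1)) + 1L
  if (ix <= 1L || ix >= N) stop("xylem plane coincides with a surface node")
  vol <- rep(dz, N)
  vol[c(1L, N)] <- dz / 2

  # scenario-dependent parameters (all evaluated at the upstream potential,
  # so the assembled system is linear)
  kappa_xyl <- membrane_conductance(law, psi_xyl)
  k_cc <- net$k_cc
  kappa <- rep(kappa_xyl, N)
  bs_link <- NULL
  if (scen$kind == "symplasm_conductance") {
    kappa <- rep(law$kappa_max, N)
    f <- (kappa_xyl - law$kappa_min) / (law$kappa_max - law$kappa_min)
    k_cc <- net$k_cc * (scen$kcc_min_frac + (1 - scen$kcc_min_frac) * f)
  } else if (scen$kind == "wall_air_layer") {
    k_lay <- air_layer_conductance(
      scen$air_layer_thickness, T, P, w_sat, constants
    )
    kappa <- rep(1 / (1 / kappa_xyl + 1 / k_lay), N)
  } else if (scen$kind == "bundle_sheath_only") {
    kappa <- rep(law$kappa_max, N)
    bs_link <- scen$bs_area_per_leaf_area * kappa_xyl # mol/m2/s/MPa leaf area
  }
  cvec <- net$a_int * kappa * vol # exchange conductance per leaf area, node-wise

  gs_ad <- bc$gs_ad * 1e-3 # mol m-2 s-1
  gs_ab <- bc$gs_ab * 1e-3

  # unknowns: x = [psi_cc (1..N); psi_apo (N+1..2N)]; residual form
  # (inflow - outflow = 0), assembled as triplets (duplicates are summed)
  gcc <- k_cc / dz
  gva <- net$k_vap / dz
  lo <- seq_len(N - 1L)
  hi <- lo + 1L
  axial <- function(offset, g) {
    list(
      i = offset + c(lo, lo, hi, hi),
      j = offset + c(hi, lo, lo, hi),
      v = rep(c(g, -g, g, -g), each = N - 1L)
    )
  }
  ax_cc <- axial(0L, gcc)
  ax_ap <- axial(N, gva)
  idx <- seq_len(N)
  ii <- c(ax_cc$i, ax_ap$i, idx, idx, N + idx, N + idx)
  jj <- c(ax_cc$j, ax_ap$j, idx, N + idx, idx, N + idx)
  vv <- c(ax_cc$v, ax_ap$v, -cvec, cvec, cvec, -cvec)
  rhs <- numeric(2L * N)
  if (gs_ad > 0) {
    ii <- c(ii, N + 1L); jj <- c(jj, N + 1L)
    vv <- c(vv, -gs_ad * w_sat * beta_p)
    rhs[N + 1L] <- rhs[N + 1L] + gs_ad * (w_sat - w_a)
  }
  if (gs_ab > 0) {
    ii <- c(ii, 2L * N); jj <- c(jj, 2L * N)
    vv <- c(vv, -gs_ab * w_sat * beta_p)
    rhs[2L * N] <- rhs[2L * N] + gs_ab * (w_sat - w_a)
  }
  if (is.null(bs_link)) {
    # Dirichlet pin of the cell-to-cell path at the xylem plane
    keep <- ii != ix
    ii <- c(ii[keep], ix); jj <- c(jj[keep], ix); vv <- c(vv[keep], 1)
    rhs[ix] <- psi_xyl
  } else {
    # variable bundle-sheath entry conductance in place of the pin
    ii <- c(ii, ix); jj <- c(jj, ix); vv <- c(vv, -bs_link)
    rhs[ix] <- rhs[ix] + bs_link * psi_xyl
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(2L * N, 2L * N))
  x <- as.numeric(Matrix::solve(A, rhs))
  psi_cc <- x[seq_len(N)]
  psi_apo <- x[N + seq_len(N)]

  w_lin <- function(psi) w_sat * (1 + beta_p * psi)
  E_ad <- if (gs_ad > 0) gs_ad * (w_lin(psi_apo[1]) - w_a) * 1e3 else 0
  E_ab <- if (gs_ab > 0) gs_ab * (w_lin(psi_apo[N]) - w_a) * 1e3 else 0

  scale <- psi_scale_mpa(T, constants)
  h_ssc_ad <- exp(psi_apo[1] / scale)
  h_ssc_ab <- exp(psi_apo[N] / scale)
  w_xyl <- w_sat * exp(psi_xyl / scale)
  w_ssc_ad <- w_sat * h_ssc_ad
  drv <- w_xyl - w_ssc_ad
  g_oxz <- if (drv > 0) (E_ad + E_ab) / drv else NA_real_
  w_xyl_lin <- w_lin(psi_xyl)
  w_ssc_lin_ad <- w_lin(psi_apo[1])
  w_ssc_lin_ab <- w_lin(psi_apo[N])
  drv_lin <- w_xyl_lin - w_ssc_lin_ad
  g_oxz_lin <- if (abs(drv_lin) > 0) (E_ad + E_ab) / drv_lin else NA_real_

  exch <- net$a_int * kappa * (psi_cc - psi_apo) # mol m-3 s-1

  structure(
    list(
      z = z, psi_cc = psi_cc, psi_apo = psi_apo,
      E_ad = E_ad, E_ab = E_ab,
      h_ssc_ad = h_ssc_ad, h_ssc_ab = h_ssc_ab,
      g_oxz = g_oxz, g_oxz_lin = g_oxz_lin,
      membrane_exchange = exch, node_volume = vol,
      w_sat = w_sat, w_a = w_a, w_xyl = w_xyl, w_ssc_ad = w_ssc_ad,
      w_xyl_lin = w_xyl_lin, w_ssc_lin_ad = w_ssc_lin_ad,
      w_ssc_lin_ab = w_ssc_lin_ab,
      kappa = kappa, k_cc_effective = k_cc, xylem_index = ix,
      bc = bc, net = net, law = law, scen = scen
    ),
    class = "profile_solution"
  )
}

#' @export
print.profile_solution <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Steady-state profile (%s): psi_xyl = %.3g MPa, VPD = %.3g kPa\n",
      "  E = %.3g + %.3g mmol/m2/s; h_ssc(ad) = %.4f (psi = %.3g MPa)\n",
      "  g_oxz = %.4g mmol/m2/s; max |psi_cc - psi_apo| = %.3g MPa\n"
    ),
    x$scen$kind, x$bc$psi_xyl, x$bc$air$vpd, x$E_ad, x$E_ab,
    x$h_ssc_ad, x$psi_apo[1], x$g_oxz, max(abs(x$psi_cc - x$psi_apo))
  ))
  invisible(x)
}

#' Closed-form two-node series network
#'
#' The series-resistor reduction of the outside-xylem path feeding a
#' stomatal conductance: the substomatal mole fraction is the
#' conductance-weighted mean `w_ssc = (g_oxz w_xyl + g_s w_a)/(g_oxz +
#' g_s)`, the flux is `E = g_s (w_ssc - w_a)`, and (taking w_xyl = w_sat)
#' the relative undersaturation obeys `delta_w = r/(1 + r)` with
#' `r = g_s/g_oxz`. Serves as the independent oracle for the discretized
#' solver, whose single-inlet, single-outlet linear network reduces exactly
#' to this form.
#'
#' @param g_oxz,g_s Conductances, mmol m-2 s-1 (> 0).
#' @param w_xyl,w_a Mole fractions at the xylem and in ambient air.
#' @return List with `w_ssc`, `E` (mmol m-2 s-1), `delta_w`.
#' @examples
#' two_node_closed_form(2500, 250, 0.0313, 0.012)
#' @export
two_node_closed_form <- function(g_oxz, g_s, w_xyl, w_a) {
  stopifnot(g_oxz > 0, g_s > 0)
  w_ssc <- (g_oxz * w_xyl + g_s * w_a) / (g_oxz + g_s)
  E <- g_s * (w_ssc - w_a)
  r <- g_s / g_oxz
  list(w_ssc = w_ssc, E = E, delta_w = r / (1 + r))
}

#' Model response curves over a grid of xylem potentials
#'
#' Runs one steady-state solve per grid point at fixed VPD and stomatal
#' conductance (split equally between surfaces unless a taping pattern is
#' given), optionally with a stomatal-closure schedule `gs_schedule(psi)`.
#'
#' @param net,law,scen,constants As in [solve_steady_state()].
#' @param psi_grid Xylem potentials, MPa (within `[-2.5, 0]`).
#' @param vpd Vapor pressure deficit, kPa.
#' @param gs Total stomatal conductance, mmol m-2 s-1.
#' @param T_leaf Leaf temperature, kelvin.
#' @param gs_schedule Optional function psi -> total gs, overriding `gs`.
#' @param P Pressure, kPa.
#' @return Data.frame with columns `psi_xyl`, `gs`, `g_oxz`, `h_ssc`,
#'   `psi_ssc`, `E`, `ratio`; attribute `monotone_g_oxz` records whether
#'   g_oxz is non-decreasing in psi_xyl.
#' @examples
#' pred <- predict_response_curves(psi_grid = seq(-2, -0.2, by = 0.2))
#' @export
predict_response_curves <- function(net = leaf_network(),
                                    law = membrane_law(),
                                    scen = scenario_spec(),
                                    psi_grid = seq(-2, 0, by = 0.1),
                                    vpd = 3.8, gs = 180, T_leaf = 303.15,
                                    gs_schedule = NULL,
                                    P = physical_constants()$atm_pressure,
                                    constants = physical_constants()) {
  if (any(psi_grid < -2.5 | psi_grid > 0)) {
    stop("psi_grid must lie within [-2.5, 0] MPa")
  }
  air <- air_state_from_vpd(vpd, T_leaf, P)
  rows <- lapply(seq_along(psi_grid), function(i) {
    psi <- psi_grid[i]
    gs_t <- if (is.null(gs_schedule)) gs else gs_schedule(psi)
    sol <- tryCatch(
      solve_steady_state(
        net, law, scen,
        boundary_conditions(psi, air, gs_ad = gs_t / 2, gs_ab = gs_t / 2),
        constants
      ),
      error = function(e) {
        stop(sprintf("solver failed at grid point %d (psi = %g): %s",
                     i, psi, conditionMessage(e)))
      }
    )
    data.frame(
      psi_xyl = psi, gs = gs_t, g_oxz = sol$g_oxz, h_ssc = sol$h_ssc_ad,
      psi_ssc = sol$psi_apo[1], E = sol$E_ad + sol$E_ab,
      ratio = gs_t / sol$g_oxz
    )
  })
  out <- do.call(rbind, rows)
  ord <- order(out$psi_xyl)
  attr(out, "monotone_g_oxz") <- all(diff(out$g_oxz[ord]) >= -1e-9 * max(out$g_oxz))
  out
}

#' Stomatal-closure schedule
#'
#' Piecewise-smooth total stomatal conductance as a function of xylem
#' potential: full opening at high potential, declining by `drop_factor`
#' around `psi_close` (logistic transition of width `slope`). Used to
#' emulate stomatal closure near the turgor loss point, which is what lets
#' substomatal humidity recover at the most stressed conditions.
#'
#' @param gs_max Unstressed total conductance, mmol m-2 s-1.
#' @param drop_factor Fold reduction at full closure response.
#' @param psi_close Midpoint of the closure transition, MPa.
#' @param slope Transition width, MPa.
#' @return A function of psi returning gs (mmol m-2 s-1).
#' @examples
#' sched <- gs_schedule()
#' sched(c(-0.2, -1.8))
#' @export
gs_schedule <- function(gs_max = 180, drop_factor = 3, psi_close = -1.6,
                        slope = 0.1) {
  stopifnot(gs_max > 0, drop_factor >= 1, slope > 0)
  function(psi) {
    gs_max * (1 / drop_factor +
      (1 - 1 / drop_factor) / (1 + exp((psi_close - psi) / slope)))
  }
}

#' Compare hydraulic scenarios on shared inputs
#'
#' Runs each scenario over the same grid of xylem potentials and collects
#' the diagnostics that discriminate the architectures: the conductance
#' curve g_oxz(psi_xyl), substomatal humidity, the maximum
#' symplasm-apoplasm disequilibrium, and whether the cell-to-cell path ever
#' falls below the turgor loss point.
#'
#' @param scenarios List of [scenario_spec()] objects (>= 2).
#' @param net,law,constants As in [solve_steady_state()].
#' @param psi_grid Xylem potentials, MPa.
#' @param vpd,gs,T_leaf,P Shared boundary conditions.
#' @return Object of class `scenario_comparison`: list with `summary`
#'   (one row per scenario: `scenario`, `min_g_oxz`, `max_g_oxz`,
#'   `fold_change`, `min_h_ssc`, `max_disequilibrium_MPa`,
#'   `turgor_loss`) and `curves` (per-scenario response tables).
#' @examples
#' cmp <- scenario_compare(
#'   list(scenario_spec("uniform_membrane"), scenario_spec("wall_air_layer")),
#'   psi_grid = c(-1.2, -0.6, -0.2)
#' )
#' cmp$summary
#' @export
scenario_compare <- function(scenarios,
                             net = leaf_network(), law = membrane_law(),
                             psi_grid = seq(-2, -0.1, by = 0.1),
                             vpd = 3.8, gs = 180, T_leaf = 303.15,
                             P = physical_constants()$atm_pressure,
                             constants = physical_constants()) {
  if (length(scenarios) < 2) stop("need at least two scenarios to compare")
  air <- air_state_from_vpd(vpd, T_leaf, P)
  tlp <- constants$turgor_loss_point
  curves <- list()
  summ <- list()
  for (scen in scenarios) {
    stopifnot(inherits(scen, "scenario_spec"))
    rows <- lapply(psi_grid, function(psi) {
      sol <- solve_steady_state(
        net, law, scen,
        boundary_conditions(psi, air, gs_ad = gs / 2, gs_ab = gs / 2),
        constants
      )
      data.frame(
        psi_xyl = psi, g_oxz = sol$g_oxz, h_ssc = sol$h_ssc_ad,
        E = sol$E_ad + sol$E_ab,
        diseq = max(abs(sol$psi_cc - sol$psi_apo)),
        min_psi_cc = min(sol$psi_cc)
      )
    })
    tab <- do.call(rbind, rows)
    curves[[scen$kind]] <- tab
    summ[[scen$kind]] <- data.frame(
      scenario = scen$kind,
      min_g_oxz = min(tab$g_oxz), max_g_oxz = max(tab$g_oxz),
      fold_change = max(tab$g_oxz) / min(tab$g_oxz),
      min_h_ssc = min(tab$h_ssc),
      max_disequilibrium_MPa = max(tab$diseq),
      turgor_loss = any(tab$min_psi_cc < tlp)
    )
  }
  structure(
    list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
         curves = curves),
    class = "scenario_comparison"
  )
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("Scenario comparison:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
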