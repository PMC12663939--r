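test_that("membrane law has sigmoid limits and stays within bounds", {
  law <- membrane_law(kappa_max = 1e-3, kappa_min = 2e-5, psi_50 = -0.8, slope = 0.2)
  expect_equal(membrane_conductance(law, 0), 1e-3, tolerance = 0.02)
  expect_equal(membrane_conductance(law, -0.8), (1e-3 + 2e-5) / 2)
  expect_equal(membrane_conductance(law, -50), 2e-5, tolerance = 1e-8)
  psi <- seq(-3, 0, by = 0.05)
  k <- membrane_conductance(law, psi)
  expect_true(all(k >= 2e-5 & k <= 1e-3))
  expect_true(all(diff(k) > 0))
  expect_error(membrane_law(kappa_max = 1e-5, kappa_min = 1e-3), "kappa_max")
  expect_error(membrane_law(slope = -1), "slope")
})

test_that("both-sides-taped leaf equilibrates with the xylem", {
  bc <- boundary_conditions(-0.85, air_state_from_vpd(4.2, 303.15),
    gs_ad = 0, gs_ab = 0
  )
  sol <- solve_steady_state(small_net(), membrane_law(), scenario_spec(), bc)
  expect_equal(sol$E_ad + sol$E_ab, 0)
  expect_equal(sol$psi_apo, rep(-0.85, length(sol$psi_apo)), tolerance = 1e-10)
  expect_equal(sol$psi_cc, rep(-0.85, length(sol$psi_cc)), tolerance = 1e-10)
  expect_equal(sol$h_ssc_ad, psi_to_h(-0.85, 303.15), tolerance = 1e-12)
})

test_that("solver conserves mass and matches the two-node oracle", {
  set.seed(42)
  for (i in 1:100) {
    net <- leaf_network(
      n_layers = sample(1:6, 1),
      thickness = runif(1, 1e-4, 4e-4),
      k_cc = 10^runif(1, -7, -5),
      k_vap = 10^runif(1, -8, -6),
      a_int = 10^runif(1, 4, 5)
    )
    law <- membrane_law(
      kappa_max = 10^runif(1, -3.5, -2.5),
      kappa_min = 10^runif(1, -5, -4.2),
      psi_50 = runif(1, -1.2, -0.2), slope = runif(1, 0.1, 0.3)
    )
    gs <- runif(1, 40, 250)
    bc <- boundary_conditions(
      runif(1, -1.8, -0.1),
      air_state_from_vpd(runif(1, 2.7, 4.2), 303.15),
      gs_ad = gs, gs_ab = 0
    )
    sol <- solve_steady_state(net, law, scenario_spec(), bc)
    E_tot <- sol$E_ad + sol$E_ab
    # conservation: surface flux equals integrated membrane exchange
    exch <- sum(sol$membrane_exchange * sol$node_volume) * 1e3
    expect_lt(abs(E_tot - exch) / E_tot, 1e-9)
    # series-network reduction (linearization-consistent quantities)
    cf <- two_node_closed_form(sol$g_oxz_lin, gs, sol$w_xyl_lin, sol$w_a)
    expect_equal(cf$w_ssc, sol$w_ssc_lin_ad, tolerance = 1e-10)
    expect_equal(cf$E, sol$E_ad, tolerance = 1e-10 * sol$E_ad)
  }
})

test_that("closed-form two-node network has the stated limits", {
  tn <- two_node_closed_form(2500, 250, 0.0313, 0.012)
  expect_equal(tn$w_ssc, 0.0295454545, tolerance = 1e-8)
  expect_equal(tn$delta_w, 0.1 / 1.1, tolerance = 1e-10)
  # infinite upstream conductance saturates the interior
  expect_equal(two_node_closed_form(1e12, 250, 0.0313, 0.012)$w_ssc, 0.0313,
    tolerance = 1e-9
  )
  # closed stomata shut down the flux
  tn0 <- two_node_closed_form(2500, 1e-12, 0.0313, 0.012)
  expect_lt(tn0$E, 1e-10)
  expect_equal(tn0$w_ssc, 0.0313, tolerance = 1e-9)
})

test_that("profiles collapse and g_oxz saturates as membrane conductance diverges", {
  law <- membrane_law()
  bc <- bc_at(-0.85, vpd = 4.2)
  big1 <- membrane_law(law$kappa_max * 1e6, law$kappa_max * 1e6 / 2, law$psi_50, law$slope)
  big2 <- membrane_law(law$kappa_max * 1e7, law$kappa_max * 1e7 / 2, law$psi_50, law$slope)
  s1 <- solve_steady_state(small_net(), big1, scenario_spec(), bc)
  s2 <- solve_steady_state(small_net(), big2, scenario_spec(), bc)
  expect_lt(max(abs(s1$psi_cc - s1$psi_apo)), 1e-3)
  # the limit conductance no longer depends on kappa
  expect_equal(s1$g_oxz, s2$g_oxz, tolerance = 1e-4)
})

test_that("symmetric forcing yields profiles symmetric about the mid-plane", {
  sol <- solve_steady_state(
    small_net(), membrane_law(), scenario_spec(), bc_at(-0.85)
  )
  expect_equal(sol$psi_cc, rev(sol$psi_cc), tolerance = 1e-10)
  expect_equal(sol$psi_apo, rev(sol$psi_apo), tolerance = 1e-10)
  expect_equal(sol$E_ad, sol$E_ab, tolerance = 1e-10)
})

test_that("g_oxz increases with each transport coefficient", {
  law <- membrane_law()
  base <- solve_steady_state(small_net(), law, scenario_spec(), bc_at(-0.85))$g_oxz
  up_kcc <- solve_steady_state(
    small_net(k_cc = 1.2e-6), law, scenario_spec(), bc_at(-0.85)
  )$g_oxz
  up_kvap <- solve_steady_state(
    small_net(k_vap = 3.6e-7), law, scenario_spec(), bc_at(-0.85)
  )$g_oxz
  up_kappa <- solve_steady_state(
    small_net(),
    membrane_law(law$kappa_max * 1.2, law$kappa_min * 1.2, law$psi_50, law$slope),
    scenario_spec(), bc_at(-0.85)
  )$g_oxz
  expect_gt(up_kcc, base)
  expect_gt(up_kvap, base)
  expect_gt(up_kappa, base)
})

test_that("obstructed abaxial surface gives a monotone vapor gradient", {
  bc <- boundary_conditions(-1.2, air_state_from_vpd(4.2, 303.15),
    gs_ad = 90, gs_ab = 0
  )
  sol <- solve_steady_state(leaf_network(), membrane_law(), scenario_spec(), bc)
  expect_equal(sol$E_ab, 0)
  expect_gt(sol$E_ad, 0)
  # potential falls monotonically from the taped abaxial side (z = L)
  # toward the transpiring adaxial surface (z = 0)
  expect_true(all(diff(sol$psi_apo) >= -1e-12))
})

test_that("response curves flag constancy and recovery correctly", {
  flat <- membrane_law(
    kappa_max = 2e-4, kappa_min = 2e-4 * (1 - 1e-9),
    psi_50 = -0.8, slope = 0.2
  )
  grid <- seq(-1.8, -0.2, by = 0.4)
  pred <- predict_response_curves(small_net(), flat, psi_grid = grid)
  # on the linearization-consistent scale the conductance of a fixed
  # network is exactly constant; the exact-Kelvin report varies only by
  # the curvature of the Kelvin relation (~1% over 2 MPa)
  g_lin <- vapply(grid, function(p) {
    solve_steady_state(small_net(), flat, scenario_spec(), bc_at(p))$g_oxz_lin
  }, numeric(1))
  expect_lt(diff(range(g_lin)) / mean(g_lin), 1e-9)
  expect_lt(diff(range(pred$g_oxz)) / mean(pred$g_oxz), 0.02)
  # g_oxz is non-decreasing in kappa at every grid point
  lo <- predict_response_curves(small_net(), membrane_law(), psi_grid = grid)
  hi_law <- local({
    l <- membrane_law()
    membrane_law(l$kappa_max * 2, l$kappa_min * 2, l$psi_50, l$slope)
  })
  hi <- predict_response_curves(small_net(), hi_law, psi_grid = grid)
  expect_true(all(hi$g_oxz >= lo$g_oxz))
  # at fixed gs the substomatal humidity declines monotonically with stress;
  # with a closure schedule it recovers at the most stressed grid point
  grid2 <- seq(-2, -0.2, by = 0.2)
  fix <- predict_response_curves(small_net(), membrane_law(), psi_grid = grid2)
  fix <- fix[order(fix$psi_xyl), ]
  expect_true(all(diff(fix$h_ssc) >= 0))
  sch <- predict_response_curves(small_net(), membrane_law(),
    psi_grid = grid2, gs_schedule = gs_schedule()
  )
  sch <- sch[order(sch$psi_xyl), ]
  expect_gt(sch$h_ssc[1], sch$h_ssc[2]) # recovery at -2 MPa
  expect_error(predict_response_curves(psi_grid = -3), "within")
})

test_that("scenario engine discriminates the four architectures", {
  scens <- lapply(c(
    "uniform_membrane", "symplasm_conductance",
    "wall_air_layer", "bundle_sheath_only"
  ), scenario_spec)
  cmp <- scenario_compare(scens,
    net = small_net(),
    psi_grid = seq(-1.8, -0.2, by = 0.4)
  )
  s <- cmp$summary
  rownames(s) <- s$scenario
  # a ~200 nm air-filled wall layer is a negligible series resistance
  expect_lt(
    abs(
      s["wall_air_layer", "min_g_oxz"] - s["uniform_membrane", "min_g_oxz"]
    ) / s["uniform_membrane", "min_g_oxz"],
    0.05
  )
  # declining symplasm conductance cannot produce interfacial disequilibrium
  expect_lt(
    s["symplasm_conductance", "max_disequilibrium_MPa"],
    0.1 * s["uniform_membrane", "max_disequilibrium_MPa"]
  )
  # membrane loss restricted to the bundle sheath drags the whole
  # downstream symplasm below the turgor loss point
  expect_true(s["bundle_sheath_only", "turgor_loss"])
  bs_sol <- solve_steady_state(
    small_net(), membrane_law(), scenario_spec("bundle_sheath_only"),
    bc_at(-1.4)
  )
  expect_lt(max(bs_sol$psi_cc), physical_constants()$turgor_loss_point)
  # the preferred scenario maintains turgor while deeply undersaturated
  expect_false(s["uniform_membrane", "turgor_loss"])
  expect_lt(s["uniform_membrane", "min_h_ssc"], 0.93)
  expect_error(scenario_compare(scens[1]), "at least two")
})
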