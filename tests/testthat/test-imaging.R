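test_that("calibration curves are monotone and exactly invertible", {
  cal <- calibration_curve()
  psi <- seq(-19.5, -0.5, by = 0.5)
  z <- cal_apply(cal, psi)
  expect_true(all(diff(z) > 0))
  expect_equal(cal_invert(cal, z), psi, tolerance = 1e-9)
  # tabulated variant with monotone interpolation
  tab <- calibration_curve(
    type = "table",
    table = data.frame(psi = seq(-20, 0, by = 2), zeta = seq(0.2, 0.8, length.out = 11))
  )
  expect_equal(cal_invert(tab, cal_apply(tab, -7)), -7, tolerance = 1e-6)
  expect_error(
    calibration_curve(
      type = "table",
      table = data.frame(psi = c(-3, -2, -1), zeta = c(0.5, 0.7, 0.6))
    ),
    "monotone"
  )
})

test_that("out-of-range pixels are counted, not propagated", {
  img <- generate_fret_image(psi_mean = -6, psi_sd = 0.5, zeta_noise_sd = 0, seed = 6)
  n_bad <- 40
  idx <- sample(length(img$zeta_map), n_bad)
  img$zeta_map[idx] <- 0.95 # beyond the calibration ceiling
  expect_message(psi <- zeta_to_psi_map(img), "40 pixel")
  expect_equal(attr(psi, "n_out_of_range"), n_bad)
  expect_equal(sum(is.na(psi)), n_bad)
})

test_that("histogram mode follows the documented binning rules", {
  set.seed(8)
  m <- matrix(rnorm(200 * 200, -11, 1), 200, 200)
  h <- psi_histogram(m)
  expect_lte(abs(h$mode - (-11)), 0.25)
  # bimodal: the heavier component wins
  mix <- matrix(c(rnorm(12000, -2, 0.3), rnorm(8000, -11, 0.3)), 100, 200)
  expect_lt(abs(psi_histogram(mix)$mode - (-2)), 0.5)
  # identical pixels: mode is the bin containing that value
  flat <- matrix(-6.1, 20, 20)
  expect_lt(abs(psi_histogram(flat)$mode - (-6.1)), 0.25)
  expect_error(psi_histogram(matrix(-5, 5, 5)), "at least 100")
  # masking restricts the pixels used
  m2 <- m
  m2[1:100, ] <- -3
  mask <- matrix(FALSE, 200, 200)
  mask[101:200, ] <- TRUE
  expect_lte(abs(psi_histogram(m2, mask = mask)$mode - (-11)), 0.25)
})

test_that("mode recovery works across seeds at moderate pixel noise", {
  cal <- calibration_curve()
  for (seed in 1:6) {
    img <- generate_fret_image(
      psi_mean = -6, psi_sd = 0.5, zeta_noise_sd = 0.002, seed = seed
    )
    psi <- zeta_to_psi_map(img, cal)
    expect_lte(
      abs(psi_histogram(psi)$mode - psi_histogram(img$truth$psi_map)$mode),
      0.25
    )
  }
})

test_that("morphometrics match shape oracles and scale invariance", {
  # disk: circularity near 1 (4*pi*A/P^2 = 1 in the continuum limit)
  disk <- disk_mask(20)
  md <- cell_morphometrics(masks = disk, autofluorescence = disk)
  expect_gte(md$circularity, 0.95)
  expect_equal(md$area_um2, sum(disk))
  # axis-aligned square: circularity near pi/4
  sq <- square_mask(40)
  ms <- cell_morphometrics(masks = sq, autofluorescence = sq)
  expect_lt(abs(ms$circularity - pi / 4), 0.05)
  # circularity is scale invariant within discretisation error
  d2 <- disk_mask(35)
  md2 <- cell_morphometrics(masks = d2, autofluorescence = d2)
  expect_lt(abs(md2$circularity - md$circularity) / md$circularity, 0.02)
  # pixel size propagates quadratically to area, linearly to perimeter
  md_um <- cell_morphometrics(masks = disk, autofluorescence = disk, pixel_size = 0.5)
  expect_equal(md_um$area_um2, md$area_um2 * 0.25)
  expect_equal(md_um$perimeter_um, md$perimeter_um * 0.5)
})

test_that("segmentation finds the rendered cells and skips the border", {
  img <- generate_fret_image(n_cells = 16, shape = c(160, 160), seed = 9)
  morph <- cell_morphometrics(img)
  expect_equal(nrow(morph), 16)
  # a cell touching the border is excluded
  m <- matrix(0, 60, 60)
  m[(row(m) - 30)^2 + (col(m) - 30)^2 <= 100] <- 1
  m[(row(m) - 2)^2 + (col(m) - 30)^2 <= 64] <- 1
  labs <- EBImage::bwlabel(m)
  got <- cell_morphometrics(masks = EBImage::imageData(labs), autofluorescence = m)
  expect_equal(nrow(got), 1)
  expect_warning(
    empty <- cell_morphometrics(matrix(0.5, 50, 50) + 0),
    "no segmentable"
  )
  expect_equal(nrow(empty), 0)
})

test_that("group comparison reproduces the expected significance patterns", {
  set.seed(21)
  g <- function(cond, mu) {
    data.frame(condition = cond, area_um2 = rnorm(25, mu, 5), circularity = rnorm(25, 0.9, 0.02))
  }
  # identical groups: nothing significant
  same <- rbind(g("a", 100), g("b", 100), g("c", 100))
  cmp <- group_compare(same)
  expect_false(any(cmp$area_um2$pairs$significant))
  expect_true(all(cmp$area_um2$letters == cmp$area_um2$letters[1]))
  # widely separated groups: everything significant
  far <- rbind(g("a", 100), g("b", 150), g("c", 200))
  cmp2 <- group_compare(far)
  expect_true(all(cmp2$area_um2$pairs$significant))
  expect_equal(length(unique(cmp2$area_um2$letters)), 3)
  # one outlier group partitions as {a, a, b}
  onebig <- rbind(g("g1", 100), g("g2", 101), g("g3", 160))
  cmp3 <- group_compare(onebig)
  lt <- cmp3$area_um2$letters
  expect_equal(lt[["g1"]], lt[["g2"]])
  expect_false(lt[["g3"]] == lt[["g1"]])
  # degenerate variance is flagged, not tested
  dg <- rbind(
    data.frame(condition = "a", area_um2 = rep(5, 10)),
    data.frame(condition = "b", area_um2 = rnorm(10, 6))
  )
  expect_true(group_compare(dg, metrics = "area_um2")$area_um2$degenerate)
  expect_error(group_compare(same[same$condition == "a", ]), "two conditions")
})

test_that("turgid and cut fixtures separate in area and circularity", {
  cells_t <- data.frame(
    cx = rep(seq(30, 170, by = 28), times = 5),
    cy = rep(seq(30, 142, by = 28), each = 6),
    r = 11 + (0:29 %% 5) * 0.6, # radius spread for non-degenerate variance
    turgid = TRUE
  )[1:25, ]
  cells_c <- transform(cells_t, turgid = FALSE)
  img_t <- generate_fret_image(shape = c(172, 200), cells = cells_t, seed = 13)
  img_c <- generate_fret_image(shape = c(172, 200), cells = cells_c, seed = 14)
  mt <- cell_morphometrics(img_t)
  mc <- cell_morphometrics(img_c)
  expect_gte(nrow(mt), 20)
  expect_gte(nrow(mc), 20)
  both <- rbind(
    cbind(condition = "intact", mt),
    cbind(condition = "cut", mc)
  )
  cmp <- group_compare(both)
  expect_true(cmp$area_um2$pairs$significant)
  expect_true(cmp$circularity$pairs$significant)
  # direction: cut cells are smaller and less circular
  expect_lt(mean(mc$area_um2), mean(mt$area_um2))
  expect_lt(mean(mc$circularity), mean(mt$circularity))
})
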