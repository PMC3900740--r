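test_that("resampling preserves density and is the identity on equal cells", {
  fix <- default_fixture()
  map <- synthesize_map(structure_factors(fix$models$apo, 6), c(64, 80))
  same <- resample_common_cell(map, map$cell)
  expect_equal(same$grid, map$grid, tolerance = 1e-10)
  # constant maps stay constant under any compatible resampling
  const <- diffmap2d:::new_projection_map(matrix(3.3, 32, 40),
                                          unit_cell_2d(81.2, 104.2))
  rs <- resample_common_cell(const, unit_cell_2d(80.6, 107.9))
  expect_equal(range(rs$grid), c(3.3, 3.3))
  # measured cell change: mean density preserved within 1%
  raster <- rasterize_model(fix$models$apo, c(64, 80))
  rs2 <- resample_common_cell(raster, unit_cell_2d(80.6, 107.9))
  expect_lt(abs(rs2$mean - raster$mean) / raster$mean, 0.01)
  expect_error(resample_common_cell(map, unit_cell_2d(50, 104.2)),
               "tolerance")
})

test_that("map subtraction is exact and antisymmetric", {
  fix <- default_fixture()
  a <- synthesize_map(structure_factors(fix$models$apo, 6), c(64, 80))
  b0 <- synthesize_map(structure_factors(fix$models$bound, 6), c(64, 80))
  b <- resample_common_cell(b0, a$cell)
  expect_equal(max(abs(subtract_maps(a, a)$grid)), 0)
  ab <- subtract_maps(a, b)
  ba <- subtract_maps(b, a)
  expect_equal(ab$grid, -ba$grid)
  small <- synthesize_map(structure_factors(fix$models$apo, 6), c(32, 40))
  expect_error(subtract_maps(a, small), "grid")
})

test_that("the strongest difference pair localizes to the 5c/12e region", {
  fix <- default_fixture()
  a <- synthesize_map(structure_factors(fix$models$apo, 6), c(128, 160))
  b <- resample_common_cell(
    synthesize_map(structure_factors(fix$models$bound, 6), c(128, 160)),
    a$cell)
  d <- subtract_maps(b, a, contour_step = 0.01)
  span <- vapply(fix$regions, function(r) {
    m <- diffmap2d:::region_mask(r, d$cell, dim(d$grid))
    max(d$grid[m]) - min(d$grid[m])
  }, numeric(1))
  # the moving pair gives the deepest positive/negative couple of all sets
  expect_equal(names(which.max(span)), "set1_5c12e")
})

test_that("half-split controls calibrate step and background", {
  fix <- default_fixture()
  sf <- structure_factors(fix$models$apo, 6)
  # identical noiseless lattices: zero control, fallback step, background 0
  lats0 <- list(simulate_lattice(sf, 0, seed = 1),
                simulate_lattice(sf, 0, seed = 2))
  ctrl0 <- half_split_control(lats0, seed = 1, grid = c(64, 80))
  expect_equal(max(abs(ctrl0$diff$grid)), 0, tolerance = 1e-12)
  expect_equal(ctrl0$contour_step, 1e-9)
  expect_equal(ctrl0$background_levels, 0L)
  # six noisy lattices at the default calibration: +/- 2 levels
  cond <- simulate_condition(fix$models$apo, fix$models$bound,
                             default_binding(8), 0, n_lattices = 6,
                             seed = 11)
  ctrl <- half_split_control(cond, seed = 3)
  expect_equal(ctrl$background_levels, 2L)
  expect_equal(ctrl$contour_step, 1.5 * ctrl$sigma_control)
  expect_error(half_split_control(cond[1]), "at least 2")
})

test_that("control noise shrinks ~sqrt(2) with twice the lattices and ignores occupancy", {
  fix <- default_fixture()
  p <- default_binding(8)
  sig <- function(n, na_mM, seeds) {
    vapply(seeds, function(s) {
      cond <- simulate_condition(fix$models$apo, fix$models$bound, p,
                                 na_mM, n_lattices = n, seed = s)
      half_split_control(cond, seed = s, grid = c(64, 80))$sigma_control
    }, numeric(1))
  }
  s6 <- sig(6, 0, 1:6)
  s12 <- sig(12, 0, 1:6)
  expect_gt(mean(s6) / mean(s12), sqrt(2) * 0.75)
  expect_lt(mean(s6) / mean(s12), sqrt(2) * 1.35)
  # background is blind to the conformational state on the lattice
  s6_hi <- sig(6, 500, 7:12)
  expect_lt(abs(mean(s6_hi) - mean(s6)) / mean(s6), 0.25)
})

test_that("contour counting applies the absolute step with floors", {
  fix <- default_fixture()
  reg <- fix$regions$set2_TMH6
  cell <- test_cell()
  d <- synthetic_diff_map(reg, cell, max_steps = 4.6, min_steps = -3.2)
  cc <- count_contours(d, reg)
  expect_equal(cc$positive_levels, 4L)
  expect_equal(cc$negative_levels, 3L)
  expect_equal(cc$peak_to_trough, 7L)
  # zero map
  z <- d; z$grid[] <- 0
  cz <- count_contours(z, reg)
  expect_equal(cz$peak_to_trough, 0L)
  # negation swaps the counts
  n <- d; n$grid <- -d$grid
  cn <- count_contours(n, reg)
  expect_equal(cn$positive_levels, cc$negative_levels)
  expect_equal(cn$negative_levels, cc$positive_levels)
  expect_equal(cn$peak_to_trough, cc$peak_to_trough)
  bad <- d; bad$contour_step <- NA_real_
  expect_error(count_contours(bad, reg), "contour step")
})

test_that("background correction floors at zero and needs all regions", {
  tc <- titration_counts(na_mM = c(0, 0, 100, 100),
                         region = rep(c("a", "b"), 2),
                         positive = c(1, 1, 5, 2), negative = c(1, 1, 2, 0),
                         pH = 8)
  out <- background_correct(tc, c(a = 2L, b = 2L))
  expect_equal(out$corrected, c(0L, 0L, 5L, 0L))
  ident <- background_correct(tc, c(a = 0L, b = 0L))
  expect_equal(ident$corrected, tc$peak_to_trough)
  expect_error(background_correct(tc, c(a = 2L)), "control")
})

test_that("regions are disjoint and confined to one protomer", {
  fix <- default_fixture()
  cell <- test_cell()
  masks <- lapply(fix$regions, function(r)
    diffmap2d:::region_mask(r, cell, c(128, 160)))
  overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_lte(max(overlap), 1L)
  # every region center sits within the protomer footprint (not the mate's)
  for (r in fix$regions) {
    expect_true(all(r$center > c(0, 0)))
    expect_true(all(r$center < c(cell$a / 2 + 5, cell$b / 2)))
  }
})

test_that("displacement estimation recovers designed shifts", {
  fix <- default_fixture()
  reg <- fix$regions$set1_5c12e
  a <- synthesize_map(structure_factors(fix$models$apo, 6), c(128, 160))
  expect_equal(estimate_displacement(a, a, reg), 0, tolerance = 1e-9)
  est <- vapply(c(1, 2, 3), function(s) {
    m <- default_models(shift_5c12e = s)
    sa <- synthesize_map(structure_factors(m$apo, 6), c(128, 160))
    sb <- resample_common_cell(
      synthesize_map(structure_factors(m$bound, 6), c(128, 160)), sa$cell)
    estimate_displacement(sa, sb, reg)
  }, numeric(1))
  expect_equal(est[2], 2, tolerance = 0.1)        # 2 A design shift
  expect_lt(abs(est[1] - 1) / 1, 0.1)             # <10% noiseless bias
  expect_lt(abs(est[3] - 3) / 3, 0.1)
  expect_true(all(diff(est) > 0))                 # monotone ordering
  # detection error when the region holds no density above threshold
  flat <- a; flat$grid[] <- 0; flat$sigma <- 1; flat$mean <- 0
  expect_error(estimate_displacement(flat, a, reg), "peak")
})
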