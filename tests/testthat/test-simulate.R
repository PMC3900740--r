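test_that("a noise-free lattice with no offset or scale is the input", {
  fix <- default_fixture()
  sf <- structure_factors(fix$models$apo, 6)
  lat <- simulate_lattice(sf, noise_sigma = 0, origin_offset = c(0, 0),
                          amp_scale = 1, seed = 1)
  expect_equal(lat$sf$hk, sf$hk)
})

test_that("a half-cell origin offset flips the phase of (1,0)", {
  fix <- default_fixture()
  sf <- structure_factors(fix$models$apo, 6)
  lat <- simulate_lattice(sf, 0, origin_offset = c(0.5, 0))
  i <- which(sf$hk$h == 1 & sf$hk$k == 0)
  expect_equal(diffmap2d:::wrap_deg(lat$sf$hk$phase[i] - sf$hk$phase[i]),
               180, tolerance = 1e-9)
  # and reflections with even h are untouched by it
  j <- which(sf$hk$h == 2 & sf$hk$k == 0)
  expect_equal(diffmap2d:::wrap_deg(lat$sf$hk$phase[j] - sf$hk$phase[j]),
               0, tolerance = 1e-9)
})

test_that("noisy amplitudes follow the Rician expectation", {
  # sampling oracle: >= 1e4 Rician draws against the closed-form mean
  cell <- unit_cell_2d(200, 200)
  idx <- reflection_indices(cell, 8)[1:500, ]
  nu <- 10; sigma <- 4
  sf <- sfset(cell, 8, idx$h, idx$k, rep(nu, 500),
              (7 * seq_len(500)) %% 360)
  draws <- unlist(lapply(1:25, function(s)
    simulate_lattice(sf, noise_sigma = sigma, seed = s)$sf$hk$amp))
  t <- nu^2 / (2 * sigma^2)
  rician_mean <- sigma * sqrt(pi / 2) * exp(-t / 2) *
    ((1 + t) * besselI(t / 2, 0) + t * besselI(t / 2, 1))
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_gt(length(draws), 1e4)
  expect_lt(abs(mean(draws) - rician_mean), 4 * se)
})

test_that("identical seeds reproduce bit-identical lattices", {
  fix <- default_fixture()
  sf <- structure_factors(fix$models$apo, 6)
  a <- simulate_lattice(sf, 3, origin_offset = c(0.2, 0.4),
                        amp_scale = 1.1, seed = 99)
  b <- simulate_lattice(sf, 3, origin_offset = c(0.2, 0.4),
                        amp_scale = 1.1, seed = 99)
  expect_identical(a$sf$hk, b$sf$hk)
  c1 <- simulate_condition(fix$models$apo, fix$models$bound,
                           default_binding(8), 100, n_lattices = 4,
                           seed = 21)
  c2 <- simulate_condition(fix$models$apo, fix$models$bound,
                           default_binding(8), 100, n_lattices = 4,
                           seed = 21)
  expect_identical(lapply(c1, function(l) l$sf$hk),
                   lapply(c2, function(l) l$sf$hk))
  # and simulation does not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(1)
  set.seed(5)
  invisible(simulate_condition(fix$models$apo, fix$models$bound,
                               default_binding(8), 100, n_lattices = 2,
                               seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("noise-free condition lattices are identical up to origin and scale", {
  fix <- default_fixture()
  lat <- simulate_condition(fix$models$apo, fix$models$bound,
                            default_binding(8), 250, n_lattices = 6,
                            noise_sigma = 0, noise_frac = 0, seed = 7)
  expect_length(lat, 6)
  base <- lat[[1]]
  for (l in lat[-1]) {
    # undo the recorded offset and scale: amplitudes and phases must match
    z <- diffmap2d:::sf_complex(l$sf) / l$amp_scale *
      exp(2i * pi * (l$sf$hk$h * l$origin_offset[1] +
                       l$sf$hk$k * l$origin_offset[2]))
    z0 <- diffmap2d:::sf_complex(base$sf) / base$amp_scale *
      exp(2i * pi * (base$sf$hk$h * base$origin_offset[1] +
                       base$sf$hk$k * base$origin_offset[2]))
    expect_equal(z, z0, tolerance = 1e-10)
  }
})

test_that("occupancy ladder is monotone and non-substrate ions stay apo", {
  fix <- default_fixture()
  p <- default_binding(8)
  ladder <- c(0, 20, 50, 100, 250, 500)
  th <- vapply(ladder, function(c0) {
    attr(simulate_condition(fix$models$apo, fix$models$bound, p, c0,
                            n_lattices = 1, noise_sigma = 0,
                            noise_frac = 0, seed = 1), "truth")$theta
  }, numeric(1))
  expect_true(all(diff(th) > 0))
  expect_equal(th, occupancy(ladder, p))
  # Mg2+ never switches the conformation
  mg <- simulate_condition(fix$models$apo, fix$models$bound, p, 500,
                           n_lattices = 1, noise_sigma = 0, noise_frac = 0,
                           ion = "Mg2+", seed = 1)
  expect_equal(attr(mg, "truth")$theta, 0)
  apo_sf <- structure_factors(fix$models$apo, 6)
  expect_equal(mg[[1]]$sf$hk$amp / mg[[1]]$amp_scale,
               apo_sf$hk$amp, tolerance = 1e-9)
})

test_that("argument errors are caught", {
  fix <- default_fixture()
  sf <- structure_factors(fix$models$apo, 6)
  expect_error(simulate_lattice(sf, noise_sigma = -1), "non-negative")
  expect_error(simulate_lattice(sf, amp_scale = 0), "positive")
  expect_error(simulate_condition(fix$models$apo, fix$models$bound,
                                  default_binding(8), 100, n_lattices = 0),
               "at least 1")
})
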