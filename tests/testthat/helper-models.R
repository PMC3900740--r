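# Shared fixtures: built in code, kept small so the suite stays fast.

test_cell <- function() unit_cell_2d(81.2, 104.2)

# A small asymmetric p1 model (3 rods) for transform oracles.
three_rod_model <- function(seed = 1, cell = unit_cell_2d(40, 50, 95)) {
  with_seed <- diffmap2d:::with_seed
  rods <- with_seed(seed, lapply(1:3, function(i) {
    helix_rod(paste0("r", i),
              center = c(stats::runif(1, 5, 35), stats::runif(1, 5, 45)),
              cov = diffmap2d:::rod_cov(stats::runif(1, 2.5, 4.5),
                                        stats::runif(1, 2, 3),
                                        stats::runif(1, 0, 180)),
              mass = stats::runif(1, 50, 150))
  }))
  conformation_model("apo", rods, cell, symmetry = "p1")
}

# Complex structure factors as a named vector keyed by "h k".
sf_as_complex <- function(sf) {
  z <- sf$hk$amp * exp(1i * sf$hk$phase * pi / 180)
  names(z) <- paste(sf$hk$h, sf$hk$k)
  z
}

# Relative RMS disagreement between two sfsets sharing indices.
sf_rel_rms <- function(a, b) {
  za <- sf_as_complex(a)
  zb <- sf_as_complex(b)
  common <- intersect(names(za), names(zb))
  sqrt(mean(Mod(za[common] - zb[common])^2)) /
    sqrt(mean(Mod(zb[common])^2))
}

# Default two-state models and regions, computed once per test file.
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(models = default_models(), regions = default_regions())
    }
    cache
  }
})

# A synthetic difference map with prescribed extremes inside a region.
synthetic_diff_map <- function(region, cell, grid = c(64, 80),
                               max_steps, min_steps, step = 0.1) {
  g <- matrix(0, grid[1], grid[2])
  mask <- diffmap2d:::region_mask(region, cell, grid)
  idx <- which(mask, arr.ind = TRUE)
  g[idx[1, 1], idx[1, 2]] <- max_steps * step
  g[idx[nrow(idx), 1], idx[nrow(idx), 2]] <- min_steps * step
  structure(list(grid = g, cell = cell, contour_step = step,
                 background_levels = 0L,
                 sigma = stats::sd(as.numeric(g))),
            class = "difference_map")
}
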