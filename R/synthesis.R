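#' Projection map
#'
#' Gridded real-space density over one unit cell, in absolute density
#' units, annotated with its mean and standard deviation. Grid element
#' `[i, j]` sits at fractional coordinates `((i-1)/nx, (j-1)/ny)`.
#'
#' @param grid Numeric `nx x ny` matrix of density values.
#' @param cell A [unit_cell_2d()].
#' @return An object of class `projection_map` with fields `grid`, `cell`,
#'   `mean`, `sigma`.
#' @name projection_map
NULL

new_projection_map <- function(grid, cell) {
  stopifnot(is.matrix(grid), nrow(grid) >= 2, ncol(grid) >= 2)
  structure(list(grid = grid, cell = cell,
                 mean = mean(grid), sigma = stats::sd(as.numeric(grid))),
            class = "projection_map")
}

#' @export
print.projection_map <- function(x, ...) {
  cat(sprintf(
    "projection map: %d x %d grid, cell %s, mean %.4g, sigma %.4g\n",
    nrow(x$grid), ncol(x$grid), format(x$cell), x$mean, x$sigma))
  invisible(x)
}

#' Fourier synthesis of a projection map
#'
#' Inverse Fourier synthesis of a reflection list: Friedel mates are
#' completed so the map is real, and the result is normalized by the cell
#' area (a single reflection of amplitude A and phase 0 gives a cosine wave
#' peaking at 2A / area at the origin). The (0,0) term is absent, so maps
#' have zero mean.
#'
#' @param sf An [sfset()].
#' @param grid Integer pair `(nx, ny)`; must oversample the resolution
#'   cutoff (all indices strictly inside the Nyquist box).
#' @return A [projection_map].
#' @export
synthesize_map <- function(sf, grid = c(128, 160)) {
  stopifnot(inherits(sf, "sfset"))
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  if (nx < 2 || ny < 2) stop("grid must be at least 2 x 2")
  if (nrow(sf$hk) > 0 &&
      (max(abs(sf$hk$h)) >= nx / 2 || max(abs(sf$hk$k)) >= ny / 2))
    stop("grid below the Nyquist limit for this reflection list")
  G <- matrix(0 + 0i, nx, ny)
  z <- sf_complex(sf)
  ih <- sf$hk$h %% nx + 1L
  ik <- sf$hk$k %% ny + 1L
  G[cbind(ih, ik)] <- z
  ihm <- (-sf$hk$h) %% nx + 1L
  ikm <- (-sf$hk$k) %% ny + 1L
  G[cbind(ihm, ikm)] <- Conj(z)
  rho <- Re(stats::fft(G, inverse = TRUE)) / cell_area(sf$cell)
  new_projection_map(rho, sf$cell)
}

#' Fourier analysis of a projection map
#'
#' Forward transform of a gridded map back to a reflection list (the exact
#' inverse of [synthesize_map()] on band-limited input). Used as the FFT
#' route when deriving structure factors from rasterized model densities.
#'
#' @param map A [projection_map].
#' @param d_min Resolution cutoff in Angstrom.
#' @return An [sfset()].
#' @export
analyze_map <- function(map, d_min) {
  stopifnot(inherits(map, "projection_map"), d_min > 0)
  nx <- nrow(map$grid); ny <- ncol(map$grid)
  idx <- reflection_indices(map$cell, d_min)
  if (max(idx$h) >= nx / 2 || max(abs(idx$k)) >= ny / 2)
    stop("map grid below the Nyquist limit for d_min")
  Fg <- stats::fft(map$grid) * cell_area(map$cell) / (nx * ny)
  z <- Fg[cbind(idx$h %% nx + 1L, idx$k %% ny + 1L)]
  sfset(map$cell, d_min, idx$h, idx$k, Mod(z), (Arg(z) * 180 / pi) %% 360)
}

#' Occupancy-mixed real-space density
#'
#' Pointwise two-state mixture `(1 - theta) rho_apo + theta rho_bound` on a
#' common fractional grid, with the unit cell interpolated linearly in
#' `theta` (the lattice relaxes gradually as sodium occupancy rises).
#'
#' @param apo,bound [conformation_model()] objects sharing rod ids.
#' @param theta Bound-state occupancy in `[0, 1]`.
#' @param grid Integer pair `(nx, ny)`.
#' @return A [projection_map] on the interpolated cell.
#' @export
mixture_density <- function(apo, bound, theta, grid = c(128, 160)) {
  check_state_pair(apo, bound, theta)
  ra <- rasterize_model(apo, grid)
  rb <- rasterize_model(bound, grid)
  cell <- interp_cell(apo$cell, bound$cell, theta)
  new_projection_map((1 - theta) * ra$grid + theta * rb$grid, cell)
}
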