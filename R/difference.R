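#' Resample a projection map onto a target unit cell
#'
#' Places one unit cell of density into a (slightly) different target cell:
#' the density is interpolated bilinearly in fractional coordinates with
#' periodic wrapping onto the target grid. Used before subtraction when
#' the lattice constants drift with occupancy.
#'
#' @param map A [projection_map].
#' @param target A [unit_cell_2d()]; must agree with the source cell within
#'   `tol` per axis.
#' @param grid Target grid, default the source grid dimensions.
#' @param tol Relative per-axis cell tolerance (default 0.1).
#' @return A [projection_map] on the target cell.
#' @export
resample_common_cell <- function(map, target, grid = dim(map$grid),
                                 tol = 0.1) {
  stopifnot(inherits(map, "projection_map"), inherits(target, "unit_cell_2d"))
  if (!cells_compatible(map$cell, target, tol))
    stop("source and target cells differ by more than the tolerance")
  nx <- nrow(map$grid); ny <- ncol(map$grid)
  mx <- as.integer(grid[1]); my <- as.integer(grid[2])
  u <- (seq_len(mx) - 1) / mx
  v <- (seq_len(my) - 1) / my
  gu <- u * nx; gv <- v * ny
  i0 <- floor(gu); j0 <- floor(gv)
  fu <- gu - i0; fv <- gv - j0
  i1 <- (i0 + 1L) %% nx; i0 <- i0 %% nx
  j1 <- (j0 + 1L) %% ny; j0 <- j0 %% ny
  G <- map$grid
  A11 <- G[cbind(rep(i0 + 1, my), rep(j0 + 1, each = mx))]
  A21 <- G[cbind(rep(i1 + 1, my), rep(j0 + 1, each = mx))]
  A12 <- G[cbind(rep(i0 + 1, my), rep(j1 + 1, each = mx))]
  A22 <- G[cbind(rep(i1 + 1, my), rep(j1 + 1, each = mx))]
  WU <- rep(fu, my); WV <- rep(fv, each = mx)
  out <- (1 - WU) * (1 - WV) * A11 + WU * (1 - WV) * A21 +
    (1 - WU) * WV * A12 + WU * WV * A22
  new_projection_map(matrix(out, mx, my), target)
}

#' Difference map between two projection maps
#'
#' Pointwise `a - b` of two maps already on the same cell and grid (with
#' `b` amplitude-scaled to `a` upstream). The contour step and background
#' level are inherited from the half-split control calibration of the
#' analysis, so all condition difference maps are plotted and counted with
#' the same absolute parameters.
#'
#' @param a,b [projection_map]s on identical grids and compatible cells.
#' @param contour_step Absolute density units per contour level (from
#'   [half_split_control()]).
#' @param background_levels Integer background level of the control.
#' @return An object of class `difference_map` with fields `grid`, `cell`,
#'   `contour_step`, `background_levels`, `sigma`.
#' @export
subtract_maps <- function(a, b, contour_step = NA_real_,
                          background_levels = NA_integer_) {
  stopifnot(inherits(a, "projection_map"), inherits(b, "projection_map"))
  if (!all(dim(a$grid) == dim(b$grid)))
    stop("maps must share grid dimensions")
  if (!cells_compatible(a$cell, b$cell, 0.01))
    stop("maps must be on the same target cell")
  g <- a$grid - b$grid
  structure(list(grid = g, cell = a$cell,
                 contour_step = contour_step,
                 background_levels = background_levels,
                 sigma = stats::sd(as.numeric(g))),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat(sprintf(
    "difference map: %d x %d, sigma %.4g, contour step %.4g, background %s\n",
    nrow(x$grid), ncol(x$grid), x$sigma, x$contour_step,
    format(x$background_levels)))
  invisible(x)
}

#' Half-split noise control
#'
#' Randomly divides the lattices of one condition into two halves, merges
#' and synthesizes each half, and subtracts them. Because both halves see
#' the same conformational state, the control difference map contains pure
#' noise; its standard deviation calibrates the absolute contour step
#' (1.5 sigma of the control) applied to all condition difference maps, and
#' its strongest feature anywhere on the map sets the background level.
#'
#' @param lattices List of >= 2 lattice datasets from one condition.
#' @param seed Integer seed for the random partition.
#' @param grid Map grid.
#' @param min_step Lower bound for the contour step, used when the control
#'   is identically zero (noise-free input).
#' @return List with `diff` (a `difference_map` carrying the calibrated
#'   `contour_step` and `background_levels`), `contour_step`,
#'   `background_levels` and `sigma_control`.
#' @export
half_split_control <- function(lattices, seed = 1, grid = c(128, 160),
                               min_step = 1e-9) {
  if (length(lattices) < 2) stop("need at least 2 lattices for a control")
  n <- length(lattices)
  perm <- with_seed(seed, sample.int(n))
  half1 <- lattices[perm[seq_len(floor(n / 2))]]
  half2 <- lattices[perm[(floor(n / 2) + 1):n]]
  m1 <- merge_lattices(half1)
  m2 <- merge_lattices(half2)
  al <- align_phase_origin(m2$sf, m1$sf)
  k <- scale_amplitudes(al$sf, m1$sf)
  al$sf$hk$amp <- al$sf$hk$amp * k
  map1 <- synthesize_map(m1$sf, grid)
  map2 <- synthesize_map(al$sf, grid)
  map2 <- resample_common_cell(map2, map1$cell)
  d <- subtract_maps(map1, map2)
  step <- max(1.5 * d$sigma, min_step)
  bg <- as.integer(floor(max(abs(d$grid)) / step))
  d$contour_step <- step
  d$background_levels <- bg
  list(diff = d, contour_step = step, background_levels = bg,
       sigma_control = d$sigma)
}

#' Elliptical peak region
#'
#' A declared region of one protomer in which difference-peak contours are
#' counted: an ellipse in the Cartesian cell frame.
#'
#' @param id Region label, e.g. `"set1_5c12e"`.
#' @param center Length-2 center in Angstrom.
#' @param semi_axes Length-2 semi-axes in Angstrom.
#' @param rotation Major-axis angle in degrees from x.
#' @return An object of class `peak_region`.
#' @export
peak_region <- function(id, center, semi_axes, rotation = 0) {
  stopifnot(length(center) == 2, length(semi_axes) == 2,
            all(semi_axes > 0))
  structure(list(id = as.character(id), center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 rotation = as.numeric(rotation)),
            class = "peak_region")
}

#' @export
print.peak_region <- function(x, ...) {
  cat(sprintf(
    "peak region '%s': center (%.1f, %.1f) A, semi-axes (%.1f, %.1f), rot %.0f deg\n",
    x$id, x$center[1], x$center[2], x$semi_axes[1], x$semi_axes[2],
    x$rotation))
  invisible(x)
}

# Logical mask of grid pixels inside the region (minimal periodic image
# relative to the region center).
region_mask <- function(region, cell, grid) {
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  M <- cell_matrix(cell)
  fu <- (seq_len(nx) - 1) / nx
  fv <- (seq_len(ny) - 1) / ny
  cf <- solve(M, region$center)
  DU <- wrap_frac(outer(fu - cf[1], rep(1, ny)))
  DV <- wrap_frac(outer(rep(1, nx), fv - cf[2]))
  DX <- M[1, 1] * DU + M[1, 2] * DV
  DY <- M[2, 1] * DU + M[2, 2] * DV
  a <- region$rotation * pi / 180
  U <- cos(a) * DX + sin(a) * DY
  V <- -sin(a) * DX + cos(a) * DY
  (U / region$semi_axes[1])^2 + (V / region$semi_axes[2])^2 <= 1
}

#' Default peak regions of the packaged rod model
#'
#' Ellipses placed from the ground-truth rod coordinates of
#' [default_models()]: the 5c/12e pair (set 1), TMH6 (set 2), TMH13 + 5e
#' (set 3), the 4/11/12c group left of the bundle, and the interface region
#' near TMH10 where order is gained.
#'
#' @return Named list of [peak_region()] objects.
#' @export
default_regions <- function() {
  list(
    set1_5c12e = peak_region("set1_5c12e", c(21.5, 26.7), c(8.5, 4.5),
                             rotation = -60.9),
    set2_TMH6 = peak_region("set2_TMH6", c(13.0, 39.5), c(5.0, 5.0)),
    set3_13_5e = peak_region("set3_13_5e", c(30.5, 32.0), c(8.3, 3.5),
                             rotation = 125),
    bundle_left_4_11_12c = peak_region("bundle_left_4_11_12c",
                                       c(9.2, 23.0), c(11.0, 4.0),
                                       rotation = 112.6),
    interface_gain = peak_region("interface_gain", c(31.5, 40.5),
                                 c(3.0, 3.0)))
}

#' Count contour levels in a region of a difference map
#'
#' Number of contour lines at the absolute, control-derived step: the
#' positive count is `floor(max(diff in region) / step)`, the negative
#' count `floor(-min(diff in region) / step)` (a contour at level n exists
#' only if the density reaches n steps), and peak-to-trough is their sum.
#'
#' @param diff A `difference_map` with a positive `contour_step`.
#' @param region A [peak_region()].
#' @return List of class `contour_count` with `region_id`,
#'   `positive_levels`, `negative_levels`, `peak_to_trough`.
#' @export
count_contours <- function(diff, region) {
  stopifnot(inherits(diff, "difference_map"), inherits(region, "peak_region"))
  if (!is.finite(diff$contour_step) || diff$contour_step <= 0)
    stop("difference map has no positive contour step")
  mask <- region_mask(region, diff$cell, dim(diff$grid))
  if (!any(mask)) stop("region mask is empty on this grid")
  vals <- diff$grid[mask]
  pos <- max(0L, as.integer(floor(max(vals) / diff$contour_step)))
  neg <- max(0L, as.integer(floor(-min(vals) / diff$contour_step)))
  structure(list(region_id = region$id, positive_levels = pos,
                 negative_levels = neg, peak_to_trough = pos + neg),
            class = "contour_count")
}

#' @export
print.contour_count <- function(x, ...) {
  cat(sprintf("contours in %s: +%d / -%d (peak-to-trough %d)\n",
              x$region_id, x$positive_levels, x$negative_levels,
              x$peak_to_trough))
  invisible(x)
}

#' Background-correct titration counts
#'
#' Subtracts the contour levels observed in the same regions of the
#' zero-sodium control difference map and floors at zero:
#' `corrected = max(0, raw - control)` per region and concentration.
#'
#' @param counts A titration counts data frame (see
#'   [titration_counts()]) with columns `region` and `peak_to_trough`.
#' @param control_counts Named integer vector of control counts per region.
#' @return The data frame with a `corrected` column added/updated.
#' @export
background_correct <- function(counts, control_counts) {
  missing <- setdiff(unique(counts$region), names(control_counts))
  if (length(missing))
    stop("no control count for region(s): ", paste(missing, collapse = ", "))
  counts$corrected <- pmax(0L, counts$peak_to_trough -
                             as.integer(control_counts[counts$region]))
  attr(counts, "corrected") <- TRUE
  counts
}

#' Estimate a helix displacement from two state maps
#'
#' Distance (Angstrom) between the intensity-weighted centroids of the
#' region's dominant density peak in two projection maps. The dominant peak
#' is located in the first map (it must exceed `threshold_sigma` map
#' sigmas), matched in the second map by the strongest density within
#' `track_radius` of it, and each peak's centroid is computed from the
#' density above half its height inside a local window of `local_radius`,
#' so the estimate follows the peak itself rather than a fixed window
#' (which would attenuate real shifts).
#'
#' @param state_a,state_b [projection_map]s on compatible cells and equal
#'   grids.
#' @param region A [peak_region()].
#' @param threshold_sigma Detection threshold in map sigmas (default 1).
#' @param local_radius Radius (Angstrom) of the centroid window around the
#'   peak (default 3, about one rod width; larger windows admit neighboring
#'   helix tails and inflate the estimate).
#' @param track_radius Maximum distance (Angstrom) at which the peak is
#'   matched between the maps (default 6; must stay below the inter-helix
#'   spacing).
#' @return Displacement in Angstrom.
#' @export
estimate_displacement <- function(state_a, state_b, region,
                                  threshold_sigma = 1, local_radius = 3,
                                  track_radius = 6) {
  stopifnot(all(dim(state_a$grid) == dim(state_b$grid)))
  pa <- dominant_peak(state_a, region, threshold_sigma)
  ca <- peak_centroid(state_a, pa, local_radius)
  pb <- nearby_peak(state_b, pa, track_radius, threshold_sigma)
  cb <- peak_centroid(state_b, pb, local_radius)
  d <- cart_delta(cb, ca, state_a$cell)
  sqrt(sum(d^2))
}

# Minimal-image Cartesian displacement from b to a.
cart_delta <- function(a, b, cell) {
  M <- cell_matrix(cell)
  df <- wrap_frac(as.numeric(solve(M, a - b)))
  as.numeric(M %*% df)
}

# Cartesian coordinates of all grid pixels.
grid_coords <- function(cell, grid) {
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  M <- cell_matrix(cell)
  fu <- (seq_len(nx) - 1) / nx
  fv <- (seq_len(ny) - 1) / ny
  F1 <- matrix(rep(fu, ny), nx, ny)
  F2 <- matrix(rep(fv, each = nx), nx, ny)
  list(X = M[1, 1] * F1 + M[1, 2] * F2, Y = M[2, 1] * F1 + M[2, 2] * F2)
}

# Location and height of the strongest pixel of a map inside a region.
dominant_peak <- function(map, region, threshold_sigma) {
  mask <- region_mask(region, map$cell, dim(map$grid))
  if (!any(mask)) stop("region mask is empty on this grid")
  g <- map$grid
  g[!mask] <- -Inf
  if (max(g) < map$mean + threshold_sigma * map$sigma)
    stop("no peak above threshold in region '", region$id, "'")
  ij <- which(g == max(g), arr.ind = TRUE)[1, ]
  xy <- grid_coords(map$cell, dim(map$grid))
  list(pos = c(xy$X[ij[1], ij[2]], xy$Y[ij[1], ij[2]]),
       height = map$grid[ij[1], ij[2]])
}

# Strongest pixel within `radius` Angstrom of a reference position.
nearby_peak <- function(map, ref_peak, radius, threshold_sigma) {
  xy <- grid_coords(map$cell, dim(map$grid))
  M <- cell_matrix(map$cell)
  cf <- solve(M, ref_peak$pos)
  nx <- nrow(map$grid); ny <- ncol(map$grid)
  DU <- wrap_frac(outer((seq_len(nx) - 1) / nx - cf[1], rep(1, ny)))
  DV <- wrap_frac(outer(rep(1, nx), (seq_len(ny) - 1) / ny - cf[2]))
  DX <- M[1, 1] * DU + M[1, 2] * DV
  DY <- M[2, 1] * DU + M[2, 2] * DV
  g <- map$grid
  g[DX^2 + DY^2 > radius^2] <- -Inf
  if (max(g) < map$mean + threshold_sigma * map$sigma)
    stop("no matching peak above threshold in the second map")
  ij <- which(g == max(g), arr.ind = TRUE)[1, ]
  list(pos = c(xy$X[ij[1], ij[2]], xy$Y[ij[1], ij[2]]),
       height = map$grid[ij[1], ij[2]])
}

# Intensity-weighted centroid of the density above half peak height within
# a local window around the peak, coordinates unwrapped around the peak.
peak_centroid <- function(map, peak, local_radius) {
  M <- cell_matrix(map$cell)
  nx <- nrow(map$grid); ny <- ncol(map$grid)
  cf <- solve(M, peak$pos)
  DU <- wrap_frac(outer((seq_len(nx) - 1) / nx - cf[1], rep(1, ny)))
  DV <- wrap_frac(outer(rep(1, nx), (seq_len(ny) - 1) / ny - cf[2]))
  DX <- M[1, 1] * DU + M[1, 2] * DV
  DY <- M[2, 1] * DU + M[2, 2] * DV
  w <- pmax(map$grid - 0.5 * peak$height, 0)
  w[DX^2 + DY^2 > local_radius^2] <- 0
  c(sum(w * DX), sum(w * DY)) / sum(w) + peak$pos
}
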