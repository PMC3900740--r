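#' Structure-factor set
#'
#' Container for a 2D reflection list: unique Miller indices (h, k) on one
#' Friedel hemisphere (h > 0, or h = 0 with k > 0), amplitudes and phases,
#' together with the unit cell and resolution cutoff. The (0,0) term is not
#' stored; synthesized maps are therefore mean-zero.
#'
#' Phase convention: the density is
#' `rho(u, v) = (1/A) * sum_hk F(h,k) exp(+2 pi i (h u + k v))`
#' over the full plane (Friedel mates implied), with fractional coordinates
#' (u, v) and cell area A, so shifting the density by fractional `t`
#' changes phases by `-360 (h t_x + k t_y)` degrees.
#'
#' @param cell A [unit_cell_2d()].
#' @param d_min Resolution cutoff in Angstrom.
#' @param h,k Integer Miller indices (hemisphere convention as above).
#' @param amp Non-negative amplitudes.
#' @param phase Phases in degrees (stored modulo 360).
#' @return An object of class `sfset`.
#' @export
sfset <- function(cell, d_min, h, k, amp, phase) {
  stopifnot(inherits(cell, "unit_cell_2d"), d_min > 0,
            length(h) == length(k), length(h) == length(amp),
            length(h) == length(phase))
  h <- as.integer(h); k <- as.integer(k)
  if (any(h < 0 | (h == 0 & k <= 0)))
    stop("reflections must lie on the hemisphere h > 0, or h = 0 with k > 0")
  if (anyDuplicated(cbind(h, k))) stop("duplicate (h,k) in reflection list")
  if (any(amp < 0)) stop("amplitudes must be non-negative")
  d <- resolution_hk(h, k, cell)
  if (any(d < d_min - 1e-9))
    stop("reflection beyond the stated resolution cutoff")
  o <- order(h, k)
  structure(list(cell = cell, d_min = d_min, friedel = "+",
                 hk = data.frame(h = h[o], k = k[o], amp = amp[o],
                                 phase = phase[o] %% 360)),
            class = "sfset")
}

#' @export
print.sfset <- function(x, ...) {
  cat(sprintf("sfset: %d reflections to %.2f A, cell %s\n",
              nrow(x$hk), x$d_min, format(x$cell)))
  invisible(x)
}

# Complex structure factors of an sfset.
sf_complex <- function(sf) {
  sf$hk$amp * exp(1i * sf$hk$phase * pi / 180)
}

sf_set_complex <- function(sf, z) {
  sf$hk$amp <- Mod(z)
  sf$hk$phase <- (Arg(z) * 180 / pi) %% 360
  sf
}

#' Hemisphere reflection list for a cell and resolution cutoff
#'
#' All Miller indices (h, k) with h > 0, or h = 0 and k > 0, whose
#' resolution is at least `d_min`. The (0,0) term is excluded.
#'
#' @param cell A [unit_cell_2d()].
#' @param d_min Resolution cutoff in Angstrom.
#' @return Data frame with integer columns `h`, `k`.
#' @export
reflection_indices <- function(cell, d_min) {
  hmax <- ceiling(cell$a / d_min) + 1
  kmax <- ceiling(cell$b / d_min) + 1
  g <- expand.grid(h = 0:hmax, k = -kmax:kmax)
  g <- g[g$h > 0 | (g$h == 0 & g$k > 0), ]
  d <- resolution_hk(g$h, g$k, cell)
  g <- g[d >= d_min, ]
  rownames(g) <- NULL
  g[order(g$h, g$k), ]
}

#' Analytic structure factors of a rod model
#'
#' Computes the exact Fourier transform of the Gaussian-rod dimer density:
#' for a rod of weight m, center c and covariance S, the contribution at
#' reciprocal vector s(h,k) is `m exp(-2 pi^2 s' S s) exp(-2 pi i s.c)`.
#' All reflections out to `d_min` on one Friedel hemisphere are returned.
#'
#' @param model A [conformation_model()].
#' @param d_min Resolution cutoff in Angstrom.
#' @param cell Optional cell overriding the model's own (used when a state
#'   is embedded in an occupancy-interpolated cell).
#' @return An [sfset()].
#' @examples
#' m <- default_models()
#' sf <- structure_factors(m$apo, d_min = 6)
#' @export
structure_factors <- function(model, d_min = 6, cell = NULL) {
  stopifnot(inherits(model, "conformation_model"), d_min > 0)
  cell <- cell %||% model$cell
  idx <- reflection_indices(cell, d_min)
  raw <- structure_factors_at(model, idx, cell)
  sfset(cell, d_min, idx$h, idx$k, raw$hk$amp, raw$hk$phase)
}

#' Occupancy-mixed structure factors of a two-state crystal
#'
#' Structure factors of a lattice whose molecules populate the apo and
#' bound states with occupancies `1 - theta` and `theta`. Complex structure
#' factors are mixed per Miller index, which is identical to pointwise
#' mixing of the two state densities on a common fractional grid; the unit
#' cell interpolates linearly with `theta` between the state cells.
#'
#' @param apo,bound [conformation_model()] objects with identical rod ids.
#' @param theta Bound-state occupancy in `[0, 1]`.
#' @param d_min Resolution cutoff in Angstrom.
#' @return An [sfset()] on the interpolated cell.
#' @export
mixture_structure_factors <- function(apo, bound, theta, d_min = 6) {
  check_state_pair(apo, bound, theta)
  cell <- interp_cell(apo$cell, bound$cell, theta)
  idx <- reflection_indices(cell, d_min)
  # evaluate each state's analytic transform at the mixture cell's indices;
  # per-index mixing keeps the fractional-grid picture exact
  za <- sf_complex(structure_factors_at(apo, idx, apo$cell))
  zb <- sf_complex(structure_factors_at(bound, idx, bound$cell))
  z <- (1 - theta) * za + theta * zb
  sfset(cell, d_min, idx$h, idx$k, Mod(z), (Arg(z) * 180 / pi) %% 360)
}

# Analytic transform of a model at an arbitrary index list, in a given cell.
structure_factors_at <- function(model, idx, cell) {
  S <- reciprocal_matrix(cell)
  sv <- cbind(S[1, 1] * idx$h + S[1, 2] * idx$k,
              S[2, 1] * idx$h + S[2, 2] * idx$k)
  z <- complex(real = numeric(nrow(idx)), imaginary = numeric(nrow(idx)))
  for (r in expand_rods(model)) {
    w <- r$mass * r$order
    if (w == 0) next
    quad <- rowSums((sv %*% r$cov) * sv)
    phase <- -2 * pi * (sv[, 1] * r$center[1] + sv[, 2] * r$center[2])
    z <- z + w * exp(-2 * pi^2 * quad) * exp(1i * phase)
  }
  structure(list(cell = cell, d_min = NA_real_, friedel = "+",
                 hk = data.frame(h = idx$h, k = idx$k, amp = Mod(z),
                                 phase = (Arg(z) * 180 / pi) %% 360)),
            class = "sfset")
}

check_state_pair <- function(apo, bound, theta = 0) {
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  if (!setequal(rod_ids(apo), rod_ids(bound)))
    stop("apo and bound models must share rod ids")
  if (apo$symmetry != bound$symmetry)
    stop("apo and bound models must share the plane group")
  invisible(TRUE)
}
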