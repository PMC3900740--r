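as_sfset <- function(x) {
  if (inherits(x, "lattice_dataset")) x$sf
  else if (inherits(x, "sfset")) x
  else stop("expected an sfset or lattice_dataset")
}

# Inner-join two reflection lists on (h, k).
common_reflections <- function(a, b) {
  m <- merge(a$hk, b$hk, by = c("h", "k"), suffixes = c("_a", "_b"))
  m[order(m$h, m$k), ]
}

#' Align the phase origin of a lattice to a reference
#'
#' Finds the fractional origin shift `t` that minimizes the
#' amplitude-weighted mean absolute (wrapped) phase difference between the
#' lattice and the reference over their common reflections; applying `t`
#' changes each lattice phase by `-360 (h t_x + k t_y)` degrees. The search
#' is a coarse translation scan on a 240 x 240 fractional grid (evaluated
#' in one FFT as a phase cross-correlation), followed by Nelder-Mead
#' refinement of the exact residual; near-degenerate coarse maxima are
#' broken toward the smallest shift vector.
#'
#' @param lattice,reference [sfset()] (or [simulate_lattice()] dataset)
#'   sharing at least 3 reflections.
#' @param coarse Coarse grid subdivision (default 240).
#' @return List with `sf` (shifted lattice), `offset` (fractional, wrapped
#'   to `(-0.5, 0.5]`) and `residual` (degrees).
#' @export
align_phase_origin <- function(lattice, reference, coarse = 240) {
  lat <- as_sfset(lattice); ref <- as_sfset(reference)
  m <- common_reflections(lat, ref)
  if (nrow(m) < 3) stop("need at least 3 common reflections to align")
  w <- m$amp_a * m$amp_b
  if (all(w == 0)) w <- rep(1, nrow(m))
  dphi <- (m$phase_a - m$phase_b) * pi / 180

  # coarse scan: C(t) = sum_hk w exp(i dphi) exp(-2 pi i (h tx + k ty)),
  # evaluated for all t on the grid via one forward FFT
  B <- matrix(0 + 0i, coarse, coarse)
  ih <- m$h %% coarse + 1L
  ik <- m$k %% coarse + 1L
  cf <- w * exp(1i * dphi)
  for (r in seq_len(nrow(m)))
    B[ih[r], ik[r]] <- B[ih[r], ik[r]] + cf[r]
  C <- Re(stats::fft(B))
  best <- max(C)
  cand <- which(C >= best - 1e-9 * abs(best), arr.ind = TRUE)
  tc <- cbind(wrap_frac((cand[, 1] - 1) / coarse),
              wrap_frac((cand[, 2] - 1) / coarse))
  pick <- which.min(tc[, 1]^2 + tc[, 2]^2)
  t0 <- tc[pick, ]

  obj <- function(t) {
    d <- wrap_deg(m$phase_a - 360 * (m$h * t[1] + m$k * t[2]) - m$phase_b)
    sum(w * abs(d)) / sum(w)
  }
  opt <- stats::optim(t0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  t_hat <- wrap_frac(opt$par)
  shifted <- lat
  shifted$hk$phase <- (lat$hk$phase -
                         360 * (lat$hk$h * t_hat[1] + lat$hk$k * t_hat[2])) %% 360
  list(sf = shifted, offset = t_hat, residual = opt$value)
}

#' Standardize a phase origin against the p2 plane-group constraint
#'
#' On the crystallographic origin of a p2 crystal all projection phases are
#' 0 or 180 degrees. This refinement finds the fractional shift that
#' minimizes the amplitude-weighted deviation of the phases from
#' centrosymmetry (coarse FFT scan on doubled indices, then Nelder-Mead),
#' which fixes the origin up to the four equivalent twofold positions
#' (half-cell shifts); the candidate closest in phase to `reference`
#' is returned (or the smallest shift if no reference is given). Unlike
#' cross-map alignment, the origin found this way is not pulled by genuine
#' structural differences between conditions.
#'
#' @param sf An [sfset()] of (approximately) p2 data.
#' @param reference Optional [sfset()] used only to choose among the four
#'   equivalent origins.
#' @param coarse Coarse grid subdivision (default 240).
#' @return List with `sf` (shifted set), `offset`, and `residual` (degrees,
#'   amplitude-weighted mean absolute deviation from 0/180).
#' @export
standardize_origin_p2 <- function(sf, reference = NULL, coarse = 240) {
  stopifnot(inherits(sf, "sfset"))
  w <- sf$hk$amp^2
  phi <- sf$hk$phase * pi / 180
  # phases doubled: centrosymmetry means 2*phase = 0 mod 360, so scan
  # C(t) = sum w cos(2 phi - 2 pi (2h tx + 2k ty)) via one FFT
  B <- matrix(0 + 0i, coarse, coarse)
  ih <- (2L * sf$hk$h) %% coarse + 1L
  ik <- (2L * sf$hk$k) %% coarse + 1L
  cf <- w * exp(2i * phi)
  for (r in seq_along(cf))
    B[ih[r], ik[r]] <- B[ih[r], ik[r]] + cf[r]
  C <- Re(stats::fft(B))
  ij <- which(C == max(C), arr.ind = TRUE)[1, ]
  t0 <- c((ij[1] - 1) / coarse, (ij[2] - 1) / coarse)
  # deviation of each shifted phase from the nearest of 0/180
  dev <- function(t) {
    ph <- sf$hk$phase - 360 * (sf$hk$h * t[1] + sf$hk$k * t[2])
    d <- abs(wrap_deg(2 * ph)) / 2
    sum(w * d) / sum(w)
  }
  opt <- stats::optim(t0, dev, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  cands <- lapply(list(c(0, 0), c(0.5, 0), c(0, 0.5), c(0.5, 0.5)),
                  function(d) wrap_frac(opt$par + d))
  apply_shift <- function(t) {
    out <- sf
    out$hk$phase <- (sf$hk$phase -
                       360 * (sf$hk$h * t[1] + sf$hk$k * t[2])) %% 360
    out
  }
  if (is.null(reference)) {
    pick <- which.min(vapply(cands, function(t) sum(t^2), numeric(1)))
  } else {
    ref <- as_sfset(reference)
    score <- vapply(cands, function(t) {
      m <- common_reflections(apply_shift(t), ref)
      ww <- m$amp_a * m$amp_b
      sum(ww * abs(wrap_deg(m$phase_a - m$phase_b))) / sum(ww)
    }, numeric(1))
    pick <- which.min(score)
  }
  t_hat <- cands[[pick]]
  list(sf = apply_shift(t_hat), offset = t_hat, residual = dev(t_hat))
}

#' Least-squares amplitude scale between two reflection lists
#'
#' The factor `k` minimizing `sum (A_ref - k A_lat)^2` over common
#' reflections: `k = sum(A_ref A_lat) / sum(A_lat^2)`.
#'
#' @param lattice,reference [sfset()] or lattice datasets.
#' @return Positive scale factor.
#' @export
scale_amplitudes <- function(lattice, reference) {
  lat <- as_sfset(lattice); ref <- as_sfset(reference)
  m <- common_reflections(lat, ref)
  if (nrow(m) < 1) stop("no common reflections to scale on")
  den <- sum(m$amp_a^2)
  if (den == 0) stop("lattice amplitudes are all zero; cannot scale")
  sum(m$amp_b * m$amp_a) / den
}

#' Merge lattice datasets into one structure-factor set
#'
#' Origin-aligns every lattice to the first, scales each to the first by
#' least squares, and vector-averages the complex structure factors per
#' Miller index. Returns the merged set together with a merge report
#' (per-lattice scale factors and offsets, and the amplitude-weighted mean
#' absolute phase residual of the lattices against the merged reference).
#'
#' @param lattices List of [sfset()] or [simulate_lattice()] datasets with
#'   compatible cells.
#' @param cell_tol Relative per-axis cell agreement tolerance.
#' @return List with `sf` (merged [sfset()], cell averaged over lattices)
#'   and `report` (class `merge_report`).
#' @export
merge_lattices <- function(lattices, cell_tol = 0.1) {
  if (length(lattices) < 1) stop("need at least one lattice to merge")
  sfs <- lapply(lattices, as_sfset)
  ref <- sfs[[1]]
  for (s in sfs)
    if (!cells_compatible(ref$cell, s$cell, cell_tol))
      stop("incompatible unit cells among lattices")
  offsets <- matrix(0, length(sfs), 2)
  scales <- numeric(length(sfs))
  aligned <- vector("list", length(sfs))
  for (i in seq_along(sfs)) {
    al <- if (i == 1) list(sf = sfs[[1]], offset = c(0, 0), residual = 0)
    else align_phase_origin(sfs[[i]], ref)
    k <- scale_amplitudes(al$sf, ref)
    al$sf$hk$amp <- al$sf$hk$amp * k
    aligned[[i]] <- al$sf
    offsets[i, ] <- al$offset
    scales[i] <- k
  }
  # vector average per (h,k) over all lattices carrying that index
  all_hk <- unique(do.call(rbind, lapply(aligned, function(s) s$hk[c("h", "k")])))
  all_hk <- all_hk[order(all_hk$h, all_hk$k), ]
  zsum <- complex(real = numeric(nrow(all_hk)),
                  imaginary = numeric(nrow(all_hk)))
  nobs <- integer(nrow(all_hk))
  key <- paste(all_hk$h, all_hk$k)
  for (s in aligned) {
    idx <- match(paste(s$hk$h, s$hk$k), key)
    zsum[idx] <- zsum[idx] + sf_complex(s)
    nobs[idx] <- nobs[idx] + 1L
  }
  zbar <- zsum / nobs
  mcell <- unit_cell_2d(mean(vapply(sfs, function(s) s$cell$a, 1)),
                        mean(vapply(sfs, function(s) s$cell$b, 1)),
                        mean(vapply(sfs, function(s) s$cell$gamma, 1)))
  merged <- sfset(mcell, ref$d_min, all_hk$h, all_hk$k, Mod(zbar),
                  (Arg(zbar) * 180 / pi) %% 360)
  # amplitude-weighted phase residual of each lattice against the merge
  resid <- vapply(aligned, function(s) {
    m <- common_reflections(s, merged)
    w <- m$amp_a * m$amp_b
    if (sum(w) == 0) return(0)
    sum(w * abs(wrap_deg(m$phase_a - m$phase_b))) / sum(w)
  }, numeric(1))
  report <- structure(list(n_lattices = length(sfs),
                           phase_residual = mean(resid),
                           per_lattice_residual = resid,
                           scale_factors = scales, offsets = offsets),
                      class = "merge_report")
  list(sf = merged, report = report)
}

#' @export
print.merge_report <- function(x, ...) {
  cat(sprintf(
    "merge of %d lattices: mean phase residual %.2f deg, scales [%s]\n",
    x$n_lattices, x$phase_residual,
    paste(sprintf("%.3f", x$scale_factors), collapse = ", ")))
  invisible(x)
}
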