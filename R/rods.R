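#' Gaussian helix rod
#'
#' One transmembrane helix seen in projection, modelled as a 2D Gaussian:
#' an isotropic rod projects to a round peak, a tilted rod to an elongated
#' one. The covariance encodes projected width and tilt elongation; `order`
#' scales the amplitude between 0 (fully disordered, invisible) and 1.
#'
#' @param id Label, e.g. `"5c"`, `"12e"`, `"6"`.
#' @param center Length-2 numeric, position in Angstrom (Cartesian cell
#'   frame, a along x).
#' @param sigma Isotropic projected s.d. in Angstrom, used when `cov` is
#'   not given.
#' @param cov Optional 2x2 symmetric positive-definite covariance (A^2).
#' @param mass Scattering weight (arbitrary density units), >= 0.
#' @param order Order parameter in `[0, 1]` scaling the amplitude.
#' @return An object of class `helix_rod`.
#' @export
helix_rod <- function(id, center, sigma = 3, cov = NULL, mass = 100,
                      order = 1) {
  if (is.null(cov)) cov <- diag(sigma^2, 2)
  cov <- (cov + t(cov)) / 2
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("rod covariance must be positive definite")
  if (order < 0 || order > 1) stop("order must lie in [0, 1]")
  if (mass < 0) stop("mass must be non-negative")
  structure(list(id = as.character(id), center = as.numeric(center),
                 cov = cov, mass = mass, order = order),
            class = "helix_rod")
}

# Covariance with principal s.d.s (s_major, s_minor) and major axis at
# `angle` degrees from x.
rod_cov <- function(s_major, s_minor, angle = 0) {
  a <- angle * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  R %*% diag(c(s_major^2, s_minor^2)) %*% t(R)
}

#' Conformational state model of the dimer
#'
#' A full description of one conformational state: the rods of one
#' protomer, the rigid in-plane operation generating the second protomer
#' (for plane group p2 a twofold rotation about the origin), and the unit
#' cell of the state.
#'
#' @param state_label `"apo"` or `"bound"` (free-form labels allowed).
#' @param rods List of [helix_rod()] for one protomer.
#' @param cell A [unit_cell_2d()].
#' @param symmetry `"p2"` (default; twofold at the origin generates the
#'   dimer mate) or `"p1"` (the rod list is used as given).
#' @return An object of class `conformation_model`.
#' @export
conformation_model <- function(state_label, rods, cell, symmetry = "p2") {
  symmetry <- match.arg(symmetry, c("p2", "p1"))
  ids <- vapply(rods, function(r) r$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate rod ids in model")
  structure(list(state_label = state_label, rods = rods, cell = cell,
                 symmetry = symmetry),
            class = "conformation_model")
}

#' @export
print.conformation_model <- function(x, ...) {
  cat(sprintf("conformation model '%s': %d rods/protomer, %s, cell %s\n",
              x$state_label, length(x$rods), x$symmetry,
              format(x$cell)))
  invisible(x)
}

rod_ids <- function(model) vapply(model$rods, function(r) r$id, character(1))

# Expand the asymmetric unit to the full dimer: under p2 the mate of a rod
# at c is a rod at -c (mod cell) with the same covariance (rotation by 180
# degrees leaves a 2x2 covariance unchanged).
expand_rods <- function(model) {
  if (model$symmetry == "p1") return(model$rods)
  mates <- lapply(model$rods, function(r) {
    r$center <- -r$center
    r$id <- paste0(r$id, "'")
    r
  })
  c(model$rods, mates)
}

# Total scattering mass of the full dimer.
model_mass <- function(model) {
  sum(vapply(expand_rods(model), function(r) r$mass * r$order, numeric(1)))
}

#' Rasterize a state model onto a real-space grid
#'
#' Evaluates the Gaussian-rod density of the full dimer on an `nx x ny`
#' grid covering one unit cell, summing periodic images of each rod so the
#' density is exactly cell-periodic (rod widths are small against the cell,
#' so nearest-image sums converge immediately).
#'
#' @param model A [conformation_model()].
#' @param grid Integer pair `(nx, ny)`.
#' @return A [projection_map] whose grid holds absolute density
#'   (mass / A^2), including the constant (mean) component.
#' @export
rasterize_model <- function(model, grid = c(128, 160)) {
  density_on_grid(expand_rods(model), model$cell, grid)
}

density_on_grid <- function(rods, cell, grid) {
  nx <- as.integer(grid[1]); ny <- as.integer(grid[2])
  M <- cell_matrix(cell)
  fu <- (seq_len(nx) - 1) / nx
  fv <- (seq_len(ny) - 1) / ny
  F1 <- matrix(rep(fu, ny), nx, ny)
  F2 <- matrix(rep(fv, each = nx), nx, ny)
  X <- M[1, 1] * F1 + M[1, 2] * F2
  Y <- M[2, 1] * F1 + M[2, 2] * F2
  rho <- matrix(0, nx, ny)
  shifts <- expand.grid(i = -1:1, j = -1:1)
  for (r in rods) {
    w <- r$mass * r$order
    if (w == 0) next
    P <- solve(r$cov)
    norm_const <- w / (2 * pi * sqrt(det(r$cov)))
    # wrap the rod center into the cell, then sum the 3x3 block of images
    cf <- wrap_frac_01(solve(M, r$center))
    c0 <- as.numeric(M %*% cf)
    for (s in seq_len(nrow(shifts))) {
      cc <- c0 + as.numeric(M %*% c(shifts$i[s], shifts$j[s]))
      dx <- X - cc[1]; dy <- Y - cc[2]
      q <- P[1, 1] * dx * dx + 2 * P[1, 2] * dx * dy + P[2, 2] * dy * dy
      rho <- rho + norm_const * exp(-0.5 * q)
    }
  }
  new_projection_map(rho, cell)
}

wrap_frac_01 <- function(x) x - floor(x)

#' Default two-state rod models
#'
#' The packaged ground truth: a 15-rod protomer (13 transmembrane helices,
#' with helices 5 and 12 split into cytoplasmic/extracellular halves) in a
#' p2 dimer. The sodium-bound state differs from the apo state by
#' * a rigid lateral shift of the 5c/12e pair (default 2 Angstrom) toward
#'   helices 10 and 13,
#' * loss of the TMH6 tilt (2:1 elongation and ~1 A centroid offset along
#'   the tilt azimuth -> isotropic, recentered),
#' * gain of TMH13 elongation (isotropic -> 2:1 axis ratio), and
#' * ordering of the 5e half helix (order 0.8 -> 1.0, chosen so the
#'   moving 5c/12e pair stays the strongest difference-peak pair, as
#'   observed),
#' with the unit cell relaxing from 81.2 x 104.2 to 80.6 x 107.9 Angstrom.
#'
#' @param shift_5c12e Lateral displacement of the 5c/12e pair in Angstrom.
#' @param cell_apo,cell_bound Unit cells of the two states.
#' @param sigma Default isotropic rod s.d. in Angstrom.
#' @param symmetry Plane group, `"p2"` or `"p1"`.
#' @return List with elements `apo` and `bound`, both
#'   [conformation_model()] objects sharing rod ids.
#' @export
default_models <- function(shift_5c12e = 2,
                           cell_apo = unit_cell_2d(81.2, 104.2),
                           cell_bound = unit_cell_2d(80.6, 107.9),
                           sigma = 3, symmetry = "p2") {
  # Inter-rod spacings are kept above ~7.5 A in both states so every helix
  # resolves as a discrete peak at 6 A, as in the experimental projection
  # map of the dimer.
  pos <- list(
    "1"   = c(37.0, 17.0),
    "2"   = c(29.0, 14.5),
    "3"   = c(21.0, 13.0),
    "4"   = c(9.0, 23.0),
    "5c"  = c(18.0, 31.0),
    "5e"  = c(27.0, 37.0),
    "6"   = c(13.0, 39.5),
    "7"   = c(19.0, 47.0),
    "8"   = c(27.5, 45.5),
    "9"   = c(35.5, 43.0),
    "10"  = c(38.0, 34.0),
    "11"  = c(5.5, 32.0),
    "12c" = c(13.0, 14.0),
    "12e" = c(23.0, 22.0),
    "13"  = c(34.0, 27.0))

  # The protein drifts with the lattice as the cell relaxes: bound-state
  # rods keep the fractional coordinates of their apo positions, and the
  # designed conformational shifts are applied on top (scaled so they come
  # out exactly in apo-cell Cartesian units once maps are placed back into
  # a common cell).
  Ma <- cell_matrix(cell_apo)
  Mb <- cell_matrix(cell_bound)
  stretch <- c(cell_bound$a / cell_apo$a, cell_bound$b / cell_apo$b)
  make_state <- function(bound) {
    rods <- lapply(names(pos), function(id) {
      ctr <- pos[[id]]
      if (bound) ctr <- as.numeric(Mb %*% solve(Ma, ctr))
      cov <- diag(sigma^2, 2)
      ord <- 1
      if (id == "6") {
        # tilted in the apo state (elongated 2:1 along the tilt azimuth,
        # projected centroid displaced ~1 A the same way), straightens and
        # recenters on Na+ binding
        if (!bound) {
          cov <- rod_cov(2 * sigma, sigma, 45)
          ctr <- ctr + 1.0 * c(cos(pi / 4), sin(pi / 4))
        }
      }
      if (id == "13") {
        # gains tilt elongation (2:1) on binding; axis points toward
        # TMH 10, away from the moving 5c/12e pair
        cov <- if (bound) rod_cov(2 * sigma, sigma, 125) else
          diag(sigma^2, 2)
      }
      if (id == "5e") ord <- if (bound) 1.0 else 0.8
      if (bound && id %in% c("5c", "12e")) {
        ctr <- ctr + shift_5c12e * shift_direction_5c12e(pos) * stretch
      }
      helix_rod(id, ctr, cov = cov, order = ord)
    })
    conformation_model(if (bound) "bound" else "apo", rods,
                       if (bound) cell_bound else cell_apo,
                       symmetry = symmetry)
  }
  list(apo = make_state(FALSE), bound = make_state(TRUE))
}

# Unit vector from the 5c/12e midpoint toward the 10/13 midpoint.
shift_direction_5c12e <- function(pos) {
  d <- (pos[["10"]] + pos[["13"]]) / 2 - (pos[["5c"]] + pos[["12e"]]) / 2
  d / sqrt(sum(d^2))
}
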