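#' 2D crystal unit cell
#'
#' Constructs the unit cell of a 2D crystal: in-plane lattice constants
#' `a`, `b` (Angstrom) and the included angle `gamma` (degrees). All
#' real-space and reciprocal-space geometry in the package is anchored to
#' this object.
#'
#' @param a,b Lattice constants in Angstrom; must be positive.
#' @param gamma Included angle in degrees, strictly between 0 and 180.
#' @return An object of class `unit_cell_2d` with fields `a`, `b`, `gamma`.
#' @examples
#' unit_cell_2d(81.2, 104.2)
#' @export
unit_cell_2d <- function(a, b, gamma = 90) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(gamma),
            length(a) == 1L, length(b) == 1L, length(gamma) == 1L)
  if (!is.finite(a) || a <= 0) stop("cell constant 'a' must be positive")
  if (!is.finite(b) || b <= 0) stop("cell constant 'b' must be positive")
  if (!is.finite(gamma) || gamma <= 0 || gamma >= 180)
    stop("cell angle 'gamma' must lie strictly between 0 and 180 degrees")
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 gamma = as.numeric(gamma)),
            class = "unit_cell_2d")
}

#' @export
print.unit_cell_2d <- function(x, ...) {
  cat(sprintf("2D unit cell: a = %.2f A, b = %.2f A, gamma = %.2f deg\n",
              x$a, x$b, x$gamma))
  invisible(x)
}

#' @export
format.unit_cell_2d <- function(x, ...) {
  sprintf("%.2f x %.2f A (gamma %.1f)", x$a, x$b, x$gamma)
}

# Real-space basis matrix: columns are the a and b cell vectors in a
# Cartesian frame with a along x. Cartesian = M %*% fractional.
cell_matrix <- function(cell) {
  g <- cell$gamma * pi / 180
  matrix(c(cell$a, 0, cell$b * cos(g), cell$b * sin(g)), 2, 2)
}

# Reciprocal basis matrix: columns a*, b* (1/Angstrom); t(S) %*% M = I.
reciprocal_matrix <- function(cell) {
  t(solve(cell_matrix(cell)))
}

#' Unit-cell area
#' @param cell A [unit_cell_2d()].
#' @return Area in square Angstrom.
#' @export
cell_area <- function(cell) {
  cell$a * cell$b * sin(cell$gamma * pi / 180)
}

#' Resolution of a reflection
#'
#' Real-space resolution d (Angstrom) of reflection (h, k) in a given cell,
#' i.e. the reciprocal of the length of the reciprocal-lattice vector
#' h a* + k b*.
#'
#' @param h,k Integer Miller indices (vectorized).
#' @param cell A [unit_cell_2d()].
#' @return Numeric vector of d-spacings in Angstrom (`Inf` for (0,0)).
#' @export
resolution_hk <- function(h, k, cell) {
  g <- cell$gamma * pi / 180
  inv_d2 <- (h^2 / cell$a^2 + k^2 / cell$b^2 -
               2 * h * k * cos(g) / (cell$a * cell$b)) / sin(g)^2
  d <- ifelse(inv_d2 <= 0, Inf, 1 / sqrt(inv_d2))
  d
}

# Fractional -> Cartesian (Angstrom). x: 2-column matrix or length-2 vector.
frac_to_cart <- function(f, cell) {
  f <- rbind_coerce(f)
  t(cell_matrix(cell) %*% t(f))
}

# Cartesian -> fractional.
cart_to_frac <- function(x, cell) {
  x <- rbind_coerce(x)
  t(solve(cell_matrix(cell)) %*% t(x))
}

rbind_coerce <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 2) else as.matrix(x)
}

# Do two cells agree within a relative tolerance per axis?
cells_compatible <- function(c1, c2, tol = 0.1) {
  abs(c1$a - c2$a) / c1$a < tol &&
    abs(c1$b - c2$b) / c1$b < tol &&
    abs(c1$gamma - c2$gamma) < 10
}

# Linear interpolation between two cells (used for occupancy-dependent
# unit-cell drift).
interp_cell <- function(cell0, cell1, theta) {
  unit_cell_2d(a = (1 - theta) * cell0$a + theta * cell1$a,
               b = (1 - theta) * cell0$b + theta * cell1$b,
               gamma = (1 - theta) * cell0$gamma + theta * cell1$gamma)
}
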