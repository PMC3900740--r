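#' Binding parameters for the Na+/H+ competition isotherm
#'
#' Parameters of the single-site binding model in which Na+ and H+ compete
#' for a common site. The apparent dissociation constant at a given pH is
#' `K_app = kd_na * (1 + [H+]/K_H)` with `K_H = 10^-pk` (molar), so acidic
#' conditions require proportionally more Na+ to reach the same occupancy.
#'
#' @param kd_na Intrinsic Na+ dissociation constant in mM; must be positive.
#' @param pk Proton dissociation constant of the shared site, as a pK.
#' @param pH Solution pH (0 < pH < 14).
#' @return An object of class `binding_params`.
#' @seealso [occupancy()], [calibrate_binding()]
#' @export
binding_params <- function(kd_na, pk, pH) {
  if (!is.numeric(kd_na) || kd_na <= 0) stop("kd_na must be positive")
  if (!is.numeric(pH) || pH <= 0 || pH >= 14) stop("pH must be in (0, 14)")
  structure(list(kd_na = kd_na, pk = pk, pH = pH), class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf(
    "binding params: kd_na = %.4g mM, pK = %.4g, pH = %.2f (K_app = %.4g mM)\n",
    x$kd_na, x$pk, x$pH, kd_apparent(x)))
  invisible(x)
}

#' Apparent Na+ dissociation constant at the parameter set's pH
#'
#' @param params A [binding_params()].
#' @return Apparent dissociation constant in mM.
#' @export
kd_apparent <- function(params) {
  params$kd_na * (1 + 10^(params$pk - params$pH))
}

#' Na+-bound occupancy on the lattice
#'
#' Fraction of molecules in the Na+-bound conformational state at a given
#' sodium concentration, under the competitive single-site isotherm
#' `theta = c / (c + K_app)`.
#'
#' @param na_mM Sodium concentration in mM (vectorized, non-negative).
#' @param params A [binding_params()].
#' @return Occupancies in `[0, 1)`, strictly increasing in `na_mM`.
#' @examples
#' p <- binding_params(kd_na = 30, pk = 3, pH = 8)
#' occupancy(c(0, 30.0045, 500), p)
#' @export
occupancy <- function(na_mM, params) {
  stopifnot(inherits(params, "binding_params"))
  if (any(!is.finite(na_mM)) || any(na_mM < 0))
    stop("na_mM must be non-negative and finite")
  kapp <- kd_apparent(params)
  na_mM / (na_mM + kapp)
}

#' Solve intrinsic binding constants from two apparent constants
#'
#' Given apparent dissociation constants measured at two pH values, solve
#' the competition model `K_app(pH) = kd_na * (1 + 10^(pk - pH))` exactly
#' for the intrinsic `kd_na` and the site pK. Used to set the simulator's
#' ground truth from measured apparent constants (defaults: 30 mM at pH 8
#' and 280 mM at pH 4).
#'
#' @param kd_app_1,kd_app_2 Apparent constants in mM.
#' @param pH_1,pH_2 The pH at which each was measured (`pH_2 < pH_1`).
#' @return A list with `kd_na` (mM) and `pk`.
#' @examples
#' calibrate_binding(30, 280, 8, 4)
#' @export
calibrate_binding <- function(kd_app_1 = 30, kd_app_2 = 280,
                              pH_1 = 8, pH_2 = 4) {
  if (kd_app_2 <= kd_app_1 || pH_2 >= pH_1)
    stop("expect the more acidic condition to have the larger apparent K_D")
  # kd_app_i = k (1 + z * 10^-pH_i) with z = 10^pk
  z <- (kd_app_2 - kd_app_1) /
    (kd_app_1 * 10^(-pH_2) - kd_app_2 * 10^(-pH_1))
  if (z <= 0) stop("apparent constants are inconsistent with competition")
  kd_na <- kd_app_1 / (1 + z * 10^(-pH_1))
  list(kd_na = kd_na, pk = log10(z))
}

#' Default binding ground truth
#'
#' Binding parameters whose apparent constants reproduce the measured
#' values of roughly 30 mM at pH 8 and 280 mM at pH 4.
#'
#' @param pH Solution pH for the returned parameter set.
#' @return A [binding_params()].
#' @export
default_binding <- function(pH = 8) {
  cal <- calibrate_binding()
  binding_params(kd_na = cal$kd_na, pk = cal$pk, pH = pH)
}
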