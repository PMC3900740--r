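#' Assemble a titration counts table
#'
#' Builds the `titration_series` data frame used by [fit_titration()]: one
#' row per (concentration, region) with raw and (optionally) corrected
#' peak-to-trough contour counts.
#'
#' @param na_mM Concentration per row, mM.
#' @param region Region label per row.
#' @param positive,negative Contour counts per row.
#' @param pH Condition pH, stored as an attribute.
#' @return Data frame of class `titration_series`.
#' @export
titration_counts <- function(na_mM, region, positive, negative, pH = NA) {
  df <- data.frame(na_mM = na_mM, region = region,
                   positive = as.integer(positive),
                   negative = as.integer(negative),
                   peak_to_trough = as.integer(positive) +
                     as.integer(negative))
  if (any(df$na_mM < 0)) stop("concentrations must be non-negative")
  attr(df, "pH") <- pH
  attr(df, "corrected") <- FALSE
  class(df) <- c("titration_series", "data.frame")
  df
}

# Hyperbolic saturation: H(c) = h_max * c^n / (c^n + kd^n).
saturation_curve <- function(c, kd, h_max, hill = 1) {
  h_max * c^hill / (c^hill + kd^hill)
}

# Profile least squares: for fixed kd the optimal h_max is linear.
profile_fit <- function(c, y, hill = 1) {
  f <- function(log_kd) {
    x <- c^hill / (c^hill + exp(log_kd)^hill)
    sxx <- sum(x^2)
    if (sxx == 0) return(list(rss = sum(y^2), h = 0))
    h <- sum(x * y) / sxx
    list(rss = sum((y - h * x)^2), h = h)
  }
  cmax <- max(c[c > 0])
  lo <- cmax * 1e-3
  hi <- cmax * 1e3
  opt <- stats::optimize(function(l) f(l)$rss, interval = log(c(lo, hi)),
                         tol = 1e-10)
  kd <- exp(opt$minimum)
  at <- f(opt$minimum)
  list(kd = kd, h_max = at$h, rss = at$rss,
       at_boundary = kd < lo * 1.05 || kd > hi * 0.95)
}

#' Fit a saturation isotherm to a contour-count titration
#'
#' Fits `H(c) = h_max * c / (c + K_D)` to the background-corrected
#' peak-to-trough counts of one region by least squares (the linear
#' parameter `h_max` is profiled out and `K_D` found by 1-D optimization on
#' the log scale), with a nonparametric bootstrap over titration points for
#' the 68% confidence interval of the apparent dissociation constant.
#'
#' @param series A `titration_series` data frame (see
#'   [titration_counts()]); must carry corrected counts
#'   ([background_correct()]), or a numeric `corrected` column.
#' @param region_id Region to fit.
#' @param seed Integer seed for the bootstrap.
#' @param n_boot Bootstrap replicates (>= 500 recommended; 0 skips the
#'   interval).
#' @param hill Hill coefficient, fixed (default 1, single-site).
#' @return An object of class `titration_fit`.
#' @examples
#' tc <- titration_counts(
#'   na_mM = c(0, 20, 50, 100, 250, 500), region = "set1_5c12e",
#'   positive = c(0, 4, 6, 8, 10, 11), negative = c(0, 2, 3, 4, 5, 5),
#'   pH = 8)
#' tc <- background_correct(tc, c(set1_5c12e = 0L))
#' fit <- fit_titration(tc, "set1_5c12e", seed = 1, n_boot = 200)
#' coef(fit)
#' @export
fit_titration <- function(series, region_id, seed = 1, n_boot = 500,
                          hill = 1) {
  if (!"corrected" %in% names(series))
    stop("series must be background-corrected before fitting")
  d <- series[series$region == region_id, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for region '", region_id, "'")
  c_ <- d$na_mM
  y <- as.numeric(d$corrected)
  if (length(unique(c_)) < 3)
    stop("need at least 3 distinct concentrations to fit")
  if (all(y == 0)) stop("all corrected counts are zero; no signal to fit")
  fit <- profile_fit(c_, y, hill)

  boot_kd <- numeric(0)
  if (n_boot > 0) {
    boot_kd <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(length(c_), replace = TRUE)
        cb <- c_[idx]; yb <- y[idx]
        if (length(unique(cb[cb > 0])) < 2 || all(yb == 0)) return(NA_real_)
        profile_fit(cb, yb, hill)$kd
      }, numeric(1))
    })
    boot_kd <- boot_kd[is.finite(boot_kd)]
  }
  ci <- if (length(boot_kd) >= 10)
    stats::quantile(boot_kd, c(0.16, 0.84), names = FALSE)
  else c(NA_real_, NA_real_)
  wide <- !all(is.finite(ci)) ||
    (ci[2] / max(ci[1], .Machine$double.eps) > 10) ||
    isTRUE(fit$at_boundary)
  structure(list(region_id = region_id, kd_app = fit$kd,
                 h_max = fit$h_max, rss = fit$rss, hill = hill,
                 ci_low = ci[1], ci_high = ci[2],
                 n_boot = length(boot_kd), boot_kd = boot_kd,
                 seed = seed, wide_ci = wide,
                 converged = is.finite(fit$kd) && fit$h_max > 0,
                 data = data.frame(na_mM = c_, corrected = y),
                 pH = attr(series, "pH")),
            class = "titration_fit")
}

#' @export
print.titration_fit <- function(x, ...) {
  cat(sprintf("Saturation-isotherm fit, region %s%s\n", x$region_id,
              if (!is.null(x$pH) && is.finite(x$pH))
                sprintf(" (pH %s)", format(x$pH)) else ""))
  cat(sprintf("  K_D,app = %.4g mM  (68%% CI %.4g - %.4g, %d bootstrap)\n",
              x$kd_app, x$ci_low, x$ci_high, x$n_boot))
  cat(sprintf("  h_max = %.3g levels, RSS = %.4g%s\n", x$h_max, x$rss,
              if (x$wide_ci) "  [wide CI: K_D poorly identified]" else ""))
  invisible(x)
}

#' @export
coef.titration_fit <- function(object, ...) {
  c(kd_app = object$kd_app, h_max = object$h_max)
}

#' @export
summary.titration_fit <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(fit = object, residual_sd = stats::sd(res),
              n_points = nrow(object$data))
  class(out) <- "summary.titration_fit"
  out
}

#' @export
print.summary.titration_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d titration points, residual s.d. %.3g levels\n",
              x$n_points, x$residual_sd))
  invisible(x)
}

#' @export
predict.titration_fit <- function(object, na_mM = NULL, ...) {
  if (is.null(na_mM)) na_mM <- object$data$na_mM
  saturation_curve(na_mM, object$kd_app, object$h_max, object$hill)
}

#' @export
residuals.titration_fit <- function(object, ...) {
  object$data$corrected - predict(object)
}

#' @export
plot.titration_fit <- function(x, ...) {
  d <- x$data
  cs <- seq(0, max(d$na_mM) * 1.05, length.out = 200)
  graphics::plot(d$na_mM, d$corrected,
                 xlab = "[Na+] (mM)",
                 ylab = "corrected peak-to-trough contour levels",
                 main = sprintf("Region %s: K_D,app = %.3g mM",
                                x$region_id, x$kd_app),
                 pch = 19, ...)
  graphics::lines(cs, predict(x, cs), col = "steelblue", lwd = 2)
  graphics::abline(v = x$kd_app, lty = 3, col = "grey40")
  invisible(x)
}

#' Fold change between two apparent dissociation constants
#'
#' Ratio `kd_app(acid) / kd_app(base)` with an interval propagated from
#' paired bootstrap replicates of the two fits.
#'
#' @param fit_acid,fit_base Converged [fit_titration()] results.
#' @return List with `ratio`, `ci_low`, `ci_high`, `n_pairs`.
#' @export
kd_ratio <- function(fit_acid, fit_base) {
  if (!fit_acid$converged || !fit_base$converged)
    stop("both fits must have converged to form a ratio")
  ratio <- fit_acid$kd_app / fit_base$kd_app
  n <- min(length(fit_acid$boot_kd), length(fit_base$boot_kd))
  ci <- c(NA_real_, NA_real_)
  if (n >= 10) {
    reps <- fit_acid$boot_kd[seq_len(n)] / fit_base$boot_kd[seq_len(n)]
    ci <- stats::quantile(reps, c(0.16, 0.84), names = FALSE)
  }
  list(ratio = ratio, ci_low = ci[1], ci_high = ci[2], n_pairs = n)
}

#' Cross-region consistency of fitted constants
#'
#' Summarizes the spread (max/min ratio) of apparent dissociation constants
#' across regions fitted at one pH; the response is expected to be a single
#' global transition, so a spread beyond 2-fold is flagged.
#'
#' @param fits List of [fit_titration()] results (>= 2).
#' @param flag_fold Spread threshold for flagging (default 2).
#' @return List with a per-region `kd_app` table, `spread`, `flagged`.
#' @export
consistency_report <- function(fits, flag_fold = 2) {
  if (length(fits) < 2) stop("need at least 2 regional fits")
  kd <- vapply(fits, function(f) f$kd_app, numeric(1))
  names(kd) <- vapply(fits, function(f) f$region_id, character(1))
  spread <- max(kd) / min(kd)
  list(kd_app = kd, spread = spread, flagged = spread > flag_fold)
}
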