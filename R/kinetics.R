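# Stability and steady-state kinetics fits used to validate variants:
# first-order inactivation (half-life via t1/2 = ln 2 / kd), Hanes-Woolf
# estimation of Michaelis-Menten parameters, catalytic efficiency, and
# Beer-Lambert conversion of absorbance slopes to rates.

#' First-order inactivation fit
#'
#' Ordinary least squares of ln(residual activity) on incubation time;
#' kd = -slope, t1/2 = ln 2 / kd. A non-negative slope is flagged
#' `no_decay` with an infinite half-life.
#'
#' @param data data.frame with columns `time` (minutes, increasing) and
#'   `activity` (> 0).
#' @return list of class `decay_fit`: `kd` (per minute), `t_half` (minutes),
#'   `r_squared`, `n_points`, `no_decay`.
#' @export
fit_first_order_decay <- function(data) {
  stopifnot(all(c("time", "activity") %in% names(data)))
  if (nrow(data) < 3L) stop("need at least 3 time points")
  if (any(data$activity <= 0)) stop("non-positive activity")
  if (is.unsorted(data$time, strictly = TRUE)) stop("times must increase")
  fit <- stats::lm(log(activity) ~ time, data = data)
  slope <- unname(stats::coef(fit)[2L])
  kd <- -slope
  no_decay <- kd <= 0
  r2 <- summary(fit)$r.squared
  structure(list(kd = kd, t_half = if (no_decay) Inf else log(2) / kd,
                 r_squared = r2, n_points = nrow(data),
                 no_decay = no_decay), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$no_decay) cat("<decay_fit: no decay detected>\n")
  else cat(sprintf("<decay_fit: kd %.4g /min, t1/2 %.4g min, R2 %.4f>\n",
                   x$kd, x$t_half, x$r_squared))
  invisible(x)
}

#' Hanes-Woolf estimation of Michaelis-Menten parameters
#'
#' Regresses S/v on S (unweighted OLS): slope = 1/Vmax, intercept =
#' KM/Vmax. kcat = Vmax / [E]; catalytic efficiency reported in
#' s^-1 mM^-1. A nonlinear least-squares Michaelis-Menten fit (`nls`,
#' started from the Hanes-Woolf estimates) is returned alongside as a
#' cross-check, never as the primary estimator.
#'
#' @param data data.frame with columns `substrate` (micromolar, >= 3
#'   distinct positive levels) and `rate` (micromolar per second, > 0).
#' @param enzyme_conc enzyme concentration, micromolar.
#' @return list of class `mm_fit`: `km` (micromolar), `vmax` (micromolar/s),
#'   `kcat` (per second), `efficiency` (s^-1 mM^-1), standard errors
#'   `km_se`/`vmax_se`, `valid`, and `nls_check` (km/kcat from the
#'   nonlinear fit, NA if it fails).
#' @export
fit_hanes_woolf <- function(data, enzyme_conc) {
  stopifnot(all(c("substrate", "rate") %in% names(data)), enzyme_conc > 0)
  if (length(unique(data$substrate)) < 3L)
    stop("need at least 3 distinct substrate levels")
  if (any(data$substrate <= 0) || any(data$rate <= 0))
    stop("substrate and rate must be positive")
  hw <- data.frame(s = data$substrate, y = data$substrate / data$rate)
  fit <- stats::lm(y ~ s, data = hw)
  co <- stats::coef(fit)
  vmax <- 1 / unname(co[2L])
  km <- unname(co[1L]) * vmax
  valid <- is.finite(vmax) && vmax > 0 && is.finite(km) && km > 0
  # delta-method standard errors: Vmax = 1/b1, KM = b0/b1
  vc <- stats::vcov(fit)
  b0 <- unname(co[1L]); b1 <- unname(co[2L])
  vmax_se <- sqrt(vc[2L, 2L]) / b1^2
  km_var <- vc[1L, 1L] / b1^2 + b0^2 * vc[2L, 2L] / b1^4 -
    2 * b0 * vc[1L, 2L] / b1^3
  km_se <- sqrt(max(km_var, 0))
  kcat <- vmax / enzyme_conc
  nls_check <- tryCatch({
    nf <- stats::nls(rate ~ Vm * substrate / (K + substrate), data = data,
                     start = list(Vm = max(vmax, max(data$rate)),
                                  K = max(km, 1)))
    cn <- stats::coef(nf)
    c(km = unname(cn["K"]), kcat = unname(cn["Vm"]) / enzyme_conc)
  }, error = function(e) c(km = NA_real_, kcat = NA_real_))
  structure(list(km = km, vmax = vmax, kcat = kcat,
                 efficiency = catalytic_efficiency(kcat, km),
                 km_se = km_se, vmax_se = vmax_se, valid = valid,
                 n_points = nrow(data), nls_check = nls_check),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit: KM %.3g uM, kcat %.3g /s, kcat/KM %.3g /s/mM%s>\n",
    x$km, x$kcat, x$efficiency, if (x$valid) "" else " [invalid]"))
  invisible(x)
}

#' Catalytic efficiency kcat/KM in s^-1 mM^-1
#'
#' @param kcat turnover number, per second.
#' @param km Michaelis constant, micromolar.
#' @return kcat / (km / 1000).
#' @export
catalytic_efficiency <- function(kcat, km) {
  stopifnot(all(km > 0))
  kcat / (km / 1000)
}

#' Convert an absorbance slope to a concentration rate
#'
#' Beer-Lambert: rate (micromolar per minute) =
#' dA/dt / (extinction * pathlength) * 1000, with the extinction
#' coefficient in mM^-1 cm^-1 and the path length in cm.
#'
#' @param dA_per_min absorbance change per minute.
#' @param extinction mM^-1 cm^-1 (e.g. 36.7 for oxidized ABTS at 420 nm,
#'   9.3 for veratraldehyde at 310 nm, 168 for the heme Soret band at
#'   409 nm).
#' @param pathlength cm (default 1).
#' @return rate in micromolar per minute (or a concentration in micromolar
#'   when a plain absorbance is supplied).
#' @export
rate_from_absorbance <- function(dA_per_min, extinction, pathlength = 1) {
  stopifnot(extinction > 0, pathlength > 0)
  dA_per_min / (extinction * pathlength) * 1000
}
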