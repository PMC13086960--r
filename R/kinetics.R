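# Foliar-uptake kinetics: the SOFU statistic R(t) = -ln(1 - Mt/M0) and the
# exponential-saturation depth law z(t) = (M0/B) (1 - exp(-A t)).

#' SOFU penetration-rate statistic
#'
#' `R(t) = -ln(1 - Mt/M0)` elementwise. When the uptaken fraction follows
#' `Mt/M0 = 1 - exp(-A t)`, R(t) is exactly linear in time with slope A,
#' the penetration rate.
#'
#' @param fraction uptaken fraction series Mt/M0, each in `[0, 1)`.
#' @return numeric R(t) series.
#' @export
#' @examples
#' sofu_rate(1 - exp(-0.02 * c(0, 50, 100)))  # 0.02 * t
sofu_rate <- function(fraction) {
  if (any(!is.finite(fraction))) stop("uptaken fraction must be finite")
  if (any(fraction < 0)) stop("uptaken fraction must be >= 0")
  if (any(fraction >= 1)) {
    stop("uptaken fraction >= 1 (complete uptake): R(t) is undefined, not clipped")
  }
  -log(1 - fraction)
}

#' Uptake amount from a penetration trace
#'
#' `Mt = B * (z0 - z(t))`: the uptaken amount is proportional to the depth
#' gained by the penetrating surfactant, with B the amount of AI carried
#' per nm of penetration.
#'
#' @param trace a `penetration_trace` (see [penetration_trace()]).
#' @param B proportionality coefficient (amount per nm), > 0.
#' @return numeric Mt series.
#' @export
uptake_from_depth <- function(trace, B) {
  stopifnot(inherits(trace, "penetration_trace"))
  if (B <= 0) stop("B must be positive")
  B * (trace$z0 - trace$depths)
}

#' Fit the penetration rate from a depth trace
#'
#' Nonlinear least-squares fit of the depth excursion `|z0 - z(t)|` to
#' `prefactor * (1 - exp(-A t))` (Levenberg–Marquardt). Initial guesses:
#' prefactor = maximum excursion, A = 1 / (time to reach half of it).
#' The prefactor M0/B is reported lumped — B and M0 are not separately
#' identifiable from a depth trace.
#'
#' @param trace a `penetration_trace` with at least 3 distinct times.
#' @param z0 surface anchor override (default: the trace's own `z0`).
#' @return An `uptake_fit`: list with `A` (ns⁻¹), `prefactor` (nm),
#'   `residual_rms` (nm), `A_se`, `prefactor_se`, `converged`, and the
#'   underlying `fit` object.
#' @export
#' @examples
#' sim <- simulate_penetration(kinetics_truth(A_true = 0.02), times = 0:200)
#' fit <- fit_penetration_rate(sim$trace)
#' fit$A  # 0.02 to solver tolerance
fit_penetration_rate <- function(trace, z0 = trace$z0) {
  stopifnot(inherits(trace, "penetration_trace"))
  t <- trace$times
  if (length(unique(t)) < 3) stop("need at least 3 distinct time points")
  y <- abs(z0 - trace$depths)
  ymax <- max(y)
  if (ymax < 1e-9) stop("degenerate trace: no depth excursion to fit")
  t_half <- t[which(y >= ymax / 2)[1]]
  if (!is.finite(t_half) || t_half <= 0) t_half <- max(t) / 10
  start <- list(prefactor = ymax, A = 1 / t_half)
  fit <- minpack.lm::nlsLM(
    y ~ prefactor * (1 - exp(-A * t)),
    data = data.frame(t = t, y = y),
    start = start,
    lower = c(prefactor = 1e-12, A = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(prefactor = NA_real_, A = NA_real_))
  structure(
    list(A = unname(cf["A"]), prefactor = unname(cf["prefactor"]),
         residual_rms = sqrt(mean(stats::resid(fit)^2)),
         A_se = unname(se["A"]), prefactor_se = unname(se["prefactor"]),
         converged = fit$convInfo$isConv %||% TRUE, fit = fit),
    class = "uptake_fit"
  )
}

#' @export
print.uptake_fit <- function(x, ...) {
  cat(sprintf("uptake_fit: A = %.6g /ns (se %.2g), prefactor = %.4g nm (se %.2g)\n",
              x$A, x$A_se, x$prefactor, x$prefactor_se))
  cat(sprintf("  residual RMS = %.3g nm; A = %.4g /h for comparison with uptake assays\n",
              x$residual_rms, rate_per_ns_to_per_hour(x$A)))
  invisible(x)
}

#' Convert a rate from ns^-1 to h^-1
#'
#' Penetration rates are fitted in ns⁻¹ (simulation time); uptake assays
#' report rates in h⁻¹ over tens of hours. 1 ns⁻¹ = 3.6e12 h⁻¹.
#'
#' @param A rate in ns⁻¹.
#' @return rate in h⁻¹.
#' @export
rate_per_ns_to_per_hour <- function(A) {
  A * 3.6e12
}
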