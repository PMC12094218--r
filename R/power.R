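#' Corrected noncentrality parameter for the standard cosinor F test
#'
#' The corrected closed form
#' `delta2 = n * (A / sigma)^2 * sigma2_cosinor(phi)`,
#' where `sigma2_cosinor(phi)` is the population (divisor-n) variance of
#' `cos(omega * t - phi)` over the design's measurement times. It equals the
#' general quadratic form `beta2' Z2'Z2 beta2 / sigma^2` with
#' `X1` = intercept, and is valid for any design, centered or not. Only the
#' ratio `A / sigma` matters.
#'
#' @param design a [sampling_design()].
#' @param amplitude rhythm amplitude `A >= 0`. Interpreted as the ratio
#'   `A / sigma` when `sigma = 1` (the default).
#' @param sigma residual standard deviation, `> 0`.
#' @param acrophase acrophase `phi` in radians (vectorised).
#' @return Noncentrality parameter(s) `delta2 >= 0`.
#' @examples
#' # dense window around the peak: almost no power
#' ncp_standard(uniform_grid_design(5, 7, 24), amplitude = 3, acrophase = pi / 2)
#' # evenly spaced: delta2 = n * (A/sigma)^2 / 2 at any phase
#' ncp_standard(evenly_spaced_design(12), amplitude = 1, acrophase = 0)
#' @seealso [ncp_zong_incorrect()], [general_ncp()], [power_from_ncp()]
#' @export
ncp_standard <- function(design, amplitude, sigma = 1, acrophase = 0) {
  stopifnot(inherits(design, "sampling_design"))
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("'amplitude' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  if (amplitude == 0) return(rep(0, length(acrophase)))
  cv <- cosinor_variance(design, acrophase)
  design$n * (amplitude / sigma)^2 * cv$sigma2_cosinor
}

#' Uncentered (incorrect) noncentrality parameter, for comparison
#'
#' The naive quadratic form
#' `delta2_wrong = beta2' X2'X2 beta2 / sigma^2
#'              = (A / sigma)^2 * sum_i cos^2(omega t_i - phi)`,
#' obtained by treating the mesor estimate as identical under the null and
#' full models. It equals the corrected [ncp_standard()] only for centered
#' designs (`mu_cos = mu_sin = 0`); on non-centered designs it can
#' drastically overstate power -- on 24 points clustered in ZT 5-7 with
#' `A/sigma = 3` it claims `delta2 ~ 210` where the true value is `~ 0.026`.
#' It is provided deliberately as a comparison baseline, never for power
#' planning.
#'
#' @inheritParams ncp_standard
#' @return Noncentrality parameter(s) under the uncentered fallacy.
#' @export
ncp_zong_incorrect <- function(design, amplitude, sigma = 1, acrophase = 0) {
  stopifnot(inherits(design, "sampling_design"))
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("'amplitude' must be >= 0", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  if (amplitude == 0) return(rep(0, length(acrophase)))
  th <- design$omega * design$times
  s <- vapply(acrophase, function(p) sum(cos(th - p)^2), numeric(1L))
  (amplitude / sigma)^2 * s
}

#' Analytic power of the cosinor F test from a noncentrality parameter
#'
#' Evaluates `P[F' > q]` where `F'` follows the noncentral
#' `F(df1, n - df1 - q, delta2)` distribution and `q` is the upper-`alpha`
#' quantile of the corresponding central F distribution. Standard cosinor:
#' `df1 = 2`, `df2 = n - 3`. The noncentral tail is computed by
#' `stats::pf(..., ncp = )`; no Monte Carlo is involved in the analytic
#' path. Note the convention: `delta2` enters undivided by its degrees of
#' freedom (some power tools use `delta2 / df1`).
#'
#' @param delta2 noncentrality parameter(s), `>= 0` (vectorised).
#' @param n number of measurements, `n >= 4`.
#' @param alpha test size in (0, 1), default 0.05.
#' @param df1 numerator degrees of freedom (2 for the standard cosinor test).
#' @param q number of null-model parameters (1 for the standard cosinor).
#' @param formula tag recorded in the result: `"corrected"` or
#'   `"zong_incorrect"`.
#' @return Object of class `cosinor_power` (a list): `delta2`, `df1`, `df2`,
#'   `alpha`, `power`, `formula`. `power` has the length of `delta2`.
#' @examples
#' power_from_ncp(0.026, n = 24)    # ~ 0.052: nearly blind design
#' power_from_ncp(12, n = 24)       # evenly spaced, A/sigma = 1
#' @export
power_from_ncp <- function(delta2, n, alpha = 0.05, df1 = 2, q = 1,
                           formula = "corrected") {
  if (any(!is.finite(delta2)) || any(delta2 < 0)) {
    stop("'delta2' must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  df2 <- n - df1 - q
  if (df2 < 1) stop(sprintf("n = %d leaves no residual degrees of freedom", n),
                    call. = FALSE)
  crit <- stats::qf(1 - alpha, df1, df2)
  pw <- stats::pf(crit, df1, df2, ncp = delta2, lower.tail = FALSE)
  structure(list(delta2 = delta2, df1 = df1, df2 = df2, alpha = alpha,
                 power = pw, formula = formula),
            class = "cosinor_power")
}

#' @export
print.cosinor_power <- function(x, digits = 4, ...) {
  cat(sprintf("Cosinor F-test power (%s formula)\n", x$formula))
  cat(sprintf("  df = (%d, %d), alpha = %g\n", x$df1, x$df2, x$alpha))
  if (length(x$delta2) == 1L) {
    cat(sprintf("  delta2 = %s -> power = %s\n",
                signif(x$delta2, digits), signif(x$power, digits)))
  } else {
    print(data.frame(delta2 = signif(x$delta2, digits),
                     power = signif(x$power, digits)))
  }
  invisible(x)
}

#' One-call analytic power for a design and effect
#'
#' Convenience wrapper: noncentrality from [ncp_standard()] (or
#' [ncp_zong_incorrect()]) followed by [power_from_ncp()].
#'
#' @inheritParams ncp_standard
#' @param alpha test size.
#' @param formula `"corrected"` (default) or `"zong_incorrect"`.
#' @return A `cosinor_power` object.
#' @export
cosinor_power <- function(design, amplitude, sigma = 1, acrophase = 0,
                          alpha = 0.05,
                          formula = c("corrected", "zong_incorrect")) {
  formula <- match.arg(formula)
  d2 <- switch(formula,
               corrected = ncp_standard(design, amplitude, sigma, acrophase),
               zong_incorrect = ncp_zong_incorrect(design, amplitude, sigma,
                                                   acrophase))
  power_from_ncp(d2, n = design$n, alpha = alpha, formula = formula)
}

#' Power as a function of acrophase
#'
#' Evaluates the corrected and the uncentered noncentrality parameters and
#' the corresponding analytic powers over a grid of acrophases. The curve is
#' flat exactly when the design is phase-invariant; for clustered designs it
#' exposes the phases at which the design is effectively blind.
#'
#' @inheritParams ncp_standard
#' @param alpha test size.
#' @param phi_grid numeric vector of acrophases in radians (default: 97
#'   points over one full turn).
#' @return Data frame with columns `phi`, `delta2_corrected`,
#'   `delta2_incorrect`, `power_corrected`, `power_incorrect`.
#' @export
power_curve_vs_phase <- function(design, amplitude, sigma = 1, alpha = 0.05,
                                 phi_grid = seq(-pi, pi, length.out = 97)) {
  if (length(phi_grid) < 1L) stop("'phi_grid' must be non-empty", call. = FALSE)
  d2c <- ncp_standard(design, amplitude, sigma, phi_grid)
  d2w <- ncp_zong_incorrect(design, amplitude, sigma, phi_grid)
  data.frame(
    phi = phi_grid,
    delta2_corrected = d2c,
    delta2_incorrect = d2w,
    power_corrected = power_from_ncp(d2c, design$n, alpha)$power,
    power_incorrect = power_from_ncp(d2w, design$n, alpha,
                                     formula = "zong_incorrect")$power
  )
}

#' Smallest number of template copies achieving a target power
#'
#' Replicates a per-cycle sampling template (each copy repeats every time
#' point once, multiplying both n and the noncentrality parameter while
#' leaving the time-point distribution unchanged) and returns the smallest
#' number of copies whose analytic power reaches the target.
#'
#' @param template a [sampling_design()] describing one copy of the schedule.
#' @param amplitude,sigma,acrophase effect size as in [ncp_standard()].
#' @param alpha test size.
#' @param target_power required power, in `(alpha, 1)`.
#' @param max_copies search cap; an unreachable target within the cap is an
#'   error (e.g. `amplitude = 0`, or a design blind at this acrophase).
#' @return List with `copies`, `n` (total measurements), `delta2`, `power`.
#' @examples
#' solve_sample_size(evenly_spaced_design(6), amplitude = 1, target_power = 0.8)
#' @export
solve_sample_size <- function(template, amplitude, sigma = 1, acrophase = 0,
                              alpha = 0.05, target_power = 0.8,
                              max_copies = 10000L) {
  stopifnot(inherits(template, "sampling_design"))
  if (!is.numeric(target_power) || target_power <= alpha || target_power >= 1) {
    stop("'target_power' must be in (alpha, 1)", call. = FALSE)
  }
  n0 <- template$n
  d2_1 <- ncp_standard(template, amplitude, sigma, acrophase)
  pow_k <- function(k) {
    n <- k * n0
    if (n < 4) return(0)
    power_from_ncp(k * d2_1, n = n, alpha = alpha)$power
  }
  if (d2_1 <= 0 || pow_k(max_copies) < target_power) {
    stop(sprintf(
      "target power %.3g not achievable within %d template copies (delta2 per copy = %.3g)",
      target_power, max_copies, d2_1), call. = FALSE)
  }
  lo <- 1L; hi <- 1L
  while (pow_k(hi) < target_power) { lo <- hi; hi <- min(2L * hi, max_copies) }
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (pow_k(mid) >= target_power) hi <- mid else lo <- mid
  }
  k <- if (pow_k(lo) >= target_power) lo else hi
  list(copies = k, n = k * n0, delta2 = k * d2_1, power = pow_k(k))
}
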