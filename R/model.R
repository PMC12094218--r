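#' Cosinor effect size
#'
#' Bundles the parameters of a single-component cosinor signal
#' `m + A * cos(omega * t - phi)` with residual standard deviation `sigma`.
#' Either the polar form (`amplitude`, `acrophase`) or the linear
#' coefficients (`a1`, `a2`) may be given; the other form is derived via
#' `a1 = A cos(phi)`, `a2 = A sin(phi)`.
#'
#' @param mesor rhythm-adjusted mean level (signal units).
#' @param amplitude half peak-to-trough range, `A >= 0`.
#' @param acrophase phase of the peak, radians; reported in `(-pi, pi]`.
#' @param sigma residual standard deviation, `> 0` (use the noiseless
#'   simulation path for `sigma = 0` fixtures).
#' @param a1,a2 alternative linear parameterization; supply instead of
#'   `amplitude`/`acrophase`.
#' @return Object of class `cosinor_effect` with fields `m`, `A`, `phi`,
#'   `sigma`, `a1`, `a2`. For `A = 0` the acrophase is undefined and stored
#'   as `NA`.
#' @examples
#' cosinor_effect(mesor = 2, amplitude = 3, acrophase = pi / 2, sigma = 1)
#' cosinor_effect(a1 = 0, a2 = 3, sigma = 1)  # same rhythm
#' @export
cosinor_effect <- function(mesor = 0, amplitude = NULL, acrophase = NULL,
                           sigma = 1, a1 = NULL, a2 = NULL) {
  if (!is.null(a1) || !is.null(a2)) {
    if (is.null(a1) || is.null(a2)) {
      stop("supply both 'a1' and 'a2' or neither", call. = FALSE)
    }
    if (!is.null(amplitude) || !is.null(acrophase)) {
      stop("supply either (amplitude, acrophase) or (a1, a2), not both",
           call. = FALSE)
    }
    amplitude <- sqrt(a1^2 + a2^2)
    acrophase <- if (amplitude > 0) atan2(a2, a1) else NA_real_
  } else {
    if (is.null(amplitude)) stop("'amplitude' is required", call. = FALSE)
    if (amplitude < 0) stop("'amplitude' must be >= 0", call. = FALSE)
    if (amplitude > 0 && is.null(acrophase)) {
      stop("'acrophase' is required when amplitude > 0", call. = FALSE)
    }
    if (amplitude == 0) acrophase <- NA_real_
    a1 <- if (amplitude == 0) 0 else amplitude * cos(acrophase)
    a2 <- if (amplitude == 0) 0 else amplitude * sin(acrophase)
  }
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("'sigma' must be > 0", call. = FALSE)
  }
  if (!is.na(acrophase)) {
    acrophase <- atan2(sin(acrophase), cos(acrophase))  # wrap to (-pi, pi]
  }
  structure(list(m = mesor, A = amplitude, phi = acrophase, sigma = sigma,
                 a1 = a1, a2 = a2),
            class = "cosinor_effect")
}

#' @export
print.cosinor_effect <- function(x, ...) {
  cat(sprintf(
    "Cosinor effect: mesor = %g, A = %g, phi = %s rad, sigma = %g (A/sigma = %g)\n",
    x$m, x$A, if (is.na(x$phi)) "undefined" else signif(x$phi, 6),
    x$sigma, x$A / x$sigma))
  invisible(x)
}

#' Cosinor design matrices
#'
#' Builds the partitioned design matrix `X = [X1 X2]` of the cosinor linear
#' model: `X1` holds the non-rhythmic columns (the intercept, plus optional
#' nuisance covariates such as trends or blocks) and `X2` holds the rhythmic
#' columns `cos(omega * t)` and `sin(omega * t)`.
#'
#' @param design a [sampling_design()].
#' @param extra_x1 optional numeric matrix (or vector) of nuisance
#'   covariates with one row per measurement; appended to the intercept.
#' @return List with matrices `X1` (n x q), `X2` (n x 2) and `X` (n x p,
#'   `p = q + 2`). Standard cosinor: `q = 1`, `p = 3`.
#' @export
cosinor_matrices <- function(design, extra_x1 = NULL) {
  stopifnot(inherits(design, "sampling_design"))
  n <- design$n
  X1 <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(extra_x1)) {
    extra_x1 <- as.matrix(extra_x1)
    if (nrow(extra_x1) != n) {
      stop(sprintf("'extra_x1' has %d rows but the design has %d times",
                   nrow(extra_x1), n), call. = FALSE)
    }
    if (is.null(colnames(extra_x1))) {
      colnames(extra_x1) <- paste0("x", seq_len(ncol(extra_x1)))
    }
    X1 <- cbind(X1, extra_x1)
  }
  th <- design$omega * design$times
  X2 <- cbind(cos = cos(th), sin = sin(th))
  list(X1 = X1, X2 = X2, X = cbind(X1, X2))
}

# Shared least-squares engine: rank-revealing QR with a condition guard.
# Clustered designs (all times in a narrow window) are ill-conditioned by
# construction, so normal equations are avoided.
.ls_qr <- function(X, what = "design matrix") {
  qrx <- qr(X, tol = 1e-12)
  if (qrx$rank < ncol(X)) {
    stop(sprintf(
      paste0("%s is rank deficient (rank %d < %d columns): the cosine/sine ",
             "columns are collinear with the non-rhythmic columns -- fewer ",
             "than 3 distinct times modulo the period, or aliased times"),
      what, qrx$rank, ncol(X)), call. = FALSE)
  }
  d <- abs(diag(qr.R(qrx)))
  if (max(d) / min(d) > 1e8) {
    warning(sprintf("%s is ill-conditioned (R-diagonal ratio %.2g); %s",
                    what, max(d) / min(d),
                    "estimates may be numerically unstable"), call. = FALSE)
  }
  qrx
}

#' Fit the cosinor model
#'
#' Least-squares fit of `y = m + a1 cos(omega t) + a2 sin(omega t) + eps`
#' together with the nested null model containing only the non-rhythmic
#' columns, and the F test of rhythmicity
#' `F = ((SSE_null - SSE_full) / (p - q)) / (SSE_full / (n - p))`,
#' referred under the null to the central `F(p - q, n - p)` distribution
#' (standard cosinor: `F(2, n - 3)`).
#'
#' Fitting uses a rank-revealing QR factorization; a rank-deficient design
#' (fewer than 3 distinct times modulo the period, or rhythmic columns
#' aliased with the nuisance columns) is an error, and an ill-conditioned
#' one raises a warning.
#'
#' @param y numeric response vector of length `n` (or an `n x G` matrix of
#'   feature series sharing the design; see [cosinor_fit_batch()]).
#' @param design a [sampling_design()].
#' @param extra_x1 optional nuisance covariates, as in [cosinor_matrices()].
#' @return Object of class `cosinor_fit`: coefficients for the full model,
#'   the null-model non-rhythmic coefficients, the two error sums of squares,
#'   the F statistic with degrees of freedom and p-value, the derived
#'   amplitude and acrophase estimates, fitted values and residuals.
#' @examples
#' d <- evenly_spaced_design(24)
#' y <- 2 + 3 * cos(d$omega * d$times - pi / 2) + rnorm(24, sd = 0.5)
#' fit <- cosinor_fit(y, d)
#' summary(fit)
#' @seealso [cosinor_f_test()], [cosinor_fit_batch()]
#' @export
cosinor_fit <- function(y, design, extra_x1 = NULL) {
  stopifnot(inherits(design, "sampling_design"))
  if (is.matrix(y) && ncol(y) > 1L) {
    return(cosinor_fit_batch(y, design, extra_x1 = extra_x1))
  }
  y <- as.numeric(y)
  mats <- cosinor_matrices(design, extra_x1)
  n <- design$n; p <- ncol(mats$X); q <- ncol(mats$X1)
  if (length(y) != n) {
    stop(sprintf("length(y) = %d but the design has %d times", length(y), n),
         call. = FALSE)
  }
  if (n <= p) {
    stop(sprintf("need n > %d observations for a residual degree of freedom (n = %d)",
                 p, n), call. = FALSE)
  }
  qr_full <- .ls_qr(mats$X, "full design matrix [X1 X2]")
  qr_null <- .ls_qr(mats$X1, "null design matrix X1")
  beta_full <- qr.coef(qr_full, y)
  beta_null <- qr.coef(qr_null, y)
  res_full <- qr.resid(qr_full, y)
  res_null <- qr.resid(qr_null, y)
  sse_full <- sum(res_full^2)
  sse_null <- sum(res_null^2)
  df1 <- p - q; df2 <- n - p
  # guard the 0/0 case (response in the null span fitted exactly): a
  # reduction below round-off relative to the response scale is no reduction
  scale <- sum(y^2) + .Machine$double.xmin
  delta_ss <- max(0, sse_null - sse_full)
  Fstat <- if (delta_ss <= 1e-14 * scale) 0 else
    (delta_ss / df1) / (sse_full / df2)
  a1 <- beta_full[["cos"]]; a2 <- beta_full[["sin"]]
  A_hat <- sqrt(a1^2 + a2^2)
  phi_hat <- if (A_hat > 0) atan2(a2, a1) else NA_real_
  structure(
    list(coefficients = beta_full, beta1_null = beta_null,
         sse_full = sse_full, sse_null = sse_null,
         statistic = Fstat, df = c(df1 = df1, df2 = df2),
         p.value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
         amplitude = A_hat, acrophase = phi_hat,
         peak_time = if (is.na(phi_hat)) NA_real_ else
           (phi_hat / design$omega) %% design$period,
         fitted.values = y - res_full, residuals = res_full,
         y = y, design = design, extra_x1 = extra_x1, n = n, p = p, q = q),
    class = "cosinor_fit"
  )
}

#' Batch cosinor fits over a feature matrix
#'
#' Fits the cosinor model to every column of an `n x G` matrix of feature
#' series sharing one sampling design, reusing a single QR factorization of
#' the design matrix. Raw p-values are returned; no multiple-testing
#' adjustment is applied.
#'
#' @param Y numeric matrix, one column per feature, one row per measurement.
#' @inheritParams cosinor_fit
#' @return A data frame with one row per feature: `mesor`, `a1`, `a2`,
#'   `amplitude`, `acrophase`, `sse_full`, `sse_null`, `F`, `p.value`.
#' @export
cosinor_fit_batch <- function(Y, design, extra_x1 = NULL) {
  stopifnot(inherits(design, "sampling_design"))
  Y <- as.matrix(Y)
  mats <- cosinor_matrices(design, extra_x1)
  n <- design$n; p <- ncol(mats$X); q <- ncol(mats$X1)
  if (nrow(Y) != n) {
    stop(sprintf("nrow(Y) = %d but the design has %d times", nrow(Y), n),
         call. = FALSE)
  }
  if (n <= p) stop("need n > p observations", call. = FALSE)
  qr_full <- .ls_qr(mats$X, "full design matrix [X1 X2]")
  qr_null <- .ls_qr(mats$X1, "null design matrix X1")
  B <- qr.coef(qr_full, Y)                      # p x G
  sse_full <- colSums(qr.resid(qr_full, Y)^2)
  sse_null <- colSums(qr.resid(qr_null, Y)^2)
  df1 <- p - q; df2 <- n - p
  scale <- colSums(Y^2) + .Machine$double.xmin
  delta_ss <- pmax(0, sse_null - sse_full)
  Fstat <- ifelse(delta_ss <= 1e-14 * scale, 0,
                  (delta_ss / df1) / (sse_full / df2))
  a1 <- B["cos", ]; a2 <- B["sin", ]
  A_hat <- sqrt(a1^2 + a2^2)
  phi_hat <- ifelse(A_hat > 0, atan2(a2, a1), NA_real_)
  data.frame(
    feature = colnames(Y) %||% paste0("V", seq_len(ncol(Y))),
    mesor = B["(Intercept)", ], a1 = a1, a2 = a2,
    amplitude = A_hat, acrophase = phi_hat,
    sse_full = sse_full, sse_null = sse_null,
    F = Fstat, p.value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' F test decision for a cosinor fit
#'
#' @param fit a [cosinor_fit()] object.
#' @param alpha test size in (0, 1).
#' @return List with `reject` (logical), `critical_value` (the upper-`alpha`
#'   quantile of the central F reference distribution), `statistic`,
#'   `p.value` and `alpha`.
#' @export
cosinor_f_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  crit <- stats::qf(1 - alpha, fit$df[["df1"]], fit$df[["df2"]])
  list(reject = fit$statistic > crit, critical_value = crit,
       statistic = fit$statistic, p.value = fit$p.value, alpha = alpha)
}

#' @export
print.cosinor_fit <- function(x, digits = 4, ...) {
  cat("Cosinor model fit\n")
  cat(sprintf("  n = %d, period = %g h\n", x$n, x$design$period))
  cat(sprintf("  mesor = %s, amplitude = %s, acrophase = %s rad (peak at %s h)\n",
              signif(x$coefficients[["(Intercept)"]], digits),
              signif(x$amplitude, digits),
              if (is.na(x$acrophase)) "NA" else signif(x$acrophase, digits),
              if (is.na(x$peak_time)) "NA" else signif(x$peak_time, digits)))
  cat(sprintf("  F(%d, %d) = %s, p = %s\n", x$df[["df1"]], x$df[["df2"]],
              signif(x$statistic, digits), format.pval(x$p.value, digits)))
  invisible(x)
}

#' @export
summary.cosinor_fit <- function(object, alpha = 0.05, ...) {
  tst <- cosinor_f_test(object, alpha)
  structure(list(fit = object, test = tst, alpha = alpha),
            class = "summary.cosinor_fit")
}

#' @export
print.summary.cosinor_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  SSE null = %s, SSE full = %s\n",
              signif(x$fit$sse_null, digits), signif(x$fit$sse_full, digits)))
  cat(sprintf("  at size alpha = %g: %s (critical F = %s)\n", x$alpha,
              if (x$test$reject) "reject the no-rhythm null" else
                "do not reject the no-rhythm null",
              signif(x$test$critical_value, digits)))
  invisible(x)
}

#' @export
coef.cosinor_fit <- function(object, ...) object$coefficients

#' @export
fitted.cosinor_fit <- function(object, ...) object$fitted.values

#' @export
residuals.cosinor_fit <- function(object, ...) object$residuals

#' @export
predict.cosinor_fit <- function(object, newtimes = NULL, ...) {
  if (is.null(newtimes)) return(object$fitted.values)
  if (!is.null(object$extra_x1)) {
    stop("prediction at new times is not defined for fits with nuisance covariates",
         call. = FALSE)
  }
  b <- object$coefficients
  w <- object$design$omega
  b[["(Intercept)"]] + b[["cos"]] * cos(w * newtimes) +
    b[["sin"]] * sin(w * newtimes)
}

#' @export
simulate.cosinor_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sd_hat <- sqrt(object$sse_full / object$df[["df2"]])
  mu <- object$fitted.values
  as.data.frame(replicate(nsim, mu + stats::rnorm(object$n, sd = sd_hat)))
}
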