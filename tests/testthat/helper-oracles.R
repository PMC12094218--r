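# Shared fixtures and independent oracles for the suite.

# Random unstructured design: times uniform on [0, period); generally
# non-centered and non-phase-invariant.
random_design <- function(n, period = 24) {
  sampling_design(stats::runif(n, 0, period), period = period)
}

# Independent least-squares oracle via lm(): fits null and full cosinor
# models without touching the package's QR path.
lm_oracle <- function(y, design, extra_x1 = NULL) {
  th <- design$omega * design$times
  df <- data.frame(y = y, c = cos(th), s = sin(th))
  if (is.null(extra_x1)) {
    full <- stats::lm(y ~ c + s, data = df)
    null <- stats::lm(y ~ 1, data = df)
  } else {
    df <- cbind(df, as.data.frame(extra_x1))
    nm <- colnames(as.data.frame(extra_x1))
    full <- stats::lm(stats::reformulate(c(nm, "c", "s"), "y"), data = df)
    null <- stats::lm(stats::reformulate(nm, "y"), data = df)
  }
  list(full = full, null = null,
       sse_full = sum(stats::resid(full)^2),
       sse_null = sum(stats::resid(null)^2))
}

# Brute-force population variance of cos(omega t - phi); the oracle behind
# the corrected noncentrality parameter.
brute_cosinor_var <- function(times, period, phi) {
  x <- cos(2 * pi / period * times - phi)
  mean(x^2) - mean(x)^2
}

# The standard gedanken design: 24 points clustered between ZT 5 and ZT 7.
gedanken_design <- function() uniform_grid_design(5, 7, 24, period = 24)
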