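#' Sampling designs for cosinor analysis
#'
#' A sampling design is the list of measurement times (in hours) together
#' with the assumed period of the rhythm under investigation. Its geometry --
#' where the times fall within the cycle -- determines the power of the
#' cosinor F test through the population variance of the rhythmic regressors.
#'
#' @param times numeric vector of measurement times in hours. Arbitrary real
#'   values are allowed, including negative times and repeated time points;
#'   repeats simply contribute repeated rows to the design matrix.
#' @param period period of the rhythm in hours (default 24, circadian).
#' @return An object of class `sampling_design`: a list with elements
#'   `times`, `period`, `omega` (angular frequency, `2*pi/period`) and `n`.
#' @examples
#' sampling_design(c(0, 6, 12, 18), period = 24)
#' @export
sampling_design <- function(times, period = 24) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times)) {
    stop("'times' must be a non-empty numeric vector without NA", call. = FALSE)
  }
  if (!is.numeric(period) || length(period) != 1L || !is.finite(period) ||
      period <= 0) {
    stop("'period' must be a single positive number (hours)", call. = FALSE)
  }
  structure(
    list(times = as.numeric(times), period = as.numeric(period),
         omega = 2 * pi / period, n = length(times)),
    class = "sampling_design"
  )
}

#' @export
print.sampling_design <- function(x, ...) {
  cat("Cosinor sampling design\n")
  cat(sprintf("  n = %d measurement times, period = %g h (omega = %.6g rad/h)\n",
              x$n, x$period, x$omega))
  shown <- utils::head(x$times, 10L)
  cat("  times:", paste(signif(shown, 6), collapse = ", "),
      if (x$n > 10L) sprintf("... (%d more)", x$n - 10L) else "", "\n")
  m <- design_moments(x)
  cat(sprintf("  centered: %s, phase-invariant: %s\n",
              m$centered, m$phase_invariant))
  invisible(x)
}

#' Evenly spaced sampling design
#'
#' Constructs the classic chronobiology schedule: `n_per_cycle` equally spaced
#' time points per cycle, over an integer number of cycles, with equal
#' replication at every time point. The spacing `period / n_per_cycle` also
#' holds for the wrap-around interval from the last point back to the first,
#' which makes the design centered and (for `n_per_cycle >= 3`)
#' phase-invariant.
#'
#' @param n_per_cycle number of distinct time points per cycle (>= 1).
#' @param n_cycles number of consecutive cycles sampled (default 1).
#' @param period period in hours (default 24).
#' @param replicates number of replicate measurements at each time point.
#' @param start time of the first measurement in hours (default 0).
#' @return A [sampling_design()] with `n_per_cycle * n_cycles * replicates`
#'   times.
#' @examples
#' evenly_spaced_design(4)                  # ZT 0, 6, 12, 18
#' evenly_spaced_design(6, replicates = 2)  # 12 samples, duplicated times
#' @export
evenly_spaced_design <- function(n_per_cycle, n_cycles = 1L, period = 24,
                                 replicates = 1L, start = 0) {
  for (nm in c("n_per_cycle", "n_cycles", "replicates")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != round(v)) {
      stop(sprintf("'%s' must be a positive integer", nm), call. = FALSE)
    }
  }
  dt <- period / n_per_cycle
  pts <- start + dt * seq.int(0L, n_per_cycle * n_cycles - 1L)
  sampling_design(rep(pts, each = replicates), period = period)
}

#' Uniform grid design on a closed interval
#'
#' Places `n` equally spaced time points on `[t_start, t_end]`, both
#' endpoints included (spacing `(t_end - t_start) / (n - 1)` for `n >= 2`).
#' Useful for designs that cluster measurements within a narrow window of the
#' cycle, such as 24 points between ZT 5 and ZT 7.
#'
#' @param t_start,t_end interval endpoints in hours, `t_end >= t_start`.
#' @param n number of time points (>= 1); `n = 1` returns `t_start` alone.
#' @param period period in hours (default 24).
#' @return A [sampling_design()].
#' @examples
#' uniform_grid_design(5, 7, 24)   # dense window around ZT 6
#' uniform_grid_design(0, 23, 24)  # same as evenly_spaced_design(24)
#' @export
uniform_grid_design <- function(t_start, t_end, n, period = 24) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (t_end < t_start) {
    stop("'t_end' must be >= 't_start'", call. = FALSE)
  }
  times <- if (n == 1L) t_start else seq(t_start, t_end, length.out = n)
  sampling_design(times, period = period)
}

#' Read a sampling design from CSV
#'
#' The file must contain a column `time` (hours). The period may be recorded
#' in a header comment of the form `# period=24`; a `period` argument, if
#' supplied, takes precedence over the file.
#'
#' @param path path to a CSV file.
#' @param period optional period in hours; overrides any `# period=` header.
#' @return A [sampling_design()].
#' @export
read_design_csv <- function(path, period = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop("empty design file: ", path, call. = FALSE)
  }
  hdr <- grep("^#\\s*period\\s*=", lines, value = TRUE)
  file_period <- if (length(hdr) > 0L) {
    as.numeric(sub("^#\\s*period\\s*=\\s*", "", hdr[1L]))
  } else NULL
  df <- utils::read.csv(text = lines, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (!"time" %in% names(df)) {
    stop("design CSV must contain a 'time' column (first data line is line ",
         which(!startsWith(trimws(lines), "#") & nzchar(trimws(lines)))[1L],
         ")", call. = FALSE)
  }
  per <- if (!is.null(period)) period else if (!is.null(file_period)) {
    file_period
  } else 24
  sampling_design(df$time, period = per)
}

#' Rhythmic moments of a sampling design
#'
#' Computes the means and population (divisor-n) variances and covariance of
#' the cosine and sine regressors evaluated at the design's time points.
#' These moments fully determine the noncentrality parameter of the cosinor
#' F test and classify the design:
#' \describe{
#'   \item{centered}{`mu_cos = mu_sin = 0`; the rhythmic regressors average
#'     to zero, so the mesor estimate is the same under the null and full
#'     models.}
#'   \item{phase-invariant}{`sigma2_cos = sigma2_sin` and `sigma_cossin = 0`;
#'     power does not depend on the rhythm's acrophase.}
#' }
#' Every evenly spaced design with at least 3 points per cycle has both
#' properties, with `sigma2_cos = sigma2_sin = 1/2`.
#'
#' @param design a [sampling_design()].
#' @param tol absolute tolerance for declaring the centered and
#'   phase-invariant flags (default `1e-10`); these are exact-zero properties
#'   of ideal designs, so only floating-point slack is needed.
#' @return An object of class `design_moments` with elements `mu_cos`,
#'   `mu_sin`, `sigma2_cos`, `sigma2_sin`, `sigma_cossin`, `centered`,
#'   `phase_invariant`, `n`.
#' @examples
#' design_moments(evenly_spaced_design(4))      # centered, phase-invariant
#' design_moments(uniform_grid_design(5, 7, 24)) # neither
#' @export
design_moments <- function(design, tol = 1e-10) {
  stopifnot(inherits(design, "sampling_design"))
  th <- design$omega * design$times
  cs <- cos(th); sn <- sin(th)
  mu_cos <- mean(cs); mu_sin <- mean(sn)
  s2c <- mean(cs^2) - mu_cos^2
  s2s <- mean(sn^2) - mu_sin^2
  scs <- mean(cs * sn) - mu_cos * mu_sin
  structure(
    list(mu_cos = mu_cos, mu_sin = mu_sin,
         sigma2_cos = s2c, sigma2_sin = s2s, sigma_cossin = scs,
         centered = abs(mu_cos) < tol && abs(mu_sin) < tol,
         phase_invariant = abs(s2c - s2s) < tol && abs(scs) < tol,
         n = design$n, tol = tol),
    class = "design_moments"
  )
}

#' @export
print.design_moments <- function(x, ...) {
  cat("Rhythmic design moments (population convention, divisor n)\n")
  cat(sprintf("  mu_cos = %.6g, mu_sin = %.6g\n", x$mu_cos, x$mu_sin))
  cat(sprintf("  sigma2_cos = %.6g, sigma2_sin = %.6g, sigma_cossin = %.6g\n",
              x$sigma2_cos, x$sigma2_sin, x$sigma_cossin))
  cat(sprintf("  centered: %s, phase-invariant: %s (tol %.1g)\n",
              x$centered, x$phase_invariant, x$tol))
  invisible(x)
}

#' Cosinor population mean and variance at a given acrophase
#'
#' For acrophase `phi`, evaluates the mean and population variance of
#' `cos(omega * t - phi)` over the design's time points. The variance is the
#' design- and phase-dependent factor of the corrected noncentrality
#' parameter `delta2 = n * A^2 / sigma^2 * sigma2_cosinor`. It satisfies
#' `sigma2_cosinor = cos(phi)^2 * sigma2_cos + sin(phi)^2 * sigma2_sin +
#' 2 * cos(phi) * sin(phi) * sigma_cossin`, and is constant in `phi` exactly
#' when the design is phase-invariant.
#'
#' @param design a [sampling_design()].
#' @param phi acrophase in radians (vectorised).
#' @return A list with numeric elements `mu_cosinor` and `sigma2_cosinor`,
#'   each the length of `phi`.
#' @examples
#' cosinor_variance(evenly_spaced_design(4), pi / 3)$sigma2_cosinor  # 1/2
#' @export
cosinor_variance <- function(design, phi) {
  stopifnot(inherits(design, "sampling_design"))
  if (!is.numeric(phi) || length(phi) < 1L) {
    stop("'phi' must be numeric", call. = FALSE)
  }
  th <- design$omega * design$times
  mu <- vapply(phi, function(p) mean(cos(th - p)), numeric(1L))
  m2 <- vapply(phi, function(p) mean(cos(th - p)^2), numeric(1L))
  list(mu_cosinor = mu, sigma2_cosinor = m2 - mu^2)
}

#' Classify a design as evenly spaced
#'
#' Checks whether the sorted distinct time points (modulo the period) have
#' constant spacing including the wrap-around interval, with equal
#' replication, i.e., whether the design is evenly spaced in the
#' chronobiological sense.
#'
#' @param design a [sampling_design()].
#' @param tol absolute tolerance on spacing and replication equality.
#' @return Logical flag.
#' @export
is_evenly_spaced <- function(design, tol = 1e-8) {
  stopifnot(inherits(design, "sampling_design"))
  tm <- sort(design$times %% design$period)
  grp <- cumsum(c(TRUE, diff(tm) > tol))
  reps <- tabulate(grp)
  if (length(unique(reps)) > 1L) return(FALSE)
  pts <- tm[!duplicated(grp)]
  k <- length(pts)
  if (k == 1L) return(TRUE)
  gaps <- c(diff(pts), design$period - pts[k] + pts[1L])
  max(gaps) - min(gaps) < tol
}
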