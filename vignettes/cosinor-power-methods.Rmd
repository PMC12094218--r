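---
title: "Power analysis for cosinor rhythm detection: model, corrected noncentrality, and validation"
author: "cosinorpower"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power analysis for cosinor rhythm detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosinorpower)
```

## The model and the test

The standard cosinor model describes a rhythmic measurement series taken at
times $t_i$ (hours) as

$$y_i = m + a_1\cos(\omega t_i) + a_2\sin(\omega t_i) + \varepsilon_i,
\qquad \varepsilon_i \sim \mathcal N(0, \sigma^2)\ \text{i.i.d.},$$

with angular frequency $\omega = 2\pi/T$ for a known period $T$ (24 h for
circadian work). The rhythmic part can equivalently be written
$A\cos(\omega t - \varphi)$ with amplitude $A = \sqrt{a_1^2 + a_2^2}$ and
acrophase $\varphi = \operatorname{atan2}(a_2, a_1)$; the intercept $m$ is
the mesor. Rhythm detection tests $H_0\!: a_1 = a_2 = 0$ with the F
statistic

$$F = \frac{(\mathrm{SSE}_\text{null} - \mathrm{SSE}_\text{full})/(p-q)}
           {\mathrm{SSE}_\text{full}/(n-p)},$$

which under $H_0$ is central $F(2,\, n-3)$ for the standard model
($p = 3$, $q = 1$).

## Why the naive noncentrality parameter is wrong

Under an alternative $(a_1, a_2) \ne 0$ the statistic is noncentral F, and
power is driven by the noncentrality parameter $\delta^2$. Writing the
design matrix in blocks $X = [X_1\; X_2]$ ($X_1$ the intercept and any
nuisance columns, $X_2$ the cosine/sine columns), it is tempting to read the
reduction in sum of squares as $\hat\beta_2^\top X_2^\top X_2 \hat\beta_2$,
giving $\delta^2 = \beta_2^\top X_2^\top X_2\beta_2/\sigma^2$. That step
silently assumes the intercept estimate is the same in the null and full
models. It is not, unless the rhythmic regressors average to zero over the
sampling times: the full- and null-model intercepts are linked by

$$\hat\beta_{1,\text{full}} = \hat\beta_{1,\text{null}}
  - \hat a_1\,\mu_{\cos} - \hat a_2\,\mu_{\sin},
\qquad \mu_{\cos} = \tfrac1n\textstyle\sum_i \cos\omega t_i,\quad
\mu_{\sin} = \tfrac1n\textstyle\sum_i \sin\omega t_i.$$

A design with $\mu_{\cos} = \mu_{\sin} = 0$ is *centered*; only then does
the naive quadratic form equal the true reduction in sum of squares. The
package deliberately implements the naive expression
(`ncp_zong_incorrect()`) alongside the correct one so the discrepancy can
be quantified, but it should never be used for planning.

## The corrected noncentrality parameter

The clean route is the Frisch–Waugh–Lovell reparameterization: replace
$X_2$ by its residual after projecting out $X_1$,

$$Z_2 = \bigl(I - X_1(X_1^\top X_1)^{-1}X_1^\top\bigr) X_2,$$

so that $X_1^\top Z_2 = 0$ and the reduction in sum of squares is exactly
$\hat\beta_2^\top Z_2^\top Z_2 \hat\beta_2$ for *any* nuisance block
(trends, batch indicators, ...). Its scaled version follows a noncentral
$\chi^2$ law with 2 degrees of freedom and noncentrality

$$\delta^2 = \beta_2^\top Z_2^\top Z_2\,\beta_2 / \sigma^2
\qquad (\texttt{general\_ncp()}).$$

For the standard model ($X_1$ = intercept), $Z_2$ is simply the
column-centered $X_2$ and the quadratic form collapses to a closed form in
the *population* (divisor-$n$) variance of the phase-shifted cosine
regressor:

$$\delta^2 = n\,\frac{A^2}{\sigma^2}\,\sigma^2_\text{cosinor}(\varphi),
\qquad
\sigma^2_\text{cosinor}(\varphi) = \tfrac1n\textstyle\sum_i
  \cos^2(\omega t_i - \varphi) -
  \Bigl(\tfrac1n\textstyle\sum_i \cos(\omega t_i - \varphi)\Bigr)^2$$

(`ncp_standard()`). The divisor-$n$ convention is forced by these
definitions; the package uses it throughout (never $n-1$). Power is then
the upper tail of the noncentral $F(2,\, n-3,\, \delta^2)$ distribution
beyond the central-F critical value (`power_from_ncp()`, computed with
`stats::pf(..., ncp=)`; accurate to roughly $10^{-10}$, no Monte Carlo in
the analytic path). Note the $\delta^2$ convention: it enters undivided by
the numerator degrees of freedom, unlike some power calculators.

## Design taxonomy

`design_moments()` summarizes a sampling schedule by
$\mu_{\cos}, \mu_{\sin}$, the population variances
$\sigma^2_{\cos}, \sigma^2_{\sin}$ and covariance $\sigma_{\cos,\sin}$, and
two flags:

* **centered** — $\mu_{\cos} = \mu_{\sin} = 0$: the naive and corrected
  noncentrality parameters coincide;
* **phase-invariant** — $\sigma^2_{\cos} = \sigma^2_{\sin}$ and
  $\sigma_{\cos,\sin} = 0$: $\delta^2$, hence power, does not depend on the
  acrophase.

An *evenly spaced* design (integer number of cycles, constant spacing
including the wrap-around interval, equal replication) is sufficient for
both, with $\sigma^2_{\cos} = \sigma^2_{\sin} = 1/2$, so
$\delta^2 = nA^2/(2\sigma^2)$ at any phase. The flags use an absolute
tolerance of $10^{-10}$ (user-overridable): they are exact-zero properties
of ideal designs, and only floating-point slack is needed.

A worked pathological case wired through the tests and the acceptance
script: 24 time points placed uniformly on the closed interval
[ZT 5, ZT 7] (spacing $2/23$ h), rhythm peaking at ZT 6
($\varphi = \pi/2$), $A/\sigma = 3$. The naive formula yields
$\delta^2 \approx 210$ (power essentially 1); the corrected formula yields
$\delta^2 \approx 0.026$ and power $\approx 0.052$ at size 0.05 — barely
above chance, because a window clustered at the peak sees almost no
curvature of the cosine. Monte Carlo rejection rates side with the
corrected formula. The endpoint-inclusive grid convention for "uniformly
between" was chosen because it is the natural reading of a closed interval
and reproduces all three figures simultaneously; comparisons of these
figures are made at two significant digits, the precision at which they are
conventionally quoted.

## Numerical choices

* **Least squares by rank-revealing QR**, never normal equations. Clustered
  designs make the cosine/sine columns nearly collinear with the intercept
  (the ZT 5–7 window has regressor variance of order $10^{-2}$), so the
  Gram matrix squares an already bad condition number. A warning is issued
  when the ratio of QR R-diagonal magnitudes exceeds $10^8$; rank
  deficiency (fewer than 3 distinct times modulo the period, or aliased
  times) is an error naming the offending structure.
* **Projections via the QR of $X_1$** rather than the explicit inverse, for
  the same stability reasons; the orthogonality $X_1^\top Z_2 = 0$ is
  asserted in tests at a scale-free tolerance of $10^{-8}\,\|X_2\|$.
* **Degenerate F statistics**: when the reduction in sum of squares is
  below $10^{-14}$ of the response's squared scale (e.g., a constant series
  fitted exactly by the null model), the statistic is reported as 0 rather
  than an arbitrary 0/0 ratio of round-off residuals.
* **Acrophase** is reported by `atan2` in $(-\pi, \pi]$ plus a peak-time
  conversion $\varphi/\omega \bmod T$; a zero-amplitude fit has an
  undefined acrophase, reported as `NA`.
* **Times** are accepted as arbitrary reals (negative and replicated values
  allowed) and enter only through $\omega t$; no modular reduction is
  applied, since the trigonometric functions are periodic.
* **Sample-size solver**: replicating a template design $k$ times
  multiplies $\delta^2$ by $k$ while leaving the time-point distribution
  unchanged, so the solver brackets by doubling and then bisects on the
  smallest sufficient $k$; an unreachable target (zero amplitude, or a
  design blind at the stated acrophase) is an explicit error.

## What the simulator emulates — and what it does not

`simulate_series()` draws i.i.d. Gaussian noise around the deterministic
cosinor mean at the design's times — exactly the error model under which
the F test and the noncentral-F power expression are derived. A fixed
integer seed gives bit-identical output. The simulation layer exists to
validate the analytic results:

* `mc_power()` compares rejection rates against `power_from_ncp()`; bands
  are 4 binomial standard errors (about a 1-in-16 000 false alarm per
  check).
* `mc_ncp_distribution()` checks the sampling law of
  $\hat\beta_2^\top Z_2^\top Z_2\hat\beta_2/\sigma^2$ against the
  noncentral $\chi^2_2(\delta^2)$ moments, mean $2 + \delta^2$ and variance
  $2(2 + 2\delta^2)$.

The generator intentionally omits features of real rhythmic data —
autocorrelated or heteroscedastic noise, non-sinusoidal waveforms,
between-subject variability, count-type measurement error. Passing tests
therefore establish the correctness of the algebra and of the Gaussian
sampling theory, not robustness to those violations. The test suite runs
its calibration checks at 8 000–20 000 replicates on designs of 24 points,
sizes chosen so the binomial bands are tight enough to separate the two
formulas decisively (analytic power 0.052 vs. a claimed ~1).

The RNG design is deliberately simple: one `set.seed()` call per simulation
entry point, with all draws in a single vectorized block. Deterministic
per-replicate substreams would matter only for parallel generation, which
this package does not do.

## Limitations

The period is assumed known; no period scanning, multi-harmonic waveforms,
weighted or generalized least squares, non-Gaussian errors, or
multiple-testing procedures for omics-scale screens are provided. Batch
fitting over feature matrices returns raw p-values and leaves any
adjustment (`p.adjust`, FDR) to the caller. The command-line front end is a
thin wrapper over the same exported functions; analyses beyond its
subcommands should use the package directly.
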