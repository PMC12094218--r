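test_that("evenly spaced constructor places times at constant spacing", {
  expect_equal(evenly_spaced_design(4)$times, c(0, 6, 12, 18))
  expect_equal(evenly_spaced_design(2, n_cycles = 2)$times, c(0, 12, 24, 36))
  d <- evenly_spaced_design(6, replicates = 2, start = 1)
  expect_length(d$times, 12)
  expect_equal(sort(unique(d$times)), c(1, 5, 9, 13, 17, 21))
  expect_true(all(table(d$times) == 2))
  expect_error(evenly_spaced_design(0), "positive integer")
  expect_error(evenly_spaced_design(4, replicates = -1), "positive integer")
})

test_that("uniform grid includes both endpoints", {
  d <- uniform_grid_design(5, 7, 24)
  expect_length(d$times, 24)
  expect_equal(d$times[1], 5)
  expect_equal(d$times[24], 7)
  expect_equal(unique(round(diff(d$times), 12)), round(2 / 23, 12))
  expect_equal(uniform_grid_design(0, 0, 1)$times, 0)
  expect_equal(uniform_grid_design(0, 23, 24)$times, 0:23)
  expect_error(uniform_grid_design(7, 5, 24), "t_end")
})

test_that("design invariants hold: omega and period, input validation", {
  d <- sampling_design(c(0, 3), period = 20)
  expect_equal(d$omega * d$period, 2 * pi)
  expect_error(sampling_design(numeric(0)), "non-empty")
  expect_error(sampling_design(0, period = -1), "positive")
})

test_that("rhythmic moments match hand-computed designs", {
  m <- design_moments(evenly_spaced_design(4))
  expect_equal(m$mu_cos, 0, tolerance = 1e-12)
  expect_equal(m$mu_sin, 0, tolerance = 1e-12)
  expect_equal(m$sigma2_cos, 0.5, tolerance = 1e-12)
  expect_equal(m$sigma2_sin, 0.5, tolerance = 1e-12)
  expect_equal(m$sigma_cossin, 0, tolerance = 1e-12)
  expect_true(m$centered)
  expect_true(m$phase_invariant)

  m1 <- design_moments(sampling_design(0))
  expect_equal(m1$mu_cos, 1)
  expect_equal(m1$mu_sin, 0)
  expect_equal(m1$sigma2_cos, 0)
  expect_equal(m1$sigma2_sin, 0)
  expect_equal(m1$sigma_cossin, 0)

  mg <- design_moments(gedanken_design())
  expect_false(mg$centered)
  expect_false(mg$phase_invariant)
  expect_gt(mg$mu_sin, 0.9)  # all phases cluster near omega*t = pi/2
})

test_that("moment identities hold on random designs", {
  set.seed(101)
  for (i in 1:25) {
    d <- random_design(sample(3:40, 1))
    m <- design_moments(d)
    expect_equal(m$sigma2_cos + m$mu_cos^2 + m$sigma2_sin + m$mu_sin^2, 1,
                 tolerance = 1e-12)
    expect_gte(m$sigma2_cos, 0)
    expect_gte(m$sigma2_sin, 0)
    expect_lte(abs(m$sigma_cossin),
               sqrt(m$sigma2_cos * m$sigma2_sin) + 1e-12)
    # shift by whole periods leaves every moment unchanged
    k <- sample(c(-3L, -1L, 2L, 5L), 1)
    m2 <- design_moments(sampling_design(d$times + k * d$period, d$period))
    expect_equal(unclass(m)[1:5], unclass(m2)[1:5], tolerance = 1e-9)
  }
})

test_that("evenly spaced designs are centered and phase-invariant with variance 1/2", {
  for (npc in c(3, 4, 5, 7, 12)) {
    for (reps in c(1, 2)) {
      m <- design_moments(evenly_spaced_design(npc, n_cycles = 2,
                                               replicates = reps,
                                               start = 1.3))
      expect_true(m$centered)
      expect_true(m$phase_invariant)
      expect_equal(m$sigma2_cos, 0.5, tolerance = 1e-10)
      expect_equal(m$sigma2_sin, 0.5, tolerance = 1e-10)
    }
  }
})

test_that("cosinor variance matches its quadratic expansion in the moments", {
  set.seed(202)
  for (i in 1:10) {
    d <- random_design(sample(4:30, 1))
    m <- design_moments(d)
    phis <- runif(7, -pi, pi)
    cv <- cosinor_variance(d, phis)
    expansion <- cos(phis)^2 * m$sigma2_cos + sin(phis)^2 * m$sigma2_sin +
      2 * cos(phis) * sin(phis) * m$sigma_cossin
    expect_equal(cv$sigma2_cosinor, expansion, tolerance = 1e-12)
  }
})

test_that("cosinor variance reduces to the marginal moments at phi = 0 and pi/2", {
  d <- gedanken_design()
  m <- design_moments(d)
  cv0 <- cosinor_variance(d, 0)
  expect_equal(cv0$mu_cosinor, m$mu_cos)
  expect_equal(cv0$sigma2_cosinor, m$sigma2_cos)
  cv90 <- cosinor_variance(d, pi / 2)
  expect_equal(cv90$mu_cosinor, m$mu_sin)
  expect_equal(cv90$sigma2_cosinor, m$sigma2_sin)
})

test_that("cosinor variance: phase-invariant designs give 1/2, one point gives 0", {
  d <- evenly_spaced_design(4)
  for (phi in c(-2, 0, 0.4, pi / 2)) {
    expect_equal(cosinor_variance(d, phi)$sigma2_cosinor, 0.5,
                 tolerance = 1e-12)
  }
  expect_equal(cosinor_variance(sampling_design(11), 1.2)$sigma2_cosinor, 0)
  # clustered window: tiny variance at the in-window peak phase
  expect_equal(cosinor_variance(gedanken_design(), pi / 2)$sigma2_cosinor,
               1.2139969142e-04, tolerance = 1e-9)
})

test_that("sigma2_cosinor is constant in phi exactly for phase-invariant designs", {
  grid <- seq(-pi, pi, length.out = 181)
  v_inv <- cosinor_variance(evenly_spaced_design(5), grid)$sigma2_cosinor
  expect_lt(diff(range(v_inv)), 1e-12)
  # clustered design: barely-varying regressors, so total variance is small
  # (bounded by 1 - mu_cos^2 - mu_sin^2 ~ 0.024), but clearly phase-dependent
  v_non <- cosinor_variance(gedanken_design(), grid)$sigma2_cosinor
  expect_gt(diff(range(v_non)), 0.01)
})

test_that("evenly spaced classifier recognises wrap-around spacing", {
  expect_true(is_evenly_spaced(evenly_spaced_design(6, n_cycles = 2,
                                                    replicates = 3,
                                                    start = 2)))
  expect_true(is_evenly_spaced(sampling_design(c(0, 6, 12, 18))))
  expect_false(is_evenly_spaced(sampling_design(c(0, 6, 12))))   # gap 12 wrap
  expect_false(is_evenly_spaced(gedanken_design()))
})

test_that("design CSV round-trips with period header and flag precedence", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("# period=20", "time", "0", "5", "10", "15"), f)
  d <- read_design_csv(f)
  expect_equal(d$period, 20)
  expect_equal(d$times, c(0, 5, 10, 15))
  expect_equal(read_design_csv(f, period = 12)$period, 12)  # flag wins
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("hour", "1", "2"), f2)
  expect_error(read_design_csv(f2), "'time' column")
  f3 <- tempfile(fileext = ".csv")
  writeLines(character(0), f3)
  expect_error(read_design_csv(f3), "empty")
  # packaged example design
  dp <- read_design_csv(system.file("extdata", "evenly_spaced_16pt.csv",
                                    package = "cosinorpower"))
  expect_equal(dp$n, 16)
  expect_true(is_evenly_spaced(dp))
})
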