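# regression, inversion and standard value assignment

test_that("a noiseless line is recovered exactly under every weighting", {
  x <- c(0, 1, 2); y <- c(0.1, 2.1, 4.1)
  for (w in c("bisquare", "ols", "inverse_x2")) {
    f <- irls_fit(x, y, weighting = w)
    expect_equal(f$beta0, 0.1, tolerance = 1e-12, info = w)
    expect_equal(f$beta1, 2.0, tolerance = 1e-12, info = w)
    expect_equal(f$r_squared, 1)
  }
  expect_error(irls_fit(c(1, 1, 2), c(1, 1.1, 2)), "3 distinct")
})

test_that("unit-weight IRLS reproduces ordinary least squares exactly", {
  set.seed(11)
  x <- rep(seq(0.5, 5, length.out = 7), each = 3)
  y <- 0.02 + 1.7 * x + rnorm(length(x), 0, 0.05)
  f <- irls_fit(x, y, weighting = "ols")
  ols <- lm(y ~ x)
  expect_identical(f$beta0, unname(coef(ols)[1]))
  expect_identical(f$beta1, unname(coef(ols)[2]))
  expect_equal(f$u_beta1, summary(ols)$coefficients[2, 2])
})

test_that("a gross outlier barely moves the robust fit", {
  set.seed(21)
  x <- rep(seq(0.5, 5, length.out = 7), each = 3)
  y <- 0.05 + 2 * x + rnorm(length(x), 0, 0.01)
  clean <- irls_fit(x, y, weighting = "ols")
  y_out <- c(y, 2 * 2.5 + 1.0)                # residual 100x the noise sd
  rob <- irls_fit(c(x, 2.5), y_out)
  expect_lt(abs(rob$beta1 / clean$beta1 - 1), 0.01)
  expect_lt(abs(rob$beta0 - clean$beta0), 0.01 * clean$beta1)
})

test_that("calibration is scale-equivariant in the molality axis", {
  set.seed(3)
  x <- rep(1:7, each = 3)
  y <- 0.1 + 0.5 * x + rnorm(21, 0, 0.02)
  for (w in c("bisquare", "ols")) {
    f1 <- irls_fit(x, y, weighting = w)
    f2 <- irls_fit(1e-12 * x, y, weighting = w)
    expect_equal(f2$beta1, f1$beta1 / 1e-12, tolerance = 1e-9)
    expect_equal(f2$beta0, f1$beta0, tolerance = 1e-9)
  }
})

test_that("seven-level curves reach R^2 >= 0.99 at 3 % multiplicative noise", {
  set.seed(41)
  levels <- seq(2.5, 25, length.out = 7)
  r2 <- replicate(200, {
    x <- rep(levels, each = 5)
    y <- x * (1 + rnorm(length(x), 0, 0.03))
    irls_fit(x, y)$r_squared
  })
  expect_true(all(r2 >= 0.99))
})

test_that("inversion is the exact inverse of the forward line", {
  f <- irls_fit(c(0, 1, 2), c(0.1, 2.1, 4.1))
  expect_equal(invert_calibration(f$beta0, f)$value, 0)
  expect_equal(invert_calibration(0.5, f)$value, 0.2)
  # round trip at arbitrary molalities, zero noise
  for (b in c(0.05, 0.37, 1.3)) {
    r <- f$beta0 + f$beta1 * b
    expect_equal(invert_calibration(r, f)$value, b, tolerance = 1e-12)
  }
  below <- invert_calibration(f$beta0 - 0.05, f)
  expect_lt(below$value, 0)                   # negative, not clipped
  expect_true(attr(below, "below_blank"))
})

test_that("inverted molality carries the fit and ratio uncertainties", {
  set.seed(5)
  x <- rep(seq(0, 6), each = 4)
  y <- 0.05 + 2 * x + rnorm(length(x), 0, 0.05)
  f <- irls_fit(x, y, weighting = "ols")
  b0 <- invert_calibration(4, f, u_ratio = 0)
  b1 <- invert_calibration(4, f, u_ratio = 0.1)
  expect_gt(b1$u, b0$u)
  expect_equal(b1$u, sqrt(b0$u^2 + (0.1 / f$beta1)^2), tolerance = 1e-10)
})

test_that("purity-by-proxy averages with a rectangular range uncertainty", {
  p <- assign_purity_by_proxy(c(0.50, 0.60, 0.70))
  expect_equal(p$value, 0.60)
  expect_equal(p$u, 0.20 / (2 * sqrt(3)), tolerance = 1e-12)
  expect_identical(p$dist, "rectangular")
  expect_equal(assign_purity_by_proxy(c(0.8, 0.8, 0.8))$u, 0)
  expect_error(assign_purity_by_proxy(0.9), "two")
  # mean bounded by the extremes for arbitrary input sets
  set.seed(9)
  for (i in 1:20) {
    ps <- runif(sample(2:10, 1), 0.4, 1)
    est <- assign_purity_by_proxy(ps)$value
    expect_true(est >= min(ps) && est <= max(ps))
  }
})

test_that("reverse IDMS recovers the SIL concentration", {
  expect_equal(reverse_idms_assign(2e-12, 1.0)$value, 2e-12)
  # exact recovery at zero noise for spikes at different ratios
  truth <- 4e-12
  nat <- c(2e-12, 4e-12, 8e-12)
  expect_equal(reverse_idms_assign(nat, nat / truth)$value, truth,
               tolerance = 1e-15)
  expect_error(reverse_idms_assign(1e-12, 0), "positive")
  # 5 % multiplicative noise, 6 spikes: bias below 2 % over 500 simulations
  set.seed(17)
  est <- replicate(500, {
    nat6 <- runif(6, 1e-12, 8e-12)
    r <- nat6 / truth * rlnorm(6, 0, sqrt(log(1 + 0.05^2)))
    reverse_idms_assign(nat6, r)$value
  })
  expect_lt(abs(mean(est) / truth - 1), 0.02)
})

test_that("blend design is linear in the target and zero at zero", {
  b0 <- blend_design(fix_model, 0)
  expect_true(all(b0 == 0))
  b1 <- blend_design(fix_model, 5)
  b2 <- blend_design(fix_model, 10)
  expect_equal(b2, 2 * b1, tolerance = 1e-14)
  # the SIL blend level sits at half the span of the default design
  d <- calibration_design()
  nz <- d$nominal_tcmp[d$nominal_tcmp > 0]
  expect_equal((max(nz) - min(nz)) / 2, 11.25)
})

test_that("curve fitting runs per peptide and the ion-ratio QC flags deviants", {
  sim <- simulate_experiment(simulation_truth(cv = 0.02, seed = 13))
  cal <- sim$calibration
  # corrupt one qualifier replicate by a factor 2
  i <- which(cal$peptide == "AVPYPQR" & cal$transition_rank == 2L &
               cal$level_id == 4 & cal$replicate == 1)
  cal$area_natural[i] <- cal$area_natural[i] * 2
  cc <- fit_calibration_curves(cal, sim$design)
  expect_named(cc$fits)
  expect_length(cc$fits, 11)
  expect_true(all(vapply(cc$fits, function(f) f$beta1 > 0, logical(1))))
  qc <- cc$ion_ratio_qc
  flagged <- qc[qc$flagged, ]
  expect_true(any(flagged$peptide == "AVPYPQR" & flagged$level_id == 4 &
                    flagged$replicate == 1))
})
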