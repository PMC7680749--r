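# LOQ, nested variance components, batch D%, linearity, selectivity

test_that("LOQ is 10 sd / slope and scale-equivariant", {
  f <- irls_fit(c(0, 1, 2), c(0, 2, 4))     # slope 2
  blanks <- c(0.1, 0.2, 0.0, 0.15, 0.05, 0.1)
  out <- loq(blanks, f)
  expect_identical(out$loq_molality, 10 * sd(blanks) / f$beta1)
  expect_equal(loq(rep(0.3, 6), f)$loq_molality, 0)
  expect_error(loq(blanks[1:5], f), "six")
  # doubling blank sd and slope leaves the LOQ unchanged
  f2 <- irls_fit(c(0, 1, 2), c(0, 4, 8))
  expect_equal(loq(2 * blanks, f2)$loq_molality, out$loq_molality)
  # expressed in mg TCMP/kg through the same chain as samples
  p <- fix_model$proteins$CASA2
  out2 <- loq(blanks, f, fix_grav, p$molar_mass, p$cf)
  w <- protein_mass_fraction(out$loq_molality, fix_grav, p$molar_mass)
  expect_equal(out2$loq_tcmp, w / p$cf$value)
})

make_nested <- function(sd_a, sd_b, sd_e, n = c(3, 3, 3), mean = 1) {
  d <- expand.grid(extraction = seq_len(n[1]), digestion = seq_len(n[2]),
                   injection = seq_len(n[3]))
  ea <- rnorm(n[1], 0, sd_a * mean)
  eb <- matrix(rnorm(n[1] * n[2], 0, sd_b * mean), n[1])
  d$response <- mean + ea[d$extraction] +
    eb[cbind(d$extraction, d$digestion)] +
    rnorm(nrow(d), 0, sd_e * mean)
  d
}

test_that("constant responses give all-zero variance components", {
  d <- make_nested(0, 0, 0)
  vc <- variance_components(d, c("extraction", "digestion", "injection"))
  expect_true(all(vc$components$rsd_pct < 1e-6))
  expect_lt(vc$total_rsd_pct, 1e-6)
})

test_that("nested EMS recovers known components without bias", {
  set.seed(33)
  sims <- replicate(300, {
    d <- make_nested(0.05, 0, 0.04)
    vc <- variance_components(d, c("extraction", "digestion", "injection"))
    vc$components$rsd_pct
  })
  avg <- rowMeans(sims)
  expect_lt(abs(avg[1] - 5), 1)               # extraction ~5 %
  expect_lt(abs(avg[2] - 0), 1)               # digestion ~0 %
  expect_lt(abs(avg[3] - 4), 1)               # injection ~4 %
})

test_that("negative moment estimates are truncated to zero and flagged", {
  set.seed(8)
  hit <- FALSE
  for (i in 1:20) {
    d <- make_nested(0, 0, 0.05)
    vc <- variance_components(d, c("extraction", "digestion", "injection"))
    expect_true(all(vc$components$variance >= 0))
    hit <- hit || any(vc$components$truncated)
  }
  expect_true(hit)
})

test_that("unbalanced designs fall back to REML", {
  skip_if_not_installed("lme4")
  set.seed(12)
  d <- make_nested(0.05, 0.02, 0.04)
  d <- d[-1, ]                                # break the balance
  vc <- variance_components(d, c("extraction", "digestion", "injection"))
  expect_identical(vc$method, "reml")
  expect_true(all(vc$components$variance >= 0))
})

test_that("published repeatability totals equal the quadrature of components", {
  # printed three-factor components (%), repeatability study
  comp <- list(FFV = c(4.7, 0.0, 3.7, 6.0), YLG = c(2.2, 0.0, 3.5, 4.1),
               ALN = c(5.3, 0.7, 4.0, 6.7), FAL = c(6.4, 0.0, 3.5, 7.3),
               NAV = c(4.6, 0.0, 5.8, 7.4), VIP = c(5.6, 0.0, 4.8, 7.4),
               AVP = c(7.3, 0.0, 12.4, 14.4), VLP = c(4.1, 2.8, 3.7, 6.2),
               YIP = c(6.3, 0.0, 15.1, 16.4), ALP = c(3.7, 3.9, 4.6, 7.1),
               IPA = c(2.2, 2.8, 4.0, 5.4))
  totals <- vapply(comp, function(x) sqrt(sum(x[1:3]^2)), numeric(1))
  printed <- vapply(comp, `[[`, numeric(1), 4)
  expect_true(all(abs(totals - printed) < 0.1))
  # repeatability better than 7.5 % for 9 of the 11 peptides
  expect_equal(sum(printed <= 7.5), 9)
})

test_that("percent difference and batch stability behave as defined", {
  expect_equal(percent_difference(105, 100), 5)
  expect_equal(percent_difference(7, 7), 0)
  for (x in c(0.1, 3, 250)) expect_equal(percent_difference(x, x), 0)
  expect_error(percent_difference(1, 0), "positive")
  d <- data.frame(peptide = c("FFV", "ALP"), measured = c(102, 94),
                  nominal = c(100, 100))
  out <- batch_stability(d)
  expect_identical(out$flagged, c(FALSE, TRUE))
})

test_that("linearity check flags proportional noise but not constant noise", {
  # full default design: level 0 plus the seven non-zero levels
  x <- rep(calibration_design()$nominal_tcmp, each = 5)
  y0 <- 0.1 + 2 * x
  lin <- linearity_check(x, y0)
  expect_equal(lin$r_squared, 1)
  expect_false(lin$heteroscedastic)
  expect_error(linearity_check(rep(1:4, 2), rnorm(8)), "five")
  set.seed(27)
  flags <- replicate(500, {
    y <- y0 * (1 + rnorm(length(x), 0, 0.05))
    linearity_check(x, y)$heteroscedastic
  })
  expect_gte(mean(flags), 0.8)
})

test_that("selectivity reports cross-channel interference against 0.5 %", {
  d <- data.frame(peptide = c("FFV", "YLG", "NAV"),
                  area_interference = c(0, 400, 1000),
                  area_analyte = c(1e5, 1e5, 1e5))
  out <- selectivity_check(d)
  expect_equal(out$interference_pct, c(0, 0.4, 1))
  expect_identical(out$flagged, c(FALSE, FALSE, TRUE))
  expect_error(selectivity_check(data.frame(peptide = "x",
                                            area_interference = 1,
                                            area_analyte = 0)), "positive")
})
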