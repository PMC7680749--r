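# Kragten propagation, Monte Carlo oracle and the peptide budgets

test_that("kragten adds independent contributions in quadrature", {
  ins <- rbind(uncertain_input("x", 10, 3), uncertain_input("y", 5, 4))
  bud <- kragten(function(v) v$x + v$y, ins)
  expect_equal(bud$u, 5)
  expect_equal(bud$U, 10)
  expect_equal(sum(bud$indexes), 100)
  expect_equal(unname(bud$indexes["x"]), 100 * 9 / 25)
})

test_that("kragten of a constant function is zero with zero indexes", {
  ins <- rbind(uncertain_input("x", 1, 0.5), uncertain_input("y", 2, 0.5))
  bud <- kragten(function(v) 42, ins)
  expect_equal(bud$u, 0)
  expect_true(all(bud$indexes == 0))
})

test_that("kragten matches first-order propagation for a product", {
  ins <- rbind(uncertain_input("x", 10, 0.5), uncertain_input("y", 2, 0.1))
  bud <- kragten(function(v) v$x * v$y, ins)
  expect_lt(abs(bud$u_rel - sqrt(2) * 0.05), 0.003)
})

test_that("kragten is exact for affine functions, both shift variants", {
  ins <- rbind(uncertain_input("x", 3, 0.2), uncertain_input("y", -1, 0.3),
               uncertain_input("z", 10, 1.5))
  f <- function(v) 2 * v$x - 3 * v$y + 0.5 * v$z + 7
  expected <- sqrt((2 * 0.2)^2 + (3 * 0.3)^2 + (0.5 * 1.5)^2)
  expect_equal(kragten(f, ins)$u, expected, tolerance = 1e-12)
  expect_equal(kragten(f, ins, symmetric = TRUE)$u, expected,
               tolerance = 1e-12)
})

test_that("budget indexes survive relabelling and zero-uncertainty padding", {
  ins <- rbind(uncertain_input("a", 4, 0.4), uncertain_input("b", 2, 0.1))
  f_ab <- function(v) v$a * v$b
  bud <- kragten(f_ab, ins)
  ins2 <- ins; ins2$name <- c("alpha", "beta")
  bud2 <- kragten(function(v) v$alpha * v$beta, ins2)
  expect_equal(unname(bud2$indexes), unname(bud$indexes))
  ins3 <- rbind(ins, uncertain_input("pad", 100, 0))
  bud3 <- kragten(function(v) v$a * v$b + 0 * v$pad, ins3)
  expect_equal(bud3$u, bud$u)
  expect_equal(unname(bud3$indexes[c("a", "b")]), unname(bud$indexes))
  expect_equal(unname(bud3$indexes["pad"]), 0)
})

test_that("kragten rejects non-finite evaluations naming the input", {
  # finite at the estimate, undefined at the +u shift
  ins <- rbind(uncertain_input("x", 1, 2), uncertain_input("y", 1, 0.1))
  expect_error(                    # log of a negative shift warns, then errs
    suppressWarnings(kragten(function(v) log(2.5 - v$x) + v$y, ins)), "'x'")
  expect_error(kragten(function(v) 1 / 0, ins), "finite")
})

test_that("monte carlo reproduces known distribution widths and is seeded", {
  ins <- rbind(uncertain_input("x", 0, 1 / sqrt(3), "rectangular"))
  mc <- monte_carlo_u(function(v) v$x, ins, n_draws = 2e5, seed = 4)
  expect_lt(abs(mc$u - 1 / sqrt(3)), 0.005)   # half-width 1 -> u = 1/sqrt(3)
  mc2 <- monte_carlo_u(function(v) v$x, ins, n_draws = 2e5, seed = 4)
  expect_identical(mc$u, mc2$u)               # bit-identical repeat
  bad <- data.frame(name = "x", value = 1, u = 1, dist = "cauchy")
  expect_error(monte_carlo_u(function(v) v$x, bad), "cauchy")
})

test_that("monte carlo agrees with kragten for a linear chain", {
  ins <- rbind(uncertain_input("x", 10, 0.3), uncertain_input("y", 5, 0.4))
  f <- function(v) 2 * v$x + v$y
  kr <- kragten(f, ins)
  mc <- monte_carlo_u(f, ins, n_draws = 1e5, seed = 2)
  # 3 standard errors of an sd estimate at n = 1e5 is ~0.7 %
  expect_lt(abs(mc$u / kr$u - 1), 0.01)
})

test_that("symmetric kragten tracks the Monte Carlo sd on the full chain", {
  bud <- default_peptide_budget("FFVAPFPEVFGK")
  kr_sym <- kragten(tcmpquant:::.tcmp_chain, bud$inputs, symmetric = TRUE)
  mc <- monte_carlo_u(tcmpquant:::.tcmp_chain, bud$inputs, n_draws = 1e5,
                      seed = 10)
  expect_lt(abs(kr_sym$u / mc$u - 1), 0.05)
})

test_that("a budget with only CF uncertain attributes everything to CF", {
  p <- fix_model$proteins$CASA1
  bud <- budget_for_peptide(measurement(3e-12, 0, "mol/g"), fix_grav,
                            measurement(p$molar_mass$value, 0, "g/mol"),
                            p$cf, unity_factors(0, 0, 0), u_mass_g = 0)
  expect_equal(unname(bud$index_groups["CF"]), 100)
  expect_equal(sum(bud$index_groups), 100)
})

test_that("the default milk budget puts CF on top with u_rel in the 10-16 % band", {
  for (pep in fix_peptides) {
    bud <- default_peptide_budget(pep)
    expect_gte(100 * bud$u_rel, 10)
    expect_lte(100 * bud$u_rel, 16)
    expect_identical(names(which.max(bud$index_groups)), "CF")
    expect_true(abs(sum(bud$index_groups) - 100) < 0.5)
  }
})

test_that("between-peptide scatter enters the protein budget as an input", {
  p <- fix_model$proteins$LACB
  b <- measurement(3e-12, 1.5e-13, "mol/g")
  b0 <- budget_for_protein(b, fix_grav, p$molar_mass, p$cf,
                           scatter_rel = 0)
  b1 <- budget_for_protein(b, fix_grav, p$molar_mass, p$cf,
                           scatter_rel = 0.10)
  expect_gt(b1$u, b0$u)
  expect_true("digestion_scatter" %in% names(b1$index_groups))
  expect_gt(b1$value_w, 0)
  expect_gt(b1$value_w_u, 0)
  expect_lt(b1$value_w_u / b1$value_w, b1$u / b1$value) # CF adds on top
})
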