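# protein mass fractions, TCMP conversion and the four aggregation approaches

test_that("gravimetric records validate their masses", {
  expect_error(gravimetric_record(0, 15, 0.25), "positive")
  expect_error(gravimetric_record(1, 0.2, 2), "aliquot")
})

test_that("the mass-fraction chain is linear in molality and 1/m_X", {
  g <- gravimetric_record()
  M <- fix_model$proteins$CASA1$molar_mass
  w1 <- protein_mass_fraction(1e-12, g, M)
  expect_equal(protein_mass_fraction(2e-12, g, M), 2 * w1)
  g2 <- gravimetric_record(m_x = 0.5)
  expect_equal(protein_mass_fraction(1e-12, g2, M), 2 * w1)
  expect_error(protein_mass_fraction(1e-12, g, 0), "positive")
})

test_that("TCMP conversion divides by the conversion factor", {
  expect_equal(tcmp_from_protein(3.66, 0.366)$value, 10)
  expect_equal(tcmp_from_protein(7.3, 1)$value, 7.3)
  expect_error(tcmp_from_protein(1, 0), "positive")
  # direction-of-conversion consistency: a per-peptide TCMP of 6.81 at
  # CF 0.366 corresponds to a CASA1 mass fraction of 2.49 mg/kg
  w <- 6.81 * fix_model$proteins$CASA1$cf$value
  expect_equal(round(w, 2), 2.49)
  expect_equal(tcmp_from_protein(w, fix_model$proteins$CASA1$cf)$value, 6.81)
})

test_that("equimolarity diagnostics flag scattered peptide molalities", {
  eq0 <- equimolarity_check(c(2e-12, 2e-12, 2e-12))
  expect_equal(eq0$rsd_pct, 0)
  expect_false(eq0$flag)
  eq <- equimolarity_check(c(1.0e-12, 0.5e-12))
  expect_equal(eq$rsd_pct, 100 * sd(c(1, 0.5)) / 0.75, tolerance = 1e-12)
  expect_true(eq$flag)                         # ~47 % > 20 %
  single <- equimolarity_check(1e-12)
  expect_true(is.na(single$rsd_pct))
  expect_true(is.na(single$flag))
})

test_that("all four approaches agree on internally consistent inputs", {
  x <- 9.3
  prots <- names(fix_model$proteins)
  pp <- data.frame(peptide = fix_peptides,
                   protein = unlist(fix_prot_of[fix_peptides]),
                   tcmp = x, u_tcmp = 0.1)
  prot <- data.frame(protein = prots,
                     w = x * vapply(fix_model$proteins, function(p)
                       p$cf$value, numeric(1)),
                     u_w = 0.05, tcmp = x, u_tcmp = 0.1)
  f_all <- fix_model$cf_all$value
  for (a in c("A1", "A2", "A3", "A4")) {
    res <- aggregate_tcmp(pp, prot, fix_model, a, f_measured = f_all)
    expect_equal(res$w_tcmp, x, tolerance = 1e-12, info = a)
    expect_equal(res$U, 2 * res$u)
  }
})

test_that("A2 equals A1 when every protein has exactly one peptide", {
  pp <- data.frame(peptide = c("P1", "P2"), protein = c("CASA1", "CASB"),
                   tcmp = c(8, 12), u_tcmp = c(0.4, 0.6))
  prot <- data.frame(protein = c("CASA1", "CASB"), w = c(1, 2),
                     u_w = c(0.1, 0.1), tcmp = c(8, 12), u_tcmp = c(0.4, 0.6))
  a1 <- aggregate_tcmp(pp, prot, fix_model, "A1")
  a2 <- aggregate_tcmp(pp, prot, fix_model, "A2")
  expect_identical(a1$w_tcmp, a2$w_tcmp)
  expect_identical(a1$u, a2$u)
})

test_that("aggregation is invariant to row order", {
  tab <- reference_aggregate_tables()
  perm <- sample(nrow(tab$per_peptide))
  a1a <- aggregate_tcmp(tab$per_peptide, tab$per_protein, fix_model, "A1")
  a1b <- aggregate_tcmp(tab$per_peptide[perm, ], tab$per_protein, fix_model,
                        "A1")
  expect_equal(a1a$w_tcmp, a1b$w_tcmp)
  permp <- sample(nrow(tab$per_protein))
  for (a in c("A2", "A3", "A4")) {
    ra <- aggregate_tcmp(tab$per_peptide, tab$per_protein, fix_model, a)
    rb <- aggregate_tcmp(tab$per_peptide, tab$per_protein[permp, ],
                         fix_model, a)
    expect_equal(ra$w_tcmp, rb$w_tcmp, info = a)
  }
})

test_that("raising one peptide molality never lowers any approach", {
  tab <- reference_aggregate_tables()
  base <- vapply(c("A1", "A2", "A3", "A4"), function(a)
    aggregate_tcmp(tab$per_peptide, tab$per_protein, fix_model, a)$w_tcmp,
    numeric(1))
  # bump one CASB peptide: recompute both tables consistently
  pp <- tab$per_peptide
  pp$tcmp[pp$peptide == "VLP"] <- pp$tcmp[pp$peptide == "VLP"] + 1
  prot <- do.call(rbind, lapply(split(pp, pp$protein), function(d) {
    cf <- fix_model$proteins[[d$protein[1]]]$cf$value
    data.frame(protein = d$protein[1], w = mean(d$tcmp) * cf,
               u_w = 0.1, tcmp = mean(d$tcmp),
               u_tcmp = sqrt(sum(d$u_tcmp^2)) / nrow(d))
  }))
  bumped <- vapply(c("A1", "A2", "A3", "A4"), function(a)
    aggregate_tcmp(pp, prot, fix_model, a)$w_tcmp, numeric(1))
  expect_true(all(bumped >= base))
})

test_that("A3 and A4 reject incomplete protein sets", {
  tab <- reference_aggregate_tables()
  no_cask <- tab$per_protein[tab$per_protein$protein != "CASK", ]
  expect_error(aggregate_tcmp(tab$per_peptide, no_cask, fix_model, "A3"),
               "CASK")
  no_lacb <- tab$per_protein[tab$per_protein$protein != "LACB", ]
  expect_error(aggregate_tcmp(tab$per_peptide, no_lacb, fix_model, "A4"),
               "LACB")
})

test_that("the A4 arithmetic reproduces the published example", {
  # five-protein sum of 8.45 mg/kg (U = 0.53 at k = 2), measured fraction
  # 0.96: TCMP = 8.80 mg/kg with U = 0.67
  prot <- data.frame(protein = names(fix_model$proteins), w = 8.45 / 5,
                     u_w = (0.53 / 2) / sqrt(5), tcmp = 0, u_tcmp = 0)
  pp <- data.frame(peptide = "x", protein = "CASA1", tcmp = 0, u_tcmp = 0)
  res <- aggregate_tcmp(pp, prot, fix_model, "A4", f_measured = 0.96)
  expect_equal(round(res$w_tcmp, 2), 8.80)
  expect_lt(abs(res$U - 0.67), 0.01)
})
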