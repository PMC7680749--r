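## Peptide molality -> marker-protein mass fraction -> total cow's milk
## protein (TCMP), with the four aggregation approaches A1-A4.

#' Gravimetric record of one sample preparation
#'
#' @param m_x mass of the test portion, g.
#' @param m_exsolv mass of extraction solvent added, g.
#' @param m_extr mass of the extract aliquot taken for digestion, g.
#' @return Object of class `gravimetric_record`. Defaults are the standard
#'   design: 1 g test portion, 15 g extraction buffer, 0.25 g aliquot.
#' @export
gravimetric_record <- function(m_x = 1, m_exsolv = 15, m_extr = 0.25) {
  if (any(c(m_x, m_exsolv, m_extr) <= 0))
    stop("all gravimetric masses must be positive")
  if (m_extr > m_exsolv + m_x)
    stop("extract aliquot cannot exceed the total extract mass")
  structure(list(m_x = m_x, m_exsolv = m_exsolv, m_extr = m_extr),
            class = "gravimetric_record")
}

#' Unity factors carrying method-efficiency uncertainties
#'
#' Extraction, digestion and standard-purity corrections are applied as
#' factors of exactly 1 whose only role is to carry a relative standard
#' uncertainty into the budget. Default magnitudes (5 % extraction, 1 %
#' digestion, 1.5 % purity) are package choices consistent with the overall
#' budget shape of a well-controlled SRM assay; see the methods vignette.
#'
#' @param u_ext,u_dig,u_purity relative standard uncertainties (k = 1).
#' @return list of three [measurement()]s named `f_ext`, `f_dig`, `f_purity`.
#' @export
unity_factors <- function(u_ext = 0.05, u_dig = 0.01, u_purity = 0.015) {
  stopifnot(u_ext >= 0, u_dig >= 0, u_purity >= 0)
  list(f_ext = measurement(1, u_ext, "", "normal"),
       f_dig = measurement(1, u_dig, "", "normal"),
       f_purity = measurement(1, u_purity, "", "rectangular"))
}

#' Marker-protein mass fraction from peptide molality
#'
#' `w_j = b(pep) * m_Exsolv / (m_X * m_Extr) * M_j * f_ext * f_dig *
#' f_purity`, evaluated literally with the gravimetric chain of the standard
#' design, and converted to mg protein per kg food. Returns the value only;
#' uncertainty propagation over this chain is done by the Kragten budget
#' functions, which re-evaluate it at shifted inputs.
#'
#' @param b peptide molality in the processed extract, mol/g (a number or a
#'   [measurement()]).
#' @param grav a [gravimetric_record()].
#' @param molar_mass protein molar mass, g/mol (number or [measurement()]).
#' @param factors a [unity_factors()] list.
#' @return mass fraction in mg protein / kg food.
#' @export
protein_mass_fraction <- function(b, grav = gravimetric_record(),
                                  molar_mass, factors = unity_factors()) {
  stopifnot(inherits(grav, "gravimetric_record"))
  bv <- if (is.measurement(b)) b$value else b
  mv <- if (is.measurement(molar_mass)) molar_mass$value else molar_mass
  if (mv <= 0) stop("molar mass must be positive")
  bv * grav$m_exsolv / (grav$m_x * grav$m_extr) * mv *
    factors$f_ext$value * factors$f_dig$value * factors$f_purity$value * 1e6
}

#' Convert a marker-protein mass fraction to TCMP
#'
#' The conversion factor CF is the protein's mass share of total milk
#' protein, so the total is obtained by *dividing* the protein mass fraction
#' by its CF: `w_TCMP = w_j / CF_j`. Uncertainty combines the two relative
#' uncertainties in quadrature.
#'
#' @param w protein mass fraction, mg/kg ([measurement()] or number).
#' @param cf conversion factor in (0, 1) ([measurement()] or number).
#' @return A [measurement()] in mg TCMP / kg.
#' @examples
#' tcmp_from_protein(3.66, 0.366) # 10 mg/kg
#' @export
tcmp_from_protein <- function(w, cf) {
  wm <- if (is.measurement(w)) w else measurement(w, 0, "mg/kg")
  cfm <- if (is.measurement(cf)) cf else measurement(cf, 0)
  if (cfm$value <= 0) stop("conversion factor must be positive")
  value <- wm$value / cfm$value
  urel2 <- (if (wm$value != 0) rel_u(wm)^2 else 0) + rel_u(cfm)^2
  measurement(value, abs(value) * sqrt(urel2), "mg/kg", "derived")
}

#' Equimolarity check across the peptides of one protein
#'
#' Every signature peptide is present at 1 mol per mol of parent protein, so
#' complete digestion implies equimolar peptide release. The relative
#' standard deviation of the member molalities is compared with a threshold
#' (default 20 %; well-digested caseins typically show 13-19 % while an
#' incompletely digested protein shows 35 % and more).
#'
#' @param molalities numeric vector of peptide molalities, mol/g.
#' @param threshold RSD flag threshold as a fraction (default 0.20).
#' @return list with `rsd_pct`, `sem` (mol/g), `n`, and `flag` (TRUE /
#'   FALSE / NA when fewer than two peptides make the check not applicable).
#' @export
equimolarity_check <- function(molalities, threshold = 0.20) {
  n <- length(molalities)
  if (n < 2L)
    return(list(rsd_pct = NA_real_, sem = NA_real_, n = n, flag = NA))
  m <- mean(molalities)
  s <- stats::sd(molalities)
  rsd <- if (m != 0) 100 * s / abs(m) else Inf
  list(rsd_pct = rsd, sem = s / sqrt(n), n = n,
       flag = rsd > 100 * threshold)
}

#' Aggregate peptide / protein results into a TCMP estimate
#'
#' The four approaches differ in where the conversion to total milk protein
#' happens:
#' * **A1** — every peptide is an independent marker: the mean of the
#'   per-peptide TCMP values.
#' * **A2** — every protein is an independent marker: the mean of the five
#'   per-protein TCMP values.
#' * **A3** — the summed mass fractions of the four caseins, divided by the
#'   combined casein conversion factor.
#' * **A4** — the summed mass fractions of all five proteins plus the
#'   unmeasured residual share: `sum / f`, where `f` is the measured protein
#'   fraction of total milk protein (default 0.96). The residual carries a
#'   rectangular uncertainty with the residual share as half-range; no
#'   conversion factor enters.
#'
#' Per-item uncertainties are treated as independent across items for the
#' A1/A2 means (unweighted arithmetic means).
#'
#' @param per_peptide data.frame with columns `peptide, protein, tcmp,
#'   u_tcmp` (k = 1).
#' @param per_protein data.frame with columns `protein, w, u_w, tcmp,
#'   u_tcmp` (w in mg/kg, k = 1).
#' @param model a [milk_model()] (for the combined conversion factors and
#'   the casein membership).
#' @param approach `"A1"`, `"A2"`, `"A3"` or `"A4"`.
#' @param f_measured measured fraction of total milk protein for A4
#'   (default 0.96).
#' @param k coverage factor for the expanded uncertainty (default 2).
#' @return Object of class `tcmp_result`: `approach`, `w_tcmp` (mg/kg), `u`
#'   (k = 1), `U` (`k * u`), `k`, `n` (items aggregated).
#' @export
aggregate_tcmp <- function(per_peptide, per_protein, model,
                           approach = c("A1", "A2", "A3", "A4"),
                           f_measured = 0.96, k = 2) {
  approach <- match.arg(approach)
  stopifnot(inherits(model, "milk_model"))
  result <- function(value, u, n)
    structure(list(approach = approach, w_tcmp = value, u = u, U = k * u,
                   k = k, n = n), class = "tcmp_result")

  if (approach == "A1") {
    n <- nrow(per_peptide)
    if (n < 1L) stop("A1 requires at least one peptide result")
    return(result(mean(per_peptide$tcmp),
                  sqrt(sum(per_peptide$u_tcmp^2)) / n, n))
  }
  if (approach == "A2") {
    n <- nrow(per_protein)
    if (n < 1L) stop("A2 requires at least one protein result")
    return(result(mean(per_protein$tcmp),
                  sqrt(sum(per_protein$u_tcmp^2)) / n, n))
  }
  caseins <- names(model$proteins)[vapply(model$proteins, `[[`, logical(1),
                                          "is_casein")]
  if (approach == "A3") {
    missing_cas <- setdiff(caseins, per_protein$protein)
    if (length(missing_cas))
      stop("A3 requires all casein proteins; missing: ",
           paste(missing_cas, collapse = ", "))
    d <- per_protein[per_protein$protein %in% caseins, ]
    w_sum <- measurement(sum(d$w), sqrt(sum(d$u_w^2)), "mg/kg", "derived")
    res <- tcmp_from_protein(w_sum, model$cf_caseins)
    return(result(res$value, res$u, nrow(d)))
  }
  # A4
  missing_all <- setdiff(names(model$proteins), per_protein$protein)
  if (length(missing_all))
    stop("A4 requires all marker proteins; missing: ",
         paste(missing_all, collapse = ", "))
  if (f_measured <= 0 || f_measured > 1)
    stop("measured fraction must lie in (0, 1]")
  w_sum <- sum(per_protein$w)
  u_sum <- sqrt(sum(per_protein$u_w^2))
  residual <- w_sum * (1 - f_measured) / f_measured
  u_res <- residual / sqrt(3)                 # rectangular half-range
  result(w_sum + residual, sqrt(u_sum^2 + u_res^2), nrow(per_protein))
}

#' @export
print.tcmp_result <- function(x, ...) {
  cat(sprintf("TCMP (%s) = %.3g +/- %.2g (k = %g) mg/kg  [n = %d]\n",
              x$approach, x$w_tcmp, x$U, x$k, x$n))
  invisible(x)
}

#' Quantify samples from peak areas and calibration fits
#'
#' The full measurement chain for unknown samples: replicate natural:SIL
#' ratios are averaged per peptide (standard error of the mean as the ratio
#' uncertainty), inverted through the peptide's calibration fit to a
#' molality, converted to the marker-protein mass fraction via the
#' gravimetric chain and molar mass, and aggregated to TCMP by all four
#' approaches. Per-peptide and per-protein Kragten budgets are evaluated on
#' the way.
#'
#' @param sample_areas data.frame `sample_id, peptide, replicate,
#'   area_natural, area_sil` (a `transition_rank` column, if present, is
#'   filtered to the quantifier rank 1).
#' @param manifest data.frame `sample_id, m_X_g, m_Exsolv_g, m_Extr_g` and
#'   optionally `nominal_tcmp`.
#' @param fits named list of [irls_fit()] results (one per peptide), e.g.
#'   from [fit_calibration_curves()].
#' @param registry transition registry (peptide -> protein map).
#' @param model a [milk_model()].
#' @param factors a [unity_factors()] list.
#' @param u_mass_g standard uncertainty of one weighing, g (default 5e-4).
#' @param f_measured,k A4 measured fraction and coverage factor.
#' @param equimolarity_threshold RSD flag threshold (fraction).
#' @return Object of class `tcmp_report`: list of per-sample results, each
#'   with `per_peptide` (molality, TCMP and budget per peptide),
#'   `per_protein` (mass fraction, between-peptide SEM, equimolarity flag,
#'   TCMP), `approaches` (data.frame A1-A4 with expanded uncertainties) and
#'   `budgets` (per-peptide uncertainty budget table).
#' @export
quantify_samples <- function(sample_areas, manifest, fits,
                             registry = milk_registry(),
                             model = milk_model(),
                             factors = unity_factors(),
                             u_mass_g = 5e-4, f_measured = 0.96, k = 2,
                             equimolarity_threshold = 0.20) {
  if ("transition_rank" %in% names(sample_areas))
    sample_areas <- sample_areas[sample_areas$transition_rank == 1L, ]
  needed <- c("sample_id", "peptide", "replicate", "area_natural", "area_sil")
  miss <- setdiff(needed, names(sample_areas))
  if (length(miss))
    stop("sample area table misses column(s): ", paste(miss, collapse = ", "))
  prot_of <- protein_of_peptide(registry)

  samples <- lapply(split(manifest, manifest$sample_id), function(man) {
    grav <- gravimetric_record(man$m_X_g, man$m_Exsolv_g, man$m_Extr_g)
    areas <- sample_areas[sample_areas$sample_id == man$sample_id, ]
    if (!nrow(areas)) return(NULL)

    pp <- do.call(rbind, lapply(split(areas, areas$peptide), function(d) {
      pep <- d$peptide[1]
      if (is.null(fits[[pep]]))
        stop("no calibration fit for peptide ", pep)
      r <- d$area_natural / d$area_sil
      u_r <- if (length(r) > 1L) stats::sd(r) / sqrt(length(r)) else 0
      b <- invert_calibration(mean(r), fits[[pep]], u_r)
      data.frame(sample_id = man$sample_id, peptide = pep,
                 protein = prot_of[[pep]], ratio = mean(r), u_ratio = u_r,
                 b = b$value, u_b = b$u,
                 below_blank = attr(b, "below_blank"),
                 stringsAsFactors = FALSE)
    }))
    rownames(pp) <- NULL

    # per-peptide mass fraction, TCMP and Kragten budget
    budgets <- vector("list", nrow(pp))
    pp$w <- pp$tcmp <- pp$u_tcmp <- NA_real_
    for (i in seq_len(nrow(pp))) {
      prot <- model$proteins[[pp$protein[i]]]
      if (is.null(prot)) stop("protein ", pp$protein[i], " not in milk model")
      bud <- budget_for_peptide(
        b = measurement(pp$b[i], pp$u_b[i], "mol/g"),
        grav = grav, molar_mass = prot$molar_mass, cf = prot$cf,
        factors = factors, u_mass_g = u_mass_g, k = k)
      pp$w[i] <- protein_mass_fraction(pp$b[i], grav, prot$molar_mass,
                                       factors)
      pp$tcmp[i] <- bud$value
      pp$u_tcmp[i] <- bud$u
      budgets[[i]] <- bud
    }
    names(budgets) <- pp$peptide

    prot_tab <- do.call(rbind, lapply(split(pp, pp$protein), function(d) {
      prot <- model$proteins[[d$protein[1]]]
      eq <- equimolarity_check(d$b, equimolarity_threshold)
      b_mean <- measurement(mean(d$b), sqrt(sum(d$u_b^2)) / nrow(d), "mol/g")
      sem_rel <- if (nrow(d) > 1L && b_mean$value != 0)
        (stats::sd(d$b) / sqrt(nrow(d))) / abs(b_mean$value) else 0
      bud <- budget_for_protein(b_mean, grav, prot$molar_mass, prot$cf,
                                factors, scatter_rel = sem_rel,
                                u_mass_g = u_mass_g, k = k)
      data.frame(sample_id = man$sample_id, protein = d$protein[1],
                 n_peptides = nrow(d), w = mean(d$w),
                 u_w = bud$value_w_u,
                 between_peptide_sem = sem_rel * mean(d$w),
                 equimolarity_rsd_pct = eq$rsd_pct,
                 equimolarity_flag = eq$flag,
                 tcmp = bud$value, u_tcmp = bud$u,
                 stringsAsFactors = FALSE)
    }))
    rownames(prot_tab) <- NULL

    app <- do.call(rbind, lapply(c("A1", "A2", "A3", "A4"), function(a) {
      res <- tryCatch(
        aggregate_tcmp(pp, prot_tab, model, a, f_measured, k),
        error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(sample_id = man$sample_id, approach = a,
                 w_tcmp = res$w_tcmp, u = res$u, U = res$U, k = res$k,
                 n = res$n, stringsAsFactors = FALSE)
    }))

    list(sample_id = man$sample_id,
         nominal_tcmp = if (!is.null(man$nominal_tcmp)) man$nominal_tcmp
                        else NA_real_,
         per_peptide = pp, per_protein = prot_tab, approaches = app,
         budgets = budgets)
  })
  structure(list(samples = Filter(Negate(is.null), samples),
                 f_measured = f_measured, k = k),
            class = "tcmp_report")
}

#' @export
print.tcmp_report <- function(x, ...) {
  for (s in x$samples) {
    cat("sample", s$sample_id,
        if (!is.na(s$nominal_tcmp))
          sprintf("(nominal %.3g mg/kg)", s$nominal_tcmp) else "", "\n")
    a <- s$approaches
    for (i in seq_len(nrow(a)))
      cat(sprintf("  %s: %6.3f +/- %.3f (k = %g) mg TCMP/kg\n",
                  a$approach[i], a$w_tcmp[i], a$U[i], a$k[i]))
    fl <- s$per_protein$protein[s$per_protein$equimolarity_flag %in% TRUE]
    if (length(fl))
      cat("  equimolarity flag:", paste(fl, collapse = ", "), "\n")
  }
  invisible(x)
}
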