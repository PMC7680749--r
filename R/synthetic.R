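## Forward-model generator of SRM peak-area tables with the statistical
## structure the quantification method assumes: milk-composition truth,
## linear ratio response, per-peptide digestion/extraction efficiencies,
## multiplicative area noise, additive baseline noise and channel crosstalk.

#' Define the ground truth of a simulated incurred-cookie experiment
#'
#' The generator emulates an incurred baked-matrix experiment: a true total
#' milk protein mass fraction maps through the conversion factors, the
#' gravimetric chain and the protein molar masses to per-peptide molalities
#' (the exact inverse of the quantification equation, so the pipeline closes
#' to identity at zero noise); molalities map to natural:SIL area ratios via
#' an ideal IDMS response with the internal standard blended at the
#' `sil_level`; peak areas get multiplicative log-normal noise (CV) plus an
#' additive baseline.
#'
#' @param tcmp true total milk protein mass fraction(s), mg/kg; one sample
#'   is generated per value (default 10.7, the mid incurred level).
#' @param cv multiplicative coefficient of variation of individual peak
#'   areas (default 0.05).
#' @param additive_sd additive baseline noise on areas, counts (default 50).
#' @param base_area_sil mean SIL peak area, counts (default 1e5).
#' @param digestion_efficiency named vector (by peptide sequence) of
#'   digestion release efficiencies in (0, 1]; unnamed peptides get 1.
#' @param extraction_efficiency named vector (by peptide) of extraction
#'   efficiencies in (0, 1]; default 1.
#' @param crosstalk fractional signal leakage between the natural and SIL
#'   channels (default 0).
#' @param n_injection injection replicates per digest (default 3).
#' @param n_digest independent digests per sample (default 2).
#' @param n_cal_rep instrumental replicates per calibration level
#'   (default 5).
#' @param design calibration design, see [calibration_design()].
#' @param sil_level internal-standard blend level, mg/kg equivalent
#'   (default 11.25: half the calibration span, giving ratio 1 there).
#' @param n_blank blank replicates for LOQ work (default 6).
#' @param seed RNG seed; a fixed seed makes [simulate_experiment()]
#'   bit-reproducible.
#' @return list of class `simulation_truth`.
#' @export
simulation_truth <- function(tcmp = 10.7, cv = 0.05, additive_sd = 50,
                             base_area_sil = 1e5,
                             digestion_efficiency = NULL,
                             extraction_efficiency = NULL,
                             crosstalk = 0, n_injection = 3L, n_digest = 2L,
                             n_cal_rep = 5L, design = calibration_design(),
                             sil_level = 11.25, n_blank = 6L, seed = 1L) {
  stopifnot(all(tcmp >= 0), cv >= 0, additive_sd >= 0, crosstalk >= 0,
            crosstalk < 1, sil_level > 0)
  if (!is.null(digestion_efficiency))
    stopifnot(all(digestion_efficiency > 0), all(digestion_efficiency <= 1))
  if (!is.null(extraction_efficiency))
    stopifnot(all(extraction_efficiency > 0), all(extraction_efficiency <= 1))
  structure(list(tcmp = tcmp, cv = cv, additive_sd = additive_sd,
                 base_area_sil = base_area_sil,
                 digestion_efficiency = digestion_efficiency,
                 extraction_efficiency = extraction_efficiency,
                 crosstalk = crosstalk, n_injection = as.integer(n_injection),
                 n_digest = as.integer(n_digest),
                 n_cal_rep = as.integer(n_cal_rep), design = design,
                 sil_level = sil_level, n_blank = as.integer(n_blank),
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

.eff_of <- function(eff, peptide) {
  if (is.null(eff)) return(1)
  if (is.null(names(eff))) return(unname(eff[1]))
  if (peptide %in% names(eff)) unname(eff[[peptide]]) else 1
}

#' Simulate an SRM peak-area experiment
#'
#' Generates, under one seeded RNG stream, the calibration-area table
#' (levels 0-7, quantifier and qualifier transitions), the unknown-sample
#' area table (digests x injections), the sample manifest, blank-ratio
#' replicates for LOQ work and the three QC runs (blank, natural-spiked,
#' SIL-spiked) used by the selectivity check. All tables use the same CSV
#' dialects the quantification readers consume, so simulate -> quantify is a
#' closed loop.
#'
#' @param truth a [simulation_truth()].
#' @param model a [milk_model()].
#' @param registry transition registry.
#' @param grav a [gravimetric_record()] shared by all simulated samples.
#' @return list with `calibration`, `design`, `samples`, `manifest`,
#'   `blank_ratios`, `qc` (list `blank`, `nat_qc`, `sil_qc`) and the `truth`
#'   echoed back.
#' @export
simulate_experiment <- function(truth = simulation_truth(),
                                model = milk_model(),
                                registry = milk_registry(),
                                grav = gravimetric_record()) {
  stopifnot(inherits(truth, "simulation_truth"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(truth$seed)

  prot_of <- protein_of_peptide(registry)
  peptides <- names(prot_of)
  unit_b <- blend_design(model, 1, grav)      # mol/g per mg/kg TCMP
  b_sil <- vapply(peptides, function(p) truth$sil_level * unit_b[[prot_of[[p]]]],
                  numeric(1))
  sdlog <- sqrt(log(1 + truth$cv^2))
  noisy <- function(mu) {
    a <- mu * stats::rlnorm(length(mu), -sdlog^2 / 2, sdlog) +
      stats::rnorm(length(mu), 0, truth$additive_sd)
    pmax(a, 1)
  }
  area_pair <- function(b_nat, peptide) {
    # true channel intensities, including crosstalk leakage (vectorised)
    a_nat_t <- truth$base_area_sil * b_nat / unname(b_sil[peptide])
    a_sil_t <- truth$base_area_sil
    nat <- a_nat_t + truth$crosstalk * a_sil_t
    sil <- a_sil_t + truth$crosstalk * a_nat_t
    list(nat = nat, sil = sil)
  }

  # calibration: synthetic peptide blends, unit efficiencies
  prot_vec <- unlist(prot_of[peptides])
  cal <- expand.grid(replicate = seq_len(truth$n_cal_rep),
                     transition_rank = 1:2, peptide = peptides,
                     level_id = truth$design$level_id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nominal <- truth$design$nominal_tcmp[match(cal$level_id,
                                             truth$design$level_id)]
  b_nat <- nominal * unname(unit_b[prot_vec[cal$peptide]])
  tr <- area_pair(b_nat, cal$peptide)
  rel <- ifelse(cal$transition_rank == 1L, 1, 0.5)  # qualifier at 50 %
  cal$area_natural <- noisy(tr$nat * rel)
  cal$area_sil <- noisy(tr$sil * rel)
  cal <- cal[, c("level_id", "peptide", "transition_rank", "replicate",
                 "area_natural", "area_sil")]

  # unknown samples: incurred protein, efficiencies apply
  sample_ids <- sprintf("S%d", seq_along(truth$tcmp))
  eff <- vapply(peptides, function(pep)
    .eff_of(truth$digestion_efficiency, pep) *
      .eff_of(truth$extraction_efficiency, pep), numeric(1))
  samples <- expand.grid(injection = seq_len(truth$n_injection),
                         digest = seq_len(truth$n_digest),
                         peptide = peptides, sample_id = sample_ids,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tcmp_s <- truth$tcmp[match(samples$sample_id, sample_ids)]
  b_nat_s <- tcmp_s * unname(unit_b[prot_vec[samples$peptide]]) *
    unname(eff[samples$peptide])
  tr_s <- area_pair(b_nat_s, samples$peptide)
  samples$transition_rank <- 1L
  samples$replicate <- paste0("d", samples$digest, "i", samples$injection)
  samples$area_natural <- noisy(tr_s$nat)
  samples$area_sil <- noisy(tr_s$sil)
  samples <- samples[, c("sample_id", "peptide", "transition_rank", "digest",
                         "replicate", "area_natural", "area_sil")]

  manifest <- data.frame(sample_id = sample_ids, m_X_g = grav$m_x,
                         m_Exsolv_g = grav$m_exsolv, m_Extr_g = grav$m_extr,
                         nominal_tcmp = truth$tcmp,
                         stringsAsFactors = FALSE)

  # blank replicates in ratio units (baseline noise over the SIL area)
  blank_ratios <- do.call(rbind, lapply(peptides, function(pep) {
    baseline <- pmax(stats::rnorm(truth$n_blank, 0, truth$additive_sd), 0)
    data.frame(peptide = pep, replicate = seq_len(truth$n_blank),
               ratio = baseline / truth$base_area_sil,
               stringsAsFactors = FALSE)
  }))

  qc_run <- function(which) {
    do.call(rbind, lapply(peptides, function(pep) {
      b_nat <- if (which == "nat") truth$sil_level * unit_b[[prot_of[[pep]]]]
               else 0
      sil_present <- which != "nat"
      a_nat_t <- truth$base_area_sil * b_nat / b_sil[[pep]]
      a_sil_t <- if (sil_present) truth$base_area_sil else 0
      if (which == "blank") { a_nat_t <- 0; a_sil_t <- 0 }
      nat <- a_nat_t + truth$crosstalk * a_sil_t
      sil <- a_sil_t + truth$crosstalk * a_nat_t
      data.frame(peptide = pep,
                 area_natural = max(nat * stats::rlnorm(1, -sdlog^2 / 2,
                                                        sdlog) +
                                      stats::rnorm(1, 0, truth$additive_sd),
                                    0),
                 area_sil = max(sil * stats::rlnorm(1, -sdlog^2 / 2, sdlog) +
                                  stats::rnorm(1, 0, truth$additive_sd), 0),
                 stringsAsFactors = FALSE)
    }))
  }

  list(calibration = cal, design = truth$design, samples = samples,
       manifest = manifest, blank_ratios = blank_ratios,
       qc = list(blank = qc_run("blank"), nat_qc = qc_run("nat"),
                 sil_qc = qc_run("sil")),
       truth = truth)
}

#' Run the full quantification pipeline on a simulated experiment
#'
#' Convenience wrapper: fits the calibration curves from the simulated
#' calibration table and quantifies the simulated samples, returning the
#' [quantify_samples()] report.
#'
#' @param sim result of [simulate_experiment()].
#' @param model,registry,grav as used for the simulation.
#' @param weighting calibration weighting scheme.
#' @param ... further arguments passed to [quantify_samples()].
#' @return a `tcmp_report`.
#' @export
quantify_experiment <- function(sim, model = milk_model(),
                                registry = milk_registry(),
                                grav = gravimetric_record(),
                                weighting = "bisquare", ...) {
  cc <- fit_calibration_curves(sim$calibration, sim$design, registry, model,
                               grav, weighting = weighting)
  quantify_samples(sim$samples, sim$manifest, cc$fits, registry, model, ...)
}

#' Write the bundled reference fixtures
#'
#' Copies the package's bundled plain-text fixtures — the milk transition
#' registry, the protein reference table and a default sample manifest —
#' into a directory, byte-identically on every call.
#'
#' @param dir output directory (created if missing).
#' @return invisibly, the written file paths.
#' @export
fixture_tables <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c("milk_transitions.tsv", "milk_reference.tsv",
             "default_manifest.csv")
  out <- vapply(files, function(f) {
    src <- system.file("extdata", f, package = "tcmpquant", mustWork = TRUE)
    dst <- file.path(dir, f)
    file.copy(src, dst, overwrite = TRUE)
    dst
  }, character(1))
  invisible(out)
}
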