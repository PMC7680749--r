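## Matrix-matched calibration: value assignment of peptide standards,
## ratio-vs-molality regression, and inversion to peptide molality.

#' Three-letter short code of a signature peptide
#'
#' The conventional short names of the milk signature peptides are the first
#' three residues of the sequence (FFVAPFPEVFGK -> FFV, ...), which are
#' unique within the eleven-peptide set.
#'
#' @param sequence peptide sequence(s).
#' @return character vector of codes.
#' @export
peptide_code <- function(sequence) toupper(substr(sequence, 1L, 3L))

#' Fit a calibration line by iteratively reweighted least squares
#'
#' Fits `ratio = beta0 + beta1 * molality` for one peptide. The default
#' weighting is robust IRLS with the Tukey bisquare psi (tuning constant
#' 4.685, scale from the normalised median absolute deviation of residuals,
#' at most 50 iterations, relative tolerance 1e-8). Ordinary least squares
#' (`"ols"`) and `1/x^2` variance weighting (`"inverse_x2"`, for the
#' proportional residual scatter seen at high molality) are available.
#' A noiseless point set (all OLS residuals numerically zero) degenerates
#' the robust scale estimate, so it short-circuits to the OLS fit.
#'
#' @param x molality of the natural peptide in the processed extract, mol/g
#'   (>= 3 distinct values required).
#' @param y measured natural:SIL peak-area ratio, same length.
#' @param weighting `"bisquare"` (default), `"ols"` or `"inverse_x2"`.
#' @param max_iter,tol IRLS iteration cap and relative coefficient tolerance.
#' @return Object of class `calibration_fit`: coefficients `beta0`, `beta1`,
#'   their standard uncertainties `u_beta0`, `u_beta1`, covariance
#'   `cov_beta`, `r_squared` (weighted), final `weights`, `residuals`,
#'   `n_points`, `converged`, and the `weighting` used.
#' @examples
#' f <- irls_fit(c(0, 1, 2), c(0.1, 2.1, 4.1))
#' c(f$beta0, f$beta1) # 0.1, 2.0
#' @export
irls_fit <- function(x, y, weighting = c("bisquare", "ols", "inverse_x2"),
                     max_iter = 50L, tol = 1e-8) {
  weighting <- match.arg(weighting)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 3L)
    stop("calibration requires at least 3 distinct molality values")

  ols <- stats::lm(y ~ x)
  noiseless <- max(abs(stats::residuals(ols))) <=
    1e-10 * max(abs(y), 1e-300)

  make_fit <- function(beta, vc, w, res, converged) {
    ybar_w <- sum(w * y) / sum(w)
    ss_tot <- sum(w * (y - ybar_w)^2)
    r2 <- if (ss_tot > 0) 1 - sum(w * res^2) / ss_tot else 1
    structure(list(beta0 = unname(beta[1]), beta1 = unname(beta[2]),
                   u_beta0 = sqrt(vc[1, 1]), u_beta1 = sqrt(vc[2, 2]),
                   cov_beta = vc[1, 2], r_squared = max(0, min(1, r2)),
                   weights = w, residuals = res, n_points = length(y),
                   converged = converged, weighting = weighting,
                   x = x, y = y),
              class = "calibration_fit")
  }

  if (weighting == "ols" || noiseless) {
    # a perfect fit triggers a harmless precision warning in summary.lm
    vc <- suppressWarnings(stats::vcov(ols))
    if (noiseless) vc[] <- 0
    return(make_fit(stats::coef(ols), vc, rep(1, length(y)),
                    stats::residuals(ols), TRUE))
  }
  if (weighting == "inverse_x2") {
    w <- 1 / pmax(x, min(x[x > 0]))^2
    fit <- stats::lm(y ~ x, weights = w)
    return(make_fit(stats::coef(fit), stats::vcov(fit), w,
                    stats::residuals(fit), TRUE))
  }
  X <- cbind("(Intercept)" = 1, x = x)
  fit <- tryCatch(
    suppressWarnings(                 # non-convergence is reported as a flag
      MASS::rlm(X, y, psi = MASS::psi.bisquare, c = 4.685,
                scale.est = "MAD", maxit = max_iter, acc = tol,
                intercept = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {              # degenerate robust scale: fall back
    vc <- suppressWarnings(stats::vcov(ols))
    return(make_fit(stats::coef(ols), vc, rep(1, length(y)),
                    stats::residuals(ols), FALSE))
  }
  sm <- summary(fit)
  vc <- sm$cov.unscaled * sm$stddev^2
  make_fit(stats::coef(fit), vc, fit$w, stats::residuals(fit),
           isTRUE(fit$converged))
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(paste0("calibration fit (%s): beta0 = %.5g +/- %.3g, ",
                     "beta1 = %.5g +/- %.3g (g/mol), R^2 = %.4f, n = %d%s\n"),
              x$weighting, x$beta0, x$u_beta0, x$beta1, x$u_beta1,
              x$r_squared, x$n_points,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Invert a calibration fit to peptide molality
#'
#' `b = (R - beta0) / beta1`, with the standard uncertainty propagated from
#' the ratio and the fitted coefficients (including their covariance). A
#' ratio below the fitted blank gives a negative molality which is returned
#' as-is and flagged `below_blank` — never clipped, so that aggregation over
#' peptides stays unbiased.
#'
#' @param ratio measured natural:SIL peak-area ratio.
#' @param fit a [irls_fit()] result.
#' @param u_ratio standard uncertainty of the ratio (e.g. the standard error
#'   of the replicate mean); default 0.
#' @return A [measurement()] in mol/g with attribute `below_blank` (logical).
#' @export
invert_calibration <- function(ratio, fit, u_ratio = 0) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$beta1 <= 0) stop("calibration slope must be positive to invert")
  b <- (ratio - fit$beta0) / fit$beta1
  var_b <- (u_ratio^2 + fit$u_beta0^2 + b^2 * fit$u_beta1^2 +
              2 * b * fit$cov_beta) / fit$beta1^2
  out <- measurement(b, sqrt(max(var_b, 0)), "mol/g", "derived")
  attr(out, "below_blank") <- b < 0
  out
}

#' Purity assignment by proxy
#'
#' When a peptide standard cannot be value-assigned directly (no quantifiable
#' amino acids for AAA), its purity is estimated as the average of the
#' purities of the other peptides synthesised in parallel, with a
#' rectangular uncertainty whose width equals the range of those purities.
#'
#' @param other_purities numeric vector of mass-fraction purities (at least
#'   two values in (0, 1]).
#' @return A [measurement()] with `dist = "rectangular"`.
#' @examples
#' assign_purity_by_proxy(c(0.50, 0.60, 0.70)) # 0.60 +/- 0.0577
#' @export
assign_purity_by_proxy <- function(other_purities) {
  if (!is.numeric(other_purities) || length(other_purities) < 2L)
    stop("purity proxy needs at least two reference purities")
  measurement(mean(other_purities),
              (max(other_purities) - min(other_purities)) / (2 * sqrt(3)),
              "", "rectangular")
}

#' Reverse-IDMS value assignment of a SIL solution
#'
#' The concentration of a stable-isotope-labelled peptide solution is
#' assigned by spiking it with known amounts of the value-assigned natural
#' analogue: each spike yields `natural molality / observed natural:SIL
#' ratio`, scaled by the gravimetric dilution factor; the assigned value is
#' the mean over spikes with the standard error of the mean as uncertainty.
#'
#' @param natural_molality known molality of the natural spike, mol/g (one
#'   value per spike).
#' @param ratio observed natural:SIL area ratio per spike (> 0).
#' @param dilution_factor gravimetric dilution factor of the SIL solution
#'   between the spiked blend and the stock being assigned (default 1).
#' @return A [measurement()] in mol/g (`u = 0` when only one spike is
#'   provided: the SEM is not estimable).
#' @export
reverse_idms_assign <- function(natural_molality, ratio, dilution_factor = 1) {
  stopifnot(is.numeric(natural_molality), is.numeric(ratio),
            length(natural_molality) == length(ratio),
            length(ratio) >= 1L)
  if (any(ratio <= 0)) stop("natural:SIL ratios must be positive")
  est <- natural_molality / ratio * dilution_factor
  u <- if (length(est) > 1L) stats::sd(est) / sqrt(length(est)) else 0
  measurement(mean(est), u, "mol/g", "derived")
}

#' Default seven-level calibration design
#'
#' Seven equidistant total-milk-protein mass fractions from 2.5 to
#' 25 mg/kg, plus level 0 (internal standard only). The SIL internal
#' standard is blended at 11.25 mg/kg — half the span of the design.
#'
#' @return data.frame with `level_id` (0-7) and `nominal_tcmp` (mg/kg).
#' @export
calibration_design <- function() {
  data.frame(level_id = 0:7,
             nominal_tcmp = c(0, seq(2.5, 25, length.out = 7)))
}

#' Per-protein calibrant molality for a target TCMP level
#'
#' Calibration blends mimic the milk composition: a target total-milk-protein
#' mass fraction maps to per-protein mass fractions through the conversion
#' factors, and then to the molality of each signature peptide in the
#' processed extract through the gravimetric chain and the protein molar
#' mass (one peptide per mole of protein). This is the exact inverse of the
#' protein mass-fraction equation, so calibrants and samples share one
#' quantitative convention end to end.
#'
#' @param model a [milk_model()].
#' @param target_tcmp total milk protein mass fraction, mg/kg (>= 0).
#' @param grav a [gravimetric_record()]; defaults to the standard design
#'   (1 g test portion, 15 g extraction solvent, 0.25 g extract aliquot).
#' @param scale extra dimensionless scale for the preparation chain
#'   (default 1); kept configurable because vendor dilution chains vary.
#' @return named numeric vector: molality (mol/g) per protein.
#' @export
blend_design <- function(model, target_tcmp, grav = gravimetric_record(),
                         scale = 1) {
  stopifnot(inherits(model, "milk_model"))
  if (target_tcmp < 0) stop("target TCMP must be >= 0")
  vapply(model$proteins, function(p) {
    w <- target_tcmp * p$cf$value * 1e-6      # g protein / g food
    w * grav$m_x * grav$m_extr / (grav$m_exsolv * p$molar_mass$value) * scale
  }, numeric(1))
}

#' Fit calibration curves for every peptide in a peak-area table
#'
#' Computes per-replicate natural:SIL area ratios from the quantifier
#' transition (`transition_rank == 1`), maps each calibration level to the
#' per-peptide molality via [blend_design()], and fits one
#' [irls_fit()] line per peptide. The second (qualifier) transition is used
#' only for an ion-ratio quality check: a replicate whose
#' qualifier:quantifier area ratio deviates more than `ion_ratio_tol` from
#' the per-peptide median is flagged.
#'
#' @param calib calibration area table: `level_id, peptide, transition_rank,
#'   replicate, area_natural, area_sil`.
#' @param design level table: `level_id, nominal_tcmp` (mg/kg).
#' @param registry transition registry mapping peptides to proteins.
#' @param model a [milk_model()].
#' @param grav a [gravimetric_record()] describing the calibrant processing.
#' @param weighting,scale passed to [irls_fit()] / [blend_design()].
#' @param ion_ratio_tol relative deviation that flags the ion-ratio QC
#'   (default 0.30).
#' @return list with `fits` (named list of `calibration_fit`, one per
#'   peptide) and `ion_ratio_qc` (data.frame of flagged replicates; empty
#'   when no qualifier transitions are present).
#' @export
fit_calibration_curves <- function(calib, design, registry = milk_registry(),
                                   model = milk_model(),
                                   grav = gravimetric_record(),
                                   weighting = "bisquare", scale = 1,
                                   ion_ratio_tol = 0.30) {
  needed <- c("level_id", "peptide", "transition_rank", "replicate",
              "area_natural", "area_sil")
  miss <- setdiff(needed, names(calib))
  if (length(miss))
    stop("calibration table misses column(s): ", paste(miss, collapse = ", "))
  prot_of <- protein_of_peptide(registry)
  unit_b <- blend_design(model, 1, grav, scale)   # molality per mg/kg TCMP

  quant <- calib[calib$transition_rank == 1L, ]
  ratio <- quant$area_natural / quant$area_sil
  nominal <- design$nominal_tcmp[match(quant$level_id, design$level_id)]
  prot_vec <- unlist(prot_of)
  x <- nominal * unname(unit_b[prot_vec[quant$peptide]])
  idx <- split(seq_along(ratio), quant$peptide)
  fits <- lapply(idx, function(i)
    irls_fit(x[i], ratio[i], weighting = weighting))

  qual <- calib[calib$transition_rank == 2L, ]
  qc <- NULL
  if (nrow(qual)) {
    m <- merge(quant[, c("level_id", "peptide", "replicate", "area_natural")],
               qual[, c("level_id", "peptide", "replicate", "area_natural")],
               by = c("level_id", "peptide", "replicate"),
               suffixes = c("_quant", "_qual"))
    m$ion_ratio <- m$area_natural_qual / m$area_natural_quant
    med <- stats::ave(m$ion_ratio, m$peptide, FUN = stats::median)
    m$deviation <- abs(m$ion_ratio / med - 1)
    m$flagged <- m$deviation > ion_ratio_tol
    qc <- m[, c("level_id", "peptide", "replicate", "ion_ratio",
                "deviation", "flagged")]
  }
  list(fits = fits, ion_ratio_qc = qc)
}

#' Peptide-to-protein lookup from a transition registry
#'
#' @param registry transition registry.
#' @return named list: protein id per peptide sequence.
#' @export
protein_of_peptide <- function(registry = milk_registry()) {
  nat <- unique(registry[registry$label == "natural", c("protein", "peptide")])
  stats::setNames(as.list(nat$protein), nat$peptide)
}
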