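## Method-validation statistics: LOQ, nested variance components,
## batch comparison (D%), linearity and selectivity.

#' Limit of quantification from blank replicates
#'
#' `LOQ = 10 * sd(blank signal) / slope`, the complete-procedure LOQ
#' estimated from replicate blank responses in the calibration signal unit
#' (natural:SIL area ratio) and the slope of the peptide's calibration
#' curve, giving a molality. When the protein molar mass, conversion factor
#' and gravimetric chain are supplied, the molality is converted to
#' mg TCMP / kg food via the same chain used for samples.
#'
#' @param blank_responses >= 6 replicate blank signals (ratio units).
#' @param fit the peptide's [irls_fit()].
#' @param grav,molar_mass,cf,factors optional chain to express the LOQ in
#'   mg TCMP / kg (all four must be given together).
#' @return list with `loq_molality` (mol/g) and, when the chain is supplied,
#'   `loq_tcmp` (mg/kg).
#' @export
loq <- function(blank_responses, fit, grav = NULL, molar_mass = NULL,
                cf = NULL, factors = unity_factors()) {
  if (length(blank_responses) < 6L)
    stop("LOQ estimation requires at least six blank replicates")
  stopifnot(inherits(fit, "calibration_fit"))
  if (fit$beta1 == 0) stop("calibration slope is zero")
  b <- 10 * stats::sd(blank_responses) / fit$beta1
  out <- list(loq_molality = b)
  if (!is.null(grav) && !is.null(molar_mass) && !is.null(cf)) {
    w <- protein_mass_fraction(b, grav, molar_mass, factors)
    cfv <- if (is.measurement(cf)) cf$value else cf
    out$loq_tcmp <- w / cfv
  }
  out
}

#' Nested variance components by expected mean squares
#'
#' Hierarchical (fully nested) ANOVA for a three-factor design such as
#' extraction > digestion > injection or analyst > day > extraction: the
#' innermost factor is the residual stratum. On balanced designs the
#' components come from the closed-form expected-mean-squares equations of
#' the nested ANOVA table; unbalanced designs fall back to REML
#' (`lme4`, if installed). Negative moment estimates are truncated to zero
#' and flagged — the conventional reporting for a stratum whose scatter is
#' below the resolution of the design. Components are expressed as percent
#' RSD of the grand mean; the total is their quadrature sum.
#'
#' @param data data.frame with the factor columns and a numeric response.
#' @param factors character vector of 3 column names, outer to inner; the
#'   innermost names the residual component (e.g. `"injection"`).
#' @param response response column name (default `"response"`).
#' @param method `"ems"` (default; requires balance) or `"reml"`.
#' @return Object of class `variance_components`: data.frame `components`
#'   (factor, variance, rsd_pct, truncated), `total_rsd_pct`, `grand_mean`,
#'   `method`.
#' @export
variance_components <- function(data, factors, response = "response",
                                method = c("ems", "reml")) {
  method <- match.arg(method)
  stopifnot(length(factors) == 3L, all(factors %in% names(data)),
            response %in% names(data))
  y <- data[[response]]
  A <- factor(data[[factors[1]]])
  B <- interaction(A, factor(data[[factors[2]]]), drop = TRUE)
  gm <- mean(y)
  if (nlevels(A) < 2L)
    stop("outer factor '", factors[1], "' needs at least two levels")

  counts_B <- table(B)
  counts_A <- table(A)
  balanced <- length(unique(counts_B)) == 1L &&
    length(unique(counts_A)) == 1L &&
    length(unique(table(A[!duplicated(B)]))) == 1L

  if (method == "reml" || !balanced) {
    if (!requireNamespace("lme4", quietly = TRUE))
      stop("unbalanced designs need the 'lme4' package for REML estimation")
    d <- data.frame(y = y, A = A, B = B)
    fit <- lme4::lmer(y ~ 1 + (1 | A) + (1 | B), data = d,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    vc <- as.data.frame(lme4::VarCorr(fit))
    v <- stats::setNames(vc$vcov, vc$grp)
    vars <- c(v[["A"]], v[["B"]], v[["Residual"]])
    trunc <- c(FALSE, FALSE, FALSE)
    method_used <- "reml"
  } else {
    n_rep <- unname(counts_B[1])                   # replicates per B cell
    n_B <- length(unique(B)) / nlevels(A)          # B levels per A
    # F statistics are not used, so the perfect-fit warning is irrelevant
    aovtab <- suppressWarnings(stats::anova(stats::aov(y ~ A + B)))
    ms <- aovtab[["Mean Sq"]]
    names(ms) <- rownames(aovtab)
    ms_A <- ms[["A"]]; ms_B <- ms[["B"]]; ms_E <- ms[["Residuals"]]
    v_E <- ms_E
    v_B <- (ms_B - ms_E) / n_rep
    v_A <- (ms_A - ms_B) / (n_rep * n_B)
    vars <- c(v_A, v_B, v_E)
    trunc <- vars < 0
    vars[trunc] <- 0
    method_used <- "ems"
  }
  rsd <- if (gm != 0) 100 * sqrt(vars) / abs(gm) else rep(NA_real_, 3)
  comp <- data.frame(factor = factors, variance = vars, rsd_pct = rsd,
                     truncated = trunc, stringsAsFactors = FALSE)
  structure(list(components = comp,
                 total_rsd_pct = sqrt(sum(rsd^2)),
                 grand_mean = gm, method = method_used),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("nested variance components (", x$method, "):\n", sep = "")
  c <- x$components
  for (i in seq_len(nrow(c)))
    cat(sprintf("  %-12s %5.1f%%%s\n", c$factor[i], c$rsd_pct[i],
                if (c$truncated[i]) " (negative estimate, set to 0)" else ""))
  cat(sprintf("  total        %5.1f%%\n", x$total_rsd_pct))
  invisible(x)
}

#' Percent difference of a measured amount from its nominal value
#'
#' `D% = 100 * (measured - nominal) / nominal`; the batch-comparison
#' statistic for standard-blend preparations.
#'
#' @param measured measured amount(s).
#' @param nominal nominal amount(s), > 0.
#' @return percent difference(s).
#' @export
percent_difference <- function(measured, nominal) {
  if (any(nominal <= 0)) stop("nominal amounts must be positive")
  100 * (measured - nominal) / nominal
}

#' Batch-stability report over peptide standard preparations
#'
#' @param d data.frame with columns `peptide`, `measured`, `nominal` (one
#'   row per peptide and preparation).
#' @param threshold absolute D% flag threshold (default 5).
#' @return the input with `d_pct` and `flagged` columns appended.
#' @export
batch_stability <- function(d, threshold = 5) {
  stopifnot(all(c("peptide", "measured", "nominal") %in% names(d)))
  d$d_pct <- percent_difference(d$measured, d$nominal)
  d$flagged <- abs(d$d_pct) >= threshold
  d
}

#' Linearity and heteroscedasticity check of a calibration curve
#'
#' Reports the R-squared of the straight-line fit over the calibration
#' levels and flags a monotone trend of the absolute residuals with level —
#' the signature of proportional, rather than constant, measurement noise.
#' The trend statistic is the Spearman rank correlation between the level
#' and the per-level mean absolute residual (replicates pooled per level).
#'
#' @param x calibration levels (>= 5 distinct values).
#' @param y replicate responses, same length.
#' @param trend_threshold rank-correlation threshold (default 0.8).
#' @return list with `r_squared`, `trend_rho` and `heteroscedastic` flag.
#' @export
linearity_check <- function(x, y, trend_threshold = 0.8) {
  if (length(unique(x)) < 5L)
    stop("linearity check requires at least five calibration levels")
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # noiseless data is valid
  res <- abs(stats::residuals(fit))
  lev_res <- tapply(res, x, mean)
  lev <- as.numeric(names(lev_res))
  rho <- if (stats::sd(lev_res) == 0) 0 else
    suppressWarnings(stats::cor(lev, unname(lev_res), method = "spearman"))
  list(r_squared = r2, trend_rho = rho,
       heteroscedastic = is.finite(rho) && rho > trend_threshold)
}

#' Cross-channel interference (selectivity) check
#'
#' For runs where only one label state was spiked, any signal in the channel
#' lacking its analyte is interference:
#' `interference% = 100 * blank-channel signal / spiked-analogue signal`.
#' Channels above the threshold (default 0.5 %) are flagged.
#'
#' @param d data.frame with columns `peptide`, `area_interference` (signal
#'   in the channel lacking its analyte) and `area_analyte` (signal of the
#'   corresponding spiked analogue).
#' @param threshold_pct flag threshold in percent.
#' @return the input with `interference_pct` and `flagged` appended.
#' @export
selectivity_check <- function(d, threshold_pct = 0.5) {
  stopifnot(all(c("peptide", "area_interference", "area_analyte")
                %in% names(d)))
  if (any(d$area_analyte <= 0))
    stop("spiked-analogue areas must be positive")
  d$interference_pct <- 100 * d$area_interference / d$area_analyte
  d$flagged <- d$interference_pct > threshold_pct
  d
}
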