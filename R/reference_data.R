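## Protein-level reference knowledge: molar-mass statistics, milk
## composition and conversion factors to total cow's milk protein (TCMP).

#' Read a protein reference table
#'
#' The reference TSV carries, per marker protein, the literature molar-mass
#' range (g/mol) and the range of the theoretical concentration in milk
#' (g/l), plus a casein flag. Midpoints and rectangular standard
#' uncertainties are derived with [rectangular_u()]. The table is editable so
#' that other allergenic ingredients can be configured.
#'
#' @param path TSV path; default: the bundled cow's-milk table.
#' @return data.frame with columns `protein, molar_mass_min, molar_mass_max,
#'   c_prot_min, c_prot_max, is_casein`.
#' @export
read_reference_table <- function(path = system.file("extdata",
                                                    "milk_reference.tsv",
                                                    package = "tcmpquant",
                                                    mustWork = TRUE)) {
  ref <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("protein", "molar_mass_min", "molar_mass_max",
              "c_prot_min", "c_prot_max")
  miss <- setdiff(needed, names(ref))
  if (length(miss))
    stop("reference table misses column(s): ", paste(miss, collapse = ", "))
  if (is.null(ref$is_casein)) ref$is_casein <- grepl("^CAS", ref$protein)
  ref
}

#' Conversion factor of a marker protein to total milk protein
#'
#' `CF = (c_prot / w_MP) / d_milk`: the mass share of one marker protein in
#' total milk protein, from its concentration in milk (g/l), the total milk
#' protein content of milk (g/kg) and the milk density (kg/l). The standard
#' uncertainty is propagated from the relative uncertainties of `c_prot` and
#' `w_MP` in quadrature; the density carries no stated uncertainty and is
#' treated as exact.
#'
#' @param c_prot [measurement()], protein concentration in milk, g/l.
#' @param w_mp [measurement()], total milk protein content of milk, g/kg.
#' @param d_milk milk density, kg/l (default 1.035).
#' @return dimensionless [measurement()].
#' @examples
#' wmp <- measurement(33, 1.5, "g/kg", "normal")
#' conversion_factor(rectangular_u(10, 15, "g/l"), wmp) # 0.366
#' @export
conversion_factor <- function(c_prot, w_mp, d_milk = 1.035) {
  stopifnot(is.measurement(c_prot), is.measurement(w_mp))
  if (c_prot$value <= 0 || w_mp$value <= 0 || d_milk <= 0)
    stop("conversion factor inputs must be positive")
  value <- (c_prot$value / w_mp$value) / d_milk
  u <- value * sqrt(rel_u(c_prot)^2 + rel_u(w_mp)^2)
  measurement(value, u, "", "derived")
}

#' Assemble the milk composition model
#'
#' Builds the per-protein reference set (molar masses, milk concentrations
#' and conversion factors) from a reference table, together with the global
#' quantities: milk density and total milk protein content of milk
#' (33 +/- 3 g/kg at k = 2).
#'
#' @param reference reference data.frame from [read_reference_table()].
#' @param d_milk milk density, kg/l.
#' @param w_mp total milk protein in milk as a [measurement()] (g/kg, k = 1
#'   uncertainty).
#' @return An object of class `milk_model`: list with `proteins` (named list
#'   carrying, per protein, `molar_mass`, `c_prot` and `cf` measurements and
#'   the casein flag), `d_milk`, `w_mp`, `cf_caseins`, `cf_all` (combined
#'   conversion factors) and `residual_fraction` (`1 - sum(CF)`, the
#'   unmeasured protein share).
#' @export
milk_model <- function(reference = read_reference_table(),
                       d_milk = 1.035,
                       w_mp = measurement(33, 1.5, "g/kg", "normal")) {
  proteins <- lapply(seq_len(nrow(reference)), function(i) {
    r <- reference[i, ]
    mm <- rectangular_u(r$molar_mass_min, r$molar_mass_max, "g/mol")
    cp <- rectangular_u(r$c_prot_min, r$c_prot_max, "g/l")
    list(protein = r$protein, molar_mass = mm, c_prot = cp,
         cf = conversion_factor(cp, w_mp, d_milk),
         is_casein = isTRUE(r$is_casein))
  })
  names(proteins) <- reference$protein
  model <- structure(list(proteins = proteins, d_milk = d_milk, w_mp = w_mp),
                     class = "milk_model")
  model$cf_caseins <- combined_cf(model,
                                  reference$protein[reference$is_casein])
  model$cf_all <- combined_cf(model, reference$protein)
  model$residual_fraction <- 1 - model$cf_all$value
  model
}

#' @export
print.milk_model <- function(x, ...) {
  cat("milk composition model:", length(x$proteins), "marker proteins\n")
  for (p in x$proteins)
    cat(sprintf("  %-6s M = %s;  c_prot = %s;  CF = %.3f\n", p$protein,
                format(p$molar_mass, digits = 6), format(p$c_prot),
                p$cf$value))
  cat(sprintf("  CF(caseins) = %.3f; CF(all) = %.3f; residual = %.3f\n",
              x$cf_caseins$value, x$cf_all$value, x$residual_fraction))
  invisible(x)
}

#' Combined conversion factor for a protein set
#'
#' The combined CF of a set of marker proteins is the sum of their individual
#' CFs. The shared total-milk-protein term `w_MP` is common to every CF, so
#' its uncertainty contribution is summed linearly (fully correlated) while
#' the independent `c_prot` contributions add in quadrature.
#'
#' @param model a [milk_model()].
#' @param protein_ids character vector of registered protein ids.
#' @return dimensionless [measurement()].
#' @export
combined_cf <- function(model, protein_ids) {
  stopifnot(inherits(model, "milk_model"))
  unknown <- setdiff(protein_ids, names(model$proteins))
  if (length(unknown))
    stop("unknown protein id(s): ", paste(unknown, collapse = ", "))
  cfs <- lapply(model$proteins[protein_ids], `[[`, "cf")
  value <- sum(vapply(cfs, `[[`, numeric(1), "value"))
  urel_wmp <- rel_u(model$w_mp)
  u_corr <- value * urel_wmp                 # shared w_MP, linear
  u_cprot <- sqrt(sum(vapply(model$proteins[protein_ids], function(p)
    (p$cf$value * rel_u(p$c_prot))^2, numeric(1))))
  measurement(value, sqrt(u_corr^2 + u_cprot^2), "", "derived")
}

#' Conversion factor summary table
#'
#' @param model a [milk_model()].
#' @return data.frame with per-protein and combined CF values, standard and
#'   relative uncertainties (mirrors the reference-data report layout).
#' @export
cf_table <- function(model) {
  stopifnot(inherits(model, "milk_model"))
  rows <- lapply(model$proteins, function(p)
    data.frame(protein = p$protein, cf = p$cf$value, u = p$cf$u,
               u_rel_pct = 100 * rel_u(p$cf)))
  cas <- model$cf_caseins
  all <- model$cf_all
  out <- rbind(do.call(rbind, rows),
               data.frame(protein = "SUM_CAS", cf = cas$value, u = cas$u,
                          u_rel_pct = 100 * rel_u(cas)),
               data.frame(protein = "SUM_PROT", cf = all$value, u = all$u,
                          u_rel_pct = 100 * rel_u(all)))
  rownames(out) <- NULL
  out
}

#' Moisture-loss correction between dough and baked matrix
#'
#' Baking removes water, concentrating the analyte: a mass fraction
#' `w_dough` in the wet dough corresponds to `w_dough / (1 - loss)` in the
#' baked product, where `loss` is the fractional mass (moisture) loss on
#' baking (0.16 for the incurred-cookie process).
#'
#' @param w_dough mass fraction in the wet dough, mg/kg (vectorised).
#' @param mass_loss_fraction fractional mass loss on baking, in `[0, 1)`.
#' @return mass fraction in the baked matrix, mg/kg.
#' @examples
#' moisture_correct(2.3, 0.16) # 2.74
#' @export
moisture_correct <- function(w_dough, mass_loss_fraction) {
  if (!is.numeric(mass_loss_fraction) || length(mass_loss_fraction) != 1L ||
      mass_loss_fraction < 0 || mass_loss_fraction >= 1)
    stop("mass_loss_fraction must lie in [0, 1)")
  w_dough / (1 - mass_loss_fraction)
}
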