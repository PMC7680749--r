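# shared fixtures built in code: default model/registry and a helper that
# evaluates the default per-peptide budget at a given molality uncertainty

fix_model <- milk_model()
fix_registry <- milk_registry()
fix_grav <- gravimetric_record()
fix_prot_of <- protein_of_peptide(fix_registry)
fix_peptides <- names(fix_prot_of)

default_peptide_budget <- function(peptide, tcmp = 10.7, u_rel_b = 0.05,
                                   ...) {
  prot <- fix_model$proteins[[fix_prot_of[[peptide]]]]
  b0 <- tcmp * blend_design(fix_model, 1, fix_grav)[[prot$protein]]
  budget_for_peptide(measurement(b0, u_rel_b * b0, "mol/g"), fix_grav,
                     prot$molar_mass, prot$cf, ...)
}

# per-peptide / per-protein tables from the bundled reference TCMP results,
# shaped for aggregate_tcmp()
reference_aggregate_tables <- function(model = fix_model) {
  ref <- reference_tcmp_results()
  pp <- data.frame(peptide = ref$peptide, protein = ref$protein,
                   tcmp = ref$w_tcmp, u_tcmp = ref$U_k2 / 2)
  prot <- do.call(rbind, lapply(split(pp, pp$protein), function(d) {
    cf <- model$proteins[[d$protein[1]]]$cf$value
    tcmp_j <- mean(d$tcmp)
    data.frame(protein = d$protein[1], w = tcmp_j * cf,
               u_w = sqrt(sum(d$u_tcmp^2)) / nrow(d) * cf,
               tcmp = tcmp_j, u_tcmp = sqrt(sum(d$u_tcmp^2)) / nrow(d))
  }))
  rownames(prot) <- NULL
  list(per_peptide = pp, per_protein = prot)
}
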