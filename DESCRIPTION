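Package: tcmpquant
Title: Total Cow's Milk Protein Quantification from SRM Isotope-Dilution Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational chain for quantifying total cow's milk protein
    (TCMP) in processed food from selected reaction monitoring (SRM) peak
    areas with stable-isotope-labelled internal standards. Provides peptide
    mass and fragment-ion calculators for the eleven milk signature
    peptides, protein reference data (molar masses, milk composition,
    conversion factors), matrix-matched calibration by iteratively
    reweighted least squares, conversion of peptide molalities to protein
    and total-milk-protein mass fractions by four aggregation approaches,
    GUM-compliant uncertainty budgets via the Kragten one-at-a-time method
    with a Monte Carlo cross-check, method-validation statistics (LOQ,
    nested variance components, batch comparison, linearity, selectivity),
    and a synthetic peak-area generator so the full pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
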