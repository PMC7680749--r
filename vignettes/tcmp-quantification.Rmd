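---
title: "Quantifying total cow's milk protein by SRM-IDMS: models, budgets and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying total cow's milk protein by SRM-IDMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmpquant)
```

## The measurement problem

Food-allergen risk assessment is anchored to one reporting quantity: the
mass of *total* allergenic-ingredient protein per mass of food (here: mg
total cow's milk protein, TCMP, per kg of baked cookie). No instrument
measures that quantity directly. A mass-spectrometric reference method
instead measures surrogates — tryptic *signature peptides*, each unique to
one marker protein and released at exactly 1 mol per mol of parent protein —
and converts them upward: peptide molality → marker-protein mass fraction →
TCMP. `tcmpquant` implements that computational chain, its uncertainty
budget and its validation statistics.

Eleven signature peptides cover five marker proteins: two for
alpha-S1-casein (CASA1), four for alpha-S2-casein (CASA2), two for
beta-casein (CASB), one for kappa-casein (CASK) and two for
beta-lactoglobulin (LACB). Together these proteins account for roughly 97 %
of the protein mass of cow's milk.

## The quantification chain

**Calibration and inversion.** Each peptide is measured by selected reaction
monitoring as the peak-area ratio $R$ of the natural form over its
stable-isotope-labelled (SIL) internal standard. Matrix-matched calibrants
(peptide blends mimicking the milk composition, spiked into blank extract
*before* digestion so processing losses cancel) give a straight line
$R = \beta_0 + \beta_1 b$, fitted by iteratively reweighted least squares;
inversion gives the molality of the peptide in the processed extract,

$$ b(\mathrm{pep}) = \frac{R - \beta_0}{\beta_1}. $$

**Protein mass fraction.** With the gravimetric chain of the standard
design — test portion $m_X$ (1 g), extraction solvent $m_{Exsolv}$ (15 g),
extract aliquot $m_{Extr}$ (0.25 g) — and the protein's average molar mass
$M_j$,

$$ w_j = b(\mathrm{pep}) \, \frac{m_{Exsolv}}{m_X \, m_{Extr}} \, M_j \,
   f_{ext} \, f_{dig} \, f_{purity}, $$

where the three $f$ terms are *unity factors*: exactly 1, carrying only the
relative uncertainty of extraction, digestion and standard purity into the
budget. The synthetic-data generator uses the exact inverse of this mapping,
so the simulate→quantify loop closes to identity at zero noise.

**Conversion to TCMP.** Each protein's *conversion factor*
$\mathrm{CF}_j = (c_{prot}/w_{MP})/d_{milk}$ is its mass share of total milk
protein, built from the protein's concentration in milk ($c_{prot}$, g/l),
the total milk protein content of milk ($w_{MP}$ = 33 ± 3 g/kg at $k$ = 2)
and the milk density (1.035 kg/l, treated as exact since no uncertainty is
stated for it). Because CF is a *share*, the total is recovered by
**division**:

$$ w_{TCMP} = w_j / \mathrm{CF}_j. $$

Some published presentations write this conversion as a multiplication;
the numbers they report alongside it (e.g. a per-peptide TCMP of 6.81 mg/kg
at CF = 0.366 next to a protein fraction of 2.49 mg/kg at a nominal level
of 10.7 mg/kg) are only mutually consistent with division, which is what
this package implements.

**Four aggregation approaches.** A TCMP estimate can be assembled four ways,
with different uncertainty behaviour (`aggregate_tcmp()`):

* **A1** — each of the 11 peptides is an independent marker; mean of the
  per-peptide TCMP values.
* **A2** — each of the 5 proteins is an independent marker; per-protein
  means first (between-peptide SEM retained as a budget input), then the
  mean of the per-protein TCMP values.
* **A3** — the summed mass fractions of the four caseins divided by the
  combined casein CF.
* **A4** — the summed mass fractions of all five proteins plus the
  unmeasured residual share: total = sum / $f$, with $f$ the measured
  fraction of total milk protein. The residual carries a rectangular
  uncertainty (half-range = the residual share), and *no* conversion factor
  enters — which is why A4 typically has the smallest expanded uncertainty.

The measured fraction defaults to $f = 0.96$; the combined-CF value 0.966 is
also available (`f_measured` argument). Both appear in practice because the
residual share is conventionally quoted as "4 %"; the package exposes the
choice rather than hiding it.

## Uncertainty budgets

All combined uncertainties follow the GUM via the **Kragten** numerical
method (`kragten()`): the measurement function is re-evaluated with each
input shifted by $+u_i$ one at a time; the combined standard uncertainty is
the quadrature sum of the resulting output shifts, and each input's *index*
is its percentage share of the combined variance. Range-type inputs (molar
masses, milk concentrations, purity) enter as rectangular distributions with
$u$ = half-range/√3; $w_{MP}$ is normal with $u$ = 1.5 g/kg.

Two numerical points deserve care:

* **Correlated conversion factors.** The five CFs share the $w_{MP}$
  denominator. `combined_cf()` therefore sums the $w_{MP}$ contribution
  linearly across proteins (fully correlated) and the independent
  $c_{prot}$ contributions in quadrature. Per-protein CF uncertainties are
  not asserted against published roundings beyond two units of the final
  digit: the upstream rounding chain of published tables is not
  recoverable.
* **Shift direction.** The classic Kragten scheme shifts by $+u$. On the
  reciprocal term $1/\mathrm{CF}$ with a 12 % relative uncertainty this
  one-sided shift gives a sensitivity $u/(\mathrm{CF}+u)$ rather than
  $u/\mathrm{CF}$, sitting about 10 % below a 10^5^-draw Monte Carlo
  standard deviation. The symmetric variant
  $(f(x+u)-f(x-u))/2$ (`symmetric = TRUE`) removes the first-order bias and
  tracks the Monte Carlo within ~5 % on the full chain; it is what the
  package's Monte Carlo cross-checks compare against. Both variants are
  exact for affine measurement functions. `monte_carlo_u()` is the seeded
  oracle: every input sampled from its tagged distribution.

**Default input magnitudes.** The relative uncertainties of the unity
factors are not universal constants; the package defaults are
$u_{rel}(f_{ext})$ = 5 %, $u_{rel}(f_{dig})$ = 1 %,
$u_{rel}(f_{purity})$ = 1.5 %, and a 5 % relative uncertainty on the
molality when none is measured. These were chosen once, as magnitudes
representative of a well-controlled SRM assay in which extraction is the
dominant efficiency term and digestion is tightly controlled; with the
reference CF and molar-mass tables they place every peptide's combined
relative uncertainty in the 10–16 % range with the conversion factor as the
top-ranked contributor — the qualitative budget shape this method exhibits
in practice. All are arguments (`unity_factors()`), not constants.

## Calibration details

* **Weighting.** "IRLS" conventionally denotes robust regression: the
  default is Tukey bisquare (tuning constant 4.685, scale from the
  normalised median absolute deviation, at most 50 iterations, relative
  tolerance 10^-8^), as provided by `MASS::rlm`. Ordinary least squares and
  $1/x^2$ variance weighting (for the proportional residual growth seen at
  high molality) are options. A noiseless point set degenerates the robust
  scale estimate and short-circuits to the OLS solution, which is identical
  there.
* **Design.** Seven equidistant levels from 2.5 to 25 mg TCMP/kg plus level
  0 (internal standard only). The SIL blend sits at 11.25 mg/kg — half the
  design span — giving area ratios near 1 at the centre of the range.
* **Two transitions, one number.** The first listed transition is the
  quantifier; the second is a qualifier used only for an ion-ratio QC
  (replicates whose qualifier:quantifier ratio deviates more than 30 % from
  the peptide's median are flagged). This keeps the quantitative chain
  single-valued, as in standard SRM practice.
* **Below-blank signals** invert to *negative* molalities, flagged but never
  truncated: truncation would bias every downstream mean upward.
* **Value assignment.** Natural standards are value-assigned by amino acid
  analysis; a peptide that AAA cannot cover is assigned by proxy
  (`assign_purity_by_proxy()`): the mean purity of the peptides synthesised
  in parallel, with a rectangular uncertainty spanning their range. SIL
  solutions are assigned by reverse isotope dilution against the natural
  standards (`reverse_idms_assign()`).

## Validation statistics

* **LOQ** = 10 × sd(blank signal) / slope, from ≥ 6 blank replicates,
  expressed in mg TCMP/kg through the same chain as samples.
* **Precision** via hierarchical (fully nested) three-factor ANOVA
  (`variance_components()`): closed-form expected-mean-squares estimates on
  balanced designs, REML (lme4) on unbalanced ones. Negative moment
  estimates are truncated to zero and flagged — the standard reporting
  convention for strata whose scatter is below the design's resolution.
  The total is the quadrature sum of the component RSDs, which reproduces
  the conventional "Total" column of such reports.
* **Batch stability**: per-peptide percent difference
  $D_\% = 100\,(\text{measured}-\text{nominal})/\text{nominal}$, flagged at
  |D%| ≥ 5.
* **Equimolarity**: complete digestion implies equal molality across a
  protein's peptides; the RSD across members is flagged above 20 % —
  between the 13–19 % seen for well-digested caseins and the 35–42 % of an
  incompletely digested protein.
* **Linearity**: R² of the straight-line fit plus a heteroscedasticity flag:
  Spearman rank correlation > 0.8 between level and the *per-level mean*
  absolute residual. The per-level mean (rather than the raw per-replicate
  residuals, whose rank correlation is diluted by within-level noise) gives
  the flag useful power against CV-constant noise over the 8-level design.
* **Selectivity**: signal in a channel lacking its analyte, as a percentage
  of the matching spiked-analogue signal, flagged above 0.5 %.

## What the synthetic generator does and does not emulate

`simulate_experiment()` generates peak-area tables with the statistical
structure the method assumes: linear IDMS response with ratio 1 at the SIL
level, per-peptide digestion/extraction efficiencies in (0, 1],
multiplicative log-normal area noise (default CV 5 %), additive baseline
noise (for LOQ work), and a configurable natural↔SIL channel crosstalk that
propagates exactly into the selectivity check. Calibrants are synthetic
peptides (unit efficiency); incurred-sample peptides see the protein's
digestion efficiency — which is precisely what makes an incompletely
digested protein visible as an equimolarity failure downstream.

It does **not** simulate chromatograms (no peak shapes, retention drift or
integration errors), matrix-dependent ionisation suppression beyond the
per-peptide response factors, or between-day/analyst effects (those are
exercised directly through the nested-design generator in the tests).
Passing tests therefore demonstrate that the *computational chain* is
correct and unbiased under the method's own model assumptions — not that
the wet-lab assumptions hold for any particular food matrix.

## Problem sizes and numerical conventions used by the test-suite

The package's own checks run at the scale of the underlying study design:
7 + 1 calibration levels × 5 instrumental replicates, samples measured as
2 digests × 3 injections, 500 simulated experiments for the
parameter-recovery check (bias and k = 2 coverage of the A2 estimator at
10.7 mg/kg truth, CV 5 %), 1000 replicates of the 3×3×3 nested design for
variance-component recovery, and 10^5^ Monte Carlo draws for the budget
cross-check. Masses are computed from a fixed internal monoisotopic residue
table (5 decimals; proton 1.007276 Da, water 18.010565 Da) so results are
bit-stable across platforms.

Transition-table reproduction deserves one caveat: published transition
tables mix conventions. Within the bundled registry, two rows match the
*neutral* monoisotopic mass rather than MH⁺, one row matches neither (and
one SIL mass equals its natural counterpart) — these are print-level
inconsistencies, flagged per row by `registry_mass_report()` with a ±1.1 Da
validation tolerance rather than silently reproduced.

## Known limitations

* The blend-preparation scaling between the printed calibrant molality
  range and the gravimetric chain is not fully specified by the study
  design; `blend_design()` exposes a `scale` argument rather than guessing
  a dilution chain.
* Reported A1–A3 central values from the reference study can only be
  approached from rounded per-peptide inputs (agreement within 2.5–3 %);
  the unrounded inputs were never published.
* Single-peptide proteins (CASK here, and CASA1 whenever one standard lacks
  a value assignment) have no internal equimolarity check; their digestion
  completeness is an assumption imported from the multi-peptide proteins.
* The uncertainty treatment assumes independent inputs except for the
  shared $w_{MP}$ inside combined CFs; correlations introduced by shared
  calibrants across peptides are not modelled.
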