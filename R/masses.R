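## Peptide mass and fragment-ion calculators for the SRM transition registry.
##
## Residue masses are fixed internal constants (monoisotopic to 5 decimals)
## so that all mass arithmetic is bit-stable across platforms.

# monoisotopic residue (amino-acid minus water) masses, Da
.AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)

# average residue masses, Da
.AA_AVG <- c(
  G = 57.05190, A = 71.07880, S = 87.07820, P = 97.11670, V = 99.13260,
  T = 101.10510, C = 103.13880, L = 113.15940, I = 113.15940, N = 114.10380,
  D = 115.08860, Q = 128.13070, K = 128.17410, E = 129.11550, M = 131.19260,
  H = 137.14110, F = 147.17660, R = 156.18750, Y = 163.17600, W = 186.21320)

.MASS_WATER_MONO <- 18.010565
.MASS_WATER_AVG  <- 18.01528
.MASS_PROTON     <- 1.007276
.SHIFT_13C       <- 1.003355   # 13C - 12C
.SHIFT_15N       <- 0.997035   # 15N - 14N
.MASS_CAM        <- 57.02146   # carbamidomethyl (iodoacetamide) on Cys

.check_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("peptide sequence must be a single non-empty string")
  aa <- strsplit(sequence, "")[[1]]
  bad <- setdiff(aa, names(.AA_MONO))
  if (length(bad))
    stop("unknown amino-acid letter(s) in sequence '", sequence, "': ",
         paste(unique(bad), collapse = ", "))
  aa
}

.residue_sum <- function(aa, type = "monoisotopic", carbamidomethyl = FALSE) {
  tab <- if (type == "monoisotopic") .AA_MONO else .AA_AVG
  s <- sum(tab[aa])
  if (carbamidomethyl) s <- s + .MASS_CAM * sum(aa == "C")
  s
}

#' Neutral peptide mass
#'
#' Sum of residue masses plus one water (the condensation terminus).
#'
#' @param sequence peptide as a string of one-letter amino-acid codes
#'   (canonical 20 letters only).
#' @param type `"monoisotopic"` (default) or `"average"`.
#' @param carbamidomethyl add +57.02146 Da per cysteine (iodoacetamide
#'   blocking, a fixed modification); default `FALSE` — none of the milk
#'   signature peptides contains cysteine.
#' @return Neutral mass in Da.
#' @export
peptide_mass <- function(sequence, type = c("monoisotopic", "average"),
                         carbamidomethyl = FALSE) {
  type <- match.arg(type)
  aa <- .check_sequence(sequence)
  water <- if (type == "monoisotopic") .MASS_WATER_MONO else .MASS_WATER_AVG
  .residue_sum(aa, type, carbamidomethyl) + water
}

#' Monoisotopic MH+ mass of a peptide
#'
#' Singly protonated monoisotopic mass: residue masses + water + one proton
#' (1.007276 Da).
#'
#' @inheritParams peptide_mass
#' @return MH+ mass in Da.
#' @examples
#' monoisotopic_mh("YLGYLEQLLR") # 1267.704
#' monoisotopic_mh("FALPQYLK")   # 979.561
#' @export
monoisotopic_mh <- function(sequence, carbamidomethyl = FALSE) {
  peptide_mass(sequence, "monoisotopic", carbamidomethyl) + .MASS_PROTON
}

#' MH+ mass of the stable-isotope-labelled (SIL) analogue
#'
#' SIL analogues carry a fully labelled C-terminal residue:
#' \eqn{^{13}C_6{}^{15}N_2}-lysine (+8.0142 Da exact, +8 nominal) or
#' \eqn{^{13}C_6{}^{15}N_4}-arginine (+10.0083 Da exact, +10 nominal).
#'
#' @inheritParams peptide_mass
#' @param mode `"exact"` uses the isotopic mass differences; `"nominal"` uses
#'   the integer +8/+10 shifts conventionally printed in transition tables.
#' @return SIL MH+ mass in Da.
#' @examples
#' sil_mh("FALPQYLK", "nominal") # 987.561
#' sil_mh("FALPQYLK", "exact")   # 987.575
#' @export
sil_mh <- function(sequence, mode = c("exact", "nominal"),
                   carbamidomethyl = FALSE) {
  mode <- match.arg(mode)
  aa <- .check_sequence(sequence)
  last <- aa[length(aa)]
  if (!last %in% c("K", "R"))
    stop("SIL labelling requires a C-terminal K or R; sequence '", sequence,
         "' ends in ", last)
  shift <- if (mode == "nominal") {
    if (last == "K") 8 else 10
  } else {
    if (last == "K") 6 * .SHIFT_13C + 2 * .SHIFT_15N
    else             6 * .SHIFT_13C + 4 * .SHIFT_15N
  }
  monoisotopic_mh(sequence, carbamidomethyl) + shift
}

#' b/y fragment ion m/z
#'
#' Standard sequence-ion masses: a b ion is the N-terminal residue sum plus
#' the charging protons; a y ion is the C-terminal residue sum plus water
#' plus the charging protons.
#'
#' @inheritParams peptide_mass
#' @param ion_type `"b"` or `"y"`.
#' @param index number of residues in the fragment, `1 <= index < nchar(sequence)`.
#' @param charge positive integer charge state.
#' @param label `"natural"` or `"sil"`; for a SIL peptide the C-terminal
#'   label shift (exact) is added to y ions (b ions of a C-terminally
#'   labelled peptide are unshifted).
#' @return m/z in Th.
#' @examples
#' fragment_mz("VIPYVR", "y", 1)      # arginine y1, 175.119
#' fragment_mz("YLGYLEQLLR", "y", 6)  # 771.47
#' @export
fragment_mz <- function(sequence, ion_type = c("b", "y"), index, charge = 1L,
                        label = c("natural", "sil"),
                        carbamidomethyl = FALSE) {
  ion_type <- match.arg(ion_type)
  label <- match.arg(label)
  aa <- .check_sequence(sequence)
  n <- length(aa)
  if (!is.numeric(index) || length(index) != 1L || index < 1 || index >= n)
    stop("fragment index must satisfy 1 <= index < ", n,
         " for sequence '", sequence, "' (got ", index, ")")
  if (!is.numeric(charge) || charge < 1) stop("charge must be >= 1")
  frag <- if (ion_type == "b") aa[seq_len(index)] else aa[(n - index + 1):n]
  neutral <- .residue_sum(frag, "monoisotopic", carbamidomethyl)
  if (ion_type == "y") neutral <- neutral + .MASS_WATER_MONO
  if (label == "sil" && ion_type == "y") {
    last <- aa[n]
    neutral <- neutral + if (last == "K") 6 * .SHIFT_13C + 2 * .SHIFT_15N
                         else             6 * .SHIFT_13C + 4 * .SHIFT_15N
  }
  (neutral + charge * .MASS_PROTON) / charge
}

#' Multiply-charged precursor m/z
#'
#' @inheritParams sil_mh
#' @param charge positive integer charge state (SRM precursors here are 2+).
#' @param label `"natural"` or `"sil"`.
#' @param sil_mode label-shift convention passed to [sil_mh()] when
#'   `label = "sil"`.
#' @return Precursor m/z in Th, `(neutral + charge * 1.007276) / charge`.
#' @export
precursor_mz <- function(sequence, charge = 2L, label = c("natural", "sil"),
                         sil_mode = "nominal", carbamidomethyl = FALSE) {
  label <- match.arg(label)
  mh <- if (label == "sil") sil_mh(sequence, sil_mode, carbamidomethyl)
        else monoisotopic_mh(sequence, carbamidomethyl)
  neutral <- mh - .MASS_PROTON
  (neutral + charge * .MASS_PROTON) / charge
}

#' Read / write an SRM transition registry
#'
#' The registry is a TSV with one row per transition and columns
#' `protein, peptide, label, rt_min, precursor_mz, product_mz, ion, ce, cone,
#' stated_mh, note`. `stated_mh` carries the precursor monoisotopic mass as
#' stated by the acquisition method (used by [registry_mass_report()] to
#' cross-check conventions); `note` records known quirks of a row.
#'
#' @param path file path.
#' @return `read_transition_registry` returns a data.frame.
#' @export
read_transition_registry <- function(path) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("protein", "peptide", "label", "rt_min", "precursor_mz",
              "product_mz", "ion", "ce", "cone")
  miss <- setdiff(needed, names(reg))
  if (length(miss))
    stop("transition registry misses column(s): ", paste(miss, collapse = ", "))
  if (any(reg$precursor_mz <= 0) || any(reg$product_mz <= 0))
    stop("transition m/z values must be positive")
  reg
}

#' @rdname read_transition_registry
#' @param registry data.frame as returned by [read_transition_registry()].
#' @export
write_transition_registry <- function(registry, path) {
  utils::write.table(registry, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Bundled milk signature-peptide transition registry
#'
#' The eleven tryptic signature peptides for the five major allergenic milk
#' proteins (alpha-S1-, alpha-S2-, beta-, kappa-casein and
#' beta-lactoglobulin), with their scheduled SRM transitions: two
#' transitions per natural peptide (quantifier first, qualifier second) and
#' one per SIL analogue.
#'
#' @return A transition-registry data.frame (33 transition rows; 11 natural
#'   and 11 SIL peptide entries).
#' @export
milk_registry <- function() {
  read_transition_registry(
    system.file("extdata", "milk_transitions.tsv", package = "tcmpquant",
                mustWork = TRUE))
}

#' Cross-check registry masses against computed values
#'
#' For each natural peptide, compares the stated precursor monoisotopic mass
#' with the computed MH+ and neutral monoisotopic masses and classifies the
#' convention of the stated value: `"mh"` (matches MH+), `"neutral"`
#' (matches the neutral mass — the stated value omitted the proton) or
#' `"mismatch"` (matches neither; a print error). Rows are additionally
#' checked to lie within `tol_da` of the *closer* convention, so genuine
#' typos are flagged without failing the whole table.
#'
#' @param registry transition registry (default: bundled milk registry).
#' @param tol_match agreement tolerance in Da used to call a convention
#'   (default 0.01).
#' @param tol_da overall per-row validation tolerance in Da (default 1.1).
#' @return data.frame with one row per natural peptide: computed MH+ and
#'   neutral masses, stated mass, convention call, and deviation from the
#'   closer convention.
#' @export
registry_mass_report <- function(registry = milk_registry(),
                                 tol_match = 0.01, tol_da = 1.1) {
  nat <- unique(registry[registry$label == "natural",
                         c("protein", "peptide", "stated_mh")])
  mh <- vapply(nat$peptide, monoisotopic_mh, numeric(1))
  neutral <- mh - .MASS_PROTON
  d_mh <- nat$stated_mh - mh
  d_neutral <- nat$stated_mh - neutral
  convention <- ifelse(abs(d_mh) <= tol_match, "mh",
                ifelse(abs(d_neutral) <= tol_match, "neutral", "mismatch"))
  closer <- pmin(abs(d_mh), abs(d_neutral))
  data.frame(protein = nat$protein, peptide = nat$peptide,
             stated_mh = nat$stated_mh,
             computed_mh = round(mh, 4), computed_neutral = round(neutral, 4),
             convention = convention, deviation_da = round(closer, 4),
             within_tolerance = closer <= tol_da,
             row.names = NULL)
}
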