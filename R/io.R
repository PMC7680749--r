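## File I/O and run configuration. One CSV dialect throughout: comma
## separator, UTF-8, mandatory header row, decimal point.

#' Default run configuration
#'
#' Central knobs of a quantification run, with the package defaults:
#' coverage factor k = 2, A4 measured fraction 0.96, robust (bisquare)
#' calibration weighting, equimolarity flag at 20 % RSD, batch D% flag at
#' 5 %, interference flag at 0.5 %.
#'
#' @param ... overrides of any listed element.
#' @return named list.
#' @export
run_config <- function(...) {
  cfg <- list(k = 2, f_measured = 0.96, weighting = "bisquare",
              equimolarity_threshold = 0.20, d_pct_threshold = 5,
              interference_threshold_pct = 0.5, u_mass_g = 5e-4,
              seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, dots)
}

#' Read / write peak-area and manifest CSV tables
#'
#' Thin, validating wrappers around the package CSV dialect.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_areas_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("peptide", "replicate", "area_natural", "area_sil")
  miss <- setdiff(needed, names(d))
  if (length(miss))
    stop("area table '", path, "' misses column(s): ",
         paste(miss, collapse = ", "))
  d
}

#' @rdname read_areas_csv
#' @export
read_manifest_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "m_X_g", "m_Exsolv_g", "m_Extr_g")
  miss <- setdiff(needed, names(d))
  if (length(miss))
    stop("manifest '", path, "' misses column(s): ",
         paste(miss, collapse = ", "))
  d
}

#' @rdname read_areas_csv
#' @param x data.frame to write.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a quantification report to JSON
#'
#' Emits a schema-versioned JSON report per sample: per-peptide molality
#' with uncertainty, per-protein mass fraction and equimolarity diagnostics,
#' per-approach TCMP with expanded uncertainty, and flags.
#'
#' @param report a `tcmp_report` from [quantify_samples()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "tcmp_report"))
  payload <- list(
    schema = "tcmpquant-report/1",
    k = report$k, f_measured = report$f_measured,
    samples = lapply(report$samples, function(s) list(
      sample_id = s$sample_id,
      nominal_tcmp = s$nominal_tcmp,
      per_peptide = s$per_peptide,
      per_protein = s$per_protein,
      approaches = s$approaches)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Bundled reference per-peptide TCMP results
#'
#' Reported study values for an incurred baked-cookie sample at a nominal
#' level of 10.7 mg TCMP/kg: per-peptide TCMP mass fraction, expanded
#' uncertainty (k = 2), relative standard uncertainty and the percent
#' contribution indexes of the main budget inputs. Used for
#' consistency checks of the aggregation approaches.
#'
#' @return data.frame, one row per signature peptide (11 rows).
#' @export
reference_tcmp_results <- function() {
  utils::read.delim(system.file("extdata", "reference_tcmp_results.tsv",
                                package = "tcmpquant", mustWork = TRUE),
                    comment.char = "#", stringsAsFactors = FALSE)
}
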