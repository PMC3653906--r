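#' File formats
#'
#' All tabular interchange files are TSV: UTF-8, LF line endings, dot
#' decimal separator, mandatory header row, numbers written with full
#' precision (15 significant digits). Readers validate headers strictly
#' and name the missing column or the offending line in their errors.
#'
#' @name urinpep-formats
#' @keywords internal
NULL

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(v) {
    s <- formatC(v, digits = 15, format = "g")
    s[is.na(v)] <- NA
    s
  })
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8", na = "")
  invisible(path)
}

.read_tsv <- function(path, required, numeric_cols, what,
                      id_col = NULL) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path))
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, na.strings = "")
  .check_columns(df, required, what)
  df <- .check_numeric_cols(df, numeric_cols, what)
  if (!is.null(id_col) && anyDuplicated(df[[id_col]])) {
    dup <- df[[id_col]][duplicated(df[[id_col]])][1L]
    line <- which(df[[id_col]] == dup)[2L] + 1L
    stop(sprintf("%s: duplicate id '%s' at line %d", what, dup, line))
  }
  df
}

#' Read / write a per-sample peak-list TSV
#'
#' Columns: `mz`, `charge`, `intensity`, `migration_time_min`, `snr`,
#' `n_spectra`.
#'
#' @param path File path.
#' @return `read_peaklist`: a raw-signal `data.frame`.
#' @export
read_peaklist <- function(path) {
  cols <- c("mz", "charge", "intensity", "migration_time_min", "snr",
            "n_spectra")
  df <- .read_tsv(path, cols, cols, "read_peaklist")
  raw_signals(df$mz, df$charge, df$intensity, df$migration_time_min,
              df$snr, df$n_spectra)
}

#' @rdname read_peaklist
#' @param signals Raw-signal `data.frame`.
#' @export
write_peaklist <- function(signals, path) {
  .check_columns(signals, c("mz", "charge", "intensity",
                            "migration_time_min", "snr", "n_spectra"),
                 "write_peaklist")
  .write_tsv(signals, path)
}

#' Read / write a peptide-feature TSV
#'
#' Columns: `mass_da`, `time_min`, `intensity`, `charges`, `n_signals`.
#'
#' @param path File path.
#' @return `read_features`: a feature `data.frame`.
#' @export
read_features <- function(path) {
  df <- .read_tsv(path, c("mass_da", "time_min", "intensity"),
                  c("mass_da", "time_min", "intensity"), "read_features")
  df
}

#' @rdname read_features
#' @param features Feature `data.frame`.
#' @export
write_features <- function(features, path) {
  .check_columns(features, c("mass_da", "time_min", "intensity"),
                 "write_features")
  .write_tsv(features, path)
}

#' Read / write a reference or housekeeping panel TSV
#'
#' Columns: `peptide_id`, `mass_da`, `time_min`, and for housekeeping
#' panels `ref_intensity`.
#'
#' @param path File path.
#' @return `read_panel`: a panel `data.frame`.
#' @export
read_panel <- function(path) {
  df <- .read_tsv(path, c("peptide_id", "mass_da", "time_min"),
                  c("mass_da", "time_min"), "read_panel",
                  id_col = "peptide_id")
  if ("ref_intensity" %in% names(df)) {
    df <- .check_numeric_cols(df, "ref_intensity", "read_panel")
  }
  df
}

#' @rdname read_panel
#' @param panel Panel `data.frame`.
#' @export
write_panel <- function(panel, path) {
  .check_columns(panel, c("peptide_id", "mass_da", "time_min"),
                 "write_panel")
  .write_tsv(panel, path)
}

#' Read / write a clinical table TSV
#'
#' Columns: `patient_id`, `age_years`, `sex`, `dialysis`,
#' `creatinine_umol_l`, `urine_protein_g_per_g`, `event`,
#' `followup_years`.
#'
#' @param path File path.
#' @return `read_clinical`: a clinical `data.frame` (logical `dialysis`
#'   and `event`, `NA` event = unknown outcome).
#' @export
read_clinical <- function(path) {
  df <- .read_tsv(path,
                  c("patient_id", "age_years", "sex", "dialysis",
                    "creatinine_umol_l", "urine_protein_g_per_g", "event",
                    "followup_years"),
                  c("age_years", "creatinine_umol_l",
                    "urine_protein_g_per_g", "followup_years"),
                  "read_clinical", id_col = "patient_id")
  df$dialysis <- as.logical(df$dialysis)
  df$event <- as.logical(df$event)
  df
}

#' @rdname read_clinical
#' @param clinical Clinical `data.frame`.
#' @export
write_clinical <- function(clinical, path) {
  .check_columns(clinical,
                 c("patient_id", "age_years", "sex", "dialysis",
                   "creatinine_umol_l", "urine_protein_g_per_g", "event",
                   "followup_years"), "write_clinical")
  .write_tsv(clinical, path)
}

#' Read / write a peptide matrix TSV
#'
#' First three columns `peptide_id`, `mass_da`, `time_min`; one column per
#' sample; empty cell = peptide not detected in that sample.
#'
#' @param path File path.
#' @return `read_matrix_tsv`: a `peptide_matrix`.
#' @export
read_matrix_tsv <- function(path) {
  df <- .read_tsv(path, c("peptide_id", "mass_da", "time_min"),
                  c("mass_da", "time_min"), "read_matrix_tsv",
                  id_col = "peptide_id")
  sids <- setdiff(names(df), c("peptide_id", "mass_da", "time_min"))
  df <- .check_numeric_cols(df, sids, "read_matrix_tsv")
  mat <- as.matrix(df[, sids, drop = FALSE])
  rownames(mat) <- df$peptide_id
  peptides <- data.frame(peptide_id = df$peptide_id, mass_da = df$mass_da,
                         time_min = df$time_min,
                         support = as.integer(rowSums(!is.na(mat))))
  structure(list(peptides = peptides, samples = sids, intensities = mat),
            class = "peptide_matrix")
}

#' @rdname read_matrix_tsv
#' @param matrix A `peptide_matrix`.
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "peptide_matrix"))
  df <- cbind(matrix$peptides[, c("peptide_id", "mass_da", "time_min")],
              as.data.frame(matrix$intensities))
  .write_tsv(df, path)
}

#' Read / write a classifier model JSON
#'
#' Schema: `{"panel": [{"peptide_id", "mass_da", "time_min", "weight"}],
#' "offset", "cutoff", "missing_policy"}`.
#'
#' @param path File path.
#' @return `read_model`: a `classifier_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_model: file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("panel", "offset", "cutoff", "missing_policy")) {
    if (is.null(obj[[f]])) stop(sprintf("read_model: missing field '%s'", f))
  }
  classifier_model(as.data.frame(obj$panel), offset = obj$offset,
                   cutoff = obj$cutoff, missing_policy = obj$missing_policy)
}

#' @rdname read_model
#' @param model A `classifier_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "classifier_model"))
  jsonlite::write_json(
    list(panel = model$panel, offset = model$offset, cutoff = model$cutoff,
         missing_policy = model$missing_policy),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a run configuration JSON
#'
#' The JSON holds any subset of [synthetic_config()] fields plus the
#' pipeline tolerances; unknown fields are rejected.
#'
#' @param path File path.
#' @return `read_config`: a validated `synthetic_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_config: file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(synthetic_config))
  bad <- setdiff(names(obj), known)
  if (length(bad) > 0L) {
    stop(sprintf("read_config: unknown field(s): %s",
                 paste(bad, collapse = ", ")))
  }
  do.call(synthetic_config, obj)
}

#' @rdname read_config
#' @param config A `synthetic_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
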