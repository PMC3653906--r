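#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC of a score against a binary label.
#'
#' @param scores Numeric vector of scores (higher = more positive-like).
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return AUROC in `[0, 1]`; `NA` if either class is empty.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ppm deviation between two masses, relative to the smaller of the pair.
.ppm_dev <- function(m1, m2) {
  abs(m1 - m2) / pmin(m1, m2) * 1e6
}

# ppm deviation relative to a stated reference mass.
.ppm_dev_ref <- function(m, ref) {
  abs(m - ref) / ref * 1e6
}

.check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.check_numeric_cols <- function(df, cols, what) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      bad <- suppressWarnings(as.numeric(as.character(v)))
      nb <- which(is.na(bad) & !is.na(v) & as.character(v) != "")
      if (length(nb) > 0L) {
        stop(sprintf("%s: non-numeric value in column '%s' at line %d",
                     what, cl, nb[1L] + 1L), call. = FALSE)
      }
      df[[cl]] <- bad
    }
  }
  df
}
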