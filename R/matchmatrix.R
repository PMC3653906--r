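#' Assemble a consensus peptide matrix across samples
#'
#' Processes samples in input order. Each feature joins the nearest
#' existing consensus peptide (ppm deviation relative to the current
#' consensus mass, strictly below `ppm`; time difference at most `dt`) or
#' founds a new consensus peptide. Within a sample, at most one feature may
#' join a given consensus peptide: features are assigned in ascending order
#' of their ppm deviation, and a feature whose target is already taken
#' founds a new peptide. Consensus mass is an intensity-weighted running
#' mean; consensus time an unweighted running mean.
#'
#' @param sample_features Named list of per-sample feature `data.frame`s
#'   (columns `mass_da`, `time_min`, `intensity`), already calibrated and
#'   normalized. Names are the sample ids.
#' @param ppm Cross-sample mass tolerance in ppm (default 50).
#' @param dt Cross-sample migration-time tolerance in minutes (default 0.35).
#' @return A `peptide_matrix`: list with `peptides` (`peptide_id`,
#'   `mass_da`, `time_min`, `support`), `samples`, and `intensities`
#'   (peptides x samples matrix, `NA` = not detected).
#' @export
build_matrix <- function(sample_features, ppm = 50, dt = 0.35) {
  stopifnot(is.list(sample_features))
  sids <- names(sample_features)
  if (is.null(sids) || any(sids == "")) stop("sample_features must be named")
  if (anyDuplicated(sids)) stop("duplicate sample ids")
  n_s <- length(sids)

  cap <- max(64L, sum(vapply(sample_features, nrow, 1L)))
  cmass <- numeric(cap)    # running intensity-weighted mean mass
  cwsum <- numeric(cap)    # running intensity weight sum
  ctsum <- numeric(cap)    # running time sum
  cn <- integer(cap)       # running member count
  n_pep <- 0L
  cells <- vector("list", n_s)

  for (si in seq_len(n_s)) {
    fx <- sample_features[[si]]
    .check_columns(fx, c("mass_da", "time_min", "intensity"), "build_matrix")
    nf <- nrow(fx)
    if (nf == 0L) { cells[[si]] <- integer(0); next }

    target <- integer(nf)    # consensus index or 0 (found new)
    best_ppm <- rep(Inf, nf)
    if (n_pep > 0L) {
      cm <- cmass[seq_len(n_pep)]
      ct <- ctsum[seq_len(n_pep)] / cn[seq_len(n_pep)]
      for (i in seq_len(nf)) {
        dp <- abs(fx$mass_da[i] - cm) / cm * 1e6
        ok <- which(dp < ppm & abs(fx$time_min[i] - ct) <= dt)
        if (length(ok) > 0L) {
          j <- ok[which.min(dp[ok])]
          target[i] <- j
          best_ppm[i] <- dp[j]
        }
      }
    }
    taken <- logical(n_pep)
    assign_to <- integer(nf)
    for (i in order(best_ppm)) {
      j <- target[i]
      if (j > 0L && !taken[j]) {
        taken[j] <- TRUE
        assign_to[i] <- j
      } else {
        n_pep <- n_pep + 1L
        if (n_pep > cap) {  # grow
          cap <- cap * 2L
          length(cmass) <- cap; length(cwsum) <- cap
          length(ctsum) <- cap; length(cn) <- cap
        }
        cmass[n_pep] <- 0; cwsum[n_pep] <- 0
        ctsum[n_pep] <- 0; cn[n_pep] <- 0L
        assign_to[i] <- n_pep
      }
    }
    for (i in seq_len(nf)) {
      j <- assign_to[i]
      w <- fx$intensity[i]
      if (w <= 0) w <- .Machine$double.eps
      cmass[j] <- (cmass[j] * cwsum[j] + fx$mass_da[i] * w) / (cwsum[j] + w)
      cwsum[j] <- cwsum[j] + w
      ctsum[j] <- ctsum[j] + fx$time_min[i]
      cn[j] <- cn[j] + 1L
    }
    cells[[si]] <- cbind(pep = assign_to, intensity = fx$intensity)
  }

  ids <- sprintf("pep%05d", seq_len(n_pep))
  mat <- matrix(NA_real_, nrow = n_pep, ncol = n_s,
                dimnames = list(ids, sids))
  for (si in seq_len(n_s)) {
    cl <- cells[[si]]
    if (length(cl) > 0L) mat[cl[, "pep"], si] <- cl[, "intensity"]
  }
  peptides <- data.frame(peptide_id = ids,
                         mass_da = cmass[seq_len(n_pep)],
                         time_min = ctsum[seq_len(n_pep)] / cn[seq_len(n_pep)],
                         support = as.integer(rowSums(!is.na(mat))))
  structure(list(peptides = peptides, samples = sids, intensities = mat),
            class = "peptide_matrix")
}

#' @export
print.peptide_matrix <- function(x, ...) {
  cat(sprintf("peptide_matrix: %d consensus peptides x %d samples (%.1f%% cells present)\n",
              nrow(x$peptides), length(x$samples),
              100 * mean(!is.na(x$intensities))))
  invisible(x)
}

#' Filter consensus peptides by detection frequency
#'
#' Keeps the peptides detected in strictly more than `min_frac` of the
#' samples (the study convention "present in >50% of the samples" with the
#' default `min_frac = 0.5`).
#'
#' @param matrix A `peptide_matrix`.
#' @param min_frac Detection fraction; rows with
#'   `support / n_samples > min_frac` are kept. Default 0.5.
#' @return The filtered `peptide_matrix`.
#' @export
presence_filter <- function(matrix, min_frac = 0.5) {
  stopifnot(inherits(matrix, "peptide_matrix"), min_frac >= 0, min_frac < 1)
  n <- length(matrix$samples)
  keep <- matrix$peptides$support / n > min_frac
  subset_matrix(matrix, keep)
}

#' Subset a peptide matrix by row
#'
#' @param matrix A `peptide_matrix`.
#' @param keep Logical or integer row index.
#' @return The row-subset `peptide_matrix`.
#' @export
subset_matrix <- function(matrix, keep) {
  structure(list(peptides = matrix$peptides[keep, , drop = FALSE],
                 samples = matrix$samples,
                 intensities = matrix$intensities[keep, , drop = FALSE]),
            class = "peptide_matrix")
}
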