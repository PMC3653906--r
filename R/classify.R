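#' Construct a multi-peptide linear classifier model
#'
#' The model scores a sample as `offset + sum_i w_i * log10(1 + x_i)` over
#' its peptide panel, where `x_i` is the matched (normalized) intensity of
#' panel peptide `i`, or the missing-policy value when the peptide is not
#' detected. Samples with score strictly above `cutoff` fall on the
#' high-risk side; a score exactly at the cutoff is low-risk.
#'
#' @param panel `data.frame` with `peptide_id`, `mass_da`, `time_min`,
#'   `weight`.
#' @param offset Scalar added to the weighted sum.
#' @param cutoff Prognostic score cutoff (default 0.55).
#' @param missing_policy `"zero"` (undetected peptide contributes
#'   `log10(1 + 0) = 0`; absence is informative under detection-limit
#'   censoring) or `"min_observed"` (undetected contributes the minimum
#'   observed transformed intensity of that sample).
#' @return A `classifier_model` object.
#' @export
classifier_model <- function(panel, offset = 0, cutoff = 0.55,
                             missing_policy = c("zero", "min_observed")) {
  missing_policy <- match.arg(missing_policy)
  .check_columns(panel, c("peptide_id", "mass_da", "time_min", "weight"),
                 "classifier_model")
  if (nrow(panel) == 0L) stop("classifier panel is empty")
  if (anyDuplicated(panel$peptide_id)) stop("duplicate panel peptide ids")
  stopifnot(is.finite(offset), is.finite(cutoff))
  structure(list(panel = panel, offset = offset, cutoff = cutoff,
                 missing_policy = missing_policy),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("classifier_model: %d peptides, offset %.4g, cutoff %.4g, missing = %s\n",
              nrow(x$panel), x$offset, x$cutoff, x$missing_policy))
  invisible(x)
}

# Match model panel peptides to matrix rows, one-to-one, greedy by ppm.
.match_panel_rows <- function(pm, model, ppm, dt) {
  feats <- data.frame(mass_da = pm$peptides$mass_da,
                      time_min = pm$peptides$time_min)
  pairs <- match_to_panel(feats, model$panel, ppm = ppm, dt = dt)
  # row index of the matrix for each panel entry (NA if unmatched)
  row_of <- rep(NA_integer_, nrow(model$panel))
  row_of[pairs$panel_idx] <- pairs$feature_idx
  row_of
}

#' Score samples of a peptide matrix with a classifier model
#'
#' Panel peptides are matched to the matrix's consensus peptides by
#' mass/time tolerance, then each sample is scored as
#' `offset + sum_i w_i * log10(1 + x_i)`.
#'
#' @param matrix A `peptide_matrix` of normalized intensities.
#' @param model A `classifier_model`.
#' @param ppm,dt Panel-matching tolerances (defaults 50 ppm, 0.35 min).
#' @return `data.frame` with `sample_id`, `score`, `n_panel_detected`,
#'   `above_cutoff`.
#' @export
score_matrix <- function(matrix, model, ppm = 50, dt = 0.35) {
  stopifnot(inherits(matrix, "peptide_matrix"),
            inherits(model, "classifier_model"))
  row_of <- .match_panel_rows(matrix, model, ppm, dt)
  w <- model$panel$weight
  n_samp <- length(matrix$samples)
  scores <- numeric(n_samp)
  ndet <- integer(n_samp)
  for (j in seq_len(n_samp)) {
    x <- rep(NA_real_, length(w))
    ok <- !is.na(row_of)
    x[ok] <- matrix$intensities[row_of[ok], j]
    det <- !is.na(x)
    lt <- log10(1 + ifelse(det, x, 0))
    if (model$missing_policy == "min_observed") {
      fill <- if (any(det)) min(lt[det]) else 0
      lt[!det] <- fill
    } else {
      lt[!det] <- 0
    }
    scores[j] <- model$offset + sum(w * lt)
    ndet[j] <- sum(det)
  }
  data.frame(sample_id = matrix$samples, score = scores,
             n_panel_detected = ndet,
             above_cutoff = scores > model$cutoff)
}

#' Score a single sample's feature list
#'
#' Wraps the feature list as a one-sample matrix and calls
#' [score_matrix()].
#'
#' @param features Calibrated, normalized feature `data.frame`.
#' @param model A `classifier_model`.
#' @param sample_id Sample id for the result row.
#' @param ppm,dt Panel-matching tolerances.
#' @return One-row score `data.frame` (see [score_matrix()]).
#' @export
score_sample <- function(features, model, sample_id = "sample",
                         ppm = 50, dt = 0.35) {
  pm <- build_matrix(setNames(list(features), sample_id), ppm = ppm, dt = dt)
  score_matrix(pm, model, ppm = ppm, dt = dt)
}

#' Train a regularized linear discriminant classifier
#'
#' Fits a ridge-regularized two-class linear discriminant on
#' `log10(1 + intensity)` (missing cells filled per `missing_policy`):
#' `w = (S + lambda I)^{-1} (mu_1 - mu_0)` with `S` the pooled within-class
#' covariance, offset `-w . (mu_1 + mu_0) / 2`, so the signed discriminant
#' is positive on the class-1 side; the cutoff is 0. Exists to exercise the
#' classifier framework on synthetic cohorts; it does not reproduce any
#' published weight vector.
#'
#' @param matrix A presence-filtered `peptide_matrix`.
#' @param labels Binary vector (0/1 or logical), one per sample.
#' @param regularization Ridge penalty `lambda` > 0 (default 1).
#' @param missing_policy Missing-cell fill for training and scoring.
#' @return A `classifier_model` whose panel is the matrix's peptides.
#' @export
train_model <- function(matrix, labels, regularization = 1,
                        missing_policy = c("zero", "min_observed")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(matrix, "peptide_matrix"), regularization > 0)
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary")
  if (length(labels) != length(matrix$samples)) {
    stop("one label per sample required")
  }
  if (min(table(factor(labels, levels = c(0L, 1L)))) < 2L) {
    stop("need at least 2 samples per class")
  }
  X <- t(matrix$intensities)
  X[is.na(X)] <- 0
  X <- log10(1 + X)
  mu0 <- colMeans(X[labels == 0L, , drop = FALSE])
  mu1 <- colMeans(X[labels == 1L, , drop = FALSE])
  C0 <- crossprod(scale(X[labels == 0L, , drop = FALSE], center = mu0,
                        scale = FALSE))
  C1 <- crossprod(scale(X[labels == 1L, , drop = FALSE], center = mu1,
                        scale = FALSE))
  S <- (C0 + C1) / (length(labels) - 2L)
  w <- solve(S + regularization * diag(ncol(X)), mu1 - mu0)
  offset <- -sum(w * (mu1 + mu0) / 2)
  panel <- data.frame(peptide_id = matrix$peptides$peptide_id,
                      mass_da = matrix$peptides$mass_da,
                      time_min = matrix$peptides$time_min,
                      weight = as.numeric(w))
  classifier_model(panel, offset = offset, cutoff = 0,
                   missing_policy = missing_policy)
}

#' Prognostic 2x2 table for a score cutoff
#'
#' Cross-tabulates endpoint events against the score cutoff and derives
#' sensitivity, specificity and negative predictive value (NPV =
#' probability of no event given score at or below the cutoff). Samples
#' with unknown outcome are excluded and counted.
#'
#' @param scores Score `data.frame` from [score_matrix()] (needs
#'   `sample_id`, `score`).
#' @param events Named binary vector (or vector aligned with a
#'   `sample_id` attribute via names) of outcomes; `NA` = unknown.
#' @param cutoff Score cutoff; strictly greater = high-risk side.
#' @return A list of counts (`event_above`, `noevent_above`,
#'   `event_below`, `noevent_below`, `n_known`, `n_unknown`) and rates
#'   (`sensitivity`, `specificity`, `npv`); undefined rates are `NaN`.
#' @export
prognostic_table <- function(scores, events, cutoff = 0.55) {
  .check_columns(scores, c("sample_id", "score"), "prognostic_table")
  if (is.null(names(events))) {
    if (length(events) != nrow(scores)) {
      stop("events must be named by sample id or aligned with scores")
    }
    names(events) <- scores$sample_id
  }
  common <- intersect(scores$sample_id, names(events))
  if (length(common) == 0L) stop("no overlapping sample ids")
  ev <- events[match(scores$sample_id, names(events))]
  known <- !is.na(ev)
  ev <- as.logical(ev[known])
  hi <- scores$score[known] > cutoff
  a <- sum(ev & hi)      # events above cutoff
  b <- sum(!ev & hi)     # no-event above
  c_ <- sum(ev & !hi)    # events below
  d <- sum(!ev & !hi)    # no-event below
  list(event_above = a, noevent_above = b,
       event_below = c_, noevent_below = d,
       n_known = sum(known), n_unknown = sum(!known),
       sensitivity = if (a + c_ > 0) a / (a + c_) else NaN,
       specificity = if (b + d > 0) d / (b + d) else NaN,
       npv = if (c_ + d > 0) d / (c_ + d) else NaN)
}
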