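#' Match peptide features to a reference panel
#'
#' Pairs deconvoluted features with panel entries one-to-one. A pairing is
#' admissible when the mass deviation (ppm, relative to the panel mass) is
#' strictly below `ppm` and the migration-time difference is at most `dt`.
#' Assignment is greedy by ascending ppm deviation; when two features are
#' equidistant in ppm from one entry, the earlier-time feature wins.
#' Unmatched features and entries are omitted.
#'
#' @param features Feature `data.frame` with `mass_da`, `time_min`.
#' @param panel Panel `data.frame` with `peptide_id`, `mass_da`, `time_min`.
#' @param ppm Mass tolerance in ppm (default 50).
#' @param dt Time tolerance in minutes (default 0.35).
#' @return A `data.frame` of pairs: `feature_idx`, `panel_idx`,
#'   `peptide_id`, `ppm_dev`, `dt_dev`.
#' @export
match_to_panel <- function(features, panel, ppm = 50, dt = 0.35) {
  if (nrow(panel) == 0L) stop("reference panel is empty")
  .check_columns(features, c("mass_da", "time_min"), "match_to_panel")
  .check_columns(panel, c("peptide_id", "mass_da", "time_min"),
                 "match_to_panel")
  empty <- data.frame(feature_idx = integer(0), panel_idx = integer(0),
                      peptide_id = character(0), ppm_dev = numeric(0),
                      dt_dev = numeric(0))
  if (nrow(features) == 0L) return(empty)

  dppm <- abs(outer(features$mass_da, panel$mass_da, "-")) /
    rep(panel$mass_da, each = nrow(features)) * 1e6
  dtm <- abs(outer(features$time_min, panel$time_min, "-"))
  cand <- which(dppm < ppm & dtm <= dt, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)

  cdf <- data.frame(feature_idx = cand[, 1L], panel_idx = cand[, 2L],
                    ppm_dev = dppm[cand], dt_dev = dtm[cand])
  cdf <- cdf[order(cdf$ppm_dev, features$time_min[cdf$feature_idx]), ,
             drop = FALSE]
  f_used <- logical(nrow(features))
  p_used <- logical(nrow(panel))
  keep <- logical(nrow(cdf))
  for (i in seq_len(nrow(cdf))) {
    fi <- cdf$feature_idx[i]; pi <- cdf$panel_idx[i]
    if (!f_used[fi] && !p_used[pi]) {
      keep[i] <- TRUE
      f_used[fi] <- TRUE
      p_used[pi] <- TRUE
    }
  }
  out <- cdf[keep, , drop = FALSE]
  out$peptide_id <- as.character(panel$peptide_id[out$panel_idx])
  rownames(out) <- NULL
  out[, c("feature_idx", "panel_idx", "peptide_id", "ppm_dev", "dt_dev")]
}

# Build a monotone warp function observed -> canonical from lowess output,
# with linear extrapolation continuing the terminal segments.
.warp_fun <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  ux <- !duplicated(x)
  x <- x[ux]; y <- y[ux]
  y <- cummax(y)  # enforce monotone non-decreasing
  n <- length(x)
  if (n == 1L) {
    off <- y - x
    return(function(t) t + off)
  }
  s_lo <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  s_hi <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  function(t) {
    out <- approx(x, y, xout = t, rule = 2)$y
    lo <- t < x[1L]
    hi <- t > x[n]
    out[lo] <- y[1L] + s_lo * (t[lo] - x[1L])
    out[hi] <- y[n] + s_hi * (t[hi] - x[n])
    out
  }
}

#' Calibrate CE migration times against a reference panel
#'
#' Matches features to the reference panel, fits observed time -> canonical
#' time by locally weighted regression (tricube weights, two robustifying
#' iterations, span `span`), forces the fitted map monotone non-decreasing,
#' and applies it to *all* feature times. Extrapolation beyond the anchor
#' range continues the terminal local fits linearly. A sample passes QC when
#' every post-calibration anchor residual is below `max_residual` minutes.
#'
#' Anchor matching uses a deliberately wide time window (`anchor_dt`,
#' default 6 min): before calibration the observed times still carry the
#' run's drift, so the cross-sample tolerance of 0.35 min would miss the
#' very anchors needed to remove that drift. The 0.35 min rule applies
#' *after* calibration, as the QC bound.
#'
#' The default span 0.1 is chosen so that locally linear fits can follow
#' drift with kinks on the scale of a few minutes; wider spans over-smooth
#' such drift and leave residual structure above the QC bound. The span is
#' floored adaptively so each local window spans at least 6 anchors.
#'
#' @param features Feature `data.frame` (`mass_da`, `time_min`, ...).
#' @param panel Reference panel (`peptide_id`, `mass_da`, `time_min`).
#' @param span Locally weighted regression span in (0, 1] (default 0.1).
#' @param min_anchors Minimum panel matches required (default 10).
#' @param ppm Mass tolerance in ppm for anchor matching (default 50).
#' @param anchor_dt Pre-calibration anchor time window in minutes
#'   (default 6, wide enough for several minutes of run-to-run drift).
#' @param max_residual QC bound on post-calibration anchor deviation in
#'   minutes (default 0.35).
#' @return A list: `features` (times calibrated), `n_anchors`,
#'   `residual_sd`, `max_residual` (observed), `qc_pass`, and the warp
#'   function `warp`.
#' @export
calibrate_times <- function(features, panel, span = 0.1, min_anchors = 10,
                            ppm = 50, anchor_dt = 6, max_residual = 0.35) {
  stopifnot(span > 0, span <= 1)
  pairs <- match_to_panel(features, panel, ppm = ppm, dt = anchor_dt)
  if (nrow(pairs) < min_anchors) {
    stop(sprintf(
      "calibration failure: %d panel anchors found, %d required",
      nrow(pairs), min_anchors), call. = FALSE)
  }
  obs <- features$time_min[pairs$feature_idx]
  canon <- panel$time_min[pairs$panel_idx]
  span_used <- max(span, min(1, 6 / nrow(pairs)))
  # robustness iterations degenerate when the plain fit is already exact
  # (residual-based weights collapse), so only robustify if it is not
  fit <- lowess(obs, canon, f = span_used, iter = 0)
  res0 <- approx(fit$x, fit$y, xout = obs, rule = 2)$y - canon
  if (median(abs(res0)) > 1e-6) {
    fit <- lowess(obs, canon, f = span_used, iter = 2)
  }
  warp <- .warp_fun(fit$x, fit$y)
  out <- features
  out$time_min <- warp(features$time_min)
  resid <- warp(obs) - canon
  list(features = out,
       n_anchors = nrow(pairs),
       residual_sd = sd(resid),
       max_residual = max(abs(resid)),
       qc_pass = max(abs(resid)) < max_residual,
       warp = warp)
}

#' Normalize feature intensities to housekeeping peptides
#'
#' Detects the housekeeping peptides among the (calibrated) features by
#' mass/time tolerance matching and rescales every intensity by the median
#' over detected housekeeping peptides of reference-to-observed intensity
#' ratios. The median-of-ratios is robust to individual aberrant
#' housekeeping peptides and removes multiplicative urine-dilution and
#' analytical variance.
#'
#' @param features Calibrated feature `data.frame`.
#' @param hk Housekeeping panel: `peptide_id`, `mass_da`, `time_min`,
#'   `ref_intensity` (> 0).
#' @param ppm,dt Matching tolerances (defaults 50 ppm, 0.35 min).
#' @param min_hk Minimum housekeeping detections required (default 3).
#' @return A list: `features` (intensities scaled), `scale_factor`,
#'   `n_housekeeping` detected.
#' @export
normalize_intensities <- function(features, hk, ppm = 50, dt = 0.35,
                                  min_hk = 3) {
  .check_columns(hk, c("peptide_id", "mass_da", "time_min", "ref_intensity"),
                 "normalize_intensities")
  if (any(hk$ref_intensity <= 0)) stop("housekeeping ref_intensity must be > 0")
  pairs <- match_to_panel(features, hk, ppm = ppm, dt = dt)
  if (nrow(pairs) < min_hk) {
    stop(sprintf(
      "normalization failure: %d housekeeping peptides detected, %d required",
      nrow(pairs), min_hk), call. = FALSE)
  }
  ratios <- hk$ref_intensity[pairs$panel_idx] /
    features$intensity[pairs$feature_idx]
  s <- median(ratios)
  out <- features
  out$intensity <- features$intensity * s
  list(features = out, scale_factor = s, n_housekeeping = nrow(pairs))
}
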