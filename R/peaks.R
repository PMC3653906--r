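#' Construct a raw CE-MS signal table
#'
#' A raw signal is one detected mass-spectral peak: an m/z value with its
#' assigned charge, intensity, CE migration time, signal-to-noise ratio and
#' the number of consecutive spectra in which it was observed.
#'
#' @param mz m/z in Thomson (> proton mass).
#' @param charge Integer charge state (>= 1).
#' @param intensity Non-negative signal intensity (arbitrary units).
#' @param migration_time_min CE migration time in minutes.
#' @param snr Signal-to-noise ratio (>= 0).
#' @param n_spectra Count of consecutive spectra (>= 1).
#' @return A `data.frame` with one row per signal and the columns above.
#' @export
raw_signals <- function(mz, charge, intensity, migration_time_min,
                        snr, n_spectra) {
  df <- data.frame(mz = as.numeric(mz),
                   charge = as.integer(charge),
                   intensity = as.numeric(intensity),
                   migration_time_min = as.numeric(migration_time_min),
                   snr = as.numeric(snr),
                   n_spectra = as.integer(n_spectra))
  if (nrow(df) > 0L) {
    if (any(df$mz <= 0)) stop("mz must be positive")
    if (any(df$charge < 1L)) stop("charge must be >= 1")
    if (any(df$intensity < 0)) stop("intensity must be non-negative")
    if (any(df$snr < 0)) stop("snr must be non-negative")
    if (any(df$n_spectra < 1L)) stop("n_spectra must be >= 1")
  }
  df
}

#' Filter raw signals by charge, signal-to-noise and spectral persistence
#'
#' Keeps exactly the signals with charge strictly greater than
#' `min_charge_excl`, signal-to-noise at least `min_snr`, and at least
#' `min_spectra` consecutive spectra; input order is preserved. Defaults
#' implement the platform's standard acceptance rule (z > 1, S/N >= 4,
#' >= 3 consecutive spectra).
#'
#' @param signals Raw-signal `data.frame` (see [raw_signals()]).
#' @param min_charge_excl Exclusive lower bound on charge (default 1).
#' @param min_snr Inclusive lower bound on S/N (default 4).
#' @param min_spectra Inclusive lower bound on spectra count (default 3).
#' @return The filtered signal `data.frame`.
#' @export
filter_signals <- function(signals, min_charge_excl = 1, min_snr = 4,
                           min_spectra = 3) {
  stopifnot(min_charge_excl >= 0, min_snr >= 0, min_spectra >= 0)
  .check_columns(signals, c("mz", "charge", "intensity",
                            "migration_time_min", "snr", "n_spectra"),
                 "filter_signals")
  keep <- signals$charge > min_charge_excl &
    signals$snr >= min_snr &
    signals$n_spectra >= min_spectra
  out <- signals[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Neutral monoisotopic mass from m/z and charge
#'
#' `M = z * (mz - m_proton)` with the proton mass fixed at 1.007276 Da.
#'
#' @param mz m/z in Thomson; must exceed the proton mass.
#' @param z Integer charge (>= 1). Recycled against `mz`.
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(mz, z) {
  if (any(z < 1)) stop("charge z must be >= 1")
  if (any(mz <= .PROTON_MASS)) stop("mz must exceed the proton mass")
  z * (mz - .PROTON_MASS)
}

# Connected components of a small undirected adjacency matrix (logical).
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0L) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Deconvolute charge-state series into neutral-mass peptide features
#'
#' Signals representing the same molecule observed at different charge
#' states are merged into one feature. Two signals belong together when
#' their neutral masses agree within `mass_tol_ppm` (ppm computed relative
#' to the smaller mass of the pair) *and* their migration times agree within
#' `time_tol_min`; grouping is the transitive closure of that relation,
#' found by sorting on neutral mass, chaining mass-adjacent signals, and
#' splitting each chain into connected components under the joint
#' mass-and-time criterion. The feature mass is the intensity-weighted mean
#' of member masses, the feature time the intensity-weighted mean time, and
#' the feature intensity the sum of member intensities, so total intensity
#' is conserved.
#'
#' @param signals Filtered raw-signal `data.frame`.
#' @param mass_tol_ppm Mass agreement tolerance in ppm (default 25, the
#'   platform's stated monoisotopic mass accuracy).
#' @param time_tol_min Co-elution tolerance in minutes (default 0.1;
#'   deliberately tighter than the 0.35 min cross-sample tolerance because
#'   within-run co-migration is tighter).
#' @return A `data.frame` of peptide features: `mass_da`, `time_min`,
#'   `intensity`, `charges` (comma-separated charge states), `n_signals`.
#' @export
deconvolute <- function(signals, mass_tol_ppm = 25, time_tol_min = 0.1) {
  if (mass_tol_ppm < 0 || time_tol_min < 0) stop("tolerances must be non-negative")
  .check_columns(signals, c("mz", "charge", "intensity",
                            "migration_time_min"), "deconvolute")
  n <- nrow(signals)
  if (n == 0L) {
    return(data.frame(mass_da = numeric(0), time_min = numeric(0),
                      intensity = numeric(0), charges = character(0),
                      n_signals = integer(0)))
  }
  mass <- neutral_mass(signals$mz, signals$charge)
  tm <- signals$migration_time_min
  ord <- order(mass, tm)
  m_s <- mass[ord]

  # Single-linkage chains on mass alone: a superset of the true groups, so
  # component-finding inside each chain yields the exact transitive closure.
  if (n > 1L) {
    gap_ppm <- (m_s[-1L] - m_s[-n]) / m_s[-n] * 1e6
    chain <- cumsum(c(1L, as.integer(gap_ppm > mass_tol_ppm)))
  } else {
    chain <- 1L
  }

  groups <- integer(n)  # group id per position in `ord`
  next_id <- 0L
  for (ch in unique(chain)) {
    idx <- which(chain == ch)
    k <- length(idx)
    if (k == 1L) {
      next_id <- next_id + 1L
      groups[idx] <- next_id
      next
    }
    mm <- m_s[idx]
    tt <- tm[ord][idx]
    adj <- (abs(outer(mm, mm, "-")) / outer(mm, mm, pmin) * 1e6
            <= mass_tol_ppm) &
      (abs(outer(tt, tt, "-")) <= time_tol_min)
    comp <- .components(adj)
    groups[idx] <- next_id + comp
    next_id <- next_id + max(comp)
  }

  gid <- integer(n)
  gid[ord] <- groups
  w <- signals$intensity
  # guard zero-intensity groups: fall back to unweighted means
  agg <- lapply(split(seq_len(n), gid), function(ix) {
    wi <- w[ix]
    if (sum(wi) <= 0) wi <- rep(1, length(ix))
    data.frame(
      mass_da = sum(mass[ix] * wi) / sum(wi),
      time_min = sum(tm[ix] * wi) / sum(wi),
      intensity = sum(w[ix]),
      charges = paste(sort(unique(signals$charge[ix])), collapse = ","),
      n_signals = length(ix))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$mass_da, out$time_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}
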