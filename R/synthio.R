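#' Configuration for the synthetic CE-MS cohort generator
#'
#' Bundles every knob of the simulated study: cohort size, peptide panel
#' composition, effect sizes, and the nuisance processes (urine dilution,
#' migration-time drift, detection-limit censoring, measurement noise) that
#' the analysis pipeline is meant to remove.
#'
#' @param n_patients Cohort size (default 53).
#' @param seed Integer random seed (mandatory for generation).
#' @param n_marker_up Serum-protein-like marker peptides whose abundance
#'   rises with disease severity (default 30).
#' @param n_marker_down Collagen/uromodulin-like marker peptides whose
#'   abundance falls with severity (default 42).
#' @param n_housekeeping Housekeeping peptides with severity-independent
#'   abundance (default 29; must be >= 3).
#' @param n_reference Total reference-panel size including markers and
#'   housekeeping peptides (default 200, standing in for a full panel of
#'   1770).
#' @param n_noise_peptides Spurious sample-specific peptides per sample
#'   (default 30).
#' @param dilution_sd Log-scale SD of the per-sample urine dilution factor
#'   (default 0.5).
#' @param drift_amplitude SD in minutes of the per-run migration-time warp
#'   at its knots (default 0.5).
#' @param detection_limit Raw-intensity detection limit; peptides below it
#'   are censored out of the peak list (default 50).
#' @param effect_size Marker log-abundance (natural log) change per unit
#'   latent severity (default 1.5).
#' @param abundance_sd Log-scale SD of per-measurement peptide abundance
#'   noise (default 0.5).
#' @param hk_sd Log-scale SD of housekeeping-peptide abundance noise
#'   (default 0.15; housekeeping peptides are by definition low-variance).
#' @param mass_ppm_sd Per-signal mass measurement error SD in ppm
#'   (default 5).
#' @param time_sd Per-signal migration-time measurement error SD in
#'   minutes (default 0.02).
#' @param n_dialysis Number of dialysis patients, taken from the top of the
#'   severity range (default 6).
#' @param n_lost_followup Patients with unknown outcome (default 4).
#' @param event_intercept,event_slope Logistic-link coefficients of the
#'   endpoint probability on latent severity (defaults -9 and 13, giving
#'   roughly 16 expected events in a 53-patient cohort, concentrated at
#'   high severity).
#' @param event_min_severity Hard floor: patients below this severity never
#'   experience the endpoint (default 0 = pure logistic link).
#' @param followup_years Follow-up window in years (default 3.6).
#' @param junk_fraction Fraction of extra low-quality signals (z = 1 or
#'   sub-threshold S/N) added per sample to exercise signal filtering
#'   (default 0.15).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_patients = 53, seed = 1,
                             n_marker_up = 30, n_marker_down = 42,
                             n_housekeeping = 29, n_reference = 200,
                             n_noise_peptides = 30,
                             dilution_sd = 0.5, drift_amplitude = 0.5,
                             detection_limit = 50, effect_size = 1.5,
                             abundance_sd = 0.5, hk_sd = 0.15,
                             mass_ppm_sd = 5, time_sd = 0.02,
                             n_dialysis = 6, n_lost_followup = 4,
                             event_intercept = -9, event_slope = 13,
                             event_min_severity = 0,
                             followup_years = 3.6,
                             junk_fraction = 0.15) {
  cfg <- list(n_patients = as.integer(n_patients), seed = seed,
              n_marker_up = as.integer(n_marker_up),
              n_marker_down = as.integer(n_marker_down),
              n_housekeeping = as.integer(n_housekeeping),
              n_reference = as.integer(n_reference),
              n_noise_peptides = as.integer(n_noise_peptides),
              dilution_sd = dilution_sd, drift_amplitude = drift_amplitude,
              detection_limit = detection_limit, effect_size = effect_size,
              abundance_sd = abundance_sd, hk_sd = hk_sd,
              mass_ppm_sd = mass_ppm_sd, time_sd = time_sd,
              n_dialysis = as.integer(n_dialysis),
              n_lost_followup = as.integer(n_lost_followup),
              event_intercept = event_intercept, event_slope = event_slope,
              event_min_severity = event_min_severity,
              followup_years = followup_years,
              junk_fraction = junk_fraction)
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' Validate a synthetic generator configuration
#'
#' @param cfg A `synthetic_config` (or plain list with its fields).
#' @return The config, invisibly; errors name the offending field.
#' @export
validate_config <- function(cfg) {
  counts <- c("n_patients", "n_marker_up", "n_marker_down",
              "n_housekeeping", "n_reference", "n_noise_peptides",
              "n_dialysis", "n_lost_followup")
  for (f in counts) {
    if (is.null(cfg[[f]]) || is.na(cfg[[f]]) || cfg[[f]] < 0L) {
      stop(sprintf("config field '%s' must be a non-negative count", f))
    }
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop("config field 'seed' must be a single integer")
  }
  if (cfg$n_housekeeping < 3L) stop("n_housekeeping must be >= 3")
  if (cfg$detection_limit < 0) stop("detection_limit must be >= 0")
  if (cfg$dilution_sd < 0 || cfg$drift_amplitude < 0 ||
      cfg$abundance_sd < 0 || cfg$hk_sd < 0 || cfg$mass_ppm_sd < 0 ||
      cfg$time_sd < 0) {
    stop("noise SDs must be non-negative")
  }
  n_named <- cfg$n_marker_up + cfg$n_marker_down + cfg$n_housekeeping
  if (cfg$n_reference < n_named) {
    stop("n_reference must be >= n_marker_up + n_marker_down + n_housekeeping")
  }
  if (cfg$n_dialysis + cfg$n_lost_followup > cfg$n_patients &&
      cfg$n_patients > 0L) {
    stop("n_dialysis + n_lost_followup exceeds n_patients")
  }
  invisible(cfg)
}

#' Simulate a CKD cohort
#'
#' Draws latent disease severity uniformly on (0, 1) per patient and derives
#' the clinical covariates from it: true eGFR falls with severity
#' (`100 * (1 - s)^1.7`, spanning CKD stages I-V), serum creatinine is the
#' exact MDRD inverse of that eGFR given age and sex (so eGFR round-trips
#' through [mdrd_egfr()]), urine protein rises log-linearly with severity,
#' the `n_dialysis` most severe patients are flagged as dialysed (their
#' creatinine drawn separately, as creatinine under dialysis does not
#' reflect eGFR), and the combined death/dialysis-initiation endpoint is
#' Bernoulli with a logistic link on severity (optionally floored to zero
#' below `event_min_severity`). `n_lost_followup` randomly chosen patients
#' have unknown outcome.
#'
#' @param config A `synthetic_config`.
#' @return List with `patients` (clinical `data.frame`: `patient_id`,
#'   `age_years`, `sex`, `dialysis`, `creatinine_umol_l`,
#'   `urine_protein_g_per_g`, `event`, `followup_years`) and `truth`
#'   (latent `severity`, `egfr`, `event_prob` per patient).
#' @export
simulate_cohort <- function(config) {
  validate_config(config)
  n <- config$n_patients
  if (n == 0L) {
    return(list(
      patients = data.frame(patient_id = character(0),
                            age_years = numeric(0), sex = character(0),
                            dialysis = logical(0),
                            creatinine_umol_l = numeric(0),
                            urine_protein_g_per_g = numeric(0),
                            event = logical(0), followup_years = numeric(0)),
      truth = list(severity = numeric(0), egfr = numeric(0),
                   event_prob = numeric(0))))
  }
  set.seed(config$seed)
  ids <- sprintf("pt%03d", seq_len(n))
  severity <- runif(n)
  age <- pmax(20, pmin(95, rnorm(n, mean = 70, sd = 11.6)))
  sex <- ifelse(runif(n) < 33 / 53, "M", "F")
  egfr <- pmax(2, 100 * (1 - severity)^1.7)
  dialysis <- rank(-severity, ties.method = "first") <= config$n_dialysis
  creat <- mdrd_creatinine(egfr, age, sex)
  # creatinine under dialysis varies with the treatment, not with eGFR
  creat[dialysis] <- exp(rnorm(sum(dialysis), log(600), 0.2))
  uprot <- exp(-2.2 + 3.6 * severity + rnorm(n, 0, 0.3))
  p_event <- plogis(config$event_intercept + config$event_slope * severity)
  p_event[severity < config$event_min_severity] <- 0
  event <- rbinom(n, 1L, p_event) == 1L
  followup <- rep(config$followup_years, n)
  if (config$n_lost_followup > 0L) {
    lost <- sample.int(n, config$n_lost_followup)
    event[lost] <- NA
    followup[lost] <- runif(config$n_lost_followup, 0.2,
                            config$followup_years * 0.9)
  }
  patients <- data.frame(patient_id = ids, age_years = age, sex = sex,
                         dialysis = dialysis, creatinine_umol_l = creat,
                         urine_protein_g_per_g = uprot, event = event,
                         followup_years = followup)
  truth <- list(severity = setNames(severity, ids),
                egfr = setNames(egfr, ids),
                event_prob = setNames(p_event, ids))
  list(patients = patients, truth = truth)
}

# Monotone piecewise-linear per-run time warp over the canonical window;
# redrawn until strictly increasing (violations are rare at default
# amplitude). Returns knot positions and warped knot values.
.draw_warp <- function(amplitude, t_lo = 18, t_hi = 45, n_knots = 5L) {
  kx <- seq(t_lo, t_hi, length.out = n_knots)
  repeat {
    ky <- kx + rnorm(n_knots, 0, amplitude)
    if (all(diff(ky) > 0)) break
  }
  list(knots_x = kx, knots_y = ky)
}

.apply_warp <- function(t, warp) {
  n <- length(warp$knots_x)
  s_lo <- (warp$knots_y[2L] - warp$knots_y[1L]) /
    (warp$knots_x[2L] - warp$knots_x[1L])
  s_hi <- (warp$knots_y[n] - warp$knots_y[n - 1L]) /
    (warp$knots_x[n] - warp$knots_x[n - 1L])
  out <- approx(warp$knots_x, warp$knots_y, xout = t, rule = 2)$y
  lo <- t < warp$knots_x[1L]; hi <- t > warp$knots_x[n]
  out[lo] <- warp$knots_y[1L] + s_lo * (t[lo] - warp$knots_x[1L])
  out[hi] <- warp$knots_y[n] + s_hi * (t[hi] - warp$knots_x[n])
  out
}

# Charge states eligible for a neutral mass: z in 2..6 with m/z in the
# instrument window; fallback to the nearest-window z if none qualify.
.eligible_charges <- function(mass, mz_lo = 350, mz_hi = 2200) {
  z <- 2:6
  mz <- (mass + z * .PROTON_MASS) / z
  ok <- z[mz >= mz_lo & mz <= mz_hi]
  if (length(ok) == 0L) ok <- z[which.min(abs(log(mz / sqrt(mz_lo * mz_hi))))]
  ok
}

#' Simulate per-sample CE-MS peak lists
#'
#' Emits, for each patient, the raw signal list a CE-MS run would yield for
#' the cohort's peptide panel: true lognormal abundances (markers shifted
#' by `effect_size * severity` on the log scale in their planted
#' direction), multiplied by a per-sample lognormal dilution factor,
#' censored below the detection limit, split over 1-3 charge states
#' (z in 2..6) at `m/z = (M + z * 1.007276) / z` with ppm-scale mass error,
#' migration times passed through a per-run monotone piecewise-linear warp
#' plus jitter, and topped up with sample-specific noise peptides and
#' filter-fodder junk signals (z = 1 or sub-threshold S/N).
#'
#' Also returns the reference and housekeeping panels, the marker
#' directory, the full ground truth (dilution factors, warps, true
#' abundance matrix) and the planted linear classifier whose weights are
#' `+c` for up-markers and `-c` for down-markers, with the offset chosen
#' analytically so the expected score crosses the 0.55 cutoff at severity
#' 0.6.
#'
#' @param patients Clinical table from [simulate_cohort()].
#' @param truth Truth list from [simulate_cohort()].
#' @param config The same `synthetic_config`.
#' @return List: `peaklists` (named list of raw-signal `data.frame`s),
#'   `reference_panel`, `housekeeping_panel`, `markers` (`peptide_id`,
#'   `direction` +1/-1), `model` (planted `classifier_model`), and `truth`
#'   (input truth extended with `dilution`, `warps`, `abundance` matrix
#'   peptides x patients, `panel`).
#' @export
simulate_peaklists <- function(patients, truth, config) {
  validate_config(config)
  if (is.null(truth$severity)) stop("truth$severity missing")
  n <- nrow(patients)
  set.seed(config$seed + 1L)

  n_up <- config$n_marker_up
  n_dn <- config$n_marker_down
  n_hk <- config$n_housekeeping
  n_ref <- config$n_reference
  pep_ids <- sprintf("ref%04d", seq_len(n_ref))
  role <- rep("filler", n_ref)
  if (n_up > 0L) role[seq_len(n_up)] <- "up"
  if (n_dn > 0L) role[n_up + seq_len(n_dn)] <- "down"
  if (n_hk > 0L) role[n_up + n_dn + seq_len(n_hk)] <- "housekeeping"
  dir <- ifelse(role == "up", 1, ifelse(role == "down", -1, 0))

  # panel invariant: masses unique within 50 ppm at nearby times, so panel
  # identity is well defined at the matching tolerances (rejection sampling)
  mass <- numeric(n_ref)
  tmin <- numeric(n_ref)
  for (i in seq_len(n_ref)) {
    repeat {
      m <- exp(runif(1, log(800), log(12000)))
      tt <- runif(1, 18, 45)
      prev <- seq_len(i - 1L)
      clash <- any(abs(mass[prev] - m) / pmin(mass[prev], m) * 1e6 < 50 &
                     abs(tmin[prev] - tt) < 0.7)
      if (!clash) { mass[i] <- m; tmin[i] <- tt; break }
    }
  }
  mu <- runif(n_ref, log(200), log(5000))
  panel <- data.frame(peptide_id = pep_ids, mass_da = mass,
                      time_min = tmin, role = role, direction = dir,
                      mu_log = mu)
  reference_panel <- panel[, c("peptide_id", "mass_da", "time_min")]
  hk_idx <- which(role == "housekeeping")
  housekeeping_panel <- data.frame(
    peptide_id = pep_ids[hk_idx], mass_da = mass[hk_idx],
    time_min = tmin[hk_idx], ref_intensity = exp(mu[hk_idx]))
  markers <- data.frame(peptide_id = pep_ids[dir != 0],
                        direction = dir[dir != 0])

  sev <- truth$severity[patients$patient_id]
  sdv <- ifelse(role == "housekeeping", config$hk_sd, config$abundance_sd)
  # true abundance matrix: peptides x patients
  logA <- outer(mu, rep(1, n)) +
    outer(dir * config$effect_size, sev) +
    base::matrix(rnorm(n_ref * n, 0, rep(sdv, n)), nrow = n_ref)
  A <- exp(logA)
  dimnames(A) <- list(pep_ids, patients$patient_id)

  dilution <- setNames(exp(rnorm(n, 0, config$dilution_sd)),
                       patients$patient_id)
  warps <- lapply(seq_len(n), function(i) .draw_warp(config$drift_amplitude))
  names(warps) <- patients$patient_id

  # intensity split over up to 3 charge states
  split_w <- c(0.6, 0.25, 0.15)

  peaklists <- vector("list", n)
  for (j in seq_len(n)) {
    raw_int <- A[, j] * dilution[j]
    det <- which(raw_int >= config$detection_limit)
    rows <- vector("list", length(det))
    for (ii in seq_along(det)) {
      i <- det[ii]
      zs <- .eligible_charges(mass[i])
      k <- min(3L, length(zs))
      zs <- zs[seq_len(k)]
      w <- split_w[seq_len(k)] / sum(split_w[seq_len(k)])
      m_err <- mass[i] * (1 + rnorm(k, 0, config$mass_ppm_sd) / 1e6)
      t_obs <- .apply_warp(rep(tmin[i], k), warps[[j]]) +
        rnorm(k, 0, config$time_sd)
      rows[[ii]] <- data.frame(
        mz = (m_err + zs * .PROTON_MASS) / zs,
        charge = zs,
        intensity = raw_int[i] * w,
        migration_time_min = t_obs,
        snr = 4 + rexp(k, 1 / 15),
        n_spectra = 3L + rpois(k, 4))
    }
    sig <- if (length(rows) > 0L) do.call(rbind, rows) else
      raw_signals(numeric(0), integer(0), numeric(0), numeric(0),
                  numeric(0), integer(0))
    # sample-specific spurious peptides (survive filtering, support 1)
    if (config$n_noise_peptides > 0L) {
      nn <- config$n_noise_peptides
      nm <- exp(runif(nn, log(800), log(12000)))
      nz <- vapply(nm, function(m) .eligible_charges(m)[1L], 1L)
      noise <- data.frame(
        mz = (nm + nz * .PROTON_MASS) / nz,
        charge = nz,
        intensity = exp(runif(nn, log(config$detection_limit + 1), log(2000))),
        migration_time_min = runif(nn, 18, 45),
        snr = 4 + rexp(nn, 1 / 15),
        n_spectra = 3L + rpois(nn, 4))
      sig <- rbind(sig, noise)
    }
    # junk signals the quality filter must remove
    n_junk <- round(config$junk_fraction * nrow(sig))
    if (n_junk > 0L) {
      jm <- exp(runif(n_junk, log(400), log(6000)))
      z1 <- rep_len(c(TRUE, FALSE), n_junk)  # alternate z=1 / low-S/N
      junk <- data.frame(
        mz = ifelse(z1, jm + .PROTON_MASS, (jm + 2 * .PROTON_MASS) / 2),
        charge = ifelse(z1, 1L, 2L),
        intensity = exp(runif(n_junk, log(50), log(1000))),
        migration_time_min = runif(n_junk, 18, 45),
        snr = ifelse(z1, 4 + rexp(n_junk, 1 / 15), runif(n_junk, 0.2, 3.9)),
        n_spectra = 3L + rpois(n_junk, 2))
      sig <- rbind(sig, junk)
    }
    rownames(sig) <- NULL
    peaklists[[j]] <- sig
  }
  names(peaklists) <- patients$patient_id

  model <- .planted_model(panel, config)

  truth$dilution <- dilution
  truth$warps <- warps
  truth$abundance <- A
  truth$panel <- panel
  list(peaklists = peaklists, reference_panel = reference_panel,
       housekeeping_panel = housekeeping_panel, markers = markers,
       model = model, truth = truth)
}

# Planted classifier: weights +/- c on the markers; offset fixed so the
# expected score (approximating E[log10 x] by mu/ln10) equals the cutoff
# at severity 0.6, with the score spanning ~1.4 units over severity 0..1.
.planted_model <- function(panel, config, cutoff = 0.55, s0 = 0.6,
                           span_units = 1.4) {
  mk <- panel$direction != 0
  n_mk <- sum(mk)
  if (n_mk == 0L) stop("planted model needs at least one marker peptide")
  cc <- span_units * log(10) / (config$effect_size * n_mk)
  w <- panel$direction[mk] * cc
  slope <- cc * config$effect_size * n_mk / log(10)
  base_term <- sum(w * panel$mu_log[mk]) / log(10)
  offset <- cutoff - base_term - slope * s0
  classifier_model(
    data.frame(peptide_id = panel$peptide_id[mk],
               mass_da = panel$mass_da[mk],
               time_min = panel$time_min[mk],
               weight = w),
    offset = offset, cutoff = cutoff, missing_policy = "zero")
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper running [simulate_cohort()] then
#' [simulate_peaklists()].
#'
#' @param config A `synthetic_config`.
#' @return The [simulate_peaklists()] result with `patients` added.
#' @export
simulate_study <- function(config) {
  coh <- simulate_cohort(config)
  out <- simulate_peaklists(coh$patients, coh$truth, config)
  out$patients <- coh$patients
  out
}
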