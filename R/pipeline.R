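#' Preprocess one sample's raw peak list into calibrated, normalized
#' features
#'
#' Runs the per-sample stages in order: quality filtering
#' ([filter_signals()]), charge-state deconvolution ([deconvolute()]),
#' migration-time calibration against the reference panel
#' ([calibrate_times()]) and housekeeping normalization
#' ([normalize_intensities()]).
#'
#' @param signals Raw-signal `data.frame`.
#' @param reference_panel Reference panel (`peptide_id`, `mass_da`,
#'   `time_min`).
#' @param housekeeping_panel Housekeeping panel (adds `ref_intensity`).
#' @param sample_id Sample id used in error messages.
#' @param min_snr,min_spectra,min_charge_excl Signal filters.
#' @param deconv_ppm,deconv_dt Deconvolution tolerances.
#' @param ppm,dt Panel-matching tolerances.
#' @param span,min_anchors,anchor_dt Calibration parameters.
#' @param min_hk Minimum housekeeping detections.
#' @return List: `features` (calibrated, normalized), `qc` (anchor count,
#'   residual SD, max residual, calibration QC flag, scale factor,
#'   housekeeping count, signal counts).
#' @export
preprocess_sample <- function(signals, reference_panel, housekeeping_panel,
                              sample_id = "sample",
                              min_snr = 4, min_spectra = 3,
                              min_charge_excl = 1,
                              deconv_ppm = 25, deconv_dt = 0.1,
                              ppm = 50, dt = 0.35,
                              span = 0.1, min_anchors = 10, anchor_dt = 6,
                              min_hk = 3) {
  filt <- filter_signals(signals, min_charge_excl = min_charge_excl,
                         min_snr = min_snr, min_spectra = min_spectra)
  feats <- deconvolute(filt, mass_tol_ppm = deconv_ppm,
                       time_tol_min = deconv_dt)
  cal <- tryCatch(
    calibrate_times(feats, reference_panel, span = span,
                    min_anchors = min_anchors, ppm = ppm,
                    anchor_dt = anchor_dt),
    error = function(e) stop(sprintf("sample %s: %s", sample_id,
                                     conditionMessage(e)), call. = FALSE))
  norm <- tryCatch(
    normalize_intensities(cal$features, housekeeping_panel, ppm = ppm,
                          dt = dt, min_hk = min_hk),
    error = function(e) stop(sprintf("sample %s: %s", sample_id,
                                     conditionMessage(e)), call. = FALSE))
  list(features = norm$features,
       qc = list(sample_id = sample_id,
                 n_signals = nrow(signals), n_filtered = nrow(filt),
                 n_features = nrow(feats),
                 n_anchors = cal$n_anchors,
                 residual_sd = cal$residual_sd,
                 max_residual = cal$max_residual,
                 calibration_qc_pass = cal$qc_pass,
                 scale_factor = norm$scale_factor,
                 n_housekeeping = norm$n_housekeeping))
}

#' Run the full synthetic-study pipeline
#'
#' Generates a synthetic cohort with its per-sample CE-MS peak lists, then
#' runs every analysis stage: per-sample preprocessing, cross-sample
#' consensus matching, presence filtering, classifier scoring with the
#' planted model, and the cohort statistics (eGFR, stage groups,
#' score-eGFR and score-proteinuria correlations, unbalanced one-way F,
#' prognostic table at the cutoff, patient clustering, per-peptide eGFR
#' correlations, monotone-peptide selection).
#'
#' @param config A `synthetic_config` (its `seed` drives all randomness).
#' @param out_dir Optional directory; when given, the clinical table,
#'   panels, matrix, scores, model and a JSON report are written there.
#' @param k_clusters Clusters for the patient dendrogram cut (default 4).
#' @param presence_min_frac Presence-filter threshold (default 0.5).
#' @return A report list: `config`, `patients`, `truth`, `matrix`
#'   (presence-filtered), `matrix_full`, `scores`, `qc`, and `stats`
#'   (the [analyze_cohort_table()] output plus clustering and
#'   monotone-peptide results).
#' @export
run_pipeline <- function(config = synthetic_config(), out_dir = NULL,
                         k_clusters = 4, presence_min_frac = 0.5) {
  study <- simulate_study(config)
  patients <- study$patients

  processed <- lapply(patients$patient_id, function(pid) {
    preprocess_sample(study$peaklists[[pid]], study$reference_panel,
                      study$housekeeping_panel, sample_id = pid)
  })
  names(processed) <- patients$patient_id
  feats <- lapply(processed, `[[`, "features")
  qc <- lapply(processed, `[[`, "qc")

  pm_full <- build_matrix(feats)
  pm <- presence_filter(pm_full, min_frac = presence_min_frac)

  scores <- score_matrix(pm, study$model)
  clin <- patients
  clin$score <- scores$score[match(clin$patient_id, scores$sample_id)]

  stats <- analyze_cohort_table(clin, cutoff = study$model$cutoff)
  clus <- cluster_patients(pm, k = min(k_clusters, length(pm$samples)))
  stats$clusters <- clus$assignments
  stats$monotone <- monotone_peptides(pm_full, stats$stage_group,
                                      min_frac = presence_min_frac)
  stats$per_peptide <- per_peptide_egfr_correlation(pm, stats$egfr)

  report <- list(config = config, patients = clin, truth = study$truth,
                 model = study$model, matrix = pm, matrix_full = pm_full,
                 scores = scores, qc = qc, stats = stats)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_clinical(patients, file.path(out_dir, "clinical.tsv"))
    write_panel(study$reference_panel, file.path(out_dir, "reference_panel.tsv"))
    write_panel(study$housekeeping_panel,
                file.path(out_dir, "housekeeping_panel.tsv"))
    write_matrix_tsv(pm, file.path(out_dir, "matrix.tsv"))
    write_model(study$model, file.path(out_dir, "model.json"))
    .write_tsv(scores, file.path(out_dir, "scores.tsv"))
    jsonlite::write_json(
      list(config = unclass(config),
           qc = qc,
           stats = list(
             score_egfr_pearson = stats$score_egfr_pearson,
             score_egfr_line = stats$score_egfr_line,
             score_uprotein_spearman = stats$score_uprotein_spearman,
             stage_glm_f = stats$stage_glm_f,
             mean_creatinine_umol_l = stats$mean_creatinine_umol_l,
             prognostic = stats$prognostic,
             lost_to_followup_pct = stats$lost_to_followup_pct,
             n_monotone = length(stats$monotone$selected),
             cluster_sizes = as.integer(table(stats$clusters)))),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}
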