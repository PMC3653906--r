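#' MDRD estimated glomerular filtration rate
#'
#' Simplified (abbreviated) four-variable MDRD equation with the original
#' coefficient 186:
#' `eGFR = 186 * (Scr_mgdl)^-1.154 * age^-0.203 * 0.742[female] * 1.210[black]`
#' where serum creatinine in umol/L is converted to mg/dL by dividing by
#' 88.4.
#'
#' @param creatinine_umol_l Serum creatinine in umol/L (> 0).
#' @param age_years Age in years (> 0).
#' @param sex `"M"` or `"F"` (recycled).
#' @param black Logical, Black-race coefficient applied when `TRUE`
#'   (default `FALSE`).
#' @return eGFR in mL/min/1.73 m^2.
#' @export
mdrd_egfr <- function(creatinine_umol_l, age_years, sex, black = FALSE) {
  if (any(creatinine_umol_l <= 0, na.rm = TRUE)) stop("creatinine must be > 0")
  if (any(age_years <= 0, na.rm = TRUE)) stop("age must be > 0")
  sex <- rep_len(as.character(sex), length(creatinine_umol_l))
  if (!all(sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  black <- rep_len(black, length(creatinine_umol_l))
  186 * (creatinine_umol_l / 88.4)^(-1.154) * age_years^(-0.203) *
    ifelse(sex == "F", 0.742, 1) * ifelse(black, 1.210, 1)
}

#' Invert the MDRD equation for serum creatinine
#'
#' Returns the creatinine (umol/L) that yields the given eGFR for a
#' patient's age/sex/race; exact inverse of [mdrd_egfr()].
#'
#' @inheritParams mdrd_egfr
#' @param egfr Target eGFR in mL/min/1.73 m^2 (> 0).
#' @return Serum creatinine in umol/L.
#' @export
mdrd_creatinine <- function(egfr, age_years, sex, black = FALSE) {
  if (any(egfr <= 0)) stop("egfr must be > 0")
  sex <- rep_len(as.character(sex), length(egfr))
  black <- rep_len(black, length(egfr))
  k <- 186 * age_years^(-0.203) * ifelse(sex == "F", 0.742, 1) *
    ifelse(black, 1.210, 1)
  88.4 * (egfr / k)^(-1 / 1.154)
}

#' Assign CKD stage groups from eGFR
#'
#' Four ordered bands with default cutpoints 60, 30, 15 (upper bound
#' inclusive): group 1 = eGFR > 60 (stages I-II), group 2 = 30 < eGFR <= 60
#' (stage III), group 3 = 15 < eGFR <= 30 (stage IV), group 4 = eGFR <= 15
#' (stage V).
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (>= 0; `NA` propagates).
#' @param cutpoints Strictly decreasing band boundaries (default
#'   `c(60, 30, 15)`).
#' @return Integer group index 1..(length(cutpoints) + 1).
#' @export
assign_stage_group <- function(egfr, cutpoints = c(60, 30, 15)) {
  if (any(diff(cutpoints) >= 0)) stop("cutpoints must be strictly decreasing")
  if (any(egfr < 0, na.rm = TRUE)) stop("egfr must be non-negative")
  g <- rep(1L, length(egfr))
  for (cp in cutpoints) g <- g + as.integer(egfr <= cp)
  g[is.na(egfr)] <- NA_integer_
  g
}

#' One-way fixed-effects F test for unbalanced groups
#'
#' General-linear-model analysis of a continuous response across groups of
#' unequal size: `F = (SSB / (k - 1)) / (SSW / (N - k))`, p from the F
#' distribution. Implemented through `lm`/`anova`.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor); pairs with `NA` in
#'   either are dropped.
#' @return `data.frame` with `kind = "glm_F"`, `value` (F), `df1`, `df2`,
#'   `n`, `p_value`.
#' @export
glm_f_unbalanced <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (length(values) - nlevels(groups) < 1L) {
    stop("need at least one group with >= 2 values")
  }
  a <- anova(lm(values ~ groups))
  data.frame(kind = "glm_F", value = a$`F value`[1L],
             df1 = a$Df[1L], df2 = a$Df[2L],
             n = length(values), p_value = a$`Pr(>F)`[1L])
}

#' Pearson or Spearman correlation with missing-pair handling
#'
#' Drops pairs with a missing member, counts them, and returns the
#' coefficient with a two-sided p-value. Spearman uses average ranks for
#' ties. A constant input yields a flagged result (`NA` coefficient,
#' `constant_input = TRUE`) rather than an error.
#'
#' @param x,y Paired numeric vectors.
#' @param method `"pearson"` or `"spearman"`.
#' @return `data.frame` with `kind`, `value`, `n`, `n_dropped`, `p_value`,
#'   `constant_input`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y)
  n_dropped <- sum(!keep)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  kind <- if (method == "pearson") "pearson_R" else "spearman_rho"
  if (sd(x) == 0 || sd(y) == 0) {
    return(data.frame(kind = kind, value = NA_real_, n = length(x),
                      n_dropped = n_dropped, p_value = NA_real_,
                      constant_input = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  data.frame(kind = kind, value = unname(ct$estimate), n = length(x),
             n_dropped = n_dropped, p_value = ct$p.value,
             constant_input = FALSE)
}

#' Ordinary least squares line fit
#'
#' @param x,y Paired numeric vectors, `n >= 3`, `x` not constant.
#' @return `data.frame` with `slope`, `intercept`, `r_squared`, `n`.
#' @export
fit_line <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0) stop("x is constant")
  fit <- lm(y ~ x)
  r2 <- if (sd(y) == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  data.frame(slope = unname(coef(fit)[2L]),
             intercept = unname(coef(fit)[1L]),
             r_squared = r2,
             n = length(x))
}

#' Cluster patients by their peptide profiles
#'
#' Agglomerative average-linkage (UPGMA) clustering of per-patient peptide
#' vectors under the Euclidean distance, cut into `k` clusters. Missing
#' matrix cells are zero-filled before the distance computation (absence
#' reflects sub-detection-limit abundance after normalization).
#'
#' @param matrix A `peptide_matrix`.
#' @param k Number of clusters (1 <= k <= number of samples).
#' @return List with `assignments` (named integer vector per sample) and
#'   `tree` (the `hclust` object; `NULL` when only one sample).
#' @export
cluster_patients <- function(matrix, k = 4) {
  stopifnot(inherits(matrix, "peptide_matrix"))
  n <- length(matrix$samples)
  if (k < 1 || k > n) stop("k must be between 1 and the number of samples")
  if (n == 1L) {
    return(list(assignments = setNames(1L, matrix$samples), tree = NULL))
  }
  X <- t(matrix$intensities)
  X[is.na(X)] <- 0
  tree <- hclust(dist(X, method = "euclidean"), method = "average")
  list(assignments = cutree(tree, k = k), tree = tree)
}

#' Compare clinical variables between the two largest clusters
#'
#' For each clinical variable, a Welch two-sample t test (parametric) and a
#' Wilcoxon rank-sum test (non-parametric), both two-sided, between the two
#' largest clusters; per-variable missing values are dropped.
#'
#' @param patients Clinical `data.frame` with a `patient_id` column.
#' @param assignments Named cluster assignment vector (names = patient ids).
#' @param variables Character vector of numeric column names to test.
#' @return `data.frame` per variable: cluster ids and sizes, means, `t`,
#'   `p_t` (Welch), `w`, `p_wilcoxon`.
#' @export
compare_clusters <- function(patients, assignments, variables) {
  .check_columns(patients, c("patient_id", variables), "compare_clusters")
  sizes <- sort(table(assignments), decreasing = TRUE)
  if (length(sizes) < 2L) stop("need at least two clusters")
  top <- names(sizes)[1:2]
  ids1 <- names(assignments)[assignments == top[1L]]
  ids2 <- names(assignments)[assignments == top[2L]]
  if (length(ids1) < 2L || length(ids2) < 2L) {
    stop("selected clusters must each have >= 2 patients")
  }
  rows <- lapply(variables, function(v) {
    x1 <- patients[[v]][patients$patient_id %in% ids1]
    x2 <- patients[[v]][patients$patient_id %in% ids2]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    tt <- tryCatch(t.test(x1, x2), error = function(e) NULL)
    wt <- suppressWarnings(wilcox.test(x1, x2, exact = FALSE))
    pw <- wt$p.value
    if (is.nan(pw)) pw <- 1  # all ties: no evidence of difference
    data.frame(variable = v,
               cluster_a = top[1L], cluster_b = top[2L],
               n_a = length(x1), n_b = length(x2),
               mean_a = mean(x1), mean_b = mean(x2),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p_t = if (is.null(tt)) NA_real_ else tt$p.value,
               w = unname(wt$statistic), p_wilcoxon = pw)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-peptide Spearman correlation with eGFR
#'
#' Correlates each consensus peptide's intensity profile (missing cells as
#' zero) against eGFR across non-dialysis patients. A negative correlation
#' (abundance rising as renal function falls) is labelled
#' `"increased-with-CKD"`; positive, `"decreased-with-CKD"`.
#' Benjamini-Hochberg adjusted p-values are reported alongside raw ones;
#' constant peptide rows are flagged and carry no direction.
#'
#' @param matrix A `peptide_matrix` whose samples are patient ids.
#' @param egfr Named eGFR vector (names = patient ids); patients with `NA`
#'   eGFR (e.g. on dialysis) are excluded.
#' @return `data.frame`: `peptide_id`, `rho`, `p_value`, `p_adjusted`
#'   (BH), `n`, `direction`, `constant`.
#' @export
per_peptide_egfr_correlation <- function(matrix, egfr) {
  stopifnot(inherits(matrix, "peptide_matrix"))
  if (is.null(names(egfr))) stop("egfr must be named by patient id")
  common <- intersect(matrix$samples, names(egfr)[!is.na(egfr)])
  if (length(common) < 3L) stop("need >= 3 patients with known eGFR")
  e <- egfr[common]
  X <- matrix$intensities[, common, drop = FALSE]
  X[is.na(X)] <- 0
  rows <- lapply(seq_len(nrow(X)), function(i) {
    xi <- X[i, ]
    if (sd(xi) == 0) {
      return(data.frame(peptide_id = matrix$peptides$peptide_id[i],
                        rho = NA_real_, p_value = NA_real_,
                        n = length(e), direction = NA_character_,
                        constant = TRUE))
    }
    ct <- suppressWarnings(cor.test(xi, e, method = "spearman",
                                    exact = FALSE))
    data.frame(peptide_id = matrix$peptides$peptide_id[i],
               rho = unname(ct$estimate), p_value = ct$p.value,
               n = length(e),
               direction = if (ct$estimate < 0) "increased-with-CKD"
                           else "decreased-with-CKD",
               constant = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out[, c("peptide_id", "rho", "p_value", "p_adjusted", "n",
          "direction", "constant")]
}

#' Select peptides varying monotonically across stage groups
#'
#' Applies the presence filter (strictly more than `min_frac` of samples),
#' computes per-stage-group mean signal (missing cells as zero), and keeps
#' peptides whose group-mean sequence across the ordered groups is
#' non-strictly monotone (non-increasing or non-decreasing; ties allowed).
#' The group-mean table is the heatmap substrate.
#'
#' @param matrix A `peptide_matrix`.
#' @param stage_groups Named integer group per sample (names = sample ids);
#'   samples with `NA` group are excluded.
#' @param min_frac Presence threshold (default 0.5).
#' @return List with `selected` (peptide ids), `group_means` (filtered
#'   peptides x groups matrix), `monotone` (logical per filtered peptide).
#' @export
monotone_peptides <- function(matrix, stage_groups, min_frac = 0.5) {
  stopifnot(inherits(matrix, "peptide_matrix"))
  if (is.null(names(stage_groups))) stop("stage_groups must be named")
  keep_s <- intersect(matrix$samples, names(stage_groups)[!is.na(stage_groups)])
  g <- stage_groups[keep_s]
  lv <- sort(unique(g))
  if (length(lv) < 2L) stop("need >= 2 non-empty stage groups")
  fm <- presence_filter(matrix, min_frac = min_frac)
  X <- fm$intensities[, keep_s, drop = FALSE]
  X[is.na(X)] <- 0
  gm <- sapply(lv, function(l) rowMeans(X[, g == l, drop = FALSE]))
  gm <- base::matrix(gm, nrow = nrow(X),
                     dimnames = list(fm$peptides$peptide_id,
                                     paste0("group", lv)))
  mono <- apply(gm, 1L, function(v) {
    d <- diff(v)
    all(d >= 0) || all(d <= 0)
  })
  list(selected = fm$peptides$peptide_id[mono],
       group_means = gm[mono, , drop = FALSE],
       monotone = mono)
}

#' Compute cohort statistics from a clinical table with classifier scores
#'
#' The cross-sectional and prognostic summary of a scored CKD cohort:
#' MDRD eGFR (non-dialysis patients), stage groups, Pearson correlation
#' and OLS line of score vs eGFR, Spearman correlation of score vs urine
#' protein, unbalanced one-way F of score across stage groups, mean serum
#' creatinine, the prognostic 2x2 at the score cutoff, and the
#' lost-to-follow-up fraction.
#'
#' @param clinical Clinical `data.frame` with columns `patient_id`,
#'   `age_years`, `sex`, `dialysis`, `creatinine_umol_l`,
#'   `urine_protein_g_per_g`, `event` (`NA` = lost to follow-up) and a
#'   `score` column of classifier scores.
#' @param cutoff Prognostic score cutoff (default 0.55).
#' @param cutpoints Stage-group cutpoints (default `c(60, 30, 15)`).
#' @return A list of the statistics described above.
#' @export
analyze_cohort_table <- function(clinical, cutoff = 0.55,
                                 cutpoints = c(60, 30, 15)) {
  .check_columns(clinical,
                 c("patient_id", "age_years", "sex", "dialysis",
                   "creatinine_umol_l", "urine_protein_g_per_g",
                   "event", "score"), "analyze_cohort_table")
  egfr <- rep(NA_real_, nrow(clinical))
  nd <- !clinical$dialysis
  egfr[nd] <- mdrd_egfr(clinical$creatinine_umol_l[nd],
                        clinical$age_years[nd], clinical$sex[nd])
  stage <- assign_stage_group(egfr, cutpoints)
  scores <- data.frame(sample_id = clinical$patient_id,
                       score = clinical$score)
  ev <- setNames(clinical$event, clinical$patient_id)
  list(
    egfr = setNames(egfr, clinical$patient_id),
    stage_group = setNames(stage, clinical$patient_id),
    score_egfr_pearson = correlate(clinical$score[nd], egfr[nd],
                                   method = "pearson"),
    score_egfr_line = fit_line(egfr[nd], clinical$score[nd]),
    score_uprotein_spearman = correlate(clinical$score,
                                        clinical$urine_protein_g_per_g,
                                        method = "spearman"),
    stage_glm_f = glm_f_unbalanced(clinical$score[nd], stage[nd]),
    mean_creatinine_umol_l = mean(clinical$creatinine_umol_l),
    prognostic = prognostic_table(scores, ev, cutoff = cutoff),
    lost_to_followup_pct = 100 * mean(is.na(clinical$event))
  )
}
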