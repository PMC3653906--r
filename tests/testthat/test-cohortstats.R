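test_that("MDRD eGFR matches hand evaluation and its known structure", {
  # creatinine 88.4 umol/L = 1 mg/dL, male: eGFR = 186 * 70^-0.203
  expect_equal(mdrd_egfr(88.4, 70, "M"), 186 * 70^(-0.203),
               tolerance = 1e-12)
  expect_equal(round(mdrd_egfr(88.4, 70, "M"), 1), 78.5)
  # female factor is exactly multiplicative
  expect_equal(mdrd_egfr(150, 60, "F"), 0.742 * mdrd_egfr(150, 60, "M"))
  expect_equal(mdrd_egfr(150, 60, "M", black = TRUE),
               1.210 * mdrd_egfr(150, 60, "M"))
  expect_error(mdrd_egfr(0, 70, "M"), "creatinine")
  expect_error(mdrd_egfr(100, -1, "M"), "age")
  # strictly decreasing in creatinine and age
  cr <- seq(50, 900, by = 50)
  expect_true(all(diff(mdrd_egfr(cr, 70, "M")) < 0))
  ages <- seq(20, 90, by = 5)
  expect_true(all(diff(mdrd_egfr(150, ages, "M")) < 0))
})

test_that("stage groups split at 60/30/15 with upper-bound inclusion", {
  expect_equal(assign_stage_group(c(64.3, 45, 15, 90, 60, 30.0001, 14.9)),
               c(1L, 2L, 4L, 1L, 2L, 2L, 4L))
  expect_equal(assign_stage_group(c(30, 15.0001)), c(3L, 3L))
  expect_true(is.na(assign_stage_group(NA_real_)))
  expect_error(assign_stage_group(-1), "egfr")
  expect_error(assign_stage_group(50, cutpoints = c(30, 60)), "decreasing")
})

test_that("the unbalanced one-way F matches hand ANOVA and the t-squared identity", {
  # groups {1,2} and {3,4}: SSB = 4, SSW = 1, df = (1, 2), F = 8
  r <- glm_f_unbalanced(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(r$value, 8)
  expect_equal(c(r$df1, r$df2), c(1, 2))
  # equal means, positive within-variance: F = 0
  r0 <- glm_f_unbalanced(c(1, 3, 1, 3), c("a", "a", "b", "b"))
  expect_equal(r0$value, 0)
  # k = 2 unbalanced: F equals the square of the pooled-variance t statistic
  set.seed(41)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(12, 0.5)
    f <- glm_f_unbalanced(c(x, y), rep(c("a", "b"), c(7, 12)))$value
    t2 <- t.test(x, y, var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-9)
  }
  expect_error(glm_f_unbalanced(1:4, rep("a", 4)), "group")
})

test_that("correlation handles exact, monotone and degenerate inputs", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(correlate(x, 2 * x + 1, "pearson")$value, 1)
  r <- correlate(x, exp(x), "spearman")
  expect_equal(r$value, 1)
  expect_lt(correlate(x, exp(x), "pearson")$value, 1)
  cc <- correlate(x, rep(2, 5), "pearson")
  expect_true(cc$constant_input)
  expect_true(is.na(cc$value))
  # missing pairs are dropped and counted
  rm <- correlate(c(x, NA), c(2 * x + 1, 5), "pearson")
  expect_equal(rm$n, 5L)
  expect_equal(rm$n_dropped, 1L)
})

test_that("independent pairs rarely show |R| above 0.1 at n = 1000", {
  set.seed(42)
  rs <- sapply(1:50, function(i)
    abs(correlate(rnorm(1000), rnorm(1000), "pearson")$value))
  expect_gte(mean(rs < 0.1), 0.99)
})

test_that("least squares reproduces exact lines and the closed-form solution", {
  x <- seq(0, 100, by = 10)
  f <- fit_line(x, -0.019 * x + 1.12)
  expect_equal(f$slope, -0.019, tolerance = 1e-12)
  expect_equal(f$intercept, 1.12, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  # degenerate: constant response
  f0 <- fit_line(x, rep(2, length(x)))
  expect_equal(f0$slope, 0)
  expect_equal(f0$r_squared, 0)
  expect_error(fit_line(rep(1, 5), 1:5), "constant")
  # normal-equations oracle on random instances
  set.seed(43)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    xi <- rnorm(n); yi <- rnorm(n)
    f <- fit_line(xi, yi)
    b <- solve(cbind(n, sum(xi), deparse.level = 0) |>
                 rbind(c(sum(xi), sum(xi^2))), c(sum(yi), sum(xi * yi)))
    expect_equal(c(f$intercept, f$slope), as.numeric(b), tolerance = 1e-9)
  }
})

test_that("average-linkage clustering matches the O(n^3) oracle", {
  set.seed(44)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 3), nrow = n)
    rownames(X) <- sprintf("s%02d", seq_len(n))
    pm <- as_peptide_matrix(t(X))
    k <- sample(2:(n - 1), 1)
    got <- cluster_patients(pm, k = k)$assignments
    want <- oracle_upgma(X, k)
    expect_true(same_partition(got[rownames(X)], want))
  }
})

test_that("clustering splits well-separated blobs and honors edge cases", {
  set.seed(45)
  X <- cbind(matrix(rnorm(5 * 10, 0, 0.1), ncol = 10),
             matrix(rnorm(5 * 10, 50, 0.1), ncol = 10))
  pm <- as_peptide_matrix(X)
  cl <- cluster_patients(pm, k = 2)$assignments
  expect_equal(length(unique(cl[1:10])), 1L)
  expect_equal(length(unique(cl[11:20])), 1L)
  expect_false(cl[1] == cl[11])
  # invariant to peptide-row relabeling/reordering
  pm2 <- as_peptide_matrix(X[5:1, ])
  expect_true(same_partition(cl, cluster_patients(pm2, k = 2)$assignments))
  # single sample
  one <- cluster_patients(as_peptide_matrix(X[, 1, drop = FALSE]), k = 1)
  expect_equal(unname(one$assignments), 1L)
  expect_error(cluster_patients(pm, k = 21), "k")
})

test_that("cluster comparisons run both parametric and rank tests", {
  set.seed(46)
  pts <- data.frame(patient_id = sprintf("p%02d", 1:40),
                    flat = rep(5, 40),
                    shifted = c(rnorm(20, 0), rnorm(20, 3)))
  asg <- setNames(rep(1:2, each = 20), pts$patient_id)
  out <- compare_clusters(pts, asg, c("flat", "shifted"))
  # identical values: rank-sum p at its maximum
  expect_equal(out$p_wilcoxon[out$variable == "flat"], 1)
  # 3 SD shift at n = 20 + 20: both tests significant
  expect_lt(out$p_t[out$variable == "shifted"], 0.01)
  expect_lt(out$p_wilcoxon[out$variable == "shifted"], 0.01)
})

test_that("the Welch test keeps its nominal type-I error under the null", {
  set.seed(47)
  pvals <- replicate(1000, {
    t.test(rnorm(20), rnorm(20))$p.value
  })
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})

test_that("per-peptide eGFR correlations recover planted directions", {
  set.seed(48)
  n <- 60
  egfr <- runif(n, 5, 95)
  up <- exp(8 - 0.03 * egfr + rnorm(n, 0, 0.3))    # rises as eGFR falls
  down <- exp(4 + 0.03 * egfr + rnorm(n, 0, 0.3))  # falls as eGFR falls
  flat <- rep(100, n)
  X <- rbind(up, down, flat)
  pm <- as_peptide_matrix(X)
  names(egfr) <- colnames(pm$intensities)
  out <- per_peptide_egfr_correlation(pm, egfr)
  expect_equal(out$direction[1:2],
               c("increased-with-CKD", "decreased-with-CKD"))
  expect_true(out$constant[3])
  expect_true(is.na(out$direction[3]))
  expect_true(all(out$p_adjusted >= out$p_value, na.rm = TRUE))
})

test_that("permuted eGFR labels yield ~5% raw false positives", {
  set.seed(49)
  n <- 40; p <- 150
  X <- exp(matrix(rnorm(p * n, 6, 0.5), nrow = p))
  pm <- as_peptide_matrix(X)
  egfr <- setNames(sample(runif(n, 5, 95)), colnames(pm$intensities))
  out <- per_peptide_egfr_correlation(pm, egfr)
  fpr <- mean(out$p_value < 0.05, na.rm = TRUE)
  expect_lt(abs(fpr - 0.05), 0.05)
})

test_that("monotone-peptide selection keeps ordered group-mean profiles", {
  # 4 groups x 3 samples; rows: increasing, non-monotone, constant
  g <- setNames(rep(1:4, each = 3), sprintf("s%03d", 1:12))
  mk_row <- function(means) rep(means, each = 3)
  X <- rbind(mk_row(c(1, 2, 3, 4)),
             mk_row(c(1, 3, 2, 4)),
             mk_row(c(2, 2, 2, 2)),
             mk_row(c(9, 5, 5, 1)))
  pm <- as_peptide_matrix(X)
  out <- monotone_peptides(pm, g)
  expect_equal(unname(out$monotone), c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(out$group_means["pep00001", ], setNames(c(1, 2, 3, 4),
               paste0("group", 1:4)))
  expect_error(monotone_peptides(pm, setNames(rep(1, 12), names(g))),
               "groups")
})

test_that("cohort-table analysis assembles every headline statistic", {
  set.seed(50)
  rep1 <- run_pipeline(tiny_config(seed = 51))
  st <- rep1$stats
  expect_s3_class(st$score_egfr_pearson, "data.frame")
  expect_true(is.finite(st$score_egfr_line$slope))
  expect_true(is.finite(st$stage_glm_f$value))
  expect_equal(st$prognostic$n_known + st$prognostic$n_unknown,
               nrow(rep1$patients))
  expect_true(all(is.na(st$egfr[rep1$patients$patient_id[rep1$patients$dialysis]])))
})
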