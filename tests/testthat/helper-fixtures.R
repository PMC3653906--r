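# Shared fixtures and independent oracles for the test suite.

# Small, fast generator configuration for structural tests.
tiny_config <- function(seed = 1, ...) {
  synthetic_config(n_patients = 12, seed = seed, n_marker_up = 10,
                   n_marker_down = 12, n_housekeeping = 12,
                   n_reference = 60, n_noise_peptides = 5,
                   n_dialysis = 2, n_lost_followup = 1, ...)
}

# All nuisance processes switched off: the pipeline must reconstruct the
# panel exactly from such data.
zero_noise_config <- function(n_patients = 20, n_reference = 100,
                              seed = 1, ...) {
  base <- list(n_patients = n_patients, seed = seed,
               n_marker_up = 15, n_marker_down = 15,
               n_housekeeping = 15, n_reference = n_reference,
               n_noise_peptides = 0, dilution_sd = 0,
               drift_amplitude = 0, detection_limit = 0,
               abundance_sd = 0, hk_sd = 0, mass_ppm_sd = 0,
               time_sd = 0, junk_fraction = 0, n_dialysis = 0,
               n_lost_followup = 0)
  do.call(synthetic_config, utils::modifyList(base, list(...)))
}

# Wrap an intensity matrix (peptides x samples, NA = missing) as a
# peptide_matrix, inventing well-separated masses/times.
as_peptide_matrix <- function(X, mass = NULL, time = NULL) {
  n <- nrow(X)
  if (is.null(mass)) mass <- 1000 + 10 * seq_len(n)
  if (is.null(time)) time <- 20 + (seq_len(n) %% 20)
  if (is.null(rownames(X))) rownames(X) <- sprintf("pep%05d", seq_len(n))
  if (is.null(colnames(X))) colnames(X) <- sprintf("s%03d", seq_len(ncol(X)))
  structure(list(
    peptides = data.frame(peptide_id = rownames(X), mass_da = mass,
                          time_min = time,
                          support = as.integer(rowSums(!is.na(X)))),
    samples = colnames(X),
    intensities = X), class = "peptide_matrix")
}

# Brute-force transitive-closure grouping oracle for deconvolution:
# connected components of the pairwise "same molecule" relation.
oracle_deconv_groups <- function(mass, time, ppm = 25, dt = 0.1) {
  n <- length(mass)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- abs(mass[i] - mass[j]) / min(mass[i], mass[j]) * 1e6 <= ppm &&
        abs(time[i] - time[j]) <= dt
    }
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    stack <- i
    while (length(stack) > 0L) {
      v <- stack[1L]; stack <- stack[-1L]
      if (comp[v] > 0L) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  comp
}

# O(n^3) average-linkage (UPGMA) clustering oracle: repeatedly merge the
# pair of clusters with the smallest average pairwise Euclidean distance;
# ties broken by the lower first index. Returns k-cluster assignments.
oracle_upgma <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (a in seq_len(m - 1L)) {
      for (b in seq(a + 1L, m)) {
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < best[1L] - 1e-12) best <- c(d, a, b)
      }
    }
    a <- best[2L]; b <- best[3L]
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
  }
  out <- integer(n)
  for (ci in seq_along(clusters)) out[clusters[[ci]]] <- ci
  out
}

# Partition equality up to label renaming: canonicalize labels by first
# occurrence; two partitions are identical iff their canonical forms are.
same_partition <- function(a, b) {
  canon <- function(x) match(x, unique(x))
  identical(canon(as.vector(a)), canon(as.vector(b)))
}

# Simple k-fold cross-validated AUROC for train_model/score_matrix.
cv_auroc <- function(pm, labels, folds = 3, regularization = 1) {
  n <- length(labels)
  fold <- rep_len(seq_len(folds), n)
  aucs <- sapply(seq_len(folds), function(f) {
    tr <- fold != f
    m <- train_model(subset_samples(pm, tr), labels[tr],
                     regularization = regularization)
    sc <- score_matrix(subset_samples(pm, !tr), m)
    auroc(sc$score, labels[!tr])
  })
  mean(aucs)
}

# Column (sample) subset of a peptide_matrix, for cross-validation.
subset_samples <- function(pm, keep) {
  X <- pm$intensities[, keep, drop = FALSE]
  structure(list(
    peptides = data.frame(pm$peptides[, c("peptide_id", "mass_da",
                                          "time_min")],
                          support = as.integer(rowSums(!is.na(X)))),
    samples = pm$samples[keep],
    intensities = X), class = "peptide_matrix")
}
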