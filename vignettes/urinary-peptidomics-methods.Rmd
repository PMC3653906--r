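---
title: "Methods: urinary CE-MS peptidomics processing and classifier analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: urinary CE-MS peptidomics processing and classifier analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urinpep)
```

## The problem

Capillary electrophoresis coupled to mass spectrometry (CE-MS) profiles the
urinary low-molecular-weight peptidome: each run yields a peak list of
signals characterized by m/z, charge, intensity, CE migration time,
signal-to-noise ratio and spectral persistence. In chronic kidney disease
(CKD), the relative abundances of hundreds of urinary peptides shift with
declining renal function — fragments of abundant serum proteins
(β2-microglobulin, albumin, transthyretin, α1-antitrypsin) rise as the
glomerular filtration rate falls, while fragments of structural and
tubular proteins (collagen types I and III, uromodulin) fall. Multi-peptide
classifiers such as CKD273 condense these shifts into one numeric score
with a prognostic cutoff.

Raw per-patient CE-MS data for such cohorts are generally not publicly
deposited, so this package pairs the analysis pipeline with a synthetic
cohort generator that emits peak lists with the statistical structure the
pipeline assumes, together with the full ground truth (latent severities,
dilution factors, time warps, true abundances). Every stage can therefore
be tested as a parameter-recovery problem.

## Pipeline stages and their models

### Signal filtering

Only signals with charge > 1, signal-to-noise ≥ 4 and at least 3
consecutive spectra are retained (`filter_signals()`). Singly charged
species in urine are dominated by matrix and salt clusters; the S/N and
persistence thresholds remove spurious centroids. Boundaries are
inclusive for S/N and spectra count, exclusive for charge.

### Charge deconvolution

One peptide of neutral monoisotopic mass $M$ appears at
$m/z = (M + z\,m_p)/z$ for several charge states $z$, with
$m_p = 1.007276$ Da. `deconvolute()` groups signals whose neutral masses
agree within 25 ppm (the platform's monoisotopic mass accuracy; ppm is
computed relative to the smaller mass of a pair) *and* whose migration
times agree within 0.1 min. Grouping is the exact transitive closure of
that pairwise relation, computed efficiently by sorting on mass,
chaining mass-adjacent signals (a superset of the closure), and taking
connected components under the joint criterion inside each chain. The
feature mass is the intensity-weighted mean of member masses and the
feature intensity the member sum, so total intensity is conserved. The
co-elution tolerance (0.1 min) is deliberately tighter than the
cross-sample tolerance (0.35 min): within one run, charge states of one
molecule co-migrate almost exactly.

### Migration-time calibration

Observed times are mapped onto the canonical times of a reference panel
by locally weighted regression (`calibrate_times()`): tricube weights,
two robustifying iterations, and linear extrapolation continuing the
terminal local fits. Three numerical choices matter:

* **Anchor window.** Anchors are matched with the 50 ppm mass tolerance
  but a wide 6 min time window, because pre-calibration times still carry
  the drift that calibration is meant to remove; a 0.35 min window would
  miss exactly the anchors needed under a few minutes of drift. The
  0.35 min rule is enforced *after* calibration, as the per-sample QC
  bound on anchor residuals.
* **Span.** Default 0.1 of the anchors per local window, floored so each
  window holds at least 6 anchors. Wider spans (0.5) leave systematic
  residuals of ~0.07–0.25 min around drift kinks on the scale of a few
  minutes, which violates the 0.35 min control and, on clean 50-anchor
  warps, the 0.05 min recovery the test suite demands. With hundreds of
  anchors per run the floored span still averages over dozens of points,
  so the fit is not noise-limited.
* **Degenerate-fit guard.** `stats::lowess`'s robustness iterations
  collapse when the plain fit is already exact (all residuals ~0 make
  the residual-scaled weights degenerate), so the robustifying passes are
  only applied when the non-robust fit has a median absolute residual
  above $10^{-6}$ min. The fitted map is forced monotone non-decreasing
  by a running maximum.

### Intensity normalization

Urine concentration varies multiplicatively between voids. A panel of
housekeeping peptides — peptides selected for stable abundance across
subjects — carries reference intensities; `normalize_intensities()`
rescales each sample by the *median* of reference-to-observed intensity
ratios over the detected housekeeping peptides (at least 3 required).
The median, rather than the mean, tolerates individual aberrant
housekeeping peptides. Normalization is scale-equivariant, so it exactly
cancels any multiplicative dilution.

### Cross-sample matching

`build_matrix()` accumulates consensus peptides greedily in sample order:
each feature joins the nearest existing consensus peptide within 50 ppm
(relative to the current consensus mass) and 0.35 min, or founds a new
one; within a sample at most one feature may join a given consensus
peptide (nearest ppm wins; the loser founds a new peptide). Consensus
mass is an intensity-weighted running mean, which stabilizes as support
grows. Greedy accumulation mirrors how platform databases are built and
is deterministic given sample order; global order invariance is not
guaranteed in pathological overlap cases, but is verified on
well-separated panels. Missing cells stay missing in the matrix —
downstream stages decide how absence is treated.

The presence filter keeps peptides detected in strictly more than 50% of
samples.

### Classifier scoring

A classifier model is a peptide panel with linear weights, an offset, a
prognostic cutoff (default 0.55) and a missing-data policy. A sample's
score is

$$ s = \beta_0 + \sum_i w_i \log_{10}(1 + x_i), $$

with $x_i$ the matched normalized intensity. Intensities span decades,
so the log transform is standard; the $+1$ keeps the transform defined
at zero so the default missing policy ("zero") lets an undetected panel
peptide contribute exactly 0 — under detection-limit censoring, absence
is informative. Scores strictly above the cutoff are high-risk; the
boundary value itself is low-risk. `train_model()` fits a
ridge-regularized linear discriminant
($w = (S + \lambda I)^{-1}(\mu_1 - \mu_0)$ on log intensities, pooled
within-class covariance $S$) — it exists to exercise the framework on
synthetic cohorts, not to reproduce any published weight vector, which
was trained on proprietary data and is not recoverable from the
literature.

### Cohort statistics

* **eGFR** by the simplified (abbreviated) MDRD equation with the
  original coefficient 186 (the study era predates the 175
  re-expression), creatinine converted from µmol/L via 88.4, the female
  factor 0.742 and the Black-race factor 1.210 (race defaults to false
  when unrecorded). Dialysis patients carry no eGFR — creatinine under
  dialysis does not reflect filtration — and are excluded from every
  eGFR-based analysis.
* **Stage groups** partition eGFR at cutpoints 60, 30, 15 with
  upper-bound inclusion, i.e. the integer bands 90–61, 60–31, 30–16,
  15–0 extended to the reals.
* **Unbalanced one-way GLM F**, Pearson/Spearman correlations and OLS
  fits are delegated to `lm`/`anova` and `cor.test`; Spearman uses
  average ranks for ties, constant inputs yield flagged results rather
  than errors.
* **Patient clustering** is agglomerative average linkage (UPGMA) on
  Euclidean distances over per-patient peptide vectors with missing
  cells zero-filled; the dendrogram is cut at a configurable k
  (default 4, matching the four-cluster structure typically reported;
  the original cut rule is unstated). The two largest clusters are
  compared per clinical variable with a Welch t test and a Wilcoxon
  rank-sum test; an all-ties comparison reports the maximal rank-sum
  p of 1.
* **Per-peptide associations** are Spearman correlations of each
  peptide row (missing as zero) with eGFR; ρ < 0 is labelled
  increased-with-CKD. Benjamini–Hochberg adjusted p-values are reported
  alongside raw ones; selection at raw p < 0.05 mirrors the original
  reporting.
* **Monotone peptides** are those whose per-stage-group mean signal is
  non-strictly monotone across the ordered groups; whether ties should
  count is unstated in the source analyses, and non-strict monotonicity
  (ties allowed) was chosen and flagged.

## The synthetic generator

`simulate_cohort()` draws a latent severity $s \sim U(0,1)$ per patient
and derives everything from it:

* true eGFR $= 100\,(1-s)^{1.7}$ (spanning stages I–V; the default
  53-patient cohort lands all four stage groups non-empty),
* serum creatinine by exact MDRD inversion given age
  ($\mathcal N(70, 11.6^2)$, truncated to 20–95) and sex (M with
  probability 33/53), so generated eGFR round-trips through
  `mdrd_egfr()` to < 0.1 mL/min/1.73 m²,
* urine protein $\exp(-2.2 + 3.6 s + \varepsilon)$ g/g creatinine
  (≈1.1 g/g cohort mean),
* the 6 most severe patients flagged as dialysed, with creatinine drawn
  separately around 600 µmol/L,
* a combined death/dialysis endpoint, Bernoulli with logistic link
  $\operatorname{logit} p = -9 + 13 s$ (≈16 expected events per 53,
  concentrated at high severity). An optional hard floor
  (`event_min_severity`) zeroes the risk below a severity threshold;
  with the floor at 0.65 the generator emulates the empirically observed
  regime in which no low-score patient reaches an endpoint. The default
  keeps the pure logistic link,
* 4 patients lost to follow-up (unknown outcome), i.e. 7.5% of 53.

`simulate_peaklists()` draws a reference panel of 200 peptides (standing
in for a full calibration panel of 1770; masses log-uniform on
0.8–12 kDa, times uniform on 18–45 min, rejection-sampled so no two
panel peptides fall within 50 ppm *and* 0.7 min — the panel identity
invariant). Within it, 30 "up" markers (serum-protein-like), 42 "down"
markers (collagen/uromodulin-like; the 42 echoes the 29 + 8 + 5
collagen-I/collagen-III/uromodulin fragment counts of the motivating
analysis) and 29 housekeeping peptides. Abundances are lognormal with
severity entering the log-mean linearly: $\log A = \mu_i + d_i\,
\beta\, s + \varepsilon$, with direction $d_i = \pm 1$, effect size
$\beta = 1.5$ (≈4.5-fold swing over the severity range) and noise SD 0.5
(0.15 for housekeeping peptides — low variability is their defining,
selected-for property, and a 29-peptide median-of-ratios can only pin
dilution to within 10% if the housekeeping CV is below ~20%). Samples
are then distorted by a lognormal dilution factor (SD 0.5), a monotone
piecewise-linear time warp (5 knots, amplitude 0.5 min, redrawn until
strictly increasing), per-signal mass error (5 ppm SD) and time jitter
(0.02 min SD), left-censored at a detection limit of 50 intensity units
(censoring, not random dropout — absence means sub-detection abundance),
split over up to three charge states ($z \in 2..6$ within an m/z window
of 350–2200 Th), and topped with 30 sample-specific noise peptides plus
15% junk signals ($z = 1$ or S/N < 4) that the quality filter must
remove.

The planted classifier weighs the markers $\pm c$ with $c$ set so the
expected score spans ≈1.4 units over the severity range, and the offset
chosen analytically (from the drawn abundance log-means) so the expected
score crosses the 0.55 cutoff at severity 0.6.

None of the marker effect sizes, noise magnitudes or abundance scales of
the real cohort are published; the values above are one-time realism
choices, not estimates, and the generator is correspondingly cleaner
than real data: no isotopic fine structure, no longitudinal sampling, no
correlated biological covariates (comorbidity, medication), and
noise that is exactly lognormal and independent across peptides.
Passing recovery tests on these data therefore demonstrates the
pipeline's correctness under its stated assumptions, not its field
performance; on real cohorts the score–eGFR and score–proteinuria
associations are expected to be substantially weaker than on the
synthetic defaults.

## Problem sizes used in the test suite

Structural tests run on 8–20-patient cohorts with 60–100-peptide panels;
Monte-Carlo recovery checks use up to 200 patients or 100 replicate
samples; oracle equivalence uses exhaustive algorithms at n ≤ 50 signals
(deconvolution) and n ≤ 8 patients (UPGMA). These sizes were chosen as
the smallest at which the tested properties are statistically
well-resolved.

## Known limitations

* Greedy consensus matching can split a true peptide across two rows
  when masses drift near the tolerance boundary; the running-mean
  centroid bounds but does not eliminate this.
* The presence filter interacts with detection-limit censoring:
  down-markers that disappear in severe CKD can drop below 50% presence
  in severely skewed cohorts.
* `train_model()` is a plain ridge discriminant; it makes no attempt at
  the support-vector machinery used for published urinary classifiers.
* The dendrogram cut rule (k = 4) and the treatment of score ties at the
  cutoff (low-risk) are conventions; both are parameters.
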