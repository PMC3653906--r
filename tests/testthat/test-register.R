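panel3 <- data.frame(peptide_id = c("a", "b", "c"),
                     mass_da = c(2000, 3000, 4000),
                     time_min = c(20, 25, 30))

test_that("panel matching respects the 50 ppm / 0.35 min tolerances", {
  # 25 ppm, inside both tolerances -> paired
  f <- data.frame(mass_da = 2000.05, time_min = 20.1, intensity = 1)
  p <- match_to_panel(f, panel3)
  expect_equal(nrow(p), 1L)
  expect_equal(p$peptide_id, "a")
  expect_equal(p$ppm_dev, 25, tolerance = 1e-6)
  # 75 ppm -> unpaired
  f2 <- data.frame(mass_da = 2000.15, time_min = 20.1, intensity = 1)
  expect_equal(nrow(match_to_panel(f2, panel3)), 0L)
  # outside time tolerance -> unpaired
  f3 <- data.frame(mass_da = 2000.01, time_min = 21.0, intensity = 1)
  expect_equal(nrow(match_to_panel(f3, panel3)), 0L)
  expect_error(match_to_panel(f, panel3[0, ]), "empty")
})

test_that("equidistant candidates resolve to the earlier-time feature", {
  f <- data.frame(mass_da = c(2000.04, 2000.04), time_min = c(20.2, 20.1),
                  intensity = c(1, 1))
  p <- match_to_panel(f, panel3)
  expect_equal(nrow(p), 1L)
  expect_equal(p$feature_idx, 2L)  # the 20.1 min feature
})

test_that("greedy matching is one-to-one and ppm-ascending", {
  # two features compete for entry "a"; nearer ppm wins, other unpaired
  f <- data.frame(mass_da = c(2000.02, 2000.06),
                  time_min = c(20.0, 20.0), intensity = c(1, 1))
  p <- match_to_panel(f, panel3)
  expect_equal(nrow(p), 1L)
  expect_equal(p$feature_idx, 1L)
  expect_true(!anyDuplicated(p$feature_idx) && !anyDuplicated(p$panel_idx))
})

make_anchor_features <- function(panel, warp) {
  data.frame(mass_da = panel$mass_da,
             time_min = warp(panel$time_min),
             intensity = rep(100, nrow(panel)))
}

big_panel <- data.frame(peptide_id = sprintf("p%03d", 1:50),
                        mass_da = 1000 + 40 * (1:50),
                        time_min = seq(18, 45, length.out = 50))

test_that("identity warp leaves calibrated times unchanged", {
  f <- make_anchor_features(big_panel, identity)
  cal <- calibrate_times(f, big_panel)
  expect_equal(cal$features$time_min, f$time_min, tolerance = 1e-6)
  expect_true(cal$qc_pass)
})

test_that("linear drift is removed to anchor residuals below 0.05 min", {
  f <- make_anchor_features(big_panel, function(t) 1.1 * t + 0.5)
  cal <- calibrate_times(f, big_panel)
  expect_equal(cal$n_anchors, 50L)
  expect_lt(cal$max_residual, 0.05)
  # the fitted map must undo the drift for non-anchor times too
  expect_equal(cal$warp(1.1 * 30 + 0.5), 30, tolerance = 0.05)
})

test_that("piecewise-linear drift is removed below 0.05 min", {
  kx <- seq(18, 45, length.out = 5)
  ky <- kx + c(0.4, -0.3, 0.5, -0.2, 0.3)
  warp <- function(t) approx(kx, ky, xout = t, rule = 2)$y
  f <- make_anchor_features(big_panel, warp)
  cal <- calibrate_times(f, big_panel)
  expect_lt(cal$max_residual, 0.05)
})

test_that("calibration map is monotone over the observed range", {
  set.seed(3)
  f <- make_anchor_features(big_panel, function(t) 1.05 * t - 0.3)
  f$time_min <- f$time_min + rnorm(50, 0, 0.05)
  cal <- calibrate_times(f, big_panel)
  grid <- seq(15, 50, by = 0.05)
  expect_true(all(diff(cal$warp(grid)) >= 0))
})

test_that("too few anchors is a calibration failure", {
  f <- make_anchor_features(big_panel[1:3, ], identity)
  expect_error(calibrate_times(f, big_panel, min_anchors = 10),
               "calibration failure")
})

hk_panel <- data.frame(peptide_id = sprintf("hk%02d", 1:5),
                       mass_da = 1500 + 100 * (1:5),
                       time_min = 20 + 2 * (1:5),
                       ref_intensity = c(100, 200, 300, 400, 500))

test_that("uniform dilution is inverted by the median-of-ratios factor", {
  f <- data.frame(mass_da = hk_panel$mass_da, time_min = hk_panel$time_min,
                  intensity = 2 * hk_panel$ref_intensity)
  nr <- normalize_intensities(f, hk_panel)
  expect_equal(nr$scale_factor, 0.5)
  expect_equal(nr$features$intensity, hk_panel$ref_intensity)
  expect_equal(nr$n_housekeeping, 5L)
})

test_that("normalization is scale-equivariant", {
  set.seed(4)
  f <- data.frame(mass_da = c(hk_panel$mass_da, 3000),
                  time_min = c(hk_panel$time_min, 40),
                  intensity = c(hk_panel$ref_intensity * runif(5, 0.5, 2), 77))
  n1 <- normalize_intensities(f, hk_panel)
  f2 <- f; f2$intensity <- f$intensity * 13
  n2 <- normalize_intensities(f2, hk_panel)
  expect_equal(n1$features$intensity, n2$features$intensity,
               tolerance = 1e-12)
})

test_that("missing housekeeping detections are a normalization failure", {
  f <- data.frame(mass_da = 9000, time_min = 40, intensity = 5)
  expect_error(normalize_intensities(f, hk_panel), "normalization failure")
})

test_that("planted dilution factors are recovered within 10% for >=95% of samples", {
  # housekeeping-only samples with lognormal dilution (sd = 0.5) and
  # low-variance housekeeping noise, as the generator emits them
  set.seed(5)
  hk29 <- data.frame(peptide_id = sprintf("hk%02d", 1:29),
                     mass_da = 1000 + 50 * (1:29),
                     time_min = seq(18, 45, length.out = 29),
                     ref_intensity = exp(runif(29, log(200), log(5000))))
  ok <- vapply(1:100, function(i) {
    d <- exp(rnorm(1, 0, 0.5))
    f <- data.frame(mass_da = hk29$mass_da, time_min = hk29$time_min,
                    intensity = hk29$ref_intensity * d *
                      exp(rnorm(29, 0, 0.15)))
    s <- normalize_intensities(f, hk29)$scale_factor
    abs(s * d - 1) < 0.10
  }, TRUE)
  expect_gte(mean(ok), 0.95)
})

test_that("normalization shrinks the between-sample housekeeping CV", {
  set.seed(6)
  hk29 <- data.frame(peptide_id = sprintf("hk%02d", 1:29),
                     mass_da = 1000 + 50 * (1:29),
                     time_min = seq(18, 45, length.out = 29),
                     ref_intensity = exp(runif(29, log(200), log(5000))))
  raw <- lapply(1:40, function(i) {
    d <- exp(rnorm(1, 0, 0.5))
    data.frame(mass_da = hk29$mass_da, time_min = hk29$time_min,
               intensity = hk29$ref_intensity * d * exp(rnorm(29, 0, 0.15)))
  })
  nrm <- lapply(raw, function(f)
    normalize_intensities(f, hk29)$features)
  cv <- function(lst) {
    M <- sapply(lst, function(f) f$intensity)
    mean(apply(M, 1, sd) / apply(M, 1, mean))
  }
  expect_lt(cv(nrm), cv(raw))
})
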