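test_that("a model with no cross-coupling has zero spectral GC everywhere", {
  truth <- var_ground_truth(list(diag(c(0.6, 0.5, 0.4)), diag(0.2, 3)))
  sgc <- spectral_gc(truth, fs = 200)
  expect_lt(max(sgc$gc, na.rm = TRUE), 1e-6)
})

test_that("bivariate spectral GC satisfies the Geweke integral identity against the oracle", {
  truth <- coupled_bivariate_truth(0.5)
  cm <- spectral_gc_circle_mean(truth, 1, 2)
  orc <- true_timedomain_gc(truth, 1, 2, n_samples = 1e6, seed = 6)
  expect_lt(abs(cm - orc) / orc, 0.02)
  # and the state-space time-domain value agrees with both
  expect_lt(abs(timedomain_gc_ss(truth, 1, 2) - cm) / cm, 1e-6)
})

test_that("conditioning removes the indirect route in a 1->2->3 chain", {
  A <- diag(0.5, 3); A[2, 1] <- 0.5; A[3, 2] <- 0.5
  truth <- var_ground_truth(list(A))
  # conditional on channel 2 the 1->3 influence vanishes
  sgc <- spectral_gc(truth, fs = 200)
  expect_lt(max(sgc$gc[3, 1, ]), 1e-3)
  # but a bivariate analysis of {1,3} alone sees a strong influence:
  # reduced-regression oracle dropping channel 2 from both regressions
  set.seed(17)
  y <- varconn:::simulate_var_signals(truth, 1e6, 200)
  gram <- varconn:::lag_gram(y, 20)
  v_full <- varconn:::gram_residual_variance(gram, 3, c(1, 3), 20)
  v_red <- varconn:::gram_residual_variance(gram, 3, 3, 20)
  expect_gt(log(v_red / v_full), 1e-2)
})

test_that("spectral GC is non-negative and finite over random stable models", {
  for (s in 1:6) {
    truth <- random_stable_truth(4, sample(1:3, 1), seed = 200 + s)
    sgc <- spectral_gc(truth, fs = 200, freq = seq(0.5, 100, by = 0.5))
    vals <- sgc$gc[!is.na(sgc$gc)]
    expect_true(all(is.finite(vals)))
    expect_true(all(vals >= 0))
  }
})

test_that("permuting channels permutes the GC table accordingly", {
  truth <- random_stable_truth(4, 2, density = 0.4, seed = 77)
  sgc <- spectral_gc(truth, fs = 200, freq = seq(1, 100, by = 1))
  perm <- c(2, 4, 1, 3)
  truth_p <- var_ground_truth(lapply(truth$coeffs, function(A) A[perm, perm]),
                              truth$noise_cov[perm, perm])
  sgc_p <- spectral_gc(truth_p, fs = 200, freq = seq(1, 100, by = 1))
  expect_equal(sgc_p$gc, sgc$gc[perm, perm, ], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("unstable models are rejected with the spectral radius reported", {
  eps <- make_epochs(random_stable_truth(3, 1, seed = 3), n_epochs = 10,
                     seed = 3)
  m <- fit_var(eps, 1)
  m$stable <- FALSE; m$spectral_radius <- 1.02
  expect_error(spectral_gc(m), "unstable")
})

test_that("band integration matches closed-form integrals", {
  # hand-built spectral object: constant, zero, and piecewise-linear
  freq <- seq(0.1, 100, by = 0.1)
  nf <- length(freq)
  g <- array(NA_real_, c(2, 2, nf))
  cval <- 0.37
  g[2, 1, ] <- cval                       # constant spectrum
  g[1, 2, ] <- pmax(0, 1 - abs(freq - 8) / 4)  # triangle peaked at 8 Hz
  sgc <- structure(list(gc = g, freq = freq, fs = 200,
                        region_labels = c("a", "b")),
                   class = "spectral_gc")
  theta <- band_integral(sgc, 6, 10)
  expect_equal(theta[2, 1], 4 * cval, tolerance = 1e-9)
  # triangle: integral over [6,10] of (1 - |f-8|/4) = width * mean = 4 * 0.75
  expect_equal(theta[1, 2], 3, tolerance = 1e-6)
  expect_equal(band_integral(sgc, 6, 10, reduce = "mean")[2, 1], cval,
               tolerance = 1e-9)
  # additivity over a partition of the band
  two <- band_integral(sgc, 6, 8)[1, 2] + band_integral(sgc, 8, 10)[1, 2]
  expect_equal(two, theta[1, 2], tolerance = 1e-9)
  zero <- sgc; zero$gc[1, 2, ] <- 0; zero$gc[2, 1, ] <- 0
  expect_equal(band_integral(zero, 2, 4)[1, 2], 0)
  expect_error(band_integral(sgc, 90, 120), "outside")
})

test_that("the canonical band table matches the analysis definitions", {
  b <- canonical_bands()
  expect_equal(b$band, c("delta", "theta", "beta", "gamma_low", "gamma_mid",
                         "gamma_high"))
  expect_equal(b$lo, c(2, 6, 15, 35, 55, 70))
  expect_equal(b$hi, c(4, 10, 25, 45, 75, 90))
})

test_that("one six-channel animal yields 30 directed pairs x 6 bands", {
  eps <- make_epochs(default_ground_truth(), n_epochs = 12, seed = 55)
  coh <- gc_cohort(list(eps), order = 2, qc_action = "none",
                   freq = seq(0.5, 100, by = 0.5))
  expect_equal(nrow(coh$band_gc), 180)
  expect_equal(sort(unique(coh$band_gc$band)), sort(canonical_bands()$band))
  # determinism: identical truth and seed give identical tables
  eps2 <- make_epochs(default_ground_truth(), n_epochs = 12, seed = 55)
  coh2 <- gc_cohort(list(eps2), order = 2, qc_action = "none",
                    freq = seq(0.5, 100, by = 0.5))
  expect_identical(coh$band_gc$gc_value, coh2$band_gc$gc_value)
})

test_that("QC failures exclude animals with a recorded reason, never silently", {
  truth <- var_ground_truth(list(matrix(0, 3, 3)))  # white noise: R2 ~ 0
  eps <- make_epochs(truth, n_epochs = 12, seed = 66)
  coh <- gc_cohort(list(eps), order = 1, qc_action = "enforce")
  expect_false(any(coh$qc$included))
  expect_match(coh$qc$reason[1], "R2")
  expect_null(coh$band_gc)
})

test_that("true edges separate from null edges in band-summed GC", {
  truth <- default_ground_truth()
  edges <- default_true_edges()
  key <- function(df) paste(df$source_region, df$target_region)
  true_keys <- paste(edges$source, edges$target)
  hits <- vapply(1:10, function(s) {
    bg <- simulate_band_cohort(truth, 1, n_epochs = 40, seed = 400 + s)
    tot <- stats::aggregate(gc_value ~ source_region + target_region, bg, sum)
    is_true <- key(tot) %in% true_keys
    min(tot$gc_value[is_true]) > max(tot$gc_value[!is_true])
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
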