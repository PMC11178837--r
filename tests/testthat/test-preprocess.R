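test_that("down-sampling honours the floor(duration * target_fs) length contract", {
  set.seed(1)
  rec <- lfp_recording(matrix(rnorm(1017 * 60), 1), fs = 1017)
  dn <- downsample_recording(rec, 200)
  expect_equal(ncol(dn$signals), 60 * 200)
  expect_equal(dn$fs, 200)
  expect_error(downsample_recording(dn, 400), "below")
})

test_that("down-sampling preserves DC and passband, attenuates above Nyquist", {
  fs <- 1017
  tt <- (0:(fs * 20 - 1)) / fs
  dc <- lfp_recording(matrix(5, 1, length(tt)), fs)
  dn <- downsample_recording(dc, 200)
  expect_lt(max(abs(dn$signals - 5)), 1e-6)

  x80 <- sin(2 * pi * 80 * tt); x120 <- sin(2 * pi * 120 * tt)
  dn2 <- downsample_recording(lfp_recording(rbind(x80, x120), fs), 200)
  n_in <- length(tt); n_out <- ncol(dn2$signals)
  # periodogram power scales with length; compare per-sample power
  p80_in <- periodogram_power(x80, fs, 80) / n_in
  p80_out <- periodogram_power(dn2$signals[1, ], 200, 80) / n_out
  expect_lt(abs(10 * log10(p80_out / p80_in)), 1)
  p120_in <- periodogram_power(x120, fs, 120) / n_in
  # 120 Hz aliases to 80 Hz at 200 Hz sampling; it must arrive attenuated
  p120_out <- periodogram_power(dn2$signals[2, ], 200, 80) / n_out
  expect_gt(10 * log10(p120_in / p120_out), 20)
})

test_that("notch removes the target line while sparing nearby frequencies", {
  fs <- 1017
  tt <- (0:(fs * 20 - 1)) / fs
  x50 <- sin(2 * pi * 50 * tt); x10 <- sin(2 * pi * 10 * tt)
  out <- notch_filter(lfp_recording(rbind(x50, x10), fs), 50, 2)
  expect_lt(periodogram_power(out$signals[1, ], fs, 50) /
              periodogram_power(x50, fs, 50), 1e-4)
  core <- seq(2000, length(tt) - 2000)  # avoid filtfilt edge transients
  expect_lt(max(abs(out$signals[2, core] - x10[core])) / max(abs(x10)), 0.01)
  zeros <- notch_filter(lfp_recording(matrix(0, 1, 5000), fs), 50, 2)
  expect_true(all(zeros$signals == 0))
  expect_error(notch_filter(lfp_recording(matrix(rnorm(1000), 1), 80), 50),
               "fs/2")
})

test_that("normalisation yields exact zero mean and unit SD, idempotently and scale-free", {
  set.seed(2)
  sig <- matrix(rnorm(4000, mean = 3, sd = 7), 2)
  rec <- lfp_recording(sig, 200)
  nm <- normalize_recordings(rec)
  expect_lt(max(abs(rowMeans(nm$signals))), 1e-10)
  expect_lt(max(abs(apply(nm$signals, 1, sd) - 1)), 1e-6)
  again <- normalize_recordings(nm)
  expect_lt(max(abs(again$signals - nm$signals)), 1e-6)
  scaled <- rec; scaled$signals[1, ] <- scaled$signals[1, ] * 1000
  nm2 <- normalize_recordings(scaled)
  expect_lt(max(abs(nm2$signals[1, ] - nm$signals[1, ])), 1e-9)
  flat <- rec; flat$signals[2, ] <- 1
  expect_error(normalize_recordings(flat), "zero-variance")
})

test_that("global normalisation pools per-site statistics across animals", {
  set.seed(3)
  recs <- lapply(1:3, function(i)
    lfp_recording(matrix(rnorm(2000, sd = i), 2, 1000), 200,
                  animal_id = paste0("a", i)))
  out <- normalize_recordings(recs, scope = "global")
  pooled <- do.call(cbind, lapply(out, function(r) r$signals))
  expect_lt(max(abs(rowMeans(pooled))), 1e-10)
  expect_lt(max(abs(apply(pooled, 1, sd) - 1)), 1e-6)
  # within-animal SD deliberately differs: relative amplitude preserved
  expect_gt(sd(out[[3]]$signals[1, ]), sd(out[[1]]$signals[1, ]))
})

test_that("epoch segmentation follows the drop-remainder contract", {
  mk <- function(seconds) lfp_recording(matrix(rnorm(200 * seconds), 1),
                                        fs = 200)
  set.seed(4)
  expect_equal(dim(segment_epochs(mk(600), 5)$epochs)[1], 120)
  expect_equal(dim(segment_epochs(mk(5), 5)$epochs)[1], 1)
  expect_equal(dim(segment_epochs(mk(12.5), 5)$epochs)[1], 2)
  expect_error(segment_epochs(mk(3), 5), "shorter")
})

test_that("epochs concatenate back to the original samples exactly", {
  set.seed(5)
  rec <- lfp_recording(matrix(rnorm(12000), 2), 200)
  eps <- segment_epochs(rec, 5)
  back <- concatenate_epochs(eps)
  expect_identical(dim(back$signals), c(2L, 6000L))
  expect_equal(back$signals, rec$signals, ignore_attr = TRUE)
})

test_that("artifact rejection removes exactly the contaminated epochs", {
  set.seed(6)
  rec <- lfp_recording(matrix(rnorm(2 * 200 * 60), 2), 200)
  eps <- segment_epochs(normalize_recordings(rec), 5)
  clean <- reject_artifacts(eps, 6)
  expect_equal(clean$n_rejected, 0L)

  dirty <- eps
  dirty$epochs[4, 1, 100:150] <- dirty$epochs[4, 1, 100:150] + 10
  pruned <- reject_artifacts(dirty, 6)
  expect_equal(pruned$n_rejected, 1L)
  expect_equal(unique(pruned$rejection_log$epoch), 4)
  expect_equal(dim(pruned$epochs)[1], dim(eps$epochs)[1] - 1)
  # surviving epochs keep their order
  expect_equal(pruned$epochs[4, , ], eps$epochs[5, , ])

  same <- reject_artifacts(dirty, Inf)
  expect_equal(same$epochs, dirty$epochs)

  all_bad <- eps
  all_bad$epochs <- all_bad$epochs + 100
  expect_error(reject_artifacts(all_bad, 6), "all epochs rejected")
})

test_that("the full chain yields 120 clean epochs from ten contaminated minutes", {
  truth <- var_ground_truth(list(diag(c(0.8, 0.7))),
                            region_labels = c("PRL", "IL"))
  rec <- simulate_var_recording(truth, nuisance_spec(line_amp = 0.5),
                                duration = 600, fs = 1017, seed = 9)
  eps <- preprocess_recording(rec, target_fs = 200, notch = 50,
                              epoch_len = 5, z_thresh = 6)
  expect_equal(dim(eps$epochs)[1], 120)
  expect_equal(eps$fs, 200)
  # the notch actually removed the line: check residual 50 Hz power
  cat_sig <- concatenate_epochs(eps)$signals[1, ]
  p50 <- periodogram_power(cat_sig, 200, 50)
  p45 <- periodogram_power(cat_sig, 200, 45.3)
  expect_lt(p50 / length(cat_sig), 0.05)
  expect_identical(eps$preprocess_log$order,
                   c("downsample", "notch", "normalize", "epoch", "reject"))
})
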