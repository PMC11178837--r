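# Zero-phase FIR low-pass: Hamming windowed-sinc (odd tap count, so the
# group delay is an integer), coefficients normalised for exactly unit
# DC gain, reflection padding so edges carry no start-up transient.
fir_lowpass_zerophase <- function(x, fs, cutoff, ntaps = 201) {
  ntaps <- min(ntaps, 2 * (length(x) %/% 4) + 1)
  if (ntaps %% 2 == 0) ntaps <- ntaps - 1
  b <- signal::fir1(ntaps - 1, cutoff / (fs / 2), type = "low")
  b <- b / sum(b)
  d <- (ntaps - 1) %/% 2
  n <- length(x)
  pad_l <- 2 * x[1] - x[(d + 1):2]
  pad_r <- 2 * x[n] - x[(n - 1):(n - d)]
  y <- signal::fftfilt(b, c(pad_l, x, pad_r))
  y[(2 * d + 1):(2 * d + n)]
}

#' Down-sample a recording with anti-alias filtering
#'
#' Applies a zero-phase windowed-sinc FIR low-pass with cutoff at the
#' new Nyquist frequency, then resamples by cubic-spline interpolation
#' on the new time grid.  The output has exactly
#' `floor(duration * target_fs)` samples.  The FIR transition band is a
#' few Hz either side of the cutoff, so components at 80% of the new
#' Nyquist pass within 1 dB while anything beyond the transition band is
#' attenuated by more than 50 dB before resampling.
#'
#' @param rec an [lfp_recording()].
#' @param target_fs new sampling rate in Hz; must be below `rec$fs`.
#' @return A down-sampled `lfp_recording`.
#' @export
downsample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (target_fs >= rec$fs)
    stop("target_fs must be below the current sampling rate")
  n_in <- ncol(rec$signals)
  dur <- n_in / rec$fs
  n_out <- floor(dur * target_fs)
  t_in <- (seq_len(n_in) - 1) / rec$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  out <- matrix(0, nrow(rec$signals), n_out)
  for (i in seq_len(nrow(rec$signals))) {
    x <- fir_lowpass_zerophase(rec$signals[i, ], rec$fs, target_fs / 2)
    out[i, ] <- spline(t_in, x, xout = t_out, method = "fmm")$y
  }
  lfp_recording(out, fs = target_fs, region_labels = rec$region_labels,
                animal_id = rec$animal_id, genotype = rec$genotype)
}

# second-order IIR notch (constrained biquad), unity gain away from f0
design_notch <- function(freq, bandwidth, fs) {
  w0 <- 2 * pi * freq / fs
  Q <- freq / bandwidth
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Notch-filter a recording
#'
#' Removes narrow-band line contamination with a second-order IIR notch
#' applied forward and backward (zero phase).  The default 2 Hz
#' bandwidth keeps the flanking gamma bands (35-45 and 55-75 Hz)
#' untouched when notching 50 Hz.
#'
#' @param rec an [lfp_recording()].
#' @param freq notch centre in Hz; must lie below Nyquist.
#' @param bandwidth -3 dB width in Hz.
#' @return The filtered `lfp_recording`.
#' @export
notch_filter <- function(rec, freq = 50, bandwidth = 2) {
  stopifnot(inherits(rec, "lfp_recording"))
  if (freq <= 0 || freq >= rec$fs / 2)
    stop("notch frequency must lie in (0, fs/2)")
  flt <- design_notch(freq, bandwidth, rec$fs)
  out <- rec
  for (i in seq_len(nrow(rec$signals)))
    out$signals[i, ] <- signal::filtfilt(flt$b, flt$a, rec$signals[i, ])
  out
}

#' De-mean and normalise recordings
#'
#' Z-scores signals so every site enters the VAR on a common scale.
#' `scope = "per_recording"` (default) standardises each channel within
#' its recording; `scope = "global"` standardises each site by the mean
#' and SD pooled across all recordings, so relative amplitude
#' differences between animals are preserved.
#'
#' @param recs a list of [lfp_recording()]s (or a single recording).
#' @param scope `"per_recording"` or `"global"`.
#' @return A list of normalised recordings (or a single recording if a
#'   single one was supplied).
#' @export
normalize_recordings <- function(recs, scope = c("per_recording", "global")) {
  scope <- match.arg(scope)
  single <- inherits(recs, "lfp_recording")
  if (single) recs <- list(recs)
  if (!length(recs)) stop("empty collection of recordings")
  for (r in recs) {
    sds <- apply(r$signals, 1, sd)
    if (any(sds == 0))
      stop("zero-variance channel in ", r$animal_id, ": ",
           paste(r$region_labels[sds == 0], collapse = ", "))
  }
  if (scope == "per_recording") {
    out <- lapply(recs, function(r) {
      r$signals <- t(scale(t(r$signals)))[, , drop = FALSE]
      attr(r$signals, "scaled:center") <- NULL
      attr(r$signals, "scaled:scale") <- NULL
      rownames(r$signals) <- r$region_labels
      r
    })
  } else {
    labels <- recs[[1]]$region_labels
    pooled <- lapply(seq_along(labels), function(i)
      unlist(lapply(recs, function(r) r$signals[i, ])))
    mu <- vapply(pooled, mean, 0)
    sig <- vapply(pooled, sd, 0)
    out <- lapply(recs, function(r) {
      r$signals <- (r$signals - mu) / sig
      r
    })
  }
  if (single) out[[1]] else out
}

#' Segment a recording into fixed-length epochs
#'
#' Contiguous, non-overlapping epochs from the start of the recording;
#' a trailing remainder shorter than `epoch_len` is dropped.  Epoch k
#' covers the half-open sample interval `[k*L, (k+1)*L)` (0-based).
#'
#' @param rec an [lfp_recording()].
#' @param epoch_len epoch length in seconds (default 5).
#' @return An `epoch_set`: list with `epochs` (epoch x channel x sample
#'   array), `fs`, `epoch_len`, metadata, and an empty rejection log.
#' @export
segment_epochs <- function(rec, epoch_len = 5) {
  stopifnot(inherits(rec, "lfp_recording"))
  L <- round(epoch_len * rec$fs)
  n_samp <- ncol(rec$signals)
  if (n_samp < L) stop("recording shorter than one epoch")
  n_ep <- floor(n_samp / L)
  eps <- array(0, dim = c(n_ep, nrow(rec$signals), L),
               dimnames = list(NULL, rec$region_labels, NULL))
  for (k in seq_len(n_ep))
    eps[k, , ] <- rec$signals[, ((k - 1) * L + 1):(k * L)]
  structure(
    list(epochs = eps, fs = rec$fs, epoch_len = epoch_len,
         region_labels = rec$region_labels, animal_id = rec$animal_id,
         genotype = rec$genotype, n_rejected = 0L,
         rejection_log = data.frame(epoch = integer(), channel = character(),
                                    reason = character())),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs)
  cat(sprintf("<epoch_set> %s (%s): %d epochs x %d channels x %d samples (%g s @ %g Hz), %d rejected\n",
              x$animal_id, x$genotype, d[1], d[2], d[3], x$epoch_len, x$fs,
              x$n_rejected))
  invisible(x)
}

#' @export
#' @method duration epoch_set
duration.epoch_set <- function(x) dim(x$epochs)[1] * x$epoch_len

#' Reject epochs containing high-amplitude artifacts
#'
#' Removes every epoch in which any sample of any channel exceeds
#' `z_threshold` in absolute value (signals are assumed normalised, so
#' the threshold is in SD units).  The order of surviving epochs is
#' preserved and the rejection log records each removed epoch and its
#' offending channels.  Rejecting everything is an error: the pipeline
#' must not silently proceed on an empty epoch set.
#'
#' @param eps an `epoch_set`.
#' @param z_threshold rejection threshold in SD units (default 6, which
#'   makes false rejections on clean Gaussian data essentially
#'   impossible at 5 s x 200 Hz epochs).
#' @return The pruned `epoch_set`, with `n_rejected` and
#'   `rejection_log` updated.
#' @export
reject_artifacts <- function(eps, z_threshold = 6) {
  stopifnot(inherits(eps, "epoch_set"))
  if (!is.numeric(z_threshold) || z_threshold <= 0)
    stop("z_threshold must be positive")
  d <- dim(eps$epochs)
  bad <- logical(d[1])
  log_rows <- list()
  for (k in seq_len(d[1])) {
    mx <- apply(abs(eps$epochs[k, , , drop = FALSE]), 2, max)
    offend <- which(mx > z_threshold)
    if (length(offend)) {
      bad[k] <- TRUE
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        epoch = k, channel = eps$region_labels[offend],
        reason = sprintf("|z| > %g (max %.2f)", z_threshold, max(mx)))
    }
  }
  if (all(bad))
    stop("all epochs rejected at |z| > ", z_threshold,
         "; refusing to proceed with an empty epoch set")
  eps$epochs <- eps$epochs[!bad, , , drop = FALSE]
  eps$n_rejected <- eps$n_rejected + sum(bad)
  if (length(log_rows))
    eps$rejection_log <- rbind(eps$rejection_log, do.call(rbind, log_rows))
  eps
}

#' Full preprocessing chain for one recording
#'
#' Fixed stage order: down-sample, notch, z-score, epoch, reject.  The
#' applied parameters are recorded in the returned epoch set's
#' `preprocess_log`.
#'
#' @param rec an [lfp_recording()].
#' @param target_fs analysis sampling rate (Hz).
#' @param notch line frequency to remove (Hz); `NULL` skips notching.
#' @param notch_bw notch bandwidth (Hz).
#' @param epoch_len epoch length (s).
#' @param z_thresh artifact-rejection threshold (SD units).
#' @return An `epoch_set` ready for VAR fitting.
#' @export
preprocess_recording <- function(rec, target_fs = 200, notch = 50,
                                 notch_bw = 2, epoch_len = 5, z_thresh = 6) {
  out <- downsample_recording(rec, target_fs)
  if (!is.null(notch)) out <- notch_filter(out, notch, notch_bw)
  out <- normalize_recordings(out)
  eps <- segment_epochs(out, epoch_len)
  eps <- reject_artifacts(eps, z_thresh)
  eps$preprocess_log <- list(target_fs = target_fs, notch = notch,
                             notch_bw = notch_bw, epoch_len = epoch_len,
                             z_thresh = z_thresh,
                             order = c("downsample", "notch", "normalize",
                                       "epoch", "reject"))
  eps
}

#' Concatenate the epochs of an epoch set back into a recording
#'
#' Inverse of [segment_epochs()] for clean data (exact round trip of
#' sample values).
#'
#' @param eps an `epoch_set`.
#' @return An [lfp_recording()].
#' @export
concatenate_epochs <- function(eps) {
  stopifnot(inherits(eps, "epoch_set"))
  d <- dim(eps$epochs)
  sig <- matrix(0, d[2], d[1] * d[3])
  for (k in seq_len(d[1]))
    sig[, ((k - 1) * d[3] + 1):(k * d[3])] <- eps$epochs[k, , ]
  lfp_recording(sig, fs = eps$fs, region_labels = eps$region_labels,
                animal_id = eps$animal_id, genotype = eps$genotype)
}
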