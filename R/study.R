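#' Simulate a cohort of animals straight to band-limited GC
#'
#' Convenience wrapper for simulation studies (power and calibration of
#' the group comparison): per animal, draws a clean VAR recording at the
#' analysis sampling rate (no nuisance components, so no preprocessing
#' beyond epoching is required), fits the VAR at a fixed order and
#' computes band-limited conditional GC.
#'
#' @param truth generative [var_ground_truth()].
#' @param n_animals animals to simulate.
#' @param n_epochs epochs per animal.
#' @param epoch_len epoch length (s).
#' @param fs analysis sampling rate (Hz).
#' @param order VAR order fitted (defaults to the truth's order).
#' @param freq frequency grid in Hz (default 0.5 Hz over (0, 100]).
#' @param bands band table.
#' @param genotype genotype label attached to all animals.
#' @param seed base seed; animal i uses substream `fan_seed(seed, genotype, i)`.
#' @param id_prefix animal id prefix.
#' @return Tidy band-GC table (see [band_gc()]).
#' @export
simulate_band_cohort <- function(truth, n_animals, n_epochs = 40,
                                 epoch_len = 5, fs = 200, order = NULL,
                                 freq = NULL, bands = canonical_bands(),
                                 genotype = "WT", seed = 1,
                                 id_prefix = genotype) {
  if (is.null(order)) order <- truth$order
  if (is.null(freq)) freq <- seq(0.5, min(100, fs / 2), by = 0.5)
  tabs <- vector("list", n_animals)
  for (i in seq_len(n_animals)) {
    rec <- simulate_var_recording(
      truth, nuisance_spec(), duration = n_epochs * epoch_len, fs = fs,
      seed = fan_seed(seed, genotype, i),
      animal_id = sprintf("%s%02d", id_prefix, i), genotype = genotype)
    rec <- normalize_recordings(rec)
    eps <- segment_epochs(rec, epoch_len)
    model <- fit_var(eps, order)
    sgc <- spectral_gc(model, freq = freq)
    tabs[[i]] <- band_gc(sgc, bands = bands, animal_id = rec$animal_id,
                         genotype = genotype)
  }
  do.call(rbind, tabs)
}
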