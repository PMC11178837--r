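# 32-bit FNV-1a hash of a character string, as hex; used to stamp every
# pipeline output with its configuration
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), b)
    # 32-bit modular multiply, split to stay within double precision
    lo <- h %% 65536; hi <- (h - lo) / 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# deterministic per-stage, per-unit substream seed: depends only on the
# global seed, a stage tag and the unit index, so adding an animal never
# reshuffles the streams of the others
fan_seed <- function(seed, stage, index = 0) {
  tag <- sum(as.integer(charToRaw(stage)) * seq_along(charToRaw(stage)))
  as.integer((as.numeric(seed) * 1009 + tag * 131071 + index * 7919) %%
               (2^31 - 1)) + 1L
}

#' Pipeline configuration
#'
#' Bundles every stage parameter of the resting-state
#' connectivity pipeline plus the synthetic-cohort settings, validates
#' them up front (before any computation), and carries the global seed.
#' The configuration hash stamps every output file, so re-running with
#' any changed parameter changes the hash.
#'
#' @param n_wt,n_het animals per genotype.
#' @param duration,fs_acquisition recording length (s) and acquisition
#'   rate (Hz) for the synthetic recordings.
#' @param nuisance a [nuisance_spec()].
#' @param truth_wt,truth_het generative [var_ground_truth()]s.
#' @param target_fs,notch,notch_bw,epoch_len,z_thresh preprocessing
#'   parameters (see [preprocess_recording()]).
#' @param max_order,fixed_order VAR order selection (AIC search bound,
#'   or a fixed order bypassing AIC).
#' @param freq_step frequency-grid spacing in Hz over (0, 100].
#' @param bands band table (see [canonical_bands()]).
#' @param band_reduce `"integral"` or `"mean"`.
#' @param qc_action adequacy gating (see [gc_cohort()]).
#' @param mode comparison mode, `"broadband"` or `"per_band"`.
#' @param alpha,fdr_method FDR settings.
#' @param behavior_spec a [behavior_cohort_spec()] or `NULL` to skip the
#'   behavioural branch.
#' @param final_session session used for the discrimination ratio.
#' @param seed global seed, fanned out to per-stage substreams.
#' @return A validated list of class `pipeline_config` with a
#'   `config_hash` attribute.
#' @export
pipeline_config <- function(n_wt = 14, n_het = 11,
                            duration = 600, fs_acquisition = 1017,
                            nuisance = nuisance_spec(line_amp = 0.5,
                                                     artifact_rate = 1),
                            truth_wt = default_ground_truth(),
                            truth_het = default_ground_truth(),
                            target_fs = 200, notch = 50, notch_bw = 2,
                            epoch_len = 5, z_thresh = 6,
                            max_order = 30, fixed_order = NULL,
                            freq_step = 0.25, bands = canonical_bands(),
                            band_reduce = "integral",
                            qc_action = "enforce",
                            mode = "broadband", alpha = 0.05,
                            fdr_method = "BH",
                            behavior_spec = behavior_cohort_spec(),
                            final_session = NULL, seed = 1) {
  check_bands(bands, fmax = min(100, target_fs / 2))
  if (target_fs >= fs_acquisition)
    stop("target_fs must be below fs_acquisition")
  if (!is.null(notch) && notch >= target_fs / 2)
    stop("notch frequency must survive down-sampling (below target Nyquist)")
  stopifnot(inherits(truth_wt, "var_truth"), inherits(truth_het, "var_truth"),
            inherits(nuisance, "nuisance_spec"))
  if (is.null(final_session) && !is.null(behavior_spec))
    final_session <- behavior_spec$n_sessions
  cfg <- list(n_wt = n_wt, n_het = n_het, duration = duration,
              fs_acquisition = fs_acquisition, nuisance = nuisance,
              truth_wt = truth_wt, truth_het = truth_het,
              target_fs = target_fs, notch = notch, notch_bw = notch_bw,
              epoch_len = epoch_len, z_thresh = z_thresh,
              max_order = max_order, fixed_order = fixed_order,
              freq_step = freq_step, bands = bands,
              band_reduce = band_reduce, qc_action = qc_action,
              mode = mode, alpha = alpha, fdr_method = fdr_method,
              behavior_spec = behavior_spec, final_session = final_session,
              seed = seed)
  class(cfg) <- "pipeline_config"
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

#' Configuration hash
#' @param config a `pipeline_config` (or any serialisable list).
#' @return 8-hex-digit hash of the YAML serialisation.
#' @export
config_hash <- function(config) {
  ser <- yaml::as.yaml(rapply(unclass(config), function(x)
    if (is.numeric(x)) signif(x, 12) else x, how = "replace"))
  fnv1a_hash(ser)
}

#' Simulate the LFP cohort of a pipeline configuration
#'
#' One recording per animal from the genotype's ground truth, with
#' per-animal seeds fanned out from the global seed.
#'
#' @param config a [pipeline_config()].
#' @return List of [lfp_recording()]s.
#' @export
simulate_cohort <- function(config) {
  recs <- list()
  for (i in seq_len(config$n_wt))
    recs[[length(recs) + 1L]] <- simulate_var_recording(
      config$truth_wt, config$nuisance, duration = config$duration,
      fs = config$fs_acquisition, seed = fan_seed(config$seed, "sim_wt", i),
      animal_id = sprintf("WT%02d", i), genotype = "WT")
  for (i in seq_len(config$n_het))
    recs[[length(recs) + 1L]] <- simulate_var_recording(
      config$truth_het, config$nuisance, duration = config$duration,
      fs = config$fs_acquisition, seed = fan_seed(config$seed, "sim_het", i),
      animal_id = sprintf("HET%02d", i), genotype = "HET")
  recs
}

#' Run the full pipeline
#'
#' Executes simulate (or ingest) -> preprocess -> VAR -> spectral GC ->
#' band integration -> group comparison, plus the behavioural branch,
#' writing every result table as CSV into `out_dir` together with a
#' manifest recording the configuration and its hash.  Idempotent for a
#' fixed config and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @param recordings optionally, a pre-built list of
#'   [lfp_recording()]s to analyse instead of simulating.
#' @return A list of class `pipeline_result`: `band_gc`, `qc`,
#'   `comparison`, `summary`, `behavior` (sessions, acquisition,
#'   discrimination), `config_hash`.
#' @export
run_pipeline <- function(config, out_dir = NULL, recordings = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- attr(config, "config_hash")
  if (is.null(recordings)) recordings <- simulate_cohort(config)

  eps <- lapply(recordings, function(rec)
    preprocess_recording(rec, target_fs = config$target_fs,
                         notch = config$notch, notch_bw = config$notch_bw,
                         epoch_len = config$epoch_len,
                         z_thresh = config$z_thresh))
  freq <- seq(config$freq_step, min(100, config$target_fs / 2),
              by = config$freq_step)
  coh <- gc_cohort(eps, max_order = config$max_order,
                   order = config$fixed_order, freq = freq,
                   bands = config$bands, reduce = config$band_reduce,
                   qc_action = config$qc_action)
  cmp <- compare_network(coh$band_gc, mode = config$mode,
                         alpha = config$alpha,
                         fdr_method = config$fdr_method)
  summ <- network_summary(coh$band_gc, cmp)

  behav <- NULL
  if (!is.null(config$behavior_spec)) {
    spec <- config$behavior_spec
    spec$seed <- fan_seed(config$seed, "behavior")
    sessions <- simulate_behavior_cohort(spec)
    behav <- list(sessions = sessions,
                  acquisition = acquisition_curves(sessions),
                  discrimination = session_discrimination(
                    sessions, session = config$final_session),
                  per_cue = per_cue_breakdown(sessions,
                                              config$final_session))
  }

  res <- structure(list(band_gc = coh$band_gc, qc = coh$qc,
                        comparison = cmp, summary = summ, behavior = behav,
                        config_hash = hash),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, config, out_dir)
  res
}

write_pipeline_result <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) { df$config_hash <- res$config_hash; df }
  write.csv(stamp(res$band_gc), file.path(out_dir, "bandgc.csv"),
            row.names = FALSE)
  write.csv(stamp(res$qc), file.path(out_dir, "qc.csv"), row.names = FALSE)
  write.csv(stamp(res$comparison$table),
            file.path(out_dir, "comparison.csv"), row.names = FALSE)
  write.csv(stamp(res$summary$medians),
            file.path(out_dir, "network_medians.csv"), row.names = FALSE)
  if (!is.null(res$behavior)) {
    write.csv(stamp(res$behavior$sessions),
              file.path(out_dir, "behavior_sessions.csv"), row.names = FALSE)
    write.csv(stamp(res$behavior$discrimination),
              file.path(out_dir, "discrimination.csv"), row.names = FALSE)
  }
  manifest <- list(config_hash = res$config_hash,
                   package_version = as.character(utils::packageVersion("varconn")),
                   mode = config$mode, seed = config$seed,
                   n_wt = config$n_wt, n_het = config$n_het,
                   family_size = res$comparison$family_size,
                   files = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read / write a pipeline configuration as YAML
#'
#' Ground truths and the behaviour spec are serialised field-by-field so
#' the round trip reproduces an identical configuration (and hash).
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `path` (write) or the restored `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  obj <- unclass(config)
  obj$truth_wt <- truth_to_list(config$truth_wt)
  obj$truth_het <- truth_to_list(config$truth_het)
  obj$nuisance <- unclass(config$nuisance)
  obj$behavior_spec <- if (is.null(config$behavior_spec)) NULL else
    unclass(config$behavior_spec)
  yaml::write_yaml(obj, path)
  invisible(path)
}

truth_to_list <- function(truth) {
  rows <- function(m) apply(unname(m), 1, c, simplify = FALSE)
  list(coeffs = lapply(truth$coeffs, rows),
       noise_cov = rows(truth$noise_cov),
       region_labels = truth$region_labels)
}

truth_from_list <- function(x) {
  coeffs <- lapply(x$coeffs, function(rows) do.call(rbind, rows))
  var_ground_truth(coeffs, noise_cov = do.call(rbind, x$noise_cov),
                   region_labels = x$region_labels)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$truth_wt <- truth_from_list(obj$truth_wt)
  obj$truth_het <- truth_from_list(obj$truth_het)
  obj$nuisance <- do.call(nuisance_spec, obj$nuisance)
  if (!is.null(obj$behavior_spec)) {
    bs <- obj$behavior_spec
    bs$final_rates <- lapply(bs$final_rates, function(g) lapply(g, unlist))
    obj$behavior_spec <- do.call(behavior_cohort_spec, bs)
  }
  obj$bands <- as.data.frame(obj$bands, stringsAsFactors = FALSE)
  do.call(pipeline_config, obj)
}
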