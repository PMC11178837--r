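#' LFP recording container
#'
#' A continuous multichannel recording: a channels x samples signal
#' matrix together with its sampling rate and site metadata.  This is the
#' unit that flows through the preprocessing stages.
#'
#' @param signals numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param region_labels character vector naming each channel (e.g. the
#'   six recorded sites `PRL, IL, NAcC, NAcS, dCA1, vCA1`).
#' @param animal_id identifier for the animal.
#' @param genotype group label, conventionally `"WT"` or `"HET"`.
#'
#' @return An object of class `lfp_recording`.
#' @export
lfp_recording <- function(signals, fs, region_labels = rownames(signals),
                          animal_id = "animal1", genotype = "WT") {
  signals <- as.matrix(signals)
  if (!is.numeric(signals)) stop("signals must be numeric")
  if (!all(is.finite(signals))) stop("signals contain non-finite samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar")
  if (is.null(region_labels)) region_labels <- paste0("ch", seq_len(nrow(signals)))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(signals))
    stop("need one region label per channel")
  rownames(signals) <- region_labels
  structure(
    list(signals = signals, fs = fs, region_labels = region_labels,
         animal_id = as.character(animal_id), genotype = as.character(genotype)),
    class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %s (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$animal_id, x$genotype, nrow(x$signals), ncol(x$signals),
              x$fs, ncol(x$signals) / x$fs))
  cat("  channels:", paste(x$region_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @method duration lfp_recording
duration.lfp_recording <- function(x) ncol(x$signals) / x$fs

#' Duration of a recording or epoch set, in seconds
#' @param x an `lfp_recording` or `epoch_set`.
#' @export
duration <- function(x) UseMethod("duration")

#' Write / read a recording as plain text
#'
#' The signal matrix is stored as a samples x channels CSV (one column
#' per site) and the metadata (`fs`, `animal_id`, `genotype`,
#' `region_labels`, and any provenance fields supplied) as a JSON
#' sidecar `<path>.meta.json`.
#'
#' @param rec an `lfp_recording`.
#' @param path CSV file path.
#' @param extra named list of extra metadata stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path, extra = list()) {
  stopifnot(inherits(rec, "lfp_recording"))
  df <- as.data.frame(t(rec$signals))
  names(df) <- rec$region_labels
  write.csv(df, path, row.names = FALSE)
  meta <- c(list(fs = rec$fs, region_labels = rec$region_labels,
                 animal_id = rec$animal_id, genotype = rec$genotype), extra)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  df <- read.csv(path, check.names = FALSE)
  lfp_recording(t(as.matrix(df)), fs = meta$fs,
                region_labels = meta$region_labels,
                animal_id = meta$animal_id, genotype = meta$genotype)
}
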