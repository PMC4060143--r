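#' Labeled multichannel recording
#'
#' The basic container passed between pipeline stages: a channels-by-samples
#' amplitude matrix with sampling rate, channel labels, a channel-to-region
#' map, and session metadata (condition label, subject id, modality).
#' EEG amplitudes are in microvolts; respiration is in arbitrary belt units.
#'
#' @param samples numeric matrix, channels x samples; `rownames` may carry the
#'   channel labels.
#' @param fs sampling rate in Hz, positive.
#' @param channel_labels character vector, one label per row.
#' @param region_map named character vector mapping channel labels to regions;
#'   required for EEG region-level analyses, may be `NULL` for respiration.
#' @param condition `"meditation"`, `"control"` or `NA`.
#' @param subject_id subject identifier.
#' @param modality `"eeg"` or `"respiration"`.
#' @param units amplitude units (default `"uV"`).
#' @return an object of class `"recording"`.
#' @export
recording <- function(samples, fs, channel_labels = rownames(samples),
                      region_map = NULL, condition = NA_character_,
                      subject_id = NA_character_, modality = "eeg",
                      units = "uV") {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (length(fs) != 1 || !is.finite(fs) || fs <= 0) stop("fs must be a positive number")
  if (anyNA(samples) || any(!is.finite(samples))) stop("samples must be finite with no missing values")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_labels) != nrow(samples)) stop("one label per channel row required")
  if (!is.null(region_map)) {
    missing_ch <- setdiff(channel_labels, names(region_map))
    if (identical(modality, "eeg") && length(missing_ch) > 0)
      stop("channels without a region: ", paste(missing_ch, collapse = ", "))
    region_map <- region_map[intersect(names(region_map), channel_labels)]
  }
  if (!is.na(condition)) condition <- match.arg(condition, c("meditation", "control"))
  rownames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs, channel_labels = channel_labels,
         region_map = region_map, condition = condition,
         subject_id = subject_id, modality = modality, units = units),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s | %d ch x %d samples @ %g Hz (%.1f s) | subject=%s condition=%s\n",
              x$modality, nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, x$subject_id, x$condition))
  invisible(x)
}

#' @export
#' @rdname recording
n_samples <- function(rec) ncol(rec$samples)

#' @export
#' @rdname recording
rec_duration <- function(rec) ncol(rec$samples) / rec$fs

# Replace the sample matrix, keeping metadata (and updated fs) consistent.
with_samples <- function(rec, samples, fs = rec$fs) {
  rec$samples <- samples
  rownames(rec$samples) <- rec$channel_labels
  rec$fs <- fs
  rec
}
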