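# Minimal EDF (16-bit write/read) and BDF (24-bit read) codec. Implements just
# the subset of the European Data Format needed to round-trip sessions: fixed
# 256-byte main header, one 256-byte signal header per channel, integer
# samples scaled by the physical/digital ranges, 1-second data records.

edf_pad <- function(s, width) {
  s <- substr(as.character(s), 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

edf_num <- function(x, width) edf_pad(formatC(x, format = "g", digits = 7), width)

#' Write a recording (or EEG + respiration session) to EDF
#'
#' Samples are scaled to 16-bit integers over a symmetric physical range per
#' channel (quantization error at most `range/32767`). The final partial
#' 1-second record is zero-padded; the true sample count, generating metadata
#' and units go to a JSON sidecar (`<path>.json`) which [read_session()] uses
#' to trim and relabel.
#'
#' @param rec a [recording()], or a session list with `eeg` and `resp`
#'   recordings sharing one sampling rate.
#' @param path output file path.
#' @param sidecar write the JSON sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, sidecar = TRUE) {
  if (!inherits(rec, "recording") && is.list(rec) && !is.null(rec$eeg)) {
    eeg <- rec$eeg; resp <- rec$resp
    if (!is.null(resp) && resp$fs != eeg$fs) stop("eeg and resp rates differ")
    samples <- rbind(eeg$samples, if (!is.null(resp)) resp$samples)
    labels <- c(eeg$channel_labels, if (!is.null(resp)) resp$channel_labels)
    units <- c(rep(eeg$units, nrow(eeg$samples)),
               if (!is.null(resp)) rep(resp$units, nrow(resp$samples)))
    fs <- eeg$fs; condition <- eeg$condition; subject <- eeg$subject_id
  } else {
    stopifnot(inherits(rec, "recording"))
    samples <- rec$samples; labels <- rec$channel_labels
    units <- rep(rec$units, nrow(samples)); fs <- rec$fs
    condition <- rec$condition; subject <- rec$subject_id
  }
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer needs an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(samples); n <- ncol(samples)
  n_rec <- as.integer(ceiling(n / fs))
  if (n_rec * fs > n) samples <- cbind(samples, matrix(0, ns, n_rec * fs - n))

  pm <- apply(abs(samples), 1, max)
  pm <- ifelse(pm == 0, 1, pm * 1.0001)
  dig <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(paste0("subject ", subject), 80),
    edf_pad(paste0("condition ", condition), 80),
    "01.01.26", "00.00.00",
    edf_pad((ns + 1) * 256, 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_num(1, 8),
    edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(f, w) writeChar(paste0(vapply(f, edf_pad, "", width = w),
                                           collapse = ""), con, eos = NULL)
  field(labels, 16)
  field(rep("", ns), 80)
  field(units, 8)
  field(formatC(-pm, format = "g", digits = 7), 8)
  field(formatC(pm, format = "g", digits = 7), 8)
  field(rep(-dig, ns), 8)
  field(rep(dig, ns), 8)
  field(rep("", ns), 80)
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)

  scale <- dig / pm
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      v <- as.integer(round(samples[i, idx] * scale[i]))
      writeBin(v, con, size = 2, endian = "little")
    }
  }
  if (sidecar) {
    meta <- list(n_samples = n, fs = fs, channel_labels = labels,
                 units = units, condition = condition, subject_id = subject)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read an EDF or BDF file
#'
#' Detects BDF by the BioSemi magic byte and decodes its 24-bit samples;
#' otherwise 16-bit EDF. Amplitudes are rescaled by each signal's
#' physical/digital gain.
#'
#' @param path file path.
#' @return list: `samples` (channels x samples), `fs`, `labels`, `units`,
#'   `format` (`"edf"` or `"bdf"`).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  is_bdf <- magic[1] == as.raw(255) &&
    rawToChar(magic[2:8]) == "BIOSEMI"
  rd <- function(w) trimws(rawToChar(readBin(con, "raw", w)))
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16)
  fields(80)
  units <- fields(8)
  pmin_ <- as.numeric(fields(8))
  pmax_ <- as.numeric(fields(8))
  dmin_ <- as.numeric(fields(8))
  dmax_ <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1) stop("heterogeneous per-signal rates not supported")
  fs <- spr[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  offset <- pmax_ - gain * dmax_
  samples <- matrix(0, ns, n_rec * spr[1])
  if (is_bdf) {
    for (r in seq_len(n_rec)) {
      for (i in seq_len(ns)) {
        b <- readBin(con, "raw", 3 * spr[1])
        m <- matrix(as.integer(b), nrow = 3)
        v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)  # sign-extend 24 bit
        samples[i, ((r - 1) * spr[1] + 1):(r * spr[1])] <- v * gain[i] + offset[i]
      }
    }
  } else {
    for (r in seq_len(n_rec)) {
      for (i in seq_len(ns)) {
        v <- readBin(con, "integer", spr[1], size = 2, endian = "little")
        samples[i, ((r - 1) * spr[1] + 1):(r * spr[1])] <- v * gain[i] + offset[i]
      }
    }
  }
  rownames(samples) <- labels
  list(samples = samples, fs = fs, labels = labels, units = units,
       format = if (is_bdf) "bdf" else "edf")
}

#' Read a session file into recordings
#'
#' Splits EEG channels from the respiration channel (label `"Resp"`), maps
#' EEG labels onto the 32-channel montage (unknown labels are dropped with a
#' warning and the region map restricted to the labels present), and trims the
#' zero-padded tail using the JSON sidecar when available.
#'
#' @param path an EDF/BDF file written by [write_edf()] or compatible.
#' @param condition,subject_id metadata overrides (default: sidecar values).
#' @return list with `eeg` and `resp` [recording()]s (`resp` may be `NULL`).
#' @export
read_session <- function(path, condition = NULL, subject_id = NULL) {
  raw <- read_edf(path)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n <- meta$n_samples %||% ncol(raw$samples)
  condition <- condition %||% meta$condition %||% NA_character_
  subject_id <- subject_id %||% meta$subject_id %||% NA_character_
  if (!is.null(condition) && is.na(condition)) condition <- NA_character_
  samples <- raw$samples[, seq_len(n), drop = FALSE]

  resp_idx <- which(raw$labels == "Resp")
  eeg_idx <- setdiff(seq_along(raw$labels), resp_idx)
  known <- raw$labels[eeg_idx] %in% biosemi32_labels()
  if (any(!known)) {
    warning("dropping unknown channel labels: ",
            paste(raw$labels[eeg_idx][!known], collapse = ", "))
    eeg_idx <- eeg_idx[known]
  }
  eeg <- recording(samples[eeg_idx, , drop = FALSE], raw$fs,
                   channel_labels = raw$labels[eeg_idx],
                   region_map = biosemi32_regions(),
                   condition = condition, subject_id = subject_id,
                   modality = "eeg", units = "uV")
  resp <- NULL
  if (length(resp_idx) == 1) {
    resp <- recording(samples[resp_idx, , drop = FALSE], raw$fs,
                      channel_labels = "Resp", condition = condition,
                      subject_id = subject_id, modality = "respiration",
                      units = "a.u.")
  }
  list(eeg = eeg, resp = resp)
}
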