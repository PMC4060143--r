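#' Wrapped phase difference between two channels
#'
#' `theta = phi_i - phi_j`, wrapped to `(-pi, pi]`. Inputs must share the same
#' time/frequency grid (equal dimensions).
#'
#' @param phase_i,phase_j numeric vectors or matrices of instantaneous phase.
#' @return wrapped phase differences with the same shape.
#' @export
phase_difference <- function(phase_i, phase_j) {
  if (!identical(dim(phase_i), dim(phase_j)) ||
      length(phase_i) != length(phase_j))
    stop("phase grids do not match")
  d <- phase_i - phase_j
  -(((-d + pi) %% (2 * pi)) - pi)
}

#' Phase-lock value over a sliding rectangular window
#'
#' `PLV(n] = (1/L) |sum over the window of exp(i*theta)|`, computed for every
#' window position by cumulative sums (step 1), optionally subsampled with
#' `step`. Always lies in `[0, 1]`.
#'
#' @param theta phase-difference vector, or matrix (frequencies x time).
#' @param L window length in samples.
#' @param step positions between reported windows (default 1 = fully sliding).
#' @return object of class `"plv_series"`: `values` (frequencies x windows),
#'   `positions` (sample index of each window end), `L`, `step`.
#' @export
plv <- function(theta, L, step = 1L) {
  if (is.vector(theta)) theta <- matrix(theta, nrow = 1)
  L <- as.integer(L)
  n <- ncol(theta)
  if (L < 1 || L > n) stop("window empty or longer than the series")
  pos <- seq(L, n, by = as.integer(step))
  vals <- matrix(0, nrow(theta), length(pos))
  for (i in seq_len(nrow(theta))) {
    cs <- cumsum(exp(1i * theta[i, ]))
    w <- cs[pos] - c(0, cs)[pos - L + 1]
    vals[i, ] <- clamp01(Mod(w) / L)
  }
  structure(list(values = vals, positions = pos, L = L, step = step),
            class = "plv_series")
}

# PLV between two channels' tf maps for each grid frequency.
plv_pair <- function(tf_i, tf_j, win_sec = 2, step = NULL) {
  if (!isTRUE(all.equal(tf_i$frequencies, tf_j$frequencies)) ||
      ncol(tf_i$coefficients) != ncol(tf_j$coefficients))
    stop("time/frequency grids do not match")
  L <- round(win_sec * tf_i$fs)
  theta <- phase_difference(st_phase(tf_i), st_phase(tf_j))
  plv(theta, L, step = step %||% 1L)
}

#' Phase-randomized surrogate of a signal
#'
#' Returns a real signal with exactly the reference's amplitude spectrum but
#' independent uniformly random Fourier phases (conjugate-symmetric
#' construction; DC and Nyquist terms keep their magnitude with a random
#' sign), destroying any phase synchronization while preserving the
#' periodogram.
#'
#' @param x numeric reference signal.
#' @return surrogate signal of the same length.
#' @export
phase_randomize <- function(x) {
  n <- length(x)
  A <- Mod(stats::fft(x))
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  ph <- stats::runif(half, -pi, pi)
  Z <- complex(length.out = n)
  Z[1] <- A[1] * sign(stats::runif(1) - 0.5)
  if (half > 0) {
    Z[2:(half + 1)] <- A[2:(half + 1)] * exp(1i * ph)
    Z[n:(n - half + 1)] <- Conj(Z[2:(half + 1)])
  }
  if (n %% 2 == 0) Z[n / 2 + 1] <- A[n / 2 + 1] * sign(stats::runif(1) - 0.5)
  Re(stats::fft(Z, inverse = TRUE) / n)
}

#' Surrogate-based PLV significance threshold
#'
#' Builds `n_pairs` independent pairs of phase-randomized surrogates of an
#' EEG-like reference, computes the PLV between the members of each pair on
#' the frequency grid with rectangular windows of `win_sec` seconds, pools all
#' PLV values and returns the empirical quantile at the given confidence
#' level. This is the null level of synchrony expected between asynchronous
#' signals with the reference's spectrum.
#'
#' @param reference preprocessed EEG reference: numeric vector or
#'   single-channel [recording()].
#' @param fs sampling rate (taken from the recording when given).
#' @param n_pairs number of surrogate pairs (>= 50; default 500).
#' @param confidence pooled-distribution quantile level (default 0.9).
#' @param freqs analysis grid in Hz (default 4-32 Hz in 1 Hz steps).
#' @param win_sec PLV window length in seconds (default 2).
#' @param step window positions pooled every `step` samples; the default pools
#'   non-overlapping windows, which samples the same pooled distribution as
#'   the fully sliding version at a fraction of the memory.
#' @param seed RNG seed for the surrogate phases.
#' @return object of class `"surrogate_threshold"`: `threshold`, `confidence`,
#'   `n_pairs`, `freqs`, `n_values`, `seed`, `method`.
#' @export
surrogate_threshold <- function(reference, fs = NULL, n_pairs = 500,
                                confidence = 0.9, freqs = seq(4, 32, by = 1),
                                win_sec = 2, step = NULL, seed = 1L) {
  if (inherits(reference, "recording")) {
    if (nrow(reference$samples) != 1)
      stop("pass a single-channel reference")
    fs <- reference$fs
    reference <- as.numeric(reference$samples[1, ])
  }
  if (is.null(fs)) stop("fs required for vector input")
  if (n_pairs < 50) stop("n_pairs < 50: pooled quantile would be unstable")
  if (confidence < 0 || confidence > 1) stop("confidence must be in [0,1]")
  n <- length(reference)
  L <- round(win_sec * fs)
  if (is.null(step)) step <- L
  plan <- st_plan(n, fs, freqs)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(derive_seed(seed, "surrogate"))

  n_win <- length(seq(L, n, by = step))
  pool <- matrix(NA_real_, nrow = length(freqs) * n_win, ncol = n_pairs)
  for (p in seq_len(n_pairs)) {
    s1 <- phase_randomize(reference)
    s2 <- phase_randomize(reference)
    t1 <- stransform(s1, fs, plan = plan)
    t2 <- stransform(s2, fs, plan = plan)
    v <- plv(phase_difference(st_phase(t1), st_phase(t2)), L, step = step)
    pool[, p] <- as.numeric(v$values)
  }
  thr <- unname(stats::quantile(pool, probs = confidence, type = 7))
  structure(list(threshold = thr, confidence = confidence, n_pairs = n_pairs,
                 freqs = freqs, win_sec = win_sec, n_values = length(pool),
                 seed = seed, method = "phase_randomization"),
            class = "surrogate_threshold")
}

#' @export
print.surrogate_threshold <- function(x, ...) {
  cat(sprintf("<surrogate_threshold> %.3f at %.0f%% confidence (%d pairs, %d pooled PLVs)\n",
              x$threshold, 100 * x$confidence, x$n_pairs, x$n_values))
  invisible(x)
}

#' All cross-region electrode pairs
#'
#' Electrodes in the same region are never paired (their synchrony is high
#' simply because of proximity).
#'
#' @param region_map named character vector channel -> region.
#' @param channels channel labels to pair (defaults to all mapped channels).
#' @return two-column character matrix of channel pairs.
#' @export
cross_region_pairs <- function(region_map, channels = names(region_map)) {
  idx <- utils::combn(channels, 2)
  keep <- region_map[idx[1, ]] != region_map[idx[2, ]]
  t(idx[, keep, drop = FALSE])
}

#' Per-pair band-wise PLV summaries for one recording
#'
#' Estimates each channel's instantaneous phase by S-transform on `freqs`,
#' then for every admissible pair and band reduces the PLV over that band's
#' frequencies and all window positions to a median (plus the fraction of
#' windows exceeding `exceed_at`, exported for sensitivity checks).
#'
#' @param rec a preprocessed EEG [recording()].
#' @param pairs two-column matrix of channel label pairs (default all
#'   cross-region pairs of the recording's montage).
#' @param freqs phase-estimation grid in Hz (default 4-32 @ 1 Hz).
#' @param bands band definitions over which frequencies are grouped.
#' @param win_sec PLV window in seconds.
#' @param step PLV window stride in samples (default: non-overlapping).
#' @param exceed_at PLV level for the exported exceedance fraction.
#' @return data.frame: `channel_i`, `channel_j`, `band`, `median_plv`,
#'   `exceed_frac`, plus the recording's condition/subject metadata.
#' @export
pair_plv_summaries <- function(rec, pairs = NULL, freqs = seq(4, 32, by = 1),
                               bands = eeg_bands(), win_sec = 2, step = NULL,
                               exceed_at = 0.79) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(pairs))
    pairs <- cross_region_pairs(rec$region_map, rec$channel_labels)
  L <- round(win_sec * rec$fs)
  if (is.null(step)) step <- L
  plan <- st_plan(ncol(rec$samples), rec$fs, freqs)
  phases <- lapply(seq_len(nrow(rec$samples)), function(i)
    st_phase(stransform(rec$samples[i, ], rec$fs, plan = plan)))
  names(phases) <- rec$channel_labels
  band_sel <- lapply(bands, function(e) which(freqs >= e[1] & freqs < e[2]))
  rows <- vector("list", nrow(pairs) * length(bands))
  k <- 0L
  for (pidx in seq_len(nrow(pairs))) {
    ci <- pairs[pidx, 1]; cj <- pairs[pidx, 2]
    theta <- phase_difference(phases[[ci]], phases[[cj]])
    v <- plv(theta, L, step = step)$values
    for (b in names(bands)) {
      sel <- band_sel[[b]]
      if (length(sel) == 0) next
      vb <- v[sel, , drop = FALSE]
      k <- k + 1L
      rows[[k]] <- data.frame(
        channel_i = ci, channel_j = cj, band = b,
        median_plv = stats::median(vb), exceed_frac = mean(vb > exceed_at),
        subject = rec$subject_id, condition = rec$condition,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Count synchronous electrode pairs
#'
#' A pair counts as synchronous in a band when its median-over-windows PLV
#' exceeds the (surrogate-derived) threshold. Counts are tabulated per band
#' and, when present in the input, per condition (and averaged across
#' subjects).
#'
#' @param plv_set a [pair_plv_summaries()] data.frame (rows from several
#'   recordings may be concatenated).
#' @param threshold PLV threshold in `[0,1]` (a [surrogate_threshold()] object
#'   is also accepted).
#' @return data.frame with `condition` (if available), `band`, `n_pairs`
#'   (mean count across subjects), `n_admissible`.
#' @export
count_synchronous_pairs <- function(plv_set, threshold) {
  if (inherits(threshold, "surrogate_threshold")) threshold <- threshold$threshold
  if (threshold < 0 || threshold > 1) stop("threshold outside [0,1]")
  plv_set$sync <- plv_set$median_plv > threshold
  has_cond <- "condition" %in% names(plv_set) && !all(is.na(plv_set$condition))
  grp <- if (has_cond) c("condition", "band") else "band"
  per_subj <- stats::aggregate(
    sync ~ ., data = plv_set[, c(grp, "subject", "sync")], FUN = sum)
  adm <- stats::aggregate(
    sync ~ ., data = plv_set[, c(grp, "subject", "sync")], FUN = length)
  out <- stats::aggregate(per_subj$sync, by = per_subj[, grp, drop = FALSE], FUN = mean)
  names(out)[ncol(out)] <- "n_pairs"
  out$n_admissible <- stats::aggregate(adm$sync, by = adm[, grp, drop = FALSE],
                                       FUN = mean)$x
  out
}
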