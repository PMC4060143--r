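#' Design a linear-phase FIR filter from band edges and attenuation targets
#'
#' Filters are designed with a Kaiser window at whatever order the requested
#' transition width and stopband attenuation demand, so the design ports
#' across sampling rates; passband edges are honoured exactly (the -6 dB
#' cutoffs sit half a transition width outside them). Lengths are forced odd
#' so group delay is an integer number of samples and can be compensated
#' exactly.
#'
#' @param kind `"bandpass"`, `"highpass"` or `"lowpass"`.
#' @param edges passband edge(s) in Hz: `c(lo, hi)` for bandpass, single
#'   values otherwise. Must lie strictly inside `(0, fs/2)`.
#' @param fs sampling rate in Hz.
#' @param transition transition width in Hz; defaults to
#'   `min(1, lowest edge)` which keeps the stopband from crossing 0 Hz.
#' @param stopband_db target stopband attenuation (dB, default 45).
#' @return object of class `"fir_spec"`: coefficients `h`, `taps`, `delay`
#'   (samples), plus the design parameters.
#' @export
design_fir <- function(kind = c("bandpass", "highpass", "lowpass"),
                       edges, fs, transition = NULL, stopband_db = 45) {
  kind <- match.arg(kind)
  nyq <- fs / 2
  if (any(edges <= 0) || any(edges >= nyq))
    stop("band edges must lie strictly inside (0, fs/2)")
  if (kind == "bandpass" && (length(edges) != 2 || edges[1] >= edges[2]))
    stop("bandpass needs edges c(lo, hi) with lo < hi")
  if (is.null(transition)) transition <- min(1, min(edges))
  transition <- min(transition, 2 * (nyq - max(edges)))

  A <- stopband_db
  beta <- if (A > 50) 0.1102 * (A - 8.7)
          else if (A >= 21) 0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
          else 0
  dw <- 2 * pi * transition / fs
  ord <- ceiling((A - 8) / (2.285 * dw))
  if (ord %% 2 == 1) ord <- ord + 1  # odd length => integer delay

  # cutoffs half a transition outside the passband; a nominal near-zero low
  # edge clamps the cutoff at edge/2 rather than inflating the filter order
  cut <- switch(kind,
    bandpass = c(max(edges[1] - transition / 2, edges[1] / 2),
                 min(edges[2] + transition / 2, (edges[2] + nyq) / 2)),
    highpass = max(edges[1] - transition / 2, edges[1] / 2),
    lowpass  = min(edges[1] + transition / 2, (edges[1] + nyq) / 2))
  type <- switch(kind, bandpass = "pass", highpass = "high", lowpass = "low")
  h <- signal::fir1(ord, cut / nyq, type = type,
                    window = signal::kaiser(ord + 1, beta))
  structure(list(h = as.numeric(h), taps = ord + 1L, delay = ord %/% 2L,
                 kind = kind, edges = edges, fs = fs,
                 transition = transition, stopband_db = stopband_db),
            class = "fir_spec")
}

#' Zero-phase FIR filtering of a recording
#'
#' Applies a linear-phase FIR filter by FFT convolution and shifts the output
#' back by the filter's group delay, so the result is zero-phase. Output
#' length equals input length; the filter-length transient at each end is
#' flagged via `attr(, "transient_samples")` and is what
#' [discard_transient()] removes.
#'
#' @param rec a [recording()] (or numeric vector/matrix plus `fs`).
#' @param spec a [design_fir()] spec, or a numeric coefficient vector of odd
#'   length.
#' @param fs required when `rec` is not a recording.
#' @return filtered object of the same type as `rec`.
#' @export
fir_filter <- function(rec, spec, fs = NULL) {
  h <- if (inherits(spec, "fir_spec")) spec$h else as.numeric(spec)
  if (length(h) %% 2 != 1) stop("filter length must be odd (integer group delay)")
  if (inherits(spec, "fir_spec") && inherits(rec, "recording") &&
      !isTRUE(all.equal(spec$fs, rec$fs)))
    stop("filter was designed for fs=", spec$fs, " but recording has fs=", rec$fs)
  fs_in <- if (inherits(rec, "recording")) rec$fs else fs
  if (inherits(spec, "fir_spec") && !is.null(fs_in) && max(spec$edges) >= fs_in / 2)
    stop("band edge at or above Nyquist")
  delay <- (length(h) - 1L) %/% 2L
  filt1 <- function(x) {
    y <- Re(conv_fft(x, h))
    y[(delay + 1):(delay + length(x))]
  }
  if (inherits(rec, "recording")) {
    y <- t(apply(rec$samples, 1, filt1))
    out <- with_samples(rec, y)
  } else if (is.matrix(rec)) {
    out <- t(apply(rec, 1, filt1))
  } else {
    out <- filt1(rec)
  }
  attr(out, "transient_samples") <- length(h)
  out
}

#' Amplitude-threshold artifact mask
#'
#' Flags high-voltage stretches (absolute amplitude above `upper` uV, dilated
#' by a guard interval) and flat stretches (sliding-window peak amplitude
#' below `lower` uV) per channel. A channel flat for more than
#' `flat_drop_frac` of the session is dropped entirely. Downstream averages
#' must use only kept samples.
#'
#' @param rec an EEG [recording()] in microvolts.
#' @param upper,lower rejection bounds in uV (defaults 200 and 2).
#' @param guard guard interval in seconds dilated around high-voltage samples.
#' @param flat_window sliding window length in seconds for flat detection.
#' @param flat_drop_frac fraction of flat windows above which a channel is
#'   dropped.
#' @return object of class `"artifact_mask"`: logical `keep` matrix
#'   (channels x samples, `TRUE` = keep), thresholds, `flat_channels`, and a
#'   per-channel rejected-fraction summary.
#' @export
amplitude_artifact_mask <- function(rec, upper = 200, lower = 2, guard = 0.25,
                                    flat_window = 1, flat_drop_frac = 0.5) {
  stopifnot(inherits(rec, "recording"), upper > lower, lower > 0)
  x <- rec$samples
  if (any(!is.finite(x))) stop("non-finite samples")
  n <- ncol(x); fs <- rec$fs
  g <- max(1L, round(guard * fs))
  w <- max(2L, round(flat_window * fs))
  stride <- max(1L, w %/% 4L)
  keep <- matrix(TRUE, nrow(x), n)
  flat_channels <- character(0)
  for (i in seq_len(nrow(x))) {
    bad <- abs(x[i, ]) > upper
    if (any(bad)) {
      # dilate by the guard interval on both sides
      idx <- which(bad)
      lo <- pmax(idx - g, 1L); hi <- pmin(idx + g, n)
      for (k in seq_along(idx)) keep[i, lo[k]:hi[k]] <- FALSE
    }
    starts <- seq(1L, max(1L, n - w + 1L), by = stride)
    flat_hits <- 0L
    for (s0 in starts) {
      seg <- s0:(s0 + w - 1L)
      if (max(abs(x[i, seg])) < lower) {
        keep[i, seg] <- FALSE
        flat_hits <- flat_hits + 1L
      }
    }
    if (flat_hits / length(starts) > flat_drop_frac) {
      keep[i, ] <- FALSE
      flat_channels <- c(flat_channels, rec$channel_labels[i])
    }
  }
  rejected <- 1 - rowMeans(keep)
  names(rejected) <- rec$channel_labels
  structure(list(keep = keep, upper = upper, lower = lower,
                 flat_channels = flat_channels, rejected_fraction = rejected,
                 fs = fs),
            class = "artifact_mask")
}

#' Logistic infomax ICA
#'
#' Square independent component analysis with the logistic-nonlinearity
#' natural-gradient (infomax) rule: data are centered and sphered, then the
#' unmixing matrix is updated over shuffled sample blocks as
#' `W <- W + lr * (I + (1 - 2*g(u)) u') W` with `g` the logistic function,
#' annealing the learning rate until the weight change falls below `tol`.
#'
#' @param x channels x samples numeric matrix (at least 2 channels; more
#'   samples than `20 * channels`).
#' @param seed seed for the block shuffling (and hence the iterate path).
#' @param max_iter iteration cap; non-convergence raises an error carrying the
#'   final weight change.
#' @param tol convergence tolerance on the relative weight change.
#' @param lrate initial learning rate (default `6.5e-4 / log(channels)`).
#' @return list with `unmixing` (components x channels, sphering folded in),
#'   `mixing` (its inverse), `sources` (components x samples), `iterations`,
#'   `final_change`.
#' @export
infomax_ica <- function(x, seed = 1L, max_iter = 500L, tol = 1e-6, lrate = NULL) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  nc <- nrow(x); nt <- ncol(x)
  if (nt < 20 * nc) stop("recording too short for ICA: need > 20 * n_channels samples")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)

  xm <- rowMeans(x)
  xc <- x - xm
  cv <- tcrossprod(xc) / (nt - 1)
  eg <- eigen(cv, symmetric = TRUE)
  d <- pmax(eg$values, 1e-12)
  sphere <- eg$vectors %*% diag(1 / sqrt(d), nc) %*% t(eg$vectors)
  xw <- sphere %*% xc

  if (is.null(lrate)) lrate <- 6.5e-4 / log(nc)
  block <- max(8L, floor(sqrt(nt / 3)))
  W <- diag(nc)
  I <- diag(nc) * block
  change <- Inf
  prev_change <- Inf
  oldW <- W
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    perm <- sample.int(nt)
    blown <- FALSE
    for (s0 in seq(1L, nt - block + 1L, by = block)) {
      u <- W %*% xw[, perm[s0:(s0 + block - 1L)], drop = FALSE]
      y <- 1 / (1 + exp(-u))
      W <- W + lrate * (I + (1 - 2 * y) %*% t(u)) %*% W
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) { blown <- TRUE; break }
    }
    if (blown) {  # restart with a gentler rate
      W <- diag(nc); oldW <- W
      lrate <- lrate * 0.5
      prev_change <- Inf
      if (lrate < 1e-8) stop("infomax ICA diverged even at minimal learning rate")
      next
    }
    dW <- W - oldW
    change <- sum(dW^2) / sum(W^2)
    oldW <- W
    if (change < tol) break
    # anneal: always a little, harder when the change stops shrinking
    lrate <- lrate * if (change > prev_change) 0.90 else 0.995
    prev_change <- change
  }
  if (change >= tol)
    stop(sprintf("infomax ICA did not converge: weight change %.3g after %d iterations (tol %.1g)",
                 change, it, tol))
  unmix <- W %*% sphere
  mix <- solve(unmix)
  list(unmixing = unmix, mixing = mix, sources = unmix %*% xc,
       center = xm, iterations = it, final_change = change)
}

#' Remove ocular components from EEG via infomax ICA
#'
#' Runs [infomax_ica()], correlates each component's time course with an
#' ocular reference, zeroes components with `|r|` above `threshold`, and
#' remixes. If no reference channel is supplied, a frontal template (mean of
#' frontal channels low-passed below 5 Hz) stands in for the EOG.
#'
#' @param rec an EEG [recording()] with at least 8 channels.
#' @param reference numeric vector of the same length as the recording, or
#'   `NULL` for the frontal template.
#' @param threshold absolute Pearson correlation above which a component is
#'   rejected (default 0.7).
#' @param seed,max_iter,tol passed to [infomax_ica()].
#' @return the cleaned recording; removed component indices and their
#'   correlations are in `attr(, "ica_report")`.
#' @export
remove_ocular_ica <- function(rec, reference = NULL, threshold = 0.7,
                              seed = 1L, max_iter = 500L, tol = 1e-6) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$samples) < 8) stop("need >= 8 channels for ocular ICA")
  if (is.null(reference)) {
    regions <- biosemi32_regions()[rec$channel_labels]
    fr <- which(regions == "frontal")
    if (length(fr) == 0) stop("no frontal channels for the default ocular template")
    template <- colMeans(rec$samples[fr, , drop = FALSE])
    reference <- lowpass_fft(template, rec$fs, 5)
  }
  if (length(reference) != ncol(rec$samples)) stop("reference length mismatch")

  ica <- infomax_ica(rec$samples, seed = seed, max_iter = max_iter, tol = tol)
  r <- as.numeric(stats::cor(t(ica$sources), reference))
  drop_idx <- which(abs(r) > threshold)
  S <- ica$sources
  if (length(drop_idx) > 0) S[drop_idx, ] <- 0
  cleaned <- ica$mixing %*% S + ica$center
  out <- with_samples(rec, cleaned)
  attr(out, "ica_report") <- list(removed = drop_idx, correlations = r,
                                  iterations = ica$iterations)
  out
}

# Brick-wall FFT lowpass used only to build the ocular template.
lowpass_fft <- function(x, fs, fc) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  X[f > fc] <- 0
  Re(stats::fft(X, inverse = TRUE) / n)
}

#' Integer-factor downsampling
#'
#' Decimates by taking every k-th sample after verifying that spectral content
#' above the target Nyquist has already been attenuated (anything above
#' `target_fs / 2` carrying more than `alias_tol` of total power is an error:
#' the caller must low-pass first).
#'
#' @param rec a [recording()].
#' @param target_fs target rate in Hz; `fs / target_fs` must be an integer.
#' @param alias_tol maximal tolerated fraction of power above the target
#'   Nyquist.
#' @return the decimated recording (`fs` updated).
#' @export
downsample <- function(rec, target_fs = 64, alias_tol = 0.01) {
  stopifnot(inherits(rec, "recording"))
  fac <- rec$fs / target_fs
  if (abs(fac - round(fac)) > 1e-9) stop("fs/target_fs must be an integer decimation factor")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(rec)
  n <- ncol(rec$samples)
  f <- (0:(n - 1)) * rec$fs / n
  f <- pmin(f, rec$fs - f)
  hi <- f > target_fs / 2
  for (i in seq_len(nrow(rec$samples))) {
    P <- Mod(stats::fft(rec$samples[i, ]))^2
    frac <- sum(P[hi]) / sum(P)
    if (frac > alias_tol)
      stop(sprintf("channel %s has %.2g of its power above the target Nyquist (%g Hz); low-pass before downsampling",
                   rec$channel_labels[i], frac, target_fs / 2))
  }
  idx <- seq(1L, n, by = fac)
  with_samples(rec, rec$samples[, idx, drop = FALSE], fs = target_fs)
}

# Decimate an artifact mask consistently with downsample(): a kept output
# sample requires all native samples in its group to be kept.
downsample_mask <- function(mask, factor) {
  n <- ncol(mask$keep)
  idx <- seq(1L, n, by = factor)
  keep <- matrix(TRUE, nrow(mask$keep), length(idx))
  for (j in seq_along(idx)) {
    grp <- idx[j]:min(idx[j] + factor - 1L, n)
    keep[, j] <- matrixRowAll(mask$keep[, grp, drop = FALSE])
  }
  mask$keep <- keep
  mask$fs <- mask$fs / factor
  mask
}

matrixRowAll <- function(m) rowSums(m) == ncol(m)

#' Discard the leading filter transient
#'
#' Removes the first `n_samples` samples from every channel (and, if given, a
#' matching artifact mask), typically one filter length after zero-phase FIR
#' filtering.
#'
#' @param rec a [recording()].
#' @param n_samples number of leading samples to drop; by default the
#'   `transient_samples` attribute left by [fir_filter()].
#' @return the trimmed recording.
#' @export
discard_transient <- function(rec, n_samples = attr(rec, "transient_samples")) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(n_samples)) stop("n_samples not given and no transient attribute present")
  n_samples <- as.integer(n_samples)
  if (n_samples < 0) stop("n_samples must be >= 0")
  if (n_samples >= ncol(rec$samples)) stop("n_samples >= recording length")
  if (n_samples == 0L) return(rec)
  with_samples(rec, rec$samples[, -(seq_len(n_samples)), drop = FALSE])
}
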