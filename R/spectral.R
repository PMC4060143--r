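#' Four-term Blackman-Harris window
#'
#' The -92 dB sidelobe four-term cosine-sum taper applied to each Bartlett
#' segment before its periodogram is taken.
#'
#' @param n window length in samples.
#' @return numeric vector of length `n`.
#' @export
blackman_harris <- function(n) {
  a <- c(0.35875, 0.48829, 0.14128, 0.01168)
  k <- seq_len(n) - 1
  a[1] - a[2] * cos(2 * pi * k / (n - 1)) +
    a[3] * cos(4 * pi * k / (n - 1)) - a[4] * cos(6 * pi * k / (n - 1))
}

#' Bartlett (averaged-periodogram) PSD estimate
#'
#' Splits each channel into consecutive non-overlapping segments of length
#' `segment_length`, tapers each with the four-term Blackman-Harris window,
#' and averages the per-segment periodograms:
#' `P(w) = (1/K) * sum_k (1/N) |sum_n x_k[n] w[n] e^(-jwn)|^2`.
#' Segments containing any mask-rejected sample are excluded from the average
#' for that channel.
#'
#' @param rec a [recording()] (or numeric matrix with `fs` supplied).
#' @param segment_length segment length N in samples.
#' @param mask optional [amplitude_artifact_mask()] at the recording's rate.
#' @param fs sampling rate when `rec` is a bare matrix/vector.
#' @return object of class `"psd_estimate"`: `frequencies` (Hz, up to
#'   Nyquist), `power` (channels x frequencies), `segment_length`,
#'   `n_segments` per channel, `window`.
#' @export
bartlett_psd <- function(rec, segment_length, mask = NULL, fs = NULL) {
  if (inherits(rec, "recording")) {
    x <- rec$samples; fs <- rec$fs; labels <- rec$channel_labels
  } else {
    if (is.vector(rec)) rec <- matrix(rec, nrow = 1)
    x <- rec; labels <- rownames(rec) %||% paste0("ch", seq_len(nrow(rec)))
    if (is.null(fs)) stop("fs required for matrix input")
  }
  N <- as.integer(segment_length)
  n <- ncol(x)
  if (N > n) stop("segment_length exceeds usable data")
  w <- blackman_harris(N)
  nfreq <- N %/% 2 + 1
  freqs <- (0:(nfreq - 1)) * fs / N
  pow <- matrix(0, nrow(x), nfreq)
  nseg <- integer(nrow(x))
  starts <- seq(1L, n - N + 1L, by = N)
  for (i in seq_len(nrow(x))) {
    acc <- numeric(nfreq)
    k <- 0L
    for (s0 in starts) {
      seg <- s0:(s0 + N - 1L)
      if (!is.null(mask) && !all(mask$keep[i, seg])) next
      X <- stats::fft(x[i, seg] * w)
      acc <- acc + Mod(X[seq_len(nfreq)])^2 / N
      k <- k + 1L
    }
    if (k == 0L) stop("no artifact-free segments for channel ", labels[i])
    pow[i, ] <- acc / k
    nseg[i] <- k
  }
  rownames(pow) <- labels
  structure(list(frequencies = freqs, power = pow, segment_length = N,
                 n_segments = nseg, window = w, fs = fs),
            class = "psd_estimate")
}

#' Aggregate a PSD into band-by-region mean power
#'
#' For every band the value is the mean over the region's channels of the mean
#' PSD over the band's frequencies, using left-closed right-open band
#' intervals.
#'
#' @param psd a [bartlett_psd()] estimate.
#' @param region_map named character vector channel -> region.
#' @param bands named list of `c(lo, hi)` Hz intervals (default [eeg_bands()]).
#' @param subject_id,condition row metadata.
#' @return data.frame with columns `subject`, `condition`, `band`, `region`,
#'   `power`.
#' @export
band_region_power <- function(psd, region_map, bands = eeg_bands(),
                              subject_id = NA_character_,
                              condition = NA_character_) {
  stopifnot(inherits(psd, "psd_estimate"))
  labels <- rownames(psd$power)
  regions <- region_map[labels]
  if (anyNA(regions)) stop("channels without region mapping: ",
                           paste(labels[is.na(regions)], collapse = ", "))
  rows <- list()
  for (b in names(bands)) {
    sel <- psd$frequencies >= bands[[b]][1] & psd$frequencies < bands[[b]][2]
    if (!any(sel)) stop("no PSD frequencies inside band ", b)
    ch_mean <- rowMeans(psd$power[, sel, drop = FALSE])
    for (r in unique(regions)) {
      rows[[paste(b, r)]] <- data.frame(
        subject = subject_id, condition = condition, band = b, region = r,
        power = mean(ch_mean[regions == r]), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Box-Cox normalization with a normality pre-test
#'
#' Estimates the Box-Cox exponent by profile maximum likelihood and applies
#' `y = (x^lambda - 1)/lambda` (or `log x` at `lambda = 0`). By default the
#' transform is applied only when a Shapiro-Wilk test (on an evenly spaced
#' subsample of at most 5000 values) rejects normality at `alpha`; pass
#' `force = TRUE` to transform unconditionally.
#'
#' @param x positive numeric values.
#' @param alpha significance level of the normality pre-test.
#' @param force apply the transform regardless of the pre-test.
#' @param lambda_grid grid over which the profile likelihood is maximized.
#' @return list with `values`, `lambda` (`NA` when not applied), `applied`,
#'   `shapiro_p`.
#' @export
boxcox_normalize <- function(x, alpha = 0.05, force = FALSE,
                             lambda_grid = seq(-2, 2, by = 0.01)) {
  if (any(x <= 0)) stop("Box-Cox requires strictly positive values")
  sub <- x[even_subsample(length(x), 5000)]
  p <- if (length(unique(sub)) < 3) 0 else stats::shapiro.test(sub)$p.value
  if (!force && p >= alpha)
    return(list(values = x, lambda = NA_real_, applied = FALSE, shapiro_p = p))
  bc <- MASS::boxcox(x ~ 1, lambda = lambda_grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  values <- if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
  list(values = values, lambda = lambda, applied = TRUE, shapiro_p = p)
}

#' Within-subject (repeated-measures) ANOVA from sums of squares
#'
#' Balanced fully-within designs with one or two factors. Each within effect
#' is tested against its own interaction with subjects:
#' `F = MS_effect / MS_(effect x subject)`. Replicate rows inside a
#' subject-by-cell combination are averaged first; for balanced replicates
#' this yields the same F ratios as the replicate-level decomposition because
#' both numerator and denominator scale by the replicate count.
#'
#' @param data data.frame in long format.
#' @param dv name of the response column.
#' @param within character vector of one or two within-subject factor columns.
#' @param subject name of the subject column.
#' @return object of class `"rm_anova"`: data.frame of effects with `df1`,
#'   `df2`, `F`, `p`, plus cell means in `attr(, "cell_means")`.
#' @export
rm_anova <- function(data, dv = "power", within = c("condition", "region"),
                     subject = "subject") {
  stopifnot(length(within) %in% c(1L, 2L))
  cols <- c(subject, within, dv)
  if (!all(cols %in% names(data))) stop("missing columns: ",
                                        paste(setdiff(cols, names(data)), collapse = ", "))
  # aggregate replicates to subject x cell means
  f <- stats::aggregate(data[[dv]],
                        by = lapply(cols[-length(cols)], function(cn) data[[cn]]),
                        FUN = mean)
  names(f) <- c(subject, within, "y")
  s <- factor(f[[subject]])
  n <- nlevels(s)
  if (n < 2) stop("need at least 2 subjects")
  a <- factor(f[[within[1]]])
  A <- nlevels(a)
  two <- length(within) == 2L
  b <- if (two) factor(f[[within[2]]]) else factor(rep("cell", nrow(f)))
  B <- nlevels(b)
  if (nrow(f) != n * A * B) stop("design is incomplete or unbalanced")
  y <- f$y
  gm <- mean(y)
  m_s <- tapply(y, s, mean); m_a <- tapply(y, a, mean)
  m_as <- tapply(y, list(a, s), mean)
  ss <- function(x) sum(x^2)
  effects <- list()

  SS_A <- n * B * ss(m_a - gm)
  SS_AS <- B * ss(sweep(sweep(m_as, 1, m_a), 2, m_s) + gm)
  df_A <- A - 1; df_AS <- (A - 1) * (n - 1)
  effects[[within[1]]] <- c(SS_A / df_A / (SS_AS / df_AS), df_A, df_AS)

  if (two) {
    m_b <- tapply(y, b, mean)
    m_bs <- tapply(y, list(b, s), mean)
    m_ab <- tapply(y, list(a, b), mean)
    SS_B <- n * A * ss(m_b - gm)
    SS_BS <- A * ss(sweep(sweep(m_bs, 1, m_b), 2, m_s) + gm)
    df_B <- B - 1; df_BS <- (B - 1) * (n - 1)
    effects[[within[2]]] <- c(SS_B / df_B / (SS_BS / df_BS), df_B, df_BS)

    dev_ab <- sweep(sweep(m_ab, 1, m_a), 2, m_b) + gm
    SS_AB <- n * ss(dev_ab)
    SS_T <- ss(y - gm)
    SS_S <- A * B * ss(m_s - gm)
    SS_ABS <- SS_T - SS_S - SS_A - SS_B - SS_AB - SS_AS - SS_BS
    SS_ABS <- max(SS_ABS, 0)
    df_AB <- (A - 1) * (B - 1); df_ABS <- (A - 1) * (B - 1) * (n - 1)
    effects[[paste(within, collapse = ":")]] <-
      c(SS_AB / df_AB / (SS_ABS / df_ABS), df_AB, df_ABS)
  }

  out <- data.frame(
    effect = names(effects),
    df1 = vapply(effects, `[`, numeric(1), 2),
    df2 = vapply(effects, `[`, numeric(1), 3),
    F = vapply(effects, `[`, numeric(1), 1),
    stringsAsFactors = FALSE)
  out$F[!is.finite(out$F)] <- 0  # zero variance in both strata
  out$p <- stats::pf(out$F, out$df1, out$df2, lower.tail = FALSE)
  rownames(out) <- NULL
  cell <- if (two) tapply(y, list(a, b), mean) else tapply(y, a, mean)
  structure(out, class = c("rm_anova", "data.frame"), cell_means = cell)
}

#' Band-wise condition-by-location ANOVA of a power table
#'
#' Runs the two-way within-subject ANOVA (Condition x Location) per band on a
#' [band_region_power()] table, optionally Box-Cox-normalizing each band's
#' values first when they fail the normality pre-test.
#'
#' @param table data.frame with columns `subject`, `condition`, `band`,
#'   `region`, `power`.
#' @param boxcox apply [boxcox_normalize()] per band before testing.
#' @return named list of [rm_anova()] results, one per band, each with the
#'   Box-Cox lambda used stored as `attr(, "lambda")`.
#' @export
band_power_anova <- function(table, boxcox = TRUE) {
  out <- list()
  for (b in unique(table$band)) {
    tb <- table[table$band == b, ]
    lambda <- NA_real_
    if (boxcox) {
      bc <- boxcox_normalize(tb$power)
      tb$power <- bc$values
      lambda <- bc$lambda
    }
    res <- rm_anova(tb, dv = "power", within = c("condition", "region"))
    attr(res, "lambda") <- lambda
    out[[b]] <- res
  }
  out
}
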