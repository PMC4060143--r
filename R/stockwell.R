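#' Stockwell (S-) transform
#'
#' Computes `S(f,n] = sum_m x[m] (|f|/sqrt(2*pi)) exp(-(n-m)^2 f^2 / 2)
#' exp(-i 2*pi f m)` with `f` expressed in cycles/sample internally (the
#' user-facing grid is in Hz; the conversion is `f_cps = f_Hz / fs`), i.e. a
#' Gaussian analysis window whose standard deviation is one signal period.
#' The implementation is FFT-accelerated: each frequency is a linear
#' convolution of the modulated signal with the sampled Gaussian, computed on
#' a zero-padded grid so circular wrap-around is negligible (`pad_sigmas`
#' Gaussian widths of padding); it matches the direct double summation to
#' near machine precision.
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param fmin,fmax,df frequency grid `seq(fmin, fmax, by = df)` in Hz;
#'   `0 < fmin <= fmax < fs/2`. `f = 0` is excluded by construction (the
#'   Gaussian degenerates there).
#' @param pad_sigmas zero-padding in units of the widest Gaussian.
#' @param plan optional precomputed [st_plan()] (for repeated transforms of
#'   equal-length signals on the same grid).
#' @return object of class `"tf_map"`: complex `coefficients`
#'   (frequencies x time), `frequencies` (Hz), `fs`. Use [st_amplitude()] and
#'   [st_phase()] for `|S|` and `arg S`.
#' @export
stransform <- function(x, fs, fmin, fmax, df, pad_sigmas = 8, plan = NULL) {
  if (is.null(plan)) plan <- st_plan(length(x), fs, seq_fgrid(fmin, fmax, df), pad_sigmas)
  n <- length(x)
  if (n != plan$n) stop("signal length does not match plan")
  xp <- c(x, rep(0, plan$npad - n))
  X <- stats::fft(xp)
  S <- matrix(0i, nrow = length(plan$freqs), ncol = n)
  for (j in seq_along(plan$freqs)) {
    if (is.na(plan$kbin[j])) {
      fc <- plan$freqs[j] / fs
      y <- xp * exp(-2i * pi * fc * (0:(plan$npad - 1)))
      Y <- stats::fft(y)
    } else {
      # modulation in time = rotation in frequency when f sits on a DFT bin
      Y <- rotate_left(X, plan$kbin[j])
    }
    S[j, ] <- (stats::fft(Y * plan$G[[j]], inverse = TRUE) / plan$npad)[seq_len(n)]
  }
  structure(list(coefficients = S, frequencies = plan$freqs, fs = fs),
            class = "tf_map")
}

seq_fgrid <- function(fmin, fmax, df) {
  if (fmin <= 0) stop("fmin must be > 0 (f = 0 excluded: degenerate Gaussian)")
  if (df <= 0 || fmax < fmin) stop("need df > 0 and fmax >= fmin")
  k <- floor((fmax - fmin) / df + 1e-9)
  fmin + (0:k) * df
}

#' Precompute an S-transform plan
#'
#' Caches the padded length and the FFT of each frequency's Gaussian window so
#' that many equal-length signals (e.g. surrogate pairs) can be transformed
#' cheaply on the same grid.
#'
#' @param n signal length in samples.
#' @param fs sampling rate (Hz).
#' @param freqs frequency grid in Hz.
#' @param pad_sigmas padding in units of the widest Gaussian width.
#' @return plan list used by [stransform()].
#' @export
st_plan <- function(n, fs, freqs, pad_sigmas = 8) {
  if (any(freqs <= 0) || any(freqs > fs / 2 + 1e-12))
    stop("frequency grid must lie inside (0, fs/2]")
  sigma_max <- fs / min(freqs)               # samples
  pad <- ceiling(pad_sigmas * sigma_max)
  # try to place all grid frequencies on DFT bins so the modulation FFT can be
  # replaced by a spectrum rotation; fall back to per-frequency modulation
  base <- 1L
  for (mult in 1:8) {
    b <- (fs / min(diff(c(0, freqs)))) * mult
    if (abs(b - round(b)) < 1e-9 &&
        all(abs(freqs * round(b) / fs - round(freqs * round(b) / fs)) < 1e-9)) {
      base <- as.integer(round(b)); break
    }
  }
  npad <- next_fast_len(n + pad, multiple_of = base)
  kbin <- freqs * npad / fs
  kbin <- ifelse(abs(kbin - round(kbin)) < 1e-9, as.integer(round(kbin)), NA_integer_)
  idx <- 0:(npad - 1)
  tt <- ifelse(idx <= npad / 2, idx, idx - npad)   # wrapped window time axis
  G <- lapply(freqs, function(f) {
    fc <- f / fs
    stats::fft(fc / sqrt(2 * pi) * exp(-tt^2 * fc^2 / 2))
  })
  list(n = n, fs = fs, freqs = freqs, npad = npad, kbin = kbin, G = G)
}

rotate_left <- function(v, k) {
  n <- length(v)
  k <- k %% n
  if (k == 0) return(v)
  c(v[(k + 1):n], v[1:k])
}

#' @rdname stransform
#' @param tf a `"tf_map"`.
#' @export
st_amplitude <- function(tf) Mod(tf$coefficients)

#' @rdname stransform
#' @export
st_phase <- function(tf) Arg(tf$coefficients)

#' @export
print.tf_map <- function(x, ...) {
  cat(sprintf("<tf_map> %d frequencies (%g-%g Hz) x %d samples @ %g Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              ncol(x$coefficients), x$fs))
  invisible(x)
}

#' Respiration time-frequency condition contrast
#'
#' Takes one Stockwell map per subject and condition, averages coefficient
#' amplitudes over time and frequency into one value per subject and
#' condition, Box-Cox transforms those cell values, and runs a one-factor
#' within-subject ANOVA with Condition as the factor. (For a balanced grid,
#' keeping frequencies as within-cell replicates yields the same F ratio, so
#' the aggregation order only determines what the Box-Cox normalizes; applying
#' it to the cell values normalizes exactly the distribution entering the
#' test, whereas profile likelihood on the raw per-bin amplitudes is pulled to
#' extreme exponents by the quiet bins between spectral peaks.) Also returns
#' the per-condition mean amplitude spectra for the classic "slower breathing
#' during meditation" comparison.
#'
#' @param resp_maps list of entries, each a list with `subject`, `condition`
#'   and `map` (a [stransform()] result); every subject must appear in both
#'   conditions.
#' @return list with `anova` ([rm_anova()] result), `spectra` (data.frame of
#'   per-condition mean amplitude by frequency), `lambda` (Box-Cox exponent).
#' @export
respiration_tfa_contrast <- function(resp_maps) {
  rows <- lapply(resp_maps, function(e) {
    amp <- rowMeans(st_amplitude(e$map))
    data.frame(subject = e$subject, condition = e$condition,
               frequency = e$map$frequencies, amplitude = amp,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  tab <- table(unique(df[, c("subject", "condition")]))
  if (any(tab != 1)) stop("every subject needs exactly one map per condition")
  cells <- stats::aggregate(amplitude ~ subject + condition, data = df, FUN = mean)
  bc <- boxcox_normalize(cells$amplitude, force = TRUE)
  cells$value <- bc$values
  an <- rm_anova(cells, dv = "value", within = "condition")
  spec <- stats::aggregate(amplitude ~ condition + frequency, data = df, FUN = mean)
  list(anova = an, spectra = spec, lambda = bc$lambda)
}
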