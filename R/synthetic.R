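#' Configuration for the synthetic session generator
#'
#' Describes a study cohort's signal structure: per-condition, per-band,
#' per-region EEG power multipliers, cross-region phase coupling, respiration
#' rates and the 1/f background level. Defaults encode the direction of the
#' condition contrasts this pipeline is designed to detect: theta and beta
#' power elevated during meditation in (almost) all regions, alpha elevated
#' occipitally and right-temporally, stronger cross-region alpha coupling, and
#' slower breathing during meditation.
#'
#' @param n_channels number of EEG channels (default 32; fewer channels take a
#'   region-balanced subset of the montage).
#' @param fs_native native sampling rate in Hz (default 256).
#' @param duration session length in seconds (default 900, i.e. 15 minutes);
#'   `duration * fs_native` must be an integer.
#' @param bands named list of `c(lo, hi)` Hz band edges synthesized as
#'   independent narrowband (band-pass-filtered Gaussian) processes.
#' @param band_power nested list `condition -> band -> named region vector` of
#'   positive variance multipliers; see [default_band_power()].
#' @param coupling_strength named per-condition coefficient in `[0,1]`: the
#'   fraction (in amplitude) of the coupling band replaced by a source shared
#'   across all channels, which raises cross-region phase synchrony.
#' @param coupling_band `c(lo, hi)` Hz band carrying the shared source.
#' @param resp_rate named per-condition breathing frequency in Hz.
#' @param noise_floor relative amplitude of the 1/f background process.
#' @param seed integer master seed; sessions are pure functions of
#'   `(config, subject_id, condition)`.
#' @return object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_channels = 32, fs_native = 256, duration = 900,
                             bands = eeg_bands(),
                             band_power = default_band_power(names(bands)),
                             coupling_strength = c(meditation = 0.90, control = 0.20),
                             coupling_band = c(8, 12),
                             resp_rate = c(meditation = 0.13, control = 0.25),
                             noise_floor = 0.3, seed = 1L) {
  stopifnot(n_channels >= 1, n_channels <= 32, fs_native > 0, duration > 0)
  n <- duration * fs_native
  if (abs(n - round(n)) > 1e-9) stop("duration * fs_native must be an integer sample count")
  for (cond in names(band_power)) for (b in names(band_power[[cond]])) {
    if (any(band_power[[cond]][[b]] <= 0)) stop("all power multipliers must be > 0")
  }
  if (any(coupling_strength < 0 | coupling_strength > 1))
    stop("coupling_strength must lie in [0,1]")
  if (any(resp_rate <= 0 | resp_rate >= fs_native / 2))
    stop("resp_rate must lie in (0, fs_native/2)")
  hi <- max(vapply(bands, max, numeric(1)))
  if (hi >= fs_native / 2)
    stop("highest synthesized band edge (", hi, " Hz) must be below Nyquist")
  labels <- reduced_montage(n_channels)
  structure(
    list(n_channels = n_channels, fs_native = fs_native, duration = duration,
         bands = bands, band_power = band_power,
         coupling_strength = coupling_strength, coupling_band = coupling_band,
         resp_rate = resp_rate, noise_floor = noise_floor, seed = as.integer(seed),
         channels = labels),
    class = "synthetic_config")
}

#' Default per-condition band-power multipliers
#'
#' Control multipliers are 1 in every cell. Meditation multipliers follow the
#' qualitative pattern this pipeline targets: beta and theta raised in all
#' regions (theta essentially flat frontally), alpha raised mainly in the
#' occipital and right temporal regions and slightly lowered parietally.
#'
#' @param band_names which bands to include (subset of theta/alpha/beta).
#' @return nested list `condition -> band -> named numeric vector over regions`.
#' @export
default_band_power <- function(band_names = c("theta", "alpha", "beta")) {
  regions <- eeg_regions()
  rv <- function(frontal, central, parietal, occipital, rt, lt)
    stats::setNames(c(frontal, central, parietal, occipital, rt, lt), regions)
  meditation <- list(
    theta = rv(0.98, 1.60, 1.35, 1.70, 1.75, 1.40),
    alpha = rv(1.05, 1.15, 0.92, 1.12, 1.25, 1.06),
    beta  = rv(1.30, 1.55, 1.45, 1.45, 1.40, 1.35))
  control <- list(
    theta = rv(1, 1, 1, 1, 1, 1),
    alpha = rv(1, 1, 1, 1, 1, 1),
    beta  = rv(1, 1, 1, 1, 1, 1))
  list(meditation = meditation[band_names], control = control[band_names])
}

# Invented but realistic baseline variances (uV^2) per band and region:
# posterior alpha dominance, frontal theta, modest beta.
base_band_variance <- function() {
  regions <- eeg_regions()
  rv <- function(...) stats::setNames(c(...), regions)
  list(theta = rv(55, 22, 38, 85, 55, 55) * 0.9,
       alpha = rv(40, 20, 50, 160, 80, 72),
       beta  = rv(26, 16, 20, 31, 29, 28))
}

# Region-balanced subset of the 32-channel montage.
reduced_montage <- function(n_channels) {
  labels <- biosemi32_labels()
  if (n_channels == 32) return(labels)
  regions <- biosemi32_regions()[labels]
  # round-robin across regions so every region stays represented
  order_by_region <- unlist(lapply(seq_len(max(table(regions))), function(k) {
    labels[unlist(lapply(eeg_regions(), function(r) which(regions == r)[k]))]
  }))
  order_by_region <- order_by_region[!is.na(order_by_region)]
  sort_idx <- match(order_by_region[seq_len(n_channels)], labels)
  labels[sort(sort_idx)]
}

# Unit-variance Gaussian noise confined to [f1, f2) Hz by Fourier masking.
narrowband_noise <- function(n, f1, f2, fs) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)  # two-sided
  Z[!(f >= f1 & f < f2)] <- 0
  x <- Re(stats::fft(Z, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s == 0) stop("empty band [", f1, ",", f2, ") at fs=", fs)
  x / s
}

# 1/f-amplitude background, unit variance, band-limited to [f_lo, fs/2).
pink_noise <- function(n, fs, f_lo = 0.1) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  scale <- 1 / sqrt(pmax(f, 1))
  scale[f < f_lo] <- 0
  x <- Re(stats::fft(Z * scale, inverse = TRUE) / n)
  x / stats::sd(x)
}

# Smooth unit-variance modulation signal (lowpass noise below f_hi Hz).
slow_noise <- function(n, fs, f_hi = 0.05) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- (0:(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  Z[f > f_hi] <- 0
  x <- Re(stats::fft(Z, inverse = TRUE) / n)
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x / s
}

session_seed <- function(config, subject_id, condition) {
  sid <- sum(utf8ToInt(as.character(subject_id))) %% 65536
  base <- derive_seed(config$seed, "simulate", extra = sid)
  as.integer((as.numeric(base) + 31 * (condition == "meditation")) %% 2147483629 + 1)
}

#' Generate one synthetic EEG + respiration session
#'
#' EEG channels are superpositions of independent narrowband Gaussian
#' processes (one per band) whose variances are the baseline region variance
#' times `band_power[[condition]][[band]][region]`, plus a 1/f background.
#' When `coupling_strength[condition] > 0`, the coupling-band component of
#' every channel is mixed as `sqrt(1-rho^2) * own + rho * shared`, keeping the
#' band variance fixed while raising cross-channel phase synchrony.
#' Respiration is a quasi-sinusoid at `resp_rate[condition]` with slow
#' amplitude and frequency jitter. Identical `(config, subject_id, condition)`
#' give bit-identical output.
#'
#' @param config a [synthetic_config()].
#' @param subject_id subject identifier.
#' @param condition `"meditation"` or `"control"`.
#' @return list with elements `eeg` and `resp`, both [recording()]s.
#' @export
generate_session <- function(config, subject_id, condition) {
  stopifnot(inherits(config, "synthetic_config"))
  condition <- match.arg(condition, c("meditation", "control"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(session_seed(config, subject_id, condition))

  fs <- config$fs_native
  n <- as.integer(round(config$duration * fs))
  labels <- config$channels
  regions <- biosemi32_regions()[labels]
  base_var <- base_band_variance()
  bp <- config$band_power[[condition]]
  rho <- unname(config$coupling_strength[condition])
  cband <- config$coupling_band

  shared <- narrowband_noise(n, cband[1], cband[2], fs)
  x <- matrix(0, nrow = length(labels), ncol = n)
  for (i in seq_along(labels)) {
    region <- regions[i]
    ch <- numeric(n)
    total_var <- 0
    for (b in names(config$bands)) {
      edges <- config$bands[[b]]
      v_base <- if (b %in% names(base_var)) base_var[[b]][region] else 40
      mult <- bp[[b]][region]
      if (is.null(mult) || is.na(mult)) mult <- 1
      v <- v_base * mult
      own <- narrowband_noise(n, edges[1], edges[2], fs)
      overlaps <- edges[1] < cband[2] && edges[2] > cband[1]
      comp <- if (rho > 0 && overlaps) sqrt(1 - rho^2) * own + rho * shared else own
      ch <- ch + sqrt(v) * comp
      total_var <- total_var + v
    }
    if (config$noise_floor > 0)
      ch <- ch + config$noise_floor * sqrt(total_var) * pink_noise(n, fs)
    x[i, ] <- ch
  }
  eeg <- recording(x, fs, channel_labels = labels,
                   region_map = biosemi32_regions(),
                   condition = condition, subject_id = subject_id,
                   modality = "eeg", units = "uV")

  f0 <- unname(config$resp_rate[condition])
  # breathing variability is mostly breath-to-breath (correlation of a couple
  # of cycles), with a smaller slow drift on top
  finst <- f0 * (1 + 0.06 * slow_noise(n, fs, f_hi = f0 / 3) +
                   0.02 * slow_noise(n, fs, f_hi = 0.02))
  amp <- 1 + 0.12 * slow_noise(n, fs, f_hi = f0 / 2) +
    0.05 * slow_noise(n, fs, f_hi = 0.03)
  phase <- 2 * pi * cumsum(finst) / fs
  r <- amp * sin(phase) + 0.03 * stats::rnorm(n)
  resp <- recording(matrix(r, nrow = 1), fs, channel_labels = "Resp",
                    condition = condition, subject_id = subject_id,
                    modality = "respiration", units = "a.u.")
  list(eeg = eeg, resp = resp)
}

#' Generate a labeled cohort of synthetic sessions
#'
#' @param config a [synthetic_config()].
#' @param n_subjects number of subjects; each contributes one meditation and
#'   one control session.
#' @return list of sessions; each element has `eeg`, `resp` (see
#'   [generate_session()]).
#' @export
generate_cohort <- function(config, n_subjects) {
  out <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (cond in c("meditation", "control")) {
      out[[paste(sid, cond, sep = "_")]] <- generate_session(config, sid, cond)
    }
  }
  out
}

#' Inject stereotyped artifacts into a recording
#'
#' Adds eye blinks (0.5 s raised-cosine transients with a frontal-dominant
#' spatial pattern), high-voltage segments exceeding the 200 uV rejection
#' bound on every channel, and/or scales chosen channels below the 2 uV flat
#' bound -- the three artifact classes the preprocessing stage must catch.
#'
#' @param rec an EEG [recording()].
#' @param blink_rate blink events per minute (>= 0).
#' @param hv_segments list of `c(start_s, duration_s, amplitude_uV)` entries.
#' @param flat_channels channel labels to flatten below 2 uV.
#' @param blink_amplitude peak blink amplitude in uV at the frontal pole.
#' @param seed seed for blink timing (defaults to a fixed value so injection
#'   is reproducible).
#' @return the modified recording; blink times are attached as
#'   `attr(, "artifact_log")`.
#' @export
inject_artifacts <- function(rec, blink_rate = 0, hv_segments = list(),
                             flat_channels = character(0),
                             blink_amplitude = 120, seed = 99L) {
  stopifnot(inherits(rec, "recording"), blink_rate >= 0, blink_amplitude >= 0)
  x <- rec$samples
  fs <- rec$fs
  n <- ncol(x)
  log <- list(blinks = numeric(0), hv = hv_segments, flat = flat_channels)

  if (blink_rate > 0) {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    n_blinks <- max(1L, round(blink_rate * n / fs / 60))
    len <- round(0.5 * fs)
    template <- blink_amplitude * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = len)))
    starts <- sort(sample.int(n - len, n_blinks))
    w <- blink_spatial_weights(rec)
    for (s0 in starts) {
      idx <- s0:(s0 + len - 1)
      x[, idx] <- x[, idx] + outer(w, template)
    }
    log$blinks <- starts / fs
  }

  for (seg in hv_segments) {
    start <- seg[1]; dur <- seg[2]; amp <- seg[3]
    if (amp < 0 || dur <= 0) stop("hv segment amplitude/duration must be positive")
    i0 <- floor(start * fs) + 1
    i1 <- floor((start + dur) * fs)
    if (i0 < 1 || i1 > n) stop("hv segment outside recording duration")
    x[, i0:i1] <- x[, i0:i1] + amp
  }

  for (ch in flat_channels) {
    i <- match(ch, rec$channel_labels)
    if (is.na(i)) stop("unknown channel: ", ch)
    peak <- max(abs(x[i, ]))
    if (peak > 0) x[i, ] <- x[i, ] * (1.0 / peak)
  }

  out <- with_samples(rec, x)
  attr(out, "artifact_log") <- log
  out
}

# Blink topography: strongest at the frontal pole, decaying towards the back.
blink_spatial_weights <- function(rec) {
  regions <- biosemi32_regions()[rec$channel_labels]
  w <- c(frontal = 1, central = 0.35, parietal = 0.12, occipital = 0.05,
         right_temporal = 0.22, left_temporal = 0.22)[regions]
  w <- unname(w)
  w[rec$channel_labels %in% c("Fp1", "Fp2")] <- 1.3
  w[is.na(w)] <- 0.1
  w
}
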