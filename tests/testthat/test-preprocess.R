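test_that("bandpass removes DC, keeps 10 Hz, and meets stopband at 50 Hz", {
  fs <- 256
  bp <- design_fir("bandpass", c(2, 35), fs)
  n <- 8192
  x <- 5 + sin(2 * pi * 10 * (0:(n - 1)) / fs)
  y <- fir_filter(x, bp)
  X <- Mod(stats::fft(x)); Y <- Mod(stats::fft(y))
  fr <- (0:(n - 1)) * fs / n
  expect_lt(20 * log10((Y[1] + 1e-12) / X[1]), -40)          # DC down > 40 dB
  i10 <- which.min(abs(fr - 10))
  expect_lt(abs(Y[i10] / X[i10] - 1), 0.05)                  # 10 Hz within 5%
  x50 <- sin(2 * pi * 50 * (0:(n - 1)) / fs)
  y50 <- fir_filter(x50, bp)
  mid <- 2000:6000
  expect_lt(20 * log10(stats::sd(y50[mid]) / stats::sd(x50[mid])), -40)
  expect_equal(as.numeric(fir_filter(rep(0, 1000), bp)), rep(0, 1000))
})

test_that("passband filtering is idempotent within 1%", {
  fs <- 256
  bp <- design_fir("bandpass", c(2, 35), fs)
  x <- sin(2 * pi * 10 * (0:8191) / fs)
  y1 <- fir_filter(x, bp)
  y2 <- fir_filter(y1, bp)
  mid <- 3000:5000
  expect_lt(max(abs(y2[mid] - y1[mid])) / max(abs(y1[mid])), 0.01)
})

test_that("filter design rejects edges at or beyond Nyquist", {
  expect_error(design_fir("lowpass", 128, 256), "inside")
  expect_error(design_fir("bandpass", c(35, 2), 256), "lo < hi")
})

test_that("amplitude mask rejects nothing on clean data and flags flat channels", {
  cfg <- small_config(seed = 4)
  rec <- generate_session(cfg, "S01", "control")$eeg
  m <- amplitude_artifact_mask(rec)
  expect_true(all(m$keep))
  expect_identical(m$flat_channels, character(0))

  low <- mindsig:::with_samples(rec, rec$samples * (1 / max(abs(rec$samples))))
  m2 <- amplitude_artifact_mask(low)
  expect_true(all(rec$channel_labels %in% m2$flat_channels))
  expect_false(any(m2$keep))

  bad <- rec; bad$samples[1, 10] <- NaN
  expect_error(amplitude_artifact_mask(bad), "non-finite")
})

test_that("masked segments are excluded exactly from Bartlett averaging", {
  cfg <- small_config(seed = 8, n_channels = 1)
  rec <- generate_session(cfg, "S01", "control")$eeg
  hv <- inject_artifacts(rec, hv_segments = list(c(4, 2, 800)))
  m <- amplitude_artifact_mask(hv)
  N <- 512
  p_masked <- bartlett_psd(hv, N, mask = m)
  # oracle: average periodograms over fully-kept segments only
  w <- blackman_harris(N)
  starts <- seq(1, ncol(hv$samples) - N + 1, by = N)
  kept <- starts[vapply(starts, function(s0) all(m$keep[1, s0:(s0 + N - 1)]),
                        logical(1))]
  acc <- 0
  for (s0 in kept) {
    X <- stats::fft(hv$samples[1, s0:(s0 + N - 1)] * w)
    acc <- acc + Mod(X[1:(N / 2 + 1)])^2 / N
  }
  expect_equal(p_masked$power[1, ], acc / length(kept), tolerance = 1e-12)
  expect_equal(p_masked$n_segments[1], length(kept))
  expect_lt(length(kept), length(starts))
})

test_that("infomax ICA recovers a two-source mixture", {
  set.seed(1)
  n <- 5000
  s1 <- as.numeric(scale(sin(2 * pi * 7 * (1:n) / 256) *
                           (1 + 0.3 * sin(2 * pi * 0.2 * (1:n) / 256))))
  s2 <- as.numeric(scale(stats::runif(n, -1, 1)^3))
  X <- matrix(c(1, .6, .4, 1), 2) %*% rbind(s1, s2)
  ic <- infomax_ica(X, seed = 2)
  cr <- abs(stats::cor(t(ic$sources), cbind(s1, s2)))
  expect_gte(max(cr[, 1]), 0.95)
  expect_gte(max(cr[, 2]), 0.95)
})

test_that("ocular ICA removes blinks but spares alpha; identity without blinks", {
  cfg <- small_config(seed = 5, n_channels = 12, duration = 40,
                      coupling_strength = c(meditation = 0.2, control = 0.2))
  s <- generate_session(cfg, "S1", "meditation")$eeg
  sb <- inject_artifacts(s, blink_rate = 15)
  cl <- remove_ocular_ica(sb, seed = 3)
  frontal <- which(biosemi32_regions()[s$channel_labels] == "frontal")
  lowpow <- function(rec) {
    p <- bartlett_psd(rec, 512)
    mean(p$power[frontal, p$frequencies > 0.2 & p$frequencies < 2])
  }
  alphapow <- function(rec) {
    p <- bartlett_psd(rec, 512)
    mean(p$power[, p$frequencies >= 8 & p$frequencies < 12])
  }
  removed_frac <- 1 - (lowpow(cl) - lowpow(s)) / (lowpow(sb) - lowpow(s))
  expect_gte(removed_frac, 0.8)
  expect_lte(abs(alphapow(cl) / alphapow(sb) - 1), 0.10)
  expect_gte(length(attr(cl, "ica_report")$removed), 1)

  cl0 <- remove_ocular_ica(s, seed = 3)
  expect_length(attr(cl0, "ica_report")$removed, 0)
  expect_lt(max(abs(cl0$samples - s$samples)) / max(abs(s$samples)), 1e-8)
})

test_that("ICA cleanup does not inflate non-frontal variance", {
  cfg <- small_config(seed = 9, n_channels = 12, duration = 40)
  s <- generate_session(cfg, "S1", "control")$eeg
  sb <- inject_artifacts(s, blink_rate = 10)
  cl <- remove_ocular_ica(sb, seed = 4)
  nf <- biosemi32_regions()[s$channel_labels] != "frontal"
  v_before <- sum(apply(sb$samples[nf, ], 1, stats::var))
  v_after <- sum(apply(cl$samples[nf, ], 1, stats::var))
  expect_lte(v_after, v_before * 1.01)
})

test_that("downsampling decimates by an integer factor and guards aliasing", {
  fs <- 256
  x10 <- recording(matrix(sin(2 * pi * 10 * (0:25599) / fs), 1), fs)
  d <- downsample(x10, 64)
  expect_equal(d$fs, 64)
  expect_equal(ncol(d$samples), 6400)
  expect_lt(abs(max(abs(d$samples[1, 100:6000])) - 1), 0.02)
  x40 <- recording(matrix(sin(2 * pi * 40 * (0:2559) / fs), 1), fs)
  expect_error(downsample(x40, 64), "Nyquist")
  expect_error(downsample(x10, 48), "integer")
})

test_that("transient discard trims consistently and removes the step transient", {
  cfg <- small_config(seed = 1, n_channels = 2)
  rec <- generate_session(cfg, "S01", "control")$eeg
  expect_identical(discard_transient(rec, 0)$samples, rec$samples)
  tr <- discard_transient(rec, 100)
  expect_equal(ncol(tr$samples), ncol(rec$samples) - 100)
  expect_equal(tr$samples[, 1], rec$samples[, 101])
  expect_error(discard_transient(rec, ncol(rec$samples)), "length")

  # step response: after one filter length the lowpass output is settled
  fs <- 256
  lp <- design_fir("lowpass", 30, fs, transition = 2)
  step <- c(rep(0, 200), rep(1, 8000))
  y <- fir_filter(step, lp)
  settled <- y[(lp$taps + 201):7500]
  expect_lt(max(abs(settled - 1)), 0.01)
})
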