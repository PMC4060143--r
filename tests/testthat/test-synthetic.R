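test_that("identical config and seed give bit-identical sessions", {
  cfg <- small_config(seed = 7)
  a <- generate_session(cfg, "S01", "meditation")
  b <- generate_session(cfg, "S01", "meditation")
  expect_identical(a$eeg$samples, b$eeg$samples)
  expect_identical(a$resp$samples, b$resp$samples)
  c_ <- generate_session(cfg, "S02", "meditation")
  expect_false(identical(a$eeg$samples, c_$eeg$samples))
})

test_that("a single synthesized band is narrowband where requested", {
  bp <- list(meditation = list(alpha = stats::setNames(rep(1, 6), eeg_regions())),
             control = list(alpha = stats::setNames(rep(1, 6), eeg_regions())))
  cfg <- synthetic_config(n_channels = 1, duration = 20,
                          bands = list(alpha = c(8, 12)), band_power = bp,
                          coupling_strength = c(meditation = 0, control = 0),
                          noise_floor = 0, seed = 3)
  s <- generate_session(cfg, "S01", "control")$eeg
  psd <- bartlett_psd(s, 1024)
  pk <- psd$frequencies[which.max(psd$power[1, ])]
  expect_gte(pk, 8); expect_lt(pk, 12)
  # essentially no power outside the band
  out_band <- psd$frequencies < 6 | psd$frequencies > 14
  expect_lt(mean(psd$power[1, out_band]), 0.01 * max(psd$power[1, ]))
})

test_that("band-power multiplier of 2 doubles the band PSD (variance scaling)", {
  bp <- default_band_power()
  for (r in eeg_regions()) bp$meditation$theta[r] <- 2.0
  for (b in c("alpha", "beta")) bp$meditation[[b]][] <- 1
  ratios <- vapply(1:6, function(sd) {
    cfg <- synthetic_config(n_channels = 6, duration = 60, band_power = bp,
                            coupling_strength = c(meditation = 0, control = 0),
                            noise_floor = 0, seed = sd)
    ps <- lapply(c("meditation", "control"), function(cc) {
      bartlett_psd(generate_session(cfg, "S1", cc)$eeg, 1024)
    })
    th <- vapply(ps, function(p)
      mean(p$power[, p$frequencies >= 4 & p$frequencies < 8]), numeric(1))
    th[1] / th[2]
  }, numeric(1))
  expect_gt(mean(ratios), 1.7)
  expect_lt(mean(ratios), 2.3)
})

test_that("respiration dominant frequency tracks resp_rate within a bin", {
  cfg <- small_config(seed = 5, duration = 120)
  for (cond in c("meditation", "control")) {
    r <- generate_session(cfg, "S01", cond)$resp
    d <- downsample(recording(r$samples, r$fs, channel_labels = "Resp",
                              modality = "respiration"), 8, alias_tol = 0.2)
    tf <- stransform(d$samples[1, ], 8, 0.0625, 1, 0.0625)
    peak <- tf$frequencies[which.max(rowMeans(st_amplitude(tf)))]
    expect_lte(abs(peak - cfg$resp_rate[cond]), 0.0625)
  }
})

test_that("cross-region PLV is non-decreasing in coupling strength", {
  mean_plv <- function(rho, seed) {
    cfg <- synthetic_config(n_channels = 6, duration = 20, seed = seed,
                            coupling_strength = c(meditation = rho, control = 0))
    rec <- generate_session(cfg, "S01", "meditation")$eeg
    s <- pair_plv_summaries(rec, freqs = c(9, 10, 11),
                            bands = list(alpha = c(8, 12)))
    mean(s$median_plv)
  }
  seeds <- 1:7
  m <- vapply(c(0, 0.45, 0.9), function(r)
    mean(vapply(seeds, function(s) mean_plv(r, s), numeric(1))), numeric(1))
  expect_true(all(diff(m) > 0))
})

test_that("artifact injection is identity at zero rates and honors its contracts", {
  cfg <- small_config(seed = 2)
  rec <- generate_session(cfg, "S01", "control")$eeg
  expect_equal(inject_artifacts(rec)$samples, rec$samples)

  hv <- inject_artifacts(rec, hv_segments = list(c(5, 1, 500)))
  mask <- amplitude_artifact_mask(hv)
  rejected <- which(!mask$keep[1, ])
  lo <- floor(5 * rec$fs) + 1; hi <- floor(6 * rec$fs)
  g <- round(0.25 * rec$fs)
  expect_true(all(lo:hi %in% rejected))
  expect_true(all(rejected >= lo - g & rejected <= hi + g))

  fl <- inject_artifacts(rec, flat_channels = rec$channel_labels[3])
  expect_lt(max(abs(fl$samples[3, ])), 2)
  expect_error(inject_artifacts(rec, hv_segments = list(c(19.9, 1, 500))),
               "outside")
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(duration = 1.00001), "integer sample count")
  expect_error(synthetic_config(resp_rate = c(meditation = -1, control = 0.25)),
               "resp_rate")
  expect_error(synthetic_config(coupling_strength = c(meditation = 2, control = 0)),
               "coupling_strength")
  expect_error(synthetic_config(bands = list(hf = c(100, 140))), "Nyquist")
  bp <- default_band_power()
  bp$meditation$theta[1] <- -1
  expect_error(synthetic_config(band_power = bp), "multipliers")
})
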