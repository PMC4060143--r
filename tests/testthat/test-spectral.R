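test_that("Bartlett PSD matches the direct summation and basic constructions", {
  expect_equal(max(bartlett_psd(rep(0, 512), 128, fs = 64)$power), 0)

  set.seed(3)
  x <- rnorm(512)
  p <- bartlett_psd(x, 128, fs = 64)
  expect_equal(max(abs(p$power[1, ] - bartlett_brute(x, 128, 64))), 0,
               tolerance = 1e-9)

  # exact-bin sinusoid peaks at its bin, Blackman-Harris sidelobes far down
  fs <- 64; N <- 256
  xs <- sin(2 * pi * 8 * (0:2047) / fs)
  ps <- bartlett_psd(xs, N, fs = fs)
  expect_equal(ps$frequencies[which.max(ps$power[1, ])], 8)
  far <- abs(ps$frequencies - 8) > 2
  expect_lt(max(ps$power[1, far]) / max(ps$power[1, ]), 10^(-60 / 10))
})

test_that("PSD of white noise is flat and scales with amplitude squared", {
  set.seed(11)
  acc <- 0
  for (i in 1:100) acc <- acc + bartlett_psd(rnorm(8192), 256, fs = 64)$power[1, ]
  p <- acc / 100
  f <- bartlett_psd(rnorm(256), 256, fs = 64)$frequencies
  band <- f >= 4 & f <= 30
  expect_lt(max(abs(p[band] / mean(p[band]) - 1)), 0.10)  # flat within 10%

  set.seed(12)
  x <- rnorm(2048)
  p1 <- bartlett_psd(x, 256, fs = 64)$power
  expect_equal(bartlett_psd(-x, 256, fs = 64)$power, p1)
  expect_equal(bartlett_psd(3 * x, 256, fs = 64)$power, 9 * p1)
})

test_that("band/region aggregation averages frequencies then channels", {
  psd <- structure(list(
    frequencies = seq(0, 31, by = 1),
    power = rbind(Fp1 = rep(2, 32), AF3 = rep(4, 32), Cz = rep(10, 32)),
    segment_length = 64, n_segments = c(1, 1, 1), window = NULL, fs = 64),
    class = "psd_estimate")
  tab <- band_region_power(psd, biosemi32_regions(),
                           subject_id = "S1", condition = "control")
  expect_equal(tab$power[tab$band == "alpha" & tab$region == "frontal"], 3)
  expect_equal(tab$power[tab$band == "theta" & tab$region == "central"], 10)
  expect_error(band_region_power(psd, biosemi32_regions(),
                                 bands = list(hf = c(40, 50))), "band")
})

test_that("Box-Cox recovers the expected exponent classes", {
  set.seed(21)
  ln <- exp(rnorm(500))
  bc <- boxcox_normalize(ln, force = TRUE)
  expect_gte(bc$lambda, -0.2); expect_lte(bc$lambda, 0.2)

  # positive normal data with spread comparable to the mean: lambda is
  # identifiable and close to 1 (a tight-spread shifted normal leaves the
  # profile likelihood almost flat in lambda)
  nm <- rnorm(500, mean = 12, sd = 3)
  bc2 <- boxcox_normalize(nm, force = TRUE)
  expect_gte(bc2$lambda, 0.7); expect_lte(bc2$lambda, 1.3)

  # a normal sample passes the pre-test and is left untouched
  bc3 <- boxcox_normalize(nm)
  expect_false(bc3$applied)
  expect_identical(bc3$values, nm)

  # lambda = 1 is the shift x - 1 exactly
  y <- (c(2, 4, 6)^1 - 1) / 1
  expect_equal(y, c(1, 3, 5))
  expect_error(boxcox_normalize(c(1, -2, 3)), "positive")
})

test_that("two-way within-subject ANOVA matches aov and hand-computed SS", {
  set.seed(42)
  d <- expand.grid(subject = paste0("s", 1:3), condition = c("a", "b"),
                   region = c("x", "y"))
  d$power <- rnorm(12)
  mine <- rm_anova(d, dv = "power", within = c("condition", "region"))
  or <- summary(stats::aov(power ~ condition * region +
                             Error(subject / (condition * region)), data = d))
  f_or <- c(or[["Error: subject:condition"]][[1]]["condition", "F value"],
            or[["Error: subject:region"]][[1]]["region", "F value"],
            or[["Error: subject:condition:region"]][[1]]["condition:region", "F value"])
  expect_equal(mine$F, unname(f_or), tolerance = 1e-10)
  expect_equal(mine$df1, c(1, 1, 1))
  expect_equal(mine$df2, c(2, 2, 2))

  # identical cells -> all F = 0
  d0 <- d; d0$power <- 5
  expect_equal(rm_anova(d0, dv = "power", within = c("condition", "region"))$F,
               c(0, 0, 0))
})

test_that("ANOVA F is invariant to shifting and positive scaling", {
  set.seed(43)
  d <- expand.grid(subject = paste0("s", 1:6), condition = c("a", "b"),
                   region = eeg_regions())
  d$power <- rnorm(nrow(d)) + (d$condition == "a") * 0.5
  f0 <- rm_anova(d, dv = "power", within = c("condition", "region"))$F
  d$power <- 100 + 3 * d$power
  f1 <- rm_anova(d, dv = "power", within = c("condition", "region"))$F
  expect_equal(f0, f1, tolerance = 1e-10)
})

test_that("an injected pure condition effect dominates the interaction", {
  set.seed(44)
  d <- expand.grid(subject = paste0("s", 1:8), condition = c("meditation", "control"),
                   region = eeg_regions())
  d$power <- rnorm(nrow(d), sd = 0.3) + ifelse(d$condition == "meditation", 2, 0)
  res <- rm_anova(d, dv = "power", within = c("condition", "region"))
  f_cond <- res$F[res$effect == "condition"]
  f_int <- res$F[res$effect == "condition:region"]
  expect_gt(f_cond, 10 * f_int)
  cm <- attr(res, "cell_means")
  expect_true(all(cm["meditation", ] > cm["control", ]))
})

test_that("replicate rows collapse to the same F as pre-averaged cells", {
  set.seed(45)
  d <- expand.grid(subject = paste0("s", 1:4), condition = c("a", "b"),
                   rep = 1:5)
  d$power <- rnorm(nrow(d)) + (d$condition == "a") * 1
  f_rep <- rm_anova(d, dv = "power", within = "condition")$F
  dm <- stats::aggregate(power ~ subject + condition, d, mean)
  f_cell <- rm_anova(dm, dv = "power", within = "condition")$F
  expect_equal(f_rep, f_cell, tolerance = 1e-12)
})
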