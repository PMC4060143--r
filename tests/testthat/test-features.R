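test_that("feature vectors follow the channel-major, frequency-ordered layout", {
  m1 <- fake_tf_map(3, 10, seed = 1)
  f1 <- extract_features(list(chA = m1))
  expect_equal(dim(f1$x), c(10, 3))
  expect_equal(f1$x[4, ], Mod(m1$coefficients[, 4]),
               ignore_attr = TRUE)
  expect_equal(colnames(f1$x), paste0("chA_", 1:3, "Hz"))

  maps32 <- lapply(1:32, function(i) fake_tf_map(113, 4, seed = i))
  names(maps32) <- paste0("c", 1:32)
  f32 <- extract_features(maps32)
  expect_equal(ncol(f32$x), 3616)

  bad <- list(a = fake_tf_map(3, 10), b = fake_tf_map(4, 10))
  expect_error(extract_features(bad), "grid")
})

test_that("a grid sinusoid dominates its own coordinate in every vector", {
  fs <- 64
  x <- sin(2 * pi * 10 * (0:1023) / fs)
  tf <- stransform(x, fs, 4, 16, 2)
  f <- extract_features(list(cz = tf))
  dominant <- apply(f$x[200:800, ], 1, which.max)
  expect_true(all(tf$frequencies[dominant] == 10))
})

test_that("KCCA index separates dependence from independence and obeys kappa", {
  set.seed(10)
  x <- matrix(rnorm(100 * 3), 100)
  self <- kcca_dependency(x, x)
  expect_equal(self$value, kcca_oracle(x, x, 0.02, self$sigma_x, self$sigma_y),
               tolerance = 1e-4)
  expect_gt(self$value, 0.8)
  set.seed(11)
  y2 <- x + matrix(rnorm(100 * 3, sd = 0.5), 100)
  dep <- kcca_dependency(x, y2)
  expect_equal(dep$value, kcca_oracle(x, y2, 0.02, dep$sigma_x, dep$sigma_y),
               tolerance = 1e-4)

  ind <- vapply(1:8, function(i) {
    a <- matrix(rnorm(200 * 3), 200); b <- matrix(rnorm(200 * 3), 200)
    kcca_dependency(a, b)$value
  }, numeric(1))
  expect_lt(mean(ind), self$value - 0.4)

  # index decreases with the regularizer and vanishes as kappa grows
  a <- matrix(rnorm(200 * 3), 200); b <- matrix(rnorm(200 * 3), 200)
  v <- vapply(c(0.02, 0.2, 2), function(k) kcca_dependency(a, b, kappa = k)$value,
              numeric(1))
  expect_true(all(diff(v) < 0))
  expect_lt(kcca_dependency(x, x, kappa = 1000)$value, 0.01)

  expect_warning(kcca_dependency(matrix(1, 50, 2), matrix(rnorm(100), 50)),
                 "degenerate")
  expect_error(kcca_dependency(matrix(rnorm(10), 5), matrix(rnorm(10), 5)),
               "20")
  expect_error(kcca_dependency(x, x, kappa = 0), "kappa")
})

test_that("lag-0 dependency is the maximum over lags for stationary sequences", {
  set.seed(11)
  z <- sapply(1:3, function(j) as.numeric(stats::arima.sim(list(ar = 0.7), 300)))
  sel <- quiet(select_downsampling_factor(z, max_lag = 5, max_n = 150))
  expect_equal(which.max(sel$index), 1)
})

test_that("the first-local-minimum rule picks small lags for iid features", {
  set.seed(3)
  L <- vapply(1:5, function(i) {
    z <- matrix(rnorm(300 * 4), 300)
    quiet(select_downsampling_factor(z, max_lag = 6, max_n = 200))$L
  }, integer(1))
  expect_gte(mean(L == 1L), 0.8)
})

test_that("slower-decaying dependence yields larger downsampling factors", {
  arL <- function(phi, seed) {
    set.seed(seed)
    z <- sapply(1:4, function(j) as.numeric(stats::arima.sim(list(ar = phi), 400)))
    quiet(select_downsampling_factor(z, max_lag = 10, max_n = 150))$L
  }
  L9 <- vapply(1:8, function(s) arL(0.9, s), integer(1))
  L5 <- vapply(1:8, function(s) arL(0.5, s + 100), integer(1))
  expect_gte(mean(L9 >= L5), 0.9)
})

test_that("downsampling retains floor(N/L) label-aligned samples", {
  f <- extract_features(list(a = fake_tf_map(2, 1000)),
                        labels = rep(c("meditation", "control"), each = 500))
  d <- apply_downsampling(f, 7)
  expect_equal(nrow(d$x), floor(1000 / 7))  # 142
  expect_equal(d$labels, f$labels[seq(1, by = 7, length.out = 142)])
  expect_equal(d$L_ds, 7L)
  # label counts follow the stride arithmetic and stay near-balanced
  expect_equal(sum(d$labels == "meditation"), length(seq(1, 500, by = 7)))  # 72
  expect_equal(sum(d$labels == "control"), 142 - 72)
  expect_lt(abs(mean(d$labels == "meditation") - 0.5), 0.02)
})

test_that("min-max normalization follows the published per-group rule", {
  x <- matrix(c(2, 4, 6, 1, 2, 3), ncol = 2)
  n <- minmax_normalize(x)
  expect_equal(n[, 1], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_warning(minmax_normalize(cbind(x[, 1], rep(5, 3))), "zero-range")

  # per-group: each split maps its own extremes to {0, 1}
  xx <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 1)
  g <- rep(c("train", "test"), each = 3)
  pg <- minmax_normalize(xx, split = g, method = "per_group")
  expect_equal(as.numeric(pg), c(0, 0.5, 1, 0, 0.5, 1))
  # train_bounds: the test rows inherit the training extremes
  tb <- minmax_normalize(xx, split = g, method = "train_bounds")
  expect_equal(as.numeric(tb[1:3]), c(0, 0.5, 1))
  expect_gt(max(tb[4:6]), 1)
})

test_that("the RBF-SVM separates well-separated classes and is chance on shuffles", {
  set.seed(20)
  n <- 200
  x <- rbind(matrix(rnorm(n / 2 * 4), ncol = 4),
             matrix(rnorm(n / 2 * 4, mean = 8), ncol = 4))
  y <- rep(c("meditation", "control"), each = n / 2)
  rep1 <- quiet(train_eval_svm(x, y, folds = 10, cost_grid = c(1, 10)))
  expect_gte(rep1$accuracy, 0.99)
  expect_length(rep1$decision_values, n)

  # feature-order permutation leaves the kernel, hence the accuracy, unchanged
  rep2 <- quiet(train_eval_svm(x[, c(3, 1, 4, 2)], y, folds = 10,
                               cost_grid = c(1, 10)))
  expect_equal(rep2$accuracy, rep1$accuracy)

  acc_null <- vapply(1:10, function(i) {
    set.seed(30 + i)
    ys <- sample(y)
    quiet(train_eval_svm(x, ys, folds = 10, fold_type = "random",
                         cost_grid = 1, sigma_grid = 4))$accuracy
  }, numeric(1))
  expect_gt(mean(acc_null), 0.4)
  expect_lt(mean(acc_null), 0.6)

  expect_error(train_eval_svm(x[98:103, ], y[98:103], folds = 10), "folds")
  expect_error(train_eval_svm(x, rep("a", n), folds = 10), "two classes")
})

test_that("joint features concatenate dimensions and reject misalignment", {
  eeg <- extract_features(lapply(1:32, function(i) fake_tf_map(113, 5, seed = i)))
  resp <- extract_features(list(fake_tf_map(256, 5, seed = 99)))
  joint <- build_joint_features(eeg, resp)
  expect_equal(ncol(joint$x), 3616 + 256)  # 3872

  short <- extract_features(list(fake_tf_map(256, 4, seed = 98)))
  expect_error(build_joint_features(eeg, short), "unalignable")
  empty <- extract_features(list(fake_tf_map(3, 5)))
  empty$x <- empty$x[0, , drop = FALSE]
  expect_error(build_joint_features(eeg, empty), "empty")
})

test_that("uninformative respiration features leave EEG accuracy unchanged", {
  set.seed(40)
  n <- 120
  xe <- rbind(matrix(rnorm(n / 2 * 6), ncol = 6),
              matrix(rnorm(n / 2 * 6, mean = 5), ncol = 6))
  y <- rep(c("meditation", "control"), each = n / 2)
  feeg <- structure(list(x = xe, frequencies = 1:6, channels = "e",
                         labels = y, L_ds = 1L), class = "feature_set")
  fresp <- structure(list(x = matrix(0, n, 3), frequencies = 1:3, channels = "r",
                          labels = y, L_ds = 1L), class = "feature_set")
  joint <- build_joint_features(feeg, fresp)
  a_eeg <- quiet(train_eval_svm(feeg, folds = 10, cost_grid = 1, sigma_grid = 3))
  a_joint <- quiet(train_eval_svm(joint, folds = 10, cost_grid = 1, sigma_grid = 3))
  expect_lte(abs(a_joint$accuracy - a_eeg$accuracy), 0.05)
})
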