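#' Assemble S-transform feature vectors
#'
#' For channels `c = 1..C` with S-transform amplitudes on a shared grid of `F`
#' frequencies, the feature vector at time `n` is the concatenation
#' `z_n = [z_1n', ..., z_Cn']'` with `z_cn = (|S_c(f_1,n]|, ..., |S_c(f_F,n]|)`
#' - channel-major blocks, frequency-ordered within each block. Amplitudes
#' (not complex coefficients) are used so the downstream kernels get real
#' inputs.
#'
#' @param tf_maps list of [stransform()] maps, one per channel, sharing the
#'   frequency and time grids.
#' @param labels optional per-time-sample class labels.
#' @return object of class `"feature_set"`: `x` (time samples x `C*F`
#'   features), `frequencies`, `channels`, `labels`, `L_ds` (1 until
#'   downsampled).
#' @export
extract_features <- function(tf_maps, labels = NULL) {
  if (inherits(tf_maps, "tf_map")) tf_maps <- list(tf_maps)
  f0 <- tf_maps[[1]]$frequencies
  n0 <- ncol(tf_maps[[1]]$coefficients)
  for (m in tf_maps) {
    if (!isTRUE(all.equal(m$frequencies, f0)) || ncol(m$coefficients) != n0)
      stop("channels do not share the time/frequency grid")
  }
  blocks <- lapply(tf_maps, function(m) t(Mod(m$coefficients)))
  x <- do.call(cbind, blocks)
  chn <- names(tf_maps) %||% paste0("ch", seq_along(tf_maps))
  colnames(x) <- as.vector(t(outer(chn, f0, function(c, f) paste0(c, "_", f, "Hz"))))
  if (!is.null(labels) && length(labels) != nrow(x))
    stop("one label per time sample required")
  structure(list(x = x, frequencies = f0, channels = chn,
                 labels = labels, L_ds = 1L),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d samples x %d features (%d channels x %d freqs), L_ds=%d\n",
              nrow(x$x), ncol(x$x), length(x$channels), length(x$frequencies), x$L_ds))
  invisible(x)
}

# Median pairwise Euclidean distance on a deterministic subsample.
median_pairwise_dist <- function(x, max_n = 300) {
  x <- as.matrix(x)
  sub <- x[even_subsample(nrow(x), max_n), , drop = FALSE]
  stats::median(stats::dist(sub))
}

#' Regularized KCCA dependency index
#'
#' First kernel canonical correlation between paired samples with Gaussian
#' kernels: the index is the square root of the largest eigenvalue of
#' `(Kx + n*kappa*I)^-1 Ky (Ky + n*kappa*I)^-1 Kx` on centered Gram matrices.
#' The `n*kappa` ridge follows from writing the population criterion's
#' denominator `var[g(x)] + kappa*||g||^2` in Gram form (`var` carries a
#' `1/n`). Inputs are deterministically subsampled to at most `max_n` points
#' for tractability; kernel widths default to each variable's median pairwise
#' distance.
#'
#' @param x,y paired samples: matrices (rows = observations) or vectors of
#'   equal length, at least 20 observations.
#' @param kappa ridge parameter, must be > 0 (default 0.02).
#' @param sigma_x,sigma_y Gaussian kernel widths (default: median heuristic).
#' @param max_n Gram matrices are capped at this many points.
#' @return object of class `"kcca_index"`: `value` in `[0,1]`, `kappa`,
#'   `sigma_x`, `sigma_y`, `n_used`.
#' @export
kcca_dependency <- function(x, y, kappa = 0.02, sigma_x = NULL, sigma_y = NULL,
                            max_n = 500) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must be paired (equal rows)")
  if (nrow(x) < 20) stop("need at least 20 paired samples")
  if (kappa <= 0) stop("kappa must be > 0")
  idx <- even_subsample(nrow(x), max_n)
  x <- x[idx, , drop = FALSE]; y <- y[idx, , drop = FALSE]
  n <- nrow(x)
  sigma_x <- sigma_x %||% median_pairwise_dist(x)
  sigma_y <- sigma_y %||% median_pairwise_dist(y)
  if (!is.finite(sigma_x) || sigma_x == 0 || !is.finite(sigma_y) || sigma_y == 0) {
    warning("degenerate (constant) input: KCCA index set to 0")
    return(structure(list(value = 0, kappa = kappa, sigma_x = sigma_x,
                          sigma_y = sigma_y, n_used = n), class = "kcca_index"))
  }
  Kx <- gauss_gram(x, sigma_x)
  Ky <- gauss_gram(y, sigma_y)
  H <- diag(n) - matrix(1 / n, n, n)
  Kx <- H %*% Kx %*% H
  Ky <- H %*% Ky %*% H
  R <- n * kappa * diag(n)
  A <- solve(Kx + R, Ky)
  B <- solve(Ky + R, Kx)
  ev <- eigen(A %*% B, only.values = TRUE)$values
  rho2 <- max(Re(ev))
  structure(list(value = sqrt(clamp01(rho2)), kappa = kappa,
                 sigma_x = sigma_x, sigma_y = sigma_y, n_used = n),
            class = "kcca_index")
}

gauss_gram <- function(x, sigma) {
  d2 <- as.matrix(stats::dist(x))^2
  exp(-d2 / (2 * sigma^2))
}

#' @export
print.kcca_index <- function(x, ...) {
  cat(sprintf("<kcca_index> %.4f (kappa=%g, n=%d)\n", x$value, x$kappa, x$n_used))
  invisible(x)
}

#' Select the KCCA downsampling factor
#'
#' Evaluates the dependency index `I(l)` between the feature sequence and its
#' lag-`l` shift for `l = 0..max_lag` and returns the smallest `L > 0` that is
#' a local minimizer: `I(L-1) > I(L)` and `I(L) <= I(L+1) + tol`, where
#' `tol = tie_tol * (I(0) - I(1))` scales with the curve's own initial drop.
#' The tolerance absorbs finite-sample noise on flat stretches (without it, an
#' exactly flat population curve is crossed at a random lag), while leaving
#' slowly decaying curves - where the drop at lag 1 is small - essentially
#' untouched. If no local minimum exists within `max_lag`, `max_lag` is
#' returned with a warning. Retained indices are
#' `1, 1+L, ..., 1+L*(floor(N/L)-1)`.
#'
#' @param features a `"feature_set"` or numeric matrix (rows = time samples).
#' @param max_lag largest lag scanned (>= 2).
#' @param tie_tol ascent tolerance as a fraction of `I(0) - I(1)`.
#' @param ... passed to [kcca_dependency()] (`kappa`, `max_n`, ...).
#' @return object of class `"kcca_selection"`: `L`, `index` (values at lags
#'   `0..max_lag`), `retained_idx`.
#' @export
select_downsampling_factor <- function(features, max_lag = 10, tie_tol = 0.1,
                                       ...) {
  x <- if (inherits(features, "feature_set")) features$x else as.matrix(features)
  if (max_lag < 2) stop("max_lag must be >= 2")
  N <- nrow(x)
  if (N < max_lag + 21) stop("not enough samples at the largest lag")
  I <- numeric(max_lag + 1)
  for (l in 0:max_lag) {
    a <- x[seq_len(N - l), , drop = FALSE]
    b <- x[seq_len(N - l) + l, , drop = FALSE]
    I[l + 1] <- kcca_dependency(a, b, ...)$value
  }
  L <- NA_integer_
  tol <- tie_tol * max(I[1] - I[2], 0)
  for (l in 1:(max_lag - 1)) {
    if (I[l] > I[l + 1] && I[l + 1] <= I[l + 2] + tol) { L <- l; break }
  }
  if (is.na(L)) {
    warning("no local minimum of I_KCCA within max_lag; using max_lag")
    L <- max_lag
  }
  retained <- seq(1L, by = L, length.out = floor(N / L))
  structure(list(L = as.integer(L), index = I, lags = 0:max_lag,
                 retained_idx = retained),
            class = "kcca_selection")
}

#' Apply a downsampling factor to a feature set
#'
#' @param features a `"feature_set"`.
#' @param L downsampling factor (or a `"kcca_selection"`).
#' @return the thinned feature set with `L_ds` recorded.
#' @export
apply_downsampling <- function(features, L) {
  stopifnot(inherits(features, "feature_set"))
  if (inherits(L, "kcca_selection")) L <- L$L
  idx <- seq(1L, by = L, length.out = floor(nrow(features$x) / L))
  features$x <- features$x[idx, , drop = FALSE]
  if (!is.null(features$labels)) features$labels <- features$labels[idx]
  features$L_ds <- as.integer(L)
  features
}

#' Min-max feature normalization
#'
#' `(x - min) / (max - min)` per feature. With `method = "per_group"` each
#' split (train/test/validation) uses its own extremes, exactly as the
#' original recipe states; `method = "train_bounds"` (the leakage-safe
#' default) computes bounds on the training split only and applies them
#' everywhere. Zero-range features map to 0 with a warning.
#'
#' @param x numeric matrix (rows = samples) or a `"feature_set"`.
#' @param split optional character/factor of group labels per row; for
#'   `"train_bounds"` the group named `"train"` defines the bounds (all rows
#'   when `split` is `NULL`).
#' @param method `"train_bounds"` or `"per_group"`.
#' @return normalized object of the same type, with the bounds in
#'   `attr(, "bounds")`.
#' @export
minmax_normalize <- function(x, split = NULL,
                             method = c("train_bounds", "per_group")) {
  method <- match.arg(method)
  fs_obj <- NULL
  if (inherits(x, "feature_set")) { fs_obj <- x; x <- x$x }
  x <- as.matrix(x)
  norm_block <- function(block, lo, hi) {
    rng <- hi - lo
    zero <- rng <= 0
    if (any(zero)) {
      warning(sum(zero), " zero-range feature(s) mapped to 0")
      rng[zero] <- 1
    }
    out <- sweep(sweep(block, 2, lo), 2, rng, "/")
    out[, zero] <- 0
    out
  }
  if (method == "per_group" && !is.null(split)) {
    out <- x
    for (g in unique(split)) {
      rows <- which(split == g)
      blk <- x[rows, , drop = FALSE]
      out[rows, ] <- norm_block(blk, apply(blk, 2, min), apply(blk, 2, max))
    }
    bounds <- NULL
  } else {
    ref_rows <- if (!is.null(split) && method == "train_bounds" && "train" %in% split)
      which(split == "train") else seq_len(nrow(x))
    lo <- apply(x[ref_rows, , drop = FALSE], 2, min)
    hi <- apply(x[ref_rows, , drop = FALSE], 2, max)
    out <- norm_block(x, lo, hi)
    bounds <- list(min = lo, max = hi)
  }
  if (!is.null(fs_obj)) {
    fs_obj$x <- out
    attr(fs_obj, "bounds") <- bounds
    return(fs_obj)
  }
  attr(out, "bounds") <- bounds
  out
}

#' RBF-SVM training with cross-validated hyperparameter selection
#'
#' Grid-searches the RBF width `sigma` and cost `c` by k-fold cross-validation.
#' Folds default to contiguous temporal blocks stratified by class: fold `k`
#' holds block `k` of each class's (temporally ordered) samples, so every fold
#' carries both classes and temporal-adjacency effects act on both classes
#' symmetrically instead of biasing the accuracy of autocorrelated features;
#' `fold_type = "random"` reproduces plain random folds. For strongly
#' autocorrelated features an embargo (`fold_gap`) additionally excludes
#' training samples within that many positions of the held-out block, the
#' standard guard against adjacency leakage in time-series cross-validation. Features are min-max normalized inside each fold: bounds from the
#' training part applied to the held-out part (`normalize = "train_bounds"`),
#' or each part on its own (`"per_group"`). Reports the CV accuracy at the
#' selected hyperparameters and the decision-function values of a final model
#' fit on all data -- the candidate "meditation depth" score.
#'
#' @param x numeric feature matrix or `"feature_set"` (rows = samples).
#' @param labels two-level factor/character of class labels (taken from the
#'   feature set when omitted).
#' @param folds number of CV folds (default 10).
#' @param fold_type `"blocked"` (contiguous) or `"random"`.
#' @param sigma_grid RBF width grid; default `2^(-4:4)` times the median
#'   pairwise distance.
#' @param cost_grid penalty grid; default `2^(-2:6)`.
#' @param normalize fold-wise normalization mode (see above).
#' @param fold_gap embargo width in sample positions (per class) around the
#'   held-out block; 0 disables it.
#' @param seed seed for random folds.
#' @return object of class `"classifier_report"`: `accuracy` (CV accuracy at
#'   the optimum), `sigma`, `cost`, `fold_accuracy`, `fold_id`,
#'   `decision_values`.
#' @export
train_eval_svm <- function(x, labels = NULL, folds = 10,
                           fold_type = c("blocked", "random"),
                           sigma_grid = NULL, cost_grid = 2^(-2:6),
                           normalize = c("train_bounds", "per_group"),
                           fold_gap = 0L, seed = 1L) {
  fold_type <- match.arg(fold_type)
  normalize <- match.arg(normalize)
  if (inherits(x, "feature_set")) {
    labels <- labels %||% x$labels
    x <- x$x
  }
  x <- as.matrix(x)
  if (is.null(labels)) stop("labels required")
  y <- factor(labels)
  if (nlevels(y) != 2) stop("exactly two classes required")
  N <- nrow(x)
  if (N < folds) stop("fewer samples than folds")
  pos_in_class <- integer(N)
  if (fold_type == "blocked") {
    fold_id <- integer(N)
    for (g in levels(y)) {
      rows <- which(y == g)
      fold_id[rows] <- ceiling(seq_along(rows) / length(rows) * folds)
      pos_in_class[rows] <- seq_along(rows)
    }
  } else {
    old_seed <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    fold_id <- sample(rep(seq_len(folds), length.out = N))
  }
  for (k in seq_len(folds)) {
    if (nlevels(droplevels(y[fold_id != k])) != 2)
      stop("training fold ", k, " lacks one of the classes")
  }
  if (is.null(sigma_grid)) sigma_grid <- 2^(-4:4) * median_pairwise_dist(x)
  sigma_grid <- sigma_grid[sigma_grid > 0]

  cv_acc <- function(sigma, cost) {
    acc <- rep(NA_real_, folds)
    for (k in seq_len(folds)) {
      tr <- fold_id != k; te <- !tr
      if (!any(te)) next
      if (fold_gap > 0L && fold_type == "blocked") {
        for (g in levels(y)) {
          rows <- y == g
          rng <- range(pos_in_class[rows & te])
          embargo <- rows & tr & pos_in_class >= rng[1] - fold_gap &
            pos_in_class <= rng[2] + fold_gap
          tr[embargo] <- FALSE
        }
        if (nlevels(droplevels(y[tr])) != 2) stop("embargo removed a whole class")
      }
      if (normalize == "train_bounds") {
        sp <- ifelse(tr, "train", "test")
        xn <- suppressWarnings(minmax_normalize(x, split = sp, method = "train_bounds"))
      } else {
        sp <- ifelse(tr, "train", "test")
        xn <- suppressWarnings(minmax_normalize(x, split = sp, method = "per_group"))
      }
      fit <- e1071::svm(xn[tr, , drop = FALSE], y[tr], kernel = "radial",
                        gamma = 1 / (2 * sigma^2), cost = cost, scale = FALSE)
      pred <- stats::predict(fit, xn[te, , drop = FALSE])
      acc[k] <- mean(pred == y[te])
    }
    acc
  }

  best <- list(acc = -Inf)
  for (sig in sigma_grid) for (cc in cost_grid) {
    a <- cv_acc(sig, cc)
    if (mean(a, na.rm = TRUE) > best$acc + 1e-12)
      best <- list(acc = mean(a, na.rm = TRUE), sigma = sig, cost = cc,
                   fold_acc = a)
  }
  xn_all <- suppressWarnings(minmax_normalize(x))
  final <- e1071::svm(xn_all, y, kernel = "radial",
                      gamma = 1 / (2 * best$sigma^2), cost = best$cost,
                      scale = FALSE, decision.values = TRUE)
  dv <- attr(stats::predict(final, xn_all, decision.values = TRUE),
             "decision.values")
  structure(list(accuracy = best$acc, sigma = best$sigma, cost = best$cost,
                 fold_accuracy = best$fold_acc, fold_id = fold_id,
                 decision_values = as.numeric(dv), levels = levels(y)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> CV accuracy %.3f (sigma=%.3g, cost=%.3g, %d folds)\n",
              x$accuracy, x$sigma, x$cost, length(x$fold_accuracy)))
  invisible(x)
}

#' Concatenate EEG and respiration features
#'
#' Joins the two modalities' full-rate feature vectors sample by sample; the
#' KCCA downsampling factor is then re-selected on the joint sequence by the
#' caller. Sample counts must match exactly (both modalities live on the same
#' post-preprocessing time grid).
#'
#' @param eeg_features,resp_features `"feature_set"` objects with equal sample
#'   counts and (if labeled) identical labels.
#' @return the joint `"feature_set"`.
#' @export
build_joint_features <- function(eeg_features, resp_features) {
  stopifnot(inherits(eeg_features, "feature_set"),
            inherits(resp_features, "feature_set"))
  if (nrow(eeg_features$x) == 0 || nrow(resp_features$x) == 0)
    stop("empty feature set")
  if (nrow(eeg_features$x) != nrow(resp_features$x))
    stop("unalignable sample counts: ", nrow(eeg_features$x), " vs ",
         nrow(resp_features$x))
  if (!is.null(eeg_features$labels) && !is.null(resp_features$labels) &&
      !identical(as.character(eeg_features$labels),
                 as.character(resp_features$labels)))
    stop("label sequences differ between modalities")
  structure(list(x = cbind(eeg_features$x, resp_features$x),
                 frequencies = list(eeg = eeg_features$frequencies,
                                    resp = resp_features$frequencies),
                 channels = c(eeg_features$channels, resp_features$channels),
                 labels = eeg_features$labels %||% resp_features$labels,
                 L_ds = 1L),
            class = "feature_set")
}
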