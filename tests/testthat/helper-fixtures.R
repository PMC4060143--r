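# Shared fixtures and independent brute-force oracles. Everything is built in
# code at test time; no stored data.

small_config <- function(seed = 1, n_channels = 6, duration = 20, ...) {
  synthetic_config(n_channels = n_channels, duration = duration, seed = seed, ...)
}

# A tf_map built by hand (for interface tests that do not need a transform).
fake_tf_map <- function(n_freq, n_time, fs = 64, seed = 1) {
  set.seed(seed)
  structure(list(
    coefficients = matrix(complex(real = rnorm(n_freq * n_time),
                                  imaginary = rnorm(n_freq * n_time)),
                          nrow = n_freq),
    frequencies = seq_len(n_freq), fs = fs), class = "tf_map")
}

# Direct O(N^2) evaluation of the S-transform double sum.
st_brute <- function(x, fs, freqs) {
  n <- length(x); m <- 0:(n - 1)
  S <- matrix(0i, length(freqs), n)
  for (j in seq_along(freqs)) {
    fc <- freqs[j] / fs
    base <- x * fc / sqrt(2 * pi) * exp(-2i * pi * fc * m)
    for (tt in 0:(n - 1)) S[j, tt + 1] <- sum(base * exp(-(tt - m)^2 * fc^2 / 2))
  }
  S
}

# Direct evaluation of the averaged-periodogram PSD (no FFT).
bartlett_brute <- function(x, N, fs) {
  w <- blackman_harris(N)
  K <- floor(length(x) / N)
  nf <- N %/% 2 + 1
  acc <- numeric(nf)
  for (k in seq_len(K)) {
    seg <- x[((k - 1) * N + 1):(k * N)]
    for (j in seq_len(nf)) {
      acc[j] <- acc[j] + Mod(sum(seg * w * exp(-2i * pi * (j - 1) * (0:(N - 1)) / N)))^2 / N
    }
  }
  acc / K
}

# Naive per-window PLV recomputation.
plv_naive <- function(theta, L, step = 1L) {
  pos <- seq(L, length(theta), by = step)
  vapply(pos, function(p) Mod(sum(exp(1i * theta[(p - L + 1):p]))) / L, numeric(1))
}

# Independent KCCA oracle. Writing g_x in the eigenbasis of the centered Gram
# (Kx = U D U', directions restricted to the span) turns the regularized
# canonical-correlation problem into an ordinary SVD:
#   rho = sigma_max( (I + nk D_x^-1)^-1/2  U_x' U_y  (I + nk D_y^-1)^-1/2 )
# -- a route entirely different from the implementation's resolvent product.
kcca_oracle <- function(x, y, kappa, sigma_x, sigma_y) {
  n <- nrow(x)
  H <- diag(n) - matrix(1 / n, n, n)
  Kx <- H %*% exp(-as.matrix(dist(x))^2 / (2 * sigma_x^2)) %*% H
  Ky <- H %*% exp(-as.matrix(dist(y))^2 / (2 * sigma_y^2)) %*% H
  basis <- function(K) {
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    keep <- e$values > 1e-8 * max(e$values)
    list(U = e$vectors[, keep, drop = FALSE], d = e$values[keep])
  }
  bx <- basis(Kx); by <- basis(Ky)
  wx <- 1 / sqrt(1 + n * kappa / bx$d)
  wy <- 1 / sqrt(1 + n * kappa / by$d)
  M <- diag(wx, length(wx)) %*% t(bx$U) %*% by$U %*% diag(wy, length(wy))
  max(svd(M)$d)
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
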