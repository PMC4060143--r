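# Internal numeric helpers shared across modules.

# Smallest length >= n that is a multiple of `multiple_of` and 7-smooth
# (prime factors in {2,3,5,7}), so R's mixed-radix FFT stays fast.
next_fast_len <- function(n, multiple_of = 1L) {
  n <- max(as.integer(ceiling(n)), 1L)
  m <- max(as.integer(multiple_of), 1L)
  cand <- as.integer(ceiling(n / m)) * m
  repeat {
    k <- cand
    for (p in c(2L, 3L, 5L, 7L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(cand)
    cand <- cand + m
  }
}

# Linear convolution via zero-padded FFT; returns the full length(x)+length(h)-1
# sequence (complex -- caller takes Re() for real inputs).
conv_fft <- function(x, h) {
  n <- length(x) + length(h) - 1L
  nf <- next_fast_len(n)
  X <- stats::fft(c(x, rep(0, nf - length(x))))
  H <- stats::fft(c(h, rep(0, nf - length(h))))
  y <- stats::fft(X * H, inverse = TRUE) / nf
  y[seq_len(n)]
}

#' Derive a per-stage seed from the pipeline master seed
#'
#' The master seed fans out to stage seeds through a fixed affine map so that
#' toggling one stage on or off never shifts the random stream of another.
#' Extra integer context (e.g. a subject index) can be folded in via `extra`.
#'
#' @param master_seed integer master seed.
#' @param stage stage name, one of the pipeline stage labels.
#' @param extra optional non-negative integer folded into the derivation.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, stage, extra = 0L) {
  stages <- c("simulate", "preprocess", "spectral", "respiration",
              "synchrony", "surrogate", "classify", "ica")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  m <- 2147483629
  s <- (as.numeric(master_seed) %% m) * 48271 + i * 100003 + as.numeric(extra) * 7919
  as.integer(s %% m + 1)
}

# Evenly spaced deterministic subsample of 1..n (no RNG involvement).
even_subsample <- function(n, max_n) {
  if (n <= max_n) return(seq_len(n))
  unique(round(seq(1, n, length.out = max_n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(pmax(x, 0), 1)
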