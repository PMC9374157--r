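## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_config <- function(...) stop(sprintf(...), call. = FALSE)

## Deterministic per-unit seed derivation; keeps results < 2^31 so they are
## valid R integer seeds.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(index)) %% 2147483647L)
}

## next power of two >= n (for FFT padding)
next_pow2 <- function(n) 2L^ceiling(log2(n))

## FFT-based linear convolution of a filter kernel with every row of x,
## returning the delay-compensated "same"-length result. kernel must be
## symmetric (linear phase) and of odd length for exact zero-phase output.
fft_filter_rows <- function(x, kernel) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n_t <- ncol(x)
  L <- length(kernel)
  nfft <- next_pow2(n_t + L - 1L)
  H <- stats::fft(c(kernel, rep(0, nfft - L)))
  X <- stats::mvfft(t(cbind(x, matrix(0, nrow(x), nfft - n_t))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / nfft
  delay <- (L - 1L) %/% 2L
  t(y[delay + seq_len(n_t), , drop = FALSE])
}

## One-sided spectrum multiplier implementing the FFT Hilbert method.
hilbert_mask <- function(n) {
  h <- rep(0, n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  h
}

## Analytic signal (FFT Hilbert method) of every row of x.
analytic_rows <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  X <- stats::mvfft(t(x)) * hilbert_mask(ncol(x))
  t(stats::mvfft(X, inverse = TRUE) / ncol(x))
}

## Band-pass filter + analytic signal in one FFT round trip, operating on
## a [time x series] matrix; returns the complex analytic signal with the
## filter group delay compensated. Zero-padding keeps the convolution
## linear; the Hilbert step is applied on the padded grid, where the
## filtered signal has decayed to ~0 at the boundaries.
filter_analytic_cols <- function(x, kernel) {
  n_t <- nrow(x)
  L <- length(kernel)
  nfft <- next_pow2(n_t + L - 1L)
  H <- stats::fft(c(kernel, rep(0, nfft - L))) * hilbert_mask(nfft)
  X <- stats::mvfft(rbind(x, matrix(0, nfft - n_t, ncol(x))))
  y <- stats::mvfft(X * H, inverse = TRUE) / nfft
  delay <- (L - 1L) %/% 2L
  y[delay + seq_len(n_t), , drop = FALSE]
}

## sample standard deviation (n - 1 denominator) -- the convention used
## throughout the package.
sd1 <- function(x) stats::sd(x)

## Root mean square.
rms <- function(x) sqrt(mean(x^2))

## Inclusive-endpoint index set of time window [t0, t1] on axis `times`.
window_idx <- function(times, window) {
  idx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (!length(idx)) stop("time window [", window[1], ", ", window[2],
                         "] contains no samples", call. = FALSE)
  idx
}
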