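## Filtering, time-frequency power, phase extraction, ROI time-course
## extraction and laterality contrasts.

## Hamming-window FIR band-pass kernel. Transition bandwidths follow the
## half-amplitude convention: the -6 dB points sit at f_lo - trans_lo/2 and
## f_hi + trans_hi/2, and the filter length is the Hamming rule-of-thumb
## 3.3 / (narrowest transition width). Hamming design gives ~0.0194
## passband ripple and ~53 dB stopband attenuation.
fir_bandpass_kernel <- function(f_lo, f_hi, srate,
                                transition_lo = 2, transition_hi = 2) {
  nyq <- srate / 2
  if (f_hi + transition_hi >= nyq)
    stop_config("upper band edge plus transition must stay below Nyquist")
  L <- ceiling(3.3 * srate / min(transition_lo, transition_hi))
  if (L %% 2L == 0L) L <- L + 1L
  cutoffs <- c(f_lo - transition_lo / 2, f_hi + transition_hi / 2) / nyq
  signal::fir1(L - 1L, cutoffs, type = "pass",
               window = signal::hamming(L))
}

#' Zero-phase FIR band-pass filter
#'
#' Hamming-window linear-phase FIR design (0.0194 passband ripple, 53 dB
#' stopband attenuation) with configurable transition bandwidths, applied
#' by FFT convolution with exact group-delay compensation, so the output
#' is zero-phase. Time is the last dimension.
#'
#' @param x numeric vector, matrix `[signals x time]`, or 3-D array
#'   `[trials x sources x time]`.
#' @param f_lo,f_hi passband edges in Hz.
#' @param srate sampling rate.
#' @param transition_lo,transition_hi transition bandwidths in Hz
#'   (default 2, the theta-band connectivity design).
#' @return filtered data, same shape as `x`.
#' @examples
#' t <- seq(0, 4, by = 1 / 128)
#' y <- fir_bandpass(sin(2 * pi * 5 * t), 3, 7, 128)
#' @export
fir_bandpass <- function(x, f_lo, f_hi, srate,
                         transition_lo = 2, transition_hi = 2) {
  h <- fir_bandpass_kernel(f_lo, f_hi, srate, transition_lo, transition_hi)
  dims <- dim(x)
  n_t <- if (is.null(dims)) length(x) else dims[length(dims)]
  if (n_t < length(h))
    stop_config(paste0("epoch (%d samples) is shorter than the filter ",
                       "(%d taps); provide a longer (padded) epoch"),
                n_t, length(h))
  if (is.null(dims)) return(drop(fft_filter_rows(x, h)))
  if (length(dims) == 2L) return(fft_filter_rows(x, h))
  flat <- matrix(aperm(x, c(3, 1, 2)), nrow = n_t)   # time x (trials*sources)
  out <- t(fft_filter_rows(t(flat), h))
  aperm(array(out, dim = c(n_t, dims[1], dims[2])), c(2, 3, 1))
}

#' Analytic signal and instantaneous phase
#'
#' FFT-based Hilbert transform along the last dimension. Phases are in
#' `(-pi, pi]`.
#'
#' @param x vector, matrix `[signals x time]` or array
#'   `[trials x sources x time]` of band-limited real signals.
#' @return for `analytic_signal` a complex object of the same shape; for
#'   `instantaneous_phase` the phase in radians.
#' @export
analytic_signal <- function(x) {
  dims <- dim(x)
  if (is.null(dims)) return(drop(analytic_rows(x)))
  if (length(dims) == 2L) return(analytic_rows(x))
  n_t <- dims[3L]
  flat <- matrix(aperm(x, c(3, 1, 2)), nrow = n_t)
  out <- t(analytic_rows(t(flat)))
  aperm(array(out, dim = c(n_t, dims[1], dims[2])), c(2, 3, 1))
}

#' @rdname analytic_signal
#' @export
instantaneous_phase <- function(x) Arg(analytic_signal(x))

## Complex Morlet wavelet at frequency f with n_cycles, sampled at srate.
## Gaussian envelope SD sigma_t = n_cycles / (2 pi f); support +-4 sigma.
## The kernel is scaled so a unit-amplitude sinusoid at f yields an
## analytic envelope of ~1 (peak frequency-domain gain 2).
morlet_kernel <- function(f, n_cycles, srate) {
  sigma_t <- n_cycles / (2 * pi * f)
  t <- seq(-4 * sigma_t, 4 * sigma_t, by = 1 / srate)
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w * (2 / sum(Mod(w)))
}

#' Morlet band power time courses
#'
#' Convolves each trial with complex Morlet wavelets at integer frequencies
#' `f_lo..f_hi` (cycle count fixed per band: 3 for theta, 4 for alpha, 5
#' for beta), takes squared magnitudes, averages across the band's
#' frequencies, and then decimates to `power_srate` (a moving-average guard
#' of the decimation width is applied before subsampling).
#'
#' @param x matrix `[trials x time]` of (ROI) time courses.
#' @param band a [band_spec()].
#' @param srate sampling rate of `x`.
#' @param times time axis of `x` in seconds (length `ncol(x)`).
#' @param power_srate output rate; must divide `srate`.
#' @return list of class `band_power` with `values` `[trials x time]`
#'   (non-negative), `times`, `srate = power_srate`, `band`.
#' @export
morlet_band_power <- function(x, band, srate, times,
                              power_srate = srate) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n_t <- ncol(x)
  if (srate %% power_srate != 0)
    stop_config("power_srate must divide srate")
  freqs <- seq(ceiling(band$f_lo), floor(band$f_hi), by = 1)
  kern0 <- morlet_kernel(freqs[1], band$n_cycles, srate)
  if (n_t < length(kern0))
    stop_config("epoch too short for the %g Hz wavelet (%d taps)",
                freqs[1], length(kern0))
  nfft <- next_pow2(n_t + length(kern0) - 1L)
  X <- stats::mvfft(t(cbind(x, matrix(0, nrow(x), nfft - n_t))))
  pow <- matrix(0, nrow(x), n_t)
  for (f in freqs) {
    k <- morlet_kernel(f, band$n_cycles, srate)
    H <- stats::fft(c(k, rep(0, nfft - length(k))))
    y <- stats::mvfft(X * H, inverse = TRUE) / nfft
    delay <- (length(k) - 1L) %/% 2L
    pow <- pow + Mod(t(y[delay + seq_len(n_t), , drop = FALSE]))^2
  }
  pow <- pow / length(freqs)
  dec <- as.integer(srate / power_srate)
  if (dec > 1L) {
    guard <- rep(1 / dec, dec)
    pow <- t(apply(pow, 1, function(p)
      stats::filter(p, guard, sides = 2)))
    keep <- seq(1L, n_t, by = dec)
    ## moving-average guard is NA at the very edges; fall back to raw there
    pow[is.na(pow)] <- 0
    pow <- pow[, keep, drop = FALSE]
    times <- times[keep]
  }
  structure(list(values = pow, times = times, srate = power_srate,
                 band = band), class = "band_power")
}

#' ROI time course by sign-adjusted first singular vector
#'
#' Per trial: the ROI's source signals are sign-adjusted for dipole
#' orientation, the first right-singular vector of the sources-by-time
#' matrix is taken as the ROI time course, rescaled so its RMS equals the
#' mean RMS of the member sources, and sign-fixed so it correlates
#' non-negatively with the sign-adjusted ROI mean.
#'
#' @param x array `[trials x sources x time]` restricted to the ROI's
#'   sources (in the ROI's index order), or matrix `[sources x time]` for a
#'   single trial.
#' @param roi a [roi_definition()] (only `orientation_signs` is used here).
#' @return matrix `[trials x time]` (or vector for a single trial).
#' @export
roi_timecourse_pca_flip <- function(x, roi) {
  one <- function(m) {
    m <- m * roi$orientation_signs
    if (all(m == 0)) {
      warning("rank-0 ROI input; returning zero time course", call. = FALSE)
      return(numeric(ncol(m)))
    }
    cc <- m %*% t(m)
    eg <- eigen(cc, symmetric = TRUE)
    u1 <- eg$vectors[, 1L]
    s1 <- sqrt(max(eg$values[1L], 0))
    v1 <- drop(t(m) %*% u1) / s1          # unit-norm right-singular vector
    tc <- v1 * mean(apply(m, 1, rms)) / rms(v1)
    if (sum(tc * colMeans(m)) < 0) tc <- -tc
    tc
  }
  if (length(dim(x)) == 2L) {
    if (nrow(x) < 2L) stop_config("ROI must contain >= 2 sources")
    return(one(x))
  }
  if (dim(x)[2L] < 2L) stop_config("ROI must contain >= 2 sources")
  t(apply(x, 1, one))
}

#' Split hemisphere power into contralateral and ipsilateral time courses
#'
#' For each trial the contralateral time course is the ROI opposite the
#' trial's reference side (cued side for attention/alpha, response side for
#' motor/beta) and the ipsilateral one is the same-side ROI. No averaging
#' across trials happens here. Swapping every side label exchanges the two
#' outputs exactly.
#'
#' @param power_left,power_right matrices `[trials x time]` from the left
#'   and right ROI, on the same time axis.
#' @param trials a [trial_table()].
#' @param reference `"cued_side"` or `"response_side"`.
#' @return list with matrices `contralateral`, `ipsilateral`, and `kept`
#'   (row indices used; trials with missing side labels are skipped with a
#'   message).
#' @export
lateralize <- function(power_left, power_right, trials,
                       reference = c("cued_side", "response_side")) {
  reference <- match.arg(reference)
  side <- trials[[reference]]
  if (nrow(power_left) != length(side) ||
      nrow(power_right) != length(side))
    stop_config("power matrices and trial table disagree on trial count")
  kept <- which(side %in% c("left", "right"))
  if (length(kept) < length(side))
    message(length(side) - length(kept), " trial(s) without ", reference,
            " label skipped")
  contra <- ipsi <- matrix(NA_real_, length(kept), ncol(power_left))
  left_cue <- side[kept] == "left"
  contra[left_cue, ] <- power_right[kept[left_cue], , drop = FALSE]
  contra[!left_cue, ] <- power_left[kept[!left_cue], , drop = FALSE]
  ipsi[left_cue, ] <- power_left[kept[left_cue], , drop = FALSE]
  ipsi[!left_cue, ] <- power_right[kept[!left_cue], , drop = FALSE]
  list(contralateral = contra, ipsilateral = ipsi, kept = kept)
}

#' Per-trial mean power in a time window
#'
#' Arithmetic mean over samples with `t0 <= t <= t1` (closed interval,
#' inclusive endpoints).
#'
#' @param power matrix `[trials x time]` or a `band_power` object.
#' @param window `c(t0, t1)` in seconds.
#' @param times time axis (taken from the object if `power` is a
#'   `band_power`).
#' @return numeric vector, one scalar per trial.
#' @export
mean_window_power <- function(power, window, times = NULL) {
  if (inherits(power, "band_power")) {
    times <- power$times
    power <- power$values
  }
  if (is.null(times)) stop_config("`times` required")
  idx <- window_idx(times, window)
  rowMeans(power[, idx, drop = FALSE])
}
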