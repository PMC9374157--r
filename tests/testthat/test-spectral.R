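srate <- 512
tt <- seq(-1, 2.5, by = 1 / srate)
center <- abs(tt - 0.75) < 0.5

test_that("the theta FIR band-pass has the designed pass and stop bands", {
  y5 <- fir_bandpass(sin(2 * pi * 5 * tt), 3, 7, srate)
  expect_lt(abs(max(abs(y5[center])) - 1), 0.05)
  y20 <- fir_bandpass(sin(2 * pi * 20 * tt), 3, 7, srate)
  expect_lt(max(abs(y20[center])), 0.05)
  expect_identical(fir_bandpass(numeric(length(tt)), 3, 7, srate),
                   numeric(length(tt)))
  expect_error(fir_bandpass(rnorm(100), 3, 7, srate), "padded")
  expect_error(fir_bandpass(rnorm(1000), 50, 70, 128), "Nyquist")
})

test_that("filtering is zero-phase and the Hilbert phase advances at 2 pi f", {
  f0 <- 5
  x <- cos(2 * pi * f0 * tt)
  y <- fir_bandpass(x, 3, 7, srate)
  ## zero-phase: filtered tone stays aligned with the input
  expect_gt(cor(x[center], y[center]), 0.999)
  ph <- instantaneous_phase(y)
  dphi <- atan2(sin(diff(ph)), cos(diff(ph)))   # wrapped increments
  slope <- mean(dphi[center[-1]]) * srate
  expect_equal(slope, 2 * pi * f0, tolerance = 0.01)
})

test_that("band power scales with amplitude squared", {
  x <- rbind(sin(2 * pi * 5 * tt), 2 * sin(2 * pi * 5 * tt))
  bp <- morlet_band_power(x, default_bands()$theta, srate, tt,
                          power_srate = 128)
  i0 <- which.min(abs(bp$times - 0.75))
  expect_equal(bp$values[2, i0] / bp$values[1, i0], 4.0, tolerance = 0.02)
  expect_true(all(bp$values >= 0))
  expect_equal(bp$srate, 128)
  ## zero in, zero out
  z <- morlet_band_power(matrix(0, 1, length(tt)),
                         default_bands()$theta, srate, tt)
  expect_true(all(z$values == 0))
  expect_error(morlet_band_power(x, default_bands()$theta, srate, tt,
                                 power_srate = 100), "divide")
})

test_that("band power is translation covariant away from edges", {
  env <- exp(-(tt - 0.5)^2 / (2 * 0.15^2))
  x1 <- env * sin(2 * pi * 5 * tt)
  shift <- round(0.4 * srate)
  env2 <- exp(-(tt - 0.9)^2 / (2 * 0.15^2))
  x2 <- env2 * sin(2 * pi * 5 * (tt - 0.4))
  b1 <- morlet_band_power(x1, default_bands()$theta, srate, tt)
  b2 <- morlet_band_power(x2, default_bands()$theta, srate, tt)
  inner <- which(tt > -0.2 & tt < 1.6)
  expect_equal(b2$values[1, inner + shift],
               b1$values[1, inner], tolerance = 0.02)
})

test_that("decimation introduces no distortion on band-limited power", {
  x <- rbind(sin(2 * pi * 5 * tt) * (1 + 0.3 * sin(2 * pi * 0.7 * tt)))
  full <- morlet_band_power(x, default_bands()$theta, srate, tt)
  dec <- morlet_band_power(x, default_bands()$theta, srate, tt,
                           power_srate = 128)
  keep <- seq(1, length(tt), by = 4)
  inner <- which(tt[keep] > -0.5 & tt[keep] < 2.0)
  expect_equal(dec$values[1, inner], full$values[1, keep][inner],
               tolerance = 0.01)
})

test_that("pca_flip recovers a common source with sign adjustment", {
  T_ <- 300
  s <- sin(2 * pi * 3 * seq_len(T_) / 100)
  roi2 <- roi_definition("r", 1:2, c(1, -1))
  ## sources {+s, -s} with orientation signs {+1, -1}: output tracks +s
  out <- roi_timecourse_pca_flip(rbind(s, -s), roi2)
  expect_gt(cor(out, s), 0.999)
  ## identical sources, all +1: rank-1 identity
  roi3 <- roi_definition("r", 1:3, c(1, 1, 1))
  out3 <- roi_timecourse_pca_flip(rbind(s, s, s), roi3)
  expect_gt(cor(out3, s), 0.999)
  ## RMS matches the mean source RMS
  expect_equal(sqrt(mean(out3^2)), sqrt(mean(s^2)), tolerance = 1e-10)
  ## common signal + unit noise, 20 sources: correlation > 0.9
  set.seed(2)
  hits <- replicate(10, {
    x <- matrix(rep(s, 20), 20, byrow = TRUE) + matrix(rnorm(20 * T_), 20)
    roi20 <- roi_definition("r", 1:20, rep(1, 20))
    cor(roi_timecourse_pca_flip(x, roi20), s)
  })
  expect_true(all(hits > 0.9))
  expect_warning(roi_timecourse_pca_flip(matrix(0, 3, 10), roi3),
                 "rank-0")
})

test_that("lateralization maps sides correctly and is an involution", {
  s <- cached_subject()
  n_tr <- nrow(s$trials)
  L <- matrix(rnorm(n_tr * 10), n_tr)
  R <- matrix(rnorm(n_tr * 10), n_tr)
  lat <- lateralize(L, R, s$trials, "cued_side")
  left_trials <- which(s$trials$cued_side == "left")
  expect_identical(lat$contralateral[left_trials[1], ],
                   R[left_trials[1], ])
  expect_identical(lat$ipsilateral[left_trials[1], ], L[left_trials[1], ])
  ## identical hemispheres: contra - ipsi is exactly zero
  lat0 <- lateralize(L, L, s$trials, "cued_side")
  expect_true(all(lat0$contralateral == lat0$ipsilateral))
  ## swapping all side labels exchanges the outputs exactly
  flipped <- s$trials
  flipped$cued_side <- ifelse(flipped$cued_side == "left", "right", "left")
  lat2 <- lateralize(L, R, flipped, "cued_side")
  expect_identical(lat2$contralateral, lat$ipsilateral)
  expect_identical(lat2$ipsilateral, lat$contralateral)
})

test_that("window means use closed intervals on the power grid", {
  times <- -1 + (0:447) / 128
  p <- matrix(rep(3.5, length(times)), 1)
  expect_equal(mean_window_power(p, c(0.355, 0.985), times), 3.5)
  ## the canonical connectivity window holds 81 samples at 128 Hz
  expect_length(window_idx(times, c(0.355, 0.985)), 81)
  ## linear ramp averages to its midpoint
  ramp <- matrix(seq_along(times), 1)
  idx <- window_idx(times, c(0, 1))
  expect_equal(mean_window_power(ramp, c(0, 1), times), mean(idx))
  expect_error(mean_window_power(p, c(5, 6), times), "window")
})
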