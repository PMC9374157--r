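test_that("PLV analytic limits hold", {
  set.seed(1)
  p1 <- runif(300, -pi, pi)
  expect_equal(plv_pair(p1, p1), 1)
  expect_equal(plv_pair(p1, p1 + pi / 3), 1)            # constant lag
  ## common phase-constant invariance and symmetry
  p2 <- runif(300, -pi, pi)
  expect_equal(plv_pair(p1 + 0.7, p2 + 0.7), plv_pair(p1, p2))
  expect_equal(plv_pair(p2, p1), plv_pair(p1, p2))
  expect_error(plv_pair(c(1, NA, 2), c(1, 2, 3)), "finite")
  expect_error(plv_pair(1, 2), ">= 2")
})

test_that("multivariate PLV equals the brute-force pairwise RMS", {
  set.seed(3)
  for (i in 1:8) {
    M <- sample(1:6, 1); N <- sample(1:6, 1); T_ <- 80
    A <- matrix(runif(M * T_, -pi, pi), M)
    B <- matrix(runif(N * T_, -pi, pi), N)
    brute <- sqrt(mean(outer(seq_len(M), seq_len(N),
                             Vectorize(function(m, n)
                               plv_pair(A[m, ], B[n, ])))^2))
    expect_equal(plv_multivariate(A, B), brute, tolerance = 1e-12)
  }
  ## reductions
  a <- runif(80, -pi, pi); b <- runif(80, -pi, pi)
  expect_equal(plv_multivariate(a, b), plv_pair(a, b))
  A <- rbind(a, a, a); B <- rbind(b, b)
  expect_equal(plv_multivariate(A, B), plv_pair(a, b))
  expect_error(plv_multivariate(matrix(0, 2, 10), matrix(0, 2, 12)),
               "mismatch")
})

test_that("wPLI is lag-sensitive and amplitude invariant", {
  t <- seq(0, 2, by = 1 / 256)
  z <- exp(1i * 2 * pi * 5 * t)
  expect_equal(as.numeric(wpli_pair(z, z * exp(-1i * pi / 2))), 1)
  ## zero lag: degenerate, flagged
  w0 <- wpli_pair(z, z)
  expect_equal(as.numeric(w0), 0)
  expect_true(attr(w0, "degenerate"))
  ## alternating +-pi/4 lags with equal amplitude cancel (signed
  ## imaginary parts sum to zero over an even number of samples)
  te <- t[1:512]
  ze <- exp(1i * 2 * pi * 5 * te)
  lag <- rep(c(pi / 4, -pi / 4), length.out = 512)
  walt <- wpli_pair(ze, ze * exp(-1i * lag))
  expect_equal(as.numeric(walt), 0, tolerance = 1e-10)
  ## invariance to positive rescaling of either signal; symmetry
  set.seed(4)
  z2 <- z * exp(-1i * (pi / 5 + 0.4 * rnorm(length(t))))
  expect_equal(as.numeric(wpli_pair(3.7 * z, z2)),
               as.numeric(wpli_pair(z, z2)))
  expect_equal(as.numeric(wpli_pair(z2, z)),
               as.numeric(wpli_pair(z, z2)))
  ## common phase rotation leaves wPLI unchanged
  expect_equal(as.numeric(wpli_pair(z * exp(1i * 0.9), z2 * exp(1i * 0.9))),
               as.numeric(wpli_pair(z, z2)))
})

test_that("multivariate wPLI reduces to the pairwise value", {
  t <- seq(0, 1, by = 1 / 256)
  set.seed(5)
  z1 <- exp(1i * (2 * pi * 5 * t + 0.3 * rnorm(length(t))))
  z2 <- exp(1i * (2 * pi * 5 * t - pi / 3 + 0.3 * rnorm(length(t))))
  expect_equal(thetalink:::wpli_multivariate(z1, z2),
               as.numeric(wpli_pair(z1, z2)), tolerance = 1e-12)
})

test_that("the connectivity table assigns laterality from the trial labels", {
  ## Hand_R carries a copy of the mPFC theta phase; Hand_L independent
  ## noise. Trials responding left must show high contralateral
  ## (mPFC-Hand_R) and low ipsilateral PLV; right-response trials reverse.
  srate <- 128
  times <- seq(-1, 2.5, by = 1 / srate)
  n_t <- length(times)
  rois <- default_rois()
  n_src <- length(attr(rois, "source_labels"))
  set.seed(11)
  n_tr <- 8
  dat <- array(rnorm(n_tr * n_src * n_t, sd = 0.05), c(n_tr, n_src, n_t))
  for (tr in seq_len(n_tr)) {
    ph <- 2 * pi * 5 * times + runif(1, -pi, pi)
    for (k in seq_along(rois$mPFC$source_indices))
      dat[tr, rois$mPFC$source_indices[k], ] <-
        cos(ph) * rois$mPFC$orientation_signs[k] + rnorm(n_t, sd = 0.05)
    for (k in seq_along(rois$Hand_R$source_indices))
      dat[tr, rois$Hand_R$source_indices[k], ] <-
        cos(ph - pi / 4) + rnorm(n_t, sd = 0.05)
    for (k in seq_along(rois$Hand_L$source_indices))
      dat[tr, rois$Hand_L$source_indices[k], ] <-
        cos(2 * pi * 5 * times + runif(1, -pi, pi) +
              cumsum(rnorm(n_t, sd = 0.3))) + rnorm(n_t, sd = 0.05)
  }
  trials <- trial_table(data.frame(
    trial_id = 1:n_tr, task = "implementation",
    cued_side = "left",
    response_side = rep(c("left", "right"), each = n_tr / 2),
    correct = TRUE, catch = c(TRUE, rep(FALSE, n_tr - 1)),
    rt_ms = 700, block = 1))
  es <- epoch_set("t01", dat, srate, -1, attr(rois, "source_labels"))
  tab <- build_connectivity_table(list(list(epochs = es, trials = trials)),
                                  rois)
  ## catch trial excluded
  expect_false(1 %in% tab$trial_id)
  expect_setequal(unique(tab$roi_pair),
                  c("mPFC-Hand", "mPFC-LatOcc", "mPFC-Control"))
  hand <- tab[tab$roi_pair == "mPFC-Hand", ]
  left <- hand[hand$trial_id %in% 2:4, ]    # left responses
  right <- hand[hand$trial_id %in% 5:8, ]
  expect_true(all(left$plv[left$laterality == "contralateral"] >
                    left$plv[left$laterality == "ipsilateral"]))
  expect_true(all(right$plv[right$laterality == "ipsilateral"] >
                    right$plv[right$laterality == "contralateral"]))
  expect_true(all(tab$plv >= 0 & tab$plv <= 1))
  expect_true(all(tab$wpli >= 0 & tab$wpli <= 1))
  ## TSV export keeps the exact header
  f <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity_table(tab, f)
  expect_identical(strsplit(readLines(f, n = 1), "\t")[[1]],
                   c("subject_id", "trial_id", "task", "roi_pair",
                     "laterality", "plv", "wpli"))
})

test_that("PLV detects zero-lag coupling that wPLI discards", {
  ## generator in zero-lag mode: PLV keeps seeing the coupling, wPLI
  ## collapses toward zero (spurious-conduction robustness)
  cfg0 <- tiny_sim(n_subjects = 2, n_trials = 24, seed = 21,
                   coupling = list(kappa_impl = 30, kappa_mem = 30,
                                   lag_rad = 0))
  cfg1 <- tiny_sim(n_subjects = 2, n_trials = 24, seed = 21,
                   coupling = list(kappa_impl = 30, kappa_mem = 30,
                                   lag_rad = pi / 4))
  get_tab <- function(cfg) {
    s <- simulate_subject(cfg, 77)
    build_connectivity_table(list(s), cfg$rois)
  }
  t0 <- get_tab(cfg0); t1 <- get_tab(cfg1)
  hand0 <- t0[t0$roi_pair == "mPFC-Hand", ]
  hand1 <- t1[t1$roi_pair == "mPFC-Hand", ]
  expect_gt(mean(hand0$plv), 0.7)            # PLV sees zero-lag coupling
  expect_gt(mean(hand1$wpli), 0.5)           # wPLI sees lagged coupling
  expect_lt(mean(hand0$wpli), mean(hand1$wpli) - 0.2)
})
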