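## Synthetic group datasets with the statistical structure the analysis
## pipeline assumes: 1/f background, band-limited oscillations with
## condition-dependent amplitudes, von-Mises phase coupling between a
## medial-prefrontal seed and posterior regions, and reaction times with a
## built-in task -> theta -> RT mediation structure.

#' Default ROI layout for simulated subjects
#'
#' A compact source space: a bilateral medial-prefrontal seed (mPFC), left
#' and right hand-motor ROIs, left and right lateral-occipital ROIs, and a
#' bilateral parahippocampal control ROI. Orientation signs alternate so
#' the sign-adjustment step of ROI extraction is exercised.
#'
#' @param n_mpfc sources in the mPFC seed.
#' @param n_roi sources in each remaining ROI.
#' @return named list of [roi_definition()] plus attribute `source_labels`.
#' @export
default_rois <- function(n_mpfc = 4L, n_roi = 3L) {
  sizes <- c(mPFC = n_mpfc, Hand_L = n_roi, Hand_R = n_roi,
             LatOcc_L = n_roi, LatOcc_R = n_roi, Parahippocampal = n_roi)
  hemis <- c("bilateral", "left", "right", "left", "right", "bilateral")
  rois <- vector("list", length(sizes))
  labels <- character()
  at <- 0L
  for (i in seq_along(sizes)) {
    idx <- at + seq_len(sizes[i])
    signs <- rep_len(c(1, -1), sizes[i])
    rois[[i]] <- roi_definition(names(sizes)[i], idx, signs, hemis[i])
    labels <- c(labels, paste0(names(sizes)[i], "_", seq_len(sizes[i])))
    at <- at + sizes[i]
  }
  names(rois) <- names(sizes)
  attr(rois, "source_labels") <- labels
  rois
}

#' Simulation configuration
#'
#' Defaults mirror the study design this package targets: 30 subjects, 240
#' trials per task balanced over cued side x response side, 10% catch
#' trials, epochs from -1.0 to 2.5 s around the retro-cue at 512
#' samples/s. Effect sizes are fractional amplitude modulations; coupling
#' is parameterized by von Mises concentrations per task and a mean phase
#' lag; reaction times follow a linear mediation structure
#' (task -> trial theta amplitude -> RT) on top of subject offsets.
#'
#' @param n_subjects subjects in the group.
#' @param n_trials_per_task trials per task.
#' @param srate sampling rate (samples/s).
#' @param epoch epoch window in seconds relative to cue onset.
#' @param rois ROI layout, see [default_rois()].
#' @param effects list: `alpha_lat_suppression` (fractional alpha amplitude
#'   reduction contralateral to the cued side), `beta_lat_suppression`
#'   (reduction contralateral to the response side),
#'   `beta_task_scale` (relative extra beta suppression under
#'   implementation), `theta_task_gain` (fractional mPFC theta amplitude
#'   increase for implementation).
#' @param coupling list: `kappa_impl`, `kappa_mem` — concentrations of
#'   the mPFC<->posterior theta phase coupling per task (the
#'   phase-difference variance is `1/kappa`; implemented as correlated
#'   Gaussian jitter streams whose marginal variance is task-invariant,
#'   so equal kappas give an exactly null coupling contrast and larger
#'   `kappa_impl` gives tighter implementation-trial locking) — and
#'   `lag_rad`, the mean phase lag (the nonzero default lets the
#'   lag-sensitive wPLI see the coupling; set 0 to demonstrate PLV/wPLI
#'   divergence).
#' @param mediation list: `beta0_ms` (baseline RT), `beta_task_ms` (RT cost
#'   of memorization), `beta_theta_ms_per_unit` (RT change per unit trial
#'   theta amplitude), `subject_sd_ms`, `resid_sd_ms`.
#' @param noise list: `one_over_f_exponent`, `snr` (global oscillation
#'   amplitude scale relative to unit-SD background noise).
#' @param amplitudes baseline oscillation amplitudes (units of the
#'   background-noise SD, before `snr` scaling): `mpfc_theta` (large so
#'   amplitude-dependent phase-estimation noise cannot masquerade as a
#'   connectivity effect), `posterior_theta`, `alpha`, `beta`.
#' @param subject_variability SDs of the subject random effects, drawn
#'   once per subject: `theta_gain_sd` (theta task gain), `kappa_log_sd`
#'   (log-scale multiplier on both coupling concentrations),
#'   `task_slope_sd_ms` (RT task-effect slope), `suppression_sd`
#'   (alpha/beta suppression fractions).
#' @param accuracy per-task correct-response probabilities for regular and
#'   catch trials.
#' @param catch_rt baseline and task effect for catch-trial RTs (ms).
#' @param theta_amp_sd log-scale SD of the trial-to-trial mPFC theta
#'   amplitude multiplier (drives the mediator's trial variability).
#' @param catch_fraction fraction of trials flagged as catch.
#' @param seed integer master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 30L,
                       n_trials_per_task = 240L,
                       srate = 512,
                       epoch = c(-1.0, 2.5),
                       rois = default_rois(),
                       effects = list(alpha_lat_suppression = 0.4,
                                      beta_lat_suppression = 0.3,
                                      beta_task_scale = 0.3,
                                      theta_task_gain = 0.3),
                       coupling = list(kappa_impl = 8, kappa_mem = 2,
                                       lag_rad = pi / 4),
                       mediation = list(beta0_ms = 871, beta_task_ms = 471,
                                        beta_theta_ms_per_unit = -30,
                                        subject_sd_ms = 80,
                                        resid_sd_ms = 120),
                       noise = list(one_over_f_exponent = 1, snr = 1),
                       amplitudes = list(mpfc_theta = 4.0,
                                         posterior_theta = 1.2,
                                         alpha = 1.5, beta = 1.2),
                       subject_variability = list(theta_gain_sd = 0.10,
                                                  kappa_log_sd = 0.25,
                                                  task_slope_sd_ms = 30,
                                                  suppression_sd = 0.08,
                                                  accuracy_sd = 0.02),
                       accuracy = list(regular = c(implementation = 0.940,
                                                   memorization = 0.911),
                                       catch = c(implementation = 0.965,
                                                 memorization = 0.964)),
                       catch_rt = list(beta0_ms = 817, beta_task_ms = 126),
                       theta_amp_sd = 0.3,
                       catch_fraction = 0.10,
                       seed = 1L) {
  fr <- unlist(effects[c("alpha_lat_suppression", "beta_lat_suppression",
                         "theta_task_gain")])
  if (any(fr < 0 | fr > 1)) stop_config("effect fractions must lie in [0, 1]")
  if (coupling$kappa_impl < 0 || coupling$kappa_mem < 0)
    stop_config("kappa must be >= 0")
  if (catch_fraction < 0 || catch_fraction >= 1)
    stop_config("catch_fraction must lie in [0, 1)")
  if (epoch[1] > -0.2 || epoch[2] < 1.0)
    stop_config("epoch too short to contain the analysis windows")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials_per_task = as.integer(n_trials_per_task),
                 srate = srate, epoch = epoch, rois = rois,
                 effects = effects, coupling = coupling,
                 mediation = mediation, noise = noise,
                 amplitudes = amplitudes,
                 subject_variability = subject_variability,
                 accuracy = accuracy,
                 catch_rt = catch_rt, theta_amp_sd = theta_amp_sd,
                 catch_fraction = catch_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

## Best & Fisher (1979) rejection sampler for the von Mises distribution,
## mean 0, concentration kappa.
rvonmises <- function(n, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    m <- length(need)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    out[need[ok]] <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
    need <- need[!ok]
  }
  out
}

## 1/f^expo noise by spectral shaping of white noise, one column per
## series. Shaping is circular on the epoch length, which is adequate for a
## stationary background process.
pink_noise <- function(n_times, n_series, exponent = 1) {
  white <- matrix(stats::rnorm(n_times * n_series), n_times, n_series)
  if (exponent == 0) return(white)
  f <- seq_len(n_times) - 1L
  f <- pmin(f, n_times - f)             # two-sided frequency index
  g <- ifelse(f == 0, 0, f^(-exponent / 2))
  X <- stats::mvfft(white) * g
  x <- Re(stats::mvfft(X, inverse = TRUE)) / n_times
  ## renormalize to unit SD
  x / sqrt(mean(apply(x[, seq_len(min(8L, n_series)), drop = FALSE], 2,
                      stats::var)))
}

## Linear interpolation of per-cycle jitter nodes to the sample grid, so
## the phase modulation stays smooth (piecewise-constant jitter would
## splatter the oscillation's spectrum into neighbouring bands).
interp_nodes <- function(nodes, n_times, seg_len) {
  n_seg <- nrow(nodes)
  pos <- (seq_len(n_times) - 1) / seg_len
  i0 <- pmin(floor(pos) + 1L, n_seg - 1L)
  w <- pos - (i0 - 1L)
  nodes[i0, , drop = FALSE] * (1 - w) + nodes[i0 + 1L, , drop = FALSE] * w
}

## Gaussian jitter nodes (one per theta cycle); concentration kappa maps
## to node SD 1/sqrt(kappa), matching the von Mises dispersion for
## moderate kappa.
jitter_nodes <- function(n_seg, n_trials, kappa)
  matrix(stats::rnorm(n_seg * n_trials, 0, 1 / sqrt(kappa)), n_seg,
         n_trials)

## Constrain every column of x to the frequency band [lo, hi] Hz (soft
## cosine edges of width `taper`). Phase jitter frequency-modulates the
## oscillations; this keeps their sidebands out of neighbouring analysis
## bands, as the generative model promises band-limited rhythms.
bandlimit_cols <- function(x, srate, lo, hi, taper = 1) {
  n <- nrow(x)
  f <- (seq_len(n) - 1) * srate / n
  f <- pmin(f, srate - f)
  g <- numeric(n)
  g[f >= lo & f <= hi] <- 1
  up <- f > lo - taper & f < lo
  g[up] <- 0.5 * (1 + cos(pi * (lo - f[up]) / taper))
  dn <- f > hi & f < hi + taper
  g[dn] <- 0.5 * (1 + cos(pi * (f[dn] - hi) / taper))
  Re(stats::mvfft(stats::mvfft(x) * g, inverse = TRUE)) / n
}

## Random-walk oscillation phase, [n_times x n_trials]:
## 2*pi*f0*t + phi0 + cumulative drift.
osc_phase <- function(times, n_trials, f0, walk_sd) {
  n_t <- length(times)
  drift <- apply(matrix(stats::rnorm(n_t * n_trials, 0, walk_sd), n_t,
                        n_trials), 2, cumsum)
  outer(2 * pi * f0 * times, rep(1, n_trials)) +
    matrix(stats::runif(n_trials, -pi, pi), n_t, n_trials, byrow = TRUE) +
    drift
}

## Balanced trial design for one subject.
build_trial_design <- function(config) {
  n <- config$n_trials_per_task
  one_task <- function(task) {
    cells <- expand.grid(cued_side = c("left", "right"),
                         response_side = c("left", "right"),
                         stringsAsFactors = FALSE)
    reps <- rep(n %/% 4L, 4L) + (seq_len(4L) <= n %% 4L)
    df <- cells[rep(seq_len(4L), reps), ]
    df$task <- task
    ## catch flag spread evenly across the cell-balanced sequence
    n_catch <- round(config$catch_fraction * n)
    df$catch <- FALSE
    if (n_catch > 0)
      df$catch[round(seq(1, n, length.out = n_catch))] <- TRUE
    df
  }
  df <- rbind(one_task("implementation"), one_task("memorization"))
  df <- df[sample.int(nrow(df)), ]
  df$trial_id <- seq_len(nrow(df))
  df$block <- ceiling(df$trial_id / (nrow(df) / 6))
  rownames(df) <- NULL
  df
}

#' Simulate one subject
#'
#' Each source signal is 1/f background noise plus band-limited
#' oscillations whose amplitudes are set by the trial's condition labels:
#' lateral-occipital alpha is suppressed contralateral to the cued side,
#' hand-motor beta contralateral to the response side (more strongly under
#' implementation), and mPFC theta is amplified under implementation with a
#' lognormal trial-to-trial amplitude that also drives reaction times.
#' mPFC and posterior (hand/occipital) sources share a theta phase process;
#' the posterior copy lags by `lag_rad` and is jittered by von Mises noise
#' whose concentration depends on the task, so within-trial phase locking
#' is stronger under implementation. The parahippocampal control ROI
#' carries an uncoupled theta rhythm.
#'
#' @param config a [sim_config()].
#' @param subject_seed integer seed for this subject.
#' @param subject_id subject label.
#' @return list with `epochs` ([epoch_set()]), `trials` ([trial_table()])
#'   and `truth` (per-trial theta amplitude, subject RT offset).
#' @export
simulate_subject <- function(config, subject_seed,
                             subject_id = sprintf("sim%04d", subject_seed)) {
  set.seed(subject_seed)
  srate <- config$srate
  times <- seq(config$epoch[1], config$epoch[2], by = 1 / srate)
  n_t <- length(times)
  rois <- config$rois
  labels <- attr(rois, "source_labels")
  n_src <- length(labels)
  design <- build_trial_design(config)
  n_tr <- nrow(design)
  impl <- design$task == "implementation"

  eff <- config$effects; med <- config$mediation
  sv <- config$subject_variability
  amp <- config$amplitudes
  snr <- config$noise$snr
  seg_len <- max(2L, round(srate / 5))     # one 5 Hz theta cycle

  ## --- subject random effects (drawn once per subject) --------------------
  gain_s <- max(0, stats::rnorm(1, eff$theta_task_gain, sv$theta_gain_sd))
  kappa_mult_s <- exp(stats::rnorm(1, 0, sv$kappa_log_sd))
  kappa_impl_s <- config$coupling$kappa_impl * kappa_mult_s
  kappa_mem_s <- config$coupling$kappa_mem * kappa_mult_s
  alpha_sup_s <- min(1, max(0, stats::rnorm(1, eff$alpha_lat_suppression,
                                            sv$suppression_sd)))
  beta_sup_s <- min(1, max(0, stats::rnorm(1, eff$beta_lat_suppression,
                                           sv$suppression_sd)))
  beta_task_s <- stats::rnorm(1, med$beta_task_ms, sv$task_slope_sd_ms)
  subj_offset <- stats::rnorm(1, 0, med$subject_sd_ms)

  ## --- shared theta phase process (drives mPFC and coupled posterior) ----
  ## Task modulates phase COUPLING without touching any signal's marginal
  ## statistics: a common Gaussian jitter stream `u` rides on the mPFC
  ## phase, and each posterior source carries a correlation-rho(task) copy
  ## of it with the same marginal variance. The marginal distribution of
  ## every signal is task-invariant (no power confound), while the
  ## mPFC-posterior phase-difference variance is 2*sigma^2*(1 - rho(task))
  ## = 1/kappa(task) by construction. Equal kappas give identical joint
  ## distributions across tasks, hence an exactly null coupling contrast.
  walk_sd <- 0.35 / sqrt(srate)
  phi_theta <- osc_phase(times, n_tr, 5, walk_sd)
  n_seg <- ceiling(n_t / seg_len) + 1L
  k_floor <- 0.05                         # kappa 0 -> near-uniform jitter
  k_impl_eff <- max(kappa_impl_s, k_floor)
  k_mem_eff <- max(kappa_mem_s, k_floor)
  k_min <- min(k_impl_eff, k_mem_eff)
  sigma_marg <- 1 / sqrt(k_min)           # marginal jitter SD (radians)
  rho_tr <- ifelse(impl, 1 - k_min / (2 * k_impl_eff),
                   1 - k_min / (2 * k_mem_eff))
  u_nodes <- matrix(stats::rnorm(n_seg * n_tr, 0, sigma_marg), n_seg, n_tr)
  u <- interp_nodes(u_nodes, n_t, seg_len)

  ## trial-level mPFC theta amplitude (the mediator's ground truth).
  ## Oscillation amplitudes are large relative to the in-band share of the
  ## unit-SD background so that phase estimates stay clean: amplitude
  ## (power) differences between conditions must not masquerade as
  ## phase-locking differences through estimation noise.
  amp_mult <- exp(stats::rnorm(n_tr, 0, config$theta_amp_sd))
  theta_amp <- snr * amp$mpfc_theta * (1 + gain_s * impl) * amp_mult

  ## --- independent rhythm phase processes ---------------------------------
  phi_alpha_L <- osc_phase(times, n_tr, 11, walk_sd)
  phi_alpha_R <- osc_phase(times, n_tr, 11, walk_sd)
  phi_beta_L <- osc_phase(times, n_tr, 22, walk_sd)
  phi_beta_R <- osc_phase(times, n_tr, 22, walk_sd)
  phi_ctrl <- osc_phase(times, n_tr, 5, walk_sd)

  ## condition-dependent amplitudes, one value per trial
  alpha_amp <- function(hemi) {
    contra <- (hemi == "left") == (design$cued_side == "right")
    snr * amp$alpha * (1 - alpha_sup_s * contra)
  }
  beta_amp <- function(hemi) {
    contra <- (hemi == "left") == (design$response_side == "right")
    sup <- pmin(1, beta_sup_s * (1 + eff$beta_task_scale * impl))
    snr * amp$beta * (1 - sup * contra)
  }

  data <- array(0, dim = c(n_tr, n_src, n_t))
  source_jitter_kappa <- 40   # within-ROI phase coherence
  ## control-ROI stream: same marginal dispersion as the coupled ROIs
  ctrl_jit <- interp_nodes(jitter_nodes(n_seg, n_tr, k_min), n_t, seg_len)

  for (roi in rois) {
    nm <- roi$name
    coupled <- nm %in% c("Hand_L", "Hand_R", "LatOcc_L", "LatOcc_R")
    if (coupled) {
      ## one correlated copy of the mPFC stream per ROI: its sources
      ## share it, so within-ROI joint statistics (which the
      ## data-dependent SVD extraction sees) stay task-invariant, while
      ## the mPFC<->ROI phase-difference variance is 1/kappa(task)
      eps <- matrix(stats::rnorm(n_seg * n_tr, 0, sigma_marg), n_seg,
                    n_tr)
      v_nodes <- sweep(u_nodes, 2, rho_tr, `*`) +
        sweep(eps, 2, sqrt(1 - rho_tr^2), `*`)
      ph_roi <- phi_theta + config$coupling$lag_rad +
        interp_nodes(v_nodes, n_t, seg_len)
    }
    for (k in seq_along(roi$source_indices)) {
      s_idx <- roi$source_indices[k]
      sgn <- roi$orientation_signs[k]
      x <- pink_noise(n_t, n_tr, config$noise$one_over_f_exponent)
      src_jit <- interp_nodes(jitter_nodes(n_seg, n_tr,
                                           source_jitter_kappa),
                              n_t, seg_len)
      if (nm == "mPFC") {
        ph <- phi_theta + u + src_jit
        x <- x + bandlimit_cols(cos(ph) * rep(theta_amp, each = n_t),
                                srate, 2.5, 7.5)
      } else if (coupled) {
        ph <- ph_roi + src_jit
        x <- x + bandlimit_cols(cos(ph) * (snr * amp$posterior_theta),
                                srate, 2.5, 7.5)
        if (nm == "LatOcc_L")
          x <- x + cos(phi_alpha_L) * rep(alpha_amp("left"), each = n_t)
        if (nm == "LatOcc_R")
          x <- x + cos(phi_alpha_R) * rep(alpha_amp("right"), each = n_t)
        if (nm == "Hand_L")
          x <- x + cos(phi_beta_L) * rep(beta_amp("left"), each = n_t)
        if (nm == "Hand_R")
          x <- x + cos(phi_beta_R) * rep(beta_amp("right"), each = n_t)
      } else {   # uncoupled control ROI (task-invariant jitter stream)
        ph <- phi_ctrl + ctrl_jit + src_jit
        x <- x + bandlimit_cols(cos(ph) * (snr * amp$posterior_theta),
                                srate, 2.5, 7.5)
      }
      data[, s_idx, ] <- t(x) * sgn
    }
  }

  ## --- behavior -----------------------------------------------------------
  p_reg <- config$accuracy$regular
  p_cat <- config$accuracy$catch
  acc_shift <- stats::rnorm(1, 0, sv$accuracy_sd %||% 0)
  p_correct <- pmin(0.999, pmax(0.5, acc_shift +
    ifelse(design$catch, p_cat[design$task], p_reg[design$task])))
  correct <- stats::runif(n_tr) < p_correct
  memo <- as.numeric(!impl)
  rt <- rep(NA_real_, n_tr)
  reg_ok <- correct & !design$catch
  rt[reg_ok] <- med$beta0_ms + beta_task_s * memo[reg_ok] +
    med$beta_theta_ms_per_unit * theta_amp[reg_ok] + subj_offset +
    stats::rnorm(sum(reg_ok), 0, med$resid_sd_ms)
  cat_ok <- correct & design$catch
  rt[cat_ok] <- config$catch_rt$beta0_ms +
    config$catch_rt$beta_task_ms * memo[cat_ok] + subj_offset +
    stats::rnorm(sum(cat_ok), 0, med$resid_sd_ms)
  rt <- pmax(rt, 150, na.rm = FALSE)

  trials <- trial_table(data.frame(
    trial_id = design$trial_id, task = design$task,
    cued_side = design$cued_side, response_side = design$response_side,
    correct = correct, catch = design$catch, rt_ms = rt,
    block = design$block))

  list(epochs = epoch_set(subject_id, data, srate, config$epoch[1], labels),
       trials = trials,
       truth = list(theta_amp = theta_amp, subject_offset_ms = subj_offset,
                    theta_task_gain = gain_s,
                    kappa_impl = kappa_impl_s, kappa_mem = kappa_mem_s,
                    beta_task_ms = beta_task_s))
}

#' Simulate a full group
#'
#' Per-subject seeds are derived deterministically from `config$seed`, so
#' the same configuration always produces a bit-identical group.
#'
#' @param config a [sim_config()].
#' @return list of per-subject results as returned by [simulate_subject()].
#' @export
simulate_group <- function(config) {
  if (config$n_subjects < 2) stop_config("n_subjects must be >= 2")
  lapply(seq_len(config$n_subjects), function(i)
    simulate_subject(config, derive_seed(config$seed, i),
                     subject_id = sprintf("sim%04d", i)))
}

#' Calibrate coupling concentration against expected within-trial PLV
#'
#' Monte-Carlo mapping from von Mises concentration to the expected
#' phase-locking value of a window of `T` samples whose phase differences
#' are von Mises distributed (plus optional wrapped-normal observation
#' noise). At `kappa = 0` the expectation approaches the resultant length
#' of `T` uniform phasors, `sqrt(pi) / (2 sqrt(T))`.
#'
#' @param kappas numeric vector of concentrations.
#' @param noise_sd SD of additional Gaussian phase noise (radians).
#' @param T window length in samples (>= 50).
#' @param n_rep Monte-Carlo repetitions per kappa.
#' @param seed RNG seed.
#' @return data.frame with columns `kappa`, `plv`.
#' @export
coupling_calibration <- function(kappas, noise_sd = 0, T = 322L,
                                 n_rep = 1000L, seed = 1L) {
  if (T < 50) stop_config("T must be >= 50")
  set.seed(seed)
  plv <- vapply(kappas, function(k) {
    d <- matrix(rvonmises(T * n_rep, k), T, n_rep)
    if (noise_sd > 0) d <- d + stats::rnorm(T * n_rep, 0, noise_sd)
    mean(Mod(colMeans(exp(1i * d))))
  }, numeric(1))
  data.frame(kappa = kappas, plv = plv)
}

#' Simulate trial tables with a known linear mediation structure
#'
#' A direct generator for the inference stage: a binary within-subject
#' treatment shifts the mediator by `a`; the outcome is
#' `beta0 + c * treat + b * mediator + subject offset + residual`. The true
#' indirect effect is exactly `a * b`.
#'
#' @param n_subjects,n_trials design size (trials split evenly between the
#'   two treatment levels within each subject).
#' @param a treatment effect on the mediator (group mean).
#' @param b mediator effect on the outcome.
#' @param cp direct treatment effect on the outcome (group mean).
#' @param beta0 outcome baseline.
#' @param med_sd residual SD of the mediator.
#' @param subject_sd SD of subject outcome offsets.
#' @param a_sd,cp_sd SDs of the per-subject treatment effects on mediator
#'   and outcome (the random slopes of the fitted models).
#' @param resid_sd residual SD of the outcome.
#' @param seed RNG seed.
#' @return data.frame with columns `subject`, `treat`, `mediator`,
#'   `outcome`.
#' @export
simulate_mediation_trials <- function(n_subjects = 30L, n_trials = 200L,
                                      a = 0.1, b = -3, cp = 500,
                                      beta0 = 900, med_sd = 0.5,
                                      subject_sd = 80, a_sd = 0.05,
                                      cp_sd = 30, resid_sd = 150,
                                      seed = 1L) {
  set.seed(seed)
  treat <- rep(rep(c(0, 1), length.out = n_trials), n_subjects)
  subject <- rep(seq_len(n_subjects), each = n_trials)
  offset <- stats::rnorm(n_subjects, 0, subject_sd)[subject]
  a_i <- stats::rnorm(n_subjects, a, a_sd)[subject]
  cp_i <- stats::rnorm(n_subjects, cp, cp_sd)[subject]
  mediator <- 1 + a_i * treat + stats::rnorm(length(treat), 0, med_sd)
  outcome <- beta0 + cp_i * treat + b * mediator + offset +
    stats::rnorm(length(treat), 0, resid_sd)
  data.frame(subject = factor(subject), treat = treat,
             mediator = mediator, outcome = outcome)
}
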