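## Orchestration: run the full analysis chain on a simulated or
## user-supplied group dataset and emit a structured report mirroring the
## analysis plan (behavior, alpha/beta/theta oscillatory contrasts,
## trial-level mediation, theta-phase connectivity).

## Assert that the wavelet for the slowest analysis frequency fits between
## the epoch edges and the analysis window (no silent edge contamination).
check_wavelet_margins <- function(tmin, tmax, analysis_window, bands) {
  half <- max(vapply(bands, function(b)
    4 * b$n_cycles / (2 * pi * b$f_lo), numeric(1)))
  if (tmin > analysis_window[1] - half ||
      tmax < analysis_window[2] + half)
    stop_config(paste0("epoch [%g, %g] s leaves less than one wavelet ",
                       "half-length (%.3f s) of margin around the analysis ",
                       "window [%g, %g] s"),
                tmin, tmax, half, analysis_window[1], analysis_window[2])
  invisible(half)
}

## Reduce one subject's raw epochs to the group-level ingredients: ROI band
## power condition means in the analysis window, per-trial theta scalars,
## connectivity rows and behavioral summaries. The raw tensor can be
## discarded afterwards.
reduce_subject <- function(epochs, trials, rois, config,
                           theta_window = NULL) {
  validate_epochs_trials(epochs, trials)
  theta_window <- theta_window %||% config$plv_window
  bands <- default_bands()
  check_wavelet_margins(epochs$tmin, epochs$tmax, config$analysis_window,
                        bands)
  roi_power <- function(roi_name, band) {
    roi <- rois[[roi_name]]
    tc <- roi_timecourse_pca_flip(
      epochs$data[, roi$source_indices, , drop = FALSE], roi)
    morlet_band_power(tc, band, epochs$srate, epochs$times,
                      power_srate = config$power_srate)
  }
  alpha_L <- roi_power("LatOcc_L", bands$alpha)
  alpha_R <- roi_power("LatOcc_R", bands$alpha)
  beta_L <- roi_power("Hand_L", bands$beta)
  beta_R <- roi_power("Hand_R", bands$beta)
  theta_m <- roi_power("mPFC", bands$theta)

  pidx <- window_idx(alpha_L$times, config$analysis_window)
  ptimes <- alpha_L$times[pidx]
  correct <- trials$correct
  impl <- trials$task == "implementation"
  congruent <- trials$cued_side == trials$response_side

  cell_mean <- function(values, rows)
    colMeans(values[rows, pidx, drop = FALSE])
  ## power analyses use all correct trials (catch included)
  alpha_lat <- lateralize(alpha_L$values, alpha_R$values, trials,
                          "cued_side")
  beta_lat <- lateralize(beta_L$values, beta_R$values, trials,
                         "response_side")
  lat_cells <- function(lat, task_rows) list(
    contra = cell_mean(lat$contralateral, which(task_rows[lat$kept] &
                                                  correct[lat$kept])),
    ipsi = cell_mean(lat$ipsilateral, which(task_rows[lat$kept] &
                                              correct[lat$kept])))
  out <- list(
    subject_id = epochs$subject_id,
    times = ptimes,
    alpha = list(impl = lat_cells(alpha_lat, impl),
                 mem = lat_cells(alpha_lat, !impl)),
    beta = list(impl = lat_cells(beta_lat, impl),
                mem = lat_cells(beta_lat, !impl)),
    theta = list(impl = cell_mean(theta_m$values, which(impl & correct)),
                 mem = cell_mean(theta_m$values, which(!impl & correct)),
                 impl_cong = cell_mean(theta_m$values,
                                       which(impl & correct & congruent)),
                 impl_incong = cell_mean(theta_m$values,
                                         which(impl & correct & !congruent)),
                 mem_cong = cell_mean(theta_m$values,
                                      which(!impl & correct & congruent)),
                 mem_incong = cell_mean(theta_m$values,
                                        which(!impl & correct & !congruent))),
    theta_scalar = mean_window_power(theta_m$values, theta_window,
                                     theta_m$times),
    connectivity = connectivity_rows_subject(epochs, trials, rois, config),
    trials = trials,
    accuracy = mean(correct[!trials$catch]),
    catch_accuracy = c(
      implementation = mean(correct[trials$catch & impl]),
      memorization = mean(correct[trials$catch & !impl])))
  out
}

## Stack one named cell across subjects into a [subjects x time] matrix.
stack_cells <- function(reduced, path) {
  do.call(rbind, lapply(reduced, function(r) {
    v <- r
    for (p in path) v <- v[[p]]
    v
  }))
}

#' Congruency control contrasts on theta time courses
#'
#' Four cluster tests with the standard machinery: congruent vs
#' incongruent within each task, and task (implementation vs memorization)
#' within each congruency level. Separate significance of these contrasts
#' cannot be taken as evidence for an interaction; the returned object
#' carries that warning.
#'
#' @param cells list of `[subjects x time]` matrices named `impl_cong`,
#'   `impl_incong`, `mem_cong`, `mem_incong`.
#' @param config an [analysis_config()].
#' @param times time axis.
#' @param seed RNG seed for the permutations.
#' @return list of four `cluster_test` objects (`congruency_impl`,
#'   `congruency_mem`, `task_cong`, `task_incong`) plus `note`.
#' @export
congruency_contrasts <- function(cells, config = analysis_config(),
                                 times = NULL, seed = 1L) {
  need <- c("impl_cong", "impl_incong", "mem_cong", "mem_incong")
  if (!all(need %in% names(cells)))
    stop_config("cells must contain: %s", paste(need, collapse = ", "))
  run <- function(A, B, k)
    permutation_cluster_test(A, B,
                             n_permutations = config$n_permutations,
                             seed = derive_seed(seed, k),
                             tail = "two-sided",
                             alpha_level = config$alpha_level,
                             times = times)
  list(congruency_impl = run(cells$impl_cong, cells$impl_incong, 1L),
       congruency_mem = run(cells$mem_cong, cells$mem_incong, 2L),
       task_cong = run(cells$impl_cong, cells$mem_cong, 3L),
       task_incong = run(cells$impl_incong, cells$mem_incong, 4L),
       note = paste("Separate significance of congruency contrasts cannot",
                    "be taken as evidence for an interaction."))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: subject exclusion, behavioral tests, alpha
#' laterality repeated-measures cluster tests, beta laterality-by-task
#' cluster tests (including the one-sided interaction, implementation <
#' memorization), the theta task contrast with congruency controls,
#' trial-level theta scalar extraction and SD trimming, the RT/theta mixed
#' models and causal mediation, and the theta-phase connectivity mixed
#' models (PLV and wPLI, target pairs and control pair). Power analyses
#' use all correct trials (catch included); connectivity and mediation use
#' only correct regular trials. All randomness derives from
#' `config$rng_seed`.
#'
#' @param config an [analysis_config()].
#' @param sim a [sim_config()]; subjects are then simulated one at a time
#'   and reduced immediately (memory stays bounded).
#' @param data alternatively, a list of `list(epochs =, trials =)` per
#'   subject, or a character vector of directories readable by
#'   [read_epochs()].
#' @param rois ROI definitions; defaults to the simulation layout.
#' @param mediation_B bootstrap draws for the mediation stage.
#' @param boot_fit bootstrap engine, see [mediation_analysis()].
#' @param theta_window window for the trial theta scalar; defaults to
#'   `config$plv_window` (set independently to re-center it on an observed
#'   cluster).
#' @param verbose print stage progress.
#' @return object of class `run_report` with blocks `behavioral`, `alpha`,
#'   `beta`, `theta`, `congruency`, `mediation`, `connectivity`,
#'   `exclusions`, `accounting` and `provenance`.
#' @export
run_all <- function(config = analysis_config(), sim = NULL, data = NULL,
                    rois = NULL, mediation_B = 1000L,
                    boot_fit = c("subject", "full"), theta_window = NULL,
                    verbose = FALSE) {
  boot_fit <- match.arg(boot_fit)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(sim) && is.null(data))
    stop_config("supply either `sim` or `data`")
  rois <- rois %||% (if (!is.null(sim)) sim$rois else default_rois())

  ## ---- acquire and reduce subjects one at a time -------------------------
  n_sub <- if (!is.null(data)) length(data) else sim$n_subjects
  reduced <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    if (!is.null(data)) {
      d <- data[[i]]
      if (is.character(d))
        d <- list(epochs = read_epochs(d),
                  trials = read_trial_table(file.path(d, "trials.tsv")))
    } else {
      d <- simulate_subject(sim, derive_seed(sim$seed, i),
                            subject_id = sprintf("sim%04d", i))
    }
    say("reducing subject %d/%d (%s)", i, n_sub, d$epochs$subject_id)
    reduced[[i]] <- reduce_subject(d$epochs, d$trials, rois, config,
                                   theta_window)
    rm(d)
  }

  ## ---- subject exclusion -------------------------------------------------
  accs <- vapply(reduced, `[[`, numeric(1), "accuracy")
  excl <- lapply(seq_along(reduced), function(i)
    subject_exclusion(accs[i], accs, reduced[[i]]$catch_accuracy,
                      k = config$subject_excl_k,
                      catch_floor = config$catch_acc_floor))
  keep <- vapply(excl, `[[`, logical(1), "keep")
  exclusions <- data.frame(
    subject_id = vapply(reduced, `[[`, "", "subject_id"),
    accuracy = accs, keep = keep,
    reasons = vapply(excl, function(e)
      paste(e$reasons, collapse = ";"), ""))
  say("excluded %d of %d subjects", sum(!keep), n_sub)
  reduced <- reduced[keep]
  if (length(reduced) < 3) stop_config("fewer than 3 subjects retained")
  times <- reduced[[1]]$times
  seed0 <- config$rng_seed

  ## ---- behavioral --------------------------------------------------------
  trials_all <- do.call(rbind, lapply(reduced, function(r) {
    d <- as.data.frame(r$trials)
    d$subject_id <- r$subject_id
    d
  }))
  behavioral <- behavioral_tests(trials_all)

  ## ---- oscillatory cluster blocks ---------------------------------------
  rm_block <- function(prefix, seed_off) {
    A1 <- stack_cells(reduced, c(prefix, "impl", "contra"))
    A2 <- stack_cells(reduced, c(prefix, "impl", "ipsi"))
    B1 <- stack_cells(reduced, c(prefix, "mem", "contra"))
    B2 <- stack_cells(reduced, c(prefix, "mem", "ipsi"))
    an <- pointwise_rm_anova(A1, A2, B1, B2)
    run_f <- function(contrast, k)
      permutation_cluster_test(contrast,
                               n_permutations = config$n_permutations,
                               seed = derive_seed(seed0, seed_off + k),
                               stat = "F",
                               alpha_level = config$alpha_level,
                               times = times)
    list(task = run_f(an$contrasts$factor1, 1L),
         laterality = run_f(an$contrasts$factor2, 2L),
         interaction = run_f(an$contrasts$interaction, 3L),
         cells = list(A1 = A1, A2 = A2, B1 = B1, B2 = B2))
  }
  say("alpha laterality block")
  alpha <- rm_block("alpha", 10L)
  say("beta laterality block")
  beta <- rm_block("beta", 20L)
  ## directional interaction: implementation more contra-suppressed, i.e.
  ## (impl contra - ipsi) < (mem contra - ipsi)
  beta$interaction_one_sided <- permutation_cluster_test(
    (beta$cells$A1 - beta$cells$A2) - (beta$cells$B1 - beta$cells$B2),
    n_permutations = config$n_permutations,
    seed = derive_seed(seed0, 24L), tail = "one-sided-neg",
    alpha_level = config$alpha_level, times = times)

  say("theta task block")
  th_impl <- stack_cells(reduced, c("theta", "impl"))
  th_mem <- stack_cells(reduced, c("theta", "mem"))
  theta <- list(
    task = permutation_cluster_test(th_impl, th_mem,
                                    n_permutations = config$n_permutations,
                                    seed = derive_seed(seed0, 30L),
                                    tail = "one-sided-pos",
                                    alpha_level = config$alpha_level,
                                    times = times))
  congruency <- congruency_contrasts(
    list(impl_cong = stack_cells(reduced, c("theta", "impl_cong")),
         impl_incong = stack_cells(reduced, c("theta", "impl_incong")),
         mem_cong = stack_cells(reduced, c("theta", "mem_cong")),
         mem_incong = stack_cells(reduced, c("theta", "mem_incong"))),
    config, times, seed = derive_seed(seed0, 40L))

  ## ---- trial-level mediation --------------------------------------------
  say("mediation block")
  med_rows <- do.call(rbind, lapply(reduced, function(r) {
    tt <- r$trials
    ok <- tt$correct & !tt$catch & !is.na(tt$rt_ms)
    data.frame(subject = r$subject_id, task = tt$task[ok],
               treat = as.numeric(tt$task[ok] == "memorization"),
               theta = r$theta_scalar[ok], rt = tt$rt_ms[ok])
  }))
  n_med_input <- nrow(med_rows)
  trim_groups <- function(values, groups) {
    keep <- rep(TRUE, length(values))
    for (ix in split(seq_along(values), groups))
      if (length(ix) >= 3)
        keep[ix] <- suppressWarnings(trim_by_sd(values[ix], config$trim_k))
    keep
  }
  ## theta trim per subject across tasks (individual mean); RT trim per
  ## subject and task
  keep_theta <- trim_groups(med_rows$theta, med_rows["subject"])
  keep_rt <- trim_groups(med_rows$rt, med_rows[c("subject", "task")])
  med_rows <- med_rows[keep_theta & keep_rt, ]
  mediation <- mediation_analysis(med_rows, treat = "treat",
                                  mediator = "theta", outcome = "rt",
                                  subject = "subject", B = mediation_B,
                                  seed = derive_seed(seed0, 50L),
                                  boot_fit = boot_fit)

  ## ---- connectivity ------------------------------------------------------
  say("connectivity block")
  conn <- do.call(rbind, lapply(reduced, `[[`, "connectivity"))
  rownames(conn) <- NULL
  class(conn) <- c("connectivity_table", "data.frame")
  conn$task_impl <- as.numeric(conn$task == "implementation")
  conn$contra <- as.numeric(conn$laterality == "contralateral")
  conn_lmm <- function(pair, measure) {
    d <- conn[conn$roi_pair == pair, ]
    f <- if (pair == "mPFC-Control")
      stats::as.formula(sprintf("%s ~ task_impl + (1 + task_impl | subject_id)",
                                measure))
    else
      stats::as.formula(sprintf(
        "%s ~ task_impl * contra + (1 + task_impl | subject_id)", measure))
    fit_lmm(d, f)
  }
  connectivity <- list(
    plv_hand = conn_lmm("mPFC-Hand", "plv"),
    plv_latocc = conn_lmm("mPFC-LatOcc", "plv"),
    plv_control = conn_lmm("mPFC-Control", "plv"),
    wpli_hand = conn_lmm("mPFC-Hand", "wpli"),
    wpli_latocc = conn_lmm("mPFC-LatOcc", "wpli"),
    wpli_control = conn_lmm("mPFC-Control", "wpli"),
    table = conn)

  ## ---- accounting --------------------------------------------------------
  n_trials_total <- nrow(trials_all)
  n_correct <- sum(trials_all$correct)
  n_correct_regular <- sum(trials_all$correct & !trials_all$catch)
  accounting <- list(
    subjects = list(n_input = n_sub, n_analyzed = sum(keep),
                    n_excluded = sum(!keep)),
    power_trials = list(n_input = n_trials_total, n_analyzed = n_correct,
                        n_excluded = n_trials_total - n_correct,
                        note = "correct trials, catch included"),
    mediation_trials = list(n_input = n_med_input,
                            n_analyzed = nrow(med_rows),
                            n_excluded = n_med_input - nrow(med_rows),
                            note = "correct regular trials after SD trims"),
    connectivity_trials = list(
      n_input = n_trials_total,
      n_analyzed = n_correct_regular,
      n_excluded = n_trials_total - n_correct_regular,
      note = "correct regular trials only"))
  for (a in accounting)
    stopifnot(a$n_input == a$n_analyzed + a$n_excluded)

  structure(list(behavioral = behavioral, alpha = alpha[c("task",
                                                          "laterality",
                                                          "interaction")],
                 beta = beta[c("task", "laterality", "interaction",
                               "interaction_one_sided")],
                 theta = theta, congruency = congruency,
                 mediation = mediation, connectivity = connectivity,
                 exclusions = exclusions, accounting = accounting,
                 provenance = list(
                   rng_seed = config$rng_seed,
                   sim_seed = if (!is.null(sim)) sim$seed else NA,
                   n_permutations = config$n_permutations,
                   package_version =
                     as.character(utils::packageVersion("thetalink")))),
            class = "run_report")
}

## Strip a cluster_test to its serializable summary.
cluster_json <- function(ct) {
  list(clusters = ct$clusters, threshold = ct$threshold,
       n_permutations = ct$n_permutations, tail = ct$tail,
       stat = ct$stat, alpha_level = ct$alpha_level, caveat = ct$caveat)
}

#' Serialize results to JSON
#'
#' `write_cluster_json` writes one cluster test; `write_report_json`
#' writes the numeric content of a full [run_all()] report (behavioral
#' blocks, cluster tables, mixed-model coefficient tables, mediation
#' estimates, exclusions, trial accounting and provenance). Model fit
#' objects and raw traces are omitted.
#'
#' @param x a `cluster_test` or `run_report`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_cluster_json <- function(x, file) {
  jsonlite::write_json(cluster_json(x), file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_cluster_json
#' @export
write_report_json <- function(x, file) {
  lmm_json <- function(l)
    list(formula = l$formula, fixed = l$fixed, random_sd = as.list(l$random_sd),
         sigma = l$sigma, singular = l$singular, fallback = l$fallback)
  med <- x$mediation
  payload <- list(
    behavioral = x$behavioral[c("rt_regular", "rt_catch", "error_regular",
                                "error_catch")],
    alpha = lapply(x$alpha, cluster_json),
    beta = lapply(x$beta, cluster_json),
    theta = lapply(x$theta, cluster_json),
    congruency = c(lapply(x$congruency[1:4], cluster_json),
                   list(note = x$congruency$note)),
    mediation = list(acme = med$acme, ade = med$ade, total = med$total,
                     prop_mediated = med$prop_mediated, B = med$B,
                     boot_fit = med$boot_fit, seed = med$seed),
    connectivity = lapply(x$connectivity[c("plv_hand", "plv_latocc",
                                           "plv_control", "wpli_hand",
                                           "wpli_latocc", "wpli_control")],
                          lmm_json),
    exclusions = x$exclusions,
    accounting = x$accounting,
    provenance = x$provenance)
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  subjects: %d analyzed, %d excluded\n",
              x$accounting$subjects$n_analyzed,
              x$accounting$subjects$n_excluded))
  b <- x$behavioral$rt_regular
  cat(sprintf("  RT (regular): impl %.0f ms vs mem %.0f ms, t = %.2f, p = %.3g\n",
              b$mean_implementation, b$mean_memorization, b$statistic,
              b$p_value))
  sig <- function(ct) {
    cl <- ct$clusters
    if (!nrow(cl) || !any(cl$significant)) return("none")
    i <- which(cl$significant)
    paste(sprintf("p=%.4g (d=%.2f)", cl$p_value[i], cl$d[i]),
          collapse = ", ")
  }
  cat("  alpha clusters: laterality ", sig(x$alpha$laterality),
      "; task ", sig(x$alpha$task),
      "; interaction ", sig(x$alpha$interaction), "\n", sep = "")
  cat("  beta clusters: laterality ", sig(x$beta$laterality),
      "; one-sided interaction ", sig(x$beta$interaction_one_sided),
      "\n", sep = "")
  cat("  theta task cluster: ", sig(x$theta$task), "\n", sep = "")
  pl <- x$connectivity$plv_hand$fixed
  cat(sprintf("  PLV mPFC-Hand task effect: beta = %.4g, p = %.3g\n",
              pl$estimate[pl$name == "task_impl"],
              pl$p_value[pl$name == "task_impl"]))
  cat(sprintf("  mediation ACME = %.4g, CI95 [%.4g, %.4g], p = %.4g\n",
              x$mediation$acme$estimate, x$mediation$acme$ci[1],
              x$mediation$acme$ci[2], x$mediation$acme$p))
  cat("  ", x$theta$task$caveat, "\n")
  invisible(x)
}
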