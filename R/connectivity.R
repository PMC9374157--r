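## Within-trial phase-synchronization estimators between ROI source sets:
## pairwise and multivariate PLV, and wPLI as a leakage-robust control.

#' Phase-locking value between two phase series
#'
#' `PLV = | mean_t exp(i (phi1(t) - phi2(t))) |` over the samples of the
#' window. 1 for any constant phase difference; approaches
#' `sqrt(pi) / (2 sqrt(T))` in expectation for independent uniform phases.
#'
#' @param phase1,phase2 numeric vectors of phases in radians.
#' @param window optional `c(t0, t1)` window in seconds (inclusive).
#' @param times time axis, required with `window`.
#' @return scalar in \[0, 1\].
#' @export
plv_pair <- function(phase1, phase2, window = NULL, times = NULL) {
  if (!is.null(window)) {
    idx <- window_idx(times, window)
    phase1 <- phase1[idx]; phase2 <- phase2[idx]
  }
  if (length(phase1) < 2L) stop_config("need >= 2 samples")
  if (!all(is.finite(phase1)) || !all(is.finite(phase2)))
    stop_config("non-finite phases")
  Mod(mean(exp(1i * (phase1 - phase2))))
}

#' Multivariate PLV between two ROIs
#'
#' Root mean square of the `M x N` matrix of pairwise PLVs between all
#' sources of the two ROIs:
#' `sqrt( mean_{m,n} plv(m, n)^2 )`. Reduces to [plv_pair()] for
#' `M = N = 1`.
#'
#' @param phasesA matrix `[M x time]` of phases for ROI 1.
#' @param phasesB matrix `[N x time]` of phases for ROI 2.
#' @param window,times optional window selection as in [plv_pair()].
#' @return scalar in \[0, 1\].
#' @export
plv_multivariate <- function(phasesA, phasesB, window = NULL, times = NULL) {
  if (is.null(dim(phasesA))) phasesA <- matrix(phasesA, nrow = 1L)
  if (is.null(dim(phasesB))) phasesB <- matrix(phasesB, nrow = 1L)
  if (ncol(phasesA) != ncol(phasesB))
    stop_config("window mismatch: phase matrices differ in length")
  if (!is.null(window)) {
    idx <- window_idx(times, window)
    phasesA <- phasesA[, idx, drop = FALSE]
    phasesB <- phasesB[, idx, drop = FALSE]
  }
  if (!all(is.finite(phasesA)) || !all(is.finite(phasesB)))
    stop_config("non-finite phases")
  T_ <- ncol(phasesA)
  cross <- exp(1i * phasesA) %*% Conj(t(exp(1i * phasesB))) / T_
  sqrt(mean(Mod(cross)^2))
}

#' Weighted phase-lag index between two analytic signals
#'
#' `wPLI = | sum_t Im X(t) | / sum_t | Im X(t) |` with
#' `X(t) = s1(t) * conj(s2(t))`. Insensitive to zero-lag (volume-conducted)
#' coupling: for exact zero-lag signals the imaginary cross-spectrum
#' vanishes and the value is defined as 0, flagged `degenerate`.
#'
#' @param analytic1,analytic2 complex vectors (analytic signals).
#' @param window,times optional window selection as in [plv_pair()].
#' @return scalar in \[0, 1\] with attribute `degenerate` (logical).
#' @export
wpli_pair <- function(analytic1, analytic2, window = NULL, times = NULL) {
  if (!is.null(window)) {
    idx <- window_idx(times, window)
    analytic1 <- analytic1[idx]; analytic2 <- analytic2[idx]
  }
  if (length(analytic1) < 2L) stop_config("need >= 2 samples")
  if (!all(is.finite(analytic1)) || !all(is.finite(analytic2)))
    stop_config("non-finite input")
  im <- Im(analytic1 * Conj(analytic2))
  denom <- sum(abs(im))
  if (denom < .Machine$double.eps * length(im)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- abs(sum(im)) / denom
  attr(out, "degenerate") <- FALSE
  out
}

## Multivariate wPLI: RMS aggregation of the pairwise wPLIs, mirroring the
## multivariate PLV rule (aggregation rule is a package convention).
wpli_multivariate <- function(analyticA, analyticB) {
  if (is.null(dim(analyticA))) analyticA <- matrix(analyticA, nrow = 1L)
  if (is.null(dim(analyticB))) analyticB <- matrix(analyticB, nrow = 1L)
  Ra <- Re(analyticA); Ia <- Im(analyticA)
  Rb <- Re(analyticB); Ib <- Im(analyticB)
  vals <- matrix(0, nrow(analyticA), nrow(analyticB))
  for (m in seq_len(nrow(analyticA))) {
    ## Im(a conj(b)) = Im(a) Re(b) - Re(a) Im(b), all rows of B at once
    imm <- Rb * matrix(Ia[m, ], nrow(analyticB), ncol(analyticB),
                       byrow = TRUE) -
      Ib * matrix(Ra[m, ], nrow(analyticB), ncol(analyticB), byrow = TRUE)
    denom <- rowSums(abs(imm))
    num <- abs(rowSums(imm))
    vals[m, ] <- ifelse(denom < .Machine$double.eps * ncol(imm), 0,
                        num / denom)
  }
  sqrt(mean(vals^2))
}

#' Build the per-trial connectivity table
#'
#' For every correct, non-catch trial of every subject, computes the
#' multivariate theta PLV and wPLI between the (bilateral) mPFC seed and
#' each posterior ROI, in the within-trial window. Laterality of hand ROIs
#' is assigned per trial relative to the response side, of occipital ROIs
#' relative to the cued side; a control ROI (if present) is labelled
#' `bilateral` and its pair tagged `mPFC-Control`.
#'
#' @param subjects list of `list(epochs =, trials =)` per subject (e.g.
#'   from [simulate_group()]).
#' @param rois named list of [roi_definition()] containing at least `mPFC`,
#'   `Hand_L`, `Hand_R`, `LatOcc_L`, `LatOcc_R`; `Parahippocampal` is used
#'   as the control pair when present.
#' @param config an [analysis_config()]; the connectivity window is
#'   `config$plv_window` and the theta band-pass uses 2 Hz transitions on
#'   the data's native sampling rate.
#' @return data.frame of class `connectivity_table` with columns
#'   `subject_id`, `trial_id`, `task`, `roi_pair`, `laterality`, `plv`,
#'   `wpli`.
#' @export
build_connectivity_table <- function(subjects, rois,
                                     config = analysis_config()) {
  for (r in rois) if (!length(r$source_indices))
    stop_config("ROI %s has zero sources", r$name)
  rows <- lapply(subjects, function(sub)
    connectivity_rows_subject(sub$epochs, sub$trials, rois, config))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("connectivity_table", "data.frame")
  out
}

## Per-subject connectivity rows. The theta band-pass and Hilbert
## transform are applied to all ROI sources of all correct regular trials
## in one FFT pass; pairwise estimators then run trial by trial on the
## connectivity window.
connectivity_rows_subject <- function(epochs, trials, rois, config) {
  validate_epochs_trials(epochs, trials)
  keep <- which(trials$correct & !trials$catch)
  src <- sort(unique(unlist(lapply(rois, `[[`, "source_indices"))))
  n_k <- length(keep)
  n_s <- length(src)
  n_t <- length(epochs$times)
  h <- fir_bandpass_kernel(3, 7, epochs$srate, 2, 2)
  if (n_t < length(h))
    stop_config("epoch shorter than the theta filter (%d taps)", length(h))
  ## [time x (trial, source)] layout: column (j - 1) * n_k + i holds
  ## trial keep[i], source src[j]
  flat <- matrix(aperm(epochs$data[keep, src, , drop = FALSE],
                       c(3, 1, 2)), nrow = n_t)
  ana <- filter_analytic_cols(flat, h)
  widx <- window_idx(epochs$times, config$plv_window)
  ana <- ana[widx, , drop = FALSE]

  col_of <- function(j_set, i) (j_set - 1L) * n_k + i
  loc <- match(rois$mPFC$source_indices, src)
  pairs <- list()
  for (nm in c("Hand_L", "Hand_R", "LatOcc_L", "LatOcc_R"))
    pairs[[nm]] <- match(rois[[nm]]$source_indices, src)
  ctrl <- if (!is.null(rois$Parahippocampal))
    match(rois$Parahippocampal$source_indices, src) else NULL
  n_pairs <- 4L + !is.null(ctrl)

  pair_name <- lat_name <- character(n_k * n_pairs)
  plv <- wpli <- numeric(n_k * n_pairs)
  trial_row <- integer(n_k * n_pairs)
  at <- 0L
  for (i in seq_len(n_k)) {
    tr <- keep[i]
    a_m <- t(ana[, col_of(loc, i), drop = FALSE])
    ph_m <- Arg(a_m)
    resp <- trials$response_side[tr]
    cued <- trials$cued_side[tr]
    spec <- list(
      list(pairs[[if (resp == "left") "Hand_R" else "Hand_L"]],
           "mPFC-Hand", "contralateral"),
      list(pairs[[if (resp == "left") "Hand_L" else "Hand_R"]],
           "mPFC-Hand", "ipsilateral"),
      list(pairs[[if (cued == "left") "LatOcc_R" else "LatOcc_L"]],
           "mPFC-LatOcc", "contralateral"),
      list(pairs[[if (cued == "left") "LatOcc_L" else "LatOcc_R"]],
           "mPFC-LatOcc", "ipsilateral"))
    if (!is.null(ctrl))
      spec <- c(spec, list(list(ctrl, "mPFC-Control", "bilateral")))
    for (sp in spec) {
      a_p <- t(ana[, col_of(sp[[1]], i), drop = FALSE])
      at <- at + 1L
      trial_row[at] <- tr
      pair_name[at] <- sp[[2]]
      lat_name[at] <- sp[[3]]
      plv[at] <- plv_multivariate(ph_m, Arg(a_p))
      wpli[at] <- wpli_multivariate(a_m, a_p)
    }
  }
  data.frame(subject_id = epochs$subject_id,
             trial_id = trials$trial_id[trial_row],
             task = trials$task[trial_row], roi_pair = pair_name,
             laterality = lat_name, plv = plv, wpli = wpli)
}

#' Write a connectivity table as TSV
#'
#' Tab-separated with header exactly
#' `subject_id trial_id task roi_pair laterality plv wpli`.
#'
#' @param table a `connectivity_table`.
#' @param file path.
#' @export
write_connectivity_table <- function(table, file) {
  utils::write.table(as.data.frame(table), file, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(file)
}
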