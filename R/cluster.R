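## Pointwise paired tests / repeated-measures factorial F on time courses,
## cluster formation, sign-flip permutation null, cluster p-values and
## windowed effect sizes.

#' Pointwise paired t statistic trace
#'
#' Paired t with `n - 1` df at every timepoint. Timepoints with zero
#' variance across subjects get statistic 0 (with a warning): they can
#' never exceed the cluster-forming threshold.
#'
#' @param condA,condB matrices `[subjects x time]`; if `condB` is `NULL`,
#'   `condA` is treated as a per-subject contrast tested against zero.
#' @return numeric t trace of length `ncol(condA)`.
#' @export
pointwise_paired_stat <- function(condA, condB = NULL) {
  D <- if (is.null(condB)) condA else condA - condB
  n <- nrow(D)
  if (n < 3) stop_config("need >= 3 subjects")
  m <- colMeans(D)
  v <- (colSums(D^2) - n * m^2) / (n - 1)
  zero <- v <= 0
  if (any(zero)) {
    warning(sum(zero), " timepoint(s) with zero variance; statistic set to 0",
            call. = FALSE)
    v[zero] <- Inf
  }
  m / sqrt(v / n)
}

#' Pointwise two-way repeated-measures F traces
#'
#' For a complete 2 x 2 within-subject design the main effects and the
#' interaction are single-df contrasts of the per-subject cell means, so
#' each F trace equals the squared paired t of the corresponding contrast:
#' factor-1 contrast `(A1 + A2) - (B1 + B2)`, factor-2 contrast
#' `(A1 - A2) + (B1 - B2)`, interaction `(A1 - A2) - (B1 - B2)`, where the
#' first letter indexes factor 1 and the digit factor 2.
#'
#' @param A1,A2,B1,B2 matrices `[subjects x time]` of within-subject cell
#'   means.
#' @return list with `F` (list of traces `factor1`, `factor2`,
#'   `interaction`), `contrasts` (the per-subject contrast matrices used,
#'   exchangeable under the respective null and therefore the unit of
#'   sign-flip permutation), and `df = c(1, n - 1)`.
#' @export
pointwise_rm_anova <- function(A1, A2, B1, B2) {
  dims <- dim(A1)
  for (m in list(A2, B1, B2))
    if (!identical(dim(m), dims)) stop_config("cells must share dimensions")
  contrasts <- list(factor1 = ((A1 + A2) - (B1 + B2)) / 2,
                    factor2 = ((A1 - A2) + (B1 - B2)) / 2,
                    interaction = (A1 - A2) - (B1 - B2))
  Ftr <- lapply(contrasts, function(D)
    suppressWarnings(pointwise_paired_stat(D))^2)
  list(F = Ftr, contrasts = contrasts, df = c(1, nrow(A1) - 1))
}

#' Form candidate clusters from a statistic trace
#'
#' Maximal runs of contiguous suprathreshold samples sharing a sign; the
#' cluster mass is the sum of the statistic over the run.
#'
#' @param stat_trace numeric trace.
#' @param threshold positive cluster-forming threshold (critical value of
#'   the pointwise test).
#' @param tail `"two-sided"`, `"one-sided-pos"` or `"one-sided-neg"`
#'   (which suprathreshold signs count).
#' @return data.frame with `start_idx`, `end_idx`, `sign`, `mass`
#'   (zero rows when nothing is suprathreshold).
#' @export
form_clusters <- function(stat_trace, threshold,
                          tail = c("two-sided", "one-sided-pos",
                                   "one-sided-neg")) {
  tail <- match.arg(tail)
  lab <- integer(length(stat_trace))
  if (tail != "one-sided-neg") lab[stat_trace > threshold] <- 1L
  if (tail != "one-sided-pos") lab[stat_trace < -threshold] <- -1L
  out <- data.frame(start_idx = integer(), end_idx = integer(),
                    sign = integer(), mass = numeric())
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values != 0L)) {
    idx <- starts[j]:ends[j]
    out <- rbind(out, data.frame(start_idx = starts[j], end_idx = ends[j],
                                 sign = r$values[j],
                                 mass = sum(stat_trace[idx])))
  }
  out
}

## Max cluster mass per row of a [n_perm x time] statistic matrix,
## iterating over timepoints with running mass vectors (fast in R).
max_mass_rows <- function(tmat, threshold, tail) {
  n <- nrow(tmat)
  pos <- neg <- best <- numeric(n)
  use_pos <- tail != "one-sided-neg"
  use_neg <- tail != "one-sided-pos"
  for (j in seq_len(ncol(tmat))) {
    v <- tmat[, j]
    if (use_pos) {
      pos <- ifelse(v > threshold, pos + v, 0)
      best <- pmax(best, pos)
    }
    if (use_neg) {
      neg <- ifelse(v < -threshold, neg + v, 0)
      best <- pmax(best, -neg)
    }
  }
  best
}

#' Cluster-based sign-flip permutation test on paired time courses
#'
#' Pointwise paired t (or single-df repeated-measures F) with cluster
#' formation at the pointwise critical value for `alpha_level`, and a
#' max-cluster-mass null built by randomly flipping the sign of each
#' subject's condition difference (the per-subject contrast for factorial
#' effects) over `n_permutations` permutations. A cluster's p-value is the
#' proportion of permutations whose largest cluster mass reaches the
#' observed mass (ties count against the observed; the smallest reportable
#' p is `1 / n_permutations`; the observed statistic is not added to the
#' denominator).
#'
#' @param condA matrix `[subjects x time]`, or a per-subject contrast if
#'   `condB` is `NULL`.
#' @param condB optional matrix `[subjects x time]`.
#' @param n_permutations number of sign-flip permutations.
#' @param seed RNG seed (same seed, same p-values).
#' @param tail `"two-sided"` (default), `"one-sided-pos"` (A > B) or
#'   `"one-sided-neg"` (A < B); one-sided tests use the one-sided pointwise
#'   critical value and compare signed mass.
#' @param stat `"t"` or `"F"` (single-df F = t^2, used for factorial
#'   effects; always two-sided by construction).
#' @param alpha_level pointwise and cluster alpha (default 0.05).
#' @param times optional time axis in seconds for reporting cluster
#'   boundaries.
#' @return object of class `cluster_test`: `clusters` data.frame
#'   (`start_idx`, `end_idx`, `start_s`, `end_s`, `sign`, `mass`,
#'   `p_value`, `significant`, `d`), `stat_trace`, `threshold`,
#'   `n_permutations`, `tail`, `stat`, `times`, and the boundary caveat
#'   carried as `caveat`.
#' @export
permutation_cluster_test <- function(condA, condB = NULL,
                                     n_permutations = 10000L, seed = 1L,
                                     tail = c("two-sided", "one-sided-pos",
                                              "one-sided-neg"),
                                     stat = c("t", "F"),
                                     alpha_level = 0.05, times = NULL) {
  tail <- match.arg(tail)
  stat <- match.arg(stat)
  if (n_permutations < 100)
    warning("fewer than 100 permutations: p-value resolution is coarse",
            call. = FALSE)
  D <- if (is.null(condB)) condA else condA - condB
  n <- nrow(D)
  n_t <- ncol(D)
  t_obs <- suppressWarnings(pointwise_paired_stat(D))

  if (stat == "t") {
    thr <- if (tail == "two-sided")
      stats::qt(1 - alpha_level / 2, n - 1) else stats::qt(1 - alpha_level,
                                                           n - 1)
    trace_obs <- t_obs
    trace_tail <- tail
  } else {
    thr <- stats::qf(1 - alpha_level, 1, n - 1)
    trace_obs <- t_obs^2
    trace_tail <- "one-sided-pos"   # F is non-negative
  }
  clusters <- form_clusters(trace_obs, thr, trace_tail)

  ## permutation null of the max cluster mass (fully vectorized):
  ## sign flips leave colSums(D^2) invariant, so the permuted t trace
  ## needs only the permuted means.
  set.seed(seed)
  S <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
              n_permutations, n)
  M <- (S %*% D) / n
  ss <- colSums(D^2)
  V <- sweep(-n * M^2, 2, ss, `+`) / (n - 1)
  V[V <= 0] <- Inf
  Tp <- M / sqrt(V / n)
  if (stat == "F") Tp <- Tp^2
  null_max <- max_mass_rows(Tp, thr, trace_tail)

  if (nrow(clusters)) {
    obs_mass <- abs(clusters$mass)
    clusters$p_value <- pmax(vapply(obs_mass, function(m)
      sum(null_max >= m), numeric(1)) / n_permutations, 1 / n_permutations)
    clusters$significant <- clusters$p_value < alpha_level
    clusters$d <- vapply(seq_len(nrow(clusters)), function(i)
      suppressWarnings(
        cohens_d_window(D, window = NULL,
                        idx = clusters$start_idx[i]:clusters$end_idx[i])),
      numeric(1))
  } else {
    clusters$p_value <- numeric(0)
    clusters$significant <- logical(0)
    clusters$d <- numeric(0)
  }
  if (!is.null(times)) {
    clusters$start_s <- if (nrow(clusters)) times[clusters$start_idx] else
      numeric(0)
    clusters$end_s <- if (nrow(clusters)) times[clusters$end_idx] else
      numeric(0)
  }
  structure(list(clusters = clusters, stat_trace = trace_obs,
                 threshold = thr, n_permutations = n_permutations,
                 tail = tail, stat = stat, times = times,
                 alpha_level = alpha_level, null_max = null_max,
                 caveat = paste("Cluster boundaries reflect the",
                                "cluster-level inference only; individual",
                                "boundary timepoints are not themselves",
                                "significant and have to be interpreted",
                                "cautiously.")),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %s statistic, %s, %d permutations\n",
              x$stat, x$tail, x$n_permutations))
  cat(sprintf("  cluster-forming threshold %.3f (alpha %.3g)\n",
              x$threshold, x$alpha_level))
  if (!nrow(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    df <- x$clusters
    for (i in seq_len(nrow(df))) {
      loc <- if (!is.null(x$times))
        sprintf("%.3f-%.3f s", df$start_s[i], df$end_s[i])
      else sprintf("samples %d-%d", df$start_idx[i], df$end_idx[i])
      cat(sprintf("  cluster %d: %s, mass %.2f, p = %.4g%s, d = %.2f\n",
                  i, loc, df$mass[i], df$p_value[i],
                  ifelse(df$significant[i], " *", ""), df$d[i]))
    }
  }
  cat(" ", x$caveat, "\n")
  invisible(x)
}

#' Cohen's d over a time window
#'
#' Per subject, the condition difference is averaged over the window; d is
#' the mean of those subject values divided by their SD (n - 1
#' denominator). With zero SD the value is undefined and a signed infinity
#' is returned with a warning.
#'
#' @param condA,condB matrices `[subjects x time]` (or a contrast in
#'   `condA` with `condB = NULL`).
#' @param window `c(t0, t1)` in seconds (requires `times`).
#' @param times time axis.
#' @param idx alternative direct column index set.
#' @return scalar Cohen's d.
#' @export
cohens_d_window <- function(condA, condB = NULL, window = NULL,
                            times = NULL, idx = NULL) {
  D <- if (is.null(condB)) condA else condA - condB
  if (is.null(idx)) {
    if (is.null(window)) stop_config("supply `window` or `idx`")
    idx <- window_idx(times, window)
  }
  per_subj <- rowMeans(D[, idx, drop = FALSE])
  s <- sd1(per_subj)
  if (s == 0) {
    warning("zero SD of subject window means; d undefined", call. = FALSE)
    return(sign(mean(per_subj)) * Inf)
  }
  mean(per_subj) / s
}
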