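## Data containers, on-disk formats, validation, and the trial/subject
## filtering rules applied before any statistics.

#' Construct and validate an epoch set
#'
#' An `epoch_set` holds one subject's epoched source-level data as a
#' `trials x sources x time` array together with its time axis. Epochs are
#' time-locked to the retro-cue onset: `tmin` is the (non-positive) start of
#' the epoch in seconds relative to the cue, and the time axis runs
#' `tmin, tmin + 1/srate, ...` up to `tmax`.
#'
#' @param subject_id character scalar.
#' @param data numeric array `[n_trials x n_sources x n_times]`, arbitrary
#'   source units. Must be finite everywhere.
#' @param srate sampling rate in samples/second.
#' @param tmin epoch start in seconds relative to cue onset (`tmin <= 0`).
#' @param source_labels character vector, one label per source.
#' @return An object of class `epoch_set` with fields `subject_id`, `data`,
#'   `srate`, `tmin`, `tmax`, `times`, `source_labels`.
#' @examples
#' es <- epoch_set("s01", array(rnorm(2 * 3 * 36), c(2, 3, 36)),
#'                 srate = 10, tmin = -1,
#'                 source_labels = c("a", "b", "c"))
#' range(es$times)
#' @export
epoch_set <- function(subject_id, data, srate, tmin, source_labels) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_config("`data` must be a trials x sources x time array")
  if (!all(is.finite(data)))
    stop_config("epoch data contains non-finite values")
  if (tmin > 0) stop_config("tmin must be <= 0 (pre-cue interval required)")
  n_times <- dim(data)[3L]
  tmax <- tmin + (n_times - 1L) / srate
  if (tmax <= 0) stop_config("epoch must extend past cue onset (tmax > 0)")
  if (length(source_labels) != dim(data)[2L])
    stop_config("source_labels length (%d) != number of sources (%d)",
                length(source_labels), dim(data)[2L])
  ## n_times consistency with the declared window, within one sample
  if (abs(n_times - (round((tmax - tmin) * srate) + 1L)) > 1L)
    stop_config("time axis inconsistent with srate/tmin/tmax")
  structure(list(subject_id = as.character(subject_id), data = data,
                 srate = srate, tmin = tmin, tmax = tmax,
                 times = tmin + (seq_len(n_times) - 1L) / srate,
                 source_labels = as.character(source_labels)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s: %d trials x %d sources x %d samples\n",
              x$subject_id, d[1], d[2], d[3]))
  cat(sprintf("  srate %g Hz, epoch [%g, %g] s relative to cue onset\n",
              x$srate, x$tmin, x$tmax))
  invisible(x)
}

#' Construct and validate a per-trial metadata table
#'
#' One row per trial of the matching [epoch_set()], in the same order.
#' Missing reaction times (no-response trials) are kept as `NA` and excluded
#' from RT analyses downstream. Congruency is derivable as
#' `cued_side == response_side`.
#'
#' @param df data.frame with columns `trial_id`, `task`
#'   (`"implementation"`/`"memorization"`), `cued_side`, `response_side`
#'   (`"left"`/`"right"`), `correct`, `catch` (logical), `rt_ms` (numeric,
#'   `NA` allowed), `block` (integer).
#' @return the validated data.frame, classed `trial_table`.
#' @export
trial_table <- function(df) {
  req <- c("trial_id", "task", "cued_side", "response_side", "correct",
           "catch", "rt_ms", "block")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop_config("trial table missing columns: %s",
                                paste(miss, collapse = ", "))
  df <- df[, req]
  if (!all(df$task %in% c("implementation", "memorization")))
    stop_config("task must be 'implementation' or 'memorization'")
  for (col in c("cued_side", "response_side"))
    if (!all(df[[col]] %in% c("left", "right")))
      stop_config("%s must be 'left' or 'right'", col)
  df$correct <- as.logical(df$correct)
  df$catch <- as.logical(df$catch)
  df$rt_ms <- as.numeric(df$rt_ms)
  if (any(df$rt_ms < 0, na.rm = TRUE)) stop_config("negative rt_ms")
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Assert that an epoch set and trial table describe the same trials
#' @param epochs an [epoch_set()].
#' @param trials a [trial_table()].
#' @return invisibly `TRUE`; errors on length mismatch.
#' @export
validate_epochs_trials <- function(epochs, trials) {
  if (dim(epochs$data)[1L] != nrow(trials))
    stop_config("trial table has %d rows but epoch set has %d trials",
                nrow(trials), dim(epochs$data)[1L])
  invisible(TRUE)
}

#' Define a region of interest as a labelled set of sources
#'
#' ROIs are abstract labelled source sets: a name, the (1-based) indices of
#' the member sources in the epoch array, and a dipole orientation sign per
#' source that is applied before any ROI aggregation.
#'
#' @param name character.
#' @param source_indices integer vector, unique, 1-based.
#' @param orientation_signs vector of +1/-1, one per source.
#' @param hemisphere one of `"left"`, `"right"`, `"bilateral"`.
#' @return a `roi_definition` list.
#' @export
roi_definition <- function(name, source_indices, orientation_signs,
                           hemisphere = c("bilateral", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  source_indices <- as.integer(source_indices)
  if (anyDuplicated(source_indices)) stop_config("duplicate source indices")
  if (any(source_indices < 1L)) stop_config("source indices must be >= 1")
  if (length(orientation_signs) != length(source_indices))
    stop_config("orientation_signs and source_indices lengths differ")
  if (!all(orientation_signs %in% c(-1, 1)))
    stop_config("orientation signs must be +1 or -1")
  structure(list(name = name, source_indices = source_indices,
                 orientation_signs = as.numeric(orientation_signs),
                 hemisphere = hemisphere),
            class = "roi_definition")
}

#' Frequency band specification
#'
#' The three analysis bands and their wavelet cycle counts: theta 3--7 Hz
#' (3 cycles), alpha 8--14 Hz (4 cycles), beta 15--30 Hz (5 cycles).
#'
#' @param name band name.
#' @param f_lo,f_hi band edges in Hz.
#' @param n_cycles Morlet cycles for this band.
#' @return a `band_spec` list.
#' @export
band_spec <- function(name, f_lo, f_hi, n_cycles) {
  if (!(f_lo > 0 && f_lo < f_hi)) stop_config("need 0 < f_lo < f_hi")
  if (n_cycles < 1) stop_config("n_cycles must be >= 1")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi, n_cycles = n_cycles),
            class = "band_spec")
}

#' Canonical analysis bands
#' @return named list of [band_spec()]: theta, alpha, beta.
#' @export
default_bands <- function() {
  list(theta = band_spec("theta", 3, 7, 3),
       alpha = band_spec("alpha", 8, 14, 4),
       beta  = band_spec("beta", 15, 30, 5))
}

#' Analysis configuration
#'
#' Collects the fixed analysis constants: the statistical window 0--1.8 s
#' from cue onset, the 355--985 ms trial-scalar / connectivity window, the
#' permutation count and alpha level, the outlier-trimming multipliers, the
#' subject-exclusion rules and the power-grid sampling rate.
#'
#' @param analysis_window statistical window in seconds.
#' @param plv_window within-trial connectivity / theta-scalar window (s).
#' @param n_permutations permutations for cluster tests.
#' @param alpha_level significance level.
#' @param trim_k SD multiplier for trial trimming.
#' @param subject_excl_k SD multiplier for subject accuracy exclusion.
#' @param catch_acc_floor minimum catch-trial accuracy per task.
#' @param power_srate sampling rate of power time courses (must divide the
#'   data rate).
#' @param rng_seed integer seed for all stochastic stages.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(analysis_window = c(0, 1.8),
                            plv_window = c(0.355, 0.985),
                            n_permutations = 10000L,
                            alpha_level = 0.05,
                            trim_k = 3,
                            subject_excl_k = 2.5,
                            catch_acc_floor = 0.60,
                            power_srate = 128,
                            rng_seed = 1L) {
  if (!(alpha_level > 0 && alpha_level < 1)) stop_config("bad alpha_level")
  if (diff(analysis_window) <= 0 || diff(plv_window) <= 0)
    stop_config("windows must have positive length")
  structure(list(analysis_window = analysis_window, plv_window = plv_window,
                 n_permutations = as.integer(n_permutations),
                 alpha_level = alpha_level, trim_k = trim_k,
                 subject_excl_k = subject_excl_k,
                 catch_acc_floor = catch_acc_floor,
                 power_srate = power_srate, rng_seed = as.integer(rng_seed)),
            class = "analysis_config")
}

## ---------------------------------------------------------------- on-disk ----

#' Write / read one subject's epochs to a directory
#'
#' The array container is a raw little-endian float64 file `epochs.bin`
#' holding the tensor with time fastest, then sources, then trials; the
#' `meta.json` sidecar records `subject_id`, `srate`, `tmin`, `tmax`,
#' `shape` and `source_labels`. The sidecar is authoritative: axis order,
#' `tmin` and `srate` are always taken from it, never inferred from the
#' array file.
#'
#' @param epochs an [epoch_set()].
#' @param path directory (created if needed).
#' @param trials optional [trial_table()], written as `trials.tsv`
#'   (tab-separated, `n/a` for missing RT).
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, trials = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(subject_id = epochs$subject_id, srate = epochs$srate,
               tmin = epochs$tmin, tmax = epochs$tmax,
               shape = dim(epochs$data),
               source_labels = epochs$source_labels)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "epochs.bin"), "wb")
  on.exit(close(con))
  ## aperm so that time is the fastest-varying index on disk
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con,
           size = 8, endian = "little")
  if (!is.null(trials)) {
    validate_epochs_trials(epochs, trials)
    write_trial_table(trials, file.path(path, "trials.tsv"))
  }
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  sidecar <- file.path(path, "meta.json")
  if (!file.exists(sidecar))
    stop_config("missing sidecar meta.json in %s", path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  binfile <- file.path(path, "epochs.bin")
  if (!file.exists(binfile)) stop_config("missing epochs.bin in %s", path)
  shape <- as.integer(meta$shape)
  n_expected <- prod(shape)
  n_avail <- file.size(binfile) / 8
  if (n_avail != n_expected)
    stop_config(paste0("integrity error: sidecar declares %d trials ",
                       "(%d values) but array file holds %d values"),
                shape[1], n_expected, n_avail)
  con <- file(binfile, "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n_expected, size = 8, endian = "little")
  data <- aperm(array(raw, dim = rev(shape)), c(3, 2, 1))
  epoch_set(meta$subject_id, data, srate = meta$srate, tmin = meta$tmin,
            source_labels = meta$source_labels)
}

#' Write / read a trial table as BIDS-events-like TSV
#'
#' Tab-separated UTF-8 with header exactly
#' `trial_id task cued_side response_side correct catch rt_ms block`;
#' missing reaction times are serialized as `n/a`.
#'
#' @param trials a [trial_table()].
#' @param file file path.
#' @return `file` (write) or the [trial_table()] (read).
#' @export
write_trial_table <- function(trials, file) {
  out <- as.data.frame(trials)
  out$correct <- as.integer(out$correct)
  out$catch <- as.integer(out$catch)
  out$rt_ms <- ifelse(is.na(out$rt_ms), "n/a", format(out$rt_ms, digits = 15))
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(file)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          na.strings = "n/a", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  df$correct <- as.logical(df$correct)
  df$catch <- as.logical(df$catch)
  trial_table(df)
}

#' Write / read ROI definitions as JSON
#'
#' The JSON layout is a list of `{name, source_indices, orientation_signs,
#' hemisphere}`; indices are 0-based on disk and 1-based in R.
#'
#' @param rois list of [roi_definition()].
#' @param file file path.
#' @export
write_rois <- function(rois, file) {
  payload <- lapply(rois, function(r)
    list(name = r$name, source_indices = r$source_indices - 1L,
         orientation_signs = r$orientation_signs, hemisphere = r$hemisphere))
  jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_rois
#' @export
read_rois <- function(file) {
  payload <- jsonlite::read_json(file, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  rois <- lapply(payload, function(r)
    roi_definition(r$name, unlist(r$source_indices) + 1L,
                   unlist(r$orientation_signs), r$hemisphere))
  names(rois) <- vapply(rois, `[[`, "", "name")
  rois
}

## ------------------------------------------------------------- filtering ----

#' Single-pass SD-based outlier trimming
#'
#' Returns a keep-mask that is `FALSE` exactly where
#' `|x - mean(x)| > k * sd(x)`, with mean and SD (n-1 denominator) computed
#' once on the full input. The rule is deliberately single-pass: it is never
#' re-applied iteratively to the survivors.
#'
#' @param values numeric vector (>= 3 finite values).
#' @param k SD multiplier (default 3).
#' @return logical keep-mask, same length as `values`. Non-finite entries
#'   are excluded from the statistics and marked `FALSE`.
#' @examples
#' trim_by_sd(c(rep(5, 10), 100), k = 3)  # drops only the 100
#' @export
trim_by_sd <- function(values, k = 3) {
  if (k <= 0) stop_config("k must be > 0")
  finite <- is.finite(values)
  if (sum(finite) < 3) stop_config("need >= 3 finite values")
  m <- mean(values[finite])
  s <- sd1(values[finite])
  if (s == 0) {
    warning("all values identical (SD = 0); keeping all", call. = FALSE)
    return(finite)
  }
  finite & (abs(values - m) <= k * s)
}

#' Subject-level exclusion decision
#'
#' A subject is dropped when their overall accuracy falls more than
#' `k` SDs below the group mean accuracy (low task performance), or when
#' their catch-trial accuracy is below the floor (default 60%) in either
#' task. The deviation rule is interpreted as a lower-tail cutoff
#' (`mean - k * SD`); this reading is recorded in the returned object.
#'
#' @param accuracy this subject's overall accuracy in \[0, 1\].
#' @param group_accuracies accuracies of all subjects (including this one),
#'   length >= 3.
#' @param catch_accuracy named or unnamed numeric vector of per-task
#'   catch-trial accuracies.
#' @param k SD multiplier (default 2.5).
#' @param catch_floor catch accuracy floor (default 0.60).
#' @return list with `keep` (logical) and `reasons` (character vector among
#'   `"low_accuracy"`, `"catch_floor"`).
#' @export
subject_exclusion <- function(accuracy, group_accuracies, catch_accuracy,
                              k = 2.5, catch_floor = 0.60) {
  if (length(group_accuracies) < 3) stop_config("group size must be >= 3")
  vals <- c(accuracy, group_accuracies, catch_accuracy)
  if (any(vals < 0 | vals > 1)) stop_config("accuracies must lie in [0, 1]")
  reasons <- character()
  cutoff <- mean(group_accuracies) - k * sd1(group_accuracies)
  if (accuracy < cutoff) reasons <- c(reasons, "low_accuracy")
  if (any(catch_accuracy < catch_floor)) reasons <- c(reasons, "catch_floor")
  list(keep = length(reasons) == 0L, reasons = reasons,
       accuracy_cutoff = cutoff, rule = "accuracy below mean - k*SD")
}
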