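## Trial-level linear mixed models, the Baron-Kenny criterion chain,
## bootstrap causal mediation (ACME/ADE), and the behavioral group tests.

#' Fit a trial-level linear mixed model
#'
#' REML fit of a fixed formula (no model selection): the random-effect
#' structure is taken exactly as given. P-values use Satterthwaite
#' approximate df via lmerTest (or a normal approximation when
#' `p_method = "normal"`, which is faster in large simulation loops).
#' A singular fit is refit with a random-intercept-only structure and
#' flagged.
#'
#' @param data data.frame of trial rows.
#' @param formula lme4-style formula, e.g.
#'   `rt ~ theta + task + (1 + task | subject)`.
#' @param p_method `"satterthwaite"` or `"normal"`.
#' @param reml logical, REML (default) or ML.
#' @return object of class `lmm_result`: `fixed` (data.frame with
#'   `name`, `estimate`, `se`, `t`, `df_approx`, `ci_lo`, `ci_hi`,
#'   `p_value`), `random_sd`, `sigma`, `singular`, `fallback`, `formula`,
#'   and the underlying `fit`.
#' @export
fit_lmm <- function(data, formula, p_method = c("satterthwaite", "normal"),
                    reml = TRUE) {
  p_method <- match.arg(p_method)
  bars <- lme4::findbars(formula)
  grp_vars <- unique(vapply(bars, function(b) deparse(b[[3]]), ""))
  for (g in grp_vars) {
    lv <- length(unique(data[[g]]))
    if (lv < 2)
      stop_config("grouping factor '%s' has %d level(s); need >= 2", g, lv)
    if (lv < 10)
      warning("fewer than 10 grouping levels for '", g,
              "'; mixed-model inference may be unstable", call. = FALSE)
  }
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fitter <- if (p_method == "satterthwaite") lmerTest::lmer else lme4::lmer
  fit <- fitter(formula, data = data, REML = reml, control = ctrl)
  fallback <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4) && length(bars)) {
    fb <- stats::as.formula(paste(
      deparse(formula[[2]]), "~",
      paste(deparse(lme4::nobars(formula)[[3]]), collapse = ""), "+",
      paste(sprintf("(1 | %s)", grp_vars), collapse = " + ")))
    fit2 <- tryCatch(fitter(fb, data = data, REML = reml, control = ctrl),
                     error = function(e) NULL)
    if (!is.null(fit2)) {
      fit <- fit2
      fallback <- TRUE
      formula <- fb
    }
  }
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tval <- est / se
  if (p_method == "satterthwaite") {
    cf <- stats::coef(summary(fit))
    df_approx <- cf[, "df"]
    pval <- cf[, "Pr(>|t|)"]
  } else {
    df_approx <- rep(Inf, length(est))
    pval <- 2 * stats::pnorm(-abs(tval))
  }
  q <- ifelse(is.finite(df_approx), stats::qt(0.975, df_approx), 1.959964)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fixed = data.frame(name = names(est), estimate = unname(est),
                       se = unname(se), t = unname(tval),
                       df_approx = unname(df_approx),
                       ci_lo = unname(est - q * se),
                       ci_hi = unname(est + q * se),
                       p_value = unname(pval)),
    random_sd = stats::setNames(vc$sdcor, paste(vc$grp, vc$var1, vc$var2,
                                                sep = ".")),
    sigma = stats::sigma(fit),
    singular = lme4::isSingular(fit, tol = 1e-4),
    fallback = fallback,
    formula = paste(deparse(formula), collapse = ""),
    fit = fit), class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result>", x$formula, "\n")
  if (x$fallback) cat("  (singular fit; random-intercept-only fallback)\n")
  df <- x$fixed
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-20s beta = %9.4g  CI95 [%.4g, %.4g]  t(%.1f) = %.2f  p = %.3g\n",
                df$name[i], df$estimate[i], df$ci_lo[i], df$ci_hi[i],
                df$df_approx[i], df$t[i], df$p_value[i]))
  invisible(x)
}

## Extract one fixed-effect coefficient by (partial) name.
coef_of <- function(lmm, name) {
  i <- which(lmm$fixed$name == name)
  if (!length(i)) stop_config("no fixed effect named '%s'", name)
  lmm$fixed$estimate[i]
}

## Per-subject OLS coefficients for the two mediation models; the unit of
## the subject-level bootstrap.
subject_coefs <- function(data, treat, mediator, outcome, subject) {
  subs <- split(data, data[[subject]], drop = TRUE)
  out <- t(vapply(subs, function(d) {
    x <- cbind(1, d[[mediator]], d[[treat]])
    co_out <- stats::lm.fit(x, d[[outcome]])$coefficients
    xm <- cbind(1, d[[treat]])
    co_med <- stats::lm.fit(xm, d[[mediator]])$coefficients
    co_tot <- stats::lm.fit(xm, d[[outcome]])$coefficients
    c(a = unname(co_med[2]), b = unname(co_out[2]), cp = unname(co_out[3]),
      total = unname(co_tot[2]))
  }, numeric(4)))
  if (any(!is.finite(out)))
    stop_config("per-subject regressions undefined (collinear or one-level treatment)")
  out
}

#' Causal mediation analysis with a subject-level bootstrap
#'
#' Evaluates the Baron-Kenny criterion chain first (treatment on outcome,
#' treatment on mediator, mediator on outcome given treatment — each as a
#' mixed model via [fit_lmm()] with the fixed structures
#' `outcome ~ treat`, `mediator ~ treat`, `outcome ~ mediator + treat`,
#' all with `(1 + treat | subject)`), then estimates the average causal
#' mediation effect ACME = a * b (treatment effect on the mediator times
#' the mediator effect on the outcome), the average direct effect
#' ADE = c', and the total effect. Uncertainty is a nonparametric
#' bootstrap that resamples subjects with replacement and refits both
#' models per draw: by default with the two-stage estimator (per-subject
#' OLS coefficients averaged over resampled subjects, which coincides with
#' the mixed-model fixed effects in balanced within-subject designs);
#' `boot_fit = "full"` does literal mixed-model refits (slow). CIs are
#' percentile; `p = 2 * min(frac <= 0, frac >= 0)`.
#'
#' @param data trial rows.
#' @param treat,mediator,outcome,subject column names.
#' @param B bootstrap draws (warn below 200).
#' @param seed RNG seed; results are bit-reproducible for a fixed seed.
#' @param boot_fit `"subject"` (two-stage, default) or `"full"`.
#' @param p_method p-value method for the criterion-chain fits.
#' @return object of class `mediation_result` with components `acme`,
#'   `ade`, `total` (each `estimate`, `ci`, `p`), `prop_mediated`,
#'   `chain` (the three `lmm_result`s), `B`, `n_dropped`, `seed`.
#' @export
mediation_analysis <- function(data, treat = "treat", mediator = "mediator",
                               outcome = "outcome", subject = "subject",
                               B = 1000L, seed = 1L,
                               boot_fit = c("subject", "full"),
                               p_method = c("satterthwaite", "normal")) {
  boot_fit <- match.arg(boot_fit)
  p_method <- match.arg(p_method)
  if (B < 200) warning("B < 200 bootstrap draws: intervals are unstable",
                       call. = FALSE)
  f_tot <- stats::as.formula(sprintf("%s ~ %s + (1 + %s | %s)",
                                     outcome, treat, treat, subject))
  f_med <- stats::as.formula(sprintf("%s ~ %s + (1 + %s | %s)",
                                     mediator, treat, treat, subject))
  f_out <- stats::as.formula(sprintf("%s ~ %s + %s + (1 + %s | %s)",
                                     outcome, mediator, treat, treat,
                                     subject))
  chain <- list(total = fit_lmm(data, f_tot, p_method),
                mediator = fit_lmm(data, f_med, p_method),
                outcome = fit_lmm(data, f_out, p_method))
  a_hat <- coef_of(chain$mediator, treat)
  b_hat <- coef_of(chain$outcome, mediator)
  cp_hat <- coef_of(chain$outcome, treat)
  tot_hat <- coef_of(chain$total, treat)

  set.seed(seed)
  n_dropped <- 0L
  if (boot_fit == "subject") {
    co <- subject_coefs(data, treat, mediator, outcome, subject)
    n_sub <- nrow(co)
    draws <- matrix(NA_real_, B, 3,
                    dimnames = list(NULL, c("acme", "ade", "total")))
    for (bb in seq_len(B)) {
      idx <- sample.int(n_sub, replace = TRUE)
      m <- colMeans(co[idx, , drop = FALSE])
      draws[bb, ] <- c(m["a"] * m["b"], m["cp"], m["total"])
    }
  } else {
    subs <- split(data, data[[subject]], drop = TRUE)
    n_sub <- length(subs)
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    draws <- matrix(NA_real_, B, 3,
                    dimnames = list(NULL, c("acme", "ade", "total")))
    for (bb in seq_len(B)) {
      idx <- sample.int(n_sub, replace = TRUE)
      d <- do.call(rbind, lapply(seq_along(idx), function(k) {
        dd <- subs[[idx[k]]]
        dd[[subject]] <- k
        dd
      }))
      fit1 <- tryCatch(lme4::lmer(f_med, data = d, REML = TRUE,
                                  control = ctrl), error = function(e) NULL)
      fit2 <- tryCatch(lme4::lmer(f_out, data = d, REML = TRUE,
                                  control = ctrl), error = function(e) NULL)
      if (is.null(fit1) || is.null(fit2)) {
        n_dropped <- n_dropped + 1L
        next
      }
      a_b <- lme4::fixef(fit1)[[treat]]
      b_b <- lme4::fixef(fit2)[[mediator]]
      cp_b <- lme4::fixef(fit2)[[treat]]
      draws[bb, ] <- c(a_b * b_b, cp_b, a_b * b_b + cp_b)
    }
    draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  }

  summarize <- function(v, est) {
    ci <- unname(stats::quantile(v, c(0.025, 0.975), type = 7))
    ## bootstrap p resolution is 2/B; smaller values are not resolvable
    list(estimate = est, ci = ci,
         p = max(2 * min(mean(v <= 0), mean(v >= 0)), 2 / nrow(draws)))
  }
  acme <- summarize(draws[, "acme"], a_hat * b_hat)
  ade <- summarize(draws[, "ade"], cp_hat)
  total <- summarize(draws[, "total"], tot_hat)
  structure(list(acme = acme, ade = ade, total = total,
                 prop_mediated = (a_hat * b_hat) / tot_hat,
                 a = a_hat, b = b_hat, chain = chain, draws = draws,
                 B = B, n_dropped = n_dropped, seed = seed,
                 boot_fit = boot_fit),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  line <- function(nm, s)
    cat(sprintf("  %-6s %9.4g  CI95 [%.4g, %.4g]  p = %.4g\n", nm,
                s$estimate, s$ci[1], s$ci[2], s$p))
  cat(sprintf("<mediation_result> %d bootstrap draws (%s refits%s)\n",
              x$B, x$boot_fit,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  line("ACME", x$acme); line("ADE", x$ade); line("total", x$total)
  cat(sprintf("  proportion mediated: %.3f\n", x$prop_mediated))
  invisible(x)
}

#' Behavioral group comparisons
#'
#' Per-subject mean RTs (correct trials) and error rates are computed
#' first, separately for regular and catch trials; tasks are then compared
#' on the subject means. RTs use paired t tests. Error rates are gated by
#' a Shapiro-Wilk test on the paired differences: when its p < 0.05 a
#' Wilcoxon signed-rank test is reported (exact for fewer than 5
#' subjects), otherwise a paired t. Differences are taken as memorization
#' minus implementation. Effect sizes: Cohen's d for t tests (mean of
#' differences over their SD), matched-pairs rank-biserial correlation for
#' Wilcoxon.
#'
#' @param subjects list of per-subject `list(trials = trial_table)` (e.g.
#'   from [simulate_group()]), or a single data.frame with a `subject_id`
#'   column bound to trial-table columns.
#' @return object of class `behavioral_report`: per-subject summary table
#'   and one test block per measure (`rt_regular`, `rt_catch`,
#'   `error_regular`, `error_catch`), each recording the gate decision.
#' @export
behavioral_tests <- function(subjects) {
  df <- if (is.data.frame(subjects)) subjects else
    do.call(rbind, lapply(subjects, function(s) {
      d <- as.data.frame(s$trials)
      d$subject_id <- s$epochs$subject_id %||% s$subject_id
      d
    }))
  agg <- do.call(rbind, lapply(split(df, df[c("subject_id", "task")]),
                               function(d) data.frame(
    subject_id = d$subject_id[1], task = d$task[1],
    rt_regular = mean(d$rt_ms[d$correct & !d$catch], na.rm = TRUE),
    rt_catch = mean(d$rt_ms[d$correct & d$catch], na.rm = TRUE),
    error_regular = mean(!d$correct[!d$catch]),
    error_catch = mean(!d$correct[d$catch]))))
  rownames(agg) <- NULL
  wide <- function(measure) {
    imp <- agg[agg$task == "implementation", ]
    mem <- agg[agg$task == "memorization", ]
    mem <- mem[match(imp$subject_id, mem$subject_id), ]
    cbind(implementation = imp[[measure]], memorization = mem[[measure]])
  }
  one_test <- function(measure, force_t = FALSE) {
    w <- wide(measure)
    w <- w[stats::complete.cases(w), , drop = FALSE]
    diffs <- w[, "memorization"] - w[, "implementation"]
    n <- length(diffs)
    if (n < 3)
      return(list(measure = measure, n = n,
                  mean_implementation = NA_real_,
                  mean_memorization = NA_real_, test = "insufficient",
                  shapiro_p = NA_real_, statistic = NA_real_,
                  p_value = NA_real_, effect_size = NA_real_,
                  effect_size_type = NA_character_))
    if (sd1(diffs) == 0)
      return(list(measure = measure, n = n,
                  mean_implementation = mean(w[, "implementation"]),
                  mean_memorization = mean(w[, "memorization"]),
                  test = "paired_t", shapiro_p = NA_real_,
                  statistic = if (mean(diffs) == 0) 0 else
                    sign(mean(diffs)) * Inf,
                  p_value = if (mean(diffs) == 0) 1 else 0,
                  effect_size = if (mean(diffs) == 0) 0 else
                    sign(mean(diffs)) * Inf,
                  effect_size_type = "cohens_d"))
    sw <- if (force_t || n < 3) NULL else stats::shapiro.test(diffs)
    use_wilcoxon <- !is.null(sw) && sw$p.value < 0.05
    if (use_wilcoxon) {
      ## exact distribution whenever it is defined (always for n < 5);
      ## ties/zeroes force the normal approximation at larger n
      has_ties <- any(diffs == 0) || anyDuplicated(abs(diffs[diffs != 0]))
      ht <- suppressWarnings(
        stats::wilcox.test(w[, "memorization"], w[, "implementation"],
                           paired = TRUE,
                           exact = n < 5 || (n < 50 && !has_ties)))
      pr <- diffs[diffs != 0]
      rk <- rank(abs(pr))
      eff <- (sum(rk[pr > 0]) - sum(rk[pr < 0])) / sum(rk)
      eff_name <- "rank_biserial"
    } else {
      ht <- stats::t.test(w[, "memorization"], w[, "implementation"],
                          paired = TRUE)
      eff <- mean(diffs) / sd1(diffs)
      eff_name <- "cohens_d"
    }
    list(measure = measure, n = n,
         mean_implementation = mean(w[, "implementation"]),
         mean_memorization = mean(w[, "memorization"]),
         test = if (use_wilcoxon) "wilcoxon" else "paired_t",
         shapiro_p = if (is.null(sw)) NA_real_ else sw$p.value,
         statistic = unname(ht$statistic), p_value = ht$p.value,
         effect_size = eff, effect_size_type = eff_name)
  }
  structure(list(per_subject = agg,
                 rt_regular = one_test("rt_regular", force_t = TRUE),
                 rt_catch = one_test("rt_catch", force_t = TRUE),
                 error_regular = one_test("error_regular"),
                 error_catch = one_test("error_catch")),
            class = "behavioral_report")
}

#' @export
print.behavioral_report <- function(x, ...) {
  cat("<behavioral_report>\n")
  for (nm in c("rt_regular", "rt_catch", "error_regular", "error_catch")) {
    b <- x[[nm]]
    cat(sprintf("  %-13s impl %.4g vs mem %.4g: %s stat %.3f, p = %.3g, %s = %.3f\n",
                nm, b$mean_implementation, b$mean_memorization, b$test,
                b$statistic, b$p_value, b$effect_size_type, b$effect_size))
  }
  invisible(x)
}
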