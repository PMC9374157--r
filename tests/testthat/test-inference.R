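test_that("fit_lmm recovers known fixed effects with Satterthwaite df", {
  d <- simulate_mediation_trials(n_subjects = 20, n_trials = 80,
                                 a = 0.1, b = -3, cp = -250, seed = 2)
  fit <- fit_lmm(d, outcome ~ treat + (1 + treat | subject))
  co <- fit$fixed
  i <- co$name == "treat"
  expect_lt(abs(co$estimate[i] - (-250 + 0.1 * -3)), 3 * co$se[i])
  expect_true(co$ci_lo[i] < co$estimate[i] &
                co$estimate[i] < co$ci_hi[i])
  expect_true(is.finite(co$df_approx[i]) && co$df_approx[i] > 1)
  expect_true(all(co$p_value > 0 & co$p_value <= 1))
  expect_match(fit$formula, "treat | subject", fixed = TRUE)
  ## one grouping level is refused
  expect_error(fit_lmm(d[d$subject == d$subject[1], ],
                       outcome ~ treat + (1 + treat | subject)),
               "level")
})

test_that("singular random-slope fits fall back to random intercepts", {
  ## few subjects, no true slope heterogeneity: the slope variance lands
  ## on the boundary (fixed seed pins the singular fit)
  set.seed(1)
  n <- 8; m <- 20
  d <- data.frame(subject = factor(rep(1:n, each = m)),
                  treat = rep(rep(0:1, m / 2), n))
  d$y <- 2 + 1 * d$treat + rep(rnorm(n, 0, 2), each = m) + rnorm(n * m)
  fit <- suppressWarnings(
    suppressMessages(fit_lmm(d, y ~ treat + (1 + treat | subject))))
  expect_true(fit$fallback)
  expect_match(fit$formula, "(1 | subject)", fixed = TRUE)
  expect_lt(abs(fit$fixed$estimate[fit$fixed$name == "treat"] - 1), 0.5)
})

test_that("mediation analysis recovers the product of paths", {
  d <- simulate_mediation_trials(n_subjects = 24, n_trials = 100,
                                 a = 0.3, b = -5, cp = 400, seed = 7)
  med <- suppressWarnings(
    mediation_analysis(d, B = 400, seed = 5, p_method = "normal"))
  ## truth: ACME = a * b = -1.5
  expect_true(med$acme$ci[1] <= -1.5 && -1.5 <= med$acme$ci[2])
  expect_true(med$ade$ci[1] <= 400 && 400 <= med$ade$ci[2])
  ## linearity: total ~ ACME + ADE within bootstrap tolerance
  expect_equal(med$total$estimate, med$acme$estimate + med$ade$estimate,
               tolerance = 0.05 * abs(med$total$estimate))
  ## Baron-Kenny chain is present with the stated structures
  expect_named(med$chain, c("total", "mediator", "outcome"))
  expect_match(med$chain$outcome$formula, "mediator + treat",
               fixed = TRUE)
  ## reproducibility is bit-exact under a fixed seed
  med2 <- suppressWarnings(
    mediation_analysis(d, B = 400, seed = 5, p_method = "normal"))
  expect_identical(med$draws, med2$draws)
  expect_identical(med$acme, med2$acme)
})

test_that("a null mediator path yields an ACME interval covering zero", {
  d0 <- simulate_mediation_trials(n_subjects = 24, n_trials = 100,
                                  a = 0.3, b = 0, cp = 400, seed = 11)
  med0 <- suppressWarnings(
    mediation_analysis(d0, B = 300, seed = 2, p_method = "normal"))
  expect_true(med0$acme$ci[1] <= 0 && 0 <= med0$acme$ci[2])
  expect_gt(med0$acme$p, 0.05)
})

test_that("the full-refit bootstrap agrees with the two-stage engine", {
  d <- simulate_mediation_trials(n_subjects = 16, n_trials = 60,
                                 a = 0.3, b = -5, cp = 300, seed = 9)
  m_fast <- suppressWarnings(
    mediation_analysis(d, B = 60, seed = 3, p_method = "normal"))
  m_full <- suppressWarnings(
    mediation_analysis(d, B = 60, seed = 3, boot_fit = "full",
                       p_method = "normal"))
  ## identical point estimates (same mixed-model fits)
  expect_identical(m_fast$acme$estimate, m_full$acme$estimate)
  ## compatible uncertainty
  expect_equal(diff(m_fast$acme$ci), diff(m_full$acme$ci),
               tolerance = 0.6)
})

test_that("behavioral tests match the closed-form paired t", {
  ## per-subject means are exact: every trial of a subject shares its RT
  set.seed(21)
  n <- 30
  base <- rnorm(n, 900, 50)
  dd <- rnorm(n, 100, 10)
  dd <- (dd - mean(dd)) / sd(dd) * 10 + 100   # mean 100, sd 10 exactly
  subjects <- lapply(1:n, function(i) {
    tr <- data.frame(
      trial_id = 1:8, task = rep(c("implementation", "memorization"),
                                 each = 4),
      cued_side = "left", response_side = "right",
      correct = TRUE, catch = rep(c(FALSE, FALSE, FALSE, TRUE), 2),
      rt_ms = rep(c(base[i], base[i] + dd[i]), each = 4), block = 1L)
    list(trials = trial_table(tr), subject_id = sprintf("s%02d", i))
  })
  rep <- suppressWarnings(behavioral_tests(subjects))
  t_oracle <- 100 / (10 / sqrt(n))
  expect_equal(rep$rt_regular$statistic, t_oracle, tolerance = 1e-8)
  expect_equal(rep$rt_regular$effect_size, 10, tolerance = 1e-8)
  expect_equal(rep$rt_regular$mean_memorization -
                 rep$rt_regular$mean_implementation, 100)
})

test_that("the normality gate routes skewed error rates to Wilcoxon", {
  set.seed(22)
  n <- 24
  err_impl <- rep(0.05, n)
  err_mem <- 0.05 + rexp(n, 10)^2 * 40        # heavily right-skewed
  subjects <- lapply(1:n, function(i) {
    n_tr <- 40
    mk <- function(task, p_err) data.frame(
      trial_id = 1:n_tr, task = task, cued_side = "left",
      response_side = "right",
      correct = c(rep(FALSE, round(p_err * n_tr)),
                  rep(TRUE, n_tr - round(p_err * n_tr))),
      catch = FALSE, rt_ms = 800, block = 1L)
    tr <- rbind(mk("implementation", err_impl[i]), mk("memorization",
                                                      min(err_mem[i], 1)))
    tr$rt_ms[!tr$correct] <- NA
    tr$trial_id <- seq_len(nrow(tr))
    list(trials = trial_table(tr), subject_id = sprintf("s%02d", i))
  })
  rep <- suppressWarnings(behavioral_tests(subjects))
  expect_lt(rep$error_regular$shapiro_p, 0.05)
  expect_identical(rep$error_regular$test, "wilcoxon")
  expect_identical(rep$error_regular$effect_size_type, "rank_biserial")
  ## identical RTs across tasks: t = 0, p = 1
  expect_identical(rep$rt_regular$statistic, 0)
  expect_identical(rep$rt_regular$p_value, 1)
  ## no catch trials at all: the catch blocks degrade gracefully
  expect_identical(rep$rt_catch$test, "insufficient")
})
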