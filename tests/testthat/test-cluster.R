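test_that("the pointwise paired t matches a textbook oracle", {
  set.seed(10)
  A <- matrix(rnorm(8 * 20), 8, 20) + 0.5
  B <- matrix(rnorm(8 * 20), 8, 20)
  tr <- pointwise_paired_stat(A, B)
  oracle <- vapply(1:20, function(j)
    unname(t.test(A[, j], B[, j], paired = TRUE)$statistic), numeric(1))
  expect_equal(tr, oracle, tolerance = 1e-12)
  expect_identical(suppressWarnings(pointwise_paired_stat(A, A)),
                   rep(0, 20))
  expect_warning(pointwise_paired_stat(matrix(1, 5, 3), matrix(0, 5, 3)),
                 "zero variance")
})

test_that("the 2x2 repeated-measures F matches an aov oracle", {
  set.seed(11)
  n <- 12
  cells <- replicate(4, matrix(rnorm(n * 6), n, 6), simplify = FALSE)
  ## inject a pure factor-1 main effect
  cells[[1]] <- cells[[1]] + 1; cells[[2]] <- cells[[2]] + 1
  an <- pointwise_rm_anova(cells[[1]], cells[[2]], cells[[3]], cells[[4]])
  j <- 3
  d <- data.frame(
    y = c(cells[[1]][, j], cells[[2]][, j], cells[[3]][, j],
          cells[[4]][, j]),
    f1 = factor(rep(c("a", "a", "b", "b"), each = n)),
    f2 = factor(rep(c("x", "y", "x", "y"), each = n)),
    id = factor(rep(seq_len(n), 4)))
  fit <- summary(aov(y ~ f1 * f2 + Error(id / (f1 * f2)), data = d))
  f_oracle <- c(fit[["Error: id:f1"]][[1]]["f1", "F value"],
                fit[["Error: id:f2"]][[1]]["f2", "F value"],
                fit[["Error: id:f1:f2"]][[1]]["f1:f2", "F value"])
  expect_equal(c(an$F$factor1[j], an$F$factor2[j], an$F$interaction[j]),
               unname(f_oracle), tolerance = 1e-8)
  ## orthogonal design: a pure main effect leaves the interaction flat
  expect_lt(mean(an$F$interaction), mean(an$F$factor1) / 10)
})

test_that("cluster formation finds maximal same-sign runs", {
  expect_equal(nrow(form_clusters(rep(0.5, 50), 2, "two-sided")), 0)
  tr <- rep(0, 30); tr[11:20] <- 3
  cl <- form_clusters(tr, 2, "two-sided")
  expect_equal(nrow(cl), 1)
  expect_equal(cl$mass, 30)
  expect_equal(c(cl$start_idx, cl$end_idx), c(11, 20))
  ## an interrupting subthreshold sample splits the run
  tr[15] <- 1
  cl2 <- form_clusters(tr, 2, "two-sided")
  expect_equal(nrow(cl2), 2)
  ## brute-force run-length oracle on random traces, both signs
  set.seed(12)
  for (i in 1:10) {
    x <- rnorm(100, sd = 2)
    cl <- form_clusters(x, 2, "two-sided")
    lab <- ifelse(x > 2, 1L, ifelse(x < -2, -1L, 0L))
    runs <- rle(lab)
    expect_equal(nrow(cl), sum(runs$values != 0))
    expect_equal(sum(cl$mass), sum(x[lab != 0]))
  }
  ## one-sided forms ignore the other sign
  expect_equal(nrow(form_clusters(c(-3, -3, 3), 2, "one-sided-neg")), 1)
})

test_that("the permutation test is deterministic and its p-values bounded", {
  set.seed(13)
  D <- matrix(rnorm(15 * 60), 15, 60)
  D[, 20:30] <- D[, 20:30] + 1.2
  r1 <- permutation_cluster_test(D, n_permutations = 500, seed = 99)
  r2 <- permutation_cluster_test(D, n_permutations = 500, seed = 99)
  expect_identical(r1$clusters, r2$clusters)
  expect_true(all(r1$clusters$p_value >= 1 / 500))
  expect_true(all(r1$clusters$p_value <= 1))
  big <- which(r1$clusters$start_idx <= 30 & r1$clusters$end_idx >= 20)
  expect_true(any(r1$clusters$significant[big]))
  expect_warning(permutation_cluster_test(D, n_permutations = 50,
                                          seed = 1), "100 permutations")
  ## the report text carries the boundary caveat
  expect_match(r1$caveat, "cautiously")
  expect_output(print(r1), "cautiously")
})

test_that("one-sided tails compare signed mass in the predicted direction", {
  set.seed(14)
  D <- matrix(rnorm(15 * 60), 15, 60)
  D[, 10:20] <- D[, 10:20] - 1.5          # negative-going effect
  neg <- permutation_cluster_test(D, n_permutations = 500, seed = 5,
                                  tail = "one-sided-neg")
  expect_true(any(neg$clusters$significant))
  expect_true(all(neg$clusters$sign == -1))
  ## the same data tested in the opposite direction finds nothing
  pos <- permutation_cluster_test(D, n_permutations = 500, seed = 5,
                                  tail = "one-sided-pos")
  expect_false(any(pos$clusters$significant))
  ## one-sided threshold is the less extreme critical value
  expect_lt(neg$threshold, permutation_cluster_test(
    D, n_permutations = 100, seed = 1)$threshold)
})

test_that("F-statistic clustering squares the t machinery", {
  set.seed(15)
  D <- matrix(rnorm(12 * 40), 12, 40)
  D[, 5:15] <- D[, 5:15] + 1.3
  rF <- permutation_cluster_test(D, n_permutations = 400, seed = 3,
                                 stat = "F")
  rt_ <- permutation_cluster_test(D, n_permutations = 400, seed = 3)
  expect_equal(rF$stat_trace, rt_$stat_trace^2, tolerance = 1e-12)
  expect_equal(rF$threshold, qf(0.95, 1, 11))
  expect_true(all(rF$clusters$sign == 1))
  expect_true(any(rF$clusters$significant))
})

test_that("windowed Cohen's d follows its definition and recovers truth", {
  A <- matrix(c(1, 2, 3), 3, 4)
  B <- matrix(0, 3, 4)
  expect_equal(cohens_d_window(A, B, idx = 1:4), 2.0)
  expect_warning(d0 <- cohens_d_window(A, A, idx = 1:4), "undefined")
  expect_true(is.infinite(d0) || is.nan(d0))
  ## recovery of a standardized subject-level shift of 0.6 at n = 30:
  ## subject window means ~ N(0.6, 1), plus within-window noise
  set.seed(16)
  ds <- replicate(300, {
    D <- matrix(rnorm(30, 0.6, 1), 30, 10) + matrix(rnorm(300, 0, 0.1),
                                                    30, 10)
    cohens_d_window(D, window = NULL, idx = 1:10)
  })
  expect_equal(mean(ds), 0.6, tolerance = 0.15)
})

test_that("permutation p-values are Monte-Carlo consistent in n_perm", {
  set.seed(17)
  D <- matrix(rnorm(15 * 60), 15, 60)
  D[, 25:40] <- D[, 25:40] + 0.55
  p1 <- permutation_cluster_test(D, n_permutations = 1000, seed = 1)
  p2 <- permutation_cluster_test(D, n_permutations = 4000, seed = 2)
  m1 <- p1$clusters[which.max(abs(p1$clusters$mass)), "p_value"]
  m2 <- p2$clusters[which.max(abs(p2$clusters$mass)), "p_value"]
  ## O(1/sqrt(n_perm)) agreement between the two estimates
  se <- sqrt(m1 * (1 - m1) / 1000) + sqrt(m2 * (1 - m2) / 4000)
  expect_lt(abs(m1 - m2), 4 * se + 1e-9)
})
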