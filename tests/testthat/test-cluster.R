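times50 <- seq(0, 98, by = 2)

test_that("pointwise paired t matches the textbook computation", {
  set.seed(3)
  n <- 10
  a <- matrix(rnorm(n * 50), n); colnames(a) <- times50
  b <- matrix(rnorm(n * 50), n); colnames(b) <- times50

  # identical inputs: t = 0 everywhere
  expect_true(all(pointwise_paired_t(a, a)$t == 0))

  # constant offset with zero variance: finite sentinel, with warning
  expect_warning(ts <- pointwise_paired_t(a + 1, a), "sentinel")
  expect_true(all(is.finite(ts$t)))
  expect_true(all(ts$t > 1e5))

  # random data: per-timepoint agreement with stats::t.test
  got <- pointwise_paired_t(a, b)
  want <- vapply(1:50, function(j) {
    unname(t.test(a[, j], b[, j], paired = TRUE)$statistic)
  }, numeric(1))
  expect_equal(got$t, want, tolerance = 1e-12)
  expect_equal(unique(got$df), n - 1)
  expect_error(pointwise_paired_t(a[1:2, ], b[1:2, ]), "3 participants")
})

test_that("constant-zero differences produce no clusters", {
  d <- matrix(0, 8, 50); colnames(d) <- times50
  ct <- cluster_permutation_test(d, seed = 1)
  expect_equal(nrow(ct$clusters), 0)
  expect_length(ct$clusters$p, 0)
})

test_that("cluster geometry: maximal, non-overlapping, ordered runs", {
  set.seed(9)
  d <- matrix(rnorm(12 * 50, 0, 0.5), 12)
  d[, 10:18] <- d[, 10:18] + 2   # positive cluster
  d[, 35:40] <- d[, 35:40] - 2   # negative cluster
  colnames(d) <- times50
  ct <- cluster_permutation_test(d, seed = 4, n_permutations = 500)
  cl <- tidy(ct)
  expect_true(all(diff(cl$start_ms) > 0))
  expect_true(all(cl$end_ms >= cl$start_ms))
  # non-overlap
  expect_true(all(cl$start_ms[-1] > cl$end_ms[-nrow(cl)]))
  expect_true(any(cl$sign == 1 & cl$start_ms <= 20 & cl$end_ms >= 30))
  expect_true(any(cl$sign == -1))
  # p-values within the Monte-Carlo bounds
  expect_true(all(cl$p >= 1 / (glance(ct)$n_permutations + 1)))
  expect_true(all(cl$p <= 1))
  # masses have the sign of their cluster
  expect_true(all(sign(cl$mass) == cl$sign))
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration (n = 6)", {
  set.seed(11)
  d <- matrix(rnorm(6 * 50, 0, 1), 6)
  d[, 15:25] <- d[, 15:25] + 1.3
  colnames(d) <- times50
  ex <- cluster_permutation_test(d, method = "exhaustive")
  expect_equal(glance(ex)$n_permutations, 64)
  nperm <- 2000
  mc <- cluster_permutation_test(d, method = "montecarlo", seed = 2,
                                 n_permutations = nperm)
  expect_equal(nrow(tidy(ex)), nrow(tidy(mc)))
  for (i in seq_len(nrow(tidy(ex)))) {
    p_ex <- tidy(ex)$p[i]
    se <- sqrt(p_ex * (1 - p_ex) / nperm)
    expect_lt(abs(tidy(mc)$p[i] - p_ex), 2 * se + 1 / (nperm + 1))
  }
})

test_that("auto method switches to exhaustive enumeration when cheap", {
  set.seed(12)
  d <- matrix(rnorm(6 * 50), 6) + 1
  colnames(d) <- times50
  ct <- cluster_permutation_test(d, n_permutations = 2000, seed = 1)
  expect_equal(glance(ct)$method, "exhaustive")
  ct2 <- cluster_permutation_test(rbind(d, d), n_permutations = 500,
                                  seed = 1)
  expect_equal(glance(ct2)$method, "montecarlo")
})

test_that("permutation p-values respect two-sided symmetry and scaling", {
  set.seed(13)
  d <- matrix(rnorm(10 * 50, 0, 1), 10)
  d[, 20:30] <- d[, 20:30] + 1
  colnames(d) <- times50
  p1 <- cluster_permutation_test(d, seed = 5, n_permutations = 400)
  p2 <- cluster_permutation_test(-d, seed = 5, n_permutations = 400)
  expect_equal(tidy(p1)$p, tidy(p2)$p)
  expect_equal(tidy(p1)$mass, -tidy(p2)$mass)
  # scaling all difference waves by c > 1 never increases any p
  p3 <- cluster_permutation_test(3 * d, seed = 5, n_permutations = 400)
  expect_true(all(tidy(p3)$p <= tidy(p1)$p))
})

test_that("cluster-window mean amplitudes obey analytic identities", {
  times <- seq(-250, 1000, by = 2)
  mk <- function(v) diffs_from_matrix(matrix(v, 1, length(times),
                                             byrow = TRUE), times)
  # constant difference
  expect_equal(extract_cluster_mean_amplitude(
    mk(rep(2, length(times))), c(400, 1000))$mean_amplitude, 2)
  # antisymmetric about the window midpoint (700)
  expect_equal(extract_cluster_mean_amplitude(
    mk(times - 700), c(400, 1000))$mean_amplitude, 0, tolerance = 1e-9)
  # linear ramp 0 -> 1 across the window
  ramp <- pmin(pmax((times - 400) / 600, 0), 1)
  expect_equal(extract_cluster_mean_amplitude(
    mk(ramp), c(400, 1000))$mean_amplitude, 0.5, tolerance = 2e-3)
})

test_that("amplitude ANOVA separates condition and group effects", {
  cells <- tidyr::expand_grid(
    participant = sprintf("p%02d", 1:16),
    task = c("A", "B", "C"))
  cells$group <- ifelse(as.integer(substr(cells$participant, 2, 3)) <= 8,
                        "G1", "G2")
  # all cells equal -> all F = 0
  cells$mean_amplitude <- 1
  a0 <- amplitude_anova(cells)
  expect_true(all(a0$statistic == 0))
  # one condition shifted by +5 uV, zero noise
  cells$mean_amplitude <- ifelse(cells$task == "B", 6, 1)
  a1 <- amplitude_anova(cells)
  fC <- a1$statistic[a1$effect == "Condition"]
  fG <- a1$statistic[a1$effect == "Group"]
  expect_gt(fC, fG)
  expect_equal(fG, 0)
})

test_that("amplitude ANOVA matches hand-computed sums of squares", {
  set.seed(17)
  cells <- tidyr::expand_grid(participant = sprintf("p%02d", 1:12),
                              task = c("A", "B"))
  cells$group <- ifelse(as.integer(substr(cells$participant, 2, 3)) <= 6,
                        "G1", "G2")
  cells$mean_amplitude <- rnorm(nrow(cells))
  got <- amplitude_anova(cells)

  # balanced two-way ANOVA from cell means
  y <- cells$mean_amplitude
  gm <- mean(y)
  mA <- tapply(y, cells$task, mean)
  mB <- tapply(y, cells$group, mean)
  mAB <- tapply(y, paste(cells$task, cells$group), mean)
  n_per <- 6
  ss_A <- 2 * n_per * sum((mA - gm)^2)
  ss_B <- 2 * n_per * sum((mB - gm)^2)
  ss_AB <- n_per * sum((mAB - gm)^2) - ss_A - ss_B
  pred <- mAB[paste(cells$task, cells$group)]
  ss_res <- sum((y - pred)^2)
  df_res <- nrow(cells) - 4
  expect_equal(got$statistic[got$effect == "Condition"],
               (ss_A / 1) / (ss_res / df_res), tolerance = 1e-10)
  expect_equal(got$statistic[got$effect == "Group"],
               (ss_B / 1) / (ss_res / df_res), tolerance = 1e-10)
  expect_equal(got$statistic[got$effect == "Condition x Group"],
               (ss_AB / 1) / (ss_res / df_res), tolerance = 1e-10)
})
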