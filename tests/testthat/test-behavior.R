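make_cells <- function(n_per_group = 6, tasks = c("A", "B"),
                       fill = function(g, tk, st) 0.8) {
  grid <- tidyr::expand_grid(
    participant = sprintf("p%02d", seq_len(2 * n_per_group)),
    task = tasks, sequence_type = c("intact", "disrupted"))
  grid$group <- ifelse(as.integer(substr(grid$participant, 2, 3)) <=
                         n_per_group, "DCD", "TD")
  grid$prop_correct <- mapply(fill, grid$group, grid$task,
                              grid$sequence_type)
  grid
}

test_that("accuracy table counts proportions and applies exclusions", {
  bh <- tibble::tibble(
    participant = rep(c("a", "b"), each = 40),
    group = rep(c("DCD", "TD"), each = 40),
    task = "Spatial",
    trial = rep(1:40, 2),
    sequence_type = rep(rep(c("intact", "disrupted"), each = 20), 2),
    correct = TRUE)
  # 15 of 20 correct -> 0.75
  bh$correct[bh$participant == "a" &
               bh$sequence_type == "disrupted"][1:5] <- FALSE
  acc <- accuracy_table(bh)
  expect_equal(acc$prop_correct[acc$participant == "a" &
                                  acc$sequence_type == "disrupted"], 0.75)
  expect_true(all(acc$prop_correct[acc$participant == "b"] == 1))
  expect_equal(unique(acc$n), 20L)

  # participant with 9 responses in one condition is excluded
  bh9 <- bh[!(bh$participant == "a" & bh$sequence_type == "intact" &
                bh$trial > 9), ]
  acc9 <- accuracy_table(bh9)
  expect_false("a" %in% acc9$participant)
  expect_equal(nrow(exclusion_report(acc9)), 1)

  # permutation invariance to trial order
  accr <- accuracy_table(bh[sample(nrow(bh)), ])
  expect_equal(dplyr::arrange(accr, participant, sequence_type),
               dplyr::arrange(acc, participant, sequence_type))
})

test_that("accuracy ANOVA detects constructed effects and nulls", {
  flat <- accuracy_anova(make_cells())
  expect_true(all(flat$statistic == 0))

  # group gap confined to disrupted cells drives the interaction
  cells <- make_cells(fill = function(g, tk, st) {
    0.9 - 0.2 * (g == "DCD" && st == "disrupted")
  })
  a <- accuracy_anova(cells)
  fx <- function(e) a$statistic[a$effect == e]
  expect_gt(fx("Group x SequenceType"), 0)
  expect_gt(fx("Group"), 0)
  expect_equal(fx("Condition"), 0)
  expect_true(all(c("SequenceType", "Condition", "Group",
                    "Group x Condition") %in% a$effect))
  expect_true(all(a$ges >= 0 & a$ges <= 1))
})

test_that("mixed ANOVA F-values match a hand split-plot decomposition", {
  set.seed(31)
  n <- 5 # per group
  cells <- make_cells(n_per_group = n,
                      fill = function(g, tk, st) runif(1, 0.5, 1))
  got <- accuracy_anova(cells)

  y <- cells$prop_correct
  A <- factor(cells$sequence_type) # within
  B <- factor(cells$task)          # within
  G <- factor(cells$group)         # between
  S <- factor(cells$participant)
  gm <- mean(y)
  a <- 2; b <- 2; g <- 2
  m_s <- tapply(y, S, mean)
  m_g <- tapply(y, G, mean)
  grp_of <- tapply(as.character(G), S, unique)
  # between stratum
  ss_G <- a * b * n * sum((m_g - gm)^2)
  ss_S <- a * b * sum((m_s - m_g[grp_of])^2)
  f_G <- (ss_G / (g - 1)) / (ss_S / (g * (n - 1)))
  expect_equal(got$statistic[got$effect == "Group"], unname(f_G),
               tolerance = 1e-8)

  # within stratum for the 2-level factor A: subject difference scores
  d_s <- tapply(y[A == "disrupted"], S[A == "disrupted"], mean) -
    tapply(y[A == "intact"], S[A == "intact"], mean)
  d_g <- tapply(d_s, grp_of[names(d_s)], mean)
  d_gm <- mean(d_s)
  ss_A <- b * g * n * d_gm^2 / 2
  ss_AG <- b * n * sum((d_g - d_gm)^2) / 2
  ss_AS <- b * sum((d_s - d_g[grp_of[names(d_s)]])^2) / 2
  df_AS <- g * (n - 1)
  expect_equal(got$statistic[got$effect == "SequenceType"],
               unname((ss_A / 1) / (ss_AS / df_AS)), tolerance = 1e-8)
  expect_equal(got$statistic[got$effect == "Group x SequenceType"],
               unname((ss_AG / 1) / (ss_AS / df_AS)), tolerance = 1e-8)
})

test_that("post-hoc group tests reproduce hand-computed t and D", {
  # hand-listed 3-vs-3 comparison
  av <- c(0.9, 0.8, 0.85); bv <- c(0.7, 0.75, 0.65)
  cells <- tibble::tibble(
    participant = sprintf("p%d", 1:6),
    group = rep(c("A", "B"), each = 3),
    task = "Spatial", sequence_type = "disrupted",
    prop_correct = c(av, bv))
  res <- posthoc_group_tests(cells, alpha = 0.01)
  sp <- sqrt((2 * var(av) + 2 * var(bv)) / 4)
  t_hand <- (mean(av) - mean(bv)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$cohens_d, (mean(av) - mean(bv)) / sp,
               tolerance = 1e-10)
  expect_equal(res$significant, res$p.value < 0.01)

  # identical groups: t = 0, D = 0, not significant
  cells0 <- cells
  cells0$prop_correct <- rep(c(0.8, 0.9, 0.7), 2)
  res0 <- posthoc_group_tests(cells0)
  expect_equal(res0$t, 0)
  expect_equal(res0$cohens_d, 0)
  expect_false(res0$significant)

  # zero variance: sentinel with warning
  cellsz <- cells
  cellsz$prop_correct <- rep(c(1, 0.5), each = 3)
  expect_warning(resz <- posthoc_group_tests(cellsz), "sentinel")
  expect_true(is.finite(resz$t))
  expect_true(resz$significant)
})

test_that("separated groups are detected in nearly every simulation", {
  set.seed(33)
  hits <- 0
  for (i in 1:40) {
    cells <- tibble::tibble(
      participant = sprintf("p%02d", 1:40),
      group = rep(c("A", "B"), each = 20),
      task = "Visual", sequence_type = "disrupted",
      prop_correct = c(rnorm(20, 0.9, 0.05), rnorm(20, 0.7, 0.05)))
    r <- posthoc_group_tests(cells, alpha = 0.01)
    if (r$significant && r$cohens_d > 2.5) hits <- hits + 1
  }
  expect_gte(hits, 39)
})

test_that("learning slopes are exact on log-linear input and invariant", {
  # constant RT: slope 0
  cfg0 <- clean_config(tasks = "Visuomotor",
                       rt_slope_log = c(DCD = 0, TD = 0))
  sl0 <- suppressWarnings(learning_slopes(simulate_behavior(cfg0)))
  expect_true(all(abs(sl0$slope) < 1e-12))

  # scale invariance: RT * c leaves slopes unchanged
  cfg <- tiny_config(seed = 41, tasks = "Visuomotor")
  bh <- simulate_behavior(cfg)
  sl1 <- learning_slopes(bh)
  bh2 <- bh
  rtc <- paste0("rt_", 1:12)
  bh2[rtc] <- bh2[rtc] * 3.7
  sl2 <- learning_slopes(bh2)
  expect_equal(sl1$slope, sl2$slope, tolerance = 1e-10)
  expect_equal(glance(sl1)$t, glance(sl2)$t, tolerance = 1e-8)
  expect_equal(unique(sl1$n_points), 9)

  # nonpositive RTs are excluded with a message
  bh3 <- bh
  bh3$rt_2[1] <- -5
  expect_message(learning_slopes(bh3), "non-positive")
})

test_that("disruption RT analysis recovers the programmed cost", {
  cfg <- clean_config(tasks = "Visuomotor",
                      n_per_group = c(DCD = 6, TD = 6),
                      rt_slope_log = c(DCD = 0, TD = 0))
  bh <- simulate_behavior(cfg)
  res <- suppressWarnings(disruption_rt_test(bh))
  # zero noise: identical groups, pure sequence-type effect
  fx <- function(e) res$statistic[res$effect == e]
  expect_equal(fx("Group"), 0)
  expect_equal(fx("Group x SequenceType"), 0)
  expect_gt(fx("SequenceType"), 1e4)
  expect_true(all(res$ges >= 0 & res$ges <= 1))
  ft <- first_response_test(res)
  expect_true(all(c("t", "df", "p.value") %in% names(ft)))

  # the mean disrupted - intact difference equals the programmed cost
  long <- sptlearn:::visuomotor_long(bh)
  at <- dplyr::filter(long,
                      (sequence_type == "disrupted" &
                         position == disruption_position) |
                        (sequence_type == "intact" & position %in% 10:11))
  mm <- tapply(at$rt, at$sequence_type, mean)
  expect_equal(unname(mm["disrupted"] - mm["intact"]),
               cfg$rt_disruption_cost, tolerance = 1e-9)
})

test_that("null RT data keep the sequence-type effect near nominal size", {
  set.seed(51)
  hits <- 0
  nsim <- 60
  for (i in 1:nsim) {
    cfg <- tiny_config(seed = 6000 + i, tasks = "Visuomotor",
                       n_per_group = c(DCD = 8, TD = 8),
                       trials_per_task = 24, rt_disruption_cost = 0)
    res <- disruption_rt_test(simulate_behavior(cfg))
    p <- res$p.value[res$effect == "SequenceType"]
    if (p < 0.05) hits <- hits + 1
  }
  # binomial(60, .05): central band
  expect_gte(hits, 0)
  expect_lte(hits, 9)
})
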