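#' Pointwise paired t-statistics between two sets of waveforms
#'
#' Computes the paired t-statistic at every timepoint on the per-participant
#' A - B differences. If `erps_b` is omitted, `erps_a` is taken to be the
#' difference waveforms themselves (one-sample t against zero — the same
#' statistic). Where the across-participant variance is exactly zero the t
#' is guarded to a large finite sentinel (sign-matched, with a warning)
#' instead of +/-Inf.
#'
#' @param erps_a waveforms: a long tibble with columns `participant`,
#'   `time`, `amplitude` (e.g. [diff_waves()] output) or a
#'   participants-by-time matrix.
#' @param erps_b optional matched waveforms (same participants and time
#'   axis).
#' @return tibble with columns `time` (ms; sample index when a bare matrix
#'   is given), `t`, and `df`.
#' @export
pointwise_paired_t <- function(erps_a, erps_b = NULL) {
  da <- as_waveform_matrix(erps_a)
  d <- da$m
  if (!is.null(erps_b)) {
    db <- as_waveform_matrix(erps_b)
    if (!identical(dim(db$m), dim(d))) {
      abort("A and B must have the same participants and time axis")
    }
    if (!is.null(rownames(d)) && !is.null(rownames(db$m))) {
      db$m <- db$m[rownames(d), , drop = FALSE]
    }
    d <- d - db$m
  }
  n <- nrow(d)
  if (n < 3) abort("paired t needs at least 3 participants")
  tibble(time = da$times, t = guarded_t(d), df = n - 1)
}

as_waveform_matrix <- function(x) {
  if (is.matrix(x)) {
    return(list(m = x, times = as.numeric(colnames(x) %||%
                                            seq_len(ncol(x)))))
  }
  waveform_matrix(x)
}

# column-wise one-sample t with zero-variance guard
guarded_t <- function(d) {
  n <- nrow(d)
  m <- unname(colMeans(d))
  v <- (unname(colSums(d^2)) - n * m^2) / (n - 1)
  v[v < 0] <- 0
  se <- sqrt(v / n)
  t <- ifelse(se > 0, m / se,
              ifelse(abs(m) > 0, sign(m) * T_SENTINEL, 0))
  if (any(se == 0 & abs(m) > 0)) {
    warn("zero variance at some timepoints; t guarded to a finite sentinel")
  }
  t
}

#' Cluster-based temporal permutation test on difference waveforms
#'
#' Nonparametric paired test with cluster correction for multiple
#' comparisons over time at a single electrode. Clusters are maximal runs
#' of contiguous timepoints whose |t| exceeds the two-sided t-criterion at
#' `cluster_alpha` (df = n - 1), formed separately for positive and
#' negative exceedances; the cluster statistic is the mass (sum of t). The
#' null distribution is the maximum |cluster mass| under random
#' per-participant sign flips of the difference waves; when `2^n` does not
#' exceed `n_permutations` the full set of sign patterns is enumerated
#' instead (method `"exhaustive"`). Monte-Carlo p-values use the +1
#' correction, `p = (1 + #{null >= observed}) / (1 + n_permutations)`.
#'
#' @param diffs difference waveforms: long tibble ([diff_waves()]) for a
#'   single task, or a participants-by-time matrix with time (ms) as
#'   column names.
#' @param cluster_alpha two-sided alpha of the cluster-forming t-threshold.
#' @param n_permutations number of random sign-flip permutations.
#' @param seed integer seed for the permutation draw (mandatory for
#'   reproducible Monte-Carlo p-values).
#' @param method `"auto"` (exhaustive when feasible), `"montecarlo"`, or
#'   `"exhaustive"`.
#' @return an object of class `spt_cluster_test`: list with `t_series`
#'   (tibble `time`, `t`), `clusters` (tibble `start_ms`, `end_ms`, `sign`,
#'   `mass`, `p`), and `settings`. `tidy()` returns the cluster table,
#'   `glance()` the settings.
#' @examples
#' set.seed(1)
#' d <- matrix(rnorm(8 * 50), 8, 50)
#' d[, 20:30] <- d[, 20:30] + 1.2
#' colnames(d) <- seq(0, 98, by = 2)
#' ct <- cluster_permutation_test(d, seed = 42, n_permutations = 500)
#' tidy(ct)
#' @export
cluster_permutation_test <- function(diffs, cluster_alpha = 0.05,
                                     n_permutations = 2000, seed = NULL,
                                     method = c("auto", "montecarlo",
                                                "exhaustive")) {
  method <- match.arg(method)
  wm <- as_waveform_matrix(diffs)
  d <- wm$m
  n <- nrow(d)
  if (n < 2) abort("need at least 2 participants")
  if (n < 5) inform("fewer than 5 participants: permutation test is coarse")

  t_obs <- guarded_t(d)
  crit <- qt(1 - cluster_alpha / 2, df = n - 1)
  obs <- find_clusters(t_obs, crit, wm$times)

  if (method == "auto") {
    method <- if (n <= 30 && 2^n <= n_permutations) "exhaustive"
              else "montecarlo"
  }
  if (nrow(obs)) {
    if (method == "exhaustive") {
      if (n > 30) abort("exhaustive enumeration infeasible for n > 30")
      signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      n_eff <- nrow(signs)
    } else {
      if (is.null(seed)) abort("`seed` is required for Monte-Carlo permutation")
      set.seed(as.integer(seed))
      signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                      n_permutations, n)
      n_eff <- n_permutations
    }
    null_max <- perm_max_mass(d, signs, crit)
    obs$p <- if (method == "exhaustive") {
      vapply(abs(obs$mass),
             function(mm) mean(null_max >= mm - 1e-12), numeric(1))
    } else {
      vapply(abs(obs$mass),
             function(mm) (1 + sum(null_max >= mm - 1e-12)) / (1 + n_eff),
             numeric(1))
    }
  } else {
    n_eff <- 0L
    obs$p <- numeric(0)
  }

  structure(list(
    t_series = tibble(time = wm$times, t = t_obs),
    clusters = obs,
    settings = list(cluster_alpha = cluster_alpha, t_crit = crit,
                    n_participants = n, n_permutations = n_eff,
                    method = method, seed = seed, tail = "two-sided",
                    note = paste("cluster-forming alpha and permutation",
                                 "count are analysis defaults, not taken",
                                 "from any published analysis"))
  ), class = "spt_cluster_test")
}

# maximal runs of suprathreshold |t|, split by sign; ordered by start time
find_clusters <- function(t, crit, times) {
  code <- (t > crit) - (t < -crit)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  tibble(
    start_ms = times[starts[keep]],
    end_ms = times[ends[keep]],
    sign = r$values[keep],
    mass = vapply(which(keep), function(i) {
      sum(t[starts[i]:ends[i]])
    }, numeric(1))
  )
}

# maximum |cluster mass| for each row of a sign-flip matrix; exploits that
# the per-timepoint sum of squares is invariant under sign flips
perm_max_mass <- function(d, signs, crit) {
  n <- nrow(d)
  ss <- colSums(d^2)
  means <- (signs %*% d) / n
  vapply(seq_len(nrow(signs)), function(i) {
    m <- means[i, ]
    v <- (ss - n * m^2) / (n - 1)
    v[v < 0] <- 0
    se <- sqrt(v / n)
    t <- ifelse(se > 0, m / se,
                ifelse(abs(m) > 0, sign(m) * T_SENTINEL, 0))
    code <- (t > crit) - (t < -crit)
    if (!any(code != 0)) return(0)
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values != 0)
    max(abs(vapply(keep, function(j) sum(t[starts[j]:ends[j]]),
                   numeric(1))))
  }, numeric(1))
}

#' Mean amplitude of the difference waveform over a window
#'
#' Extracts, per participant, the average disrupted-minus-intact amplitude
#' over a time window — by default the 400–1000 ms P3 window into which the
#' significant clusters fall.
#'
#' @param diffs difference waveforms ([diff_waves()] output; may span
#'   several tasks).
#' @param window_ms averaging window in ms (closed, nearest-sample).
#' @return tibble with `participant`, `group`, `task`, `window_lo`,
#'   `window_hi`, `mean_amplitude` (uV).
#' @export
extract_cluster_mean_amplitude <- function(diffs, window_ms = c(400, 1000)) {
  require_cols(diffs, c("participant", "task", "time", "amplitude"))
  times <- sort(unique(diffs$time))
  idx <- window_indices(times, window_ms)
  sel <- times[idx]
  diffs |>
    filter(.data$time >= min(sel) - 1e-9, .data$time <= max(sel) + 1e-9) |>
    group_by(dplyr::across(dplyr::any_of(c("participant", "group",
                                           "task")))) |>
    summarise(mean_amplitude = mean(.data$amplitude), .groups = "drop") |>
    mutate(window_lo = window_ms[1], window_hi = window_ms[2])
}

#' Condition-by-group ANOVA on cluster mean amplitudes
#'
#' Between-cells ANOVA (Type III sums of squares, sum-to-zero contrasts) of
#' the per-participant difference-score amplitudes with factors Condition
#' (task) and Group.
#'
#' @param cells output of [extract_cluster_mean_amplitude()] (several
#'   tasks).
#' @return tibble with `effect`, `df1`, `df2`, `statistic` (F), `p.value`.
#' @export
amplitude_anova <- function(cells) {
  require_cols(cells, c("group", "task", "mean_amplitude"))
  grid <- tidyr::expand_grid(group = unique(cells$group),
                             task = unique(cells$task))
  have <- distinct(cells[, c("group", "task")])
  empty <- dplyr::anti_join(grid, have, by = c("group", "task"))
  if (nrow(empty)) {
    warn(paste("empty design cell(s):",
               paste(paste(empty$group, empty$task), collapse = ", ")))
  }
  if (length(unique(cells$group)) < 2 || length(unique(cells$task)) < 2) {
    abort("need at least 2 levels of both Condition and Group")
  }
  dat <- mutate(cells, group = factor(.data$group),
                condition = factor(.data$task))
  fit <- withr_contrasts(
    lm(mean_amplitude ~ condition * group, data = dat))
  aov3 <- tryCatch(car::Anova(fit, type = 3),
                   error = function(e) type3_by_hand(fit))
  rn <- rownames(aov3)
  keep <- !rn %in% c("(Intercept)", "Residuals")
  df_res <- aov3[rn == "Residuals", "Df"]
  out <- tibble(effect = sub("condition", "Condition",
                             sub("group", "Group", rn[keep])),
                df1 = aov3$Df[keep], df2 = df_res,
                ss = aov3$`Sum Sq`[keep],
                statistic = aov3$`F value`[keep],
                p.value = aov3$`Pr(>F)`[keep])
  # a vanishing effect sum of squares is a null effect even when the
  # residual variance is itself zero (degenerate constructed data)
  zero <- out$ss < 1e-12
  out$statistic[zero] <- 0
  out$p.value[zero] <- 1
  out$effect <- gsub(":", " x ", out$effect, fixed = TRUE)
  select(out, -"ss")
}

# Type III sums of squares by direct column-drop projections; used when a
# zero residual (degenerate constructed data) trips the standard route.
type3_by_hand <- function(fit) {
  mm <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  asgn <- attr(mm, "assign")
  labels <- attr(stats::terms(fit), "term.labels")
  rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
  rss_full <- rss(mm)
  df_res <- nrow(mm) - ncol(mm)
  ms_res <- rss_full / df_res
  rows <- purrr::map(seq_along(labels), function(k) {
    keep <- asgn != k
    ss <- rss(mm[, keep, drop = FALSE]) - rss_full
    df <- sum(asgn == k)
    f <- if (ss < 1e-12) 0 else if (ms_res == 0) Inf else (ss / df) / ms_res
    data.frame(`Sum Sq` = ss, Df = df, `F value` = f,
               `Pr(>F)` = if (is.finite(f)) {
                 pf(f, df, df_res, lower.tail = FALSE)
               } else 0,
               check.names = FALSE, row.names = labels[k])
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(`Sum Sq` = rss_full, Df = df_res,
                        `F value` = NA, `Pr(>F)` = NA,
                        check.names = FALSE, row.names = "Residuals"))
}

# fit with sum-to-zero contrasts (required for sensible Type III SS)
withr_contrasts <- function(expr) {
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  eval.parent(substitute(expr))
}
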