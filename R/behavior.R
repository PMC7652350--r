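#' Proportion-correct accuracy per participant, task and sequence type
#'
#' Applies the minimum-response exclusion rule (a participant is dropped
#' from a task when either sequence type has fewer than `min_responses`
#' recorded responses) and tabulates the proportion of correct yes/no
#' sequence judgements per cell.
#'
#' @param trials behavioural trial table ([simulate_behavior()] schema or
#'   [read_behavior_tsv()]).
#' @param min_responses exclusion threshold per condition.
#' @return tibble with `participant`, `group`, `task`, `sequence_type`,
#'   `n` (responses) and `prop_correct`; exclusions are carried in the
#'   `exclusions` attribute ([exclusion_report()]).
#' @export
accuracy_table <- function(trials, min_responses = 10) {
  require_cols(trials, c("participant", "group", "task", "sequence_type",
                         "correct"), "behavior table")
  kept <- exclude_low_trial_participants(trials, min_trials = min_responses)
  out <- kept |>
    group_by(.data$participant, .data$group, .data$task,
             .data$sequence_type) |>
    summarise(n = dplyr::n(), prop_correct = mean(.data$correct),
              .groups = "drop")
  attr(out, "exclusions") <- exclusion_report(kept)
  out
}

#' Mixed ANOVA on accuracy: SequenceType x Condition x Group
#'
#' Repeated-measures ANOVA of the proportion-correct cells with sequence
#' type and condition (task) as within-participant factors and group as the
#' between-participant factor, using an `Error(participant)` stratum
#' structure. Generalized eta squared follows the observed-factor
#' convention (effect SS over effect SS plus all error SS).
#'
#' @param cells output of [accuracy_table()] (all tasks).
#' @return tibble (class `spt_anova`) with `effect`, `df1`, `df2`,
#'   `statistic` (F), `p.value`, `ges`.
#' @export
accuracy_anova <- function(cells) {
  require_cols(cells, c("participant", "group", "task", "sequence_type",
                        "prop_correct"))
  mixed_anova(cells, dv = "prop_correct",
              within = c("sequence_type", "task"), between = "group",
              labels = c(sequence_type = "SequenceType",
                         task = "Condition", group = "Group"))
}

#' Post-hoc between-group t-tests per condition and sequence type
#'
#' Two-sample t-tests (pooled-variance Student by default, matching the
#' conventional df = n1 + n2 - 2 reporting; Welch optional) comparing the
#' groups' proportion-correct scores separately for each condition x
#' sequence-type cell, with Cohen's D from the pooled SD and a
#' significance flag at `alpha` (default .01, guarding against Type I
#' error accumulation over the ten comparisons).
#'
#' @param cells output of [accuracy_table()].
#' @param alpha per-test significance level.
#' @param var_equal use the pooled-variance Student t (default) or Welch.
#' @return tibble with `task`, `sequence_type`, `t`, `df`, `p.value`,
#'   `cohens_d`, `significant`.
#' @export
posthoc_group_tests <- function(cells, alpha = 0.01, var_equal = TRUE) {
  require_cols(cells, c("participant", "group", "task", "sequence_type",
                        "prop_correct"))
  groups <- sort(unique(cells$group))
  if (length(groups) != 2) abort("exactly two groups are required")
  cells |>
    group_by(.data$task, .data$sequence_type) |>
    dplyr::group_modify(function(df, key) {
      a <- df$prop_correct[df$group == groups[1]]
      b <- df$prop_correct[df$group == groups[2]]
      if (length(a) < 2 || length(b) < 2) {
        abort("both groups need at least 2 participants per cell")
      }
      sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
        (length(a) + length(b) - 2)
      if (sp2 == 0) {
        warn("zero variance in a post-hoc cell; t guarded to sentinel")
        tt <- list(statistic = sign(mean(a) - mean(b)) * T_SENTINEL,
                   parameter = length(a) + length(b) - 2,
                   p.value = if (mean(a) == mean(b)) 1 else 0)
      } else {
        tt <- t.test(a, b, var.equal = var_equal)
      }
      d <- if (sp2 == 0) 0 else (mean(a) - mean(b)) / sqrt(sp2)
      tibble(t = unname(tt$statistic), df = unname(tt$parameter),
             p.value = tt$p.value, cohens_d = d,
             significant = tt$p.value < alpha)
    }) |>
    ungroup()
}

#' Log-RT learning slopes in the visuomotor task
#'
#' For every participant, takes the median correct-trial reaction time at
#' each of the first `n_responses` stimulus positions (intact and disrupted
#' trials pooled — positions 1..9 precede any disruption), fits ordinary
#' least squares of log(RT) on the response index, and compares the groups'
#' slopes with a two-sample t-test (Welch by default, as RT-slope spreads
#' need not be equal).
#'
#' @param trials behavioural trial table; only `task == "Visuomotor"` rows
#'   with `correct == TRUE` are used. Non-positive RTs are excluded with a
#'   message.
#' @param n_responses number of leading responses to fit (default 9).
#' @param var_equal pooled-variance t instead of Welch.
#' @return tibble (class `spt_slopes`) with `participant`, `group`,
#'   `slope`, `intercept_log`, `n_points`; `glance()` returns the group
#'   comparison (`t`, `df`, `p.value`, group means).
#' @export
learning_slopes <- function(trials, n_responses = 9, var_equal = FALSE) {
  rts <- visuomotor_long(trials)
  rts <- filter(rts, .data$position <= n_responses)
  fits <- rts |>
    group_by(.data$participant, .data$group, .data$position) |>
    summarise(med_rt = median(.data$rt), .groups = "drop_last") |>
    dplyr::group_modify(function(df, key) {
      k <- df$position
      y <- log(df$med_rt)
      b <- sum((k - mean(k)) * (y - mean(y))) / sum((k - mean(k))^2)
      tibble(slope = b, intercept_log = mean(y) - b * mean(k),
             n_points = nrow(df))
    }) |>
    ungroup()

  groups <- sort(unique(fits$group))
  test <- if (length(groups) == 2) {
    tt <- safe_two_sample_t(fits$slope, fits$group, var_equal = var_equal)
    tibble(t = unname(tt$statistic), df = unname(tt$parameter),
           p.value = tt$p.value,
           mean_slope_1 = mean(fits$slope[fits$group == groups[1]]),
           mean_slope_2 = mean(fits$slope[fits$group == groups[2]]),
           group_1 = groups[1], group_2 = groups[2])
  } else {
    tibble()
  }
  structure(fits, test = test,
            class = unique(c("spt_slopes", class(fits))))
}

# long view of visuomotor per-stimulus RTs for correct trials
visuomotor_long <- function(trials) {
  require_cols(trials, c("participant", "group", "task", "sequence_type",
                         "correct"), "behavior table")
  vm <- filter(trials, .data$task == "Visuomotor", .data$correct)
  rt_cols <- grep("^rt_\\d+$", names(vm), value = TRUE)
  if (!nrow(vm) || !length(rt_cols)) {
    abort("no visuomotor reaction-time data found")
  }
  long <- vm |>
    select(dplyr::all_of(c("participant", "group", "trial",
                           "sequence_type", "disruption_position",
                           rt_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(rt_cols), names_to = "position",
                        names_pattern = "rt_(\\d+)", values_to = "rt") |>
    mutate(position = as.integer(.data$position)) |>
    filter(!is.na(.data$rt))
  bad <- long$rt <= 0
  if (any(bad)) {
    inform(sprintf("excluded %d non-positive reaction time(s)", sum(bad)))
    long <- long[!bad, ]
  }
  long
}

#' Reaction-time slowing at the disrupting stimulus
#'
#' Compares, per participant, the median RT at the disrupting stimulus of
#' disrupted trials against the median RT at the same positions (10/11) of
#' intact trials, in a SequenceType (within) x Group (between) mixed ANOVA
#' with generalized eta squared. Also reports the between-group Welch
#' t-test on each participant's median very-first-response RT (overall
#' response-speed check).
#'
#' @param trials behavioural trial table.
#' @return tibble (class `spt_anova`) of ANOVA effects; the first-response
#'   test is attached as attribute `first_response` (see
#'   [first_response_test()]).
#' @export
disruption_rt_test <- function(trials) {
  long <- visuomotor_long(trials)
  matched <- long |>
    filter((.data$sequence_type == "disrupted" &
              .data$position == .data$disruption_position) |
             (.data$sequence_type == "intact" & .data$position %in%
                c(10L, 11L)))
  cells <- matched |>
    group_by(.data$participant, .data$group, .data$sequence_type) |>
    summarise(rt = median(.data$rt), .groups = "drop")
  miss <- cells |>
    count(.data$participant) |>
    filter(.data$n < 2)
  if (nrow(miss)) {
    warn(paste("participants without both matched cells dropped:",
               paste(miss$participant, collapse = ", ")))
    cells <- filter(cells, !.data$participant %in% miss$participant)
  }
  res <- mixed_anova(cells, dv = "rt", within = "sequence_type",
                     between = "group",
                     labels = c(sequence_type = "SequenceType",
                                group = "Group"))
  first <- long |>
    filter(.data$position == 1L) |>
    group_by(.data$participant, .data$group) |>
    summarise(rt = median(.data$rt), .groups = "drop")
  ft <- safe_two_sample_t(first$rt, first$group)
  attr(res, "first_response") <-
    tibble(t = unname(ft$statistic), df = unname(ft$parameter),
           p.value = ft$p.value)
  res
}

# two-sample t robust to zero-variance (constant) input: degenerate data
# yield a 0 or sentinel statistic with a warning instead of an error
safe_two_sample_t <- function(values, groups, var_equal = FALSE) {
  sp <- split(values, groups)
  if (length(sp) != 2) abort("exactly two groups are required")
  a <- sp[[1]]; b <- sp[[2]]
  if (var(a) + var(b) == 0) {
    warn("zero variance in both groups; t guarded to a sentinel")
    delta <- mean(a) - mean(b)
    list(statistic = if (delta == 0) 0 else sign(delta) * T_SENTINEL,
         parameter = length(a) + length(b) - 2,
         p.value = if (delta == 0) 1 else 0)
  } else {
    t.test(a, b, var.equal = var_equal)
  }
}

#' @rdname disruption_rt_test
#' @param x result of [disruption_rt_test()].
#' @export
first_response_test <- function(x) {
  attr(x, "first_response") %||% abort("no first-response test attached")
}

# Mixed ANOVA via aov() with an Error(participant) stratum; returns a tidy
# effect table with generalized eta squared (all error strata in the
# denominator, manipulated-factor convention).
mixed_anova <- function(data, dv, within, between, labels) {
  data <- mutate(data,
                 dplyr::across(dplyr::all_of(c("participant", within,
                                               between)), factor))
  rhs <- paste(c(between, within), collapse = " * ")
  err <- if (length(within)) {
    sprintf(" + Error(participant/(%s))", paste(within, collapse = " * "))
  } else ""
  form <- stats::as.formula(paste(dv, "~", rhs, err))
  fit <- aov(form, data = as.data.frame(data))
  smry <- summary(fit)

  rows <- list()
  err_ss <- 0
  for (stratum in smry) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    rn <- trimws(rownames(tab))
    resid <- rn == "Residuals"
    err_ss <- err_ss + sum(tab[resid, "Sum Sq"])
    for (i in which(!resid)) {
      rows[[length(rows) + 1]] <- tibble(
        effect = rn[i], ss = tab[i, "Sum Sq"], df1 = tab[i, "Df"],
        df2 = tab[resid, "Df"][1],
        statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"])
    }
  }
  out <- bind_rows(rows)
  zero <- out$ss < 1e-12
  out$statistic[zero] <- 0
  out$p.value[zero] <- 1
  out <- out |>
    mutate(ges = ifelse(.data$ss + err_ss > 0,
                        .data$ss / (.data$ss + err_ss), 0)) |>
    select(-"ss")
  for (nm in names(labels)) {
    out$effect <- gsub(nm, labels[[nm]], out$effect, fixed = TRUE)
  }
  out$effect <- gsub(":", " x ", out$effect, fixed = TRUE)
  structure(out, class = unique(c("spt_anova", class(out))))
}
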