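#' Percent-area latency of a waveform
#'
#' Returns the timepoint at which a stated fraction (default 50%) of the
#' rectified area under the waveform within a window has accumulated. For a
#' positive-polarity component, negative samples are zeroed before the
#' cumulative trapezoidal area is computed; the crossing time is linearly
#' interpolated between the bracketing samples.
#'
#' @param values numeric waveform (uV), or a data frame with `time` and
#'   `amplitude` columns.
#' @param times sample times in ms (ignored when `values` is a data frame).
#' @param window_ms measurement window in ms; default the full axis.
#' @param fraction area fraction in (0, 1); default 0.5.
#' @param polarity `"positive"` (negative samples zeroed) or `"negative"`
#'   (the waveform is inverted first).
#' @return the latency in ms (scalar).
#' @examples
#' t <- seq(0, 1000, by = 2)
#' rect <- as.numeric(t >= 500 & t <= 700)
#' fractional_area_latency(rect, t) # 600
#' @export
fractional_area_latency <- function(values, times = NULL,
                                    window_ms = NULL, fraction = 0.5,
                                    polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  if (is.data.frame(values)) {
    times <- values$time
    values <- values$amplitude
  }
  if (is.null(times)) abort("`times` is required")
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  if (is.null(window_ms)) window_ms <- range(times)
  idx <- window_indices(times, window_ms)
  tt <- unname(times[idx])
  v <- unname(values[idx])
  if (polarity == "negative") v <- -v
  v <- pmax(v, 0)
  cum <- cumtrapz1(tt, v)
  total <- cum[length(cum)]
  if (total <= 0) {
    abort("waveform has no area of the requested polarity in the window")
  }
  target <- fraction * total
  i <- which(cum >= target)[1]
  if (i == 1L) return(tt[1])
  seg <- cum[i] - cum[i - 1]
  if (seg <= 0) return(tt[i - 1])
  tt[i - 1] + (target - cum[i - 1]) / seg * (tt[i] - tt[i - 1])
}

#' Leave-one-out jackknife percent-area latencies
#'
#' For each group (and task) in a set of per-participant difference
#' waveforms, builds the N leave-one-out grand averages (each omitting one
#' participant), measures the percent-area latency of each, and reports the
#' replicates. The group summary latency is the mean of the replicates.
#'
#' @param diffs difference waveforms ([diff_waves()]), one task; must
#'   contain a `group` column.
#' @param window_ms measurement window in ms; typically the span of the
#'   significant clusters, falling back to the 400–1000 ms P3 window.
#' @param fraction area fraction (default 0.5).
#' @return an object of class `spt_jackknife`: a tibble with one row per
#'   replicate (`group`, `task`, `excluded_participant`, `latency_ms`) and
#'   attributes `window_ms`, `fraction`. `glance()` summarises each group
#'   (mean latency, SD of replicates, N).
#' @export
jackknife_latencies <- function(diffs, window_ms = c(400, 1000),
                                fraction = 0.5) {
  require_cols(diffs, c("participant", "group", "time", "amplitude"))
  task <- if ("task" %in% names(diffs)) unique(diffs$task) else "task"
  if (length(task) > 1) abort("jackknife_latencies expects a single task")

  out <- purrr::map(split(as_tibble(diffs), diffs$group), function(dg) {
    wm <- waveform_matrix(dg)
    n <- nrow(wm$m)
    if (n < 3) abort("jackknife needs at least 3 participants per group")
    tot <- colSums(wm$m)
    reps <- purrr::map(seq_len(n), function(i) {
      loo <- (tot - wm$m[i, ]) / (n - 1)
      lat <- tryCatch(
        fractional_area_latency(loo, wm$times, window_ms, fraction),
        error = function(e) NA_real_)
      tibble(excluded_participant = rownames(wm$m)[i], latency_ms = lat)
    }) |> bind_rows()
    if (anyNA(reps$latency_ms)) {
      abort(paste0(
        "zero-area jackknife replicate(s) in group ", dg$group[1],
        " (excluding: ",
        paste(reps$excluded_participant[is.na(reps$latency_ms)],
              collapse = ", "),
        "); latency test aborted"))
    }
    mutate(reps, group = dg$group[1], task = task, .before = 1)
  }) |> bind_rows()

  structure(out, window_ms = window_ms, fraction = fraction,
            class = unique(c("spt_jackknife", class(out))))
}

#' Jackknife-adjusted group test on percent-area latencies
#'
#' One-way ANOVA of the two groups' jackknife replicate latencies, with the
#' F-statistic rescaled by the jackknife adjustment
#' `F_adjusted = F / (N - 1)^2` to undo the artificial variance reduction
#' of leave-one-out scores; p is taken from an F distribution with
#' (1, n1 + n2 - 2) degrees of freedom on the adjusted statistic.
#'
#' `N` follows the per-group convention of the jackknife scoring method:
#' leave-one-out averaging within a group of n participants shrinks the
#' replicate variance by (n - 1)^2, so for equal group sizes `N = n`. For
#' unequal sizes the default `N` is the value whose `(N - 1)^2` equals the
#' exact pooled-variance correction
#' `(n1 + n2 - 2) / (1/(n1 - 1) + 1/(n2 - 1))` (reducing to `n` when
#' `n1 = n2`, and non-integer otherwise). The N actually used is recorded
#' in the output and can be overridden.
#'
#' @param replicates_a either an `spt_jackknife` object containing exactly
#'   two groups, or a numeric vector of group-A replicate latencies.
#' @param replicates_b numeric vector of group-B replicates (when
#'   `replicates_a` is a vector).
#' @param n_override optional N to use in the `(N - 1)^2` adjustment.
#' @param effect label for the tested effect.
#' @return a tibble (class `spt_jackknife_test`) with `effect`, `F_raw`,
#'   `N`, `F_adjusted`, `df1`, `df2`, `p.value`.
#' @export
adjusted_group_test <- function(replicates_a, replicates_b = NULL,
                                n_override = NULL, effect = "Group") {
  if (inherits(replicates_a, "spt_jackknife")) {
    gs <- split(replicates_a$latency_ms, replicates_a$group)
    if (length(gs) != 2) abort("need exactly two groups of replicates")
    a <- gs[[1]]; b <- gs[[2]]
  } else {
    a <- replicates_a; b <- replicates_b
  }
  if (length(a) < 3 || length(b) < 3) {
    abort("need at least 3 replicates per group")
  }
  x <- c(a, b)
  g <- rep(c("A", "B"), c(length(a), length(b)))
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - mean(x))^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  if (ssb == 0 && ssw == 0) {
    abort("degenerate data: zero between- and within-group variance")
  }
  n_tot <- length(x)
  df1 <- 1L
  df2 <- n_tot - 2L
  f_raw <- if (ssw == 0) Inf else (ssb / df1) / (ssw / df2)
  n_adj <- n_override %||%
    (1 + sqrt(df2 / (1 / (length(a) - 1) + 1 / (length(b) - 1))))
  f_adj <- f_raw / (n_adj - 1)^2
  structure(
    tibble(effect = effect, F_raw = f_raw, N = n_adj,
           F_adjusted = f_adj, df1 = df1, df2 = df2,
           p.value = pf(f_adj, df1, df2, lower.tail = FALSE)),
    class = c("spt_jackknife_test", class(tibble())))
}

#' Latency table for a set of conditions
#'
#' Assembles, per group and condition, the summary percent-area latency
#' (mean of jackknife replicates) and the SD of the replicates, together
#' with the adjusted group test per condition — the shape in which such
#' latency results are conventionally reported.
#'
#' @param jk_list named list of `spt_jackknife` objects, one per condition
#'   (the names are the condition labels).
#' @return tibble with `condition`, `group`, `latency_ms`, `sd_replicates`,
#'   `N`, and (joined per condition) `F_adjusted`, `p.value`.
#' @export
latency_table <- function(jk_list) {
  summaries <- purrr::imap(jk_list, function(jk, cond) {
    jk |>
      group_by(.data$group) |>
      summarise(sd_replicates = sd(.data$latency_ms),
                latency_ms = mean(.data$latency_ms),
                N = dplyr::n(), .groups = "drop") |>
      select("group", "latency_ms", "sd_replicates", "N") |>
      mutate(condition = cond, .before = 1)
  }) |> bind_rows()
  tests <- purrr::imap(jk_list, function(jk, cond) {
    tryCatch(
      mutate(adjusted_group_test(jk), condition = cond, .before = 1),
      error = function(e) tibble(condition = cond, F_adjusted = NA_real_,
                                 p.value = NA_real_))
  }) |> bind_rows()
  left_join(summaries,
            tests[, c("condition", "F_adjusted", "p.value")],
            by = "condition")
}

#' Mean group delay across conditions
#'
#' Average, over the requested conditions, of the group-1 minus group-2
#' latency difference — e.g. the mean DCD - TD P3 delay across the
#' conditions showing a reliable group effect.
#'
#' @param latencies tibble with columns `group`, `condition`, and a latency
#'   column (`latency_ms`).
#' @param conditions conditions to average over; default all present.
#' @param groups length-2 character: `c(minuend, subtrahend)`.
#' @return the mean delay in ms (scalar).
#' @examples
#' tab <- tibble::tribble(
#'   ~group, ~condition, ~latency_ms,
#'   "DCD", "Control", 791, "TD", "Control", 694,
#'   "DCD", "Visual",  856, "TD", "Visual",  774)
#' mean_group_delay(tab, groups = c("DCD", "TD"))
#' @export
mean_group_delay <- function(latencies, conditions = NULL,
                             groups = c("DCD", "TD")) {
  require_cols(latencies, c("group", "condition", "latency_ms"))
  if (is.null(conditions)) conditions <- unique(latencies$condition)
  per <- vapply(conditions, function(cc) {
    l1 <- latencies$latency_ms[latencies$condition == cc &
                                 latencies$group == groups[1]]
    l2 <- latencies$latency_ms[latencies$condition == cc &
                                 latencies$group == groups[2]]
    if (length(l1) != 1 || length(l2) != 1) {
      abort(sprintf("missing or duplicated latency cell in condition '%s'",
                    cc))
    }
    l1 - l2
  }, numeric(1))
  mean(per)
}

#' Measurement window from significant clusters
#'
#' The union span (min start to max end) of the significant clusters of one
#' or more cluster tests; falls back to the 400–1000 ms P3 window when no
#' cluster reaches significance.
#'
#' @param ... `spt_cluster_test` objects.
#' @param alpha significance level for including a cluster.
#' @param fallback window used when nothing is significant.
#' @return length-2 numeric window in ms.
#' @export
cluster_window <- function(..., alpha = 0.05, fallback = c(400, 1000)) {
  cl <- purrr::map(list(...), ~ .x$clusters) |> bind_rows()
  sig <- cl[!is.na(cl$p) & cl$p < alpha & cl$sign > 0, ]
  if (!nrow(sig)) return(fallback)
  c(min(sig$start_ms), max(sig$end_ms))
}
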