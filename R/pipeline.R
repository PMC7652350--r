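#' Run the full serial-prediction-task analysis pipeline
#'
#' Executes, in fixed order: simulation (unless data are supplied),
#' preprocessing (baseline correction, amplitude-threshold artifact
#' rejection, low-trial participant exclusion, correct-trial averaging),
#' the per-task within-group cluster permutation tests, cluster-window mean
#' amplitudes with their Condition x Group ANOVA, percent-area latency with
#' jackknife group tests (measurement window: union span of each task's
#' significant clusters, falling back to 400–1000 ms), and the behavioural
#' accuracy and visuomotor learning analyses. Every stage logs its
#' parameters; all randomness derives deterministically from
#' `config$seed`, so a run is reproducible from its configuration alone.
#'
#' @param config an [sim_config()] object (also the source of all stage
#'   seeds).
#' @param epochs optional pre-made `spt_epochs` table; default simulated
#'   from `config`.
#' @param behavior optional behavioural trial table; an empty table skips
#'   the behavioural stage with a log entry. Default simulated from
#'   `config`.
#' @param cluster_alpha cluster-forming alpha.
#' @param n_permutations permutations per cluster test.
#' @param threshold_uv artifact rejection threshold (uV).
#' @param min_trials minimum usable trials per condition.
#' @param fraction percent-area fraction for latency.
#' @param out_dir optional directory; when given, a JSON summary and TSV
#'   tables are written into it.
#' @param quiet suppress progress messages.
#' @return an object of class `spt_run`: a list with elements `erps`,
#'   `cluster_tests` (nested list task -> group), `amplitude_cells`,
#'   `amplitude_anova`, `latencies` (Table-shaped latency summary),
#'   `mean_delay_ms`, `accuracy`, `accuracy_anova`, `posthoc`, `slopes`,
#'   `rt_test`, `exclusions`, and `settings`.
#' @export
run_pipeline <- function(config,
                         epochs = NULL, behavior = NULL,
                         cluster_alpha = 0.05, n_permutations = 1000,
                         threshold_uv = 100, min_trials = 10,
                         fraction = 0.5, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "spt_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  say("[simulate] seed=%d, groups=%s", config$seed,
      paste(config$groups, collapse = "/"))
  if (is.null(epochs)) epochs <- stage("simulate", simulate_epochs(config))
  if (is.null(behavior)) {
    behavior <- stage("simulate", simulate_behavior(config))
  }

  say(paste("[preprocess] baseline -250..0 ms, threshold +/-%g uV,",
            "min %d trials/condition"), threshold_uv, min_trials)
  epochs <- stage("preprocess", {
    epochs |>
      baseline_correct() |>
      reject_artifacts(threshold_uv = threshold_uv) |>
      exclude_low_trial_participants(min_trials = min_trials)
  })
  excl <- exclusion_report(epochs)
  say("[preprocess] %d trial(s) rejected, %d participant-task exclusion(s)",
      sum(epochs$rejected), nrow(excl))
  erps <- stage("average", average_erp(epochs, correct_only = TRUE))
  diffs <- stage("average", diff_waves(erps))

  tasks <- intersect(config$tasks, unique(diffs$task))
  groups <- config$groups
  say("[cluster] alpha=%g, %d permutation(s) per test", cluster_alpha,
      n_permutations)
  cluster_tests <- purrr::map(setNames(tasks, tasks), function(tk) {
    purrr::imap(setNames(groups, groups), function(g, gi) {
      dsub <- filter(diffs, .data$task == tk, .data$group == g)
      stage(paste0("cluster:", tk, ":", g),
            cluster_permutation_test(
              dsub, cluster_alpha = cluster_alpha,
              n_permutations = n_permutations,
              seed = derive_seed(config$seed,
                                 10L + match(tk, config$tasks) * 2L +
                                   match(g, groups))))
    })
  })

  amp_cells <- stage("amplitude",
                     extract_cluster_mean_amplitude(diffs,
                                                    window_ms = c(400, 1000)))
  amp_anova <- if (length(tasks) >= 2 && length(groups) >= 2) {
    stage("amplitude", amplitude_anova(amp_cells))
  }

  say("[latency] fraction=%g, window from significant clusters", fraction)
  jks <- purrr::map(setNames(tasks, tasks), function(tk) {
    win <- do.call(cluster_window, unname(cluster_tests[[tk]]))
    stage(paste0("latency:", tk),
          jackknife_latencies(filter(diffs, .data$task == tk),
                              window_ms = win, fraction = fraction))
  })
  lat_tab <- stage("latency", latency_table(jks))
  sig_conditions <- unique(lat_tab$condition[!is.na(lat_tab$p.value) &
                                               lat_tab$p.value < 0.05])
  delay_conditions <- if (length(sig_conditions)) sig_conditions else
    unique(lat_tab$condition)
  mean_delay <- if (length(groups) == 2) {
    stage("latency", mean_group_delay(lat_tab, delay_conditions,
                                      groups = groups))
  }

  beh <- list(accuracy = NULL, accuracy_anova = NULL, posthoc = NULL,
              slopes = NULL, rt_test = NULL)
  if (is.null(behavior) || nrow(behavior) == 0) {
    say("[behavior] skipped: empty behavioural table")
  } else {
    say("[behavior] accuracy + visuomotor learning analyses")
    beh$accuracy <- stage("behavior:accuracy",
                          accuracy_table(behavior,
                                         min_responses = min_trials))
    if (length(unique(beh$accuracy$task)) >= 2) {
      beh$accuracy_anova <- stage("behavior:anova",
                                  accuracy_anova(beh$accuracy))
      beh$posthoc <- stage("behavior:posthoc",
                           posthoc_group_tests(beh$accuracy))
    }
    if ("Visuomotor" %in% behavior$task) {
      beh$slopes <- stage("behavior:slopes", learning_slopes(behavior))
      beh$rt_test <- stage("behavior:rt", disruption_rt_test(behavior))
    } else {
      say("[behavior] no visuomotor task: learning analyses skipped")
    }
  }

  res <- structure(list(
    erps = erps, cluster_tests = cluster_tests,
    amplitude_cells = amp_cells, amplitude_anova = amp_anova,
    latencies = lat_tab, mean_delay_ms = mean_delay,
    delay_conditions = delay_conditions,
    accuracy = beh$accuracy, accuracy_anova = beh$accuracy_anova,
    posthoc = beh$posthoc, slopes = beh$slopes, rt_test = beh$rt_test,
    exclusions = excl,
    settings = list(seed = config$seed, cluster_alpha = cluster_alpha,
                    n_permutations = n_permutations,
                    threshold_uv = threshold_uv, min_trials = min_trials,
                    fraction = fraction)
  ), class = "spt_run")

  if (!is.null(out_dir)) write_run(res, out_dir, config, quiet = quiet)
  res
}

#' Serialize a pipeline run to disk
#'
#' Writes a machine-readable JSON summary plus human-readable TSV tables
#' (cluster windows and p-values, the latency table, accuracy cells, and
#' learning slopes) into `out_dir`, together with the configuration needed
#' to reproduce the run.
#'
#' @param run an `spt_run` object.
#' @param out_dir output directory (created if missing).
#' @param config the [sim_config()] the run was made with.
#' @param quiet suppress messages.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir, config, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, f) {
    if (!is.null(x)) {
      utils::write.table(as.data.frame(x), file.path(out_dir, f),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  clusters <- purrr::imap(run$cluster_tests, function(by_group, tk) {
    purrr::imap(by_group, function(ct, g) {
      if (nrow(ct$clusters)) {
        mutate(ct$clusters, task = tk, group = g, .before = 1)
      }
    }) |> bind_rows()
  }) |> bind_rows()
  wtsv(clusters, "clusters.tsv")
  wtsv(run$latencies, "latency_table.tsv")
  wtsv(run$accuracy, "accuracy.tsv")
  wtsv(run$posthoc, "posthoc.tsv")
  wtsv(run$slopes, "slopes.tsv")
  wtsv(run$exclusions, "exclusions.tsv")

  summary <- list(
    config = config_summary(config),
    settings = run$settings,
    clusters = clusters,
    latency = run$latencies,
    mean_delay_ms = run$mean_delay_ms,
    delay_conditions = run$delay_conditions,
    amplitude_anova = run$amplitude_anova,
    accuracy_anova = run$accuracy_anova,
    posthoc = run$posthoc,
    slope_test = if (!is.null(run$slopes)) attr(run$slopes, "test"),
    rt_test = run$rt_test,
    first_response_test = if (!is.null(run$rt_test)) {
      first_response_test(run$rt_test)
    },
    exclusions = run$exclusions
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
  if (!quiet) inform(sprintf("[report] written to %s", out_dir))
  invisible(out_dir)
}

config_summary <- function(config) {
  c <- unclass(config)
  c$accuracy_probs <- as.data.frame(c$accuracy_probs)
  c$p3_amplitude <- as.data.frame(c$p3_amplitude)
  c
}

#' @export
print.spt_run <- function(x, ...) {
  cat("<spt_run>\n")
  cat(sprintf("  seed %d | cluster alpha %g | %d permutations\n",
              x$settings$seed, x$settings$cluster_alpha,
              x$settings$n_permutations))
  nsig <- sum(purrr::map_int(x$cluster_tests, function(bg) {
    sum(purrr::map_int(bg, ~ sum(!is.na(.x$clusters$p) &
                                   .x$clusters$p < 0.05)))
  }))
  cat(sprintf("  significant clusters: %d\n", nsig))
  if (!is.null(x$mean_delay_ms)) {
    cat(sprintf("  mean group latency delay: %.1f ms (conditions: %s)\n",
                x$mean_delay_ms, paste(x$delay_conditions, collapse = ", ")))
  }
  if (!is.null(x$slopes)) {
    tst <- attr(x$slopes, "test")
    if (nrow(tst)) {
      cat(sprintf("  log-RT slopes: %s %.3f vs %s %.3f (p = %.3g)\n",
                  tst$group_1, tst$mean_slope_1, tst$group_2,
                  tst$mean_slope_2, tst$p.value))
    }
  }
  cat(sprintf("  exclusions: %d participant-task pair(s)\n",
              nrow(x$exclusions)))
  invisible(x)
}
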