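#' Simulation configuration for a serial prediction task study
#'
#' Bundles every parameter of the synthetic-data generator: cohort layout,
#' epoch geometry, the P3-like evoked component, background noise, response
#' accuracy, and visuomotor reaction-time learning. The defaults describe a
#' two-group child cohort (DCD n = 24, TD n = 23) performing five tasks
#' (Control, Spatial, Temporal, Visual, Visuomotor) with 60 trials per task
#' (72 in the visuomotor task), half of them disrupted at stimulus position
#' 10 or 11, recorded at 500 Hz over a -250..1000 ms epoch at Pz.
#'
#' The P3 is modelled as a Gaussian bump whose amplitude depends on sequence
#' type (disrupted larger than intact, with no group difference by default)
#' and whose centre is the participant's true latency (group means TD 700 ms,
#' DCD 784 ms) plus single-trial jitter. Background noise is 1/f ("pink")
#' plus white noise. Visuomotor reaction times follow a decreasing power law:
#' `RT_k = exp(log(rt_intercept) + slope * k + noise)` for stimulus index
#' `k = 1..12`, with `rt_disruption_cost` milliseconds added at the
#' disrupting stimulus of disrupted trials.
#'
#' @param n_per_group named integer vector, participants per group.
#' @param tasks character vector of task labels.
#' @param trials_per_task named integer vector of trials per task; any task
#'   not named falls back to the unnamed default (60). The default gives the
#'   visuomotor task 72 trials.
#' @param p_disrupted fraction of trials whose sequence is disrupted.
#' @param sample_rate sampling rate in Hz.
#' @param epoch_window epoch limits in ms relative to the disruption-locked
#'   stimulus, `c(start, end)` with `start < 0 < end`.
#' @param p3_amplitude P3 amplitude in uV: either a named vector
#'   `c(intact = , disrupted = )` applied to both groups, or a data frame
#'   with columns `group`, `sequence_type`, `amplitude`.
#' @param p3_latency_mean named numeric, true mean P3 latency (ms) per group.
#' @param p3_latency_sd between-participant SD of true latency (ms).
#' @param p3_jitter_sd single-trial latency jitter SD (ms).
#' @param p3_width Gaussian SD of the P3 bump (ms).
#' @param noise_white_sd white-noise SD (uV).
#' @param noise_pink_sd 1/f-noise SD (uV).
#' @param noise_pink_exponent spectral exponent alpha (power ~ 1/f^alpha).
#' @param accuracy_probs probability of a correct response per cell: a data
#'   frame with columns `group`, `task` (optional), `sequence_type`, `prob`,
#'   or `NULL` for the built-in defaults (overall ~.905 intact / ~.82
#'   disrupted, with no group gap in the Control task).
#' @param rt_intercept baseline reaction time (ms).
#' @param rt_slope_log named numeric, group mean slope of log-RT per
#'   response index.
#' @param rt_slope_sd between-participant SD of the true log-RT slope.
#' @param rt_disruption_cost ms added to the RT at the disrupting stimulus.
#' @param rt_noise lognormal sigma of single-response RT noise.
#' @param seed integer master seed; mandatory so that identical
#'   configurations yield identical data.
#'
#' @return an object of class `spt_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, n_per_group = c(DCD = 4, TD = 4),
#'                   tasks = "Spatial")
#' cfg$p3_latency_mean
#' @export
sim_config <- function(n_per_group = c(DCD = 24, TD = 23),
                       tasks = c("Control", "Spatial", "Temporal",
                                 "Visual", "Visuomotor"),
                       trials_per_task = c(60, Visuomotor = 72),
                       p_disrupted = 0.5,
                       sample_rate = 500,
                       epoch_window = c(-250, 1000),
                       p3_amplitude = c(intact = 3, disrupted = 13),
                       p3_latency_mean = c(DCD = 784, TD = 700),
                       p3_latency_sd = 50,
                       p3_jitter_sd = 40,
                       p3_width = 80,
                       noise_white_sd = 7,
                       noise_pink_sd = 10,
                       noise_pink_exponent = 1,
                       accuracy_probs = NULL,
                       rt_intercept = 900,
                       rt_slope_log = c(DCD = -0.098, TD = -0.075),
                       rt_slope_sd = 0.015,
                       rt_disruption_cost = 150,
                       rt_noise = 0.2,
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory in sim_config()")
  groups <- names(n_per_group)
  if (is.null(groups) || any(!nzchar(groups))) {
    abort("`n_per_group` must be a named vector (one count per group)")
  }
  if (any(n_per_group <= 0)) abort("participant counts must be positive")
  if (p_disrupted < 0 || p_disrupted > 1) abort("p_disrupted must be in [0, 1]")
  if (sample_rate <= 0) abort("sample_rate must be positive")
  if (length(epoch_window) != 2 ||
      !(epoch_window[1] < 0 && 0 < epoch_window[2])) {
    abort("epoch_window must satisfy start < 0 < end")
  }
  if (!all(groups %in% names(p3_latency_mean))) {
    abort("p3_latency_mean must name every group")
  }
  if (!all(groups %in% names(rt_slope_log))) {
    abort("rt_slope_log must name every group")
  }
  for (v in c("p3_latency_sd", "p3_jitter_sd", "p3_width", "noise_white_sd",
              "noise_pink_sd", "rt_noise", "rt_slope_sd")) {
    if (get(v) < 0) abort(sprintf("%s must be non-negative", v))
  }
  if (rt_intercept <= 0) abort("rt_intercept must be positive")

  trials <- resolve_trials(tasks, trials_per_task)
  if (any(trials <= 0)) abort("trial counts must be positive")

  amp <- resolve_amplitudes(p3_amplitude, groups)
  acc <- resolve_accuracy(accuracy_probs, groups, tasks)
  if (any(acc$prob < 0 | acc$prob > 1)) {
    abort("accuracy probabilities must lie in [0, 1]")
  }

  structure(list(
    n_per_group = n_per_group, groups = groups, tasks = tasks,
    trials_per_task = trials, p_disrupted = p_disrupted,
    sample_rate = sample_rate, epoch_window = epoch_window,
    p3_amplitude = amp,
    p3_latency_mean = p3_latency_mean[groups],
    p3_latency_sd = p3_latency_sd, p3_jitter_sd = p3_jitter_sd,
    p3_width = p3_width,
    noise_white_sd = noise_white_sd, noise_pink_sd = noise_pink_sd,
    noise_pink_exponent = noise_pink_exponent,
    accuracy_probs = acc,
    rt_intercept = rt_intercept,
    rt_slope_log = rt_slope_log[groups], rt_slope_sd = rt_slope_sd,
    rt_disruption_cost = rt_disruption_cost, rt_noise = rt_noise,
    seed = as.integer(seed)
  ), class = "spt_config")
}

resolve_trials <- function(tasks, trials_per_task) {
  nm <- names(trials_per_task)
  if (is.null(nm)) nm <- rep("", length(trials_per_task))
  default <- trials_per_task[nm == ""]
  default <- if (length(default)) default[[1]] else 60
  out <- setNames(rep(as.integer(default), length(tasks)), tasks)
  named <- intersect(tasks, nm)
  out[named] <- as.integer(trials_per_task[named])
  out
}

resolve_amplitudes <- function(p3_amplitude, groups) {
  if (is.data.frame(p3_amplitude)) {
    require_cols(p3_amplitude, c("group", "sequence_type", "amplitude"),
                 "p3_amplitude")
    return(as_tibble(p3_amplitude))
  }
  if (!all(c("intact", "disrupted") %in% names(p3_amplitude))) {
    abort("p3_amplitude must name 'intact' and 'disrupted'")
  }
  tidyr::expand_grid(group = groups,
                     sequence_type = c("intact", "disrupted")) |>
    mutate(amplitude = unname(p3_amplitude[.data$sequence_type]))
}

resolve_accuracy <- function(accuracy_probs, groups, tasks) {
  if (is.null(accuracy_probs)) return(default_accuracy(groups, tasks))
  accuracy_probs <- as_tibble(accuracy_probs)
  require_cols(accuracy_probs, c("group", "sequence_type", "prob"),
               "accuracy_probs")
  if (!"task" %in% names(accuracy_probs)) {
    accuracy_probs <- tidyr::expand_grid(task = tasks, accuracy_probs)
  }
  grid <- tidyr::expand_grid(group = groups, task = tasks,
                             sequence_type = c("intact", "disrupted"))
  out <- left_join(grid, accuracy_probs,
                   by = c("group", "task", "sequence_type"))
  if (anyNA(out$prob)) abort("accuracy_probs does not cover every cell")
  out
}

# Default response-accuracy surface: a clear group deficit, larger for
# disrupted sequences, absent in the Control task.
default_accuracy <- function(groups, tasks) {
  grid <- tidyr::expand_grid(group = groups, task = tasks,
                             sequence_type = c("intact", "disrupted"))
  base <- c(intact = 0.94, disrupted = 0.89)
  lo   <- c(intact = 0.87, disrupted = 0.75)
  ctrl <- c(intact = 0.92, disrupted = 0.85)
  impaired <- if ("DCD" %in% groups) "DCD" else groups[1]
  grid |>
    mutate(prob = dplyr::case_when(
      .data$group != impaired ~ base[.data$sequence_type],
      .data$task == "Control" ~ ctrl[.data$sequence_type],
      TRUE ~ lo[.data$sequence_type]
    ))
}

#' @export
print.spt_config <- function(x, ...) {
  cat("<spt_config>\n")
  cat("  groups:", paste(sprintf("%s (n=%d)", x$groups,
                                 x$n_per_group[x$groups]), collapse = ", "), "\n")
  cat("  tasks:", paste(sprintf("%s (%d trials)", x$tasks,
                                x$trials_per_task[x$tasks]), collapse = ", "), "\n")
  cat(sprintf("  epochs: %g..%g ms @ %g Hz\n",
              x$epoch_window[1], x$epoch_window[2], x$sample_rate))
  cat(sprintf("  P3 latency: %s; width %g ms; jitter %g ms\n",
              paste(sprintf("%s %g ms", names(x$p3_latency_mean),
                            x$p3_latency_mean), collapse = ", "),
              x$p3_width, x$p3_jitter_sd))
  cat(sprintf("  noise: white %g uV, pink %g uV (alpha=%g)\n",
              x$noise_white_sd, x$noise_pink_sd, x$noise_pink_exponent))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
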