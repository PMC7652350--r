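# Shared fixture builders. Everything is generated in code at test time.

# small cohort configuration; override any sim_config() argument
tiny_config <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    seed = seed,
    n_per_group = c(DCD = 4, TD = 4),
    tasks = "Spatial",
    trials_per_task = 24
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

# deterministic, noise-free configuration (no latency spread, no noise)
clean_config <- function(seed = 1, ...) {
  tiny_config(seed = seed,
              p3_latency_sd = 0, p3_jitter_sd = 0,
              noise_white_sd = 0, noise_pink_sd = 0,
              rt_slope_sd = 0, rt_noise = 0,
              accuracy_probs = all_correct_probs(), ...)
}

all_correct_probs <- function(p = 1) {
  expand.grid(group = c("DCD", "TD"),
              sequence_type = c("intact", "disrupted"),
              stringsAsFactors = FALSE) |>
    transform(prob = p)
}

# hand-built epoch table from a trials x samples matrix
epochs_from_matrix <- function(m, times, sample_rate = 500,
                               participant = "p01", task = "task",
                               sequence_type = "disrupted",
                               response_correct = TRUE, group = "G") {
  n <- nrow(m)
  rec <- function(v) rep_len(v, n)
  new_epochs(tibble::tibble(
    participant = rec(participant), group = rec(group), task = rec(task),
    trial = seq_len(n), sequence_type = rec(sequence_type),
    disruption_position = NA_integer_,
    response_correct = rec(response_correct), rejected = FALSE,
    signal = lapply(seq_len(n), function(i) m[i, ])
  ), times = times, sample_rate = sample_rate)
}

# long difference-waveform tibble from a participants x time matrix
diffs_from_matrix <- function(m, times, group = "G", task = "task") {
  n <- nrow(m)
  ids <- sprintf("%s%02d", group, seq_len(n))
  tibble::tibble(
    participant = rep(ids, each = length(times)),
    group = group, task = task,
    time = rep(times, n),
    amplitude = as.vector(t(m))
  )
}

# smooth random waveform: a few Gaussian bumps plus a slow sinusoid,
# guaranteed to have positive area
random_smooth_waveform <- function(times) {
  v <- numeric(length(times))
  for (b in seq_len(sample(3:7, 1))) {
    v <- v + runif(1, -4, 8) *
      exp(-(times - runif(1, min(times) + 100, max(times) - 100))^2 /
            (2 * runif(1, 30, 120)^2))
  }
  v <- v + runif(1, 0, 2) * sin(2 * pi * times / runif(1, 400, 900))
  # ensure some positive area
  v + 3 * exp(-(times - runif(1, 300, 700))^2 / (2 * 80^2))
}
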