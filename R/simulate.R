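#' Simulate single-channel EEG epochs with a P3-like component
#'
#' Generates, for every participant and task in the configuration, one epoch
#' per trial: a Gaussian P3-like bump (amplitude set by sequence type,
#' centre at the participant's true latency plus single-trial jitter) on top
#' of 1/f ("pink") and white noise. Trial metadata carry the sequence type,
#' the disruption position (10 or 11, drawn uniformly), and a simulated
#' correctness flag drawn from the configured accuracy probabilities,
#' independently of the EEG signal.
#'
#' @param config an [sim_config()] object.
#' @param tasks optional subset of `config$tasks` to simulate.
#' @return a tibble of class `spt_epochs`: one row per trial with columns
#'   `participant`, `group`, `task`, `trial`, `sequence_type`,
#'   `disruption_position`, `response_correct`, `rejected`, and the
#'   list-column `signal` (uV); attributes `times` (ms), `sample_rate`, and
#'   `ground_truth` (see [ground_truth()]).
#' @seealso [simulate_behavior()], [average_erp()]
#' @examples
#' cfg <- sim_config(seed = 1, n_per_group = c(DCD = 2, TD = 2),
#'                   tasks = "Spatial", trials_per_task = 8)
#' ep <- simulate_epochs(cfg)
#' dplyr::count(ep, group, sequence_type)
#' @export
simulate_epochs <- function(config, tasks = config$tasks) {
  stopifnot(inherits(config, "spt_config"))
  tasks <- match.arg(tasks, config$tasks, several.ok = TRUE)
  truth <- participant_truth(config)

  set.seed(derive_seed(config$seed, 1L))
  times <- epoch_time_axis(config)
  nt <- length(times)

  amp_key <- with(config$p3_amplitude,
                  setNames(amplitude, paste(group, sequence_type)))
  acc_key <- with(config$accuracy_probs,
                  setNames(prob, paste(group, task, sequence_type)))

  pieces <- vector("list", nrow(truth$participants) * length(tasks))
  k <- 0L
  for (i in seq_len(nrow(truth$participants))) {
    pp <- truth$participants[i, ]
    for (task in tasks) {
      n <- config$trials_per_task[[task]]
      n_dis <- round(config$p_disrupted * n)
      stype <- rep("intact", n)
      stype[sample.int(n, n_dis)] <- "disrupted"
      dpos <- ifelse(stype == "disrupted",
                     sample(c(10L, 11L), n, replace = TRUE), NA_integer_)
      correct <- rbinom(n, 1L,
                        acc_key[paste(pp$group, task, stype)]) == 1L

      centers <- pp$p3_latency_ms + rnorm(n, 0, config$p3_jitter_sd)
      amps <- amp_key[paste(pp$group, stype)]
      bump <- amps * exp(-outer(centers, times, "-")^2 /
                           (2 * config$p3_width^2))
      sig <- bump +
        pink_noise_matrix(n, nt, config$noise_pink_exponent,
                          config$noise_pink_sd) +
        if (config$noise_white_sd > 0) {
          matrix(rnorm(n * nt, 0, config$noise_white_sd), n, nt)
        } else 0

      k <- k + 1L
      pieces[[k]] <- tibble(
        participant = pp$participant, group = pp$group, task = task,
        trial = seq_len(n), sequence_type = stype,
        disruption_position = dpos, response_correct = correct,
        rejected = FALSE,
        signal = lapply(seq_len(n), function(j) sig[j, ])
      )
    }
  }
  out <- bind_rows(pieces)
  new_epochs(out, times = times, sample_rate = config$sample_rate,
             ground_truth = truth)
}

#' Simulate the behavioural trial table
#'
#' One row per trial for every participant and task: the yes/no sequence
#' judgement (correct with the configured cell probability) and, for the
#' visuomotor task, reaction times at the 12 stimulus positions (six
#' repetitions of a two-element sequence). RTs follow
#' `exp(log(rt_intercept) + slope_i * k + noise)` in the stimulus index `k`,
#' with the participant's true slope `slope_i`, and `rt_disruption_cost` ms
#' added at the disrupting stimulus of disrupted trials.
#'
#' @inheritParams simulate_epochs
#' @return a tibble of class `spt_behavior`: columns `participant`, `group`,
#'   `task`, `trial`, `sequence_type`, `disruption_position`, `response`
#'   ("yes"/"no"), `correct`, and `rt_1`..`rt_12` (ms; `NA` outside the
#'   visuomotor task); attribute `ground_truth`.
#' @examples
#' cfg <- sim_config(seed = 1, n_per_group = c(DCD = 2, TD = 2))
#' bh <- simulate_behavior(cfg)
#' dplyr::count(bh, task, sequence_type)
#' @export
simulate_behavior <- function(config, tasks = config$tasks) {
  stopifnot(inherits(config, "spt_config"))
  tasks <- match.arg(tasks, config$tasks, several.ok = TRUE)
  truth <- participant_truth(config)

  set.seed(derive_seed(config$seed, 2L))
  acc_key <- with(config$accuracy_probs,
                  setNames(prob, paste(group, task, sequence_type)))

  pieces <- vector("list", nrow(truth$participants) * length(tasks))
  k <- 0L
  for (i in seq_len(nrow(truth$participants))) {
    pp <- truth$participants[i, ]
    for (task in tasks) {
      n <- config$trials_per_task[[task]]
      n_dis <- round(config$p_disrupted * n)
      stype <- rep("intact", n)
      stype[sample.int(n, n_dis)] <- "disrupted"
      dpos <- ifelse(stype == "disrupted",
                     sample(c(10L, 11L), n, replace = TRUE), NA_integer_)
      correct <- rbinom(n, 1L,
                        acc_key[paste(pp$group, task, stype)]) == 1L
      # correct <=> (yes & disrupted) | (no & intact)
      response <- ifelse(xor(stype == "disrupted", correct), "no", "yes")

      tb <- tibble(
        participant = pp$participant, group = pp$group, task = task,
        trial = seq_len(n), sequence_type = stype,
        disruption_position = dpos, response = response, correct = correct
      )
      rt <- matrix(NA_real_, n, 12)
      if (task == "Visuomotor") {
        kk <- matrix(rep(1:12, each = n), n, 12)
        rt <- exp(log(config$rt_intercept) + pp$rt_slope * kk +
                    matrix(rnorm(n * 12, 0, config$rt_noise), n, 12))
        dis <- which(stype == "disrupted")
        rt[cbind(dis, dpos[dis])] <-
          rt[cbind(dis, dpos[dis])] + config$rt_disruption_cost
      }
      colnames(rt) <- paste0("rt_", 1:12)
      k <- k + 1L
      pieces[[k]] <- dplyr::bind_cols(tb, as_tibble(rt))
    }
  }
  out <- bind_rows(pieces)
  attr(out, "ground_truth") <- truth
  class(out) <- c("spt_behavior", class(out))
  out
}

#' Ground truth of a simulated dataset
#'
#' @param x an object produced by [simulate_epochs()] or
#'   [simulate_behavior()].
#' @return a list with `participants` (tibble of true per-participant P3
#'   latency and log-RT slope) and `accuracy` (true probability correct per
#'   group x task x sequence-type cell).
#' @export
ground_truth <- function(x) {
  gt <- attr(x, "ground_truth")
  if (is.null(gt)) abort("object carries no ground truth")
  gt
}

# Participant-level true parameters, drawn from a dedicated seed stream so
# that simulate_epochs() and simulate_behavior() agree on the same truth.
participant_truth <- function(config) {
  set.seed(derive_seed(config$seed, 0L))
  parts <- purrr::map2(config$groups, config$n_per_group[config$groups],
    function(g, n) {
      tibble(
        participant = sprintf("%s%02d", g, seq_len(n)),
        group = g,
        p3_latency_ms = rnorm(n, config$p3_latency_mean[[g]],
                              config$p3_latency_sd),
        rt_slope = rnorm(n, config$rt_slope_log[[g]], config$rt_slope_sd)
      )
    }) |> bind_rows()
  list(participants = parts, accuracy = config$accuracy_probs)
}

epoch_time_axis <- function(config) {
  step <- 1000 / config$sample_rate
  seq(config$epoch_window[1], config$epoch_window[2], by = step)
}

#' Synthesize 1/f-shaped noise by spectral shaping of white noise
#'
#' Each row is an independent realisation with power spectral density
#' proportional to 1/f^alpha, rescaled to the requested standard deviation.
#'
#' @param n number of rows (trials).
#' @param len samples per row.
#' @param alpha spectral exponent.
#' @param sd target SD in uV; 0 returns a zero matrix.
#' @return an `n x len` numeric matrix.
#' @keywords internal
pink_noise_matrix <- function(n, len, alpha, sd) {
  if (sd == 0 || n == 0) return(matrix(0, n, len))
  w <- matrix(rnorm(n * len), len, n)
  f <- c(0, pmin(seq_len(len - 1), len - seq_len(len - 1)))
  scale <- c(0, f[-1]^(-alpha / 2))
  x <- Re(stats::mvfft(stats::mvfft(w) * scale, inverse = TRUE)) / len
  x <- x - rep(colMeans(x), each = len)
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  x <- sweep(x, 2, sd / s, `*`)
  t(x)
}

#' @export
print.spt_epochs <- function(x, ...) {
  times <- attr(x, "times")
  cat(sprintf("<spt_epochs> %d trials, %d samples (%g..%g ms @ %g Hz)\n",
              nrow(x), length(times), min(times), max(times),
              attr(x, "sample_rate")))
  NextMethod()
}
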