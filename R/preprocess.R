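#' Zero-delay Hamming-windowed sinc FIR band-pass filter
#'
#' Designs a linear-phase FIR band-pass (default 0.1–40 Hz) with a Hamming
#' window and applies it with group-delay compensation, so the output is
#' delay-free. The filter order follows a transition-band heuristic: the
#' transition band is 1 Hz for cutoffs below 8 Hz — but never wider than the
#' cutoff frequency itself, so the low edge of a 0.1 Hz high-pass gets a
#' 0.1 Hz band — and 25% of the cutoff above 8 Hz; the order is
#' `3.3 * sample_rate / min(transition bands)` (Hamming main-lobe rule).
#'
#' @param x numeric vector, a continuous single-channel recording (uV).
#' @param sample_rate sampling rate in Hz; must exceed `2 * high_hz`.
#' @param low_hz,high_hz band edges in Hz.
#' @param order optional FIR order override (even integer).
#' @return filtered numeric vector, same length as `x`.
#' @examples
#' fs <- 500
#' t <- seq(0, 4, by = 1 / fs)
#' x <- sin(2 * pi * 10 * t)
#' y <- bandpass_filter(x, fs, order = 500)
#' max(abs(y[500:1500] - x[500:1500])) < 0.05
#' @export
bandpass_filter <- function(x, sample_rate, low_hz = 0.1, high_hz = 40,
                            order = NULL) {
  if (high_hz >= sample_rate / 2) abort("high cutoff must be below Nyquist")
  if (low_hz <= 0 || low_hz >= high_hz) abort("need 0 < low_hz < high_hz")
  tb <- function(f) if (f < 8) min(1, f) else 0.25 * f
  if (is.null(order)) {
    order <- ceiling(3.3 * sample_rate / min(tb(low_hz), tb(high_hz)))
  }
  order <- as.integer(order)
  if (order %% 2L == 1L) order <- order + 1L
  if (length(x) <= order) {
    abort(sprintf(paste("signal (%d samples) is shorter than the filter",
                        "(order %d); supply a lower `order`"),
                  length(x), order))
  }
  b <- signal::fir1(order, c(low_hz, high_hz) / (sample_rate / 2),
                    type = "pass", window = signal::hamming(order + 1))
  gd <- order %/% 2L
  y <- signal::fftfilt(b, c(x, numeric(gd)))
  y[(gd + 1L):(gd + length(x))]
}

#' Cut epochs around event markers
#'
#' Epochs a continuous recording around event sample indices. Time zero of
#' each epoch is `event + shift_ms`; the temporal task uses
#' `shift_ms = 300` (the offset of the shorter stimulus), all other tasks 0.
#' Windows are closed at both ends and resolved to the nearest sample.
#' Events too close to the recording edge yield an epoch flagged
#' `valid = FALSE` (with an all-`NA` signal) rather than being dropped.
#'
#' @param x numeric vector, continuous recording (uV).
#' @param events integer vector of event sample indices (1-based).
#' @param sample_rate sampling rate in Hz.
#' @param window_ms epoch window in ms relative to time zero.
#' @param shift_ms epoch-onset shift in ms applied to every event.
#' @param meta optional data frame (one row per event) of trial metadata to
#'   bind to the epochs; defaults provide minimal columns.
#' @return an `spt_epochs` tibble with a `valid` flag column.
#' @export
epoch_trials <- function(x, events, sample_rate,
                         window_ms = c(-250, 1000), shift_ms = 0,
                         meta = NULL) {
  step <- 1000 / sample_rate
  rel <- round(window_ms[1] / step):round(window_ms[2] / step)
  times <- rel * step
  centers <- as.integer(events) + as.integer(round(shift_ms / step))
  first <- centers + rel[1]
  last <- centers + rel[length(rel)]
  valid <- first >= 1L & last <= length(x)
  sig <- lapply(seq_along(events), function(i) {
    if (valid[i]) x[(first[i]):(last[i])] else rep(NA_real_, length(rel))
  })
  if (is.null(meta)) {
    meta <- tibble(participant = "p01", task = "task",
                   trial = seq_along(events),
                   sequence_type = NA_character_)
  }
  out <- as_tibble(meta)
  out$event_sample <- as.integer(events)
  out$valid <- valid
  out$signal <- sig
  new_epochs(out, times = times, sample_rate = sample_rate)
}

#' Baseline-correct epochs
#'
#' Subtracts from every trial its mean over the baseline window (default
#' -250..0 ms, relative to the — possibly shifted — epoch time zero).
#'
#' @param epochs an `spt_epochs` tibble.
#' @param window_ms baseline window in ms.
#' @return the epochs with baseline-corrected signals.
#' @export
baseline_correct <- function(epochs, window_ms = c(-250, 0)) {
  times <- epoch_times(epochs)
  idx <- window_indices(times, window_ms)
  if (!length(idx)) abort("empty baseline window")
  epochs$signal <- lapply(epochs$signal, function(v) {
    if (anyNA(v)) v else v - mean(v[idx])
  })
  epochs
}

#' Flag trials exceeding an absolute amplitude threshold
#'
#' Semi-automated artifact rejection: a trial is flagged when any sample
#' strictly exceeds `threshold_uv` in absolute value, so a sample sitting
#' exactly at the threshold is kept; an optional manually supplied
#' blacklist of row indices is applied afterwards. Rejection only sets the
#' `rejected` flag — retained samples are never altered.
#'
#' @param epochs an `spt_epochs` tibble.
#' @param threshold_uv rejection threshold in uV.
#' @param blacklist optional integer vector of epoch row numbers to reject
#'   in addition (the manual-inspection channel).
#' @return the epochs with an updated `rejected` column.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 100, blacklist = NULL) {
  auto <- vapply(epochs$signal, function(v) {
    !anyNA(v) && max(abs(v)) > threshold_uv
  }, logical(1))
  rejected <- auto | epochs$rejected
  if (!is.null(blacklist)) rejected[blacklist] <- TRUE
  if ("valid" %in% names(epochs)) rejected <- rejected | !epochs$valid
  epochs$rejected <- rejected
  epochs
}

#' Exclude participants with too few usable trials in either condition
#'
#' A participant is retained for a task only if both sequence-type
#' conditions hold at least `min_trials` usable trials (usable = not
#' rejected; for behavioural tables every recorded response counts). The
#' exclusions are reported in the `exclusions` attribute, one row per
#' dropped participant x task with the offending counts.
#'
#' @param data an `spt_epochs` or behavioural tibble with columns
#'   `participant`, `task`, `sequence_type`.
#' @param min_trials minimum usable trials per condition.
#' @return the filtered data; see [exclusion_report()].
#' @export
exclude_low_trial_participants <- function(data, min_trials = 10) {
  require_cols(data, c("participant", "task", "sequence_type"))
  usable <- if ("rejected" %in% names(data)) !data$rejected else
    rep(TRUE, nrow(data))
  counts <- as_tibble(data[usable, c("participant", "task",
                                     "sequence_type")]) |>
    count(.data$participant, .data$task, .data$sequence_type) |>
    tidyr::pivot_wider(names_from = "sequence_type", values_from = "n",
                       values_fill = 0L)
  for (st in c("intact", "disrupted")) {
    if (!st %in% names(counts)) counts[[st]] <- 0L
  }
  bad <- counts |>
    filter(.data$intact < min_trials | .data$disrupted < min_trials)
  # participants present in data but with zero usable trials in a task are
  # caught too: pairs absent from `counts` entirely
  all_pairs <- distinct(as_tibble(data[, c("participant", "task")]))
  missing <- dplyr::anti_join(all_pairs, counts,
                              by = c("participant", "task")) |>
    mutate(intact = 0L, disrupted = 0L)
  bad <- bind_rows(bad, missing) |> arrange(.data$task, .data$participant)

  keep <- !paste(data$participant, data$task) %in%
    paste(bad$participant, bad$task)
  out <- data[keep, ]
  attr(out, "times") <- attr(data, "times")
  attr(out, "sample_rate") <- attr(data, "sample_rate")
  attr(out, "ground_truth") <- attr(data, "ground_truth")
  attr(out, "exclusions") <- bad
  class(out) <- class(data)
  out
}

#' @rdname exclude_low_trial_participants
#' @export
exclusion_report <- function(data) {
  attr(data, "exclusions") %||%
    tibble(participant = character(), task = character(),
           intact = integer(), disrupted = integer())
}

#' Average epochs into per-participant ERPs
#'
#' Computes, for every participant x task x sequence-type cell, the
#' pointwise mean over non-rejected (and, by default, correct-response)
#' trials, mirroring correct-trial averaging by sequence type.
#'
#' @param epochs an `spt_epochs` tibble.
#' @param correct_only average only trials with a correct response.
#' @return a long tibble of class `spt_erp`: columns `participant`,
#'   `group`, `task`, `sequence_type`, `n_trials`, `time`, `amplitude`.
#' @export
average_erp <- function(epochs, correct_only = TRUE) {
  times <- epoch_times(epochs)
  use <- !epochs$rejected
  if (correct_only) {
    require_cols(epochs, "response_correct", "epochs (correct_only = TRUE)")
    use <- use & epochs$response_correct
  }
  if ("valid" %in% names(epochs)) use <- use & epochs$valid
  sub <- epochs[use, ]
  if (!nrow(sub)) abort("zero usable trials to average")
  cells <- distinct(as_tibble(
    epochs[, intersect(c("participant", "group", "task", "sequence_type"),
                       names(epochs))]))
  key <- paste(sub$participant, sub$task, sub$sequence_type)
  cells$key <- paste(cells$participant, cells$task, cells$sequence_type)
  empty <- setdiff(cells$key, unique(key))
  if (length(empty)) {
    abort(paste0("zero usable trials in condition cell(s): ",
                 paste(empty, collapse = "; ")))
  }
  mat <- epoch_matrix(sub)
  sums <- rowsum(mat, key)
  ns <- as.vector(table(key)[rownames(sums)])
  means <- sums / ns
  ord <- match(cells$key, rownames(means))
  out <- cells |>
    mutate(n_trials = ns[ord]) |>
    select(-"key")
  out <- tidyr::uncount(out, length(times), .id = "sample_i") |>
    mutate(time = times[.data$sample_i],
           amplitude = as.vector(t(means[ord, , drop = FALSE]))) |>
    select(-"sample_i")
  structure(out, times = times,
            sample_rate = attr(epochs, "sample_rate"),
            class = unique(c("spt_erp", class(out))))
}

#' Disrupted-minus-intact difference waveforms
#'
#' @param erps an `spt_erp` tibble containing both sequence types for every
#'   participant x task.
#' @return a long tibble (class `spt_erp_diff`) with columns `participant`,
#'   `group`, `task`, `time`, `amplitude` where `amplitude` is
#'   disrupted - intact.
#' @export
diff_waves <- function(erps) {
  require_cols(erps, c("participant", "task", "sequence_type", "time",
                       "amplitude"), "ERP table")
  wide <- erps |>
    select(dplyr::any_of(c("participant", "group", "task", "sequence_type",
                           "time", "amplitude"))) |>
    tidyr::pivot_wider(names_from = "sequence_type",
                       values_from = "amplitude")
  if (!all(c("intact", "disrupted") %in% names(wide)) ||
      anyNA(wide$intact) || anyNA(wide$disrupted)) {
    abort("both sequence types are required for every participant x task")
  }
  out <- wide |>
    mutate(amplitude = .data$disrupted - .data$intact) |>
    select(-"intact", -"disrupted")
  structure(out, times = attr(erps, "times"),
            sample_rate = attr(erps, "sample_rate"),
            class = unique(c("spt_erp_diff", class(out))))
}

# participants x time matrix from a long (difference) waveform table,
# for one task at a time
waveform_matrix <- function(diffs) {
  parts <- unique(diffs$participant)
  times <- sort(unique(diffs$time))
  wide <- tidyr::pivot_wider(
    diffs[, c("participant", "time", "amplitude")],
    names_from = "time", values_from = "amplitude")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$participant
  m <- m[, order(as.numeric(colnames(m))), drop = FALSE]
  if (anyNA(m)) abort("waveforms do not share a common time axis")
  list(m = m[parts, , drop = FALSE], times = times)
}
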