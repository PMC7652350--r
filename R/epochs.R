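#' Construct an epoch table
#'
#' An `spt_epochs` object is an ordinary tibble (one row per trial) whose
#' `signal` list-column holds the single-channel waveform of each trial, with
#' the shared time axis stored once as an attribute. All preprocessing
#' functions take and return this shape, so they compose with dplyr verbs.
#'
#' @param data a data frame with at least `participant`, `task`,
#'   `sequence_type` and a `signal` list-column; a `rejected` column is
#'   added if absent.
#' @param times numeric vector of sample times in ms, strictly increasing
#'   with uniform step `1000 / sample_rate`.
#' @param sample_rate sampling rate in Hz.
#' @param ground_truth optional ground-truth list to carry along.
#' @return a tibble of class `spt_epochs`.
#' @export
new_epochs <- function(data, times, sample_rate,
                       ground_truth = attr(data, "ground_truth")) {
  data <- as_tibble(data)
  require_cols(data, c("participant", "task", "sequence_type", "signal"),
               "epoch table")
  if (!"rejected" %in% names(data)) data$rejected <- FALSE
  step <- 1000 / sample_rate
  if (length(times) > 1 &&
      max(abs(diff(times) - step)) > 1e-6 * step) {
    abort("`times` must be uniform with step 1000 / sample_rate")
  }
  lens <- lengths(data$signal)
  if (any(lens != length(times) & lens != 0)) {
    abort("every signal must have the same length as `times`")
  }
  structure(data,
            times = times, sample_rate = sample_rate,
            ground_truth = ground_truth,
            class = unique(c("spt_epochs", class(data))))
}

#' @rdname new_epochs
#' @param x an `spt_epochs` or `spt_erp` object.
#' @export
epoch_times <- function(x) {
  t <- attr(x, "times")
  if (is.null(t)) abort("object has no time axis attribute")
  t
}

#' Stack epoch signals into a trials-by-samples matrix
#' @param x an `spt_epochs` object (or any tibble with a `signal`
#'   list-column).
#' @return numeric matrix, one row per trial.
#' @export
epoch_matrix <- function(x) {
  do.call(rbind, x$signal)
}

epoch_meta_cols <- c("participant", "group", "task", "trial",
                     "sequence_type", "disruption_position",
                     "response_correct", "rejected")

#' Write / read epochs in the plain tabular format
#'
#' The tabular epoch format is a pair of TSV files: `<stem>_signals.tsv`, a
#' numeric matrix with one row per trial and one column per sample (header
#' `t<ms>`), and `<stem>_metadata.tsv` with the trial metadata columns
#' `participant`, `group`, `task`, `trial`, `sequence_type`,
#' `disruption_position`, `response_correct`, `rejected`.
#'
#' @param epochs an `spt_epochs` object.
#' @param stem path stem (without suffix) to write to / read from.
#' @return `write_epochs_tsv` returns `stem` invisibly; `read_epochs_tsv`
#'   returns an `spt_epochs` tibble.
#' @export
write_epochs_tsv <- function(epochs, stem) {
  times <- epoch_times(epochs)
  sig <- epoch_matrix(epochs)
  colnames(sig) <- paste0("t", format(times, trim = TRUE, scientific = FALSE))
  utils::write.table(sig, paste0(stem, "_signals.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- as.data.frame(epochs[intersect(epoch_meta_cols, names(epochs))])
  utils::write.table(meta, paste0(stem, "_metadata.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(stem)
}

#' @rdname write_epochs_tsv
#' @param sample_rate sampling rate in Hz of the stored data.
#' @export
read_epochs_tsv <- function(stem, sample_rate = 500) {
  sig <- as.matrix(utils::read.delim(paste0(stem, "_signals.tsv"),
                                     check.names = FALSE))
  meta <- as_tibble(utils::read.delim(paste0(stem, "_metadata.tsv")))
  require_cols(meta, c("participant", "group", "task", "trial",
                       "sequence_type", "response_correct"),
               "epoch metadata")
  times <- as.numeric(sub("^t", "", colnames(sig)))
  meta$signal <- lapply(seq_len(nrow(sig)), function(i) unname(sig[i, ]))
  new_epochs(meta, times = times, sample_rate = sample_rate)
}

#' Write / read a behavioural trial table as TSV
#' @param behavior a behavioural trial table ([simulate_behavior()] schema).
#' @param path file path.
#' @export
write_behavior_tsv <- function(behavior, path) {
  utils::write.table(as.data.frame(behavior), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  out <- as_tibble(utils::read.delim(path))
  require_cols(out, c("participant", "group", "task", "trial",
                      "sequence_type", "correct"), "behavior table")
  class(out) <- c("spt_behavior", class(out))
  out
}
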