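#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows across n distinct pull rename count
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd qt pt pf var median lm coef aov rnorm runif rbinom
#'   fft t.test setNames complete.cases
NULL

# Sentinel t-value used when a variance is exactly zero but the mean is not.
T_SENTINEL <- 1e6

#' Resolve a millisecond value to the nearest sample index
#'
#' Windows are closed at both ends in milliseconds and resolved to the nearest
#' sample on the epoch time axis.
#'
#' @param times numeric vector of sample times (ms), strictly increasing.
#' @param window_ms length-2 numeric, `c(lo, hi)` in ms.
#' @return integer vector of indices `lo:hi` into `times`.
#' @keywords internal
window_indices <- function(times, window_ms) {
  stopifnot(length(window_ms) == 2L, window_ms[1] <= window_ms[2])
  if (window_ms[1] < min(times) - 1e-9 || window_ms[2] > max(times) + 1e-9) {
    abort(sprintf(
      "window [%g, %g] ms lies outside the epoch time axis [%g, %g] ms",
      window_ms[1], window_ms[2], min(times), max(times)
    ))
  }
  lo <- which.min(abs(times - window_ms[1]))
  hi <- which.min(abs(times - window_ms[2]))
  if (hi < lo) abort("empty window after resolving to samples")
  lo:hi
}

#' Cumulative trapezoidal integral
#' @param x abscissa, strictly increasing.
#' @param y ordinates.
#' @return vector of the same length as `y`; first element 0.
#' @keywords internal
cumtrapz1 <- function(x, y) {
  n <- length(y)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

# Deterministic per-stage seed derivation; keeps results independent across
# stages while reproducible from one master seed. Stays below 2^31.
derive_seed <- function(seed, stage) {
  (as.integer(seed) + 97L * as.integer(stage)) %% 2147483647L
}

# Column presence check with a readable error.
require_cols <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}
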