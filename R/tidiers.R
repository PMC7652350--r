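#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a cluster permutation test
#'
#' @param x an `spt_cluster_test`.
#' @param ... unused.
#' @return the cluster table: `start_ms`, `end_ms`, `sign`, `mass`, `p`.
#' @method tidy spt_cluster_test
#' @export
tidy.spt_cluster_test <- function(x, ...) x$clusters

#' @rdname tidy.spt_cluster_test
#' @return for `glance()`, a one-row tibble of test settings.
#' @method glance spt_cluster_test
#' @export
glance.spt_cluster_test <- function(x, ...) {
  s <- x$settings
  tibble(cluster_alpha = s$cluster_alpha, t_crit = s$t_crit,
         n_participants = s$n_participants,
         n_permutations = s$n_permutations, method = s$method,
         tail = s$tail, n_clusters = nrow(x$clusters))
}

#' @method print spt_cluster_test
#' @export
print.spt_cluster_test <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<spt_cluster_test> n=%d, %s, %d permutation(s), alpha=%g\n",
              s$n_participants, s$method, s$n_permutations,
              s$cluster_alpha))
  if (nrow(x$clusters)) print(x$clusters) else cat("  no clusters\n")
  invisible(x)
}

#' Tidy jackknife latency replicates
#'
#' @param x an `spt_jackknife`.
#' @param ... unused.
#' @return the replicate table.
#' @method tidy spt_jackknife
#' @export
tidy.spt_jackknife <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.spt_jackknife
#' @return for `glance()`, one row per group: mean replicate latency, SD of
#'   replicates, N, and the measurement window.
#' @method glance spt_jackknife
#' @export
glance.spt_jackknife <- function(x, ...) {
  win <- attr(x, "window_ms")
  as_tibble(x) |>
    group_by(dplyr::across(dplyr::any_of(c("group", "task")))) |>
    summarise(sd_replicates = sd(.data$latency_ms),
              latency_ms = mean(.data$latency_ms), N = dplyr::n(),
              .groups = "drop") |>
    select("group", dplyr::any_of("task"), "latency_ms",
           "sd_replicates", "N") |>
    mutate(window_lo = win[1], window_hi = win[2],
           fraction = attr(x, "fraction"))
}

#' Tidy learning-slope fits
#' @param x an `spt_slopes` object.
#' @param ... unused.
#' @return per-participant slopes.
#' @method tidy spt_slopes
#' @export
tidy.spt_slopes <- function(x, ...) as_tibble(x)

#' @rdname tidy.spt_slopes
#' @return for `glance()`, the between-group slope t-test.
#' @method glance spt_slopes
#' @export
glance.spt_slopes <- function(x, ...) attr(x, "test")
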