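# broom-style tidiers for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn run_workflow `tidy()` returns the labelled pair table.
#' @param x a `paralog_workflow` object.
#' @param ... unused.
#' @export
tidy.paralog_workflow <- function(x, ...) x$pairs

#' @describeIn run_workflow `glance()` returns the one-row stage summary.
#' @export
glance.paralog_workflow <- function(x, ...) x$summary

#' @describeIn compare_divergence_between_origins `tidy()` returns one row
#'   per test.
#' @param x a `divergence_comparison` object.
#' @param ... unused.
#' @export
tidy.divergence_comparison <- function(x, ...) x$tests

#' @describeIn compare_divergence_between_origins `glance()` returns group
#'   means/medians and both p-values in one row.
#' @export
glance.divergence_comparison <- function(x, ...) {
  g <- x$groups
  tibble(n_1 = g$n[1], n_2 = g$n[2],
         mean_percent_id_1 = g$mean_percent_id[1],
         mean_percent_id_2 = g$mean_percent_id[2],
         mean_ks_1 = g$mean_ks[1], mean_ks_2 = g$mean_ks[2],
         median_ks_1 = g$median_ks[1], median_ks_2 = g$median_ks[2],
         p_percent_id = x$tests$p_value[x$tests$test ==
                                          "percent_id_rank_sum"][1],
         p_ks = if (any(x$tests$test == "log_ks_welch_t")) {
           x$tests$p_value[x$tests$test == "log_ks_welch_t"][1]
         } else {
           NA_real_
         },
         n_ks_excluded = x$n_ks_excluded)
}

#' @describeIn permutation_median_iqr_test `tidy()` returns one row per
#'   statistic (median, IQR).
#' @param x a `permutation_result` object.
#' @param ... unused.
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(statistic = c("median", "iqr"),
         observed_diff = c(x$observed_median_diff, x$observed_iqr_diff),
         p_value = c(x$p_median, x$p_iqr),
         p_display = c(x$p_median_display, x$p_iqr_display),
         n_rounds = x$n_rounds, seed = x$seed)
}

#' @describeIn permutation_median_iqr_test `glance()` returns a one-row
#'   summary.
#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed_median_diff = x$observed_median_diff,
         observed_iqr_diff = x$observed_iqr_diff,
         p_median = x$p_median, p_iqr = x$p_iqr,
         n_rounds = x$n_rounds, seed = x$seed, strict = x$strict)
}

#' @describeIn build_control_same_isogroup `tidy()` returns the pair table.
#' @param x a `control_pairs` object.
#' @param ... unused.
#' @export
tidy.control_pairs <- function(x, ...) x$pairs

#' @describeIn build_control_same_isogroup `glance()` returns the sampling
#'   summary.
#' @export
glance.control_pairs <- function(x, ...) {
  tibble(kind = x$kind, n_requested = x$n_requested,
         n_realized = x$n_realized, seed = x$seed)
}
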