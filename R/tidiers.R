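#' Tidy a condition comparison
#'
#' @param x A `condition_comparison` from [compare_conditions()].
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `p.value`, `method` and the
#'   two sample medians.
#' @method tidy condition_comparison
#' @export
tidy.condition_comparison <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value, method = x$method,
         median_a = x$median_a, median_b = x$median_b)
}

#' Glance at a condition comparison
#'
#' @param x A `condition_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with sample sizes, `p.value` and `method`.
#' @method glance condition_comparison
#' @export
glance.condition_comparison <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b, p.value = x$p.value, method = x$method)
}

#' Tidy a pipeline result into its per-episode table
#'
#' @param x A `caf_pipeline_result`.
#' @param ... Unused.
#' @return The episodes tibble with the run's condition attached.
#' @method tidy caf_pipeline_result
#' @export
tidy.caf_pipeline_result <- function(x, ...) {
  ep <- x$episodes
  ep$condition <- x$condition
  ep
}

#' Glance at a pipeline result
#'
#' @param x A `caf_pipeline_result`.
#' @param ... Unused.
#' @return The one-row summary tibble.
#' @method glance caf_pipeline_result
#' @export
glance.caf_pipeline_result <- function(x, ...) {
  x$summary
}
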