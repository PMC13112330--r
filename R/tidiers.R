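#' Tidy a rank test result
#'
#' One-row tibble in broom style: statistic name and value, effective sample
#' size, alternative, raw and (if set) adjusted p-value, and whether the
#' p-value came from the exact permutation distribution.
#'
#' @param x A `rank_test` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.rank_test <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    statistic = unname(x$statistic),
    statistic_name = names(x$statistic) %||% "statistic",
    n = x$n_effective,
    df = x$df,
    alternative = x$alternative,
    p_value = x$p_value,
    p_adjusted = x$p_adjusted,
    adjustment = x$adjustment,
    exact = x$exact
  )
}

#' @rdname tidy.rank_test
#' @export
glance.rank_test <- function(x, ...) tidy.rank_test(x, ...)

#' Tidy a Dunn post hoc table
#'
#' @param x A `dunn_test` tibble.
#' @param ... Unused.
#' @return The pairwise comparison tibble with the adjustment method as a
#'   column.
#' @export
tidy.dunn_test <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$adjustment <- attr(x, "adjustment") %||% NA_character_
  out
}
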