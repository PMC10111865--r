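#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an F-test association fit
#'
#' @param x A `cna_ftest` from [association_ftest()].
#' @param ... Unused.
#' @return One row per model term with estimate, standard error,
#'   statistic, and p-value.
#' @export
tidy.cna_ftest <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "x"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$slope_se),
    statistic = c(NA_real_, x$statistic),
    p.value = c(NA_real_, x$p_value)
  )
}

#' One-row summary of an F-test association fit
#'
#' @inheritParams tidy.cna_ftest
#' @return Tibble with `r.squared, statistic, p.value, nobs,
#'   perfect.fit`.
#' @export
glance.cna_ftest <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, statistic = x$statistic,
    p.value = x$p_value, nobs = x$n, perfect.fit = x$perfect_fit
  )
}

#' Tidy CNA calls into the merged segment table
#'
#' @param x A `cna_calls` object from [call_cna()].
#' @param ... Unused.
#' @return The merged, state-labeled segment tibble.
#' @export
tidy.cna_calls <- function(x, ...) {
  x$segments
}

#' One-row summary of CNA calls
#'
#' @inheritParams tidy.cna_calls
#' @return Tibble with sample id, event counts by scope, and counts of
#'   filtered/flagged segments.
#' @export
glance.cna_calls <- function(x, ...) {
  ev <- x$events
  tibble::tibble(
    sample_id = if (nrow(x$segments) > 0) x$segments$sample_id[1]
    else NA_character_,
    n_segments = nrow(x$segments),
    n_events = nrow(ev),
    n_whole = sum(ev$scope == "whole_chromosome"),
    n_arm = sum(ev$scope == "arm"),
    n_focal = sum(ev$scope == "focal"),
    n_length_filtered = nrow(x$filter_log),
    n_flagged = nrow(x$flag_log)
  )
}
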