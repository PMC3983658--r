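# broom-style tidiers for fitted/compared objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a group comparison
#'
#' One row per group with its size, mean T_rep and standard error.
#'
#' @param x A `trep_group_comparison`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.trep_group_comparison <- function(x, ...) {
  x$groups
}

#' One-row summary of a group comparison
#'
#' @param x A `trep_group_comparison`.
#' @param ... Unused.
#' @return A one-row tibble with `difference` (minutes), `statistic`, `df`,
#'   `p_value`, `method`.
#' @exportS3Method generics::glance
glance.trep_group_comparison <- function(x, ...) {
  tibble(difference = x$difference, statistic = x$statistic, df = x$df,
         p_value = x$p_value, method = x$method)
}

#' One-row summary of an oscillation profile
#'
#' @param x An [oscillation_profile()].
#' @param ... Unused.
#' @return A one-row tibble with the subset, amplitude, extreme correlations
#'   and their timepoints, and the number of significant timepoints.
#' @exportS3Method generics::glance
glance.oscillation_profile <- function(x, ...) {
  ok <- is.finite(x$r)
  tibble(
    subset = attr(x, "gene_filter") %||% "all",
    alpha = attr(x, "alpha"),
    amplitude = oscillation_amplitude(x),
    min_r = if (any(ok)) min(x$r[ok]) else NA_real_,
    min_r_time = if (any(ok)) x$time[ok][which.min(x$r[ok])] else NA_real_,
    max_r = if (any(ok)) max(x$r[ok]) else NA_real_,
    max_r_time = if (any(ok)) x$time[ok][which.max(x$r[ok])] else NA_real_,
    n_significant = sum(x$significant[ok], na.rm = TRUE),
    n_timepoints = nrow(x)
  )
}
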