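# Pearson correlation on pairwise-complete observations, the analytic
# per-timepoint significance threshold, and small profile utilities.

#' Pearson correlation on pairwise-complete pairs
#'
#' Computes the product-moment correlation after dropping pairs with a
#' missing value in either vector. The result is flagged undefined (r = NA)
#' rather than silently zero when fewer than 3 complete pairs remain or when
#' either vector is constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row tibble with columns `r`, `n_pairs`, `undefined` and
#'   `reason` (`NA`, `"insufficient_pairs"` or `"constant_input"`).
#' @export
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 2, 4))
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "repcycle_data_error")
  }
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) {
    return(tibble(r = NA_real_, n_pairs = n, undefined = TRUE,
                  reason = "insufficient_pairs"))
  }
  cx <- x[ok]
  cy <- y[ok]
  if (sd(cx) == 0 || sd(cy) == 0) {
    return(tibble(r = NA_real_, n_pairs = n, undefined = TRUE,
                  reason = "constant_input"))
  }
  tibble(r = cor(cx, cy), n_pairs = n, undefined = FALSE, reason = NA_character_)
}

#' Two-tailed significance threshold for a Pearson correlation
#'
#' Inverts the t-test for a correlation coefficient
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom):
#' returns the |r| whose two-tailed p-value equals `alpha`. For example
#' `critical_r(800, 0.0025)` is about 0.107 and `critical_r(292, 0.0025)`
#' about 0.176.
#'
#' @param n Number of pairs (>= 4).
#' @param alpha Two-tailed significance level in (0, 1).
#' @return The critical |r| in (0, 1).
#' @export
critical_r <- function(n, alpha) {
  if (!is.numeric(n) || any(n < 4) || any(n != floor(n))) {
    stop_field("n", "sample size must be an integer >= 4")
  }
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop_field("alpha", "two-tailed alpha must lie in (0, 1)")
  }
  tc <- qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + n - 2)
}

#' Fraction of variance explained
#'
#' The squared Pearson correlation of `x` and `y` on pairwise-complete pairs;
#' `NA` when the correlation is undefined.
#'
#' @inheritParams pearson_r
#' @return A scalar in `[0, 1]`, or `NA`.
#' @export
variance_explained <- function(x, y) {
  pearson_r(x, y)$r^2
}

#' Moving average of an oscillation profile's correlation series
#'
#' Replaces the correlation series by its k-point forward moving average
#' (`r'_i = mean(r_i, ..., r_{i + k - 1})`, missing values dropped within the
#' window), shortening the series by `k - 1`. A two-point average (`k = 2`)
#' is the conventional smoothing for densely sampled human time courses;
#' `k = 1` is the identity.
#'
#' @param profile An oscillation profile (see [oscillation_profile()]) or any
#'   data frame with columns `time` and `r`.
#' @param k Window length (>= 1).
#' @return A tibble with columns `time` (mean time of the window) and `r`
#'   (smoothed correlation).
#' @export
smooth_profile <- function(profile, k = 2) {
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k != floor(k)) {
    stop_field("k", "smoothing window must be an integer >= 1")
  }
  assert_columns(profile, c("time", "r"), "oscillation profile")
  n <- nrow(profile)
  if (k > n) {
    abort("smoothing window exceeds the number of timepoints",
          class = "repcycle_data_error")
  }
  idx <- seq_len(n - k + 1)
  tibble(
    time = vapply(idx, function(i) mean(profile$time[i:(i + k - 1)]), numeric(1)),
    r = vapply(idx, function(i) mean(profile$r[i:(i + k - 1)], na.rm = TRUE),
               numeric(1))
  )
}
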