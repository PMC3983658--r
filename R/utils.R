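# Internal helpers: validation, numeric formatting, coordinate conversion.

stop_field <- function(field, msg, class = "repcycle_config_error") {
  abort(paste0("Invalid `", field, "`: ", msg), class = class, field = field)
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "repcycle_data_error")
  }
  invisible(df)
}

# Format numbers for TSV output so that write -> read -> write is byte-stable.
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.10g", v)
  }, character(1))
  out
}

#' Convert 1-based inclusive coordinates to 0-based half-open
#'
#' Genomic inputs in GFF-style 1-based inclusive coordinates are converted at
#' the package boundary; everything downstream uses BED-native 0-based
#' half-open intervals. A 1 bp feature at base 7 (1-based `start = end = 7`)
#' becomes `start = 6, end = 7`.
#'
#' @param start,end Integer vectors of 1-based inclusive coordinates.
#' @return A list with elements `start` and `end` in 0-based half-open form.
#' @export
#' @examples
#' from_one_based(7, 7) # list(start = 6, end = 7)
from_one_based <- function(start, end) {
  if (any(start < 1) || any(end < start)) {
    abort("1-based inclusive coordinates require start >= 1 and end >= start",
          class = "repcycle_data_error")
  }
  list(start = as.integer(start) - 1L, end = as.integer(end))
}

# Interval midpoint under the 0-based half-open convention.
interval_midpoint <- function(start, end) {
  as.integer(floor((as.numeric(start) + as.numeric(end)) / 2))
}

# Strand-aware 5' end: first covered base for "+", last covered base for "-".
five_prime_end <- function(start, end, strand) {
  ifelse(strand == "+", as.numeric(start), as.numeric(end) - 1)
}

s_bounds <- function(profile) {
  s <- c(attr(profile, "s_start"), attr(profile, "s_end"))
  if (length(s) != 2 || any(!is.finite(s))) {
    abort("profile is missing its S-phase bounds; build it with trep_profile()",
          class = "repcycle_data_error")
  }
  s
}
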