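# Decile binning by T_rep, top/bottom group comparisons (Student's t), and
# the copy-number correction of asynchronous expression levels.

new_group_comparison <- function(groups, difference, statistic, df, p_value,
                                 method) {
  structure(
    list(groups = groups, difference = difference, statistic = statistic,
         df = df, p_value = p_value, method = method),
    class = "trep_group_comparison"
  )
}

#' @export
print.trep_group_comparison <- function(x, ...) {
  cat("Group comparison of mean T_rep (", x$method, ")\n", sep = "")
  print(x$groups)
  cat(sprintf("difference = %.4g, t = %.4g, df = %.4g, two-tailed p = %.4g\n",
              x$difference, x$statistic, x$df, x$p_value))
  invisible(x)
}

# Student's (pooled) or Welch's two-sample t-test with guards for the
# degenerate zero-variance cases that arise in constructed examples.
two_group_t <- function(g1, g2, var_equal = TRUE) {
  m1 <- mean(g1); m2 <- mean(g2)
  v1 <- var(g1); v2 <- var(g2)
  n1 <- length(g1); n2 <- length(g2)
  if (v1 == 0 && v2 == 0) {
    if (m1 == m2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p = 0))
  }
  ht <- stats::t.test(g1, g2, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

group_comparison <- function(g1, g2, labels, var_equal = TRUE) {
  tt <- two_group_t(g1, g2, var_equal)
  groups <- tibble(
    group = labels,
    n = c(length(g1), length(g2)),
    mean_trep = c(mean(g1), mean(g2)),
    se_trep = c(sd(g1) / sqrt(length(g1)), sd(g2) / sqrt(length(g2)))
  )
  new_group_comparison(
    groups, difference = mean(g1) - mean(g2), statistic = tt$t, df = tt$df,
    p_value = tt$p,
    method = if (var_equal) "Student's t, pooled variance" else "Welch's t"
  )
}

# Deterministic expression ranking: ties broken lexicographically by gene id,
# with a note when ties span a selection boundary.
rank_by <- function(ids, values, decreasing) {
  ord <- order(values, ids, decreasing = c(decreasing, FALSE), method = "radix")
  ord
}

check_boundary_ties <- function(values, ord, k, what) {
  if (k < length(ord) && values[ord[k]] == values[ord[k + 1]]) {
    inform(sprintf(
      "%s: ties span the rank-%d boundary; broken lexicographically by gene id",
      what, k))
  }
}

#' Median expression within T_rep deciles
#'
#' Ranks genes by increasing T_rep (ties broken by gene id), splits them into
#' 10 bins whose sizes differ by at most one (the remainder going to the
#' earliest bins), and reports the median expression per bin. With a
#' timepoint that tracks S-phase transcription, a flat profile over early
#' deciles and a decline over late deciles indicates the association is
#' confined to late-replicating genes.
#'
#' @param data Data frame with one row per gene.
#' @param trep,expression Columns of `data` holding T_rep and the expression
#'   value at the chosen timepoint (tidy-eval; defaults `trep`, `value`).
#' @param gene_id Column holding gene ids (used for deterministic tie
#'   breaking); default `gene_id`.
#' @return A tibble of class `trep_decile_table`: `decile` (1 = earliest),
#'   `n`, `median_expression`, `trep_min`, `trep_max`.
#' @export
decile_median_expression <- function(data, trep = trep, expression = value,
                                     gene_id = gene_id) {
  df <- tibble(
    gene_id = as.character(dplyr::pull(data, {{ gene_id }})),
    trep = dplyr::pull(data, {{ trep }}),
    expression = dplyr::pull(data, {{ expression }})
  ) %>%
    filter(is.finite(.data$trep), !is.na(.data$expression))
  n <- nrow(df)
  if (n < 10) {
    abort("decile binning needs at least 10 genes with both T_rep and expression",
          class = "repcycle_data_error")
  }
  ord <- rank_by(df$gene_id, df$trep, decreasing = FALSE)
  df <- df[ord, ]
  base <- n %/% 10
  extra <- n %% 10
  sizes <- rep(base, 10) + c(rep(1, extra), rep(0, 10 - extra))
  df$decile <- rep(seq_len(10), times = sizes)
  out <- df %>%
    group_by(.data$decile) %>%
    summarise(
      n = dplyr::n(),
      median_expression = median(.data$expression),
      trep_min = min(.data$trep),
      trep_max = max(.data$trep),
      .groups = "drop"
    )
  class(out) <- c("trep_decile_table", class(out))
  out
}

#' Mean T_rep of the most-induced versus most-repressed decile
#'
#' Takes the top and bottom 10% of genes by expression at the chosen
#' timepoint and compares their mean T_rep with a two-tailed two-sample
#' t-test (Student's pooled-variance by default).
#'
#' @inheritParams decile_median_expression
#' @param var_equal Use the pooled-variance Student's t-test (default);
#'   `FALSE` gives Welch's test.
#' @return A `trep_group_comparison` (groups `induced`, `repressed`); see
#'   also [tidy()][generics::tidy] and [glance()][generics::glance] methods.
#' @export
decile_extremes_trep <- function(data, trep = trep, expression = value,
                                 gene_id = gene_id, var_equal = TRUE) {
  df <- tibble(
    gene_id = as.character(dplyr::pull(data, {{ gene_id }})),
    trep = dplyr::pull(data, {{ trep }}),
    expression = dplyr::pull(data, {{ expression }})
  ) %>%
    filter(is.finite(.data$trep), !is.na(.data$expression))
  n <- nrow(df)
  if (n < 20) {
    abort("extreme-decile comparison needs at least 20 genes",
          class = "repcycle_data_error")
  }
  k <- n %/% 10
  ord_hi <- rank_by(df$gene_id, df$expression, decreasing = TRUE)
  ord_lo <- rank_by(df$gene_id, df$expression, decreasing = FALSE)
  check_boundary_ties(df$expression, ord_hi, k, "decile_extremes_trep")
  induced <- df$trep[ord_hi[seq_len(k)]]
  repressed <- df$trep[ord_lo[seq_len(k)]]
  group_comparison(induced, repressed, c("induced", "repressed"), var_equal)
}

#' Mean T_rep of the k highest- versus k lowest-expressed genes
#'
#' Compares mean T_rep between the `k` genes with the highest and the `k`
#' with the lowest asynchronous expression level (two-tailed t-test). Ties
#' spanning the k-th rank are broken lexicographically by gene id and noted.
#'
#' @param async Asynchronous expression table (`gene_id`, `level`).
#' @param gene_trep Gene table with a `trep` column.
#' @param k Group size (default 100).
#' @param var_equal Pooled-variance Student's t-test (default) or Welch.
#' @return A `trep_group_comparison` (groups `top`, `bottom`).
#' @export
compare_top_bottom_expression <- function(async, gene_trep, k = 100,
                                          var_equal = TRUE) {
  assert_columns(async, c("gene_id", "level"), "asynchronous expression table")
  assert_columns(gene_trep, c("gene_id", "trep"), "gene table")
  df <- dplyr::inner_join(async, gene_trep[, c("gene_id", "trep")],
                          by = "gene_id") %>%
    filter(is.finite(.data$trep), is.finite(.data$level))
  if (nrow(df) < 2 * k) {
    abort(sprintf("need at least 2k = %d genes with T_rep and level; have %d",
                  2 * k, nrow(df)),
          class = "repcycle_data_error")
  }
  ord_hi <- rank_by(df$gene_id, df$level, decreasing = TRUE)
  ord_lo <- rank_by(df$gene_id, df$level, decreasing = FALSE)
  check_boundary_ties(df$level, ord_hi, k, "compare_top_bottom_expression")
  top <- df$trep[ord_hi[seq_len(k)]]
  bottom <- df$trep[ord_lo[seq_len(k)]]
  group_comparison(top, bottom, c("top", "bottom"), var_equal)
}

#' Correct asynchronous expression for replication copy number
#'
#' A gene replicated at time `trep` spends a fraction
#' `f = (cycle_length - trep) / cycle_length` of the cycle with two copies,
#' inflating its apparent asynchronous expression. The correction subtracts a
#' fraction of each level proportional to that time:
#' `corrected = level * (1 - kappa * f)`. With the default `kappa = 0.5` the
#' correction agrees with exact per-copy normalization `level / (1 + f)` at
#' both endpoints `f = 0` and `f = 1`.
#'
#' @param async Asynchronous expression table with `per_copy_normalized`
#'   FALSE.
#' @param gene_trep Gene table with a `trep` column on the same clock as
#'   `cycle_length` (minutes from release).
#' @param cycle_length Cell-cycle length in minutes; must exceed every
#'   observed T_rep.
#' @param kappa Correction strength in `[0, 1]`; 0.5 by default (see above).
#' @return `async` with corrected `level` and `per_copy_normalized = TRUE`;
#'   genes without T_rep keep their level unchanged.
#' @export
copy_number_correction <- function(async, gene_trep, cycle_length,
                                   kappa = 0.5) {
  assert_columns(async, c("gene_id", "level", "per_copy_normalized"),
                 "asynchronous expression table")
  assert_columns(gene_trep, c("gene_id", "trep"), "gene table")
  if (any(async$per_copy_normalized)) {
    abort("levels are already per-copy normalized", class = "repcycle_data_error")
  }
  if (!is.numeric(kappa) || kappa < 0 || kappa > 1) {
    stop_field("kappa", "correction strength must lie in [0, 1]")
  }
  df <- left_join(async, gene_trep[, c("gene_id", "trep")], by = "gene_id")
  f <- (cycle_length - df$trep) / cycle_length
  bad <- which(is.finite(f) & (f < 0 | f > 1))
  if (length(bad) > 0) {
    abort(sprintf(
      "two-copy fraction outside [0, 1] for gene %s; cycle_length inconsistent with T_rep",
      df$gene_id[bad[1]]), class = "repcycle_data_error")
  }
  corrected <- ifelse(is.finite(f), df$level * (1 - kappa * f), df$level)
  mutate(async, level = corrected, per_copy_normalized = TRUE)
}
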