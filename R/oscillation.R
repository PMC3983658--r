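# The oscillation profile: the per-timepoint Pearson correlation between
# cell-cycle expression and per-gene T_rep, plus peak-expression-time
# ordering and the T_rep moving average along it.

#' Per-timepoint correlation between expression and replication timing
#'
#' For each timepoint of the synchronized time course, computes the Pearson
#' correlation (pairwise-complete) between the genes' log2 expression ratios
#' at that timepoint and their T_rep. Under this sign convention a positive r
#' means up-regulated genes tend to replicate late, a negative r that
#' up-regulated genes replicate early. Each row carries the analytic
#' significance threshold [critical_r()] at its own pair count.
#'
#' @param expr Long-form expression tibble (`gene_id`, `time`, `phase`,
#'   `value`), as from [read_expression()] or [simulate_cc_expression()].
#' @param gene_trep Gene table with a `trep` column; rows with labels
#'   (`early_late`, `ori_proximal`) enable `gene_filter`.
#' @param alpha Two-tailed significance level for the per-timepoint
#'   threshold (no multiple-testing correction across timepoints; compare the
#'   number of significant timepoints with `alpha * n_timepoints` expected by
#'   chance).
#' @param gene_filter Optional subset: one of `"early"`, `"late"`
#'   (requires an `early_late` column), `"proximal"`, `"distal"` (requires
#'   `ori_proximal`).
#' @return A tibble of class `oscillation_profile` with columns `time`,
#'   `phase`, `r`, `n_pairs`, `critical_r`, `significant`; attribute `alpha`.
#' @export
oscillation_profile <- function(expr, gene_trep, alpha = 0.0025,
                                gene_filter = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop_field("alpha", "two-tailed alpha must lie in (0, 1)")
  }
  assert_columns(expr, c("gene_id", "time", "phase", "value"), "expression table")
  assert_columns(gene_trep, c("gene_id", "trep"), "gene table")
  genes <- gene_trep
  if (!is.null(gene_filter)) {
    gene_filter <- match.arg(gene_filter, c("early", "late", "proximal", "distal"))
    genes <- switch(gene_filter,
      early = {
        assert_columns(genes, "early_late", "gene table")
        filter(genes, .data$early_late == "early")
      },
      late = {
        assert_columns(genes, "early_late", "gene table")
        filter(genes, .data$early_late == "late")
      },
      proximal = {
        assert_columns(genes, "ori_proximal", "gene table")
        filter(genes, .data$ori_proximal)
      },
      distal = {
        assert_columns(genes, "ori_proximal", "gene table")
        filter(genes, !.data$ori_proximal)
      }
    )
  }
  joined <- dplyr::inner_join(expr, genes[, c("gene_id", "trep")], by = "gene_id")
  n_lost <- length(setdiff(unique(expr$gene_id), genes$gene_id))
  if (is.null(gene_filter) && n_lost > 0) {
    inform(sprintf(
      "oscillation_profile: %d expression gene(s) absent from the T_rep table were excluded",
      n_lost))
  }
  out <- joined %>%
    group_by(.data$time, .data$phase) %>%
    summarise(res = list(pearson_r(.data$value, .data$trep)), .groups = "drop") %>%
    tidyr::unnest("res") %>%
    arrange(.data$time)
  out <- out %>%
    mutate(
      critical_r = ifelse(.data$n_pairs >= 4, critical_r(pmax(.data$n_pairs, 4), alpha), NA_real_),
      significant = abs(.data$r) > .data$critical_r
    ) %>%
    select("time", "phase", "r", "n_pairs", "critical_r", "significant")
  attr(out, "alpha") <- alpha
  attr(out, "gene_filter") <- gene_filter %||% "all"
  class(out) <- c("oscillation_profile", class(out))
  out
}

#' Oscillation amplitude of a profile
#'
#' The range (max r - min r) of the correlation series, ignoring missing
#' values. Used to compare the strength of the oscillation between gene
#' subsets (e.g. ORI-proximal versus distal).
#'
#' @param profile An [oscillation_profile()].
#' @return A scalar amplitude.
#' @export
oscillation_amplitude <- function(profile) {
  assert_columns(profile, "r", "oscillation profile")
  r <- profile$r[is.finite(profile$r)]
  if (length(r) == 0) return(NA_real_)
  diff(range(r))
}

#' Time of maximal expression for each gene
#'
#' Returns, per gene, the timepoint at which its expression is maximal; ties
#' are broken by the earliest timepoint. Genes with no observed values get
#' `NA`.
#'
#' @param expr Long-form expression tibble.
#' @return A tibble with columns `gene_id`, `peak_time`.
#' @export
peak_expression_time <- function(expr) {
  assert_columns(expr, c("gene_id", "time", "value"), "expression table")
  expr %>%
    arrange(.data$gene_id, .data$time) %>%
    group_by(.data$gene_id) %>%
    summarise(peak_time = if (all(is.na(.data$value))) NA_real_ else
      .data$time[which.max(.data$value)], .groups = "drop")
}

#' Moving average of T_rep along the peak-expression-time ordering
#'
#' Orders genes by their time of maximal expression (linear from mitosis,
#' non-wrapping; ties broken by gene id for determinism) and slides a window
#' of `window` consecutive genes in steps of one, reporting each window's
#' mean T_rep and standard error (`sd / sqrt(window)`). Genes without T_rep
#' or peak time are dropped first.
#'
#' @param gene_trep Gene table with a `trep` column.
#' @param peak_times Tibble from [peak_expression_time()].
#' @param window Number of genes per window (>= 2); 100 suits budding-yeast-
#'   sized gene lists, 60 smaller ones.
#' @param circular If `TRUE`, windows wrap around the end of the ordering.
#'   Off by default (the ordering begins immediately after mitosis).
#' @return A tibble of class `trep_moving_average` with columns
#'   `window_index`, `peak_time` (the center gene's peak time), `mean_trep`,
#'   `se_trep`.
#' @export
trep_moving_average <- function(gene_trep, peak_times, window = 100,
                                circular = FALSE) {
  if (!is.numeric(window) || length(window) != 1 || window < 2 ||
      window != floor(window)) {
    stop_field("window", "moving-average window must be an integer >= 2")
  }
  assert_columns(gene_trep, c("gene_id", "trep"), "gene table")
  assert_columns(peak_times, c("gene_id", "peak_time"), "peak time table")
  dat <- gene_trep %>%
    dplyr::inner_join(peak_times, by = "gene_id") %>%
    filter(is.finite(.data$trep), is.finite(.data$peak_time)) %>%
    arrange(.data$peak_time, .data$gene_id)
  n <- nrow(dat)
  if (window > n) {
    abort(sprintf("window (%d) exceeds the %d ordered genes with T_rep", window, n),
          class = "repcycle_data_error")
  }
  x <- dat$trep
  pt <- dat$peak_time
  if (circular) {
    x <- c(x, x[seq_len(window - 1)])
    pt <- c(pt, pt[seq_len(window - 1)])
  }
  means <- zoo::rollmean(x, k = window, align = "left")
  sds <- zoo::rollapply(x, width = window, FUN = sd, align = "left")
  centers <- seq_along(means) + (ceiling(window / 2) - 1)
  tibble(
    window_index = seq_along(means),
    peak_time = pt[centers],
    mean_trep = means,
    se_trep = sds / sqrt(window)
  ) -> out
  class(out) <- c("trep_moving_average", class(out))
  out
}
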