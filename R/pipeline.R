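# Orchestration: validated run configuration, the simulate/associate/report
# stages, and the reproducibility manifest. inst/exec/repcycle is a thin
# command-line front-end over these functions.

#' Build and validate a run configuration
#'
#' Collects the dataset-specific constants of the analysis: input paths (or
#' simulation parameters), the per-timepoint significance level, the
#' early/late fraction, the ORI-proximity cutoff, which timepoints represent
#' G2 and M/G1 expression, the moving-average window, smoothing, and the
#' t-test variant. Invalid fields raise a `repcycle_config_error` naming the
#' field.
#'
#' @param genes,oris,trep,expression,async Input file paths (the `associate`
#'   stage requires them to exist at run time).
#' @param s_start,s_end S-phase bounds of the T_rep profile input (minutes).
#' @param alpha Two-tailed per-timepoint significance level.
#' @param early_late_fraction Position of the early/late cutoff within S
#'   phase, in (0, 1).
#' @param ori_proximal_bp ORI-proximity cutoff in bp.
#' @param g2_time,mg1_time Timepoints (minutes) representing G2 and M/G1
#'   expression; `NULL` picks the first timepoint carrying that phase label.
#' @param ma_window Moving-average window in genes.
#' @param smooth_k Moving-average length for plotting the correlation series
#'   (1 = no smoothing; 2 suits densely sampled human-style courses).
#' @param var_equal Pooled-variance Student's t-test (default) or Welch.
#' @param top_bottom_k Group size for the highest/lowest asynchronous
#'   expression comparison.
#' @param seed Integer seed recorded in the manifest.
#' @param sim A [sim_params()] list for the `simulate` stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genes = NULL, oris = NULL, trep = NULL,
                       expression = NULL, async = NULL,
                       s_start = 30, s_end = 60,
                       alpha = 0.0025, early_late_fraction = 0.5,
                       ori_proximal_bp = 35000,
                       g2_time = NULL, mg1_time = NULL,
                       ma_window = 100, smooth_k = 1, var_equal = TRUE,
                       top_bottom_k = 100, seed = 1L, sim = NULL) {
  num_in <- function(x, field, lo, hi, open = TRUE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) ||
        (open && (x <= lo || x >= hi)) || (!open && (x < lo || x > hi))) {
      stop_field(field, sprintf("must be a number in %s%g, %g%s",
                                if (open) "(" else "[", lo, hi,
                                if (open) ")" else "]"))
    }
  }
  num_in(alpha, "alpha", 0, 1)
  num_in(early_late_fraction, "early_late_fraction", 0, 1)
  if (!is.numeric(ori_proximal_bp) || ori_proximal_bp <= 0) {
    stop_field("ori_proximal_bp", "must be a positive number of bp")
  }
  if (!is.numeric(ma_window) || ma_window < 2 || ma_window != floor(ma_window)) {
    stop_field("ma_window", "must be an integer >= 2")
  }
  if (!is.numeric(smooth_k) || smooth_k < 1 || smooth_k != floor(smooth_k)) {
    stop_field("smooth_k", "must be an integer >= 1")
  }
  if (!is.numeric(top_bottom_k) || top_bottom_k < 2) {
    stop_field("top_bottom_k", "must be an integer >= 2")
  }
  if (!is.logical(var_equal) || length(var_equal) != 1 || is.na(var_equal)) {
    stop_field("var_equal", "must be TRUE or FALSE")
  }
  if (!is.null(sim) && !inherits(sim, "sim_params")) {
    stop_field("sim", "must be a sim_params() list")
  }
  if (s_start >= s_end) stop_field("s_start/s_end", "must satisfy s_start < s_end")
  structure(list(
    genes = genes, oris = oris, trep = trep, expression = expression,
    async = async, s_start = s_start, s_end = s_end, alpha = alpha,
    early_late_fraction = early_late_fraction,
    ori_proximal_bp = ori_proximal_bp, g2_time = g2_time,
    mg1_time = mg1_time, ma_window = ma_window, smooth_k = smooth_k,
    var_equal = var_equal, top_bottom_k = top_bottom_k,
    seed = as.integer(seed), sim = sim
  ), class = "run_config")
}

require_inputs <- function(config, fields) {
  for (f in fields) {
    p <- config[[f]]
    if (is.null(p)) stop_field(f, "input path is required for this stage")
    if (!file.exists(p)) stop_field(f, sprintf("input file not found: %s", p))
  }
}

#' Simulate stage: write a synthetic dataset directory
#'
#' @param config A [run_config()] whose `sim` field holds the
#'   [sim_params()]; the configured `seed` overrides the one in `sim`.
#' @param outdir Output directory.
#' @return The simulated dataset list, invisibly.
#' @export
cmd_simulate <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim %||% sim_params()
  sim$seed <- config$seed
  simulate_dataset(sim, outdir = outdir)
}

pick_phase_time <- function(tp, phase_label, override, field) {
  if (!is.null(override)) {
    if (!override %in% tp$time) {
      stop_field(field, sprintf("timepoint %s not present in the expression data",
                                format(override)))
    }
    return(override)
  }
  hit <- tp$time[tp$phase == phase_label]
  if (length(hit) == 0) {
    stop_field(field, sprintf("no timepoint labelled %s in the expression data",
                              phase_label))
  }
  hit[1]
}

#' Associate stage: run the full analysis and write report tables
#'
#' Reads the five inputs, maps T_rep onto genes, labels early/late and
#' ORI-proximity strata, and writes `oscillation_profile.tsv` (overall plus
#' the four strata), `moving_average.tsv`, `decile_table.tsv`,
#' `comparisons.tsv` and a JSON manifest with the configuration, seed, input
#' hashes and package version.
#'
#' @param config A [run_config()] with all five input paths set.
#' @param outdir Output directory for the report tables.
#' @return A list with all computed objects, invisibly.
#' @export
cmd_associate <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  require_inputs(config, c("genes", "oris", "trep", "expression", "async"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  genes <- read_genes(config$genes)
  oris <- read_oris(config$oris)
  profile <- read_trep_profile(config$trep, config$s_start, config$s_end)
  expr <- read_expression(config$expression)
  async <- read_async(config$async)

  gene_trep <- genes %>%
    interpolate_trep(profile) %>%
    classify_early_late(profile, config$early_late_fraction) %>%
    nearest_ori_distance(oris) %>%
    classify_ori_proximity(config$ori_proximal_bp)

  subsets <- c(all = list(NULL), list(early = "early", late = "late",
                                      proximal = "proximal", distal = "distal"))
  osc <- purrr::imap(subsets, function(flt, nm) {
    prof <- tryCatch(
      oscillation_profile(expr, gene_trep, alpha = config$alpha,
                          gene_filter = flt),
      error = function(e) NULL)
    if (is.null(prof)) return(NULL)
    mutate(as_tibble(prof), subset = nm, .before = 1)
  })
  osc_table <- bind_rows(osc)
  if (config$smooth_k > 1) {
    osc_table <- osc_table %>%
      group_by(.data$subset) %>%
      mutate(r_smoothed = c(smooth_profile(
        tibble(time = .data$time, r = .data$r), config$smooth_k)$r,
        rep(NA_real_, config$smooth_k - 1))) %>%
      ungroup()
  }

  tp <- expression_timepoints(expr)
  g2_time <- pick_phase_time(tp, "G2", config$g2_time, "g2_time")
  mg1_time <- pick_phase_time(tp, "M/G1", config$mg1_time, "mg1_time")

  peak_times <- peak_expression_time(expr)
  ma <- trep_moving_average(gene_trep, peak_times,
                            window = min(config$ma_window,
                                         sum(is.finite(gene_trep$trep))))

  expr_g2 <- filter(expr, .data$time == g2_time) %>%
    select("gene_id", "value")
  decile_data <- dplyr::inner_join(gene_trep, expr_g2, by = "gene_id")
  deciles <- decile_median_expression(decile_data)

  extremes <- decile_extremes_trep(decile_data, var_equal = config$var_equal)
  top_bottom <- compare_top_bottom_expression(
    async, gene_trep, k = min(config$top_bottom_k,
                              nrow(gene_trep) %/% 2),
    var_equal = config$var_equal)
  comparisons <- bind_rows(
    mutate(generics::glance(extremes), comparison = "induced_vs_repressed_g2",
           .before = 1),
    mutate(generics::glance(top_bottom), comparison = "top_vs_bottom_async",
           .before = 1)
  )

  write_table(osc_table, file.path(outdir, "oscillation_profile.tsv"))
  write_table(as_tibble(ma), file.path(outdir, "moving_average.tsv"))
  write_table(as_tibble(deciles), file.path(outdir, "decile_table.tsv"))
  write_table(comparisons, file.path(outdir, "comparisons.tsv"))
  write_table(gene_trep, file.path(outdir, "gene_trep.tsv"))

  manifest <- list(
    package = "repcycle",
    version = as.character(utils::packageVersion("repcycle")),
    seed = config$seed,
    config = config[setdiff(names(config), "sim")],
    g2_time = g2_time, mg1_time = mg1_time,
    input_md5 = setNames(as.list(unname(tools::md5sum(c(
      config$genes, config$oris, config$trep, config$expression, config$async
    )))), c("genes", "oris", "trep", "expression", "async")),
    n_genes = nrow(genes),
    n_genes_with_trep = sum(is.finite(gene_trep$trep))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  invisible(list(gene_trep = gene_trep, oscillation = osc_table,
                 moving_average = ma, deciles = deciles,
                 comparisons = comparisons, g2_time = g2_time,
                 mg1_time = mg1_time))
}

#' Report stage: summarize the association tables as text
#'
#' @param tables_dir Directory written by [cmd_associate()].
#' @return Character vector of summary lines, invisibly; also printed.
#' @export
cmd_report <- function(tables_dir) {
  path <- file.path(tables_dir, "oscillation_profile.tsv")
  if (!file.exists(path)) {
    stop_field("tables_dir", sprintf("no oscillation_profile.tsv under %s",
                                     tables_dir))
  }
  osc <- readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
  lines <- c("Oscillation of the expression/T_rep correlation by gene subset:")
  for (nm in unique(osc$subset)) {
    sub <- osc[osc$subset == nm & is.finite(osc$r), ]
    lines <- c(lines, sprintf(
      " %-9s amplitude %.3f (min r %+.3f at %g min, max r %+.3f at %g min), %d/%d significant",
      nm, diff(range(sub$r)), min(sub$r), sub$time[which.min(sub$r)],
      max(sub$r), sub$time[which.max(sub$r)],
      sum(sub$significant, na.rm = TRUE), nrow(sub)))
  }
  cmp_path <- file.path(tables_dir, "comparisons.tsv")
  if (file.exists(cmp_path)) {
    cmp <- readr::read_tsv(cmp_path, progress = FALSE, show_col_types = FALSE)
    lines <- c(lines, "Group comparisons of mean T_rep:")
    lines <- c(lines, sprintf(
      " %-24s difference %+.2f min (t = %.2f, p = %.3g)",
      cmp$comparison, cmp$difference, cmp$statistic, cmp$p_value))
  }
  writeLines(lines)
  invisible(lines)
}
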