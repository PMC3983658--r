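# Truth-tracked synthetic data: genome layout, ORI firing program with
# expression-to-firing-time coupling, fork-progression T_rep rendering,
# sinusoidal cell-cycle expression, and correlated asynchronous levels.
# Every stage is a pure function of the parameters (including the seed).

#' Simulation parameters
#'
#' Builds the validated parameter list consumed by all `simulate_*`
#' functions. The defaults define the reference synthetic study conditions:
#' a 2 x 2 Mb genome with 400 genes and 40 origins, ORI firing times drawn
#' late-skewed on a 30-50 min firing window inside a 90 min cycle, forks at
#' 2.9 kb/min, 9 expression timepoints spanning just under two cycles, and
#' expression-to-firing-time coupling (`beta`, minutes of firing advance per
#' unit mean S-phase expression) restricted to late-firing origins.
#'
#' @param seed Integer seed; every simulated output is a deterministic
#'   function of the parameters including this seed.
#' @param n_chrom,chrom_length Number of chromosomes and their length (bp).
#' @param n_genes,n_oris Total gene and origin counts (split evenly across
#'   chromosomes).
#' @param fork_speed Replication fork speed in kb/min.
#' @param s_start,s_end Bounds of the ORI firing window, minutes after
#'   release.
#' @param s_phase_end End of S phase as annotated on the rendered profile
#'   (>= `s_end`; fork progression continues replicating sequence after the
#'   last origin fires, so bulk DNA synthesis ends later than the firing
#'   window).
#' @param cycle_length Cell-cycle length in minutes.
#' @param timepoints Sampling times (minutes) of the expression time course;
#'   must be strictly increasing and span at least one cycle.
#' @param amplitude_mean,amplitude_sd Mean and sd of the per-gene oscillation
#'   amplitude `A_g` (log2 units; truncated below at 0.1).
#' @param noise_sd Per-observation expression noise sd (log2 units).
#' @param beta Coupling strength: minutes of firing-time advance per unit
#'   mean S-phase expression near the origin. `beta = 0` disables coupling.
#' @param coupling_mode One of `"none"`, `"all_oris"`,
#'   `"late_ori_proximal"` (adjust only origins with base firing time past
#'   the S midpoint; the default, matching the observation that the
#'   association is confined to late-firing origins).
#' @param coupling_radius Genes within this distance (bp) of a coupled
#'   origin's point are the coupled genes.
#' @param coupled_phase_jitter Coupled genes peak at a phase drawn uniformly
#'   from `[s_end, s_end + coupled_phase_jitter]` minutes (early G2), so
#'   their transcript level rises through S phase.
#' @param firing_shape Shape `a` of the `Beta(a, 1)` draw of base firing
#'   times on the firing window; `a = 2` skews firing late (few early, many
#'   late origins).
#' @param probe_spacing Spacing of profile probes in bp.
#' @param gamma Coupling of asynchronous level to mean S-phase expression
#'   (`level = exp(base + gamma * E_S + noise)`).
#' @param async_base_mean,async_base_sd,async_noise_sd Log-scale location,
#'   spread and noise of asynchronous levels.
#' @param status_probs Probabilities of ORI status `confirmed`/`likely` for
#'   firing origins.
#' @param n_decoy_oris Number of additional `dubious` annotations: decoy
#'   entries at random positions that never fire (emulating false-positive
#'   origin calls, which the status filter of [read_oris()] removes).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(seed = 1L,
                       n_chrom = 2L,
                       chrom_length = 2e6,
                       n_genes = 400L,
                       n_oris = 40L,
                       fork_speed = 2.9,
                       s_start = 30,
                       s_end = 50,
                       s_phase_end = 60,
                       cycle_length = 90,
                       timepoints = seq(0, 160, by = 20),
                       amplitude_mean = 1,
                       amplitude_sd = 0.25,
                       noise_sd = 0.2,
                       beta = 4,
                       coupling_mode = c("late_ori_proximal", "all_oris", "none"),
                       coupling_radius = 35000,
                       coupled_phase_jitter = 4,
                       firing_shape = 2,
                       probe_spacing = 2000,
                       gamma = 0.8,
                       async_base_mean = log(10),
                       async_base_sd = 1,
                       async_noise_sd = 0.3,
                       status_probs = c(confirmed = 0.7, likely = 0.3),
                       n_decoy_oris = 4L) {
  coupling_mode <- match.arg(coupling_mode)
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^31 - 10000) {
    stop_field("seed", "seed must be an integer below 2^31 - 10000 in magnitude")
  }
  if (!(s_start < s_end && s_end < cycle_length)) {
    stop_field("s_start/s_end/cycle_length",
               "must satisfy s_start < s_end < cycle_length")
  }
  if (s_phase_end < s_end || s_phase_end >= cycle_length) {
    stop_field("s_phase_end", "must satisfy s_end <= s_phase_end < cycle_length")
  }
  if (fork_speed <= 0) stop_field("fork_speed", "must be > 0")
  if (beta < 0) stop_field("beta", "must be >= 0")
  if (any(diff(timepoints) <= 0)) {
    stop_field("timepoints", "must be strictly increasing")
  }
  if (max(timepoints) - min(timepoints) < cycle_length) {
    stop_field("timepoints", "must span at least one cell cycle")
  }
  if (coupling_radius <= 0) stop_field("coupling_radius", "must be > 0")
  if (noise_sd < 0 || amplitude_sd < 0) {
    stop_field("noise_sd/amplitude_sd", "must be >= 0")
  }
  structure(as.list(environment()), class = "sim_params")
}

chrom_names <- function(params) paste0("chr", seq_len(params$n_chrom))

split_counts <- function(total, k) diff(round(seq(0, total, length.out = k + 1)))

#' Cell-cycle phase label of a time
#'
#' Maps minutes since release onto the phase partition used by the
#' generator: M/G1 around division (the last 5 minutes of the cycle plus the
#' first half of G1), then G1 until `s_start`, S until `s_end`, G2 for the
#' first half of the remainder, and M for the rest.
#'
#' @param t Numeric vector of times (minutes).
#' @param params A [sim_params()] list.
#' @return Character vector of phase labels.
#' @export
cycle_phase <- function(t, params) {
  tc <- t %% params$cycle_length
  g1_split <- params$s_start / 2
  g2_end <- params$s_end + (params$cycle_length - params$s_end) / 2
  m_end <- params$cycle_length - 5
  dplyr::case_when(
    tc < g1_split | tc >= m_end ~ "M/G1",
    tc < params$s_start ~ "G1",
    tc < params$s_end ~ "S",
    tc < g2_end ~ "G2",
    TRUE ~ "M"
  )
}

# Place n non-overlapping intervals of the given lengths (plus a minimum gap)
# uniformly on [0, chrom_length).
place_intervals <- function(n, lengths, chrom_length, min_gap) {
  need <- sum(lengths) + (n - 1) * min_gap
  if (n > 0 && need > chrom_length) {
    abort(sprintf(
      "infeasible density: %d features need %.0f bp but the chromosome has %.0f",
      n, need, chrom_length), class = "repcycle_config_error")
  }
  if (n == 0) return(numeric(0))
  free <- chrom_length - need
  offsets <- sort(runif(n, 0, free))
  starts <- offsets + cumsum(c(0, lengths[-n] + min_gap))
  floor(starts)
}

#' Simulate the genome layout: genes and origins
#'
#' Draws non-overlapping gene intervals with random strands and origin
#' intervals with a minimum spacing, uniformly over each chromosome, plus
#' each origin's base firing time (before any coupling adjustment), drawn
#' `s_start + (s_end - s_start) * Beta(firing_shape, 1)`. A further
#' `n_decoy_oris` dubious annotations are added at random positions with no
#' firing time (they never fire). Deterministic given the seed.
#'
#' @param params A [sim_params()] list.
#' @return A list with elements `genes` (gene table) and `oris` (ORI table
#'   with `base_time`).
#' @export
simulate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed + 101L, {
    gene_counts <- split_counts(params$n_genes, params$n_chrom)
    ori_counts <- split_counts(params$n_oris, params$n_chrom)
    genes <- list()
    oris <- list()
    for (ci in seq_len(params$n_chrom)) {
      ng <- gene_counts[ci]
      lens <- round(runif(ng, 500, 2000))
      starts <- place_intervals(ng, lens, params$chrom_length, min_gap = 100)
      genes[[ci]] <- tibble(
        gene_id = character(ng), chrom = chrom_names(params)[ci],
        start = as.integer(starts), end = as.integer(starts + lens),
        strand = sample(c("+", "-"), ng, replace = TRUE)
      )
      no <- ori_counts[ci]
      widths <- round(runif(no, 200, 800))
      ostarts <- place_intervals(no, widths, params$chrom_length, min_gap = 5000)
      status <- if (no > 0) {
        sample(names(params$status_probs), no, replace = TRUE,
               prob = params$status_probs)
      } else character(0)
      oris[[ci]] <- tibble(
        ori_id = character(no), chrom = chrom_names(params)[ci],
        start = as.integer(ostarts), end = as.integer(ostarts + widths),
        status = status,
        base_time = params$s_start +
          (params$s_end - params$s_start) * rbeta(no, params$firing_shape, 1)
      )
    }
    genes <- bind_rows(genes)
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    oris <- bind_rows(oris)
    if (params$n_oris > 0 && params$n_decoy_oris > 0) {
      nd <- params$n_decoy_oris
      dstart <- floor(runif(nd, 0, params$chrom_length - 500))
      decoys <- tibble(
        ori_id = character(nd),
        chrom = sample(chrom_names(params), nd, replace = TRUE),
        start = as.integer(dstart), end = as.integer(dstart + 400L),
        status = "dubious", base_time = NA_real_
      )
      oris <- bind_rows(oris, decoys) %>% arrange(.data$chrom, .data$start)
    }
    if (nrow(oris) > 0) oris$ori_id <- sprintf("ori%03d", seq_len(nrow(oris)))
    list(genes = genes, oris = oris)
  })
}

# Origins subject to the coupling adjustment under the given mode.
coupled_ori_mask <- function(oris, params) {
  if (params$coupling_mode == "none" || params$beta == 0 || nrow(oris) == 0) {
    return(rep(FALSE, nrow(oris)))
  }
  fires <- !is.na(oris$base_time)
  if (params$coupling_mode == "all_oris") return(fires)
  mid_s <- (params$s_start + params$s_end) / 2
  fires & oris$base_time > mid_s
}

# Genes whose midpoint lies within the coupling radius of a coupled origin.
coupled_gene_mask <- function(genes, oris, params) {
  mask <- coupled_ori_mask(oris, params)
  if (!any(mask)) return(rep(FALSE, nrow(genes)))
  mid <- interval_midpoint(genes$start, genes$end)
  opts <- split(interval_midpoint(oris$start[mask], oris$end[mask]),
                oris$chrom[mask])
  vapply(seq_len(nrow(genes)), function(i) {
    p <- opts[[genes$chrom[i]]]
    !is.null(p) && length(p) > 0 && min(abs(p - mid[i])) <= params$coupling_radius
  }, logical(1))
}

#' Simulate the cell-cycle expression time course
#'
#' Each gene's log2 ratio follows
#' `A_g * cos(2 * pi * (t - phi_g) / cycle_length) + N(0, noise_sd^2)`.
#' Peak phases `phi_g` are uniform over the cycle, except that genes lying
#' within the coupling radius of a coupled origin (when `oris` is supplied,
#' `beta > 0` and the coupling mode is active) peak in early G2 - their
#' transcript level therefore rises fastest during S phase, emulating
#' S-phase-transcribed genes.
#'
#' @param genes Gene table.
#' @param params A [sim_params()] list.
#' @param oris Optional ORI table with `base_time` (from
#'   [simulate_genome()]); required for coupled phase assignment.
#' @return A list with `expression` (long tibble: `gene_id`, `time`,
#'   `phase`, `value`) and `truth` (per-gene `phase_phi`, `amplitude`,
#'   `coupled`, `e_s` = the gene's mid-S cosine value).
#' @export
simulate_cc_expression <- function(genes, params, oris = NULL) {
  stopifnot(inherits(params, "sim_params"))
  n <- nrow(genes)
  coupled <- if (is.null(oris)) rep(FALSE, n) else
    coupled_gene_mask(genes, oris, params)
  withr::with_seed(params$seed + 307L, {
    phi <- runif(n, 0, params$cycle_length)
    phi[coupled] <- runif(sum(coupled), params$s_end,
                          params$s_end + params$coupled_phase_jitter)
    amp <- pmax(rnorm(n, params$amplitude_mean, params$amplitude_sd), 0.1)
    tp <- params$timepoints
    clean <- amp * cos(2 * pi * outer(-phi, tp, `+`) / params$cycle_length)
    noise <- matrix(rnorm(n * length(tp), 0, params$noise_sd), nrow = n)
    vals <- clean + noise
  })
  mid_s <- (params$s_start + params$s_end) / 2
  truth <- tibble(
    gene_id = genes$gene_id, phase_phi = phi, amplitude = amp,
    coupled = coupled,
    e_s = amp * cos(2 * pi * (mid_s - phi) / params$cycle_length)
  )
  expression <- tibble(
    gene_id = rep(genes$gene_id, each = length(params$timepoints)),
    time = rep(params$timepoints, times = n),
    phase = rep(cycle_phase(params$timepoints, params), times = n),
    value = as.vector(t(vals))
  )
  list(expression = expression, truth = truth)
}

#' Realize the ORI firing program under expression coupling
#'
#' Base firing times (drawn in [simulate_genome()], or here if absent) are
#' advanced for coupled origins by `beta` times the mean S-phase expression
#' `E_S` (each neighbouring gene's amplitude-weighted cosine at mid-S) of
#' genes within the coupling radius, then clamped to the firing window:
#' `fire = clamp(base - beta * E_S, s_start, s_end)`. Under
#' `coupling_mode = "late_ori_proximal"` only origins with base time past
#' the S midpoint are adjusted; under `"none"` or `beta = 0` realized times
#' equal base times.
#'
#' @param oris ORI table (with `base_time`).
#' @param genes Gene table.
#' @param expr_truth Truth tibble from [simulate_cc_expression()] (uses
#'   `phase_phi`, `amplitude`).
#' @param params A [sim_params()] list.
#' @return `oris` with columns `base_time`, `firing_time`, `coupled`.
#' @export
simulate_replication_program <- function(oris, genes, expr_truth, params) {
  stopifnot(inherits(params, "sim_params"))
  if (nrow(oris) == 0) {
    return(mutate(oris, base_time = numeric(0), firing_time = numeric(0),
                  coupled = logical(0)))
  }
  if (!"base_time" %in% names(oris)) {
    oris$base_time <- withr::with_seed(params$seed + 211L,
      params$s_start + (params$s_end - params$s_start) *
        rbeta(nrow(oris), params$firing_shape, 1))
    oris$base_time[oris$status == "dubious"] <- NA_real_
  }
  mid_s <- (params$s_start + params$s_end) / 2
  es_gene <- expr_truth$amplitude *
    cos(2 * pi * (mid_s - expr_truth$phase_phi) / params$cycle_length)
  es_gene <- es_gene[match(genes$gene_id, expr_truth$gene_id)]
  gmid <- interval_midpoint(genes$start, genes$end)
  opt <- interval_midpoint(oris$start, oris$end)
  mask <- coupled_ori_mask(oris, params)
  es_ori <- vapply(seq_len(nrow(oris)), function(i) {
    sel <- genes$chrom == oris$chrom[i] &
      abs(gmid - opt[i]) <= params$coupling_radius
    if (!any(sel)) 0 else mean(es_gene[sel], na.rm = TRUE)
  }, numeric(1))
  fire <- oris$base_time
  fire[mask] <- pmin(pmax(oris$base_time[mask] - params$beta * es_ori[mask],
                          params$s_start), params$s_end)
  mutate(oris, firing_time = fire, coupled = mask)
}

#' Render the replication-timing profile by fork progression
#'
#' At each probe `x` the replication time is the earliest arrival over
#' origins: `trep(x) = min_i(fire_i + |x - x_i| / fork_speed)`, the classic
#' V-shaped profile of bidirectional forks at constant speed. Chromosomes
#' without origins are omitted with a warning. The profile is annotated with
#' S bounds `(s_start, s_phase_end)`.
#'
#' @param oris ORI table with `firing_time` ([simulate_replication_program()]).
#' @param params A [sim_params()] list.
#' @return A [trep_profile()].
#' @export
render_trep_profile <- function(oris, params) {
  stopifnot(inherits(params, "sim_params"))
  assert_columns(oris, c("chrom", "start", "end", "firing_time"), "ORI table")
  v_bp <- params$fork_speed * 1000
  probes <- seq(0, params$chrom_length - 1, by = params$probe_spacing)
  rows <- lapply(chrom_names(params), function(chr) {
    sel <- oris$chrom == chr & is.finite(oris$firing_time)
    if (!any(sel)) {
      warn(sprintf("no origins on %s; omitting its profile", chr))
      return(NULL)
    }
    pts <- interval_midpoint(oris$start[sel], oris$end[sel])
    fire <- oris$firing_time[sel]
    trep <- do.call(pmin, lapply(seq_along(pts), function(i) {
      fire[i] + abs(probes - pts[i]) / v_bp
    }))
    tibble(chrom = chr, position = probes, trep = trep)
  })
  trep_profile(bind_rows(rows), s_start = params$s_start,
               s_end = params$s_phase_end)
}

#' Simulate asynchronous expression levels
#'
#' Levels are log-normal around a gene-specific baseline with a contribution
#' from mean S-phase expression:
#' `level = exp(base_g + gamma * E_S(g) + noise)`. With `gamma > 0`, genes
#' transcribed in S phase (which, under coupling, fire nearby origins early)
#' also have high asynchronous levels.
#'
#' @param genes Gene table.
#' @param truth Truth tibble from [simulate_cc_expression()].
#' @param params A [sim_params()] list.
#' @return An asynchronous expression tibble (`gene_id`, `level`,
#'   `per_copy_normalized = FALSE`).
#' @export
simulate_async_expression <- function(genes, truth, params) {
  stopifnot(inherits(params, "sim_params"))
  es <- truth$e_s[match(genes$gene_id, truth$gene_id)]
  withr::with_seed(params$seed + 401L, {
    base <- rnorm(nrow(genes), params$async_base_mean, params$async_base_sd)
    noise <- rnorm(nrow(genes), 0, params$async_noise_sd)
  })
  tibble(
    gene_id = genes$gene_id,
    level = exp(base + params$gamma * es + noise),
    per_copy_normalized = FALSE
  )
}

#' Simulate a gene set with monotone late-only expression coupling
#'
#' A purpose-built scenario for the decile analysis: T_rep is uniform over
#' `trep_range`; expression at the probed timepoint is flat (pure noise) for
#' genes replicating before the midpoint cutoff and decreases linearly with
#' T_rep beyond it. This is the idealized form of an association confined to
#' late-replicating genes.
#'
#' @param n_genes Number of genes.
#' @param trep_range Range of T_rep (minutes).
#' @param slope Decrease in expression per minute of T_rep past the cutoff
#'   (log2 units/min).
#' @param noise_sd Expression noise sd.
#' @param seed Integer seed.
#' @return A tibble with `gene_id`, `trep`, `value`.
#' @export
simulate_monotone_coupling <- function(n_genes = 400, trep_range = c(30, 70),
                                       slope = 0.05, noise_sd = 0.15,
                                       seed = 1L) {
  cutoff <- mean(trep_range)
  withr::with_seed(as.integer(seed) + 503L, {
    trep <- runif(n_genes, trep_range[1], trep_range[2])
    value <- -slope * pmax(trep - cutoff, 0) + rnorm(n_genes, 0, noise_sd)
  })
  tibble(gene_id = sprintf("g%04d", seq_len(n_genes)), trep = trep,
         value = value)
}

#' Simulate a complete dataset (optionally written to disk)
#'
#' Runs the full generative chain - genome, expression (with coupled
#' phases), firing program, fork-rendered profile, asynchronous levels - and
#' optionally writes the file set `genes.bed`, `oris.tsv`, `trep.bedgraph`,
#' `cc_expression.tsv`, `async.tsv`, `truth.json`, all readable by the
#' package's readers. Identical parameters (including seed) give a
#' byte-identical file set.
#'
#' @param params A [sim_params()] list.
#' @param outdir Optional output directory (created if needed).
#' @return A list with `genes`, `oris`, `profile`, `expression`, `async`,
#'   `truth`, `params` (invisible when writing to disk).
#' @export
simulate_dataset <- function(params, outdir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  genome <- simulate_genome(params)
  expr <- simulate_cc_expression(genome$genes, params, oris = genome$oris)
  oris <- simulate_replication_program(genome$oris, genome$genes, expr$truth,
                                       params)
  profile <- render_trep_profile(oris, params)
  async <- simulate_async_expression(genome$genes, expr$truth, params)
  out <- list(genes = genome$genes, oris = oris, profile = profile,
              expression = expr$expression, async = async,
              truth = expr$truth, params = params)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outdir)) {
      abort(sprintf("cannot create output directory %s", outdir),
            class = "repcycle_config_error")
    }
    write_genes(out$genes, file.path(outdir, "genes.bed"))
    write_oris(oris, file.path(outdir, "oris.tsv"))
    write_trep_profile(profile, file.path(outdir, "trep.bedgraph"))
    write_expression(out$expression, file.path(outdir, "cc_expression.tsv"))
    write_async(async, file.path(outdir, "async.tsv"))
    truth <- list(
      schema = "repcycle-truth/1",
      params = unclass(params),
      genes = expr$truth,
      oris = oris[, c("ori_id", "chrom", "base_time", "firing_time", "coupled")]
    )
    jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    return(invisible(out))
  }
  out
}
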