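# Per-gene replication times and stratification labels: linear interpolation
# of the T_rep profile to gene midpoints, early/late S classification, and
# ORI proximity.

#' Gene midpoints
#'
#' Adds a `midpoint` column: `floor((start + end) / 2)` under the 0-based
#' half-open convention, so a 1 bp gene at `(0, 1)` has midpoint 0.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @return `genes` with a `midpoint` column.
#' @export
gene_midpoints <- function(genes) {
  assert_columns(genes, c("chrom", "start", "end"), "gene table")
  if (any(genes$start >= genes$end)) {
    abort("gene intervals must satisfy start < end", class = "repcycle_data_error")
  }
  mutate(genes, midpoint = interval_midpoint(.data$start, .data$end))
}

#' Map a replication-timing profile onto genes
#'
#' Each gene receives the T_rep value at its midpoint, linearly interpolated
#' between the two flanking probes of the same chromosome. A midpoint that
#' falls exactly on a probe takes that probe's value. Midpoints outside the
#' probed span of a chromosome, or on chromosomes absent from the profile,
#' get a missing T_rep (no extrapolation); their count is reported.
#'
#' @param genes Gene table.
#' @param profile A [trep_profile()].
#' @return `genes` with columns `midpoint` and `trep` added.
#' @export
interpolate_trep <- function(genes, profile) {
  assert_columns(profile, c("chrom", "position", "trep"), "T_rep profile")
  genes <- gene_midpoints(genes)
  by_chrom <- split(profile, profile$chrom)
  trep <- rep(NA_real_, nrow(genes))
  for (chr in unique(genes$chrom)) {
    idx <- which(genes$chrom == chr)
    prof <- by_chrom[[chr]]
    if (is.null(prof) || nrow(prof) == 0) next
    if (nrow(prof) == 1) {
      # a single probe only supports exact hits
      hit <- genes$midpoint[idx] == prof$position[1]
      trep[idx[hit]] <- prof$trep[1]
      next
    }
    trep[idx] <- approx(prof$position, prof$trep, xout = genes$midpoint[idx],
                        method = "linear", rule = 1, ties = "ordered")$y
  }
  n_missing <- sum(is.na(trep))
  if (n_missing > 0) {
    inform(sprintf(
      "interpolate_trep: %d of %d genes have no T_rep (outside probed span or unprofiled chromosome)",
      n_missing, nrow(genes)))
  }
  mutate(genes, trep = trep)
}

#' Classify genes as early- or late-replicating
#'
#' The cutoff sits `fraction` of the way through S phase as annotated on the
#' profile: `cutoff = s_start + fraction * (s_end - s_start)`. Genes with
#' `trep <= cutoff` are labelled `early` (the tie goes to early; the first
#' half of S phase is read as inclusive), the rest `late`; missing T_rep
#' stays `NA`.
#'
#' @param gene_trep Gene table with a `trep` column (see [interpolate_trep()]).
#' @param profile The [trep_profile()] carrying the S-phase bounds.
#' @param fraction Position of the cutoff within S phase, in (0, 1).
#'   Default 0.5 (halfway through S phase).
#' @return `gene_trep` with an `early_late` column (`"early"`/`"late"`/`NA`).
#' @export
classify_early_late <- function(gene_trep, profile, fraction = 0.5) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    stop_field("fraction", "early/late cutoff fraction must lie in (0, 1)")
  }
  assert_columns(gene_trep, "trep", "gene table")
  s <- s_bounds(profile)
  cutoff <- s[1] + fraction * (s[2] - s[1])
  mutate(gene_trep, early_late = dplyr::case_when(
    is.na(.data$trep) ~ NA_character_,
    .data$trep <= cutoff ~ "early",
    TRUE ~ "late"
  ))
}

#' Distance from each gene's 5' end to the nearest ORI
#'
#' The ORI point location is the interval midpoint `floor((start + end) / 2)`.
#' The gene anchor is its strand-aware 5' end (`start` for `+`, `end - 1` for
#' `-`). Genes on chromosomes without any ORI get a missing distance.
#'
#' @param genes Gene table (any table with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; extra columns are preserved).
#' @param oris ORI table.
#' @return `genes` with an `ori_distance` column (bp, >= 0, or `NA`).
#' @export
nearest_ori_distance <- function(genes, oris) {
  assert_columns(genes, c("chrom", "start", "end", "strand"), "gene table")
  assert_columns(oris, c("chrom", "start", "end"), "ORI table")
  fp <- five_prime_end(genes$start, genes$end, genes$strand)
  pts <- split(interval_midpoint(oris$start, oris$end), oris$chrom)
  dist <- rep(NA_real_, nrow(genes))
  for (chr in unique(genes$chrom)) {
    p <- pts[[chr]]
    if (is.null(p) || length(p) == 0) next
    p <- sort(p)
    idx <- which(genes$chrom == chr)
    x <- fp[idx]
    # nearest point via the insertion position in the sorted ORI points
    pos <- findInterval(x, p)
    d_lo <- ifelse(pos >= 1, x - p[pmax(pos, 1)], Inf)
    d_hi <- ifelse(pos < length(p), p[pmin(pos + 1, length(p))] - x, Inf)
    dist[idx] <- pmin(abs(d_lo), abs(d_hi))
  }
  mutate(genes, ori_distance = dist)
}

#' Label genes as ORI-proximal or ORI-distal
#'
#' A gene is proximal when its 5'-end distance to the nearest ORI is `<=
#' cutoff_bp` (inclusive, matching "within N kb"); distal otherwise; missing
#' distances stay `NA`.
#'
#' @param gene_trep Gene table with an `ori_distance` column.
#' @param cutoff_bp Positive distance cutoff in bp (5 kb was used for
#'   budding-yeast-density ORI maps, 10 kb for sparser maps).
#' @return `gene_trep` with a logical `ori_proximal` column.
#' @export
classify_ori_proximity <- function(gene_trep, cutoff_bp) {
  if (!is.numeric(cutoff_bp) || length(cutoff_bp) != 1 || cutoff_bp <= 0) {
    stop_field("cutoff_bp", "ORI proximity cutoff must be a positive number of bp")
  }
  assert_columns(gene_trep, "ori_distance", "gene table")
  mutate(gene_trep, ori_proximal = .data$ori_distance <= cutoff_bp)
}

#' Call early-replicating peaks (local T_rep minima)
#'
#' The profile is box-smoothed over `+/- smooth_window_bp` around each probe;
#' peaks are probes whose smoothed value is a strict minimum over that window
#' and lies at least `prominence` below the lower of the two flanking maxima
#' (the maxima of the smoothed profile between the candidate and its
#' neighbouring candidates or the chromosome ends). Chromosome boundary
#' probes are never peaks.
#'
#' @param profile A [trep_profile()].
#' @param smooth_window_bp Half-width of the box smoother in bp. Default:
#'   3x the median probe spacing.
#' @param prominence Minimum depth below the flanking maxima for a peak to be
#'   reported, in T_rep units. Default: 10% of the S-phase span.
#' @return A tibble with columns `chrom`, `peak_position`, `peak_trep` (the
#'   unsmoothed T_rep at the peak probe).
#' @export
call_early_peaks <- function(profile, smooth_window_bp = NULL, prominence = NULL) {
  assert_columns(profile, c("chrom", "position", "trep"), "T_rep profile")
  spacing <- profile %>%
    group_by(.data$chrom) %>%
    summarise(sp = list(diff(.data$position)), .groups = "drop")
  med_spacing <- median(unlist(spacing$sp))
  if (is.null(smooth_window_bp)) smooth_window_bp <- 3 * med_spacing
  if (is.null(prominence)) {
    s <- s_bounds(profile)
    prominence <- 0.1 * (s[2] - s[1])
  }
  if (is.finite(med_spacing) && smooth_window_bp < med_spacing) {
    warn("smoothing window is smaller than the median probe spacing; the profile is effectively unsmoothed")
  }
  out <- lapply(split(profile, profile$chrom), function(prof) {
    n <- nrow(prof)
    if (n < 3) return(NULL)
    pos <- prof$position
    lo <- findInterval(pos - smooth_window_bp, pos, left.open = TRUE) + 1L
    hi <- findInterval(pos + smooth_window_bp, pos)
    cs <- cumsum(prof$trep)
    smoothed <- (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
    cand <- integer(0)
    for (i in 2:(n - 1)) {
      win <- setdiff(seq.int(lo[i], hi[i]), i)
      if (length(win) > 0 && smoothed[i] < min(smoothed[win])) cand <- c(cand, i)
    }
    if (length(cand) == 0) return(NULL)
    bounds <- c(1L, cand, n)
    keep <- vapply(seq_along(cand), function(k) {
      i <- cand[k]
      left_max <- max(smoothed[bounds[k]:i])
      right_max <- max(smoothed[i:bounds[k + 2]])
      min(left_max, right_max) - smoothed[i] >= prominence
    }, logical(1))
    cand <- cand[keep]
    if (length(cand) == 0) return(NULL)
    tibble(chrom = prof$chrom[1], peak_position = pos[cand],
           peak_trep = prof$trep[cand])
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), peak_position = numeric(),
                  peak_trep = numeric())
  }
  out
}

#' Retain candidate ORI sites near early-replicating peaks
#'
#' Keeps sites whose point location (interval midpoint) lies within
#' `window_bp` (inclusive) of any same-chromosome peak. With no peaks at all
#' an empty table is returned with a warning. This mirrors the definition of
#' active origins as binding sites near early-replicating peaks in
#' low-resolution timing profiles.
#'
#' @param candidate_sites ORI table of candidate binding sites.
#' @param peaks Peak table from [call_early_peaks()].
#' @param window_bp Inclusive distance window in bp (default 1 Mb, suited to
#'   low-resolution human-style profiles).
#' @return The retained subset of `candidate_sites`.
#' @export
activate_oris <- function(candidate_sites, peaks, window_bp = 1e6) {
  assert_columns(candidate_sites, c("chrom", "start", "end"), "ORI table")
  if (nrow(peaks) == 0) {
    warn("no early-replicating peaks supplied; returning an empty ORI table")
    return(candidate_sites[0, , drop = FALSE])
  }
  assert_columns(peaks, c("chrom", "peak_position"), "peak table")
  pt <- interval_midpoint(candidate_sites$start, candidate_sites$end)
  keep <- vapply(seq_len(nrow(candidate_sites)), function(i) {
    pp <- peaks$peak_position[peaks$chrom == candidate_sites$chrom[i]]
    length(pp) > 0 && min(abs(pp - pt[i])) <= window_bp
  }, logical(1))
  candidate_sites[keep, , drop = FALSE]
}
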