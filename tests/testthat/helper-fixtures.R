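# Shared fixtures, built in code.

make_genes <- function(n = 5, chrom = "chr1", strand = NULL) {
  start <- seq(1000, by = 3000, length.out = n)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(start + 1000),
    strand = strand %||% rep(c("+", "-"), length.out = n)
  )
}

make_profile <- function(positions = c(1000, 5000, 9000),
                         trep = c(10, 40, 20), chrom = "chr1",
                         s_start = 0, s_end = 60) {
  trep_profile(
    tibble::tibble(chrom = chrom, position = positions, trep = trep),
    s_start = s_start, s_end = s_end
  )
}

make_oris <- function(points, chrom = "chr1", status = "confirmed",
                      width = 100) {
  tibble::tibble(
    ori_id = sprintf("ori%03d", seq_along(points)),
    chrom = chrom,
    start = as.integer(points - width / 2),
    end = as.integer(points + width / 2),
    status = rep(status, length.out = length(points))
  )
}

# Desk-scale simulation parameters for unit tests (same geometry as the
# defaults: ~100 kb ORI spacing, ~5 kb gene spacing, but a smaller genome).
small_params <- function(seed = 1L, n_genes = 160L, n_oris = 16L,
                         chrom_length = 8e5, ...) {
  sim_params(seed = seed, n_chrom = 2L, chrom_length = chrom_length,
             n_genes = n_genes, n_oris = n_oris, ...)
}

# Naive O(probes) interpolation oracle used to validate interpolate_trep().
oracle_interpolate <- function(profile, chrom, midpoint) {
  prof <- profile[profile$chrom == chrom, ]
  if (nrow(prof) < 2) return(NA_real_)
  pos <- prof$position
  if (midpoint < min(pos) || midpoint > max(pos)) return(NA_real_)
  for (j in seq_len(nrow(prof))) {
    if (pos[j] == midpoint) return(prof$trep[j])
  }
  j <- max(which(pos < midpoint))
  p1 <- pos[j]; p2 <- pos[j + 1]
  t1 <- prof$trep[j]; t2 <- prof$trep[j + 1]
  t1 + (midpoint - p1) / (p2 - p1) * (t2 - t1)
}

# Definitional Pearson correlation oracle.
oracle_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

`%||%` <- rlang::`%||%`
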