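# The synthetic-data generator: determinism, geometry, the firing program,
# fork rendering, expression structure, and end-to-end file output.

test_that("the same seed reproduces identical tables", {
  p <- small_params(seed = 9)
  g1 <- simulate_genome(p)
  g2 <- simulate_genome(p)
  expect_identical(g1, g2)
  e1 <- simulate_cc_expression(g1$genes, p, oris = g1$oris)
  e2 <- simulate_cc_expression(g2$genes, p, oris = g2$oris)
  expect_identical(e1, e2)
})

test_that("gene intervals fit the chromosome and are pairwise disjoint", {
  p <- small_params(seed = 10)
  g <- simulate_genome(p)
  expect_true(all(g$genes$start >= 0 & g$genes$end <= p$chrom_length))
  for (chr in unique(g$genes$chrom)) {
    gg <- dplyr::arrange(g$genes[g$genes$chrom == chr, ], start)
    # brute-force overlap scan
    expect_true(all(gg$start[-1] >= gg$end[-nrow(gg)]))
  }
  expect_error(simulate_genome(sim_params(n_genes = 4000, chrom_length = 1e6,
                                          n_oris = 4)),
               "infeasible", class = "repcycle_config_error")
})

test_that("n_oris = 0 gives an empty ORI table but genes are still generated", {
  p <- small_params(seed = 11, n_oris = 0L)
  g <- simulate_genome(p)
  expect_equal(nrow(g$oris), 0)
  expect_equal(nrow(g$genes), p$n_genes)
})

test_that("base firing times stay in the firing window and beta = 0 is the identity", {
  p <- small_params(seed = 12, beta = 0)
  g <- simulate_genome(p)
  fires <- !is.na(g$oris$base_time)
  expect_true(all(g$oris$base_time[fires] >= p$s_start &
                    g$oris$base_time[fires] <= p$s_end))
  expect_true(all(g$oris$status[!fires] == "dubious"))
  expr <- simulate_cc_expression(g$genes, p, oris = g$oris)
  prog <- simulate_replication_program(g$oris, g$genes, expr$truth, p)
  expect_equal(prog$firing_time, prog$base_time)
  expect_false(any(prog$coupled))
})

test_that("a single ORI with one nearby unit-expression gene advances by exactly beta", {
  p <- sim_params(seed = 13, n_chrom = 1, chrom_length = 2e5, n_genes = 2,
                  n_oris = 1, beta = 5, coupling_mode = "all_oris",
                  coupling_radius = 10000)
  oris <- tibble::tibble(ori_id = "o1", chrom = "chr1", start = 99900L,
                         end = 100100L, status = "confirmed", base_time = 45)
  genes <- tibble::tibble(gene_id = c("g1", "g2"), chrom = "chr1",
                          start = c(98000L, 150000L), end = c(99000L, 151000L),
                          strand = "+")
  mid_s <- (p$s_start + p$s_end) / 2
  truth <- tibble::tibble(gene_id = c("g1", "g2"),
                          phase_phi = c(mid_s, 0), amplitude = c(1, 1),
                          coupled = c(TRUE, FALSE), e_s = c(1, NA))
  prog <- simulate_replication_program(oris, genes, truth, p)
  # only g1 is within the radius; its E_S = 1 * cos(0) = 1 -> advance = beta
  expect_equal(prog$firing_time, 45 - 5)
})

test_that("late_ori_proximal mode leaves early-firing origins unchanged", {
  p <- small_params(seed = 14, coupling_mode = "late_ori_proximal")
  g <- simulate_genome(p)
  expr <- simulate_cc_expression(g$genes, p, oris = g$oris)
  prog <- simulate_replication_program(g$oris, g$genes, expr$truth, p)
  mid_s <- (p$s_start + p$s_end) / 2
  early <- !is.na(prog$base_time) & prog$base_time <= mid_s
  expect_equal(prog$firing_time[early], prog$base_time[early])
  expect_false(any(prog$coupled[early]))
  # clamping keeps realized times in the firing window; decoys never fire
  fires <- is.finite(prog$firing_time)
  expect_true(all(prog$firing_time[fires] >= p$s_start &
                    prog$firing_time[fires] <= p$s_end))
  expect_true(all(prog$status[!fires] == "dubious"))
})

test_that("the rendered profile matches the fork-progression closed form", {
  p <- sim_params(seed = 15, n_chrom = 1, chrom_length = 3e5, n_genes = 10,
                  n_oris = 1, fork_speed = 2, probe_spacing = 1000)
  oris <- tibble::tibble(ori_id = "o1", chrom = "chr1", start = 99950L,
                         end = 100050L, status = "confirmed",
                         base_time = 10, firing_time = 10)
  prof <- render_trep_profile(oris, p)
  # probe at 150 kb: 10 + 50000 bp / 2000 bp/min = 35
  expect_equal(prof$trep[prof$position == 150000], 35)
  # the probe at the ORI position is the local minimizer: its firing time
  expect_equal(prof$trep[prof$position == 1e5], 10)
  # Lipschitz: adjacent probes differ by at most spacing / fork speed
  expect_true(all(abs(diff(prof$trep)) <= p$probe_spacing / 2000 + 1e-9))
})

test_that("the profile minimum equals the earliest realized firing time", {
  p <- small_params(seed = 16)
  g <- simulate_genome(p)
  expr <- simulate_cc_expression(g$genes, p, oris = g$oris)
  prog <- simulate_replication_program(g$oris, g$genes, expr$truth, p)
  prof <- render_trep_profile(prog, p)
  for (chr in unique(prof$chrom)) {
    fire <- prog$firing_time[prog$chrom == chr & is.finite(prog$firing_time)]
    prof_min <- min(prof$trep[prof$chrom == chr])
    # the probe nearest the earliest ORI sits within half a spacing of it
    expect_lte(abs(prof_min - min(fire)), p$probe_spacing / 2 / (p$fork_speed * 1000))
  }
})

test_that("a chromosome without origins is omitted from the profile with a warning", {
  p <- sim_params(seed = 17, n_chrom = 2, chrom_length = 2e5, n_genes = 10,
                  n_oris = 1)
  oris <- tibble::tibble(ori_id = "o1", chrom = "chr1", start = 99950L,
                         end = 100050L, status = "confirmed",
                         base_time = 10, firing_time = 10)
  expect_warning(prof <- render_trep_profile(oris, p), "chr2")
  expect_equal(unique(prof$chrom), "chr1")
})

test_that("noise-free expression equals the cosine model exactly", {
  p <- sim_params(seed = 18, n_chrom = 1, chrom_length = 2e5, n_genes = 4,
                  n_oris = 2, noise_sd = 0, amplitude_sd = 0,
                  timepoints = c(0, 45, 90, 135), beta = 0,
                  coupling_mode = "none")
  g <- simulate_genome(p)
  sim <- simulate_cc_expression(g$genes, p)
  joined <- dplyr::inner_join(sim$expression, sim$truth, by = "gene_id")
  expect_equal(
    joined$value,
    joined$amplitude * cos(2 * pi * (joined$time - joined$phase_phi) / 90),
    tolerance = 1e-12
  )
  # phi = 0, A = 1: e(0) = 1 and e(cycle/2) = -1
  one <- sim$truth$gene_id[1]
  shift <- sim$truth$phase_phi[1]
  manual <- cos(2 * pi * (c(0, 45) - shift) / 90)
  got <- joined$value[joined$gene_id == one & joined$time %in% c(0, 45)]
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("expression averages to about zero over the sampled cycle", {
  p <- small_params(seed = 19, timepoints = seq(0, 90, by = 5))
  g <- simulate_genome(p)
  sim <- simulate_cc_expression(g$genes, p)
  m <- mean(sim$expression$value)
  n_obs <- nrow(sim$expression)
  # the cosine terms cancel over a full cycle; noise shrinks as 1/sqrt(n)
  expect_lt(abs(m), 3 * (p$amplitude_mean + p$noise_sd) / sqrt(n_obs) + 0.02)
})

test_that("coupled genes peak in early G2", {
  p <- small_params(seed = 20)
  g <- simulate_genome(p)
  sim <- simulate_cc_expression(g$genes, p, oris = g$oris)
  coup <- sim$truth[sim$truth$coupled, ]
  expect_gt(nrow(coup), 0)
  expect_true(all(coup$phase_phi >= p$s_end &
                    coup$phase_phi <= p$s_end + p$coupled_phase_jitter))
  expect_equal(unique(cycle_phase(coup$phase_phi, p)), "G2")
})

test_that("gamma = 0 decouples asynchronous level from replication timing", {
  p <- small_params(seed = 21, gamma = 0)
  d <- simulate_dataset(p)
  gt <- suppressMessages(interpolate_trep(d$genes, d$profile))
  joined <- dplyr::inner_join(d$async, gt, by = "gene_id")
  res <- pearson_r(log(joined$level), joined$trep)
  expect_lt(abs(res$r), critical_r(res$n_pairs, 0.01))
})

test_that("simulate_dataset writes a byte-identical, re-readable file set", {
  p <- small_params(seed = 22)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  suppressMessages(simulate_dataset(p, outdir = d1))
  suppressMessages(simulate_dataset(p, outdir = d2))
  files <- c("genes.bed", "oris.tsv", "trep.bedgraph", "cc_expression.tsv",
             "async.tsv", "truth.json")
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # the files are readable by the package's own readers
  genes <- read_genes(file.path(d1, "genes.bed"))
  oris <- suppressMessages(read_oris(file.path(d1, "oris.tsv")))
  prof <- read_trep_profile(file.path(d1, "trep.bedgraph"), p$s_start,
                            p$s_phase_end)
  expr <- read_expression(file.path(d1, "cc_expression.tsv"))
  async <- read_async(file.path(d1, "async.tsv"))
  expect_equal(nrow(genes), p$n_genes)
  expect_gt(nrow(oris), 0)
  expect_equal(dplyr::n_distinct(expr$time), length(p$timepoints))
  expect_equal(nrow(async), p$n_genes)
  expect_gt(nrow(prof), 0)
})
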