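# Decile binning, top/bottom comparisons and the copy-number correction.

test_that("20 genes split into ten deciles of two, ordered by trep", {
  set.seed(41)
  dat <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    trep = sample(seq(10, 48, by = 2)),
    value = rnorm(20)
  )
  dec <- decile_median_expression(dat)
  expect_equal(dec$n, rep(2L, 10))
  expect_equal(dec$decile, 1:10)
  # bin 1 holds the two smallest trep values
  expect_equal(dec$trep_max[1], sort(dat$trep)[2])
  # bins partition: concatenated ranges cover the data in order
  expect_true(all(dec$trep_min[-1] >= dec$trep_max[-10]))
})

test_that("decile sizes differ by at most one and bins partition the gene set", {
  set.seed(42)
  for (n in c(10, 23, 57, 104)) {
    dat <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                          trep = runif(n, 10, 60), value = rnorm(n))
    dec <- decile_median_expression(dat)
    expect_equal(sum(dec$n), n)
    expect_lte(diff(range(dec$n)), 1)
    # the earliest bins take the remainder
    expect_true(all(diff(dec$n) <= 0))
  }
  expect_error(decile_median_expression(
    tibble::tibble(gene_id = letters[1:9], trep = 1:9, value = rnorm(9))),
    class = "repcycle_data_error")
})

test_that("identical expression gives identical medians in all deciles", {
  dat <- tibble::tibble(gene_id = sprintf("g%02d", 1:30),
                        trep = runif(30, 10, 60), value = 1.5)
  dec <- decile_median_expression(dat)
  expect_equal(dec$median_expression, rep(1.5, 10))
})

test_that("monotone late-only coupling produces the flat-then-decreasing decile shape", {
  dat <- simulate_monotone_coupling(n_genes = 400, seed = 7)
  dec <- decile_median_expression(dat)
  late <- dec$median_expression[6:10]
  expect_true(all(diff(late) < 0))
  early_range <- diff(range(dec$median_expression[1:5]))
  expect_lt(early_range, abs(mean(diff(late))))
})

test_that("identical extreme deciles give difference 0 and p = 1", {
  dat <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                        trep = rep(30, 20), value = 1:20)
  cmp <- decile_extremes_trep(dat)
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$groups$n, c(2L, 2L))
})

test_that("the extreme-decile t-test matches stats::t.test on 20 genes", {
  set.seed(43)
  dat <- tibble::tibble(gene_id = sprintf("g%02d", 1:20),
                        trep = runif(20, 10, 50), value = rnorm(20))
  cmp <- decile_extremes_trep(dat)
  ord_hi <- order(-dat$value, dat$gene_id)
  ord_lo <- order(dat$value, dat$gene_id)
  induced <- dat$trep[ord_hi[1:2]]
  repressed <- dat$trep[ord_lo[1:2]]
  ht <- stats::t.test(induced, repressed, var.equal = TRUE)
  expect_equal(cmp$statistic, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(cmp$p_value, unname(ht$p.value), tolerance = 1e-12)
  expect_equal(cmp$difference, mean(induced) - mean(repressed))
  expect_equal(tidy(cmp)$mean_trep, c(mean(induced), mean(repressed)))
  # Welch variant is exposed
  cmpw <- decile_extremes_trep(dat, var_equal = FALSE)
  htw <- stats::t.test(induced, repressed, var.equal = FALSE)
  expect_equal(cmpw$statistic, unname(htw$statistic), tolerance = 1e-12)
  expect_error(decile_extremes_trep(dat[1:15, ]), class = "repcycle_data_error")
})

test_that("top/bottom comparison partitions the data at k = n/2", {
  set.seed(44)
  n <- 40
  async <- tibble::tibble(gene_id = sprintf("g%02d", 1:n),
                          level = runif(n, 1, 100),
                          per_copy_normalized = FALSE)
  gt <- tibble::tibble(gene_id = async$gene_id, trep = runif(n, 10, 50))
  cmp <- compare_top_bottom_expression(async, gt, k = n / 2)
  expect_equal(cmp$groups$n, c(20L, 20L))
  # the two groups partition all genes: group means average to the grand mean
  expect_equal(mean(cmp$groups$mean_trep), mean(gt$trep), tolerance = 1e-12)
  expect_error(compare_top_bottom_expression(async, gt, k = 21),
               class = "repcycle_data_error")
})

test_that("ties at the k-th rank are broken by gene id, deterministically, with a note", {
  async <- tibble::tibble(gene_id = c("a", "b", "c", "d", "e", "f"),
                          level = c(9, 5, 5, 5, 2, 1),
                          per_copy_normalized = FALSE)
  gt <- tibble::tibble(gene_id = async$gene_id, trep = c(10, 20, 30, 40, 50, 60))
  expect_message(cmp1 <- compare_top_bottom_expression(async, gt, k = 2), "ties")
  cmp2 <- suppressMessages(compare_top_bottom_expression(async, gt, k = 2))
  # top 2 = a then b (lexicographic among the tied 5s)
  expect_equal(cmp1$groups$mean_trep[1], mean(c(10, 20)))
  expect_equal(cmp1$groups$mean_trep, cmp2$groups$mean_trep)
})

test_that("identical top and bottom groups give p = 1", {
  async <- tibble::tibble(gene_id = sprintf("g%02d", 1:10),
                          level = rep(5, 10), per_copy_normalized = FALSE)
  gt <- tibble::tibble(gene_id = async$gene_id, trep = rep(33, 10))
  cmp <- suppressMessages(compare_top_bottom_expression(async, gt, k = 5))
  expect_equal(cmp$difference, 0)
  expect_equal(cmp$p_value, 1)
})

test_that("copy-number correction leaves f = 0 unchanged and halves at f = 1", {
  async <- tibble::tibble(gene_id = c("a", "b"), level = c(3, 2),
                          per_copy_normalized = FALSE)
  # cycle_length 90: trep 90 -> f = 0; trep 0 -> f = 1
  gt <- tibble::tibble(gene_id = c("a", "b"), trep = c(90, 0))
  out <- copy_number_correction(async, gt, cycle_length = 90)
  expect_equal(out$level[1], 3)           # f = 0: unchanged
  expect_equal(out$level[2], 1)           # f = 1, kappa 0.5: 2 * 0.5 = 2/(1+1)
  expect_true(all(out$per_copy_normalized))
  expect_error(copy_number_correction(out, gt, cycle_length = 90),
               "already", class = "repcycle_data_error")
  expect_error(copy_number_correction(async, gt, cycle_length = 80),
               class = "repcycle_data_error")
})

test_that("correction weakens a purely copy-number-driven association", {
  set.seed(45)
  n <- 300
  trep <- runif(n, 20, 70)
  f <- (90 - trep) / 90
  async <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                          level = 10 * (1 + f) * exp(rnorm(n, 0, 0.02)),
                          per_copy_normalized = FALSE)
  gt <- tibble::tibble(gene_id = async$gene_id, trep = trep)
  r_before <- abs(pearson_r(async$level, trep)$r)
  corrected <- copy_number_correction(async, gt, cycle_length = 90)
  r_after <- abs(pearson_r(corrected$level, trep)$r)
  expect_lt(r_after, r_before)
})
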