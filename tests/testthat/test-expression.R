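test_that("FPKM follows the closed form and its invariances", {
  counts <- tibble::tibble(tu_id = c("a", "b"), s1 = c(10, 0), s2 = c(10, 5))
  lengths <- c(a = 1000, b = 500)
  libs <- c(s1 = 1e6, s2 = 2e6)
  fp <- compute_fpkm(counts, lengths, libs)
  expect_equal(fp$s1, c(10, 0))          # 10 * 1e9 / (1000 * 1e6)
  expect_equal(fp$s2[1], 5)              # doubling libsize halves FPKM
  # permutation invariance
  fp_perm <- compute_fpkm(counts[2:1, ], lengths, libs)
  expect_equal(dplyr::arrange(fp_perm, tu_id), dplyr::arrange(fp, tu_id))
  expect_error(compute_fpkm(counts, lengths, c(s1 = 0, s2 = 1)), "positive")
})

test_that("BH adjustment matches the hand-computed and brute-force step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(99)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})

test_that("identical groups are ns and the fold-change rule is strict", {
  counts <- tibble::tibble(
    tu_id = c("flat", "exact2", "zero"),
    c1 = c(100, 100, 0), c2 = c(100, 100, 0), c3 = c(100, 100, 0),
    t1 = c(100, 200, 0), t2 = c(100, 200, 0), t3 = c(100, 200, 0)
  )
  samples <- tibble::tibble(sample = c("c1", "c2", "c3", "t1", "t2", "t3"),
                            group = rep(c("control", "treated"), each = 3))
  de <- nb_diff_test(counts, samples)
  flat <- de[de$tu_id == "flat", ]
  expect_equal(flat$status, "ns")
  # normalization makes the planted 2x slightly less than 2 after scaling,
  # and fold_change exactly 2.0 would still be ns under the strict rule
  expect_equal(de$status[de$tu_id == "exact2"], "ns")
  zero <- de[de$tu_id == "zero", ]
  expect_equal(zero$status, "ns")
  expect_equal(zero$p_value, 1)
})

test_that("null simulations stay within the nominal error budget", {
  ids <- sprintf("tu%04d", 1:2000)
  sim <- simulate_counts(ids, baseline_log2_mean = log2(500),
                         baseline_log2_sd = 1.5, dispersion = 0.1,
                         seed = 501)
  de <- nb_diff_test(sim$counts, sim$samples)
  expect_lte(mean(de$status != "ns"), 0.01)
})

test_that("planted fold changes are detected with high sensitivity", {
  ids <- sprintf("tu%04d", 1:2000)
  lfc <- setNames(rep(3, 200), ids[1:200])
  sim <- simulate_counts(ids, baseline_log2_mean = log2(500),
                         baseline_log2_sd = 1.5, planted_lfc = lfc,
                         dispersion = 0.1, seed = 502)
  de <- nb_diff_test(sim$counts, sim$samples)
  expect_gte(mean(de$status[match(names(lfc), de$tu_id)] == "up"), 0.9)
})

test_that("counts approach the planted fold change in the Poisson limit", {
  ids <- sprintf("p%03d", 1:400)
  lfc <- setNames(rep(3, 400), ids)
  sim <- simulate_counts(ids, n_reps = 5, baseline_log2_mean = 11,
                         baseline_log2_sd = 0, planted_lfc = lfc,
                         dispersion = 1e-6, seed = 503)
  m <- as.matrix(sim$counts[, -1])
  emp_fc <- rowMeans(m[, 6:10]) / rowMeans(m[, 1:5])
  expect_lt(abs(median(emp_fc) - 8) / 8, 0.05)
  expect_error(simulate_counts(ids, dispersion = 0), "positive")
})

test_that("perfect and inverted profiles give r = 1 and r = -1", {
  fpkm <- tibble::tibble(
    tu_id = c("p1", "g1", "p2", "g2"),
    s1 = c(1, 1, 1, 8), s2 = c(2, 2, 2, 4), s3 = c(4, 4, 4, 2),
    s4 = c(8, 8, 8, 1)
  )
  pc <- prompt_gene_correlation(fpkm, tibble::tibble(tu_id = c("p1", "p2"),
                                                     gene_id = c("g1", "g2")))
  pairs <- tidy(pc)
  expect_equal(pairs$r[pairs$tu_id == "p1"], 1)
  expect_lt(pairs$r[pairs$tu_id == "p2"], 0)
})

test_that("planted coupling is recovered by the pooled correlation", {
  np <- 209
  pids <- sprintf("P%03d", 1:np); gids <- sprintf("G%03d", 1:np)
  rs <- vapply(1:4, function(s) {
    sim <- simulate_counts(c(pids, gids),
                           pairs = tibble::tibble(prompt = pids, gene = gids),
                           coupling_r = 0.65, seed = 600 + s)
    fp <- compute_fpkm(sim$counts, sim$lengths)
    glance(prompt_gene_correlation(
      fp, tibble::tibble(tu_id = pids, gene_id = gids)))$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.65), 0.08)
})

test_that("orientation comparison runs the paired signed-rank per class", {
  # equal profiles: p = 1, zero median difference
  fpkm_eq <- tibble::tibble(
    tu_id = c("p1", "g1", "p2", "g2"),
    s1 = c(5, 5, 3, 3), s2 = c(6, 6, 2, 2), s3 = c(7, 7, 1, 1)
  )
  pr <- tibble::tibble(tu_id = c("p1", "p2"), gene_id = c("g1", "g2"),
                       pair_class = "antisense/antisense")
  res <- orientation_pair_comparison(fpkm_eq, pr)
  expect_equal(res$p_value, 1)
  expect_equal(res$median_diff, 0)

  # PROMPT always 10x the gene across 20 pairs: decisive PROMPT-higher call
  set.seed(123)
  n <- 20
  gene_vals <- matrix(runif(n * 4, 1, 10), nrow = n)
  fpkm <- tibble::tibble(
    tu_id = c(sprintf("p%02d", 1:n), sprintf("g%02d", 1:n))
  ) %>% dplyr::bind_cols(tibble::as_tibble(
    rbind(gene_vals * 10, gene_vals),
    .name_repair = ~sprintf("s%d", 1:4)
  ))
  pr20 <- tibble::tibble(tu_id = sprintf("p%02d", 1:n),
                         gene_id = sprintf("g%02d", 1:n),
                         pair_class = "sense/sense")
  res20 <- orientation_pair_comparison(fpkm, pr20)
  expect_equal(res20$higher, "PROMPT")
  expect_lt(res20$p_value, 0.01)
  # exact signed-rank reference at n = 20, all positive differences
  expect_equal(res20$p_value, 2 / 2^20, tolerance = 1e-6)

  # single-class input reports only that class; undersized classes warn
  pr_mix <- dplyr::bind_rows(pr20,
                             tibble::tibble(tu_id = "p01", gene_id = "g02",
                                            pair_class = "sense/antisense"))
  expect_warning(res_mix <- orientation_pair_comparison(fpkm, pr_mix),
                 "omitted")
  expect_equal(res_mix$pair_class, "sense/sense")
})
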