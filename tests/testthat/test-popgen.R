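make_gt <- function(rows) {
  m <- do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
  n_sites <- ncol(m)
  promptscape:::new_genotype_table(
    tibble::tibble(chrom = "c", pos = seq_len(n_sites), ref = "A", alt = "G"), m
  )
}

test_that("haplotype counting and frequency bookkeeping", {
  gt <- make_gt(c("01", "01", "11"))
  hf <- haplotype_frequencies(gt)
  expect_equal(hf$haplotype, c("01", "11"))
  expect_equal(hf$frequency, c(2 / 3, 1 / 3))
  expect_equal(sum(hf$frequency), 1)

  single <- haplotype_frequencies(make_gt("0110"))
  expect_equal(single$frequency, 1)

  gt_na <- make_gt(c("01", "11"))
  gt_na$haplotypes[1, 1] <- NA
  expect_equal(haplotype_frequencies(gt_na)$haplotype, "11")
  gt_na$haplotypes[2, 2] <- NA
  expect_error(haplotype_frequencies(gt_na), "missing")
})

test_that("simulated populations recount to their planted truth", {
  pop <- simulate_population(n_individuals = 505, seed = 41)
  hf <- haplotype_frequencies(pop$genotypes)
  truth <- pop$truth[order(-pop$truth$drawn_count), ]
  expect_equal(hf$count, truth$drawn_count)
  expect_equal(hf$frequency, truth$drawn_count / 1010)
  expect_equal(nrow(pop$genotypes$haplotypes), 1010)
  # determinism
  pop2 <- simulate_population(n_individuals = 505, seed = 41)
  expect_identical(pop$genotypes$haplotypes, pop2$genotypes$haplotypes)
  expect_error(simulate_population(freqs = c(0.5, 0.4)), "sum to 1")
  expect_error(simulate_population(freqs = c(1.5, -0.5)), "non-negative")
})

test_that("LD statistics match the plug-in formulas", {
  # perfectly coupled sites
  perfect <- make_gt(c(rep("00", 30), rep("11", 20)))
  expect_equal(ld_r2(perfect, 1, 2)$r2, 1)

  # balanced table: D = 0
  balanced <- make_gt(c(rep("00", 25), rep("01", 25), rep("10", 25),
                        rep("11", 25)))
  res0 <- ld_r2(balanced, 1, 2)
  expect_equal(res0$D, 0)
  expect_equal(res0$r2, 0)

  # printed contingency example: {00:40, 11:40, 01:10, 10:10}
  ex <- make_gt(c(rep("00", 40), rep("11", 40), rep("01", 10), rep("10", 10)))
  res <- ld_r2(ex, 1, 2)
  expect_equal(res$D, 0.15)
  expect_equal(res$r2, 0.36)

  # monomorphic site flagged
  mono <- make_gt(c("00", "00", "01"))
  expect_warning(rm <- ld_r2(mono, 1, 2), "monomorphic")
  expect_true(is.na(rm$r2))

  # brute-force property on random tables
  set.seed(53)
  for (i in 1:200) {
    repeat {
      a <- rbinom(40, 1, runif(1, 0.2, 0.8))
      b <- rbinom(40, 1, runif(1, 0.2, 0.8))
      if (length(unique(a)) > 1 && length(unique(b)) > 1) break
    }
    gt <- promptscape:::new_genotype_table(
      tibble::tibble(chrom = "c", pos = 1:2, ref = "A", alt = "G"),
      cbind(a, b)
    )
    got <- ld_r2(gt, 1, 2)
    ref <- ld_brute(a, b)
    expect_equal(got$D, ref$D, tolerance = 1e-12)
    expect_equal(got$r2, ref$r2, tolerance = 1e-12)
  }
})

test_that("tau follows the max-normalized specificity index", {
  expect_equal(tau_specificity(c(5, 0, 0, 0)), 1)
  expect_equal(tau_specificity(c(3, 3, 3)), 0)
  expect_equal(tau_specificity(c(2, 1, 0)), 0.75)
  # scale invariance and range
  set.seed(61)
  for (i in 1:100) {
    x <- runif(sample(2:12, 1), 0, 50)
    tau <- tau_specificity(x)
    expect_gte(tau, 0); expect_lte(tau, 1)
    expect_equal(tau, tau_specificity(x * 7.3))
  }
  expect_warning(tz <- tau_specificity(c(0, 0)), "zero")
  expect_true(is.na(tz))
  expect_error(tau_specificity(5), "at least 2")
  expect_error(tau_specificity(c(1, -1)), "non-negative")
})

test_that("JC distance: closed form, gap handling and saturation", {
  same <- jc_distance("ACGTACGT", "ACGTACGT")
  expect_equal(same$p, 0); expect_equal(same$d, 0)

  # 3 mismatches over 30 valid columns -> p = 0.1, d = 0.10732
  a <- strrep("A", 30)
  b <- paste0("CCC", strrep("A", 27))
  res <- jc_distance(a, b)
  expect_equal(res$p, 0.1)
  expect_equal(res$d, -0.75 * log(1 - 0.4 / 3))
  expect_equal(res$d, 0.10732, tolerance = 1e-4)

  # gap and N columns are excluded
  gap <- jc_distance("AC-GN", "ACCGA")
  expect_equal(gap$n_columns, 3)

  sat <- jc_distance(strrep("A", 20), strrep("C", 20))
  expect_true(sat$saturated)
  expect_true(is.na(sat$d))
  expect_error(jc_distance("ACG", "AC"), "length")
})

test_that("JC distance agrees with ape and inverts the simulator", {
  skip_if_not_installed("ape")
  set.seed(71)
  for (i in 1:20) {
    div <- simulate_divergence(n_pairs = 1, ar_sub_rate = runif(1, 0.02, 0.4),
                               seed = i)
    p <- div$pairs
    ours <- jc_distance(p$ar_a, p$ar_b)$d
    mat <- rbind(strsplit(tolower(p$ar_a), "")[[1]],
                 strsplit(tolower(p$ar_b), "")[[1]])
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(mat), model = "JC69"))
    expect_equal(ours, ref, tolerance = 1e-9)
  }
  # estimator consistency: mean estimated distance ~ planted rate
  div <- simulate_divergence(n_pairs = 300, ar_sub_rate = 0.12,
                             suppression = 1, len_range = c(1000, 1000),
                             seed = 72)
  d_hat <- vapply(seq_len(300), function(i) {
    jc_distance(div$pairs$ar_a[i], div$pairs$ar_b[i])$d
  }, numeric(1))
  expect_lt(abs(mean(d_hat) - 0.12), 0.005)
})

test_that("substitution ratios summarize matched pairs correctly", {
  # neutral control: suppression 1 gives median ~ 1 and no signal
  div0 <- simulate_divergence(n_pairs = 200, suppression = 1, seed = 81)
  sr0 <- substitution_ratio(div0$pairs)
  expect_lt(abs(sr0$summary$median_ratio - 1), 0.05)
  expect_gt(sr0$summary$p_value, 0.05)

  # arithmetic: d_p = 0.093, d_ar = 0.100 -> ratio 0.93
  p_of_d <- function(d, L) {
    n_mm <- round(L * 0.75 * (1 - exp(-4 * d / 3)))
    paste0(strrep("C", n_mm), strrep("A", L - n_mm))
  }
  L <- 100000
  pairs <- tibble::tibble(
    pair_id = "x",
    prompt_a = strrep("A", L), prompt_b = p_of_d(0.093, L),
    ar_a = strrep("A", L), ar_b = p_of_d(0.100, L)
  )
  sr <- substitution_ratio(pairs)
  expect_equal(sr$ratios$ratio, 0.93, tolerance = 1e-3)

  # suppressed simulation recovers the planted factor
  div <- simulate_divergence(n_pairs = 500, ar_sub_rate = 0.10,
                             suppression = 0.93, seed = 82)
  sr93 <- substitution_ratio(div$pairs)
  expect_lt(abs(sr93$summary$median_ratio - 0.93), 0.03)
  expect_lt(sr93$summary$p_value, 0.01)
})
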