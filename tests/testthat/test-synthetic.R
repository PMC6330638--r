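test_that("genome generation is deterministic and respects its contract", {
  a1 <- generate_genome(n_chrom = 2, chrom_len = 5e4, n_genes = 10, seed = 1)
  a2 <- generate_genome(n_chrom = 2, chrom_len = 5e4, n_genes = 10, seed = 1)
  expect_identical(a1$genome$sequence, a2$genome$sequence)
  expect_identical(a1$genes, a2$genes)
  expect_equal(nrow(a1$genes), 10)
  expect_true(all(a1$genes$start >= 1 & a1$genes$end <= 5e4))
  expect_true(all(c("+", "-") %in% a1$genes$strand))
  # genes do not overlap within a chromosome
  by_chrom <- split(a1$genes, a1$genes$chrom)
  for (g in by_chrom) {
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # GC near the configured background
  expect_equal(mean(gc_content(tibble::tibble(id = a1$genome$id,
                                              sequence = a1$genome$sequence))),
               0.42, tolerance = 0.01)
  expect_error(generate_genome(n_chrom = 1, chrom_len = 1e4, n_genes = 10),
               "infeasible")
})

test_that("planted PROMPT loci honor distances, orientations and the truth", {
  ann <- generate_genome(n_chrom = 4, chrom_len = 1e5, n_genes = 80, seed = 2)
  loci <- plant_prompt_loci(ann, n_prompts = 30, n_decoy_lnc = 10,
                            n_decoy_coding = 5, seed = 2)
  truth <- loci$truth
  expect_equal(sum(truth$class == "prompt"), 30)
  pr <- truth[truth$class == "prompt", ]
  expect_true(all(pr$distance >= 400 & pr$distance <= 800))
  expect_true(all(pr$orientation %in% c("sense", "antisense")))

  # orientation counts in the truth file are an honest Binomial draw record
  mix_counts <- table(pr$orientation)
  expect_equal(sum(mix_counts), 30)

  # planted TU sequences match what the patched genome yields
  extracted <- promptscape:::extract_spliced(loci$tus, loci$annotation$genome)
  expect_equal(extracted$sequence, loci$tus$sequence)

  # every truth id resolves to an emitted TU
  expect_setequal(truth$tu_id, loci$tus$tu_id)

  # determinism
  loci2 <- plant_prompt_loci(ann, n_prompts = 30, n_decoy_lnc = 10,
                             n_decoy_coding = 5, seed = 2)
  expect_identical(loci$tus$sequence, loci2$tus$sequence)
})

test_that("orientation mix recounts from the truth file at larger n", {
  ann <- generate_genome(n_chrom = 10, chrom_len = 1e5, n_genes = 200,
                         seed = 3)
  loci <- plant_prompt_loci(ann, n_prompts = 150, n_decoy_lnc = 0,
                            n_decoy_coding = 0, seed = 3)
  pr <- loci$truth[loci$truth$class == "prompt", ]
  sense_frac <- mean(pr$orientation == "sense")
  # binomial draw around 4.5%
  expect_lt(abs(sense_frac - 0.045), 3 * sqrt(0.045 * 0.955 / nrow(pr)))
})

test_that("null counts keep genomewide DE calls near the nominal level", {
  ids <- sprintf("t%03d", 1:500)
  sim <- simulate_counts(ids, planted_lfc = NULL, dispersion = 0.1, seed = 90)
  de <- nb_diff_test(sim$counts, sim$samples)
  expect_lte(mean(de$status != "ns"), 0.02)
  # determinism of the generator
  sim2 <- simulate_counts(ids, planted_lfc = NULL, dispersion = 0.1, seed = 90)
  expect_identical(sim$counts, sim2$counts)
})

test_that("structured scaffolds fold into the designed hairpins", {
  for (s in 1:5) {
    ps <- plant_structured_sequence(n_loops = 5,
                                    loop_motifs = c("4" = "WAACCA"), seed = s)
    # the motif instance sits at the recorded loop-4 offset
    expect_equal(substr(ps$sequence, ps$motif_truth$start,
                        ps$motif_truth$start + 5),
                 ps$motif_truth$instance)
    loop4 <- ps$elements[ps$elements$region == "loop" &
                           ps$elements$loop_index == 4, ]
    expect_gte(ps$motif_truth$start, loop4$start)
    expect_lte(ps$motif_truth$start + 5, loop4$end)
    folded <- fold_mfe(c(x = ps$sequence))
    ann <- annotate_elements(folded$dot_bracket)
    expect_gte(nrow(ann$loops), 5)
  }
  expect_error(plant_structured_sequence(loop_len = 4,
                                         loop_motifs = c("1" = "WAACCA")),
               "longer than the loop")
  s1 <- plant_structured_sequence(seed = 4)$sequence
  s2 <- plant_structured_sequence(seed = 4)$sequence
  expect_identical(s1, s2)
})

test_that("divergence pairs store realized substitution counts and rates", {
  div <- simulate_divergence(n_pairs = 50, ar_sub_rate = 0.1,
                             suppression = 0.93, len_range = c(800, 1200),
                             seed = 7)
  expect_equal(nrow(div$pairs), 50)
  expect_equal(nchar(div$pairs$prompt_a), div$truth$length)
  # truth counts match a direct recount of mismatches
  mm <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, div$pairs$ar_a, div$pairs$ar_b)
  expect_equal(unname(mm), div$truth$n_sub_ar)
  expect_identical(div$pairs,
                   simulate_divergence(n_pairs = 50, ar_sub_rate = 0.1,
                                       suppression = 0.93,
                                       len_range = c(800, 1200),
                                       seed = 7)$pairs)
  expect_error(simulate_divergence(ar_sub_rate = -1), "positive")
  expect_error(simulate_divergence(ar_sub_rate = 50), "saturated")
})

test_that("one-haplotype populations are uniform and LD-degenerate", {
  pop <- simulate_population(haplotypes = c("0101"), freqs = 1,
                             n_individuals = 20, seed = 5)
  hf <- haplotype_frequencies(pop$genotypes)
  expect_equal(hf$haplotype, "0101")
  expect_equal(hf$frequency, 1)
  expect_warning(res <- ld_r2(pop$genotypes, 1, 2), "monomorphic")
  expect_true(is.na(res$r2))
})

test_that("the synthetic surrogate plants its described architecture", {
  sur <- synthetic_prompt_surrogate()
  # motif in loop 4, intact across the planted SNPs
  expect_equal(sur$motif_truth$loop_index, 4)
  expect_equal(nrow(sur$snps), 3)
  expect_equal(sum(sur$snps$in_stem), 1)
  expect_true(all(substring(sur$hap1_seq, sur$snps$pos, sur$snps$pos) ==
                    sur$snps$ref))
  expect_identical(synthetic_prompt_surrogate()$hap1_seq, sur$hap1_seq)
})
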