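test_that("folding basics: unpairable sequences and simple hairpins", {
  res <- fold_mfe(c(a = "AAAAAAAAAA", hp = "GGGCGCAAAAAAGCGCCC"))
  expect_equal(res$dot_bracket[1], "..........")
  expect_equal(res$mfe[1], 0)
  expect_lt(res$mfe[2], 0)
  expect_equal(res$mfe_per_bp, res$mfe / res$length)
  expect_true(all(res$mfe <= 0))
  expect_error(fold_mfe("ACGX"), "non-nucleotide")
  # RNA and DNA spellings fold identically
  expect_equal(fold_mfe("GGGCGCAAAAAAGCGCCC")$mfe,
               fold_mfe("GGGCGCAAAAAAGCGCCC" |> chartr(old = "T", new = "U"))$mfe)
})

test_that("MFE equals exhaustive enumeration on short random sequences", {
  set.seed(31)
  for (i in 1:40) {
    s <- random_seq(sample(8:14, 1))
    expect_equal(fold_mfe(s)$mfe, mfe_brute(s), tolerance = 1e-6, info = s)
  }
})

test_that("element annotation matches the structure parse", {
  ann <- annotate_elements("(((....)))")
  expect_equal(ann$labels,
               c(rep("stem", 3), rep("hairpin_loop", 4), rep("stem", 3)))
  expect_equal(ann$loops$start, 4)
  expect_equal(ann$loops$end, 7)

  expect_equal(annotate_elements("....")$labels, rep("exterior", 4))

  ann2 <- annotate_elements("((..((...))..))")
  expect_equal(which(ann2$labels == "internal_loop"), c(3, 4, 12, 13))
  expect_equal(which(ann2$labels == "hairpin_loop"), 7:9)

  # bulge and multiloop classification
  ann3 <- annotate_elements("((.((...))((...))))")
  expect_equal(which(ann3$labels == "multiloop"), 3)
  ann4 <- annotate_elements("((.((...))))")
  expect_equal(ann4$labels[3], "bulge")

  expect_error(annotate_elements("((..)"), "unbalanced")
  # stems are exactly the paired positions; labels cover every position
  db <- "((..((...))..))...((....))"
  a <- annotate_elements(db)
  expect_equal(sum(a$labels == "stem"),
               sum(strsplit(db, "")[[1]] %in% c("(", ")")))
  expect_length(a$labels, nchar(db))
})

test_that("motif scanning matches a sliding window and honors strand/N rules", {
  hits <- scan_motifs(c(s = "TTAACCATT"),
                      tibble::tibble(motif_id = "MYB1AT", consensus = "WAACCA"))
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$start, 2)
  expect_equal(plus$matched, "TAACCA")

  # motif longer than the sequence: no hits
  expect_equal(nrow(scan_motifs(c(s = "ACG"),
                                tibble::tibble(motif_id = "m",
                                               consensus = "ACGTACGT"))), 0)

  # palindromic motif hits both strands at the same locus
  pal <- scan_motifs(c(s = "AAGAATTCAA"),
                     tibble::tibble(motif_id = "pal", consensus = "GAATTC"))
  expect_equal(nrow(pal), 2)
  expect_equal(unique(pal$start), 3)
  expect_setequal(pal$strand, c("+", "-"))

  # N in the scanned sequence never matches
  expect_equal(nrow(scan_motifs(c(s = "TTANCCATT"),
                                tibble::tibble(motif_id = "m",
                                               consensus = "WAACCA"))), 0)

  # overlapping matches are all reported
  ovl <- scan_motifs(c(s = "AAAAA"),
                     tibble::tibble(motif_id = "m", consensus = "AAA"),
                     both_strands = FALSE)
  expect_equal(ovl$start, 1:3)
})

test_that("minus-strand hits are reported in plus coordinates", {
  # GGGTTC on the minus strand of GAACCC (revcomp)
  hits <- scan_motifs(c(s = "TTGAACCCTT"),
                      tibble::tibble(motif_id = "m", consensus = "GGGTTC"))
  expect_equal(hits$strand, "-")
  expect_equal(hits$start, 3)
  expect_equal(hits$end, 8)
  expect_equal(hits$matched, "GGGTTC")
})

test_that("loop enrichment detects concentrated hits and flags degeneracy", {
  labels <- c(rep("stem", 25), rep("hairpin_loop", 25),
              rep("stem", 25), rep("hairpin_loop", 25))
  loop_hits <- tibble::tibble(
    id = "s", motif_id = "m",
    start = c(26, 30, 35, 40, 45, 76, 80, 85, 90, 95),
    end = c(26, 30, 35, 40, 45, 76, 80, 85, 90, 95) + 1,
    strand = "+", matched = "AA"
  )
  res <- loop_motif_enrichment(loop_hits, labels)
  expect_lt(res$p_value, 0.01)
  expect_gt(res$odds_ratio, 1)

  # proportional hits: odds ratio near 1, no signal
  prop_hits <- tibble::tibble(id = "s", motif_id = "m",
                              start = c(1, 26, 51, 76), end = c(5, 30, 55, 80),
                              strand = "+", matched = "AAAAA")
  res2 <- loop_motif_enrichment(prop_hits, labels)
  expect_equal(res2$odds_ratio, 1, tolerance = 0.3)

  expect_error(loop_motif_enrichment(loop_hits[0, ], labels), "no motif hits")
  expect_warning(res3 <- loop_motif_enrichment(prop_hits, rep("stem", 100)),
                 "one class")
  expect_equal(res3$p_value, 1)
})

test_that("SNP delta-MFE obeys the energy bookkeeping", {
  # substitution in a long exterior run changes nothing
  s <- paste0("GGGGCCCC", strrep("A", 30), "GGGGCCCC")
  hp <- paste0("GCGCGC", "AAAAA", "GCGCGC")
  hairpin <- "GGGCGCAAAAAAGCGCCC"
  ext <- snp_delta_mfe(paste0(hairpin, strrep("A", 20)),
                       tibble::tibble(pos = 30, ref = "A", alt = "C"))
  expect_equal(ext$delta_mfe, 0)
  expect_false(ext$structure_changed)

  # disrupting a GC pair in a forced hairpin destabilizes
  gc_hit <- snp_delta_mfe(hairpin, tibble::tibble(pos = 2, ref = "G", alt = "A"))
  expect_gt(gc_hit$delta_mfe, 0)

  # antisymmetry: applying a SNP and then its reverse cancels
  fwd <- snp_delta_mfe(hairpin, tibble::tibble(pos = 2, ref = "G", alt = "A"))
  mutated <- promptscape:::apply_snps(hairpin,
                                      tibble::tibble(pos = 2, ref = "G", alt = "A"))
  rev <- snp_delta_mfe(mutated, tibble::tibble(pos = 2, ref = "A", alt = "G"))
  expect_equal(fwd$delta_mfe + rev$delta_mfe, 0)
  expect_equal(fwd$delta_mfe, fwd$mfe_alt - fwd$mfe_ref)

  expect_error(snp_delta_mfe(hairpin, tibble::tibble(pos = 2, ref = "C",
                                                     alt = "A")),
               "position 2")
})

test_that("haplotype-level variants combine SNPs into one refold", {
  sur <- synthetic_prompt_surrogate()
  hap <- snp_delta_mfe(sur$hap1_seq, sur$snps, combine = TRUE)
  expect_equal(nrow(hap), 1)
  expect_equal(hap$delta_mfe, hap$mfe_alt - hap$mfe_ref)
  expect_gt(hap$delta_mfe, 0)  # the planted stem wobble destabilizes Hap2
})

test_that("loop deletions remove exactly the loop interval and destabilize", {
  # no hairpins -> empty result
  expect_equal(nrow(loop_deletion_mutants(strrep("A", 30))), 0)

  res <- loop_deletion_mutants("GGGCGCAAAAAAGCGCCC")
  expect_equal(nrow(res), 1)
  expect_equal(nchar(res$mutant_seq),
               nchar("GGGCGCAAAAAAGCGCCC") - (res$loop_end - res$loop_start + 1))
  expect_gt(res$delta_mfe, 0)

  scaffold <- plant_structured_sequence(n_loops = 5, seed = 77)
  res5 <- loop_deletion_mutants(scaffold$sequence)
  expect_equal(res5$loop_index, 1:5)
  expect_true(all(diff(res5$loop_start) > 0))  # reported 5' to 3'
})

test_that("loop-to-stem search pairs up former loop positions", {
  # hairpin whose loop UUU can pair with a downstream AAA context
  scaffold <- plant_structured_sequence(n_loops = 2, stem_len = 6,
                                        loop_len = 5, seed = 13)
  wt <- fold_mfe(c(s = scaffold$sequence))
  ann <- annotate_elements(wt$dot_bracket)
  before <- promptscape:::pair_table(wt$dot_bracket)
  res <- loop_to_stem_mutation(scaffold$sequence, loop_index = 1,
                               n_changes = 3)
  loop1 <- ann$loops[1, ]
  frac_before <- mean(before[loop1$start:loop1$end] > 0)
  expect_gte(res$paired_fraction, frac_before)
  if (res$changed) {
    # only loop positions were touched
    diffs <- which(strsplit(res$mutant_seq, "")[[1]] !=
                     strsplit(toupper(scaffold$sequence), "")[[1]])
    expect_true(all(diffs >= loop1$start & diffs <= loop1$end))
    expect_lte(length(diffs), 3)
  }

  # n_changes = 0 is the identity
  id0 <- loop_to_stem_mutation(scaffold$sequence, 1, 0)
  expect_false(id0$changed)
  expect_equal(id0$mutant_seq, toupper(scaffold$sequence))

  expect_error(loop_to_stem_mutation(scaffold$sequence, 99, 1), "out of range")
})

test_that("planted loop motifs are recovered with hairpin-loop context", {
  motifs <- tibble::tibble(motif_id = "MYB1AT", consensus = "WAACCA")
  recovered <- 0; total <- 0
  for (s in 1:10) {
    ps <- plant_structured_sequence(n_loops = 5,
                                    loop_motifs = c("2" = "WAACCA",
                                                    "4" = "WAACCA"),
                                    seed = 100 + s)
    folded <- fold_mfe(c(x = ps$sequence))
    ann <- annotate_elements(folded$dot_bracket)
    hits <- scan_motifs(c(x = ps$sequence), motifs, both_strands = FALSE)
    hits <- hit_element_context(hits, ann$labels)
    for (k in seq_len(nrow(ps$motif_truth))) {
      total <- total + 1
      hit <- hits[hits$start == ps$motif_truth$start[k], ]
      if (nrow(hit) == 1 && hit$element_context == "hairpin_loop") {
        recovered <- recovered + 1
      }
    }
  }
  expect_gte(recovered / total, 0.9)
})
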