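# Synthetic-data generators. Every pipeline input can be generated with
# known ground truth: a genome with genes, planted PROMPT loci plus decoy
# classes, NB counts with planted fold changes and PROMPT-gene coupling,
# phased population haplotypes, diverged PROMPT/ancestral-repeat alignment
# pairs, and multi-hairpin sequences with motifs planted in loops. All
# generators are deterministic under a fixed seed.

#' Generate a synthetic genome with non-overlapping genes
#'
#' Chromosomes are iid nucleotides at the background GC; genes are placed
#' in equal slots with a guaranteed clear margin on both sides, so upstream
#' loci can be planted later without collisions. Strands are random.
#'
#' @param n_chrom,chrom_len Number and length of chromosomes.
#' @param n_genes Total genes, distributed evenly across chromosomes.
#' @param gene_length_range Min/max gene length (nt).
#' @param margin Guaranteed gene-free distance on each side of every gene.
#' @param gc Background GC fraction.
#' @param seed RNG seed.
#' @return A [genome_annotation()] with attached sequences.
#' @export
generate_genome <- function(n_chrom = 10, chrom_len = 1e5, n_genes = 200,
                            gene_length_range = c(600, 1200), margin = 1800,
                            gc = 0.42, seed = 1) {
  per_chrom <- rep(n_genes %/% n_chrom, n_chrom)
  extra <- n_genes %% n_chrom
  if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1
  slot <- chrom_len / max(per_chrom)
  if (slot < gene_length_range[2] + 2 * margin) {
    abort("infeasible packing: genes do not fit with the requested margin")
  }
  with_seed(seed, {
    chroms <- paste0("chr", sprintf("%02d", seq_len(n_chrom)))
    genome <- tibble(
      id = chroms,
      sequence = vapply(seq_len(n_chrom), function(i) random_dna(chrom_len, gc),
                        character(1))
    )
    genes <- purrr::map(seq_len(n_chrom), function(ci) {
      k <- per_chrom[ci]
      if (k == 0) return(NULL)
      slot_starts <- floor((seq_len(k) - 1) * (chrom_len / k)) + 1
      len <- sample_range(gene_length_range[1], gene_length_range[2], k)
      slack <- floor(chrom_len / k) - len - 2 * margin
      offset <- floor(runif(k) * (slack + 1))
      start <- slot_starts + margin + offset
      tibble(
        gene_id = sprintf("gene_%s_%03d", chroms[ci], seq_len(k)),
        chrom = chroms[ci],
        strand = sample(c("+", "-"), k, replace = TRUE),
        start = start, end = start + len - 1
      )
    }) %>% bind_rows()
    genome_annotation(genes, genome = genome)
  })
}

patch_genome <- function(genome, chrom, start, segment) {
  i <- which(genome$id == chrom)
  s <- genome$sequence[i]
  genome$sequence[i] <- paste0(
    substring(s, 1, start - 1), segment,
    substring(s, start + nchar(segment), nchar(s))
  )
  genome
}

overlaps_any <- function(start, end, ivs) {
  any(ivs$start <= end & ivs$end >= start)
}

# rejection-sample a segment that passes (or fails) the lncRNA sequence
# filters in both orientations, so planted truth holds by construction
sample_noncoding_segment <- function(len, gc = 0.42, max_try = 60) {
  for (i in seq_len(max_try)) {
    s <- random_dna(len, gc)
    if (find_longest_orf(c(x = s))$orf_len >= 250) next
    sc <- coding_potential_score(tibble(id = c("f", "r"),
                                        sequence = c(s, reverse_complement(s))))
    if (max(sc$score) < -0.05) return(s)
  }
  abort("could not sample a noncoding segment; increase max_try")
}

sample_coding_segment <- function(len, max_try = 60) {
  stopifnot(len >= 420)
  sense_codons <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    c("TAA", "TAG", "TGA")
  )
  for (i in seq_len(max_try)) {
    n_codons <- (len - 60) %/% 3 - 2
    orf <- paste0("ATG", paste(sample(sense_codons, n_codons, replace = TRUE),
                               collapse = ""), "TAA")
    utr5 <- random_dna(30)
    rest <- len - nchar(orf) - 30
    s <- paste0(utr5, orf, random_dna(max(rest, 0)))
    s <- substring(s, 1, len)
    orf_len <- find_longest_orf(c(x = s))$orf_len
    sc <- coding_potential_score(c(x = s))$score
    if (orf_len >= 300 && sc > 0.1) return(s)
  }
  abort("could not sample a coding segment")
}

#' Plant PROMPT loci, decoy lncRNAs and coding decoys in a genome
#'
#' Planted PROMPTs satisfy the PROMPT definition by construction: the whole
#' TU lies strictly upstream of its gene's TSS at a distance drawn from
#' `distance_range`, on a strand drawn from `orientation_mix`, with a
#' sequence sampled to pass the lncRNA filters (length, ORF, coding score)
#' in both orientations. Decoy classes make classifier specificity
#' testable: intergenic lncRNAs verified to be farther than `decoy_min_gap`
#' from every TSS, coding decoys placed upstream like PROMPTs but carrying
#' a long ORF, and (optionally) lncRNAs overlapping a gene body. The
#' genome sequence is patched so extracted TU sequences match the planted
#' ones.
#'
#' @param annotation A [genome_annotation()] from [generate_genome()].
#' @param n_prompts,n_decoy_lnc,n_decoy_coding,n_decoy_overlap Counts per
#'   class.
#' @param distance_range TSS distance range for planted PROMPTs (default
#'   400-800 bp, the observed range in poplar).
#' @param orientation_mix Named probabilities for `antisense` / `sense`
#'   orientation (default 95.5% / 4.5%).
#' @param tu_length_range TU length range (nt).
#' @param decoy_min_gap Minimum TSS distance for intergenic decoys
#'   (default 2500, the classification window).
#' @param seed RNG seed.
#' @return List with `tus` (TU tibble including sequences), `truth`
#'   (tibble: `tu_id`, `class`, `gene_id`, `distance`, `orientation`) and
#'   `annotation` (the patched annotation).
#' @export
plant_prompt_loci <- function(annotation, n_prompts = 60,
                              distance_range = c(400, 800),
                              orientation_mix = c(antisense = 0.955,
                                                  sense = 0.045),
                              n_decoy_lnc = 40, n_decoy_coding = 20,
                              n_decoy_overlap = 0,
                              tu_length_range = c(300, 600),
                              decoy_min_gap = 2500, seed = 1) {
  genes <- annotation$genes
  genome <- annotation$genome
  if (is.null(genome)) abort("annotation must carry genome sequences")
  chrom_len <- annotation$chrom_lengths

  with_seed(seed, {
    occupied <- genes %>% select("chrom", "start", "end")
    tus <- list(); truth <- list()
    upstream_classes <- c(rep("prompt", n_prompts),
                          rep("decoy_coding", n_decoy_coding))
    host_genes <- sample(genes$gene_id, length(upstream_classes))

    for (i in seq_along(upstream_classes)) {
      cls <- upstream_classes[i]
      g <- genes[genes$gene_id == host_genes[i], ]
      d <- sample_range(distance_range[1], distance_range[2])
      len <- sample_range(tu_length_range[1], tu_length_range[2])
      if (cls == "decoy_coding") len <- max(len, 450)
      if (g$strand == "+") {
        tu_end <- g$tss - d; tu_start <- tu_end - len + 1
      } else {
        tu_start <- g$tss + d; tu_end <- tu_start + len - 1
      }
      if (tu_start < 1 || tu_end > chrom_len[[g$chrom]] ||
          overlaps_any(tu_start, tu_end, occupied[occupied$chrom == g$chrom, ])) {
        warn(sprintf("insufficient upstream space at gene %s; skipped", g$gene_id))
        next
      }
      orientation <- sample(names(orientation_mix), 1, prob = orientation_mix)
      tu_strand <- if (orientation == "sense") g$strand else
        setdiff(c("+", "-"), g$strand)
      segment <- if (cls == "prompt") sample_noncoding_segment(len) else
        sample_coding_segment(len)
      # the segment is the TU's own 5'->3' sequence; store its plus-strand
      # image in the genome
      plus_image <- if (tu_strand == "+") segment else reverse_complement(segment)
      genome <- patch_genome(genome, g$chrom, tu_start, plus_image)
      id <- sprintf("%s_%04d", toupper(cls), i)
      tus[[id]] <- tu_tbl(id, g$chrom, tu_strand, tu_start, tu_end,
                          sequence = segment)
      occupied <- bind_rows(occupied,
                            tibble(chrom = g$chrom, start = tu_start, end = tu_end))
      truth[[id]] <- tibble(tu_id = id, class = cls, gene_id = g$gene_id,
                            distance = d, orientation = orientation)
    }

    # intergenic decoys: anywhere that does NOT satisfy the PROMPT geometry
    placed <- 0; tries <- 0
    while (placed < n_decoy_lnc && tries < n_decoy_lnc * 200) {
      tries <- tries + 1
      chrom <- sample(names(chrom_len), 1)
      len <- sample_range(tu_length_range[1], tu_length_range[2])
      tu_start <- sample(seq_len(chrom_len[[chrom]] - len), 1)
      tu_end <- tu_start + len - 1
      cg <- genes[genes$chrom == chrom, ]
      qualifies <- any(
        ifelse(cg$strand == "+",
               tu_end < cg$start & (cg$tss - tu_end) <= decoy_min_gap,
               tu_start > cg$end & (tu_start - cg$tss) <= decoy_min_gap)
      )
      if (qualifies ||
          overlaps_any(tu_start, tu_end, occupied[occupied$chrom == chrom, ])) {
        next
      }
      placed <- placed + 1
      tu_strand <- sample(c("+", "-"), 1)
      segment <- sample_noncoding_segment(len)
      plus_image <- if (tu_strand == "+") segment else reverse_complement(segment)
      genome <- patch_genome(genome, chrom, tu_start, plus_image)
      id <- sprintf("DECOY_LNC_%04d", placed)
      tus[[id]] <- tu_tbl(id, chrom, tu_strand, tu_start, tu_end,
                          sequence = segment)
      occupied <- bind_rows(occupied, tibble(chrom = chrom, start = tu_start,
                                             end = tu_end))
      truth[[id]] <- tibble(tu_id = id, class = "decoy_intergenic",
                            gene_id = NA_character_, distance = NA_real_,
                            orientation = NA_character_)
    }
    if (placed < n_decoy_lnc) {
      warn("could not place all intergenic decoys")
    }

    if (n_decoy_overlap > 0) {
      hosts <- sample(setdiff(genes$gene_id, host_genes), n_decoy_overlap)
      for (j in seq_len(n_decoy_overlap)) {
        g <- genes[genes$gene_id == hosts[j], ]
        len <- sample_range(tu_length_range[1], tu_length_range[2])
        tu_start <- g$start + 10
        tu_end <- min(tu_start + len - 1, g$end)
        id <- sprintf("DECOY_OVL_%04d", j)
        segment <- sample_noncoding_segment(tu_end - tu_start + 1)
        tu_strand <- sample(c("+", "-"), 1)
        plus_image <- if (tu_strand == "+") segment else
          reverse_complement(segment)
        genome <- patch_genome(genome, g$chrom, tu_start, plus_image)
        tus[[id]] <- tu_tbl(id, g$chrom, tu_strand, tu_start, tu_end,
                            sequence = segment)
        truth[[id]] <- tibble(tu_id = id, class = "decoy_overlap",
                              gene_id = g$gene_id, distance = NA_real_,
                              orientation = NA_character_)
      }
    }

    ann <- genome_annotation(genes, genome = genome)
    list(tus = bind_rows(tus), truth = bind_rows(truth), annotation = ann)
  })
}

# ---------------------------------------------------------------------------
# Counts

#' Simulate NB counts with planted fold changes and PROMPT-gene coupling
#'
#' Per-TU baseline log2 means are Gaussian; planted log2 fold changes are
#' added to the treated group; PROMPT/downstream-gene pairs share a
#' Gaussian latent factor on the log scale so that their baseline
#' abundances across pairs correlate at `coupling_r` (the across-pairs
#' scatter statistic), plus a fully shared per-sample factor giving
#' within-pair co-variation. Counts are drawn NB with the given dispersion
#' (`var = mu + dispersion * mu^2`).
#'
#' @param tu_ids Character vector of TU ids (pairs' members must be
#'   included).
#' @param n_reps Replicates per group (the study used 3).
#' @param groups Two group labels, control first.
#' @param baseline_log2_mean,baseline_log2_sd Baseline abundance
#'   distribution (log2 scale).
#' @param planted_lfc Named vector of log2 fold changes (unnamed TUs get
#'   0).
#' @param dispersion NB dispersion, must be positive.
#' @param pairs Optional tibble `(prompt, gene)` of coupled pairs.
#' @param coupling_r Target across-pairs correlation of baseline log
#'   abundance (default 0.65).
#' @param sample_factor_sd SD (log2) of the shared per-sample factor within
#'   a pair.
#' @param libsize_rel Optional named per-sample relative depths (default
#'   all 1).
#' @param seed RNG seed.
#' @return List with `counts` (tibble `tu_id` + samples), `samples`
#'   (`sample`, `group`), `lengths` (`tu_id`, `length`; nominal 1 kb), and
#'   `truth` (per-TU baseline, lfc, pair id and realized latents).
#' @export
simulate_counts <- function(tu_ids, n_reps = 3,
                            groups = c("control", "treated"),
                            baseline_log2_mean = 6, baseline_log2_sd = 1.5,
                            planted_lfc = NULL, dispersion = 0.1,
                            pairs = NULL, coupling_r = 0.65,
                            sample_factor_sd = 0.5, libsize_rel = NULL,
                            seed = 1) {
  if (dispersion <= 0) abort("dispersion must be positive")
  if (n_reps < 2) abort("need at least 2 replicates per group")
  n_tu <- length(tu_ids)
  stopifnot(!anyDuplicated(tu_ids))
  lfc <- setNames(rep(0, n_tu), tu_ids)
  if (!is.null(planted_lfc)) lfc[names(planted_lfc)] <- planted_lfc

  samples <- tibble(
    sample = paste0(rep(groups, each = n_reps), "_", rep(seq_len(n_reps), 2)),
    group = rep(groups, each = n_reps)
  )

  with_seed(seed, {
    base <- baseline_log2_mean + baseline_log2_sd * rnorm(n_tu)
    names(base) <- tu_ids
    pair_id <- setNames(rep(NA_integer_, n_tu), tu_ids)
    if (!is.null(pairs) && nrow(pairs) > 0) {
      pairs <- as_tibble(pairs)
      stopifnot(all(c(pairs$prompt, pairs$gene) %in% tu_ids))
      z <- rnorm(nrow(pairs))
      e1 <- rnorm(nrow(pairs)); e2 <- rnorm(nrow(pairs))
      base[pairs$prompt] <- baseline_log2_mean + baseline_log2_sd *
        (sqrt(coupling_r) * z + sqrt(1 - coupling_r) * e1)
      base[pairs$gene] <- baseline_log2_mean + baseline_log2_sd *
        (sqrt(coupling_r) * z + sqrt(1 - coupling_r) * e2)
      pair_id[pairs$prompt] <- seq_len(nrow(pairs))
      pair_id[pairs$gene] <- seq_len(nrow(pairs))
    }
    n_samp <- nrow(samples)
    sample_factor <- if (!is.null(pairs) && nrow(pairs) > 0) {
      matrix(rnorm(nrow(pairs) * n_samp, sd = sample_factor_sd),
             nrow = nrow(pairs))
    } else {
      NULL
    }
    lib <- rep(1, n_samp)
    if (!is.null(libsize_rel)) lib <- unname(libsize_rel[samples$sample])

    counts <- matrix(0L, nrow = n_tu, ncol = n_samp,
                     dimnames = list(tu_ids, samples$sample))
    treated <- samples$group == groups[2]
    for (s in seq_len(n_samp)) {
      logmu <- if (treated[s]) base + lfc else base
      if (!is.null(sample_factor)) {
        has_pair <- !is.na(pair_id)
        logmu[has_pair] <- logmu[has_pair] + sample_factor[pair_id[has_pair], s]
      }
      mu <- 2^logmu * lib[s]
      counts[, s] <- rnbinom(n_tu, mu = mu, size = 1 / dispersion)
    }
    list(
      counts = bind_cols(tibble(tu_id = tu_ids), as_tibble(counts)),
      samples = samples,
      lengths = tibble(tu_id = tu_ids, length = 1000),
      truth = tibble(tu_id = tu_ids, baseline_log2 = unname(base),
                     lfc = unname(lfc), pair_id = unname(pair_id))
    )
  })
}

#' Simulate expression profiles with one or more planted co-expression
#' modules
#'
#' Module members (one PROMPT plus `module_size` genes per module) share a
#' per-sample latent factor with loading `sqrt(r_within)`; background genes
#' are independent. Values are returned on a positive FPKM-like scale
#' (`2^x - 1` of the Gaussian log2 profiles) so the designed correlation
#' structure is exactly recovered on `log2(x + 1)`.
#'
#' @param n_modules Number of planted modules.
#' @param module_size Genes per module (PROMPT excluded).
#' @param n_background Independent background genes.
#' @param n_samples Number of samples/conditions.
#' @param r_within Pairwise correlation among module members.
#' @param seed RNG seed.
#' @return List with `expr` (tibble `tu_id` + sample columns), `kinds`
#'   (`id`, `kind`) and `truth` (`id`, `module`).
#' @export
simulate_coexpression <- function(n_modules = 1, module_size = 80,
                                  n_background = 500, n_samples = 100,
                                  r_within = 0.95, seed = 1) {
  with_seed(seed, {
    rows <- list(); truth <- list(); kinds <- list()
    for (m in seq_len(n_modules)) {
      f <- rnorm(n_samples)
      ids <- c(sprintf("PROMPT_M%02d", m),
               sprintf("geneM%02d_%03d", m, seq_len(module_size)))
      x <- t(vapply(ids, function(id) {
        sqrt(r_within) * f + sqrt(1 - r_within) * rnorm(n_samples)
      }, numeric(n_samples)))
      rows[[m]] <- x
      truth[[m]] <- tibble(id = ids, module = m)
      kinds[[m]] <- tibble(id = ids,
                           kind = c("PROMPT", rep("gene", module_size)))
    }
    bg_ids <- sprintf("bg_%04d", seq_len(n_background))
    bg <- matrix(rnorm(n_background * n_samples), nrow = n_background,
                 dimnames = list(bg_ids, NULL))
    all_x <- rbind(do.call(rbind, rows), bg)
    expr <- 2^(6 + all_x) - 1
    colnames(expr) <- sprintf("s%02d", seq_len(n_samples))
    list(
      expr = bind_cols(tibble(tu_id = rownames(all_x)), as_tibble(expr)),
      kinds = bind_rows(kinds) %>%
        bind_rows(tibble(id = bg_ids, kind = "gene")),
      truth = bind_rows(truth) %>%
        bind_rows(tibble(id = bg_ids, module = 0L))
    )
  })
}

# ---------------------------------------------------------------------------
# Population

#' Simulate a phased natural population from haplotype frequencies
#'
#' Individuals are pairs of haplotypes drawn multinomially from the given
#' frequencies (the three-haplotype scenario of a 505-individual poplar
#' population is the default).
#'
#' @param haplotypes Character vector of allele strings (0/1 per site).
#' @param freqs Haplotype frequencies, summing to 1.
#' @param n_individuals Number of diploid individuals.
#' @param sites Optional site tibble (`chrom`, `pos`, `ref`, `alt`);
#'   auto-generated when omitted.
#' @param seed RNG seed.
#' @return List with `genotypes` (a `genotype_table`) and `truth`
#'   (`haplotype`, `planted_freq`, `drawn_count`).
#' @export
simulate_population <- function(haplotypes = c("00000000", "11111111",
                                               "11110000"),
                                freqs = c(0.595, 0.394, 0.011),
                                n_individuals = 505, sites = NULL, seed = 1) {
  if (any(freqs < 0)) abort("haplotype frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-9) abort("haplotype frequencies must sum to 1")
  n_sites <- nchar(haplotypes[1])
  stopifnot(all(nchar(haplotypes) == n_sites))
  if (is.null(sites)) {
    sites <- tibble(chrom = "chr04", pos = 20582000L + 40L * seq_len(n_sites),
                    ref = "A", alt = "G")
  }
  with_seed(seed, {
    n_hap_rows <- 2 * n_individuals
    drawn <- as.vector(rmultinom(1, n_hap_rows, freqs))
    pool <- sample(rep(seq_along(haplotypes), drawn))
    mat <- do.call(rbind, lapply(pool, function(h) {
      as.integer(seq_char(haplotypes[h]))
    }))
    rownames(mat) <- paste0(
      rep(sprintf("ind%04d", seq_len(n_individuals)), each = 2),
      rep(c("_a", "_b"), n_individuals)
    )
    list(
      genotypes = new_genotype_table(sites, mat),
      truth = tibble(haplotype = haplotypes, planted_freq = freqs,
                     drawn_count = drawn)
    )
  })
}

#' Simulate diverged PROMPT / ancestral-repeat alignment pairs
#'
#' Each pair holds two alignments: an ancestral-repeat alignment whose
#' derived sequence is mutated from the ancestor under Jukes-Cantor at
#' distance `ar_sub_rate`, and a PROMPT alignment mutated at
#' `suppression * ar_sub_rate`. A suppression factor below 1 emulates
#' purifying selection on the PROMPT sequence.
#'
#' @param n_pairs Number of matched pairs.
#' @param ar_sub_rate JC substitution distance of the neutral repeats.
#' @param suppression Multiplier on the PROMPT substitution distance
#'   (default 0.93, i.e. 7% suppression).
#' @param len_range Alignment length range.
#' @param gc Base composition of the ancestors.
#' @param seed RNG seed.
#' @return List with `pairs` (tibble `pair_id`, `prompt_a`, `prompt_b`,
#'   `ar_a`, `ar_b`) and `truth` (per-pair realized mismatch counts).
#' @export
simulate_divergence <- function(n_pairs = 500, ar_sub_rate = 0.10,
                                suppression = 0.93,
                                len_range = c(1000, 1000), gc = 0.42,
                                seed = 1) {
  if (ar_sub_rate <= 0 || suppression <= 0) abort("rates must be positive")
  p_of_d <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  p_ar <- p_of_d(ar_sub_rate)
  p_pr <- p_of_d(suppression * ar_sub_rate)
  if (p_ar >= 0.75 || p_pr >= 0.75) abort("rate implies saturated divergence (p >= 0.75)")
  mutate_seq <- function(s, p) {
    chars <- seq_char(s)
    hit <- runif(length(chars)) < p
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    list(seq = paste(chars, collapse = ""), n_sub = sum(hit))
  }
  with_seed(seed, {
    out <- purrr::map(seq_len(n_pairs), function(i) {
      len <- sample_range(len_range[1], len_range[2])
      anc_p <- random_dna(len, gc)
      anc_a <- random_dna(len, gc)
      mp <- mutate_seq(anc_p, p_pr)
      ma <- mutate_seq(anc_a, p_ar)
      list(
        pair = tibble(pair_id = sprintf("pair_%04d", i),
                      prompt_a = anc_p, prompt_b = mp$seq,
                      ar_a = anc_a, ar_b = ma$seq),
        truth = tibble(pair_id = sprintf("pair_%04d", i), length = len,
                       n_sub_prompt = mp$n_sub, n_sub_ar = ma$n_sub)
      )
    })
    list(pairs = purrr::map(out, "pair") %>% bind_rows(),
         truth = purrr::map(out, "truth") %>% bind_rows())
  })
}

# ---------------------------------------------------------------------------
# Structured sequences

concretize_iupac <- function(consensus) {
  paste(vapply(seq_char(toupper(consensus)), function(ch) {
    letters <- seq_char(IUPAC_CODES[[ch]])
    if (length(letters) == 1) letters else sample(letters, 1)
  }, character(1)), collapse = "")
}

#' Build a multi-hairpin sequence with motifs planted in loops
#'
#' Constructs `n_loops` hairpins joined by short single-stranded linkers:
#' each stem is a GC-rich random duplex (left arm and its reverse
#' complement), each loop is AT-rich so it stays unpaired, and chosen loops
#' carry a concrete instance of an IUPAC motif at a recorded offset. The
#' emitted molecule folds into (at least) the designed hairpins under the
#' thermodynamic model.
#'
#' @param n_loops Number of hairpins.
#' @param loop_motifs Named character vector mapping loop index (as
#'   character) to an IUPAC consensus, e.g. `c("4" = "WAACCA")`.
#' @param stem_len,loop_len Stem arm and loop lengths (nt); the loop must
#'   fit the motif.
#' @param linker_len Length of the single-stranded linkers.
#' @param seed RNG seed.
#' @return List with `sequence`, `elements` (tibble `region`, `loop_index`,
#'   `start`, `end` of the intended stems/loops) and `motif_truth`
#'   (`loop_index`, `motif_id`/consensus, `instance`, `start`).
#' @export
plant_structured_sequence <- function(n_loops = 5, loop_motifs = NULL,
                                      stem_len = 8, loop_len = 12,
                                      linker_len = 3, seed = 1) {
  if (!is.null(loop_motifs)) {
    too_long <- nchar(loop_motifs) > loop_len
    if (any(too_long)) abort("motif longer than the loop")
  }
  gc_rich <- function(n) {
    paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
                 prob = c(0.4, 0.4, 0.1, 0.1)), collapse = "")
  }
  at_rich <- function(n) {
    paste(sample(c("A", "T", "C"), n, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2)), collapse = "")
  }
  with_seed(seed, {
    pieces <- character(0)
    elements <- list(); motif_truth <- list()
    pos <- 0
    add_piece <- function(s) {
      pieces <<- c(pieces, s)
      start <- pos + 1
      pos <<- pos + nchar(s)
      c(start, pos)
    }
    add_piece(strrep("A", linker_len))
    for (i in seq_len(n_loops)) {
      stem5 <- gc_rich(stem_len)
      iv <- add_piece(stem5)
      elements[[length(elements) + 1]] <-
        tibble(region = "stem", loop_index = i, start = iv[1], end = iv[2])
      loop <- at_rich(loop_len)
      motif <- if (!is.null(loop_motifs) && as.character(i) %in% names(loop_motifs))
        loop_motifs[[as.character(i)]] else NULL
      offset <- 0L
      instance <- NA_character_
      if (!is.null(motif)) {
        instance <- concretize_iupac(motif)
        offset <- sample(0:(loop_len - nchar(instance)), 1)
        loop <- paste0(substring(loop, 1, offset), instance,
                       substring(loop, offset + nchar(instance) + 1, loop_len))
      }
      iv <- add_piece(loop)
      elements[[length(elements) + 1]] <-
        tibble(region = "loop", loop_index = i, start = iv[1], end = iv[2])
      if (!is.null(motif)) {
        motif_truth[[length(motif_truth) + 1]] <-
          tibble(loop_index = i, consensus = motif, instance = instance,
                 start = iv[1] + offset)
      }
      iv <- add_piece(reverse_complement(stem5))
      elements[[length(elements) + 1]] <-
        tibble(region = "stem", loop_index = i, start = iv[1], end = iv[2])
      add_piece(strrep("A", linker_len))
    }
    list(sequence = paste(pieces, collapse = ""),
         elements = bind_rows(elements),
         motif_truth = if (length(motif_truth)) bind_rows(motif_truth) else
           tibble(loop_index = integer(), consensus = character(),
                  instance = character(), start = integer()))
  })
}

#' Synthetic stand-in for the PROMPT_1281 haplotype pair
#'
#' The published PROMPT_1281 sequence is not redistributable here, so this
#' builds a synthetic surrogate with the reported architecture: five
#' hairpin loops with a MYB1AT motif (WAACCA) in loop 4 and three
#' transcript SNPs, one of which softens a stem Watson-Crick pair into a
#' G-U wobble so that Hap2 (the alternate allele string) folds less stably
#' than Hap1 (the reference) by a small energy margin, while the loop SNPs
#' leave the energy unchanged. Genomic haplotype strings over eight sites
#' (the transcript SNPs plus flanking/intronic ones) are provided for
#' population simulation. All downstream numbers computed from this object
#' are properties of the surrogate, not of any published molecule.
#'
#' @param seed RNG seed.
#' @return List with `hap1_seq`, `snps` (tibble `pos`, `ref`, `alt`,
#'   `in_stem`), `elements` and `motif_truth` from the underlying
#'   scaffold, and `haplotype_strings` over eight genomic sites (`hap1` =
#'   all ref, `hap2` = all alt, `hap3` = half alt).
#' @export
synthetic_prompt_surrogate <- function(seed = 1281) {
  scaffold <- plant_structured_sequence(
    n_loops = 5, loop_motifs = c("4" = "WAACCA"),
    stem_len = 9, loop_len = 12, linker_len = 3, seed = seed
  )
  sq <- scaffold$sequence
  with_seed(seed + 1, {
    stems <- scaffold$elements %>% filter(.data$region == "stem")
    loops <- scaffold$elements %>% filter(.data$region == "loop")
    # the transcript carries three SNPs: one weak stem perturbation (a
    # Watson-Crick pair softened to a G-U wobble, a small positive
    # delta-MFE) and two loop SNPs (no pairing energy, delta-MFE ~ 0)
    stem_positions <- unlist(purrr::map2(stems$start + 1, stems$end - 1, seq))
    wobbleable <- sample(stem_positions[substring(sq, stem_positions,
                                                  stem_positions) %in% c("C", "A")])
    loop4 <- scaffold$motif_truth$start[1]
    loop_pool <- sample(setdiff(
      unlist(purrr::map2(loops$start, loops$end, seq)),
      seq(loop4, loop4 + 5)  # keep the motif instance intact
    ))
    wt_mfe <- fold_mfe(c(wt = sq))$mfe
    try_snp <- function(p, alt) {
      s2 <- sq
      substr(s2, p, p) <- alt
      fold_mfe(c(m = s2))$mfe
    }
    # one destabilizing stem SNP: soften a Watson-Crick pair to a G-U
    # wobble (C -> T against G, A -> G against T), verified to cost energy
    stem_pos <- NA_integer_; stem_alt <- NA_character_
    for (p in wobbleable) {
      alt <- c(A = "G", C = "T")[[substr(sq, p, p)]]
      if (try_snp(p, alt) > wt_mfe) {
        stem_pos <- p; stem_alt <- alt
        break
      }
    }
    # two energy-neutral loop SNPs: in-loop substitutions verified to
    # leave the minimum free energy untouched
    loop_pos <- integer(0); loop_alt <- character(0)
    for (p in loop_pool) {
      if (length(loop_pos) == 2) break
      alt <- c(A = "T", T = "A", C = "A", G = "T")[[substr(sq, p, p)]]
      if (try_snp(p, alt) == wt_mfe) {
        loop_pos <- c(loop_pos, p); loop_alt <- c(loop_alt, alt)
      }
    }
    if (is.na(stem_pos) || length(loop_pos) < 2) {
      abort("could not plant the surrogate SNP set; try another seed")
    }
    all_pos <- c(stem_pos, loop_pos)
    ord <- order(all_pos)
    snps <- tibble(
      pos = as.integer(all_pos[ord]),
      ref = vapply(all_pos[ord], function(p) substr(sq, p, p), character(1)),
      alt = c(stem_alt, loop_alt)[ord],
      in_stem = (all_pos == stem_pos)[ord]
    )
    list(
      hap1_seq = sq,
      snps = snps,
      elements = scaffold$elements,
      motif_truth = scaffold$motif_truth,
      haplotype_strings = c(
        hap1 = strrep("0", 8),
        hap2 = strrep("1", 8),
        hap3 = paste0(strrep("1", 4), strrep("0", 4))
      )
    )
  })
}

#' Synthetic gene-to-GO annotation map
#'
#' Random term assignments with an optional term enriched in a chosen gene
#' set, for testing enrichment machinery. Purely synthetic: no ontology
#' semantics.
#'
#' @param universe Gene ids.
#' @param n_terms Number of random terms.
#' @param genes_per_term Genes sampled per term.
#' @param enriched_genes Optional gene set to enrich.
#' @param enriched_term Term id for the enriched set.
#' @param seed RNG seed.
#' @return Tibble `(gene_id, go_id)`.
#' @export
make_go_map <- function(universe, n_terms = 20, genes_per_term = 15,
                        enriched_genes = NULL,
                        enriched_term = "GO:SYNTH0000", seed = 1) {
  with_seed(seed, {
    base <- purrr::map(seq_len(n_terms), function(t) {
      tibble(gene_id = sample(universe, min(genes_per_term, length(universe))),
             go_id = sprintf("GO:SYNTH%04d", t))
    }) %>% bind_rows()
    if (!is.null(enriched_genes)) {
      base <- bind_rows(base, tibble(gene_id = enriched_genes,
                                     go_id = enriched_term))
    }
    distinct(base)
  })
}
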