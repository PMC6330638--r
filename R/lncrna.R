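# lncRNA filtering and PROMPT classification. The filter cascade follows
# the strict printed thresholds: length > 200 nt, longest ORF < 300 nt
# (both strands), coding-potential score < 0.

#' Longest open reading frame across all six frames
#'
#' An ORF is ATG...stop, stop codon included in the length, and a stop is
#' required (no open-ended ORFs). Both strands and all three frames per
#' strand are scanned. Codons containing `N` match neither start nor stop.
#'
#' @param seqs Sequence tibble, named character vector or single string.
#' @return Tibble with `id`, `orf_len` (nt; 0 when no ORF), `frame` (1-3)
#'   and `strand` (`+`/`-`) of the longest ORF.
#' @export
find_longest_orf <- function(seqs) {
  seqs <- as_sequence_tbl(seqs)
  purrr::map2(seqs$id, seqs$sequence, function(sid, sq) {
    sq <- normalize_dna(sq)
    best <- list(len = 0L, frame = NA_integer_, strand = NA_character_)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") sq else reverse_complement(sq)
      for (frame in 1:3) {
        len <- longest_orf_in_frame(s, frame)
        if (len > best$len) best <- list(len = len, frame = frame, strand = strand)
      }
    }
    tibble(id = sid, orf_len = best$len, frame = best$frame, strand = best$strand)
  }) %>% bind_rows()
}

longest_orf_in_frame <- function(sequence, frame) {
  n <- nchar(sequence)
  if (n - frame + 1 < 6) return(0L)
  starts_at <- seq(frame, n - 2, by = 3)
  codons <- substring(sequence, starts_at, starts_at + 2)
  atg <- which(codons == "ATG")
  stop_idx <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(atg) == 0 || length(stop_idx) == 0) return(0L)
  # for each start codon, the first stop strictly after it
  nxt <- stop_idx[findInterval(atg, stop_idx) + 1]
  lens <- (nxt - atg + 1) * 3L
  lens <- lens[!is.na(nxt)]
  if (length(lens) == 0) 0L else max(lens)
}

#' GC fraction of a sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` bases are excluded from the denominator.
#' All-`N` (or empty) input yields `NA` with a warning.
#'
#' @param seqs Sequence tibble, named character vector or single string.
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(seqs) {
  seqs <- as_sequence_tbl(seqs)
  out <- vapply(normalize_dna(seqs$sequence), function(sq) {
    counts <- table(factor(seq_char(sq), levels = c("A", "C", "G", "T", "N")))
    denom <- sum(counts[c("A", "C", "G", "T")])
    if (denom == 0) return(NA_real_)
    unname((counts[["G"]] + counts[["C"]]) / denom)
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(out)) warn("GC content undefined for all-N sequence(s); returning NA")
  out
}

# ---------------------------------------------------------------------------
# Coding potential

# Hexamer log-odds model trained on the fly against synthetic coding and
# noncoding backgrounds (random sense codons with mild GC3 bias versus iid
# nucleotides at the genome background GC). Cached per session; the training
# seed is a fixed constant so scores are deterministic.
coding_model_cache <- new.env(parent = emptyenv())

train_coding_model <- function(n_seqs = 150, seq_len = 1200, gc = 0.42,
                               seed = 7001) {
  key <- paste(n_seqs, seq_len, gc, seed, sep = "_")
  if (!is.null(coding_model_cache[[key]])) return(coding_model_cache[[key]])
  model <- with_seed(seed, {
    sense_codons <- setdiff(
      apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        c("A", "C", "G", "T")), 1, paste, collapse = ""),
      c("TAA", "TAG", "TGA")
    )
    # mild third-position G/C preference, as in plant coding sequence
    w <- ifelse(substr(sense_codons, 3, 3) %in% c("G", "C"), 1.4, 1)
    coding <- vapply(seq_len(n_seqs), function(i) {
      paste(sample(sense_codons, seq_len / 3, replace = TRUE, prob = w),
            collapse = "")
    }, character(1))
    noncoding <- vapply(seq_len(n_seqs), function(i) random_dna(seq_len, gc),
                        character(1))
    hex_counts <- function(ss) {
      kmers <- unlist(lapply(ss, function(s) {
        n <- nchar(s)
        substring(s, 1:(n - 5), 6:n)
      }))
      kmers <- kmers[!grepl("N", kmers)]
      tab <- table(kmers)
      all_hex <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 6)),
                       1, paste, collapse = "")
      counts <- setNames(rep(1, length(all_hex)), all_hex)  # +1 pseudocount
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
      counts / sum(counts)
    }
    list(logodds = log(hex_counts(coding)) - log(hex_counts(noncoding)))
  })
  coding_model_cache[[key]] <- model
  model
}

#' Heuristic coding-potential score
#'
#' A deterministic score implementing the standard decision contract of
#' coding-potential classifiers: score < 0 means noncoding. It combines
#' longest-ORF coverage (fraction of the transcript occupied by the longest
#' ORF) with the mean hexamer log-odds of the sequence under synthetic
#' coding versus noncoding backgrounds. To import scores from an external
#' tool instead, read them with [read_coding_scores()] and pass that table
#' to [filter_lncrna()].
#'
#' @param seqs Sequence tibble, named character vector or single string.
#' @return Tibble with `id`, `orf_coverage`, `hexamer_score`, `score`.
#' @export
coding_potential_score <- function(seqs) {
  seqs <- as_sequence_tbl(seqs)
  model <- train_coding_model()
  orf <- find_longest_orf(seqs)
  hex <- vapply(normalize_dna(seqs$sequence), function(sq) {
    n <- nchar(sq)
    if (n < 6) return(0)
    kmers <- substring(sq, 1:(n - 5), 6:n)
    kmers <- kmers[!grepl("N", kmers)]
    if (length(kmers) == 0) return(0)
    mean(model$logodds[kmers])
  }, numeric(1), USE.NAMES = FALSE)
  tibble(
    id = seqs$id,
    orf_coverage = orf$orf_len / nchar(seqs$sequence),
    hexamer_score = hex
  ) %>%
    mutate(score = 2 * (.data$orf_coverage - 0.5) + .data$hexamer_score)
}

# ---------------------------------------------------------------------------
# Filtering and PROMPT classification

#' Filter transcriptional units to lncRNA candidates
#'
#' Keeps a TU iff `length > 200` nt AND `longest ORF < 300` nt AND
#' `coding score < 0` (all strict, as printed). Rejected TUs are retained
#' with `class = "rejected"` and the first failing rule recorded, so the
#' filter cascade is auditable.
#'
#' @param tus TU tibble with `tu_id` and `sequence` (e.g. from
#'   [read_gff3()] or [plant_prompt_loci()]).
#' @param scores Optional tibble `(tu_id, score)` of externally computed
#'   coding-potential scores; when omitted the built-in
#'   [coding_potential_score()] heuristic is used.
#' @param min_len,max_orf Thresholds (strict `>` / `<`); defaults 200 / 300.
#' @param fold Also fold each kept candidate to attach `mfe` and
#'   `mfe_per_bp` (the descriptive metrics)? Default `TRUE`.
#' @return Tibble of lncRNA records: `tu_id`, `length`, `longest_orf_len`,
#'   `coding_score`, `gc_fraction`, `mfe`, `mfe_per_bp`, `class`
#'   (`other_lncRNA` or `rejected`), `fail_reason`.
#' @export
filter_lncrna <- function(tus, scores = NULL, min_len = 200, max_orf = 300,
                          fold = TRUE) {
  tus <- as_tibble(tus)
  stopifnot(all(c("tu_id", "sequence") %in% names(tus)))
  seq_tbl <- tibble(id = tus$tu_id, sequence = tus$sequence)
  orf <- find_longest_orf(seq_tbl)
  if (is.null(scores)) {
    sc <- coding_potential_score(seq_tbl)
    score_vec <- setNames(sc$score, sc$id)
  } else {
    scores <- as_tibble(scores)
    missing_ids <- setdiff(tus$tu_id, scores$tu_id)
    if (length(missing_ids)) {
      abort(sprintf("no coding score for TU '%s'", missing_ids[1]))
    }
    score_vec <- setNames(scores$score, scores$tu_id)
  }
  rec <- tibble(
    tu_id = tus$tu_id,
    length = nchar(tus$sequence),
    longest_orf_len = orf$orf_len,
    coding_score = unname(score_vec[tus$tu_id]),
    gc_fraction = gc_content(seq_tbl),
    sequence = tus$sequence
  ) %>%
    mutate(
      fail_reason = dplyr::case_when(
        length <= min_len ~ sprintf("length <= %d", min_len),
        longest_orf_len >= max_orf ~ sprintf("ORF >= %d", max_orf),
        coding_score >= 0 ~ "coding score >= 0",
        TRUE ~ NA_character_
      ),
      class = if_else(is.na(.data$fail_reason), "other_lncRNA", "rejected")
    )
  if (fold && any(rec$class != "rejected")) {
    kept <- rec %>% filter(.data$class != "rejected")
    folded <- fold_mfe(tibble(id = kept$tu_id, sequence = kept$sequence))
    rec <- rec %>%
      left_join(select(folded, tu_id = "id", "mfe", "mfe_per_bp"), by = "tu_id")
  } else {
    rec$mfe <- NA_real_
    rec$mfe_per_bp <- NA_real_
  }
  select(rec, "tu_id", "length", "longest_orf_len", "coding_score",
         "gc_fraction", "mfe", "mfe_per_bp", "class", "fail_reason",
         "sequence")
}

#' Classify lncRNAs as PROMPTs relative to protein-coding TSSs
#'
#' A lncRNA is a PROMPT iff its whole span lies strictly upstream of some
#' gene's TSS on the same chromosome (no overlap with the gene body) and
#' its distance to that TSS is at most `window_bp`. Distance is
#' `TSS - TU end` for `+` genes and `TU start - TSS` for `-` genes. When
#' several genes qualify the nearest TSS wins; exact ties go to the
#' lexicographically smaller gene id. Orientation is `sense` when the TU
#' and gene strands agree, `antisense` otherwise; `pair_class` is
#' `sense/sense` for sense pairs, and for antisense PROMPTs
#' `antisense/antisense`, unless the TU also sits in the window of a
#' second, opposite-strand gene (a shared divergent promoter), which is
#' reported as `sense/antisense`.
#'
#' @param lncrnas Tibble with at least `tu_id`, `chrom`, `strand`, `start`,
#'   `end` (e.g. TU tibble joined to [filter_lncrna()] output; rejected
#'   records should be filtered out first).
#' @param annotation A [genome_annotation()].
#' @param window_bp Maximum distance to the TSS (default 2500).
#' @return Tibble with one row per classified PROMPT: `tu_id`, `gene_id`,
#'   `distance_to_tss`, `orientation`, `pair_class`. lncRNAs with no
#'   qualifying gene are absent from the result.
#' @export
classify_prompts <- function(lncrnas, annotation, window_bp = 2500) {
  lncrnas <- as_tibble(lncrnas)
  stopifnot(all(c("tu_id", "chrom", "strand", "start", "end") %in% names(lncrnas)))
  genes <- annotation$genes

  purrr::map(seq_len(nrow(lncrnas)), function(i) {
    tu <- lncrnas[i, ]
    cand <- genes %>% filter(.data$chrom == tu$chrom)
    if (nrow(cand) == 0) return(NULL)
    cand <- cand %>%
      mutate(
        upstream = if_else(.data$strand == "+", tu$end < .data$start,
                           tu$start > .data$end),
        distance = if_else(.data$strand == "+", .data$tss - tu$end,
                           tu$start - .data$tss)
      ) %>%
      filter(.data$upstream, .data$distance >= 0, .data$distance <= window_bp)
    if (nrow(cand) == 0) return(NULL)
    cand <- cand %>% arrange(.data$distance, .data$gene_id)
    hit <- cand[1, ]
    orientation <- if (tu$strand == hit$strand) "sense" else "antisense"
    pair_class <- if (orientation == "sense") {
      "sense/sense"
    } else if (any(cand$strand != hit$strand)) {
      "sense/antisense"
    } else {
      "antisense/antisense"
    }
    tibble(tu_id = tu$tu_id, gene_id = hit$gene_id,
           distance_to_tss = hit$distance, orientation = orientation,
           pair_class = pair_class)
  }) %>% bind_rows() %>%
    {
      if (nrow(.) == 0) {
        tibble(tu_id = character(), gene_id = character(),
               distance_to_tss = numeric(), orientation = character(),
               pair_class = character())
      } else .
    }
}

#' Chromosomal density of PROMPTs
#'
#' Counts PROMPT starts in half-open bins `[1, 1+bin)`, `[1+bin, 1+2bin)`,
#' ... per chromosome, and reports each chromosome's overall rate per Mb
#' (`count * 1e6 / chromosome length`).
#'
#' @param prompts Tibble with `chrom` and `start` for each PROMPT (join the
#'   classification onto the TU table to get coordinates).
#' @param annotation A [genome_annotation()] carrying `chrom_lengths`.
#' @param bin_bp Bin width in bp (default 20000).
#' @return A list of two tibbles: `bins` (`chrom`, `bin_start`, `bin_end`,
#'   `count`) and `per_chrom` (`chrom`, `n`, `per_mb`).
#' @export
chromosome_density <- function(prompts, annotation, bin_bp = 20000) {
  stopifnot(bin_bp > 0)
  lens <- annotation$chrom_lengths
  if (is.null(lens)) abort("annotation has no chromosome lengths")
  bins <- purrr::imap(lens, function(len, chrom) {
    starts <- seq(1, len, by = bin_bp)
    pos <- prompts$start[prompts$chrom == chrom]
    idx <- floor((pos - 1) / bin_bp) + 1
    tibble(chrom = chrom, bin_start = starts,
           bin_end = pmin(starts + bin_bp - 1, len),
           count = as.integer(tabulate(idx, nbins = length(starts))))
  }) %>% bind_rows()
  per_chrom <- tibble(chrom = names(lens), length = unname(lens)) %>%
    left_join(
      prompts %>% group_by(.data$chrom) %>% summarise(n = n()),
      by = "chrom"
    ) %>%
    mutate(n = if_else(is.na(.data$n), 0L, as.integer(.data$n)),
           per_mb = .data$n * 1e6 / .data$length) %>%
    select("chrom", "n", "per_mb")
  list(bins = bins, per_chrom = per_chrom)
}
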