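# Structural annotation on top of the folding engine: element labelling of
# dot-bracket strings, IUPAC motif scanning, loop enrichment, and the
# variant / loop-mutant energy experiments.

pair_table <- function(dot_bracket) {
  chars <- seq_char(dot_bracket)
  if (!all(chars %in% c("(", ")", "."))) {
    abort("dot-bracket string may only contain '(', ')' and '.'")
  }
  n <- length(chars)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) abort("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0) abort("unbalanced dot-bracket string")
  pt
}

#' Annotate structural elements of a dot-bracket string
#'
#' Performs the standard pseudoknot-free structure parse. Paired positions
#' are labelled `stem`; each unpaired position is classified by the loop
#' that encloses it: `hairpin_loop` (closing pair with no inner helices),
#' `internal_loop` / `bulge` (one inner helix, unpaired on both / one side),
#' `multiloop` (two or more inner helices) or `exterior` (not enclosed by
#' any pair). Hairpin loops are numbered 5' to 3'.
#'
#' @param dot_bracket A single dot-bracket string.
#' @return A list with `labels` (character vector, one label per position)
#'   and `loops` (tibble of maximal hairpin-loop intervals: `loop_index`,
#'   `start`, `end`).
#' @export
annotate_elements <- function(dot_bracket) {
  pt <- pair_table(dot_bracket)
  n <- length(pt)
  labels <- rep(NA_character_, n)
  labels[pt > 0] <- "stem"

  # enclosing pair of every position: nearest (i,j) with i < pos < j
  enclosing <- integer(n)  # 0 = exterior, else index of the opening base
  depth_stack <- integer(0)
  chars <- seq_char(dot_bracket)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      enclosing[i] <- if (length(depth_stack)) depth_stack[length(depth_stack)] else 0L
      depth_stack <- c(depth_stack, i)
    } else if (chars[i] == ")") {
      depth_stack <- depth_stack[-length(depth_stack)]
      enclosing[i] <- if (length(depth_stack)) depth_stack[length(depth_stack)] else 0L
    } else {
      enclosing[i] <- if (length(depth_stack)) depth_stack[length(depth_stack)] else 0L
    }
  }

  unpaired <- which(pt == 0)
  for (open in unique(enclosing[unpaired])) {
    members <- unpaired[enclosing[unpaired] == open]
    if (open == 0L) {
      labels[members] <- "exterior"
      next
    }
    close <- pt[open]
    # direct child helices of the loop closed by (open, close)
    inner <- (open + 1):(close - 1)
    children <- inner[pt[inner] > 0 & enclosing[inner] == open & chars[inner] == "("]
    n_child <- length(children)
    if (n_child == 0) {
      labels[members] <- "hairpin_loop"
    } else if (n_child == 1) {
      child_open <- children[1]
      child_close <- pt[child_open]
      left <- sum(members > open & members < child_open)
      right <- sum(members > child_close & members < close)
      labels[members] <- if (left > 0 && right > 0) "internal_loop" else "bulge"
    } else {
      labels[members] <- "multiloop"
    }
  }

  hp <- which(labels == "hairpin_loop")
  loops <- tibble(loop_index = integer(), start = integer(), end = integer())
  if (length(hp)) {
    breaks <- c(0, which(diff(hp) > 1), length(hp))
    ivs <- purrr::map(seq_len(length(breaks) - 1), function(k) {
      seg <- hp[(breaks[k] + 1):breaks[k + 1]]
      tibble(start = min(seg), end = max(seg))
    }) %>% bind_rows()
    loops <- ivs %>% arrange(.data$start) %>%
      mutate(loop_index = row_number()) %>%
      select("loop_index", "start", "end")
  }
  list(labels = labels, loops = loops)
}

iupac_regex <- function(consensus, allow_n_in_subject = FALSE) {
  chars <- seq_char(toupper(consensus))
  classes <- vapply(chars, function(ch) {
    letters <- IUPAC_CODES[[ch]]
    if (is.null(letters)) abort(sprintf("'%s' is not an IUPAC code", ch))
    # conservative rule: an N in the scanned sequence never satisfies a motif
    if (allow_n_in_subject) letters <- paste0(letters, "N")
    if (nchar(letters) == 1) letters else paste0("[", letters, "]")
  }, character(1))
  paste(classes, collapse = "")
}

scan_one_strand <- function(sequence, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

#' Scan sequences for IUPAC consensus motifs
#'
#' Reports every position where a consensus matches, optionally on both
#' strands. `N` in the scanned sequence never matches any consensus letter
#' (conservative rule). Minus-strand hits are reported in plus-strand
#' coordinates (`start` = leftmost covered base); `matched` is the
#' strand-oriented substring that satisfies the consensus.
#'
#' @param seqs Sequence tibble (`id`, `sequence`), named character vector or
#'   single string.
#' @param motifs Motif tibble with `motif_id` and `consensus` (see
#'   [read_motif_table()]).
#' @param both_strands Scan the reverse complement too? Default `TRUE`.
#' @return Tibble of hits: `id`, `motif_id`, `start`, `end`, `strand`,
#'   `matched`.
#' @export
scan_motifs <- function(seqs, motifs, both_strands = TRUE) {
  seqs <- as_sequence_tbl(seqs)
  assert_dna(seqs$sequence, what = "scan_motifs() input")
  motifs <- as_tibble(motifs)
  stopifnot(all(c("motif_id", "consensus") %in% names(motifs)))

  purrr::pmap(list(seqs$id, normalize_dna(seqs$sequence)), function(sid, sq) {
    L <- nchar(sq)
    rc <- if (both_strands) reverse_complement(sq) else NULL
    purrr::pmap(list(motifs$motif_id, motifs$consensus), function(mid, cons) {
      w <- nchar(cons)
      if (w > L) return(NULL)
      pat <- iupac_regex(cons)
      plus <- scan_one_strand(sq, pat)
      res <- list()
      if (length(plus)) {
        res$p <- tibble(id = sid, motif_id = mid, start = plus,
                        end = plus + w - 1, strand = "+",
                        matched = substring(sq, plus, plus + w - 1))
      }
      if (both_strands) {
        minus <- scan_one_strand(rc, pat)
        if (length(minus)) {
          start_plus <- L - (minus + w - 1) + 1
          res$m <- tibble(id = sid, motif_id = mid, start = start_plus,
                          end = start_plus + w - 1, strand = "-",
                          matched = substring(rc, minus, minus + w - 1))
        }
      }
      bind_rows(res)
    }) %>% bind_rows()
  }) %>% bind_rows() %>%
    {
      if (nrow(.) == 0) {
        tibble(id = character(), motif_id = character(), start = integer(),
               end = integer(), strand = character(), matched = character())
      } else {
        arrange(., .data$id, .data$motif_id, .data$start, .data$strand)
      }
    }
}

#' Add the structural context of each motif hit
#'
#' @param hits Hit tibble from [scan_motifs()] for a single sequence.
#' @param labels Per-position element labels from [annotate_elements()].
#' @return `hits` with an `element_context` column (label at the hit
#'   midpoint).
#' @export
hit_element_context <- function(hits, labels) {
  mid <- floor((hits$start + hits$end) / 2)
  mutate(hits, element_context = labels[mid])
}

#' Test whether motif hits concentrate in loop regions
#'
#' Every sequence position covered by at least one hit is classified as loop
#' (any unpaired-loop label: hairpin, internal, bulge, multiloop, exterior
#' excluded or included per `loop_classes`) versus non-loop, and compared to
#' the overall composition of the sequence with a one-sided hypergeometric
#' test (enrichment in loops).
#'
#' @param hits Hit tibble from [scan_motifs()] (single sequence).
#' @param labels Per-position labels from [annotate_elements()].
#' @param loop_classes Labels counted as "loop". Defaults to the unpaired
#'   loop classes of a structure parse; exterior is excluded since it is not
#'   part of any folded element.
#' @return A one-row tibble: `n_positions`, `n_loop_positions`,
#'   `n_hit_positions`, `n_hit_loop`, `odds_ratio`, `p_value`, `degenerate`.
#' @export
loop_motif_enrichment <- function(hits, labels,
                                  loop_classes = c("hairpin_loop",
                                                   "internal_loop", "bulge",
                                                   "multiloop")) {
  if (nrow(hits) == 0) abort("no motif hits to test")
  N <- length(labels)
  is_loop <- labels %in% loop_classes
  K <- sum(is_loop)
  covered <- sort(unique(unlist(purrr::map2(hits$start, hits$end, seq))))
  covered <- covered[covered >= 1 & covered <= N]
  n <- length(covered)
  k <- sum(is_loop[covered])
  degenerate <- K == 0 || K == N
  if (degenerate) {
    warn("all positions fall in one class; enrichment p set to 1")
    p <- 1
    or <- NA_real_
  } else {
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    a <- k; b <- n - k; cc <- K - k; d <- (N - K) - (n - k)
    or <- (a * d) / (b * cc)
  }
  tibble(n_positions = N, n_loop_positions = K, n_hit_positions = n,
         n_hit_loop = k, odds_ratio = or, p_value = p,
         degenerate = degenerate)
}

# ---------------------------------------------------------------------------
# Variant effects

apply_snps <- function(sequence, snps) {
  sq <- seq_char(normalize_dna(sequence))
  for (i in seq_len(nrow(snps))) {
    pos <- snps$pos[i]
    if (pos < 1 || pos > length(sq)) {
      abort(sprintf("SNP position %d outside sequence", pos))
    }
    if (sq[pos] != normalize_dna(snps$ref[i])) {
      abort(sprintf("reference allele mismatch at position %d: sequence has %s, SNP says %s",
                    pos, sq[pos], snps$ref[i]))
    }
    sq[pos] <- normalize_dna(snps$alt[i])
  }
  paste(sq, collapse = "")
}

#' Energy effect of nucleotide variants on a folded RNA
#'
#' Folds the reference sequence and each variant, and reports
#' `delta_mfe = mfe_alt - mfe_ref` plus whether the MFE dot-bracket changed.
#' With `combine = TRUE` all SNPs are applied jointly (a haplotype), giving
#' one row.
#'
#' @param sequence Reference sequence (DNA or RNA).
#' @param snps Tibble with `pos`, `ref`, `alt` (1-based positions on
#'   `sequence`).
#' @param combine Apply all SNPs at once instead of one at a time?
#' @return Tibble with `pos`, `ref`, `alt`, `mfe_ref`, `mfe_alt`,
#'   `delta_mfe`, `structure_changed` (for `combine = TRUE` the `pos`,
#'   `ref`, `alt` columns are collapsed into comma-separated strings).
#' @export
snp_delta_mfe <- function(sequence, snps, combine = FALSE) {
  snps <- as_tibble(snps)
  stopifnot(all(c("pos", "ref", "alt") %in% names(snps)))
  ref_fold <- fold_mfe(c(ref = sequence))
  if (combine) {
    alt_seq <- apply_snps(sequence, snps)
    alt <- tibble(id = "hap", sequence = alt_seq)
  } else {
    alt <- tibble(
      id = paste0("snp", seq_len(nrow(snps))),
      sequence = vapply(seq_len(nrow(snps)),
                        function(i) apply_snps(sequence, snps[i, ]),
                        character(1))
    )
  }
  alt_fold <- fold_mfe(alt)
  out <- tibble(
    pos = if (combine) paste(snps$pos, collapse = ",") else snps$pos,
    ref = if (combine) paste(snps$ref, collapse = ",") else snps$ref,
    alt = if (combine) paste(snps$alt, collapse = ",") else snps$alt,
    mfe_ref = ref_fold$mfe,
    mfe_alt = alt_fold$mfe,
    structure_changed = alt_fold$dot_bracket != ref_fold$dot_bracket
  ) %>%
    mutate(delta_mfe = .data$mfe_alt - .data$mfe_ref, .before = "structure_changed")
  out
}

#' Delete each hairpin loop in turn and refold
#'
#' For every numbered hairpin loop of the MFE structure, removes exactly the
#' unpaired loop interval (closing pair retained), refolds the shortened
#' molecule, and reports the energy change relative to the original MFE.
#'
#' @param sequence Sequence to analyse (DNA or RNA).
#' @return Tibble with `loop_index`, `loop_start`, `loop_end`, `mutant_seq`,
#'   `mfe`, `delta_mfe`, `structure_changed`. Zero rows when the structure
#'   has no hairpin loops.
#' @export
loop_deletion_mutants <- function(sequence) {
  folded <- fold_mfe(c(wt = sequence))
  ann <- annotate_elements(folded$dot_bracket)
  if (nrow(ann$loops) == 0) {
    return(tibble(loop_index = integer(), loop_start = integer(),
                  loop_end = integer(), mutant_seq = character(),
                  mfe = numeric(), delta_mfe = numeric(),
                  structure_changed = logical()))
  }
  sq <- normalize_dna(sequence)
  mutants <- ann$loops %>%
    mutate(mutant_seq = purrr::map2_chr(.data$start, .data$end, function(s, e) {
      paste0(substring(sq, 1, s - 1), substring(sq, e + 1, nchar(sq)))
    }))
  refold <- fold_mfe(tibble(id = paste0("del", mutants$loop_index),
                            sequence = mutants$mutant_seq))
  tibble(
    loop_index = mutants$loop_index,
    loop_start = mutants$start, loop_end = mutants$end,
    mutant_seq = mutants$mutant_seq,
    mfe = refold$mfe,
    delta_mfe = refold$mfe - folded$mfe,
    structure_changed = TRUE
  )
}

#' Convert a hairpin loop into a stem by minimal substitution
#'
#' Searches all substitution sets of size at most `n_changes` confined to
#' the chosen hairpin-loop interval, refolds every candidate, and returns
#' the one that maximizes the paired fraction of the former loop positions
#' (ties broken by fewer changes, then lower MFE, then sequence order). The
#' positions outside the loop are never touched.
#'
#' @param sequence Sequence to mutate.
#' @param loop_index Which hairpin loop (5' to 3' numbering of the MFE
#'   structure).
#' @param n_changes Maximum number of substituted loop positions.
#' @param max_candidates Guard against combinatorial blow-up; raise for
#'   exhaustive searches on long loops.
#' @return A one-row tibble: `mutant_seq`, `dot_bracket`, `mfe`,
#'   `paired_fraction` (of former loop positions), `n_changes_used`,
#'   `changed` (FALSE when no substitution improves pairing, in which case
#'   the original sequence is returned).
#' @export
loop_to_stem_mutation <- function(sequence, loop_index, n_changes,
                                  max_candidates = 50000) {
  folded <- fold_mfe(c(wt = sequence))
  ann <- annotate_elements(folded$dot_bracket)
  if (loop_index < 1 || loop_index > nrow(ann$loops)) {
    abort(sprintf("loop_index %d out of range (structure has %d hairpin loops)",
                  loop_index, nrow(ann$loops)))
  }
  loop <- ann$loops[ann$loops$loop_index == loop_index, ]
  loop_pos <- seq(loop$start, loop$end)
  if (n_changes > length(loop_pos)) {
    abort("n_changes exceeds the loop length")
  }
  sq <- normalize_dna(sequence)
  paired_frac <- function(db) {
    pt <- pair_table(db)
    mean(pt[loop_pos] > 0)
  }
  base <- tibble(mutant_seq = sq, dot_bracket = folded$dot_bracket,
                 mfe = folded$mfe, paired_fraction = paired_frac(folded$dot_bracket),
                 n_changes_used = 0L, changed = FALSE)
  if (n_changes == 0) return(base)

  alphabet <- c("A", "C", "G", "T")
  cands <- list()
  for (k in seq_len(n_changes)) {
    subsets <- utils::combn(loop_pos, k, simplify = FALSE)
    for (subset in subsets) {
      alts <- purrr::map(subset, function(p) setdiff(alphabet, substr(sq, p, p)))
      grid <- do.call(expand.grid, c(alts, stringsAsFactors = FALSE))
      for (r in seq_len(nrow(grid))) {
        s <- seq_char(sq)
        s[subset] <- unlist(grid[r, ], use.names = FALSE)
        cands[[length(cands) + 1]] <- list(seq = paste(s, collapse = ""), k = k)
      }
      if (length(cands) > max_candidates) {
        abort("candidate space too large; lower n_changes or raise max_candidates")
      }
    }
  }
  cand_tbl <- tibble(
    id = paste0("m", seq_along(cands)),
    sequence = vapply(cands, `[[`, "", "seq"),
    k = vapply(cands, function(x) x$k, numeric(1))
  )
  refold <- fold_mfe(cand_tbl[, c("id", "sequence")])
  scored <- refold %>%
    mutate(k = cand_tbl$k,
           paired_fraction = vapply(.data$dot_bracket, paired_frac, numeric(1))) %>%
    arrange(desc(.data$paired_fraction), .data$k, .data$mfe)
  best <- scored[1, ]
  if (best$paired_fraction <= base$paired_fraction) {
    return(base)
  }
  tibble(mutant_seq = best$sequence, dot_bracket = best$dot_bracket,
         mfe = best$mfe, paired_fraction = best$paired_fraction,
         n_changes_used = as.integer(best$k), changed = TRUE)
}
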