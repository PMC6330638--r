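# On-disk formats. FASTA goes through Biostrings, GFF3 through rtracklayer,
# VCF through vcfR; the genotype TSV dialect (one haplotype row per
# chromosome copy) is defined by this package, see read_genotypes().

#' Read a FASTA file into a tibble
#'
#' Sequences are uppercased and RNA (`U`) is normalized to DNA (`T`) so that
#' one alphabet flows through the package; folding functions transcribe back
#' to RNA internally.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id: '%s'", ids[duplicated(ids)][1]))
  }
  seqs <- normalize_dna(as.character(set))
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("empty FASTA record: '%s'", ids[nchar(seqs) == 0][1]))
  }
  tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs A tibble with `id` and `sequence` columns (or a named
#'   character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as_sequence_tbl(seqs)
  set <- Biostrings::BStringSet(setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Construct a genome annotation object
#'
#' The container every interval operation works against: chromosome
#' sequences (optional), chromosome lengths, and a gene table with 1-based
#' closed coordinates. The TSS is derived from the strand: `start` for `+`
#' genes, `end` for `-` genes.
#'
#' @param genes Tibble with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @param genome Optional tibble with `id`, `sequence` (as from
#'   [read_fasta()]).
#' @param chrom_lengths Optional named vector of chromosome lengths; derived
#'   from `genome` when omitted.
#' @return A `genome_annotation` object (list with `genes`, `genome`,
#'   `chrom_lengths`).
#' @export
genome_annotation <- function(genes, genome = NULL, chrom_lengths = NULL) {
  genes <- as_tibble(genes)
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) abort("gene_ids must be unique")
  if (!all(genes$strand %in% c("+", "-"))) abort("gene strand must be '+' or '-'")
  if (any(genes$start < 1 | genes$start > genes$end)) {
    abort("gene coordinates must satisfy 1 <= start <= end")
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  if (is.null(chrom_lengths) && !is.null(genome)) {
    genome <- as_sequence_tbl(genome)
    chrom_lengths <- setNames(nchar(genome$sequence), genome$id)
  }
  if (!is.null(chrom_lengths)) {
    over <- genes$end > chrom_lengths[genes$chrom]
    if (any(over, na.rm = TRUE)) {
      abort(sprintf("gene '%s' extends beyond its chromosome",
                    genes$gene_id[which(over)[1]]))
    }
  }
  structure(
    list(genes = genes, genome = genome, chrom_lengths = chrom_lengths),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %d genes on %d chromosomes%s\n",
              nrow(x$genes), length(unique(x$genes$chrom)),
              if (is.null(x$genome)) " (no sequence attached)" else ""))
  invisible(x)
}

tu_tbl <- function(tu_id, chrom, strand, start, end, exon_starts = NULL,
                   exon_ends = NULL, sequence = NA_character_) {
  if (is.null(exon_starts)) {
    exon_starts <- as.list(start)
    exon_ends <- as.list(end)
  }
  tibble(
    tu_id = tu_id, chrom = chrom, strand = strand,
    start = start, end = end,
    exon_starts = exon_starts, exon_ends = exon_ends,
    length = purrr::map2_dbl(exon_starts, exon_ends, ~sum(.y - .x + 1)),
    sequence = sequence
  )
}

extract_spliced <- function(tus, genome) {
  genome <- as_sequence_tbl(genome)
  chrom_seq <- setNames(genome$sequence, genome$id)
  tus$sequence <- purrr::pmap_chr(
    list(tus$chrom, tus$strand, tus$exon_starts, tus$exon_ends),
    function(chrom, strand, es, ee) {
      pieces <- substring(chrom_seq[[chrom]], es, ee)
      s <- paste(pieces, collapse = "")
      if (strand == "-") reverse_complement(s) else s
    }
  )
  tus
}

#' Read gene and transcript annotation from GFF3
#'
#' Coordinates are kept 1-based closed as in the file. Transcript-like
#' features (`transcript`, `mRNA`, `lnc_RNA`, `ncRNA`) become transcriptional
#' units; their `exon` children define the spliced sequence when a genome is
#' supplied. Transcripts without exon children are treated as single-exon.
#'
#' @param path Path to a GFF3 file.
#' @param genome Optional genome tibble (from [read_fasta()]) used to attach
#'   chromosome lengths and spliced TU sequences.
#' @return A list with `annotation` (a [genome_annotation()]) and `tus`
#'   (a TU tibble).
#' @export
read_gff3 <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(gr)
  meta$seqnames <- as.character(meta$seqnames)
  meta$strand <- as.character(meta$strand)

  genes <- meta[meta$type == "gene", , drop = FALSE]
  gene_tbl <- tibble(
    gene_id = as.character(genes$ID), chrom = genes$seqnames,
    strand = genes$strand, start = genes$start, end = genes$end
  )

  tx_types <- c("transcript", "mRNA", "lnc_RNA", "ncRNA")
  tx <- meta[meta$type %in% tx_types, , drop = FALSE]
  exons <- meta[meta$type == "exon", , drop = FALSE]
  exon_parent <- vapply(exons$Parent, function(p) as.character(p)[1], character(1))

  tus <- purrr::map(seq_len(nrow(tx)), function(i) {
    id <- as.character(tx$ID[i])
    ex <- exons[exon_parent == id, , drop = FALSE]
    if (nrow(ex) == 0) {
      es <- tx$start[i]; ee <- tx$end[i]
    } else {
      ord <- order(ex$start)
      es <- ex$start[ord]; ee <- ex$end[ord]
      if (any(es < tx$start[i] | ee > tx$end[i])) {
        abort(sprintf("exon outside parent span for feature '%s'", id))
      }
      if (any(es[-1] <= ee[-length(ee)])) {
        abort(sprintf("overlapping exons in feature '%s'", id))
      }
    }
    tu_tbl(id, tx$seqnames[i], tx$strand[i], tx$start[i], tx$end[i],
           list(es), list(ee))
  }) %>% bind_rows()

  chrom_lengths <- NULL
  sl <- GenomeInfoDb::seqlengths(gr)
  if (length(sl) && !all(is.na(sl))) chrom_lengths <- sl[!is.na(sl)]

  ann <- genome_annotation(gene_tbl, genome = genome,
                           chrom_lengths = chrom_lengths)
  if (!is.null(genome) && nrow(tus)) tus <- extract_spliced(tus, genome)
  list(annotation = ann, tus = tus)
}

#' Write an annotation and its transcriptional units to GFF3
#'
#' @param annotation A [genome_annotation()].
#' @param tus Optional TU tibble to write as `transcript` + `exon` features.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, tus = NULL, path) {
  g <- annotation$genes
  feats <- list(GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id
  ))
  if (!is.null(tus) && nrow(tus)) {
    feats <- c(feats, list(GenomicRanges::GRanges(
      tus$chrom, IRanges::IRanges(tus$start, tus$end), strand = tus$strand,
      type = "transcript", ID = tus$tu_id
    )))
    ex <- tidyr::unnest(
      tus[, c("tu_id", "chrom", "strand", "exon_starts", "exon_ends")],
      c("exon_starts", "exon_ends")
    )
    exon_gr <- GenomicRanges::GRanges(
      ex$chrom, IRanges::IRanges(ex$exon_starts, ex$exon_ends),
      strand = ex$strand, type = "exon",
      ID = paste0(ex$tu_id, ".exon", stats::ave(ex$exon_starts, ex$tu_id,
                                                FUN = seq_along))
    )
    S4Vectors::mcols(exon_gr)$Parent <- as.character(ex$tu_id)
    feats <- c(feats, list(exon_gr))
  }
  all_gr <- suppressWarnings(do.call(c, feats))
  if (!is.null(annotation$chrom_lengths)) {
    GenomeInfoDb::seqlengths(all_gr) <-
      annotation$chrom_lengths[GenomeInfoDb::seqlevels(all_gr)]
  }
  rtracklayer::export(all_gr, path, format = "gff3")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Genotypes

new_genotype_table <- function(sites, haplotypes) {
  sites <- as_tibble(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  sites$site_id <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  stopifnot(ncol(haplotypes) == nrow(sites))
  colnames(haplotypes) <- sites$site_id
  ok <- haplotypes %in% c(0L, 1L, NA)
  if (!all(ok)) abort("haplotype allele codes must be 0, 1 or missing")
  structure(list(sites = sites, haplotypes = haplotypes),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d haplotype rows x %d sites\n",
              nrow(x$haplotypes), nrow(x$sites)))
  invisible(x)
}

#' Read phased genotypes from VCF or the package's haplotype TSV dialect
#'
#' VCF input must be phased (`0|1`); unphased diploid calls are rejected
#' because downstream haplotype counting needs chromosome-copy resolution.
#' Each diploid individual contributes two haplotype rows (`<id>_a`,
#' `<id>_b`); a VCF whose genotypes carry a single allele is read in haploid
#' mode (one row per individual). The TSV dialect is this package's own
#' interchange: a header row `hap_id` followed by one column per site named
#' `chrom:pos:ref:alt`, values 0/1/NA, one row per chromosome copy.
#'
#' @param path Path to a `.vcf` file or a haplotype TSV.
#' @return A `genotype_table` (list of `sites` tibble and a haplotype-by-site
#'   0/1 matrix with NA for missing).
#' @export
read_genotypes <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("^##fileformat=VCF", first)) {
    return(read_genotypes_vcf(path))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(df)[1] != "hap_id") {
    abort("genotype TSV must start with a 'hap_id' column")
  }
  site_ids <- names(df)[-1]
  parts <- strsplit(site_ids, ":", fixed = TRUE)
  sites <- tibble(
    chrom = vapply(parts, `[`, "", 1),
    pos = as.integer(vapply(parts, `[`, "", 2)),
    ref = vapply(parts, `[`, "", 3),
    alt = vapply(parts, `[`, "", 4)
  )
  mat <- as.matrix(df[, -1])
  mode(mat) <- "integer"
  rownames(mat) <- df$hap_id
  new_genotype_table(sites, mat)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  sites <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
                  ref = fix$REF, alt = fix$ALT)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) abort("VCF has no GT field")
  inds <- colnames(gt)
  diploid <- any(grepl("[|/]", gt), na.rm = TRUE)
  if (diploid && any(grepl("/", gt) & gt != "./.", na.rm = TRUE)) {
    abort("unphased diploid genotypes: phase ('|') is required for haplotype counting")
  }
  parse_allele <- function(x) {
    x[x == "."] <- NA
    as.integer(x)
  }
  if (diploid) {
    a1 <- parse_allele(sub("[|/].*$", "", gt))
    a2 <- parse_allele(sub("^.*[|/]", "", gt))
    mat <- rbind(matrix(a1, ncol = nrow(sites), byrow = TRUE),
                 matrix(a2, ncol = nrow(sites), byrow = TRUE))
    rownames(mat) <- c(paste0(inds, "_a"), paste0(inds, "_b"))
    # interleave so the two copies of an individual sit together
    mat <- mat[order(rep(seq_along(inds), 2), rep(1:2, each = length(inds))), ,
               drop = FALSE]
  } else {
    mat <- matrix(parse_allele(gt), ncol = nrow(sites), byrow = TRUE)
    rownames(mat) <- inds
  }
  new_genotype_table(sites, mat)
}

#' Write a genotype table to the haplotype TSV dialect
#'
#' @param gt A `genotype_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path) {
  df <- as.data.frame(gt$haplotypes)
  df <- cbind(hap_id = rownames(gt$haplotypes), df)
  readr::write_tsv(as_tibble(df), path)
  invisible(path)
}

#' Write a genotype table as a minimal phased VCF
#'
#' Consecutive pairs of haplotype rows are combined into one phased diploid
#' individual, so the table must have an even number of rows.
#'
#' @inheritParams write_genotypes
#' @export
write_vcf <- function(gt, path) {
  n <- nrow(gt$haplotypes)
  if (n %% 2 != 0) abort("VCF output needs an even number of haplotype rows")
  ind_idx <- split(seq_len(n), rep(seq_len(n / 2), each = 2))
  ind_ids <- sub("_(a|b|1|2)$", "", rownames(gt$haplotypes)[seq(1, n, by = 2)])
  code <- function(x) ifelse(is.na(x), ".", as.character(x))
  gt_cols <- vapply(ind_idx, function(ix) {
    paste(code(gt$haplotypes[ix[1], ]), code(gt$haplotypes[ix[2], ]), sep = "|")
  }, character(nrow(gt$sites)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind_ids), collapse = "\t")
  )
  body <- paste(gt$sites$chrom, gt$sites$pos, gt$sites$site_id, gt$sites$ref,
                gt$sites$alt, ".", "PASS", ".", "GT",
                apply(matrix(gt_cols, nrow = nrow(gt$sites)), 1, paste,
                      collapse = "\t"),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Tabular inputs

#' Read a TU-by-sample count matrix from TSV
#'
#' First column `tu_id`, remaining columns one per sample; a header row is
#' required.
#'
#' @param path Path to the TSV.
#' @return A tibble with `tu_id` plus one numeric column per sample.
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(df)[1] != "tu_id") abort("count matrix must start with a 'tu_id' column")
  if (anyDuplicated(df$tu_id)) abort("duplicate tu_id in count matrix")
  df
}

#' @rdname read_count_matrix
#' @param counts Count tibble as returned by [read_count_matrix()].
#' @export
write_count_matrix <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Read an IUPAC consensus motif table
#'
#' Tab-separated with columns `motif_id`, `consensus`, `source`, `note`.
#' Consensus strings are configuration, not ground truth: edit the shipped
#' table to match your motif library of record.
#'
#' @param path Path to the motif TSV. Defaults to the small PLACE-style
#'   table shipped with the package.
#' @return A tibble with the four columns above.
#' @export
read_motif_table <- function(path = system.file("extdata", "motifs_place_style.tsv",
                                                package = "promptscape")) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  stopifnot(all(c("motif_id", "consensus") %in% names(df)))
  if (anyDuplicated(df$motif_id)) abort("motif_ids must be unique")
  bad <- !grepl(paste0("^[", paste(names(IUPAC_CODES), collapse = ""), "]+$"),
                toupper(df$consensus))
  if (any(bad)) {
    abort(sprintf("motif '%s' has non-IUPAC characters", df$motif_id[bad][1]))
  }
  df$consensus <- toupper(df$consensus)
  df
}

#' Read externally computed coding-potential scores
#'
#' Pass-through mode for users who ran a dedicated coding-potential tool:
#' a TSV with columns `tu_id` and `score` (score < 0 means noncoding).
#'
#' @param path Path to the score TSV.
#' @return Tibble with `tu_id`, `score`.
#' @export
read_coding_scores <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("tu_id", "score") %in% names(df)))
  df
}
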