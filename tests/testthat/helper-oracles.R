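# Independent oracles used to verify the implementation paths. These are
# deliberately written as naive brute-force routines, separate from the
# package internals.

# --- six-frame ORF scan by explicit codon walking --------------------------
orf_brute <- function(sequence) {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }
  best <- 0L
  for (s in c(sequence, revcomp(sequence))) {
    n <- nchar(s)
    for (frame in 1:3) {
      i <- frame
      while (i + 2 <= n) {
        if (substr(s, i, i + 2) == "ATG") {
          j <- i + 3
          while (j + 2 <= n) {
            codon <- substr(s, j, j + 2)
            if (codon %in% c("TAA", "TAG", "TGA")) {
              best <- max(best, j + 2 - i + 1)
              break
            }
            j <- j + 3
          }
        }
        i <- i + 3
      }
    }
  }
  best
}

# --- Benjamini-Hochberg step-up from first principles ----------------------
bh_brute <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[ord[i]] * n / i)
    q[ord[i]] <- min(running, 1)
  }
  q
}

# --- exhaustive hypergeometric upper tail ---------------------------------
# P(X >= k) by summing the counting formula directly
hyper_uppertail_brute <- function(k, n_success, n_total, n_draw) {
  kmax <- min(n_success, n_draw)
  if (k > kmax) return(0)
  sum(vapply(k:kmax, function(x) {
    choose(n_success, x) * choose(n_total - n_success, n_draw - x) /
      choose(n_total, n_draw)
  }, numeric(1)))
}

# --- LD from the 2x2 haplotype contingency table --------------------------
ld_brute <- function(a, b) {
  n <- length(a)
  pA <- sum(a) / n; pB <- sum(b) / n
  pAB <- sum(a == 1 & b == 1) / n
  D <- pAB - pA * pB
  list(D = D, r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# --- exhaustive secondary-structure enumeration ---------------------------
# all pseudoknot-free structures over canonical pairs (AU, GC, GU) with a
# minimum hairpin loop of 3, scored with RNAeval; the minimum is the MFE.
enumerate_structures <- function(sequence) {
  rna <- chartr("Tt", "UU", toupper(sequence))
  chars <- strsplit(rna, "")[[1]]
  n <- length(chars)
  pairable <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  memo <- new.env(parent = emptyenv())
  recurse <- function(i, j) {
    if (i > j) return("")
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- paste0(".", recurse(i + 1, j))
    if (j - i >= 4) {
      for (k in (i + 4):j) {
        if (pairable(chars[i], chars[k])) {
          inner <- recurse(i + 1, k - 1)
          rest <- recurse(k + 1, j)
          out <- c(out, as.vector(outer(paste0("(", inner, ")"), rest,
                                        paste0)))
        }
      }
    }
    memo[[key]] <- out
    out
  }
  recurse(1, n)
}

rnaeval_brute <- function(sequence, structures) {
  rna <- chartr("Tt", "UU", toupper(sequence))
  infile <- tempfile()
  on.exit(unlink(infile))
  writeLines(as.vector(rbind(rep(rna, length(structures)), structures)),
             infile)
  out <- system2("RNAeval", stdin = infile, stdout = TRUE, stderr = FALSE)
  energy_lines <- out[seq(2, length(out), by = 2)]
  vapply(energy_lines, function(l) {
    as.numeric(gsub("[() ]", "", regmatches(l, regexpr("\\(\\s*-?[0-9.]+\\)$", l))))
  }, numeric(1), USE.NAMES = FALSE)
}

mfe_brute <- function(sequence) {
  structs <- enumerate_structures(sequence)
  min(rnaeval_brute(sequence, structs))
}

# --- misc fixtures ---------------------------------------------------------
random_seq <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

toy_annotation <- function() {
  genome_annotation(
    tibble::tibble(
      gene_id = c("geneA", "geneB"),
      chrom = c("chr1", "chr1"),
      strand = c("+", "-"),
      start = c(10000, 30000),
      end = c(12000, 32000)
    ),
    chrom_lengths = c(chr1 = 50000)
  )
}
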