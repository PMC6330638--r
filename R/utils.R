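# Shared low-level helpers: sequence alphabet handling, reverse complement,
# seed derivation. Coordinates are GFF3-style 1-based closed throughout the
# package; BED-style intervals are converted at the I/O boundary only.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

normalize_dna <- function(x) {
  x <- toupper(x)
  chartr("U", "T", x)
}

dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))

assert_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, normalize_dna(x))
  if (any(bad)) {
    abort(sprintf(
      "%s contains non-nucleotide characters (first offender: '%s')",
      what, substr(x[which(bad)[1]], 1, 40)
    ))
  }
  invisible(TRUE)
}

reverse_complement <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", normalize_dna(x))
  vapply(strsplit(comp, "", fixed = TRUE), function(s) {
    paste(rev(s), collapse = "")
  }, character(1))
}

#' @noRd
seq_char <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Derive a reproducible 32-bit sub-seed from a run seed and a named stream,
# so independent generators driven by one pipeline seed do not share streams.
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483629L)
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483647))
  }
  force(code)
}

# Random DNA with a target GC fraction (the poplar genome background is
# roughly 0.34-0.42 GC; generators default to 0.42).
random_dna <- function(n, gc = 0.42) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

as_sequence_tbl <- function(x, id_prefix = "seq") {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    return(as_tibble(x[, c("id", "sequence")]))
  }
  ids <- names(x)
  if (is.null(ids)) ids <- paste0(id_prefix, seq_along(x))
  tibble(id = ids, sequence = unname(x))
}

# uniform integer draw from [a, b], robust to a == b (sample()'s scalar trap)
sample_range <- function(a, b, n = 1) {
  vals <- seq(as.integer(a), as.integer(b))
  if (length(vals) == 1) rep(vals, n) else sample(vals, n, replace = TRUE)
}
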