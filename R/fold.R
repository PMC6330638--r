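# Thermodynamic folding. Energies come from the ViennaRNA programs on the
# PATH (RNAfold / RNAeval), i.e. the Turner 2004 nearest-neighbor parameters
# at 37 degrees C with the engine's defaults (dangles=2, lonely pairs
# allowed, minimum hairpin loop 3, no pseudoknots). DNA input is transcribed
# T->U before folding; all coordinates are reported on the input sequence.

vienna_binary <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path)) {
    abort(sprintf("ViennaRNA program '%s' not found on PATH", name))
  }
  path
}

run_vienna <- function(binary, args, input_lines) {
  infile <- tempfile(fileext = ".txt")
  on.exit(unlink(infile), add = TRUE)
  writeLines(input_lines, infile)
  out <- suppressWarnings(
    system2(vienna_binary(binary), args = args, stdin = infile, stdout = TRUE,
            stderr = FALSE)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    abort(sprintf("%s exited with status %d", binary, status))
  }
  out
}

parse_energy <- function(line) {
  m <- regmatches(line, regexpr("\\(\\s*(-?[0-9]+\\.[0-9]+)\\)\\s*$", line))
  if (length(m) == 0) abort(sprintf("cannot parse ViennaRNA energy from '%s'", line))
  as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
}

#' Fold sequences into their minimum-free-energy secondary structure
#'
#' Computes the MFE structure of each sequence under the standard
#' nearest-neighbor thermodynamic model (Turner 2004 parameters, 37 degrees
#' C, no pseudoknots) via RNAfold. Input may be DNA or RNA; DNA is
#' transcribed internally and the returned `sequence` column keeps the
#' input alphabet.
#'
#' @param seqs A tibble with `id` and `sequence` columns, a (optionally
#'   named) character vector, or a single sequence string.
#' @return A tibble with `id`, `sequence`, `length`, `dot_bracket`, `mfe`
#'   (kcal/mol) and `mfe_per_bp` (= mfe / length).
#' @examples
#' \dontrun{
#' fold_mfe("GGGCGCAAGCCUAAGCGCCC")
#' }
#' @export
fold_mfe <- function(seqs) {
  seqs <- as_sequence_tbl(seqs)
  if (nrow(seqs) == 0) {
    return(tibble(id = character(), sequence = character(), length = integer(),
                  dot_bracket = character(), mfe = numeric(),
                  mfe_per_bp = numeric()))
  }
  assert_dna(seqs$sequence, allow_n = TRUE, what = "fold_mfe() input")
  if (any(nchar(seqs$sequence) < 1)) abort("cannot fold an empty sequence")
  rna <- dna_to_rna(seqs$sequence)
  lines <- as.vector(rbind(paste0("> ", seq_len(nrow(seqs))), rna))
  out <- run_vienna("RNAfold", c("--noPS"), lines)
  struct_lines <- out[seq(3, length(out), by = 3)]
  tibble(
    id = seqs$id,
    sequence = seqs$sequence,
    length = nchar(seqs$sequence),
    dot_bracket = sub("\\s.*$", "", struct_lines),
    mfe = vapply(struct_lines, parse_energy, numeric(1), USE.NAMES = FALSE)
  ) %>%
    mutate(mfe_per_bp = .data$mfe / .data$length)
}

#' Evaluate the free energy of given structures
#'
#' Scores (sequence, dot-bracket) pairs with RNAeval under the same energy
#' model as [fold_mfe()]. Useful for comparing alternative structures of the
#' same molecule.
#'
#' @param seqs Character vector of sequences (DNA or RNA).
#' @param structures Character vector of dot-bracket strings, same length.
#' @return Numeric vector of free energies in kcal/mol.
#' @export
eval_energy <- function(seqs, structures) {
  stopifnot(length(seqs) == length(structures))
  if (length(seqs) == 0) return(numeric(0))
  assert_dna(seqs, allow_n = TRUE, what = "eval_energy() input")
  if (any(nchar(seqs) != nchar(structures))) {
    abort("sequence and structure lengths differ")
  }
  lines <- as.vector(rbind(dna_to_rna(seqs), structures))
  out <- run_vienna("RNAeval", character(0), lines)
  energy_lines <- out[seq(2, length(out), by = 2)]
  vapply(energy_lines, parse_energy, numeric(1), USE.NAMES = FALSE)
}
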