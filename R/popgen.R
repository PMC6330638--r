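# Haplotype frequencies, linkage disequilibrium, tissue specificity tau,
# and the substitution-rate ratio against neutrally evolving ancestral
# repeats.

#' Haplotype frequencies over a set of sites
#'
#' Distinct allele strings are counted over haplotype rows with no missing
#' call at the chosen sites; frequencies are over the retained rows.
#'
#' @param gt A `genotype_table` (see [read_genotypes()]).
#' @param sites Site ids (or indices) to use; default all sites.
#' @return Tibble `(haplotype, count, frequency)` in decreasing frequency
#'   order.
#' @export
haplotype_frequencies <- function(gt, sites = NULL) {
  mat <- gt$haplotypes
  if (!is.null(sites)) {
    mat <- mat[, sites, drop = FALSE]
  }
  complete <- rowSums(is.na(mat)) == 0
  if (!any(complete)) abort("all haplotype rows have missing data at these sites")
  strings <- apply(mat[complete, , drop = FALSE], 1, paste, collapse = "")
  tab <- sort(table(strings), decreasing = TRUE)
  tibble(haplotype = names(tab), count = as.integer(tab),
         frequency = as.integer(tab) / sum(tab))
}

#' Linkage disequilibrium between two biallelic sites
#'
#' Haplotype-count based: `D = p_AB - p_A p_B`,
#' `r2 = D^2 / (p_A (1 - p_A) p_B (1 - p_B))`, `D'` scaled by the
#' admissible range, and a chi-square p-value from `n * r2 ~ chi2(1)`.
#' Rows missing either site are excluded pairwise; a monomorphic site gives
#' `NA` statistics with a warning.
#'
#' @param gt A `genotype_table`.
#' @param site_a,site_b Site ids or column indices.
#' @return One-row tibble: `site_a`, `site_b`, `n_haplotypes`, `D`,
#'   `D_prime`, `r2`, `p_value`.
#' @export
ld_r2 <- function(gt, site_a, site_b) {
  a <- gt$haplotypes[, site_a]
  b <- gt$haplotypes[, site_b]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  site_name <- function(s) if (is.character(s)) s else colnames(gt$haplotypes)[s]
  out <- tibble(site_a = site_name(site_a), site_b = site_name(site_b),
                n_haplotypes = n, D = NA_real_, D_prime = NA_real_,
                r2 = NA_real_, p_value = NA_real_)
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    warn("monomorphic site: LD undefined")
    return(out)
  }
  pAB <- mean(a == 1 & b == 1)
  D <- pAB - pA * pB
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- D^2 / denom
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  out$D <- D
  out$D_prime <- if (dmax == 0) NA_real_ else abs(D) / dmax
  out$r2 <- r2
  out$p_value <- pchisq(n * r2, df = 1, lower.tail = FALSE)
  out
}

#' Pairwise LD across all site pairs
#'
#' @param gt A `genotype_table`.
#' @return Tibble of [ld_r2()] rows for every unordered site pair.
#' @export
ld_matrix <- function(gt) {
  ids <- gt$sites$site_id
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  suppressWarnings(
    purrr::map(pairs, ~ld_r2(gt, .x[1], .x[2])) %>% bind_rows()
  )
}

#' Tissue/condition specificity index tau
#'
#' `tau = sum(1 - x_i / x_max) / (N - 1)` on max-normalized non-negative
#' expression values: 0 for uniform expression, 1 for single-condition
#' expression.
#'
#' @param values Non-negative expression values, one per condition
#'   (at least 2).
#' @return tau in `[0, 1]`, or `NA` with a warning when all values are 0.
#' @export
tau_specificity <- function(values) {
  if (length(values) < 2) abort("tau needs at least 2 conditions")
  if (any(values < 0)) abort("tau is defined for non-negative values")
  mx <- max(values)
  if (mx == 0) {
    warn("all values are zero: tau undefined")
    return(NA_real_)
  }
  sum(1 - values / mx) / (length(values) - 1)
}

#' Jukes-Cantor distance of an aligned sequence pair
#'
#' Columns containing a gap (`-`) or `N` in either sequence are excluded;
#' `p` is the mismatch proportion over the remaining columns and
#' `d = -(3/4) * log(1 - 4p/3)`. Saturated pairs (`p >= 0.75`) get
#' `d = NA` and are flagged.
#'
#' @param seq_a,seq_b Equal-length aligned sequences.
#' @return One-row tibble: `n_columns` (valid columns), `mismatches`, `p`,
#'   `d`, `saturated`.
#' @export
jc_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) abort("aligned sequences differ in length")
  a <- seq_char(normalize_dna(seq_a))
  b <- seq_char(normalize_dna(seq_b))
  valid <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[valid]; b <- b[valid]
  n <- length(a)
  if (n == 0) abort("no valid aligned columns")
  mm <- sum(a != b)
  p <- mm / n
  saturated <- p >= 0.75
  d <- if (saturated) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  tibble(n_columns = n, mismatches = mm, p = p, d = d, saturated = saturated)
}

#' Substitution-rate ratio of PROMPTs versus ancestral repeats
#'
#' For each matched pair of alignments (a PROMPT alignment and its
#' neighbouring ancestral-repeat alignment), computes the Jukes-Cantor
#' distances and their ratio `d_prompt / d_ar`. A ratio below 1 indicates
#' purifying selection (or locally reduced mutation); the one-sided
#' Wilcoxon signed-rank test compares the ratios against 1. Pairs with
#' `d_ar = 0` or a saturated distance are dropped with a warning.
#'
#' @param pairs Tibble with columns `pair_id`, `prompt_a`, `prompt_b`,
#'   `ar_a`, `ar_b` holding the aligned sequences (as produced by
#'   [simulate_divergence()] or read from interleaved FASTA).
#' @return A list with `ratios` (per-pair tibble: `pair_id`, `d_prompt`,
#'   `d_ar`, `ratio`) and `summary` (one-row tibble: `n_pairs`,
#'   `median_ratio`, `p_value` for the one-sided test ratio < 1).
#' @export
substitution_ratio <- function(pairs) {
  pairs <- as_tibble(pairs)
  need <- c("pair_id", "prompt_a", "prompt_b", "ar_a", "ar_b")
  stopifnot(all(need %in% names(pairs)))
  per <- purrr::pmap(pairs[need], function(pair_id, prompt_a, prompt_b,
                                           ar_a, ar_b) {
    dp <- jc_distance(prompt_a, prompt_b)
    da <- jc_distance(ar_a, ar_b)
    tibble(pair_id = pair_id, d_prompt = dp$d, d_ar = da$d)
  }) %>% bind_rows()
  bad <- is.na(per$d_prompt) | is.na(per$d_ar) | per$d_ar == 0
  if (any(bad)) {
    warn(sprintf("%d pair(s) dropped (saturated or d_ar = 0)", sum(bad)))
  }
  per <- per[!bad, ] %>% mutate(ratio = .data$d_prompt / .data$d_ar)
  p <- if (nrow(per) >= 2 && any(per$ratio != 1)) {
    suppressWarnings(wilcox.test(per$ratio, mu = 1, alternative = "less")$p.value)
  } else {
    1
  }
  list(
    ratios = per,
    summary = tibble(n_pairs = nrow(per), median_ratio = median(per$ratio),
                     p_value = p)
  )
}
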