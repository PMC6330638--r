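# Quantification and differential expression. The DE engine is a per-TU
# negative-binomial Wald test with method-of-moments dispersion pooled
# across the two groups and total-count library-size normalization; the
# status rule exposes both published threshold presets.

counts_matrix <- function(counts) {
  counts <- as_tibble(counts)
  stopifnot(names(counts)[1] == "tu_id")
  m <- as.matrix(counts[, -1])
  rownames(m) <- counts$tu_id
  mode(m) <- "numeric"
  if (any(m < 0)) abort("counts must be non-negative")
  m
}

#' Fragments per kilobase per million mapped fragments
#'
#' `fpkm = count * 1e9 / (length * libsize)`.
#'
#' @param counts Count tibble (`tu_id` + one column per sample).
#' @param lengths Tibble `(tu_id, length)` or named vector of transcript
#'   lengths in nt.
#' @param libsizes Named vector of per-sample library sizes (total mapped
#'   fragments); defaults to the column sums of `counts`.
#' @return A tibble of the same shape as `counts` holding FPKM values.
#' @export
compute_fpkm <- function(counts, lengths, libsizes = NULL) {
  m <- counts_matrix(counts)
  if (is.data.frame(lengths)) lengths <- setNames(lengths$length, lengths$tu_id)
  len <- lengths[rownames(m)]
  if (anyNA(len)) abort("missing length for some TU")
  if (any(len <= 0)) abort("transcript lengths must be positive")
  if (is.null(libsizes)) libsizes <- colSums(m)
  libsizes <- libsizes[colnames(m)]
  if (anyNA(libsizes) || any(libsizes <= 0)) abort("library sizes must be positive")
  fpkm <- m * 1e9 / (len %o% libsizes)
  bind_cols(tibble(tu_id = rownames(m)), as_tibble(fpkm))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `p.adjust(..., method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Negative-binomial differential expression test
#'
#' For each TU, counts are library-size normalized (total-count scaling to
#' the mean library size), a common NB dispersion is estimated by pooled
#' method of moments across the two groups, and a Wald test is applied to
#' the log fold change of the group means. Two published threshold presets
#' are exposed: `"results"` calls a TU `up` iff `fold_change > 2`,
#' `p < 0.005` and `q < 0.05` (and `down` for `fold_change < 0.5`);
#' `"methods"` uses `p < 0.01` with the same fold-change rule and no FDR
#' gate. All inequalities are strict.
#'
#' @param counts Count tibble (`tu_id` + sample columns).
#' @param samples Tibble `(sample, group)` mapping the count columns to
#'   conditions.
#' @param control,treated Names of the two groups to contrast (fold change
#'   is treated / control).
#' @param preset `"results"` (default) or `"methods"`.
#' @return Tibble with `tu_id`, `base_mean`, `log2fc`, `fold_change`,
#'   `p_value`, `q_value`, `status` (`up` / `down` / `ns`), of class
#'   `de_result`.
#' @export
nb_diff_test <- function(counts, samples, control = "control",
                         treated = "treated",
                         preset = c("results", "methods")) {
  preset <- match.arg(preset)
  m <- counts_matrix(counts)
  samples <- as_tibble(samples)
  stopifnot(all(c("sample", "group") %in% names(samples)))
  ctrl_cols <- samples$sample[samples$group == control]
  trt_cols <- samples$sample[samples$group == treated]
  if (length(ctrl_cols) < 2 || length(trt_cols) < 2) {
    abort("need at least 2 replicates per group")
  }
  if (!all(c(ctrl_cols, trt_cols) %in% colnames(m))) {
    abort("sample names not found among count columns")
  }
  libs <- colSums(m)
  sf <- libs / mean(libs)
  norm <- sweep(m, 2, sf, "/")

  x0 <- norm[, ctrl_cols, drop = FALSE]
  x1 <- norm[, trt_cols, drop = FALSE]
  n0 <- ncol(x0); n1 <- ncol(x1)
  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  v0 <- apply(x0, 1, var); v1 <- apply(x1, 1, var)

  # pooled method-of-moments NB dispersion: var = mu + alpha * mu^2
  a0 <- ifelse(m0 > 0, (v0 - m0) / m0^2, NA)
  a1 <- ifelse(m1 > 0, (v1 - m1) / m1^2, NA)
  alpha <- pmax(rowMeans(cbind(a0, a1), na.rm = TRUE), 0)
  alpha[is.nan(alpha)] <- 0

  eps <- 0.5  # continuity shift for zero group means
  l0 <- log(m0 + eps); l1 <- log(m1 + eps)
  se <- sqrt((1 / (m0 + eps) + alpha) / n0 + (1 / (m1 + eps) + alpha) / n1)
  z <- (l1 - l0) / se
  p <- 2 * pnorm(-abs(z))
  all_zero <- m0 == 0 & m1 == 0
  p[all_zero] <- 1
  q <- bh_adjust(p)

  fc <- ifelse(m0 > 0, m1 / m0, ifelse(m1 > 0, Inf, NA))
  log2fc <- log2((m1 + eps) / (m0 + eps))
  passes <- switch(preset,
    results = p < 0.005 & q < 0.05,
    methods = p < 0.01
  )
  status <- dplyr::case_when(
    all_zero ~ "ns",
    passes & !is.na(fc) & fc > 2 ~ "up",
    passes & !is.na(fc) & fc < 0.5 ~ "down",
    TRUE ~ "ns"
  )
  out <- tibble(
    tu_id = rownames(m),
    base_mean = unname((m0 * n0 + m1 * n1) / (n0 + n1)),
    log2fc = unname(log2fc), fold_change = unname(fc),
    p_value = unname(p), q_value = unname(q), status = unname(status)
  )
  class(out) <- c("de_result", class(out))
  attr(out, "preset") <- preset
  out
}

# ---------------------------------------------------------------------------
# PROMPT / downstream-gene correlation

#' Correlation between PROMPTs and their downstream genes
#'
#' Computes, on `log2(FPKM + 1)`: (i) the per-pair Pearson correlation
#' across samples and its two-sided t-test p, and (ii) the pooled
#' correlation across pairs of the pair-mean PROMPT versus gene values (the
#' headline statistic of the PROMPT/gene scatter). Pairs with zero variance
#' in either member get `r = NA` with a warning.
#'
#' @param fpkm FPKM tibble (`tu_id` + sample columns) containing both the
#'   PROMPTs and their downstream genes.
#' @param prompts PROMPT table with `tu_id` and `gene_id` (from
#'   [classify_prompts()] or the synthetic truth).
#' @return A `prompt_correlation` object; `tidy()` returns the per-pair
#'   tibble, `glance()` the pooled estimate.
#' @export
prompt_gene_correlation <- function(fpkm, prompts) {
  m <- counts_matrix(fpkm)  # same layout checks; values are FPKM
  lx <- log2(m + 1)
  prompts <- as_tibble(prompts)
  keep <- prompts$tu_id %in% rownames(lx) & prompts$gene_id %in% rownames(lx)
  prompts <- prompts[keep, ]
  if (nrow(prompts) == 0) abort("no PROMPT/gene pair present in the matrix")
  if (ncol(lx) < 3) abort("need at least 3 samples for per-pair correlation")

  pair_cor <- purrr::map2(prompts$tu_id, prompts$gene_id, function(p, g) {
    x <- lx[p, ]; y <- lx[g, ]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(tu_id = p, gene_id = g, r = NA_real_, p_value = NA_real_))
    }
    ct <- cor.test(x, y)
    tibble(tu_id = p, gene_id = g, r = unname(ct$estimate),
           p_value = ct$p.value)
  }) %>% bind_rows()
  if (anyNA(pair_cor$r)) warn("zero-variance pair(s): correlation undefined")

  pm_prompt <- rowMeans(lx[prompts$tu_id, , drop = FALSE])
  pm_gene <- rowMeans(lx[prompts$gene_id, , drop = FALSE])
  pooled <- if (nrow(prompts) >= 3 && sd(pm_prompt) > 0 && sd(pm_gene) > 0) {
    ct <- cor.test(pm_prompt, pm_gene)
    tibble(r = unname(ct$estimate), p_value = ct$p.value, n_pairs = nrow(prompts))
  } else {
    tibble(r = NA_real_, p_value = NA_real_, n_pairs = nrow(prompts))
  }
  structure(list(pairs = pair_cor, pooled = pooled),
            class = "prompt_correlation")
}

#' @export
print.prompt_correlation <- function(x, ...) {
  cat(sprintf("<prompt_correlation> %d pairs; pooled r = %.3f (p = %.3g)\n",
              x$pooled$n_pairs, x$pooled$r, x$pooled$p_value))
  invisible(x)
}

#' Compare PROMPT and downstream-gene expression by orientation class
#'
#' For each `pair_class` with at least `min_pairs` pairs, performs a paired
#' Wilcoxon signed-rank test of per-pair mean FPKM (PROMPT versus gene)
#' and reports the medians. Classes with fewer pairs are dropped with a
#' warning.
#'
#' @param fpkm FPKM tibble (`tu_id` + sample columns).
#' @param prompts PROMPT table with `tu_id`, `gene_id`, `pair_class`.
#' @param min_pairs Minimum pairs per class (default 2).
#' @return Tibble with `pair_class`, `n_pairs`, `median_prompt`,
#'   `median_gene`, `median_diff`, `p_value`, `higher` (which member has
#'   the larger median).
#' @export
orientation_pair_comparison <- function(fpkm, prompts, min_pairs = 2) {
  m <- counts_matrix(fpkm)
  prompts <- as_tibble(prompts)
  stopifnot(all(c("tu_id", "gene_id", "pair_class") %in% names(prompts)))
  prompts <- prompts %>%
    filter(.data$tu_id %in% rownames(m), .data$gene_id %in% rownames(m))
  out <- prompts %>%
    group_by(.data$pair_class) %>%
    dplyr::group_map(function(df, key) {
      if (nrow(df) < min_pairs) {
        warn(sprintf("pair class '%s' has < %d pairs; omitted",
                     key$pair_class, min_pairs))
        return(NULL)
      }
      pv <- rowMeans(m[df$tu_id, , drop = FALSE])
      gv <- rowMeans(m[df$gene_id, , drop = FALSE])
      p <- if (all(pv == gv)) 1 else
        suppressWarnings(wilcox.test(pv, gv, paired = TRUE)$p.value)
      tibble(pair_class = key$pair_class, n_pairs = nrow(df),
             median_prompt = median(pv), median_gene = median(gv),
             median_diff = median(pv - gv), p_value = p,
             higher = dplyr::case_when(
               median(pv) > median(gv) ~ "PROMPT",
               median(pv) < median(gv) ~ "gene",
               TRUE ~ "tie"
             ))
    }) %>% bind_rows()
  out
}
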