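# Z-score co-expression network, greedy non-overlapping modules around
# top-degree PROMPTs, and hypergeometric GO enrichment.

#' Build a Z-score co-expression network
#'
#' Computes all-pairs Pearson correlations on `log2(x + 1)` across samples,
#' standardizes the off-diagonal upper-triangle correlations
#' (`Z = (r - mean) / sd`, the "empirical" normalization) and keeps edges
#' with `Z > z_threshold`. A Fisher z-transform variant is available for
#' comparison. When all profiles are identical the correlation spread is
#' zero and the network has no edges (with a warning).
#'
#' @param expr Expression tibble (`tu_id` + one column per sample), e.g.
#'   FPKM.
#' @param node_kinds Tibble `(id, kind)` with `kind` in `PROMPT` / `gene`.
#' @param z_threshold Keep edges with Z strictly above this (default 5).
#' @param method `"empirical"` (default) standardizes the observed r
#'   distribution; `"fisher"` standardizes `atanh(r)` by its nominal
#'   `1/sqrt(n - 3)` standard error.
#' @return A `coexpression_network`: list with `nodes`, `edges`
#'   (`from`, `to`, `r`, `z`), `z_threshold`, `r_mean`, `r_sd`.
#' @export
build_network <- function(expr, node_kinds, z_threshold = 5,
                          method = c("empirical", "fisher")) {
  method <- match.arg(method)
  m <- counts_matrix(expr)
  if (ncol(m) < 4) abort("need at least 4 samples to build a network")
  node_kinds <- as_tibble(node_kinds)
  stopifnot(all(c("id", "kind") %in% names(node_kinds)))
  if (!all(rownames(m) %in% node_kinds$id)) {
    abort("every expression row needs a kind (PROMPT or gene)")
  }
  lx <- log2(m + 1)
  keep <- apply(lx, 1, sd) > 0
  if (!all(keep)) lx <- lx[keep, , drop = FALSE]
  cmat <- suppressWarnings(cor(t(lx)))
  ut <- upper.tri(cmat)
  r <- cmat[ut]
  idx <- which(ut, arr.ind = TRUE)
  if (method == "empirical") {
    r_mean <- mean(r); r_sd <- sd(r)
    if (is.na(r_sd) || r_sd == 0) {
      warn("correlation spread is zero; network has no edges")
      edges <- tibble(from = character(), to = character(),
                      r = numeric(), z = numeric())
      return(new_network(node_kinds, edges, z_threshold, mean(r), 0))
    }
    z <- (r - r_mean) / r_sd
  } else {
    r_mean <- 0; r_sd <- 1 / sqrt(ncol(lx) - 3)
    z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) / r_sd
  }
  sel <- z > z_threshold
  edges <- tibble(
    from = rownames(cmat)[idx[sel, 1]],
    to = rownames(cmat)[idx[sel, 2]],
    r = r[sel], z = z[sel]
  )
  new_network(node_kinds, edges, z_threshold, r_mean, r_sd)
}

new_network <- function(nodes, edges, z_threshold, r_mean, r_sd) {
  structure(
    list(nodes = nodes, edges = edges, z_threshold = z_threshold,
         r_mean = r_mean, r_sd = r_sd),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("<coexpression_network> %d nodes, %d edges (Z > %g)\n",
              nrow(x$nodes), nrow(x$edges), x$z_threshold))
  invisible(x)
}

network_neighbors <- function(network, id, kind = NULL) {
  e <- network$edges
  nb <- c(e$to[e$from == id], e$from[e$to == id])
  if (!is.null(kind)) {
    kinds <- setNames(network$nodes$kind, network$nodes$id)
    nb <- nb[kinds[nb] == kind]
  }
  unique(nb)
}

#' Rank PROMPTs by co-expression degree
#'
#' Degree counts gene-kind neighbors only; ties are broken by id so the
#' downstream greedy module extraction is deterministic.
#'
#' @param network A `coexpression_network`.
#' @return Tibble `(prompt_id, degree)` in decreasing degree order.
#' @export
rank_prompts_by_degree <- function(network) {
  prompt_ids <- network$nodes$id[network$nodes$kind == "PROMPT"]
  tibble(
    prompt_id = prompt_ids,
    degree = vapply(prompt_ids, function(p) {
      length(network_neighbors(network, p, kind = "gene"))
    }, numeric(1), USE.NAMES = FALSE)
  ) %>% arrange(desc(.data$degree), .data$prompt_id)
}

#' Extract non-overlapping network modules around central PROMPTs
#'
#' Greedy by degree rank: each module is a central PROMPT plus its
#' gene-kind neighbors that have not yet been claimed by a higher-ranked
#' module; modules smaller than `min_size` genes are discarded and only the
#' genes of kept modules are removed from the pool.
#'
#' @param network A `coexpression_network`.
#' @param min_size Minimum number of member genes (default 51).
#' @return Tibble with `module_id` (`NM1`, `NM2`, ...), `prompt_id`,
#'   `size`, and a `members` list-column of gene ids.
#' @export
extract_modules <- function(network, min_size = 51) {
  ranked <- rank_prompts_by_degree(network)
  assigned <- character(0)
  modules <- list()
  for (i in seq_len(nrow(ranked))) {
    p <- ranked$prompt_id[i]
    members <- setdiff(network_neighbors(network, p, kind = "gene"), assigned)
    if (length(members) >= min_size) {
      assigned <- c(assigned, members)
      modules[[length(modules) + 1]] <-
        tibble(prompt_id = p, size = length(members), members = list(sort(members)))
    }
  }
  if (length(modules) == 0) {
    return(tibble(module_id = character(), prompt_id = character(),
                  size = integer(), members = list()))
  }
  bind_rows(modules) %>%
    mutate(module_id = paste0("NM", row_number()), .before = "prompt_id")
}

#' Hypergeometric GO enrichment of a gene set
#'
#' For each term, `p = P(X >= k)` where X is hypergeometric with population
#' `universe`, successes the term-annotated genes, and draws the module
#' size; BH adjustment across terms. No ontology propagation is performed:
#' the map is used exactly as given.
#'
#' @param module_genes Character vector of gene ids (must lie in
#'   `universe`).
#' @param go_map Tibble `(gene_id, go_id)` annotations.
#' @param universe Character vector: the gene population.
#' @return Tibble `(go_id, n_term, overlap, p_value, q_value)` sorted by p.
#' @export
go_enrichment <- function(module_genes, go_map, universe) {
  if (length(module_genes) == 0) {
    return(tibble(go_id = character(), n_term = integer(),
                  overlap = integer(), p_value = numeric(),
                  q_value = numeric()))
  }
  if (!all(module_genes %in% universe)) {
    abort("module genes must be a subset of the universe")
  }
  go_map <- as_tibble(go_map) %>% filter(.data$gene_id %in% universe)
  N <- length(unique(universe))
  n <- length(unique(module_genes))
  out <- go_map %>%
    group_by(.data$go_id) %>%
    summarise(
      n_term = dplyr::n_distinct(.data$gene_id),
      overlap = sum(unique(.data$gene_id) %in% module_genes)
    ) %>%
    mutate(p_value = phyper(.data$overlap - 1, .data$n_term,
                            N - .data$n_term, n, lower.tail = FALSE)) %>%
    mutate(q_value = bh_adjust(.data$p_value)) %>%
    arrange(.data$p_value)
  out
}

#' Strictly co-expressed partner genes of a PROMPT
#'
#' The stricter pairing rule used for trans-target candidates: keep genes
#' whose correlation with the PROMPT exceeds `r_min` with
#' `p < p_max` (Pearson on `log2(x + 1)` across samples).
#'
#' @param expr Expression tibble (`tu_id` + sample columns).
#' @param prompt_id The PROMPT of interest.
#' @param candidates Gene ids to test (default: all other rows).
#' @param r_min,p_max Strict thresholds (defaults 0.9999 and 1e-4).
#' @return Tibble `(gene_id, r, p_value)` of the retained partners.
#' @export
strict_coexpressed_genes <- function(expr, prompt_id, candidates = NULL,
                                     r_min = 0.9999, p_max = 1e-4) {
  m <- counts_matrix(expr)
  if (!prompt_id %in% rownames(m)) abort("prompt_id not found in matrix")
  if (is.null(candidates)) candidates <- setdiff(rownames(m), prompt_id)
  lx <- log2(m + 1)
  x <- lx[prompt_id, ]
  purrr::map(candidates, function(g) {
    y <- lx[g, ]
    if (sd(x) == 0 || sd(y) == 0) return(NULL)
    ct <- suppressWarnings(cor.test(x, y))
    tibble(gene_id = g, r = unname(ct$estimate), p_value = ct$p.value)
  }) %>% bind_rows() %>%
    {
      if (nrow(.) == 0) tibble(gene_id = character(), r = numeric(),
                               p_value = numeric())
      else filter(., .data$r > r_min, .data$p_value < p_max)
    }
}
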