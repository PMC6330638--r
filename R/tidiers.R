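# broom-style verbs and quick ggplot views of the result objects.

#' @exportS3Method generics::tidy
tidy.coexpression_network <- function(x, ...) x$edges

#' @exportS3Method generics::glance
glance.coexpression_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    z_threshold = x$z_threshold, r_mean = x$r_mean, r_sd = x$r_sd
  )
}

#' @exportS3Method generics::tidy
tidy.prompt_correlation <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.prompt_correlation <- function(x, ...) x$pooled

#' Volcano view of a differential-expression result
#'
#' @param object A `de_result` from [nb_diff_test()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.de_result <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(neg_log10_p = -log10(pmax(.data$p_value, 1e-300)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc, y = .data$neg_log10_p,
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (treated / control)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Degree distribution of a co-expression network
#'
#' @param object A `coexpression_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.coexpression_network <- function(object, ...) {
  deg <- rank_prompts_by_degree(object)
  ggplot2::ggplot(deg, ggplot2::aes(x = stats::reorder(.data$prompt_id,
                                                       -.data$degree),
                                    y = .data$degree)) +
    ggplot2::geom_col(fill = "#16a085") +
    ggplot2::labs(x = NULL, y = "co-expressed genes (degree)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' MFE versus transcript length for lncRNA records
#'
#' Reproduces the descriptive stability view: folding energy against
#' transcript length, coloured by class.
#'
#' @param records Output of [filter_lncrna()] (folded).
#' @return A ggplot object.
#' @export
plot_mfe_length <- function(records) {
  df <- records %>% filter(!is.na(.data$mfe))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$mfe,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "length (nt)", y = "MFE (kcal/mol)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Per-chromosome PROMPT density barplot
#'
#' @param density Output of [chromosome_density()].
#' @return A ggplot object.
#' @export
plot_prompt_density <- function(density) {
  ggplot2::ggplot(density$per_chrom,
                  ggplot2::aes(x = .data$chrom, y = .data$per_mb)) +
    ggplot2::geom_col(fill = "#8e44ad") +
    ggplot2::labs(x = NULL, y = "PROMPTs per Mb") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
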