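#' Plot the running enrichment sum for one gene set
#'
#' Draws `f(i)` along the ranked list, with the maximum (the enrichment
#' score) marked and member positions shown as a rug — the standard
#' enrichment "mountain" plot.
#'
#' @param ranked a ranked gene list from [rank_genes()].
#' @param members member gene symbols of the set.
#' @param set_name optional title label.
#' @return a ggplot object.
#' @export
plot_running_sum <- function(ranked, members, set_name = NULL) {
  genes <- ranked_gene_vector(ranked)
  n <- length(genes)
  is_member <- genes %in% members
  n_s <- sum(is_member)
  if (n_s == 0 || n_s >= n) abort("degenerate set for this ranked list")
  f <- cumsum(is_member) / n_s - cumsum(!is_member) / (n - n_s)
  i_max <- which.max(f)
  df <- tibble::tibble(rank = seq_len(n), f = f)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$f)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(data = df[i_max, ], colour = "#d95f02", size = 2) +
    ggplot2::annotate("text", x = i_max, y = f[i_max],
                      label = sprintf("ES = %.3f", f[i_max]),
                      vjust = -0.8, hjust = 0.3, size = 3.2) +
    ggplot2::geom_rug(data = df[is_member, ], sides = "b",
                      alpha = 0.5, length = ggplot2::unit(0.03, "npc")) +
    ggplot2::labs(x = "rank in list", y = "running sum f(i)",
                  title = set_name,
                  subtitle = sprintf("N = %d, N_S = %d", n, n_s)) +
    ggplot2::theme_minimal()
}

#' Plot top enriched sets of a result
#'
#' Dot plot of the `top_n` sets per direction, ordered by enrichment
#' score, coloured by permutation p-value.
#'
#' @param object a `gsea_result` from [rank_gene_sets()].
#' @param top_n sets shown per direction (default 10).
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gsea_result <- function(object, top_n = 10, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$direction) |>
    dplyr::slice_min(.data$rank, n = top_n, with_ties = FALSE) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$es,
                                   y = stats::reorder(.data$set, .data$es),
                                   colour = .data$p_value)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::facet_wrap(~direction, scales = "free_y") +
    ggplot2::scale_colour_gradient(low = "#d7301f", high = "#74a9cf",
                                   name = "perm. p") +
    ggplot2::labs(x = "enrichment score", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
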