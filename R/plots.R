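#' Manhattan-style plot of the family-based GWAS
#'
#' One point per SNP at its minimum p across models and strata, coloured by
#' the winning genetic model, with the candidate-selection and corrected
#' genome-wide thresholds drawn.
#'
#' @param results Output of [run_family_gwas()].
#' @param p_family_max Selection threshold line (default 1e-3).
#' @return A ggplot object.
#' @export
plot_family_gwas <- function(results, p_family_max = 1e-3) {
  best <- best_association(results)
  best$order <- seq_len(nrow(best))
  ggplot2::ggplot(best, ggplot2::aes(x = .data$order, y = -log10(.data$p),
                                     colour = .data$model)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = -log10(p_family_max), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(genome_wide_threshold()),
                        linetype = 3) +
    ggplot2::labs(x = "SNP", y = expression(-log[10](p)),
                  colour = "best model",
                  title = "Family-based GWAS (min p over models and strata)") +
    ggplot2::theme_minimal()
}

#' Score-card distribution plot
#'
#' Stacked category points per SNP-gene pair, ordered by total score, with
#' the selection cutoff marked.
#'
#' @param cards Output of [prioritize()].
#' @param cutoff Cutoff line (default 4).
#' @return A ggplot object.
#' @export
plot_score_cards <- function(cards, cutoff = 4) {
  long <- cards |>
    mutate(pair = paste(.data$snp, .data$gene, sep = " / ")) |>
    select("pair", "total",
           statistical = "statistical_points", genomic = "genomic_points",
           previous = "previous_points", physiological = "physiological_points") |>
    tidyr::pivot_longer(c("statistical", "genomic", "previous", "physiological"),
                        names_to = "category", values_to = "points")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$pair, .data$total),
                                     y = .data$points, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = cutoff, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "points", title = "SNP-gene pair scores") +
    ggplot2::theme_minimal()
}

#' Genetic-score distributions by affection status
#'
#' @param scores Output of [compute_gs()].
#' @return A ggplot object.
#' @export
plot_gs_distribution <- function(scores) {
  df <- scores[scores$status %in% c("affected", "unaffected"), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gs, fill = .data$status)) +
    ggplot2::geom_histogram(position = "identity", alpha = 0.5, bins = 30) +
    ggplot2::labs(x = "genetic score", y = "children",
                  title = "Genetic score by affection status") +
    ggplot2::theme_minimal()
}

#' Plot a bootstrap replicate distribution
#'
#' @param object A [bootstrap_statistic()] result.
#' @param ... Unused.
#' @return A ggplot object showing the replicate histogram, the observed
#'   value (solid) and the percentile 95% CI (dashed).
#' @method autoplot bootstrap_result
#' @export
autoplot.bootstrap_result <- function(object, ...) {
  df <- tibble(replicate = object$replicates)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replicate)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed) +
    ggplot2::geom_vline(xintercept = object$ci, linetype = 2) +
    ggplot2::labs(x = "bootstrap statistic", y = "replicates",
                  title = paste0("Family bootstrap (B = ", object$B, ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
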