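#' Histogram of conservation breadth
#'
#' Bars count conserved clusters per genome-fraction quarter (how many of
#' the surveyed genomes each cluster's members cover).
#'
#' @param breadth Tibble from [conservation_breadth()].
#' @return A ggplot object.
#' @export
plot_conservation_breadth <- function(breadth) {
  ggplot2::ggplot(breadth, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::scale_x_discrete(drop = FALSE) +
    ggplot2::labs(x = "fraction of genomes covered",
                  y = "conserved clusters",
                  title = "Conservation breadth of sORF clusters") +
    ggplot2::theme_minimal()
}

#' Coding-probability distribution of scored candidates
#'
#' @param candidates Candidate tibble with a `coding_probability` column
#'   (see [score_candidates()]).
#' @param threshold Cutoff drawn as a dashed line (default 0.5).
#' @return A ggplot object.
#' @export
plot_coding_scores <- function(candidates, threshold = 0.5) {
  ggplot2::ggplot(candidates,
                  ggplot2::aes(x = .data$coding_probability)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "coding probability", y = "ORF candidates") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Stage-count overview of a pipeline run
#'
#' @param object A `sorf_run`.
#' @param ... Unused.
#' @return A ggplot object showing per-species candidate counts by stage.
#' @exportS3Method ggplot2::autoplot
autoplot.sorf_run <- function(object, ...) {
  long <- object$species_counts |>
    tidyr::pivot_longer(-"species_id", names_to = "stage",
                        values_to = "count") |>
    mutate(stage = factor(.data$stage, levels = unique(.data$stage)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stage, y = .data$count,
                                     fill = .data$species_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "count", fill = "species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
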