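# ggplot2 views of the main result types.

#' Stacked-bar view of taxonomic read distribution
#'
#' @param data Tidy taxonomic-distribution tibble with columns `sample_id`,
#'   `species_id`, `percent` (e.g. `report$taxonomic`).
#' @return A ggplot.
#' @export
plot_taxonomic_distribution <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$sample_id, y = .data$percent,
                                     fill = .data$species_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of assigned read pairs",
                  fill = "species") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Dot/triangle view of gene coverage at both thresholds
#'
#' Dots mark the 1-read-pair threshold and triangles the 5-read-pair
#' threshold, one panel per species, echoing the conventional paired
#' coverage display for library-method comparisons.
#'
#' @param data Tidy coverage tibble with columns `sample_id`, `species_id`,
#'   `threshold`, `coverage` (e.g. `report$coverage`).
#' @return A ggplot.
#' @export
plot_gene_coverage <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$sample_id,
                                     y = .data$coverage,
                                     shape = factor(.data$threshold),
                                     colour = if ("arm" %in% names(data))
                                       .data$arm else .data$sample_id)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$species_id)) +
    ggplot2::scale_shape_manual(values = c(16, 17)) +
    ggplot2::labs(x = NULL, y = "gene coverage (%)",
                  shape = "read-pair threshold", colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Boxplot view of per-gene depth over expressed genes
#'
#' @param tables List of [gene_count_table()]s.
#' @return A ggplot (log10 depth scale).
#' @export
plot_gene_depth <- function(tables) {
  data <- purrr::map(tables, as_tibble) |>
    purrr::list_rbind() |>
    filter(.data$count >= 1)
  ggplot2::ggplot(data, ggplot2::aes(x = .data$sample_id, y = .data$count)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$species_id), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "read pairs per expressed gene") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a run report
#'
#' @param object A [run_experiment()] report.
#' @param type One of `"coverage"`, `"taxonomic"`, `"depth"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot run_report
#' @export
autoplot.run_report <- function(object, type = c("coverage", "taxonomic",
                                                 "depth"), ...) {
  switch(match.arg(type),
         coverage = plot_gene_coverage(object$coverage),
         taxonomic = plot_taxonomic_distribution(object$taxonomic),
         depth = plot_gene_depth(object$tables))
}
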