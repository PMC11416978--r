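#' Plot method-stratified EPT error rates
#'
#' Bar chart of the percentage of laboratories with at least one error,
#' by typing method, annotated with lab counts.
#'
#' @param object A `hladq_ept_summary` from [aggregate_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hladq_ept_summary
#' @export
autoplot.hladq_ept_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$error_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%d/%d labs", .data$labs_with_error_n, .data$labs_n)),
      vjust = -0.4, size = 3
    ) +
    ggplot2::labs(
      x = "typing method",
      y = "laboratories with ≥ 1 error (%)",
      title = "EPT error rate by typing method"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a haplotype-frequency table
#'
#' Column chart of population haplotype frequencies, predisposing
#' haplotypes highlighted.
#'
#' @param table A frequency tibble ([read_frequency_table()]).
#' @return A ggplot object.
#' @export
plot_haplotype_frequencies <- function(table) {
  validate_frequency_table(table)
  df <- table
  if (!"haplotype" %in% names(df)) {
    df$haplotype <- paste0(df$dqa1, "~", df$dqb1)
  }
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = stats::reorder(.data$haplotype, -.data$frequency),
      y = .data$frequency, fill = .data$predisposing
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey65"),
      name = "CD-predisposing"
    ) +
    ggplot2::labs(x = NULL, y = "haplotype frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot interpretation category counts
#'
#' @param results A tibble from [interpret_genotypes()].
#' @return A ggplot object.
#' @export
plot_category_counts <- function(results) {
  stopifnot("category" %in% names(results))
  df <- dplyr::count(results, .data$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "samples") +
    ggplot2::theme_minimal()
}
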