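# ggplot2 visualisations for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a concordance matrix as a tile heatmap
#'
#' @param object A `pathway_concordance` object ([compare_pathways()]).
#' @param ... Unused.
#' @return A ggplot: outcome of one pathway against the other, tiles
#'   labelled with patient counts, diagonal (concordant) cells outlined.
#' @export
autoplot.pathway_concordance <- function(object, ...) {
  d <- tidy(object)
  names(d)[1:2] <- c("a", "b")
  d <- d %>% mutate(
    a = factor(.data$a, levels = rev(outcome_levels)),
    b = factor(.data$b, levels = outcome_levels)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$b, y = .data$a, fill = .data$n)) +
    ggplot2::geom_tile(color = "grey40") +
    ggplot2::geom_tile(
      data = filter(d, .data$concordant), fill = NA,
      color = "black", linewidth = 0.8
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(
      x = paste(object$labels[2], "outcome"),
      y = paste(object$labels[1], "outcome"),
      fill = "patients",
      title = sprintf("Diagnostic outcome concordance (n = %d)", object$n)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of diagnosed patients by primary variant type
#'
#' @param tallies Output of [tally_diagnoses()], or a named list of such
#'   tallies (one bar group per pathway).
#' @return A ggplot.
#' @export
plot_diagnosis_types <- function(tallies) {
  if (inherits(tallies, "data.frame")) tallies <- list(cohort = tallies)
  d <- purrr::imap(tallies, ~ mutate(.x, pathway = .y)) %>% bind_rows()
  d <- mutate(d, type = factor(.data$type, levels = c("snv", "indel", "cnv", "str", "mito")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$type, y = .data$n, fill = .data$pathway)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "primary variant type", y = "diagnosed patients", fill = NULL
    ) +
    ggplot2::theme_minimal()
}
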