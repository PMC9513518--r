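# ggplot2 views of the report objects. Deliberately plain: counts on a 4x4
# grid, involvement-pattern bars, death-timing bars.

#' Plot the (N, H) score matrix
#'
#' Renders the 4x4 grid of two-part score combinations with hepatic scores on
#' the horizontal axis and neuromuscular scores on the vertical axis, the cell
#' shading giving the patient count and the four established-subtype cells
#' outlined.
#'
#' @param x A `gsd4_score_matrix`, `gsd4_report`, or cohort tibble.
#' @return A ggplot object.
#' @export
plot_score_matrix <- function(x) {
  sm <- if (inherits(x, "gsd4_report")) {
    x$score_matrix
  } else if (inherits(x, "gsd4_score_matrix")) {
    x
  } else {
    score_matrix(x)
  }
  dat <- tidy(sm) %>%
    mutate(established = .data$score %in% c("N3-H0", "N1-H0", "N0-H3", "N0-H1"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$h_score, y = .data$n_score)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count),
                       color = "grey70", linewidth = 0.3) +
    ggplot2::geom_tile(data = filter(dat, .data$established), fill = NA,
                       color = "black", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "hepatic score", y = "neuromuscular score",
                  fill = "patients",
                  title = sprintf("Two-part phenotype scores (n = %d)",
                                  sm$n_scored),
                  subtitle = "outlined cells: established subtypes") +
    ggplot2::theme_minimal()
}

#' Plot tri-system involvement patterns
#'
#' Bar chart of the Venn-category counts among tri-assessable patients.
#'
#' @param x A `gsd4_venn_summary`, `gsd4_report`, or cohort tibble.
#' @return A ggplot object.
#' @export
plot_involvement <- function(x) {
  vs <- if (inherits(x, "gsd4_report")) {
    x$venn
  } else if (inherits(x, "gsd4_venn_summary")) {
    x
  } else {
    venn_summary(x)
  }
  dat <- mutate(vs$counts,
                category = factor(.data$category,
                                  levels = rev(setdiff(.venn_levels,
                                                       "not_assessable"))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$count, y = .data$category)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), hjust = -0.3) +
    ggplot2::labs(x = "patients", y = NULL,
                  title = sprintf("Tri-system involvement (n = %d assessable)",
                                  vs$n_assessable)) +
    ggplot2::theme_minimal()
}

#' Plot death-timing clusters
#'
#' @param x A `gsd4_survival_summary`, `gsd4_report`, or cohort tibble.
#' @return A ggplot object.
#' @export
plot_survival <- function(x) {
  sv <- if (inherits(x, "gsd4_report")) {
    x$survival
  } else if (inherits(x, "gsd4_survival_summary")) {
    x
  } else {
    survival_summary(x)
  }
  dat <- mutate(sv$cluster_bins,
                bin = factor(.data$bin, levels = .data$bin))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = "age at death", y = "deaths",
                  title = sprintf("Death timing (%d deaths)", sv$n_deceased)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.gsd4_score_matrix <- function(object, ...) plot_score_matrix(object)

#' @export
autoplot.gsd4_venn_summary <- function(object, ...) plot_involvement(object)

#' @export
autoplot.gsd4_survival_summary <- function(object, ...) plot_survival(object)

#' @export
autoplot.gsd4_report <- function(object, ...) plot_score_matrix(object)
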