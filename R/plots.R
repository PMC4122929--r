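# ggplot2 displays for the main result types

#' Ks (or percent identity) distribution by duplication origin
#'
#' Histograms of within-pair divergence, faceted by origin label, the
#' standard display for comparing WGD- and tandem-derived paralogs.
#'
#' @param data tibble with a `label` column and the plotted variable.
#' @param var variable to plot (`"ks"` or `"percent_id"`).
#' @param bins histogram bins.
#' @param max_ks Ks values above this are dropped from the display (they
#'   remain in the data); use `Inf` to show everything.
#' @return A ggplot object.
#' @export
plot_divergence_by_origin <- function(data, var = c("ks", "percent_id"),
                                      bins = 30, max_ks = 1.5) {
  var <- match.arg(var)
  d <- data |> filter(.data$label %in% c("WGD", "LGD"))
  if (var == "ks") {
    d <- d |> filter(!is.na(.data$ks), .data$ks <= max_ks)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[var]])) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$label), ncol = 1,
                        scales = "free_y") +
    ggplot2::labs(x = if (var == "ks") "Ks (synonymous divergence)" else
      "percent identity within pair", y = "pairs") +
    ggplot2::theme_minimal()
}

#' Annotation-hit concordance by pair group
#'
#' Stacked proportions of SAME_HIT / DIFFERENT_HIT (NO_HIT optionally
#' hidden, as is conventional for this display; the chi-squared test always
#' uses the full 3x3 table).
#'
#' @param table a [concordance_table()] result.
#' @param show_no_hit include the NO_HIT category.
#' @return A ggplot object.
#' @export
plot_hit_concordance <- function(table, show_no_hit = FALSE) {
  long <- table |>
    tidyr::pivot_longer(c("SAME_HIT", "DIFFERENT_HIT", "NO_HIT"),
                        names_to = "category", values_to = "n")
  if (!show_no_hit) long <- long |> filter(.data$category != "NO_HIT")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$group, y = .data$n,
                               fill = .data$category)) +
    ggplot2::geom_col(position = "fill") +
    ggplot2::labs(x = NULL, y = "proportion of pairs", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Coding-potential differences by pair group
#'
#' Boxplots of the absolute within-pair difference in coding-potential
#' score for the paralog pairs and the two control sets.
#'
#' @param deltas named list of numeric |delta score| vectors (e.g. the
#'   `score_deltas` element of a pipeline result).
#' @return A ggplot object.
#' @export
plot_score_differences <- function(deltas) {
  d <- bind_rows(lapply(names(deltas), function(g) {
    tibble(group = g, delta_score = deltas[[g]])
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$delta_score)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "|difference in coding potential|") +
    ggplot2::theme_minimal()
}

#' @rdname plot_divergence_by_origin
#' @param object a `paralog_pipeline` result.
#' @param ... passed to [plot_divergence_by_origin()].
#' @export
autoplot.paralog_pipeline <- function(object, ...) {
  d <- object$workflow$pairs |>
    filter(.data$label %in% c("WGD", "LGD")) |>
    left_join(object$kaks |> select("id_a", "id_b", ks = "Ks"),
              by = c("id_a", "id_b"))
  plot_divergence_by_origin(d, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
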