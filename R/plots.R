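#' Plot a pairwise comparison
#'
#' Fold change against outlier significance (-log10 p) for quantified
#' links, colored by category; unique links are shown in side panels at
#' their condition's edge.
#'
#' @param object An `xl_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xl_comparison <- function(object, ...) {
  df <- tidy(object)
  conditions <- attr(object, "conditions")
  quant <- df[df$detection == "quantified", ]
  ggplot2::ggplot(quant,
                  ggplot2::aes(x = .data$fold_change,
                               y = -log10(.data$p_value),
                               color = .data$category)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "alpha")),
                        linetype = "dashed", color = "gray40") +
    ggplot2::scale_color_manual(values = xl_category_colors(),
                                drop = FALSE) +
    ggplot2::labs(
      x = bquote(log[2] ~ .(conditions[1]) / .(conditions[2])),
      y = expression(-log[10] ~ italic(p)),
      color = "category",
      title = paste0(conditions[1], " versus ", conditions[2]),
      subtitle = paste0(nrow(df), " quantified cross-links (",
                        sum(df$detection != "quantified"),
                        " unique by singlet detection)")
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of category counts
#'
#' @param cmp An `xl_comparison`.
#' @return A ggplot object.
#' @export
plot_category_counts <- function(cmp) {
  cc <- category_counts(cmp)
  cc$category <- factor(cc$category, levels = xl_category_levels())
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$category, y = .data$n,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::scale_fill_manual(values = xl_category_colors(),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "cross-links") +
    ggplot2::theme_minimal()
}

#' Plot the three-way Venn category counts
#'
#' @param object An `xl_threeway`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xl_threeway <- function(object, ...) {
  df <- dplyr::count(tibble::as_tibble(object), .data$venn_category)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$venn_category,
                                                      -.data$n),
                                   y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "cross-links") +
    ggplot2::theme_minimal()
}

#' Score trace of a sampling run
#'
#' @param object An `xl_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.xl_ensemble <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$score,
                                   color = factor(.data$run))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "recorded model", y = "score (-log posterior)",
                  color = "run") +
    ggplot2::theme_minimal()
}

#' Satisfaction / contact map of a cluster
#'
#' Gray shading shows the bead-bead contact frequency over the cluster
#' members; restrained residue pairs are overlaid as satisfied (green) or
#' violated (orange) circles.
#'
#' @param report Output of [satisfaction_report()].
#' @param representation The `xl_representation` (for residue numbers).
#' @return A ggplot object.
#' @export
plot_satisfaction_map <- function(report, representation) {
  cm <- report$contact
  resno <- representation$beads$resno
  df <- tibble::tibble(
    i = resno[rep(seq_len(nrow(cm)), times = ncol(cm))],
    j = resno[rep(seq_len(ncol(cm)), each = nrow(cm))],
    freq = as.vector(cm)
  )
  links <- report$links
  links$status <- ifelse(links$satisfied, "satisfied", "violated")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$freq)) +
    ggplot2::scale_fill_gradient(low = "white", high = "gray20") +
    ggplot2::geom_point(
      data = links,
      ggplot2::aes(x = .data$res_a, y = .data$res_b,
                   color = .data$status), size = 2
    ) +
    ggplot2::geom_point(
      data = links,
      ggplot2::aes(x = .data$res_b, y = .data$res_a,
                   color = .data$status), size = 2
    ) +
    ggplot2::scale_color_manual(values = c(satisfied = "forestgreen",
                                           violated = "darkorange")) +
    ggplot2::labs(x = "residue", y = "residue", fill = "contact freq.",
                  color = NULL) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

xl_category_colors <- function() {
  c(unique_1 = "#2166AC", enriched_1 = "#67A9CF", mutual = "gray55",
    enriched_2 = "#1B7837", unique_2 = "#5AAE61")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
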