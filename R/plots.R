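# ggplot2 visualizations: selectivity heatmaps and score distributions.

kopl_heatmap <- function(df, fill, title, legend) {
  df <- dplyr::mutate(df,
    pos_f = factor(position_label(.data$position), levels = position_label(kopl_positions())),
    res_f = factor(.data$residue, levels = rev(sort(unique(.data$residue)))))
  ggplot2::ggplot(df, ggplot2::aes(.data$pos_f, .data$res_f, fill = .data[[fill]])) +
    ggplot2::geom_tile(color = "grey85") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7", high = "#b2182b",
                                  midpoint = max(df[[fill]]) / 2, name = legend) +
    ggplot2::labs(x = "position relative to central lysine", y = "fixed residue",
                  title = title) +
    ggplot2::theme_minimal()
}

#' Heatmap of a selectivity matrix
#'
#' Position x residue tile plot in the red-high / blue-low convention of
#' oriented-peptide-library selectivity profiles. Phospho rows, if present,
#' appear below the standard residues.
#'
#' @param object A `kopl_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kopl_matrix
#' @export
autoplot.kopl_matrix <- function(object, ...) {
  kopl_heatmap(tibble::as_tibble(object), "score",
               sprintf("Selectivity matrix (%s%s)", matrix_mode(object),
                       if (is_transformed(object)) ", ln(1+x)" else ""),
               "score")
}

#' Heatmap of a planted ground-truth profile
#'
#' @param object A `kopl_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kopl_profile
#' @export
autoplot.kopl_profile <- function(object, ...) {
  kopl_heatmap(tibble::as_tibble(object), "weight", "Planted selectivity profile", "weight")
}

#' Score distribution of scanned candidates
#'
#' Histogram of PSSM scores over all scanned motifs, optionally marking the
#' score cutoff implied by a top-fraction threshold.
#'
#' @param object A `kopl_candidates` table.
#' @param top_fraction Optional fraction in (0, 1]; draws the count-mode
#'   cutoff line.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kopl_candidates
#' @export
autoplot.kopl_candidates <- function(object, top_fraction = NULL, bins = 60, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "#4393c3", color = "white") +
    ggplot2::labs(x = "PSSM score", y = "motifs",
                  title = "Distribution of PSSM scores over lysine-centered 7-mers") +
    ggplot2::theme_minimal()
  if (!is.null(top_fraction) && nrow(object) > 0) {
    kept <- top_candidates(object, top_fraction)
    p <- p + ggplot2::geom_vline(xintercept = min(kept$score),
                                 linetype = "dashed", color = "#b2182b")
  }
  p
}
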