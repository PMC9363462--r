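#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of per-position amino-acid enrichment factors
#'
#' Residues on the y axis (alphabetical, top to bottom), randomized positions
#' on the x axis, tile fill = EF. Undefined entries (residue unseen before
#' selection) are left blank.
#'
#' @param pos_ef A [position_aa_ef()] tibble.
#' @param trans Fill transformation (default `"log2"`; EF is a ratio, so a
#'   log scale centers no-change at the midpoint).
#' @return A ggplot object.
#' @export
plot_position_ef <- function(pos_ef, trans = "log2") {
  df <- pos_ef[!pos_ef$undefined, ]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rel_pos,
    y = factor(.data$residue, levels = rev(AA_ALPHABET)),
    fill = .data$ef
  )) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "EF") +
    ggplot2::labs(
      x = "position relative to reactive Gln", y = NULL,
      title = "Per-position amino-acid enrichment"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of permutation importances
#'
#' Features sorted by importance; bars colored by the Pearson-derived sign
#' (association with an increase or decrease of enrichment).
#'
#' @param object An `importance_report` from [permutation_importance()].
#' @param top_n How many features to show (default 20).
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.importance_report <- function(object, top_n = 20L, ...) {
  df <- object[order(object$rank), ]
  df <- head(df, top_n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$importance, y = .data$feature, fill = .data$sign
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        xmin = .data$importance - .data$sd,
        xmax = .data$importance + .data$sd
      ),
      width = 0.3
    ) +
    ggplot2::scale_fill_manual(
      values = c(`+` = "#2e7d32", `-` = "#c62828"),
      na.value = "grey60",
      name = "association"
    ) +
    ggplot2::labs(
      x = "permutation importance (held-out MSE increase)", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.importance_report
#' @param x An `importance_report`.
#' @export
plot_importance <- function(x, top_n = 20L) {
  autoplot.importance_report(x, top_n = top_n)
}

#' Boxplots of enrichment by hydrophobic residue count
#'
#' @param etable A [peptide_ef()] tibble.
#' @param design A [library_design()].
#' @param hydrophobic Hydrophobic residue set.
#' @return A ggplot object.
#' @export
plot_hydrophobicity <- function(etable, design,
                                hydrophobic = HYDROPHOBIC_AA) {
  df <- etable[!is.na(etable$ef), ]
  pos <- design$randomized_indices
  df$n_hydrophobic <- rowSums(vapply(
    pos,
    function(i) substr(df$peptide, i, i) %in% hydrophobic,
    logical(nrow(df))
  ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$n_hydrophobic), y = .data$ef
  )) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::labs(
      x = "hydrophobic residues at randomized positions",
      y = "enrichment factor"
    ) +
    ggplot2::theme_minimal()
}
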