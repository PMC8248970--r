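# ggplot2 visualisations of harmonization diagnostics.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_density labs
#'   facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot samples on the top two principal components
#'
#' Scatterplot of the PCA scores coloured by batch: batch-shifted data
#' separates into per-batch clusters, harmonized data overlaps.
#'
#' @param object A `"combat_pca"` from [pca_top2()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.combat_pca <- function(object, ...) {
  sc <- object$scores
  has_batch <- "batch" %in% names(sc)
  p <- ggplot(sc, if (has_batch) aes(.data$PC1, .data$PC2, colour = .data$batch)
              else aes(.data$PC1, .data$PC2)) +
    geom_point(alpha = 0.8) +
    labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2L]),
      colour = "batch"
    ) +
    theme_minimal()
  p
}

#' @rdname harmonization_diagnostics
#' @param object A `"combat_diagnostics"` report.
#' @export
autoplot.combat_diagnostics <- function(object, ...) {
  autoplot(object$pca) +
    labs(
      subtitle = sprintf(
        "ANOVA significant fraction: %.3f (alpha = %g)",
        object$fraction_significant, object$alpha
      )
    )
}

#' Compare per-batch feature distributions before/after harmonization
#'
#' Overlaid per-batch density curves for a handful of features, the visual
#' companion to the ANOVA/KS diagnostics.
#'
#' @param data A data frame of samples.
#' @param features Feature column names to plot (keep it small); defaults
#'   to the first 4 numeric feature columns.
#' @param batch Name of the batch column.
#' @param id Sample identifier column (ignored for plotting).
#' @return A ggplot object faceted by feature.
#' @export
plot_batch_densities <- function(data, features = NULL, batch = "batch",
                                 id = "sample_id") {
  data <- as_tibble(data)
  if (is.null(features)) {
    candidates <- setdiff(names(data), c(id, batch))
    features <- head(candidates[vapply(data[candidates], is.numeric, logical(1))], 4L)
  }
  long <- tidyr::pivot_longer(
    data[c(batch, features)],
    cols = dplyr::all_of(features),
    names_to = "feature", values_to = "value"
  )
  ggplot(long, aes(.data$value, colour = .data[[batch]])) +
    geom_density() +
    facet_wrap(~feature, scales = "free") +
    labs(x = NULL, colour = "batch") +
    theme_minimal()
}
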