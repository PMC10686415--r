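#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   geom_text geom_hline geom_vline geom_violin labs scale_fill_gradient2
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Volcano plot of a called contrast
#'
#' log2 fold-change against -log10 p, colored by call, with the
#' fold-change gate and alpha threshold drawn.
#'
#' @param results A called contrast tibble from [adjust_and_call()].
#' @param fc_cutoff,alpha Thresholds to draw; defaults 1.1 and 0.05.
#' @return A ggplot.
#' @export
plot_volcano <- function(results, fc_cutoff = 1.1, alpha = 0.05) {
  df <- dplyr::filter(results, !is.na(.data$p))
  ggplot(df, aes(x = .data$log2fc, y = -log10(.data$p),
                 colour = .data$call)) +
    geom_point(size = 0.8, alpha = 0.7) +
    geom_vline(xintercept = c(-1, 1) * log2(fc_cutoff), linetype = "dashed") +
    labs(x = "log2 fold-change (sorted / control)", y = "-log10 p",
         colour = NULL) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.profile_pca <- function(object, colour = "cell_type", ...) {
  sc <- object$scores
  if (!colour %in% names(sc)) colour <- NULL
  p <- ggplot(sc, aes(x = .data$PC1, y = .data$PC2)) +
    labs(x = sprintf("PC1 (%.1f%%)", 100 * object$var_frac[1]),
         y = sprintf("PC2 (%.1f%%)", 100 * object$var_frac[2])) +
    theme_minimal()
  if (is.null(colour)) p + geom_point() else
    p + geom_point(aes(colour = .data[[colour]]))
}

#' @exportS3Method ggplot2::autoplot
autoplot.module_trait <- function(object, ...) {
  df <- tidy.module_trait(object)
  df$stars <- dplyr::case_when(df$p < 0.001 ~ "***", df$p < 0.01 ~ "**",
                               df$p < 0.05 ~ "*", TRUE ~ "")
  ggplot(df, aes(x = .data$trait, y = .data$module, fill = .data$r)) +
    geom_tile() +
    geom_text(aes(label = .data$stars)) +
    scale_fill_gradient2(limits = c(-1, 1)) +
    labs(x = NULL, y = NULL, fill = "r") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.sphere_calibration <- function(object, ...) {
  cv <- object$curve
  cv$max_area <- pi * (cv$diameter / 2)^2
  ggplot(cv, aes(x = .data$diameter)) +
    geom_line(aes(y = .data$max_area), linetype = "dashed") +
    geom_line(aes(y = .data$mean_area), colour = "purple") +
    geom_point(aes(y = .data$mean_area)) +
    labs(x = "diameter", y = "mean cross-sectional area") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.complex_coregulation <- function(object, ...) {
  df <- tidy.complex_coregulation(object)
  ggplot(df, aes(x = .data$pair_class, y = .data$r)) +
    geom_violin() +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = NULL, y = "pairwise Pearson r") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.variance_partition <- function(object, ...) {
  df <- tidy.variance_partition(object)
  ggplot(df, aes(x = .data$covariate, y = .data$fraction)) +
    geom_violin() +
    labs(x = NULL, y = "variance fraction") +
    theme_minimal()
}
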