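# ggplot2 figures for the result objects.

#' Scree plot with the broken-stick expectation
#'
#' @param object An `fa_pca` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fa_pca
#' @export
autoplot.fa_pca <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$explained,
                                   fill = .data$retained)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$broken_stick),
                       linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(y = .data$broken_stick)) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = "PCA axis", y = "Fraction of variance",
                  fill = "Beats broken stick",
                  title = "Variance explained vs broken-stick expectation") +
    ggplot2::theme_minimal()
}

#' PCA biplot of species scores and trait loadings
#'
#' @param pca An `fa_pca` object.
#' @param axes Which two axes to plot (default `c(1, 2)`).
#' @param loading_scale Multiplier applied to the loading arrows.
#' @return A ggplot.
#' @export
plot_pca_biplot <- function(pca, axes = c(1, 2), loading_scale = NULL) {
  stopifnot(inherits(pca, "fa_pca"), length(axes) == 2)
  ax <- paste0("PC", axes)
  sc <- as_tibble(pca$species_scores[, ax, drop = FALSE], rownames = "species")
  ld <- as_tibble(pca$eigenvectors[, ax, drop = FALSE], rownames = "trait")
  if (is.null(loading_scale)) {
    loading_scale <- 0.8 * max(abs(as.matrix(sc[ax]))) /
      max(abs(as.matrix(ld[ax])))
  }
  ld[ax] <- ld[ax] * loading_scale
  ggplot2::ggplot(sc, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]])) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey85") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey85") +
    ggplot2::geom_segment(data = ld,
                          ggplot2::aes(x = 0, y = 0, xend = .data[[ax[1]]],
                                       yend = .data[[ax[2]]]),
                          colour = "firebrick",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = ld, ggplot2::aes(label = .data$trait),
                       colour = "firebrick", size = 3, vjust = -0.4) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$species), size = 3,
                       vjust = -0.6) +
    ggplot2::labs(title = "Species-mean PCA biplot") +
    ggplot2::theme_minimal()
}

#' Signal-scan overview: K and lambda per trait with the dual decision
#'
#' @param object An `fa_signal_scan` tibble (or the `signal` element of an
#'   `fa_analysis`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fa_signal_scan
#' @export
autoplot.fa_signal_scan <- function(object, ...) {
  d <- as_tibble(object)
  d <- d[!is.na(d$K), ]
  d$trait <- factor(d$trait, levels = rev(d$trait[!duplicated(d$trait)]))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$K, y = .data$trait,
                                  colour = .data$signal_present)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = "Blomberg's K", y = NULL,
                  colour = "Signal (both tests)",
                  title = "Phylogenetic signal per trait") +
    ggplot2::theme_minimal()
}

#' @method autoplot fa_analysis
#' @export
autoplot.fa_analysis <- function(object, ...) {
  autoplot.fa_signal_scan(object$signal, ...)
}
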