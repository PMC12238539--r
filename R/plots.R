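#' Plot per-replicate accuracies of a CV experiment
#'
#' Boxplots of the cross-validation and test-set accuracies (`r2_g`, `r2_p`,
#' `r2_i`) over replicate runs.
#'
#' @param object A `gp_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gp_cv <- function(object, ...) {
  dat <- tidy(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::labs(x = NULL, y = expression(r^2),
                  title = sprintf("Prediction accuracy: %s", object$trait)) +
    ggplot2::theme_minimal()
}

#' Plot a down-sampling null distribution
#'
#' Histogram of the per-replicate values with an optional observed value
#' marked; the usual companion to [coverage_zscore()].
#'
#' @param object A `downsample_dist`.
#' @param observed Optional observed value to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.downsample_dist <- function(object, observed = NULL, ...) {
  dat <- tibble(value = object$values)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "white") +
    ggplot2::labs(x = "down-sampled value", y = "replicates") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_vline(xintercept = observed, colour = "red",
                                 linetype = 2)
  }
  p
}

#' Bar plot of top variant importances
#'
#' @param cv A `gp_cv`.
#' @param top_n Number of columns shown (default 20).
#' @return A ggplot object.
#' @export
plot_importance <- function(cv, top_n = 20) {
  stopifnot(inherits(cv, "gp_cv"))
  dat <- head(arrange(cv$coefficients, dplyr::desc(.data$importance)), top_n)
  dat$column_id <- factor(dat$column_id, levels = rev(dat$column_id))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$importance, y = .data$column_id)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "|mean coefficient|", y = NULL) +
    ggplot2::theme_minimal()
}

#' Bar plot of phenotype means per allele class
#'
#' Mirrors the per-allele phenotype panels used for candidate loci: one bar
#' per code class with its mean, standard-deviation error bar, sample size
#' and compact significance letter.
#'
#' @param comp Result of [allele_phenotype_comparison()].
#' @return A ggplot object.
#' @export
plot_allele_phenotype <- function(comp) {
  dat <- comp$summary
  dat$label <- sprintf("(%d)", dat$n)
  dat$class <- factor(dat$class, levels = c(-1, 0, 1))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$letters,
                                    y = .data$mean + .data$sd),
                       vjust = -0.5, na.rm = TRUE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), y = -Inf,
                       vjust = -0.5, size = 3) +
    ggplot2::labs(x = "code class (-1 hom alt, 0 het, 1 hom ref)",
                  y = "phenotype mean ± sd") +
    ggplot2::theme_minimal()
}
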