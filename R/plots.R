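# ggplot2 visualisations of the pipeline's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot per-fold nested-CV metrics
#'
#' @param object An `ad_cv` object.
#' @param ... Unused.
#' @return A ggplot: per-fold metric distribution with the mean overlaid.
#' @export
autoplot.ad_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              c("accuracy", "sensitivity", "specificity"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "firebrick") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = paste(object$pair, collapse = " vs "),
                  subtitle = paste0("variant '", object$variant, "', ",
                                    if (object$select) "nested selection"
                                    else "all features"),
                  x = NULL, y = "outer-fold value") +
    ggplot2::theme_minimal()
}

#' Plot the wrapper accuracy path of a selection result
#'
#' @param object An `ad_selection` object.
#' @param ... Unused.
#' @return A ggplot: wrapper CV accuracy as each feature is added.
#' @export
autoplot.ad_selection <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$step, y = .data$cv_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$feature), angle = 35,
                       hjust = 0, vjust = -0.6, size = 2.6) +
    ggplot2::scale_x_continuous(breaks = td$step,
                                expand = ggplot2::expansion(mult = c(0.05, 0.25))) +
    ggplot2::labs(x = "selection step", y = "wrapper CV accuracy") +
    ggplot2::theme_minimal()
}

#' Plot class means of selected asymmetry features across NC/MCI/AD
#'
#' @param means Tibble from [class_feature_means()].
#' @param features Character vector of feature names to show (default: all
#'   rows of `means`, capped at 12).
#' @param classes Class ordering.
#' @return A ggplot of per-class means, one panel per feature.
#' @export
plot_class_means <- function(means, features = NULL,
                             classes = c("NC", "MCI", "AD")) {
  if (is.null(features)) features <- utils::head(means$name, 12)
  sub <- means[means$name %in% features, ]
  long <- tidyr::pivot_longer(sub, dplyr::all_of(classes),
                              names_to = "class", values_to = "mean")
  long$class <- factor(long$class, levels = classes)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$mean,
                                     group = .data$name)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~name, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "class mean") +
    ggplot2::theme_minimal()
}
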