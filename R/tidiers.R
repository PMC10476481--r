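# broom-style tidiers for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a nested-CV result
#'
#' @param x An `ad_cv` object.
#' @param ... Unused.
#' @return Long tibble: one row per outer fold with `repeat_`, `fold`,
#'   `accuracy`, `sensitivity`, `specificity`, chosen hyperparameters and
#'   the number of selected features.
#' @export
tidy.ad_cv <- function(x, ...) {
  f <- x$folds
  tibble::tibble(pair = paste(x$pair, collapse = "-"),
                 variant = x$variant, selection = x$select,
                 repeat_ = f$repeat_, fold = f$fold,
                 accuracy = f$accuracy, sensitivity = f$sensitivity,
                 specificity = f$specificity, C_reg = f$C_reg, u = f$u,
                 n_selected = vapply(f$selected, length, integer(1)))
}

#' One-row summary of a nested-CV result
#'
#' @param x An `ad_cv` object.
#' @param ... Unused.
#' @return One-row tibble with mean and sd of each metric.
#' @export
glance.ad_cv <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(pair = paste(x$pair, collapse = "-"),
                        variant = x$variant, selection = x$select,
                        n_folds = nrow(x$folds))
  for (i in seq_len(nrow(s))) {
    out[[s$metric[i]]] <- s$mean[i]
    out[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
  }
  out
}

#' Tidy a selection result
#'
#' @param x An `ad_selection` object.
#' @param ... Unused.
#' @return Tibble: one row per selected feature in selection order, with the
#'   wrapper CV accuracy reached at that step and the Fisher score.
#' @export
tidy.ad_selection <- function(x, ...) {
  tibble::tibble(step = seq_along(x$selected), feature = x$selected,
                 cv_accuracy = x$step_accuracy,
                 fisher_score = unname(x$scores[x$selected]))
}

#' One-row summary of a selection result
#'
#' @param x An `ad_selection` object.
#' @param ... Unused.
#' @return One-row tibble: counts and the final wrapper CV accuracy.
#' @export
glance.ad_selection <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 n_candidates = length(x$candidates),
                 n_features = length(x$scores),
                 final_cv_accuracy = if (length(x$step_accuracy))
                   x$step_accuracy[length(x$step_accuracy)] else NA_real_)
}

#' Tidy a trained SVM
#'
#' @param x An `ad_svm` model.
#' @param ... Unused.
#' @return Tibble of support-vector dual coefficients.
#' @export
tidy.ad_svm <- function(x, ...) {
  tibble::tibble(sv = seq_along(x$coefs), coef = x$coefs)
}

#' One-row summary of a trained SVM
#'
#' @param x An `ad_svm` model.
#' @param ... Unused.
#' @return One-row tibble: kernel, width/degree, C, support count, bias.
#' @export
glance.ad_svm <- function(x, ...) {
  tibble::tibble(kernel = x$kernel$kind, u = x$kernel$u, C_reg = x$C_reg,
                 n_support = length(x$coefs), q_star = x$q_star)
}
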