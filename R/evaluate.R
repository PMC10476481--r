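# Evaluation: confusion-matrix metrics and repeated nested cross-validation
# (feature selection and hyperparameter search confined to each outer
# training fold).

#' Confusion-matrix metrics for a binary evaluation
#'
#' Accuracy `(TP + TN) / n`, sensitivity `TP / (TP + FN)` (recall of the
#' patient class) and specificity `TN / (TN + FP)` (recall of the control
#' class). The decomposition identity
#' `accuracy = (sensitivity * P + specificity * N) / (P + N)` is asserted on
#' every call.
#'
#' @param y_true,y_pred Label vectors of equal length (>= 1).
#' @param positive The patient-class label (e.g. `"AD"`, `"MCI"`, or `1`).
#' @return One-row tibble: `TP`, `TN`, `FP`, `FN`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(y_true, y_pred, positive) {
  abort_if(length(y_true) != length(y_pred) || length(y_true) < 1,
           "y_true and y_pred must have equal positive length")
  pos <- y_true == positive
  abort_if(!any(pos), "no positive-class samples: sensitivity undefined")
  abort_if(all(pos), "no negative-class samples: specificity undefined")
  hit <- y_pred == y_true
  TP <- sum(pos & hit); FN <- sum(pos & !hit)
  TN <- sum(!pos & hit); FP <- sum(!pos & !hit)
  acc <- (TP + TN) / length(y_true)
  sens <- TP / (TP + FN)
  spec <- TN / (TN + FP)
  P <- sum(pos); N <- sum(!pos)
  stopifnot(abs(acc - (sens * P + spec * N) / (P + N)) < 1e-12)
  tibble::tibble(TP = TP, TN = TN, FP = FP, FN = FN, accuracy = acc,
                 sensitivity = sens, specificity = spec)
}

#' Repeated nested cross-validation of the asymmetry classifier
#'
#' For each outer fold: (optionally) run sequential forward selection on the
#' training fold only, grid-search the SVM hyperparameters on the training
#' fold only, train on the training fold, and evaluate on the held-out fold.
#' Standardisation parameters are fit on the training fold and applied to the
#' test fold. Aggregates mean and sd of the metrics over folds x repeats.
#'
#' @param features Cohort feature tibble from [extract_features()] (all
#'   classes; the `pair` filter is applied here), or an already-built variant
#'   tibble when `variant = NULL`.
#' @param pair Length-2 character: `c(control, patient)`, e.g.
#'   `c("NC", "AD")`; the second entry is the positive class.
#' @param variant Feature-set variant passed to [build_variant()], or `NULL`
#'   if `features` is already the desired matrix.
#' @param select Run nested feature selection (`TRUE`, the "after selection"
#'   arm) or use all features (`FALSE`, the "before selection" arm).
#' @param cfg A [selection_config()] for the nested selection stage.
#' @param kind Kernel kind for the final classifier.
#' @param C_grid,u_grid Hyperparameter grids for [grid_search()].
#' @param outer_folds Outer CV folds (default 5).
#' @param repeats Repetitions with reshuffled folds (default 1).
#' @param seed Integer master seed.
#' @return An `ad_cv` object: `folds` (per-fold tibble incl. selected
#'   features), `summary` (mean/sd per metric), and the settings.
#' @export
nested_cross_validate <- function(features, pair = c("NC", "AD"),
                                  variant = "whole", select = TRUE,
                                  cfg = selection_config(),
                                  kind = "rbf",
                                  C_grid = c(0.1, 1, 10, 100),
                                  u_grid = NULL,
                                  outer_folds = 5, repeats = 1, seed = 1) {
  if (!is.null(variant)) features <- build_variant(features, variant)
  tbl <- features[features$class %in% pair, , drop = FALSE]
  abort_if(min(table(tbl$class)) < outer_folds,
           "need >= outer_folds subjects per class")
  cols <- feature_columns(tbl)
  X <- as.matrix(tbl[cols])
  y <- tbl$class
  yy <- ifelse(y == pair[2], 1, -1)  # patient class is positive
  rows <- list()
  for (rep in seq_len(repeats)) {
    fold_id <- stratified_folds(yy, outer_folds,
                                derive_seed(seed, "outer", rep))
    for (f in seq_len(outer_folds)) {
      tr <- fold_id != f
      sel_seed <- derive_seed(seed, "fold", rep, f)
      if (select) {
        sel_cfg <- cfg
        sel_cfg$seed <- sel_seed
        sel <- sequential_forward_select(X[tr, , drop = FALSE], y = y[tr],
                                         cfg = sel_cfg)
        use <- sel$selected
      } else {
        use <- cols
      }
      st <- standardize_fit(X[tr, use, drop = FALSE])
      Xtr <- st$X
      Xte <- standardize_apply(X[!tr, use, drop = FALSE], st)
      gs <- grid_search(Xtr, yy[tr], kind = kind, C_grid = C_grid,
                        u_grid = u_grid, folds = cfg$inner_folds,
                        seed = sel_seed)
      model <- train_svm(Xtr, yy[tr], kernel_spec(kind, u = gs$u), gs$C_reg)
      pred <- predict(model, Xte)
      met <- compute_metrics(yy[!tr], pred, positive = 1)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(repeat_ = rep, fold = f, n_test = sum(!tr),
                       C_reg = gs$C_reg, u = gs$u,
                       selected = list(use)),
        met)
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  metrics <- c("accuracy", "sensitivity", "specificity")
  summary <- tibble::tibble(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds_tbl[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(folds_tbl[[m]]), numeric(1)))
  structure(list(folds = folds_tbl, summary = summary, pair = pair,
                 variant = if (is.null(variant))
                   attr(features, "variant") %||% "custom" else variant,
                 select = select, outer_folds = outer_folds,
                 repeats = repeats, seed = seed),
            class = "ad_cv")
}

#' @export
print.ad_cv <- function(x, ...) {
  cat("<ad_cv> ", paste(x$pair, collapse = " vs "), ", variant '",
      x$variant, "', ", if (x$select) "with" else "without",
      " nested selection\n", sep = "")
  s <- x$summary
  cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric, s$mean, s$sd), sep = "")
  invisible(x)
}

#' Mean accuracy of an `ad_cv` result
#'
#' @param cv An `ad_cv` object.
#' @return Mean outer-fold accuracy.
#' @export
cv_mean_accuracy <- function(cv) {
  cv$summary$mean[cv$summary$metric == "accuracy"]
}
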