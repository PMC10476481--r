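# Feature selection: Fisher-score filter, SVM-wrapper sequential forward
# selection, monotonicity flags across the NC/MCI/AD continuum, and
# per-structure selected-feature counts.

#' Fisher score of each feature for a binary class split
#'
#' `score = sum_c n_c (mu_c - mu)^2 / sum_c n_c sigma_c^2` with population
#' variances. A feature constant within both classes but differing between
#' them separates perfectly and scores `+Inf` (an explicit sentinel ranked
#' above all finite scores); a feature constant overall scores 0.
#'
#' @param X Numeric matrix or data frame of features (rows = subjects).
#' @param y Binary class labels (any two-level vector/factor).
#' @return Named numeric vector of scores (may contain `Inf`).
#' @export
fisher_score <- function(X, y) {
  X <- as.matrix(X)
  cls <- unique(y)
  abort_if(length(cls) != 2, "fisher_score needs exactly two classes")
  abort_if(min(table(y)) < 2, "need >= 2 subjects per class")
  mu <- colMeans(X)
  num <- 0; den <- 0
  for (c in cls) {
    Xc <- X[y == c, , drop = FALSE]
    nc <- nrow(Xc)
    muc <- colMeans(Xc)
    varc <- colMeans(sweep(Xc, 2, muc)^2)
    num <- num + nc * (muc - mu)^2
    den <- den + nc * varc
  }
  score <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  stats::setNames(score, colnames(X))
}

#' Selection configuration
#'
#' @param max_k Maximum number of features to select (default 15).
#' @param delta_min Minimum CV-accuracy improvement to keep adding features
#'   (default 0.002).
#' @param inner_folds Folds of the wrapper's inner CV (default 5).
#' @param n_filter Number of top-Fisher candidates passed to the wrapper
#'   (default 40).
#' @param kernel_kind,C_reg,u Wrapper SVM settings; `u = NULL` uses the
#'   median-pairwise-distance heuristic on the standardised candidates.
#' @param seed Integer seed for the wrapper's fold assignment.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(max_k = 15, delta_min = 0.002, inner_folds = 5,
                             n_filter = 40, kernel_kind = "rbf", C_reg = 1,
                             u = NULL, seed = 1) {
  abort_if(max_k < 1, "max_k must be >= 1")
  abort_if(inner_folds < 2, "inner_folds must be >= 2")
  structure(list(max_k = as.integer(max_k), delta_min = delta_min,
                 inner_folds = as.integer(inner_folds),
                 n_filter = as.integer(n_filter),
                 kernel_kind = kernel_kind, C_reg = C_reg, u = u,
                 seed = seed),
            class = "selection_config")
}

# Rank candidate names by (score desc, name asc); Inf sentinels first.
rank_by_score <- function(scores) {
  names(scores)[order(-scores, names(scores), method = "radix")]
}

#' Sequential forward feature selection with an SVM wrapper
#'
#' Filter stage: the `n_filter` candidates with the highest Fisher scores.
#' Wrapper stage: greedily add the candidate that maximises stratified
#' inner-fold CV accuracy of an SVM on the standardised features; stop when
#' the best improvement falls below `delta_min` or `max_k` is reached. Ties
#' break by higher Fisher score, then lexicographic name, so the result is
#' fully deterministic given the seed.
#'
#' @param features A feature tibble (`subject_id`, `class`, feature columns)
#'   restricted to two classes, or a numeric matrix plus `y`.
#' @param y Binary labels; omit when `features` carries a `class` column.
#' @param cfg A [selection_config()].
#' @return An `ad_selection` object: `selected` (ordered names),
#'   `step_accuracy`, `scores` (Fisher, all features), `candidates`, `cfg`.
#' @export
sequential_forward_select <- function(features, y = NULL,
                                      cfg = selection_config()) {
  if (is.data.frame(features)) {
    y <- y %||% features$class
    X <- as.matrix(features[feature_columns(features)])
  } else {
    X <- as.matrix(features)
  }
  abort_if(is.null(y), "class labels are required")
  abort_if(length(unique(y)) != 2, "selection needs exactly two classes")
  abort_if(min(table(y)) < cfg$inner_folds,
           "need >= inner_folds subjects per class")
  yy <- ifelse(y == sort(unique(as.character(y)))[1], -1, 1)
  scores <- fisher_score(X, y)
  candidates <- utils::head(rank_by_score(scores),
                            min(cfg$n_filter, ncol(X)))
  Xs <- standardize_fit(X[, candidates, drop = FALSE])$X
  u <- cfg$u %||% median_pairwise_distance(Xs)
  kernel <- kernel_spec(cfg$kernel_kind, u = u)
  folds <- stratified_folds(yy, cfg$inner_folds, derive_seed(cfg$seed, "sfs"))
  selected <- character(0)
  step_acc <- numeric(0)
  best_acc <- 0
  repeat {
    if (length(selected) >= cfg$max_k) break
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    accs <- vapply(remaining, function(f) {
      cv_accuracy(Xs[, c(selected, f), drop = FALSE], yy, folds, kernel,
                  cfg$C_reg)
    }, numeric(1))
    # ties: higher fisher score, then name
    ord <- order(-accs, -rank(scores[remaining], ties.method = "first"),
                 remaining, method = "radix")
    best <- remaining[ord[1]]
    if (accs[best] - best_acc < cfg$delta_min && length(selected) > 0) break
    if (length(selected) == 0 || accs[best] - best_acc >= cfg$delta_min) {
      selected <- c(selected, best)
      step_acc <- c(step_acc, unname(accs[best]))
      best_acc <- unname(accs[best])
    } else break
  }
  structure(list(selected = selected, step_accuracy = step_acc,
                 scores = scores, candidates = candidates, cfg = cfg,
                 u = u),
            class = "ad_selection")
}

#' @export
print.ad_selection <- function(x, ...) {
  cat("<ad_selection> ", length(x$selected), " features selected (of ",
      length(x$scores), " candidates filtered to ", length(x$candidates),
      ")\n", sep = "")
  if (length(x$selected)) {
    cat(paste0("  ", seq_along(x$selected), ". ", x$selected,
               "  (cv acc ", sprintf("%.3f", x$step_accuracy), ")\n"),
        sep = "")
  }
  invisible(x)
}

#' Per-class feature means across the NC/MCI/AD continuum
#'
#' @param features Cohort feature tibble with a 3-class `class` column.
#' @param classes Class ordering (default `c("NC", "MCI", "AD")`).
#' @return Tibble: `name`, one mean column per class.
#' @export
class_feature_means <- function(features, classes = c("NC", "MCI", "AD")) {
  abort_if(!all(classes %in% features$class),
           "all three classes must be present")
  cols <- feature_columns(features)
  out <- tibble::tibble(name = cols)
  for (cl in classes) {
    out[[cl]] <- unname(colMeans(as.matrix(features[features$class == cl,
                                                    cols])))
  }
  out
}

#' Monotonicity flags over an ordered class triple
#'
#' A feature is flagged monotone iff its class means are strictly increasing
#' or strictly decreasing across the ordered triple (ties never count).
#'
#' @param means Tibble from [class_feature_means()] (columns `name` and the
#'   three ordered class means), or a numeric length-3 vector for a single
#'   feature.
#' @param classes Class ordering used to read the mean columns.
#' @return Logical vector, named by feature.
#' @export
monotone_flags <- function(means, classes = c("NC", "MCI", "AD")) {
  if (is.numeric(means) && is.null(dim(means))) {
    abort_if(length(means) != 3 || !all(is.finite(means)),
             "need three finite means")
    return((means[1] < means[2] & means[2] < means[3]) ||
             (means[1] > means[2] & means[2] > means[3]))
  }
  m <- as.matrix(means[classes])
  flags <- (m[, 1] < m[, 2] & m[, 2] < m[, 3]) |
    (m[, 1] > m[, 2] & m[, 2] > m[, 3])
  stats::setNames(as.logical(flags), means$name)
}

#' Selected/monotone feature counts per structure and hemisphere
#'
#' @param selection An `ad_selection`, or a character vector of selected
#'   feature names.
#' @param monotone Optional named logical vector of monotone flags (e.g. from
#'   [monotone_flags()]).
#' @return Tibble: `structure`, `hemisphere` (left/right/diff/ratio),
#'   `n_selected`, `n_monotone`; counts partition the selected set.
#' @export
count_by_structure <- function(selection, monotone = NULL) {
  sel <- if (inherits(selection, "ad_selection")) selection$selected
         else as.character(selection)
  grid <- tidyr::expand_grid(structure = STRUCTURES,
                             hemisphere = c(HEMISPHERES, "diff", "ratio"))
  if (length(sel) == 0) {
    grid$n_selected <- 0L
    grid$n_monotone <- 0L
    return(grid)
  }
  meta <- feature_metadata(sel)
  abort_if(!all(meta$structure %in% STRUCTURES) ||
             !all(meta$hemisphere %in% c(HEMISPHERES, "diff", "ratio")),
           "selected feature names carry unknown structure/hemisphere tags")
  meta$monotone <- if (is.null(monotone)) FALSE else {
    abort_if(!all(sel %in% names(monotone)),
             "monotone flags missing for some selected features")
    unname(monotone[sel])
  }
  counts <- dplyr::summarise(
    dplyr::group_by(meta, structure, hemisphere),
    n_selected = dplyr::n(), n_monotone = sum(monotone), .groups = "drop")
  out <- dplyr::left_join(grid, counts, by = c("structure", "hemisphere"))
  out$n_selected[is.na(out$n_selected)] <- 0L
  out$n_monotone[is.na(out$n_monotone)] <- 0L
  out
}

# Standardise columns to zero mean / unit sd; constant columns keep sd 1.
standardize_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(X = sweep(sweep(X, 2, mu), 2, sd, "/"), mu = mu, sd = sd)
}

standardize_apply <- function(X, fit) {
  sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")
}
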