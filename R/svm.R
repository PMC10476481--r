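# Kernel SVM: kernel evaluation, training (libsvm dual via e1071, with the
# decision function reconstructed from stored support vectors, dual
# coefficients and bias), and hyperparameter grid search.

#' Kernel specification
#'
#' Three kernels: polynomial `(x'y + 1)^u` (u a positive integer degree),
#' radial basis `exp(-|x - y|^2 / u^2)` (u the kernel width), and sigmoid
#' `tanh(C_sig x'y + C_sig)`.
#'
#' @param kind `"rbf"` (default), `"polynomial"` or `"sigmoid"`.
#' @param u Kernel width (rbf) or degree (polynomial); must be positive, and
#'   a positive integer for the polynomial kernel.
#' @param C_sig Sigmoid constant.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "polynomial", "sigmoid"), u = 1,
                        C_sig = 1) {
  kind <- match.arg(kind)
  abort_if(kind != "sigmoid" && u <= 0, "u must be positive")
  abort_if(kind == "polynomial" && u != round(u),
           "polynomial degree u must be a positive integer")
  structure(list(kind = kind, u = u, C_sig = C_sig), class = "kernel_spec")
}

#' Evaluate a kernel between two vectors (or matrix rows and a vector)
#'
#' @param spec A [kernel_spec()].
#' @param x Numeric vector, or matrix whose rows are vectors.
#' @param x_o Numeric vector of the same dimension.
#' @return Numeric kernel value(s).
#' @export
kernel_eval <- function(spec, x, x_o) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  abort_if(ncol(x) != length(x_o), "dimension mismatch")
  switch(spec$kind,
    polynomial = drop((x %*% x_o + 1)^spec$u),
    rbf = drop(exp(-rowSums(sweep(x, 2, x_o)^2) / spec$u^2)),
    sigmoid = drop(tanh(spec$C_sig * (x %*% x_o) + spec$C_sig))
  )
}

# Kernel matrix between row sets of A and B.
kernel_matrix <- function(spec, A, B) {
  switch(spec$kind,
    polynomial = (A %*% t(B) + 1)^spec$u,
    rbf = {
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
      exp(-pmax(d2, 0) / spec$u^2)
    },
    sigmoid = tanh(spec$C_sig * (A %*% t(B)) + spec$C_sig)
  )
}

#' Train a soft-margin kernel SVM
#'
#' Solves the soft-margin dual with libsvm (via e1071) and stores the parts
#' of the decision function — support vectors `x_o`, dual coefficients
#' `beta_o y_o`, and bias `q*` — so that
#' `f(x) = sign(sum_o beta_o y_o K(x_o, x) + q*)` is recoverable exactly.
#'
#' @param X Numeric matrix (rows = samples) or data frame of features.
#' @param y Labels in `{-1, +1}` (numeric, or a factor with those levels).
#' @param kernel A [kernel_spec()].
#' @param C_reg Soft-margin regularisation constant (> 0).
#' @return An `ad_svm` model: `kernel`, `C_reg`, `SV`, `coefs`
#'   (= `beta_o y_o`), `q_star`, `features`.
#' @export
train_svm <- function(X, y, kernel = kernel_spec(), C_reg = 1) {
  X <- as.matrix(X)
  abort_if(!all(is.finite(X)), "non-finite feature values")
  y <- as.numeric(as.character(y))
  abort_if(!all(y %in% c(-1, 1)), "labels must be -1 / +1")
  abort_if(length(unique(y)) < 2, "both classes must be present")
  abort_if(C_reg <= 0, "C_reg must be positive")
  yf <- factor(y, levels = c(1, -1))  # first level <=> positive decision
  args <- switch(kernel$kind,
    rbf = list(kernel = "radial", gamma = 1 / kernel$u^2),
    polynomial = list(kernel = "polynomial", degree = kernel$u, gamma = 1,
                      coef0 = 1),
    sigmoid = list(kernel = "sigmoid", gamma = kernel$C_sig,
                   coef0 = kernel$C_sig))
  fit <- do.call(e1071::svm,
                 c(list(x = X, y = yf, cost = C_reg, scale = FALSE), args))
  coefs <- drop(fit$coefs)
  q_star <- -fit$rho
  # libsvm orients decision values toward the class appearing first in the
  # training data; re-sign so positive decision always means +1
  dec <- drop(kernel_matrix(kernel, X, unname(fit$SV)) %*% coefs) + q_star
  pred <- as.numeric(as.character(predict(fit, X)))
  agree <- mean(sign(dec)[pred != 0] == pred[pred != 0], na.rm = TRUE)
  if (!is.nan(agree) && agree < 0.5) {
    coefs <- -coefs
    q_star <- -q_star
  }
  structure(list(kernel = kernel, C_reg = C_reg,
                 SV = unname(fit$SV), coefs = coefs,
                 q_star = q_star,
                 features = colnames(X)),
            class = "ad_svm")
}

#' Decision values of a trained SVM
#'
#' Recomputes `sum_o beta_o y_o K(x_o, x) + q*` from the stored model parts.
#'
#' @param model An `ad_svm` from [train_svm()].
#' @param X Numeric matrix of query rows.
#' @return Numeric vector of decision values (positive => class +1).
#' @export
decision_values <- function(model, X) {
  X <- as.matrix(X)
  drop(kernel_matrix(model$kernel, X, model$SV) %*% model$coefs) +
    model$q_star
}

#' Predict class labels with a trained SVM
#'
#' @param object An `ad_svm` model.
#' @param newdata Numeric matrix or data frame of query rows.
#' @param ... Unused.
#' @return Numeric vector of labels in `{-1, +1}` (ties at 0 go to +1).
#' @export
predict.ad_svm <- function(object, newdata, ...) {
  ifelse(decision_values(object, as.matrix(newdata)) >= 0, 1, -1)
}

#' @export
print.ad_svm <- function(x, ...) {
  cat("<ad_svm> ", x$kernel$kind, " kernel (u = ", signif(x$kernel$u, 4),
      "), C = ", x$C_reg, ", ", nrow(x$SV), " support vectors\n", sep = "")
  invisible(x)
}

# Deterministic stratified fold assignment: within each class, indices are
# shuffled by the seed and dealt round-robin.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Pooled k-fold CV accuracy of an SVM on (X, y).
cv_accuracy <- function(X, y, folds, kernel, C_reg) {
  correct <- 0
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) next
    m <- train_svm(X[tr, , drop = FALSE], y[tr], kernel, C_reg)
    correct <- correct + sum(predict(m, X[!tr, , drop = FALSE]) == y[!tr])
  }
  correct / length(y)
}

#' Hyperparameter grid search by stratified cross-validation
#'
#' Maximises pooled k-fold CV accuracy over a `(C_reg, u)` grid; ties break
#' toward smaller `C_reg`, then smaller `u`, so the winner is independent of
#' grid ordering.
#'
#' @param X Numeric feature matrix.
#' @param y Labels in `{-1, +1}`.
#' @param kind Kernel kind (see [kernel_spec()]).
#' @param C_grid Candidate regularisation constants.
#' @param u_grid Candidate kernel widths/degrees; default scales
#'   `c(0.25, 0.5, 1, 2, 4)` by the median pairwise distance of `X` (rbf).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @return List: `C_reg`, `u`, `accuracy`, and the full `grid` tibble.
#' @export
grid_search <- function(X, y, kind = "rbf",
                        C_grid = c(0.1, 1, 10, 100),
                        u_grid = NULL, folds = 5, seed = 1) {
  X <- as.matrix(X)
  abort_if(length(C_grid) == 0, "C_grid must be nonempty")
  if (is.null(u_grid)) {
    u_grid <- c(0.25, 0.5, 1, 2, 4) * median_pairwise_distance(X)
  }
  abort_if(length(u_grid) == 0, "u_grid must be nonempty")
  fold_id <- stratified_folds(y, folds, derive_seed(seed, "grid"))
  grid <- tidyr::expand_grid(C_reg = sort(unique(C_grid)),
                             u = sort(unique(u_grid)))
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    cv_accuracy(X, y, fold_id, kernel_spec(kind, u = grid$u[i]),
                grid$C_reg[i])
  }, numeric(1))
  best <- which.max(grid$accuracy)  # ties: first of the sorted grid
  list(C_reg = grid$C_reg[best], u = grid$u[best],
       accuracy = grid$accuracy[best], grid = grid)
}

# Median pairwise Euclidean distance (deterministic; 1 if degenerate).
median_pairwise_distance <- function(X) {
  n <- nrow(X)
  if (n > 200) X <- X[round(seq(1, n, length.out = 200)), , drop = FALSE]
  d <- stats::median(stats::dist(X))
  if (!is.finite(d) || d <= 0) 1 else d
}
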