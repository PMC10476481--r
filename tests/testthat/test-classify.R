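test_that("kernel evaluations match closed forms and are symmetric", {
  rbf <- kernel_spec("rbf", u = 2)
  x <- c(1, 1); z <- c(1, 1 + 2)  # |x - z| = u
  expect_equal(kernel_eval(rbf, x, x), 1)
  expect_equal(kernel_eval(rbf, x, z), exp(-1))
  poly <- kernel_spec("polynomial", u = 2)
  expect_equal(kernel_eval(poly, c(1, 1), c(1, 1)), 9)
  sig <- kernel_spec("sigmoid", C_sig = 0.5)
  expect_equal(kernel_eval(sig, c(1, 0), c(0, 1)), tanh(0.5))
  # symmetry in the arguments
  withr::with_seed(1, {
    for (spec in list(rbf, poly, sig)) {
      a <- rnorm(4); b <- rnorm(4)
      expect_equal(kernel_eval(spec, a, b), kernel_eval(spec, b, a))
    }
  })
  expect_true(all(kernel_eval(rbf, matrix(rnorm(20), 5), rnorm(4)) <= 1))
  expect_error(kernel_eval(rbf, c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("the stored model parts reproduce the solver's decision function", {
  withr::with_seed(2, {
    X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 3), 20, 2))
  })
  y <- rep(c(-1, 1), each = 20)
  for (kind in c("rbf", "polynomial", "sigmoid")) {
    spec <- kernel_spec(kind, u = if (kind == "polynomial") 2 else 1.5)
    m <- train_svm(X, y, spec, C_reg = 1)
    fit <- e1071::svm(X, factor(y, levels = c(1, -1)),
                      kernel = switch(kind, rbf = "radial", kind),
                      gamma = switch(kind, rbf = 1 / 1.5^2,
                                     polynomial = 1, sigmoid = 1),
                      degree = 2, coef0 = 1, cost = 1, scale = FALSE)
    dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
    # libsvm orients its decision values toward the first-appearing class
    # (-1 here); the stored parts are canonically oriented toward +1
    expect_lt(max(abs(decision_values(m, X) - (-drop(dv)))), 1e-8)
  }
})

test_that("predictions equal the sign of manually recomputed decision values", {
  withr::with_seed(3, {
    X <- rbind(matrix(rnorm(30, 0), 15, 2), matrix(rnorm(30, 2.5), 15, 2))
    Q <- matrix(rnorm(40), 20, 2)
  })
  y <- rep(c(-1, 1), each = 15)
  m <- train_svm(X, y, kernel_spec("rbf", u = 1.5), C_reg = 2)
  # manual sum over support vectors via kernel_eval (independent of the
  # vectorised kernel_matrix path)
  manual <- vapply(seq_len(nrow(Q)), function(i) {
    sum(vapply(seq_len(nrow(m$SV)), function(o) {
      m$coefs[o] * kernel_eval(m$kernel, Q[i, ], m$SV[o, ])
    }, numeric(1))) + m$q_star
  }, numeric(1))
  expect_equal(predict(m, Q), ifelse(manual >= 0, 1, -1))
  expect_lt(max(abs(decision_values(m, Q) - manual)), 1e-8)
})

test_that("a separable problem is fit perfectly and duplication is invariant", {
  withr::with_seed(4, {
    X <- rbind(matrix(rnorm(40, 0, 0.5), 20, 2),
               matrix(rnorm(40, 5, 0.5), 20, 2))
    grid <- matrix(rnorm(30, 2.5), 15, 2)
  })
  y <- rep(c(-1, 1), each = 20)
  # separability double-checked by the margin between class hulls
  gap <- min(as.matrix(dist(X))[1:20, 21:40])
  expect_gt(gap, 0)
  m <- train_svm(X, y, kernel_spec("rbf", u = 3), C_reg = 10)
  expect_equal(predict(m, X), y)

  m2 <- train_svm(rbind(X, X), c(y, y), kernel_spec("rbf", u = 3), C_reg = 10)
  expect_equal(predict(m, grid), predict(m2, grid))
  expect_error(train_svm(X, rep(1, 40), kernel_spec()), "classes")
})

test_that("grid search maximises CV accuracy deterministically", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(60, 0, 0.4), 30, 2),
               matrix(rnorm(60, 3, 0.4), 30, 2))
  })
  y <- rep(c(-1, 1), each = 30)
  single <- grid_search(X, y, C_grid = 1, u_grid = 2, seed = 1)
  expect_equal(single$C_reg, 1)
  expect_equal(single$u, 2)

  gs <- grid_search(X, y, C_grid = c(0.1, 1, 10), u_grid = c(0.5, 1, 2, 4),
                    seed = 1)
  expect_equal(gs$accuracy, 1)
  perm <- grid_search(X, y, C_grid = c(10, 0.1, 1), u_grid = c(4, 2, 1, 0.5),
                      seed = 1)
  expect_equal(perm[c("C_reg", "u")], gs[c("C_reg", "u")])
})

test_that("confusion metrics match their definitions and identity", {
  y_true <- c(rep("AD", 50), rep("NC", 50))
  y_pred <- c(rep("AD", 45), rep("NC", 5), rep("NC", 48), rep("AD", 2))
  m <- compute_metrics(y_true, y_pred, positive = "AD")
  expect_equal(m$TP, 45); expect_equal(m$FN, 5)
  expect_equal(m$TN, 48); expect_equal(m$FP, 2)
  expect_equal(m$accuracy, 0.93)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.96)

  perfect <- compute_metrics(c(1, 1, -1), c(1, 1, -1), positive = 1)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
               c(1, 1, 1))
  expect_error(compute_metrics(c(1, 1), c(1, 1), positive = 1), "negative")
  expect_error(compute_metrics(c(-1, -1), c(1, 1), positive = 1), "positive")
})

test_that("nested CV recovers a separable signal and is seed-deterministic", {
  tbl <- toy_features(n_per_class = 20, n_noise = 10, shift = 5, seed = 6)
  cv <- nested_cross_validate(tbl, pair = c("NC", "AD"), variant = NULL,
                              select = TRUE,
                              cfg = selection_config(max_k = 2,
                                                     inner_folds = 3,
                                                     n_filter = 5),
                              outer_folds = 4, seed = 11)
  expect_gte(cv_mean_accuracy(cv), 0.95)
  cv2 <- nested_cross_validate(tbl, pair = c("NC", "AD"), variant = NULL,
                               select = TRUE,
                               cfg = selection_config(max_k = 2,
                                                      inner_folds = 3,
                                                      n_filter = 5),
                               outer_folds = 4, seed = 11)
  expect_identical(cv$summary, cv2$summary)
  expect_identical(cv$folds$selected, cv2$folds$selected)
  # accuracy decomposition identity per fold
  f <- cv$folds
  expect_equal(f$accuracy,
               (f$sensitivity * (f$TP + f$FN) + f$specificity * (f$TN + f$FP)) /
                 f$n_test)
})

test_that("nested selection beats no selection when most features are noise", {
  tbl <- toy_features(n_per_class = 15, n_noise = 60, shift = 2.5, seed = 8)
  base <- nested_cross_validate(tbl, pair = c("NC", "AD"), variant = NULL,
                                select = FALSE, outer_folds = 3, seed = 2)
  cfg <- selection_config(max_k = 3, inner_folds = 3, n_filter = 10)
  sel <- nested_cross_validate(tbl, pair = c("NC", "AD"), variant = NULL,
                               select = TRUE, cfg = cfg, outer_folds = 3,
                               seed = 2)
  expect_gte(cv_mean_accuracy(sel), cv_mean_accuracy(base))
})

test_that("tidiers expose per-fold and summary views", {
  tbl <- toy_features(n_per_class = 10, n_noise = 5, seed = 9)
  cv <- nested_cross_validate(tbl, pair = c("NC", "AD"), variant = NULL,
                              select = FALSE, outer_folds = 3, seed = 3)
  td <- tidy(cv)
  expect_equal(nrow(td), 3)
  expect_true(all(c("accuracy", "sensitivity", "specificity") %in% names(td)))
  g <- glance(cv)
  expect_equal(nrow(g), 1)
  expect_equal(g$accuracy, cv_mean_accuracy(cv))

  sel <- sequential_forward_select(tbl, cfg = selection_config(
    max_k = 2, inner_folds = 2, n_filter = 4))
  expect_equal(nrow(tidy(sel)), length(sel$selected))
  expect_equal(glance(sel)$n_candidates, 4)

  m <- train_svm(matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4), c(-1, -1, 1, 1),
                 kernel_spec("rbf", u = 1), 1)
  expect_equal(glance(m)$n_support, length(m$coefs))
})
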