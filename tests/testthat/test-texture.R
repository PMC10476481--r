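test_that("quantization bins in-mask values uniformly and handles degeneracy", {
  v <- voxel_grid(array(c(0, 0.5, 1.0, 9, 9, 9), c(6, 1, 1)))
  m <- binary_mask(array(c(rep(TRUE, 3), rep(FALSE, 3)), c(6, 1, 1)))
  q <- quantize(v, m, Z = 2)
  expect_equal(q$data[1:3, 1, 1], c(0L, 1L, 1L))
  expect_equal(q$data[4:6, 1, 1], rep(-1L, 3))

  const <- quantize(voxel_grid(array(5, c(4, 4, 4))),
                    binary_mask(array(TRUE, c(4, 4, 4))), Z = 8)
  expect_true(all(const$data == 0L))

  # min-max invariance: scaling the image leaves levels unchanged
  v2 <- voxel_grid(array(runif(64), c(4, 4, 4)))
  mk <- binary_mask(array(TRUE, c(4, 4, 4)))
  expect_identical(quantize(v2, mk, 8)$data,
                   quantize(voxel_grid(2 * v2$data), mk, 8)$data)
  expect_error(quantize(v2, mk, Z = 1), "Z")
})

test_that("GLCM matches the hand-enumerated 1D strip", {
  q <- strip_quantized(c(0, 0, 1, 1), Z = 2)
  spec <- glcm_spec(Z = 2, d = 1, directions = matrix(c(1L, 0L, 0L), 1),
                    symmetric = TRUE)
  g <- glcm(q, spec)
  expect_equal(g$P, matrix(c(2, 1, 1, 2) / 6, 2, 2))
  expect_equal(g$pair_count, 6)

  const <- glcm(strip_quantized(c(0, 0, 0), Z = 2), spec)
  expect_equal(const$P[1, 1], 1)
  expect_equal(sum(const$P), 1)
  expect_error(glcm(strip_quantized(0, Z = 2), spec), "pairs")
})

test_that("GLCM agrees with the brute-force pair-enumeration oracle", {
  for (s in 1:50) {
    q <- random_quantized(n = 6, Z = 4, seed = s)
    qv <- as_quantized(q, 4)
    sym <- s %% 2 == 0
    spec <- glcm_spec(Z = 4, d = 1, symmetric = sym)
    got <- tryCatch(glcm(qv, spec)$P, error = function(e) NULL)
    if (is.null(got)) next
    expect_lt(max(abs(got - glcm_oracle(q, 4, symmetric = sym))), 1e-12)
  }
})

test_that("GLCM statistics match closed forms and conventions", {
  feat <- function(P) glcm_features(structure(
    list(P = P, spec = glcm_spec(Z = nrow(P)), pair_count = 1),
    class = "glcm"))

  f1 <- feat(matrix(1, 1, 1))
  expect_equal(unname(f1), c(1, 0, 1, 0, 0))  # degenerate correlation -> 0

  f2 <- feat(matrix(0.25, 2, 2))
  expect_equal(f2[["energy"]], 0.25)
  expect_equal(f2[["entropy"]], 2)

  f3 <- feat(diag(c(0.5, 0.5)))
  expect_equal(f3[["contrast"]], 0)
  expect_equal(f3[["correlation"]], 1)
})

test_that("GLCM invariants hold on random instances", {
  for (s in 1:20) {
    q <- random_quantized(n = 6, Z = 4, seed = 100 + s)
    qv <- as_quantized(q, 4)
    g <- glcm(qv, glcm_spec(Z = 4, symmetric = TRUE))
    expect_lt(abs(sum(g$P) - 1), 1e-12)
    expect_true(isTRUE(all.equal(g$P, t(g$P))))
    f <- glcm_features(g)
    expect_true(f[["energy"]] > 0 && f[["energy"]] <= 1)
    expect_true(f[["idm"]] > 0 && f[["idm"]] <= 1)
    expect_true(f[["entropy"]] >= 0 && f[["entropy"]] <= 2 * log2(4))
    expect_true(abs(f[["correlation"]]) <= 1 + 1e-12)
    # gray-level reversal preserves energy, contrast, idm, entropy
    qr <- q
    qr[qr >= 0] <- 3L - qr[qr >= 0]
    fr <- glcm_features(glcm(as_quantized(qr, 4), glcm_spec(Z = 4)))
    expect_equal(f[c("energy", "contrast", "idm", "entropy")],
                 fr[c("energy", "contrast", "idm", "entropy")])
  }
})

test_that("run-length matrix counts maximal runs on strips", {
  r1 <- rlm(strip_quantized(c(0, 0, 1, 1, 1), Z = 2),
            directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(r1$n_runs, 2)
  expect_equal(r1$R[1, 2], 1)  # level 0, length 2
  expect_equal(r1$R[2, 3], 1)  # level 1, length 3

  r2 <- rlm(strip_quantized(c(0, 1, 0, 1), Z = 2),
            directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(r2$n_runs, 4)
  expect_true(all(which(r2$R > 0, arr.ind = TRUE)[, "col"] == 1))

  # a mask gap terminates the run
  r3 <- rlm(strip_quantized(c(0, 0, -1, 0), Z = 2),
            directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(r3$n_runs, 2)
})

test_that("RLM agrees with the brute-force scanline oracle", {
  for (s in 1:50) {
    q <- random_quantized(n = 6, Z = 4, seed = 200 + s)
    got <- rlm(as_quantized(q, 4))
    exp_R <- rlm_oracle(q, 4)
    # pad to common width
    w <- max(ncol(got$R), ncol(exp_R))
    pad <- function(R) cbind(R, matrix(0, nrow(R), w - ncol(R)))
    expect_lt(max(abs(pad(got$R) - pad(exp_R))), 1e-12)
    # voxel-coverage identity: sum_ij R[i,j] * j = in-mask voxels per direction
    nvox <- sum(q >= 0)
    expect_equal(sum(sweep(got$R, 2, seq_len(ncol(got$R)), "*")),
                 nvox * nrow(glcm_directions()))
  }
})

test_that("run-length statistics match hand evaluations", {
  r <- rlm(strip_quantized(c(0, 0, 1, 1, 1), Z = 2),
           directions = matrix(c(1L, 0L, 0L), 1))
  f <- rlm_features(r)
  expect_equal(f[["sre"]], (1 / 2) * (1 / 4 + 1 / 9))  # 13/72
  expect_equal(f[["sre"]], 13 / 72)

  # all runs length 1 -> SRE = LRE = 1; all at lowest level -> LGRE = 1
  r2 <- rlm(strip_quantized(c(0, 1, 0, 1), Z = 2),
            directions = matrix(c(1L, 0L, 0L), 1))
  f2 <- rlm_features(r2)
  expect_equal(f2[["sre"]], 1)
  expect_equal(f2[["lre"]], 1)

  r3 <- rlm(strip_quantized(c(0, 0, -1, 0), Z = 2),
            directions = matrix(c(1L, 0L, 0L), 1))
  expect_equal(rlm_features(r3)[["lgre"]], 1)
})

test_that("first-order features match arithmetic on small masks", {
  v <- voxel_grid(array(c(1, 2, 3, 0), c(4, 1, 1)))
  m <- binary_mask(array(c(TRUE, TRUE, TRUE, FALSE), c(4, 1, 1)))
  f <- first_order_features(v, m, bins = 4)
  expect_equal(f[["mean"]], 2)
  expect_equal(f[["variance"]], 2 / 3)

  const <- first_order_features(voxel_grid(array(7, c(3, 3, 3))),
                                binary_mask(array(TRUE, c(3, 3, 3))), 8)
  expect_equal(const[["variance"]], 0)
  expect_equal(const[["energy"]], 1)
  expect_equal(const[["entropy"]], 0)

  two <- first_order_features(voxel_grid(array(c(0, 1), c(2, 1, 1))),
                              binary_mask(array(TRUE, c(2, 1, 1))), 2)
  expect_equal(two[["entropy"]], 1)
})

test_that("subject extraction yields 144 finite named features", {
  s <- subject_cached("NC", seed = 3)
  f <- extract_subject_features(s)
  cols <- setdiff(names(f), c("subject_id", "class"))
  expect_length(cols, 144)
  expect_true(all(is.finite(unlist(f[cols]))))
  meta <- feature_metadata(cols)
  expect_equal(sort(unique(meta$structure)), sort(c("gm", "wm", "csf", "hc")))
  expect_equal(sort(unique(meta$family)),
               sort(c("shape", "firstorder", "glcm", "rlm")))
  # volume features agree with structure_volume
  expect_equal(f$hc_left_shape_volume,
               structure_volume(structure_mask(s$labels, "hc", "left")))
})

test_that("smoother texture lowers GLCM contrast and raises IDM monotonically", {
  cfg <- phantom_config(grid_shape = c(40, 40, 40),
                        jitter = list(global_sd = 0, volume_sd = 0, corr_sd = 0),
                        noise_sigma = 0)
  mult <- c(1, 1.5, 2.25)
  contrast <- idm <- numeric(3)
  for (i in seq_along(mult)) {
    eff <- class_effect("NC", texture = list(
      gm = list(left = list(correlation_length_multiplier = mult[i]))))
    s <- simulate_subject(cfg, eff, "s", seed = 11)
    m <- structure_mask(s$labels, "gm", "left")
    g <- glcm_features(glcm(quantize(s$intensity, m, 32)))
    contrast[i] <- g[["contrast"]]; idm[i] <- g[["idm"]]
  }
  expect_true(all(diff(contrast) < 0))
  expect_true(all(diff(idm) > 0))
})
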