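# Independent brute-force oracles for GLCM and RLM, written as direct
# transliterations of the definitions (explicit voxel loops), deliberately
# sharing no code with the package implementations.

glcm_oracle <- function(qdata, Z, d = 1, dirs = glcm_directions(),
                        symmetric = TRUE) {
  dm <- dim(qdata)
  C <- matrix(0, Z, Z)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    l1 <- qdata[i, j, k]
    if (l1 < 0) next
    for (r in seq_len(nrow(dirs))) {
      ii <- i + d * dirs[r, 1]; jj <- j + d * dirs[r, 2]; kk <- k + d * dirs[r, 3]
      if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] || kk < 1 || kk > dm[3])
        next
      l2 <- qdata[ii, jj, kk]
      if (l2 < 0) next
      C[l1 + 1, l2 + 1] <- C[l1 + 1, l2 + 1] + 1
    }
  }
  if (symmetric) C <- C + t(C)
  C / sum(C)
}

rlm_oracle <- function(qdata, Z, dirs = glcm_directions()) {
  dm <- dim(qdata)
  runs_lev <- integer(0)
  runs_len <- integer(0)
  in_grid <- function(p) all(p >= 1) && all(p <= dm)
  for (r in seq_len(nrow(dirs))) {
    dir <- dirs[r, ]
    for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
      p <- c(i, j, k)
      if (in_grid(p - dir)) next  # not a line start
      cur_lev <- -1L; cur_len <- 0L
      while (in_grid(p)) {
        lv <- qdata[p[1], p[2], p[3]]
        if (lv >= 0 && lv == cur_lev) {
          cur_len <- cur_len + 1L
        } else {
          if (cur_len > 0) {
            runs_lev <- c(runs_lev, cur_lev); runs_len <- c(runs_len, cur_len)
          }
          if (lv >= 0) { cur_lev <- lv; cur_len <- 1L }
          else { cur_lev <- -1L; cur_len <- 0L }
        }
        p <- p + dir
      }
      if (cur_len > 0) {
        runs_lev <- c(runs_lev, cur_lev); runs_len <- c(runs_len, cur_len)
      }
    }
  }
  lmax <- max(runs_len)
  R <- matrix(0, Z, lmax)
  for (q in seq_along(runs_lev)) {
    R[runs_lev[q] + 1, runs_len[q]] <- R[runs_lev[q] + 1, runs_len[q]] + 1
  }
  R
}

# Random small masked quantised volume (levels 0..Z-1 in mask, -1 outside).
random_quantized <- function(n = 6, Z = 4, p_mask = 0.7, seed = 1) {
  withr::with_seed(seed, {
    q <- array(sample(0:(Z - 1), n^3, replace = TRUE), c(n, n, n))
    m <- array(stats::runif(n^3) < p_mask, c(n, n, n))
    q[!m] <- -1L
    q
  })
}

# Wrap a bare quantised array as the package's quantized_volume.
as_quantized <- function(qdata, Z) {
  structure(list(data = qdata, Z = as.integer(Z),
                 mask = binary_mask(qdata >= 0)),
            class = "quantized_volume")
}

# 1D strip embedded in a 3D array (everything else outside the mask).
strip_quantized <- function(levels, Z) {
  q <- array(-1L, c(length(levels), 1, 1))
  q[, 1, 1] <- as.integer(levels)
  as_quantized(q, Z)
}
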