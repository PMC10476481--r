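# Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' Streams the master seed and any number of string/numeric tags through a
#' 31-multiplier rolling hash modulo 2^31 - 1, so every stochastic stage of the
#' pipeline (per-subject fields, fold assignment, wrapper CV) gets its own
#' deterministic seed that fits in a 32-bit integer.
#'
#' @param seed Integer master seed.
#' @param ... Additional tags (coerced to character) identifying the consumer.
#' @return A single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, character(1))),
               collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Shift a 3D array by (dx, dy, dz), filling vacated entries with `fill`.
shift3 <- function(a, dx, dy, dz, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, s) {
    lo <- max(1L, 1L - s); hi <- min(n, n - s)
    if (lo > hi) integer(0) else lo:hi
  }
  sx <- src(d[1], dx); sy <- src(d[2], dy); sz <- src(d[3], dz)
  if (!length(sx) || !length(sy) || !length(sz)) return(out)
  out[sx + dx, sy + dy, sz + dz] <- a[sx, sy, sz]
  out
}

# Separable 3D Gaussian smoothing. Each axis is convolved by multiplying
# with a banded kernel matrix whose rows are renormalised at the array edges
# (kernel mass falling outside the grid is redistributed, so a constant
# array stays constant).
smooth_gaussian3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  d <- dim(a)
  band <- function(n) {
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), `-`), sd = sigma)
    K[abs(outer(seq_len(n), seq_len(n), `-`)) > ceiling(3 * sigma)] <- 0
    K / rowSums(K)
  }
  # axis 1
  dim(a) <- c(d[1], d[2] * d[3])
  a <- band(d[1]) %*% a
  dim(a) <- d
  # axis 2
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- c(d[2], d[1] * d[3])
  a <- band(d[2]) %*% a
  dim(a) <- c(d[2], d[1], d[3])
  a <- aperm(a, c(2, 1, 3))
  # axis 3
  a <- aperm(a, c(3, 1, 2))
  dim(a) <- c(d[3], d[1] * d[2])
  a <- band(d[3]) %*% a
  dim(a) <- c(d[3], d[1], d[2])
  aperm(a, c(2, 3, 1))
}

# Bounding box (with margin) of a logical 3D array; returns index ranges.
bbox3 <- function(mask, margin = 0L) {
  d <- dim(mask)
  idx <- which(mask)
  stopifnot(length(idx) > 0)
  co <- arrayInd(idx, d)
  lapply(1:3, function(a) {
    max(1L, min(co[, a]) - margin):min(d[a], max(co[, a]) + margin)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)
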