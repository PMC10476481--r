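# Masked 3D texture features: gray-level quantisation, co-occurrence matrix
# (GLCM) and its five statistics, run-length matrix (RLM) and the classical
# eight run-emphasis statistics, and first-order histogram features.

#' The 13 canonical 3D co-occurrence directions
#'
#' One representative per +/- pair of the 26-neighbourhood, so the symmetric
#' closure covers every neighbour direction exactly once.
#'
#' @return A 13 x 3 integer matrix of voxel offsets.
#' @export
glcm_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  # keep the representative whose first nonzero component is positive
  keep <- apply(g, 1, function(d) d[which(d != 0)[1]] > 0)
  out <- unname(g[keep, , drop = FALSE])
  storage.mode(out) <- "integer"
  out
}

#' Quantise in-mask intensities to Z gray levels
#'
#' Uniform bins over the in-mask `[min, max]`; the maximum maps to level
#' `Z - 1`; a constant region maps entirely to level 0. Outside-mask voxels
#' carry the sentinel -1.
#'
#' @param v A [voxel_grid()].
#' @param mask A nonempty [binary_mask()] of the same shape.
#' @param Z Number of gray levels (>= 2).
#' @return A `quantized_volume`: list with `data` (integer array, -1 outside
#'   the mask), `Z` and `mask`.
#' @export
quantize <- function(v, mask, Z = 32) {
  abort_if(Z < 2, "Z must be >= 2")
  m <- mask$data
  abort_if(!identical(dim(m), dim(v$data)), "mask shape mismatch")
  abort_if(!any(m), "mask is empty")
  vals <- v$data[m]
  rng <- range(vals)
  q <- array(-1L, dim(v$data))
  if (rng[1] == rng[2]) {
    q[m] <- 0L
  } else {
    lev <- floor((vals - rng[1]) / (rng[2] - rng[1]) * Z)
    lev[lev >= Z] <- Z - 1
    q[m] <- as.integer(lev)
  }
  structure(list(data = q, Z = as.integer(Z), mask = mask),
            class = "quantized_volume")
}

#' GLCM specification
#'
#' @param Z Number of gray levels.
#' @param d Pair distance in voxels (positive integer).
#' @param directions Integer matrix of 3D offsets (rows); default the 13
#'   canonical directions of [glcm_directions()].
#' @param symmetric If `TRUE` (default) pairs are counted in both `+d` and
#'   `-d` senses, making the matrix symmetric.
#' @return An object of class `glcm_spec`.
#' @export
glcm_spec <- function(Z = 32, d = 1, directions = glcm_directions(),
                      symmetric = TRUE) {
  abort_if(d < 1 || d != round(d), "d must be a positive integer")
  directions <- rbind(directions)
  abort_if(nrow(directions) == 0, "directions must be nonempty")
  structure(list(Z = as.integer(Z), d = as.integer(d),
                 directions = directions, symmetric = isTRUE(symmetric)),
            class = "glcm_spec")
}

#' Gray-level co-occurrence matrix within a mask
#'
#' Counts ordered gray-level pairs `(level(p), level(p + d*dir))` over every
#' direction, restricted to pairs whose both endpoints are in-mask, and
#' normalises by the total pair count. With `symmetric = TRUE` each pair is
#' also counted in the reverse sense, so `P = t(P)`.
#'
#' @param q A `quantized_volume` from [quantize()].
#' @param spec A [glcm_spec()] (its `Z` must match `q`).
#' @return A `glcm` object: list with `P` (Z x Z probability matrix),
#'   `spec`, `pair_count`.
#' @export
glcm <- function(q, spec = glcm_spec(Z = q$Z)) {
  Z <- q$Z
  abort_if(spec$Z != Z, "spec$Z must match the quantized volume")
  dm <- dim(q$data)
  idx <- which(q$data >= 0L)
  co <- arrayInd(idx, dm)
  lev <- q$data[idx]
  counts <- numeric(Z * Z)
  for (r in seq_len(nrow(spec$directions))) {
    off <- spec$directions[r, ] * spec$d
    nb <- cbind(co[, 1] + off[1], co[, 2] + off[2], co[, 3] + off[3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
      nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    nbi <- (nb[ok, 3] - 1L) * dm[1] * dm[2] + (nb[ok, 2] - 1L) * dm[1] +
      nb[ok, 1]
    nlev <- q$data[nbi]
    inm <- nlev >= 0L
    if (!any(inm)) next
    counts <- counts + tabulate(lev[ok][inm] * Z + nlev[inm] + 1L, Z * Z)
  }
  C <- matrix(counts, Z, Z, byrow = TRUE)  # row = first level, col = second
  if (spec$symmetric) C <- C + t(C)
  total <- sum(C)
  abort_if(total == 0, "no valid voxel pairs for the given offsets")
  structure(list(P = C / total, spec = spec, pair_count = total),
            class = "glcm")
}

#' The five GLCM statistics
#'
#' Energy `sum(P^2)`; contrast `sum((o-k)^2 P)`; inverse difference moment
#' `sum(P / (1 + (o-k)^2))`; entropy `-sum(P log2 P)` with `0 log 0 := 0`;
#' correlation `(sum(o k P) - eta_x eta_y) / (gamma_x gamma_y)` with marginal
#' means `eta` and standard deviations `gamma` (0 by convention when a
#' marginal variance vanishes, so feature tables stay finite).
#'
#' @param g A `glcm` object.
#' @return Named numeric vector: `energy`, `contrast`, `idm`, `entropy`,
#'   `correlation`.
#' @export
glcm_features <- function(g) {
  P <- g$P
  Z <- nrow(P)
  o <- matrix(0:(Z - 1), Z, Z)
  k <- t(o)
  energy <- sum(P^2)
  contrast <- sum((o - k)^2 * P)
  idm <- sum(P / (1 + (o - k)^2))
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  px <- rowSums(P); py <- colSums(P)
  lv <- 0:(Z - 1)
  mx <- sum(lv * px); my <- sum(lv * py)
  sx <- sqrt(sum((lv - mx)^2 * px)); sy <- sqrt(sum((lv - my)^2 * py))
  correlation <- if (sx * sy == 0) 0 else (sum(o * k * P) - mx * my) / (sx * sy)
  c(energy = energy, contrast = contrast, idm = idm, entropy = entropy,
    correlation = correlation)
}

#' Run-length matrix within a mask
#'
#' For each direction, maximal collinear runs of equal gray level strictly
#' inside the mask (a mask gap or grid boundary terminates a run); run counts
#' are summed over directions.
#'
#' @param q A `quantized_volume` from [quantize()].
#' @param directions Integer matrix of 3D offsets; default
#'   [glcm_directions()] (runs are unoriented, so one representative per
#'   +/- pair suffices).
#' @return A `run_length_matrix`: list with `R` (Z x Lmax count matrix, rows
#'   = levels, cols = run lengths), `n_runs`, `directions`.
#' @export
rlm <- function(q, directions = glcm_directions()) {
  Z <- q$Z
  dm <- dim(q$data)
  idx <- which(q$data >= 0L)
  abort_if(length(idx) == 0, "mask is empty")
  co <- arrayInd(idx, dm)
  lev <- q$data[idx]
  run_lev <- vector("list", nrow(directions))
  run_len <- vector("list", nrow(directions))
  for (r in seq_len(nrow(directions))) {
    d3 <- directions[r, ]
    step <- sum(d3^2)
    # position along the line and line identity (cross-product components)
    p <- co[, 1] * d3[1] + co[, 2] * d3[2] + co[, 3] * d3[3]
    k1 <- co[, 1] * d3[2] - co[, 2] * d3[1]
    k2 <- co[, 1] * d3[3] - co[, 3] * d3[1]
    k3 <- co[, 2] * d3[3] - co[, 3] * d3[2]
    line <- (k1 + 256L) + 513L * ((k2 + 256L) + 513L * (k3 + 256L))
    ord <- order(line, p)
    lo <- line[ord]; po <- p[ord]; lv <- lev[ord]
    n <- length(ord)
    new_run <- c(TRUE, lo[-1] != lo[-n] | po[-1] != po[-n] + step |
                   lv[-1] != lv[-n])
    grp <- cumsum(new_run)
    run_len[[r]] <- tabulate(grp)
    run_lev[[r]] <- lv[new_run]
  }
  run_len <- unlist(run_len)
  run_lev <- unlist(run_lev)
  lmax <- max(run_len)
  R <- matrix(0, Z, lmax)
  tab <- table(factor(run_lev, levels = 0:(Z - 1)),
               factor(run_len, levels = seq_len(lmax)))
  R[] <- as.numeric(tab)
  structure(list(R = R, n_runs = sum(R), directions = directions),
            class = "run_length_matrix")
}

#' The eight run-length statistics
#'
#' With 1-based gray index `g = level + 1` (avoiding division by zero at
#' level 0) and run length `j`: short/long-run emphasis weight by `1/j^2` /
#' `j^2`, low/high gray-level emphasis by `1/g^2` / `g^2`, and the four joint
#' statistics multiply the weights. All are normalised by the total number of
#' runs.
#'
#' @param r A `run_length_matrix` from [rlm()].
#' @return Named numeric vector: `sre`, `lre`, `lgre`, `hgre`, `srlge`,
#'   `lrlge`, `srhge`, `lrhge`.
#' @export
rlm_features <- function(r) {
  R <- r$R
  abort_if(r$n_runs < 1, "run-length matrix has no runs")
  g <- matrix(seq_len(nrow(R)), nrow(R), ncol(R))
  j <- matrix(seq_len(ncol(R)), nrow(R), ncol(R), byrow = TRUE)
  N <- r$n_runs
  c(sre = sum(R / j^2), lre = sum(R * j^2),
    lgre = sum(R / g^2), hgre = sum(R * g^2),
    srlge = sum(R / (j^2 * g^2)), lrlge = sum(R * j^2 / g^2),
    srhge = sum(R * g^2 / j^2), lrhge = sum(R * j^2 * g^2)) / N
}

#' First-order histogram features within a mask
#'
#' Mean and population variance of the raw in-mask intensities, plus energy
#' `sum(p^2)` and entropy `-sum(p log2 p)` of a uniform-bin histogram over
#' the in-mask range (a constant region occupies a single bin).
#'
#' @param v A [voxel_grid()].
#' @param mask A nonempty [binary_mask()].
#' @param bins Number of histogram bins.
#' @return Named numeric vector: `mean`, `variance`, `energy`, `entropy`.
#' @export
first_order_features <- function(v, mask, bins = 32) {
  vals <- v$data[mask$data]
  abort_if(length(vals) == 0, "mask is empty")
  mu <- mean(vals)
  va <- mean((vals - mu)^2)
  rng <- range(vals)
  if (rng[1] == rng[2]) {
    p <- 1
  } else {
    b <- floor((vals - rng[1]) / (rng[2] - rng[1]) * bins)
    b[b >= bins] <- bins - 1
    p <- tabulate(b + 1L, bins)
    p <- p[p > 0] / length(vals)
  }
  c(mean = mu, variance = va, energy = sum(p^2), entropy = -sum(p * log2(p)))
}

#' Feature extraction settings
#'
#' @param Z Gray levels for GLCM/RLM quantisation (default 32).
#' @param d GLCM pair distance in voxels (default 1).
#' @param bins First-order histogram bins (default 32).
#' @return A list of class `feature_spec`.
#' @export
feature_spec <- function(Z = 32, d = 1, bins = 32) {
  structure(list(Z = as.integer(Z), d = as.integer(d),
                 bins = as.integer(bins)), class = "feature_spec")
}

#' Extract the full per-hemisphere feature vector of one subject
#'
#' For each of the 4 structures x 2 hemispheres: the structure volume (mm^3,
#' `shape` family), 4 first-order, 5 GLCM and 8 RLM features — 144 features
#' named `{structure}_{hemisphere}_{family}_{feature}`.
#'
#' @param subject A `subject_record` (see [simulate_subject()]), or a list
#'   with elements `subject_id`, `class_label`, `intensity`, `labels`.
#' @param spec A [feature_spec()].
#' @return A one-row tibble: `subject_id`, `class`, then 144 feature columns.
#' @export
extract_subject_features <- function(subject, spec = feature_spec()) {
  out <- list(subject_id = subject$subject_id,
              class = subject$class_label %||% NA_character_)
  for (s in STRUCTURES) {
    for (h in HEMISPHERES) {
      m <- structure_mask(subject$labels, s, h)
      abort_if(!any(m$data),
               paste0("empty mask for (", s, ", ", h, ")"))
      pre <- paste(s, h, sep = "_")
      out[[paste0(pre, "_shape_volume")]] <- structure_volume(m)
      fo <- first_order_features(subject$intensity, m, spec$bins)
      for (f in names(fo)) out[[paste0(pre, "_firstorder_", f)]] <- fo[[f]]
      q <- quantize(subject$intensity, m, spec$Z)
      gf <- glcm_features(glcm(q, glcm_spec(Z = spec$Z, d = spec$d)))
      for (f in names(gf)) out[[paste0(pre, "_glcm_", f)]] <- gf[[f]]
      rf <- rlm_features(rlm(q))
      for (f in names(rf)) out[[paste0(pre, "_rlm_", f)]] <- rf[[f]]
    }
  }
  tibble::as_tibble(out)
}

#' Extract features for a whole cohort
#'
#' @param cohort A cohort as returned by [generate_cohort()] (in-memory
#'   records), or a bare list of `subject_record`s.
#' @param spec A [feature_spec()].
#' @return A tibble, one row per subject: `subject_id`, `class`, 144 feature
#'   columns. Metadata attributes record `Z`, `d`, `bins`.
#' @export
extract_features <- function(cohort, spec = feature_spec()) {
  records <- if (!is.null(cohort$records)) cohort$records else cohort
  abort_if(length(records) == 0, "no subject records")
  out <- dplyr::bind_rows(lapply(records, extract_subject_features,
                                 spec = spec))
  attr(out, "feature_spec") <- spec
  out
}

#' Parse feature names into metadata
#'
#' Decomposes names of the form `{structure}_{hemisphere}_{family}_{feature}`
#' (hemisphere may be `left`, `right`, or the asymmetry tags `diff`/`ratio`).
#'
#' @param names Character vector of feature column names.
#' @return Tibble: `name`, `structure`, `hemisphere`, `family`, `feature`.
#' @export
feature_metadata <- function(names) {
  parts <- strsplit(names, "_")
  tibble::tibble(
    name = names,
    structure = vapply(parts, `[`, "", 1),
    hemisphere = vapply(parts, `[`, "", 2),
    family = vapply(parts, `[`, "", 3),
    feature = vapply(parts, function(p) paste(p[-(1:3)], collapse = "_"), "")
  )
}

# Feature columns of a cohort tibble (everything except id/class).
feature_columns <- function(tbl) {
  setdiff(names(tbl), c("subject_id", "class"))
}
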