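# Synthetic brain phantom: nested-ellipsoid geometry with mirror-symmetric
# left/right hemispheres, per-structure correlated random-field texture,
# class-graded asymmetry effects, and Rician magnitude noise.

#' Default ellipsoid geometry for a phantom grid
#'
#' Each hemisphere is a stack of nested ellipsoids (CSF shell > WM shell >
#' GM core > HC blob) centred at 26% / 74% of the left-right axis; radii are
#' fractions of the grid so the same geometry scales to any grid size. The
#' two hemispheres are exact mirror images before class effects are applied.
#'
#' @param grid_shape Integer length-3 grid dimensions.
#' @return Named list, per structure: `center` offset (voxels, relative to the
#'   hemisphere centre) and `radii` (voxels).
#' @export
default_geometry <- function(grid_shape = c(64, 64, 64)) {
  n <- grid_shape
  list(
    csf = list(center = c(0, 0, 0),
               radii = c(0.200 * n[1], 0.360 * n[2], 0.360 * n[3])),
    wm  = list(center = c(0, 0, 0),
               radii = c(0.165 * n[1], 0.300 * n[2], 0.300 * n[3])),
    gm  = list(center = c(0, 0, 0),
               radii = c(0.115 * n[1], 0.210 * n[2], 0.210 * n[3])),
    hc  = list(center = c(0, -0.060 * n[2], -0.070 * n[3]),
               radii = c(0.075 * n[1], 0.090 * n[2], 0.080 * n[3]))
  )
}

#' Default texture parameters per structure
#'
#' Base intensities follow a T1-weighted ordering (WM bright, GM mid, CSF
#' dark); the texture is a stationary correlated random field of the given
#' amplitude and correlation length (voxels).
#'
#' @return Named list per structure: `base_intensity`, `amplitude`,
#'   `correlation_length_vox`.
#' @export
default_texture_params <- function() {
  list(
    csf = list(base_intensity = 0.20, amplitude = 0.05, correlation_length_vox = 1.5),
    wm  = list(base_intensity = 0.80, amplitude = 0.08, correlation_length_vox = 1.5),
    gm  = list(base_intensity = 0.60, amplitude = 0.08, correlation_length_vox = 1.5),
    hc  = list(base_intensity = 0.55, amplitude = 0.08, correlation_length_vox = 1.5)
  )
}

#' Phantom configuration
#'
#' @param grid_shape Integer length-3 grid dimensions (default 64^3).
#' @param voxel_size_mm Isotropic voxel edge length in mm (default 1.5).
#' @param structure_geometry Per-structure ellipsoid geometry; see
#'   [default_geometry()].
#' @param texture_params Per-structure texture parameters; see
#'   [default_texture_params()].
#' @param noise_sigma Rician noise sigma; default 2% of the GM base intensity.
#' @param jitter Per-subject log-normal variability: `global_sd` (whole-brain
#'   radii), `volume_sd` (per structure x hemisphere volume), `corr_sd`
#'   (correlation length). Set all to 0 for fully deterministic geometry.
#' @param mirror_texture If `TRUE`, the right-hemisphere texture field is an
#'   exact mirror copy of the left, producing a perfectly symmetric subject
#'   (used by symmetry identities; default `FALSE`).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           voxel_size_mm = 1.5,
                           structure_geometry = default_geometry(grid_shape),
                           texture_params = default_texture_params(),
                           noise_sigma = 0.02 * texture_params$gm$base_intensity,
                           jitter = list(global_sd = 0.03, volume_sd = 0.05,
                                         corr_sd = 0.05),
                           mirror_texture = FALSE) {
  abort_if(length(grid_shape) != 3 || any(grid_shape < 16),
           "grid_shape must be 3 integers >= 16")
  abort_if(voxel_size_mm <= 0, "voxel_size_mm must be positive")
  abort_if(noise_sigma < 0, "noise_sigma must be nonnegative")
  abort_if(!all(STRUCTURES %in% names(structure_geometry)),
           "structure_geometry must cover gm, wm, csf, hc")
  for (s in STRUCTURES) {
    abort_if(any(structure_geometry[[s]]$radii <= 0), "all radii must be > 0")
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 structure_geometry = structure_geometry,
                 texture_params = texture_params,
                 noise_sigma = noise_sigma,
                 jitter = jitter,
                 mirror_texture = mirror_texture),
            class = "phantom_config")
}

#' Class effect: how a diagnostic class perturbs the symmetric phantom
#'
#' Effects are per (structure, hemisphere): `volume_scale` multiplies the
#' structure volume (radii scale as the cube root) and `texture` carries a
#' `correlation_length_multiplier` and an additive `intensity_shift`.
#'
#' @param class_label One of `"NC"`, `"MCI"`, `"AD"`.
#' @param volume_scale Named list `structure -> c(left = s, right = s)`;
#'   omitted entries default to 1 (identity).
#' @param texture Named list `structure -> hemisphere -> list(
#'   correlation_length_multiplier, intensity_shift)`; omitted entries are
#'   identity.
#' @return An object of class `class_effect`.
#' @export
class_effect <- function(class_label, volume_scale = list(), texture = list()) {
  abort_if(!class_label %in% c("NC", "MCI", "AD"),
           "class_label must be NC, MCI or AD")
  vs <- lapply(STRUCTURES, function(s) {
    v <- volume_scale[[s]] %||% c(left = 1, right = 1)
    abort_if(any(v <= 0), "volume_scale entries must be > 0")
    v
  })
  names(vs) <- STRUCTURES
  tx <- lapply(STRUCTURES, function(s) {
    lapply(stats::setNames(HEMISPHERES, HEMISPHERES), function(h) {
      t <- texture[[s]][[h]] %||% list()
      list(correlation_length_multiplier =
             t$correlation_length_multiplier %||% 1,
           intensity_shift = t$intensity_shift %||% 0)
    })
  })
  names(tx) <- STRUCTURES
  structure(list(class_label = class_label, volume_scale = vs, texture = tx),
            class = "class_effect")
}

#' Default class effects for the emulated NC/MCI/AD cohort
#'
#' The shipped effects encode the premise that hemispheric asymmetry grows
#' along the NC -> MCI -> AD continuum: AD shrinks the left hippocampus to
#' 70% of its mirror volume and coarsens left gray-matter texture
#' (correlation length x 1.5); MCI sits halfway (85% volume, x 1.25); NC is
#' identity. Effects are componentwise monotone across the three classes.
#'
#' @return Named list of [class_effect()] objects for `NC`, `MCI`, `AD`.
#' @export
default_class_effects <- function() {
  list(
    NC = class_effect("NC"),
    MCI = class_effect(
      "MCI",
      volume_scale = list(hc = c(left = 0.85, right = 1)),
      texture = list(gm = list(left = list(correlation_length_multiplier = 1.25,
                                           intensity_shift = 0)))),
    AD = class_effect(
      "AD",
      volume_scale = list(hc = c(left = 0.70, right = 1)),
      texture = list(gm = list(left = list(correlation_length_multiplier = 1.5,
                                           intensity_shift = 0))))
  )
}

# Rasterise one ellipsoid: logical array of voxel centres inside it.
rasterize_ellipsoid <- function(grid_shape, center, radii) {
  n <- grid_shape
  x <- (seq_len(n[1]) - (n[1] + 1) / 2 - center[1]) / radii[1]
  y <- (seq_len(n[2]) - (n[2] + 1) / 2 - center[2]) / radii[2]
  z <- (seq_len(n[3]) - (n[3] + 1) / 2 - center[3]) / radii[3]
  d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  d2 <= 1
}

# Hemisphere centre offsets (relative to grid centre), mirror-symmetric in x.
hemi_center <- function(grid_shape, hemisphere) {
  dx <- 0.24 * grid_shape[1]
  c(if (hemisphere == "left") -dx else dx, 0, 0)
}

# Per-subject multiplicative jitter factors, deterministic in the seed.
subject_jitter <- function(config, seed) {
  j <- config$jitter
  withr::with_seed(derive_seed(seed, "jitter"), {
    global <- exp(stats::rnorm(1, 0, j$global_sd %||% 0))
    vol <- matrix(exp(stats::rnorm(8, 0, j$volume_sd %||% 0)), 4, 2,
                  dimnames = list(STRUCTURES, HEMISPHERES))
    corr <- matrix(exp(stats::rnorm(8, 0, j$corr_sd %||% 0)), 4, 2,
                   dimnames = list(STRUCTURES, HEMISPHERES))
    list(global = global, volume = vol, corr = corr)
  })
}

#' Build the label map of one phantom subject
#'
#' Rasterises the four bilateral structures as nested ellipsoids; a
#' `volume_scale` of `s` multiplies each radius by `s^(1/3)` so the parameter
#' reads directly as a volume ratio. Overlaps resolve by the fixed precedence
#' hippocampus > gray matter > white matter > CSF.
#'
#' @param config A [phantom_config()].
#' @param effect A [class_effect()].
#' @param seed Integer seed (drives per-subject geometry jitter).
#' @return A [label_map()] with legend labels 1..8.
#' @export
build_label_map <- function(config, effect, seed = 1) {
  n <- config$grid_shape
  jit <- subject_jitter(config, seed)
  lab <- array(0L, n)
  legend <- tidyr::expand_grid(structure = STRUCTURES,
                               hemisphere = HEMISPHERES)
  legend$label <- seq_len(nrow(legend))
  # precedence: rasterise CSF first, HC last, so later structures overwrite
  order_prec <- c("csf", "wm", "gm", "hc")
  for (s in order_prec) {
    geo <- config$structure_geometry[[s]]
    for (h in HEMISPHERES) {
      scale <- (effect$volume_scale[[s]][[h]] * jit$volume[s, h])^(1 / 3) *
        jit$global
      ctr <- hemi_center(n, h) + geo$center * c(if (h == "left") 1 else -1, 1, 1)
      inside <- rasterize_ellipsoid(n, ctr, geo$radii * scale)
      lb <- legend$label[legend$structure == s & legend$hemisphere == h]
      lab[inside] <- lb
    }
  }
  for (i in seq_len(nrow(legend))) {
    abort_if(!any(lab == legend$label[i]),
             paste0("degenerate geometry: empty mask for (",
                    legend$structure[i], ", ", legend$hemisphere[i], ")"))
  }
  label_map(lab, legend, config$voxel_size_mm)
}

#' Synthesise per-structure correlated texture for a labelled phantom
#'
#' Each (structure, hemisphere) region receives a stationary random field:
#' white Gaussian noise smoothed with an isotropic Gaussian kernel of width
#' `correlation_length_vox x correlation_length_multiplier`, standardised to
#' unit variance over the region, scaled by the structure amplitude, and added
#' to `base_intensity + intensity_shift`. Background stays 0.
#'
#' @param labels A [label_map()].
#' @param config A [phantom_config()].
#' @param effect A [class_effect()].
#' @param seed Integer seed.
#' @return A [voxel_grid()] (noise-free; see [add_rician_noise()]).
#' @export
synthesize_texture <- function(labels, config, effect, seed = 1) {
  n <- dim(labels$data)
  jit <- subject_jitter(config, seed)
  img <- array(0, n)
  for (s in STRUCTURES) {
    tp <- config$texture_params[[s]]
    for (h in HEMISPHERES) {
      if (config$mirror_texture && h == "right") next
      m <- labels$data == labels$legend$label[
        labels$legend$structure == s & labels$legend$hemisphere == h]
      if (!any(m)) next
      te <- effect$texture[[s]][[h]]
      base <- tp$base_intensity + te$intensity_shift
      if (tp$amplitude == 0) {
        img[m] <- base
        next
      }
      sig <- tp$correlation_length_vox * te$correlation_length_multiplier *
        jit$corr[s, h]
      r <- max(1L, as.integer(ceiling(3 * sig)))
      bb <- bbox3(m, margin = r)
      sub_dim <- vapply(bb, length, integer(1))
      field <- withr::with_seed(
        derive_seed(seed, "texture", s, h),
        array(stats::rnorm(prod(sub_dim)), sub_dim))
      field <- smooth_gaussian3(field, sig)
      sub_m <- m[bb[[1]], bb[[2]], bb[[3]]]
      vals <- field[sub_m]
      sdv <- stats::sd(vals)
      if (!is.finite(sdv) || sdv == 0) sdv <- 1
      vals <- (vals - mean(vals)) / sdv
      tmp <- array(0, sub_dim)
      tmp[sub_m] <- base + tp$amplitude * vals
      full <- array(0, n)
      full[bb[[1]], bb[[2]], bb[[3]]] <- tmp
      img[m] <- full[m]
    }
  }
  if (config$mirror_texture) {
    flipped <- img[rev(seq_len(n[1])), , , drop = FALSE]
    right_labels <- labels$legend$label[labels$legend$hemisphere == "right"]
    rm_ <- array(labels$data %in% right_labels, n)
    img[rm_] <- flipped[rm_]
  }
  voxel_grid(img, labels$spacing_mm)
}

#' Add Rician magnitude noise
#'
#' Models MR magnitude noise: each voxel becomes
#' `sqrt((I + n1)^2 + n2^2)` with `n1, n2` independent zero-mean Gaussians of
#' standard deviation `sigma`. With `sigma = 0` the (nonnegative) input is
#' returned unchanged up to `abs()`.
#'
#' @param v A [voxel_grid()].
#' @param sigma Nonnegative noise standard deviation.
#' @param seed Integer seed.
#' @return A [voxel_grid()] with strictly nonnegative intensities.
#' @export
add_rician_noise <- function(v, sigma, seed = 1) {
  abort_if(sigma < 0, "sigma must be nonnegative")
  if (sigma == 0) return(voxel_grid(abs(v$data), v$spacing_mm))
  d <- dim(v$data)
  out <- withr::with_seed(derive_seed(seed, "rician"), {
    n1 <- array(stats::rnorm(prod(d), 0, sigma), d)
    n2 <- array(stats::rnorm(prod(d), 0, sigma), d)
    sqrt((v$data + n1)^2 + n2^2)
  })
  voxel_grid(out, v$spacing_mm)
}

#' Simulate one phantom subject in memory
#'
#' @param config A [phantom_config()].
#' @param effect A [class_effect()].
#' @param subject_id Subject identifier string.
#' @param seed Integer seed for this subject.
#' @return A `subject_record`: list with `subject_id`, `class_label`,
#'   `intensity` ([voxel_grid()]) and `labels` ([label_map()]).
#' @export
simulate_subject <- function(config, effect, subject_id = "S001", seed = 1) {
  labels <- build_label_map(config, effect, seed)
  tex <- synthesize_texture(labels, config, effect, seed)
  img <- add_rician_noise(tex, config$noise_sigma, seed)
  structure(list(subject_id = subject_id,
                 class_label = effect$class_label,
                 intensity = img, labels = labels),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat("<subject_record> ", x$subject_id, " (", x$class_label, "), grid ",
      paste(dim(x$intensity$data), collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Generate a seeded phantom cohort
#'
#' Per-subject seeds derive deterministically from `(seed, class, index)`.
#' When `dir` is given, intensity and label volumes are written as NIfTI-1
#' (`.nii.gz`), the label legend as JSON, and a manifest CSV with columns
#' `subject_id,class,intensity_path,label_path`; otherwise subject records
#' are kept in memory.
#'
#' @param n_per_class Named integer vector / list, e.g.
#'   `c(NC = 50, MCI = 50, AD = 50)`.
#' @param config A [phantom_config()].
#' @param effects Named list of [class_effect()] per class; defaults to
#'   [default_class_effects()].
#' @param seed Integer master seed.
#' @param dir Output directory (created if needed), or `NULL` to keep the
#'   cohort in memory.
#' @return A list with `manifest` (tibble) and `records` (list of
#'   `subject_record`, `NULL`-free only when `dir` is `NULL`).
#' @export
generate_cohort <- function(n_per_class = c(NC = 50, MCI = 50, AD = 50),
                            config = phantom_config(),
                            effects = default_class_effects(),
                            seed = 1, dir = NULL) {
  abort_if(any(unlist(n_per_class) < 1), "n_per_class values must be >= 1")
  abort_if(!all(names(n_per_class) %in% names(effects)),
           "every class needs a matching effect")
  if (!is.null(dir) && !dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    abort_if(!ok && !dir.exists(dir), paste0("cannot create directory: ", dir))
  }
  records <- list()
  rows <- list()
  for (cls in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cls]])) {
      sid <- sprintf("%s_%03d", cls, i)
      s_seed <- derive_seed(seed, "subject", cls, i)
      rec <- simulate_subject(config, effects[[cls]], sid, s_seed)
      ipath <- lpath <- NA_character_
      if (!is.null(dir)) {
        ipath <- file.path(dir, paste0(sid, "_intensity.nii.gz"))
        lpath <- file.path(dir, paste0(sid, "_labels.nii.gz"))
        write_volume(rec$intensity, ipath)
        write_volume(rec$labels, lpath)
      } else {
        records[[sid]] <- rec
      }
      rows[[sid]] <- tibble::tibble(subject_id = sid, class = cls,
                                    intensity_path = ipath, label_path = lpath)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    legend <- build_label_map(config, effects[[names(n_per_class)[1]]],
                              derive_seed(seed, "legend"))$legend
    jsonlite::write_json(legend, file.path(dir, "legend.json"),
                         dataframe = "rows", auto_unbox = TRUE)
  }
  list(manifest = manifest, records = records)
}
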