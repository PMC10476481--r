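# Volume containers and preprocessing: NIfTI I/O, intensity normalisation,
# denoising, hemisphere splitting, structure masks and volumes.
#
# Conventions: arrays are indexed [x, y, z]; the first array axis is the
# left-right axis after canonical reorientation on read, with "left" at low x.
# Voxel indices are 1-based (R); the midplane fallback split is half-open.

STRUCTURES <- c("gm", "wm", "csf", "hc")
HEMISPHERES <- c("left", "right")

#' Construct a voxel grid
#'
#' A `voxel_grid` is the package's intensity-image container: a 3D numeric
#' array plus voxel spacing in millimetres.
#'
#' @param data 3D numeric array of intensities (finite).
#' @param spacing_mm Numeric length-3 vector of positive voxel edge lengths
#'   (mm); a scalar is recycled isotropically.
#' @return An object of class `voxel_grid` with elements `data`, `spacing_mm`.
#' @export
voxel_grid <- function(data, spacing_mm = 1.5) {
  abort_if(length(dim(data)) != 3, "voxel_grid data must be a 3D array")
  abort_if(!all(is.finite(data)), "voxel_grid data must be finite")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  abort_if(length(spacing_mm) != 3 || any(spacing_mm <= 0),
           "spacing_mm must be 3 positive reals")
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing_mm, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Construct a label map
#'
#' A `label_map` pairs a 3D integer label array with a legend mapping each
#' positive label to an anatomical structure (`gm`, `wm`, `csf`, `hc`) and
#' hemisphere (`left`, `right`). Label 0 is background.
#'
#' @param data 3D array of non-negative integer labels.
#' @param legend Tibble/data frame with columns `label`, `structure`,
#'   `hemisphere` covering every nonzero label present in `data`.
#' @param spacing_mm Voxel spacing as in [voxel_grid()].
#' @return An object of class `label_map`.
#' @export
label_map <- function(data, legend, spacing_mm = 1.5) {
  abort_if(length(dim(data)) != 3, "label_map data must be a 3D array")
  abort_if(any(data < 0) || any(data != round(data)),
           "label_map data must be nonnegative integers")
  legend <- tibble::as_tibble(legend)
  abort_if(!all(c("label", "structure", "hemisphere") %in% names(legend)),
           "legend needs columns label, structure, hemisphere")
  present <- setdiff(unique(as.vector(data)), 0)
  abort_if(!all(present %in% legend$label),
           "every nonzero voxel label must appear in the legend")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  structure(list(data = data, legend = legend,
                 spacing_mm = as.numeric(spacing_mm)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      nrow(x$legend), " legend entries\n", sep = "")
  invisible(x)
}

#' Construct a binary mask
#'
#' @param data 3D logical array.
#' @param spacing_mm Voxel spacing as in [voxel_grid()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing_mm = 1.5) {
  abort_if(length(dim(data)) != 3, "binary_mask data must be a 3D array")
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  structure(list(data = as.logical(data) |> array(dim(data)),
                 spacing_mm = as.numeric(spacing_mm)),
            class = "binary_mask")
}

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 file and, when the header carries a usable orientation,
#' reorients the array to the canonical `LAS` convention so the first array
#' axis runs left to right. Spacing is taken from the header `pixdim`.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [voxel_grid()].
#' @export
read_volume <- function(path) {
  abort_if(!file.exists(path), paste0("file not found: ", path))
  img <- RNifti::readNifti(path)
  abort_if(length(dim(img)) != 3,
           paste0("expected a 3D volume, got ", length(dim(img)), "D: ", path))
  ort <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(ort) && nzchar(ort) && ort != "LAS") {
    RNifti::orientation(img) <- "LAS"
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  voxel_grid(array(as.numeric(img), dim(img)), sp)
}

#' Write a volume (or label map) as NIfTI-1
#'
#' @param v A [voxel_grid()] or [label_map()].
#' @param path Output path (`.nii` or `.nii.gz`); the directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  abort_if(!inherits(v, c("voxel_grid", "label_map")),
           "v must be a voxel_grid or label_map")
  dir <- dirname(path)
  abort_if(!dir.exists(dir), paste0("output directory does not exist: ", dir))
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing_mm
  # voxel -> world affine in the canonical LAS convention (axis 1 = left-right)
  aff <- diag(c(-v$spacing_mm[1], v$spacing_mm[2], v$spacing_mm[3], 1))
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Min-max intensity normalisation within a brain mask
#'
#' Rescales in-mask intensities linearly to `[0, 1]` (min-max over mask
#' voxels); voxels outside the mask are set to 0. Min-max (rather than
#' z-score) keeps gray-level quantisation bins comparable across subjects.
#'
#' @param v A [voxel_grid()].
#' @param brain_mask A nonempty [binary_mask()] of the same shape.
#' @return A normalised [voxel_grid()].
#' @export
normalize_intensity <- function(v, brain_mask) {
  m <- brain_mask$data
  abort_if(!identical(dim(m), dim(v$data)), "mask shape mismatch")
  vals <- v$data[m]
  abort_if(length(vals) == 0, "brain mask is empty")
  rng <- range(vals)
  abort_if(rng[1] == rng[2],
           "image is constant within the mask; normalisation is degenerate")
  out <- array(0, dim(v$data))
  out[m] <- (v$data[m] - rng[1]) / (rng[2] - rng[1])
  voxel_grid(out, v$spacing_mm)
}

#' Denoise a volume
#'
#' @param v A [voxel_grid()].
#' @param method One of `"none"` (identity, the default), `"gaussian"` or
#'   `"median"`.
#' @param param Gaussian kernel width (sd, voxels, > 0) or median filter
#'   radius (voxels, >= 1).
#' @return A [voxel_grid()].
#' @export
denoise <- function(v, method = c("none", "gaussian", "median"), param = 1) {
  method <- match.arg(method)
  if (method == "none") return(v)
  if (method == "gaussian") {
    abort_if(!is.numeric(param) || param <= 0, "gaussian width must be > 0")
    return(voxel_grid(smooth_gaussian3(v$data, param), v$spacing_mm))
  }
  r <- as.integer(param)
  abort_if(r < 1, "median radius must be >= 1")
  offs <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  d <- dim(v$data)
  stack <- vapply(seq_len(nrow(offs)), function(i) {
    as.vector(shift3(v$data, offs$dx[i], offs$dy[i], offs$dz[i], fill = NA))
  }, numeric(prod(d)))
  med <- apply(stack, 1, stats::median, na.rm = TRUE)
  voxel_grid(array(med, d), v$spacing_mm)
}

#' Split a labelled brain into hemisphere masks
#'
#' The primary path unions the legend's left- (resp. right-) tagged labels.
#' The midplane fallback splits the labelled bounding box at the midpoint of
#' the left-right axis with the half-open convention `[lo, mid)` = left,
#' `[mid, hi]` = right.
#'
#' @param labels A [label_map()].
#' @param method `"legend"` (default) or `"midplane"`.
#' @return A list with nonempty disjoint [binary_mask()] elements `left`,
#'   `right`.
#' @export
split_hemispheres <- function(labels, method = c("legend", "midplane")) {
  method <- match.arg(method)
  d <- dim(labels$data)
  if (method == "legend") {
    mk <- function(h) {
      labs <- labels$legend$label[labels$legend$hemisphere == h]
      array(labels$data %in% labs, d)
    }
    left <- mk("left"); right <- mk("right")
  } else {
    nz <- labels$data > 0
    abort_if(!any(nz), "label map has no labelled voxels")
    xs <- which(apply(nz, 1, any))
    lo <- min(xs); hi <- max(xs)
    mid <- lo + (hi - lo + 1L) %/% 2L
    xidx <- slice.index(nz, 1)
    left <- nz & (xidx < mid)
    right <- nz & (xidx >= mid)
  }
  abort_if(!any(left), "left hemisphere mask is empty")
  abort_if(!any(right), "right hemisphere mask is empty")
  list(left = binary_mask(left, labels$spacing_mm),
       right = binary_mask(right, labels$spacing_mm))
}

#' Extract the mask of one (structure, hemisphere) entry
#'
#' @param labels A [label_map()].
#' @param structure One of `"gm"`, `"wm"`, `"csf"`, `"hc"`.
#' @param hemisphere `"left"` or `"right"`.
#' @return A [binary_mask()] of the voxels carrying that legend entry.
#' @export
structure_mask <- function(labels, structure, hemisphere) {
  row <- labels$legend[labels$legend$structure == structure &
                         labels$legend$hemisphere == hemisphere, ]
  abort_if(nrow(row) == 0,
           paste0("(", structure, ", ", hemisphere, ") not present in legend"))
  binary_mask(array(labels$data %in% row$label, dim(labels$data)),
              labels$spacing_mm)
}

#' Physical volume of a binary mask
#'
#' @param m A [binary_mask()].
#' @return Volume in cubic millimetres: voxel count times voxel volume.
#' @export
structure_volume <- function(m) {
  sum(m$data) * prod(m$spacing_mm)
}
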