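#' Voxel grid geometry
#'
#' An `image_grid` couples a 3D voxel lattice to physical space: `shape` in
#' voxels (axes ordered x, y, z with z the axial slice index), `spacing` in
#' mm/voxel, and a 4x4 `affine` mapping 0-based voxel indices to physical mm
#' coordinates. The axial plane is by convention spanned by the first two
#' voxel axes; all in-plane diameter measurements use `spacing[1:2]`.
#'
#' @param shape integer vector of 3 positive voxel counts.
#' @param spacing numeric vector of 3 positive mm/voxel sizes.
#' @param affine optional 4x4 voxel-to-mm matrix; defaults to
#'   `diag(c(spacing, 1))` (axis-aligned, origin at the first voxel).
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(64, 64, 32), spacing = c(1, 1, 1.2))
#' g$affine
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), affine = NULL) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || any(shape <= 0L)) stop("shape must be 3 positive integers")
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be 3 positive reals")
  if (is.null(affine)) affine <- diag(c(spacing, 1))
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12) stop("affine is singular")
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> ", paste(x$shape, collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      sep = "")
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) && max(abs(a$affine - b$affine)) < tol
}

#' Label volume
#'
#' A `label_volume` is a 3D integer lattice on an [image_grid()]: 0 is
#' background, any positive value is enhancing-tumor foreground. Study
#' metadata (index, date, patient) travels with the volume so longitudinal
#' series can be assembled.
#'
#' @param data 3D integer array matching `grid$shape`; values must be >= 0.
#' @param grid an [image_grid()].
#' @param study_index nonnegative integer position in the longitudinal series.
#' @param study_date optional `Date`.
#' @param patient_id patient identifier string.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, grid, study_index = 0L, study_date = NULL,
                         patient_id = "P0") {
  if (!inherits(grid, "image_grid")) stop("grid must be an image_grid")
  data <- as.array(data)
  if (length(dim(data)) != 3L || !all(dim(data) == grid$shape))
    stop("data shape ", paste(dim(data), collapse = "x"),
         " does not match grid shape ", paste(grid$shape, collapse = "x"))
  storage.mode(data) <- "integer"
  if (min(data) < 0L) stop("label values must be >= 0")
  structure(list(grid = grid, data = data,
                 study_index = as.integer(study_index),
                 study_date = study_date,
                 patient_id = as.character(patient_id)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> patient ", x$patient_id, ", study ", x$study_index,
      ", ", paste(x$grid$shape, collapse = "x"), " voxels, ",
      sum(x$data > 0L), " foreground\n", sep = "")
  invisible(x)
}

#' Read a NIfTI-1 label volume
#'
#' Reads a single-file NIfTI-1 volume (`.nii` or `.nii.gz`) with integer
#' voxel values. Spacing and the voxel-to-mm affine are taken from the
#' header (sform preferred, then qform, then pixdim). Float-typed files are
#' accepted only if every value is integral; 4D files and intensity
#' rescaling are rejected.
#'
#' @param path path to a readable NIfTI-1 file.
#' @param study_index,study_date,patient_id metadata attached to the volume.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path, study_index = 0L, study_date = NULL,
                              patient_id = "P0") {
  nii <- read_nifti(path)
  grid <- image_grid(dim(nii$data), spacing = nii$spacing, affine = nii$affine)
  label_volume(nii$data, grid, study_index = study_index,
               study_date = study_date, patient_id = patient_id)
}

#' Write a label volume as NIfTI-1
#'
#' @param vol a [label_volume()].
#' @param path output path; a `.gz` suffix selects gzip compression.
#' @return The path, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  write_nifti(vol$data, vol$grid$affine, vol$grid$spacing, path)
}

#' Resample a label volume onto a reference grid
#'
#' Nearest-neighbor pull-back resampling: every voxel of `ref` is mapped
#' through `ref$affine` to physical space and back through the inverse of
#' the source affine; the nearest source voxel supplies the label (0 outside
#' the source field of view). Labels are categorical, so no interpolation or
#' partial-volume handling is performed, and the output label set is always
#' a subset of the input's. Registration proper is out of scope: volumes are
#' assumed co-registered through their stored affines.
#'
#' @param vol a [label_volume()].
#' @param ref target [image_grid()].
#' @return A [label_volume()] on `ref`.
#' @export
resample_labels <- function(vol, ref) {
  stopifnot(inherits(vol, "label_volume"), inherits(ref, "image_grid"))
  if (grids_equal(vol$grid, ref)) {
    out <- vol
    out$grid <- ref
    return(out)
  }
  M <- solve(vol$grid$affine) %*% ref$affine   # ref voxel -> source voxel
  sh <- ref$shape
  ijk <- cbind(
    rep.int(seq_len(sh[1]) - 1L, sh[2] * sh[3]),
    rep.int(rep(seq_len(sh[2]) - 1L, each = sh[1]), sh[3]),
    rep(seq_len(sh[3]) - 1L, each = sh[1] * sh[2])
  )
  src <- ijk %*% t(M[1:3, 1:3])
  src <- sweep(src, 2L, M[1:3, 4], "+")
  src <- round(src)
  inb <- src[, 1] >= 0 & src[, 1] < dim(vol$data)[1] &
         src[, 2] >= 0 & src[, 2] < dim(vol$data)[2] &
         src[, 3] >= 0 & src[, 3] < dim(vol$data)[3]
  vals <- integer(nrow(src))
  if (any(inb)) {
    lin <- src[inb, 1] + dim(vol$data)[1] * (src[inb, 2] + dim(vol$data)[2] * src[inb, 3])
    vals[inb] <- vol$data[lin + 1]
  }
  label_volume(array(vals, dim = sh), ref, study_index = vol$study_index,
               study_date = vol$study_date, patient_id = vol$patient_id)
}
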