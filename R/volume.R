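#' 3-D image volume with physical geometry
#'
#' The raster currency of the pipeline: a 3-D scalar array together with the
#' voxel spacing (mm), the world position of voxel `(1,1,1)` (mm) and the
#' direction matrix mapping array axes to patient axes. World coordinates are
#' right-anterior-superior (RAS) millimetres and refer to voxel centres.
#'
#' @param data 3-D numeric array.
#' @param spacing Numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin Numeric length-3, world coordinate (mm) of voxel `(1,1,1)`.
#' @param orientation 3x3 direction matrix; column k is the unit world
#'   direction along array axis k. Defaults to the identity (axis-aligned RAS).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         orientation = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    am_stop(sprintf("`data` must be a 3-D array, got dimensions [%s]",
                    paste(dim(data), collapse = ", ")),
            "arterymap_dim_error")
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    am_stop("`spacing` must be 3 strictly positive finite values",
            "arterymap_argument_error")
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    am_stop("`origin` must be 3 finite values", "arterymap_argument_error")
  }
  orientation <- matrix(as.numeric(orientation), 3, 3)
  structure(
    list(data = data, spacing = spacing, origin = origin,
         orientation = orientation),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  origin (mm): ", paste(signif(x$origin, 6), collapse = ", "), "\n",
      sep = "")
  rng <- range(x$data)
  cat("  intensity range: [", signif(rng[1], 6), ", ", signif(rng[2], 6),
      "]\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' World coordinates of voxel indices
#'
#' Maps 1-based voxel indices to RAS world coordinates (mm) via
#' `origin + orientation %*% diag(spacing) %*% (ijk - 1)`.
#'
#' @param volume An [image_volume()].
#' @param ijk Integer matrix (n x 3) of 1-based voxel indices.
#' @return Numeric matrix (n x 3) of world coordinates in mm.
#' @export
voxel_to_world <- function(volume, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(ijk - 1, 2, volume$spacing, `*`) %*% t(volume$orientation) +
    matrix(volume$origin, nrow(ijk), 3, byrow = TRUE)
}

#' Inverse of [voxel_to_world()]
#' @inheritParams voxel_to_world
#' @param xyz Numeric matrix (n x 3) of world coordinates (mm).
#' @return Numeric matrix (n x 3) of fractional 1-based voxel indices.
#' @export
world_to_voxel <- function(volume, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  rel <- (xyz - matrix(volume$origin, nrow(xyz), 3, byrow = TRUE)) %*%
    volume$orientation   # orientation is orthonormal: inverse = transpose
  sweep(rel, 2, volume$spacing, `/`) + 1
}

#' Read a NIfTI-1 volume
#'
#' Reads a `.nii`/`.nii.gz` file into an [image_volume()]. Spacing, origin and
#' axis orientation are derived from the file's xform affine (NIfTI affines
#' are already RAS). Integer intensities are preserved bit-exactly.
#'
#' @param path Path to a NIfTI-1 file.
#' @return An [image_volume()].
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) {
    am_stop(sprintf("file not found: %s", path), "arterymap_format_error")
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) {
                    am_stop(sprintf("not a readable NIfTI file: %s (%s)",
                                    path, conditionMessage(e)),
                            "arterymap_format_error")
                  })
  arr <- as.array(img)
  d <- dim(arr)
  # trailing singleton dimensions (e.g. 3-D data stored as X x Y x Z x 1) are
  # tolerated; true 4-D data is rejected.
  if (length(d) > 3L && all(d[-(1:3)] == 1L)) {
    arr <- array(arr, dim = d[1:3])
    d <- dim(arr)
  }
  if (length(d) != 3L) {
    am_stop(sprintf("expected a 3-D volume, got dimensions [%s]",
                    paste(d, collapse = ", ")),
            "arterymap_dim_error")
  }
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3, drop = FALSE]
  spacing <- sqrt(colSums(rot^2))
  if (any(spacing <= 0)) {
    am_stop("degenerate affine: zero-length axis", "arterymap_format_error")
  }
  orientation <- sweep(rot, 2, spacing, `/`)
  image_volume(arr, spacing = spacing, origin = aff[1:3, 4],
               orientation = orientation)
}

#' Write an [image_volume()] to NIfTI-1
#'
#' @param volume An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype Passed to [RNifti::writeNifti()]; `"auto"` keeps the
#'   storage mode of `data`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, datatype = "auto") {
  stopifnot(inherits(volume, "image_volume"))
  aff <- diag(4)
  aff[1:3, 1:3] <- volume$orientation %*% diag(volume$spacing)
  aff[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(volume$data)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Maximum intensity projection
#'
#' Collapses a volume along one array axis by taking the per-ray maximum,
#' the standard rendering used to verify which arteries an angiographic
#' volume contains.
#'
#' @param volume An [image_volume()].
#' @param axis Array axis to project along (1, 2 or 3).
#' @return A 2-D numeric matrix over the two remaining axes (in order).
#' @export
maximum_intensity_projection <- function(volume, axis = 3) {
  stopifnot(inherits(volume, "image_volume"))
  if (!(length(axis) == 1L && axis %in% 1:3)) {
    am_stop("`axis` must be 1, 2 or 3", "arterymap_argument_error")
  }
  apply(volume$data, setdiff(1:3, axis), max)
}

#' Write a maximum intensity projection as PNG
#'
#' Intensities are linearly rescaled to `[0, 1]` over the projection's range.
#'
#' @inheritParams maximum_intensity_projection
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mip_png <- function(volume, path, axis = 3) {
  mip <- maximum_intensity_projection(volume, axis)
  rng <- range(mip)
  img <- if (diff(rng) > 0) (mip - rng[1]) / diff(rng) else mip * 0
  # array axis 1 runs along PNG columns; flip so the second axis points up
  png::writePNG(t(img)[rev(seq_len(ncol(img))), , drop = FALSE], path)
  invisible(path)
}
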