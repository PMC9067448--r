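#' Binary voxel mask
#'
#' Boolean 3-D mask on the grid of a source volume, carrying the source
#' geometry and a provenance record of the parameters that produced it.
#'
#' @param data 3-D logical array.
#' @param spacing,origin,orientation Grid geometry (see [image_volume()]).
#' @param provenance Named list describing how the mask was produced.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        orientation = diag(3), provenance = list()) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    am_stop("`data` must be a 3-D array", "arterymap_dim_error")
  }
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 orientation = matrix(as.numeric(orientation), 3, 3),
                 provenance = provenance),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

#' @export
dim.binary_mask <- function(x) dim(x$data)

same_grid <- function(a, b, tol = 1e-9) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$orientation - b$orientation)) <= tol
}

#' Threshold a vesselness map into a vessel mask
#'
#' Foreground is every voxel whose response is at least `threshold`.
#'
#' @param vness A `vesselness_map` from [multiscale_vesselness()].
#' @param threshold Scalar in the open interval (0, 1), or `"auto"` for an
#'   Otsu threshold of the positive responses.
#' @return A [binary_mask()].
#' @export
threshold_segment <- function(vness, threshold = 0.5) {
  stopifnot(inherits(vness, "vesselness_map"))
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(vness$response[vness$response > 0])
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    am_stop("`threshold` must lie strictly inside (0, 1)",
            "arterymap_argument_error")
  }
  binary_mask(vness$response >= threshold, vness$spacing, vness$origin,
              vness$orientation,
              provenance = list(source = "threshold_segment",
                                threshold = threshold))
}

#' Otsu's threshold for a sample of intensities
#'
#' Maximizes the between-class variance on a fixed-bin histogram.
#'
#' @param values Numeric vector.
#' @param nbins Number of histogram bins.
#' @return Threshold on the scale of `values`.
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0 || diff(range(values)) == 0) {
    am_stop("cannot threshold a constant sample", "arterymap_argument_error")
  }
  rng <- range(values)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(values, br, rightmost.closed = TRUE),
                           nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  total_w <- w[nbins]
  total_m <- m[nbins]
  w0 <- w[-nbins]; m0 <- m[-nbins]
  w1 <- total_w - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins - 1L)
  between[valid] <- (total_m * w0[valid] - m0[valid] * total_w)^2 /
    (w0[valid] * w1[valid])
  br[which.max(between) + 1L]
}

#' Euclidean distance transform (mm)
#'
#' Exact spacing-aware distance of every voxel to the nearest `TRUE` voxel.
#'
#' @param seed 3-D logical array of seed voxels.
#' @param spacing Per-axis voxel size in mm.
#' @return 3-D numeric array of distances in mm (`Inf` when no seed exists).
#' @export
distance_transform <- function(seed, spacing = c(1, 1, 1)) {
  stopifnot(is.array(seed), length(dim(seed)) == 3L)
  d2 <- cpp_edt_squared(as.logical(seed), as.integer(dim(seed)),
                        as.numeric(spacing))
  array(sqrt(d2), dim(seed))
}

#' Label connected components of a mask
#'
#' @param mask 3-D logical array.
#' @param connectivity 26 (default) or 6.
#' @return 3-D integer array of component labels (0 = background), numbered
#'   in deterministic lexicographic discovery order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L,
            connectivity %in% c(6L, 26L))
  array(cpp_label_components(as.logical(mask), as.integer(dim(mask)),
                             as.integer(connectivity)),
        dim(mask))
}

# ball closing and hole filling used for the head mask
close_and_fill <- function(mask, spacing, closing_mm) {
  if (closing_mm > 0) {
    grown <- distance_transform(mask, spacing) <= closing_mm
    mask <- distance_transform(!grown, spacing) > closing_mm
  }
  # fill internal cavities: background components not touching the border
  bg <- label_components(!mask, connectivity = 6L)
  border_labels <- unique(c(bg[1, , ], bg[dim(bg)[1], , ], bg[, 1, ],
                            bg[, dim(bg)[2], ], bg[, , 1], bg[, , dim(bg)[3]]))
  border_labels <- border_labels[border_labels > 0]
  mask | (bg > 0 & !(bg %in% border_labels))
}

#' Subcutaneous band mask
#'
#' Builds the shell of tissue between the skin surface and a given depth --
#' the region to which the superficial arterial model is restricted. The head
#' is segmented as the largest connected component above an automatic (Otsu)
#' intensity threshold, morphologically closed and hole-filled; the band is
#' every head voxel whose spacing-aware Euclidean distance to the outside
#' falls within `band_depth_mm`. A positive `skin_margin_mm` additionally
#' excludes the outermost shell (the cutis itself, where the air-tissue
#' boundary dominates the image and no subcutaneous artery runs).
#'
#' @param volume An [image_volume()] containing a bright head on a dark
#'   background.
#' @param band_depth_mm Band depth below the skin surface, in mm.
#' @param closing_mm Radius of the morphological ball closing, in mm.
#' @param skin_margin_mm Depth of the excluded skin shell, in mm (default 0:
#'   the band starts at the surface).
#' @return A [binary_mask()].
#' @export
subcutaneous_band_mask <- function(volume, band_depth_mm = 15,
                                   closing_mm = 2, skin_margin_mm = 0) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.numeric(band_depth_mm) || band_depth_mm <= 0) {
    am_stop("`band_depth_mm` must be positive", "arterymap_argument_error")
  }
  vals <- as.numeric(volume$data)
  if (diff(range(vals)) == 0) {
    am_stop("volume is constant; no head object found",
            "arterymap_segmentation_failure")
  }
  thr <- otsu_threshold(vals)
  raw <- volume$data > thr
  if (!any(raw)) {
    am_stop("no voxels above the automatic head threshold",
            "arterymap_segmentation_failure")
  }
  lab <- label_components(raw, 26L)
  counts <- tabulate(lab[lab > 0])
  head_mask <- lab == which.max(counts)
  head_mask <- close_and_fill(head_mask, volume$spacing, closing_mm)
  depth <- distance_transform(!head_mask, volume$spacing)
  band <- head_mask & depth <= band_depth_mm & depth > skin_margin_mm
  binary_mask(band, volume$spacing, volume$origin, volume$orientation,
              provenance = list(source = "subcutaneous_band_mask",
                                band_depth_mm = band_depth_mm,
                                closing_mm = closing_mm,
                                skin_margin_mm = skin_margin_mm,
                                head_threshold = thr))
}

#' Restrict a vessel mask to the subcutaneous band
#'
#' Intersects the vessel mask with the band and removes 26-connected
#' components smaller than `min_component_voxels` -- the separation step that
#' keeps only the superficial arterial network.
#'
#' @param vessel_mask,band [binary_mask()]s on the same grid.
#' @param min_component_voxels Minimum surviving component size in voxels.
#' @return A [binary_mask()].
#' @export
separate_superficial <- function(vessel_mask, band,
                                 min_component_voxels = 20L) {
  stopifnot(inherits(vessel_mask, "binary_mask"), inherits(band, "binary_mask"))
  if (!same_grid(vessel_mask, band)) {
    am_stop("vessel mask and band are on different grids",
            "arterymap_geometry_error")
  }
  inter <- vessel_mask$data & band$data
  if (min_component_voxels > 1L && any(inter)) {
    lab <- label_components(inter, 26L)
    counts <- tabulate(lab[lab > 0])
    keep <- which(counts >= min_component_voxels)
    inter <- lab %in% keep & inter
    inter <- array(inter, dim(vessel_mask$data))
  }
  binary_mask(inter, vessel_mask$spacing, vessel_mask$origin,
              vessel_mask$orientation,
              provenance = list(source = "separate_superficial",
                                min_component_voxels = min_component_voxels))
}
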