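#' Read a DICOM series directory into a volume
#'
#' Minimal reader for single-frame DICOM slice files in the explicit-VR
#' little-endian transfer syntax (the uncompressed interchange form). Slices
#' are sorted by their through-plane position (projection of
#' ImagePositionPatient onto the slice normal), the inter-slice distance is
#' required to be uniform, and the DICOM LPS frame is converted to the
#' package's RAS world frame on read.
#'
#' @param directory Directory containing exactly one series of slice files.
#' @param gap_tolerance_mm Maximum allowed deviation of individual slice gaps
#'   from their median, in mm.
#' @return An [image_volume()] whose array axes are (column, row, slice).
#' @export
read_dicom_series <- function(directory, gap_tolerance_mm = 0.01) {
  if (!dir.exists(directory)) {
    am_stop(sprintf("not a directory: %s", directory), "arterymap_format_error")
  }
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) {
    am_stop("directory contains no files", "arterymap_format_error")
  }
  slices <- lapply(sort(files), parse_dicom_file)
  uids <- vapply(slices, function(s) s$series_uid, character(1))
  if (length(unique(uids)) != 1L) {
    am_stop(sprintf("directory mixes %d series (UIDs: %s)",
                    length(unique(uids)), paste(unique(uids), collapse = ", ")),
            "arterymap_ambiguity_error")
  }
  iop <- slices[[1]]$orientation
  col_dir <- iop[1:3]  # direction of increasing column index
  row_dir <- iop[4:6]  # direction of increasing row index
  normal <- c(col_dir[2] * row_dir[3] - col_dir[3] * row_dir[2],
              col_dir[3] * row_dir[1] - col_dir[1] * row_dir[3],
              col_dir[1] * row_dir[2] - col_dir[2] * row_dir[1])
  pos <- vapply(slices, function(s) sum(s$position * normal), numeric(1))
  ord <- order(pos)
  slices <- slices[ord]
  pos <- pos[ord]
  if (length(slices) > 1L) {
    gaps <- diff(pos)
    if (any(gaps <= 0)) {
      am_stop("duplicate or non-increasing slice positions",
              "arterymap_spacing_error")
    }
    if (max(abs(gaps - stats::median(gaps))) > gap_tolerance_mm) {
      am_stop(sprintf("non-uniform slice gaps (range %.4f-%.4f mm)",
                      min(gaps), max(gaps)),
              "arterymap_spacing_error")
    }
    sz <- stats::median(gaps)
  } else {
    sz <- slices[[1]]$slice_thickness %||% 1
  }
  nc <- slices[[1]]$cols
  nr <- slices[[1]]$rows
  arr <- array(0, dim = c(nc, nr, length(slices)))
  for (k in seq_along(slices)) {
    s <- slices[[k]]
    if (s$cols != nc || s$rows != nr) {
      am_stop("slices disagree on matrix size", "arterymap_format_error")
    }
    # pixel data is stored row by row, column index varying fastest
    arr[, , k] <- matrix(s$pixels, nrow = nc)
  }
  # LPS -> RAS: negate the first two world components
  flip <- c(-1, -1, 1)
  orientation <- cbind(col_dir * flip, row_dir * flip, normal * flip)
  origin <- slices[[1]]$position * flip
  spacing <- c(slices[[1]]$pixel_spacing[2],  # column spacing
               slices[[1]]$pixel_spacing[1],  # row spacing
               sz)
  image_volume(arr, spacing = spacing, origin = origin,
               orientation = orientation)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- minimal explicit-VR little-endian DICOM element parser -----------------

.dcm_long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM") {
    am_stop(sprintf("%s: missing DICM magic (not a part-10 DICOM file)", path),
            "arterymap_format_error")
  }
  pos <- 133L
  n <- length(raw)
  u16 <- function(at) sum(as.integer(raw[at + 0:1]) * c(1L, 256L))
  u32 <- function(at) sum(as.numeric(raw[at + 0:3]) * 256^(0:3))
  wanted <- list()
  transfer_syntax <- NULL
  while (pos + 7 <= n) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(raw[pos + 4:5])
    if (!grepl("^[A-Z]{2}$", vr)) {
      am_stop(sprintf("%s: implicit VR or corrupt element at offset %d; only explicit VR little endian is supported",
                      path, pos - 1L),
              "arterymap_format_error")
    }
    if (vr %in% .dcm_long_vrs) {
      len <- u32(pos + 8L); hdr <- 12L
    } else {
      len <- u16(pos + 6L); hdr <- 8L
    }
    if (len == 4294967295) {
      am_stop(sprintf("%s: undefined-length element (%04x,%04x) unsupported",
                      path, group, elem),
              "arterymap_format_error")
    }
    body <- pos + hdr
    key <- sprintf("%04x,%04x", group, elem)
    if (key == "0002,0010") {
      transfer_syntax <- sub("\\0+$", "", rawToChar(raw[body:(body + len - 1L)]))
    }
    if (key %in% c("0020,000e", "0020,0032", "0020,0037", "0028,0010",
                   "0028,0011", "0028,0030", "0028,0100", "0028,0103",
                   "0018,0050", "7fe0,0010")) {
      wanted[[key]] <- list(vr = vr, bytes = raw[body:(body + len - 1L)])
    }
    pos <- body + len
  }
  if (!is.null(transfer_syntax) && transfer_syntax != "1.2.840.10008.1.2.1") {
    am_stop(sprintf("%s: unsupported transfer syntax %s", path, transfer_syntax),
            "arterymap_format_error")
  }
  str_of <- function(key) {
    v <- wanted[[key]]
    if (is.null(v)) return(NULL)
    trimws(sub("\\0+$", "", rawToChar(v$bytes)))
  }
  nums_of <- function(key) {
    s <- str_of(key)
    if (is.null(s)) return(NULL)
    as.numeric(strsplit(s, "\\\\")[[1]])
  }
  us_of <- function(key) {
    v <- wanted[[key]]
    if (is.null(v)) return(NULL)
    readBin(v$bytes, "integer", size = 2, signed = FALSE, endian = "little")
  }
  need <- function(x, what) {
    if (is.null(x)) {
      am_stop(sprintf("%s: missing required DICOM attribute %s", path, what),
              "arterymap_format_error")
    }
    x
  }
  rows <- need(us_of("0028,0010"), "Rows")
  cols <- need(us_of("0028,0011"), "Columns")
  bits <- need(us_of("0028,0100"), "BitsAllocated")
  signed <- (us_of("0028,0103") %||% 0L) == 1L
  if (!bits %in% c(8L, 16L)) {
    am_stop(sprintf("%s: unsupported BitsAllocated %d", path, bits),
            "arterymap_format_error")
  }
  px <- need(wanted[["7fe0,0010"]], "PixelData")$bytes
  pixels <- readBin(px, "integer", n = rows * cols, size = bits / 8L,
                    signed = if (bits == 8L) FALSE else signed,
                    endian = "little")
  if (bits == 16L && !signed) pixels <- ifelse(pixels < 0, pixels + 65536, pixels)
  list(
    series_uid = need(str_of("0020,000e"), "SeriesInstanceUID"),
    position = need(nums_of("0020,0032"), "ImagePositionPatient"),
    orientation = need(nums_of("0020,0037"), "ImageOrientationPatient"),
    pixel_spacing = need(nums_of("0028,0030"), "PixelSpacing"),
    slice_thickness = {
      st <- nums_of("0018,0050"); if (is.null(st)) NULL else st[1]
    },
    rows = rows, cols = cols, pixels = pixels
  )
}
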