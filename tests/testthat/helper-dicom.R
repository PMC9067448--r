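# Minimal synthetic DICOM slice writer (explicit VR little endian) used to
# exercise the series reader without shipping binary fixtures.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_element <- function(group, elem, vr, payload) {
  if (length(payload) %% 2 == 1) {
    payload <- c(payload, if (vr %in% c("UI", "OB")) as.raw(0) else charToRaw(" "))
  }
  hdr <- c(dcm_u16(group), dcm_u16(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UT", "UN")) {
    c(hdr, as.raw(c(0, 0)), dcm_u32(length(payload)), payload)
  } else {
    c(hdr, dcm_u16(length(payload)), payload)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_element(group, elem, vr, charToRaw(s))
dcm_us <- function(group, elem, x) dcm_element(group, elem, "US", dcm_u16(x))

write_test_dicom_slice <- function(path, pixels, rows, cols,
                                   position = c(0, 0, 0),
                                   orientation = c(1, 0, 0, 0, 1, 0),
                                   pixel_spacing = c(1, 1),
                                   series_uid = "1.2.3.4",
                                   slice_thickness = 1) {
  ds <- function(v) paste(format(v, trim = TRUE, scientific = FALSE), collapse = "\\")
  px <- writeBin(as.integer(pixels), raw(), size = 2, endian = "little")
  meta <- c(
    dcm_element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  )
  body <- c(
    dcm_str(0x0018, 0x0050, "DS", ds(slice_thickness)),
    dcm_str(0x0020, 0x000E, "UI", series_uid),
    dcm_str(0x0020, 0x0032, "DS", ds(position)),
    dcm_str(0x0020, 0x0037, "DS", ds(orientation)),
    dcm_us(0x0028, 0x0010, rows),
    dcm_us(0x0028, 0x0011, cols),
    dcm_str(0x0028, 0x0030, "DS", ds(pixel_spacing)),
    dcm_us(0x0028, 0x0100, 16),
    dcm_us(0x0028, 0x0103, 0),
    dcm_element(0x7FE0, 0x0010, "OW", px)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# write a whole synthetic series; slice k holds value base + k
write_test_dicom_series <- function(dir, n_slices = 5, rows = 6, cols = 4,
                                    slice_gap = 1, series_uid = "1.2.3.4",
                                    shuffle_names = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  order_tag <- if (shuffle_names) rev(seq_len(n_slices)) else seq_len(n_slices)
  for (k in seq_len(n_slices)) {
    pixels <- matrix(k * 10 + seq_len(rows * cols), nrow = rows, byrow = TRUE)
    # pixel data row by row
    write_test_dicom_slice(
      file.path(dir, sprintf("slice_%02d.dcm", order_tag[k])),
      pixels = as.integer(t(pixels)),
      rows = rows, cols = cols,
      position = c(0, 0, (k - 1) * slice_gap),
      pixel_spacing = c(1, 1),
      series_uid = series_uid,
      slice_thickness = slice_gap
    )
  }
  invisible(dir)
}
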