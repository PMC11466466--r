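# Minimal explicit-VR little-endian DICOM slice writer for reader tests.

write_test_dicom_slice <- function(file, stored, uid, ipp,
                                   iop = c(1, 0, 0, 0, 1, 0),
                                   pixel_spacing = c(1, 1),
                                   slope = 1, intercept = 0) {
  con <- file(file, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  pad_even <- function(x) if (length(x) %% 2L) c(x, charToRaw(" ")) else x
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  short_tag <- function(g, e, vr, payload) {
    payload <- pad_even(payload)
    w16(c(g, e))
    writeChar(vr, con, eos = NULL)
    w16(length(payload))
    writeBin(payload, con)
  }
  ds <- function(v) charToRaw(paste(format(v, trim = TRUE, scientific = FALSE),
                                    collapse = "\\"))
  us <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "little")
  short_tag(0x0020, 0x000E, "UI", charToRaw(uid))
  short_tag(0x0020, 0x0032, "DS", ds(ipp))
  short_tag(0x0020, 0x0037, "DS", ds(iop))
  short_tag(0x0028, 0x0010, "US", us(nrow(stored)))   # Rows
  short_tag(0x0028, 0x0011, "US", us(ncol(stored)))   # Columns
  short_tag(0x0028, 0x0030, "DS", ds(pixel_spacing))
  short_tag(0x0028, 0x0100, "US", us(16))
  short_tag(0x0028, 0x0103, "US", us(1))
  short_tag(0x0028, 0x1052, "DS", ds(intercept))
  short_tag(0x0028, 0x1053, "DS", ds(slope))
  # PixelData, OW long form; row-major (column index fastest)
  px <- writeBin(as.integer(t(stored)), raw(), size = 2L, endian = "little")
  w16(c(0x7FE0, 0x0010))
  writeChar("OW", con, eos = NULL)
  w16(0)
  writeBin(as.integer(length(px)), con, size = 4L, endian = "little")
  writeBin(px, con)
  invisible(file)
}

# stored: rows x cols matrices per slice
write_test_dicom_series <- function(dir, slices, spacing = c(1, 1),
                                    dz = 2, uid = "1.2.3.4",
                                    slope = 1, intercept = -1000) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(slices)) {
    write_test_dicom_slice(file.path(dir, sprintf("slice%02d.dcm", k)),
                           slices[[k]], uid = uid,
                           ipp = c(0, 0, (k - 1) * dz),
                           pixel_spacing = spacing,
                           slope = slope, intercept = intercept)
  }
  dir
}
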