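# Minimal DICOM part-10 writer (explicit VR little endian) used only to
# build test fixtures for the series reader. Writes single-frame 16-bit
# unsigned grayscale slices with the geometry tags the reader consumes.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_elem <- function(group, elem, vr, body) {
  if (is.character(body)) {
    body <- charToRaw(body)
    if (length(body) %% 2 == 1) body <- c(body, charToRaw(" "))
  }
  long <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  c(dcm_u16(group), dcm_u16(elem), charToRaw(vr),
    if (long) c(as.raw(c(0, 0)), dcm_u32(length(body))) else dcm_u16(length(body)),
    body)
}

dcm_ds <- function(v) paste(formatC(v, digits = 10, format = "g"), collapse = "\\")

# pixels: columns x rows integer matrix (x fastest, like the package volume)
write_dicom_slice <- function(path, pixels, ipp, iop = c(1, 0, 0, 0, 1, 0),
                              pixel_spacing = c(1, 1),
                              series_uid = "1.2.3.4.5") {
  cols <- nrow(pixels); rows <- ncol(pixels)
  px <- writeBin(as.integer(as.vector(pixels)), raw(), size = 2, endian = "little")
  meta <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_elem(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"))
  body <- c(
    dcm_elem(0x0008, 0x0060, "CS", "CT"),
    dcm_elem(0x0018, 0x0050, "DS", dcm_ds(1)),
    dcm_elem(0x0020, 0x000e, "UI", series_uid),
    dcm_elem(0x0020, 0x0032, "DS", dcm_ds(ipp)),
    dcm_elem(0x0020, 0x0037, "DS", dcm_ds(iop)),
    dcm_elem(0x0028, 0x0010, "US", dcm_u16(rows)),
    dcm_elem(0x0028, 0x0011, "US", dcm_u16(cols)),
    dcm_elem(0x0028, 0x0030, "DS", dcm_ds(pixel_spacing)),
    dcm_elem(0x0028, 0x0100, "US", dcm_u16(16)),
    dcm_elem(0x0028, 0x0103, "US", dcm_u16(0)),
    dcm_elem(0x7fe0, 0x0010, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# write an n-slice series of a small volume (LPS geometry, axial slices)
write_dicom_series <- function(dir, vox, spacing = c(1, 1, 1),
                               origin_lps = c(0, 0, 0), series_uid = "1.2.3.4.5") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_len(dim(vox)[3])) {
    write_dicom_slice(file.path(dir, sprintf("slice%03d.dcm", k)),
                      pixels = vox[, , k],
                      ipp = origin_lps + c(0, 0, (k - 1) * spacing[3]),
                      pixel_spacing = spacing[c(2, 1)],
                      series_uid = series_uid)
  }
  invisible(dir)
}
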