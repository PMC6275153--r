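# Minimal DICOM series reader.
#
# Scope: uncompressed, single-frame, explicit-VR little-endian CT-like slices
# (transfer syntax 1.2.840.10008.1.2.1), which is what cone-beam machines
# export for the volumes this package consumes. Sequences are skipped, pixel
# data must be 8/16-bit grayscale. Geometry follows the DICOM patient-based
# LPS convention and is converted to the package's internal frame on ingest.

.tag <- function(group, element) sprintf("%04x,%04x", group, element)

# VRs with a 2-byte reserved field and 4-byte length in explicit VR
.long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop_parse(sprintf("%s: not a DICOM part-10 file", basename(path)))
  pos <- 133L
  n <- length(raw)
  elems <- list()
  u16 <- function(b) as.integer(b[1]) + 256L * as.integer(b[2])
  u32 <- function(b) u16(b[1:2]) + 65536 * u16(b[3:4])
  while (pos + 7 <= n) {
    group <- u16(raw[pos:(pos + 1)]); elem <- u16(raw[(pos + 2):(pos + 3)])
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop_parse(sprintf("%s: implicit-VR or corrupt element at offset %d; only explicit VR little endian is supported",
                         basename(path), pos - 1))
    if (vr %in% .long_vrs) {
      len <- u32(raw[(pos + 8):(pos + 11)]); hdr <- 12L
    } else {
      len <- u16(raw[(pos + 6):(pos + 7)]); hdr <- 8L
    }
    if (vr == "SQ" || len == 4294967295) {  # skip sequences / undefined length
      pos <- pos + hdr
      # scan for sequence delimitation item (fffe,e0dd)
      repeat {
        if (pos + 7 > n) stop_parse("unterminated sequence")
        if (u16(raw[pos:(pos + 1)]) == 0xfffe && u16(raw[(pos + 2):(pos + 3)]) == 0xe0dd) {
          pos <- pos + 8L; break
        }
        pos <- pos + 2L
      }
      next
    }
    body <- if (len > 0) raw[(pos + hdr):(pos + hdr + len - 1)] else raw(0)
    elems[[.tag(group, elem)]] <- list(vr = vr, bytes = body)
    pos <- pos + hdr + len
  }
  elems
}

.dcm_str <- function(elems, tag) {
  e <- elems[[tag]]
  if (is.null(e)) return(NULL)
  trimws(rawToChar(e$bytes))
}

.dcm_ds <- function(elems, tag) {
  s <- .dcm_str(elems, tag)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dcm_us <- function(elems, tag) {
  e <- elems[[tag]]
  if (is.null(e)) return(NULL)
  readBin(e$bytes, "integer", n = length(e$bytes) / 2, size = 2,
          endian = "little", signed = FALSE)
}

#' Read one DICOM series from a directory
#'
#' Reads every readable DICOM file in \code{dir}, checks that all slices
#' belong to one series with consistent orientation and uniform slice
#' spacing, sorts slices along the slice normal and assembles them into a
#' \code{\link{cf_volume}} in the internal world convention.
#'
#' @param dir directory containing one DICOM series.
#' @return A \code{cf_volume}.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop_header(sprintf("no files in %s", dir))
  slices <- lapply(files, read_dicom_file)

  uid <- unique(vapply(slices, function(e) .dcm_str(e, .tag(0x0020, 0x000e)) %||% "",
                       character(1)))
  if (length(uid) > 1)
    stop_mixed_series(sprintf("directory mixes %d series", length(uid)))

  iops <- lapply(slices, function(e) .dcm_ds(e, .tag(0x0020, 0x0037)))
  if (any(vapply(iops, is.null, logical(1))))
    stop_header("slice lacks ImageOrientationPatient")
  iop0 <- iops[[1]]
  if (any(vapply(iops, function(v) max(abs(v - iop0)), numeric(1)) > 1e-4))
    stop_mixed_series("slices have inconsistent orientation tags")

  ps <- .dcm_ds(slices[[1]], .tag(0x0028, 0x0030))
  if (is.null(ps) || length(ps) != 2 || any(!is.finite(ps)) || any(ps <= 0))
    stop_header("missing or invalid PixelSpacing")
  rows <- .dcm_us(slices[[1]], .tag(0x0028, 0x0010))
  cols <- .dcm_us(slices[[1]], .tag(0x0028, 0x0011))
  bits <- .dcm_us(slices[[1]], .tag(0x0028, 0x0100)) %||% 16L
  signed <- (.dcm_us(slices[[1]], .tag(0x0028, 0x0103)) %||% 0L) == 1L
  if (is.null(rows) || is.null(cols)) stop_header("missing Rows/Columns")
  if (!bits %in% c(8L, 16L)) stop_header("only 8/16-bit pixel data supported")

  row_dir <- iop0[1:3]; col_dir <- iop0[4:6]        # LPS direction cosines
  normal <- c(row_dir[2] * col_dir[3] - row_dir[3] * col_dir[2],
              row_dir[3] * col_dir[1] - row_dir[1] * col_dir[3],
              row_dir[1] * col_dir[2] - row_dir[2] * col_dir[1])
  ipps <- lapply(slices, function(e) .dcm_ds(e, .tag(0x0020, 0x0032)))
  if (any(vapply(ipps, is.null, logical(1))))
    stop_header("slice lacks ImagePositionPatient")
  zpos <- vapply(ipps, function(p) sum(p * normal), numeric(1))
  ord <- order(zpos)
  slices <- slices[ord]; ipps <- ipps[ord]; zpos <- zpos[ord]
  nz <- length(slices)
  slice_sp <- if (nz > 1) diff(zpos) else
    (.dcm_ds(slices[[1]], .tag(0x0018, 0x0050)) %||% 1)
  if (nz > 1 && (any(slice_sp <= 0) || diff(range(slice_sp)) > 1e-4))
    stop_mixed_series("non-uniform slice spacing in series")
  slice_sp <- slice_sp[1]

  vox <- array(0, dim = c(cols, rows, nz))
  npix <- as.numeric(rows) * cols
  for (s in seq_len(nz)) {
    pd <- slices[[s]][[.tag(0x7fe0, 0x0010)]]
    if (is.null(pd)) stop_header("slice lacks PixelData")
    vals <- readBin(pd$bytes, "integer", n = npix, size = bits / 8,
                    endian = "little", signed = if (bits == 8) signed else signed)
    if (bits == 16 && !signed) vals <- ifelse(vals < 0, vals + 65536, vals)
    vox[, , s] <- vals   # stream is row-major: column index varies fastest
  }

  lps_axes <- cbind(row_dir, col_dir, normal)
  lps_origin <- ipps[[1]]
  # LPS -> internal (X left+, Y anterior+, Z superior+): flip the P axis
  D <- diag(c(1, -1, 1))
  cf_volume(vox, spacing = c(ps[2], ps[1], slice_sp),
            origin = as.numeric(D %*% lps_origin),
            axes = D %*% lps_axes)
}
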