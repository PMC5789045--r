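# Minimal DICOM reader for the real-data input path: uncompressed
# single-frame grayscale files in implicit or explicit VR little endian.
# Only the handful of tags the pipeline needs are interpreted; everything
# else is skipped by length. Sequences with undefined length and compressed
# transfer syntaxes are rejected.

.u16 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}

.u32 <- function(raw, off) {
  as.integer(raw[off + 1]) + 256 * as.integer(raw[off + 2]) +
    65536 * as.integer(raw[off + 3]) + 16777216 * as.integer(raw[off + 4])
}

# VRs carrying a 2-byte reserved field and a 4-byte length in explicit VR
.long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.parse_dicom_elements <- function(raw, off, explicit, stop_group = NULL) {
  n <- length(raw)
  out <- list()
  while (off < n) {
    if (off + 8 > n) break
    group <- .u16(raw, off)
    elem <- .u16(raw, off + 2)
    if (!is.null(stop_group) && group != stop_group) break
    if (explicit) {
      vr <- rawToChar(raw[(off + 5):(off + 6)])
      if (vr %in% .long_vrs) {
        len <- .u32(raw, off + 8)
        hdr <- 12L
      } else {
        len <- .u16(raw, off + 6)
        hdr <- 8L
      }
    } else {
      vr <- NA_character_
      len <- .u32(raw, off + 4)
      hdr <- 8L
    }
    if (len == 4294967295)
      stop("DICOM elements with undefined length are not supported")
    key <- sprintf("%04x,%04x", group, elem)
    out[[key]] <- list(off = off + hdr, len = len, vr = vr)
    off <- off + hdr + len
    if (!is.null(stop_group) && group == stop_group && elem == 0L) {
      # group length element: keep going, groups checked per element
    }
  }
  list(elements = out, off = off)
}

.dicom_string <- function(raw, el) {
  if (is.null(el) || el$len == 0) return(NA_character_)
  bytes <- raw[(el$off + 1):(el$off + el$len)]
  bytes <- bytes[bytes != as.raw(0)]   # strip even-length NUL padding
  trimws(rawToChar(bytes))
}

#' Read a knee ROI from a DICOM file
#'
#' Supports uncompressed grayscale DICOM in implicit or explicit VR little
#' endian (transfer syntaxes 1.2.840.10008.1.2 and 1.2.840.10008.1.2.1),
#' which covers plain radiography exports. Pixel spacing is taken from
#' `ImagerPixelSpacing` (0018,1164), falling back to `PixelSpacing`
#' (0028,0030); the side is taken from `ImageLaterality` (0020,0062) unless
#' given explicitly.
#'
#' @param path DICOM file path.
#' @param side optional override, `"left"` or `"right"`.
#' @param kl_grade optional KL grade annotation.
#' @param source_id identifier; defaults to the file name.
#' @return A [knee_roi()].
#' @export
read_dicom <- function(path, side = NULL, kl_grade = NA_integer_,
                       source_id = basename(path)) {
  raw <- readBin(path, "raw", file.size(path))
  off <- 0L
  explicit <- TRUE
  if (length(raw) >= 132 && rawToChar(raw[129:132]) == "DICM") {
    meta <- .parse_dicom_elements(raw, 132L, explicit = TRUE, stop_group = 2L)
    ts <- .dicom_string(raw, meta$elements[["0002,0010"]])
    off <- meta$off
    if (is.na(ts) || ts == "1.2.840.10008.1.2.1") {
      explicit <- TRUE
    } else if (ts == "1.2.840.10008.1.2") {
      explicit <- FALSE
    } else {
      stop("unsupported DICOM transfer syntax: ", ts)
    }
  } else {
    # headerless implicit VR stream
    explicit <- FALSE
  }
  els <- .parse_dicom_elements(raw, off, explicit = explicit)$elements

  need_u16 <- function(key, what) {
    el <- els[[key]]
    if (is.null(el)) stop("DICOM file lacks ", what)
    .u16(raw, el$off)
  }
  rows <- need_u16("0028,0010", "Rows")
  cols <- need_u16("0028,0011", "Columns")
  bits <- need_u16("0028,0100", "BitsAllocated")
  if (!bits %in% c(8L, 16L)) stop("unsupported BitsAllocated: ", bits)

  sp <- .dicom_string(raw, els[["0018,1164"]])
  if (is.na(sp)) sp <- .dicom_string(raw, els[["0028,0030"]])
  if (is.na(sp)) stop("DICOM file lacks ImagerPixelSpacing / PixelSpacing")
  spacing <- as.numeric(strsplit(sp, "\\\\")[[1]][1])

  if (is.null(side)) {
    lat <- .dicom_string(raw, els[["0020,0062"]])
    side <- if (!is.na(lat) && toupper(lat) == "L") "left" else "right"
  }

  px_el <- els[["7fe0,0010"]]
  if (is.null(px_el)) stop("DICOM file lacks PixelData")
  npx <- rows * cols
  if (bits == 16L) {
    v <- readBin(raw[(px_el$off + 1):(px_el$off + 2L * npx)], "integer",
                 n = npx, size = 2L, signed = FALSE, endian = "little")
  } else {
    v <- as.integer(raw[(px_el$off + 1):(px_el$off + npx)])
  }
  knee_roi(matrix(v, nrow = rows, ncol = cols, byrow = TRUE),
           spacing_mm = spacing, side = side, kl_grade = kl_grade,
           source_id = source_id)
}
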