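# Minimal single-frame DICOM support.
#
# Covers the subset of DICOM that uncompressed grayscale MR exports use:
# part-10 files (128-byte preamble + "DICM"), explicit or implicit VR
# little endian transfer syntax, single-frame MONOCHROME pixel data with
# 8 or 16 bits allocated. Sequences with undefined length and compressed
# transfer syntaxes are rejected with a format error. This is deliberately
# small: the pipeline only needs per-slice pixels, InstanceNumber for
# ordering and PixelSpacing for geometry.

TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
TS_IMPLICIT_LE <- "1.2.840.10008.1.2"

dcm_u16 <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}

dcm_u32 <- function(raw, pos) {
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}

dcm_string <- function(value) {
  trimws(rawToChar(value[value != as.raw(0)]))
}

# VRs that use the 4-byte length form in explicit little endian.
LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

#' Read one DICOM file (minimal parser)
#'
#' @param path path to an uncompressed little-endian single-frame DICOM file.
#' @return list with `pixels` (integer matrix, row-major as displayed),
#'   `instance_number`, `pixel_spacing` (row, col in mm, `NA` if absent)
#'   and `bits_allocated`.
#' @export
read_dicom <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  n <- length(raw)
  off <- 1L
  if (n > 132L && rawToChar(raw[129:132]) == "DICM") off <- 133L
  else if (n <= 8L) stop("not a readable DICOM file: ", path, call. = FALSE)

  elements <- new.env(parent = emptyenv())
  ts <- TS_EXPLICIT_LE
  in_meta_checked <- FALSE
  explicit <- TRUE

  while (off + 7L <= n) {
    group <- dcm_u16(raw, off)
    elem <- dcm_u16(raw, off + 2L)
    if (group != 2L && !in_meta_checked) {
      # leaving the (always explicit) file meta group: fix dataset syntax
      in_meta_checked <- TRUE
      explicit <- !identical(ts, TS_IMPLICIT_LE)
      if (!identical(ts, TS_EXPLICIT_LE) && !identical(ts, TS_IMPLICIT_LE))
        stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
    }
    use_explicit <- if (group == 2L) TRUE else explicit
    if (use_explicit) {
      vr <- rawToChar(raw[(off + 4L):(off + 5L)])
      if (vr %in% LONG_VRS) {
        len <- dcm_u32(raw, off + 8L); vstart <- off + 12L
      } else {
        len <- dcm_u16(raw, off + 6L); vstart <- off + 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(raw, off + 4L); vstart <- off + 8L
    }
    if (len == 4294967295) # undefined length (sequences): unsupported
      stop("unsupported DICOM element with undefined length", call. = FALSE)
    if (vstart + len - 1L > n)
      stop("truncated DICOM file: ", path, call. = FALSE)
    key <- sprintf("%04x,%04x", group, elem)
    assign(key, raw[seq.int(vstart, length.out = len)], envir = elements)
    if (group == 2L && elem == 16L)  # (0002,0010) TransferSyntaxUID
      ts <- dcm_string(get(key, envir = elements))
    off <- as.integer(vstart + len)
    if (group == 0x7fe0 && elem == 0x10) break
  }

  need <- function(key, what) {
    if (!exists(key, envir = elements))
      stop("DICOM file lacks required element ", what, ": ", path, call. = FALSE)
    get(key, envir = elements)
  }
  rows <- dcm_u16(need("0028,0010", "Rows"), 1L)
  cols <- dcm_u16(need("0028,0011", "Columns"), 1L)
  bits <- dcm_u16(need("0028,0100", "BitsAllocated"), 1L)
  pixrep <- if (exists("0028,0103", envir = elements))
    dcm_u16(get("0028,0103", envir = elements), 1L) else 0L
  inst <- if (exists("0020,0013", envir = elements))
    as.integer(dcm_string(get("0020,0013", envir = elements))) else NA_integer_
  spacing <- if (exists("0028,0030", envir = elements)) {
    as.numeric(strsplit(dcm_string(get("0028,0030", envir = elements)),
                        "\\\\")[[1]])
  } else c(NA_real_, NA_real_)

  pd <- need("7fe0,0010", "PixelData")
  if (!bits %in% c(8L, 16L))
    stop("unsupported BitsAllocated: ", bits, call. = FALSE)
  vals <- readBin(pd, "integer", n = rows * cols, size = bits / 8L,
                  signed = (pixrep == 1L && bits == 16L), endian = "little")
  if (bits == 8L) vals <- vals %% 256L  # readBin size=1 is signed
  if (bits == 16L && pixrep == 0L) vals <- ifelse(vals < 0L, vals + 65536L, vals)
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  list(pixels = pixels, instance_number = inst,
       pixel_spacing = spacing, bits_allocated = bits)
}

dcm_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L)
      value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  tag <- writeBin(c(as.integer(group), as.integer(elem)), raw(),
                  size = 2, endian = "little")
  if (vr %in% LONG_VRS) {
    len <- writeBin(as.integer(length(value)), raw(), size = 4,
                    endian = "little")
    c(tag, charToRaw(vr), as.raw(c(0, 0)), len, value)
  } else {
    len <- writeBin(as.integer(length(value)), raw(), size = 2,
                    endian = "little")
    c(tag, charToRaw(vr), len, value)
  }
}

dcm_us <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")

#' Write one slice as a DICOM file
#'
#' Writes an explicit-VR little-endian part-10 file with 16-bit unsigned
#' MONOCHROME2 pixels. Used to export phantom slices and to build synthetic
#' series in tests; the metadata is the minimal set a series reader needs
#' (Rows, Columns, InstanceNumber, PixelSpacing, PixelData).
#'
#' @param pixels integer matrix of pixel values in `[0, 65535]`.
#' @param path output file path.
#' @param instance_number value for InstanceNumber (slice order key).
#' @param pixel_spacing length-2 numeric, (row, col) spacing in mm.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(pixels, path, instance_number = 1L,
                        pixel_spacing = c(1, 1)) {
  pixels <- round(pixels)
  if (any(pixels < 0) || any(pixels > 65535))
    stop("pixel values must be in [0, 65535]", call. = FALSE)
  uid_root <- "1.2.826.0.1.3680043.9999"
  sop_uid <- sprintf("%s.%d.%d", uid_root, instance_number,
                     sum(pixels[1, ]) %% 1000L)
  meta <- c(
    dcm_element(2L, 2L, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    dcm_element(2L, 3L, "UI", sop_uid),
    dcm_element(2L, 16L, "UI", TS_EXPLICIT_LE))
  meta <- c(dcm_element(2L, 0L, "UL",
                        writeBin(length(meta), raw(), size = 4,
                                 endian = "little")),
            meta)
  v <- as.integer(t(pixels))
  v <- ifelse(v > 32767L, v - 65536L, v)  # two's complement for writeBin size=2
  px <- writeBin(v, raw(), size = 2, endian = "little")
  body <- c(
    dcm_element(0x08, 0x16, "UI", "1.2.840.10008.5.1.4.1.1.7"),
    dcm_element(0x08, 0x18, "UI", sop_uid),
    dcm_element(0x20, 0x13, "IS", as.character(as.integer(instance_number))),
    dcm_element(0x28, 0x02, "US", dcm_us(1L)),
    dcm_element(0x28, 0x04, "CS", "MONOCHROME2"),
    dcm_element(0x28, 0x10, "US", dcm_us(nrow(pixels))),
    dcm_element(0x28, 0x11, "US", dcm_us(ncol(pixels))),
    dcm_element(0x28, 0x30, "DS",
                sprintf("%g\\%g", pixel_spacing[1], pixel_spacing[2])),
    dcm_element(0x28, 0x100, "US", dcm_us(16L)),
    dcm_element(0x28, 0x101, "US", dcm_us(16L)),
    dcm_element(0x28, 0x102, "US", dcm_us(15L)),
    dcm_element(0x28, 0x103, "US", dcm_us(0L)),
    dcm_element(0x7fe0, 0x10, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}
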