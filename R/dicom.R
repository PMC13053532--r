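# Minimal single-frame grayscale DICOM reader.
#
# Supports Part-10 files (128-byte preamble + "DICM") with explicit- or
# implicit-VR little-endian transfer syntax and uncompressed MONOCHROME1/2
# pixel data, 8 or 16 bits allocated, one sample per pixel, one frame.
# That covers the radiograph exports this package targets; compressed,
# big-endian, color and multi-frame payloads are rejected explicitly.

dicom_string <- function(v) {
  sub(" +$", "", rawToChar(v[v != as.raw(0)]))
}

read_uint <- function(raw) {
  b <- as.integer(raw)
  sum(b * 256^(seq_along(b) - 1))
}

read_dicom_gray <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  read_dicom_from_raw(bytes, path)
}

# Parse one data element at 1-based offset `pos`; returns the element and the
# offset just past it, or NULL at end of stream.
parse_elem <- function(bytes, pos, explicit) {
  if (pos + 7L > length(bytes) + 1L) return(NULL)
  long_vrs <- c("OB", "OW", "OF", "OL", "OD", "SQ", "UC", "UR", "UT", "UN")
  group <- read_uint(bytes[pos:(pos + 1L)])
  elem  <- read_uint(bytes[(pos + 2L):(pos + 3L)])
  pos <- pos + 4L
  if (explicit) {
    vr <- rawToChar(bytes[pos:(pos + 1L)])
    if (vr %in% long_vrs) {
      len <- read_uint(bytes[(pos + 4L):(pos + 7L)])
      pos <- pos + 8L
    } else {
      len <- read_uint(bytes[(pos + 2L):(pos + 3L)])
      pos <- pos + 4L
    }
  } else {
    vr <- NA_character_
    len <- read_uint(bytes[pos:(pos + 3L)])
    pos <- pos + 4L
  }
  if (len == 4294967295)
    stop("undefined-length (likely compressed) DICOM payloads are not supported",
         call. = FALSE)
  val <- if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0)
  list(group = group, elem = elem, vr = vr, value = val, next_pos = pos + len)
}

read_dicom_from_raw <- function(bytes, path = "<raw>") {
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("'", path, "' is not a DICOM part-10 file", call. = FALSE)

  # Pass 1: the file meta group (always explicit VR little endian).
  pos <- 133L
  transfer_syntax <- "1.2.840.10008.1.2.1"
  repeat {
    e <- parse_elem(bytes, pos, explicit = TRUE)
    if (is.null(e) || e$group != 0x0002) break
    if (e$elem == 0x0010)
      transfer_syntax <- dicom_string(e$value)
    pos <- e$next_pos
  }
  if (!transfer_syntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
    stop("unsupported transfer syntax '", transfer_syntax,
         "' (only uncompressed little endian)", call. = FALSE)
  explicit <- transfer_syntax == "1.2.840.10008.1.2.1"

  # Pass 2: the dataset proper.
  fields <- list()
  pix <- NULL
  repeat {
    e <- parse_elem(bytes, pos, explicit = explicit)
    if (is.null(e)) break
    key <- sprintf("%04x,%04x", e$group, e$elem)
    if (key == "7fe0,0010") { pix <- e$value; break }
    fields[[key]] <- e$value
    pos <- e$next_pos
  }

  us <- function(key, default = NULL) {
    v <- fields[[key]]
    if (is.null(v)) default else read_uint(v[1:2])
  }
  str_field <- function(key, default = "") {
    v <- fields[[key]]
    if (is.null(v)) default else dicom_string(v)
  }

  rows <- us("0028,0010"); cols <- us("0028,0011")
  if (is.null(rows) || is.null(cols) || is.null(pix))
    stop("DICOM file lacks Rows/Columns/PixelData", call. = FALSE)
  if (us("0028,0002", 1) != 1)
    stop("color DICOM (SamplesPerPixel > 1) without a reduction rule",
         call. = FALSE)
  nframes <- suppressWarnings(as.integer(str_field("0028,0008", "1")))
  if (!is.na(nframes) && nframes > 1)
    stop("multi-frame DICOM is not supported", call. = FALSE)
  photometric <- str_field("0028,0004", "MONOCHROME2")
  if (!photometric %in% c("MONOCHROME1", "MONOCHROME2"))
    stop("unsupported photometric interpretation '", photometric, "'",
         call. = FALSE)
  bits_alloc <- us("0028,0100", 16)
  bits_stored <- us("0028,0101", bits_alloc)
  signed <- us("0028,0103", 0) == 1

  nbytes <- bits_alloc %/% 8L
  npix <- rows * cols
  if (length(pix) < npix * nbytes)
    stop("truncated DICOM pixel data", call. = FALSE)
  if (nbytes == 1L) {
    v <- as.integer(pix[seq_len(npix)])
  } else if (nbytes == 2L) {
    idx <- seq_len(npix)
    v <- as.integer(pix[2L * idx - 1L]) + 256L * as.integer(pix[2L * idx])
    if (signed) v <- ifelse(v >= 32768L, v - 65536L, v)
  } else stop("unsupported BitsAllocated = ", bits_alloc, call. = FALSE)
  m <- matrix(v, nrow = rows, ncol = cols, byrow = TRUE)  # row-major pixel order
  if (photometric == "MONOCHROME1") m <- max(m) - m       # invert: white-is-low
  list(values = m, stored_bits = as.integer(bits_stored))
}
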