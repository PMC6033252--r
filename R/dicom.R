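# Minimal DICOM Part 10 I/O: explicit-VR little-endian, single-frame
# grayscale, uncompressed pixel data. The archival pipeline re-encodes pixels
# itself, so transfer-syntax breadth is deliberately narrow; the writer/reader
# pair is a bit-exact round trip on the supported subset.

TRANSFER_SYNTAX_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
SOP_CLASS_SECONDARY_CAPTURE <- "1.2.840.10008.5.1.4.1.1.7"

# metadata whitelist: the archive's five search-engine fields plus geometry.
DICOM_METADATA_FIELDS <- c(
  "HIMSID", "PatientName", "PatientSurname", "CitizenshipID", "StudyDate"
)

#' Construct an image record
#'
#' The in-memory representation of one decoded grayscale image plane plus its
#' DICOM-style metadata: the unit every other module operates on.
#'
#' @param pixels Integer matrix of unsigned grey levels.
#' @param bits_stored Bits per sample, in 8..16.
#' @param metadata Named list of character scalars. Supported archival keys:
#'   `HIMSID`, `PatientName`, `PatientSurname`, `CitizenshipID`, `StudyDate`
#'   (ISO-8601). Keys must be unique.
#' @return An `image_record` object.
#' @export
image_record <- function(pixels, bits_stored = 16L, metadata = list()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  bits_stored <- as.integer(bits_stored)
  if (bits_stored < 8L || bits_stored > 16L) {
    rp_stop("roipack_format_error", "bits_stored must be in [8,16], got %d",
            bits_stored)
  }
  if (nrow(pixels) == 0L || ncol(pixels) == 0L) {
    rp_stop("roipack_format_error", "pixel matrix must be non-empty")
  }
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) >= bitwShiftL(1L, bits_stored)) {
    rp_stop("roipack_range_error",
            "pixel values must lie in [0, 2^bits_stored - 1]")
  }
  metadata <- as.list(metadata)
  if (length(metadata) > 0L) {
    if (is.null(names(metadata)) || anyDuplicated(names(metadata)) > 0L ||
        any(names(metadata) == "")) {
      rp_stop("roipack_format_error", "metadata keys must be unique and named")
    }
    metadata <- lapply(metadata, as.character)
  }
  structure(
    list(
      pixels = pixels,
      rows = nrow(pixels),
      cols = ncol(pixels),
      bits_stored = bits_stored,
      metadata = metadata
    ),
    class = "image_record"
  )
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf(
    "<image_record> %dx%d, %d bits, %d metadata field(s)\n",
    x$rows, x$cols, x$bits_stored, length(x$metadata)
  ))
  invisible(x)
}

## ---- byte helpers -----------------------------------------------------------

u16le <- function(x) {
  x <- as.integer(x)
  as.raw(c(bitwAnd(x, 255L), bitwAnd(bitwShiftR(x, 8L), 255L)))
}

u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

rd_u16 <- function(bytes, at) {
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1L])
}

rd_u32 <- function(bytes, at) {
  as.numeric(bytes[at]) + 256 * as.numeric(bytes[at + 1L]) +
    65536 * as.numeric(bytes[at + 2L]) + 16777216 * as.numeric(bytes[at + 3L])
}

LONG_FORM_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
KNOWN_VRS <- c(
  LONG_FORM_VRS,
  "AE", "AS", "AT", "CS", "DA", "DS", "DT", "FL", "FD", "IS", "LO", "LT",
  "PN", "SH", "SL", "SS", "ST", "TM", "UI", "UL", "US"
)

dicom_element <- function(group, element, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2L == 1L) {
      pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
      value <- c(value, pad)
    }
  }
  head <- c(u16le(group), u16le(element), charToRaw(vr))
  if (vr %in% LONG_FORM_VRS) {
    c(head, as.raw(c(0L, 0L)), u32le(length(value)), value)
  } else {
    c(head, u16le(length(value)), value)
  }
}

iso_to_da <- function(x) gsub("-", "", x, fixed = TRUE)
da_to_iso <- function(x) {
  x <- trimws(x)
  if (grepl("^[0-9]{8}$", x)) {
    paste(substr(x, 1, 4), substr(x, 5, 6), substr(x, 7, 8), sep = "-")
  } else {
    x
  }
}

## ---- writer -----------------------------------------------------------------

#' Serialize an image record to DICOM bytes
#'
#' Writes a Part 10 DICOM object (128-byte preamble, file meta group,
#' explicit-VR little-endian dataset) with uncompressed grayscale pixel data:
#' 1 byte/pixel when `bits_stored <= 8`, else 2 bytes/pixel. The whitelisted
#' metadata fields are mapped onto standard tags (patient name/surname as a
#' `Surname^Name` person name, citizenship id as PatientID, HIMS id as
#' AccessionNumber, study date as StudyDate). `read_dicom(write_dicom(rec))`
#' reproduces the pixel matrix bit-exactly and all whitelisted fields.
#'
#' @param rec An [image_record()].
#' @return Raw vector of DICOM bytes.
#' @export
write_dicom <- function(rec) {
  stopifnot(inherits(rec, "image_record"))
  md <- rec$metadata
  bytes_pp <- if (rec$bits_stored <= 8L) 1L else 2L
  n_px <- rec$rows * rec$cols

  pixel_bytes <- writeBin(
    as.integer(as.vector(t(rec$pixels))), raw(),
    size = bytes_pp, endian = "little"
  )
  if (length(pixel_bytes) %% 2L == 1L) pixel_bytes <- c(pixel_bytes, as.raw(0L))

  get_md <- function(key) {
    v <- md[[key]]
    if (is.null(v) || !nzchar(v)) NULL else as.character(v)
  }

  ds <- list(
    dicom_element(0x0008L, 0x0016L, "UI", SOP_CLASS_SECONDARY_CAPTURE),
    dicom_element(0x0008L, 0x0018L, "UI", "1.2.826.0.1.3680043.8.498.1")
  )
  if (!is.null(get_md("StudyDate"))) {
    ds <- c(ds, list(dicom_element(0x0008L, 0x0020L, "DA",
                                   iso_to_da(get_md("StudyDate")))))
  }
  if (!is.null(get_md("HIMSID"))) {
    ds <- c(ds, list(dicom_element(0x0008L, 0x0050L, "SH", get_md("HIMSID"))))
  }
  if (!is.null(get_md("PatientSurname")) || !is.null(get_md("PatientName"))) {
    pn <- paste(
      if (is.null(get_md("PatientSurname"))) "" else get_md("PatientSurname"),
      if (is.null(get_md("PatientName"))) "" else get_md("PatientName"),
      sep = "^"
    )
    ds <- c(ds, list(dicom_element(0x0010L, 0x0010L, "PN", pn)))
  }
  if (!is.null(get_md("CitizenshipID"))) {
    ds <- c(ds, list(dicom_element(0x0010L, 0x0020L, "LO",
                                   get_md("CitizenshipID"))))
  }
  ds <- c(ds, list(
    dicom_element(0x0028L, 0x0002L, "US", u16le(1L)),
    dicom_element(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dicom_element(0x0028L, 0x0010L, "US", u16le(rec$rows)),
    dicom_element(0x0028L, 0x0011L, "US", u16le(rec$cols)),
    dicom_element(0x0028L, 0x0100L, "US", u16le(8L * bytes_pp)),
    dicom_element(0x0028L, 0x0101L, "US", u16le(rec$bits_stored)),
    dicom_element(0x0028L, 0x0102L, "US", u16le(rec$bits_stored - 1L)),
    dicom_element(0x0028L, 0x0103L, "US", u16le(0L)),
    dicom_element(0x7FE0L, 0x0010L, "OW", pixel_bytes)
  ))
  dataset <- do.call(c, ds)

  meta_body <- c(
    dicom_element(0x0002L, 0x0001L, "OB", as.raw(c(0L, 1L))),
    dicom_element(0x0002L, 0x0002L, "UI", SOP_CLASS_SECONDARY_CAPTURE),
    dicom_element(0x0002L, 0x0003L, "UI", "1.2.826.0.1.3680043.8.498.1"),
    dicom_element(0x0002L, 0x0010L, "UI", TRANSFER_SYNTAX_EXPLICIT_LE)
  )
  meta <- c(
    dicom_element(0x0002L, 0x0000L, "UL", u32le(length(meta_body))),
    meta_body
  )

  c(raw(128L), charToRaw("DICM"), meta, dataset)
}

## ---- reader -----------------------------------------------------------------

#' Parse DICOM bytes into an image record
#'
#' Accepts Part 10 explicit-VR little-endian objects with uncompressed
#' grayscale pixel data; any other transfer syntax raises an
#' `roipack_unsupported_syntax` error, and non-DICOM input a
#' `roipack_parse_error`.
#'
#' @param bytes Raw vector (or path to a file, which is read binary).
#' @return An [image_record()].
#' @rdname write_dicom
#' @export
read_dicom <- function(bytes) {
  if (is.character(bytes)) {
    bytes <- readBin(bytes, "raw", n = file.size(bytes))
  }
  if (length(bytes) < 132L ||
      !identical(bytes[129:132], charToRaw("DICM"))) {
    rp_stop("roipack_parse_error", "not a DICOM part-10 stream")
  }
  p <- 133L
  n <- length(bytes)
  ts <- NULL
  fields <- list()
  rows <- cols <- bits_stored <- bits_alloc <- NA_integer_
  pixel_raw <- NULL

  read_str <- function(value) trimws(rawToChar(value[value != as.raw(0L)]))

  while (p <= n) {
    if (p + 7L > n) rp_stop("roipack_parse_error", "truncated DICOM element")
    group <- rd_u16(bytes, p)
    element <- rd_u16(bytes, p + 2L)
    vr <- rawToChar(bytes[(p + 4L):(p + 5L)])
    if (!(vr %in% KNOWN_VRS)) {
      rp_stop("roipack_parse_error",
              "unknown VR %s at offset %d (implicit VR unsupported)",
              sQuote(vr), p - 1L)
    }
    if (vr %in% LONG_FORM_VRS) {
      if (p + 11L > n) rp_stop("roipack_parse_error", "truncated DICOM element")
      len <- rd_u32(bytes, p + 8L)
      vstart <- p + 12L
    } else {
      len <- rd_u16(bytes, p + 6L)
      vstart <- p + 8L
    }
    if (vstart + len - 1L > n) {
      rp_stop("roipack_parse_error", "element value overruns stream")
    }
    value <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0L)

    if (group != 0x0002L && is.null(ts)) {
      ts <- TRANSFER_SYNTAX_EXPLICIT_LE # no meta TS seen; assume and verify VRs
    }
    if (group == 0x0002L && element == 0x0010L) {
      ts <- read_str(value)
      if (!identical(ts, TRANSFER_SYNTAX_EXPLICIT_LE)) {
        rp_stop("roipack_unsupported_syntax",
                "unsupported transfer syntax %s", sQuote(ts))
      }
    } else if (group == 0x0008L && element == 0x0020L) {
      fields$StudyDate <- da_to_iso(read_str(value))
    } else if (group == 0x0008L && element == 0x0050L) {
      fields$HIMSID <- read_str(value)
    } else if (group == 0x0010L && element == 0x0010L) {
      pn <- strsplit(read_str(value), "^", fixed = TRUE)[[1]]
      if (length(pn) >= 1L && nzchar(pn[1])) fields$PatientSurname <- pn[1]
      if (length(pn) >= 2L && nzchar(pn[2])) fields$PatientName <- pn[2]
    } else if (group == 0x0010L && element == 0x0020L) {
      fields$CitizenshipID <- read_str(value)
    } else if (group == 0x0028L && element == 0x0010L) {
      rows <- rd_u16(value, 1L)
    } else if (group == 0x0028L && element == 0x0011L) {
      cols <- rd_u16(value, 1L)
    } else if (group == 0x0028L && element == 0x0100L) {
      bits_alloc <- rd_u16(value, 1L)
    } else if (group == 0x0028L && element == 0x0101L) {
      bits_stored <- rd_u16(value, 1L)
    } else if (group == 0x7FE0L && element == 0x0010L) {
      pixel_raw <- value
    }
    p <- vstart + len
  }

  if (is.na(rows) || is.na(cols) || is.null(pixel_raw)) {
    rp_stop("roipack_parse_error",
            "stream lacks image geometry or pixel data")
  }
  if (is.na(bits_stored)) bits_stored <- if (is.na(bits_alloc)) 16L else bits_alloc
  bytes_pp <- if (is.na(bits_alloc)) {
    if (bits_stored <= 8L) 1L else 2L
  } else {
    bits_alloc %/% 8L
  }
  need <- rows * cols * bytes_pp
  if (length(pixel_raw) < need) {
    rp_stop("roipack_parse_error", "pixel data shorter than rows*cols")
  }
  vals <- readBin(pixel_raw[seq_len(need)], "integer",
                  n = rows * cols, size = bytes_pp,
                  signed = FALSE, endian = "little")
  pixels <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)

  ord <- intersect(DICOM_METADATA_FIELDS, names(fields))
  image_record(pixels, bits_stored = bits_stored, metadata = fields[ord])
}

#' Wrap a pixel plane and patient metadata as DICOM bytes
#'
#' Convenience entry used by the phantom generator: builds an
#' [image_record()] and serializes it. The archival metadata fields
#' (`PatientName`, `PatientSurname`, `CitizenshipID`, `StudyDate`, `HIMSID`)
#' must all be present.
#'
#' @param image An [image_record()] or integer pixel matrix.
#' @param metadata Named list with the five archival fields.
#' @param bits_stored Used when `image` is a bare matrix.
#' @return Raw vector of DICOM bytes.
#' @export
wrap_dicom <- function(image, metadata, bits_stored = 16L) {
  required <- DICOM_METADATA_FIELDS
  missing <- setdiff(required, names(metadata))
  if (length(missing) > 0L) {
    rp_stop("roipack_format_error",
            "metadata must include %s", paste(missing, collapse = ", "))
  }
  if (inherits(image, "image_record")) {
    rec <- image_record(image$pixels, image$bits_stored, metadata)
  } else {
    rec <- image_record(image, bits_stored, metadata)
  }
  write_dicom(rec)
}
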