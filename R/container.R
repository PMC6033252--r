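# The .mipp container: a four-section dynamic file structure holding one or
# more compressed images per package.
#
# Byte layout (all integers little-endian):
#   magic "MIPP" | version u8
#   [u32 tree_size]   [serialized Huffman codebook]
#   [u32 text_bytes]  [u32 text_bitcount] [Huffman-coded text payload]
#   [u16 image_number]
#   per image:
#   [u32 roi_size] [bbox 4 x u32] [frame rows u32] [frame cols u32]
#   [bits u8] [ROI stream]
#
# The text payload (before Huffman coding) is a deterministic JSON
# serialization of the per-image records: frame dimensions, whitelisted
# metadata pairs, and the text runs with anchors and intensity. One shared
# codebook serves the whole package.

CONTAINER_MAGIC <- "MIPP"
CONTAINER_VERSION <- 1L

#' Construct a compressed-image entry
#'
#' The per-image unit stored in a package: the lossless ROI stream, its
#' bounding box, frame geometry, extracted text runs, and whitelisted
#' metadata.
#'
#' @param roi_stream Raw vector from [encode_plane()].
#' @param bbox Integer `c(row0, col0, row1, col1)`, 0-based half-open,
#'   within the frame.
#' @param rows,cols Frame dimensions.
#' @param bits_stored Bits per sample.
#' @param runs Tibble of text runs (`text`, `row`, `col`, `intensity`).
#' @param metadata Named list of whitelisted metadata strings.
#' @return A `compressed_image` object.
#' @export
compressed_image <- function(roi_stream, bbox, rows, cols, bits_stored,
                             runs, metadata = list()) {
  stopifnot(is.raw(roi_stream), length(bbox) == 4L)
  bbox <- as.integer(bbox)
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (bbox[1L] < 0L || bbox[2L] < 0L || bbox[3L] > rows || bbox[4L] > cols ||
      bbox[3L] <= bbox[1L] || bbox[4L] <= bbox[2L]) {
    rp_stop("roipack_completeness_error", "bbox outside frame or empty")
  }
  runs <- tibble::as_tibble(runs)
  needed <- c("text", "row", "col", "intensity")
  if (!all(needed %in% names(runs))) {
    rp_stop("roipack_completeness_error",
            "runs must have columns text, row, col, intensity")
  }
  structure(
    list(roi_stream = roi_stream, bbox = bbox, rows = rows, cols = cols,
         bits_stored = as.integer(bits_stored),
         runs = runs[needed], metadata = as.list(metadata)),
    class = "compressed_image"
  )
}

# deterministic text payload for a list of entries
serialize_text_records <- function(entries) {
  recs <- lapply(entries, function(e) {
    list(
      rows = e$rows,
      cols = e$cols,
      metadata = e$metadata,
      runs = lapply(seq_len(nrow(e$runs)), function(i) {
        list(text = e$runs$text[i], row = e$runs$row[i],
             col = e$runs$col[i], intensity = e$runs$intensity[i])
      })
    )
  })
  charToRaw(as.character(jsonlite::toJSON(recs, auto_unbox = TRUE)))
}

deserialize_text_records <- function(payload) {
  recs <- jsonlite::fromJSON(rawToChar(payload), simplifyVector = FALSE)
  lapply(recs, function(r) {
    runs <- if (length(r$runs) == 0L) {
      tibble::tibble(text = character(0), row = integer(0),
                     col = integer(0), intensity = integer(0))
    } else {
      tibble::tibble(
        text = vapply(r$runs, function(x) as.character(x$text), character(1)),
        row = vapply(r$runs, function(x) as.integer(x$row), integer(1)),
        col = vapply(r$runs, function(x) as.integer(x$col), integer(1)),
        intensity = vapply(r$runs, function(x) as.integer(x$intensity),
                           integer(1))
      )
    }
    list(rows = as.integer(r$rows), cols = as.integer(r$cols),
         metadata = lapply(r$metadata, as.character), runs = runs)
  })
}

#' Write a package file
#'
#' Serializes one or more [compressed_image()] entries into the four-section
#' container: shared Huffman codebook, Huffman-coded text payload, image
#' count, and per-image ROI records. `read_package()` is its exact inverse.
#'
#' @param entries List of `compressed_image` objects (length >= 1).
#' @return Raw vector: the package bytes.
#' @export
write_package <- function(entries) {
  if (inherits(entries, "compressed_image")) entries <- list(entries)
  if (length(entries) == 0L) {
    rp_stop("roipack_completeness_error", "a package needs at least one image")
  }
  ok <- vapply(entries, inherits, logical(1), "compressed_image")
  if (!all(ok)) {
    rp_stop("roipack_completeness_error",
            "entry %d is not a compressed_image", which(!ok)[1L])
  }

  payload <- serialize_text_records(entries)
  book <- build_codebook(payload)
  enc <- huffman_encode(payload, book)
  tree <- serialize_codebook(book)

  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(CONTAINER_MAGIC), con)
  writeBin(as.raw(CONTAINER_VERSION), con)
  writeBin(length(tree), con, size = 4L, endian = "little")
  writeBin(tree, con)
  writeBin(length(enc$bits), con, size = 4L, endian = "little")
  writeBin(as.integer(enc$bit_count), con, size = 4L, endian = "little")
  if (length(enc$bits) > 0L) writeBin(enc$bits, con)
  writeBin(length(entries), con, size = 2L, endian = "little")
  for (e in entries) {
    writeBin(length(e$roi_stream), con, size = 4L, endian = "little")
    writeBin(e$bbox, con, size = 4L, endian = "little")
    writeBin(c(e$rows, e$cols), con, size = 4L, endian = "little")
    writeBin(as.raw(e$bits_stored), con)
    writeBin(e$roi_stream, con)
  }
  rawConnectionValue(con)
}

#' Read a package file
#'
#' Parses container bytes back into the list of [compressed_image()] entries,
#' validating the magic, every size prefix against the buffer, and the image
#' count against the text records.
#'
#' @param bytes Raw vector (or path to a package file).
#' @return List of `compressed_image` objects.
#' @export
read_package <- function(bytes) {
  if (is.character(bytes)) {
    bytes <- readBin(bytes, "raw", n = file.size(bytes))
  }
  stopifnot(is.raw(bytes))
  pos <- 1L
  n <- length(bytes)
  take <- function(k, section) {
    if (pos + k - 1L > n) {
      rp_stop("roipack_truncation_error",
              "package truncated in %s section", section)
    }
    out <- bytes[pos:(pos + k - 1L)]
    pos <<- pos + k
    out
  }
  u32 <- function(section) {
    b <- take(4L, section)
    as.integer(rd_u32(b, 1L))
  }

  magic <- take(4L, "magic")
  if (!identical(magic, charToRaw(CONTAINER_MAGIC))) {
    rp_stop("roipack_format_error", "bad magic: not a MIPP package")
  }
  version <- as.integer(take(1L, "version"))
  if (version != CONTAINER_VERSION) {
    rp_stop("roipack_format_error", "unsupported container version %d",
            version)
  }
  tree_size <- u32("codebook")
  tree <- take(tree_size, "codebook")
  book <- deserialize_codebook(tree)
  text_bytes <- u32("text")
  bit_count <- u32("text")
  text_raw <- take(text_bytes, "text")
  payload <- huffman_decode(text_raw, bit_count, book)
  records <- deserialize_text_records(payload)

  img_n <- as.integer(rd_u16(take(2L, "image number"), 1L))
  if (img_n < 1L) {
    rp_stop("roipack_consistency_error", "image_number must be >= 1")
  }
  if (img_n != length(records)) {
    rp_stop("roipack_consistency_error",
            "image_number %d does not match %d text records",
            img_n, length(records))
  }
  entries <- vector("list", img_n)
  for (i in seq_len(img_n)) {
    roi_size <- u32("roi")
    bbox <- as.integer(vapply(1:4, function(j) {
      rd_u32(take(4L, "roi"), 1L)
    }, numeric(1)))
    rows <- as.integer(rd_u32(take(4L, "roi"), 1L))
    cols <- as.integer(rd_u32(take(4L, "roi"), 1L))
    bits <- as.integer(take(1L, "roi"))
    stream <- take(roi_size, "roi")
    rec <- records[[i]]
    if (rec$rows != rows || rec$cols != cols) {
      rp_stop("roipack_consistency_error",
              "frame dims disagree between roi record and text record %d", i)
    }
    entries[[i]] <- compressed_image(
      roi_stream = stream, bbox = bbox, rows = rows, cols = cols,
      bits_stored = bits, runs = rec$runs, metadata = rec$metadata
    )
  }
  if (pos != n + 1L) {
    rp_stop("roipack_consistency_error",
            "%d trailing byte(s) after last roi section", n - pos + 1L)
  }
  entries
}

#' Section map of a package
#'
#' Sizes of each container section, for inspection and size accounting.
#'
#' @param bytes Package raw vector (or path).
#' @return Tibble with `section` and `bytes` columns.
#' @export
package_sections <- function(bytes) {
  if (is.character(bytes)) {
    bytes <- readBin(bytes, "raw", n = file.size(bytes))
  }
  tree_size <- as.integer(rd_u32(bytes, 6L))
  p <- 10L + tree_size
  text_bytes <- as.integer(rd_u32(bytes, p))
  p <- p + 8L + text_bytes
  img_n <- rd_u16(bytes, p)
  p <- p + 2L
  roi <- integer(img_n)
  for (i in seq_len(img_n)) {
    roi_size <- as.integer(rd_u32(bytes, p))
    roi[i] <- roi_size
    p <- p + 4L + 16L + 8L + 1L + roi_size
  }
  tibble::tibble(
    section = c("header", "codebook", "text", "image_number",
                paste0("roi_", seq_len(img_n))),
    bytes = c(5L, 4L + tree_size, 8L + text_bytes, 2L, 4L + 25L + roi)
  )
}
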