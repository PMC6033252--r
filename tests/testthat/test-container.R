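random_entry <- function(seed) {
  set.seed(seed)
  bits <- sample(8:16, 1)
  rows <- sample(30:80, 1)
  cols <- sample(30:80, 1)
  bb <- c(
    r0 <- sample(0:(rows - 10), 1), c0 <- sample(0:(cols - 10), 1),
    r0 + sample(5:(rows - r0), 1), c0 + sample(5:(cols - c0), 1)
  )
  crop <- matrix(sample.int(2L^bits, (bb[3] - bb[1]) * (bb[4] - bb[2]),
                            replace = TRUE) - 1L,
                 bb[3] - bb[1], bb[4] - bb[2])
  n_runs <- sample(0:3, 1)
  runs <- tibble::tibble(
    text = vapply(seq_len(n_runs), function(i) {
      paste(sample(c(LETTERS, 0:9, " "), sample(1:12, 1), replace = TRUE),
            collapse = "")
    }, character(1)),
    row = sample(0:(rows - 8), n_runs, replace = TRUE),
    col = sample(0:(cols - 8), n_runs, replace = TRUE),
    intensity = sample.int(2L^bits, n_runs, replace = TRUE) - 1L
  )
  runs$text <- trimws(runs$text)
  runs <- runs[nzchar(runs$text), ]
  compressed_image(
    roi_stream = encode_plane(crop, bits), bbox = bb, rows = rows,
    cols = cols, bits_stored = bits, runs = runs,
    metadata = random_metadata()
  )
}

entries_equal <- function(a, b) {
  identical(a$roi_stream, b$roi_stream) &&
    identical(a$bbox, b$bbox) &&
    identical(a$rows, b$rows) && identical(a$cols, b$cols) &&
    identical(a$bits_stored, b$bits_stored) &&
    runs_equal(a$runs, b$runs) &&
    identical(a$metadata[order(names(a$metadata))],
              b$metadata[order(names(b$metadata))])
}

test_that("packages round-trip structurally for randomized contents", {
  for (seed in 1:25) {
    n_img <- sample(1:4, 1)
    entries <- lapply(seed * 10L + seq_len(n_img), random_entry)
    bytes <- write_package(entries)
    back <- read_package(bytes)
    expect_identical(length(back), n_img)
    for (i in seq_len(n_img)) {
      expect_true(entries_equal(entries[[i]], back[[i]]))
    }
  }
})

test_that("the image-number field reflects the package size", {
  entries <- lapply(101:103, random_entry)
  bytes <- write_package(entries)
  secs <- package_sections(bytes)
  # u16 image_number sits right after the text section
  at <- 5L + secs$bytes[secs$section == "codebook"] +
    secs$bytes[secs$section == "text"] + 1L
  expect_identical(roipack:::rd_u16(bytes, at), 3L)
})

test_that("the byte layout walks as declared", {
  entries <- list(random_entry(7))
  bytes <- write_package(entries)
  expect_identical(rawToChar(bytes[1:4]), "MIPP")
  expect_identical(as.integer(bytes[5]), 1L) # version
  tree_size <- roipack:::rd_u32(bytes, 6L)
  book <- deserialize_codebook(bytes[10:(9 + tree_size)])
  expect_s3_class(book, "huffman_codebook")
  p <- 10L + tree_size
  text_bytes <- roipack:::rd_u32(bytes, p)
  bit_count <- roipack:::rd_u32(bytes, p + 4L)
  expect_identical(text_bytes, ceiling(bit_count / 8))
  p <- p + 8L + text_bytes
  expect_identical(roipack:::rd_u16(bytes, p), 1L)
  p <- p + 2L
  roi_size <- roipack:::rd_u32(bytes, p)
  expect_identical(5 + (4 + tree_size) + (8 + text_bytes) + 2 +
                     (4 + 16 + 8 + 1 + roi_size),
                   as.numeric(length(bytes)))
})

test_that("closed-form package size holds for random packages", {
  for (seed in 31:36) {
    entries <- lapply(seed * 3L + 1:2, random_entry)
    bytes <- write_package(entries)
    tree <- roipack:::rd_u32(bytes, 6L)
    text_bytes <- roipack:::rd_u32(bytes, 10L + tree)
    roi_sizes <- vapply(read_package(bytes),
                        function(e) length(e$roi_stream), integer(1))
    expect_identical(
      as.numeric(length(bytes)),
      5 + (4 + tree) + (8 + text_bytes) + 2 + sum(4 + 16 + 8 + 1 + roi_sizes)
    )
  }
})

test_that("corrupt packages fail with named sections", {
  entries <- list(random_entry(50))
  bytes <- write_package(entries)
  err <- tryCatch(read_package(bytes[-length(bytes)]), error = identity)
  expect_s3_class(err, "roipack_truncation_error")
  expect_match(conditionMessage(err), "roi")

  bad <- bytes
  bad[1] <- as.raw(0x58)
  expect_error(read_package(bad), class = "roipack_format_error")

  expect_error(write_package(list()), class = "roipack_completeness_error")

  # hand-build a zero-image package: consistency must fail
  book <- build_codebook(charToRaw("[]"))
  enc <- huffman_encode(charToRaw("[]"), book)
  tree <- serialize_codebook(book)
  con <- rawConnection(raw(0), "wb")
  writeBin(charToRaw("MIPP"), con)
  writeBin(as.raw(1L), con)
  writeBin(length(tree), con, size = 4, endian = "little")
  writeBin(tree, con)
  writeBin(length(enc$bits), con, size = 4, endian = "little")
  writeBin(enc$bit_count, con, size = 4, endian = "little")
  writeBin(enc$bits, con)
  writeBin(0L, con, size = 2, endian = "little")
  zero_pkg <- rawConnectionValue(con)
  close(con)
  expect_error(read_package(zero_pkg), class = "roipack_consistency_error")
})
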