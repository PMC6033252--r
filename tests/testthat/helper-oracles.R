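# Independent oracles used across the suite.

# Optimal prefix-code cost by exhaustive search: enumerate every length
# multiset satisfying the Kraft equality (full code tree), assign shortest
# lengths to the most frequent symbols, and take the minimum total bits.
# Tractable for <= 6 symbols with lengths <= 8.
optimal_prefix_bits <- function(freqs) {
  n <- length(freqs)
  if (n == 1L) {
    return(sum(freqs)) # one symbol, one bit each (degenerate convention)
  }
  grids <- do.call(expand.grid, rep(list(1:8), n))
  # non-decreasing length vectors only (multisets)
  keep <- rep(TRUE, nrow(grids))
  for (j in seq_len(n - 1L)) {
    keep <- keep & grids[[j]] <= grids[[j + 1L]]
  }
  grids <- grids[keep, , drop = FALSE]
  # Kraft equality in integer arithmetic scaled by 2^8
  kraft <- rowSums(matrix(2^(8 - as.matrix(grids)), nrow = nrow(grids)))
  grids <- grids[kraft == 256, , drop = FALSE]
  fr <- sort(freqs, decreasing = TRUE)
  min(apply(as.matrix(grids), 1L, function(l) sum(fr * sort(l))))
}

# total encoded bits of a payload under the package's codec
huffman_payload_bits <- function(payload) {
  book <- build_codebook(payload)
  huffman_encode(payload, book)$bit_count
}

random_metadata <- function() {
  list(
    HIMSID = as.character(sample.int(999999L, 1L)),
    PatientName = paste(sample(LETTERS, 5L), collapse = ""),
    PatientSurname = paste(sample(LETTERS, 6L), collapse = ""),
    CitizenshipID = paste(sample(0:9, 11L, replace = TRUE), collapse = ""),
    StudyDate = sprintf("20%02d-%02d-%02d", sample(10:20, 1L),
                        sample(1:12, 1L), sample(1:28, 1L))
  )
}

random_record <- function(rows = 32L, cols = 32L, bits = 16L,
                          metadata = random_metadata()) {
  px <- matrix(sample.int(2L^bits, rows * cols, replace = TRUE) - 1L,
               rows, cols)
  image_record(px, bits_stored = bits, metadata = metadata)
}

small_phantom <- function(seed, rows = 192L, cols = 192L, ...) {
  generate_phantom(phantom_spec(
    rows = rows, cols = cols, seed = seed,
    text_lines = c("ID 123", "2016-01-01"), ...
  ))
}

# criteria search oracle: brute-force scan over stored metadata
scan_oracle <- function(ar, name = NULL, surname = NULL,
                        citizenship_id = NULL, date_from = NULL,
                        date_to = NULL) {
  ids <- roipack:::archive_ids(ar)
  keep <- vapply(ids, function(id) {
    p <- roipack:::archive_meta(ar, id)$patient
    ok <- TRUE
    if (!is.null(name)) ok <- ok && identical(p$name, name)
    if (!is.null(surname)) ok <- ok && identical(p$surname, surname)
    if (!is.null(citizenship_id)) {
      ok <- ok && identical(p$citizenship_id, citizenship_id)
    }
    if (!is.null(date_from) || !is.null(date_to)) {
      d <- p$study_date
      ok <- ok && !is.null(d) &&
        (is.null(date_from) || d >= date_from) &&
        (is.null(date_to) || d < date_to)
    }
    ok
  }, logical(1))
  sort(ids[keep])
}

runs_equal <- function(a, b) {
  a <- as.data.frame(a)[order(a$row, a$col), ]
  b <- as.data.frame(b)[order(b$row, b$col), ]
  rownames(a) <- rownames(b) <- NULL
  isTRUE(all.equal(a, b, check.attributes = FALSE))
}
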