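test_that("known payloads hit their optimal encoded sizes", {
  enc <- huffman_encode(charToRaw("abracadabra"),
                        build_codebook(charToRaw("abracadabra")))
  expect_identical(enc$bit_count, 23L)

  book1 <- build_codebook(charToRaw("aaaa"))
  expect_identical(book1$lengths, 1L)
  expect_identical(huffman_encode(charToRaw("aaaa"), book1)$bit_count, 4L)

  uni <- charToRaw("wxyz")
  expect_true(all(build_codebook(uni)$lengths == 2L))
})

test_that("codebooks satisfy Kraft equality and prefix-freeness", {
  set.seed(2)
  for (i in 1:20) {
    n_sym <- sample(2:12, 1)
    payload <- as.raw(sample(sample(0:255, n_sym), 200, replace = TRUE,
                             prob = runif(n_sym)))
    book <- build_codebook(payload)
    expect_equal(sum(2^(-book$lengths)), 1)
    cc <- roipack:::canonical_codes(book)
    codes <- mapply(function(code, len) {
      paste(as.integer((code %/% 2^((len - 1):0)) %% 2), collapse = "")
    }, cc$codes, cc$lengths)
    for (a in seq_along(codes)) {
      for (b in seq_along(codes)) {
        if (a != b) expect_false(startsWith(codes[b], codes[a]))
      }
    }
  }
})

test_that("encoded size equals sum of frequency times length", {
  set.seed(3)
  for (i in 1:10) {
    payload <- as.raw(sample(0:20, 300, replace = TRUE))
    book <- build_codebook(payload)
    freq <- tabulate(as.integer(payload) + 1L, 256L)
    expected <- sum(freq[book$symbols + 1L] * book$lengths)
    expect_identical(huffman_encode(payload, book)$bit_count, expected)
  }
})

test_that("tree construction is exhaustive-search optimal on small alphabets", {
  set.seed(4)
  for (i in 1:25) {
    n_sym <- sample(2:6, 1)
    freqs <- sample(1:20, n_sym, replace = TRUE)
    syms <- sample(0:255, n_sym)
    payload <- as.raw(rep(syms, times = freqs))
    expect_identical(huffman_payload_bits(payload),
                     as.integer(optimal_prefix_bits(freqs)))
  }
})

test_that("decode inverts encode for arbitrary payloads", {
  set.seed(5)
  for (i in 1:20) {
    payload <- as.raw(sample(0:255, sample(1:500, 1), replace = TRUE))
    book <- build_codebook(payload)
    enc <- huffman_encode(payload, book)
    expect_identical(huffman_decode(enc$bits, enc$bit_count, book), payload)
  }
  # empty payload with a nonempty book: zero bits
  book <- build_codebook(charToRaw("xy"))
  enc <- huffman_encode(raw(0), book)
  expect_identical(enc$bit_count, 0L)
  expect_identical(huffman_decode(enc$bits, 0L, book), raw(0))
})

test_that("error modes: empty payload, coverage, truncation", {
  expect_error(build_codebook(raw(0)), class = "roipack_empty_payload")
  book <- build_codebook(charToRaw("aab"))
  expect_error(huffman_encode(charToRaw("abc"), book),
               class = "roipack_coverage_error")
  enc <- huffman_encode(charToRaw("aab"), book)
  expect_error(huffman_decode(enc$bits, 8L * length(enc$bits) + 1L, book),
               class = "roipack_truncation_error")
  # a uniform 4-symbol book has only 2-bit codes: an odd bit count must
  # leave a dangling half-code
  uni <- build_codebook(charToRaw("wxyz"))
  expect_error(huffman_decode(as.raw(0L), 3L, uni),
               class = "roipack_truncation_error")
})

test_that("codebook serialization is a fixed-layout identity", {
  set.seed(6)
  for (i in 1:10) {
    payload <- as.raw(sample(0:255, sample(2:300, 1), replace = TRUE))
    book <- build_codebook(payload)
    blob <- serialize_codebook(book)
    expect_identical(length(blob), 1L + 2L * book$symbol_count)
    back <- deserialize_codebook(blob)
    expect_identical(back$symbols, book$symbols)
    expect_identical(back$lengths, book$lengths)
  }
  five <- build_codebook(charToRaw("abracadabra"))
  expect_identical(length(serialize_codebook(five)), 11L)
  expect_error(deserialize_codebook(as.raw(c(7, 1, 2, 250))),
               class = "roipack_structure_error")
  expect_error(deserialize_codebook(as.raw(c(2, 10, 3, 10, 3))),
               class = "roipack_structure_error")
})

test_that("compressed text never exceeds the trivial 8-bit bound", {
  set.seed(7)
  for (i in 1:10) {
    payload <- as.raw(sample(0:255, sample(10:200, 1), replace = TRUE))
    expect_lte(huffman_payload_bits(payload), 8L * length(payload))
  }
})
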