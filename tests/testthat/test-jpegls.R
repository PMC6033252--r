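test_that("the median edge detector follows its three-branch rule", {
  expect_identical(med_predict(100, 120, 90), 120)
  expect_identical(med_predict(7, 7, 7), 7)
  expect_identical(med_predict(10, 30, 20), 20)
  expect_identical(med_predict(100, 120, 130), 100)
  # vectorized
  expect_identical(med_predict(c(100, 10), c(120, 30), c(90, 20)),
                   c(120, 20))
})

test_that("golomb-rice primitives match their closed forms and invert", {
  expect_identical(golomb_rice_encode(9L, 2L), c(1L, 1L, 0L, 0L, 1L))
  for (k in c(0L, 3L, 7L)) {
    expect_identical(length(golomb_rice_encode(0L, k)), k + 1L)
  }
  set.seed(8)
  for (i in 1:300) {
    m <- sample(0:65535, 1)
    k <- sample(0:14, 1)
    bits <- golomb_rice_encode(m, k)
    dec <- golomb_rice_decode(bits, k)
    expect_identical(dec$value, m)
    expect_identical(dec$n_bits, length(bits))
  }
  expect_error(golomb_rice_decode(c(1L, 1L), 0L),
               class = "roipack_truncation_error")
})

test_that("plane coding is lossless across bit depths and content", {
  set.seed(10)
  for (i in 1:15) {
    bits <- sample(8:16, 1)
    nr <- sample(2:40, 1)
    nc <- sample(2:40, 1)
    m <- matrix(sample.int(2L^bits, nr * nc, replace = TRUE) - 1L, nr, nc)
    stream <- encode_plane(m, bits)
    back <- decode_plane(stream)
    expect_identical(back[, ], m)
    expect_identical(attr(back, "bits_stored"), bits)
  }
  # adversarial alternating extremes exercise the escape path
  alt <- matrix(rep(c(0L, 65535L), length.out = 31 * 17), 31, 17)
  expect_identical(decode_plane(encode_plane(alt, 16L))[, ], alt)
  # minimal edge case
  z <- matrix(0L, 2, 2)
  expect_identical(decode_plane(encode_plane(z, 16L))[, ], z)
})

test_that("phantom crops round-trip bit-exactly", {
  for (seed in 1:5) {
    ph <- small_phantom(seed)
    seg <- segment_roi(ph$record)
    bb <- seg$bbox
    crop <- ph$record$pixels[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4]]
    expect_identical(decode_plane(encode_plane(crop, 16L))[, ], crop)
  }
})

test_that("flat planes compress far below raw size", {
  m <- matrix(513L, 256, 256)
  stream <- encode_plane(m, 16L)
  # regular mode floors near 1 bit/sample on constant input (~2 with
  # context warm-up); assert well under a fifth of the raw bytes
  expect_lt(length(stream), 0.2 * 256 * 256 * 2)
  expect_identical(decode_plane(stream)[, ], m)
})

test_that("noise increases stream size on the same crop", {
  ph <- small_phantom(31, noise_sigma = 0)
  seg <- segment_roi(ph$record)
  bb <- seg$bbox
  crop <- ph$record$pixels[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4]]
  set.seed(31)
  noisy <- pmin(65535L, pmax(0L, crop + as.integer(round(rnorm(length(crop),
                                                               0, 16)))))
  noisy <- matrix(noisy, nrow(crop))
  expect_lt(length(encode_plane(crop, 16L)),
            length(encode_plane(noisy, 16L)))
})

test_that("encoder and decoder end in identical context state", {
  set.seed(12)
  m <- matrix(sample.int(4096L, 600, replace = TRUE) - 1L, 20, 30)
  enc <- encode_plane(m, 12L, with_state = TRUE)
  dec <- decode_plane(enc, with_state = TRUE)
  expect_identical(attr(enc, "state"), attr(dec, "state"))
})

test_that("format and range violations are rejected", {
  expect_error(encode_plane(matrix(256L, 2, 2), 8L),
               class = "roipack_range_error")
  expect_error(encode_plane(matrix(0L, 2, 2), 20L),
               class = "roipack_format_error")
  expect_error(decode_plane(as.raw(1:5)), class = "roipack_format_error")
  good <- encode_plane(matrix(sample(0:255, 400, TRUE), 20, 20), 8L)
  expect_error(decode_plane(good[1:20]), class = "roipack_truncation_error")
})
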