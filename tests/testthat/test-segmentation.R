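disk_image <- function(n = 96L, r = 25L, value = 1000L) {
  ctr <- (n + 1) / 2
  d2 <- outer(seq_len(n), seq_len(n),
              function(i, j) (i - ctr)^2 + (j - ctr)^2)
  m <- matrix(0L, n, n)
  m[d2 <= r^2] <- value
  m
}

test_that("a noiseless disk yields exact region means", {
  img <- disk_image()
  res <- segment_roi(image_record(img, 16L))
  expect_true(res$converged)
  expect_identical(res$c_in, 1000)
  expect_identical(res$c_out, 0)
  truth <- img > 0L
  expect_gte(dice_coefficient(res$mask, truth), 0.99)
})

test_that("phantom masks are recovered accurately with and without noise", {
  ph <- small_phantom(21, rows = 256L, cols = 256L, noise_sigma = 0)
  res <- segment_roi(ph$record)
  expect_gte(dice_coefficient(res$mask, ph$truth$roi_mask), 0.98)

  noisy <- small_phantom(22, rows = 256L, cols = 256L,
                         noise_sigma = 0.05 * 65535, noise_everywhere = TRUE)
  res2 <- segment_roi(noisy$record)
  expect_gte(dice_coefficient(res2$mask, noisy$truth$roi_mask), 0.90)
})

test_that("the energy trace is non-increasing", {
  ph <- small_phantom(23)
  res <- segment_roi(ph$record)
  increases <- diff(res$energy)
  expect_true(all(increases <= 1e-6 * res$energy[1]))
})

test_that("ROI always labels the brighter region", {
  ph <- small_phantom(24, noise_sigma = 0)
  maxv <- 2L^16L - 1L
  res <- segment_roi(ph$record)
  inverted <- image_record(maxv - ph$record$pixels, 16L)
  res_inv <- segment_roi(inverted)
  # the brighter phase of the inverted image is the old background
  expect_gt(res$c_in, res$c_out)
  expect_gt(res_inv$c_in, res_inv$c_out)
  expect_lt(dice_coefficient(res_inv$mask, ph$truth$roi_mask), 0.5)
})

test_that("degenerate inputs raise the dedicated errors", {
  expect_error(segment_roi(image_record(matrix(5L, 32, 32), 16L)),
               class = "roipack_degenerate_image")
})

test_that("bbox_of is tight, padded and clipped", {
  m <- matrix(FALSE, 10, 12)
  m[4, 8] <- TRUE
  expect_identical(bbox_of(m), c(3L, 7L, 4L, 8L))
  expect_identical(bbox_of(matrix(TRUE, 5, 6)), c(0L, 0L, 5L, 6L))
  expect_error(bbox_of(matrix(FALSE, 3, 3)), class = "roipack_empty_mask")

  set.seed(9)
  for (i in 1:20) {
    m <- matrix(runif(30 * 40) < 0.05, 30, 40)
    if (!any(m)) next
    bb <- bbox_of(m, pad = 2L)
    idx <- which(m, arr.ind = TRUE)
    expect_true(all(idx[, 1] > bb[1] & idx[, 1] <= bb[3]))
    expect_true(all(idx[, 2] > bb[2] & idx[, 2] <= bb[4]))
    # shrinking any unclipped side violates the pad or drops a pixel
    if (bb[1] > 0) expect_lte(min(idx[, 1]) - 1 - bb[1], 2)
    if (bb[2] > 0) expect_lte(min(idx[, 2]) - 1 - bb[2], 2)
    if (bb[3] < 30) expect_lte(bb[3] - max(idx[, 1]), 2)
    if (bb[4] < 40) expect_lte(bb[4] - max(idx[, 2]), 2)
  }
})

test_that("glance and tidy expose the fit summary", {
  ph <- small_phantom(25)
  res <- segment_roi(ph$record)
  g <- glance(res)
  expect_s3_class(g, "tbl_df")
  expect_identical(nrow(g), 1L)
  expect_identical(g$iterations, res$iterations)
  td <- tidy(res)
  expect_identical(nrow(td), length(res$energy))
})
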