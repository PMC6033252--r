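random_patient <- function() {
  list(
    name = sample(c("AYSE", "ERDAL", "MEHMET", "FATMA"), 1),
    surname = sample(c("YILMAZ", "ERDAL", "KAYA", "DEMIR"), 1),
    citizenship_id = paste(sample(0:9, 11, replace = TRUE), collapse = ""),
    study_date = sprintf("20%02d-%02d-%02d", sample(13:17, 1),
                         sample(1:12, 1), sample(1:28, 1))
  )
}

test_that("put/get is the identity, including edge-case blob sizes", {
  ar <- archive_open(chunk_size = 256L)
  blob <- as.raw(sample(0:255, 1000, replace = TRUE))
  archive_put(ar, 1L, random_patient(), blob)
  expect_identical(archive_get(ar, 1L), blob)

  archive_put(ar, 2L, random_patient(), raw(0))
  expect_identical(archive_get(ar, 2L), raw(0))
  expect_identical(search_by_id(ar, 2L)$n_chunks, 0L)

  # exact multiple of the chunk size
  blob2 <- as.raw(rep(7L, 512))
  e <- archive_put(ar, 3L, random_patient(), blob2)
  expect_identical(e$n_chunks, 2L)
  expect_identical(archive_get(ar, 3L), blob2)
})

test_that("chunk count follows the ceiling rule", {
  ar <- archive_open(chunk_size = 256L * 1024L)
  blob <- as.raw(rep(1L, 1024 * 1024))
  e <- archive_put(ar, 10L, random_patient(), blob)
  expect_identical(e$n_chunks, 4L)
  set.seed(13)
  ar2 <- archive_open(chunk_size = 1000L)
  for (i in 1:20) {
    n <- sample(0:5000, 1)
    e <- archive_put(ar2, i, random_patient(), as.raw(rep(0L, n)))
    expect_identical(e$n_chunks, as.integer(ceiling(n / 1000)))
    expect_identical(length(archive_get(ar2, i)), n)
  }
})

test_that("duplicate keys conflict unless overwrite is requested", {
  ar <- archive_open()
  archive_put(ar, 5L, random_patient(), as.raw(1:3))
  expect_error(archive_put(ar, 5L, random_patient(), as.raw(4:6)),
               class = "roipack_key_conflict")
  archive_put(ar, 5L, random_patient(), as.raw(7:9), overwrite = TRUE)
  expect_identical(archive_get(ar, 5L), as.raw(7:9))
})

test_that("primary-key search finds entries and rejects unknown ids", {
  ar <- archive_open()
  p <- random_patient()
  archive_put(ar, 42L, p, as.raw(1:10))
  e <- search_by_id(ar, 42L)
  expect_identical(e$hims_id, 42L)
  expect_identical(e$patient$surname, p$surname)
  expect_error(search_by_id(ar, 43L), class = "roipack_not_found")
  expect_error(archive_get(ar, 43L), class = "roipack_not_found")
})

test_that("criteria search equals the linear-scan oracle", {
  set.seed(14)
  ar <- archive_open()
  for (i in 1:200) {
    archive_put(ar, i, random_patient(), as.raw(i %% 256))
  }
  for (trial in 1:30) {
    crit <- list()
    if (runif(1) < 0.5) crit$name <- sample(c("AYSE", "ERDAL", "NOBODY"), 1)
    if (runif(1) < 0.5) crit$surname <- sample(c("KAYA", "ERDAL"), 1)
    if (runif(1) < 0.4) {
      crit$date_from <- "2014-01-01"
      crit$date_to <- "2016-01-01"
    }
    if (length(crit) == 0L) crit$surname <- "DEMIR"
    got <- do.call(search_by_criteria, c(list(ar), crit))
    want <- do.call(scan_oracle, c(list(ar), crit))
    expect_identical(got, want)
  }
})

test_that("date ranges are half-open as in the query convention", {
  ar <- archive_open()
  dates <- c("2015-12-31", "2016-01-01", "2016-06-15", "2017-01-01")
  for (i in seq_along(dates)) {
    p <- random_patient()
    p$study_date <- dates[i]
    archive_put(ar, i, p, as.raw(i))
  }
  got <- search_by_criteria(ar, date_from = "2016-01-01",
                            date_to = "2017-01-01")
  expect_identical(got, c(2L, 3L))
})

test_that("criteria-less searches are refused by default", {
  ar <- archive_open()
  archive_put(ar, 1L, random_patient(), as.raw(1))
  expect_error(search_by_criteria(ar), class = "roipack_empty_criteria")
  expect_identical(search_by_criteria(ar, allow_scan = TRUE), 1L)
})

test_that("memory and file backends answer identically", {
  set.seed(15)
  dir <- tempfile("ar")
  mem <- archive_open("memory", chunk_size = 700L)
  fil <- archive_open("file", path = dir, chunk_size = 700L)
  blobs <- lapply(1:25, function(i) {
    as.raw(sample(0:255, sample(0:3000, 1), replace = TRUE))
  })
  pats <- lapply(1:25, function(i) random_patient())
  for (i in 1:25) {
    archive_put(mem, i, pats[[i]], blobs[[i]])
    archive_put(fil, i, pats[[i]], blobs[[i]])
  }
  for (i in 1:25) {
    expect_identical(archive_get(mem, i), archive_get(fil, i))
  }
  for (sn in c("YILMAZ", "KAYA", "ERDAL", "DEMIR")) {
    expect_identical(search_by_criteria(mem, surname = sn),
                     search_by_criteria(fil, surname = sn))
  }
  # a cold re-open of the file backend sees the same store
  fil2 <- archive_open("file", path = dir, chunk_size = 700L)
  expect_identical(archive_get(fil2, 7L), blobs[[7]])
  expect_identical(search_by_criteria(fil2, surname = "KAYA"),
                   search_by_criteria(mem, surname = "KAYA"))
  unlink(dir, recursive = TRUE)
})

test_that("a package survives the archive loop end to end", {
  ph <- small_phantom(99)
  pkg <- compress_package(list(ph$record))
  ar <- archive_open(chunk_size = 4096L)
  archive_put(ar, 52721L, list(name = "ERDAL", surname = "ERDAL",
                               study_date = "2016-03-01"), pkg)
  back <- archive_get(ar, 52721L)
  expect_identical(back, pkg)
  recon <- reconstruct_package(back)
  bb <- read_package(back)[[1]]$bbox
  expect_identical(
    recon[[1]]$pixels[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4]],
    ph$record$pixels[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4]]
  )
})
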