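test_that("write/read round trips pixels and metadata bit-exactly", {
  set.seed(1)
  for (i in 1:10) {
    bits <- sample(8:16, 1)
    rec <- random_record(rows = sample(8:40, 1), cols = sample(8:40, 1),
                         bits = bits)
    back <- read_dicom(write_dicom(rec))
    expect_identical(back$pixels, rec$pixels)
    expect_identical(back$bits_stored > 8L, bits > 8L)
    expect_identical(back$metadata[order(names(back$metadata))],
                     rec$metadata[order(names(rec$metadata))])
  }
})

test_that("phantom metadata survives the DICOM boundary", {
  ph <- small_phantom(3)
  back <- read_dicom(write_dicom(ph$record))
  expect_identical(back$metadata$PatientName, "AYSE")
  expect_identical(back$metadata$StudyDate, "2016-01-01")
  expect_identical(back$pixels, ph$record$pixels)
})

test_that("pixel payload width follows bits_stored", {
  rec8 <- random_record(rows = 11L, cols = 13L, bits = 8L)
  rec16 <- random_record(rows = 11L, cols = 13L, bits = 16L)
  stream8 <- write_dicom(rec8)
  stream16 <- write_dicom(rec16)
  # locate the pixel-data element (7FE0,0010) and check its declared length
  find_pixel_len <- function(bytes) {
    tag <- as.raw(c(0xE0, 0x7F, 0x10, 0x00))
    for (p in seq_len(length(bytes) - 12L)) {
      if (identical(bytes[p:(p + 3L)], tag)) {
        return(roipack:::rd_u32(bytes, p + 8L))
      }
    }
    NA
  }
  expect_equal(find_pixel_len(stream8), 2 * ceiling(11 * 13 / 2)) # padded
  expect_equal(find_pixel_len(stream16), 11 * 13 * 2)
})

test_that("optional metadata fields may be absent", {
  rec <- random_record(metadata = list(PatientName = "ONLY"))
  back <- read_dicom(write_dicom(rec))
  expect_identical(back$metadata, list(PatientName = "ONLY"))
})

test_that("non-DICOM input is rejected", {
  expect_error(read_dicom(raw(0)), class = "roipack_parse_error")
  expect_error(read_dicom(as.raw(sample(0:255, 200, replace = TRUE))),
               class = "roipack_parse_error")
})

test_that("wrap_dicom demands the archival fields", {
  ph <- small_phantom(4)
  expect_error(wrap_dicom(ph$record, list(PatientName = "X")),
               class = "roipack_format_error")
  md <- random_metadata()
  bytes <- wrap_dicom(ph$record, md)
  expect_identical(read_dicom(bytes)$pixels, ph$record$pixels)
})

test_that("an independent DICOM reader parses the writer's output", {
  rec <- random_record(rows = 9L, cols = 7L, bits = 16L,
                       metadata = list(PatientName = "ERDAL",
                                       PatientSurname = "TEST",
                                       HIMSID = "52721"))
  f <- tempfile(fileext = ".dcm")
  writeBin(write_dicom(rec), f)
  script <- paste(
    "import sys, pydicom",
    "d = pydicom.dcmread(sys.argv[1])",
    "print(d.Rows, d.Columns, d.BitsStored, str(d.PatientName),",
    "      d.AccessionNumber, int(d.pixel_array[0,0]), sep='|')",
    sep = "\n"
  )
  out <- tryCatch(
    system2("python", c("-c", shQuote(script), shQuote(f)),
            stdout = TRUE, stderr = TRUE),
    error = function(e) NULL
  )
  expect_false(is.null(out))
  parts <- strsplit(paste(out, collapse = ""), "|", fixed = TRUE)[[1]]
  expect_identical(parts[1:3], c("9", "7", "16"))
  expect_identical(parts[4], "TEST^ERDAL")
  expect_identical(parts[5], "52721")
  expect_identical(as.integer(parts[6]), rec$pixels[1, 1])
})
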