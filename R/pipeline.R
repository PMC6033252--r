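# End-to-end orchestration: segment -> crop -> lossless ROI coding -> OCR ->
# container, the reverse reconstruction, a scatter-gather worker pool for
# batches (map one image per worker, reduce by consolidating into a single
# container in input order), and the compression metrics in both ratio
# conventions.

#' Compress a single image
#'
#' Runs the full per-image preprocessing: Chan-Vese segmentation, bounding
#' box crop of the ROI (pixels inside the box but outside the mask are kept -
#' a lossless superset), LOCO-I encoding of the crop, and OCR text extraction
#' over the non-ROI region. The background is discarded: only the ROI stream,
#' the text runs and the whitelisted metadata survive.
#'
#' @param rec An [image_record()].
#' @param seg A [segmentation_params()].
#' @param atlas Font atlas for OCR.
#' @param pad Bounding-box padding in pixels.
#' @return A [compressed_image()].
#' @export
compress_image <- function(rec, seg = segmentation_params(),
                           atlas = default_font_atlas(), pad = 0L) {
  stopifnot(inherits(rec, "image_record"))
  id <- rec$metadata$HIMSID
  ctx <- if (is.null(id)) "image" else sprintf("image HIMSID=%s", id)
  roi <- tryCatch(
    segment_roi(rec, seg, pad = pad),
    roipack_error = function(e) {
      rp_stop(class(e)[1L], "%s: %s", ctx, conditionMessage(e))
    }
  )
  bb <- roi$bbox
  crop <- rec$pixels[(bb[1L] + 1L):bb[3L], (bb[2L] + 1L):bb[4L],
                     drop = FALSE]
  stream <- encode_plane(crop, rec$bits_stored)
  runs <- extract_runs(rec, roi$mask, atlas)
  md <- rec$metadata[intersect(DICOM_METADATA_FIELDS, names(rec$metadata))]
  compressed_image(
    roi_stream = stream, bbox = bb, rows = rec$rows, cols = rec$cols,
    bits_stored = rec$bits_stored, runs = runs, metadata = md
  )
}

#' Compress a batch of images into one package
#'
#' Scatter-gather batch contract: each image is compressed independently
#' (map), up to `workers` concurrently via a fork-based worker pool, and the
#' results are consolidated into one container in input order (reduce). The
#' output bytes are identical for any worker count; any per-image failure
#' aborts the package with that image's diagnostics.
#'
#' @param recs List of [image_record()]s.
#' @param seg A [segmentation_params()].
#' @param atlas Font atlas for OCR.
#' @param workers Worker count (>= 1).
#' @param pad Bounding-box padding.
#' @return Raw vector: package bytes.
#' @export
compress_package <- function(recs, seg = segmentation_params(),
                             atlas = default_font_atlas(),
                             workers = 1L, pad = 0L) {
  if (inherits(recs, "image_record")) recs <- list(recs)
  stopifnot(length(recs) >= 1L, workers >= 1L)
  map_one <- function(rec) {
    tryCatch(compress_image(rec, seg, atlas, pad), error = identity)
  }
  entries <- if (workers == 1L || .Platform$OS.type == "windows") {
    lapply(recs, map_one)
  } else {
    parallel::mclapply(recs, map_one, mc.cores = workers)
  }
  failed <- vapply(entries, inherits, logical(1), "condition")
  if (any(failed)) {
    msgs <- vapply(entries[failed], conditionMessage, character(1))
    rp_stop("roipack_map_failure",
            "%d image(s) failed:\n%s", sum(failed),
            paste(sprintf("  [%d] %s", which(failed), msgs), collapse = "\n"))
  }
  write_package(entries)
}

#' Reconstruct images from a package
#'
#' Reverse preprocessing: for each stored image, create a black canvas of the
#' original frame size, re-render the text runs at their stored coordinates
#' and intensity, and paste the losslessly decoded ROI crop at its bounding
#' box. ROI pixels are bit-exact; the discarded background is regenerated as
#' black.
#'
#' @param package Raw package bytes (or path).
#' @param atlas Font atlas for re-rendering.
#' @param as_dicom If `TRUE`, return DICOM byte streams instead of records.
#' @return List of [image_record()]s (or raw DICOM vectors).
#' @export
reconstruct_package <- function(package, atlas = default_font_atlas(),
                                as_dicom = FALSE) {
  entries <- if (is.list(package)) package else read_package(package)
  out <- lapply(entries, function(e) {
    canvas <- matrix(0L, e$rows, e$cols)
    for (i in seq_len(nrow(e$runs))) {
      r <- e$runs[i, ]
      if (r$row < 0L || r$col < 0L ||
          r$row + atlas$height > e$rows ||
          r$col + (nchar(r$text) - 1L) * atlas$advance + atlas$width >
            e$cols) {
        rp_stop("roipack_consistency_error",
                "text run %s outside the %dx%d frame",
                sQuote(r$text), e$rows, e$cols)
      }
      canvas <- render_text(canvas, r$text, r$row, r$col, r$intensity, atlas)
    }
    crop <- decode_plane(e$roi_stream)
    bb <- e$bbox
    if (!identical(dim(crop), c(bb[3L] - bb[1L], bb[4L] - bb[2L]))) {
      rp_stop("roipack_consistency_error",
              "roi stream decodes to %dx%d, bbox implies %dx%d",
              nrow(crop), ncol(crop), bb[3L] - bb[1L], bb[4L] - bb[2L])
    }
    canvas[(bb[1L] + 1L):bb[3L], (bb[2L] + 1L):bb[4L]] <- crop
    rec <- image_record(canvas, e$bits_stored, e$metadata)
    if (as_dicom) write_dicom(rec) else rec
  })
  out
}

#' Compression metrics for a package
#'
#' Per-image and total sizes in both ratio conventions: `fold_ratio`
#' (original bytes over compressed bytes) and `percent_saved`
#' (`100 * (1 - compressed/original)`). The ROI segment compares the raw
#' bounding-box crop against its LOCO-I stream; the non-ROI segment compares
#' the raw background (frame minus bounding box) against its share of the
#' codebook and coded text sections; the total row compares whole raw frames
#' against the whole package including container overhead.
#'
#' Shared sections (codebook + coded text + their size prefixes) are
#' apportioned to images proportionally to their serialized text-record
#' length.
#'
#' @param recs The original [image_record()]s (same order as packaged).
#' @param package Package bytes (or path).
#' @return Tibble with columns `image`, `segment`, `s_orig`, `s_comp`,
#'   `fold_ratio`, `percent_saved`; class `roipack_metrics`.
#' @export
compression_metrics <- function(recs, package) {
  if (inherits(recs, "image_record")) recs <- list(recs)
  if (is.character(package)) {
    package <- readBin(package, "raw", n = file.size(package))
  }
  entries <- read_package(package)
  if (length(entries) != length(recs)) {
    rp_stop("roipack_consistency_error",
            "package holds %d images, %d originals given",
            length(entries), length(recs))
  }
  n <- length(entries)
  # shared non-ROI sections: tree and text with their prefixes
  secs <- package_sections(package)
  shared <- sum(secs$bytes[secs$section %in% c("codebook", "text")])
  rec_len <- vapply(entries, function(e) {
    length(serialize_text_records(list(e)))
  }, numeric(1))
  share <- shared * rec_len / sum(rec_len)

  rows_out <- list()
  for (i in seq_len(n)) {
    e <- entries[[i]]
    bpp <- if (e$bits_stored <= 8L) 1L else 2L
    bb <- e$bbox
    bbox_px <- (bb[3L] - bb[1L]) * (bb[4L] - bb[2L])
    frame_px <- e$rows * e$cols
    roi_orig <- bbox_px * bpp
    nonroi_orig <- (frame_px - bbox_px) * bpp
    roi_comp <- length(e$roi_stream)
    nonroi_comp <- share[i]
    rows_out[[i]] <- tibble::tibble(
      image = i,
      segment = c("roi", "non_roi"),
      s_orig = c(roi_orig, nonroi_orig),
      s_comp = c(roi_comp, nonroi_comp)
    )
  }
  per_image <- do.call(rbind, rows_out)
  total_orig <- sum(vapply(recs, function(r) {
    r$rows * r$cols * (if (r$bits_stored <= 8L) 1L else 2L)
  }, numeric(1)))
  total <- tibble::tibble(
    image = NA_integer_,
    segment = "total",
    s_orig = total_orig,
    s_comp = length(package)
  )
  out <- rbind(per_image, total)
  out$fold_ratio <- out$s_orig / out$s_comp
  out$percent_saved <- 100 * (1 - out$s_comp / out$s_orig)
  class(out) <- c("roipack_metrics", class(out))
  out
}

#' @export
glance.roipack_metrics <- function(x, ...) {
  seg_mean <- function(s) {
    mean(x$percent_saved[x$segment == s], na.rm = TRUE)
  }
  tibble::tibble(
    n_images = sum(x$segment == "roi"),
    roi_fold = mean(x$fold_ratio[x$segment == "roi"]),
    non_roi_percent_saved = seg_mean("non_roi"),
    total_percent_saved = seg_mean("total")
  )
}

#' @export
autoplot.roipack_metrics <- function(object, ...) {
  df <- object[object$segment != "total", ]
  ggplot2::ggplot(df, ggplot2::aes(x = factor(image), y = percent_saved,
                                   fill = segment)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "image", y = "% saved", fill = "segment")
}
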