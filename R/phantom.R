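# Synthetic MRI-like phantom generation with exact ground truth: a smooth
# bright "anatomy" blob of controlled area on a near-black background, plus
# burned-in annotation text from the shared bitmap font. Everything downstream
# (segmentation, OCR, codecs, pipeline, archive) is testable against the
# generator's ground truth without any patient data.

#' Specify a synthetic phantom
#'
#' Defaults emulate a typical MR series frame: 16-bit samples, black
#' background, maximal-intensity text overlay, and an ROI occupying 32.84% of
#' the frame (the average ROI area fraction of the kind of MRI corpus this
#' toolkit targets). Noise is confined to the ROI by default so the
#' background-discard behavior stays exercisable under both clean and noisy
#' regimes (`noise_everywhere = TRUE` adds it globally).
#'
#' @param rows,cols Frame size in pixels.
#' @param bits_stored Bits per sample, 8..16.
#' @param roi_fraction Target ROI area fraction, in (0, 1).
#' @param noise_sigma Additive Gaussian noise standard deviation in grey
#'   levels (>= 0). The default is 1% of the representable range.
#' @param noise_everywhere Add noise to the whole frame instead of the ROI
#'   only.
#' @param text_lines Character vector of annotation strings (uppercase
#'   letters, digits, `- . : /` and space).
#' @param text_intensity Grey level of rendered glyph pixels; defaults to the
#'   maximal grey level.
#' @param background_level Grey level of the non-ROI background.
#' @param seed Integer RNG seed; identical specs generate bit-identical
#'   phantoms.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(rows = 512L, cols = 512L, bits_stored = 16L,
                         roi_fraction = 0.3284,
                         noise_sigma = 0.01 * (2^bits_stored - 1),
                         noise_everywhere = FALSE,
                         text_lines = c("PATIENT 12345", "MRI T1 AX",
                                        "2016-01-01"),
                         text_intensity = 2^bits_stored - 1,
                         background_level = 0L,
                         seed = 1L) {
  bits_stored <- as.integer(bits_stored)
  maxval <- 2^bits_stored - 1
  stopifnot(
    rows >= 32L, cols >= 32L,
    bits_stored >= 8L, bits_stored <= 16L,
    roi_fraction > 0, roi_fraction < 1,
    noise_sigma >= 0,
    text_intensity <= maxval, text_intensity >= 0,
    background_level >= 0, background_level <= maxval
  )
  text_lines <- as.character(text_lines)
  if (any(text_lines != trimws(text_lines)) || any(!nzchar(text_lines))) {
    rp_stop("roipack_format_error",
            "text lines must be nonempty with no leading/trailing spaces")
  }
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         bits_stored = bits_stored, roi_fraction = roi_fraction,
         noise_sigma = noise_sigma, noise_everywhere = noise_everywhere,
         text_lines = text_lines, text_intensity = as.integer(text_intensity),
         background_level = as.integer(background_level),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# smooth anatomy field: sum of 2-5 anisotropic Gaussian blobs near the frame
# center; the ROI is the superlevel set whose threshold is found by bisection
# so the realized area fraction matches the request.
phantom_field <- function(rows, cols) {
  k <- sample(2:5, 1L)
  rr <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  f <- matrix(0, rows, cols)
  for (i in seq_len(k)) {
    cy <- runif(1, 0.35, 0.65) * rows
    cx <- runif(1, 0.35, 0.65) * cols
    sy <- runif(1, 0.10, 0.22) * rows
    sx <- runif(1, 0.10, 0.22) * cols
    amp <- runif(1, 0.6, 1.0)
    f <- f + amp * exp(-((rr - cy)^2 / (2 * sy^2) + (cc - cx)^2 / (2 * sx^2)))
  }
  f
}

threshold_for_fraction <- function(field, fraction) {
  lo <- 0
  hi <- max(field)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (mean(field > mid) > fraction) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic phantom with ground truth
#'
#' Produces a deterministic (seeded) MRI-like frame: a smooth ellipsoidal
#' anatomy region of approximately `roi_fraction` area in the frame center,
#' background at `background_level`, annotation lines rendered in the non-ROI
#' margin from the built-in font, and optional additive Gaussian noise. The
#' ground truth records the exact ROI mask (always disjoint from glyph
#' pixels), the rendered text runs with their anchors, and the realized area
#' fraction.
#'
#' @param spec A [phantom_spec()].
#' @return List with `record` (an [image_record()] carrying generated patient
#'   metadata) and `truth` (list: `roi_mask`, `text_runs` tibble with
#'   columns `text`, `row`, `col` (0-based anchors), `intensity`, and
#'   `roi_area_fraction`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  atlas <- default_font_atlas()
  maxval <- 2^spec$bits_stored - 1

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  field <- phantom_field(spec$rows, spec$cols)
  thr <- threshold_for_fraction(field, spec$roi_fraction)
  mask <- field > thr

  # smooth interior intensities: 0.3..0.9 of range above background
  img <- matrix(spec$background_level, spec$rows, spec$cols)
  rel <- (field[mask] - thr) / (max(field) - thr)
  img[mask] <- as.integer(round((0.3 + 0.6 * rel) * maxval))

  # place text lines in the margins; a line band must not touch the mask
  runs <- place_text_lines(spec, mask, atlas)
  for (i in seq_len(nrow(runs))) {
    img <- render_text(img, runs$text[i], runs$row[i], runs$col[i],
                       spec$text_intensity, atlas)
  }

  if (spec$noise_sigma > 0) {
    if (spec$noise_everywhere) {
      glyph_px <- matrix(FALSE, spec$rows, spec$cols)
      for (i in seq_len(nrow(runs))) {
        ink <- run_ink_pixels(runs$text[i], runs$row[i], runs$col[i], atlas)
        glyph_px[ink] <- TRUE
      }
      tgt <- !glyph_px
    } else {
      tgt <- mask
    }
    nse <- round(rnorm(sum(tgt), 0, spec$noise_sigma))
    img[tgt] <- pmin(maxval, pmax(0, img[tgt] + nse))
  }
  storage.mode(img) <- "integer"

  metadata <- list(
    HIMSID = as.character(100000L + spec$seed %% 100000L),
    PatientName = "AYSE",
    PatientSurname = "YILMAZ",
    CitizenshipID = sprintf("%.0f", 10000000000 + (spec$seed %% 99999)),
    StudyDate = "2016-01-01"
  )
  record <- image_record(img, spec$bits_stored, metadata)
  truth <- list(
    roi_mask = mask,
    text_runs = runs,
    roi_area_fraction = mean(mask)
  )
  list(record = record, truth = truth)
}

# choose anchors for each text line: scan candidate bands from the top and
# bottom margins inward and take the first whose clearance-expanded footprint
# is disjoint from the ROI mask and from already placed lines. Glyphs must
# sit clear of anatomy: a segmented mask is only pixel-accurate and the OCR
# stage masks a dilated ROI zone, so real burned-in overlays keep a margin.
place_text_lines <- function(spec, mask, atlas, clearance = 5L) {
  n <- length(spec$text_lines)
  if (n == 0L) {
    return(tibble::tibble(text = character(0), row = integer(0),
                          col = integer(0), intensity = integer(0)))
  }
  margin <- 4L
  spacing <- atlas$height + 3L
  col0 <- margin
  rows_out <- integer(n)
  cols_out <- integer(n)
  slots <- seq(margin, spec$rows - margin - atlas$height, by = spacing)
  if (length(slots) == 0L) {
    rp_stop("roipack_sizing_error",
            "frame of %d rows has no room for a text band", spec$rows)
  }
  # interleave top-down and bottom-up preferences
  pref <- unique(as.vector(rbind(slots, rev(slots))))
  taken <- logical(length(slots))
  for (i in seq_len(n)) {
    line <- spec$text_lines[[i]]
    width <- (nchar(line) - 1L) * atlas$advance + atlas$width
    if (col0 + width > spec$cols - margin) {
      rp_stop("roipack_sizing_error",
              "text line %s too wide for a %d-column frame",
              sQuote(line), spec$cols)
    }
    placed <- FALSE
    col_cands <- unique(c(col0, spec$cols - margin - width))
    for (r0 in pref) {
      slot_idx <- match(r0, slots)
      if (taken[slot_idx]) next
      for (cc in col_cands) {
        band <- mask[
          max(1L, r0 + 1L - clearance):
            min(spec$rows, r0 + atlas$height + clearance),
          max(1L, cc + 1L - clearance):
            min(spec$cols, cc + width + clearance),
          drop = FALSE
        ]
        if (!any(band)) {
          rows_out[i] <- r0
          cols_out[i] <- cc
          taken[slot_idx] <- TRUE
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) {
      rp_stop("roipack_sizing_error",
              "roi_fraction too large to fit text line %s in the margins",
              sQuote(line))
    }
  }
  tibble::tibble(
    text = spec$text_lines,
    row = rows_out,
    col = cols_out,
    intensity = rep(spec$text_intensity, n)
  )
}
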