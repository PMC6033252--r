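# Deterministic template-matching OCR against the known bitmap font. The
# background is deleted after text extraction, so the OCR step must be exactly
# reversible for rendered text: glyph cells are matched by Hamming distance to
# the atlas, anchors are recovered to the pixel.

#' Otsu threshold of a set of grey values
#'
#' Maximizes between-class variance over a 256-bin histogram; used to
#' binarize the non-ROI region before glyph matching.
#'
#' @param values Numeric vector of grey levels.
#' @return Threshold; values strictly above it are foreground.
#' @export
otsu_threshold <- function(values) {
  if (length(values) == 0L) {
    return(Inf)
  }
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(rng[1]) # everything at one level: nothing strictly above
  }
  breaks <- seq(rng[1], rng[2], length.out = 257L)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), nbins = 256L)
  w <- cumsum(h)
  mids <- (breaks[-1L] + breaks[-257L]) / 2
  m <- cumsum(h * mids)
  total_w <- w[256L]
  total_m <- m[256L]
  between <- (total_m * w - m * total_w)^2 /
    (w * (total_w - w))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# binary dilation by k pixels (8-neighborhood, iterated)
mask_dilate <- function(mask, k) {
  k <- as.integer(k)
  if (k <= 0L) {
    return(mask)
  }
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- mask
  for (i in seq_len(k)) {
    g <- out
    g[-1L, ] <- g[-1L, ] | out[-nr, ]
    g[-nr, ] <- g[-nr, ] | out[-1L, ]
    g[, -1L] <- g[, -1L] | g[, -nc]
    g[, -nc] <- g[, -nc] | g[, -1L]
    out <- g
  }
  out
}

#' Match one glyph cell against the font atlas
#'
#' Returns the atlas character with minimal Hamming distance to the
#' binarized cell, ties broken by character code point. An entirely blank
#' cell is the space character by convention.
#'
#' @param cell Logical matrix of the atlas glyph dimensions (`TRUE` = ink).
#' @param atlas A [default_font_atlas()]-style atlas.
#' @return List with `character` and `distance`.
#' @export
match_glyph <- function(cell, atlas = default_font_atlas()) {
  stopifnot(identical(dim(cell), c(atlas$height, atlas$width)))
  if (!any(cell)) {
    return(list(character = " ", distance = 0L))
  }
  chars <- names(atlas$glyphs)
  dists <- vapply(atlas$glyphs, function(g) sum(g != cell), integer(1))
  ord <- order(dists, chars)
  list(character = chars[ord[1L]], distance = as.integer(dists[ord[1L]]))
}

#' Extract burned-in text runs from the non-ROI region
#'
#' Binarizes the pixels outside the ROI mask (Otsu by default), groups the
#' above-threshold pixels into text lines by vertical overlap of connected
#' components, aligns each line to the monospaced glyph grid (searching the
#' small set of feasible cell offsets for the alignment with minimal total
#' Hamming distance), and matches every cell against the atlas. Runs are
#' returned top-to-bottom, left-to-right with exact 0-based anchors; each
#' run's intensity is the median grey level of its matched ink pixels.
#'
#' Cells whose best match still differs from the atlas glyph are kept but
#' counted in the `unmatched` attribute - they are never silently dropped.
#'
#' @param image An [image_record()] or integer matrix.
#' @param roi_mask Logical matrix of the same shape; `TRUE` pixels are
#'   excluded from OCR.
#' @param atlas Font atlas shared with the renderer.
#' @param threshold Binarization threshold; `NULL` (default) uses Otsu on the
#'   non-ROI pixels.
#' @param roi_margin Pixels of dilation applied to `roi_mask` before OCR: a
#'   segmented mask is accurate to a pixel or two, and bright anatomy-edge
#'   strays just outside it must not be mistaken for glyph ink.
#' @return Tibble with columns `text`, `row`, `col`, `intensity` and an
#'   integer attribute `unmatched` (count of imperfectly matched cells).
#' @export
extract_runs <- function(image, roi_mask, atlas = default_font_atlas(),
                         threshold = NULL, roi_margin = 3L) {
  px <- if (inherits(image, "image_record")) image$pixels else image
  stopifnot(is.matrix(px), identical(dim(px), dim(roi_mask)))
  empty <- tibble::tibble(text = character(0), row = integer(0),
                          col = integer(0), intensity = integer(0))
  attr(empty, "unmatched") <- 0L

  excl <- mask_dilate(roi_mask, roi_margin)
  outside <- px[!excl]
  if (is.null(threshold)) {
    threshold <- otsu_threshold(outside)
  }
  fg <- px > threshold & !excl
  if (!any(fg)) {
    return(empty)
  }

  # group ink rows into line bands: runs of consecutive rows containing ink
  # separated by blank rows (glyph rows within a line always overlap).
  ink_rows <- which(rowSums(fg) > 0L)
  bands <- split(ink_rows, cumsum(c(1L, diff(ink_rows) > 1L)))

  texts <- character(0)
  rows0 <- integer(0)
  cols0 <- integer(0)
  intens <- integer(0)
  unmatched <- 0L

  for (band in bands) {
    sub <- fg[band, , drop = FALSE]
    ink_cols <- which(colSums(sub) > 0L)
    c_lo <- min(ink_cols)
    c_hi <- max(ink_cols)
    r_lo <- min(band)
    # candidate grid offsets: the ink bbox top-left may sit up to
    # (height-1, width-1) pixels below/right of the true cell origin.
    best <- NULL
    for (dr in 0:(atlas$height - 1L)) {
      anchor_r <- r_lo - dr
      if (anchor_r < 1L || anchor_r + atlas$height - 1L > nrow(fg)) next
      for (dc in 0:(atlas$width - 1L)) {
        anchor_c <- c_lo - dc
        if (anchor_c < 1L) next
        ncell <- ceiling((c_hi - anchor_c + 1L) / atlas$advance)
        if (anchor_c + (ncell - 1L) * atlas$advance + atlas$width - 1L >
            ncol(fg)) {
          next
        }
        total <- 0L
        chars <- character(ncell)
        dists <- integer(ncell)
        for (k in seq_len(ncell)) {
          cc0 <- anchor_c + (k - 1L) * atlas$advance
          cell <- fg[anchor_r:(anchor_r + atlas$height - 1L),
                     cc0:(cc0 + atlas$width - 1L), drop = FALSE]
          mg <- match_glyph(cell, atlas)
          chars[k] <- mg$character
          dists[k] <- mg$distance
          total <- total + mg$distance
        }
        if (is.null(best) || total < best$total) {
          best <- list(total = total, anchor_r = anchor_r,
                       anchor_c = anchor_c, chars = chars, dists = dists)
        }
        if (best$total == 0L) break
      }
      if (!is.null(best) && best$total == 0L) break
    }
    if (is.null(best)) next
    # trim trailing blanks; leading blanks shift the anchor right
    chars <- best$chars
    nlead <- match(FALSE, chars == " ", nomatch = length(chars) + 1L) - 1L
    if (nlead >= length(chars)) next
    chars <- chars[(nlead + 1L):length(chars)]
    while (length(chars) > 0L && chars[length(chars)] == " ") {
      chars <- chars[-length(chars)]
    }
    if (length(chars) == 0L) next
    anchor_c <- best$anchor_c + nlead * atlas$advance
    text <- paste(chars, collapse = "")
    unmatched <- unmatched + sum(best$dists > 0L)
    # run intensity: median of the matched glyph ink pixels
    ink <- run_ink_pixels(text, best$anchor_r - 1L, anchor_c - 1L, atlas)
    ink <- ink[fg[ink], , drop = FALSE]
    med_int <- if (nrow(ink) > 0L) {
      as.integer(round(median(px[ink])))
    } else {
      NA_integer_
    }
    texts <- c(texts, text)
    rows0 <- c(rows0, best$anchor_r - 1L)
    cols0 <- c(cols0, anchor_c - 1L)
    intens <- c(intens, med_int)
  }

  ord <- order(rows0, cols0)
  out <- tibble::tibble(text = texts[ord], row = rows0[ord],
                        col = cols0[ord], intensity = intens[ord])
  attr(out, "unmatched") <- unmatched
  out
}

# morphological opening: erosion then dilation, both by k pixels
mask_open <- function(mask, k) {
  if (k <= 0L) {
    return(mask)
  }
  mask_dilate(!mask_dilate(!mask, k), k)
}
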