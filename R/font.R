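# 5x7 monospaced bitmap font shared by the phantom renderer and the OCR
# matcher. Glyph rows are strings of '#' (ink) and '.' (blank); all glyphs are
# 5 columns wide, 7 rows tall, advanced 6 columns per character.

.FONT_ROWS <- list(
  "A" = c(".###.", "#...#", "#...#", "#...#", "#####", "#...#", "#...#"),
  "B" = c("####.", "#...#", "#...#", "####.", "#...#", "#...#", "####."),
  "C" = c(".###.", "#...#", "#....", "#....", "#....", "#...#", ".###."),
  "D" = c("###..", "#..#.", "#...#", "#...#", "#...#", "#..#.", "###.."),
  "E" = c("#####", "#....", "#....", "####.", "#....", "#....", "#####"),
  "F" = c("#####", "#....", "#....", "####.", "#....", "#....", "#...."),
  "G" = c(".###.", "#...#", "#....", "#.###", "#...#", "#...#", ".####"),
  "H" = c("#...#", "#...#", "#...#", "#####", "#...#", "#...#", "#...#"),
  "I" = c(".###.", "..#..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "J" = c("..###", "...#.", "...#.", "...#.", "...#.", "#..#.", ".##.."),
  "K" = c("#...#", "#..#.", "#.#..", "##...", "#.#..", "#..#.", "#...#"),
  "L" = c("#....", "#....", "#....", "#....", "#....", "#....", "#####"),
  "M" = c("#...#", "##.##", "#.#.#", "#.#.#", "#...#", "#...#", "#...#"),
  "N" = c("#...#", "##..#", "#.#.#", "#..##", "#...#", "#...#", "#...#"),
  "O" = c(".###.", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "P" = c("####.", "#...#", "#...#", "####.", "#....", "#....", "#...."),
  "Q" = c(".###.", "#...#", "#...#", "#...#", "#.#.#", "#..#.", ".##.#"),
  "R" = c("####.", "#...#", "#...#", "####.", "#.#..", "#..#.", "#...#"),
  "S" = c(".####", "#....", "#....", ".###.", "....#", "....#", "####."),
  "T" = c("#####", "..#..", "..#..", "..#..", "..#..", "..#..", "..#.."),
  "U" = c("#...#", "#...#", "#...#", "#...#", "#...#", "#...#", ".###."),
  "V" = c("#...#", "#...#", "#...#", "#...#", "#...#", ".#.#.", "..#.."),
  "W" = c("#...#", "#...#", "#...#", "#.#.#", "#.#.#", "##.##", "#...#"),
  "X" = c("#...#", "#...#", ".#.#.", "..#..", ".#.#.", "#...#", "#...#"),
  "Y" = c("#...#", "#...#", ".#.#.", "..#..", "..#..", "..#..", "..#.."),
  "Z" = c("#####", "....#", "...#.", "..#..", ".#...", "#....", "#####"),
  "0" = c(".###.", "#...#", "#..##", "#.#.#", "##..#", "#...#", ".###."),
  "1" = c("..#..", ".##..", "..#..", "..#..", "..#..", "..#..", ".###."),
  "2" = c(".###.", "#...#", "....#", "...#.", "..#..", ".#...", "#####"),
  "3" = c(".###.", "#...#", "....#", "..##.", "....#", "#...#", ".###."),
  "4" = c("...#.", "..##.", ".#.#.", "#..#.", "#####", "...#.", "...#."),
  "5" = c("#####", "#....", "####.", "....#", "....#", "#...#", ".###."),
  "6" = c(".###.", "#....", "#....", "####.", "#...#", "#...#", ".###."),
  "7" = c("#####", "....#", "...#.", "..#..", "..#..", "..#..", "..#.."),
  "8" = c(".###.", "#...#", "#...#", ".###.", "#...#", "#...#", ".###."),
  "9" = c(".###.", "#...#", "#...#", ".####", "....#", "....#", ".###."),
  "-" = c(".....", ".....", ".....", "#####", ".....", ".....", "....."),
  "." = c(".....", ".....", ".....", ".....", ".....", ".##..", ".##.."),
  ":" = c(".....", ".##..", ".##..", ".....", ".##..", ".##..", "....."),
  "/" = c("....#", "...#.", "...#.", "..#..", ".#...", ".#...", "#...."),
  " " = c(".....", ".....", ".....", ".....", ".....", ".....", ".....")
)

.font_cache <- new.env(parent = emptyenv())

#' Built-in monospaced bitmap font atlas
#'
#' Returns the fixed 5x7 monospaced font used both to burn annotation text
#' into synthetic phantoms and as the template set for the deterministic OCR
#' matcher. A shared, exactly known atlas is what makes text extraction
#' reversible: every rendered glyph can be recovered pixel for pixel.
#'
#' @return A `font_atlas` object: list with `glyphs` (named list of 7x5
#'   logical matrices, `TRUE` = ink), `height`, `width` and `advance`
#'   (columns from one glyph origin to the next).
#' @examples
#' atlas <- default_font_atlas()
#' atlas$glyphs[["A"]]
#' @export
default_font_atlas <- function() {
  if (!is.null(.font_cache$atlas)) {
    return(.font_cache$atlas)
  }
  glyphs <- lapply(.FONT_ROWS, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) {
      strsplit(r, "")[[1]] == "#"
    }))
    dimnames(m) <- NULL
    m
  })
  atlas <- structure(
    list(glyphs = glyphs, height = 7L, width = 5L, advance = 6L),
    class = "font_atlas"
  )
  .font_cache$atlas <- atlas
  atlas
}

#' Render a text run into an image matrix
#'
#' Stamps glyph bitmaps at a monospaced advance starting from the run anchor
#' (the top-left pixel of the first glyph cell, 0-based). Only ink pixels are
#' modified; the rest of the image is untouched. Used by the phantom
#' generator to burn annotations in and by package reconstruction to re-render
#' extracted text at its stored coordinates.
#'
#' @param image Integer matrix (grey levels).
#' @param text Character scalar; every character must exist in the atlas.
#' @param row,col 0-based anchor of the first glyph's top-left pixel.
#' @param intensity Grey level written at ink pixels.
#' @param atlas A `font_atlas`, by default [default_font_atlas()].
#' @return A modified copy of `image`.
#' @export
render_text <- function(image, text, row, col, intensity,
                        atlas = default_font_atlas()) {
  stopifnot(is.matrix(image), length(text) == 1L)
  if (nchar(text) == 0L) {
    return(image)
  }
  chars <- strsplit(text, "")[[1]]
  missing <- setdiff(chars, names(atlas$glyphs))
  if (length(missing) > 0L) {
    rp_stop(
      "roipack_unsupported_character",
      "character(s) not in font atlas: %s",
      paste(sQuote(missing), collapse = ", ")
    )
  }
  n <- length(chars)
  r0 <- as.integer(row) + 1L # to 1-based
  c0 <- as.integer(col) + 1L
  r1 <- r0 + atlas$height - 1L
  cend <- c0 + (n - 1L) * atlas$advance + atlas$width - 1L
  if (r0 < 1L || c0 < 1L || r1 > nrow(image) || cend > ncol(image)) {
    rp_stop(
      "roipack_text_out_of_frame",
      "text run %s at (%d,%d) does not fit in a %dx%d frame",
      sQuote(text), row, col, nrow(image), ncol(image)
    )
  }
  for (i in seq_len(n)) {
    g <- atlas$glyphs[[chars[i]]]
    cc <- c0 + (i - 1L) * atlas$advance
    block <- image[r0:r1, cc:(cc + atlas$width - 1L), drop = FALSE]
    block[g] <- as.integer(intensity)
    image[r0:r1, cc:(cc + atlas$width - 1L)] <- block
  }
  image
}

# ink pixel coordinates (1-based matrix indices) a run would touch
run_ink_pixels <- function(text, row, col, atlas = default_font_atlas()) {
  chars <- strsplit(text, "")[[1]]
  out <- vector("list", length(chars))
  for (i in seq_along(chars)) {
    g <- atlas$glyphs[[chars[i]]]
    idx <- which(g, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      out[[i]] <- cbind(
        idx[, 1L] + row, # row/col are 0-based; result 1-based
        idx[, 2L] + col + (i - 1L) * atlas$advance
      )
    }
  }
  do.call(rbind, out)
}
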