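# R-facing surface of the LOCO-I plane codec. The sequential per-pixel coding
# loops live in src/jpegls.cpp; the standalone MED predictor and Golomb-Rice
# primitives are also exposed here for direct use and testing.

#' Median edge detector prediction
#'
#' The three-neighbor LOCO-I predictor: `min(a, b)` when `c >= max(a, b)`,
#' `max(a, b)` when `c <= min(a, b)`, otherwise the planar `a + b - c`.
#' Vectorized over its arguments.
#'
#' @param a Left neighbor sample.
#' @param b Above neighbor sample.
#' @param c Above-left neighbor sample.
#' @return Predicted sample value(s).
#' @examples
#' med_predict(100, 120, 90) # 120: c below both neighbors, predict max
#' @export
med_predict <- function(a, b, c) {
  mn <- pmin(a, b)
  mx <- pmax(a, b)
  ifelse(c >= mx, mn, ifelse(c <= mn, mx, a + b - c))
}

golomb_cap <- function(max_bits) {
  bpp <- max(8L, as.integer(max_bits))
  2L * (bpp + max(8L, bpp)) - as.integer(max_bits) - 1L
}

#' Limited-length Golomb-Rice coding of a mapped error
#'
#' Encodes a non-negative mapped error `m` with Rice parameter `k`: the
#' quotient `m %/% 2^k` in unary (ones terminated by a zero) followed by the
#' `k` low bits, escaping to a fixed `max_bits`-bit representation when the
#' quotient reaches the limited-length cap. `golomb_rice_decode()` inverts it
#' exactly.
#'
#' @param m Non-negative integer mapped error (`m < 2^max_bits`).
#' @param k Rice parameter (>= 0).
#' @param max_bits Sample precision that sets the escape cap (default 16).
#' @return Integer vector of bits (0/1).
#' @examples
#' golomb_rice_encode(9, 2) # 11001: quotient 2 in unary, remainder 01
#' @export
golomb_rice_encode <- function(m, k, max_bits = 16L) {
  m <- as.integer(m)
  k <- as.integer(k)
  stopifnot(m >= 0L, k >= 0L, m < 2^max_bits)
  cap <- golomb_cap(max_bits)
  q <- bitwShiftR(m, k)
  int_bits <- function(v, n) {
    if (n == 0L) return(integer(0))
    as.integer(bitwAnd(bitwShiftR(v, (n - 1L):0L), 1L))
  }
  if (q < cap) {
    c(rep(1L, q), 0L, int_bits(m, k))
  } else {
    c(rep(1L, cap), 0L, int_bits(m, as.integer(max_bits)))
  }
}

#' @param bits Integer vector of bits as produced by `golomb_rice_encode()`.
#' @return For the decoder, a list with `value` and `n_bits` consumed.
#' @rdname golomb_rice_encode
#' @export
golomb_rice_decode <- function(bits, k, max_bits = 16L) {
  k <- as.integer(k)
  cap <- golomb_cap(max_bits)
  q <- 0L
  p <- 1L
  repeat {
    if (p > length(bits)) {
      rp_stop("roipack_truncation_error", "bits exhausted in unary prefix")
    }
    if (bits[p] == 0L) break
    q <- q + 1L
    p <- p + 1L
    if (q > cap) {
      rp_stop("roipack_format_error", "unary run exceeds cap")
    }
  }
  p <- p + 1L # consume terminator
  nrem <- if (q < cap) k else as.integer(max_bits)
  if (p + nrem - 1L > length(bits)) {
    rp_stop("roipack_truncation_error", "bits exhausted in remainder")
  }
  rem <- 0L
  if (nrem > 0L) {
    rem <- sum(bits[p:(p + nrem - 1L)] * 2L^((nrem - 1L):0L))
  }
  value <- if (q < cap) bitwShiftL(q, k) + as.integer(rem) else as.integer(rem)
  list(value = value, n_bits = p + nrem - 1L)
}

#' Lossless LOCO-I plane codec
#'
#' `encode_plane()` compresses an integer matrix losslessly in raster order
#' with the LOCO-I regular mode: MED prediction, 365 quantized-gradient
#' contexts with bias correction, Rice error mapping, and per-context
#' Golomb-Rice coding. The returned stream is self-describing (13-byte
#' header: magic, rows, cols, bits) and `decode_plane()` reproduces the
#' matrix bit-exactly.
#'
#' @param crop Integer matrix; all values in `[0, 2^bits_stored - 1]`.
#' @param bits_stored Bits per sample, 8..16.
#' @param with_state Also return the final context state (`A`, `B`, `C`, `N`
#'   arrays) as an attribute, for diagnostics.
#' @return `encode_plane()`: raw vector. `decode_plane()`: integer matrix
#'   with attribute `bits_stored`.
#' @export
encode_plane <- function(crop, bits_stored = 16L, with_state = FALSE) {
  stopifnot(is.matrix(crop))
  storage.mode(crop) <- "integer"
  bits_stored <- as.integer(bits_stored)
  if (bits_stored < 8L || bits_stored > 16L) {
    rp_stop("roipack_format_error", "bits_stored must be in [8,16]")
  }
  if (length(crop) == 0L) {
    rp_stop("roipack_format_error", "empty plane")
  }
  if (min(crop) < 0L || max(crop) >= 2L^bits_stored) {
    rp_stop("roipack_range_error",
            "plane values out of range for %d bits", bits_stored)
  }
  res <- .jls_encode(crop, bits_stored, with_state)
  stream <- res$stream
  if (with_state) {
    attr(stream, "state") <- res[c("A", "B", "C", "N")]
  }
  stream
}

#' @param stream Raw vector produced by `encode_plane()`.
#' @rdname encode_plane
#' @export
decode_plane <- function(stream, with_state = FALSE) {
  stopifnot(is.raw(stream))
  res <- tryCatch(
    .jls_decode(stream, with_state),
    error = function(e) {
      msg <- conditionMessage(e)
      cls <- if (grepl("truncation", msg)) {
        "roipack_truncation_error"
      } else {
        "roipack_format_error"
      }
      rp_stop(cls, "%s", msg)
    }
  )
  out <- res$pixels
  attr(out, "bits_stored") <- res$bits
  if (with_state) {
    attr(out, "state") <- res[c("A", "B", "C", "N")]
  }
  out
}
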