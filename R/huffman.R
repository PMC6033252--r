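# Canonical Huffman codec for the OCR text payload. Code lengths come from
# the classical minimum-redundancy tree (deterministic tie-breaks); codes are
# the canonical ones derived from sorted lengths, so the serialized codebook
# only needs (symbol, length) pairs.

#' Build a canonical Huffman codebook from a byte payload
#'
#' Computes optimal prefix-code lengths for the payload's byte frequencies
#' (merging the two lowest-frequency nodes, ties broken by the lowest byte
#' value contained in each node) and canonicalizes them: codes are assigned
#' in (length, symbol) order. A single-symbol payload gets the one-bit code
#' `0`, the only departure from a Kraft-complete tree.
#'
#' @param payload Raw vector (or character scalar, taken as its bytes) of
#'   length >= 1.
#' @return A `huffman_codebook`: list with `symbols` (integer byte values,
#'   ascending), `lengths` (bits per symbol) and `symbol_count`.
#' @examples
#' book <- build_codebook(charToRaw("abracadabra"))
#' sum(build_codebook(charToRaw("abracadabra"))$lengths *
#'     as.vector(table(as.integer(charToRaw("abracadabra")))))
#' @export
build_codebook <- function(payload) {
  if (is.character(payload)) payload <- charToRaw(payload)
  stopifnot(is.raw(payload))
  if (length(payload) == 0L) {
    rp_stop("roipack_empty_payload", "cannot build a codebook from 0 bytes")
  }
  counts <- tabulate(as.integer(payload) + 1L, nbins = 256L)
  symbols <- which(counts > 0L) - 1L
  freqs <- counts[counts > 0L]
  lengths <- huffman_lengths(symbols, freqs)
  new_codebook(symbols, lengths)
}

# optimal code lengths; nodes keyed by (frequency, smallest contained symbol)
huffman_lengths <- function(symbols, freqs) {
  n <- length(symbols)
  if (n == 1L) {
    return(1L)
  }
  node_freq <- as.numeric(freqs)
  node_rank <- as.integer(symbols) # smallest byte value in the subtree
  node_leaves <- lapply(seq_len(n), identity)
  depths <- integer(n)
  active <- rep(TRUE, length(node_freq))
  while (sum(active) > 1L) {
    idx <- which(active)
    ord <- idx[order(node_freq[idx], node_rank[idx])]
    i1 <- ord[1L]
    i2 <- ord[2L]
    leaves <- c(node_leaves[[i1]], node_leaves[[i2]])
    depths[leaves] <- depths[leaves] + 1L
    node_freq <- c(node_freq, node_freq[i1] + node_freq[i2])
    node_rank <- c(node_rank, min(node_rank[i1], node_rank[i2]))
    node_leaves <- c(node_leaves, list(leaves))
    active[c(i1, i2)] <- FALSE
    active <- c(active, TRUE)
  }
  depths
}

new_codebook <- function(symbols, lengths) {
  ord <- order(symbols)
  symbols <- as.integer(symbols[ord])
  lengths <- as.integer(lengths[ord])
  if (length(symbols) >= 2L) {
    kraft <- sum(2^(-lengths))
    if (abs(kraft - 1) > 1e-12) {
      rp_stop("roipack_structure_error",
              "code lengths violate Kraft equality (sum = %g)", kraft)
    }
  }
  structure(
    list(symbols = symbols, lengths = lengths,
         symbol_count = length(symbols)),
    class = "huffman_codebook"
  )
}

#' @export
print.huffman_codebook <- function(x, ...) {
  cat(sprintf("<huffman_codebook> %d symbols, lengths %d..%d\n",
              x$symbol_count, min(x$lengths), max(x$lengths)))
  invisible(x)
}

# canonical code assignment: (length, symbol) order, numerically increasing
canonical_codes <- function(book) {
  ord <- order(book$lengths, book$symbols)
  lens <- book$lengths[ord]
  codes <- numeric(length(lens))
  code <- 0
  for (i in seq_along(lens)) {
    if (i > 1L) {
      code <- (code + 1) * 2^(lens[i] - lens[i - 1L])
    }
    codes[i] <- code
  }
  list(order = ord, codes = codes, lengths = lens,
       symbols = book$symbols[ord])
}

code_bit_list <- function(book) {
  cc <- canonical_codes(book)
  out <- vector("list", 256L)
  for (i in seq_along(cc$symbols)) {
    n <- cc$lengths[i]
    out[[cc$symbols[i] + 1L]] <-
      as.integer((cc$codes[i] %/% 2^((n - 1L):0L)) %% 2)
  }
  out
}

#' Huffman-encode a byte payload
#'
#' Concatenates the canonical codes of each payload byte, zero-padding the
#' final partial byte; the exact bit count is reported alongside.
#'
#' @param payload Raw vector (or character scalar); every byte must appear in
#'   the codebook.
#' @param book A [build_codebook()] result.
#' @return List with `bits` (raw vector, bits packed MSB-first) and
#'   `bit_count`.
#' @export
huffman_encode <- function(payload, book) {
  if (is.character(payload)) payload <- charToRaw(payload)
  stopifnot(is.raw(payload), inherits(book, "huffman_codebook"))
  if (length(payload) == 0L) {
    return(list(bits = raw(0L), bit_count = 0L))
  }
  lut <- code_bit_list(book)
  present <- !vapply(lut[as.integer(payload) + 1L], is.null, logical(1))
  if (!all(present)) {
    bad <- unique(as.integer(payload)[!present])
    rp_stop("roipack_coverage_error",
            "payload byte(s) not in codebook: %s",
            paste(bad, collapse = ", "))
  }
  bits <- unlist(lut[as.integer(payload) + 1L], use.names = FALSE)
  bit_count <- length(bits)
  npad <- (8L - bit_count %% 8L) %% 8L
  padded <- c(bits, rep(0L, npad))
  # pack MSB-first
  m <- matrix(padded, nrow = 8L)
  bytes <- as.raw(colSums(m * 2L^(7:0)))
  list(bits = bytes, bit_count = bit_count)
}

#' Huffman-decode a bitstream
#'
#' Walks the canonical code table bit by bit and reproduces the exact
#' original payload. Running out of bits mid-code raises an
#' `roipack_truncation_error`.
#'
#' @param bits Raw vector as produced by [huffman_encode()].
#' @param bit_count Number of meaningful bits in `bits`.
#' @param book The codebook used to encode.
#' @return Raw vector: the original payload.
#' @export
huffman_decode <- function(bits, bit_count, book) {
  stopifnot(is.raw(bits), inherits(book, "huffman_codebook"))
  bit_count <- as.integer(bit_count)
  if (bit_count > 8L * length(bits)) {
    rp_stop("roipack_truncation_error",
            "bit_count exceeds stream length")
  }
  if (bit_count == 0L) {
    return(raw(0L))
  }
  cc <- canonical_codes(book)
  maxlen <- max(cc$lengths)
  # per-length first code / first index / count
  first_code <- rep(NA_real_, maxlen)
  first_idx <- rep(NA_integer_, maxlen)
  n_at <- integer(maxlen)
  for (i in seq_along(cc$lengths)) {
    l <- cc$lengths[i]
    if (is.na(first_idx[l])) {
      first_idx[l] <- i
      first_code[l] <- cc$codes[i]
    }
    n_at[l] <- n_at[l] + 1L
  }
  bitvec <- as.integer(rawToBits(bits)) # LSB-first within each byte
  # reorder each byte's bits to MSB-first to match the writer
  idx <- as.vector(matrix(seq_along(bitvec), nrow = 8L)[8:1, , drop = FALSE])
  bitvec <- bitvec[idx][seq_len(bit_count)]
  out <- raw(0L)
  outlist <- list()
  code <- 0
  len <- 0L
  for (p in seq_len(bit_count)) {
    code <- code * 2 + bitvec[p]
    len <- len + 1L
    if (len <= maxlen && n_at[len] > 0L &&
        code >= first_code[len] && code < first_code[len] + n_at[len]) {
      sym <- cc$symbols[first_idx[len] + (code - first_code[len])]
      outlist[[length(outlist) + 1L]] <- sym
      code <- 0
      len <- 0L
    } else if (len > maxlen) {
      rp_stop("roipack_truncation_error", "invalid code in stream")
    }
  }
  if (len != 0L) {
    rp_stop("roipack_truncation_error", "bits exhausted mid-code")
  }
  as.raw(unlist(outlist))
}

#' Serialize / deserialize a Huffman codebook
#'
#' Canonical codes are reconstructible from lengths alone, so the wire form
#' is just `symbol_count` (one byte; 0 denotes the full 256-symbol alphabet)
#' followed by `(symbol, length)` byte pairs.
#'
#' @param book A `huffman_codebook`.
#' @return `serialize_codebook()`: raw vector of `1 + 2 * symbol_count`
#'   bytes; `deserialize_codebook()`: the reconstructed codebook.
#' @export
serialize_codebook <- function(book) {
  stopifnot(inherits(book, "huffman_codebook"))
  n <- book$symbol_count
  c(as.raw(n %% 256L),
    as.raw(as.vector(rbind(book$symbols, book$lengths))))
}

#' @param bytes Raw vector produced by `serialize_codebook()`.
#' @rdname serialize_codebook
#' @export
deserialize_codebook <- function(bytes) {
  stopifnot(is.raw(bytes))
  if (length(bytes) < 3L) {
    rp_stop("roipack_structure_error", "codebook blob too short")
  }
  n <- as.integer(bytes[1L])
  if (n == 0L) n <- 256L
  if (length(bytes) != 1L + 2L * n) {
    rp_stop("roipack_structure_error",
            "codebook blob length %d does not match %d symbols",
            length(bytes), n)
  }
  pairs <- matrix(as.integer(bytes[-1L]), nrow = 2L)
  symbols <- pairs[1L, ]
  lengths <- pairs[2L, ]
  if (anyDuplicated(symbols) > 0L || any(lengths < 1L)) {
    rp_stop("roipack_structure_error", "invalid codebook entries")
  }
  if (n == 1L && lengths != 1L) {
    rp_stop("roipack_structure_error", "single-symbol book must have length 1")
  }
  new_codebook(symbols, lengths)
}
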