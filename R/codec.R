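#' Quantize wavelet coefficients to the packed-block bitwidths
#'
#' Casts floating-point coefficients (computed from a window expressed in
#' 0.01 uS units) to the integer fields of the block format: values are
#' truncated toward zero, mirroring a C integer cast of a Q15.16 fixed-point
#' value to Q15.0 on a 16-bit MCU. Approximation (A4) coefficients are
#' unsigned 12-bit and clamped to \[0, 4095\]; detail coefficients are signed
#' 8-bit and clamped to \[-128, 127\]. Any clamping is recorded.
#'
#' @param w a [wavelet_coeffs()] object in 0.01 uS units.
#' @return An object of class `quantized_coeffs`: list with `values`
#'   (integer vector of length 145), `saturated` (logical vector marking
#'   clamped positions), and `any_saturated`.
#' @export
quantize_coeffs <- function(w) {
  flat <- if (inherits(w, "wavelet_coeffs")) w4_flat(w) else as.numeric(w)
  if (length(flat) != W4_LENGTH)
    stop("expected 145 coefficients", call. = FALSE)
  if (any(!is.finite(flat)))
    stop("non-finite coefficient cannot be quantized", call. = FALSE)
  v <- trunc(flat)
  a_idx <- 1:12
  sat <- logical(W4_LENGTH)
  sat[a_idx] <- v[a_idx] < 0 | v[a_idx] > 4095
  v[a_idx] <- pmin(pmax(v[a_idx], 0), 4095)
  d_idx <- 13:W4_LENGTH
  sat[d_idx] <- v[d_idx] < -128 | v[d_idx] > 127
  v[d_idx] <- pmin(pmax(v[d_idx], -128), 127)
  structure(list(values = as.integer(v), saturated = sat,
                 any_saturated = any(sat)),
            class = "quantized_coeffs")
}

#' @export
print.quantized_coeffs <- function(x, ...) {
  cat(sprintf("<quantized_coeffs> 145 ints, %d nonzero, %s\n",
              sum(x$values != 0L),
              if (x$any_saturated) "saturation occurred" else "no saturation"))
  invisible(x)
}

#' Select the K largest-magnitude coefficients
#'
#' Returns the 1-based positions of the `k` largest `abs(values)`, ordered
#' by non-increasing magnitude with ties broken in favour of the lowest
#' index (the behaviour of a strict greater-than scan). For `k >= 12` the
#' twelve A4 positions are unconditionally retained first (in positional
#' order) and only detail positions compete for the remaining slots, so the
#' packed-block layout is always well formed; for `k < 12` the `k`
#' largest-magnitude A4 values are kept and all details are dropped.
#'
#' @param q a [quantize_coeffs()] result (or numeric/integer 145-vector).
#' @param k number of coefficients to retain, 1..145.
#' @return Integer vector of `k` distinct positions in 1..145.
#' @export
select_top_k <- function(q, k) {
  v <- if (inherits(q, "quantized_coeffs")) q$values else as.numeric(q)
  if (length(v) != W4_LENGTH)
    stop("expected 145 coefficients", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > W4_LENGTH)
    stop("'k' must be between 1 and 145", call. = FALSE)
  if (k < 12L) {
    a <- 1:12
    ord <- a[order(-abs(v[a]), a)]
    return(ord[seq_len(k)])
  }
  d <- 13:W4_LENGTH
  ord <- d[order(-abs(v[d]), d)]
  c(1:12, ord[seq_len(k - 12L)])
}

#' Payload size of a packed block
#'
#' Number of payload bits used to encode `k` retained coefficients:
#' 16 bits per retained A4 word (value plus address nibble); for `k >= 12`,
#' twelve A4 words carrying the first six detail addresses in their nibbles,
#' plus 16-bit words packing two signed 8-bit detail values each, plus one
#' 16-bit word (value + 8-bit address) per detail beyond the sixth. Always a
#' multiple of 16 — the natural word size of the target architecture.
#'
#' @param k retained coefficient count, 1..145.
#' @return Integer bit count; e.g. `bits_for_k(18)` is 240 (30 bytes).
#' @export
bits_for_k <- function(k) {
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 1L) || any(k > W4_LENGTH))
    stop("'k' must be between 1 and 145", call. = FALSE)
  ifelse(k < 12L,
         16L * k,
         192L + 16L * as.integer(ceiling(pmin(k - 12L, 6L) / 2)) +
           16L * pmax(0L, k - 18L))
}

#' Compression ratio achieved at a given K
#'
#' Raw window size (128 samples x 32 bits) over [bits_for_k()].
#'
#' @param k retained coefficient count.
#' @return Numeric ratio, e.g. `cr_for_k(18)` is 17.07.
#' @export
cr_for_k <- function(k) {
  (WINDOW_LENGTH * 32) / bits_for_k(k)
}

# two's-complement helpers for signed 8-bit payload fields
as_u8 <- function(v) as.integer(v %% 256L)
from_u8 <- function(u) ifelse(u > 127L, u - 256L, u)

word_to_bytes <- function(words) {
  # little-endian 16-bit words -> raw
  as.raw(as.vector(rbind(words %% 256L, words %/% 256L)))
}

bytes_to_words <- function(payload) {
  b <- as.integer(payload)
  b[seq(1L, length(b), 2L)] + 256L * b[seq(2L, length(b), 2L)]
}

#' Encode retained coefficients into a packed block
#'
#' Produces the bit-exact block layout used on the wire and in storage.
#' With `k >= 12`: twelve 16-bit A-words whose bits 15..4 hold the unsigned
#' 12-bit A4 values in positional order and whose low nibbles carry the
#' 8-bit absolute addresses (0-based flat index, 12..144) of the first
#' `min(k - 12, 6)` details, split low nibble into word `2j` and high nibble
#' into word `2j + 1`; unused nibbles are zero (a sentinel — real detail
#' addresses are >= 12). Then the first six detail values packed two signed
#' bytes per word (even-position value in the low byte), then one word per
#' detail beyond the sixth with the value in the high byte and the address
#' in the low byte. With `k < 12`: `k` A-words whose low nibbles hold the
#' retained A4 position (0..11), so the decoder can zero-fill dropped slots.
#'
#' @param q a [quantize_coeffs()] result.
#' @param lsi index list from [select_top_k()] (1-based positions).
#' @return An object of class `compressed_block`: list with `k`,
#'   `payload` (raw vector) and `bit_count`.
#' @export
encode_block <- function(q, lsi) {
  v <- if (inherits(q, "quantized_coeffs")) q$values else as.integer(q)
  lsi <- as.integer(lsi)
  k <- length(lsi)
  if (k < 1L || k > W4_LENGTH || anyDuplicated(lsi) ||
      any(lsi < 1L) || any(lsi > W4_LENGTH))
    stop("invalid index list", call. = FALSE)
  if (k >= 12L) {
    if (!all(1:12 %in% lsi[1:12]))
      stop("for k >= 12 the first 12 indices must cover the A4 slice",
           call. = FALSE)
    a_vals <- v[1:12]
    if (any(a_vals < 0L | a_vals > 4095L))
      stop("A4 value outside unsigned 12-bit range", call. = FALSE)
    d_pos <- lsi[-(1:12)]
    d_vals <- v[d_pos]
    if (any(d_vals < -128L | d_vals > 127L))
      stop("detail value outside signed 8-bit range", call. = FALSE)
    addr <- d_pos - 1L   # absolute 0-based flat addresses, 12..144
    a_words <- bitwShiftL(a_vals, 4L)
    nd <- length(d_pos)
    nd6 <- min(nd, 6L)
    for (j in seq_len(nd6)) {
      a_words[2L * j - 1L] <- bitwOr(a_words[2L * j - 1L],
                                     bitwAnd(addr[j], 15L))
      a_words[2L * j] <- bitwOr(a_words[2L * j],
                                bitwAnd(bitwShiftR(addr[j], 4L), 15L))
    }
    d_words <- integer(0)
    if (nd6 > 0L) {
      u <- as_u8(d_vals[seq_len(nd6)])
      if (nd6 %% 2L == 1L) u <- c(u, 0L)
      d_words <- u[seq(1L, length(u), 2L)] +
        256L * u[seq(2L, length(u), 2L)]
    }
    x_words <- integer(0)
    if (nd > 6L) {
      xi <- seq(7L, nd)
      x_words <- 256L * as_u8(d_vals[xi]) + addr[xi]
    }
    words <- c(a_words, d_words, x_words)
  } else {
    if (any(lsi > 12L))
      stop("for k < 12 only A4 positions may be retained", call. = FALSE)
    pos <- sort(lsi)
    a_vals <- v[pos]
    if (any(a_vals < 0L | a_vals > 4095L))
      stop("A4 value outside unsigned 12-bit range", call. = FALSE)
    words <- bitwOr(bitwShiftL(a_vals, 4L), pos - 1L)
  }
  bits <- bits_for_k(k)
  stopifnot(length(words) * 16L == bits)
  structure(list(k = k, payload = word_to_bytes(words), bit_count = bits),
            class = "compressed_block")
}

#' @export
print.compressed_block <- function(x, ...) {
  cat(sprintf("<compressed_block> k = %d, %d bits (%d bytes), CR = %.2f\n",
              x$k, x$bit_count, x$bit_count / 8L, cr_for_k(x$k)))
  invisible(x)
}

corrupt_block <- function(msg) {
  stop(errorCondition(paste0("corrupt block: ", msg),
                      class = c("edacodec_corrupt_block", "error")))
}

#' Decode a packed block into a sparse coefficient vector
#'
#' Exact inverse of [encode_block()]: positions not present in the block
#' decode to zero. Structural violations (truncated payload, a detail
#' address below 12, duplicate addresses, a nonzero sentinel nibble) raise
#' a condition of class `edacodec_corrupt_block`.
#'
#' @param b a `compressed_block`.
#' @return A `quantized_coeffs` object whose `values` are zero except at the
#'   retained positions.
#' @export
decode_block <- function(b) {
  if (!inherits(b, "compressed_block"))
    stop("'b' must be a compressed_block", call. = FALSE)
  k <- as.integer(b$k)
  if (k < 1L || k > W4_LENGTH) corrupt_block("k out of range")
  bits <- bits_for_k(k)
  if (length(b$payload) != bits / 8L)
    corrupt_block(sprintf("payload has %d bytes, expected %d for k = %d",
                          length(b$payload), bits / 8L, k))
  words <- bytes_to_words(b$payload)
  v <- integer(W4_LENGTH)
  if (k >= 12L) {
    a_words <- words[1:12]
    v[1:12] <- bitwShiftR(a_words, 4L)
    nd <- k - 12L
    nd6 <- min(nd, 6L)
    nibbles <- bitwAnd(a_words, 15L)
    addr <- nibbles[seq(1L, 11L, 2L)] + 16L * nibbles[seq(2L, 12L, 2L)]
    if (nd6 < 6L && any(addr[seq(nd6 + 1L, 6L)] != 0L))
      corrupt_block("nonzero address nibble in unused slot")
    addr <- addr[seq_len(nd6)]
    if (any(addr < 12L)) corrupt_block("detail address below 12")
    pos <- integer(0)
    vals <- integer(0)
    if (nd6 > 0L) {
      nw <- ceiling(nd6 / 2)
      dw <- words[12L + seq_len(nw)]
      u <- as.vector(rbind(dw %% 256L, dw %/% 256L))[seq_len(nd6)]
      pos <- addr + 1L
      vals <- from_u8(u)
    }
    if (nd > 6L) {
      xw <- words[(12L + ceiling(nd6 / 2) + 1L):length(words)]
      xaddr <- bitwAnd(xw, 255L)
      if (any(xaddr < 12L)) corrupt_block("detail address below 12")
      pos <- c(pos, xaddr + 1L)
      vals <- c(vals, from_u8(bitwShiftR(xw, 8L)))
    }
    if (anyDuplicated(pos)) corrupt_block("duplicate detail address")
    v[pos] <- vals
  } else {
    pos0 <- bitwAnd(words, 15L)
    if (any(pos0 > 11L)) corrupt_block("A4 address above 11")
    if (anyDuplicated(pos0)) corrupt_block("duplicate A4 address")
    v[pos0 + 1L] <- bitwShiftR(words, 4L)
  }
  structure(list(values = v, saturated = logical(W4_LENGTH),
                 any_saturated = FALSE),
            class = "quantized_coeffs")
}

#' Compress / decompress one 64-second window
#'
#' `compress_window()` runs the full encoding pipeline: scale the window
#' from uS to 0.01 uS units, apply the four-level wavelet transform,
#' quantize to the block bitwidths, select the K largest-magnitude
#' coefficients and pack them. `decompress_window()` inverts it: decode the
#' sparse coefficient vector, zero-fill, apply the inverse transform and
#' rescale to uS. Both are deterministic.
#'
#' @param x an [eda_window()] (uS).
#' @param k number of coefficients to retain (default 18: a 30-byte block,
#'   compression ratio 17.1).
#' @param fb a [db3_filterbank()].
#' @return `compress_window()`: a `compressed_block`. `decompress_window()`:
#'   a numeric vector of 128 reconstructed samples in uS.
#' @examples
#' w <- eda_window(rep(2, 128))
#' b <- compress_window(w, k = 18)
#' xhat <- decompress_window(b)
#' max(abs(xhat - as.numeric(w)))  # within the 0.01 uS resolution
#' @export
compress_window <- function(x, k = 18L, fb = db3_filterbank()) {
  x <- as_eda_window(x)
  w <- ml_dwt(as.numeric(x) * 100, fb)
  q <- quantize_coeffs(w)
  lsi <- select_top_k(q, k)
  b <- encode_block(q, lsi)
  b$t0 <- attr(x, "t0")
  b
}

#' @rdname compress_window
#' @param b a `compressed_block` from [compress_window()].
#' @export
decompress_window <- function(b, fb = db3_filterbank()) {
  q <- decode_block(b)
  inverse_ml_dwt(w4_from_flat(as.numeric(q$values)), fb) / 100
}
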