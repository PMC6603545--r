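#' Daubechies-3 analysis/synthesis filter bank
#'
#' Returns the orthonormal 6-tap Daubechies filters with three vanishing
#' moments, normalised so that each filter has unit L2 norm (hence the
#' scaling filter sums to sqrt(2) and the wavelet filter sums to 0).
#'
#' `h0`/`h1` are the analysis (decomposition) low-/high-pass filters; the
#' synthesis filters used by [inverse_ml_dwt()] are their time reverses, as
#' for any orthogonal wavelet.
#'
#' @return An object of class `filterbank`: a list with numeric components
#'   `h0` and `h1`, each of length 6.
#' @examples
#' fb <- db3_filterbank()
#' sum(fb$h0^2)  # 1
#' sum(fb$h0)    # sqrt(2)
#' @export
db3_filterbank <- function() {
  h0 <- c(0.03522629188570953, -0.08544127388202666, -0.13501102001025458,
          0.45987750211849154, 0.80689150931109250, 0.33267055295008263)
  h1 <- c(-0.33267055295008263, 0.80689150931109250, -0.45987750211849154,
          -0.13501102001025458, 0.08544127388202666, 0.03522629188570953)
  structure(list(h0 = h0, h1 = h1), class = "filterbank")
}

validate_filterbank <- function(fb) {
  if (!is.list(fb) || is.null(fb$h0) || is.null(fb$h1))
    stop("'fb' must be a filterbank with components h0 and h1", call. = FALSE)
  if (length(fb$h0) != 6L || length(fb$h1) != 6L)
    stop("db3 filters must have 6 taps", call. = FALSE)
  invisible(fb)
}

# Fixed decomposition geometry for 128-sample windows:
# approximation lengths 128 -> 66 -> 35 -> 20 -> 12,
# flat layout [A4 | D4 | D3 | D2 | D1] of total length 145.
W4_LEVEL_LENGTHS <- c(A4 = 12L, D4 = 12L, D3 = 20L, D2 = 35L, D1 = 66L)
W4_LENGTH <- 145L
WINDOW_LENGTH <- 128L
EDA_FS <- 2

#' Construct a 64-second EDA window
#'
#' Wraps 128 skin-conductance samples (microsiemens, sampled at 2 Hz) as an
#' `eda_window`, validating length, finiteness and non-negativity
#' (conductance cannot be negative).
#'
#' @param samples numeric vector of exactly 128 conductance values (uS).
#' @param fs sampling rate in Hz; only 2 Hz is supported.
#' @param t0 optional window start time in seconds.
#' @return A numeric vector of class `eda_window` with attributes `fs`, `t0`.
#' @examples
#' w <- eda_window(rep(2, 128))
#' @export
eda_window <- function(samples, fs = EDA_FS, t0 = NA_real_) {
  samples <- as.numeric(samples)
  if (length(samples) != WINDOW_LENGTH)
    stop("an EDA window must contain exactly 128 samples (64 s at 2 Hz), got ",
         length(samples), call. = FALSE)
  if (any(!is.finite(samples)))
    stop("EDA window contains non-finite samples", call. = FALSE)
  if (any(samples < 0))
    stop("conductance values must be non-negative", call. = FALSE)
  if (!isTRUE(all.equal(fs, EDA_FS)))
    stop("only fs = 2 Hz is supported", call. = FALSE)
  structure(samples, fs = fs, t0 = t0, class = "eda_window")
}

#' @export
print.eda_window <- function(x, ...) {
  cat(sprintf("<eda_window> 128 samples @ %g Hz, range [%.3f, %.3f] uS\n",
              attr(x, "fs"), min(x), max(x)))
  invisible(x)
}

as_eda_window <- function(x) {
  if (inherits(x, "eda_window")) x else eda_window(x)
}

#' Whole-sample symmetric padding
#'
#' Mirrors `width` samples of a vector onto each end without repeating the
#' edge sample's neighbours out of order:
#' `[x3,x2,x1,x0 | x0..x(N-1) | x(N-1),x(N-2),...]` for `width = 4`.
#' This boundary extension suppresses the large edge coefficients that
#' plain (unpadded) convolution produces, which would otherwise dominate
#' the top-K selection and distort reconstructions near window borders.
#'
#' @param a numeric vector, length at least `width`.
#' @param width number of mirrored samples per side.
#' @return Numeric vector of length `length(a) + 2 * width`.
#' @examples
#' pad_symmetric(c(1, 2, 3, 4))  # 4 3 2 1 1 2 3 4 4 3 2 1
#' @export
pad_symmetric <- function(a, width = 4L) {
  a <- as.numeric(a)
  n <- length(a)
  width <- as.integer(width)
  if (width < 0L) stop("'width' must be non-negative", call. = FALSE)
  if (n < width)
    stop("input of length ", n, " is shorter than pad width ", width,
         call. = FALSE)
  if (width == 0L) return(a)
  c(a[width:1], a, a[n:(n - width + 1L)])
}

#' One analysis step of the discrete wavelet transform
#'
#' Applies whole-sample symmetric extension followed by the stride-2
#' correlation with the db3 analysis filters. For an input of length N the
#' output length is `floor((N + 5) / 2)`, the convention that reproduces
#' the fixed level lengths (66, 35, 20, 12) of the 128-sample window
#' decomposition and admits an exact inverse.
#'
#' @param a numeric vector, length at least 6.
#' @param fb a [db3_filterbank()].
#' @return A list with numeric components `approx` and `detail`, equal length.
#' @export
dwt_step <- function(a, fb = db3_filterbank()) {
  validate_filterbank(fb)
  a <- as.numeric(a)
  n <- length(a)
  if (n < 6L)
    stop("dwt_step requires at least 6 samples, got ", n, call. = FALSE)
  ext <- pad_symmetric(a, 5L)
  # stride-2 convolution with the analysis filters, even output phase
  m <- length(ext) - 5L
  idx <- seq(2L, m, by = 2L)
  g0 <- rev(fb$h0)
  g1 <- rev(fb$h1)
  approx <- vapply(idx, function(i) sum(g0 * ext[i:(i + 5L)]), numeric(1))
  detail <- vapply(idx, function(i) sum(g1 * ext[i:(i + 5L)]), numeric(1))
  list(approx = approx, detail = detail)
}

#' Assemble a multilevel coefficient object
#'
#' @param A4,D4,D3,D2,D1 numeric level vectors of lengths 12, 12, 20, 35, 66.
#' @return An object of class `wavelet_coeffs`.
#' @seealso [ml_dwt()], [w4_flat()], [w4_from_flat()]
#' @export
wavelet_coeffs <- function(A4, D4, D3, D2, D1) {
  w <- list(A4 = as.numeric(A4), D4 = as.numeric(D4), D3 = as.numeric(D3),
            D2 = as.numeric(D2), D1 = as.numeric(D1))
  lens <- vapply(w, length, integer(1))
  if (!identical(unname(lens), unname(as.integer(W4_LEVEL_LENGTHS))))
    stop("level lengths must be (12, 12, 20, 35, 66); got (",
         paste(lens, collapse = ", "), ")", call. = FALSE)
  structure(w, class = "wavelet_coeffs")
}

#' @export
print.wavelet_coeffs <- function(x, ...) {
  e <- energy_fractions(x)
  cat("<wavelet_coeffs> 145 coefficients [A4:12 D4:12 D3:20 D2:35 D1:66]\n")
  cat(sprintf("  %%energy A4 %.3f | D4 %.3g | D3 %.3g | D2 %.3g | D1 %.3g\n",
              e["A4"], e["D4"], e["D3"], e["D2"], e["D1"]))
  invisible(x)
}

#' Flatten / reassemble the 145-coefficient vector
#'
#' The flat layout is `[A4 | D4 | D3 | D2 | D1]`, i.e. (1-based R indices)
#' A4 = 1:12, D4 = 13:24, D3 = 25:44, D2 = 45:79, D1 = 80:145.
#'
#' @param w a `wavelet_coeffs` object.
#' @return `w4_flat()`: numeric vector of length 145.
#' @export
w4_flat <- function(w) {
  stopifnot(inherits(w, "wavelet_coeffs"))
  c(w$A4, w$D4, w$D3, w$D2, w$D1)
}

#' @rdname w4_flat
#' @param flat numeric vector of length 145.
#' @export
w4_from_flat <- function(flat) {
  flat <- as.numeric(flat)
  if (length(flat) != W4_LENGTH)
    stop("flat coefficient vector must have length 145, got ", length(flat),
         call. = FALSE)
  ends <- cumsum(W4_LEVEL_LENGTHS)
  starts <- c(1L, head(ends, -1L) + 1L)
  wavelet_coeffs(flat[starts[1]:ends[1]], flat[starts[2]:ends[2]],
                 flat[starts[3]:ends[3]], flat[starts[4]:ends[4]],
                 flat[starts[5]:ends[5]])
}

#' Slice indices of the flat coefficient vector
#'
#' @return Named list of 1-based index ranges into the flat 145-vector.
#' @export
w4_slices <- function() {
  ends <- cumsum(W4_LEVEL_LENGTHS)
  starts <- c(1L, head(ends, -1L) + 1L)
  stats::setNames(Map(seq.int, starts, ends), names(W4_LEVEL_LENGTHS))
}

#' Four-level wavelet decomposition of one EDA window
#'
#' Recursively applies [dwt_step()] four times to a 128-sample window,
#' producing approximation lengths 66, 35, 20, 12 and retaining the detail
#' vector at each level. The result holds 145 coefficients in total and is
#' exactly invertible by [inverse_ml_dwt()].
#'
#' @param x an [eda_window()] or numeric vector of 128 samples. Units are
#'   preserved: pass samples in 0.01 uS units when the result will be
#'   quantized for encoding (see [compress_window()]).
#' @param fb a [db3_filterbank()].
#' @return A [wavelet_coeffs()] object.
#' @examples
#' w <- ml_dwt(eda_window(rep(1.5, 128)))
#' length(w4_flat(w))  # 145
#' @export
ml_dwt <- function(x, fb = db3_filterbank()) {
  if (inherits(x, "eda_window")) {
    a <- as.numeric(x)
  } else {
    a <- as.numeric(x)
    if (length(a) != WINDOW_LENGTH)
      stop("ml_dwt expects a 128-sample window", call. = FALSE)
    if (any(!is.finite(a))) stop("non-finite samples", call. = FALSE)
  }
  details <- vector("list", 4L)
  for (lev in 1:4) {
    s <- dwt_step(a, fb)
    a <- s$approx
    details[[lev]] <- s$detail
  }
  wavelet_coeffs(A4 = a, D4 = details[[4]], D3 = details[[3]],
                 D2 = details[[2]], D1 = details[[1]])
}

# One synthesis step: upsample, convolve with the synthesis filters
# (time-reversed analysis filters), trim the 4 boundary samples each side,
# then cut to the known parent length.
idwt_step <- function(approx, detail, out_len, fb = db3_filterbank()) {
  if (length(approx) != length(detail))
    stop("approx and detail must have equal length", call. = FALSE)
  g0 <- rev(fb$h0)
  g1 <- rev(fb$h1)
  up <- function(v) {
    u <- numeric(2L * length(v))
    u[seq(1L, length(u), by = 2L)] <- v
    u
  }
  full_conv <- function(u, f) {
    n <- length(u)
    y <- numeric(n + 5L)
    for (k in 1:6) y[k:(k + n - 1L)] <- y[k:(k + n - 1L)] + f[k] * u
    y
  }
  y <- full_conv(up(approx), g0) + full_conv(up(detail), g1)
  y <- y[5:(length(y) - 4L)]
  if (out_len > length(y))
    stop("requested output length exceeds synthesis support", call. = FALSE)
  y[seq_len(out_len)]
}

#' Inverse four-level wavelet transform
#'
#' Reconstructs the 128-sample window from a coefficient object. When the
#' coefficients are unaltered this is an exact inverse of [ml_dwt()] (round
#' trip error at floating-point level); with coefficients zeroed by
#' compression it returns the corresponding low-distortion approximation.
#'
#' @param w a [wavelet_coeffs()] object (level lengths are validated).
#' @param fb a [db3_filterbank()].
#' @return Numeric vector of 128 samples, in the units of the coefficients.
#' @export
inverse_ml_dwt <- function(w, fb = db3_filterbank()) {
  if (!inherits(w, "wavelet_coeffs")) {
    if (is.numeric(w) && length(w) == W4_LENGTH) w <- w4_from_flat(w)
    else stop("'w' must be a wavelet_coeffs object or a flat 145-vector",
              call. = FALSE)
  }
  a <- idwt_step(w$A4, w$D4, 20L, fb)
  a <- idwt_step(a, w$D3, 35L, fb)
  a <- idwt_step(a, w$D2, 66L, fb)
  idwt_step(a, w$D1, WINDOW_LENGTH, fb)
}
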