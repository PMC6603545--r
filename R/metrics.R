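#' Compression ratio
#'
#' Ratio of bits needed for the raw signal to bits in the compressed
#' payload. A raw 64-second window at 2 Hz is stored as 128 samples of
#' 32-bit fixed point (Q15.16), i.e. 4096 bits (an input data rate of
#' 64 bits/s).
#'
#' @param raw_bits bits of the uncompressed representation.
#' @param payload_bits bits of the compressed payload; must be positive.
#' @return Numeric ratio.
#' @examples
#' compression_ratio(4096, 240)  # 17.07, prints as 17.1x
#' @export
compression_ratio <- function(raw_bits, payload_bits) {
  if (any(payload_bits <= 0))
    stop("'payload_bits' must be positive", call. = FALSE)
  raw_bits / payload_bits
}

#' Percent root-mean-square difference
#'
#' `100 * sqrt(sum((x - xhat)^2) / sum(x^2))`. The denominator is the raw
#' signal energy, not mean-subtracted.
#'
#' @param x reference signal.
#' @param xhat reconstructed signal, same length.
#' @return Percent distortion (>= 0).
#' @export
prd <- function(x, xhat) {
  x <- as.numeric(x); xhat <- as.numeric(xhat)
  if (length(x) != length(xhat))
    stop("signals must have equal length", call. = FALSE)
  den <- sum(x^2)
  if (den == 0)
    stop("PRD is undefined for an all-zero reference signal", call. = FALSE)
  100 * sqrt(sum((x - xhat)^2) / den)
}

#' Root-mean-square reconstruction error
#'
#' `sqrt(mean((x - xhat)^2))`, in the units of the input (uS for EDA).
#'
#' @inheritParams prd
#' @return RMS error (>= 0).
#' @export
rms_err <- function(x, xhat) {
  x <- as.numeric(x); xhat <- as.numeric(xhat)
  if (length(x) != length(xhat))
    stop("signals must have equal length", call. = FALSE)
  sqrt(mean((x - xhat)^2))
}

#' Per-level energy fractions of the wavelet decomposition
#'
#' Share of the total squared-coefficient energy contained in each of the
#' five coefficient vectors, in percent. The shares sum to 100.
#'
#' @param w a [wavelet_coeffs()] object or flat 145-vector.
#' @return Named numeric vector (`A4`, `D4`, `D3`, `D2`, `D1`), percents.
#' @export
energy_fractions <- function(w) {
  if (!inherits(w, "wavelet_coeffs")) w <- w4_from_flat(w)
  e <- vapply(w[c("A4", "D4", "D3", "D2", "D1")],
              function(v) sum(v^2), numeric(1))
  tot <- sum(e)
  if (tot == 0)
    stop("energy fractions are undefined for all-zero coefficients",
         call. = FALSE)
  100 * e / tot
}

#' Population relative error of a feature
#'
#' Signed relative error of the population total of a feature extracted
#' from reconstructions against the total from the originals:
#' `(sum(recon) - sum(orig)) / sum(orig)`.
#'
#' @param orig per-window feature values from the original signals.
#' @param recon per-window feature values from the reconstructions.
#' @return Signed ratio (e.g. -0.25 means the reconstruction total is 25%
#'   low).
#' @export
feature_relative_error <- function(orig, recon) {
  so <- sum(as.numeric(orig))
  if (so == 0)
    stop("relative error is undefined when the original total is zero",
         call. = FALSE)
  (sum(as.numeric(recon)) - so) / so
}

#' Recording duration achievable in a fixed memory budget
#'
#' How long EDA can be recorded into `storage_bytes` of on-chip memory at a
#' given compression ratio. Two modes:
#'
#' * first principles (default): the raw data rate is 64 bits/s (32-bit
#'   samples at 2 Hz), so duration (hours) is
#'   `storage_bytes * 8 / (64 / cr) / 3600`;
#' * base-duration: `base_hours * cr`, for reproducing duration tables
#'   quoted against a device whose uncompressed capacity is stated as
#'   `base_hours` (the two modes differ when that stated capacity does not
#'   equal the 64 bits/s arithmetic).
#'
#' @param cr compression ratio (>= 1, or the stated table value).
#' @param storage_bytes available storage, default 48 kB.
#' @param base_hours if given, use the base-duration mode.
#' @return Duration in hours.
#' @export
storage_duration <- function(cr, storage_bytes = 48 * 1024, base_hours = NULL) {
  if (any(cr <= 0)) stop("'cr' must be positive", call. = FALSE)
  if (!is.null(base_hours)) {
    if (base_hours <= 0) stop("'base_hours' must be positive", call. = FALSE)
    return(base_hours * cr)
  }
  if (storage_bytes <= 0) stop("'storage_bytes' must be positive", call. = FALSE)
  storage_bytes * 8 / (64 / cr) / 3600
}

#' Bits required to store a coefficient magnitude
#'
#' Field-sizing helper: `log2` of the maximum magnitude a field must hold,
#' and the number of integer bits that implies (plus one sign bit if the
#' field is signed).
#'
#' @param max_abs maximum absolute value to represent (> 0).
#' @param signed does the field need a sign bit?
#' @return List with `log2` (the raw bit measure) and `bits` (integer field
#'   width).
#' @examples
#' coeff_bitwidth(2399.53)$log2  # 11.2285 -> a 12-bit unsigned field
#' @export
coeff_bitwidth <- function(max_abs, signed = FALSE) {
  if (max_abs <= 0) stop("'max_abs' must be positive", call. = FALSE)
  l2 <- log2(max_abs)
  list(log2 = l2, bits = as.integer(ceiling(l2)) + as.integer(signed))
}

#' Distortion report for one window at one K
#'
#' Compresses a window at the requested `k`, reconstructs it and collects
#' the distortion metrics and feature errors in one row.
#'
#' @param x an [eda_window()] (uS).
#' @param k retained coefficient count.
#' @param min_amplitude SCR detection threshold passed to [detect_scrs()].
#' @return A one-row data.frame: `k`, `cr`, `prd`, `rms_err`, tonic
#'   absolute errors (`err_scl`, `err_std`, `err_min`, `err_max`, uS) and
#'   phasic sums for original and reconstruction.
#' @export
distortion_report <- function(x, k, min_amplitude = 0.01) {
  x <- as_eda_window(x)
  b <- compress_window(x, k)
  xhat <- decompress_window(b)
  fo <- extract_features(x, min_amplitude = min_amplitude)
  xr <- pmax(as.numeric(xhat), 0)
  fr <- extract_features(eda_window(xr), min_amplitude = min_amplitude)
  data.frame(
    k = k,
    cr = cr_for_k(k),
    prd = prd(x, xhat),
    rms_err = rms_err(x, xhat),
    err_scl = abs(fr$scl - fo$scl),
    err_std = abs(fr$sc_std - fo$sc_std),
    err_min = abs(fr$sc_min - fo$sc_min),
    err_max = abs(fr$sc_max - fo$sc_max),
    sum_amp_orig = fo$sum_amp, sum_amp_recon = fr$sum_amp,
    sum_dur_orig = fo$sum_dur, sum_dur_recon = fr$sum_dur,
    sum_auc_orig = fo$sum_auc, sum_auc_recon = fr$sum_auc
  )
}

#' Write an evaluation report
#'
#' Serialises a distortion table (as produced by [eda_evaluate_file()] or
#' rbind-ed [distortion_report()] rows) to CSV, and optionally a population
#' summary to JSON.
#'
#' @param report data.frame of per-window rows.
#' @param csv_path output CSV path.
#' @param json_path optional path for a JSON summary (per-`k` means and
#'   population feature relative errors).
#' @return Invisibly, the summary data.frame.
#' @export
write_report <- function(report, csv_path, json_path = NULL) {
  utils::write.csv(report, csv_path, row.names = FALSE)
  summ <- summarize_report(report)
  if (!is.null(json_path))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(summ)
}

summarize_report <- function(report) {
  re_or_na <- function(orig, recon) {
    if (sum(orig) == 0) NA_real_ else feature_relative_error(orig, recon)
  }
  do.call(rbind, lapply(split(report, report$k), function(d) {
    data.frame(
      k = d$k[1],
      cr = d$cr[1],
      mean_prd = mean(d$prd),
      mean_rms_err = mean(d$rms_err),
      mean_err_scl = mean(d$err_scl),
      mean_err_std = mean(d$err_std),
      mean_err_min = mean(d$err_min),
      mean_err_max = mean(d$err_max),
      re_sum_amp = re_or_na(d$sum_amp_orig, d$sum_amp_recon),
      re_sum_dur = re_or_na(d$sum_dur_orig, d$sum_dur_recon),
      re_sum_auc = re_or_na(d$sum_auc_orig, d$sum_auc_recon)
    )
  }))
}
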