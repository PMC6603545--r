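#' Tonic EDA features of a window
#'
#' The slowly varying descriptors of a 64-second window: the skin
#' conductance level (SCL, the window mean), minimum, maximum, and the
#' population standard deviation of the samples.
#'
#' @param x an [eda_window()] or numeric vector.
#' @return Named list: `scl`, `sc_min`, `sc_max`, `sc_std` (all uS).
#' @export
tonic_features <- function(x) {
  v <- as.numeric(x)
  m <- mean(v)
  list(scl = m, sc_min = min(v), sc_max = max(v),
       sc_std = sqrt(mean((v - m)^2)))
}

# Interior and boundary extrema of a sampled signal, from runs of the
# slope sign. A plateau does not spawn extrema of its own: a trough sits at
# the start of a rising run whose last non-flat predecessor was falling (or
# absent, as at the window start), a peak symmetrically. Window boundaries
# count as extrema so events that begin at or run off the edge are kept.
local_extrema <- function(v) {
  n <- length(v)
  if (n < 2L) return(list(minima = integer(0), maxima = integer(0)))
  r <- rle(sign(diff(v)))
  starts <- cumsum(c(1L, head(r$lengths, -1L)))
  minima <- integer(0)
  maxima <- integer(0)
  prev <- 0L
  for (j in seq_along(r$values)) {
    val <- r$values[j]
    if (val == 0) next
    if (val > 0 && prev <= 0L) minima <- c(minima, starts[j])
    if (val < 0 && prev >= 0L) maxima <- c(maxima, starts[j])
    prev <- val
  }
  if (prev > 0L) maxima <- c(maxima, n)
  if (prev < 0L) minima <- c(minima, n)
  list(minima = minima, maxima = maxima)
}

#' Detect skin conductance responses (SCRs)
#'
#' Trough-to-peak detector for the phasic events in an EDA window. An event
#' onsets at a local minimum and peaks at the following local maximum;
#' its amplitude is the trough-to-peak rise. The event duration runs from
#' the onset until the signal first falls back to half the peak amplitude
#' (peak value minus amplitude / 2), truncated at the window end, and the
#' area under the curve is the triangular estimate
#' `0.5 * amplitude * duration`. A new event may begin only after the
#' previous event's peak; compound (overlapping) responses are not
#' deconvolved. Events smaller than `min_amplitude` are discarded, so
#' raising the threshold can only remove events.
#'
#' @param x an [eda_window()] or numeric vector (uS).
#' @param min_amplitude smallest trough-to-peak rise to accept, in uS.
#'   Defaults to 0.01 uS, the acquisition resolution.
#' @param fs sampling rate (Hz).
#' @return A data.frame of class `scr_events` with columns `onset_idx`,
#'   `peak_idx` (1-based sample indices), `amplitude` (uS), `duration` (s),
#'   `auc` (uS s). Zero rows when no event qualifies.
#' @export
detect_scrs <- function(x, min_amplitude = 0.01, fs = EDA_FS) {
  v <- as.numeric(x)
  n <- length(v)
  ex <- local_extrema(v)
  onset <- integer(0); peak <- integer(0)
  amp <- numeric(0); dur <- numeric(0)
  pos <- 1L
  for (tr in ex$minima) {
    if (tr < pos) next
    pk_candidates <- ex$maxima[ex$maxima > tr]
    if (length(pk_candidates) == 0L) break
    pk <- pk_candidates[1L]
    a <- v[pk] - v[tr]
    if (a > 0) {
      half <- v[pk] - a / 2
      after <- if (pk < n) which(v[(pk + 1L):n] <= half) else integer(0)
      t_end <- if (length(after)) pk + after[1L] else n
      onset <- c(onset, tr); peak <- c(peak, pk)
      amp <- c(amp, a); dur <- c(dur, (t_end - tr) / fs)
    }
    pos <- pk + 1L
  }
  keep <- amp >= min_amplitude
  ev <- data.frame(onset_idx = onset[keep], peak_idx = peak[keep],
                   amplitude = amp[keep], duration = dur[keep])
  ev$auc <- 0.5 * ev$amplitude * ev$duration
  class(ev) <- c("scr_events", "data.frame")
  ev
}

#' Sum the phasic features over detected events
#'
#' @param events an `scr_events` data.frame from [detect_scrs()].
#' @return Named list `sum_amp` (uS), `sum_dur` (s), `sum_auc` (uS s);
#'   zeros for an empty event list.
#' @export
phasic_sums <- function(events) {
  if (NROW(events) == 0L)
    return(list(sum_amp = 0, sum_dur = 0, sum_auc = 0))
  list(sum_amp = sum(events$amplitude),
       sum_dur = sum(events$duration),
       sum_auc = sum(events$auc))
}

#' Full feature set of one window
#'
#' Combines [tonic_features()] with the phasic sums over [detect_scrs()]
#' output.
#'
#' @inheritParams detect_scrs
#' @return A one-row data.frame: `scl`, `sc_min`, `sc_max`, `sc_std`,
#'   `sum_amp`, `sum_dur`, `sum_auc`, `n_scrs`.
#' @export
extract_features <- function(x, min_amplitude = 0.01, fs = EDA_FS) {
  tf <- tonic_features(x)
  ev <- detect_scrs(x, min_amplitude = min_amplitude, fs = fs)
  ps <- phasic_sums(ev)
  data.frame(scl = tf$scl, sc_min = tf$sc_min, sc_max = tf$sc_max,
             sc_std = tf$sc_std, sum_amp = ps$sum_amp, sum_dur = ps$sum_dur,
             sum_auc = ps$sum_auc, n_scrs = NROW(ev))
}

#' Write per-window features to CSV
#'
#' @param windows list of [eda_window()] objects.
#' @param path output CSV path.
#' @inheritParams detect_scrs
#' @return Invisibly, the feature data.frame (one row per window).
#' @export
write_features_csv <- function(windows, path, min_amplitude = 0.01) {
  rows <- do.call(rbind, lapply(windows, extract_features,
                                min_amplitude = min_amplitude))
  rows <- cbind(window = seq_along(windows), rows)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
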