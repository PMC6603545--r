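#' Configuration for the synthetic EDA session generator
#'
#' The generator emulates an in-lab wrist EDA recording at 2 Hz: a slowly
#' drifting tonic baseline (bounded random walk inside the validated sensor
#' range 0.25-6.67 uS), Poisson-arrival phasic SCR pulses shaped as a
#' difference of exponentials (fast rise, slow decay) with lognormal
#' amplitudes, and small additive measurement noise. The composite signal
#' is clipped to the sensor-plausible range 0-10 uS.
#'
#' Defaults describe a mildly aroused laboratory subject: a 2 uS starting
#' level, ~2 SCRs per minute, median pulse amplitude ~0.2 uS (lognormal,
#' sd 0.4 on the log scale, i.e. bulk of amplitudes 0.1-0.45 uS), a 1 s
#' rise and 4 s decay time constant, and 0.005 uS white noise — comparable
#' to the 0.01-0.02 uS resolution of wrist-worn acquisition hardware.
#'
#' @param duration session length in seconds (default 640 s = ten windows).
#' @param fs sampling rate, Hz (fixed at 2).
#' @param baseline_start tonic level at t = 0, uS.
#' @param baseline_drift_sd per-sample standard deviation of the tonic
#'   random walk, uS.
#' @param scr_rate mean SCR arrival rate, events per minute.
#' @param amp_log_mean,amp_log_sd lognormal amplitude parameters (log-uS).
#' @param rise_tau,decay_tau pulse rise and decay time constants, s.
#' @param noise_sd additive white noise standard deviation, uS.
#' @param seed optional integer seed; a fixed seed makes the session
#'   fully reproducible.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration = 640, fs = EDA_FS, baseline_start = 2,
                         baseline_drift_sd = 0.01, scr_rate = 2,
                         amp_log_mean = log(0.2), amp_log_sd = 0.4,
                         rise_tau = 1, decay_tau = 4, noise_sd = 0.005,
                         seed = NULL) {
  cfg <- list(duration = duration, fs = fs, baseline_start = baseline_start,
              baseline_drift_sd = baseline_drift_sd, scr_rate = scr_rate,
              amp_log_mean = amp_log_mean, amp_log_sd = amp_log_sd,
              rise_tau = rise_tau, decay_tau = decay_tau,
              noise_sd = noise_sd, seed = seed)
  with(cfg, {
    if (duration <= 0 || fs != EDA_FS) stop("invalid duration/fs", call. = FALSE)
    if (baseline_start < 0 || baseline_drift_sd < 0 || scr_rate < 0 ||
        amp_log_sd < 0 || rise_tau <= 0 || decay_tau <= 0 || noise_sd < 0)
      stop("rates and scales must be non-negative (taus positive)",
           call. = FALSE)
    if (decay_tau <= rise_tau)
      stop("'decay_tau' must exceed 'rise_tau'", call. = FALSE)
  })
  structure(cfg, class = "synth_config")
}

# biexponential pulse kernel normalised to unit peak
scr_pulse <- function(t, rise_tau, decay_tau) {
  p <- exp(-t / decay_tau) - exp(-t / rise_tau)
  t_peak <- log(decay_tau / rise_tau) * rise_tau * decay_tau /
    (decay_tau - rise_tau)
  peak <- exp(-t_peak / decay_tau) - exp(-t_peak / rise_tau)
  ifelse(t < 0, 0, p / peak)
}

# random walk reflected into [lo, hi]
bounded_walk <- function(n, start, sd, lo = 0.25, hi = 6.67) {
  steps <- stats::rnorm(n - 1L, 0, sd)
  b <- numeric(n)
  b[1] <- min(max(start, lo), hi)
  for (i in 2:n) {
    x <- b[i - 1L] + steps[i - 1L]
    if (x < lo) x <- lo + (lo - x)
    if (x > hi) x <- hi - (x - hi)
    b[i] <- min(max(x, lo), hi)
  }
  b
}

#' Generate a synthetic EDA session with ground truth
#'
#' Draws one session from a [synth_config()]: tonic bounded random walk,
#' Poisson SCR arrivals with biexponential pulses, additive white noise,
#' clipped to 0-10 uS. Identical seeds give identical output.
#'
#' @param cfg a [synth_config()].
#' @return List with `time_s`, `samples` (uS), `events` (data.frame of true
#'   pulse `time_s` and `amplitude`), and the `config` used.
#' @examples
#' s <- generate_session(synth_config(duration = 128, seed = 1))
#' length(s$samples)  # 256
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- round(cfg$duration * cfg$fs)
  t <- (seq_len(n) - 1L) / cfg$fs
  tonic <- if (cfg$baseline_drift_sd > 0 && n > 1L)
    bounded_walk(n, cfg$baseline_start, cfg$baseline_drift_sd)
  else rep(min(max(cfg$baseline_start, 0), 6.67), n)
  n_ev <- if (cfg$scr_rate > 0)
    stats::rpois(1L, cfg$scr_rate * cfg$duration / 60) else 0L
  events <- data.frame(time_s = numeric(0), amplitude = numeric(0))
  phasic <- numeric(n)
  if (n_ev > 0L) {
    ev_t <- sort(stats::runif(n_ev, 0, cfg$duration))
    ev_a <- stats::rlnorm(n_ev, cfg$amp_log_mean, cfg$amp_log_sd)
    for (j in seq_len(n_ev))
      phasic <- phasic + ev_a[j] * scr_pulse(t - ev_t[j],
                                             cfg$rise_tau, cfg$decay_tau)
    events <- data.frame(time_s = ev_t, amplitude = ev_a)
  }
  noise <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else numeric(n)
  samples <- pmin(pmax(tonic + phasic + noise, 0), 10)
  list(time_s = t, samples = samples, events = events, config = cfg)
}

#' Acquisition low-pass filter
#'
#' Minimum-order Chebyshev type-II low-pass used to condition raw sessions
#' before windowing and compression: 0.6 Hz passband edge with at most 3 dB
#' attenuation and 0.9 Hz stopband edge with at least 74 dB attenuation, at
#' a 2 Hz sampling rate. The order is computed from the closed-form
#' Chebyshev order bound on the bilinear-prewarped edge frequencies, and
#' the filter is applied causally (forward only), as an on-line acquisition
#' chain would. DC gain is unity.
#'
#' @param samples numeric signal (uS).
#' @param fs sampling rate; must be 2 Hz.
#' @param fpass,fstop passband / stopband edges, Hz.
#' @param rp,rs passband / stopband attenuation specs, dB.
#' @return Filtered signal, same length.
#' @export
preprocess_filter <- function(samples, fs = EDA_FS, fpass = 0.6, fstop = 0.9,
                              rp = 3, rs = 74) {
  if (!isTRUE(all.equal(fs, EDA_FS)))
    stop("the acquisition filter is specified for fs = 2 Hz", call. = FALSE)
  wp <- fpass / (fs / 2)
  ws <- fstop / (fs / 2)
  if (wp <= 0 || ws >= 1 || wp >= ws)
    stop("infeasible filter specification", call. = FALSE)
  ord <- cheb2_min_order(wp, ws, rp, rs)
  flt <- signal::cheby2(ord, Rp = rs, W = ws, type = "low")
  as.numeric(signal::filter(flt, samples))
}

# minimum Chebyshev order for prewarped digital edges
cheb2_min_order <- function(wp, ws, rp, rs) {
  wpa <- tan(pi * wp / 2)
  wsa <- tan(pi * ws / 2)
  as.integer(ceiling(acosh(sqrt((10^(rs / 10) - 1) / (10^(rp / 10) - 1))) /
                       acosh(wsa / wpa)))
}

#' Split a session into 64-second windows
#'
#' Non-overlapping 128-sample windows; a trailing remainder shorter than
#' one window is dropped (with a warning if nothing remains).
#'
#' @param samples numeric signal (uS), 2 Hz.
#' @param t0 time of the first sample, seconds.
#' @return List of [eda_window()] objects (possibly empty).
#' @export
window_session <- function(samples, t0 = 0) {
  samples <- as.numeric(samples)
  nw <- length(samples) %/% WINDOW_LENGTH
  if (nw == 0L) {
    warning("session shorter than one 64-s window; no windows produced")
    return(list())
  }
  lapply(seq_len(nw), function(i) {
    idx <- ((i - 1L) * WINDOW_LENGTH + 1L):(i * WINDOW_LENGTH)
    eda_window(samples[idx], t0 = t0 + (i - 1L) * WINDOW_LENGTH / EDA_FS)
  })
}

#' Read / write EDA session CSV files
#'
#' The on-disk dialect is a UTF-8 CSV with header
#' `time_s,conductance_uS` and '.' as the decimal mark. On read, sampling
#' uniformity at 2 Hz is validated to within 1 ms.
#'
#' @param path file path.
#' @return `read_eda_csv()`: list with `time_s` and `samples`.
#' @export
read_eda_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "conductance_uS") %in% names(d)))
    stop("CSV must have columns 'time_s' and 'conductance_uS'", call. = FALSE)
  if (nrow(d) == 0L) stop("empty EDA CSV", call. = FALSE)
  if (nrow(d) > 1L) {
    dt <- diff(d$time_s)
    if (any(abs(dt - 1 / EDA_FS) > 1e-3))
      stop("samples are not uniform at 2 Hz (0.5 s spacing, 1 ms tolerance)",
           call. = FALSE)
  }
  list(time_s = d$time_s, samples = d$conductance_uS)
}

#' @rdname read_eda_csv
#' @param time_s,samples session vectors of equal length.
#' @export
write_session_csv <- function(time_s, samples, path) {
  stopifnot(length(time_s) == length(samples))
  utils::write.csv(data.frame(time_s = time_s, conductance_uS = samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write ground-truth events as JSON
#'
#' @param events data.frame with `time_s` and `amplitude`.
#' @param path output path.
#' @export
write_events_json <- function(events, path) {
  jsonlite::write_json(events, path, dataframe = "columns", digits = NA)
  invisible(path)
}
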