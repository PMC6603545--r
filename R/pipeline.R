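#' Resolve a target compression ratio to a retained-coefficient count
#'
#' Returns the largest `k` whose compression ratio still meets or exceeds
#' the target — i.e. the highest-fidelity setting that satisfies the
#' requested storage budget.
#'
#' @param target_cr requested compression ratio (> 1).
#' @return Integer `k` in 1..145.
#' @export
resolve_k <- function(target_cr) {
  if (target_cr <= 0) stop("'target_cr' must be positive", call. = FALSE)
  ks <- which(cr_for_k(1:145) >= target_cr)
  if (length(ks) == 0L)
    stop("no k achieves a compression ratio of ", target_cr, call. = FALSE)
  max(ks)
}

#' Compress an EDA session file
#'
#' Reads a 2 Hz session CSV, splits it into 64-second windows, compresses
#' each at the requested `k` (or `target_cr`), and writes the block
#' container. Per-window compression ratio, PRD and RMS error are returned
#' (and logged at `verbose = TRUE`).
#'
#' @param csv_in input session CSV (`time_s,conductance_uS`).
#' @param container_out output container path.
#' @param k retained coefficient count; exactly one of `k` / `target_cr`.
#' @param target_cr alternative to `k`: see [resolve_k()].
#' @param verbose print a per-window summary line.
#' @return Invisibly, a data.frame with one row per window (`window`, `t0`,
#'   `k`, `cr`, `prd`, `rms_err`).
#' @export
eda_compress_file <- function(csv_in, container_out, k = NULL,
                              target_cr = NULL, verbose = FALSE) {
  if (is.null(k) == is.null(target_cr))
    stop("give exactly one of 'k' or 'target_cr'", call. = FALSE)
  if (is.null(k)) k <- resolve_k(target_cr)
  s <- read_eda_csv(csv_in)
  windows <- window_session(s$samples, t0 = s$time_s[1])
  if (length(windows) == 0L)
    stop("input shorter than one 64-s window; nothing to compress",
         call. = FALSE)
  blocks <- lapply(windows, compress_window, k = k)
  write_block_container(blocks, container_out)
  rows <- do.call(rbind, lapply(seq_along(windows), function(i) {
    xhat <- decompress_window(blocks[[i]])
    data.frame(window = i, t0 = attr(windows[[i]], "t0"), k = k,
               cr = cr_for_k(k), prd = prd(windows[[i]], xhat),
               rms_err = rms_err(windows[[i]], xhat))
  }))
  if (verbose)
    for (i in seq_len(nrow(rows)))
      message(sprintf("window %3d  CR %.2f  PRD %6.3f%%  RMSErr %.4f uS",
                      rows$window[i], rows$cr[i], rows$prd[i],
                      rows$rms_err[i]))
  invisible(rows)
}

#' Decompress a block container to a session CSV
#'
#' @param container_in input container path.
#' @param csv_out output CSV path.
#' @return Invisibly, the reconstructed sample vector (uS).
#' @export
eda_decompress_file <- function(container_in, csv_out) {
  blocks <- read_block_container(container_in)
  if (length(blocks) == 0L) stop("container holds no blocks", call. = FALSE)
  recon <- lapply(blocks, decompress_window)
  samples <- unlist(recon)
  t0 <- blocks[[1]]$t0
  time_s <- t0 + (seq_along(samples) - 1L) / EDA_FS
  write_session_csv(time_s, samples, csv_out)
  invisible(samples)
}

#' Sweep K and tabulate distortion and feature errors
#'
#' For each `k` in `k_list`, compresses every window of the input session,
#' reconstructs it, and collects sample-level distortion together with
#' tonic absolute errors and phasic population relative errors. This is
#' the evaluation a codec user runs to choose an operating point.
#'
#' @param csv_in input session CSV.
#' @param k_list integer vector of retained-coefficient counts.
#' @param csv_out optional path for the per-window table.
#' @param json_out optional path for the per-`k` population summary.
#' @param min_amplitude SCR detection threshold (uS).
#' @return List with `windows` (per-window data.frame) and `summary`
#'   (per-`k` data.frame; see [write_report()]).
#' @export
eda_evaluate_file <- function(csv_in, k_list = c(11, 14, 18, 21, 32, 64),
                              csv_out = NULL, json_out = NULL,
                              min_amplitude = 0.01) {
  s <- read_eda_csv(csv_in)
  windows <- window_session(s$samples, t0 = s$time_s[1])
  if (length(windows) == 0L)
    stop("input shorter than one 64-s window", call. = FALSE)
  rows <- do.call(rbind, lapply(sort(as.integer(k_list)), function(k) {
    d <- do.call(rbind, lapply(windows, distortion_report, k = k,
                               min_amplitude = min_amplitude))
    cbind(window = seq_along(windows), d)
  }))
  summ <- summarize_report(rows)
  if (!is.null(csv_out)) utils::write.csv(rows, csv_out, row.names = FALSE)
  if (!is.null(json_out))
    jsonlite::write_json(summ, json_out, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  list(windows = rows, summary = summ)
}

#' Simulate a session to disk
#'
#' Wraps [generate_session()] and writes the session CSV, the ground-truth
#' event JSON, and (optionally) the low-pass-filtered session used as
#' compression input.
#'
#' @param cfg a [synth_config()].
#' @param csv_out session CSV path.
#' @param events_out optional ground-truth events JSON path.
#' @param filtered must the acquisition low-pass ([preprocess_filter()]) be
#'   applied before writing?
#' @return Invisibly, the [generate_session()] result.
#' @export
eda_simulate_file <- function(cfg, csv_out, events_out = NULL,
                              filtered = TRUE) {
  s <- generate_session(cfg)
  samples <- if (filtered) pmax(preprocess_filter(s$samples), 0) else s$samples
  write_session_csv(s$time_s, samples, csv_out)
  if (!is.null(events_out)) write_events_json(s$events, events_out)
  s$written_samples <- samples
  invisible(s)
}

#' Extract features from a session file
#'
#' @param csv_in input session CSV.
#' @param csv_out output feature CSV (one row per 64-s window).
#' @param min_amplitude SCR detection threshold (uS).
#' @return Invisibly, the feature data.frame.
#' @export
eda_features_file <- function(csv_in, csv_out, min_amplitude = 0.01) {
  s <- read_eda_csv(csv_in)
  windows <- window_session(s$samples, t0 = s$time_s[1])
  if (length(windows) == 0L)
    stop("input shorter than one 64-s window", call. = FALSE)
  write_features_csv(windows, csv_out, min_amplitude = min_amplitude)
}
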