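# Independent brute-force oracles and small fixture builders used across
# the test files. These deliberately avoid the package's internal code
# paths: explicit index arithmetic and double loops only.

# whole-sample mirror built directly from index arithmetic
oracle_pad <- function(x, width) {
  n <- length(x)
  out <- numeric(n + 2 * width)
  for (i in seq_along(out)) {
    j <- i - width            # position relative to x, 1-based; <=0 is left pad
    if (j < 1) j <- 1 - j     # mirror: 0 -> 1, -1 -> 2, ...
    if (j > n) j <- 2 * n + 1 - j
    out[i] <- x[j]
  }
  out
}

# analysis step by explicit extension, full convolution and downsampling
oracle_dwt <- function(x, h) {
  n <- length(x)
  ext <- oracle_pad(x, 5)
  z <- numeric(length(ext) + 5)
  for (m in seq_along(z)) {
    acc <- 0
    for (j in 0:5) {
      i <- m - j
      if (i >= 1 && i <= length(ext)) acc <- acc + h[j + 1] * ext[i]
    }
    z[m] <- acc
  }
  # valid region starts where the filter fully overlaps the extension;
  # keep the even output phase
  z[seq(7, by = 2, length.out = (n + 5) %/% 2)]
}

# top-k positions by a full sort with lowest-index tie-break
oracle_top_k <- function(v, k) {
  ord <- order(-abs(v), seq_along(v))
  sort(ord[seq_len(k)])
}

# a smooth deterministic test window (no randomness)
fixture_window <- function(level = 2) {
  n <- 0:127
  eda_window(level + sin(2 * pi * n / 128) + 0.3 * sin(2 * pi * 7 * n / 128))
}

# a small population of synthetic windows under a fixed seed
fixture_population <- function(n_windows = 20, seed = 7101) {
  sessions <- ceiling(n_windows / 10)
  wins <- list()
  for (i in seq_len(sessions)) {
    s <- generate_session(synth_config(duration = 640, seed = seed + i))
    wins <- c(wins, window_session(s$samples))
  }
  wins[seq_len(n_windows)]
}
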