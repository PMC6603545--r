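#' Read and write compressed-block container files
#'
#' The container is a little-endian binary stream: a 4-byte magic `"EDW1"`,
#' then one record per window: `uint32` window start time (whole seconds),
#' `uint8` retained-coefficient count K, followed by the packed payload
#' whose length is fully determined by K ([bits_for_k()] / 8 bytes). K
#' lives in the record header, not the payload, so compression-ratio
#' accounting counts payload bits only.
#'
#' @param blocks list of `compressed_block` objects (each may carry a `t0`).
#' @param path file path.
#' @return `write_block_container()`: invisibly, `path`.
#'   `read_block_container()`: list of `compressed_block` objects with `t0`.
#' @export
write_block_container <- function(blocks, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("EDW1"), con)
  for (b in blocks) {
    stopifnot(inherits(b, "compressed_block"))
    t0 <- b$t0
    if (is.null(t0) || is.na(t0)) t0 <- 0
    writeBin(as.integer(round(t0)), con, size = 4L, endian = "little")
    writeBin(as.raw(b$k), con)
    writeBin(b$payload, con)
  }
  invisible(path)
}

#' @rdname write_block_container
#' @export
read_block_container <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 4L || !identical(rawToChar(raw_all[1:4]), "EDW1"))
    stop("not an EDW1 block container", call. = FALSE)
  pos <- 5L
  blocks <- list()
  n <- length(raw_all)
  while (pos <= n) {
    if (pos + 4L > n) corrupt_block("truncated record header")
    t0 <- readBin(raw_all[pos:(pos + 3L)], "integer", size = 4L,
                  endian = "little")
    k <- as.integer(raw_all[pos + 4L])
    nbytes <- bits_for_k(k) / 8L
    if (pos + 4L + nbytes > n) corrupt_block("truncated payload")
    payload <- raw_all[(pos + 5L):(pos + 4L + nbytes)]
    blocks[[length(blocks) + 1L]] <-
      structure(list(k = k, payload = payload,
                     bit_count = bits_for_k(k), t0 = as.numeric(t0)),
                class = "compressed_block")
    pos <- pos + 5L + nbytes
  }
  blocks
}
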