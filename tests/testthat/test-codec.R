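test_that("quantization truncates toward zero and clamps to field ranges", {
  flat <- numeric(145)
  flat[13] <- 123.881          # largest detail seen in practice fits 8 bits
  flat[14] <- -0.9             # truncation toward zero, not floor
  flat[15] <- -130.2           # below the signed 8-bit floor
  flat[1] <- 4500.7            # above the unsigned 12-bit ceiling
  flat[2] <- 1234.56
  q <- quantize_coeffs(w4_from_flat(flat))
  expect_identical(q$values[13], 123L)
  expect_identical(q$values[14], 0L)
  expect_identical(q$values[15], -128L)
  expect_identical(q$values[1], 4095L)
  expect_identical(q$values[2], 1234L)
  expect_true(q$saturated[1])
  expect_true(q$saturated[15])
  expect_false(q$saturated[2])
  expect_true(q$any_saturated)
  flat[3] <- NaN
  expect_error(quantize_coeffs(w4_from_flat(flat)), "non-finite")
})

test_that("top-K selection matches a full-sort oracle on the detail slice", {
  set.seed(51)
  for (i in 1:25) {
    v <- sample(-128:127, 145, replace = TRUE)
    v[1:12] <- sample(0:4095, 12)
    for (k in c(12, 13, 18, 40, 145)) {
      sel <- select_top_k(v, k)
      expect_equal(sort(sel[1:12]), 1:12)
      if (k > 12) {
        details <- v[13:145]
        expect_setequal(sel[13:k] - 12L, oracle_top_k(details, k - 12))
      }
    }
  }
})

test_that("selection order and ties follow the strict-greater scan", {
  v <- integer(145)
  v[1:12] <- 100L
  v[31] <- 50L; v[41] <- -50L   # equal magnitude, lower index must win
  sel <- select_top_k(v, 13)
  expect_identical(sel[13], 31L)
  sel14 <- select_top_k(v, 14)
  expect_identical(sel14[13:14], c(31L, 41L))
  expect_setequal(select_top_k(v, 145), 1:145)
  expect_error(select_top_k(v, 0), "between")
  expect_error(select_top_k(v, 146), "between")
})

test_that("selection below 12 keeps the largest A4 entries only", {
  v <- integer(145)
  v[1:12] <- c(5L, 900L, 20L, 300L, 1L, 0L, 7L, 8L, 9L, 10L, 11L, 12L)
  v[50] <- 127L                 # details never compete below k = 12
  sel <- select_top_k(v, 3)
  expect_identical(sel, c(2L, 4L, 3L))
})

test_that("payload size formula reproduces the published block geometry", {
  expect_identical(bits_for_k(18L), 240L)   # the 30-byte block
  expect_identical(bits_for_k(12L), 192L)   # A-words only
  expect_identical(bits_for_k(11L), 176L)
  expect_identical(bits_for_k(13L), 208L)
  # monotone non-decreasing over the whole range
  expect_true(all(diff(bits_for_k(1:145)) >= 0))
  # the six published operating points, to one decimal
  expect_equal(round(cr_for_k(c(64, 32, 21, 18, 14, 11)), 1),
               c(4.2, 8.8, 14.2, 17.1, 19.7, 23.3))
  expect_error(bits_for_k(0), "between")
})

test_that("encoding matches a hand-computed golden byte layout", {
  v <- integer(145)
  v[1:12] <- 1:12
  v[101] <- 7L                 # absolute 0-based address 100 = 0x64
  q <- structure(list(values = v, saturated = logical(145),
                      any_saturated = FALSE), class = "quantized_coeffs")
  b <- encode_block(q, c(1:12, 101L))
  golden <- as.raw(c(0x14, 0x00, 0x26, 0x00, 0x30, 0x00, 0x40, 0x00,
                     0x50, 0x00, 0x60, 0x00, 0x70, 0x00, 0x80, 0x00,
                     0x90, 0x00, 0xA0, 0x00, 0xB0, 0x00, 0xC0, 0x00,
                     0x07, 0x00))
  expect_identical(b$payload, golden)
  expect_identical(b$bit_count, 208L)
  d <- decode_block(b)
  expect_identical(d$values, v)
})

test_that("encode/decode round trip is lossless over randomized blocks", {
  set.seed(61)
  for (i in 1:300) {
    v <- integer(145)
    v[1:12] <- sample(0:4095, 12)
    nd <- sample(0:40, 1)
    pos <- sample(13:145, nd)
    v[pos] <- sample(-128:127, nd, replace = TRUE)
    k <- sample(1:145, 1)
    q <- quantize_coeffs(w4_from_flat(as.numeric(v)))
    lsi <- select_top_k(q, k)
    b <- encode_block(q, lsi)
    expect_identical(b$bit_count, bits_for_k(k))
    d <- decode_block(b)
    expect_identical(d$values[lsi], v[lsi])
    expect_true(all(d$values[setdiff(1:145, lsi)] == 0L))
    expect_lte(sum(d$values != 0L), k)
  }
})

test_that("blocks with k below 12 drop the smallest A4 entries", {
  v <- integer(145)
  v[1:12] <- c(10L, 500L, 30L, 400L, 50L, 60L, 70L, 80L, 90L, 100L,
               110L, 120L)
  q <- quantize_coeffs(w4_from_flat(as.numeric(v)))
  b <- encode_block(q, select_top_k(q, 11))
  expect_identical(b$bit_count, 176L)
  d <- decode_block(b)
  expect_identical(d$values[1], 0L)           # the smallest A4 was dropped
  expect_identical(d$values[2:12], v[2:12])
  expect_true(all(d$values[13:145] == 0L))
})

test_that("structural corruption is rejected on decode", {
  v <- integer(145); v[1:12] <- 100L; v[20] <- 50L; v[30] <- -40L
  q <- quantize_coeffs(w4_from_flat(as.numeric(v)))
  b <- encode_block(q, select_top_k(q, 14))
  short <- b; short$payload <- b$payload[-length(b$payload)]
  expect_error(decode_block(short), class = "edacodec_corrupt_block")
  # address below 12 in the first detail slot
  bad <- b
  bad$payload[1] <- as.raw(bitwAnd(as.integer(bad$payload[1]), 0xF0))
  bad$payload[3] <- as.raw(bitwAnd(as.integer(bad$payload[3]), 0xF0))
  expect_error(decode_block(bad), class = "edacodec_corrupt_block")
  # nonzero sentinel nibble in an unused slot
  bad2 <- b
  bad2$payload[23] <- as.raw(bitwOr(as.integer(bad2$payload[23]), 0x01))
  expect_error(decode_block(bad2), class = "edacodec_corrupt_block")
})

test_that("all-zero-nibble block with k = 12 decodes to A4 only", {
  v <- integer(145); v[1:12] <- (1:12) * 100L
  q <- quantize_coeffs(w4_from_flat(as.numeric(v)))
  b <- encode_block(q, select_top_k(q, 12))
  expect_true(all(bitwAnd(as.integer(b$payload[seq(1, 23, 2)]), 15L) == 0L))
  d <- decode_block(b)
  expect_identical(d$values, v)
})

test_that("window compression respects the quantization resolution bound", {
  w <- eda_window(rep(2, 128))
  xhat <- decompress_window(compress_window(w, 12))
  expect_lt(max(abs(xhat - 2)), 0.01)

  # full retention of a smooth (non-saturating) window: the only loss is
  # the 0.01 uS coefficient resolution
  x <- fixture_window(2)
  expect_false(quantize_coeffs(ml_dwt(as.numeric(x) * 100))$any_saturated)
  xh <- decompress_window(compress_window(x, 145))
  # a unit quantization error per coefficient cannot grow through the
  # orthonormal synthesis by more than sqrt(145) in 0.01 uS units
  expect_lt(max(abs(xh - as.numeric(x))), 0.01 * sqrt(145))
  expect_lt(rms_err(x, xh), 0.01)
})

test_that("reconstruction error is non-increasing as more coefficients are kept", {
  wins <- fixture_population(10, seed = 81)
  ks <- c(11, 12, 14, 18, 21, 32, 64, 100, 145)
  for (w in wins) {
    errs <- vapply(ks, function(k)
      rms_err(w, decompress_window(compress_window(w, k))), numeric(1))
    expect_true(all(diff(errs) <= 1e-6),
                info = paste("errs:", paste(signif(errs, 3), collapse = " ")))
  }
})
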