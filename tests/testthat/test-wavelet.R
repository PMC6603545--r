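test_that("db3 filter bank satisfies the orthonormal wavelet identities", {
  fb <- db3_filterbank()
  expect_length(fb$h0, 6)
  expect_length(fb$h1, 6)
  expect_equal(sum(fb$h0^2), 1, tolerance = 1e-12)
  expect_equal(sum(fb$h1^2), 1, tolerance = 1e-12)
  expect_lt(abs(sum(fb$h0) - sqrt(2)), 1e-12)
  expect_lt(abs(sum(fb$h1)), 1e-12)
})

test_that("symmetric padding mirrors whole samples on both ends", {
  expect_equal(pad_symmetric(c(1, 2, 3, 4)),
               c(4, 3, 2, 1, 1, 2, 3, 4, 4, 3, 2, 1))
  expect_equal(pad_symmetric(rep(5, 5)), rep(5, 13))
  set.seed(11)
  x <- rnorm(10)
  for (w in c(1, 4, 5)) expect_equal(pad_symmetric(x, w), oracle_pad(x, w))
  expect_error(pad_symmetric(c(1, 2), 4), "shorter")
})

test_that("one analysis step matches the brute-force definition on many lengths", {
  fb <- db3_filterbank()
  set.seed(21)
  for (n in c(6, 7, 10, 13, 20, 35, 64)) {
    x <- rnorm(n)
    s <- dwt_step(x, fb)
    expect_equal(s$approx, oracle_dwt(x, fb$h0), tolerance = 1e-12,
                 info = paste("approx, n =", n))
    expect_equal(s$detail, oracle_dwt(x, fb$h1), tolerance = 1e-12,
                 info = paste("detail, n =", n))
    expect_length(s$approx, (n + 5) %/% 2)
  }
  expect_error(dwt_step(rnorm(5)), "at least 6")
})

test_that("a constant input passes through as c * sqrt(2) with zero detail", {
  s <- dwt_step(rep(3, 128))
  expect_equal(s$approx, rep(3 * sqrt(2), 66), tolerance = 1e-9)
  expect_lt(max(abs(s$detail)), 1e-9)
})

test_that("four-level decomposition has the fixed length chain and layout", {
  w <- ml_dwt(fixture_window())
  expect_equal(vapply(unclass(w), length, integer(1)),
               c(A4 = 12L, D4 = 12L, D3 = 20L, D2 = 35L, D1 = 66L))
  flat <- w4_flat(w)
  expect_length(flat, 145)
  sl <- w4_slices()
  expect_equal(flat[sl$A4], w$A4)
  expect_equal(flat[sl$D1], w$D1)
  expect_equal(w4_from_flat(flat), w)
  expect_error(w4_from_flat(rnorm(144)), "145")
})

test_that("decomposition agrees with an independent db3 implementation", {
  # frozen output of a reference symmetric-extension db3 wavedec for the
  # deterministic fixture window (two superposed sinusoids on a 2 uS level)
  w <- ml_dwt(fixture_window())
  expect_equal(w$A4[1:4],
               c(8.7710646848537, 8.80450665986397, 8.59917328873996,
                 8.91075943577362), tolerance = 1e-10)
  expect_equal(w$D4[1:4],
               c(0.0718774786763205, -0.19449203663713, -0.501784915476092,
                 0.38354126968816), tolerance = 1e-10)
  expect_equal(w$D3[1:4],
               c(-0.147166026068607, -0.380046403624687, 0.355276196213784,
                 -0.353825929825755), tolerance = 1e-10)
  expect_equal(w$D2[1:4],
               c(0.178452232857053, -0.0692587049385673, 0.0955478879483013,
                 -0.0474198801946928), tolerance = 1e-10)
  expect_equal(w$D1[1:4],
               c(-0.031346329607162, 0.0344850888290104, 0.00336580256847814,
                 -0.000979096276641458), tolerance = 1e-10)
  expect_equal(sum(w4_flat(w)^2), 872.7761015741827, tolerance = 1e-10)
})

test_that("transform is linear and energy-compacting for constants", {
  set.seed(31)
  x <- runif(128, 1, 4)
  y <- runif(128, 0.5, 2)
  wa <- w4_flat(ml_dwt(eda_window(x)))
  wb <- w4_flat(ml_dwt(eda_window(y)))
  wab <- w4_flat(ml_dwt(2 * x + 0.5 * y))
  expect_equal(wab, 2 * wa + 0.5 * wb, tolerance = 1e-9)

  wc <- ml_dwt(eda_window(rep(2.5, 128)))
  expect_lt(max(abs(c(wc$D1, wc$D2, wc$D3, wc$D4))), 1e-9)
  expect_equal(unname(energy_fractions(wc)["A4"]), 100, tolerance = 1e-9)
  expect_equal(wc$A4, rep(2.5 * 4, 12), tolerance = 1e-9)  # sqrt(2)^4
})

test_that("round trip through the inverse transform is exact", {
  set.seed(41)
  for (i in 1:100) {
    x <- runif(128, 0, 8)
    w <- ml_dwt(eda_window(x))
    r <- inverse_ml_dwt(w)
    expect_lt(max(abs(r - x)) / max(abs(x)), 1e-9)
  }
})

test_that("inverse transform handles degenerate coefficient inputs", {
  z <- inverse_ml_dwt(w4_from_flat(numeric(145)))
  expect_equal(z, numeric(128))
  wc <- ml_dwt(eda_window(rep(2, 128)))
  wz <- wavelet_coeffs(wc$A4, numeric(12), numeric(20), numeric(35),
                       numeric(66))
  expect_equal(inverse_ml_dwt(wz), rep(2, 128), tolerance = 1e-9)
  expect_error(wavelet_coeffs(1:11, numeric(12), numeric(20), numeric(35),
                              numeric(66)), "level lengths")
})

test_that("eda_window validates its invariants", {
  expect_error(eda_window(rep(1, 127)), "128")
  expect_error(eda_window(c(rep(1, 127), NA)), "finite")
  expect_error(eda_window(c(rep(1, 127), -0.1)), "non-negative")
  expect_error(eda_window(rep(1, 128), fs = 4), "2 Hz")
})
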