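Package: edacodec
Title: Wavelet Compression and Feature-Distortion Analysis for Electrodermal Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossy compression codec for skin-conductance (electrodermal
    activity, EDA) time series sampled at 2 Hz, as used by memory-constrained
    wearable recorders. Implements a four-level Daubechies-3 discrete wavelet
    transform of 64-second windows with symmetric boundary extension, top-K
    magnitude selection of quantized coefficients, a bit-exact packed block
    format for 16-bit architectures, and signal reconstruction by the inverse
    transform. Includes distortion metrics (compression ratio, percent
    root-mean-square difference, RMS error, per-level energy fractions),
    tonic and phasic EDA feature extraction with a trough-to-peak skin
    conductance response detector, a seeded synthetic EDA session generator
    with a Chebyshev type-II preprocessing filter, and file-level compress /
    decompress / evaluate entry points with a command-line wrapper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
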