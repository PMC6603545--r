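---
title: "Wavelet compression of electrodermal activity: model, codec and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet compression of electrodermal activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edacodec)
```

## The problem

Electrodermal activity (EDA) — skin conductance, in microsiemens — is a
slow signal with two components: a tonic level that drifts over minutes,
and phasic skin conductance responses (SCRs), second-scale trough-to-peak
pulses triggered by sympathetic arousal. A wearable recorder that keeps
raw 32-bit samples at 2 Hz produces 64 bits/s, too much for the tens of
kilobytes of storage available on a single low-power microcontroller.
`edacodec` implements and evaluates the lossy codec that makes on-chip
recording feasible: transform 64-second windows into a sparse wavelet
representation, keep only the few coefficients that matter, pack them
bit-tight, and reconstruct off-line.

The package serves two audiences: engineers choosing a codec operating
point for a recorder, and psychophysiologists who need to know how much
compression their *features* — not their raw traces — can tolerate.

## Transform

Each window of 128 samples is decomposed four times with the orthonormal
6-tap Daubechies-3 filters (`db3_filterbank()`; unit L2 norm, so the
scaling filter sums to √2). One analysis step extends the input by five
mirrored samples on each side (whole-sample symmetry) and computes the
stride-2 correlation with the analysis pair, giving `floor((N+5)/2)`
outputs from `N` inputs. Four steps produce approximation lengths
128 → 66 → 35 → 20 → 12 and detail lengths 66, 35, 20, 12, i.e. the flat
vector `W4 = [A4 | D4 | D3 | D2 | D1]` of 145 coefficients.

Two conventions were genuinely open and are fixed as follows:

* **Output length.** A literal half-length rule (`M = N/2`) with a 4-sample
  pad cannot turn 35 level-2 coefficients into the 20 level-3 coefficients
  the fixed layout requires. We use the `floor((N+5)/2)` convention of
  mainstream wavelet libraries' symmetric mode, which reproduces the layout
  exactly and admits an exact inverse. One reference implementation of this
  convention (PyWavelets) was used to freeze cross-check constants in the
  test suite.
* **Filter orientation.** The analysis/synthesis orientation of the db3
  taps is pinned by the perfect-reconstruction property, which the tests
  enforce at a relative 1e-9 on arbitrary windows (observed error is at
  machine precision).

Symmetric extension matters: without it, border discontinuities generate
large detail coefficients that hijack the top-K selection and distort
window edges.

## Codec

Windows are scaled to 0.01 µS units *before* the transform, so
coefficients are meaningful integers after truncation toward zero
(mirroring the integer cast a fixed-point MCU performs; round-half rules
were rejected as unfaithful to that cast). Fields are sized from the
observed coefficient ranges of real EDA: `A4` is non-negative for a
non-negative signal and fits an unsigned 12-bit field (values to 4095,
i.e. 40.95 µS·4 at the level-4 gain); details fit signed 8-bit. Values
outside a field saturate, and saturation is recorded —
`quantize_coeffs()` never silently wraps.

`select_top_k()` retains the K largest magnitudes with the tie-break of a
strict greater-than scan (lowest index wins). The twelve `A4` positions
are force-included for K ≥ 12 rather than trusting that they always
dominate: this keeps the block layout well-formed for every input, at zero
cost whenever the assumption holds anyway.

The packed block (`encode_block()`) is built from 16-bit words, the
natural register width of the target class of MCUs:

| region | content |
|---|---|
| 12 A-words | bits 15..4: `A4[i]` unsigned 12-bit; bits 3..0: address nibbles of the first six details (8-bit absolute index 12–144, low nibble in word `2j`, high nibble in word `2j+1`; unused nibbles 0 — a valid sentinel since real detail addresses are ≥ 12) |
| detail words | two signed 8-bit detail values per word, even position in the low byte, odd count padded with a zero high byte |
| extended words | for details beyond the sixth: value in the high byte, 8-bit address in the low byte |

Hence `bits_for_k(k) = 192 + 16·ceil(min(k−12,6)/2) + 16·max(0,k−18)` for
k ≥ 12, and the published operating ladder follows:
K = 64, 32, 21, 18, 14, 11 → CR = 4.2, 8.8, 14.2, 17.1, 19.7, 23.3 (one
decimal), with K = 18 the canonical 30-byte block.

For K < 12 some `A4` entries must be dropped (that is what CR 23.3×
means). A block of K words with all-zero nibbles would be undecodable —
the decoder could not know *which* slots were dropped — so each word's low
nibble carries its own `A4` position (0–11). This is the minimal
completion of the layout that decodes unambiguously; the decoder
zero-fills the dropped slots. Note the consequence, visible in every
evaluation sweep: zeroing even the smallest tonic-scale `A4` coefficient
costs orders of magnitude more distortion than zeroing details, so the
K = 11 point is a cliff, not one more step on the ladder.

`decode_block()` is the exact inverse and validates structure (payload
length, address range, duplicates, sentinel nibbles), raising an
`edacodec_corrupt_block` condition otherwise. The container file
(`write_block_container()`) is little-endian: magic `EDW1`, then per
window a `uint32` start time, `uint8` K, and the payload; K lives in the
record header, so compression-ratio accounting counts payload bits only.

## Metrics

* `compression_ratio()` — raw bits over payload bits; raw side is 32
  bits/sample at 2 Hz.
* `prd()` — 100·√(Σ(x−x̂)²/Σx²). The denominator is *not* mean-subtracted;
  part of the literature subtracts the mean, we deliberately do not, so
  values are comparable only to the non-subtracted convention.
* `rms_err()` — √mean((x−x̂)²), in µS.
* `energy_fractions()` — per-level share of Σc² in percent; the shares sum
  to 100 by construction.
* `feature_relative_error()` — signed population relative error
  (Σf_recon − Σf_orig)/Σf_orig; plots may take magnitudes, the number
  itself keeps its sign.
* `storage_duration()` — recording hours in a memory budget. Two modes:
  first-principles (storage·8/(64/CR)/3600; 48 kB uncompressed → 1.71 h)
  and a base-duration mode (`base_hours · CR`) for reproducing duration
  tables quoted against a device whose stated uncompressed capacity
  (0.60 h on 48 kB) disagrees with the 64 bits/s arithmetic. The package
  asserts neither as ground truth.

## EDA features and the SCR detector

Tonic features are the window mean (SCL), min, max and population standard
deviation. Phasic features are sums over detected SCRs of amplitude
(trough to peak, µS), duration (onset until the signal first falls to
peak − amplitude/2, truncated at the window end, s) and the triangular
AUC = ½·amplitude·duration.

The detector (`detect_scrs()`) is deliberately simple and fully specified:
slope-sign runs locate troughs and peaks (plateaus inherit the preceding
slope; window boundaries count as extrema), each trough pairs with the
next peak, a new event may begin only after the previous peak, and events
below `min_amplitude` (default 0.01 µS, the acquisition resolution — the
field's own minimum-amplitude conventions vary, so results that depend on
this threshold are qualitative) are discarded after detection, which makes
the event count monotone non-increasing in the threshold. There is no
tonic/phasic decomposition and no deconvolution of compound responses;
overlapping SCRs merge into fewer, larger events. That is acceptable here
because the evaluation only ever compares *the same detector* on original
and reconstructed signals: the quantity of interest is the feature error
introduced by compression, not agreement with any particular
physiological scoring toolkit.

## Synthetic sessions

`generate_session()` draws: a tonic baseline as a Gaussian random walk
(per-sample σ 0.01 µS) reflected into 0.25–6.67 µS, the validated range of
the class of sensor emulated; SCR arrivals as a Poisson process (default
2/min, a mildly aroused subject); pulse shapes as a difference of
exponentials with 1 s rise and 4 s decay, normalised to unit peak, with
lognormal amplitudes (meanlog log 0.2, sdlog 0.4 → bulk 0.1–0.45 µS);
white measurement noise (σ 0.005 µS); and clips the sum to 0–10 µS.
Everything is seeded and reproducible. The acquisition low-pass — a
causal, minimum-order (order 5, from the closed-form Chebyshev bound on
the bilinear-prewarped edges) Chebyshev type-II filter with 0.6 Hz
passband (≤3 dB) and 0.9 Hz stopband (≥74 dB) at 2 Hz — belongs to the
dataset-preparation path, not the codec; zero-phase filtering was rejected
because an on-line acquisition chain cannot look ahead.

What the generator does *not* model: motion artifacts, electrode-contact
dropouts, site-dependent amplitude differences (wrist vs palm),
sigmoid-exponential tonic shapes, or any coupling between arousal state
and SCR rate. Passing tests on synthetic populations therefore
demonstrates codec correctness and the *mechanism* of feature degradation
(details lost first → phasic features suffer first), not clinical-grade
error magnitudes on human data.

## Evaluation design and observed behaviour

`eda_evaluate_file()` sweeps K over the ladder and reports per-window PRD
and RMS error, tonic absolute errors, and phasic population relative
errors, mirroring how the codec's operating point is chosen in practice.
The package's tests assert the qualitative structure this produces on
synthetic populations: reconstruction error is monotone non-increasing in
K per window; energy compaction puts >99 % of wavelet energy in `A4`
(mean ≈ 99.9 % across 120 generator windows — the acceptance script
recomputes this); tonic relative errors stay below the phasic relative
errors at every K on the ladder; and phasic errors grow as K shrinks.

Problem sizes in the default test and acceptance runs — populations of
10–120 windows (sessions of 640 s), 100–300 randomized codec round trips,
the six-point K ladder — were chosen so the full suite documents every
property in well under a minute while keeping stochastic assertions at
least three standard errors from their thresholds.

## Known limitations

* Only the fixed geometry is supported: 128-sample windows, fs = 2 Hz,
  db3, four levels. This is a feature (the block format depends on it),
  not laziness, but it means the codec cannot be re-targeted without
  touching the layout constants.
* Quantization saturates at 40.95 µS (A4) and ±1.28 µS (details) in
  0.01 µS units; windows with pathologically large detail energy (not
  EDA-like) lose information beyond the resolution bound, flagged via the
  saturation record.
* The K = 11 operating point drops tonic information and is qualitatively
  worse than every K ≥ 12 point; it is provided for completeness of the
  ladder, with the cliff documented above.
* PRD values are tied to the non-mean-subtracted convention and are not
  comparable to mean-subtracted PRD figures elsewhere.
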