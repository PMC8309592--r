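---
title: "Methods: from tagged video seconds to band-power statistics and single-second decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tagged video seconds to band-power statistics and single-second decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdepeeg)
```

## The problem

Visual design elements and principles (VDEPs) — here colour (cold/warm),
balance (asymmetrical/symmetrical), movement (fast/slow) and light
(bright/dark) — are compositional properties of video content that are
believed to modulate viewers' brain activity. `vdepeeg` implements a
complete analysis chain for studying that link with multi-participant EEG
recorded during video viewing, in the array dialect popularised by the
DEAP affective-computing dataset: one array per participant of shape
`trials x 40 channels x 8064 samples` at 128 Hz, where a 63-s trial is a
3-s pre-trial baseline followed by 60 s of video, channels 1–32 are EEG
and 33–40 are peripheral.

Because such recordings are access-restricted, the package ships a
synthetic generator producing data of exactly that shape with *known*
ground truth, so every downstream stage is testable end to end. The chain
is:

1. per-second expert tags, resolved across two annotators;
2. an extraction–transformation process (ETP) turning tagged seconds into
   labelled one-second `128 x 32` epochs;
3. mean band power per epoch in the five classical EEG bands, compared
   between classes with rank-sum tests;
4. a compact convolutional network that decodes the VDEP class of a
   single epoch, evaluated by repeated random 90/10 splits.

## Synthetic data model

Each EEG channel is pink (`1/f`) background noise plus one sinusoid per
band at the band's geometric-centre frequency, with a fresh random phase
per second and channel. Class effects enter as per-band amplitude
multipliers (`band_gains`): a map `vdep -> class -> band -> multiplier`,
multiplicative across dimensions because all four dimensions label every
second simultaneously. The pre-trial baseline carries no oscillatory
class effect, peripheral channels are white-noise placeholders, and
trials beyond the annotated `n_videos` are unannotated filler that the
ETP must skip — mirroring a study in which only 26 of 40 stimulus videos
could be retrieved and tagged.

Choices and defaults (all surfaced in `sim_config()`):

- **One sinusoid per band rather than band-limited noise.** Oscillation
  power is then analytic (`A^2/2` for amplitude `A`), which gives
  closed-form oracles for the spectral tests.
- **Latent class runs are geometric** with mean `mean_run_s = 5` s,
  alternating class between runs, so interval construction is
  non-trivial. Five seconds is a realistic shot length for music-video
  footage.
- **Default effects**: balance, light and movement carry a modest
  broadband amplitude multiplier (1.15–1.25) for one class — higher power
  for symmetrical, bright and fast content, the directions reported for
  real footage — and colour carries none, matching the qualitative
  finding that colour is the hardest dimension to decode.
- **Annotator model**: each expert independently reports "unclear" with
  probability `annot_unclear` (default 0.05), otherwise the true class
  with probability `annot_agreement` (default 0.95). No published
  agreement rates exist for this kind of tagging, so both are explicit
  configuration, never hard-coded. Under this model the probability that
  a second survives resolution is `(1-u)^2 (a^2 + (1-a)^2)`, which the
  tests check by simulation.

What the generator does **not** emulate: volume conduction and channel
correlation, artefacts (EOG/EMG), non-stationarity, participant-specific
spectra, or any raw-to-preprocessed chain (the data are simulated as if
already downsampled, filtered and re-referenced). Passing tests therefore
demonstrate pipeline correctness and statistical calibration, not
performance claims about real EEG.

## Annotation resolution and balancing

A (video, second, dimension) is kept iff both experts gave the same
non-"unclear" label; a second is discarded if *either* expert was unclear
(the strictest reading) or the experts disagreed, and both discard
reasons are reported separately because published summary tables often
merge them. Maximal constant-class runs within a video form the interval
set; discarded seconds break runs.

Class counts are summarised per dimension together with `n_v`, the size
of the smaller class. Balancing draws `n_v` seconds per class uniformly
without replacement. The pipeline balances **epoch-yielding seconds**
(after ETP trimming) rather than raw tagged seconds, because trimming
consumes interval edges unevenly and only second-level balancing after
trimming guarantees an exactly balanced epoch set; `balance = "tags"`
restores tag-level balancing.

## The ETP

Second `s` (0-based) of a video occupies samples
`[(s + 3) * 128, (s + 4) * 128)` of its trial — the 3-s baseline is
skipped, ranges are half-open and 0-based. For each interval of `L` whole
seconds, 0.5 s (64 samples) is trimmed from each end and the remainder is
split into `L - 1` contiguous non-overlapping one-second epochs; a 5-s
interval yields 4 epochs, an interval shorter than 2 s yields none. Only
EEG channels 1–32 are retained. The non-overlapping unit-stride grid
anchored at interval start + 0.5 s is the reading consistent with four
epochs from a five-second segment; no perception-time lag is applied. An
epoch's `second` metadata is the tagged second in which it starts, so one
interior annotated second contributes exactly one epoch per participant —
32 epochs under the default pool.

Epochs bound for the decoder are min-max normalized to `[0, 1]` over the
whole `128 x 32` matrix (all channels jointly, the literal reading of a
normalization over the full sample; `per_channel = TRUE` is available). A
constant epoch maps to zeros with a warning. The statistics path consumes
**un-normalized** epochs, since band power on amplitude-rescaled data
would be meaningless; `band_power_table()` enforces this.

## Spectral estimates

Band edges default to delta 1–4, theta 4–8, alpha 8–13, beta 13–30,
gamma 30–45 Hz: conventional ranges truncated at 45 Hz, the upper edge of
the DEAP-style band-pass. A band filter keeps DFT coefficients with
`lo <= f < hi` (both conjugate halves), always zeroing DC and Nyquist,
and inverse-transforms. "Mean band power" is the time-average of squared
band-filtered samples, averaged unweighted over the 32 EEG channels;
`measure = "amplitude"` provides the mean-rectified alternative for
readings of "mean absolute power" as amplitude rather than power. Delta
is computed even though a 4-Hz high-pass upstream leaves only residual
delta content in real recordings — the caveat travels with the output,
not the code. Tests verify the estimates against independent periodogram
integration at 1e-6 relative tolerance.

## Statistics

Normality screening uses the Kolmogorov–Smirnov test with the Lilliefors
correction (parameters estimated from the sample; p-values via the
standard Lilliefors approximation as implemented in `nortest`). Class
comparisons use the two-sided Mann–Whitney U test per band: U is the
pair-count statistic (ties counting half), p is exact by enumeration for
tie-free samples with `n1 + n2 <= 12` and otherwise a normal
approximation with tie and continuity corrections. The direction of the
effect (which class has the larger mean rank) and a significance flag at
`alpha = 0.05` are reported per band.

Two deliberate fidelity choices, both relaxable: no multiple-testing
correction by default (a Holm-adjusted column is always computed and a
flag makes it drive the significance call), and epochs are pooled across
participants as independent observations. The latter ignores the
repeated-measures structure — epochs from one participant are correlated
— and is a known limitation of the pooled design, not a recommendation.

## The decoder

Channels are first re-ordered by scalp proximity: the default layout is a
greedy nearest-neighbour chain over schematic 10–20 montage coordinates
starting at Fp1, which reduces the mean scalp distance between adjacent
matrix columns below that of the native recording order (the tests verify
this), so 3x3 convolutions see spatially coherent neighbourhoods. The
layout is data — any permutation can be supplied.

The network is deliberately small: two conv blocks (8 then 16 filters,
3x3 kernels, ReLU, 2x2 average pooling), a 32-unit dense layer, and one
sigmoid output, trained with Adam (learning rate 3e-3, batch 64) on
binary cross-entropy, at most 12 passes with early stopping on validation
loss (patience 2). Inputs are centred by subtracting 0.5 from the
`[0, 1]`-normalized epochs, which measurably speeds convergence. The
targets the model faces — band-amplitude contrasts — are low-dimensional,
and this capacity reaches the same operating point as wider nets at half
the training cost; all of it is configurable through `model_config()`.
Forward/backward kernels are compiled (im2col + BLAS matrix products)
with pure-R reference implementations kept as test oracles, and the
backward pass is verified against numerical differentiation.

Evaluation is non-exhaustive 10-fold cross-validation: 10 *independent*
random stratified 90/10 splits (Monte-Carlo CV, not a partition), one
fresh model per split, reporting ROC AUC (rank statistic), accuracy at
0.5, and PR-AUC (step integration) per fold and on average. Splits are at
the epoch level by default, so epochs from the same participant and
video can appear on both sides — this mirrors the pooled single-epoch
design and inflates scores relative to subject-wise generalisation;
`group_split = TRUE` holds out whole participants instead.

## Numerical and scale choices

- Seeds: every stochastic stage takes a seed; stage seeds are derived
  from one global seed by a fixed integer map, and all generators
  save/restore the caller's RNG state.
- Degenerate inputs: constant epochs normalize to zeros with a warning;
  constant samples are an error in `lilliefors()`; single-class tables,
  labels or folds are contract errors, not silent NAs.
- Exactness boundaries: the exact rank-sum enumeration threshold
  (`n1 + n2 <= 12`, tie-free) is a contract, not a performance heuristic.
- Test scale: calibration suites run 1000 null replicates of the
  five-band comparison (50 epochs each) and the decoder-recovery suite
  uses 2000 epochs per condition with 10 CV repeats — sizes chosen so
  Monte-Carlo error is small relative to the tested tolerances while the
  whole suite stays comfortably runnable on a laptop core.

## Known limitations

Pooled epochs ignore participant-level correlation; epoch-level CV
overstates subject-wise generalisation; the synthetic signal model is
deliberately simple (no spatial covariance, no artefacts), so decoder
scores on synthetic data say nothing about achievable accuracy on real
recordings; and delta-band results on 4-Hz high-passed data reflect
filter leakage more than physiology.
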