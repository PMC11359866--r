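---
title: "Methods: UWB radar fall classification with SE-RCNet and adaptive weighted fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: UWB radar fall classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Falls are a leading cause of injury among the elderly, and distinguishing
*types* of falls (backwards, sideways, at an angle, while sitting down) from
each other and from everyday activities matters for triage and care.
Ultra-wideband (UWB) impulse radar is an attractive sensor for this task: it
is privacy-preserving, works in the dark and through light occlusion, and its
large bandwidth gives centimetre-scale range resolution, so the motion of a
human torso is visible both in range and — through the Doppler effect — in
radial velocity.

`uwbfall` implements the full recognition chain for a 10-class task (5 daily
activities, 5 fall variants): echo simulation, three-map preprocessing, a
convolutional classifier with squeeze-and-excitation (SE) channel attention,
and decision-level fusion of the three maps' classifiers.

## Echo model and the synthetic generator

A recording is a real-valued *pulse matrix* `X[i, n]`: fast time (range bin
`i`) by slow time (pulse index `n`). The default geometry matches an
impulse-radar module of the PulsOn-440 class: PRF 240 Hz, carrier 4.3 GHz,
bandwidth 1.7 GHz, 5 s recordings (1200 pulses). The simulator places a
single human-scale point scatterer at range `R(t)` and synthesizes

    X[i, n] = a(t_n) * exp(-(r_i - R(t_n))^2 / (2 s^2)) * cos(4 pi fc R(t_n) / c)
              + clutter[i] + noise[i, n]

with `s = c/(2B) ~ 8.8 cm` (the physical range resolution carried by the
envelope), a static clutter column, and i.i.d. Gaussian noise. The fast-time
axis is a decimated range grid (default 256 bins over 5 m), not the raw
16 GHz RF sampling: the classifier consumes magnitude maps, so only the
envelope and the slow-time carrier phase matter. The two-way phase term makes
the Doppler shift `fd = 2 v fc / c` appear after analytic-signal conversion.
Because the echo is real-valued, the sign of the Doppler shift is not
observable from a single decimated bin — walking towards and away from the
radar are distinguished by the range trajectory rather than the sign of
`fd`. This mirrors what the magnitude maps show anyway.

Per-class trajectories are piecewise smooth raised-cosine segments with
seeded jitter:

* **falls** (classes 1, 3, 5, 8, 9): a 0.7–1.2 m displacement burst whose
  peak radial speed is drawn from the 1.5–3 m/s band, then stillness with a
  small decaying settle oscillation. Backwards falls move away, the two
  45-degree falls move towards the radar and differ only in their subtle
  settle cue — deliberately near-ambiguous, as mirrored falls are for a
  single radar.
* **walking** (6, 7): strictly monotone range across the scene with a
  10–15 % gait modulation. With a 5 m scene and 5 s recordings the sustained
  speed is ~0.7–0.85 m/s, peaking near 1 m/s — the span the room allows.
* **sit / stand / bend** (0, 4, 2): 0.15–0.35 m transients below 0.8 m/s;
  bending returns to the starting range.

Start ranges (1.8–4.6 m depending on class) are a configurable guess: room
geometry is not fixed by the sensor. What the generator does **not** model:
multi-limb micro-Doppler (a single scatterer has no gait "fan" or arm
swing), multipath/wall reflections, antenna patterns, multiple people, or
between-subject body-profile variation. Classifiers trained on these
simulations therefore validate the *pipeline* — map construction, network
mechanics, fusion arithmetic — not performance on real human returns.

## Three-map preprocessing

1. **MTI.** The three-pulse canceller `y(n) = x(n+1) - 2x(n) + x(n-1)` is
   applied per range bin along slow time. It annihilates constants and
   linear ramps exactly (the static clutter column) and has magnitude
   response `4 sin^2(pi f / prf)`. The output is 2 pulses shorter; all map
   time axes refer to the filtered grid.
2. **Range–time map.** The analytic signal is formed per range bin with the
   FFT half-spectrum Hilbert method, and its magnitude is the envelope. The
   Hilbert transform runs along slow time because that is where the Doppler
   structure lives; the FFT length is zero-padded to the next 5-smooth
   integer (1198 = 2 x 599 would otherwise hit the FFT's worst case) and
   truncated back.
3. **Time–Doppler map.** The analytic values are coherently summed across
   range bins into one complex series (standard micro-Doppler practice) and
   a magnitude STFT is taken: 128-point Hamming window, 110-point overlap
   (hop 18), zero-centred frequency axis spanning ±PRF/2.
4. **Range–Doppler map.** A magnitude FFT along slow time per range bin,
   zero-centred, zero-padded to a 5-smooth length (pure spectral
   interpolation).

**A note on MTI spectral skew.** The canceller's response rises with
frequency, so the ~2 Hz-wide spectrum of a target that dwells only ~0.2 s in
each range bin (v = 1 m/s) is skewed upward by ~0.3 Hz. The effect is below
the time–Doppler map's 1.875 Hz resolution but visible at the range–Doppler
map's 0.2 Hz grid; it shrinks linearly with target speed. Calibration
measurements of Doppler placement therefore either use the unfiltered
analytic signal (no clutter, nothing to cancel) or slower targets.

**Images.** Maps are log-compressed (20·log10 relative to the map maximum,
floored at −60 dB — a conventional radar dynamic range that keeps noise from
dominating the normalization), min–max scaled to [0, 1] and bilinearly
resampled to 80 × 80. The dB step makes images invariant to overall echo
scaling. Images are single-channel magnitude maps; colormapped 3-channel
input is supported through the classifier's channel parameter but is a
cosmetic rendering choice.

## SE-RCNet

The classifier maps an 80 × 80 image to 10 logits:

* initial 3 × 3 convolution + ReLU;
* six *dense residual blocks*: conv–BN–ReLU, conv–BN–ReLU, element-wise sum
  of the two paths, SE recalibration of the sum, concatenation with the
  block input (the "dense" connection; an additive merge is available via
  `merge = "add"`), then 2 × 2 max-pooling — spatially
  80 → 40 → 20 → 10 → 5 → 2 → 1;
* flatten and a dense softmax head.

The SE module squeezes each channel to its spatial mean, passes it through a
bottleneck (reduction r = 4, ReLU) and a sigmoid, and rescales channels by
the resulting gates — channel attention that suppresses uninformative
channels. Setting all gates to 1 recovers the plain residual block, which is
how the block wiring is tested.

Choices the architecture description leaves open and how they are fixed
here (all config-exposed): 3 × 3 kernels, "same" padding, stride 1; channel
widths [16, 32, 48, 64, 80, 96]; Adam (lr 1e-3, batch 32); cross-entropy
loss; He-normal initialization. Batch normalization uses the statistics of
the batch being processed, in training and at prediction alike, rather than
tracked running averages: the package guarantees bit-reproducible training
and prediction given a seed, and prediction must be a pure function of the
weights (a zero learning rate leaves the model exactly untouched). The
consequence — predictions depend mildly on the composition of the batch
being scored — is documented in `predict.sercnet_model`, which scores its
input as one batch.

The implementation is self-contained: im2col + GEMM convolutions (Armadillo
kernels in `src/`), hand-derived backward passes for every layer, verified
against central finite differences to 1e-5 relative error in the test suite.

## Confidence fusion

Each map's classifier emits logits `z`; `softmax_probs()` converts them
shift-invariantly to probabilities `s`, with confidence `smax = max(s)` and
prediction `imax = argmax(s)` (ties to the lowest class index — as are all
ties in the fusion chain; the choice is arbitrary but fixed and tested).

* **Decision fusion**: majority of the three predictions; if all differ, the
  most confident map wins.
* **Adaptive weighted fusion**: per sample, the three confidences are
  sum-normalized to `m` (the only normalization that makes the triple a
  probability vector over maps); with per-map validation accuracies
  `n = [n1, n2, n3]`, the Hadamard product `w = n ∘ m` weights each map, the
  weights of maps agreeing on a class are summed into `w'`, and
  `argmax(w')` is the fused class. Classes predicted by no map score 0.

`n` is the scalar overall validation accuracy of each map. A per-class
variant (a 3 × K accuracy matrix, each map weighted by its accuracy on its
own predicted class) is available but not the default; the scalar reading
matches "the accuracy of the k-th radar map type". Normalization of `m` is
per sample, not across the test set — the per-sample reading is the one that
makes the fused decision independent of unrelated samples.

When all validation accuracies are equal, the adaptive rule reduces to the
confidence rule on all-different predictions, and whenever the maps are
unanimous both rules return the common class for any positive `n` — both
properties are tested on random instances against a brute-force scorer.

## Evaluation protocol

`split_622()` partitions samples 6:2:2 (train/validation/test), stratified
per class — the plain random split would leave class ratios to chance at
small n, and stratification is what a careful experimenter does with a
balanced corpus. `kfold()` provides stratified 5-fold plans.
Precision/recall/F1 are macro-averaged (unweighted class means) by default,
with micro averaging behind a flag; a class never predicted gets precision 0
rather than NaN. Improvement rows of the experiment report are printed in
both conventions — absolute percentage points and relative percent — because
published comparisons of fused versus best-single-map results are
ambiguous between the two.

`run_experiment()` drives the whole protocol: simulate → maps → stratified
split → one SE-RCNet per map → validation accuracies `n` → test-set fusion
with both rules → metrics tables and confusion matrices, fully seeded. Its
`degrade_kind`/`degrade_sigma` options corrupt one map kind with additive
pixel noise to study how the two fusion rules cope with an unreliable map:
equal-weight decision fusion lets a confidently wrong degraded map carry
all-different votes, while the adaptive rule scales it down by its (low)
validation accuracy.

## Problem sizes used by the tests

Full-corpus training (2700 recordings, 100 epochs, six blocks) is a
GPU-scale computation. The test suite and the acceptance script instead use
reduced configurations, chosen as the package's own desk-scale protocol:

* parameter recovery: 500 recordings (50 per class), time–Doppler maps, a
  4-block network (channels 12/16/24/32), 25 epochs — validation accuracy
  comfortably clears 5 × the 10 % chance level (typically ~0.6; mirrored
  45-degree falls stay partly confused, as they should);
* fusion comparison: 10 replicates of 100 recordings each with a tiny
  2-block network, 6 epochs, range–Doppler degraded at sigma 0.6; macro F1
  pooled over replicates consistently favours the adaptive rule;
* contract tests use 0.05–1 s recordings and 8–64 range bins.

## Known limitations

* Single-scatterer echoes: no true micro-Doppler signature, so absolute
  accuracies on simulations say nothing about accuracies on human data.
* The Doppler sign ambiguity of the real-valued decimated echo model
  (discussed above).
* Batch-statistics normalization is non-standard (though documented);
  models exported to other runtimes would need frozen statistics.
* The training loop is CPU-bound R + BLAS; it is meant for desk-scale
  experiments, not full-corpus training.
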