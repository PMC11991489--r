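---
title: "Muscle-brain connectivity analysis with mbconn: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle-brain connectivity analysis with mbconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`mbconn` analyses paired EEG/EMG recordings from motor studies in which each
subject is measured under two sleep conditions (good / poor) and three motor
states (rest, left- and right-biceps isometric contraction). It covers five
analysis layers — preprocessing, EMG fatigue spectra, phase-locking-value
(PLV) functional connectivity with binary graph metrics, network-based
statistic (NBS) group inference, and MVAR-based partial directed coherence
(PDC) between motor-cortex channels and muscle — plus a synthetic study
generator that stands in for human recordings, which are not redistributable
in studies of this kind. This vignette records the models, the parameter
choices that matter, and the design decisions that were genuinely open.

# Preprocessing

The cleaning chain is fixed: EEG takes band-pass 1–100 Hz, band-stop notches
48–52 Hz and 98–102 Hz, resampling to 500 Hz, re-referencing to the mean of
the bilateral mastoids (M1, M2), segmentation into non-overlapping 2 s
epochs, and amplitude-based epoch rejection. EMG takes a 20–150 Hz band-pass
applied twice (a cascade of identical passes, squaring the magnitude
response), resampling, and epoching.

Design choices:

* **Filter family.** All filters are 4th-order Butterworth run
  forward–backward (`signal::filtfilt`), i.e. zero phase. Zero phase is not
  optional here: any phase delay would bias the Hilbert phases that PLV is
  built on. The suite verifies that a symmetric pulse keeps its peak sample
  exactly.
* **Notches as band-stops.** The notches are specified by their printed
  corner frequencies (48–52, 98–102 Hz) rather than by a Q factor, so the
  configuration is bit-for-bit auditable.
* **Resampling.** Integer-ratio decimation uses an 8th-order zero-phase
  anti-alias low-pass at 80 % of the new Nyquist followed by sample picking;
  non-integer ratios fall back to polyphase resampling. Upsampling is
  refused — the pipeline never needs it.
* **Epoch rejection.** Manual artifact screening is replaced by a
  deterministic rule: drop an epoch if any channel exceeds 150 µV peak
  absolute amplitude, or if any channel's RMS z-scored across epochs exceeds
  5. Both thresholds are configuration keys. Independent component analysis
  is deliberately out of scope; the synthetic data contain no blink or
  cardiac artifacts, so nothing in the test bed would exercise it.

# EMG fatigue features

Per epoch and per sub-band (20–100 Hz, 100–150 Hz) the pipeline computes RMS
on the band-filtered time signal and MPF / MF on a Welch spectrum:

* Welch uses 1 s Hann windows with 50 % overlap — 1 Hz resolution at the
  rates used, the field default for surface EMG.
* MPF is the power-weighted mean frequency over the band; MF is the
  smallest frequency at which cumulative band power reaches half the band
  total (left-continuous, hence deterministic on a discrete grid).
* The fatigue-relevant invariant — a rigid spectral downshift by δ moves
  both MPF and MF by −δ within bin resolution — is asserted in the test
  suite. Features are computed per epoch; subject-level means are exported
  alongside, so both analysis granularities remain available.

# PLV connectivity and the sensor-space ROI proxy

PLV between two phase series is the modulus of the time-averaged unit phasor
of their difference. Channels are band-pass filtered per epoch, phases are
extracted with an FFT Hilbert transform, 10 % of samples at each epoch edge
are trimmed (filter and Hilbert transients), PLV is computed over samples
within each epoch and averaged across epochs. Epoch-wise averaging was
chosen over concatenation to avoid phase discontinuities at epoch seams.

The 13 sensorimotor regions of interest (Brodmann areas 1–6, 8 left; 1, 2,
4–6, 8 right — right BA3 has no scout in the template this design follows)
are represented by their nearest 10-10 channels rather than by source
modelling, which is unverifiable without subject anatomy. Each ROI-pair
value is the mean PLV over cross-ROI channel pairs; identical channels
shared by adjacent ROIs are excluded, since a self-pair would contribute a
hard 1. The map is a documented proxy and can be replaced wholesale through
the configuration.

Band edges follow the conventional partition δ 1–4, θ 4–8, α 8–13, β 13–30,
γ1 30–60, γ2 60–100 Hz. The γ2 upper edge is 60–100 Hz throughout; a 60–90
Hz variant appears in some figure material of the source literature, and the
wider band was kept as the text-stated definition.

# Graph metrics

PLV matrices are thresholded by sparsity (the strongest
`round(s·N(N−1)/2)` edges become binary links; ties break deterministically
by weight, then row, then column) over the grid 0.22–0.29 in steps of 0.01.
At each level the package computes the binary Watts–Strogatz clustering
coefficient, characteristic path length over connected pairs (with a
disconnection flag), global efficiency

E_g = 1/(N(N−1)) Σ_{i≠j} 1/d_ij,

with zero contribution from disconnected pairs (forced by the formula), and
local efficiency as the same quantity on each node's neighbour subgraph with
the 1/(k_i(k_i−1)) normalization, nodes of degree < 2 contributing 0. The
small-world index is σ = (C/C_random)/(L/L_random) against an ensemble of
degree-preserving Maslov–Sneppen rewirings (100 × E attempted swaps per
null; 1000 nulls by default, 100 in the test suite for speed — both
configuration keys). Across-sparsity aggregation is the arithmetic mean,
with per-level values retained in the output table. Every metric is checked
against exhaustive BFS brute-force oracles on graphs of up to 13 nodes.

# NBS group inference

For a paired design the package computes edge-wise paired t statistics on
subject difference matrices, masks edges at p < 0.05, and scores connected
components by extent (edge count). The permutation null is per-subject sign
flips of the difference matrices — the natural exchangeability unit for
matched conditions — with the identical edge threshold, and the component
p-value uses the +1 correction, making 1/(n_perm+1) the smallest attainable
value. The intensity variant of the component statistic is not implemented.
Calibration (family-wise error ≈ 0.05 on null data) and planted-component
recovery are part of the acceptance suite.

Outlier handling for scalar endpoints replaces values with |z| > 3 by the
mean of the non-flagged values — one reading of the ambiguous "sequential
means" convention in the source literature; the operation is idempotent and
is the only interpretation implemented.

# MVAR and PDC

A joint model over C3, C4 and the (resampled) EMG channel is fitted per
subject, condition and contraction state on up to 180 s of cleaned
continuous signal: ordinary least squares on the stacked lag regression,
model order by minimum BIC over 1–20 (neither the estimator nor the order is
dictated by the source literature), stability checked on the companion
matrix.

Two PDC variants are provided, because the printed formula in the source
literature is transfer-function based:

* `paper_H` (default): PDC_ij(f) = |H_ij(f)|² / Σ_k |H_kj(f)|², with
  H(f) = [I − Σ_k A_k e^(−i2πfk/fs)]⁻¹. Column sums over targets are exactly
  1 at every frequency; the suite asserts this to 1e−10. Formally this
  normalization is the one conventionally used for DTF, but it is
  implemented verbatim as the primary variant.
* `standard_Abar`: conventional PDC, |Ā_ij(f)| / sqrt(Σ_k |Ā_kj(f)|²),
  offered for cross-checks against standard implementations. On coupled
  systems the two variants disagree (H-based measures see cascade paths,
  Ā-based ones only direct links); this is documented rather than hidden,
  and the zero-coupling acceptance check uses a chain model whose silent
  directions have no path at all, so both variants agree there.

Band PDC is the arithmetic mean over in-band bins for β, γ1, γ2; condition
contrasts are paired t-tests per (directed pair, band) with
Benjamini–Hochberg FDR across the family and the sign of the mean difference
reported.

# Synthetic study generator

The generator emulates the study layout — n subjects × 2 sleep conditions ×
3 motor states, 30 EEG channels (including M1/M2) plus one bipolar EMG
channel at a native 1000 Hz — and implants three condition effects with
recorded ground truth:

1. **Interhemispheric PLV reduction at deprived rest.** Two 10 Hz hemisphere
   sources whose phase difference is von Mises distributed; left
   sensorimotor channels (C3, CP3, C1) lock to the left source, right ones
   (C4, CP4, C2) to the right, each with its own small von Mises channel
   jitter, on a 1/f background. The inter-source concentration κ drops from
   6 (good-sleep rest) to 1 (deprived rest); contractions use κ = 4 in both
   conditions. Phase-coupled pairs admit an analytic PLV oracle, the Bessel
   ratio I₁(κ)/I₀(κ).
2. **EMG spectral downshift.** EMG is Gaussian noise shaped by a Gaussian
   bump (width 25 Hz) band-limited to 20–150 Hz whose in-band centroid is
   solved numerically; good-sleep contractions center at 95 Hz (per-subject
   SD 2 Hz), the deprived left contraction at −10 Hz from the subject's
   baseline.
3. **Directed γ-band coupling.** During contraction a 35–55 Hz narrowband
   cortical component is injected into the task-relevant cortex channel and
   added, lagged, into the EMG (cortex→muscle), while an EMG γ component
   feeds back, lagged, into the cortex channel (muscle→cortex). For the left
   contraction the cortex→EMG gain rises (8 → 16 µV) and the EMG→cortex gain
   falls (3 → 0.8 µV) under deprivation; right-contraction gains are
   condition-invariant.

Effect magnitudes were fixed once, by power calibration of the scaled-down
study (12 subjects) so that each injected effect is detected by its pipeline
stage with power ≥ 0.8; they are all exposed through the effect list and
recorded in `ground_truth.json`.

What the generator does **not** emulate: volume conduction from a common
source model, ocular/cardiac artifacts, non-stationary fatigue drift within
a contraction, and electrode noise correlations. Passing tests therefore
demonstrate correctness of the estimators and the inference chain under the
stated generative model, not robustness to real-recording artifact
structure.

# Problem sizes and numerical conventions

* Synthetic study: rest recordings 40 s, contractions 60 s (native 1000 Hz);
  the package-default PDC segment of 180 s is truncated to the available
  length. These sizes keep a full 12-subject study (72 recordings) and all
  downstream stages runnable on a laptop-scale machine while leaving every
  estimator deep inside its asymptotic regime (≥ 20 epochs per PLV matrix,
  ≥ 22,500 samples per MVAR fit).
* All randomness flows from one master seed; every stage and recording draws
  a derived 31-bit substream, so a study regenerates byte-identically.
* Degenerate inputs have defined behaviour: constant signals refuse phase
  extraction, empty graphs refuse path lengths, all-rejected epoch sets halt
  with a diagnostic, zero-variance paired differences raise a
  degenerate-test error, and configuration validation is total (violations
  are reported, never thrown).

# Known limitations

* The ROI map is a sensor-space proxy; ROI-level PLV inherits volume
  conduction of real sensor data, which the synthetic bed does not model.
* The `paper_H` PDC variant mixes direct and cascade influence; directional
  conclusions on systems with strong indirect paths should be cross-checked
  with `standard_Abar`.
* NBS uses the extent statistic only, and the sign-flip null keeps large
  constant effects partially in the permutation distribution: a flipped
  edge with a strong effect re-crosses the threshold with probability
  ≈ P(|Σ of n random signs| ≥ t_crit·√n), independent of the effect
  magnitude. At a 0.05 edge threshold with 12 subjects this places a focal
  5-edge true component near the 95th percentile of the null maximum
  extent, so such focal effects are localized reliably but reach
  family-wise significance in only about two thirds of replicates,
  whatever their amplitude. Broader effects (as in the synthetic study's
  interhemispheric contrast) do not suffer from this; an intensity-type
  component statistic would, but is deliberately not implemented.
* The EDF writer quantizes to 16 bits over the recording's own symmetric
  range; round-trip error is bounded by the quantization step and checked in
  the suite.
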