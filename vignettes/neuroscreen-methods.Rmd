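---
title: "Methods: simulation-validated dual-endpoint neurotoxicity screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-validated dual-endpoint neurotoxicity screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroscreen)
```

## Overview

`neuroscreen` quantifies in vitro neurotoxicity with two endpoint
families that are routinely combined in screening studies of cultured
neuronal networks:

* **network electrophysiology** — raw multi-well microelectrode-array
  (MEA) voltage recordings are turned into per-electrode spike trains and
  per-well network metrics (firing, bursting, synchrony);
* **neurite-outgrowth morphometry** — two-channel fluorescence images
  (a nuclear stain plus a neurite marker such as β-III-tubulin) are turned
  into six per-cell phenotypes describing the neurite tree.

A statistics layer normalizes longitudinal metrics to their pre-dose
baseline, classifies excitatory/inhibitory effects over dose and time,
runs the normality → homogeneity → ANOVA → Dunnett testing chain for dose
groups, and computes relative qPCR expression (ΔΔCt).

No public raw data exist for the assay this package models, so the
package carries a first-class synthetic-data module that generates MEA
recordings and neuron images with exact ground truth. Every downstream
stage is validated against that ground truth; the test suite and
`scripts/acceptance.R` re-run these validations from scratch.

## The MEA chain

### Acquisition model and spike detection

Recordings are modelled on the common screening configuration: 24-well
plates with 16 extracellular electrodes per well, 12.5 kHz sampling,
5-minute recordings, 200–3000 Hz acquisition band. Detection follows the
adaptive-threshold convention:

1. zero-phase band-pass (4th-order Butterworth, applied
   forward–backward via `signal::filtfilt`) over 200–3000 Hz;
2. per-electrode background-noise scale estimated in non-overlapping 1 s
   bins as `median(|x|) / 0.6745` — the normal-consistent median absolute
   deviation about zero. A robust estimator is essential: spikes occupy
   few samples but inflate a plain SD noticeably (the unit tests
   demonstrate this directly);
3. a spike at every local extremum whose amplitude reaches
   `threshold_multiplier` (default 6) times the local noise SD, on both
   polarities by default; events closer than a 1.5 ms dead time are merged
   to the larger extremum;
4. an absolute threshold floor (default 0.01 µV) so silent stretches
   cannot produce a zero threshold; electrodes whose noise estimate sits
   below the floor and that yield no events are flagged dead and excluded
   from well-level denominators.

Because the threshold is a multiple of the estimated noise, detection is
invariant to rescaling a trace, and per-electrode thresholds are
independent. At a signal-to-noise ratio of 10 (50 µV spikes in 5 µV
band-limited noise) the detector recovers > 99.9 % of stamped spikes with
no false positives over 4,800 electrode-seconds of pure noise; the
6×SD rule puts the threshold far into the Gaussian tail, so the
theoretical false-positive rate is negligible and the measured one is
zero.

### Network metrics

* **Mean firing rate** — spikes divided by the analysis duration (Hz).
  At the well level the default divides total spikes by duration × number
  of active electrodes (reported as 0 when none are active); a
  `well_total` mode divides by duration alone. The aggregation convention
  is configurable because figures in the screening literature do not
  always state it.
* **Bursts** — the ISI-threshold rule: a maximal run of ≥ 5 consecutive
  spikes on one electrode with every inter-spike interval ≤ 0.1 s.
  Greedy left-to-right run construction provably yields exactly the
  maximal qualifying runs; the test suite checks equivalence against a
  brute-force enumerator on 1,000 random trains. A well reports the total
  burst count across electrodes and the mean burst frequency over
  electrodes that burst at all.
* **Active electrodes** — mean firing rate ≥ 5 spikes/min, a widespread
  MEA convention (the assay literature uses the count without defining
  the criterion).
* **Synchrony index** — the mean over electrode pairs of the spike time
  tiling coefficient (STTC) computed on trains discretized at 10 ms with
  a ± 50 ms coincidence window, clipped to [0, 1]. STTC was chosen over a
  raw cross-correlogram-area ratio deliberately: the area ratio's value
  for two *identical* trains depends on firing rate and record length
  (off-peak correlogram mass grows with both), so it cannot serve as a
  normalized index, whereas STTC's chance correction pins identical
  trains at 1 and independent trains near 0 regardless of rate. The
  vendor index the assay literature cites is not published as a formula;
  this index is a documented stand-in with the same range and the same
  monotone response to synchrony, not a bit-exact clone.
* **Normalized multiinformation (NMI)** — trains are binarized in 50 ms
  bins; the multiinformation `Σᵢ H(Xᵢ) − H(X₁…X_m)` (plug-in entropies
  over observed binary patterns) is normalized by `Σᵢ H(Xᵢ) − maxᵢ H(Xᵢ)`,
  its maximum over distributions where every channel determines the
  others, so identical channels score exactly 1. At most 12 channels (the
  most active) enter the joint entropy: with 50 ms bins a 5-minute
  recording provides 6,000 pattern observations, and capping the channel
  count keeps the pattern space estimable. Independent channels score
  ≤ 0.05 at that size (estimator bias bound checked by simulation).

### The synthetic MEA generator

Activity on each electrode is a homogeneous Poisson background plus
burst events. Burst onsets come from a well-level "mother" Poisson
process: each electrode copies each mother onset with probability equal
to `synchrony_coupling` and receives independent onsets at the
complementary rate, so the per-electrode burst rate is independent of the
coupling while the coupling acts as a monotone synchrony knob. Bursts
carry 5 + negative-binomial spikes with intra-burst ISIs drawn from
`[0.5, 1] × intra_burst_isi`, guaranteeing detectability under the
ISI-threshold rule; bursts on one electrode are kept non-overlapping (a
0.11 s guard) so the ground-truth table lists exactly the bursts present.
Rendering stamps a 1.2 ms biphasic template — peak aligned to the spike
time, so detected and true times coincide — onto band-limited Gaussian
noise rescaled to the requested SD; overlapping waveforms sum linearly.

Default conditions: 0.5 Hz background, 6 bursts/min, 8.3 spikes/burst,
20 ms intra-burst ISI, coupling 0.5, 50 µV spikes in 5 µV noise (SNR 10).
Real recordings differ in ways the generator does not emulate — waveform
diversity across units, electrode drift, network bursts with propagation
delays, non-Gaussian artifact noise — so passing tests demonstrate
correctness of the measurement chain, not biological realism.

## The morphometry chain

### Segmentation

Nuclei are detected on the nuclear channel by Otsu thresholding followed
by watershed splitting on the distance transform (touching nuclei
separate). A nucleus is marker-positive when the median neurite-marker
intensity in a 3 px perinuclear ring exceeds the marker background by a
configurable factor (default 2); the marker-positive fraction is the
assay's QC statistic. Marker-positive nuclei dilated by 6 px form the
soma mask. The neurite mask is the Otsu-thresholded marker channel minus
soma interiors, with components below 8 px discarded.

### Skeleton graph and the six phenotypes

The neurite mask is thinned to a 1-px skeleton by sequential
topology-preserving thinning: border pixels are deleted one at a time
when deletion keeps the Yokoi 8-connectivity number at 1 and the pixel is
not a line endpoint, in four directional subpasses whose candidate sets
are frozen at subpass start. The directional structure matters: parallel
(Zhang–Suen-style) thinning erases 2-px-wide diagonal bands outright, and
naive sequential deletion chases along them; both failure modes were
observed during development and are guarded by a dedicated test.

Skeleton pixels become a graph (8-connectivity; step lengths 1 and √2),
reduced to a segment multigraph: junction clusters (adjacent junction
pixels merged) and free endpoints are nodes, branch-free chains are edges
with their geodesic pixel length. Spur edges shorter than 5 px are
pruned, junctions left with degree 2 are spliced, and frayed multi-stub
soma contacts are collapsed to a single root.

A root is an endpoint from which a soma is reachable *through the
neurite mask* within a 15 px walk. The walk, rather than a distance test,
is deliberate: cutting the soma out of the mask leaves a blunt stub whose
skeleton endpoint retracts several pixels during thinning, while
background always separates a stroke from foreign somas, making the walk
specific. When one segment joins two would-be roots of the same soma (a
short neurite), the end with the longer walk is demoted to an extremity.

Per soma: number of roots, nodes (junctions), extremities (non-root
endpoints) and segments (edges); total neurite length is the sum of
segment lengths; maximum neurite length is the longest root-to-extremity
geodesic. "Segment" is defined as a maximal branch-point-free path
(standard skeleton morphometry); treated-versus-control comparisons are
invariant to this choice up to monotone relabeling. Lengths are in px
(µm if a pixel size is supplied; the screening figures report relative
values, so units cancel). Well aggregates are cell-weighted means by
default with an image-weighted option.

### The synthetic image generator

Somas are discs placed with a minimum separation; each marker-positive
soma grows neurites as binary trees of straight ~3-px strokes (length
uniform in 25–60 px, bifurcation probability 0.35 up to 3 levels,
daughters at 30–50° on either side). The geometry is constructed so the
analysis is identifiable: accepted strokes keep a ≥ 1 px gap from all
existing structures (checked on the 1-px dilation of each candidate, with
the parent and sibling explicitly allowed near a shared branch point), a
keep-out zone of soma radius + 10 px keeps strokes from terminating near
foreign somas, and a bifurcation is committed only when *both* daughters
fit — otherwise the tip becomes an extremity. Every node therefore has
degree 3 and every tree satisfies `segments = nodes + extremities`, and
the stored tree is exactly the rendered one. Stroke width is ~3 px
(cross footprint) because 2-px strokes — stacked 2×2 blocks — are a
degenerate input for any thinning algorithm.

On 50 such images (4 somas each) the pipeline recovers all four count
phenotypes exactly and both length phenotypes with ≈ 5 % mean absolute
relative error; the residual length error combines the 8-connected
geodesic's ≤ 8 % overestimate of Euclidean length with root-side
truncation at the soma mask. Real images differ in ways the generator
does not emulate: curved and tapering neurites, crossing fascicles,
uneven staining, out-of-focus light. Crossing neurites in particular are
resolved arbitrarily by skeleton analysis, which is why the count
phenotypes can be exact here and only approximate on real data.

## The statistics layer

* **Baseline normalization** — relative value = value(t) / value(0 h) per
  (compound, dose, metric) series; a 0 → 0 series gives 0 (complete,
  sustained suppression) and activity after a zero baseline is undefined
  and excluded with a warning. Scale-invariance is tested.
* **Dose-group testing** — Shapiro-Wilk per group, Bartlett across
  groups, one-way ANOVA, then two-sided Dunnett many-to-one comparisons
  against the dose-0 control with flags at 0.05 and 0.01. Adjusted
  p-values come from the exact multivariate-t distribution of the maximum
  absolute statistic (`mvtnorm::pmvt` with correlation
  `ρᵢⱼ = λᵢλⱼ`, `λᵢ = 1/√(1 + n₀/nᵢ)`), handling unbalanced designs with
  no table lookup. Normality or homogeneity rejections are reported as
  flags and the parametric chain still runs — the assay literature does
  not specify a fallback, and silently switching tests would change the
  error rate. All-constant endpoints return a `degenerate` status rather
  than fabricated p-values. The null family-wise error rate is verified
  by simulation (4 groups × n = 4, 10,000 reps) to sit at 0.05 ± 0.01,
  and the implementation is cross-checked against `multcomp::glht` in the
  unit tests.
* **Effect classification** — a relative value above 1 + margin is
  excitatory, below 1 − margin inhibitory (default margin 0.2, chosen so
  ordinary sampling fluctuation of well-level relatives does not trigger
  calls; configurable). Ordered directions per dose collapse into
  trajectory labels such as `inhibition->excitation`, matching how
  time-by-dose reversals are described narratively in screening studies.
* **ΔΔCt** — `ΔCt = Ct_target − Ct_reference` per condition,
  `ΔΔCt = ΔCt_sample − ΔCt_calibrator`; the package returns −ΔΔCt so
  positive values mean enhanced expression relative to the calibrator
  (fold change `2^(−ΔΔCt)`). Replicate Ct values are averaged before
  differencing.

## Pipeline, formats, determinism

`run_config()` validates every setting (unknown keys are rejected) and
serializes to JSON; `run_pipeline()` executes simulate → detect → metrics
→ normalize → classify and the image branch → phenotypes → ANOVA/Dunnett,
writing CSV tables whose filenames carry the config hash, plus a
provenance JSON (hash, seed, package version). All randomness derives
from the config seed; a rerun reproduces outputs byte for byte. Spike
times are stored as decimal seconds with 6 fractional digits (1 µs,
comfortably below the 80 µs sampling resolution). Voltage recordings use
a documented directory container (`header.json` + a CSV matrix with one
column per electrode); images are 2-page float TIFFs with JSON
ground-truth sidecars.

The default pipeline keeps one MEA well per dose group and reports
descriptive relatives only — mirroring the practical reality that
screening studies often end with a single analysable well per group —
while the morphometry branch (4 replicates per dose) carries the formal
testing chain. The end-to-end validation of effect recovery instead uses
3 replicate wells, the replicate number stated for the MEA experiments it
models, because a single well's relative value carries the full
well-level burst-count variance of the mother-process model
(the shared onsets make well totals overdispersed relative to Poisson).

## Validation problem sizes

The acceptance tests run: the burst oracle on 1,000 random trains; the
detector at 16 electrodes × 300 s (SNR 10) plus the same amount of pure
noise; synchrony/NMI monotonicity over couplings {0, 0.2, 0.5, 0.8, 1.0}
× 20 seeds at 16 × 300 s; 50 images × 4 somas; 10,000 Dunnett null
replicates; and a rendered 3-well recovery experiment at 120 s per
timepoint. `scripts/acceptance.R` recomputes the same quantities at
moderately smaller sizes (500 trains, 8 electrodes × 120 s, 8 seeds per
coupling, 25 images, 4,000 replicates, 60 s recordings) so a full run
stays fast on one CPU; both size sets are package choices made once.

## Known limitations

* The synchrony index and NMI are principled stand-ins for vendor
  metrics whose formulas are not published; absolute values are not
  comparable across software, monotone orderings are.
* Skeleton morphometry resolves neurite crossings arbitrarily; counts on
  real images are estimates, not exact.
* The generator's dose effects are multiplicative on rates and lengths;
  real compounds can change burst structure (e.g. ISI distributions)
  without changing rates, which this scenario model does not represent.
* Spike sorting, network-burst detection across electrodes, EC50/BMD
  curve fitting and NOAEL estimation are out of scope.
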