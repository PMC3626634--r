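---
title: "Methods: segment-weighted EEG coherence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segment-weighted EEG coherence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohgraph)
```

cohgraph turns multichannel scalp EEG into weighted functional brain
networks and group-level statistics. This vignette explains the models and
estimators, the parameters that matter, the synthetic cohort generator used
to validate the chain end to end, and the numerical choices and limitations
a careful user should know about.

## The montage and distance classes

All analyses run on the standard clinical 19-electrode 10-20 montage,
represented as a schematic integer grid: columns −2…2 (negative = left),
rows 2 (fronto-polar) down to −2 (occipital), midline at x = 0. The grid is
the basis for three pair classes used by the connectivity summaries:

* **neighbor** — grid Euclidean distance d < 2. These pairs are dominated
  by volume conduction through skull and scalp and are excluded from the
  range comparison.
* **short range** — 2 ≤ d < 3.
* **long range** — d ≥ 3, i.e. 75% or more of the maximum aligned
  inter-electrode distance (4, e.g. T3–T4).

The 171 unordered pairs split into 50 neighbor, 62 short and 59 long pairs;
8 pairs are homologous inter-hemispheric (left/right mirror images such as
C3–C4) and 56 are intra-hemispheric non-midline (28 per side). These counts
are montage constants, pinned by brute-force enumeration in the tests.
Whether diagonal steps "count" is not observable from the class
definitions alone; the integer-grid Euclidean metric used here reproduces
every stated distance (neighbor exclusion, d = 2 short pairs, maximum
aligned distance 4), which is why it was fixed as the package's convention.

## Preprocessing

The fixed order is load → resample → notch → band-pass → average reference
→ segment assembly, and every step is deterministic.

* **Filters.** Both the power-line notch (default 60 Hz, configurable 50)
  and the band-pass (default 1–70 Hz) are linear-phase windowed-sinc FIR
  filters (Hamming window). The band-pass transition width is 25% of the
  lower edge; filters are applied in a single FFT-convolution pass with the
  group delay compensated exactly, so the effective response is the
  magnitude response and the phase structure — on which coherence depends —
  is untouched. In-band sinusoids are preserved within 5% and the notch
  frequency is attenuated by more than 20 dB (verified against the design
  in the tests).
* **Resampling.** Mixed source rates are harmonized by exact Fourier
  (sinc) resampling: the spectrum is truncated (an ideal anti-alias
  low-pass) or zero-padded. This is appropriate for band-limited signals
  and introduces no group delay; mild ringing at record edges is possible.
* **Average reference.** Subtracting the instantaneous channel mean is the
  reference used for all connectivity computations.
* **Segment assembly.** Recordings arrive as lists of artifact-free
  continuous segments. Segments shorter than one Welch window are dropped
  (logged), an optional amplitude veto can drop artifactual segments
  (default off), and subjects retaining less than `min_total_duration`
  (default 120 s — two minutes of awake data) are rejected with a reason
  code rather than analyzed.

Semi-automated ICA artifact rejection is deliberately out of scope: it
requires human review and belongs upstream of this package.

## The connectivity measure

Within one continuous segment, magnitude-squared coherence (MSC) is
estimated by Welch's method: 2-s Hann windows with 50% overlap (0.5 Hz
resolution — at least 8 bins in theta and 4 in each alpha sub-band), only
whole windows inside a segment, per-window demeaning, and
MSC = |Sxy|² / (Sxx·Syy) from the window-averaged spectra. MSC is bounded
in [0, 1] by construction and blind to sign and constant phase offsets.

Discontinuous segments are **never concatenated** — splicing would inject
artifactual broadband power at the seams. Instead, per-segment in-band
coherences are combined as a weighted average with weights equal to segment
length, so long artifact-free stretches dominate and short fragments
contribute negligibly. The band value is the *mean* over in-band frequency
bins (the band integral divided by bandwidth): an unnormalized band
integral would leave the value outside [0, 1] and make bands of different
widths incomparable, so the bounded form is used and documented here as a
deliberate convention. Band membership is half-open (`low ≤ f < high`) so
adjacent bands never double-count their shared edge.

The default bands are theta (4–8 Hz), lower alpha (8–10 Hz) and upper
alpha (10–12 Hz): good signal-to-noise in routine clinical EEG, and the
least contamination by muscle artifact (beta/gamma) and residual motion
(delta). The band list is configurable.

Three summaries are derived per band from the 19 × 19 matrix:

* **mean coherence** over all 171 pairs (global connectivity);
* **inter/intra ratio** — mean over the 8 homologous pairs divided by the
  mean over the 56 intra-hemispheric non-midline pairs (sensitive to
  direct, largely callosal, inter-hemispheric connectivity);
* **long/short ratio** — mean over long-range divided by mean over
  short-range pairs, neighbors excluded (the developmental-disconnection
  contrast). Zero denominators yield `NA` (flagged undefined, never
  clipped) and are excluded listwise downstream, with counts reported.

## Graphs, topology, resilience

The functional graph keeps all 171 edges, weighted by coherence — no
thresholding or binarization, so results do not depend on an arbitrary
cutoff. Edge strength maps to a functional distance d = −ln w: perfect
synchrony is distance 0, incoherence infinitely far.

* **Characteristic path length**: mean shortest-path distance over all
  pairs (Dijkstra on the −ln weights); infinite for disconnected graphs.
* **Global efficiency**: mean inverse shortest-path distance; finite for
  disconnected graphs (unreachable pairs contribute 0). A pair at distance
  exactly 0 (weight 1) contributes the capped value 1/1e−12; estimated
  coherences between distinct channels are below 1 in practice, so the cap
  is a numerical guard, not a modelling choice.
* **Clustering coefficient**: the geometric-mean (Onnela-form) weighted
  clustering, averaged over nodes, computed on the raw coherence weights —
  they are already bounded by 1, so no rescaling by the maximum weight is
  applied. Nodes with fewer than two positive-weight neighbors contribute 0
  by convention. Among the common weighted-clustering variants this is the
  one whose uniform-graph value equals the uniform weight, which gives the
  package a clean closed-form check.

On uniform complete graphs with weight c the three measures have closed
forms (L = −ln c, E = 1/(−ln c), C = c), and the implementation is checked
against an independent Floyd–Warshall brute force and a triple-loop
clustering oracle on hundreds of random graphs at 1e−12 tolerance.

**Resilience.** Attacks remove nodes with their edges and report the
global efficiency of the damaged graph relative to baseline, for
k = 1…5 removals. "Highly connected" is ranked by node *strength* (sum of
incident weights): in a fully weighted graph every node has binary degree
18, so strength is the only meaningful hub ranking. Targeted attack ranks
once on the intact graph and removes the top k simultaneously (a
sequential re-ranking mode exists behind a flag); ties break by montage
order, making the profile deterministic. Random failure averages the same
ratio over seeded uniform k-subsets (default 1000 replicates; the mean, SD
and replicate count are reported), and is checked against exhaustive
subset enumeration on small graphs. Damaged-graph efficiency is computed
over the remaining node pairs only. **Hub concentration** is the strength
of the rank-1…3 nodes divided by the total strength of all 19.

## The group model

Every derived measure y (per band) is fit by ordinary least squares to the
additive two-way model with an age covariate:

y = ȳ + β_ASD·ASD + β_TSC·TSC + β_age·age

with ASD and TSC binary group flags and age in years. "Generalized linear
model" here means the Gaussian identity-link case: the model is
linear-additive, so OLS with coefficient t-tests (residual df = n − 4) is
the exact fit. Coefficient tests are two-sided — no direction is assumed
for the group effects; the one exception is the callosal-disconnection
validation, which is a one-tailed pooled-variance two-sample t-test
(alternative: the disconnection group's inter/intra ratio is *lower*),
because there the direction is the hypothesis. The additive model cannot
express non-additive subgroup structure; the post-hoc subgroup t-tests
(e.g. ASD-with-TSC versus ASD-without-TSC) probe exactly that, and under a
purely additive truth with no other-condition effect they stay at the
alpha level.

No multiple-testing correction is applied across the measure × band ×
condition grid: the measures are strongly correlated and a principled
correction would require their joint distribution, so the output labels
all p-values as raw. Covariates that are constant in a given table (a
single-age cohort, an absent group factor) are dropped and recorded rather
than made errors — in the extreme case the model degrades exactly to a
pooled two-sample t-test — while genuinely aliased designs (e.g. two
identical flags) are errors naming the collinearity. Demographics use
Fisher's exact test for binary contrasts and two-sample t-tests for age.

## The synthetic cohort generator

No clinical recordings ship with the package; instead a generator produces
cohorts with known injected structure so that every downstream stage is
testable. Each channel mixes band-limited latent Gaussian sources,
synthesized spectrally (random complex coefficients on in-band FFT bins):
their in-band spectra are flat, so the expected in-band MSC of every pair
is a **closed-form** function of the mixing weights
(`expected_coherence()`), which is how the defaults were calibrated and
how tests check monotonicity without Monte-Carlo.

* **One network-wide source** carries long-range coherence. Its
  per-electrode projection is a fixed signed (dipole-like) pattern —
  anterior rows positive, posterior negative — centered to zero mean, so
  the average reference passes it through unchanged (a constant-sign
  topography would be cancelled exactly). Sign patterns are invisible to
  MSC.
* **Five regional sources** (four scalp quadrants + a central region) with
  Gaussian membership weights (width `region_width`, default 1 grid unit)
  carry short-range coherence that decays with distance through membership
  overlap. Each region's per-channel phases are fixed so its weighted
  phasor sum is zero: the average reference sees no common mode from it.
  Constant per-pair phase offsets do not affect MSC.
* **Per-channel sensor noise**, band-limited to the same 4–12 Hz source
  band, so in-band signal-to-noise is exactly the gain ratio.
* **Hubs** (Fz, Cz, Pz): amplified network-wide projection (×`hub_gain`,
  default 2.5) and sensor noise divided by √`hub_gain` — high-SNR,
  strongly coupled nodes that become the top-strength hubs of the graph.

Mixing is fixed within a segment (the stationarity assumption of
coherence); sources are redrawn per segment; segment lengths and counts
are drawn uniformly from configurable ranges, deliberately exercising the
length-weighted estimator.

Group effects act multiplicatively on gains and therefore approximately
additively on the derived measures at these effect sizes:

* **TSC** scales all shared gains by `beta_tsc_global` (default 0.75):
  global underconnectivity that also degrades path length, clustering and
  efficiency.
* **ASD** scales the network-wide gain by `beta_asd_longshort` (default
  0.7) and the regional gains by `2 − beta_asd_longshort`: the long/short
  ratio falls while mean coherence moves little. ASD also shrinks the hub
  excess by `hub_flattening_asd` (default 0.25): hub concentration falls
  and resilience to targeted attack rises.
* **Age** increases all shared gains by `beta_age` per year (default 1%),
  the maturational trend the ANCOVA's covariate absorbs.
* **Callosal disconnection** (`acc = TRUE`) replaces the network-wide
  source by independent left/right copies (midline channels receive both):
  homologous inter-hemispheric coherence collapses to the local-kernel
  floor while intra-hemispheric structure is untouched.

A per-subject log-normal jitter (`subject_sd`, default 0.1) on the shared
gains provides between-subject variability. Default cell sizes are
46/29/16/14 (control / TSC-only / ASD-only / TSC+ASD) with ages uniform on
1–16 years. The effect-size defaults were calibrated once, at the
covariance level, to make recovery checks meaningful at these cell sizes;
they are not claimed to match any clinical effect size.

What the generator does **not** emulate: eye-blink/muscle/motion
artifacts, epileptiform discharges, volume-conduction head geometry, 1/f
background spectra outside the source band, non-stationarity within
segments, and realistic inter-subject topographic variability. Passing the
package's tests therefore demonstrates that the estimators and statistics
recover known structure from signals with EEG-like second-order
statistics — not that any clinical result would replicate.

## Numerical choices and degenerate inputs

* Welch windows: whole windows only, per-window demeaning, Hann taper;
  MSC clamped into [0, 1] against rounding; a channel pair with zero power
  at a frequency reports 0 there.
* Distances: w = 0 → infinite distance (edge absent); w = 1 → distance 0;
  efficiency contributions capped at 1/1e−12.
* Ties in strength rankings break by montage order; all stochastic steps
  (random failure, cohort generation) take explicit seeds, per-subject
  seeds derive from the cohort seed by a counter-based substream, so
  results are independent of cohort order and bit-reproducible.
* EDF support is a minimal reader/writer for continuous 16-bit files with
  a common sampling rate — enough to round-trip synthetic cohorts and read
  plain clinical exports; EDF+D (discontinuous) files and mixed
  per-signal rates are rejected with clear errors. Physical scaling uses a
  symmetric per-signal range; quantization error is range/32767.

## Problem sizes used by the checks

The test-suite and the acceptance script run the full chain at reduced
problem sizes chosen as the package's own validation conditions: 128 Hz
sampling, 2–3 segments of 20–30 s per subject for cohort-level checks
(graph oracles use hundreds of random graphs up to 10 nodes; the
coherence oracle uses a 90-s segment, ~90 Welch windows; the end-to-end
cohort uses the full 105-subject design with 25 random-failure
replicates). Estimator properties do not depend on the sampling rate for
band-limited sources, and every check's tolerance is stated next to the
check itself.

## Known limitations

* Coherence is sensitive to volume conduction; the neighbor-pair exclusion
  mitigates but does not remove it. Phase-lag-type measures are out of
  scope.
* The 19-electrode montage gives coarse, variable correspondence between
  electrodes and functional regions; graph nodes are electrodes, not
  sources.
* The additive ANCOVA cannot represent interaction structure; use the
  post-hoc subgroup tests alongside it.
* The EDF layer is intentionally minimal (no annotations, no EDF+D).
* Random-failure profiles are Monte-Carlo estimates; their SE scales as
  sd/√replicates and the replicate count is always reported.
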