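---
title: "Classifying spinal interneurons from patch-clamp properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying spinal interneurons from patch-clamp properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adult spinal Shox2 interneurons are heterogeneous, and co-expression of the
transcription factor Chx10 splits them into subpopulations with different
roles in locomotor circuits. `ephysclust` implements an unbiased,
electrophysiology-only route to that subdivision: extract a standard panel
of 12 passive and active membrane properties from whole-cell patch-clamp
recordings, remove redundant properties with a Pearson correlation screen,
and classify the neurons three ways — by firing pattern, by silhouette-elbow
k-means, and by hierarchical clustering with data-driven metric/linkage
selection — then compare the partitions statistically.

Because per-neuron raw data for the reference cohort (171 neurons: 143
Shox2, 28 Chx10) are not publicly deposited, the package ships a
synthetic-data module that emulates the study conditions at two levels:
trace-level recordings with exact ground truth, and feature-level tables
drawn from the published per-cluster mean/SD parameters. Every stage of the
pipeline is validated against these generators and against independent
brute-force oracles.

## The 12 properties and their measurement rules

All features carry their unit in the column name
(`em_mv`, `rin_mohm`, `tau_ms`, `cm_pf`, `rheobase_pa`, `ap_threshold_mv`,
`ap_halfwidth_ms`, `fahp_duration_ms`, `sahp_duration_ms`,
`fahp_amplitude_norm`, `pic_on_mv`, `fi_slope_hz_per_pa`).

* **Resting potential** (E~m~): mean voltage over the resting epoch.
* **Input resistance** (R~in~): least-squares slope of steady-state voltage
  deflection against injected current over the hyperpolarizing steps.
* **Time constant** (τ): time to 63% of the maximal deflection on a
  subthreshold depolarizing step.
* **Capacitance** (C~m~): computed as `Cm = tau / Rin` in consistent units
  (pF = ms/MΩ × 1000). The conventional formula is sometimes quoted with
  the ratio inverted; the dimensionally consistent form is used here and
  logged, and it reproduces the printed order of magnitude (τ ≈ 42 ms,
  R~in~ ≈ 700 MΩ → C~m~ ≈ 60 pF).
* **Rheobase**: smallest step of a 2 pA grid that elicits a spike. The
  acquisition convention allows 2–3 pA; the grid is fixed at 2 pA for
  determinism.
* **AP threshold**: voltage at the first sample where dV/dt exceeds
  10 mV/ms before the peak ("first deflection"; the conventional range is
  10–20 mV/ms, and the slope is configurable).
* **AP half width**: width at the voltage midway between threshold and
  peak, with linear interpolation of the two crossings.
* **fAHP**: trough within 10 ms after the downward threshold re-crossing.
  Duration is threshold-time → trough-time; amplitude is
  (threshold − trough)/(peak − threshold), i.e. normalized by the AP
  amplitude measured from threshold (the peak−trough convention is
  available).
* **sAHP**: smoothed (2 ms moving average) minimum in the 10–300 ms
  window after the threshold crossing, truncated before the next spike.
  For initial-doublet and initial-burst cells both AHPs are measured from
  the last spike of the initial group.
* **PIC onset**: on a slow (28 mV/s) voltage-clamp ramp, a leak line is
  fit to the first 30% of the I–V relation; onset is the command voltage
  where the leak-subtracted current first falls below
  −max(3σ~noise~, 1 pA) and stays below for ≥ 20 ms. The 30%/3σ/20 ms
  constants are implementation choices (the measurement rule itself does
  not quantify them); the 1 pA floor keeps the criterion meaningful on
  noise-free synthetic traces.
* **F/I slope**: least-squares slope of spike count over the 1-s step
  against current over the 1–49 pA (3 pA increment) family.

QC follows the study's exclusions: a neuron fails when its resting
potential is more depolarized than −40 mV or any detected AP peak does not
reach 0 mV. Missing protocol elements propagate as explicit `NA` markers,
never zeros.

## Firing-pattern taxonomy

`classify_firing()` applies a fixed precedence: **delayed** when the
first-spike latency is ≥ 200 ms; **initial burst** when ≥ 3 opening spikes
exceed 25 Hz instantaneous rate and the remainder of the step is silent or
irregular; **initial doublet** when the initial interspike interval is
< 40 ms and firing continues regularly at a lower steady rate; **tonic**
when firing spans the step regularly; otherwise **unclassified**. The
40 ms and 25 Hz thresholds are the published ones. The 200 ms delay cutoff
and the regularity criterion (CV of ISIs over the final 500 ms < 0.5) are
not quantified in the source taxonomy; both are exposed as configurable
parameters with these defaults, chosen so that delayed exemplars with
multi-hundred-ms latencies and visibly irregular post-burst firing are
captured. The precedence order makes the categories mutually exclusive and
exhaustive, which a property-style test verifies over randomized spike
trains.

## Feature reduction

The correlation screen computes all pairwise Pearson correlations with
two-sided t-distribution p-values and iteratively removes features until no
retained pair is correlated at α = 0.001 (the threshold used for "highly
correlated" shading in the reference analysis; 0.01 is available). Each
iteration takes the currently most significant pair and drops its
lower-priority member. The default keep-priority ranks the six published
non-redundant properties (E~m~, C~m~, fAHP duration, fAHP amplitude,
PIC~on~, F/I slope) above all others, making the published reduction
reproducible; without a priority list, the member with the larger mean |r|
against the remaining features is dropped. Standardization (z-scoring with
sample SD, configurable to population SD) precedes PCA, which is an
ordinary eigendecomposition of the standardized data; per-group ellipsoid
summaries (mean ± SD of the first three component scores) support the
usual 3-D visualization.

## Clustering

**k-means.** Lloyd's algorithm with squared-Euclidean objective on the
standardized retained features, initial centers drawn uniformly from data
points without replacement. For each k in 2–8, 100 restarts (the analysis
convention of iterating the algorithm many times), keeping the restart
with the highest mean silhouette. The number of clusters is the smallest
k after which no larger k improves the best mean silhouette by ≥ 0.01 —
an explicit "plateau" formalization of the visual elbow-on-silhouette
rule. Silhouettes use Euclidean distance by default; the per-iteration
within-cluster sum of squares trace is retained so the monotone descent
of the objective is testable.

**Hierarchical.** Dendrograms are built for every combination of
{euclidean, cosine, correlation, cityblock} × {average, complete, single,
weighted} and the combination maximizing the cophenetic correlation
coefficient is selected — the criterion that picked cosine/average in the
reference analysis. The tree is cut with the inconsistency coefficient:
for each link, the links within depth 2 below it (the conventional depth)
are collected, and the inconsistency is the standardized excess of the
link's height over their mean. The cut threshold is
max(inconsistency) × (1 − 10⁻⁶) — "just below the maximum" — and a link
survives only if it and all its descendants are below the threshold; when
no link is inconsistent the tree stays whole. The exact cutoff semantics
of the original analysis environment are not recoverable from its
description, so this rule is documented and both the depth and the cutoff
are configurable.

**Statistics.** Cluster characterization is normality-gated: Shapiro–Wilk
at 0.05 per group, then unpaired t-test / one-way ANOVA with Tukey
post-hoc on the parametric branch or Mann–Whitney / Kruskal–Wallis with
Dunn's post-hoc (Bonferroni-adjusted z-tests on mean ranks with tie
correction) on the nonparametric branch. Composition differences use the
Pearson chi-square without continuity correction, population enrichment
per cluster uses the exact binomial tail against the cohort-wide base
proportion (one-sided toward enrichment by default; the published k1
result corresponds to (143/171)²³ ≈ 0.016), and the k×H correspondence
reports per-cell overlap as 100 × count / min(row size, column size) — the
only denominator under which 100% is attainable for unequal clusters —
with cells above 80% flagged. No correction across the 12 features is
applied by default, mirroring the reference analysis; a family-wise switch
exists. The repeated-measures ANOVA mentioned alongside these tests is not
applicable to independent clusters and is not implemented.

## The synthetic-data generator

**Feature level.** Each cluster-by-population subgroup is a diagonal
Gaussian with the published mean and SD per feature (no covariances are
published, so independence is the only parameterization-faithful choice).
`simulate_reference_cohort()` emits the exact published composition
(Shox2 23/7/56/57 and Chx10 0/4/12/12 across k1–k4). Draws are plain
Gaussians by default: truncating at physical bounds would shift means
(e.g. +2.3 pF on the k1 capacitance) away from the published moments the
generator exists to match, so truncation and a moment-matched lognormal
for strictly positive features are opt-in (`truncate`,
`positive_model = "lognormal"`).

**Redundancy structure.** For screen testing, `dependency_fixture()`
draws the six retained features independently from the pooled
cohort-level distribution (law-of-total-variance pooling of the published
subgroups; positive features lognormal) and derives the six redundant
ones: R~in~ = κ/C~m~^0.6^ × lognormal noise (an imperfect inverse size
scaling — a perfect 1/C~m~ would make τ = R~in~C~m~ a constant times noise
and hence uncorrelated with everything, defeating the screen), τ =
R~in~C~m~, rheobase = ½(threshold − V~hold~)/R~in~ × lognormal, threshold
= PIC~on~ + 12 mV + noise, half width = 0.22 × fAHP duration + noise, and
sAHP duration = 110 − 100 × F/I slope + noise. Noise magnitudes put every
induced pairwise correlation far below p = 10⁻⁴ at n = 171. A pooled
(single-population) base is used because the 7-subgroup mixture itself
induces p < 0.001 correlations *between* retained features (the k1
cluster is simultaneously high-C~m~ and depolarized-PIC~on~), which no
screen could leave intact.

**Trace level.** Recordings are template-based, not conductance-based:
spike times follow archetype rules (regular tonic trains; a < 40 ms
doublet then 3.9 Hz steady firing; ≥ 3 spikes at 40 Hz then silence; a
400 ms delayed onset) and a stereotyped AP waveform — slow 5 mV/ms
approach to threshold, triangular spike whose width at the midpoint level
equals the nominal half width, linear descent to the fAHP trough, fast
recovery, and an alpha-function sAHP with its minimum at the nominal sAHP
latency — rides on an exact RC passive response. An initial doublet/burst
is followed by a single cumulative sAHP rather than one per spike, so the
waveform under the measured (last-of-group) spike is undistorted.
First-spike latencies sit at ≥ 5 membrane time constants (130 ms; 400 ms
for the delayed archetype) so spikes ride a settled baseline and the
attached ground truth is exact; noise-free round-trip tolerances are
E~m~ ± 0.1 mV, R~in~ ± 2%, τ ± 5%, threshold ± 1 mV, half width ± 0.1 ms,
fAHP duration ± 0.3 ms, normalized fAHP amplitude ± 0.03, sAHP duration
± 15%, PIC~on~ ± 1 mV at 20 kHz sampling. The voltage-clamp ramp is a
leak line plus an inward deflection of 3 pA/mV beyond the nominal PIC
onset.

What the generator does **not** emulate: conductance dynamics, synaptic
noise, temperature effects, electrode artifacts, and any feature
covariance beyond the explicit redundancy formulas. Tests passing on these
fixtures therefore validate the measurement rules, the reduction, and the
clustering machinery — not robustness to real-rig pathology.

## What the fixtures can and cannot reproduce

Three published quantities are recomputed exactly or near-exactly: the
firing-type percentages from the printed counts, the 171/143/28 fixture
composition, and the six-variable reduction. Parameter recovery holds: the
grand mean of the k1 capacitance over repeated draws stays within ± 3 pF
of 148.3 pF, and k-means at k = 4 recovers the generative labels of the
half-SD fixture with median ARI ≥ 0.9 (≥ 0.4 at unscaled SDs on the
4-component pooled mixture).

The k-selection outcome is different. On the half-SD diagonal-Gaussian
fixture the best-of-restarts mean-silhouette curve is maximal at k = 2 and
declines monotonically, so the plateau rule selects k = 2 — not the
published k = 4 — and the corresponding acceptance check records this
honestly. The geometry explains it: the two dominant clusters (k3, k4;
80% of neurons) differ mainly along two of the six standardized axes by
about 2 within-cluster SDs, so merging them costs little mean silhouette
while the extra splits at k = 4 add none. The module's own tests show the
elbow behaves correctly when structure is present (it selects 4 on
clearly separated 4-Gaussian data, and does so on the published fixture
once SDs are scaled to ≈ 0.25–0.35); recovering the published selection
from printed moments alone would require the real data's covariance
structure, which is not available.

## Problem sizes and determinism

The test suite and the acceptance script run at the analysis scale:
171 neurons, k = 2–8 with 100 restarts per k, 20 generator seeds for the
k-selection majority, 200 draws for moment recovery, and 200 noisy
replicates per firing archetype at 20 kHz (classification uses the
suprathreshold sweep alone, full protocols where extraction is tested).
Every stochastic entry point takes an explicit integer seed, restores the
caller's RNG state, and is bit-reproducible: the same seed and
configuration yield byte-identical pipeline outputs.

## Known limitations

* Diagonal Gaussians cannot carry the covariance that shaped the
  published silhouette curve; see above.
* The inconsistency-cut semantics are one defensible reading of a
  loosely specified rule; different readings change the hierarchical
  cluster count (which is why the count itself is not asserted).
* Dunn's post-hoc z-tests use the normal approximation; very small groups
  (< 3) are excluded from normality gating and force the nonparametric
  branch.
* The trace synthesizer is a measurement-validation instrument, not a
  biophysical model; its parameters are plausible for adult lumbar
  interneurons but are not fitted to any recording.
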