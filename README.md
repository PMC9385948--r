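# ephysclust

Unbiased electrophysiological classification of adult spinal Shox2/Chx10
interneurons from whole-cell patch-clamp recordings.

Spinal interneurons marked by the transcription factor Shox2 are
heterogeneous; co-expression of Chx10 splits them into subpopulations with
distinct locomotor roles. `ephysclust` implements a complete, reproducible
pipeline for subdividing such neurons by their membrane properties alone:

1. **Feature extraction** — rule-based measurement of 12 passive/active
   properties from current- and voltage-clamp sweeps: resting potential
   E<sub>m</sub>; input resistance R<sub>in</sub> (slope of steady-state
   ΔV vs ΔI over hyperpolarizing steps); time constant τ (time to 63% of
   the maximal subthreshold deflection); capacitance
   C<sub>m</sub> = τ/R<sub>in</sub>; rheobase on a 2 pA grid; AP threshold
   (first dV/dt ≥ 10 mV/ms before the peak); AP half width at the
   threshold–peak midpoint; fast and slow AHP durations and the normalized
   fAHP amplitude (threshold − trough)/(peak − threshold); persistent
   inward current onset PIC<sub>on</sub> from the leak-subtracted current
   on a 28 mV/s voltage ramp; and the F/I slope over 1–49 pA steps — plus
   the QC exclusions (E<sub>m</sub> > −40 mV or AP peak < 0 mV).
2. **Firing taxonomy** — tonic, initial doublet (initial ISI < 40 ms),
   initial burst (≥ 3 spikes > 25 Hz then silence/irregular firing), and
   delayed types, assigned by an explicit precedence rule.
3. **Feature reduction** — a Pearson correlation screen (p < 0.001)
   that removes redundant properties down to the six-variable panel
   {E<sub>m</sub>, C<sub>m</sub>, fAHP duration, fAHP amplitude,
   PIC<sub>on</sub>, F/I slope}, then z-scoring and PCA.
4. **Dual clustering** — best-of-restarts Lloyd k-means with the number of
   clusters chosen by a silhouette-elbow (plateau) rule over k = 2–8, and
   hierarchical clustering with the metric/linkage pair selected by the
   cophenetic correlation coefficient and the tree cut just below the
   maximum inconsistency coefficient.
5. **Cluster statistics** — Shapiro–Wilk-gated t/Mann-Whitney and
   ANOVA+Tukey / Kruskal–Wallis+Dunn comparisons, chi-square composition
   tests, exact binomial enrichment per cluster, and a k×H correspondence
   table with min-denominator overlap percentages.

Because the reference cohort's raw data are not deposited, the package
includes a first-class synthetic-data module: template-based trace
synthesis for the four firing archetypes (with exact ground truth for
extraction testing) and feature-table generation from the published
per-cluster mean ± SD parameters of the 171-neuron cohort (143 Shox2,
28 Chx10), packaged in `inst/extdata/reference_cohort.json`.

## Worked example

```r
library(ephysclust)

# synthesize a doublet-firing neuron and extract its features
rec <- synthesize_recording(archetype_catalog()$initial_doublet,
                            seed = 1, neuron_id = "cell_01")
extract_features(rec)[c("neuron_id", "em_mv", "rin_mohm", "tau_ms",
                        "cm_pf", "rheobase_pa", "ap_threshold_mv",
                        "firing_type", "qc_pass")]
#>   neuron_id em_mv rin_mohm tau_ms cm_pf rheobase_pa ap_threshold_mv
#> 1   cell_01   -50    800.9   25.8 32.21          18          -35.49
#>       firing_type qc_pass
#> 1 initial_doublet    TRUE

# full pipeline on the published-composition synthetic cohort
tab <- simulate_reference_cohort(generator_config(seed = 42))
report <- run_pipeline(tab, pipeline_config(seed = 42, restarts = 50))
report
#> <run_report>
#>   neurons: 171 (0 excluded)
#>   screen: 10 retained (em_mv, rin_mohm, cm_pf, rheobase_pa, ...)
#>   k-means: chosen k = 2
#>   hierarchical: euclidean/average, 14 clusters
#>   correspondence: 14 combinations, 100% of neurons in high-overlap cells

report$enrichment
#>   cluster   n n_target proportion p_value
#> 1       1 153      125      0.817   0.778
#> 2       2  18       18      1.000   0.040
```

The extracted values match the archetype's ground truth (R<sub>in</sub>
800 MΩ, τ 28 ms, rheobase 18 pA, threshold −36 mV) within the documented
extraction tolerances. On this independently-drawn cohort the screen keeps
10 of 12 features (with independent draws only mixture-induced
correlations exist); on the dependency-structured fixture
(`dependency_fixture()`) it reproduces the published six-variable
reduction. The enrichment table flags the pure-Shox2 cluster
(p = 0.04 here; the analogous published cluster of 23 Shox2 neurons gives
(143/171)²³ ≈ 0.016).

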