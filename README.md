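# genostorm

Trajectory analysis of the post-trauma "genomic storm" in peripheral-blood
neutrophil expression profiles.

Severe blunt trauma with hemorrhagic shock perturbs a majority of the
circulating-leukocyte transcriptome at once. Patients of advanced age
(≥55 years) respond differently from the young: their neutrophils mount a
*blunted* early transcriptomic response (days 0.5–1 after injury) and then
*fail to return to baseline* in the sub-acute period (day 4 onward), while
younger patients respond strongly early and recover. `genostorm` is for
researchers analysing this kind of longitudinal expression cohort: it
quantifies each patient's total transcriptomic deviation from a
healthy-control baseline and provides the surrounding selection,
classification and cohort-comparison machinery.

## The core statistic

For a patient expression vector *e* and a healthy-control baseline with
per-probe mean *M<sub>i</sub>* and variance *V<sub>i</sub>*, the
distance-from-reference (DFR) score is

    DFR = Σ_i (e_i − M_i)² / V_i

summing over the working probe set (the whole array, the trauma-responsive
selection, or a user-supplied gene panel). Up- and downregulation accumulate
alike; the score is zero exactly at baseline, additive over disjoint probe
subsets, and conventionally displayed ×10⁻³. Around it the package
implements:

* per-probe one-way F-tests with Benjamini–Hochberg adjustment and signed
  fold-change filtering (`select_trauma_responsive()`, `restrict_gene_set()`),
* leave-one-out cross-validated nearest-centroid classification with a
  Monte Carlo label-permutation null (`loocv_misclassification()`,
  `monte_carlo_label_permutation()`),
* aged–young matched-pair construction and trajectory group comparisons:
  ANOVA + Student–Newman–Keuls, Kruskal–Wallis, Holm–Šidák (`match_pairs()`,
  `anova_newman_keuls()`, ...),
* an age-by-time linear model for longitudinal plasma cytokine panels
  (`cytokine_glm()`) and univariate clinical contingency statistics
  (`contingency_stats()`),
* a synthetic-cohort generator encoding the age-dependent storm
  (`simulate_cohort()`, `simulate_cytokines()`), so the whole pipeline is
  testable without clinical data.

## Worked example

Simulate a default cohort (17 controls, 17 aged and 17 young complicated
patients sampled at days 0.5, 1, 4 and 7 with dropout), build the control
reference, and summarise genome-wide DFR trajectories:

```r
library(genostorm)

sim <- simulate_cohort(simulation_params(seed = 7))
ref <- build_reference(sim$matrix, sim$truth$control_ids)
dfr_trajectories(sim$matrix, sim$meta, ref)
#>  cohort timepoint_days mean_score sd_score  n               display
#>    aged            0.5   1554.160 68.86595 17 1.554 ± 0.069 (x10^3)
#>    aged            1.0   1528.834 77.50982 15 1.529 ± 0.078 (x10^3)
#>    aged            4.0   1819.518 90.30218 10 1.820 ± 0.090 (x10^3)
#>    aged            7.0   1620.596 57.74697  9 1.621 ± 0.058 (x10^3)
#>   young            0.5   2310.747 85.45223 17 2.311 ± 0.085 (x10^3)
#>   young            1.0   1960.314 79.70871 15 1.960 ± 0.080 (x10^3)
#>   young            4.0   1356.014 64.51439 12 1.356 ± 0.065 (x10^3)
#>   young            7.0   1178.667 45.01860 11 1.179 ± 0.045 (x10^3)
```

The young cohort is more perturbed than the aged at days 0.5 and 1, the
ordering crosses over by day 4 (aged 1.820 vs young 1.356, ×10³), and the
young trend back toward baseline — the qualitative signature the generator
encodes. Is the day-4 difference significant?

```r
day4 <- merge(dfr_scores(sim$matrix, ref), sim$meta, by = "sample_id")
day4 <- day4[!is.na(day4$timepoint_days) & day4$timepoint_days == 4, ]
anova_newman_keuls(day4$score, day4$age_group)
#> GroupComparison (newman-keuls): omnibus F = 196.7, p = 8.271e-12
#>   1 pairwise rejection(s) at alpha = 0.05
```

`run_pipeline(pipeline_config())` chains every stage (selection → DFR →
LOOCV + permutation → group comparisons) and can write a TSV/JSON artifact
bundle with a manifest of all seeds and thresholds.

## Documentation

The methods vignette (`vignettes/genostorm-methods.Rmd`) describes the
model and its assumptions, the synthetic generator's defaults and what they
do and do not emulate, numerical safeguards (variance flooring, the
estimated-baseline DFR inflation factor), and known limitations.
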