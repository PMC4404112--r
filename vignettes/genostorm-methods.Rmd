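---
title: "Quantifying the post-trauma genomic storm: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the post-trauma genomic storm: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genostorm)
```

## The scientific problem

Severe blunt trauma with hemorrhagic shock triggers a massive, genome-scale
reorganisation of circulating-leukocyte gene expression — a "genomic storm"
affecting a majority of the transcriptome — in which pro-inflammatory (SIRS)
and compensatory anti-inflammatory (CARS) programmes run simultaneously.
Clinically, patients of advanced age (55 years and older) fare worse after
comparable injuries, and their peripheral neutrophils (PMNs) show a
distinctive temporal expression pattern: a *blunted* early response
(consistent with immuno-senescence) followed by a *failure to return to
baseline* in the sub-acute period, while younger patients respond more
strongly at 12–24 hours and then trend back toward healthy-control
expression by day 4.

`genostorm` implements the quantitative machinery needed to detect and
summarise this signature: trauma-responsive probe selection, a scalar
distance-from-reference (DFR) perturbation score and its cohort
trajectories, cross-validated class prediction with a permutation null,
matched-pair construction, trajectory group comparisons, a longitudinal
age-by-time cytokine model, and univariate clinical contingency statistics
— all exercised against a synthetic-cohort generator so that every stage is
testable without access to clinical data.

## The DFR score

For patient expression vector $e$ and a healthy-control baseline with
per-probe mean $M_i$ and variance $V_i$,

$$\mathrm{DFR} = \sum_i \frac{(e_i - M_i)^2}{V_i}.$$

Every probe contributes its squared standardized deviation, so up- and
downregulation accumulate alike; the score is non-negative, zero exactly at
baseline, and additive over disjoint probe subsets. A natural-log variant
(log of the sum) exists, but reported values follow the no-log convention;
the conventional $\times 10^3$ divisor is applied only when formatting.

Two numerical choices matter:

* **Variance floor.** Probes with near-zero control variance would dominate
  the sum. `build_reference()` raises variances below the 10th percentile
  of the positive per-probe variances to that percentile. The floor is a
  standardization safeguard; set `floor_quantile = 0` to floor only
  exactly-zero variances.
* **Estimated-baseline inflation.** With the baseline *estimated* from $n$
  controls, the per-probe expectation for a null sample is not 1 but
  $\frac{n-1}{n-3}\left(1 + \frac{1}{n}\right)$
  (the $(e_i - \hat M_i)^2$ numerator gains a $1 + 1/n$ factor, and
  $E[1/\hat V_i]$ contributes $\frac{n-1}{(n-3)V_i}$). With 20 controls
  that is $\approx 1.17$ per probe. The test suite asserts the empirical
  mean is within three standard errors of this corrected value; treating a
  genome-wide DFR near `n_probes` as "unperturbed" is only correct for
  large control groups.

The probe universe is an explicit parameter everywhere: genome-wide scores
default to all probes passing reference flooring, while gene-panel scores
(e.g. a previously published outcome-predictive panel restricted to the
genes actually responsive in PMNs) use the output of `restrict_gene_set()`.

## Probe selection

`select_trauma_responsive()` combines a per-probe one-way ANOVA F-test
across the sample groups with a fold-change filter versus the control
group. Two readings of the significance threshold circulate in this type of
analysis — raw $P < 0.001$ and a false-discovery-adjusted $P < 0.001$ — so
both are supported through `use_adjusted`; the default is the adjusted
(Benjamini–Hochberg) reading, and the mode is recorded in the result.
Whether controls form a third F-test group is likewise left to the caller:
the default is to include every provided group. Fold changes are computed
on linear-scale ratios of per-group geometric means ($2^{\Delta \log_2}$)
and reported with the signed convention in which $-3.1$ means 3.1-fold
down: magnitudes are never inside $(-1, 1)$. Probes whose within-group mean
square is exactly zero have it floored at the same quantile rule as
reference variances; a probe constant across all samples gets $F = 0$,
$p = 1$.

## Classification

The classifier behind the LOOCV misclassification estimate is deliberately
simple and pluggable: nearest centroid on the working probe set with a
deterministic lexicographic tie-break. Probe selection is re-run inside
every leave-one-out fold by default — selecting on the full data first and
cross-validating afterwards biases the rate downward, and the test suite
demonstrates that bias on null data. The Monte Carlo null permutes sample
labels (preserving class sizes), re-runs the entire pipeline per
permutation, and reports the add-one-smoothed p-value
$(1 + \#\{\text{permuted} \le \text{observed}\})/(1 + n_{\mathrm{perm}})$,
which is never zero and is valid under label exchangeability.

## Cohort statistics

* **Matched pairs.** Candidate aged–young pairs must agree exactly on
  gender, 28-day survival and the sampled-timepoint set; among candidates
  the summed per-region |AIS difference| is minimised greedily (cheapest
  candidate first, ties by ascending patient id). Greedy matching is a
  deliberate choice — the matching criteria, not an optimization algorithm,
  are the substance — and it is verified against an exhaustive assignment
  oracle on small instances in the tests.
* **Trajectory comparisons.** One-way ANOVA with Student–Newman–Keuls
  step-down pairwise comparisons on the studentized range (`ptukey`);
  a non-rejected stretch blocks nested comparisons, and with two groups
  the decision coincides with the pooled t-test. Kruskal–Wallis and
  Holm–Šidák are provided for the non-parametric and many-comparison
  settings; Holm–Šidák is implemented directly (the step-down Šidák
  criterion $1-(1-\alpha)^{1/(m-j+1)}$), since standard adjustment menus
  offer Holm–Bonferroni instead.
* **Cytokine model.** Longitudinal dropout (discharge or death) makes the
  design unbalanced, so per-analyte comparisons use a fixed-effects linear
  model on log concentrations with categorical age and categorical time,
  tested with type-II F statistics (`car::Anova`). Time is categorical at
  the sampling grid — the question is whether age and/or time drive the
  differences, not a slope estimate. No repeated-measures covariance
  structure is fitted; with one sample per patient-timepoint and strong
  between-patient dropout this is a pragmatic simplification, and a known
  limitation. An interaction term is available via `include_interaction`.
* **Contingency statistics.** Fisher's exact test on 2×2 collapses
  (category vs rest), sample odds ratios with the Haldane half-count
  correction at zero cells, and percent formatting at the precision of the
  source table so worked examples are string-stable.

## The synthetic-cohort generator

`simulate_cohort()` is first-class, tested code that defines the study
conditions for every property test. Its defaults encode the qualitative
structure of the age-dependent storm:

| parameter | default | rationale |
|---|---|---|
| `n_probes` | 1000 | desk-scale stand-in for an array |
| `n_controls` | 17 | healthy-control group size of the motivating cohort |
| `n_patients_per_cell` | 17 | matched complicated aged/young pairs |
| `timepoints_days` | 0.5, 1, 4, 7 | acute and sub-acute sampling grid |
| `fraction_responsive` | 0.75 | a storm touching >75% of the transcriptome |
| `amplitude` (young) | 1.2, 1.0, 0.5, 0.25 SD | strong early response, recovery |
| `amplitude` (aged) | 0.7, 0.7, 0.9, 0.8 SD | blunted early, persistent late |
| `noise_sd` | 1 control SD | residual within-cohort variability |
| `dropout_hazard` | 0.15 | monotone loss by discharge/death |

Amplitudes are mean absolute probe shifts in control-SD units with a sign
fixed per probe (not per patient), so cohort centroids separate coherently,
mirroring coherent up/down regulation of real trauma-responsive genes.
Control baselines come from hyperpriors — $M_i \sim N(8, 2^2)$ log2 units,
$V_i$ scaled-inverse-$\chi^2$ with mean 0.25 ($\nu = 10$) — whose exact
values are irrelevant downstream because the DFR standardizes them out. No
effect-size scale in SD units is available from the clinical literature for
this signature, so the amplitude defaults are tuned to reproduce
*orderings* (young > aged on days 0.5 and 1, aged > young on day 4), not
printed DFR magnitudes. The truth record carries the responsive-probe set,
the true baselines, and the analytic expected DFR per cohort-timepoint
($n_{\mathrm{probes}}\sigma^2_{\mathrm{noise}} + n_{\mathrm{resp}}\,a^2$
against the true baseline), which the tests check against.

What the generator does *not* emulate — probe-level chip artifacts, batch
effects, probe–probe correlation, intermediate outcome classes, and
realistic AIS/gender joint distributions — bounds what passing tests show:
they validate the statistical machinery under idealised independence, not
performance on real arrays. Cytokine panels are log-normal with an additive
age effect (negative by default: the aged mount a weaker circulating
response) and an early-peaking exponential time profile.

## Problem sizes and reproducibility

All simulation-based checks run at deliberately modest sizes — 400–1000
probes, 17 patients per cell, 100 seeded replicates for the
trajectory-ordering recovery rate, 99–1000 label permutations — chosen so a
full verification pass completes on a laptop in minutes while keeping
binomial error bands tight enough to be meaningful. Every stochastic stage
takes an explicit integer seed, and identical seeds reproduce matrices,
panels and permutation streams bit-identically; the pipeline manifest
records every threshold and seed of a run.

## Known limitations

* Printed DFR magnitudes from the motivating clinical study (e.g. day-4
  genome-wide DFR (×10³) of 116 ± 54 vs 88 ± 29) require the original
  deposited arrays and are not reproduced here; the package documents them
  as external-data reproductions only.
* Normalization is upstream: expression inputs are assumed normalized
  log2-scale intensities, and fold-change conversion to the linear scale is
  the only rescaling performed.
* The GEO series-matrix reader is a convenience for the common textual
  layout; it does not attempt SOFT-family generality.
* Stepwise multivariate outcome models, pathway-knowledge-base Z-scores,
  and gene-set curation are out of scope; gene sets are consumed as
  user-supplied lists.
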