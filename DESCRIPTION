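Package: genostorm
Title: Distance-from-Reference Trajectory Analysis of the Post-Trauma
    Neutrophil Transcriptome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the "genomic storm" that follows severe
    traumatic injury in peripheral-blood neutrophil expression profiles.
    Implements trauma-responsive probe selection by per-probe one-way
    F-tests with false-discovery adjustment and fold-change filtering, a
    distance-from-reference (DFR) score summarising each patient's total
    transcriptomic deviation from a healthy-control baseline, leave-one-out
    cross-validated classification with a Monte Carlo permutation null,
    matched-pair cohort construction, trajectory group comparisons
    (ANOVA with Student-Newman-Keuls, Kruskal-Wallis, Holm-Sidak), an
    age-by-time linear model for longitudinal plasma cytokine panels, and
    univariate clinical contingency statistics. A synthetic-cohort
    generator emulating the age-dependent trauma response (young > aged
    early amplitude with a crossover by day 4, dropout, cytokine
    trajectories) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
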