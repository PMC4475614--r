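Package: synerdock
Title: Drug-Combination Synergy Scoring, IC50 Estimation, Cohort
    Association Statistics and Docking-Pose Consensus Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for quantifying two-drug combination
    effects in cell-viability screens and for locating consensus ligand
    binding sites in docking-pose ensembles. Normalizes viability plates
    against vehicle controls, fits the log(inhibitor) versus normalized
    response model to estimate IC50 values with residual-bootstrap
    confidence intervals, computes IC50-equivalent doses and the
    combination index at the 50 percent effect level with a banded
    synergy classification and isobologram coordinates, provides the
    rank-based and correlation statistics used for clinical expression
    cohorts (Kruskal-Wallis with an exact small-sample permutation
    option, 2log Pearson correlation with t-based significance, paired
    one-tailed t tests), and scores per-residue contact frequencies over
    the lowest-energy docking poses to segment consensus pocket regions
    and protein-protein interface residues. Includes seeded synthetic
    data generators so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
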