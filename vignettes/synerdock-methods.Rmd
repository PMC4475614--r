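---
title: "Methods: dose-response fitting, combination-index synergy, cohort statistics and pose consensus"
author: "synerdock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response fitting, combination-index synergy, cohort statistics and pose consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synerdock)
```

synerdock is a pipeline for quantifying the interaction of two drugs in
cell-viability screens — the kind of experiment where a neuroblastoma
line is treated with a cystine-transport inhibitor such as sulfasalazine
together with an ornithine-decarboxylase inhibitor such as DFMO — and
for locating consensus ligand binding sites in docking-pose ensembles on
a receptor structure. This vignette describes the models, their
assumptions, the tunable parameters, and the design choices behind the
implementation.

## Plate normalization

An MTS viability plate measures optical density at 490 nm; the formazan
signal is proportional to the number of living cells. `normalize_plate()`
converts each treated well to percent of vehicle control,

$$\mathrm{response}(d) = 100\cdot
  \frac{\overline{OD}_{\mathrm{treated}}(d) - \overline{OD}_{\mathrm{blank}}}
       {\overline{OD}_{\mathrm{vehicle}} - \overline{OD}_{\mathrm{blank}}},$$

with the blank term zero when the plate has no blank wells. Treated
wells at dose 0 are folded into the vehicle pool, the vehicle condition
is exactly 100 by construction, and responses above 100 are retained —
clipping them would bias the top plateau of the subsequent fit. A plate
whose vehicle mean does not exceed its blank mean is rejected as
degenerate. Normalization is invariant to rescaling all ODs by a
constant, so gain settings of the reader do not matter.

## The dose-response model and IC50 estimation

`fit_normalized_logistic()` fits the two-parameter "log(inhibitor)
versus normalized response" family

$$Y = \frac{100}{1 + 10^{(X - \log_{10}\mathrm{IC}_{50})\cdot h}},
  \qquad X = \log_{10}(\mathrm{dose}),$$

with Top fixed at 100 and Bottom at 0 (the data are already on the
percent-of-vehicle scale). The Hill slope $h$ is free by default
(`variable_slope = TRUE`, requiring at least four distinct nonzero
doses) or fixed at 1 (three doses suffice). Dose-0 points anchor the
normalization but never enter the fit: the model lives on log dose.

Optimization is deterministic. $\log_{10}\mathrm{IC}_{50}$ starts at
the dose whose response is nearest 50; the slope is started at 1, 0.5
and 2; each start is polished by Levenberg–Marquardt
(`minpack.lm::nls.lm`), the lowest sum of squared errors wins, and ties
go to the slope nearest 1. No random numbers are used in fitting, so a
fit is reproducible by construction, and a failed optimization returns
`converged = FALSE` instead of raising. On noiseless data the planted
parameters are recovered to under $10^{-6}$ relative error; the test
suite also checks the returned SSE against a $200\times200$ brute-force
grid.

### Bootstrap confidence intervals

`estimate_ic50()` reports $\mathrm{IC}_{50} = 10^{\widehat{\log
\mathrm{IC}_{50}}}$ with a residual-bootstrap interval. Residual (not
case) resampling is used because a plate has few distinct doses — case
resampling would routinely drop entire dose levels. Three details
matter for calibration, and all three were measured during development
on simulated plates (seven log-spaced doses, six replicate wells, 2%
Gaussian OD noise — the design the generator emulates):

* **Replicate-level residuals.** Fitting per-dose means leaves a
  residual pool of barely more members than parameters; intervals built
  from it run far below nominal coverage. `normalize_plate(plate,
  aggregate = FALSE)` keeps one row per well (including each vehicle
  well), giving the bootstrap an honest residual pool. Residuals are
  inflated by $\sqrt{n/(n-p)}$ to restore the variance absorbed by the
  $p$ fitted parameters.
* **The vehicle anchor.** Dividing by a noisy vehicle mean puts a
  shared multiplicative error on every well of a plate; in the
  simulated design it contributes about half of the IC50 estimator's
  variance, and within-curve residuals cannot see it. When the points
  carry several dose-0 rows, every bootstrap replicate resamples the
  vehicle wells and rescales the curve accordingly (deviations inflated
  by $\sqrt{n_v/(n_v-1)}$ so their variance is an unbiased image of the
  vehicle-mean variance).
* **Studentization.** Plain percentile intervals do not calibrate
  against plate-to-plate variability of their own width and measured a
  few points short of nominal even with the corrections above. The
  default interval is therefore a bootstrap-t: each replicate's
  $\log_{10}\mathrm{IC}_{50}^*$ is studentized by its delta-method
  standard error, and the resulting quantiles are applied to the
  full-data estimate on the log scale. Measured coverage at the
  simulated design is 96–97% for a nominal 95% interval over disjoint
  100- and 200-plate seed blocks; the percentile construction remains
  available via `interval = "percentile"`.

Bootstrap refits that fail to converge are dropped and counted, with a
warning past 10%. Everything is reproducible from the `seed` argument,
which never touches the caller's RNG state.

## Combination index and isobolograms

Synergy is scored at the 50% effect level in the Loewe/equivalent-dose
style. Each drug's combination dose is expressed as a fraction of its
own single-agent IC50 (`ic50_equivalent()`), and the combination index
is the sum

$$\mathrm{CI} = e_A + e_B
  = \frac{\mathrm{IC}_{50,A}^{\mathrm{comb}}}{\mathrm{IC}_{50,A}}
  + \frac{d_B}{\mathrm{IC}_{50,B}}.$$

The design encoded by `synergy_table()` is fixed-B/varying-A: for every
fixed dose of drug B a full drug-A dose-response curve is measured in
its presence, drug A's combination IC50 is fit from that plate, and the
fixed B dose enters as its equivalent directly. On the isobologram the
line of additivity joins $(1,0)$ and $(0,1)$ in equivalent-dose axes; a
point lies below the line exactly when $\mathrm{CI} < 1$.

CI values are refined into bands: strong synergism $[0.2, 0.4)$,
synergism $[0.4, 0.6)$, moderate synergism $[0.6, 0.8)$, slight
synergism $[0.8, 0.9)$, additive $[0.9, 1.1)$, moderate antagonism
$[1.1, 1.3]$ and antagonism above 1.3. Three conventions are worth
stating because the band table alone does not pin them down:

* Published band descriptions overlap at their endpoints; we adopt
  lower-closed/upper-open intervals, except that 1.3 itself belongs to
  moderate antagonism (antagonism is strictly "> 1.3"). The bands then
  partition $[0,\infty)$ with no gaps; a property test sweeps every
  boundary.
* The scale stops at 0.2; a CI below it is reported as `"below-scale"`
  rather than silently assigned a stronger class that no convention
  defines.
* CI is always computed and classified on unrounded equivalents;
  3-decimal half-up rounding is applied only when a report is written
  (`write_synergy_report()`). Summing pre-rounded equivalents can
  differ from the rounded unrounded sum in the third decimal, and the
  unrounded-first order is the numerically defensible one.

No Bliss, HSA, ZIP or median-effect (Chou–Talalay $D_m$/$m$) modelling
is attempted: the CI here is the simple equivalent-dose sum, and the
effect level is carried as an explicit field (fixed at 50) so other
levels could be added without changing the schema.

## Cohort association statistics

`cohort_matrix` holds per-sample gene expression on the 2log (log
base-2) scale with categorical clinical annotations — the structure of
public neuroblastoma cohorts annotated for age at diagnosis, MYCN
amplification and INSS stage. Unknown or missing annotations are
dropped listwise per test, never imputed.

* `kruskal_wallis()` tests expression against groups with the
  tie-corrected H statistic and the $\chi^2_{k-1}$ approximation
  (delegated to `stats::kruskal.test`). Two-group comparisons use the
  same test rather than switching to a rank-sum test, so two- and
  multi-group analyses live on one scale; with $k=2$ the two are
  equivalent. For total $n \le 8$ an exact permutation p-value is also
  computed by full enumeration of label assignments; the suite checks
  it against an independent combinatorial oracle. The statistic is
  invariant under strictly monotone transforms of the values.
* `pearson_log2()` computes the product-moment correlation of two
  already-2log vectors (no re-transform) and derives significance from
  $t = r\big/\sqrt{(1-r^2)/(n-2)}$ with $n-2$ degrees of freedom
  (`correlation_significance()`). The p-value is two-sided; $|r| = 1$
  returns the degenerate $p = 0$ limit with a flag. At published
  operating points — $r = 0.289$, $n = 88$ and $r = 0.225$, $n = 649$ —
  the formula lands within 10% of the reported p-values, the slack
  coming from 3-decimal rounding of the printed correlations.
* `ranked_dual_gene_export()` produces the plotting table for a ranked
  dual-gene panel: samples ordered by one gene's expression (ties
  broken by sample id), both genes' values and all annotations carried
  along.
* `paired_onetailed_t()` is the treatment-versus-control viability
  test: paired t on per-experiment means, one-tailed in the direction
  control > treated. Identical pairs throughout give $t = 0$,
  $p = 0.5$; constant non-zero differences have no estimable variance
  and are an error.

No multiple-testing correction is applied across cohorts, and no
survival analysis is included; both are outside this package's scope.

## Docking-pose consensus binding sites

Given a receptor (`structure_model`, heavy atoms only) and a
`pose_ensemble` of ligand coordinates with docking energies, the
consensus procedure is:

1. **Contact surface** (`contact_residues()`): a residue belongs to a
   pose's contact surface when any of its heavy atoms is within the
   cutoff (default 3.6 Å, boundary included) of any ligand atom.
   Hydrogens are ignored throughout — crystal structures typically
   lack them and the 3.6 Å convention is heavy-atom style. Detection
   runs on a cell-list spatial grid whose arithmetic is identical to
   the all-pairs definition; the suite asserts exact set equality
   against a brute-force oracle on 50 random fixtures, and
   monotonicity in the cutoff.
2. **Conservation scores** (`conservation_scores()`): poses are ranked
   by energy (ascending; ties keep input order, so results are
   deterministic) and the top $K = 50$ kept. A residue's score is the
   fraction of kept poses whose contact surface contains it — a value
   in $[0,1]$. Scores are invariant under a rigid-body transform
   applied jointly to structure and poses.
3. **Region segmentation**: residues scoring at or above the threshold
   (default 0.5) are grouped into sequence-consecutive runs per chain,
   bridging gaps of up to 2 residues, and the runs are ranked by mean
   score. The segmentation rule is plumbing of this package — a
   published consensus-of-regions result does not come with one — so
   both parameters are exposed in `run_config()`.
4. **Interfaces and overlap**: `interface_residues()` lists the
   symmetric residue pairs of two chains within the cutoff (the dimer
   interface, with the same 3.6 Å default); `site_overlap()` compares
   two sites by shared residues, Jaccard index, and the Euclidean
   distance between the ligands' unweighted geometric centers.

PDB input goes through `bio3d`; waters and non-ligand heteroatoms are
excluded, and alternate locations are resolved by highest occupancy.
Docking itself (pose generation, scoring functions, minimization) is
out of scope: the package consumes ensembles, it does not produce them.

## Synthetic data: what it emulates and what it does not

Every stage is testable offline through seeded generators
(`gen_viability_plate()`, `gen_combination_grid()`, `gen_cohort()`,
`gen_pose_ensemble()`); each is a pure function of its arguments
including the seed, and none disturbs the caller's RNG stream.

* Plates carry additive Gaussian OD noise (default sd 2% of the
  vehicle OD) on a logistic truth, seven log-spaced doses around the
  planted IC50 and six replicate wells per dose — three independent
  experiments in duplicate, the usual design for these assays.
  Gaussian rather than proportional noise is deliberate: it is simple,
  and sufficient for recovery studies. Real plates add edge effects,
  drift and occasional outliers that are not modelled, so passing
  recovery tests bounds statistical error, not assay artefacts.
* Combination grids plant a CI by solving the equivalent-dose identity
  for drug A's true combination IC50 at each fixed B dose, then
  simulating a full plate at that truth; a round trip through
  `synergy_table()` recovers the planted CI with median absolute error
  well under 0.05 at 2% noise.
* Cohorts draw 2log values from normal distributions, shift the target
  gene by a stated number of SDs in one group, and build the partner
  gene with a target correlation via the bivariate-normal construction
  $g_2 = r z_1 + \sqrt{1-r^2}\,z_2$. (When both a shift and a
  correlation are planted, the shift adds a small extra correlation —
  acceptable for calibration studies, stated here so nobody reads the
  planted $r$ as exact in that case.) Microarray probe effects,
  normalization batch structure and annotation errors of real cohorts
  are not simulated.
* Pose ensembles place pseudo-residues along an extended chain
  (sequence neighbors are spatial neighbors, distant residues cannot
  touch the ligand), put the reference ligand 2.5 Å alongside a
  designated pocket, and jitter rigid copies with energies increasing
  in the displacement. This emulates the consensus geometry of a
  docking run, not its energetics.

## Problem sizes used in the checks

The simulation studies behind the package's own acceptance checks use:
100 plates for IC50 recovery (median relative error observed ≈ 2%,
bound 5%); 100 plates × 500 bootstrap replicates for interval coverage
(observed 96–97%, bound 90%); 200 cohort simulations at $n = 300/300$
for Kruskal–Wallis power (observed 100% at a 1-SD shift) and type-I
error (observed ≈ 4–5%, band 5% ± 2%); 50 random fixtures for the
contact-detection oracle; and a 120-residue structure with 60 poses at
0.5 Å jitter for planted-pocket recovery. These sizes give stable
estimates at desk scale while keeping a full run in the low tens of
seconds.

## Known limitations

* Single-agent IC50s from published figures cannot be re-derived
  without the raw plate data; the package validates its estimator by
  parameter recovery on synthetic plates instead.
* The CI here is evaluated at one effect level from one fitted IC50
  per fixed B dose; it does not model the full response surface.
* The logistic fit assumes homoscedastic noise on the percent scale;
  strongly heteroscedastic plates would need weights the API does not
  currently expose.
* Region segmentation parameters (threshold, gap bridging) have no
  canonical published values; defaults are sensible but should be
  revisited per receptor.
* `read_structure_pdb()` reads model 1 of PDB files only; mmCIF is not
  supported.
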