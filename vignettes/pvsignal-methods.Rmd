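---
title: "Methods: empirical-Bayes signal detection and drug clustering in pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical-Bayes signal detection and drug clustering in pvsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

This vignette is the package's account of the statistical machinery it
implements: the models, the tunable parameters and why their defaults are
what they are, the numerical choices, what the synthetic-data generator
does and does not emulate, and the known limitations.

## The disproportionality problem

A spontaneous reporting database is, after ingestion, a drug × ADE
contingency table of counts `N_ij`. There is no denominator of exposed
patients, so all inference is *disproportionality* analysis: each count is
compared with its expected value under row–column independence,

$$E_{ij} = \frac{n_{i\cdot}\, n_{\cdot j}}{n_{\cdot\cdot}},$$

and the relative reporting ratio is `RR_ij = N_ij / E_ij`. An `RR` of 100
means the pair was reported 100 times as often as the database-wide
baseline. `RR` is unbiased but wildly unstable when `E` is small: a single
report against `E = 0.01` yields `RR = 100` with no evidential weight.

Two conventions matter here and are fixed throughout the package:

* **The baseline `E` is frozen at the full post-ingest table.** Every
  downstream filter (report floor, pulmonary subsetting, selection rules)
  reuses the same `E`. Recomputing `E` after subsetting columns would
  silently change the baseline each stage; `subset_counts()` therefore
  carries the original `E` forward, and the tests assert that rebuilding a
  table from subsetted records gives a *different* (disallowed) baseline.
* **Duplicate `(case, drug, event)` rows count once** by default
  (`dedup = TRUE` in `build_count_table()`), since replicated transmissions
  of one case are a known artifact of spontaneous-report databases. The
  flag exists because whether a given extract is already deduplicated is
  usually unknowable from the data alone.

## The Gamma-Poisson Shrinker

The GPS model treats each cell's count as Poisson with mean
`λ_ij · E_ij` and gives the rate multiplier a two-component gamma mixture
prior:

$$\pi(\lambda) = P\,\mathrm{Gamma}(\lambda;\alpha_1,\beta_1)
  + (1-P)\,\mathrm{Gamma}(\lambda;\alpha_2,\beta_2).$$

**Gammas are rate-parameterized** (`mean = α/β`) — the GPS convention, and
worth stating prominently because shape/scale confusion is the classic
implementation bug. The prior mean is `P·α₁/β₁ + (1−P)·α₂/β₂`;
`print.pv_gps_model()` displays it for exactly this sanity check.

Marginally each count is a two-component negative-binomial mixture; the
five hyperparameters are estimated by maximizing the summed marginal
log-likelihood (`fit_gps()`). Posterior quantities per cell:

* `Qn` — the posterior weight of component 1 given the count,
* `EBGM = exp(E[log λ | N])` — a weighted digamma expression over the
  updated components `Gamma(α_k + N, β_k + E)`,
* `EB05`, `EB95` — the 5th/95th posterior percentiles, solved from the
  posterior mixture CDF.

`EB05 > 1` is the conservative signal criterion: the whole lower tail of
the posterior must clear the null ratio. For small counts EBGM sits near
the prior mean regardless of `RR`; as `N` and `E` grow at fixed ratio,
`EBGM → RR` and the shrinkage vanishes. (Note the limit requires `E` to
grow too: at fixed `E`, `EBGM/RR → E/(β+E)` for the dominant component,
which is *not* 1 — the tests assert the joint limit.)

### Numerical choices

* All mixture arithmetic is in log space (`log-sum-exp`), stable for
  counts up to at least 1e5.
* Posterior quantiles are found by vectorized bisection between the two
  component quantiles (the mixture quantile is always bracketed by them),
  to an absolute tolerance of 1e-9. Tests verify self-consistency
  (`CDF(q) = p` to 1e-7) and agreement with brute-force quadrature of the
  Poisson × prior integrand to 1e-6.
* `fit_gps()` optimizes on transformed coordinates (log shapes/rates,
  logit weight) with `nlminb`, from five restarts: the conventional
  initial value `(0.2, 0.1, 2, 4, 1/3)` plus four jittered copies
  (Gaussian jitter, sd 0.4, seeded — fits are deterministic given
  `seed`). Any start with a finite objective competes, because
  quasi-Newton codes report "false convergence" on the flat likelihood of
  degenerate data even when the optimum is fine; the per-start
  convergence codes are kept in the fit report.
* The two components are only identified up to a label swap, so fits are
  canonicalized with component 1 the larger-mean component. A fitted
  weight within 0.05 of 0 or 1 is flagged as effectively
  single-component.
* Zero-margin rows/columns are excluded before fitting (`E` undefined
  there); zero-*count* cells are scored like any other, so downstream
  block designs stay complete.
* No data squashing is applied (large GPS implementations bin cells for
  speed); at the table sizes this package targets (hundreds of drugs by
  tens of terms) the exact likelihood is fast.

## Staged selection

The filter order is fixed: report floor → GPS scoring on the full table →
pulmonary vocabulary subsetting → rule-based selection. Parameters, with
defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `min_reports` | 500 | per-drug floor on exploded report rows; drugs below it contribute only noise-driven ratios |
| `rr_threshold` | 2 | `RR > 2`, strict: a cell at exactly 2 is not flagged |
| `eb05_threshold` | 1 | `EB05 > 1`, strict |
| `min_ades` | 2 | a drug must show ≥ 2 distinct flagged pulmonary terms |
| `retention` | 0.5 | fraction of selected drugs kept by the tuned graphical lasso |

The report floor counts *exploded per-drug rows* (a two-drug case
contributes one row to each drug), matching how report totals are usually
tabulated per drug class. The pulmonary vocabulary is defined by SOC
membership (respiratory, thoracic and mediastinal disorders) plus an
explicit extra-HLT list for the viral/fungal infection terms that live in
the infections SOC; named unrelated terms are removed first, then terms
with zero reports in the cohort.

Ranking of selected drugs (`rank_drugs()`) is by descending flagged-term
count; ties break by descending maximum flagged-cell score (EBGM or RR per
the active rule) and then lexicographically. The tie rule is a documented
package convention — printed rankings in published profile tables do not
specify theirs.

## Graphical-lasso drug clustering

Each selected drug's profile is its EBGM vector over the analyzed terms.
The drug–drug association matrix is the Pearson **correlation** of these
profiles (not the covariance: profiles span different EBGM scales). The
graphical lasso maximizes the L1-penalized Gaussian log-likelihood

$$\log\det\Theta - \mathrm{tr}(S\Theta) - \rho\lVert\Theta\rVert_1$$

by block coordinate descent (compiled C++; each column a coordinate-descent
lasso), converging when the covariance estimate changes by less than 1e-6
elementwise. Soft-thresholding leaves exact zeros; an edge is declared
where `|θ_ij| > 1e-8` (guarding round-off only). At `ρ = 0` the estimate
equals the matrix inverse (tested to 1e-4), and exactly block-diagonal
inputs never acquire cross-block edges.

"Shrinking a drug away" is operationalized as **node isolation**: a drug
with no off-diagonal nonzeros in the precision matrix. `tune_retention()`
searches a log-spaced penalty grid (25 points up to the full-shrinkage
penalty `max|off-diag correlation|`), refined by bisection, for the
retained fraction closest to the target; ties prefer the larger penalty
(the sparser, more conservative graph). Retention can jump by more than
one drug between penalties — strongly correlated blocks enter and leave
together — so an unreachable target is reported with the closest
achievable value and a flag rather than silently passed over.

GL clusters are the connected components of the retained graph, labeled in
decreasing size order (ties by smallest member id) so "cluster 1" is
always the largest group. Reverse Cuthill-McKee ordering (BFS from a
pseudo-peripheral start, neighbors in ascending degree, ties by index,
order reversed) is used purely for layout: it concentrates adjacency near
the diagonal, which untangles arc and circular diagrams. For diagram
rendering the profile matrix is also exported in block-diagonal expansion
(`m × q` → `m × mq`, each drug's terms in its own column block).

## Rank-based homogeneity testing

Whether GL clusters (or nominal ATC classes) are internally homogeneous is
tested with the Friedman statistic over a complete block design: **blocks
are the analyzed ADE terms, treatments are the group's drugs**. This is
the only matched design available for unequal-sized drug groups, and it is
why zero-count cells are scored rather than dropped — every block must be
complete. Midrank ties use the standard correction; a design in which
every block is fully tied carries no information and is reported as
statistic 0, p = 1 rather than NaN. Groups with fewer than two drugs are
reported untestable. A leave-one-out `drop` argument re-tests a group
without one named drug, the usual sensitivity check when a single drug
drives heterogeneity.

Pairwise group comparisons use the Wilcoxon signed-rank test on **per-ADE
group means**: for groups A and B, the mean EBGM over A's drugs is paired
against the mean over B's drugs term by term. Pairing group means keeps
the vectors matched and equal-length for unequal group sizes. The exact
null distribution is enumerated by convolution over (mid)ranks for up to
25 non-zero pairs; beyond that a normal approximation with tie and
continuity corrections is used. Bonferroni correction multiplies by the
number of group pairs.

A power note: over 17 term-blocks, a rank statistic can only reach small
p-values when a deviant drug tops *most* blocks. One drug elevated on half
the terms of a 7-drug group yields χ² ≈ 8.5 on 6 df (p ≈ 0.2) no matter
how large the elevation — the statistic is bounded by the ranks. The
package's power checks therefore plant elevation on 12 of 17 terms, where
rejection at p < 0.01 is genuinely attainable. Calibration checks confirm
the nominal 5% type-I error (rejection rate within [0.04, 0.06] over
10,000 null replicates at the 17 × 5 design scale) and the conservatism of
the exact signed-rank test at n = 17.

## The synthetic-report generator

The generator emulates the structures that make spontaneous-report data
hard, with known ground truth:

* **Counts** (`gen_gps_counts`): cell multipliers drawn from the
  two-gamma mixture at the conventional hyperparameters
  `(0.2, 0.1, 2, 4, 1/3)` — prior mean exactly 1 — and counts Poisson
  around `λ·E`, with the design baseline `E = outer(drug_scale,
  ade_scale)` spanning 5–50, the range where shrinkage is visibly active
  but identifiable.
* **Planted structure** (`gen_planted_counts`): a quiet baseline
  (`λ ≈ 1` with 5% lognormal jitter) carrying planted cluster blocks
  (shared elevation, default multiplier 5) and optional scattered-signal
  drugs elevated on idiosyncratic small term sets — signals that pass the
  EB05 rule but fall to the graphical lasso, exactly the behaviour the
  staged funnel is supposed to produce.
* **Profiles** (`gen_clustered_profiles`): the clustering validation
  geometry — 44 drugs × 17 terms, four blocks of 6/6/5/5 correlated
  signal drugs plus 22 independent null drugs, elevation 5, Gaussian
  profile noise sd 0.5. Under the 50% retention calibration the tuned
  lasso keeps exactly the 22 block drugs and recovers the four blocks as
  GL clusters (adjusted Rand index ≥ 0.9 in the tests).
* **Case files** (`gen_case_reports`): case-level rows realizing a target
  table exactly, with 30% of drug mentions written as dictionary variants
  (salt, manufacturer-prefixed, brand-like alias) and 28% of cases
  listing two drugs — chosen to echo the ~1.28 ratio of per-drug report
  rows to case reports typical of hypertension-cohort extracts. Ingesting
  the files with the emitted dictionary reproduces the target counts
  bit-exactly; without it, variant rows go unmatched.
* **Full scenario** (`gen_pipeline_scenario`): a 60-drug cohort — 22
  planted block drugs, 22 scattered-signal drugs, 16 nulls — that drives
  the complete pipeline through the 60 → 44 → 22 funnel at desk scale.

What the generator does **not** emulate: reporting delays and secular
trends, demographic confounding and stratified baselines, indication
channeling (the tendency of sicker patients to receive specific drugs),
duplicate transmissions with *differing* case ids, and the heavy-tailed
margin distribution of real extracts. Passing tests therefore demonstrate
the correctness and internal calibration of the machinery under the
generative model, not robustness to those real-data pathologies.

## Problem sizes used in validation

Test and acceptance runs use desk-scale designs chosen once: 5,000 cells
for hyperparameter recovery (each parameter recovered within 25%, weight
within ±0.1), 100 random cells for quadrature equivalence, the 44 × 17
profile geometry for retention and cluster recovery, 10,000 replicates for
type-I calibration, and a 60 × 17 cohort for the end-to-end funnel. These
sizes make every property sharply testable while keeping a full validation
run on one CPU comfortable.

## Known limitations

* Only the independence baseline for `E` is provided; stratified expected
  counts (age, sex, reporting year) are out of scope.
* PRR, ROR and IC statistics are not implemented — the workflow is
  RR/EBGM-based by design.
* The graphical lasso consumes Pearson correlations of EBGM profiles;
  rank-based association is not offered.
* Drug-name normalization is deterministic token stripping plus exact
  dictionary lookup — intentionally auditable, but it will not recover
  misspellings (`"Revathio"`) absent from the dictionary; unmatched names
  are reported, never silently dropped.
* GL cluster extraction reads clusters as connected components of the
  precision graph; other readings (e.g. visual groupings of a rendered
  layout) are possible and would not generally coincide.
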