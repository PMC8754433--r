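# pvsignal

Signal detection for spontaneous adverse drug event (ADE) reporting data.

Spontaneous reporting systems (FAERS-style databases) accumulate millions of
case reports linking drugs to adverse events, but the raw reporting
frequencies are noisy: rarely prescribed drugs produce wildly unstable
ratios, multi-drug cases multiply rows, and the same active ingredient hides
behind dozens of brand, salt and formulation names. `pvsignal` implements a
complete disproportionality-analysis workflow for such data, aimed at
pharmacoepidemiologists who want to go from case-level report files to
ranked drug–event signals, data-driven drug clusters, and class-homogeneity
tests:

1. **Ingest** — read case-level reports, normalize drug names to active
   ingredients through a synonym/ATC dictionary, explode multi-drug cases
   (one record per drug–event pair), and build the drug × ADE contingency
   table with independence-baseline expected counts
   `E_ij = n_i. n_.j / n..`.
2. **Score** — the relative reporting ratio `RR_ij = N_ij / E_ij` and the
   Gamma-Poisson Shrinker (GPS) empirical-Bayes model: the rate multiplier
   `λ_ij = μ_ij / E_ij` is given a two-component gamma mixture prior
   `P·Gamma(α₁, β₁) + (1−P)·Gamma(α₂, β₂)` (rate parameterization), the five
   hyperparameters are estimated by marginal maximum likelihood over the
   negative-binomial mixture, and each cell gets its posterior summaries:
   `EBGM = exp(E[log λ | N])` and the posterior quantiles EB05/EB95. EBGM
   shrinks unstable small-count ratios toward the prior mean while leaving
   well-supported large counts alone; `EB05 > 1` is the conservative signal
   rule.
3. **Select** — staged filtering: a per-drug report-count floor (default
   500), restriction to the analyzed pulmonary HLT vocabulary, the `RR > 2`
   rule, and the two-condition EB05 rule (`EB05 > 1` on at least two distinct
   pulmonary ADEs).
4. **Cluster** — Pearson correlation of per-drug EBGM profiles, sparse
   precision estimation by the graphical lasso (block coordinate descent,
   compiled), with the L1 penalty tuned so a target fraction of drugs
   (default 50%) keeps at least one edge; connected components of the
   resulting graph are the GL clusters, and reverse Cuthill-McKee ordering
   plus a block-expanded profile matrix are exported for circular/arc
   diagrams.
5. **Compare** — Friedman rank tests of EBGM homogeneity within ATC classes
   or GL clusters (blocks = analyzed ADE terms, treatments = drugs), and
   pairwise class comparisons by the Wilcoxon signed-rank test (exact null
   for small n) with Bonferroni correction.

A synthetic spontaneous-report generator (`sim_config()`, `gen_gps_counts()`,
`gen_clustered_profiles()`, `gen_case_reports()`, `gen_pipeline_scenario()`)
produces FAERS-like inputs with known ground truth — planted signal drugs,
cluster blocks, name variants, multi-drug cases — so every stage is testable
end to end without any external data.

## Worked example

Simulate a 30-drug cohort with two planted 5-drug signal blocks, fit the
GPS prior, and score every drug–ADE pair:

```r
library(pvsignal)

cfg <- sim_config(n_drugs = 30, n_ades = 17, seed = 8,
                  blocks = list(list(drugs = 1:5,  ades = 1:6),
                                list(drugs = 6:10, ades = 9:14)))
planted <- gen_planted_counts(cfg)
fit <- fit_gps(planted$counts, seed = 8)
fit
#> <pv_gps_fit> loglik -1730.970 on 510 cells
#> <pv_gps_model> alpha1=391.4 beta1=79.59 alpha2=187.1 beta2=187.4 P=0.1171 (prior mean 1.458)

signals <- score_table(planted$counts, fit)
dplyr::arrange(tibble::as_tibble(signals), dplyr::desc(ebgm))[1:3, ]
#>   drug   ade       n     e    rr    qn  ebgm  eb05  eb95
#> 1 drug06 ade10    99  15.2  6.51     1  5.17  4.79  5.56
#> 2 drug09 ade13   125  20.9  5.97     1  5.13  4.77  5.51
#> 3 drug10 ade10   112  18.5  6.05     1  5.13  4.76  5.51
```

The fitted mixture has found the planted structure: a heavy component near
the elevated multiplier 5 holding ~12% of the prior mass, and a tight
component at baseline. The top EBGM scores sit just *below* their raw RR
values — that is the shrinkage working. The conservative EB05 rule then
recovers exactly the ten planted drugs:

```r
sel <- select_by_eb05(signals)   # EB05 > 1 on >= 2 distinct ADEs
retained_drugs(sel)
#>  [1] "drug01" "drug02" "drug03" "drug04" "drug05"
#>  [6] "drug06" "drug07" "drug08" "drug09" "drug10"
```

At the clustering stage, the graphical-lasso penalty is tuned so half of
the candidate drugs keep at least one association. On the bundled 44-drug
validation geometry (four planted blocks of 6/6/5/5 correlated drugs plus
22 null drugs):

```r
profiles <- gen_clustered_profiles(sim_config(seed = 7))$profiles
tuned <- tune_retention(profiles, target_fraction = 0.5)
tuned
#> <pv_retention> penalty 0.8502 keeps 22 drugs (50.0%)
table(tuned$graph$clusters)
#> 1 2 3 4
#> 6 6 5 5
```

All 22 null drugs are shrunk to isolation and dropped; the four planted
blocks come back exactly as GL clusters 1–4. `autoplot(tuned$graph)` draws
the RCM-ordered circular diagram, and `within_group_homogeneity()` /
`pairwise_class_comparison()` test whether clusters are internally
homogeneous and mutually distinct.

`run_pipeline(pipeline_config(...))` chains every stage over report files on
disk (see `gen_pipeline_scenario()` for a complete synthetic input set) and
writes per-stage tables plus a JSON manifest that records the seed, every
threshold, and per-stage drug counts; identical config and seed give
byte-identical outputs.

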