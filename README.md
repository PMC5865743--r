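# miRSubSurv

Survival signatures built from **miRNA-integrated subpathways**.

Expression-based prognostic signatures for heterogeneous cancers such as
acute myeloid leukemia are notoriously unstable: gene lists fitted on one
cohort rarely transfer to another. Working at the level of *subpathways* —
compact regions of biological pathways — and including the microRNAs that
regulate their member genes gives signatures a functional footing and far
fewer degrees of freedom. `miRSubSurv` implements that strategy end to end
for matched miRNA + mRNA expression cohorts with right-censored survival,
and ships a synthetic-cohort generator with *planted* prognostic
subpathways so every stage can be validated without access to restricted
patient data.

## The method

1. **Subpathway reconstruction.** Each pathway is an undirected gene graph
   (parsed from KGML or simulated). A subpathway is a *maximal* gene set in
   which every pair lies within shortest-path distance *k* (default 3) in
   the full pathway graph — a distance-based k-clique, enumerated as the
   maximal cliques of the k-th graph power. miRNAs with an experimentally
   verified (low-throughput) interaction to at least one member gene are
   embedded in the region; regions with fewer than 1 miRNA or 3 genes are
   dropped.
2. **Cox screening.** Every miRNA and gene is screened with a univariate
   Cox proportional-hazards model on standardized log2(FPKM + 1) values;
   features with Wald *P* < 0.05 are "survival features".
3. **Pooled hypergeometric statistic.** For a subpathway holding
   *t*<sub>g</sub> genes and *t*<sub>mir</sub> miRNAs of which
   *r*<sub>g</sub> + *r*<sub>mir</sub> are survival features, with
   *n*<sub>g</sub> + *n*<sub>mir</sub> survival features among the
   *m*<sub>g</sub> + *m*<sub>mir</sub> measured features overall,

   P = 1 − Σ<sub>k=0</sub><sup>r<sub>g</sub>+r<sub>mir</sub>−1</sup>
   C(t<sub>g</sub>+t<sub>mir</sub>, k) ·
   C(m<sub>g</sub>+m<sub>mir</sub>−t<sub>g</sub>−t<sub>mir</sub>,
   n<sub>g</sub>+n<sub>mir</sub>−k) /
   C(m<sub>g</sub>+m<sub>mir</sub>, n<sub>g</sub>+n<sub>mir</sub>),

   i.e. the upper tail of a hypergeometric urn pooling genes and miRNAs.
   Subpathways with *P* < 0.05 are called survival-related.
4. **Robustness ranking.** Steps 2–3 are repeated over 100 stratified
   half-subsets of the training set; a subpathway's *count* (0–100) is the
   number of subsets in which it is significant, and dense ranks on the
   count order the candidates.
5. **Risk scores.** For each robust subpathway, a per-sample risk score is
   the linear combination of *all* measured member features (significant or
   not) weighted by their training-set Cox coefficients; a combined score
   weights the sub-scores by a second round of univariate Cox fits.
   Cohorts are dichotomized at the *training* median score and compared
   with Kaplan–Meier curves and the two-group log-rank test.

## Worked example

The `analysis/` directory is a numbered workflow over the package — run the
scripts in order from the repository root:

```sh
Rscript analysis/01_simulate.R           # synthetic pathways + cohort
Rscript analysis/02_build_subpathways.R  # region statistics
Rscript analysis/03_screen.R             # exclusion, split, Cox screen
Rscript analysis/04_rank_robustness.R    # 100-subset robustness counts
Rscript analysis/05_evaluate.R           # risk scores, KM + log-rank
```

The demo scenario simulates 250 patients and 40 pathways, three of which
carry planted survival signal. Stage 4 prints:

```
top 5 subpathways by robustness count:
  90014_1    count  25  mean p 0.277  [planted]
  90028_1    count  17  mean p 0.401
  90034_1    count   8  mean p 0.44
  90013_1    count   7  mean p 0.422
  90017_1    count   6  mean p 0.538
planted subpathways hold ranks: 1, 7, 9
```

The count is the number of half-subsets (of 100) in which the subpathway's
pooled hypergeometric test is significant — the top-ranked candidate here
is a genuinely planted region. Stage 5 fits risk scores on the training
samples only and evaluates both cohorts:

```
  90014_1    train  chi2   29.05   log-rank P 7.06e-08
  90014_1    test   chi2   13.26   log-rank P 0.000272
  combined   train  chi2   57.68   log-rank P 3.09e-14
  combined   test   chi2    5.77   log-rank P 0.0163
```

High- versus low-risk groups (split at the training median score) separate
strongly on the held-out test set for the top-ranked subpathway and for the
combined model — the planted signal is recovered out of sample.

The same machinery is available programmatically:

```r
library(miRSubSurv)
cfg <- pipeline_config(outdir = "run1",
                       scenario = scenario_config(seed = 7),
                       n_subsets = 100, seed = 7)
res <- run_pipeline(cfg)
head(res$robustness)
```

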