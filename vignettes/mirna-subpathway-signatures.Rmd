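---
title: "Robust miRNA-integrated subpathway signatures for survival analysis"
author: "miRSubSurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust miRNA-integrated subpathway signatures for survival analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRSubSurv)
```

## Motivation and model

Single-gene prognostic signatures for heterogeneous cancers transfer poorly
between cohorts. `miRSubSurv` works instead with *subpathways* — compact
regions of biological pathways — and integrates the microRNAs that regulate
their member genes, on the premise that a functional unit perturbed in a
disease is more reproducible across cohorts than any individual transcript.
The package covers the complete workflow: region reconstruction, Cox
feature screening, a pooled enrichment statistic, resampling-based
robustness ranking, and risk-score evaluation with Kaplan–Meier curves and
log-rank tests.

### Subpathway regions

A pathway is an undirected gene graph (self-loops dropped, relation
subtypes and directionality collapsed — downstream statistics use
membership and distance only, so edge labels would be dead weight). A
subpathway is a **maximal set of genes whose pairwise shortest-path
distance in the full parent graph is at most k**; these sets are exactly
the maximal cliques of the k-th power of the graph and are enumerated with
Bron–Kerbosch (pivoting) via `igraph`. Two choices deserve emphasis:

* **Distance is measured in the full pathway graph**, not inside the
  candidate subset: two genes joined only through an intermediate outside
  the region still count as close. This is the "distance similarity"
  reading of region mining and is what the exhaustive-enumeration oracle in
  the test suite checks.
* **Indices are assigned deterministically** — maximal sets sorted by size
  (descending) then lexicographic gene list, then numbered `_1, _2, …`.
  Region ids are only meaningful relative to a fixed pathway snapshot, so
  determinism, not any particular historic numbering, is the contract.

`k = 3` is the conventional default for this mining style and is exposed as
a parameter. A miRNA is embedded in a region when it has at least one
curated interaction (by default restricted to the `low-throughput`
evidence class, i.e. individually verified experiments) with a member gene;
only edges to member genes are recorded. Regions with fewer than 1 miRNA or
3 genes carry too little material for either the enrichment statistic or a
risk score and are dropped.

### Cox screening

Every miRNA and gene is screened with a univariate Cox proportional-hazards
fit (Efron tie handling, via the `survival` package) and the Wald test.
Expression enters as **standardized log2(FPKM + 1)**: the log tames the
right skew of FPKM-like data and the per-feature z-score makes coefficients
comparable across features — which matters later, when those coefficients
become risk-score weights. Whether to transform at all is a genuinely open
choice for this kind of screen; the package fixes one transform, applies it
identically in screening and scoring, and exposes `transform = "none"` for
raw covariates. Selection is at raw *P* < 0.05 with **no multiple-testing
correction by design**: the screen is not an inference in its own right but
the input to the enrichment urn below, whose calibration absorbs the
marginal selection rate. Zero-variance covariates are flagged `degenerate`
(*P* = 1 by convention); runaway fits (monotone partial likelihood,
non-convergence) are flagged `nonconverged` and excluded.

### The pooled hypergeometric statistic

Genes and miRNAs are pooled into one urn of the
$N = m_g + m_{mir}$ measured features, of which the subpathway marks
$K = t_g + t_{mir}$; drawing the $n = n_g + n_{mir}$ survival features and
observing $r = r_g + r_{mir}$ inside the subpathway gives the upper-tail
p-value

$$P \;=\; 1 - \sum_{k=0}^{r-1}
\frac{\binom{K}{k}\binom{N-K}{\,n-k\,}}{\binom{N}{n}}
\;=\; \Pr(X \ge r), \qquad X \sim \mathrm{Hypergeom}(N, K, n).$$

The urn is the **measured data**: subpathway members absent from the
expression matrices are excluded from every count, otherwise the urn and
the draw would live in different universes. Degenerate inputs
($n = 0$, $K = 0$, or $r = 0$) return exactly 1 — no evidence, not an
error. The implementation uses `phyper` (log-space stable); the acceptance
suite sweeps *every* valid configuration with $N \le 60$ against direct
summation of the formula, exact on integer-valued binomials for
$N \le 30$. Pooling the two molecular strata into one urn (rather than
testing them separately and combining) is a deliberate modelling choice —
it weights a survival miRNA and a survival gene identically — and the
statistic is implemented exactly in that pooled form. A Benjamini–Hochberg
column accompanies the calls for information, but selection is on raw
p-values, consistent with the screening step.

### Robustness over resampled subsets

Stability, not single-shot significance, is the ranking criterion. The
training cohort is stratified into *good*/*poor* survivors at the median
observed time (censored samples classified by their censored time — the
simplest reproducible rule, isolated in `median_survival_strata` so a
different policy is a one-function change). One hundred stratified
half-subsets are drawn independently without replacement within each
subset; each subset is re-screened and every subpathway re-tested. A
subpathway's **count** (0–100) is the number of subsets calling it
significant; dense ranks on the count order candidates, with count ties
broken by mean p-value then id so the table is fully deterministic.
Selection supports both `top_n` on dense ranks (default 3) and a
`min_count` threshold, because "top ranked" and "count above a cutoff" are
both natural readings of a robustness criterion; the default is the
rank-based one.

### Risk scores and evaluation

A subpathway's risk score is
$\mathrm{score}_i = \sum_j w_j \, x_{ij}$ over **all measured member
features** — including screening-insignificant ones, so the score reflects
the whole region rather than its cherry-picked extremes — with $w_j$ the
univariate Cox coefficient of feature $j$ refit on the **full training
set** and $x_{ij}$ the transformed expression, using training-set centering
and scaling frozen into the model. A combined model treats each sub-score
as a covariate in its own training-set Cox fit and combines linearly with
those coefficients. Groups are dichotomized at the **training median
score**; applying the training cutoff to the test set avoids any test-set
leakage (a test-set-own-median variant is available through the `cutoff`
argument of `evaluate_risk_model`). Ties at the cutoff go to the low-risk
group — a fixed, documented rule rather than an accident of floating-point
comparison. Curves are product-limit estimates and the two-group log-rank
test uses the standard observed-minus-expected form with hypergeometric
variance; reported p-values are floored at 1e-300 so a printed zero is
recognisable as underflow.

## The synthetic-cohort generator

The generator exists so the pipeline's statistical behaviour can be
verified with known ground truth; it emulates exactly the structure the
method assumes and nothing more.

* **Pathways**: Erdős–Rényi graphs per pathway at `edge_prob`, repaired to
  connectivity with minimal bridging edges (a k-clique search on a dust of
  isolated vertices is degenerate; at `edge_prob = 0` the repair yields a
  random tree). Gene ids are globally unique across pathways.
* **Interactions**: independent Bernoulli inclusion of each (miRNA, gene)
  pair at `interaction_prob`, tagged `low-throughput` with probability
  `low_throughput_frac` (default 0.8) so the evidence filter is exercised.
* **Expression**: log-normal with feature-specific location
  ($\mu \sim N(2,1)$) and scale ($\sigma \sim U(0.4, 1.2)$) — non-negative,
  right-skewed, FPKM-like. No batch effects, isoforms or
  miRNA-target anticorrelation are simulated; a passing pipeline on this
  generator demonstrates statistical correctness of the method, not
  biological fidelity of any particular cohort.
* **Survival**: proportional hazards,
  $h_i = h_0 \exp\!\big(\beta \sum_{j \in \text{planted}} x_{ij}\big)$,
  where the planted features are all members of the designated subpathways
  and $x$ is the standardized log2(x+1) value — the same covariate scale
  the screen fits, so the generating model and the analysis model agree
  exactly. Event times are exponential; censoring is `min_followup` (1
  month by default, in keeping with the cohort-hygiene filter) plus an
  independent exponential whose rate is solved numerically so the expected
  censored fraction equals `censor_rate`. Defaults: $h_0 = \log 2 / 12$
  per month (12-month baseline median survival), `censor_rate = 0.3`,
  112 samples — the scale of a single-disease TCGA cohort.
* **Determinism**: one master seed with fixed per-artifact offsets; the
  same `scenario_config` reproduces every artifact bit for bit.

A known limitation: with many planted features the linear predictor's
variance grows linearly in their number, producing heavy-tailed hazards —
some simulated patients die within days. The 1-month exclusion filter then
removes a larger share of samples than it would in a real cohort (where
very early deaths are rare and mostly unrelated to disease biology). The
bundled analysis scripts therefore use a moderate per-feature effect
(β = 0.5) for the narrative demo, while validation scenarios that fix
β = 1.0 analyze the full generated cohort.

## Numerical and procedural choices

* **Rounding in stratified allocation**: largest-remainder per stratum with
  total target $\lceil f \cdot n \rceil$, ties between strata broken by
  stratum name; the 1-month exclusion keeps the boundary itself (strictly
  `< 1` is removed).
* **Cox numerics**: `coxph.fit` with Efron ties (exact when times are
  untied, as in the continuous-time generator); non-convergence detection
  via iteration cap, non-finite estimates, or $|\hat\beta| > 15$ on the
  standardized scale (a standardized log-hazard ratio beyond $e^{15}$ is a
  monotone-likelihood artefact, not a finding).
* **Tie-breaking everywhere**: subpathway indexing, robustness ordering and
  cutoff dichotomization all have explicit deterministic rules, so a run is
  reproducible from its config and seed alone — `run_pipeline` writes an
  md5 manifest and re-running reproduces it byte for byte.
* **Problem sizes in the validation suite**: the oracle sweeps use every
  pooled hypergeometric input with $N \le 60$, 200 random graphs of up to
  12 nodes for region extraction, 200 null screens of 1000 features at 200
  samples for calibration, and 5 replicates of the planted-recovery
  scenario (40 pathways, 3 planted, 150/60 train/test, 100 half-subsets) —
  sizes at which the exhaustive oracles are exact and the whole suite runs
  in a few minutes on a laptop.

## What the validation does and does not show

The acceptance suite demonstrates: exact agreement of the enrichment
statistic with its defining sum; exact agreement of region extraction with
brute-force enumeration; Cox coefficients matching direct partial-likelihood
maximisation; correct null calibration (5% feature rejections, uniform
log-rank p-values); and end-to-end recovery of planted prognostic
subpathways with held-out significance. It does not — and cannot — show
that any particular real cohort yields stable subpathways, nor that a
region id from one pathway-database snapshot maps onto another; those
depend on the data vintage, which is precisely why the robustness count,
rather than a fixed list, is the product of the pipeline.
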