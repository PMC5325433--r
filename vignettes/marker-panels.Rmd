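---
title: "Methods: complementary membrane-marker panels for gastric cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complementary membrane-marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcpanel)
```

This vignette documents the models, parameter choices and numerical
conventions behind `gcpanel`, and what the synthetic-data generators do
and do not emulate.

## 1. The expression screen

A candidate membrane marker for in-vivo detection of gastric-cancer
metastases must be enriched in tumors and silent in the tissues a probe
or antibody would encounter around the stomach and its draining nodes.
The screen formalizes this with two order statistics per probe:

* `normal_max`: the maximum signal over a panel of normal tissues
  (default: esophagus, pancreas, spleen, adipose, lymph node, artery,
  vein, peripheral blood cells, monocyte, macrophage). Stomach, colon and
  small intestine are excluded entirely: the markers of interest are
  physiologically expressed in gastrointestinal epithelium, and that
  expression does not confound nodal detection.
* `tumor_kth`: the k-th largest value among tumor samples, with
  duplicates counted (descending sort, 1-based position `k`). With
  `k = 40` of 56 tumors this demands expression in at least 71.4% of
  cases — the "frequent" half of the selection criterion.

A probe is selected iff `normal_max < 150` (strict) and
`tumor_kth >= 500` (inclusive). The boundary semantics copy the wording
of the selection rule ("below" the normal ceiling, "at least" the tumor
floor) and are tested explicitly at 149.9/150.0 and 499.9/500.0.

Two conventions were genuinely open and are decided as follows:

* **Absolute thresholds.** The thresholds are applied to raw
  MAS5-summarized signal scores; no ratio normalization is applied. The
  screen's inputs are assumed already globally normalized (MAS5), which
  is the convention for this kind of signal value.
* **Unknown tissue labels** outside panel ∪ excluded ∪ {tumor} are
  ignored with a warning rather than an error, so a richer atlas of
  normal tissues does not break the screen; only the declared panel
  contributes to `normal_max`.

## 2. The IHC score model

Tissue-microarray (TMA) cores are scored by the proportion of tumor
cells with membranous staining, binned per decile to 0–10
(`0% -> 0`, `1–10% -> 1`, ..., `91–100% -> 10`, i.e. `ceiling(pct/10)`
for positive proportions). Duplicate cores per site (primary lesion
`Pr`, nodal metastasis `LN`) are summed to a 0–20 IHC score.

**Missing cores.** When only one replicate core is available the score
is doubled to stay on the 0–20 scale and flagged `imputed = TRUE`;
downstream analyses can exclude flagged values. When both cores are
missing the site value is missing. This is a package decision: the
source scoring system displays missing nodal cores as blank without
stating a policy, and doubling is the only choice that keeps the band
thresholds meaningful for single-core cases.

**Bands.** Marker-specific intervals partition 0–20:

| marker | `++` | `+` | `−` |
|--------|------|-----|-----|
| CDH17  | 18–20 | 9–17 | 0–8 |
| CLDN18 | 14–20 | 6–13 | 0–5 |
| CLDN7  | 12–20 | 8–11 | 0–7 |

The CLDN18 and CLDN7 negative intervals are derived as complements of
the stated `+`/`++` ranges (the scheme records this in
`derived_notes`); for CLDN7 the lowest interval is printed ambiguously
in the source material and is treated as `−` from context. Scheme
validation rejects any band set that fails to partition 0–20.

**Subgroups.** Cases are classified from their primary-lesion (`Pr`)
CDH17/CLDN18 bands — when `Pr` and `LN` disagree, `Pr` wins, matching
the stated use of primary-lesion scores:

* Group 1: CDH17 `++`, CLDN18 `+` or `−` (strong intestinal-type
  marker, dispensable gastric-type marker);
* Group 2: both `++`, or both `+`;
* Group 3: CDH17 `−`, any CLDN18;
* unclassified: CDH17 `+` with CLDN18 `++` or `−`.

Exhaustively enumerating all 21 × 21 integer score pairs partitions the
grid into 42 / 93 / 189 / 117 cells (Group 1/2/3/unclassified); this
count is frozen in the tests as a refactoring guard.

**Whole sections** are categorized per region on the same 0–10 score:
Category 1 (8–10), 2 (5–7), 3 (1–4), 4 (0), with exactly ten regions
per primary lesion and one category per metastatic node.

## 3. Coverage

A case is covered by a panel when positive for at least one panel
marker. Missing calls count as negative — a missing core cannot serve
as evidence of positivity. Printed percentages round half away from
zero (one decimal by default), the convention that reproduces
`40/56 -> 71.4`, `50/56 -> 89.3` and `98/106 -> 92.5`; base R's
round-half-even would give 92.5 but 6.2 for 1/16, so the rounding
primitive is explicit.

Positivity itself is configurable because the source analysis never
pins it numerically: expression-side coverage can use a per-marker
threshold rule (inclusive `>=`, mirroring the tumor floor), and
TMA-side coverage can use the band rule (band ≠ `−`) or, as in
`marker_report()`, group-membership coverage (covered = classifiable,
i.e. 98 of 106 = Groups 1–3). Both semantics are exposed.

`best_panel_greedy()` generalizes two-marker coupling to greedy set
cover with lexicographic tie-breaks; the tests bound it by the
exhaustive optimum and by the classical `1 − 1/e` guarantee on small
instances.

## 4. Two-way clustering

Rows (cases/samples) and columns (antibodies/probes) are clustered
independently — city-block distance for samples and correlation
distance for antibodies, taking the stated axis–metric assignment
literally — with average linkage (UPGMA), then the matrix is reordered
by both leaf orders. Numerical conventions:

* **Missing values** use pairwise-complete distances with *mean*
  aggregation for city block, so distances remain comparable across
  missingness patterns (TMA matrices contain blank nodal cells).
  Distances are undefined (error) without jointly observed components.
* **log base 150**: expression scores are transformed as
  `ln(max(x, 1)) / ln(150)` so the normal ceiling maps to 1; values
  below 1 clip to 0, avoiding divergence at zero on the positive score
  scale.
* **Correlation** defaults to centered Pearson; the uncentered cosine
  variant is exposed (`centered = FALSE`) because the clustering tool
  this mirrors offers both and the choice is not documented.
* **Tie-breaks**: merges at equal height pick the smallest (index,
  index) pair, with leaves indexed by input order and merged clusters
  by creation order; leaf order puts the earlier-created child on the
  left. No optimal-leaf-ordering, for determinism.
* Average linkage uses the exact group-average (Lance–Williams) update;
  the tests verify equality with a naive re-scan that re-averages all
  original pairwise distances at every step (n ≤ 12), with
  `stats::hclust(method = "average")` as a second cross-check.

Export formats: Newick (via `ape`, heights as branch lengths) and the
tab-delimited clustered-table trio (`.cdt`/`.gtr`/`.atr`) read by
TreeView-style viewers.

## 5. Survival and categorical statistics

* **Kaplan–Meier** via `survival::survfit` (product-limit; censored
  times shrink the risk set without steps).
* **Gehan generalized Wilcoxon**: a weighted log-rank test with weights
  equal to the number at risk (Gehan–Breslow). This variant is
  implemented in the package because the installed survival stack only
  offers the `S(t)^rho` (Peto–Peto) weighting family; Peto–Prentice
  weights are available via `weights = "peto"`. The p-value uses a
  chi-square approximation with `groups − 1` degrees of freedom, or
  exact enumeration of all label permutations when total n ≤ 12.
* **Cox proportional hazards** via `survival::coxph` with Breslow ties
  (Efron behind a flag), tolerance 1e−8, ≤ 50 iterations. Ordinal
  three-level covariates are coded 0/1/2 so hazard ratios are per level
  step. Convergence warnings (separation, infinite coefficients) are
  escalated to diagnostic errors rather than silent output.
* **Fisher exact (2×2)** via `stats::fisher.test` (two-sided p = sum of
  hypergeometric probabilities ≤ the observed table's), **Pearson
  chi-square (r×c)** via `stats::chisq.test` without continuity
  correction; when any expected count is below 5 the result is flagged
  and a seeded Monte-Carlo exact p (1e5 tables by default) is attached.
* **Mann–Whitney U** with exact enumeration when pooled n ≤ 12 (valid
  under ties, unlike the textbook exact distribution) and a
  tie-corrected, continuity-corrected normal approximation otherwise.
* **Censoring convention**: deaths from other causes are coded
  `event = 0` (cause-specific survival). **No multiplicity correction**
  is applied to pairwise group comparisons; p-values are reported raw.

## 6. What the synthetic generators emulate

The generators provide seeded inputs with the statistical structure each
stage assumes; they are first-class, tested code.

**Expression fixture** (`generate_expression_fixture`). Background
signal is log-normal (meanlog `log(50)`, sdlog 1): positive and
right-skewed like MAS5 scores. Planted markers draw normal-panel values
uniform on [1, 100] and at least `k` tumor values at or above 600; each
decoy class violates exactly one criterion (normal-leaky: one panel
tissue at 300–3000; tumor-weak: tumors capped at 400; tumor-rare: high
in at most `k − 1` tumors). A post-check damps any background probe
that would pass the screen by chance, so the screen's answer set equals
the planted set *by construction* — the identifiability tests verify
this with an independent brute-force filter. Default sizes: 10,000
probes (the probe universe of the motivating screen is of ambiguous
size, so this is configurable), 13 normal tissues (the ten-tissue panel
plus the three excluded gastrointestinal tissues, one sample each), 56
tumors. Not emulated: probe-level microarray physics, MAS5 itself,
probe–gene structure, inter-sample normalization artifacts — so passing
tests show the *selection logic* is right, not that the thresholds are
optimal for real arrays.

**TMA fixture** (`generate_tma_fixture`). Each case gets a latent
subgroup (default weights 30/30/38/8, the observed composition of the
motivating 106-case cohort); its primary-lesion (CDH17, CLDN18)
aggregate is drawn uniformly inside the latent group's score box, so
the classifier recovers latent labels exactly. Duplicate cores split
the aggregate with a core-to-core difference of at most
`replicate_noise` (default 2; with 0, only parity-compatible aggregates
are drawn). Nodal aggregates are the primary value ± 2 (clamped),
mimicking the observed primary–nodal correlation; individual LN cores
go missing with rate 0.1 by default (nodal cores without a cancer
component). Not emulated: observer disagreement beyond the noise bound,
staining-intensity variation, and any real dependence between subgroup
and missingness.

**Survival fixture** (`generate_survival_fixture`). Exponential event
times per group, independent exponential censoring, administrative cap.
Defaults: hazards 2e−4/day for Group 1 and 5–6e−4/day for the rest,
censoring 2e−4/day, 10-year cap — chosen once to give the
better-prognosis group roughly a third the hazard of the others at a
realistic advanced-gastric-cancer scale. Constant hazards are a
simplification; real cohort hazards are not exponential.

## 7. Test and simulation sizes

The suite validates each engine against an independent oracle at sizes
where the oracle is exact and fast: random screens up to 200 × 50
probes/samples, agglomeration up to n = 12, exhaustive enumeration for
Fisher/Mann–Whitney/permutation tests up to pooled n ≤ 12, a 2,000-rep
null simulation for the Gehan test's type-I error (50 per arm), and a
500-rep parameter-recovery simulation for the Cox model (n = 500, true
hazard ratio 2, CI coverage ≈ 0.95). These sizes make the oracles
exhaustive or the Monte-Carlo error negligible relative to the asserted
tolerances.

## 8. Known limitations

* Patient-level results of the motivating study (group sizes, hazard
  ratios, survival curves) are not reproducible here because the TMA
  and clinical data are not deposited; those components are validated
  by construction recovery and simulation instead.
* The Gehan implementation's chi-square approximation is first-order;
  for very small groups use the exact permutation option.
* Band schemes assume integer 0–20 scores; fractional IHC scores are
  rejected rather than rounded.
* The greedy panel selector optimizes raw coverage only (no costs, no
  redundancy constraints).
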