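---
title: "Methods: consensus-map meta-QTL analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus-map meta-QTL analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mqtlmeta)
```

## The problem

QTL mapping studies for abiotic-stress tolerance in chickpea (and crops
generally) each report loci on their own population-specific linkage map,
with their own marker set, environments and precision. A locus that is real
and stable should recur across studies, but the reports cannot be compared
until all positions live on one coordinate system and the clustering of
reported peaks is modelled explicitly. That is what this package does:
curate the multi-study catalog, build a consensus map, project every QTL
onto it, cluster the projected peaks into meta-QTL (MQTL), and carry the
MQTL through to physical coordinates, validation and candidate genes.

## The mixture model and its assumptions

On one linkage group, let $x_i$ be the projected peak position of QTL $i$
and let $\sigma_i$ be fixed from its projected 95% CI,
$\sigma_i = (\mathrm{CI}_{hi} - \mathrm{CI}_{lo})/3.92$ (the normal-CI
relation $\pm 1.96\sigma$). The model is

$$x_i \sim \sum_{k=1}^{K} \pi_k \, N(\mu_k, \sigma_i^2),$$

a one-dimensional Gaussian mixture in which the variances are **known and
per-observation**, not free component parameters. This heteroscedastic
form is the defining feature of QTL meta-analysis: a precisely mapped QTL
(narrow CI) pins its component mean down hard, while a vague one barely
moves it, and it is what makes post-hoc MQTL CIs far narrower than any
member QTL (down to a few hundredths of a cM when many precise QTL
coincide). The free parameters are the $K$ means and the mixing
proportions, $p = 2K - 1$.

Assumptions worth stating: reported CIs are approximately normal and
honest; projection errors are small relative to $\sigma_i$; QTL from
different studies are independent draws (pseudo-replication across related
populations is *not* modelled); and every QTL belongs to some component —
there is no explicit outlier class, so background loci either join a
component or earn one of their own.

Fitting is EM. The E-step computes posteriors $r_{ik}$ in log space; the
M-step is a precision-weighted mean
$\mu_k = \sum_i r_{ik} x_i / \sigma_i^2 \big/ \sum_i r_{ik}/\sigma_i^2$
and $\pi_k = \bar r_{\cdot k}$. The log-likelihood is monotone across
iterations (asserted in the tests); for $K = 1$ the closed form is the
precision-weighted mean, which the tests check to $10^{-8}$, and on tiny
instances the EM optimum is checked against a brute-force grid oracle.

## Choosing the number of MQTL

For each group the model is fitted for $K = 1, \dots, K_{\max}$ and five
criteria are computed: AIC ($-2\ell + 2p$), AIC3 ($-2\ell + 3p$), AICc
(AIC $+\, 2p(p+1)/(n-p-1)$, $+\infty$ when $n \le p+1$), BIC
($-2\ell + p\ln n$), and AWE ($-2\ell_c + 2p(3/2 + \ln n)$, with $\ell_c$
the posterior-weighted complete-data log-likelihood). Each criterion votes
for its minimiser; a $K$ with at least three of five votes wins, otherwise
the smallest $K$ among the most-voted. Groups with more than 10 QTL get
the full sweep ($K_{\max} = \min(n_{\text{distinct}}, 15)$ by default);
smaller groups are capped at $K_{\max} = 4$, a regime the sweep rule was
not designed for and that real chromosome-level catalogs rarely enter.

Each MQTL's 95% CI is
$\hat\mu_k \pm 1.96\big/\sqrt{\sum_i r_{ik}/\sigma_i^2}$; primary members
are assigned by maximum posterior; a QTL is additionally a *shared* member
of every MQTL whose CI overlaps its own. The MQTL PVE is the mean
`r2_pct` of its primary members — the literature does not pin down a
summary rule, and the mean is the transparent choice; it is documented
here precisely because other choices (max, precision-weighted mean) are
defensible and would change the reported values. Components that end up
with no primary member are merged into their nearest neighbour and logged.

## Catalog curation parameters

* LOD = likelihood ratio / 4.6; studies that only declared "LOD threshold
  3" have missing LODs set to 3 (flagged).
* Missing 95% CIs are imputed from the population design:
  $530/(R^2 N)$ cM for F2:3 and backcross, $163/(R^2 N)$ for RILs, with
  $R^2$ as a **proportion** (a percent reading would give sub-0.3 cM
  intervals for typical designs, inconsistent with observed projected
  CIs). No constant exists for MAGIC designs: such records need explicit
  CIs or are flagged `not_projectable` — never silently given a constant.
* Explicit CI bounds always take precedence over imputation.
* Multi-environment duplicates collapse to the highest-PVE instance; ties
  break by higher LOD, then first occurrence. Identity is
  `(study, qtl_id)`, with a fallback on `(study, trait, group, flanking
  markers)` since the literature keys on "the same QTL" without defining
  identity.

## Consensus map construction

Redundant within-map marker names get positional suffixes `a`, `b`, `c`.
Marker order comes from a pairwise precedence graph (edge $u \to v$
weighted by the number of maps placing $u$ before $v$); within each
strongly connected component a minimum-weight feedback arc set is removed —
exactly, by subset dynamic programming, up to 12 markers, greedily by net
agreement above that — and the DAG is linearised with mean-position
tie-breaking so the order is deterministic and interleaves map-private
markers sensibly. Positions minimise the total absolute deviation from
each map's inter-marker distances subject to monotonicity, with each map
contributing distance constraints between markers at most
`interval_parameter` apart in its own order; the L1 problem is solved by
coordinate descent on the inter-marker gaps with weighted-median updates,
whose even-count median lands on the interval midpoint — the documented
tie rule (two maps disagreeing 4 vs 6 cM place the marker at 5). The
sweep `intervals = 1:3` yields one candidate consensus per parameter;
per-map RMSE against each candidate is computed on raw positions (no
affine rescaling — none is defined for the published procedure), a map
whose pooled RMSE exceeds 3x the median is dropped and the candidate
re-merged once (the "poorly represented map" rule; configurable), and the
candidate with the least mean RMSE wins, ties to the smallest parameter.

The per-group summary reports density = markers/cM rounded to 2 decimals,
and the average density as the *mean of the per-group unrounded
densities* — on the published chickpea table this reading reproduces the
printed average (5.05) while total/total (4.49) does not.

## Projection

Each QTL maps through the piecewise-linear transform defined by the
anchor markers its study map shares with the consensus; the peak and each
CI bound use their own flanking pair, preserving monotonicity across
anchor intervals. QC rejects projections with a local scale ratio outside
$[0.2, 5]$, peaks extrapolated more than 10 cM beyond the shared span, or
degenerate (zero-length) anchor intervals; all thresholds are
configurable defaults, since the published procedure names none. The
published account attributes some projection failures to "low AIC
values", which conflates projection with the downstream model selection;
here projection QC and meta-analysis are kept strictly separate.

## The synthetic generator

`simulate_mqtl_study()` emulates the statistical shape of the published
chickpea compendium: 8 linkage groups spread over 139.64–392.7 cM, 21
studies of 126–1200 individuals (80% RIL / 10% F2:3 / 10% MAGIC), 72 QTL
per study (1512 total), LOD in [2, 54.9], and PVE from a mixture with
0.75 weight on U(2, 10), 0.20 on U(10, 25) and 0.05 on U(25, 76.715),
matching the described "mode in 5–10%, tail to 76.7" shape. QTL peaks
scatter around true MQTL components with the sd implied by the CI formula
at the drawn $(N, R^2)$; 5% are uniform background. The physical layer is
a monotone piecewise-linear cM-to-bp map (~1 Mb/cM with jitter), MTAs
normal around true MQTL, genes at a configurable density with a
description vocabulary including stress keywords and "uncharacterized
protein". Everything derives from one seed through named substreams, so
identical configs are byte-identical.

What it does **not** emulate: linkage disequilibrium, marker ascertainment,
shared parents between studies, trait-specific effect architecture, or
recombination interference (only monotonicity of cM vs bp matters
downstream). Passing recovery tests on this generator therefore shows the
estimator works when its assumptions hold — not that real catalogs satisfy
them.

## Recovery experiments and problem sizes

The recovery experiment plants 3 true MQTL at 40/80/120 cM on one 160 cM
group (separation 40 cM), 200 QTL from 20 studies, and no background; over
40 seeded replicates the 3-of-5 vote must pick $K = 3$ in at least 85%,
with means within 3 standard errors. Background is excluded deliberately:
with 5% uniform background the mixture is misspecified and extra
components lawfully absorb background points that carry tight CIs, which
is a property of the model (and visible in the end-to-end example in the
README), not an estimation failure. Test problem sizes throughout
(200-QTL recovery runs, 150-QTL end-to-end runs, 25–40 replicate loops)
were chosen as the smallest sizes at which the asymptotic behaviour under
test is already stable.

## Numerical choices

* EM: $|\Delta \ell| < 10^{-6}$ or 500 iterations; 10 restarts from
  quantile-spread means with seeded jitter; all restart seeds derive from
  one user seed.
* $\sigma$ floor 0.1 cM, so zero-width reported CIs cannot produce
  singular likelihoods.
* L1 gap fitting: coordinate descent to $10^{-9}$ max gap change, 400
  passes cap; deterministic update order.
* Printed-table roundings use round-half-up, matching how the published
  densities (e.g. 2.10) were evidently rounded.
* Physical intervals are closed, 1-based; published start/stop pairs may
  be inverted and are normalised by min/max before overlap tests; strand
  is ignored for gene windowing.

## Known limitations

* MQTL PVE summarisation (mean of members) is a documented convention,
  not an identified quantity.
* The breeder's rule thresholds (< 2 Mb, > 10% PVE) and the candidate-gene
  gate (> 30% PVE, 1 Mb flanks) are the field's published conventions,
  exposed as arguments but not derived from any optimality argument.
* The peak cM-to-bp interpolation between flanking markers is a stand-in
  for an unpublished peak formula; within small intervals the choice is
  immaterial, across 20 Mb intervals it is not.
* Order-conflict resolution above 12-marker components is greedy; exact
  behaviour is only guaranteed where the exact solver runs.
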