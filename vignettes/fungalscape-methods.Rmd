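---
title: "Methods: regional soil-mycobiome survey analysis with fungalscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional soil-mycobiome survey analysis with fungalscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fungalscape)
```

## Scope

fungalscape implements the post-clustering half of a regional soil fungal
ITS metabarcoding study: it starts from an OTU-by-sample count table
(clustering, chimera removal and read filtering are upstream concerns) and
carries it through sample/OTU quality control, taxonomic and functional
annotation, diversity transforms, niche modelling along environmental
gradients, distance-based community statistics, and checkerboard
co-occurrence analysis. Because the real survey data of interest are not
redistributable, the package ships a synthetic-survey generator with known
ground truth; every stage is exercised and tested end to end against that
truth.

## The synthetic survey generator

The generator emulates the structure of a regional soil survey:

* **Plots and environment.** Plots carry coordinates on a rectangle,
  sampling dates over two seasons, collector labels, habitat types, and
  soil chemistry. Soil pH (KCl scale) is uniform over the configured range
  (default 3–8). Calcium is constructed rank-correlated with pH
  (calcareous soils are base-rich; Spearman ≈ 0.7 by construction), the
  C/N ratio negatively so; P, K, Mg, C are lognormal; δ¹⁵N and δ¹³C are
  normal. Tree basal-area proportions come from a habitat-specific
  simplex; open habitats are frequently treeless. The ectomycorrhizal
  (EcM) plant percentage is the sum over EcM tree genera.
* **OTU niches.** Each OTU has a Gaussian niche on pH: expected relative
  abundance ∝ `base × exp(-(pH - opt)² / (2 w²))`, times the host tree's
  basal-area share for host-linked EcM OTUs (zero where the host is
  absent). Counts are multinomial at a lognormal depth clamped to
  [504, 12763] reads; the lognormal parameters (`meanlog` 7.675, `sdlog`
  0.484) give a clamped mean near 2420 and SD near 1240 reads, the
  regime the pipeline is designed for. Niche optima are drawn from a
  pool extending 1.5 pH units beyond the sampled range: a regional
  species pool is always wider than any one gradient, and the overflow
  keeps the community-level expected abundance roughly flat inside the
  range, so one OTU's relative abundance is not distorted by a trending
  denominator. Widths default to 0.6–1.6 pH units — narrow enough that
  unimodality is detectable across a five-unit gradient, wide enough
  that abundant OTUs are observed over most of it.
* **Molds and artifacts.** OTUs are assigned genera from a small built-in
  synthetic traits table covering EcM lineages and exploration types,
  saprotroph guilds, and the four mold clades (Mortierellales,
  Umbelopsidales, Mucorales, Pezizomycotina molds). Mold OTUs receive
  moderate base abundances (lognormal, meanlog 0.3, sdlog 0.5): molds are
  ubiquitous at the few-percent level, and in the generator only the
  explicit spoilage process pushes a single mold OTU above the flagging
  thresholds, so the truth labels are exactly the flaggable samples.
  Spoilage inflates one mold OTU of a designated group to a share drawn
  uniformly in (threshold + 0.02, 0.9]; low-depth samples are
  down-sampled below 500 reads; negative controls carry ≤ 50 noise reads
  and positive controls a fixed 8-OTU mock community.

What the generator does *not* emulate: read-level errors, chimeras,
tag-switching, spatial autocorrelation of community composition (off by
default; a flag adds a smooth spatial gradient), multi-group mold
co-blooms (single-group spoilage is the canonical case; a flag spreads the
bloom over several OTUs), and environmental confounding between pH and
tree composition. Tests passing on these surveys therefore demonstrate the
*machinery* — filtering rules, estimators, null models — not robustness to
every artifact of real sequencing data.

## Quality control

The chain applies, in order: control-sample removal, a < 500-read depth
filter, an OTU blocklist, removal of samples emptied by the blocklist, and
mold-spoilage screening. A sample is spoiled when the relative abundance
of its single most abundant mold OTU exceeds 30 % (Pezizomycotina molds),
15 % (Umbelopsidales) or 15 % (Mortierellales); comparisons are strict, so
a sample sitting exactly at a threshold is retained. Mucorales are
profiled and reported but carry no removal threshold. Shares are computed
after blocklist removal, on the sample's total over all retained OTUs.
Two readings of "most abundant OTU" are possible — the per-sample maximum
or the globally most common mold OTU; the removal rule uses the per-sample
maximum, while `global_top_mold_share()` exports the global-top-OTU share
as a covariate. The report records per-stage sample/sequence/OTU counts
and removed ids, and the chain is idempotent. Per-guild analyses
additionally gate samples (< 20 OTUs of the guild; optionally < 100 reads,
used for EcM fungi).

## Taxonomy and function

Identification uses up to ten reference hits per OTU and rank-specific
thresholds: kingdom > 70 % similarity with e-value < 1e-20; phylum and
class > 75 % with < 1e-50; order, family, genus > 80 %, > 85 %, > 90 %.
Only similarity cut-offs are defined for the three deepest ranks, so the
class-level e-value ceiling is inherited there (configurable). At each
rank the passing hits must agree unanimously; any conflict, or an empty
passing set, leaves the rank (and all deeper ranks) unassigned. Hits with
partially empty taxonomy paths count only at ranks where they carry a
label. Functional annotation joins the genus against a traits table;
genera flagged multi-lifestyle require a species-level override row, and
EcM lineage plus exploration type are attached only when the guild is EcM.

## Transforms and diversity

* `logratio_pct(p)` = log₁₀((p + 0.01) / (100 − p + 0.01)) maps
  percentages to a symmetric scale anchored at −4 (0 %), 0 (50 %), 4
  (100 %). Base 10 with the offset applied to both numerator and
  complement is the only variant reproducing all three anchors to
  < 5 × 10⁻⁵.
* Richness is depth-normalised by averaging the raw residuals of two
  least-squares fits — richness on √depth and on ln depth; either alone
  over-corrects at one depth extreme. With constant depths both slopes
  are undefined and the function falls back to mean-centering. Residuals
  sum to zero and are location-invariant.
* Rarefaction is the analytic hypergeometric expectation
  `E[S(m)] = S − Σᵢ C(N−Nᵢ, m)/C(N, m)` (no resampling noise), with an
  option to zero sample-wise singletons — single reads of an OTU in a
  sample, a plausible index-switching signature — before pooling.
  Pooled and per-sample modes are provided; pooled is the default.
* Shannon diversity uses natural logarithms (base is an argument).

## Niche models

Predictor preselection fits one regression random forest (999 trees) on
the candidates plus ten label-shuffled decoy copies of each. The decoys
carry the candidates' marginal distributions but no signal; the largest
decoy importance estimates the level reached by the best *spurious*
in-sample association, and candidates are kept only above
`max(0, largest decoy importance)`. One decoy copy per candidate is not
enough: the strongest of ~20 spurious candidate correlations beats the
strongest of 20 fresh decoys about half the time, so a pure-noise
response would "select" something in roughly half of runs. With a tenfold
decoy ensemble the family-wise false-selection rate is ≈ 1/(1 + 10), and
empirically ~90 % of pure-noise runs select nothing. Importance is raw
permutation importance (mean MSE increase) — reported in raw units, since
percent-increase scaling depends on the forest's error and muddles
cross-response comparison.

Selected predictors are standardized and the response regressed on
linear + quadratic terms per predictor, plus one additive combined model;
variance explained is the OLS R² in percent. Shapes are classified at
α = 0.05 on the coefficient t-tests: no curvature → positive / negative /
flat by the linear term; concave → unimodal if the vertex lies within the
predictor's observed 5th–95th percentile range, saturating
(rise-then-plateau) above it, negative below it; convex mirrors to U /
positive / negative. A sigmoid class cannot be expressed by a quadratic
and is deliberately not emitted. No multiple-testing correction is
applied within a model; Benjamini–Hochberg across responses is left to
the caller (`p.adjust`). Per-OTU models use the log-ratio of the OTU's
relative abundance as response and skip OTUs below a prevalence floor
(default 20 samples).

## Community structure

Bray–Curtis dissimilarity on Hellinger-transformed counts feeds
PERMANOVA, NMDS and environmental vector fitting. PERMANOVA partitions
the Gower-centered inner-product matrix with sequential (type-I) sums of
squares in the user's term order — matching a model-building narrative
where core predictors enter first — with p-values from free permutation
of sample labels, `p = (#{F* ≥ F} + 1)/(n_perm + 1)`. Restricted
permutation (e.g. within collectors) is not implemented; unrestricted
exchange is the assumption. The implementation is cross-checked against
vegan's `adonis2` in the tests and reduces exactly to one-way ANOVA on
Euclidean distances of univariate data.

Moran eigenvector maps use the classical PCNM construction (truncation at
the longest minimum-spanning-tree edge, off-range distances set to four
times the truncation, eigenvectors of the Gower-centered matrix with
positive eigenvalues), applicable to geographic, temporal and
plant-phylogenetic community distances (comdist, comdistnt, PhyloSor
dissimilarity). Temporal distances pool February–April to mid-March and
November–January to mid-December before differencing, since little
community turnover is resolvable within the dormant-season windows. NMDS
minimises Kruskal stress-1 by monotone regression from 20 random starts.

## Co-occurrence

The checkerboard C-score of an OTU pair is `(Rᵢ − S)(Rⱼ − S)` on
presence–absence (presence = count ≥ 1 by default; the floor is an
argument). The null model preserves both row and column totals and is
sampled with the trial-swap chain — sequential 2×2 checkerboard swaps
with trial counting, whose stationary distribution is uniform over the
margin-preserving set (the plain swap chain is not uniform). Defaults:
30 000 trial swaps of burn-in, 1 000 between samples, 999 null matrices.
SES = (obs − null mean)/null sd; **positive SES means segregation
(avoidance), negative means aggregation**. Margins that admit no swap
leave the null constant; such pairs are flagged with undefined SES and
p = 1 rather than a spurious zero.

## Numerical choices and problem sizes

Determinism: every stochastic routine takes a seed and is reproducible
bit-for-bit given it. Degenerate inputs (zero-total samples, constant
responses, constant predictors, rank-deficient designs, distance
matrices without positive eigenvalues) return explicit errors, zero-R²
fits, or flagged results rather than NaNs. The test suite runs the
generator at 10–300 plots and 10–150 OTUs, PERMANOVA calibration on 1 000
null data sets of 12 samples, swap-null enumeration on a 3×3 margin
class, and the niche benchmarks on 20 seeds of 300-plot surveys — sizes
chosen so the full suite completes in minutes on one core while every
guarantee is still exercised at its stated strength.

## Known limitations

The taxonomy module consumes tabular best-hit files and never touches
sequences; the synthetic traits table covers only the genera the
generator emits and is not a reference database; the PERMANOVA
implementation targets modest n (its permutation loop re-indexes the
centered matrix, quadratic per permutation); GDM-style dissimilarity
splines, structural equation models and richness map extrapolation are
out of scope. The interface is function-based (tibbles in, tibbles out);
there is no shell entry point — `scripts/acceptance.R` shows the
programmatic route.
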