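---
title: "Pathway-centric mining of chemoactivity and constitutive expression"
author: "chemopath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-centric mining of chemoactivity and constitutive expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemopath)
```

## The problem

Screening a compound against a panel of tumor cell lines produces a
*chemoactivity profile*: one GI50-derived value per cell line, describing
which lines the compound inhibits. Untreated (constitutive) expression of
the same lines is measured once. If a pathway's genes correlate, as a
coordinated group, with a compound's chemoactivity profile, that pathway
is a candidate explanation for the compound's cellular response — and its
genes are candidate response biomarkers. `chemopath` implements this
mining strategy end to end: profile filtering and normalization,
self-organizing-map (SOM) clustering of profiles, signed Kruskal-Wallis
pathway scoring, iterative t-test selection of discriminating genes,
cross-validated linear-discriminant evaluation, and hypergeometric overlap
enrichment — plus a synthetic panel generator with planted ground truth so
every stage is testable without external data.

## Chemoactivity normalization

Raw profiles are filtered first: a profile must report values in strictly
more than `minCellsReported` cell lines (default 40) and show a
coefficient of variation (sd over |mean|) of at least `minCV` (default
0.05). Minimal variation means pan-cytotoxicity or inactivity — nothing to
correlate. The CV denominator gets a floor of 1e-12; a profile centered at
zero is scored by its sd alone.

Normalization is two-stage (`normalizeChemo()`): first *across tumor cell
type* — each cell line's column is standardized over all compounds,
removing systematic biases from generally hyper- or hypo-sensitive lines —
then *within each record*, z-scoring each compound over its non-missing
cells. After this, positive values mark sensitive cells and negative
insensitive ones. Whether the first stage should center only or fully
standardize is genuinely open; full standardization is the default
(`stage1 = "zscore"`), with `"center"` available. Stage 1 is skipped when
re-normalizing an already-normalized set (making the operation idempotent)
and for single-compound sets, where per-cell statistics over one value are
undefined.

One consequence worth knowing: per-cell centering subtracts a mixture of
all compound-cluster profiles from each profile. Profiles therefore
acquire small anti-correlated components of *other* clusters' responses,
and a handful of weakly responding cells can flip sign relative to the
unnormalized truth. This is inherent to the normalization, not an
artifact of this implementation; the trimming step (below) is what removes
such cells.

## SOM clustering of profiles

Tens of thousands of profiles are reduced to a rectangular grid of
prototype ("codebook") profiles by a batch Kohonen SOM (`trainSOM()`). The
production-scale grid is 54 x 37 = 1998 nodes; desk-scale analyses in this
package's tests use 6 x 5 on a 40-compound synthetic panel, which keeps
every stage in seconds while preserving a meaningful top-decile cut.

Missing values are first-class: distances are squared Euclidean over the
observed entries only, normalized by their count, and codebook updates use
only observed components. Each epoch assigns every profile to its
best-matching unit (ties to the lowest node index), then moves every
codebook toward the neighborhood-weighted mean of the assigned samples
with a learning rate decaying linearly 0.5 to 0.01. The Gaussian
neighborhood radius decays linearly from `max(rows, cols)/2` to 0.5. A
final radius of 1 — the other natural choice — leaves each codebook
blended with its grid neighbors, and the mean quantization error then
*rises* over training; at 0.5 the late epochs are effectively
BMU-only and the error settles. Codebooks are initialized from randomly
drawn data rows, so training is fully reproducible given the seed.

Caveats: a grid with exactly as many nodes as well-separated clusters can
leave a dead node and merge two clusters (a known SOM failure mode); use
more nodes than expected clusters. Early epochs can raise the quantization
error from a lucky data-row initialization before the shrinking
neighborhood brings it down, so the error log should be judged by its
tail.

## Pathway H-scores

For a given chemoactivity profile (a node codebook, or a single raw
compound profile) every measured gene receives a Pearson correlation
computed over jointly observed entries (undefined below 3 overlaps or at
zero variance). For each pathway, member and non-member genes are jointly
ranked and compared by the two-group Kruskal-Wallis statistic with midrank
ties and tie correction,

$$H = \frac{12}{N(N+1)} \sum_g n_g\left(\bar R_g - \tfrac{N+1}{2}\right)^2
\Big/ \left(1 - \frac{\sum_t (t^3-t)}{N^3-N}\right),$$

with a chi-square (1 df) p-value. The ranked quantity is the correlation
*strength* |r|: a chemo-important pathway's genes sit skewed toward the
extreme correlation values, and coherent pathways legitimately mix
positively associated genes (over-expressed in sensitive lines) with
negatively associated ones — ranking raw signed correlations would let the
two halves cancel and score exactly the most interesting pathways near
zero. The score is signed by the comparison of group means of the ranked
quantity, so positive H means member genes out-correlate non-members on
average; the sign invariant `sign(H) = sign(mean_r_in - mean_r_out)` holds
exactly on every record. Gene-set membership is matched to expression rows
exactly and case-sensitively (an explicit case-insensitive switch exists):
silent case-folding produces irreproducible overlaps.

Because H grows with member count at fixed rank shift, a large moderately
shifted pathway can outscore a small extreme one; top-percentile selection
(`topPercentilePathways()`, `ceiling` count, boundary ties included,
remaining ties alphabetical) is therefore the right consumer of these
scores, not single-best ranking.

## Discriminating genes: pool and trim

For a node, the union of member genes of its top-decile pathways is
filtered to those significantly correlated with the reference profile
(two-sided p from $t = r\sqrt{(n-2)/(1-r^2)}$, nominal 0.05). Genes are
classed once, by initial correlation sign: negative r = over-expressed in
insensitive cells, positive r = over-expressed in sensitive cells. Cells
are classed by chemoactivity sign (exactly zero counts as insensitive, a
determinism tie rule).

Trimming (`trimDiscriminant()`) alternates two Student's t-test sweeps
(pooled variance by default, Welch by config): drop genes whose expression
does not separate the current sensitive vs insensitive cells at
`trimAlpha`, then drop cells whose expression does not separate the
current over vs under gene groups. Both tests additionally require the
difference to point the way the class claims — a nominally sensitive cell
whose under-expressed group dominates contradicts its class and is
dropped however significant the difference. The four response classes are
directional by definition, and without this rule cells whose normalized
chemoactivity sign flipped (see above) would survive and silently cap
downstream accuracy. A degenerate test (any group below two values) drops
the tested item. Iteration stops when a full pass drops nothing (both
separability invariants then hold), when a class empties (reported as a
failure naming the class), or at `maxIter` (default 100, far above the
structural bound of |pool| + |cells| passes).

No multiple-testing correction is applied inside trimming; the nominal
threshold is justified empirically by the shuffle-null simulation
(`shuffleNullFPR()`): each permutation round shuffles every retained
gene's values across the retained cells and re-runs the full two-step
trim; the estimate is the fraction of shuffled genes that survive.
Survival requires jointly passing the gene-dimension test, with the right
direction, inside a cell set that itself still passes — a conjunction that
lands orders of magnitude below the nominal level (the acceptance script
computes it on every run).

## LDA evaluation

`ldaCvAccuracy()` scores a gene panel by stratified k-fold (default 5)
cross-validated Fisher LDA; the consensus accuracy is the fraction of all
cells predicted correctly when held out. Folds are derived from the seed
and the *sorted* cell ids, so column order never changes the partition,
and `k = n` degenerates to exact leave-one-out. The discriminant solves
$(S_w + \lambda I)\,w = \mu_1 - \mu_0$ with $\lambda = 10^{-8}\,
\overline{\mathrm{diag}(S_w)}$: the ridge makes the system positive
definite when genes outnumber cells and — unlike a pseudo-inverse with a
relative singular-value tolerance — keeps directions whose within-class
variance vanishes, which are exactly the ones Fisher's criterion rewards
most. For well-conditioned problems it is numerically invisible (the
direction matches `MASS::lda` to machine cosine). Missing expression
entries are mean-imputed per gene from training-fold means only.

`methodComparison()` contrasts the pathway route with a conventional
baseline (`conventionalSelection()`: all genes ranked by correlation
significance, cut by alpha — the default, 0.05 — or by top percentile of
|r|). The baseline deliberately ignores pathway structure, so it should
select from the *unfiltered* expression matrix (`exprAll`). All four arms
(pathway/conventional x trimmed/untrimmed) of one unit share fold seeds,
making the comparison paired. On synthetic panels the pathway-trimmed arm
reliably uses substantially fewer genes; its accuracy advantage is real in
the mean but small relative to panel-to-panel noise at desk scale, because
the baseline's extra genes are selected on the full panel and so carry
panel-internal predictive value. The published-scale contrast (hundreds of
conventional genes against tens of cells) is not reachable on a
desk-scale synthetic, and the comparison here should be read as a
direction check on gene-count parsimony first.

## Concordance and noise experiments

`pathwayOverlapConcordance()` asks whether raw per-compound profiles and
their cluster codebook select the same top pathways: nodes are sampled,
raw member profiles drawn (with replacement when a node holds fewer than
requested), and the overlap fraction of top-decile pathway sets computed.
`noiseDegradation()` adds white noise to expression, bisecting the noise
sd until the mean per-gene original-vs-degraded correlation hits a target
(one noise pattern drawn once and scaled, so the bisection is monotone and
converges; contract tolerance 0.02), then re-runs pool and trim. The
candidate pool contracts reliably — attenuation pushes marginal
correlations below the significance gate — while the post-trim count on a
small panel can move either way, because the trim also discards noisier
cells; both ratios are reported.

## Enrichment

`enrichmentReport()` tests gene-set over-representation of a query (for
example, a trimmed discriminant set) by the hypergeometric upper tail
$P(X \ge k)$, evaluated in log space. The universe is the set of genes
that survived expression filtering — overlap probabilities must condition
on what was measurable, so printed p-values are not comparable with runs
against a whole-genome universe. Only enrichment (not depletion) is
tested; sets sharing fewer than `minOverlap` (default 2) genes are not
reported; ranking follows raw p (ties alphabetical) with
Benjamini-Hochberg values reported alongside.

## The synthetic panel

`generatePanel()` emulates the structure the real screen provides: 59
cells; compound clusters (4 x 10 by default) sharing a +/-1 base
sensitivity profile over a drawn sensitive subset (both classes at least 5
cells, drawn between 20 and 39) plus per-compound Gaussian noise; one
planted pathway per cluster whose member genes carry expression
$g = \pm\,\frac{\text{effect}}{\sqrt 2}\, s + N(0, \sigma^2)$ against the
cluster's base profile $s$, half positively and half negatively
associated so all four response classes are populated; 600 genes total, 40
pathways of 8-25 members, background genes standard normal and background
pathways drawn from background genes only. The planted correlation with
the base profile has closed form
$\text{effect}/\sqrt{\text{effect}^2 + 2\sigma^2}$, verified at a
500-cell panel in the tests. Defaults `effectSize = 1.5`, `noiseSd = 0.5`
define the study condition for truth recovery; `missingRate = 0.02`
reflects the sporadic missingness of real GI50 records while keeping
nearly every profile above the coverage rule. The orchestrated pipeline
caps the coverage rule at panel size minus one so the strict "more than"
reading survives panels smaller than the published one.

What the generator does *not* emulate: tissue-of-origin correlation
structure among cell lines, dose-response-derived noise, overlapping or
hierarchical pathways, and the continuum of weak real effects between
"planted" and "pure noise". Passing tests therefore demonstrate that the
machinery recovers planted coordinated signal under honest noise and
missingness — not that real-data effect sizes or printed p-values are
reproduced.

## Problem sizes and runtime choices

Tests and the acceptance script run desk-scale configurations chosen so
the full suite completes in minutes: 6 x 5 maps with 30 epochs for
pipeline work, the 54 x 37 production grid exercised once (10 epochs) to
verify capacity, 10-25 seeded panels for the stochastic rate checks,
10^4 permutations for the shuffle null, and 20 x 5 node/member samples
for concordance. All randomness flows from a single seed argument.

## Known limitations

* The accuracy half of the pathway-vs-conventional comparison is a
  near-tie at desk scale (see above); gene-count parsimony is the robust
  direction.
* Chi-square p-values for H are asymptotic; no permutation p-values are
  offered.
* Flat gene sets only: no GO-graph propagation, no probe-level
  processing, no cross-platform harmonization.
* The SOM offers rectangular grids only, and node count should exceed the
  expected cluster count.
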