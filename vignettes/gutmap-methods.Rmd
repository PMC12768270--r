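---
title: "Methods: cross-species mapping of gut anteroposterior organization"
author: "gutmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species mapping of gut anteroposterior organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutmap)
```

## The problem

Adult bilaterian guts are segmented tubes. Bulk RNA-seq of dissected
segments, ordered from mouth to anus (the anteroposterior, AP, axis),
carries a spatial signal at three scales: (i) within a species, segments
organize into molecular *compartments* — an anterior "block" of segments
with uniformly high mutual transcriptome correlation, followed by a
posterior "gradient" whose pairwise similarity decays with AP distance,
with the transition typically at a sphincter; (ii) across species, a subset
of transcription-factor (TF) programs occupies equivalent relative AP
positions, forming conserved AP *modules*; (iii) given imputed segment
identities, small *marker sets* discriminate them. `gutmap` implements this
chain — preprocessing, integration over orthogroups, seriation, compartment
calling, AP-association screening, module extraction and sparse
discriminant marker selection — together with a generator of synthetic
multi-species studies with planted truth, which is how every stage is
validated.

## Per-species preprocessing

Counts move through a fixed stage order (`raw → filtered → normalized →
batch_removed → segment_level → zscored`), enforced by stage tags so no
stage can be skipped or repeated.

- **Filtering**: a gene is kept if it has ≥ `min_count` (default 10) raw
  counts in at least `min_samples` samples, defaulting to the number of
  replicates — a gene must be detectable in one full segment's worth of
  samples. The 10-count threshold is the conventional a-priori choice for
  bulk libraries; it is deliberately not data-adaptive.
- **Normalization**: `log2(CPM + 1)`. A variance-stabilizing transform in
  the strict sense is not used: every downstream statistic is either
  rank-based (Spearman correlations), z-scored, or an F-ratio, all of which
  are insensitive to the exact monotone variance flattener. A square-root
  alternative (`method = "sqrt"`) is provided for users who want a
  Poisson-anchored stabilizer.
- **Batch removal**: replicates are batches. Gene-wise two-way linear
  residualization (`limma::removeBatchEffect` with a segment design matrix)
  subtracts batch coefficients estimated jointly with segment means, so
  planted additive batch offsets are removed exactly while segment signal
  is untouched. Designs in which batch is confounded with segment are
  rejected up front.
- **Replicate collapse**: one column per segment (mean over replicates),
  ordered by AP rank. Collapsing happens after batch removal and before
  z-scoring; the display and all segment-level statistics work on these
  profiles. Collapsing before z-scoring was a genuinely open choice — the
  alternative (z-scoring replicate-level columns) changes nothing for
  rank-based statistics and complicates the integrated matrix, so the
  simpler convention was adopted.
- **Z-scoring**: per gene, (value − mean) / sd across segments, with the
  sample (n−1) sd by default — the base-R `scale()` convention —
  configurable to the population sd. Constant genes become all-zero rows
  and are flagged rather than dropped.
- **Variance selection**: `top_variant()` ranks genes by across-segment
  variance (computed on pre-z-score values; z-scoring erases variance
  differences by construction) with lexicographic tie-breaks, defaulting to
  the top 2000.

## R2E seriation

Rank-2 Elliptical seriation orders the rows (or columns) of a matrix so
that a Robinson structure — similarity decaying monotonically away from the
diagonal — becomes visible.

1. **Iterated correlation.** Start from the Pearson correlation matrix
   between items; repeatedly replace it with the correlation matrix of its
   own rows. Each round contracts the spectrum; iteration stops at the
   first matrix with effective rank ≤ 2, where the effective rank is the
   number of eigenvalues above `exp(-13)` (≈ 2.26e-6). The natural-exponent
   reading of that cutoff is the default; `1e-13` is accepted anywhere a
   threshold is taken, as the choice between the two readings is
   immaterial on data with a genuine rank-2 limit. On ordered data a
   handful of iterations suffice (the test suite bounds it at 10; 4–6 is
   typical).
2. **Elliptical ordering.** The leading two left singular vectors of the
   rank-2 matrix place every item on an ellipse; `atan2` of the two
   coordinates gives a circular order. The circle must be cut to obtain a
   linear order: the cut goes at a large angular gap between consecutive
   items. Two numerical details matter here, both deterministic:
   - *Cut refinement.* For series whose end-to-end correlation decays to
     ~0, the iteration can curl the ellipse almost closed, so the true
     endpoint gap is not always the single largest one. Candidate gaps
     within 50% of the maximum (at most 12) are therefore scored by the
     Robinson-violation count of the initial correlation matrix under the
     corresponding rotation, and the best-scoring cut wins. On perfect
     Robinson inputs this restores exact recovery in the rare rotated
     cases.
   - *Over-contraction guard.* Occasionally an iteration jumps from rank 3
     directly to rank 1 (a line), where angular order is lost; the previous
     matrix's leading two singular vectors are then used instead.
3. **Orientation.** A seriation and its reversal are equivalent; the
   direction is fixed by an `anchor` item required to fall in the first
   half (e.g., the known anterior-most segment), or, absent an anchor, by
   requiring the lexicographically smaller of the two end items first.
   SVD sign indeterminacy is removed by forcing each singular vector's
   largest-magnitude entry positive, so results are reproducible across
   BLAS implementations.

`constrained_cluster()` partitions a seriation into contiguous blocks by
agglomerative merging of adjacent blocks under average linkage on
(1 − correlation) — hierarchical clustering that cannot break the seriation
order.

## Compartments

`segment_correlation()` computes Spearman correlations between segments on
the most variant genes (top 2000 by default; Spearman makes the result
invariant to the normalization's monotone transform). `detect_boundary()`
scans every interior cut b of the AP-ordered series and scores the
bipartition as

> score(b) = mean within-compartment correlation (both compartments)
> − mean cross-compartment correlation,

taking the argmax, ties to the most anterior cut. The symmetric form —
rather than an anterior-only coherence term — is what makes the detector
exactly invariant under reversal of the segment order and exactly flat on
fully exchangeable segments (which trigger a degenerate-profile warning and
return the smallest candidate). On two-block equicorrelated data the argmax
is provably the true split. The boundary is reported as the 1-based AP rank
of the first posterior segment, matching anatomical tables.

Compartment character is then a decay question: within each compartment,
pairwise correlation is regressed on segment distance; a compartment is a
*block* if the decay slope's 95% CI includes zero or the slope is below
`beta_min` (default 0.02 correlation units per segment), else a *gradient*.
The slope threshold is this package's construction — "graded" is not
otherwise quantified — and is configurable; compartments with too few
distinct distances to fit a slope default to *block*.

## Orthology and integration

Orthogroups arrive in OrthoFinder's `Orthogroups.tsv` dialect. Size filters
drop orthogroups with more than 120 genes outright and those with more than
80 genes whose per-species counts are unbalanced — operationalized as
(max per-species count) / (min nonzero per-species count) > 3, a definition
this package had to fix since "unbalanced" is otherwise informal; both
thresholds and the ratio are arguments.

1-to-many orthology is resolved to the **best ancestral orthologue**: for
each species, the paralog with the highest mean Smith–Waterman local
alignment similarity (BLOSUM62, gap open 2, gap extension 0.1 — permissive
penalties suited to within-orthogroup comparisons) to all members from the
*other* species. Alignment runs in a compiled double-precision Gotoh kernel
that allows transitions between the two gap states (with penalties this
low, a deletion–insertion pair can legitimately outscore a poor
substitution). Scores are normalized by the geometric mean of the two
self-alignment scores, making them length-comparable in \[0, 1\]; raw
scores are available (`normalize = FALSE`), and within an orthogroup of
similar-length proteins the ranking — the thing that matters for
resolution — is unchanged by the normalization. Ties break to the
lexicographically smaller gene id; the margin to the runner-up is recorded
but deliberately not enforced.

TF flags expand to the orthogroup level (any flagged member flags the
group, idempotently), and a manual override table can dissolve and regroup
orthogroups — the mechanism for Hox-like families where automatic
orthogroups fragment paralogue positions; a 21-groups-to-8-groups
regrouping is expressible directly.

`integrate_species()` builds the cross-species substrate: rows are
orthogroups whose representative gene survived expression filtering in
*every* species, values are each species' z-scored representative profile
concatenated over segments. Within-species z-scoring is the step that makes
columns cluster by AP position rather than by species, and the test suite
asserts exactly that (adjusted Rand index of a column clustering against
species labels vs against relative-AP labels).

## AP association, terminal markers

Per orthogroup and species, `fit_ap_trend()` regresses the profile on an
orthogonal polynomial in AP rank (degree 3, reduced to n−2 when segments
are few) and tests against the intercept-only model with an exact F-test.
With 5–10 support points this is a deterministic, parameter-light smooth
trend test: affine-invariant, exactly calibrated under an i.i.d. null (the
suite checks type-I error at 0.05 over thousands of null profiles), and
powered against bumps of the generator's width on the log-expression scale,
where a planted bump spans ~4 log2 units against segment-level noise of a
few tenths. Power falls steeply below ~8 segments — with 7 segments the
cubic leaves only 3 residual df — which is the dominant limitation of the
screen and the reason short gut series recover fewer conserved orthogroups.

`screen_conserved()` applies Benjamini–Hochberg within each species across
tested orthogroups and flags orthogroups with q < 0.05 in all species
(a `min_species` relaxation is available). Terminal classification works on
the fitted profile: the primary peak's relative position assigns
`anterior` (first tercile) or `posterior` (last tercile); a secondary local
maximum in the opposite tercile reaching ≥ 50% of the primary amplitude
above the profile mean upgrades the call to `both`; anything else is
`internal`. The 50% ratio is a package construction, configurable. The
cross-species terminal flag requires every species to be terminal at some
end but not all at the same single end — the signature of terminus markers
that swap ends between lineages.

## Modules

Restricted to the conserved set, gene–gene Spearman correlation over all
pooled (species, segment) columns feeds R2E seriation, and the seriation is
cut into k contiguous modules by the constrained clustering above. The
module count, when `k = "auto"`, minimizes BIC under a segmented
mean-profile model: each gene's pooled profile is modelled as its module's
mean profile plus Gaussian noise, and k pays `k · p · log(N)` (p pooled
columns, N matrix entries). Two simpler rules were evaluated and rejected
on planted data: maximizing mean within-module correlation minus mean
between-adjacent-module correlation is monotone decreasing in k (the
between term at small k contains distant, anticorrelated pairs) and always
returns k = 2; merge-cost elbow rules misfire on edge modules whose
truncated bumps are internally noisier. The BIC rule recovers five planted
modules with ARI > 0.8 in ≥ 80% of replicates at the generator's study
conditions, which is what the acceptance suite asserts. Modules are
renumbered anterior→posterior by the cross-species median relative peak of
their mean profiles, so module indices follow the axis regardless of the
seriation's orientation. `module_position()` then flags, per module,
species whose peak falls in a different compartment than the cross-species
majority — shifted ("anteriorised") modules.

## Sparse PLS-DA

Marker discovery for imputed segment-identity groups is a from-scratch
sparse PLS discriminant analysis. Classes are one-hot encoded and centered;
per component, the weight vector is the leading left singular vector of the
feature-by-class cross-covariance, hard-thresholded to the `keepX`
largest-magnitude entries (signs kept, exact count enforced under ties by
magnitude-then-name order) and renormalized — the keepX semantics of
lasso-style sparse PLS. Scores deflate both matrices before the next
component, classification is by nearest class centroid in score space, and
prediction uses the standard PLS rotation `W (PᵀW)⁻¹`. In the unpenalized
two-class one-component limit the weight direction equals the class-mean
difference (asserted to 1e-8 cosine), and the unpenalized direction agrees
with an independent PLS-DA implementation.

`cv_select_keepX()` uses leave-one-species-out folds — samples within a
species are not exchangeable, so species is the honest CV unit — with a
stratified k-fold fallback (and warning) for single-species data. Balanced
error (mean of per-class error rates) guards against fold-level class
imbalance. The chosen keepX is the smallest whose error is within a
tolerance (default 0.02) of the minimum: the "optimal sufficient" marker
set. The keepX grid and tolerance have no canonical values; the defaults
are package choices, surfaced as arguments. Permuted labels drive the mean
CV error to 1 − 1/K as a null check.

Group imputation — which segments share an identity — is an input, not a
computation: it encodes the analyst's hypothesis (in the pipeline's
simulated runs, compartment membership from the detected boundaries).

## The synthetic generator

`synth_config()`/`simulate_gut_study()` emulate the study design this kind
of analysis targets: S species (default 5), 6–10 ordered gut segments each,
3 replicates, ~2000 orthogroups, negative-binomial counts. Expression
archetypes are planted per orthogroup:

- **block**: a steep logistic step, high before the per-species boundary
  (relative position `boundary_rel`, default 0.45) and at the 5% floor
  after it. The step is steep enough (< 2% residual amplitude at the first
  posterior segment) that the planted boundary is actually where the
  transcriptional boundary sits.
- **gradient**: monotone ramps confined to the posterior compartment, each
  gene with its own onset drawn between one segment before the boundary and
  the last segment, and its own curvature. The onset stagger is essential:
  with a common onset all gradient genes are comonotone and posterior
  similarity would not decay with distance — the defining property of the
  gradient compartment would be missing. Onsets beginning one segment
  before the boundary guarantee the first posterior segment carries signal,
  i.e., the planted boundary is identifiable at all.
- **modules**: five Gaussian bumps (relative centers 0.06–0.94, width 0.12,
  40 genes each by default) whose per-species centers jitter with sd 0.05
  in relative units — the conserved-but-not-identical positioning the
  module extraction must tolerate. Module orthogroups are all TF-flagged
  (modules model conserved TF programs); random non-module orthogroups top
  the TF set up to `tf_fraction` (0.15).
- **terminal**: bumps at the gut ends, with the end (anterior, posterior or
  both) drawn independently per species — terminus markers swap ends across
  lineages, and the cross-species terminal flag must recover that.
- **null**: flat.

Counts are NB with gene-wise dispersion from a log-normal law (median
≈ 0.08, the bulk RNA-seq range), log-normal library sizes (sd 0.3), and
gene-by-replicate multiplicative batch factors (sd 0.15). Batch effects are
gene-specific on purpose: a scalar per-replicate factor would be absorbed
entirely by CPM normalization and leave the batch-removal stage nothing to
do. Sequences: each orthogroup gets a random ancestor protein (300
residues); each species' primary orthologue mutates 10% of sites, and a
`paralog_rate` fraction of orthogroups carries one extra paralog in one
species mutated at an additional 30% — the planted 1-to-many case whose
resolution is scored against truth. A single master seed drives fixed
substreams, so identical configs reproduce byte-identical counts,
sequences and truth.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: gene–gene expression correlation beyond the
planted archetypes, GC/length biases, isoform ambiguity in quantification,
compositional effects, real phylogenetic covariance among species, indels
in protein evolution (substitutions only), and genuinely multimodal or
species-specific expression programs. Results on real studies depend on
those, and on dissection granularity, in ways the planted-truth validation
cannot certify.

## Problem sizes and determinism

The test and acceptance workloads are sized to be informative yet quick:
50 random Robinson problems at n = 8 (with full 8! enumeration oracles on a
subset and at n = 6), 100-replicate noise sweeps at 8–9 segments, 200
orthogroups for ancestral-orthologue recovery, 2000 null and 500 bump
profiles for the trend test, 20 replicates of five-module recovery, and a
three-species demo pipeline (240 orthogroups) run twice to assert
byte-identical reports. All randomness flows from explicit seeds; reruns
are exactly reproducible.

## Known limitations

- Boundary detection assumes a bipartite organization; multi-boundary
  segmentation is out of scope by design.
- The trend screen's power drops quickly below 8 segments (polynomial df),
  so conserved-set recall is segment-count-limited; the cross-species
  intersection rule compounds per-species misses multiplicatively.
- Compartment labels (block vs gradient) depend on the `beta_min` slope
  threshold when compartments are short; the boundary position itself is
  much more stable than the labels.
- sPLS-DA marker sets are only as meaningful as the imputed segment
  identities they discriminate; the method will happily find markers for
  biologically wrong groupings.
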