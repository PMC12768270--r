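# gutmap

Comparative transcriptomics of adult gut anteroposterior (AP) organization
across distantly related bilaterian species.

Adult through-guts — from annelids and sea urchins to fish — are tubes of
ordered segments, and bulk RNA-seq of those segments carries a spatial
signal: which segments form coherent molecular territories, where the
territories end, and which gene programs occupy equivalent positions in
species separated by half a billion years. `gutmap` implements the full
analysis path for that question, for researchers working with segment-level
RNA-seq from several species plus an orthology table:

- **Per-species preprocessing** — detectability filtering (≥ 10 counts in at
  least a replicate's worth of samples), log2-CPM normalization, removal of
  replicate batch effects while protecting segment effects
  (`limma::removeBatchEffect`), replicate collapsing and within-species
  z-scoring, with each stage tagged and order-enforced.
- **Rank-2 Elliptical (R2E) seriation**, from first principles. Pearson
  correlation matrices are iterated — the correlation of the correlation
  matrix, repeatedly — until the effective rank (eigenvalues > e^-13) drops
  to 2. The left singular vectors of that matrix lie on an ellipse; items
  are ordered by their angular position, the circle is cut at the best
  large angular gap, and orientation is fixed deterministically (an anchor
  item or a lexicographic rule). This recovers the ordering of a Robinson
  matrix: segments sort by AP position, genes by expression peak.
- **Compartment detection** — Spearman correlations between segments (top
  2000 most-variant genes) are scanned for the bipartite "anterior block /
  posterior gradient" organization: the boundary maximizes
  within-compartment minus cross-compartment correlation, and each
  compartment is labelled *block* (no decay of similarity with distance) or
  *gradient* (similarity decays along the tube).
- **Orthology handling** — OrthoFinder-dialect `Orthogroups.tsv` IO, size
  and balance filters (> 120 genes, or > 80 and unbalanced), resolution of
  1-to-many orthology to a "best ancestral orthologue" per species by mean
  cross-species Smith–Waterman similarity (BLOSUM62, gap open 2 / extend
  0.1; compiled double-precision kernel), TF-flag expansion to orthogroup
  level, and manual orthogroup overrides for families (e.g., Hox) whose
  automatic orthogroups fragment.
- **Cross-species integration** on orthogroup rows of within-species
  z-scores — the transformation that makes segments cluster by position
  rather than by species.
- **AP-association screen** — per species, an exact F-test of each profile
  against an orthogonal-polynomial trend in AP rank; Benjamini–Hochberg
  control within species; "conserved" = associated in every species.
  Terminal markers (peaking at a gut end, with ends swapping between
  species) are classified from the fitted profiles.
- **Conserved AP modules** — gene–gene Spearman correlation over pooled
  segments, R2E seriation, contiguous (seriation-guided) average-linkage
  clustering, module count chosen by BIC, and per-species placement of each
  module relative to the compartment boundary with deviation flags.
- **Sparse PLS-DA marker discovery** (from scratch) — penalized partial
  least squares discriminant analysis with exact per-component `keepX`
  sparsity, leave-one-species-out cross-validation, and the smallest
  sufficient marker set.
- **A synthetic multi-species generator** with complete planted ground
  truth (boundaries, module positions, terminal ends, ancestor-like
  paralogs, batch effects), so the whole pipeline is testable without any
  download.

## Quick start

```r
library(gutmap)

# a three-species simulated study with planted truth
cfg <- synth_config(n_species = 3, segments_per_species = c(8, 7, 9),
                    n_orthogroups = 240,
                    module_spec = transform(default_module_spec(), n_genes = 14),
                    seed = 42)
sim <- simulate_gut_study(cfg)

# per-species preprocessing and compartment calls
seg <- lapply(sim$datasets, preprocess_species)
calls <- lapply(seg, function(ds) detect_boundary(segment_correlation(ds)))
calls$sp1
#> compartment_call: boundary at segment 4 of 8 (anterior block, posterior gradient)
#>   decay slopes: anterior 0.1270, posterior 0.1583 (rho/segment)

# orthology resolution and integration
resolved <- resolve_orthogroups(filter_orthogroups(sim$orthology), sim$sequences)
im <- integrate_species(lapply(seg, zscore_rows), resolved,
                        tf_flags = sim$truth$tf)

# conserved AP-associated orthogroups and modules
assoc <- screen_conserved(im, q_threshold = 0.05, tf_only = TRUE)
assoc
#> ap_association: 70 orthogroups x 3 species tested; 50 conserved
#> AP-associated (q < 0.05 in >= 3 species); 0 cross-species terminal
mods <- extract_modules(im, orthogroups = assoc$conserved, k = "auto")
mods
#> module_set: 5 modules over 50 orthogroups (sizes 11, 14, 2, 10, 13)
```

The boundary at segment 4 is the planted block/gradient transition for this
species (`sim$truth$boundary`), the conserved set is dominated by the 70
planted module genes, and `module_position(mods, calls)` places each module
relative to each species' boundary.

Or run everything from one config:

```r
report <- run_pipeline(demo_config(), out_dir = "demo_run")
report
#> gutmap run report
#>   sp1: boundary 4 (block | gradient)
#>   sp2: boundary 4 (block | gradient)
#>   sp3: boundary 5 (gradient | gradient)
#>   conserved AP-associated orthogroups: 50
#>   modules: k = 5 (sizes 11, 14, 2, 10, 13)
#>   markers: keepX = 5
#>   truth: mean |boundary error| = 0.00, module ARI = 1.000, marker signal fraction = 1.00
```

Every boundary matches its planted position, the five planted modules are
recovered exactly (adjusted Rand index 1.0 against the planted membership),
and all five selected markers carry planted AP signal.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "gutmap",
                               load_package = "installed")'
```

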