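# LEDtools

Quantifies **lineage-specific expression divergence (LED)** of 1:1:1
orthologous genes from tissue-level expression profiles in three species,
and relates it to genic properties and gene function. The intended users
are comparative transcriptomics researchers with per-species gene × tissue
TPM tables (e.g. from a curated expression atlas), an ortholog triple
table, and optionally per-gene sequence-divergence values, interaction
counts, and GO annotations.

## The statistic

For an ortholog triple in species X, Y, Z, each gene's expression profile
is its vector of relative abundances over the T shared tissues (values
log2(TPM + 1), normalized to sum to 1). Pairwise expression divergence is
the Euclidean distance between profiles, e.g.
E_X,Y = sqrt(Σ_t (X_t − Y_t)²). The three distances define an unrooted
three-taxon tree whose branch lengths follow from the three-point formula:

    LED_X = (E_X,Y + E_X,Z − E_Y,Z) / 2

and cyclically for Y and Z. LED_X is the expression divergence assigned to
the lineage leading to X; a gene with a large single-lineage regulatory
change shows one disproportionally long branch. Branch lengths can be
scaled to per-generation rates by dividing by
(365 / days_to_anthesis) × divergence_My × 1e6 per species.

Downstream, the package provides: two-sample permutation tests on the
difference of medians (distribution comparisons before/after scaling),
Pearson/Spearman correlation tests of LED against tissue specificity (τ)
and sequence divergence (branch length, Ka, Ka/Ks), Poisson regression of
interaction counts on LED with a deviance goodness-of-fit check, a
primary-tissue enrichment battery for the top-1% LED genes (overall χ²,
hanging chi-gram components (O−E)/√E, exact binomial tests with Bonferroni
correction), and rank-based GO enrichment (one-sided two-sample KS over a
true-path-propagated DAG; `classic` and topology-aware `elim` algorithms).
A synthetic-data generator with planted lineage/tissue shifts makes the
whole pipeline testable without external data.

## Worked example

Simulate a three-species bundle (2,000 ortholog triples, nine tissues, 1%
of genes carrying a 32-fold single-tissue shift in one lineage) and run the
full pipeline:

```r
library(LEDtools)

cfg <- simulationConfig(n_genes = 2000, seed = 1)
writeSimulatedBundle(cfg, "demo")
res <- runPipeline("demo/config.yaml", outdir = "demo/results")

head(res$led[, c("triple_id", "e_xy", "e_xz", "e_yz",
                 "led_x", "led_y", "led_z")], 3)
#>   triple_id       e_xy       e_xz       e_yz      led_x      led_y      led_z
#> 1   og00001 0.05381246 0.04161311 0.04361928 0.02590315 0.02790931 0.01570997
#> 2   og00002 0.05875869 0.05207761 0.05644975 0.02719327 0.03156541 0.02488433
#> 3   og00003 0.04399467 0.04615683 0.04685878 0.02164636 0.02234831 0.02451047
```

Each row decomposes a triple's three pairwise profile distances into three
branch lengths (led_x + led_y = e_xy, and so on). The distribution tests
compare lineages genome-wide; with default branch lengths (0.25, 0.25,
0.30) the outgroup lineage z is detectably more diverged:

```r
res$distribution_tests[1:3, ]
#>   scale species_a species_b observed_stat     p_value n_permutations
#> 1   led species_x species_y  0.0003895305 0.195804196           1000
#> 2   led species_x species_z  0.0021113040 0.000999001           1000
#> 3   led species_y species_z  0.0025008346 0.000999001           1000
```

The planted anther shifts surface as positive hanging-chi-gram components
for anther among top-1% LED genes (observed 6 vs ≈2.3 expected per
species), and the planted GO term ranks first:

```r
subset(res$tissue_enrichment, tissue == "anther",
       c(species, observed, expected, chi_component, binom_p_adj))
#>      species observed expected chi_component binom_p_adj
#> 4  species_x        6     2.22      2.536970   0.1646271
#> 13 species_y        6     2.33      2.404297   0.2050751
#> 22 species_z        6     2.38      2.346497   0.2255793

head(res$go_enrichment[, c("term", "name", "n_annotated", "p_value")], 3)
#>         term                    name n_annotated    p_value
#> 1 GO:0000013 planted_top_scoring_set          20 0.00000000
#> 2 GO:0000113          background_100          23 0.06247911
#> 3 GO:0000041          background_028          28 0.06790710
```

(At 2,000 genes the 20-gene top set is too small for per-tissue binomial
significance after Bonferroni; at the 10,000-gene scale used in the test
suite the anther enrichment reaches adjusted p < 0.001.)

All outputs are also written as TSV (`led.tsv`, `led_per_generation.tsv`,
`distribution_tests.tsv`, `correlations.tsv`, `poisson.tsv`,
`tissue_enrichment.tsv`, `go_enrichment.tsv`) plus a `manifest.yaml` with
counts at each filtering step; reruns with the same config are
byte-identical. `inst/scripts/led-pipeline.R` wraps `simulate` and `run`
for shell use.

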