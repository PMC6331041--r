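---
title: "Quantifying lineage-specific expression divergence in three species"
author: "LEDtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lineage-specific expression divergence in three species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(LEDtools)
```

## The model

Consider a gene with 1:1:1 orthologs in three species X, Y and Z, and its
expression measured (as TPM) across the same T tissues in each species. The
gene's *expression profile* in a species is the vector of relative
abundances over tissues: values are transformed to
$v_t = \log_2(\mathrm{TPM}_t + 1)$ and normalized so that
$\sum_t v_t / \sum_s v_s = 1$. Working on relative abundances makes profiles
comparable across species despite library-composition differences; the log
keeps a handful of extremely expressed tissues from dominating the geometry.

Pairwise expression divergence between two species is the Euclidean distance
between the orthologs' profiles,
$E_{X,Y} = \sqrt{\sum_t (X_t - Y_t)^2}$. The three pairwise distances of an
ortholog triple define an unrooted three-taxon tree whose branch lengths are
obtained by the classical three-point decomposition:

$$\mathrm{LED}_X = \tfrac12\,(E_{X,Y} + E_{X,Z} - E_{Y,Z}),$$

and cyclically for Y and Z. LED — lineage-specific expression divergence —
is the expression change assigned to one lineage since the internal node.
Under neutral drift all three branches are comparable; a large single-lineage
regulatory change produces one disproportionally long branch. Because the
distances come from actual vectors they are metric, so all branch lengths
are non-negative up to floating-point error; the implementation clamps
negatives of magnitude at most $10^{-12}$ and treats anything larger as a
non-metric input error rather than silently repairing it.

Branches span different amounts of evolutionary time, and species differ in
generation time. `branchScale()` converts days-to-anthesis (one generation)
and the branch age in millions of years into total generations per branch,
$(365/\mathrm{days}) \times \mathrm{My} \times 10^6$, and
`scalePerGeneration()` divides every gene's branch length by its lineage's
divisor. Dividing each point by a constant is the only per-gene operation
that rescales the whole distribution, so distribution-level comparisons
before and after scaling are both supported. The $10^6$ constant cancels in
cross-species orderings.

## Filtering and its boundary

A gene enters the analysis only where it is meaningfully expressed:
$\log_2(\mathrm{TPM}) > 2$ (TPM > 4) in at least one tissue, applied to raw
TPM with a strict inequality, so TPM = 4 is excluded and zeros never pass.
The pseudocount is used only for profile construction, not for filtering. A
triple is retained only when all three members pass in their own species —
all three profiles are needed to place the internal node, and a union rule
would let one noisy species inject undefined profiles. The profile scale
(log-relative versus raw-TPM shares) is a configuration switch; log is the
default since the transform precedes profile construction in the upstream
protocol this package consumes.

## Genic correlates

* **Tissue specificity** uses the standard index
  $\tau = \sum_i (1 - x_i/x_{\max}) / (T - 1)$, computed on the same
  $\log_2(\mathrm{TPM}+1)$ values as the profiles so that the two views of a
  gene share a scale; $\tau$ is 0 for uniform expression and 1 for
  single-tissue expression, and invariant to rescaling the vector.
* **Primary tissue** is the raw-TPM argmax (the argmax is unchanged by the
  monotone log transform; raw TPM is stated for definiteness), with ties
  broken by the canonical tissue order.
* **Sequence divergence** (gene-tree branch length, Ka, Ka/Ks) and
  **interaction counts** are consumed as per-gene tables produced upstream;
  Ka/Ks undefined at Ks = 0 is represented as missing, never infinity, and
  every correlation reports its complete-case n.

## Inference

* Distribution differences use two-sample permutation tests with the
  absolute difference of medians (1,000 label permutations by default). The
  p-value is the add-one estimator $(1+b)/(1+B)$, never zero, and an exact
  mode enumerates all label assignments for small samples. The alternative
  is two-sided via the absolute statistic.
* Correlations report Pearson's r, or Spearman's ρ as Pearson on mid-ranks,
  with the one-sample t test $t = r\sqrt{(n-2)/(1-r^2)}$ at $n-2$ df.
* Connectivity is related to LED by Poisson regression with log link
  (`stats::glm` IRLS; tolerance $10^{-8}$, 100 iterations), Wald p for the
  slope, and a $\chi^2$ goodness-of-fit test on the residual deviance at
  $n-2$ df. The deviance approximation is known to drift from $\chi^2$ when
  mean counts sit near 1, which bounds what the calibration tests can assert
  (see below).
* The primary-tissue battery compares top-1% LED genes against genome-wide
  primary-tissue frequencies: an overall $\chi^2$ goodness-of-fit statistic,
  per-tissue hanging-chi-gram components $(O-E)/\sqrt{E}$, and two-sided
  exact binomial tests (minimum-likelihood method) Bonferroni-corrected by
  the number of tissue classes (9), whether or not a class is empty in the
  top set.
* GO enrichment ranks genes by descending LED and applies a one-sided
  two-sample Kolmogorov–Smirnov test per term (annotated versus remaining
  genes), over a true-path-propagated DAG restricted to `is_a` edges, with
  terms under 10 annotated genes skipped and p < 0.01 declared significant.
  Two algorithms are provided: `classic` (every term independent) and the
  default `elim`, which processes terms children-before-parents and removes
  the genes of any term with p below `alpha_elim` from its ancestors before
  they are tested. `elim` was chosen as the default topology-aware method
  because it is fully specified by its published description and exactly
  reproducible; hybrid weighting schemes in wide use are not, and
  reproducibility was weighted above matching any particular tool's output.

## The synthetic-data generator

`simulateTripletExpression()` emulates the statistical structure the
analysis assumes, not RNA-seq mechanics:

* an ancestral $\log_2$ expression vector per gene (mean 5, SD 2 across
  genes — TPM mostly in the tens to hundreds, as in tissue atlases);
* independent Gaussian drift per lineage and tissue with variance equal to
  the lineage's branch length, so squared profile distance grows roughly
  linearly with branch length (the Brownian property that motivates the
  Euclidean distance); defaults (0.25, 0.25, 0.30) mirror two sister
  lineages and a slightly older outgroup;
* for a `shift_fraction` (default 1%) of genes, a single-tissue,
  single-lineage displacement of `shift_magnitude` log2 units (default 5,
  i.e. a 32-fold change — 10 drift SDs at the default branch lengths),
  concentrated on anther by default so that the primary-tissue battery has
  a recoverable planted signal;
* back-transformation $2^v - 1$, additive measurement noise on the TPM
  scale (SD 0.1), flooring at zero.

`simulateCorrelates()` draws divergence measures with means linear in the
gene's *quantile-normalized* LED (rank $-$ 0.5 over n, a U[0,1] predictor)
times lognormal noise, and interaction counts as Poisson with log-mean
$\beta_0 + \beta_1 \times$ normalized LED. Quantile rather than min-max
normalization keeps the planted coefficients identifiable under the
right-skewed LED distribution; this is what makes the round-trip recovery
tests meaningful. `simulateGo()` builds a three-level DAG (one root per GO
namespace) with uniform random background annotation sets of 10–50 genes
and, optionally, one planted term annotating exactly the top-scoring genes.

What the generator does **not** emulate: read-level sampling noise,
library-size and quantile-normalization artifacts, correlated drift across
tissues, gene–gene expression correlation, and annotation bias in real GO
data. Passing tests therefore demonstrate that the statistics recover the
structure they are designed for, not that real grass data satisfy that
structure.

## Numerical and design choices

* Profiles must sum to 1 within $10^{-9}$; additivity identities of the
  branch decomposition hold within $10^{-9}$ and are property-tested at
  $10^5$ triples.
* `selectTopFraction` takes $\lceil fN\rceil$ genes with deterministic
  tie-breaking (descending score, then lexicographic identifier).
* Permutation p-values are reproducible bit-for-bit given a seed; the
  pipeline derives independent sub-seeds for each stage from the run seed.
* Calibration checks use study-shaped designs: the Poisson
  goodness-of-fit calibration uses an Exp(1) predictor (right-skewed, like
  LED); with a bounded uniform predictor at mean counts near 1 the deviance
  test is anticonservative and no implementation would pass a calibration
  check there.
* Problem sizes in the shipped tests: $10^5$ random triples for the algebra
  properties, $10^4$ profile pairs against the loop oracle, 2,000 null
  replicates for permutation type-I error, 100 replicates of n = 5,000 for
  Poisson calibration, 10,000 simulated genes for pipeline-level recovery.
  These sizes were chosen to give tight Monte-Carlo bounds while keeping a
  default test run to a few minutes.

## Limitations

* The three-taxon decomposition cannot distinguish a shift on lineage X
  from a shift on the internal branch ancestral to Y and Z; resolving that
  requires a fourth taxon and the corresponding four-point correction,
  which is out of scope here.
* Per-gene LED values are estimates with substantial sampling noise at
  T = 9 tissues; the package's inferential surface is deliberately
  distribution- and rank-based.
* The Bonferroni factor for the tissue battery is fixed at the number of
  tissue classes, which is conservative when some classes are empty in the
  top set.
* GO enrichment p-values use the asymptotic one-sided KS tail; for terms
  near the 10-gene floor they are approximate (the null-calibration test
  bounds the practical consequence).
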