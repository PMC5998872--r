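---
title: "Signature construction and nu-SVR deconvolution: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature construction and nu-SVR deconvolution: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svrdecon)
```

## The model

Bulk expression of a mixed tissue is treated as a linear combination of
cell-type profiles. For gene $i$ in mixture $j$,

$$ M_{ij} = \sum_{k=1}^{r} S_{ik} \, F_{kj}, $$

i.e. $M \approx S F$ with $S$ a $t \times r$ signature matrix (expression of
$t$ discriminating genes in $r$ cell types) and $F$ the non-negative,
sum-to-one fraction vector per mixture. The package solves both halves:
building $S$ from replicated reference arrays, and estimating $F$ per
mixture by support-vector regression.

Key assumptions: mixing is linear on the intensity scale (no saturation or
interaction between cell types), the reference panel spans the cell types
actually present, and the mixture's signature genes are not expressed by
cell types outside the panel — which is why genes active in
non-hematopoietic tissues or cancer cells are black-listed before gene
selection when profiling immune infiltrates in tumors.

## Reference QC

Reference arrays are quantile normalized, then clustered (complete linkage,
Euclidean distance on sample columns) as a visual check that replicates
group with their annotated type. The decision rule for outliers is
correlation-based: a sample is flagged when strictly more than $2/3$ of its
Pearson correlations to same-class peers fall below $0.85$. Both numbers
are exposed (`r_threshold`, `pair_fraction`) but their defaults are the
method's standard operating point. The rule is accounted per sample, since
that is the only reading that yields a decision for an individual array.
Flagged samples and indistinguishable classes (`suggest_merges()`) are only
*reported*; removal (`drop_samples()`) and merging (`merge_classes()`) are
explicit user actions, keeping the audit trail in the user's hands.

## Building the signature matrix

1. **Quantile normalization** of the reference arrays (each column is
   mapped onto the across-column mean of order statistics; ties take the
   mean of the quantiles they span — the deterministic symmetric rule).
2. **Black-list filtering.** Genes with enrichment score $> 0$ in more than
   5% of normal tissue types, or log2 expression $> 7$ in at least one
   cancer cell line, are removed *before* differential testing, so they can
   never enter the signature. All threshold comparisons are strict; both
   tables are consumed as inputs.
3. **Pairwise differential expression.** For every unordered pair of cell
   types, each gene gets a two-sided Welch (unequal-variance) $t$-test on
   the replicate columns. Q-values are computed within each pair's own
   family of tests (Benjamini–Hochberg by default; a Storey-style
   $\pi_0$-scaled variant is available but not default, as $\pi_0$
   estimation is unstable in small families). Genes with $q < 0.3$ are kept
   and ranked by descending $|\log_2$ fold change$|$ of the class means,
   computed with a pseudocount of 1 on linear intensities to guard dim
   genes; rank ties break by gene ID for reproducibility.
4. **Top-G union and condition-number sizing.** For each $G$ in $[5, 100]$
   the union of every pair's top-$G$ genes defines a candidate list, the
   candidate signature is the matrix of per-class replicate means (raw
   linear scale — standardization happens later, at regression time), and
   its 2-norm condition number $\kappa = \sigma_{\max}/\sigma_{\min}$ is
   recorded. The chosen $G$ minimizes $\kappa$ (ties to the smallest $G$);
   a lower $\kappa$ means a better-posed linear system. Lists smaller than
   $r$ genes are skipped; a rank-deficient candidate reports
   $\kappa = \infty$ with a warning rather than an error, so the scan can
   continue.

Classes with only two replicates are allowed with a warning about
statistical power; they occur in real reference panels.

## Solving for the fractions

Mixtures are quantile normalized, restricted to the genes shared with the
signature (an error is raised if fewer shared genes than cell types
remain), and standardized: by default the signature is z-scored *globally*
(one mean and sd over all entries) so relative magnitudes between cell
types survive standardization, while each mixture column is z-scored over
its signature-gene entries. A per-column signature scope is available via
`deconv_config(zscore_scope = "per-column")`; whether signature and mixture
should share one standardization block is not determined by the method
description, so both scopes are explicit and the global one is the default.

Each mixture column is regressed on the signature columns by
$\nu$-support-vector regression with a linear kernel
(`e1071::svm(type = "nu-regression")`), where observations are genes and
features are cell types; the support vectors are a subset of signature
genes. $\nu \in \{0.25, 0.5, 0.75\}$ are all fit and the model with the
lowest RMSE between the standardized mixture and its reconstruction
$S_{std}\,w$ wins (raw, pre-clipping coefficients; ties go to the smallest
$\nu$). The cost constant defaults to 1.0 and the solver tolerance to
1e-6 — the method description fixes neither, and $\nu$ rather than cost is
the operative control, so both are exposed and held fixed by default.
Negative coefficients are then clipped to zero and the remainder normalized
to sum to one; no re-fit is performed after clipping. Samples are solved
independently, so any execution order gives identical output.

Per-sample diagnostics (chosen $\nu$, reconstruction RMSE, reconstruction
Pearson $r$) travel with the proportion table. Note the two RMSEs in this
package are different quantities: reconstruction RMSE lives on standardized
expression over signature genes, benchmark RMSE on proportions.

## Benchmarking

Validation compositions (e.g. flow cytometry) typically type a subset of
classes at coarser granularity. `rescale_subset()` first sums fine classes
into benchmark classes via a class map (e.g. resting + activated NK
$\to$ NK), restricts to the typed subset and renormalizes each sample to
sum 1; `benchmark_proportions()` then reports Pearson $r$ and RMSE per cell
type (across samples), per sample (across cell types) and pooled. Classes
never typed in the truth are dropped with a message — mirroring cell types
that validation panels leave unmeasured.

## What the synthetic generator emulates — and what it does not

`generator_spec()` defaults describe the verification conditions used
throughout the tests: $r = 8$ cell types, $g = 1000$ genes, 5 markers per
type, 3 replicates per type, 1% log-scale replicate noise, 50 mixtures
with flat-Dirichlet compositions, all under one seed.

* Base intensities are $2^{\mathcal{N}(6,2)}$ — positive, right-skewed,
  spanning the dynamic range typical of array intensities — and *shared*
  across classes, so non-marker genes are non-differential by construction.
* Marker genes draw their base from a narrower mid-intensity band
  $2^{\mathcal{N}(6,1)}$ and are elevated `marker_effect`-fold (default 10)
  in their own class only. This mimics lineage markers, which are
  moderately expressed in their own type and near background elsewhere; it
  also keeps the cell-type contrast, rather than base-intensity
  heterogeneity, as the dominant structure of the signature rows. Marker
  sets are disjoint across classes.
* Noise is multiplicative log-normal by default (sd on the log2 scale),
  matching intensity-dependent array noise; additive Gaussian is available
  by flag. Mixtures satisfy $M = S_{true} F$ exactly at zero noise.

The generator does **not** emulate probe-level artifacts, batch effects,
cross-hybridization, platform differences, or markers shared between
related cell types. Passing the recovery tests therefore demonstrates the
correctness of the pipeline's computations and its behavior under the
stated noise model — not performance on real arrays, where reference and
mixture data disagree in ways no seeded simulation reproduces.

Problem sizes in the test suite are chosen to exercise every code path at
comfortable desk scale: the full-size recovery run uses the default spec
above; smaller panels (3–5 classes, 200–400 genes) cover QC, ranking and
invariant properties.

## Numerical choices and degenerate inputs

* Standard deviations use the $n-1$ (sample) denominator everywhere.
* All threshold comparisons (ES, cancer log2, $q$, correlation, pair
  fraction) are strict inequalities.
* Duplicate gene rows are collapsed by mean at load; files on the log2
  scale must be declared (`log2_input = TRUE`) and are anti-logged, since
  all statistics operate on linear intensities.
* Constant vectors cannot be z-scored and raise an error naming the sample;
  a gene constant and equal in both groups tests as $t = 0, p = 1$;
  constant and different is reported as infinitely significant in the
  vectorized screen but is an error in the scalar `welch_t_test()`.
* Quantile normalization of a single column is a no-op with a warning.
* Proportion tables are validated on write: non-negative, rows summing to
  1 within 1e-8 (slightly wider than the 1e-9 production tolerance to
  absorb binary representation of boundary cases).
* Dendrogram determinism: columns are ordered by sample label before
  clustering so equal-height merges resolve identically across runs.

## Known limitations

* Estimates are relative fractions of the modeled panel, not absolute
  abundances; cell types absent from the panel bias the fractions of
  present ones upward.
* No deconvolution p-value is computed (no permutation machinery).
* $\pi_0$-adaptive q-values are approximate for the small per-pair test
  families; the default BH control is the conservative choice.
* The condition-number criterion can legitimately choose a small $G$ whose
  union list omits weakly ranked markers; this is a property of the
  selection rule, visible in the `trace` element returned by `select_g()`.
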