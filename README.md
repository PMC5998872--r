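# svrdecon

Cell-type deconvolution of bulk gene-expression profiles by ν-support
vector regression, with signature-matrix construction driven by
condition-number minimization.

## The problem

Bulk transcriptomes of heterogeneous tissues — tumor biopsies above all —
mix the expression of many cell populations. The composition of the immune
infiltrate (tumor-infiltrating lymphocytes) carries prognostic and
therapeutic information, but flow cytometry and immunohistochemistry cannot
be applied retrospectively to archived expression data. In silico
deconvolution treats the bulk profile as a linear mixture,

```
M ≈ S × F
```

where `M` (t genes × mixtures) is the observed bulk expression over `t`
signature genes, `S` (t × r) holds the expression of those genes in `r`
cell types, and `F` (r × mixtures) holds the non-negative, sum-to-one
fractions to be estimated. `svrdecon` is for researchers who want both
halves of that problem under their control:

* **Signature construction** from replicated reference arrays:
  quantile normalization; correlation-based QC of replicate arrays
  (complete-linkage clustering; a sample is flagged when > 2/3 of its
  within-class Pearson correlations fall below 0.85); black lists for genes
  active in normal tissues (enrichment score > 0 in > 5% of tissues) or
  cancer cell lines (log2 expression > 7); pairwise Welch t-tests with
  per-pair Benjamini–Hochberg q-values (q < 0.3); ranking by |log2 fold
  change|; and selection of the per-pair list size `G ∈ [5, 100]` that
  minimizes the condition number κ = σ_max/σ_min of the resulting matrix.
* **Deconvolution** per mixture sample by linear-kernel ν-SVR
  (ν ∈ {0.25, 0.5, 0.75}, lowest reconstruction RMSE wins), followed by
  clipping of negative coefficients and normalization to sum 1.
* **Benchmarking** against known compositions (subset rescaling,
  per-cell-type and per-sample Pearson r and RMSE), and a seeded
  **synthetic-data generator** so the whole pipeline is verifiable with
  known ground truth.

## Worked example

Simulate a 4-cell-type reference panel with planted markers, build the
signature, deconvolve 6 mixtures, and score against the known truth:

```r
library(svrdecon)

spec <- generator_spec(n_classes = 4, n_genes = 300, markers_per_class = 5,
                       replicates_per_class = 3, n_mixtures = 6, seed = 42)
refs <- generate_references(spec)
mix  <- generate_mixtures(refs)

sel <- build_signature_matrix(refs$expression, refs$annotation,
                              g_min = 5, g_max = 40)
sel
#> Signature gene-list selection: G = 5 | condition number = 1.701 | 12 signature genes

est <- deconvolve(mix$expression, sel$signature)
round(proportion_matrix(est), 3)
#>         CT01  CT02  CT03  CT04
#> MIX001 0.053 0.076 0.351 0.520
#> MIX002 0.270 0.028 0.618 0.084
#> MIX003 0.137 0.617 0.077 0.170
#> MIX004 0.319 0.043 0.066 0.572
#> MIX005 0.498 0.013 0.323 0.166
#> MIX006 0.016 0.544 0.137 0.304

benchmark_proportions(est, mix$truth)
#> Benchmark over 6 samples, 4 cell types
#>   pooled Pearson r: 0.9976 | pooled RMSE: 0.01432
#>   class pearson_r   rmse
#> 1  CT01     0.996 0.0168
#> 2  CT02     0.999 0.0141
#> 3  CT03     0.998 0.0126
#> 4  CT04     0.998 0.0134
```

Each row of the proportion table is one mixture; entries are the estimated
fractions of the four cell types (non-negative, summing to 1), and the
benchmark compares them with the generator's true Dirichlet compositions:
pooled correlation 0.998 and RMSE 0.014 here, i.e. fractions recovered to
about one percentage point.

Real data follow the same path: load a reference matrix and phenotype
annotation with `read_expression_matrix()` / `read_annotation()`, screen
replicates with `detect_outliers()` (then `drop_samples()` /
`merge_classes()` as warranted), pass enrichment-score and cell-line tables
to `normal_tissue_blacklist()` / `cancer_blacklist()`, and hand any mixture
matrix sharing the signature's gene symbols to `deconvolve()`.

The same pipeline is scriptable from a shell:

```sh
exec/svrdecon simulate --out-dir sim --seed 1
exec/svrdecon build-signature --refs sim/refs.tsv --classes sim/classes.tsv --out sig.tsv
exec/svrdecon deconvolve --mixtures sim/mixtures.tsv --signature sig.tsv --out props.csv
exec/svrdecon evaluate --est props.csv --truth sim/truth.csv --out bench.json
```

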