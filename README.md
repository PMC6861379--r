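# lncmeta

Heterogeneity-aware meta-analysis of multi-study RNA-seq count data, built
for the problem of identifying disease-associated long noncoding RNAs
(lncRNAs) whose single-study findings fail to replicate. Individual lncRNA
studies are small (arms of 3–20 samples are common) and span different
tissues, so apparently contradictory results can simply reflect sampling
noise and between-study heterogeneity. `lncmeta` addresses this by pooling
per-gene effects across studies with an explicit heterogeneity model, then
characterising the surviving genes by tissue specificity, co-expression
structure, and gene-set enrichment.

## What it computes

For each gene *g* and study *i*, expression is TMM-normalised log2-CPM and
the effect is the standardized mean difference with Hedges' small-sample
correction:

    d = (x̄_case − x̄_control) / s_pooled,   g = J·d,   J = 1 − 3/(4(n₁+n₂−2)−1)
    v = (n₁+n₂)/(n₁n₂) + g²/(2(n₁+n₂))

Between-study heterogeneity is tested with Cochran's Q (χ², k−1 df) and
I² = max(0, (Q−df)/Q)·100. Genes with **I² > 50 and p_Q < 0.01** are pooled
under a DerSimonian–Laird random-effects model, all others under the
inverse-variance fixed-effects model; a gene is called differentially
expressed when its 95% CI excludes zero **and** its Benjamini–Hochberg FDR
is below 0.05. An adaptively weighted Fisher combination of per-study
p-values (minimising the χ²-tail of −2Σw·ln p over study subsets) is
reported alongside.

Downstream stages: Jensen–Shannon tissue specificity
(score_t = 1 − √JSD(density, e_t), in [0,1]), Manhattan-distance gene
clustering, weighted co-expression analysis (soft-thresholded |cor|^β
adjacency, topological overlap, dendrogram modules, eigengenes, module–trait
statistics) and hypergeometric over-representation plus permutation GSEA.
Negative-binomial multi-study simulators with known ground truth make every
stage testable end to end.

## Worked example

```r
library(lncmeta)
cfg <- simulation_config(n_studies = 5, n_cases = rep(10L, 5),
                         n_controls = rep(10L, 5), n_genes = 500,
                         frac_de = 0.2, delta = 1, tau2 = 0.1, seed = 42)
sim <- generate_multistudy_counts(cfg)
res <- run_meta(sim$studies)
head(res[order(res$p_meta), ], 5)
```

```
      gene_id k   I2 model smd_pooled ci_low ci_high      fdr de_call direction
143 gene00143 5 0.00   FEM      -1.61 -2.070  -1.158 1.99e-09    TRUE      down
364 gene00364 5 8.73   FEM       1.43  0.984   1.872 4.75e-08    TRUE        up
203 gene00203 5 5.53   FEM       1.42  0.973   1.859 4.75e-08    TRUE        up
147 gene00147 5 0.00   FEM      -1.40 -1.838  -0.962 4.75e-08    TRUE      down
27  gene00027 5 0.00   FEM       1.39  0.949   1.826 5.28e-08    TRUE        up
```

Here 94 of 500 genes are called differentially expressed, 92 of them true
positives of the simulation (100 genes carried a planted standardized
effect of ±1). Each row reports the heterogeneity diagnosis (`I2`, and the
fixed/random model it selected), the pooled SMD with its 95% CI, and the
FDR-based call. Per-study detail for any gene — the content of a forest
plot — comes from `forest_data(sim$studies, "gene00143")`:

```
    study      y      v ci_low ci_high n_case n_control
1 study01 -2.432 0.3478  -3.59 -1.2758     10        10
...
6  pooled -1.614 0.0541  -2.07 -1.1578     50        50
```

The whole pipeline (normalisation → meta-analysis with tissue subgroups →
DE-set overlap → tissue specificity → co-expression modules → enrichment)
runs from one configuration object and writes TSV artifacts plus a hashed
manifest:

```r
out <- run_all(pipeline_config(seed = 1), "artifacts/")
```

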