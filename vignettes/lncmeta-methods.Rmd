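---
title: "Methods: multi-study meta-analysis for lncRNA discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-study meta-analysis for lncRNA discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Single-study lncRNA differential-expression results replicate poorly:
cohorts are small (case/control arms of 3–20 samples are typical), tissues
differ between studies, and lncRNAs are expressed at low, noisy levels.
`lncmeta` treats each study as one unit of evidence and pools per-gene
effects across studies with an explicit between-study heterogeneity model,
so that a gene is only called disease-associated when the combined evidence
supports it.

# The statistical model

## Within-study effect size

Counts are normalised within each study by edgeR's trimmed-mean-of-M-values
(TMM) strategy and converted to log2 counts per million with a prior count
(default 0.5, configurable): `log2((count + prior) / (effective library +
2·prior) · 1e6)`. The per-study effect for a gene is the standardized mean
difference on this scale,

$$d = \frac{\bar x_{case} - \bar x_{control}}{s_{pooled}}, \qquad
  g = J\,d, \qquad J = 1 - \frac{3}{4(n_1+n_2-2)-1},$$

with sampling variance $v = (n_1+n_2)/(n_1 n_2) + g^2/(2(n_1+n_2))$.
Two choices here were genuinely open and are package decisions:

* **Scale.** The SMD is computed on log2-CPM (configurable to raw CPM).
  On the log scale the variance of expression is approximately
  mean-independent, which is what the SMD variance formula assumes.
* **Small-sample correction.** Hedges' $J$ is applied because arms as
  small as 3 appear in realistic designs, where the uncorrected $d$ is
  biased upward by several percent.

Genes with zero pooled SD in a study are degenerate there and that study
is excluded for them; genes computable in fewer than two studies are
reported unanalysed with reason code `insufficient_studies`.

## Heterogeneity and pooling

Cochran's $Q = \sum w_i (y_i - \bar y)^2$ with $w_i = 1/v_i$ is referred
to $\chi^2_{k-1}$, and $I^2 = \max(0, (Q - df)/Q)\cdot 100$. A gene is
pooled under the DerSimonian–Laird random-effects model exactly when
$I^2 > 50$ **and** $p_Q < 0.01$ (both strict; at the thresholds the
fixed-effects model is used), otherwise under the inverse-variance
fixed-effects model. The 95% CI uses the normal quantile 1.96, the
standard large-sample meta-analytic interval. A gene is called
differentially expressed when its CI excludes zero and its
Benjamini–Hochberg FDR (computed within each run, including subgroup
runs) is below 0.05.

## Adaptively weighted Fisher combination

For binary study-inclusion weights $w$, $U(w) = -2\sum w_i \ln p_i$ and
$s(w) = P(\chi^2_{2|w|} \ge U(w))$. The adaptive statistic is
$\min_w s(w)$; because at fixed subset size the minimum is attained by the
smallest p-values, the search over the $k$ nested subsets of sorted
p-values is exact (verified against exhaustive $2^k - 1$ enumeration in
the tests). The raw minimum is **anti-conservative** as a p-value — it is
a minimum over adaptively chosen tests — so `run_meta(aw_perm = B)` offers
a permutation calibration that permutes case/control labels within each
study and pools null statistics across genes. The AW results are reported
alongside the SMD results; DE calls use the SMD/CI/FDR rule, which is the
operational rule of the pooling model. FDR for subgroup analyses is
computed within each subgroup run.

# Tissue specificity

A gene's atlas profile is converted to a density $p$ and compared with the
extreme pattern $e_t$ concentrated in tissue $t$:
$score_t = 1 - \sqrt{JSD(p, e_t)}$ with base-2 entropies, so scores lie in
$[0,1]$ and equal 1 exactly for exclusive expression. Base 2 is what bounds
the distance by 1. Genes with all-zero rows have no density and are
excluded with a reason code rather than scored 0. Gene clustering uses
Manhattan distance with complete linkage (configurable), matching the
common heatmap practice for tissue panels.

A caveat worth knowing: at a fixed dominance ratio the score decreases
with the number of tissues — a gene exactly 10× above uniform background
scores 0.70 with 3 tissues but 0.51 with 8 — so scores should be compared
within one atlas, not across atlases of different width.

# Co-expression analysis

The network is unsigned, $a_{ij} = |cor(x_i, x_j)|^\beta$ (Pearson), the
WGCNA default when the sign convention is not dictated. $\beta$ is the
smallest candidate power whose signed scale-free fit $R^2$ (regression of
log-binned connectivity frequency on log connectivity, 10 equal-width
bins) reaches the target 0.8; if none reaches it, the best power is used
with a warning. The topological overlap matrix is

$$TOM_{ij} = \frac{L_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},$$

verified against a triple-loop oracle to 1e-12.

Module detection is a deliberately simple surrogate for hybrid dynamic
tree cutting, with three numerical choices:

* **Cut height.** Average-linkage clustering of $1 - TOM$ is cut at 99% of
  the merge-height *range* above the first merge. The range-relative form
  matters: at high powers TOM dissimilarities compress into a narrow band
  below 1, and a cut at 99% of the absolute maximum height falls far below
  the root and shatters modules.
* **Straggler assignment.** Branches below `min_module_size` (default 30)
  are unassigned; unassigned genes are then adopted by the module whose
  eigengene they correlate with at $|kME| \ge 0.3$, mirroring the PAM
  stage of the hybrid algorithm. Without this stage, loosely attached
  module genes cut off as singletons depress recovery even when the
  detected modules are pure.
* **Eigengene merging.** Modules whose eigengenes have $1 - cor$ below
  `merge_cut` (default 0.25) are merged iteratively, closest pair first;
  ties resolve to the lowest module index.

Eigengenes are first singular vectors of the row-standardized module
submatrix, scaled to unit variance and sign-aligned so the mean gene
correlation is positive. Module significance uses the two standard
indices: the eigengene–trait correlation (t-distribution p, $df = n-2$)
and the per-module correlation between module membership $|kME|$ and gene
significance $GS = |cor(gene, trait)|$. Binary traits are encoded
case = 1/control = 0 and tissue brain/blood as 1/0; these encodings are
package defaults, not reconstructions of any particular dataset.

# Enrichment

Over-representation uses the exact hypergeometric upper tail with BH
adjustment; the universe is the set of genes entering the co-expression
network (the conservative, self-contained background), and sets are
filtered to 10–500 members by default. Module gene lists are unranked, so
ORA is the operative path; a weighted Kolmogorov–Smirnov running-sum GSEA
with a set-membership permutation null is provided for ranked inputs.

# The synthetic-data generator

`generate_multistudy_counts` draws counts
$NB(\mu = s_j q_g 2^{x_j \lambda_{gj}}, \phi)$ with case indicator $x_j$,
per-sample library sizes log-uniform over `lib_size_range` (default
5e5–5e6, making TMM non-trivial), and per-gene relative abundances from a
normalized gamma. Defaults mirror a realistic 20-study design with
unequal arms (cases 3–58, controls 3–234, blood and brain halves); the
validation harnesses use balanced 20/20 arms so that recovery targets are
clean. The user-facing effect `delta` is the **true standardized effect**:
it is converted to a log2 shift per gene and study as
$\lambda_{gj} = (\delta_g + b_{gj})\,\sigma_{gj}$ with
$b_{gj} \sim N(0, \tau^2)$ and
$\sigma_{gj} = \sqrt{\overline{1/\mu} + \psi_1(1/\phi)}/\ln 2$, where
$\psi_1(1/\phi)$ is the exact log-variance of the gamma mixing component
and $\overline{1/\mu}$ the delta-method Poisson term. This makes the true
per-study SMD equal $\delta_g + b_{gj}$ by construction, so recovery is
checkable analytically (plain $\phi$ in place of $\psi_1(1/\phi)$
understates the log-scale SD by ~2.5% at $\phi = 0.1$ and visibly
attenuates recovered effects). Optional latent modules multiply the NB
mean by a per-sample factor shared within a module, with module 1's factor
correlated with case status, so the end-to-end pipeline has disease-linked
co-expression structure; calibration runs leave this off.

What the generator does **not** emulate: read-level noise, gene length and
GC effects, batch structure beyond per-study random effects, count
correlation between genes outside the planted modules, and the extreme
zero-inflation of very low-abundance lncRNAs. Passing tests therefore
demonstrate the statistics are implemented correctly and calibrated under
the stated model, not that real data meet that model.

`generate_tissue_atlas` plants one-tissue-dominant genes at a 10× ratio;
`generate_coexpression_data` builds gene = $\rho E_m + \sqrt{1-\rho^2}\,
\varepsilon$ with a trait-linked first module; `generate_gene_sets` plants
one set per module drawing `enrichment_strength` of members from it.

# Validation problem sizes

The test-suite and acceptance-script harnesses use: 1,000 random instances
for the pooling/FDR closed-form oracles (1e-10); a 10,000-gene, 5-study
homogeneous null for heterogeneity calibration; 2,000 genes × 10 studies
(20/20 arms) for effect recovery (±0.05 of $J\delta$) and random-effects
CI coverage; 500 p-vectors for the adaptive-Fisher exhaustive check;
20-node matrices for the TOM oracle (1e-12); the 200-gene/60-sample/
3-module benchmark (ARI ≥ 0.8, 200 trait-linkage runs); 100 simulations
for planted-set detection and the ORA null; and the 5-study × 2,000-gene
deterministic end-to-end fixture.

# Known limitations

* **Random-effects CI coverage.** The DerSimonian–Laird interval with the
  1.96 quantile undercovers at small-to-moderate study counts: at
  $k = 10$, $\tau^2 = 0.2$, $v \approx 0.10$ its true coverage is ≈92%,
  not 95% (20,000-replicate simulation; metafor's DL implementation
  agrees). Knapp–Hartung-type adjustments would fix this but are outside
  the model implemented here; treat the CI as mildly optimistic when few
  studies are pooled under REM.
* The raw AW-Fisher statistic is anti-conservative (see above); use the
  permutation calibration for inference on it.
* The module detector is a static-cut surrogate of hybrid dynamic tree
  cutting; deeply nested or strongly unequal-density modules may need the
  full algorithm.
* Within-study normalisation is an interpretation: studies are normalised
  independently and combined at the effect-size level (and, for the
  network, as per-gene z-scores within study). Cross-study normalisation
  is deliberately not attempted.
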