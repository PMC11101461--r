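---
title: "Multi-omics biomarker discovery with snfmark: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omics biomarker discovery with snfmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snfmark)
```

## The problem

Neuroblastoma cohorts are typically profiled on several molecular levels at
once — DNA methylation (beta values per CpG reporter), mRNA expression (FPKM)
and miRNA expression — for on the order of a hundred patients. No single layer
carries the whole subtype structure, and univariate screens on any one layer
waste the shared signal. `snfmark` implements an integrative route from the
three raw layers to a ranked list of candidate biomarkers:

1. per-layer quality control and normalization;
2. similarity network fusion (SNF) of the per-layer patient similarity
   networks into one fused network;
3. selection of the number of disease subtypes with a similarity-space
   clustering-quality ratio;
4. ranked-SNF (rSNF) feature scoring: how concordant is the clustering induced
   by each single feature with the fused clustering;
5. intersection of the top-ranked gene sets of the methylation and mRNA layers
   into *essential genes*;
6. construction of a TF–miRNA–target regulatory network from curated
   interaction tables restricted to those essential genes and the top-ranked
   miRNAs, with hub nodes ranked by maximal clique centrality (MCC);
7. prognostic and diagnostic validation of the hubs (Kaplan–Meier / log-rank,
   chi-square stage association, ROC/AUC).

Everything runs on a synthetic cohort with known ground truth, so every stage
is testable without access to restricted patient-level data.

## Preprocessing model

Methylation samples are screened by their mean detection p-value with a strict
`< 0.005` rule. Features are then filtered in a fixed order — rows containing
NA, multimapped reporters, X/Y-chromosome features (methylation and mRNA only;
the sex filter avoids selecting sex-linked pseudo-biomarkers), and all-zero
rows — with a per-step accounting report that reconciles exactly
(`before − Σremoved = after`). The order matters only for the per-step
tallies, not for the surviving set.

mRNA FPKM values are rescaled per patient to TPM (`column / column sum × 1e6`)
so expression is comparable across samples, and every layer is then min–max
normalized **per feature across patients**. The per-feature axis is the one
that matters here because SNF's patient–patient distances aggregate feature
coordinates; a feature on an inflated scale would dominate the metric.
Constant features map to all zeros rather than being dropped, preserving
feature accounting. Note that TPM rescaling is defined on FPKM input: the
filters and the min–max step are idempotent, but re-running the mRNA chain on
an already-normalized matrix re-applies the column scaling, so preprocessing
is applied once per raw layer.

## SNF

For each layer, patient affinity uses the scaled exponential similarity
kernel on Euclidean distances,

$$W(i,j) = \exp\!\left(-\frac{d(i,j)^2}{\alpha\,\varepsilon_{ij}}\right),
\qquad
\varepsilon_{ij} = \frac{\overline{d}(i, N_i) + \overline{d}(j, N_j) + d(i,j)}{3},$$

where $N_i$ is the set of the $k$ nearest neighbors of patient $i$. Two
row-stochastic kernels are derived from each $W$: a dense kernel
$P = W / (2\sum_{l \ne i} W(i,l))$ with $P(i,i) = 1/2$, and a sparse kernel
$S$ that row-normalizes over the $k$ nearest neighbors only. One fusion
iteration updates each view by cross-diffusion,
$P_v \leftarrow S_v \, \overline{P}_{u \ne v} \, S_v^\top$, after which the
iterate is re-symmetrized and its half-diagonal row normalization restored —
without that projection the iterates drift numerically. After $T$ iterations
the per-view kernels are averaged into the fused matrix.

Neighbor ties are broken by patient index, making runs bit-reproducible.
Defaults are $T = 15$, $k = 20$, $\alpha = 0.5$; `convergence_curve()`
reproduces the diagnostic that justifies them, the relative change between
fused matrices at consecutive parameter values in spectral norm, over
$T, k \in 2..50$ and $\alpha \in 0.05..1$. On the packaged synthetic cohort
the $T$-sweep decays below $10^{-3}$ well before $T = 15$ and then sits at
the numerical floor; the test suite asserts monotone decay down to that floor
($10^{-12}$) rather than strict monotonicity among values that are pure
floating-point noise.

## Cluster-count selection

`spectral_cluster()` is the symmetric normalized-Laplacian variant: the $c$
leading eigenvectors of $D^{-1/2} W D^{-1/2}$, rows scaled to unit norm,
then seeded k-means with 50 restarts. The number of clusters is chosen from
2..7 by the quality ratio

$$Q = \frac{\min_k \nabla(c_k)}{\max_{k \ne r} \Delta(c_k, c_r)},$$

the minimum within-cluster pairwise similarity over the maximum
between-cluster similarity (a similarity-space Dunn-index analogue; diagonal
entries never participate). Decisions the ratio's definition leaves open are
resolved as follows: singleton clusters contribute no within-pair and are
skipped in the outer minimum; a zero denominator with a positive numerator is
reported as $Q = +\infty$ with a `separated` flag (perfectly disconnected
clusters); a zero numerator with a zero denominator scores 0, since such a
partition carries no separation evidence. Ties between cluster counts go to
the smaller $c$ (parsimony).

## rSNF feature ranking

Each feature's one-dimensional patient profile is run through the same
affinity kernel (same $k$ and $\alpha$ as the fused run — the paper-level
method leaves this open and consistency is the simplest contract to state and
test), spectral-clustered into the fused solution's $c$ groups, and scored by
normalized mutual information against the fused partition. NMI is normalized
by the larger of the two partition entropies, which keeps the score in
$[0,1]$ and is the conservative choice among the standard normalizations; any
fixed choice preserves the induced ranking. Constant features are degenerate
under the kernel and score 0; NaN scores rank last. Per-feature k-means uses
20 restarts: the embeddings come from one-dimensional profiles, where the
restart landscape is small.

The top 10% of each layer's ranking is selected with a ceiling rule,
`ceiling(fraction * m)` — the rule is forced by reconciling published layer
sizes with published selection counts (379,522 features select 37,953;
1,594 select 160). Methylation and mRNA selections are mapped to gene symbols
(`;`-separated annotations contribute every symbol; unannotated features
drop out) and intersected into the essential-gene set.

## Regulatory network and MCC

Interaction records mimic curated TF–miRNA and miRNA–target databases:
each record carries a sign (activation / repression / generic regulation), an
evidence class (ChIP-seq–supported "level2", "literature", or "other") and a
cell-line context (tumor / normal). Filters keep level2 and literature
records from tumor contexts whose endpoints lie in the essential-gene and
top-miRNA sets. The network is a directed signed graph; parallel edges
collapse with specific signs overriding generic regulation and conflicting
specific signs flagged ambiguous; a symbol acting both as TF and as target
keeps the TF role.

MCC is computed on the undirected simple projection (direction and sign are
reporting attributes, not topology): $\mathrm{MCC}(v) = \sum_{C \ni v,
|C| \ge 2} (|C|-1)!$ over maximal cliques enumerated exactly via
Bron–Kerbosch with pivoting. For a node through which no triangle passes the
score equals its degree — which is the operative regime for a tripartite
TF→miRNA→gene topology, whose undirected projection is triangle-free. The
implementation is nonetheless general and is verified against an exhaustive
subset-enumeration oracle on random graphs. Hub ties break by degree, then
symbol order.

## Validation statistics

Expression is dichotomized at mean ± 0.25 standard deviations: below the
lower cutoff is "low", above the upper cutoff is "high", and patients
strictly inside the band are excluded from the two-group comparison. The
two-cutoff reading is the default because the "±" phrasing defines two
boundaries; the single-cutoff alternative (split at the mean) is available
via `rule = "single"`. Survival uses the Kaplan–Meier product-limit estimator
and the standard two-group log-rank chi-square (hypergeometric variance, ties
grouped by event time); stage association uses Pearson's chi-square without
continuity correction; no multiple-testing adjustment is applied, matching
the per-node `p < 0.05` convention of the framework this package implements.
AUC is the Mann–Whitney rank statistic
$P(\text{case} > \text{control}) + \tfrac12 P(\text{tie})$ with a fixed
direction — higher score predicts case, never auto-flipped, so
anti-predictive markers report AUC below 0.5.

## The synthetic cohort

`cohort_spec()` defaults describe the cohort the pipeline is designed around:
99 patients in 4 equiprobable latent subtypes, a 3-SD mean shift carried by
10% of each layer's clean features, and defect rates of 20% NA, 5%
multimapped and 3% sex-chromosome methylation reporters plus 2% all-zero
features per layer. Feature counts default to desk scale — 2,000 methylation
reporters, 2,000 genes, 500 miRNAs — so the full pipeline runs in about a
minute on one CPU; the selection and recovery behavior is driven by the
informative fraction and effect size, not by the absolute layer size, and the
arithmetic-forced selection counts are checked at the published sizes
directly.

Generation details, and why they look the way they do:

* **Methylation** is a sigmoid-transformed Gaussian rather than a Beta draw:
  it keeps the subtype mean-shift parameterization identical across layers
  while guaranteeing beta values in $[0,1]$. Expression layers exponentiate
  the same latent model into log-normal, FPKM-like positives.
* **Informative features** are shifted by `effect_size * noise_sd` in one
  random subtype each. The informative fraction is taken relative to the
  layer's *clean* features and planted features are never defective — so a
  top-10% selection after filtering is commensurate with the planted count,
  and recovery is a meaningful 0–100% scale.
* **Informative methylation reporters** are annotated to informative mRNA
  genes (cycled), so an essential-gene intersection exists by construction
  and is recorded in `truth$shared_informative_genes`.
* **Survival** is exponential with a 1,500-day baseline median and
  multiplicative subtype hazard ratios (default geometric spacing 1→4);
  censoring is uniform administrative, with the horizon solved numerically so
  the expected censored fraction matches `censoring_rate`. This is the
  simplest model in which log-rank separation between expression groups is
  tunable. INSS stages are drawn from per-subtype distributions that skew
  high-hazard subtypes toward stage 4.
* **Interaction tables** use the column vocabulary of the real databases so
  every filter branch is exercised, and plant one hub TF (drawn from the
  shared informative genes) and one hub miRNA with many high-confidence
  tumor-context edges. With the default degrees the two planted hubs occupy
  the top of the MCC ranking; which of the two wins depends on how many of
  their partners survive the data-driven essential/top-miRNA filters, so
  recovery checks assert on the pair, not on one fixed winner.

What the generator does **not** emulate: array chemistry and probe-level
artifacts, sequencing counts and depth effects, batch effects, correlated
feature blocks, or realistic miRNA targeting biology. Passing tests therefore
demonstrate the pipeline's statistical machinery and bookkeeping under the
stated generative assumptions — not performance on real TARGET/GEO cohorts.

## Problem sizes used in the checks

The packaged end-to-end checks run the 99-patient cohort at the desk-scale
layer sizes above; unit fixtures use 60–80 patients with a few hundred
features per layer, sizes at which the planted structure is still recovered
reliably by the default $k = 20$ kernel. The brute-force MCC oracle runs on
random graphs of up to 15 nodes, where exhaustive subset enumeration is
exact and fast.

## Worked example

```{r example, eval = FALSE}
spec <- cohort_spec(seed = 7)
report <- run_pipeline(pipeline_config(spec = spec, diagnostics = TRUE))
report
report$hubs
ggplot2::autoplot(report$selection)
ggplot2::autoplot(report$convergence)
```

## Known limitations

* The fused matrix, not a consensus over seeds, feeds the downstream steps;
  k-means restarts make the clustering stable but a pathological similarity
  matrix can still flip label assignments between platforms.
* Maximal clique enumeration is exponential in the worst case; the networks
  this pipeline builds are sparse and tripartite-like, where it is fast, but
  `mcc_scores()` on a dense arbitrary graph can be expensive.
* The per-feature rSNF loop is linear in the feature count with an
  $O(n^3)$ eigendecomposition per feature; at array scale (hundreds of
  thousands of reporters) it parallelizes trivially across features, but the
  packaged default is single-core.
* With `rule = "two-cutoff"` dichotomization, up to a third of patients can
  fall inside the exclusion band for near-symmetric expression
  distributions, reducing log-rank power at small $n$.
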