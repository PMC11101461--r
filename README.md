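# snfmark

Multi-omics biomarker discovery for neuroblastoma-style cohorts: similarity
network fusion (SNF) of methylation / mRNA / miRNA layers, ranked-SNF feature
selection, TF–miRNA–target regulatory-network construction with maximal
clique centrality (MCC) hub ranking, and survival / stage / ROC validation of
the candidate biomarkers. A synthetic-cohort generator with planted ground
truth (subtypes, informative features, network hubs) makes every stage of the
pipeline verifiable on one machine.

## Who it is for

Computational biologists who have feature-by-patient matrices for several
omics layers of one cohort (beta values, FPKM, miRNA expression), clinical
follow-up (overall survival, INSS stage), and curated interaction tables
(TransmiR-/TarBase-style), and who want an integrative, network-based
candidate-biomarker list rather than per-layer univariate screens — or who
want to study the behavior of this class of pipeline under controlled,
simulated conditions.

## The method

Per layer, patient similarity uses the scaled exponential kernel
`W(i,j) = exp(−d(i,j)² / (α·ε_ij))` with a local scale `ε_ij` from the k
nearest neighbors. SNF cross-diffuses the layers' dense kernels `P_v` through
their sparse kNN kernels `S_v` (`P_v ← S_v · mean(P_u, u≠v) · S_vᵀ`, T
iterations, default `T = 15, k = 20, α = 0.5`) and averages them into a fused
patient network. The number of subtypes `c` is picked from 2..7 by the
clustering-quality ratio `Q = min intra-cluster similarity / max
inter-cluster similarity` under spectral clustering. Each feature is then
scored by the normalized mutual information (NMI) between the clustering its
own similarity network induces and the fused clustering; the top 10% per
layer (ceiling rule) are kept, methylation- and mRNA-derived gene sets are
intersected into *essential genes*, and a directed signed regulatory network
is assembled from TF→miRNA and miRNA→target records involving those genes
and the top miRNAs (level2/literature evidence, tumor context only). Hubs
are ranked by `MCC(v) = Σ_{cliques C ∋ v} (|C|−1)!`, and each hub is
validated by Kaplan–Meier / log-rank on mean ± 0.25 SD expression groups,
chi-square association with INSS stage, and rank-statistic AUC.

## Worked example

```r
library(snfmark)

spec <- cohort_spec(seed = 7)      # 99 patients, 4 subtypes, 2000/2000/500 features
report <- run_pipeline(pipeline_config(spec = spec))
report
#> <pipeline_report>
#>   c* = 4 (NMI vs truth 1.000)
#>   essential genes: 140; network: 34 nodes / 32 edges
#>   top hub: hsa-mir-0302 (MCC 16)

head(report$hubs, 5)
#> # A tibble: 5 x 5
#>   node         role    mcc degree  rank
#> 1 hsa-mir-0302 miRNA    16     16     1
#> 2 GENE0962     TF       13     13     2
#> 3 GENE0733     TF        3      3     3
#> 4 hsa-mir-0108 miRNA     2      2     4
#> 5 GENE0059     gene      1      1     5

head(report$validation[, c("node", "role", "lr_p", "chisq_p", "auc_stage4")], 3)
#> # A tibble: 3 x 5
#>   node         role      lr_p chisq_p auc_stage4
#> 1 hsa-mir-0302 miRNA 0.308     0.207       0.405
#> 2 GENE0962     TF    0.000753  0.0101      0.676
#> 3 GENE0733     TF    0.152     0.123       0.242
```

The report says: the fused network recovers the four planted subtypes exactly
(`c* = 4`, NMI 1 against the generator's truth); 140 genes are informative in
both the methylation and mRNA top deciles; the filtered interaction network
has 34 nodes, and its two top hubs are exactly the planted hub miRNA
(MCC 16) and hub TF (MCC 13) — in this tripartite topology MCC equals node
degree. The hub TF's expression groups separate survival strongly
(log-rank p = 7.5e-4) and associate with stage (chi-square p = 0.01),
consistent with its planted subtype linkage; `auc_stage4` is each marker's
ability to discriminate stage-4 patients.

The quality-ratio profile behind `c* = 4` is in `report$selection$profile`,
and `ggplot2::autoplot()` has methods for the selection profile, convergence
curves (`diagnostics = TRUE`), feature rankings, KM fits and ROC curves.
`cohort_spec()`, `snf_params()` and `pipeline_config()` expose every knob
(effect size, defect rates, hazard ratios, k/alpha/T, selection fraction,
dichotomization width). See the vignette in `vignettes/` for the model,
parameter meanings and design decisions.

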