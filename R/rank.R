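#' Normalized mutual information between two partitions
#'
#' Mutual information of the label contingency table normalized by the larger
#' of the two entropies, giving a symmetric score in \[0, 1\] that equals 1
#' exactly when the partitions are identical up to relabeling. Two trivial
#' single-cluster partitions are identical, hence score 1; a single-cluster
#' partition against a non-trivial one scores 0.
#'
#' @param a,b label vectors over the same patients.
#' @return NMI score in \[0, 1\].
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) abort("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  pj <- rowSums(tab) / n
  pk <- colSums(tab) / n
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- h(pj); hb <- h(pk)
  if (ha == 0 && hb == 0) return(1)
  p <- tab / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (pj[row(p)[nz]] * pk[col(p)[nz]])))
  max(0, min(1, mi / max(ha, hb)))
}

#' Ranked-SNF feature scoring
#'
#' For each feature of a layer: build a patient similarity matrix from that
#' single feature's profile (same kernel and hyperparameters as the fused
#' run), spectral-cluster it into the fused solution's `c` groups, and score
#' the concordance of the two partitions by [nmi()]. Features are ranked by
#' score, descending; constant (degenerate) features score 0 and rank last.
#'
#' @param x preprocessed [omics_matrix()].
#' @param fused_labels cluster labels from the fused similarity matrix.
#' @param c number of clusters (the fused run's selection).
#' @param params [snf_params()] reused for the single-feature kernels.
#' @param seed seed for the per-feature spectral clustering.
#' @param nstart k-means restarts per feature (default 20; the per-feature
#'   embeddings are one-dimensional profiles, where fewer restarts suffice).
#' @return tibble (class `feature_ranking`) with `feature_id`, `layer`,
#'   `score`, `rank` (1 = best), sorted by rank.
#' @export
rank_features <- function(x, fused_labels, c, params = snf_params(),
                          seed = 1L, nstart = 20) {
  vals <- x$values
  if (length(fused_labels) != ncol(vals)) {
    abort("fused_labels must cover the layer's patients")
  }
  scores <- vapply(seq_len(nrow(vals)), function(i) {
    v <- vals[i, ]
    if (length(unique(v)) == 1) return(0)  # degenerate: no similarity signal
    w <- affinity_matrix(v, params)
    lab <- spectral_cluster(w, c, seed = seed, nstart = nstart)
    nmi(lab, fused_labels)
  }, numeric(1))
  scores[is.na(scores)] <- 0
  ord <- order(-scores, rownames(vals))
  structure(
    tibble(
      feature_id = rownames(vals)[ord],
      layer = x$layer,
      score = scores[ord],
      rank = seq_along(ord)
    ),
    class = c("feature_ranking", class(tibble()))
  )
}

#' Select the top fraction of a feature ranking
#'
#' Takes the top `ceiling(fraction * m)` features; the ceiling reconciles a
#' 10% rule with selections like 379,522 features -> 37,953 and
#' 1,594 -> 160. Boundary ties are already resolved by the ranking's stable
#' order (score descending, then feature ID).
#'
#' @param ranking a [rank_features()] tibble (any tibble with `feature_id`
#'   ordered best-first works).
#' @param fraction fraction in (0, 1\].
#' @return tibble of the selected rows (a feature set).
#' @export
select_top_fraction <- function(ranking, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  head(ranking, n_top_features(nrow(ranking), fraction))
}

#' Number of features a top-fraction selection keeps
#'
#' @param m total feature count.
#' @param fraction selection fraction.
#' @return `ceiling(fraction * m)` as an integer.
#' @export
n_top_features <- function(m, fraction = 0.10) {
  as.integer(ceiling(fraction * m))
}

#' Map selected features to gene symbols
#'
#' Union of the gene symbols annotated to the selected features; `;`-separated
#' multi-gene annotations contribute every symbol, unannotated features are
#' dropped.
#'
#' @param feature_set tibble with a `feature_id` column
#'   (e.g. from [select_top_fraction()]).
#' @param annotation tibble with `reporter_id` and `gene_symbol` columns.
#' @return character vector of unique gene symbols.
#' @export
map_features_to_genes <- function(feature_set, annotation) {
  ids <- feature_set$feature_id
  sym <- annotation$gene_symbol[match(ids, annotation$reporter_id)]
  sym <- sym[!is.na(sym) & sym != ""]
  unique(unlist(strsplit(sym, ";", fixed = TRUE)))
}

#' Essential genes: intersection of two layers' top gene sets
#'
#' Genes present among the top-ranked features of both the methylation and
#' mRNA layers.
#'
#' @param methyl_genes,mrna_genes character vectors of gene symbols.
#' @return character vector (sorted) of shared genes; empty with a warning if
#'   the sets are disjoint.
#' @export
essential_genes <- function(methyl_genes, mrna_genes) {
  out <- sort(intersect(methyl_genes, mrna_genes))
  if (length(out) == 0) {
    warn("no shared genes between layers: downstream network will be empty")
  }
  out
}
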