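#' Spectral clustering of a patient similarity matrix
#'
#' Normalized-Laplacian spectral embedding (the symmetric variant: leading
#' `c` eigenvectors of `D^{-1/2} W D^{-1/2}`, rows scaled to unit length)
#' followed by seeded k-means with multiple restarts. Deterministic given the
#' seed; cluster labels are canonicalized by first occurrence in patient
#' order.
#'
#' @param s symmetric nonnegative similarity matrix.
#' @param c number of clusters, `2 <= c <= n - 1`.
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of k-means restarts (default 50).
#' @return integer vector of labels in `1..c`, named by patient when `s` has
#'   dimnames.
#' @export
spectral_cluster <- function(s, c, seed = 1L, nstart = 50) {
  n <- nrow(s)
  if (c < 2 || c > n - 1) abort("need 2 <= c <= n - 1")
  ncomp <- if (all(s[upper.tri(s)] > 0)) 1L else {
    g <- igraph::graph_from_adjacency_matrix(s > 0, mode = "undirected", diag = FALSE)
    igraph::components(g)$no
  }
  if (ncomp > c) {
    warn(sprintf("similarity graph has %d components but c = %d", ncomp, c))
  }
  deg <- rowSums(s)
  deg[deg <= 0] <- .Machine$double.eps
  dhalf <- 1 / sqrt(deg)
  lsym <- s * outer(dhalf, dhalf)  # normalized adjacency D^-1/2 W D^-1/2
  ev <- eigen(lsym, symmetric = TRUE)
  emb <- ev$vectors[, seq_len(c), drop = FALSE]
  rn <- sqrt(rowSums(emb^2))
  rn[rn == 0] <- 1
  emb <- emb / rn
  km <- withr::with_seed(seed, kmeans(emb, centers = c, nstart = nstart, iter.max = 100))
  labels <- canonicalize_labels(km$cluster)
  names(labels) <- rownames(s)
  labels
}

# Relabel clusters 1..c by order of first appearance.
canonicalize_labels <- function(labels) {
  first <- match(unique(labels), labels)
  map <- integer(max(labels))
  map[labels[sort(first)]] <- seq_along(first)
  as.integer(map[labels])
}

#' Clustering-quality ratio of a partition under a similarity matrix
#'
#' The similarity-space analogue of the Dunn index: for each cluster the
#' intra-cluster similarity is the minimum pairwise similarity of its members
#' (`i != j`; diagonal entries never participate); the numerator is the
#' minimum of those over clusters, the denominator the maximum similarity
#' between members of different clusters, and `Q` their ratio. Higher `Q`
#' means tighter, better-separated clusters.
#'
#' Singleton clusters have no within pair and are skipped in the numerator's
#' minimum. A zero denominator yields `Q = Inf` with `separated = TRUE`.
#'
#' @param s symmetric similarity matrix.
#' @param labels integer cluster labels over the patients of `s`.
#' @return tibble (class `quality_ratio`) with columns `numerator`
#'   (min intra-cluster similarity), `denominator` (max inter-cluster
#'   similarity), `q` and `separated`.
#' @export
quality_ratio <- function(s, labels) {
  n <- nrow(s)
  if (length(labels) != n) abort("one label per patient required")
  same <- outer(labels, labels, "==")
  offdiag <- !diag(TRUE, n)
  within <- same & offdiag
  between <- !same
  if (!any(within)) abort("all clusters are singletons: no within-cluster pair")
  if (!any(between)) abort("a single cluster has no between-cluster pair")
  nabla <- min(s[within])
  delta <- max(s[between])
  tibble(
    numerator = nabla,
    denominator = delta,
    # a zero denominator flags perfect separation (Q = +Inf) unless the
    # numerator is also zero, which carries no separation evidence at all
    q = if (delta > 0) nabla / delta else if (nabla > 0) Inf else 0,
    separated = delta == 0 && nabla > 0
  )
}

#' Select the number of clusters by the quality ratio
#'
#' Spectral-clusters the similarity matrix for every candidate cluster count,
#' scores each partition with [quality_ratio()], and returns the count with
#' the highest `Q` (ties broken toward the smaller, more parsimonious count).
#'
#' @param s symmetric similarity matrix (typically the fused SNF output).
#' @param c_range candidate counts (default `2:7`).
#' @param seed seed passed to [spectral_cluster()].
#' @param nstart k-means restarts per candidate.
#' @return list (class `cluster_selection`) with `c_star`, `labels` (for
#'   `c_star`), and `profile`: a tibble of `c`, `numerator`, `denominator`,
#'   `q`, `separated`.
#' @export
select_n_clusters <- function(s, c_range = 2:7, seed = 1L, nstart = 50) {
  n <- nrow(s)
  if (any(c_range < 2 | c_range > n - 1)) abort("c_range must lie in [2, n - 1]")
  runs <- lapply(c_range, function(c) {
    lab <- spectral_cluster(s, c, seed = seed, nstart = nstart)
    list(labels = lab, q = quality_ratio(s, lab))
  })
  profile <- bind_cols(
    tibble(c = as.integer(c_range)),
    bind_rows(lapply(runs, `[[`, "q"))
  )
  best <- which(profile$q == max(profile$q))[1]  # ties -> smaller c
  structure(list(
    c_star = profile$c[best],
    labels = runs[[best]]$labels,
    profile = profile
  ), class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("<cluster_selection> c* = %d\n", x$c_star))
  print(x$profile)
  invisible(x)
}

#' @rdname select_n_clusters
#' @param x a `cluster_selection`.
#' @param ... unused.
#' @export
tidy.cluster_selection <- function(x, ...) x$profile

#' @rdname select_n_clusters
#' @export
glance.cluster_selection <- function(x, ...) {
  tibble(c_star = x$c_star, q_max = max(x$profile$q),
         n_candidates = nrow(x$profile))
}
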