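#' SNF hyperparameters
#'
#' @param k number of nearest neighbors for the local kernel scale and the
#'   sparse kernel (default 20).
#' @param alpha bandwidth scale of the scaled exponential similarity kernel
#'   (default 0.5).
#' @param t number of fusion iterations (default 15).
#'
#' The defaults are the values at which the fusion's relative spectral-norm
#' change between consecutive settings has flattened on cohorts of ~100
#' patients; all are overridable.
#'
#' @return an `snf_params` list.
#' @export
snf_params <- function(k = 20, alpha = 0.5, t = 15) {
  if (k < 1) abort("k must be >= 1")
  if (alpha <= 0) abort("alpha must be positive")
  if (t < 1) abort("t must be >= 1")
  structure(list(k = as.integer(k), alpha = alpha, t = as.integer(t)),
            class = "snf_params")
}

# k nearest neighbors of each row of a distance matrix, excluding self,
# ties broken by patient index.
knn_index <- function(d, k) {
  n <- nrow(d)
  k <- min(k, n - 1L)
  res <- vapply(seq_len(n), function(i) {
    ord <- order(d[i, -i], seq_len(n - 1L))[seq_len(k)]
    seq_len(n)[-i][ord]
  }, integer(k))
  if (k == 1L) matrix(res, ncol = 1L) else t(res)
}

#' Patient affinity matrix from one omics layer
#'
#' Scaled exponential similarity kernel on Euclidean patient-patient
#' distances: with `N_i` the `k` nearest neighbors of patient `i`, the local
#' scale is `eps_ij = (mean(d(i, N_i)) + mean(d(j, N_j)) + d(i, j)) / 3` and
#' `W(i, j) = exp(-d(i, j)^2 / (alpha * eps_ij))`. Identical patients get
#' weight 1; the matrix is symmetric by construction.
#'
#' @param x an [omics_matrix()] (features x patients) or a numeric matrix in
#'   the same orientation; a single-feature profile may be passed as a
#'   numeric vector over patients.
#' @param params [snf_params()].
#' @return symmetric nonnegative patient similarity matrix with patient
#'   dimnames.
#' @export
affinity_matrix <- function(x, params = snf_params()) {
  if (inherits(x, "omics_matrix")) x <- x$values
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1, dimnames = list("f", names(x)))
  n <- ncol(x)
  if (n < 3) abort("at least 3 patients required")
  d <- as.matrix(dist(t(x)))
  nn <- knn_index(d, params$k)
  mean_nn <- vapply(seq_len(n), function(i) mean(d[i, nn[i, ]]), numeric(1))
  eps <- (outer(mean_nn, mean_nn, "+") + d) / 3
  w <- exp(-d^2 / (params$alpha * eps))
  w[d == 0] <- 1  # includes the diagonal and exact duplicates
  w <- (w + t(w)) / 2
  dimnames(w) <- list(colnames(x), colnames(x))
  w
}

#' Full (dense) transition kernel
#'
#' Row-stochastic matrix giving half the mass to the diagonal:
#' `P(i, j) = W(i, j) / (2 * sum_{l != i} W(i, l))` off the diagonal and
#' `P(i, i) = 1/2`; every row sums to 1.
#'
#' @param w symmetric nonnegative similarity matrix.
#' @return row-stochastic matrix of the same dimension.
#' @export
full_kernel <- function(w) {
  off <- w
  diag(off) <- 0
  rs <- rowSums(off)
  if (any(rs <= 0)) abort("a patient has zero similarity to all others")
  p <- off / (2 * rs)
  diag(p) <- 0.5
  p
}

#' Sparse (kNN-masked) transition kernel
#'
#' Keeps only each patient's `k` most similar neighbors (ties broken by
#' patient index) and row-normalizes over them:
#' `S(i, j) = W(i, j) / sum_{l in N_i} W(i, l)` for `j` in `N_i`, else 0.
#' Rows sum to 1; the result is generally asymmetric and has zero diagonal.
#'
#' @param w symmetric nonnegative similarity matrix.
#' @param k neighbor count, `k < n`.
#' @return row-stochastic sparse kernel.
#' @export
sparse_kernel <- function(w, k) {
  n <- nrow(w)
  if (k >= n) abort("k must be smaller than the number of patients")
  s <- matrix(0, n, n, dimnames = dimnames(w))
  for (i in seq_len(n)) {
    ord <- order(-w[i, -i], seq_len(n - 1L))[seq_len(k)]
    nb <- seq_len(n)[-i][ord]
    tot <- sum(w[i, nb])
    if (tot <= 0) abort("a patient has zero similarity to all neighbors")
    s[i, nb] <- w[i, nb] / tot
  }
  s
}

# Re-symmetrize and restore the half-diagonal row normalization after an
# update step; keeps the iteration on the full_kernel manifold.
renormalize_kernel <- function(p) {
  p <- (p + t(p)) / 2
  p[p < 0] <- 0
  full_kernel(p)
}

#' Fuse patient similarity networks by iterative cross-diffusion
#'
#' Each view `v` holds a dense kernel `P_v` and a sparse kernel `S_v`; one
#' fusion iteration updates `P_v <- S_v %*% mean(P_u, u != v) %*% t(S_v)`,
#' then re-symmetrizes and restores the row normalization. After `t`
#' iterations the per-view kernels are averaged (and symmetrized) into the
#' fused similarity matrix.
#'
#' @param w_list list of >= 2 symmetric similarity matrices over the same
#'   patients in the same order (checked; no silent reindexing).
#' @param params [snf_params()].
#' @return fused symmetric nonnegative similarity matrix.
#' @export
snf_fuse <- function(w_list, params = snf_params()) {
  if (length(w_list) < 2) abort("at least two views required")
  ids <- dimnames(w_list[[1]])[[1]]
  for (w in w_list) {
    if (!is.null(ids) && !identical(dimnames(w)[[1]], ids)) {
      abort("views must share an identical patient ordering")
    }
    if (nrow(w) != nrow(w_list[[1]])) abort("views must have equal dimensions")
  }
  p <- lapply(w_list, full_kernel)
  s <- lapply(w_list, sparse_kernel, k = min(params$k, nrow(w_list[[1]]) - 1L))
  v <- length(w_list)
  for (iter in seq_len(params$t)) {
    p_new <- vector("list", v)
    for (i in seq_len(v)) {
      others <- Reduce(`+`, p[-i]) / (v - 1)
      p_new[[i]] <- renormalize_kernel(s[[i]] %*% others %*% t(s[[i]]))
    }
    p <- p_new
  }
  fused <- Reduce(`+`, p) / v
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- dimnames(w_list[[1]])
  fused
}

#' Convergence diagnostics over an SNF hyperparameter sweep
#'
#' Re-runs the fusion across a sorted grid of one hyperparameter (holding the
#' other two fixed) and reports, for each consecutive pair of grid values, the
#' relative change between the fused matrices in spectral norm:
#' `||F(g[i+1]) - F(g[i])||_2 / ||F(g[i])||_2`.
#'
#' @param w_list list of per-view similarity matrices (for sweeps of `t` or
#'   `k`) — for an `alpha` sweep supply `x_list`, the preprocessed layers,
#'   since the affinity kernel itself depends on `alpha`.
#' @param grid ascending parameter values (length >= 2); typical ranges are
#'   2..50 for `t` and `k` and 0.05..1 (step 0.05) for `alpha`.
#' @param which one of `"t"`, `"k"`, `"alpha"`.
#' @param params base [snf_params()] supplying the two fixed values.
#' @param x_list list of [omics_matrix()] layers, required when
#'   `which = "alpha"`.
#' @return tibble with `parameter`, `value` (the larger grid value of each
#'   pair) and `relative_change`; `nrow = length(grid) - 1`. Class
#'   `snf_convergence` for [autoplot()].
#' @export
convergence_curve <- function(w_list, grid, which = c("t", "k", "alpha"),
                              params = snf_params(), x_list = NULL) {
  which <- match.arg(which)
  if (length(grid) < 2) abort("grid must have at least two values")
  if (is.unsorted(grid, strictly = TRUE)) abort("grid must be strictly ascending")
  fused_at <- function(g) {
    pr <- params
    pr[[which]] <- g
    if (which == "alpha") {
      if (is.null(x_list)) abort("alpha sweep needs x_list (affinity depends on alpha)")
      snf_fuse(lapply(x_list, affinity_matrix, params = pr), pr)
    } else {
      snf_fuse(w_list, pr)
    }
  }
  fused <- lapply(grid, fused_at)
  rel <- vapply(seq_len(length(grid) - 1L), function(i) {
    norm(fused[[i + 1]] - fused[[i]], type = "2") / norm(fused[[i]], type = "2")
  }, numeric(1))
  structure(
    tibble(parameter = which, value = grid[-1], relative_change = rel),
    class = c("snf_convergence", class(tibble()))
  )
}
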