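test_that("affinity kernel matches hand evaluation on equidistant points", {
  # equilateral triangle in 2-D: all pairwise d = 1
  pts <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  x <- t(pts)
  dimnames(x) <- list(c("f1", "f2"), c("A", "B", "C"))
  w <- affinity_matrix(x, snf_params(k = 1, alpha = 0.5))
  # eps = (1 + 1 + 1)/3 = 1; W = exp(-1 / (0.5 * 1)) = exp(-2)
  off <- w[upper.tri(w)]
  expect_equal(off, rep(exp(-2), 3), tolerance = 1e-12)
  expect_equal(diag(w), c(A = 1, B = 1, C = 1))
  expect_true(isSymmetric(w))
})

test_that("identical patients get affinity 1 and alpha acts monotonically", {
  x <- matrix(c(0, 0, 1, 5), 1, 4,
              dimnames = list("f", paste0("P", 1:4)))
  w <- affinity_matrix(x, snf_params(k = 2, alpha = 0.5))
  expect_equal(w["P1", "P2"], 1)
  set.seed(2)
  y <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("f", 1:5), paste0("P", 1:8)))
  w1 <- affinity_matrix(y, snf_params(k = 3, alpha = 0.3))
  w2 <- affinity_matrix(y, snf_params(k = 3, alpha = 0.8))
  off <- upper.tri(w1)
  expect_true(all(w2[off] > w1[off]))
  expect_true(all(is.finite(w1)))
})

test_that("full kernel is the half-diagonal row normalization", {
  w <- matrix(c(1, 0.4, 0.4, 1), 2, 2)
  p <- full_kernel(w)
  expect_equal(p[1, 2], 0.5)
  expect_equal(p[1, 1], 0.5)
  set.seed(3)
  w <- matrix(runif(64), 8, 8); w <- (w + t(w)) / 2
  p <- full_kernel(w)
  expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-10)
  # permutation commutes
  perm <- sample(8)
  expect_equal(full_kernel(w[perm, perm]), p[perm, perm], tolerance = 1e-12)
  bad <- diag(2)
  expect_error(full_kernel(bad), "zero similarity")
})

test_that("sparse kernel keeps k neighbors with unit row sums", {
  set.seed(5)
  w <- matrix(runif(36, 0.1, 1), 6, 6); w <- (w + t(w)) / 2; diag(w) <- 1
  s_full <- sparse_kernel(w, 5)  # k = n - 1: row-normalized, zero diagonal
  expect_equal(diag(s_full), rep(0, 6))
  off <- w; diag(off) <- 0
  expect_equal(s_full, off / rowSums(off), tolerance = 1e-12)
  s1 <- sparse_kernel(w, 1)
  expect_equal(rowSums(s1 > 0), rep(1, 6), ignore_attr = TRUE)
  expect_equal(rowSums(s1), rep(1, 6), tolerance = 1e-12)
  expect_error(sparse_kernel(w, 6), "smaller")
})

test_that("fusing identical views reproduces the single-view clustering", {
  g <- rep(1:2, each = 10)
  ids <- sprintf("P%02d", 1:20)
  w <- matrix(0.1, 20, 20, dimnames = list(ids, ids))
  w[outer(g, g, "==")] <- 0.9
  diag(w) <- 1
  fused <- snf_fuse(list(w, w, w), snf_params(k = 5, t = 10))
  expect_true(isSymmetric(fused))
  expect_true(all(fused >= 0))
  lab_fused <- spectral_cluster(fused, 2, seed = 1)
  lab_single <- spectral_cluster(w, 2, seed = 1)
  expect_equal(nmi(lab_fused, lab_single), 1)
  expect_equal(nmi(lab_fused, g), 1)
})

test_that("fusion combines two orthogonal 2-block views into 4 blocks", {
  toy <- orthogonal_views(per = 8)
  fused <- snf_fuse(toy$views, snf_params(k = 9, t = 15))
  lab <- spectral_cluster(fused, 4, seed = 1)
  expect_equal(nmi(lab, toy$groups), 1)
  # neither single view can resolve 4 groups
  lab1 <- spectral_cluster(toy$views[[1]], 4, seed = 1)
  expect_lt(nmi(lab1, toy$groups), 1)
})

test_that("fusion is invariant to simultaneous patient permutation", {
  set.seed(7)
  n <- 12
  ids <- sprintf("P%02d", 1:n)
  mk <- function() {
    w <- matrix(runif(n * n, 0.05, 1), n, n)
    w <- (w + t(w)) / 2; diag(w) <- 1
    dimnames(w) <- list(ids, ids); w
  }
  views <- list(mk(), mk())
  fused <- snf_fuse(views, snf_params(k = 4, t = 5))
  perm <- sample(n)
  views_p <- lapply(views, function(w) w[perm, perm])
  fused_p <- snf_fuse(views_p, snf_params(k = 4, t = 5))
  expect_equal(fused_p, fused[perm, perm], tolerance = 1e-10)
})

test_that("mismatched patient orderings are rejected", {
  toy <- orthogonal_views(per = 4)
  v2 <- toy$views[[2]]
  shuffled <- v2[rev(seq_len(nrow(v2))), rev(seq_len(nrow(v2)))]
  expect_error(snf_fuse(list(toy$views[[1]], shuffled)), "ordering")
  expect_error(snf_fuse(toy$views[1]), "at least two")
})

test_that("convergence curve has the expected shape on a strong 2-block toy", {
  g <- rep(1:2, each = 10)
  ids <- sprintf("P%02d", 1:20)
  w <- matrix(0.1, 20, 20, dimnames = list(ids, ids))
  w[outer(g, g, "==")] <- 0.9
  diag(w) <- 1
  w2 <- w + 0.01  # slightly perturbed second view
  diag(w2) <- 1
  curve <- convergence_curve(list(w, w2), grid = 2:20, which = "t",
                             params = snf_params(k = 5))
  expect_equal(nrow(curve), 18)
  expect_lt(curve$relative_change[curve$value == 15], 1e-3)
  expect_error(convergence_curve(list(w, w2), grid = 5, which = "t"), "two values")
  expect_error(convergence_curve(list(w, w2), grid = c(5, 3), which = "t"),
               "ascending")
})
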