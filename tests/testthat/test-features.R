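test_that("complete-case restriction drops rows with any missing value", {
  m <- matrix(1:30, 10, 3)
  m[2, 1] <- NA
  m[7, 3] <- NA
  expect_equal(nrow(complete_case_matrix(m)), 8)
  expect_equal(complete_case_matrix(matrix(1:6, 2, 3)), matrix(1:6, 2, 3))
  all_na <- matrix(NA_real_, 2, 2)
  expect_warning(out <- complete_case_matrix(all_na), "no complete-case")
  expect_equal(nrow(out), 0)
})

test_that("PCA explains collinear samples with one component", {
  # samples lie on a line in feature space -> rank 1
  base <- c(1, 2, 3, 4)
  m <- outer(base, c(0, 1, 2, 3))
  rownames(m) <- paste0("p", 1:4)
  colnames(m) <- paste0("s", 1:4)
  pc <- pca_decompose(m)
  expect_equal(pc$var_explained[1], 1, tolerance = 1e-12)
  expect_equal(sum(pc$var_explained), 1, tolerance = 1e-9)
  # sign convention: dominant loading positive
  expect_gt(pc$loadings[which.max(abs(pc$loadings[, 1])), 1], 0)
  expect_error(pca_decompose(matrix(5, 3, 3)), "degenerate")
})

test_that("PCA fractions are rotation-invariant and reconstruction is exact", {
  set.seed(14)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("p", 1:20), paste0("s", 1:10)))
  pc <- pca_decompose(m)
  # orthogonal mix of the samples preserves the spectrum; the rotation must
  # fix the ones vector so the per-feature centering is unaffected
  n <- 10
  e <- rep(1, n) / sqrt(n)
  B <- qr.Q(qr(cbind(e, matrix(rnorm(n * (n - 1)), n))))
  O <- qr.Q(qr(matrix(rnorm((n - 1)^2), n - 1)))
  R <- B %*% rbind(c(1, rep(0, n - 1)), cbind(0, O)) %*% t(B)
  centered <- m - rowMeans(m)
  m2 <- centered %*% t(R)
  colnames(m2) <- paste0("s", 1:10)
  pc2 <- pca_decompose(m2)
  expect_equal(pc2$var_explained, pc$var_explained, tolerance = 1e-9)
  # full reconstruction of the centered matrix
  rec <- pc$scores %*% t(pc$loadings)
  expect_equal(rec, t(centered), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("top variance contributors follow eigenvalue-weighted loadings", {
  base <- c(0.1, 5, 1, 3)
  m <- outer(base, c(0, 1, 2, 3)) +
    matrix(rnorm(16, 0, 1e-4), 4, 4)
  rownames(m) <- c("pw", "px", "py", "pz")
  colnames(m) <- paste0("s", 1:4)
  pc <- pca_decompose(m)
  top <- top_variance_contributors(pc, k = 4, n_components = 1)
  expect_equal(top, rownames(m)[order(-abs(pc$loadings[, 1]),
                                      rownames(m))])
  # k = all rows returns the whole set
  expect_setequal(top_variance_contributors(pc, k = 4), rownames(m))
  # contribution is invariant to sample permutation
  pc_perm <- pca_decompose(m[, c(3, 1, 4, 2)])
  expect_equal(top_variance_contributors(pc_perm, k = 4, n_components = 1),
               top)
})

test_that("hierarchical clustering recovers duplicate-column blocks", {
  set.seed(19)
  a <- rnorm(30)
  b <- rnorm(30)
  m <- cbind(a1 = a, a2 = a + rnorm(30, 0, 1e-8), b1 = b,
             b2 = b + rnorm(30, 0, 1e-8))
  hc <- hierarchical_cluster(m, k = 2)
  expect_equal(unname(hc$labels["a1"]), unname(hc$labels["a2"]))
  expect_equal(unname(hc$labels["b1"]), unname(hc$labels["b2"]))
  expect_false(hc$labels["a1"] == hc$labels["b1"])

  # two columns produce the trivial single-merge dendrogram
  hc2 <- hierarchical_cluster(m[, 1:2])
  expect_equal(nrow(hc2$hclust$merge), 1)

  const <- cbind(x = rep(1, 5), y = rnorm(5))
  expect_error(hierarchical_cluster(const), "zero-variance.*x")

  # newick export round-trips through ape
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, colnames(m))
})

test_that("clustering labels are permutation-invariant up to relabeling", {
  co <- sim_cohort(51, n_proteins = 150, n_spike = 20, de_fraction = 0.3,
                   effect_size = 2, groups = c("A", "B", "C"),
                   samples_per_batch = 9, n_batches = 2)
  m <- fit_stabilizer(co$anchor)
  g <- apply_stabilizer(co$endogenous, m)
  rel <- complete_case_matrix(median_center(g))
  hc1 <- hierarchical_cluster(rel, k = 3)
  perm <- sample(ncol(rel))
  hc2 <- hierarchical_cluster(rel[, perm], k = 3)
  expect_equal(ari(hc1$labels[colnames(rel)],
                   hc2$labels[colnames(rel)]), 1)
})

test_that("fold-change correlation implements the Pearson product moment", {
  v <- setNames(c(1, 2, 3), c("P1", "P2", "P3"))
  expect_equal(fold_change_correlation(v, v)$r, 1)
  expect_equal(fold_change_correlation(v, -v)$r, -1)
  w <- setNames(c(2, 4, 6.5), names(v))
  # closed-form product-moment on (1,2,3) vs (2,4,6.5)
  r_hand <- (sum(v * w) - 3 * mean(v) * mean(w)) /
    sqrt((sum(v^2) - 3 * mean(v)^2) * (sum(w^2) - 3 * mean(w)^2))
  out <- fold_change_correlation(v, w)
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$r2, r_hand^2)
  expect_equal(out$n_shared, 3)
  # intersection semantics and the overlap floor
  v2 <- setNames(c(1, 2), c("P1", "P2"))
  expect_error(fold_change_correlation(v, v2), "insufficient-overlap")
})

test_that("probe collapse takes the per-gene median", {
  vals <- c(1, 3, 5, 10, 1, 3)
  genes <- c("A", "A", "A", "B", "C", "C")
  out <- collapse_by_gene_median(vals, genes)
  expect_equal(out, c(A = 3, B = 10, C = 2))
  expect_equal(collapse_by_gene_median(7, "X"), c(X = 7))
})
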