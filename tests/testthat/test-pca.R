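test_that("variance preselection keeps the top-variance fraction", {
  set.seed(5)
  x <- toy_matrix(rnbinom(8000, mu = 50, size = 5), nr = 1000)
  kept <- variance_preselect(x, 0.20)
  expect_equal(nrow(kept), 200L)
  expect_identical(variance_preselect(x, 1.0), x)

  # brute-force oracle: sort by variance, take top k
  v <- apply(x, 1, var)
  top <- rownames(x)[order(-v, rownames(x))][1:200]
  expect_setequal(rownames(kept), top)
  # input order preserved
  expect_identical(rownames(kept), rownames(x)[rownames(x) %in% top])
})

test_that("PCA satisfies the SVD identities", {
  set.seed(8)
  x <- toy_matrix(rnorm(120, 100, 10), nr = 20)
  p <- run_pca(x)
  centered <- t(x) - colMeans(t(x))[col(t(x))]
  centered <- scale(t(x), center = TRUE, scale = FALSE)
  recon <- p$scores %*% t(p$loadings)
  expect_lt(max(abs(recon - centered)), 1e-8)
  expect_true(all(diff(p$variance_explained) < 1e-12))
  # orthogonal scores, unit-norm loadings
  g <- crossprod(p$scores)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8 * max(diag(g)))
  expect_equal(unname(colSums(p$loadings^2)), rep(1, ncol(p$loadings)))

  # rank-1 matrix concentrates all variance in PC1
  r1 <- outer(c(1, 2, 3), c(1, 2, 3, 4))
  dimnames(r1) <- list(paste0("P", 1:3), paste0("S", 1:4))
  p1 <- run_pca(r1)
  expect_equal(p1$variance_explained[1], 1)

  const <- toy_matrix(rep(3, 8), nr = 2)
  expect_error(run_pca(const), "constant")
})

test_that("component association classifies forced structures", {
  scores <- matrix(c(rep(1, 4), rep(-1, 4), rnorm(8, sd = 0.01)), ncol = 2,
                   dimnames = list(paste0("S", 1:8), c("PC1", "PC2")))
  p <- structure(list(scores = scores,
                      loadings = matrix(0, 2, 2),
                      variance_explained = c(0.9, 0.1)),
                 class = "pca_result")
  meta <- sample_metadata(paste0("S", 1:8),
                          rep(c("D", "D*"), times = 4),
                          rep(c("1", "2"), each = 4))
  a <- pc_association(p, meta, 2)$table
  expect_equal(a$dominant_factor[1], "batch")
  expect_lt(a$batch_p[1], 1e-6)

  # constant scores: guarded to p = 1 / "neither"
  p$scores[, 1] <- 0
  a2 <- pc_association(p, meta, 1)$table
  expect_equal(a2$batch_p[1], 1)
  expect_equal(a2$dominant_factor[1], "neither")

  meta_one <- meta; meta_one$batch <- c("1", rep("2", 7))
  expect_error(pc_association(p, meta_one, 1), ">= 2 samples")
})

test_that("dominant-factor classification is scale invariant", {
  ds <- small_dataset(seed = 31)
  a1 <- pc_association(pca_workflow(ds$noisy), ds$meta, 3)$table
  a2 <- pc_association(pca_workflow(ds$noisy * 7), ds$meta, 3)$table
  expect_identical(a1$dominant_factor, a2$dominant_factor)
})

test_that("component removal keeps the remaining scores intact", {
  ds <- small_dataset(seed = 12)
  p <- pca_workflow(ds$noisy)
  expect_identical(remove_pcs(p)[, ], p$scores)
  f <- remove_pcs(p, 1)
  expect_identical(f[, ], p$scores[, -1])
  expect_equal(attr(f, "dropped"), 1L)
  expect_error(remove_pcs(p, seq_len(ncol(p$scores))), "all components")
  expect_error(remove_pcs(p, 99), "invalid")
})

test_that("Ward clustering recovers separated groups and matches the oracle", {
  set.seed(3)
  cloud <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 5, 0.1), 5))
  rownames(cloud) <- paste0("S", 1:10)
  cl <- cluster_samples(cloud, 2)
  expect_equal(length(unique(cl$labels[1:5])), 1L)
  expect_equal(length(unique(cl$labels[6:10])), 1L)
  expect_false(cl$labels[1] == cl$labels[6])

  # permutation invariance (up to label swap)
  perm <- sample(10)
  cl2 <- cluster_samples(cloud[perm, ], 2)
  expect_equal(canon_partition(cl2$labels[rownames(cloud)]),
               canon_partition(cl$labels))

  # brute-force O(n^3) Ward oracle: identical merge heights and partitions
  set.seed(9)
  y <- matrix(rnorm(18), 9, 2, dimnames = list(paste0("S", 1:9), NULL))
  tree <- cluster_samples(y, 2)$tree
  orc <- oracle_ward(y)
  expect_equal(sort(tree$height), sort(orc$heights), tolerance = 1e-10)
  for (k in 2:8)
    expect_equal(canon_partition(unname(stats::cutree(tree, k))),
                 canon_partition(orc$partitions[[k]]))

  expect_error(cluster_samples(cloud, 20), "exceeds")
})

test_that("traceback selects strong exclusive loaders deterministically", {
  # loadings concentrated on one protein -> singleton
  x <- toy_matrix(abs(rnorm(40, 10, 0.01)), nr = 10)
  x["P1", ] <- c(100, 200, 150, 250)
  p <- run_pca(x)
  expect_identical(traceback_proteins(p, 1), "P1")

  # all-equal loadings -> empty under the strength rule
  p_eq <- structure(list(scores = matrix(0, 2, 2),
                         loadings = matrix(0.5, 4, 2,
                                           dimnames = list(paste0("P", 1:4), NULL)),
                         variance_explained = c(0.5, 0.5)),
                    class = "pca_result")
  expect_length(traceback_proteins(p_eq, 1), 0L)

  # permutation invariance in protein order
  ds <- small_dataset(seed = 41)
  xr <- variance_preselect(log2(ds$noisy + 1), 0.2)
  t1 <- traceback_proteins(run_pca(xr), 1)
  perm <- sample(nrow(xr))
  t2 <- traceback_proteins(run_pca(xr[perm, ]), 1)
  expect_setequal(t1, t2)
})

test_that("removing first-component proteins exposes a disjoint signal set", {
  # constructed separable case: batch signal confined to proteins B*,
  # class signal confined to proteins C*, disjoint supports
  set.seed(6)
  n <- 8
  base <- matrix(100 + rnorm(40 * n, sd = 0.1), 40, n,
                 dimnames = list(c(paste0("B", 1:10), paste0("C", 1:5),
                                   paste0("N", 1:25)), paste0("S", 1:n)))
  batch2 <- 5:8; dstar <- c(3, 4, 7, 8)
  base[1:10, batch2] <- base[1:10, batch2] + rep(seq(30, 120, 10), length(batch2))
  base[11:15, dstar] <- base[11:15, dstar] + 15
  feats <- minus_pc1_features(base)
  expect_true(all(grepl("^C", feats)))
  expect_length(intersect(feats, paste0("B", 1:10)), 0L)
  expect_true(all(grepl("^B", attr(feats, "pc1_set"))))
})

test_that("top-n t-statistic ranking behaves at the boundaries", {
  ds <- small_dataset(seed = 19, n_proteins = 60)
  expect_setequal(top_n_by_tstat(ds$clean, ds$meta, 60), rownames(ds$clean))

  x <- toy_matrix(rep(c(10, 11), each = 4), nr = 1,
                  proteins = "P1", samples = paste0("S", 1:8))
  x <- rbind(x, toy_matrix(rnorm(8, 50, 0.1), nr = 1, proteins = "P2",
                           samples = paste0("S", 1:8)))
  x["P2", 5:8] <- x["P2", 5:8] + 500
  meta <- toy_meta(x, classes = rep(c("D", "D*"), each = 4),
                   batches = rep(c("1", "2"), times = 4))
  expect_identical(top_n_by_tstat(x, meta, 1), "P2")
})

test_that("co-clustering prediction resolves trivial and empty cases", {
  ds <- small_dataset(seed = 23)
  unk <- ds$noisy[, ds$meta$class == "D*", drop = FALSE]
  colnames(unk) <- paste0("U", 1:4)
  pr <- predict_labels_by_coclustering(ds$noisy, ds$meta, unk,
                                       unknown_batch = ds$meta$batch[ds$meta$class == "D*"])
  expect_true(all(pr == "D*"))

  empty <- ds$noisy[, 0, drop = FALSE]
  expect_length(predict_labels_by_coclustering(ds$noisy, ds$meta, empty), 0L)
})

test_that("preselected PCA finds the same batch-dominant component as full PCA", {
  agree <- vapply(1:20, function(s) {
    ds <- simulate_dataset(sim_config(n_proteins = 500, seed = 300 + s))
    lx <- log2(ds$noisy + 1)
    a_top <- pc_association(run_pca(variance_preselect(lx, 0.2)), ds$meta, 1)$table
    a_all <- pc_association(run_pca(lx), ds$meta, 1)$table
    a_top$dominant_factor[1] == a_all$dominant_factor[1]
  }, TRUE)
  expect_gte(mean(agree), 0.95)
})
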