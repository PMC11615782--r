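test_that("rclr matches hand-worked examples and the clr oracle", {
  X <- matrix(c(1, exp(1), exp(2)), 3, 1,
              dimnames = list(paste0("o", 1:3), "s1"))
  expect_equal(as.numeric(rclr_transform(X)), c(-1, 0, 1))

  X2 <- matrix(c(exp(1), exp(1), 0), 3, 1,
               dimnames = list(paste0("o", 1:3), "s1"))
  r2 <- rclr_transform(X2)
  expect_equal(as.numeric(r2[1:2, 1]), c(0, 0))
  expect_true(is.na(r2[3, 1]))

  dense <- toy_table() + 1   # zero-free
  expect_equal(rclr_transform(dense), oracle_clr(dense))

  bad <- toy_table()
  bad[, 2] <- 0
  expect_error(rclr_transform(bad), "s2")
})

test_that("rpca_features recovers low-rank structure and duplicates", {
  # rank-1 zero-free table: scores match a direct SVD oracle up to sign
  set.seed(3)
  u <- exp(rnorm(10)); v <- exp(rnorm(8))
  X <- outer(u, v)
  dimnames(X) <- list(paste0("o", 1:10), paste0("s", 1:8))
  ft <- rpca_features(X, rank = 1)
  M <- oracle_clr(X)
  sv <- svd(M)
  sc_o <- sv$v[, 1] * sv$d[1]
  expect_true(max(abs(as.numeric(ft$F) - sc_o)) < 1e-6 ||
                max(abs(as.numeric(ft$F) + sc_o)) < 1e-6)
  recon <- ft$loadings %*% t(ft$F)
  expect_lt(max(abs(recon - M)), 1e-6)

  # duplicated samples get identical scores
  Xd <- toy_table(10, 5, seed = 8)
  Xd <- cbind(Xd, dup = Xd[, 3])
  colnames(Xd)[6] <- "dup"
  ftd <- suppressWarnings(rpca_features(Xd, rank = 2))
  expect_equal(unname(ftd$F["dup", ]), unname(ftd$F["s3", ]), tolerance = 1e-4)

  # full rank on dense input: exact reconstruction
  Xf <- toy_table(6, 5, seed = 2) + 1
  ftf <- rpca_features(Xf, rank = 5)
  expect_lt(max(abs(ftf$loadings %*% t(ftf$F) - oracle_clr(Xf))), 1e-6)

  expect_error(rpca_features(Xf, rank = 99), "rank")
})

test_that("sum pooling is presence-based and validates labels", {
  E <- matrix(c(1, 2, 3, -1, 0.5, 0.5), 3, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("PC1", "PC2")))
  emb <- structure(list(X = E, explained_variance = c(1, 0.5)),
                   class = "pf_embedding")
  X <- matrix(c(2, 0, 0,   5, 3, 0), 3, 2,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  ft <- sum_pool_phylo(X, emb)
  expect_equal(unname(ft$F["s1", ]), c(1, 2))       # singleton sum
  expect_equal(unname(ft$F["s2", ]), c(4, 1))       # A + B
  # positive rescaling leaves features unchanged
  ft2 <- sum_pool_phylo(X * 10, emb)
  expect_identical(ft$F, ft2$F)

  X_extra <- rbind(X, D = c(1, 1))
  expect_error(sum_pool_phylo(X_extra, emb), "D")
})

test_that("fuse_features concatenates, standardizes, and validates", {
  A <- structure(list(F = matrix(rnorm(12), 4, 3,
                                 dimnames = list(paste0("s", 1:4), NULL)),
                      kind = "abundance"), class = "pf_features")
  P <- structure(list(F = matrix(rnorm(8), 4, 2,
                                 dimnames = list(paste0("s", 1:4), NULL)),
                      kind = "phylogeny"), class = "pf_features")
  fused <- fuse_features(A, P, standardize = FALSE)
  expect_identical(dim(fused$F), c(4L, 5L))
  expect_equal(unname(fused$F[, 1:3]), unname(A$F))  # slice recovers block

  # zero phylogeny block passes through as zeros
  P0 <- P; P0$F[] <- 0
  f0 <- fuse_features(A, P0, standardize = FALSE)
  expect_equal(unname(f0$F[, 4:5]), matrix(0, 4, 2))

  Pbad <- P
  rownames(Pbad$F) <- paste0("x", 1:4)
  expect_error(fuse_features(A, Pbad), "mismatch")
})

test_that("permanova_f reproduces the hand-computed pseudo-F and null behavior", {
  # 1-D features {0,1 | 10,11}: F = 200
  F_ <- matrix(c(0, 1, 10, 11), 4, 1,
               dimnames = list(paste0("s", 1:4), NULL))
  g <- c("a", "a", "b", "b")
  res <- permanova_f(F_, g, n_permutations = 0)
  expect_equal(res$F, 200)

  # matches the small-case oracle on random instances with <= 6 samples
  set.seed(31)
  for (i in 1:10) {
    n <- sample(4:6, 1)
    Fi <- matrix(rnorm(n * 2), n, 2, dimnames = list(paste0("s", 1:n), NULL))
    gi <- rep(c("a", "b"), c(2, n - 2))
    expect_equal(permanova_f(Fi, gi, n_permutations = 0)$F,
                 oracle_pseudo_f(Fi, gi), tolerance = 1e-10)
  }

  # unstructured labels: permutation p roughly uniform, F near 1 over repeats
  set.seed(12)
  fstats <- replicate(30, {
    Fn <- matrix(rnorm(24), 12, 2, dimnames = list(paste0("s", 1:12), NULL))
    permanova_f(Fn, rep(c("a", "b"), 6), n_permutations = 0)$F
  })
  expect_gt(mean(fstats), 0.5)
  expect_lt(mean(fstats), 1.8)

  # duplicating all samples increases F (df effect), direction only
  F2 <- rbind(F_, F_ + 1e-9)
  rownames(F2) <- paste0("s", 1:8)
  res2 <- permanova_f(F2, c(g, g), n_permutations = 0)
  expect_gt(res2$F, res$F)

  # agrees with vegan's adonis2 pseudo-F on Euclidean distances
  set.seed(44)
  Fv <- matrix(rnorm(30), 10, 3, dimnames = list(paste0("s", 1:10), NULL))
  gv <- rep(c("a", "b"), 5)
  f_vegan <- vegan::adonis2(dist(Fv) ~ gv, permutations = 0)$F[1]
  expect_equal(permanova_f(Fv, gv, n_permutations = 0)$F, f_vegan,
               tolerance = 1e-10)

  expect_error(permanova_f(F_, c("a", "b", "b", "b")), "< 2 samples")
  # identical features within groups: SS_within = 0 -> Inf with warning
  Fz <- matrix(c(0, 0, 5, 5), 4, 1, dimnames = list(paste0("s", 1:4), NULL))
  expect_warning(rz <- permanova_f(Fz, g, n_permutations = 0), "Inf")
  expect_identical(rz$F, Inf)
})

test_that("kmeans_ari and adjusted_rand_index behave at the extremes", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)

  set.seed(4)
  blob1 <- matrix(rnorm(40, 0), 20, 2)
  blob2 <- matrix(rnorm(40, 8), 20, 2)
  F_ <- rbind(blob1, blob2)
  rownames(F_) <- paste0("s", 1:40)
  labs <- rep(c("a", "b"), each = 20)
  expect_equal(kmeans_ari(F_, labs, k = 2, seed = 1), 1)

  # labels independent of structure: ARI near 0
  set.seed(6)
  aris <- replicate(20, {
    perm_labs <- sample(labs)
    adjusted_rand_index(rep(1:2, each = 20), perm_labs)
  })
  expect_lt(abs(mean(aris)), 0.1)

  expect_error(kmeans_ari(F_, labs, k = 99), "exceeds")
})

test_that("knn_eval separates separable data and errors on degenerate input", {
  set.seed(8)
  F_ <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 10), 30, 2))
  rownames(F_) <- paste0("s", 1:60)
  labs <- rep(c("a", "b"), each = 30)
  res <- knn_eval(F_, labs, k_neighbors = 1, n_folds = 10, seed = 2)
  expect_gt(res$auprc, 0.99)
  expect_gt(res$aps, 0.99)

  # permuted labels: APS near prevalence
  set.seed(13)
  labs_p <- sample(rep(c("a", "b"), c(15, 45)))
  res_p <- knn_eval(F_, labs_p, k_neighbors = 5, n_folds = 5, seed = 3)
  expect_lt(res_p$aps, 0.65)

  expect_error(knn_eval(F_, rep("a", 60), n_folds = 5), "2 classes")
  expect_error(knn_eval(F_, rep(c("a", "b"), c(3, 57)), n_folds = 10),
               "fewer")
})
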