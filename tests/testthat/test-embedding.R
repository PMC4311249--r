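test_that("pairwise distances honour the chosen norm", {
  d <- pairwise_distances(rbind(c(0, 0), c(3, 4)))
  expect_equal(d$values[1, 2], 5)
  expect_equal(diag(d$values), c(0, 0), ignore_attr = TRUE)

  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  dc <- pairwise_distances(x, "correlation")
  expect_equal(dc$values["a", "b"], 0)
  expect_equal(dc$values["a", "c"], 2)

  xc <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  err <- tryCatch(pairwise_distances(xc, "correlation"), error = identity)
  expect_s3_class(err, "ncmce_input")
  expect_match(conditionMessage(err), "a")
})

test_that("MST is optimal (brute-force check) and deterministic under ties", {
  # unique-MST 3-node example
  w <- matrix(c(0, 1, 4, 1, 0, 2, 4, 2, 0), 3)
  t3 <- minimum_spanning_tree(w)
  expect_equal(sum(t3$edges$weight), 3)
  expect_identical(t3$edges[, c("i", "j")],
                   data.frame(i = c(1L, 2L), j = c(2L, 3L)))

  # tie case: e-b and e-c both sqrt(41); lexicographic rule picks (b, e)
  pts <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1), e = c(5, 5))
  t4 <- minimum_spanning_tree(pairwise_distances(pts))
  expect_equal(sum(t4$edges$weight), 2 + sqrt(41))
  expect_true(any(t4$edges$i == 2 & t4$edges$j == 4))   # edge (b, e)
  expect_false(any(t4$edges$i == 3 & t4$edges$j == 4))

  # n = 2 trivial tree
  expect_equal(nrow(minimum_spanning_tree(matrix(c(0, 7, 7, 0), 2))$edges), 1)

  # random instances vs exhaustive Prufer enumeration
  set.seed(8)
  for (n in c(4, 5, 6)) {
    for (rep in 1:5) {
      x <- matrix(rnorm(n * 3), n)
      d <- pairwise_distances(x)
      t <- minimum_spanning_tree(d)
      expect_equal(sum(t$edges$weight), oracle_mst_weight(d$values))
    }
  }
})

test_that("MC-kernel sums tree paths and is an additive tree metric", {
  path_t <- structure(list(edges = data.frame(i = c(1L, 2L), j = c(2L, 3L),
                                              weight = c(1, 2)),
                           n = 3L, ids = c("a", "b", "c")),
                      class = "spanning_tree")
  k <- mc_kernel(path_t)
  expect_equal(k$values["a", "c"], 3)
  expect_equal(diag(k$values), rep(0, 3), ignore_attr = TRUE)

  pts <- rbind(a = c(0, 0), b = c(1, 0), c = c(0, 1), e = c(5, 5))
  k4 <- mc_kernel(minimum_spanning_tree(pairwise_distances(pts)))
  expect_equal(k4$values["c", "e"], 2 + sqrt(41))

  # dominance over the input metric + four-point condition, random instances
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(5:9, 1)
    d <- pairwise_distances(matrix(rnorm(n * 4), n))
    K <- mc_kernel(minimum_spanning_tree(d))$values
    expect_true(all(K - d$values >= -1e-9))
    expect_equal(K, t(K))
    quartets <- utils::combn(n, 4)
    for (q in seq_len(ncol(quartets))) {
      expect_true(four_point_ok(K, quartets[1, q], quartets[2, q],
                                quartets[3, q], quartets[4, q]))
    }
  }

  bad <- structure(list(edges = data.frame(i = 1L, j = 2L, weight = 1),
                        n = 3L, ids = c("a", "b", "c")),
                   class = "spanning_tree")
  expect_s3_class(tryCatch(mc_kernel(bad), error = identity),
                  "ncmce_structure")
})

test_that("ncMCE embeds the kernel by its SVD with fixed sign convention", {
  # exchange-type 2x2 kernel: singular values both 2; first dimension has
  # equal signs across samples, second dimension opposite signs
  e <- ncmce_embed(matrix(c(0, 2, 2, 0), 2), d = 2)
  expect_equal(e$spectrum, c(2, 2))
  expect_equal(abs(unname(e$coords)), matrix(1, 2, 2))
  expect_true(all(e$coords[, 1] > 0))
  expect_equal(sum(sign(e$coords[, 2])), 0)

  # rank-1 kernel: second spectrum entry 0
  v <- c(1, 2, 3)
  e1 <- ncmce_embed(tcrossprod(v), d = 2)
  expect_equal(e1$spectrum[2], 0)

  # permutation equivariance of coordinates
  set.seed(4)
  x <- matrix(rnorm(8 * 3), 8)
  K <- mc_kernel(minimum_spanning_tree(pairwise_distances(x)))$values
  perm <- sample(8)
  e_orig <- ncmce_embed(K, d = 3)
  e_perm <- ncmce_embed(K[perm, perm], d = 3)
  expect_equal(unname(e_perm$coords), unname(e_orig$coords[perm, ]),
               tolerance = 1e-9)

  # rank-d reconstruction from the SVD is Frobenius-optimal: error must match
  # the tail singular values
  sv <- svd(K)
  recon_err <- sqrt(sum((K - sv$u[, 1:3] %*% diag(sv$d[1:3]) %*%
                           t(sv$v[, 1:3]))^2))
  expect_equal(sqrt(sum(sv$d[-(1:3)]^2)), recon_err)
  expect_equal(ncmce_embed(K, d = 8)$spectrum, sv$d, tolerance = 1e-9)

  expect_s3_class(tryCatch(ncmce_embed(K, d = 9), error = identity),
                  "ncmce_dimension")
})

test_that("MCE double-centres the kernel before the SVD", {
  # constant off-diagonal kernel: centring annihilates the constant pattern
  Kc <- matrix(5, 4, 4); diag(Kc) <- 0
  e <- mce_embed(Kc, d = 2)
  expect_equal(sum(e$coords[, 1]), 0, tolerance = 1e-9)

  set.seed(6)
  A <- matrix(rnorm(25), 5); K <- A + t(A); diag(K) <- 0; K <- abs(K)
  # step-by-step oracle: explicit J K J then full SVD
  J <- diag(5) - matrix(1 / 5, 5, 5)
  Kcent <- J %*% K %*% J
  expect_equal(colSums(Kcent), rep(0, 5), tolerance = 1e-9)
  e2 <- mce_embed(K, d = 3)
  sv <- svd(Kcent)
  expect_equal(e2$spectrum, sv$d[1:3], tolerance = 1e-9)
  expect_equal(abs(unname(e2$coords)),
               abs(sweep(sv$v[, 1:3], 2, sqrt(sv$d[1:3]), `*`)),
               tolerance = 1e-9)
})

test_that("PCA baseline matches an independent eigendecomposition", {
  e <- pca_embed(rbind(c(1, 0), c(-1, 0)), d = 1)
  expect_equal(sort(unname(e$coords[, 1])), c(-1, 1))

  set.seed(10)
  x <- matrix(rnorm(24), 6, 4)
  e2 <- pca_embed(x, d = 4)
  expect_equal(sum(e2$spectrum), sum(apply(x, 2, var)))   # variance conserved

  eg <- eigen(cov(x), symmetric = TRUE)
  scores <- sweep(x, 2, colMeans(x)) %*% eg$vectors
  for (j in 1:4) {
    expect_equal(abs(unname(e2$coords[, j])), abs(unname(scores[, j])),
                 tolerance = 1e-8)
  }

  # invariance to adding a constant to any column
  x2 <- x; x2[, 2] <- x2[, 2] + 100
  expect_equal(pca_embed(x2, d = 2)$coords, pca_embed(x, d = 2)$coords,
               tolerance = 1e-8)

  expect_s3_class(tryCatch(pca_embed(x, d = 5), error = identity),
                  "ncmce_dimension")
})

test_that("the pipeline composes distances, MST, kernel and SVD", {
  g <- genotype_matrix(matrix(c(0, 2, 0, 2), 2), sample_ids = c("s1", "s2"))
  e <- embed_pipeline(g, "ncMCE", d = 2)
  expect_equal(sum(sign(e$coords[, 2])), 0)
  expect_message(embed_pipeline(g, "PCA", norm = "euclidean", d = 1),
                 "ignores the norm")

  # ncMCE pipeline equals the hand-chained steps
  set.seed(12)
  x <- matrix(rnorm(30), 10)
  e2 <- embed_pipeline(x, "ncMCE", d = 2)
  k <- mc_kernel(minimum_spanning_tree(pairwise_distances(x)))
  expect_equal(e2$coords, ncmce_embed(k, 2)$coords)

  # spectra are non-increasing for all methods
  for (m in c("ncMCE", "MCE", "PCA")) {
    e3 <- embed_pipeline(x, m, d = 3)
    expect_true(all(diff(e3$spectrum) <= 1e-12))
  }
})
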