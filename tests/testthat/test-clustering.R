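test_that("z-scoring centers and scales every dimension", {
  expect_equal(as.numeric(zscore_apply(zscore_fit(cbind(1:3)), cbind(1:3))),
               c(-1, 0, 1))
  set.seed(3)
  X <- matrix(rnorm(50 * 11, mean = 2, sd = 4), 50, 11)
  Z <- zscore_apply(zscore_fit(X), X)
  expect_lt(max(abs(colMeans(Z))), 1e-12)
  expect_equal(apply(Z, 2, sd), rep(1, 11), tolerance = 1e-12)
  Xz <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(zscore_fit(Xz), "b")
})

test_that("distance metrics match their definitions", {
  expect_equal(dist_sed(c(1, 2), c(1, 2)), 0)
  expect_equal(dist_sed(c(1, 0), c(0, 1)), 2)
  expect_equal(dist_cd(c(1, 1), 3 * c(1, 1)), 0)
  expect_equal(dist_cd(c(1, 0), c(0, 1)), 1)
  expect_equal(dist_cd(c(1, 2), -c(1, 2)), 2)
  expect_error(dist_cd(c(1, 0), c(0, 0)), "zero-norm")
  expect_error(dist_sed(1:2, 1:3), "equal length")
  set.seed(5)
  for (i in 1:10) {
    u <- rnorm(6); v <- rnorm(6)
    sed_loop <- 0
    for (j in 1:6) sed_loop <- sed_loop + (u[j] - v[j])^2
    expect_equal(dist_sed(u, v), sed_loop)
    expect_equal(dist_cd(u, v),
                 1 - sum(u * v) / sqrt(sum(u^2)) / sqrt(sum(v^2)))
  }
})

test_that("k-means separates well-separated blobs and is seeded", {
  set.seed(7)
  blobs <- make_blobs(25, rbind(c(0, 0, 3), c(3, 0, 0)), sd = 0.2)
  fit <- kmeans_cluster(blobs$X, 2, metric = "sed", replicates = 5, seed = 2)
  expect_equal(mclust::adjustedRandIndex(fit$labels, blobs$labels), 1)
  refit <- kmeans_cluster(blobs$X, 2, metric = "sed", replicates = 5, seed = 2)
  expect_identical(fit$labels, refit$labels)
  expect_equal(fit$objective, refit$objective)
})

test_that("k-means objective attains the exhaustive bipartition optimum", {
  set.seed(9)
  X <- matrix(rnorm(12), 6, 2)
  fit <- kmeans_cluster(X, 2, metric = "sed", replicates = 20, seed = 4)
  expect_equal(fit$objective, oracle_best_bipartition(X), tolerance = 1e-9)
})

test_that("degenerate and best-of-replicates behavior", {
  set.seed(13)
  X <- matrix(rnorm(16), 8, 2)
  fit_n <- kmeans_cluster(X, 8, metric = "sed", replicates = 3, seed = 1)
  expect_equal(fit_n$objective, 0, tolerance = 1e-12)
  expect_equal(sort(fit_n$labels), 1:8)
  one <- kmeans_cluster(X, 3, metric = "sed", replicates = 1, seed = 6)
  many <- kmeans_cluster(X, 3, metric = "sed", replicates = 10, seed = 6)
  expect_lte(many$objective, one$objective + 1e-12)
})

test_that("reference phenotypes are per-cluster medians, label-permutation stable", {
  set.seed(21)
  raw <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("mu", "r_a", "r_b")))
  labels <- rep(1:2, each = 10)
  zeta <- raw_centroids(labels, raw)
  expect_equal(zeta["CL1", ], apply(raw[1:10, ], 2, median))
  flipped <- raw_centroids(3L - labels, raw)
  expect_equal(unname(zeta["CL1", ]), unname(flipped["CL2", ]))
})

test_that("cosine k-means equals SED k-means on unit-normalized vectors", {
  set.seed(31)
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  blobs <- make_blobs(20, 5 * dirs, sd = 0.3)
  cd_fit <- kmeans_cluster(blobs$X, 3, metric = "cd", replicates = 10, seed = 8)
  U <- blobs$X / sqrt(rowSums(blobs$X^2))
  sed_fit <- kmeans_cluster(U, 3, metric = "sed", replicates = 10, seed = 8)
  expect_equal(mclust::adjustedRandIndex(cd_fit$labels, sed_fit$labels), 1)
  # 1 - cos(theta) = |u - v|^2 / 2 on the unit sphere
  u <- U[1, ]; v <- U[25, ]
  expect_equal(dist_cd(u, v), dist_sed(u, v) / 2)
})

test_that("DBSCAN clusters a tight blob, flags outliers, defaults np_min", {
  expect_equal(dbscan_default_npmin(11), 22L)
  set.seed(41)
  blob <- matrix(rnorm(40, sd = 0.1), 20, 2)
  fit <- dbscan_cluster(blob, eps = 1, np_min = 4, metric = "sed")
  expect_equal(fit$diagnostics$n_clusters, 1)
  expect_equal(fit$diagnostics$frac_clustered, 1)
  withfar <- rbind(blob, c(10, 10))
  fit2 <- dbscan_cluster(withfar, eps = 1, np_min = 4, metric = "sed")
  expect_lt(fit2$diagnostics$frac_clustered, 1)
  expect_equal(fit2$labels[21], 0L)
})

test_that("DBSCAN labels equal the reachability-definition oracle", {
  set.seed(43)
  X <- rbind(matrix(rnorm(24, sd = 0.15), 12, 2),
             matrix(rnorm(24, mean = 2, sd = 0.15), 12, 2),
             matrix(runif(12, -4, 6), 6, 2))
  for (metric in c("sed", "cd")) {
    eps <- if (metric == "sed") 0.25 else 0.02
    D <- phenoclust:::pairwise_dist(X, metric)
    fit <- dbscan_cluster(X, eps = eps, np_min = 4, metric = metric)
    expect_identical(fit$labels, oracle_dbscan(D, eps, 4))
    refit <- dbscan_cluster(X, eps = eps, np_min = 4, metric = metric)
    expect_identical(fit$labels, refit$labels)
  }
})
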