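test_that("per-dimension rescaling maps the pooled range onto [0, 1]", {
  cent <- rbind(c(0, 2), c(5, 4), c(10, 6))
  colnames(cent) <- c("d1", "d2")
  rs <- rescale_01(cent, c(5, 3))
  expect_equal(rs$A["d1", ], c(0, 0.5, 1))
  expect_equal(unname(rs$queries[1, "d1"]), 0.5)
  # a query outside the centroid range is allowed to leave [0, 1]
  rs2 <- rescale_01(cent, c(20, 3), scaling = "centroids")
  expect_gt(rs2$queries[1, "d1"], 1)
  # zero-spread dimension dropped with a warning
  cent3 <- rbind(c(0, 1), c(5, 1))
  colnames(cent3) <- c("d1", "d2")
  expect_warning(rs3 <- rescale_01(cent3, c(2, 1)), "zero-spread")
  expect_equal(rs3$dims, "d1")
})

test_that("NNLS recovers exact memberships and constructed mixtures", {
  set.seed(14)
  A <- matrix(runif(8 * 3), 8, 3)
  fit <- nnls_decompose(A, A[, 3])
  expect_equal(fit$proportions, c(0, 0, 100), tolerance = 1e-8)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  mix <- nnls_decompose(A, 0.6 * A[, 1] + 0.4 * A[, 2])
  expect_equal(mix$proportions, c(60, 40, 0), tolerance = 1e-6)
  expect_equal(mix$rss, 0, tolerance = 1e-10)
  expect_true(all(mix$coefficients >= 0))
  expect_equal(sum(mix$proportions), 100, tolerance = 1e-9)
})

test_that("NNLS equals unconstrained least squares when that is nonnegative", {
  set.seed(16)
  found <- 0
  while (found < 5) {
    A <- matrix(runif(10 * 4, 0.1, 1), 10, 4)
    b <- as.numeric(A %*% runif(4, 0.3, 1)) + rnorm(10, 0, 0.01)
    ls <- oracle_ls(A, b)
    if (all(ls >= 0)) {
      found <- found + 1
      expect_equal(nnls_decompose(A, b)$coefficients, ls, tolerance = 1e-6)
    }
  }
})

test_that("NNLS residual never exceeds the best single-centroid fit", {
  set.seed(18)
  for (i in 1:5) {
    A <- matrix(runif(6 * 4), 6, 4)
    b <- runif(6)
    rss <- nnls_decompose(A, b)$rss
    single <- min(vapply(1:4, function(j) {
      x <- max(0, sum(A[, j] * b) / sum(A[, j]^2))
      sum((A[, j] * x - b)^2)
    }, numeric(1)))
    expect_lte(rss, single + 1e-10)
  }
})

test_that("duplicated centroid columns split but conserve the summed proportion", {
  set.seed(22)
  A <- matrix(runif(8 * 3), 8, 3)
  b <- 0.7 * A[, 1] + 0.3 * A[, 2]
  base <- nnls_decompose(A, b)
  dup <- nnls_decompose(cbind(A, A[, 1]), b)
  expect_equal(dup$proportions[2], base$proportions[2], tolerance = 1e-6)
  expect_equal(dup$proportions[1] + dup$proportions[4], base$proportions[1],
               tolerance = 1e-6)
})

test_that("Gaussian smoothing is identity at window 1 and mean-preserving", {
  y <- c(10, 12, 9, 14, 11, 13, 10, 12, 15, 11)
  expect_equal(phenoclust:::gaussian_smooth(y, 1), y)
  expect_equal(phenoclust:::gaussian_smooth(rep(5, 8), 5), rep(5, 8))
  set.seed(33)
  trace <- 50 + cumsum(rnorm(60))
  sm <- phenoclust:::gaussian_smooth(trace, 5)
  interior <- 3:58
  expect_equal(mean(sm[interior]), mean(trace[interior]), tolerance = 0.01)
})

test_that("a constant-phenotype batch decomposes to one constant dominant cluster", {
  arch <- default_archetypes()
  sim <- simulate_experiment(constant_rate_config(arch[[2]], dur = 10,
                                                  n_samp = 11), seed = 3)
  rates <- compute_rate_vectors(sim$experiment)
  model <- make_model(archetype_matrix(arch))
  dec <- decompose_timecourse(rates, model, smooth_window = 5)
  pcols <- grep("^pct_", names(dec$proportions))
  dominant <- apply(dec$proportions[, pcols], 1, which.max)
  expect_true(all(dominant == 2))
  raw_dom <- apply(dec$proportions_raw[, pcols], 1, which.max)
  expect_true(all(raw_dom == 2))
  expect_true(all(dec$proportions$rss >= 0))
  # window 1 leaves proportions untouched
  dec1 <- decompose_timecourse(rates, model, smooth_window = 1)
  expect_equal(dec1$proportions[, pcols], dec1$proportions_raw[, pcols])
})

test_that("proportion rows sum to 100 where defined", {
  arch <- default_archetypes()
  sim <- simulate_experiment(constant_rate_config(arch[[4]], dur = 10,
                                                  n_samp = 9, sigma = 0.02),
                             seed = 9)
  rates <- compute_rate_vectors(sim$experiment)
  dec <- decompose_timecourse(rates, make_model(archetype_matrix(arch)))
  pcols <- grep("^pct_", names(dec$proportions))
  sums <- rowSums(dec$proportions[, pcols])
  expect_equal(sums[!is.na(sums)], rep(100, sum(!is.na(sums))),
               tolerance = 1e-9, ignore_attr = TRUE)
})
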