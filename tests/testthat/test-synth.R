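test_that("noise-free single-archetype growth matches the closed form", {
  arch <- archetype("a", mu = 0.2, c(PDO = 3, Gly = -5))
  cfg <- constant_rate_config(arch, dur = 10, n_samp = 11,
                              init = c(BM = 0.15, Gly = 800))
  sim <- simulate_experiment(cfg, seed = 1)
  final_bm <- sim$experiment$samples$BM[11]
  expect_equal(final_bm, 0.15 * exp(0.2 * 10), tolerance = 1e-3)
  # product trajectory: c(t) = (r/mu) * (BM(t) - BM(0))
  pdo <- sim$experiment$samples$PDO
  bm <- sim$experiment$samples$BM
  expect_equal(pdo, (3 / 0.2) * (bm - 0.15), tolerance = 1e-4)
})

test_that("substrate exhaustion time matches the analytic integral", {
  arch <- archetype("a", mu = 0.1, c(Gly = -10))
  cfg <- simulation_config("exh", data.frame(start = 0, end = 40, archetype = 1),
                           list(arch), init = c(BM = 0.5, Gly = 100),
                           sample_times = seq(0, 40, by = 0.5),
                           noise_sigma = 0)
  expect_message(sim <- simulate_experiment(cfg, seed = 1), "exhausted")
  # consumed(t) = (r/mu) * BM0 * (exp(mu t) - 1) = 100
  t_true <- log(1 + 0.1 * 100 / (10 * 0.5)) / 0.1
  # quadrature cross-check of the analytic inversion
  consumed <- function(t) stats::integrate(function(u) 10 * 0.5 * exp(0.1 * u),
                                           0, t)$value
  expect_equal(consumed(t_true), 100, tolerance = 1e-6)
  s <- sim$experiment$samples
  t_sim <- s$time_h[min(which(s$Gly <= 1e-6))]
  expect_equal(t_sim, t_true, tolerance = 0.01 * t_true + 0.5)
  # rates are zeroed after exhaustion
  tr <- sim$truth
  expect_true(all(tr$r_Gly[tr$time_h > t_true + 0.5] == 0))
})

test_that("simulation is deterministic: zero noise ignores the seed, noise honors it", {
  arch <- archetype("a", mu = 0.1, c(PDO = 4, Gly = -6))
  cfg0 <- constant_rate_config(arch, sigma = 0)
  s1 <- simulate_experiment(cfg0, seed = 1)$experiment$samples
  s2 <- simulate_experiment(cfg0, seed = 999)$experiment$samples
  expect_identical(s1, s2)
  cfgN <- constant_rate_config(arch, sigma = 0.05)
  n1 <- simulate_experiment(cfgN, seed = 4)$experiment$samples
  n2 <- simulate_experiment(cfgN, seed = 4)$experiment$samples
  n3 <- simulate_experiment(cfgN, seed = 5)$experiment$samples
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))
})

test_that("schedule validation catches gaps and bad sampling", {
  arch <- default_archetypes()[1:2]
  expect_error(simulation_config(
    "bad", data.frame(start = c(0, 6), end = c(5, 10), archetype = 1:2),
    arch, c(BM = 0.2, Gly = 500), 0:5), "contiguous")
  expect_error(simulation_config(
    "bad", data.frame(start = 0, end = 10, archetype = 1),
    arch, c(BM = 0.2, Gly = 500), c(0, 3, 3, 5)), "strictly increasing")
})

test_that("generated datasets carry truth, tags and the planted tag design", {
  ds <- study_dataset(0.02)
  expect_length(ds$experiments, 20)
  n_samp <- vapply(ds$experiments, function(e) nrow(e$samples), integer(1))
  expect_true(all(n_samp >= 4 & n_samp <= 15))
  expect_equal(nrow(ds$truth), sum(n_samp))
  # archetype 1 is planted only under BES = yes
  bes <- vapply(ds$experiments, function(e) e$tags[["BES"]], character(1))
  ids <- vapply(ds$experiments, function(e) e$experiment_id, character(1))
  uses1 <- vapply(ids, function(id) {
    1L %in% ds$truth$archetype[ds$truth$experiment_id == id]
  }, logical(1))
  expect_true(all(bes[uses1] == "yes"))
  expect_true(any(uses1))
  # determinism
  ds2 <- suppressMessages(generate_dataset(20, seed = 7, noise_sigma = 0.02))
  expect_identical(ds$experiments[[5]]$samples, ds2$experiments[[5]]$samples)
  # degenerate case
  empty <- generate_dataset(0)
  expect_length(empty$experiments, 0)
})

test_that("planted rates are recovered through the rates module (closed loop)", {
  ds <- study_dataset(0)
  rt <- study_rates(0)
  m <- suppressMessages(rate_matrix(rt))
  tm <- truth_rates(attr(m, "ids"), ds$truth, colnames(m))
  rel <- abs(m - tm) / abs(tm)
  rel <- rel[is.finite(rel)]
  expect_lt(median(rel), 0.03)
})
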