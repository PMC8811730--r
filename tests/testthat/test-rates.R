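test_that("interpolation passes through knots and preserves monotonicity", {
  expect_equal(interpolate_concentration(0:2, 1:3, 0:2), c(1, 2, 3))
  # monotone decreasing knots stay monotone on a dense grid
  tt <- c(0, 1, 2.5, 4, 6)
  vv <- c(100, 60, 35, 20, 5)
  dense <- interpolate_concentration(tt, vv, seq(0, 6, by = 0.01))
  expect_true(all(diff(dense) <= 1e-9))
  expect_error(interpolate_concentration(0:2, 1:3, c(-0.5, 1)), "outside")
  expect_error(interpolate_concentration(0, 1, 0), "2 knots")
})

test_that("interpolant matches an independent Fritsch-Carlson evaluation", {
  x <- c(0, 1, 2, 3); y <- c(0, 1, 8, 27)
  xq <- c(0.25, 0.5, 1.5, 2.2, 2.9)
  expect_equal(interpolate_concentration(x, y, xq), oracle_pchip(x, y, xq),
               tolerance = 1e-10)
  set.seed(11)
  for (i in 1:5) {
    x <- sort(runif(7, 0, 10)); y <- cumsum(runif(7, -2, 3))
    xq <- runif(20, min(x), max(x))
    expect_equal(interpolate_concentration(x, y, xq), oracle_pchip(x, y, xq),
                 tolerance = 1e-10)
  }
})

test_that("specific rate divides the slope by biomass, preserving sign", {
  expect_equal(specific_rate(2, 4), 2)
  expect_equal(specific_rate(1, -3), -3)
  expect_error(specific_rate(0, 1), "positive")
})

test_that("growth rate recovers exact exponential and ramped profiles", {
  tt <- seq(0, 8, by = 2)
  expect_equal(growth_rate(tt, 0.1 * exp(0.2 * tt), 4, 8), 0.2,
               tolerance = 1e-9)
  expect_equal(growth_rate(tt, rep(0.5, 5), 4, 8), 0)
  # mu(t) ramp: compare to a centered finite difference of ln(biomass)
  mu_t <- function(t) 0.05 + 0.02 * t
  lnbm <- function(t) log(0.1) + 0.05 * t + 0.01 * t^2  # integral of mu
  tt <- seq(0, 10, by = 0.25)
  est <- growth_rate(tt, exp(lnbm(tt)), 5, 2)
  fd <- (lnbm(5 + 1e-4) - lnbm(5 - 1e-4)) / 2e-4
  expect_equal(est, fd, tolerance = 0.02 * abs(fd))
  expect_error(growth_rate(c(0, 1), c(0, 0), 0.5, 1), "positive biomass")
})

test_that("constant planted rates are recovered at interior points", {
  arch <- archetype("a", mu = 0.1, c(PDO = 5, AcAc = 2, Gly = -8))
  sim <- simulate_experiment(constant_rate_config(arch), seed = 1)
  rates <- compute_rate_vectors(sim$experiment)
  expect_gt(nrow(rates), 5)
  expect_equal(rates$mu, rep(0.1, nrow(rates)), tolerance = 0.03)
  expect_equal(rates$r_PDO, rep(5, nrow(rates)), tolerance = 0.03)
  expect_equal(rates$r_Gly, rep(-8, nrow(rates)), tolerance = 0.03)
  # interpolated concentrations carried for conditionality
  expect_true(all(rates$c_PDO >= 0))
})

test_that("degenerate experiments yield empty tables", {
  two <- cultivation_experiment("t", data.frame(time_h = 0:1,
                                                BM = c(0.1, 0.2)))
  expect_warning(out <- compute_rate_vectors(two), "fewer than 3")
  expect_equal(nrow(out), 0)
  dead <- cultivation_experiment("d", data.frame(time_h = 0:3,
                                                 BM = rep(0, 4)))
  expect_warning(out <- compute_rate_vectors(dead), "biomass")
  expect_equal(nrow(out), 0)
})

test_that("a strictly decreasing compound has strictly negative rates", {
  tt <- 0:8
  e <- cultivation_experiment("neg", data.frame(
    time_h = tt, BM = 0.2 * exp(0.1 * tt), Gly = 400 - 30 * tt - tt^2))
  rates <- compute_rate_vectors(e)
  expect_true(all(rates$r_Gly < 0))
})

test_that("cumulative fed-batch columns yield the consumption-sign rate", {
  arch <- archetype("a", mu = 0.1, c(PDO = 5, Gly = -8))
  cfg_inst <- constant_rate_config(arch, id = "inst")
  cfg_cum <- constant_rate_config(arch, id = "cum")
  cfg_cum$cumulative <- "Gly"
  r_inst <- compute_rate_vectors(simulate_experiment(cfg_inst, seed = 1)$experiment)
  r_cum <- compute_rate_vectors(simulate_experiment(cfg_cum, seed = 1)$experiment)
  expect_true(all(r_cum$r_Gly < 0))
  expect_equal(r_cum$r_Gly, r_inst$r_Gly, tolerance = 1e-6)
  expect_true(all(r_cum$cum_Gly))
})

test_that("recovery error shrinks as sampling density increases", {
  arch <- archetype("a", mu = 0.12, c(PDO = 6, BuAc = 1.5, Gly = -9))
  err <- vapply(c(7, 25), function(ns) {
    sim <- simulate_experiment(constant_rate_config(arch, n_samp = ns),
                               seed = 1)
    r <- compute_rate_vectors(sim$experiment)
    max(abs(r$r_PDO - 6) / 6)
  }, numeric(1))
  expect_lt(err[2], err[1] / 2)
})

test_that("percentile trimming matches a brute-force per-dimension check", {
  rt <- study_rates(0.02)
  expect_equal(nrow(remove_outliers(rt, 0, 100)$removed), 0)
  tr <- suppressMessages(remove_outliers(rt, 3, 97))
  # partition
  expect_equal(nrow(tr$kept) + nrow(tr$removed), nrow(rt))
  # brute-force double loop over dimensions and vectors
  dims <- c("mu", grep("^r_", names(rt), value = TRUE))
  out <- logical(nrow(rt))
  for (d in dims) {
    v <- rt[[d]]
    lo <- stats::quantile(v, 0.03, na.rm = TRUE, type = 7)
    hi <- stats::quantile(v, 0.97, na.rm = TRUE, type = 7)
    for (i in seq_len(nrow(rt))) {
      if (!is.na(v[i]) && (v[i] < lo || v[i] > hi)) out[i] <- TRUE
    }
  }
  expect_equal(sort(as.integer(rownames(tr$removed))), which(out))
  # widening the band never removes more vectors
  wider <- suppressMessages(remove_outliers(rt, 1, 99))
  expect_lte(nrow(wider$removed), nrow(tr$removed))
  # identical vectors are never outliers
  same <- rt[rep(1, 20), ]
  expect_equal(nrow(suppressMessages(remove_outliers(same))$removed), 0)
})
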