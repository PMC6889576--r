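test_that("demographic model constructors validate their epochs", {
  expect_error(demographic_model(c(5, 10), c(100, 100)), "start at time 0")
  expect_error(demographic_model(c(0, 10), c(100, 100), c(0, 0.1)),
               "oldest epoch")
  m <- scenario_model("african", 4)
  expect_equal(unname(m$epochs[1, "N0"]), 40000)
  expect_equal(unname(m$epochs[2, "t0"]), 3500)
  m2 <- scenario_model("ooa", 20)
  expect_equal(unname(m2$epochs[, "N0"]), c(40000, 2000, 10000))
  expect_length(scenario_family(), 8)
})

test_that("coalescent moments match theory for constant size", {
  m <- constant_model(10000)
  st2 <- coal_stats(2, 5, m, 4000, seed = 1)
  se <- sd(st2$tmrca_gens) / sqrt(4000)
  expect_lt(abs(mean(st2$tmrca_gens) - 20000), 2 * se)   # E[T2] = 2N
  st <- coal_stats(10, 5, m, 4000, seed = 2)
  a1 <- sum(1 / 1:9)
  expect_lt(abs(mean(st$S) - 5 * a1), 2 * sd(st$S) / sqrt(4000))
  expect_lt(abs(mean(st$pi) - 5), 2 * sd(st$pi) / sqrt(4000))
})

test_that("fixed seed reproduces simulations bit-exactly", {
  m <- scenario_model("ooa", 10)
  a <- coal_stats(20, 8, m, 50, seed = 9)
  b <- coal_stats(20, 8, m, 50, seed = 9)
  expect_identical(a, b)
  pa <- coal_panel(12, 6, m, 1000, seed = 4)
  pb <- coal_panel(12, 6, m, 1000, seed = 4)
  expect_identical(pa$panel$mat, pb$panel$mat)
  expect_identical(pa$panel$positions, pb$panel$positions)
})

test_that("simulated site frequency spectrum fits the neutral expectation", {
  m <- constant_model(10000)
  set.seed(10)
  # E[xi_i] = theta / i per frequency class; per-class variances exceed the
  # Poisson value because sites on one genealogy are correlated, so the
  # check uses Monte-Carlo batch standard errors rather than a plain
  # chi-square statistic
  n_batch <- 20; per_batch <- 400
  batches <- t(vapply(seq_len(n_batch), function(b)
    ltapop:::cpp_coal_sfs(20, 10 / (4 * 10000), m$epochs, per_batch) / per_batch,
    numeric(19)))
  mu <- colMeans(batches)
  se <- apply(batches, 2, sd) / sqrt(n_batch)
  expected <- 10 / (1:19)
  z <- (mu - expected) / se
  expect_true(all(abs(z) < 5))
  expect_lt(abs(mean(mu / expected) - 1), 0.05)
})

test_that("growth shifts D negative; a pure bottleneck shifts D positive", {
  n <- 50; theta <- 10
  d_const <- mean(coal_stats(n, theta, constant_model(10000), 2000,
                             seed = 5)$D, na.rm = TRUE)
  d_growth <- mean(coal_stats(n, theta, scenario_model("african", 10), 2000,
                              seed = 6)$D, na.rm = TRUE)
  # bottleneck-only model: size drops 10000 -> 2000 between 2500 and 3000
  # generations ago, no recent growth
  bott <- demographic_model(t0 = c(0, 2500, 3000),
                            N0 = c(10000, 2000, 10000))
  d_bott <- mean(coal_stats(n, theta, bott, 2000, seed = 7)$D, na.rm = TRUE)
  expect_lt(d_growth, d_const)
  expect_gt(d_bott, d_const)
})

test_that("null p-values follow the add-one convention and center correctly", {
  m <- constant_model(10000)
  # observed larger than anything the null can produce
  pv <- null_pvalue(1e6, "D", 20, 5, m, reps = 500, seed = 3)
  expect_equal(pv$p_value, 1 / 501)
  # observed at the null median -> p about 0.5
  st <- coal_stats(20, 5, m, 2000, seed = 8)
  med <- median(st$D, na.rm = TRUE)
  pv2 <- null_pvalue(med, "D", 20, 5, m, reps = 1000, seed = 13)
  expect_gt(pv2$p_value, 0.4); expect_lt(pv2$p_value, 0.6)
  expect_warning(null_pvalue(0, "D", 10, 5, m, reps = 50, seed = 1),
                 "fewer than 100")
})

test_that("allele ages: n=2 closed forms for both weightings, monotone in i", {
  m <- constant_model(10000)
  # pooled (default): E = E[T2^2] / (2 E[T2]) = 2N generations
  est_p <- allele_age_mc(1, 2, m, reps = 20000, seed = 1)
  expect_lt(abs(est_p$mean_years - 400000), 3 * 2 * 400000 / sqrt(20000) * 2)
  expect_gt(est_p$mean_years, 350000); expect_lt(est_p$mean_years, 450000)
  # per-genealogy: E = E[T2] / 2 = N generations
  est_g <- allele_age_mc(1, 2, m, reps = 20000, weighting = "per_genealogy",
                         seed = 2)
  expect_gt(est_g$mean_years, 180000); expect_lt(est_g$mean_years, 220000)
  # older ages for higher derived counts
  young <- allele_age_mc(1, 20, m, reps = 8000, seed = 3)
  old <- allele_age_mc(19, 20, m, reps = 8000, seed = 4)
  expect_gt(old$mean_years, young$mean_years)
})

test_that("pooled allele ages track the Kimura-Ota frequency curve at large n", {
  m <- constant_model(10000)
  n <- 50
  for (i in c(12, 25, 40)) {
    x <- i / n
    ko_years <- -2 * x * log(x) / (1 - x) * 2 * 10000 * 20
    est <- allele_age_mc(i, n, m, reps = 30000, seed = 40 + i)
    expect_lt(abs(est$mean_years / ko_years - 1), 0.10)
  }
})

test_that("TMRCA expectations: analytic constant case and asymptote", {
  m <- constant_model(10000)
  expect_equal(unname(tmrca_expectation(2, m)$years), 2 * 10000 * 20)
  expect_equal(unname(tmrca_expectation(1000, m)$years),
               4 * 10000 * (1 - 1e-3) * 20)
  # piecewise model: Monte-Carlo stable across seeds
  mm <- scenario_model("ooa", 20)
  t1 <- tmrca_expectation(20, mm, reps = 8000, seed = 1)
  t2 <- tmrca_expectation(20, mm, reps = 8000, seed = 2)
  expect_lt(abs(t1$gens - t2$gens) / t1$gens, 0.1)
  expect_equal(t1$method, "monte-carlo")
})

test_that("Ne from theta is linear and validated", {
  expect_equal(ne_from_theta(4e-4, 1e-8), 10000)
  expect_equal(ne_from_theta(8e-4, 1e-8), 20000)
  expect_equal(ne_from_theta(2 * 4e-4, 1e-8), 2 * ne_from_theta(4e-4, 1e-8))
  expect_error(ne_from_theta(0, 1e-8), "positive")
})
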