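test_that("EHH hand examples, core value and monotone decay", {
  # 4 derived carriers split 2+2 at the first flanking site
  mat <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1),
               c(0, 0, 0), c(0, 1, 0))
  p <- hap_panel(c(100, 200, 300), mat, rep("X", 6))
  cv <- ehh_curve(p, 1, 1)
  expect_equal(cv$ehh[cv$offsets == 0], 1)
  expect_equal(cv$n_carriers, 4)
  expect_equal(cv$ehh[cv$offsets == 100], 2 / 6, tolerance = 1e-12)  # 2+2 split
  # identical carriers -> EHH stays 1
  mat1 <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(0, 1, 0))
  cv1 <- ehh_curve(hap_panel(c(1, 2, 3), mat1, rep("X", 4)), 1, 1)
  expect_true(all(cv1$ehh == 1))
  expect_error(ehh_curve(hap_panel(c(1, 2), diag(2), rep("X", 2)), 1, 1),
               "fewer than 2")
  # monotone non-increasing outward on random panels
  set.seed(31)
  for (k in 1:5) {
    m <- matrix(rbinom(30 * 12, 1, 0.5), 30, 12)
    pp <- hap_panel(sort(sample(1e5, 12)), m, rep("X", 30))
    core <- 6
    if (sum(m[, core]) < 2 || sum(1 - m[, core]) < 2) next
    for (al in 0:1) {
      cv <- ehh_curve(pp, core, al)
      right <- cv$ehh[cv$offsets >= 0][order(cv$offsets[cv$offsets >= 0])]
      left <- cv$ehh[cv$offsets <= 0][order(-cv$offsets[cv$offsets <= 0])]
      expect_true(all(diff(right) <= 1e-12))
      expect_true(all(diff(left) <= 1e-12))
    }
  }
})

test_that("iHS integral matches hand trapezoid computation and is antisymmetric", {
  # derived carriers identical; ancestral split at the single flanking site
  mat <- rbind(c(1, 1), c(1, 1), c(0, 1), c(0, 0))
  p <- hap_panel(c(1000, 3000), mat, rep("X", 4))
  r <- ihs_core(p, 1, cutoff = 0.05)
  # derived arm right: EHH 1 at core, 1 at +2000 -> area 2000 (runs off edge)
  expect_equal(r$ihh_d, 2000, tolerance = 1e-9)
  # ancestral: carriers split at +2000: EHH 0 -> trapezoid (1+0)/2*2000
  expect_equal(r$ihh_a, 1000, tolerance = 1e-9)
  expect_equal(r$score, log(1000 / 2000), tolerance = 1e-12)
  expect_true(r$truncated)   # derived arm hit the edge above the cutoff
  # antisymmetry under polarity flip
  pf <- hap_panel(p$positions, 1L - p$mat, rep("X", 4))
  rf <- ihs_core(pf, 1, cutoff = 0.05)
  expect_equal(rf$score, -r$score, tolerance = 1e-12)
  # label-symmetric panel scores 0
  ms <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 0), c(0, 0, 1))
  rs <- ihs_core(hap_panel(c(10, 20, 30), ms, rep("X", 4)), 1)
  expect_equal(rs$score, 0, tolerance = 1e-12)
})

test_that("max_gap truncates the integral", {
  mat <- rbind(c(1, 1), c(1, 1), c(0, 1), c(0, 0))
  p <- hap_panel(c(1000, 900000), mat, rep("X", 4))
  r <- ihs_core(p, 1, max_gap = 200000)
  expect_true(r$truncated)
  expect_equal(r$ihh_d, 0)
})

test_that("nSL equals the pairwise hand computation on a 4-chromosome toy", {
  mat <- rbind(c(0, 1, 1, 0, 0),
               c(1, 1, 1, 0, 1),
               c(0, 0, 0, 1, 0),
               c(1, 1, 0, 1, 1))
  p <- hap_panel(c(10, 20, 30, 40, 50), mat, rep("X", 4))
  core <- 3
  # derived carriers rows 1,2: identical at sites 2,3,4; differ at 1 and 5
  # L(1,2) = sites {2,3,4} = 3
  # ancestral carriers rows 3,4: identical at 3,4; differ at 2 and 5 -> L = 2
  r <- nsl_core(p, core)
  expect_equal(r$sl_d, 3)
  expect_equal(r$sl_a, 2)
  expect_equal(r$score, log(2 / 3), tolerance = 1e-12)
  # identical derived carriers vs maximally diverse ancestral -> negative
  m2 <- rbind(c(1, 1, 1), c(1, 1, 1), c(1, 0, 0), c(0, 0, 1))
  m2 <- rbind(m2, c(0, 1, 0))
  r2 <- nsl_core(hap_panel(c(1, 2, 3), m2, rep("X", 5)), 2)
  expect_lt(r2$score, 0)
  # label-swap symmetry gives 0
  ms <- rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 0), c(0, 0, 1))
  expect_equal(nsl_core(hap_panel(c(1, 2, 3), ms, rep("X", 4)), 1)$score, 0,
               tolerance = 1e-12)
})

test_that("standardization centers and scales within frequency bins", {
  set.seed(12)
  freq <- runif(2000, 0.05, 0.95)
  score <- rnorm(2000, mean = 2 * freq, sd = 0.5 + freq)
  std <- standardize_scores(score, freq, n_bins = 100, min_per_bin = 20)
  bins <- pmin(pmax(ceiling(freq * 100), 1), 100)
  # reconstruct merged groups the same way to verify per-bin moments
  counts <- tabulate(bins, nbins = 100)
  group <- integer(100); g <- 1L; acc <- 0L
  for (b in 1:100) {
    group[b] <- g; acc <- acc + counts[b]
    if (acc >= 20) { g <- g + 1L; acc <- 0L }
  }
  if (acc > 0 && g > 1L) group[group == g] <- g - 1L
  for (gg in unique(group[bins])) {
    sel <- group[bins] == gg
    expect_lt(abs(mean(std[sel])), 1e-9)
    expect_lt(abs(sd(std[sel]) - 1), 1e-9)
  }
  # a single score cannot be standardized
  expect_true(is.na(standardize_scores(0.5, 0.4)))
})

test_that("outlier calling is strict and uses absolute values", {
  expect_equal(call_outliers(c(2.01, -2.01, 2.0, 1.5, NA)),
               c(TRUE, TRUE, FALSE, FALSE, NA))
})

test_that("scan_scores restricts cores to the derived-frequency band", {
  sim <- make_neutral_region(n = 60, theta = 10, L = 40000, seed = 51)
  sc <- scan_scores(sim$panel, "nsl", maf_min = 0.05)
  expect_true(all(sc$freq_derived >= 0.05 & sc$freq_derived <= 0.95))
  f <- colSums(sim$panel$mat) / 60
  expect_equal(nrow(sc), sum(f >= 0.05 & f <= 0.95))
})
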