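test_that("theta-pi and theta-W closed forms", {
  # n = 4, derived counts {2, 3}, L = 100
  mat <- rbind(c(1, 1), c(1, 1), c(0, 1), c(0, 0))
  p <- hap_panel(c(10, 60), mat, rep("X", 4))
  tp <- theta_pi(p, L = 100)
  expect_equal(tp$counts, 8 / 12 + 6 / 12, tolerance = 1e-12)
  expect_equal(tp$per_site, tp$counts / 100)
  tw <- theta_w(3, 4, 100)
  expect_equal(tw$per_site, 3 / (11 / 6) / 100, tolerance = 1e-12)
  expect_equal(theta_w(0, 4, 100)$counts, 0)
  # monomorphic panel
  mono <- hap_panel(c(10), matrix(0L, 4, 1), rep("X", 4))
  expect_equal(theta_pi(mono, L = 100)$counts, 0)
  expect_error(theta_pi(hap_panel(c(10), matrix(0L, 1, 1), "X")), "2 chromosomes")
})

test_that("Tajima's D matches an independent constant-by-constant evaluation", {
  # n = 10, five singleton sites
  mat <- matrix(0L, 10, 5)
  for (s in 1:5) mat[s, s] <- 1L
  p <- hap_panel(seq(10, 50, by = 10), mat, rep("X", 10))
  # independent oracle: direct evaluation of the 1989 formulas
  n <- 10; S <- 5
  a1 <- sum(1 / 1:9); a2 <- sum(1 / (1:9)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  pi_c <- 5 * 2 * 1 * 9 / (10 * 9)
  d_expect <- (pi_c - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
  expect_equal(tajimas_d(p), d_expect, tolerance = 1e-12)
  expect_true(is.na(tajimas_d(hap_panel(10, matrix(0L, 10, 1), rep("X", 10)))))
  # invariant to relabeling chromosomes
  p2 <- hap_panel(p$positions, p$mat[sample(10), ], rep("X", 10))
  expect_equal(tajimas_d(p2), tajimas_d(p))
})

test_that("Fay-Wu H hand examples and polarity-flip structure", {
  # one site, n = 4, derived count 3: pi = 0.5, thetaH = 1.5, H = -1
  p3 <- hap_panel(10, matrix(c(1, 1, 1, 0), 4, 1), rep("X", 4))
  expect_equal(fay_wu_h(p3), -1, tolerance = 1e-12)
  # singleton: pi = 0.5, thetaH = 1/6, H = +1/3
  p1 <- hap_panel(10, matrix(c(1, 0, 0, 0), 4, 1), rep("X", 4))
  expect_equal(fay_wu_h(p1), 1 / 3, tolerance = 1e-12)
  # flipping all polarities maps i -> n - i
  expect_equal(fay_wu_h(hap_panel(10, 1L - p3$mat, rep("X", 4))),
               fay_wu_h(p1))
  # unpolarized sites are excluded with a message
  pu <- hap_panel(c(10, 20), cbind(p3$mat, c(1L, 0L, 0L, 0L)), rep("X", 4))
  pu$sites$polarized <- c(TRUE, FALSE)
  expect_message(h <- fay_wu_h(pu), "unpolarized")
  expect_equal(h, -1)
})

test_that("haplotype spectrum, counts and Nei diversity", {
  # 5 chromosomes, all distinct
  m <- diag(5); p <- hap_panel(1:5 * 10, m, rep("X", 5))
  sp <- haplotype_spectrum(p)
  expect_equal(sp$h, 5)
  expect_equal(sp$h_diversity, 1)
  # two haplotypes 5/5 in n = 10
  m2 <- matrix(0L, 10, 2); m2[1:5, ] <- 1L
  sp2 <- haplotype_spectrum(hap_panel(c(10, 20), m2, rep(c("A", "B"), each = 5)))
  expect_equal(sp2$h, 2)
  expect_equal(sp2$h_diversity, (10 / 9) * 0.5, tolerance = 1e-12)
  # per-population counts sum to population sizes
  expect_equal(sum(sp2$haplotypes$A), 5)
  expect_equal(sum(sp2$haplotypes$B), 5)
  # identical haplotypes -> diversity 0
  sp0 <- haplotype_spectrum(hap_panel(10, matrix(1L, 6, 1), rep("X", 6)))
  expect_equal(sp0$h_diversity, 0)
})

test_that("MAF classification uses the 5% boundary inclusively", {
  mat <- matrix(0L, 100, 3)
  mat[1:5, 1] <- 1L      # MAF 0.05 -> common
  mat[1:3, 2] <- 1L      # MAF 0.03 -> rare
  p <- hap_panel(c(10, 20, 30), mat, rep("X", 100))
  cl <- classify_maf(p)
  expect_equal(cl$maf, c(0.05, 0.03, 0))
  expect_equal(cl$class, c("common", "rare", "rare"))
})

test_that("singletons count the minor allele seen exactly once", {
  mat <- cbind(c(1, 0, 0, 0), c(0, 1, 1, 1), c(1, 1, 0, 0))
  p <- hap_panel(c(1, 2, 3), mat, rep("X", 4))
  # site 1: minor count 1; site 2: minor (the 0) count 1; site 3: minor 2
  expect_equal(count_singletons(p), 2)
})

test_that("regional sharing Venn cells partition the segregating sites", {
  set.seed(5)
  sim <- make_neutral_region(n = 60, theta = 12, L = 8000, seed = 11,
                             pops = c("p1", "p2", "p3", "p4", "p5", "p6"))
  groups <- list(AFR = c("p1", "p2"), EUR = c("p3", "p4"),
                 EAS = "p5", SAS = "p6")
  sh <- regional_sharing(sim$panel, groups)
  seg_any <- {
    keep <- sim$panel$pops %in% unlist(groups)
    cs <- colSums(sim$panel$mat[keep, , drop = FALSE])
    ns <- sum(keep)
    # segregating within at least one region
    sapply(seq_len(ncol(sim$panel$mat)), function(s) {
      any(sapply(groups, function(pp) {
        k <- sim$panel$pops %in% pp
        cc <- sum(sim$panel$mat[k, s])
        cc > 0 && cc < sum(k)
      }))
    })
  }
  expect_equal(sum(sh$count), sum(seg_any))
  # an exclusion empties that region's private cell
  sh2 <- regional_sharing(sim$panel, groups, exclusions = c("p5"))
  expect_false("EAS" %in% sh2$regions)
})

test_that("per-population summary table is coherent", {
  sim <- make_neutral_region(n = 40, theta = 8, L = 6000, seed = 21,
                             pops = c("P1", "P2"))
  tab <- pop_summary_table(sim$panel, L = 6000)
  expect_setequal(tab$pop, c("P1", "P2"))
  expect_equal(tab$n2, c(20, 20))
  for (k in 1:2) {
    sl <- subset_panel(sim$panel, pop = tab$pop[k])
    i <- colSums(sl$mat)
    expect_equal(tab$S[k], sum(i > 0 & i < 20))
    expect_equal(tab$theta_w[k], theta_w(tab$S[k], 20, 6000)$per_site)
  }
  expect_true(all(tab$h_diversity >= 0 & tab$h_diversity <= 1))
})
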