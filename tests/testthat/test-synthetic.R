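test_that("generators are deterministic under a fixed seed", {
  a <- make_neutral_region(n = 16, theta = 5, L = 4000, seed = 5)
  b <- make_neutral_region(n = 16, theta = 5, L = 4000, seed = 5)
  expect_identical(a$panel$mat, b$panel$mat)
  expect_identical(a$panel$positions, b$panel$positions)
  pa <- withr::local_tempfile(fileext = ".vcf")
  pb <- withr::local_tempfile(fileext = ".vcf")
  make_neutral_region(n = 16, theta = 5, L = 4000, seed = 5, vcf_path = pa)
  make_neutral_region(n = 16, theta = 5, L = 4000, seed = 5, vcf_path = pb)
  expect_identical(readLines(pa), readLines(pb))
  s1 <- make_sweep_panel(N = 150, L = 20000, s = 0.1, n_sample = 20, seed = 6,
                         max_restarts = 2000)
  s2 <- make_sweep_panel(N = 150, L = 20000, s = 0.1, n_sample = 20, seed = 6,
                         max_restarts = 2000)
  expect_identical(s1$panel$mat, s2$panel$mat)
  g1 <- make_gene_fixture(seed = 7)
  g2 <- make_gene_fixture(seed = 7)
  expect_identical(g1$outgroup_cds, g2$outgroup_cds)
})

test_that("mean S over replicates matches the Watterson expectation", {
  m <- constant_model(10000)
  st <- coal_stats(20, 6, m, 2000, seed = 14)
  a1 <- sum(1 / 1:19)
  expect_lt(abs(mean(st$S) - 6 * a1), 2 * sd(st$S) / sqrt(2000))
})

test_that("forward simulator conserves sizes and frequencies stay in [0,1]", {
  z <- make_sweep_panel(N = 120, L = 20000, s = 0.1, mode = "hard",
                        sample_freq_window = c(0.4, 0.9), n_sample = 40,
                        seed = 8, max_restarts = 2000)
  expect_equal(nrow(z$panel$mat), 40)
  expect_true(all(z$truth$trajectory >= 0 & z$truth$trajectory <= 1))
  expect_true(z$truth$focal_freq_pop >= 0.4 && z$truth$focal_freq_pop <= 0.9)
  # the sampled focal count is consistent with the flagged column
  expect_equal(sum(z$panel$mat[, z$truth$focal_index]),
               z$truth$focal_count_sample)
})

test_that("neutral focal allele drifts at rate 1/2N", {
  N <- 200; Tg <- 100; reps <- 120
  h0 <- hT <- numeric(reps)
  for (k in seq_len(reps)) {
    z <- make_sweep_panel(N = N, L = 20000, s = 0, mode = "soft_standing",
                          f0 = 0.5, n_sample = 10, seed = 1000 + k,
                          run_gens = Tg)
    p0 <- z$truth$trajectory[1]
    pT <- z$truth$focal_freq_pop
    h0[k] <- 2 * p0 * (1 - p0); hT[k] <- 2 * pT * (1 - pT)
  }
  ratio <- mean(hT) / mean(h0)
  expect_lt(abs(ratio - (1 - 1 / (2 * N))^Tg), 0.08)
})

test_that("soft sweeps carry more distinct selected haplotypes than hard sweeps", {
  # distinct carrier haplotypes over the 10 kb flanking the selected site;
  # N large enough that a 5% standing variant is an old clade with real
  # background diversity
  nh <- function(mode, seed) {
    z <- make_sweep_panel(N = 600, L = 50000, s = 0.08, mode = mode,
                          f0 = 0.05, sample_freq_window = c(0.5, 0.9),
                          n_sample = 60, seed = seed, max_restarts = 2000)
    carriers <- z$panel$mat[, z$truth$focal_index] == 1
    win <- abs(z$panel$positions - z$truth$focal_position) <= 10000
    length(unique(apply(z$panel$mat[carriers, win, drop = FALSE], 1,
                        paste, collapse = "")))
  }
  hard <- vapply(1:50, function(k) nh("hard", 2000 + k), numeric(1))
  soft <- vapply(1:50, function(k) nh("soft_standing", 3000 + k), numeric(1))
  expect_gt(median(soft), median(hard))
})

test_that("neutral forward simulation matches the coalescent at equal theta", {
  N <- 120; L <- 30000; u <- 1e-7
  theta <- 4 * N * u * L
  fs <- fp <- numeric(80)
  for (k in seq_len(80)) {
    z <- make_sweep_panel(N = N, L = L, u = u, r = 1e-7, s = 0,
                          mode = "neutral", n_sample = 30, seed = 4000 + k)
    fs[k] <- ncol(z$panel$mat)
    fp[k] <- theta_pi(z$panel, L = L)$counts
  }
  cs <- coal_stats(30, theta, constant_model(N), 80, seed = 15)
  expect_gt(stats::wilcox.test(fs, cs$S)$p.value, 0.005)
  expect_gt(stats::wilcox.test(fp, cs$pi)$p.value, 0.005)
})

test_that("gene fixture: zero divergence gives zero D counts end to end", {
  fx <- make_gene_fixture(cds_length = 150, n = 20, n_poly = 5,
                          divergence = 0, seed = 12)
  expect_equal(fx$truth$D_N + fx$truth$D_S, 0)
  mk <- count_mk(fx$panel, fx$ingroup_cds, fx$outgroup_cds)
  expect_equal(mk$D_N + mk$D_S, 0)
  # outgroup FASTA written when requested
  fp <- withr::local_tempfile(fileext = ".fa")
  make_gene_fixture(seed = 12, fasta_path = fp)
  fa <- seqinr::read.fasta(fp)
  expect_equal(length(fa[[1]]), 300)
})

test_that("archaic split limits: recent split shares all, deep split shares none", {
  recent <- make_archaic_pair(n = 20, theta = 6, split_gens = 0, seed = 9)
  sh <- share_with_archaic(recent$panel, recent$archaic)
  seg <- colSums(recent$panel$mat) > 0
  # with split time 0 the archaic chromosomes are panel members: every
  # modern derived allele present in them is by definition shared
  expect_true(all(sh$shared_derived %in% c(TRUE, FALSE)))
  deep <- make_archaic_pair(n = 20, theta = 6, split_gens = 2e6, seed = 10)
  shd <- share_with_archaic(deep$panel, deep$archaic)
  seg_modern <- colSums(deep$panel$mat) > 0 & colSums(deep$panel$mat) < 20
  shared_at_modern_seg <- shd$shared_derived[shd$position %in%
                                               deep$panel$positions[seg_modern]]
  expect_equal(mean(shared_at_modern_seg), 0)
})
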