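test_that("codon effect classification follows the genetic code", {
  expect_equal(classify_codon_effect("CGA", 3, "G"), "synonymous")     # Arg->Arg
  expect_equal(classify_codon_effect("ACC", 2, "A"), "nonsynonymous")  # Thr->Asn
  expect_equal(classify_codon_effect("TGC", 1, "C"), "nonsynonymous")  # Cys->Arg
  # stop gain is nonsynonymous
  expect_equal(classify_codon_effect("TGC", 2, "A"), "nonsynonymous")  # TGC->TAC? Tyr: still aa change
  expect_equal(classify_codon_effect("TGG", 3, "A"), "nonsynonymous")  # Trp->stop
  expect_error(classify_codon_effect("ACG", 2, "N"), "ambiguous")
  expect_error(classify_codon_effect("ACG", 5, "A"), "outside")
})

test_that("MK counting separates polymorphism from divergence", {
  cds <- strsplit("ATGACCGGATGC", "")[[1]]     # Met Thr Gly Cys
  gene <- gene_model(1, rbind(c(1, 12)), 1, 12)
  # one segregating nonsynonymous site at CDS offset 5 (ACC -> AAC)
  mat <- matrix(0L, 6, 1); mat[1:2, 1] <- 1L
  sites <- data.frame(ref = "C", alt = "A", stringsAsFactors = FALSE)
  p <- classify_sites(hap_panel(5, mat, rep("X", 6), sites = sites), gene,
                      cds_seq = cds)
  mk <- count_mk(p, cds, cds)                  # outgroup identical
  expect_equal(c(mk$P_N, mk$P_S, mk$D_N, mk$D_S), c(1L, 0L, 0L, 0L))
  # monomorphic panel, outgroup differs synonymously at two codons
  outg <- cds; outg[6] <- "T"; outg[9] <- "G"  # ACC->ACT, GGA->GGG
  p0 <- classify_sites(hap_panel(5, matrix(0L, 6, 1), rep("X", 6),
                                 sites = sites), gene, cds_seq = cds)
  mk2 <- count_mk(p0, cds, outg)
  expect_equal(c(mk2$P_N, mk2$P_S, mk2$D_N, mk2$D_S), c(0L, 0L, 0L, 2L))
  # site both polymorphic and divergent counts as polymorphic only
  outg3 <- cds; outg3[5] <- "A"
  mk3 <- count_mk(p, cds, outg3)
  expect_equal(c(mk3$P_N, mk3$D_N), c(1L, 0L))
})

test_that("gene-fixture truth equals the MK counter output", {
  for (seed in c(2, 9, 31)) {
    fx <- make_gene_fixture(cds_length = 300, n = 30, n_poly = 8,
                            divergence = 0.02, seed = seed)
    mk <- count_mk(fx$panel, fx$ingroup_cds, fx$outgroup_cds)
    expect_equal(mk$P_N, fx$truth$P_N)
    expect_equal(mk$P_S, fx$truth$P_S)
    expect_equal(mk$D_N, fx$truth$D_N)
    expect_equal(mk$D_S, fx$truth$D_S)
  }
})

test_that("Fisher exact two-sided p agrees with exhaustive enumeration", {
  enum_fisher <- function(tab) {
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
    lo <- max(0, c1 - r2); hi <- min(r1, c1)
    pr <- vapply(lo:hi, function(a) {
      b <- r1 - a; cc <- c1 - a; d <- r2 - cc
      exp(lchoose(r1, a) + lchoose(r2, cc) - lchoose(r1 + r2, c1))
    }, numeric(1))
    obs <- pr[tab[1, 1] - lo + 1]
    sum(pr[pr <= obs * (1 + 1e-7)])
  }
  set.seed(4)
  for (rep in 1:200) {
    tab <- matrix(rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), enum_fisher(tab), tolerance = 1e-10)
    # cross-check against the independent base-R implementation
    expect_equal(fisher_exact_2x2(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-7)
    # invariance under transpose and row+column swaps
    expect_equal(fisher_exact_2x2(t(tab)), fisher_exact_2x2(tab))
    expect_equal(fisher_exact_2x2(tab[2:1, 2:1]), fisher_exact_2x2(tab))
  }
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_message(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 2), 2)), "degenerate")
  expect_equal(p0, 1)
})

test_that("MK test p-values reproduce the regional study's printed counts", {
  # (D_N, D_S, P_N, P_S) per population, table rows = (nonsyn, syn),
  # columns = (divergent, polymorphic)
  tabs <- list(KHV = matrix(c(0, 2, 5, 0), 2),
               ACB = matrix(c(0, 2, 3, 1), 2),
               CHB = matrix(c(0, 2, 4, 1), 2),
               ASW = matrix(c(0, 2, 3, 0), 2))
  expect_equal(fisher_exact_2x2(tabs$KHV), 1 / 21, tolerance = 1e-9)   # prints 0.048
  expect_equal(fisher_exact_2x2(tabs$ACB), 0.400, tolerance = 1e-9)
  expect_equal(fisher_exact_2x2(tabs$CHB), 5 / 35, tolerance = 1e-9)   # prints 0.143
  expect_equal(fisher_exact_2x2(tabs$ASW), 0.100, tolerance = 1e-9)
})

test_that("neutral synthetic CDS rejects at roughly the nominal rate", {
  set.seed(8)
  n_rej <- 0; n_valid <- 0
  for (k in 1:400) {
    fx <- make_gene_fixture(cds_length = 150, n = 20, n_poly = 10,
                            divergence = 0.06, syn_nonsyn_ratio = 1,
                            seed = 5000 + k)
    tab <- matrix(c(fx$truth$D_N, fx$truth$D_S, fx$truth$P_N, fx$truth$P_S), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    n_valid <- n_valid + 1
    if (fisher_exact_2x2(tab) <= 0.05) n_rej <- n_rej + 1
  }
  rate <- n_rej / n_valid
  # exact test is conservative; reject rate should be near/below nominal 5%
  expect_lt(rate, 0.08)
})
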