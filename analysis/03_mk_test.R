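#!/usr/bin/env Rscript
# McDonald-Kreitman analysis: (i) on the simulated coding-gene fixture,
# where the truth record validates the counting end to end, and (ii) on the
# published per-population count tables for the LTalpha coding region, whose
# exact Fisher p-values the package reproduces.

suppressPackageStartupMessages(library(ltapop))
dir.create("results", showWarnings = FALSE)

fx <- make_gene_fixture(cds_length = 618, n = 120, n_poly = 10,
                        divergence = 0.012, syn_nonsyn_ratio = 2, seed = 44)
mk <- count_mk(fx$panel, fx$ingroup_cds, fx$outgroup_cds)
stopifnot(identical(c(mk$P_N, mk$P_S, mk$D_N, mk$D_S),
                    c(fx$truth$P_N, fx$truth$P_S, fx$truth$D_N, fx$truth$D_S)))
cat(sprintf("simulated gene: P_N=%d P_S=%d D_N=%d D_S=%d  MK p=%.3f\n",
            mk$P_N, mk$P_S, mk$D_N, mk$D_S, mk_test(mk)$p_value))

# published count tables (D_N, D_S, P_N, P_S) for four populations
published <- list(KHV = c(0, 2, 5, 0), ACB = c(0, 2, 3, 1),
                  CHB = c(0, 2, 4, 1), ASW = c(0, 2, 3, 0))
out <- do.call(rbind, lapply(names(published), function(pp) {
  z <- published[[pp]]
  tab <- matrix(c(z[1], z[2], z[3], z[4]), 2)
  data.frame(pop = pp, D_N = z[1], D_S = z[2], P_N = z[3], P_S = z[4],
             p_value = fisher_exact_2x2(tab))
}))
write.table(out, "results/mk_published_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(out, digits = 3)
cat("\nKHV shows the excess of nonsynonymous polymorphism (p < 0.05)\n")
cat("reported for the Kinh population; the other populations are borderline\n")
cat("or non-significant, matching the printed table.\n")
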