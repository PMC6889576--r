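#!/usr/bin/env Rscript
# Population differentiation (Weir-Cockerham FST with empirical percentile
# ranks, plus island-model calibration) and genealogy-based allele ages for
# the region's frequency classes. Writes results/fst.tsv and results/ages.tsv.

suppressPackageStartupMessages(library(ltapop))
dir.create("results", showWarnings = FALSE)

region <- genomic_region("chr6", 1, 9637)
samples <- read.table("results/data/region.vcf.samples.tsv", header = TRUE,
                      sep = "\t")
panel <- polarize_panel(read_vcf_region("results/data/region.vcf", region,
                                        samples))

fst <- wc_fst(panel, groups = list(AFR = "AFR1", EUR = "EUR1", EAS = "EAS1"))
fst$percentile <- empirical_percentile(fst$fst,
                                       fst$fst[!is.na(fst$fst)])$percentile
write.table(fst, "results/fst.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ms <- wc_fst_mean(fst)
cat(sprintf("mean FST across %d sites: weighted %.4f, mean-of-ratios %.4f\n",
            ms$n_sites, ms$weighted, ms$mean))
cat("(all chromosomes come from one panmictic simulation, so FST ~ 0)\n")

# island-model calibration: 2 demes, M = 4Nm = 9 -> expect ~ 1/(1+M) = 0.1
reps <- sim_island(c(50, 50), N_total = 10000, M = 9, theta = 5, reps = 300,
                   seed = 11)
A <- W <- 0
for (cm in reps) if (ncol(cm)) for (s in seq_len(ncol(cm))) {
  z <- wc_fst_site(cm[, s], c(50, 50))
  if (!is.na(z$fst)) { A <- A + z$a; W <- W + z$w }
}
cat(sprintf("island-model check: weighted FST %.3f vs theory %.3f\n",
            A / (A + W), 1 / (1 + 9)))

# allele ages per derived-count class (pooled panel, constant N = 10,000)
n <- n_chrom(panel)
counts <- sort(unique(derived_counts(panel)))
counts <- counts[counts > 0 & counts < n]
classes <- counts[round(seq(1, length(counts), length.out = min(8, length(counts))))]
model <- constant_model(10000)
ages <- do.call(rbind, lapply(classes, function(i) {
  est <- allele_age_mc(i, n, model, reps = 20000, seed = 300 + i)
  data.frame(derived_count = i, freq = i / n,
             mean_age_years = est$mean_years, sd_years = est$sd_years)
}))
write.table(ages, "results/ages.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
print(ages, digits = 4)
cat(sprintf("\nTMRCA expectation for n=%d, N=10,000: %.0f years\n",
            n, tmrca_expectation(n, model)$years))
cat("high-frequency derived alleles date back hundreds of thousands of years,\n")
cat("the age scale on which archaic sharing of derived alleles is expected.\n")
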