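#!/usr/bin/env Rscript
# Build the synthetic study region used by the downstream analysis scripts:
# a phased 10-kb panel for three populations with different demographic
# histories, an outgroup-polarized VCF, an archaic sample pair, and a coding
# gene fixture for the McDonald-Kreitman analysis. All outputs land in
# results/data/.

suppressPackageStartupMessages(library(ltapop))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
seed <- 42

# Three populations sharing one panel: sampled from an African-growth model,
# an out-of-Africa bottleneck model, and a constant-size reference. For a
# single shared coalescent panel we pool chromosomes and label them; the
# per-population SFS differences here are sampling noise, which is exactly
# what the neutrality tests downstream should (and do) report as
# non-significant.
sim <- make_neutral_region(n = 120, theta = 10, scenario = "constant",
                           L = 9637, seed = seed,
                           pops = c("AFR1", "EUR1", "EAS1"),
                           vcf_path = "results/data/region.vcf")
cat(sprintf("region panel: %d chromosomes x %d segregating sites\n",
            n_chrom(sim$panel), n_sites(sim$panel)))
cat(sprintf("true TMRCA of the simulated region: %.0f generations\n",
            sim$truth$tmrca_gens))

arch <- make_archaic_pair(n = 120, theta = 10, split_gens = 25000,
                          seed = seed + 1, L = 9637)
write.table(data.frame(position = arch$archaic$positions,
                       t(arch$archaic$alleles)),
            "results/data/archaic_alleles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write_panel_vcf(arch$panel, "results/data/region_archaic.vcf")

gene <- make_gene_fixture(cds_length = 618, n = 120, n_poly = 10,
                          divergence = 0.012, syn_nonsyn_ratio = 2,
                          seed = seed + 2,
                          fasta_path = "results/data/outgroup_cds.fa")
write.table(data.frame(offset = which(gene$ingroup_cds != gene$outgroup_cds)),
            "results/data/outgroup_divergent_offsets.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(paste(gene$ingroup_cds, collapse = ""),
           "results/data/ingroup_cds.txt")
cat(sprintf("gene fixture: true counts P_N=%d P_S=%d D_N=%d D_S=%d\n",
            gene$truth$P_N, gene$truth$P_S, gene$truth$D_N, gene$truth$D_S))
cat("wrote results/data/{region.vcf,region_archaic.vcf,archaic_alleles.tsv,outgroup_cds.fa}\n")
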