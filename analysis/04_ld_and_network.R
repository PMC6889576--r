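#!/usr/bin/env Rscript
# Pairwise D-prime LD matrices per population (MAF >= 1%) and the pooled
# median-joining haplotype network. Writes results/ld_<pop>.tsv and
# results/network_{nodes,edges}.tsv.

suppressPackageStartupMessages(library(ltapop))
dir.create("results", showWarnings = FALSE)

region <- genomic_region("chr6", 1, 9637)
samples <- read.table("results/data/region.vcf.samples.tsv", header = TRUE,
                      sep = "\t")
panel <- polarize_panel(read_vcf_region("results/data/region.vcf", region,
                                        samples))

for (pp in unique(panel$pops)) {
  ld <- ld_matrix(panel, pop = pp, maf_min = 0.01)
  write.table(ld, sprintf("results/ld_%s.tsv", pp), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cat(sprintf("%s: %d SNP pairs, %.1f%% in complete LD (D'x100 = 100), %.1f%% with LOD > 2\n",
              pp, nrow(ld), 100 * mean(ld$Dprime_x100 == 100),
              100 * mean(ld$LOD > 2)))
}

# network over distinct haplotypes; collapse to the most informative sites
# (common variants) so medians are interpretable
common <- which(classify_maf(panel)$class == "common")
sub <- subset_panel(panel, sites = common)
net <- median_joining(sub$mat, groups = sub$pops)
rep <- cluster_report(net)
write.table(rep$nodes, "results/network_nodes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(net$edges, "results/network_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("network: %d nodes (%d observed haplotypes, %d inferred medians), %d edges, %d reticulation(s)\n",
            nrow(net$nodes), sum(net$nodes$observed),
            sum(!net$nodes$observed), nrow(net$edges), rep$reticulations))
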