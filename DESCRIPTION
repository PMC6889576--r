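Package: ltapop
Title: Population-Genetic Analysis of Diversity, Linkage and Selection in
    the LTalpha / MHC Class III Region
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for regional population-genetic analysis of
    phased haplotype panels, built around the lymphotoxin-alpha (LTalpha) gene
    in the MHC class III region. Implements site-frequency-spectrum diversity
    and neutrality statistics (theta-pi, Watterson's theta, Tajima's D, Fay and
    Wu's H) calibrated against coalescent-simulated demographic null models,
    the McDonald-Kreitman test with exact Fisher inference, pairwise D-prime
    linkage disequilibrium with LOD support, EHH/iHS/nSL haplotype-length
    selection scans, Weir-Cockerham FST with empirical percentile ranking,
    median-joining haplotype networks, genealogy-based allele-age and TMRCA
    estimation, and a seeded synthetic-data module (neutral coalescent panels
    under growth/bottleneck demographies, forward Wright-Fisher selective
    sweeps with recombination, coding-gene fixtures with outgroup divergence,
    and archaic sample pairs) so that every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    seqinr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
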