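---
title: "Methods: population-genetic analysis of the LTalpha region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genetic analysis of the LTalpha region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ltapop` re-implements, as a tested pipeline, the population-genetic
analysis of a ~10-kb region of the MHC class III locus on chromosome 6
containing the lymphotoxin-alpha (LTalpha) gene: diversity and
site-frequency-spectrum neutrality statistics calibrated against
coalescent-simulated demographic nulls, the McDonald-Kreitman (MK) test,
pairwise D' linkage disequilibrium, EHH/iHS/nSL haplotype-length selection
scans, Weir-Cockerham FST, median-joining haplotype networks, and
genealogy-based allele ages. A synthetic-data module generates every input
the pipeline needs, so the whole analysis is testable without downloads.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic data do and do not establish about real
data.

## The haplotype panel

All stages consume a `hap_panel`: a binary matrix of phased chromosomes by
segregating sites with 1-based physical positions, a population label per
chromosome, and per-site metadata (ref/alt alleles, ancestral state,
polarization flag, genic region class). At polarized sites 0 is ancestral
and 1 derived; unpolarized sites stay in ref/alt orientation and are
excluded from statistics that require polarity (Fay-Wu's H, iHS cores).
Coordinates are 1-based and closed both internally and at file interfaces:
R's indexing is 1-based, so the usual argument for 0-based half-open
internals (off-by-one safety in windowed arithmetic) does not apply here,
and matching VCF/GFF convention end-to-end removes a conversion layer.

Polarization prefers the VCF `AA` INFO tag and falls back to an outgroup
FASTA; lowercase (low-confidence) ancestral calls are accepted
case-insensitively. An ancestral base matching neither allele marks the
site unpolarized rather than guessing. Polarizing twice with the same
source is a no-op by construction (the per-site flip state is tracked).

## Diversity and neutrality statistics

Per population and interval the package reports the number of segregating
sites S, singletons (minor allele observed exactly once — the minor rather
than derived convention, so the count is defined at unpolarized sites too),
the distinct-haplotype count and Nei's haplotype diversity
$h = \frac{n}{n-1}\,(1 - \sum_k p_k^2)$, and two estimators of the scaled
mutation rate: $\theta_\pi$ (mean pairwise differences,
$\sum_s 2 i_s (n - i_s)/(n(n-1))$) and Watterson's $\theta_W = S/a_1$ with
$a_1 = \sum_{i<n} 1/i$, both reported per site and on the region-total
scale. Tajima's D uses the 1989 normalization constants and the counts
scale; Fay-Wu's H is the unnormalized $\theta_\pi - \theta_H$ with
$\theta_H = \sum_s 2 i_s^2/(n(n-1))$ over derived counts, matching the
magnitudes conventionally printed for these data. MAF classes use the
common/rare boundary at 5%, with the boundary itself common.

## Coalescent nulls and demographic scenarios

Significance of D and H is assessed against neutral coalescent simulations
under single-population piecewise demographies, re-implemented (not
wrapped) in compiled code: waiting times are solved analytically within
constant or exponential epochs, mutations fall on branches as a Poisson
process with $\mu_{\text{region}} = \theta/(4 N_{\text{present}})$ (the ms
convention: the null conditions on $\theta$, not on observed S; $\theta$
defaults to the population's observed region-scale $\theta_W$). The
empirical p-value uses the add-one convention
$(1 + \#\{\text{sim} \ge \text{obs}\})/(\text{reps}+1)$; S = 0 replicates,
where the statistics are undefined, are resampled and logged.

Two scenario families mirror the human histories used to calibrate the
regional tests: African exponential growth (2-10 fold from N = 10,000
diploids starting 70 kya) and an out-of-Africa bottleneck (10,000 to 2,000
at 60 kya) followed by 10-40 fold growth from 50 kya; generation time 20
years. "f-fold growth from T until the present" is implemented as
exponential growth over [0, T] reaching f times the pre-growth size at
present; an instantaneous-change reading is possible but the exponential
form is the standard ms idiom for growth. The simulator was cross-checked
against an independent coalescent implementation (msprime, diploid time
scale) for TMRCA, S and the mean of D under both constant and
bottleneck-plus-growth models.

Two empirical facts matter when interpreting the calibration tests. First,
the finite-sample mean of Tajima's D under neutrality is not 0 but about
-0.10 at n = 50 and $\theta = 10$ (the normalization makes D a ratio of
correlated estimates). Second, the bottleneck-plus-growth family is not
uniformly "bottleneck-like": for 20-40 fold growth the recent expansion
dominates and the mean of D is *more negative* than constant size; only
the mildest (10x) member is net positive relative to constant. A pure
bottleneck with no recent growth does shift D positive, and that
directional property is what the unit tests assert.

## McDonald-Kreitman test

Coding variants are classified synonymous/nonsynonymous by translating the
codon with all other positions at the ingroup reference (major) base;
stop gain counts as nonsynonymous; codons carrying several changes are
classified one change at a time against that background (the dominant
DnaSP convention — counts here are tiny, so pathway ambiguity is
immaterial). Polymorphic sites are those segregating within the
population; fixed differences require 100% within-population frequency of
an allele differing from the aligned outgroup; sites both polymorphic and
outgroup-mismatched count as polymorphic only. The two-sided Fisher exact
p sums hypergeometric masses not exceeding the observed table's mass, with
a documented 1e-7 relative tie tolerance (floating-point equality of
masses decides inclusion); a table with an empty margin returns p = 1 by
convention. The implementation is checked against exhaustive margin-fixed
enumeration and against `stats::fisher.test` as independent oracles.

## Linkage disequilibrium

From phased two-site gamete counts, $D = p_{AB} - p_A p_B$, D' is |D|
normalized by its frequency-dependent bound, and LOD is the base-10
likelihood ratio of the fitted gamete frequencies against linkage
equilibrium. Because inputs are phased, gametes are counted directly — no
EM over unphased genotypes. Matrices filter sites at within-population
MAF < 1% and report D' x 100 rounded to integers, the convention of the
standard LD-plot annotation; "complete LD" means the rounded value is 100.
No haplotype-block partitioning is attempted: block drawing is a display
heuristic of the plotting tool, not part of the statistics.

## Haplotype-length scans

EHH for a core allele class is the probability that two random carriers
are identical over all sites between the core and a flanking point; it is
1 at the core and non-increasing outward. iHS integrates the EHH curve
over physical distance (trapezoid rule) separately for ancestral and
derived carriers, stopping once EHH falls below 0.05 (the crossing
trapezoid is included; no interpolation to the exact crossing) or when an
inter-site gap exceeds 200 kb; cores whose integral runs off the panel
edge above the cutoff are flagged truncated and dropped by default. The
unstandardized score is $\ln(iHH_A/iHH_D)$, negative when derived-allele
haplotypes are long. nSL replaces physical distance by the number of
consecutive segregating sites over which a pair is identical; its mean
tract length is computed via the identity
$E[L] = 1 + \sum_k EHH_{\text{left}}(k) + \sum_k EHH_{\text{right}}(k)$,
truncating at the panel edge as the statistic's standard implementations
do. Cores need a derived frequency in [0.05, 0.95] and at least two
carriers of each allele.

Standardization bins scores by derived allele frequency into 100
equal-width bins, merges adjacent bins left to right until each holds at
least 20 scores, and z-scores within merged bins; outliers are |score| > 2
(strictly), the conventional most-extreme-5% threshold under approximate
normality. The bin count and occupancy floor are choices (the reference
normalization tool's behavior is equivalent in spirit); both are
parameters.

## FST and percentile ranks

Weir-Cockerham variance components are computed at the chromosome
(haploid) level, the natural formulation for phased data: with r groups,
between/within mean squares of the allele indicator give
$a = (MSB - MSW)/n_c$ and $\hat F_{ST} = a/(a + MSW)$; the estimator is
slightly negative at undifferentiated sites, which is expected behavior,
not an error. Multi-locus summaries report both the ratio-of-sums
("weighted") and the mean of per-site ratios, because the field's standard
tool prints both and published means do not always say which was quoted.
Percentile ranks against a background distribution use weak inequality
(fraction of background <= value), with outlier flags at the <= 2.5% and
>= 95% tails. The island-model calibration (d demes of N/d diploids,
per-lineage migration m, M = 4Nm with N the total size) has the classic
two-deme equilibrium expectation $F_{ST} = 1/(1+M)$ under this
parameterization, which the simulated check recovers.

## Median-joining networks

Distinct haplotypes (binary characters; unpolarized or missing-state sites
are excluded from the characters) are joined by the minimum-spanning
network (the union of all minimum spanning trees at tolerance epsilon = 0,
the most-parsimonious setting). Candidate median vectors — majority
consensus of triples mutually linked in the current network — are inserted
greedily while they reduce the minimum-spanning-tree cost of the node set;
ties are broken by lexicographic haplotype order so the result is
independent of input order; unobserved medians of degree < 3 are pruned.
Total cost never increases across insertions and the procedure terminates
because each insertion strictly lowers an integer-valued cost. The
reticulation count (edges - nodes + components) summarizes cycles, which
arise from recombination among haplotypes. No algorithmic cluster
partition is claimed: published cluster labels for such networks are
drawn by eye, so the report exposes components and node frequencies only.

## Allele ages and TMRCA

The age of a derived allele observed i times in n chromosomes is estimated
by Monte-Carlo: in each simulated genealogy, every branch subtending
exactly i tips receives an age drawn uniformly along its length, weighted
by branch length. Pooling those weighted draws across genealogies (the
default, `weighting = "pooled"`) conditions the genealogy on carrying a
count-i mutation, which is the consistent estimator of the age of an
observed variant; it reproduces the classical frequency-age curve
$-2x\ln x/(1-x)$ (in units of 2N generations) within a few percent at
n = 50. The per-genealogy variant (average of within-genealogy weighted
means) is retained as an option; at n = 2, i = 1 the two have expectations
$E[T_2^2]/(2E[T_2]) = 2N$ and $E[T_2]/2 = N$ generations respectively —
a useful pair of closed forms for validation. TMRCA expectations use the
analytic $4N(1 - 1/n)$ generations for constant size and Monte-Carlo means
otherwise. $N_e = \theta/(4\mu)$ is provided as a helper. This estimator
deliberately approximates the full importance-sampling machinery of
genealogy-likelihood software (which conditions on the entire site
configuration); parity with published point estimates from such software
is not claimed.

## Synthetic data: what it emulates, and what it does not

`make_neutral_region` writes coalescent panels (uniform positions on
1..L, infinite-sites with collision rejection, AA-tagged VCF).
`make_archaic_pair` adds two "archaic" chromosomes from a lineage isolated
for a configurable time (default checks use splits far older than the
modern TMRCA, so derived-allele sharing cleanly separates old from young
variants, up to incomplete lineage sorting realized by the simulation).
`make_gene_fixture` builds a stop-free random CDS with a controllable
nonsynonymous:synonymous mix of polymorphisms and outgroup substitutions,
recording true MK counts. `make_sweep_panel` is a discrete-generation
Wright-Fisher diploid forward simulation: multiplicative fitness (1,
1 + hs, 1 + s) at a focal site at L/2, neutral mutations (finite-sites
with position reuse after loss/fixation) and uniform recombination, 10N
generations of burn-in, then selection until the focal frequency enters a
target window — sampling at a window rather than fixation realizes the
partial-sweep regime in which multiple common haplotypes persist.
Soft-standing mode promotes an existing neutral variant with frequency
nearest f0 (real standing variation on correlated backgrounds);
soft-recurrent injects k independent copies.

Default forward-simulation conditions are N = 1,000 diploids, L = 200 kb,
u = r = 1e-7 per bp per generation: the human-like 1e-8 rates rescaled by
the same factor 10 that maps N = 10,000 onto N = 1,000, preserving per-bp
4Nu and 4Nr. Test problem sizes (50 sweep and 50 neutral replicates for
the power checks; n = 50, theta = 10, 2000 replicates for estimator
calibration; 2000 trials of 500-replicate nulls for the type-I check) are
the package's reference conditions and are stated in the tests themselves.
One property deserves a note: the extra haplotype diversity of
soft-standing sweeps is only detectable when the standing clade is old
enough to carry background diversity — at N = 600 and above the package's
checks see it clearly (distinct carrier haplotypes within 10 kb of the
selected site, median 6 vs 3 against hard sweeps); at N = 300 it drowns
in recombination noise. That is population genetics, not numerics.

Passing these checks shows the machinery is correct and calibrated under
the stated models. It does not show that real 1000 Genomes panels would
reproduce published per-population values: those depend on the accession
data themselves (sample composition, phasing, ancestral-allele calls),
and no claim of full-data parity is made at desk scale.

## Known limitations

* Null coalescent simulations have no recombination (matching the
  assumption of the genealogy-based age estimator); recombination lives
  only in the forward simulator.
* The MK module does not correct divergence for multiple hits, does not
  polarize the test, and does not estimate the adaptive fraction.
* iHS/nSL use physical distance only — no genetic map integration.
* The median-joining implementation targets the small haplotype sets of a
  single region (hundreds of distinct haplotypes at most); epsilon > 0
  settings are supported but quadratic in candidate medians.
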