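# Synthetic-data generators: every fixture the pipeline consumes can be
# produced here, seeded, and written in standard formats (VCF / FASTA / TSV).

#' Neutral coalescent region fixture
#'
#' Simulates a phased panel under a demographic scenario, assigns uniform
#' positions on 1..L, optionally writes a phased VCF (with the ancestral
#' allele as the AA tag) plus a sample map, and records simulation truth
#' (TMRCA, S, mutation ages).
#'
#' @param n chromosomes (even if writing a VCF).
#' @param theta region-scaled mutation rate.
#' @param scenario a [demographic_model()] or a name understood by
#'   [scenario_model()].
#' @param L region length (bp).
#' @param seed integer seed.
#' @param pops population label(s) recycled across chromosomes (consecutive
#'   pairs form diploid samples).
#' @param vcf_path optional path to write the VCF.
#' @param n_archaic,archaic_split_gens optional archaic chromosomes (see
#'   [coal_panel()]).
#' @return list with `panel`, `truth` (list: S, tmrca_gens, age_gens,
#'   archaic_mat), and `vcf_path`.
#' @export
make_neutral_region <- function(n, theta, scenario = "constant", L = 10000,
                                seed = 1, pops = "POP1", vcf_path = NULL,
                                n_archaic = 0, archaic_split_gens = 0) {
  model <- if (inherits(scenario, "demographic_model")) scenario
           else scenario_model(scenario)
  sim <- coal_panel(n, theta, model, L, n_archaic = n_archaic,
                    archaic_split_gens = archaic_split_gens, seed = seed)
  panel <- sim$panel
  panel$pops <- rep_len(rep(pops, each = 2), n)
  # alleles: ancestral (0) = A, derived (1) = G; AA tag = A
  S <- ncol(panel$mat)
  panel$sites$ref <- rep("A", S)
  panel$sites$alt <- rep("G", S)
  panel$sites$aa <- rep("A", S)
  panel$sites$polarized <- rep(TRUE, S)
  if (!is.null(vcf_path)) write_panel_vcf(panel, vcf_path)
  list(panel = panel,
       truth = list(S = sim$S, tmrca_gens = sim$tmrca_gens,
                    age_gens = sim$age_gens, archaic_mat = sim$archaic_mat),
       vcf_path = vcf_path)
}

#' Forward-simulated selective sweep panel
#'
#' Discrete-generation Wright-Fisher diploid simulation with multiplicative
#' fitness (1, 1 + h s, 1 + s) at a focal site at L/2, neutral mutations and
#' uniform recombination elsewhere, burn-in of `burnin` generations
#' (default 10N), then selection until the focal frequency enters
#' `sample_freq_window` (restarting from the burned-in state when the allele
#' is lost). Chromosomes are sampled without replacement.
#'
#' @param N diploid population size.
#' @param L region length (bp).
#' @param u,r per-bp per-generation mutation and recombination rates
#'   (defaults 1e-7: the human-like 1e-8 rescaled by the same factor 10 that
#'   maps N = 10,000 diploids onto the default N = 1,000, preserving
#'   per-bp 4Nu and 4Nr).
#' @param s selection coefficient (0 = neutral).
#' @param h_dom dominance coefficient (default 0.5).
#' @param mode `"neutral"`, `"hard"`, `"soft_standing"` (focal allele = an
#'   existing neutral variant with frequency nearest `f0`) or
#'   `"soft_recurrent"` (`k_origins` independent copies).
#' @param f0 standing frequency for `soft_standing`.
#' @param k_origins origin count for `soft_recurrent`.
#' @param sample_freq_window target focal frequency interval at sampling.
#' @param n_sample chromosomes to sample.
#' @param seed integer seed.
#' @param burnin burn-in generations (default `10 * N`).
#' @param max_restarts restart budget after allele loss.
#' @param run_gens if positive, run exactly this many generations after the
#'   focal allele is introduced instead of waiting for the window (used for
#'   drift checks).
#' @param vcf_path optional path to write the panel as a phased VCF.
#' @return list with `panel` (polarized, 1 = derived), `truth` (focal
#'   position/index/frequency, restarts, trajectory) and `vcf_path`.
#' @export
make_sweep_panel <- function(N, L, u = 1e-7, r = 1e-7, s = 0.05, h_dom = 0.5,
                             mode = c("hard", "soft_standing",
                                      "soft_recurrent", "neutral"),
                             f0 = 0.05, k_origins = 4,
                             sample_freq_window = c(0.6, 0.9),
                             n_sample = 100, seed = 1, burnin = 10 * N,
                             max_restarts = 500, run_gens = 0,
                             vcf_path = NULL) {
  mode <- match.arg(mode)
  if (s > 0 && N * s <= 1)
    warning("N*s <= 1: sweep unlikely to leave a detectable signature")
  mode_code <- match(mode, c("neutral", "hard", "soft_standing", "soft_recurrent")) - 1L
  set.seed(seed)
  res <- cpp_forward_sim(as.integer(N), as.integer(L), u, r, s, h_dom,
                         mode_code, f0, as.integer(k_origins),
                         sample_freq_window[1], sample_freq_window[2],
                         as.integer(n_sample), as.integer(burnin),
                         as.integer(max_restarts),
                         as.integer(run_gens > 0), as.integer(run_gens),
                         as.integer(200 * N))
  panel <- hap_panel(res$positions, res$mat, rep("SIM", n_sample))
  S <- ncol(panel$mat)
  panel$sites$ref <- rep("A", S); panel$sites$alt <- rep("G", S)
  panel$sites$aa <- rep("A", S); panel$sites$polarized <- rep(TRUE, S)
  if (!is.null(vcf_path)) write_panel_vcf(panel, vcf_path)
  list(panel = panel,
       truth = list(focal_position = L %/% 2, focal_index = res$focal_index,
                    focal_count_sample = res$focal_count_sample,
                    focal_freq_pop = res$focal_freq_pop,
                    restarts = res$restarts,
                    gens_after_setup = res$gens_after_setup,
                    trajectory = res$trajectory),
       vcf_path = vcf_path)
}

random_cds <- function(n_codons) {
  codons <- character(n_codons)
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!(cd %in% stops)) break
    }
    codons[k] <- cd
  }
  codons[1] <- "ATG"
  strsplit(paste(codons, collapse = ""), "")[[1]]
}

#' Coding-gene fixture for the McDonald-Kreitman test
#'
#' Generates a random CDS without premature stops, within-population
#' polymorphisms and outgroup substitutions with a controllable
#' nonsynonymous:synonymous mix, and records the true MK counts.
#'
#' @param cds_length coding length, divisible by 3.
#' @param n chromosomes in the panel.
#' @param n_poly segregating coding sites to place.
#' @param divergence expected substitutions per site to the outgroup.
#' @param syn_nonsyn_ratio target nonsynonymous:synonymous ratio of proposed
#'   changes (1 = balanced).
#' @param seed integer seed.
#' @param fasta_path optional path for the outgroup CDS FASTA.
#' @return list with `panel` (CDS-classified sites), `gene` (the
#'   [gene_model()]), `ingroup_cds`, `outgroup_cds`, `truth`
#'   (true P_N/P_S/D_N/D_S) and `fasta_path`.
#' @export
make_gene_fixture <- function(cds_length = 300, n = 40, n_poly = 6,
                              divergence = 0.01, syn_nonsyn_ratio = 1,
                              seed = 1, fasta_path = NULL) {
  if (cds_length %% 3 != 0) stop("cds_length must be divisible by 3")
  set.seed(seed)
  cds <- random_cds(cds_length / 3)
  bases <- c("A", "C", "G", "T")
  p_nonsyn <- syn_nonsyn_ratio / (1 + syn_nonsyn_ratio)
  propose <- function(seq_bg, excluded, want_nonsyn) {
    # random site+base of the wanted class, not in `excluded`
    for (it in 1:2000) {
      off <- sample.int(cds_length, 1)
      if (off %in% excluded || off <= 3) next     # keep the start codon intact
      alt <- sample(setdiff(bases, seq_bg[off]), 1)
      eff <- classify_codon_effect(seq_bg, off, alt)
      if ((eff == "nonsynonymous") == want_nonsyn) return(list(off = off, alt = alt, eff = eff))
    }
    stop("could not place a change of the requested class")
  }
  # polymorphisms
  used <- integer(0)
  P_N <- P_S <- 0L
  poly <- list()
  for (q in seq_len(n_poly)) {
    want <- runif(1) < p_nonsyn
    ch <- propose(cds, used, want)
    used <- c(used, ch$off)
    cnt <- sample.int(n - 1, 1)
    if (ch$eff == "nonsynonymous") P_N <- P_N + 1L else P_S <- P_S + 1L
    poly[[q]] <- list(off = ch$off, alt = ch$alt, count = cnt, eff = ch$eff)
  }
  # outgroup substitutions
  outg <- cds
  D_N <- D_S <- 0L
  n_div <- rpois(1, divergence * cds_length)
  for (q in seq_len(n_div)) {
    want <- runif(1) < p_nonsyn
    ch <- propose(cds, used, want)
    used <- c(used, ch$off)
    outg[ch$off] <- ch$alt
    if (ch$eff == "nonsynonymous") D_N <- D_N + 1L else D_S <- D_S + 1L
  }
  # assemble the panel: gene occupies positions 101..(100 + cds_length),
  # single exon, CDS from gene-local offset 1
  gene <- gene_model(gene_start = 101,
                     exons_local = cbind(1, cds_length),
                     cds_start_offset = 1, cds_length = cds_length)
  offs <- sort(vapply(poly, function(z) z$off, numeric(1)))
  poly <- poly[order(vapply(poly, function(z) z$off, numeric(1)))]
  mat <- matrix(0L, nrow = n, ncol = length(poly))
  for (q in seq_along(poly))
    mat[sample.int(n, poly[[q]]$count), q] <- 1L
  positions <- 101L + as.integer(offs) - 1L
  sites <- data.frame(ref = cds[offs],
                      alt = vapply(poly, function(z) z$alt, character(1)),
                      aa = cds[offs], polarized = TRUE,
                      stringsAsFactors = FALSE)
  panel <- hap_panel(positions, mat, rep("SIMPOP", n), sites = sites)
  panel <- classify_sites(panel, gene, cds_seq = cds)
  if (!is.null(fasta_path))
    seqinr::write.fasta(list(outg), names = "outgroup_cds", file.out = fasta_path)
  list(panel = panel, gene = gene, ingroup_cds = cds, outgroup_cds = outg,
       truth = list(P_N = P_N, P_S = P_S, D_N = D_N, D_S = D_S),
       fasta_path = fasta_path)
}

#' Archaic sample pair for a simulated region
#'
#' Convenience wrapper around [make_neutral_region()] with two archaic
#' chromosomes splitting `split_gens` generations ago; returns the modern
#' panel, the [archaic_panel()] (sources "Neandertal" and "Denisovan") and
#' the truth sharing flags derived from the simulated genealogy.
#'
#' @param n modern chromosomes.
#' @param theta region-scaled mutation rate.
#' @param split_gens archaic split time (generations).
#' @param scenario demographic scenario for the moderns.
#' @param L region length.
#' @param seed integer seed.
#' @return list with `panel`, `archaic`, `truth_shared` (matrix source x
#'   site of true derived-sharing flags).
#' @export
make_archaic_pair <- function(n, theta, split_gens, scenario = "constant",
                              L = 10000, seed = 1) {
  sim <- make_neutral_region(n, theta, scenario = scenario, L = L, seed = seed,
                             n_archaic = 2, archaic_split_gens = split_gens)
  am <- sim$truth$archaic_mat
  alleles <- matrix(ifelse(am == 1, "G", "A"), nrow = 2)
  rownames(alleles) <- c("Neandertal", "Denisovan")
  arch <- archaic_panel(sim$panel$positions, alleles)
  # keep only sites segregating among moderns for the truth flags
  list(panel = sim$panel, archaic = arch,
       truth_shared = am == 1)
}
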