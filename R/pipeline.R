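# End-to-end orchestration: ingest -> per-population summaries -> neutrality
# p-values under demographic scenarios -> LD -> haplotype scans -> FST ->
# median-joining network -> allele ages, written as TSV reports.

#' Validate a pipeline run configuration
#'
#' Collects all problems rather than stopping at the first. Unknown keys
#' warn; missing required keys and unreadable files are errors.
#'
#' @param config path to a YAML file or a named list.
#' @return the normalized config list (with defaults filled); errors with the
#'   full problem list otherwise.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("vcf", "region", "samples", "out_dir")
  known <- c(required, "gene_model", "ancestral_fasta", "scenarios", "seed",
             "reps", "maf_ld", "maf_scan", "outlier_threshold", "groups",
             "gene_interval", "ingroup_cds", "outgroup_cds")
  errs <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warning("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in required)
    if (is.null(config[[k]])) errs <- c(errs, sprintf("missing required key '%s'", k))
  for (k in c("vcf", "samples"))
    if (!is.null(config[[k]]) && !file.exists(config[[k]]))
      errs <- c(errs, sprintf("file for '%s' not found: %s", k, config[[k]]))
  if (!is.null(config$region) &&
      !all(c("chrom", "start", "end") %in% names(config$region)))
    errs <- c(errs, "region must have chrom, start, end")
  if (length(errs)) stop(paste(errs, collapse = "; "))
  defaults <- list(scenarios = "constant", seed = 1, reps = 1000,
                   maf_ld = 0.01, maf_scan = 0.05, outlier_threshold = 2)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  config
}

#' Run the full regional analysis and write TSV reports
#'
#' Stages: VCF ingest and polarization; per-population diversity/neutrality
#' summary (with simulation p-values for Tajima's D and Fay-Wu H under each
#' configured scenario); pairwise LD; iHS and nSL scans with within-run
#' standardization; Weir-Cockerham FST across configured groups; the
#' median-joining network of pooled haplotypes; Monte-Carlo allele ages for
#' segregating frequency classes. All randomness derives from `config$seed`.
#'
#' @param config a config list/path accepted by [validate_config()].
#' @return the output directory, invisibly (contains `table1.tsv`,
#'   `sites.tsv`, `haplotypes.tsv`, `ld.tsv`, `scan_<stat>.tsv`, `fst.tsv`,
#'   `network_nodes.tsv`, `network_edges.tsv`, `ages.tsv`, `run_log.txt`).
#' @export
run_report <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("seed: %d", cfg$seed),
                 sprintf("time: %s", format(Sys.time(), "%Y-%m-%d")))
  set.seed(cfg$seed)
  region <- genomic_region(cfg$region$chrom, cfg$region$start, cfg$region$end)
  samples <- read.table(cfg$samples, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  panel <- read_vcf_region(cfg$vcf, region, samples)
  anc <- if (!is.null(cfg$ancestral_fasta))
    ancestral_from_fasta(cfg$ancestral_fasta, region$start) else NULL
  panel <- polarize_panel(panel, anc)
  log_lines <- c(log_lines,
                 sprintf("sites: %d retained, %d polarized", ncol(panel$mat),
                         sum(panel$sites$polarized)))

  L <- region$end - region$start + 1
  tab1 <- pop_summary_table(panel, L = L)
  scen_names <- cfg$scenarios
  for (sc in scen_names) {
    model <- if (sc == "constant") constant_model(10000) else {
      parts <- strsplit(sc, ":")[[1]]
      scenario_model(parts[1], as.numeric(sub("x", "", parts[2])))
    }
    pd <- ph <- numeric(nrow(tab1))
    for (k in seq_len(nrow(tab1))) {
      n <- tab1$n2[k]
      theta <- max(tab1$theta_w[k] * L, 1e-6)
      pd[k] <- null_pvalue(tab1$D_T[k], "D", n, theta, model,
                           reps = cfg$reps)$p_value
      ph[k] <- if (is.na(tab1$H[k])) NA else
        null_pvalue(tab1$H[k], "H", n, theta, model, reps = cfg$reps,
                    tail = "upper")$p_value
    }
    tab1[[paste0("P_D_", gsub("[^a-zA-Z0-9]", "_", sc))]] <- pd
    tab1[[paste0("P_H_", gsub("[^a-zA-Z0-9]", "_", sc))]] <- ph
  }
  tsv <- function(x, f) write.table(x, file.path(cfg$out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(tab1, "table1.tsv")

  # per-site table
  freqs <- do.call(cbind, lapply(unique(panel$pops), function(pp) {
    sl <- subset_panel(panel, pop = pp)
    colSums(sl$mat) / nrow(sl$mat)
  }))
  colnames(freqs) <- paste0("freq_", unique(panel$pops))
  sites <- cbind(panel$sites, freqs, classify_maf(panel)[, c("maf", "class")])
  tsv(sites, "sites.tsv")

  spec <- haplotype_spectrum(panel)
  tsv(spec$haplotypes, "haplotypes.tsv")

  # LD per population
  ld_all <- do.call(rbind, lapply(unique(panel$pops), function(pp) {
    out <- tryCatch(ld_matrix(panel, pop = pp, maf_min = cfg$maf_ld),
                    warning = function(w) NULL)
    if (is.null(out) || !nrow(out)) return(NULL)
    cbind(pop = pp, out)
  }))
  if (!is.null(ld_all)) tsv(ld_all, "ld.tsv")

  # scans
  for (stat in c("ihs", "nsl")) {
    scan_all <- do.call(rbind, lapply(unique(panel$pops), function(pp) {
      sl <- subset_panel(panel, pop = pp, drop_monomorphic = TRUE)
      if (ncol(sl$mat) < 3) return(NULL)
      sc <- scan_scores(sl, stat = stat, maf_min = cfg$maf_scan)
      if (!nrow(sc)) return(NULL)
      sc$std <- standardize_scores(sc$score, sc$freq_derived)
      sc$outlier <- call_outliers(sc$std, cfg$outlier_threshold)
      cbind(pop = pp, sc)
    }))
    if (!is.null(scan_all)) tsv(scan_all, sprintf("scan_%s.tsv", stat))
  }

  # FST
  if (!is.null(cfg$groups)) {
    fst_tab <- wc_fst(panel, cfg$groups)
    fst_tab$percentile <- empirical_percentile(fst_tab$fst,
                                               fst_tab$fst[!is.na(fst_tab$fst)])$percentile
    tsv(fst_tab, "fst.tsv")
    ms <- wc_fst_mean(fst_tab)
    log_lines <- c(log_lines, sprintf("fst weighted: %.6f mean: %.6f",
                                      ms$weighted, ms$mean))
  }

  # network over pooled distinct haplotypes
  net <- median_joining(panel$mat, groups = panel$pops)
  tsv(net$nodes, "network_nodes.tsv")
  tsv(net$edges, "network_edges.tsv")

  # allele ages per pooled derived count class
  n <- nrow(panel$mat)
  counts <- sort(unique(colSums(panel$mat)))
  counts <- counts[counts > 0 & counts < n]
  model_age <- constant_model(10000)
  ages <- do.call(rbind, lapply(counts, function(i) {
    est <- allele_age_mc(i, n, model_age, reps = min(cfg$reps * 5, 20000))
    data.frame(derived_count = i, mean_years = est$mean_years,
               sd_years = est$sd_years)
  }))
  if (!is.null(ages)) tsv(ages, "ages.tsv")

  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(cfg$out_dir)
}
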