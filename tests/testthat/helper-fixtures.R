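# Shared fixtures, built in code.

# A small deterministic two-population panel: 6 chromosomes x 5 sites.
toy_panel <- function() {
  mat <- rbind(c(0, 1, 0, 0, 1),
               c(0, 1, 0, 0, 1),
               c(1, 0, 0, 1, 1),
               c(1, 0, 0, 1, 0),
               c(0, 0, 1, 1, 0),
               c(0, 0, 0, 1, 0))
  hap_panel(positions = c(100, 250, 400, 600, 900), mat = mat,
            pops = c("A", "A", "A", "A", "B", "B"),
            sites = data.frame(ref = c("A", "C", "G", "T", "A"),
                               alt = c("G", "T", "A", "C", "C"),
                               stringsAsFactors = FALSE))
}

# write a small VCF text fixture directly (for reader tests)
write_toy_vcf <- function(path, extra_records = character()) {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", "S2"), collapse = "\t"))
  rec <- function(pos, ref, alt, info, g1, g2)
    paste(c("chr6", pos, ".", ref, alt, ".", "PASS", info, "GT", g1, g2),
          collapse = "\t")
  body <- c(rec(1000, "A", "G", "AA=A", "0|1", "1|1"),
            rec(2000, "C", "T,G", "AA=C", "0|1", "0|2"),   # tri-allelic
            rec(3000, "T", "C", "AA=C", "0|0", "0|1"),
            extra_records)
  writeLines(c(hdr, body), path)
  path
}

# Heavy shared fixture for the sweep-power and standardization checks:
# 50 forward-simulated hard sweeps and 50 matched neutral panels
# (N = 1000 diploids, L = 200 kb, u = r = 1e-7, s = 0.05, sampling at
# derived frequency 0.6-0.9, n = 100 chromosomes). Built once per session.
.sweep_cache <- new.env(parent = emptyenv())

sweep_fixture <- function(n_reps = 50) {
  key <- paste0("reps", n_reps)
  if (!is.null(.sweep_cache[[key]])) return(.sweep_cache[[key]])
  sweeps <- lapply(seq_len(n_reps), function(k)
    make_sweep_panel(N = 1000, L = 200000, s = 0.05, mode = "hard",
                     sample_freq_window = c(0.6, 0.9), n_sample = 100,
                     seed = 100 + k))
  neutrals <- lapply(seq_len(n_reps), function(k)
    make_sweep_panel(N = 1000, L = 200000, s = 0, mode = "neutral",
                     n_sample = 100, seed = 200 + k))
  out <- list(sweeps = sweeps, neutrals = neutrals)
  .sweep_cache[[key]] <- out
  out
}

# EHH value at a signed physical offset from the core: linear interpolation
# between recorded points; 0 beyond the point where the decay reached 0;
# the last recorded value when the curve ran off the panel edge still > 0.
ehh_at <- function(curve, offset) {
  keep <- if (offset >= 0) curve$offsets >= 0 else curve$offsets <= 0
  o <- abs(curve$offsets[keep]); e <- curve$ehh[keep]
  ord <- order(o); o <- o[ord]; e <- e[ord]
  x <- abs(offset)
  if (!length(o)) return(NA_real_)
  if (x <= max(o)) return(stats::approx(o, e, x)$y)
  last <- e[length(e)]
  if (last <= 0) 0 else last
}
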