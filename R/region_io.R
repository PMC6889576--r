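#' Genomic region (1-based, closed)
#'
#' @param chrom chromosome name.
#' @param start,end 1-based closed coordinates, `start <= end`.
#' @param assembly assembly label, e.g. `"GRCh37"`.
#' @return a `genomic_region` object.
#' @export
genomic_region <- function(chrom, start, end, assembly = "GRCh37") {
  start <- as.integer(start); end <- as.integer(end)
  if (start > end) stop("start must be <= end")
  structure(list(chrom = chrom, start = start, end = end, assembly = assembly),
            class = "genomic_region")
}

#' @export
print.genomic_region <- function(x, ...) {
  cat(sprintf("%s:%d-%d (%s, %d bp)\n", x$chrom, x$start, x$end, x$assembly,
              x$end - x$start + 1L))
  invisible(x)
}

#' Gene model with exons and a coding region
#'
#' Exons are given in gene-local coordinates (1-based, closed, position +1 is
#' the first base of the gene). The coding sequence starts at gene-local
#' offset `cds_start_offset` (the A of the ATG) and runs for `cds_length`
#' coding bases along the exons.
#'
#' @param gene_start genomic position of gene-local +1.
#' @param exons_local two-column matrix (start, end) of exon intervals in
#'   gene-local coordinates, ordered, non-overlapping.
#' @param cds_start_offset gene-local offset of the translation start.
#' @param cds_length coding length in bp, divisible by 3.
#' @param strand `"+"` or `"-"` (orientation of the coding sequence relative
#'   to the gene-local axis).
#' @return a `gene_model` object with derived genomic exon and CDS intervals;
#'   CDS intervals carry the cumulative coding offset of their first base.
#' @export
gene_model <- function(gene_start, exons_local, cds_start_offset, cds_length,
                       strand = "+") {
  exons_local <- matrix(as.integer(exons_local), ncol = 2)
  if (nrow(exons_local) > 1) {
    if (any(diff(exons_local[, 1]) <= 0)) stop("exons must be ordered")
    if (any(exons_local[-1, 1] <= exons_local[-nrow(exons_local), 2]))
      stop("exons must not overlap")
  }
  if (cds_length %% 3 != 0) stop("cds_length must be divisible by 3")
  exons <- cbind(gene_start + exons_local[, 1] - 1L,
                 gene_start + exons_local[, 2] - 1L)
  # walk exon bases from the translation start collecting cds_length bases
  cds <- NULL
  remaining <- cds_length
  coding_off <- 1L
  cds_start_g <- gene_start + as.integer(cds_start_offset) - 1L
  for (i in seq_len(nrow(exons))) {
    lo <- max(exons[i, 1], cds_start_g)
    hi <- exons[i, 2]
    if (hi < lo || remaining <= 0) next
    take <- min(hi - lo + 1L, remaining)
    cds <- rbind(cds, c(lo, lo + take - 1L, coding_off))
    coding_off <- coding_off + take
    remaining <- remaining - take
  }
  if (is.null(cds) || remaining > 0)
    stop("exons do not contain cds_length coding bases after the start offset")
  colnames(cds) <- c("start", "end", "coding_offset")
  structure(list(gene_start = gene_start,
                 gene_end = exons[nrow(exons), 2],
                 exons = exons, cds = cds,
                 cds_start_offset = as.integer(cds_start_offset),
                 cds_length = as.integer(cds_length), strand = strand),
            class = "gene_model")
}

#' Coding offset of genomic positions within a gene model
#'
#' @param gene a [gene_model()].
#' @param positions genomic positions.
#' @return integer vector of 1-based offsets within the coding sequence
#'   (`NA` for non-CDS positions). For minus-strand genes the offset counts
#'   from the other end.
#' @export
cds_offset <- function(gene, positions) {
  out <- rep(NA_integer_, length(positions))
  for (i in seq_len(nrow(gene$cds))) {
    row <- gene$cds[i, ]
    hit <- positions >= row["start"] & positions <= row["end"]
    out[hit] <- as.integer(row["coding_offset"] + positions[hit] - row["start"])
  }
  if (gene$strand == "-") out <- ifelse(is.na(out), NA_integer_,
                                        gene$cds_length - out + 1L)
  out
}

#' Read a phased haplotype panel from a VCF region
#'
#' Retains bi-allelic SNPs only; indels and multi-allelic records are
#' excluded with a message. Sites with any unphased or missing genotype among
#' the selected samples are dropped with a warning (`strict = TRUE` errors).
#' Chromosomes are ordered as the two phased haplotypes of each sample in
#' `sample_map` order. The INFO `AA` tag, when present, is stored per site
#' for later polarization.
#'
#' @param path VCF file (plain text or gzipped).
#' @param region a [genomic_region()].
#' @param sample_map data.frame with columns `sample` and `pop`.
#' @param strict error (rather than drop) on unphased/missing genotypes.
#' @return a [hap_panel()] with `polarized = FALSE` at all sites.
#' @export
read_vcf_region <- function(path, region, sample_map, strict = FALSE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  pos <- as.integer(fix$POS)
  keep <- fix$CHROM == region$chrom & pos >= region$start & pos <= region$end
  is_snp <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_dropped <- sum(keep & !is_snp)
  if (n_dropped > 0)
    message(sprintf("excluded %d non-bi-allelic-SNP record(s)", n_dropped))
  keep <- keep & is_snp
  if (!any(keep)) stop("no bi-allelic SNPs in region")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  missing_samples <- setdiff(sample_map$sample, colnames(gt))
  if (length(missing_samples))
    stop("sample(s) absent from VCF: ", paste(missing_samples, collapse = ", "))
  gt <- gt[keep, sample_map$sample, drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  pos <- pos[keep]
  ok_site <- apply(gt, 1, function(g) all(g %in% c("0|0", "0|1", "1|0", "1|1")))
  if (any(!ok_site)) {
    msg <- sprintf("%d site(s) with unphased or missing genotypes", sum(!ok_site))
    if (strict) stop(msg) else warning(msg, " dropped")
  }
  gt <- gt[ok_site, , drop = FALSE]
  fix <- fix[ok_site, , drop = FALSE]
  pos <- pos[ok_site]
  ord <- order(pos)
  gt <- gt[ord, , drop = FALSE]; fix <- fix[ord, , drop = FALSE]; pos <- pos[ord]
  # haplotype matrix: 2 rows per sample
  n_s <- ncol(gt)
  mat <- matrix(0L, nrow = 2 * n_s, ncol = nrow(gt))
  for (j in seq_len(n_s)) {
    g <- gt[, j]
    mat[2 * j - 1, ] <- as.integer(substr(g, 1, 1))
    mat[2 * j, ] <- as.integer(substr(g, 3, 3))
  }
  aa <- extract_aa(fix$INFO)
  sites <- data.frame(ref = fix$REF, alt = fix$ALT, aa = aa,
                      polarized = FALSE, flipped = FALSE,
                      stringsAsFactors = FALSE)
  hap_panel(pos, mat, rep(sample_map$pop, each = 2), sites = sites,
            chrom = region$chrom)
}

extract_aa <- function(info) {
  m <- regmatches(info, regexpr("(?:^|;)AA=([^;]+)", info))
  out <- rep(NA_character_, length(info))
  has <- lengths(regmatches(info, gregexpr("(?:^|;)AA=", info))) > 0
  out[has] <- toupper(sub(".*AA=([^;]+).*", "\\1", info[has]))
  out
}

#' Write a panel as a phased VCF
#'
#' Consecutive chromosome pairs become diploid samples. Sites keep their
#' ref/alt alleles (defaults `A`/`G` when unset) and, when known, the
#' ancestral allele as an `AA` INFO tag. If the panel has been polarized with
#' column flips, columns are written back in ref/alt orientation so that a
#' read/polarize round trip is exact.
#'
#' @param panel a [hap_panel()] with an even number of chromosomes.
#' @param path output file.
#' @param sample_names optional sample names (default pop-derived).
#' @return `path`, invisibly. A `<path>.samples.tsv` sample map is written
#'   alongside.
#' @export
write_panel_vcf <- function(panel, path, sample_names = NULL) {
  n <- nrow(panel$mat)
  if (n %% 2 != 0) stop("panel must have an even number of chromosomes")
  n_s <- n / 2
  pops <- panel$pops[seq(1, n, by = 2)]
  if (is.null(sample_names))
    sample_names <- sprintf("%s_%03d", pops, stats::ave(seq_len(n_s), pops, FUN = seq_along))
  ref <- ifelse(is.na(panel$sites$ref), "A", panel$sites$ref)
  alt <- ifelse(is.na(panel$sites$alt), "G", panel$sites$alt)
  aa <- panel$sites$aa
  flipped <- if (!is.null(panel$sites$flipped)) panel$sites$flipped else rep(FALSE, ncol(panel$mat))
  mat <- panel$mat
  if (any(flipped)) mat[, flipped] <- 1L - mat[, flipped]
  info <- ifelse(is.na(aa), ".", paste0("AA=", aa))
  lines <- c("##fileformat=VCFv4.2",
             '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample_names), collapse = "\t"))
  body <- vapply(seq_along(panel$positions), function(s) {
    gts <- paste0(mat[seq(1, n, by = 2), s], "|", mat[seq(2, n, by = 2), s])
    paste(c(panel$chrom, panel$positions[s], ".", ref[s], alt[s], ".",
            "PASS", info[s], "GT", gts), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  write.table(data.frame(sample = sample_names, pop = pops),
              paste0(path, ".samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ancestral sequence lookup from a FASTA file
#'
#' @param path FASTA with a single sequence covering the region.
#' @param start genomic position of the first base of the sequence.
#' @return an `ancestral_seq` lookup for [polarize_panel()].
#' @export
ancestral_from_fasta <- function(path, start) {
  fa <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE)
  structure(list(seq = toupper(as.character(fa[[1]])), start = as.integer(start)),
            class = "ancestral_seq")
}

ancestral_base <- function(anc, positions) {
  idx <- positions - anc$start + 1L
  out <- rep(NA_character_, length(positions))
  ok <- idx >= 1 & idx <= length(anc$seq)
  out[ok] <- anc$seq[idx[ok]]
  out
}

#' Polarize a panel to ancestral/derived states
#'
#' The ancestral allele is taken from the VCF `AA` tag stored per site, or
#' from an outgroup FASTA ([ancestral_from_fasta()]) which takes precedence
#' when given. Case-insensitive. Where the ancestral base equals the
#' alternate allele the matrix column is flipped so that 1 = derived; where
#' it matches neither allele (or is not A/C/G/T) the site is flagged
#' unpolarized. Polarizing twice with the same source is idempotent.
#'
#' @param panel a [hap_panel()].
#' @param ancestral optional `ancestral_seq`; default uses per-site `AA`.
#' @return the polarized [hap_panel()].
#' @export
polarize_panel <- function(panel, ancestral = NULL) {
  aa <- if (is.null(ancestral)) panel$sites$aa else ancestral_base(ancestral, panel$positions)
  aa <- toupper(aa)
  aa[!aa %in% c("A", "C", "G", "T")] <- NA_character_
  ref <- panel$sites$ref; alt <- panel$sites$alt
  flipped_now <- if (!is.null(panel$sites$flipped)) panel$sites$flipped else rep(FALSE, ncol(panel$mat))
  want_flip <- !is.na(aa) & aa == alt
  polarized <- !is.na(aa) & (aa == ref | aa == alt)
  toggle <- which(want_flip != flipped_now)
  if (length(toggle)) panel$mat[, toggle] <- 1L - panel$mat[, toggle]
  panel$sites$aa <- aa
  panel$sites$polarized <- polarized
  panel$sites$flipped <- want_flip
  panel$sites$derived_is_alt <- !want_flip
  panel
}

#' Classify sites by genic region
#'
#' Assigns each site exactly one of `upstream`, `intron`, `UTR`, `CDS`; CDS
#' sites get a coding offset, codon index and within-codon position, and, when
#' a reference coding sequence is supplied, a synonymous/nonsynonymous call
#' for the alternate allele.
#'
#' @param panel a [hap_panel()].
#' @param gene a [gene_model()].
#' @param cds_seq optional reference CDS as a character vector of bases in
#'   coding orientation (length `gene$cds_length`).
#' @return the panel with `region_class`, `cds_offset`, `codon_index`,
#'   `codon_pos` and `coding_effect` site columns filled.
#' @export
classify_sites <- function(panel, gene, cds_seq = NULL) {
  pos <- panel$positions
  cls <- rep("upstream", length(pos))
  in_gene <- pos >= gene$gene_start & pos <= gene$gene_end
  cls[in_gene] <- "intron"
  in_exon <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(gene$exons)))
    in_exon <- in_exon | (pos >= gene$exons[i, 1] & pos <= gene$exons[i, 2])
  cls[in_gene & in_exon] <- "UTR"
  off <- cds_offset(gene, pos)
  cls[!is.na(off)] <- "CDS"
  panel$sites$region_class <- cls
  panel$sites$cds_offset <- off
  panel$sites$codon_index <- ifelse(is.na(off), NA_integer_, (off - 1L) %/% 3L + 1L)
  panel$sites$codon_pos <- ifelse(is.na(off), NA_integer_, (off - 1L) %% 3L + 1L)
  eff <- rep(NA_character_, length(pos))
  eff[is.na(off)] <- "not-coding"
  if (!is.null(cds_seq)) {
    cds_seq <- toupper(cds_seq)
    for (s in which(!is.na(off))) {
      alt <- panel$sites$alt[s]
      if (gene$strand == "-") alt <- revcomp(alt)
      if (is.na(alt)) { eff[s] <- "unknown"; next }
      eff[s] <- classify_codon_effect(cds_seq, off[s], alt)
    }
  } else {
    eff[!is.na(off)] <- "unknown"
  }
  panel$sites$coding_effect <- eff
  panel
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", rev(strsplit(paste(rev(x), collapse = ""), "")[[1]]))[1]
}

#' Archaic allele panel
#'
#' @param positions genomic positions.
#' @param alleles character matrix, one row per archaic source (rownames are
#'   source labels), one column per position; `NA` or `"N"` = missing.
#' @return an `archaic_panel`.
#' @export
archaic_panel <- function(positions, alleles) {
  alleles <- as.matrix(alleles)
  if (ncol(alleles) != length(positions))
    stop("one allele column per position required")
  structure(list(positions = as.integer(positions),
                 alleles = toupper(alleles)), class = "archaic_panel")
}

#' Derived-allele sharing with archaic samples
#'
#' For every polarized panel site covered by the archaic panel, reports
#' whether each archaic source carries the modern derived allele. Missing
#' archaic data and unpolarized sites give `NA`.
#'
#' @param panel a polarized [hap_panel()].
#' @param archaic an [archaic_panel()].
#' @return data.frame with `position`, `source`, `shared_derived`.
#' @export
share_with_archaic <- function(panel, archaic) {
  idx <- match(panel$positions, archaic$positions)
  derived <- ifelse(panel$sites$flipped, panel$sites$ref, panel$sites$alt)
  out <- do.call(rbind, lapply(seq_len(nrow(archaic$alleles)), function(a) {
    al <- archaic$alleles[a, idx]
    shared <- ifelse(is.na(al) | al == "N" | !panel$sites$polarized | is.na(derived),
                     NA, al == derived)
    data.frame(position = panel$positions,
               source = rownames(archaic$alleles)[a],
               shared_derived = shared, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
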