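#' Synonymous/nonsynonymous classification of a coding change
#'
#' Translates the codon containing the site with all other positions at the
#' reference (ingroup-major) base and compares to the codon carrying
#' `alt_base`. Stop gain/loss counts as nonsynonymous.
#'
#' @param cds_seq reference coding sequence, character vector of bases (or a
#'   single string), length divisible by 3, in coding orientation.
#' @param site_offset 1-based offset of the site within the CDS.
#' @param alt_base alternative nucleotide.
#' @return `"synonymous"` or `"nonsynonymous"`.
#' @export
classify_codon_effect <- function(cds_seq, site_offset, alt_base) {
  if (length(cds_seq) == 1 && nchar(cds_seq) > 1)
    cds_seq <- strsplit(cds_seq, "")[[1]]
  cds_seq <- toupper(cds_seq)
  alt_base <- toupper(alt_base)
  if (!alt_base %in% c("A", "C", "G", "T")) stop("ambiguous alternate base")
  if (site_offset < 1 || site_offset > length(cds_seq))
    stop("site_offset outside the CDS")
  codon_i <- (site_offset - 1) %/% 3
  cpos <- (site_offset - 1) %% 3 + 1
  codon <- cds_seq[(codon_i * 3 + 1):(codon_i * 3 + 3)]
  if (!all(codon %in% c("A", "C", "G", "T"))) stop("ambiguous reference codon")
  mut <- codon
  mut[cpos] <- alt_base
  aa_ref <- seqinr::translate(codon)
  aa_mut <- seqinr::translate(mut)
  if (aa_ref == aa_mut) "synonymous" else "nonsynonymous"
}

#' McDonald-Kreitman site counts
#'
#' Counts replacement/silent polymorphic sites within the population slice
#' and replacement/silent fixed differences against an aligned outgroup CDS.
#' A site that is polymorphic within the population counts as polymorphic
#' only, even when the outgroup also differs. A fixed difference requires the
#' within-population base to be at 100% frequency and different from the
#' outgroup. Each change is classified against the codon background of the
#' ingroup reference sequence.
#'
#' @param panel a [hap_panel()] slice (one population) whose sites carry
#'   `cds_offset` (see [classify_sites()]); non-CDS sites are ignored.
#' @param ingroup_cds reference (ingroup) CDS, character vector of bases.
#' @param outgroup_cds aligned outgroup CDS, same length, no gaps.
#' @return list with counts `P_N`, `P_S`, `D_N`, `D_S` and the 2x2 `table`
#'   (rows: nonsynonymous/synonymous; columns: divergent/polymorphic).
#' @export
count_mk <- function(panel, ingroup_cds, outgroup_cds) {
  if (length(ingroup_cds) == 1 && nchar(ingroup_cds) > 1)
    ingroup_cds <- strsplit(ingroup_cds, "")[[1]]
  if (length(outgroup_cds) == 1 && nchar(outgroup_cds) > 1)
    outgroup_cds <- strsplit(outgroup_cds, "")[[1]]
  ingroup_cds <- toupper(ingroup_cds); outgroup_cds <- toupper(outgroup_cds)
  if (length(ingroup_cds) != length(outgroup_cds))
    stop("ingroup and outgroup CDS must be aligned (equal length)")
  if (length(ingroup_cds) %% 3 != 0) stop("CDS length not divisible by 3")
  off <- panel$sites$cds_offset
  if (is.null(off)) stop("panel sites lack cds_offset; run classify_sites() first")
  n <- nrow(panel$mat)
  P_N <- P_S <- 0L
  poly_offsets <- integer()
  for (s in which(!is.na(off))) {
    cnt <- sum(panel$mat[, s])
    if (cnt == 0 || cnt == n) next      # monomorphic in this population
    poly_offsets <- c(poly_offsets, off[s])
    # the segregating change at this site, classified on the ingroup background
    ref_base <- ingroup_cds[off[s]]
    alleles <- c(panel$sites$ref[s], panel$sites$alt[s])
    if (!is.null(panel$sites$flipped) && isTRUE(panel$sites$flipped[s]))
      alleles <- rev(alleles)
    # alleles[1] corresponds to matrix 0, alleles[2] to matrix 1
    other <- setdiff(alleles, ref_base)
    alt_base <- if (length(other)) other[1] else alleles[2]
    eff <- classify_codon_effect(ingroup_cds, off[s], alt_base)
    if (eff == "nonsynonymous") P_N <- P_N + 1L else P_S <- P_S + 1L
  }
  # fixed differences: outgroup mismatch at offsets not polymorphic here.
  # Sites where the population is fixed for a non-reference base are handled
  # by comparing that fixed base (not the reference) to the outgroup.
  fixed_base <- ingroup_cds
  for (s in which(!is.na(off))) {
    cnt <- sum(panel$mat[, s])
    if (cnt == n) {
      alleles <- c(panel$sites$ref[s], panel$sites$alt[s])
      if (!is.null(panel$sites$flipped) && isTRUE(panel$sites$flipped[s]))
        alleles <- rev(alleles)
      if (!is.na(alleles[2])) fixed_base[off[s]] <- alleles[2]
    }
  }
  D_N <- D_S <- 0L
  for (k in seq_along(fixed_base)) {
    if (k %in% poly_offsets) next
    if (fixed_base[k] == outgroup_cds[k]) next
    if (!outgroup_cds[k] %in% c("A", "C", "G", "T")) next
    eff <- classify_codon_effect(fixed_base, k, outgroup_cds[k])
    if (eff == "nonsynonymous") D_N <- D_N + 1L else D_S <- D_S + 1L
  }
  tab <- matrix(c(D_N, P_N, D_S, P_S), nrow = 2, byrow = TRUE,
                dimnames = list(c("nonsynonymous", "synonymous"),
                                c("divergent", "polymorphic")))
  list(P_N = P_N, P_S = P_S, D_N = D_N, D_S = D_S, table = tab)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the observed table's
#' probability (relative tie tolerance 1e-7). A table with an empty row or
#' column returns p = 1 by convention.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be nonnegative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    message("fisher_exact_2x2: degenerate margin, p = 1")
    return(1.0)
  }
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' McDonald-Kreitman test
#'
#' @param counts output of [count_mk()], or a 2x2 table (rows
#'   nonsynonymous/synonymous, columns divergent/polymorphic).
#' @return list with the table, the neutrality-index style ratios and the
#'   two-sided Fisher p-value.
#' @export
mk_test <- function(counts) {
  tab <- if (is.list(counts)) counts$table else as.matrix(counts)
  p <- fisher_exact_2x2(tab)
  list(table = tab, p_value = p)
}
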