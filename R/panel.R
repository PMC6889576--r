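#' Phased haplotype panel
#'
#' The central container of the package: a binary matrix of phased
#' chromosomes by segregating sites, with 1-based physical positions, a
#' population label per chromosome, and per-site metadata (alleles,
#' polarization state, genic region class).
#'
#' Matrix entries are 0/1. At polarized sites 0 is the ancestral and 1 the
#' derived allele; at unpolarized sites 0 is the reference and 1 the
#' alternate allele, and the site's `polarized` flag is `FALSE`.
#'
#' @param positions integer vector of strictly increasing 1-based positions.
#' @param mat binary matrix, chromosomes in rows, sites in columns.
#' @param pops character vector of population labels, one per chromosome.
#' @param sites optional data.frame of per-site metadata (one row per site);
#'   columns `ref`, `alt`, `aa` (ancestral allele), `polarized`,
#'   `region_class`, `coding_effect` are filled with defaults when missing.
#' @param chrom chromosome name.
#' @return an object of class `hap_panel`.
#' @export
hap_panel <- function(positions, mat, pops, sites = NULL, chrom = "chr6") {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  positions <- as.integer(positions)
  if (length(positions) != ncol(mat))
    stop("length(positions) must equal ncol(mat)")
  if (length(pops) != nrow(mat))
    stop("length(pops) must equal nrow(mat)")
  if (ncol(mat) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (length(mat) && !all(mat %in% c(0L, 1L)))
    stop("matrix entries must be 0/1")
  if (is.null(sites)) sites <- data.frame(row.names = seq_along(positions))
  n <- length(positions)
  defaults <- list(ref = rep(NA_character_, n), alt = rep(NA_character_, n),
                   aa = rep(NA_character_, n),
                   polarized = rep(TRUE, n),
                   flipped = rep(FALSE, n),
                   derived_is_alt = rep(TRUE, n),
                   region_class = rep(NA_character_, n),
                   coding_effect = rep(NA_character_, n))
  for (col in names(defaults))
    if (is.null(sites[[col]])) sites[[col]] <- defaults[[col]]
  sites$position <- positions
  structure(list(positions = positions, mat = mat,
                 pops = as.character(pops), sites = sites, chrom = chrom),
            class = "hap_panel")
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("hap_panel: %d chromosomes x %d sites (%s:%s-%s)\n",
              nrow(x$mat), ncol(x$mat), x$chrom,
              if (length(x$positions)) min(x$positions) else NA,
              if (length(x$positions)) max(x$positions) else NA))
  cat(sprintf("  populations: %s\n",
              paste(names(table(x$pops)), table(x$pops), sep = ":", collapse = " ")))
  cat(sprintf("  polarized sites: %d / %d\n",
              sum(x$sites$polarized), ncol(x$mat)))
  invisible(x)
}

#' Number of chromosomes and sites
#' @param panel a [hap_panel()].
#' @return integer.
#' @export
n_chrom <- function(panel) nrow(panel$mat)

#' @rdname n_chrom
#' @export
n_sites <- function(panel) ncol(panel$mat)

#' Restrict a panel to populations, an interval, or explicit sites
#'
#' @param panel a [hap_panel()].
#' @param pop population label(s) to keep (default: all).
#' @param interval length-2 numeric `c(start, end)`, 1-based closed.
#' @param sites integer or logical index of sites to keep.
#' @param drop_monomorphic drop sites that no longer segregate in the kept
#'   chromosomes.
#' @return a [hap_panel()].
#' @export
subset_panel <- function(panel, pop = NULL, interval = NULL, sites = NULL,
                         drop_monomorphic = FALSE) {
  keep_row <- if (is.null(pop)) rep(TRUE, nrow(panel$mat)) else panel$pops %in% pop
  if (!any(keep_row)) stop("no chromosomes left after population filter")
  keep_col <- rep(TRUE, ncol(panel$mat))
  if (!is.null(interval))
    keep_col <- keep_col & panel$positions >= interval[1] & panel$positions <= interval[2]
  if (!is.null(sites)) {
    sel <- rep(FALSE, ncol(panel$mat))
    sel[sites] <- TRUE
    keep_col <- keep_col & sel
  }
  mat <- panel$mat[keep_row, keep_col, drop = FALSE]
  if (drop_monomorphic && ncol(mat)) {
    cs <- colSums(mat)
    seg <- cs > 0 & cs < nrow(mat)
    mat <- mat[, seg, drop = FALSE]
    keep_col[keep_col] <- seg
  }
  hap_panel(panel$positions[keep_col], mat, panel$pops[keep_row],
            sites = panel$sites[keep_col, , drop = FALSE], chrom = panel$chrom)
}

#' Derived (or alternate) allele counts and frequencies
#' @param panel a [hap_panel()].
#' @return `derived_counts`: integer vector; `derived_freqs`: numeric vector.
#' @export
derived_counts <- function(panel) colSums(panel$mat)

#' @rdname derived_counts
#' @export
derived_freqs <- function(panel) colSums(panel$mat) / nrow(panel$mat)
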