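#' Weir-Cockerham per-site FST from allele counts
#'
#' Variance-component estimator for haploid (chromosome-level) samples:
#' with `r` groups, sample sizes `n_i` and allele frequencies `p_i`,
#' the among-group component is `a = (MSB - MSW)/nc` and the estimator is
#' `a / (a + MSW)`, where `MSB` and `MSW` are the between/within mean
#' squares of the 0/1 allele indicator and
#' `nc = (sum n_i - sum n_i^2 / sum n_i) / (r - 1)`.
#' The estimator is slightly negative in expectation at undifferentiated
#' sites. `NA` when the site is monomorphic across all groups.
#'
#' @param counts derived (or alt) allele count per group.
#' @param sizes chromosomes sampled per group.
#' @return list with components `a` (among), `w` (within), `fst`.
#' @export
wc_fst_site <- function(counts, sizes) {
  r <- length(counts)
  if (r < 2) stop("at least two groups required")
  if (any(sizes < 1)) stop("each group needs at least one chromosome")
  p <- counts / sizes
  ntot <- sum(sizes)
  pbar <- sum(counts) / ntot
  if (pbar <= 0 || pbar >= 1) return(list(a = NA_real_, w = NA_real_, fst = NA_real_))
  nc <- (ntot - sum(sizes^2) / ntot) / (r - 1)
  MSB <- sum(sizes * (p - pbar)^2) / (r - 1)
  MSW <- sum(sizes * p * (1 - p)) / (ntot - r)
  a <- (MSB - MSW) / nc
  list(a = a, w = MSW, fst = a / (a + MSW))
}

#' Per-site and mean FST over a panel
#'
#' @param panel a [hap_panel()].
#' @param groups named list mapping group name -> population labels, or a
#'   character vector of group labels (one per chromosome).
#' @return data.frame with `position`, per-group frequencies, `a`, `w`,
#'   `fst`.
#' @export
wc_fst <- function(panel, groups) {
  lab <- if (is.list(groups)) {
    g <- rep(NA_character_, nrow(panel$mat))
    for (nm in names(groups)) g[panel$pops %in% groups[[nm]]] <- nm
    g
  } else as.character(groups)
  keep <- !is.na(lab)
  mat <- panel$mat[keep, , drop = FALSE]
  lab <- lab[keep]
  gl <- sort(unique(lab))
  sizes <- vapply(gl, function(g) sum(lab == g), numeric(1))
  counts <- vapply(gl, function(g) colSums(mat[lab == g, , drop = FALSE]), numeric(ncol(mat)))
  if (ncol(mat) == 1) counts <- matrix(counts, nrow = 1)
  res <- t(apply(counts, 1, function(cc) {
    z <- wc_fst_site(cc, sizes)
    c(z$a, z$w, z$fst)
  }))
  freqs <- sweep(counts, 2, sizes, "/")
  colnames(freqs) <- paste0("freq_", gl)
  out <- data.frame(position = panel$positions, freqs,
                    a = res[, 1], w = res[, 2], fst = res[, 3])
  rownames(out) <- NULL
  out
}

#' Multi-locus FST summaries
#'
#' Reports both the ratio-of-sums ("weighted", `sum a / sum (a + w)`) and the
#' mean of per-site ratios ("mean"), over non-NA sites.
#'
#' @param fst_table output of [wc_fst()] (needs columns `a`, `w`, `fst`).
#' @return list with `weighted`, `mean`, `n_sites`.
#' @export
wc_fst_mean <- function(fst_table) {
  ok <- !is.na(fst_table$fst)
  if (!any(ok)) stop("no segregating site with a defined FST")
  list(weighted = sum(fst_table$a[ok]) / sum(fst_table$a[ok] + fst_table$w[ok]),
       mean = mean(fst_table$fst[ok]),
       n_sites = sum(ok))
}

#' Empirical percentile of a value in a background distribution
#'
#' Percentile computed with weak inequality: `100 * mean(background <=
#' value)`. Outlier flags at the lower 2.5% and upper 95% tails.
#'
#' @param value numeric scalar (or vector).
#' @param background numeric vector of genome-wide per-site values.
#' @param lower,upper outlier tail probabilities (defaults 2.5 and 95).
#' @return data.frame with `value`, `percentile`, `outlier_low`,
#'   `outlier_high`.
#' @export
empirical_percentile <- function(value, background, lower = 2.5, upper = 95) {
  if (!length(background)) stop("empty background distribution")
  pct <- vapply(value, function(v) 100 * mean(background <= v), numeric(1))
  data.frame(value = value, percentile = pct,
             outlier_low = pct <= lower, outlier_high = pct >= upper)
}
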