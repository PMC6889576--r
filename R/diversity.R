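#' Nucleotide diversity (theta-pi)
#'
#' Mean number of pairwise differences, on the region-total ("counts") scale
#' and per surveyed base pair:
#' `pi = sum_sites 2 i (n - i) / (n (n - 1))` with `i` the derived (or
#' minor, at unpolarized sites) allele count.
#'
#' @param panel a [hap_panel()] restricted to one population/interval.
#' @param L surveyed length in bp (for the per-site value); default spans the
#'   panel positions.
#' @return list with `counts` and `per_site`.
#' @export
theta_pi <- function(panel, L = NULL) {
  n <- nrow(panel$mat)
  if (n < 2) stop("at least 2 chromosomes required")
  if (is.null(L)) L <- diff(range(panel$positions)) + 1
  i <- colSums(panel$mat)
  counts <- sum(2 * i * (n - i) / (n * (n - 1)))
  list(counts = counts, per_site = counts / L)
}

#' Watterson's theta
#'
#' `theta_W = S / a1`, `a1 = sum_{i=1}^{n-1} 1/i`, on counts and per-site
#' scales.
#'
#' @param S number of segregating sites.
#' @param n number of chromosomes.
#' @param L surveyed length in bp.
#' @return list with `counts` and `per_site`.
#' @export
theta_w <- function(S, n, L) {
  if (n < 2) stop("at least 2 chromosomes required")
  a1 <- sum(1 / seq_len(n - 1))
  counts <- S / a1
  list(counts = counts, per_site = counts / L)
}

#' Tajima (1989) normalization constants
#' @param n number of chromosomes.
#' @return named list of a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

tajimas_d_from <- function(S, pi_counts, n) {
  if (S < 1) return(NA_real_)
  k <- tajima_constants(n)
  (pi_counts - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Tajima's D
#'
#' Computed on the counts scale from segregating sites within the panel
#' slice. `NA` when no site segregates.
#'
#' @param panel a [hap_panel()] restricted to one population/interval.
#' @return numeric scalar.
#' @export
tajimas_d <- function(panel) {
  n <- nrow(panel$mat)
  i <- colSums(panel$mat)
  seg <- i > 0 & i < n
  S <- sum(seg)
  pi_counts <- sum(2 * i[seg] * (n - i[seg]) / (n * (n - 1)))
  tajimas_d_from(S, pi_counts, n)
}

fay_wu_h_from <- function(i, n) {
  pi_counts <- sum(2 * i * (n - i) / (n * (n - 1)))
  thetaH <- sum(2 * i^2 / (n * (n - 1)))
  pi_counts - thetaH
}

#' Fay and Wu's H (unnormalized, counts scale)
#'
#' `H = pi - theta_H` with `theta_H = sum 2 i^2 / (n (n-1))` over derived
#' allele counts. Requires polarized sites; unpolarized segregating sites are
#' excluded with a message. `NA` when no polarized segregating site remains.
#'
#' @param panel a [hap_panel()] restricted to one population/interval.
#' @return numeric scalar.
#' @export
fay_wu_h <- function(panel) {
  n <- nrow(panel$mat)
  i <- colSums(panel$mat)
  seg <- i > 0 & i < n
  pol <- panel$sites$polarized
  skipped <- sum(seg & !pol)
  if (skipped > 0)
    message(sprintf("fay_wu_h: %d unpolarized segregating site(s) excluded", skipped))
  use <- seg & pol
  if (!any(use)) return(NA_real_)
  fay_wu_h_from(i[use], n)
}

#' Haplotype spectrum and diversity
#'
#' Distinct haplotype strings over all retained sites, with counts per
#' population and pooled, and Nei's haplotype diversity
#' `h_div = n/(n-1) (1 - sum p_k^2)`.
#'
#' @param panel a [hap_panel()].
#' @return list with `haplotypes` (data.frame: haplotype string, pooled count,
#'   one count column per population), `h` (number of distinct haplotypes) and
#'   `h_diversity`.
#' @export
haplotype_spectrum <- function(panel) {
  strs <- apply(panel$mat, 1, paste, collapse = "")
  if (ncol(panel$mat) == 0) strs <- rep("", nrow(panel$mat))
  n <- length(strs)
  tab <- table(strs)
  p <- as.numeric(tab) / n
  hd <- if (n > 1) n / (n - 1) * (1 - sum(p^2)) else 0
  df <- data.frame(haplotype = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  for (pp in unique(panel$pops)) {
    tp <- table(factor(strs[panel$pops == pp], levels = names(tab)))
    df[[pp]] <- as.integer(tp)
  }
  df <- df[order(-df$count, df$haplotype), ]
  rownames(df) <- NULL
  list(haplotypes = df, h = nrow(df), h_diversity = hd)
}

#' Minor allele frequency and common/rare class
#'
#' MAF is the frequency of the second most frequent allele; sites with
#' MAF >= `threshold` are `common`, below it `rare` (monomorphic sites have
#' MAF 0 and are `rare`).
#'
#' @param panel a [hap_panel()].
#' @param pop optional population restriction; default pooled.
#' @param threshold common/rare boundary (default 0.05; the boundary itself
#'   is common).
#' @return data.frame with `position`, `maf`, `class`.
#' @export
classify_maf <- function(panel, pop = NULL, threshold = 0.05) {
  sl <- if (is.null(pop)) panel else subset_panel(panel, pop = pop)
  f <- colSums(sl$mat) / nrow(sl$mat)
  maf <- pmin(f, 1 - f)
  data.frame(position = sl$positions, maf = maf,
             class = ifelse(maf >= threshold, "common", "rare"),
             stringsAsFactors = FALSE)
}

#' Singleton count
#'
#' Sites whose minor allele appears exactly once among the slice's
#' chromosomes.
#'
#' @param panel a [hap_panel()] slice.
#' @return integer.
#' @export
count_singletons <- function(panel) {
  n <- nrow(panel$mat)
  i <- colSums(panel$mat)
  sum(pmin(i, n - i) == 1)
}

#' Region-private and shared polymorphism counts (Venn cells)
#'
#' For each nonempty subset of geographic regions, counts the sites that
#' segregate in exactly the populations of those regions (after excluding
#' `exclusions`).
#'
#' @param panel a [hap_panel()].
#' @param region_groups named list mapping region name -> character vector of
#'   population labels.
#' @param exclusions populations to drop entirely (e.g. recently admixed
#'   ones).
#' @return data.frame with `regions` (comma-separated subset) and `count`;
#'   cells form a partition of the segregating sites among non-excluded
#'   populations.
#' @export
regional_sharing <- function(panel, region_groups, exclusions = character()) {
  groups <- lapply(region_groups, setdiff, y = exclusions)
  seg_in_region <- sapply(groups, function(pops) {
    keep <- panel$pops %in% pops
    if (!any(keep)) return(rep(FALSE, ncol(panel$mat)))
    cs <- colSums(panel$mat[keep, , drop = FALSE])
    cs > 0 & cs < sum(keep)
  })
  seg_any <- rowSums(seg_in_region) > 0
  key <- apply(seg_in_region, 1, function(z) paste(names(groups)[z], collapse = ","))
  tab <- table(key[seg_any])
  data.frame(regions = names(tab), count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Per-population summary table
#'
#' The per-population analog of a regional diversity table: chromosomes (2N),
#' segregating sites, singletons, distinct haplotypes and haplotype
#' diversity, theta-pi and theta-W per site, Tajima's D and Fay and Wu's H on
#' the counts scale.
#'
#' @param panel a [hap_panel()].
#' @param interval optional `c(start, end)` restriction.
#' @param L surveyed bp (default interval/panel span).
#' @return data.frame, one row per population.
#' @export
pop_summary_table <- function(panel, interval = NULL, L = NULL) {
  if (!is.null(interval)) panel <- subset_panel(panel, interval = interval)
  if (is.null(L)) L <- diff(range(panel$positions)) + 1
  pops <- unique(panel$pops)
  rows <- lapply(pops, function(pp) {
    sl <- subset_panel(panel, pop = pp)
    n <- nrow(sl$mat)
    i <- colSums(sl$mat)
    seg <- i > 0 & i < n
    slseg <- subset_panel(sl, drop_monomorphic = TRUE)
    S <- sum(seg)
    spec <- haplotype_spectrum(sl)
    data.frame(pop = pp, n2 = n, S = S,
               singletons = count_singletons(sl),
               h = spec$h, h_diversity = spec$h_diversity,
               theta_pi = theta_pi(sl, L = L)$per_site,
               theta_w = theta_w(S, n, L)$per_site,
               D_T = tajimas_d(sl),
               H = suppressMessages(fay_wu_h(slseg)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
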