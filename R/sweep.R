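#' Extended haplotype homozygosity from a core site
#'
#' For the chromosomes carrying `allele` at the core, EHH at a flanking site
#' is the probability that two random carriers are identical over all sites
#' between the core and that site (inclusive). EHH is 1 at the core and
#' non-increasing outward.
#'
#' @param panel a [hap_panel()] slice (one population).
#' @param core core site index (column) or position (`by = "position"`).
#' @param allele 0 (ancestral) or 1 (derived).
#' @param by interpret `core` as `"index"` or `"position"`.
#' @return list with `offsets` (signed bp relative to core), `ehh` (values at
#'   those offsets, not including the core itself), `core_position` and
#'   `n_carriers`. Sites beyond the point where EHH reaches 0 are omitted
#'   (EHH stays 0 there).
#' @export
ehh_curve <- function(panel, core, allele, by = c("index", "position")) {
  by <- match.arg(by)
  if (by == "position") core <- match(core, panel$positions)
  if (is.na(core) || core < 1 || core > ncol(panel$mat)) stop("core site not found")
  res <- cpp_ehh_curve(panel$mat, core, as.integer(allele))
  pos <- panel$positions
  nl <- length(res$left); nr <- length(res$right)
  off_l <- if (nl) pos[(core - 1):(core - nl)] - pos[core] else numeric(0)
  off_r <- if (nr) pos[(core + 1):(core + nr)] - pos[core] else numeric(0)
  list(offsets = c(rev(off_l), 0, off_r),
       ehh = c(rev(res$left), 1, res$right),
       core_position = pos[core], n_carriers = res$n_carriers)
}

# trapezoid integral of one EHH arm over physical distance.
# values: EHH at successive sites away from the core (core itself = 1);
# dists: |bp| from core, increasing. Integration stops once EHH < cutoff
# (the crossing trapezoid is included) or at a gap > max_gap (truncated).
integrate_arm <- function(values, dists, cutoff, max_gap) {
  ihh <- 0
  prev_v <- 1
  prev_d <- 0
  truncated <- TRUE           # stays TRUE if we run off the panel edge
  for (k in seq_along(values)) {
    gap <- dists[k] - prev_d
    if (gap > max_gap) { truncated <- TRUE; break }
    ihh <- ihh + 0.5 * (prev_v + values[k]) * gap
    prev_v <- values[k]; prev_d <- dists[k]
    if (values[k] < cutoff) { truncated <- FALSE; break }
    truncated <- TRUE
  }
  if (length(values) == 0) truncated <- TRUE
  list(ihh = ihh, truncated = truncated)
}

#' Unstandardized iHS at one core site
#'
#' Integrates the EHH curve of each core-allele class over physical distance
#' (trapezoid rule, both directions, stopping where EHH drops below
#' `cutoff`); the score is `ln(iHH_A / iHH_D)`. Negative scores mean longer
#' haplotypes around the derived allele.
#'
#' @param panel a polarized [hap_panel()] slice.
#' @param core core site index.
#' @param cutoff EHH integration cutoff (default 0.05).
#' @param max_gap maximum allowed inter-site gap in bp (default 200000);
#'   larger gaps truncate the integral.
#' @return list with `ihh_a`, `ihh_d`, `score`, `truncated`, `freq_derived`.
#' @export
ihs_core <- function(panel, core, cutoff = 0.05, max_gap = 200000) {
  f <- sum(panel$mat[, core]) / nrow(panel$mat)
  arms <- lapply(c(0L, 1L), function(al) {
    res <- cpp_ehh_curve(panel$mat, core, al)
    pos <- panel$positions
    nl <- length(res$left); nr <- length(res$right)
    dl <- if (nl) pos[core] - pos[(core - 1):(core - nl)] else numeric(0)
    dr <- if (nr) pos[(core + 1):(core + nr)] - pos[core] else numeric(0)
    left <- integrate_arm(res$left, dl, cutoff, max_gap)
    right <- integrate_arm(res$right, dr, cutoff, max_gap)
    list(ihh = left$ihh + right$ihh, truncated = left$truncated || right$truncated)
  })
  ihh_a <- arms[[1]]$ihh; ihh_d <- arms[[2]]$ihh
  score <- if (ihh_d <= 0 || ihh_a <= 0) NA_real_ else log(ihh_a / ihh_d)
  list(ihh_a = ihh_a, ihh_d = ihh_d, score = score,
       truncated = arms[[1]]$truncated || arms[[2]]$truncated,
       freq_derived = f)
}

#' Unstandardized nSL at one core site
#'
#' For each pair of chromosomes within an allele class, the shared tract
#' length L is the number of consecutive sites (including the core) over
#' which the pair is identical; `SL` is the mean over pairs and the score is
#' `ln(SL_A / SL_D)`. Distances are counted in segregating sites, so the
#' statistic does not use the recombination map.
#'
#' @param panel a polarized [hap_panel()] slice.
#' @param core core site index.
#' @return list with `sl_a`, `sl_d`, `score`, `freq_derived`.
#' @export
nsl_core <- function(panel, core) {
  n <- nrow(panel$mat)
  cnt <- sum(panel$mat[, core])
  f <- cnt / n
  sl <- vapply(c(0L, 1L), function(al) {
    k <- if (al == 1L) cnt else n - cnt
    if (k < 2) return(NA_real_)
    res <- cpp_ehh_curve(panel$mat, core, al)
    # mean pairwise tract length = 1 + sum of per-step pair-identity
    # probabilities in each direction (truncated at the panel edge)
    1 + sum(res$left) + sum(res$right)
  }, numeric(1))
  score <- if (any(is.na(sl)) || any(sl <= 0)) NA_real_ else log(sl[1] / sl[2])
  list(sl_a = sl[1], sl_d = sl[2], score = score, freq_derived = f)
}

#' Haplotype-length scan over all eligible cores
#'
#' Computes unstandardized iHS or nSL at every polarized site whose derived
#' allele frequency lies within `[maf_min, 1 - maf_min]`.
#'
#' @param panel a polarized [hap_panel()] slice (one population).
#' @param stat `"ihs"` or `"nsl"`.
#' @param maf_min derived-frequency band edge for eligible cores (default
#'   0.05).
#' @param cutoff,max_gap see [ihs_core()].
#' @param drop_truncated drop cores whose integral hit the panel edge or a
#'   gap (default TRUE; they are retained with `truncated = TRUE` otherwise).
#' @return data.frame with `position`, `freq_derived`, `score` and, for iHS,
#'   `ihh_a`, `ihh_d`, `truncated`.
#' @export
scan_scores <- function(panel, stat = c("ihs", "nsl"), maf_min = 0.05,
                        cutoff = 0.05, max_gap = 200000,
                        drop_truncated = TRUE) {
  stat <- match.arg(stat)
  n <- nrow(panel$mat)
  cnt <- colSums(panel$mat)
  f <- cnt / n
  # both allele classes need >= 2 carriers for an EHH curve
  eligible <- which(f >= maf_min & f <= 1 - maf_min & panel$sites$polarized &
                      cnt >= 2 & n - cnt >= 2)
  rows <- lapply(eligible, function(core) {
    if (stat == "ihs") {
      r <- ihs_core(panel, core, cutoff = cutoff, max_gap = max_gap)
      data.frame(position = panel$positions[core], freq_derived = r$freq_derived,
                 score = r$score, ihh_a = r$ihh_a, ihh_d = r$ihh_d,
                 truncated = r$truncated)
    } else {
      r <- nsl_core(panel, core)
      data.frame(position = panel$positions[core], freq_derived = r$freq_derived,
                 score = r$score, truncated = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(position = integer(),
                                      freq_derived = numeric(),
                                      score = numeric(), truncated = logical()))
  if (drop_truncated && stat == "ihs") out <- out[!out$truncated, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardize scan scores within derived-frequency bins
#'
#' Scores are binned by derived allele frequency into `n_bins` equal-width
#' bins; adjacent bins are merged left-to-right until each holds at least
#' `min_per_bin` scores; within each merged bin the mean is subtracted and
#' the standard deviation divided out.
#'
#' @param score numeric vector of unstandardized scores (NA allowed).
#' @param freq_derived matching derived allele frequencies.
#' @param n_bins number of equal-width frequency bins (default 100).
#' @param min_per_bin minimum scores per merged bin (default 20).
#' @return numeric vector of standardized scores (NA where the input was NA
#'   or the bin was degenerate).
#' @export
standardize_scores <- function(score, freq_derived, n_bins = 100,
                               min_per_bin = 20) {
  ok <- !is.na(score)
  out <- rep(NA_real_, length(score))
  if (!any(ok)) return(out)
  bin <- pmin(pmax(ceiling(freq_derived[ok] * n_bins), 1L), n_bins)
  # merge adjacent bins until each occupied group has >= min_per_bin
  counts <- tabulate(bin, nbins = n_bins)
  group <- integer(n_bins)
  g <- 1L; acc <- 0L
  for (b in seq_len(n_bins)) {
    group[b] <- g
    acc <- acc + counts[b]
    if (acc >= min_per_bin) { g <- g + 1L; acc <- 0L }
  }
  if (acc > 0 && g > 1L) group[group == g] <- g - 1L  # fold leftover tail back
  gb <- group[bin]
  z <- rep(NA_real_, sum(ok))
  for (gg in unique(gb)) {
    sel <- gb == gg
    m <- mean(score[ok][sel])
    s <- stats::sd(score[ok][sel])
    if (sum(sel) >= 2 && !is.na(s) && s > 0) z[sel] <- (score[ok][sel] - m) / s
  }
  out[ok] <- z
  out
}

#' Flag outlier standardized scores
#'
#' @param std standardized scores.
#' @param threshold absolute-value threshold (default 2, strict `>`).
#' @return logical vector (`NA` where `std` is `NA`).
#' @export
call_outliers <- function(std, threshold = 2) {
  abs(std) > threshold
}
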