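#' Pairwise D' and LOD from phased two-site haplotype counts
#'
#' `D = p_AB - p_A p_B` from phased gamete frequencies;
#' `D' = D / Dmax` with the usual frequency-dependent bound, and
#' `LOD = sum_g n_g log10(f_g(Dhat) / f_g(0))` over the four gamete classes
#' (likelihood of the estimated LD against independence).
#'
#' @param n_ab integer vector of the four gamete counts `(AB, Ab, aB, ab)`,
#'   where `A`/`B` denote the allele coded 1 at each site.
#' @return list with `D`, `D_prime` (absolute, in `[0,1]`) and `LOD`.
#' @export
d_prime <- function(n_ab) {
  if (length(n_ab) != 4) stop("four gamete counts required")
  n <- sum(n_ab)
  f <- n_ab / n
  pA <- f[1] + f[2]
  pB <- f[1] + f[3]
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) stop("monomorphic site in pair")
  D <- f[1] - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else       min(pA * pB, (1 - pA) * (1 - pB))
  Dp <- if (D == 0) 0 else abs(D) / Dmax
  f_hat <- c(pA * pB + D, pA * (1 - pB) - D, (1 - pA) * pB - D,
             (1 - pA) * (1 - pB) + D)
  f_0 <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  use <- n_ab > 0
  LOD <- sum(n_ab[use] * log10(f_hat[use] / f_0[use]))
  list(D = unname(D), D_prime = unname(min(Dp, 1)), LOD = unname(LOD))
}

gamete_counts <- function(x, y) {
  c(sum(x == 1 & y == 1), sum(x == 1 & y == 0),
    sum(x == 0 & y == 1), sum(x == 0 & y == 0))
}

#' Pairwise LD matrix over one or two windows
#'
#' All within-window (and, with `window2`, between-window) site pairs for one
#' population, after a minor-allele-frequency filter. Emitted in long format
#' with `Dprime_x100` rounded to integer as in the conventional LD-plot
#' annotation.
#'
#' @param panel a [hap_panel()].
#' @param pop population label(s); default all chromosomes.
#' @param window `c(start, end)`; default the panel span.
#' @param window2 optional second window for between-window pairs.
#' @param maf_min minimum within-population MAF (default 0.01; sites below
#'   are excluded).
#' @return data.frame with `pos_a`, `pos_b`, `D`, `D_prime`, `Dprime_x100`,
#'   `LOD`; symmetric pairs are listed once with `pos_a < pos_b`.
#' @export
ld_matrix <- function(panel, pop = NULL, window = NULL, window2 = NULL,
                      maf_min = 0.01) {
  sl <- subset_panel(panel, pop = pop)
  pick_window <- function(w) {
    if (is.null(w)) w <- range(sl$positions)
    idx <- which(sl$positions >= w[1] & sl$positions <= w[2])
    f <- colSums(sl$mat[, idx, drop = FALSE]) / nrow(sl$mat)
    idx[pmin(f, 1 - f) >= maf_min]
  }
  i1 <- pick_window(window)
  pairs <- if (is.null(window2)) {
    if (length(i1) < 2) NULL else t(utils::combn(i1, 2))
  } else {
    i2 <- pick_window(window2)
    if (!length(i1) || !length(i2)) NULL else as.matrix(expand.grid(i1, i2))
  }
  if (is.null(pairs) || !nrow(pairs)) {
    warning("no site pairs left after MAF filter")
    return(data.frame(pos_a = integer(), pos_b = integer(), D = numeric(),
                      D_prime = numeric(), Dprime_x100 = integer(),
                      LOD = numeric()))
  }
  res <- apply(pairs, 1, function(pr) {
    g <- gamete_counts(sl$mat[, pr[1]], sl$mat[, pr[2]])
    ld <- d_prime(g)
    c(sl$positions[pr[1]], sl$positions[pr[2]], ld$D, ld$D_prime, ld$LOD)
  })
  out <- data.frame(pos_a = pmin(res[1, ], res[2, ]),
                    pos_b = pmax(res[1, ], res[2, ]),
                    D = res[3, ], D_prime = res[4, ],
                    Dprime_x100 = as.integer(round(res[4, ] * 100)),
                    LOD = res[5, ])
  out[order(out$pos_a, out$pos_b), ]
}
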