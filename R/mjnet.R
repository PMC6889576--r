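# Median-joining haplotype networks over binary characters.
#
# The network is grown from the observed haplotypes by repeatedly proposing
# majority-consensus (median) vectors of triples that are mutually linked in
# the current minimum-spanning network and inserting the median that most
# reduces the minimum-spanning-tree cost of the node set (lexicographic
# tie-breaks so output is order-invariant). Unobserved medians of degree < 3
# are pruned afterwards.

hamming_matrix <- function(mat) {
  # rows = haplotypes (0/1)
  m <- as.matrix(mat)
  tc <- tcrossprod(m)
  ones <- rowSums(m)
  outer(ones, ones, "+") - 2 * tc
}

mst_cost <- function(d) {
  # Prim; d: symmetric distance matrix
  n <- nrow(d)
  if (n <= 1) return(0)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  cost <- 0
  for (k in seq_len(n - 1)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best[cand])]
    cost <- cost + best[v]
    in_tree[v] <- TRUE
    best <- pmin(best, d[v, ])
  }
  cost
}

# minimum-spanning network at tolerance eps: edge {u,v} is kept iff u and v
# are not already connected using only edges shorter than d(u,v) - eps
# (eps = 0 gives the union of all minimum spanning trees).
msn_edges <- function(d, eps = 0) {
  n <- nrow(d)
  if (n <= 1) return(matrix(numeric(0), ncol = 3,
                            dimnames = list(NULL, c("a", "b", "w"))))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[pairs]
  ord <- order(w, pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]; w <- w[ord]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  keep <- logical(length(w))
  k <- 1
  while (k <= length(w)) {
    # process one weight level at a time against components of strictly
    # smaller weight (minus eps)
    lvl <- w[k]
    idx <- which(w >= lvl - 1e-9 & w <= lvl + 1e-9)
    idx <- idx[idx >= k]
    comp_snapshot <- vapply(seq_len(n), find, integer(1))
    for (e in idx) {
      a <- pairs[e, 1]; b <- pairs[e, 2]
      if (eps > 0) {
        # connectivity using edges < lvl - eps: recompute
        par2 <- seq_len(n)
        f2 <- function(x) { while (par2[x] != x) { par2[x] <<- par2[par2[x]]; x <- par2[x] }; x }
        sel <- which(keep & w < lvl - eps)
        for (e2 in sel) {
          ra <- f2(pairs[e2, 1]); rb <- f2(pairs[e2, 2])
          if (ra != rb) par2[ra] <- rb
        }
        keep[e] <- f2(a) != f2(b)
      } else {
        keep[e] <- comp_snapshot[a] != comp_snapshot[b]
      }
    }
    for (e in idx) {
      if (keep[e]) {
        ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
        if (ra != rb) parent[ra] <- rb
      }
    }
    k <- max(idx) + 1
  }
  cbind(a = pairs[keep, 1], b = pairs[keep, 2], w = w[keep])
}

majority_median <- function(u, v, w) {
  s <- u + v + w
  as.integer(s >= 2)
}

#' Median-joining haplotype network
#'
#' Builds a haplotype network over binary characters: starting from the
#' distinct observed haplotypes, candidate median (majority-consensus)
#' vectors of linked triples are inserted while they reduce the total
#' minimum-spanning-tree cost; the final network is the minimum-spanning
#' network over the augmented node set, with unobserved degree-< 3 medians
#' pruned. Ties are broken by lexicographic haplotype order, so the result
#' does not depend on input order.
#'
#' @param mat binary matrix of haplotypes (rows; duplicates allowed — they
#'   collapse into one node) or a [haplotype_spectrum()] result.
#' @param groups optional group label per input row (for node frequency
#'   vectors).
#' @param eps tolerance parameter of the minimum-spanning network (default
#'   0 = most parsimonious).
#' @param max_medians cap on inserted median vectors.
#' @return a `haplo_network`: list with `nodes` (data.frame: id, haplotype
#'   string, observed, count, per-group counts), `edges` (data.frame: a, b,
#'   weight), and `total_cost` (sum of edge weights).
#' @export
median_joining <- function(mat, groups = NULL, eps = 0, max_medians = 64) {
  if (is.list(mat) && !is.null(mat$haplotypes)) {
    df <- mat$haplotypes
    hapmat <- do.call(rbind, lapply(strsplit(df$haplotype, ""), as.integer))
    counts <- df$count
    grp_counts <- df[, setdiff(colnames(df), c("haplotype", "count")), drop = FALSE]
  } else {
    mat <- as.matrix(mat)
    if (!all(mat %in% c(0, 1))) stop("characters must be binary (0/1)")
    strs <- apply(mat, 1, paste, collapse = "")
    uniq <- sort(unique(strs))
    hapmat <- do.call(rbind, lapply(strsplit(uniq, ""), as.integer))
    counts <- as.integer(table(factor(strs, levels = uniq)))
    grp_counts <- NULL
    if (!is.null(groups)) {
      grp_counts <- as.data.frame.matrix(table(factor(strs, levels = uniq), groups))
    }
  }
  n_obs <- nrow(hapmat)
  observed <- rep(TRUE, n_obs)
  nodes <- hapmat
  repeat {
    d <- hamming_matrix(nodes)
    base_cost <- mst_cost(d)
    ed <- msn_edges(d, eps)
    if (!nrow(ed)) break
    # linked triples: two links sharing a node
    adj <- lapply(seq_len(nrow(nodes)), function(i) {
      c(ed[ed[, "a"] == i, "b"], ed[ed[, "b"] == i, "a"])
    })
    cand <- list()
    for (u in seq_len(nrow(nodes))) {
      nb <- adj[[u]]
      if (length(nb) < 2) next
      cmb <- utils::combn(nb, 2)
      for (q in seq_len(ncol(cmb))) {
        m <- majority_median(nodes[u, ], nodes[cmb[1, q], ], nodes[cmb[2, q], ])
        cand[[length(cand) + 1L]] <- m
      }
    }
    if (!length(cand)) break
    cmat <- unique(do.call(rbind, cand))
    strs_nodes <- apply(nodes, 1, paste, collapse = "")
    strs_cand <- apply(cmat, 1, paste, collapse = "")
    new <- !(strs_cand %in% strs_nodes)
    cmat <- cmat[new, , drop = FALSE]
    strs_cand <- strs_cand[new]
    if (!nrow(cmat)) break
    ord <- order(strs_cand)
    cmat <- cmat[ord, , drop = FALSE]
    reductions <- vapply(seq_len(nrow(cmat)), function(q) {
      base_cost - mst_cost(hamming_matrix(rbind(nodes, cmat[q, ])))
    }, numeric(1))
    best <- which.max(reductions)        # first max = lexicographically least
    if (reductions[best] <= 0) break
    nodes <- rbind(nodes, cmat[best, ])
    observed <- c(observed, FALSE)
    if (sum(!observed) >= max_medians) break
  }
  # final network + pruning of unobserved low-degree medians
  repeat {
    d <- hamming_matrix(nodes)
    ed <- msn_edges(d, eps)
    deg <- tabulate(c(ed[, "a"], ed[, "b"]), nbins = nrow(nodes))
    drop <- which(!observed & deg < 3)
    if (!length(drop)) break
    nodes <- nodes[-drop, , drop = FALSE]
    observed <- observed[-drop]
  }
  strs <- apply(nodes, 1, paste, collapse = "")
  node_df <- data.frame(id = seq_along(strs), haplotype = strs,
                        observed = observed,
                        count = 0L, stringsAsFactors = FALSE)
  obs_strs <- apply(hapmat, 1, paste, collapse = "")
  idx <- match(obs_strs, strs)
  node_df$count[idx] <- counts
  if (!is.null(grp_counts)) {
    for (gname in colnames(grp_counts)) {
      col <- integer(nrow(node_df))
      col[idx] <- grp_counts[[gname]]
      node_df[[gname]] <- col
    }
  }
  edge_df <- data.frame(a = as.integer(ed[, "a"]), b = as.integer(ed[, "b"]),
                        weight = ed[, "w"])
  structure(list(nodes = node_df, edges = edge_df,
                 total_cost = sum(edge_df$weight)),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("haplo_network: %d nodes (%d observed), %d edges, total cost %g\n",
              nrow(x$nodes), sum(x$nodes$observed), nrow(x$edges), x$total_cost))
  invisible(x)
}

#' Node frequency table and cycle summary of a network
#'
#' @param network a `haplo_network` from [median_joining()].
#' @return list with the `nodes` table, `n_components` and `reticulations`
#'   (independent cycles, `edges - nodes + components`).
#' @export
cluster_report <- function(network) {
  n <- nrow(network$nodes)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (e in seq_len(nrow(network$edges))) {
    ra <- find(network$edges$a[e]); rb <- find(network$edges$b[e])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(seq_len(n), find, integer(1))
  ncomp <- length(unique(comp))
  list(nodes = cbind(network$nodes, component = match(comp, unique(comp))),
       n_components = ncomp,
       reticulations = nrow(network$edges) - n + ncomp)
}
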