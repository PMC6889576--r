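#' Piecewise demographic model
#'
#' Epochs run backward from the present; epoch `j` covers
#' `[t0_j, t0_{j+1})` generations before present with diploid size
#' `N(t) = N0_j * exp(-g_j (t - t0_j))`, so `g_j > 0` is growth toward the
#' present within the epoch. The final (oldest) epoch must be constant.
#'
#' @param t0 epoch start times (generations before present), first must be 0,
#'   strictly increasing.
#' @param N0 diploid size at each epoch start.
#' @param g per-generation growth rate within each epoch (0 = constant).
#' @param generation_time years per generation (default 20).
#' @return a `demographic_model`.
#' @export
demographic_model <- function(t0, N0, g = rep(0, length(t0)),
                              generation_time = 20) {
  if (t0[1] != 0) stop("first epoch must start at time 0")
  if (length(t0) > 1 && any(diff(t0) <= 0)) stop("epoch times must increase")
  if (any(N0 <= 0)) stop("population sizes must be positive")
  if (g[length(g)] != 0) stop("the oldest epoch must have zero growth")
  structure(list(epochs = cbind(t0 = t0, N0 = N0, g = g),
                 generation_time = generation_time),
            class = "demographic_model")
}

#' @rdname demographic_model
#' @param N constant diploid size.
#' @export
constant_model <- function(N, generation_time = 20) {
  demographic_model(0, N, 0, generation_time)
}

#' Demographic scenario families for neutrality-test calibration
#'
#' Two families of single-population histories:
#' * `african`: exponential growth to `fold` times a base size of 10,000
#'   diploids, starting 70,000 years ago (folds 2, 4, 6, 8, 10);
#' * `ooa` (out-of-Africa): a bottleneck at 60,000 years ago from 10,000 to
#'   2,000 diploids, followed by exponential growth to `fold` times 2,000
#'   starting 50,000 years ago (folds 10, 20, 40).
#'
#' Growth over `[0, T]` is exponential, reaching `fold` times the pre-growth
#' size at present. Generation time 20 years.
#'
#' @param family `"african"`, `"ooa"` or `"constant"`.
#' @param fold growth fold for the family (see above).
#' @param N base size for `"constant"` (default 10,000).
#' @return a [demographic_model()].
#' @export
scenario_model <- function(family = c("african", "ooa", "constant"),
                           fold = NULL, N = 10000) {
  family <- match.arg(family)
  gen <- 20
  if (family == "constant") return(constant_model(N, gen))
  if (family == "african") {
    if (is.null(fold)) fold <- 4
    stopifnot(fold %in% c(2, 4, 6, 8, 10))
    Tg <- 70000 / gen
    g <- log(fold) / Tg
    demographic_model(t0 = c(0, Tg), N0 = c(10000 * fold, 10000),
                      g = c(g, 0), generation_time = gen)
  } else {
    if (is.null(fold)) fold <- 20
    stopifnot(fold %in% c(10, 20, 40))
    Tg <- 50000 / gen            # growth onset
    Tb <- 60000 / gen            # bottleneck start
    g <- log(fold) / Tg
    demographic_model(t0 = c(0, Tg, Tb), N0 = c(2000 * fold, 2000, 10000),
                      g = c(g, 0, 0), generation_time = gen)
  }
}

#' All scenario-family members
#' @return named list of [demographic_model()]s (african 2-10x, ooa 10-40x).
#' @export
scenario_family <- function() {
  out <- list()
  for (f in c(2, 4, 6, 8, 10))
    out[[sprintf("african_%dx", f)]] <- scenario_model("african", f)
  for (f in c(10, 20, 40))
    out[[sprintf("ooa_%dx", f)]] <- scenario_model("ooa", f)
  out
}

mu_from_theta <- function(theta, model) {
  # theta = 4 * N_present * mu_region (ms convention, present-day size)
  theta / (4 * model$epochs[1, "N0"])
}

#' Neutral coalescent summary statistics
#'
#' Simulates `reps` genealogies of `n` chromosomes under `model` with
#' region-scaled mutation rate `theta` (per region, `4 N_present mu L`) and
#' returns per-replicate S, theta-pi, Tajima's D, Fay and Wu's H (counts
#' scale), singletons and TMRCA (generations).
#'
#' @param n chromosomes.
#' @param theta region-scaled mutation rate.
#' @param model a [demographic_model()].
#' @param reps replicates.
#' @param seed optional integer seed.
#' @return data.frame with columns `S`, `pi`, `D`, `H`, `singletons`,
#'   `tmrca_gens`.
#' @export
coal_stats <- function(n, theta, model, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  raw <- cpp_coal_stats(n, mu_from_theta(theta, model), model$epochs, reps)
  S <- raw[, "S"]; pi <- raw[, "pi"]; thetaH <- raw[, "thetaH"]
  k <- tajima_constants(n)
  D <- ifelse(S >= 1, (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1)), NA)
  H <- ifelse(S >= 1, pi - thetaH, NA)
  data.frame(S = S, pi = pi, D = D, H = H,
             singletons = raw[, "singletons"], tmrca_gens = raw[, "tmrca"])
}

#' Simulate one neutral coalescent panel
#'
#' @inheritParams coal_stats
#' @param L region length in bp (positions uniform on 1..L).
#' @param n_archaic optional archaic chromosomes from a lineage splitting
#'   `archaic_split_gens` generations ago (constant archaic size =
#'   modern size at the split).
#' @param archaic_split_gens split time in generations.
#' @param seed optional integer seed.
#' @return list with a [hap_panel()] (`panel`), the archaic allele matrix
#'   rows when requested (`archaic_mat`), mutation ages in generations
#'   (`age_gens`), `tmrca_gens` and `S`.
#' @export
coal_panel <- function(n, theta, model, L, n_archaic = 0,
                       archaic_split_gens = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N_arch <- size_at(model, archaic_split_gens)
  raw <- cpp_coal_panel(n, n_archaic, archaic_split_gens, N_arch,
                        mu_from_theta(theta, model), model$epochs, as.integer(L))
  mat <- raw$mat
  modern <- mat[seq_len(n), , drop = FALSE]
  panel <- hap_panel(raw$positions, modern, rep("POP1", n))
  list(panel = panel,
       archaic_mat = if (n_archaic > 0) mat[n + seq_len(n_archaic), , drop = FALSE] else NULL,
       age_gens = raw$age_gens, tmrca_gens = raw$tmrca_gens, S = raw$S)
}

size_at <- function(model, t) {
  e <- model$epochs
  j <- max(which(e[, "t0"] <= t))
  e[j, "N0"] * exp(-e[j, "g"] * (t - e[j, "t0"]))
}

#' Simulation-based p-value for a neutrality statistic
#'
#' Compares an observed Tajima's D or Fay-Wu H to its null distribution under
#' a demographic model, with the add-one convention
#' `P_upper = (1 + #{sim >= obs}) / (reps + 1)`. Replicates with S = 0 (the
#' statistic undefined) are resampled until `reps` valid replicates are
#' available.
#'
#' @param observed observed statistic (counts scale).
#' @param stat `"D"` or `"H"`.
#' @param n chromosomes.
#' @param theta region-scaled mutation rate for the null.
#' @param model a [demographic_model()].
#' @param reps valid null replicates (default 10000).
#' @param tail `"upper"`, `"lower"` or `"two-sided"`.
#' @param seed optional integer seed.
#' @return list with `p_value`, `tail`, `null_mean`, `null_sd`, `reps`,
#'   `n_resampled`.
#' @export
null_pvalue <- function(observed, stat = c("D", "H"), n, theta, model,
                        reps = 10000, tail = c("upper", "lower", "two-sided"),
                        seed = NULL) {
  stat <- match.arg(stat)
  tail <- match.arg(tail)
  if (reps < 100) warning("fewer than 100 null replicates")
  if (!is.null(seed)) set.seed(seed)
  vals <- numeric(0)
  n_invalid <- 0
  while (length(vals) < reps) {
    need <- reps - length(vals)
    batch <- coal_stats(n, theta, model, ceiling(need * 1.05) + 10)
    v <- batch[[stat]]
    n_invalid <- n_invalid + sum(is.na(v))
    vals <- c(vals, v[!is.na(v)])
  }
  vals <- vals[seq_len(reps)]
  p_up <- (1 + sum(vals >= observed)) / (reps + 1)
  p_lo <- (1 + sum(vals <= observed)) / (reps + 1)
  p <- switch(tail, upper = p_up, lower = p_lo,
              `two-sided` = min(1, 2 * min(p_up, p_lo)))
  list(p_value = p, tail = tail, null_mean = mean(vals), null_sd = sd(vals),
       reps = reps, n_resampled = n_invalid)
}

#' Monte-Carlo allele age for a derived allele at count i of n
#'
#' Simulates genealogies under `model`; in each, branches subtending exactly
#' `i` tips receive a uniform age draw weighted by branch length. With
#' `weighting = "pooled"` (default) branches are pooled across genealogies
#' with length weights, which conditions genealogies on carrying a count-i
#' mutation and is the consistent estimator of the age of an observed
#' variant; `"per_genealogy"` instead averages each genealogy's
#' length-weighted mean age unweighted across genealogies.
#'
#' @param i derived allele count (1..n-1).
#' @param n sample size (chromosomes).
#' @param model a [demographic_model()].
#' @param reps simulated genealogies (default 100000).
#' @param weighting `"pooled"` (default; the frequency-conditioned
#'   estimator, which matches the Kimura-Ota age curve at large n) or
#'   `"per_genealogy"`.
#' @param seed optional integer seed.
#' @return list with `mean_years`, `sd_years`, `mean_gens`, `n_used`.
#' @export
allele_age_mc <- function(i, n, model, reps = 100000,
                          weighting = c("pooled", "per_genealogy"),
                          seed = NULL) {
  weighting <- match.arg(weighting)
  if (i < 1 || i > n - 1) stop("i must be in 1..n-1")
  if (!is.null(seed)) set.seed(seed)
  out <- cpp_coal_ages(n, i, model$epochs, reps)
  w <- out[, "w"]; a <- out[, "age"]
  ok <- w > 0
  if (!any(ok)) stop("no genealogy carried a branch subtending exactly i tips")
  if (weighting == "per_genealogy") {
    ages <- a[ok]
    m <- mean(ages); s <- sd(ages)
  } else {
    m <- sum(w[ok] * a[ok]) / sum(w[ok])
    s <- sqrt(sum(w[ok] * (a[ok] - m)^2) / sum(w[ok]))
  }
  gt <- model$generation_time
  list(mean_years = m * gt, sd_years = s * gt, mean_gens = m,
       n_used = sum(ok))
}

#' Expected TMRCA of a sample
#'
#' Analytic `4N(1 - 1/n)` generations for a constant-size model; Monte-Carlo
#' mean otherwise.
#'
#' @param n chromosomes.
#' @param model a [demographic_model()].
#' @param reps Monte-Carlo replicates for non-constant models.
#' @param seed optional integer seed.
#' @return list with `gens`, `years`, `method`.
#' @export
tmrca_expectation <- function(n, model, reps = 20000, seed = NULL) {
  constant <- nrow(model$epochs) == 1 && model$epochs[1, "g"] == 0
  if (constant) {
    g <- 4 * unname(model$epochs[1, "N0"]) * (1 - 1 / n)
    return(list(gens = g, years = g * model$generation_time,
                method = "analytic"))
  }
  if (!is.null(seed)) set.seed(seed)
  v <- cpp_coal_tmrca(n, model$epochs, reps)
  list(gens = mean(v), years = mean(v) * model$generation_time,
       method = "monte-carlo")
}

#' Effective population size from theta
#'
#' `N_e = theta / (4 mu)`, both rates per site.
#'
#' @param theta_per_site scaled mutation rate per site.
#' @param mu_per_site mutation rate per site per generation.
#' @return N_e (diploids).
#' @export
ne_from_theta <- function(theta_per_site, mu_per_site) {
  if (theta_per_site <= 0 || mu_per_site <= 0) stop("rates must be positive")
  theta_per_site / (4 * mu_per_site)
}

#' Island-model coalescent (derived counts per deme)
#'
#' `d` demes of `N_total / d` diploids each with symmetric per-lineage
#' migration probability `m = M / (4 N_total)` per generation. For two demes
#' the classic equilibrium expectation is `FST = 1 / (1 + M)`.
#'
#' @param n_per_deme chromosomes sampled per deme.
#' @param N_total total diploid size across demes.
#' @param M scaled migration rate `4 N_total m`.
#' @param theta region-scaled mutation rate (`4 N_total mu_region`).
#' @param reps replicates.
#' @param seed optional integer seed.
#' @return list of matrices (demes x sites) of derived allele counts.
#' @export
sim_island <- function(n_per_deme, N_total, M, theta, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(n_per_deme)
  m <- M / (4 * N_total)
  mu <- theta / (4 * N_total)
  cpp_island_counts(as.integer(n_per_deme), N_total / d, m, -1, N_total, mu, reps)
}

#' Two-population split model (derived counts per deme)
#'
#' Two demes of `N` diploids each, no migration, merging into a single
#' ancestral population of `N` diploids `split_gens` generations ago.
#'
#' @param n_per_deme chromosomes sampled per deme (length 2).
#' @param N diploid size per deme (and ancestrally).
#' @param split_gens split time in generations.
#' @param theta region-scaled mutation rate (`4 N mu_region`).
#' @param reps replicates.
#' @param seed optional integer seed.
#' @return list of matrices (2 x sites) of derived allele counts.
#' @export
sim_split <- function(n_per_deme, N, split_gens, theta, reps, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- theta / (4 * N)
  cpp_island_counts(as.integer(n_per_deme), N, 0, split_gens, N, mu, reps)
}
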