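#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Piecewise demography, time in generations before present.
// Epoch j covers [t0[j], t0[j+1]) with diploid size
//   N(t) = N0[j] * exp(-g[j] * (t - t0[j]))
// so g > 0 means the population grows toward the present within the epoch.
// The last epoch must have g == 0 (checked in R) so total hazard diverges.
// ---------------------------------------------------------------------------
struct Demography {
  std::vector<double> t0, N0, g;

  int epoch_of(double t) const {
    int j = (int)t0.size() - 1;
    while (j > 0 && t < t0[j]) --j;
    return j;
  }

  // Solve for t' >= t with \int_t^{t'} C / (2 N(s)) ds = E  (C = #pairs)
  double advance(double t, double C, double E) const {
    int j = epoch_of(t);
    const int J = (int)t0.size();
    while (true) {
      double tend = (j + 1 < J) ? t0[j + 1] : R_PosInf;
      double haz;
      if (g[j] == 0.0) {
        haz = R_finite(tend) ? C * (tend - t) / (2.0 * N0[j]) : R_PosInf;
      } else {
        double a = std::exp(g[j] * (t - t0[j]));
        if (!R_finite(tend)) stop("open-ended epoch must have zero growth");
        double b = std::exp(g[j] * (tend - t0[j]));
        haz = C * (b - a) / (2.0 * N0[j] * g[j]);
      }
      if (E <= haz) {
        if (g[j] == 0.0) return t + 2.0 * N0[j] * E / C;
        double a = std::exp(g[j] * (t - t0[j]));
        return t0[j] + std::log(a + 2.0 * N0[j] * g[j] * E / C) / g[j];
      }
      E -= haz;
      t = tend;
      ++j;
    }
  }
};

static Demography as_demography(const NumericMatrix& epochs) {
  Demography d;
  int J = epochs.nrow();
  d.t0.resize(J); d.N0.resize(J); d.g.resize(J);
  for (int j = 0; j < J; ++j) {
    d.t0[j] = epochs(j, 0);
    d.N0[j] = epochs(j, 1);
    d.g[j]  = epochs(j, 2);
  }
  return d;
}

// Binary coalescent tree over n tips: nodes 0..n-1 tips, n..2n-2 internal.
struct Tree {
  int n;
  std::vector<double> time;   // node times (gens); tips at 0
  std::vector<int> parent;    // -1 for root
  std::vector<int> left, right;
  std::vector<int> ndesc;     // tips below (tips: 1)
};

// Standard single-population coalescent under `dem`.
static Tree sim_tree(int n, const Demography& dem) {
  Tree tr;
  tr.n = n;
  int m = 2 * n - 1;
  tr.time.assign(m, 0.0);
  tr.parent.assign(m, -1);
  tr.left.assign(m, -1);
  tr.right.assign(m, -1);
  tr.ndesc.assign(m, 0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) { active[i] = i; tr.ndesc[i] = 1; }
  double t = 0.0;
  int nxt = n;
  int k = n;
  while (k > 1) {
    double C = 0.5 * k * (k - 1);
    double E = exp_rand();
    t = dem.advance(t, C, E);
    int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
    int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    tr.time[nxt] = t;
    tr.left[nxt] = a; tr.right[nxt] = b;
    tr.parent[a] = nxt; tr.parent[b] = nxt;
    tr.ndesc[nxt] = tr.ndesc[a] + tr.ndesc[b];
    // replace i with new node, remove j
    if (i > j) std::swap(i, j);
    active[i] = nxt;
    active[j] = active[k - 1];
    active.pop_back();
    ++nxt;
    --k;
  }
  return tr;
}

// Per-replicate SFS-level summaries: S, pi, thetaH (counts scale), n_singleton,
// tmrca (gens). Mutations are Poisson(mu * branch length), mu = per-region
// per-generation rate.
// [[Rcpp::export]]
NumericMatrix cpp_coal_stats(int n, double mu, NumericMatrix epochs, int reps) {
  Demography dem = as_demography(epochs);
  NumericMatrix out(reps, 5);
  colnames(out) = CharacterVector::create("S", "pi", "thetaH", "singletons", "tmrca");
  double denom = (double)n * (n - 1);
  for (int r = 0; r < reps; ++r) {
    Tree tr = sim_tree(n, dem);
    double S = 0, pi = 0, thetaH = 0, sing = 0;
    int root = 2 * n - 2;
    for (int v = 0; v < root; ++v) {
      double len = tr.time[tr.parent[v]] - tr.time[v];
      int mcount = (int)R::rpois(mu * len);
      if (mcount > 0) {
        double i = (double)tr.ndesc[v];
        S += mcount;
        pi += mcount * 2.0 * i * (n - i) / denom;
        thetaH += mcount * 2.0 * i * i / denom;
        if (tr.ndesc[v] == 1) sing += mcount;
      }
    }
    out(r, 0) = S; out(r, 1) = pi; out(r, 2) = thetaH;
    out(r, 3) = sing; out(r, 4) = tr.time[root];
  }
  return out;
}

// Aggregated unfolded SFS over `reps` replicates: entry i-1 counts sites at
// derived count i.
// [[Rcpp::export]]
NumericVector cpp_coal_sfs(int n, double mu, NumericMatrix epochs, int reps) {
  Demography dem = as_demography(epochs);
  NumericVector sfs(n - 1);
  for (int r = 0; r < reps; ++r) {
    Tree tr = sim_tree(n, dem);
    int root = 2 * n - 2;
    for (int v = 0; v < root; ++v) {
      double len = tr.time[tr.parent[v]] - tr.time[v];
      int mcount = (int)R::rpois(mu * len);
      if (mcount > 0) sfs[tr.ndesc[v] - 1] += mcount;
    }
  }
  return sfs;
}

static void collect_tips(const Tree& tr, int v, std::vector<int>& tips) {
  std::vector<int> stack = {v};
  while (!stack.empty()) {
    int u = stack.back(); stack.pop_back();
    if (u < tr.n) tips.push_back(u);
    else { stack.push_back(tr.left[u]); stack.push_back(tr.right[u]); }
  }
}

static IntegerVector draw_positions(int S, int L) {
  if (S > L) stop("more mutations than available positions; increase L");
  std::unordered_set<int> used;
  IntegerVector pos(S);
  for (int s = 0; s < S; ++s) {
    int p;
    do {
      p = (int)(unif_rand() * L) + 1;
      if (p > L) p = L;
    } while (used.count(p));
    used.insert(p);
    pos[s] = p;
  }
  return pos;
}

// Joint modern + archaic panel. Moderns follow `epochs`; `n_arch` archaic
// lineages (constant size N_arch) stay isolated until `split_gen`, then join.
// Returns binary matrix (rows: n modern then n_arch archaic chromosomes),
// positions in 1..L, mutation ages (midpoint of branch, gens), tmrca.
// [[Rcpp::export]]
List cpp_coal_panel(int n, int n_arch, double split_gen, double N_arch,
                    double mu, NumericMatrix epochs, int L) {
  Demography dem = as_demography(epochs);
  int ntot = n + n_arch;
  int m = 2 * ntot - 1;
  Tree tr;
  tr.n = ntot;
  tr.time.assign(m, 0.0);
  tr.parent.assign(m, -1);
  tr.left.assign(m, -1); tr.right.assign(m, -1);
  tr.ndesc.assign(m, 0);
  std::vector<int> mod(n), arc(n_arch);
  for (int i = 0; i < n; ++i) { mod[i] = i; tr.ndesc[i] = 1; }
  for (int i = 0; i < n_arch; ++i) { arc[i] = n + i; tr.ndesc[n + i] = 1; }
  int nxt = ntot;
  double t = 0.0;
  bool merged = (n_arch == 0) || (split_gen <= 0.0);
  if (merged) {
    for (int i = 0; i < n_arch; ++i) mod.push_back(arc[i]);
    arc.clear();
  }

  auto merge_pair = [&](std::vector<int>& grp, int i, int j, double tt) {
    int a = grp[i], b = grp[j];
    tr.time[nxt] = tt;
    tr.left[nxt] = a; tr.right[nxt] = b;
    tr.parent[a] = nxt; tr.parent[b] = nxt;
    tr.ndesc[nxt] = tr.ndesc[a] + tr.ndesc[b];
    if (i > j) std::swap(i, j);
    grp[i] = nxt;
    grp[j] = grp.back();
    grp.pop_back();
    ++nxt;
  };

  while ((int)mod.size() + (int)arc.size() > 1) {
    if (!merged) {
      int km = (int)mod.size(), ka = (int)arc.size();
      // candidate next event in each group; archaic is constant-size
      double tm = (km > 1) ? dem.advance(t, 0.5 * km * (km - 1), exp_rand()) : R_PosInf;
      double ta = (ka > 1) ? t + exp_rand() * 2.0 * N_arch / (0.5 * ka * (ka - 1)) : R_PosInf;
      double tev = std::min(tm, ta);
      if (tev >= split_gen) {
        t = split_gen;
        merged = true;
        for (int v : arc) mod.push_back(v);
        arc.clear();
        continue;
      }
      t = tev;
      std::vector<int>& grp = (tm <= ta) ? mod : arc;
      int k = (int)grp.size();
      int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
      if (j >= i) ++j;
      merge_pair(grp, i, j, t);
    } else {
      int k = (int)mod.size();
      t = dem.advance(t, 0.5 * k * (k - 1), exp_rand());
      int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j == k - 1) j = k - 2;
      if (j >= i) ++j;
      merge_pair(mod, i, j, t);
    }
  }
  int root = nxt - 1;

  // mutations
  std::vector<int> mut_node;
  std::vector<double> mut_age;
  for (int v = 0; v < root; ++v) {
    if (tr.parent[v] < 0) continue;
    double len = tr.time[tr.parent[v]] - tr.time[v];
    int mcount = (int)R::rpois(mu * len);
    for (int q = 0; q < mcount; ++q) {
      mut_node.push_back(v);
      mut_age.push_back(tr.time[v] + unif_rand() * len);
    }
  }
  int S = (int)mut_node.size();
  IntegerVector pos = draw_positions(S, L);
  // order by position
  IntegerVector ord(S);
  for (int s = 0; s < S; ++s) ord[s] = s;
  std::sort(ord.begin(), ord.end(), [&](int a, int b){ return pos[a] < pos[b]; });

  IntegerMatrix mat(ntot, S);
  IntegerVector pos_sorted(S);
  NumericVector age_sorted(S);
  for (int c = 0; c < S; ++c) {
    int s = ord[c];
    pos_sorted[c] = pos[s];
    age_sorted[c] = mut_age[s];
    std::vector<int> tips;
    collect_tips(tr, mut_node[s], tips);
    for (int tp : tips) mat(tp, c) = 1;
  }
  return List::create(_["positions"] = pos_sorted,
                      _["mat"] = mat,
                      _["age_gens"] = age_sorted,
                      _["tmrca_gens"] = tr.time[root],
                      _["S"] = S);
}

// Branch-length weighting for allele-age estimation: for each replicate
// genealogy, branches subtending exactly i tips contribute (length, uniform
// age draw). Returns per-replicate total qualifying length and
// length-weighted mean of the uniform age draws (NA when no branch
// qualifies).
// [[Rcpp::export]]
NumericMatrix cpp_coal_ages(int n, int i, NumericMatrix epochs, int reps) {
  Demography dem = as_demography(epochs);
  NumericMatrix out(reps, 2);
  colnames(out) = CharacterVector::create("w", "age");
  for (int r = 0; r < reps; ++r) {
    Tree tr = sim_tree(n, dem);
    int root = 2 * n - 2;
    double sw = 0.0, swa = 0.0;
    for (int v = 0; v < root; ++v) {
      if (tr.ndesc[v] != i) continue;
      double len = tr.time[tr.parent[v]] - tr.time[v];
      double a = tr.time[v] + unif_rand() * len;
      sw += len;
      swa += len * a;
    }
    out(r, 0) = sw;
    out(r, 1) = (sw > 0) ? swa / sw : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_coal_tmrca(int n, NumericMatrix epochs, int reps) {
  Demography dem = as_demography(epochs);
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    Tree tr = sim_tree(n, dem);
    out[r] = tr.time[2 * n - 2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Structured coalescent: d demes of constant diploid size N_deme each,
// per-lineage per-generation migration probability mig (uniform target deme).
// At merge_gen all lineages collapse into one population of size N_anc
// (merge_gen < 0 disables). Returns, per replicate, a d x S matrix of derived
// allele counts per deme.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_island_counts(IntegerVector n_per_deme, double N_deme, double mig,
                       double merge_gen, double N_anc, double mu, int reps) {
  int d = n_per_deme.size();
  List out(reps);
  for (int r = 0; r < reps; ++r) {
    int ntot = 0;
    for (int q = 0; q < d; ++q) ntot += n_per_deme[q];
    int m = 2 * ntot - 1;
    std::vector<double> time(m, 0.0);
    std::vector<int> parent(m, -1), leftc(m, -1), rightc(m, -1);
    // per-node per-deme descendant counts
    std::vector<std::vector<int>> cnt(m, std::vector<int>(d, 0));
    std::vector<int> deme; deme.reserve(ntot);
    std::vector<int> active; active.reserve(ntot);
    {
      int id = 0;
      for (int q = 0; q < d; ++q)
        for (int j = 0; j < n_per_deme[q]; ++j) {
          deme.push_back(q);
          cnt[id][q] = 1;
          active.push_back(id);
          ++id;
        }
    }
    std::vector<int> lin_deme(m, 0);
    for (int v = 0; v < ntot; ++v) lin_deme[v] = deme[v];
    double t = 0.0;
    int nxt = ntot;
    bool merged = (merge_gen == 0.0);
    if (merged) for (int v : active) lin_deme[v] = 0;

    while ((int)active.size() > 1) {
      int k = (int)active.size();
      // rates
      std::vector<int> kd(d, 0);
      for (int v : active) kd[lin_deme[v]]++;
      double rate_coal = 0.0;
      double Ncur = merged ? N_anc : N_deme;
      for (int q = 0; q < d; ++q)
        rate_coal += 0.5 * kd[q] * (kd[q] - 1) / (2.0 * Ncur);
      double rate_mig = merged ? 0.0 : (double)k * mig;
      double total = rate_coal + rate_mig;
      if (total <= 0.0) {
        // isolated lineages waiting for the merge
        if (!merged && merge_gen > 0) { t = merge_gen; merged = true;
          for (int v : active) lin_deme[v] = 0; continue; }
        stop("island model: zero total rate");
      }
      double dt = exp_rand() / total;
      if (!merged && merge_gen > 0 && t + dt > merge_gen) {
        t = merge_gen;
        merged = true;
        for (int v : active) lin_deme[v] = 0;
        continue;
      }
      t += dt;
      if (unif_rand() * total < rate_coal) {
        // pick deme proportional to its pair count
        double u = unif_rand() * rate_coal;
        int q = 0;
        for (; q < d; ++q) {
          double rq = 0.5 * kd[q] * (kd[q] - 1) / (2.0 * Ncur);
          if (u < rq) break;
          u -= rq;
        }
        if (q == d) q = d - 1;
        // pick two active lineages in deme q
        std::vector<int> idx;
        for (int z = 0; z < k; ++z) if (lin_deme[active[z]] == q) idx.push_back(z);
        int kk = (int)idx.size();
        int i = (int)(unif_rand() * kk); if (i == kk) i = kk - 1;
        int j = (int)(unif_rand() * (kk - 1)); if (j == kk - 1) j = kk - 2;
        if (j >= i) ++j;
        int zi = idx[i], zj = idx[j];
        int a = active[zi], b = active[zj];
        time[nxt] = t;
        leftc[nxt] = a; rightc[nxt] = b;
        parent[a] = nxt; parent[b] = nxt;
        for (int qq = 0; qq < d; ++qq) cnt[nxt][qq] = cnt[a][qq] + cnt[b][qq];
        lin_deme[nxt] = q;
        if (zi > zj) std::swap(zi, zj);
        active[zi] = nxt;
        active[zj] = active[k - 1];
        active.pop_back();
        ++nxt;
      } else {
        int z = (int)(unif_rand() * k); if (z == k) z = k - 1;
        int v = active[z];
        int to = (int)(unif_rand() * (d - 1)); if (to == d - 1) to = d - 2;
        if (to >= lin_deme[v]) ++to;
        lin_deme[v] = to;
      }
    }
    int root = nxt - 1;
    std::vector<int> mut_node;
    for (int v = 0; v < root; ++v) {
      if (parent[v] < 0) continue;
      double len = time[parent[v]] - time[v];
      int mcount = (int)R::rpois(mu * len);
      for (int q = 0; q < mcount; ++q) mut_node.push_back(v);
    }
    int S = (int)mut_node.size();
    IntegerMatrix counts(d, S);
    for (int s = 0; s < S; ++s)
      for (int q = 0; q < d; ++q) counts(q, s) = cnt[mut_node[s]][q];
    out[r] = counts;
  }
  return out;
}
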