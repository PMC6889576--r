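#include <Rcpp.h>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Discrete-generation Wright-Fisher diploid forward simulation over an
// L-bp region. Each chromosome is a sorted vector of positions carrying
// derived neutral alleles; the focal (possibly selected) allele at
// focal_pos is tracked separately. Fitness is multiplicative at the focal
// site: 1, 1 + h*s, 1 + s.

typedef std::vector<int> Hap;

struct Popu {
  std::vector<Hap> hap;        // 2N chromosomes
  std::vector<char> focal;     // focal allele per chromosome
};

static inline int rand_int(int n) {
  int v = (int)(unif_rand() * n);
  return (v >= n) ? n - 1 : v;
}

// recombinant gamete from one diploid parent (haplotypes a and b)
static void make_gamete(const Hap& ha, const Hap& hb, char fa, char fb,
                        double rL, int L, int focal_pos,
                        Hap& out, char& fout) {
  out.clear();
  int ncx = (int)R::rpois(rL);
  int first = rand_int(2);
  if (ncx == 0) {
    const Hap& h = first == 0 ? ha : hb;
    out = h;
    fout = first == 0 ? fa : fb;
    return;
  }
  std::vector<int> bks(ncx);
  for (int i = 0; i < ncx; ++i) bks[i] = rand_int(L) + 1;
  std::sort(bks.begin(), bks.end());
  bks.push_back(L + 1);
  // walk segments [prev, bk) taking alternating haplotypes
  int cur = first, prev = 1;
  size_t ia = 0, ib = 0;
  fout = 0;
  for (int bk : bks) {
    const Hap& h = cur == 0 ? ha : hb;
    size_t& idx = cur == 0 ? ia : ib;
    // advance the *other* haplotype's cursor past the segment too
    size_t& oidx = cur == 0 ? ib : ia;
    const Hap& oh = cur == 0 ? hb : ha;
    while (idx < h.size() && h[idx] < prev) ++idx;
    while (idx < h.size() && h[idx] < bk) out.push_back(h[idx++]);
    while (oidx < oh.size() && oh[oidx] < bk) ++oidx;
    if (focal_pos >= prev && focal_pos < bk) fout = cur == 0 ? fa : fb;
    prev = bk;
    cur = 1 - cur;
  }
}

static double focal_freq(const Popu& p) {
  long c = 0;
  for (char f : p.focal) c += f;
  return (double)c / p.focal.size();
}

// remove positions fixed in every chromosome (keeps vectors short) and
// rebuild the occupied-position set so extinct/fixed positions become
// available for new mutations again (finite L would otherwise exhaust)
static void purge_fixed(Popu& p, std::unordered_set<int>& used, int focal_pos) {
  std::unordered_map<int, int> cnt;
  int twoN = (int)p.hap.size();
  for (const Hap& h : p.hap)
    for (int x : h) cnt[x]++;
  std::unordered_set<int> fixed;
  for (auto& kv : cnt) if (kv.second == twoN) fixed.insert(kv.first);
  if (!fixed.empty()) {
    for (Hap& h : p.hap) {
      Hap nh; nh.reserve(h.size());
      for (int x : h) if (!fixed.count(x)) nh.push_back(x);
      h.swap(nh);
    }
  }
  used.clear();
  used.insert(focal_pos);
  for (auto& kv : cnt) if (!fixed.count(kv.first)) used.insert(kv.first);
}

static void next_generation(const Popu& cur, Popu& nxt, int N, double s,
                            double hdom, double uL, double rL, int L,
                            int focal_pos, std::unordered_set<int>& used) {
  // fitness by focal genotype
  std::vector<double> cum(N);
  double tot = 0.0;
  bool sel = (s != 0.0);
  for (int i = 0; i < N; ++i) {
    double w = 1.0;
    if (sel) {
      int gcount = cur.focal[2 * i] + cur.focal[2 * i + 1];
      w = (gcount == 0) ? 1.0 : (gcount == 1 ? 1.0 + hdom * s : 1.0 + s);
    }
    tot += w;
    cum[i] = tot;
  }
  nxt.hap.resize(2 * N);
  nxt.focal.resize(2 * N);
  for (int i = 0; i < N; ++i) {
    for (int side = 0; side < 2; ++side) {
      int par;
      if (sel) {
        double u = unif_rand() * tot;
        par = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (par >= N) par = N - 1;
      } else {
        par = rand_int(N);
      }
      Hap& g = nxt.hap[2 * i + side];
      char f;
      make_gamete(cur.hap[2 * par], cur.hap[2 * par + 1],
                  cur.focal[2 * par], cur.focal[2 * par + 1],
                  rL, L, focal_pos, g, f);
      int nmut = (int)R::rpois(uL);
      for (int q = 0; q < nmut; ++q) {
        int p;
        do { p = rand_int(L) + 1; } while (used.count(p) || p == focal_pos);
        used.insert(p);
        g.insert(std::lower_bound(g.begin(), g.end(), p), p);
      }
      nxt.focal[2 * i + side] = f;
    }
  }
}

// Sample n chromosomes without replacement; return positions segregating in
// the sample (plus the focal column when segregating or requested).
static List sample_panel(const Popu& p, int n_sample, int focal_pos,
                         bool focal_present) {
  int twoN = (int)p.hap.size();
  std::vector<int> pool(twoN);
  for (int i = 0; i < twoN; ++i) pool[i] = i;
  std::vector<int> pick(n_sample);
  for (int i = 0; i < n_sample; ++i) {
    int j = i + rand_int(twoN - i);
    std::swap(pool[i], pool[j]);
    pick[i] = pool[i];
  }
  // count alleles in sample
  std::unordered_map<int, int> cnt;
  for (int idx : pick)
    for (int x : p.hap[idx]) cnt[x]++;
  int focal_cnt = 0;
  for (int idx : pick) focal_cnt += p.focal[idx];
  std::vector<int> segpos;
  for (auto& kv : cnt)
    if (kv.second > 0 && kv.second < n_sample) segpos.push_back(kv.first);
  bool add_focal = focal_present && focal_cnt > 0 && focal_cnt < n_sample;
  if (add_focal) segpos.push_back(focal_pos);
  std::sort(segpos.begin(), segpos.end());
  int S = (int)segpos.size();
  IntegerMatrix mat(n_sample, S);
  std::unordered_map<int, int> col;
  for (int s = 0; s < S; ++s) col[segpos[s]] = s;
  for (int i = 0; i < n_sample; ++i) {
    const Hap& h = p.hap[pick[i]];
    for (int x : h) {
      auto it = col.find(x);
      if (it != col.end()) mat(i, it->second) = 1;
    }
    if (add_focal && p.focal[pick[i]]) mat(i, col[focal_pos]) = 1;
  }
  int focal_idx = add_focal ? col[focal_pos] + 1 : NA_INTEGER; // 1-based
  return List::create(_["positions"] = wrap(segpos),
                      _["mat"] = mat,
                      _["focal_index"] = focal_idx,
                      _["focal_count_sample"] = focal_cnt);
}

// mode: 0 neutral, 1 hard sweep, 2 soft (standing at ~f0), 3 soft (k origins)
// stop_rule: 0 = stop when focal frequency enters [f_lo, f_hi];
//            1 = run exactly run_gens generations after setup
// [[Rcpp::export]]
List cpp_forward_sim(int N, int L, double u, double r, double s, double hdom,
                     int mode, double f0, int k_origins,
                     double f_lo, double f_hi, int n_sample,
                     int burnin, int max_restarts, int stop_rule,
                     int run_gens, int max_sweep_gens) {
  double uL = u * (double)L, rL = r * (double)L;
  int focal_pos = L / 2;
  std::unordered_set<int> used;
  used.insert(focal_pos);
  Popu A, B;
  A.hap.assign(2 * N, Hap());
  A.focal.assign(2 * N, 0);
  Popu* cur = &A; Popu* nxt = &B;

  for (int gen = 0; gen < burnin; ++gen) {
    next_generation(*cur, *nxt, N, 0.0, hdom, uL, rL, L, focal_pos, used);
    std::swap(cur, nxt);
    if (gen % 100 == 99) purge_fixed(*cur, used, focal_pos);
  }
  purge_fixed(*cur, used, focal_pos);

  if (mode == 0) {
    List panel = sample_panel(*cur, n_sample, focal_pos, false);
    panel["restarts"] = 0;
    panel["gens_after_setup"] = 0;
    panel["focal_freq_pop"] = NA_REAL;
    panel["trajectory"] = NumericVector(0);
    return panel;
  }

  Popu saved = *cur;   // state to restore on loss
  int restarts = 0;
  std::vector<double> traj;
  while (true) {
    // set up the focal allele
    if (mode == 1) {
      int c = rand_int(2 * N);
      cur->focal[c] = 1;
    } else if (mode == 2) {
      // choose an existing neutral variant with frequency nearest f0
      std::unordered_map<int, int> cnt;
      for (const Hap& h : cur->hap) for (int x : h) cnt[x]++;
      int best = -1; double bestd = 2.0;
      for (auto& kv : cnt) {
        double fr = (double)kv.second / (2 * N);
        if (fr <= 0.0 || fr >= 1.0) continue;
        double dd = std::fabs(fr - f0);
        if (dd < bestd) { bestd = dd; best = kv.first; }
      }
      if (best < 0) stop("no standing variant available for soft sweep");
      for (int i = 0; i < 2 * N; ++i) {
        Hap& h = cur->hap[i];
        auto it = std::lower_bound(h.begin(), h.end(), best);
        if (it != h.end() && *it == best) { cur->focal[i] = 1; h.erase(it); }
        else cur->focal[i] = 0;
      }
    } else if (mode == 3) {
      for (int q = 0; q < k_origins; ++q) {
        int c;
        do { c = rand_int(2 * N); } while (cur->focal[c]);
        cur->focal[c] = 1;
      }
    }
    traj.clear();
    traj.push_back(focal_freq(*cur));
    bool lost = false, done = false;
    int gen = 0;
    while (!done && !lost) {
      next_generation(*cur, *nxt, N, s, hdom, uL, rL, L, focal_pos, used);
      std::swap(cur, nxt);
      ++gen;
      if (gen % 100 == 99) purge_fixed(*cur, used, focal_pos);
      double fr = focal_freq(*cur);
      traj.push_back(fr);
      if (stop_rule == 1) {
        if (gen >= run_gens) done = true;
      } else {
        if (fr <= 0.0) lost = true;
        else if (fr >= 1.0) lost = true;           // overshot the window
        else if (fr >= f_lo && fr <= f_hi) done = true;
        else if (gen > max_sweep_gens) lost = true;
      }
    }
    if (done) break;
    ++restarts;
    if (restarts > max_restarts) stop("focal allele never reached the sampling window within the restart budget");
    *cur = saved;
  }
  purge_fixed(*cur, used, focal_pos);
  double fr = focal_freq(*cur);
  List panel = sample_panel(*cur, n_sample, focal_pos, true);
  panel["restarts"] = restarts;
  panel["gens_after_setup"] = (int)traj.size() - 1;
  panel["focal_freq_pop"] = fr;
  panel["trajectory"] = wrap(traj);
  return panel;
}
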