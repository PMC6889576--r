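#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity decay from a core site, one allele class.
// EHH at offset k sites from the core is sum_g C(n_g,2) / C(n_c,2) over the
// partition of core-allele carriers into distinct haplotypes across the
// interval [core, core +/- k]. Values are returned outward from the core in
// each direction, truncated after EHH first reaches 0 (all remaining values
// are 0 by the nested-partition property).
// mat: n x S binary matrix; core: 1-based column; allele: 0 or 1.
// [[Rcpp::export]]
List cpp_ehh_curve(IntegerMatrix mat, int core, int allele) {
  int n = mat.nrow(), S = mat.ncol();
  int c0 = core - 1;
  std::vector<int> carriers;
  for (int i = 0; i < n; ++i)
    if (mat(i, c0) == allele) carriers.push_back(i);
  int nc = (int)carriers.size();
  if (nc < 2) stop("fewer than 2 carriers of the core allele");
  double denom = 0.5 * nc * (nc - 1);

  auto decay = [&](int step) {
    std::vector<double> ehh;
    std::vector<int> grp(nc, 0);
    int ngrp = 1;
    for (int c = c0 + step; c >= 0 && c < S; c += step) {
      // split groups by allele at c
      std::vector<int> remap(2 * ngrp, -1);
      int nn = 0;
      for (int i = 0; i < nc; ++i) {
        int key = 2 * grp[i] + mat(carriers[i], c);
        if (remap[key] < 0) remap[key] = nn++;
        grp[i] = remap[key];
      }
      ngrp = nn;
      std::vector<int> sz(ngrp, 0);
      for (int i = 0; i < nc; ++i) sz[grp[i]]++;
      double hom = 0.0;
      for (int g = 0; g < ngrp; ++g) hom += 0.5 * sz[g] * (sz[g] - 1.0);
      ehh.push_back(hom / denom);
      if (hom == 0.0) break;
    }
    return ehh;
  };

  return List::create(_["left"] = wrap(decay(-1)),
                      _["right"] = wrap(decay(+1)),
                      _["n_carriers"] = nc);
}
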