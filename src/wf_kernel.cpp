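#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Gamete formation for one generation of a Wright-Fisher diploid population.
//
// haps:        2N x m parental haplotype matrix (0/1); rows 2k-2 and 2k-1
//              (0-based) are the two haplotypes of parent k (1-based).
// parent:      length-G vector of 1-based parent indices, one per gamete.
// gpos:        genetic position of each marker (Morgans, within chromosome).
// chrom_start: 0-based index of the first marker of each chromosome.
// chrom_len:   number of markers on each chromosome.
//
// Crossovers are Poisson on the genetic map (Haldane, no interference);
// chromosomes assort independently.  Uses R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix wf_gametes_cpp(const IntegerMatrix& haps,
                             const IntegerVector& parent,
                             const NumericVector& gpos,
                             const IntegerVector& chrom_start,
                             const IntegerVector& chrom_len) {
  const int G = parent.size();
  const int m = haps.ncol();
  const int nchrom = chrom_start.size();
  IntegerMatrix out(G, m);
  std::vector<double> xpos;

  for (int g = 0; g < G; ++g) {
    const int r1 = 2 * (parent[g] - 1);
    const int r2 = r1 + 1;
    for (int c = 0; c < nchrom; ++c) {
      const int s = chrom_start[c];
      const int len = chrom_len[c];
      const double g0 = gpos[s];
      const double L = gpos[s + len - 1] - g0;
      int nx = (L > 0.0) ? static_cast<int>(R::rpois(L)) : 0;
      xpos.resize(nx);
      for (int k = 0; k < nx; ++k) xpos[k] = g0 + unif_rand() * L;
      std::sort(xpos.begin(), xpos.end());
      int cur = (unif_rand() < 0.5) ? r1 : r2;
      int xi = 0;
      for (int j = s; j < s + len; ++j) {
        const double p = gpos[j];
        while (xi < nx && xpos[xi] <= p) {
          cur = (cur == r1) ? r2 : r1;
          ++xi;
        }
        out(g, j) = haps(cur, j);
      }
    }
  }
  return out;
}
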