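#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Draw gametes from stored haplotype pairs by Poisson (no-interference)
// crossover placement on the female centimorgan map.
//
// H           : (2n x k) haplotype matrix; rows 2i, 2i+1 (0-based) belong to
//               individual i.  Entries are 0/1 allele codes.
// parent      : 0-based individual index producing each gamete.
// male        : per gamete, whether the transmitting parent is male.  Males
//               do not recombine: each chromosome is one intact parental
//               haplotype chosen with probability 1/2.
// cm          : per-site position on the female map (cM), non-decreasing
//               within a chromosome block.
// chr_first/chr_last : 0-based first/last column of each chromosome block.
// cm_lo/cm_hi : female map range of each chromosome; crossover count is
//               Poisson((cm_hi-cm_lo)/100) and positions are uniform on the
//               cM interval, so recombination fractions follow Haldane's
//               map function.
//
// Uses R's RNG (RNGScope is injected by Rcpp attributes), so results are
// reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix gametes_cpp(const IntegerMatrix& H,
                          const IntegerVector& parent,
                          const LogicalVector& male,
                          const NumericVector& cm,
                          const IntegerVector& chr_first,
                          const IntegerVector& chr_last,
                          const NumericVector& cm_lo,
                          const NumericVector& cm_hi) {
  const int n = parent.size();
  const int k = H.ncol();
  const int nchr = chr_first.size();
  IntegerMatrix G(n, k);
  std::vector<double> xpos;

  for (int g = 0; g < n; ++g) {
    const int r0 = 2 * parent[g];
    const int r1 = r0 + 1;
    if (r1 >= H.nrow())
      stop("parent index out of range");
    for (int c = 0; c < nchr; ++c) {
      const int a = chr_first[c];
      const int b = chr_last[c];
      const double span = cm_hi[c] - cm_lo[c];
      if (male[g] || span <= 0.0) {
        const int src = (unif_rand() < 0.5) ? r0 : r1;
        for (int j = a; j <= b; ++j) G(g, j) = H(src, j);
        continue;
      }
      const int ncx = static_cast<int>(R::rpois(span / 100.0));
      int cur = (unif_rand() < 0.5) ? 0 : 1;
      if (ncx == 0) {
        const int src = cur ? r1 : r0;
        for (int j = a; j <= b; ++j) G(g, j) = H(src, j);
        continue;
      }
      xpos.resize(ncx);
      for (int i = 0; i < ncx; ++i)
        xpos[i] = cm_lo[c] + unif_rand() * span;
      std::sort(xpos.begin(), xpos.end());
      int xi = 0;
      for (int j = a; j <= b; ++j) {
        while (xi < ncx && xpos[xi] <= cm[j]) { cur ^= 1; ++xi; }
        G(g, j) = cur ? H(r1, j) : H(r0, j);
      }
    }
  }
  return G;
}
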