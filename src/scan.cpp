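#include <Rcpp.h>
using namespace Rcpp;

// Bases and IUPAC codes are encoded as 4-bit masks (A=1, C=2, G=4, T=8); a
// segment base is compatible with a consensus code iff the masks intersect.

static inline int complement_bits(int b) {
  return ((b & 1) ? 8 : 0) | ((b & 2) ? 4 : 0) |
         ((b & 4) ? 2 : 0) | ((b & 8) ? 1 : 0);
}

// Best ungapped overlap fraction of the shorter vector along the longer.
static double slide_best(const std::vector<int>& longer,
                         const std::vector<int>& shorter) {
  const int nl = longer.size(), ns = shorter.size();
  int best = 0;
  for (int off = 0; off <= nl - ns; ++off) {
    int hits = 0;
    for (int j = 0; j < ns; ++j) {
      if (longer[off + j] & shorter[j]) ++hits;
    }
    if (hits > best) best = hits;
    if (best == ns) break;
  }
  return static_cast<double>(best) / ns;
}

// [[Rcpp::export]]
NumericVector motif_best_similarity(IntegerVector seg_bits, List motif_bits) {
  const int n = seg_bits.size();
  std::vector<int> fwd(n), rc(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = seg_bits[i];
    rc[n - 1 - i] = complement_bits(seg_bits[i]);
  }
  const int m = motif_bits.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    IntegerVector mv = motif_bits[k];
    std::vector<int> motif(mv.begin(), mv.end());
    double best;
    if (static_cast<int>(motif.size()) <= n) {
      best = slide_best(fwd, motif);
      if (best < 1.0) best = std::max(best, slide_best(rc, motif));
    } else {
      best = slide_best(motif, fwd);
      if (best < 1.0) best = std::max(best, slide_best(motif, rc));
    }
    out[k] = best;
  }
  return out;
}
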