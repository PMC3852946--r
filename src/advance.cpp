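#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 32 random bits per unif_rand() call; R guarantees unif_rand() in (0, 1).
struct BitPool {
  uint64_t pool = 0;
  int left = 0;
  inline int bit() {
    if (left == 0) {
      pool = (uint64_t)(unif_rand() * 4294967296.0);
      left = 32;
    }
    int b = (int)(pool & 1u);
    pool >>= 1;
    --left;
    return b;
  }
};

// One forward generation of a constant-size, randomly mating, non-overlapping
// diploid population.
//
// Mating: all nc individuals are shuffled into nc/2 disjoint monogamous pairs;
// each pair draws one family size (Poisson(2) or floor(Gamma(shape, scale))).
// If the census is not filled after a round of pairs, individuals are
// reshuffled and mating continues; the last family is truncated so the
// offspring generation has exactly nc individuals.  Disjoint pairing keeps the
// per-parent offspring variance equal to the family-size variance, which is
// what ties Ne/Nc to 4/(Vk+2).
//
// geno is nc x 2L (two gene copies per locus, adjacent columns).  Each child
// inherits one uniformly chosen copy per locus from each parent.
//
// mut_mode: 0 none, 1 strict SMM (+-1 repeat, lower bound 1 reflecting),
// 2 SMM reflected inside [win_lo, win_hi].  The number of mutations is
// Poisson(mu * nc * 2L); each hits a uniform gene-copy-by-locus slot.
//
// All randomness comes from R's RNG stream (reproducible under set.seed()).
// Family sizes: Poisson(2), or an inverse-CDF draw from the precomputed
// discrete floored-gamma distribution (fam_cdf[k] = P(X <= k)).
// [[Rcpp::export]]
IntegerMatrix cpp_advance_one(const IntegerMatrix& geno,
                              const NumericVector& fam_cdf, bool poisson,
                              double mu, int mut_mode, int win_lo,
                              int win_hi) {
  const int nc = geno.nrow();
  const int ncol = geno.ncol();
  const int L = ncol / 2;
  if (nc < 2)
    stop("population must have at least 2 individuals");
  if (ncol % 2 != 0)
    stop("genotype matrix must have an even number of columns");

  IntegerMatrix child(nc, ncol);
  RNGScope scope;

  const double* cdf_ptr = fam_cdf.begin();
  const int cdf_n = fam_cdf.size();
  const double cdf0 = poisson ? 0.0 : (cdf_n > 0 ? cdf_ptr[0] : 0.0);

  // assign a (p1, p2) parent pair to every offspring slot
  std::vector<int> par1(nc), par2(nc), perm(nc);
  int pos = nc;  // force a shuffle on first use
  int filled = 0;
  while (filled < nc) {
    if (pos + 1 >= nc) {  // new pairing round: Fisher-Yates shuffle
      for (int i = 0; i < nc; ++i) perm[i] = i;
      for (int i = nc - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        int tmp = perm[i]; perm[i] = perm[j]; perm[j] = tmp;
      }
      pos = 0;
    }
    const int p1 = perm[pos];
    const int p2 = perm[pos + 1];
    pos += 2;
    int fam;
    if (poisson) {
      fam = (int)R::rpois(2.0);
    } else {
      double u = unif_rand();
      if (u < cdf0) {
        fam = 0;  // childless matings dominate under sweepstakes variance
      } else {
        fam = (int)(std::upper_bound(cdf_ptr, cdf_ptr + cdf_n, u) - cdf_ptr);
      }
    }
    if (fam <= 0) continue;
    if (fam > nc - filled) fam = nc - filled;  // truncate the last family
    for (int c = filled; c < filled + fam; ++c) { par1[c] = p1; par2[c] = p2; }
    filled += fam;
  }

  // Mendelian inheritance, locus-major for cache locality
  const int* g = INTEGER(geno);
  int* ch = INTEGER(child);
  BitPool bp;
  for (int l = 0; l < L; ++l) {
    const int* ga = g + (size_t)(2 * l) * nc;
    const int* gb = ga + nc;
    int* ca = ch + (size_t)(2 * l) * nc;
    int* cb = ca + nc;
    for (int c = 0; c < nc; ++c) {
      ca[c] = bp.bit() ? gb[par1[c]] : ga[par1[c]];
      cb[c] = bp.bit() ? gb[par2[c]] : ga[par2[c]];
    }
  }

  if (mut_mode > 0 && mu > 0) {
    const double slots = (double)nc * (double)ncol;
    const int nmut = (int)R::rpois(mu * slots);
    for (int m = 0; m < nmut; ++m) {
      size_t idx = (size_t)(unif_rand() * slots);
      if (idx >= (size_t)nc * ncol) idx = (size_t)nc * ncol - 1;
      int v = ch[idx] + (bp.bit() ? 1 : -1);
      if (mut_mode == 1) {
        if (v < 1) v = 2 - v;  // reflect at repeat count 1
      } else {
        if (v < win_lo) v = 2 * win_lo - v;  // reflect inside the window
        if (v > win_hi) v = 2 * win_hi - v;
      }
      ch[idx] = v;
    }
  }
  return child;
}
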