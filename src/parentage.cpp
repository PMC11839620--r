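#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Probability that a parent with genotype (g1,g2) transmits allele x.
static inline double transmit(int g1, int g2, int x) {
  return 0.5 * ((g1 == x) + (g2 == x));
}

// LOD and Mendelian-mismatch matrices for offspring x candidate trios.
//
// off, mom: S x 2L matrices of allele indices (1-based within locus,
// 0 = missing); mom holds each offspring's known mother. cand: C x 2L.
// freqs: list of L numeric vectors of allele frequencies by index.
//
// Per typed locus the LOD term is
//   ln[ (1-e) T(go|gm,gc) + e P(go) ] - ln[ (1-e) T(go|gm) + e P(go) ]
// with T the Mendelian transition probability (father = candidate in the
// numerator, a random male drawn from the allele frequencies in the
// denominator) and P(go) the Hardy-Weinberg genotype frequency; e is the
// per-genotype mistyping rate. Loci missing in any of the three individuals
// are skipped; a locus whose denominator is exactly zero (mother-offspring
// incompatibility at e = 0) is skipped likewise.
// [[Rcpp::export]]
List lod_mismatch_matrix(IntegerMatrix off, IntegerMatrix mom,
                         IntegerMatrix cand, List freqs, double error_rate) {
  const int S = off.nrow(), C = cand.nrow();
  const int L = freqs.size();
  if (off.ncol() != 2 * L || mom.ncol() != 2 * L || cand.ncol() != 2 * L)
    stop("genotype matrices must have 2 columns per locus");
  NumericMatrix lod(S, C);
  IntegerMatrix mm(S, C);

  std::vector<NumericVector> fr(L);
  for (int l = 0; l < L; ++l) fr[l] = as<NumericVector>(freqs[l]);

  for (int s = 0; s < S; ++s) {
    for (int c = 0; c < C; ++c) {
      double acc = 0.0;
      int nmm = 0, shared = 0;
      for (int l = 0; l < L; ++l) {
        int oa = off(s, 2 * l), ob = off(s, 2 * l + 1);
        int ma = mom(s, 2 * l), mb = mom(s, 2 * l + 1);
        int ca = cand(c, 2 * l), cb = cand(c, 2 * l + 1);
        if (oa == 0 || ma == 0 || ca == 0) continue;
        ++shared;
        const NumericVector &p = fr[l];
        double pa = p[oa - 1], pb = p[ob - 1];
        double phw = (oa == ob) ? pa * pa : 2.0 * pa * pb;
        double Ma = transmit(ma, mb, oa), Mb = transmit(ma, mb, ob);
        double Ca = transmit(ca, cb, oa), Cb = transmit(ca, cb, ob);
        double t_cand, t_rand;
        if (oa == ob) {
          t_cand = Ma * Ca;
          t_rand = Ma * pa;
        } else {
          t_cand = Ma * Cb + Mb * Ca;
          t_rand = Ma * pb + Mb * pa;
        }
        // trio Mendelian incompatibility
        bool mhas_a = (ma == oa || mb == oa), mhas_b = (ma == ob || mb == ob);
        bool chas_a = (ca == oa || cb == oa), chas_b = (ca == ob || cb == ob);
        bool compat = (oa == ob) ? (mhas_a && chas_a)
                                 : ((mhas_a && chas_b) || (mhas_b && chas_a));
        if (!compat) ++nmm;
        double num = (1.0 - error_rate) * t_cand + error_rate * phw;
        double den = (1.0 - error_rate) * t_rand + error_rate * phw;
        if (den <= 0.0) { --shared; continue; } // mother-offspring conflict at e=0
        acc += std::log(num) - std::log(den);   // log(0) = -Inf is intended
      }
      if (shared == 0) {
        lod(s, c) = NA_REAL;
        mm(s, c) = NA_INTEGER;
      } else {
        lod(s, c) = acc;
        mm(s, c) = nmm;
      }
    }
  }
  return List::create(_["lod"] = lod, _["mismatch"] = mm);
}
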