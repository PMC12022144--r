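#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Extended haplotype homozygosity decay from a core site, computed over the
// whole population of haplotypes (the convention used for cross-population
// comparisons). Haplotype classes are grown site by site away from the core;
// the core allele itself is part of the extended haplotype string. The curve
// starts at 1 at extension distance zero.

// One decay step: split classes by the alleles at column `site`, return the
// pair-homozygosity sum(n_h*(n_h-1)) / (n*(n-1)).
static double split_step(const IntegerMatrix &H, std::vector<int> &grp,
                         int &ngrp, int site) {
  int n = (int)grp.size();
  // new group id = 2*old + allele, then compact
  std::vector<int> remap(2 * ngrp, -1);
  std::vector<int> count;
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    int key = 2 * grp[i] + (H(i, site) != 0 ? 1 : 0);
    if (remap[key] < 0) {
      remap[key] = next_id++;
      count.push_back(0);
    }
    grp[i] = remap[key];
    count[grp[i]]++;
  }
  ngrp = next_id;
  double hom = 0.0;
  for (int k = 0; k < ngrp; ++k)
    hom += (double)count[k] * (count[k] - 1);
  return hom / ((double)n * (n - 1));
}

// EHH curve in one direction (dir = +1 right, -1 left) from 0-based core.
// Element j of the result is EHH over sites core..core+dir*j inclusive,
// with element 0 fixed at 1 (zero extension).
// [[Rcpp::export]]
NumericVector ehh_curve_cpp(IntegerMatrix H, int core, int dir) {
  int n = H.nrow(), m = H.ncol();
  if (n < 2) stop("need at least 2 haplotypes");
  int len = (dir > 0) ? (m - core) : (core + 1);
  NumericVector out(len);
  out[0] = 1.0;
  std::vector<int> grp(n, 0);
  int ngrp = 1;
  // include the core allele in the haplotype string
  double v = split_step(H, grp, ngrp, core);
  for (int j = 1; j < len; ++j) {
    v = split_step(H, grp, ngrp, core + dir * j);
    out[j] = v;
    if (v == 0.0) {  // cannot recover; fill remainder with zeros
      for (int k = j + 1; k < len; ++k) out[k] = 0.0;
      break;
    }
  }
  return out;
}

// Integrated EHH at a set of core sites. Trapezoidal integration over
// genetic distance (cM), each direction truncated at the first site where
// EHH < trunc with a partial trapezoid to the interpolated crossing point.
// [[Rcpp::export]]
NumericVector ihh_sites_cpp(IntegerMatrix H, NumericVector cm,
                            IntegerVector cores, double trunc) {
  int n = H.nrow(), m = H.ncol();
  if (n < 2) stop("need at least 2 haplotypes");
  if (cm.size() != m) stop("cm length must match site count");
  NumericVector out(cores.size());
  std::vector<int> grp(n);
  for (int ci = 0; ci < cores.size(); ++ci) {
    int core = cores[ci];
    if (core < 0 || core >= m) stop("core index out of range");
    double total = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      int len = (dir > 0) ? (m - core) : (core + 1);
      std::fill(grp.begin(), grp.end(), 0);
      int ngrp = 1;
      double v_prev = 1.0, d_prev = 0.0;
      split_step(H, grp, ngrp, core);
      for (int j = 1; j < len; ++j) {
        double v = split_step(H, grp, ngrp, core + dir * j);
        double d = std::fabs(cm[core + dir * j] - cm[core]);
        if (v < trunc) {
          if (v_prev > v) {
            double frac = (v_prev - trunc) / (v_prev - v);
            total += 0.5 * (v_prev + trunc) * frac * (d - d_prev);
          }
          v_prev = v;
          break;
        }
        total += 0.5 * (v_prev + v) * (d - d_prev);
        v_prev = v;
        d_prev = d;
        if (v == 0.0) break;
      }
    }
    out[ci] = total;
  }
  return out;
}
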