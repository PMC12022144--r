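#include <Rcpp.h>
#include <algorithm>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// Forward Wright-Fisher simulation on a continuous sequence [0, L).
// Haplotypes are sparse sorted vectors of derived-mutation positions
// (infinite-sites; the founding allele is ancestral everywhere).
// All randomness goes through R's RNG so set.seed() controls runs exactly.

typedef std::vector<double> Hap;

static inline bool carries(const Hap &h, double pos) {
  return std::binary_search(h.begin(), h.end(), pos);
}

// Gamete from a diploid parent (h1, h2): Poisson(rho*L) crossovers at
// uniform breakpoints, segments alternate starting from a random haplotype.
static Hap make_gamete(const Hap &h1, const Hap &h2, double rho_L, double L) {
  int k = (int)R::rpois(rho_L);
  bool start2 = unif_rand() < 0.5;
  if (k == 0) return start2 ? h2 : h1;
  std::vector<double> br(k);
  for (int i = 0; i < k; ++i) br[i] = unif_rand() * L;
  std::sort(br.begin(), br.end());
  Hap out;
  out.reserve(std::max(h1.size(), h2.size()));
  const Hap *cur = start2 ? &h2 : &h1;
  const Hap *oth = start2 ? &h1 : &h2;
  double lo = 0.0;
  for (int i = 0; i <= k; ++i) {
    double hi = (i < k) ? br[i] : L;
    Hap::const_iterator a = std::lower_bound(cur->begin(), cur->end(), lo);
    Hap::const_iterator b = std::lower_bound(cur->begin(), cur->end(), hi);
    out.insert(out.end(), a, b);
    std::swap(cur, oth);
    lo = hi;
  }
  return out;
}

static void add_mutations(Hap &h, double mu_L, double L) {
  int nm = (int)R::rpois(mu_L);
  for (int i = 0; i < nm; ++i) {
    double x = unif_rand() * L;
    Hap::iterator it = std::lower_bound(h.begin(), h.end(), x);
    if (it == h.end() || *it != x) h.insert(it, x);
  }
}

// Remove mutations fixed in the whole population (they are no longer
// segregating; under founding-state polarization they leave the panel).
static void prune_fixed(std::vector<Hap> &pop, double keep_pos) {
  int nhap = (int)pop.size();
  std::unordered_map<double, int> cnt;
  for (int h = 0; h < nhap; ++h)
    for (size_t i = 0; i < pop[h].size(); ++i) cnt[pop[h][i]]++;
  std::vector<double> fixed;
  for (std::unordered_map<double, int>::iterator it = cnt.begin();
       it != cnt.end(); ++it)
    if (it->second == nhap && it->first != keep_pos) fixed.push_back(it->first);
  if (fixed.empty()) return;
  std::sort(fixed.begin(), fixed.end());
  for (int h = 0; h < nhap; ++h) {
    Hap &v = pop[h];
    Hap keep;
    keep.reserve(v.size());
    for (size_t i = 0; i < v.size(); ++i)
      if (!std::binary_search(fixed.begin(), fixed.end(), v[i]))
        keep.push_back(v[i]);
    v.swap(keep);
  }
}

static double sel_count(const std::vector<Hap> &pop, double sel_pos) {
  int c = 0;
  for (size_t h = 0; h < pop.size(); ++h)
    if (carries(pop[h], sel_pos)) ++c;
  return (double)c;
}

static int pick_uniform(int n) {
  int j = (int)(unif_rand() * n);
  return j >= n ? n - 1 : j;
}

static int pick_weighted(const std::vector<double> &cumw) {
  double u = unif_rand() * cumw.back();
  return (int)(std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin());
}

static void next_generation(std::vector<Hap> &pop, double L, double mu,
                            double rho, double s, double sel_pos) {
  int nhap = (int)pop.size();
  int N = nhap / 2;
  double mu_L = mu * L, rho_L = rho * L;
  bool selection = s > 0.0;
  std::vector<double> cumw;
  if (selection) {
    cumw.resize(N);
    double acc = 0.0;
    for (int d = 0; d < N; ++d) {
      int g = (carries(pop[2 * d], sel_pos) ? 1 : 0) +
              (carries(pop[2 * d + 1], sel_pos) ? 1 : 0);
      acc += 1.0 + 0.5 * s * g;  // additive fitness: 1, 1+s/2, 1+s
      cumw[d] = acc;
    }
  }
  std::vector<Hap> next(nhap);
  for (int j = 0; j < N; ++j) {
    for (int c = 0; c < 2; ++c) {
      int p = selection ? pick_weighted(cumw) : pick_uniform(N);
      Hap gam = make_gamete(pop[2 * p], pop[2 * p + 1], rho_L, L);
      add_mutations(gam, mu_L, L);
      next[2 * j + c].swap(gam);
    }
  }
  pop.swap(next);
}

static std::vector<Hap> from_list(List haps) {
  int n = haps.size();
  std::vector<Hap> pop(n);
  for (int i = 0; i < n; ++i) {
    NumericVector v = haps[i];
    pop[i].assign(v.begin(), v.end());
  }
  return pop;
}

static List to_list(const std::vector<Hap> &pop) {
  List out(pop.size());
  for (size_t i = 0; i < pop.size(); ++i) out[i] = NumericVector(pop[i].begin(), pop[i].end());
  return out;
}

// Evolve a population of phased haplotypes for up to `gens` generations.
// If s > 0, selection acts additively on the derived allele at sel_pos.
// Stops early when the population frequency at sel_pos reaches freq_stop
// (if freq_stop >= 0) or when the selected allele is lost (if s > 0).
// [[Rcpp::export]]
List wf_evolve_cpp(List haps, double L, double mu, double rho, int gens,
                   double s, double sel_pos, double freq_stop,
                   int prune_every) {
  std::vector<Hap> pop = from_list(haps);
  int nhap = (int)pop.size();
  int ran = 0;
  bool track = (s > 0.0) || (freq_stop >= 0.0);
  double f = track ? sel_count(pop, sel_pos) / nhap : 0.0;
  for (int g = 0; g < gens; ++g) {
    next_generation(pop, L, mu, rho, s, sel_pos);
    ++ran;
    if (track) {
      f = sel_count(pop, sel_pos) / nhap;
      if (freq_stop >= 0.0 && f >= freq_stop) break;
      if (s > 0.0 && f == 0.0) break;
    }
    if (prune_every > 0 && (g + 1) % prune_every == 0)
      prune_fixed(pop, track ? sel_pos : -1.0);
    if ((g & 255) == 0) Rcpp::checkUserInterrupt();
  }
  prune_fixed(pop, track ? sel_pos : -1.0);
  return List::create(_["haps"] = to_list(pop), _["gens_run"] = ran,
                      _["sel_freq"] = track ? f : NA_REAL);
}

// Inject a derived allele at sel_pos into one random haplotype (frequency
// 1/(2N)); errors if any haplotype already carries it.
// [[Rcpp::export]]
List wf_inject_cpp(List haps, double sel_pos) {
  std::vector<Hap> pop = from_list(haps);
  for (size_t h = 0; h < pop.size(); ++h)
    if (carries(pop[h], sel_pos)) stop("position already segregating");
  int h = pick_uniform((int)pop.size());
  Hap &v = pop[h];
  v.insert(std::lower_bound(v.begin(), v.end(), sel_pos), sel_pos);
  return to_list(pop);
}
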