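#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Forward-in-time Wright-Fisher evolution of a diploid population.
//
// `chrom` holds one chromosome per row (2 rows per diploid, rows 2i and
// 2i+1), alleles coded 0/1.  Each generation draws parents proportional to
// fitness, applies selfing with probability `selfing`, recombines gametes
// with per-interval probability `r` (crossover count ~ Binomial(S-1, r)),
// and mutates with per-site probability `mu` (0 <-> 1 flips, keeping sites
// biallelic).  Fitness at the focal site is 1, 1+s/2, 1+s for genotypes
// 0/1/2 when `select` is true, otherwise neutral.
//
// All randomness comes from R's RNG stream so set.seed() in R governs the
// whole simulation.

static inline int pick_parent(const std::vector<double> &cumw) {
  double u = unif_rand() * cumw.back();
  // binary search for first cumw[i] > u
  int lo = 0, hi = (int)cumw.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cumw[mid] > u) hi = mid; else lo = mid + 1;
  }
  return lo;
}

// Produce one gamete from diploid parent `p` of population `pop` into `out`.
static void make_gamete(const std::vector<uint8_t> &pop, int S, int p,
                        double r, std::vector<uint8_t> &out, size_t out_off) {
  const uint8_t *c0 = &pop[(size_t)(2 * p) * S];
  const uint8_t *c1 = &pop[(size_t)(2 * p + 1) * S];
  int ncross = (int)R::rbinom((double)(S - 1), r);
  int cur = (unif_rand() < 0.5) ? 0 : 1;
  uint8_t *dst = &out[out_off];
  if (ncross == 0) {
    std::memcpy(dst, cur == 0 ? c0 : c1, S);
    return;
  }
  // distinct crossover breakpoints in [1, S-1]; breakpoint b means the
  // template switches between sites b-1 and b
  std::vector<int> bp;
  bp.reserve(ncross);
  while ((int)bp.size() < ncross) {
    int b = 1 + (int)(unif_rand() * (S - 1));
    if (b > S - 1) b = S - 1;
    bool dup = false;
    for (int x : bp) if (x == b) { dup = true; break; }
    if (!dup) bp.push_back(b);
  }
  std::sort(bp.begin(), bp.end());
  int start = 0;
  for (int k = 0; k <= ncross; ++k) {
    int end = (k == ncross) ? S : bp[k];
    std::memcpy(dst + start, (cur == 0 ? c0 : c1) + start, end - start);
    cur = 1 - cur;
    start = end;
  }
}

// [[Rcpp::export]]
IntegerMatrix wf_evolve_cpp(IntegerMatrix chrom, int n_diploid, int n_gens,
                            double mu, double r, double selfing,
                            double s, int focal0, bool select) {
  const int S = chrom.ncol();
  const int n_in = chrom.nrow() / 2;
  if (chrom.nrow() % 2 != 0) stop("chromosome count must be even");

  // row-major byte buffers (chromosome-contiguous)
  std::vector<uint8_t> cur((size_t)2 * std::max(n_in, n_diploid) * S);
  std::vector<uint8_t> nxt((size_t)2 * n_diploid * S);
  for (int i = 0; i < 2 * n_in; ++i)
    for (int j = 0; j < S; ++j)
      cur[(size_t)i * S + j] = (uint8_t)chrom(i, j);

  int n_cur = n_in;
  std::vector<double> cumw;

  for (int g = 0; g < n_gens; ++g) {
    // fitness and cumulative weights over current diploids
    cumw.assign(n_cur, 0.0);
    double acc = 0.0;
    for (int i = 0; i < n_cur; ++i) {
      double w = 1.0;
      if (select) {
        int dose = cur[(size_t)(2 * i) * S + focal0] +
                   cur[(size_t)(2 * i + 1) * S + focal0];
        w = 1.0 + 0.5 * s * dose;
      }
      acc += w;
      cumw[i] = acc;
    }

    for (int j = 0; j < n_diploid; ++j) {
      int p1 = pick_parent(cumw);
      int p2 = (unif_rand() < selfing) ? p1 : pick_parent(cumw);
      make_gamete(cur, S, p1, r, nxt, (size_t)(2 * j) * S);
      make_gamete(cur, S, p2, r, nxt, (size_t)(2 * j + 1) * S);
    }

    // mutation: per-chromosome count ~ Binomial(S, mu), flip at random sites
    if (mu > 0) {
      for (int i = 0; i < 2 * n_diploid; ++i) {
        int nm = (int)R::rbinom((double)S, mu);
        for (int k = 0; k < nm; ++k) {
          int site = (int)(unif_rand() * S);
          if (site >= S) site = S - 1;
          size_t idx = (size_t)i * S + site;
          nxt[idx] = 1 - nxt[idx];
        }
      }
    }

    std::swap(cur, nxt);
    n_cur = n_diploid;
    if (nxt.size() < (size_t)2 * n_diploid * S)
      nxt.resize((size_t)2 * n_diploid * S);
  }

  IntegerMatrix out(2 * n_cur, S);
  for (int i = 0; i < 2 * n_cur; ++i)
    for (int j = 0; j < S; ++j)
      out(i, j) = cur[(size_t)i * S + j];
  return out;
}
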