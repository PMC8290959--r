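#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Integrated EHH (iHH) for a set of core sites.
//
// EHH at extent e is the probability that two random chromosomes of the
// population carry identical allele strings over the sites strictly between
// the core and e, inclusive of e (the core site itself does not partition:
// EHH at distance 0 is 1 by definition).  The curve is integrated by the
// trapezoid rule over physical distance in bp, separately left and right,
// each flank truncated at the first extent where EHH < `truncation` or cut
// where an inter-site gap exceeds `max_gap`.  If a flank reaches the
// chromosome edge before truncation: with clip_edge the partial area is
// kept (and the clip counted), otherwise the whole iHH is NaN.
//
// `alleles` is chromosomes x sites with entries 0/1/NA; chromosomes hitting
// a missing allele leave the computation from that extent on.

struct FlankResult {
  double area;
  bool truncated;   // EHH dropped below the cutoff before the edge
  bool degenerate;  // fewer than 2 chromosomes left
};

static FlankResult flank_area(const IntegerMatrix &alleles,
                              const IntegerVector &pos, int core, int step,
                              double truncation, double max_gap) {
  const int n = alleles.nrow(), S = alleles.ncol();
  FlankResult res = {0.0, false, false};
  std::vector<int> grp(n, 0);        // group id per chromosome; -1 = removed
  int n_act = n;
  if (n_act < 2) { res.degenerate = true; return res; }

  double ehh_prev = 1.0, dist_prev = 0.0;
  int prev_pos = pos[core];
  int n_groups = 1;

  for (int e = core + step; e >= 0 && e < S; e += step) {
    double gap = std::abs((double)pos[e] - prev_pos);
    if (gap > max_gap) { res.truncated = true; return res; }  // cut at gap start
    // drop chromosomes missing at e, refine groups by allele at e
    std::vector<int> remap(2 * n_groups, -1);
    int next_id = 0;
    for (int i = 0; i < n; ++i) {
      if (grp[i] < 0) continue;
      int a = alleles(i, e);
      if (a == NA_INTEGER) { grp[i] = -1; --n_act; continue; }
      int key = 2 * grp[i] + a;
      if (remap[key] < 0) remap[key] = next_id++;
      grp[i] = remap[key];
    }
    n_groups = next_id;
    if (n_act < 2) { res.degenerate = true; return res; }

    std::vector<double> cnt(n_groups, 0.0);
    for (int i = 0; i < n; ++i) if (grp[i] >= 0) cnt[grp[i]] += 1.0;
    double num = 0.0;
    for (double c : cnt) num += c * (c - 1.0) / 2.0;
    double ehh = num / ((double)n_act * (n_act - 1.0) / 2.0);

    double dist = std::abs((double)pos[e] - pos[core]);
    res.area += 0.5 * (ehh_prev + ehh) * (dist - dist_prev);
    ehh_prev = ehh; dist_prev = dist; prev_pos = pos[e];
    if (ehh < truncation) { res.truncated = true; return res; }
  }
  return res;  // chromosome edge reached
}

// [[Rcpp::export]]
NumericVector ihh_scan_cpp(IntegerMatrix alleles, IntegerVector pos,
                           IntegerVector cores, double truncation,
                           double max_gap, bool clip_edge) {
  const int nc = cores.size();
  NumericVector out(nc);
  int n_clipped = 0;
  for (int k = 0; k < nc; ++k) {
    FlankResult L = flank_area(alleles, pos, cores[k], -1, truncation, max_gap);
    FlankResult R_ = flank_area(alleles, pos, cores[k], +1, truncation, max_gap);
    if (L.degenerate || R_.degenerate) { out[k] = NA_REAL; continue; }
    bool clipped = !L.truncated || !R_.truncated;
    if (clipped && !clip_edge) { out[k] = NA_REAL; continue; }
    if (clipped) ++n_clipped;
    out[k] = L.area + R_.area;
  }
  out.attr("n_clipped") = n_clipped;
  return out;
}
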