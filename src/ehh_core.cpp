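#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Extended haplotype homozygosity. At marker distance x from a core SNP the
// carriers of the focal allele are partitioned by their allele string over the
// markers between the core (exclusive) and x (inclusive); EHH(x) is the
// probability that two random carriers fall in the same group:
//   EHH(x) = sum_k C(c_k, 2) / C(n, 2).
// EHH at the core itself is 1 (single group). Curves are truncated at the
// first marker where EHH drops below `floor_val` (that marker is included in
// the returned curve so the crossing is visible; integration stops before it).

struct EhhScratch {
  std::vector<int> grp, remap, cnt;
  void init(int n) {
    grp.assign(n, 0);
    if ((int)remap.size() < 2 * n + 2) remap.resize(2 * n + 2);
    if ((int)cnt.size() < n) cnt.resize(n);
  }
};

// advance the partition by one site; returns the new EHH value
static inline double ehh_step(const RawMatrix& haps, const std::vector<int>& car,
                              int j, EhhScratch& sc, int& ngrp) {
  int n = (int)car.size();
  for (int t = 0; t < 2 * ngrp; ++t) sc.remap[t] = -1;
  int nn = 0;
  for (int i = 0; i < n; ++i) {
    int key = 2 * sc.grp[i] + (int)haps(car[i], j);
    if (sc.remap[key] < 0) sc.remap[key] = nn++;
    sc.grp[i] = sc.remap[key];
  }
  ngrp = nn;
  for (int k = 0; k < ngrp; ++k) sc.cnt[k] = 0;
  for (int i = 0; i < n; ++i) sc.cnt[sc.grp[i]]++;
  double num = 0.0;
  for (int k = 0; k < ngrp; ++k) num += (double)sc.cnt[k] * (sc.cnt[k] - 1) / 2.0;
  return num / ((double)n * (n - 1) / 2.0);
}

static void ehh_flank(const RawMatrix& haps, const std::vector<int>& car,
                      int core, int dir, double floor_val, EhhScratch& sc,
                      std::vector<int>& idx, std::vector<double>& val) {
  int S = haps.ncol();
  sc.init((int)car.size());
  int ngrp = 1;
  for (int j = core + dir; j >= 0 && j < S; j += dir) {
    double e = ehh_step(haps, car, j, sc, ngrp);
    idx.push_back(j);
    val.push_back(e);
    if (e < floor_val) break;
  }
}

// [[Rcpp::export]]
List ehh_core_cpp(RawMatrix haps, IntegerVector carriers, int core, double floor_val) {
  std::vector<int> car(carriers.begin(), carriers.end());  // 0-based rows
  EhhScratch sc;
  std::vector<int> li, ri;
  std::vector<double> lv, rv;
  ehh_flank(haps, car, core, -1, floor_val, sc, li, lv);
  ehh_flank(haps, car, core, +1, floor_val, sc, ri, rv);
  return List::create(_["left_idx"] = IntegerVector(li.begin(), li.end()),
                      _["left_ehh"] = NumericVector(lv.begin(), lv.end()),
                      _["right_idx"] = IntegerVector(ri.begin(), ri.end()),
                      _["right_ehh"] = NumericVector(rv.begin(), rv.end()));
}

// integrated EHH for one flank: trapezoid against bp, starting at (core, 1),
// accumulating only while EHH stays >= floor_val.
// `poly[j]` marks sites polymorphic within the carriers' population: sites
// monomorphic there cannot split any group, so EHH is unchanged across them
// and the trapezoid contribution reduces to e * gap — they are skipped
// without touching the partition (identical result, much faster).
static double ihh_flank(const RawMatrix& haps, const std::vector<int>& car,
                        const NumericVector& pos, const LogicalVector& poly,
                        int core, int dir, double floor_val, double max_gap,
                        EhhScratch& sc) {
  int n = (int)car.size();
  int S = haps.ncol();
  sc.init(n);
  int ngrp = 1;
  double area = 0.0, prev_e = 1.0, prev_p = pos[core];
  for (int j = core + dir; j >= 0 && j < S; j += dir) {
    double gap = std::abs(pos[j] - prev_p);
    if (max_gap > 0 && gap > max_gap) break;
    double e = poly[j] ? ehh_step(haps, car, j, sc, ngrp) : prev_e;
    if (e < floor_val) break;
    area += 0.5 * (e + prev_e) * gap;
    prev_e = e;
    prev_p = pos[j];
    if (ngrp == n) break;  // fully broken up: EHH is 0 from here on
  }
  return area;
}

// iHH for ancestral and derived carriers at each core SNP (for iHS);
// poly flags sites polymorphic within the scanned population
// [[Rcpp::export]]
NumericMatrix ihs_ihh_cpp(RawMatrix haps, NumericVector pos, IntegerVector cores,
                          double floor_val, double max_gap, LogicalVector poly) {
  int nh = haps.nrow();
  EhhScratch sc;
  NumericMatrix out(cores.size(), 2);
  std::vector<int> anc, der;
  for (int t = 0; t < cores.size(); ++t) {
    int core = cores[t];
    anc.clear(); der.clear();
    for (int i = 0; i < nh; ++i) {
      if (haps(i, core) == 0x00) anc.push_back(i); else der.push_back(i);
    }
    out(t, 0) = (anc.size() >= 2) ? ihh_flank(haps, anc, pos, poly, core, -1, floor_val, max_gap, sc) +
                                    ihh_flank(haps, anc, pos, poly, core, +1, floor_val, max_gap, sc)
                                  : NA_REAL;
    out(t, 1) = (der.size() >= 2) ? ihh_flank(haps, der, pos, poly, core, -1, floor_val, max_gap, sc) +
                                    ihh_flank(haps, der, pos, poly, core, +1, floor_val, max_gap, sc)
                                  : NA_REAL;
  }
  return out;
}

// allele-agnostic iHH over a fixed haplotype set at each core SNP (for XP-EHH)
// [[Rcpp::export]]
NumericVector pop_ihh_cpp(RawMatrix haps, NumericVector pos, IntegerVector rows,
                          IntegerVector cores, double floor_val, double max_gap,
                          LogicalVector poly) {
  std::vector<int> car(rows.begin(), rows.end());
  EhhScratch sc;
  NumericVector out(cores.size());
  for (int t = 0; t < cores.size(); ++t) {
    out[t] = ihh_flank(haps, car, pos, poly, cores[t], -1, floor_val, max_gap, sc) +
             ihh_flank(haps, car, pos, poly, cores[t], +1, floor_val, max_gap, sc);
  }
  return out;
}
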