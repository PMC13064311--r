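#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Forward-in-time Wright-Fisher core. Discrete non-overlapping generations,
// diploid individuals, per-gamete Poisson crossovers (no interference) and
// Poisson mutations (infinite-sites: every mutation creates a new biallelic
// site at a previously unused integer position; allele 1 is always derived).
// Optional: symmetric two-deme migration, additive viability selection at one
// sweep site, biased full-sib mating, exact pedigree kinship tracking.
// All randomness comes from R's RNG so set.seed() makes runs bit-identical.
//
// Haplotypes are kept in one contiguous row-major buffer per chromosome
// (2N rows of S bytes); columns are purged of lost/fixed sites every few
// generations, with fixed derived positions recorded.

struct Chrom {
  std::vector<uint8_t> data;   // 2N x S row-major
  int S;
  std::vector<int> pos;        // site positions (bp, 1-based), unsorted
  std::unordered_set<int> used;   // positions in use (segregating + fixed)
  std::vector<int> fixed;      // positions fixed for the derived allele
  double len;
};

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

static inline int sample_cum(const std::vector<double>& cum) {
  double u = unif_rand() * cum.back();
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

// build one gamete from a parent's two haplotype rows
static void make_gamete(const uint8_t* a, const uint8_t* b, const std::vector<int>& pos,
                        int S, double len, double rec, uint8_t* out) {
  int nco = (rec > 0) ? (int)R::rpois(rec * len) : 0;
  int start = (unif_rand() < 0.5) ? 0 : 1;
  if (nco == 0) {
    std::memcpy(out, start ? b : a, S);
    return;
  }
  double bp[8];
  std::vector<double> bpv;
  double* bpp = bp;
  if (nco > 8) { bpv.resize(nco); bpp = bpv.data(); }
  for (int i = 0; i < nco; ++i) bpp[i] = unif_rand() * len;
  std::sort(bpp, bpp + nco);
  // parity of breakpoints left of a site decides its source haplotype
  if (nco == 1) {
    const uint8_t* s0 = start ? b : a;
    const uint8_t* s1 = start ? a : b;
    double bp0 = bpp[0];
    for (int j = 0; j < S; ++j)
      out[j] = (pos[j] > bp0) ? s1[j] : s0[j];
    return;
  }
  for (int j = 0; j < S; ++j) {
    double p = (double)pos[j];
    int k = 0;
    for (int t = 0; t < nco; ++t) { if (bpp[t] <= p) ++k; else break; }
    out[j] = ((start + k) & 1) ? b[j] : a[j];
  }
}

// [[Rcpp::export]]
List wf_evolve_cpp(List haps_in, List pos_in, NumericVector chrom_len, List fixed_in,
                   IntegerVector deme_of_ind, IntegerVector n_offspring,
                   int n_gens, double mu, double rec, double mig, double sib_prob,
                   int sweep_chrom, double sweep_pos, double sweep_s, double sweep_h,
                   bool track_pedigree, NumericMatrix kinship_in, IntegerVector famid_in) {
  int n_chrom = haps_in.size();
  std::vector<Chrom> chrom(n_chrom);
  int n_hap0 = 0;
  for (int c = 0; c < n_chrom; ++c) {
    RawMatrix m = haps_in[c];
    NumericVector p = pos_in[c];
    IntegerVector fx = fixed_in[c];
    n_hap0 = m.nrow();
    chrom[c].len = chrom_len[c];
    chrom[c].S = m.ncol();
    chrom[c].pos.assign(p.begin(), p.end());
    chrom[c].data.assign((size_t)m.nrow() * m.ncol(), 0);
    for (int i = 0; i < m.nrow(); ++i)        // R matrices are column-major
      for (int j = 0; j < m.ncol(); ++j)
        chrom[c].data[(size_t)i * m.ncol() + j] = m(i, j);
    for (int j = 0; j < (int)p.size(); ++j) chrom[c].used.insert((int)p[j]);
    for (int j = 0; j < fx.size(); ++j) {
      chrom[c].fixed.push_back(fx[j]);
      chrom[c].used.insert(fx[j]);
    }
  }
  int n_ind = n_hap0 / 2;
  int n_demes = n_offspring.size();
  std::vector<int> deme(deme_of_ind.begin(), deme_of_ind.end());
  std::vector<int> famid(n_ind);
  if (famid_in.size() == n_ind) famid.assign(famid_in.begin(), famid_in.end());
  else for (int i = 0; i < n_ind; ++i) famid[i] = -1 - i;

  bool ped = track_pedigree;
  std::vector<double> K;  // kinship, row-major n_ind x n_ind
  std::vector<double> Fped(n_ind, 0.0);
  if (ped) {
    K.assign((size_t)n_ind * n_ind, 0.0);
    if (kinship_in.nrow() == n_ind) {
      for (int i = 0; i < n_ind; ++i)
        for (int j = 0; j < n_ind; ++j) K[(size_t)i * n_ind + j] = kinship_in(i, j);
    } else {
      for (int i = 0; i < n_ind; ++i) K[(size_t)i * n_ind + i] = 0.5;
    }
    for (int i = 0; i < n_ind; ++i) Fped[i] = 2.0 * K[(size_t)i * n_ind + i] - 1.0;
  }

  int n_ind_new = 0;
  for (int d = 0; d < n_demes; ++d) n_ind_new += n_offspring[d];

  for (int g = 0; g < n_gens; ++g) {
    std::vector<std::vector<int> > members(n_demes);
    for (int i = 0; i < n_ind; ++i) members[deme[i]].push_back(i);

    // fitness at the sweep site, per-deme cumulative weights
    int swc = -1;
    if (sweep_chrom >= 0) {
      for (int j = 0; j < chrom[sweep_chrom].S; ++j)
        if (chrom[sweep_chrom].pos[j] == (int)sweep_pos) { swc = j; break; }
    }
    std::vector<std::vector<double> > cum(n_demes);
    if (swc >= 0) {
      const Chrom& sc = chrom[sweep_chrom];
      for (int d = 0; d < n_demes; ++d) {
        double acc = 0.0;
        cum[d].resize(members[d].size());
        for (size_t k = 0; k < members[d].size(); ++k) {
          int i = members[d][k];
          int gt = sc.data[(size_t)(2 * i) * sc.S + swc] +
                   sc.data[(size_t)(2 * i + 1) * sc.S + swc];
          double w = (gt == 2) ? 1.0 + sweep_s : (gt == 1 ? 1.0 + sweep_h * sweep_s : 1.0);
          acc += w;
          cum[d][k] = acc;
        }
      }
    }

    // choose parents. Populations with sib-biased mating reproduce through
    // random monogamous couples (so full-sib pairs exist in every
    // generation); otherwise parents are two distinct random individuals.
    std::vector<int> mom(n_ind_new), dad(n_ind_new), newdeme(n_ind_new), newfam(n_ind_new);
    int o = 0;
    for (int d = 0; d < n_demes; ++d) {
      const std::vector<int>& mem = members[d];
      int nm = (int)mem.size();
      if (nm < 2 && n_offspring[d] > 0) stop("deme with fewer than 2 individuals cannot reproduce");
      std::vector<int> shuffled;
      int n_couple = 0;
      if (sib_prob > 0) {
        shuffled = mem;
        for (int q = nm - 1; q > 0; --q) std::swap(shuffled[q], shuffled[runif_int(q + 1)]);
        n_couple = nm / 2;
      }
      for (int k = 0; k < n_offspring[d]; ++k, ++o) {
        int pi = -1, pj = -1;
        bool sib_done = false;
        if (sib_prob > 0 && unif_rand() < sib_prob) {
          // pick an individual, mate it with a full sib if one exists
          int a = mem[runif_int(nm)];
          std::vector<int> sibs;
          for (int q = 0; q < nm; ++q)
            if (mem[q] != a && famid[mem[q]] == famid[a] && famid[a] >= 0) sibs.push_back(mem[q]);
          if (!sibs.empty()) {
            pi = a;
            pj = sibs[runif_int((int)sibs.size())];
            sib_done = true;
          }
        }
        if (!sib_done && sib_prob > 0) {
          int cp = runif_int(n_couple);
          pi = shuffled[2 * cp];
          pj = shuffled[2 * cp + 1];
          sib_done = true;
        }
        if (!sib_done) {
          int d1 = d, d2 = d;
          if (mig > 0 && n_demes == 2) {
            if (unif_rand() < mig) d1 = 1 - d;
            if (unif_rand() < mig) d2 = 1 - d;
          }
          if (swc >= 0) {
            pi = members[d1][sample_cum(cum[d1])];
            do { pj = members[d2][sample_cum(cum[d2])]; } while (pj == pi);
          } else {
            pi = members[d1][runif_int((int)members[d1].size())];
            do { pj = members[d2][runif_int((int)members[d2].size())]; } while (pj == pi);
          }
        }
        mom[o] = pi; dad[o] = pj; newdeme[o] = d;
        int lo = std::min(pi, pj), hi = std::max(pi, pj);
        newfam[o] = lo * n_ind + hi;
      }
    }

    // gametes; mutations drawn as one Poisson batch per chromosome and
    // assigned to uniformly random gametes (equivalent to per-gamete Poisson)
    bool purge_now = (g % 8 == 7) || (g == n_gens - 1);
    for (int c = 0; c < n_chrom; ++c) {
      Chrom& C = chrom[c];
      int S_old = C.S;
      int n_mut = (mu > 0) ? (int)R::rpois(mu * C.len * 2.0 * n_ind_new) : 0;
      int S_new = S_old + n_mut;
      std::vector<uint8_t> nd((size_t)2 * n_ind_new * S_new, 0);
      for (int k = 0; k < n_ind_new; ++k) {
        int par[2] = { mom[k], dad[k] };
        for (int h = 0; h < 2; ++h) {
          if (S_old > 0)
            make_gamete(&C.data[(size_t)(2 * par[h]) * S_old],
                        &C.data[(size_t)(2 * par[h] + 1) * S_old],
                        C.pos, S_old, C.len, rec,
                        &nd[(size_t)(2 * k + h) * S_new]);
        }
      }
      for (int t = 0; t < n_mut; ++t) {
        int p;
        do { p = 1 + runif_int((int)C.len); } while (C.used.count(p));
        C.used.insert(p);
        C.pos.push_back(p);
        nd[(size_t)runif_int(2 * n_ind_new) * S_new + S_old + t] = 1;
      }
      if (purge_now && S_new > 0) {
        std::vector<int> cnt(S_new, 0);
        for (int r = 0; r < 2 * n_ind_new; ++r) {
          const uint8_t* hp = &nd[(size_t)r * S_new];
          for (int j = 0; j < S_new; ++j) cnt[j] += hp[j];
        }
        std::vector<int> keep;
        keep.reserve(S_new);
        bool sweep_here = (sweep_chrom == c);
        for (int j = 0; j < S_new; ++j) {
          bool is_sweep = sweep_here && C.pos[j] == (int)sweep_pos;
          if (cnt[j] == 0) {
            if (!is_sweep) C.used.erase(C.pos[j]);
            else keep.push_back(j);  // keep a lost sweep column: caller sees freq 0
          } else if (cnt[j] == 2 * n_ind_new && !is_sweep) {
            C.fixed.push_back(C.pos[j]);
          } else {
            keep.push_back(j);
          }
        }
        if ((int)keep.size() < S_new) {
          int S_k = (int)keep.size();
          std::vector<int> npos(S_k);
          for (int j = 0; j < S_k; ++j) npos[j] = C.pos[keep[j]];
          std::vector<uint8_t> nd2((size_t)2 * n_ind_new * S_k);
          for (int r = 0; r < 2 * n_ind_new; ++r) {
            const uint8_t* src = &nd[(size_t)r * S_new];
            uint8_t* dst = &nd2[(size_t)r * S_k];
            for (int j = 0; j < S_k; ++j) dst[j] = src[keep[j]];
          }
          nd.swap(nd2);
          C.pos.swap(npos);
          S_new = S_k;
        }
      }
      C.data.swap(nd);
      C.S = S_new;
    }

    // pedigree kinship
    if (ped) {
      std::vector<double> Knew((size_t)n_ind_new * n_ind_new, 0.0);
      std::vector<double> Fnew(n_ind_new, 0.0);
      for (int a = 0; a < n_ind_new; ++a) {
        Fnew[a] = K[(size_t)mom[a] * n_ind + dad[a]];
        for (int b = 0; b <= a; ++b) {
          double v;
          if (a == b) v = 0.5 * (1.0 + Fnew[a]);
          else v = 0.25 * (K[(size_t)mom[a] * n_ind + mom[b]] + K[(size_t)mom[a] * n_ind + dad[b]] +
                           K[(size_t)dad[a] * n_ind + mom[b]] + K[(size_t)dad[a] * n_ind + dad[b]]);
          Knew[(size_t)a * n_ind_new + b] = v;
          Knew[(size_t)b * n_ind_new + a] = v;
        }
      }
      K.swap(Knew);
      Fped.assign(Fnew.begin(), Fnew.end());
    }
    famid.assign(newfam.begin(), newfam.end());
    deme.assign(newdeme.begin(), newdeme.end());
    n_ind = n_ind_new;
  }

  if (!ped) Fped.assign(n_ind, 0.0);

  // pack results
  List out_haps(n_chrom), out_pos(n_chrom), out_fixed(n_chrom);
  double sweep_freq = NA_REAL;
  for (int c = 0; c < n_chrom; ++c) {
    const Chrom& C = chrom[c];
    RawMatrix m(2 * n_ind, C.S);
    for (int i = 0; i < 2 * n_ind; ++i)
      for (int j = 0; j < C.S; ++j) m(i, j) = C.data[(size_t)i * C.S + j];
    out_haps[c] = m;
    out_pos[c] = IntegerVector(C.pos.begin(), C.pos.end());
    out_fixed[c] = IntegerVector(C.fixed.begin(), C.fixed.end());
    if (c == sweep_chrom) {
      int swc = -1;
      for (int j = 0; j < C.S; ++j) if (C.pos[j] == (int)sweep_pos) { swc = j; break; }
      if (swc >= 0) {
        int tot = 0;
        for (int i = 0; i < 2 * n_ind; ++i) tot += C.data[(size_t)i * C.S + swc];
        sweep_freq = (double)tot / (2.0 * n_ind);
      } else {
        bool fx = std::find(C.fixed.begin(), C.fixed.end(), (int)sweep_pos) != C.fixed.end();
        sweep_freq = fx ? 1.0 : 0.0;
      }
    }
  }
  NumericMatrix Kout(ped ? n_ind : 0, ped ? n_ind : 0);
  if (ped)
    for (int i = 0; i < n_ind; ++i)
      for (int j = 0; j < n_ind; ++j) Kout(i, j) = K[(size_t)i * n_ind + j];
  return List::create(_["haps"] = out_haps, _["pos"] = out_pos, _["fixed"] = out_fixed,
                      _["deme"] = IntegerVector(deme.begin(), deme.end()),
                      _["famid"] = IntegerVector(famid.begin(), famid.end()),
                      _["kinship"] = Kout,
                      _["ped_f"] = NumericVector(Fped.begin(), Fped.end()),
                      _["sweep_freq"] = sweep_freq);
}
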