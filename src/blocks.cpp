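#include <Rcpp.h>
#include <map>
#include <vector>
#include <stdint.h>
using namespace Rcpp;

// Sliding-window haplotype block enumeration with canonical strain-group
// labelling and global partition de-duplication.
//
// geno: variants x strains integer matrix, codes 0/1, NA_INTEGER = missing.
// chrom: integer chromosome code per variant; variants of one chromosome
//        must be contiguous (the R wrapper guarantees this).
// window_sizes: window widths; windows never span chromosome boundaries.
//
// A strain missing any call in the window gets no label. A window is kept
// iff, over labelled strains, 2 <= n_groups <= max_groups, every group has
// >= min_group_size members, and the labelled fraction of all strains is
// >= min_nonmissing_frac. Labels are canonical: the first labelled strain
// (panel column order) gets group 0, the next new allele string group 1, ...
//
// widx is a global window index (windows enumerated by window size, then
// chromosome run, then start) so callers can precompute per-window genomic
// spans once per panel and reuse them across strain subsets.
//
// Panels of up to 64 strains use a bitmask fast path: each group is carved
// out of the window's strain set with bitwise allele-mask intersections, in
// increasing-strain order, which reproduces the canonical labelling of the
// generic path exactly.

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

struct BlockOut {
  std::vector<int> start, end, w, pid, widx;
  int n_windows;
};

// generic path: arbitrary strain count
static void enumerate_generic(const IntegerMatrix& geno,
                              const std::vector<int>& run_start,
                              const std::vector<int>& run_end,
                              const IntegerVector& window_sizes,
                              int min_group_size, int max_groups,
                              double min_frac,
                              BlockOut& out,
                              std::vector<std::vector<int> >& part_labels) {
  const int S = geno.ncol();
  std::map<std::vector<int>, int> part_index;
  std::vector<int> reps, lab(S);
  int widx = 0;
  for (int wi = 0; wi < window_sizes.size(); ++wi) {
    const int w = window_sizes[wi];
    for (size_t r = 0; r < run_start.size(); ++r) {
      for (int i = run_start[r]; i + w - 1 <= run_end[r]; ++i) {
        ++widx;
        reps.clear();
        std::fill(lab.begin(), lab.end(), -1);
        bool reject = false;
        int nonmiss = 0;
        for (int s = 0; s < S && !reject; ++s) {
          bool miss = false;
          for (int j = 0; j < w; ++j)
            if (geno(i + j, s) == NA_INTEGER) { miss = true; break; }
          if (miss) continue;
          ++nonmiss;
          int g = -1;
          for (size_t q = 0; q < reps.size(); ++q) {
            const int t = reps[q];
            bool eq = true;
            for (int j = 0; j < w; ++j)
              if (geno(i + j, s) != geno(i + j, t)) { eq = false; break; }
            if (eq) { g = (int) q; break; }
          }
          if (g < 0) {
            if ((int) reps.size() == max_groups) { reject = true; break; }
            reps.push_back(s);
            g = (int) reps.size() - 1;
          }
          lab[s] = g;
        }
        if (reject) continue;
        const int k = (int) reps.size();
        if (k < 2) continue;
        if ((double) nonmiss < min_frac * (double) S - 1e-9) continue;
        std::vector<int> sizes(k, 0);
        for (int s = 0; s < S; ++s) if (lab[s] >= 0) ++sizes[lab[s]];
        bool small = false;
        for (int g = 0; g < k; ++g)
          if (sizes[g] < min_group_size) { small = true; break; }
        if (small) continue;
        int pid;
        std::map<std::vector<int>, int>::iterator it = part_index.find(lab);
        if (it == part_index.end()) {
          pid = (int) part_labels.size();
          part_index.insert(std::make_pair(lab, pid));
          part_labels.push_back(lab);
        } else pid = it->second;
        out.start.push_back(i + 1);
        out.end.push_back(i + w);
        out.w.push_back(w);
        out.pid.push_back(pid + 1);
        out.widx.push_back(widx);
      }
    }
  }
  out.n_windows = widx;
}

// bitmask path: S <= 64 strains
static void enumerate_bits(const IntegerMatrix& geno,
                           const std::vector<int>& run_start,
                           const std::vector<int>& run_end,
                           const IntegerVector& window_sizes,
                           int min_group_size, int max_groups,
                           double min_frac,
                           BlockOut& out,
                           std::vector<std::vector<int> >& part_labels) {
  const int V = geno.nrow(), S = geno.ncol();
  const uint64_t full = (S == 64) ? ~UINT64_C(0)
                                  : ((UINT64_C(1) << S) - 1);
  std::vector<uint64_t> A(V, 0), M(V, 0);   // alt-allele and missing bits
  for (int s = 0; s < S; ++s)
    for (int i = 0; i < V; ++i) {
      const int g = geno(i, s);
      if (g == NA_INTEGER) M[i] |= UINT64_C(1) << s;
      else if (g == 1) A[i] |= UINT64_C(1) << s;
    }

  std::map<std::vector<uint64_t>, int> part_index;
  std::vector<uint64_t> gmask;
  const int min_present = (int) std::ceil(min_frac * (double) S - 1e-9);
  int widx = 0;
  for (int wi = 0; wi < window_sizes.size(); ++wi) {
    const int w = window_sizes[wi];
    for (size_t r = 0; r < run_start.size(); ++r) {
      for (int i = run_start[r]; i + w - 1 <= run_end[r]; ++i) {
        ++widx;
        uint64_t miss = 0;
        for (int j = 0; j < w; ++j) miss |= M[i + j];
        uint64_t present = full & ~miss;
        if (popcount64(present) < min_present) continue;
        gmask.clear();
        uint64_t remaining = present;
        bool reject = false, small = false;
        while (remaining) {
          if ((int) gmask.size() == max_groups) { reject = true; break; }
          const int s = __builtin_ctzll(remaining);
          uint64_t members = present;
          for (int j = 0; j < w; ++j)
            members &= ((A[i + j] >> s) & 1) ? A[i + j] : ~A[i + j];
          if (popcount64(members) < min_group_size) { small = true; break; }
          gmask.push_back(members);
          remaining &= ~members;
        }
        if (reject || small) continue;
        if ((int) gmask.size() < 2) continue;
        int pid;
        std::map<std::vector<uint64_t>, int>::iterator it =
          part_index.find(gmask);
        if (it == part_index.end()) {
          pid = (int) part_labels.size();
          part_index.insert(std::make_pair(gmask, pid));
          std::vector<int> lab(S, -1);
          for (size_t g = 0; g < gmask.size(); ++g)
            for (int s2 = 0; s2 < S; ++s2)
              if ((gmask[g] >> s2) & 1) lab[s2] = (int) g;
          part_labels.push_back(lab);
        } else pid = it->second;
        out.start.push_back(i + 1);
        out.end.push_back(i + w);
        out.w.push_back(w);
        out.pid.push_back(pid + 1);
        out.widx.push_back(widx);
      }
    }
  }
  out.n_windows = widx;
}

// [[Rcpp::export(name = ".enumerate_blocks_cpp")]]
List enumerate_blocks_cpp(IntegerMatrix geno, IntegerVector chrom,
                          IntegerVector window_sizes, int min_group_size,
                          int max_groups, double min_nonmissing_frac) {
  const int V = geno.nrow(), S = geno.ncol();
  std::vector<int> run_start, run_end;
  for (int i = 0; i < V; ++i) {
    if (i == 0 || chrom[i] != chrom[i - 1]) run_start.push_back(i);
    if (i == V - 1 || chrom[i] != chrom[i + 1]) run_end.push_back(i);
  }
  BlockOut out;
  out.n_windows = 0;
  std::vector<std::vector<int> > part_labels;
  if (S <= 64)
    enumerate_bits(geno, run_start, run_end, window_sizes, min_group_size,
                   max_groups, min_nonmissing_frac, out, part_labels);
  else
    enumerate_generic(geno, run_start, run_end, window_sizes,
                      min_group_size, max_groups, min_nonmissing_frac,
                      out, part_labels);

  const int U = (int) part_labels.size();
  IntegerMatrix parts(U, S);
  for (int u = 0; u < U; ++u)
    for (int s = 0; s < S; ++s)
      parts(u, s) = part_labels[u][s] < 0 ? NA_INTEGER : part_labels[u][s];

  return List::create(
    _["start"] = wrap(out.start), _["end"] = wrap(out.end),
    _["window"] = wrap(out.w), _["part_id"] = wrap(out.pid),
    _["widx"] = wrap(out.widx), _["partitions"] = parts,
    _["n_windows"] = out.n_windows);
}

// One-way fixed-effects ANOVA of y grouped by each row of a label matrix.
// labels: U x S, canonical group codes 0..k-1, NA = strain excluded.
// y: length S, no missing values; centred internally for stability.
// Returns f, p, eta (between/total SS), mean_range (max-min group mean),
// k, n and a degenerate flag (total SS == 0). Perfect separation (zero
// within-group SS, unequal means) reports p = p_floor and eta = 1.
// [[Rcpp::export(name = ".anova_partitions_cpp")]]
List anova_partitions_cpp(IntegerMatrix labels, NumericVector y,
                          double p_floor) {
  const int U = labels.nrow(), S = labels.ncol();
  if (y.size() != S) stop("labels/y dimension mismatch");

  NumericVector f(U), p(U), eta(U), mrange(U);
  IntegerVector k(U), n(U);
  LogicalVector degen(U);
  std::vector<double> sum_g, cnt_g;
  for (int u = 0; u < U; ++u) {
    // centre on the mean of the labelled strains only: bitwise invariant
    // to dropping strains that carry no label in this partition
    double mu = 0;
    int N0 = 0;
    for (int s = 0; s < S; ++s) {
      if (labels(u, s) == NA_INTEGER) continue;
      mu += y[s];
      ++N0;
    }
    if (N0 > 0) mu /= (double) N0;
    sum_g.clear(); cnt_g.clear();
    double tot = 0, tot2 = 0;
    int N = 0;
    for (int s = 0; s < S; ++s) {
      const int g = labels(u, s);
      if (g == NA_INTEGER) continue;
      const double yc = y[s] - mu;
      if ((int) sum_g.size() <= g) { sum_g.resize(g + 1, 0.0);
                                     cnt_g.resize(g + 1, 0.0); }
      sum_g[g] += yc;
      cnt_g[g] += 1.0;
      tot += yc;
      tot2 += yc * yc;
      ++N;
    }
    int kk = 0;
    double ssb = 0, mmin = R_PosInf, mmax = R_NegInf;
    for (size_t g = 0; g < sum_g.size(); ++g) {
      if (cnt_g[g] <= 0) continue;
      ++kk;
      const double m = sum_g[g] / cnt_g[g];
      ssb += sum_g[g] * m;
      if (m < mmin) mmin = m;
      if (m > mmax) mmax = m;
    }
    const double corr = tot * tot / (double) N;
    double sst = tot2 - corr;
    ssb -= corr;
    if (ssb < 0) ssb = 0;
    double ssw = sst - ssb;
    if (ssw < 0) ssw = 0;
    k[u] = kk;
    n[u] = N;
    mrange[u] = mmax - mmin;
    if (sst <= 0) {
      degen[u] = true;
      f[u] = NA_REAL; p[u] = NA_REAL; eta[u] = NA_REAL;
      continue;
    }
    degen[u] = false;
    if (ssw == 0) {
      f[u] = R_PosInf; p[u] = p_floor; eta[u] = 1.0;
      continue;
    }
    const double df1 = kk - 1, df2 = N - kk;
    const double ff = (ssb / df1) / (ssw / df2);
    f[u] = ff;
    double pp = R::pf(ff, df1, df2, 0, 0);
    if (pp < p_floor) pp = p_floor;
    p[u] = pp;
    double e = ssb / sst;
    if (e < 0) e = 0;
    if (e > 1) e = 1;
    eta[u] = e;
  }
  return List::create(_["f"] = f, _["p"] = p, _["eta"] = eta,
                      _["mean_range"] = mrange, _["k"] = k, _["n"] = n,
                      _["degenerate"] = degen);
}
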