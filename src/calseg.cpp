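#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Needleman-Wunsch style edit-distance DP over two state vectors (1-based
// state codes).  Two-row rolling storage; O(la*lb) time, O(lb) space.
static double om_pair(const int* a, int la, const int* b, int lb,
                      const NumericMatrix& sub, double indel) {
  std::vector<double> prev(lb + 1), cur(lb + 1);
  for (int j = 0; j <= lb; ++j) prev[j] = j * indel;
  for (int i = 1; i <= la; ++i) {
    cur[0] = i * indel;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= lb; ++j) {
      double m = prev[j - 1] + sub(ai, b[j - 1] - 1);
      const double del = prev[j] + indel;
      if (del < m) m = del;
      const double ins = cur[j - 1] + indel;
      if (ins < m) m = ins;
      cur[j] = m;
    }
    std::swap(prev, cur);
  }
  return prev[lb];
}

// [[Rcpp::export(name = ".om_distance_cpp")]]
double om_distance_cpp(IntegerVector a, IntegerVector b,
                       NumericMatrix sub, double indel) {
  return om_pair(a.begin(), a.size(), b.begin(), b.size(), sub, indel);
}

// Allison-Dix bit-parallel longest-common-subsequence length for sequences of
// length <= 64.  When the substitution cost is constant with sub >= 2*indel,
// substitutions are never strictly cheaper than delete+insert, so the OM
// distance reduces to indel * (la + lb - 2*LLCS).
static int llcs_bits(const uint64_t* Sa, const int* b, int lb, int la) {
  uint64_t R = 0;
  for (int j = 0; j < lb; ++j) {
    uint64_t x = R | Sa[b[j] - 1];
    R = x & ~(x - ((R << 1) | 1ULL));
  }
  (void)la;
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(R);
#else
  int c = 0; while (R) { c += (int)(R & 1ULL); R >>= 1; } return c;
#endif
}

// Full pairwise OM matrix over the rows of `seqs` (u x L, 1-based codes).
// fastpath: use the LLCS reduction (caller guarantees validity).
// [[Rcpp::export(name = ".om_matrix_cpp")]]
NumericMatrix om_matrix_cpp(IntegerMatrix seqs, NumericMatrix sub,
                            double indel, bool fastpath, int n_states) {
  const int u = seqs.nrow(), L = seqs.ncol();
  NumericMatrix d(u, u);
  // row-major copies for cache locality
  std::vector<int> rows((size_t)u * L);
  for (int i = 0; i < u; ++i)
    for (int j = 0; j < L; ++j) rows[(size_t)i * L + j] = seqs(i, j);
  if (fastpath && L <= 64) {
    std::vector<uint64_t> masks((size_t)u * n_states, 0ULL);
    for (int i = 0; i < u; ++i)
      for (int j = 0; j < L; ++j)
        masks[(size_t)i * n_states + (rows[(size_t)i * L + j] - 1)] |=
          (1ULL << j);
    for (int i = 0; i < u; ++i) {
      const uint64_t* Si = &masks[(size_t)i * n_states];
      for (int j = i + 1; j < u; ++j) {
        const int lcs = llcs_bits(Si, &rows[(size_t)j * L], L, L);
        const double v = indel * (2.0 * L - 2.0 * lcs);
        d(i, j) = v; d(j, i) = v;
      }
      if (i % 64 == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    for (int i = 0; i < u; ++i) {
      for (int j = i + 1; j < u; ++j) {
        const double v = om_pair(&rows[(size_t)i * L], L,
                                 &rows[(size_t)j * L], L, sub, indel);
        d(i, j) = v; d(j, i) = v;
      }
      if (i % 16 == 0) Rcpp::checkUserInterrupt();
    }
  }
  return d;
}

// One BUILD + SWAP run.  first_medoid = -1 uses the canonical BUILD seed
// (weighted column-sum minimizer); >= 0 forces that point as first medoid.
static void pam_run(const NumericMatrix& d, const NumericVector& w, int k,
                    int maxit, int first_medoid,
                    std::vector<int>& med_out, std::vector<int>& n1_out,
                    std::vector<double>& d1_out, double& obj_out,
                    int& iter_out) {
  const int u = d.nrow();
  const double eps = 1e-12;
  std::vector<int> med;                 // medoid row indices (0-based), sorted
  std::vector<bool> is_med(u, false);
  std::vector<double> D(u);             // distance to nearest medoid

  // BUILD: first medoid minimizes total weighted distance (unless forced)
  {
    int best = first_medoid;
    if (best < 0) {
      double bestv = R_PosInf;
      for (int j = 0; j < u; ++j) {
        double s = 0;
        for (int i = 0; i < u; ++i) s += w[i] * d(i, j);
        if (s < bestv - eps) { bestv = s; best = j; }
      }
    }
    med.push_back(best); is_med[best] = true;
    for (int i = 0; i < u; ++i) D[i] = d(i, best);
  }
  while ((int)med.size() < k) {
    int best = -1; double bestg = -1.0;
    for (int j = 0; j < u; ++j) {
      if (is_med[j]) continue;
      double g = 0;
      for (int i = 0; i < u; ++i) {
        const double red = D[i] - d(i, j);
        if (red > 0) g += w[i] * red;
      }
      if (g > bestg + eps) { bestg = g; best = j; }
    }
    if (best < 0) { // all remaining gains zero: take lowest-index non-medoid
      for (int j = 0; j < u; ++j) if (!is_med[j]) { best = j; break; }
    }
    med.push_back(best); is_med[best] = true;
    for (int i = 0; i < u; ++i) D[i] = std::min(D[i], d(i, best));
  }
  std::sort(med.begin(), med.end());

  // nearest / second-nearest bookkeeping
  std::vector<int> n1(u);
  std::vector<double> d1(u), d2(u);
  auto refresh = [&]() {
    for (int i = 0; i < u; ++i) {
      double b1 = R_PosInf, b2 = R_PosInf; int m1 = -1;
      for (size_t t = 0; t < med.size(); ++t) {
        const double v = d(i, med[t]);
        if (v < b1 - eps) { b2 = b1; b1 = v; m1 = (int)t; }
        else if (v < b2 - eps) { b2 = v; }
      }
      n1[i] = m1; d1[i] = b1; d2[i] = b2;
    }
  };
  refresh();

  int iter = 0;
  if (k < u) {
    while (iter < maxit) {
      double bestdT = -eps; int bm = -1, bh = -1;
      for (size_t t = 0; t < med.size(); ++t) {
        for (int h = 0; h < u; ++h) {
          if (is_med[h]) continue;
          double dT = 0;
          for (int i = 0; i < u; ++i) {
            const double dih = d(i, h);
            if (n1[i] == (int)t) {
              const double alt = std::min(dih, d2[i]);
              dT += w[i] * (alt - d1[i]);
            } else if (dih < d1[i]) {
              dT += w[i] * (dih - d1[i]);
            }
          }
          if (dT < bestdT) { bestdT = dT; bm = (int)t; bh = h; }
        }
        Rcpp::checkUserInterrupt();
      }
      if (bm < 0) break;
      is_med[med[bm]] = false; is_med[bh] = true;
      med[bm] = bh;
      std::sort(med.begin(), med.end());
      refresh();
      ++iter;
    }
  }

  double obj = 0;
  for (int i = 0; i < u; ++i) obj += w[i] * d1[i];
  med_out = med; n1_out = n1; d1_out = d1; obj_out = obj; iter_out = iter;
}

// Weighted PAM: greedy BUILD then best-improvement SWAP.  Ties broken by
// lowest index throughout for bit-reproducibility.  restarts > 1 reruns the
// search with each of the first `restarts` points forced as the initial
// BUILD medoid (a deterministic multi-start that escapes the rare local
// optimum on small instances); the best objective wins, earliest on ties.
// [[Rcpp::export(name = ".pam_cpp")]]
List pam_cpp(NumericMatrix d, NumericVector w, int k, int maxit,
             int restarts) {
  const int u = d.nrow();
  std::vector<int> med, n1, bmed, bn1;
  std::vector<double> d1, bd1;
  double obj = 0, bobj = R_PosInf;
  int iter = 0, biter = 0;
  if (restarts > u) restarts = u;
  for (int s = -1; s < (restarts > 1 ? restarts : 0); ++s) {
    pam_run(d, w, k, maxit, s, med, n1, d1, obj, iter);
    if (obj < bobj - 1e-12) {
      bobj = obj; bmed = med; bn1 = n1; bd1 = d1; biter = iter;
    }
    Rcpp::checkUserInterrupt();
  }
  IntegerVector assign(u), medoids(k);
  for (int t = 0; t < k; ++t) medoids[t] = bmed[t] + 1;
  for (int i = 0; i < u; ++i) assign[i] = bn1[i] + 1;
  return List::create(_["medoids"] = medoids, _["assignment"] = assign,
                      _["objective"] = bobj, _["iterations"] = biter);
}

// Weighted silhouette widths.  a_i excludes self in a weight-corrected way
// (denominator W_own - w_i), keeping the metric invariant to weight scaling.
// [[Rcpp::export(name = ".silhouette_cpp")]]
NumericVector silhouette_cpp(NumericMatrix d, NumericVector w,
                             IntegerVector asgn, int k) {
  const int u = d.nrow();
  std::vector<double> W(k, 0.0);
  for (int i = 0; i < u; ++i) W[asgn[i] - 1] += w[i];
  NumericVector s(u);
  std::vector<double> sums(k);
  for (int i = 0; i < u; ++i) {
    std::fill(sums.begin(), sums.end(), 0.0);
    for (int j = 0; j < u; ++j) sums[asgn[j] - 1] += w[j] * d(i, j);
    const int own = asgn[i] - 1;
    const double denom = W[own] - w[i];
    if (denom <= 1e-12) { s[i] = 0.0; continue; }
    const double a = sums[own] / denom;
    double b = R_PosInf;
    for (int c = 0; c < k; ++c) {
      if (c == own || W[c] <= 0) continue;
      b = std::min(b, sums[c] / W[c]);
    }
    const double mx = std::max(a, b);
    s[i] = (mx > 0) ? (b - a) / mx : 0.0;
  }
  return s;
}

// Point-biserial correlation and Hubert's Gamma over weighted pairs.
// PBC: weighted Pearson correlation of d_ij with 1[different cluster].
// HG: (s+ - s-)/(s+ + s-) over concordant/discordant (within, between) pairs
// of pairs, computed exactly from weighted mass histograms of the distinct
// distance values (ties contribute to neither).
// [[Rcpp::export(name = ".pbc_hg_cpp")]]
List pbc_hg_cpp(NumericMatrix d, NumericVector w, IntegerVector asgn) {
  const int u = d.nrow();
  double sw = 0, sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  std::map<double, std::pair<double, double> > hist; // value -> (within, between)
  for (int i = 0; i < u; ++i) {
    for (int j = i + 1; j < u; ++j) {
      const double ww = w[i] * w[j];
      const double x = d(i, j);
      const double y = (asgn[i] != asgn[j]) ? 1.0 : 0.0;
      sw += ww; sx += ww * x; sy += ww * y;
      sxx += ww * x * x; syy += ww * y * y; sxy += ww * x * y;
      std::pair<double, double>& h = hist[x];
      if (y > 0.5) h.second += ww; else h.first += ww;
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  bool degenerate = false;
  double pbc = 0.0;
  const double vx = sxx - sx * sx / sw, vy = syy - sy * sy / sw;
  if (vx > 1e-12 && vy > 1e-12) {
    pbc = (sxy - sx * sy / sw) / std::sqrt(vx * vy);
  } else degenerate = true;

  double splus = 0, sminus = 0, cumW = 0, totW = 0;
  for (std::map<double, std::pair<double, double> >::iterator it = hist.begin();
       it != hist.end(); ++it) totW += it->second.first;
  for (std::map<double, std::pair<double, double> >::iterator it = hist.begin();
       it != hist.end(); ++it) {
    const double within = it->second.first, between = it->second.second;
    splus += between * cumW;               // within pairs strictly smaller
    sminus += between * (totW - cumW - within); // within strictly larger
    cumW += within;
  }
  double hg = 0.0;
  if (splus + sminus > 1e-12) hg = (splus - sminus) / (splus + sminus);
  else degenerate = true;
  return List::create(_["pbc"] = pbc, _["hg"] = hg,
                      _["degenerate"] = degenerate);
}
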