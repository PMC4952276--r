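// Maximal information coefficient (MIC) via the MINE grid-search
// approximation: for every grid shape (p columns, q rows) with p*q <= B =
// n^alpha, the y-axis is equipartitioned and the x-axis partition is
// optimised by dynamic programming over "clumps" (maximal runs of x-sorted
// points sharing a row, never splitting tied x values); both orientations
// are searched and the largest normalised mutual information is returned.
//
// All cell counts are integers, so entropies are assembled from a
// precomputed m*log(m) table; the per-column profile phi is built
// incrementally while sweeping the right boundary.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// group points into at most q contiguous groups of near-equal size along
// the sort order `ord` of values `v`, keeping tied values together
static std::vector<int> equipartition(const std::vector<double>& v,
                                      const std::vector<int>& ord, int q) {
  const int n = (int)ord.size();
  std::vector<int> grp(n, 0);
  int i = 0, row = 0, inrow = 0;
  double target = (double)n / q;
  while (i < n) {
    int j = i;
    while (j < n && v[ord[j]] == v[ord[i]]) ++j;
    const int tie = j - i;
    if (inrow != 0 && row < q - 1 &&
        std::fabs(inrow + tie - target) >= std::fabs(inrow - target)) {
      ++row;
      inrow = 0;
      target = (double)(n - i) / (q - row);
    }
    for (int t = i; t < j; ++t) grp[ord[t]] = row;
    inrow += tie;
    i = j;
  }
  return grp;
}

static std::vector<int> order_of(const std::vector<double>& v) {
  std::vector<int> ord(v.size());
  for (size_t i = 0; i < v.size(); ++i) ord[i] = (int)i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  return ord;
}

// best normalised MI over grids with <= maxcols columns for one row
// assignment; updates `best`
static void optimize_axis(const std::vector<double>& x,
                          const std::vector<int>& xord,
                          const std::vector<int>& rowAssign, int qeff,
                          int maxcols, double cpar,
                          const std::vector<double>& lgtab, double* best) {
  const int n = (int)x.size();

  // clumps in x order: new clump only where both x value and row change
  std::vector<int> clumpOfPos(n);
  int k = 0;
  for (int pos = 0; pos < n; ++pos) {
    if (pos > 0) {
      const bool samex = x[xord[pos]] == x[xord[pos - 1]];
      const bool samerow = rowAssign[xord[pos]] == rowAssign[xord[pos - 1]];
      if (!samex && !samerow) ++k;
    }
    clumpOfPos[pos] = k;
  }
  int nclumps = k + 1;

  // superclumps: cap the number of clumps at max(c * maxcols, 1)
  const int cap = std::max((int)(cpar * maxcols), 1);
  if (nclumps > cap) {
    std::vector<double> cval(n);
    std::vector<int> posord(n);
    for (int pos = 0; pos < n; ++pos) {
      cval[pos] = (double)clumpOfPos[pos];
      posord[pos] = pos;
    }
    std::vector<int> sup = equipartition(cval, posord, cap);
    int m = 0;
    for (int pos = 0; pos < n; ++pos) {
      if (pos > 0 && sup[pos] != sup[pos - 1]) ++m;
      clumpOfPos[pos] = m;
    }
    nclumps = m + 1;
  }
  const int K = nclumps;

  // per-clump size and sparse per-row counts (most clumps live in one row)
  std::vector<int> csize(K, 0);
  std::vector<std::vector<std::pair<int, int> > > crows(K);
  {
    std::vector<int> tmp(qeff, 0);
    int start = 0;
    for (int ci = 0; ci < K; ++ci) {
      int pos = start;
      while (pos < n && clumpOfPos[pos] == ci) {
        ++tmp[rowAssign[xord[pos]]];
        ++pos;
      }
      csize[ci] = pos - start;
      for (int r = 0; r < qeff; ++r)
        if (tmp[r]) {
          crows[ci].push_back(std::make_pair(r, tmp[r]));
          tmp[r] = 0;
        }
      start = pos;
    }
  }

  const double logn = std::log((double)n);
  // H(Q) over all points
  double HQ;
  {
    std::vector<int> Nr(qeff, 0);
    for (int i = 0; i < n; ++i) ++Nr[rowAssign[i]];
    double s = 0.0;
    for (int r = 0; r < qeff; ++r) s += lgtab[Nr[r]];
    HQ = (n * logn - s) / n;
  }

  // phi(a, b) for a column spanning clumps a+1..b (0 <= a < b <= K):
  //   phi = (sum_r lgtab[nr] - lgtab[np]) / n
  // so that I(P;Q) = H(Q) + sum over columns of phi. Built by sweeping b
  // for each fixed a with incremental row counts.
  std::vector<double> phi((size_t)K * (K + 1), 0.0);
  {
    std::vector<int> cnt(qeff, 0);
    for (int a = 0; a < K; ++a) {
      double S = 0.0;
      int np = 0;
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int b = a + 1; b <= K; ++b) {
        const std::vector<std::pair<int, int> >& cr = crows[b - 1];
        for (size_t e = 0; e < cr.size(); ++e) {
          const int r = cr[e].first, d = cr[e].second;
          S -= lgtab[cnt[r]];
          cnt[r] += d;
          S += lgtab[cnt[r]];
        }
        np += csize[b - 1];
        phi[(size_t)a * (K + 1) + b] = (S - lgtab[np]) / n;
      }
    }
  }

  const int L = std::min(maxcols, K);
  // G[t][l]: best sum of phi over partitions of clumps 1..t into <= l cols
  std::vector<double> prev(K + 1), cur(K + 1);
  for (int t = 1; t <= K; ++t) prev[t] = phi[t];
  for (int l = 2; l <= L; ++l) {
    for (int t = 1; t <= K; ++t) {
      double bestG = prev[t];  // fewer columns allowed too
      const double* phis = &phi[0];
      for (int s = 1; s < t; ++s) {
        const double cand = prev[s] + phis[(size_t)s * (K + 1) + t];
        if (cand > bestG) bestG = cand;
      }
      cur[t] = bestG;
    }
    double I = HQ + cur[K];
    if (I < 0.0) I = 0.0;
    const double denom = std::log((double)std::min(l, qeff));
    if (denom > 0.0) {
      const double m = I / denom;
      if (m > *best) *best = m;
    }
    std::swap(prev, cur);
  }
}

// [[Rcpp::export]]
double mic_cpp(NumericVector xv, NumericVector yv, double alpha, double cpar) {
  const int n = xv.size();
  if (n != yv.size()) stop("x and y must have equal length");
  if (n < 4) stop("need at least 4 observations for MIC");
  std::vector<double> x(xv.begin(), xv.end());
  std::vector<double> y(yv.begin(), yv.end());

  double B = std::pow((double)n, alpha);
  if (B < 4.0) B = 4.0;
  if (B > n) B = n;

  std::vector<double> lgtab(n + 1);
  lgtab[0] = 0.0;
  for (int m = 1; m <= n; ++m) lgtab[m] = m * std::log((double)m);

  double best = 0.0;
  for (int orient = 0; orient < 2; ++orient) {
    const std::vector<double>& xx = orient ? y : x;
    const std::vector<double>& yy = orient ? x : y;
    std::vector<int> xord = order_of(xx);
    std::vector<int> yord = order_of(yy);
    for (int q = 2; q * 2 <= (int)B; ++q) {
      const int maxcols = (int)std::floor(B / q);
      if (maxcols < 2) break;
      std::vector<int> rowAssign = equipartition(yy, yord, q);
      int qeff = 0;
      for (int i = 0; i < n; ++i) qeff = std::max(qeff, rowAssign[i]);
      ++qeff;
      if (qeff < 2) continue;  // constant axis
      optimize_axis(xx, xord, rowAssign, qeff, maxcols, cpar, lgtab, &best);
    }
  }
  if (best > 1.0) best = 1.0;
  return best;
}
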