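#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scott bin count for circular data on [-pi, pi): h = 3.49 * sd * N^(-1/3),
// count = ceil(2*pi / h), floored at 2. `sdv` is the ordinary sample sd.
static int scott_count(double sdv, double n) {
  if (sdv <= 0.0) return -1; // signals constant input to the caller
  double h = 3.49 * sdv * std::pow(n, -1.0 / 3.0);
  int b = (int)std::ceil(2.0 * M_PI / h);
  return b < 2 ? 2 : b;
}

static double pooled_sd(const double* x, const double* y, int n) {
  double s = 0.0, ss = 0.0;
  for (int t = 0; t < n; ++t) { s += x[t]; ss += x[t] * x[t]; }
  for (int t = 0; t < n; ++t) { s += y[t]; ss += y[t] * y[t]; }
  double nn = 2.0 * n;
  double v = (ss - s * s / nn) / (nn - 1.0);
  return v > 0 ? std::sqrt(v) : 0.0;
}

// Bin phases (radians in [-pi, pi)) into 0..B-1 with edges anchored on
// [-pi, pi).
static void bin_phases(const double* p, int n, int B, int* out) {
  const double scale = B / (2.0 * M_PI);
  for (int t = 0; t < n; ++t) {
    int b = (int)((p[t] + M_PI) * scale);
    if (b < 0) b = 0;
    if (b >= B) b = B - 1;
    out[t] = b;
  }
}

// Reusable count buffers + log table so the per-pair loop never allocates.
struct TeWork {
  std::vector<int> c3, cyx, cfy, cy;
  std::vector<double> logtab; // logtab[k] = log(k)
  void ensure(int B, int m) {
    if ((int)c3.size() < B * B * B) c3.resize((size_t)B * B * B);
    if ((int)cyx.size() < B * B) { cyx.resize((size_t)B * B);
                                   cfy.resize((size_t)B * B); }
    if ((int)cy.size() < B) cy.resize(B);
    if ((int)logtab.size() < m + 1) {
      int old = logtab.size();
      logtab.resize(m + 1);
      if (old == 0) { logtab[0] = 0.0; old = 1; }
      for (int k = old; k <= m; ++k) logtab[k] = std::log((double)k);
    }
  }
};

// Transfer entropy on binned series, TE(x->y) with prediction delay d:
// TE = sum p(yf, yp, xp) log[ p(yf|yp,xp) / p(yf|yp) ], natural log.
// Computed through the entropy decomposition
//   TE = [ S(c3) + S(cy) - S(cyx) - S(cfy) ] / m,  S(c) = sum c * log c,
// which needs no divisions and only table-lookup logs of integer counts.
static double te_binned(const int* bx, const int* by, int n, int B, int d,
                        TeWork& w) {
  int m = n - d;
  w.ensure(B, m);
  std::fill(w.c3.begin(), w.c3.begin() + (size_t)B * B * B, 0);
  std::fill(w.cyx.begin(), w.cyx.begin() + (size_t)B * B, 0);
  std::fill(w.cfy.begin(), w.cfy.begin() + (size_t)B * B, 0);
  std::fill(w.cy.begin(), w.cy.begin() + B, 0);
  for (int t = 0; t < m; ++t) {
    int yf = by[t + d], yp = by[t], xp = bx[t];
    ++w.c3[(size_t)(yf * B + yp) * B + xp];
    ++w.cyx[(size_t)yp * B + xp];
    ++w.cfy[(size_t)yf * B + yp];
    ++w.cy[yp];
  }
  double s3 = 0.0, s1 = 0.0, s2x = 0.0, s2f = 0.0;
  for (size_t i = 0, e = (size_t)B * B * B; i < e; ++i)
    if (w.c3[i]) s3 += w.c3[i] * w.logtab[w.c3[i]];
  for (size_t i = 0, e = (size_t)B * B; i < e; ++i) {
    if (w.cyx[i]) s2x += w.cyx[i] * w.logtab[w.cyx[i]];
    if (w.cfy[i]) s2f += w.cfy[i] * w.logtab[w.cfy[i]];
  }
  for (int i = 0; i < B; ++i)
    if (w.cy[i]) s1 += w.cy[i] * w.logtab[w.cy[i]];
  double te = (s3 + s1 - s2x - s2f) / m;
  return te > 0.0 ? te : 0.0; // clip finite-sample negatives
}

// [[Rcpp::export]]
NumericVector cpp_pte_pair(NumericVector px, NumericVector py, int n_bins,
                           int delay) {
  int n = px.size();
  if (py.size() != n) stop("phase series must have equal length");
  int B = n_bins;
  if (B <= 0) {
    B = scott_count(pooled_sd(px.begin(), py.begin(), n), 2.0 * n);
    if (B < 0) stop("constant phase input: bin width undefined");
  }
  std::vector<int> bx(n), by(n);
  bin_phases(px.begin(), n, B, bx.data());
  bin_phases(py.begin(), n, B, by.data());
  TeWork w;
  return NumericVector::create(
      te_binned(bx.data(), by.data(), n, B, delay, w),
      te_binned(by.data(), bx.data(), n, B, delay, w));
}

// Full directed PTE matrix for one segment. phases is nodes x samples, or
// samples x nodes when nodes_in_cols is true (the internal layout produced
// by the batched FFT path). n_bins <= 0 requests the pooled Scott rule per
// pair.
// [[Rcpp::export]]
NumericMatrix cpp_pte_matrix(NumericMatrix phases, int n_bins, int delay,
                             bool nodes_in_cols = false) {
  int n = nodes_in_cols ? phases.ncol() : phases.nrow();
  int N = nodes_in_cols ? phases.nrow() : phases.ncol();
  NumericMatrix out(n, n);
  // copy so each node's series is contiguous
  std::vector<double> rows((size_t)n * N);
  if (nodes_in_cols) {
    for (int i = 0; i < n; ++i)
      for (int t = 0; t < N; ++t) rows[(size_t)i * N + t] = phases(t, i);
  } else {
    for (int i = 0; i < n; ++i)
      for (int t = 0; t < N; ++t) rows[(size_t)i * N + t] = phases(i, t);
  }
  std::vector<int> bi(N), bj(N);
  TeWork w;
  for (int i = 0; i < n - 1; ++i) {
    const double* xi = rows.data() + (size_t)i * N;
    for (int j = i + 1; j < n; ++j) {
      const double* xj = rows.data() + (size_t)j * N;
      int B = n_bins;
      if (B <= 0) {
        B = scott_count(pooled_sd(xi, xj, N), 2.0 * N);
        if (B < 0) stop("constant phase input: bin width undefined");
      }
      bin_phases(xi, N, B, bi.data());
      bin_phases(xj, N, B, bj.data());
      out(i, j) = te_binned(bi.data(), bj.data(), N, B, delay, w);
      out(j, i) = te_binned(bj.data(), bi.data(), N, B, delay, w);
    }
  }
  return out;
}

// Build the analytic-signal spectrum of a phase-randomized surrogate from
// the *original* forward spectrum f (n x nodes): positive-frequency rows
// 2..half+1 get magnitude-preserving uniform random phases (drawn as
// normalized Gaussian pairs via R's RNG, column by column) and the Hilbert
// doubling; DC and Nyquist are untouched; negative frequencies are zero.
// Inverse-transforming the result gives the surrogate's analytic signal.
// [[Rcpp::export]]
ComplexMatrix cpp_surrogate_spectrum(ComplexMatrix f, int half, bool even) {
  int n = f.nrow(), nn = f.ncol();
  if (half + 1 > n) stop("half exceeds spectrum length");
  ComplexMatrix out(n, nn);              // zero-initialised
  GetRNGstate();
  for (int c = 0; c < nn; ++c) {
    out(0, c) = f(0, c);
    for (int r = 1; r <= half; ++r) {
      Rcomplex v = f(r, c);
      double mag = 2.0 * std::sqrt(v.r * v.r + v.i * v.i);
      double x = norm_rand(), y = norm_rand();
      double s = std::sqrt(x * x + y * y);
      if (s == 0.0) { x = 1.0; s = 1.0; y = 0.0; }
      v.r = mag * x / s;
      v.i = mag * y / s;
      out(r, c) = v;
    }
    if (even) out(n / 2, c) = f(n / 2, c);
  }
  PutRNGstate();
  return out;
}

// Degree-preserving randomization by directed double-edge swaps.
// edges: m x 2 matrix of 1-based (from, to); swap attempts use R's RNG so
// results are reproducible under set.seed(). Weights travel with their row.
// Returns the rewired edge matrix; attempt statistics in attributes.
// [[Rcpp::export]]
IntegerMatrix cpp_edge_swap(IntegerMatrix edges, int n, double attempts) {
  int m = edges.nrow();
  IntegerMatrix out = clone(edges);
  std::vector<char> adj((size_t)n * n, 0);
  for (int e = 0; e < m; ++e)
    adj[(size_t)(out(e, 0) - 1) * n + (out(e, 1) - 1)] = 1;
  double done = 0.0;
  GetRNGstate();
  for (double it = 0.0; it < attempts; ++it) {
    int e1 = (int)(unif_rand() * m), e2 = (int)(unif_rand() * m);
    if (e1 >= m) e1 = m - 1;
    if (e2 >= m) e2 = m - 1;
    if (e1 == e2) continue;
    int a = out(e1, 0) - 1, b = out(e1, 1) - 1;
    int c = out(e2, 0) - 1, d = out(e2, 1) - 1;
    if (a == d || c == b) continue;               // would create self-loop
    if (adj[(size_t)a * n + d] || adj[(size_t)c * n + b]) continue;
    adj[(size_t)a * n + b] = 0; adj[(size_t)c * n + d] = 0;
    adj[(size_t)a * n + d] = 1; adj[(size_t)c * n + b] = 1;
    out(e1, 1) = d + 1; out(e2, 1) = b + 1;
    done += 1.0;
  }
  PutRNGstate();
  out.attr("swaps_done") = done;
  out.attr("attempts") = attempts;
  return out;
}
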