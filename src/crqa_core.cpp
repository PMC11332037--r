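#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Flatten an R matrix (column-major) into a row-major buffer so the
// point-vs-point scans below walk contiguous memory.
static std::vector<double> row_major(const NumericMatrix& M) {
  const int n = M.nrow(), d = M.ncol();
  std::vector<double> out((size_t)n * d);
  for (int j = 0; j < d; ++j)
    for (int i = 0; i < n; ++i)
      out[(size_t)i * d + j] = M(i, j);
  return out;
}

static inline double dist2_ptr(const double* a, const double* b, int d) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double diff = a[k] - b[k];
    s += diff * diff;
  }
  return s;
}

// Count of cross-recurrent pairs: ||x_i - y_j|| <= radius (Euclidean).
// [[Rcpp::export]]
double cpp_count_recurrent(NumericMatrix X, NumericMatrix Y, double radius) {
  const int nx = X.nrow(), ny = Y.nrow(), d = X.ncol();
  const double r2 = radius * radius;
  std::vector<double> xf = row_major(X), yf = row_major(Y);
  double count = 0.0;
  for (int i = 0; i < nx; ++i) {
    const double* xi = &xf[(size_t)i * d];
    for (int j = 0; j < ny; ++j)
      if (dist2_ptr(xi, &yf[(size_t)j * d], d) <= r2) count += 1.0;
  }
  return count;
}

// Quantile of the cross-distance distribution estimated from a uniform
// subsample of pairs; used to seed the radius search.
// [[Rcpp::export]]
double cpp_dist_quantile(NumericMatrix X, NumericMatrix Y, double prob,
                         int max_pairs) {
  const int nx = X.nrow(), ny = Y.nrow(), d = X.ncol();
  std::vector<double> xf = row_major(X), yf = row_major(Y);
  const double total = (double)nx * ny;
  int step = (int)std::ceil(total / max_pairs);
  if (step < 1) step = 1;
  std::vector<double> dists;
  dists.reserve((size_t)(total / step) + 1);
  for (long long idx = 0; idx < (long long)total; idx += step) {
    int i = (int)(idx / ny), j = (int)(idx % ny);
    dists.push_back(dist2_ptr(&xf[(size_t)i * d], &yf[(size_t)j * d], d));
  }
  size_t k = (size_t)(prob * (dists.size() - 1));
  std::nth_element(dists.begin(), dists.begin() + k, dists.end());
  return std::sqrt(dists[k]);
}

// Full cross-recurrence measures without materialising the plot. One pass
// over diagonals collects the recurrence count and diagonal run lengths; one
// pass over columns collects vertical run lengths. Histograms index run
// length.
// [[Rcpp::export]]
List cpp_crqa_measures(NumericMatrix X, NumericMatrix Y, double radius,
                       int min_diag, int min_vert) {
  const int nx = X.nrow(), ny = Y.nrow(), d = X.ncol();
  const double r2 = radius * radius;
  std::vector<double> xf = row_major(X), yf = row_major(Y);
  const int maxlen = std::max(nx, ny);
  std::vector<double> diag_hist(maxlen + 1, 0.0), vert_hist(maxlen + 1, 0.0);
  double ones = 0.0;

  for (int off = -(nx - 1); off <= ny - 1; ++off) {
    int i = off < 0 ? -off : 0;
    int j = off < 0 ? 0 : off;
    int run = 0;
    for (; i < nx && j < ny; ++i, ++j) {
      if (dist2_ptr(&xf[(size_t)i * d], &yf[(size_t)j * d], d) <= r2) {
        ones += 1.0;
        ++run;
      } else if (run > 0) {
        diag_hist[run] += 1.0;
        run = 0;
      }
    }
    if (run > 0) diag_hist[run] += 1.0;
  }

  for (int j = 0; j < ny; ++j) {
    const double* yj = &yf[(size_t)j * d];
    int run = 0;
    for (int i = 0; i < nx; ++i) {
      if (dist2_ptr(&xf[(size_t)i * d], yj, d) <= r2) {
        ++run;
      } else if (run > 0) {
        vert_hist[run] += 1.0;
        run = 0;
      }
    }
    if (run > 0) vert_hist[run] += 1.0;
  }

  double det_pts = 0.0, lam_pts = 0.0;
  for (int l = 1; l <= maxlen; ++l) {
    if (l >= min_diag) det_pts += l * diag_hist[l];
    if (l >= min_vert) lam_pts += l * vert_hist[l];
  }
  double rr = ones / ((double)nx * (double)ny);
  double det = ones > 0 ? det_pts / ones : NA_REAL;
  double lam = ones > 0 ? lam_pts / ones : NA_REAL;
  return List::create(_["RR"] = rr, _["DET"] = det, _["LAM"] = lam,
                      _["n_recurrent"] = ones,
                      _["diag_hist"] = NumericVector(diag_hist.begin(), diag_hist.end()),
                      _["vert_hist"] = NumericVector(vert_hist.begin(), vert_hist.end()));
}

// False-nearest-neighbour fraction for embedding dimensions 1..max_dim
// (Kennel criterion, Euclidean metric, relative tolerance rtol).
// [[Rcpp::export]]
NumericVector cpp_fnn(NumericVector x, int delay, int max_dim, double rtol) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end());
  NumericVector frac(max_dim, NA_REAL);
  for (int d = 1; d <= max_dim; ++d) {
    // points usable in dim d that also have a (d+1)-th coordinate
    int np = n - d * delay;
    if (np < 10) break;
    int false_nn = 0, total = 0;
    for (int i = 0; i < np; ++i) {
      double best = R_PosInf;
      int jbest = -1;
      for (int j = 0; j < np; ++j) {
        if (j == i) continue;
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          double diff = xv[i + k * delay] - xv[j + k * delay];
          s += diff * diff;
          if (s >= best) break;
        }
        if (s < best) { best = s; jbest = j; }
      }
      if (jbest < 0) continue;
      double rd = std::sqrt(best);
      double extra = std::fabs(xv[i + d * delay] - xv[jbest + d * delay]);
      ++total;
      if (rd <= 0.0) {
        if (extra > 0.0) ++false_nn;
      } else if (extra / rd > rtol) {
        ++false_nn;
      }
    }
    frac[d - 1] = total > 0 ? (double)false_nn / total : NA_REAL;
  }
  return frac;
}

// Monte-Carlo permutation null for the mean(Tx) - mean(NT) statistic: draws
// n_perm random relabelings preserving the 6/6 split (uses R's RNG).
// [[Rcpp::export]]
NumericVector cpp_perm_null(NumericVector ratings, int n_tx, int n_perm) {
  const int n = ratings.size();
  const int n_nt = n - n_tx;
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += ratings[i];
  NumericVector out(n_perm);
  std::vector<int> idx(n);
  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    // partial Fisher-Yates: first n_tx entries form the Tx relabeling
    double tx_sum = 0.0;
    for (int i = 0; i < n_tx; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
      tx_sum += ratings[idx[i]];
    }
    out[p] = tx_sum / n_tx - (total - tx_sum) / n_nt;
  }
  return out;
}
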