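#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// quartic (biweight) kernel weight at squared distance r2, bandwidth units
static inline double quartic_w(double r2) {
  if (r2 >= 1.0) return 0.0;
  double t = 1.0 - r2;
  return (3.0 / M_PI) * t * t;
}

// Kernel intensity f(q) = h^-2 * sum_i K((q - x_i)/h) with compact support
// ||u|| <= 1. Source points are binned on a grid of cell size h so each
// query only visits its 3x3 cell neighbourhood; falls back to a plain
// double loop when the grid would be degenerate or enormous.
// [[Rcpp::export]]
NumericVector cpp_quartic_density(NumericVector px, NumericVector py,
                                  NumericVector qx, NumericVector qy,
                                  double h) {
  const R_xlen_t n = px.size(), m = qx.size();
  NumericVector out(m);
  if (n == 0) return out;
  const double inv_h = 1.0 / h, inv_h2 = inv_h * inv_h;

  double xmin = px[0], ymin = py[0], xmax = px[0], ymax = py[0];
  for (R_xlen_t i = 1; i < n; ++i) {
    if (px[i] < xmin) xmin = px[i];
    if (px[i] > xmax) xmax = px[i];
    if (py[i] < ymin) ymin = py[i];
    if (py[i] > ymax) ymax = py[i];
  }
  double nx_d = std::floor((xmax - xmin) * inv_h) + 1.0;
  double ny_d = std::floor((ymax - ymin) * inv_h) + 1.0;

  if (nx_d * ny_d > 1.6e7 || n < 64) {
    // brute force
    for (R_xlen_t j = 0; j < m; ++j) {
      double acc = 0.0;
      for (R_xlen_t i = 0; i < n; ++i) {
        double dx = (qx[j] - px[i]) * inv_h, dy = (qy[j] - py[i]) * inv_h;
        acc += quartic_w(dx * dx + dy * dy);
      }
      out[j] = acc * inv_h2;
    }
    return out;
  }

  const int nx = (int)nx_d, ny = (int)ny_d;
  std::vector<int> count(nx * ny + 1, 0);
  std::vector<int> cell(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int cx = (int)((px[i] - xmin) * inv_h);
    int cy = (int)((py[i] - ymin) * inv_h);
    if (cx >= nx) cx = nx - 1;
    if (cy >= ny) cy = ny - 1;
    cell[i] = cy * nx + cx;
    ++count[cell[i] + 1];
  }
  for (size_t c = 1; c < count.size(); ++c) count[c] += count[c - 1];
  std::vector<int> idx(n);
  {
    std::vector<int> pos(count.begin(), count.end() - 1);
    for (R_xlen_t i = 0; i < n; ++i) idx[pos[cell[i]]++] = (int)i;
  }

  for (R_xlen_t j = 0; j < m; ++j) {
    double acc = 0.0;
    int cx = (int)std::floor((qx[j] - xmin) * inv_h);
    int cy = (int)std::floor((qy[j] - ymin) * inv_h);
    for (int gy = cy - 1; gy <= cy + 1; ++gy) {
      if (gy < 0 || gy >= ny) continue;
      for (int gx = cx - 1; gx <= cx + 1; ++gx) {
        if (gx < 0 || gx >= nx) continue;
        int c = gy * nx + gx;
        for (int t = count[c]; t < count[c + 1]; ++t) {
          int i = idx[t];
          double dx = (qx[j] - px[i]) * inv_h, dy = (qy[j] - py[i]) * inv_h;
          acc += quartic_w(dx * dx + dy * dy);
        }
      }
    }
    out[j] = acc * inv_h2;
  }
  return out;
}

// k nearest source points per query, brute force with an insertion buffer.
// Sources are scanned in index order and replacement requires a strictly
// smaller distance, so equal distances keep the lowest index.
// [[Rcpp::export]]
List cpp_knn(NumericVector px, NumericVector py,
             NumericVector qx, NumericVector qy, int k) {
  const R_xlen_t n = px.size(), m = qx.size();
  IntegerMatrix nn_idx(m, k);
  NumericMatrix nn_dist(m, k);
  std::vector<double> bd(k);
  std::vector<int> bi(k);
  for (R_xlen_t j = 0; j < m; ++j) {
    int filled = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double dx = qx[j] - px[i], dy = qy[j] - py[i];
      double d2 = dx * dx + dy * dy;
      if (filled < k) {
        int p = filled++;
        while (p > 0 && bd[p - 1] > d2) {
          bd[p] = bd[p - 1]; bi[p] = bi[p - 1]; --p;
        }
        bd[p] = d2; bi[p] = (int)i;
      } else if (d2 < bd[k - 1]) {
        int p = k - 1;
        while (p > 0 && bd[p - 1] > d2) {
          bd[p] = bd[p - 1]; bi[p] = bi[p - 1]; --p;
        }
        bd[p] = d2; bi[p] = (int)i;
      }
    }
    for (int t = 0; t < k; ++t) {
      nn_idx(j, t) = bi[t] + 1;
      nn_dist(j, t) = std::sqrt(bd[t]);
    }
  }
  return List::create(_["index"] = nn_idx, _["dist"] = nn_dist);
}

// EM for a univariate Gaussian mixture. Responsibilities are computed with
// per-observation max-scaling so well-separated, low-variance components do
// not underflow. Returns the log-likelihood trace for convergence checks.
// [[Rcpp::export]]
List cpp_em_gmm(NumericVector x, NumericVector w0, NumericVector mu0,
                NumericVector var0, int max_iter, double tol,
                double var_floor) {
  const R_xlen_t n = x.size();
  const int K = w0.size();
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> mu(mu0.begin(), mu0.end());
  std::vector<double> v(var0.begin(), var0.end());
  for (int k = 0; k < K; ++k) if (v[k] < var_floor) v[k] = var_floor;

  std::vector<double> logw(K), inv2v(K), lognorm(K), ld(K);
  std::vector<double> Nk(K), Sk(K), Qk(K);
  NumericVector trace(max_iter);
  double ll_prev = R_NegInf, ll = R_NegInf;
  bool converged = false, collapsed = false;
  int it = 0;
  const double LOG2PI = std::log(2.0 * M_PI);

  for (it = 0; it < max_iter; ++it) {
    for (int k = 0; k < K; ++k) {
      logw[k] = std::log(w[k]);
      inv2v[k] = 0.5 / v[k];
      lognorm[k] = -0.5 * (LOG2PI + std::log(v[k]));
    }
    std::fill(Nk.begin(), Nk.end(), 0.0);
    std::fill(Sk.begin(), Sk.end(), 0.0);
    std::fill(Qk.begin(), Qk.end(), 0.0);
    ll = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
      double mx = R_NegInf;
      for (int k = 0; k < K; ++k) {
        double d = x[i] - mu[k];
        ld[k] = logw[k] + lognorm[k] - d * d * inv2v[k];
        if (ld[k] > mx) mx = ld[k];
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) { ld[k] = std::exp(ld[k] - mx); s += ld[k]; }
      ll += mx + std::log(s);
      double inv_s = 1.0 / s;
      for (int k = 0; k < K; ++k) {
        double r = ld[k] * inv_s;
        Nk[k] += r;
        Sk[k] += r * x[i];
        Qk[k] += r * x[i] * x[i];
      }
    }
    trace[it] = ll;
    for (int k = 0; k < K; ++k) {
      if (Nk[k] < 1e-10 * n) { collapsed = true; break; }
      w[k] = Nk[k] / n;
      mu[k] = Sk[k] / Nk[k];
      double vv = Qk[k] / Nk[k] - mu[k] * mu[k];
      v[k] = (vv < var_floor) ? var_floor : vv;
    }
    if (collapsed) { ++it; break; }
    if (it > 0 && std::fabs(ll - ll_prev) <= tol * (std::fabs(ll_prev) + 1e-300)) {
      converged = true; ++it; break;
    }
    ll_prev = ll;
  }
  if (it == 0) it = 1;
  return List::create(
    _["w"] = NumericVector(w.begin(), w.end()),
    _["mu"] = NumericVector(mu.begin(), mu.end()),
    _["var"] = NumericVector(v.begin(), v.end()),
    _["loglik"] = ll,
    _["trace"] = trace[Range(0, it - 1)],
    _["iterations"] = it,
    _["converged"] = converged,
    _["collapsed"] = collapsed);
}
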