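// Compiled kernels for the tomography and sparse-coding hot paths:
// ray line integrals (forward projection), filtered back projection,
// SART with exact ray-pixel intersection lengths (Siddon traversal),
// bilateral filtering, and batch orthogonal matching pursuit.
//
// Image convention: square n x n matrix; column c (0-based) maps to
// x = -1 + c*h, row r maps to y = 1 - r*h with h = 2/(n-1), so the
// pixel centers sample the phantom frame [-1,1]^2 with y up.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double bilin(const arma::mat& img, double x, double y, int n, double h) {
  // bilinear sample in frame coordinates, zero outside the grid
  double cf = (x + 1.0) / h;
  double rf = (1.0 - y) / h;
  int c0 = (int)std::floor(cf);
  int r0 = (int)std::floor(rf);
  double fc = cf - c0, fr = rf - r0;
  double v = 0.0;
  for (int dr = 0; dr <= 1; ++dr) {
    int r = r0 + dr;
    if (r < 0 || r >= n) continue;
    double wr = dr ? fr : (1.0 - fr);
    for (int dc = 0; dc <= 1; ++dc) {
      int c = c0 + dc;
      if (c < 0 || c >= n) continue;
      double wc = dc ? fc : (1.0 - fc);
      v += wr * wc * img(r, c);
    }
  }
  return v;
}

// [[Rcpp::export]]
arma::vec cpp_line_integrals(const arma::mat& img, const arma::vec& theta,
                             const arma::vec& r, double step, double tmax) {
  int n = img.n_rows;
  double h = 2.0 / (n - 1);
  int K = theta.n_elem;
  arma::vec out(K, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    double bx = r[k] * ct, by = r[k] * st;
    // direction perpendicular to the ray normal
    double dx = -st, dy = ct;
    double acc = 0.0;
    int m = (int)std::ceil(2.0 * tmax / step);
    for (int s = 0; s <= m; ++s) {
      double t = -tmax + s * step;
      acc += bilin(img, bx + t * dx, by + t * dy, n, h);
    }
    out[k] = acc * step;
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_backproject(const arma::mat& q, const arma::vec& theta,
                          double r0, double dr, int n) {
  // q: rows = angles, cols = radial samples (filtered projections)
  int K = theta.n_elem, M = q.n_cols;
  double h = 2.0 / (n - 1);
  arma::mat f(n, n, arma::fill::zeros);
  arma::vec ct(K), st(K);
  for (int k = 0; k < K; ++k) { ct[k] = std::cos(theta[k]); st[k] = std::sin(theta[k]); }
  for (int r = 0; r < n; ++r) {
    double y = 1.0 - r * h;
    for (int c = 0; c < n; ++c) {
      double x = -1.0 + c * h;
      double acc = 0.0;
      for (int k = 0; k < K; ++k) {
        double u = (x * ct[k] + y * st[k] - r0) / dr;
        int u0 = (int)std::floor(u);
        double fu = u - u0;
        if (u0 >= 0 && u0 < M - 1)
          acc += (1.0 - fu) * q(k, u0) + fu * q(k, u0 + 1);
        else if (u0 == -1)
          acc += fu * q(k, 0);
        else if (u0 == M - 1)
          acc += (1.0 - fu) * q(k, M - 1);
      }
      f(r, c) = acc * M_PI / K;
    }
  }
  return f;
}

// Siddon traversal: exact intersection lengths of one ray with the pixel
// grid. Returns number of cells written into (idx, len) buffers; lengths in
// frame units.
static int siddon(double thetak, double rk, int n, double h,
                  std::vector<int>& idx, std::vector<double>& len) {
  const double INF = std::numeric_limits<double>::infinity();
  double ct = std::cos(thetak), st = std::sin(thetak);
  double bx = rk * ct, by = rk * st;
  double dx = -st, dy = ct;
  double xmin = -1.0 - h / 2.0, xmax = 1.0 + h / 2.0;
  double ymin = xmin, ymax = xmax;
  double tmin = -INF, tmax = INF;
  if (std::fabs(dx) > 1e-14) {
    double t1 = (xmin - bx) / dx, t2 = (xmax - bx) / dx;
    tmin = std::max(tmin, std::min(t1, t2));
    tmax = std::min(tmax, std::max(t1, t2));
  } else if (bx <= xmin || bx >= xmax) return 0;
  if (std::fabs(dy) > 1e-14) {
    double t1 = (ymin - by) / dy, t2 = (ymax - by) / dy;
    tmin = std::max(tmin, std::min(t1, t2));
    tmax = std::min(tmax, std::max(t1, t2));
  } else if (by <= ymin || by >= ymax) return 0;
  if (!(tmin < tmax)) return 0;

  double t = tmin;
  double px = bx + t * dx, py = by + t * dy;
  int j = (int)std::floor((px - xmin) / h);
  int i = (int)std::floor((ymax - py) / h);
  if (j < 0) j = 0; if (j > n - 1) j = n - 1;
  if (i < 0) i = 0; if (i > n - 1) i = n - 1;
  double dtx = (std::fabs(dx) > 1e-14) ? h / std::fabs(dx) : INF;
  double dty = (std::fabs(dy) > 1e-14) ? h / std::fabs(dy) : INF;
  double tx, ty;
  if (dx > 1e-14)       tx = t + ((xmin + (j + 1) * h) - px) / dx;
  else if (dx < -1e-14) tx = t + ((xmin + j * h) - px) / dx;
  else                  tx = INF;
  if (dy > 1e-14)       ty = t + ((ymax - i * h) - py) / dy;
  else if (dy < -1e-14) ty = t + ((ymax - (i + 1) * h) - py) / dy;
  else                  ty = INF;

  int cnt = 0;
  while (true) {
    double tn = std::min(std::min(tx, ty), tmax);
    double L = tn - t;
    if (L > 1e-14 && i >= 0 && i < n && j >= 0 && j < n) {
      idx[cnt] = i + j * n;  // column-major linear index
      len[cnt] = L;
      ++cnt;
    }
    t = tn;
    if (tn >= tmax - 1e-14) break;
    if (tx <= ty) { j += (dx > 0) ? 1 : -1; tx += dtx; }
    else          { i += (dy > 0) ? -1 : 1; ty += dty; }
    if (i < 0 || i >= n || j < 0 || j >= n) break;
  }
  return cnt;
}

// [[Rcpp::export]]
List cpp_sart(const arma::mat& p, const arma::vec& theta, const arma::vec& offsets,
              int n, double lambda, int niter, const arma::mat& f0) {
  // p: rows = angles, cols = rays, in PIXEL-LENGTH units (line integral / h).
  // Update per projection angle (Eq. with sum a_ij^2 ray normalization and
  // per-pixel sum a_ij normalization); intersection lengths in pixel units.
  int K = theta.n_elem, M = offsets.n_elem;
  double h = 2.0 / (n - 1);
  arma::mat f = f0;
  std::vector<int> idx(4 * n + 8);
  std::vector<double> len(4 * n + 8);
  arma::vec num(n * n), den(n * n);
  arma::vec resid(niter, arma::fill::zeros);
  int skipped = 0;

  for (int it = 0; it < niter; ++it) {
    for (int k = 0; k < K; ++k) {
      num.zeros(); den.zeros();
      for (int m = 0; m < M; ++m) {
        int cnt = siddon(theta[k], offsets[m], n, h, idx, len);
        if (cnt == 0) continue;
        double s1 = 0.0, s2 = 0.0;
        for (int c = 0; c < cnt; ++c) {
          double a = len[c] / h;  // pixel units
          s1 += a * f(idx[c]);
          s2 += a * a;
        }
        if (s2 <= 0) { ++skipped; continue; }
        double corr = (lambda * p(k, m) - s1) / s2;
        for (int c = 0; c < cnt; ++c) {
          double a = len[c] / h;
          num[idx[c]] += corr * a;
          den[idx[c]] += a;
        }
      }
      for (int q = 0; q < n * n; ++q)
        if (den[q] > 0) f(q) += num[q] / den[q];
    }
    // full residual ||A f - p|| after the sweep
    double rs = 0.0;
    for (int k = 0; k < K; ++k)
      for (int m = 0; m < M; ++m) {
        int cnt = siddon(theta[k], offsets[m], n, h, idx, len);
        double s1 = 0.0;
        bool any = false;
        for (int c = 0; c < cnt; ++c) { s1 += (len[c] / h) * f(idx[c]); any = true; }
        if (!any) continue;
        double e = s1 - p(k, m);
        rs += e * e;
      }
    resid[it] = std::sqrt(rs);
  }
  return List::create(_["image"] = f, _["residuals"] = resid,
                      _["skipped"] = skipped);
}

// [[Rcpp::export]]
arma::mat cpp_siddon_project(const arma::mat& img, const arma::vec& theta,
                             const arma::vec& offsets) {
  // forward projection with the same ray model as cpp_sart, pixel units
  int n = img.n_rows, K = theta.n_elem, M = offsets.n_elem;
  double h = 2.0 / (n - 1);
  std::vector<int> idx(4 * n + 8);
  std::vector<double> len(4 * n + 8);
  arma::mat out(K, M, arma::fill::zeros);
  for (int k = 0; k < K; ++k)
    for (int m = 0; m < M; ++m) {
      int cnt = siddon(theta[k], offsets[m], n, h, idx, len);
      double s = 0.0;
      for (int c = 0; c < cnt; ++c) s += (len[c] / h) * img(idx[c]);
      out(k, m) = s;
    }
  return out;
}

static inline int reflect_idx(int i, int n) {
  // symmetric reflection including the edge sample: (dcba|abcd)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// [[Rcpp::export]]
arma::mat cpp_bilateral(const arma::mat& img, double sigma_s, double sigma_r,
                        int radius) {
  int nr = img.n_rows, nc = img.n_cols;
  int w = 2 * radius + 1;
  arma::mat sw(w, w);
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      sw(a + radius, b + radius) =
        std::exp(-(a * a + b * b) / (2.0 * sigma_s * sigma_s));
  arma::mat out(nr, nc);
  double inv2r2 = 1.0 / (2.0 * sigma_r * sigma_r);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double v0 = img(r, c), acc = 0.0, wsum = 0.0;
      for (int a = -radius; a <= radius; ++a) {
        int rr = reflect_idx(r + a, nr);
        for (int b = -radius; b <= radius; ++b) {
          int cc = reflect_idx(c + b, nc);
          double v = img(rr, cc);
          double d = v - v0;
          double wt = sw(a + radius, b + radius) * std::exp(-d * d * inv2r2);
          acc += wt * v;
          wsum += wt;
        }
      }
      out(r, c) = acc / wsum;
    }
  return out;
}

// [[Rcpp::export]]
List cpp_omp(const arma::mat& A, const arma::mat& X, int sparsity, double eps) {
  // Batch OMP with precomputed Gram matrix. A: d x m with unit-norm columns,
  // X: d x N. Greedy max-|correlation| selection with full least-squares
  // refit on the selected support at each step.
  int m = A.n_cols, N = X.n_cols;
  arma::mat G = A.t() * A;
  arma::mat B = A.t() * X;
  arma::imat support(sparsity, N, arma::fill::zeros);
  arma::mat coef(sparsity, N, arma::fill::zeros);
  arma::vec rnorm(N, arma::fill::zeros);
  std::vector<arma::uword> S;
  S.reserve(sparsity);
  arma::vec b(m), c(m);
  for (int s = 0; s < N; ++s) {
    b = B.col(s);
    c = b;
    double xx = arma::dot(X.col(s), X.col(s));
    double r2 = xx;
    S.clear();
    arma::vec w;
    for (int it = 0; it < sparsity; ++it) {
      if (std::sqrt(std::max(r2, 0.0)) <= eps) break;
      arma::uword jbest = arma::index_max(arma::abs(c));
      if (std::fabs(c[jbest]) <= 1e-12) break;
      S.push_back(jbest);
      arma::uvec Sv(S);
      arma::mat Gs = G.submat(Sv, Sv);
      arma::vec bs = b.elem(Sv);
      w = arma::solve(Gs, bs, arma::solve_opts::likely_sympd);
      // residual correlations; selected atoms are forced to zero so the
      // argmax never re-selects them (they are zero in exact arithmetic)
      c = b;
      for (size_t q = 0; q < S.size(); ++q)
        c -= w[q] * G.unsafe_col(S[q]);
      for (size_t q = 0; q < S.size(); ++q) c[S[q]] = 0.0;
      r2 = xx - arma::dot(w, bs);
    }
    for (size_t q = 0; q < S.size(); ++q) {
      support(q, s) = (int)S[q] + 1;
      coef(q, s) = w[q];
    }
    rnorm[s] = std::sqrt(std::max(r2, 0.0));
  }
  return List::create(_["support"] = support, _["coef"] = coef,
                      _["residual_norm"] = rnorm);
}
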