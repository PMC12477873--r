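// Dense two-phase bounded-variable revised simplex.
// Mirrors the reference R implementation in R/lp.R (engine = "r"); the two
// engines are cross-checked on random instances in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct PhaseResult {
  int status; // 0 optimal, 2 unbounded, 3 maxit
  vec y;
};

struct Work {
  mat Aaug;
  vec b, lbA, ubA, xval;
  uvec basis;
  ivec stat; // 1 at-lb, 2 at-ub, 3 free, 0 basic
  std::vector<bool> enterable;
  mat Binv;
  int niter, maxit, bland_after;
  double tol, dtol;

  bool refactor() {
    mat B(Aaug.n_rows, Aaug.n_rows);
    for (uword k = 0; k < basis.n_elem; ++k) B.col(k) = Aaug.col(basis[k]);
    return inv(Binv, B);
  }

  PhaseResult run_phase(const vec& cc) {
    const uword m = Aaug.n_rows, N = Aaug.n_cols;
    int degenerate_streak = 0;
    int since_refactor = 0;
    const int refactor_every = 100;
    PhaseResult res;
    res.y.set_size(m);
    for (;;) {
      if (niter >= maxit) { res.status = 3; return res; }
      ++niter;
      if (since_refactor >= refactor_every) {
        if (!refactor()) Rcpp::stop("singular basis encountered in LP");
        since_refactor = 0;
        vec rhs = b;
        for (uword j = 0; j < N; ++j) {
          if (stat[j] != 0 && xval[j] != 0.0) rhs -= Aaug.col(j) * xval[j];
        }
        vec xB = Binv * rhs;
        for (uword k = 0; k < m; ++k) xval[basis[k]] = xB[k];
      }
      vec cB(m);
      for (uword k = 0; k < m; ++k) cB[k] = cc[basis[k]];
      vec y = Binv.t() * cB;
      vec d_full = cc - Aaug.t() * y;

      bool use_bland = (niter > bland_after) ||
                       (degenerate_streak > (int)N);
      sword e = -1;
      double best = 0.0;
      double sigma = 1.0;
      for (uword j = 0; j < N; ++j) {
        if (stat[j] == 0 || !enterable[j]) continue;
        double dj = d_full[j];
        bool up = (stat[j] == 1 || stat[j] == 3) && dj > dtol;
        bool dn = (stat[j] == 2 || stat[j] == 3) && dj < -dtol;
        if (!up && !dn) continue;
        if (use_bland) { e = j; sigma = up ? 1.0 : -1.0; break; }
        if (std::abs(dj) > best) { best = std::abs(dj); e = j; sigma = up ? 1.0 : -1.0; }
      }
      if (e < 0) { res.status = 0; res.y = y; return res; }

      vec w = Binv * Aaug.col((uword)e);
      vec sw = sigma * w;
      double tstar = datum::inf;
      for (uword k = 0; k < m; ++k) {
        double t = datum::inf;
        if (sw[k] > tol) {
          double l = lbA[basis[k]];
          t = std::isfinite(l) ? (xval[basis[k]] - l) / sw[k] : datum::inf;
        } else if (sw[k] < -tol) {
          double u = ubA[basis[k]];
          t = std::isfinite(u) ? (u - xval[basis[k]]) / (-sw[k]) : datum::inf;
        }
        if (t < 0) t = 0;
        if (t < tstar) tstar = t;
      }
      double t_flip = ubA[e] - lbA[e];
      bool flip = std::isfinite(t_flip) && t_flip <= tstar;
      if (flip) tstar = t_flip;
      if (!std::isfinite(tstar)) { res.status = 2; return res; }
      degenerate_streak = (tstar < tol) ? degenerate_streak + 1 : 0;

      if (flip) {
        xval[e] = (sigma > 0) ? ubA[e] : lbA[e];
        stat[e] = (sigma > 0) ? 2 : 1;
        for (uword k = 0; k < m; ++k) xval[basis[k]] -= tstar * sw[k];
      } else {
        double rel = tol * (1.0 + std::abs(tstar));
        sword r = -1;
        double bestw = -1.0;
        uword bestidx = 0;
        for (uword k = 0; k < m; ++k) {
          double t = datum::inf;
          if (sw[k] > tol) {
            double l = lbA[basis[k]];
            t = std::isfinite(l) ? (xval[basis[k]] - l) / sw[k] : datum::inf;
          } else if (sw[k] < -tol) {
            double u = ubA[basis[k]];
            t = std::isfinite(u) ? (u - xval[basis[k]]) / (-sw[k]) : datum::inf;
          }
          if (t < 0) t = 0;
          if (t <= tstar + rel) {
            if (use_bland) {
              if (r < 0 || basis[k] < bestidx) { r = k; bestidx = basis[k]; }
            } else if (std::abs(sw[k]) > bestw) {
              bestw = std::abs(sw[k]); r = k;
            }
          }
        }
        if (r < 0 || std::abs(w[r]) < 1e-9) {
          if (!refactor()) Rcpp::stop("singular basis encountered in LP");
          since_refactor = 0;
          continue;
        }
        uword lv = basis[r];
        xval[e] += sigma * tstar;
        for (uword k = 0; k < m; ++k) xval[basis[k]] -= tstar * sw[k];
        stat[lv] = (sw[r] > 0) ? 1 : 2;
        xval[lv] = (sw[r] > 0) ? lbA[lv] : ubA[lv];
        basis[r] = (uword)e;
        stat[e] = 0;
        rowvec pivrow = Binv.row(r) / w[r];
        Binv -= w * pivrow;
        Binv.row(r) = pivrow;
        ++since_refactor;
      }
    }
  }
};

} // namespace

// [[Rcpp::export(.simplex_bounded_cpp)]]
Rcpp::List simplex_bounded_cpp(const arma::mat& A, const arma::vec& b,
                               const arma::vec& c, const arma::vec& lb,
                               const arma::vec& ub, int maxit, double tol) {
  const uword m = A.n_rows, n = A.n_cols, N = n + m;
  Work w;
  w.tol = tol;
  w.dtol = 1e-7;
  w.maxit = maxit;
  w.bland_after = 3 * (int)N;
  w.niter = 0;
  w.b = b;
  w.stat.set_size(N);
  w.xval.set_size(N);
  vec x0(n);
  for (uword j = 0; j < n; ++j) {
    if (std::isfinite(lb[j])) { x0[j] = lb[j]; w.stat[j] = 1; }
    else if (std::isfinite(ub[j])) { x0[j] = ub[j]; w.stat[j] = 2; }
    else { x0[j] = 0.0; w.stat[j] = 3; }
  }
  vec resid = b - A * x0;
  w.Aaug.zeros(m, N);
  w.Aaug.cols(0, n - 1) = A;
  vec sgn(m);
  for (uword i = 0; i < m; ++i) {
    sgn[i] = (resid[i] >= 0) ? 1.0 : -1.0;
    w.Aaug(i, n + i) = sgn[i];
  }
  w.lbA.set_size(N); w.ubA.set_size(N);
  w.lbA.head(n) = lb; w.ubA.head(n) = ub;
  w.lbA.tail(m).zeros();
  w.ubA.tail(m).fill(datum::inf);
  w.basis.set_size(m);
  w.xval.head(n) = x0;
  for (uword i = 0; i < m; ++i) {
    w.basis[i] = n + i;
    w.stat[n + i] = 0;
    w.xval[n + i] = std::abs(resid[i]);
  }
  w.enterable.assign(N, true);
  w.Binv = diagmat(sgn); // the signed artificial basis inverts itself

  // phase 1
  vec c1(N, fill::zeros);
  c1.tail(m).fill(-1.0);
  PhaseResult ph1 = w.run_phase(c1);
  if (ph1.status == 3) {
    return Rcpp::List::create(Rcpp::Named("status") = 3,
                              Rcpp::Named("niter") = w.niter);
  }
  double art_sum = 0.0;
  for (uword i = 0; i < m; ++i) art_sum += w.xval[n + i];
  if (art_sum > 1e-7) {
    return Rcpp::List::create(Rcpp::Named("status") = 1,
                              Rcpp::Named("niter") = w.niter);
  }
  // pivot residual artificials out where possible
  for (uword r = 0; r < m; ++r) {
    if (w.basis[r] < n) continue;
    rowvec row_r = w.Binv.row(r) * w.Aaug.cols(0, n - 1);
    for (uword j = 0; j < n; ++j) {
      if (w.stat[j] == 0) continue;
      if (std::abs(row_r[j]) > 1e-7) {
        uword lv = w.basis[r];
        w.stat[lv] = 1;
        w.xval[lv] = 0.0;
        w.basis[r] = j;
        w.stat[j] = 0;
        if (!w.refactor()) Rcpp::stop("singular basis encountered in LP");
        break;
      }
    }
  }
  for (uword i = 0; i < m; ++i) {
    w.ubA[n + i] = 0.0;
    w.enterable[n + i] = false;
  }

  // phase 2
  vec c2(N, fill::zeros);
  c2.head(n) = c;
  PhaseResult ph2 = w.run_phase(c2);
  if (ph2.status != 0) {
    return Rcpp::List::create(Rcpp::Named("status") = ph2.status,
                              Rcpp::Named("niter") = w.niter);
  }
  vec x = w.xval.head(n);
  return Rcpp::List::create(
      Rcpp::Named("status") = 0,
      Rcpp::Named("x") = x,
      Rcpp::Named("y") = ph2.y,
      Rcpp::Named("objective") = dot(c, x),
      Rcpp::Named("niter") = w.niter);
}
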