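// Homogeneous self-dual interior-point solver (Mehrotra predictor-corrector).
//
// Solves  min c'x  s.t.  A x = b, x >= 0  on the homogeneous embedding
//
//   A x - b tau            = 0
//   A'y + s - c tau        = 0
//   -c'x + b'y - kappa     = 0,   x, s, tau, kappa >= 0
//
// whose strictly complementary solutions either recover an optimum
// (tau > 0) or certify primal/dual infeasibility (kappa > 0). Unlike a
// simplex, the path-following iteration is indifferent to the massive
// degeneracy of flux-balance programs, which is why it is the engine for
// the proteome-coupled LPs. Normal equations are regularized and solved by
// Cholesky with dynamic damping.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

// [[Rcpp::export(name = ".ipm_core")]]
List ipm_core(NumericMatrix A_, NumericVector b_, NumericVector c_,
              IntegerVector dir, bool maximize, int max_iter = 200,
              double tol = 1e-9, bool debug = false) {
  const int m = A_.nrow(), n0 = A_.ncol();

  // convert to standard form: append one slack column per inequality row
  int n_slack = 0;
  for (int i = 0; i < m; ++i) if (dir[i] != 0) ++n_slack;
  const int n = n0 + n_slack;
  mat A(m, n, arma::fill::zeros);
  vec b(m), c(n, arma::fill::zeros);
  for (int i = 0; i < m; ++i) {
    b[i] = b_[i];
    for (int j = 0; j < n0; ++j) A(i, j) = A_(i, j);
  }
  {
    int k = n0;
    for (int i = 0; i < m; ++i)
      if (dir[i] != 0) A(i, k++) = (dir[i] < 0) ? 1.0 : -1.0;  // <= : +slack
  }
  for (int j = 0; j < n0; ++j) c[j] = maximize ? -c_[j] : c_[j];

  // starting point
  vec x(n, arma::fill::ones), s(n, arma::fill::ones), y(m, arma::fill::zeros);
  double tau = 1.0, kappa = 1.0;

  const double bnorm = 1.0 + arma::norm(b, "inf");
  const double cnorm = 1.0 + arma::norm(c, "inf");

  auto solve_normal = [&](const mat& AD, const vec& dvec,
                          const vec& rhs1, const vec& rhs2,
                          vec& sol1, vec& sol2) -> bool {
    // M = A diag(dvec) A' (+ damping); two solves with shared factor and
    // one pass of iterative refinement each (the diagonal spreads over
    // many orders near convergence)
    mat M = AD * A.t();
    M = 0.5 * (M + M.t());
    double damp = 1e-13 * (1.0 + M.diag().max());
    for (int attempt = 0; attempt < 10; ++attempt) {
      mat Mr = M;
      Mr.diag() += damp;
      mat L;
      if (arma::chol(L, Mr, "lower")) {
        auto tri = [&](const vec& r) {
          return vec(arma::solve(arma::trimatu(L.t()),
                                 arma::solve(arma::trimatl(L), r)));
        };
        sol1 = tri(rhs1);
        sol1 += tri(rhs1 - Mr * sol1);
        sol2 = tri(rhs2);
        sol2 += tri(rhs2 - Mr * sol2);
        if (sol1.is_finite() && sol2.is_finite()) return true;
      }
      damp *= 100.0;
    }
    return false;
  };

  int status = 3;  // 3 = numerical failure / iteration limit
  double best_quality = std::numeric_limits<double>::infinity();
  vec best_x, best_y;
  double best_tau = 1.0;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    vec r1 = b * tau - A * x;                    // primal residual
    vec r2 = c * tau - A.t() * y - s;            // dual residual
    double r3 = kappa + arma::dot(c, x) - arma::dot(b, y);  // gap residual
    double mu = (arma::dot(x, s) + tau * kappa) / (n + 1);

    // convergence / infeasibility tests (Andersen & Andersen style)
    double pinf = arma::norm(r1, "inf") / (tau * bnorm);
    double dinf = arma::norm(r2, "inf") / (tau * cnorm);
    double gap = std::fabs(arma::dot(c, x) / tau - arma::dot(b, y) / tau) /
      (1.0 + std::fabs(arma::dot(b, y) / tau));
    if (debug && iter % 10 == 0)
      Rcpp::Rcout << "it=" << iter << " mu=" << mu << " pinf=" << pinf
                  << " dinf=" << dinf << " gap=" << gap
                  << " tau=" << tau << " kappa=" << kappa << "\n";
    double quality = std::max(std::max(pinf, dinf), gap);
    if (quality < best_quality && tau > 1e-8 * std::max(1.0, kappa)) {
      best_quality = quality;
      best_x = x; best_y = y; best_tau = tau;
    }
    if (pinf < tol * 1e3 && dinf < tol * 1e3 && gap < tol * 1e3 &&
        tau > 1e-8 * std::max(1.0, kappa)) {
      status = 0;  // optimal
      break;
    }
    if (mu < tol * 1e-2 && tau < 1e-8 * std::max(1.0, kappa)) {
      // infeasibility ray: classify by the certificate signs
      double bty = arma::dot(b, y), ctx = arma::dot(c, x);
      if (bty > std::fabs(ctx)) status = 1;        // primal infeasible
      else if (ctx < -std::fabs(bty) * 0.0) status = 2;  // unbounded
      else status = (bty > 0) ? 1 : 2;
      break;
    }

    vec dvec = x / s;
    // clamp the scaling spread for stability
    double dmax = dvec.max();
    dvec = arma::clamp(dvec, dmax * 1e-16, dmax);
    mat AD = A;
    AD.each_row() %= dvec.t();

    // --- affine (predictor) direction: eta = 1, sigma = 0
    vec rxs = -x % s;
    double rtk = -tau * kappa;

    auto directions = [&](const vec& rxs_, double rtk_, double eta,
                          vec& dx, vec& ds, vec& dy,
                          double& dtau, double& dkappa) -> bool {
      vec rhat2 = eta * r2 - rxs_ / x;            // = eta r2 - X^{-1} rxs
      vec rhs_u = b + A * (dvec % c);
      vec rhs_v = eta * r1 + A * (dvec % rhat2);
      vec u, v;
      if (!solve_normal(AD, dvec, rhs_u, rhs_v, u, v)) return false;
      // scalar equation for dtau:
      //  (kappa/tau + c'Dc - c'D A' u*?) ... assembled numerically:
      // dx = D (A' dy - c dtau - rhat2); dy = v + u dtau
      // eq3: -c'dx + b'dy - dkappa = eta r3, dkappa = (rtk_ - kappa dtau)/tau
      vec Dc = dvec % c;
      double cDc = arma::dot(c, Dc);
      vec Atu = A.t() * u, Atv = A.t() * v;
      double c_D_Atu = arma::dot(Dc, Atu);
      double c_D_Atv = arma::dot(Dc, Atv);
      double c_D_rhat = arma::dot(Dc, rhat2);
      // -c'dx = -c'D(A'(v+u dtau)) + c'Dc dtau + c'D rhat2
      // eq3: (-c_D_Atv - c_D_Atu dtau) + cDc dtau + c_D_rhat
      //      + b'(v + u dtau) + (kappa/tau) dtau - rtk_/tau = eta r3
      double lhs = -c_D_Atu + cDc + arma::dot(b, u) + kappa / tau;
      double rhs = eta * r3 + rtk_ / tau + c_D_Atv - c_D_rhat - arma::dot(b, v);
      if (std::fabs(lhs) < 1e-300) return false;
      dtau = rhs / lhs;
      dy = v + u * dtau;
      dx = dvec % (A.t() * dy - c * dtau - rhat2);
      ds = (rxs_ - s % dx) / x;
      dkappa = (rtk_ - kappa * dtau) / tau;
      return dx.is_finite() && ds.is_finite() && dy.is_finite() &&
        std::isfinite(dtau) && std::isfinite(dkappa);
    };

    vec dx, ds, dy;
    double dtau, dkappa;
    if (!directions(rxs, rtk, 1.0, dx, ds, dy, dtau, dkappa)) { status = 3; break; }

    auto step_len = [&](const vec& dx_, const vec& ds_, double dtau_,
                        double dkappa_) {
      double a = 1.0;
      for (int j = 0; j < n; ++j) {
        if (dx_[j] < 0) a = std::min(a, -x[j] / dx_[j]);
        if (ds_[j] < 0) a = std::min(a, -s[j] / ds_[j]);
      }
      if (dtau_ < 0) a = std::min(a, -tau / dtau_);
      if (dkappa_ < 0) a = std::min(a, -kappa / dkappa_);
      return a;
    };
    double a_aff = step_len(dx, ds, dtau, dkappa);
    double mu_aff = (arma::dot(x + a_aff * dx, s + a_aff * ds) +
                     (tau + a_aff * dtau) * (kappa + a_aff * dkappa)) / (n + 1);
    double sigma = std::pow(mu_aff / mu, 3);
    sigma = std::min(std::max(sigma, 1e-8), 1.0 - 1e-8);

    // --- corrector
    vec rxs_c = sigma * mu - x % s - dx % ds;
    double rtk_c = sigma * mu - tau * kappa - dtau * dkappa;
    double eta = 1.0 - sigma;
    vec dx2, ds2, dy2;
    double dtau2, dkappa2;
    if (!directions(rxs_c, rtk_c, eta, dx2, ds2, dy2, dtau2, dkappa2)) {
      status = 3; break;
    }
    double a = 0.99 * step_len(dx2, ds2, dtau2, dkappa2);
    a = std::min(a, 1.0);
    if (a < 1e-13) { status = 3; break; }
    // step-quality guard: reject steps that blow the barrier parameter up
    bool accepted = false;
    for (int half = 0; half < 6; ++half) {
      vec xn = x + a * dx2, sn = s + a * ds2;
      double taun = tau + a * dtau2, kappan = kappa + a * dkappa2;
      double mun = (arma::dot(xn, sn) + taun * kappan) / (n + 1);
      if (mun < 5.0 * mu || mun < tol) {
        x = xn; s = sn; y += a * dy2; tau = taun; kappa = kappan;
        accepted = true;
        break;
      }
      a *= 0.5;
    }
    if (!accepted) { status = 3; break; }
    (void)dmax;
  }
  // salvage: a stalled run whose best iterate was already accurate counts
  if (status == 3 && best_quality < 1e-7) {
    status = 0;
    x = best_x; y = best_y; tau = best_tau;
  }

  NumericVector xout(n0), yout(m);
  double obj = NA_REAL;
  if (status == 0) {
    for (int j = 0; j < n0; ++j) {
      double v = x[j] / tau;
      xout[j] = (v < 0 && v > -1e-10) ? 0.0 : v;
    }
    obj = 0.0;
    for (int j = 0; j < n0; ++j) obj += c_[j] * xout[j];
    for (int i = 0; i < m; ++i) {
      double yi = y[i] / tau;
      yout[i] = maximize ? -yi : yi;
    }
  }
  return List::create(_["status"] = status, _["x"] = xout,
                      _["objective"] = obj, _["duals"] = yout,
                      _["iterations"] = iter);
}
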