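// Revised two-phase simplex with explicit basis inverse.
//
// Solves   min/max c'x   s.t.  A x (<=|=|>=) b,  x >= 0.
//
// Proteome-coupled LPs are small (a few hundred rows) but mix coefficient
// magnitudes over ~6 orders (turnover numbers against fluxes) and are almost
// fully degenerate (nearly every right-hand side is zero). Reduced costs and
// the entering column are therefore recomputed from the original data at
// every iteration through an explicit basis inverse, which is itself rebuilt
// by LU (refactorization) periodically and before any terminal decision;
// phantom pivots from a drifted tableau cannot occur. A graded perturbation
// of the right-hand side breaks ties in the ratio test (anti-cycling), and
// Bland's rule takes over when the objective stalls. Final primal values and
// row duals are recovered from the basis against the unperturbed data.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;

static const double EPS_COST = 1e-9;   // reduced-cost optimality tolerance
static const double EPS_PIV = 1e-8;    // minimal admissible pivot magnitude
static const double EPS_FEAS = 1e-7;   // phase-1 residual => infeasible

struct Simplex {
  int m, ntot;
  mat Aext;              // m x ntot, row-flipped original data
  vec bvec;              // perturbed rhs, >= 0
  vec borig;             // unperturbed rhs
  vec c1, c2;            // phase costs
  std::vector<int> basis;
  std::vector<char> is_art;
  mat Binv;
  vec xB;
  int iter = 0, max_iter;
  bool always_bland = false;
  bool debug = false;
  int refactor_every = 100;
  std::vector<char> kept_row;   // original-row survival mask after excision

  bool refactor() {
    mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = Aext.col(basis[i]);
    mat I_(m, m, arma::fill::eye);
    mat Bi;
    if (!arma::solve(Bi, B, I_, arma::solve_opts::fast)) { if (debug) Rcpp::Rcout << "[rf] solve failed iter=" << iter << "\n"; return false; }
    if (!Bi.is_finite()) { if (debug) Rcpp::Rcout << "[rf] not finite\n"; return false; }
    double q = arma::norm(B * Bi - I_, "inf");
    if (q > 1e-6 * m) { if (debug) Rcpp::Rcout << "[rf] quality " << q << " iter=" << iter << "\n"; return false; }
    Binv = Bi;
    xB = Binv * bvec;
    return true;
  }

  // basis crash repair: pivoted QR identifies dependent basis columns,
  // which are replaced by per-row unit columns not already in the basis
  void repair_basis(const std::vector<int>& unit_col_of_row) {
    mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = Aext.col(basis[i]);
    mat Q, R;
    arma::uvec P;
    if (!arma::qr(Q, R, P, B, "vector")) return;
    double rmax = std::fabs(R(0, 0));
    std::vector<char> kept(m, 0);
    for (int i = 0; i < m; ++i)
      if (std::fabs(R(i, i)) > 1e-10 * std::max(1.0, rmax)) kept[P[i]] = 1;
    int k = 0;
    for (int i = 0; i < m; ++i) {
      if (kept[i]) continue;
      while (k < m) {
        int uc = unit_col_of_row[k];
        ++k;
        if (uc < 0) continue;
        bool already = false;
        for (int j = 0; j < m && !already; ++j)
          if (basis[j] == uc) already = true;
        if (!already) { basis[i] = uc; break; }
      }
    }
  }

  // after phase 1: drop rows whose artificial is still basic (redundant
  // constraints) and remove all artificial columns, so that phase 2 runs
  // on a purely structural basis and equality rows can never be silently
  // relaxed again
  bool excise_artificials(std::vector<int>& unit_col_of_row, int n_art_cols) {
    // first try to pivot basic artificials out (preserving their rows);
    // only rows with no admissible pivot are genuinely redundant
    for (int i = 0; i < m; ++i) {
      if (!is_art[basis[i]]) continue;
      arma::rowvec ti = Binv.row(i) * Aext;   // tableau row i, fresh
      int pc = -1;
      double best = 1e-7;
      for (int j = 0; j < ntot; ++j)
        if (!is_art[j] && std::fabs(ti[j]) > best) { pc = j; best = std::fabs(ti[j]); }
      if (pc < 0) continue;
      vec d = Binv * Aext.col(pc);
      double pv = d[i];
      if (std::fabs(pv) < 1e-9) continue;
      Binv.row(i) /= pv;
      for (int r2 = 0; r2 < m; ++r2) {
        if (r2 == i) continue;
        double f = d[r2];
        if (f != 0.0) Binv.row(r2) -= f * Binv.row(i);
      }
      basis[i] = pc;
      xB = Binv * bvec;
    }
    std::vector<arma::uword> drop_rows;
    for (int i = 0; i < m; ++i)
      if (is_art[basis[i]]) drop_rows.push_back(i);
    if (kept_row.empty()) kept_row.assign(m, 1);
    if (!drop_rows.empty()) {
      // mark dropped rows in original coordinates: kept_row currently has
      // one entry per surviving row, in order
      {
        int live = -1, k2 = 0;
        for (size_t oi = 0; oi < kept_row.size(); ++oi) {
          if (!kept_row[oi]) continue;
          ++live;
          if (k2 < (int)drop_rows.size() && (int)drop_rows[k2] == live) {
            kept_row[oi] = 0; ++k2;
          }
        }
      }
      arma::uvec dr(drop_rows.size());
      for (size_t k = 0; k < drop_rows.size(); ++k) dr[k] = drop_rows[k];
      Aext.shed_rows(dr);
      // shed entries of vectors/basis
      std::vector<int> nb; nb.reserve(m - drop_rows.size());
      vec b2(m - (int)drop_rows.size()), bo2(m - (int)drop_rows.size());
      std::vector<int> uc2;
      int k = 0, j = 0;
      for (int i = 0; i < m; ++i) {
        if (k < (int)drop_rows.size() && drop_rows[k] == i) { ++k; continue; }
        nb.push_back(basis[i]);
        b2[j] = bvec[i]; bo2[j] = borig[i];
        uc2.push_back(unit_col_of_row[i]);
        ++j;
      }
      basis = nb; bvec = b2; borig = bo2; unit_col_of_row = uc2;
      m -= (int)drop_rows.size();
    }
    // artificial columns sit at the end of Aext
    if (n_art_cols > 0) {
      Aext.shed_cols(ntot - n_art_cols, ntot - 1);
      ntot -= n_art_cols;
      c1.resize(ntot); c2.resize(ntot);
      is_art.assign(ntot, 0);
      for (int i = 0; i < m; ++i)
        if (unit_col_of_row[i] >= ntot) unit_col_of_row[i] = -1;
    }
    return refactor();
  }

  vec reduced_costs(const vec& c) {
    vec cb(m);
    for (int i = 0; i < m; ++i) cb[i] = c[basis[i]];
    vec y = Binv.t() * cb;
    return c - Aext.t() * y;
  }

  double objective(const vec& c) {
    double o = 0.0;
    for (int i = 0; i < m; ++i) o += c[basis[i]] * xB[i];
    return o;
  }

  // returns 0 optimal, 2 unbounded, 3 numerical failure / iteration limit
  int run_phase(bool phase2, std::vector<int>& unit_col_of_row) {
    const vec& c = phase2 ? c2 : c1;
    int stall = 0, since_refactor = 0, repairs = 0;
    const int max_repairs = 8;
    double last_obj = std::numeric_limits<double>::infinity();
    for (;;) {
      if (iter >= max_iter) { if (debug) Rcpp::Rcout << "[ph] max_iter\n"; return 3; }
      vec r = reduced_costs(c);
      bool bland = always_bland || stall > m + 60;
      int pc = -1;
      std::vector<char> skip(ntot, 0);
      int pr = -1, n_skipped = 0;
      vec d;
      for (;;) {
        // entering selection (repeated when a column offers no stable pivot)
        pc = -1;
        double best = -EPS_COST;
        for (int j = 0; j < ntot; ++j) {
          if (skip[j] || (phase2 && is_art[j])) continue;
          if (r[j] < (bland ? -EPS_COST : best)) {
            pc = j;
            if (bland) break;
            best = r[j];
          }
        }
        if (pc < 0) {
          if (!refactor()) {
            if (repairs++ > max_repairs) return 3;
            repair_basis(unit_col_of_row);
            if (!refactor()) return 3;
            pr = -2;  // restart outer loop
            break;
          }
          // primal feasibility of the terminal basis
          if (xB.min() < -1e-7 * (1.0 + arma::abs(bvec).max())) return 3;
          return 0;
        }
        d = Binv * Aext.col(pc);
        // Harris two-pass ratio test: every positive entry participates in
        // the step bound (any cutoff lets excluded rows be driven far
        // negative); the largest admissible pivot is then chosen
        const double d_zero = 1e-14;
        const double delta = 1e-10 * (1.0 + arma::abs(bvec).max());
        double t_max = std::numeric_limits<double>::infinity();
        for (int i = 0; i < m; ++i)
          if (d[i] > d_zero)
            t_max = std::min(t_max, (std::max(xB[i], 0.0) + delta) / d[i]);
        if (!std::isfinite(t_max)) return 2;  // no blocking row: ray
        pr = -1;
        for (int i = 0; i < m; ++i) {
          if (d[i] > d_zero && std::max(xB[i], 0.0) / d[i] <= t_max + 1e-15 &&
              (pr < 0 || d[i] > d[pr])) {
            pr = i;
          }
        }
        if (pr >= 0 && d[pr] > 1e-5) {
          if (debug) {
            double t_act = std::max(xB[pr], 0.0) / d[pr];
            if (t_act > 1e3 || xB.min() < -1e-6)
              Rcpp::Rcout << "[pv] iter=" << iter << " pc=" << pc << " pr=" << pr
                          << " d=" << d[pr] << " t=" << t_act
                          << " xBmin=" << xB.min() << " tmax=" << t_max << "\n";
          }
          break;   // stable pivot found
        }
        // only noise-level pivots available: pass on this column
        skip[pc] = 1;
        pr = -1;
        if (++n_skipped > 120) {
          // nothing pivotable remains: accept the current (refactor-
          // verified) point as optimal within tolerance
          if (!refactor()) return 3;
          if (xB.min() < -1e-7 * (1.0 + arma::abs(bvec).max())) return 3;
          return 0;
        }
      }
      if (pr == -2) continue;
      double pv = d[pr];
      Binv.row(pr) /= pv;
      for (int i = 0; i < m; ++i) {
        if (i == pr) continue;
        double f = d[i];
        if (f != 0.0) Binv.row(i) -= f * Binv.row(pr);
      }
      basis[pr] = pc;
      xB = Binv * bvec;   // keep the iterate consistent with the inverse
      ++iter; ++since_refactor;
      bool need_refactor = since_refactor >= refactor_every ||
        xB.min() < -1e-7 * (1.0 + arma::abs(bvec).max());
      if (need_refactor) {
        if (!refactor()) {
          if (repairs++ > max_repairs) return 3;
          repair_basis(unit_col_of_row);
          if (!refactor()) return 3;
        }
        since_refactor = 0;
        // a truly infeasible basis after exact refactorization means an
        // earlier pivot was corrupted; retry from scratch
        if (xB.min() < -1e-6 * (1.0 + arma::abs(bvec).max())) { if (debug) Rcpp::Rcout << "[ph] xB neg " << xB.min() << " iter=" << iter << "\n"; return 3; }
      }
      double obj = objective(c);
      if (obj >= last_obj - 1e-12) ++stall; else { stall = 0; last_obj = obj; }
    }
  }
};

// [[Rcpp::export(name = ".simplex_core")]]
List simplex_core(NumericMatrix A_, NumericVector b_, NumericVector c_,
                  IntegerVector dir, bool maximize, int max_iter,
                  bool phase1_only, bool debug = false) {
  const int m = A_.nrow(), n = A_.ncol();

  // anti-degeneracy perturbation: FBA-type programs are almost fully
  // degenerate (nearly every rhs is zero), which stalls any simplex. The
  // rhs is shifted *within the range space of A* (b + A w, w >= 0 a small
  // deterministic golden-ratio scatter), which is equivalent to shifting
  // every variable by w and therefore cannot create spurious
  // infeasibility: conservation relations among the rows stay satisfied.
  // Row flips are decided on the perturbed rhs so the initial slack /
  // artificial basis is feasible; the primal point and objective are
  // recovered against the unperturbed rhs at the end.
  // small programs are solved essentially exactly; the stronger shift is
  // only needed against the massive degeneracy of the large coupled LPs
  const double wscale = (m >= 100) ? 1e-6 : 1e-10;
  vec w(n);
  for (int j = 0; j < n; ++j) {
    double g = 0.6180339887498949 * (j + 1);
    double u = g - (double)(long long)g;   // fractional part
    w[j] = wscale * (0.5 + u);
  }
  std::vector<int> rdir(m), flipped(m, 0);
  mat A(m, n);
  vec b(m), bpert(m);
  for (int i = 0; i < m; ++i) {
    double pi_ = 0.0;
    for (int j = 0; j < n; ++j) pi_ += A_(i, j) * w[j];
    double s = (b_[i] + pi_ < 0.0) ? -1.0 : 1.0;
    flipped[i] = (s < 0.0);
    b[i] = s * b_[i];
    bpert[i] = s * (b_[i] + pi_);
    rdir[i] = (s < 0.0) ? -dir[i] : dir[i];
    for (int j = 0; j < n; ++j) A(i, j) = s * A_(i, j);
  }

  std::vector<int> slack_col(m, -1), art_col(m, -1);
  int ncol = n;
  for (int i = 0; i < m; ++i) if (rdir[i] != 0) slack_col[i] = ncol++;
  for (int i = 0; i < m; ++i) if (rdir[i] >= 0) art_col[i] = ncol++;
  const int ntot = ncol;
  // per-row unit column usable for basis repair (artificial if present,
  // else the '<=' slack, which is +e_i)
  std::vector<int> unit_col_of_row(m);
  int n_art_cols = 0;
  for (int i = 0; i < m; ++i) {
    unit_col_of_row[i] = (art_col[i] >= 0) ? art_col[i] : slack_col[i];
    if (art_col[i] >= 0) ++n_art_cols;
  }

  Simplex S;
  S.debug = debug;
  S.m = m; S.ntot = ntot; S.max_iter = max_iter;
  S.Aext = mat(m, ntot, arma::fill::zeros);
  if (n > 0) S.Aext.cols(0, n - 1) = A;
  for (int i = 0; i < m; ++i) {
    if (slack_col[i] >= 0) S.Aext(i, slack_col[i]) = (rdir[i] < 0) ? 1.0 : -1.0;
    if (art_col[i] >= 0) S.Aext(i, art_col[i]) = 1.0;
  }
  S.is_art.assign(ntot, 0);
  for (int i = 0; i < m; ++i) if (art_col[i] >= 0) S.is_art[art_col[i]] = 1;
  S.borig = b;
  S.bvec = bpert;
  S.c1 = vec(ntot, arma::fill::zeros);
  S.c2 = vec(ntot, arma::fill::zeros);
  for (int i = 0; i < m; ++i) if (art_col[i] >= 0) S.c1[art_col[i]] = 1.0;
  for (int j = 0; j < n; ++j) S.c2[j] = maximize ? -c_[j] : c_[j];
  // artificials may stay basic at zero after phase 1; a large phase-2 cost
  // keeps any direction that would raise them unattractive
  double cmax = 1.0;
  for (int j = 0; j < n; ++j) cmax = std::max(cmax, std::fabs(S.c2[j]));
  for (int i = 0; i < m; ++i) if (art_col[i] >= 0) S.c2[art_col[i]] = 1e6 * cmax;

  // pristine copies for attempt restarts (the first attempt may excise
  // rows/columns before failing); each attempt draws a different
  // anti-degeneracy scatter so restarts explore a different pivot path
  std::vector<vec> bpert_k;
  for (int k = 0; k < 4; ++k) {
    vec wk(n);
    for (int j = 0; j < n; ++j) {
      double g = 0.6180339887498949 * (j + 1) + 0.218 * k * (j + 3);
      double u = g - (double)(long long)g;
      wk[j] = wscale * (0.5 + u);
    }
    vec cand = b + S.Aext.cols(0, n - 1) * wk;
    for (double shrink = 1.0; shrink > 1e-4 && cand.min() < 0; shrink *= 0.1) {
      cand = b + S.Aext.cols(0, n - 1) * (shrink * 0.1 * wk);
    }
    bpert_k.push_back(cand.min() >= 0 ? cand : S.bvec);
  }
  const mat Aext0 = S.Aext;
  const vec bvec0 = S.bvec, borig0 = S.borig, c10 = S.c1, c20 = S.c2;
  const std::vector<char> is_art0 = S.is_art;
  const std::vector<int> unit0 = unit_col_of_row;

  int status = 3;
  double phase1 = NA_REAL;
  const int n_attempts = 4;
  for (int attempt = 0; attempt < n_attempts && status == 3; ++attempt) {
    S.always_bland = attempt > 0;       // robust (terminating) retry path
    const int cadence[4] = { 30, 12, 5, 1 };
    S.refactor_every = cadence[attempt];
    S.iter = 0;
    S.m = m; S.ntot = ntot;
    S.Aext = Aext0; S.bvec = bpert_k[attempt]; S.borig = borig0;
    S.c1 = c10; S.c2 = c20; S.is_art = is_art0;
    S.kept_row.clear();
    unit_col_of_row = unit0;
    S.basis.assign(m, 0);
    for (int i = 0; i < m; ++i)
      S.basis[i] = (rdir[i] < 0) ? slack_col[i] : art_col[i];
    if (!S.refactor()) { status = 3; continue; }

    status = S.run_phase(false, unit_col_of_row);
    phase1 = S.objective(S.c1);
    if (status == 0 && phase1 > EPS_FEAS) status = 1;
    if (status == 2) status = 1;  // phase 1 is bounded below by 0
    if (phase1_only) continue;
    if (status == 0) {
      if (!S.excise_artificials(unit_col_of_row, n_art_cols)) {
        status = 3;
      } else {
        status = S.run_phase(true, unit_col_of_row);
      }
    }
  }

  NumericVector x(n, 0.0), y(m, 0.0);
  double obj = NA_REAL;
  if (status == 0 || status == 2) {
    // recover the primal point against the *unperturbed* right-hand side;
    // dropped (redundant) rows keep dual zero
    vec xb = S.Binv * S.borig;
    for (int i = 0; i < S.m; ++i)
      if (S.basis[i] < n) {
        double v = xb[i];
        if (v < 0.0 && v > -1e-7) v = 0.0;
        x[S.basis[i]] = v;
      }
    if (status == 0) {
      obj = 0.0;
      for (int j = 0; j < n; ++j) obj += c_[j] * x[j];
      vec cb(S.m);
      for (int i = 0; i < S.m; ++i) cb[i] = S.c2[S.basis[i]];
      vec yv = S.Binv.t() * cb;
      // map reduced-row duals back to original row positions
      for (int i = 0, j = 0; i < m && j < S.m; ++i) {
        if (S.kept_row.empty() ? true : S.kept_row[i]) {
          double yi = yv[j++];
          if (flipped[i]) yi = -yi;
          y[i] = maximize ? -yi : yi;
        }
      }
    }
  }
  // self-audit: residual of the recovered point on the unperturbed system
  double resid_max = NA_REAL;
  if (status == 0) {
    vec xfull(S.ntot, arma::fill::zeros);
    vec xb = S.Binv * S.borig;
    for (int i = 0; i < S.m; ++i) xfull[S.basis[i]] = xb[i];
    vec rr = S.Aext * xfull - S.borig;
    resid_max = arma::abs(rr).max();
  }
  return List::create(_["status"] = status, _["x"] = x, _["objective"] = obj,
                      _["duals"] = y, _["iterations"] = S.iter,
                      _["phase1"] = phase1, _["resid_max"] = resid_max);
}
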