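// Bounded-variable two-phase primal simplex for flux balance problems:
//   maximize c'v  subject to  S v = 0,  lb <= v <= ub  (all bounds finite).
// Dense with an explicitly maintained basis inverse and periodic
// refactorization; Dantzig pricing with a Bland fallback against cycling.
// Toy/desk problem sizes only (hundreds of reactions), by design.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double TOL_PIV = 1e-9;    // pivot / reduced-cost tolerance
const double TOL_FEAS = 1e-7;   // phase-1 residual considered feasible
const double BIG = 1e30;

struct LpResult {
  int status;      // 0 optimal, 1 infeasible, 2 iteration limit, 3 singular basis
  double obj;
  vec x;
};

struct Simplex {
  // columns 0..n-1 structural (S), n..n+m-1 artificial (signed unit cols)
  const mat& S;
  int m, n, N;
  vec lo, up;          // bounds for all N vars
  vec asign;           // sign of artificial columns
  ivec basis;          // m basic var indices
  ivec vstat;          // 0 nonbasic at lo, 1 nonbasic at up, 2 basic
  vec x;               // all var values
  mat Binv;
  long pivots;

  Simplex(const mat& S_, const vec& lb, const vec& ub)
    : S(S_), m(S_.n_rows), n(S_.n_cols), N(S_.n_cols + S_.n_rows),
      lo(N), up(N), asign(m), basis(m), vstat(N), x(N, fill::zeros),
      Binv(m, m, fill::zeros), pivots(0) {
    for (int j = 0; j < n; ++j) { lo[j] = lb[j]; up[j] = ub[j]; }
    // nonbasic structural vars sit at the bound closest to zero
    for (int j = 0; j < n; ++j) {
      bool atLo = std::abs(lo[j]) <= std::abs(up[j]);
      vstat[j] = atLo ? 0 : 1;
      x[j] = atLo ? lo[j] : up[j];
    }
    vec r = -S * x.head(n);   // residual the artificials must absorb
    for (int i = 0; i < m; ++i) {
      asign[i] = (r[i] >= 0) ? 1.0 : -1.0;
      int j = n + i;
      lo[j] = 0.0; up[j] = BIG;
      x[j] = std::abs(r[i]);
      basis[i] = j;
      vstat[j] = 2;
      Binv(i, i) = asign[i];  // inverse of diag(asign)
    }
  }

  vec colOf(int j) const {
    if (j < n) return S.col(j);
    vec e(m, fill::zeros); e[(uword)(j - n)] = asign[j - n]; return e;
  }

  bool refactor() {
    mat B(m, m);
    for (int i = 0; i < m; ++i) B.col(i) = colOf(basis[i]);
    mat Bi;
    if (!inv(Bi, B)) return false;
    Binv = Bi;
    // recompute basic values from the nonbasic ones
    vec rhs(m, fill::zeros);
    for (int j = 0; j < N; ++j)
      if (vstat[j] != 2 && x[j] != 0.0) rhs -= colOf(j) * x[j];
    vec xb = Binv * rhs;
    for (int i = 0; i < m; ++i) x[basis[i]] = xb[i];
    return true;
  }

  // one simplex phase; cost vector over all N vars, always maximizing
  // returns status code (0 optimal reached)
  int phase(const vec& cost, long maxit) {
    long it = 0;
    bool bland = false;
    while (true) {
      if (++it > maxit) return 2;
      if (it > maxit / 2) bland = true;
      // duals and reduced costs
      vec cb(m);
      for (int i = 0; i < m; ++i) cb[i] = cost[basis[i]];
      vec y = Binv.t() * cb;
      vec yS = S.t() * y;   // structural part of y'A
      int enter = -1; double best = 0.0; int edir = 0;
      for (int j = 0; j < N; ++j) {
        if (vstat[j] == 2) continue;
        if (up[j] - lo[j] < 1e-12) continue;           // fixed, never enters
        double d = cost[j] - (j < n ? yS[j] : y[j - n] * asign[j - n]);
        int dir = 0;
        if (vstat[j] == 0 && d > TOL_PIV) dir = 1;     // increase from lo
        else if (vstat[j] == 1 && d < -TOL_PIV) dir = -1; // decrease from up
        if (dir == 0) continue;
        if (bland) { enter = j; edir = dir; break; }
        if (std::abs(d) > best) { best = std::abs(d); enter = j; edir = dir; }
      }
      if (enter < 0) return 0;  // optimal for this phase

      vec w = Binv * colOf(enter);
      // x_B changes by -edir * t * w for step length t >= 0
      double tmax = up[enter] - lo[enter];   // bound-flip limit
      int leave = -1; double leavePiv = 0.0; int leaveTo = 0;
      for (int i = 0; i < m; ++i) {
        double coef = edir * w[i];
        int bj = basis[i];
        double lim; int to;
        if (coef > TOL_PIV)       { lim = (x[bj] - lo[bj]) / coef; to = 0; }
        else if (coef < -TOL_PIV) { lim = (up[bj] - x[bj]) / (-coef); to = 1; }
        else continue;
        if (lim < 0) lim = 0.0;
        if (lim < tmax - 1e-12) {
          tmax = lim; leave = i; leavePiv = coef; leaveTo = to;
        } else if (leave >= 0 && lim < tmax + 1e-12) {
          // tie: Bland takes the lowest variable index, otherwise the
          // largest pivot magnitude for stability
          bool take = bland ? (bj < basis[leave])
                            : (std::abs(coef) > std::abs(leavePiv));
          if (take) { leave = i; leavePiv = coef; leaveTo = to; }
        }
      }
      if (tmax >= BIG) return 4;  // unbounded (cannot occur with finite bounds)

      for (int i = 0; i < m; ++i) x[basis[i]] -= edir * tmax * w[i];
      if (leave < 0) {
        // pure bound flip: entering variable crosses to its other bound
        x[enter] = (edir == 1) ? up[enter] : lo[enter];
        vstat[enter] = (edir == 1) ? 1 : 0;
      } else {
        x[enter] += edir * tmax;
        int out = basis[leave];
        x[out] = (leaveTo == 0) ? lo[out] : up[out];  // snap exactly
        vstat[out] = leaveTo;
        basis[leave] = enter;
        vstat[enter] = 2;
        // eta update of Binv
        rowvec pr = Binv.row(leave) / w[leave];
        for (int i = 0; i < m; ++i) {
          if (i == leave) continue;
          if (w[i] != 0.0) Binv.row(i) -= w[i] * pr;
        }
        Binv.row(leave) = pr;
        if (++pivots % 100 == 0) { if (!refactor()) return 3; }
      }
    }
  }
};

LpResult lp_core(const mat& S, const vec& c, const vec& lb, const vec& ub,
                 int sense /* +1 max, -1 min */) {
  int m = S.n_rows, n = S.n_cols;
  LpResult res; res.status = 0; res.obj = NA_REAL; res.x = vec(n, fill::zeros);
  Simplex sx(S, lb, ub);
  long maxit = 200L * (m + n) + 2000L;

  // phase 1: minimize sum of artificials
  vec c1(sx.N, fill::zeros);
  for (int i = 0; i < m; ++i) c1[n + i] = -1.0;
  int st = sx.phase(c1, maxit);
  if (st == 3) { sx.refactor(); st = sx.phase(c1, maxit); }
  if (st != 0) { res.status = (st == 3) ? 3 : 2; return res; }
  double p1 = 0.0;
  for (int i = 0; i < m; ++i) p1 += sx.x[n + i];
  if (p1 > TOL_FEAS * (1.0 + norm(lb, "inf") + norm(ub, "inf"))) {
    res.status = 1; return res;
  }
  // lock artificials at zero
  for (int i = 0; i < m; ++i) {
    sx.up[n + i] = 0.0;
    if (sx.vstat[n + i] != 2) sx.x[n + i] = 0.0;
  }
  // phase 2
  vec c2(sx.N, fill::zeros);
  for (int j = 0; j < n; ++j) c2[j] = sense * c[j];
  st = sx.phase(c2, maxit);
  if (st == 3) { sx.refactor(); st = sx.phase(c2, maxit); }
  if (st != 0) { res.status = 2; return res; }
  sx.refactor();  // clean values before reporting
  res.x = sx.x.head(n);
  // clamp fp dust into bounds
  for (int j = 0; j < n; ++j) {
    if (res.x[j] < lb[j]) res.x[j] = lb[j];
    if (res.x[j] > ub[j]) res.x[j] = ub[j];
  }
  res.obj = dot(c, res.x);
  res.status = 0;
  return res;
}

} // namespace

// [[Rcpp::export(name = ".lp_solve_cpp")]]
Rcpp::List lp_solve_cpp(const arma::mat& S, const arma::vec& c,
                        const arma::vec& lb, const arma::vec& ub,
                        int sense) {
  LpResult r = lp_core(S, c, lb, ub, sense);
  return Rcpp::List::create(
    Rcpp::Named("status") = r.status,
    Rcpp::Named("objective") = r.obj,
    Rcpp::Named("flux") = Rcpp::NumericVector(r.x.begin(), r.x.end()));
}

// Solve many LPs over the same polytope (used by FVA and warm-up generation).
// objs: one objective per column; senses: +1 max / -1 min per column.
// [[Rcpp::export(name = ".lp_solve_many_cpp")]]
Rcpp::List lp_solve_many_cpp(const arma::mat& S, const arma::mat& objs,
                             const arma::vec& senses,
                             const arma::vec& lb, const arma::vec& ub,
                             bool keep_solutions) {
  int k = objs.n_cols, n = S.n_cols;
  vec ov(k); ivec stv(k);
  mat sols;
  if (keep_solutions) sols.set_size(n, k);
  for (int q = 0; q < k; ++q) {
    LpResult r = lp_core(S, objs.col(q), lb, ub, (int) senses[q]);
    ov[q] = r.obj; stv[q] = r.status;
    if (keep_solutions) sols.col(q) = r.x;
  }
  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("objective") = Rcpp::NumericVector(ov.begin(), ov.end()),
    Rcpp::Named("status") = Rcpp::IntegerVector(stv.begin(), stv.end()));
  if (keep_solutions) out["solutions"] = Rcpp::wrap(sols);
  return out;
}
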