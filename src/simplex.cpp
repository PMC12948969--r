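// Dense bounded-variable two-phase primal simplex.
//
// Solves   min / max  c'v   s.t.  S v = b,  lb <= v <= ub
// for the small LPs of constraint-based metabolic modelling (FBA, FVA,
// corner-based vertex sampling, pFBA reformulations).  The basis is kept
// between consecutive objectives over the same polytope, so FVA sweeps and
// random-objective sampling re-optimise from the previous vertex.
//
// Tolerances: primal feasibility 1e-9, dual (reduced cost) 1e-9.  The basis
// matrix is refactorised at every iteration via LAPACK; problems here have
// tens of rows, so accuracy is preferred over factor updates.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

const double FEAS_TOL = 1e-9;
const double OPT_TOL = 1e-9;
const double INF = std::numeric_limits<double>::infinity();

class BoundedSimplex {
public:
  int m, n, ntot;        // rows, structural cols, cols incl. artificials
  mat A;                 // m x ntot
  vec b, lb, ub;         // bounds cover artificials too
  ivec basis;            // m basic column indices
  ivec vstat;            // 0 = at lb, 1 = at ub, 2 = basic
  vec x;                 // current point (length ntot)
  bool feasible_basis = false;
  int last_status = -1;  // 0 ok, 1 infeasible, 2 iter limit

  BoundedSimplex(const mat& S, const vec& rhs, const vec& l, const vec& u)
      : m(S.n_rows), n(S.n_cols), ntot(S.n_cols + S.n_rows) {
    A.set_size(m, ntot);
    A.cols(0, n - 1) = S;
    A.cols(n, ntot - 1).zeros();
    b = rhs;
    lb.set_size(ntot);
    ub.set_size(ntot);
    lb.head(n) = l;
    ub.head(n) = u;
    lb.tail(m).zeros();
    ub.tail(m).zeros();
    basis.set_size(m);
    vstat.set_size(ntot);
    x.zeros(ntot);
  }

  // Set each nonbasic structural variable at its bound nearest zero and
  // start from an all-artificial basis absorbing the residual.
  bool phase1() {
    for (int j = 0; j < n; ++j) {
      x(j) = (std::abs(lb(j)) <= std::abs(ub(j))) ? lb(j) : ub(j);
      vstat(j) = (x(j) == lb(j)) ? 0 : 1;
    }
    vec r = b - A.cols(0, n - 1) * x.head(n);
    for (int i = 0; i < m; ++i) {
      double s = (r(i) >= 0) ? 1.0 : -1.0;
      int j = n + i;
      A.col(j).zeros();
      A(i, j) = s;
      lb(j) = 0.0;
      ub(j) = INF;
      basis(i) = j;
      vstat(j) = 2;
      x(j) = std::abs(r(i));
    }
    vec c(ntot, fill::zeros);
    c.tail(m).ones();
    int st = iterate(c);
    double art = accu(x.tail(m));
    // artificials are pinned at zero for all later objectives
    for (int j = n; j < ntot; ++j) ub(j) = 0.0;
    if (st != 0 || art > 1e-7) {
      last_status = (st == 2) ? 2 : 1;
      return false;
    }
    feasible_basis = true;
    last_status = 0;
    return true;
  }

  // Optimise a structural objective from the current feasible basis.
  // Returns status; on success x holds an optimal vertex.
  int optimize(const vec& c_struct, bool maximize) {
    if (!feasible_basis && !phase1()) return last_status;
    vec c(ntot, fill::zeros);
    c.head(n) = maximize ? vec(-c_struct) : c_struct;
    int st = iterate(c);
    last_status = st;
    return st;
  }

  double objective(const vec& c_struct) const {
    return dot(c_struct, x.head(n));
  }

private:
  void refresh_basics() {
    // recompute basic values exactly from the nonbasic bounds
    vec rhs = b;
    for (int j = 0; j < ntot; ++j)
      if (vstat(j) != 2 && x(j) != 0.0) rhs -= A.col(j) * x(j);
    mat B = A.cols(conv_to<uvec>::from(basis));
    vec xB;
    bool ok = solve(xB, B, rhs, solve_opts::no_approx);
    if (!ok) return;
    for (int i = 0; i < m; ++i) x(basis(i)) = xB(i);
  }

  int iterate(const vec& c) {
    const int max_iter = 5000 + 200 * ntot;
    const int bland_after = 500 + 20 * ntot;
    for (int iter = 0; iter < max_iter; ++iter) {
      mat B = A.cols(conv_to<uvec>::from(basis));
      vec cB(m);
      for (int i = 0; i < m; ++i) cB(i) = c(basis(i));
      vec y;
      if (!solve(y, B.t(), cB, solve_opts::no_approx)) return 1;

      // entering variable
      int q = -1;
      double best = OPT_TOL;
      bool bland = iter > bland_after;
      for (int j = 0; j < ntot; ++j) {
        if (vstat(j) == 2) continue;
        if (ub(j) - lb(j) < 1e-15) continue;  // fixed, cannot move
        double d = c(j) - dot(y, A.col(j));
        double viol = 0.0;
        if (vstat(j) == 0 && d < -OPT_TOL) viol = -d;
        else if (vstat(j) == 1 && d > OPT_TOL) viol = d;
        else continue;
        if (bland) { q = j; break; }
        if (viol > best) { best = viol; q = j; }
      }
      if (q < 0) {            // optimal
        refresh_basics();
        return 0;
      }

      vec w;
      if (!solve(w, B, A.col(q), solve_opts::no_approx)) return 1;
      double t = (vstat(q) == 0) ? 1.0 : -1.0;

      // ratio test: basic variables move by -t*theta*w
      double theta = ub(q) - lb(q);  // bound flip distance (may be inf)
      int leave = -1;
      int leave_to = 0;  // 0 -> lb, 1 -> ub
      for (int i = 0; i < m; ++i) {
        double tw = t * w(i);
        int bj = basis(i);
        double lim;
        int to;
        if (tw > FEAS_TOL) {
          lim = (x(bj) - lb(bj)) / tw;
          to = 0;
        } else if (tw < -FEAS_TOL) {
          lim = (x(bj) - ub(bj)) / tw;
          to = 1;
        } else continue;
        if (lim < theta - 1e-12) {
          theta = std::max(lim, 0.0);
          leave = i;
          leave_to = to;
        }
      }
      if (std::isinf(theta)) return 3;  // unbounded (finite bounds: unreachable)

      // apply step
      x(q) += t * theta;
      for (int i = 0; i < m; ++i) x(basis(i)) -= t * theta * w(i);
      if (leave < 0) {
        vstat(q) = 1 - vstat(q);          // bound flip
        x(q) = (vstat(q) == 0) ? lb(q) : ub(q);
      } else {
        int bj = basis(leave);
        x(bj) = (leave_to == 0) ? lb(bj) : ub(bj);
        vstat(bj) = leave_to;
        basis(leave) = q;
        vstat(q) = 2;
      }
    }
    return 2;
  }
};

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_lp(const arma::mat& S, const arma::vec& b, const arma::vec& lb,
                  const arma::vec& ub, const arma::vec& obj, bool maximize) {
  BoundedSimplex lp(S, b, lb, ub);
  int st = lp.optimize(obj, maximize);
  return Rcpp::List::create(
      Rcpp::Named("status") = st,
      Rcpp::Named("objective") = (st == 0) ? lp.objective(obj) : NA_REAL,
      Rcpp::Named("solution") = Rcpp::NumericVector(
          lp.x.begin(), lp.x.begin() + S.n_cols));
}

// [[Rcpp::export]]
bool cpp_feasible(const arma::mat& S, const arma::vec& b, const arma::vec& lb,
                  const arma::vec& ub) {
  BoundedSimplex lp(S, b, lb, ub);
  return lp.phase1();
}

// Flux variability: min and max of each requested column (1-based indices),
// warm-starting every solve from the previous optimal basis.
// [[Rcpp::export]]
Rcpp::List cpp_fva(const arma::mat& S, const arma::vec& b, const arma::vec& lb,
                   const arma::vec& ub, const arma::ivec& idx) {
  BoundedSimplex lp(S, b, lb, ub);
  int k = idx.n_elem, n = S.n_cols;
  mat out(k, 2);
  ivec status(k, fill::zeros);
  if (!lp.phase1()) {
    out.fill(NA_REAL);
    status.fill(lp.last_status);
    return Rcpp::List::create(Rcpp::Named("ranges") = out,
                              Rcpp::Named("status") = status);
  }
  vec c(n, fill::zeros);
  for (int t = 0; t < k; ++t) {
    int j = idx(t) - 1;
    c(j) = 1.0;
    int s1 = lp.optimize(c, false);
    out(t, 0) = (s1 == 0) ? lp.x(j) : NA_REAL;
    int s2 = lp.optimize(c, true);
    out(t, 1) = (s2 == 0) ? lp.x(j) : NA_REAL;
    status(t) = (s1 == 0 && s2 == 0) ? 0 : std::max(s1, s2);
    c(j) = 0.0;
  }
  return Rcpp::List::create(Rcpp::Named("ranges") = out,
                            Rcpp::Named("status") = status);
}

// Corner-based sampling driver: one LP per row of W (objective weights),
// sense[i] TRUE = maximize.  Returns the optimal vertex per sample.
// [[Rcpp::export]]
Rcpp::List cpp_sample_vertices(const arma::mat& S, const arma::vec& b,
                               const arma::vec& lb, const arma::vec& ub,
                               const arma::mat& W,
                               const arma::uvec& maximize) {
  BoundedSimplex lp(S, b, lb, ub);
  int ns = W.n_rows, n = S.n_cols;
  mat out(ns, n, fill::value(NA_REAL));
  vec objs(ns, fill::value(NA_REAL));
  ivec status(ns, fill::zeros);
  if (!lp.phase1()) {
    status.fill(lp.last_status);
    return Rcpp::List::create(Rcpp::Named("samples") = out,
                              Rcpp::Named("objectives") = objs,
                              Rcpp::Named("status") = status);
  }
  for (int i = 0; i < ns; ++i) {
    vec c = W.row(i).t();
    int st = lp.optimize(c, maximize(i) == 1);
    status(i) = st;
    if (st == 0) {
      out.row(i) = lp.x.head(n).t();
      objs(i) = lp.objective(c);
    }
  }
  return Rcpp::List::create(Rcpp::Named("samples") = out,
                            Rcpp::Named("objectives") = objs,
                            Rcpp::Named("status") = status);
}
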