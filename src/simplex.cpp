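// Dense two-phase primal simplex for box-constrained linear programs:
//
//     max (or min)  c'v   subject to   A v = b,   lb <= v <= ub
//
// This is the FBA engine of the package. Networks here are tiny (tens of
// reactions), so a dense tableau with Bland's anti-cycling rule is both
// simple and fast; the evolutionary loop calls it ~10^5-10^6 times.
//
// Formulation: shift x = v - lb (so x >= 0), append one slack row
// x_j + s_j = u_j per finite upper bound u_j = ub_j - lb_j, and Phase-1
// artificial variables on the (sign-normalised) equality rows. Bland's
// rule (lowest eligible index enters; lowest basic index leaves among
// minimum ratios) makes every solve deterministic and cycle-free.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double EPS_PIV = 1e-9;   // minimum pivot magnitude
const double EPS_RED = 1e-9;   // reduced-cost optimality tolerance
const double EPS_FEAS = 1e-7;  // Phase-1 residual tolerance

// status: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit,
//         4 invalid bounds (non-finite lb or lb > ub)
// infeasout: Phase-1 optimum (minimum total artificial mass); 0 when a
// feasible point exists, > 0 otherwise — a natural infeasibility degree.
int solve_box_lp(int m, int n, const double* A, const double* bvec,
                 const double* cvec, const double* lb, const double* ub,
                 bool maximize, double* vout, double* objout,
                 double* infeasout) {
  std::vector<double> u(n);
  int ns = 0;
  for (int j = 0; j < n; ++j) {
    if (!std::isfinite(lb[j])) return 4;
    u[j] = ub[j] - lb[j];
    if (u[j] < -1e-12) return 4;
    if (u[j] < 0) u[j] = 0;
    if (std::isfinite(u[j])) ++ns;
  }

  const int M = m + ns;          // constraint rows
  const int N = n + ns + m;      // structural + slack + artificial columns
  std::vector<double> T((size_t)M * N, 0.0), r(M, 0.0), red(N, 0.0);
  std::vector<int> basis(M);
  std::vector<char> banned(N, 0);

  // equality rows, sign-normalised so rhs >= 0; artificial basis
  for (int i = 0; i < m; ++i) {
    double rhs = bvec[i];
    for (int j = 0; j < n; ++j) rhs -= A[i + (size_t)j * m] * lb[j];
    const double sgn = (rhs < 0.0) ? -1.0 : 1.0;
    for (int j = 0; j < n; ++j)
      T[(size_t)i * N + j] = sgn * A[i + (size_t)j * m];
    r[i] = sgn * rhs;
    T[(size_t)i * N + (n + ns + i)] = 1.0;
    basis[i] = n + ns + i;
  }
  // upper-bound slack rows; slack basis
  {
    int k = 0;
    for (int j = 0; j < n; ++j) {
      if (!std::isfinite(u[j])) continue;
      const int row = m + k;
      T[(size_t)row * N + j] = 1.0;
      T[(size_t)row * N + (n + k)] = 1.0;
      r[row] = u[j];
      basis[row] = n + k;
      ++k;
    }
  }

  auto pivot = [&](int prow, int pcol) {
    double* rowp = &T[(size_t)prow * N];
    const double inv = 1.0 / rowp[pcol];
    for (int j = 0; j < N; ++j) rowp[j] *= inv;
    rowp[pcol] = 1.0;
    r[prow] *= inv;
    for (int i = 0; i < M; ++i) {
      if (i == prow) continue;
      double* rowi = &T[(size_t)i * N];
      const double f = rowi[pcol];
      if (f != 0.0) {
        for (int j = 0; j < N; ++j) rowi[j] -= f * rowp[j];
        rowi[pcol] = 0.0;
        r[i] -= f * r[prow];
      }
    }
    const double f = red[pcol];
    if (f != 0.0) {
      for (int j = 0; j < N; ++j) red[j] -= f * rowp[j];
      red[pcol] = 0.0;
    }
    basis[prow] = pcol;
  };

  const long maxit = 200L * (M + N) + 1000L;
  auto iterate = [&]() -> int {
    for (long it = 0; it < maxit; ++it) {
      int enter = -1;
      for (int j = 0; j < N; ++j) {
        if (!banned[j] && red[j] < -EPS_RED) { enter = j; break; }
      }
      if (enter < 0) return 0;
      int leave = -1;
      double best = 0.0;
      for (int i = 0; i < M; ++i) {
        const double a = T[(size_t)i * N + enter];
        if (a > EPS_PIV) {
          const double ratio = r[i] / a;
          if (leave < 0 || ratio < best - 1e-12 ||
              (ratio < best + 1e-12 && basis[i] < basis[leave])) {
            leave = i;
            best = ratio;
          }
        }
      }
      if (leave < 0) return 2;
      pivot(leave, enter);
    }
    return 3;
  };

  // ---- Phase 1: minimise the sum of artificials
  for (int j = 0; j < N; ++j) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += T[(size_t)i * N + j];
    red[j] = ((j >= n + ns) ? 1.0 : 0.0) - s;
  }
  {
    const int st = iterate();
    if (st == 3) return 3;
    // Phase-1 objective is bounded below by 0, so st == 2 cannot occur
    // with exact arithmetic; treat it as an iteration failure.
    if (st == 2) return 3;
  }
  double infeas = 0.0, scale = 1.0;
  for (int i = 0; i < M; ++i) {
    if (basis[i] >= n + ns) infeas += r[i];
    if (std::fabs(r[i]) > scale) scale = std::fabs(r[i]);
  }
  if (infeasout) *infeasout = (infeas > EPS_FEAS * scale) ? infeas : 0.0;
  if (infeas > EPS_FEAS * scale) return 1;

  // drive residual (zero-valued) artificials out of the basis where possible
  for (int i = 0; i < M; ++i) {
    if (basis[i] < n + ns) continue;
    int piv = -1;
    for (int j = 0; j < n + ns; ++j) {
      if (std::fabs(T[(size_t)i * N + j]) > 1e-7) { piv = j; break; }
    }
    if (piv >= 0) pivot(i, piv);
    // else: redundant row; artificial stays basic at value ~0
  }
  for (int j = n + ns; j < N; ++j) banned[j] = 1;

  // ---- Phase 2: minimise d'x with d = -c (max) or c (min)
  std::vector<double> d(N, 0.0);
  for (int j = 0; j < n; ++j) d[j] = maximize ? -cvec[j] : cvec[j];
  for (int j = 0; j < N; ++j) {
    double s = 0.0;
    for (int i = 0; i < M; ++i) {
      const double db = (basis[i] < N) ? d[basis[i]] : 0.0;
      if (db != 0.0) s += db * T[(size_t)i * N + j];
    }
    red[j] = d[j] - s;
  }
  {
    const int st = iterate();
    if (st != 0) return st;  // 2 unbounded, 3 iteration limit
  }

  // recover v = lb + x, clipped into the box against roundoff
  std::vector<double> x(n, 0.0);
  for (int i = 0; i < M; ++i) {
    if (basis[i] < n) x[basis[i]] = r[i];
  }
  double obj = 0.0;
  for (int j = 0; j < n; ++j) {
    double xj = x[j];
    if (xj < 0.0) xj = 0.0;
    if (std::isfinite(u[j]) && xj > u[j]) xj = u[j];
    vout[j] = lb[j] + xj;
    obj += cvec[j] * vout[j];
  }
  *objout = obj;
  return 0;
}

}  // namespace

//' @name simplex_box_lp
//' @noRd
// [[Rcpp::export(name = ".simplex_box_lp")]]
List simplex_box_lp(NumericMatrix A, NumericVector b, NumericVector cost,
                    NumericVector lb, NumericVector ub, bool maximize) {
  const int m = A.nrow(), n = A.ncol();
  if (b.size() != m || cost.size() != n || lb.size() != n || ub.size() != n)
    stop("inconsistent LP dimensions");
  NumericVector v(n);
  double obj = NA_REAL, infeas = 0.0;
  int status = solve_box_lp(m, n, REAL(A), REAL(b), REAL(cost), REAL(lb),
                            REAL(ub), maximize, REAL(v), &obj, &infeas);
  if (status == 4) stop("invalid bounds: lb must be finite and lb <= ub");
  if (status == 3) stop("simplex iteration limit reached");
  return List::create(_["status"] = status,
                      _["objective"] = (status == 0) ? obj : NA_REAL,
                      _["v"] = v,
                      _["infeasibility"] = infeas);
}

//' @name fba_solve_batch
//' @noRd
// [[Rcpp::export(name = ".fba_solve_batch")]]
List fba_solve_batch(NumericMatrix S, NumericMatrix LB, NumericMatrix UB,
                     int objective_col, bool maximize) {
  const int m = S.nrow(), n = S.ncol();
  const int K = LB.nrow();
  if (UB.nrow() != K || LB.ncol() != n || UB.ncol() != n)
    stop("bound matrices must be K x n");
  if (objective_col < 1 || objective_col > n)
    stop("objective_col out of range");

  std::vector<double> b(m, 0.0), lb(n), ub(n), cost(n, 0.0);
  cost[objective_col - 1] = 1.0;

  IntegerVector status(K);
  NumericVector objval(K, NA_REAL);
  NumericVector infeas(K, 0.0);
  NumericMatrix V(K, n);
  std::vector<double> v(n);

  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < n; ++j) {
      lb[j] = LB(k, j);
      ub[j] = UB(k, j);
    }
    double obj = NA_REAL, inf_k = 0.0;
    int st = solve_box_lp(m, n, REAL(S), b.data(), cost.data(), lb.data(),
                          ub.data(), maximize, v.data(), &obj, &inf_k);
    if (st == 3) stop("simplex iteration limit reached in batch solve");
    if (st == 4) st = 1;  // invalid decoded box treated as infeasible
    status[k] = st;
    infeas[k] = inf_k;
    if (st == 0) {
      objval[k] = obj;
      for (int j = 0; j < n; ++j) V(k, j) = v[j];
    } else {
      for (int j = 0; j < n; ++j) V(k, j) = NA_REAL;
    }
  }
  return List::create(_["status"] = status, _["objective"] = objval,
                      _["fluxes"] = V, _["infeasibility"] = infeas);
}
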