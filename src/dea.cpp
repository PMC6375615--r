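// Two-phase dense primal simplex and the VRS (BCC) envelopment programs.
//
// The LPs solved here are tiny (a few dozen rows/columns) but are solved
// hundreds of thousands of times per Monte-Carlo run, hence compiled code.
// Minimization form: min c'x  s.t.  A x (<=,=,>=) b, x >= 0.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double TOL = 1e-9;

struct LPResult {
  int status;            // 0 ok, 1 infeasible, 2 unbounded, 3 iteration limit
  double objective;
  std::vector<double> x;
};

// Standard tableau simplex on equality form with artificials already
// appended. Dantzig pricing with a Bland fallback to guarantee termination.
static int simplex_core(std::vector<std::vector<double>> &T,
                        std::vector<int> &basis, int m, int ncols,
                        int maxit, bool bland_from_start) {
  int it = 0;
  bool bland = bland_from_start;
  while (true) {
    if (++it > maxit) {
      if (!bland) { bland = true; it = 0; continue; }
      return 3;
    }
    // entering column: most negative reduced cost (row m holds -z row costs)
    int enter = -1;
    double best = -TOL;
    for (int j = 0; j < ncols; ++j) {
      double rc = T[m][j];
      if (bland) {
        if (rc < -TOL) { enter = j; break; }
      } else if (rc < best) {
        best = rc; enter = j;
      }
    }
    if (enter < 0) return 0;  // optimal
    // ratio test
    int leave = -1;
    double best_ratio = 0.0;
    for (int i = 0; i < m; ++i) {
      double a = T[i][enter];
      if (a > TOL) {
        double ratio = T[i][ncols] / a;
        // ties go to the smallest basis index (required for Bland's rule)
        if (leave < 0 || ratio < best_ratio - TOL ||
            (std::fabs(ratio - best_ratio) <= TOL && basis[i] < basis[leave])) {
          leave = i; best_ratio = ratio;
        }
      }
    }
    if (leave < 0) return 2;  // unbounded
    // pivot
    double piv = T[leave][enter];
    for (int j = 0; j <= ncols; ++j) T[leave][j] /= piv;
    for (int i = 0; i <= m; ++i) {
      if (i == leave) continue;
      double f = T[i][enter];
      if (std::fabs(f) > 0.0) {
        for (int j = 0; j <= ncols; ++j) T[i][j] -= f * T[leave][j];
      }
    }
    basis[leave] = enter;
  }
}

// ctype: -1 '<=', 0 '=', 1 '>='
static LPResult lp_solve(const std::vector<std::vector<double>> &A,
                         const std::vector<double> &b,
                         const std::vector<double> &c,
                         const std::vector<int> &ctype) {
  int m = (int)A.size();
  int n = (int)c.size();
  // normalize rows so rhs >= 0
  std::vector<std::vector<double>> Ar(A);
  std::vector<double> br(b);
  std::vector<int> ct(ctype);
  for (int i = 0; i < m; ++i) {
    if (br[i] < 0) {
      for (int j = 0; j < n; ++j) Ar[i][j] = -Ar[i][j];
      br[i] = -br[i];
      ct[i] = -ct[i];
    }
  }
  // columns: n structural, then one slack/surplus per inequality row,
  // then one artificial per '>='/'=' row
  int nslack = 0, nart = 0;
  for (int i = 0; i < m; ++i) {
    if (ct[i] != 0) ++nslack;
    if (ct[i] != -1) ++nart;
  }
  int ncols = n + nslack + nart;
  std::vector<std::vector<double>> T(m + 1, std::vector<double>(ncols + 1, 0.0));
  std::vector<int> basis(m, -1);
  int js = n, ja = n + nslack;
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) T[i][j] = Ar[i][j];
    T[i][ncols] = br[i];
    if (ct[i] == -1) {            // <= : slack is basic
      T[i][js] = 1.0; basis[i] = js; ++js;
    } else if (ct[i] == 1) {      // >= : surplus + artificial
      T[i][js] = -1.0; ++js;
      T[i][ja] = 1.0; basis[i] = ja; ++ja;
    } else {                      // = : artificial
      T[i][ja] = 1.0; basis[i] = ja; ++ja;
    }
  }
  LPResult res;
  res.x.assign(n, 0.0);
  int maxit = 200 * (m + ncols);
  // Phase 1: minimize sum of artificials
  if (nart > 0) {
    for (int j = n + nslack; j < ncols; ++j) T[m][j] = 1.0;
    for (int i = 0; i < m; ++i) {
      if (basis[i] >= n + nslack) {
        for (int j = 0; j <= ncols; ++j) T[m][j] -= T[i][j];
      }
    }
    int st = simplex_core(T, basis, m, ncols, maxit, false);
    if (st != 0) { res.status = (st == 2) ? 1 : st; return res; }
    if (T[m][ncols] < -1e-7) { res.status = 1; return res; }  // -z = sum art > 0
    // drive any artificial still basic (at zero) out of the basis
    for (int i = 0; i < m; ++i) {
      if (basis[i] >= n + nslack) {
        int enter = -1;
        for (int j = 0; j < n + nslack; ++j) {
          if (std::fabs(T[i][j]) > 1e-8) { enter = j; break; }
        }
        if (enter >= 0) {
          double piv = T[i][enter];
          for (int j = 0; j <= ncols; ++j) T[i][j] /= piv;
          for (int k2 = 0; k2 <= m; ++k2) {
            if (k2 == i) continue;
            double f = T[k2][enter];
            if (std::fabs(f) > 0.0)
              for (int j = 0; j <= ncols; ++j) T[k2][j] -= f * T[i][j];
          }
          basis[i] = enter;
        }
        // else: redundant row, harmless
      }
    }
    // block artificial columns from re-entering
    for (int i = 0; i <= m; ++i)
      for (int j = n + nslack; j < ncols; ++j) T[i][j] = 0.0;
  }
  // Phase 2 objective
  for (int j = 0; j <= ncols; ++j) T[m][j] = 0.0;
  for (int j = 0; j < n; ++j) T[m][j] = c[j];
  for (int i = 0; i < m; ++i) {
    int bj = basis[i];
    double cb = (bj < n) ? c[bj] : 0.0;
    if (cb != 0.0)
      for (int j = 0; j <= ncols; ++j) T[m][j] -= cb * T[i][j];
  }
  // artificial columns were zeroed above, so they can never re-enter
  int st = simplex_core(T, basis, m, ncols, maxit, false);
  if (st != 0) { res.status = st; return res; }
  for (int i = 0; i < m; ++i)
    if (basis[i] < n) res.x[basis[i]] = T[i][ncols];
  res.objective = -T[m][ncols];
  res.status = 0;
  return res;
}

// Build and solve the two-phase VRS envelopment program for DMU k.
// orientation: 0 input (min theta), 1 output (max phi).
// Returns objective, lambdas, input slacks, output slacks.
static int vrs_one(const NumericMatrix &X, const NumericMatrix &Y, int k,
                   int orientation, double &obj,
                   std::vector<double> &lambda,
                   std::vector<double> &sx, std::vector<double> &sy) {
  int n = X.nrow(), m = X.ncol(), s = Y.ncol();
  int nrow = m + s + 1;
  int nvar = n + 1;  // lambdas + theta/phi
  std::vector<std::vector<double>> A(nrow, std::vector<double>(nvar, 0.0));
  std::vector<double> b(nrow, 0.0), c(nvar, 0.0);
  std::vector<int> ct(nrow, 0);
  // rows 0..m-1: inputs, rows m..m+s-1: outputs, last: convexity
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) A[i][j] = X(j, i);
    ct[i] = -1;
    if (orientation == 0) { A[i][n] = -X(k, i); b[i] = 0.0; }
    else                  { b[i] = X(k, i); }
  }
  for (int r = 0; r < s; ++r) {
    for (int j = 0; j < n; ++j) A[m + r][j] = Y(j, r);
    ct[m + r] = 1;
    if (orientation == 0) { b[m + r] = Y(k, r); }
    else                  { A[m + r][n] = -Y(k, r); b[m + r] = 0.0; }
  }
  for (int j = 0; j < n; ++j) A[m + s][j] = 1.0;
  b[m + s] = 1.0; ct[m + s] = 0;
  c[n] = (orientation == 0) ? 1.0 : -1.0;  // min theta / max phi
  LPResult p1 = lp_solve(A, b, c, ct);
  if (p1.status != 0) return p1.status;
  obj = p1.x[n];
  // Phase 2: fix the radial factor, maximize total slack.
  // Variables: lambdas (n), input slacks (m), output slacks (s); equalities.
  int nvar2 = n + m + s;
  std::vector<std::vector<double>> A2(nrow, std::vector<double>(nvar2, 0.0));
  std::vector<double> b2(nrow, 0.0), c2(nvar2, 0.0);
  std::vector<int> ct2(nrow, 0);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) A2[i][j] = X(j, i);
    A2[i][n + i] = 1.0;
    b2[i] = (orientation == 0) ? obj * X(k, i) : X(k, i);
  }
  for (int r = 0; r < s; ++r) {
    for (int j = 0; j < n; ++j) A2[m + r][j] = Y(j, r);
    A2[m + r][n + m + r] = -1.0;
    b2[m + r] = (orientation == 0) ? Y(k, r) : obj * Y(k, r);
  }
  for (int j = 0; j < n; ++j) A2[m + s][j] = 1.0;
  b2[m + s] = 1.0;
  for (int j = n; j < nvar2; ++j) c2[j] = -1.0;  // max sum slacks
  LPResult p2 = lp_solve(A2, b2, c2, ct2);
  if (p2.status != 0) return p2.status;
  lambda.assign(p2.x.begin(), p2.x.begin() + n);
  sx.assign(p2.x.begin() + n, p2.x.begin() + n + m);
  sy.assign(p2.x.begin() + n + m, p2.x.begin() + n + m + s);
  return 0;
}

// [[Rcpp::export(name = ".dea_vrs_cpp")]]
List dea_vrs_cpp(NumericMatrix X, NumericMatrix Y, int orientation,
                 IntegerVector which_dmu) {
  int n = X.nrow(), m = X.ncol(), s = Y.ncol();
  int nk = which_dmu.size();
  NumericVector obj(nk), slack_total(nk);
  NumericMatrix lambda(nk, n), sx(nk, m), sy(nk, s);
  IntegerVector status(nk);
  // DEA scores are invariant to per-column rescaling; normalize every
  // column to unit maximum so the simplex tolerances are well scaled,
  // then report slacks back in original units.
  NumericMatrix Xs(n, m), Ys(n, s);
  std::vector<double> cx(m, 1.0), cy(s, 1.0);
  for (int i = 0; i < m; ++i) {
    double mx = 0.0;
    for (int j = 0; j < n; ++j) mx = std::max(mx, X(j, i));
    cx[i] = (mx > 0) ? mx : 1.0;
    // relative conditioning floor: keeps near-zero inputs well inside
    // the simplex tolerances without visibly moving the frontier
    for (int j = 0; j < n; ++j)
      Xs(j, i) = std::max(X(j, i) / cx[i], 1e-7);
  }
  for (int r = 0; r < s; ++r) {
    double mx = 0.0;
    for (int j = 0; j < n; ++j) mx = std::max(mx, Y(j, r));
    cy[r] = (mx > 0) ? mx : 1.0;
    for (int j = 0; j < n; ++j) Ys(j, r) = Y(j, r) / cy[r];
  }
  for (int q = 0; q < nk; ++q) {
    int k = which_dmu[q] - 1;
    double o = NA_REAL;
    std::vector<double> lam, isl, osl;
    int st = vrs_one(Xs, Ys, k, orientation, o, lam, isl, osl);
    status[q] = st;
    if (st == 0) {
      obj[q] = o;
      double tot = 0.0;
      for (int j = 0; j < n; ++j) lambda(q, j) = lam[j];
      for (int i = 0; i < m; ++i) {
        sx(q, i) = isl[i] * cx[i]; tot += isl[i];
      }
      for (int r = 0; r < s; ++r) {
        sy(q, r) = osl[r] * cy[r]; tot += osl[r];
      }
      // total slack on the scaled (unit-max) axes: scale-free gauge of
      // whether any residual slack exists
      slack_total[q] = tot;
    } else {
      obj[q] = NA_REAL; slack_total[q] = NA_REAL;
    }
  }
  return List::create(_["objective"] = obj, _["lambda"] = lambda,
                      _["input_slacks"] = sx, _["output_slacks"] = sy,
                      _["slack_total"] = slack_total, _["status"] = status);
}

// Generic LP entry point, used for diagnostics and cross-checks.
// [[Rcpp::export(name = ".lp_simplex_cpp")]]
List lp_simplex_cpp(NumericMatrix A, NumericVector b, NumericVector cc,
                    IntegerVector ctype) {
  int m = A.nrow(), n = A.ncol();
  std::vector<std::vector<double>> Av(m, std::vector<double>(n));
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) Av[i][j] = A(i, j);
  std::vector<double> bv(b.begin(), b.end()), cv(cc.begin(), cc.end());
  std::vector<int> ctv(ctype.begin(), ctype.end());
  LPResult r = lp_solve(Av, bv, cv, ctv);
  return List::create(_["status"] = r.status, _["objective"] = r.objective,
                      _["x"] = NumericVector(r.x.begin(), r.x.end()));
}
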