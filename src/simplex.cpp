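#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Dense two-phase primal simplex for
//   minimize c'x  subject to  A x = b, x >= 0.
// Bland's rule throughout, so the method terminates on degenerate tableaus.
// Status codes: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit.

namespace {

const double PIV_TOL = 1e-9;

struct Tableau {
  arma::mat T;              // m x (ncol+1), last column = rhs
  arma::rowvec zc;          // reduced-cost row z_j - c_j, length ncol+1
  std::vector<int> basis;   // basis[r] = column basic in row r
};

void pivot(Tableau &tb, int r, int j) {
  tb.T.row(r) /= tb.T(r, j);
  for (arma::uword i = 0; i < tb.T.n_rows; ++i) {
    if ((int)i != r && std::abs(tb.T(i, j)) > 0.0)
      tb.T.row(i) -= tb.T(i, j) * tb.T.row(r);
  }
  tb.zc -= tb.zc(j) * tb.T.row(r);
  tb.basis[r] = j;
}

// Run simplex iterations on the tableau, allowing only columns with
// allowed[j] true to enter. Returns 0 on optimality, 2 on unboundedness,
// 3 on iteration limit.
int iterate(Tableau &tb, const std::vector<bool> &allowed, int max_iter) {
  const int m = tb.T.n_rows;
  const int ncol = tb.T.n_cols - 1;
  for (int it = 0; it < max_iter; ++it) {
    // Bland: entering column = smallest index with positive reduced cost.
    int enter = -1;
    for (int j = 0; j < ncol; ++j) {
      if (allowed[j] && tb.zc(j) > PIV_TOL) { enter = j; break; }
    }
    if (enter < 0) return 0;
    // Ratio test; Bland tie-break on smallest basis index.
    int leave = -1;
    double best = 0.0;
    for (int r = 0; r < m; ++r) {
      double a = tb.T(r, enter);
      if (a > PIV_TOL) {
        double ratio = tb.T(r, ncol) / a;
        if (leave < 0 || ratio < best - PIV_TOL ||
            (ratio < best + PIV_TOL && tb.basis[r] < tb.basis[leave])) {
          leave = r; best = ratio;
        }
      }
    }
    if (leave < 0) return 2;
    pivot(tb, leave, enter);
  }
  return 3;
}

} // namespace

// [[Rcpp::export(name = ".simplex_cpp")]]
Rcpp::List simplex_cpp(const arma::mat &A, const arma::vec &b,
                       const arma::vec &c) {
  const int m = A.n_rows, n = A.n_cols;
  if (m == 0) {
    // No constraints: optimum is 0 iff c >= 0 (variables at zero), else unbounded.
    for (int j = 0; j < n; ++j)
      if (c(j) < -PIV_TOL)
        return Rcpp::List::create(Rcpp::Named("status") = 2,
                                  Rcpp::Named("x") = arma::vec(n, arma::fill::zeros),
                                  Rcpp::Named("objective") = NA_REAL);
    return Rcpp::List::create(Rcpp::Named("status") = 0,
                              Rcpp::Named("x") = arma::vec(n, arma::fill::zeros),
                              Rcpp::Named("objective") = 0.0);
  }

  Tableau tb;
  tb.T.set_size(m, n + m + 1);
  tb.T.cols(0, n - 1) = A;
  tb.T.cols(n, n + m - 1) = arma::eye(m, m);
  tb.T.col(n + m) = b;
  for (int r = 0; r < m; ++r) {
    if (tb.T(r, n + m) < 0) tb.T.row(r) *= -1.0;   // b >= 0; artificial keeps +1...
    tb.T(r, n + r) = 1.0;                           // ...so rewrite its column
  }
  tb.basis.resize(m);
  for (int r = 0; r < m; ++r) tb.basis[r] = n + r;

  // Phase 1: minimize the sum of artificials; zc(j) = z_j - c1_j with
  // c1 = (0,...,0,1,...,1); for basic artificials z_j = column sums.
  tb.zc = arma::sum(tb.T, 0);
  for (int j = n; j < n + m; ++j) tb.zc(j) -= 1.0;

  std::vector<bool> allowed(n + m, true);
  int max_iter = 2000 * (n + m + 10);
  int st = iterate(tb, allowed, max_iter);
  if (st == 3)
    return Rcpp::List::create(Rcpp::Named("status") = 3,
                              Rcpp::Named("x") = arma::vec(n, arma::fill::zeros),
                              Rcpp::Named("objective") = NA_REAL);
  if (tb.zc(n + m) > 1e-7)   // phase-1 optimum > 0: original system infeasible
    return Rcpp::List::create(Rcpp::Named("status") = 1,
                              Rcpp::Named("x") = arma::vec(n, arma::fill::zeros),
                              Rcpp::Named("objective") = NA_REAL);

  // Drive remaining artificials out of the basis; a row with no structural
  // pivot is redundant and is zeroed out (harmless for further pivoting).
  std::vector<bool> live(m, true);
  for (int r = 0; r < m; ++r) {
    if (tb.basis[r] >= n) {
      int piv = -1;
      for (int j = 0; j < n; ++j)
        if (std::abs(tb.T(r, j)) > PIV_TOL) { piv = j; break; }
      if (piv >= 0) pivot(tb, r, piv);
      else { tb.T.row(r).zeros(); live[r] = false; tb.basis[r] = -1; }
    }
  }

  // Phase 2 on structural columns only.
  for (int j = n; j < n + m; ++j) allowed[j] = false;
  tb.zc.zeros();
  for (int j = 0; j < n; ++j) tb.zc(j) = -c(j);
  for (int r = 0; r < m; ++r)
    if (live[r] && tb.basis[r] >= 0 && c(tb.basis[r]) != 0.0)
      tb.zc += c(tb.basis[r]) * tb.T.row(r);
  for (int r = 0; r < m; ++r)
    if (tb.basis[r] >= 0) tb.zc(tb.basis[r]) = 0.0;

  st = iterate(tb, allowed, max_iter);
  arma::vec x(n, arma::fill::zeros);
  for (int r = 0; r < m; ++r)
    if (tb.basis[r] >= 0 && tb.basis[r] < n) x(tb.basis[r]) = tb.T(r, n + m);
  if (st != 0)
    return Rcpp::List::create(Rcpp::Named("status") = st,
                              Rcpp::Named("x") = x,
                              Rcpp::Named("objective") = NA_REAL);
  return Rcpp::List::create(Rcpp::Named("status") = 0,
                            Rcpp::Named("x") = x,
                            Rcpp::Named("objective") = arma::dot(c, x));
}
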