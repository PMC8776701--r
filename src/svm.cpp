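// C-SVC dual solver (SMO with maximal-violating-pair working-set selection)
// on a precomputed kernel, plus the inner cross-validated AUC objective used
// by the hyperparameter tuner. Small-n radiotherapy cohorts: the full kernel
// matrix always fits in memory.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static const double TAU = 1e-12;

// rank-based AUC, ties counted 1/2 (average ranks)
static double auc_rank(const arma::vec& s, const arma::ivec& y) {
  const int n = s.n_elem;
  arma::uvec ord = arma::stable_sort_index(s);
  arma::vec r(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && s(ord(j + 1)) == s(ord(i))) ++j;
    const double avg = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) r(ord(k)) = avg;
    i = j + 1;
  }
  double sum_pos = 0.0;
  int n1 = 0;
  for (int t = 0; t < n; ++t)
    if (y(t) == 1) { sum_pos += r(t); ++n1; }
  const int n0 = n - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (sum_pos - n1 * (n1 + 1.0) / 2.0) / (double(n1) * double(n0));
}

struct SvmFit {
  arma::vec alpha;
  double b;
  int iter;
};

// minimize 1/2 a'Qa - e'a  s.t.  0 <= a <= C, y'a = 0, with Q = (y y') % K
static SvmFit smo_solve(const arma::mat& K, const arma::vec& y, double C,
                        double tol, int max_iter) {
  const int n = K.n_rows;
  arma::vec a(n, arma::fill::zeros);
  arma::vec G(n);
  G.fill(-1.0);
  int iter = 0;
  while (iter < max_iter) {
    int i = -1, j = -1;
    double m = -std::numeric_limits<double>::infinity();
    double M = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      const bool up  = (y(t) > 0) ? (a(t) < C) : (a(t) > 0);
      const bool low = (y(t) > 0) ? (a(t) > 0) : (a(t) < C);
      const double v = -y(t) * G(t);
      if (up && v > m) { m = v; i = t; }
      if (low && v < M) { M = v; j = t; }
    }
    if (i < 0 || j < 0 || m - M < tol) break;
    ++iter;
    const double yi = y(i), yj = y(j);
    const double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    const double old_ai = a(i), old_aj = a(j);
    if (yi != yj) {
      double quad = Kii + Kjj + 2.0 * (yi * yj) * Kij;  // = Qii+Qjj+2Qij
      if (quad <= 0) quad = TAU;
      const double delta = (-G(i) - G(j)) / quad;
      const double diff = a(i) - a(j);
      a(i) += delta; a(j) += delta;
      if (diff > 0) { if (a(j) < 0) { a(j) = 0; a(i) = diff; } }
      else          { if (a(i) < 0) { a(i) = 0; a(j) = -diff; } }
      if (diff > 0) { if (a(i) > C) { a(i) = C; a(j) = C - diff; } }
      else          { if (a(j) > C) { a(j) = C; a(i) = C + diff; } }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      const double delta = (G(i) - G(j)) / quad;
      const double sum = a(i) + a(j);
      a(i) -= delta; a(j) += delta;
      if (sum > C) { if (a(i) > C) { a(i) = C; a(j) = sum - C; } }
      else         { if (a(j) < 0) { a(j) = 0; a(i) = sum; } }
      if (sum > C) { if (a(j) > C) { a(j) = C; a(i) = sum - C; } }
      else         { if (a(i) < 0) { a(i) = 0; a(j) = sum; } }
    }
    const double dai = a(i) - old_ai, daj = a(j) - old_aj;
    for (int t = 0; t < n; ++t)
      G(t) += y(t) * (yi * K(t, i) * dai + yj * K(t, j) * daj);
  }
  // offset from KKT conditions (libsvm's rho, sign-flipped)
  double ub = std::numeric_limits<double>::infinity();
  double lb = -std::numeric_limits<double>::infinity();
  double sum_free = 0.0;
  int n_free = 0;
  for (int t = 0; t < n; ++t) {
    const double yG = y(t) * G(t);
    if (a(t) >= C - 1e-12) {
      if (y(t) < 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (a(t) <= 1e-12) {
      if (y(t) > 0) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else { ++n_free; sum_free += yG; }
  }
  const double rho = n_free > 0 ? sum_free / n_free : (ub + lb) / 2.0;
  SvmFit fit;
  fit.alpha = a;
  fit.b = -rho;
  fit.iter = iter;
  return fit;
}

// [[Rcpp::export]]
List svm_train_cpp(const arma::mat& K, const arma::vec& y, double C,
                   double tol = 1e-3, int max_iter = 100000) {
  if (K.n_rows != K.n_cols || K.n_rows != y.n_elem)
    stop("kernel/label dimension mismatch");
  SvmFit fit = smo_solve(K, y, C, tol, max_iter);
  return List::create(_["alpha"] = fit.alpha, _["b"] = fit.b,
                      _["iter"] = fit.iter);
}

// mean AUC of an RBF-SVM over precomputed stratified folds.
// D2: full n x n squared-distance matrix; fold: 1-based fold ids.
// [[Rcpp::export]]
double cv_auc_cpp(const arma::mat& D2, const arma::ivec& y01,
                  const arma::ivec& fold, double C, double gamma,
                  double tol = 1e-3, int max_iter = 100000) {
  const int n = D2.n_rows;
  const int k = fold.max();
  arma::vec y = arma::conv_to<arma::vec>::from(y01) * 2.0 - 1.0;
  double total = 0.0;
  int used = 0;
  for (int f = 1; f <= k; ++f) {
    arma::uvec tr = arma::find(fold != f);
    arma::uvec te = arma::find(fold == f);
    if (te.n_elem == 0) continue;
    arma::ivec yte = y01.elem(te);
    if (arma::all(yte == yte(0))) continue;  // AUC undefined on one class
    arma::mat Ktr = arma::exp(-gamma * D2.submat(tr, tr));
    SvmFit fit = smo_solve(Ktr, y.elem(tr), C, tol, max_iter);
    arma::vec coef = fit.alpha % y.elem(tr);
    arma::mat Kte = arma::exp(-gamma * D2.submat(te, tr));
    arma::vec scores = Kte * coef + fit.b;
    total += auc_rank(scores, yte);
    ++used;
  }
  if (used == 0) return NA_REAL;
  return total / used;
}
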