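// Orthogonal matching pursuit hot path. The greedy selection/least-squares
// loop runs once per image patch during reconstruction, so it is compiled;
// all validation and user-facing semantics live in the R wrappers.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct OmpResult {
  arma::uvec support;     // 0-based, in order of selection
  arma::vec coef;
  double residual_norm;
  arma::vec trace;        // residual norms, starting at ||y||
  bool rank_warning;
};

// Core greedy pursuit. D must have unit-norm columns. tol_abs is the
// absolute residual-norm threshold (the caller resolves relative tols).
OmpResult omp_core(const arma::vec& y, const arma::mat& D, int k_max,
                   double tol_abs) {
  OmpResult out;
  out.rank_warning = false;
  const arma::uword q = D.n_rows, m = D.n_cols;
  double ny = arma::norm(y);
  std::vector<double> trace{ny};
  std::vector<arma::uword> support;
  arma::vec r = y, coef;
  double nr = ny;
  std::vector<bool> used(m, false);

  while ((int)support.size() < k_max && nr > tol_abs) {
    arma::vec corr = arma::abs(D.t() * r);
    // first (lowest-index) maximum among unused atoms
    arma::uword best = 0;
    double best_v = -1.0;
    for (arma::uword j = 0; j < m; ++j) {
      if (!used[j] && corr[j] > best_v) { best_v = corr[j]; best = j; }
    }
    if (best_v <= 1e-14 * std::max(ny, 1.0)) break;  // r orthogonal to D

    std::vector<arma::uword> cand = support;
    cand.push_back(best);
    arma::uvec idx(cand.size());
    for (size_t i = 0; i < cand.size(); ++i) idx[i] = cand[i];
    arma::mat G = D.cols(idx);
    arma::mat Q, R;
    if (!arma::qr_econ(Q, R, G)) { out.rank_warning = true; break; }
    arma::vec rd = arma::abs(R.diag());
    if (rd.min() < 1e-12 * rd.max()) { out.rank_warning = true; break; }
    arma::vec c = arma::solve(arma::trimatu(R), Q.t() * y);
    support = cand;
    used[best] = true;
    coef = c;
    r = y - G * c;
    nr = arma::norm(r);
    trace.push_back(nr);
    (void)q;
  }
  out.support = arma::uvec(support.size());
  for (size_t i = 0; i < support.size(); ++i) out.support[i] = support[i];
  out.coef = coef;
  out.residual_norm = nr;
  out.trace = arma::vec(trace);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".omp_cpp")]]
List omp_cpp(const arma::vec& y, const arma::mat& D, int k_max,
             double tol_abs) {
  OmpResult res = omp_core(y, D, k_max, tol_abs);
  if (res.rank_warning)
    Rf_warning("support submatrix numerically rank-deficient; stopping pursuit");
  IntegerVector sup(res.support.n_elem);
  for (arma::uword i = 0; i < res.support.n_elem; ++i)
    sup[i] = (int)res.support[i] + 1;  // 1-based for R
  return List::create(
      _["support"] = sup,
      _["coefficients"] = NumericVector(res.coef.begin(), res.coef.end()),
      _["residual_norm"] = res.residual_norm,
      _["residual_trace"] = NumericVector(res.trace.begin(), res.trace.end()));
}

// Code every query patch (column of Y) against D_l and synthesize the
// corresponding high-resolution residual patch from D_h with the same
// coefficients, undoing the query and atom normalizations. Columns of Y
// with (near-)zero norm yield zero residual patches.
// [[Rcpp::export(name = ".omp_synthesize_cpp")]]
List omp_synthesize_cpp(const arma::mat& Y, const arma::mat& Dl,
                        const arma::mat& Dh, const arma::vec& atom_norms,
                        int k_max, double tol, bool relative, bool center) {
  arma::mat out(Dh.n_rows, Y.n_cols, arma::fill::zeros);
  IntegerVector n_atoms(Y.n_cols);
  bool any_rank_warning = false;
  for (arma::uword i = 0; i < Y.n_cols; ++i) {
    arma::vec y = Y.col(i);
    if (center) y -= arma::mean(y);
    double ny = arma::norm(y);
    if (ny <= 1e-12 || k_max == 0) continue;
    double tol_abs = relative ? tol : tol / ny;  // thresholds on y/ny
    OmpResult code = omp_core(y / ny, Dl, k_max, tol_abs);
    if (code.rank_warning) any_rank_warning = true;
    n_atoms[i] = (int)code.support.n_elem;
    if (code.support.n_elem == 0) continue;
    arma::vec w = code.coef * ny;
    for (arma::uword j = 0; j < w.n_elem; ++j)
      w[j] /= atom_norms[code.support[j]];
    out.col(i) = Dh.cols(code.support) * w;
  }
  if (any_rank_warning)
    Rf_warning("rank-deficient support encountered in at least one patch");
  return List::create(_["residuals"] = out, _["n_atoms"] = n_atoms);
}
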