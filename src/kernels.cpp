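#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Binomial(2, p) via single-uniform inversion against the CDF cut points
// (1-p)^2 and 1-p^2; uses R's RNG stream so set.seed() governs output.
static inline int rbinom2(double p) {
  double u = unif_rand();
  double q0 = (1.0 - p) * (1.0 - p);
  double q1 = 1.0 - p * p;
  return (u > q0) + (u > q1);
}

// n x m matrix of Binomial(2, p[t]) allele counts, column t has parameter p[t].
// [[Rcpp::export]]
IntegerMatrix cpp_binom2_matrix(int n, NumericVector p) {
  int m = p.size();
  IntegerMatrix X(n, m);
  GetRNGstate();
  for (int t = 0; t < m; ++t) {
    double pt = p[t];
    for (int j = 0; j < n; ++j) X(j, t) = rbinom2(pt);
  }
  PutRNGstate();
  return X;
}

// Accumulated polygenic score sum_t beta[t] * X_t without storing the
// genotype matrix; X_t ~ Binomial(2, p[t]).
// [[Rcpp::export]]
NumericVector cpp_bg_score(int n, NumericVector p, NumericVector beta) {
  int m = p.size();
  if (beta.size() != m) stop("length(beta) != length(p)");
  NumericVector g(n);
  GetRNGstate();
  for (int t = 0; t < m; ++t) {
    double pt = p[t], bt = beta[t];
    for (int j = 0; j < n; ++j) g[j] += bt * rbinom2(pt);
  }
  PutRNGstate();
  return g;
}

// Fill the SQ/CP buffer from a residual matrix: SQ columns 1..r then CP
// columns in lexicographic pair order.
static void fill_sqcp(const arma::mat& E, arma::mat& Z, bool include_cp) {
  int r = E.n_cols;
  for (int k = 0; k < r; ++k) Z.col(k) = arma::square(E.col(k));
  if (include_cp) {
    int c = r;
    for (int k = 0; k < r - 1; ++k)
      for (int k2 = k + 1; k2 < r; ++k2) Z.col(c++) = E.col(k) % E.col(k2);
  }
}

// Centered cross products of the SQ/CP matrix built from residuals E:
// C = Zc' Zc, v = Zc' xc (xc assumed mean zero), without forming the n x n
// kernel. Centering is applied algebraically via the column means.
// [[Rcpp::export]]
List cpp_sqcp_cross(const arma::mat& E, const arma::vec& xc, bool include_cp) {
  int n = E.n_rows, r = E.n_cols;
  int d = include_cp ? r + r * (r - 1) / 2 : r;
  arma::mat Z(n, d);
  fill_sqcp(E, Z, include_cp);
  arma::rowvec mu = arma::mean(Z, 0);
  arma::mat C = Z.t() * Z;
  C -= (double)n * (mu.t() * mu);
  arma::vec v = Z.t() * xc;           // xc has mean zero => no mean correction
  return List::create(_["C"] = C, _["v"] = v, _["n"] = n, _["d"] = d);
}

// Genome-scan core. E0: traits residualized on covariates (columns mean
// zero). X: n x m dosage matrix. Per SNP: mean-impute missing, center,
// remove the SNP's additive effect from each trait by a rank-one update
// (Frisch-Waugh-Lovell), optionally studentize by the leverage of the
// intercept+SNP design, build SQ/CP, and return the small-dimension
// ingredients of the kernel test: eigenvalues of the centered Z kernel,
// w = U'v rotations, per-column v and diag(C) for marginal tests, x'x.
// h0: baseline leverage of the covariate design (1/n with intercept only);
// the per-SNP leverage adds xc^2/xx on top.
// [[Rcpp::export]]
List cpp_lit_scan(const arma::mat& E0, const arma::mat& X, bool include_cp,
                  bool studentize, double rank_tol, const arma::vec& h0) {
  int n = E0.n_rows, r = E0.n_cols, m = X.n_cols;
  if ((int)h0.n_elem != n) stop("h0 length mismatch");
  int d = include_cp ? r + r * (r - 1) / 2 : r;
  arma::mat lam(m, d, arma::fill::zeros), W(m, d, arma::fill::zeros);
  arma::mat Vraw(m, d, arma::fill::zeros), Cdiag(m, d, arma::fill::zeros);
  arma::vec xxs(m, arma::fill::zeros);
  arma::ivec d1s(m, arma::fill::zeros);
  arma::mat E(n, r), Z(n, d);
  arma::vec xc(n), f(n);
  for (int s = 0; s < m; ++s) {
    // mean-impute missing dosages
    double sum = 0; int nobs = 0;
    for (int j = 0; j < n; ++j) {
      double x = X(j, s);
      if (arma::is_finite(x)) { sum += x; ++nobs; }
    }
    if (nobs == 0) { d1s[s] = -1; continue; }
    double mu = sum / nobs;
    for (int j = 0; j < n; ++j) {
      double x = X(j, s);
      xc[j] = arma::is_finite(x) ? x - mu : 0.0;
    }
    xc -= arma::mean(xc);
    double xx = arma::dot(xc, xc);
    if (xx < 1e-12 * n) { d1s[s] = -1; continue; }  // monomorphic / degenerate
    arma::rowvec alpha = (xc.t() * E0) / xx;
    E = E0 - xc * alpha;
    if (studentize) {
      for (int j = 0; j < n; ++j) {
        double h = h0[j] + xc[j] * xc[j] / xx;
        f[j] = (h < 1.0 - 1e-10) ? 1.0 / std::sqrt(1.0 - h) : 1.0;
      }
      E.each_col() %= f;
      E.each_row() -= arma::mean(E, 0);
    }
    fill_sqcp(E, Z, include_cp);
    arma::rowvec zm = arma::mean(Z, 0);
    arma::mat C = Z.t() * Z;
    C -= (double)n * (zm.t() * zm);
    arma::vec v = Z.t() * xc;
    v -= zm.t() * arma::accu(xc);   // xc mean ~0; exact correction anyway
    arma::vec ev; arma::mat U;
    arma::eig_sym(ev, U, C);        // ascending
    arma::vec w = U.t() * v;
    double evmax = ev.max();
    int d1 = 0;
    for (int i = d - 1; i >= 0; --i) {
      if (ev[i] > rank_tol * evmax && ev[i] > 0) {
        lam(s, d1) = ev[i];
        W(s, d1) = w[i];
        ++d1;
      }
    }
    d1s[s] = d1;
    xxs[s] = xx;
    for (int i = 0; i < d; ++i) { Vraw(s, i) = v[i]; Cdiag(s, i) = C(i, i); }
  }
  return List::create(_["lambda"] = lam, _["w"] = W, _["v"] = Vraw,
                      _["cdiag"] = Cdiag, _["xx"] = xxs, _["d1"] = d1s,
                      _["n"] = n, _["d"] = d);
}

// n x r noise matrix from the named error family, each column standardized
// to mean 0, sd 1 (sample convention) and scaled by scale[k], in one pass.
// dist: 0 = normal, 1 = centered-scaled chi-squared(5), 2 = t(3).
// [[Rcpp::export]]
NumericMatrix cpp_noise_matrix(int n, int r, int dist, NumericVector scale) {
  if (scale.size() != r) stop("length(scale) != r");
  NumericMatrix E(n, r);
  GetRNGstate();
  for (int k = 0; k < r; ++k) {
    double* col = &E(0, k);
    switch (dist) {
    case 0: for (int j = 0; j < n; ++j) col[j] = norm_rand(); break;
    case 1: for (int j = 0; j < n; ++j) col[j] = (R::rchisq(5.0) - 5.0) / std::sqrt(10.0); break;
    case 2: for (int j = 0; j < n; ++j) col[j] = R::rt(3.0) / std::sqrt(3.0); break;
    default: stop("unknown error distribution code");
    }
    double s = 0, ss = 0;
    for (int j = 0; j < n; ++j) { s += col[j]; ss += col[j] * col[j]; }
    double mu = s / n;
    double sd = std::sqrt((ss - n * mu * mu) / (n - 1));
    if (sd <= 0) stop("constant noise column");
    double f = scale[k] / sd;
    for (int j = 0; j < n; ++j) col[j] = (col[j] - mu) * f;
  }
  PutRNGstate();
  return E;
}
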