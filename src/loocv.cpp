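// Leave-one-out cross-validation engine for the sparse PLS grid search.
// Mirrors the R reference implementation (fit_spls / spls_engine) exactly:
// per fold the predictor scaling, the within-participant split and the
// sparse component path are refit on the N-1 training rows; fits for
// K = 1..maxK share one component path per keepX value.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// soft-threshold so exactly keepX entries survive; ties at the boundary keep
// the lower column index (deterministic, matches the R implementation)
static vec soft_threshold_keep(const vec& w, const unsigned int keepX) {
  const unsigned int p = w.n_elem;
  if (keepX >= p) return w;
  uvec ord = stable_sort_index(-abs(w));
  const double thr = std::abs(w(ord(keepX)));
  vec out(p, fill::zeros);
  bool any_nonzero = false;
  for (unsigned int j = 0; j < keepX; ++j) {
    const unsigned int idx = ord(j);
    const double v = std::abs(w(idx)) - thr;
    if (v > 0) { out(idx) = (w(idx) > 0 ? v : -v); any_nonzero = true; }
  }
  if (!any_nonzero)  // complete tie: fall back to hard selection
    for (unsigned int j = 0; j < keepX; ++j) out(ord(j)) = w(ord(j));
  return out;
}

// cumulative response-scale coefficient path for K = 1..maxK components
static mat spls_beta_path(mat Xc, vec yc, const unsigned int maxK,
                          const unsigned int keepX) {
  const unsigned int p = Xc.n_cols;
  mat W(p, maxK, fill::zeros), P(p, maxK, fill::zeros), beta(p, maxK, fill::zeros);
  vec d(maxK, fill::zeros);
  const double tol = 1e-12;
  const double y0 = std::max(1.0, norm(yc));
  unsigned int k_done = 0;
  for (unsigned int k = 0; k < maxK; ++k) {
    vec w = Xc.t() * yc;
    if (norm(w) < tol * y0) break;
    w = soft_threshold_keep(w, keepX);
    const double nw = norm(w);
    if (nw < tol) break;
    w /= nw;
    vec t = Xc * w;
    const double tk2 = dot(t, t);
    if (tk2 < tol) break;
    const double dk = dot(t, yc) / tk2;
    vec pk = Xc.t() * t / tk2;
    Xc -= t * pk.t();
    yc -= dk * t;
    W.col(k) = w; P.col(k) = pk; d(k) = dk;
    k_done = k + 1;
    mat Wk = W.cols(0, k), Pk = P.cols(0, k);
    beta.col(k) = Wk * solve(Pk.t() * Wk, d.subvec(0, k));
  }
  // past saturation the fit no longer changes: carry the last beta forward
  for (unsigned int k = k_done; k < maxK; ++k)
    if (k_done > 0) beta.col(k) = beta.col(k_done - 1);
  return beta;
}

// [[Rcpp::export(name = ".loocv_sqerr_cpp")]]
arma::cube loocv_sqerr_cpp(const arma::mat& X, const arma::vec& y,
                           const arma::ivec& subj, const int maxK,
                           const arma::ivec& keepX_values,
                           const bool multilevel) {
  const unsigned int N = X.n_rows, p = X.n_cols, nkx = keepX_values.n_elem;
  const int n_subj = multilevel ? (subj.max() + 1) : 0;
  cube err(N, (unsigned int)maxK, nkx, fill::value(datum::nan));

  for (unsigned int i = 0; i < N; ++i) {
    // training scaling (mean, sd with n-2 ... n-1 denominator as stats::sd)
    mat Xt(N - 1, p);
    vec yt(N - 1);
    ivec st(N - 1);
    unsigned int r = 0;
    for (unsigned int q = 0; q < N; ++q) {
      if (q == i) continue;
      Xt.row(r) = X.row(q);
      yt(r) = y(q);
      if (multilevel) st(r) = subj(q);
      ++r;
    }
    rowvec mu = mean(Xt, 0);
    rowvec sd = stddev(Xt, 0, 0);  // normalises by n-1
    sd.elem(find(sd == 0)).ones();
    mat Xs = (Xt.each_row() - mu).each_row() / sd;
    rowvec xh = (X.row(i) - mu) / sd;

    mat Xw;
    vec yw;
    rowvec xh_w;
    double base;
    if (multilevel) {
      mat smean(n_subj, p, fill::zeros);
      vec symean(n_subj, fill::zeros), cnt(n_subj, fill::zeros);
      for (unsigned int q = 0; q < N - 1; ++q) {
        smean.row(st(q)) += Xs.row(q);
        symean(st(q)) += yt(q);
        cnt(st(q)) += 1.0;
      }
      for (int s = 0; s < n_subj; ++s)
        if (cnt(s) > 0) { smean.row(s) /= cnt(s); symean(s) /= cnt(s); }
      Xw.set_size(N - 1, p);
      yw.set_size(N - 1);
      for (unsigned int q = 0; q < N - 1; ++q) {
        Xw.row(q) = Xs.row(q) - smean.row(st(q));
        yw(q) = yt(q) - symean(st(q));
      }
      xh_w = xh - smean.row(subj(i));
      base = symean(subj(i));
    } else {
      rowvec cm = mean(Xs, 0);
      Xw = Xs.each_row() - cm;
      base = mean(yt);
      yw = yt - base;
      xh_w = xh - cm;
    }

    for (unsigned int j = 0; j < nkx; ++j) {
      mat beta = spls_beta_path(Xw, yw, maxK, (unsigned int)keepX_values(j));
      for (int k = 0; k < maxK; ++k) {
        const double pred = base + dot(xh_w, beta.col(k));
        const double e = y(i) - pred;
        err(i, k, j) = e * e;
      }
    }
  }
  return err;
}
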