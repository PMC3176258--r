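// Hot path of the backward-elimination wrapper: linear soft-margin SVM
// (dual coordinate descent, L1 hinge loss, bias as a regularized augmented
// feature), Platt sigmoid calibration, and leave-one-(sample|group)-out
// cross-validated decision values. The per-step routine evaluates, for every
// remaining analyte, the LOOCV KLD obtained after removing that analyte,
// with warm starts from the full-panel dual solution of the same fold.
//
// Determinism: cyclic coordinate order, no RNG anywhere.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Train on columns (samples) of Z (features x samples) listed in idx.
// Feature row `skip` is excluded by keeping w[skip] pinned at zero; pass
// skip = -1 to use the full panel. alpha is the warm-start dual vector
// (indexed like idx) and is updated in place. Returns (w, b).
static void dcd_train(const mat& Z, const uvec& idx, const vec& y, double C,
                      int skip, double tol, int max_pass, vec& alpha,
                      vec& w, double& b, const vec& qii_full) {
  const int m = Z.n_rows;
  const int n = idx.n_elem;
  w.zeros(m);
  b = 0.0;
  // reconstruct primal from warm-start duals
  for (int i = 0; i < n; ++i) {
    if (alpha[i] != 0.0) {
      double d = alpha[i] * y[idx[i]];
      w += d * Z.col(idx[i]);
      b += d;
    }
  }
  if (skip >= 0) w[skip] = 0.0;

  vec qii(n);
  for (int i = 0; i < n; ++i) {
    double q = qii_full[idx[i]];
    if (skip >= 0) { double z = Z(skip, idx[i]); q -= z * z; }
    qii[i] = q;
  }

  for (int pass = 0; pass < max_pass; ++pass) {
    double max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      const uword s = idx[i];
      double yi = y[s];
      double G = yi * (dot(w, Z.col(s)) + b) - 1.0;
      double PG = G;
      if (alpha[i] <= 0.0 && G > 0.0) PG = 0.0;
      else if (alpha[i] >= C && G < 0.0) PG = 0.0;
      double apg = std::fabs(PG);
      if (apg > max_pg) max_pg = apg;
      if (PG != 0.0 && qii[i] > 0.0) {
        double old = alpha[i];
        double a = std::min(std::max(old - G / qii[i], 0.0), C);
        if (a != old) {
          alpha[i] = a;
          double d = (a - old) * yi;
          w += d * Z.col(s);
          b += d;
          if (skip >= 0) w[skip] = 0.0;
        }
      }
    }
    if (max_pg < tol) break;
  }
}

// Platt (1999) sigmoid fit with the Newton scheme of Lin, Lin & Weng (2007):
// p(y=+1 | d) = 1 / (1 + exp(A*d + B)).
static void platt_fit(const vec& dec, const vec& y, double& A, double& B) {
  const int n = dec.n_elem;
  double prior1 = 0.0, prior0 = 0.0;
  for (int i = 0; i < n; ++i) (y[i] > 0 ? prior1 : prior0)++;
  const double hi = (prior1 + 1.0) / (prior1 + 2.0);
  const double lo = 1.0 / (prior0 + 2.0);
  vec t(n);
  for (int i = 0; i < n; ++i) t[i] = y[i] > 0 ? hi : lo;

  A = 0.0;
  B = std::log((prior0 + 1.0) / (prior1 + 1.0));
  double fval = 0.0;
  for (int i = 0; i < n; ++i) {
    double fApB = dec[i] * A + B;
    fval += fApB >= 0 ? t[i] * fApB + std::log1p(std::exp(-fApB))
                      : (t[i] - 1.0) * fApB + std::log1p(std::exp(fApB));
  }
  const double minstep = 1e-10, sigma = 1e-12, eps = 1e-5;
  for (int it = 0; it < 100; ++it) {
    double h11 = sigma, h22 = sigma, h21 = 0.0, g1 = 0.0, g2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double fApB = dec[i] * A + B, p, q;
      if (fApB >= 0) {
        double e = std::exp(-fApB);
        p = e / (1.0 + e); q = 1.0 / (1.0 + e);
      } else {
        double e = std::exp(fApB);
        p = 1.0 / (1.0 + e); q = e / (1.0 + e);
      }
      double d2 = p * q;
      h11 += dec[i] * dec[i] * d2;
      h22 += d2;
      h21 += dec[i] * d2;
      double d1 = t[i] - p;
      g1 += dec[i] * d1;
      g2 += d1;
    }
    if (std::fabs(g1) < eps && std::fabs(g2) < eps) break;
    double det = h11 * h22 - h21 * h21;
    double dA = -(h22 * g1 - h21 * g2) / det;
    double dB = -(-h21 * g1 + h11 * g2) / det;
    double gd = g1 * dA + g2 * dB;
    double stepsize = 1.0;
    while (stepsize >= minstep) {
      double nA = A + stepsize * dA, nB = B + stepsize * dB, nf = 0.0;
      for (int i = 0; i < n; ++i) {
        double fApB = dec[i] * nA + nB;
        nf += fApB >= 0 ? t[i] * fApB + std::log1p(std::exp(-fApB))
                        : (t[i] - 1.0) * fApB + std::log1p(std::exp(fApB));
      }
      if (nf < fval + 1e-4 * stepsize * gd) { A = nA; B = nB; fval = nf; break; }
      stepsize /= 2.0;
    }
    if (stepsize < minstep) break;
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_platt(const arma::vec& dec, const arma::vec& y) {
  double A, B;
  platt_fit(dec, y, A, B);
  return Rcpp::NumericVector::create(A, B);
}

// [[Rcpp::export]]
Rcpp::List cpp_svm_train(const arma::mat& Zt, const arma::vec& y, double C,
                         double tol, int max_pass) {
  // Zt: features x samples, already scaled by the caller.
  const int n = Zt.n_cols;
  uvec idx = regspace<uvec>(0, n - 1);
  vec qii(n);
  for (int i = 0; i < n; ++i) qii[i] = dot(Zt.col(i), Zt.col(i)) + 1.0;
  vec alpha(n, fill::zeros), w;
  double b;
  dcd_train(Zt, idx, y, C, -1, tol, max_pass, alpha, w, b, qii);
  vec dec = Zt.t() * w + b;
  return Rcpp::List::create(Rcpp::Named("w") = w, Rcpp::Named("b") = b,
                            Rcpp::Named("alpha") = alpha,
                            Rcpp::Named("decision") = dec);
}

// Per-fold z-scaling from training columns: sd uses the n-1 denominator;
// constant features get scale 1 so they carry zero information after
// centering.
static void fold_scale(const mat& Xt, const uvec& tr, vec& center, vec& scale) {
  const int m = Xt.n_rows;
  center.zeros(m);
  scale.ones(m);
  const int n = tr.n_elem;
  for (uword i = 0; i < tr.n_elem; ++i) center += Xt.col(tr[i]);
  center /= n;
  vec ss(m, fill::zeros);
  for (uword i = 0; i < tr.n_elem; ++i) {
    vec d = Xt.col(tr[i]) - center;
    ss += d % d;
  }
  if (n > 1) {
    for (int g = 0; g < m; ++g) {
      double s = std::sqrt(ss[g] / (n - 1));
      scale[g] = s > 0 ? s : 1.0;
    }
  }
}

// [[Rcpp::export]]
arma::vec cpp_loocv_decisions(const arma::mat& Xt, const arma::vec& y,
                              const arma::ivec& fold, double C, double tol,
                              int max_pass) {
  // Xt: features x samples (raw); fold: positive integer fold id per sample.
  const int n = Xt.n_cols, m = Xt.n_rows;
  const int nf = fold.max();
  vec dec(n, fill::zeros);
  for (int f = 1; f <= nf; ++f) {
    uvec te = find(fold == f), tr = find(fold != f);
    if (te.n_elem == 0) continue;
    vec center, scale;
    fold_scale(Xt, tr, center, scale);
    mat Z(m, n);
    for (int s = 0; s < n; ++s) Z.col(s) = (Xt.col(s) - center) / scale;
    vec qii(n);
    for (int s = 0; s < n; ++s) qii[s] = dot(Z.col(s), Z.col(s)) + 1.0;
    vec alpha(tr.n_elem, fill::zeros), w;
    double b;
    dcd_train(Z, tr, y, C, -1, tol, max_pass, alpha, w, b, qii);
    for (uword i = 0; i < te.n_elem; ++i)
      dec[te[i]] = dot(w, Z.col(te[i])) + b;
  }
  return dec;
}

static double kld_from_dec(const vec& dec, const vec& y, double clip) {
  double A, B;
  platt_fit(dec, y, A, B);
  const int n = dec.n_elem;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    double fApB = dec[i] * A + B;
    double p = fApB >= 0 ? std::exp(-fApB) / (1.0 + std::exp(-fApB))
                         : 1.0 / (1.0 + std::exp(fApB));
    double pt = y[i] > 0 ? p : 1.0 - p;
    pt = std::min(std::max(pt, clip), 1.0 - clip);
    acc -= std::log(pt);
  }
  return acc / n;
}

// [[Rcpp::export]]
Rcpp::List cpp_step_klds(const arma::mat& Xt, const arma::vec& y,
                         const arma::ivec& fold, double C, double clip,
                         double tol, int max_pass) {
  // Xt: current candidate panel (analytes x samples, raw). For each analyte
  // j, LOOCV over folds with j removed, one sigmoid calibration over the
  // collected out-of-fold decisions, then KLD = -mean log p(true class).
  // Also returns the full-panel KLD (no analyte removed).
  const int n = Xt.n_cols, m = Xt.n_rows;
  const int nf = fold.max();
  mat D(m, n, fill::zeros);    // decision of sample s when analyte j removed
  vec dec_full(n, fill::zeros);

  for (int f = 1; f <= nf; ++f) {
    uvec te = find(fold == f), tr = find(fold != f);
    if (te.n_elem == 0) continue;
    vec center, scale;
    fold_scale(Xt, tr, center, scale);
    mat Z(m, n);
    for (int s = 0; s < n; ++s) Z.col(s) = (Xt.col(s) - center) / scale;
    vec qii(n);
    for (int s = 0; s < n; ++s) qii[s] = dot(Z.col(s), Z.col(s)) + 1.0;

    vec alpha_full(tr.n_elem, fill::zeros), w;
    double b;
    dcd_train(Z, tr, y, C, -1, tol, max_pass, alpha_full, w, b, qii);
    for (uword i = 0; i < te.n_elem; ++i)
      dec_full[te[i]] = dot(w, Z.col(te[i])) + b;

    for (int j = 0; j < m; ++j) {
      vec alpha = alpha_full;  // warm start from the full-panel duals
      vec wj;
      double bj;
      dcd_train(Z, tr, y, C, j, tol, max_pass, alpha, wj, bj, qii);
      for (uword i = 0; i < te.n_elem; ++i) {
        const uword s = te[i];
        D(j, s) = dot(wj, Z.col(s)) + bj - wj[j] * Z(j, s);
      }
    }
    Rcpp::checkUserInterrupt();
  }

  vec klds(m);
  for (int j = 0; j < m; ++j) klds[j] = kld_from_dec(D.row(j).t(), y, clip);
  double kld_full = kld_from_dec(dec_full, y, clip);
  return Rcpp::List::create(Rcpp::Named("klds") = klds,
                            Rcpp::Named("kld_full") = kld_full,
                            Rcpp::Named("D") = D,
                            Rcpp::Named("dec_full") = dec_full);
}
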