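// Non-negative Tucker decomposition: multiplicative updates on the
// Frobenius loss. The R wrapper handles initialisation, multi-start and
// factor normalisation; this is only the hot iteration loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// mode products for a third-order tensor
static cube ttm1(const cube& x, const mat& m) {
  cube out(m.n_rows, x.n_cols, x.n_slices);
  for (uword k = 0; k < x.n_slices; ++k) out.slice(k) = m * x.slice(k);
  return out;
}
static cube ttm2(const cube& x, const mat& m) {
  cube out(x.n_rows, m.n_rows, x.n_slices);
  for (uword k = 0; k < x.n_slices; ++k) out.slice(k) = x.slice(k) * m.t();
  return out;
}
static cube ttm3(const cube& x, const mat& m) {
  cube out(x.n_rows, x.n_cols, m.n_rows);
  out.zeros();
  for (uword j = 0; j < m.n_rows; ++j)
    for (uword k = 0; k < x.n_slices; ++k)
      out.slice(j) += m(j, k) * x.slice(k);
  return out;
}

// mode-n unfoldings (columns ordered with the lower remaining mode fastest,
// matching kron(C,B) / kron(C,A) / kron(B,A) respectively)
static mat unfold1(const cube& x) {
  return mat(const_cast<double*>(x.memptr()), x.n_rows,
             x.n_cols * x.n_slices, false);
}
static mat unfold2(const cube& x) {
  mat out(x.n_cols, x.n_rows * x.n_slices);
  for (uword k = 0; k < x.n_slices; ++k)
    out.cols(k * x.n_rows, (k + 1) * x.n_rows - 1) = x.slice(k).t();
  return out;
}
static mat unfold3(const cube& x) {
  mat out(x.n_slices, x.n_rows * x.n_cols);
  for (uword k = 0; k < x.n_slices; ++k)
    out.row(k) = vectorise(x.slice(k)).t();
  return out;
}

// [[Rcpp::export(name = ".ntd_mu")]]
Rcpp::List ntd_mu(const arma::cube& x, arma::mat a, arma::mat b, arma::mat c,
                  arma::cube g, int max_iter, double tol) {
  const double eps = 1e-12;
  const double xnorm2 = accu(square(x));
  double prev = datum::inf, loss = datum::nan;

  for (int it = 1; it <= max_iter; ++it) {
    mat btb = b.t() * b, ctc = c.t() * c;
    mat g1 = unfold1(g);
    cube w = ttm3(ttm2(x, b.t()), c.t());
    mat num = unfold1(w) * g1.t();
    mat den = a * (g1 * kron(ctc, btb) * g1.t());
    a %= num / (den + eps);

    mat ata = a.t() * a;
    mat g2 = unfold2(g);
    w = ttm3(ttm1(x, a.t()), c.t());
    num = unfold2(w) * g2.t();
    den = b * (g2 * kron(ctc, ata) * g2.t());
    b %= num / (den + eps);

    btb = b.t() * b;
    mat g3 = unfold3(g);
    w = ttm2(ttm1(x, a.t()), b.t());
    num = unfold3(w) * g3.t();
    den = c * (g3 * kron(btb, ata) * g3.t());
    c %= num / (den + eps);

    ctc = c.t() * c;
    cube xt = ttm3(ttm2(ttm1(x, a.t()), b.t()), c.t());
    cube gt = ttm3(ttm2(ttm1(g, ata), btb), ctc);
    g %= xt / (gt + eps);

    if (it % 25 == 0 || it == max_iter) {
      gt = ttm3(ttm2(ttm1(g, ata), btb), ctc);
      double loss2 = xnorm2 - 2.0 * accu(g % xt) + accu(g % gt);
      loss = std::sqrt(std::max(loss2, 0.0));
      if (std::isfinite(prev) &&
          std::abs(prev - loss) < tol * std::max(std::sqrt(xnorm2), 1.0))
        break;
      prev = loss;
    }
  }
  return Rcpp::List::create(Rcpp::Named("a") = a, Rcpp::Named("b") = b,
                            Rcpp::Named("c") = c, Rcpp::Named("g") = g,
                            Rcpp::Named("loss") = loss);
}
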