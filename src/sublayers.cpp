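// Compiled hot path of the encoder: layer-normalized, shortest-path
// biased multi-head attention and the GELU MLP, forward and backward.
// These mirror the reference R implementations (attn_sub_fwd/bwd,
// mlp_sub_fwd/bwd) exactly; equivalence is asserted in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// return an arma::vec as a plain R numeric vector (not an n x 1 matrix)
static NumericVector as_rvec(const arma::vec& v) {
  return NumericVector(v.begin(), v.end());
}

static const double EPS_LN = 1e-5;

struct LnCache {
  arma::mat xhat;
  arma::vec invstd;
  arma::mat y;
};

static LnCache layernorm_fwd(const arma::mat& x, const arma::vec& g,
                             const arma::vec& b) {
  LnCache c;
  arma::vec mu = arma::mean(x, 1);
  arma::mat xc = x.each_col() - mu;
  c.invstd = 1.0 / arma::sqrt(arma::mean(arma::square(xc), 1) + EPS_LN);
  c.xhat = xc.each_col() % c.invstd;
  c.y = c.xhat.each_row() % g.t();
  c.y.each_row() += b.t();
  return c;
}

static arma::mat layernorm_bwd(const arma::mat& dy, const LnCache& c,
                               const arma::vec& g, arma::vec& dg,
                               arma::vec& db) {
  dg = arma::sum(dy % c.xhat, 0).t();
  db = arma::sum(dy, 0).t();
  arma::mat dxhat = dy.each_row() % g.t();
  arma::vec m1 = arma::mean(dxhat, 1);
  arma::vec m2 = arma::mean(dxhat % c.xhat, 1);
  arma::mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= c.xhat.each_col() % m2;
  dx.each_col() %= c.invstd;
  return dx;
}

static inline double norm_cdf(double x) { return 0.5 * std::erfc(-x * M_SQRT1_2); }
static inline double norm_pdf(double x) {
  return 0.3989422804014327 * std::exp(-0.5 * x * x);
}

static arma::mat gelu_fwd(const arma::mat& x) {
  arma::mat y = x;
  y.transform([](double v) { return v * norm_cdf(v); });
  return y;
}

static arma::mat gelu_bwd(const arma::mat& x, const arma::mat& dy) {
  arma::mat g = x;
  g.transform([](double v) { return norm_cdf(v) + v * norm_pdf(v); });
  return dy % g;
}

// row-softmax with -inf support
static void softmax_rows_ip(arma::mat& a) {
  for (arma::uword i = 0; i < a.n_rows; ++i) {
    double m = a.row(i).max();
    arma::rowvec e = arma::exp(a.row(i) - m);
    a.row(i) = e / arma::accu(e);
  }
}

// [[Rcpp::export(name = ".cpp_attn_fwd")]]
List cpp_attn_fwd(const arma::mat& x, const arma::mat& Wq,
                  const arma::mat& Wk, const arma::mat& Wv,
                  const arma::mat& Wo, const arma::vec& bo,
                  const arma::mat& bias, const arma::imat& dist_idx,
                  const LogicalVector& mask, const arma::vec& ln_g,
                  const arma::vec& ln_b, int n_heads, int D) {
  LnCache ln = layernorm_fwd(x, ln_g, ln_b);
  const arma::mat& X = ln.y;
  arma::uword n = X.n_rows;
  arma::mat Q = X * Wq, K = X * Wk, V = X * Wv;
  arma::mat Oc(n, X.n_cols, arma::fill::zeros);
  arma::cube P(n, n, n_heads);
  bool masked = is_false(all(mask));
  double s = std::sqrt((double) D);
  for (int h = 0; h < n_heads; ++h) {
    arma::uword c0 = h * D, c1 = (h + 1) * D - 1;
    arma::mat A = Q.cols(c0, c1) * K.cols(c0, c1).t() / s;
    const double* bcol = bias.colptr(h);
    for (arma::uword j = 0; j < n; ++j)
      for (arma::uword i = 0; i < n; ++i)
        A(i, j) += bcol[dist_idx(i, j) - 1];
    if (masked)
      for (arma::uword j = 0; j < n; ++j)
        if (!mask[j]) A.col(j).fill(-arma::datum::inf);
    softmax_rows_ip(A);
    P.slice(h) = A;
    Oc.cols(c0, c1) = A * V.cols(c0, c1);
  }
  arma::mat y = Oc * Wo;
  y.each_row() += bo.t();
  if (masked)
    for (arma::uword i = 0; i < n; ++i)
      if (!mask[i]) y.row(i).zeros();
  return List::create(_["y"] = y, _["xhat"] = ln.xhat,
                      _["invstd"] = ln.invstd, _["X"] = X, _["Q"] = Q,
                      _["K"] = K, _["V"] = V, _["P"] = P, _["Oc"] = Oc);
}

// [[Rcpp::export(name = ".cpp_attn_bwd")]]
List cpp_attn_bwd(arma::mat dy, const List& cache, const arma::mat& Wq,
                  const arma::mat& Wk, const arma::mat& Wv,
                  const arma::mat& Wo, const arma::mat& bias,
                  const arma::imat& dist_idx, const LogicalVector& mask,
                  const arma::vec& ln_g, int n_heads, int D) {
  arma::mat X = cache["X"], Q = cache["Q"], K = cache["K"],
            V = cache["V"], Oc = cache["Oc"];
  arma::cube P = cache["P"];
  LnCache ln;
  ln.xhat = as<arma::mat>(cache["xhat"]);
  ln.invstd = as<arma::vec>(cache["invstd"]);
  arma::uword n = X.n_rows;
  bool masked = is_false(all(mask));
  if (masked)
    for (arma::uword i = 0; i < n; ++i)
      if (!mask[i]) dy.row(i).zeros();
  arma::mat dWo = Oc.t() * dy;
  arma::vec dbo = arma::sum(dy, 0).t();
  arma::mat dOc = dy * Wo.t();
  arma::mat dQ(n, X.n_cols, arma::fill::zeros), dK = dQ, dV = dQ;
  arma::mat dbias(bias.n_rows, bias.n_cols, arma::fill::zeros);
  double s = std::sqrt((double) D);
  for (int h = 0; h < n_heads; ++h) {
    arma::uword c0 = h * D, c1 = (h + 1) * D - 1;
    const arma::mat& Ph = P.slice(h);
    arma::mat dP = dOc.cols(c0, c1) * V.cols(c0, c1).t();
    dV.cols(c0, c1) = Ph.t() * dOc.cols(c0, c1);
    arma::mat dA = Ph % (dP.each_col() - arma::sum(dP % Ph, 1));
    double* dbcol = dbias.colptr(h);
    for (arma::uword j = 0; j < n; ++j)
      for (arma::uword i = 0; i < n; ++i)
        dbcol[dist_idx(i, j) - 1] += dA(i, j);
    dQ.cols(c0, c1) = dA * K.cols(c0, c1) / s;
    dK.cols(c0, c1) = dA.t() * Q.cols(c0, c1) / s;
  }
  arma::mat dX = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
  arma::vec dg, db;
  arma::mat dx = layernorm_bwd(dX, ln, ln_g, dg, db);
  return List::create(_["dx"] = dx, _["Wq"] = X.t() * dQ,
                      _["Wk"] = X.t() * dK, _["Wv"] = X.t() * dV,
                      _["Wo"] = dWo, _["bo"] = as_rvec(dbo),
                      _["bias"] = dbias, _["ln_g"] = as_rvec(dg),
                      _["ln_b"] = as_rvec(db));
}

// [[Rcpp::export(name = ".cpp_mlp_fwd")]]
List cpp_mlp_fwd(const arma::mat& x, const arma::mat& Wm1,
                 const arma::vec& bm1, const arma::mat& Wm2,
                 const arma::vec& bm2, const arma::vec& ln_g,
                 const arma::vec& ln_b, const LogicalVector& mask) {
  LnCache ln = layernorm_fwd(x, ln_g, ln_b);
  arma::mat m1 = ln.y * Wm1;
  m1.each_row() += bm1.t();
  arma::mat a1 = gelu_fwd(m1);
  arma::mat y = a1 * Wm2;
  y.each_row() += bm2.t();
  if (is_false(all(mask)))
    for (arma::uword i = 0; i < y.n_rows; ++i)
      if (!mask[i]) y.row(i).zeros();
  return List::create(_["y"] = y, _["xhat"] = ln.xhat,
                      _["invstd"] = ln.invstd, _["X"] = ln.y,
                      _["m1"] = m1, _["a1"] = a1);
}

// [[Rcpp::export(name = ".cpp_mlp_bwd")]]
List cpp_mlp_bwd(arma::mat dy, const List& cache, const arma::mat& Wm1,
                 const arma::mat& Wm2, const arma::vec& ln_g,
                 const LogicalVector& mask) {
  arma::mat X = cache["X"], m1 = cache["m1"], a1 = cache["a1"];
  LnCache ln;
  ln.xhat = as<arma::mat>(cache["xhat"]);
  ln.invstd = as<arma::vec>(cache["invstd"]);
  if (is_false(all(mask)))
    for (arma::uword i = 0; i < dy.n_rows; ++i)
      if (!mask[i]) dy.row(i).zeros();
  arma::mat dWm2 = a1.t() * dy;
  arma::vec dbm2 = arma::sum(dy, 0).t();
  arma::mat da1 = dy * Wm2.t();
  arma::mat dm1 = gelu_bwd(m1, da1);
  arma::mat dWm1 = X.t() * dm1;
  arma::vec dbm1 = arma::sum(dm1, 0).t();
  arma::mat dX = dm1 * Wm1.t();
  arma::vec dg, db;
  arma::mat dx = layernorm_bwd(dX, ln, ln_g, dg, db);
  return List::create(_["dx"] = dx, _["Wm1"] = dWm1,
                      _["bm1"] = as_rvec(dbm1), _["Wm2"] = dWm2,
                      _["bm2"] = as_rvec(dbm2), _["ln_g"] = as_rvec(dg),
                      _["ln_b"] = as_rvec(db));
}
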