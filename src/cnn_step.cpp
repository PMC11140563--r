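// Fast path for the 1-D CNN surrogate: one fused forward/backward pass per
// minibatch, mirroring the reference implementation in R/cnn.R exactly
// (channels-first layout, column index (t-1)*batch + b). The R functions
// remain the independent reference; tests assert equality of the two paths.
// Nothing here mutates its R arguments: updated batch-norm running
// statistics are returned separately and folded back in on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

struct LayerCache {
  arma::mat cols, xhat, drop, relu;
  arma::vec inv;
  int len_in = 0, out_len = 0;
};

static arma::mat forward_pass(const arma::mat &Z0, int batch, int len0,
                              const List &params, int k, double dropout,
                              bool avg_pool, bool training,
                              std::vector<LayerCache> &caches,
                              std::vector<arma::vec> &new_stats,
                              arma::mat &Fm, arma::mat &H, arma::mat &relu1,
                              arma::mat &pool_mask, arma::uvec &pidx1,
                              arma::uvec &pidx2, int &plen_out) {
  List conv = params["conv"];
  int n_conv = conv.size();
  arma::mat Z = Z0;
  int len = len0;
  caches.resize(n_conv);
  new_stats.clear();
  for (int i = 0; i < n_conv; ++i) {
    List ly = conv[i];
    arma::mat W = ly["W"];
    arma::vec b = ly["b"], gamma = ly["gamma"], beta = ly["beta"];
    int ch = Z.n_rows;
    int out_len = len - k + 1;
    arma::mat cols(k * ch, batch * out_len);
    for (int o = 0; o < k; ++o)
      cols.rows(o * ch, (o + 1) * ch - 1) =
        Z.cols(o * batch, (o + out_len) * batch - 1);
    arma::mat A = W * cols;
    A.each_col() += b;
    arma::mat relu = arma::conv_to<arma::mat>::from(A > 0);
    A = A % relu;
    arma::vec inv;
    arma::mat xhat;
    if (training) {
      arma::vec mu = arma::mean(A, 1);
      A.each_col() -= mu;
      arma::vec v = arma::mean(A % A, 1);
      inv = 1.0 / arma::sqrt(v + BN_EPS);
      xhat = A.each_col() % inv;
      arma::vec rmean = ly["rmean"], rvar = ly["rvar"];
      new_stats.push_back(BN_MOMENTUM * rmean + (1 - BN_MOMENTUM) * mu);
      new_stats.push_back(BN_MOMENTUM * rvar + (1 - BN_MOMENTUM) * v);
    } else {
      arma::vec rmean = ly["rmean"], rvar = ly["rvar"];
      inv = 1.0 / arma::sqrt(rvar + BN_EPS);
      A.each_col() -= rmean;
      xhat = A.each_col() % inv;
    }
    arma::mat Y = xhat.each_col() % gamma;
    Y.each_col() += beta;
    arma::mat drop;
    if (training && dropout > 0) {
      NumericVector u = runif(Y.n_elem);  // R's RNG: seeding stays in R
      drop = arma::mat(u.begin(), Y.n_rows, Y.n_cols);
      drop.transform([dropout](double x) {
        return x >= dropout ? 1.0 / (1.0 - dropout) : 0.0;
      });
      Y = Y % drop;
    }
    if (training) {
      caches[i].cols = std::move(cols);
      caches[i].relu = std::move(relu);
      caches[i].xhat = std::move(xhat);
      caches[i].inv = inv;
      caches[i].drop = std::move(drop);
      caches[i].len_in = len;
      caches[i].out_len = out_len;
    }
    Z = std::move(Y);
    len = out_len;
  }
  int plen = len / 2;
  plen_out = plen;
  pidx1.set_size(batch * plen);
  pidx2.set_size(batch * plen);
  for (int t = 0; t < plen; ++t)
    for (int b2 = 0; b2 < batch; ++b2) {
      pidx1(t * batch + b2) = (2 * t) * batch + b2;
      pidx2(t * batch + b2) = (2 * t + 1) * batch + b2;
    }
  arma::mat Z1 = Z.cols(pidx1), Z2 = Z.cols(pidx2), P;
  if (avg_pool) {
    P = (Z1 + Z2) / 2.0;
  } else {
    pool_mask = arma::conv_to<arma::mat>::from(Z1 >= Z2);
    P = arma::max(Z1, Z2);
  }
  int ch = P.n_rows;
  Fm.set_size(ch * plen, batch);
  for (int t = 0; t < plen; ++t)
    Fm.rows(t * ch, (t + 1) * ch - 1) =
      P.cols(t * batch, (t + 1) * batch - 1);
  arma::mat W1 = params["W1"], W2 = params["W2"];
  arma::vec b1 = params["b1"], b2 = params["b2"];
  H = Fm.t() * W1;
  H.each_row() += b1.t();
  relu1 = arma::conv_to<arma::mat>::from(H > 0);
  H = H % relu1;
  arma::mat out = H * W2;
  out.each_row() += b2.t();
  return out;
}

// [[Rcpp::export(name = ".cnn_step_cpp")]]
List cnn_step_cpp(const arma::mat &Z0, const arma::mat &yb, int batch,
                  int len0, const List &params, int k, double dropout,
                  bool avg_pool, bool use_mae) {
  std::vector<LayerCache> caches;
  std::vector<arma::vec> new_stats;
  arma::mat Fm, H, relu1, pool_mask;
  arma::uvec pidx1, pidx2;
  int plen = 0;
  arma::mat out = forward_pass(Z0, batch, len0, params, k, dropout, avg_pool,
                               true, caches, new_stats, Fm, H, relu1,
                               pool_mask, pidx1, pidx2, plen);
  arma::mat err = out - yb;
  if (!err.is_finite())
    stop("non-finite loss; try a lower learning rate");
  double loss;
  arma::mat dOut;
  if (use_mae) {
    loss = arma::accu(arma::abs(err)) / err.n_elem;
    dOut = arma::sign(err) / (double)err.n_elem;
  } else {
    loss = arma::accu(err % err) / err.n_elem;
    dOut = 2.0 * err / (double)err.n_elem;
  }

  List conv = params["conv"];
  int n_conv = conv.size();
  arma::mat W1 = params["W1"], W2 = params["W2"];
  List grads_conv(n_conv);

  arma::mat Hmat = H;
  arma::mat dH = dOut * W2.t();
  arma::mat gW2 = Hmat.t() * dOut;
  arma::rowvec gb2 = arma::sum(dOut, 0);
  dH = dH % relu1;
  arma::mat gW1 = Fm * dH;
  arma::rowvec gb1 = arma::sum(dH, 0);
  arma::mat dF = W1 * dH.t();                 // flat x batch
  int ch = W1.n_rows / plen;
  arma::mat dP(ch, batch * plen);
  for (int t = 0; t < plen; ++t)
    dP.cols(t * batch, (t + 1) * batch - 1) =
      dF.rows(t * ch, (t + 1) * ch - 1);
  int last_len = caches[n_conv - 1].out_len;
  arma::mat dZ(ch, batch * last_len, arma::fill::zeros);
  if (avg_pool) {
    dZ.cols(pidx1) = dP / 2.0;
    dZ.cols(pidx2) = dP / 2.0;
  } else {
    dZ.cols(pidx1) = dP % pool_mask;
    dZ.cols(pidx2) = dP % (1.0 - pool_mask);
  }
  for (int i = n_conv - 1; i >= 0; --i) {
    LayerCache &cc = caches[i];
    List ly = conv[i];
    arma::mat W = ly["W"];
    arma::vec gamma = ly["gamma"];
    if (cc.drop.n_elem > 0) dZ = dZ % cc.drop;
    double N = dZ.n_cols;
    arma::vec dgamma = arma::sum(dZ % cc.xhat, 1);
    arma::vec dbeta = arma::sum(dZ, 1);
    arma::mat dxhat = dZ.each_col() % gamma;
    arma::vec s1 = arma::sum(dxhat, 1);
    arma::vec s2 = arma::sum(dxhat % cc.xhat, 1);
    arma::mat dX = N * dxhat;
    dX.each_col() -= s1;
    dX -= cc.xhat.each_col() % s2;
    dX.each_col() %= (cc.inv / N);
    arma::mat dA = dX % cc.relu;
    arma::mat gW = dA * cc.cols.t();
    arma::vec gb = arma::sum(dA, 1);
    arma::mat dcols = W.t() * dA;
    int ch_in = dcols.n_rows / k;
    arma::mat dZ_in(ch_in, batch * cc.len_in, arma::fill::zeros);
    for (int o = 0; o < k; ++o)
      dZ_in.cols(o * batch, (o + cc.out_len) * batch - 1) +=
        dcols.rows(o * ch_in, (o + 1) * ch_in - 1);
    grads_conv[i] = List::create(Named("W") = gW, Named("b") = gb,
                                 Named("gamma") = dgamma,
                                 Named("beta") = dbeta);
    dZ = std::move(dZ_in);
  }
  List grads = List::create(Named("conv") = grads_conv,
                            Named("W1") = gW1,
                            Named("b1") = arma::vec(gb1.t()),
                            Named("W2") = gW2,
                            Named("b2") = arma::vec(gb2.t()));
  List stats(2 * n_conv);
  for (int i = 0; i < 2 * n_conv; ++i) stats[i] = new_stats[i];
  return List::create(Named("loss") = loss, Named("grads") = grads,
                      Named("bn_stats") = stats, Named("out") = out);
}

// [[Rcpp::export(name = ".cnn_infer_cpp")]]
arma::mat cnn_infer_cpp(const arma::mat &Z0, int batch, int len0,
                        const List &params, int k, bool avg_pool) {
  std::vector<LayerCache> caches;
  std::vector<arma::vec> new_stats;
  arma::mat Fm, H, relu1, pool_mask;
  arma::uvec pidx1, pidx2;
  int plen = 0;
  return forward_pass(Z0, batch, len0, params, k, 0.0, avg_pool, false,
                      caches, new_stats, Fm, H, relu1, pool_mask,
                      pidx1, pidx2, plen);
}

// Adam update over the structured parameter list (conv W/b/gamma/beta plus
// the dense layers); running batch-norm statistics are not trainable and
// pass through untouched. Returns fresh lists; inputs are not mutated.
static arma::mat as_mat(SEXP s) {
  NumericVector nv(s);
  if (Rf_isMatrix(s)) {
    IntegerVector d = nv.attr("dim");
    return arma::mat(nv.begin(), d[0], d[1]);
  }
  return arma::mat(nv.begin(), nv.size(), 1);
}

static void adam_one(arma::mat &p, const arma::mat &g, arma::mat &m,
                     arma::mat &v, double lr, double t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * (g % g);
  arma::mat mh = m / (1 - std::pow(b1, t));
  arma::mat vh = v / (1 - std::pow(b2, t));
  p -= lr * mh / (arma::sqrt(vh) + eps);
}

// [[Rcpp::export(name = ".adam_step_cpp")]]
List adam_step_cpp(const List &params, const List &grads, const List &m_in,
                   const List &v_in, double lr, double t) {
  List p = clone(params), m = clone(m_in), v = clone(v_in);
  List pc = p["conv"], gc = grads["conv"], mc = m["conv"], vc = v["conv"];
  const char *names[4] = {"W", "b", "gamma", "beta"};
  for (int i = 0; i < pc.size(); ++i) {
    List pl = pc[i], gl = gc[i], ml = mc[i], vl = vc[i];
    for (int j = 0; j < 4; ++j) {
      arma::mat pp = as_mat(pl[names[j]]), gg = as_mat(gl[names[j]]);
      arma::mat mm = as_mat(ml[names[j]]), vv = as_mat(vl[names[j]]);
      gg.reshape(pp.n_rows, pp.n_cols);
      mm.reshape(pp.n_rows, pp.n_cols);
      vv.reshape(pp.n_rows, pp.n_cols);
      adam_one(pp, gg, mm, vv, lr, t);
      if (pp.n_cols == 1) {
        pl[names[j]] = NumericVector(pp.begin(), pp.end());
        ml[names[j]] = NumericVector(mm.begin(), mm.end());
        vl[names[j]] = NumericVector(vv.begin(), vv.end());
      } else {
        pl[names[j]] = pp;
        ml[names[j]] = mm;
        vl[names[j]] = vv;
      }
    }
  }
  const char *dn[4] = {"W1", "b1", "W2", "b2"};
  for (int j = 0; j < 4; ++j) {
    arma::mat pp = as_mat(p[dn[j]]), gg = as_mat(grads[dn[j]]);
    arma::mat mm = as_mat(m[dn[j]]), vv = as_mat(v[dn[j]]);
    gg.reshape(pp.n_rows, pp.n_cols);
    mm.reshape(pp.n_rows, pp.n_cols);
    vv.reshape(pp.n_rows, pp.n_cols);
    adam_one(pp, gg, mm, vv, lr, t);
    if (pp.n_cols == 1) {
      p[dn[j]] = NumericVector(pp.begin(), pp.end());
      m[dn[j]] = NumericVector(mm.begin(), mm.end());
      v[dn[j]] = NumericVector(vv.begin(), vv.end());
    } else {
      p[dn[j]] = pp;
      m[dn[j]] = mm;
      v[dn[j]] = vv;
    }
  }
  return List::create(Named("p") = p, Named("m") = m, Named("v") = v);
}
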