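// Compiled forward/backward kernels for the phase-error classifier.
//
// The network layout and parameter shapes match build_model() exactly:
//   strided conv stack (ReLU) -> tokens -> pre-LN transformer encoder with
//   per-head relative position bias -> final LN -> global average pooling ->
//   ReLU hidden head -> 3-class logits.
// Token activations are kept as a single (T*B, D) matrix with sample-major
// row blocks; only the attention product itself is evaluated per sample and
// head.  nn_step_cpp() runs one forward+backward pass on a mini-batch and
// returns the loss, logits and all parameter gradients; nn_infer_cpp() is
// the inference path (optionally exporting attention maps).  The pure-R
// implementation in nn_model.R computes the same quantities and serves as a
// cross-check in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

struct ConvLayer {
  int K, stride, Cin, Cout, Lin, Tout;
  mat W;            // (K*Cin, Cout), row index = k + c*K
  vec b;
  std::vector<mat> Wj;  // per-offset (Cin, Cout)
};

struct NetCfg {
  int n_conv, n_layers, n_heads, D, dh, mlp_mult, head_hidden, rel_buckets;
  int max_tokens;
  ivec strides, kernels;
};

void r_set_seed(int s) {
  Environment base = Environment::base_env();
  Function f = base["set.seed"];
  f(s);
}

NetCfg parse_cfg(const List& cfg) {
  NetCfg c;
  c.strides = as<ivec>(cfg["conv_strides"]);
  c.kernels = as<ivec>(cfg["conv_kernels"]);
  c.n_conv = c.strides.n_elem;
  c.n_layers = as<int>(cfg["n_layers"]);
  c.n_heads = as<int>(cfg["n_heads"]);
  c.D = as<int>(cfg["embed_dim"]);
  c.dh = c.D / c.n_heads;
  c.mlp_mult = as<int>(cfg["mlp_mult"]);
  c.head_hidden = as<int>(cfg["head_hidden"]);
  c.rel_buckets = as<int>(cfg["rel_bias_buckets"]);
  c.max_tokens = as<int>(cfg["max_field_of_view"]) /
                 as<int>(cfg["downsample_factor"]);
  return c;
}

// Signed log-spaced bucket index (0-based) for offset d; mirrors
// rel_bucket_index() in R (which is 1-based).
int bucket_of(int d, int B, int maxd) {
  if (d == 0) return B;
  int ad = std::abs(d);
  int exact = std::max(1, B / 2);
  int b;
  if (ad <= exact) {
    b = ad;
  } else {
    double lg = exact + 1.0 +
      std::floor(std::log((double)ad / exact) /
                 std::log((double)std::max(maxd, exact + 1) / exact) *
                 (B - exact - 1));
    b = std::min((int)lg, B);
  }
  return B + (d > 0 ? b : -b);
}

umat bucket_matrix(int T, int B, int maxd) {
  umat bm(T, T);
  for (int i = 0; i < T; ++i)
    for (int j = 0; j < T; ++j)
      bm(i, j) = (uword)bucket_of(i - j, B, maxd);
  return bm;
}

void softmax_rows_inplace(mat& S) {
  vec mx = max(S, 1);
  S.each_col() -= mx;
  S = exp(S);
  S.each_col() /= sum(S, 1);
}

mat relu_mask(const mat& x) { return conv_to<mat>::from(x > 0); }

struct LNCache { mat xhat; vec istd; };

mat ln_forward(const mat& x, const vec& g, const vec& b, LNCache& c) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec v = mean(xc % xc, 1);
  c.istd = 1.0 / sqrt(v + 1e-5);
  c.xhat = xc.each_col() % c.istd;
  mat y = c.xhat.each_row() % g.t();
  y.each_row() += b.t();
  return y;
}

mat ln_backward(const mat& dy, const vec& g, const LNCache& c,
                vec& dg, vec& db) {
  dg += sum(dy % c.xhat, 0).t();
  db += sum(dy, 0).t();
  mat dxhat = dy.each_row() % g.t();
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % c.xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= c.xhat.each_col() % m2;
  dx.each_col() %= c.istd;
  return dx;
}

std::vector<ConvLayer> parse_conv(const List& params, const NetCfg& c, int L0,
                                  int Cin0) {
  std::vector<ConvLayer> layers(c.n_conv);
  int L = L0, Cin = Cin0;
  for (int l = 0; l < c.n_conv; ++l) {
    ConvLayer& cl = layers[l];
    cl.K = c.kernels(l);
    cl.stride = c.strides(l);
    cl.Lin = L;
    cl.Cin = Cin;
    std::string nm = "conv" + std::to_string(l + 1);
    cl.W = as<mat>(params[nm + "_W"]);
    cl.b = as<vec>(params[nm + "_b"]);
    cl.Cout = cl.W.n_cols;
    cl.Tout = (L + cl.stride - 1) / cl.stride;
    cl.Wj.resize(cl.K);
    for (int j = 0; j < cl.K; ++j) {
      mat wj(cl.Cin, cl.Cout);
      for (int cc = 0; cc < cl.Cin; ++cc) wj.row(cc) = cl.W.row(j + cc * cl.K);
      cl.Wj[j] = wj;
    }
    L = cl.Tout;
    Cin = cl.Cout;
  }
  return layers;
}

// Valid output range [t0, t1] and first input row r0 for kernel offset j.
inline void conv_range(const ConvLayer& cl, int j, int& t0, int& t1, int& r0) {
  int pad = (cl.K - 1) / 2;
  t0 = std::max(0, (int)std::ceil((double)(pad - j) / cl.stride));
  t1 = std::min(cl.Tout - 1, (int)std::floor((double)(cl.Lin - 1 + pad - j) /
                                             cl.stride));
  r0 = t0 * cl.stride - pad + j;
}

inline uvec conv_rows(const ConvLayer& cl, int t0, int t1, int r0) {
  int nt = t1 - t0 + 1;
  uvec rows(nt);
  for (int t = 0; t < nt; ++t) rows(t) = (uword)(r0 + t * cl.stride);
  return rows;
}

cube conv_fwd(const ConvLayer& cl, const cube& X, cube& mask, bool keep_mask) {
  int B = X.n_slices;
  cube Y(cl.Tout, cl.Cout, B);
  for (int b = 0; b < B; ++b) {
    mat y(cl.Tout, cl.Cout);
    y.each_row() = cl.b.t();
    for (int j = 0; j < cl.K; ++j) {
      int t0, t1, r0;
      conv_range(cl, j, t0, t1, r0);
      if (t1 < t0) continue;
      uvec rows = conv_rows(cl, t0, t1, r0);
      y.rows(t0, t1) += X.slice(b).rows(rows) * cl.Wj[j];
    }
    mat mk = relu_mask(y);
    if (keep_mask) mask.slice(b) = mk;
    Y.slice(b) = y % mk;        // ReLU
  }
  return Y;
}

cube conv_bwd(const ConvLayer& cl, const cube& Xin, const cube& dY,
              mat& dW, vec& db) {
  int B = dY.n_slices;
  cube dX(cl.Lin, cl.Cin, B, fill::zeros);
  mat dWj(cl.Cin, cl.Cout);
  for (int b = 0; b < B; ++b) {
    const mat& dYb = dY.slice(b);
    db += sum(dYb, 0).t();
    for (int j = 0; j < cl.K; ++j) {
      int t0, t1, r0;
      conv_range(cl, j, t0, t1, r0);
      if (t1 < t0) continue;
      uvec rows = conv_rows(cl, t0, t1, r0);
      mat dYsub = dYb.rows(t0, t1);
      dWj = Xin.slice(b).rows(rows).t() * dYsub;
      for (int cc = 0; cc < cl.Cin; ++cc)
        dW.row(j + cc * cl.K) += dWj.row(cc);
      dX.slice(b).rows(rows) += dYsub * cl.Wj[j].t();
    }
  }
  return dX;
}

std::vector<mat> expand_bias(const mat& relb, const umat& bm, int n_heads) {
  int T = bm.n_rows;
  std::vector<mat> biasmats(n_heads);
  for (int hh = 0; hh < n_heads; ++hh) {
    const vec w = relb.col(hh);
    mat bmat(T, T);
    for (uword i = 0; i < bm.n_elem; ++i) bmat(i) = w(bm(i));
    biasmats[hh] = bmat;
  }
  return biasmats;
}

mat drop_mask(int nr, int nc, double p) {
  mat dm(nr, nc);
  for (uword i = 0; i < dm.n_elem; ++i)
    dm(i) = (R::runif(0, 1) >= p) / (1 - p);
  return dm;
}

struct LayerCache {
  LNCache ln1, ln2;
  mat ln1y, Q, K, V, O, X1, ln2y, Hh, Hmask, dm1, dm2;
  std::vector<mat> A;           // B * n_heads attention matrices
};

} // namespace

// [[Rcpp::export]]
List nn_step_cpp(List params, List cfg, NumericVector x_, IntegerVector y,
                 double dropout, int dropout_seed) {
  NetCfg c = parse_cfg(cfg);
  IntegerVector xd = x_.attr("dim");
  int L0 = xd[0], Cin0 = xd[1], B = xd[2];
  cube X0(x_.begin(), L0, Cin0, B);
  std::vector<ConvLayer> conv = parse_conv(params, c, L0, Cin0);

  // ---- conv stack ----
  std::vector<cube> conv_in(c.n_conv), conv_mask(c.n_conv);
  cube h = X0;
  for (int l = 0; l < c.n_conv; ++l) {
    conv_in[l] = h;
    conv_mask[l] = cube(conv[l].Tout, conv[l].Cout, B);
    h = conv_fwd(conv[l], h, conv_mask[l], true);
  }
  int T = h.n_rows, D = c.D;
  umat bm = bucket_matrix(T, c.rel_buckets, c.max_tokens);
  bool use_drop = dropout > 0;
  if (use_drop) r_set_seed(dropout_seed);

  // tokens, sample-major row blocks: row = t + b*T
  mat X(T * B, D);
  for (int b = 0; b < B; ++b) X.rows(b * T, b * T + T - 1) = h.slice(b);
  mat Xtokens = X;  // kept for conv backward shape

  // ---- transformer ----
  std::vector<LayerCache> caches(c.n_layers);
  std::vector<mat> Xin_layer(c.n_layers);
  double sdh = std::sqrt((double)c.dh);
  for (int l = 0; l < c.n_layers; ++l) {
    std::string pre = "t" + std::to_string(l + 1) + "_";
    LayerCache& cc = caches[l];
    Xin_layer[l] = X;
    mat ln1y = ln_forward(X, as<vec>(params[pre + "ln1_g"]),
                          as<vec>(params[pre + "ln1_b"]), cc.ln1);
    cc.ln1y = ln1y;
    cc.Q = ln1y * as<mat>(params[pre + "Wq"]);
    cc.K = ln1y * as<mat>(params[pre + "Wk"]);
    cc.V = ln1y * as<mat>(params[pre + "Wv"]);
    std::vector<mat> biasmats =
      expand_bias(as<mat>(params[pre + "relb"]), bm, c.n_heads);
    cc.A.resize(B * c.n_heads);
    mat O(T * B, D);
    for (int b = 0; b < B; ++b) {
      span rb(b * T, b * T + T - 1);
      for (int hh = 0; hh < c.n_heads; ++hh) {
        span cs(hh * c.dh, (hh + 1) * c.dh - 1);
        mat S = cc.Q(rb, cs) * cc.K(rb, cs).t() / sdh + biasmats[hh];
        softmax_rows_inplace(S);
        cc.A[b * c.n_heads + hh] = S;
        O(rb, cs) = S * cc.V(rb, cs);
      }
    }
    cc.O = O;
    mat AO = O * as<mat>(params[pre + "Wo"]);
    AO.each_row() += as<vec>(params[pre + "bo"]).t();
    if (use_drop) { cc.dm1 = drop_mask(T * B, D, dropout); AO %= cc.dm1; }
    mat X1 = X + AO;
    cc.X1 = X1;
    mat ln2y = ln_forward(X1, as<vec>(params[pre + "ln2_g"]),
                          as<vec>(params[pre + "ln2_b"]), cc.ln2);
    cc.ln2y = ln2y;
    mat Hpre = ln2y * as<mat>(params[pre + "W1"]);
    Hpre.each_row() += as<vec>(params[pre + "b1"]).t();
    cc.Hmask = relu_mask(Hpre);
    mat Hh = Hpre % cc.Hmask;
    if (use_drop) { cc.dm2 = drop_mask(T * B, Hh.n_cols, dropout); Hh %= cc.dm2; }
    cc.Hh = Hh;
    mat M = Hh * as<mat>(params[pre + "W2"]);
    M.each_row() += as<vec>(params[pre + "b2"]).t();
    X = X1 + M;
  }

  // ---- final LN, GAP, head ----
  LNCache lnf;
  mat lnfy = ln_forward(X, as<vec>(params["lnf_g"]), as<vec>(params["lnf_b"]),
                        lnf);
  mat G(B, D);
  for (int b = 0; b < B; ++b)
    G.row(b) = mean(lnfy.rows(b * T, b * T + T - 1), 0);
  mat hW1 = as<mat>(params["head_W1"]), hW2 = as<mat>(params["head_W2"]);
  mat H1pre = G * hW1;
  H1pre.each_row() += as<vec>(params["head_b1"]).t();
  mat H1mask = relu_mask(H1pre);
  mat H1 = H1pre % H1mask;
  mat logits = H1 * hW2;
  logits.each_row() += as<vec>(params["head_b2"]).t();

  // ---- loss ----
  mat probs = logits;
  softmax_rows_inplace(probs);
  double loss = 0;
  mat dlogits = probs;
  for (int b = 0; b < B; ++b) {
    int yy = y[b] - 1;
    loss -= std::log(std::max(probs(b, yy), 1e-12));
    dlogits(b, yy) -= 1.0;
  }
  loss /= B;
  dlogits /= B;

  // ---- backward ----
  List g;
  g["head_W2"] = wrap(mat(H1.t() * dlogits));
  g["head_b2"] = wrap(vec(sum(dlogits, 0).t()));
  mat dH1 = (dlogits * hW2.t()) % H1mask;
  g["head_W1"] = wrap(mat(G.t() * dH1));
  g["head_b1"] = wrap(vec(sum(dH1, 0).t()));
  mat dG = dH1 * hW1.t();
  mat dlnfy(T * B, D);
  for (int b = 0; b < B; ++b)
    dlnfy.rows(b * T, b * T + T - 1) = repmat(dG.row(b) / T, T, 1);
  vec dlnfg(D, fill::zeros), dlnfb(D, fill::zeros);
  mat dX = ln_backward(dlnfy, as<vec>(params["lnf_g"]), lnf, dlnfg, dlnfb);
  g["lnf_g"] = wrap(dlnfg);
  g["lnf_b"] = wrap(dlnfb);

  for (int l = c.n_layers - 1; l >= 0; --l) {
    std::string pre = "t" + std::to_string(l + 1) + "_";
    LayerCache& cc = caches[l];
    mat W1 = as<mat>(params[pre + "W1"]), W2 = as<mat>(params[pre + "W2"]);
    mat Wq = as<mat>(params[pre + "Wq"]), Wk = as<mat>(params[pre + "Wk"]);
    mat Wv = as<mat>(params[pre + "Wv"]), Wo = as<mat>(params[pre + "Wo"]);

    // MLP branch
    g[pre + "W2"] = wrap(mat(cc.Hh.t() * dX));
    g[pre + "b2"] = wrap(vec(sum(dX, 0).t()));
    mat dHh = dX * W2.t();
    if (use_drop) dHh %= cc.dm2;
    mat dHpre = dHh % cc.Hmask;
    g[pre + "W1"] = wrap(mat(cc.ln2y.t() * dHpre));
    g[pre + "b1"] = wrap(vec(sum(dHpre, 0).t()));
    vec dln2g(D, fill::zeros), dln2b(D, fill::zeros);
    mat dX1 = dX + ln_backward(dHpre * W1.t(),
                               as<vec>(params[pre + "ln2_g"]), cc.ln2,
                               dln2g, dln2b);
    g[pre + "ln2_g"] = wrap(dln2g); g[pre + "ln2_b"] = wrap(dln2b);

    // attention branch
    mat dAO = dX1;
    if (use_drop) dAO %= cc.dm1;
    g[pre + "Wo"] = wrap(mat(cc.O.t() * dAO));
    g[pre + "bo"] = wrap(vec(sum(dAO, 0).t()));
    mat dO = dAO * Wo.t();
    mat dQ(T * B, D, fill::zeros), dK(T * B, D, fill::zeros),
        dV(T * B, D, fill::zeros);
    mat drelb(2 * c.rel_buckets + 1, c.n_heads, fill::zeros);
    for (int b = 0; b < B; ++b) {
      span rb(b * T, b * T + T - 1);
      for (int hh = 0; hh < c.n_heads; ++hh) {
        span cs(hh * c.dh, (hh + 1) * c.dh - 1);
        const mat& A = cc.A[b * c.n_heads + hh];
        mat dOb = dO(rb, cs);
        mat dA = dOb * cc.V(rb, cs).t();
        dV(rb, cs) += A.t() * dOb;
        vec rs = sum(dA % A, 1);
        mat dS = dA;
        dS.each_col() -= rs;
        dS %= A;
        for (uword i = 0; i < bm.n_elem; ++i) drelb(bm(i), hh) += dS(i);
        dQ(rb, cs) += dS * cc.K(rb, cs) / sdh;
        dK(rb, cs) += dS.t() * cc.Q(rb, cs) / sdh;
      }
    }
    g[pre + "relb"] = wrap(drelb);
    g[pre + "Wq"] = wrap(mat(cc.ln1y.t() * dQ));
    g[pre + "Wk"] = wrap(mat(cc.ln1y.t() * dK));
    g[pre + "Wv"] = wrap(mat(cc.ln1y.t() * dV));
    vec dln1g(D, fill::zeros), dln1b(D, fill::zeros);
    mat dln1y = dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();
    dX = dX1 + ln_backward(dln1y, as<vec>(params[pre + "ln1_g"]), cc.ln1,
                           dln1g, dln1b);
    g[pre + "ln1_g"] = wrap(dln1g); g[pre + "ln1_b"] = wrap(dln1b);
  }

  // ---- conv backward ----
  cube dh(T, D, B);
  for (int b = 0; b < B; ++b) dh.slice(b) = dX.rows(b * T, b * T + T - 1);
  for (int l = c.n_conv - 1; l >= 0; --l) {
    dh %= conv_mask[l];
    mat dW(conv[l].W.n_rows, conv[l].W.n_cols, fill::zeros);
    vec db(conv[l].Cout, fill::zeros);
    dh = conv_bwd(conv[l], conv_in[l], dh, dW, db);
    std::string nm = "conv" + std::to_string(l + 1);
    g[nm + "_W"] = wrap(dW);
    g[nm + "_b"] = wrap(db);
  }

  return List::create(_["loss"] = loss, _["logits"] = wrap(logits),
                      _["probs"] = wrap(probs), _["grads"] = g);
}

// [[Rcpp::export]]
List nn_infer_cpp(List params, List cfg, NumericVector x_,
                  bool want_attention) {
  NetCfg c = parse_cfg(cfg);
  IntegerVector xd = x_.attr("dim");
  int L0 = xd[0], Cin0 = xd[1], B = xd[2];
  cube X0(x_.begin(), L0, Cin0, B);
  std::vector<ConvLayer> conv = parse_conv(params, c, L0, Cin0);
  cube h = X0, dummy;
  for (int l = 0; l < c.n_conv; ++l) {
    dummy = cube(0, 0, 0);
    h = conv_fwd(conv[l], h, dummy, false);
  }
  int T = h.n_rows, D = c.D;
  umat bm = bucket_matrix(T, c.rel_buckets, c.max_tokens);
  NumericVector attn;
  if (want_attention) {
    attn = NumericVector((R_xlen_t)c.n_layers * c.n_heads * T * T);
    attn.attr("dim") = IntegerVector::create(c.n_layers, c.n_heads, T, T);
  }
  mat X(T * B, D);
  for (int b = 0; b < B; ++b) X.rows(b * T, b * T + T - 1) = h.slice(b);
  double sdh = std::sqrt((double)c.dh);
  for (int l = 0; l < c.n_layers; ++l) {
    std::string pre = "t" + std::to_string(l + 1) + "_";
    LNCache c1, c2;
    mat ln1y = ln_forward(X, as<vec>(params[pre + "ln1_g"]),
                          as<vec>(params[pre + "ln1_b"]), c1);
    mat Q = ln1y * as<mat>(params[pre + "Wq"]);
    mat K = ln1y * as<mat>(params[pre + "Wk"]);
    mat V = ln1y * as<mat>(params[pre + "Wv"]);
    std::vector<mat> biasmats =
      expand_bias(as<mat>(params[pre + "relb"]), bm, c.n_heads);
    mat O(T * B, D);
    for (int b = 0; b < B; ++b) {
      span rb(b * T, b * T + T - 1);
      for (int hh = 0; hh < c.n_heads; ++hh) {
        span cs(hh * c.dh, (hh + 1) * c.dh - 1);
        mat S = Q(rb, cs) * K(rb, cs).t() / sdh + biasmats[hh];
        softmax_rows_inplace(S);
        if (want_attention && b == 0)
          for (int i = 0; i < T; ++i)
            for (int j = 0; j < T; ++j)
              attn[l + c.n_layers * (hh + c.n_heads *
                    ((R_xlen_t)i + (R_xlen_t)T * j))] = S(i, j);
        O(rb, cs) = S * V(rb, cs);
      }
    }
    mat AO = O * as<mat>(params[pre + "Wo"]);
    AO.each_row() += as<vec>(params[pre + "bo"]).t();
    mat X1 = X + AO;
    mat ln2y = ln_forward(X1, as<vec>(params[pre + "ln2_g"]),
                          as<vec>(params[pre + "ln2_b"]), c2);
    mat Hpre = ln2y * as<mat>(params[pre + "W1"]);
    Hpre.each_row() += as<vec>(params[pre + "b1"]).t();
    mat Hh = Hpre % relu_mask(Hpre);
    mat M = Hh * as<mat>(params[pre + "W2"]);
    M.each_row() += as<vec>(params[pre + "b2"]).t();
    X = X1 + M;
  }
  LNCache lnf;
  mat lnfy = ln_forward(X, as<vec>(params["lnf_g"]), as<vec>(params["lnf_b"]),
                        lnf);
  mat G(B, D);
  for (int b = 0; b < B; ++b)
    G.row(b) = mean(lnfy.rows(b * T, b * T + T - 1), 0);
  mat H1pre = G * as<mat>(params["head_W1"]);
  H1pre.each_row() += as<vec>(params["head_b1"]).t();
  mat H1 = H1pre % relu_mask(H1pre);
  mat logits = H1 * as<mat>(params["head_W2"]);
  logits.each_row() += as<vec>(params["head_b2"]).t();
  List out = List::create(_["logits"] = wrap(logits), _["n_tokens"] = T);
  if (want_attention) out["attention"] = attn;
  return out;
}
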