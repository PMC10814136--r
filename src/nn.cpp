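// Deep regression models for 1-D spectra: CNN, LSTM, CNN-LSTM,
// Transformer encoder, CNN-Transformer. Single-precision forward/backward
// with hand-derived gradients and an AdamW training loop. Each spectrum is
// a sequence of B band positions; convolutions are kernel-3, stride-1,
// zero-padded so the token count is preserved end to end.
#include <RcppArmadillo.h>
#include <random>
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

typedef std::mt19937 RNG;

static void enable_ftz() {
  // flush denormals to zero: saturated attention rows otherwise produce
  // subnormal activations that stall the FPU
#if defined(__SSE2__)
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
#endif
}


struct P {
  fmat w, g, m, v;
  void setsize(int r, int c) {
    w.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
  void uni(float k, RNG& rng) {
    std::uniform_real_distribution<float> d(-k, k);
    for (uword i = 0; i < w.n_elem; ++i) w(i) = d(rng);
  }
};

typedef std::vector<std::pair<std::string, P*>> ParamList;

// ---- layers -------------------------------------------------------------

struct Lin {
  P W, b;
  fmat X;
  void init(int cin, int cout, RNG& rng) {
    W.setsize(cin, cout); b.setsize(1, cout);
    float k = 1.0f / std::sqrt((float)cin);
    W.uni(k, rng); b.uni(k, rng);
  }
  // Glorot/Xavier uniform, the conventional init for attention and
  // feed-forward projections; biases start at zero
  void init_xavier(int cin, int cout, RNG& rng) {
    W.setsize(cin, cout); b.setsize(1, cout);
    float k = std::sqrt(6.0f / (float)(cin + cout));
    W.uni(k, rng);
  }
  fmat fwd(const fmat& x) {
    X = x;
    fmat y = x * W.w;
    y.each_row() += b.w.row(0);
    return y;
  }
  fmat bwd(const fmat& gy) {
    W.g += X.t() * gy;
    b.g += sum(gy, 0);
    return gy * W.w.t();
  }
  void reg(ParamList& ps, const std::string& n) {
    ps.push_back({n + ".W", &W});
    ps.push_back({n + ".b", &b});
  }
};

// kernel-3 same-padding 1-D convolution over an L x Cin sequence,
// realised as im2col followed by a linear map (3*Cin -> Cout)
struct Conv3 {
  Lin lin;
  int cin = 0, cout = 0;
  void init(int cin_, int cout_, RNG& rng) {
    cin = cin_; cout = cout_;
    lin.W.setsize(3 * cin, cout); lin.b.setsize(1, cout);
    float k = 1.0f / std::sqrt((float)(3 * cin));
    lin.W.uni(k, rng); lin.b.uni(k, rng);
  }
  fmat fwd(const fmat& x) {
    int L = x.n_rows;
    fmat xc(L, 3 * cin, fill::zeros);
    xc.cols(cin, 2 * cin - 1) = x;
    if (L > 1) {
      xc.submat(1, 0, L - 1, cin - 1) = x.rows(0, L - 2);
      xc.submat(0, 2 * cin, L - 2, 3 * cin - 1) = x.rows(1, L - 1);
    }
    return lin.fwd(xc);
  }
  fmat bwd(const fmat& gy) {
    fmat gxc = lin.bwd(gy);
    int L = gy.n_rows;
    fmat gx = gxc.cols(cin, 2 * cin - 1);
    if (L > 1) {
      gx.rows(0, L - 2) += gxc.submat(1, 0, L - 1, cin - 1);
      gx.rows(1, L - 1) += gxc.submat(0, 2 * cin, L - 2, 3 * cin - 1);
    }
    return gx;
  }
  void reg(ParamList& ps, const std::string& n) { lin.reg(ps, n); }
};

struct ReLU {
  fmat mask;
  fmat fwd(const fmat& x) {
    mask = conv_to<fmat>::from(x > 0.0f);
    return x % mask;
  }
  fmat bwd(const fmat& gy) { return gy % mask; }
};

struct Dropout {
  float p = 0.0f;
  bool active = false;
  fmat mask;
  fmat fwd(const fmat& x, bool train, RNG& rng) {
    active = train && p > 0.0f;
    if (!active) return x;
    std::uniform_real_distribution<float> d(0.0f, 1.0f);
    mask.set_size(size(x));
    float keep = 1.0f - p;
    for (uword i = 0; i < mask.n_elem; ++i)
      mask(i) = d(rng) < keep ? 1.0f / keep : 0.0f;
    return x % mask;
  }
  fmat bwd(const fmat& gy) { return active ? fmat(gy % mask) : gy; }
};

struct LayerNorm {
  P ga, be;
  fmat xhat;
  fvec sig;
  void init(int d) {
    ga.setsize(1, d); ga.w.ones();
    be.setsize(1, d);
  }
  fmat fwd(const fmat& x) {
    fvec mu = mean(x, 1);
    fvec va = var(x, 1, 1);  // population variance per token row
    sig = sqrt(va + 1e-5f);
    xhat = x;
    xhat.each_col() -= mu;
    xhat.each_col() /= sig;
    fmat y = xhat;
    y.each_row() %= ga.w.row(0);
    y.each_row() += be.w.row(0);
    return y;
  }
  fmat bwd(const fmat& gy) {
    ga.g += sum(gy % xhat, 0);
    be.g += sum(gy, 0);
    fmat dxh = gy;
    dxh.each_row() %= ga.w.row(0);
    fvec m1 = mean(dxh, 1);
    fvec m2 = mean(dxh % xhat, 1);
    fmat dx = dxh;
    dx.each_col() -= m1;
    fmat t = xhat;
    t.each_col() %= m2;
    dx -= t;
    dx.each_col() /= sig;
    return dx;
  }
  void reg(ParamList& ps, const std::string& n) {
    ps.push_back({n + ".gamma", &ga});
    ps.push_back({n + ".beta", &be});
  }
};

struct MHA {
  int d = 0, h = 0, dk = 0;
  Lin Wq, Wk, Wv, Wo;
  fmat Q, K, V, O;
  std::vector<fmat> Ph;
  void init(int d_, int h_, RNG& rng) {
    d = d_; h = h_; dk = d / h;
    Wq.init_xavier(d, d, rng); Wk.init_xavier(d, d, rng);
    Wv.init_xavier(d, d, rng); Wo.init_xavier(d, d, rng);
  }
  fmat fwd(const fmat& x) {
    Q = Wq.fwd(x); K = Wk.fwd(x); V = Wv.fwd(x);
    int L = x.n_rows;
    O.set_size(L, d);
    Ph.assign(h, fmat());
    float sc = 1.0f / std::sqrt((float)dk);
    for (int i = 0; i < h; ++i) {
      int a = i * dk, b = (i + 1) * dk - 1;
      fmat S = Q.cols(a, b) * K.cols(a, b).t() * sc;
      S.each_col() -= max(S, 1);
      fmat E = exp(S);
      fvec rs = sum(E, 1);
      E.each_col() /= rs;
      Ph[i] = E;
      O.cols(a, b) = E * V.cols(a, b);
    }
    return Wo.fwd(O);
  }
  fmat bwd(const fmat& gy) {
    fmat gO = Wo.bwd(gy);
    fmat gQ(size(Q), fill::zeros), gK(size(K), fill::zeros),
        gV(size(V), fill::zeros);
    float sc = 1.0f / std::sqrt((float)dk);
    for (int i = 0; i < h; ++i) {
      int a = i * dk, b = (i + 1) * dk - 1;
      fmat gOh = gO.cols(a, b);
      fmat gP = gOh * V.cols(a, b).t();
      gV.cols(a, b) = Ph[i].t() * gOh;
      fvec rs = sum(gP % Ph[i], 1);
      fmat gS = Ph[i] % gP;
      fmat t = Ph[i];
      t.each_col() %= rs;
      gS -= t;
      gS *= sc;
      gQ.cols(a, b) = gS * K.cols(a, b);
      gK.cols(a, b) = gS.t() * Q.cols(a, b);
    }
    return Wq.bwd(gQ) + Wk.bwd(gK) + Wv.bwd(gV);
  }
  void reg(ParamList& ps, const std::string& n) {
    Wq.reg(ps, n + ".Wq"); Wk.reg(ps, n + ".Wk");
    Wv.reg(ps, n + ".Wv"); Wo.reg(ps, n + ".Wo");
  }
};

struct FFN {
  Lin l1, l2;
  ReLU r;
  void init(int d, int ff, RNG& rng) {
    l1.init_xavier(d, ff, rng); l2.init_xavier(ff, d, rng);
  }
  fmat fwd(const fmat& x) { return l2.fwd(r.fwd(l1.fwd(x))); }
  fmat bwd(const fmat& gy) { return l1.bwd(r.bwd(l2.bwd(gy))); }
  void reg(ParamList& ps, const std::string& n) {
    l1.reg(ps, n + ".l1"); l2.reg(ps, n + ".l2");
  }
};

// post-norm encoder block: LayerNorm(X + MHA(X)) then LayerNorm(X + FFN(X))
struct Encoder {
  MHA mha;
  LayerNorm ln1, ln2;
  FFN ffn;
  void init(int d, int h, int ff, RNG& rng) {
    mha.init(d, h, rng); ln1.init(d); ffn.init(d, ff, rng); ln2.init(d);
  }
  fmat fwd(const fmat& x) {
    fmat n1 = ln1.fwd(x + mha.fwd(x));
    return ln2.fwd(n1 + ffn.fwd(n1));
  }
  fmat bwd(const fmat& gy) {
    fmat g2 = ln2.bwd(gy);
    fmat gn1 = g2 + ffn.bwd(g2);
    fmat g1 = ln1.bwd(gn1);
    return g1 + mha.bwd(g1);
  }
  void reg(ParamList& ps, const std::string& n) {
    mha.reg(ps, n + ".mha"); ln1.reg(ps, n + ".ln1");
    ffn.reg(ps, n + ".ffn"); ln2.reg(ps, n + ".ln2");
  }
};

struct LSTM {
  int cin = 0, H = 0;
  P Wx, Wh, b;
  fmat Xs, Is, Fs, Gs, Os, Cs, Hs;
  void init(int cin_, int H_, RNG& rng) {
    cin = cin_; H = H_;
    Wx.setsize(cin, 4 * H); Wh.setsize(H, 4 * H); b.setsize(1, 4 * H);
    float k = 1.0f / std::sqrt((float)H);
    Wx.uni(k, rng); Wh.uni(k, rng); b.uni(k, rng);
  }
  static frowvec sig(const frowvec& z) { return 1.0f / (1.0f + exp(-z)); }
  frowvec fwd(const fmat& x) {
    int T = x.n_rows;
    Xs = x;
    Is.set_size(T, H); Fs.set_size(T, H); Gs.set_size(T, H);
    Os.set_size(T, H); Cs.set_size(T, H); Hs.set_size(T, H);
    frowvec hp(H, fill::zeros), cp(H, fill::zeros);
    for (int t = 0; t < T; ++t) {
      frowvec z = x.row(t) * Wx.w + hp * Wh.w + b.w.row(0);
      frowvec i = sig(z.cols(0, H - 1));
      frowvec f = sig(z.cols(H, 2 * H - 1));
      frowvec g = tanh(z.cols(2 * H, 3 * H - 1));
      frowvec o = sig(z.cols(3 * H, 4 * H - 1));
      cp = f % cp + i % g;
      hp = o % tanh(cp);
      Is.row(t) = i; Fs.row(t) = f; Gs.row(t) = g; Os.row(t) = o;
      Cs.row(t) = cp; Hs.row(t) = hp;
    }
    return hp;
  }
  fmat bwd(const frowvec& ghT) {
    int T = Xs.n_rows;
    fmat gX(T, cin, fill::zeros);
    frowvec gh = ghT, gc(H, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      frowvec i = Is.row(t), f = Fs.row(t), g = Gs.row(t), o = Os.row(t);
      frowvec tc = tanh(Cs.row(t));
      gc += gh % o % (1.0f - tc % tc);
      frowvec go = gh % tc;
      frowvec cprev = t > 0 ? frowvec(Cs.row(t - 1)) : frowvec(H, fill::zeros);
      frowvec hprev = t > 0 ? frowvec(Hs.row(t - 1)) : frowvec(H, fill::zeros);
      frowvec zi = gc % g % i % (1.0f - i);
      frowvec zf = gc % cprev % f % (1.0f - f);
      frowvec zg = gc % i % (1.0f - g % g);
      frowvec zo = go % o % (1.0f - o);
      frowvec z = join_rows(join_rows(zi, zf), join_rows(zg, zo));
      Wx.g += Xs.row(t).t() * z;
      Wh.g += hprev.t() * z;
      b.g += z;
      gX.row(t) = z * Wx.w.t();
      gh = z * Wh.w.t();
      gc = gc % f;
    }
    return gX;
  }
  void reg(ParamList& ps, const std::string& n) {
    ps.push_back({n + ".Wx", &Wx});
    ps.push_back({n + ".Wh", &Wh});
    ps.push_back({n + ".b", &b});
  }
};

// fixed sinusoidal positional encoding, PE[pos,2i]=sin, PE[pos,2i+1]=cos
static fmat make_pe(int L, int d) {
  mat pe(L, d);
  for (int pos = 0; pos < L; ++pos)
    for (int i = 0; i < d / 2; ++i) {
      double ang = pos / std::pow(10000.0, (2.0 * i) / d);
      pe(pos, 2 * i) = std::sin(ang);
      pe(pos, 2 * i + 1) = std::cos(ang);
    }
  return conv_to<fmat>::from(pe);
}

// ---- architectures ------------------------------------------------------

struct Model {
  ParamList ps;
  bool has_conv = false;
  fmat cam_A, cam_G;  // final conv feature map and its output gradient
  fmat in_grad;       // gradient of the scalar output w.r.t. the input
  virtual float fwd(const fvec& x, bool train, RNG& rng) = 0;
  virtual void bwd(float gy) = 0;
  virtual ~Model() {}
};

struct CNNModel : Model {
  Conv3 c1, c2;
  ReLU r1, r2, r3;
  Dropout drop;
  Lin fc1, fc2;
  int L;
  CNNModel(int L_, RNG& rng) : L(L_) {
    has_conv = true;
    c1.init(1, 128, rng); c2.init(128, 256, rng);
    fc1.init(L * 256, 64, rng); fc2.init(64, 1, rng);
    drop.p = 0.3f;
    c1.reg(ps, "conv1"); c2.reg(ps, "conv2");
    fc1.reg(ps, "fc1"); fc2.reg(ps, "fc2");
  }
  float fwd(const fvec& x, bool train, RNG& rng) override {
    fmat A = r2.fwd(c2.fwd(r1.fwd(c1.fwd(fmat(x)))));
    cam_A = A;
    fmat flat = vectorise(A).t();
    fmat hcur = drop.fwd(r3.fwd(fc1.fwd(flat)), train, rng);
    return fc2.fwd(hcur)(0, 0);
  }
  void bwd(float gy) override {
    fmat g(1, 1); g(0, 0) = gy;
    fmat gf = r3.bwd(drop.bwd(fc2.bwd(g)));
    fmat gflat = fc1.bwd(gf);
    fmat gA = reshape(gflat.t(), L, 256);
    cam_G = gA;
    in_grad = c1.bwd(r1.bwd(c2.bwd(r2.bwd(gA))));
  }
};

struct TransformerCore {
  std::vector<Encoder> enc;
  Lin head;  // fully connected regression head on the flattened tokens
  fmat pe;
  int L = 0, d = 0;
  void init(int L_, int d_, int h, int ff, int nlayers, RNG& rng) {
    L = L_; d = d_;
    enc.resize(nlayers);
    for (auto& e : enc) e.init(d, h, ff, rng);
    head.init(L * d, 1, rng);
    pe = make_pe(L, d);
  }
  float fwd(fmat x) {
    x += pe;
    for (auto& e : enc) x = e.fwd(x);
    return head.fwd(fmat(vectorise(x).t()))(0, 0);
  }
  fmat bwd(float gy) {
    fmat g(1, 1); g(0, 0) = gy;
    fmat gx = reshape(head.bwd(g).t(), L, d);
    for (int i = enc.size() - 1; i >= 0; --i) gx = enc[i].bwd(gx);
    return gx;  // additive PE passes the gradient through unchanged
  }
  void reg(ParamList& ps) {
    for (size_t i = 0; i < enc.size(); ++i)
      enc[i].reg(ps, "enc" + std::to_string(i + 1));
    head.reg(ps, "head");
  }
};

struct TransformerModel : Model {
  Lin lift;
  TransformerCore core;
  TransformerModel(int L, RNG& rng) {
    lift.init(1, 256, rng);
    core.init(L, 256, 4, 1024, 6, rng);
    lift.reg(ps, "lift");
    core.reg(ps);
  }
  float fwd(const fvec& x, bool, RNG&) override {
    return core.fwd(lift.fwd(fmat(x)));
  }
  void bwd(float gy) override { in_grad = lift.bwd(core.bwd(gy)); }
};

struct CNNTransformerModel : Model {
  Conv3 c1, c2;
  ReLU r1, r2;
  TransformerCore core;
  CNNTransformerModel(int L, RNG& rng) {
    has_conv = true;
    c1.init(1, 128, rng); c2.init(128, 256, rng);
    core.init(L, 256, 4, 1024, 6, rng);
    c1.reg(ps, "conv1"); c2.reg(ps, "conv2");
    core.reg(ps);
  }
  float fwd(const fvec& x, bool, RNG&) override {
    fmat A = r2.fwd(c2.fwd(r1.fwd(c1.fwd(fmat(x)))));
    cam_A = A;
    return core.fwd(A);
  }
  void bwd(float gy) override {
    fmat gA = core.bwd(gy);
    cam_G = gA;
    in_grad = c1.bwd(r1.bwd(c2.bwd(r2.bwd(gA))));
  }
};

struct LSTMModel : Model {
  Lin lift, head;
  LSTM lstm;
  LSTMModel(int L, RNG& rng) {
    lift.init(L, 1024, rng);
    lstm.init(1024, 1024, rng);
    head.init(1024, 1, rng);
    lift.reg(ps, "lift"); lstm.reg(ps, "lstm"); head.reg(ps, "head");
  }
  float fwd(const fvec& x, bool, RNG&) override {
    fmat lifted = lift.fwd(fmat(x).t());      // 1 x 1024
    frowvec h = lstm.fwd(lifted);             // single-step recurrence
    return head.fwd(fmat(h))(0, 0);
  }
  void bwd(float gy) override {
    fmat g(1, 1); g(0, 0) = gy;
    fmat gh = head.bwd(g);
    fmat gx = lstm.bwd(gh.row(0));
    in_grad = lift.bwd(gx).t();
  }
};

struct CNNLSTMModel : Model {
  Conv3 c1, c2, c3;
  ReLU r1, r2, r3;
  LSTM lstm;
  Lin head;
  CNNLSTMModel(int, RNG& rng) {
    has_conv = true;
    c1.init(1, 128, rng); c2.init(128, 256, rng); c3.init(256, 512, rng);
    lstm.init(512, 256, rng);
    head.init(256, 1, rng);
    c1.reg(ps, "conv1"); c2.reg(ps, "conv2"); c3.reg(ps, "conv3");
    lstm.reg(ps, "lstm"); head.reg(ps, "head");
  }
  float fwd(const fvec& x, bool, RNG&) override {
    fmat A = r3.fwd(c3.fwd(r2.fwd(c2.fwd(r1.fwd(c1.fwd(fmat(x)))))));
    cam_A = A;
    frowvec h = lstm.fwd(A);
    return head.fwd(fmat(h))(0, 0);
  }
  void bwd(float gy) override {
    fmat g(1, 1); g(0, 0) = gy;
    fmat gh = head.bwd(g);
    fmat gA = lstm.bwd(gh.row(0));
    cam_G = gA;
    in_grad = c1.bwd(r1.bwd(c2.bwd(r2.bwd(c3.bwd(r3.bwd(gA))))));
  }
};

static Model* make_model(int arch, int L, RNG& rng) {
  switch (arch) {
    case 1: return new CNNModel(L, rng);
    case 2: return new LSTMModel(L, rng);
    case 3: return new CNNLSTMModel(L, rng);
    case 4: return new TransformerModel(L, rng);
    case 5: return new CNNTransformerModel(L, rng);
  }
  Rcpp::stop("unknown architecture id %d", arch);
  return nullptr;
}

// ---- weight (de)serialisation -------------------------------------------

static Rcpp::List export_weights(const Model& m) {
  Rcpp::List out(m.ps.size());
  Rcpp::CharacterVector nm(m.ps.size());
  for (size_t i = 0; i < m.ps.size(); ++i) {
    nm[i] = m.ps[i].first;
    out[i] = Rcpp::wrap(conv_to<mat>::from(m.ps[i].second->w));
  }
  out.attr("names") = nm;
  return out;
}

static void import_weights(Model& m, const Rcpp::List& weights) {
  if ((size_t)weights.size() != m.ps.size())
    Rcpp::stop("weight list has %d entries; model expects %d",
               (int)weights.size(), (int)m.ps.size());
  for (size_t i = 0; i < m.ps.size(); ++i) {
    mat w = Rcpp::as<mat>(weights[i]);
    if (w.n_rows != m.ps[i].second->w.n_rows ||
        w.n_cols != m.ps[i].second->w.n_cols)
      Rcpp::stop("weight `%s` has wrong shape", m.ps[i].first.c_str());
    m.ps[i].second->w = conv_to<fmat>::from(w);
  }
}

// ---- exported interface -------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_nn_init(int arch, int L, int seed) {
  RNG rng((uint32_t)seed);
  std::unique_ptr<Model> m(make_model(arch, L, rng));
  return export_weights(*m);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_nn_predict(int arch, Rcpp::List weights,
                                   Rcpp::NumericMatrix X) {
  enable_ftz();
  RNG rng(0);
  fmat Xf = conv_to<fmat>::from(Rcpp::as<mat>(X));
  std::unique_ptr<Model> m(make_model(arch, Xf.n_cols, rng));
  import_weights(*m, weights);
  Rcpp::NumericVector out(Xf.n_rows);
  for (uword i = 0; i < Xf.n_rows; ++i)
    out[i] = m->fwd(Xf.row(i).t(), false, rng);
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_nn_train(int arch, Rcpp::List weights, Rcpp::NumericMatrix X,
                        Rcpp::NumericVector y, Rcpp::NumericMatrix Xval,
                        Rcpp::NumericVector yval, double lr, int batch,
                        int max_epochs, int patience, int seed,
                        double weight_decay, double max_grad_norm,
                        int warmup_epochs) {
  enable_ftz();
  fmat Xf = conv_to<fmat>::from(Rcpp::as<mat>(X));
  fmat Xv = conv_to<fmat>::from(Rcpp::as<mat>(Xval));
  fvec yf = conv_to<fvec>::from(Rcpp::as<vec>(y));
  fvec yv = conv_to<fvec>::from(Rcpp::as<vec>(yval));
  int N = Xf.n_rows, L = Xf.n_cols;
  RNG rng((uint32_t)seed);
  std::unique_ptr<Model> m(make_model(arch, L, rng));
  import_weights(*m, weights);

  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  long step = 0;
  std::vector<double> hist_train, hist_val;
  double best_val = datum::inf;
  int best_epoch = 0, wait = 0;
  std::vector<fmat> best_w(m->ps.size());
  for (size_t i = 0; i < m->ps.size(); ++i) best_w[i] = m->ps[i].second->w;

  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  long steps_per_epoch = (N + batch - 1) / batch;
  long warm_steps = warmup_epochs * steps_per_epoch;

  for (int epoch = 1; epoch <= max_epochs; ++epoch) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epoch_se = 0.0;
    for (int s = 0; s < N; s += batch) {
      int mb = std::min(batch, N - s);
      for (auto& pr : m->ps) pr.second->g.zeros();
      for (int k = 0; k < mb; ++k) {
        const fvec xrow = Xf.row(idx[s + k]).t();
        float pred = m->fwd(xrow, true, rng);
        float err = pred - yf(idx[s + k]);
        epoch_se += (double)err * err;
        m->bwd(2.0f * err / mb);
      }
      ++step;
      // linear learning-rate warmup over the first warmup_epochs
      double lr_t = warm_steps > 0 && step < warm_steps
                        ? lr * (double)step / (double)warm_steps
                        : lr;
      float c1 = 1.0f - std::pow(b1, (float)step);
      float c2 = 1.0f - std::pow(b2, (float)step);
      if (max_grad_norm > 0) {  // global-norm gradient clipping
        double sq = 0.0;
        for (auto& pr : m->ps)
          sq += (double)accu(square(conv_to<fvec>::from(
              vectorise(pr.second->g))));
        double gnorm = std::sqrt(sq) / mb;
        if (gnorm > max_grad_norm) {
          float sc = (float)(max_grad_norm / gnorm);
          for (auto& pr : m->ps) pr.second->g *= sc;
        }
      }
      for (auto& pr : m->ps) {
        P& p = *pr.second;
        p.g /= (float)mb;
        p.m = b1 * p.m + (1.0f - b1) * p.g;
        p.v = b2 * p.v + (1.0f - b2) * (p.g % p.g);
        p.w -= (float)lr_t *
               ((p.m / c1) / (sqrt(p.v / c2) + eps) +
                (float)weight_decay * p.w);
      }
    }
    double train_mse = epoch_se / N;
    if (!std::isfinite(train_mse))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", epoch);
    hist_train.push_back(train_mse);

    double val_se = 0.0;
    for (uword i = 0; i < Xv.n_rows; ++i) {
      float pred = m->fwd(Xv.row(i).t(), false, rng);
      float err = pred - yv(i);
      val_se += (double)err * err;
    }
    double val_rmse = std::sqrt(val_se / Xv.n_rows);
    hist_val.push_back(val_rmse);

    if (val_rmse < best_val) {
      best_val = val_rmse;
      best_epoch = epoch;
      for (size_t i = 0; i < m->ps.size(); ++i)
        best_w[i] = m->ps[i].second->w;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }

  for (size_t i = 0; i < m->ps.size(); ++i) m->ps[i].second->w = best_w[i];
  return Rcpp::List::create(
      Rcpp::Named("weights") = export_weights(*m),
      Rcpp::Named("train_mse") = hist_train,
      Rcpp::Named("val_rmse") = hist_val,
      Rcpp::Named("best_epoch") = best_epoch);
}

// [[Rcpp::export]]
Rcpp::List cpp_nn_gradcam(int arch, Rcpp::List weights,
                          Rcpp::NumericMatrix X) {
  RNG rng(0);
  fmat Xf = conv_to<fmat>::from(Rcpp::as<mat>(X));
  std::unique_ptr<Model> m(make_model(arch, Xf.n_cols, rng));
  if (!m->has_conv)
    Rcpp::stop("Grad-CAM requires a model with a convolutional front-end");
  import_weights(*m, weights);
  Rcpp::List As(Xf.n_rows), Gs(Xf.n_rows);
  for (uword i = 0; i < Xf.n_rows; ++i) {
    for (auto& pr : m->ps) pr.second->g.zeros();
    m->fwd(Xf.row(i).t(), false, rng);
    m->bwd(1.0f);
    As[i] = Rcpp::wrap(conv_to<mat>::from(m->cam_A));
    Gs[i] = Rcpp::wrap(conv_to<mat>::from(m->cam_G));
  }
  return Rcpp::List::create(Rcpp::Named("A") = As, Rcpp::Named("G") = Gs);
}

// [[Rcpp::export]]
Rcpp::CharacterVector cpp_nn_param_names(int arch, int L) {
  RNG rng(0);
  std::unique_ptr<Model> m(make_model(arch, L, rng));
  Rcpp::CharacterVector nm(m->ps.size());
  for (size_t i = 0; i < m->ps.size(); ++i) nm[i] = m->ps[i].first;
  return nm;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_nn_inputgrad(int arch, Rcpp::List weights,
                                     Rcpp::NumericVector x) {
  RNG rng(0);
  fvec xf = conv_to<fvec>::from(Rcpp::as<vec>(x));
  std::unique_ptr<Model> m(make_model(arch, xf.n_elem, rng));
  import_weights(*m, weights);
  for (auto& pr : m->ps) pr.second->g.zeros();
  m->fwd(xf, false, rng);
  m->bwd(1.0f);
  return Rcpp::wrap(conv_to<vec>::from(vectorise(m->in_grad)));
}
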