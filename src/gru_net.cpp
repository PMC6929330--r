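// Convolutional-recurrent network over PSSM profiles.
//
// Layout: input profile (N x 20) -> transpose to channels x length ->
// [conv1d -> ReLU -> pool]_1 -> [conv1d -> ReLU -> pool]_2 (length N
// becomes floor(floor(N/3)/3) with the default kernel=stride=3 pooling)
// -> stacked GRU over the remaining steps -> final hidden state ->
// fully connected + ReLU (+ inverted dropout in training) -> sigmoid.
//
// Training is plain backpropagation-through-time with Adam; all
// randomness (shuffling, dropout) comes from an explicit 64-bit
// generator seeded by the caller, so runs are reproducible bit for bit.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct NetConfig {
  int in_ch, c1, c2, kernel, pool_k, pool_s, hidden, layers, fc;
  double dropout;
  bool pool_max, squash;
};

static NetConfig parse_config(const Rcpp::List& cfg) {
  NetConfig c;
  Rcpp::IntegerVector filt = cfg["conv_filters"];
  c.in_ch = Rcpp::as<int>(cfg["input_channels"]);
  c.c1 = filt[0];
  c.c2 = filt[1];
  c.kernel = Rcpp::as<int>(cfg["conv_kernel"]);
  c.pool_k = Rcpp::as<int>(cfg["pool_kernel"]);
  c.pool_s = Rcpp::as<int>(cfg["pool_stride"]);
  c.hidden = Rcpp::as<int>(cfg["gru_hidden"]);
  c.layers = Rcpp::as<int>(cfg["gru_layers"]);
  c.fc = Rcpp::as<int>(cfg["fc_size"]);
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  c.pool_max = Rcpp::as<std::string>(cfg["pool"]) == "max";
  c.squash = Rcpp::as<bool>(cfg["input_squash"]);
  if (c.kernel % 2 == 0) Rcpp::stop("conv_kernel must be odd");
  return c;
}

// Parameters live in a flat vector of matrices in a fixed order:
// [Wc1, bc1, Wc2, bc2, {Wiz,Wir,Win,Whz,Whr,Whn,biz,bir,bin,bhz,bhr,bhn}
//  per GRU layer, Wf, bf, Wo, bo]; biases are column vectors, Wo is 1 x F
// and bo is 1 x 1.
typedef std::vector<mat> ParamSet;

static const char* GRU_NAMES[12] = {"W_iz", "W_ir", "W_in", "W_hz", "W_hr",
                                    "W_hn", "b_iz", "b_ir", "b_in", "b_hz",
                                    "b_hr", "b_hn"};

static ParamSet params_from_list(const Rcpp::List& p, const NetConfig& cfg) {
  ParamSet ps;
  ps.push_back(Rcpp::as<mat>(p["conv1_W"]));
  ps.push_back(Rcpp::as<mat>(p["conv1_b"]));
  ps.push_back(Rcpp::as<mat>(p["conv2_W"]));
  ps.push_back(Rcpp::as<mat>(p["conv2_b"]));
  Rcpp::List gru = p["gru"];
  if ((int)gru.size() != cfg.layers)
    Rcpp::stop("params have %d GRU layers, config says %d",
               (int)gru.size(), cfg.layers);
  for (int l = 0; l < cfg.layers; ++l) {
    Rcpp::List gl = gru[l];
    for (int j = 0; j < 12; ++j) ps.push_back(Rcpp::as<mat>(gl[GRU_NAMES[j]]));
  }
  ps.push_back(Rcpp::as<mat>(p["fc_W"]));
  ps.push_back(Rcpp::as<mat>(p["fc_b"]));
  ps.push_back(Rcpp::as<mat>(p["out_W"]));
  ps.push_back(Rcpp::as<mat>(p["out_b"]));
  return ps;
}

static Rcpp::List params_to_list(const ParamSet& ps, const NetConfig& cfg) {
  Rcpp::List gru(cfg.layers);
  for (int l = 0; l < cfg.layers; ++l) {
    Rcpp::List gl;
    for (int j = 0; j < 12; ++j)
      gl[GRU_NAMES[j]] = Rcpp::wrap(ps[4 + 12 * l + j]);
    gru[l] = gl;
  }
  return Rcpp::List::create(
      Rcpp::Named("conv1_W") = Rcpp::wrap(ps[0]),
      Rcpp::Named("conv1_b") = Rcpp::wrap(ps[1]),
      Rcpp::Named("conv2_W") = Rcpp::wrap(ps[2]),
      Rcpp::Named("conv2_b") = Rcpp::wrap(ps[3]),
      Rcpp::Named("gru") = gru,
      Rcpp::Named("fc_W") = Rcpp::wrap(ps[4 + 12 * cfg.layers]),
      Rcpp::Named("fc_b") = Rcpp::wrap(ps[5 + 12 * cfg.layers]),
      Rcpp::Named("out_W") = Rcpp::wrap(ps[6 + 12 * cfg.layers]),
      Rcpp::Named("out_b") = Rcpp::wrap(ps[7 + 12 * cfg.layers]));
}

static ParamSet zeros_like(const ParamSet& ps) {
  ParamSet z;
  z.reserve(ps.size());
  for (const mat& m : ps) z.push_back(zeros<mat>(m.n_rows, m.n_cols));
  return z;
}

// im2col with zero padding (k-1)/2: column i stacks the k-wide window of
// A centred at i, channel-major within the window.
static mat im2col(const mat& A, int k) {
  const int ch = A.n_rows, n = A.n_cols, pad = (k - 1) / 2;
  mat P(ch * k, n, fill::zeros);
  for (int off = 0; off < k; ++off) {
    const int shift = off - pad;  // source column = i + shift
    const int lo = std::max(0, -shift), hi = std::min(n, n - shift);
    if (lo < hi)
      P.rows(off * ch, (off + 1) * ch - 1).cols(lo, hi - 1) =
          A.cols(lo + shift, hi - 1 + shift);
  }
  return P;
}

static void col2im_add(mat& dA, const mat& dP, int k) {
  const int ch = dA.n_rows, n = dA.n_cols, pad = (k - 1) / 2;
  for (int off = 0; off < k; ++off) {
    const int shift = off - pad;
    const int lo = std::max(0, -shift), hi = std::min(n, n - shift);
    if (lo < hi)
      dA.cols(lo + shift, hi - 1 + shift) +=
          dP.rows(off * ch, (off + 1) * ch - 1).cols(lo, hi - 1);
  }
}

// Pooling over complete windows only: out length (n - pool_k)/pool_s + 1.
static mat pool_forward(const mat& A, const NetConfig& cfg, umat& argmax) {
  const int ch = A.n_rows, n = A.n_cols;
  if (n < cfg.pool_k) Rcpp::stop("sequence too short for pooling");
  const int m = (n - cfg.pool_k) / cfg.pool_s + 1;
  mat O(ch, m);
  if (cfg.pool_max) argmax.set_size(ch, m);
  for (int j = 0; j < m; ++j) {
    const int s = j * cfg.pool_s;
    if (cfg.pool_max) {
      for (int c = 0; c < ch; ++c) {
        uword idx;
        const rowvec win = A(span(c, c), span(s, s + cfg.pool_k - 1));
        O(c, j) = win.max(idx);
        argmax(c, j) = s + idx;
      }
    } else {
      O.col(j) = mean(A.cols(s, s + cfg.pool_k - 1), 1);
    }
  }
  return O;
}

static void pool_backward(mat& dA, const mat& dO, const NetConfig& cfg,
                          const umat& argmax) {
  const int ch = dA.n_rows, m = dO.n_cols;
  for (int j = 0; j < m; ++j) {
    const int s = j * cfg.pool_s;
    if (cfg.pool_max) {
      for (int c = 0; c < ch; ++c) dA(c, argmax(c, j)) += dO(c, j);
    } else {
      for (int off = 0; off < cfg.pool_k; ++off)
        dA.col(s + off) += dO.col(j) / cfg.pool_k;
    }
  }
}

struct GruCache {
  mat X;                     // input sequence, D x T
  mat Z, R, Nn, H, HNpre;    // gates / states, hidden x T
};

struct Cache {
  mat A0, P1, Z1, O1, P2, Z2, S;
  umat idx1, idx2;
  std::vector<GruCache> gru;
  vec hT, fc_pre, fc_act, mask;
  double out_z, p;
};

static double uniform01(std::mt19937_64& rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0);  // 53-bit mantissa
}

static double forward(const mat& X, const ParamSet& ps, const NetConfig& cfg,
                      bool training, std::mt19937_64& rng, Cache& c) {
  if ((int)X.n_cols != cfg.in_ch)
    Rcpp::stop("profile must have %d columns, got %d", cfg.in_ch,
               (int)X.n_cols);
  c.A0 = X.t();
  if (cfg.squash) c.A0 = 1.0 / (1.0 + exp(-c.A0));

  c.P1 = im2col(c.A0, cfg.kernel);
  c.Z1 = ps[0] * c.P1;
  c.Z1.each_col() += ps[1].col(0);
  mat A1 = c.Z1 % conv_to<mat>::from(c.Z1 > 0);  // ReLU
  c.O1 = pool_forward(A1, cfg, c.idx1);

  c.P2 = im2col(c.O1, cfg.kernel);
  c.Z2 = ps[2] * c.P2;
  c.Z2.each_col() += ps[3].col(0);
  mat A2 = c.Z2 % conv_to<mat>::from(c.Z2 > 0);  // ReLU
  c.S = pool_forward(A2, cfg, c.idx2);

  const int T = c.S.n_cols, H = cfg.hidden;
  c.gru.assign(cfg.layers, GruCache());
  mat Xseq = c.S;
  for (int l = 0; l < cfg.layers; ++l) {
    const mat& Wiz = ps[4 + 12 * l + 0], &Wir = ps[4 + 12 * l + 1],
               &Win = ps[4 + 12 * l + 2], &Whz = ps[4 + 12 * l + 3],
               &Whr = ps[4 + 12 * l + 4], &Whn = ps[4 + 12 * l + 5];
    const vec biz = ps[4 + 12 * l + 6].col(0), bir = ps[4 + 12 * l + 7].col(0),
              bin = ps[4 + 12 * l + 8].col(0), bhz = ps[4 + 12 * l + 9].col(0),
              bhr = ps[4 + 12 * l + 10].col(0),
              bhn = ps[4 + 12 * l + 11].col(0);
    GruCache& g = c.gru[l];
    g.X = Xseq;
    g.Z.set_size(H, T); g.R.set_size(H, T);
    g.Nn.set_size(H, T); g.H.set_size(H, T); g.HNpre.set_size(H, T);
    vec h(H, fill::zeros);
    for (int t = 0; t < T; ++t) {
      const vec xt = g.X.col(t);
      const vec z = 1.0 / (1.0 + exp(-(Wiz * xt + biz + Whz * h + bhz)));
      const vec r = 1.0 / (1.0 + exp(-(Wir * xt + bir + Whr * h + bhr)));
      const vec hn = Whn * h + bhn;
      const vec n = tanh(Win * xt + bin + r % hn);
      h = (1.0 - z) % n + z % h;
      g.Z.col(t) = z; g.R.col(t) = r; g.Nn.col(t) = n;
      g.HNpre.col(t) = hn; g.H.col(t) = h;
    }
    Xseq = g.H;
  }
  c.hT = Xseq.col(T - 1);

  const int base = 4 + 12 * cfg.layers;
  c.fc_pre = ps[base] * c.hT + ps[base + 1].col(0);
  c.fc_act = c.fc_pre % conv_to<vec>::from(c.fc_pre > 0);  // ReLU
  c.mask.set_size(cfg.fc);
  if (training && cfg.dropout > 0) {
    const double keep = 1.0 - cfg.dropout;
    for (int i = 0; i < cfg.fc; ++i)
      c.mask(i) = (uniform01(rng) < keep) ? 1.0 / keep : 0.0;
  } else {
    c.mask.ones();
  }
  const vec fcd = c.fc_act % c.mask;
  c.out_z = dot(ps[base + 2].row(0).t(), fcd) + ps[base + 3](0, 0);
  c.p = 1.0 / (1.0 + std::exp(-c.out_z));
  return c.p;
}

// dz = dL/d(out_z); gradients are accumulated (+=) into `g`.
static void backward(const Cache& c, const ParamSet& ps, const NetConfig& cfg,
                     double dz, ParamSet& g) {
  const int base = 4 + 12 * cfg.layers;
  const vec fcd = c.fc_act % c.mask;
  g[base + 2].row(0) += dz * fcd.t();
  g[base + 3](0, 0) += dz;
  vec dfc = (ps[base + 2].row(0).t() * dz) % c.mask;
  vec dfc_pre = dfc % conv_to<vec>::from(c.fc_pre > 0);
  g[base] += dfc_pre * c.hT.t();
  g[base + 1].col(0) += dfc_pre;

  const int T = c.S.n_cols, H = cfg.hidden;
  // gradient flowing into each layer's output sequence; top layer gets a
  // contribution only at the final step
  mat dH(H, T, fill::zeros);
  dH.col(T - 1) = ps[base].t() * dfc_pre;
  mat dX;  // becomes dH of the layer below / d(front-end output)
  for (int l = cfg.layers - 1; l >= 0; --l) {
    const GruCache& gc = c.gru[l];
    const mat& Wiz = ps[4 + 12 * l + 0], &Wir = ps[4 + 12 * l + 1],
               &Win = ps[4 + 12 * l + 2], &Whz = ps[4 + 12 * l + 3],
               &Whr = ps[4 + 12 * l + 4], &Whn = ps[4 + 12 * l + 5];
    mat& dWiz = g[4 + 12 * l + 0]; mat& dWir = g[4 + 12 * l + 1];
    mat& dWin = g[4 + 12 * l + 2]; mat& dWhz = g[4 + 12 * l + 3];
    mat& dWhr = g[4 + 12 * l + 4]; mat& dWhn = g[4 + 12 * l + 5];
    dX.zeros(gc.X.n_rows, T);
    vec dh_carry(H, fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      const vec z = gc.Z.col(t), r = gc.R.col(t), n = gc.Nn.col(t),
                hn = gc.HNpre.col(t);
      const vec h_prev =
          (t > 0) ? vec(gc.H.col(t - 1)) : vec(H, fill::zeros);
      const vec dh = dH.col(t) + dh_carry;
      const vec dz_pre = (dh % (h_prev - n)) % z % (1.0 - z);
      const vec dn_pre = (dh % (1.0 - z)) % (1.0 - n % n);
      const vec dhn = dn_pre % r;
      const vec dr_pre = (dn_pre % hn) % r % (1.0 - r);
      const vec xt = gc.X.col(t);
      dWiz += dz_pre * xt.t(); dWhz += dz_pre * h_prev.t();
      dWir += dr_pre * xt.t(); dWhr += dr_pre * h_prev.t();
      dWin += dn_pre * xt.t(); dWhn += dhn * h_prev.t();
      g[4 + 12 * l + 6].col(0) += dz_pre;   // b_iz
      g[4 + 12 * l + 7].col(0) += dr_pre;   // b_ir
      g[4 + 12 * l + 8].col(0) += dn_pre;   // b_in
      g[4 + 12 * l + 9].col(0) += dz_pre;   // b_hz
      g[4 + 12 * l + 10].col(0) += dr_pre;  // b_hr
      g[4 + 12 * l + 11].col(0) += dhn;     // b_hn
      dX.col(t) = Wiz.t() * dz_pre + Wir.t() * dr_pre + Win.t() * dn_pre;
      dh_carry = dh % z + Whz.t() * dz_pre + Whr.t() * dr_pre + Whn.t() * dhn;
    }
    dH = dX;
  }

  // front-end: dX is d(pooled conv2 output), c2 x T
  mat dA2(c.Z2.n_rows, c.Z2.n_cols, fill::zeros);
  pool_backward(dA2, dX, cfg, c.idx2);
  mat dZ2 = dA2 % conv_to<mat>::from(c.Z2 > 0);
  g[2] += dZ2 * c.P2.t();
  g[3].col(0) += sum(dZ2, 1);
  mat dO1(c.O1.n_rows, c.O1.n_cols, fill::zeros);
  col2im_add(dO1, ps[2].t() * dZ2, cfg.kernel);
  mat dA1(c.Z1.n_rows, c.Z1.n_cols, fill::zeros);
  pool_backward(dA1, dO1, cfg, c.idx1);
  mat dZ1 = dA1 % conv_to<mat>::from(c.Z1 > 0);
  g[0] += dZ1 * c.P1.t();
  g[1].col(0) += sum(dZ1, 1);
}

static double sample_loss(double p, double y, double w) {
  const double eps = 1e-7;
  const double pc = std::min(1.0 - eps, std::max(eps, p));
  return -w * (y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_predict(Rcpp::List profiles, Rcpp::List params,
                                Rcpp::List config) {
  NetConfig cfg = parse_config(config);
  ParamSet ps = params_from_list(params, cfg);
  std::mt19937_64 rng(0);
  const int n = profiles.size();
  Rcpp::NumericVector out(n);
  Cache c;
  for (int i = 0; i < n; ++i)
    out[i] = forward(Rcpp::as<mat>(profiles[i]), ps, cfg, false, rng, c);
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_front_end(const arma::mat& profile, Rcpp::List params,
                        Rcpp::List config) {
  NetConfig cfg = parse_config(config);
  ParamSet ps = params_from_list(params, cfg);
  std::mt19937_64 rng(0);
  Cache c;
  forward(profile, ps, cfg, false, rng, c);
  return c.S.t();  // steps x channels
}

// Loss and exact gradients for one sample (no dropout): the hook used by
// finite-difference checks.
// [[Rcpp::export]]
Rcpp::List cpp_loss_grad(const arma::mat& profile, double y, double w,
                         Rcpp::List params, Rcpp::List config) {
  NetConfig cfg = parse_config(config);
  ParamSet ps = params_from_list(params, cfg);
  ParamSet g = zeros_like(ps);
  std::mt19937_64 rng(0);
  Cache c;
  const double p = forward(profile, ps, cfg, false, rng, c);
  backward(c, ps, cfg, w * (p - y), g);
  return Rcpp::List::create(Rcpp::Named("loss") = sample_loss(p, y, w),
                            Rcpp::Named("prob") = p,
                            Rcpp::Named("grads") = params_to_list(g, cfg));
}

// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List profiles, Rcpp::NumericVector y,
                     Rcpp::NumericVector w, Rcpp::List params,
                     Rcpp::List config, int epochs, double lr, double beta1,
                     double beta2, double adam_eps, int batch_size,
                     int seed) {
  NetConfig cfg = parse_config(config);
  ParamSet ps = params_from_list(params, cfg);
  ParamSet grad = zeros_like(ps), m = zeros_like(ps), v = zeros_like(ps);
  const int n = profiles.size();
  std::vector<mat> xs(n);
  for (int i = 0; i < n; ++i) xs[i] = Rcpp::as<mat>(profiles[i]);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  Rcpp::NumericVector history(epochs);
  Cache c;
  long step = 0;
  for (int e = 0; e < epochs; ++e) {
    // Fisher-Yates with the explicit generator (std::shuffle semantics
    // vary across standard libraries)
    for (int i = n - 1; i > 0; --i) {
      const int j = static_cast<int>(rng() % static_cast<uint64_t>(i + 1));
      std::swap(order[i], order[j]);
    }
    double epoch_loss = 0.0;
    int pos = 0;
    while (pos < n) {
      const int bn = std::min(batch_size, n - pos);
      for (mat& gm : grad) gm.zeros();
      for (int b = 0; b < bn; ++b) {
        const int i = order[pos + b];
        const double p = forward(xs[i], ps, cfg, true, rng, c);
        epoch_loss += sample_loss(p, y[i], w[i]);
        backward(c, ps, cfg, w[i] * (p - y[i]) / bn, grad);
      }
      ++step;
      const double bc1 = 1.0 - std::pow(beta1, (double)step);
      const double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t k = 0; k < ps.size(); ++k) {
        m[k] = beta1 * m[k] + (1.0 - beta1) * grad[k];
        v[k] = beta2 * v[k] + (1.0 - beta2) * square(grad[k]);
        ps[k] -= lr * (m[k] / bc1) / (sqrt(v[k] / bc2) + adam_eps);
      }
      pos += bn;
    }
    history[e] = epoch_loss / n;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = params_to_list(ps, cfg),
                            Rcpp::Named("history") = history);
}
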