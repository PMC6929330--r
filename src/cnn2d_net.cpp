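// 2-D CNN comparator over the 20 x 20 summed-PSSM matrix (one channel):
// valid k x k convolution -> ReLU -> 2 x 2 max pooling -> fully connected
// sigmoid output, trained with Adam on weighted binary cross-entropy.
// Inputs arrive as n x 400 rows (row-major 20 x 20 images), already
// standardized by the caller. Each image's patch matrix (im2col) is
// precomputed once, so the convolution is a single BLAS product; the
// backward pass exploits the sparsity left by max pooling.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Cnn2d {
  mat W;    // F x k*k
  vec b;    // F
  vec Wf;   // F * nq (filter-major: index f * nq + q)
  double bf;
  int k, out, pg, nq, npos;
};

Cnn2d make_net(const Rcpp::List& params, int k) {
  Cnn2d net;
  net.W = Rcpp::as<mat>(params["W"]);
  net.b = Rcpp::as<vec>(params["b"]);
  net.Wf = Rcpp::as<vec>(params["Wf"]);
  net.bf = Rcpp::as<double>(params["bf"]);
  net.k = k;
  net.out = 20 - k + 1;
  net.pg = net.out / 2;
  net.nq = net.pg * net.pg;
  net.npos = net.out * net.out;
  return net;
}

// patch matrix of one image: npos x k*k, conv position p = j*out + i
// (column-major), patch entry m = di*k + dj
mat im2col_one(const rowvec& x, const Cnn2d& net) {
  mat P(net.npos, net.k * net.k);
  for (int j = 0; j < net.out; ++j)
    for (int i = 0; i < net.out; ++i) {
      const int p = j * net.out + i;
      for (int di = 0; di < net.k; ++di)
        for (int dj = 0; dj < net.k; ++dj)
          P(p, di * net.k + dj) = x((i + di) * 20 + (j + dj));
    }
  return P;
}

struct FwdCache {
  mat Z;        // npos x F (pre-ReLU conv)
  mat pooled;   // nq x F (after ReLU + max pool)
  umat argp;    // nq x F winning conv position
  double p;
};

void forward_one(const mat& P, const Cnn2d& net, FwdCache& c) {
  const int F = net.W.n_rows, pg = net.pg, out = net.out;
  c.Z = P * net.W.t();
  c.Z.each_row() += net.b.t();
  c.pooled.set_size(net.nq, F);
  c.argp.set_size(net.nq, F);
  double z_out = net.bf;
  for (int f = 0; f < F; ++f) {
    const double* zf = c.Z.colptr(f);
    for (int b2 = 0; b2 < pg; ++b2)
      for (int a = 0; a < pg; ++a) {
        const int q = b2 * pg + a;
        double best = 0.0;  // ReLU floor: max(0, z) over the window
        int bp = 2 * b2 * out + 2 * a;
        const int p00 = 2 * b2 * out + 2 * a;
        const int cand[4] = {p00, p00 + 1, p00 + out, p00 + out + 1};
        for (int o = 0; o < 4; ++o)
          if (zf[cand[o]] > best) { best = zf[cand[o]]; bp = cand[o]; }
        c.pooled(q, f) = best;
        c.argp(q, f) = bp;
        z_out += net.Wf(f * net.nq + q) * best;
      }
  }
  c.p = 1.0 / (1.0 + std::exp(-z_out));
}

struct Grads {
  mat W; vec b; vec Wf; double bf;
  void zero(const Cnn2d& net) {
    W.zeros(net.W.n_rows, net.W.n_cols);
    b.zeros(net.b.n_elem);
    Wf.zeros(net.Wf.n_elem);
    bf = 0.0;
  }
};

void backward_one(const FwdCache& c, const mat& P, const Cnn2d& net,
                  double dz, Grads& g) {
  const int F = net.W.n_rows, kk = net.k * net.k;
  g.bf += dz;
  for (int f = 0; f < F; ++f) {
    for (int q = 0; q < net.nq; ++q) {
      const double pooled = c.pooled(q, f);
      g.Wf(f * net.nq + q) += dz * pooled;
      if (pooled > 0.0) {  // ReLU open at the max location
        const double dp = dz * net.Wf(f * net.nq + q);
        const int p = c.argp(q, f);
        g.b(f) += dp;
        for (int m = 0; m < kk; ++m) g.W(f, m) += dp * P(p, m);
      }
    }
  }
}

double sample_loss(double p, double y, double w) {
  const double eps = 1e-7;
  const double pc = std::min(1.0 - eps, std::max(eps, p));
  return -w * (y * std::log(pc) + (1.0 - y) * std::log(1.0 - pc));
}

void adam_update(mat& p, mat& m, mat& v, const mat& g, double lr, long t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  p -= lr * (m / (1.0 - std::pow(b1, (double)t))) /
       (sqrt(v / (1.0 - std::pow(b2, (double)t))) + eps);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cnn2d_train(const arma::mat& x, Rcpp::NumericVector y,
                           Rcpp::NumericVector w, Rcpp::List params, int k,
                           int epochs, double lr, int batch_size, int seed) {
  Cnn2d net = make_net(params, k);
  const int n = x.n_rows;
  std::vector<mat> P(n);
  for (int i = 0; i < n; ++i) P[i] = im2col_one(x.row(i), net);

  Grads grad; grad.zero(net);
  mat mW(size(net.W), fill::zeros), vW(size(net.W), fill::zeros);
  mat mb(net.b.n_elem, 1, fill::zeros), vb(net.b.n_elem, 1, fill::zeros);
  mat mWf(net.Wf.n_elem, 1, fill::zeros), vWf(net.Wf.n_elem, 1, fill::zeros);
  mat mbf(1, 1, fill::zeros), vbf(1, 1, fill::zeros);

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  Rcpp::NumericVector history(epochs);
  FwdCache c;
  long step = 0;
  for (int e = 0; e < epochs; ++e) {
    for (int i = n - 1; i > 0; --i) {
      const int j = static_cast<int>(rng() % static_cast<uint64_t>(i + 1));
      std::swap(order[i], order[j]);
    }
    double eloss = 0.0;
    int pos = 0;
    while (pos < n) {
      const int bn = std::min(batch_size, n - pos);
      grad.zero(net);
      for (int bi = 0; bi < bn; ++bi) {
        const int i = order[pos + bi];
        forward_one(P[i], net, c);
        eloss += sample_loss(c.p, y[i], w[i]);
        backward_one(c, P[i], net, w[i] * (c.p - y[i]) / bn, grad);
      }
      ++step;
      mat gb(grad.b), gWf(grad.Wf), gbf(1, 1);
      gbf(0, 0) = grad.bf;
      adam_update(net.W, mW, vW, grad.W, lr, step);
      { mat pb(net.b); adam_update(pb, mb, vb, gb, lr, step);
        net.b = pb.col(0); }
      { mat pWf(net.Wf); adam_update(pWf, mWf, vWf, gWf, lr, step);
        net.Wf = pWf.col(0); }
      { mat pbf(1, 1); pbf(0, 0) = net.bf;
        adam_update(pbf, mbf, vbf, gbf, lr, step); net.bf = pbf(0, 0); }
      pos += bn;
    }
    history[e] = eloss / n;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("params") = Rcpp::List::create(
          Rcpp::Named("W") = Rcpp::wrap(net.W),
          Rcpp::Named("b") = Rcpp::wrap(net.b),
          Rcpp::Named("Wf") = Rcpp::wrap(net.Wf),
          Rcpp::Named("bf") = net.bf),
      Rcpp::Named("history") = history);
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_cnn2d_predict(const arma::mat& x, Rcpp::List params,
                                      int k) {
  Cnn2d net = make_net(params, k);
  const int n = x.n_rows;
  Rcpp::NumericVector out(n);
  FwdCache c;
  for (int i = 0; i < n; ++i) {
    forward_one(im2col_one(x.row(i), net), net, c);
    out[i] = c.p;
  }
  return out;
}
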