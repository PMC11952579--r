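// Small 1-D convolutional network for binary spike-train classification.
//
// Architecture: a stack of valid (unpadded) strided 1-D convolutions with
// ReLU and inverted dropout, global average pooling over time, and a dense
// softmax head, trained with Adam on categorical cross-entropy with
// reduce-on-plateau learning rate and early stopping. All randomness
// (init, shuffling, dropout) comes from an internal mt19937 seeded from R,
// so training is deterministic given the seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace arma;

namespace {

struct Net {
  int n_layers;
  std::vector<int> kernel, stride, chan; // chan[0] = input channels
  std::vector<mat> W;  // (kernel*ch_in) x ch_out
  std::vector<rowvec> b;
  mat Wd;              // ch_last x n_classes
  rowvec bd;
  std::vector<int> len; // len[0] = input length, len[l] after layer l
};

int out_len(int len, int k, int s) { return (len - k) / s + 1; }

void build_lengths(Net &net) {
  for (int l = 0; l < net.n_layers; ++l) {
    int ol = out_len(net.len[l], net.kernel[l], net.stride[l]);
    if (ol < 1) Rcpp::stop("layer %d output length < 1 (input %d, kernel %d)",
                           l + 1, net.len[l], net.kernel[l]);
    net.len[l + 1] = ol;
  }
}

// patch layout: P(j, c*k + r) = A(j*s + r, c)
mat im2col(const mat &A, int k, int s, int ol) {
  int ch = A.n_cols;
  mat P(ol, k * ch);
  for (int c = 0; c < ch; ++c) {
    const double *a = A.colptr(c);
    for (int r = 0; r < k; ++r) {
      double *p = P.colptr(c * k + r);
      for (int j = 0; j < ol; ++j) p[j] = a[j * s + r];
    }
  }
  return P;
}

void col2im_add(mat &dA, const mat &dP, int k, int s) {
  int ol = dP.n_rows, ch = dA.n_cols;
  for (int c = 0; c < ch; ++c) {
    double *a = dA.colptr(c);
    for (int r = 0; r < k; ++r) {
      const double *p = dP.colptr(c * k + r);
      for (int j = 0; j < ol; ++j) a[j * s + r] += p[j];
    }
  }
}

struct Cache {
  std::vector<mat> P, Z, A, mask; // per layer
  rowvec v;                       // pooled
  rowvec logits, probs;
};

// forward one sample; x is len0 x ch0
double forward(const Net &net, const mat &x, int y, bool train,
               double dropout, std::mt19937 &rng, Cache &c) {
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  mat A = x;
  c.P.resize(net.n_layers); c.Z.resize(net.n_layers);
  c.A.resize(net.n_layers); c.mask.resize(net.n_layers);
  for (int l = 0; l < net.n_layers; ++l) {
    mat P = im2col(A, net.kernel[l], net.stride[l], net.len[l + 1]);
    mat Z = P * net.W[l];
    Z.each_row() += net.b[l];
    mat Al = clamp(Z, 0.0, datum::inf);
    if (train && dropout > 0) {
      mat m(Al.n_rows, Al.n_cols);
      for (uword i = 0; i < m.n_elem; ++i)
        m(i) = unif(rng) < dropout ? 0.0 : 1.0 / (1.0 - dropout);
      Al %= m;
      c.mask[l] = std::move(m);
    }
    c.P[l] = std::move(P); c.Z[l] = std::move(Z);
    c.A[l] = Al;
    A = std::move(Al);
  }
  c.v = mean(A, 0);
  c.logits = c.v * net.Wd + net.bd;
  rowvec sh = c.logits - c.logits.max();
  rowvec e = exp(sh);
  c.probs = e / accu(e);
  double p = std::max(c.probs(y), 1e-12);
  return -std::log(p);
}

struct Grads {
  std::vector<mat> dW;
  std::vector<rowvec> db;
  mat dWd;
  rowvec dbd;
  void init(const Net &net) {
    dW.resize(net.n_layers); db.resize(net.n_layers);
    for (int l = 0; l < net.n_layers; ++l) {
      dW[l] = zeros<mat>(net.W[l].n_rows, net.W[l].n_cols);
      db[l] = zeros<rowvec>(net.b[l].n_elem);
    }
    dWd = zeros<mat>(net.Wd.n_rows, net.Wd.n_cols);
    dbd = zeros<rowvec>(net.bd.n_elem);
  }
};

void backward(const Net &net, const mat &x, int y, bool dropped,
              const Cache &c, Grads &g) {
  rowvec dlog = c.probs;
  dlog(y) -= 1.0;
  g.dWd += c.v.t() * dlog;
  g.dbd += dlog;
  rowvec dv = dlog * net.Wd.t();
  // pooled mean -> broadcast
  mat dA = repmat(dv / c.A[net.n_layers - 1].n_rows,
                  c.A[net.n_layers - 1].n_rows, 1);
  for (int l = net.n_layers - 1; l >= 0; --l) {
    if (dropped && c.mask[l].n_elem) dA %= c.mask[l];
    mat dZ = dA % conv_to<mat>::from(c.Z[l] > 0);
    g.dW[l] += c.P[l].t() * dZ;
    g.db[l] += sum(dZ, 0);
    mat dP = dZ * net.W[l].t();
    int prev_len = net.len[l];
    int prev_ch = l == 0 ? net.chan[0] : net.chan[l];
    mat dprev = zeros<mat>(prev_len, prev_ch);
    col2im_add(dprev, dP, net.kernel[l], net.stride[l]);
    dA = std::move(dprev);
  }
  (void)x;
}

struct Adam {
  std::vector<mat> mW, vW;
  std::vector<rowvec> mb, vb;
  mat mWd, vWd;
  rowvec mbd, vbd;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void init(const Net &net) {
    int L = net.n_layers;
    mW.resize(L); vW.resize(L); mb.resize(L); vb.resize(L);
    for (int l = 0; l < L; ++l) {
      mW[l] = zeros<mat>(net.W[l].n_rows, net.W[l].n_cols);
      vW[l] = mW[l];
      mb[l] = zeros<rowvec>(net.b[l].n_elem);
      vb[l] = mb[l];
    }
    mWd = zeros<mat>(net.Wd.n_rows, net.Wd.n_cols); vWd = mWd;
    mbd = zeros<rowvec>(net.bd.n_elem); vbd = mbd;
  }
  template <class M>
  void upd1(M &w, const M &grad, M &m, M &v, double lr) {
    m = b1 * m + (1 - b1) * grad;
    v = b2 * v + (1 - b2) * (grad % grad);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
  void step(Net &net, const Grads &g, double lr, double inv_batch) {
    ++t;
    for (int l = 0; l < net.n_layers; ++l) {
      upd1(net.W[l], mat(g.dW[l] * inv_batch), mW[l], vW[l], lr);
      upd1(net.b[l], rowvec(g.db[l] * inv_batch), mb[l], vb[l], lr);
    }
    upd1(net.Wd, mat(g.dWd * inv_batch), mWd, vWd, lr);
    upd1(net.bd, rowvec(g.dbd * inv_batch), mbd, vbd, lr);
  }
};

Net init_net(int input_len, int in_ch, Rcpp::IntegerVector channels,
             Rcpp::IntegerVector kernels, Rcpp::IntegerVector strides,
             int n_classes, std::mt19937 &rng) {
  Net net;
  net.n_layers = channels.size();
  net.chan.resize(net.n_layers + 1);
  net.chan[0] = in_ch;
  for (int l = 0; l < net.n_layers; ++l) net.chan[l + 1] = channels[l];
  net.kernel.assign(kernels.begin(), kernels.end());
  net.stride.assign(strides.begin(), strides.end());
  net.len.resize(net.n_layers + 1);
  net.len[0] = input_len;
  build_lengths(net);
  std::normal_distribution<double> norm(0.0, 1.0);
  net.W.resize(net.n_layers); net.b.resize(net.n_layers);
  for (int l = 0; l < net.n_layers; ++l) {
    int fan_in = net.kernel[l] * net.chan[l];
    double sdv = std::sqrt(2.0 / fan_in);
    net.W[l].set_size(fan_in, net.chan[l + 1]);
    for (uword i = 0; i < net.W[l].n_elem; ++i) net.W[l](i) = sdv * norm(rng);
    net.b[l] = zeros<rowvec>(net.chan[l + 1]);
  }
  int cl = net.chan[net.n_layers];
  double sdd = std::sqrt(2.0 / (cl + n_classes));
  net.Wd.set_size(cl, n_classes);
  for (uword i = 0; i < net.Wd.n_elem; ++i) net.Wd(i) = sdd * norm(rng);
  net.bd = zeros<rowvec>(n_classes);
  return net;
}

Rcpp::List net_to_list(const Net &net) {
  Rcpp::List W(net.n_layers), b(net.n_layers);
  for (int l = 0; l < net.n_layers; ++l) {
    W[l] = Rcpp::wrap(net.W[l]);
    b[l] = Rcpp::wrap(net.b[l]);
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("b") = b,
    Rcpp::Named("Wd") = Rcpp::wrap(net.Wd), Rcpp::Named("bd") = Rcpp::wrap(net.bd),
    Rcpp::Named("kernel") = net.kernel, Rcpp::Named("stride") = net.stride,
    Rcpp::Named("chan") = net.chan, Rcpp::Named("input_len") = net.len[0]);
}

Net net_from_list(Rcpp::List m) {
  Net net;
  Rcpp::List W = m["W"], b = m["b"];
  net.n_layers = W.size();
  net.kernel = Rcpp::as<std::vector<int>>(m["kernel"]);
  net.stride = Rcpp::as<std::vector<int>>(m["stride"]);
  net.chan = Rcpp::as<std::vector<int>>(m["chan"]);
  net.W.resize(net.n_layers); net.b.resize(net.n_layers);
  for (int l = 0; l < net.n_layers; ++l) {
    net.W[l] = Rcpp::as<mat>(W[l]);
    net.b[l] = Rcpp::as<rowvec>(b[l]);
  }
  net.Wd = Rcpp::as<mat>(m["Wd"]);
  net.bd = Rcpp::as<rowvec>(m["bd"]);
  net.len.resize(net.n_layers + 1);
  net.len[0] = Rcpp::as<int>(m["input_len"]);
  build_lengths(net);
  return net;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(const arma::mat &X, Rcpp::IntegerVector y,
                         int n_classes, Rcpp::IntegerVector channels,
                         Rcpp::IntegerVector kernels,
                         Rcpp::IntegerVector strides,
                         double dropout, double lr, int batch_size,
                         int max_epochs, int patience, int lr_patience,
                         double lr_factor, double min_lr, int seed) {
  int n = X.n_rows, input_len = X.n_cols;
  if ((int)y.size() != n) Rcpp::stop("X/y size mismatch");
  std::mt19937 rng((unsigned)seed);
  Net net = init_net(input_len, 1, channels, kernels, strides, n_classes, rng);
  Adam opt; opt.init(net);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  double best_loss = datum::inf;
  int since_best = 0, since_lr = 0;
  Net best = net;
  std::vector<double> history;
  Cache cache;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double epoch_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int end = std::min(n, start + batch_size);
      Grads g; g.init(net);
      for (int ii = start; ii < end; ++ii) {
        int i = order[ii];
        mat x = X.row(i).t();
        epoch_loss += forward(net, x, y[i], true, dropout, rng, cache);
        backward(net, x, y[i], dropout > 0, cache, g);
      }
      opt.step(net, g, lr, 1.0 / (end - start));
    }
    epoch_loss /= n;
    history.push_back(epoch_loss);
    if (epoch_loss < best_loss - 1e-4) {
      best_loss = epoch_loss;
      best = net;
      since_best = 0; since_lr = 0;
    } else {
      ++since_best; ++since_lr;
      if (since_lr >= lr_patience && lr > min_lr) {
        lr = std::max(min_lr, lr * lr_factor);
        since_lr = 0;
      }
      if (since_best >= patience) break;
    }
  }
  Rcpp::List out = net_to_list(best);
  out["history"] = history;
  out["n_params"] = [&]() {
    long np = 0;
    for (int l = 0; l < best.n_layers; ++l)
      np += best.W[l].n_elem + best.b[l].n_elem;
    return (double)(np + best.Wd.n_elem + best.bd.n_elem);
  }();
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(Rcpp::List model, const arma::mat &X) {
  Net net = net_from_list(model);
  if ((int)X.n_cols != net.len[0])
    Rcpp::stop("input length %d does not match model input %d",
               (int)X.n_cols, net.len[0]);
  int n = X.n_rows, k = net.bd.n_elem;
  mat probs(n, k);
  std::mt19937 rng(0);
  Cache c;
  for (int i = 0; i < n; ++i) {
    mat x = X.row(i).t();
    forward(net, x, 0, false, 0.0, rng, c);
    probs.row(i) = c.probs;
  }
  return probs;
}
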