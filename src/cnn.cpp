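// 1D convolutional regression network: four valid-padding Conv1D layers
// (ReLU), one max-pool after the second, a dense ReLU layer and a linear
// output, trained with Adam on mean squared error. Single precision
// throughout; convolutions are lowered to gemm via im2col.
//
// Activations for a batch of B windows are stored as (len*B x channels)
// matrices whose rows are grouped in per-sample blocks of `len`.

#include <RcppArmadillo.h>
#include <random>
using namespace arma;

// Sliding k-windows of every per-sample block: (len*B x C) ->
// ((len-k+1)*B x k*C). Column c*k+j holds channel c at window offset j.
static fmat im2col_b(const fmat& A, int B, int k) {
  const int L = A.n_rows / B, C = A.n_cols, nL = L - k + 1;
  fmat col(nL * B, k * C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < k; ++j)
        col.submat(b * nL, c * k + j, b * nL + nL - 1, c * k + j) =
            A.submat(b * L + j, c, b * L + j + nL - 1, c);
  return col;
}

// Adjoint of im2col_b: scatter-add window gradients back onto the input.
static fmat col2im_b(const fmat& dcol, int B, int L, int C, int k) {
  const int nL = L - k + 1;
  fmat dA(L * B, C, fill::zeros);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < k; ++j)
        dA.submat(b * L + j, c, b * L + j + nL - 1, c) +=
            dcol.submat(b * nL, c * k + j, b * nL + nL - 1, c * k + j);
  return dA;
}

// Length-wise max pooling by `pool` within each per-sample block;
// records the winning row of each pooled cell for the backward pass.
static fmat maxpool_b(const fmat& A, int B, int pool, umat& win) {
  const int L = A.n_rows / B, C = A.n_cols, pL = L / pool;
  fmat P(pL * B, C);
  win.set_size(pL * B, C);
  for (int b = 0; b < B; ++b)
    for (int r = 0; r < pL; ++r)
      for (int c = 0; c < C; ++c) {
        int base = b * L + r * pool, best = base;
        float v = A(base, c);
        for (int q = 1; q < pool; ++q)
          if (A(base + q, c) > v) { v = A(base + q, c); best = base + q; }
        P(b * pL + r, c) = v;
        win(b * pL + r, c) = best;
      }
  return P;
}

static fmat unpool_b(const fmat& dP, const umat& win, int B, int L) {
  fmat dA(L * B, dP.n_cols, fill::zeros);
  for (uword c = 0; c < dP.n_cols; ++c)
    for (uword r = 0; r < dP.n_rows; ++r)
      dA(win(r, c), c) += dP(r, c);
  return dA;
}

// (len*B x C) block layout -> (B x len*C) rows; flat index = c*len + t.
static fmat flatten_b(const fmat& A, int B) {
  const int L = A.n_rows / B, C = A.n_cols;
  fmat F(B, L * C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < L; ++t) F(b, c * L + t) = A(b * L + t, c);
  return F;
}

static fmat unflatten_b(const fmat& dF, int B, int L, int C) {
  fmat dA(L * B, C);
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c)
      for (int t = 0; t < L; ++t) dA(b * L + t, c) = dF(b, c * L + t);
  return dA;
}

static void relu_(fmat& A) {
  float* a = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i)
    if (a[i] < 0.0f) a[i] = 0.0f;
}

// Zero the gradient wherever the forward activation was clipped.
static void relu_bwd_(fmat& dA, const fmat& A) {
  float* d = dA.memptr();
  const float* a = A.memptr();
  const uword n = A.n_elem;
  for (uword i = 0; i < n; ++i)
    if (a[i] <= 0.0f) d[i] = 0.0f;
}

struct Layer {
  fmat W, mW, vW;
  frowvec b, mb, vb;
  void init(int nin, int nout, float sd, std::mt19937& rng) {
    std::normal_distribution<float> g(0.0f, sd);
    W.set_size(nin, nout);
    for (auto& w : W) w = g(rng);
    b.zeros(nout);
    mW.zeros(nin, nout); vW.zeros(nin, nout);
    mb.zeros(nout); vb.zeros(nout);
  }
};

static void adam_step(Layer& L, const fmat& dW, const frowvec& db,
                      float lr, int t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  const float c1 = 1.0f - std::pow(b1, (float)t);
  const float c2 = 1.0f - std::pow(b2, (float)t);
  L.mW = b1 * L.mW + (1 - b1) * dW;
  L.vW = b2 * L.vW + (1 - b2) * square(dW);
  L.W -= lr * (L.mW / c1) / (sqrt(L.vW / c2) + eps);
  L.mb = b1 * L.mb + (1 - b1) * db;
  L.vb = b2 * L.vb + (1 - b2) * square(db);
  L.b -= lr * (L.mb / c1) / (sqrt(L.vb / c2) + eps);
}

struct Net {
  int input_len, k, pool, f1, f2, f3, f4, dense, l1, l2, lp, l3, l4, flat;
  Layer c1, c2, c3, c4, d1, d2;

  void configure(int input_len_, int k_, int pool_, int f1_, int f2_,
                 int f3_, int f4_, int dense_) {
    input_len = input_len_; k = k_; pool = pool_;
    f1 = f1_; f2 = f2_; f3 = f3_; f4 = f4_; dense = dense_;
    l1 = input_len - k + 1;
    l2 = l1 - k + 1;
    if (l2 % pool != 0) Rcpp::stop("second conv length %d not divisible by pool %d", l2, pool);
    lp = l2 / pool;
    l3 = lp - k + 1;
    l4 = l3 - k + 1;
    if (l4 < 1) Rcpp::stop("input length %d too short for the kernel chain", input_len);
    flat = l4 * f4;
  }

  // Glorot-normal: sd = sqrt(2 / (fan_in + fan_out)); conv fans span the
  // receptive field.
  void init(std::mt19937& rng) {
    c1.init(k * 1,  f1, std::sqrt(2.0f / (k * 1 + k * f1)), rng);
    c2.init(k * f1, f2, std::sqrt(2.0f / (k * f1 + k * f2)), rng);
    c3.init(k * f2, f3, std::sqrt(2.0f / (k * f2 + k * f3)), rng);
    c4.init(k * f3, f4, std::sqrt(2.0f / (k * f3 + k * f4)), rng);
    d1.init(flat, dense, std::sqrt(2.0f / (flat + dense)), rng);
    d2.init(dense, 1, std::sqrt(2.0f / (dense + 1)), rng);
  }

  // Forward pass; intermediates are kept only when training.
  struct Cache {
    fmat col1, a1, col2, a2, p, col3, a3, col4, a4, f, h;
    umat win;
  };

  fvec forward(const fmat& Xb, Cache* cc) const {
    const int B = Xb.n_rows;
    fmat a0(input_len * B, 1);
    for (int b = 0; b < B; ++b)
      for (int t = 0; t < input_len; ++t) a0(b * input_len + t, 0) = Xb(b, t);
    fmat col1 = im2col_b(a0, B, k);
    fmat a1 = col1 * c1.W; a1.each_row() += c1.b; relu_(a1);
    fmat col2 = im2col_b(a1, B, k);
    fmat a2 = col2 * c2.W; a2.each_row() += c2.b; relu_(a2);
    umat win;
    fmat p = maxpool_b(a2, B, pool, win);
    fmat col3 = im2col_b(p, B, k);
    fmat a3 = col3 * c3.W; a3.each_row() += c3.b; relu_(a3);
    fmat col4 = im2col_b(a3, B, k);
    fmat a4 = col4 * c4.W; a4.each_row() += c4.b; relu_(a4);
    fmat f = flatten_b(a4, B);
    fmat h = f * d1.W; h.each_row() += d1.b; relu_(h);
    fvec out = h * d2.W + d2.b(0);
    if (cc) {
      cc->col1 = std::move(col1); cc->a1 = std::move(a1);
      cc->col2 = std::move(col2); cc->a2 = std::move(a2);
      cc->p = std::move(p); cc->win = std::move(win);
      cc->col3 = std::move(col3); cc->a3 = std::move(a3);
      cc->col4 = std::move(col4); cc->a4 = std::move(a4);
      cc->f = std::move(f); cc->h = std::move(h);
    }
    return out;
  }

  void backward(const fmat& Xb, const fvec& dout, const Cache& cc,
                float lr, int step) {
    const int B = Xb.n_rows;
    // output layer
    fmat dW6 = cc.h.t() * dout;
    frowvec db6(1); db6(0) = accu(dout);
    fmat dh = dout * d2.W.t();
    relu_bwd_(dh, cc.h);
    fmat dW5 = cc.f.t() * dh;
    frowvec db5 = sum(dh, 0);
    fmat df = dh * d1.W.t();
    fmat da4 = unflatten_b(df, B, l4, f4);
    relu_bwd_(da4, cc.a4);
    fmat dW4 = cc.col4.t() * da4;
    frowvec db4 = sum(da4, 0);
    fmat da3 = col2im_b(da4 * c4.W.t(), B, l3, f3, k);
    relu_bwd_(da3, cc.a3);
    fmat dW3 = cc.col3.t() * da3;
    frowvec db3 = sum(da3, 0);
    fmat dp = col2im_b(da3 * c3.W.t(), B, lp, f2, k);
    fmat da2 = unpool_b(dp, cc.win, B, l2);
    relu_bwd_(da2, cc.a2);
    fmat dW2 = cc.col2.t() * da2;
    frowvec db2 = sum(da2, 0);
    fmat da1 = col2im_b(da2 * c2.W.t(), B, l1, f1, k);
    relu_bwd_(da1, cc.a1);
    fmat dW1 = cc.col1.t() * da1;
    frowvec db1 = sum(da1, 0);

    adam_step(c1, dW1, db1, lr, step);
    adam_step(c2, dW2, db2, lr, step);
    adam_step(c3, dW3, db3, lr, step);
    adam_step(c4, dW4, db4, lr, step);
    adam_step(d1, dW5, db5, lr, step);
    adam_step(d2, dW6, db6, lr, step);
  }
};

static fmat as_f(const Rcpp::NumericMatrix& X) {
  fmat out(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i) out(i, j) = (float)X(i, j);
  return out;
}

static Rcpp::NumericMatrix as_r(const fmat& M) {
  Rcpp::NumericMatrix out(M.n_rows, M.n_cols);
  for (uword j = 0; j < M.n_cols; ++j)
    for (uword i = 0; i < M.n_rows; ++i) out(i, j) = M(i, j);
  return out;
}

static void load_layer(Layer& L, const Rcpp::List& w, const char* nm_W,
                       const char* nm_b) {
  Rcpp::NumericMatrix W = w[nm_W];
  Rcpp::NumericVector b = w[nm_b];
  L.W = as_f(W);
  L.b.set_size(b.size());
  for (int i = 0; i < b.size(); ++i) L.b(i) = (float)b[i];
}

static Net net_from_config(const Rcpp::List& cfg) {
  Net net;
  Rcpp::IntegerVector filt = cfg["conv_filters"];
  net.configure(Rcpp::as<int>(cfg["input_len"]), Rcpp::as<int>(cfg["kernel_size"]),
                Rcpp::as<int>(cfg["pool_size"]), filt[0], filt[1], filt[2],
                filt[3], Rcpp::as<int>(cfg["dense_units"]));
  return net;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::NumericMatrix X, Rcpp::NumericVector y,
                         Rcpp::List cfg) {
  Net net = net_from_config(cfg);
  const int N = X.nrow();
  if (X.ncol() != net.input_len)
    Rcpp::stop("frames have %d samples but the network expects %d",
               X.ncol(), net.input_len);
  const int epochs = Rcpp::as<int>(cfg["epochs"]);
  const int batch = Rcpp::as<int>(cfg["batch_size"]);
  const float lr = (float)Rcpp::as<double>(cfg["learning_rate"]);
  const unsigned seed = (unsigned)Rcpp::as<int>(cfg["rng_seed"]);

  std::mt19937 rng(seed);
  net.init(rng);

  fmat Xf = as_f(X);
  fvec yf(N);
  for (int i = 0; i < N; ++i) yf(i) = (float)y[i];

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  Rcpp::NumericVector history(epochs);
  int step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    Rcpp::checkUserInterrupt();
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    for (int start = 0; start < N; start += batch) {
      const int B = std::min(batch, N - start);
      fmat Xb(B, net.input_len);
      fvec yb(B);
      for (int i = 0; i < B; ++i) {
        Xb.row(i) = Xf.row(order[start + i]);
        yb(i) = yf(order[start + i]);
      }
      Net::Cache cc;
      fvec pred = net.forward(Xb, &cc);
      fvec resid = pred - yb;
      double loss = dot(resid, resid) / B;
      if (!std::isfinite(loss))
        Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      ep_loss += loss * B;
      fvec dout = (2.0f / B) * resid;
      ++step;
      net.backward(Xb, dout, cc, lr, step);
    }
    history[ep] = ep_loss / N;
  }

  return Rcpp::List::create(
      Rcpp::Named("weights") = Rcpp::List::create(
          Rcpp::Named("W1") = as_r(net.c1.W), Rcpp::Named("b1") = as_r(net.c1.b),
          Rcpp::Named("W2") = as_r(net.c2.W), Rcpp::Named("b2") = as_r(net.c2.b),
          Rcpp::Named("W3") = as_r(net.c3.W), Rcpp::Named("b3") = as_r(net.c3.b),
          Rcpp::Named("W4") = as_r(net.c4.W), Rcpp::Named("b4") = as_r(net.c4.b),
          Rcpp::Named("W5") = as_r(net.d1.W), Rcpp::Named("b5") = as_r(net.d1.b),
          Rcpp::Named("W6") = as_r(net.d2.W), Rcpp::Named("b6") = as_r(net.d2.b)),
      Rcpp::Named("history") = history);
}

// [[Rcpp::export]]
Rcpp::NumericVector cnn_predict_cpp(Rcpp::List weights, Rcpp::NumericMatrix X,
                                    Rcpp::List cfg) {
  Net net = net_from_config(cfg);
  if (X.ncol() != net.input_len)
    Rcpp::stop("frames have %d samples but the network expects %d",
               X.ncol(), net.input_len);
  load_layer(net.c1, weights, "W1", "b1");
  load_layer(net.c2, weights, "W2", "b2");
  load_layer(net.c3, weights, "W3", "b3");
  load_layer(net.c4, weights, "W4", "b4");
  load_layer(net.d1, weights, "W5", "b5");
  load_layer(net.d2, weights, "W6", "b6");

  const int N = X.nrow(), chunk = 2048;
  fmat Xf = as_f(X);
  Rcpp::NumericVector out(N);
  for (int start = 0; start < N; start += chunk) {
    const int B = std::min(chunk, N - start);
    fvec pred = net.forward(Xf.rows(start, start + B - 1), nullptr);
    for (int i = 0; i < B; ++i) out[start + i] = pred(i);
  }
  return out;
}
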