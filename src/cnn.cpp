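// Compact 1D CNN for binary sequence classification, trained with Adam on
// binary cross-entropy, plus rescale-rule contribution backpropagation
// relative to a reference input. Single-threaded, deterministic given a
// seed. Conventions:
//   activations: L x C matrices (position x channel); after flatten, (D x 1)
//   conv weights: (in_ch * k) x out_ch; column block j = kernel tap j
//   flatten: column-major vectorisation (channel-major)
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

enum LayerType { CONV = 0, POOL = 1, DROP = 2, FLATTEN = 3, DENSE = 4 };
enum Act { LINEAR = 0, RELU = 1, SIGMOID = 2 };

struct Layer {
  int type;
  int k = 0, in_ch = 0, out_ch = 0, pad_l = 0, pad_r = 0; // conv
  int p = 0;                   // pool size
  double rate = 0.0;           // dropout
  int in_dim = 0, out_dim = 0; // dense
  int act = RELU;
};

static std::vector<Layer> parse_arch(const List& arch) {
  std::vector<Layer> out;
  for (int i = 0; i < arch.size(); ++i) {
    List li = arch[i];
    std::string t = as<std::string>(li["type"]);
    Layer ly;
    if (t == "conv") {
      ly.type = CONV;
      ly.k = as<int>(li["k"]); ly.in_ch = as<int>(li["in_ch"]);
      ly.out_ch = as<int>(li["out_ch"]);
      ly.pad_l = as<int>(li["pad_l"]); ly.pad_r = as<int>(li["pad_r"]);
      ly.act = RELU;
    } else if (t == "pool") {
      ly.type = POOL; ly.p = as<int>(li["p"]);
    } else if (t == "drop") {
      ly.type = DROP; ly.rate = as<double>(li["rate"]);
    } else if (t == "flatten") {
      ly.type = FLATTEN;
    } else if (t == "dense") {
      ly.type = DENSE;
      ly.in_dim = as<int>(li["in_dim"]); ly.out_dim = as<int>(li["out_dim"]);
      std::string a = as<std::string>(li["act"]);
      ly.act = (a == "relu") ? RELU : (a == "sigmoid" ? SIGMOID : LINEAR);
    } else stop("unknown layer type: " + t);
    out.push_back(ly);
  }
  return out;
}

template <typename M>
static void im2col(const M& X, int k, int pad_l, M& col) {
  const int L = X.n_rows, C = X.n_cols;
  col.zeros(L, C * k);
  for (int j = 0; j < k; ++j) {
    int out_lo = std::max(0, pad_l - j);         // first output row with data
    int in_lo = out_lo + j - pad_l;              // corresponding input row
    int len = std::min(L - out_lo, L - in_lo);
    if (len <= 0) continue;
    col.submat(out_lo, j * C, out_lo + len - 1, (j + 1) * C - 1) =
      X.rows(in_lo, in_lo + len - 1);
  }
}

template <typename M>
static void col2im(const M& dcol, int k, int pad_l, M& dX) {
  const int L = dX.n_rows, C = dX.n_cols;
  for (int j = 0; j < k; ++j) {
    int out_lo = std::max(0, pad_l - j);
    int in_lo = out_lo + j - pad_l;
    int len = std::min(L - out_lo, L - in_lo);
    if (len <= 0) continue;
    dX.rows(in_lo, in_lo + len - 1) +=
      dcol.submat(out_lo, j * C, out_lo + len - 1, (j + 1) * C - 1);
  }
}

template <typename M>
static M codes_to_onehot(const int* codes, int L) {
  M X(L, 4, arma::fill::zeros);
  for (int i = 0; i < L; ++i)
    if (codes[i] >= 0 && codes[i] < 4) X(i, codes[i]) = 1;
  return X;
}

// ------------------------- float training engine -------------------------

struct ParamsF {
  std::vector<arma::fmat> W;
  std::vector<arma::fvec> b;
  std::vector<int> widx; // arch index of each weighted layer
};

static ParamsF params_from_list(const List& params,
                                const std::vector<Layer>& arch) {
  ParamsF P;
  for (size_t i = 0; i < arch.size(); ++i) {
    if (arch[i].type == CONV || arch[i].type == DENSE) {
      List pi = params[i];
      P.W.push_back(arma::conv_to<arma::fmat>::from(as<arma::mat>(pi["W"])));
      P.b.push_back(arma::conv_to<arma::fvec>::from(as<arma::vec>(pi["b"])));
      P.widx.push_back((int)i);
    }
  }
  return P;
}

static List params_to_list(const ParamsF& P, const List& tmpl) {
  List out = clone(tmpl);
  for (size_t w = 0; w < P.W.size(); ++w) {
    List pi = out[P.widx[w]];
    pi["W"] = wrap(arma::conv_to<arma::mat>::from(P.W[w]));
    pi["b"] = wrap(arma::conv_to<arma::vec>::from(P.b[w]));
    out[P.widx[w]] = pi;
  }
  return out;
}


// Batched engine: a minibatch of B examples is stacked as a (B*L) x C
// matrix (per-example blocks of L rows), so convolutions and dense layers
// run as single BLAS calls over the whole batch. After flatten,
// activations are (D x B) with one column per example.

struct BatchCache {
  std::vector<arma::fmat> in;   // input activation per dense layer
  std::vector<int> in_rows, in_cols; // input dims per layer (arch order)
  std::vector<arma::fmat> col;  // im2col result per conv layer (in order)
  std::vector<arma::fmat> z;    // pre-activation per weighted layer
  std::vector<arma::umat> am;   // argmax per pool layer (rows x channels)
  std::vector<arma::fmat> mask; // per dropout layer
};

static void im2col_batch(const arma::fmat& X, int B, int L, int k, int pad_l,
                         arma::fmat& col) {
  const int C = X.n_cols;
  col.zeros(X.n_rows, C * k);
  for (int e = 0; e < B; ++e) {
    const int base = e * L;
    for (int j = 0; j < k; ++j) {
      int out_lo = std::max(0, pad_l - j);
      int in_lo = out_lo + j - pad_l;
      int len = std::min(L - out_lo, L - in_lo);
      if (len <= 0) continue;
      col.submat(base + out_lo, j * C, base + out_lo + len - 1,
                 (j + 1) * C - 1) =
        X.rows(base + in_lo, base + in_lo + len - 1);
    }
  }
}

static void col2im_batch(const arma::fmat& dcol, int B, int L, int k,
                         int pad_l, arma::fmat& dX) {
  const int C = dX.n_cols;
  for (int e = 0; e < B; ++e) {
    const int base = e * L;
    for (int j = 0; j < k; ++j) {
      int out_lo = std::max(0, pad_l - j);
      int in_lo = out_lo + j - pad_l;
      int len = std::min(L - out_lo, L - in_lo);
      if (len <= 0) continue;
      dX.rows(base + in_lo, base + in_lo + len - 1) +=
        dcol.submat(base + out_lo, j * C, base + out_lo + len - 1,
                    (j + 1) * C - 1);
    }
  }
}

// expand a batch of integer-coded sequences into stacked one-hot rows
static arma::fmat codes_to_onehot_batch(const IntegerMatrix& X,
                                        const std::vector<int>& idx) {
  const int L = X.nrow(), B = (int)idx.size();
  arma::fmat out(B * L, 4, arma::fill::zeros);
  for (int e = 0; e < B; ++e) {
    const int* codes = &X(0, idx[e]);
    for (int i = 0; i < L; ++i)
      if (codes[i] >= 0 && codes[i] < 4) out(e * L + i, codes[i]) = 1.0f;
  }
  return out;
}

// forward pass over one batch; returns the B output activations
static arma::fvec fwd_batch(const std::vector<Layer>& arch, const ParamsF& P,
                            const arma::fmat& X0, int B, bool train,
                            std::mt19937* rng, BatchCache* cache) {
  arma::fmat A = X0;           // (B*L) x C until flatten, then D x B
  int L = (int)X0.n_rows / B;
  bool flat = false;
  int w = 0;
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  for (size_t i = 0; i < arch.size(); ++i) {
    const Layer& ly = arch[i];
    if (cache) {
      // only dense layers need their actual input for the backward pass;
      // for the rest the dimensions suffice
      cache->in.push_back(ly.type == DENSE ? A : arma::fmat());
      cache->in_rows.push_back((int)A.n_rows);
      cache->in_cols.push_back((int)A.n_cols);
    }
    switch (ly.type) {
    case CONV: {
      arma::fmat col;
      im2col_batch(A, B, L, ly.k, ly.pad_l, col);
      arma::fmat Z = col * P.W[w];
      Z.each_row() += P.b[w].t();
      if (cache) { cache->col.push_back(col); cache->z.push_back(Z); }
      A = arma::clamp(Z, 0.0f, arma::datum::inf);
      ++w;
      break;
    }
    case POOL: {
      const int Lout = L / ly.p;
      arma::fmat O(B * Lout, A.n_cols);
      arma::umat am(B * Lout, A.n_cols);
      for (arma::uword c = 0; c < A.n_cols; ++c)
        for (int e = 0; e < B; ++e) {
          const int ibase = e * L, obase = e * Lout;
          for (int r = 0; r < Lout; ++r) {
            arma::uword best = ibase + (arma::uword)r * ly.p;
            float bv = A(best, c);
            for (int j = 1; j < ly.p; ++j) {
              const float v = A(ibase + r * ly.p + j, c);
              if (v > bv) { bv = v; best = ibase + r * ly.p + j; }
            }
            O(obase + r, c) = bv;
            am(obase + r, c) = best;
          }
        }
      if (cache) cache->am.push_back(am);
      A = O;
      L = Lout;
      break;
    }
    case DROP: {
      if (train && ly.rate > 0) {
        arma::fmat M(A.n_rows, A.n_cols);
        const float keep_scale = 1.0f / (1.0f - (float)ly.rate);
        for (arma::uword j = 0; j < M.n_elem; ++j)
          M(j) = (unif(*rng) >= ly.rate) ? keep_scale : 0.0f;
        if (cache) cache->mask.push_back(M);
        A %= M;
      } else if (cache) {
        cache->mask.push_back(arma::fmat());
      }
      break;
    }
    case FLATTEN: {
      // per-example column-major vectorisation -> (D x B)
      arma::fmat F((arma::uword)L * A.n_cols, B);
      for (int e = 0; e < B; ++e)
        F.col(e) = arma::vectorise(A.rows((arma::uword)e * L,
                                          (arma::uword)(e + 1) * L - 1));
      A = F;
      flat = true;
      break;
    }
    case DENSE: {
      arma::fmat Z = P.W[w].t() * A;   // (H x B)
      Z.each_col() += P.b[w];
      if (cache) cache->z.push_back(Z);
      if (ly.act == RELU) A = arma::clamp(Z, 0.0f, arma::datum::inf);
      else if (ly.act == SIGMOID) A = 1.0f / (1.0f + arma::exp(-Z));
      else A = Z;
      ++w;
      break;
    }
    }
  }
  (void)flat;
  return A.row(0).t();
}

struct Grads {
  std::vector<arma::fmat> dW;
  std::vector<arma::fvec> db;
  void zero_like(const ParamsF& P) {
    dW.resize(P.W.size()); db.resize(P.b.size());
    for (size_t i = 0; i < P.W.size(); ++i) {
      dW[i].zeros(P.W[i].n_rows, P.W[i].n_cols);
      db[i].zeros(P.b[i].n_rows);
    }
  }
};

// backward over one batch; dz_out = dLoss/dz at the output unit per
// example (sigmoid + mean binary cross-entropy: (p - y) / B)
static void bwd_batch(const std::vector<Layer>& arch, const ParamsF& P,
                      const BatchCache& cache, const arma::frowvec& dz_out,
                      int B, Grads& G) {
  int w = (int)P.W.size() - 1;
  int zi = (int)cache.z.size() - 1;
  int pi = (int)cache.am.size() - 1;
  int mi = (int)cache.mask.size() - 1;
  arma::fmat g;          // gradient wrt the current layer's output
  bool at_output = true;
  for (int i = (int)arch.size() - 1; i >= 0; --i) {
    const Layer& ly = arch[i];
    switch (ly.type) {
    case DENSE: {
      arma::fmat dZ;
      if (at_output) {
        dZ = arma::fmat(dz_out);
        at_output = false;
      } else {
        const arma::fmat& Z = cache.z[zi];
        dZ = (ly.act == RELU)
          ? arma::fmat(g % arma::conv_to<arma::fmat>::from(Z > 0.0f))
          : g;
      }
      --zi;
      const arma::fmat& Ain = cache.in[i];     // (D x B)
      G.dW[w] += Ain * dZ.t();
      G.db[w] += arma::sum(dZ, 1);
      g = P.W[w] * dZ;
      --w;
      break;
    }
    case FLATTEN: {
      const int C = cache.in_cols[i];
      const int L = cache.in_rows[i] / B;
      arma::fmat dA(cache.in_rows[i], C);
      for (int e = 0; e < B; ++e)
        dA.rows((arma::uword)e * L, (arma::uword)(e + 1) * L - 1) =
          arma::reshape(g.col(e), L, C);
      g = dA;
      break;
    }
    case DROP: {
      const arma::fmat& M = cache.mask[mi--];
      if (M.n_elem) g %= M;
      break;
    }
    case POOL: {
      const arma::umat& am = cache.am[pi--];
      arma::fmat dIn(cache.in_rows[i], cache.in_cols[i], arma::fill::zeros);
      for (arma::uword c = 0; c < g.n_cols; ++c)
        for (arma::uword r = 0; r < g.n_rows; ++r)
          dIn(am(r, c), c) += g(r, c);
      g = dIn;
      break;
    }
    case CONV: {
      const arma::fmat& Z = cache.z[zi--];
      arma::fmat dZ = g % arma::conv_to<arma::fmat>::from(Z > 0.0f);
      const arma::fmat& col = cache.col[w];  // conv layers precede dense
      G.dW[w] += col.t() * dZ;
      G.db[w] += arma::sum(dZ, 0).t();
      arma::fmat dcol = dZ * P.W[w].t();
      const int L = cache.in_rows[i] / B;
      arma::fmat dX(cache.in_rows[i], cache.in_cols[i], arma::fill::zeros);
      col2im_batch(dcol, B, L, ly.k, ly.pad_l, dX);
      g = dX;
      --w;
      break;
    }
    }
  }
}

static double bce(double p, double y) {
  const double eps = 1e-7;
  p = std::min(1.0 - eps, std::max(eps, p));
  return -(y * std::log(p) + (1.0 - y) * std::log(1.0 - p));
}

// [[Rcpp::export]]
List cpp_train_cnn(IntegerMatrix Xtr, NumericVector ytr,
                   IntegerMatrix Xval, NumericVector yval,
                   List arch_list, List params0, List hyper) {
  std::vector<Layer> arch = parse_arch(arch_list);
  ParamsF P = params_from_list(params0, arch);
  const int Ntr = Xtr.ncol(), Nval = Xval.ncol();
  const double lr0 = as<double>(hyper["learning_rate"]);
  const int max_epochs = as<int>(hyper["max_epochs"]);
  const int batch = as<int>(hyper["batch_size"]);
  const int es_pat = as<int>(hyper["early_stop_patience"]);
  const int lr_pat = as<int>(hyper["lr_reduce_patience"]);
  const double lr_factor = as<double>(hyper["lr_reduce_factor"]);
  const double min_lr = as<double>(hyper["min_lr"]);
  const unsigned seed = (unsigned)as<int>(hyper["seed"]);

  std::mt19937 rng(seed);
  Grads m, v;
  m.zero_like(P); v.zero_like(P);
  std::vector<arma::fvec> mb(P.b.size()), vb(P.b.size());
  for (size_t i = 0; i < P.b.size(); ++i) {
    mb[i].zeros(P.b[i].n_rows); vb[i].zeros(P.b[i].n_rows);
  }
  const float beta1 = 0.9f, beta2 = 0.999f, adam_eps = 1e-7f;
  long tstep = 0;
  double lr = lr0;

  std::vector<int> order(Ntr);
  for (int i = 0; i < Ntr; ++i) order[i] = i;

  std::vector<double> h_train, h_val, h_acc, h_lr;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = -1, since_best = 0, since_lr = 0;
  ParamsF bestP = P;

  const int val_chunk = 32;
  Grads G;
  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    double train_loss = 0.0;
    for (int b0 = 0; b0 < Ntr; b0 += batch) {
      const int B = std::min(Ntr, b0 + batch) - b0;
      std::vector<int> idx(order.begin() + b0, order.begin() + b0 + B);
      arma::fmat X = codes_to_onehot_batch(Xtr, idx);
      BatchCache cache;
      arma::fvec p = fwd_batch(arch, P, X, B, true, &rng, &cache);
      arma::frowvec dz(B);
      for (int e = 0; e < B; ++e) {
        if (std::isnan(p(e))) stop("NaN in forward pass (diverged training)");
        train_loss += bce(p(e), ytr[idx[e]]);
        dz(e) = (p(e) - (float)ytr[idx[e]]) / B;
      }
      G.zero_like(P);
      bwd_batch(arch, P, cache, dz, B, G);
      ++tstep;
      const float bc1 = 1.0f - std::pow(beta1, (float)tstep);
      const float bc2 = 1.0f - std::pow(beta2, (float)tstep);
      for (size_t wi = 0; wi < P.W.size(); ++wi) {
        m.dW[wi] = beta1 * m.dW[wi] + (1.0f - beta1) * G.dW[wi];
        v.dW[wi] = beta2 * v.dW[wi] + (1.0f - beta2) * arma::square(G.dW[wi]);
        mb[wi] = beta1 * mb[wi] + (1.0f - beta1) * G.db[wi];
        vb[wi] = beta2 * vb[wi] + (1.0f - beta2) * arma::square(G.db[wi]);
        P.W[wi] -= (float)lr * (m.dW[wi] / bc1) /
                   (arma::sqrt(v.dW[wi] / bc2) + adam_eps);
        P.b[wi] -= (float)lr * (mb[wi] / bc1) /
                   (arma::sqrt(vb[wi] / bc2) + adam_eps);
      }
    }
    train_loss /= Ntr;

    double val_loss = 0.0; int correct = 0;
    for (int v0 = 0; v0 < Nval; v0 += val_chunk) {
      const int B = std::min(Nval, v0 + val_chunk) - v0;
      std::vector<int> idx(B);
      for (int e = 0; e < B; ++e) idx[e] = v0 + e;
      arma::fmat X = codes_to_onehot_batch(Xval, idx);
      arma::fvec p = fwd_batch(arch, P, X, B, false, nullptr, nullptr);
      for (int e = 0; e < B; ++e) {
        val_loss += bce(p(e), yval[v0 + e]);
        const int cls = (p(e) > 0.5f) ? 1 : 0; // p <= 0.5 classifies as low
        if (cls == (int)yval[v0 + e]) ++correct;
      }
    }
    val_loss /= Nval;
    h_train.push_back(train_loss);
    h_val.push_back(val_loss);
    h_acc.push_back((double)correct / Nval);
    h_lr.push_back(lr);

    if (val_loss < best_val - 1e-9) {
      best_val = val_loss; best_epoch = epoch; bestP = P;
      since_best = 0; since_lr = 0;
    } else {
      ++since_best; ++since_lr;
    }
    if (since_lr >= lr_pat && lr > min_lr) {
      lr = std::max(min_lr, lr * lr_factor);
      since_lr = 0;
    }
    if (since_best >= es_pat) break;
  }

  return List::create(
    _["params"] = params_to_list(bestP, params0),
    _["best_epoch"] = best_epoch + 1,
    _["history"] = List::create(_["loss"] = wrap(h_train),
                                _["val_loss"] = wrap(h_val),
                                _["val_accuracy"] = wrap(h_acc),
                                _["lr"] = wrap(h_lr)));
}

// Loss gradient for one example without dropout; the reference path for
// gradient-check tests against finite differences.
// [[Rcpp::export]]
List cpp_grad_cnn(IntegerVector x, double y, List arch_list, List params) {
  std::vector<Layer> arch = parse_arch(arch_list);
  ParamsF P = params_from_list(params, arch);
  const int L = x.size();
  arma::fmat X(L, 4, arma::fill::zeros);
  for (int i = 0; i < L; ++i)
    if (x[i] >= 0 && x[i] < 4) X(i, x[i]) = 1.0f;
  BatchCache cache;
  arma::fvec p = fwd_batch(arch, P, X, 1, false, nullptr, &cache);
  Grads G;
  G.zero_like(P);
  arma::frowvec dz(1);
  dz(0) = p(0) - (float)y;
  bwd_batch(arch, P, cache, dz, 1, G);
  List out;
  for (size_t i = 0; i < G.dW.size(); ++i)
    out.push_back(List::create(
      _["dW"] = wrap(arma::conv_to<arma::mat>::from(G.dW[i])),
      _["db"] = wrap(arma::conv_to<arma::vec>::from(G.db[i]))));
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_predict_cnn(IntegerMatrix X, List arch_list, List params) {
  std::vector<Layer> arch = parse_arch(arch_list);
  ParamsF P = params_from_list(params, arch);
  const int N = X.ncol();
  NumericVector out(N);
  const int chunk = 32;
  for (int v0 = 0; v0 < N; v0 += chunk) {
    const int B = std::min(N, v0 + chunk) - v0;
    std::vector<int> idx(B);
    for (int e = 0; e < B; ++e) idx[e] = v0 + e;
    arma::fmat Xb = codes_to_onehot_batch(X, idx);
    arma::fvec p = fwd_batch(arch, P, Xb, B, false, nullptr, nullptr);
    for (int e = 0; e < B; ++e) out[v0 + e] = p(e);
  }
  return out;
}
// --------------------- double-precision attribution ----------------------

struct ParamsD {
  std::vector<arma::mat> W;
  std::vector<arma::vec> b;
};

static ParamsD params_d(const List& params, const std::vector<Layer>& arch) {
  ParamsD P;
  for (size_t i = 0; i < arch.size(); ++i)
    if (arch[i].type == CONV || arch[i].type == DENSE) {
      List pi = params[i];
      P.W.push_back(as<arma::mat>(pi["W"]));
      P.b.push_back(as<arma::vec>(pi["b"]));
    }
  return P;
}

struct CacheD {
  std::vector<arma::mat> in;  // input activation per layer
  std::vector<arma::mat> z;   // pre-activation per weighted layer
  std::vector<arma::mat> out; // output activation per layer
};

static double fwd_d(const std::vector<Layer>& arch, const ParamsD& P,
                    const arma::mat& X0, CacheD& cache) {
  arma::mat A = X0;
  int w = 0;
  for (size_t i = 0; i < arch.size(); ++i) {
    const Layer& ly = arch[i];
    cache.in.push_back(A);
    switch (ly.type) {
    case CONV: {
      arma::mat col;
      im2col(A, ly.k, ly.pad_l, col);
      arma::mat Z = col * P.W[w];
      Z.each_row() += P.b[w].t();
      cache.z.push_back(Z);
      A = arma::clamp(Z, 0.0, arma::datum::inf);
      ++w;
      break;
    }
    case POOL: {
      const int Lout = (int)A.n_rows / ly.p;
      arma::mat O(Lout, A.n_cols);
      for (arma::uword c = 0; c < A.n_cols; ++c)
        for (int r = 0; r < Lout; ++r)
          O(r, c) = A.rows(r * ly.p, (r + 1) * ly.p - 1).col(c).max();
      A = O;
      break;
    }
    case DROP:
      break; // inference: identity
    case FLATTEN:
      A = arma::mat(arma::vectorise(A));
      break;
    case DENSE: {
      arma::vec z = P.W[w].t() * A.col(0) + P.b[w];
      cache.z.push_back(arma::mat(z));
      arma::vec a;
      if (ly.act == RELU) a = arma::clamp(z, 0.0, arma::datum::inf);
      else if (ly.act == SIGMOID) a = 1.0 / (1.0 + arma::exp(-z));
      else a = z;
      A = arma::mat(a);
      ++w;
      break;
    }
    }
    cache.out.push_back(A);
  }
  return A(0, 0);
}

// rescale multiplier for an elementwise nonlinearity
static inline double rescale_mult(double zx, double zr, double ax, double ar,
                                  int act) {
  double dz = zx - zr;
  if (std::abs(dz) > 1e-10) return (ax - ar) / dz;
  // degenerate difference: fall back to the local derivative at x
  if (act == RELU) return zx > 0 ? 1.0 : 0.0;
  if (act == SIGMOID) { double s = 1.0 / (1.0 + std::exp(-zx)); return s * (1.0 - s); }
  return 1.0;
}

// Contribution multipliers of the model output w.r.t. the input, computed
// with the rescale rule relative to a reference. Max-pooling windows are
// decomposed into chains of pairwise maxima, max(a,b) = a + relu(b - a),
// each propagated with the rescale rule, so summation-to-delta holds
// exactly through the pooling layers as well.
// [[Rcpp::export]]
List cpp_deeplift(NumericMatrix x_onehot, NumericMatrix ref_onehot,
                  List arch_list, List params) {
  std::vector<Layer> arch = parse_arch(arch_list);
  ParamsD P = params_d(params, arch);
  arma::mat X = as<arma::mat>(x_onehot), R = as<arma::mat>(ref_onehot);
  if (X.n_rows != R.n_rows || X.n_cols != R.n_cols)
    stop("reference dimensions do not match the input");
  CacheD cx, cr;
  double fx = fwd_d(arch, P, X, cx);
  double fr = fwd_d(arch, P, R, cr);

  int w = (int)P.W.size() - 1;
  int zi = (int)cx.z.size() - 1;
  arma::mat m(1, 1); m(0, 0) = 1.0; // multiplier on the output activation
  for (int i = (int)arch.size() - 1; i >= 0; --i) {
    const Layer& ly = arch[i];
    switch (ly.type) {
    case DENSE: {
      const arma::mat& zx = cx.z[zi];
      const arma::mat& zr = cr.z[zi];
      const arma::mat& ax = cx.out[i];
      const arma::mat& ar = cr.out[i];
      arma::vec mz(zx.n_rows);
      for (arma::uword j = 0; j < mz.n_rows; ++j)
        mz(j) = m(j, 0) * rescale_mult(zx(j, 0), zr(j, 0),
                                       ax(j, 0), ar(j, 0), ly.act);
      m = arma::mat(P.W[w] * mz);
      --w; --zi;
      break;
    }
    case FLATTEN: {
      const arma::mat& Ain = cx.in[i];
      m = arma::reshape(m.col(0), Ain.n_rows, Ain.n_cols);
      break;
    }
    case DROP:
      break;
    case POOL: {
      const arma::mat& ax = cx.in[i];
      const arma::mat& ar = cr.in[i];
      arma::mat mIn(ax.n_rows, ax.n_cols, arma::fill::zeros);
      const int p = ly.p;
      for (arma::uword c = 0; c < m.n_cols; ++c)
        for (arma::uword r = 0; r < m.n_rows; ++r) {
          // running maxima over the window for x and reference
          std::vector<double> Mx(p), Mr(p);
          Mx[0] = ax(r * p, c); Mr[0] = ar(r * p, c);
          for (int j = 1; j < p; ++j) {
            Mx[j] = std::max(Mx[j - 1], ax(r * p + j, c));
            Mr[j] = std::max(Mr[j - 1], ar(r * p + j, c));
          }
          double mc = m(r, c);
          for (int j = p - 1; j >= 1; --j) {
            const double dx = ax(r * p + j, c) - Mx[j - 1];
            const double dr = ar(r * p + j, c) - Mr[j - 1];
            const double rx = std::max(dx, 0.0), rr = std::max(dr, 0.0);
            double s;
            if (std::abs(dx - dr) > 1e-12) s = (rx - rr) / (dx - dr);
            else s = dx > 0 ? 1.0 : 0.0;
            mIn(r * p + j, c) += mc * s;
            mc *= (1.0 - s);
          }
          mIn(r * p, c) += mc;
        }
      m = mIn;
      break;
    }
    case CONV: {
      const arma::mat& zx = cx.z[zi];
      const arma::mat& zr = cr.z[zi];
      arma::mat mz(zx.n_rows, zx.n_cols);
      for (arma::uword c = 0; c < zx.n_cols; ++c)
        for (arma::uword rr = 0; rr < zx.n_rows; ++rr)
          mz(rr, c) = m(rr, c) * rescale_mult(zx(rr, c), zr(rr, c),
                                              std::max(zx(rr, c), 0.0),
                                              std::max(zr(rr, c), 0.0), RELU);
      --zi;
      arma::mat mcol = mz * P.W[w].t();
      const arma::mat& Ain = cx.in[i];
      arma::mat mIn(Ain.n_rows, Ain.n_cols, arma::fill::zeros);
      col2im(mcol, ly.k, ly.pad_l, mIn);
      m = mIn;
      --w;
      break;
    }
    }
  }
  return List::create(_["mult"] = wrap(m), _["f_x"] = fx, _["f_ref"] = fr);
}
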