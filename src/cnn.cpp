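// Small convolutional network for frame classification.
//
// Fixed family: N blocks of (3x3 same-padding conv -> ReLU -> 2x2 max pool,
// stride 2, floor dims), then flatten -> dense -> sigmoid, trained with
// binary cross-entropy and Adam.  Weights live in an R list so models are
// plain serialisable data; all shuffling/initialisation randomness comes
// from R, which keeps training deterministic for a fixed seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

// im2col for a 3x3 kernel, zero padding 1: (H,W,C) -> (H*W) x (9*C).
// Column block order: channel-major, then kernel offset (dj, di) row-major
// over the 3x3 neighbourhood.
static mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat out(H * W, 9 * C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = 9 * c + (dj + 1) * 3 + (di + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            if (is < 0 || is >= H) continue;
            out(j * H + i, k) = S(is, js);
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col3: scatter (H*W) x (9*C) gradients back to (H,W,C).
static cube col2im3(const mat& G, int H, int W, int C) {
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& S = out.slice(c);
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = 9 * c + (dj + 1) * 3 + (di + 1);
        for (int j = 0; j < W; ++j) {
          const int js = j + dj;
          if (js < 0 || js >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int is = i + di;
            if (is < 0 || is >= H) continue;
            S(is, js) += G(j * H + i, k);
          }
        }
      }
    }
  }
  return out;
}

// 2x2 max pool, stride 2, floor output dims; records argmax linear indices
// (into the input slice) for the backward pass.
static cube maxpool2(const cube& X, umat& arg) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube out(Ho, Wo, C);
  arg.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& S = X.slice(c);
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int i0 = 2 * i, j0 = 2 * j;
        double best = S(i0, j0);
        int bi = i0, bj = j0;
        if (S(i0 + 1, j0) > best) { best = S(i0 + 1, j0); bi = i0 + 1; bj = j0; }
        if (S(i0, j0 + 1) > best) { best = S(i0, j0 + 1); bi = i0; bj = j0 + 1; }
        if (S(i0 + 1, j0 + 1) > best) { best = S(i0 + 1, j0 + 1); bi = i0 + 1; bj = j0 + 1; }
        out(i, j, c) = best;
        arg(j * Ho + i, c) = (uword)(bj * H + bi);
      }
    }
  }
  return out;
}

static cube unpool2(const cube& G, const umat& arg, int H, int W) {
  const int C = G.n_slices, Ho = G.n_rows, Wo = G.n_cols;
  cube out(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& S = out.slice(c);
    const mat& Gs = G.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        S(arg(j * Ho + i, c)) += Gs(i, j);
  }
  return out;
}

struct Weights {
  std::vector<mat> Wc;   // (9*c_in) x c_out per conv block
  std::vector<rowvec> bc;
  vec Wd;                // flat_dim
  double bd;
};

static Weights unpack(const List& w) {
  Weights out;
  List conv = w["conv"];
  for (int l = 0; l < conv.size(); ++l) {
    List cl = conv[l];
    out.Wc.push_back(Rcpp::as<mat>(cl["W"]));
    out.bc.push_back(Rcpp::as<rowvec>(cl["b"]));
  }
  List dl = w["dense"];
  out.Wd = Rcpp::as<vec>(dl["W"]);
  out.bd = Rcpp::as<double>(dl["b"]);
  return out;
}

static List pack(const Weights& w) {
  List conv(w.Wc.size());
  for (size_t l = 0; l < w.Wc.size(); ++l)
    conv[l] = List::create(Named("W") = w.Wc[l], Named("b") = w.bc[l]);
  return List::create(Named("conv") = conv,
                      Named("dense") = List::create(Named("W") = w.Wd,
                                                    Named("b") = w.bd));
}

struct FwdCache {
  std::vector<mat> col;     // im2col input per block
  std::vector<cube> pre;    // conv output pre-pool, post-ReLU
  std::vector<umat> arg;    // pool argmax
  std::vector<int> Hin, Win, Cin;
  vec flat;
  double p;
};

static double forward1(const Weights& w, const cube& x, FwdCache* cache) {
  cube A = x;
  FwdCache local;
  FwdCache& cc = cache ? *cache : local;
  const size_t L = w.Wc.size();
  cc.col.resize(L); cc.pre.resize(L); cc.arg.resize(L);
  cc.Hin.resize(L); cc.Win.resize(L); cc.Cin.resize(L);
  for (size_t l = 0; l < L; ++l) {
    const int H = A.n_rows, W = A.n_cols, C = A.n_slices;
    cc.Hin[l] = H; cc.Win[l] = W; cc.Cin[l] = C;
    mat col = im2col3(A);
    mat Z = col * w.Wc[l];
    Z.each_row() += w.bc[l];
    Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
    const int Co = w.Wc[l].n_cols;
    cube Zc(Z.memptr(), H, W, Co);  // copies
    umat arg;
    cube P = maxpool2(Zc, arg);
    if (cache) { cc.col[l] = std::move(col); cc.pre[l] = Zc; cc.arg[l] = std::move(arg); }
    A = std::move(P);
  }
  vec flat = vectorise(A);
  double z = dot(w.Wd, flat) + w.bd;
  double p = 1.0 / (1.0 + std::exp(-z));
  if (cache) { cc.flat = std::move(flat); cc.p = p; }
  return p;
}

// Accumulate gradient of the BCE loss for one example into g.
static void backward1(const Weights& w, const FwdCache& cc, double y,
                      Weights& g) {
  const double dz = cc.p - y;  // d(BCE)/d(logit)
  g.Wd += dz * cc.flat;
  g.bd += dz;
  const size_t L = w.Wc.size();
  // gradient wrt pooled output of last block
  const cube& lastPre = cc.pre[L - 1];
  const int Ho = lastPre.n_rows / 2, Wo = lastPre.n_cols / 2,
            Co = lastPre.n_slices;
  vec da = dz * w.Wd;
  cube dP(da.memptr(), Ho, Wo, Co);
  for (int l = (int)L - 1; l >= 0; --l) {
    const int H = cc.Hin[l], W = cc.Win[l], C = cc.Cin[l];
    cube dZ = unpool2(dP, cc.arg[l], H, W);
    // ReLU mask (pre is post-ReLU: derivative is 1 where pre > 0)
    const cube& pre = cc.pre[l];
    for (uword i = 0; i < dZ.n_elem; ++i)
      if (pre(i) <= 0.0) dZ(i) = 0.0;
    const int Co_l = dZ.n_slices;
    mat dZm(dZ.memptr(), H * W, Co_l);
    g.Wc[l] += cc.col[l].t() * dZm;
    g.bc[l] += sum(dZm, 0);
    if (l > 0) {
      mat dCol = dZm * w.Wc[l].t();
      cube dX = col2im3(dCol, H, W, C);
      const int Hp = dX.n_rows / 2, Wp = dX.n_cols / 2;
      // dX is gradient wrt this block's input == previous block's pooled out
      dP = dX;
      (void)Hp; (void)Wp;
    }
  }
}

static Weights zeros_like(const Weights& w) {
  Weights g;
  for (size_t l = 0; l < w.Wc.size(); ++l) {
    g.Wc.push_back(mat(w.Wc[l].n_rows, w.Wc[l].n_cols, fill::zeros));
    g.bc.push_back(rowvec(w.bc[l].n_elem, fill::zeros));
  }
  g.Wd = vec(w.Wd.n_elem, fill::zeros);
  g.bd = 0.0;
  return g;
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(Rcpp::List weights, arma::cube X) {
  Weights w = unpack(weights);
  const int N = X.n_slices;
  vec out(N);
  for (int i = 0; i < N; ++i) {
    cube xi(X.n_rows, X.n_cols, 1);
    xi.slice(0) = X.slice(i);
    out(i) = forward1(w, xi, nullptr);
  }
  return out;
}

// Mean BCE loss and gradients over a batch; used for training and for the
// finite-difference gradient checks in the test suite.
// [[Rcpp::export]]
Rcpp::List cnn_grad_cpp(Rcpp::List weights, arma::cube X, arma::vec y) {
  Weights w = unpack(weights);
  Weights g = zeros_like(w);
  const int N = X.n_slices;
  double loss = 0.0;
  for (int i = 0; i < N; ++i) {
    cube xi(X.n_rows, X.n_cols, 1);
    xi.slice(0) = X.slice(i);
    FwdCache cc;
    double p = forward1(w, xi, &cc);
    const double eps = 1e-12;
    loss += -(y(i) * std::log(p + eps) + (1.0 - y(i)) * std::log(1.0 - p + eps));
    backward1(w, cc, y(i), g);
  }
  const double inv = 1.0 / N;
  loss *= inv;
  for (size_t l = 0; l < g.Wc.size(); ++l) { g.Wc[l] *= inv; g.bc[l] *= inv; }
  g.Wd *= inv; g.bd *= inv;
  return List::create(Named("loss") = loss, Named("grad") = pack(g));
}

struct Adam {
  Weights m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const Weights& w) : m(zeros_like(w)), v(zeros_like(w)) {}
  static void upd(mat& w, mat& m, mat& v, const mat& g, double lr,
                  double b1, double b2, double eps, double c1, double c2) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    w -= lr * (m / c1) / (sqrt(v / c2) + eps);
  }
  void step(Weights& w, const Weights& g, double lr) {
    ++t;
    const double c1 = 1.0 - std::pow(b1, (double)t);
    const double c2 = 1.0 - std::pow(b2, (double)t);
    for (size_t l = 0; l < w.Wc.size(); ++l) {
      upd(w.Wc[l], m.Wc[l], v.Wc[l], g.Wc[l], lr, b1, b2, eps, c1, c2);
      rowvec& bw = w.bc[l];
      m.bc[l] = b1 * m.bc[l] + (1 - b1) * g.bc[l];
      v.bc[l] = b2 * v.bc[l] + (1 - b2) * square(g.bc[l]);
      bw -= lr * (m.bc[l] / c1) / (sqrt(v.bc[l] / c2) + eps);
    }
    m.Wd = b1 * m.Wd + (1 - b1) * g.Wd;
    v.Wd = b2 * v.Wd + (1 - b2) * square(g.Wd);
    w.Wd -= lr * (m.Wd / c1) / (sqrt(v.Wd / c2) + eps);
    m.bd = b1 * m.bd + (1 - b1) * g.bd;
    v.bd = b2 * v.bd + (1 - b2) * g.bd * g.bd;
    w.bd -= lr * (m.bd / c1) / (std::sqrt(v.bd / c2) + eps);
  }
};

// Mini-batch Adam training.  `order` is an epochs x n matrix of 1-based
// example indices supplied by R (one shuffled row per epoch) so that the
// whole run is a deterministic function of the R RNG state.
// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List weights, arma::cube X, arma::vec y,
                         arma::imat order, double lr, int batch_size) {
  Weights w = unpack(weights);
  Adam opt(w);
  const int n = X.n_slices, epochs = order.n_rows;
  std::vector<double> epoch_loss(epochs, 0.0);
  for (int e = 0; e < epochs; ++e) {
    double tot = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int stop = std::min(start + batch_size, n);
      Weights g = zeros_like(w);
      double loss = 0.0;
      for (int k = start; k < stop; ++k) {
        const int idx = order(e, k) - 1;
        cube xi(X.n_rows, X.n_cols, 1);
        xi.slice(0) = X.slice(idx);
        FwdCache cc;
        double p = forward1(w, xi, &cc);
        const double eps = 1e-12;
        loss += -(y(idx) * std::log(p + eps) +
                  (1.0 - y(idx)) * std::log(1.0 - p + eps));
        backward1(w, cc, y(idx), g);
      }
      const double inv = 1.0 / (stop - start);
      for (size_t l = 0; l < g.Wc.size(); ++l) { g.Wc[l] *= inv; g.bc[l] *= inv; }
      g.Wd *= inv; g.bd *= inv;
      opt.step(w, g, lr);
      tot += loss;
    }
    epoch_loss[e] = tot / n;
    Rcpp::checkUserInterrupt();
  }
  return List::create(Named("weights") = pack(w),
                      Named("loss") = epoch_loss);
}
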