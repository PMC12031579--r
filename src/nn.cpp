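// Five-branch 1-D CNN -> merge -> LSTM -> fully connected classifier.
//
// Each physiological channel feeds its own weight-independent stack of
// valid convolutions (stride 1) with ReLU, max-pool (size 2, stride 2,
// floor on odd lengths) and inverted dropout after each pool. Branch
// outputs are concatenated along the feature axis, run through a single
// tanh LSTM returning all time steps, flattened, and classified by a
// ReLU layer and a 2-unit softmax. Training is plain backprop with Adam
// on the mean softmax cross-entropy. All randomness (init, shuffling,
// dropout) is drawn from R's RNG so results are reproducible from
// set.seed() alone.
//
// Convolutions are im2col + BLAS gemm; with the default geometry the
// time-step chain is 1792 -> 861 -> 406 -> 188 -> 89.

#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::umat;
using arma::cube;

struct Arch {
  int nb;                  // branches (channels)
  std::vector<int> ks;     // kernel sizes per conv layer
  std::vector<int> fs;     // filters per conv layer
  std::vector<double> drop;
  bool use_lstm;
  int H;                   // lstm hidden units
  int fc1, nout, input_len;
  int T, D, flat;          // derived: time steps, merged features, flatten

  explicit Arch(const List& a) {
    nb = as<int>(a["n_branches"]);
    ks = as<std::vector<int>>(a["conv_kernel_sizes"]);
    fs = as<std::vector<int>>(a["conv_filters"]);
    drop = as<std::vector<double>>(a["dropout_rates"]);
    use_lstm = as<bool>(a["use_lstm"]);
    H = as<int>(a["lstm_hidden"]);
    fc1 = as<int>(a["fc1_units"]);
    nout = as<int>(a["output_units"]);
    input_len = as<int>(a["input_len"]);
    int L = input_len;
    for (size_t l = 0; l < ks.size(); ++l) {
      L = L - ks[l] + 1;
      if (L <= 0) stop("convolution arithmetic exhausts the segment");
      L /= 2;
    }
    T = L;
    D = nb * fs.back();
    flat = T * (use_lstm ? H : D);
  }
  int nl() const { return (int)ks.size(); }
  int cin(int l) const { return l == 0 ? 1 : fs[l - 1]; }
};

struct Net {
  std::vector<std::vector<mat>> cW, cB;  // [branch][layer]; b stored 1 x F
  mat Wx, Wh, bl;                        // D x 4H, H x 4H, 1 x 4H
  mat W1, b1, W2, b2;                    // flat x fc1, fc1 x 1, fc1 x nout

  std::vector<mat*> tensors() {
    std::vector<mat*> v;
    for (auto& br : cW) for (auto& w : br) v.push_back(&w);
    for (auto& br : cB) for (auto& b : br) v.push_back(&b);
    if (Wx.n_elem) { v.push_back(&Wx); v.push_back(&Wh); v.push_back(&bl); }
    v.push_back(&W1); v.push_back(&b1); v.push_back(&W2); v.push_back(&b2);
    return v;
  }
};

static Net net_from_list(const Arch& A, const List& w) {
  Net n;
  List conv = w["conv"];
  n.cW.resize(A.nb); n.cB.resize(A.nb);
  for (int b = 0; b < A.nb; ++b) {
    List br = conv[b];
    for (int l = 0; l < A.nl(); ++l) {
      List ly = br[l];
      n.cW[b].push_back(as<mat>(ly["W"]));
      n.cB[b].push_back(as<mat>(ly["b"]));
    }
  }
  if (A.use_lstm) {
    List ls = w["lstm"];
    n.Wx = as<mat>(ls["Wx"]); n.Wh = as<mat>(ls["Wh"]);
    n.bl = as<mat>(ls["b"]);
  }
  List f1 = w["fc1"], f2 = w["fc2"];
  n.W1 = as<mat>(f1["W"]); n.b1 = as<mat>(f1["b"]);
  n.W2 = as<mat>(f2["W"]); n.b2 = as<mat>(f2["b"]);
  return n;
}

static List net_to_list(const Arch& A, const Net& n) {
  List conv(A.nb);
  for (int b = 0; b < A.nb; ++b) {
    List br(A.nl());
    for (int l = 0; l < A.nl(); ++l)
      br[l] = List::create(_["W"] = n.cW[b][l], _["b"] = n.cB[b][l]);
    conv[b] = br;
  }
  List out = List::create(_["conv"] = conv);
  if (A.use_lstm)
    out["lstm"] = List::create(_["Wx"] = n.Wx, _["Wh"] = n.Wh,
                               _["b"] = n.bl);
  out["fc1"] = List::create(_["W"] = n.W1, _["b"] = n.b1);
  out["fc2"] = List::create(_["W"] = n.W2, _["b"] = n.b2);
  return out;
}

static mat rnorm_mat(int r, int c, double sd) {
  mat m(r, c);
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = R::rnorm(0.0, sd);
  return m;
}
static mat runif_mat(int r, int c, double lim) {
  mat m(r, c);
  for (arma::uword i = 0; i < m.n_elem; ++i) m(i) = R::runif(-lim, lim);
  return m;
}

// [[Rcpp::export]]
List nn_init(List arch) {
  Arch A(arch);
  Net n;
  n.cW.resize(A.nb); n.cB.resize(A.nb);
  for (int b = 0; b < A.nb; ++b)
    for (int l = 0; l < A.nl(); ++l) {
      int fanin = A.ks[l] * A.cin(l);
      n.cW[b].push_back(rnorm_mat(fanin, A.fs[l], std::sqrt(2.0 / fanin)));
      n.cB[b].push_back(mat(1, A.fs[l], arma::fill::zeros));
    }
  if (A.use_lstm) {
    double lim = std::sqrt(6.0 / (A.D + A.H));
    n.Wx = runif_mat(A.D, 4 * A.H, lim);
    n.Wh = runif_mat(A.H, 4 * A.H, lim);
    n.bl = mat(1, 4 * A.H, arma::fill::zeros);
    n.bl.cols(A.H, 2 * A.H - 1).fill(1.0);  // forget-gate bias
  }
  n.W1 = rnorm_mat(A.flat, A.fc1, std::sqrt(2.0 / A.flat));
  n.b1 = mat(A.fc1, 1, arma::fill::zeros);
  n.W2 = runif_mat(A.fc1, A.nout, std::sqrt(6.0 / (A.fc1 + A.nout)));
  n.b2 = mat(A.nout, 1, arma::fill::zeros);
  return net_to_list(A, n);
}

static void im2col(const mat& Ain, int k, mat& M) {
  int L = Ain.n_rows, C = Ain.n_cols, Lo = L - k + 1;
  M.set_size(Lo, k * C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < k; ++j)
      M.col(c * k + j) = Ain.col(c).subvec(j, j + Lo - 1);
}

// Everything the backward pass needs, reused across samples.
struct Ws {
  std::vector<std::vector<mat>> Ain;   // layer inputs, [b][l] (L x C)
  std::vector<std::vector<mat>> M;     // im2col matrices
  std::vector<std::vector<mat>> Act;   // post-ReLU conv outputs
  std::vector<std::vector<umat>> Pidx; // row index chosen by each pool
  std::vector<std::vector<mat>> Mask;  // inverted-dropout masks
  mat Hm;                              // merged branch outputs (T x D)
  mat Xl, I, F, G, O, C, Tc, Hh;       // lstm per-step state (T x H)
  vec feat, a1, p;
  Ws(const Arch& A) {
    Ain.assign(A.nb, std::vector<mat>(A.nl()));
    M.assign(A.nb, std::vector<mat>(A.nl()));
    Act.assign(A.nb, std::vector<mat>(A.nl()));
    Pidx.assign(A.nb, std::vector<umat>(A.nl()));
    Mask.assign(A.nb, std::vector<mat>(A.nl()));
  }
};

// forward one sample; x is input_len x nb. Returns class probabilities.
static vec forward(const Arch& A, const Net& n, const mat& x, bool training,
                   Ws& w) {
  w.Hm.set_size(A.T, A.D);
  for (int b = 0; b < A.nb; ++b) {
    mat cur = x.col(b);
    for (int l = 0; l < A.nl(); ++l) {
      w.Ain[b][l] = cur;
      im2col(cur, A.ks[l], w.M[b][l]);
      mat Z = w.M[b][l] * n.cW[b][l];
      Z.each_row() += n.cB[b][l];
      Z.transform([](double v) { return v > 0.0 ? v : 0.0; });
      w.Act[b][l] = Z;
      int Lp = Z.n_rows / 2, F = Z.n_cols;
      mat P(Lp, F);
      umat idx(Lp, F);
      for (int f = 0; f < F; ++f)
        for (int t = 0; t < Lp; ++t) {
          double a = Z(2 * t, f), bb = Z(2 * t + 1, f);
          if (a >= bb) { P(t, f) = a; idx(t, f) = 2 * t; }
          else { P(t, f) = bb; idx(t, f) = 2 * t + 1; }
        }
      w.Pidx[b][l] = idx;
      if (training && A.drop[l] > 0.0) {
        double keep = 1.0 - A.drop[l];
        mat mk(Lp, F);
        for (arma::uword i = 0; i < mk.n_elem; ++i)
          mk(i) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
        w.Mask[b][l] = mk;
        P %= mk;
      } else {
        w.Mask[b][l].reset();
      }
      cur = P;
    }
    w.Hm.cols(b * A.fs.back(), (b + 1) * A.fs.back() - 1) = cur;
  }

  if (A.use_lstm) {
    int T = A.T, H = A.H;
    w.I.set_size(T, H); w.F.set_size(T, H); w.G.set_size(T, H);
    w.O.set_size(T, H); w.C.set_size(T, H); w.Tc.set_size(T, H);
    w.Hh.set_size(T, H);
    rowvec h(H, arma::fill::zeros), c(H, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      rowvec z = w.Hm.row(t) * n.Wx + h * n.Wh + n.bl.row(0);
      rowvec i = 1.0 / (1.0 + arma::exp(-z.subvec(0, H - 1)));
      rowvec f = 1.0 / (1.0 + arma::exp(-z.subvec(H, 2 * H - 1)));
      rowvec g = arma::tanh(z.subvec(2 * H, 3 * H - 1));
      rowvec o = 1.0 / (1.0 + arma::exp(-z.subvec(3 * H, 4 * H - 1)));
      c = f % c + i % g;
      rowvec tc = arma::tanh(c);
      h = o % tc;
      w.I.row(t) = i; w.F.row(t) = f; w.G.row(t) = g; w.O.row(t) = o;
      w.C.row(t) = c; w.Tc.row(t) = tc; w.Hh.row(t) = h;
    }
    w.feat = arma::vectorise(w.Hh);
  } else {
    w.feat = arma::vectorise(w.Hm);
  }

  vec z1 = n.W1.t() * w.feat + n.b1;
  z1.transform([](double v) { return v > 0.0 ? v : 0.0; });
  w.a1 = z1;
  vec z2 = n.W2.t() * w.a1 + n.b2.col(0);
  z2 -= z2.max();
  vec e = arma::exp(z2);
  w.p = e / arma::accu(e);
  return w.p;
}

// backward one sample, accumulating into g.
static void backward(const Arch& A, const Net& n, const Ws& w, int y,
                     Net& g) {
  vec dz2 = w.p;
  dz2(y) -= 1.0;
  g.W2 += w.a1 * dz2.t();
  g.b2 += dz2;
  vec da1 = n.W2 * dz2;
  vec dz1 = da1;
  for (arma::uword i = 0; i < dz1.n_elem; ++i)
    if (w.a1(i) <= 0.0) dz1(i) = 0.0;
  g.W1 += w.feat * dz1.t();
  g.b1 += dz1;
  vec dfeat = n.W1 * dz1;

  mat dHm;
  if (A.use_lstm) {
    int T = A.T, H = A.H;
    mat dHout(dfeat.memptr(), T, H);  // vectorise is column-major
    dHm.set_size(T, A.D);
    rowvec dh_next(H, arma::fill::zeros), dc_next(H, arma::fill::zeros);
    for (int t = T - 1; t >= 0; --t) {
      rowvec dh = dHout.row(t) + dh_next;
      rowvec o = w.O.row(t), i = w.I.row(t), f = w.F.row(t),
             gg = w.G.row(t), tc = w.Tc.row(t);
      rowvec dc = dc_next + dh % o % (1.0 - tc % tc);
      rowvec do_ = dh % tc % o % (1.0 - o);
      rowvec di = dc % gg % i % (1.0 - i);
      rowvec dg = dc % i % (1.0 - gg % gg);
      rowvec cprev = (t > 0) ? rowvec(w.C.row(t - 1))
                             : rowvec(H, arma::fill::zeros);
      rowvec df = dc % cprev % f % (1.0 - f);
      dc_next = dc % f;
      rowvec dz(4 * H);
      dz.subvec(0, H - 1) = di;
      dz.subvec(H, 2 * H - 1) = df;
      dz.subvec(2 * H, 3 * H - 1) = dg;
      dz.subvec(3 * H, 4 * H - 1) = do_;
      rowvec hprev = (t > 0) ? rowvec(w.Hh.row(t - 1))
                             : rowvec(H, arma::fill::zeros);
      g.Wx += w.Hm.row(t).t() * dz;
      g.Wh += hprev.t() * dz;
      g.bl += dz;
      dh_next = dz * n.Wh.t();
      dHm.row(t) = dz * n.Wx.t();
    }
  } else {
    dHm = mat(dfeat.memptr(), A.T, A.D);
  }

  for (int b = 0; b < A.nb; ++b) {
    int F = A.fs.back();
    mat dP = dHm.cols(b * F, (b + 1) * F - 1);
    for (int l = A.nl() - 1; l >= 0; --l) {
      if (w.Mask[b][l].n_elem) dP %= w.Mask[b][l];
      const mat& Act = w.Act[b][l];
      mat dZ(Act.n_rows, Act.n_cols, arma::fill::zeros);
      const umat& idx = w.Pidx[b][l];
      for (arma::uword f = 0; f < dP.n_cols; ++f)
        for (arma::uword t = 0; t < dP.n_rows; ++t)
          dZ(idx(t, f), f) = dP(t, f);
      for (arma::uword i = 0; i < dZ.n_elem; ++i)
        if (Act(i) <= 0.0) dZ(i) = 0.0;
      g.cW[b][l] += w.M[b][l].t() * dZ;
      g.cB[b][l] += arma::sum(dZ, 0);
      if (l > 0) {
        mat dM = dZ * n.cW[b][l].t();  // Lo x (k*C)
        int k = A.ks[l], C = A.cin(l), Lo = dM.n_rows;
        mat dA(w.Ain[b][l].n_rows, C, arma::fill::zeros);
        for (int c = 0; c < C; ++c)
          for (int j = 0; j < k; ++j)
            dA.col(c).subvec(j, j + Lo - 1) += dM.col(c * k + j);
        dP = dA;
      }
    }
  }
}

static Net zeros_like(const Arch& A, Net& n) {
  Net g;
  g.cW.resize(A.nb); g.cB.resize(A.nb);
  for (int b = 0; b < A.nb; ++b)
    for (int l = 0; l < A.nl(); ++l) {
      g.cW[b].push_back(mat(arma::size(n.cW[b][l]), arma::fill::zeros));
      g.cB[b].push_back(mat(arma::size(n.cB[b][l]), arma::fill::zeros));
    }
  if (n.Wx.n_elem) {
    g.Wx = mat(arma::size(n.Wx), arma::fill::zeros);
    g.Wh = mat(arma::size(n.Wh), arma::fill::zeros);
    g.bl = mat(arma::size(n.bl), arma::fill::zeros);
  }
  g.W1 = mat(arma::size(n.W1), arma::fill::zeros);
  g.b1 = mat(arma::size(n.b1), arma::fill::zeros);
  g.W2 = mat(arma::size(n.W2), arma::fill::zeros);
  g.b2 = mat(arma::size(n.b2), arma::fill::zeros);
  return g;
}

static double sample_loss(const vec& p, int y) {
  return -std::log(std::max(p(y), 1e-12));
}

// mean cross-entropy over a set of samples, dropout off
static double eval_loss(const Arch& A, const Net& n, const cube& X,
                        const std::vector<int>& y,
                        const std::vector<int>& idx, Ws& w) {
  double s = 0.0;
  for (int i : idx) s += sample_loss(forward(A, n, X.slice(i), false, w),
                                     y[i]);
  return s / idx.size();
}

// [[Rcpp::export]]
List nn_train(List weights, List arch, const arma::cube& X,
              IntegerVector y, List cfg) {
  Arch A(arch);
  Net n = net_from_list(A, weights);
  int N = X.n_slices;
  if ((int)y.size() != N) stop("label/sample count mismatch");
  if ((int)X.n_rows != A.input_len || (int)X.n_cols != A.nb)
    stop("input shape mismatch: expected %d x %d, got %d x %d",
         A.input_len, A.nb, (int)X.n_rows, (int)X.n_cols);
  std::vector<int> yy(y.begin(), y.end());

  double lr = as<double>(cfg["learning_rate"]);
  int batch = as<int>(cfg["batch_size"]);
  int epochs = as<int>(cfg["max_epochs"]);
  int patience = as<int>(cfg["patience"]);  // negative disables
  IntegerVector val1 = cfg["val_idx"];      // 1-based, may be empty
  double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;

  std::vector<int> val, train;
  std::vector<bool> isval(N, false);
  for (int v : val1) { val.push_back(v - 1); isval[v - 1] = true; }
  for (int i = 0; i < N; ++i) if (!isval[i]) train.push_back(i);
  if (train.empty()) stop("no training samples");

  Ws w(A);
  Net g = zeros_like(A, n), m1 = zeros_like(A, n), m2 = zeros_like(A, n);
  std::vector<mat*> tn = n.tensors(), tg = g.tensors(),
                    tm = m1.tensors(), tv = m2.tensors();
  long step = 0;

  std::vector<double> train_loss, val_loss;
  double best_val = R_PosInf;
  int best_epoch = -1;
  bool have_best = false;
  List best_weights;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle from R's RNG
    for (int i = (int)train.size() - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(train[i], train[j]);
    }
    double ep_loss = 0.0;
    for (size_t start = 0; start < train.size(); start += batch) {
      size_t end = std::min(train.size(), start + batch);
      for (auto* t : tg) t->zeros();
      for (size_t i = start; i < end; ++i) {
        int s = train[i];
        ep_loss += sample_loss(forward(A, n, X.slice(s), true, w), yy[s]);
        backward(A, n, w, yy[s], g);
      }
      double scale = 1.0 / (end - start);
      ++step;
      double bc1 = 1.0 - std::pow(beta1, (double)step);
      double bc2 = 1.0 - std::pow(beta2, (double)step);
      for (size_t k = 0; k < tn.size(); ++k) {
        mat& W = *tn[k];
        mat& G = *tg[k];
        G *= scale;
        mat& M = *tm[k];
        mat& V = *tv[k];
        M = beta1 * M + (1.0 - beta1) * G;
        V = beta2 * V + (1.0 - beta2) * (G % G);
        W -= lr * (M / bc1) / (arma::sqrt(V / bc2) + adam_eps);
      }
    }
    train_loss.push_back(ep_loss / train.size());
    if (!val.empty()) {
      double vl = eval_loss(A, n, X, yy, val, w);
      val_loss.push_back(vl);
      if (vl < best_val) {
        best_val = vl;
        best_epoch = ep;
        best_weights = net_to_list(A, n);
        have_best = true;
      } else if (patience >= 0 && ep - best_epoch > patience) {
        break;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  List final_w = have_best ? best_weights : net_to_list(A, n);
  return List::create(_["weights"] = final_w,
                      _["train_loss"] = train_loss,
                      _["val_loss"] = val_loss,
                      _["epochs_run"] = (int)train_loss.size(),
                      _["best_epoch"] = best_epoch + 1);
}

// [[Rcpp::export]]
arma::mat nn_predict(List weights, List arch, const arma::cube& X) {
  Arch A(arch);
  Net n = net_from_list(A, weights);
  if ((int)X.n_rows != A.input_len || (int)X.n_cols != A.nb)
    stop("input shape mismatch: expected %d x %d, got %d x %d",
         A.input_len, A.nb, (int)X.n_rows, (int)X.n_cols);
  Ws w(A);
  mat out(X.n_slices, A.nout);
  for (arma::uword i = 0; i < X.n_slices; ++i)
    out.row(i) = forward(A, n, X.slice(i), false, w).t();
  return out;
}

// [[Rcpp::export]]
int nn_flatten_len(List arch) {
  return Arch(arch).flat;
}
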