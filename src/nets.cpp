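// Small recurrent networks for streaming neural decoding.
//
// Layout conventions:
//   X is a cube (features x batch x time): slice t is the (F x B) input at step t.
//   LSTM layer params: W (4H x Fin), U (4H x H), b (4H); gate order i, f, g, o.
//   GRU layer params:  W (3H x Fin), U (3H x H), b (3H); gate order r, z, n with
//     n = tanh(Wn x + Un (r o h) + bn)  (reset gate applied before U).
// All forward passes are strictly causal; backward passes return parameter
// gradients and, on request, the gradient of the loss w.r.t. the inputs
// (used for electrode-contribution maps).

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + arma::exp(-x)); }

// softmax over rows-dimension (each column is one distribution)
static inline mat softmax_cols(const mat& z) {
  mat m = z.each_row() - arma::max(z, 0);
  mat e = arma::exp(m);
  return e.each_row() / arma::sum(e, 0);
}

struct LstmCache {
  cube gates;  // 4H x B x T (post-nonlinearity)
  cube h;      // H x B x T
  cube c;      // H x B x T
};

// Forward one LSTM layer over the whole sequence.
static void lstm_layer_forward(const mat& W, const mat& U, const vec& b,
                               const cube& Xin, LstmCache& cc) {
  const int H = U.n_cols, B = Xin.n_cols, T = Xin.n_slices;
  cc.gates.set_size(4 * H, B, T);
  cc.h.set_size(H, B, T);
  cc.c.set_size(H, B, T);
  mat h(H, B, arma::fill::zeros), c(H, B, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat a = W * Xin.slice(t) + U * h;
    a.each_col() += b;
    mat i = sigm(a.rows(0, H - 1));
    mat f = sigm(a.rows(H, 2 * H - 1));
    mat g = arma::tanh(a.rows(2 * H, 3 * H - 1));
    mat o = sigm(a.rows(3 * H, 4 * H - 1));
    c = f % c + i % g;
    h = o % arma::tanh(c);
    cc.gates.slice(t).rows(0, H - 1) = i;
    cc.gates.slice(t).rows(H, 2 * H - 1) = f;
    cc.gates.slice(t).rows(2 * H, 3 * H - 1) = g;
    cc.gates.slice(t).rows(3 * H, 4 * H - 1) = o;
    cc.c.slice(t) = c;
    cc.h.slice(t) = h;
  }
}

// Backward one LSTM layer. dH is the gradient arriving at this layer's hidden
// states (4H gate cache etc. from forward). Returns dX for the layer below and
// accumulates dW, dU, db.
static cube lstm_layer_backward(const mat& W, const mat& U,
                                const cube& Xin, const LstmCache& cc,
                                const cube& dH, mat& dW, mat& dU, vec& db) {
  const int H = U.n_cols, B = Xin.n_cols, T = Xin.n_slices;
  dW.zeros(W.n_rows, W.n_cols);
  dU.zeros(U.n_rows, U.n_cols);
  db.zeros(4 * H);
  cube dX(Xin.n_rows, B, T, arma::fill::zeros);
  mat dh_next(H, B, arma::fill::zeros), dc_next(H, B, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    mat i = cc.gates.slice(t).rows(0, H - 1);
    mat f = cc.gates.slice(t).rows(H, 2 * H - 1);
    mat g = cc.gates.slice(t).rows(2 * H, 3 * H - 1);
    mat o = cc.gates.slice(t).rows(3 * H, 4 * H - 1);
    mat tc = arma::tanh(cc.c.slice(t));
    mat cprev = (t == 0) ? mat(H, B, arma::fill::zeros) : cc.c.slice(t - 1);
    mat hprev = (t == 0) ? mat(H, B, arma::fill::zeros) : cc.h.slice(t - 1);
    mat dh = dH.slice(t) + dh_next;
    mat do_ = dh % tc;
    mat dtc = dh % o % (1.0 - tc % tc) + dc_next;
    mat di = dtc % g;
    mat df = dtc % cprev;
    mat dg = dtc % i;
    dc_next = dtc % f;
    mat da(4 * H, B);
    da.rows(0, H - 1) = di % i % (1.0 - i);
    da.rows(H, 2 * H - 1) = df % f % (1.0 - f);
    da.rows(2 * H, 3 * H - 1) = dg % (1.0 - g % g);
    da.rows(3 * H, 4 * H - 1) = do_ % o % (1.0 - o);
    dW += da * Xin.slice(t).t();
    dU += da * hprev.t();
    db += arma::sum(da, 1);
    dX.slice(t) = W.t() * da;
    dh_next = U.t() * da;
  }
  return dX;
}

// Full stacked-LSTM frame classifier.
// layers: list of list(W, U, b); head Wy (C x H), by (C).
// Y: (T x B) integer class labels 1..C, 0 = unlabeled; mask (T x B) 0/1.
// Returns loss, probs (C x B x T), and optionally grads / dX.
// [[Rcpp::export]]
List cpp_lstm_run(List layers, const arma::mat& Wy, const arma::vec& by,
                  const arma::cube& X, const arma::imat& Y,
                  const arma::imat& mask, bool want_grads, bool want_dx,
                  bool want_probs) {
  const int L = layers.size();
  const int B = X.n_cols, T = X.n_slices, C = Wy.n_rows;
  std::vector<LstmCache> caches(L);
  std::vector<const cube*> inputs(L);
  const cube* cur = &X;
  std::vector<cube> stored;  // keep layer inputs alive
  stored.reserve(L);
  for (int l = 0; l < L; ++l) {
    List ly = layers[l];
    mat W = ly["W"], U = ly["U"];
    vec b = ly["b"];
    inputs[l] = cur;
    lstm_layer_forward(W, U, b, *cur, caches[l]);
    cur = &caches[l].h;
  }
  const cube& Htop = caches[L - 1].h;
  // head + loss
  double loss = 0.0;
  double nmask = 0.0;
  for (int t = 0; t < T; ++t)
    for (int bb = 0; bb < B; ++bb) nmask += mask(t, bb);
  if (nmask == 0) nmask = 1.0;
  cube probs;
  if (want_probs || want_grads || want_dx) probs.set_size(C, B, T);
  cube dHtop;
  if (want_grads || want_dx) dHtop.set_size(Htop.n_rows, B, T);
  mat dWy(C, Wy.n_cols, arma::fill::zeros);
  vec dby(C, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat logits = Wy * Htop.slice(t);
    logits.each_col() += by;
    mat p = softmax_cols(logits);
    if (probs.n_elem) probs.slice(t) = p;
    mat dlog(C, B, arma::fill::zeros);
    for (int bb = 0; bb < B; ++bb) {
      if (mask(t, bb)) {
        int k = Y(t, bb) - 1;
        loss += -std::log(std::max(p(k, bb), 1e-12));
        if (want_grads || want_dx) {
          dlog.col(bb) = p.col(bb) / nmask;
          dlog(k, bb) -= 1.0 / nmask;
        }
      }
    }
    if (want_grads || want_dx) {
      dWy += dlog * Htop.slice(t).t();
      dby += arma::sum(dlog, 1);
      dHtop.slice(t) = Wy.t() * dlog;
    }
  }
  loss /= nmask;
  List out = List::create(_["loss"] = loss);
  if (want_probs) out["probs"] = probs;
  if (want_grads || want_dx) {
    List lgrads(L);
    cube dH = dHtop;
    cube dXlow;
    for (int l = L - 1; l >= 0; --l) {
      List ly = layers[l];
      mat W = ly["W"], U = ly["U"];
      mat dW, dU;
      vec db;
      dXlow = lstm_layer_backward(W, U, *inputs[l], caches[l], dH, dW, dU, db);
      lgrads[l] = List::create(_["W"] = dW, _["U"] = dU, _["b"] = db);
      dH = dXlow;
    }
    if (want_grads) {
      out["grads"] = List::create(_["layers"] = lgrads, _["Wy"] = dWy,
                                  _["by"] = dby);
    }
    if (want_dx) out["dX"] = dXlow;
  }
  return out;
}

struct GruCache {
  cube gates;  // 3H x B x T : r, z, n (post-nonlinearity)
  cube un;     // H x B x T  : Un h_{t-1} + bn-part pre-reset product
  cube h;      // H x B x T
};

static void gru_layer_forward(const mat& W, const mat& U, const vec& b,
                              const cube& Xin, GruCache& cc) {
  const int H = U.n_cols, B = Xin.n_cols, T = Xin.n_slices;
  cc.gates.set_size(3 * H, B, T);
  cc.un.set_size(H, B, T);
  cc.h.set_size(H, B, T);
  mat h(H, B, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat a = W * Xin.slice(t);
    a.each_col() += b;
    mat u = U * h;
    mat r = sigm(a.rows(0, H - 1) + u.rows(0, H - 1));
    mat z = sigm(a.rows(H, 2 * H - 1) + u.rows(H, 2 * H - 1));
    mat un = u.rows(2 * H, 3 * H - 1);
    mat n = arma::tanh(a.rows(2 * H, 3 * H - 1) + r % un);
    h = (1.0 - z) % n + z % h;
    cc.gates.slice(t).rows(0, H - 1) = r;
    cc.gates.slice(t).rows(H, 2 * H - 1) = z;
    cc.gates.slice(t).rows(2 * H, 3 * H - 1) = n;
    cc.un.slice(t) = un;
    cc.h.slice(t) = h;
  }
}

static cube gru_layer_backward(const mat& W, const mat& U,
                               const cube& Xin, const GruCache& cc,
                               const cube& dH, mat& dW, mat& dU, vec& db) {
  const int H = U.n_cols, B = Xin.n_cols, T = Xin.n_slices;
  dW.zeros(W.n_rows, W.n_cols);
  dU.zeros(U.n_rows, U.n_cols);
  db.zeros(3 * H);
  cube dX(Xin.n_rows, B, T, arma::fill::zeros);
  mat dh_next(H, B, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    mat r = cc.gates.slice(t).rows(0, H - 1);
    mat z = cc.gates.slice(t).rows(H, 2 * H - 1);
    mat n = cc.gates.slice(t).rows(2 * H, 3 * H - 1);
    mat un = cc.un.slice(t);
    mat hprev = (t == 0) ? mat(H, B, arma::fill::zeros) : cc.h.slice(t - 1);
    mat dh = dH.slice(t) + dh_next;
    mat dz = dh % (hprev - n) % z % (1.0 - z);
    mat dnpre = dh % (1.0 - z) % (1.0 - n % n);
    mat dr = dnpre % un % r % (1.0 - r);
    mat da(3 * H, B), du(3 * H, B);
    da.rows(0, H - 1) = dr;
    da.rows(H, 2 * H - 1) = dz;
    da.rows(2 * H, 3 * H - 1) = dnpre;
    du.rows(0, H - 1) = dr;
    du.rows(H, 2 * H - 1) = dz;
    du.rows(2 * H, 3 * H - 1) = dnpre % r;
    dW += da * Xin.slice(t).t();
    dU += du * hprev.t();
    db += arma::sum(da, 1);
    dX.slice(t) = W.t() * da;
    dh_next = U.t() * du + dh % z;
  }
  return dX;
}

// Sequence classifier: 1-D temporal conv (+ReLU) -> stacked GRU -> FC on the
// final hidden state -> softmax. y: B integer labels 1..C (0 = ignore).
// [[Rcpp::export]]
List cpp_seqnet_run(const arma::mat& Wc, const arma::vec& bc, int kern,
                    int stride, List glayers, const arma::mat& Wy,
                    const arma::vec& by, const arma::cube& X,
                    const arma::ivec& y, bool want_grads, bool want_dx) {
  const int F = X.n_rows, B = X.n_cols, T = X.n_slices;
  const int Cc = Wc.n_rows, L = glayers.size(), C = Wy.n_rows;
  const int Tp = (T - kern) / stride + 1;
  if (Tp < 1) stop("sequence too short for the convolution kernel");
  // conv forward
  cube cols(F * kern, B, Tp);
  for (int tp = 0; tp < Tp; ++tp) {
    for (int j = 0; j < kern; ++j)
      cols.slice(tp).rows(j * F, (j + 1) * F - 1) = X.slice(tp * stride + j);
  }
  cube A(Cc, B, Tp);
  for (int tp = 0; tp < Tp; ++tp) {
    mat a = Wc * cols.slice(tp);
    a.each_col() += bc;
    A.slice(tp) = arma::clamp(a, 0.0, arma::datum::inf);  // ReLU
  }
  // GRU stack
  std::vector<GruCache> caches(L);
  const cube* cur = &A;
  std::vector<const cube*> inputs(L);
  for (int l = 0; l < L; ++l) {
    List ly = glayers[l];
    mat W = ly["W"], U = ly["U"];
    vec b = ly["b"];
    inputs[l] = cur;
    gru_layer_forward(W, U, b, *cur, caches[l]);
    cur = &caches[l].h;
  }
  const mat hlast = caches[L - 1].h.slice(Tp - 1);
  mat logits = Wy * hlast;
  logits.each_col() += by;
  mat p = softmax_cols(logits);
  double loss = 0.0;
  double nlab = 0.0;
  for (int bb = 0; bb < B; ++bb)
    if (y(bb) > 0) {
      loss += -std::log(std::max(p(y(bb) - 1, bb), 1e-12));
      nlab += 1.0;
    }
  if (nlab == 0) nlab = 1.0;
  loss /= nlab;
  List out = List::create(_["loss"] = loss, _["probs"] = p);
  if (!(want_grads || want_dx)) return out;

  mat dlog(C, B, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb)
    if (y(bb) > 0) {
      dlog.col(bb) = p.col(bb) / nlab;
      dlog(y(bb) - 1, bb) -= 1.0 / nlab;
    }
  mat dWy = dlog * hlast.t();
  vec dby = arma::sum(dlog, 1);
  const int H = Wy.n_cols;
  cube dH(H, B, Tp, arma::fill::zeros);
  dH.slice(Tp - 1) = Wy.t() * dlog;
  List lgrads(L);
  cube dcur = dH;
  for (int l = L - 1; l >= 0; --l) {
    List ly = glayers[l];
    mat W = ly["W"], U = ly["U"];
    mat dW, dU;
    vec db;
    dcur = gru_layer_backward(W, U, *inputs[l], caches[l], dcur, dW, dU, db);
    lgrads[l] = List::create(_["W"] = dW, _["U"] = dU, _["b"] = db);
  }
  // conv backward (dcur is gradient at ReLU output)
  mat dWc(Cc, F * kern, arma::fill::zeros);
  vec dbc(Cc, arma::fill::zeros);
  cube dX;
  if (want_dx) dX.zeros(F, B, T);
  for (int tp = 0; tp < Tp; ++tp) {
    mat da = dcur.slice(tp);
    da.elem(arma::find(A.slice(tp) <= 0)).zeros();
    dWc += da * cols.slice(tp).t();
    dbc += arma::sum(da, 1);
    if (want_dx) {
      mat dcol = Wc.t() * da;  // (F*kern) x B
      for (int j = 0; j < kern; ++j)
        dX.slice(tp * stride + j) += dcol.rows(j * F, (j + 1) * F - 1);
    }
  }
  if (want_grads) {
    out["grads"] = List::create(_["Wc"] = dWc, _["bc"] = dbc,
                                _["layers"] = lgrads, _["Wy"] = dWy,
                                _["by"] = dby);
  }
  if (want_dx) out["dX"] = dX;
  return out;
}
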