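// Compact single-layer LSTM sequence labeler: forward pass, full BPTT and
// Adam updates, with padded positions masked out of the loss. All
// randomness (weight init, shuffling) is drawn in R and passed in, so
// training is deterministic given the R seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::as;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// column-wise softmax, numerically stabilised
static inline mat softmax_cols(const mat& z) {
  mat s = z.each_row() - max(z, 0);
  s = exp(s);
  return s.each_row() / sum(s, 0);
}

struct LstmParams {
  mat Wx, Wh, Wy;
  vec b, by;
};

struct LstmGrads {
  mat Wx, Wh, Wy;
  vec b, by;
  void zero(const LstmParams& p) {
    Wx = zeros<mat>(p.Wx.n_rows, p.Wx.n_cols);
    Wh = zeros<mat>(p.Wh.n_rows, p.Wh.n_cols);
    Wy = zeros<mat>(p.Wy.n_rows, p.Wy.n_cols);
    b = zeros<vec>(p.b.n_elem);
    by = zeros<vec>(p.by.n_elem);
  }
};

// forward over one minibatch; fills gate/state cubes (H x B x T) and the
// class-probability cube (K x B x T)
static void forward_batch(const LstmParams& par, const cube& X,
                          cube& I, cube& F, cube& O, cube& G,
                          cube& C, cube& Hc, cube& P) {
  const uword H = par.Wh.n_cols, B = X.n_cols, T = X.n_slices;
  mat h_prev = zeros<mat>(H, B), c_prev = zeros<mat>(H, B);
  for (uword t = 0; t < T; ++t) {
    mat A = par.Wx * X.slice(t) + par.Wh * h_prev;
    A.each_col() += par.b;
    mat It = sigmoid(A.rows(0, H - 1));
    mat Ft = sigmoid(A.rows(H, 2 * H - 1));
    mat Ot = sigmoid(A.rows(2 * H, 3 * H - 1));
    mat Gt = tanh(A.rows(3 * H, 4 * H - 1));
    mat Ct = Ft % c_prev + It % Gt;
    mat Ht = Ot % tanh(Ct);
    mat Z = par.Wy * Ht;
    Z.each_col() += par.by;
    I.slice(t) = It; F.slice(t) = Ft; O.slice(t) = Ot; G.slice(t) = Gt;
    C.slice(t) = Ct; Hc.slice(t) = Ht; P.slice(t) = softmax_cols(Z);
    h_prev = Ht; c_prev = Ct;
  }
}

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const Rcpp::List& inputs,
                          const Rcpp::IntegerMatrix& targets,
                          const Rcpp::IntegerMatrix& perms,
                          Rcpp::List init, int batch_size,
                          double learning_rate, double clip_norm) {
  const int n = inputs.size();
  Rcpp::NumericMatrix first = inputs[0];
  const uword T = first.nrow(), D = first.ncol();

  LstmParams par;
  par.Wx = as<mat>(Rcpp::wrap(init["Wx"]));
  par.Wh = as<mat>(Rcpp::wrap(init["Wh"]));
  par.Wy = as<mat>(Rcpp::wrap(init["Wy"]));
  par.b = as<vec>(Rcpp::wrap(init["b"]));
  par.by = as<vec>(Rcpp::wrap(init["by"]));
  const uword H = par.Wh.n_cols, K = par.Wy.n_rows;

  // keep inputs as arma matrices (T x D)
  std::vector<mat> Xall(n);
  for (int i = 0; i < n; ++i) Xall[i] = as<mat>(Rcpp::wrap(inputs[i]));

  const int epochs = perms.nrow();
  LstmGrads g, m, v;
  m.zero(par); v.zero(par);
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  std::vector<double> epoch_loss(epochs, 0.0);

  for (int ep = 0; ep < epochs; ++ep) {
    double loss_sum = 0.0;
    long loss_count = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int B = std::min(batch_size, n - start);
      // gather minibatch into a D x B x T cube
      cube X(D, B, T);
      std::vector<int> idx(B);
      for (int j = 0; j < B; ++j) {
        idx[j] = perms(ep, start + j) - 1;
        const mat& Xi = Xall[idx[j]];
        for (uword t = 0; t < T; ++t) X.slice(t).col(j) = Xi.row(t).t();
      }
      cube I(H, B, T), F(H, B, T), O(H, B, T), G(H, B, T);
      cube C(H, B, T), Hc(H, B, T), P(K, B, T);
      forward_batch(par, X, I, F, O, G, C, Hc, P);

      long M = 0;
      for (int j = 0; j < B; ++j)
        for (uword t = 0; t < T; ++t)
          if (targets(idx[j], t) > 0) ++M;
      if (M == 0) continue;

      g.zero(par);
      mat dH_next = zeros<mat>(H, B), dC_next = zeros<mat>(H, B);
      for (int ti = (int)T - 1; ti >= 0; --ti) {
        const uword t = (uword)ti;
        mat dZ = P.slice(t);
        for (int j = 0; j < B; ++j) {
          int y = targets(idx[j], t);
          if (y > 0) {
            dZ(y - 1, j) -= 1.0;
            loss_sum += -std::log(std::max(P.slice(t)(y - 1, j), 1e-12));
          } else {
            dZ.col(j).zeros();
          }
        }
        dZ /= (double)M;
        g.Wy += dZ * Hc.slice(t).t();
        g.by += sum(dZ, 1);
        mat dH = par.Wy.t() * dZ + dH_next;
        mat tc = tanh(C.slice(t));
        mat dO = dH % tc;
        mat daO = dO % O.slice(t) % (1.0 - O.slice(t));
        mat dC = dH % O.slice(t) % (1.0 - tc % tc) + dC_next;
        mat dI = dC % G.slice(t);
        mat daI = dI % I.slice(t) % (1.0 - I.slice(t));
        mat dG = dC % I.slice(t);
        mat daG = dG % (1.0 - G.slice(t) % G.slice(t));
        mat c_prev = (t == 0) ? zeros<mat>(H, B) : C.slice(t - 1);
        mat dF = dC % c_prev;
        mat daF = dF % F.slice(t) % (1.0 - F.slice(t));
        dC_next = dC % F.slice(t);
        mat dA = join_cols(daI, daF, daO, daG);
        g.Wx += dA * X.slice(t).t();
        mat h_prev = (t == 0) ? zeros<mat>(H, B) : Hc.slice(t - 1);
        g.Wh += dA * h_prev.t();
        g.b += sum(dA, 1);
        dH_next = par.Wh.t() * dA;
      }
      loss_count += M;

      // global-norm gradient clipping for stability
      double gn = std::sqrt(accu(g.Wx % g.Wx) + accu(g.Wh % g.Wh) +
                            accu(g.Wy % g.Wy) + accu(g.b % g.b) +
                            accu(g.by % g.by));
      if (clip_norm > 0 && gn > clip_norm) {
        double sc = clip_norm / gn;
        g.Wx *= sc; g.Wh *= sc; g.Wy *= sc; g.b *= sc; g.by *= sc;
      }
      if (!std::isfinite(gn)) Rcpp::stop("non-finite gradient norm");

      // Adam
      ++step;
      double bc1 = 1.0 - std::pow(b1, (double)step);
      double bc2 = 1.0 - std::pow(b2, (double)step);
      auto adam = [&](mat& p, mat& mm, mat& vv, const mat& gg) {
        mm = b1 * mm + (1 - b1) * gg;
        vv = b2 * vv + (1 - b2) * (gg % gg);
        p -= learning_rate * (mm / bc1) / (sqrt(vv / bc2) + eps);
      };
      adam(par.Wx, m.Wx, v.Wx, g.Wx);
      adam(par.Wh, m.Wh, v.Wh, g.Wh);
      adam(par.Wy, m.Wy, v.Wy, g.Wy);
      mat bP = par.b, bM = m.b, bV = v.b, bG = g.b;
      adam(bP, bM, bV, bG);
      par.b = bP; m.b = bM; v.b = bV;
      mat byP = par.by, byM = m.by, byV = v.by, byG = g.by;
      adam(byP, byM, byV, byG);
      par.by = byP; m.by = byM; v.by = byV;
    }
    epoch_loss[ep] = loss_count > 0 ? loss_sum / (double)loss_count : NA_REAL;
    if (!std::isfinite(epoch_loss[ep]))
      Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("Wx") = par.Wx, Rcpp::Named("Wh") = par.Wh,
    Rcpp::Named("b") = par.b, Rcpp::Named("Wy") = par.Wy,
    Rcpp::Named("by") = par.by,
    Rcpp::Named("epoch_loss") = epoch_loss);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix lstm_forward_cpp(const Rcpp::NumericMatrix& input,
                                     const Rcpp::List& weights) {
  mat X = as<mat>(Rcpp::wrap(input));  // T x D
  LstmParams par;
  par.Wx = as<mat>(Rcpp::wrap(weights["Wx"]));
  par.Wh = as<mat>(Rcpp::wrap(weights["Wh"]));
  par.Wy = as<mat>(Rcpp::wrap(weights["Wy"]));
  par.b = as<vec>(Rcpp::wrap(weights["b"]));
  par.by = as<vec>(Rcpp::wrap(weights["by"]));
  const uword H = par.Wh.n_cols, T = X.n_rows, K = par.Wy.n_rows;
  vec h = zeros<vec>(H), c = zeros<vec>(H);
  mat out(T, K);
  for (uword t = 0; t < T; ++t) {
    vec a = par.Wx * X.row(t).t() + par.Wh * h + par.b;
    vec i = 1.0 / (1.0 + exp(-a.subvec(0, H - 1)));
    vec f = 1.0 / (1.0 + exp(-a.subvec(H, 2 * H - 1)));
    vec o = 1.0 / (1.0 + exp(-a.subvec(2 * H, 3 * H - 1)));
    vec gg = tanh(a.subvec(3 * H, 4 * H - 1));
    c = f % c + i % gg;
    h = o % tanh(c);
    vec z = par.Wy * h + par.by;
    z -= z.max();
    vec p = exp(z);
    p /= accu(p);
    out.row(t) = p.t();
  }
  return Rcpp::wrap(out);
}
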