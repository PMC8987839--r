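// Compact LeNet-class CNN for 32x32 RGB patch classification.
//
// Layout conventions (must match the R side):
//  * A patch is a column of X, the R array c(S, S, C) flattened
//    column-major: index = row + S*col + S*S*channel.
//  * im2col rows for a 3x3 valid convolution: k = di + 3*dj + 9*channel,
//    so a conv weight matrix is (filters x 9*channels).
//  * Pooled activations are re-laid-out in "image layout"
//    (row + H*col + H*W*filter) so they can feed the next im2col and,
//    after the second pool, the dense layer directly.
//
// All randomness (weight init, shuffling, dropout masks) lives in R;
// this file is deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// ---- im2col / col2im for 3x3 valid convolutions ----------------------

static void im2col_one(const double* img, int H, int W, int C,
                       mat& cols, uword col0) {
  const int Ho = H - 2, Wo = W - 2;
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      double* dst = cols.colptr(col0 + (uword)(i + Ho * j));
      for (int ch = 0; ch < C; ++ch) {
        const double* chan = img + (size_t)H * W * ch;
        for (int dj = 0; dj < 3; ++dj)
          for (int di = 0; di < 3; ++di)
            dst[di + 3 * dj + 9 * ch] = chan[(i + di) + H * (j + dj)];
      }
    }
  }
}

static void col2im_one(const mat& dcols, uword col0, int H, int W, int C,
                       double* dimg) {
  const int Ho = H - 2, Wo = W - 2;
  for (int j = 0; j < Wo; ++j) {
    for (int i = 0; i < Ho; ++i) {
      const double* src = dcols.colptr(col0 + (uword)(i + Ho * j));
      for (int ch = 0; ch < C; ++ch) {
        double* chan = dimg + (size_t)H * W * ch;
        for (int dj = 0; dj < 3; ++dj)
          for (int di = 0; di < 3; ++di)
            chan[(i + di) + H * (j + dj)] += src[di + 3 * dj + 9 * ch];
      }
    }
  }
}

// ---- 2x2 max pooling (stride 2, floor) -------------------------------
// A is (F x Ho*Wo*N), filter-major; output is image layout (Hp*Wp*F x N).

static void pool2(const mat& A, int Ho, int Wo, int F, int N,
                  mat& out, uvec& argcol) {
  const int Hp = Ho / 2, Wp = Wo / 2;
  out.set_size((uword)Hp * Wp * F, N);
  argcol.set_size((uword)Hp * Wp * F * N);
  for (int n = 0; n < N; ++n) {
    const uword off = (uword)n * Ho * Wo;
    for (int f = 0; f < F; ++f) {
      for (int jp = 0; jp < Wp; ++jp) {
        for (int ip = 0; ip < Hp; ++ip) {
          const uword cs[4] = {
            off + (uword)(2 * ip     + Ho * (2 * jp)),
            off + (uword)(2 * ip + 1 + Ho * (2 * jp)),
            off + (uword)(2 * ip     + Ho * (2 * jp + 1)),
            off + (uword)(2 * ip + 1 + Ho * (2 * jp + 1)) };
          double best = A(f, cs[0]);
          uword bc = cs[0];
          for (int k = 1; k < 4; ++k) {
            const double v = A(f, cs[k]);
            if (v > best) { best = v; bc = cs[k]; }  // ties -> first, deterministic
          }
          const uword dst = (uword)ip + (uword)Hp * jp + (uword)Hp * Wp * f;
          out(dst, n) = best;
          argcol(dst + (uword)Hp * Wp * F * n) = bc;
        }
      }
    }
  }
}

static void unpool2(const mat& dout, const uvec& argcol, int Ho, int Wo,
                    int F, int N, mat& dA) {
  const int Hp = Ho / 2, Wp = Wo / 2;
  dA.zeros(F, (uword)Ho * Wo * N);
  for (int n = 0; n < N; ++n) {
    for (int f = 0; f < F; ++f) {
      for (uword p = 0; p < (uword)Hp * Wp; ++p) {
        const uword dst = p + (uword)Hp * Wp * f;
        dA(f, argcol(dst + (uword)Hp * Wp * F * n)) += dout(dst, n);
      }
    }
  }
}

// ---- forward pass shared by training and inference -------------------

struct FwdState {
  mat cols1, A1, P1, cols2, A2, P2, H3, probs;
  uvec arg1, arg2;
  int Ho1, Wo1, Hp1, Wp1, Ho2, Wo2, Hp2, Wp2, N;
};

static void forward(const Rcpp::List& params, const mat& X, int S,
                    const mat& dropmask, FwdState& st) {
  const mat W1 = params["W1"]; const vec b1 = params["b1"];
  const mat W2 = params["W2"]; const vec b2 = params["b2"];
  const mat W3 = params["W3"]; const vec b3 = params["b3"];
  const mat W4 = params["W4"]; const vec b4 = params["b4"];
  const int f1 = (int)W1.n_rows, f2 = (int)W2.n_rows;
  const int N = (int)X.n_cols;

  st.N = N;
  st.Ho1 = S - 2;  st.Wo1 = S - 2;
  st.Hp1 = st.Ho1 / 2;  st.Wp1 = st.Wo1 / 2;
  st.Ho2 = st.Hp1 - 2;  st.Wo2 = st.Wp1 - 2;
  st.Hp2 = st.Ho2 / 2;  st.Wp2 = st.Wo2 / 2;

  st.cols1.set_size(9 * 3, (uword)st.Ho1 * st.Wo1 * N);
  for (int n = 0; n < N; ++n)
    im2col_one(X.colptr(n), S, S, 3, st.cols1, (uword)n * st.Ho1 * st.Wo1);

  st.A1 = W1 * st.cols1;
  st.A1.each_col() += b1;
  st.A1.transform([](double v) { return v > 0.0 ? v : 0.0; });

  pool2(st.A1, st.Ho1, st.Wo1, f1, N, st.P1, st.arg1);

  st.cols2.set_size(9 * f1, (uword)st.Ho2 * st.Wo2 * N);
  for (int n = 0; n < N; ++n)
    im2col_one(st.P1.colptr(n), st.Hp1, st.Wp1, f1, st.cols2,
               (uword)n * st.Ho2 * st.Wo2);

  st.A2 = W2 * st.cols2;
  st.A2.each_col() += b2;
  st.A2.transform([](double v) { return v > 0.0 ? v : 0.0; });

  pool2(st.A2, st.Ho2, st.Wo2, f2, N, st.P2, st.arg2);

  st.H3 = W3 * st.P2;           // P2 image layout == flattened features
  st.H3.each_col() += b3;
  st.H3.transform([](double v) { return v > 0.0 ? v : 0.0; });
  if (dropmask.n_elem > 0) st.H3 %= dropmask;

  mat Z4 = W4 * st.H3;
  Z4.each_col() += b4;
  const rowvec m = max(Z4, 0);
  Z4.each_row() -= m;
  st.probs = exp(Z4);
  const rowvec s = sum(st.probs, 0);
  st.probs.each_row() /= s;
}

// Forward only: class probabilities (2 x N), no dropout.
// [[Rcpp::export]]
arma::mat cnn_probs_cpp(Rcpp::List params, const arma::mat& X, int patch_px) {
  FwdState st;
  mat nodrop;
  forward(params, X, patch_px, nodrop, st);
  return st.probs;
}

// One minibatch: loss (+ per-parameter gradients when want_grad).
// y is 0/1 per column; w is a per-sample loss weight (may be empty).
// [[Rcpp::export]]
Rcpp::List cnn_batch_cpp(Rcpp::List params, const arma::mat& X,
                         const arma::ivec& y, const arma::mat& dropmask,
                         const arma::vec& w, int patch_px, bool want_grad) {
  FwdState st;
  forward(params, X, patch_px, dropmask, st);
  const int N = st.N;

  vec wts = w.n_elem > 0 ? w : vec(N, fill::ones);
  const double wsum = accu(wts);
  double loss = 0.0;
  int correct = 0;
  for (int n = 0; n < N; ++n) {
    const double p = st.probs(y(n), n);
    loss -= wts(n) * std::log(p + 1e-12);
    if ((st.probs(1, n) > st.probs(0, n) ? 1 : 0) == y(n)) ++correct;
  }
  loss /= wsum;

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("correct") = correct,
    Rcpp::Named("probs") = st.probs);
  if (!want_grad) return out;

  const mat W2 = params["W2"]; const mat W3 = params["W3"];
  const mat W4 = params["W4"];
  const int f1 = (int)Rcpp::as<mat>(params["W1"]).n_rows;
  const int f2 = (int)W2.n_rows;

  mat dZ4 = st.probs;
  for (int n = 0; n < N; ++n) {
    dZ4(y(n), n) -= 1.0;
    dZ4.col(n) *= wts(n) / wsum;
  }

  const mat dW4 = dZ4 * st.H3.t();
  const vec db4 = sum(dZ4, 1);
  mat dH = W4.t() * dZ4;
  if (dropmask.n_elem > 0) dH %= dropmask;
  dH %= conv_to<mat>::from(st.H3 > 0);

  const mat dW3 = dH * st.P2.t();
  const vec db3 = sum(dH, 1);
  const mat dF = W3.t() * dH;

  mat dA2;
  unpool2(dF, st.arg2, st.Ho2, st.Wo2, f2, N, dA2);
  dA2 %= conv_to<mat>::from(st.A2 > 0);

  const mat dW2 = dA2 * st.cols2.t();
  const vec db2 = sum(dA2, 1);
  const mat dcols2 = W2.t() * dA2;

  mat dP1(st.P1.n_rows, N, fill::zeros);
  for (int n = 0; n < N; ++n)
    col2im_one(dcols2, (uword)n * st.Ho2 * st.Wo2, st.Hp1, st.Wp1, f1,
               dP1.colptr(n));

  mat dA1;
  unpool2(dP1, st.arg1, st.Ho1, st.Wo1, f1, N, dA1);
  dA1 %= conv_to<mat>::from(st.A1 > 0);

  const mat dW1 = dA1 * st.cols1.t();
  const vec db1 = sum(dA1, 1);

  out["grads"] = Rcpp::List::create(
    Rcpp::Named("W1") = dW1, Rcpp::Named("b1") = db1,
    Rcpp::Named("W2") = dW2, Rcpp::Named("b2") = db2,
    Rcpp::Named("W3") = dW3, Rcpp::Named("b3") = db3,
    Rcpp::Named("W4") = dW4, Rcpp::Named("b4") = db4);
  return out;
}

// ---- 4-connected component labelling (baseline despeckler) -----------
// [[Rcpp::export]]
Rcpp::IntegerMatrix label4_cpp(Rcpp::LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  Rcpp::IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        const int cr = stack.back().first, cc = stack.back().second;
        stack.pop_back();
        const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          const int nr = cr + dr[k], nc = cc + dc[k];
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            lab(nr, nc) = next;
            stack.push_back(std::make_pair(nr, nc));
          }
        }
      }
    }
  }
  return lab;
}
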