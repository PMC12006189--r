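// Compact trainable encoders used as per-channel feature extractors:
//  - a single-layer LSTM followed by a fully-connected head, and
//  - a 1-D two-stage CNN over magnitude spectra.
// Both are trained with softmax cross-entropy on two output units
// (binary cross-entropy over the two classes) and Adam, with inverted
// dropout. All randomness flows through one std::mt19937 seed so training
// is bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static mat init_uniform(int r, int c, std::mt19937& g) {
  // fan-average uniform (Glorot-style) initialization
  double s = std::sqrt(6.0 / (double)(r + c));
  std::uniform_real_distribution<double> d(-s, s);
  mat M(r, c);
  for (uword i = 0; i < M.n_elem; ++i) M(i) = d(g);
  return M;
}

static mat dropout_mask(int r, int c, double p, std::mt19937& g) {
  // inverted dropout: keep with prob 1-p, scale by 1/(1-p)
  if (p <= 0.0) return ones<mat>(r, c);
  std::uniform_real_distribution<double> d(0.0, 1.0);
  mat M(r, c);
  double keep = 1.0 - p;
  for (uword i = 0; i < M.n_elem; ++i) M(i) = (d(g) < keep) ? 1.0 / keep : 0.0;
  return M;
}

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  int t = 0;
  std::vector<mat> m, v;
  explicit Adam(double lr_) : lr(lr_) {}
  void init(const std::vector<mat*>& ps) {
    for (auto p : ps) { m.push_back(zeros(size(*p))); v.push_back(zeros(size(*p))); }
  }
  void step(std::vector<mat*>& ps, std::vector<mat*>& gs, double clip = 5.0) {
    double sq = 0.0;
    for (auto gp : gs) sq += accu(square(*gp));
    double nrm = std::sqrt(sq);
    if (nrm > clip && nrm > 0)
      for (auto gp : gs) *gp *= clip / nrm;
    ++t;
    for (size_t i = 0; i < ps.size(); ++i) {
      m[i] = b1 * m[i] + (1 - b1) * (*gs[i]);
      v[i] = b2 * v[i] + (1 - b2) * square(*gs[i]);
      mat mh = m[i] / (1 - std::pow(b1, t));
      mat vh = v[i] / (1 - std::pow(b2, t));
      *ps[i] -= lr * mh / (sqrt(vh) + eps);
    }
  }
};

// softmax cross-entropy on 2 x B scores; fills dS, returns mean loss
static double softmax_ce(const mat& S, const ivec& yb, mat& dS, int& correct) {
  int B = S.n_cols;
  mat P = S;
  P.each_row() -= max(S, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  double loss = 0.0;
  dS = P;
  for (int j = 0; j < B; ++j) {
    int y = yb(j);
    loss -= std::log(std::max(P(y, j), 1e-12));
    dS(y, j) -= 1.0;
    if ((P(1, j) > P(0, j) ? 1 : 0) == y) ++correct;
  }
  dS /= B;
  return loss / B;
}

static mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// ---------------------------------------------------------------- LSTM --

struct LstmCache {
  std::vector<mat> H, Cprev, gates, tC;
};

// forward over all timesteps for a batch; X is T x B (one input per step)
static mat lstm_forward(const mat& Xb, const mat& W, const vec& b, int h,
                        LstmCache* cache) {
  int T = Xb.n_rows, B = Xb.n_cols;
  mat hp = zeros(h, B), Cp = zeros(h, B);
  if (cache) { cache->H.resize(T); cache->Cprev.resize(T);
               cache->gates.resize(T); cache->tC.resize(T); }
  for (int t = 0; t < T; ++t) {
    mat Z = join_cols(hp, Xb.row(t));
    mat G = W * Z;
    G.each_col() += b;
    mat f = sigmoid(G.rows(0, h - 1));
    mat i = sigmoid(G.rows(h, 2 * h - 1));
    mat g = tanh(G.rows(2 * h, 3 * h - 1));
    mat o = sigmoid(G.rows(3 * h, 4 * h - 1));
    mat C = f % Cp + i % g;
    mat tC = tanh(C);
    if (cache) {
      cache->H[t] = hp; cache->Cprev[t] = Cp;
      cache->gates[t] = join_cols(join_cols(f, i), join_cols(g, o));
      cache->tC[t] = tC;
    }
    hp = o % tC;
    Cp = C;
  }
  return hp;  // final hidden state, h x B
}

// [[Rcpp::export]]
List cpp_lstm_train(const arma::mat& X, const arma::ivec& y, int hidden,
                    int fc_size, int epochs, int batch, double lr,
                    double dropout, int seed) {
  int T = X.n_rows, N = X.n_cols, h = hidden;
  std::mt19937 rng(seed);
  mat W = init_uniform(4 * h, h + 1, rng);
  vec b = zeros(4 * h);
  b.rows(0, h - 1).fill(1.0);  // forget-gate bias 1: standard LSTM practice
  mat Wfc = init_uniform(fc_size, h, rng);
  vec bfc = zeros(fc_size);
  mat Wout = init_uniform(2, fc_size, rng);
  vec bout = zeros(2);

  mat bM(b), bfcM(bfc), boutM(bout);  // Adam works on mat; sync after steps
  std::vector<mat*> params = { &W, &bM, &Wfc, &bfcM, &Wout, &boutM };
  Adam opt(lr);
  opt.init(params);

  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  vec loss_hist(epochs), acc_hist(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    int ep_correct = 0, nb = 0;
    for (int s0 = 0; s0 < N; s0 += batch) {
      int B = std::min(batch, N - s0);
      uvec cols(B);
      ivec yb(B);
      for (int j = 0; j < B; ++j) { cols(j) = idx[s0 + j]; yb(j) = y(idx[s0 + j]); }
      mat Xb = X.cols(cols);

      LstmCache cache;
      b = bM.col(0); bfc = bfcM.col(0); bout = boutM.col(0);
      mat hT = lstm_forward(Xb, W, b, h, &cache);
      mat m1 = dropout_mask(h, B, dropout, rng);
      mat hd = hT % m1;
      mat a = Wfc * hd;
      a.each_col() += bfc;
      mat r = max(a, zeros(size(a)));
      mat m2 = dropout_mask(fc_size, B, dropout, rng);
      mat rd = r % m2;
      mat S = Wout * rd;
      S.each_col() += bout;

      mat dS;
      int corr = 0;
      double loss = softmax_ce(S, yb, dS, corr);
      ep_loss += loss; ep_correct += corr; ++nb;

      mat gWout = dS * rd.t();
      mat gbout = sum(dS, 1);
      mat dr = (Wout.t() * dS) % m2;
      mat da = dr % conv_to<mat>::from(a > 0);
      mat gWfc = da * hd.t();
      mat gbfc = sum(da, 1);
      mat dh = (Wfc.t() * da) % m1;

      mat gW = zeros(size(W));
      mat gb = zeros(4 * h, 1);
      mat dC = zeros(h, B);
      for (int t = T - 1; t >= 0; --t) {
        const mat& G = cache.gates[t];
        mat f = G.rows(0, h - 1), i = G.rows(h, 2 * h - 1);
        mat g = G.rows(2 * h, 3 * h - 1), o = G.rows(3 * h, 4 * h - 1);
        const mat& tC = cache.tC[t];
        mat dO = dh % tC;
        dC += dh % o % (1 - tC % tC);
        mat dF = dC % cache.Cprev[t];
        mat dI = dC % g;
        mat dG = dC % i;
        mat dfp = dF % f % (1 - f);
        mat dip = dI % i % (1 - i);
        mat dgp = dG % (1 - g % g);
        mat dop = dO % o % (1 - o);
        mat dGm = join_cols(join_cols(dfp, dip), join_cols(dgp, dop));
        mat Z = join_cols(cache.H[t], Xb.row(t));
        gW += dGm * Z.t();
        gb += sum(dGm, 1);
        mat dZ = W.t() * dGm;
        dh = dZ.rows(0, h - 1);
        dC = dC % f;
      }
      std::vector<mat*> grads = { &gW, &gb, &gWfc, &gbfc, &gWout, &gbout };
      opt.step(params, grads);
    }
    loss_hist(ep) = ep_loss / nb;
    acc_hist(ep) = (double)ep_correct / N;
  }
  b = bM.col(0); bfc = bfcM.col(0); bout = boutM.col(0);
  return List::create(Named("W") = W, Named("b") = b, Named("Wfc") = Wfc,
                      Named("bfc") = bfc, Named("Wout") = Wout,
                      Named("bout") = bout, Named("hidden") = h,
                      Named("fc_size") = fc_size,
                      Named("loss") = loss_hist, Named("train_acc") = acc_hist);
}

// [[Rcpp::export]]
arma::mat cpp_lstm_apply(const arma::mat& X, const arma::mat& W,
                         const arma::vec& b, const arma::mat& Wfc,
                         const arma::vec& bfc, const arma::mat& Wout,
                         const arma::vec& bout, int hidden) {
  mat hT = lstm_forward(X, W, b, hidden, nullptr);
  mat a = Wfc * hT;
  a.each_col() += bfc;
  mat r = max(a, zeros(size(a)));
  mat S = Wout * r;
  S.each_col() += bout;
  return S.t();  // N x 2 pre-softmax activations
}

// ----------------------------------------------------------------- CNN --

// 1-D convolution with kernel 5, stride 1, same padding, via im2col
static mat im2col5(const mat& A) {
  int Cin = A.n_rows, L = A.n_cols;
  mat P(Cin * 5, L, fill::zeros);
  for (int k = 0; k < 5; ++k) {
    int off = k - 2;
    int j0 = std::max(0, -off), j1 = std::min(L, L - off);
    if (j1 > j0)
      P.submat(k * Cin, j0, (k + 1) * Cin - 1, j1 - 1) =
          A.cols(j0 + off, j1 - 1 + off);
  }
  return P;
}

static mat col2im5(const mat& P, int Cin, int L) {
  mat A(Cin, L, fill::zeros);
  for (int k = 0; k < 5; ++k) {
    int off = k - 2;
    int j0 = std::max(0, -off), j1 = std::min(L, L - off);
    if (j1 > j0)
      A.cols(j0 + off, j1 - 1 + off) +=
          P.submat(k * Cin, j0, (k + 1) * Cin - 1, j1 - 1);
  }
  return A;
}

static mat maxpool2(const mat& A, umat& arg) {
  int C = A.n_rows, L = A.n_cols / 2;
  mat O(C, L);
  arg.set_size(C, L);
  for (int j = 0; j < L; ++j)
    for (int c = 0; c < C; ++c) {
      double a0 = A(c, 2 * j), a1 = A(c, 2 * j + 1);
      if (a0 >= a1) { O(c, j) = a0; arg(c, j) = 2 * j; }
      else { O(c, j) = a1; arg(c, j) = 2 * j + 1; }
    }
  return O;
}

struct CnnParams {
  mat W1, W2, Wfc, Wout;
  vec b1, b2, bfc, bout;
};

struct CnnCache {
  mat P1, A1r, D1, pool1, P2, A2r, D2, pool2, hfc_r;
  umat arg1, arg2;
  vec flat, dfc_mask;
};

// forward one sample (x: length-D column vector); training=true applies
// dropout masks drawn from rng
static vec cnn_forward(const vec& x, const CnnParams& p, double dropout,
                       bool training, std::mt19937& rng, CnnCache* cc) {
  mat A0 = x.t();  // 1 x D
  mat P1 = im2col5(A0);
  mat A1 = p.W1 * P1;
  A1.each_col() += p.b1;
  mat A1r = max(A1, zeros(size(A1)));
  mat D1 = training ? dropout_mask(A1r.n_rows, A1r.n_cols, dropout, rng)
                    : ones<mat>(A1r.n_rows, A1r.n_cols);
  umat arg1;
  mat pool1 = maxpool2(A1r % D1, arg1);
  mat P2 = im2col5(pool1);
  mat A2 = p.W2 * P2;
  A2.each_col() += p.b2;
  mat A2r = max(A2, zeros(size(A2)));
  mat D2 = training ? dropout_mask(A2r.n_rows, A2r.n_cols, dropout, rng)
                    : ones<mat>(A2r.n_rows, A2r.n_cols);
  umat arg2;
  mat pool2 = maxpool2(A2r % D2, arg2);
  vec flat = vectorise(pool2);
  vec hfc = p.Wfc * flat + p.bfc;
  vec hfc_r = max(hfc, zeros<vec>(hfc.n_elem));
  vec dm = training ? vec(dropout_mask(hfc_r.n_elem, 1, dropout, rng).col(0))
                    : ones<vec>(hfc_r.n_elem);
  vec hd = hfc_r % dm;
  vec s = p.Wout * hd + p.bout;
  if (cc) {
    cc->P1 = P1; cc->A1r = A1; cc->D1 = D1; cc->pool1 = pool1;
    cc->P2 = P2; cc->A2r = A2; cc->D2 = D2; cc->pool2 = pool2;
    cc->arg1 = arg1; cc->arg2 = arg2; cc->flat = flat;
    cc->hfc_r = join_rows(hfc, hfc_r % dm); cc->dfc_mask = dm;
  }
  return s;
}

// [[Rcpp::export]]
List cpp_cnn_train(const arma::mat& X, const arma::ivec& y, int epochs,
                   int batch, double lr, double dropout, int seed) {
  int D = X.n_rows, N = X.n_cols;
  if (D % 4 != 0) Rcpp::stop("input length must be divisible by 4");
  int n1 = 16, n2 = 32, fc = 64;
  int flatdim = n2 * (D / 4);
  std::mt19937 rng(seed);
  CnnParams p;
  p.W1 = init_uniform(n1, 5, rng);        p.b1 = zeros(n1);
  p.W2 = init_uniform(n2, n1 * 5, rng);   p.b2 = zeros(n2);
  p.Wfc = init_uniform(fc, flatdim, rng); p.bfc = zeros(fc);
  p.Wout = init_uniform(2, fc, rng);      p.bout = zeros(2);

  mat b1M(p.b1), b2M(p.b2), bfcM(p.bfc), boutM(p.bout);
  std::vector<mat*> params = { &p.W1, &b1M, &p.W2, &b2M, &p.Wfc, &bfcM,
                               &p.Wout, &boutM };
  Adam opt(lr);
  opt.init(params);

  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  vec loss_hist(epochs), acc_hist(epochs);

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double ep_loss = 0.0;
    int ep_correct = 0, nb = 0;
    for (int s0 = 0; s0 < N; s0 += batch) {
      int B = std::min(batch, N - s0);
      mat gW1 = zeros(size(p.W1)), gW2 = zeros(size(p.W2));
      mat gWfc = zeros(size(p.Wfc)), gWout = zeros(size(p.Wout));
      mat gb1 = zeros(n1, 1), gb2 = zeros(n2, 1), gbfc = zeros(fc, 1),
          gbout = zeros(2, 1);
      p.b1 = b1M.col(0); p.b2 = b2M.col(0);
      p.bfc = bfcM.col(0); p.bout = boutM.col(0);
      double bloss = 0.0;
      for (int j = 0; j < B; ++j) {
        int i = idx[s0 + j];
        CnnCache cc;
        vec s = cnn_forward(X.col(i), p, dropout, true, rng, &cc);
        // softmax CE for one sample
        vec P = exp(s - s.max());
        P /= accu(P);
        int yy = y(i);
        bloss += -std::log(std::max(P(yy), 1e-12));
        if ((P(1) > P(0) ? 1 : 0) == yy) ++ep_correct;
        vec dS = P;
        dS(yy) -= 1.0;

        vec hd = cc.hfc_r.col(1);
        gWout += dS * hd.t();
        gbout += dS;
        vec dhd = p.Wout.t() * dS;
        vec hfc_pre = cc.hfc_r.col(0);
        vec dhfc = dhd % cc.dfc_mask % conv_to<vec>::from(hfc_pre > 0);
        gWfc += dhfc * cc.flat.t();
        gbfc += dhfc;
        vec dflat = p.Wfc.t() * dhfc;
        mat dpool2 = reshape(dflat, n2, D / 4);
        // unpool 2
        mat dA2d = zeros(n2, D / 2);
        for (int c = 0; c < n2; ++c)
          for (int q = 0; q < D / 4; ++q)
            dA2d(c, cc.arg2(c, q)) += dpool2(c, q);
        mat dA2 = dA2d % cc.D2 % conv_to<mat>::from(cc.A2r > 0);
        gW2 += dA2 * cc.P2.t();
        gb2 += sum(dA2, 1);
        mat dP2 = p.W2.t() * dA2;
        mat dpool1 = col2im5(dP2, n1, D / 2);
        mat dA1d = zeros(n1, D);
        for (int c = 0; c < n1; ++c)
          for (int q = 0; q < D / 2; ++q)
            dA1d(c, cc.arg1(c, q)) += dpool1(c, q);
        mat dA1 = dA1d % cc.D1 % conv_to<mat>::from(cc.A1r > 0);
        gW1 += dA1 * cc.P1.t();
        gb1 += sum(dA1, 1);
      }
      for (auto gp : { &gW1, &gb1, &gW2, &gb2, &gWfc, &gbfc, &gWout, &gbout })
        *gp /= B;
      std::vector<mat*> grads = { &gW1, &gb1, &gW2, &gb2, &gWfc, &gbfc,
                                  &gWout, &gbout };
      opt.step(params, grads);
      bloss /= B;
      ep_loss += bloss; ++nb;
    }
    loss_hist(ep) = ep_loss / nb;
    acc_hist(ep) = (double)ep_correct / N;
  }
  p.b1 = b1M.col(0); p.b2 = b2M.col(0); p.bfc = bfcM.col(0);
  p.bout = boutM.col(0);
  return List::create(Named("W1") = p.W1, Named("b1") = p.b1,
                      Named("W2") = p.W2, Named("b2") = p.b2,
                      Named("Wfc") = p.Wfc, Named("bfc") = p.bfc,
                      Named("Wout") = p.Wout, Named("bout") = p.bout,
                      Named("loss") = loss_hist, Named("train_acc") = acc_hist);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_apply(const arma::mat& X, const arma::mat& W1,
                        const arma::vec& b1, const arma::mat& W2,
                        const arma::vec& b2, const arma::mat& Wfc,
                        const arma::vec& bfc, const arma::mat& Wout,
                        const arma::vec& bout) {
  CnnParams p;
  p.W1 = W1; p.b1 = b1; p.W2 = W2; p.b2 = b2;
  p.Wfc = Wfc; p.bfc = bfc; p.Wout = Wout; p.bout = bout;
  std::mt19937 rng(0);
  mat out(X.n_cols, 2);
  for (uword i = 0; i < X.n_cols; ++i) {
    vec s = cnn_forward(X.col(i), p, 0.0, false, rng, nullptr);
    out(i, 0) = s(0);
    out(i, 1) = s(1);
  }
  return out;
}
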