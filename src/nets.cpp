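// Compiled training loops for the adversarial augmenter and the LSTM
// classifier. The networks are small but the training protocols run for
// thousands of epochs, so the per-batch arithmetic lives here; all
// initialization, forward passes for prediction, and bookkeeping stay in R.
// Layouts mirror the R code exactly: sequence slabs are matrices
// [batch x (L * channels)] with column index ch * L + t (column-major
// equivalent of R's array(dim = c(B, L, C))). All randomness is drawn from
// R's RNG so set.seed() upstream makes training deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat lrelu(const mat& x, double a = 0.2) {
  return arma::max(x, a * x);
}
static inline mat d_lrelu(const mat& x, double a = 0.2) {
  return conv_to<mat>::from(x > 0) * (1.0 - a) + a;
}

// uniform(-1, 1) noise from R's RNG
static mat r_unif_mat(int n, int m) {
  mat z(n, m);
  for (uword j = 0; j < z.n_cols; ++j)
    for (uword i = 0; i < z.n_rows; ++i) z(i, j) = R::runif(-1.0, 1.0);
  return z;
}

static uvec r_shuffle(int n) {
  // Fisher-Yates with R's RNG (matches determinism, not R's sample order)
  uvec idx = regspace<uvec>(0, n - 1);
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
  return idx;
}

struct Adam {
  mat m, v;
  void init(const mat& p) { m = zeros(size(p)); v = zeros(size(p)); }
  void step(mat& p, const mat& g, double lr, double b1, double b2, int t) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    double corr = lr * std::sqrt(1 - std::pow(b2, t)) / (1 - std::pow(b1, t));
    p -= corr * m / (sqrt(v) + 1e-8);
  }
};

// 1-D same-padding convolution helpers on slab layout
// x: [B x (L*Cin)], K: [k x (Cin*Cout)] with column index cin * Cout + cout
// (we instead store K as cube for clarity)
static void conv1d_fwd(const mat& x, int L, int cin, const cube& K,
                       const rowvec& b, mat& out) {
  int B = x.n_rows, k = K.n_rows, cout_n = K.n_slices, half = (k - 1) / 2;
  out.zeros(B, L * cout_n);
  for (int co = 0; co < cout_n; ++co) {
    for (int t = 0; t < L; ++t) {
      colvec acc(B, fill::value(b[co]));
      for (int j = 0; j < k; ++j) {
        int s = t + j - half;
        if (s < 0 || s >= L) continue;
        for (int ci = 0; ci < cin; ++ci) {
          acc += K(j, ci, co) * x.col(ci * L + s);
        }
      }
      out.col(co * L + t) = acc;
    }
  }
}

static void conv1d_bwd(const mat& x, int L, int cin, const cube& K,
                       const mat& dout, cube& dK, rowvec& db, mat& dx,
                       bool need_dx) {
  int B = x.n_rows, k = K.n_rows, cout_n = K.n_slices, half = (k - 1) / 2;
  dK.zeros(k, cin, cout_n);
  db.zeros(cout_n);
  if (need_dx) dx.zeros(B, L * cin);
  for (int co = 0; co < cout_n; ++co) {
    for (int t = 0; t < L; ++t) {
      const colvec& g = dout.col(co * L + t);
      db[co] += accu(g);
      for (int j = 0; j < k; ++j) {
        int s = t + j - half;
        if (s < 0 || s >= L) continue;
        for (int ci = 0; ci < cin; ++ci) {
          dK(j, ci, co) += dot(x.col(ci * L + s), g);
          if (need_dx) dx.col(ci * L + s) += K(j, ci, co) * g;
        }
      }
    }
  }
}

static double bce_logits(const mat& logit, const mat& y) {
  mat l = arma::max(logit, zeros(size(logit))) - logit % y +
          log1p(exp(-abs(logit)));
  return accu(l) / logit.n_elem;
}

struct GenNet {
  mat W0, W1;
  rowvec b0, b1;
  cube K; // [k x f x 1]
  double bK;
};

struct GenCache {
  mat z, pre0, h0, pre1, h1, o, x;
};

static void gen_fwd(const GenNet& g, const mat& z, int L, int f, GenCache& c) {
  c.z = z;
  c.pre0 = z * g.W0; c.pre0.each_row() += g.b0;
  c.h0 = arma::max(c.pre0, zeros(size(c.pre0)));
  c.pre1 = c.h0 * g.W1; c.pre1.each_row() += g.b1;
  c.h1 = arma::max(c.pre1, zeros(size(c.pre1)));
  rowvec bk(1); bk[0] = g.bK;
  conv1d_fwd(c.h1, L, f, g.K, bk, c.o);
  c.x = tanh(c.o);
}

struct Disc {
  cube K; // [k x 1 x f]
  rowvec bK;
  mat W1, W2;
  rowvec b1;
  double b2;
};

struct DiscCache {
  mat x, c1, a1, pre_h, h, logit;
};

static void disc_fwd(const Disc& d, const mat& x, int L, int f, DiscCache& c) {
  c.x = x;
  conv1d_fwd(x, L, 1, d.K, d.bK, c.c1);
  c.a1 = lrelu(c.c1);
  c.pre_h = c.a1 * d.W1; c.pre_h.each_row() += d.b1;
  c.h = lrelu(c.pre_h);
  c.logit = c.h * d.W2 + d.b2;
}

struct DiscGrads {
  cube dK;
  rowvec dbK;
  mat dW1, dW2;
  rowvec db1;
  double db2;
  mat dx;
};

static void disc_bwd(const Disc& d, const DiscCache& c, const mat& dlogit,
                     int L, int f, DiscGrads& g, bool need_dx,
                     bool need_wgrads = true) {
  if (need_wgrads) {
    g.dW2 = c.h.t() * dlogit;
    g.db2 = accu(dlogit);
  }
  mat dh = (dlogit * d.W2.t()) % d_lrelu(c.pre_h);
  if (need_wgrads) {
    g.dW1 = c.a1.t() * dh;
    g.db1 = sum(dh, 0);
  }
  mat da1 = (dh * d.W1.t()) % d_lrelu(c.c1);
  if (need_wgrads) {
    conv1d_bwd(c.x, L, 1, d.K, da1, g.dK, g.dbK, g.dx, need_dx);
  } else {
    // input gradient only (generator update path): kernel taps accumulate
    // into dx without touching the discriminator weight gradients
    int k = d.K.n_rows, half = (k - 1) / 2;
    g.dx.zeros(c.x.n_rows, L);
    for (int co = 0; co < f; ++co) {
      for (int t = 0; t < L; ++t) {
        const colvec gcol = da1.col(co * L + t);
        for (int j = 0; j < k; ++j) {
          int ssrc = t + j - half;
          if (ssrc < 0 || ssrc >= L) continue;
          g.dx.col(ssrc) += d.K(j, 0, co) * gcol;
        }
      }
    }
  }
}

// [[Rcpp::export]]
Rcpp::List dcgan_train_cpp(const arma::mat& X, Rcpp::List init,
                           int epochs, int batch_size, double lr,
                           double beta1, int noise_dim, int filters,
                           int kernel, bool lr_decay) {
  Rcpp::RNGScope scope;
  int n = X.n_rows, L = X.n_cols, f = filters;
  Rcpp::List gi = init["g"], di = init["d"];
  GenNet G;
  G.W0 = Rcpp::as<mat>(gi["W0"]); G.b0 = Rcpp::as<rowvec>(gi["b0"]);
  G.W1 = Rcpp::as<mat>(gi["W1"]); G.b1 = Rcpp::as<rowvec>(gi["b1"]);
  {
    mat Kg = Rcpp::as<mat>(gi["K"]); // k x f (single output channel)
    G.K.set_size(kernel, f, 1);
    G.K.slice(0) = Kg;
    G.bK = Rcpp::as<double>(gi["bK"]);
  }
  Disc D;
  {
    mat Kd = Rcpp::as<mat>(di["K"]); // k x f (single input channel)
    D.K.set_size(kernel, 1, f);
    for (int j = 0; j < kernel; ++j)
      for (int co = 0; co < f; ++co) D.K(j, 0, co) = Kd(j, co);
    D.bK = Rcpp::as<rowvec>(di["bK"]);
    D.W1 = Rcpp::as<mat>(di["W1"]); D.b1 = Rcpp::as<rowvec>(di["b1"]);
    D.W2 = Rcpp::as<mat>(di["W2"]); D.b2 = Rcpp::as<double>(di["b2"]);
  }
  Adam aGW0, aGb0, aGW1, aGb1, aGK, aGbK;
  aGW0.init(G.W0); aGb0.init(G.b0); aGW1.init(G.W1); aGb1.init(G.b1);
  aGK.init(G.K.slice(0)); mat gbk(1, 1, fill::zeros); aGbK.init(gbk);
  Adam aDK, aDbK, aDW1, aDb1, aDW2, aDb2;
  mat DKm(kernel, f);
  for (int j = 0; j < kernel; ++j)
    for (int co = 0; co < f; ++co) DKm(j, co) = D.K(j, 0, co);
  aDK.init(DKm); aDbK.init(D.bK); aDW1.init(D.W1); aDb1.init(D.b1);
  aDW2.init(D.W2); mat db2m(1, 1, fill::zeros); aDb2.init(db2m);

  vec d_loss(epochs), g_loss(epochs);
  GenCache gc; DiscCache dc; DiscGrads dg;
  int t_adam = 0;
  double lr0 = lr;
  for (int ep = 0; ep < epochs; ++ep) {
    // variable learning rate: linear decay from the configured value
    lr = lr_decay ? lr0 * (1.0 - (double)ep / epochs) + 1e-5 : lr0;
    uvec idx = r_shuffle(n);
    int nb = (n + batch_size - 1) / batch_size; // partial final batch kept
    double dl = 0, gl = 0;
    for (int b = 0; b < nb; ++b) {
      int lo = b * batch_size;
      int hi = std::min(lo + batch_size, n) - 1;
      mat real = X.rows(idx.subvec(lo, hi));
      int B = real.n_rows;
      mat z = r_unif_mat(B, noise_dim);
      gen_fwd(G, z, L, f, gc);
      mat fake = gc.x;
      // --- discriminator step on real + fake
      mat xb = join_cols(real, fake);
      mat yb = join_cols(ones(B, 1), zeros(B, 1));
      disc_fwd(D, xb, L, f, dc);
      dl += bce_logits(dc.logit, yb);
      mat dlogit = (1.0 / (1.0 + exp(-dc.logit)) - yb) / (2.0 * B);
      disc_bwd(D, dc, dlogit, L, f, dg, false);
      ++t_adam;
      {
        mat dKm(kernel, f);
        for (int j = 0; j < kernel; ++j)
          for (int co = 0; co < f; ++co) dKm(j, co) = dg.dK(j, 0, co);
        aDK.step(DKm, dKm, lr, beta1, 0.999, t_adam);
        for (int j = 0; j < kernel; ++j)
          for (int co = 0; co < f; ++co) D.K(j, 0, co) = DKm(j, co);
        mat bk = conv_to<mat>::from(D.bK), dbk = conv_to<mat>::from(dg.dbK);
        aDbK.step(bk, dbk, lr, beta1, 0.999, t_adam);
        D.bK = conv_to<rowvec>::from(bk);
        aDW1.step(D.W1, dg.dW1, lr, beta1, 0.999, t_adam);
        mat b1m = conv_to<mat>::from(D.b1), db1m = conv_to<mat>::from(dg.db1);
        aDb1.step(b1m, db1m, lr, beta1, 0.999, t_adam);
        D.b1 = conv_to<rowvec>::from(b1m);
        aDW2.step(D.W2, dg.dW2, lr, beta1, 0.999, t_adam);
        mat b2g(1, 1); b2g(0, 0) = dg.db2;
        db2m(0, 0) = D.b2;
        aDb2.step(db2m, b2g, lr, beta1, 0.999, t_adam);
        D.b2 = db2m(0, 0);
      }
      // --- generator step: reuse the minibatch noise and the cached
      // generator forward (G unchanged during the discriminator update)
      disc_fwd(D, gc.x, L, f, dc);
      gl += bce_logits(dc.logit, ones(B, 1));
      mat dlogit2 = (1.0 / (1.0 + exp(-dc.logit)) - 1.0) / B;
      disc_bwd(D, dc, dlogit2, L, f, dg, true, false);
      // backprop into the generator
      mat dxo = dg.dx % (1 - square(tanh(gc.o)));
      cube dKg; rowvec dbKg; mat dh1raw;
      conv1d_bwd(gc.h1, L, f, G.K, dxo, dKg, dbKg, dh1raw, true);
      mat dh1 = dh1raw % conv_to<mat>::from(gc.pre1 > 0);
      mat dW1 = gc.h0.t() * dh1;
      rowvec db1 = sum(dh1, 0);
      mat dh0 = (dh1 * G.W1.t()) % conv_to<mat>::from(gc.pre0 > 0);
      mat dW0 = z.t() * dh0;
      rowvec db0 = sum(dh0, 0);
      aGW0.step(G.W0, dW0, lr, beta1, 0.999, t_adam);
      mat b0m = conv_to<mat>::from(G.b0), db0m = conv_to<mat>::from(db0);
      aGb0.step(b0m, db0m, lr, beta1, 0.999, t_adam);
      G.b0 = conv_to<rowvec>::from(b0m);
      aGW1.step(G.W1, dW1, lr, beta1, 0.999, t_adam);
      mat b1m = conv_to<mat>::from(G.b1), db1m = conv_to<mat>::from(db1);
      aGb1.step(b1m, db1m, lr, beta1, 0.999, t_adam);
      G.b1 = conv_to<rowvec>::from(b1m);
      mat Kg = G.K.slice(0);
      aGK.step(Kg, dKg.slice(0), lr, beta1, 0.999, t_adam);
      G.K.slice(0) = Kg;
      mat bkg(1, 1); bkg(0, 0) = G.bK;
      mat dbkg(1, 1); dbkg(0, 0) = dbKg[0];
      aGbK.step(bkg, dbkg, lr, beta1, 0.999, t_adam);
      G.bK = bkg(0, 0);
    }
    d_loss[ep] = dl / nb;
    g_loss[ep] = gl / nb;
  }
  mat Kd_out(kernel, f);
  for (int j = 0; j < kernel; ++j)
    for (int co = 0; co < f; ++co) Kd_out(j, co) = D.K(j, 0, co);
  return Rcpp::List::create(
    Rcpp::Named("g") = Rcpp::List::create(
      Rcpp::Named("W0") = G.W0, Rcpp::Named("b0") = G.b0,
      Rcpp::Named("W1") = G.W1, Rcpp::Named("b1") = G.b1,
      Rcpp::Named("K") = G.K.slice(0), Rcpp::Named("bK") = G.bK),
    Rcpp::Named("d") = Rcpp::List::create(
      Rcpp::Named("K") = Kd_out, Rcpp::Named("bK") = D.bK,
      Rcpp::Named("W1") = D.W1, Rcpp::Named("b1") = D.b1,
      Rcpp::Named("W2") = D.W2, Rcpp::Named("b2") = D.b2),
    Rcpp::Named("d_loss") = d_loss,
    Rcpp::Named("g_loss") = g_loss);
}

// [[Rcpp::export]]
arma::mat gen_sample_cpp(Rcpp::List gpar, const arma::mat& z, int L, int filters) {
  GenNet G;
  G.W0 = Rcpp::as<mat>(gpar["W0"]); G.b0 = Rcpp::as<rowvec>(gpar["b0"]);
  G.W1 = Rcpp::as<mat>(gpar["W1"]); G.b1 = Rcpp::as<rowvec>(gpar["b1"]);
  mat Kg = Rcpp::as<mat>(gpar["K"]);
  G.K.set_size(Kg.n_rows, filters, 1);
  G.K.slice(0) = Kg;
  G.bK = Rcpp::as<double>(gpar["bK"]);
  GenCache c;
  gen_fwd(G, z, L, filters, c);
  return c.x;
}

// ---------------- LSTM (single step) ------------------------------------

// [[Rcpp::export]]
Rcpp::List lstm_train_cpp(const arma::mat& X, const arma::ivec& y,
                          Rcpp::List init, int epochs, int batch_size,
                          int units, double lr, double decay) {
  Rcpp::RNGScope scope;
  int n = X.n_rows;
  mat W = Rcpp::as<mat>(init["W"]);
  rowvec b = Rcpp::as<rowvec>(init["b"]);
  mat U = Rcpp::as<mat>(init["U"]); // unused at t=1 (h0 = 0) but carried
  mat Wy = Rcpp::as<mat>(init["Wy"]);
  rowvec by = Rcpp::as<rowvec>(init["by"]);
  mat vW = zeros(size(W)), vWy = zeros(size(Wy));
  rowvec vb = zeros<rowvec>(b.n_elem), vby = zeros<rowvec>(by.n_elem);
  int u = units;
  vec loss(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    uvec idx = r_shuffle(n);
    int nb = n / batch_size;
    if (nb < 1) nb = 1;
    double tot = 0;
    for (int bI = 0; bI < nb; ++bI) {
      int lo = bI * batch_size;
      int hi = (bI == nb - 1) ? n - 1 : (bI + 1) * batch_size - 1;
      uvec rows = idx.subvec(lo, hi);
      mat Xb = X.rows(rows);
      int B = Xb.n_rows;
      mat Y(B, 2);
      for (int i = 0; i < B; ++i) {
        int yi = y[rows[i]];
        Y(i, 0) = 1 - yi; Y(i, 1) = yi;
      }
      mat zg = Xb * W; zg.each_row() += b;
      mat gi = 1.0 / (1.0 + exp(-zg.cols(0, u - 1)));
      mat gcell = tanh(zg.cols(2 * u, 3 * u - 1));
      mat go = 1.0 / (1.0 + exp(-zg.cols(3 * u, 4 * u - 1)));
      mat cell = gi % gcell;
      mat tc = tanh(cell);
      mat h = go % tc;
      mat logits = h * Wy; logits.each_row() += by;
      vec mx = arma::max(logits, 1);
      mat el = exp(logits.each_col() - mx);
      mat probs = el.each_col() / sum(el, 1);
      tot += -accu(log(sum(probs % Y, 1) + 1e-12));
      mat dlogits = (probs - Y) / B;
      mat dWy = h.t() * dlogits;
      rowvec dby = sum(dlogits, 0);
      mat dh = dlogits * Wy.t();
      mat dgo = dh % tc % go % (1 - go);
      mat dcell = dh % go % (1 - square(tc));
      mat dgi = dcell % gcell % gi % (1 - gi);
      mat dgc = dcell % gi % (1 - square(gcell));
      mat dz(B, 4 * u, fill::zeros);
      dz.cols(0, u - 1) = dgi;
      dz.cols(2 * u, 3 * u - 1) = dgc;
      dz.cols(3 * u, 4 * u - 1) = dgo;
      mat dW = Xb.t() * dz;
      rowvec db = sum(dz, 0);
      vW = decay * vW + (1 - decay) * square(dW);
      W -= lr * dW / (sqrt(vW) + 1e-8);
      vb = decay * vb + (1 - decay) * square(db);
      b -= lr * db / (sqrt(vb) + 1e-8);
      vWy = decay * vWy + (1 - decay) * square(dWy);
      Wy -= lr * dWy / (sqrt(vWy) + 1e-8);
      vby = decay * vby + (1 - decay) * square(dby);
      by -= lr * dby / (sqrt(vby) + 1e-8);
    }
    loss[ep] = tot / n;
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("b") = b, Rcpp::Named("U") = U,
    Rcpp::Named("Wy") = Wy, Rcpp::Named("by") = by,
    Rcpp::Named("loss") = loss);
}
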