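// Fast training loop for the attention encoder + inductive matrix
// completion model. Mirrors the reference R implementation in
// R/model.R / R/train.R (forward_backward + adam_step); the test suite
// pins the two paths to each other.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat lrelu(const mat& x, double slope) {
  return arma::max(x, zeros(size(x))) + slope * arma::min(x, zeros(size(x)));
}

static inline mat lrelu_grad(const mat& x, double slope) {
  mat g(size(x));
  g.fill(slope);
  g.elem(find(x >= 0)).fill(1.0);
  return g;
}

struct AdamState {
  mat m, v;
  AdamState() {}
  explicit AdamState(const mat& p) : m(size(p), fill::zeros),
                                     v(size(p), fill::zeros) {}
  void step(mat& p, const mat& g, double lr, double wd,
            double c1, double c2) {
    const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
    m = beta1 * m + (1 - beta1) * g;
    v = beta2 * v + (1 - beta2) * (g % g);
    p -= lr * ((m / c1) / (sqrt(v / c2) + eps) + wd * p);
  }
};

struct HeadCache {
  mat XW, Zpre, alpha, HN, S, C, P1, P2, B1, B2, Mk;
};

// forward through one head; fills the cache
static void head_forward(const mat& X, const uvec& off_mask,
                         const vec& W, const vec& a,
                         const mat& W1_sum, const mat& W1_cat,
                         double slope, bool plain_gat, HeadCache& c) {
  const uword N = X.n_rows, d = X.n_cols;
  c.XW = X.each_row() % W.t();
  vec a1 = a.subvec(0, d - 1), a2 = a.subvec(d, 2 * d - 1);
  vec u = c.XW * a1, v = c.XW * a2;
  c.Zpre.set_size(N, N);
  c.Zpre.each_col() = u;
  c.Zpre.each_row() += v.t();
  mat E = lrelu(c.Zpre, slope);
  E.elem(off_mask).fill(-datum::inf);
  vec rowmax = arma::max(E, 1);
  mat A = exp(E.each_col() - rowmax);
  A.elem(off_mask).fill(0.0);
  c.alpha = A.each_col() / sum(A, 1);
  c.HN = c.alpha * X;
  c.S = X + c.HN;
  c.C = join_rows(X, c.HN);
  c.P2 = c.C * W1_cat;
  c.B2 = lrelu(c.P2, slope);
  if (plain_gat) {
    c.Mk = c.B2;
  } else {
    c.P1 = c.S * W1_sum;
    c.B1 = lrelu(c.P1, slope);
    c.Mk = c.B1 + c.B2 + c.B1 % c.B2;
  }
}

// backward through one head; returns parameter gradients
static void head_backward(const mat& X, const HeadCache& c,
                          const vec& W, const vec& a,
                          const mat& W1_sum, const mat& W1_cat,
                          const mat& dMk, double slope, bool plain_gat,
                          vec& gW, vec& ga, mat& gW1_sum, mat& gW1_cat) {
  const uword d = X.n_cols;
  mat dHN;
  if (plain_gat) {
    mat dP2 = dMk % lrelu_grad(c.P2, slope);
    gW1_cat = c.C.t() * dP2;
    gW1_sum.zeros(W1_sum.n_rows, W1_sum.n_cols);
    mat dC = dP2 * W1_cat.t();
    dHN = dC.cols(d, 2 * d - 1);
  } else {
    mat dB1 = dMk % (1 + c.B2);
    mat dB2 = dMk % (1 + c.B1);
    mat dP1 = dB1 % lrelu_grad(c.P1, slope);
    mat dP2 = dB2 % lrelu_grad(c.P2, slope);
    gW1_sum = c.S.t() * dP1;
    gW1_cat = c.C.t() * dP2;
    mat dS = dP1 * W1_sum.t();
    mat dC = dP2 * W1_cat.t();
    dHN = dS + dC.cols(d, 2 * d - 1);
  }
  mat dalpha = dHN * X.t();
  vec rowdot = sum(c.alpha % dalpha, 1);
  mat dE = c.alpha % (dalpha.each_col() - rowdot);
  mat dZ = dE % lrelu_grad(c.Zpre, slope);
  vec du = sum(dZ, 1);
  vec dv = sum(dZ, 0).t();
  vec a1 = a.subvec(0, d - 1), a2 = a.subvec(d, 2 * d - 1);
  ga = join_cols(c.XW.t() * du, c.XW.t() * dv);
  mat dXW = du * a1.t() + dv * a2.t();
  gW = sum(dXW % X, 0).t();
}

// [[Rcpp::export(name = ".train_core_cpp")]]
Rcpp::List train_core_cpp(const arma::mat& A, const arma::mat& X,
                          const arma::umat& mask, Rcpp::List heads_init,
                          const arma::mat& Pd0, const arma::mat& Pl0,
                          int nd, int nl, double slope, double lambda,
                          double lr, double wd, int epochs,
                          bool plain_gat) {
  const uword N = X.n_rows;
  const int H = heads_init.size();
  uvec off_mask = find(mask == 0);

  std::vector<vec> Wh(H), ah(H);
  std::vector<mat> W1s(H), W1c(H);
  for (int h = 0; h < H; ++h) {
    Rcpp::List hp = heads_init[h];
    Wh[h] = Rcpp::as<vec>(hp["W"]);
    ah[h] = Rcpp::as<vec>(hp["a"]);
    W1s[h] = Rcpp::as<mat>(hp["W1_sum"]);
    W1c[h] = Rcpp::as<mat>(hp["W1_cat"]);
  }
  mat Pd = Pd0, Pl = Pl0;
  const uword k = W1s[0].n_cols;

  std::vector<AdamState> sW, sa, sW1s, sW1c;
  for (int h = 0; h < H; ++h) {
    sW.emplace_back(mat(Wh[h]));
    sa.emplace_back(mat(ah[h]));
    sW1s.emplace_back(W1s[h]);
    sW1c.emplace_back(W1c[h]);
  }
  AdamState sPd(Pd), sPl(Pl);

  vec losses(epochs, fill::zeros);
  std::vector<HeadCache> caches(H);

  for (int ep = 0; ep < epochs; ++ep) {
    // forward
    mat M(N, H * k);
    for (int h = 0; h < H; ++h) {
      head_forward(X, off_mask, Wh[h], ah[h], W1s[h], W1c[h], slope,
                   plain_gat, caches[h]);
      M.cols(h * k, (h + 1) * k - 1) = caches[h].Mk;
    }
    mat Md = M.rows(0, nd - 1);
    mat Ml = M.rows(nd, N - 1);
    mat Ud = Md * Pd;
    mat Ul = Ml * Pl;
    // linear low-rank reconstruction; scores are squashed only on report
    mat G = Ul * Ud.t();
    mat diff = G - A;
    double pen = accu(Pd % Pd) + accu(Pl % Pl);
    for (int h = 0; h < H; ++h) {
      pen += accu(W1s[h] % W1s[h]) + accu(W1c[h] % W1c[h]);
    }
    double loss = accu(diff % diff) + lambda * pen;
    losses(ep) = loss;
    if (!std::isfinite(loss)) {
      Rcpp::stop("training diverged at epoch %d (non-finite loss)", ep + 1);
    }

    // backward
    mat dG = 2 * diff;
    mat dUl = dG * Ud;
    mat dUd = dG.t() * Ul;
    mat gPl = Ml.t() * dUl + 2 * lambda * Pl;
    mat gPd = Md.t() * dUd + 2 * lambda * Pd;
    mat dM = join_cols(dUd * Pd.t(), dUl * Pl.t());

    double c1 = 1 - std::pow(0.9, ep + 1);
    double c2 = 1 - std::pow(0.999, ep + 1);
    for (int h = 0; h < H; ++h) {
      vec gW, ga;
      mat gW1_sum, gW1_cat;
      head_backward(X, caches[h], Wh[h], ah[h], W1s[h], W1c[h],
                    dM.cols(h * k, (h + 1) * k - 1), slope, plain_gat,
                    gW, ga, gW1_sum, gW1_cat);
      gW1_sum += 2 * lambda * W1s[h];
      gW1_cat += 2 * lambda * W1c[h];
      mat Wm(Wh[h]), am(ah[h]);
      sW[h].step(Wm, mat(gW), lr, wd, c1, c2);
      sa[h].step(am, mat(ga), lr, wd, c1, c2);
      Wh[h] = Wm.col(0);
      ah[h] = am.col(0);
      sW1s[h].step(W1s[h], gW1_sum, lr, wd, c1, c2);
      sW1c[h].step(W1c[h], gW1_cat, lr, wd, c1, c2);
    }
    sPd.step(Pd, gPd, lr, wd, c1, c2);
    sPl.step(Pl, gPl, lr, wd, c1, c2);
  }

  Rcpp::List heads_out(H);
  for (int h = 0; h < H; ++h) {
    heads_out[h] = Rcpp::List::create(
      Rcpp::Named("W") = Wh[h], Rcpp::Named("a") = ah[h],
      Rcpp::Named("W1_sum") = W1s[h], Rcpp::Named("W1_cat") = W1c[h]);
  }
  return Rcpp::List::create(
    Rcpp::Named("heads") = heads_out,
    Rcpp::Named("Pd") = Pd, Rcpp::Named("Pl") = Pl,
    Rcpp::Named("losses") = losses);
}
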