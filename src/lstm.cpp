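// Bidirectional LSTM binary sequence classifier: batched forward pass and
// backpropagation through time, Adam updates, early stopping on validation
// accuracy. Sequences are front-aligned in (D x B x T) cubes; the readout for
// sequence b is the hidden state at its last real time step, so gradients at
// padded steps vanish identically and no explicit mask is required in the
// backward pass. All randomness (initialisation, shuffling) comes from R's
// RNG, so results are reproducible under set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::Named;
using Rcpp::stop;

struct Dir { mat W, U; vec b; };           // one LSTM direction
struct Net {
  Dir f, r;                                // forward / reverse directions
  std::vector<mat> Wd;                     // dense head (last layer 1 row)
  std::vector<vec> bd;
};

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

static double runif_sym(double s) { return (2.0 * R::unif_rand() - 1.0) * s; }

static mat rand_mat(int r, int c) {
  double s = std::sqrt(6.0 / (r + c));
  mat m(r, c);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = runif_sym(s);
  return m;
}

static Net net_init(int D, int H, const std::vector<int>& widths) {
  Net n;
  for (Dir* d : {&n.f, &n.r}) {
    d->W = rand_mat(4 * H, D);
    d->U = rand_mat(4 * H, H);
    d->b = zeros<vec>(4 * H);
    d->b.subvec(H, 2 * H - 1).fill(1.0); // forget-gate bias
  }
  int in = 2 * H;
  for (int w : widths) {
    n.Wd.push_back(rand_mat(w, in));
    n.bd.push_back(zeros<vec>(w));
    in = w;
  }
  n.Wd.push_back(rand_mat(1, in));
  n.bd.push_back(zeros<vec>(1));
  return n;
}

static Net net_zeros_like(const Net& n) {
  Net z;
  for (int k = 0; k < 2; ++k) {
    const Dir& s = k ? n.r : n.f;
    Dir& d = k ? z.r : z.f;
    d.W = zeros<mat>(size(s.W));
    d.U = zeros<mat>(size(s.U));
    d.b = zeros<vec>(size(s.b));
  }
  for (size_t i = 0; i < n.Wd.size(); ++i) {
    z.Wd.push_back(zeros<mat>(size(n.Wd[i])));
    z.bd.push_back(zeros<vec>(size(n.bd[i])));
  }
  return z;
}

// ---- forward / backward for one direction ----------------------------------

struct Cache { cube G, C, Hs; }; // activated gates (4H), cell, hidden

static void dir_forward(const Dir& d, const cube& X, Cache& cc) {
  const int H = d.U.n_cols, B = X.n_cols, T = X.n_slices;
  cc.G.set_size(4 * H, B, T);
  cc.C.set_size(H, B, T);
  cc.Hs.set_size(H, B, T);
  mat h = zeros<mat>(H, B), c = zeros<mat>(H, B);
  for (int t = 0; t < T; ++t) {
    mat A = d.W * X.slice(t) + d.U * h;
    A.each_col() += d.b;
    mat gi = sigm(A.rows(0, H - 1));
    mat gf = sigm(A.rows(H, 2 * H - 1));
    mat gg = tanh(A.rows(2 * H, 3 * H - 1));
    mat go = sigm(A.rows(3 * H, 4 * H - 1));
    c = gf % c + gi % gg;
    h = go % tanh(c);
    cc.G.slice(t) = join_cols(join_cols(gi, gf), join_cols(gg, go));
    cc.C.slice(t) = c;
    cc.Hs.slice(t) = h;
  }
}

static mat dir_readout(const cube& Hs, const std::vector<int>& len) {
  mat Z(Hs.n_rows, Hs.n_cols);
  for (uword b = 0; b < Hs.n_cols; ++b)
    Z.col(b) = Hs.slice(len[b] - 1).col(b);
  return Z;
}

static void dir_backward(const Dir& d, const cube& X, const Cache& cc,
                         const mat& dZ, const std::vector<int>& len,
                         Dir& g) {
  const int H = d.U.n_cols, B = X.n_cols, T = X.n_slices;
  g.W = zeros<mat>(size(d.W));
  g.U = zeros<mat>(size(d.U));
  g.b = zeros<vec>(size(d.b));
  mat dh_next = zeros<mat>(H, B), dc_next = zeros<mat>(H, B);
  for (int t = T - 1; t >= 0; --t) {
    mat dh = dh_next;
    for (int b = 0; b < B; ++b)
      if (len[b] - 1 == t) dh.col(b) += dZ.col(b);
    const mat gi = cc.G.slice(t).rows(0, H - 1);
    const mat gf = cc.G.slice(t).rows(H, 2 * H - 1);
    const mat gg = cc.G.slice(t).rows(2 * H, 3 * H - 1);
    const mat go = cc.G.slice(t).rows(3 * H, 4 * H - 1);
    const mat tc = tanh(cc.C.slice(t));
    mat dc = dc_next + dh % go % (1.0 - tc % tc);
    mat c_prev = (t > 0) ? mat(cc.C.slice(t - 1)) : zeros<mat>(H, B);
    mat h_prev = (t > 0) ? mat(cc.Hs.slice(t - 1)) : zeros<mat>(H, B);
    mat dAi = (dc % gg) % gi % (1.0 - gi);
    mat dAf = (dc % c_prev) % gf % (1.0 - gf);
    mat dAg = (dc % gi) % (1.0 - gg % gg);
    mat dAo = (dh % tc) % go % (1.0 - go);
    mat dA = join_cols(join_cols(dAi, dAf), join_cols(dAg, dAo));
    g.W += dA * X.slice(t).t();
    g.U += dA * h_prev.t();
    g.b += sum(dA, 1);
    dh_next = d.U.t() * dA;
    dc_next = dc % gf;
  }
}

// ---- full network -----------------------------------------------------------

// forward only: probabilities for a batch
static rowvec net_prob(const Net& n, const cube& Xf, const cube& Xr,
                       const std::vector<int>& len) {
  Cache cf, cr;
  dir_forward(n.f, Xf, cf);
  dir_forward(n.r, Xr, cr);
  mat z = join_cols(dir_readout(cf.Hs, len), dir_readout(cr.Hs, len));
  for (size_t l = 0; l + 1 < n.Wd.size(); ++l) {
    z = n.Wd[l] * z;
    z.each_col() += n.bd[l];
    z = clamp(z, 0.0, datum::inf); // ReLU
  }
  mat logit = n.Wd.back() * z;
  logit.each_col() += n.bd.back();
  return sigm(logit.row(0));
}

// loss + gradient on a batch; mean binary cross-entropy
static double net_grad(const Net& n, const cube& Xf, const cube& Xr,
                       const std::vector<int>& len, const rowvec& y,
                       Net& g) {
  const int B = Xf.n_cols;
  Cache cf, cr;
  dir_forward(n.f, Xf, cf);
  dir_forward(n.r, Xr, cr);
  mat zf = dir_readout(cf.Hs, len), zr = dir_readout(cr.Hs, len);
  std::vector<mat> acts; // layer inputs
  mat z = join_cols(zf, zr);
  acts.push_back(z);
  for (size_t l = 0; l + 1 < n.Wd.size(); ++l) {
    z = n.Wd[l] * z;
    z.each_col() += n.bd[l];
    z = clamp(z, 0.0, datum::inf);
    acts.push_back(z);
  }
  mat logit = n.Wd.back() * z;
  logit.each_col() += n.bd.back();
  rowvec p = sigm(logit.row(0));
  const double eps = 1e-12;
  double loss = -mean(y % log(p + eps) + (1.0 - y) % log(1.0 - p + eps));

  g = net_zeros_like(n);
  mat dlogit = (conv_to<mat>::from(p - y)) / (double)B; // 1 x B
  mat dz = dlogit;
  for (int l = (int)n.Wd.size() - 1; l >= 0; --l) {
    g.Wd[l] = dz * acts[l].t();
    g.bd[l] = sum(dz, 1);
    if (l > 0) {
      dz = n.Wd[l].t() * dz;
      dz = dz % conv_to<mat>::from(acts[l] > 0.0); // through ReLU
    } else {
      dz = n.Wd[0].t() * dz;
    }
  }
  const int H = n.f.U.n_cols;
  mat dZf = dz.rows(0, H - 1), dZr = dz.rows(H, 2 * H - 1);
  dir_backward(n.f, Xf, cf, dZf, len, g.f);
  dir_backward(n.r, Xr, cr, dZr, len, g.r);
  return loss;
}

// ---- data plumbing ----------------------------------------------------------

static void build_cubes(const std::vector<mat>& xs, const uvec& idx,
                        cube& Xf, cube& Xr, std::vector<int>& len) {
  const int B = idx.n_elem;
  const int D = xs[0].n_cols;
  int T = 1;
  len.assign(B, 1);
  for (int b = 0; b < B; ++b) {
    len[b] = xs[idx[b]].n_rows;
    T = std::max(T, len[b]);
  }
  Xf.zeros(D, B, T);
  Xr.zeros(D, B, T);
  for (int b = 0; b < B; ++b) {
    const mat& x = xs[idx[b]]; // T_b x D
    for (int t = 0; t < len[b]; ++t) {
      Xf.slice(t).col(b) = x.row(t).t();
      Xr.slice(t).col(b) = x.row(len[b] - 1 - t).t();
    }
  }
}

static std::vector<mat> as_matlist(const List& Xlist) {
  std::vector<mat> xs;
  for (int i = 0; i < Xlist.size(); ++i)
    xs.push_back(Rcpp::as<mat>(Xlist[i]));
  if (xs.empty()) stop("empty sequence list");
  for (auto& x : xs)
    if (x.n_rows == 0) stop("empty series cannot be encoded");
  return xs;
}

static List net_to_list(const Net& n) {
  List Wd(n.Wd.size()), bd(n.bd.size());
  for (size_t i = 0; i < n.Wd.size(); ++i) {
    Wd[i] = n.Wd[i];
    bd[i] = n.bd[i];
  }
  return List::create(Named("Wf") = n.f.W, Named("Uf") = n.f.U,
                      Named("bf") = n.f.b, Named("Wr") = n.r.W,
                      Named("Ur") = n.r.U, Named("br") = n.r.b,
                      Named("Wd") = Wd, Named("bd") = bd);
}

static Net net_from_list(const List& w) {
  Net n;
  n.f.W = Rcpp::as<mat>(w["Wf"]); n.f.U = Rcpp::as<mat>(w["Uf"]);
  n.f.b = Rcpp::as<vec>(w["bf"]);
  n.r.W = Rcpp::as<mat>(w["Wr"]); n.r.U = Rcpp::as<mat>(w["Ur"]);
  n.r.b = Rcpp::as<vec>(w["br"]);
  List Wd = w["Wd"], bd = w["bd"];
  for (int i = 0; i < Wd.size(); ++i) {
    n.Wd.push_back(Rcpp::as<mat>(Wd[i]));
    n.bd.push_back(Rcpp::as<vec>(bd[i]));
  }
  return n;
}

// Adam over every tensor of the net
struct Adam {
  Net m, v;
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  explicit Adam(const Net& n) : m(net_zeros_like(n)), v(net_zeros_like(n)) {}
  void upd(mat& w, mat& mm, mat& vv, const mat& g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
  }
  void upd(vec& w, vec& mm, vec& vv, const vec& g, double lr) {
    mm = b1 * mm + (1 - b1) * g;
    vv = b2 * vv + (1 - b2) * (g % g);
    double c1 = 1 - std::pow(b1, (double)t), c2 = 1 - std::pow(b2, (double)t);
    w -= lr * (mm / c1) / (sqrt(vv / c2) + eps);
  }
  void step(Net& n, const Net& g, double lr) {
    ++t;
    upd(n.f.W, m.f.W, v.f.W, g.f.W, lr);
    upd(n.f.U, m.f.U, v.f.U, g.f.U, lr);
    upd(n.f.b, m.f.b, v.f.b, g.f.b, lr);
    upd(n.r.W, m.r.W, v.r.W, g.r.W, lr);
    upd(n.r.U, m.r.U, v.r.U, g.r.U, lr);
    upd(n.r.b, m.r.b, v.r.b, g.r.b, lr);
    for (size_t i = 0; i < n.Wd.size(); ++i) {
      upd(n.Wd[i], m.Wd[i], v.Wd[i], g.Wd[i], lr);
      upd(n.bd[i], m.bd[i], v.bd[i], g.bd[i], lr);
    }
  }
};

static double net_gnorm(const Net& g) {
  double s = 0;
  s += accu(square(g.f.W)) + accu(square(g.f.U)) + accu(square(g.f.b));
  s += accu(square(g.r.W)) + accu(square(g.r.U)) + accu(square(g.r.b));
  for (size_t i = 0; i < g.Wd.size(); ++i)
    s += accu(square(g.Wd[i])) + accu(square(g.bd[i]));
  return std::sqrt(s);
}

static void net_scale(Net& g, double f) {
  g.f.W *= f; g.f.U *= f; g.f.b *= f;
  g.r.W *= f; g.r.U *= f; g.r.b *= f;
  for (size_t i = 0; i < g.Wd.size(); ++i) { g.Wd[i] *= f; g.bd[i] *= f; }
}

// ---- exported entry points --------------------------------------------------

//' @noRd
// [[Rcpp::export(name = ".nn_train_cpp")]]
List nn_train_cpp(List Xlist, NumericVector y, IntegerVector train_idx,
                  IntegerVector val_idx, int hidden, IntegerVector dense,
                  int epochs, int batch, double lr, int patience,
                  double grad_clip = 5.0) {
  std::vector<mat> xs = as_matlist(Xlist);
  const int D = xs[0].n_cols;
  std::vector<int> widths(dense.begin(), dense.end());
  Net net = net_init(D, hidden, widths);

  uvec tr(train_idx.size()), va(val_idx.size());
  for (int i = 0; i < train_idx.size(); ++i) tr[i] = train_idx[i] - 1;
  for (int i = 0; i < val_idx.size(); ++i) va[i] = val_idx[i] - 1;

  cube Vf, Vr;
  std::vector<int> vlen;
  rowvec yv;
  if (va.n_elem > 0) {
    build_cubes(xs, va, Vf, Vr, vlen);
    yv.set_size(va.n_elem);
    for (uword i = 0; i < va.n_elem; ++i) yv[i] = y[va[i]];
  }

  Adam opt(net);
  Net best = net;
  double best_acc = -1.0, best_loss = datum::inf;
  int best_epoch = 0, stale = 0, epochs_run = 0;
  std::vector<double> tl_hist;

  std::vector<uword> perm(tr.begin(), tr.end());
  for (int ep = 1; ep <= epochs; ++ep) {
    epochs_run = ep;
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = (int)perm.size() - 1; i > 0; --i) {
      int j = (int)std::floor(R::unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double tl = 0;
    int nb = 0;
    for (size_t s = 0; s < perm.size(); s += batch) {
      size_t e = std::min(perm.size(), s + batch);
      uvec idx(e - s);
      rowvec yb(e - s);
      for (size_t i = s; i < e; ++i) {
        idx[i - s] = perm[i];
        yb[i - s] = y[perm[i]];
      }
      cube Xf, Xr;
      std::vector<int> len;
      build_cubes(xs, idx, Xf, Xr, len);
      Net g;
      tl += net_grad(net, Xf, Xr, len, yb, g);
      double gn = net_gnorm(g);
      if (gn > grad_clip) net_scale(g, grad_clip / gn);
      opt.step(net, g, lr);
      ++nb;
    }
    tl_hist.push_back(tl / std::max(1, nb));
    if (va.n_elem > 0) {
      rowvec pv = net_prob(net, Vf, Vr, vlen);
      double acc = 0;
      for (uword i = 0; i < pv.n_elem; ++i)
        if ((pv[i] >= 0.5) == (yv[i] >= 0.5)) acc += 1.0;
      acc /= pv.n_elem;
      double vloss =
          -mean(yv % log(pv + 1e-12) + (1.0 - yv) % log(1.0 - pv + 1e-12));
      if (acc > best_acc + 1e-12) {
        best_acc = acc;
        best_loss = vloss;
        best = net;
        best_epoch = ep;
        stale = 0;
      } else {
        if (++stale >= patience) break;
      }
    } else {
      best = net;
      best_epoch = ep;
    }
  }
  if (va.n_elem == 0) { best_acc = NA_REAL; best_loss = NA_REAL; }
  return List::create(Named("weights") = net_to_list(best),
                      Named("val_acc") = best_acc,
                      Named("val_loss") = best_loss,
                      Named("best_epoch") = best_epoch,
                      Named("epochs_run") = epochs_run,
                      Named("train_loss") = tl_hist);
}

//' @noRd
// [[Rcpp::export(name = ".nn_predict_cpp")]]
NumericVector nn_predict_cpp(List weights, List Xlist) {
  std::vector<mat> xs = as_matlist(Xlist);
  Net net = net_from_list(weights);
  uvec idx = regspace<uvec>(0, xs.size() - 1);
  cube Xf, Xr;
  std::vector<int> len;
  build_cubes(xs, idx, Xf, Xr, len);
  rowvec p = net_prob(net, Xf, Xr, len);
  return NumericVector(p.begin(), p.end());
}

//' @noRd
// [[Rcpp::export(name = ".nn_init_cpp")]]
List nn_init_cpp(int D, int hidden, IntegerVector dense) {
  std::vector<int> widths(dense.begin(), dense.end());
  return net_to_list(net_init(D, hidden, widths));
}

//' @noRd
// [[Rcpp::export(name = ".nn_loss_grad_cpp")]]
List nn_loss_grad_cpp(List weights, List Xlist, NumericVector y) {
  std::vector<mat> xs = as_matlist(Xlist);
  Net net = net_from_list(weights);
  uvec idx = regspace<uvec>(0, xs.size() - 1);
  cube Xf, Xr;
  std::vector<int> len;
  build_cubes(xs, idx, Xf, Xr, len);
  rowvec yb(xs.size());
  for (size_t i = 0; i < xs.size(); ++i) yb[i] = y[i];
  Net g;
  double loss = net_grad(net, Xf, Xr, len, yb, g);
  return List::create(Named("loss") = loss, Named("grad") = net_to_list(g));
}
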