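// Multi-task fully convolutional network for proximity / pseudomarker
// regression, implemented directly on Armadillo.
//
// Architecture (widths configurable through the parameter shapes):
//   3 blocks x 3 valid 5x5 convolutions with ResNet-like skip connections
//   (block input center-cropped by 6 px per side and added to the block's
//   last pre-activation; block 1 uses a 1x1 projection to match channels),
//   a 25x25 valid reduction convolution (27 -> 3 for a 63x63 input),
//   one shared 1x1 "fully connected" stage, then two branches of two 1x1
//   stages each (proximity -> 1 channel, pseudomarkers -> 5 channels).
//   Batch normalization on all convolutional layers except the skip
//   projection; dropout on the fully connected stages. Everything is
//   stride 1 and valid, so the network is translation-covariant and dense
//   whole-tile inference uses the same code path as 63x63 patches.
//
// All randomness (init noise, shuffling, augmentation, dropout) uses R's
// RNG, so results are reproducible under set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

namespace {

const double BN_EPS = 1e-5;

struct Conv {
  mat W;  // (Cout, k*k*Cin)
  vec b;
  int k = 1;
  bool bn = false;
  vec g, be, rm, rv; // batch-norm gamma/beta and running mean/var
};

struct Net {
  Conv conv[9]; // three blocks of three 5x5 convs
  Conv red;     // 25x25 reduction conv
  Conv proj;    // 1x1 skip projection for block 1 (no BN)
  Conv fc[5];   // shared, prox hidden, prox out, psi hidden, psi out
};

mat get_mat(const List &p, const std::string &nm) {
  return as<mat>(p[nm]);
}
vec get_vec(const List &p, const std::string &nm) {
  return as<vec>(p[nm]);
}

Net parse_net(const List &p) {
  Net n;
  for (int i = 0; i < 9; ++i) {
    std::string s = "conv" + std::to_string(i + 1);
    n.conv[i].W = get_mat(p, s + "_W");
    n.conv[i].b = get_vec(p, s + "_b");
    n.conv[i].k = 5;
    n.conv[i].bn = true;
    std::string bnm = "bn" + std::to_string(i + 1);
    n.conv[i].g = get_vec(p, bnm + "_gamma");
    n.conv[i].be = get_vec(p, bnm + "_beta");
    n.conv[i].rm = get_vec(p, bnm + "_mean");
    n.conv[i].rv = get_vec(p, bnm + "_var");
  }
  n.red.W = get_mat(p, "red_W");
  n.red.b = get_vec(p, "red_b");
  n.red.k = 25;
  n.red.bn = true;
  n.red.g = get_vec(p, "bnred_gamma");
  n.red.be = get_vec(p, "bnred_beta");
  n.red.rm = get_vec(p, "bnred_mean");
  n.red.rv = get_vec(p, "bnred_var");
  n.proj.W = get_mat(p, "proj_W");
  n.proj.b = get_vec(p, "proj_b");
  n.proj.k = 1;
  const char *fcn[5] = {"fc_shared", "fc_prox1", "fc_prox2", "fc_psi1",
                        "fc_psi2"};
  for (int i = 0; i < 5; ++i) {
    n.fc[i].W = get_mat(p, std::string(fcn[i]) + "_W");
    n.fc[i].b = get_vec(p, std::string(fcn[i]) + "_b");
    n.fc[i].k = 1;
  }
  return n;
}

List dump_net(const Net &n) {
  List p;
  for (int i = 0; i < 9; ++i) {
    std::string s = "conv" + std::to_string(i + 1);
    p[s + "_W"] = n.conv[i].W;
    p[s + "_b"] = n.conv[i].b;
    std::string bnm = "bn" + std::to_string(i + 1);
    p[bnm + "_gamma"] = n.conv[i].g;
    p[bnm + "_beta"] = n.conv[i].be;
    p[bnm + "_mean"] = n.conv[i].rm;
    p[bnm + "_var"] = n.conv[i].rv;
  }
  p["red_W"] = n.red.W;
  p["red_b"] = n.red.b;
  p["bnred_gamma"] = n.red.g;
  p["bnred_beta"] = n.red.be;
  p["bnred_mean"] = n.red.rm;
  p["bnred_var"] = n.red.rv;
  p["proj_W"] = n.proj.W;
  p["proj_b"] = n.proj.b;
  const char *fcn[5] = {"fc_shared", "fc_prox1", "fc_prox2", "fc_psi1",
                        "fc_psi2"};
  for (int i = 0; i < 5; ++i) {
    p[std::string(fcn[i]) + "_W"] = n.fc[i].W;
    p[std::string(fcn[i]) + "_b"] = n.fc[i].b;
  }
  return p;
}

// ---- convolution primitives ----------------------------------------------

// im2col row order is (kr, kc, ci) fastest-to-slowest = kr + k*kc +
// k*k*ci, matching the weight layout produced in R.

cube conv_forward(const cube &in, const Conv &L);

// Reused workspaces for the batched im2col buffers (R is single-threaded;
// these avoid re-allocating and re-faulting hundreds of MB per minibatch).
std::vector<double> ws_x, ws_dy, ws_dx;

double *ws_get(std::vector<double> &v, size_t n) {
  if (v.size() < n) v.resize(n);
  return v.data();
}

// Fill columns [c0, c1) of the im2col matrix directly into `dest` (column
// major, leading dimension k*k*Cin).
void im2col_into(const cube &in, int k, arma::uword c0, arma::uword c1,
                 int Hout, double *dest) {
  int Cin = in.n_slices;
  arma::uword H = in.n_rows;
  arma::uword rows = (arma::uword)k * k * Cin;
  for (arma::uword j = c0; j < c1; ++j) {
    arma::uword r = j % Hout, c = j / Hout;
    double *col = dest + (j - c0) * rows;
    arma::uword idx = 0;
    for (int ci = 0; ci < Cin; ++ci) {
      const double *base = in.slice_memptr(ci) + c * H + r;
      for (int kc = 0; kc < k; ++kc) {
        const double *p = base + (arma::uword)kc * H;
        for (int kr = 0; kr < k; ++kr)
          col[idx++] = p[kr];
      }
    }
  }
}

// Batched convolution: one im2col + GEMM across the whole minibatch, which
// is far cheaper than per-sample GEMMs for the small training patches.
std::vector<cube> conv_forward_batch(const std::vector<cube> &in,
                                     const Conv &L) {
  int B = in.size();
  int k = L.k;
  int Hout = in[0].n_rows - k + 1, Wout = in[0].n_cols - k + 1;
  arma::uword ncol = (arma::uword)Hout * Wout;
  arma::uword rows = (arma::uword)k * k * in[0].n_slices;
  mat X(ws_get(ws_x, rows * B * ncol), rows, (arma::uword)B * ncol, false,
        true);
  for (int i = 0; i < B; ++i)
    im2col_into(in[i], k, 0, ncol, Hout, X.colptr((arma::uword)i * ncol));
  mat Y = L.W * X;
  Y.each_col() += L.b;
  std::vector<cube> out(B);
  for (int i = 0; i < B; ++i) {
    out[i].set_size(Hout, Wout, L.W.n_rows);
    for (arma::uword ch = 0; ch < out[i].n_slices; ++ch) {
      double *dst = out[i].slice_memptr(ch);
      for (arma::uword j = 0; j < ncol; ++j)
        dst[j] = Y(ch, (arma::uword)i * ncol + j);
    }
  }
  return out;
}

void conv_backward_batch(const std::vector<cube> &in, const Conv &L,
                         const std::vector<cube> &dout, mat &dW, vec &db,
                         std::vector<cube> &din, bool need_din) {
  int B = in.size();
  int k = L.k;
  int Hout = dout[0].n_rows, Wout = dout[0].n_cols;
  arma::uword ncol = (arma::uword)Hout * Wout;
  arma::uword rows = (arma::uword)k * k * in[0].n_slices;
  mat X(ws_get(ws_x, rows * B * ncol), rows, (arma::uword)B * ncol, false,
        true);
  mat dY(ws_get(ws_dy, L.W.n_rows * B * ncol), L.W.n_rows,
         (arma::uword)B * ncol, false, true);
  for (int i = 0; i < B; ++i) {
    im2col_into(in[i], k, 0, ncol, Hout, X.colptr((arma::uword)i * ncol));
    for (arma::uword j = 0; j < ncol; ++j) {
      double *col = dY.colptr((arma::uword)i * ncol + j);
      for (arma::uword ch = 0; ch < dY.n_rows; ++ch)
        col[ch] = dout[i].slice_memptr(ch)[j];
    }
  }
  dW += dY * X.t();
  db += arma::sum(dY, 1);
  if (!need_din) return;
  mat dX(ws_get(ws_dx, rows * B * ncol), rows, (arma::uword)B * ncol, false,
         true);
  dX = L.W.t() * dY;
  din.resize(B);
  for (int i = 0; i < B; ++i) {
    din[i].zeros(in[i].n_rows, in[i].n_cols, in[i].n_slices);
    arma::uword H = din[i].n_rows;
    for (arma::uword j = 0; j < ncol; ++j) {
      arma::uword r = j % Hout, c = j / Hout;
      arma::uword idx = 0;
      const double *col = dX.colptr((arma::uword)i * ncol + j);
      for (arma::uword ci = 0; ci < din[i].n_slices; ++ci) {
        double *base = din[i].slice_memptr(ci) + c * H + r;
        for (int kc = 0; kc < k; ++kc) {
          double *p = base + (arma::uword)kc * H;
          for (int kr = 0; kr < k; ++kr)
            p[kr] += col[idx++];
        }
      }
    }
  }
}

// Single-sample convolution (dense inference); chunked so the im2col
// buffer stays modest even for whole tiles and the 25x25 reduction kernel.
cube conv_forward(const cube &in, const Conv &L) {
  int k = L.k;
  int Hout = in.n_rows - k + 1, Wout = in.n_cols - k + 1;
  cube out(Hout, Wout, L.W.n_rows);
  arma::uword ncol = (arma::uword)Hout * Wout;
  arma::uword rows = L.W.n_cols;
  arma::uword chunk = std::max<arma::uword>(1, 8000000 / rows);
  for (arma::uword c0 = 0; c0 < ncol; c0 += chunk) {
    arma::uword c1 = std::min(ncol, c0 + chunk);
    mat X(ws_get(ws_x, rows * (c1 - c0)), rows, c1 - c0, false, true);
    im2col_into(in, k, c0, c1, Hout, X.memptr());
    mat Y = L.W * X;
    Y.each_col() += L.b;
    for (arma::uword j = c0; j < c1; ++j)
      for (arma::uword ch = 0; ch < out.n_slices; ++ch)
        out[ch * ncol + j] = Y(ch, j - c0);
  }
  return out;
}

cube crop6(const cube &a) {
  return a.subcube(6, 6, 0, a.n_rows - 7, a.n_cols - 7, a.n_slices - 1);
}

// ---- batch norm (training) ------------------------------------------------

struct BNCache {
  vec mu, var;
  std::vector<cube> xhat;
};

void bn_forward_train(std::vector<cube> &z, Conv &L, BNCache &cache,
                      double momentum) {
  arma::uword C = z[0].n_slices;
  arma::uword N = z.size() * z[0].n_rows * z[0].n_cols;
  cache.mu.zeros(C);
  cache.var.zeros(C);
  for (auto &c : z)
    for (arma::uword ch = 0; ch < C; ++ch)
      cache.mu[ch] += arma::accu(c.slice(ch));
  cache.mu /= (double)N;
  for (auto &c : z)
    for (arma::uword ch = 0; ch < C; ++ch)
      cache.var[ch] += arma::accu(arma::square(c.slice(ch) - cache.mu[ch]));
  cache.var /= (double)N;
  L.rm = momentum * L.rm + (1 - momentum) * cache.mu;
  L.rv = momentum * L.rv + (1 - momentum) * cache.var;
  cache.xhat.resize(z.size());
  for (size_t i = 0; i < z.size(); ++i) {
    cache.xhat[i].set_size(arma::size(z[i]));
    for (arma::uword ch = 0; ch < C; ++ch) {
      double s = std::sqrt(cache.var[ch] + BN_EPS);
      cache.xhat[i].slice(ch) = (z[i].slice(ch) - cache.mu[ch]) / s;
      z[i].slice(ch) = L.g[ch] * cache.xhat[i].slice(ch) + L.be[ch];
    }
  }
}

void bn_backward(std::vector<cube> &dz, const BNCache &cache, const Conv &L,
                 vec &dg, vec &dbe) {
  // dz holds dL/dy on entry, dL/dx on exit
  arma::uword C = dz[0].n_slices;
  double N = (double)(dz.size() * dz[0].n_rows * dz[0].n_cols);
  vec sum_dy(C, arma::fill::zeros), sum_dyx(C, arma::fill::zeros);
  for (size_t i = 0; i < dz.size(); ++i)
    for (arma::uword ch = 0; ch < C; ++ch) {
      sum_dy[ch] += arma::accu(dz[i].slice(ch));
      sum_dyx[ch] += arma::accu(dz[i].slice(ch) % cache.xhat[i].slice(ch));
    }
  dg += sum_dyx;
  dbe += sum_dy;
  for (size_t i = 0; i < dz.size(); ++i)
    for (arma::uword ch = 0; ch < C; ++ch) {
      double s = std::sqrt(cache.var[ch] + BN_EPS);
      dz[i].slice(ch) = (L.g[ch] / s) *
        (dz[i].slice(ch) - sum_dy[ch] / N -
         cache.xhat[i].slice(ch) * (sum_dyx[ch] / N));
    }
}

void bn_forward_infer(cube &z, const Conv &L) {
  for (arma::uword ch = 0; ch < z.n_slices; ++ch) {
    double s = std::sqrt(L.rv[ch] + BN_EPS);
    z.slice(ch) = L.g[ch] * (z.slice(ch) - L.rm[ch]) / s + L.be[ch];
  }
}

// ---- parameter enumeration for Adam ---------------------------------------

struct NetGrad {
  Net g; // same shapes, used as gradient storage
};

void zero_like(Net &g, const Net &n) {
  g = n;
  for (int i = 0; i < 9; ++i) {
    g.conv[i].W.zeros();
    g.conv[i].b.zeros();
    g.conv[i].g.zeros();
    g.conv[i].be.zeros();
  }
  g.red.W.zeros(); g.red.b.zeros(); g.red.g.zeros(); g.red.be.zeros();
  g.proj.W.zeros(); g.proj.b.zeros();
  for (int i = 0; i < 5; ++i) { g.fc[i].W.zeros(); g.fc[i].b.zeros(); }
}

void enumerate_params(Net &n, std::vector<mat *> &ms, std::vector<vec *> &vs) {
  ms.clear(); vs.clear();
  for (int i = 0; i < 9; ++i) {
    ms.push_back(&n.conv[i].W);
    vs.push_back(&n.conv[i].b);
    vs.push_back(&n.conv[i].g);
    vs.push_back(&n.conv[i].be);
  }
  ms.push_back(&n.red.W);
  vs.push_back(&n.red.b);
  vs.push_back(&n.red.g);
  vs.push_back(&n.red.be);
  ms.push_back(&n.proj.W);
  vs.push_back(&n.proj.b);
  for (int i = 0; i < 5; ++i) {
    ms.push_back(&n.fc[i].W);
    vs.push_back(&n.fc[i].b);
  }
}

// ---- geometric augmentation -----------------------------------------------

cube dihedral(const cube &a, int rot, bool flip) {
  cube out = a;
  for (arma::uword s = 0; s < a.n_slices; ++s) {
    mat m = a.slice(s);
    if (flip) m = arma::fliplr(m);
    for (int r = 0; r < rot; ++r) m = arma::flipud(m.t()); // rotate 90 ccw
    out.slice(s) = m;
  }
  return out;
}

cube cube_from_array(const double *src, int h, int w, int c) {
  cube out(h, w, c);
  std::copy(src, src + (size_t)h * w * c, out.memptr());
  return out;
}

} // namespace

// ---- training --------------------------------------------------------------

// [[Rcpp::export(name = ".net_train")]]
List net_train(List params, NumericVector x, NumericVector y, List cfg) {
  IntegerVector xd = x.attr("dim"), yd = y.attr("dim");
  int P = xd[0], C = xd[2], N = xd[3];
  int LP = yd[0], LC = yd[2];
  if (yd[3] != N) stop("input/label count mismatch");
  Net net = parse_net(params);

  double lr = as<double>(cfg["learning_rate"]);
  int epochs = as<int>(cfg["epochs"]);
  int batch = as<int>(cfg["batch_size"]);
  double w_prox = as<double>(cfg["loss_weight_proximity"]);
  double w_ph = as<double>(cfg["loss_weight_phenotype"]);
  double dropout = as<double>(cfg["dropout"]);
  double noise_sd = as<double>(cfg["input_noise_sd"]);
  bool augment = as<bool>(cfg["augment"]);
  double momentum = as<double>(cfg["bn_momentum"]);

  Net grad;
  zero_like(grad, net);
  std::vector<mat *> pm, gm;
  std::vector<vec *> pv, gv;
  enumerate_params(net, pm, pv);
  enumerate_params(grad, gm, gv);
  std::vector<mat> mm(pm.size()), mv(pm.size());
  std::vector<vec> vm(pv.size()), vv(pv.size());
  for (size_t i = 0; i < pm.size(); ++i) {
    mm[i].zeros(arma::size(*pm[i]));
    mv[i].zeros(arma::size(*pm[i]));
  }
  for (size_t i = 0; i < pv.size(); ++i) {
    vm[i].zeros(arma::size(*pv[i]));
    vv[i].zeros(arma::size(*pv[i]));
  }
  double beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8;
  long tstep = 0;

  RNGScope scope;
  NumericMatrix history(epochs, 3);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle with R RNG
    for (int i = N - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0, ep_lp = 0, ep_ls = 0;
    int nb = 0;
    for (int b0 = 0; b0 < N; b0 += batch) {
      int B = std::min(batch, N - b0);
      // ---- assemble batch with augmentation
      std::vector<cube> a0(B), lab(B);
      for (int i = 0; i < B; ++i) {
        int id = order[b0 + i];
        cube xi = cube_from_array(&x[(size_t)id * P * P * C], P, P, C);
        cube yi = cube_from_array(&y[(size_t)id * LP * LP * LC], LP, LP, LC);
        if (augment) {
          int rot = (int)(unif_rand() * 4); if (rot > 3) rot = 3;
          bool fl = unif_rand() < 0.5;
          xi = dihedral(xi, rot, fl);
          yi = dihedral(yi, rot, fl);
          double s1 = 0.6 + unif_rand() * 1.4;
          double s2 = -0.2 + unif_rand() * 0.4;
          xi = xi * s1 + s2;
        }
        if (noise_sd > 0)
          for (arma::uword e = 0; e < xi.n_elem; ++e)
            xi[e] += norm_rand() * noise_sd;
        a0[i] = std::move(xi);
        lab[i] = std::move(yi);
      }

      // ---- forward
      std::vector<std::vector<cube>> zin(10), zpre(10); // conv inputs, pre-BN
      std::vector<BNCache> bnc(10);
      std::vector<std::vector<cube>> block_in(3);
      std::vector<cube> act = a0;
      for (int blk = 0; blk < 3; ++blk) {
        block_in[blk] = act;
        for (int l = 0; l < 3; ++l) {
          int s = blk * 3 + l;
          zin[s] = act;
          std::vector<cube> z = conv_forward_batch(act, net.conv[s]);
          bn_forward_train(z, net.conv[s], bnc[s], momentum);
          if (l == 2) {
            std::vector<cube> sk(B);
            for (int i = 0; i < B; ++i) sk[i] = crop6(block_in[blk][i]);
            if (blk == 0) sk = conv_forward_batch(sk, net.proj);
            for (int i = 0; i < B; ++i) z[i] += sk[i];
          }
          zpre[s] = z; // pre-ReLU (post-BN, post-skip)
          for (int i = 0; i < B; ++i)
            z[i].transform([](double v) { return v > 0 ? v : 0.0; });
          act = std::move(z);
        }
      }
      zin[9] = act;
      {
        std::vector<cube> z = conv_forward_batch(act, net.red);
        bn_forward_train(z, net.red, bnc[9], momentum);
        zpre[9] = z;
        for (int i = 0; i < B; ++i)
          z[i].transform([](double v) { return v > 0 ? v : 0.0; });
        act = std::move(z);
      }
      // FC stages
      std::vector<std::vector<cube>> fin(5), fpre(5), dmask(5);
      auto fc_stage = [&](int fi, std::vector<cube> &a, bool relu_drop) {
        fin[fi] = a;
        std::vector<cube> z = conv_forward_batch(a, net.fc[fi]);
        fpre[fi] = z;
        if (relu_drop) {
          dmask[fi].resize(B);
          for (int i = 0; i < B; ++i) {
            z[i].transform([](double v) { return v > 0 ? v : 0.0; });
            dmask[fi][i].set_size(arma::size(z[i]));
            if (dropout > 0) {
              for (arma::uword e = 0; e < z[i].n_elem; ++e)
                dmask[fi][i][e] =
                    unif_rand() < dropout ? 0.0 : 1.0 / (1.0 - dropout);
              z[i] %= dmask[fi][i];
            } else {
              dmask[fi][i].ones();
            }
          }
        }
        a = std::move(z);
      };
      std::vector<cube> shared = act;
      fc_stage(0, shared, true);
      std::vector<cube> prox = shared;
      fc_stage(1, prox, true);
      fc_stage(2, prox, false);
      std::vector<cube> psi = shared;
      fc_stage(3, psi, true);
      fc_stage(4, psi, false);

      // ---- loss and output gradients (MSE per branch, means over batch,
      //      spatial positions and channels)
      double np = (double)B * LP * LP * 1;
      double ns = (double)B * LP * LP * (LC - 1);
      double lp = 0, ls = 0;
      std::vector<cube> dprox(B), dpsi(B);
      for (int i = 0; i < B; ++i) {
        cube tp = lab[i].slices(0, 0);
        cube ts = lab[i].slices(1, LC - 1);
        cube ep = prox[i] - tp;
        cube es = psi[i] - ts;
        lp += arma::accu(arma::square(ep));
        ls += arma::accu(arma::square(es));
        dprox[i] = (2.0 * w_prox / np) * ep;
        dpsi[i] = (2.0 * w_ph / ns) * es;
      }
      lp /= np;
      ls /= ns;
      double loss = w_prox * lp + w_ph * ls;
      if (!std::isfinite(loss))
        stop("training diverged (non-finite loss) at epoch %d", ep + 1);
      ep_loss += loss; ep_lp += lp; ep_ls += ls; ++nb;

      // ---- backward
      auto mask_relu_drop = [&](int fi, std::vector<cube> &dout) {
        for (int i = 0; i < B; ++i) {
          dout[i] %= dmask[fi][i];
          for (arma::uword e = 0; e < dout[i].n_elem; ++e)
            if (fpre[fi][i][e] <= 0) dout[i][e] = 0;
        }
      };
      std::vector<cube> dp2;
      conv_backward_batch(fin[2], net.fc[2], dprox, grad.fc[2].W,
                          grad.fc[2].b, dp2, true);
      mask_relu_drop(1, dp2);
      std::vector<cube> dshared;
      conv_backward_batch(fin[1], net.fc[1], dp2, grad.fc[1].W,
                          grad.fc[1].b, dshared, true);
      std::vector<cube> ds2;
      conv_backward_batch(fin[4], net.fc[4], dpsi, grad.fc[4].W,
                          grad.fc[4].b, ds2, true);
      mask_relu_drop(3, ds2);
      {
        std::vector<cube> tmp;
        conv_backward_batch(fin[3], net.fc[3], ds2, grad.fc[3].W,
                            grad.fc[3].b, tmp, true);
        for (int i = 0; i < B; ++i) dshared[i] += tmp[i];
      }
      // shared FC
      mask_relu_drop(0, dshared);
      std::vector<cube> dact;
      conv_backward_batch(fin[0], net.fc[0], dshared, grad.fc[0].W,
                          grad.fc[0].b, dact, true);
      // reduction conv
      for (int i = 0; i < B; ++i)
        for (arma::uword e = 0; e < dact[i].n_elem; ++e)
          if (zpre[9][i][e] <= 0) dact[i][e] = 0;
      bn_backward(dact, bnc[9], net.red, grad.red.g, grad.red.be);
      {
        std::vector<cube> din;
        conv_backward_batch(zin[9], net.red, dact, grad.red.W, grad.red.b,
                            din, true);
        dact = std::move(din);
      }
      // blocks, in reverse
      std::vector<cube> dblock_in(B); // gradient flowing via skip path
      for (int blk = 2; blk >= 0; --blk) {
        for (int i = 0; i < B; ++i) dblock_in[i].reset();
        for (int l = 2; l >= 0; --l) {
          int s = blk * 3 + l;
          for (int i = 0; i < B; ++i)
            for (arma::uword e = 0; e < dact[i].n_elem; ++e)
              if (zpre[s][i][e] <= 0) dact[i][e] = 0;
          if (l == 2) {
            // skip branch receives the same gradient (post-BN addition)
            std::vector<cube> dsk = dact;
            if (blk == 0) {
              std::vector<cube> cropped(B), tmp;
              for (int i = 0; i < B; ++i)
                cropped[i] = crop6(block_in[blk][i]);
              conv_backward_batch(cropped, net.proj, dsk, grad.proj.W,
                                  grad.proj.b, tmp, true);
              dsk = std::move(tmp);
            }
            for (int i = 0; i < B; ++i) {
              // pad back into full block-input shape
              cube full(block_in[blk][i].n_rows, block_in[blk][i].n_cols,
                        dsk[i].n_slices, arma::fill::zeros);
              full.subcube(6, 6, 0, full.n_rows - 7, full.n_cols - 7,
                           full.n_slices - 1) = dsk[i];
              dblock_in[i] = full;
            }
          }
          bn_backward(dact, bnc[s], net.conv[s], grad.conv[s].g,
                      grad.conv[s].be);
          std::vector<cube> din;
          conv_backward_batch(zin[s], net.conv[s], dact, grad.conv[s].W,
                              grad.conv[s].b, din, true);
          dact = std::move(din);
        }
        for (int i = 0; i < B; ++i) dact[i] += dblock_in[i];
      }

      // ---- Adam update
      ++tstep;
      double bc1 = 1 - std::pow(beta1, (double)tstep);
      double bc2 = 1 - std::pow(beta2, (double)tstep);
      for (size_t i = 0; i < pm.size(); ++i) {
        mm[i] = beta1 * mm[i] + (1 - beta1) * (*gm[i]);
        mv[i] = beta2 * mv[i] + (1 - beta2) * arma::square(*gm[i]);
        *pm[i] -= lr * (mm[i] / bc1) / (arma::sqrt(mv[i] / bc2) + adam_eps);
        gm[i]->zeros();
      }
      for (size_t i = 0; i < pv.size(); ++i) {
        vm[i] = beta1 * vm[i] + (1 - beta1) * (*gv[i]);
        vv[i] = beta2 * vv[i] + (1 - beta2) * arma::square(*gv[i]);
        *pv[i] -= lr * (vm[i] / bc1) / (arma::sqrt(vv[i] / bc2) + adam_eps);
        gv[i]->zeros();
      }
    }
    history(ep, 0) = ep_loss / nb;
    history(ep, 1) = ep_lp / nb;
    history(ep, 2) = ep_ls / nb;
    Rcpp::checkUserInterrupt();
  }
  colnames(history) = CharacterVector::create("loss", "mse_proximity",
                                              "mse_phenotype");
  return List::create(_["params"] = dump_net(net), _["history"] = history);
}

// ---- inference -------------------------------------------------------------

// Dense valid-convolution inference: (H, W, 7) -> (H - 60, W - 60, 6).
// Batch norm uses running statistics; no dropout.
// [[Rcpp::export(name = ".net_infer")]]
NumericVector net_infer(List params, NumericVector img) {
  IntegerVector d = img.attr("dim");
  int H = d[0], W = d[1], C = d[2];
  if (H < 63 || W < 63) stop("input smaller than the 63 px receptive field");
  Net net = parse_net(params);
  cube a = cube_from_array(&img[0], H, W, C);
  for (int blk = 0; blk < 3; ++blk) {
    cube bin = a;
    for (int l = 0; l < 3; ++l) {
      int s = blk * 3 + l;
      cube z = conv_forward(a, net.conv[s]);
      bn_forward_infer(z, net.conv[s]);
      if (l == 2) {
        cube sk = crop6(bin);
        if (blk == 0) sk = conv_forward(sk, net.proj);
        z += sk;
      }
      z.transform([](double v) { return v > 0 ? v : 0.0; });
      a = std::move(z);
    }
  }
  cube z = conv_forward(a, net.red);
  bn_forward_infer(z, net.red);
  z.transform([](double v) { return v > 0 ? v : 0.0; });
  cube shared = conv_forward(z, net.fc[0]);
  shared.transform([](double v) { return v > 0 ? v : 0.0; });
  cube p1 = conv_forward(shared, net.fc[1]);
  p1.transform([](double v) { return v > 0 ? v : 0.0; });
  cube prox = conv_forward(p1, net.fc[2]);
  cube s1 = conv_forward(shared, net.fc[3]);
  s1.transform([](double v) { return v > 0 ? v : 0.0; });
  cube psi = conv_forward(s1, net.fc[4]);

  int Ho = prox.n_rows, Wo = prox.n_cols;
  NumericVector out((R_xlen_t)Ho * Wo * 6);
  out.attr("dim") = IntegerVector::create(Ho, Wo, 6);
  std::copy(prox.memptr(), prox.memptr() + (size_t)Ho * Wo, out.begin());
  std::copy(psi.memptr(), psi.memptr() + (size_t)Ho * Wo * 5,
            out.begin() + (size_t)Ho * Wo);
  return out;
}
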