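// Fused whole-network passes for the training loop. The layer-by-layer R
// implementation (model_forward_array / model_backward_array) is the
// reference; these routines compute the same quantities in one call,
// reusing the im2col buffers between the forward and backward passes.
//
// Weight list order (14 convolutions): head, block1.a, block1.b, ...,
// blockN.a, blockN.b, tail.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static void im2col3_into(const cube& x, mat& out) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  out.set_size(9 * C, (size_t)H * W);
  for (int c = 0; c < C; ++c) {
    const mat& ch = x.slice(c);
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const int r = c * 9 + (ky + 1) * 3 + (kx + 1);
        for (int j = 0; j < W; ++j) {
          const int jj = clampi(j + kx, 0, W - 1);
          const size_t col0 = (size_t)j * H;
          for (int i = 0; i < H; ++i) {
            out(r, col0 + i) = ch(clampi(i + ky, 0, H - 1), jj);
          }
        }
      }
    }
  }
}

static cube mat_to_cube(const mat& y, int H, int W) {
  cube out(H, W, y.n_rows);
  for (size_t c = 0; c < y.n_rows; ++c)
    out.slice(c) = reshape(y.row(c), H, W);
  return out;
}

static mat cube_to_mat(const cube& x) {
  mat out(x.n_slices, (size_t)x.n_rows * x.n_cols);
  for (size_t c = 0; c < x.n_slices; ++c)
    out.row(c) = vectorise(x.slice(c)).t();
  return out;
}

static cube col2im3(const mat& cols, int H, int W, int C) {
  cube g(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    mat& ch = g.slice(c);
    for (int ky = -1; ky <= 1; ++ky) {
      for (int kx = -1; kx <= 1; ++kx) {
        const int r = c * 9 + (ky + 1) * 3 + (kx + 1);
        for (int j = 0; j < W; ++j) {
          const int jj = clampi(j + kx, 0, W - 1);
          const size_t col0 = (size_t)j * H;
          for (int i = 0; i < H; ++i) {
            ch(clampi(i + ky, 0, H - 1), jj) += cols(r, col0 + i);
          }
        }
      }
    }
  }
  return g;
}

struct NetDef {
  std::vector<mat> W;
  std::vector<vec> b;
  int n_blocks;
  bool related;
};

static NetDef read_net(const Rcpp::List& Ws, const Rcpp::List& bs,
                       bool related) {
  NetDef nd;
  nd.related = related;
  const int L = Ws.size();
  nd.n_blocks = (L - 2) / 2;
  for (int i = 0; i < L; ++i) {
    nd.W.push_back(Rcpp::as<mat>(Ws[i]));
    nd.b.push_back(Rcpp::as<vec>(bs[i]));
  }
  return nd;
}

static void mask_related_cube(cube& x) {
  if (x.n_slices >= 4) {
    x.slice(2).zeros();
    x.slice(3).zeros();
  }
}

// Forward pass; when `keep` is non-null, stores per-conv im2col matrices
// and the pre-activation / shortcut intermediates needed for backprop.
struct FwdCache {
  std::vector<mat> cols;      // one per conv layer
  std::vector<cube> u1, s;    // per block: first-conv preact, shortcut sum
  cube h0;                    // head preact
};

static cube net_forward_impl(const NetDef& nd, cube x, FwdCache* keep) {
  const int H = x.n_rows, Wd = x.n_cols;
  if (nd.related) mask_related_cube(x);
  mat cols;
  im2col3_into(x, cols);
  mat y = nd.W[0] * cols;
  y.each_col() += nd.b[0];
  cube h0 = mat_to_cube(y, H, Wd);
  if (keep) { keep->cols.push_back(std::move(cols)); keep->h0 = h0; }
  cube a = h0;
  a.transform([](double v) { return v > 0 ? v : 0.0; });
  for (int bl = 0; bl < nd.n_blocks; ++bl) {
    const int li = 1 + 2 * bl;
    mat c1;
    im2col3_into(a, c1);
    mat y1 = nd.W[li] * c1;
    y1.each_col() += nd.b[li];
    cube u1 = mat_to_cube(y1, H, Wd);
    cube r1 = u1;
    r1.transform([](double v) { return v > 0 ? v : 0.0; });
    mat c2;
    im2col3_into(r1, c2);
    mat y2 = nd.W[li + 1] * c2;
    y2.each_col() += nd.b[li + 1];
    cube s = a + mat_to_cube(y2, H, Wd);
    if (keep) {
      keep->cols.push_back(std::move(c1));
      keep->cols.push_back(std::move(c2));
      keep->u1.push_back(std::move(u1));
      keep->s.push_back(s);
    }
    a = s;
    a.transform([](double v) { return v > 0 ? v : 0.0; });
  }
  mat ct;
  im2col3_into(a, ct);
  mat yt = nd.W.back() * ct;
  yt.each_col() += nd.b.back();
  if (keep) keep->cols.push_back(std::move(ct));
  cube out = mat_to_cube(yt, H, Wd);
  if (nd.related) mask_related_cube(out);
  return out;
}

// [[Rcpp::export]]
arma::cube net_forward_cpp(const arma::cube& x, const Rcpp::List& Ws,
                           const Rcpp::List& bs, bool related) {
  NetDef nd = read_net(Ws, bs, related);
  return net_forward_impl(nd, x, nullptr);
}

// Composite loss on the prediction: sum of per-band MSE against the label
// plus lambda * mean-norm of forward differences along `axis` (0 = rows)
// for the channels in reg_channels (0-based). Writes d(loss)/d(pred)
// into gout.
static double loss_and_grad(const cube& pred, const cube& label,
                            double lambda, const Rcpp::IntegerVector& reg_channels,
                            int axis, bool l2, cube& gout) {
  const int H = pred.n_rows, W = pred.n_cols, C = pred.n_slices;
  const double n_px = (double)H * W;
  double loss = 0.0;
  gout.set_size(H, W, C);
  for (int c = 0; c < C; ++c) {
    mat d = pred.slice(c) - label.slice(c);
    loss += accu(square(d)) / n_px;
    gout.slice(c) = 2.0 * d / n_px;
  }
  if (lambda > 0) {
    for (int k = 0; k < reg_channels.size(); ++k) {
      const int c = reg_channels[k];
      const mat& m = pred.slice(c);
      mat d = (axis == 0)
        ? mat(m.rows(1, H - 1) - m.rows(0, H - 2))
        : mat(m.cols(1, W - 1) - m.cols(0, W - 2));
      const double nd = (double)d.n_elem;
      if (l2) {
        loss += lambda * accu(square(d)) / nd;
      } else {
        loss += lambda * accu(abs(d)) / nd;
      }
      mat gd = l2 ? mat(2.0 * d / nd) : mat(sign(d) / nd);
      if (axis == 0) {
        gout.slice(c).rows(1, H - 1) += lambda * gd;
        gout.slice(c).rows(0, H - 2) -= lambda * gd;
      } else {
        gout.slice(c).cols(1, W - 1) += lambda * gd;
        gout.slice(c).cols(0, W - 2) -= lambda * gd;
      }
    }
  }
  return loss;
}

// One training example: forward, composite loss, full backward. Returns
// the loss and the per-layer weight/bias gradients (flat lists in the
// same order as the weights).
// [[Rcpp::export]]
Rcpp::List net_grad_cpp(const arma::cube& x, const arma::cube& label,
                        const Rcpp::List& Ws, const Rcpp::List& bs,
                        bool related, double lambda,
                        const Rcpp::IntegerVector& reg_channels,
                        int axis, bool l2) {
  NetDef nd = read_net(Ws, bs, related);
  const int H = x.n_rows, Wd = x.n_cols;
  FwdCache cache;
  cube pred = net_forward_impl(nd, x, &cache);
  cube gout;
  double loss = loss_and_grad(pred, label, lambda, reg_channels, axis, l2, gout);
  if (nd.related) mask_related_cube(gout);

  const int L = nd.W.size();
  Rcpp::List gws(L), gbs(L);

  // tail
  mat G = cube_to_mat(gout);
  gws[L - 1] = mat(G * cache.cols[L - 1].t());
  gbs[L - 1] = vec(sum(G, 1));
  mat gcols = nd.W[L - 1].t() * G;
  const int hid = nd.W[1].n_rows;
  cube ga = col2im3(gcols, H, Wd, hid);

  for (int bl = nd.n_blocks - 1; bl >= 0; --bl) {
    const int li = 1 + 2 * bl;
    // through the post-shortcut ReLU
    cube gs = ga;
    for (size_t i = 0; i < gs.n_elem; ++i)
      if (cache.s[bl](i) <= 0) gs(i) = 0;
    mat G2 = cube_to_mat(gs);
    gws[li + 1] = mat(G2 * cache.cols[li + 1].t());
    gbs[li + 1] = vec(sum(G2, 1));
    cube gr1 = col2im3(nd.W[li + 1].t() * G2, H, Wd, hid);
    for (size_t i = 0; i < gr1.n_elem; ++i)
      if (cache.u1[bl](i) <= 0) gr1(i) = 0;
    mat G1 = cube_to_mat(gr1);
    gws[li] = mat(G1 * cache.cols[li].t());
    gbs[li] = vec(sum(G1, 1));
    ga = gs + col2im3(nd.W[li].t() * G1, H, Wd, hid);
  }

  cube gh0 = ga;
  for (size_t i = 0; i < gh0.n_elem; ++i)
    if (cache.h0(i) <= 0) gh0(i) = 0;
  mat G0 = cube_to_mat(gh0);
  gws[0] = mat(G0 * cache.cols[0].t());
  gbs[0] = vec(sum(G0, 1));

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("gw") = gws,
                            Rcpp::Named("gb") = gbs);
}
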