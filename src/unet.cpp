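// Residual U-Net for 4-class semantic segmentation of CT slices.
//
// Encoder: five residual convolution blocks (two 3x3 convs + identity or
// 1x1-projection shortcut, ReLU), with 2x2 max pooling (stride 2) between
// the first four; decoder: nearest-neighbour 2x upsampling, skip
// concatenation and a residual block per level; head: 1x1 conv + softmax.
// Feature maps are stored channels x pixels (pixel index = row + col*H,
// matching R's column-major rasters); 3x3 convolutions run as im2col + GEMM.
// Training minimises per-pixel multi-class cross-entropy with Adam over
// shuffled minibatches; all randomness is injected from R (weight init by
// seed, shuffling orders precomputed), so runs are bit-reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
#include <random>

using namespace arma;

namespace {

struct Conv {
  int cin, cout, k;
  mat W;   // cout x (cin*k*k)
  vec b;
  mat mW, vW;  // Adam first/second moments
  vec mb, vb;
};

struct Dims {
  ivec enc;  // encoder channels c0..c4
  int K;     // classes
};

// layer schedule; construction order defines the weight-list order
std::vector<Conv> make_layers(const Dims& d) {
  std::vector<Conv> L;
  auto add_block = [&](int cin, int cout) {
    L.push_back({cin, cout, 3, {}, {}, {}, {}, {}, {}});
    L.push_back({cout, cout, 3, {}, {}, {}, {}, {}, {}});
    if (cin != cout) L.push_back({cin, cout, 1, {}, {}, {}, {}, {}, {}});
  };
  add_block(1, (int)d.enc[0]);
  for (int i = 1; i < 5; ++i) add_block((int)d.enc[i - 1], (int)d.enc[i]);
  int prev = (int)d.enc[4];
  for (int j = 0; j < 4; ++j) {
    int skip = (int)d.enc[3 - j];
    add_block(prev + skip, skip);
    prev = skip;
  }
  L.push_back({(int)d.enc[0], d.K, 1, {}, {}, {}, {}, {}, {}});  // head
  return L;
}

int block_nlayers(const std::vector<Conv>& L, int li) {
  return (L[li].cin != L[li].cout) ? 3 : 2;
}

void load_weights(std::vector<Conv>& L, const Rcpp::List& w) {
  if ((size_t)w.size() != 2 * L.size()) Rcpp::stop("weight list has wrong length");
  for (size_t i = 0; i < L.size(); ++i) {
    L[i].W = Rcpp::as<mat>(w[2 * i]);
    L[i].b = Rcpp::as<vec>(w[2 * i + 1]);
    if ((int)L[i].W.n_rows != L[i].cout ||
        (int)L[i].W.n_cols != L[i].cin * L[i].k * L[i].k) {
      Rcpp::stop("weight matrix %d has wrong shape", (int)i + 1);
    }
  }
}

Rcpp::List dump_weights(const std::vector<Conv>& L) {
  Rcpp::List out(2 * L.size());
  Rcpp::CharacterVector nm(2 * L.size());
  for (size_t i = 0; i < L.size(); ++i) {
    out[2 * i] = L[i].W;
    out[2 * i + 1] = L[i].b;
    nm[2 * i] = "W" + std::to_string(i + 1);
    nm[2 * i + 1] = "b" + std::to_string(i + 1);
  }
  out.attr("names") = nm;
  return out;
}

// im2col for 3x3 same-padding convolution; X is C x (H*W)
mat im2col3(const mat& X, int H, int W) {
  const int C = X.n_rows;
  mat out(C * 9, H * W, fill::zeros);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      for (int c = 0; c < W; ++c) {
        const int c2 = c + dc;
        if (c2 < 0 || c2 >= W || r0 > r1) continue;
        out.submat(k * C, c * H + r0, (k + 1) * C - 1, c * H + r1) =
            X.submat(0, c2 * H + r0 + dr, C - 1, c2 * H + r1 + dr);
      }
      ++k;
    }
  }
  return out;
}

// adjoint of im2col3
mat col2im3(const mat& G, int C, int H, int W) {
  mat out(C, H * W, fill::zeros);
  int k = 0;
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
      for (int c = 0; c < W; ++c) {
        const int c2 = c + dc;
        if (c2 < 0 || c2 >= W || r0 > r1) continue;
        out.submat(0, c2 * H + r0 + dr, C - 1, c2 * H + r1 + dr) +=
            G.submat(k * C, c * H + r0, (k + 1) * C - 1, c * H + r1);
      }
      ++k;
    }
  }
  return out;
}

mat conv_fwd(const Conv& c, const mat& X, int H, int W) {
  mat Y = (c.k == 1) ? mat(c.W * X) : mat(c.W * im2col3(X, H, W));
  Y.each_col() += c.b;
  return Y;
}

mat conv_bwd(const Conv& c, const mat& X, const mat& dY, int H, int W,
             mat& dWacc, vec& dbacc) {
  dbacc += sum(dY, 1);
  if (c.k == 1) {
    dWacc += dY * X.t();
    return c.W.t() * dY;
  }
  mat col = im2col3(X, H, W);
  dWacc += dY * col.t();
  return col2im3(c.W.t() * dY, c.cin, H, W);
}

struct BlockCache {
  mat x, a1, out;
  int H = 0, W = 0;
};

mat block_fwd(const std::vector<Conv>& L, int li, const mat& x, int H, int W,
              BlockCache& cc) {
  cc.x = x; cc.H = H; cc.W = W;
  mat a1 = conv_fwd(L[li], x, H, W);
  a1.transform([](double v) { return v > 0 ? v : 0.0; });
  cc.a1 = a1;
  mat a2 = conv_fwd(L[li + 1], a1, H, W);
  if (L[li].cin != L[li].cout) a2 += conv_fwd(L[li + 2], x, H, W);
  else a2 += x;
  a2.transform([](double v) { return v > 0 ? v : 0.0; });
  cc.out = a2;
  return a2;
}

mat block_bwd(const std::vector<Conv>& L, int li, const BlockCache& cc,
              const mat& dout, std::vector<mat>& dW, std::vector<vec>& db) {
  mat dpre = dout % conv_to<mat>::from(cc.out > 0);
  mat da1 = conv_bwd(L[li + 1], cc.a1, dpre, cc.H, cc.W, dW[li + 1], db[li + 1]);
  da1 %= conv_to<mat>::from(cc.a1 > 0);
  mat dx = conv_bwd(L[li], cc.x, da1, cc.H, cc.W, dW[li], db[li]);
  if (L[li].cin != L[li].cout) {
    dx += conv_bwd(L[li + 2], cc.x, dpre, cc.H, cc.W, dW[li + 2], db[li + 2]);
  } else {
    dx += dpre;
  }
  return dx;
}

mat maxpool2(const mat& X, int H, int W, umat& idx) {
  const int C = X.n_rows, H2 = H / 2, W2 = W / 2;
  mat out(C, H2 * W2);
  idx.set_size(C, H2 * W2);
  for (int c2 = 0; c2 < W2; ++c2) {
    for (int r2 = 0; r2 < H2; ++r2) {
      const int p = r2 + c2 * H2;
      const int q[4] = {2 * r2 + 2 * c2 * H, 2 * r2 + 1 + 2 * c2 * H,
                        2 * r2 + (2 * c2 + 1) * H,
                        2 * r2 + 1 + (2 * c2 + 1) * H};
      for (int ch = 0; ch < C; ++ch) {
        double best = X(ch, q[0]); int bi = q[0];
        for (int t = 1; t < 4; ++t) {
          if (X(ch, q[t]) > best) { best = X(ch, q[t]); bi = q[t]; }
        }
        out(ch, p) = best;
        idx(ch, p) = bi;
      }
    }
  }
  return out;
}

mat maxpool2_bwd(const mat& dY, const umat& idx, int HW_in) {
  mat dX(dY.n_rows, HW_in, fill::zeros);
  for (uword p = 0; p < dY.n_cols; ++p) {
    for (uword ch = 0; ch < dY.n_rows; ++ch) {
      dX(ch, idx(ch, p)) += dY(ch, p);
    }
  }
  return dX;
}

mat upsample2(const mat& X, int H, int W) {
  const int H2 = 2 * H, W2 = 2 * W;
  mat out(X.n_rows, H2 * W2);
  for (int c2 = 0; c2 < W2; ++c2) {
    const int cs = c2 / 2;
    for (int r2 = 0; r2 < H2; ++r2) {
      out.col(r2 + c2 * H2) = X.col(r2 / 2 + cs * H);
    }
  }
  return out;
}

mat upsample2_bwd(const mat& dY, int H, int W) {
  const int H2 = 2 * H, W2 = 2 * W;
  mat dX(dY.n_rows, H * W, fill::zeros);
  for (int c2 = 0; c2 < W2; ++c2) {
    const int cs = c2 / 2;
    for (int r2 = 0; r2 < H2; ++r2) {
      dX.col(r2 / 2 + cs * H) += dY.col(r2 + c2 * H2);
    }
  }
  return dX;
}

struct NetCache {
  BlockCache enc[5], dec[4];
  umat pool_idx[4];
  mat head_in;
  int S = 0;
};

// forward pass; returns class logits (K x S*S)
mat net_fwd(const std::vector<Conv>& L, const Dims& d, const mat& x0, int S,
            NetCache& nc) {
  nc.S = S;
  int li = 0, H = S;
  mat cur = x0;
  mat skips[5];
  for (int i = 0; i < 5; ++i) {
    cur = block_fwd(L, li, cur, H, H, nc.enc[i]);
    li += block_nlayers(L, li);
    skips[i] = cur;
    if (i < 4) {
      cur = maxpool2(cur, H, H, nc.pool_idx[i]);
      H /= 2;
    }
  }
  for (int j = 0; j < 4; ++j) {
    mat up = upsample2(cur, H, H);
    H *= 2;
    cur = block_fwd(L, li, join_cols(up, skips[3 - j]), H, H, nc.dec[j]);
    li += block_nlayers(L, li);
  }
  nc.head_in = cur;
  return conv_fwd(L.back(), cur, H, H);
}

void net_bwd(const std::vector<Conv>& L, const Dims& d, const mat& dZ,
             const NetCache& nc, std::vector<mat>& dW, std::vector<vec>& db) {
  std::vector<int> starts;
  int li = 0;
  for (int i = 0; i < 9; ++i) {
    starts.push_back(li);
    li += block_nlayers(L, li);
  }
  const int head = li;
  int H = nc.S;
  mat dskip[4];  // gradients flowing into encoder outputs via the skips
  mat dcur = conv_bwd(L[head], nc.head_in, dZ, H, H, dW[head], db[head]);
  for (int j = 3; j >= 0; --j) {
    dcur = block_bwd(L, starts[5 + j], nc.dec[j], dcur, dW, db);
    const int up_ch = (j == 0) ? (int)d.enc[4] : (int)d.enc[4 - j];
    mat dup = dcur.rows(0, up_ch - 1);
    dskip[3 - j] = dcur.rows(up_ch, dcur.n_rows - 1);
    H /= 2;
    dcur = upsample2_bwd(dup, H, H);
  }
  // dcur now sits at the bottleneck output (e4), H = S/16
  for (int i = 4; i >= 0; --i) {
    mat g = (i == 4) ? dcur : mat(dcur + dskip[i]);
    dcur = block_bwd(L, starts[i], nc.enc[i], g, dW, db);
    if (i > 0) {
      H *= 2;
      dcur = maxpool2_bwd(dcur, nc.pool_idx[i - 1], H * H);
    }
  }
}

mat softmax_cols(const mat& Z) {
  mat P = Z;
  P.each_row() -= max(P, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  return P;
}

// weighted cross-entropy loss and logit gradient; labels are 0-based per
// pixel, w holds one weight per class (all 1 = plain cross-entropy); the
// loss is normalised by the total weight so its scale is comparable across
// weightings
double ce_loss_grad(const mat& Z, const ivec& lab, const vec& w, mat& dZ) {
  mat P = softmax_cols(Z);
  double wsum = 0.0;
  for (uword p = 0; p < Z.n_cols; ++p) wsum += w[(uword)lab[p]];
  double loss = 0.0;
  dZ.set_size(size(P));
  for (uword p = 0; p < Z.n_cols; ++p) {
    const int y = (int)lab[p];
    const double wp = w[y] / wsum;
    loss -= wp * std::log(std::max(P(y, p), 1e-12));
    for (uword c = 0; c < P.n_rows; ++c) dZ(c, p) = wp * P(c, p);
    dZ(y, p) -= wp;
  }
  return loss;
}

void adam_step(std::vector<Conv>& L, const std::vector<mat>& dW,
               const std::vector<vec>& db, double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const double c1 = 1.0 - std::pow(b1, t), c2 = 1.0 - std::pow(b2, t);
  for (size_t i = 0; i < L.size(); ++i) {
    Conv& c = L[i];
    c.mW = b1 * c.mW + (1 - b1) * dW[i];
    c.vW = b2 * c.vW + (1 - b2) * square(dW[i]);
    c.W -= lr * (c.mW / c1) / (sqrt(c.vW / c2) + eps);
    c.mb = b1 * c.mb + (1 - b1) * db[i];
    c.vb = b2 * c.vb + (1 - b2) * square(db[i]);
    c.b -= lr * (c.mb / c1) / (sqrt(c.vb / c2) + eps);
  }
}

// mean IoU of one predicted label image vs truth, absent classes score 1
double mean_iou_labels(const ivec& pred, const ivec& truth, int K) {
  double acc = 0.0;
  for (int c = 0; c < K; ++c) {
    uword inter = 0, uni = 0;
    for (uword p = 0; p < pred.n_elem; ++p) {
      const bool a = pred[p] == c, b = truth[p] == c;
      inter += a && b;
      uni += a || b;
    }
    acc += (uni == 0) ? 1.0 : (double)inter / (double)uni;
  }
  return acc / K;
}

ivec argmax_cols(const mat& Z) {
  ivec out(Z.n_cols);
  for (uword p = 0; p < Z.n_cols; ++p) out[p] = (int)index_max(Z.col(p));
  return out;
}

Dims make_dims(const Rcpp::IntegerVector& channels, int n_classes) {
  if (channels.size() != 5) Rcpp::stop("channels must have length 5");
  Dims d;
  d.enc = ivec(5);
  for (int i = 0; i < 5; ++i) d.enc[i] = channels[i];
  d.K = n_classes;
  return d;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List unet_init_cpp(Rcpp::IntegerVector channels, int n_classes,
                         int seed) {
  Dims d = make_dims(channels, n_classes);
  std::vector<Conv> L = make_layers(d);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  for (auto& c : L) {
    const int fan_in = c.cin * c.k * c.k;
    const double sd = std::sqrt(2.0 / fan_in);
    c.W.set_size(c.cout, fan_in);
    for (uword j = 0; j < c.W.n_cols; ++j) {
      for (uword i = 0; i < c.W.n_rows; ++i) c.W(i, j) = sd * nd(rng);
    }
    c.b.zeros(c.cout);
  }
  return dump_weights(L);
}

// [[Rcpp::export]]
arma::mat unet_forward_cpp(arma::mat x, Rcpp::List weights,
                           Rcpp::IntegerVector channels, int n_classes) {
  const int S = x.n_rows;
  Dims d = make_dims(channels, n_classes);
  std::vector<Conv> L = make_layers(d);
  load_weights(L, weights);
  NetCache nc;
  mat x0 = reshape(x, 1, S * S);
  return softmax_cols(net_fwd(L, d, x0, S, nc));  // K x S*S
}

// loss and analytic weight gradients for one image (gradient checking)
// [[Rcpp::export]]
Rcpp::List unet_lossgrad_cpp(arma::mat x, arma::ivec lab, Rcpp::List weights,
                             Rcpp::IntegerVector channels, int n_classes,
                             arma::vec class_weights) {
  const int S = x.n_rows;
  Dims d = make_dims(channels, n_classes);
  std::vector<Conv> L = make_layers(d);
  load_weights(L, weights);
  std::vector<mat> dW(L.size());
  std::vector<vec> db(L.size());
  for (size_t i = 0; i < L.size(); ++i) {
    dW[i].zeros(size(L[i].W));
    db[i].zeros(L[i].b.n_elem);
  }
  NetCache nc;
  mat x0 = reshape(x, 1, S * S);
  mat Z = net_fwd(L, d, x0, S, nc);
  mat dZ;
  double loss = ce_loss_grad(Z, lab, class_weights, dZ);
  net_bwd(L, d, dZ, nc, dW, db);
  Rcpp::List gW(L.size()), gb(L.size());
  for (size_t i = 0; i < L.size(); ++i) { gW[i] = dW[i]; gb[i] = db[i]; }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("dW") = gW,
                            Rcpp::Named("db") = gb);
}

// [[Rcpp::export]]
Rcpp::List unet_train_cpp(arma::cube X, arma::imat Y,
                          Rcpp::List weights, Rcpp::IntegerVector channels,
                          int n_classes, double lr, int epochs,
                          int batch_size, Rcpp::IntegerVector train_idx,
                          Rcpp::IntegerVector holdout_idx,
                          Rcpp::List orders, arma::vec class_weights) {
  // X: S x S x N images; Y: (S*S) x N 0-based labels
  const int S = X.n_rows;
  Dims d = make_dims(channels, n_classes);
  std::vector<Conv> L = make_layers(d);
  load_weights(L, weights);
  for (auto& c : L) {
    c.mW.zeros(size(c.W)); c.vW.zeros(size(c.W));
    c.mb.zeros(c.b.n_elem); c.vb.zeros(c.b.n_elem);
  }
  const int n_train = train_idx.size(), n_hold = holdout_idx.size();
  std::vector<mat> dW(L.size());
  std::vector<vec> db(L.size());
  mat hist(epochs, 4);  // train loss, holdout loss, train mIoU, holdout mIoU
  int t_adam = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    Rcpp::checkUserInterrupt();
    Rcpp::IntegerVector ord = orders[ep];
    if (ord.size() != n_train) Rcpp::stop("order %d has wrong length", ep + 1);
    double ep_loss = 0.0;
    int done = 0;
    while (done < n_train) {
      const int bs = std::min(batch_size, n_train - done);
      for (size_t i = 0; i < L.size(); ++i) {
        dW[i].zeros(size(L[i].W));
        db[i].zeros(L[i].b.n_elem);
      }
      for (int b = 0; b < bs; ++b) {
        const int img = train_idx[ord[done + b] - 1] - 1;
        mat x0 = reshape(X.slice(img), 1, S * S);
        NetCache nc;
        mat Z = net_fwd(L, d, x0, S, nc);
        mat dZ;
        ep_loss += ce_loss_grad(Z, Y.col(img), class_weights, dZ);
        dZ /= bs;
        net_bwd(L, d, dZ, nc, dW, db);
      }
      adam_step(L, dW, db, lr, ++t_adam);
      done += bs;
    }
    hist(ep, 0) = ep_loss / n_train;
    // epoch-end evaluation (no gradients)
    auto evaluate = [&](const Rcpp::IntegerVector& idx, double& loss_out,
                        double& miou_out) {
      double loss = 0.0, miou = 0.0;
      for (int i = 0; i < idx.size(); ++i) {
        const int img = idx[i] - 1;
        mat x0 = reshape(X.slice(img), 1, S * S);
        NetCache nc;
        mat Z = net_fwd(L, d, x0, S, nc);
        mat dZ;
        loss += ce_loss_grad(Z, Y.col(img), class_weights, dZ);
        miou += mean_iou_labels(argmax_cols(Z), Y.col(img), d.K);
      }
      const int m = std::max((int)idx.size(), 1);
      loss_out = loss / m;
      miou_out = miou / m;
    };
    double tl, tm, hl, hm;
    evaluate(train_idx, tl, tm);
    if (n_hold > 0) evaluate(holdout_idx, hl, hm);
    else { hl = datum::nan; hm = datum::nan; }
    hist(ep, 1) = hl;
    hist(ep, 2) = tm;
    hist(ep, 3) = hm;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = dump_weights(L),
                            Rcpp::Named("history") = hist);
}
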