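// Minimal encoder-decoder ("SegNet-style") semantic segmenter for two-class
// ROI masks, trained with SGD + momentum and random translation
// augmentation. Activations live as (H*W) x C column-major matrices;
// convolutions are im2col + GEMM. All randomness (shuffling, augmentation)
// comes from R's RNG so training is reproducible under set.seed().

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

enum OpType { CONV3 = 0, RELU = 1, POOL = 2, UP = 3, CONV1 = 4 };

struct Net {
  std::vector<int> type;
  std::vector<arma::mat> W;      // conv ops: (Cin*9) x Cout, or Cin x Cout
  std::vector<arma::rowvec> b;
  std::vector<arma::mat> vW;     // momentum buffers
  std::vector<arma::rowvec> vb;
};

arma::mat im2col3(const arma::mat& A, int H, int W) {
  int C = A.n_cols;
  arma::mat out(H * W, C * 9, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    arma::mat chan(const_cast<double*>(A.colptr(c)), H, W, false, true);
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        arma::mat sh(H, W, arma::fill::zeros);
        int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
        int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
        if (r1 >= r0 && c1 >= c0)
          sh.submat(r0, c0, r1, c1) =
              chan.submat(r0 + dr, c0 + dc, r1 + dr, c1 + dc);
        out.col(col++) = arma::vectorise(sh);
      }
  }
  return out;
}

arma::mat col2im3(const arma::mat& dcol, int H, int W, int C) {
  arma::mat dA(H * W, C, arma::fill::zeros);
  int col = 0;
  for (int c = 0; c < C; ++c) {
    arma::mat chan(dA.colptr(c), H, W, false, true);
    for (int dc = -1; dc <= 1; ++dc)
      for (int dr = -1; dr <= 1; ++dr) {
        arma::mat sh(const_cast<double*>(dcol.colptr(col)), H, W, false, true);
        int r0 = std::max(0, -dr), r1 = H - 1 - std::max(0, dr);
        int c0 = std::max(0, -dc), c1 = W - 1 - std::max(0, dc);
        if (r1 >= r0 && c1 >= c0)
          chan.submat(r0 + dr, c0 + dc, r1 + dr, c1 + dc) +=
              sh.submat(r0, c0, r1, c1);
        ++col;
      }
  }
  return dA;
}

arma::mat pool2(const arma::mat& A, int H, int W, arma::umat& idx) {
  int C = A.n_cols, Hp = H / 2, Wp = W / 2;
  arma::mat out(Hp * Wp, C);
  idx.set_size(Hp * Wp, C);
  for (int c = 0; c < C; ++c) {
    const double* a = A.colptr(c);
    for (int j = 0; j < Wp; ++j)
      for (int i = 0; i < Hp; ++i) {
        int best = (2 * i) + (2 * j) * H;
        double bv = a[best];
        const int cand[3] = {(2 * i + 1) + (2 * j) * H,
                             (2 * i) + (2 * j + 1) * H,
                             (2 * i + 1) + (2 * j + 1) * H};
        for (int k = 0; k < 3; ++k)
          if (a[cand[k]] > bv) { bv = a[cand[k]]; best = cand[k]; }
        out(i + j * Hp, c) = bv;
        idx(i + j * Hp, c) = best;
      }
  }
  return out;
}

arma::mat unpool2_grad(const arma::mat& dY, const arma::umat& idx,
                       int H, int W) {
  int C = dY.n_cols;
  arma::mat dA(H * W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (arma::uword k = 0; k < dY.n_rows; ++k)
      dA(idx(k, c), c) += dY(k, c);
  return dA;
}

arma::uvec up_map(int H, int W) {  // src index for each pixel of the 2H x 2W grid
  arma::uvec map(4 * H * W);
  int Ho = 2 * H;
  for (int c = 0; c < 2 * W; ++c)
    for (int r = 0; r < Ho; ++r)
      map(r + c * Ho) = (r / 2) + (c / 2) * H;
  return map;
}

struct Cache {
  std::vector<arma::mat> in;
  std::vector<int> H, W;
  std::vector<arma::umat> poolidx;
  arma::mat logits;
};

void forward(Net& net, const arma::mat& img, int H, int W, Cache& cc) {
  arma::mat A = img;  // (H*W) x 1
  int curH = H, curW = W;
  size_t nops = net.type.size();
  cc.in.resize(nops); cc.H.resize(nops); cc.W.resize(nops);
  cc.poolidx.assign(nops, arma::umat());
  for (size_t k = 0; k < nops; ++k) {
    cc.in[k] = A; cc.H[k] = curH; cc.W[k] = curW;
    switch (net.type[k]) {
      case CONV3: {
        arma::mat Xc = im2col3(A, curH, curW);
        A = Xc * net.W[k];
        A.each_row() += net.b[k];
        break;
      }
      case RELU: A = arma::clamp(A, 0.0, arma::datum::inf); break;
      case POOL: {
        arma::umat idx;
        A = pool2(A, curH, curW, idx);
        cc.poolidx[k] = idx;
        curH /= 2; curW /= 2;
        break;
      }
      case UP: {
        A = A.rows(up_map(curH, curW));
        curH *= 2; curW *= 2;
        break;
      }
      case CONV1: {
        A = A * net.W[k];
        A.each_row() += net.b[k];
        break;
      }
    }
  }
  cc.logits = A;
}

void backward_update(Net& net, Cache& cc, const arma::mat& dLogits,
                     double lr, double momentum) {
  arma::mat dA = dLogits;
  for (int k = (int)net.type.size() - 1; k >= 0; --k) {
    const arma::mat& A = cc.in[k];
    int H = cc.H[k], W = cc.W[k];
    switch (net.type[k]) {
      case CONV3: {
        arma::mat Xc = im2col3(A, H, W);
        arma::mat dW = Xc.t() * dA;
        arma::rowvec db = arma::sum(dA, 0);
        arma::mat dXc = dA * net.W[k].t();
        dA = col2im3(dXc, H, W, (int)A.n_cols);
        net.vW[k] = momentum * net.vW[k] - lr * dW;
        net.vb[k] = momentum * net.vb[k] - lr * db;
        net.W[k] += net.vW[k];
        net.b[k] += net.vb[k];
        break;
      }
      case RELU: dA = dA % (A > 0); break;
      case POOL: dA = unpool2_grad(dA, cc.poolidx[k], H, W); break;
      case UP: {
        arma::uvec map = up_map(H, W);
        arma::mat acc(H * W, dA.n_cols, arma::fill::zeros);
        for (arma::uword c = 0; c < dA.n_cols; ++c)
          for (arma::uword i = 0; i < map.n_elem; ++i)
            acc(map(i), c) += dA(i, c);
        dA = acc;
        break;
      }
      case CONV1: {
        arma::mat dW = A.t() * dA;
        arma::rowvec db = arma::sum(dA, 0);
        dA = dA * net.W[k].t();
        net.vW[k] = momentum * net.vW[k] - lr * dW;
        net.vb[k] = momentum * net.vb[k] - lr * db;
        net.W[k] += net.vW[k];
        net.b[k] += net.vb[k];
        break;
      }
    }
  }
}

// cross-entropy grad and pixel accuracy; y is 0/1 per pixel
double ce_grad(const arma::mat& logits, const arma::ivec& y, arma::mat& dL,
               double& acc) {
  int n = (int)logits.n_rows;
  dL.set_size(n, 2);
  double loss = 0; int correct = 0;
  for (int i = 0; i < n; ++i) {
    double m = std::max(logits(i, 0), logits(i, 1));
    double e0 = std::exp(logits(i, 0) - m), e1 = std::exp(logits(i, 1) - m);
    double Z = e0 + e1, p0 = e0 / Z, p1 = e1 / Z;
    int yi = y(i);
    loss -= std::log(std::max(yi == 1 ? p1 : p0, 1e-12));
    dL(i, 0) = (p0 - (yi == 0 ? 1.0 : 0.0)) / n;
    dL(i, 1) = (p1 - (yi == 1 ? 1.0 : 0.0)) / n;
    int pred = logits(i, 1) > logits(i, 0) ? 1 : 0;  // tie -> not-ROI
    if (pred == yi) ++correct;
  }
  acc = (double)correct / n;
  return loss / n;
}

Net net_from_list(List ops) {
  Net net;
  for (int k = 0; k < ops.size(); ++k) {
    List op = ops[k];
    std::string t = as<std::string>(op["type"]);
    int code = t == "conv3" ? CONV3 : t == "relu" ? RELU : t == "pool" ? POOL
               : t == "up" ? UP : CONV1;
    net.type.push_back(code);
    if (code == CONV3 || code == CONV1) {
      net.W.push_back(as<arma::mat>(op["W"]));
      net.b.push_back(as<arma::rowvec>(op["b"]));
    } else {
      net.W.push_back(arma::mat());
      net.b.push_back(arma::rowvec());
    }
    net.vW.push_back(arma::mat(net.W.back().n_rows, net.W.back().n_cols,
                               arma::fill::zeros));
    net.vb.push_back(arma::rowvec(net.b.back().n_elem, arma::fill::zeros));
  }
  return net;
}

List net_to_list(const Net& net, List ops) {
  for (size_t k = 0; k < net.type.size(); ++k) {
    if (net.type[k] == CONV3 || net.type[k] == CONV1) {
      List op = ops[k];
      op["W"] = wrap(net.W[k]);
      op["b"] = wrap(arma::vec(net.b[k].t()));
      ops[k] = op;
    }
  }
  return ops;
}

// edge-replicated translation of an image (double) or mask (int)
template <typename M>
M shift_mat(const M& A, int dr, int dc) {
  int H = A.n_rows, Wd = A.n_cols;
  M out(H, Wd);
  for (int c = 0; c < Wd; ++c) {
    int sc = std::min(std::max(c - dc, 0), Wd - 1);
    for (int r = 0; r < H; ++r) {
      int sr = std::min(std::max(r - dr, 0), H - 1);
      out(r, c) = A(sr, sc);
    }
  }
  return out;
}

int runif_int(int lo, int hi) {  // inclusive
  int v = lo + (int)(unif_rand() * (hi - lo + 1));
  return std::min(v, hi);
}

double eval_net(Net& net, const std::vector<arma::mat>& imgs,
                const std::vector<arma::imat>& masks) {
  if (imgs.empty()) return NA_REAL;
  double acc = 0;
  Cache cc;
  for (size_t i = 0; i < imgs.size(); ++i) {
    int H = (int)imgs[i].n_rows, W = (int)imgs[i].n_cols;
    arma::mat flat = arma::reshape(imgs[i], H * W, 1);
    forward(net, flat, H, W, cc);
    int correct = 0, n = H * W;
    arma::ivec y = arma::vectorise(masks[i]);
    for (int p = 0; p < n; ++p) {
      int pred = cc.logits(p, 1) > cc.logits(p, 0) ? 1 : 0;
      if (pred == y(p)) ++correct;
    }
    acc += (double)correct / n;
  }
  return acc / imgs.size();
}

} // namespace

// [[Rcpp::export(name = ".train_segnet_cpp")]]
List train_segnet_cpp(List ops, List train_imgs, List train_masks,
                      List val_imgs, List val_masks,
                      int epochs, double lr, double momentum, int aug) {
  Net net = net_from_list(ops);
  int n = train_imgs.size();
  std::vector<arma::mat> timg(n), vimg;
  std::vector<arma::imat> tmask(n), vmask;
  for (int i = 0; i < n; ++i) {
    timg[i] = as<arma::mat>(train_imgs[i]);
    tmask[i] = as<arma::imat>(train_masks[i]);
  }
  for (int i = 0; i < val_imgs.size(); ++i) {
    vimg.push_back(as<arma::mat>(val_imgs[i]));
    vmask.push_back(as<arma::imat>(val_masks[i]));
  }
  NumericVector train_acc(epochs), val_acc(epochs), loss_log(epochs);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  Cache cc;
  arma::mat dL;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i)  // Fisher-Yates with R's RNG
      std::swap(order[i], order[runif_int(0, i)]);
    double acc_sum = 0, loss_sum = 0;
    for (int ii = 0; ii < n; ++ii) {
      const arma::mat& img0 = timg[order[ii]];
      const arma::imat& msk0 = tmask[order[ii]];
      int H = (int)img0.n_rows, W = (int)img0.n_cols;
      arma::mat img = img0;
      arma::imat msk = msk0;
      if (aug > 0) {
        int dr = runif_int(-aug, aug), dc = runif_int(-aug, aug);
        img = shift_mat(img0, dr, dc);
        msk = shift_mat(msk0, dr, dc);
      }
      arma::mat flat = arma::reshape(img, H * W, 1);
      forward(net, flat, H, W, cc);
      double acc;
      arma::ivec y = arma::vectorise(msk);
      loss_sum += ce_grad(cc.logits, y, dL, acc);
      acc_sum += acc;
      backward_update(net, cc, dL, lr, momentum);
      if (ii % 32 == 0) Rcpp::checkUserInterrupt();
    }
    train_acc[ep] = acc_sum / n;
    loss_log[ep] = loss_sum / n;
    val_acc[ep] = eval_net(net, vimg, vmask);
  }
  return List::create(_["ops"] = net_to_list(net, ops),
                      _["train_acc"] = train_acc,
                      _["val_acc"] = val_acc,
                      _["loss"] = loss_log);
}

// [[Rcpp::export(name = ".predict_segnet_cpp")]]
IntegerMatrix predict_segnet_cpp(List ops, NumericMatrix img) {
  Net net = net_from_list(ops);
  arma::mat A = as<arma::mat>(img);
  int H = (int)A.n_rows, W = (int)A.n_cols;
  arma::mat flat = arma::reshape(A, H * W, 1);
  Cache cc;
  forward(net, flat, H, W, cc);
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      int p = r + c * H;
      out(r, c) = cc.logits(p, 1) > cc.logits(p, 0) ? 1 : 0;
    }
  return out;
}
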