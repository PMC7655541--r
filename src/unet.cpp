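// Encoder-decoder segmentation network (U-Net style), single precision
// (the usual arithmetic for CNN training; deterministic on one thread).
// Feature maps are (H*W) x C matrices, pixel index = col*H + row (R order).
// Conv weights arrive as R arrays dim (3,3,Cin,Cout) flattened column-major,
// i.e. a (9*Cin) x Cout matrix whose row index is kr + 3*kc + 9*ci.
//
// Layer order (li = 0-based index into the weight list, one (W,b) pair each):
//   encoder level d = 0..depth-1 : convA li=2d, convB li=2d+1, then 2x2 pool
//   bottleneck                   : convA li=2*depth, convB li=2*depth+1
//   decoder level d = depth-1..0 : upsample, concat skip[d],
//                                  convA li=2*depth+2+2*(depth-1-d), convB +1
//   head                         : 1x1 conv li=4*depth+2, sigmoid
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef arma::fmat mat;
typedef arma::fvec fvec;
typedef arma::frowvec frowvec;

using arma::uword;

static mat im2col3(const mat& X, int H, int W) {
  const int N = H * W, Cin = (int)X.n_cols;
  mat M(N, (uword)9 * Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    const float* src = X.colptr(ci);
    for (int kc = 0; kc < 3; ++kc) {
      int dc = kc - 1;
      for (int kr = 0; kr < 3; ++kr) {
        int dr = kr - 1;
        float* dst = M.colptr((uword)(kr + 3 * kc + 9 * ci));
        int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int c = c0; c < c1; ++c)
          std::memcpy(dst + (size_t)c * H + r0,
                      src + (size_t)(c + dc) * H + (r0 + dr),
                      sizeof(float) * (r1 - r0));
      }
    }
  }
  return M;
}

static mat col2im3(const mat& dM, int H, int W, int Cin) {
  mat dX(H * W, Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    float* dst = dX.colptr(ci);
    for (int kc = 0; kc < 3; ++kc) {
      int dc = kc - 1;
      for (int kr = 0; kr < 3; ++kr) {
        int dr = kr - 1;
        const float* src = dM.colptr((uword)(kr + 3 * kc + 9 * ci));
        int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
        int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
        for (int c = c0; c < c1; ++c) {
          float* drow = dst + (size_t)(c + dc) * H + (r0 + dr);
          const float* srow = src + (size_t)c * H + r0;
          for (int r = 0; r < r1 - r0; ++r) drow[r] += srow[r];
        }
      }
    }
  }
  return dX;
}

struct ConvCache {
  mat M;  // im2col of input (empty in inference mode)
  mat A;  // post-ReLU output
  int H = 0, W = 0, Cin = 0;
};

struct Net {
  std::vector<mat> W;
  std::vector<frowvec> b;
  int depth;
};

static Net unpack(List weights, int depth) {
  Net net;
  net.depth = depth;
  for (int i = 0; i < weights.size(); i += 2) {
    NumericVector w = weights[i];
    NumericVector bb = weights[i + 1];
    int cout = (int)bb.size();
    arma::mat wd(const_cast<double*>(w.begin()), (uword)(w.size() / cout),
                 cout, false);
    arma::rowvec bd(const_cast<double*>(bb.begin()), cout, false);
    net.W.push_back(arma::conv_to<mat>::from(wd));
    net.b.push_back(arma::conv_to<frowvec>::from(bd));
  }
  return net;
}

static mat conv_relu(const Net& net, int li, const mat& X, int H, int W,
                     ConvCache* cache) {
  mat M = im2col3(X, H, W);
  mat Y = M * net.W[li];
  Y.each_row() += net.b[li];
  Y.transform([](float v) { return v > 0 ? v : 0.0f; });
  if (cache) {
    cache->M = std::move(M);
    cache->A = Y;
    cache->H = H;
    cache->W = W;
    cache->Cin = (int)X.n_cols;
  }
  return Y;
}

static mat conv_backward(const Net& net, int li, const ConvCache& C, mat dY,
                         std::vector<mat>& gW, std::vector<frowvec>& gb) {
  dY %= arma::conv_to<mat>::from(C.A > 0);
  gW[li] = C.M.t() * dY;
  gb[li] = arma::sum(dY, 0);
  mat dM = dY * net.W[li].t();
  return col2im3(dM, C.H, C.W, C.Cin);
}

static mat maxpool2(const mat& X, int H, int W, arma::umat* argmax) {
  int Ho = H / 2, Wo = W / 2, C = (int)X.n_cols;
  mat Y(Ho * Wo, C);
  if (argmax) argmax->set_size(Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const float* src = X.colptr(ch);
    float* dst = Y.colptr(ch);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        size_t i00 = (size_t)(2 * c) * H + 2 * r;
        size_t idx[4] = {i00, i00 + 1, i00 + H, i00 + H + 1};
        int best = 0;
        for (int k = 1; k < 4; ++k)
          if (src[idx[k]] > src[idx[best]]) best = k;
        dst[(size_t)c * Ho + r] = src[idx[best]];
        if (argmax) (*argmax)((size_t)c * Ho + r, ch) = idx[best];
      }
  }
  return Y;
}

static mat upsample2(const mat& X, int H, int W) {
  int Ho = H * 2, Wo = W * 2, C = (int)X.n_cols;
  mat Y((uword)Ho * Wo, C);
  for (int ch = 0; ch < C; ++ch) {
    const float* src = X.colptr(ch);
    float* dst = Y.colptr(ch);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r)
        dst[(size_t)c * Ho + r] = src[(size_t)(c / 2) * H + r / 2];
  }
  return Y;
}

static mat upsample2_backward(const mat& dY, int H, int W) {
  // H, W are the small (pre-upsample) dims
  int Ho = H * 2, Wo = W * 2, C = (int)dY.n_cols;
  mat dX((uword)H * W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    float* dst = dX.colptr(ch);
    const float* src = dY.colptr(ch);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r)
        dst[(size_t)(c / 2) * H + r / 2] += src[(size_t)c * Ho + r];
  }
  return dX;
}

struct ForwardState {
  std::vector<ConvCache> conv;
  std::vector<arma::umat> pool_argmax;  // per encoder level
  fvec p;
};

static fvec unet_forward_impl(const Net& net, const mat& img, int H, int W,
                                   ForwardState* st) {
  const int depth = net.depth;
  const bool keep = st != nullptr;
  ForwardState local;
  ForwardState& S = keep ? *st : local;
  if (keep) {
    S.conv.resize(4 * depth + 3);
    S.pool_argmax.resize(depth);
  }
  mat X = img;
  std::vector<mat> skips(depth);
  int h = H, w = W, li = 0;
  for (int d = 0; d < depth; ++d) {
    X = conv_relu(net, li, X, h, w, keep ? &S.conv[li] : nullptr);
    ++li;
    X = conv_relu(net, li, X, h, w, keep ? &S.conv[li] : nullptr);
    ++li;
    skips[d] = X;
    X = maxpool2(X, h, w, keep ? &S.pool_argmax[d] : nullptr);
    h /= 2;
    w /= 2;
  }
  X = conv_relu(net, li, X, h, w, keep ? &S.conv[li] : nullptr);
  ++li;
  X = conv_relu(net, li, X, h, w, keep ? &S.conv[li] : nullptr);
  ++li;
  for (int d = depth - 1; d >= 0; --d) {
    mat up = upsample2(X, h, w);
    h *= 2;
    w *= 2;
    mat cat = arma::join_rows(up, skips[d]);
    X = conv_relu(net, li, cat, h, w, keep ? &S.conv[li] : nullptr);
    ++li;
    X = conv_relu(net, li, X, h, w, keep ? &S.conv[li] : nullptr);
    ++li;
  }
  fvec z = X * net.W[li].col(0) + net.b[li](0);
  if (keep) S.conv[li].A = std::move(X);
  fvec p = 1.0f / (1.0f + arma::exp(-z));
  if (keep) S.p = p;
  return p;
}

// [[Rcpp::export(name = ".cpp_unet_forward")]]
NumericVector cpp_unet_forward(List weights, NumericVector image, int H, int W,
                               int cin, int depth) {
  Net net = unpack(weights, depth);
  arma::mat imgd(const_cast<double*>(image.begin()), (uword)H * W, cin,
                 false);
  mat img = arma::conv_to<mat>::from(imgd);
  fvec p = unet_forward_impl(net, img, H, W, nullptr);
  return NumericVector(p.begin(), p.end());
}

// Soft-Dice + BCE loss and the full parameter gradient for one image/mask pair.
// [[Rcpp::export(name = ".cpp_unet_grad")]]
List cpp_unet_grad(List weights, NumericVector image, NumericVector target,
                   int H, int W, int cin, int depth, double bce_weight,
                   double dice_weight) {
  Net net = unpack(weights, depth);
  arma::mat imgd(const_cast<double*>(image.begin()), (uword)H * W, cin,
                 false);
  mat img = arma::conv_to<mat>::from(imgd);
  arma::vec yd(const_cast<double*>(target.begin()), (uword)H * W, false);
  fvec y = arma::conv_to<fvec>::from(yd);
  ForwardState S;
  unet_forward_impl(net, img, H, W, &S);
  const fvec& p = S.p;
  const float N = (float)p.n_elem, eps = 1e-6f;
  fvec pc = arma::clamp(p, eps, 1.0f - eps);
  float bce = -arma::mean(y % arma::log(pc) + (1.0f - y) % arma::log(1.0f - pc));
  float sp = arma::accu(p), sy = arma::accu(y), spy = arma::accu(p % y);
  const float deps = 1.0f;
  float dice = (2.0f * spy + deps) / (sp + sy + deps);
  double loss = (double)bce_weight * bce + dice_weight * (1.0f - dice);

  fvec dz = (float)bce_weight * (p - y) / N;
  float denom = sp + sy + deps;
  fvec ddice_dp = (2.0f * y * denom - (2.0f * spy + deps)) / (denom * denom);
  dz += (float)dice_weight * (-ddice_dp) % (p % (1.0f - p));

  const int n_layers = 4 * depth + 3;
  std::vector<mat> gW(n_layers);
  std::vector<frowvec> gb(n_layers);

  // head
  int li = n_layers - 1;
  const mat& Xhead = S.conv[li].A;
  gW[li] = Xhead.t() * dz;
  gb[li].set_size(1);
  gb[li](0) = arma::accu(dz);
  mat dX = dz * net.W[li].col(0).t();

  // decoder levels, last executed first (d = 0 is full resolution)
  std::vector<mat> skip_grad(depth);
  for (int d = 0; d < depth; ++d) {
    int liA = 2 * depth + 2 + 2 * (depth - 1 - d);
    dX = conv_backward(net, liA + 1, S.conv[liA + 1], std::move(dX), gW, gb);
    dX = conv_backward(net, liA, S.conv[liA], std::move(dX), gW, gb);
    int skip_ch = (int)S.conv[2 * d + 1].A.n_cols;
    int up_ch = (int)dX.n_cols - skip_ch;
    skip_grad[d] = dX.cols(up_ch, dX.n_cols - 1);
    mat d_up = dX.cols(0, up_ch - 1);
    dX = upsample2_backward(d_up, H >> (d + 1), W >> (d + 1));
  }

  // bottleneck
  dX = conv_backward(net, 2 * depth + 1, S.conv[2 * depth + 1], std::move(dX),
                     gW, gb);
  dX = conv_backward(net, 2 * depth, S.conv[2 * depth], std::move(dX), gW, gb);

  // encoder levels, deepest first
  for (int d = depth - 1; d >= 0; --d) {
    int h = H >> d, w = W >> d;
    mat dPre((uword)h * w, S.conv[2 * d + 1].A.n_cols, arma::fill::zeros);
    const arma::umat& am = S.pool_argmax[d];
    for (uword ch = 0; ch < dPre.n_cols; ++ch) {
      float* dst = dPre.colptr(ch);
      const float* src = dX.colptr(ch);
      for (uword i = 0; i < dX.n_rows; ++i) dst[am(i, ch)] += src[i];
    }
    dPre += skip_grad[d];
    dPre = conv_backward(net, 2 * d + 1, S.conv[2 * d + 1], std::move(dPre),
                         gW, gb);
    dPre = conv_backward(net, 2 * d, S.conv[2 * d], std::move(dPre), gW, gb);
    dX = std::move(dPre);
  }

  List grads(2 * n_layers);
  for (int i = 0; i < n_layers; ++i) {
    grads[2 * i] = NumericVector(gW[i].begin(), gW[i].end());
    grads[2 * i + 1] = NumericVector(gb[i].begin(), gb[i].end());
  }
  return List::create(_["loss"] = loss, _["bce"] = bce, _["dice"] = dice,
                      _["grads"] = grads);
}
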