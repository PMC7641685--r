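// Compact sequential CNN for 8-bit grayscale mammogram classification:
// stacked valid-convolution + ReLU + max-pool blocks, one dense ReLU layer
// with inverted dropout, and a single sigmoid output, trained with Adam on a
// class-weighted binary cross-entropy. Written against Armadillo (im2col +
// GEMM) so training at the 100x100 input scale stays desk-fast on one CPU.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

struct LayerShape {
  int in_h, in_w, in_c;   // input to the conv
  int co_h, co_w;         // after valid conv
  int po_h, po_w;         // after pooling
  int f;                  // filters
};

struct NetShape {
  int k, p, dense_units, flat;
  std::vector<LayerShape> conv;
};

NetShape make_shape(int in_h, int in_w, const IntegerVector& filters, int k,
                    int p, int dense_units) {
  NetShape s;
  s.k = k; s.p = p; s.dense_units = dense_units;
  int h = in_h, w = in_w, c = 1;
  for (int l = 0; l < filters.size(); ++l) {
    LayerShape ls;
    ls.in_h = h; ls.in_w = w; ls.in_c = c; ls.f = filters[l];
    ls.co_h = h - k + 1; ls.co_w = w - k + 1;
    if (ls.co_h < 1 || ls.co_w < 1)
      stop("convolution block %d does not fit the input size", l + 1);
    ls.po_h = ls.co_h / p; ls.po_w = ls.co_w / p;
    if (ls.po_h < 1 || ls.po_w < 1)
      stop("pooling in block %d collapses the feature map", l + 1);
    s.conv.push_back(ls);
    h = ls.po_h; w = ls.po_w; c = ls.f;
  }
  s.flat = h * w * c;
  return s;
}

struct Net {
  NetShape shape;
  std::vector<mat> Wc;  // filters x in_c*k*k
  std::vector<vec> bc;
  mat Wd; vec bd;       // dense_units x flat
  mat Wo; vec bo;       // 1 x dense_units
};

Net net_from_list(const List& weights, const NetShape& shape) {
  Net net;
  net.shape = shape;
  List cw = weights["conv_w"], cb = weights["conv_b"];
  for (int l = 0; l < (int)shape.conv.size(); ++l) {
    net.Wc.push_back(as<mat>(cw[l]));
    net.bc.push_back(as<vec>(cb[l]));
  }
  net.Wd = as<mat>(weights["dense_w"]);
  net.bd = as<vec>(weights["dense_b"]);
  net.Wo = as<mat>(weights["out_w"]);
  net.bo = as<vec>(weights["out_b"]);
  return net;
}

List net_to_list(const Net& net) {
  List cw(net.Wc.size()), cb(net.bc.size());
  for (size_t l = 0; l < net.Wc.size(); ++l) {
    cw[l] = net.Wc[l];
    cb[l] = net.bc[l];
  }
  return List::create(_["conv_w"] = cw, _["conv_b"] = cb,
                      _["dense_w"] = net.Wd, _["dense_b"] = net.bd,
                      _["out_w"] = net.Wo, _["out_b"] = net.bo);
}

// Unfold k x k patches of a (h, w, c) feature cube stored as a stack of
// channel matrices; column j*co_h + i holds the patch at output position
// (i, j), rows ordered channel-major then column-major within the patch.
mat im2col(const std::vector<mat>& x, const LayerShape& ls, int k) {
  mat out(ls.in_c * k * k, ls.co_h * ls.co_w);
  for (int ch = 0; ch < ls.in_c; ++ch)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        uword row = ch * k * k + dj * k + di;
        for (int j = 0; j < ls.co_w; ++j)
          for (int i = 0; i < ls.co_h; ++i)
            out(row, (uword)j * ls.co_h + i) = x[ch](i + di, j + dj);
      }
  return out;
}

void col2im_add(std::vector<mat>& dx, const mat& dcol, const LayerShape& ls,
                int k) {
  for (int ch = 0; ch < ls.in_c; ++ch)
    for (int dj = 0; dj < k; ++dj)
      for (int di = 0; di < k; ++di) {
        uword row = ch * k * k + dj * k + di;
        for (int j = 0; j < ls.co_w; ++j)
          for (int i = 0; i < ls.co_h; ++i)
            dx[ch](i + di, j + dj) += dcol(row, (uword)j * ls.co_h + i);
      }
}

struct ConvCache {
  mat cols;          // im2col of the input
  arma::umat relu;   // ReLU mask on conv output (f x co_h*co_w)
  arma::umat argmax; // pooled argmax, linear index into co grid (f x po)
  mat pooled;        // f x po_h*po_w
};

struct Cache {
  std::vector<ConvCache> conv;
  vec flat;
  vec h1;            // dense activations after ReLU (and dropout at train)
  arma::uvec drop;   // dropout keep mask
  double p;          // predicted probability
};

double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

// Forward one sample; x100 is the raw input matrix. When `train` is true a
// dropout mask drawn from `gen` is applied to the dense layer.
void forward_sample(const Net& net, const mat& x, Cache& cc, bool train,
                    double dropout, std::mt19937& gen) {
  const NetShape& s = net.shape;
  std::vector<mat> cur{x};
  cc.conv.resize(s.conv.size());
  for (size_t l = 0; l < s.conv.size(); ++l) {
    const LayerShape& ls = s.conv[l];
    ConvCache& c = cc.conv[l];
    c.cols = im2col(cur, ls, s.k);
    mat z = net.Wc[l] * c.cols;
    z.each_col() += net.bc[l];
    c.relu = (z > 0);
    z.elem(arma::find(z < 0)).zeros();
    // max-pool each channel on the (co_h, co_w) grid
    int po = ls.po_h * ls.po_w;
    c.pooled.set_size(ls.f, po);
    c.argmax.set_size(ls.f, po);
    for (int f = 0; f < ls.f; ++f) {
      for (int pj = 0; pj < ls.po_w; ++pj)
        for (int pi = 0; pi < ls.po_h; ++pi) {
          double best = -1.0; uword bidx = 0;
          for (int dj = 0; dj < s.p; ++dj)
            for (int di = 0; di < s.p; ++di) {
              uword idx = (uword)(pj * s.p + dj) * ls.co_h + pi * s.p + di;
              double v = z(f, idx);
              if (v > best) { best = v; bidx = idx; }
            }
          uword pidx = (uword)pj * ls.po_h + pi;
          c.pooled(f, pidx) = best;
          c.argmax(f, pidx) = bidx;
        }
    }
    cur.clear();
    for (int f = 0; f < ls.f; ++f)
      cur.push_back(arma::reshape(c.pooled.row(f), ls.po_h, ls.po_w));
  }
  cc.flat.set_size(s.flat);
  uword off = 0;
  for (size_t ch = 0; ch < cur.size(); ++ch) {
    cc.flat.subvec(off, off + cur[ch].n_elem - 1) = arma::vectorise(cur[ch]);
    off += cur[ch].n_elem;
  }
  vec z1 = net.Wd * cc.flat + net.bd;
  cc.h1 = z1;
  cc.h1.elem(arma::find(z1 < 0)).zeros();
  if (train && dropout > 0) {
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    cc.drop.set_size(cc.h1.n_elem);
    for (uword i = 0; i < cc.h1.n_elem; ++i)
      cc.drop(i) = unif(gen) >= dropout ? 1 : 0;
    for (uword i = 0; i < cc.h1.n_elem; ++i)
      cc.h1(i) = cc.drop(i) ? cc.h1(i) / (1.0 - dropout) : 0.0;
  } else {
    cc.drop.reset();
  }
  double z2 = arma::as_scalar(net.Wo * cc.h1) + net.bo(0);
  cc.p = sigmoid(z2);
}

struct Grads {
  std::vector<mat> Wc; std::vector<vec> bc;
  mat Wd; vec bd; mat Wo; vec bo;
  void zero_like(const Net& net) {
    Wc.clear(); bc.clear();
    for (size_t l = 0; l < net.Wc.size(); ++l) {
      Wc.push_back(arma::zeros<mat>(arma::size(net.Wc[l])));
      bc.push_back(arma::zeros<vec>(net.bc[l].n_elem));
    }
    Wd = arma::zeros<mat>(arma::size(net.Wd));
    bd = arma::zeros<vec>(net.bd.n_elem);
    Wo = arma::zeros<mat>(arma::size(net.Wo));
    bo = arma::zeros<vec>(1);
  }
};

// Backpropagate one sample given its forward cache; dz is dLoss/dlogit.
void backward_sample(const Net& net, const mat& x, const Cache& cc, double dz,
                     double dropout, Grads& g) {
  const NetShape& s = net.shape;
  g.Wo += dz * cc.h1.t();
  g.bo(0) += dz;
  vec dh1 = net.Wo.t() * dz;
  if (cc.drop.n_elem > 0)
    for (uword i = 0; i < dh1.n_elem; ++i)
      dh1(i) = cc.drop(i) ? dh1(i) / (1.0 - dropout) : 0.0;
  for (uword i = 0; i < dh1.n_elem; ++i)
    if (cc.h1(i) <= 0) dh1(i) = 0;      // ReLU (h1 kept post-dropout scale)
  g.Wd += dh1 * cc.flat.t();
  g.bd += dh1;
  vec dflat = net.Wd.t() * dh1;

  // back through the conv blocks, last to first
  uword off = dflat.n_elem;
  std::vector<mat> dcur;                // gradient on current block's output
  for (int l = (int)s.conv.size() - 1; l >= 0; --l) {
    const LayerShape& ls = s.conv[l];
    const ConvCache& c = cc.conv[l];
    mat dpool(ls.f, ls.po_h * ls.po_w);
    if (l == (int)s.conv.size() - 1) {
      uword per = (uword)ls.po_h * ls.po_w;
      off -= per * ls.f;
      for (int f = 0; f < ls.f; ++f)
        dpool.row(f) =
            dflat.subvec(off + f * per, off + (f + 1) * per - 1).t();
    } else {
      for (int f = 0; f < ls.f; ++f)
        dpool.row(f) = arma::vectorise(dcur[f]).t();
    }
    mat dz_conv(ls.f, (uword)ls.co_h * ls.co_w, arma::fill::zeros);
    for (int f = 0; f < ls.f; ++f)
      for (uword pidx = 0; pidx < (uword)ls.po_h * ls.po_w; ++pidx)
        dz_conv(f, c.argmax(f, pidx)) += dpool(f, pidx);
    dz_conv %= arma::conv_to<mat>::from(c.relu);
    g.Wc[l] += dz_conv * c.cols.t();
    g.bc[l] += arma::sum(dz_conv, 1);
    if (l > 0) {
      mat dcol = net.Wc[l].t() * dz_conv;
      dcur.assign(ls.in_c, arma::zeros<mat>(ls.in_h, ls.in_w));
      col2im_add(dcur, dcol, ls, s.k);
    }
  }
  (void)x;
}

struct Adam {
  double lr, b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  Grads m, v;
  void init(const Net& net, double lr_) {
    lr = lr_;
    m.zero_like(net);
    v.zero_like(net);
  }
  void step_one(mat& w, mat& mm, mat& vv, const mat& grad, double corr1,
                double corr2) {
    mm = b1 * mm + (1 - b1) * grad;
    vv = b2 * vv + (1 - b2) * (grad % grad);
    w -= lr * (mm / corr1) / (arma::sqrt(vv / corr2) + eps);
  }
  void step_one(vec& w, vec& mm, vec& vv, const vec& grad, double corr1,
                double corr2) {
    mm = b1 * mm + (1 - b1) * grad;
    vv = b2 * vv + (1 - b2) * (grad % grad);
    w -= lr * (mm / corr1) / (arma::sqrt(vv / corr2) + eps);
  }
  void update(Net& net, const Grads& g) {
    ++t;
    double corr1 = 1 - std::pow(b1, t), corr2 = 1 - std::pow(b2, t);
    for (size_t l = 0; l < net.Wc.size(); ++l) {
      step_one(net.Wc[l], m.Wc[l], v.Wc[l], g.Wc[l], corr1, corr2);
      step_one(net.bc[l], m.bc[l], v.bc[l], g.bc[l], corr1, corr2);
    }
    step_one(net.Wd, m.Wd, v.Wd, g.Wd, corr1, corr2);
    step_one(net.bd, m.bd, v.bd, g.bd, corr1, corr2);
    step_one(net.Wo, m.Wo, v.Wo, g.Wo, corr1, corr2);
    step_one(net.bo, m.bo, v.bo, g.bo, corr1, corr2);
  }
};

double wbce(double p, double y, double w0, double w1) {
  double pc = std::min(std::max(p, 1e-7), 1.0 - 1e-7);
  return y > 0.5 ? -w1 * std::log(pc) : -w0 * std::log(1.0 - pc);
}

}  // namespace

// [[Rcpp::export]]
List cnn_init_cpp(int in_h, int in_w, IntegerVector filters, int kernel,
                  int pool, int dense_units, int seed) {
  NetShape s = make_shape(in_h, in_w, filters, kernel, pool, dense_units);
  std::mt19937 gen(seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  Net net;
  net.shape = s;
  for (size_t l = 0; l < s.conv.size(); ++l) {
    const LayerShape& ls = s.conv[l];
    int fan_in = ls.in_c * s.k * s.k;
    mat W(ls.f, fan_in);
    for (uword i = 0; i < W.n_elem; ++i)
      W(i) = norm(gen) * std::sqrt(2.0 / fan_in);
    net.Wc.push_back(W);
    net.bc.push_back(arma::zeros<vec>(ls.f));
  }
  net.Wd.set_size(s.dense_units, s.flat);
  for (uword i = 0; i < net.Wd.n_elem; ++i)
    net.Wd(i) = norm(gen) * std::sqrt(2.0 / s.flat);
  net.bd = arma::zeros<vec>(s.dense_units);
  net.Wo.set_size(1, s.dense_units);
  for (uword i = 0; i < net.Wo.n_elem; ++i)
    net.Wo(i) = norm(gen) * std::sqrt(2.0 / s.dense_units);
  net.bo = arma::zeros<vec>(1);
  return net_to_list(net);
}

// [[Rcpp::export]]
arma::vec cnn_predict_cpp(List weights, arma::cube x, IntegerVector filters,
                          int kernel, int pool, int dense_units) {
  NetShape s = make_shape(x.n_rows, x.n_cols, filters, kernel, pool,
                          dense_units);
  Net net = net_from_list(weights, s);
  std::mt19937 gen(0);
  vec out(x.n_slices);
  Cache cc;
  for (uword i = 0; i < x.n_slices; ++i) {
    forward_sample(net, x.slice(i), cc, false, 0.0, gen);
    out(i) = cc.p;
  }
  return out;
}

// Mean weighted loss and analytic gradients over a batch, dropout disabled.
// Exposed for gradient-checking in tests.
// [[Rcpp::export]]
List cnn_grad_cpp(List weights, arma::cube x, arma::vec y,
                  IntegerVector filters, int kernel, int pool,
                  int dense_units, double w0, double w1) {
  NetShape s = make_shape(x.n_rows, x.n_cols, filters, kernel, pool,
                          dense_units);
  Net net = net_from_list(weights, s);
  std::mt19937 gen(0);
  Grads g;
  g.zero_like(net);
  Cache cc;
  double loss = 0;
  uword n = x.n_slices;
  for (uword i = 0; i < n; ++i) {
    forward_sample(net, x.slice(i), cc, false, 0.0, gen);
    loss += wbce(cc.p, y(i), w0, w1) / n;
    double dz = (y(i) > 0.5 ? w1 * (cc.p - 1.0) : w0 * cc.p) / (double)n;
    backward_sample(net, x.slice(i), cc, dz, 0.0, g);
  }
  Net gn;
  gn.shape = s;
  gn.Wc = g.Wc; gn.bc = g.bc; gn.Wd = g.Wd; gn.bd = g.bd;
  gn.Wo = g.Wo; gn.bo = g.bo;
  return List::create(_["loss"] = loss, _["grads"] = net_to_list(gn));
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, arma::cube x, arma::vec y, arma::cube xval,
                   arma::vec yval, IntegerVector filters, int kernel, int pool,
                   int dense_units, int epochs, int batch_size, double lr,
                   double dropout, double w0, double w1, int seed) {
  NetShape s = make_shape(x.n_rows, x.n_cols, filters, kernel, pool,
                          dense_units);
  Net net = net_from_list(weights, s);
  std::mt19937 gen(seed);
  Adam adam;
  adam.init(net, lr);
  uword n = x.n_slices;
  std::vector<uword> idx(n);
  for (uword i = 0; i < n; ++i) idx[i] = i;
  mat history(epochs, 4);
  Grads g;
  Cache cc;
  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), gen);
    double loss_sum = 0;
    uword correct = 0;
    for (uword start = 0; start < n; start += batch_size) {
      uword stop_i = std::min(n, start + (uword)batch_size);
      g.zero_like(net);
      for (uword b = start; b < stop_i; ++b) {
        uword i = idx[b];
        forward_sample(net, x.slice(i), cc, true, dropout, gen);
        double yy = y(i);
        loss_sum += wbce(cc.p, yy, w0, w1);
        if ((cc.p >= 0.5) == (yy > 0.5)) ++correct;
        double dz = yy > 0.5 ? w1 * (cc.p - 1.0) : w0 * cc.p;
        backward_sample(net, x.slice(i), cc, dz / (double)(stop_i - start),
                        dropout, g);
      }
      adam.update(net, g);
    }
    history(ep, 0) = loss_sum / n;
    history(ep, 1) = (double)correct / n;
    if (xval.n_slices > 0) {
      double vloss = 0;
      uword vcorrect = 0;
      for (uword i = 0; i < xval.n_slices; ++i) {
        forward_sample(net, xval.slice(i), cc, false, 0.0, gen);
        vloss += wbce(cc.p, yval(i), w0, w1);
        if ((cc.p >= 0.5) == (yval(i) > 0.5)) ++vcorrect;
      }
      history(ep, 2) = vloss / xval.n_slices;
      history(ep, 3) = (double)vcorrect / xval.n_slices;
    } else {
      history(ep, 2) = NA_REAL;
      history(ep, 3) = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = net_to_list(net),
                      _["history"] = history);
}
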