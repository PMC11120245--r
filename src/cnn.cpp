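// Convolutional network with a channel-and-frequency attention (CFA) block,
// trained with Adam on softmax cross-entropy. Single precision; conv layers
// are im2col + BLAS gemm. Feature maps are stored as (H*W) x C matrices with
// the spatial index column-major in H (matching R's array layout), so an R
// array dim c(60, 100, 177, n) maps directly onto per-plane columns.
//
// Architecture (fixed):
//   conv1 3x3/1 pad1 177->177, ReLU, [CFA], pool1 max 5x5/5 -> 12x20,
//   conv2 5x5/1 pad2 177->128, ReLU, pool2 2x2/2 -> 6x10,
//   conv3 5x5/1 pad2 128->128, ReLU,
//   conv4 5x5/1 pad2 128->64, ReLU, dropout(p), pool3 2x2/2 -> 3x5,
//   flatten 960, fc 960->4.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;

static const int NCH = 177, NCLASS = 4, H0 = 60, W0 = 100;

struct Net {
  fmat c1W, c1b, f1W, f1b, f2W, f2b, c2W, c2b, c3W, c3b, c4W, c4b, fcW, fcb;
  bool cfa;
  std::vector<fmat*> params() {
    std::vector<fmat*> p = {&c1W, &c1b};
    if (cfa) { p.push_back(&f1W); p.push_back(&f1b);
               p.push_back(&f2W); p.push_back(&f2b); }
    p.insert(p.end(), {&c2W, &c2b, &c3W, &c3b, &c4W, &c4b, &fcW, &fcb});
    return p;
  }
};

static fmat initMat(int nr, int nc, double fanIn, std::mt19937& rng) {
  double bound = 1.0 / std::sqrt(fanIn);
  std::uniform_real_distribution<double> U(-bound, bound);
  fmat m(nr, nc);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i) m(i, j) = (float)U(rng);
  return m;
}

static Net makeNet(int seed, bool cfa) {
  std::mt19937 rng((unsigned)seed);
  Net n; n.cfa = cfa;
  n.c1W = initMat(NCH * 9, NCH, NCH * 9, rng);
  n.c1b = initMat(1, NCH, NCH * 9, rng);
  n.f1W = initMat(NCH, 59, NCH, rng);  n.f1b = initMat(1, 59, NCH, rng);
  n.f2W = initMat(59, NCH, 59, rng);   n.f2b = initMat(1, NCH, 59, rng);
  n.c2W = initMat(NCH * 25, 128, NCH * 25, rng);
  n.c2b = initMat(1, 128, NCH * 25, rng);
  n.c3W = initMat(128 * 25, 128, 128 * 25, rng);
  n.c3b = initMat(1, 128, 128 * 25, rng);
  n.c4W = initMat(128 * 25, 64, 128 * 25, rng);
  n.c4b = initMat(1, 64, 128 * 25, rng);
  n.fcW = initMat(960, NCLASS, 960, rng);
  n.fcb = initMat(1, NCLASS, 960, rng);
  return n;
}

static List netToList(Net& n) {
  List out = List::create(
    Named("conv1_W") = n.c1W, Named("conv1_b") = n.c1b,
    Named("cfa_fc1_W") = n.f1W, Named("cfa_fc1_b") = n.f1b,
    Named("cfa_fc2_W") = n.f2W, Named("cfa_fc2_b") = n.f2b,
    Named("conv2_W") = n.c2W, Named("conv2_b") = n.c2b,
    Named("conv3_W") = n.c3W, Named("conv3_b") = n.c3b,
    Named("conv4_W") = n.c4W, Named("conv4_b") = n.c4b,
    Named("fc_W") = n.fcW, Named("fc_b") = n.fcb);
  out.attr("cfa") = n.cfa;
  return out;
}

static fmat asF(SEXP s) {
  Rcpp::NumericMatrix m(s);
  fmat f(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) f(i, j) = (float)m(i, j);
  return f;
}

static Net listToNet(List w, bool cfa) {
  Net n; n.cfa = cfa;
  n.c1W = asF(w["conv1_W"]); n.c1b = asF(w["conv1_b"]);
  n.f1W = asF(w["cfa_fc1_W"]); n.f1b = asF(w["cfa_fc1_b"]);
  n.f2W = asF(w["cfa_fc2_W"]); n.f2b = asF(w["cfa_fc2_b"]);
  n.c2W = asF(w["conv2_W"]); n.c2b = asF(w["conv2_b"]);
  n.c3W = asF(w["conv3_W"]); n.c3b = asF(w["conv3_b"]);
  n.c4W = asF(w["conv4_W"]); n.c4b = asF(w["conv4_b"]);
  n.fcW = asF(w["fc_W"]); n.fcb = asF(w["fc_b"]);
  return n;
}

// ---- conv / pool primitives (stride-1 convs, unpadded max pools) ----------

static void im2col(const fmat& X, int H, int W, int k, int pad, fmat& cols) {
  int C = X.n_cols, Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  cols.zeros(Ho * Wo, C * k * k);
  for (int c = 0; c < C; ++c) {
    const float* xp = X.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int q = (c * k + kj) * k + ki;
        float* cp = cols.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          int iw = wo - pad + kj;
          if (iw < 0 || iw >= W) continue;
          int ho0 = std::max(0, pad - ki);
          int ho1 = std::min(Ho, H + pad - ki);
          if (ho1 <= ho0) continue;
          std::memcpy(cp + (size_t)wo * Ho + ho0,
                      xp + (size_t)iw * H + (ho0 - pad + ki),
                      sizeof(float) * (ho1 - ho0));
        }
      }
    }
  }
}

static void col2im(const fmat& cols, int H, int W, int k, int pad, fmat& X) {
  int C = X.n_cols, Ho = H + 2 * pad - k + 1, Wo = W + 2 * pad - k + 1;
  X.zeros();
  for (int c = 0; c < C; ++c) {
    float* xp = X.colptr(c);
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int q = (c * k + kj) * k + ki;
        const float* cp = cols.colptr(q);
        for (int wo = 0; wo < Wo; ++wo) {
          int iw = wo - pad + kj;
          if (iw < 0 || iw >= W) continue;
          int ho0 = std::max(0, pad - ki);
          int ho1 = std::min(Ho, H + pad - ki);
          float* xq = xp + (size_t)iw * H + (ho0 - pad + ki);
          const float* cq = cp + (size_t)wo * Ho + ho0;
          for (int t = 0; t < ho1 - ho0; ++t) xq[t] += cq[t];
        }
      }
    }
  }
}

static void maxpool(const fmat& X, int H, int W, int k, int s,
                    fmat& Y, umat& idx) {
  int C = X.n_cols, Ho = (H - k) / s + 1, Wo = (W - k) / s + 1;
  Y.set_size(Ho * Wo, C); idx.set_size(Ho * Wo, C);
  for (int c = 0; c < C; ++c) {
    const float* xp = X.colptr(c);
    for (int wo = 0; wo < Wo; ++wo)
      for (int ho = 0; ho < Ho; ++ho) {
        float best = -std::numeric_limits<float>::infinity();
        int bi = 0;
        for (int kj = 0; kj < k; ++kj)
          for (int ki = 0; ki < k; ++ki) {
            int p = (wo * s + kj) * H + ho * s + ki;
            if (xp[p] > best) { best = xp[p]; bi = p; }
          }
        Y(wo * Ho + ho, c) = best;
        idx(wo * Ho + ho, c) = bi;
      }
  }
}

static void unpool(const fmat& dY, const umat& idx, fmat& dX) {
  dX.zeros();
  for (uword c = 0; c < dY.n_cols; ++c)
    for (uword i = 0; i < dY.n_rows; ++i)
      dX(idx(i, c), c) += dY(i, c);
}

static inline void relu_(fmat& m) { m.transform([](float v) {
  return v > 0.f ? v : 0.f; }); }

// ---- per-image forward/backward -------------------------------------------

struct Acts {
  fmat x0, cols1, z1, a1, a1w, p1, cols2, z2, a2, p2, cols3, z3, a3,
       cols4, z4, a4, d4, p3, mask4;
  umat i1, i2, i3;
  frowvec s, h1p, h1, h2p, h2, w;
  uvec amax;                     // row index of per-channel max of a1
  frowvec probs;
};

static void forwardImage(const Net& n, Acts& A, bool train, float dropP,
                         std::mt19937* rng) {
  im2col(A.x0, H0, W0, 3, 1, A.cols1);
  A.z1 = A.cols1 * n.c1W;
  A.z1.each_row() += n.c1b.row(0);
  A.a1 = A.z1; relu_(A.a1);
  if (n.cfa) {
    A.s.set_size(NCH); A.amax.set_size(NCH);
    for (int c = 0; c < NCH; ++c) {
      uword im; float mx = A.a1.col(c).max(im);
      A.amax(c) = im;
      A.s(c) = mx + mean(A.a1.col(c));
    }
    A.h1p = A.s * n.f1W + n.f1b.row(0);
    A.h1 = A.h1p; A.h1.transform([](float v){ return v > 0.f ? v : 0.f; });
    A.h2p = A.h1 * n.f2W + n.f2b.row(0);
    A.h2 = A.h2p; A.h2.transform([](float v){ return v > 0.f ? v : 0.f; });
    A.w = 1.0f / (1.0f + exp(-A.h2));
    A.a1w = A.a1;
    A.a1w.each_row() %= A.w;
  } else {
    A.a1w = A.a1;
  }
  maxpool(A.a1w, H0, W0, 5, 5, A.p1, A.i1);            // 12 x 20
  im2col(A.p1, 12, 20, 5, 2, A.cols2);
  A.z2 = A.cols2 * n.c2W; A.z2.each_row() += n.c2b.row(0);
  A.a2 = A.z2; relu_(A.a2);
  maxpool(A.a2, 12, 20, 2, 2, A.p2, A.i2);             // 6 x 10
  im2col(A.p2, 6, 10, 5, 2, A.cols3);
  A.z3 = A.cols3 * n.c3W; A.z3.each_row() += n.c3b.row(0);
  A.a3 = A.z3; relu_(A.a3);
  im2col(A.a3, 6, 10, 5, 2, A.cols4);
  A.z4 = A.cols4 * n.c4W; A.z4.each_row() += n.c4b.row(0);
  A.a4 = A.z4; relu_(A.a4);
  if (train && dropP > 0.f && rng) {
    std::uniform_real_distribution<float> U(0.f, 1.f);
    A.mask4.set_size(A.a4.n_rows, A.a4.n_cols);
    float scale = 1.f / (1.f - dropP);
    for (uword j = 0; j < A.mask4.n_cols; ++j)
      for (uword i = 0; i < A.mask4.n_rows; ++i)
        A.mask4(i, j) = U(*rng) < dropP ? 0.f : scale;
    A.d4 = A.a4 % A.mask4;
  } else {
    A.d4 = A.a4;
  }
  maxpool(A.d4, 6, 10, 2, 2, A.p3, A.i3);              // 3 x 5
  frowvec flat(A.p3.memptr(), 960);                     // copy
  frowvec logits = flat * n.fcW + n.fcb.row(0);
  logits -= logits.max();
  frowvec e = exp(logits);
  A.probs = e / accu(e);
}

static float backwardImage(const Net& n, Acts& A, int label, float gscale,
                           bool train, Net& g) {
  float p = std::max(A.probs(label), 1e-12f);
  float loss = -std::log(p);
  frowvec dlog = A.probs;
  dlog(label) -= 1.f;
  dlog *= gscale;

  frowvec flat(A.p3.memptr(), 960);
  g.fcW += flat.t() * dlog;
  g.fcb.row(0) += dlog;
  frowvec dflatv = dlog * n.fcW.t();
  fmat dp3(dflatv.memptr(), 15, 64);                    // copies
  fmat dd4(A.d4.n_rows, A.d4.n_cols);
  unpool(dp3, A.i3, dd4);
  if (train && A.mask4.n_elem) dd4 %= A.mask4;
  fmat dz4 = dd4;
  dz4.elem(find(A.z4 <= 0)).zeros();
  g.c4W += A.cols4.t() * dz4;
  g.c4b.row(0) += sum(dz4, 0);
  fmat dcols4 = dz4 * n.c4W.t();
  fmat da3(60, 128);
  col2im(dcols4, 6, 10, 5, 2, da3);
  fmat dz3 = da3; dz3.elem(find(A.z3 <= 0)).zeros();
  g.c3W += A.cols3.t() * dz3;
  g.c3b.row(0) += sum(dz3, 0);
  fmat dcols3 = dz3 * n.c3W.t();
  fmat dp2(60, 128);
  col2im(dcols3, 6, 10, 5, 2, dp2);
  fmat da2(240, 128);
  unpool(dp2, A.i2, da2);
  fmat dz2 = da2; dz2.elem(find(A.z2 <= 0)).zeros();
  g.c2W += A.cols2.t() * dz2;
  g.c2b.row(0) += sum(dz2, 0);
  fmat dcols2 = dz2 * n.c2W.t();
  fmat dp1(240, NCH);
  col2im(dcols2, 12, 20, 5, 2, dp1);
  fmat da1w(6000, NCH);
  unpool(dp1, A.i1, da1w);

  fmat da1;
  if (n.cfa) {
    da1 = da1w;
    da1.each_row() %= A.w;
    frowvec dwch = sum(da1w % A.a1, 0);
    frowvec dh2 = dwch % A.w % (1.f - A.w);
    dh2.elem(find(A.h2p <= 0)).zeros();
    g.f2W += A.h1.t() * dh2;
    g.f2b.row(0) += dh2;
    frowvec dh1 = dh2 * n.f2W.t();
    dh1.elem(find(A.h1p <= 0)).zeros();
    g.f1W += A.s.t() * dh1;
    g.f1b.row(0) += dh1;
    frowvec ds = dh1 * n.f1W.t();
    da1.each_row() += ds / 6000.f;                      // mean-pool path
    for (int c = 0; c < NCH; ++c)                       // max-pool path
      da1(A.amax(c), c) += ds(c);
  } else {
    da1 = da1w;
  }
  fmat dz1 = da1;
  dz1.elem(find(A.z1 <= 0)).zeros();
  g.c1W += A.cols1.t() * dz1;
  g.c1b.row(0) += sum(dz1, 0);
  return loss;
}

static void loadImage(const double* x, size_t img, fmat& x0) {
  x0.set_size(6000, NCH);
  const double* p = x + img * (size_t)6000 * NCH;
  float* q = x0.memptr();
  for (size_t i = 0; i < (size_t)6000 * NCH; ++i) q[i] = (float)p[i];
}

// ---- exported API ----------------------------------------------------------

// [[Rcpp::export]]
List cpp_init_weights(int seed, bool cfa) {
  Net n = makeNet(seed, cfa);
  return netToList(n);
}

// [[Rcpp::export]]
List cpp_train(Rcpp::NumericVector x, Rcpp::IntegerVector labels,
               Rcpp::IntegerVector trainIdx, List weights, bool cfa,
               int epochs, int batch, double lr, double dropout, int seed,
               bool verbose) {
  Rcpp::IntegerVector dims = x.attr("dim");
  if (dims.size() != 4 || dims[0] != H0 || dims[1] != W0 || dims[2] != NCH)
    Rcpp::stop("stack array must be 60 x 100 x 177 x n");
  Net n = listToNet(weights, cfa);
  Net g = n, m = n, v = n;                       // same shapes
  for (fmat* p : g.params()) p->zeros();
  for (fmat* p : m.params()) p->zeros();
  for (fmat* p : v.params()) p->zeros();

  std::mt19937 rng((unsigned)seed);
  std::vector<int> idx(trainIdx.begin(), trainIdx.end());
  Acts A;
  std::vector<double> lossHist;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long tstep = 0;
  auto pn = n.params();
  auto pg = g.params();
  auto pm = m.params();
  auto pv = v.params();

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epLoss = 0;
    int seen = 0;
    for (size_t b0 = 0; b0 < idx.size(); b0 += batch) {
      size_t b1i = std::min(idx.size(), b0 + batch);
      int bs = (int)(b1i - b0);
      for (fmat* p : pg) p->zeros();
      float gscale = 1.f / bs;
      for (size_t t = b0; t < b1i; ++t) {
        loadImage(x.begin(), (size_t)(idx[t] - 1), A.x0);
        forwardImage(n, A, true, (float)dropout, &rng);
        epLoss += backwardImage(n, A, labels[idx[t] - 1], gscale, true, g);
        ++seen;
      }
      ++tstep;
      double c1 = 1.0 - std::pow(b1, (double)tstep);
      double c2 = 1.0 - std::pow(b2, (double)tstep);
      for (size_t k = 0; k < pn.size(); ++k) {
        *pm[k] = (float)b1 * (*pm[k]) + (float)(1 - b1) * (*pg[k]);
        *pv[k] = (float)b2 * (*pv[k]) + (float)(1 - b2) * square(*pg[k]);
        *pn[k] -= (float)(lr / c1) * (*pm[k]) /
                  (sqrt((*pv[k]) / (float)c2) + (float)eps);
      }
      if (!std::isfinite(epLoss))
        Rcpp::stop("training error: non-finite loss at epoch %d", ep + 1);
    }
    lossHist.push_back(epLoss / std::max(seen, 1));
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << " loss " << lossHist.back()
                  << std::endl;
    Rcpp::checkUserInterrupt();
  }
  List out = netToList(n);
  out.attr("loss") = Rcpp::wrap(lossHist);
  return out;
}

// [[Rcpp::export]]
List cpp_predict(Rcpp::NumericVector x, Rcpp::IntegerVector idx,
                 List weights, bool cfa) {
  Rcpp::IntegerVector dims = x.attr("dim");
  if (dims.size() != 4 || dims[0] != H0 || dims[1] != W0 || dims[2] != NCH)
    Rcpp::stop("stack array must be 60 x 100 x 177 x n");
  Net n = listToNet(weights, cfa);
  Acts A;
  int N = idx.size();
  Rcpp::NumericMatrix probs(N, NCLASS), att(N, NCH);
  for (int i = 0; i < N; ++i) {
    loadImage(x.begin(), (size_t)(idx[i] - 1), A.x0);
    forwardImage(n, A, false, 0.f, nullptr);
    for (int k = 0; k < NCLASS; ++k) probs(i, k) = A.probs(k);
    for (int c = 0; c < NCH; ++c) att(i, c) = cfa ? A.w(c) : NA_REAL;
  }
  return List::create(Named("probs") = probs, Named("attention") = att);
}

// [[Rcpp::export]]
List cpp_forward_shapes(Rcpp::NumericVector x, List weights, bool cfa) {
  Rcpp::IntegerVector dims = x.attr("dim");
  if (dims.size() != 4 || dims[0] != H0 || dims[1] != W0 || dims[2] != NCH)
    Rcpp::stop("shape error: input must be batch of 177 x 60 x 100");
  int N = dims[3];
  Net n = listToNet(weights, cfa);
  Acts A;
  Rcpp::NumericMatrix logits(N, NCLASS);
  // shapes recorded from the actual matrices of the last forward pass
  auto shp = [&](const fmat& mat, int C, int Hc, int Wc) {
    if ((int)mat.n_cols != C || (int)mat.n_rows != Hc * Wc)
      Rcpp::stop("internal shape mismatch");
    return Rcpp::IntegerVector::create(N, C, Hc, Wc);
  };
  List shapes;
  for (int i = 0; i < N; ++i) {
    loadImage(x.begin(), (size_t)i, A.x0);
    forwardImage(n, A, false, 0.f, nullptr);
    for (int k = 0; k < NCLASS; ++k) logits(i, k) = A.probs(k);
    if (i == N - 1) {
      shapes = List::create(
        Named("input") = shp(A.x0, NCH, 60, 100),
        Named("conv1") = shp(A.a1, NCH, 60, 100),
        Named("cfa") = shp(A.a1w, NCH, 60, 100),
        Named("pool1") = shp(A.p1, NCH, 12, 20),
        Named("conv2") = shp(A.a2, 128, 12, 20),
        Named("pool2") = shp(A.p2, 128, 6, 10),
        Named("conv3") = shp(A.a3, 128, 6, 10),
        Named("conv4") = shp(A.a4, 64, 6, 10),
        Named("dropout") = shp(A.d4, 64, 6, 10),
        Named("pool3") = shp(A.p3, 64, 3, 5),
        Named("flatten") = Rcpp::IntegerVector::create(N, 960),
        Named("fc") = Rcpp::IntegerVector::create(N, NCLASS));
    }
  }
  return List::create(Named("shapes") = shapes, Named("probs") = logits);
}

// Standalone CFA block in double precision with adaptive global pooling:
// works for any spatial size, channel count must match the fc1 weights.
// [[Rcpp::export]]
List cpp_cfa_forward(Rcpp::NumericVector x, Rcpp::NumericMatrix f1W,
                     Rcpp::NumericVector f1b, Rcpp::NumericMatrix f2W,
                     Rcpp::NumericVector f2b) {
  Rcpp::IntegerVector dims = x.attr("dim");
  if (dims.size() != 4) Rcpp::stop("input must be h x w x channels x batch");
  int hw = dims[0] * dims[1], C = dims[2], N = dims[3];
  if (C != f1W.nrow())
    Rcpp::stop("shape error: expected %d channels, got %d", f1W.nrow(), C);
  mat W1(f1W.begin(), f1W.nrow(), f1W.ncol(), false);
  mat W2(f2W.begin(), f2W.nrow(), f2W.ncol(), false);
  rowvec b1v(f1b.begin(), f1b.size());
  rowvec b2v(f2b.begin(), f2b.size());
  Rcpp::NumericVector out(x.size());
  out.attr("dim") = dims;
  Rcpp::NumericMatrix wts(N, C);
  for (int i = 0; i < N; ++i) {
    mat X(x.begin() + (size_t)i * hw * C, hw, C, false);
    rowvec s = max(X, 0) + mean(X, 0);
    rowvec h1 = s * W1 + b1v;  h1.transform([](double v){ return v > 0 ? v : 0; });
    rowvec h2 = h1 * W2 + b2v; h2.transform([](double v){ return v > 0 ? v : 0; });
    rowvec w = 1.0 / (1.0 + exp(-h2));
    mat Y(out.begin() + (size_t)i * hw * C, hw, C, false);
    Y = X;
    Y.each_row() %= w;
    for (int c = 0; c < C; ++c) wts(i, c) = w(c);
  }
  return List::create(Named("output") = out, Named("weights") = wts);
}
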