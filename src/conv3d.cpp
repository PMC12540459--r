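#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are R arrays of dim (C, D, H, W), column-major, so the channel
// index is fastest. Depthwise kernels have dim (k, k, k, C); dense kernels
// (k, k, k, Cin, Cout). All convolutions zero-pad by k/2 ("same" padding).

static inline int outlen(int n, int k, int p, int s) { return (n + 2 * p - k) / s + 1; }

// [[Rcpp::export]]
NumericVector cpp_dw3_fwd(NumericVector x, IntegerVector xdim,
                          NumericVector w, int k, NumericVector b, int stride) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int p = k / 2;
  const int oD = outlen(D, k, p, stride), oH = outlen(H, k, p, stride),
            oW = outlen(W, k, p, stride);
  NumericVector out(static_cast<R_xlen_t>(C) * oD * oH * oW);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *po = out.begin();
  for (int ow = 0; ow < oW; ++ow)
    for (int oh = 0; oh < oH; ++oh)
      for (int od = 0; od < oD; ++od) {
        double *o = po + static_cast<R_xlen_t>(C) * (od + static_cast<R_xlen_t>(oD) * (oh + static_cast<R_xlen_t>(oH) * ow));
        for (int c = 0; c < C; ++c) o[c] = pb[c];
        for (int cc = 0; cc < k; ++cc) {
          int iw = ow * stride + cc - p; if (iw < 0 || iw >= W) continue;
          for (int bb = 0; bb < k; ++bb) {
            int ih = oh * stride + bb - p; if (ih < 0 || ih >= H) continue;
            for (int aa = 0; aa < k; ++aa) {
              int id = od * stride + aa - p; if (id < 0 || id >= D) continue;
              const double *xi = px + static_cast<R_xlen_t>(C) * (id + static_cast<R_xlen_t>(D) * (ih + static_cast<R_xlen_t>(H) * iw));
              const double *wk = pw + aa + k * (bb + k * cc);
              for (int c = 0; c < C; ++c) o[c] += wk[static_cast<R_xlen_t>(k) * k * k * c] * xi[c];
            }
          }
        }
      }
  out.attr("dim") = IntegerVector::create(C, oD, oH, oW);
  return out;
}

// [[Rcpp::export]]
List cpp_dw3_bwd(NumericVector dy, NumericVector x, IntegerVector xdim,
                 NumericVector w, int k, int stride) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int p = k / 2;
  const int oD = outlen(D, k, p, stride), oH = outlen(H, k, p, stride),
            oW = outlen(W, k, p, stride);
  NumericVector dx(x.size()), dw(w.size()), db(C);
  const double *px = x.begin(), *pw = w.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin(), *pdb = db.begin();
  for (int ow = 0; ow < oW; ++ow)
    for (int oh = 0; oh < oH; ++oh)
      for (int od = 0; od < oD; ++od) {
        const double *g = pdy + static_cast<R_xlen_t>(C) * (od + static_cast<R_xlen_t>(oD) * (oh + static_cast<R_xlen_t>(oH) * ow));
        for (int c = 0; c < C; ++c) pdb[c] += g[c];
        for (int cc = 0; cc < k; ++cc) {
          int iw = ow * stride + cc - p; if (iw < 0 || iw >= W) continue;
          for (int bb = 0; bb < k; ++bb) {
            int ih = oh * stride + bb - p; if (ih < 0 || ih >= H) continue;
            for (int aa = 0; aa < k; ++aa) {
              int id = od * stride + aa - p; if (id < 0 || id >= D) continue;
              R_xlen_t xi = static_cast<R_xlen_t>(C) * (id + static_cast<R_xlen_t>(D) * (ih + static_cast<R_xlen_t>(H) * iw));
              R_xlen_t wk = aa + k * (bb + k * cc);
              for (int c = 0; c < C; ++c) {
                pdx[xi + c] += pw[wk + static_cast<R_xlen_t>(k) * k * k * c] * g[c];
                pdw[wk + static_cast<R_xlen_t>(k) * k * k * c] += px[xi + c] * g[c];
              }
            }
          }
        }
      }
  dx.attr("dim") = xdim;
  dw.attr("dim") = IntegerVector::create(k, k, k, C);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Depthwise transposed convolution, stride 2, padding k/2, output length 2n
// per axis: the raw transposed output (length 2n-1) is preceded by one zero
// slice, i.e. out[2i + a - p + 1] += w[a] * x[i].
// [[Rcpp::export]]
NumericVector cpp_dwt3_fwd(NumericVector x, IntegerVector xdim,
                           NumericVector w, int k, NumericVector b) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int p = k / 2;
  const int oD = 2 * D, oH = 2 * H, oW = 2 * W;
  NumericVector out(static_cast<R_xlen_t>(C) * oD * oH * oW);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *po = out.begin();
  // bias covers the raw transposed-conv extent; the leading slab per axis is
  // the zero padding that rounds 2n-1 up to 2n
  for (int ow = 1; ow < oW; ++ow)
    for (int oh = 1; oh < oH; ++oh)
      for (int od = 1; od < oD; ++od) {
        double *o = po + static_cast<R_xlen_t>(C) * (od + static_cast<R_xlen_t>(oD) * (oh + static_cast<R_xlen_t>(oH) * ow));
        for (int c = 0; c < C; ++c) o[c] = pb[c];
      }
  for (int iw = 0; iw < W; ++iw)
    for (int ih = 0; ih < H; ++ih)
      for (int id = 0; id < D; ++id) {
        const double *xi = px + static_cast<R_xlen_t>(C) * (id + static_cast<R_xlen_t>(D) * (ih + static_cast<R_xlen_t>(H) * iw));
        for (int cc = 0; cc < k; ++cc) {
          int ow = 2 * iw + cc - p + 1; if (ow < 1 || ow >= oW) continue;
          for (int bb = 0; bb < k; ++bb) {
            int oh = 2 * ih + bb - p + 1; if (oh < 1 || oh >= oH) continue;
            for (int aa = 0; aa < k; ++aa) {
              int od = 2 * id + aa - p + 1; if (od < 1 || od >= oD) continue;
              double *o = po + static_cast<R_xlen_t>(C) * (od + static_cast<R_xlen_t>(oD) * (oh + static_cast<R_xlen_t>(oH) * ow));
              const double *wk = pw + aa + k * (bb + k * cc);
              for (int c = 0; c < C; ++c) o[c] += wk[static_cast<R_xlen_t>(k) * k * k * c] * xi[c];
            }
          }
        }
      }
  out.attr("dim") = IntegerVector::create(C, oD, oH, oW);
  return out;
}

// [[Rcpp::export]]
List cpp_dwt3_bwd(NumericVector dy, NumericVector x, IntegerVector xdim,
                  NumericVector w, int k) {
  const int C = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int p = k / 2;
  const int oD = 2 * D, oH = 2 * H, oW = 2 * W;
  NumericVector dx(x.size()), dw(w.size()), db(C);
  const double *px = x.begin(), *pw = w.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin(), *pdb = db.begin();
  for (int ow = 1; ow < oW; ++ow)
    for (int oh = 1; oh < oH; ++oh)
      for (int od = 1; od < oD; ++od) {
        const double *g = pdy + static_cast<R_xlen_t>(C) * (od + static_cast<R_xlen_t>(oD) * (oh + static_cast<R_xlen_t>(oH) * ow));
        for (int c = 0; c < C; ++c) pdb[c] += g[c];
      }
  for (int iw = 0; iw < W; ++iw)
    for (int ih = 0; ih < H; ++ih)
      for (int id = 0; id < D; ++id) {
        R_xlen_t xi = static_cast<R_xlen_t>(C) * (id + static_cast<R_xlen_t>(D) * (ih + static_cast<R_xlen_t>(H) * iw));
        for (int cc = 0; cc < k; ++cc) {
          int ow = 2 * iw + cc - p + 1; if (ow < 1 || ow >= oW) continue;
          for (int bb = 0; bb < k; ++bb) {
            int oh = 2 * ih + bb - p + 1; if (oh < 1 || oh >= oH) continue;
            for (int aa = 0; aa < k; ++aa) {
              int od = 2 * id + aa - p + 1; if (od < 1 || od >= oD) continue;
              const double *g = pdy + static_cast<R_xlen_t>(C) * (od + static_cast<R_xlen_t>(oD) * (oh + static_cast<R_xlen_t>(oH) * ow));
              R_xlen_t wk = aa + k * (bb + k * cc);
              for (int c = 0; c < C; ++c) {
                pdx[xi + c] += pw[wk + static_cast<R_xlen_t>(k) * k * k * c] * g[c];
                pdw[wk + static_cast<R_xlen_t>(k) * k * k * c] += px[xi + c] * g[c];
              }
            }
          }
        }
      }
  dx.attr("dim") = xdim;
  dw.attr("dim") = IntegerVector::create(k, k, k, C);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Dense 3D convolution (small channel counts; used by the CBAM spatial gate).
// x: (Cin, D, H, W); w: (k, k, k, Cin, Cout); stride 1, same padding.
// Kernel offsets are the outer loops so the voxel loops run without bounds
// checks.
// [[Rcpp::export]]
NumericVector cpp_dense3_fwd(NumericVector x, IntegerVector xdim,
                             NumericVector w, int k, int cout, NumericVector b) {
  const int Cin = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int p = k / 2;
  NumericVector out(static_cast<R_xlen_t>(cout) * D * H * W);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *po = out.begin();
  const R_xlen_t kk = static_cast<R_xlen_t>(k) * k * k;
  for (R_xlen_t i = 0; i < out.size(); i += cout)
    for (int co = 0; co < cout; ++co) po[i + co] = pb[co];
  for (int cc = 0; cc < k; ++cc) {
    int wlo = std::max(0, p - cc), whi = std::min(W, W + p - cc);
    for (int bb = 0; bb < k; ++bb) {
      int hlo = std::max(0, p - bb), hhi = std::min(H, H + p - bb);
      for (int aa = 0; aa < k; ++aa) {
        int dlo = std::max(0, p - aa), dhi = std::min(D, D + p - aa);
        const double *wk = pw + aa + k * (bb + k * cc);
        for (int ow = wlo; ow < whi; ++ow) {
          int iw = ow + cc - p;
          for (int oh = hlo; oh < hhi; ++oh) {
            int ih = oh + bb - p;
            const double *xrow = px + static_cast<R_xlen_t>(Cin) * ((dlo + aa - p) + static_cast<R_xlen_t>(D) * (ih + static_cast<R_xlen_t>(H) * iw));
            double *orow = po + static_cast<R_xlen_t>(cout) * (dlo + static_cast<R_xlen_t>(D) * (oh + static_cast<R_xlen_t>(H) * ow));
            for (int od = dlo; od < dhi; ++od) {
              for (int co = 0; co < cout; ++co) {
                double acc = 0.0;
                for (int ci = 0; ci < Cin; ++ci)
                  acc += wk[kk * (ci + static_cast<R_xlen_t>(Cin) * co)] * xrow[ci];
                orow[co] += acc;
              }
              xrow += Cin; orow += cout;
            }
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(cout, D, H, W);
  return out;
}

// [[Rcpp::export]]
List cpp_dense3_bwd(NumericVector dy, NumericVector x, IntegerVector xdim,
                    NumericVector w, int k, int cout) {
  const int Cin = xdim[0], D = xdim[1], H = xdim[2], W = xdim[3];
  const int p = k / 2;
  NumericVector dx(x.size()), dw(w.size()), db(cout);
  const double *px = x.begin(), *pw = w.begin(), *pdy = dy.begin();
  double *pdx = dx.begin(), *pdw = dw.begin(), *pdb = db.begin();
  const R_xlen_t kk = static_cast<R_xlen_t>(k) * k * k;
  for (R_xlen_t i = 0; i < dy.size(); i += cout)
    for (int co = 0; co < cout; ++co) pdb[co] += pdy[i + co];
  for (int cc = 0; cc < k; ++cc) {
    int wlo = std::max(0, p - cc), whi = std::min(W, W + p - cc);
    for (int bb = 0; bb < k; ++bb) {
      int hlo = std::max(0, p - bb), hhi = std::min(H, H + p - bb);
      for (int aa = 0; aa < k; ++aa) {
        int dlo = std::max(0, p - aa), dhi = std::min(D, D + p - aa);
        R_xlen_t wk = aa + k * (bb + k * cc);
        for (int ow = wlo; ow < whi; ++ow) {
          int iw = ow + cc - p;
          for (int oh = hlo; oh < hhi; ++oh) {
            int ih = oh + bb - p;
            const double *xrow = px + static_cast<R_xlen_t>(Cin) * ((dlo + aa - p) + static_cast<R_xlen_t>(D) * (ih + static_cast<R_xlen_t>(H) * iw));
            double *dxrow = pdx + static_cast<R_xlen_t>(Cin) * ((dlo + aa - p) + static_cast<R_xlen_t>(D) * (ih + static_cast<R_xlen_t>(H) * iw));
            const double *grow = pdy + static_cast<R_xlen_t>(cout) * (dlo + static_cast<R_xlen_t>(D) * (oh + static_cast<R_xlen_t>(H) * ow));
            for (int od = dlo; od < dhi; ++od) {
              for (int co = 0; co < cout; ++co) {
                const double g = grow[co];
                for (int ci = 0; ci < Cin; ++ci) {
                  dxrow[ci] += pw[wk + kk * (ci + static_cast<R_xlen_t>(Cin) * co)] * g;
                  pdw[wk + kk * (ci + static_cast<R_xlen_t>(Cin) * co)] += xrow[ci] * g;
                }
              }
              xrow += Cin; dxrow += Cin; grow += cout;
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xdim;
  dw.attr("dim") = IntegerVector::create(k, k, k, Cin, cout);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Exact GELU y = x * Phi(x) and its derivative Phi(x) + x * phi(x).
// [[Rcpp::export]]
NumericVector cpp_gelu_fwd(NumericVector x) {
  NumericVector y(x.size());
  const double isq2 = M_SQRT1_2;
  for (R_xlen_t i = 0; i < x.size(); ++i)
    y[i] = 0.5 * x[i] * (1.0 + std::erf(x[i] * isq2));
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_gelu_bwd(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  const double isq2 = M_SQRT1_2, ispi = 0.3989422804014327;  // 1/sqrt(2*pi)
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double phi = 0.5 * (1.0 + std::erf(x[i] * isq2));
    double dens = ispi * std::exp(-0.5 * x[i] * x[i]);
    dx[i] = dy[i] * (phi + x[i] * dens);
  }
  dx.attr("dim") = x.attr("dim");
  return dx;
}

// 26-connectivity connected component labelling of a binary 3D mask by
// breadth-first flood fill. Returns integer labels (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label26(IntegerVector mask, IntegerVector mdim) {
  const int D = mdim[0], H = mdim[1], W = mdim[2];
  IntegerVector lab(mask.size());
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (mask[s] == 0 || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int d = v % D, h = (v / D) % H, w = v / (static_cast<R_xlen_t>(D) * H);
      for (int dw_ = -1; dw_ <= 1; ++dw_)
        for (int dh = -1; dh <= 1; ++dh)
          for (int dd = -1; dd <= 1; ++dd) {
            if (dd == 0 && dh == 0 && dw_ == 0) continue;
            int nd = d + dd, nh = h + dh, nw = w + dw_;
            if (nd < 0 || nd >= D || nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
            R_xlen_t u = nd + static_cast<R_xlen_t>(D) * (nh + static_cast<R_xlen_t>(H) * nw);
            if (mask[u] != 0 && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
          }
    }
  }
  lab.attr("dim") = mdim;
  return lab;
}
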