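#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Tensors are R arrays in channel-first layout: dim = (C, X, Y, Z), column
// major.  Convolutions use odd kernels (1 or 3), stride 1, zero padding
// (k-1)/2, which keeps spatial dims fixed.  Internally the kernels convert
// to planar (one contiguous spatial block per channel) buffers so the
// innermost x loops are unit-stride and vectorizable.

static inline long idx4(int c, int x, int y, int z, int C, int X, int Y) {
  return c + (long)C * (x + (long)X * (y + (long)Y * z));
}

// channel-first (C,X,Y,Z) -> planar: plane[c][s], s = x + X*(y + Y*z)
static void to_planar(const double *src, double *dst, int C, long nvox) {
  for (long s = 0; s < nvox; ++s)
    for (int c = 0; c < C; ++c)
      dst[(long)c * nvox + s] = src[s * C + c];
}

static void from_planar(const double *src, double *dst, int C, long nvox) {
  for (long s = 0; s < nvox; ++s)
    for (int c = 0; c < C; ++c)
      dst[s * C + c] = src[(long)c * nvox + s];
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector input, NumericVector weight,
                             NumericVector bias) {
  IntegerVector xd = input.attr("dim");
  IntegerVector wd = weight.attr("dim");
  const int Ci = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int Co = wd[0], k = wd[2];
  const int p = (k - 1) / 2;
  if (wd[1] != Ci) stop("conv3d: weight expects %d input channels, got %d", wd[1], Ci);
  const long nvox = (long)X * Y * Z;
  std::vector<double> xP(Ci * nvox), oP(Co * nvox);
  to_planar(input.begin(), xP.data(), Ci, nvox);
  for (int co = 0; co < Co; ++co)
    std::fill(oP.begin() + (long)co * nvox, oP.begin() + (long)(co + 1) * nvox,
              bias[co]);
  const double *wp = weight.begin();
  for (int dz = 0; dz < k; ++dz) {
    int zlo = std::max(0, p - dz), zhi = std::min(Z - 1, Z - 1 + p - dz);
    for (int dy = 0; dy < k; ++dy) {
      int ylo = std::max(0, p - dy), yhi = std::min(Y - 1, Y - 1 + p - dy);
      for (int dx = 0; dx < k; ++dx) {
        int xlo = std::max(0, p - dx), xhi = std::min(X - 1, X - 1 + p - dx);
        long shift = (dx - p) + (long)X * ((dy - p) + (long)Y * (dz - p));
        for (int ci = 0; ci < Ci; ++ci) {
          const double *xc = xP.data() + (long)ci * nvox;
          for (int co = 0; co < Co; ++co) {
            double w = wp[co + (long)Co * (ci + (long)Ci * (dx + k * (dy + (long)k * dz)))];
            if (w == 0.0) continue;
            double *oc = oP.data() + (long)co * nvox;
            for (int z = zlo; z <= zhi; ++z)
              for (int y = ylo; y <= yhi; ++y) {
                long row = (long)X * (y + (long)Y * z);
                const double *xr = xc + row + shift;
                double *orow = oc + row;
                for (int x = xlo; x <= xhi; ++x)
                  orow[x] += w * xr[x];
              }
          }
        }
      }
    }
  }
  NumericVector out(Co * nvox);
  out.attr("dim") = IntegerVector::create(Co, X, Y, Z);
  from_planar(oP.data(), out.begin(), Co, nvox);
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector input, NumericVector weight,
                    NumericVector gout) {
  IntegerVector xd = input.attr("dim");
  IntegerVector wd = weight.attr("dim");
  const int Ci = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  const int Co = wd[0], k = wd[2];
  const int p = (k - 1) / 2;
  const long nvox = (long)X * Y * Z;
  std::vector<double> xP(Ci * nvox), gP(Co * nvox), gxP(Ci * nvox, 0.0);
  to_planar(input.begin(), xP.data(), Ci, nvox);
  to_planar(gout.begin(), gP.data(), Co, nvox);
  NumericVector gw(weight.size()), gb(Co);
  gw.attr("dim") = wd;
  double *gwp = gw.begin();
  for (int co = 0; co < Co; ++co) {
    const double *gc = gP.data() + (long)co * nvox;
    double acc = 0.0;
    for (long s = 0; s < nvox; ++s) acc += gc[s];
    gb[co] = acc;
  }
  const double *wp = weight.begin();
  for (int dz = 0; dz < k; ++dz) {
    int zlo = std::max(0, p - dz), zhi = std::min(Z - 1, Z - 1 + p - dz);
    for (int dy = 0; dy < k; ++dy) {
      int ylo = std::max(0, p - dy), yhi = std::min(Y - 1, Y - 1 + p - dy);
      for (int dx = 0; dx < k; ++dx) {
        int xlo = std::max(0, p - dx), xhi = std::min(X - 1, X - 1 + p - dx);
        long shift = (dx - p) + (long)X * ((dy - p) + (long)Y * (dz - p));
        for (int ci = 0; ci < Ci; ++ci) {
          const double *xc = xP.data() + (long)ci * nvox;
          double *gxc = gxP.data() + (long)ci * nvox;
          for (int co = 0; co < Co; ++co) {
            long wi = co + (long)Co * (ci + (long)Ci * (dx + k * (dy + (long)k * dz)));
            double w = wp[wi];
            const double *gc = gP.data() + (long)co * nvox;
            double acc = 0.0;
            for (int z = zlo; z <= zhi; ++z)
              for (int y = ylo; y <= yhi; ++y) {
                long row = (long)X * (y + (long)Y * z);
                const double *grow = gc + row;
                const double *xr = xc + row + shift;
                double *gxr = gxc + row + shift;
                for (int x = xlo; x <= xhi; ++x) {
                  double g = grow[x];
                  acc += g * xr[x];
                  gxr[x] += w * g;
                }
              }
            gwp[wi] = acc;
          }
        }
      }
    }
  }
  NumericVector gx(input.size());
  gx.attr("dim") = xd;
  from_planar(gxP.data(), gx.begin(), Ci, nvox);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling, stride 2.  Returns pooled values and 1-based argmax
// linear indices into the input array (for the backward pass).
// [[Rcpp::export]]
List maxpool3d_fwd_cpp(NumericVector input) {
  IntegerVector xd = input.attr("dim");
  const int C = xd[0], X = xd[1], Y = xd[2], Z = xd[3];
  if (X % 2 || Y % 2 || Z % 2) stop("maxpool3d: spatial dims must be even");
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2;
  NumericVector out(C * (long)Xo * Yo * Zo);
  IntegerVector arg(out.size());
  out.attr("dim") = IntegerVector::create(C, Xo, Yo, Zo);
  const double *xp = input.begin();
  double *op = out.begin();
  int *ap = arg.begin();
  long o = 0;
  for (int z = 0; z < Zo; ++z)
    for (int y = 0; y < Yo; ++y)
      for (int x = 0; x < Xo; ++x)
        for (int c = 0; c < C; ++c, ++o) {
          double best = -R_PosInf; long bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                long i = idx4(c, 2 * x + dx, 2 * y + dy, 2 * z + dz, C, X, Y);
                if (xp[i] > best) { best = xp[i]; bi = i; }
              }
          op[o] = best;
          ap[o] = (int)(bi + 1);
        }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bwd_cpp(NumericVector gout, IntegerVector argmax,
                                IntegerVector in_dim) {
  long n = (long)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector gx(n);
  gx.attr("dim") = in_dim;
  double *gxp = gx.begin();
  const double *gp = gout.begin();
  const int *ap = argmax.begin();
  for (long i = 0; i < gout.size(); ++i) gxp[ap[i] - 1] += gp[i];
  return gx;
}
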