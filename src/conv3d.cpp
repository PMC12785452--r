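#include <Rcpp.h>
using namespace Rcpp;

// Volumes are C x S^3 matrices; spatial index = ix + S*(iy + S*iz), 0-based.
// Column layout of the unfolded matrix: row = kx + k*(ky + k*kz) + k^3*c,
// column = px + P*(py + P*pz) with P the output edge.

// [[Rcpp::export]]
NumericMatrix vol2col_cpp(NumericMatrix x, int S, int k, int stride, int pad) {
  const int C = x.nrow();
  const int P = (S + 2 * pad - k) / stride + 1;
  const int k3 = k * k * k;
  NumericMatrix out(C * k3, P * P * P);
  for (int pz = 0; pz < P; ++pz) {
    for (int py = 0; py < P; ++py) {
      for (int px = 0; px < P; ++px) {
        const int col = px + P * (py + P * pz);
        for (int c = 0; c < C; ++c) {
          for (int kz = 0; kz < k; ++kz) {
            const int iz = pz * stride - pad + kz;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = py * stride - pad + ky;
              for (int kx = 0; kx < k; ++kx) {
                const int ix = px * stride - pad + kx;
                double v = 0.0;
                if (ix >= 0 && ix < S && iy >= 0 && iy < S && iz >= 0 && iz < S)
                  v = x(c, ix + S * (iy + S * iz));
                out(kx + k * (ky + k * kz) + k3 * c, col) = v;
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of vol2col: scatter-add unfolded columns back onto a C x S^3 volume.
// [[Rcpp::export]]
NumericMatrix col2vol_cpp(NumericMatrix cols, int C, int S, int k, int stride,
                          int pad) {
  const int P = (S + 2 * pad - k) / stride + 1;
  const int k3 = k * k * k;
  if (cols.nrow() != C * k3 || cols.ncol() != P * P * P)
    stop("col2vol: shape mismatch");
  NumericMatrix out(C, S * S * S);
  for (int pz = 0; pz < P; ++pz) {
    for (int py = 0; py < P; ++py) {
      for (int px = 0; px < P; ++px) {
        const int col = px + P * (py + P * pz);
        for (int c = 0; c < C; ++c) {
          for (int kz = 0; kz < k; ++kz) {
            const int iz = pz * stride - pad + kz;
            if (iz < 0 || iz >= S) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = py * stride - pad + ky;
              if (iy < 0 || iy >= S) continue;
              for (int kx = 0; kx < k; ++kx) {
                const int ix = px * stride - pad + kx;
                if (ix < 0 || ix >= S) continue;
                out(c, ix + S * (iy + S * iz)) +=
                    cols(kx + k * (ky + k * kz) + k3 * c, col);
              }
            }
          }
        }
      }
    }
  }
  return out;
}
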