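// Low-level CPU kernels for the 3D segmentation backend.
//
// Feature maps are n x C matrices with n = H*W*Z voxels; voxel (i,j,z)
// (0-based) maps to row i + H*(j + W*z), i.e. column-major over the first
// array axis, matching as.vector() of an R array dim c(H, W, Z).

#include <RcppArmadillo.h>
#include <cstring>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Direct "same"-padded cubic convolution, stencil-style: for every output
// channel the k^3 taps of every input channel are accumulated in row-wise
// passes (the first array axis is contiguous), keeping memory traffic at
// O(n * Cin * Cout) rather than materializing im2col columns. Weight
// layout: W is (k^3*Cin) x Cout, row c*k^3 + o for input channel c and
// offset o enumerated di fastest, then dj, then dk, each in -r..r.

struct Tap { int di, dj, dk, o; };

static std::vector<Tap> make_taps(int k) {
  const int r = (k - 1) / 2;
  std::vector<Tap> taps;
  int o = 0;
  for (int dk = -r; dk <= r; ++dk)
    for (int dj = -r; dj <= r; ++dj)
      for (int di = -r; di <= r; ++di, ++o) taps.push_back({di, dj, dk, o});
  return taps;
}

// [[Rcpp::export]]
arma::mat conv3_fwd(const arma::mat& X, const arma::mat& Wm,
                    const arma::vec& bias, int H, int W, int Z, int k) {
  const size_t n = (size_t)H * W * Z;
  const int Cin = X.n_cols;
  const int Cout = Wm.n_cols;
  const int k3 = k * k * k;
  const std::vector<Tap> taps = make_taps(k);
  arma::mat Y(n, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* yc = Y.colptr(co);
    const double b = bias[co];
    for (size_t v = 0; v < n; ++v) yc[v] = b;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = X.colptr(ci);
      const double* w = Wm.colptr(co) + (size_t)ci * k3;
      for (int z = 0; z < Z; ++z) {
        for (int j = 0; j < W; ++j) {
          double* yr = yc + (size_t)H * (j + (size_t)W * z);
          for (const Tap& t : taps) {
            const int jj = j + t.dj, zz = z + t.dk;
            if (jj < 0 || jj >= W || zz < 0 || zz >= Z) continue;
            const double wt = w[t.o];
            if (wt == 0.0) continue;
            const double* xr = xc + t.di + (size_t)H * (jj + (size_t)W * zz);
            const int ilo = std::max(0, -t.di), ihi = std::min(H, H - t.di);
            for (int i = ilo; i < ihi; ++i) yr[i] += wt * xr[i];
          }
        }
      }
    }
  }
  return Y;
}

// Gradient w.r.t. the input: same stencil with negated offsets and the
// weight matrix read transposed over channels.
// [[Rcpp::export]]
arma::mat conv3_bwd_data(const arma::mat& dY, const arma::mat& Wm,
                         int H, int W, int Z, int k, int Cin) {
  const size_t n = (size_t)H * W * Z;
  const int Cout = dY.n_cols;
  const int k3 = k * k * k;
  const std::vector<Tap> taps = make_taps(k);
  arma::mat dX(n, Cin, arma::fill::zeros);
  for (int ci = 0; ci < Cin; ++ci) {
    double* dc = dX.colptr(ci);
    for (int co = 0; co < Cout; ++co) {
      const double* gc = dY.colptr(co);
      const double* w = Wm.colptr(co) + (size_t)ci * k3;
      for (int z = 0; z < Z; ++z) {
        for (int j = 0; j < W; ++j) {
          double* dr = dc + (size_t)H * (j + (size_t)W * z);
          for (const Tap& t : taps) {
            // dX[v] += w_o * dY[v - shift_o]
            const int jj = j - t.dj, zz = z - t.dk;
            if (jj < 0 || jj >= W || zz < 0 || zz >= Z) continue;
            const double wt = w[t.o];
            if (wt == 0.0) continue;
            const double* gr = gc - t.di + (size_t)H * (jj + (size_t)W * zz);
            const int ilo = std::max(0, t.di), ihi = std::min(H, H + t.di);
            for (int i = ilo; i < ihi; ++i) dr[i] += wt * gr[i];
          }
        }
      }
    }
  }
  return dX;
}

// Gradient w.r.t. the weights: per (cin, cout) pair, tap-wise dot products
// of the shifted input column with the output-gradient column.
// [[Rcpp::export]]
arma::mat conv3_bwd_weights(const arma::mat& X, const arma::mat& dY,
                            int H, int W, int Z, int k) {
  const int Cin = X.n_cols;
  const int Cout = dY.n_cols;
  const int k3 = k * k * k;
  const std::vector<Tap> taps = make_taps(k);
  arma::mat dW((size_t)k3 * Cin, Cout, arma::fill::zeros);
  for (int co = 0; co < Cout; ++co) {
    const double* gc = dY.colptr(co);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* xc = X.colptr(ci);
      double* wc = dW.colptr(co) + (size_t)ci * k3;
      for (int z = 0; z < Z; ++z) {
        for (int j = 0; j < W; ++j) {
          const size_t row0 = (size_t)H * (j + (size_t)W * z);
          for (const Tap& t : taps) {
            const int jj = j + t.dj, zz = z + t.dk;
            if (jj < 0 || jj >= W || zz < 0 || zz >= Z) continue;
            const double* xr = xc + t.di + (size_t)H * (jj + (size_t)W * zz);
            const double* gr = gc + row0;
            const int ilo = std::max(0, -t.di), ihi = std::min(H, H - t.di);
            double acc = 0.0;
            for (int i = ilo; i < ihi; ++i) acc += xr[i] * gr[i];
            wc[t.o] += acc;
          }
        }
      }
    }
  }
  return dW;
}

// 2x2x2 max pooling, stride 2. Dimensions must be even. Returns the pooled
// map and the 1-based input row index of each maximum (for backprop).
// [[Rcpp::export]]
List maxpool3_fwd(const arma::mat& X, int H, int W, int Z) {
  const int C = X.n_cols;
  const int Ho = H / 2, Wo = W / 2, Zo = Z / 2;
  const int no = Ho * Wo * Zo;
  arma::mat Y(no, C);
  arma::imat Idx(no, C);

  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double* yc = Y.colptr(c);
    arma::sword* ic = Idx.colptr(c);
    for (int z = 0; z < Zo; ++z) {
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bestv = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const size_t v = (size_t)(2 * i + di) +
                  (size_t)H * ((2 * j + dj) + (size_t)W * (2 * z + dz));
                if (xc[v] > best) { best = xc[v]; bestv = v; }
              }
          const size_t vo = (size_t)i + (size_t)Ho * (j + (size_t)Wo * z);
          yc[vo] = best;
          ic[vo] = (arma::sword)bestv + 1;
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = Idx);
}

// [[Rcpp::export]]
arma::mat maxpool3_bwd(const arma::mat& dY, const arma::imat& Idx, int n_in) {
  const int C = dY.n_cols;
  arma::mat dX(n_in, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* gc = dY.colptr(c);
    const arma::sword* ic = Idx.colptr(c);
    double* dc = dX.colptr(c);
    for (size_t v = 0; v < dY.n_rows; ++v) dc[ic[v] - 1] += gc[v];
  }
  return dX;
}

// Instance normalization (per channel over all voxels), fused passes.
// [[Rcpp::export]]
List inorm_fwd(const arma::mat& X, const arma::vec& gamma,
               const arma::vec& beta, double eps) {
  const size_t n = X.n_rows;
  const int C = X.n_cols;
  arma::mat Y(n, C);
  arma::vec mu(C), inv_sd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    double s = 0.0, s2 = 0.0;
    for (size_t v = 0; v < n; ++v) { s += xc[v]; s2 += xc[v] * xc[v]; }
    const double m = s / n;
    const double var = s2 / n - m * m;
    const double inv = 1.0 / std::sqrt(var + eps);
    mu[c] = m;
    inv_sd[c] = inv;
    const double a = gamma[c] * inv, b = beta[c] - a * m;
    double* yc = Y.colptr(c);
    for (size_t v = 0; v < n; ++v) yc[v] = a * xc[v] + b;
  }
  return List::create(_["y"] = Y, _["mu"] = mu, _["inv_sd"] = inv_sd);
}

// [[Rcpp::export]]
List inorm_bwd(const arma::mat& X, const arma::mat& dY, const arma::vec& mu,
               const arma::vec& inv_sd, const arma::vec& gamma) {
  const size_t n = X.n_rows;
  const int C = X.n_cols;
  arma::mat dX(n, C);
  arma::vec dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = X.colptr(c);
    const double* gc = dY.colptr(c);
    const double m = mu[c], inv = inv_sd[c], g = gamma[c];
    double sg = 0.0, sgx = 0.0, sdy = 0.0;
    for (size_t v = 0; v < n; ++v) {
      const double xcv = xc[v] - m;
      sdy += gc[v];
      sg += gc[v] * xcv;
      sgx += g * gc[v] * xcv;
    }
    dgamma[c] = sg * inv;
    dbeta[c] = sdy;
    const double dvar = sgx * (-0.5) * inv * inv * inv;
    const double dmu = -g * sdy * inv;
    double* dc = dX.colptr(c);
    const double t1 = g * inv, t2 = 2.0 * dvar / n, t3 = dmu / n;
    for (size_t v = 0; v < n; ++v)
      dc[v] = t1 * gc[v] + t2 * (xc[v] - m) + t3;
  }
  return List::create(_["dx"] = dX, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
arma::mat relu_fwd(const arma::mat& X) {
  arma::mat Y = X;
  Y.for_each([](double& v) { if (v < 0.0) v = 0.0; });
  return Y;
}

// [[Rcpp::export]]
arma::mat relu_bwd(const arma::mat& dY, const arma::mat& Y) {
  arma::mat dX = dY;
  const double* y = Y.memptr();
  double* d = dX.memptr();
  for (size_t v = 0; v < Y.n_elem; ++v) if (y[v] <= 0.0) d[v] = 0.0;
  return dX;
}

// For each row of A (physical coordinates, mm), the Euclidean distance to
// the nearest row of B. Plain all-pairs scan with running minimum.
// [[Rcpp::export]]
NumericVector nearest_dists(const arma::mat& A, const arma::mat& B) {
  const size_t na = A.n_rows, nb = B.n_rows;
  NumericVector out(na);
  for (size_t a = 0; a < na; ++a) {
    const double ax = A(a, 0), ay = A(a, 1), az = A(a, 2);
    double best = std::numeric_limits<double>::infinity();
    for (size_t b = 0; b < nb; ++b) {
      const double dx = ax - B(b, 0), dy = ay - B(b, 1), dz = az - B(b, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[a] = std::sqrt(best);
  }
  return out;
}

// Number of 6-connected foreground components in a binary volume.
// [[Rcpp::export]]
int count_components6(const IntegerVector& mask, int H, int W, int Z) {
  const size_t n = (size_t)H * W * Z;
  std::vector<char> seen(n, 0);
  std::vector<size_t> stack;
  int ncomp = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || seen[s]) continue;
    ++ncomp;
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      const size_t v = stack.back();
      stack.pop_back();
      const int i = v % H, j = (v / H) % W, z = v / ((size_t)H * W);
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int t = 0; t < 6; ++t) {
        const int ii = i + di[t], jj = j + dj[t], zz = z + dz[t];
        if (ii < 0 || ii >= H || jj < 0 || jj >= W || zz < 0 || zz >= Z) continue;
        const size_t u = (size_t)ii + (size_t)H * (jj + (size_t)W * zz);
        if (mask[u] && !seen[u]) { seen[u] = 1; stack.push_back(u); }
      }
    }
  }
  return ncomp;
}
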