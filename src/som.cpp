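#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Squared-distance argmin over model vectors; ties -> lowest index.
static int bmu_of(const NumericMatrix &mv, const double *v, int n) {
  int P = mv.nrow(), best_i = 0;
  double best = R_PosInf;
  for (int p = 0; p < P; ++p) {
    double d = 0.0;
    for (int j = 0; j < n; ++j) {
      double diff = mv(p, j) - v[j];
      d += diff * diff;
      if (d >= best) break; // cannot beat current best (strict <)
    }
    if (d < best) { best = d; best_i = p; }
  }
  return best_i;
}

// [[Rcpp::export]]
IntegerVector bmu_batch_cpp(NumericMatrix mv, NumericMatrix x) {
  int n = mv.ncol(), m = x.nrow();
  if (x.ncol() != n) stop("dimension mismatch");
  IntegerVector out(m);
  std::vector<double> v(n);
  for (int r = 0; r < m; ++r) {
    for (int j = 0; j < n; ++j) v[j] = x(r, j);
    out[r] = bmu_of(mv, v.data(), n);
  }
  return out; // 0-based pattern ids
}

// Sequential Kohonen training on an N x N x N lattice.
// mv rows are model vectors indexed id = x + N*y + N^2*z (0-based).
// idx holds 0-based row indices into x, one per training step.
// [[Rcpp::export]]
NumericMatrix train_som_cpp(NumericMatrix mv_init, int N, NumericMatrix x,
                            IntegerVector idx, double L0, double LM,
                            double R0, double g) {
  NumericMatrix mv = clone(mv_init);
  int n = mv.ncol();
  int M = idx.size();
  double phase = g * M / 100.0; // steps after which the radius reaches 0
  std::vector<double> v(n);
  for (int k = 0; k < M; ++k) {
    double L = L0 * std::pow(LM / L0, (double)k / M);
    double frac = 1.0 - (double)k / phase;
    int R = (int)std::lround(R0 * (frac > 0.0 ? frac : 0.0));
    const int row = idx[k];
    for (int j = 0; j < n; ++j) v[j] = x(row, j);
    int b = bmu_of(mv, v.data(), n);
    int bx = b % N, by = (b / N) % N, bz = b / (N * N);
    if (R == 0) {
      for (int j = 0; j < n; ++j)
        mv(b, j) += L * (v[j] - mv(b, j));
      continue;
    }
    double twoSig2 = 2.0 * (R / 3.0) * (R / 3.0);
    int x0 = std::max(0, bx - R), x1 = std::min(N - 1, bx + R);
    int y0 = std::max(0, by - R), y1 = std::min(N - 1, by + R);
    int z0 = std::max(0, bz - R), z1 = std::min(N - 1, bz + R);
    for (int zz = z0; zz <= z1; ++zz)
      for (int yy = y0; yy <= y1; ++yy)
        for (int xx = x0; xx <= x1; ++xx) {
          int dx = xx - bx, dy = yy - by, dz = zz - bz;
          double d2 = (double)(dx * dx + dy * dy + dz * dz);
          double G = std::exp(-d2 / twoSig2); // G = 1 at the BMU
          double LG = L * G;
          int p = xx + N * yy + N * N * zz;
          for (int j = 0; j < n; ++j)
            mv(p, j) += LG * (v[j] - mv(p, j));
        }
  }
  return mv;
}
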