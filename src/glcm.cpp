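#include <Rcpp.h>
using namespace Rcpp;

// Pair-counting kernel for one displacement. Volume is a quantized integer
// array (values 1..n_levels) in R's column-major layout; pairs whose
// destination voxel falls outside the grid are skipped, so the raw count is
// (I-|di|)(J-|dj|)(K-|dk|).
// [[Rcpp::export]]
NumericMatrix glcm_single_cpp(const IntegerVector& vol, const IntegerVector& dim,
                              const IntegerVector& offset, int n_levels) {
  const int I = dim[0], J = dim[1], K = dim[2];
  const int di = offset[0], dj = offset[1], dk = offset[2];
  if (di == 0 && dj == 0 && dk == 0) stop("offset must be nonzero");
  NumericMatrix M(n_levels, n_levels);

  const int i0 = std::max(0, -di), i1 = std::min(I, I - di);
  const int j0 = std::max(0, -dj), j1 = std::min(J, J - dj);
  const int k0 = std::max(0, -dk), k1 = std::min(K, K - dk);
  if (i0 >= i1 || j0 >= j1 || k0 >= k1) return M;  // too small: zero matrix

  const int* v = INTEGER(vol);
  double* m = REAL(M);
  const R_xlen_t dshift = (R_xlen_t)di + (R_xlen_t)I * (dj + (R_xlen_t)J * dk);
  for (int k = k0; k < k1; ++k) {
    for (int j = j0; j < j1; ++j) {
      R_xlen_t base = (R_xlen_t)I * (j + (R_xlen_t)J * k);
      for (int i = i0; i < i1; ++i) {
        const int x = v[base + i];
        const int y = v[base + i + dshift];
        if (x < 1 || x > n_levels || y < 1 || y > n_levels)
          stop("voxel value outside 1..n_levels");
        m[(x - 1) + (R_xlen_t)n_levels * (y - 1)] += 1.0;
      }
    }
  }
  return M;
}
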