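// Hot kernel of the growth kinematics: one combined
// extend-and-bend sweep over the section chain followed by the
// fixed-length elongation-zone resampling.  Mirrors the reference R
// implementations grow_step() / resample_root() exactly; a property test
// asserts the two paths agree.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

inline void matmul3(const double* A, const double* B, double* C) {
  // column-major 3x3: C = A * B
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      C[r + 3 * c] = A[r] * B[3 * c] + A[r + 3] * B[1 + 3 * c] +
                     A[r + 6] * B[2 + 3 * c];
}

inline void matvec3(const double* A, const double* v, double* out) {
  for (int r = 0; r < 3; ++r)
    out[r] = A[r] * v[0] + A[r + 3] * v[1] + A[r + 6] * v[2];
}

inline void tmatvec3(const double* A, const double* v, double* out) {
  // A^T * v
  for (int c = 0; c < 3; ++c)
    out[c] = A[3 * c] * v[0] + A[1 + 3 * c] * v[1] + A[2 + 3 * c] * v[2];
}

inline void tmatmul3(const double* A, const double* B, double* C) {
  // C = A^T * B
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r)
      C[r + 3 * c] = A[3 * r] * B[3 * c] + A[1 + 3 * r] * B[1 + 3 * c] +
                     A[2 + 3 * r] * B[2 + 3 * c];
}

inline void rodrigues(double ax, double ay, double az, double angle,
                      double* R) {
  double c = std::cos(angle), s = std::sin(angle), v = 1.0 - c;
  R[0] = c + ax * ax * v;
  R[1] = ax * ay * v + az * s;
  R[2] = ax * az * v - ay * s;
  R[3] = ax * ay * v - az * s;
  R[4] = c + ay * ay * v;
  R[5] = ay * az * v + ax * s;
  R[6] = ax * az * v + ay * s;
  R[7] = ay * az * v - ax * s;
  R[8] = c + az * az * v;
}

inline void ortho3(double* A) {
  // Gram-Schmidt anchored on z (col 3) then y (col 2); x = y x z.
  double nz = std::sqrt(A[6] * A[6] + A[7] * A[7] + A[8] * A[8]);
  A[6] /= nz; A[7] /= nz; A[8] /= nz;
  double dp = A[3] * A[6] + A[4] * A[7] + A[5] * A[8];
  A[3] -= dp * A[6]; A[4] -= dp * A[7]; A[5] -= dp * A[8];
  double ny = std::sqrt(A[3] * A[3] + A[4] * A[4] + A[5] * A[5]);
  A[3] /= ny; A[4] /= ny; A[5] /= ny;
  A[0] = A[4] * A[8] - A[5] * A[7];
  A[1] = A[5] * A[6] - A[3] * A[8];
  A[2] = A[3] * A[7] - A[4] * A[6];
}

}  // namespace

// [[Rcpp::export]]
List chain_step_cpp(NumericMatrix centers0, NumericVector frames0,
                    NumericVector G_left, NumericVector G_right,
                    NumericVector phi, double dt, double D,
                    double zone_length, double seg_len) {
  const int n = G_left.size();          // segments
  const int m = n + 1;                  // joints
  if (centers0.nrow() != m) stop("centers/rates size mismatch");

  std::vector<double> cen(3 * m), frm(9 * m);
  // centers0 is m x 3 column-major; store as consecutive 3-vectors.
  for (int i = 0; i < m; ++i) {
    cen[3 * i] = centers0(i, 0);
    cen[3 * i + 1] = centers0(i, 1);
    cen[3 * i + 2] = centers0(i, 2);
    for (int k = 0; k < 9; ++k) frm[9 * i + k] = frames0[9 * i + k];
  }
  std::vector<double> c_old(cen), f_old(frm);

  // ---- grow sweep (relative-transform recomposition, base -> tip) ----
  double len0 = 0.0, len1 = 0.0;
  for (int j = 0; j < n; ++j) {
    double dx = c_old[3 * (j + 1)] - c_old[3 * j];
    double dy = c_old[3 * (j + 1) + 1] - c_old[3 * j + 1];
    double dz = c_old[3 * (j + 1) + 2] - c_old[3 * j + 2];
    len0 += std::sqrt(dx * dx + dy * dy + dz * dz);
  }
  double off[3], w[3], Rrel[9], Rnew[9], M[9], tmp[9], Anew[9], d3[3];
  for (int j = 0; j < n; ++j) {
    const double* Ao = &f_old[9 * j];
    d3[0] = c_old[3 * (j + 1)] - c_old[3 * j];
    d3[1] = c_old[3 * (j + 1) + 1] - c_old[3 * j + 1];
    d3[2] = c_old[3 * (j + 1) + 2] - c_old[3 * j + 2];
    tmatvec3(Ao, d3, w);
    tmatmul3(Ao, &f_old[9 * (j + 1)], Rrel);
    double gl = G_left[j], gr = G_right[j], dG = gl - gr;
    if (dG <= 0.0) {
      off[0] = w[0]; off[1] = w[1]; off[2] = w[2] + 0.5 * (gl + gr) * dt;
      for (int k = 0; k < 9; ++k) Rnew[k] = Rrel[k];
    } else {
      double theta = dG * dt / D;
      double Rc = 0.5 * D * (gl + gr) / dG;
      double sp = std::sin(phi[j]), cp = std::cos(phi[j]);
      double lat = Rc * (1.0 - std::cos(theta));
      rodrigues(cp, -sp, 0.0, theta, M);
      double Mw[3];
      matvec3(M, w, Mw);
      off[0] = -sp * lat + Mw[0];
      off[1] = -cp * lat + Mw[1];
      off[2] = Rc * std::sin(theta) + Mw[2];
      matmul3(M, Rrel, Rnew);
    }
    const double* Aj = &frm[9 * j];
    double woff[3];
    matvec3(Aj, off, woff);
    cen[3 * (j + 1)] = cen[3 * j] + woff[0];
    cen[3 * (j + 1) + 1] = cen[3 * j + 1] + woff[1];
    cen[3 * (j + 1) + 2] = cen[3 * j + 2] + woff[2];
    matmul3(Aj, Rnew, Anew);
    ortho3(Anew);
    for (int k = 0; k < 9; ++k) frm[9 * (j + 1) + k] = Anew[k];
  }

  // ---- resample to n equal sections of seg_len from the tip ----
  std::vector<double> ell(n), cum(m);
  cum[0] = 0.0;
  for (int j = 0; j < n; ++j) {
    double dx = cen[3 * (j + 1)] - cen[3 * j];
    double dy = cen[3 * (j + 1) + 1] - cen[3 * j + 1];
    double dz = cen[3 * (j + 1) + 2] - cen[3 * j + 2];
    ell[j] = std::sqrt(dx * dx + dy * dy + dz * dz);
    cum[j + 1] = cum[j] + ell[j];
  }
  double L = cum[n];
  len1 = L;
  if (L < zone_length) stop("centerline shorter than the elongation zone");

  NumericMatrix new_centers(m, 3);
  NumericVector new_frames(9 * m);
  // relative axis-angle between consecutive frames
  std::vector<double> rang(n), raxis(3 * n);
  for (int k = 0; k < n; ++k) {
    tmatmul3(&frm[9 * k], &frm[9 * (k + 1)], Rrel);
    double wx = Rrel[5] - Rrel[7];
    double wy = Rrel[6] - Rrel[2];
    double wz = Rrel[1] - Rrel[3];
    double s2 = 0.5 * std::sqrt(wx * wx + wy * wy + wz * wz);
    double c2 = 0.5 * (Rrel[0] + Rrel[4] + Rrel[8] - 1.0);
    double a = std::atan2(s2, c2);
    if (s2 > 1e-14) {
      rang[k] = a;
      raxis[3 * k] = wx / (2.0 * s2);
      raxis[3 * k + 1] = wy / (2.0 * s2);
      raxis[3 * k + 2] = wz / (2.0 * s2);
    } else {
      rang[k] = 0.0;
      raxis[3 * k] = 0.0; raxis[3 * k + 1] = 0.0; raxis[3 * k + 2] = 1.0;
    }
  }
  double base_arc = L - zone_length;
  int kseg = 0;
  for (int i = 0; i < m; ++i) {
    double target = base_arc + seg_len * i;
    if (target > L) target = L;
    while (kseg < n - 1 && cum[kseg + 1] < target) ++kseg;
    double frac = (target - cum[kseg]) / ell[kseg];
    for (int c = 0; c < 3; ++c)
      new_centers(i, c) = cen[3 * kseg + c] +
        frac * (cen[3 * (kseg + 1) + c] - cen[3 * kseg + c]);
    double a = rang[kseg] * frac;
    if (std::fabs(a) > 1e-14) {
      rodrigues(raxis[3 * kseg], raxis[3 * kseg + 1], raxis[3 * kseg + 2],
                a, M);
      matmul3(&frm[9 * kseg], M, Anew);
      for (int k = 0; k < 9; ++k) new_frames[9 * i + k] = Anew[k];
    } else {
      for (int k = 0; k < 9; ++k) new_frames[9 * i + k] = frm[9 * kseg + k];
    }
  }
  // joints frozen out of the zone at the base
  int drop_n = 0;
  while (drop_n < m && cum[drop_n] < base_arc - 1e-12) ++drop_n;
  NumericMatrix mat_centers(drop_n, 3);
  NumericVector mat_frames(9 * drop_n);
  for (int i = 0; i < drop_n; ++i) {
    for (int c = 0; c < 3; ++c) mat_centers(i, c) = cen[3 * i + c];
    for (int k = 0; k < 9; ++k) mat_frames[9 * i + k] = frm[9 * i + k];
  }
  new_frames.attr("dim") = IntegerVector::create(3, 3, m);
  mat_frames.attr("dim") = IntegerVector::create(3, 3, drop_n);
  return List::create(_["centers"] = new_centers,
                      _["frames"] = new_frames,
                      _["mature_centers"] = mat_centers,
                      _["mature_frames"] = mat_frames,
                      _["extension"] = len1 - len0);
}
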