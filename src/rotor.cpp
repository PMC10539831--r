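#include <Rcpp.h>
using namespace Rcpp;

// 3x3 row-major helpers
static inline void matmul(const double *a, const double *b, double *c) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      c[3 * i + j] = a[3 * i] * b[j] + a[3 * i + 1] * b[3 + j] +
                     a[3 * i + 2] * b[6 + j];
}

// rotation by angle about body axis (0 = x, 1 = y, 2 = z)
static inline void axis_rot(int axis, double ang, double *r) {
  double c = std::cos(ang), s = std::sin(ang);
  for (int i = 0; i < 9; ++i) r[i] = 0.0;
  switch (axis) {
  case 0:
    r[0] = 1.0; r[4] = c; r[5] = -s; r[7] = s; r[8] = c; break;
  case 1:
    r[4] = 1.0; r[0] = c; r[2] = s; r[6] = -s; r[8] = c; break;
  default:
    r[8] = 1.0; r[0] = c; r[1] = -s; r[3] = s; r[4] = c; break;
  }
}

// Gram-Schmidt re-orthonormalization of a row-major 3x3 rotation
static void renormalize(double *m) {
  double n0 = std::sqrt(m[0] * m[0] + m[1] * m[1] + m[2] * m[2]);
  for (int j = 0; j < 3; ++j) m[j] /= n0;
  double d = m[0] * m[3] + m[1] * m[4] + m[2] * m[5];
  for (int j = 0; j < 3; ++j) m[3 + j] -= d * m[j];
  double n1 = std::sqrt(m[3] * m[3] + m[4] * m[4] + m[5] * m[5]);
  for (int j = 0; j < 3; ++j) m[3 + j] /= n1;
  m[6] = m[1] * m[5] - m[2] * m[4];
  m[7] = m[2] * m[3] - m[0] * m[5];
  m[8] = m[0] * m[4] - m[1] * m[3];
}

// Brownian rotational diffusion of a rigid symmetric top.
// Per step, small random rotations about the three body axes with variances
// (2*D_perp*dt, 2*D_perp*dt, 2*D_par*dt), composed in random order; the
// body->lab rotation matrix is right-multiplied by the increment. Uses R's
// RNG so trajectories are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix rotor_trajectory_cpp(double d_par, double d_perp, double dt,
                                   int n_steps, int stride) {
  double sig_perp = std::sqrt(2.0 * d_perp * dt);
  double sig_par = std::sqrt(2.0 * d_par * dt);
  int n_save = n_steps / stride + 1;
  NumericMatrix out(n_save, 9);

  double R[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  double dr[9], step[9], tmp[9], tmp2[9];
  int order[3];

  for (int j = 0; j < 9; ++j) out(0, j) = R[j];
  int row = 1;

  for (int i = 1; i <= n_steps; ++i) {
    double ang[3] = {sig_perp * norm_rand(), sig_perp * norm_rand(),
                     sig_par * norm_rand()};
    // random permutation of the composition order
    order[0] = (int)(unif_rand() * 3.0); if (order[0] > 2) order[0] = 2;
    order[1] = (order[0] + 1 + (unif_rand() < 0.5 ? 0 : 1)) % 3;
    order[2] = 3 - order[0] - order[1];

    axis_rot(order[0], ang[order[0]], step);
    axis_rot(order[1], ang[order[1]], dr);
    matmul(step, dr, tmp);
    axis_rot(order[2], ang[order[2]], dr);
    matmul(tmp, dr, tmp2);
    matmul(R, tmp2, tmp);
    for (int j = 0; j < 9; ++j) R[j] = tmp[j];

    if (i % 1000 == 0) renormalize(R);
    if (i % stride == 0 && row < n_save) {
      for (int j = 0; j < 9; ++j) out(row, j) = R[j];
      ++row;
    }
  }
  return out;
}

// Lag-averaged P2 cross time-correlation function of two lab-frame vector
// series (n x 3 each), symmetrized over the (u, v) order.
// [[Rcpp::export]]
NumericVector tcf_lags_cpp(NumericMatrix u, NumericMatrix v,
                           IntegerVector lags) {
  int n = u.nrow();
  int nl = lags.size();
  NumericVector out(nl);
  for (int il = 0; il < nl; ++il) {
    int l = lags[il];
    if (l < 0 || l >= n) stop("lag out of range");
    double acc = 0.0;
    int m = n - l;
    for (int i = 0; i < m; ++i) {
      double duv = u(i, 0) * v(i + l, 0) + u(i, 1) * v(i + l, 1) +
                   u(i, 2) * v(i + l, 2);
      double dvu = v(i, 0) * u(i + l, 0) + v(i, 1) * u(i + l, 1) +
                   v(i, 2) * u(i + l, 2);
      acc += 0.5 * (1.5 * duv * duv - 0.5) + 0.5 * (1.5 * dvu * dvu - 0.5);
    }
    out[il] = acc / m;
  }
  return out;
}
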