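#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// 3x3 matrices are stored column-major (element (r, c) at m[r + 3*c]) so
// they map directly onto R matrices.

static inline void mat33_mult(const double* A, const double* B, double* C) {
  for (int c = 0; c < 3; ++c) {
    const double b0 = B[3 * c], b1 = B[1 + 3 * c], b2 = B[2 + 3 * c];
    C[3 * c]     = A[0] * b0 + A[3] * b1 + A[6] * b2;
    C[1 + 3 * c] = A[1] * b0 + A[4] * b1 + A[7] * b2;
    C[2 + 3 * c] = A[2] * b0 + A[5] * b1 + A[8] * b2;
  }
}

static inline void mat33_vec(const double* A, const double* v, double* w) {
  w[0] = A[0] * v[0] + A[3] * v[1] + A[6] * v[2];
  w[1] = A[1] * v[0] + A[4] * v[1] + A[7] * v[2];
  w[2] = A[2] * v[0] + A[5] * v[1] + A[8] * v[2];
}

// w = A^T v
static inline void mat33_tvec(const double* A, const double* v, double* w) {
  w[0] = A[0] * v[0] + A[1] * v[1] + A[2] * v[2];
  w[1] = A[3] * v[0] + A[4] * v[1] + A[5] * v[2];
  w[2] = A[6] * v[0] + A[7] * v[1] + A[8] * v[2];
}

static inline void rot_z(double a, double* m) {
  const double c = std::cos(a), s = std::sin(a);
  m[0] = c;  m[1] = s;  m[2] = 0.0;
  m[3] = -s; m[4] = c;  m[5] = 0.0;
  m[6] = 0.0; m[7] = 0.0; m[8] = 1.0;
}

static inline void rot_y(double a, double* m) {
  const double c = std::cos(a), s = std::sin(a);
  m[0] = c;  m[1] = 0.0; m[2] = -s;
  m[3] = 0.0; m[4] = 1.0; m[5] = 0.0;
  m[6] = s;  m[7] = 0.0; m[8] = c;
}

// Mid-step frame construction for one base-pair step.
//
// theta = (tilt, roll, twist) in radians, (shift, slide, rise) in Angstrom.
// The tilt/roll pair defines a single bend of magnitude Gamma about an axis
// in the base-pair plane at phase phi = atan2(tilt, roll); the twist is
// applied symmetrically (half before, half after the bend); displacements
// are expressed in the mid-step triad:
//   R    = Rz(twist/2 - phi) Ry(Gamma) Rz(twist/2 + phi)
//   Tmid = Rz(twist/2 - phi) Ry(Gamma/2) Rz(phi)
//   t    = Tmid (shift, slide, rise)^T
// Pure twist gives rotation about the frame normal and translation
// (0, 0, rise); pure roll gives a rotation about the long axis.
static void step_rt(const double* th, double* R, double* t) {
  const double tilt = th[0], roll = th[1], twist = th[2];
  const double Gamma = std::sqrt(tilt * tilt + roll * roll);
  const double phi = (Gamma > 0.0) ? std::atan2(tilt, roll) : 0.0;

  double Z1[9], Y[9], Z2[9], tmp[9];
  rot_z(0.5 * twist - phi, Z1);
  rot_y(Gamma, Y);
  rot_z(0.5 * twist + phi, Z2);
  mat33_mult(Z1, Y, tmp);
  mat33_mult(tmp, Z2, R);

  double Ym[9], Zp[9], M[9];
  rot_y(0.5 * Gamma, Ym);
  rot_z(phi, Zp);
  mat33_mult(Z1, Ym, tmp);
  mat33_mult(tmp, Zp, M);
  const double d[3] = { th[3], th[4], th[5] };
  mat33_vec(M, d, t);
}

// Residual twist angle phi between the canonical start frame (identity) and
// an end frame Q: the rotation about the average of the two normals that
// carries the start short axis onto the end short axis.  Well defined as
// long as the normals are not antiparallel; returns NA in that degenerate
// case (which the nested closure test never reaches, since it requires
// cos(gamma) > threshold > 0 first).
static double phi_residual(const double* Q) {
  // n_avg ~ n1 + nN with n1 = (0,0,1), nN = Q col 2
  double n[3] = { Q[6], Q[7], Q[8] + 1.0 };
  double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2]);
  if (nn < 1e-9) return NA_REAL;
  n[0] /= nn; n[1] /= nn; n[2] /= nn;

  // x1 = (1,0,0), xN = Q col 0, both projected onto the plane normal to n
  const double x1[3] = { 1.0, 0.0, 0.0 };
  const double xN[3] = { Q[0], Q[1], Q[2] };
  double p1[3], pN[3];
  const double d1 = x1[0] * n[0] + x1[1] * n[1] + x1[2] * n[2];
  const double dN = xN[0] * n[0] + xN[1] * n[1] + xN[2] * n[2];
  for (int i = 0; i < 3; ++i) {
    p1[i] = x1[i] - d1 * n[i];
    pN[i] = xN[i] - dN * n[i];
  }
  const double l1 = std::sqrt(p1[0] * p1[0] + p1[1] * p1[1] + p1[2] * p1[2]);
  const double lN = std::sqrt(pN[0] * pN[0] + pN[1] * pN[1] + pN[2] * pN[2]);
  if (l1 < 1e-12 || lN < 1e-12) return NA_REAL;
  const double cosphi = (p1[0] * pN[0] + p1[1] * pN[1] + p1[2] * pN[2]) / (l1 * lN);
  // signed via n . (p1 x pN)
  const double cx = p1[1] * pN[2] - p1[2] * pN[1];
  const double cy = p1[2] * pN[0] - p1[0] * pN[2];
  const double cz = p1[0] * pN[1] - p1[1] * pN[0];
  const double sinphi = (n[0] * cx + n[1] * cy + n[2] * cz) / (l1 * lN);
  return std::atan2(sinphi, cosphi);
}

// [[Rcpp::export]]
List cpp_step_rt(NumericVector theta_rad) {
  if (theta_rad.size() != 6) stop("theta must have 6 entries");
  double R[9], t[3];
  step_rt(REAL(theta_rad), R, t);
  NumericMatrix Rm(3, 3);
  std::copy(R, R + 9, Rm.begin());
  NumericVector tv(3);
  std::copy(t, t + 3, tv.begin());
  return List::create(_["rotation"] = Rm, _["translation"] = tv);
}

// Build the frames of a chain from a 6 x S matrix of step parameters
// (angles already in radians).  Frame 1 is the canonical frame at the
// origin; frame k+1 = frame k composed with the step transform.
// [[Rcpp::export]]
List cpp_build_chain(NumericMatrix theta) {
  if (theta.nrow() != 6) stop("theta must be 6 x S");
  const int S = theta.ncol();
  NumericMatrix origins(S + 1, 3);
  NumericVector triads(Dimension(3, 3, S + 1));

  double T[9] = {1, 0, 0, 0, 1, 0, 0, 0, 1};
  double o[3] = {0, 0, 0};
  std::copy(T, T + 9, &triads[0]);

  double R[9], t[3], tt[3], Tn[9];
  for (int s = 0; s < S; ++s) {
    step_rt(&theta[6 * s], R, t);
    mat33_vec(T, t, tt);
    o[0] += tt[0]; o[1] += tt[1]; o[2] += tt[2];
    mat33_mult(T, R, Tn);
    std::copy(Tn, Tn + 9, T);
    origins(s + 1, 0) = o[0];
    origins(s + 1, 1) = o[1];
    origins(s + 1, 2) = o[2];
    std::copy(T, T + 9, &triads[9 * (s + 1)]);
  }
  return List::create(_["origins"] = origins, _["triads"] = triads);
}

// Columns of the sampling matrix that can contribute (frozen principal
// directions have all-zero columns and need no random draws).
static std::vector<int> active_columns(const double* A) {
  std::vector<int> act;
  for (int j = 0; j < 6; ++j) {
    bool nz = false;
    for (int i = 0; i < 6; ++i) nz = nz || (A[i + 6 * j] != 0.0);
    if (nz) act.push_back(j);
  }
  return act;
}

// Draw one chain end state: deviations dev = A z (z iid standard normal
// along the active principal directions) added to the equilibrium theta0
// per step; returns only the terminal orientation and origin.
static void sample_end(const double* th0, int S, const double* A,
                       const std::vector<int>& act, double* T, double* o) {
  T[0] = 1; T[1] = 0; T[2] = 0;
  T[3] = 0; T[4] = 1; T[5] = 0;
  T[6] = 0; T[7] = 0; T[8] = 1;
  o[0] = o[1] = o[2] = 0.0;
  const int na = (int)act.size();
  double th[6], R[9], t[3], tt[3], Tn[9];
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < 6; ++i) th[i] = th0[i + 6 * s];
    for (int a = 0; a < na; ++a) {
      const double z = norm_rand();
      const double* Aj = A + 6 * act[a];
      for (int i = 0; i < 6; ++i) th[i] += Aj[i] * z;
    }
    step_rt(th, R, t);
    mat33_vec(T, t, tt);
    o[0] += tt[0]; o[1] += tt[1]; o[2] += tt[2];
    mat33_mult(T, R, Tn);
    std::copy(Tn, Tn + 9, T);
  }
}

// Naive estimator kernel: sample n_chains full chains, tally the three
// nested closure events into n_batches contiguous batches.
// Returns a n_batches x 4 matrix (n, n_r, n_gamma, n_phi).
// [[Rcpp::export]]
NumericMatrix cpp_sample_naive(NumericMatrix theta0, NumericMatrix A,
                               int n_chains, int n_batches,
                               double capture, double cg_min, double cp_min) {
  if (theta0.nrow() != 6) stop("theta0 must be 6 x S");
  if (A.nrow() != 6 || A.ncol() != 6) stop("A must be 6 x 6");
  if (n_batches < 1) n_batches = 1;
  const int S = theta0.ncol();
  const double cap2 = capture * capture;
  std::vector<double> th0(theta0.begin(), theta0.end());
  double Amat[36];
  std::copy(A.begin(), A.end(), Amat);
  const std::vector<int> act = active_columns(Amat);

  NumericMatrix out(n_batches, 4);
  double T[9], o[3];
  for (int c = 0; c < n_chains; ++c) {
    if ((c & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    const int b = (int)(((long long)c * n_batches) / n_chains);
    out(b, 0) += 1.0;
    sample_end(th0.data(), S, Amat, act, T, o);
    const double r2 = o[0] * o[0] + o[1] * o[1] + o[2] * o[2];
    if (r2 >= cap2) continue;
    out(b, 1) += 1.0;
    const double cosg = T[8];  // n1 . nN with n1 = (0,0,1)
    if (!(cosg > cg_min)) continue;
    out(b, 2) += 1.0;
    const double phi = phi_residual(T);
    if (ISNAN(phi) || !(std::cos(phi) > cp_min)) continue;
    out(b, 3) += 1.0;
  }
  return out;
}

// Sample M half-chain end states (terminal rotation as 9 col-major entries
// per row, terminal origin as 3 entries per row).
// [[Rcpp::export]]
List cpp_sample_half_ends(NumericMatrix theta0, NumericMatrix A, int M) {
  if (theta0.nrow() != 6) stop("theta0 must be 6 x S");
  const int S = theta0.ncol();
  std::vector<double> th0(theta0.begin(), theta0.end());
  double Amat[36];
  std::copy(A.begin(), A.end(), Amat);
  const std::vector<int> act = active_columns(Amat);
  NumericMatrix Rm(M, 9), om(M, 3);
  double T[9], o[3];
  for (int m = 0; m < M; ++m) {
    if ((m & 0xFFF) == 0) Rcpp::checkUserInterrupt();
    sample_end(th0.data(), S, Amat, act, T, o);
    for (int k = 0; k < 9; ++k) Rm(m, k) = T[k];
    om(m, 0) = o[0]; om(m, 1) = o[1]; om(m, 2) = o[2];
  }
  return List::create(_["R"] = Rm, _["o"] = om);
}

static inline int64_t cell_key(int ix, int iy, int iz) {
  const int64_t B = 1 << 20;
  return (((int64_t)(ix + B)) << 42) | (((int64_t)(iy + B)) << 21) |
         (int64_t)(iz + B);
}

// Closure tallies over all ordered pairs (i, j) of first-half x second-half
// end states.  Full-chain end orientation Q = R_i S_j, end origin
// a_i + R_i b_j; the capture condition |a_i + R_i b_j| < capture is
// rewritten as |b_j - u_i| < capture with u_i = -R_i^T a_i, so an exact
// uniform grid over the b_j (cell edge = capture radius) prefilters pairs.
// Batches partition the first-half index i.  Returns n_batches x 4
// (n_pairs, n_r, n_gamma, n_phi).
// [[Rcpp::export]]
NumericMatrix cpp_pair_counts(NumericMatrix Ra, NumericMatrix aa,
                              NumericMatrix Sb, NumericMatrix bb,
                              double capture, double cg_min, double cp_min,
                              int n_batches, bool use_grid) {
  const int M1 = Ra.nrow(), M2 = Sb.nrow();
  if (aa.nrow() != M1 || bb.nrow() != M2) stop("mismatched half-chain inputs");
  if (n_batches < 1) n_batches = 1;
  const double cap2 = capture * capture;
  NumericMatrix out(n_batches, 4);

  // copy to contiguous row-wise arrays
  std::vector<double> R1(9 * M1), O1(3 * M1), R2(9 * M2), O2(3 * M2);
  for (int i = 0; i < M1; ++i) {
    for (int k = 0; k < 9; ++k) R1[9 * i + k] = Ra(i, k);
    for (int k = 0; k < 3; ++k) O1[3 * i + k] = aa(i, k);
  }
  for (int j = 0; j < M2; ++j) {
    for (int k = 0; k < 9; ++k) R2[9 * j + k] = Sb(j, k);
    for (int k = 0; k < 3; ++k) O2[3 * j + k] = bb(j, k);
  }

  std::unordered_map<int64_t, std::vector<int> > grid;
  if (use_grid) {
    grid.reserve(M2 * 2);
    for (int j = 0; j < M2; ++j) {
      const int ix = (int)std::floor(O2[3 * j] / capture);
      const int iy = (int)std::floor(O2[3 * j + 1] / capture);
      const int iz = (int)std::floor(O2[3 * j + 2] / capture);
      grid[cell_key(ix, iy, iz)].push_back(j);
    }
  }

  std::vector<int> cand;
  for (int i = 0; i < M1; ++i) {
    if ((i & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    const int b = i % n_batches;
    out(b, 0) += (double)M2;
    const double* Ri = &R1[9 * i];
    double u[3];
    mat33_tvec(Ri, &O1[3 * i], u);
    u[0] = -u[0]; u[1] = -u[1]; u[2] = -u[2];

    const int ux = (int)std::floor(u[0] / capture);
    const int uy = (int)std::floor(u[1] / capture);
    const int uz = (int)std::floor(u[2] / capture);

    cand.clear();
    if (use_grid) {
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
              grid.find(cell_key(ux + dx, uy + dy, uz + dz));
            if (it != grid.end())
              cand.insert(cand.end(), it->second.begin(), it->second.end());
          }
    }
    const int ncand = use_grid ? (int)cand.size() : M2;
    for (int jj = 0; jj < ncand; ++jj) {
      const int j = use_grid ? cand[jj] : jj;
      const double* bj = &O2[3 * j];
      const double dx = bj[0] - u[0], dy = bj[1] - u[1], dz = bj[2] - u[2];
      const double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= cap2) continue;
      out(b, 1) += 1.0;
      const double* Sj = &R2[9 * j];
      // Q col 2 = Ri %*% (Sj col 2); only its z-entry is cos(gamma)
      double qc2[3];
      mat33_vec(Ri, Sj + 6, qc2);
      if (!(qc2[2] > cg_min)) continue;
      out(b, 2) += 1.0;
      double qc0[3];
      mat33_vec(Ri, Sj, qc0);
      double Q[9];
      Q[0] = qc0[0]; Q[1] = qc0[1]; Q[2] = qc0[2];
      Q[3] = Q[4] = Q[5] = 0.0;  // col 1 unused by phi_residual
      Q[6] = qc2[0]; Q[7] = qc2[1]; Q[8] = qc2[2];
      const double phi = phi_residual(Q);
      if (ISNAN(phi) || !(std::cos(phi) > cp_min)) continue;
      out(b, 3) += 1.0;
    }
  }
  return out;
}

// Closure geometry for a set of end frames relative to the canonical start
// frame: returns (r, cos_gamma, phi) per row.
// [[Rcpp::export]]
NumericMatrix cpp_closure_stats(NumericMatrix R9, NumericMatrix o3) {
  const int n = R9.nrow();
  if (o3.nrow() != n || R9.ncol() != 9 || o3.ncol() != 3)
    stop("expected n x 9 rotations and n x 3 origins");
  NumericMatrix out(n, 3);
  double Q[9];
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 9; ++k) Q[k] = R9(i, k);
    const double x = o3(i, 0), y = o3(i, 1), z = o3(i, 2);
    out(i, 0) = std::sqrt(x * x + y * y + z * z);
    out(i, 1) = Q[8];
    out(i, 2) = phi_residual(Q);
  }
  return out;
}

// Mean tangent-tangent correlation <t1 . tk> over sampled chains, k = 0..S
// (t1 is the canonical start normal (0,0,1), so the correlation with frame
// k is just the (3,3) entry of that frame's triad).
// [[Rcpp::export]]
NumericVector cpp_tangent_corr(NumericMatrix theta0, NumericMatrix A,
                               int n_chains) {
  if (theta0.nrow() != 6) stop("theta0 must be 6 x S");
  const int S = theta0.ncol();
  std::vector<double> th0(theta0.begin(), theta0.end());
  double Amat[36];
  std::copy(A.begin(), A.end(), Amat);

  const std::vector<int> act = active_columns(Amat);
  const int na = (int)act.size();
  NumericVector corr(S + 1);
  double th[6], R[9], t[3], T[9], Tn[9];
  for (int c = 0; c < n_chains; ++c) {
    if ((c & 0xFFF) == 0) Rcpp::checkUserInterrupt();
    T[0] = 1; T[1] = 0; T[2] = 0;
    T[3] = 0; T[4] = 1; T[5] = 0;
    T[6] = 0; T[7] = 0; T[8] = 1;
    corr[0] += 1.0;
    for (int s = 0; s < S; ++s) {
      for (int i = 0; i < 6; ++i) th[i] = th0[i + 6 * s];
      for (int a = 0; a < na; ++a) {
        const double z = norm_rand();
        const double* Aj = Amat + 6 * act[a];
        for (int i = 0; i < 6; ++i) th[i] += Aj[i] * z;
      }
      step_rt(th, R, t);
      mat33_mult(T, R, Tn);
      std::copy(Tn, Tn + 9, T);
      corr[s + 1] += T[8];
    }
  }
  for (int k = 0; k <= S; ++k) corr[k] /= n_chains;
  return corr;
}
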