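// Rigid-body DNA engine: constrained Newton-Euler dynamics of a capsule
// chain with ball/weld joints, capsule collision handling, bending/twisting
// elasticity and local/global Langevin thermostats. Velocity-level
// constraint solve in force form:
//   A lambda = rhs,  A = J W^-1 J^T + cfm/dt,
//   rhs = (v_target - (erp/dt) C - J uf)/dt,   uf = u + dt W^-1 F_ext,
//   u' = uf + dt W^-1 J^T lambda.
// Collision-free steps use the exact O(N) block-tridiagonal factorization of
// the serial-chain A; steps with contacts run projected SOR and fall back to
// a direct Schur-complement active-set solve when the acceptance metric
// (implied per-step bearing-separation growth) exceeds accept_tol.
//
// The R files in R/ hold the dense reference implementations; tests compare
// the two paths step by step.

#include <RcppArmadillo.h>
#include <vector>
#include <cstring>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// ---------- small vector helpers ----------------------------------------

static inline void cross(const double* a, const double* b, double* o) {
  o[0] = a[1] * b[2] - a[2] * b[1];
  o[1] = a[2] * b[0] - a[0] * b[2];
  o[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double norm3(const double* a) { return std::sqrt(dot3(a, a)); }

static inline void quat_mul(const double* q1, const double* q2, double* o) {
  o[0] = q1[0]*q2[0] - q1[1]*q2[1] - q1[2]*q2[2] - q1[3]*q2[3];
  o[1] = q1[0]*q2[1] + q1[1]*q2[0] + q1[2]*q2[3] - q1[3]*q2[2];
  o[2] = q1[0]*q2[2] - q1[1]*q2[3] + q1[2]*q2[0] + q1[3]*q2[1];
  o[3] = q1[0]*q2[3] + q1[1]*q2[2] - q1[2]*q2[1] + q1[3]*q2[0];
}

static inline void quat_to_mat(const double* q, double* R) {
  double w = q[0], x = q[1], y = q[2], z = q[3];
  R[0] = 1 - 2*(y*y + z*z); R[1] = 2*(x*y - w*z);     R[2] = 2*(x*z + w*y);
  R[3] = 2*(x*y + w*z);     R[4] = 1 - 2*(x*x + z*z); R[5] = 2*(y*z - w*x);
  R[6] = 2*(x*z - w*y);     R[7] = 2*(y*z + w*x);     R[8] = 1 - 2*(x*x + y*y);
}

// ---------- small dense Cholesky (n <= 12), row-major --------------------

static bool chol_small(int n, double* A) {   // in place, lower triangle
  for (int j = 0; j < n; ++j) {
    double d = A[j*n + j];
    for (int k = 0; k < j; ++k) d -= A[j*n + k] * A[j*n + k];
    if (d <= 0) return false;
    d = std::sqrt(d);
    A[j*n + j] = d;
    for (int i = j + 1; i < n; ++i) {
      double s = A[i*n + j];
      for (int k = 0; k < j; ++k) s -= A[i*n + k] * A[j*n + k];
      A[i*n + j] = s / d;
    }
  }
  return true;
}

static void chol_solve(int n, const double* L, double* x) { // x in place
  for (int i = 0; i < n; ++i) {
    double s = x[i];
    for (int k = 0; k < i; ++k) s -= L[i*n + k] * x[k];
    x[i] = s / L[i*n + i];
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = x[i];
    for (int k = i + 1; k < n; ++k) s -= L[k*n + i] * x[k];
    x[i] = s / L[i*n + i];
  }
}

// ---------- segment-segment closest points (Ericson) ----------------------

static double segseg(const double* p1, const double* q1,
                     const double* p2, const double* q2,
                     double* c1, double* c2) {
  double d1[3], d2[3], r[3];
  for (int k = 0; k < 3; ++k) {
    d1[k] = q1[k] - p1[k]; d2[k] = q2[k] - p2[k]; r[k] = p1[k] - p2[k];
  }
  double a = dot3(d1, d1), e = dot3(d2, d2), f = dot3(d2, r);
  const double EPS = 1e-14;
  double s, t;
  if (a <= EPS && e <= EPS) { s = t = 0; }
  else if (a <= EPS) { s = 0; t = std::min(std::max(f / e, 0.0), 1.0); }
  else {
    double c0 = dot3(d1, r);
    if (e <= EPS) { t = 0; s = std::min(std::max(-c0 / a, 0.0), 1.0); }
    else {
      double b = dot3(d1, d2), den = a * e - b * b;
      s = (den > EPS) ? std::min(std::max((b * f - c0 * e) / den, 0.0), 1.0) : 0.0;
      t = (b * s + f) / e;
      if (t < 0) { t = 0; s = std::min(std::max(-c0 / a, 0.0), 1.0); }
      else if (t > 1) { t = 1; s = std::min(std::max((b - c0) / a, 0.0), 1.0); }
    }
  }
  for (int k = 0; k < 3; ++k) {
    c1[k] = p1[k] + s * d1[k]; c2[k] = p2[k] + t * d2[k];
  }
  double dd[3] = { c1[0]-c2[0], c1[1]-c2[1], c1[2]-c2[2] };
  return norm3(dd);
}

// ---------- polyline writhe (Klenin-Langowski solid-angle method) ---------

static double writhe_pair(const double* p1, const double* p2,
                          const double* p3, const double* p4) {
  double r12[3], r34[3], r13[3], r14[3], r23[3], r24[3];
  for (int k = 0; k < 3; ++k) {
    r12[k] = p2[k]-p1[k]; r34[k] = p4[k]-p3[k];
    r13[k] = p3[k]-p1[k]; r14[k] = p4[k]-p1[k];
    r23[k] = p3[k]-p2[k]; r24[k] = p4[k]-p2[k];
  }
  double n1[3], n2[3], n3[3], n4[3];
  cross(r13, r14, n1); cross(r14, r24, n2);
  cross(r24, r23, n3); cross(r23, r13, n4);
  double l1 = norm3(n1), l2 = norm3(n2), l3 = norm3(n3), l4 = norm3(n4);
  if (l1 < 1e-14 || l2 < 1e-14 || l3 < 1e-14 || l4 < 1e-14) return 0.0;
  for (int k = 0; k < 3; ++k) {
    n1[k] /= l1; n2[k] /= l2; n3[k] /= l3; n4[k] /= l4;
  }
  auto casin = [](double x) {
    return std::asin(std::min(1.0, std::max(-1.0, x)));
  };
  double omega = casin(dot3(n1, n2)) + casin(dot3(n2, n3)) +
                 casin(dot3(n3, n4)) + casin(dot3(n4, n1));
  double cr[3]; cross(r34, r12, cr);
  double sg = dot3(cr, r13) >= 0 ? 1.0 : -1.0;
  return omega * sg / (4.0 * M_PI);
}

static double polyline_writhe(const double* pts, int np) {
  // sum over non-adjacent segment pairs; factor 2 for ordered pairs
  double wr = 0.0;
  int ns = np - 1;
  for (int i = 0; i < ns; ++i) {
    for (int j = i + 2; j < ns; ++j) {
      wr += writhe_pair(pts + 3*i, pts + 3*(i+1), pts + 3*j, pts + 3*(j+1));
    }
  }
  return 2.0 * wr;
}

// ---------- engine --------------------------------------------------------

struct Contact {
  int b1, b2;          // b2 = -1 for plane
  double point[3], normal[3], depth;
  int64_t key;         // warm-start key
};

struct Engine {
  // bodies
  int nb, nc;                       // total bodies, chain cylinders
  std::vector<double> pos, quat, vel, omg;     // nb x {3,4,3,3}
  std::vector<double> mass, invmass, inertia, radius, len; // nb, nb, nb*3, nb, nb
  std::vector<int> stype;           // 0 capsule, 1 sphere
  std::vector<double> Rm;           // nb x 9 rotation matrices
  std::vector<double> Iwinv;        // nb x 9
  std::vector<double> force, torque;   // nb x 3

  // joints
  int nj;
  std::vector<int> jtype, ja, jb;
  std::vector<double> jaa, jab, jqref;   // nj*3, nj*3, nj*4

  // elasticity
  int ne;
  std::vector<int> ea, eb;
  double g_b, g_t;
  std::vector<double> phi_prev, phi_cum;
  bool phi_init = false;

  // clamp / drive
  int clamp_mode = 0, clamp_body = -1;
  double psi = 0, psi_target = 0, psi_rate = 0, psi_cap = 0, torque_z = 0;
  double qbead0[4] = {1, 0, 0, 0};
  int pull_body = -1;
  double pull_local[3] = {0, 0, 0}, pull_force[3] = {0, 0, 0};

  // thermostat
  int tmode = 0;
  double gamma_t = 10.0, kBT = 1.0, gamma_bg = 0.0;
  int ndof = 0;

  // solver
  double erp = 0.8, cfm = 1e-10, sor_omega = 1.3, accept_tol = 1e-6;
  double max_push = 1.0;            // cap on contact push-out velocity (b/tau)
  int sor_iter = 64;
  bool force_direct = false;

  // collisions
  bool col_enabled = false, plane_enabled = false, first_plane_attached = true;
  double contact_erp = 0.8;
  int excl_window = 1;    // bonded neighbours |i-j| <= window never collide

  double dt = 0.000592, time = 0;
  EngineRng rng{1};

  // ---- constraint row storage ----
  int mrows = 0, mperm = 0;
  std::vector<int> rA, rB;
  std::vector<double> Jva, Jwa, Jvb, Jwb, Cv, vtg, lo_, lam;
  std::vector<double> wJa, wJb;     // per row: W^-1 J^T blocks (6 each side)
  std::vector<double> adiag;
  // per permanent joint: world lever arms (filled during row assembly) and
  // a flag marking pure-ball groups eligible for the analytic block path
  std::vector<double> lever_a, lever_b;   // nj*3
  std::vector<char> grp_ball;
  std::vector<double> uf;           // nb*6 predicted velocities
  std::vector<double> acc;          // nb*6 accumulated W^-1 J^T lambda
  // groups (permanent rows)
  std::vector<int> gstart, gsize;
  // tridiagonal factor storage
  std::vector<double> cholD;        // per group 12*12
  std::vector<double> Eblk;         // per group 12*12 (E_g: g <-> g+1)
  std::vector<Contact> contacts;
  std::vector<std::pair<int64_t,double>> warm, warm_prev;

  // diagnostics
  double max_pen = 0, max_C_run = 0, cur_maxC = 0, cur_viol = 0;
  int cur_solver = 0;               // 0 exact 1 sor 2 direct
  long n_sor = 0, n_direct = 0;

  // spatial hash grid
  std::vector<int> grid_head, grid_next;
  double cell_size = 2.0;

  // ---------------- setup -------------------------------------------------

  void init_from_spec(List spec) {
    NumericMatrix P = spec["pos"], Q = spec["quat"], V = spec["vel"],
                  Wg = spec["omg"], In = spec["inertia"];
    nb = P.nrow();
    pos.assign(nb*3, 0); quat.assign(nb*4, 0); vel.assign(nb*3, 0);
    omg.assign(nb*3, 0); inertia.assign(nb*3, 0);
    for (int i = 0; i < nb; ++i) {
      for (int k = 0; k < 3; ++k) {
        pos[3*i+k] = P(i, k); vel[3*i+k] = V(i, k);
        omg[3*i+k] = Wg(i, k); inertia[3*i+k] = In(i, k);
      }
      for (int k = 0; k < 4; ++k) quat[4*i+k] = Q(i, k);
    }
    mass = as<std::vector<double>>(spec["mass"]);
    invmass.resize(nb);
    for (int i = 0; i < nb; ++i) invmass[i] = 1.0 / mass[i];
    radius = as<std::vector<double>>(spec["radius"]);
    len = as<std::vector<double>>(spec["len"]);
    stype = as<std::vector<int>>(spec["stype"]);
    nc = 0; for (int i = 0; i < nb; ++i) if (stype[i] == 0) ++nc;

    IntegerVector jt = spec["jtype"], jA = spec["ja"], jB = spec["jb"];
    NumericMatrix JA = spec["janchor_a"], JB = spec["janchor_b"],
                  JQ = spec["jqref"];
    nj = jt.size();
    jtype.assign(jt.begin(), jt.end());
    ja.assign(jA.begin(), jA.end());
    jb.assign(jB.begin(), jB.end());
    jaa.assign(nj*3, 0); jab.assign(nj*3, 0); jqref.assign(nj*4, 0);
    for (int k = 0; k < nj; ++k) {
      for (int d = 0; d < 3; ++d) { jaa[3*k+d] = JA(k, d); jab[3*k+d] = JB(k, d); }
      for (int d = 0; d < 4; ++d) jqref[4*k+d] = JQ(k, d);
    }

    IntegerMatrix EP = spec["epairs"];
    ne = EP.nrow();
    ea.resize(ne); eb.resize(ne);
    for (int k = 0; k < ne; ++k) { ea[k] = EP(k, 0); eb[k] = EP(k, 1); }
    g_b = as<double>(spec["g_b"]); g_t = as<double>(spec["g_t"]);
    phi_prev = as<std::vector<double>>(spec["phi_prev"]);
    phi_cum = as<std::vector<double>>(spec["phi_cum"]);
    phi_init = as<bool>(spec["phi_init"]);

    clamp_mode = as<int>(spec["clamp_mode"]);
    clamp_body = as<int>(spec["clamp_body"]);
    psi = as<double>(spec["psi"]);
    psi_target = as<double>(spec["psi_target"]);
    psi_rate = as<double>(spec["psi_rate"]);
    psi_cap = as<double>(spec["psi_cap"]);
    torque_z = as<double>(spec["torque_z"]);
    NumericVector qb0 = spec["qbead0"];
    for (int k = 0; k < 4; ++k) qbead0[k] = qb0[k];
    pull_body = as<int>(spec["pull_body"]);
    NumericVector pl = spec["pull_local"], pf = spec["pull_force"];
    for (int k = 0; k < 3; ++k) { pull_local[k] = pl[k]; pull_force[k] = pf[k]; }

    tmode = as<int>(spec["tmode"]);
    gamma_t = as<double>(spec["gamma"]);
    kBT = as<double>(spec["kBT"]);
    gamma_bg = as<double>(spec["gamma_bg"]);
    ndof = as<int>(spec["ndof"]);

    erp = as<double>(spec["erp"]);
    cfm = as<double>(spec["cfm"]);
    sor_omega = as<double>(spec["sor_omega"]);
    sor_iter = as<int>(spec["sor_iter"]);
    accept_tol = as<double>(spec["accept_tol"]);
    force_direct = as<bool>(spec["force_direct"]);
    contact_erp = as<double>(spec["contact_erp"]);
    max_push = as<double>(spec["max_push"]);

    col_enabled = as<bool>(spec["col_enabled"]);
    plane_enabled = as<bool>(spec["plane_enabled"]);
    first_plane_attached = as<bool>(spec["first_plane_attached"]);
    excl_window = as<int>(spec["excl_window"]);

    dt = as<double>(spec["dt"]);
    time = as<double>(spec["time"]);
    rng = EngineRng(static_cast<uint64_t>(as<double>(spec["seed"])));

    Rm.assign(nb*9, 0); Iwinv.assign(nb*9, 0);
    force.assign(nb*3, 0); torque.assign(nb*3, 0);
    uf.assign(nb*6, 0); acc.assign(nb*6, 0);

    build_groups();
    double rmax = 0;
    for (int i = 0; i < nc; ++i) rmax = std::max(rmax, radius[i]);
    cell_size = (nc > 0 ? len[0] : 1.0) + 2 * rmax;
    int gcap = 1; while (gcap < 2 * nb) gcap <<= 1;
    grid_head.assign(gcap, -1); grid_next.assign(nb, -1);
  }

  int clamp_rows() const {
    return clamp_mode == 1 ? 3 : (clamp_mode == 2 ? 2 : 0);
  }

  void build_groups() {
    gstart.clear(); gsize.clear();
    int row = 0;
    for (int k = 0; k < nj; ++k) {
      int sz = (jtype[k] == 1) ? 6 : 3;
      if (k == nj - 1) sz += clamp_rows();   // clamp rows share the last group
      gstart.push_back(row); gsize.push_back(sz); row += sz;
    }
    if (nj == 0 && clamp_rows() > 0) {
      gstart.push_back(0); gsize.push_back(clamp_rows()); row = clamp_rows();
    }
    mperm = row;
    lever_a.assign(nj * 3, 0.0);
    lever_b.assign(nj * 3, 0.0);
    grp_ball.assign(gstart.size(), 0);
    for (size_t g = 0; g < gstart.size(); ++g) {
      grp_ball[g] = (gsize[g] == 3 && (int)g < nj && jtype[g] == 0) ? 1 : 0;
    }
    int cap = mperm + 64;
    rA.resize(cap); rB.resize(cap);
    Jva.resize(cap*3); Jwa.resize(cap*3); Jvb.resize(cap*3); Jwb.resize(cap*3);
    Cv.resize(cap); vtg.resize(cap); lo_.resize(cap); lam.resize(cap);
    wJa.resize(cap*6); wJb.resize(cap*6); adiag.resize(cap);
    int G = gstart.size();
    cholD.assign(G * 144, 0);
    Eblk.assign(G * 144, 0);
  }

  void ensure_row_capacity(int m) {
    if ((int)rA.size() >= m) return;
    int cap = m + 64;
    rA.resize(cap); rB.resize(cap);
    Jva.resize(cap*3); Jwa.resize(cap*3); Jvb.resize(cap*3); Jwb.resize(cap*3);
    Cv.resize(cap); vtg.resize(cap); lo_.resize(cap); lam.resize(cap);
    wJa.resize(cap*6); wJb.resize(cap*6); adiag.resize(cap);
  }

  // ---------------- per-step pieces ---------------------------------------

  void update_frames() {
    for (int i = 0; i < nb; ++i) {
      quat_to_mat(&quat[4*i], &Rm[9*i]);
      const double* R = &Rm[9*i];
      const double* I = &inertia[3*i];
      // Iwinv = R diag(1/I) R^T
      for (int r = 0; r < 3; ++r)
        for (int c = 0; c < 3; ++c)
          Iwinv[9*i + 3*r + c] = R[3*r+0]*R[3*c+0]/I[0] +
                                 R[3*r+1]*R[3*c+1]/I[1] +
                                 R[3*r+2]*R[3*c+2]/I[2];
    }
  }

  inline void iw_mul(int i, const double* v, double* o) const {  // I_world v
    const double* R = &Rm[9*i];
    const double* I = &inertia[3*i];
    double bf[3] = { R[0]*v[0]+R[3]*v[1]+R[6]*v[2],
                     R[1]*v[0]+R[4]*v[1]+R[7]*v[2],
                     R[2]*v[0]+R[5]*v[1]+R[8]*v[2] };
    bf[0] *= I[0]; bf[1] *= I[1]; bf[2] *= I[2];
    o[0] = R[0]*bf[0]+R[1]*bf[1]+R[2]*bf[2];
    o[1] = R[3]*bf[0]+R[4]*bf[1]+R[5]*bf[2];
    o[2] = R[6]*bf[0]+R[7]*bf[1]+R[8]*bf[2];
  }

  inline void iwinv_mul(int i, const double* v, double* o) const {
    const double* M = &Iwinv[9*i];
    o[0] = M[0]*v[0]+M[1]*v[1]+M[2]*v[2];
    o[1] = M[3]*v[0]+M[4]*v[1]+M[5]*v[2];
    o[2] = M[6]*v[0]+M[7]*v[1]+M[8]*v[2];
  }

  double kinetic_energy() const {
    double K = 0;
    for (int i = 0; i < nb; ++i) {
      K += 0.5 * mass[i] * dot3(&vel[3*i], &vel[3*i]);
      double Iw[3]; iw_mul(i, &omg[3*i], Iw);
      K += 0.5 * dot3(&omg[3*i], Iw);
    }
    return K;
  }

  void elastic_and_applied_forces() {
    std::fill(force.begin(), force.end(), 0.0);
    std::fill(torque.begin(), torque.end(), 0.0);
    // elastic joint torques + twist bookkeeping
    for (int k = 0; k < ne; ++k) {
      int i = ea[k], j = eb[k];
      const double* Ri = &Rm[9*i];
      const double* Rj = &Rm[9*j];
      double t1[3] = { Ri[2], Ri[5], Ri[8] };
      double u1[3] = { Ri[0], Ri[3], Ri[6] };
      double v1[3] = { Ri[1], Ri[4], Ri[7] };
      double t2[3] = { Rj[2], Rj[5], Rj[8] };
      double u2[3] = { Rj[0], Rj[3], Rj[6] };
      double v2[3] = { Rj[1], Rj[4], Rj[7] };
      double ct = dot3(t1, t2);
      double phi;
      bool gimbal = ct < -1.0 + 1e-9 || std::acos(std::min(1.0, std::max(-1.0, ct))) > M_PI - 1e-3;
      if (gimbal) {
        phi = phi_prev[k];
      } else {
        phi = std::atan2(dot3(v1, u2) - dot3(u1, v2), dot3(u1, u2) + dot3(v1, v2));
      }
      if (!phi_init) { phi_prev[k] = phi; }
      double dphi = phi - phi_prev[k];
      if (dphi > M_PI) dphi -= 2*M_PI; else if (dphi < -M_PI) dphi += 2*M_PI;
      phi_cum[k] += dphi;
      phi_prev[k] = phi;
      double tq[3] = {0, 0, 0};
      if (!gimbal && 1 + ct > 1e-9) {
        double f = -g_t * std::sin(phi) / (1 + ct);
        tq[0] = f * (t1[0] + t2[0]); tq[1] = f * (t1[1] + t2[1]);
        tq[2] = f * (t1[2] + t2[2]);
      }
      double cr[3]; cross(t1, t2, cr);
      tq[0] -= g_b * cr[0]; tq[1] -= g_b * cr[1]; tq[2] -= g_b * cr[2];
      for (int d = 0; d < 3; ++d) {
        torque[3*j+d] += tq[d];
        torque[3*i+d] -= tq[d];
      }
    }
    phi_init = true;
    // pulling force at an attachment point
    if (pull_body >= 0) {
      const double* R = &Rm[9*pull_body];
      double rw[3] = {
        R[0]*pull_local[0]+R[1]*pull_local[1]+R[2]*pull_local[2],
        R[3]*pull_local[0]+R[4]*pull_local[1]+R[5]*pull_local[2],
        R[6]*pull_local[0]+R[7]*pull_local[1]+R[8]*pull_local[2] };
      double tq[3]; cross(rw, pull_force, tq);
      for (int d = 0; d < 3; ++d) {
        force[3*pull_body+d] += pull_force[d];
        torque[3*pull_body+d] += tq[d];
      }
    }
    // external torque on the bead (torque clamp)
    if (clamp_mode == 2 && clamp_body >= 0) torque[3*clamp_body+2] += torque_z;

    // gyroscopic term
    for (int i = 0; i < nb; ++i) {
      double Iw[3]; iw_mul(i, &omg[3*i], Iw);
      double gy[3]; cross(&omg[3*i], Iw, gy);
      torque[3*i+0] -= gy[0]; torque[3*i+1] -= gy[1]; torque[3*i+2] -= gy[2];
    }
  }

  // local Langevin friction + FDT noise at coupling g (full thermostat or
  // the weak ergodicity background under the global scheme)
  void local_kicks(double g) {
    double amp_l, amp_a[3];
    for (int i = 0; i < nb; ++i) {
      amp_l = std::sqrt(2 * g * kBT * mass[i] / dt);
      for (int d = 0; d < 3; ++d)
        force[3*i+d] += -g * mass[i] * vel[3*i+d] + amp_l * rng.norm();
      double Iw[3]; iw_mul(i, &omg[3*i], Iw);
      for (int d = 0; d < 3; ++d)
        amp_a[d] = std::sqrt(2 * g * kBT * inertia[3*i+d] / dt);
      double xi[3] = { amp_a[0]*rng.norm(), amp_a[1]*rng.norm(),
                       amp_a[2]*rng.norm() };
      const double* R = &Rm[9*i];
      for (int d = 0; d < 3; ++d)
        torque[3*i+d] += -g * Iw[d] +
          R[3*d+0]*xi[0] + R[3*d+1]*xi[1] + R[3*d+2]*xi[2];
    }
  }

  void thermostat_forces() {
    if (tmode == 1) {           // local Langevin
      local_kicks(gamma_t);
    } else if (tmode == 2) {    // global stochastic velocity rescaling
      double K = kinetic_energy();
      if (K <= 0) return;
      double cc = std::exp(-2 * gamma_t * dt);
      double r1 = rng.norm();
      double s = (ndof > 1) ? rng.chisq(ndof - 1) : 0.0;
      double a2 = cc + (1 - cc) * (r1*r1 + s) * kBT / (2*K) +
                  2 * r1 * std::sqrt(cc * (1 - cc) * kBT / (2*K));
      double sgn = (r1 + std::sqrt(2 * cc * K / ((1 - cc) * kBT))) >= 0 ? 1.0 : -1.0;
      double alpha = sgn * std::sqrt(std::max(a2, 0.0));
      double fac = (alpha - 1) / dt;
      for (int i = 0; i < nb; ++i) {
        for (int d = 0; d < 3; ++d) force[3*i+d] += fac * mass[i] * vel[3*i+d];
        double Iw[3]; iw_mul(i, &omg[3*i], Iw);
        for (int d = 0; d < 3; ++d) torque[3*i+d] += fac * Iw[d];
      }
      if (gamma_bg > 0) local_kicks(gamma_bg);
    }
  }

  void predict_velocities() {
    for (int i = 0; i < nb; ++i) {
      for (int d = 0; d < 3; ++d)
        uf[6*i+d] = vel[3*i+d] + dt * force[3*i+d] * invmass[i];
      double ti[3]; iwinv_mul(i, &torque[3*i], ti);
      for (int d = 0; d < 3; ++d)
        uf[6*i+3+d] = omg[3*i+d] + dt * ti[d];
    }
  }

  // ---- collision detection ----

  void detect_collisions() {
    contacts.clear();
    if (!col_enabled) return;
    int gcap = grid_head.size();
    std::fill(grid_head.begin(), grid_head.end(), -1);
    double inv = 1.0 / cell_size;
    auto cell_of = [&](int i, int* c) {
      c[0] = (int)std::floor(pos[3*i+0] * inv);
      c[1] = (int)std::floor(pos[3*i+1] * inv);
      c[2] = (int)std::floor(pos[3*i+2] * inv);
    };
    auto hash_of = [&](const int* c) {
      uint64_t h = (uint64_t)(c[0] * 73856093) ^ (uint64_t)(c[1] * 19349663) ^
                   (uint64_t)(c[2] * 83492791);
      return (int)(h & (uint64_t)(gcap - 1));
    };
    std::vector<int> cc(3*nc);
    for (int i = 0; i < nc; ++i) {
      cell_of(i, &cc[3*i]);
      int h = hash_of(&cc[3*i]);
      grid_next[i] = grid_head[h]; grid_head[h] = i;
    }
    // cylinder-cylinder via grid
    for (int i = 0; i < nc; ++i) {
      int c0[3] = { cc[3*i], cc[3*i+1], cc[3*i+2] };
      for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        int c[3] = { c0[0]+dx, c0[1]+dy, c0[2]+dz };
        for (int j = grid_head[hash_of(c)]; j >= 0; j = grid_next[j]) {
          if (j <= i + excl_window) continue;    // ordered; bonded window
          if (cc[3*j] != c[0] || cc[3*j+1] != c[1] || cc[3*j+2] != c[2]) continue;
          narrow_capsule_capsule(i, j);
        }
      }
    }
    // bead vs cylinders (all but the welded last one), bead vs plane
    int bead = -1;
    for (int i = nc; i < nb; ++i) if (stype[i] == 1) bead = i;
    if (bead >= 0) {
      for (int i = 0; i < nc - excl_window; ++i) narrow_capsule_sphere(i, bead);
      if (plane_enabled) {
        double z = pos[3*bead+2], R = radius[bead];
        if (z - R < 0) {
          Contact ct; ct.b1 = bead; ct.b2 = -1;
          ct.point[0] = pos[3*bead]; ct.point[1] = pos[3*bead+1];
          ct.point[2] = z - R;
          ct.normal[0] = 0; ct.normal[1] = 0; ct.normal[2] = 1;
          ct.depth = R - z; ct.key = (int64_t)bead * (nb + 2) + nb;
          contacts.push_back(ct);
        }
      }
    }
    // cylinders vs plane
    if (plane_enabled) {
      for (int i = first_plane_attached ? excl_window : 0; i < nc; ++i) {
        const double* R = &Rm[9*i];
        double hl = len[i] / 2, r = radius[i];
        double tz = R[8];   // z component of tangent
        double zlo = pos[3*i+2] - hl * std::fabs(tz) - r;
        if (zlo >= 0) continue;
        Contact ct; ct.b1 = i; ct.b2 = -1;
        double sgn = tz <= 0 ? 1.0 : -1.0;
        ct.point[0] = pos[3*i] + sgn * hl * R[2];
        ct.point[1] = pos[3*i+1] + sgn * hl * R[5];
        ct.point[2] = zlo;
        ct.normal[0] = 0; ct.normal[1] = 0; ct.normal[2] = 1;
        ct.depth = -zlo; ct.key = (int64_t)i * (nb + 2) + nb;
        contacts.push_back(ct);
      }
    }
    for (auto& ct : contacts) max_pen = std::max(max_pen, ct.depth);
  }

  void narrow_capsule_capsule(int i, int j) {
    double hl = len[i] / 2;
    const double* Ri = &Rm[9*i];
    const double* Rj = &Rm[9*j];
    double pi_[3], qi[3], pj[3], qj[3];
    for (int d = 0; d < 3; ++d) {
      double ti = Ri[3*d+2], tj = Rj[3*d+2];
      pi_[d] = pos[3*i+d] - hl * ti; qi[d] = pos[3*i+d] + hl * ti;
      pj[d] = pos[3*j+d] - (len[j]/2) * tj; qj[d] = pos[3*j+d] + (len[j]/2) * tj;
    }
    double c1[3], c2[3];
    double d = segseg(pi_, qi, pj, qj, c1, c2);
    double rsum = radius[i] + radius[j];
    if (d >= rsum) return;
    Contact ct; ct.b1 = i; ct.b2 = j;
    if (d > 1e-12) {
      for (int k = 0; k < 3; ++k) ct.normal[k] = (c1[k] - c2[k]) / d;
    } else {
      ct.normal[0] = 1; ct.normal[1] = 0; ct.normal[2] = 0;
    }
    for (int k = 0; k < 3; ++k) ct.point[k] = 0.5 * (c1[k] + c2[k]);
    ct.depth = rsum - d;
    ct.key = (int64_t)i * (nb + 2) + j;
    contacts.push_back(ct);
  }

  void narrow_capsule_sphere(int i, int bead) {
    double hl = len[i] / 2;
    const double* R = &Rm[9*i];
    double p[3], q[3];
    for (int d = 0; d < 3; ++d) {
      p[d] = pos[3*i+d] - hl * R[3*d+2];
      q[d] = pos[3*i+d] + hl * R[3*d+2];
    }
    double c1[3], c2[3];
    double dd = segseg(p, q, &pos[3*bead], &pos[3*bead], c1, c2);
    double rsum = radius[i] + radius[bead];
    if (dd >= rsum) return;
    Contact ct; ct.b1 = i; ct.b2 = bead;
    if (dd > 1e-12) {
      for (int k = 0; k < 3; ++k) ct.normal[k] = (c1[k] - pos[3*bead+k]) / dd;
    } else { ct.normal[0] = 0; ct.normal[1] = 0; ct.normal[2] = 1; }
    for (int k = 0; k < 3; ++k)
      ct.point[k] = pos[3*bead+k] + ct.normal[k] * (radius[bead] + (dd - rsum) / 2);
    ct.depth = rsum - dd;
    ct.key = (int64_t)i * (nb + 2) + bead;
    contacts.push_back(ct);
  }

  // ---- constraint rows ----

  inline void set_row(int r, int a, int b,
                      const double* jva, const double* jwa,
                      const double* jvb, const double* jwb,
                      double C, double vt, double lo) {
    rA[r] = a; rB[r] = b;
    for (int d = 0; d < 3; ++d) {
      Jva[3*r+d] = jva ? jva[d] : 0; Jwa[3*r+d] = jwa ? jwa[d] : 0;
      Jvb[3*r+d] = jvb ? jvb[d] : 0; Jwb[3*r+d] = jwb ? jwb[d] : 0;
    }
    Cv[r] = C; vtg[r] = vt; lo_[r] = lo;
  }

  void weld_error(int k, double* Cerr) {
    // axis-angle drift of q_a^-1 q_b from reference, world frame,
    // oriented so dC/dt = omega_a - omega_b
    double qa[4] = {1, 0, 0, 0};
    if (ja[k] >= 0) std::memcpy(qa, &quat[4*ja[k]], 4*sizeof(double));
    const double* qb = &quat[4*jb[k]];
    double t1[4], qerr[4];
    quat_mul(qa, &jqref[4*k], t1);
    double qbc[4] = { qb[0], -qb[1], -qb[2], -qb[3] };
    quat_mul(t1, qbc, qerr);
    if (qerr[0] < 0) for (int d = 0; d < 4; ++d) qerr[d] = -qerr[d];
    double s = std::sqrt(qerr[1]*qerr[1] + qerr[2]*qerr[2] + qerr[3]*qerr[3]);
    if (s < 1e-12) { Cerr[0] = Cerr[1] = Cerr[2] = 0; return; }
    double ang = 2 * std::atan2(s, qerr[0]);
    for (int d = 0; d < 3; ++d) Cerr[d] = ang * qerr[1+d] / s;
  }

  void assemble_rows() {
    int row = 0;
    cur_maxC = 0;
    const double I3[3][3] = {{1,0,0},{0,1,0},{0,0,1}};
    for (int k = 0; k < nj; ++k) {
      int a = ja[k], b = jb[k];
      double ra[3] = {0,0,0}, rb3[3] = {0,0,0}, pa[3], pb[3];
      if (a >= 0) {
        const double* R = &Rm[9*a];
        for (int d = 0; d < 3; ++d)
          ra[d] = R[3*d+0]*jaa[3*k] + R[3*d+1]*jaa[3*k+1] + R[3*d+2]*jaa[3*k+2];
        for (int d = 0; d < 3; ++d) pa[d] = pos[3*a+d] + ra[d];
      } else {
        for (int d = 0; d < 3; ++d) pa[d] = jaa[3*k+d];
      }
      {
        const double* R = &Rm[9*b];
        for (int d = 0; d < 3; ++d)
          rb3[d] = R[3*d+0]*jab[3*k] + R[3*d+1]*jab[3*k+1] + R[3*d+2]*jab[3*k+2];
        for (int d = 0; d < 3; ++d) pb[d] = pos[3*b+d] + rb3[d];
      }
      for (int d = 0; d < 3; ++d) lever_a[3*k+d] = ra[d];
      for (int d = 0; d < 3; ++d) lever_b[3*k+d] = rb3[d];
      for (int d = 0; d < 3; ++d) {
        // row: e_d . (v_a + w_a x r_a - v_b - w_b x r_b)
        double jwa_[3], jwb_[3], jvb_[3];
        // e x r terms: (w x r)_d = (skew(w) r)_d = -(skew(r) w)_d
        // J_w row for body a is (-skew(r_a))[d,]  = (r_a x e_d)
        double ed[3] = { I3[d][0], I3[d][1], I3[d][2] };
        cross(ra, ed, jwa_);
        cross(rb3, ed, jwb_);
        for (int t = 0; t < 3; ++t) { jwb_[t] = -jwb_[t]; jvb_[t] = -ed[t]; }
        double C = pa[d] - pb[d];
        cur_maxC = std::max(cur_maxC, std::fabs(C));
        set_row(row++, a, b, a >= 0 ? ed : nullptr, a >= 0 ? jwa_ : nullptr,
                jvb_, jwb_, C, 0.0, -INFINITY);
      }
      if (jtype[k] == 1) {
        double Ce[3]; weld_error(k, Ce);
        for (int d = 0; d < 3; ++d) {
          double ed[3] = { I3[d][0], I3[d][1], I3[d][2] };
          double med[3] = { -ed[0], -ed[1], -ed[2] };
          cur_maxC = std::max(cur_maxC, std::fabs(Ce[d]));
          set_row(row++, a, b, nullptr, a >= 0 ? ed : nullptr, nullptr, med,
                  Ce[d], 0.0, -INFINITY);
        }
      }
    }
    // bead clamp rows (appended to last group)
    if (clamp_mode != 0 && clamp_body >= 0) {
      int i = clamp_body;
      const double* R = &Rm[9*i];
      double b3[3] = { R[2], R[5], R[8] };      // bead z axis in world
      // tilt errors: C = (z_hat x b3) * (theta/sin(theta))
      double cz[3] = { -b3[1], b3[0], 0.0 };
      double sth = std::sqrt(std::max(cz[0]*cz[0] + cz[1]*cz[1], 0.0));
      double th = std::atan2(sth, b3[2]);
      double fac = sth > 1e-9 ? th / sth : 1.0;
      double ex[3] = {1,0,0}, ey[3] = {0,1,0}, ez[3] = {0,0,1};
      set_row(row++, i, -1, nullptr, ex, nullptr, nullptr,
              cz[0]*fac, 0.0, -INFINITY);
      set_row(row++, i, -1, nullptr, ey, nullptr, nullptr,
              cz[1]*fac, 0.0, -INFINITY);
      if (clamp_mode == 1) {
        set_row(row++, i, -1, nullptr, ez, nullptr, nullptr,
                psi - psi_target, psi_rate_now(), -INFINITY);
      }
    }
    // contacts (one row each, lambda >= 0)
    mrows = mperm + (int)contacts.size();
    ensure_row_capacity(mrows);
    for (size_t c = 0; c < contacts.size(); ++c) {
      const Contact& ct = contacts[c];
      int r = mperm + (int)c;
      double r1[3], r2[3] = {0,0,0};
      for (int d = 0; d < 3; ++d) r1[d] = ct.point[d] - pos[3*ct.b1+d];
      double jwa_[3], jwb_[3], jvb_[3] = {0,0,0};
      cross(r1, ct.normal, jwa_);
      // J_wa = r1 x n gives w . (r1 x n) = n . (w x r1)
      if (ct.b2 >= 0) {
        for (int d = 0; d < 3; ++d) r2[d] = ct.point[d] - pos[3*ct.b2+d];
        cross(r2, ct.normal, jwb_);
        for (int d = 0; d < 3; ++d) { jwb_[d] = -jwb_[d]; jvb_[d] = -ct.normal[d]; }
        set_row(r, ct.b1, ct.b2, ct.normal, jwa_, jvb_, jwb_,
                -ct.depth, 0.0, 0.0);
      } else {
        set_row(r, ct.b1, -1, ct.normal, jwa_, nullptr, nullptr,
                -ct.depth, 0.0, 0.0);
      }
      // contacts use their own erp through a scaled C (see rhs build)
    }
    max_C_run = std::max(max_C_run, cur_maxC);
  }

  double psi_rate_now() const {
    if (psi_rate == 0) return 0;
    double remaining = psi_cap - psi_target;
    if (psi_rate > 0 && remaining <= 0) return 0;
    if (psi_rate < 0 && remaining >= 0) return 0;
    return psi_rate;
  }

  // J_row . uf
  inline double row_dot_u(int r, const double* u) const {
    double s = 0;
    if (rA[r] >= 0) {
      const double* ua = u + 6*rA[r];
      s += dot3(&Jva[3*r], ua) + dot3(&Jwa[3*r], ua + 3);
    }
    if (rB[r] >= 0) {
      const double* ub = u + 6*rB[r];
      s += dot3(&Jvb[3*r], ub) + dot3(&Jwb[3*r], ub + 3);
    }
    return s;
  }

  // per-row W^-1 J^T blocks, computed once per step after row assembly
  void precompute_wj() {
    for (int r = 0; r < mrows; ++r) {
      if (rA[r] >= 0) {
        int i = rA[r];
        for (int d = 0; d < 3; ++d) wJa[6*r+d] = Jva[3*r+d] * invmass[i];
        iwinv_mul(i, &Jwa[3*r], &wJa[6*r+3]);
      }
      if (rB[r] >= 0) {
        int i = rB[r];
        for (int d = 0; d < 3; ++d) wJb[6*r+d] = Jvb[3*r+d] * invmass[i];
        iwinv_mul(i, &Jwb[3*r], &wJb[6*r+3]);
      }
    }
  }

  // A_{rs} = J_r W^-1 J_s^T over shared bodies (uses precomputed wJ)
  double rowdot(int r, int s) const {
    double out = 0;
    for (int side_r = 0; side_r < 2; ++side_r) {
      int br = side_r == 0 ? rA[r] : rB[r];
      if (br < 0) continue;
      const double* jv_r = side_r == 0 ? &Jva[3*r] : &Jvb[3*r];
      const double* jw_r = side_r == 0 ? &Jwa[3*r] : &Jwb[3*r];
      for (int side_s = 0; side_s < 2; ++side_s) {
        int bs = side_s == 0 ? rA[s] : rB[s];
        if (bs != br) continue;
        const double* w = side_s == 0 ? &wJa[6*s] : &wJb[6*s];
        out += dot3(jv_r, w) + dot3(jw_r, w + 3);
      }
    }
    return out;
  }

  std::vector<double> rhs;

  void build_rhs() {
    rhs.resize(mrows);
    for (int r = 0; r < mperm; ++r) {
      rhs[r] = (vtg[r] - (erp / dt) * Cv[r] - row_dot_u(r, uf.data())) / dt;
    }
    for (int r = mperm; r < mrows; ++r) {
      // contact push-out velocity, capped to avoid blow-ups on deep
      // initial overlaps (C = -depth)
      double push = std::min(-(contact_erp / dt) * Cv[r], max_push);
      rhs[r] = (vtg[r] + push - row_dot_u(r, uf.data())) / dt;
    }
  }

  // ---- tridiagonal factor/solve over permanent groups ----

  int G() const { return gstart.size(); }

  // out = skew(r1) * M * skew(r2)^T  (M symmetric 3x3, row-major)
  static inline void skew_M_skewT(const double* r1, const double* M,
                                  const double* r2, double* out) {
    double T[9];
    for (int c = 0; c < 3; ++c) {
      T[0*3+c] = -r1[2] * M[1*3+c] + r1[1] * M[2*3+c];
      T[1*3+c] =  r1[2] * M[0*3+c] - r1[0] * M[2*3+c];
      T[2*3+c] = -r1[1] * M[0*3+c] + r1[0] * M[1*3+c];
    }
    for (int i = 0; i < 3; ++i) {
      out[i*3+0] = -T[i*3+1] * r2[2] + T[i*3+2] * r2[1];
      out[i*3+1] =  T[i*3+0] * r2[2] - T[i*3+2] * r2[0];
      out[i*3+2] = -T[i*3+0] * r2[1] + T[i*3+1] * r2[0];
    }
  }

  // analytic diagonal block of a pure ball-joint group
  inline void ball_D(int g, double* Dg) const {
    int a = ja[g], b = jb[g];
    double K[9];
    double diag = (a >= 0 ? invmass[a] : 0.0) + invmass[b];
    for (int i = 0; i < 9; ++i) Dg[i] = 0.0;
    Dg[0] = Dg[4] = Dg[8] = diag;
    if (a >= 0) {
      skew_M_skewT(&lever_a[3*g], &Iwinv[9*a], &lever_a[3*g], K);
      for (int i = 0; i < 9; ++i) Dg[i] += K[i];
    }
    skew_M_skewT(&lever_b[3*g], &Iwinv[9*b], &lever_b[3*g], K);
    for (int i = 0; i < 9; ++i) Dg[i] += K[i];
  }

  // analytic coupling block between consecutive ball-joint groups sharing
  // body jb[g] == ja[g+1]
  inline void ball_E(int g, double* Eg) const {
    int s = jb[g];
    skew_M_skewT(&lever_b[3*g], &Iwinv[9*s], &lever_a[3*(g+1)], Eg);
    for (int i = 0; i < 9; ++i) Eg[i] = -Eg[i];
    Eg[0] -= invmass[s]; Eg[4] -= invmass[s]; Eg[8] -= invmass[s];
  }

  bool factor_tridiag() {
    int ng = G();
    double Dg[144], M[144];
    for (int g = 0; g < ng; ++g) {
      int s0 = gstart[g], n0 = gsize[g];
      if (grp_ball[g]) {
        ball_D(g, Dg);
      } else {
        for (int i = 0; i < n0; ++i)
          for (int j = 0; j < n0; ++j)
            Dg[i*n0+j] = i <= j ? rowdot(s0+i, s0+j) : 0.0;
        for (int i = 0; i < n0; ++i)
          for (int j = 0; j < i; ++j) Dg[i*n0+j] = Dg[j*n0+i];
      }
      for (int i = 0; i < n0; ++i) Dg[i*n0+i] += cfm / dt;
      if (g > 0) {
        // subtract E_{g-1}^T Dprev^-1 E_{g-1}
        int np = gsize[g-1];
        const double* E = &Eblk[(g-1)*144];       // np x n0
        // M = Dprev^-1 E : solve per column
        for (int c = 0; c < n0; ++c) {
          double col[12];
          for (int i = 0; i < np; ++i) col[i] = E[i*n0+c];
          chol_solve(np, &cholD[(g-1)*144], col);
          for (int i = 0; i < np; ++i) M[i*n0+c] = col[i];
        }
        for (int i = 0; i < n0; ++i)
          for (int j = 0; j < n0; ++j) {
            double s = 0;
            for (int k = 0; k < np; ++k) s += E[k*n0+i] * M[k*n0+j];
            Dg[i*n0+j] -= s;
          }
      }
      std::memcpy(&cholD[g*144], Dg, n0*n0*sizeof(double));
      if (!chol_small(n0, &cholD[g*144])) return false;
      if (g + 1 < ng) {
        int n1 = gsize[g+1], s1 = gstart[g+1];
        double* E = &Eblk[g*144];
        if (grp_ball[g] && grp_ball[g+1] && jb[g] == ja[g+1]) {
          ball_E(g, E);
        } else {
          for (int i = 0; i < n0; ++i)
            for (int j = 0; j < n1; ++j)
              E[i*n1+j] = rowdot(s0+i, s1+j);
        }
      }
    }
    return true;
  }

  // solve permanent-part system with factored blocks, x := A_perm^-1 x
  void tridiag_solve(double* x) const {
    int ng = G();
    if (ng == 0) return;
    // forward
    for (int g = 1; g < ng; ++g) {
      int np = gsize[g-1], n0 = gsize[g];
      double zp[12];
      std::memcpy(zp, x + gstart[g-1], np*sizeof(double));
      chol_solve(np, &cholD[(g-1)*144], zp);
      const double* E = &Eblk[(g-1)*144];
      for (int j = 0; j < n0; ++j) {
        double s = 0;
        for (int i = 0; i < np; ++i) s += E[i*n0+j] * zp[i];
        x[gstart[g]+j] -= s;
      }
    }
    // back
    int gl = ng - 1;
    chol_solve(gsize[gl], &cholD[gl*144], x + gstart[gl]);
    for (int g = ng - 2; g >= 0; --g) {
      int n0 = gsize[g], n1 = gsize[g+1];
      const double* E = &Eblk[g*144];
      double tmp[12];
      std::memcpy(tmp, x + gstart[g], n0*sizeof(double));
      for (int i = 0; i < n0; ++i) {
        double s = 0;
        for (int j = 0; j < n1; ++j) s += E[i*n1+j] * x[gstart[g+1]+j];
        tmp[i] -= s;
      }
      chol_solve(n0, &cholD[g*144], tmp);
      std::memcpy(x + gstart[g], tmp, n0*sizeof(double));
    }
  }

  // ---- SOR over all rows ----

  void apply_row_to_acc(int r, double dlam) {
    if (rA[r] >= 0) {
      double* a = &acc[6*rA[r]];
      const double* w = &wJa[6*r];
      for (int d = 0; d < 6; ++d) a[d] += dlam * w[d];
    }
    if (rB[r] >= 0) {
      double* a = &acc[6*rB[r]];
      const double* w = &wJb[6*r];
      for (int d = 0; d < 6; ++d) a[d] += dlam * w[d];
    }
  }

  double sor_violation() {
    double viol = 0, cfmdt = cfm / dt;
    for (int r = 0; r < mrows; ++r) {
      double res = rhs[r] - row_dot_u(r, acc.data()) - cfmdt * lam[r];
      if (lo_[r] == 0.0 && lam[r] <= 0.0) res = std::max(res, 0.0);
      viol = std::max(viol, std::fabs(res));
    }
    return viol * dt * dt;
  }

  bool solve_sor_engine() {
    double cfmdt = cfm / dt;
    std::fill(acc.begin(), acc.end(), 0.0);
    // warm start contacts from previous step
    for (int r = 0; r < mrows; ++r) {
      if (r >= mperm) {
        lam[r] = 0;
        int64_t key = contacts[r - mperm].key;
        for (auto& kv : warm_prev) if (kv.first == key) { lam[r] = kv.second; break; }
      } else lam[r] = 0;
      if (lam[r] != 0) apply_row_to_acc(r, lam[r]);
    }
    for (int r = 0; r < mrows; ++r) adiag[r] = rowdot(r, r) + cfmdt;
    for (int it = 0; it < sor_iter; ++it) {
      for (int r = 0; r < mrows; ++r) {
        double res = rhs[r] - row_dot_u(r, acc.data()) - cfmdt * lam[r];
        double nl = lam[r] + sor_omega * res / adiag[r];
        if (lo_[r] == 0.0 && nl < 0.0) nl = 0.0;
        double dl = nl - lam[r];
        if (dl != 0) { lam[r] = nl; apply_row_to_acc(r, dl); }
      }
      if ((it & 3) == 3) {
        cur_viol = sor_violation();
        if (cur_viol <= accept_tol) return true;
      }
    }
    cur_viol = sor_violation();
    return cur_viol <= accept_tol;
  }

  // ---- direct Schur solve (exact; contacts by active set) ----

  void solve_direct_engine() {
    int ncon = mrows - mperm;
    std::vector<double> rp(mperm);
    std::copy(rhs.begin(), rhs.begin() + mperm, rp.begin());
    tridiag_solve(rp.data());                     // A_jj^-1 rhs_j
    if (ncon == 0) {
      std::copy(rp.begin(), rp.end(), lam.begin());
      finish_lambda(true);
      return;
    }
    // columns of A_jc (mperm x ncon) and X = A_jj^-1 A_jc
    arma::mat B(mperm, ncon), X(mperm, ncon);
    arma::mat S(ncon, ncon);
    arma::vec rc(ncon);
    for (int c = 0; c < ncon; ++c) {
      int rc_row = mperm + c;
      for (int r = 0; r < mperm; ++r) B(r, c) = rowdot(r, rc_row);
      arma::vec col = B.col(c);
      tridiag_solve(col.memptr());
      X.col(c) = col;
      rc(c) = rhs[rc_row];
    }
    double cfmdt = cfm / dt;
    for (int c = 0; c < ncon; ++c) {
      for (int c2 = 0; c2 < ncon; ++c2)
        S(c, c2) = rowdot(mperm + c, mperm + c2) - arma::dot(B.col(c), X.col(c2));
      S(c, c) += cfmdt;
      rc(c) -= arma::dot(B.col(c), arma::vec(rp));
    }
    // active-set on lambda_c >= 0
    std::vector<bool> clamped(ncon, false);
    arma::vec lc(ncon, arma::fill::zeros);
    for (int pivot = 0; pivot < 3 * ncon + 10; ++pivot) {
      std::vector<int> free;
      for (int c = 0; c < ncon; ++c) if (!clamped[c]) free.push_back(c);
      lc.zeros();
      if (!free.empty()) {
        arma::uvec fidx(free.size());
        for (size_t i = 0; i < free.size(); ++i) fidx(i) = free[i];
        arma::mat Sf = S.submat(fidx, fidx);
        arma::vec rf = rc(fidx);
        arma::vec xf;
        if (!arma::solve(xf, Sf, rf, arma::solve_opts::likely_sympd)) {
          xf = arma::pinv(Sf) * rf;
        }
        for (size_t i = 0; i < free.size(); ++i) lc(free[i]) = xf(i);
      }
      arma::vec resid = S * lc - rc;
      bool changed = false;
      for (int c = 0; c < ncon; ++c) {
        if (!clamped[c] && lc(c) < -1e-12) { clamped[c] = true; changed = true; }
        else if (clamped[c] && resid(c) < -1e-12) { clamped[c] = false; changed = true; }
      }
      if (!changed) break;
    }
    for (int c = 0; c < ncon; ++c) lam[mperm + c] = std::max(lc(c), 0.0);
    // back-substitute joints: lambda_j = A_jj^-1 (rhs_j - A_jc lambda_c)
    arma::vec rj(mperm);
    for (int r = 0; r < mperm; ++r) rj(r) = rhs[r];
    rj -= B * lc;
    tridiag_solve(rj.memptr());
    for (int r = 0; r < mperm; ++r) lam[r] = rj(r);
    finish_lambda(true);
  }

  void finish_lambda(bool check) {
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int r = 0; r < mrows; ++r)
      if (lam[r] != 0) apply_row_to_acc(r, lam[r]);
    // the exact path solves to machine precision by construction; the
    // residual check is only informative when contacts were involved
    cur_viol = check ? sor_violation() : 0.0;
  }

  // ---- one full step ----

  void step(long step_idx) {
    update_frames();
    elastic_and_applied_forces();
    thermostat_forces();
    predict_velocities();
    detect_collisions();
    // advance turn-clamp target
    if (clamp_mode == 1) {
      double r = psi_rate_now();
      psi_target += r * dt;
      if (psi_rate > 0 && psi_target > psi_cap) psi_target = psi_cap;
      if (psi_rate < 0 && psi_target < psi_cap) psi_target = psi_cap;
    }
    assemble_rows();
    precompute_wj();
    build_rhs();
    bool have_contacts = !contacts.empty();
    if (mrows > 0) {
      if (!have_contacts && !force_direct) {
        if (!factor_tridiag())
          stop("constraint matrix not SPD at step %ld", step_idx);
        std::copy(rhs.begin(), rhs.begin() + mperm, lam.begin());
        tridiag_solve(lam.data());
        finish_lambda(false);
        cur_solver = 0;
      } else {
        if (!factor_tridiag())
          stop("constraint matrix not SPD at step %ld", step_idx);
        if (!force_direct && solve_sor_engine()) {
          cur_solver = 1; ++n_sor;
        } else {
          solve_direct_engine();
          cur_solver = 2; ++n_direct;
        }
      }
      // save warm-start multipliers
      warm_prev.clear();
      for (size_t c = 0; c < contacts.size(); ++c)
        warm_prev.push_back({contacts[c].key, lam[mperm + c]});
    }
    // velocity update and integration
    for (int i = 0; i < nb; ++i) {
      for (int d = 0; d < 3; ++d) {
        vel[3*i+d] = uf[6*i+d] + dt * acc[6*i+d];
        omg[3*i+d] = uf[6*i+3+d] + dt * acc[6*i+3+d];
        pos[3*i+d] += dt * vel[3*i+d];
      }
      // exponential map update; series branch for the (typical) small
      // per-step angle, with a first-order renormalization
      double a[3] = { omg[3*i]*dt/2, omg[3*i+1]*dt/2, omg[3*i+2]*dt/2 };
      double t2 = dot3(a, a), dq[4];
      if (t2 < 1e-6) {
        double s = 1 - t2/6;
        dq[0] = 1 - t2/2; dq[1] = s*a[0]; dq[2] = s*a[1]; dq[3] = s*a[2];
      } else {
        double th = std::sqrt(t2);
        double s = std::sin(th)/th;
        dq[0] = std::cos(th); dq[1] = s*a[0]; dq[2] = s*a[1]; dq[3] = s*a[2];
      }
      double qn[4];
      quat_mul(dq, &quat[4*i], qn);
      double n2 = qn[0]*qn[0]+qn[1]*qn[1]+qn[2]*qn[2]+qn[3]*qn[3];
      double corr = (std::fabs(n2 - 1.0) < 1e-4) ? (1.5 - 0.5 * n2)
                                                 : 1.0 / std::sqrt(n2);
      for (int d = 0; d < 4; ++d) quat[4*i+d] = qn[d] * corr;
    }
    if (clamp_body >= 0) psi += omg[3*clamp_body+2] * dt;
    time += dt;
  }

  // ---- observables ----

  double extension_z(int body, const double* local) const {
    const double* R = &Rm[9*body];
    return pos[3*body+2] + R[6]*local[0] + R[7]*local[1] + R[8]*local[2];
  }

  void chain_endpoints(double* p0, double* pe) const {
    const double* R0 = &Rm[0];
    double hl = len[0]/2;
    for (int d = 0; d < 3; ++d) p0[d] = pos[d] - hl * R0[3*d+2];
    int l = nc - 1;
    const double* Rl = &Rm[9*l];
    hl = len[l]/2;
    for (int d = 0; d < 3; ++d) pe[d] = pos[3*l+d] + hl * Rl[3*d+2];
  }

  double writhe() const {
    int np = nc + 1 + 2;
    std::vector<double> pts(3*np);
    double p0[3], pe[3];
    chain_endpoints(p0, pe);
    double H = 50.0 * nc * (nc > 0 ? len[0] : 1.0);
    pts[0] = p0[0]; pts[1] = p0[1]; pts[2] = p0[2] - H;
    pts[3] = p0[0]; pts[4] = p0[1]; pts[5] = p0[2];
    for (int i = 0; i < nc - 1; ++i) {
      // joint point between cylinder i and i+1: end of cylinder i
      const double* R = &Rm[9*i];
      double hl = len[i]/2;
      for (int d = 0; d < 3; ++d)
        pts[3*(i+2)+d] = pos[3*i+d] + hl * R[3*d+2];
    }
    pts[3*(nc+1)+0] = pe[0]; pts[3*(nc+1)+1] = pe[1]; pts[3*(nc+1)+2] = pe[2];
    pts[3*(nc+2)+0] = pe[0]; pts[3*(nc+2)+1] = pe[1]; pts[3*(nc+2)+2] = pe[2] + H;
    return polyline_writhe(pts.data(), np);
  }

  double twist_turns() const {
    double s = 0;
    for (int k = 0; k < ne; ++k) s += phi_cum[k];
    return s / (2*M_PI);
  }
};

// ------------------------ exported interface ------------------------------

// [[Rcpp::export]]
List cpp_run(List spec, double n_steps, int obs_stride, int traj_stride,
             int wr_stride, bool record_traj) {
  Engine E;
  E.init_from_spec(spec);
  long ns = (long)n_steps;
  long n_obs = ns / obs_stride + 1;
  int obs_cols = 13;
  NumericMatrix obs(n_obs, obs_cols);
  CharacterVector cn = CharacterVector::create(
    "step", "time", "E_kin", "ext", "e2e", "Tw", "Wr", "bead_psi", "sigma",
    "n_contacts", "max_depth", "max_C", "solver");
  colnames(obs) = cn;
  long n_traj = record_traj ? ns / traj_stride : 0;
  NumericVector tpos(record_traj ? n_traj * E.nb * 3 : 0);
  NumericVector tquat(record_traj ? n_traj * E.nb * 4 : 0);
  NumericVector ttime(record_traj ? n_traj : 0);
  int ext_body = as<int>(spec["ext_body"]);
  NumericVector extl = spec["ext_local"];
  double ext_local[3] = { extl[0], extl[1], extl[2] };
  double lk0 = as<double>(spec["lk0"]);

  long oi = 0, ti = 0, last_logged = -1;
  auto log_obs = [&](long stepno) {
    if (oi >= n_obs || stepno == last_logged) return;
    last_logged = stepno;
    E.update_frames();
    double p0[3], pe[3];
    E.chain_endpoints(p0, pe);
    double dd[3] = { pe[0]-p0[0], pe[1]-p0[1], pe[2]-p0[2] };
    obs(oi, 0) = (double)stepno;
    obs(oi, 1) = E.time;
    obs(oi, 2) = E.kinetic_energy();
    obs(oi, 3) = E.extension_z(ext_body, ext_local);
    obs(oi, 4) = norm3(dd);
    obs(oi, 5) = E.twist_turns();
    obs(oi, 6) = (wr_stride > 0 && (stepno % ((long)wr_stride * obs_stride)) == 0)
                 ? E.writhe() : NA_REAL;
    obs(oi, 7) = E.psi;
    obs(oi, 8) = lk0 > 0 ? E.psi / (2*M_PI*lk0) : 0.0;
    obs(oi, 9) = (double)E.contacts.size();
    double md = 0;
    for (auto& ct : E.contacts) md = std::max(md, ct.depth);
    obs(oi, 10) = md;
    obs(oi, 11) = E.cur_maxC;
    obs(oi, 12) = (double)E.cur_solver;
    ++oi;
  };

  log_obs(0);
  for (long s = 0; s < ns; ++s) {
    E.step(s);
    if (((s + 1) % obs_stride) == 0) log_obs(s + 1);
    if (record_traj && ((s + 1) % traj_stride) == 0 && ti < n_traj) {
      for (int i = 0; i < E.nb; ++i) {
        for (int d = 0; d < 3; ++d) tpos[ti*E.nb*3 + i*3 + d] = E.pos[3*i+d];
        for (int d = 0; d < 4; ++d) tquat[ti*E.nb*4 + i*4 + d] = E.quat[4*i+d];
      }
      ttime[ti] = E.time;
      ++ti;
    }
    if ((s & 0xFFFF) == 0xFFFF) Rcpp::checkUserInterrupt();
  }
  if (oi < n_obs) log_obs(ns);   // final row if strides did not align

  NumericMatrix P(E.nb, 3), V(E.nb, 3), Wm(E.nb, 3), Q(E.nb, 4);
  for (int i = 0; i < E.nb; ++i) {
    for (int d = 0; d < 3; ++d) {
      P(i, d) = E.pos[3*i+d]; V(i, d) = E.vel[3*i+d]; Wm(i, d) = E.omg[3*i+d];
    }
    for (int d = 0; d < 4; ++d) Q(i, d) = E.quat[4*i+d];
  }
  return List::create(
    _["obs"] = obs, _["n_obs"] = (double)oi,
    _["traj_pos"] = tpos, _["traj_quat"] = tquat, _["traj_time"] = ttime,
    _["n_frames"] = (double)ti,
    _["pos"] = P, _["quat"] = Q, _["vel"] = V, _["omg"] = Wm,
    _["phi_prev"] = NumericVector(E.phi_prev.begin(), E.phi_prev.end()),
    _["phi_cum"] = NumericVector(E.phi_cum.begin(), E.phi_cum.end()),
    _["psi"] = E.psi, _["psi_target"] = E.psi_target,
    _["time"] = E.time,
    _["diag"] = List::create(
      _["max_penetration"] = E.max_pen, _["max_C"] = E.max_C_run,
      _["n_sor"] = (double)E.n_sor, _["n_direct"] = (double)E.n_direct,
      _["last_violation"] = E.cur_viol)
  );
}

// [[Rcpp::export]]
List cpp_segseg(NumericVector p1, NumericVector q1,
                NumericVector p2, NumericVector q2) {
  double c1[3], c2[3];
  double d = segseg(p1.begin(), q1.begin(), p2.begin(), q2.begin(), c1, c2);
  return List::create(_["d"] = d,
                      _["c1"] = NumericVector(c1, c1+3),
                      _["c2"] = NumericVector(c2, c2+3));
}

// [[Rcpp::export]]
double cpp_polyline_writhe(NumericMatrix pts) {
  int np = pts.nrow();
  std::vector<double> p(3*np);
  for (int i = 0; i < np; ++i)
    for (int d = 0; d < 3; ++d) p[3*i+d] = pts(i, d);
  return polyline_writhe(p.data(), np);
}

// [[Rcpp::export]]
NumericVector cpp_block_tridiag_solve(List D, List E, NumericVector rhs) {
  int G = D.size();
  std::vector<int> sz(G), start(G);
  int m = 0;
  for (int g = 0; g < G; ++g) {
    NumericMatrix Dg = D[g];
    sz[g] = Dg.nrow(); start[g] = m; m += sz[g];
  }
  std::vector<double> chol_store(G*144), Eb(G*144), x(rhs.begin(), rhs.end());
  double Dg[144], M[144];
  for (int g = 0; g < G; ++g) {
    NumericMatrix Dm = D[g];
    int n0 = sz[g];
    for (int i = 0; i < n0; ++i)
      for (int j = 0; j < n0; ++j) Dg[i*n0+j] = Dm(i, j);
    if (g > 0) {
      int np = sz[g-1];
      const double* Ep = &Eb[(g-1)*144];
      for (int c = 0; c < n0; ++c) {
        double col[12];
        for (int i = 0; i < np; ++i) col[i] = Ep[i*n0+c];
        chol_solve(np, &chol_store[(g-1)*144], col);
        for (int i = 0; i < np; ++i) M[i*n0+c] = col[i];
      }
      for (int i = 0; i < n0; ++i)
        for (int j = 0; j < n0; ++j) {
          double s = 0;
          for (int k = 0; k < np; ++k) s += Ep[k*n0+i] * M[k*n0+j];
          Dg[i*n0+j] -= s;
        }
    }
    std::memcpy(&chol_store[g*144], Dg, n0*n0*sizeof(double));
    if (!chol_small(n0, &chol_store[g*144]))
      stop("cpp_block_tridiag_solve: block not SPD");
    if (g + 1 < G) {
      NumericMatrix Em = E[g];
      int n1 = sz[g+1];
      for (int i = 0; i < sz[g]; ++i)
        for (int j = 0; j < n1; ++j) Eb[g*144 + i*n1+j] = Em(i, j);
    }
  }
  for (int g = 1; g < G; ++g) {
    int np = sz[g-1], n0 = sz[g];
    double zp[12];
    std::memcpy(zp, &x[start[g-1]], np*sizeof(double));
    chol_solve(np, &chol_store[(g-1)*144], zp);
    const double* Ep = &Eb[(g-1)*144];
    for (int j = 0; j < n0; ++j) {
      double s = 0;
      for (int i = 0; i < np; ++i) s += Ep[i*n0+j] * zp[i];
      x[start[g]+j] -= s;
    }
  }
  int gl = G - 1;
  chol_solve(sz[gl], &chol_store[gl*144], &x[start[gl]]);
  for (int g = G - 2; g >= 0; --g) {
    int n0 = sz[g], n1 = sz[g+1];
    const double* Ep = &Eb[g*144];
    double tmp[12];
    std::memcpy(tmp, &x[start[g]], n0*sizeof(double));
    for (int i = 0; i < n0; ++i) {
      double s = 0;
      for (int j = 0; j < n1; ++j) s += Ep[i*n1+j] * x[start[g+1]+j];
      tmp[i] -= s;
    }
    chol_solve(n0, &chol_store[g*144], tmp);
    std::memcpy(&x[start[g]], tmp, n0*sizeof(double));
  }
  return NumericVector(x.begin(), x.end());
}

// [[Rcpp::export]]
NumericVector cpp_rng_normals(double seed, int n) {
  EngineRng r((uint64_t)seed);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = r.norm();
  return out;
}
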