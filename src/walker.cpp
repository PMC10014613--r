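// Core forward-dynamics engine for the planar 7-segment walker.
//
// Generalized coordinates (9 DOF, minimal coordinates):
//   q = (x_hip, y_hip, thH, thT_L, thS_L, thF_L, thT_R, thS_R, thF_R)
// All segment angles are absolute, counter-clockwise positive.
// Reference directions: HAT points up, thigh/shank point down, foot is flat
// (heel behind / toe in front of the ankle).  Joint angles are differences of
// segment angles: hip flexion = thT - thH, knee flexion = thT - thS,
// ankle dorsiflexion = thF - thS; all zero in the standing reference posture,
// where every muscle is at its optimum length.
//
// The monolithic ODE state is (q, qdot, u[12], v[12]) and is advanced with
// classical RK4.  Contact anchor points (horizontal spring reference of the
// heel/toe contacts) are discrete states updated once per full step.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// small dense SPD solve (9x9 Cholesky); returns false if not positive-definite
static bool cholSolve9(double A[9][9], const double b[9], double x[9]) {
  double L[9][9];
  for (int i = 0; i < 9; ++i)
    for (int j = 0; j < 9; ++j) L[i][j] = 0.0;
  for (int j = 0; j < 9; ++j) {
    double d = A[j][j];
    for (int k = 0; k < j; ++k) d -= L[j][k] * L[j][k];
    if (!(d > 1e-12) || !std::isfinite(d)) return false;
    const double Ljj = std::sqrt(d);
    L[j][j] = Ljj;
    for (int i = j + 1; i < 9; ++i) {
      double s = A[i][j];
      for (int k = 0; k < j; ++k) s -= L[i][k] * L[j][k];
      L[i][j] = s / Ljj;
    }
  }
  double y[9];
  for (int i = 0; i < 9; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= L[i][k] * y[k];
    y[i] = s / L[i][i];
  }
  for (int i = 8; i >= 0; --i) {
    double s = y[i];
    for (int k = i + 1; k < 9; ++k) s -= L[k][i] * x[k];
    x[i] = s / L[i][i];
  }
  return true;
}

// ---------------------------------------------------------------------------
struct Body {
  double mH, IH, cH;            // HAT mass, inertia, COM offset above hip
  double lT, lS;                // thigh / shank lengths (shared L/R)
  double mT[2], IT[2], cT;      // thigh mass/inertia per side, COM offset
  double mS[2], IS[2], cS;      // shank
  double mF[2], IF[2];          // foot
  double fhx, ftx, fh;          // heel offset behind ankle, toe ahead, sole depth
  double fcx, fcz;              // foot COM local offset (fcx forward, fcz down)
  double bHip, bKnee, bAnk;     // joint viscosities (Nms/rad)
  double romHip[2], romKnee[2], romAnk[2];
  double lockK, lockC;          // one-sided range-of-motion lock spring/damper
  double kh, ch, kv, cv;        // ground contact coefficients
  int prosSide;                 // -1 none, 0 left, 1 right
  double prosAnkK;              // prosthetic ankle passive stiffness (Nm/rad)
  double g;
  double Mtot;
};

static Body parseBody(const List& b) {
  Body B;
  NumericVector mass = b["mass"];     // HAT, thighL, shankL, footL, thighR, shankR, footR
  NumericVector inertia = b["inertia"];
  B.mH = mass[0]; B.mT[0] = mass[1]; B.mS[0] = mass[2]; B.mF[0] = mass[3];
  B.mT[1] = mass[4]; B.mS[1] = mass[5]; B.mF[1] = mass[6];
  B.IH = inertia[0]; B.IT[0] = inertia[1]; B.IS[0] = inertia[2]; B.IF[0] = inertia[3];
  B.IT[1] = inertia[4]; B.IS[1] = inertia[5]; B.IF[1] = inertia[6];
  B.cH = as<double>(b["com_hat"]);
  B.lT = as<double>(b["l_thigh"]); B.cT = as<double>(b["com_thigh"]);
  B.lS = as<double>(b["l_shank"]); B.cS = as<double>(b["com_shank"]);
  NumericVector fg = b["foot_geom"];  // heel_x, toe_x, height, com_x, com_z
  B.fhx = fg[0]; B.ftx = fg[1]; B.fh = fg[2]; B.fcx = fg[3]; B.fcz = fg[4];
  NumericVector visc = b["joint_viscosity"]; // hip, knee, ankle
  B.bHip = visc[0]; B.bKnee = visc[1]; B.bAnk = visc[2];
  NumericVector rh = b["rom_hip"], rk = b["rom_knee"], ra = b["rom_ankle"];
  B.romHip[0] = rh[0]; B.romHip[1] = rh[1];
  B.romKnee[0] = rk[0]; B.romKnee[1] = rk[1];
  B.romAnk[0] = ra[0]; B.romAnk[1] = ra[1];
  NumericVector lock = b["lock"];
  B.lockK = lock[0]; B.lockC = lock[1];
  NumericVector cc = b["contact"];    // kh, ch, kv, cv
  B.kh = cc[0]; B.ch = cc[1]; B.kv = cc[2]; B.cv = cc[3];
  B.prosSide = as<int>(b["pros_side"]);
  B.prosAnkK = as<double>(b["pros_ankle_k"]);
  B.g = as<double>(b["g"]);
  B.Mtot = B.mH;
  for (int s = 0; s < 2; ++s) B.Mtot += B.mT[s] + B.mS[s] + B.mF[s];
  return B;
}

struct Ctrl {
  double tau[12], taup[12];
  double beta, u0;
  double W[12][12];
  double wfeed[2][16];
  double wpos[23];
  double wa[18][12];
  double fv_sign;
  double grf_thresh;
};

static Ctrl parseCtrl(const List& c) {
  Ctrl C;
  NumericVector tau = c["tau"], taup = c["taup"];
  for (int i = 0; i < 12; ++i) { C.tau[i] = tau[i]; C.taup[i] = taup[i]; }
  C.beta = as<double>(c["beta"]);
  C.u0 = as<double>(c["u0"]);
  NumericMatrix W = c["w_cpg"];
  for (int i = 0; i < 12; ++i) for (int j = 0; j < 12; ++j) C.W[i][j] = W(i, j);
  NumericMatrix wf = c["w_feed"];
  for (int s = 0; s < 2; ++s) for (int k = 0; k < 16; ++k) C.wfeed[s][k] = wf(s, k);
  NumericVector wp = c["w_pos"];
  for (int k = 0; k < 23; ++k) C.wpos[k] = wp[k];
  NumericMatrix wa = c["w_alpha"];
  for (int m = 0; m < 18; ++m) for (int i = 0; i < 12; ++i) C.wa[m][i] = wa(m, i);
  C.fv_sign = as<double>(c["fv_sign"]);
  C.grf_thresh = as<double>(c["grf_thresh"]);
  return C;
}

// muscle matrix columns
enum { MC_SIDE = 0, MC_FCE, MC_LBAR, MC_LDBAR, MC_CPD, MC_KPE,
       MC_RHIP, MC_RKNEE, MC_RANK, MC_ACTIVE, MC_JOINT, MC_ROLE, MC_DM };

// ---------------------------------------------------------------------------
// elementary muscle / contact / joint kernels (single source of truth)

static inline double flGain(double xi) {
  double k = 0.32 + 0.71 * std::exp(-1.112 * (xi - 1.0)) * std::sin(3.722 * (xi - 0.656));
  return k > 0.0 ? k : 0.0;
}

static inline double fvGain(double eta) {
  return 1.0 + std::tanh(3.0 * eta);
}

static inline void hillTension(double fce, double lbar, double ldbar, double cpd,
                               double kpe, double L, double Ldot, double alpha,
                               double fv_sign, double out[4]) {
  const double xi = L / lbar;
  const double eta = fv_sign * Ldot / ldbar;
  const double Fce = fce * flGain(xi) * fvGain(eta) * alpha;
  const double Fpd = cpd * Ldot;
  const double Fpe = (L > lbar) ? kpe * (std::exp(15.0 * (L - lbar)) - 1.0) : 0.0;
  out[0] = Fce + Fpd + Fpe; out[1] = Fce; out[2] = Fpd; out[3] = Fpe;
}

// py: contact point height (negative = penetration); dispx: horizontal
// displacement from the touchdown anchor.  Vertical force is floored at zero
// (no adhesion); the horizontal spring-damper acts only while loaded.
static inline void contactForce(double py, double vx, double vy, double dispx,
                                double kh, double ch, double kv, double cv,
                                double out[2]) {
  double fx = 0.0, fy = 0.0;
  if (py < 0.0) {
    fy = kv * (-py) + cv * (-vy);
    if (fy < 0.0) fy = 0.0;
    if (fy > 0.0) fx = -kh * dispx - ch * vx;
  }
  out[0] = fx; out[1] = fy;
}

static inline double jointPassive(double th, double thd, double visc,
                                  double lo, double hi, double lockK,
                                  double lockC, double prosK) {
  double tau = -visc * thd;
  if (th < lo) tau += lockK * (lo - th) - lockC * thd;
  else if (th > hi) tau += -lockK * (th - hi) - lockC * thd;
  tau += -prosK * th;  // prosthetic ankle: stiff elastic return to neutral
  return tau;
}

// ---------------------------------------------------------------------------
// rigid-body dynamics: M(q) qdd = Q(q, qd, torques, forces) - c(q, qd)
// tauJ[side][hip,knee,ankle] are net joint torques; F[4][2] are world forces at
// heel_L, toe_L, heel_R, toe_R.
static bool eomCore(const Body& B, const double* q, const double* qd,
                    const double tauJ[2][3], const double F[4][2], double qdd[9]) {
  double M[9][9] = {{0.0}};
  double Q[9] = {0.0};

  const double thH = q[2], wH = qd[2];
  const double sinH = std::sin(thH), cosH = std::cos(thH);

  // HAT: com = hip + cH * (-sin, cos); d' = cH*(-cos, -sin); d'' = cH*(sin, -cos)
  M[0][0] = B.Mtot; M[1][1] = B.Mtot;
  {
    const double d1x = -B.cH * cosH, d1y = -B.cH * sinH;
    M[0][2] += B.mH * d1x; M[1][2] += B.mH * d1y;
    M[2][2] += B.mH * B.cH * B.cH + B.IH;
    // bias: a = d'' * wH^2
    const double ax = B.cH * sinH * wH * wH, ay = -B.cH * cosH * wH * wH;
    Q[0] -= B.mH * ax; Q[1] -= B.mH * ay;
    Q[2] -= B.mH * (d1x * ax + d1y * ay);
    // gravity on HAT com
    Q[1] -= B.mH * B.g;
    Q[2] -= B.mH * B.g * d1y;
  }
  Q[1] -= (B.Mtot - B.mH) * B.g;  // gravity y-components of leg segments

  for (int s = 0; s < 2; ++s) {
    const int iT = 3 + 3 * s, iS = iT + 1, iF = iT + 2;
    const double tT = q[iT], tS = q[iS], tF = q[iF];
    const double wT = qd[iT], wS = qd[iS], wF = qd[iF];
    const double sT = std::sin(tT), cT = std::cos(tT);
    const double sS = std::sin(tS), cS_ = std::cos(tS);
    const double sF = std::sin(tF), cF = std::cos(tF);

    // chain direction derivatives (unit): leg link term a*(sin,-cos):
    //   d' = a*(cos, sin); d'' = a*(-sin, cos)
    // thigh com
    {
      const double a = B.cT;
      M[0][iT] += B.mT[s] * a * cT; M[1][iT] += B.mT[s] * a * sT;
      M[iT][iT] += B.mT[s] * a * a + B.IT[s];
      const double ax = a * (-sT) * wT * wT, ay = a * cT * wT * wT;
      Q[0] -= B.mT[s] * ax; Q[1] -= B.mT[s] * ay;
      Q[iT] -= B.mT[s] * (a * cT * ax + a * sT * ay);
      Q[iT] -= B.mT[s] * B.g * (a * sT);
    }
    // shank com: terms lT (thigh) + cS (shank)
    {
      const double a1 = B.lT, a2 = B.cS;
      const double m = B.mS[s];
      M[0][iT] += m * a1 * cT; M[1][iT] += m * a1 * sT;
      M[0][iS] += m * a2 * cS_; M[1][iS] += m * a2 * sS;
      M[iT][iT] += m * a1 * a1;
      M[iS][iS] += m * a2 * a2 + B.IS[s];
      M[iT][iS] += m * a1 * a2 * (cT * cS_ + sT * sS);
      const double ax = a1 * (-sT) * wT * wT + a2 * (-sS) * wS * wS;
      const double ay = a1 * cT * wT * wT + a2 * cS_ * wS * wS;
      Q[0] -= m * ax; Q[1] -= m * ay;
      Q[iT] -= m * (a1 * cT * ax + a1 * sT * ay);
      Q[iS] -= m * (a2 * cS_ * ax + a2 * sS * ay);
      Q[iT] -= m * B.g * a1 * sT;
      Q[iS] -= m * B.g * a2 * sS;
    }
    // foot com: terms lT + lS + R(tF) * pc, pc = (fcx, -fcz)
    {
      const double m = B.mF[s];
      const double pcx = B.fcx, pcy = -B.fcz;
      // R'(tF) pc
      const double ux = -pcx * sF - pcy * cF, uy = pcx * cF - pcy * sF;
      // R(tF) pc (for d'' = -R pc)
      const double rx = pcx * cF - pcy * sF, ry = pcx * sF + pcy * cF;
      M[0][iT] += m * B.lT * cT; M[1][iT] += m * B.lT * sT;
      M[0][iS] += m * B.lS * cS_; M[1][iS] += m * B.lS * sS;
      M[0][iF] += m * ux; M[1][iF] += m * uy;
      M[iT][iT] += m * B.lT * B.lT;
      M[iS][iS] += m * B.lS * B.lS;
      M[iF][iF] += m * (pcx * pcx + pcy * pcy) + B.IF[s];
      M[iT][iS] += m * B.lT * B.lS * (cT * cS_ + sT * sS);
      M[iT][iF] += m * B.lT * (cT * ux + sT * uy);
      M[iS][iF] += m * B.lS * (cS_ * ux + sS * uy);
      const double ax = B.lT * (-sT) * wT * wT + B.lS * (-sS) * wS * wS - rx * wF * wF;
      const double ay = B.lT * cT * wT * wT + B.lS * cS_ * wS * wS - ry * wF * wF;
      Q[0] -= m * ax; Q[1] -= m * ay;
      Q[iT] -= m * (B.lT * cT * ax + B.lT * sT * ay);
      Q[iS] -= m * (B.lS * cS_ * ax + B.lS * sS * ay);
      Q[iF] -= m * (ux * ax + uy * ay);
      Q[iT] -= m * B.g * B.lT * sT;
      Q[iS] -= m * B.g * B.lS * sS;
      Q[iF] -= m * B.g * uy;
    }
    // contact forces at heel (local (-fhx,-fh)) and toe (local (ftx,-fh))
    for (int p = 0; p < 2; ++p) {
      const double plx = (p == 0) ? -B.fhx : B.ftx;
      const double ply = -B.fh;
      const double fx = F[2 * s + p][0], fy = F[2 * s + p][1];
      if (fx == 0.0 && fy == 0.0) continue;
      const double ux = -plx * sF - ply * cF, uy = plx * cF - ply * sF;
      Q[0] += fx; Q[1] += fy;
      Q[iT] += B.lT * (cT * fx + sT * fy);
      Q[iS] += B.lS * (cS_ * fx + sS * fy);
      Q[iF] += ux * fx + uy * fy;
    }
    // joint torques: hip (thT - thH), knee (thT - thS), ankle (thF - thS)
    Q[iT] += tauJ[s][0] + tauJ[s][1];
    Q[2]  -= tauJ[s][0];
    Q[iS] -= tauJ[s][1] + tauJ[s][2];
    Q[iF] += tauJ[s][2];
  }

  // symmetrize
  for (int i = 0; i < 9; ++i)
    for (int j = i + 1; j < 9; ++j) M[j][i] = M[i][j];

  return cholSolve9(M, Q, qdd);
}

// ---------------------------------------------------------------------------
// sensory feedback: 16 weighted slots per leg -> 12 CPG feed terms.
// Per-leg sensors: thigh (ipsi/contra), shank, foot, HAT segment angles and
// body-weight-normalized contact-gated vertical GRFs (ipsi/contra).
// Unit order within a leg: hipF, hipE, kneeF, kneeE, ankleF, ankleE.
static void feedCore(const double thSeg[7], const double grf[2],
                     const double wfeed[2][16], double bw, double thresh,
                     double feed[12]) {
  for (int i = 0; i < 12; ++i) feed[i] = 0.0;
  for (int lg = 0; lg < 2; ++lg) {
    const int cg = 1 - lg;
    const double s0 = thSeg[1 + 3 * lg];           // ipsi thigh
    const double s1 = thSeg[1 + 3 * cg];           // contra thigh
    const double s2 = thSeg[2 + 3 * lg];           // ipsi shank
    const double s3 = thSeg[3 + 3 * lg];           // ipsi foot
    const double s4 = thSeg[0];                    // HAT
    const double s5 = (grf[lg] > thresh) ? grf[lg] / bw : 0.0;
    const double s6 = (grf[cg] > thresh) ? grf[cg] / bw : 0.0;
    const double* w = wfeed[lg];
    const int b = 6 * lg;
    feed[b + 0] += w[0] * s0 + w[2] * s1 + w[4] * s4 + w[6] * s5;   // hipF
    feed[b + 1] += w[1] * s0 + w[3] * s1 + w[5] * s4 + w[7] * s5;   // hipE
    feed[b + 2] += w[8] * s2 + w[10] * s5;                          // kneeF
    feed[b + 3] += w[9] * s2 + w[11] * s5;                          // kneeE
    feed[b + 4] += w[12] * s3 + w[14] * s5;                         // ankleF
    feed[b + 5] += w[13] * s3 + w[15] * s6;                         // ankleE
  }
}

// posture reflex: stance-gated PD corrections on HAT pitch and the stance
// leg's joint angles, distributed to muscles.  Strictly linear in the 23
// coefficients (pure output weights on fixed, role-signed error features that
// all vanish in the reference posture).  w_pos layout:
//  [0..8]   proportional gain per muscle group (GM, IL, BFL, RF, BFS, VA,
//           GC, SO, TA) acting on the group's primary-joint angle error
//  [9..17]  derivative gain per muscle group on the primary-joint rate
//  [18,19]  HAT pitch P and D -> hip muscle groups
//  [20,21]  HAT pitch P and D -> knee muscle groups
//  [22]     HAT pitch P -> ankle muscle groups
static void postureCore(const double jAng[2][3], const double jRate[2][3],
                        double thH, double thHd, const double grf[2],
                        const double* wp, const NumericMatrix& P,
                        double bw, double thresh, double Pm[18]) {
  (void)bw;
  const int n = P.nrow();
  for (int m = 0; m < n; ++m) {
    const int s = (int)P(m, MC_SIDE);
    if (grf[s] <= thresh) { Pm[m] = 0.0; continue; }
    const int j = (int)P(m, MC_JOINT);
    const double role = P(m, MC_ROLE);
    const int dm = (int)P(m, MC_DM);
    double val = wp[dm] * jAng[s][j] + wp[9 + dm] * jRate[s][j];
    if (j == 0) val += wp[18] * thH + wp[19] * thHd;
    else if (j == 1) val += wp[20] * thH + wp[21] * thHd;
    else val += wp[22] * thH;
    Pm[m] = role * val;
  }
}

static inline double motoneuron(double drive) {
  double a = 2.0 / (1.0 + std::exp(-0.25 * drive)) - 1.0;
  if (a < 0.0) a = 0.0;
  if (a > 1.0) a = 1.0;
  return a;
}

// ---------------------------------------------------------------------------
// full dynamics evaluation at one state

struct DynOut {
  double qdd[9], ud[12], vd[12];
  double alpha[18], F[18], Edot[18];
  double grf[2], grfx[2];
  double pts[4][4];  // heel_L, toe_L, heel_R, toe_R : x, y, vx, vy
  bool ok;
};

// muscle energetics coefficients (activation/maintenance heat rate per unit
// F.L, shortening heat fraction); documented in the package vignette
static const double EN_ACT = 0.06;    // 1/s
static const double EN_SHORT = 0.25;  // dimensionless

static void contactPoints(const Body& B, const double* s, double pts[4][4]) {
  const double x = s[0], y = s[1], vx = s[9], vy = s[10];
  for (int sd = 0; sd < 2; ++sd) {
    const int iT = 3 + 3 * sd, iS = iT + 1, iF = iT + 2;
    const double tT = s[iT], tS = s[iS], tF = s[iF];
    const double wT = s[9 + iT], wS = s[9 + iS], wF = s[9 + iF];
    const double sT = std::sin(tT), cT = std::cos(tT);
    const double sS = std::sin(tS), cS_ = std::cos(tS);
    const double sF = std::sin(tF), cF = std::cos(tF);
    const double ax = x + B.lT * sT + B.lS * sS;
    const double ay = y - B.lT * cT - B.lS * cS_;
    const double avx = vx + B.lT * cT * wT + B.lS * cS_ * wS;
    const double avy = vy + B.lT * sT * wT + B.lS * sS * wS;
    for (int p = 0; p < 2; ++p) {
      const double plx = (p == 0) ? -B.fhx : B.ftx;
      const double ply = -B.fh;
      pts[2 * sd + p][0] = ax + plx * cF - ply * sF;
      pts[2 * sd + p][1] = ay + plx * sF + ply * cF;
      pts[2 * sd + p][2] = avx + wF * (-plx * sF - ply * cF);
      pts[2 * sd + p][3] = avy + wF * (plx * cF - ply * sF);
    }
  }
}

static void evalDyn(const Body& B, const NumericMatrix& P, const Ctrl& C,
                    const double* s, const double anchorX[4], const int active[4],
                    bool ground, bool ctrlOn, DynOut& o) {
  o.ok = true;
  const double* q = s;
  const double* qd = s + 9;
  const double* u = s + 18;
  const double* v = s + 30;

  // contact
  contactPoints(B, s, o.pts);
  double F[4][2] = {{0.0, 0.0}, {0.0, 0.0}, {0.0, 0.0}, {0.0, 0.0}};
  o.grf[0] = o.grf[1] = o.grfx[0] = o.grfx[1] = 0.0;
  if (ground) {
    for (int p = 0; p < 4; ++p) {
      const double dispx = active[p] ? (o.pts[p][0] - anchorX[p]) : 0.0;
      double fo[2];
      contactForce(o.pts[p][1], o.pts[p][2], o.pts[p][3], dispx,
                   B.kh, B.ch, B.kv, B.cv, fo);
      F[p][0] = fo[0]; F[p][1] = fo[1];
      o.grfx[p / 2] += fo[0];
      o.grf[p / 2] += fo[1];
    }
  }

  // joint angles & rates
  double jAng[2][3], jRate[2][3];
  for (int sd = 0; sd < 2; ++sd) {
    const int iT = 3 + 3 * sd, iS = iT + 1, iF = iT + 2;
    jAng[sd][0] = q[iT] - q[2];  jRate[sd][0] = qd[iT] - qd[2];
    jAng[sd][1] = q[iT] - q[iS]; jRate[sd][1] = qd[iT] - qd[iS];
    jAng[sd][2] = q[iF] - q[iS]; jRate[sd][2] = qd[iF] - qd[iS];
  }

  // passive joint moments
  double tauJ[2][3];
  for (int sd = 0; sd < 2; ++sd) {
    const double pk = (B.prosSide == sd) ? B.prosAnkK : 0.0;
    tauJ[sd][0] = jointPassive(jAng[sd][0], jRate[sd][0], B.bHip,
                               B.romHip[0], B.romHip[1], B.lockK, B.lockC, 0.0);
    tauJ[sd][1] = jointPassive(jAng[sd][1], jRate[sd][1], B.bKnee,
                               B.romKnee[0], B.romKnee[1], B.lockK, B.lockC, 0.0);
    tauJ[sd][2] = jointPassive(jAng[sd][2], jRate[sd][2], B.bAnk,
                               B.romAnk[0], B.romAnk[1], B.lockK, B.lockC, pk);
  }

  // neural controller
  double y[12], feed[12], Pm[18];
  for (int i = 0; i < 12; ++i) y[i] = u[i] > 0.0 ? u[i] : 0.0;
  const double bw = B.Mtot * B.g;
  if (ctrlOn) {
    const double thSeg[7] = {q[2], q[3], q[4], q[5], q[6], q[7], q[8]};
    feedCore(thSeg, o.grf, C.wfeed, bw, C.grf_thresh, feed);
    postureCore(jAng, jRate, q[2], qd[2], o.grf, C.wpos, P, bw, C.grf_thresh, Pm);
    for (int m = 0; m < 18; ++m) {
      if (P(m, MC_ACTIVE) <= 0.0) { o.alpha[m] = 0.0; continue; }
      double drive = Pm[m];
      for (int i = 0; i < 12; ++i) drive += C.wa[m][i] * y[i];
      o.alpha[m] = motoneuron(drive);
    }
  } else {
    for (int i = 0; i < 12; ++i) feed[i] = 0.0;
    for (int m = 0; m < 18; ++m) o.alpha[m] = 0.0;
  }

  // muscles (the whole apparatus, including the passive elements, is absent
  // in skeleton-only runs with the controller disabled)
  for (int m = 0; m < 18; ++m) {
    if (!ctrlOn || P(m, MC_ACTIVE) <= 0.0) { o.F[m] = 0.0; o.Edot[m] = 0.0; continue; }
    const int sd = (int)P(m, MC_SIDE);
    const double rh = P(m, MC_RHIP), rk = P(m, MC_RKNEE), ra = P(m, MC_RANK);
    const double lbar = P(m, MC_LBAR);
    const double L = lbar + rh * jAng[sd][0] + rk * jAng[sd][1] + ra * jAng[sd][2];
    const double Ldot = rh * jRate[sd][0] + rk * jRate[sd][1] + ra * jRate[sd][2];
    double ft[4];
    hillTension(P(m, MC_FCE), lbar, P(m, MC_LDBAR), P(m, MC_CPD), P(m, MC_KPE),
                L, Ldot, o.alpha[m], C.fv_sign, ft);
    o.F[m] = ft[0];
    tauJ[sd][0] -= rh * ft[0];
    tauJ[sd][1] -= rk * ft[0];
    tauJ[sd][2] -= ra * ft[0];
    // energetics: activation/maintenance + shortening heat + positive CE work
    double e = EN_ACT * P(m, MC_FCE) * lbar * o.alpha[m];
    const double vshort = Ldot < 0.0 ? -Ldot : 0.0;
    e += EN_SHORT * P(m, MC_FCE) * o.alpha[m] * vshort;
    e += ft[1] * vshort;  // CE force doing positive work while shortening
    o.Edot[m] = e;
  }

  o.ok = eomCore(B, q, qd, tauJ, F, o.qdd);

  // CPG derivatives
  for (int i = 0; i < 12; ++i) {
    double syn = 0.0;
    for (int j = 0; j < 12; ++j) syn += C.W[i][j] * y[j];
    o.ud[i] = (-u[i] + syn - C.beta * v[i] + C.u0 + feed[i]) / C.tau[i];
    o.vd[i] = (-v[i] + y[i]) / C.taup[i];
  }
}

// ---------------------------------------------------------------------------
// exported kernels

// [[Rcpp::export]]
double flGainC(double xi) { return flGain(xi); }

// [[Rcpp::export]]
double fvGainC(double eta) { return fvGain(eta); }

// [[Rcpp::export]]
NumericVector hillTensionC(double fce, double lbar, double ldbar, double cpd,
                           double kpe, double L, double Ldot, double alpha,
                           double fv_sign) {
  double out[4];
  hillTension(fce, lbar, ldbar, cpd, kpe, L, Ldot, alpha, fv_sign, out);
  return NumericVector::create(_["F"] = out[0], _["F_ce"] = out[1],
                               _["F_pd"] = out[2], _["F_pe"] = out[3]);
}

// [[Rcpp::export]]
NumericVector contactForceC(double py, double vx, double vy, double dispx,
                            double kh, double ch, double kv, double cv) {
  double out[2];
  contactForce(py, vx, vy, dispx, kh, ch, kv, cv, out);
  return NumericVector::create(_["fx"] = out[0], _["fy"] = out[1]);
}

// [[Rcpp::export]]
double jointPassiveMomentC(double th, double thd, double visc, double lo,
                           double hi, double lockK, double lockC, double prosK) {
  return jointPassive(th, thd, visc, lo, hi, lockK, lockC, prosK);
}

// [[Rcpp::export]]
NumericVector eomC(List body, NumericVector q, NumericVector qd,
                   NumericVector tau6, NumericMatrix extF) {
  Body B = parseBody(body);
  double tauJ[2][3], F[4][2], qdd[9];
  for (int s = 0; s < 2; ++s)
    for (int j = 0; j < 3; ++j) tauJ[s][j] = tau6[3 * s + j];
  for (int p = 0; p < 4; ++p) { F[p][0] = extF(p, 0); F[p][1] = extF(p, 1); }
  if (!eomCore(B, q.begin(), qd.begin(), tauJ, F, qdd))
    stop("singular or non-positive-definite mass matrix: invalid inertia configuration");
  NumericVector out(9);
  for (int i = 0; i < 9; ++i) out[i] = qdd[i];
  return out;
}

// [[Rcpp::export]]
NumericMatrix bodyPointsC(List body, NumericVector q, NumericVector qd) {
  Body B = parseBody(body);
  NumericMatrix out(17, 4);
  double s[18];
  for (int i = 0; i < 9; ++i) { s[i] = q[i]; s[9 + i] = qd[i]; }
  const double x = q[0], y = q[1], vx = qd[0], vy = qd[1];
  const double thH = q[2], wH = qd[2];
  // 0 hip
  out(0, 0) = x; out(0, 1) = y; out(0, 2) = vx; out(0, 3) = vy;
  double pts[4][4];
  contactPoints(B, s, pts);
  double comx = 0.0, comy = 0.0, comvx = 0.0, comvy = 0.0;
  // 9 comHAT
  out(9, 0) = x - B.cH * std::sin(thH);
  out(9, 1) = y + B.cH * std::cos(thH);
  out(9, 2) = vx - B.cH * std::cos(thH) * wH;
  out(9, 3) = vy - B.cH * std::sin(thH) * wH;
  comx += B.mH * out(9, 0); comy += B.mH * out(9, 1);
  comvx += B.mH * out(9, 2); comvy += B.mH * out(9, 3);
  for (int sd = 0; sd < 2; ++sd) {
    const int iT = 3 + 3 * sd, iS = iT + 1, iF = iT + 2;
    const double tT = q[iT], tS = q[iS], tF = q[iF];
    const double wT = qd[iT], wS = qd[iS], wF = qd[iF];
    const double sT = std::sin(tT), cT = std::cos(tT);
    const double sS = std::sin(tS), cS_ = std::cos(tS);
    const double sF = std::sin(tF), cF = std::cos(tF);
    const int rKnee = 1 + 4 * sd, rAnk = 2 + 4 * sd, rHeel = 3 + 4 * sd, rToe = 4 + 4 * sd;
    out(rKnee, 0) = x + B.lT * sT; out(rKnee, 1) = y - B.lT * cT;
    out(rKnee, 2) = vx + B.lT * cT * wT; out(rKnee, 3) = vy + B.lT * sT * wT;
    out(rAnk, 0) = out(rKnee, 0) + B.lS * sS; out(rAnk, 1) = out(rKnee, 1) - B.lS * cS_;
    out(rAnk, 2) = out(rKnee, 2) + B.lS * cS_ * wS; out(rAnk, 3) = out(rKnee, 3) + B.lS * sS * wS;
    for (int k = 0; k < 4; ++k) {
      out(rHeel, k) = pts[2 * sd][k];
      out(rToe, k) = pts[2 * sd + 1][k];
    }
    // segment COMs: rows 10,11,12 (left thigh/shank/foot), 13,14,15 (right)
    const int rT = 10 + 3 * sd, rS = 11 + 3 * sd, rF = 12 + 3 * sd;
    out(rT, 0) = x + B.cT * sT; out(rT, 1) = y - B.cT * cT;
    out(rT, 2) = vx + B.cT * cT * wT; out(rT, 3) = vy + B.cT * sT * wT;
    out(rS, 0) = out(rKnee, 0) + B.cS * sS; out(rS, 1) = out(rKnee, 1) - B.cS * cS_;
    out(rS, 2) = out(rKnee, 2) + B.cS * cS_ * wS; out(rS, 3) = out(rKnee, 3) + B.cS * sS * wS;
    const double pcx = B.fcx, pcy = -B.fcz;
    out(rF, 0) = out(rAnk, 0) + pcx * cF - pcy * sF;
    out(rF, 1) = out(rAnk, 1) + pcx * sF + pcy * cF;
    out(rF, 2) = out(rAnk, 2) + wF * (-pcx * sF - pcy * cF);
    out(rF, 3) = out(rAnk, 3) + wF * (pcx * cF - pcy * sF);
    comx += B.mT[sd] * out(rT, 0) + B.mS[sd] * out(rS, 0) + B.mF[sd] * out(rF, 0);
    comy += B.mT[sd] * out(rT, 1) + B.mS[sd] * out(rS, 1) + B.mF[sd] * out(rF, 1);
    comvx += B.mT[sd] * out(rT, 2) + B.mS[sd] * out(rS, 2) + B.mF[sd] * out(rF, 2);
    comvy += B.mT[sd] * out(rT, 3) + B.mS[sd] * out(rS, 3) + B.mF[sd] * out(rF, 3);
  }
  out(16, 0) = comx / B.Mtot; out(16, 1) = comy / B.Mtot;
  out(16, 2) = comvx / B.Mtot; out(16, 3) = comvy / B.Mtot;
  return out;
}

// [[Rcpp::export]]
double mechanicalEnergyC(List body, NumericVector q, NumericVector qd) {
  Body B = parseBody(body);
  NumericMatrix pts = bodyPointsC(body, q, qd);
  // rows: 9 comHAT, 10..15 leg segment COMs
  const double m[7] = {B.mH, B.mT[0], B.mS[0], B.mF[0], B.mT[1], B.mS[1], B.mF[1]};
  const double I[7] = {B.IH, B.IT[0], B.IS[0], B.IF[0], B.IT[1], B.IS[1], B.IF[1]};
  const int rows[7] = {9, 10, 11, 12, 13, 14, 15};
  const int ang[7] = {2, 3, 4, 5, 6, 7, 8};
  double E = 0.0;
  for (int i = 0; i < 7; ++i) {
    const double vx = pts(rows[i], 2), vy = pts(rows[i], 3);
    E += 0.5 * m[i] * (vx * vx + vy * vy);
    E += 0.5 * I[i] * qd[ang[i]] * qd[ang[i]];
    E += m[i] * B.g * pts(rows[i], 1);
  }
  return E;
}

// [[Rcpp::export]]
List cpgDerivC(NumericVector u, NumericVector v, NumericMatrix W, double beta,
               NumericVector tau, NumericVector taup, double u0,
               NumericVector feed) {
  const int n = u.size();
  NumericVector ud(n), vd(n), y(n);
  for (int i = 0; i < n; ++i) y[i] = u[i] > 0.0 ? u[i] : 0.0;
  for (int i = 0; i < n; ++i) {
    double syn = 0.0;
    for (int j = 0; j < n; ++j) syn += W(i, j) * y[j];
    ud[i] = (-u[i] + syn - beta * v[i] + u0 + feed[i]) / tau[i];
    vd[i] = (-v[i] + y[i]) / taup[i];
  }
  return List::create(_["ud"] = ud, _["vd"] = vd, _["y"] = y);
}

// [[Rcpp::export]]
NumericVector feedSignalsC(NumericVector thSeg, NumericVector grf,
                           NumericMatrix wfeed, double bw, double thresh) {
  double ts[7], g2[2], wf[2][16], fd[12];
  for (int i = 0; i < 7; ++i) ts[i] = thSeg[i];
  g2[0] = grf[0]; g2[1] = grf[1];
  for (int s = 0; s < 2; ++s) for (int k = 0; k < 16; ++k) wf[s][k] = wfeed(s, k);
  feedCore(ts, g2, wf, bw, thresh, fd);
  NumericVector out(12);
  for (int i = 0; i < 12; ++i) out[i] = fd[i];
  return out;
}

// [[Rcpp::export]]
NumericVector postureSignalsC(NumericVector jAng6, NumericVector jRate6,
                              double thH, double thHd, NumericVector grf,
                              NumericVector wpos, NumericMatrix muscles,
                              double bw, double thresh) {
  double jA[2][3], jR[2][3], g2[2], Pm[18];
  for (int s = 0; s < 2; ++s)
    for (int j = 0; j < 3; ++j) { jA[s][j] = jAng6[3 * s + j]; jR[s][j] = jRate6[3 * s + j]; }
  g2[0] = grf[0]; g2[1] = grf[1];
  postureCore(jA, jR, thH, thHd, g2, wpos.begin(), muscles, bw, thresh, Pm);
  NumericVector out(muscles.nrow());
  for (int m = 0; m < muscles.nrow(); ++m) out[m] = Pm[m];
  return out;
}

// [[Rcpp::export]]
NumericVector motoneuronC(NumericVector y, NumericVector Pm, NumericMatrix walpha,
                          NumericVector active) {
  const int n = walpha.nrow();
  NumericVector out(n);
  for (int m = 0; m < n; ++m) {
    if (active[m] <= 0.0) { out[m] = 0.0; continue; }
    double drive = Pm[m];
    for (int i = 0; i < walpha.ncol(); ++i) drive += walpha(m, i) * y[i];
    out[m] = motoneuron(drive);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector metabolicRateC(NumericMatrix muscles, NumericVector alpha,
                             NumericVector L, NumericVector Ldot,
                             double fv_sign) {
  const int n = muscles.nrow();
  NumericVector out(n);
  for (int m = 0; m < n; ++m) {
    if (muscles(m, MC_ACTIVE) <= 0.0) { out[m] = 0.0; continue; }
    double ft[4];
    hillTension(muscles(m, MC_FCE), muscles(m, MC_LBAR), muscles(m, MC_LDBAR),
                muscles(m, MC_CPD), muscles(m, MC_KPE), L[m], Ldot[m], alpha[m],
                fv_sign, ft);
    double e = EN_ACT * muscles(m, MC_FCE) * muscles(m, MC_LBAR) * alpha[m];
    const double vshort = Ldot[m] < 0.0 ? -Ldot[m] : 0.0;
    e += EN_SHORT * muscles(m, MC_FCE) * alpha[m] * vshort;
    e += ft[1] * vshort;
    out[m] = e;
  }
  return out;
}

// ---------------------------------------------------------------------------
// full trial integration

// [[Rcpp::export]]
List simulateTrialC(List body, NumericMatrix muscles, List ctrl, List opts) {
  Body B = parseBody(body);
  Ctrl C = parseCtrl(ctrl);

  const double duration = as<double>(opts["duration"]);
  const double dt = as<double>(opts["dt"]);
  const int logEvery = as<int>(opts["log_every"]);
  const bool ground = as<bool>(opts["ground"]);
  const bool ctrlOn = as<bool>(opts["controller_on"]);
  const bool fallOn = as<bool>(opts["fall_check"]);
  const double fallFrac = as<double>(opts["fall_height_frac"]);
  const double fallPitch = as<double>(opts["fall_pitch"]);
  const double kneeClear = as<double>(opts["knee_clearance"]);

  NumericVector q0 = opts["q0"], qd0 = opts["qd0"], cu0 = opts["cpg_u"], cv0 = opts["cpg_v"];
  double s[42], snew[42];
  for (int i = 0; i < 9; ++i) { s[i] = q0[i]; s[9 + i] = qd0[i]; }
  for (int i = 0; i < 12; ++i) { s[18 + i] = cu0[i]; s[30 + i] = cv0[i]; }

  const double yStand = B.lT + B.lS + B.fh;
  const int nstep = (int)std::lround(duration / dt);
  const int nlog = logEvery > 0 ? nstep / logEvery + 1 : 0;
  const int ncol = 69;
  NumericMatrix log(nlog > 0 ? nlog : 1, ncol);
  int logged = 0;

  double anchorX[4] = {0, 0, 0, 0};
  int active[4] = {0, 0, 0, 0};
  {
    double pts[4][4];
    contactPoints(B, s, pts);
    for (int p = 0; p < 4; ++p)
      if (pts[p][1] < 0.0) { active[p] = 1; anchorX[p] = pts[p][0]; }
  }

  DynOut k1, k2, k3, k4;
  const double x0 = s[0];
  double energy = 0.0;
  bool fell = false;
  double tEnd = 0.0;
  int step = 0;

  for (step = 0; step < nstep; ++step) {
    const double t = step * dt;
    evalDyn(B, muscles, C, s, anchorX, active, ground, ctrlOn, k1);
    if (!k1.ok) { fell = true; tEnd = t; break; }

    // logging + energy from the stage-1 evaluation (state at step start)
    double edotSum = 0.0;
    for (int m = 0; m < 18; ++m) edotSum += k1.Edot[m];
    energy += edotSum * dt;
    if (logEvery > 0 && step % logEvery == 0 && logged < nlog) {
      int c = 0;
      log(logged, c++) = t;
      for (int i = 0; i < 9; ++i) log(logged, c++) = s[i];
      for (int i = 0; i < 9; ++i) log(logged, c++) = s[9 + i];
      log(logged, c++) = k1.grf[0]; log(logged, c++) = k1.grf[1];
      log(logged, c++) = k1.grfx[0]; log(logged, c++) = k1.grfx[1];
      for (int p = 0; p < 4; ++p) { log(logged, c++) = k1.pts[p][0]; log(logged, c++) = k1.pts[p][1]; }
      for (int m = 0; m < 18; ++m) log(logged, c++) = k1.alpha[m];
      for (int m = 0; m < 18; ++m) log(logged, c++) = k1.Edot[m];
      ++logged;
    }

    // classical RK4 on the monolithic state
    double d1[42], d2[42], d3[42], d4[42];
    auto pack = [](const DynOut& k, const double* st, double* d) {
      for (int i = 0; i < 9; ++i) d[i] = st[9 + i];
      for (int i = 0; i < 9; ++i) d[9 + i] = k.qdd[i];
      for (int i = 0; i < 12; ++i) d[18 + i] = k.ud[i];
      for (int i = 0; i < 12; ++i) d[30 + i] = k.vd[i];
    };
    pack(k1, s, d1);
    for (int i = 0; i < 42; ++i) snew[i] = s[i] + 0.5 * dt * d1[i];
    evalDyn(B, muscles, C, snew, anchorX, active, ground, ctrlOn, k2);
    if (!k2.ok) { fell = true; tEnd = t; break; }
    pack(k2, snew, d2);
    for (int i = 0; i < 42; ++i) snew[i] = s[i] + 0.5 * dt * d2[i];
    evalDyn(B, muscles, C, snew, anchorX, active, ground, ctrlOn, k3);
    if (!k3.ok) { fell = true; tEnd = t; break; }
    pack(k3, snew, d3);
    for (int i = 0; i < 42; ++i) snew[i] = s[i] + dt * d3[i];
    evalDyn(B, muscles, C, snew, anchorX, active, ground, ctrlOn, k4);
    if (!k4.ok) { fell = true; tEnd = t; break; }
    pack(k4, snew, d4);
    bool finite = true;
    for (int i = 0; i < 42; ++i) {
      s[i] += dt / 6.0 * (d1[i] + 2.0 * d2[i] + 2.0 * d3[i] + d4[i]);
      if (!std::isfinite(s[i])) finite = false;
    }
    tEnd = t + dt;
    if (!finite) { fell = true; break; }

    // contact anchor bookkeeping (discrete, once per step)
    if (ground) {
      double pts[4][4];
      contactPoints(B, s, pts);
      for (int p = 0; p < 4; ++p) {
        if (pts[p][1] < 0.0) {
          if (!active[p]) { active[p] = 1; anchorX[p] = pts[p][0]; }
        } else {
          active[p] = 0;
        }
      }
      // fall detection
      if (fallOn) {
        const double kneeL = s[1] - B.lT * std::cos(s[3]);
        const double kneeR = s[1] - B.lT * std::cos(s[6]);
        if (s[1] < fallFrac * yStand || std::fabs(s[2]) > fallPitch ||
            kneeL < kneeClear || kneeR < kneeClear) {
          fell = true;
          break;
        }
      }
    }
  }

  // final log row (only when the trial ran to completion on a log boundary)
  if (logEvery > 0 && !fell && step == nstep && nstep % logEvery == 0 && logged < nlog) {
    evalDyn(B, muscles, C, s, anchorX, active, ground, ctrlOn, k1);
    if (k1.ok) {
      int c = 0;
      log(logged, c++) = nstep * dt;
      for (int i = 0; i < 9; ++i) log(logged, c++) = s[i];
      for (int i = 0; i < 9; ++i) log(logged, c++) = s[9 + i];
      log(logged, c++) = k1.grf[0]; log(logged, c++) = k1.grf[1];
      log(logged, c++) = k1.grfx[0]; log(logged, c++) = k1.grfx[1];
      for (int p = 0; p < 4; ++p) { log(logged, c++) = k1.pts[p][0]; log(logged, c++) = k1.pts[p][1]; }
      for (int m = 0; m < 18; ++m) log(logged, c++) = k1.alpha[m];
      for (int m = 0; m < 18; ++m) log(logged, c++) = k1.Edot[m];
      ++logged;
    }
  }

  if (!fell) tEnd = nstep * dt;
  const double D = std::isfinite(s[0]) ? s[0] - x0 : 0.0;

  NumericVector fin(42);
  for (int i = 0; i < 42; ++i) fin[i] = s[i];

  return List::create(
    _["log"] = log, _["n_logged"] = logged,
    _["distance"] = D, _["fell"] = fell, _["t_end"] = tEnd,
    _["energy"] = energy, _["final_state"] = fin);
}
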