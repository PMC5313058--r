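// Double-cable backward-Euler integrator.
//
// Each compartment i carries two potentials: V[i], intracellular, and
// U[i], periaxonal (between axolemma and innermost myelin membrane).
// The axolemma (capacitance c_mem, ionic conductances) separates V and
// U; the myelin sheath (c_my, g_my; all membranes already combined in
// series) separates U from the grounded extracellular space.  At node
// compartments there is no myelin and U is pinned to 0.  Axial current
// flows intracellularly (conductance gax between neighbouring centres)
// and through the periaxonal space (gp), the latter grounded at nodes.
//
// One implicit step solves the 2x2-block tridiagonal system
//   axolemma: (a+g+gaxL+gaxR) V' - (a+g) U' - gaxL V'l - gaxR V'r
//                = a (V-U) + g*Eeff + Istim
//   periax.:  -(a+g) V' + (a+g+mu+gmy+gpL+gpR) U' - gpL U'l - gpR U'r
//                = mu U - a (V-U) - g*Eeff
// with a = c_mem/dt, mu = c_my/dt, g the total ionic conductance at
// gating values advanced beforehand by the exponential update.
// Units: mV, ms, nS, pF, pA.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double vtrap(double x, double k) {
  if (std::fabs(x / k) < 1e-6) return k * (1.0 + x / (2.0 * k));
  return x / (1.0 - std::exp(-x / k));
}

// rate table: 8 rows (am, bm, ah, bh, ap, bp, as, bs), cols
// (form, a, Vh, k, s); q10: 4 (m, h, p, s)
static inline double rate(const double* r, double V) {
  if (r[0] == 0.0) {
    double u = r[4] * (V - r[2]);
    return r[1] * vtrap(u, r[3]);
  }
  return r[1] / (1.0 + std::exp(-r[4] * (V - r[2]) / r[3]));
}

struct Rates {
  double tab[8][5];
  double q10[4];
  void load(const NumericMatrix& m, const NumericVector& q) {
    for (int i = 0; i < 8; ++i)
      for (int j = 0; j < 5; ++j) tab[i][j] = m(i, j);
    for (int i = 0; i < 4; ++i) q10[i] = q[i];
  }
  // alpha/beta for gate g (0=m,1=h,2=p,3=s)
  void ab(int g, double V, double& a, double& b) const {
    a = q10[g] * rate(tab[2 * g], V);
    b = q10[g] * rate(tab[2 * g + 1], V);
  }
  double xinf(int g, double V) const {
    double a, b; ab(g, V, a, b); return a / (a + b);
  }
};

// total ionic conductance (nS) and conductance-weighted reversal (nS*mV)
static inline void ionic(double gNa, double gKs, double gNap, double gL,
                         double ENa, double EK, double ELk,
                         const double* gt,
                         double& gtot, double& gE) {
  double gna = gNa * gt[0] * gt[0] * gt[0] * gt[1];
  double gp = gNap * gt[2] * gt[2] * gt[2];
  double gk = gKs * gt[3];
  gtot = gna + gp + gk + gL;
  gE = (gna + gp) * ENa + gk * EK + gL * ELk;
}

// Solve the 2x2-block tridiagonal system in place.
// D: n blocks (row-major 2x2), Lo/Up: sub/super diagonal blocks
// (diagonal 2x2: only (0,0) and (1,1) nonzero -> stored as pairs),
// rhs: 2n.
static void block_thomas(int n, std::vector<double>& D,
                         const std::vector<double>& Lo,
                         const std::vector<double>& Up,
                         std::vector<double>& rhs) {
  // forward elimination
  for (int i = 1; i < n; ++i) {
    double* Dp = &D[4 * (i - 1)];
    double det = Dp[0] * Dp[3] - Dp[1] * Dp[2];
    double inv0 = Dp[3] / det, inv1 = -Dp[1] / det,
           inv2 = -Dp[2] / det, inv3 = Dp[0] / det;
    // L_i * inv(D_{i-1}): L_i diagonal (lv, lu)
    double lv = Lo[2 * i], lu = Lo[2 * i + 1];
    double f0 = lv * inv0, f1 = lv * inv1, f2 = lu * inv2, f3 = lu * inv3;
    // D_i -= F * U_{i-1}; U_{i-1} diagonal (uv, uu)
    double uv = Up[2 * (i - 1)], uu = Up[2 * (i - 1) + 1];
    double* Di = &D[4 * i];
    Di[0] -= f0 * uv; Di[1] -= f1 * uu;
    Di[2] -= f2 * uv; Di[3] -= f3 * uu;
    rhs[2 * i] -= f0 * rhs[2 * (i - 1)] + f1 * rhs[2 * (i - 1) + 1];
    rhs[2 * i + 1] -= f2 * rhs[2 * (i - 1)] + f3 * rhs[2 * (i - 1) + 1];
  }
  // back substitution
  for (int i = n - 1; i >= 0; --i) {
    double r0 = rhs[2 * i], r1 = rhs[2 * i + 1];
    if (i < n - 1) {
      double uv = Up[2 * i], uu = Up[2 * i + 1];
      r0 -= uv * rhs[2 * (i + 1)];
      r1 -= uu * rhs[2 * (i + 1) + 1];
    }
    double* Dp = &D[4 * i];
    double det = Dp[0] * Dp[3] - Dp[1] * Dp[2];
    rhs[2 * i] = (Dp[3] * r0 - Dp[1] * r1) / det;
    rhs[2 * i + 1] = (-Dp[2] * r0 + Dp[0] * r1) / det;
  }
}

// [[Rcpp::export]]
List cable_integrate_cpp(IntegerVector is_node,
                         NumericVector c_mem, NumericVector c_my,
                         NumericVector g_my, NumericVector g_L,
                         NumericVector g_Na, NumericVector g_Ks,
                         NumericVector g_Nap,
                         double E_Na, double E_K, double E_Lk,
                         NumericVector g_ax, NumericVector g_p,
                         NumericMatrix rate_tab, NumericVector q10,
                         NumericVector V0, NumericVector U0,
                         NumericMatrix gates0,
                         double dt, int n_steps,
                         int stim_comp, double stim_amp,
                         double stim_on, double stim_off,
                         IntegerVector record_idx, int record_every,
                         int stop_comp, double stop_delay) {
  const int n = is_node.size();
  Rates R; R.load(rate_tab, q10);

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> U(U0.begin(), U0.end());
  std::vector<double> gates(4 * n);
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < 4; ++g) gates[4 * i + g] = gates0(i, g);

  const int n_rec = record_idx.size();
  const int n_samp = n_steps / record_every + 1;
  NumericMatrix Vrec(n_samp, n_rec), Urec(n_samp, n_rec);
  NumericMatrix Grec(n_samp, 4 * n_rec);
  NumericVector trec(n_samp);

  std::vector<double> D(4 * n), Lo(2 * n), Up(2 * n), rhs(2 * n);
  // static axial couplings
  for (int i = 0; i < n; ++i) {
    Lo[2 * i] = (i > 0) ? -g_ax[i - 1] : 0.0;
    Lo[2 * i + 1] = (i > 0) ? -g_p[i - 1] : 0.0;
    Up[2 * i] = (i < n - 1) ? -g_ax[i] : 0.0;
    Up[2 * i + 1] = (i < n - 1) ? -g_p[i] : 0.0;
  }

  int diverged = -1;
  double t_stop = -1.0;  // set once stop_comp crosses 0 mV
  int samp = 0;
  auto record = [&](int s, double t) {
    trec[s] = t;
    for (int j = 0; j < n_rec; ++j) {
      int i = record_idx[j];
      Vrec(s, j) = V[i] - U[i];   // transmembrane (axolemmal) potential
      Urec(s, j) = U[i];
      for (int g = 0; g < 4; ++g) Grec(s, 4 * j + g) = gates[4 * i + g];
    }
  };
  record(samp++, 0.0);

  for (int step = 1; step <= n_steps && diverged < 0; ++step) {
    double t_new = step * dt;
    // gating: exponential update at rates for the current Vm
    for (int i = 0; i < n; ++i) {
      if (!is_node[i]) continue;
      double Vm = V[i] - U[i];
      for (int g = 0; g < 4; ++g) {
        double a, b; R.ab(g, Vm, a, b);
        double xi = a / (a + b);
        gates[4 * i + g] = xi + (gates[4 * i + g] - xi) *
          std::exp(-dt * (a + b));
      }
    }
    // assemble
    for (int i = 0; i < n; ++i) {
      double a = c_mem[i] / dt;
      double gtot, gE;
      ionic(g_Na[i], g_Ks[i], g_Nap[i], g_L[i], E_Na, E_K, E_Lk,
            &gates[4 * i], gtot, gE);
      double gaxL = (i > 0) ? g_ax[i - 1] : 0.0;
      double gaxR = (i < n - 1) ? g_ax[i] : 0.0;
      double stim = 0.0;
      if (i == stim_comp && t_new > stim_on && t_new <= stim_off)
        stim = stim_amp;
      D[4 * i] = a + gtot + gaxL + gaxR;
      D[4 * i + 1] = -(a + gtot);
      rhs[2 * i] = a * (V[i] - U[i]) + gE + stim;
      if (is_node[i]) {
        D[4 * i + 2] = 0.0; D[4 * i + 3] = 1.0;
        rhs[2 * i + 1] = 0.0;
        // node periaxonal row must not couple to neighbours
        Lo[2 * i + 1] = 0.0; Up[2 * i + 1] = 0.0;
      } else {
        double mu = c_my[i] / dt;
        double gpL = (i > 0) ? g_p[i - 1] : 0.0;
        double gpR = (i < n - 1) ? g_p[i] : 0.0;
        D[4 * i + 2] = -(a + gtot);
        D[4 * i + 3] = a + gtot + mu + g_my[i] + gpL + gpR;
        rhs[2 * i + 1] = mu * U[i] - a * (V[i] - U[i]) - gE;
      }
    }
    block_thomas(n, D, Lo, Up, rhs);
    for (int i = 0; i < n; ++i) {
      V[i] = rhs[2 * i];
      U[i] = rhs[2 * i + 1];
      if (!std::isfinite(V[i]) || std::fabs(V[i]) > 500.0) diverged = i;
    }
    if (step % record_every == 0 && samp < n_samp)
      record(samp++, t_new);
    if (stop_comp >= 0 && t_stop < 0.0 &&
        V[stop_comp] - U[stop_comp] > 0.0)
      t_stop = t_new + stop_delay;
    if (t_stop > 0.0 && t_new >= t_stop) break;
  }

  NumericMatrix gates_out(n, 4);
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < 4; ++g) gates_out(i, g) = gates[4 * i + g];

  return List::create(
    Named("t") = trec, Named("Vm") = Vrec, Named("U") = Urec,
    Named("gates_rec") = Grec,
    Named("V_final") = NumericVector(V.begin(), V.end()),
    Named("U_final") = NumericVector(U.begin(), U.end()),
    Named("gates_final") = gates_out,
    Named("n_samp") = samp,
    Named("diverged") = diverged);
}

// Stationary state: damped fixed-point iteration alternating a linear
// network solve (capacitances dropped) with gating steady states.
// [[Rcpp::export]]
List cable_stationary_cpp(IntegerVector is_node,
                          NumericVector g_my, NumericVector g_L,
                          NumericVector g_Na, NumericVector g_Ks,
                          NumericVector g_Nap,
                          double E_Na, double E_K, double E_Lk,
                          NumericVector g_ax, NumericVector g_p,
                          NumericMatrix rate_tab, NumericVector q10,
                          NumericVector V0, NumericVector U0,
                          int max_iter, double damping, double tol) {
  const int n = is_node.size();
  Rates R; R.load(rate_tab, q10);
  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> U(U0.begin(), U0.end());
  std::vector<double> D(4 * n), Lo(2 * n), Up(2 * n), rhs(2 * n);
  double delta = NA_REAL;
  int iter = 0;
  for (iter = 0; iter < max_iter; ++iter) {
    for (int i = 0; i < n; ++i) {
      Lo[2 * i] = (i > 0) ? -g_ax[i - 1] : 0.0;
      Lo[2 * i + 1] = (i > 0) ? -g_p[i - 1] : 0.0;
      Up[2 * i] = (i < n - 1) ? -g_ax[i] : 0.0;
      Up[2 * i + 1] = (i < n - 1) ? -g_p[i] : 0.0;
      double Vm = V[i] - U[i];
      double gt[4];
      for (int g = 0; g < 4; ++g) gt[g] = R.xinf(g, Vm);
      double gtot, gE;
      ionic(g_Na[i], g_Ks[i], g_Nap[i], g_L[i], E_Na, E_K, E_Lk,
            gt, gtot, gE);
      double gaxL = (i > 0) ? g_ax[i - 1] : 0.0;
      double gaxR = (i < n - 1) ? g_ax[i] : 0.0;
      D[4 * i] = gtot + gaxL + gaxR;
      D[4 * i + 1] = -gtot;
      rhs[2 * i] = gE;
      if (is_node[i]) {
        D[4 * i + 2] = 0.0; D[4 * i + 3] = 1.0;
        rhs[2 * i + 1] = 0.0;
        Lo[2 * i + 1] = 0.0; Up[2 * i + 1] = 0.0;
      } else {
        double gpL = (i > 0) ? g_p[i - 1] : 0.0;
        double gpR = (i < n - 1) ? g_p[i] : 0.0;
        D[4 * i + 2] = -gtot;
        D[4 * i + 3] = gtot + g_my[i] + gpL + gpR;
        rhs[2 * i + 1] = -gE;
      }
    }
    block_thomas(n, D, Lo, Up, rhs);
    delta = 0.0;
    for (int i = 0; i < n; ++i) {
      double dV = rhs[2 * i] - V[i], dU = rhs[2 * i + 1] - U[i];
      delta = std::max(delta, std::max(std::fabs(dV), std::fabs(dU)));
      V[i] += damping * dV;
      U[i] += damping * dU;
    }
    if (delta < tol) break;
  }
  NumericMatrix gates(n, 4);
  for (int i = 0; i < n; ++i)
    for (int g = 0; g < 4; ++g) gates(i, g) = R.xinf(g, V[i] - U[i]);
  return List::create(
    Named("V") = NumericVector(V.begin(), V.end()),
    Named("U") = NumericVector(U.begin(), U.end()),
    Named("gates") = gates,
    Named("iterations") = iter + 1,
    Named("delta") = delta);
}
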