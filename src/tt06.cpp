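// ten Tusscher-Panfilov 2006 human ventricular myocyte model and a
// heterogeneous 1D monodomain cable with unipolar pseudo-ECG output.
//
// State vector layout (19 variables):
//   0 V (mV), 1 m, 2 h, 3 j, 4 d, 5 f, 6 f2, 7 fCass, 8 r, 9 s,
//   10 xr1, 11 xr2, 12 xs, 13 Rq (ryanodine release gate),
//   14 Nai, 15 Ki, 16 Cai, 17 Cass, 18 Casr (mM)
//
// Parameter vector layout (16 entries; conductances already carry any
// pore-block scaling applied on the R side):
//   0 s_variant (0 = endocardial s-gate kinetics, 1 = epi/M kinetics),
//   1 GNa, 2 GCaL, 3 Gto, 4 GKr, 5 GKs, 6 GK1, 7 GpCa, 8 GpK,
//   9 GbNa, 10 GbCa, 11 PNaK, 12 kNaCa, 13 Ko, 14 Nao, 15 Cao

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>

using namespace Rcpp;

static const int NSTATE = 19;
static const int NPAR = 16;

// physical constants
static const double Rgas = 8314.472;   // J/(kmol K)
static const double Temp = 310.0;      // K
static const double Frdy = 96485.3415; // C/mol
static const double RTF = Rgas * Temp / Frdy;

// geometry / capacitance (TT06 values)
static const double Cm = 0.185;
static const double Vc = 0.016404;
static const double Vsr = 0.001094;
static const double Vss = 0.00005468;

// Ca dynamics constants
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, Vleak = 0.00036, Vxfer = 0.0038;
static const double k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
static const double ECsr = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Bufc = 0.2, Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;

static const double pKNa = 0.03;
static const double KmK = 1.0, KmNa = 40.0;
static const double KmNai = 87.5, KmCa = 1.38, ksat = 0.1, ncx_alpha = 2.5, ncx_gamma = 0.35;
static const double KpCa = 0.0005;

struct GateKin { double inf, tau; };

// voltage-dependent gate kinetics (s gate depends on the cell-type variant)
static inline GateKin kin_m(double V) {
  GateKin g;
  double am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
  double bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) + 0.1 / (1.0 + exp((V - 50.0) / 200.0));
  g.tau = am * bm;
  double mi = 1.0 / (1.0 + exp((-56.86 - V) / 9.03));
  g.inf = mi * mi;
  return g;
}
static inline GateKin kin_h(double V) {
  GateKin g;
  double hi = 1.0 / (1.0 + exp((V + 71.55) / 7.43));
  g.inf = hi * hi;
  double ah, bh;
  if (V < -40.0) {
    ah = 0.057 * exp(-(V + 80.0) / 6.8);
    bh = 2.7 * exp(0.079 * V) + 310000.0 * exp(0.3485 * V);
  } else {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + exp((V + 10.66) / -11.1)));
  }
  g.tau = 1.0 / (ah + bh);
  return g;
}
static inline GateKin kin_j(double V) {
  GateKin g;
  double hi = 1.0 / (1.0 + exp((V + 71.55) / 7.43));
  g.inf = hi * hi;
  double aj, bj;
  if (V < -40.0) {
    aj = (-25428.0 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) * (V + 37.78) /
         (1.0 + exp(0.311 * (V + 79.23)));
    bj = 0.02424 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
  } else {
    aj = 0.0;
    bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
  }
  g.tau = 1.0 / (aj + bj);
  return g;
}
static inline GateKin kin_d(double V) {
  GateKin g;
  g.inf = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
  double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
  double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
  double gd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
  g.tau = ad * bd + gd;
  return g;
}
static inline GateKin kin_f(double V) {
  GateKin g;
  g.inf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  g.tau = 1102.5 * exp(-(V + 27.0) * (V + 27.0) / 225.0) +
          200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
          180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
  return g;
}
static inline GateKin kin_f2(double V) {
  GateKin g;
  g.inf = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
  g.tau = 562.0 * exp(-(V + 27.0) * (V + 27.0) / 240.0) +
          31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
          80.0 / (1.0 + exp((V + 30.0) / 10.0));
  return g;
}
static inline GateKin kin_r(double V) {
  GateKin g;
  g.inf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  g.tau = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  return g;
}
static inline GateKin kin_s(double V, int variant) {
  GateKin g;
  if (variant == 0) { // endocardial
    g.inf = 1.0 / (1.0 + exp((V + 28.0) / 5.0));
    g.tau = 1000.0 * exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  } else {            // epicardial / mid-myocardial
    g.inf = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
    g.tau = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0) +
            5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
  }
  return g;
}
static inline GateKin kin_xr1(double V) {
  GateKin g;
  g.inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
  double a = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
  double b = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
  g.tau = a * b;
  return g;
}
static inline GateKin kin_xr2(double V) {
  GateKin g;
  g.inf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
  double a = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
  double b = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
  g.tau = a * b;
  return g;
}
static inline GateKin kin_xs(double V) {
  GateKin g;
  g.inf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  double a = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
  double b = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
  g.tau = a * b + 80.0;
  return g;
}

// membrane currents, total dV/dt, and concentration/release derivatives
struct Currents {
  double INa, ICaL, Ito, IKr, IKs, IK1, INaCa, INaK, IpCa, IpK, IbNa, IbCa;
  double Itot; // without stimulus
};

static inline Currents tt06_currents(const double *y, const double *p) {
  Currents c;
  const double V = y[0];
  const double m = y[1], h = y[2], j = y[3], d = y[4], f = y[5], f2 = y[6],
               fCass = y[7], r = y[8], s = y[9], xr1 = y[10], xr2 = y[11], xs = y[12];
  const double Nai = y[14], Ki = y[15], Cai = y[16], Cass = y[17];
  const double Ko = p[13], Nao = p[14], Cao = p[15];

  const double EK = RTF * log(Ko / Ki);
  const double ENa = RTF * log(Nao / Nai);
  const double EKs = RTF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double ECa = 0.5 * RTF * log(Cao / Cai);

  c.INa = p[1] * m * m * m * h * j * (V - ENa);

  const double vf = 2.0 * (V - 15.0) / RTF;
  double ical_drive;
  if (fabs(vf) < 1e-7) {
    ical_drive = 0.25 * Cass - Cao; // x*(0.25*Cass*e^x - Cao)/(e^x - 1) -> this as x -> 0
  } else {
    ical_drive = vf * (0.25 * Cass * exp(vf) - Cao) / (exp(vf) - 1.0);
  }
  c.ICaL = p[2] * d * f * f2 * fCass * 2.0 * Frdy * ical_drive;

  c.Ito = p[3] * r * s * (V - EK);
  c.IKr = p[4] * sqrt(Ko / 5.4) * xr1 * xr2 * (V - EK);
  c.IKs = p[5] * xs * xs * (V - EKs);

  const double aK1 = 0.1 / (1.0 + exp(0.06 * (V - EK - 200.0)));
  const double bK1 = (3.0 * exp(0.0002 * (V - EK + 100.0)) + exp(0.1 * (V - EK - 10.0))) /
                     (1.0 + exp(-0.5 * (V - EK)));
  c.IK1 = p[6] * sqrt(Ko / 5.4) * (aK1 / (aK1 + bK1)) * (V - EK);

  const double eg = exp(ncx_gamma * V / RTF);
  const double eg1 = exp((ncx_gamma - 1.0) * V / RTF);
  c.INaCa = p[12] * (eg * Nai * Nai * Nai * Cao - eg1 * Nao * Nao * Nao * Cai * ncx_alpha) /
            ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) * (1.0 + ksat * eg1));

  c.INaK = p[11] * Ko * Nai /
           ((Ko + KmK) * (Nai + KmNa) *
            (1.0 + 0.1245 * exp(-0.1 * V / RTF) + 0.0353 * exp(-V / RTF)));

  c.IpCa = p[7] * Cai / (Cai + KpCa);
  c.IpK = p[8] * (V - EK) / (1.0 + exp((25.0 - V) / 5.98));
  c.IbNa = p[9] * (V - ENa);
  c.IbCa = p[10] * (V - ECa);

  c.Itot = c.INa + c.ICaL + c.Ito + c.IKr + c.IKs + c.IK1 + c.INaCa + c.INaK +
           c.IpCa + c.IpK + c.IbNa + c.IbCa;
  return c;
}

// derivatives of the non-gate states (V, Rq, concentrations); the release
// flux block is shared between the rhs export and the integrator
struct CaFluxes { double Irel, Iup, Ileak, Ixfer, dRq; };

static inline CaFluxes ca_fluxes(const double *y) {
  CaFluxes fx;
  const double Rq = y[13], Cai = y[16], Cass = y[17], Casr = y[18];
  double kcasr = maxsr - (maxsr - minsr) / (1.0 + (ECsr / Casr) * (ECsr / Casr));
  double k1 = k1p / kcasr;
  double k2 = k2p * kcasr;
  double O = k1 * Cass * Cass * Rq / (k3 + k1 * Cass * Cass);
  fx.dRq = -k2 * Cass * Rq + k4 * (1.0 - Rq);
  fx.Irel = Vrel * O * (Casr - Cass);
  fx.Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  fx.Ileak = Vleak * (Casr - Cai);
  fx.Ixfer = Vxfer * (Cass - Cai);
  return fx;
}

static void tt06_rhs(const double *y, const double *p, double Istim, double *dy) {
  const double V = y[0];
  Currents c = tt06_currents(y, p);
  CaFluxes fx = ca_fluxes(y);
  const double Cai = y[16], Cass = y[17], Casr = y[18];

  dy[0] = -(c.Itot + Istim);

  GateKin g;
  g = kin_m(V);  dy[1] = (g.inf - y[1]) / g.tau;
  g = kin_h(V);  dy[2] = (g.inf - y[2]) / g.tau;
  g = kin_j(V);  dy[3] = (g.inf - y[3]) / g.tau;
  g = kin_d(V);  dy[4] = (g.inf - y[4]) / g.tau;
  g = kin_f(V);  dy[5] = (g.inf - y[5]) / g.tau;
  g = kin_f2(V); dy[6] = (g.inf - y[6]) / g.tau;
  double fci = 0.6 / (1.0 + (Cass / 0.05) * (Cass / 0.05)) + 0.4;
  double fct = 80.0 / (1.0 + (Cass / 0.05) * (Cass / 0.05)) + 2.0;
  dy[7] = (fci - y[7]) / fct;
  g = kin_r(V);  dy[8] = (g.inf - y[8]) / g.tau;
  g = kin_s(V, (int)p[0]); dy[9] = (g.inf - y[9]) / g.tau;
  g = kin_xr1(V); dy[10] = (g.inf - y[10]) / g.tau;
  g = kin_xr2(V); dy[11] = (g.inf - y[11]) / g.tau;
  g = kin_xs(V);  dy[12] = (g.inf - y[12]) / g.tau;

  dy[13] = fx.dRq;
  dy[14] = -(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) * Cm / (Vc * Frdy);
  dy[15] = -(c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK + c.IpK + Istim) * Cm / (Vc * Frdy);

  double bufc = 1.0 / (1.0 + Bufc * Kbufc / ((Cai + Kbufc) * (Cai + Kbufc)));
  dy[16] = bufc * ((fx.Ileak - fx.Iup) * Vsr / Vc + fx.Ixfer -
                   (c.IbCa + c.IpCa - 2.0 * c.INaCa) * Cm / (2.0 * Vc * Frdy));
  double bufsr = 1.0 / (1.0 + Bufsr * Kbufsr / ((Casr + Kbufsr) * (Casr + Kbufsr)));
  dy[18] = bufsr * (fx.Iup - fx.Irel - fx.Ileak);
  double bufss = 1.0 / (1.0 + Bufss * Kbufss / ((Cass + Kbufss) * (Cass + Kbufss)));
  dy[17] = bufss * (-c.ICaL * Cm / (2.0 * Vss * Frdy) + fx.Irel * Vsr / Vss - fx.Ixfer * Vc / Vss);
}

// ---------------------------------------------------------------------------
// Rush-Larsen lookup tables: gate steady states and exp(-dt/tau) tabulated
// on a voltage grid, built once per integration call.

struct GateLut {
  double vmin, vmax, dv;
  int n;
  // 12 V-dependent gates x 2 variants only differ in s; store both s variants
  std::vector<double> inf[11], rl[11]; // m h j d f f2 r xr1 xr2 xs + s(variant used)
};

// gate order inside the LUT: 0 m, 1 h, 2 j, 3 d, 4 f, 5 f2, 6 r, 7 xr1, 8 xr2, 9 xs, 10 s
static void build_lut(GateLut &L, double dt, int s_variant) {
  L.vmin = -150.0; L.vmax = 100.0; L.dv = 0.05;
  L.n = (int)((L.vmax - L.vmin) / L.dv) + 1;
  for (int gidx = 0; gidx < 11; ++gidx) { L.inf[gidx].resize(L.n); L.rl[gidx].resize(L.n); }
  for (int i = 0; i < L.n; ++i) {
    double V = L.vmin + i * L.dv;
    GateKin g;
    g = kin_m(V);   L.inf[0][i] = g.inf; L.rl[0][i] = exp(-dt / g.tau);
    g = kin_h(V);   L.inf[1][i] = g.inf; L.rl[1][i] = exp(-dt / g.tau);
    g = kin_j(V);   L.inf[2][i] = g.inf; L.rl[2][i] = exp(-dt / g.tau);
    g = kin_d(V);   L.inf[3][i] = g.inf; L.rl[3][i] = exp(-dt / g.tau);
    g = kin_f(V);   L.inf[4][i] = g.inf; L.rl[4][i] = exp(-dt / g.tau);
    g = kin_f2(V);  L.inf[5][i] = g.inf; L.rl[5][i] = exp(-dt / g.tau);
    g = kin_r(V);   L.inf[6][i] = g.inf; L.rl[6][i] = exp(-dt / g.tau);
    g = kin_xr1(V); L.inf[7][i] = g.inf; L.rl[7][i] = exp(-dt / g.tau);
    g = kin_xr2(V); L.inf[8][i] = g.inf; L.rl[8][i] = exp(-dt / g.tau);
    g = kin_xs(V);  L.inf[9][i] = g.inf; L.rl[9][i] = exp(-dt / g.tau);
    g = kin_s(V, s_variant); L.inf[10][i] = g.inf; L.rl[10][i] = exp(-dt / g.tau);
  }
}

// single Rush-Larsen + forward-Euler step for one cell; diffusion handled
// by the caller. Istim in uA/uF.
static inline void tt06_step_cell(double *y, const double *p, double dt, double Istim,
                                  const GateLut &L) {
  const double V = y[0];
  Currents c = tt06_currents(y, p);
  CaFluxes fx = ca_fluxes(y);
  const double Cai = y[16], Cass = y[17], Casr = y[18];

  // LUT interpolation index
  double u = (V - L.vmin) / L.dv;
  int i0 = (int)u;
  if (i0 < 0) i0 = 0;
  if (i0 > L.n - 2) i0 = L.n - 2;
  double w = u - i0;
  if (w < 0.0) w = 0.0; else if (w > 1.0) w = 1.0;

  static const int gate_state[11] = {1, 2, 3, 4, 5, 6, 8, 10, 11, 12, 9};
  for (int gidx = 0; gidx < 11; ++gidx) {
    double inf = L.inf[gidx][i0] * (1.0 - w) + L.inf[gidx][i0 + 1] * w;
    double rl = L.rl[gidx][i0] * (1.0 - w) + L.rl[gidx][i0 + 1] * w;
    int si = gate_state[gidx];
    y[si] = inf + (y[si] - inf) * rl;
  }
  // fCass depends on Cass, not V: exact exponential update
  {
    double q = 1.0 + (Cass / 0.05) * (Cass / 0.05);
    double fci = 0.6 / q + 0.4;
    double fct = 80.0 / q + 2.0;
    y[7] = fci + (y[7] - fci) * exp(-dt / fct);
  }

  y[0] = V + dt * (-(c.Itot + Istim));
  y[13] += dt * fx.dRq;
  y[14] += dt * (-(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) * Cm / (Vc * Frdy));
  y[15] += dt * (-(c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK + c.IpK + Istim) * Cm / (Vc * Frdy));

  double bufc = 1.0 / (1.0 + Bufc * Kbufc / ((Cai + Kbufc) * (Cai + Kbufc)));
  y[16] += dt * bufc * ((fx.Ileak - fx.Iup) * Vsr / Vc + fx.Ixfer -
                        (c.IbCa + c.IpCa - 2.0 * c.INaCa) * Cm / (2.0 * Vc * Frdy));
  double bufsr = 1.0 / (1.0 + Bufsr * Kbufsr / ((Casr + Kbufsr) * (Casr + Kbufsr)));
  y[18] += dt * bufsr * (fx.Iup - fx.Irel - fx.Ileak);
  double bufss = 1.0 / (1.0 + Bufss * Kbufss / ((Cass + Kbufss) * (Cass + Kbufss)));
  y[17] += dt * bufss * (-c.ICaL * Cm / (2.0 * Vss * Frdy) + fx.Irel * Vsr / Vss - fx.Ixfer * Vc / Vss);
}

static const char *state_names[NSTATE] = {
  "V", "m", "h", "j", "d", "f", "f2", "fCass", "r", "s",
  "xr1", "xr2", "xs", "Rq", "Nai", "Ki", "Cai", "Cass", "Casr"};

static void check_finite(const double *y, double t, int cell) {
  for (int k = 0; k < NSTATE; ++k) {
    if (!R_finite(y[k])) {
      stop("non-finite state variable '%s' at t = %.3f ms (cell %d)",
           state_names[k], t, cell + 1);
    }
  }
}

// [[Rcpp::export(name = ".tt06_rhs_cpp")]]
NumericVector tt06_rhs_cpp(NumericVector state, NumericVector params, double stimulus = 0.0) {
  if (state.size() != NSTATE) stop("state must have %d elements", NSTATE);
  if (params.size() != NPAR) stop("params must have %d elements", NPAR);
  for (int k = 0; k < NSTATE; ++k)
    if (!R_finite(state[k])) stop("non-finite state variable '%s'", state_names[k]);
  NumericVector dy(NSTATE);
  tt06_rhs(REAL(state), REAL(params), stimulus, REAL(dy));
  return dy;
}

// Paced single-cell integration. Records V (and Cai) every sample_ms over the
// final beat (or the whole run when record_all). Stimuli start at t = 0 and
// recur every cl_ms.
// [[Rcpp::export(name = ".tt06_pace_cpp")]]
List tt06_pace_cpp(NumericVector state, NumericVector params,
                   double cl_ms, int n_beats, double dt,
                   double stim_amp, double stim_dur,
                   double sample_ms, bool record_all = false,
                   bool use_lut = true) {
  if (state.size() != NSTATE) stop("state must have %d elements", NSTATE);
  if (params.size() != NPAR) stop("params must have %d elements", NPAR);
  if (n_beats < 1) stop("n_beats must be >= 1");
  if (dt <= 0 || dt > 0.02 + 1e-12) stop("dt must be in (0, 0.02] ms for the fixed-step integrator");

  std::vector<double> y(NSTATE);
  std::copy(state.begin(), state.end(), y.begin());

  GateLut L;
  build_lut(L, dt, (int)params[0]);

  const double total = cl_ms * n_beats;
  const long nsteps = (long)(total / dt + 0.5);
  const long sample_every = std::max(1L, (long)(sample_ms / dt + 0.5));
  const double rec_start = record_all ? 0.0 : cl_ms * (n_beats - 1);

  std::vector<double> tv, Vv, Caiv;
  const double *p = REAL(params);

  for (long istep = 0; istep < nsteps; ++istep) {
    double t = istep * dt;
    if (istep % sample_every == 0 && t >= rec_start - 1e-9) {
      tv.push_back(t);
      Vv.push_back(y[0]);
      Caiv.push_back(y[16]);
    }
    double tb = t - cl_ms * floor(t / cl_ms);
    double Istim = (tb < stim_dur) ? stim_amp : 0.0;
    if (use_lut) {
      tt06_step_cell(y.data(), p, dt, Istim, L);
    } else {
      double dy[NSTATE];
      tt06_rhs(y.data(), p, Istim, dy);
      for (int k = 0; k < NSTATE; ++k) y[k] += dt * dy[k];
    }
    if (!R_finite(y[0])) check_finite(y.data(), t, 0);
    if ((istep & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  check_finite(y.data(), total, 0);

  NumericVector out_state(y.begin(), y.end());
  return List::create(_["state"] = out_state,
                      _["time_ms"] = NumericVector(tv.begin(), tv.end()),
                      _["v_mV"] = NumericVector(Vv.begin(), Vv.end()),
                      _["cai_mM"] = NumericVector(Caiv.begin(), Caiv.end()),
                      _["rec_offset_ms"] = rec_start);
}

// Heterogeneous monodomain cable, operator-split explicit scheme:
// reaction step per cell (Rush-Larsen/Euler), then explicit diffusion on V
// with no-flux boundaries. Pseudo-ECG accumulated at every phi sample.
//
// states: NSTATE x n matrix; params: NPAR x n matrix (per node).
// pace_first = true stimulates nodes 1..n_stim_nodes, else the last ones.
// electrode_x_cm is measured on the fibre axis with node i centred at
// (i + 0.5) * dx.
// [[Rcpp::export(name = ".tt06_fibre_cpp")]]
List tt06_fibre_cpp(NumericMatrix states, NumericMatrix params,
                    double diffusion, double dx, double dt,
                    double cl_ms, double total_ms,
                    bool pace_first, int n_stim_nodes,
                    double stim_amp, double stim_dur,
                    double sample_ms, double electrode_x_cm,
                    double v_sample_ms = 0.0) {
  const int n = states.ncol();
  if (states.nrow() != NSTATE) stop("states must have %d rows", NSTATE);
  if (params.nrow() != NPAR || params.ncol() != n) stop("params must be %d x n", NPAR);
  const double cfl = diffusion * dt / (dx * dx);
  if (cfl >= 0.5)
    stop("explicit diffusion unstable: D*dt/dx^2 = %.3f >= 0.5 (D = %g cm^2/ms, dt = %g ms, dx = %g cm)",
         cfl, diffusion, dt, dx);
  // electrode must be off the fibre
  if (electrode_x_cm > -1e-9 && electrode_x_cm < n * dx + 1e-9)
    stop("electrode position %.3f cm lies on the fibre [0, %.3f] cm", electrode_x_cm, n * dx);

  std::vector<double> Y(NSTATE * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSTATE; ++k) Y[i * NSTATE + k] = states(k, i);
  std::vector<const double *> P(n);
  std::vector<double> Pstore(NPAR * n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < NPAR; ++k) Pstore[i * NPAR + k] = params(k, i);
    P[i] = &Pstore[i * NPAR];
  }

  // two LUTs (s-gate variants); per-node selection
  GateLut L0, L1;
  build_lut(L0, dt, 0);
  build_lut(L1, dt, 1);
  std::vector<const GateLut *> Lp(n);
  for (int i = 0; i < n; ++i) Lp[i] = ((int)Pstore[i * NPAR] == 0) ? &L0 : &L1;

  // pseudo-ECG kernel: phi ~ -sum dV * d(1/r), with r at node centres
  std::vector<double> invr(n);
  for (int i = 0; i < n; ++i) {
    double x = (i + 0.5) * dx;
    invr[i] = 1.0 / fabs(x - electrode_x_cm);
  }

  const long nsteps = (long)(total_ms / dt + 0.5);
  const long sample_every = std::max(1L, (long)(sample_ms / dt + 0.5));
  const long v_every = v_sample_ms > 0 ? std::max(1L, (long)(v_sample_ms / dt + 0.5)) : 0;

  std::vector<double> tv, phiv, stim_times;
  long last_beat = -1;
  std::vector<double> vrec;       // column-major: snapshot-major blocks of n
  std::vector<double> vrec_t;
  std::vector<double> Vnew(n);

  for (long istep = 0; istep < nsteps; ++istep) {
    double t = istep * dt;
    double beat_no = floor(t / cl_ms + 1e-9);
    double tb = t - cl_ms * beat_no;
    bool stim_on = tb < stim_dur;
    if ((long)beat_no > last_beat) {
      stim_times.push_back(beat_no * cl_ms);
      last_beat = (long)beat_no;
    }

    if (istep % sample_every == 0) {
      double phi = 0.0;
      for (int i = 0; i < n - 1; ++i) {
        double dV = Y[(i + 1) * NSTATE] - Y[i * NSTATE];
        phi -= dV * (invr[i + 1] - invr[i]);
      }
      tv.push_back(t);
      phiv.push_back(phi / dx);
    }
    if (v_every > 0 && istep % v_every == 0) {
      vrec_t.push_back(t);
      for (int i = 0; i < n; ++i) vrec.push_back(Y[i * NSTATE]);
    }

    // reaction
    for (int i = 0; i < n; ++i) {
      bool stim_here = stim_on &&
        (pace_first ? (i < n_stim_nodes) : (i >= n - n_stim_nodes));
      tt06_step_cell(&Y[i * NSTATE], P[i], dt, stim_here ? stim_amp : 0.0, *Lp[i]);
    }
    // diffusion on V, no-flux boundaries
    const double a = diffusion * dt / (dx * dx);
    for (int i = 0; i < n; ++i) {
      double vl = (i == 0) ? Y[NSTATE] : Y[(i - 1) * NSTATE];
      double vr = (i == n - 1) ? Y[(n - 2) * NSTATE] : Y[(i + 1) * NSTATE];
      double v = Y[i * NSTATE];
      Vnew[i] = v + a * (vl - 2.0 * v + vr);
    }
    for (int i = 0; i < n; ++i) Y[i * NSTATE] = Vnew[i];

    for (int i = 0; i < n; ++i)
      if (!R_finite(Y[i * NSTATE])) check_finite(&Y[i * NSTATE], t, i);
    if ((istep & 0x3FFFF) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out_states(NSTATE, n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSTATE; ++k) out_states(k, i) = Y[i * NSTATE + k];

  List out = List::create(_["time_ms"] = NumericVector(tv.begin(), tv.end()),
                          _["phi"] = NumericVector(phiv.begin(), phiv.end()),
                          _["stim_times"] = NumericVector(stim_times.begin(), stim_times.end()),
                          _["states"] = out_states);
  if (v_every > 0) {
    int nsnap = vrec_t.size();
    NumericMatrix Vm(nsnap, n);
    for (int srow = 0; srow < nsnap; ++srow)
      for (int i = 0; i < n; ++i) Vm(srow, i) = vrec[(size_t)srow * n + i];
    out["v_time_ms"] = NumericVector(vrec_t.begin(), vrec_t.end());
    out["v_mV"] = Vm;
  }
  return out;
}
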