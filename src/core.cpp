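// Fixed-step integration core for the two-compartment Purkinje neuron model.
//
// Unit system: mV, ms, mS/cm2, uA/cm2, uF/cm2, mM, um.  Pump/exchanger
// densities are supplied in mA/cm2 (as tabulated) and converted (x1000)
// where they enter the membrane equations.  Voltages advance by a
// linearized implicit (backward-Euler) 2x2 solve with conductances frozen
// within the step; Hodgkin-Huxley gates by exact exponential relaxation at
// frozen rates; the 13-state Markov chain by backward Euler with
// renormalization; ion pools by explicit Euler with hard clamps.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const double FARADAY = 96485.33212;  // C/mol
static const double RGAS    = 8.314462618;  // J/(mol K)
static const double TBODY_K = 273.15 + 36.0;

static inline double rtf_mv() { return 1000.0 * RGAS * TBODY_K / FARADAY; }

// temperature factors (T = 36 C)
static const double MT3  = std::pow(3.0, (36.0 - 37.0) / 10.0);  // 3^-0.1
static const double MTK  = std::pow(3.0, (36.0 - 22.0) / 10.0);  // Kv1.2
static const double FT23 = std::pow(2.3, (36.0 - 36.0) / 10.0);  // = 1

static inline double sq(double x) { return x * x; }

// Boltzmann sigmoid 1/(1+exp(-(v-vh)/k)).  `literal` reproduces the
// printed 1/exp(-(v-vh)/k) form (audit mode only; exceeds 1 above vh).
static inline double boltz(double v, double vh, double k, bool lit) {
  if (lit) return std::exp((v - vh) / k);
  return 1.0 / (1.0 + std::exp(-(v - vh) / k));
}

// ---------------------------------------------------------------------------
// gate kinetics: steady state (dimensionless) and time constant (ms)
// Soma time constants are tabulated in seconds and converted here (x1000).

struct InfTau { double inf, tau; };

static InfTau g_kfast_m(double v, bool lit) {
  InfTau r;
  r.inf = boltz(v, -24.0, 15.4, lit);
  r.tau = (v < -35.0)
    ? 1000.0 * (0.000103 + 0.0149 * std::exp(0.035 * v))
    : 1000.0 * (0.000129 + 1.0 / (std::exp((v + 100.7) / 12.9) +
                                  std::exp((v - 56.0) / -23.1)));
  return r;
}
static InfTau g_kfast_h(double v, bool lit) {
  InfTau r;
  r.inf = 0.31 + (1.0 - 0.31) * boltz(v, -5.8, -11.2, lit);
  r.tau = (v <= 0.0)
    ? 1000.0 * (1.22e-5 + 0.012 * std::exp(-sq((v + 56.3) / 49.6)))
    : 1000.0 * (0.0012 + 0.0023 * std::exp(-0.141 * v));
  return r;
}
static InfTau g_kmid_m(double v, bool lit) {
  InfTau r;
  r.inf = boltz(v, -24.0, 20.4, lit);
  r.tau = (v < -20.0)
    ? 1000.0 * (0.000688 + 1.0 / (std::exp((v + 64.2) / 6.5) +
                                  std::exp((v - 141.5) / -34.8)))
    : 1000.0 * (0.00016 + 0.0008 * std::exp(-0.0267 * v));
  return r;
}
static InfTau g_kslow_m(double v, bool lit) {
  InfTau r;
  r.inf = boltz(v, -16.5, 18.4, lit);
  r.tau = 1000.0 * (0.000796 + 1.0 / (std::exp((v + 73.2) / 11.7) +
                                      std::exp((v - 306.7) / -74.2)));
  return r;
}
static InfTau g_caps_m(double v, bool lit) {
  InfTau r;
  r.inf = boltz(v, -19.0, 5.5, lit);
  r.tau = (v <= -50.0)
    ? 1000.0 * (0.000264 + 0.128 * std::exp(0.103 * v))
    : 1000.0 * (0.000191 + 0.00376 * std::exp(-sq((v + 11.9) / 27.8)));
  return r;
}
static InfTau g_ihs_m(double v, bool lit) {
  InfTau r;
  r.inf = boltz(v, -90.1, -9.9, lit);
  r.tau = 1000.0 * (0.19 + 0.72 * std::exp(-sq((v + 81.5) / 11.9)));
  return r;
}
static InfTau g_bks_m(double v, bool lit) {
  InfTau r;
  r.inf = boltz(v, -28.9, 6.2, lit);
  r.tau = 1000.0 * (0.000505 + 1.0 / (std::exp((v + 86.4) / 10.1) +
                                      std::exp((v - 33.3) / -10.0)));
  return r;
}
static InfTau g_bks_h(double v, bool lit) {
  InfTau r;
  r.inf = 0.085 + (1.0 - 0.085) * boltz(v, -32.0, -5.8, lit);
  r.tau = 1000.0 * (0.0019 + 1.0 / (std::exp((v + 48.5) / 5.2) +
                                    std::exp((v - 54.2) / -12.9)));
  return r;
}
static InfTau g_bks_z(double ca) {
  InfTau r; r.inf = 1.0 / (1.0 + 0.001 / ca); r.tau = 1.0; return r;
}
// SK activation is an instantaneous function of somatic [Ca2+]
static inline double sk_z(double ca) {
  double q = 0.00019 / ca;
  return 1.0 / (1.0 + q * q * q * q);
}

// --- dendrite (alpha/beta are per-ms as tabulated) -------------------------

static InfTau g_cat_m(double v) {
  double a = 2.6 / (1.0 + std::exp(-(v + 21.0) / 8.0));
  double b = 0.18 / (1.0 + std::exp((v + 40.0) / 4.0));
  InfTau r; r.inf = a / (a + b); r.tau = 1.0 / ((a + b) * MT3); return r;
}
static InfTau g_cat_h(double v) {
  double a = 0.0025 / (1.0 + std::exp((v + 40.0) / 8.0));
  double b = 0.19 / (1.0 + std::exp(-(v + 50.0) / 10.0));
  InfTau r; r.inf = a / (a + b); r.tau = 1.0 / ((a + b) * MT3); return r;
}
static InfTau g_cae_m(double v) {
  double a = 2.6 / (1.0 + std::exp(-(v + 7.0) / 8.0));
  double b = 0.18 / (1.0 + std::exp((v + 26.0) / 4.0));
  // update factor 1-exp(-dt*mt*(a+b)/4) => effective tau = 4/((a+b)*mt)
  InfTau r; r.inf = a / (a + b); r.tau = 4.0 / ((a + b) * MT3); return r;
}
static InfTau g_cae_h(double v) {
  double a = 0.0025 / (1.0 + std::exp((v + 32.0) / 8.0));
  double b = 0.19 / (1.0 + std::exp(-(v + 42.0) / 10.0));
  InfTau r; r.inf = a / (a + b); r.tau = 10.0 / ((a + b) * MT3); return r;
}
static InfTau g_capd_m(double v) {
  double a = 8.5 / (1.0 + std::exp(-(v - 8.0) / 12.5));
  double b = 35.0 / (1.0 + std::exp((v + 74.0) / 14.5));
  InfTau r; r.inf = a / (a + b); r.tau = 1.0 / ((a + b) * MT3); return r;
}
static InfTau g_ihd_m(double v) {
  InfTau r;
  r.inf = 1.0 / (1.0 + std::exp((v + 84.1) / 10.2));
  r.tau = 1.0 / (std::exp(-17.9 - 0.116 * v) + std::exp(-1.84 + 0.09 * v))
          + 100.0;
  return r;
}
static InfTau g_kv12_m(double v) {
  double a = 0.12899 * std::exp((v + 45.0) / 33.90877);
  double b = 0.12899 * std::exp(-(v + 45.0) / 12.42101);
  InfTau r; r.inf = a / (a + b); r.tau = 1.0 / ((a + b) * MTK); return r;
}
static InfTau g_ka_m(double v) {
  double a = 1.4 / (1.0 + std::exp(-(v + 27.0) / 12.0));
  double b = 0.49 / (1.0 + std::exp((v + 30.0) / 4.0));
  InfTau r; r.inf = a / (a + b); r.tau = 1.0 / ((a + b) * MT3); return r;
}
static InfTau g_ka_h(double v) {
  double a = 0.00175 / (1.0 + std::exp((v + 50.0) / 8.0));
  double b = 0.49 / (1.0 + std::exp(-(v + 13.0) / 10.0));
  InfTau r; r.inf = a / (a + b); r.tau = 1.0 / ((a + b) * MT3); return r;
}
static InfTau g_km_m(double v) {
  InfTau r;
  r.inf = 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0));
  r.tau = (1000.0 / FT23) /
          (3.3 * (std::exp((v + 35.0) / 40.0) + std::exp(-(v + 35.0) / 20.0)));
  return r;
}
static InfTau g_kd_m(double v) {
  double a = 8.5 / (1.0 + std::exp(-(v + 17.0) / 12.5));
  double b = 35.0 / (1.0 + std::exp((v + 99.0) / 14.5));
  InfTau r; r.inf = a / (a + b); r.tau = 10.0 / ((a + b) * MT3); return r;
}
static InfTau g_kd_h(double v) {
  double a = 0.0015 / (1.0 + std::exp((v + 89.0) / 8.0));
  double b = 0.0055 / (1.0 + std::exp(-(v + 83.0) / 8.0));
  InfTau r; r.inf = a / (a + b); r.tau = 1.0 / ((a + b) * MT3 * 1.6); return r;
}
// delayed rectifier alpha with removable singularity at v = -55 mV
static inline double dr_vtrap(double v) {
  double x = -(v + 55.0);
  if (std::fabs(x / 10.0) < 1e-6) return 10.0 * (1.0 - (x / 10.0) / 2.0);
  return x / (std::exp(x / 10.0) - 1.0);
}
static InfTau g_dr_m(double v) {
  double a = 0.1 * dr_vtrap(v);
  double b = 0.125 * std::exp(-(v + 65.0) / 80.0);
  InfTau r; r.inf = a / (a + b); r.tau = 1.0 / ((a + b) * MT3); return r;
}
static InfTau g_bkd_m(double v) {
  double a = 7.5;
  double b = 0.11 * std::exp(-(v - 35.0) / 14.9);
  InfTau r; r.inf = a / (a + b); r.tau = 1.0 / (a + b); return r;
}
static InfTau g_bkd_z(double ca) {
  // alpha_z = 1, beta_z = 400/(1000*[Ca]); tau_z fixed at 10 ms
  InfTau r; r.inf = 1.0 / (1.0 + 0.4 / ca); r.tau = 10.0; return r;
}
static InfTau g_k2_m(double v) {
  double a = 25.0;
  double b = 0.075 * std::exp(-(v + 5.0) / 10.0);
  InfTau r; r.inf = a / (a + b); r.tau = 1.0 / (a + b); return r;
}
static InfTau g_k2_z(double ca) {
  InfTau r; r.inf = 1.0 / (1.0 + 0.02 / ca); r.tau = 10.0; return r;
}
static InfTau g_erg_m(double v, double vhalf) {
  InfTau r;
  r.inf = 1.0 / (1.0 + std::exp(-(v - vhalf) / 5.0));
  r.tau = 1.0 / (0.00225 * std::exp(0.12 * v) + 0.00004 * std::exp(-0.05 * v));
  return r;
}
static InfTau g_erg_h(double v) {
  InfTau r;
  r.inf = 1.0 / (1.0 + std::exp((v + 70.0) / 20.0));
  r.tau = 1.0 / (0.1 * std::exp(0.02 * v) + 0.003 * std::exp(-0.03 * v));
  return r;
}

// [[Rcpp::export(name = ".cpp_gate_inf_tau")]]
NumericVector cpp_gate_inf_tau(std::string current, std::string gate,
                               double v, double ca = NA_REAL,
                               bool literal = false,
                               double erg_vhalf = -5.0) {
  InfTau r; bool ok = true;
  if (current == "K_fast") {
    if (gate == "m") r = g_kfast_m(v, literal);
    else if (gate == "h") r = g_kfast_h(v, literal);
    else ok = false;
  } else if (current == "K_mid") { if (gate == "m") r = g_kmid_m(v, literal); else ok = false; }
  else if (current == "K_slow") { if (gate == "m") r = g_kslow_m(v, literal); else ok = false; }
  else if (current == "CaP_s")  { if (gate == "m") r = g_caps_m(v, literal); else ok = false; }
  else if (current == "Ih_s")   { if (gate == "m") r = g_ihs_m(v, literal); else ok = false; }
  else if (current == "BK_s") {
    if (gate == "m") r = g_bks_m(v, literal);
    else if (gate == "h") r = g_bks_h(v, literal);
    else if (gate == "z") {
      if (!R_finite(ca)) stop("gate BK_s/z requires a Ca concentration");
      r = g_bks_z(ca);
    } else ok = false;
  } else if (current == "SK") {
    if (gate == "z") {
      if (!R_finite(ca)) stop("gate SK/z requires a Ca concentration");
      r.inf = sk_z(ca); r.tau = 0.0;  // instantaneous
    } else ok = false;
  }
  else if (current == "CaT") { if (gate == "m") r = g_cat_m(v); else if (gate == "h") r = g_cat_h(v); else ok = false; }
  else if (current == "CaE") { if (gate == "m") r = g_cae_m(v); else if (gate == "h") r = g_cae_h(v); else ok = false; }
  else if (current == "CaP_d") { if (gate == "m") r = g_capd_m(v); else ok = false; }
  else if (current == "Ih_d")  { if (gate == "m") r = g_ihd_m(v); else ok = false; }
  else if (current == "Kv12")  { if (gate == "m") r = g_kv12_m(v); else ok = false; }
  else if (current == "KA") { if (gate == "m") r = g_ka_m(v); else if (gate == "h") r = g_ka_h(v); else ok = false; }
  else if (current == "KM") { if (gate == "m") r = g_km_m(v); else ok = false; }
  else if (current == "KD") { if (gate == "m") r = g_kd_m(v); else if (gate == "h") r = g_kd_h(v); else ok = false; }
  else if (current == "DR") { if (gate == "m") r = g_dr_m(v); else ok = false; }
  else if (current == "BK_d") {
    if (gate == "m") r = g_bkd_m(v);
    else if (gate == "z") {
      if (!R_finite(ca)) stop("gate BK_d/z requires a Ca concentration");
      r = g_bkd_z(ca);
    } else ok = false;
  } else if (current == "K2") {
    if (gate == "m") r = g_k2_m(v);
    else if (gate == "z") {
      if (!R_finite(ca)) stop("gate K2/z requires a Ca concentration");
      r = g_k2_z(ca);
    } else ok = false;
  } else if (current == "ERG") {
    if (gate == "m") r = g_erg_m(v, erg_vhalf);
    else if (gate == "h") r = g_erg_h(v);
    else ok = false;
  } else stop("unknown current id '" + current + "'");
  if (!ok) stop("unknown gate '" + gate + "' for current '" + current + "'");
  return NumericVector::create(_["inf"] = r.inf, _["tau"] = r.tau);
}

// ---------------------------------------------------------------------------
// GHK flux for the somatic P-type Ca2+ current.  Fixed [Ca]i = 100 nM,
// [Ca]o = 2 mM, T = 295 K, P = 5e-5 cm/s, z = 2.  Returns mA/cm2.

static const double GHK_P  = 5e-5;   // cm/s
static const double GHK_CI = 1e-4;   // mM
static const double GHK_CO = 2.0;    // mM
static const double GHK_T  = 295.0;  // K

static double ghk_flux_impl(double v_mv, double perm) {
  if (perm == 0.0) return 0.0;
  double vv = v_mv * 1e-3;                       // volts
  double u  = 2.0 * FARADAY * vv / (RGAS * GHK_T);
  if (std::fabs(u) < 1e-9) {
    // L'Hopital limit at V = 0: 2*P*F*([Ca]i - [Ca]o)
    return 1e-3 * perm * 2.0 * FARADAY * (GHK_CI - GHK_CO);
  }
  double num = GHK_CI - GHK_CO * std::exp(-u);
  double den = -std::expm1(-u);
  return 1e-3 * perm * 4.0 * FARADAY * FARADAY * vv / (RGAS * GHK_T)
         * num / den;
}

// [[Rcpp::export(name = ".cpp_ghk_flux")]]
double cpp_ghk_flux(double v_mv, double perm = 5e-5) {
  return ghk_flux_impl(v_mv, perm);
}

// ---------------------------------------------------------------------------
// Markov resurgent Na+ scheme: states C1-C5, O, OB, I1-I6 (13 states).

enum { ST_C1, ST_C2, ST_C3, ST_C4, ST_C5, ST_O, ST_OB,
       ST_I1, ST_I2, ST_I3, ST_I4, ST_I5, ST_I6, NSTATE };

struct MarkovRates {
  double alpha, beta, gamma, delta, Con, Coff, Oon, Ooff, a, b, eps, zeta;
};

static MarkovRates markov_rates_impl(double v) {
  MarkovRates r;
  r.alpha = 150.0 * std::exp(v / 20.0);
  r.beta  = 3.0 * std::exp(-v / 20.0);
  r.gamma = 150.0; r.delta = 40.0;
  r.Con = 0.005; r.Coff = 0.5; r.Oon = 0.75; r.Ooff = 0.005;
  r.a = std::pow(r.Oon / r.Con, 0.25);
  r.b = std::pow(r.Ooff / r.Coff, 0.25);
  r.eps = 1.75;
  r.zeta = 0.03 * std::exp(-v / 25.0);
  return r;
}

// fill the 13x13 generator M (dx/dt = M x); M[to][from] += rate, column
// sums are zero.
static void markov_fill(double v, double M[NSTATE][NSTATE]) {
  MarkovRates r = markov_rates_impl(v);
  for (int i = 0; i < NSTATE; ++i)
    for (int j = 0; j < NSTATE; ++j) M[i][j] = 0.0;
  auto add = [&](int from, int to, double rate) {
    M[to][from] += rate;
    M[from][from] -= rate;
  };
  const double a = r.alpha, b = r.beta, A = r.a, B = r.b;
  // activation pathway among closed states
  add(ST_C1, ST_C2, 4.0 * a); add(ST_C2, ST_C1, 1.0 * b);
  add(ST_C2, ST_C3, 3.0 * a); add(ST_C3, ST_C2, 2.0 * b);
  add(ST_C3, ST_C4, 2.0 * a); add(ST_C4, ST_C3, 3.0 * b);
  add(ST_C4, ST_C5, 1.0 * a); add(ST_C5, ST_C4, 4.0 * b);
  add(ST_C5, ST_O,  r.gamma); add(ST_O,  ST_C5, r.delta);
  // open-channel block
  add(ST_O, ST_OB, r.eps);    add(ST_OB, ST_O, r.zeta);
  // inactivation from open
  add(ST_O, ST_I6, r.Oon);    add(ST_I6, ST_O, r.Ooff);
  // inactivation from closed states (allosteric factors a^n, b^n)
  double fA = 1.0, fB = 1.0;
  int cs[5] = { ST_C1, ST_C2, ST_C3, ST_C4, ST_C5 };
  int is[5] = { ST_I1, ST_I2, ST_I3, ST_I4, ST_I5 };
  for (int k = 0; k < 5; ++k) {
    add(cs[k], is[k], r.Con * fA);
    add(is[k], cs[k], r.Coff * fB);
    fA *= A; fB *= B;
  }
  // activation pathway among inactivated states (scaled by a, b)
  add(ST_I1, ST_I2, 4.0 * a * A); add(ST_I2, ST_I1, 1.0 * b * B);
  add(ST_I2, ST_I3, 3.0 * a * A); add(ST_I3, ST_I2, 2.0 * b * B);
  add(ST_I3, ST_I4, 2.0 * a * A); add(ST_I4, ST_I3, 3.0 * b * B);
  add(ST_I4, ST_I5, 1.0 * a * A); add(ST_I5, ST_I4, 4.0 * b * B);
  add(ST_I5, ST_I6, r.gamma);     add(ST_I6, ST_I5, r.delta);
}

// backward-Euler step: solve (I - dt M) x' = x, then renormalize.
static void markov_be_step(double x[NSTATE], double v, double dt) {
  if (dt == 0.0) return;
  double M[NSTATE][NSTATE];
  markov_fill(v, M);
  double Amat[NSTATE][NSTATE + 1];
  for (int i = 0; i < NSTATE; ++i) {
    for (int j = 0; j < NSTATE; ++j)
      Amat[i][j] = (i == j ? 1.0 : 0.0) - dt * M[i][j];
    Amat[i][NSTATE] = x[i];
  }
  // Gaussian elimination with partial pivoting
  for (int c = 0; c < NSTATE; ++c) {
    int p = c;
    for (int i2 = c + 1; i2 < NSTATE; ++i2)
      if (std::fabs(Amat[i2][c]) > std::fabs(Amat[p][c])) p = i2;
    if (p != c)
      for (int j = c; j <= NSTATE; ++j) std::swap(Amat[c][j], Amat[p][j]);
    double piv = Amat[c][c];
    for (int i2 = c + 1; i2 < NSTATE; ++i2) {
      double f = Amat[i2][c] / piv;
      if (f == 0.0) continue;
      for (int j = c; j <= NSTATE; ++j) Amat[i2][j] -= f * Amat[c][j];
    }
  }
  for (int i = NSTATE - 1; i >= 0; --i) {
    double s = Amat[i][NSTATE];
    for (int j = i + 1; j < NSTATE; ++j) s -= Amat[i][j] * x[j];
    x[i] = s / Amat[i][i];
  }
  // occupancy conservation: clip tiny negatives, renormalize
  double tot = 0.0;
  for (int i = 0; i < NSTATE; ++i) { if (x[i] < 0.0) x[i] = 0.0; tot += x[i]; }
  for (int i = 0; i < NSTATE; ++i) x[i] /= tot;
}

// [[Rcpp::export(name = ".cpp_markov_rates")]]
NumericVector cpp_markov_rates(double v) {
  MarkovRates r = markov_rates_impl(v);
  return NumericVector::create(
    _["alpha"] = r.alpha, _["beta"] = r.beta, _["gamma"] = r.gamma,
    _["delta"] = r.delta, _["Con"] = r.Con, _["Coff"] = r.Coff,
    _["Oon"] = r.Oon, _["Ooff"] = r.Ooff, _["a"] = r.a, _["b"] = r.b,
    _["eps"] = r.eps, _["zeta"] = r.zeta);
}

static CharacterVector markov_state_names() {
  return CharacterVector::create("C1", "C2", "C3", "C4", "C5", "O", "OB",
                                 "I1", "I2", "I3", "I4", "I5", "I6");
}

// [[Rcpp::export(name = ".cpp_markov_qmatrix")]]
NumericMatrix cpp_markov_qmatrix(double v) {
  double M[NSTATE][NSTATE];
  markov_fill(v, M);
  NumericMatrix out(NSTATE, NSTATE);
  for (int i = 0; i < NSTATE; ++i)
    for (int j = 0; j < NSTATE; ++j) out(i, j) = M[i][j];
  out.attr("dimnames") = List::create(markov_state_names(),
                                      markov_state_names());
  return out;
}

// [[Rcpp::export(name = ".cpp_markov_step")]]
NumericVector cpp_markov_step(NumericVector state, double v, double dt) {
  if (state.size() != NSTATE) stop("Markov state must have 13 entries");
  double x[NSTATE];
  for (int i = 0; i < NSTATE; ++i) x[i] = state[i];
  markov_be_step(x, v, dt);
  NumericVector out(NSTATE);
  for (int i = 0; i < NSTATE; ++i) out[i] = x[i];
  out.names() = markov_state_names();
  return out;
}

// ---------------------------------------------------------------------------
// pumps (inputs in mA/cm2, outputs in uA/cm2)

static double soma_pump_impl(double v, double na, double d_pump, double kna) {
  double vv = v + 80.0;
  // narrow guard around the printed singularity at V = -80 mV
  if (std::fabs(vv) < 0.01) vv = (vv >= 0.0 ? 0.01 : -0.01);
  double e = kna - na;
  if (e > 500.0) return 0.0;  // pump fully off, avoid overflow
  return 1000.0 * d_pump * (v + 75.0) / (vv * (1.0 + std::exp(e)));
}

// slope conductance d(i_pump)/dV (mS/cm2), used to fold the pump's sharp
// voltage dependence into the implicit voltage update; always >= 0 since
// d/dV[(V+75)/(V+80)] = 5/(V+80)^2
static double soma_pump_slope(double v, double na, double d_pump,
                              double kna) {
  double vv = v + 80.0;
  if (std::fabs(vv) < 0.01) vv = (vv >= 0.0 ? 0.01 : -0.01);
  double e = kna - na;
  if (e > 500.0) return 0.0;
  return 1000.0 * d_pump * 5.0 / (vv * vv * (1.0 + std::exp(e)));
}

static double dend_pump_impl(double ko, double d_pump) {
  return 1000.0 * d_pump / (1.0 + 2.245 / ko);
}

// [[Rcpp::export(name = ".cpp_soma_pump")]]
double cpp_soma_pump(double v, double na, double d_pump, double kna) {
  return soma_pump_impl(v, na, d_pump, kna);
}

// [[Rcpp::export(name = ".cpp_dend_pump")]]
double cpp_dend_pump(double ko, double d_pump) {
  return dend_pump_impl(ko, d_pump);
}

// ---------------------------------------------------------------------------
// single ion-pool steps (exported for unit-level verification; the
// simulation loop uses the same code)

// somatic sub-membrane shell: dCa/dt = -(1e4)*I[mA/cm2]/(2 F depth) - beta*Ca
static double step_soma_ca_impl(double ca, double i_ca_uA, double dt,
                                double depth_um, double beta) {
  double dca = -(10.0) * i_ca_uA / (2.0 * FARADAY * depth_um) - beta * ca;
  ca += dt * dca;
  if (ca < 1e-4) ca = 1e-4;  // 100 nM floor
  return ca;
}

// dendritic shell with saturable extrusion and relaxation to rest
static double step_dend_ca_impl(double ca, double i_ca_uA, double dt,
                                double depth_um, double kt, double kd,
                                double tau_r, double y) {
  double chan = -(10.0) * i_ca_uA / (2.0 * FARADAY * depth_um);
  if (chan < 0.0) chan = 0.0;  // influx only
  double dca = chan - kt * ca / (ca + kd) + (y - ca) / tau_r;
  return ca + dt * dca;
}

// [[Rcpp::export(name = ".cpp_step_soma_ca")]]
double cpp_step_soma_ca(double ca, double i_ca_uA, double dt,
                        double depth_um = 0.1, double beta = 1.0) {
  return step_soma_ca_impl(ca, i_ca_uA, dt, depth_um, beta);
}

// [[Rcpp::export(name = ".cpp_step_dend_ca")]]
double cpp_step_dend_ca(double ca, double i_ca_uA, double dt, double depth_um,
                        double kt = 4e-5, double kd = 4e-5,
                        double tau_r = 2.0, double y = 4e-5) {
  return step_dend_ca_impl(ca, i_ca_uA, dt, depth_um, kt, kd, tau_r, y);
}

// extracellular K+ shell: dKo/dt = Q * I_K_net[uA/cm2] / (F * wid)
static double step_k_o_impl(double ko, double i_out, double i_in, double dt,
                            double Q, double wid, double komin, double komax) {
  ko += dt * Q * (i_out - i_in) / (FARADAY * wid);
  if (ko > komax) ko = komax;
  if (ko < komin) ko = komin;
  return ko;
}

// [[Rcpp::export(name = ".cpp_step_k_o")]]
double cpp_step_k_o(double ko, double i_out, double i_in, double dt,
                    double Q = 0.0119, double wid = 0.07,
                    double komin = 2.0, double komax = 3.03) {
  return step_k_o_impl(ko, i_out, i_in, dt, Q, wid, komin, komax);
}

// fixed-capacity FIFO delay line, pre-filled with zeros; reads return the
// sample from exactly tau earlier.  The simulation loop uses this class.
struct DelayLine {
  std::vector<double> buf;
  size_t pos;
  DelayLine(double tau_ms, double dt_ms) : pos(0) {
    size_t n = (size_t) std::lround(tau_ms / dt_ms);
    if (n < 1) n = 1;
    buf.assign(n, 0.0);
  }
  double push(double x) {
    double out = buf[pos];
    buf[pos] = x;
    pos = (pos + 1) % buf.size();
    return out;
  }
};

// [[Rcpp::export(name = ".cpp_delay_line")]]
NumericVector cpp_delay_line(NumericVector x, double tau_ms, double dt_ms) {
  DelayLine d(tau_ms, dt_ms);
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = d.push(x[i]);
  return out;
}

// ---------------------------------------------------------------------------
// full model state and stepping

struct Pars {
  // conductances, mS/cm2
  double gNaR, gKfast, gKmid, gKslow, gCaPs, gIhs, gBKs, gSK, gLs;
  double gCaT, gCaE, gCaPd, gIhd, gKv12, gKA, gKM, gKD, gDR, gBKd, gK2,
         gLd, gERG;
  double erg_vhalf;
  double ghk_perm;           // cm/s
  // reversal potentials, mV
  double EKs, ELs, EhS, ECad, ELd, EhD;
  double na_o, k_i;          // mM (Nernst closures)
  // capacitance uF/cm2
  double cm_s, cm_d;
  // geometry
  double area_s_cm2, area_d_cm2, r_coupling_Mohm, soma_diam_um;
  // pumps/exchangers, mA/cm2
  double d_pump_s, d_pump_d, g_ex_s, g_pump_s, g_ex_d, g_pump_d, kna;
  // ion dynamics
  double depth_s, beta_s;                    // soma Ca shell
  double depth_d, kt, kd, tau_r, ca_y;       // dendrite Ca shell (depth scaled by Cd)
  double tau_na_ms;                          // Na+ feedback lag
  double Qk, wid, ko_min, ko_max;            // extracellular K+
  // alcohol protocol
  bool   alcohol;
  double alc_Y, alc_M, alc_onset_s;
  bool   literal_sigmoid;
};

static double pnum(const List& L, const char* nm) {
  if (!L.containsElementNamed(nm))
    stop(std::string("missing parameter '") + nm + "'");
  return as<double>(L[nm]);
}

static Pars read_pars(const List& L) {
  Pars p;
  p.gNaR = pnum(L, "g_nar"); p.gKfast = pnum(L, "g_kfast");
  p.gKmid = pnum(L, "g_kmid"); p.gKslow = pnum(L, "g_kslow");
  p.gCaPs = pnum(L, "g_cap_s"); p.gIhs = pnum(L, "g_ih_s");
  p.gBKs = pnum(L, "g_bk_s"); p.gSK = pnum(L, "g_sk");
  p.gLs = pnum(L, "g_leak_s");
  p.gCaT = pnum(L, "g_cat"); p.gCaE = pnum(L, "g_cae");
  p.gCaPd = pnum(L, "g_cap_d"); p.gIhd = pnum(L, "g_ih_d");
  p.gKv12 = pnum(L, "g_kv12"); p.gKA = pnum(L, "g_ka");
  p.gKM = pnum(L, "g_km"); p.gKD = pnum(L, "g_kd");
  p.gDR = pnum(L, "g_dr"); p.gBKd = pnum(L, "g_bk_d");
  p.gK2 = pnum(L, "g_k2"); p.gLd = pnum(L, "g_leak_d");
  p.gERG = pnum(L, "g_erg"); p.erg_vhalf = pnum(L, "erg_vhalf");
  p.ghk_perm = pnum(L, "ghk_perm");
  p.EKs = pnum(L, "e_k_soma"); p.ELs = pnum(L, "e_leak_s");
  p.EhS = pnum(L, "e_h_s"); p.ECad = pnum(L, "e_ca_d");
  p.ELd = pnum(L, "e_leak_d"); p.EhD = pnum(L, "e_h_d");
  p.na_o = pnum(L, "na_o"); p.k_i = pnum(L, "k_i");
  p.cm_s = pnum(L, "cm_s"); p.cm_d = pnum(L, "cm_d");
  p.area_s_cm2 = pnum(L, "area_s_cm2");
  p.area_d_cm2 = pnum(L, "area_d_cm2");
  p.r_coupling_Mohm = pnum(L, "r_coupling_Mohm");
  p.soma_diam_um = pnum(L, "soma_diam_um");
  p.d_pump_s = pnum(L, "d_pump_s"); p.d_pump_d = pnum(L, "d_pump_d");
  p.g_ex_s = pnum(L, "g_ex_s"); p.g_pump_s = pnum(L, "g_pump_s");
  p.g_ex_d = pnum(L, "g_ex_d"); p.g_pump_d = pnum(L, "g_pump_d");
  p.kna = pnum(L, "k_na");
  p.depth_s = pnum(L, "depth_s"); p.beta_s = pnum(L, "beta_ca_s");
  p.depth_d = pnum(L, "depth_d"); p.kt = pnum(L, "ca_kt");
  p.kd = pnum(L, "ca_kd"); p.tau_r = pnum(L, "ca_tau_r");
  p.ca_y = pnum(L, "ca_y");
  p.tau_na_ms = pnum(L, "tau_na_s") * 1000.0;
  p.Qk = pnum(L, "k_acc_q"); p.wid = pnum(L, "k_wid");
  p.ko_min = pnum(L, "ko_min"); p.ko_max = pnum(L, "ko_max");
  p.alcohol = as<bool>(L["alcohol"]);
  p.alc_Y = pnum(L, "alc_y"); p.alc_M = pnum(L, "alc_m");
  p.alc_onset_s = pnum(L, "alc_onset_s");
  p.literal_sigmoid = as<bool>(L["literal_sigmoid"]);
  return p;
}

// gate layout in the state vector
enum {
  G_KFAST_M, G_KFAST_H, G_KMID_M, G_KSLOW_M, G_CAPS_M, G_IHS_M,
  G_BKS_M, G_BKS_H, G_BKS_Z,
  G_CAT_M, G_CAT_H, G_CAE_M, G_CAE_H, G_CAPD_M, G_IHD_M, G_KV12_M,
  G_KA_M, G_KA_H, G_KM_M, G_KD_M, G_KD_H, G_DR_M, G_BKD_M, G_BKD_Z,
  G_K2_M, G_K2_Z, G_ERG_M, G_ERG_H, NGATE
};

// [[Rcpp::export(name = ".cpp_gate_names")]]
CharacterVector cpp_gate_names() {
  return CharacterVector::create(
    "kfast_m", "kfast_h", "kmid_m", "kslow_m", "caps_m", "ihs_m",
    "bks_m", "bks_h", "bks_z",
    "cat_m", "cat_h", "cae_m", "cae_h", "capd_m", "ihd_m", "kv12_m",
    "ka_m", "ka_h", "km_m", "kd_m", "kd_h", "dr_m", "bkd_m", "bkd_z",
    "k2_m", "k2_z", "erg_m", "erg_h");
}

static inline void relax(double& x, const InfTau& it, double dt) {
  x += (1.0 - std::exp(-dt / it.tau)) * (it.inf - x);
}

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(List pars, List init, double dt, double duration_ms,
                  int stride, bool record_ions) {
  Pars P = read_pars(pars);
  const bool lit = P.literal_sigmoid;
  double vs = as<double>(init["v_soma"]);
  double vd = as<double>(init["v_dend"]);
  NumericVector g0 = init["gates"];
  if (g0.size() != NGATE) stop("gate vector must have %d entries", NGATE);
  double g[NGATE];
  for (int i = 0; i < NGATE; ++i) g[i] = g0[i];
  NumericVector mk0 = init["markov"];
  if (mk0.size() != NSTATE) stop("Markov state must have 13 entries");
  double mk[NSTATE];
  for (int i = 0; i < NSTATE; ++i) mk[i] = mk0[i];
  double ca_s = as<double>(init["ca_soma"]);
  double ca_d = as<double>(init["ca_dend"]);
  double na_i = as<double>(init["na_i"]);
  double k_o  = as<double>(init["k_o"]);

  const double RTF = rtf_mv();
  double e_na = RTF * std::log(P.na_o / na_i);
  if (e_na < 70.0) e_na = 70.0;
  double e_kd = RTF * std::log(k_o / P.k_i);

  // axial coupling expressed as a conductance density for each compartment
  const double cax_s = 1e-3 / (P.r_coupling_Mohm * P.area_s_cm2); // mS/cm2
  const double cax_d = 1e-3 / (P.r_coupling_Mohm * P.area_d_cm2);
  const double kna_coef = 40.0 / (FARADAY * P.soma_diam_um); // mM/ms per uA/cm2
  const double gex_s_uA = 1000.0 * P.g_ex_s;

  DelayLine na_hist(P.tau_na_ms, dt);

  long nsteps = (long) std::llround(duration_ms / dt);
  if (nsteps < 0) stop("negative duration");
  long nrec = nsteps / stride + 1;

  NumericVector ot(nrec), ovs(nrec), ovd(nrec);
  NumericVector ocas, ocad, onai, oko, oena, oekd, oopen;
  if (record_ions) {
    ocas = NumericVector(nrec); ocad = NumericVector(nrec);
    onai = NumericVector(nrec); oko = NumericVector(nrec);
    oena = NumericVector(nrec); oekd = NumericVector(nrec);
    oopen = NumericVector(nrec);
  }

  long irec = 0;
  auto record = [&](long step) {
    ot[irec] = step * dt; ovs[irec] = vs; ovd[irec] = vd;
    if (record_ions) {
      ocas[irec] = ca_s; ocad[irec] = ca_d; onai[irec] = na_i;
      oko[irec] = k_o; oena[irec] = e_na; oekd[irec] = e_kd;
      oopen[irec] = mk[ST_O];
    }
    ++irec;
  };
  record(0);

  for (long step = 1; step <= nsteps; ++step) {
    double t_ms = step * dt;
    double t_s  = (t_ms - dt) / 1000.0;   // protocol clock at start of step

    // --- time-dependent pump densities (alcohol block ramp) ---------------
    double dps = P.d_pump_s, dpd = P.d_pump_d;
    double gps = P.g_pump_s, gpd = P.g_pump_d;
    if (P.alcohol) {
      dps = P.d_pump_s - P.alc_Y * t_s;
      if (dps < 0.0) dps = 0.0;
      if (t_s > P.alc_onset_s) {
        dpd = P.d_pump_d - P.alc_M * t_s; if (dpd < 0.0) dpd = 0.0;
        gps = P.g_pump_s - P.alc_M * t_s; if (gps < 0.0) gps = 0.0;
        gpd = P.g_pump_d - P.alc_M * t_s; if (gpd < 0.0) gpd = 0.0;
      }
    }

    // --- (1) gates and Markov chain at old voltages -----------------------
    relax(g[G_KFAST_M], g_kfast_m(vs, lit), dt);
    relax(g[G_KFAST_H], g_kfast_h(vs, lit), dt);
    relax(g[G_KMID_M],  g_kmid_m(vs, lit), dt);
    relax(g[G_KSLOW_M], g_kslow_m(vs, lit), dt);
    relax(g[G_CAPS_M],  g_caps_m(vs, lit), dt);
    relax(g[G_IHS_M],   g_ihs_m(vs, lit), dt);
    relax(g[G_BKS_M],   g_bks_m(vs, lit), dt);
    relax(g[G_BKS_H],   g_bks_h(vs, lit), dt);
    relax(g[G_BKS_Z],   g_bks_z(ca_s), dt);
    relax(g[G_CAT_M],   g_cat_m(vd), dt);
    relax(g[G_CAT_H],   g_cat_h(vd), dt);
    relax(g[G_CAE_M],   g_cae_m(vd), dt);
    relax(g[G_CAE_H],   g_cae_h(vd), dt);
    relax(g[G_CAPD_M],  g_capd_m(vd), dt);
    relax(g[G_IHD_M],   g_ihd_m(vd), dt);
    relax(g[G_KV12_M],  g_kv12_m(vd), dt);
    relax(g[G_KA_M],    g_ka_m(vd), dt);
    relax(g[G_KA_H],    g_ka_h(vd), dt);
    relax(g[G_KM_M],    g_km_m(vd), dt);
    relax(g[G_KD_M],    g_kd_m(vd), dt);
    relax(g[G_KD_H],    g_kd_h(vd), dt);
    relax(g[G_DR_M],    g_dr_m(vd), dt);
    relax(g[G_BKD_M],   g_bkd_m(vd), dt);
    relax(g[G_BKD_Z],   g_bkd_z(ca_d), dt);
    relax(g[G_K2_M],    g_k2_m(vd), dt);
    relax(g[G_K2_Z],    g_k2_z(ca_d), dt);
    if (P.gERG > 0.0) {
      relax(g[G_ERG_M], g_erg_m(vd, P.erg_vhalf), dt);
      relax(g[G_ERG_H], g_erg_h(vd), dt);
    }
    markov_be_step(mk, vs, dt);
    double zsk = sk_z(ca_s);

    // --- (2) conductances and non-ohmic currents at old voltages ----------
    // soma (effective conductances, mS/cm2)
    double cKfast = P.gKfast * g[G_KFAST_M] * g[G_KFAST_M] * g[G_KFAST_M]
                    * g[G_KFAST_H];
    double m4;
    m4 = sq(sq(g[G_KMID_M]));  double cKmid = P.gKmid * m4;
    m4 = sq(sq(g[G_KSLOW_M])); double cKslow = P.gKslow * m4;
    double cBKs = P.gBKs * g[G_BKS_M] * g[G_BKS_M] * g[G_BKS_M]
                  * sq(g[G_BKS_Z]) * g[G_BKS_H];
    double cIhs = P.gIhs * g[G_IHS_M];
    double cSK = P.gSK * zsk;
    double cNaR = P.gNaR * mk[ST_O];
    double i_caps = P.gCaPs * g[G_CAPS_M] * 1000.0
                    * ghk_flux_impl(vs, P.ghk_perm);   // uA/cm2
    double i_pump_s = soma_pump_impl(vs, na_i, dps, P.kna);
    double g_pump_lin = soma_pump_slope(vs, na_i, dps, P.kna);
    double i_nar_old = cNaR * (vs - e_na);             // for the Na+ book

    double Gs = cKfast + cKmid + cKslow + cBKs + cIhs + cSK + cNaR + P.gLs
                + g_pump_lin;
    double Ds = (cKfast + cKmid + cKslow + cBKs + cSK) * P.EKs
                + cIhs * P.EhS + cNaR * e_na + P.gLs * P.ELs
                + g_pump_lin * vs;
    double bs = i_caps + i_pump_s + 1000.0 * (gps - P.g_ex_s);

    // dendrite
    double cCaT = P.gCaT * g[G_CAT_M] * g[G_CAT_H];
    double cCaE = P.gCaE * g[G_CAE_M] * g[G_CAE_H];
    double cCaPd = P.gCaPd * g[G_CAPD_M];
    double cIhd = P.gIhd * g[G_IHD_M];
    m4 = sq(sq(g[G_KV12_M])); double cKv12 = P.gKv12 * m4;
    m4 = sq(sq(g[G_KA_M]));   double cKA = P.gKA * m4 * g[G_KA_H];
    double cKM = P.gKM * g[G_KM_M];
    double cKD = P.gKD * g[G_KD_M] * g[G_KD_H];
    m4 = sq(sq(g[G_DR_M]));   double cDR = P.gDR * m4;
    double cBKd = P.gBKd * g[G_BKD_M] * sq(g[G_BKD_Z]);
    double cK2 = P.gK2 * g[G_K2_M] * sq(g[G_K2_Z]);
    double cERG = P.gERG > 0.0 ? P.gERG * g[G_ERG_M] * g[G_ERG_H] : 0.0;
    double i_pump_d = dend_pump_impl(k_o, dpd);

    double Gd = cCaT + cCaE + cCaPd + cIhd + cKv12 + cKA + cKM + cKD + cDR
                + cBKd + cK2 + cERG + P.gLd;
    double Dd = (cCaT + cCaE + cCaPd) * P.ECad + cIhd * P.EhD
                + (cKv12 + cKA + cKM + cKD + cDR + cBKd + cK2 + cERG) * e_kd
                + P.gLd * P.ELd;
    double bd = i_pump_d + 1000.0 * (gpd - P.g_ex_d);

    // --- (3) implicit 2x2 voltage update ----------------------------------
    double as_ = P.cm_s / dt + Gs + cax_s;
    double bs_ = -cax_s;
    double cs_ = -cax_d;
    double ds_ = P.cm_d / dt + Gd + cax_d;
    double rs_ = P.cm_s / dt * vs + Ds - bs;
    double rd_ = P.cm_d / dt * vd + Dd - bd;
    double det = as_ * ds_ - bs_ * cs_;
    double vs_new = (rs_ * ds_ - bs_ * rd_) / det;
    double vd_new = (as_ * rd_ - cs_ * rs_) / det;

    // --- (4) ion pools (currents at old V, updated gates) -----------------
    ca_s = step_soma_ca_impl(ca_s, i_caps, dt, P.depth_s, P.beta_s);
    double i_ca_d = cCaT * (vd - P.ECad) + cCaE * (vd - P.ECad)
                    + cCaPd * (vd - P.ECad);
    ca_d = step_dend_ca_impl(ca_d, i_ca_d, dt, P.depth_d,
                             P.kt, P.kd, P.tau_r, P.ca_y);

    // Na+ book-keeping: influx (resurgent Na+, exchanger) vs pump efflux,
    // as positive magnitudes, fed through the 5-s delay line
    double na_in  = -i_nar_old + 3.0 * gex_s_uA;
    double na_out = 3.0 * i_pump_s + 3.0 * 1000.0 * gps;
    double na_net_delayed = na_hist.push(na_in - na_out);
    na_i += dt * kna_coef * na_net_delayed;
    if (na_i < 10.0) na_i = 10.0;

    // extracellular K+: gated K+ efflux vs pump uptake
    double i_k_out = cKv12 * (vd - e_kd) + cKA * (vd - e_kd)
                   + cKM * (vd - e_kd) + cKD * (vd - e_kd)
                   + cDR * (vd - e_kd) + cBKd * (vd - e_kd)
                   + cK2 * (vd - e_kd);
    double i_k_in = 2.0 * i_pump_d + 2.0 * 1000.0 * gpd;
    k_o = step_k_o_impl(k_o, i_k_out, i_k_in, dt, P.Qk, P.wid,
                        P.ko_min, P.ko_max);

    // --- (5) reversal-potential refresh -----------------------------------
    e_na = RTF * std::log(P.na_o / na_i);
    if (e_na < 70.0) e_na = 70.0;
    e_kd = RTF * std::log(k_o / P.k_i);

    vs = vs_new; vd = vd_new;

    if (!std::isfinite(vs) || !std::isfinite(vd)) {
      stop("non-finite state at t = %.3f ms (V_soma = %g, V_dend = %g)",
           t_ms, vs, vd);
    }
    if (step % stride == 0) record(step);
  }

  NumericVector gfin(NGATE);
  for (int i = 0; i < NGATE; ++i) gfin[i] = g[i];
  gfin.names() = cpp_gate_names();
  NumericVector mkfin(NSTATE);
  for (int i = 0; i < NSTATE; ++i) mkfin[i] = mk[i];
  mkfin.names() = markov_state_names();
  List fin = List::create(
    _["v_soma"] = vs, _["v_dend"] = vd, _["gates"] = gfin,
    _["markov"] = mkfin, _["ca_soma"] = ca_s, _["ca_dend"] = ca_d,
    _["na_i"] = na_i, _["k_o"] = k_o, _["e_na"] = e_na, _["e_k_dend"] = e_kd);

  List out = List::create(
    _["t_ms"] = ot, _["v_soma"] = ovs, _["v_dend"] = ovd,
    _["final_state"] = fin);
  if (record_ions) {
    out["ca_soma"] = ocas; out["ca_dend"] = ocad; out["na_i"] = onai;
    out["k_o"] = oko; out["e_na"] = oena; out["e_k_dend"] = oekd;
    out["o_nar"] = oopen;
  }
  return out;
}
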