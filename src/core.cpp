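#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Signed Q4.34 two's-complement scalars: raw integers scaled by 2^34,
// saturating at [-2^38, 2^38 - 1].  Raw values travel through R as doubles,
// which is exact (|raw| < 2^39 << 2^53).

static const int FRAC_BITS = 34;
static const int64_t RAW_MAX = (int64_t(1) << 38) - 1;
static const int64_t RAW_MIN = -(int64_t(1) << 38);

struct SatCounter { long long n = 0; };

static inline int64_t sat64(int64_t v, SatCounter *sc) {
  if (v > RAW_MAX) { if (sc) sc->n++; return RAW_MAX; }
  if (v < RAW_MIN) { if (sc) sc->n++; return RAW_MIN; }
  return v;
}

static inline int64_t fx_add_i(int64_t a, int64_t b, SatCounter *sc) {
  return sat64(a + b, sc);
}
static inline int64_t fx_sub_i(int64_t a, int64_t b, SatCounter *sc) {
  return sat64(a - b, sc);
}

// full 39x39 -> 39 multiply: exact 128-bit product, arithmetic right shift
// (truncation toward -inf) of the low 34 bits, then saturation
static inline int64_t fx_mul_i(int64_t a, int64_t b, SatCounter *sc) {
  __int128 p = (__int128)a * (__int128)b;
  p >>= FRAC_BITS; // gcc: arithmetic shift, floor division by 2^34
  if (p > (__int128)RAW_MAX) { if (sc) sc->n++; return RAW_MAX; }
  if (p < (__int128)RAW_MIN) { if (sc) sc->n++; return RAW_MIN; }
  return (int64_t)p;
}

// shift-add constant multiply: sum of sign * (a >> shift); negative shift
// is a left shift (value > 1).  Arithmetic right shifts on raw.
static inline int64_t fx_scm_i(int64_t a, const int *signs, const int *shifts,
                               int nterms, SatCounter *sc) {
  int64_t acc = 0;
  for (int k = 0; k < nterms; ++k) {
    int s = shifts[k];
    int64_t t;
    if (s >= 0) {
      t = a >> s; // arithmetic shift (implementation-defined pre-C++20; gcc ok)
    } else {
      t = sat64(a * (int64_t(1) << (-s)), sc);
    }
    acc = sat64(signs[k] > 0 ? acc + t : acc - t, sc);
  }
  return acc;
}

static inline int64_t quant_i(double x) {
  if (std::isnan(x)) stop("cannot quantize NaN");
  double scaled = std::ldexp(x, FRAC_BITS);
  if (scaled >= (double)RAW_MAX) return RAW_MAX;
  if (scaled <= (double)RAW_MIN) return RAW_MIN;
  return (int64_t)std::nearbyint(scaled); // round-to-nearest-even (default FP mode)
}

// ---- vectorized primitives exposed to R (raw values as doubles) ----

// [[Rcpp::export]]
NumericVector cpp_quantize(NumericVector x) {
  int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (double)quant_i(x[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fx_add(NumericVector a, NumericVector b) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (double)fx_add_i((int64_t)a[i], (int64_t)b[i], nullptr);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fx_sub(NumericVector a, NumericVector b) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (double)fx_sub_i((int64_t)a[i], (int64_t)b[i], nullptr);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fx_mul(NumericVector a, NumericVector b) {
  int n = a.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (double)fx_mul_i((int64_t)a[i], (int64_t)b[i], nullptr);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_fx_scm(NumericVector a, IntegerVector signs, IntegerVector shifts) {
  int n = a.size(), nt = signs.size();
  std::vector<int> sg(nt), sh(nt);
  for (int k = 0; k < nt; ++k) { sg[k] = signs[k]; sh[k] = shifts[k]; }
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (double)fx_scm_i((int64_t)a[i], sg.data(), sh.data(), nt, nullptr);
  return out;
}

// ---- PWL table in raw units ----

struct PwlRaw {
  std::vector<int64_t> bp, slope, intercept;
  void load(List tab) {
    NumericVector b = tab["bp_raw"], s = tab["slope_raw"], c = tab["intercept_raw"];
    bp.assign(b.begin(), b.end());
    slope.assign(s.begin(), s.end());
    intercept.assign(c.begin(), c.end());
  }
  int64_t eval(int64_t x, SatCounter *sc) const {
    // clamp policy: out-of-domain inputs evaluate the boundary endpoint
    if (x <= bp.front()) x = bp.front();
    if (x >= bp.back())  x = bp.back();
    // binary search for segment with bp[i] <= x < bp[i+1]
    size_t lo = 0, hi = bp.size() - 1;
    while (hi - lo > 1) {
      size_t mid = (lo + hi) / 2;
      if ((int64_t)bp[mid] <= x) lo = mid; else hi = mid;
    }
    return fx_add_i(fx_mul_i(slope[lo], x, sc), intercept[lo], sc);
  }
};

// one shift-add constant multiplier, optionally cascaded with a second
// stage (rate constant followed by the Euler step)
struct ScmRaw {
  std::vector<int> signs, shifts, signs2, shifts2;
  void load(List plan) {
    IntegerVector sg = plan["signs"], sh = plan["shifts"];
    signs.assign(sg.begin(), sg.end());
    shifts.assign(sh.begin(), sh.end());
    if (plan.containsElementNamed("signs2")) {
      IntegerVector sg2 = plan["signs2"], sh2 = plan["shifts2"];
      signs2.assign(sg2.begin(), sg2.end());
      shifts2.assign(sh2.begin(), sh2.end());
    }
  }
  int64_t apply(int64_t a, SatCounter *sc) const {
    if (signs.empty()) return 0;
    int64_t v = fx_scm_i(a, signs.data(), shifts.data(), (int)signs.size(), sc);
    if (!signs2.empty())
      v = fx_scm_i(v, signs2.data(), shifts2.data(), (int)signs2.size(), sc);
    return v;
  }
};

// ---- the digital emulator: Q4.34 forward Euler over the full dataflow ----
//
// mode 0: IP3 clamp (AG and IP3 production bypassed; IP3 forced per step)
// mode 1: spike-driven (AG impulse per protocol spike flag; IP3 follows)
//
// Per step, in scheduling order: (1) IF voltage with threshold/reset,
// (2) 2-AG decay + spike increment, (3) IP3 production/decay, (4) Q2 via PWL
// and h update via dh = dt*a2*(Q2 - h*(Q2+Ca)), (5) gating PWLs, cubes by
// repeated multiplies, fluxes, Ca update.

// [[Rcpp::export]]
List cpp_run_digital(int n_steps, int out_every, int mode,
                     NumericVector clamp_raw, IntegerVector spike_flag,
                     NumericVector init_raw, List consts_raw, List scm_plans,
                     List pwl_tables, int cube_after) {
  SatCounter sc;

  int64_t V = (int64_t)init_raw["V"], AG = (int64_t)init_raw["AG"];
  int64_t IP3 = (int64_t)init_raw["IP3"], Ca = (int64_t)init_raw["Ca"];
  int64_t h = (int64_t)init_raw["h"];

  const int64_t RmIsyn = (int64_t)as<double>(consts_raw["RmIsyn"]);
  const int64_t Vth    = (int64_t)as<double>(consts_raw["Vth"]);
  const int64_t Vreset = (int64_t)as<double>(consts_raw["Vreset"]);
  const int64_t rAG    = (int64_t)as<double>(consts_raw["rAG"]);
  const int64_t IP3s   = (int64_t)as<double>(consts_raw["IP3star"]);
  const int64_t c0     = (int64_t)as<double>(consts_raw["c0"]);

  ScmRaw p_dt_tau_m, p_dt_tau_ag, p_dt_tau_ip3, p_dt_rip3, p_dt_a2,
         p_vER, p_rC, p_rL, p_one_c1, p_dt;
  p_dt_tau_m.load(scm_plans["dt_tau_m"]);
  p_dt_tau_ag.load(scm_plans["dt_tau_ag"]);
  p_dt_tau_ip3.load(scm_plans["dt_tau_ip3"]);
  p_dt_rip3.load(scm_plans["dt_rip3"]);
  p_dt_a2.load(scm_plans["dt_a2"]);
  p_vER.load(scm_plans["vER"]);
  p_rC.load(scm_plans["rC"]);
  p_rL.load(scm_plans["rL"]);
  p_one_c1.load(scm_plans["one_c1"]);
  p_dt.load(scm_plans["dt"]);

  PwlRaw q2_t, minf_t, ninf_t, hill_t;
  q2_t.load(pwl_tables["q2"]);
  minf_t.load(pwl_tables["m_inf"]);
  ninf_t.load(pwl_tables["n_inf"]);
  hill_t.load(pwl_tables["hill2"]);

  int n_out = n_steps / out_every + 1;
  NumericMatrix out(n_out, 13);
  colnames(out) = CharacterVector::create(
    "V", "AG", "IP3", "Ca", "h", "J_chan", "J_leak", "J_pump",
    "m_inf3", "n_inf3", "Q2", "h3", "spike");

  int row = 0;
  bool v_spiked = false;
  for (int i = 0; i <= n_steps; ++i) {
    // registered intermediates from the current state
    int64_t Q2  = q2_t.eval(IP3, &sc);
    int64_t m1  = minf_t.eval(IP3, &sc);
    int64_t n1  = ninf_t.eval(Ca, &sc);
    int64_t hil = hill_t.eval(Ca, &sc);
    int64_t m3 = cube_after ? fx_mul_i(fx_mul_i(m1, m1, &sc), m1, &sc) : m1;
    int64_t n3 = cube_after ? fx_mul_i(fx_mul_i(n1, n1, &sc), n1, &sc) : n1;
    int64_t h3 = fx_mul_i(fx_mul_i(h, h, &sc), h, &sc);
    int64_t Jp = p_vER.apply(hil, &sc);
    int64_t drive = fx_sub_i(c0, p_one_c1.apply(Ca, &sc), &sc);
    int64_t mnh = fx_mul_i(fx_mul_i(m3, n3, &sc), h3, &sc);
    int64_t Jc = fx_mul_i(p_rC.apply(mnh, &sc), drive, &sc);
    int64_t Jl = p_rL.apply(drive, &sc);

    if (i % out_every == 0) {
      out(row, 0) = (double)V;   out(row, 1) = (double)AG;
      out(row, 2) = (double)IP3; out(row, 3) = (double)Ca;
      out(row, 4) = (double)h;   out(row, 5) = (double)Jc;
      out(row, 6) = (double)Jl;  out(row, 7) = (double)Jp;
      out(row, 8) = (double)m3;  out(row, 9) = (double)n3;
      out(row, 10) = (double)Q2; out(row, 11) = (double)h3;
      out(row, 12) = v_spiked ? 1.0 : 0.0;
      ++row;
    }
    if (i == n_steps) break;

    // (1) IF voltage, raw-integer threshold compare
    if (mode == 1) {
      V = fx_add_i(V, p_dt_tau_m.apply(fx_sub_i(RmIsyn, V, &sc), &sc), &sc);
      v_spiked = (V >= Vth);
      if (v_spiked) V = Vreset;
    }

    int spk = (mode == 1 && spike_flag[i]) ? 1 : 0;

    // (2) 2-AG decay + impulse, (3) IP3 production; bypassed under clamp
    int64_t AG_n = AG, IP3_n;
    if (mode == 1) {
      AG_n = fx_sub_i(AG, p_dt_tau_ag.apply(AG, &sc), &sc);
      if (spk) AG_n = fx_add_i(AG_n, rAG, &sc);
      IP3_n = fx_add_i(IP3, p_dt_tau_ip3.apply(fx_sub_i(IP3s, IP3, &sc), &sc), &sc);
      IP3_n = fx_add_i(IP3_n, p_dt_rip3.apply(AG, &sc), &sc);
    } else {
      IP3_n = (int64_t)clamp_raw[i + 1 < (int)clamp_raw.size() ? i + 1 : i];
    }

    // (4) h gate: dh = dt*a2*(Q2 - h*(Q2+Ca))
    int64_t hQ = fx_mul_i(h, fx_add_i(Q2, Ca, &sc), &sc);
    int64_t h_n = fx_add_i(h, p_dt_a2.apply(fx_sub_i(Q2, hQ, &sc), &sc), &sc);

    // (5) Ca update
    int64_t flux = fx_sub_i(fx_add_i(Jc, Jl, &sc), Jp, &sc);
    int64_t Ca_n = fx_add_i(Ca, p_dt.apply(flux, &sc), &sc);

    AG = AG_n; IP3 = IP3_n; h = h_n; Ca = Ca_n;
  }

  return List::create(_["out"] = out, _["saturations"] = (double)sc.n);
}

// ---- double-precision Euler over the exact (unapproximated) dataflow ----
// Serves as the discretization-matched oracle for the digital emulator and
// as a fast fixed-step integrator for convergence checks.

// [[Rcpp::export]]
NumericMatrix cpp_run_euler(int n_steps, int out_every, int mode, double dt,
                            NumericVector clamp_vals, IntegerVector spike_flag,
                            NumericVector init, List params) {
  double V = init["V"], AG = init["AG"], IP3 = init["IP3"];
  double Ca = init["Ca"], h = init["h"];

  const double tau_m = params["tau_m"], RmIsyn = params["RmIsyn"],
               Vth = params["V_th"], Vreset = params["V_reset"];
  const double tau_AG = params["tau_AG"], rAG = params["r_AG"],
               IP3s = params["IP3_star"], tau_ip3 = params["tau_ip3"],
               rip3 = params["r_ip3"], a2 = params["a2"], d1 = params["d1"],
               d2 = params["d2"], d3 = params["d3"], d5 = params["d5"],
               c0 = params["c0"], c1 = params["c1"], rL = params["r_L"],
               rC = params["r_C"], vER = params["v_ER"], kER = params["k_ER"];

  int n_out = n_steps / out_every + 1;
  NumericMatrix out(n_out, 13);
  colnames(out) = CharacterVector::create(
    "V", "AG", "IP3", "Ca", "h", "J_chan", "J_leak", "J_pump",
    "m_inf3", "n_inf3", "Q2", "h3", "spike");

  int row = 0;
  bool v_spiked = false;
  for (int i = 0; i <= n_steps; ++i) {
    double Q2 = d2 * (IP3 + d1) / (IP3 + d3);
    double m = IP3 / (IP3 + d1), n = Ca / (Ca + d5);
    double m3 = m * m * m, n3 = n * n * n, h3 = h * h * h;
    double Jp = vER * Ca * Ca / (kER * kER + Ca * Ca);
    double drive = c0 - (1.0 + c1) * Ca;
    double Jc = rC * m3 * n3 * h3 * drive, Jl = rL * drive;

    if (i % out_every == 0) {
      out(row, 0) = V;  out(row, 1) = AG;  out(row, 2) = IP3;
      out(row, 3) = Ca; out(row, 4) = h;   out(row, 5) = Jc;
      out(row, 6) = Jl; out(row, 7) = Jp;  out(row, 8) = m3;
      out(row, 9) = n3; out(row, 10) = Q2; out(row, 11) = h3;
      out(row, 12) = v_spiked ? 1.0 : 0.0;
      ++row;
    }
    if (i == n_steps) break;

    if (mode == 1) {
      V += dt / tau_m * (RmIsyn - V);
      v_spiked = (V >= Vth);
      if (v_spiked) V = Vreset;
    }
    int spk = (mode == 1 && spike_flag[i]) ? 1 : 0;

    double AG_n = AG, IP3_n;
    if (mode == 1) {
      AG_n = AG - dt / tau_AG * AG + (spk ? rAG : 0.0);
      IP3_n = IP3 + dt * ((IP3s - IP3) / tau_ip3 + rip3 * AG);
    } else {
      IP3_n = clamp_vals[i + 1 < (int)clamp_vals.size() ? i + 1 : i];
    }
    double h_n = h + dt * a2 * (Q2 - h * (Q2 + Ca));
    double Ca_n = Ca + dt * (Jc + Jl - Jp);

    AG = AG_n; IP3 = IP3_n; h = h_n; Ca = Ca_n;
  }
  return out;
}
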