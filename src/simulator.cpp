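#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Point-soma Hodgkin-Huxley integrator.
//
// Units at this interface: V in mV, t in ms, injected current in pA,
// conductance densities in S/cm2, membrane current densities internally in
// uA/cm2, calcium in mM.  Gates use Boltzmann steady states
//   x_inf(V) = 1 / (1 + exp((v_half + v_shift - V) / slope))
// (slope > 0: activation, slope < 0: inactivation) except calcium-sensing
// gates which use a Hill function of [Ca].  Gates advance by exponential
// Euler, V by a forward step, fixed dt.

static const double FARADAY = 96485.332;
static const double RTF25 = 25.693;  // RT/F at 25 C, mV

struct Gate {
  int power;
  double v_half, slope, v_shift;
  int tau_family;            // 0 constant, 1 bell, 2 sigmoid
  std::vector<double> tc;    // tau constants
  bool ca_sensor;            // Hill gate: v_half = ca_half (mM), slope = Hill n
  double x;
};

struct Channel {
  double gbar;
  int rev_mode;              // 0 fixed erev, 1 Nernst from [Ca]
  double erev;
  std::vector<Gate> gates;
};

struct Soma {
  double area_cm2, cm, ca_gamma, ca_tau, ca_rest, ca_depth, ca_out;
  std::vector<Channel> ch;
};

static double gate_inf(const Gate& g, double v, double ca) {
  if (g.ca_sensor) {
    double c = ca > 1e-12 ? ca : 1e-12;
    return 1.0 / (1.0 + std::pow(g.v_half / c, g.slope));
  }
  return 1.0 / (1.0 + std::exp((g.v_half + g.v_shift - v) / g.slope));
}

static double gate_tau(const Gate& g, double v) {
  const std::vector<double>& c = g.tc;
  switch (g.tau_family) {
  case 1:  // bell: c0 + c1 / (exp((v-c2)/c3) + exp(-(v-c2)/c4))
    return c[0] + c[1] / (std::exp((v - c[2]) / c[3]) + std::exp(-(v - c[2]) / c[4]));
  case 2:  // sigmoid: c0 + c1 / (1 + exp((v-c2)/c3))
    return c[0] + c[1] / (1.0 + std::exp((v - c[2]) / c[3]));
  default:
    return c[0];
  }
}

static Soma parse_soma(const List& m) {
  Soma s;
  s.area_cm2 = as<double>(m["area_cm2"]);
  s.cm = as<double>(m["cm"]);
  s.ca_gamma = as<double>(m["ca_gamma"]);
  s.ca_tau = as<double>(m["ca_tau"]);
  s.ca_rest = as<double>(m["ca_rest"]);
  s.ca_depth = as<double>(m["ca_depth"]);
  s.ca_out = as<double>(m["ca_out"]);
  List chl = m["channels"];
  for (int i = 0; i < chl.size(); ++i) {
    List c = chl[i];
    Channel ch;
    ch.gbar = as<double>(c["gbar"]);
    ch.rev_mode = as<int>(c["rev_mode"]);
    ch.erev = as<double>(c["erev"]);
    List gl = c["gates"];
    for (int j = 0; j < gl.size(); ++j) {
      List g = gl[j];
      Gate gt;
      gt.power = as<int>(g["power"]);
      gt.v_half = as<double>(g["v_half"]);
      gt.slope = as<double>(g["slope"]);
      gt.v_shift = as<double>(g["v_shift"]);
      gt.tau_family = as<int>(g["tau_family"]);
      gt.tc = as<std::vector<double> >(g["tau_constants"]);
      gt.ca_sensor = as<bool>(g["ca_sensor"]);
      gt.x = 0.0;
      ch.gates.push_back(gt);
    }
    s.ch.push_back(ch);
  }
  return s;
}

// conductance sums at the present gate states: gsum (S/cm2),
// gesum = sum g_i * E_i (S/cm2 * mV), and calcium-channel members of each
static void cond_sums(const Soma& s, double ca,
                      double& gsum, double& gesum,
                      double& gca, double& geca) {
  gsum = gesum = gca = geca = 0.0;
  for (size_t i = 0; i < s.ch.size(); ++i) {
    const Channel& c = s.ch[i];
    double g = c.gbar;
    for (size_t j = 0; j < c.gates.size(); ++j) {
      double x = c.gates[j].x;
      for (int p = 0; p < c.gates[j].power; ++p) g *= x;
    }
    double e = c.erev;
    if (c.rev_mode == 1) {
      double cin = ca > 1e-12 ? ca : 1e-12;
      e = 0.5 * RTF25 * std::log(s.ca_out / cin);
      gca += g;
      geca += g * e;
    }
    gsum += g;
    gesum += g * e;
  }
}

// total membrane current density in uA/cm2 (outward positive) and calcium
// current density in mA/cm2 (inward negative) at the present gate states
static void currents(const Soma& s, double v, double ca,
                     double& itot_uA, double& ica_mA) {
  double gsum, gesum, gca, geca;
  cond_sums(s, ca, gsum, gesum, gca, geca);
  itot_uA = 1000.0 * (gsum * v - gesum);
  ica_mA = gca * v - geca;
}

static void set_gates_inf(Soma& s, double v, double ca) {
  for (size_t i = 0; i < s.ch.size(); ++i)
    for (size_t j = 0; j < s.ch[i].gates.size(); ++j)
      s.ch[i].gates[j].x = gate_inf(s.ch[i].gates[j], v, ca);
}

// fixed point of the calcium pool at clamped voltage v
static double ca_steady(Soma& s, double v) {
  double ca = s.ca_rest;
  for (int it = 0; it < 200; ++it) {
    set_gates_inf(s, v, ca);
    double itot, ica;
    currents(s, v, ca, itot, ica);
    double ca_new = s.ca_rest - s.ca_tau * (1e4 * ica * s.ca_gamma) /
      (2.0 * FARADAY * s.ca_depth);
    if (ca_new < 1e-8) ca_new = 1e-8;
    double next = 0.5 * (ca + ca_new);
    if (std::fabs(next - ca) < 1e-12) { ca = next; break; }
    ca = next;
  }
  set_gates_inf(s, v, ca);
  return ca;
}

// [[Rcpp::export(name = ".sim_membrane_current")]]
double sim_membrane_current(List model, double v) {
  Soma s = parse_soma(model);
  double ca = ca_steady(s, v);
  double itot, ica;
  currents(s, v, ca, itot, ica);
  return itot * s.area_cm2 * 1e6;  // pA, outward positive
}

static void gates_advance(Soma& s, double v, double ca, double h) {
  for (size_t i = 0; i < s.ch.size(); ++i) {
    for (size_t j = 0; j < s.ch[i].gates.size(); ++j) {
      Gate& g = s.ch[i].gates[j];
      double xi = gate_inf(g, v, ca);
      double tau = gate_tau(g, v);
      if (tau < 1e-4) tau = 1e-4;
      g.x += (xi - g.x) * (1.0 - std::exp(-h / tau));
    }
  }
}

// voltage-grid tables of x_inf and the per-step relaxation factor
// 1 - exp(-dt/tau(V)) for every voltage-sensing gate: the integration loop
// evaluates gates by linear interpolation instead of exponentials
struct GateTables {
  double vmin, vmax, step, inv_step;
  int n;
  std::vector< std::vector<double> > inf_tab, fac_tab;  // per voltage gate
  std::vector<Gate*> vgates;

  void build(Soma& s, double dt) {
    vmin = -150.0; vmax = 100.0; step = 0.05;
    inv_step = 1.0 / step;
    n = (int)((vmax - vmin) * inv_step) + 2;
    for (size_t i = 0; i < s.ch.size(); ++i)
      for (size_t j = 0; j < s.ch[i].gates.size(); ++j)
        if (!s.ch[i].gates[j].ca_sensor) vgates.push_back(&s.ch[i].gates[j]);
    inf_tab.resize(vgates.size());
    fac_tab.resize(vgates.size());
    for (size_t k = 0; k < vgates.size(); ++k) {
      inf_tab[k].resize(n);
      fac_tab[k].resize(n);
      for (int m = 0; m < n; ++m) {
        double v = vmin + m * step;
        inf_tab[k][m] = gate_inf(*vgates[k], v, 1e-4);
        double tau = gate_tau(*vgates[k], v);
        if (tau < 1e-4) tau = 1e-4;
        fac_tab[k][m] = 1.0 - std::exp(-dt / tau);
      }
    }
  }

  void advance(Soma& s, double v, double ca, double dt) {
    double u = (v - vmin) * inv_step;
    if (u < 0) u = 0;
    if (u > n - 2) u = n - 2;
    int m = (int)u;
    double w = u - m;
    for (size_t k = 0; k < vgates.size(); ++k) {
      double xi = inf_tab[k][m] + w * (inf_tab[k][m + 1] - inf_tab[k][m]);
      double fac = fac_tab[k][m] + w * (fac_tab[k][m + 1] - fac_tab[k][m]);
      Gate* g = vgates[k];
      g->x += (xi - g->x) * fac;
    }
    // calcium-sensing gates evaluated exactly (they depend on [Ca], not V)
    for (size_t i = 0; i < s.ch.size(); ++i)
      for (size_t j = 0; j < s.ch[i].gates.size(); ++j) {
        Gate& g = s.ch[i].gates[j];
        if (!g.ca_sensor) continue;
        double xi = gate_inf(g, v, ca);
        double tau = g.tc[0] < 1e-4 ? 1e-4 : g.tc[0];
        g.x += (xi - g.x) * (1.0 - std::exp(-dt / tau));
      }
  }
};

static double ca_rate(const Soma& s, double ica_mA, double ca) {
  return -(1e4 * ica_mA * s.ca_gamma) / (2.0 * FARADAY * s.ca_depth) -
    (ca - s.ca_rest) / s.ca_tau;
}

// mode 0: current clamp, drive = injected current (pA) per sample
// mode 1: ideal voltage clamp, drive = command voltage (mV) per sample
// v0: initial voltage (gates/calcium start at steady state there)
//
// Current clamp uses a midpoint (second-order) step for V and [Ca] with
// exponential gate updates staggered at half steps; voltage clamp advances
// gates/[Ca] the same way under the imposed command voltage.
// [[Rcpp::export(name = ".sim_run")]]
List sim_run(List model, NumericVector drive, double dt, int mode, double v0) {
  Soma s = parse_soma(model);
  int n = drive.size();
  NumericVector out(n);
  NumericVector ca_out(n);
  double ca = ca_steady(s, v0);
  double v = v0;
  int failed_at = -1;
  GateTables tab;
  tab.build(s, dt);

  for (int k = 0; k < n; ++k) {
    double itot, ica;
    if (mode == 1) v = drive[k];
    currents(s, v, ca, itot, ica);
    if (mode == 0) {
      out[k] = v;
    } else {
      out[k] = itot * s.area_cm2 * 1e6;  // pA
    }
    ca_out[k] = ca;
    if (k == n - 1) break;

    if (mode == 1) {
      // clamped: V is imposed, integrate gates and calcium at commanded V
      double v_next = drive[k + 1];
      double v_mid = 0.5 * (v + v_next);
      tab.advance(s, v_mid, ca, dt);
      currents(s, v_mid, ca, itot, ica);
      ca += dt * ca_rate(s, ica, ca);
      if (ca < 1e-8) ca = 1e-8;
      continue;
    }

    double iinj_mid = 0.5 * (drive[k] + drive[k + 1]) * 1e-6 / s.area_cm2;

    // staggered scheme: gates advance a full step with rates evaluated at
    // the current voltage (gate states live on the half-step grid), then V
    // advances by the exact exponential solution for frozen conductances
    tab.advance(s, v, ca, dt);
    double gsum, gesum, gca, geca;
    cond_sums(s, ca, gsum, gesum, gca, geca);
    double a = 1000.0 * gsum / s.cm;                    // 1/ms
    double vinf = (1000.0 * gesum + iinj_mid) / (1000.0 * gsum);
    double v_new = vinf + (v - vinf) * std::exp(-a * dt);
    double v_mid = 0.5 * (v + v_new);
    ica = gca * v_mid - geca;
    ca += dt * ca_rate(s, ica, ca);
    if (ca < 1e-8) ca = 1e-8;
    v = v_new;

    if (!std::isfinite(v) || std::fabs(v) > 200.0) { failed_at = k + 1; break; }
  }

  return List::create(_["samples"] = out, _["ca"] = ca_out,
                      _["failed_at"] = failed_at);
}
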