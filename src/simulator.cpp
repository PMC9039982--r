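// Time-domain core of the multi-compartment lung simulator.
//
// The lung is n parallel alveolar compartments behind a shared central
// airway resistance Rc, each with its own bronchiolar inlet resistance Rb
// and a nonlinear (or, for oracle patients, linear) pressure-volume law.
// Gas is convected through a rigid series dead space discretised into
// plug-flow slices; open compartments exchange O2/CO2 with capillary
// blood via standard dissociation curves, closed compartments are
// perfused but act as shunt.  All state advances with a fixed-step
// explicit update; flow distribution among compartments is solved
// algebraically at every step.
//
// Units: pressure cmH2O, volume L, flow L/s, time s, blood-gas tensions
// mmHg, blood gas contents mL(gas)/L(blood), Hb g/L.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double P_DRY = 713.0;   // barometric 760 minus water vapour 47 mmHg

// ---- dissociation curves -------------------------------------------------

static double o2_sat(double p) {
  if (p <= 0.0) return 0.0;
  return 1.0 / (1.0 + 23400.0 / (p * p * p + 150.0 * p));
}

static double o2_content(double p, double hb) {
  // 1.34 mL O2 per g Hb plus dissolved fraction
  return 1.34 * hb * o2_sat(p) + 0.03 * p;
}

static double co2_content(double p) {
  // linearised CO2 dissociation around 40 mmHg
  return 480.0 + 4.7 * (p - 40.0);
}

static double po2_from_content(double c, double hb) {
  double lo = 1e-3, hi = 900.0;
  if (c <= o2_content(lo, hb)) return lo;
  if (c >= o2_content(hi, hb)) return hi;
  for (int i = 0; i < 60; ++i) {
    double mid = 0.5 * (lo + hi);
    if (o2_content(mid, hb) < c) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

static double pco2_from_content(double c) {
  return 40.0 + (c - 480.0) / 4.7;
}

// ---- compartment pressure-volume law ------------------------------------

// Exponential recoil with a stiffness multiplier exp(k_stiff); the
// compartment sits at its reference volume v_ref when transmural recoil
// equals the extrinsic pressure offset p_ext.
static double p_elastic(double v, double p_ext, double k_stiff, double v_ref,
                        double a, double b, bool linear, double c_lin) {
  if (linear) return p_ext + (v - v_ref) / c_lin;
  double u = v / v_ref;
  return p_ext + a * (std::exp(b * std::exp(k_stiff) * (u - 1.0)) - 1.0);
}

// Zero-flow equilibrium volume at a given applied pressure (bisection).
static double v_equilibrium(double paw, double p_ext, double k_stiff,
                            double v_ref, double a, double b, bool linear,
                            double c_lin) {
  if (linear) return v_ref + c_lin * (paw - p_ext);
  double lo = 1e-9, hi = 6.0 * v_ref;
  if (p_elastic(lo, p_ext, k_stiff, v_ref, a, b, false, 0.0) >= paw) return 0.0;
  if (p_elastic(hi, p_ext, k_stiff, v_ref, a, b, false, 0.0) <= paw) return hi;
  for (int i = 0; i < 60; ++i) {
    double mid = 0.5 * (lo + hi);
    if (p_elastic(mid, p_ext, k_stiff, v_ref, a, b, false, 0.0) < paw)
      lo = mid;
    else
      hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export(name = ".cpp_equilibrium_volume")]]
NumericVector cpp_equilibrium_volume(double paw, NumericVector p_ext,
                                     NumericVector k_stiff, double v_ref,
                                     double a, double b, bool linear,
                                     NumericVector c_lin) {
  int n = p_ext.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = v_equilibrium(paw, p_ext[i], k_stiff[i], v_ref, a, b, linear,
                           c_lin[i % c_lin.size()]);
  return out;
}

// ---- the simulator -------------------------------------------------------

// [[Rcpp::export(name = ".cpp_sim_run")]]
List cpp_sim_run(List patient, List vent, List ctrl, Nullable<List> init) {
  // patient unpack
  NumericVector p_ext = patient["p_ext"];
  NumericVector k_stiff = patient["k_stiff"];
  NumericVector top = patient["top"];
  NumericVector rb = patient["r_b"];         // expiratory
  NumericVector rb_in = patient["r_b_insp"]; // inspiratory
  const int n = p_ext.size();
  const double v_ref = as<double>(patient["v_ref"]);
  const double a = as<double>(patient["pv_a"]);
  const double b = as<double>(patient["pv_b"]);
  const bool linear = as<bool>(patient["linear"]);
  NumericVector c_lin = patient["c_lin"];
  const double rc = as<double>(patient["r_c"]);
  const double rq = as<double>(patient["rq"]);
  const double vo2 = as<double>(patient["vo2"]);       // mL/min
  const double hb = as<double>(patient["hb"]);         // g/L
  const double shunt_anat = as<double>(patient["shunt_anat"]); // percent
  const double vd = as<double>(patient["vd"]);         // L
  const double co = as<double>(patient["cardiac_output"]); // L/min

  // ventilator unpack
  const int mode = as<int>(vent["mode"]); // 1 = pressure-cycled, 2 = VCV
  const double fio2 = as<double>(vent["fio2"]);
  double phigh = 0, plow = 0, thigh = 0, tlow = 0;
  double vt = 0, peep = 0, rr = 0, dc = 0, flow_frac = 0.7;
  double t_cycle;
  if (mode == 1) {
    phigh = as<double>(vent["p_high"]);
    plow = as<double>(vent["p_low"]);
    thigh = as<double>(vent["t_high"]);
    tlow = as<double>(vent["t_low"]);
    t_cycle = thigh + tlow;
  } else {
    vt = as<double>(vent["vt"]);
    peep = as<double>(vent["peep"]);
    rr = as<double>(vent["rr"]);
    dc = as<double>(vent["dc"]);
    flow_frac = as<double>(vent["flow_frac"]);
    t_cycle = 60.0 / rr;
  }

  // control unpack
  const double dt = as<double>(ctrl["dt"]);
  const double duration = as<double>(ctrl["duration"]);
  const double store_from = as<double>(ctrl["store_from"]);
  const int store_every = as<int>(ctrl["store_every"]);
  const double gas_accel = as<double>(ctrl["gas_accel"]);
  const double accel_until = as<double>(ctrl["accel_until"]);
  const int nds = as<int>(ctrl["n_ds_slices"]);
  const double u_close = as<double>(ctrl["u_close"]);
  const double tau_venous = as<double>(ctrl["tau_venous"]);
  // soft start: tidal volume ramps up over the first breaths so the
  // cold-start transient does not spuriously recruit closed compartments
  const int ramp_breaths = as<int>(ctrl["ramp_breaths"]);

  const double q_perf = co * (1.0 - shunt_anat / 100.0) / n; // L/min per compartment
  const double slice_vol = vd / nds;

  // state
  std::vector<double> v(n), fo2(n), fco2(n);
  std::vector<int> open(n);
  std::vector<double> ds_o2(nds), ds_co2(nds);
  double cv_o2, cv_co2;

  if (init.isNotNull()) {
    List st(init);
    NumericVector v0 = st["v"], fo20 = st["f_o2"], fco20 = st["f_co2"];
    IntegerVector op0 = st["open"];
    NumericVector dso = st["ds_o2"], dsc = st["ds_co2"];
    for (int i = 0; i < n; ++i) {
      v[i] = v0[i]; fo2[i] = fo20[i]; fco2[i] = fco20[i]; open[i] = op0[i];
    }
    for (int s = 0; s < nds; ++s) { ds_o2[s] = dso[s]; ds_co2[s] = dsc[s]; }
    cv_o2 = as<double>(st["cv_o2"]);
    cv_co2 = as<double>(st["cv_co2"]);
  } else {
    // start at zero-flow equilibrium under the expiratory pressure level
    double paw0 = (mode == 1) ? plow : peep;
    for (int i = 0; i < n; ++i) {
      double ve = v_equilibrium(paw0, p_ext[i], k_stiff[i], v_ref, a, b,
                                linear, c_lin[i % c_lin.size()]);
      if (!linear && ve <= u_close * v_ref) {
        v[i] = u_close * v_ref;
        open[i] = 0;
      } else {
        v[i] = ve;
        open[i] = 1;
      }
      fo2[i] = std::max(0.05, fio2 - 0.07);
      fco2[i] = 40.0 / P_DRY;
    }
    for (int s = 0; s < nds; ++s) { ds_o2[s] = fio2; ds_co2[s] = 0.0; }
    cv_o2 = o2_content(40.0, hb);
    cv_co2 = co2_content(46.0);
  }

  const long nsteps = (long)std::llround(duration / dt);
  const long nstore_max = (long)((duration - store_from) / dt) / store_every + 4;
  NumericMatrix trace((int)std::max(nstore_max, (long)1), 9);
  long irow = 0;

  double p_node_prev = (mode == 1) ? plow : peep;
  double pet_latch = NA_REAL;
  double o2_uptake_ml = 0.0, co2_output_ml = 0.0; // over stored window
  double ca_o2 = o2_content(90.0, hb), ca_co2 = co2_content(40.0);

  std::vector<double> pel(n), q(n), ccap_o2(n), ccap_co2(n);
  // direction-dependent bronchiolar resistance, selected from the
  // previous step's flow direction (hysteresis of one step)
  std::vector<double> rb_eff(n);
  for (int i = 0; i < n; ++i) rb_eff[i] = rb_in[i];

  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    double tc = t - std::floor(t / t_cycle) * t_cycle;  // cycle phase
    bool in_window = (t >= store_from - 1e-12);

    // ventilator boundary condition for this instant
    bool pressure_mode;
    double paw_set = 0.0, q_set = 0.0;
    if (mode == 1) {
      pressure_mode = true;
      paw_set = (tc < thigh) ? phigh : plow;
    } else {
      double t_insp = dc * t_cycle;
      double t_flow = flow_frac * t_insp;
      double vt_now = vt;
      if (ramp_breaths > 0) {
        double cyc_i = std::floor(t / t_cycle);
        if (cyc_i < ramp_breaths)
          vt_now = vt * (cyc_i + 1.0) / (ramp_breaths + 1.0);
      }
      if (tc < t_flow) { pressure_mode = false; q_set = vt_now / t_flow; }
      else if (tc < t_insp) { pressure_mode = false; q_set = 0.0; } // hold
      else { pressure_mode = true; paw_set = peep; }
    }

    // recruitment: closed compartments open when proximal pressure
    // reaches their threshold opening pressure
    for (int i = 0; i < n; ++i)
      if (!open[i] && p_node_prev >= top[i]) open[i] = 1;

    // elastic recoil of open compartments
    for (int i = 0; i < n; ++i)
      if (open[i])
        pel[i] = p_elastic(v[i], p_ext[i], k_stiff[i], v_ref, a, b, linear,
                           c_lin[i % c_lin.size()]);

    // flow distribution; two passes so the direction-dependent
    // bronchiolar resistance is consistent with this step's flow signs
    double p_node = p_node_prev, q_mouth = 0.0, paw_out = paw_set;
    for (int pass = 0; pass < 2; ++pass) {
      double sum_inv_rb = 0.0, sum_p_rb = 0.0;
      for (int i = 0; i < n; ++i) {
        if (!open[i]) continue;
        sum_inv_rb += 1.0 / rb_eff[i];
        sum_p_rb += pel[i] / rb_eff[i];
      }
      if (sum_inv_rb <= 0.0) {  // everything closed
        p_node = pressure_mode ? paw_set : p_node_prev;
        q_mouth = 0.0;
        paw_out = pressure_mode ? paw_set : p_node;
        break;
      } else if (pressure_mode) {
        p_node = (paw_set / rc + sum_p_rb) / (1.0 / rc + sum_inv_rb);
        q_mouth = (paw_set - p_node) / rc;
        paw_out = paw_set;
      } else {
        p_node = (q_set + sum_p_rb) / sum_inv_rb;
        q_mouth = q_set;
        paw_out = p_node + q_set * rc;
      }
      for (int i = 0; i < n; ++i)
        if (open[i])
          rb_eff[i] = (p_node >= pel[i]) ? rb_in[i] : rb[i];
    }

    // per-compartment flows, volume update, closing rule
    double n_open_now = 0.0;
    for (int i = 0; i < n; ++i) {
      if (!open[i]) { q[i] = 0.0; continue; }
      q[i] = (p_node - pel[i]) / rb_eff[i];
      v[i] += q[i] * dt;
      if (v[i] < 1e-9) v[i] = 1e-9;
      if (!linear && v[i] <= u_close * v_ref) {
        open[i] = 0;  // derecruited: gas trapped, perfusion becomes shunt
        q[i] = 0.0;
      } else {
        n_open_now += 1.0;
      }
    }

    // ---- gas transport and exchange ----
    double accel = (t < accel_until) ? gas_accel : 1.0;

    // composition of gas supplied to inflating compartments / dead space
    double sup_o2, sup_co2;
    {
      double w_exp = 0.0, o2_exp = 0.0, co2_exp = 0.0;
      for (int i = 0; i < n; ++i)
        if (open[i] && q[i] < 0.0) {
          w_exp += -q[i];
          o2_exp += -q[i] * fo2[i];
          co2_exp += -q[i] * fco2[i];
        }
      if (q_mouth > 0.0) { // fresh gas arrives from distal dead-space slice
        w_exp += q_mouth;
        o2_exp += q_mouth * ds_o2[nds - 1];
        co2_exp += q_mouth * ds_co2[nds - 1];
      }
      if (w_exp > 0.0) { sup_o2 = o2_exp / w_exp; sup_co2 = co2_exp / w_exp; }
      else { sup_o2 = ds_o2[nds - 1]; sup_co2 = ds_co2[nds - 1]; }
    }

    // dead-space plug flow (upwind fractional advection; slice 0 = mouth)
    double adv = std::fabs(q_mouth) * dt / slice_vol;
    int nsub = (int)std::ceil(adv / 0.9);
    if (nsub > 0) {
      double f = adv / nsub;
      for (int s2 = 0; s2 < nsub; ++s2) {
        if (q_mouth > 0.0) { // toward alveoli: mouth end refilled with fresh gas
          for (int s = nds - 1; s > 0; --s) {
            ds_o2[s] += f * (ds_o2[s - 1] - ds_o2[s]);
            ds_co2[s] += f * (ds_co2[s - 1] - ds_co2[s]);
          }
          ds_o2[0] += f * (fio2 - ds_o2[0]);
          ds_co2[0] += f * (0.0 - ds_co2[0]);
        } else if (q_mouth < 0.0) { // toward mouth: distal end refilled with mixed expirate
          for (int s = 0; s < nds - 1; ++s) {
            ds_o2[s] += f * (ds_o2[s + 1] - ds_o2[s]);
            ds_co2[s] += f * (ds_co2[s + 1] - ds_co2[s]);
          }
          ds_o2[nds - 1] += f * (sup_o2 - ds_o2[nds - 1]);
          ds_co2[nds - 1] += f * (sup_co2 - ds_co2[nds - 1]);
        }
      }
    }
    if (q_mouth < -1e-9) pet_latch = ds_co2[0] * P_DRY; // expired gas at the mouth

    // alveolar stores: convection + capillary exchange
    double j_o2_sum = 0.0, j_co2_sum = 0.0; // mL/min
    for (int i = 0; i < n; ++i) {
      if (!open[i]) { ccap_o2[i] = cv_o2; ccap_co2[i] = cv_co2; continue; }
      double pa_o2 = fo2[i] * P_DRY, pa_co2 = fco2[i] * P_DRY;
      ccap_o2[i] = o2_content(pa_o2, hb);
      ccap_co2[i] = co2_content(pa_co2);
      double j_o2 = q_perf * (ccap_o2[i] - cv_o2);   // mL/min into blood
      double j_co2 = q_perf * (cv_co2 - ccap_co2[i]); // mL/min into alveoli
      j_o2_sum += j_o2;
      j_co2_sum += j_co2;
      double dn_o2, dn_co2;
      if (q[i] > 0.0) {
        dn_o2 = q[i] * sup_o2 * dt - j_o2 * dt / 60000.0;
        dn_co2 = q[i] * sup_co2 * dt + j_co2 * dt / 60000.0;
      } else {
        dn_o2 = q[i] * fo2[i] * dt - j_o2 * dt / 60000.0;
        dn_co2 = q[i] * fco2[i] * dt + j_co2 * dt / 60000.0;
      }
      // acceleration shrinks the effective gas capacitance, leaving the
      // cyclic-mean balance point unchanged
      fo2[i] += accel * (dn_o2 - fo2[i] * q[i] * dt) / v[i];
      fco2[i] += accel * (dn_co2 - fco2[i] * q[i] * dt) / v[i];
      if (fo2[i] < 1e-6) fo2[i] = 1e-6;
      if (fco2[i] < 1e-6) fco2[i] = 1e-6;
      if (fo2[i] + fco2[i] > 0.999) {
        double sc = 0.999 / (fo2[i] + fco2[i]);
        fo2[i] *= sc; fco2[i] *= sc;
      }
    }
    if (in_window && step < nsteps) {
      o2_uptake_ml += j_o2_sum * dt / 60.0;
      co2_output_ml += j_co2_sum * dt / 60.0;
    }

    // arterial mixing: perfusion-weighted end-capillary plus shunt
    {
      double s_a = shunt_anat / 100.0;
      double sum_cc_o2 = 0.0, sum_cc_co2 = 0.0;
      for (int i = 0; i < n; ++i) { sum_cc_o2 += ccap_o2[i]; sum_cc_co2 += ccap_co2[i]; }
      ca_o2 = (1.0 - s_a) * sum_cc_o2 / n + s_a * cv_o2;
      ca_co2 = (1.0 - s_a) * sum_cc_co2 / n + s_a * cv_co2;
      // mixed venous relaxes toward the Fick steady state
      double cv_o2_tgt = ca_o2 - vo2 / co;
      double cv_co2_tgt = ca_co2 + rq * vo2 / co;
      cv_o2 += (cv_o2_tgt - cv_o2) * accel * dt / tau_venous;
      cv_co2 += (cv_co2_tgt - cv_co2) * accel * dt / tau_venous;
      if (cv_o2 < 1.0) cv_o2 = 1.0;
    }

    p_node_prev = p_node;

    // ---- storage ----
    if (in_window && (step % store_every == 0) && irow < trace.nrow()) {
      double vtot = vd, plung = 0.0, vsum_open = 0.0;
      for (int i = 0; i < n; ++i) {
        vtot += v[i];
        if (open[i]) { plung += v[i] * pel[i]; vsum_open += v[i]; }
      }
      plung = (vsum_open > 0.0) ? plung / vsum_open : p_node;
      trace(irow, 0) = t;
      trace(irow, 1) = paw_out;
      trace(irow, 2) = plung;
      trace(irow, 3) = q_mouth;
      trace(irow, 4) = vtot;
      trace(irow, 5) = po2_from_content(ca_o2, hb);
      trace(irow, 6) = pco2_from_content(ca_co2);
      trace(irow, 7) = pet_latch;
      trace(irow, 8) = n_open_now;
      ++irow;
    }
  }

  List final_state = List::create(
    _["v"] = NumericVector(v.begin(), v.end()),
    _["open"] = IntegerVector(open.begin(), open.end()),
    _["f_o2"] = NumericVector(fo2.begin(), fo2.end()),
    _["f_co2"] = NumericVector(fco2.begin(), fco2.end()),
    _["ds_o2"] = NumericVector(ds_o2.begin(), ds_o2.end()),
    _["ds_co2"] = NumericVector(ds_co2.begin(), ds_co2.end()),
    _["cv_o2"] = cv_o2, _["cv_co2"] = cv_co2);

  int last_row = (int)std::max(irow - 1, (long)0);
  return List::create(
    _["trace"] = trace(Range(0, last_row), _),
    _["state"] = final_state,
    _["o2_uptake_ml"] = o2_uptake_ml,
    _["co2_output_ml"] = co2_output_ml,
    _["window_s"] = duration - store_from);
}

// [[Rcpp::export(name = ".cpp_o2_content")]]
NumericVector cpp_o2_content(NumericVector p, double hb) {
  NumericVector out(p.size());
  for (int i = 0; i < p.size(); ++i) out[i] = o2_content(p[i], hb);
  return out;
}

// [[Rcpp::export(name = ".cpp_po2_from_content")]]
NumericVector cpp_po2_from_content(NumericVector c, double hb) {
  NumericVector out(c.size());
  for (int i = 0; i < c.size(); ++i) out[i] = po2_from_content(c[i], hb);
  return out;
}
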