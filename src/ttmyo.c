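/* Compiled right-hand side of the human ventricular cardiomyocyte model with
 * a nine-shell t-tubular lumen and a single intercellular cleft layer.
 *
 * Units: time ms, voltage mV, concentration mM, volume pL, current pA.
 * A current of 1 pA corresponds to an ion flux of 1/(z*F) fmol/ms, and
 * fmol/pL = mM, so concentration derivatives are (sum of fmol/ms)/V[pL].
 *
 * The same core is exposed two ways:
 *   - deSolve compiled-model entry points (c_initmod / c_derivs) for the
 *     stiff integrators, and
 *   - a .Call wrapper (c_eval) returning the derivative and all auxiliary
 *     currents/fluxes for diagnostics and tests.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

/* ------------------------------------------------------------------ */
/* parameter, state and auxiliary-output layouts (X-macro lists keep   */
/* the C indices and the names queried from R in a single place)       */
/* ------------------------------------------------------------------ */

#define PARAM_LIST \
  X(F) X(R_gas) X(temp) \
  X(cm_tot) X(area_frac_t) \
  X(v_myo) X(v_nsr) X(v_jsr) X(v_ds) X(v_tt) X(tt_radius) X(v_cleft) \
  X(na_b) X(k_b) X(ca_b) \
  X(f_na_t) X(f_naps_t) X(f_cal_t) X(f_kto_t) X(f_kr_t) X(f_ks_t) \
  X(f_k1_t) X(f_bna_t) X(f_kna_t) X(f_nsca_t) X(f_naca_t) X(f_nak_t) \
  X(f_pca_t) X(f_cab_t) \
  X(tau_ca_ct) X(tau_k_ct) X(tau_na_ct) \
  X(tau_ca_cb) X(tau_k_cb) X(tau_na_cb) \
  X(d_rad_ca) X(d_rad_k) X(d_rad_na) \
  X(g_na) X(g_naps) X(p_cal) X(g_kto) X(g_kr) X(g_ks) X(g_k1) \
  X(g_bna) X(g_bca) X(g_kna) X(kd_kna) X(p_nsca) X(km_nsca) \
  X(k_naca) X(gamma_naca) X(km_nai_naca) X(km_ca_naca) X(ksat_naca) \
  X(alpha_naca) X(i_nak_max) X(km_k_nak) X(km_na_nak) X(pk_na_ks) \
  X(g_pca) X(km_pca) X(tau_f_scale) X(nak_v_flat) \
  X(v1_ryr) X(ka_p) X(ka_m) X(kb_p) X(kb_m) X(kc_p) X(kc_m) \
  X(vmax_f) X(vmax_r) X(k_fb) X(k_rb) X(n_fb) X(n_rb) \
  X(tau_tr) X(tau_xfer) \
  X(cmdn_tot) X(cmdn_kon) X(cmdn_koff) \
  X(htrpn_tot) X(htrpn_kon) X(htrpn_koff) \
  X(ltrpn_tot) X(ltrpn_kon) X(ltrpn_koff) \
  X(csqn_tot) X(csqn_kon) X(csqn_koff) \
  X(stim_amp) X(stim_dur) \
  X(clamp_tub) X(clamp_cleft) X(fix_naki)

#define STATE_LIST \
  X(v) \
  X(na_m0) X(na_m1) X(na_m2) X(na_m3) X(na_h) X(na_j) \
  X(cal_c0) X(cal_c1) X(cal_o) X(cal_f) X(cal_f2) X(cal_fcass) \
  X(kto_r) X(kto_s) X(kr_xr1) X(kr_xr2) X(ks_xs) \
  X(ryr_c1) X(ryr_o1) X(ryr_o2) X(ryr_c2) \
  X(ca_i) X(ca_d) X(ca_nsr) X(ca_jsr) \
  X(b_cm) X(b_htrpn) X(b_ltrpn) X(b_cs) \
  X(na_i) X(k_i) \
  X(ca_t1) X(ca_t2) X(ca_t3) X(ca_t4) X(ca_t5) X(ca_t6) X(ca_t7) X(ca_t8) X(ca_t9) \
  X(k_t1)  X(k_t2)  X(k_t3)  X(k_t4)  X(k_t5)  X(k_t6)  X(k_t7)  X(k_t8)  X(k_t9) \
  X(na_t1) X(na_t2) X(na_t3) X(na_t4) X(na_t5) X(na_t6) X(na_t7) X(na_t8) X(na_t9) \
  X(ca_c) X(k_c) X(na_c) \
  X(int_ical_s) X(int_ical_t) X(int_inaca_s) X(int_inaca_t) \
  X(int_inaca_pos_s) X(int_inaca_pos_t) X(int_icab_s) X(int_icab_t) \
  X(int_ipca_s) X(int_ipca_t) X(int_ca_i)

#define AUX_LIST \
  X(i_na_s) X(i_na_t) X(i_naps_s) X(i_naps_t) X(i_cal_s) X(i_cal_t) \
  X(i_kto_s) X(i_kto_t) X(i_kr_s) X(i_kr_t) X(i_ks_s) X(i_ks_t) \
  X(i_k1_s) X(i_k1_t) X(i_bna_s) X(i_bna_t) X(i_bca_s) X(i_bca_t) \
  X(i_kna_s) X(i_kna_t) X(i_nsna_s) X(i_nsna_t) X(i_nsk_s) X(i_nsk_t) \
  X(i_naca_s) X(i_naca_t) X(i_nak_s) X(i_nak_t) X(i_pca_s) X(i_pca_t) \
  X(i_stim) X(j_up) X(j_rel) X(j_tr) X(j_xfer) X(i_tot)

#define X(name) ip_##name,
enum { PARAM_LIST N_PARAM };
#undef X
#define X(name) is_##name,
enum { STATE_LIST N_STATE };
#undef X
#define X(name) ia_##name,
enum { AUX_LIST N_AUX };
#undef X

#define X(name) #name,
static const char *param_names[] = { PARAM_LIST };
static const char *state_names[] = { STATE_LIST };
static const char *aux_names[]   = { AUX_LIST };
#undef X

#define N_SHELL 9

static double parms[N_PARAM];

/* safe x/(exp(x)-1) style helpers for GHK fluxes */
static double expm1_ratio(double x)  /* x/(exp(x)-1) */
{
  if (fabs(x) < 1e-6) return 1.0 - x / 2.0;
  return x / expm1(x);
}

/* floor for concentrations entering logs / Hill terms, so that trial steps
 * of the implicit solver cannot generate NaNs */
static double pos(double x) { return (x > 1e-12) ? x : 1e-12; }

/* ------------------------------------------------------------------ */
/* core right-hand side                                                */
/* ------------------------------------------------------------------ */

static void model_rhs(double t, const double *y, const double *p,
                      double *dy, double *aux)
{
  const double F  = p[ip_F];
  const double RT = p[ip_R_gas] * p[ip_temp];
  const double vfrt = y[is_v] * F / RT;
  const double V = y[is_v];

  /* local extracellular concentrations seen by each membrane pool:
   * tubular pool -> first (membrane-adjacent) shell, surface pool -> cleft */
  const double ca_o_t = pos(y[is_ca_t1]), k_o_t = pos(y[is_k_t1]),
               na_o_t = pos(y[is_na_t1]);
  const double ca_o_s = pos(y[is_ca_c]), k_o_s = pos(y[is_k_c]),
               na_o_s = pos(y[is_na_c]);

  const double na_i = pos(y[is_na_i]), k_i = pos(y[is_k_i]),
               ca_i = pos(y[is_ca_i]);
  const double ca_d = pos(y[is_ca_d]);

  /* reversal potentials per pool */
  const double e_na_s = RT / F * log(na_o_s / na_i);
  const double e_na_t = RT / F * log(na_o_t / na_i);
  const double e_k_s  = RT / F * log(k_o_s / k_i);
  const double e_k_t  = RT / F * log(k_o_t / k_i);
  const double pkna   = p[ip_pk_na_ks];
  const double e_ks_s = RT / F * log((k_o_s + pkna * na_o_s) / (k_i + pkna * na_i));
  const double e_ks_t = RT / F * log((k_o_t + pkna * na_o_t) / (k_i + pkna * na_i));
  const double e_ca_s = RT / (2.0 * F) * log(ca_o_s / ca_i);
  const double e_ca_t = RT / (2.0 * F) * log(ca_o_t / ca_i);

  /* ---------------- gating kinetics (shared across pools) ----------- */

  /* fast Na+ current: 4-state activation chain (3 identical subunits)
   * plus h/j inactivation gates */
  double am, bm;
  {
    double dv = V + 47.13;
    am = (fabs(dv) < 1e-4) ? 3.2 : 0.32 * dv / (1.0 - exp(-0.1 * dv));
    bm = 0.08 * exp(-V / 11.0);
  }
  double ah, bh, aj, bj;
  if (V < -40.0) {
    ah = 0.135 * exp((80.0 + V) / -6.8);
    bh = 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V);
    aj = (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    bj = 0.1212 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
  } else {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + exp((V + 10.66) / -11.1)));
    aj = 0.0;
    bj = 0.3 * exp(-2.535e-7 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
  }
  dy[is_na_m0] = bm * y[is_na_m1] - 3.0 * am * y[is_na_m0];
  dy[is_na_m1] = 3.0 * am * y[is_na_m0] + 2.0 * bm * y[is_na_m2]
               - (bm + 2.0 * am) * y[is_na_m1];
  dy[is_na_m2] = 2.0 * am * y[is_na_m1] + 3.0 * bm * y[is_na_m3]
               - (2.0 * bm + am) * y[is_na_m2];
  dy[is_na_m3] = am * y[is_na_m2] - 3.0 * bm * y[is_na_m3];
  dy[is_na_h]  = ah * (1.0 - y[is_na_h]) - bh * y[is_na_h];
  dy[is_na_j]  = aj * (1.0 - y[is_na_j]) - bj * y[is_na_j];

  /* L-type Ca2+ current: 3-state activation chain (2 identical subunits),
   * voltage-dependent inactivation f, f2 and Ca2+-dependent gate sensing
   * the dyadic space */
  {
    double dinf = 1.0 / (1.0 + exp(-(V + 8.0) / 7.5));
    double uinf = sqrt(dinf);
    double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
    double gd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
    double taud = ad * bd + gd;
    double a = uinf / taud, b = (1.0 - uinf) / taud;
    dy[is_cal_c0] = b * y[is_cal_c1] - 2.0 * a * y[is_cal_c0];
    dy[is_cal_c1] = 2.0 * a * y[is_cal_c0] + 2.0 * b * y[is_cal_o]
                  - (b + a) * y[is_cal_c1];
    dy[is_cal_o]  = a * y[is_cal_c1] - 2.0 * b * y[is_cal_o];
  }
  {
    double finf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
    double tf = 1102.5 * exp(-(V + 27.0) * (V + 27.0) / 225.0)
              + 200.0 / (1.0 + exp((13.0 - V) / 10.0))
              + 180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;
    tf *= p[ip_tau_f_scale];
    dy[is_cal_f] = (finf - y[is_cal_f]) / tf;
    double f2inf = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
    double tf2 = 562.0 * exp(-(V + 27.0) * (V + 27.0) / 240.0)
               + 31.0 / (1.0 + exp((25.0 - V) / 10.0))
               + 80.0 / (1.0 + exp((V + 30.0) / 10.0));
    tf2 *= p[ip_tau_f_scale];
    dy[is_cal_f2] = (f2inf - y[is_cal_f2]) / tf2;
    double s2 = (ca_d / 0.05) * (ca_d / 0.05);
    double fcinf = 0.6 / (1.0 + s2) + 0.4;
    double tfc = 80.0 / (1.0 + s2) + 2.0;
    dy[is_cal_fcass] = (fcinf - y[is_cal_fcass]) / tfc;
  }

  /* transient outward K+ current gates (epicardial kinetics) */
  {
    double rinf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
    double tr = 9.5 * exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
    double sinf = 1.0 / (1.0 + exp((V + 20.0) / 5.0));
    double ts = 85.0 * exp(-(V + 45.0) * (V + 45.0) / 320.0)
              + 5.0 / (1.0 + exp((V - 20.0) / 5.0)) + 3.0;
    dy[is_kto_r] = (rinf - y[is_kto_r]) / tr;
    dy[is_kto_s] = (sinf - y[is_kto_s]) / ts;
  }

  /* rapid delayed rectifier gates */
  {
    double x1inf = 1.0 / (1.0 + exp((-26.0 - V) / 7.0));
    double a1 = 450.0 / (1.0 + exp((-45.0 - V) / 10.0));
    double b1 = 6.0 / (1.0 + exp((V + 30.0) / 11.5));
    double x2inf = 1.0 / (1.0 + exp((V + 88.0) / 24.0));
    double a2 = 3.0 / (1.0 + exp((-60.0 - V) / 20.0));
    double b2 = 1.12 / (1.0 + exp((V - 60.0) / 20.0));
    dy[is_kr_xr1] = (x1inf - y[is_kr_xr1]) / (a1 * b1);
    dy[is_kr_xr2] = (x2inf - y[is_kr_xr2]) / (a2 * b2);
  }

  /* slow delayed rectifier gate */
  {
    double xsinf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
    double axs = 1100.0 / sqrt(1.0 + exp((-10.0 - V) / 6.0));
    double bxs = 1.0 / (1.0 + exp((V - 60.0) / 20.0));
    dy[is_ks_xs] = (xsinf - y[is_ks_xs]) / (axs * bxs);
  }

  /* RyR release channel, 4-state scheme gated by dyadic Ca2+ */
  {
    double ca4 = ca_d * ca_d * ca_d * ca_d;
    double ca3 = ca_d * ca_d * ca_d;
    double r_c1o1 = p[ip_ka_p] * ca4;
    double r_o1o2 = p[ip_kb_p] * ca3;
    dy[is_ryr_c1] = p[ip_ka_m] * y[is_ryr_o1] - r_c1o1 * y[is_ryr_c1];
    dy[is_ryr_o1] = r_c1o1 * y[is_ryr_c1] + p[ip_kb_m] * y[is_ryr_o2]
                  + p[ip_kc_m] * y[is_ryr_c2]
                  - (p[ip_ka_m] + r_o1o2 + p[ip_kc_p]) * y[is_ryr_o1];
    dy[is_ryr_o2] = r_o1o2 * y[is_ryr_o1] - p[ip_kb_m] * y[is_ryr_o2];
    dy[is_ryr_c2] = p[ip_kc_p] * y[is_ryr_o1] - p[ip_kc_m] * y[is_ryr_c2];
  }

  /* ---------------- membrane currents, per pool ---------------------- */

  const double ft = 1.0; /* helper below applies pool fractions */
  (void)ft;

  const double o_na = y[is_na_m3] * y[is_na_h] * y[is_na_j];
  double i_na_s = (1.0 - p[ip_f_na_t]) * p[ip_g_na] * o_na * (V - e_na_s);
  double i_na_t = p[ip_f_na_t] * p[ip_g_na] * o_na * (V - e_na_t);

  const double o_naps = 1.0 / (1.0 + exp(-(V + 52.3) / 6.8));
  double i_naps_s = (1.0 - p[ip_f_naps_t]) * p[ip_g_naps] * o_naps * (V - e_na_s);
  double i_naps_t = p[ip_f_naps_t] * p[ip_g_naps] * o_naps * (V - e_na_t);

  /* GHK driving force for ICaL (z = 2); intracellular activity 0.25*[Ca]d */
  const double o_cal = y[is_cal_o] * y[is_cal_f] * y[is_cal_f2] * y[is_cal_fcass];
  double ghk_s, ghk_t;
  {
    double x = 2.0 * vfrt;
    double r = expm1_ratio(x);          /* x/(e^x - 1) */
    double ex = exp(x);
    /* 4*F*(F V/RT)*(ci e^x - 0.341 co)/(e^x-1) = 4*F*0.5*r*(ci e^x - .341 co) */
    ghk_s = 2.0 * F * r * (0.25 * ca_d * ex - 0.341 * ca_o_s);
    ghk_t = 2.0 * F * r * (0.25 * ca_d * ex - 0.341 * ca_o_t);
  }
  double i_cal_s = (1.0 - p[ip_f_cal_t]) * p[ip_p_cal] * o_cal * ghk_s;
  double i_cal_t = p[ip_f_cal_t] * p[ip_p_cal] * o_cal * ghk_t;

  const double o_kto = y[is_kto_r] * y[is_kto_s];
  double i_kto_s = (1.0 - p[ip_f_kto_t]) * p[ip_g_kto] * o_kto * (V - e_k_s);
  double i_kto_t = p[ip_f_kto_t] * p[ip_g_kto] * o_kto * (V - e_k_t);

  const double o_kr = y[is_kr_xr1] * y[is_kr_xr2];
  double i_kr_s = (1.0 - p[ip_f_kr_t]) * p[ip_g_kr] * sqrt(k_o_s / 5.4) * o_kr * (V - e_k_s);
  double i_kr_t = p[ip_f_kr_t] * p[ip_g_kr] * sqrt(k_o_t / 5.4) * o_kr * (V - e_k_t);

  const double o_ks = y[is_ks_xs] * y[is_ks_xs];
  double i_ks_s = (1.0 - p[ip_f_ks_t]) * p[ip_g_ks] * o_ks * (V - e_ks_s);
  double i_ks_t = p[ip_f_ks_t] * p[ip_g_ks] * o_ks * (V - e_ks_t);

  /* inward rectifier: instantaneous rectification against local EK */
  double i_k1_s, i_k1_t;
  {
    double dv = V - e_k_s;
    double a = 0.1 / (1.0 + exp(0.06 * (dv - 200.0)));
    double b = (3.0 * exp(0.0002 * (dv + 100.0)) + exp(0.1 * (dv - 10.0))) /
               (1.0 + exp(-0.5 * dv));
    i_k1_s = (1.0 - p[ip_f_k1_t]) * p[ip_g_k1] * sqrt(k_o_s / 5.4) *
             (a / (a + b)) * dv;
    dv = V - e_k_t;
    a = 0.1 / (1.0 + exp(0.06 * (dv - 200.0)));
    b = (3.0 * exp(0.0002 * (dv + 100.0)) + exp(0.1 * (dv - 10.0))) /
        (1.0 + exp(-0.5 * dv));
    i_k1_t = p[ip_f_k1_t] * p[ip_g_k1] * sqrt(k_o_t / 5.4) *
             (a / (a + b)) * dv;
  }

  double i_bna_s = (1.0 - p[ip_f_bna_t]) * p[ip_g_bna] * (V - e_na_s);
  double i_bna_t = p[ip_f_bna_t] * p[ip_g_bna] * (V - e_na_t);
  double i_bca_s = (1.0 - p[ip_f_cab_t]) * p[ip_g_bca] * (V - e_ca_s);
  double i_bca_t = p[ip_f_cab_t] * p[ip_g_bca] * (V - e_ca_t);

  /* Na+-activated K+ current (small) */
  double o_kna;
  {
    double r = p[ip_kd_kna] / na_i;
    o_kna = 0.85 / (1.0 + pow(r, 2.8));
  }
  double i_kna_s = (1.0 - p[ip_f_kna_t]) * p[ip_g_kna] * o_kna * (V - e_k_s);
  double i_kna_t = p[ip_f_kna_t] * p[ip_g_kna] * o_kna * (V - e_k_t);

  /* Ca2+-activated non-specific monovalent current (small), GHK z = 1 */
  double i_nsna_s, i_nsna_t, i_nsk_s, i_nsk_t;
  {
    double km3 = p[ip_km_nsca] * p[ip_km_nsca] * p[ip_km_nsca];
    double ca3i = ca_i * ca_i * ca_i;
    double act = ca3i / (ca3i + km3);
    double x = vfrt;
    double r = expm1_ratio(x);
    double ex = exp(x);
    double gna_s = F * r * (0.75 * na_i * ex - 0.75 * na_o_s);
    double gna_t = F * r * (0.75 * na_i * ex - 0.75 * na_o_t);
    double gk_s  = F * r * (0.75 * k_i * ex - 0.75 * k_o_s);
    double gk_t  = F * r * (0.75 * k_i * ex - 0.75 * k_o_t);
    i_nsna_s = (1.0 - p[ip_f_nsca_t]) * p[ip_p_nsca] * act * gna_s;
    i_nsna_t = p[ip_f_nsca_t] * p[ip_p_nsca] * act * gna_t;
    i_nsk_s  = (1.0 - p[ip_f_nsca_t]) * p[ip_p_nsca] * act * gk_s;
    i_nsk_t  = p[ip_f_nsca_t] * p[ip_p_nsca] * act * gk_t;
  }

  /* Na+/Ca2+ exchanger, 3:1 stoichiometry, local external Na+ and Ca2+ */
  double i_naca_s, i_naca_t;
  {
    double g = p[ip_gamma_naca];
    double e1 = exp(g * vfrt), e2 = exp((g - 1.0) * vfrt);
    double kmna3 = p[ip_km_nai_naca] * p[ip_km_nai_naca] * p[ip_km_nai_naca];
    double nai3 = na_i * na_i * na_i;
    double no3 = na_o_s * na_o_s * na_o_s;
    i_naca_s = (1.0 - p[ip_f_naca_t]) * p[ip_k_naca] *
      (e1 * nai3 * ca_o_s - e2 * no3 * ca_i * p[ip_alpha_naca]) /
      ((kmna3 + no3) * (p[ip_km_ca_naca] + ca_o_s) * (1.0 + p[ip_ksat_naca] * e2));
    no3 = na_o_t * na_o_t * na_o_t;
    i_naca_t = p[ip_f_naca_t] * p[ip_k_naca] *
      (e1 * nai3 * ca_o_t - e2 * no3 * ca_i * p[ip_alpha_naca]) /
      ((kmna3 + no3) * (p[ip_km_ca_naca] + ca_o_t) * (1.0 + p[ip_ksat_naca] * e2));
  }

  /* Na+/K+ pump, local external K+ */
  double i_nak_s, i_nak_t;
  {
    double fv = 1.0 / (1.0 + 0.1245 * exp(-0.1 * vfrt) + 0.0353 * exp(-vfrt));
    /* optional flattening of the pump's voltage dependence (0 = full
     * dependence, 1 = rate-independent mean level) */
    fv = (1.0 - p[ip_nak_v_flat]) * fv + p[ip_nak_v_flat] * 0.65;
    double fna = 1.0 / (1.0 + pow(p[ip_km_na_nak] / na_i, 2.0));
    i_nak_s = (1.0 - p[ip_f_nak_t]) * p[ip_i_nak_max] * fv * fna *
              k_o_s / (k_o_s + p[ip_km_k_nak]);
    i_nak_t = p[ip_f_nak_t] * p[ip_i_nak_max] * fv * fna *
              k_o_t / (k_o_t + p[ip_km_k_nak]);
  }

  /* sarcolemmal Ca2+ pump */
  double i_pca = p[ip_g_pca] * ca_i / (ca_i + p[ip_km_pca]);
  double i_pca_s = (1.0 - p[ip_f_pca_t]) * i_pca;
  double i_pca_t = p[ip_f_pca_t] * i_pca;

  double i_stim = p[ip_stim_amp];

  double i_tot =
    i_na_s + i_na_t + i_naps_s + i_naps_t + i_cal_s + i_cal_t +
    i_kto_s + i_kto_t + i_kr_s + i_kr_t + i_ks_s + i_ks_t +
    i_k1_s + i_k1_t + i_bna_s + i_bna_t + i_bca_s + i_bca_t +
    i_kna_s + i_kna_t + i_nsna_s + i_nsna_t + i_nsk_s + i_nsk_t +
    i_naca_s + i_naca_t + i_nak_s + i_nak_t + i_pca_s + i_pca_t;

  dy[is_v] = -(i_tot + i_stim) / p[ip_cm_tot];

  /* ---------------- intracellular Ca2+ handling ---------------------- */

  double j_up; /* cytosol -> NSR, fmol/ms */
  {
    double fb = pow(ca_i / p[ip_k_fb], p[ip_n_fb]);
    double rb = pow(y[is_ca_nsr] / p[ip_k_rb], p[ip_n_rb]);
    j_up = p[ip_v_myo] * (p[ip_vmax_f] * fb - p[ip_vmax_r] * rb) / (1.0 + fb + rb);
  }
  double j_rel = p[ip_v_jsr] * p[ip_v1_ryr] * (y[is_ryr_o1] + y[is_ryr_o2]) *
                 (y[is_ca_jsr] - ca_d);                    /* JSR -> dyad */
  double j_tr = p[ip_v_jsr] * (y[is_ca_nsr] - y[is_ca_jsr]) / p[ip_tau_tr];
  double j_xfer = p[ip_v_myo] * (ca_d - ca_i) / p[ip_tau_xfer]; /* dyad -> cytosol */

  /* dynamic buffers (bound concentration in the host compartment) */
  double jb_cm = p[ip_cmdn_kon] * ca_i * (p[ip_cmdn_tot] - y[is_b_cm])
               - p[ip_cmdn_koff] * y[is_b_cm];
  double jb_h  = p[ip_htrpn_kon] * ca_i * (p[ip_htrpn_tot] - y[is_b_htrpn])
               - p[ip_htrpn_koff] * y[is_b_htrpn];
  double jb_l  = p[ip_ltrpn_kon] * ca_i * (p[ip_ltrpn_tot] - y[is_b_ltrpn])
               - p[ip_ltrpn_koff] * y[is_b_ltrpn];
  double jb_cs = p[ip_csqn_kon] * y[is_ca_jsr] * (p[ip_csqn_tot] - y[is_b_cs])
               - p[ip_csqn_koff] * y[is_b_cs];
  dy[is_b_cm] = jb_cm;
  dy[is_b_htrpn] = jb_h;
  dy[is_b_ltrpn] = jb_l;
  dy[is_b_cs] = jb_cs;

  /* net sarcolemmal Ca2+-carried currents per pool (outward positive) */
  double i_ca_mem_s = i_cal_s + i_bca_s + i_pca_s - 2.0 * i_naca_s;
  double i_ca_mem_t = i_cal_t + i_bca_t + i_pca_t - 2.0 * i_naca_t;

  /* ICaL delivers Ca2+ into the dyadic space; the remaining Ca2+ fluxes act
   * on the bulk cytosol */
  double j_cal = -(i_cal_s + i_cal_t) / (2.0 * F);   /* fmol/ms into dyad */
  double j_ca_other = -(i_bca_s + i_bca_t + i_pca_s + i_pca_t
                        - 2.0 * (i_naca_s + i_naca_t)) / (2.0 * F);

  dy[is_ca_d] = (j_cal + j_rel - j_xfer) / p[ip_v_ds];
  dy[is_ca_i] = (j_ca_other + j_xfer - j_up) / p[ip_v_myo]
              - (jb_cm + jb_h + jb_l);
  dy[is_ca_nsr] = (j_up - j_tr) / p[ip_v_nsr];
  dy[is_ca_jsr] = (j_tr - j_rel) / p[ip_v_jsr] - jb_cs;

  /* ---------------- intracellular Na+ and K+ ------------------------- */

  double i_na_mem = i_na_s + i_na_t + i_naps_s + i_naps_t + i_bna_s + i_bna_t +
                    i_nsna_s + i_nsna_t +
                    3.0 * (i_nak_s + i_nak_t) + 3.0 * (i_naca_s + i_naca_t);
  double i_k_mem = i_kto_s + i_kto_t + i_kr_s + i_kr_t + i_ks_s + i_ks_t +
                   i_k1_s + i_k1_t + i_kna_s + i_kna_t + i_nsk_s + i_nsk_t -
                   2.0 * (i_nak_s + i_nak_t);
  /* stimulus charge is carried by K+ so that long runs conserve mass */
  dy[is_na_i] = -i_na_mem / (F * p[ip_v_myo]);
  dy[is_k_i]  = -(i_k_mem + i_stim) / (F * p[ip_v_myo]);
  if (p[ip_fix_naki] > 0.5) { dy[is_na_i] = 0.0; dy[is_k_i] = 0.0; }

  /* ---------------- extracellular spaces ----------------------------- */

  /* per-pool, per-species membrane charge fluxes (outward positive): a
   * positive current adds cations to the adjacent extracellular space */
  double i_na_mem_t = i_na_t + i_naps_t + i_bna_t + i_nsna_t +
                      3.0 * i_nak_t + 3.0 * i_naca_t;
  double i_na_mem_s2 = i_na_s + i_naps_s + i_bna_s + i_nsna_s +
                       3.0 * i_nak_s + 3.0 * i_naca_s;
  double i_k_mem_t = i_kto_t + i_kr_t + i_ks_t + i_k1_t + i_kna_t + i_nsk_t -
                     2.0 * i_nak_t;
  double i_k_mem_s2 = i_kto_s + i_kr_s + i_ks_s + i_k1_s + i_kna_s + i_nsk_s -
                      2.0 * i_nak_s;

  /* shell volumes: equal-thickness concentric annuli, shell 1 outermost */
  double vsh[N_SHELL], vtt = p[ip_v_tt];
  {
    int k;
    for (k = 0; k < N_SHELL; k++) {
      double ro = (double)(N_SHELL - k) / N_SHELL;   /* outer radius fraction */
      double ri = (double)(N_SHELL - k - 1) / N_SHELL;
      vsh[k] = vtt * (ro * ro - ri * ri);
    }
  }

  /* radial inter-shell conductances G_k between shells k and k+1 (pL/ms):
   * G = D_eff * A_interface / dr with A = 2*pi*r*L and L = vtt/(pi a^2) */
  double grad_ca[N_SHELL - 1], grad_k[N_SHELL - 1], grad_na[N_SHELL - 1];
  {
    int k;
    double a_cm = p[ip_tt_radius] * 1e-4;         /* um -> cm */
    double vtt_cm3 = vtt * 1e-9;                  /* pL -> cm^3 */
    double len = vtt_cm3 / (M_PI * a_cm * a_cm);  /* cm */
    double dr = a_cm / N_SHELL;
    for (k = 0; k < N_SHELL - 1; k++) {
      double r = a_cm * (double)(N_SHELL - k - 1) / N_SHELL;
      double area = 2.0 * M_PI * r * len;         /* cm^2 */
      double gfac = area / dr * 1e6;              /* cm^3/s -> pL/ms */
      grad_ca[k] = p[ip_d_rad_ca] * gfac;
      grad_k[k]  = p[ip_d_rad_k] * gfac;
      grad_na[k] = p[ip_d_rad_na] * gfac;
    }
  }

  {
    int k, ion;
    const int base[3] = { is_ca_t1, is_k_t1, is_na_t1 };
    const double tau_ct[3] = { p[ip_tau_ca_ct], p[ip_tau_k_ct], p[ip_tau_na_ct] };
    const double tau_cb[3] = { p[ip_tau_ca_cb], p[ip_tau_k_cb], p[ip_tau_na_cb] };
    const double cb[3] = { p[ip_ca_b], p[ip_k_b], p[ip_na_b] };
    const int icleft[3] = { is_ca_c, is_k_c, is_na_c };
    const double imem_t[3] = { i_ca_mem_t, i_k_mem_t, i_na_mem_t };
    const double imem_s[3] = { i_ca_mem_s, i_k_mem_s2, i_na_mem_s2 };
    const double zval[3] = { 2.0, 1.0, 1.0 };

    for (ion = 0; ion < 3; ion++) {
      const double *c = y + base[ion];
      double *dc = dy + base[ion];
      const double *g = (ion == 0) ? grad_ca : (ion == 1) ? grad_k : grad_na;
      double cmean = 0.0;
      for (k = 0; k < N_SHELL; k++) cmean += c[k] * vsh[k];
      cmean /= vtt;
      double mouth_rate = (cmean - y[icleft[ion]]) / tau_ct[ion]; /* mM/ms */

      for (k = 0; k < N_SHELL; k++) {
        double flux = 0.0;                       /* fmol/ms into shell k */
        if (k > 0) flux += g[k - 1] * (c[k - 1] - c[k]);
        if (k < N_SHELL - 1) flux += g[k] * (c[k + 1] - c[k]);
        dc[k] = flux / vsh[k] - mouth_rate;
      }
      /* membrane source enters the membrane-adjacent shell (index 1) */
      dc[0] += imem_t[ion] / (zval[ion] * F) / vsh[0];

      /* cleft: tubule mouth exchange + surface membrane + bulk exchange */
      dy[icleft[ion]] =
        (vtt * mouth_rate + imem_s[ion] / (zval[ion] * F)) / p[ip_v_cleft]
        - (y[icleft[ion]] - cb[ion]) / tau_cb[ion];
    }
  }

  if (p[ip_clamp_tub] > 0.5) {
    int k;
    for (k = 0; k < 3 * N_SHELL; k++) dy[is_ca_t1 + k] = 0.0;
  }
  if (p[ip_clamp_cleft] > 0.5) {
    dy[is_ca_c] = 0.0; dy[is_k_c] = 0.0; dy[is_na_c] = 0.0;
  }

  /* ---------------- per-cycle integral accumulators ------------------ */

  dy[is_int_ical_s] = i_cal_s;
  dy[is_int_ical_t] = i_cal_t;
  dy[is_int_inaca_s] = i_naca_s;
  dy[is_int_inaca_t] = i_naca_t;
  dy[is_int_inaca_pos_s] = (i_naca_s > 0.0) ? i_naca_s : 0.0;
  dy[is_int_inaca_pos_t] = (i_naca_t > 0.0) ? i_naca_t : 0.0;
  dy[is_int_icab_s] = i_bca_s;
  dy[is_int_icab_t] = i_bca_t;
  dy[is_int_ipca_s] = i_pca_s;
  dy[is_int_ipca_t] = i_pca_t;
  dy[is_int_ca_i] = ca_i;

  if (aux) {
    aux[ia_i_na_s] = i_na_s;     aux[ia_i_na_t] = i_na_t;
    aux[ia_i_naps_s] = i_naps_s; aux[ia_i_naps_t] = i_naps_t;
    aux[ia_i_cal_s] = i_cal_s;   aux[ia_i_cal_t] = i_cal_t;
    aux[ia_i_kto_s] = i_kto_s;   aux[ia_i_kto_t] = i_kto_t;
    aux[ia_i_kr_s] = i_kr_s;     aux[ia_i_kr_t] = i_kr_t;
    aux[ia_i_ks_s] = i_ks_s;     aux[ia_i_ks_t] = i_ks_t;
    aux[ia_i_k1_s] = i_k1_s;     aux[ia_i_k1_t] = i_k1_t;
    aux[ia_i_bna_s] = i_bna_s;   aux[ia_i_bna_t] = i_bna_t;
    aux[ia_i_bca_s] = i_bca_s;   aux[ia_i_bca_t] = i_bca_t;
    aux[ia_i_kna_s] = i_kna_s;   aux[ia_i_kna_t] = i_kna_t;
    aux[ia_i_nsna_s] = i_nsna_s; aux[ia_i_nsna_t] = i_nsna_t;
    aux[ia_i_nsk_s] = i_nsk_s;   aux[ia_i_nsk_t] = i_nsk_t;
    aux[ia_i_naca_s] = i_naca_s; aux[ia_i_naca_t] = i_naca_t;
    aux[ia_i_nak_s] = i_nak_s;   aux[ia_i_nak_t] = i_nak_t;
    aux[ia_i_pca_s] = i_pca_s;   aux[ia_i_pca_t] = i_pca_t;
    aux[ia_i_stim] = i_stim;
    aux[ia_j_up] = j_up;   aux[ia_j_rel] = j_rel;
    aux[ia_j_tr] = j_tr;   aux[ia_j_xfer] = j_xfer;
    aux[ia_i_tot] = i_tot;
  }
  (void)t;
}

/* ------------------------------------------------------------------ */
/* deSolve compiled-model interface                                    */
/* ------------------------------------------------------------------ */

void c_initmod(void (*odeparms)(int *, double *))
{
  int n = N_PARAM;
  odeparms(&n, parms);
}

void c_derivs(int *neq, double *t, double *y, double *ydot,
              double *yout, int *ip)
{
  double aux[N_AUX];
  model_rhs(*t, y, parms, ydot, aux);
  if (ip[0] >= N_AUX) {
    int k;
    for (k = 0; k < N_AUX; k++) yout[k] = aux[k];
  }
  (void)neq;
}

/* ------------------------------------------------------------------ */
/* .Call interface for diagnostics and tests                            */
/* ------------------------------------------------------------------ */

static SEXP chr_vector(const char **names, int n)
{
  SEXP out = PROTECT(allocVector(STRSXP, n));
  int k;
  for (k = 0; k < n; k++) SET_STRING_ELT(out, k, mkChar(names[k]));
  UNPROTECT(1);
  return out;
}

SEXP c_param_names(void) { return chr_vector(param_names, N_PARAM); }
SEXP c_state_names(void) { return chr_vector(state_names, N_STATE); }
SEXP c_aux_names(void)   { return chr_vector(aux_names, N_AUX); }

SEXP c_eval(SEXP t, SEXP y, SEXP p)
{
  if (LENGTH(y) != N_STATE)
    error("state vector must have %d entries, got %d", N_STATE, LENGTH(y));
  if (LENGTH(p) != N_PARAM)
    error("parameter vector must have %d entries, got %d", N_PARAM, LENGTH(p));
  SEXP dy = PROTECT(allocVector(REALSXP, N_STATE));
  SEXP aux = PROTECT(allocVector(REALSXP, N_AUX));
  model_rhs(asReal(t), REAL(y), REAL(p), REAL(dy), REAL(aux));
  setAttrib(dy, R_NamesSymbol, c_state_names());
  setAttrib(aux, R_NamesSymbol, c_aux_names());
  SEXP out = PROTECT(allocVector(VECSXP, 2));
  SET_VECTOR_ELT(out, 0, dy);
  SET_VECTOR_ELT(out, 1, aux);
  SEXP nm = PROTECT(allocVector(STRSXP, 2));
  SET_STRING_ELT(nm, 0, mkChar("derivatives"));
  SET_STRING_ELT(nm, 1, mkChar("aux"));
  setAttrib(out, R_NamesSymbol, nm);
  UNPROTECT(4);
  return out;
}
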