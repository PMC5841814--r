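// Coupled forward-Euler core for the tripartite-synapse model.
//
// One fixed-step loop integrates, in a documented order, the presynaptic
// Hodgkin-Huxley pair (CA3 pyramidal bouton + GABAergic interneuron with the
// muOR/G-protein/VGCC chain), presynaptic fast/slow calcium, the five-site
// calcium-sensor release ladder (per-vesicle CTMC, frozen-rate Gillespie
// within each Euler step), cleft glutamate, the astrocyte (Li-Rinzel IP3R
// with agonist-dependent IP3 production, three release gates, vesicle pools,
// gliotransmitter), and the postsynaptic spine (AMPAR/NMDAR currents with
// morphine-modulated Mg block, stochastic L-type channels, the CaMKII/PP1
// ladder, the AMPAR-conductance map and the NO feedback boost).
//
// All couplings inside one step use previous-step values; the NO boost
// computed from Ph.CaMKII at step k acts on the sensor at step k+1.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ with splitmix64 seeding.  Three independent sub-streams
// (sensor CTMC, spontaneous Poisson, postsynaptic binomial channels) are
// derived from the master seed so that disabling one noise source leaves the
// draws of the others untouched.
// ---------------------------------------------------------------------------
namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t seed_val) {
    uint64_t x = seed_val;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // uniform on (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
};

inline double vtrap(double x, double y) {
  // x / (exp(x/y) - 1) with the removable singularity at x = 0
  if (std::fabs(x / y) < 1e-6) return y * (1.0 - x / (2.0 * y));
  return x / (std::exp(x / y) - 1.0);
}

struct HHRates {
  double an, bn, am, bm, ah, bh;
};

inline HHRates hh_rates(double V) {
  HHRates r;
  r.an = 0.01 * vtrap(-V - 60.0, 10.0);
  r.am = 0.1 * vtrap(-V - 45.0, 10.0);
  r.ah = 0.07 * std::exp((-V - 70.0) / 20.0);
  r.bn = 0.125 * std::exp((-V - 70.0) / 80.0);
  r.bm = 4.0 * std::exp((-V - 70.0) / 18.0);
  r.bh = 1.0 / (std::exp((-V - 40.0) / 10.0) + 1.0);
  return r;
}

inline double hill(double x, double K) { return x / (x + K); }

inline double hill_n(double x, double K, double n) {
  double xn = std::pow(x, n), Kn = std::pow(K, n);
  return xn / (xn + Kn);
}

struct Params {
  // neuron / GABA / GPCR
  double g_gaba_max, v_gaba, tau_g;
  double tau_mor, mor_max, mor_kd, mor_hill;
  double k_minus_max, k_minus_slope, k_plus_coef;
  // fast presynaptic calcium
  double rho_ca, a_btn, g_ca_single, ca_conv_btn, c_ext, c_rest;
  double v_mca, k_mca, tau_mca, nu_pmca, k_pmca, nu_leak, rt_zf;
  // slow presynaptic calcium (Li-Rinzel + IP3)
  double c1, nu1, nu2, nu3, k3, c0_pre;
  double d1, d2, d3, d5, a2;
  double nu_g, k_g, tau_p, p0;
  // sensor / pools / cleft
  double alpha_s, beta_s, gamma_s, delta_s, t_refr;
  double tau_rec, tau_inac;
  double sp_a1, sp_a2, sp_a3, c_md0, v_spont_gate;
  double n_vd, g_vc, g_c;
  // astrocyte
  double nu_beta, K_R, K_p, K_pi, nu_delta, k_delta, K_plcd;
  double nu_3k, K_D, K_3, r_5;
  double c1a, r_ca, r_l, v_er, K_er;
  double d1a, d2a, d3a, d5a, a2a, c_tot_a;
  double c_thresh, tau_rec_a, tau_inact_a;
  double k1p, k1m, k2p, k2m, k3p, k3m;
  double nva, gva, kappa_a, gca_clear;
  // spine voltage / receptors
  double tau_post, v_rest_post, r_m, v_ampa, v_nmda;
  double alpha_ampa, beta_ampa, a1_ampa, a2_ampa;
  double alpha_nmda, beta_nmda, k1_nmda, k2_nmda;
  double g_vi, g_nmda_inc, k_gvd, v0_gvd, tau_gvd;
  double mg0, k0_mg, mg_k_inc, z_mg, delta_mg, delta_mg_inc, f_rt;
  double s_ampa;
  // postsynaptic calcium
  double eta, gamma_n, ca_conv_spine, k_s, c_post_rest, b_t, k_endo;
  double g_l_ca, n_chan, p_open, v_l_ca;
  // CaMKII / PP1
  double camkii_total, k1_cam, K_H1, k2_cam, K_M;
  double ep0, i0, k3_cam, k4_cam, nu_pka, nu_can, K_H2;
  // NO / AMPA map
  double p_half, k_half, k_syt;
  double ek_K, ek_max, ep_max, ep_K, a_t;

  void load(const List &pl) {
    NumericVector v = pl["values"];
    CharacterVector nm = v.names();
    std::map<std::string, double> m;
    for (int i = 0; i < v.size(); ++i) m[as<std::string>(nm[i])] = v[i];
    auto g = [&](const char *k) {
      auto it = m.find(k);
      if (it == m.end()) stop("missing parameter '%s'", k);
      return it->second;
    };
    g_gaba_max = g("g_gaba_max"); v_gaba = g("v_gaba"); tau_g = g("tau_g");
    tau_mor = g("tau_mor"); mor_max = g("mor_max"); mor_kd = g("mor_kd");
    mor_hill = g("mor_hill"); k_minus_max = g("k_minus_max");
    k_minus_slope = g("k_minus_slope"); k_plus_coef = g("k_plus_coef");
    rho_ca = g("rho_ca"); a_btn = g("a_btn"); g_ca_single = g("g_ca_single");
    ca_conv_btn = g("ca_conv_btn"); c_ext = g("c_ext"); c_rest = g("c_rest");
    v_mca = g("v_mca"); k_mca = g("k_mca"); tau_mca = g("tau_mca");
    nu_pmca = g("nu_pmca"); k_pmca = g("k_pmca"); nu_leak = g("nu_leak");
    rt_zf = g("rt_zf");
    c1 = g("c1"); nu1 = g("nu1"); nu2 = g("nu2"); nu3 = g("nu3"); k3 = g("k3");
    c0_pre = g("c0_pre");
    d1 = g("d1"); d2 = g("d2"); d3 = g("d3"); d5 = g("d5"); a2 = g("a2");
    nu_g = g("nu_g"); k_g = g("k_g"); tau_p = g("tau_p"); p0 = g("p0");
    alpha_s = g("sensor_alpha"); beta_s = g("sensor_beta");
    gamma_s = g("sensor_gamma"); delta_s = g("sensor_delta");
    t_refr = g("t_refractory");
    tau_rec = g("tau_rec"); tau_inac = g("tau_inac");
    sp_a1 = g("spont_a1"); sp_a2 = g("spont_a2"); sp_a3 = g("spont_a3");
    c_md0 = g("c_md0"); v_spont_gate = g("v_spont_gate");
    n_vd = g("n_v"); g_vc = g("g_v"); g_c = g("g_c");
    nu_beta = g("nu_beta"); K_R = g("K_R"); K_p = g("K_p"); K_pi = g("K_pi");
    nu_delta = g("nu_delta"); k_delta = g("k_delta"); K_plcd = g("K_plcd");
    nu_3k = g("nu_3k"); K_D = g("K_D"); K_3 = g("K_3"); r_5 = g("r_5");
    c1a = g("c1a"); r_ca = g("r_ca"); r_l = g("r_l"); v_er = g("v_er");
    K_er = g("K_er");
    d1a = g("d1a"); d2a = g("d2a"); d3a = g("d3a"); d5a = g("d5a");
    a2a = g("a2a"); c_tot_a = g("c_tot_a");
    c_thresh = g("c_thresh"); tau_rec_a = g("tau_rec_a");
    tau_inact_a = g("tau_inact_a");
    k1p = g("k1_plus"); k1m = g("k1_minus"); k2p = g("k2_plus");
    k2m = g("k2_minus"); k3p = g("k3_plus"); k3m = g("k3_minus");
    nva = g("n_v_a"); gva = g("g_v_a"); kappa_a = g("kappa_a");
    gca_clear = g("g_c_a");
    tau_post = g("tau_post"); v_rest_post = g("v_rest_post"); r_m = g("r_m");
    v_ampa = g("v_ampa"); v_nmda = g("v_nmda");
    alpha_ampa = g("alpha_ampa"); beta_ampa = g("beta_ampa");
    a1_ampa = g("a1_ampa"); a2_ampa = g("a2_ampa");
    alpha_nmda = g("alpha_nmda"); beta_nmda = g("beta_nmda");
    k1_nmda = g("k1_nmda"); k2_nmda = g("k2_nmda");
    g_vi = g("g_vi"); g_nmda_inc = g("g_nmda_morph_inc");
    k_gvd = g("k_gvd"); v0_gvd = g("v0_gvd"); tau_gvd = g("tau_gvd");
    mg0 = g("mg0"); k0_mg = g("k0_mg"); mg_k_inc = g("mg_k_inc");
    z_mg = g("z_mg"); delta_mg = g("delta_mg");
    delta_mg_inc = g("delta_mg_inc"); f_rt = g("f_rt");
    s_ampa = g("s_ampa");
    eta = g("eta"); gamma_n = g("gamma_nmda");
    ca_conv_spine = g("ca_conv_spine"); k_s = g("k_s");
    c_post_rest = g("c_post_rest"); b_t = g("b_t"); k_endo = g("k_endo");
    g_l_ca = g("g_l_ca"); n_chan = g("n_chan"); p_open = g("p_open");
    v_l_ca = g("v_l_ca");
    camkii_total = g("camkii_total"); k1_cam = g("k1_cam");
    K_H1 = g("K_H1"); k2_cam = g("k2_cam"); K_M = g("K_M");
    ep0 = g("ep0"); i0 = g("i0"); k3_cam = g("k3_cam"); k4_cam = g("k4_cam");
    nu_pka = g("nu_pka"); nu_can = g("nu_can"); K_H2 = g("K_H2");
    p_half = g("p_half"); k_half = g("k_half"); k_syt = g("k_syt");
    ek_K = g("ek_K"); ek_max = g("ek_max"); ep_max = g("ep_max");
    ep_K = g("ep_K"); a_t = g("a_t");
  }
};

inline double morph_hill(double morph, double kd, double n) {
  if (morph <= 0.0) return 0.0;
  return 1.0 / (1.0 + std::pow(kd / morph, n));
}

inline double mg_unblock(double morph, double v, const Params &P) {
  double H = morph_hill(morph, P.mor_kd, P.mor_hill);
  double K0_eff = P.k0_mg + P.mg_k_inc * H;
  double delta_eff = P.delta_mg + P.delta_mg_inc * H;
  return 1.0 / (1.0 + (P.mg0 / K0_eff) *
                std::exp(-P.z_mg * delta_eff * P.f_rt * v));
}

// AMPAR conductance map (kinase/phosphatase Hill functions of Ph.CaMKII);
// closed form g/A_T = ((EP + 2 EK) / (EP + EK))^2.
inline double g_ampa_map(double ph, const Params &P) {
  double ph2 = ph * ph;
  double EP = 1.0 + P.ep_max * ph2 / (P.ep_K * P.ep_K + ph2);
  double EK = 1.0 + P.ek_max * ph2 / (P.ek_K * P.ek_K + ph2);
  double r = (EP + 2.0 * EK) / (EP + EK);
  return P.a_t * r * r;
}

// camkii ladder autophosphorylation coefficient pattern on nu2
const double CK_COEF[9] = {1.0, 1.8, 2.3, 2.7, 2.8, 2.7, 2.3, 1.8, 1.0};

}  // namespace

// ---------------------------------------------------------------------------
// Per-vesicle sensor CTMC: states 0 = X .. 5 = X(c)5, 6 = X(c)5*.
// Frozen-rate Gillespie within one Euler step.
// ---------------------------------------------------------------------------
static inline int ladder_advance(int s, double c, double alpha_eff, double beta,
                                 double gam, double del, double dt,
                                 Xoshiro &rng) {
  double t = 0.0;
  while (true) {
    double fwd = 0.0, bwd = 0.0;
    if (s < 5) fwd = (5 - s) * alpha_eff * c;       // X_s -> X_{s+1}
    else if (s == 5) fwd = gam;                     // X5 -> X5*
    if (s >= 1 && s <= 5) bwd = s * beta;           // X_s -> X_{s-1}
    else if (s == 6) bwd = del;                     // X5* -> X5
    double tot = fwd + bwd;
    if (tot <= 0.0) return s;
    double dtau = -std::log(rng.unif()) / tot;
    t += dtau;
    if (t > dt) return s;
    if (rng.unif() * tot < fwd) s += 1; else s -= 1;
  }
}

// [[Rcpp::export(name = ".ladder_ctmc_cpp")]]
NumericMatrix ladder_ctmc_cpp(double c_i, double alpha_eff, double beta,
                              double gamma_s, double delta_s, double t_end,
                              double dt, int n_rep, int sample_stride,
                              double seed) {
  Xoshiro rng;
  rng.seed(static_cast<uint64_t>(seed));
  int n_steps = static_cast<int>(std::round(t_end / dt));
  int n_samp = n_steps / sample_stride + 1;
  NumericMatrix occ(n_samp, 8);  // t + 7 states
  std::vector<int> state(n_rep, 0);
  int row = 0;
  for (int k = 0; k <= n_steps; ++k) {
    if (k % sample_stride == 0) {
      occ(row, 0) = k * dt;
      for (int r = 0; r < n_rep; ++r) occ(row, 1 + state[r]) += 1.0;
      for (int j = 1; j <= 7; ++j) occ(row, j) /= n_rep;
      ++row;
    }
    if (k == n_steps) break;
    for (int r = 0; r < n_rep; ++r)
      state[r] = ladder_advance(state[r], c_i, alpha_eff, beta, gamma_s,
                                delta_s, dt, rng);
  }
  return occ;
}

// ---------------------------------------------------------------------------
// Full model core.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".sim_core_cpp")]]
List sim_core_cpp(List params, List config, List protocol, double dt,
                  double duration_ms, double settle_ms, double seed,
                  int record_stride, bool presyn_only, bool no_feedback,
                  double burn_in_ms) {
  Params P;
  P.load(params);

  const double morphine = as<double>(config["morphine_uM"]);
  const bool pre_on = as<bool>(config["presyn_mu_or_on"]);
  const bool post_on = as<bool>(config["postsyn_mu_or_on"]);
  const bool mglur_on = as<bool>(config["astro_mglur_on"]);
  const bool glio_on = as<bool>(config["gliotransmission_on"]);
  const double glt_factor = as<double>(config["glt_factor"]);

  const double morph_pre = pre_on ? morphine : 0.0;
  const double morph_post = post_on ? morphine : 0.0;
  const double g_c_eff = P.g_c * glt_factor;

  const double stim_amp = as<double>(protocol["amplitude_uA_cm2"]);
  const double stim_freq = as<double>(protocol["freq_hz"]);
  const double stim_width = as<double>(protocol["width_ms"]);
  const double stim_period = 1000.0 / stim_freq;

  Xoshiro rng_sensor, rng_spont, rng_chan;
  {
    uint64_t s = static_cast<uint64_t>(seed);
    uint64_t base = Xoshiro::splitmix64(s);
    rng_sensor.seed(base ^ 0x1111111111111111ULL);
    rng_spont.seed(base ^ 0x2222222222222222ULL);
    rng_chan.seed(base ^ 0x3333333333333333ULL);
  }

  // ---- state ----
  double Vp = -70.0, Vi = -70.0;
  HHRates r0 = hh_rates(-70.0);
  double mp = r0.am / (r0.am + r0.bm), hp = r0.ah / (r0.ah + r0.bh),
         np_ = r0.an / (r0.an + r0.bn);
  double mi = mp, hi = hp, ni = np_;
  double gg = 0.0;  // activated GABA_A fraction; g_inf(-70 mV) ~ 0
  double MOR = 0.0, CaCh = 1.0;
  double mCa = 1.0 / (1.0 + std::exp((P.v_mca + 70.0) / P.k_mca));
  double cFast = P.c_rest, cSlow = 0.0;
  double cER = (P.c0_pre - P.c_rest) / P.c1;
  double pPre = P.p0;
  double qPre;
  {
    double aq = P.a2 * P.d2 * (P.p0 + P.d1) / (P.p0 + P.d3);
    double bq = P.a2 * P.c_rest;
    qPre = aq / (aq + bq);
  }
  int sensor[2] = {0, 0};
  double refr_until = -1e30;
  double Rv = 1.0, Ev = 0.0;
  double glut = 0.0;
  // astrocyte
  double pa = 0.05, ha = 0.8, ca = 0.07;
  double O1, O2, O3;
  O1 = P.k1p * ca / (P.k1p * ca + P.k1m);
  O2 = P.k2p * ca / (P.k2p * ca + P.k2m);
  O3 = P.k3p * ca / (P.k3p * ca + P.k3m);
  double Ra = 1.0, Ea = 0.0, ga = 0.0;
  // spine
  double Vpost = P.v_rest_post, mA = 0.0, mN = 0.0, gVD = 0.0;
  double cpost = P.c_post_rest;
  double Pk[11];
  Pk[0] = P.camkii_total;
  for (int i = 1; i <= 10; ++i) Pk[i] = 0.0;
  double ep = P.ep0, I1p = 0.0;
  double boost = 0.0;  // NO feedback increment applied next step

  const double vCa = P.rt_zf * std::log(P.c_ext / P.c_rest);

  long n_steps = static_cast<long>(std::round(duration_ms / dt));
  long n_settle = static_cast<long>(std::round(settle_ms / dt));
  long n_rec = n_steps / record_stride + 1;

  const int NC = 29;
  NumericMatrix trace(n_rec, NC);

  // accumulators
  double ipsc_peak_late = 0.0, g_peak_late = 0.0, cach_late_sum = 0.0;
  long cach_late_n = 0;
  double sum_glut = 0.0, sum_glio = 0.0, sum_ph = 0.0, sum_gampa = 0.0;
  long n_stat = 0;
  long n_evoked = 0, n_spont = 0;
  long spikes_pre = 0, spikes_int = 0;
  double late_start = duration_ms - 10000.0;
  if (late_start < 0) late_start = 0.0;

  long row = 0;
  double i_gaba = 0.0, i_ampa_cur = 0.0, i_nmda_cur = 0.0, mg_cur = 0.0;
  double ph_cur = 0.0, gmap_cur = g_ampa_map(0.0, P);

  for (long k = -n_settle; k <= n_steps; ++k) {
    bool settling = (k < 0);
    double t = k * dt;

    // ---- record + finiteness check ----
    if (!settling && (k % record_stride == 0)) {
      double vals[NC] = {t, Vp, Vi, gg, i_gaba, MOR, CaCh, mCa, cFast, cSlow,
                         pPre, glut, Rv, Ev,
                         static_cast<double>(n_evoked + n_spont),
                         ca, pa, ha, O1 * O2 * O3, Ra, Ea, ga, Vpost,
                         i_ampa_cur, i_nmda_cur, mg_cur, cpost, ph_cur,
                         P.s_ampa * gmap_cur};
      for (int j = 0; j < NC; ++j) {
        if (!std::isfinite(vals[j]))
          stop("integration failure: non-finite value in column %d at t = %.3f ms",
               j + 1, t);
        trace(row, j) = vals[j];
      }
      ++row;
    }
    if (!settling) {
      if (t >= late_start) {
        if (i_gaba > ipsc_peak_late) ipsc_peak_late = i_gaba;
        if (gg > g_peak_late) g_peak_late = gg;
        cach_late_sum += CaCh; ++cach_late_n;
      }
      if (t >= burn_in_ms) {
        sum_glut += glut; sum_glio += ga; sum_ph += ph_cur;
        sum_gampa += P.s_ampa * gmap_cur; ++n_stat;
      }
    }
    if (k == n_steps) break;

    double Iapp = 0.0;
    if (!settling) {
      double phase = t - std::floor(t / stim_period) * stim_period;
      if (phase < stim_width) Iapp = stim_amp;
    }
    double morph_now_pre = settling ? 0.0 : morph_pre;
    double morph_now_post = settling ? 0.0 : morph_post;

    // ---------------- 1. neurons (H-H) ----------------
    double Vp_old = Vp, Vi_old = Vi;
    i_gaba = P.g_gaba_max * gg * (Vp_old - P.v_gaba);
    {
      HHRates rp = hh_rates(Vp_old);
      double dVp = Iapp - 36.0 * std::pow(np_, 4) * (Vp_old + 82.0)
                   - 120.0 * mp * mp * mp * hp * (Vp_old - 45.0)
                   - 0.3 * (Vp_old + 59.4) - i_gaba;
      HHRates ri = hh_rates(Vi_old);
      double dVi = Iapp - 36.0 * std::pow(ni, 4) * (Vi_old + 82.0)
                   - 120.0 * mi * mi * mi * hi * (Vi_old - 45.0)
                   - 0.3 * (Vi_old + 59.4);
      double Vp_new = Vp_old + dt * dVp;
      double Vi_new = Vi_old + dt * dVi;
      if (Vp_old < 0.0 && Vp_new >= 0.0) ++spikes_pre;
      if (Vi_old < 0.0 && Vi_new >= 0.0) ++spikes_int;
      mp += dt * (rp.am * (1.0 - mp) - rp.bm * mp);
      hp += dt * (rp.ah * (1.0 - hp) - rp.bh * hp);
      np_ += dt * (rp.an * (1.0 - np_) - rp.bn * np_);
      mi += dt * (ri.am * (1.0 - mi) - ri.bm * mi);
      hi += dt * (ri.ah * (1.0 - hi) - ri.bh * hi);
      ni += dt * (ri.an * (1.0 - ni) - ri.bn * ni);
      Vp = Vp_new; Vi = Vi_new;
    }

    // ---------------- 2. GPCR / GABA gate ----------------
    {
      double mor_inf =
          P.mor_max * morph_hill(morph_now_pre, P.mor_kd, P.mor_hill);
      MOR += dt * (mor_inf - MOR) / P.tau_mor;
      double km = P.k_minus_max / (1.0 + std::exp(-Vi_old / P.k_minus_slope));
      double kp = P.k_plus_coef * MOR;
      CaCh += dt * (km * (1.0 - CaCh) - kp * CaCh);
      if (CaCh > 1.0) CaCh = 1.0;
      if (CaCh < 0.0) CaCh = 0.0;
      double g_inf = 1.0 /
          (1.0 + std::exp(-(Vi_old - 100.0 * (1.0 - CaCh)) / 5.0));
      gg += dt * (g_inf - gg) / P.tau_g;
    }

    if (presyn_only) continue;

    // ---------------- 3. presynaptic calcium ----------------
    double ci_old = cFast + cSlow;
    {
      double m_inf = 1.0 / (1.0 + std::exp((P.v_mca - Vp_old) / P.k_mca));
      double iCa = P.rho_ca * P.a_btn * mCa * mCa * P.g_ca_single *
                   (Vp_old - vCa) * 1e-3;  // pS*mV = fA -> pA
      double j_pmca = P.nu_pmca * ci_old * ci_old /
                      (ci_old * ci_old + P.k_pmca * P.k_pmca);
      double j_leak = P.nu_leak * (P.c_ext - ci_old);
      mCa += dt * (m_inf - mCa) / P.tau_mca;
      cFast += dt * (-iCa * P.ca_conv_btn + j_leak - j_pmca);
      if (cFast < 0.0) cFast = 0.0;

      // The store subsystem is gated by the bulk (non-microdomain) calcium
      // c_rest + c_slow: the ER and its IP3Rs do not see the brief AP
      // microdomain transient that drives the release sensor.
      double cb = P.c_rest + cSlow;
      if (cb < 0.0) cb = 0.0;
      double m_ip3 = hill(pPre, P.d1);
      double n_ip3 = hill(cb, P.d5);
      double j_chan = P.c1 * P.nu1 * std::pow(m_ip3, 3) * std::pow(n_ip3, 3) *
                      std::pow(qPre, 3) * (cb - cER);
      double j_erpump = P.nu3 * cb * cb / (P.k3 * P.k3 + cb * cb);
      double j_erleak = P.c1 * P.nu2 * (cb - cER);
      double dslow = -j_chan - j_erpump - j_erleak;
      cSlow += dt * dslow;
      cER += dt * (-dslow / P.c1);
      double aq = P.a2 * P.d2 * (pPre + P.d1) / (pPre + P.d3);
      double bq = P.a2 * cb;
      qPre += dt * (aq * (1.0 - qPre) - bq * qPre);
      double drive = (ga > 0.0)
          ? P.nu_g * std::pow(ga, 0.7) /
                (std::pow(P.k_g, 0.7) + std::pow(ga, 0.7))
          : 0.0;
      pPre += dt * (drive - P.tau_p * (pPre - P.p0));
    }
    double ci = cFast + cSlow;
    if (ci < 0.0) ci = 0.0;

    // ---------------- 4. release machinery ----------------
    {
      double alpha_eff = P.alpha_s * (1.0 + (no_feedback ? 0.0 : boost));
      int n_ready = 0;
      for (int vix = 0; vix < 2; ++vix) {
        sensor[vix] = ladder_advance(sensor[vix], ci, alpha_eff, P.beta_s,
                                     P.gamma_s, P.delta_s, dt, rng_sensor);
        if (sensor[vix] == 6) ++n_ready;
      }
      double fr = 0.0;
      bool evoked = false, spont = false;
      if (n_ready > 0) {
        if (t >= refr_until) {
          fr = 0.5 * n_ready;
          evoked = true;
        }
        // calcium unbinds on (attempted) fusion: reset ready sensors
        for (int vix = 0; vix < 2; ++vix)
          if (sensor[vix] == 6) sensor[vix] = 0;
      } else if (Vp_old < P.v_spont_gate && t >= refr_until) {
        double c_sp = P.c_md0 + cSlow + P.c_rest;
        if (c_sp < 0.0) c_sp = 0.0;
        double lambda = P.sp_a3 /
            (1.0 + std::exp((P.sp_a1 - c_sp) / P.sp_a2));
        if (rng_spont.unif() < lambda * dt) {
          fr = 0.5;
          spont = true;
        }
      }
      if (fr > 0.0) {
        double moved = fr * Rv;
        Rv -= moved; Ev += moved;
        refr_until = t + P.t_refr;
        if (evoked) ++n_evoked;
        if (spont) ++n_spont;
      }
      double Iv = 1.0 - Rv - Ev;
      Rv += dt * (Iv / P.tau_rec);
      Ev += dt * (-Ev / P.tau_inac);

      // ---------------- 5. cleft glutamate ----------------
      glut += dt * (P.n_vd * P.g_vc * Ev - g_c_eff * glut);
      if (glut < 0.0) glut = 0.0;
    }

    // ---------------- 6/7. astrocyte + gliotransmitter ----------------
    {
      double cER_a = (P.c_tot_a - ca) / P.c1a;
      double m_inf_a = hill(pa, P.d1a);
      double n_inf_a = hill(ca, P.d5a);
      double j_chan = P.c1a * P.r_ca * std::pow(m_inf_a, 3) *
                      std::pow(n_inf_a, 3) * std::pow(ha, 3) * (ca - cER_a);
      double j_pump = P.v_er * ca * ca / (ca * ca + P.K_er * P.K_er);
      double j_leak = P.c1a * P.r_l * (ca - cER_a);
      double ca_new = ca + dt * (-j_chan - j_pump - j_leak);

      double K_eff = P.K_R * (1.0 + (P.K_p / P.K_R) * hill(ca, P.K_pi));
      double agonist = (mglur_on && glut > 0.0)
          ? P.nu_beta * hill_n(glut, K_eff, 0.7) : 0.0;
      double plcd = P.nu_delta / (1.0 + pa / P.k_delta) *
                    hill_n(ca, P.K_plcd, 2.0);
      double degr = P.nu_3k * hill_n(ca, P.K_D, 4.0) * hill(pa, P.K_3) +
                    P.r_5 * pa;
      double pa_new = pa + dt * (agonist + plcd - degr);

      double a_ha = P.a2a * P.d2a * (pa + P.d1a) / (pa + P.d3a);
      double b_ha = P.a2a * ca;
      ha += dt * (a_ha * (1.0 - ha) - b_ha * ha);

      O1 += dt * (P.k1p * ca - (P.k1p * ca + P.k1m) * O1);
      O2 += dt * (P.k2p * ca - (P.k2p * ca + P.k2m) * O2);
      O3 += dt * (P.k3p * ca - (P.k3p * ca + P.k3m) * O3);
      double pr_a = O1 * O2 * O3;

      double theta_rel = (ca > P.c_thresh) ? 1.0 : 0.0;  // Theta(0) = 0
      double rel = theta_rel * pr_a * Ra;
      double Ia = 1.0 - Ra - Ea;
      if (glio_on) {
        Ra += dt * (Ia / P.tau_rec_a - rel);
        Ea += dt * (-Ea / P.tau_inact_a + rel);
        ga += dt * (P.nva * P.gva * P.kappa_a * Ea - P.gca_clear * ga);
        if (ga < 0.0) ga = 0.0;
      } else {
        Ra += dt * (Ia / P.tau_rec_a);
        Ea = 0.0; ga = 0.0;
      }
      ca = ca_new; pa = pa_new;
      if (ca < 0.0) ca = 0.0;
      if (pa < 0.0) pa = 0.0;
    }

    // ---------------- 8. spine voltage, receptors, calcium ----------------
    {
      double Vq = Vpost;
      gmap_cur = g_ampa_map(ph_cur, P);
      i_ampa_cur = P.s_ampa * gmap_cur * mA * (Vq - P.v_ampa);
      mg_cur = mg_unblock(morph_now_post, Vq, P);
      double g_nmda = P.g_vi +
          P.g_nmda_inc * morph_hill(morph_now_post, P.mor_kd, P.mor_hill) +
          gVD;
      i_nmda_cur = g_nmda * mN * mg_cur * (Vq - P.v_nmda);
      double i_syn = -(i_ampa_cur + i_nmda_cur);
      Vpost += dt * (-(Vq - P.v_rest_post) + P.r_m * i_syn) / P.tau_post;

      mA += dt * (P.alpha_ampa * (P.a1_ampa * glut + P.a2_ampa * ga) *
                      (1.0 - mA) - P.beta_ampa * mA);
      mN += dt * (P.alpha_nmda * (P.k1_nmda * glut + P.k2_nmda * ga) *
                      (1.0 - mN) - P.beta_nmda * mN);
      double gvd_inf = P.k_gvd * (Vq - P.v0_gvd);
      if (gvd_inf < 0.0) gvd_inf = 0.0;
      gVD += dt * (gvd_inf - gVD) / P.tau_gvd;

      int B = 0;
      int N = static_cast<int>(P.n_chan);
      for (int j = 0; j < N; ++j)
        if (rng_chan.unif() < P.p_open) ++B;
      double i_l = P.g_l_ca * B * (Vq - P.v_l_ca);
      double theta = P.b_t * P.k_endo /
                     ((P.k_endo + cpost) * (P.k_endo + cpost));
      double influx = -(P.eta * i_ampa_cur + P.gamma_n * i_nmda_cur + i_l) *
                      P.ca_conv_spine;
      double spump = P.k_s * (cpost - P.c_post_rest);
      cpost += dt * (influx - spump) / (1.0 + theta);
      if (cpost < 0.0) cpost = 0.0;
    }

    // ---------------- 9. CaMKII / PP1 / plasticity ----------------
    {
      double cr = cpost / P.K_H1;
      double cr4 = cr * cr * cr * cr;
      double v1 = 10.0 * P.k1_cam * cr4 * cr4 * Pk[0] /
                  ((1.0 + cr4) * (1.0 + cr4));
      double v2 = P.k1_cam * cr4 / (1.0 + cr4);
      double sum_iP = 0.0;
      for (int i = 1; i <= 10; ++i) sum_iP += i * Pk[i];
      double v3 = P.k2_cam * ep / (P.K_M + sum_iP);

      double dP[11];
      dP[0] = -v1 + v3 * Pk[1];
      dP[1] = v1 - v3 * Pk[1] - v2 * Pk[1] + 2.0 * v3 * Pk[2];
      for (int i = 2; i <= 9; ++i) {
        dP[i] = CK_COEF[i - 2] * v2 * Pk[i - 1] - i * v3 * Pk[i]
                - CK_COEF[i - 1] * v2 * Pk[i] + (i + 1) * v3 * Pk[i + 1];
      }
      dP[10] = CK_COEF[8] * v2 * Pk[9] - 10.0 * v3 * Pk[10];
      for (int i = 0; i <= 10; ++i) {
        Pk[i] += dt * dP[i];
        if (Pk[i] < 0.0) Pk[i] = 0.0;
      }
      double hr = cpost / P.K_H2;
      double hill3 = hr * hr * hr / (1.0 + hr * hr * hr);
      double bind = -P.k3_cam * I1p * ep + P.k4_cam * (P.ep0 - ep);
      ep += dt * bind;
      I1p += dt * (bind + P.nu_pka * P.i0 - P.nu_can * hill3 * I1p);
      if (ep < 0.0) ep = 0.0;
      if (ep > P.ep0) ep = P.ep0;
      if (I1p < 0.0) I1p = 0.0;

      ph_cur = 0.0;
      for (int i = 1; i <= 10; ++i) ph_cur += Pk[i];

      // ---------------- 10. NO boost for next step ----------------
      boost = P.k_syt / (1.0 + std::exp(-(ph_cur - P.p_half) * P.k_half));
    }
  }

  CharacterVector cn = CharacterVector::create(
      "t_ms", "v_pre_mV", "v_int_mV", "g_gaba", "i_gabaa_uA_cm2", "mor",
      "cach", "m_ca", "c_fast_uM", "c_slow_uM", "ip3_pre_uM", "glut_uM", "R",
      "E", "release_events", "c_astro_uM", "ip3_astro_uM", "h_a", "pr_a",
      "Ra", "Ea", "glio_uM", "v_post_mV", "i_ampa_pA", "i_nmda_pA",
      "mg_unblock", "c_post_uM", "ph_camkii_uM", "g_ampa");
  colnames(trace) = cn;

  return List::create(
      _["trace"] = trace,
      _["ipsc_peak_late"] = ipsc_peak_late,
      _["g_peak_late"] = g_peak_late,
      _["cach_late_mean"] = cach_late_n > 0 ? cach_late_sum / cach_late_n : NA_REAL,
      _["mean_glut"] = n_stat > 0 ? sum_glut / n_stat : NA_REAL,
      _["mean_glio"] = n_stat > 0 ? sum_glio / n_stat : NA_REAL,
      _["mean_ph_camkii"] = n_stat > 0 ? sum_ph / n_stat : NA_REAL,
      _["mean_g_ampa"] = n_stat > 0 ? sum_gampa / n_stat : NA_REAL,
      _["n_evoked"] = static_cast<double>(n_evoked),
      _["n_spont"] = static_cast<double>(n_spont),
      _["spikes_pre"] = static_cast<double>(spikes_pre),
      _["spikes_int"] = static_cast<double>(spikes_int));
}
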