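// Fixed-step RK4 integrator for the six-leg neuromechanical walking model.
//
// Continuous state layout (684 doubles):
//   [0, 648)   : 216 neurons x (V, m, q)
//                neuron id = leg*36 + network*12 + k
//                leg     0..5  = L1, L2, L3, R1, R2, R3
//                network 0..2  = PR (protractor-retractor),
//                                LD (levator-depressor),
//                                EF (extensor-flexor)
//                k       0..11 = C_a, C_b (CPG half-center),
//                                MNf_a, MNf_b, MNs_a, MNs_b (motoneurons),
//                                INpm_fa, INpm_fb, INpm_sa, INpm_sb (premotor),
//                                IN5, IN6 (sensory relay)
//   [648, 684) : 18 joints x (angle, omega); joint j of leg l at
//                648 + (l*3 + j)*2, j = 0 alpha, 1 beta, 2 gamma
//
// The "a" side of each antagonistic pair is protractor / levator / extensor.
// Discrete state (gates, gait tables, behavioural modes) is held outside the
// ODE state and updated once per integration step; gate switch times are
// logged with linear interpolation of the triggering crossing.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double sig(double v, double th, double k) {
  return 1.0 / (1.0 + std::exp(-(v - th) / k));
}

struct Pars {
  // neuron globals
  double C, gL, EL, gP, EP, EK, Eex, Einh, thm, km, taum, thq, kq, ths, ks;
  double gq_cpg[3], tauq_cpg[3], gc;
  double gMN, gq_fast, gq_slow, tauq_mn, g_pm, c_slow, g_ci, g_rel;
  // sensory gates
  double beta_crit, beta_hyst, gamma_crit, gamma_hyst;
  double g_low[3], g_high[3], w6[3];
  // muscle / joint
  double Gf, Gs, Tsc, kr, bdamp;
  double bias[3], lo[3], hi[3];
  // CPG drive tables [gait 0=tetrapod 1=tripod][network][a/b]
  double gapp[2][3][2], search_ef[2];
  // interleg (ipsilateral) pathway
  double g_inh3, g_inh9, il_rise, il_fall, il_tonic, beta_lift;
  double lev_boost[3], seg_tau[3];
  // contralateral
  double g_l2r3, th_lift, k_lift, g_pair;
  int c_l2r3, c_front, c_hind, c_mutual, c_l2r2, c_l3r3;
  // behaviour control
  double beta_min, eps_tet, beta_back, stop_tol;
  double stop_pr_front, stop_pr_other, stop_ld, stop_ef_frontmid, stop_ef_hind;
  double pm_override;
  int slow_on;
};

struct Disc {
  int pr_gate[6], ld_gate[6], ef_gate[6]; // 0 low, 1 high
  int gait[2];                            // per side: 0 tetrapod, 1 tripod
  int backward, still;
  int search[6];
  double search_drive[6];
  // pending-command state
  int pending_tri, tri_done[2], tri_seg, pair_active;
  int pending_tet[2], pending_stop, pending_back;
};

// EF cross connection (CPG -> premotor routing exchanged): hind legs during
// forward walking; front legs take it over (and hind legs lose it) when
// walking backward. Middle legs never cross.
static inline int ef_crossed(const Disc &D, int leg) {
  int seg = leg % 3;
  if (seg == 1) return 0;
  int base = (seg == 2);
  return D.backward ? !base : base;
}
static inline int pr_swapped(const Disc &D) { return D.backward; }

// gate conductance seen by the CPG of (leg, network), honouring the static
// still-stand settings and the search override of the front-leg EF gate
static inline double gate_g(const Pars &P, const Disc &D, int leg, int n) {
  int seg = leg % 3;
  if (D.still) {
    if (n == 0) return (seg == 0) ? P.stop_pr_front : P.stop_pr_other;
    if (n == 1) return P.stop_ld;
    return (seg == 2) ? P.stop_ef_hind : P.stop_ef_frontmid;
  }
  if (n == 2 && D.search[leg]) return P.g_low[2];
  int st = (n == 0) ? D.pr_gate[leg] : (n == 1) ? D.ld_gate[leg] : D.ef_gate[leg];
  return st ? P.g_high[n] : P.g_low[n];
}

// ipsilateral coordination signal: inhibition level produced by the posterior
// leg's vertical position and movement direction (quadrant rule)
static inline double il_level(const Pars &P, double beta, double omega) {
  if (beta >= P.beta_lift) return (omega > 0) ? P.il_rise : P.il_fall;
  return P.il_tonic;
}

struct Model {
  Pars P;
  Disc D;
  std::vector<double> sarr; // presynaptic transfer per neuron
  Model() : sarr(216) {}

  void rhs(const double *Y, double *DY) {
    const Pars &P = this->P;
    const Disc &D = this->D;
    // presynaptic transfer of every neuron
    for (int i = 0; i < 216; ++i) sarr[i] = sig(Y[3 * i], P.ths, P.ks);

    for (int l = 0; l < 6; ++l) {
      int side = l / 3, seg = l % 3;
      for (int n = 0; n < 3; ++n) {
        int nb = l * 36 + n * 12; // first neuron id of this local network
        double gg = gate_g(P, D, l, n);
        // CPG drives
        double ga_a, ga_b;
        if (n == 2 && D.search[l]) {
          ga_a = P.search_ef[0] * D.search_drive[l];
          ga_b = P.search_ef[1] * D.search_drive[l];
        } else {
          ga_a = P.gapp[D.gait[side]][n][0];
          ga_b = P.gapp[D.gait[side]][n][1];
          // levator drive graded by segment: the hind leg leads its side and
          // the more anterior legs run slightly fast, so the interleg
          // inhibition release sets their liftoff times (stable entrainment)
          if (n == 1) ga_a *= P.lev_boost[seg];
        }

        // --- CPG half-center (k = 0, 1) ---
        for (int k = 0; k < 2; ++k) {
          int id = nb + k;
          const double V = Y[3 * id], m = Y[3 * id + 1], q = Y[3 * id + 2];
          double other = sarr[nb + (1 - k)];
          double I = -P.gL * (V - P.EL) - P.gP * m * (V - P.EP)
                     - P.gq_cpg[n] * q * (V - P.EK)
                     - P.gc * other * (V - P.Einh)
                     + (k == 0 ? ga_a : ga_b) * (P.Eex - V);
          if (k == 0) { // relay IN6 inhibits the a neuron
            I -= gg * P.w6[n] * sarr[nb + 11] * (V - P.Einh);
          } else {      // relay IN5 excites the b neuron
            I += gg * sarr[nb + 10] * (P.Eex - V);
          }
          if (n == 1 && k == 0) {
            // levator CPG neuron: interleg + contralateral targets
            if (seg < 2) {
              // inhibition timed by the next posterior leg on the same side
              int post = l + 1;
              double pb = Y[648 + (post * 3 + 1) * 2];
              double pw = Y[648 + (post * 3 + 1) * 2 + 1];
              double gmax = (seg == 0) ? P.g_inh3 : P.g_inh9;
              I -= gmax * il_level(P, pb, pw) * (V - P.Einh);
            }
            if (P.c_l2r3 && l == 5) { // L2 lifted excites R3 levator
              double bl2 = Y[648 + (1 * 3 + 1) * 2];
              I += P.g_l2r3 * sig(bl2, P.th_lift, P.k_lift) * (P.Eex - V);
            }
            if (P.c_l2r2 && l == 4) { // experimental variant: L2 -| R2
              double bl2 = Y[648 + (1 * 3 + 1) * 2];
              I -= P.g_l2r3 * sig(bl2, P.th_lift, P.k_lift) * (V - P.Einh);
            }
            if (P.c_l3r3 && l == 5) { // experimental variant: L3 -| R3
              double bl3 = Y[648 + (2 * 3 + 1) * 2];
              I -= P.g_l2r3 * sig(bl3, P.th_lift, P.k_lift) * (V - P.Einh);
            }
            if (D.pair_active >= 0 && seg == D.pair_active) {
              // active same-segment pair pathway: excitation from the
              // contralateral partner's lifted state
              int partner = (1 - side) * 3 + seg;
              double bp = Y[648 + (partner * 3 + 1) * 2];
              I += P.g_pair * sig(bp, P.th_lift, P.k_lift) * (P.Eex - V);
            }
          }
          DY[3 * id] = I / P.C;
          DY[3 * id + 1] = (sig(V, P.thm, P.km) - m) / P.taum;
          // the LD rhythm of the more anterior segments runs slightly fast,
          // so the interleg release pins their liftoff times stably
          double tq = P.tauq_cpg[n] * (n == 1 ? P.seg_tau[seg] : 1.0);
          DY[3 * id + 2] = (sig(V, P.thq, P.kq) - q) / tq;
        }

        // --- motoneurons (k = 2..5); premotor IN of MN k is k + 4 ---
        for (int k = 2; k < 6; ++k) {
          int id = nb + k;
          const double V = Y[3 * id], q = Y[3 * id + 2];
          int slow = (k >= 4);
          double gq = slow ? P.gq_slow : P.gq_fast;
          double Cm = slow ? P.C * P.c_slow : P.C;
          double I = -P.gL * (V - P.EL) - gq * q * (V - P.EK)
                     + P.gMN * (P.Eex - V)
                     - P.g_pm * sarr[nb + k + 4] * (V - P.Einh);
          DY[3 * id] = I / Cm;
          DY[3 * id + 1] = (sig(V, P.thm, P.km) - Y[3 * id + 1]) / P.taum;
          DY[3 * id + 2] = (sig(V, P.thq, P.kq) - q) / P.tauq_mn;
        }

        // --- premotor INs (k = 6..9) ---
        int swapped = (n == 0) ? pr_swapped(D) : (n == 2) ? ef_crossed(D, l) : 0;
        int srch = D.search[l] && n < 2; // search overrides PR and LD INs
        for (int k = 6; k < 10; ++k) {
          int id = nb + k;
          const double V = Y[3 * id];
          int aside = ((k - 6) % 2 == 0); // IN of an a-side MN
          // normal routing: IN of MN_x driven by the antagonist CPG neuron
          int src = nb + (swapped ? (aside ? 0 : 1) : (aside ? 1 : 0));
          double I = -P.gL * (V - P.EL) + P.g_ci * sarr[src] * (P.Eex - V);
          if (srch) {
            if (aside) // disinhibit protractor / levator MNs
              I -= P.pm_override * (V - P.Einh);
            else       // inhibit retractor / depressor MNs
              I += P.pm_override * (P.Eex - V);
          }
          DY[3 * id] = I / P.C;
          DY[3 * id + 1] = (sig(V, P.thm, P.km) - Y[3 * id + 1]) / P.taum;
          DY[3 * id + 2] = (sig(V, P.thq, P.kq) - Y[3 * id + 2]) / 500.0;
        }

        // --- sensory relay INs (k = 10, 11): tonically active ---
        for (int k = 10; k < 12; ++k) {
          int id = nb + k;
          const double V = Y[3 * id];
          double I = -P.gL * (V - P.EL) + P.g_rel * (P.Eex - V);
          DY[3 * id] = I / P.C;
          DY[3 * id + 1] = (sig(V, P.thm, P.km) - Y[3 * id + 1]) / P.taum;
          DY[3 * id + 2] = (sig(V, P.thq, P.kq) - Y[3 * id + 2]) / 500.0;
        }

        // --- joint driven by this network (j = n) ---
        int jb = 648 + (l * 3 + n) * 2;
        double afa = sarr[nb + 2], afb = sarr[nb + 3];
        double asa = sarr[nb + 4], asb = sarr[nb + 5];
        double Gs = P.slow_on ? P.Gs : 0.0;
        double dir = (n == 1) ? 1.0 : -1.0; // levator raises beta; protractor
                                            // and extensor pull to the low end
        double x = (dir * (P.Gf * (afa - afb) + Gs * (asa - asb)) + P.bias[n]) / P.Tsc;
        double mid = 0.5 * (P.lo[n] + P.hi[n]);
        double half = 0.5 * (P.hi[n] - P.lo[n]);
        double teq = mid + half * std::tanh(x);
        double th = Y[jb], w = Y[jb + 1];
        DY[jb] = w;
        DY[jb + 1] = P.kr * (teq - th) - P.bdamp * w;
      }
    }
  }
};

// ------------------------------------------------------------------

static void fill_pars(Pars &P, List p) {
  P.C = p["C"]; P.gL = p["gL"]; P.EL = p["EL"]; P.gP = p["gP"]; P.EP = p["EP"];
  P.EK = p["EK"]; P.Eex = p["Eex"]; P.Einh = p["Einh"];
  P.thm = p["thm"]; P.km = p["km"]; P.taum = p["taum"];
  P.thq = p["thq"]; P.kq = p["kq"]; P.ths = p["ths"]; P.ks = p["ks"];
  NumericVector gq = p["gq_cpg"], tq = p["tauq_cpg"];
  for (int i = 0; i < 3; ++i) { P.gq_cpg[i] = gq[i]; P.tauq_cpg[i] = tq[i]; }
  P.gc = p["gc"];
  P.gMN = p["gMN"]; P.gq_fast = p["gq_fast"]; P.gq_slow = p["gq_slow"];
  P.tauq_mn = p["tauq_mn"]; P.g_pm = p["g_pm"]; P.c_slow = p["c_slow"];
  P.g_ci = p["g_ci"]; P.g_rel = p["g_rel"];
  P.beta_crit = p["beta_crit"]; P.beta_hyst = p["beta_hyst"];
  P.gamma_crit = p["gamma_crit"]; P.gamma_hyst = p["gamma_hyst"];
  NumericVector gl = p["g_low"], gh = p["g_high"], w6 = p["w6"];
  for (int i = 0; i < 3; ++i) { P.g_low[i] = gl[i]; P.g_high[i] = gh[i]; P.w6[i] = w6[i]; }
  P.Gf = p["Gf"]; P.Gs = p["Gs"]; P.Tsc = p["Tsc"]; P.kr = p["kr"]; P.bdamp = p["bdamp"];
  NumericVector bias = p["bias"], lo = p["lo"], hi = p["hi"];
  for (int i = 0; i < 3; ++i) { P.bias[i] = bias[i]; P.lo[i] = lo[i]; P.hi[i] = hi[i]; }
  NumericVector tet = p["gapp_tet"], tri = p["gapp_tri"], sef = p["search_ef"];
  for (int n = 0; n < 3; ++n) for (int k = 0; k < 2; ++k) {
    P.gapp[0][n][k] = tet[n * 2 + k];
    P.gapp[1][n][k] = tri[n * 2 + k];
  }
  P.search_ef[0] = sef[0]; P.search_ef[1] = sef[1];
  P.g_inh3 = p["g_inh3"]; P.g_inh9 = p["g_inh9"];
  P.il_rise = p["il_rise"]; P.il_fall = p["il_fall"]; P.il_tonic = p["il_tonic"];
  P.beta_lift = p["beta_lift"];
  NumericVector lb = p["lev_boost"], st = p["seg_tau"];
  for (int i = 0; i < 3; ++i) { P.lev_boost[i] = lb[i]; P.seg_tau[i] = st[i]; }
  P.g_l2r3 = p["g_l2r3"]; P.th_lift = p["th_lift"]; P.k_lift = p["k_lift"];
  P.g_pair = p["g_pair"];
  P.c_l2r3 = p["c_l2r3"]; P.c_front = p["c_front"]; P.c_hind = p["c_hind"];
  P.c_mutual = p["c_mutual"]; P.c_l2r2 = p["c_l2r2"]; P.c_l3r3 = p["c_l3r3"];
  P.beta_min = p["beta_min"]; P.eps_tet = p["eps_tet"]; P.beta_back = p["beta_back"];
  P.stop_tol = p["stop_tol"];
  P.stop_pr_front = p["stop_pr_front"]; P.stop_pr_other = p["stop_pr_other"];
  P.stop_ld = p["stop_ld"]; P.stop_ef_frontmid = p["stop_ef_frontmid"];
  P.stop_ef_hind = p["stop_ef_hind"];
  P.pm_override = p["pm_override"];
  P.slow_on = p["slow_on"];
}

static IntegerVector disc_pack(const Disc &D) {
  IntegerVector v(36);
  for (int l = 0; l < 6; ++l) {
    v[l] = D.pr_gate[l]; v[6 + l] = D.ld_gate[l]; v[12 + l] = D.ef_gate[l];
    v[20 + l] = D.search[l];
  }
  v[18] = D.gait[0]; v[19] = D.gait[1];
  v[26] = D.backward; v[27] = D.still;
  v[28] = D.pending_tri; v[29] = D.tri_done[0]; v[30] = D.tri_done[1];
  v[31] = D.tri_seg; v[32] = D.pair_active;
  v[33] = D.pending_tet[0] + 2 * D.pending_tet[1];
  v[34] = D.pending_stop; v[35] = D.pending_back;
  return v;
}

static void disc_unpack(Disc &D, IntegerVector v) {
  for (int l = 0; l < 6; ++l) {
    D.pr_gate[l] = v[l]; D.ld_gate[l] = v[6 + l]; D.ef_gate[l] = v[12 + l];
    D.search[l] = v[20 + l];
  }
  D.gait[0] = v[18]; D.gait[1] = v[19];
  D.backward = v[26]; D.still = v[27];
  D.pending_tri = v[28]; D.tri_done[0] = v[29]; D.tri_done[1] = v[30];
  D.tri_seg = v[31]; D.pair_active = v[32];
  D.pending_tet[0] = v[33] & 1; D.pending_tet[1] = (v[33] >> 1) & 1;
  D.pending_stop = v[34]; D.pending_back = v[35];
}

// event codes
enum {
  EV_GATE_PR = 1, EV_GATE_LD = 2, EV_GATE_EF = 3,
  EV_GAIT = 10, EV_TRI_INIT = 11, EV_TET_INIT = 12,
  EV_STOP = 20, EV_RESTART = 21, EV_SEARCH_ON = 22, EV_SEARCH_OFF = 23,
  EV_BACKWARD = 24, EV_FORWARD = 25, EV_REJECT = 26,
  EV_FAIL = 30
};

struct EvLog {
  std::vector<double> t; std::vector<int> code, a, b;
  void push(double tt, int c, int aa, int bb) {
    if (t.size() < 200000) { t.push_back(tt); code.push_back(c); a.push_back(aa); b.push_back(bb); }
  }
};

// reset gates to values consistent with the current joint angles
static void gates_from_angles(const Pars &P, Disc &D, const double *Y) {
  for (int l = 0; l < 6; ++l) {
    double beta = Y[648 + (l * 3 + 1) * 2];
    double gam  = Y[648 + (l * 3 + 2) * 2];
    int stance = beta < P.beta_crit;
    D.pr_gate[l] = stance; D.ef_gate[l] = stance;
    D.ld_gate[l] = ef_crossed(D, l) ? (gam < P.gamma_crit) : (gam > P.gamma_crit);
  }
}

// [[Rcpp::export]]
List sw_core_run(List pars, NumericMatrix schedule, double t0, double t_end,
                 double dt, double out_dt, NumericVector y0, IntegerVector disc0,
                 NumericVector search_drive0, IntegerVector rec_neurons) {
  Model M;
  fill_pars(M.P, pars);
  const Pars &P = M.P;
  Disc &D = M.D;
  disc_unpack(D, disc0);
  for (int l = 0; l < 6; ++l) D.search_drive[l] = search_drive0[l];

  std::vector<double> y(y0.begin(), y0.end());
  if (y.size() != 684) stop("state vector must have 684 elements");

  int nout = (t_end > t0) ? (int)std::floor((t_end - t0) / out_dt) + 1 : 0;
  NumericVector times(nout);
  NumericMatrix ang(nout, 18);
  int nrec = rec_neurons.size();
  NumericMatrix vrec(nrec > 0 ? nout : 0, nrec);
  EvLog ev;

  std::vector<double> k1(684), k2(684), k3(684), k4(684), yt(684), ypre(684);

  int status = 0;
  double tfail = NA_REAL;
  int cmd_i = 0, ncmd = schedule.nrow();
  int iout = 0;
  long nstep = (long)std::ceil((t_end - t0) / dt - 1e-9);

  auto record = [&](double t) {
    if (iout >= nout) return;
    times[iout] = t;
    for (int j = 0; j < 18; ++j) ang(iout, j) = y[648 + 2 * j];
    for (int r = 0; r < nrec; ++r) vrec(iout, r) = y[3 * rec_neurons[r]];
    ++iout;
  };
  record(t0);

  for (long istep = 0; istep < nstep; ++istep) {
    double t = t0 + istep * dt;

    // ---- behaviour controller -------------------------------------
    while (cmd_i < ncmd && schedule(cmd_i, 0) <= t + 1e-9) {
      int kind = (int)schedule(cmd_i, 1);
      int a = (int)schedule(cmd_i, 2), b = (int)schedule(cmd_i, 3);
      double c = schedule(cmd_i, 4);
      switch (kind) {
      case 1: // set_gait: a = 0 tetrapod, 1 tripod
        if (a == 1) {
          D.pending_tri = 1; D.tri_done[0] = D.gait[0] == 1; D.tri_done[1] = D.gait[1] == 1;
          D.tri_seg = -1;
        } else {
          for (int s = 0; s < 2; ++s) D.pending_tet[s] = (D.gait[s] == 1);
        }
        break;
      case 2: D.pending_stop = 1; break;
      case 3: // restart
        if (D.still) {
          D.still = 0;
          D.gait[0] = D.gait[1] = 0;
          gates_from_angles(P, D, y.data());
          ev.push(t, EV_RESTART, 0, 0);
        } else ev.push(t, EV_REJECT, kind, 0);
        break;
      case 4: // search: a = leg (0 or 3), b = on/off, c = drive scale
        if (a == 0 || a == 3) {
          if (b) {
            D.search[a] = 1; D.search_drive[a] = (c > 0) ? c : 1.0;
            ev.push(t, EV_SEARCH_ON, a, 0);
          } else if (D.search[a]) {
            D.search[a] = 0;
            // EF gate resumes consistently with the held (lifted) position
            D.ef_gate[a] = 0;
            ev.push(t, EV_SEARCH_OFF, a, 0);
          }
        } else ev.push(t, EV_REJECT, kind, a);
        break;
      case 5: // direction: a = 1 backward, 0 forward
        if (a == 1) {
          if (D.still) ev.push(t, EV_REJECT, kind, 1);
          else D.pending_back = 1;
        } else {
          if (D.backward) {
            D.backward = 0;
            gates_from_angles(P, D, y.data());
            ev.push(t, EV_FORWARD, 0, 0);
          }
        }
        break;
      }
      ++cmd_i;
    }

    // pending transitions evaluated on the current state
    if (D.pending_tri) {
      for (int s = 0; s < 2; ++s) {
        if (D.tri_done[s]) continue;
        for (int segc = 0; segc < 3; segc += 2) { // front or hind leg only
          if (D.tri_seg >= 0 && segc != D.tri_seg) {
            // same-segment rule enforced by the pair pathways
            int gated = (segc == 0 || D.tri_seg == 0) ? (P.c_front && P.c_mutual)
                                                      : (P.c_hind && P.c_mutual);
            if (gated) continue;
          }
          int l = s * 3 + segc;
          double beta = y[648 + (l * 3 + 1) * 2], w = y[648 + (l * 3 + 1) * 2 + 1];
          if (beta > P.beta_min && w > 0) {
            D.gait[s] = 1; D.tri_done[s] = 1;
            if (D.tri_seg < 0) D.tri_seg = segc;
            if ((segc == 0 && P.c_front) || (segc == 2 && P.c_hind))
              D.pair_active = D.tri_seg;
            ev.push(t, EV_TRI_INIT, l, segc);
            ev.push(t, EV_GAIT, s, 1);
            break;
          }
        }
      }
      if (D.tri_done[0] && D.tri_done[1]) { D.pending_tri = 0; D.pair_active = -1; }
    }
    for (int s = 0; s < 2; ++s) {
      if (D.pending_tet[s] && D.gait[s] == 1) {
        double wm = y[648 + ((s * 3 + 1) * 3 + 1) * 2 + 1];
        double wh = y[648 + ((s * 3 + 2) * 3 + 1) * 2 + 1];
        if (wm < P.eps_tet && wh < P.eps_tet) {
          D.gait[s] = 0; D.pending_tet[s] = 0;
          ev.push(t, EV_TET_INIT, s, 0);
          ev.push(t, EV_GAIT, s, 0);
        }
      }
    }
    if (D.pending_stop && !D.backward && !D.still) {
      bool ok = true;
      // zero velocity up to the slow-muscle stance ripple
      for (int l = 3; l < 6; ++l)
        if (y[648 + (l * 3 + 1) * 2 + 1] < -P.stop_tol) { ok = false; break; }
      if (ok) {
        D.still = 1; D.pending_stop = 0;
        ev.push(t, EV_STOP, 0, 0);
      }
    }
    if (D.pending_back && !D.still) {
      double b2 = y[648 + (1 * 3 + 1) * 2], b5 = y[648 + (4 * 3 + 1) * 2];
      if (b2 >= P.beta_back || b5 >= P.beta_back) {
        D.backward = 1; D.pending_back = 0;
        gates_from_angles(P, D, y.data());
        ev.push(t, EV_BACKWARD, 0, 0);
      }
    }

    // ---- integrate one RK4 step ------------------------------------
    for (int i = 0; i < 684; ++i) ypre[i] = y[i];
    M.rhs(y.data(), k1.data());
    for (int i = 0; i < 684; ++i) yt[i] = y[i] + 0.5 * dt * k1[i];
    M.rhs(yt.data(), k2.data());
    for (int i = 0; i < 684; ++i) yt[i] = y[i] + 0.5 * dt * k2[i];
    M.rhs(yt.data(), k3.data());
    for (int i = 0; i < 684; ++i) yt[i] = y[i] + dt * k3[i];
    M.rhs(yt.data(), k4.data());
    for (int i = 0; i < 684; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2 * k2[i] + 2 * k3[i] + k4[i]);

    double tn = t + dt;
    bool finite = true;
    for (int i = 0; i < 684; i += 3)
      if (!std::isfinite(y[i])) { finite = false; break; }
    if (!finite) {
      status = 1; tfail = tn;
      ev.push(tn, EV_FAIL, 0, 0);
      break;
    }

    // ---- gate automata (direction-dependent threshold crossings) ----
    if (!D.still) {
      for (int l = 0; l < 6; ++l) {
        double b0v = ypre[648 + (l * 3 + 1) * 2], b1v = y[648 + (l * 3 + 1) * 2];
        double g0v = ypre[648 + (l * 3 + 2) * 2], g1v = y[648 + (l * 3 + 2) * 2];
        double bhi = P.beta_crit + P.beta_hyst;
        // PR and EF gates share the levation-angle trigger
        for (int gi = 0; gi < 2; ++gi) {
          if (gi == 1 && D.search[l]) continue; // EF gate frozen during search
          int *g = (gi == 0) ? &D.pr_gate[l] : &D.ef_gate[l];
          int code = (gi == 0) ? EV_GATE_PR : EV_GATE_EF;
          if (!*g && b0v > P.beta_crit && b1v <= P.beta_crit) {
            *g = 1;
            double tc = tn - dt * (P.beta_crit - b1v) / (b0v - b1v);
            ev.push(tc, code, l, 1);
          } else if (*g && b0v < bhi && b1v >= bhi) {
            *g = 0;
            double tc = tn - dt * (b1v - bhi) / (b1v - b0v);
            ev.push(tc, code, l, 0);
          }
        }
        // LD gate follows the tibia angle; polarity tracks the EF role
        int crossed = ef_crossed(D, l);
        double up = P.gamma_crit, dn = P.gamma_crit;
        if (crossed) { // stance = extended (low gamma)
          double rel = P.gamma_crit + P.gamma_hyst;
          if (!D.ld_gate[l] && g0v > up && g1v <= up) {
            D.ld_gate[l] = 1; ev.push(tn, EV_GATE_LD, l, 1);
          } else if (D.ld_gate[l] && g0v < rel && g1v >= rel) {
            D.ld_gate[l] = 0; ev.push(tn, EV_GATE_LD, l, 0);
          }
        } else {       // stance = flexed (high gamma)
          double rel = P.gamma_crit - P.gamma_hyst;
          if (!D.ld_gate[l] && g0v < dn && g1v >= dn) {
            D.ld_gate[l] = 1; ev.push(tn, EV_GATE_LD, l, 1);
          } else if (D.ld_gate[l] && g0v > rel && g1v <= rel) {
            D.ld_gate[l] = 0; ev.push(tn, EV_GATE_LD, l, 0);
          }
        }
      }
    }

    if (tn + 1e-9 >= t0 + iout * out_dt) record(t0 + iout * out_dt);
  }

  int nev = ev.t.size();
  NumericMatrix evm(nev, 4);
  for (int i = 0; i < nev; ++i) {
    evm(i, 0) = ev.t[i]; evm(i, 1) = ev.code[i]; evm(i, 2) = ev.a[i]; evm(i, 3) = ev.b[i];
  }
  if (iout < nout) {
    times = head(times, iout);
    ang = ang(Range(0, std::max(iout - 1, 0)), _);
    if (nrec > 0) vrec = vrec(Range(0, std::max(iout - 1, 0)), _);
  }
  NumericVector search_drive(6);
  for (int l = 0; l < 6; ++l) search_drive[l] = D.search_drive[l];
  return List::create(
    _["times"] = times, _["angles"] = ang, _["events"] = evm,
    _["state"] = NumericVector(y.begin(), y.end()),
    _["disc"] = disc_pack(D), _["search_drive"] = search_drive,
    _["voltages"] = vrec,
    _["status"] = status, _["tfail"] = tfail);
}
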