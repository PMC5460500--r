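// Quarterly-step life-history engine.
//
// One call simulates n independent individuals from birth to death or age
// 100 in 3-month increments and accumulates population tallies.  Each
// individual carries two private RNG substreams (natural history vs
// screening) so that a screening arm and its paired no-screening baseline
// share natural-history randomness until the first intervention actually
// changes the colon.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256** (deterministic across platforms)
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s[4];
  void seed(uint64_t v) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(v);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[1] * 5, 7) * 9;
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline double normal(double mu, double sd) {
    // Box-Muller, no caching (keeps draw counts predictable)
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return mu + sd * std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
  inline int categorical(const std::vector<double> &cum) {
    double u = unif();
    for (size_t i = 0; i < cum.size(); ++i) if (u < cum[i]) return (int)i;
    return (int)cum.size() - 1;
  }
};

// ---------------------------------------------------------------------------
// Model containers
// ---------------------------------------------------------------------------

struct Adenoma {
  int stage;        // 1..6
  int seg;          // 1..13 (1 = rectum ... 13 = cecum)
  double multE;     // per-lesion early progression multiplier
  double multA;     // per-lesion advanced progression multiplier
  int birth_q;
};

struct Cancer {
  int stage;        // 1..4
  int seg;
  int origin;       // 0 adenomatous, 1 fast, 2 direct
  int init_q;
  int sym_q;        // quarter symptoms start
  int adv_q[3];     // absolute quarters at which stage becomes 2,3,4 (INT_MAX if never)
};

struct NatParams {
  double a0, a1, a2, b0, b1, b2, c0, c1, c2;
  std::vector<double> indiv_q, indiv_m;         // individual-risk CDF anchors
  std::vector<double> lesE_q, lesE_m;           // per-adenoma early CDF
  std::vector<double> lesA_q, lesA_m;           // per-adenoma advanced CDF
  double sex_init, sex_early, sex_adv;          // male multipliers (female = 1)
  double rect_early, rect_adv;
  double stage_prog[6], stage_regr[6], stage_cancer[5];
  double direct_risk[13];
  double sojourn_mean_y, sojourn_sd_y;
  std::vector<double> loc_cum;                  // cumulative location distribution
  std::vector<double> direct_cum; double direct_tot;
  double symp_stage[4];                          // symptomatic stage distribution
  double stage_time_w[4];                        // preclinical per-stage time weights
  double surv5[4];                               // 5-y CRC survival by stage
  double male_fraction;
};

struct ScreenModel {
  double det_ad[6];       // colonoscopy detection by adenoma stage
  double det_ca;          // colonoscopy cancer detection
  double flex_pen;        // detection multiplier in flexure segments
  int flex1, flex2;       // flexure segment ids
  double reach_cecum;     // probability deepest segment = 13
  int inc_lo, inc_hi;     // incomplete exams: deepest uniform on [inc_lo, inc_hi]
  double compl_p[4];      // major bleed, minor bleed, burn, perforation
  double compl_poly_mult; // x2 after polypectomy
  double compl_death_p;   // case fatality given perforation
  double sig_compl_mult;  // sigmoidoscopy complication scaling
  std::vector<double> sig_reach_cum; int sig_reach_lo;
  double sig_pen_early, sig_pen_adv;
  double fobt_sens_early, fobt_sens_adv, fobt_sens_ca, fobt_spec;
  int surv_int_crc, surv_int_adv, surv_int_small; // quarters
  int surv_stop_q;        // no surveillance at/after this quarter
};

struct Plan {
  int modality;           // 0 none, 1 colonoscopy, 2 sigmoidoscopy, 3 FOBT
  std::vector<int> scr_q; // scheduled screening quarters
  double adherence, fu_adherence;
  bool surveillance_on;
  bool trial_mode;
  int trial_lo_q, trial_hi_q, trial_fu_q, trial_gap_q;
  double trial_second_frac;
  int perfect_q;          // remove-everything intervention quarter (0 = off)
};

struct Costs {
  double colono, polyp, sig, fobt;
  double compl_c[4];
  double treat_init[4], treat_cont[4], treat_term[4]; // by cancer stage; cont/term annual
};

static std::vector<double> cumvec(const NumericVector &p) {
  std::vector<double> c(p.size());
  double s = 0;
  for (int i = 0; i < p.size(); ++i) { s += p[i]; c[i] = s; }
  for (size_t i = 0; i < c.size(); ++i) c[i] /= s;
  return c;
}

static void fill_arr(double *dst, const NumericVector &v, int n) {
  if (v.size() != n) stop("parameter vector has wrong length");
  for (int i = 0; i < n; ++i) dst[i] = v[i];
}

// piecewise-linear CDF inverse through anchor points (quantile -> multiplier)
static double pwl(const std::vector<double> &q, const std::vector<double> &m, double u) {
  if (u <= q.front()) return m.front();
  if (u >= q.back())  return m.back();
  size_t i = 1;
  while (q[i] < u) ++i;
  double w = (u - q[i - 1]) / (q[i] - q[i - 1]);
  return m[i - 1] + w * (m[i] - m[i - 1]);
}

// ---------------------------------------------------------------------------
// Tally block
// ---------------------------------------------------------------------------

static const int NAGE = 101;
static const int HORIZON_Q = 404; // age 101 exclusive; death forced by 403

struct Tally {
  std::vector<double> py;                       // person-years by age
  std::vector<double> alive_at, early_at, adv_at, carrier_at, multi_at; // [age*2+sex] for first three
  std::vector<double> inc_stage;                // [age*4+stage-1]
  std::vector<double> inc_sex;                  // [age*2+sex]
  std::vector<double> inc_mode;                 // [age*3+mode] 0 sympt,1 screen,2 other
  std::vector<double> inc_side;                 // [age*3]: rectum, left colon, right colon
  std::vector<double> crc_death, oth_death, compl_death_v;
  std::vector<double> colono;                   // [age*4+context]
  std::vector<double> sig, fobt, polyp;
  double compl_nopoly[4] = {0,0,0,0}, compl_poly[4] = {0,0,0,0};
  double ncol_nopoly = 0, ncol_poly = 0, reach_cecum_n = 0, ncol_total = 0;
  std::vector<double> cost_proc, cost_compl, cost_treat;
  double origin_init[3] = {0,0,0}, origin_diag[3] = {0,0,0};
  double sync_diag = 0, total_diag = 0;
  std::vector<double> dwell_hist;               // quarters 0..240
  double years_lost = 0;
  double stage_mode[2][4] = {{0,0,0,0},{0,0,0,0}}; // 0 symptomatic / 1 asymptomatic
  double trial_cases[3] = {0,0,0}, trial_cases_tot = 0, trial_deaths = 0, trial_n = 0;
  double aden_init = 0, aden_disappear = 0, aden_resect = 0, aden_transform = 0,
         aden_alive_end = 0;
  double clip_warn = 0;
  Tally() {
    py.assign(NAGE, 0); alive_at.assign(NAGE * 2, 0); early_at.assign(NAGE * 2, 0);
    adv_at.assign(NAGE * 2, 0); carrier_at.assign(NAGE, 0); multi_at.assign(NAGE, 0);
    inc_stage.assign(NAGE * 4, 0); inc_sex.assign(NAGE * 2, 0);
    inc_mode.assign(NAGE * 3, 0); inc_side.assign(NAGE * 3, 0);
    crc_death.assign(NAGE, 0); oth_death.assign(NAGE, 0); compl_death_v.assign(NAGE, 0);
    colono.assign(NAGE * 4, 0); sig.assign(NAGE, 0); fobt.assign(NAGE, 0); polyp.assign(NAGE, 0);
    cost_proc.assign(NAGE, 0); cost_compl.assign(NAGE, 0); cost_treat.assign(NAGE, 0);
    dwell_hist.assign(241, 0);
  }
};

// ---------------------------------------------------------------------------
// Per-individual simulation
// ---------------------------------------------------------------------------

struct Individual {
  int sex;                     // 0 female, 1 male
  double risk;                 // individual initiation multiplier
  std::vector<Adenoma> adenomas;
  std::vector<Cancer> cancers;
  int nat_death_q;
  bool alive = true;
  int death_cause = -1;        // 0 other, 1 CRC, 2 complication
  // treatment / surveillance state
  bool treat_on = false;
  int diag_q = -1, crc_death_q = -1, treat_stage = 0;
  int next_surv_q = 0;
  bool attender = false, fu_attender = false;
  uint64_t scr_key = 0;
  int trial_e_q = -1; bool trial_second = false;
  size_t next_scr = 0;
};

struct Ctx {
  const NatParams &np; const ScreenModel &sm; const Plan &pl; const Costs &co;
  const std::vector<double> &death_cdf;
  Tally &T;
  // precomputed age-rate tables indexed by quarter
  std::vector<double> sig_rate, b_rate, c_rate;
};

static inline int side_of(int seg) { // 0 rectum, 1 left colon, 2 right colon
  if (seg == 1) return 0;
  if (seg <= 6) return 1;
  return 2;
}

static void new_cancer(Individual &ind, Ctx &cx, Rng &nat, int q, int seg, int origin,
                       int aden_birth_q) {
  const NatParams &np = cx.np;
  // sojourn: truncated normal (>0), rounded to quarters, at least 1
  double t;
  do { t = nat.normal(np.sojourn_mean_y, np.sojourn_sd_y); } while (t <= 0);
  int T = (int)std::lround(t * 4.0); if (T < 1) T = 1;
  // symptomatic stage
  double u = nat.unif(), acc = 0; int sstar = 4;
  for (int k = 0; k < 4; ++k) { acc += np.symp_stage[k]; if (u < acc) { sstar = k + 1; break; } }
  // partition sojourn quarters over stages 1..sstar with the configured weights
  int cnt[4] = {0, 0, 0, 0};
  double wsum = 0; for (int k = 0; k < sstar; ++k) wsum += np.stage_time_w[k];
  for (int i = 0; i < T; ++i) {
    double v = nat.unif() * wsum, a2 = 0; int k2 = sstar - 1;
    for (int k = 0; k < sstar; ++k) { a2 += np.stage_time_w[k]; if (v < a2) { k2 = k; break; } }
    cnt[k2]++;
  }
  Cancer c; c.stage = 1; c.seg = seg; c.origin = origin; c.init_q = q; c.sym_q = q + T;
  int cq = q;
  for (int k = 0; k < 3; ++k) {
    cq += cnt[k];
    c.adv_q[k] = (k < sstar - 1) ? cq : INT32_MAX;
  }
  ind.cancers.push_back(c);
  cx.T.origin_init[origin] += 1;
  if (origin != 2) {
    int d = q - aden_birth_q; if (d > 240) d = 240; if (d < 0) d = 0;
    cx.T.dwell_hist[d] += 1;
  }
}

static void diagnose(Individual &ind, Ctx &cx, Rng &nat, int q, int mode,
                     const std::vector<int> &detected_idx) {
  Tally &T = cx.T;
  int age = q / 4; if (age > 100) age = 100;
  // most advanced detected cancer defines stage/side of the record
  int best = detected_idx[0];
  for (int i : detected_idx)
    if (ind.cancers[i].stage > ind.cancers[best].stage) best = i;
  int stage = ind.cancers[best].stage, seg = ind.cancers[best].seg;
  T.inc_stage[age * 4 + (stage - 1)] += 1;
  T.inc_sex[age * 2 + ind.sex] += 1;
  T.inc_mode[age * 3 + mode] += 1;
  T.inc_side[age * 3 + side_of(seg)] += 1;
  T.total_diag += 1;
  if (ind.cancers.size() >= 2) T.sync_diag += 1;
  T.origin_diag[ind.cancers[best].origin] += 1;
  T.stage_mode[mode == 0 ? 0 : 1][stage - 1] += 1;
  if (ind.trial_e_q >= 0 && q > ind.trial_e_q && q <= ind.trial_e_q + cx.pl.trial_fu_q) {
    T.trial_cases_tot += 1; T.trial_cases[side_of(seg)] += 1;
  }
  // curative resection of all malignant disease; stage-specific survival
  ind.cancers.clear();
  ind.treat_on = true; ind.diag_q = q; ind.treat_stage = stage; ind.crc_death_q = -1;
  double h = 1.0 - std::pow(cx.np.surv5[stage - 1], 1.0 / 20.0);
  for (int k = 1; k <= 20; ++k)
    if (nat.unif() < h) { ind.crc_death_q = q + k; break; }
  if (cx.pl.surveillance_on && q + cx.sm.surv_int_crc < cx.sm.surv_stop_q)
    ind.next_surv_q = q + cx.sm.surv_int_crc;
}

static inline Rng proc_rng(const Individual &ind, int q, int kind) {
  uint64_t k = ind.scr_key ^ (0x9E3779B97F4A7C15ULL * (uint64_t)(q * 8 + kind + 1));
  Rng r; r.seed(splitmix64(k));
  return r;
}

// returns true if the individual died of a complication during the procedure
static bool colonoscopy(Individual &ind, Ctx &cx, Rng &scr_unused, Rng &nat, int q, int context) {
  Rng scr = proc_rng(ind, q, context);
  Tally &T = cx.T; const ScreenModel &sm = cx.sm;
  int age = q / 4; if (age > 100) age = 100;
  T.colono[age * 4 + context] += 1; T.ncol_total += 1;
  T.cost_proc[age] += cx.co.colono;
  // depth of insertion
  int D;
  if (scr.unif() < sm.reach_cecum) { D = 13; T.reach_cecum_n += 1; }
  else D = sm.inc_lo + (int)(scr.unif() * (sm.inc_hi - sm.inc_lo + 1));
  // adenoma detection
  std::vector<int> det_ad;
  int n_adv_det = 0;
  for (size_t i = 0; i < ind.adenomas.size(); ++i) {
    const Adenoma &a = ind.adenomas[i];
    if (a.seg > D) continue;
    double p = sm.det_ad[a.stage - 1];
    if (a.seg == sm.flex1 || a.seg == sm.flex2) p *= sm.flex_pen;
    if (scr.unif() < p) { det_ad.push_back((int)i); if (a.stage >= 5) n_adv_det++; }
  }
  // cancer detection (a symptomatic cancer declares itself)
  std::vector<int> det_ca;
  for (size_t i = 0; i < ind.cancers.size(); ++i) {
    const Cancer &c = ind.cancers[i];
    bool sympt = (context == 2 && q >= c.sym_q);
    if (sympt) { det_ca.push_back((int)i); continue; }
    if (c.seg > D) continue;
    double p = sm.det_ca;
    if (c.seg == sm.flex1 || c.seg == sm.flex2) p *= sm.flex_pen;
    if (scr.unif() < p) det_ca.push_back((int)i);
  }
  bool poly = !det_ad.empty();
  if (poly) {
    T.polyp[age] += 1; T.cost_proc[age] += cx.co.polyp;
    // remove detected adenomas (descending index order)
    for (int k = (int)det_ad.size() - 1; k >= 0; --k) {
      T.aden_resect += 1;
      ind.adenomas.erase(ind.adenomas.begin() + det_ad[k]);
    }
  }
  int n_det = (int)det_ad.size();
  if (!det_ca.empty()) {
    diagnose(ind, cx, nat, q, context == 2 ? 0 : (context == 0 ? 1 : 2), det_ca);
  } else if (cx.pl.surveillance_on) {
    int iv = 0;
    if (n_adv_det > 0 || n_det >= 3) iv = sm.surv_int_adv;
    else if (n_det >= 1) iv = sm.surv_int_small;
    if (iv > 0 && q + iv < sm.surv_stop_q) ind.next_surv_q = q + iv;
    else if (context == 1) ind.next_surv_q = 0; // negative surveillance: back to screening
  }
  // complications
  double mult = poly ? sm.compl_poly_mult : 1.0;
  if (poly) T.ncol_poly += 1; else T.ncol_nopoly += 1;
  bool died = false;
  for (int i = 0; i < 4; ++i) {
    if (scr.unif() < sm.compl_p[i] * mult) {
      if (poly) T.compl_poly[i] += 1; else T.compl_nopoly[i] += 1;
      T.cost_compl[age] += cx.co.compl_c[i];
      if (i == 3 && scr.unif() < sm.compl_death_p) died = true;
    }
  }
  if (died) {
    ind.alive = false; ind.death_cause = 2; T.compl_death_v[age] += 1;
  }
  return died;
}

static bool sigmoidoscopy(Individual &ind, Ctx &cx, Rng &scr_outer, Rng &nat, int q) {
  Rng scr = proc_rng(ind, q, 5);
  Tally &T = cx.T; const ScreenModel &sm = cx.sm;
  int age = q / 4; if (age > 100) age = 100;
  T.sig[age] += 1; T.cost_proc[age] += cx.co.sig;
  int D = sm.sig_reach_lo + scr.categorical(sm.sig_reach_cum);
  bool finding = false;
  for (const Adenoma &a : ind.adenomas) {
    if (a.seg > D) continue;
    double p = sm.det_ad[a.stage - 1] * (a.stage <= 4 ? sm.sig_pen_early : sm.sig_pen_adv);
    if (a.seg == sm.flex1 || a.seg == sm.flex2) p *= sm.flex_pen;
    if (scr.unif() < p) finding = true;
  }
  for (const Cancer &c : ind.cancers) {
    if (c.seg > D) continue;
    if (scr.unif() < sm.det_ca * sm.sig_pen_adv) finding = true;
  }
  // complications (scaled down, no polypectomy at sigmoidoscopy)
  for (int i = 0; i < 4; ++i) {
    if (scr.unif() < sm.compl_p[i] * sm.sig_compl_mult) {
      T.compl_nopoly[i] += 0; // not counted in the colonoscopy-rate tallies
      T.cost_compl[age] += cx.co.compl_c[i];
      if (i == 3 && scr.unif() < sm.compl_death_p) {
        ind.alive = false; ind.death_cause = 2; T.compl_death_v[age] += 1;
        return true;
      }
    }
  }
  if (finding && ind.fu_attender)
    return colonoscopy(ind, cx, scr_outer, nat, q, 3);
  return false;
}

static bool stool_test(Individual &ind, Ctx &cx, Rng &scr_outer, Rng &nat, int q) {
  Rng scr = proc_rng(ind, q, 6);
  Tally &T = cx.T; const ScreenModel &sm = cx.sm;
  int age = q / 4; if (age > 100) age = 100;
  T.fobt[age] += 1; T.cost_proc[age] += cx.co.fobt;
  bool pos = false;
  for (const Adenoma &a : ind.adenomas) {
    double s = a.stage <= 4 ? sm.fobt_sens_early : sm.fobt_sens_adv;
    if (scr.unif() < s) pos = true;
  }
  for (size_t i = 0; i < ind.cancers.size(); ++i)
    if (scr.unif() < sm.fobt_sens_ca) pos = true;
  if (ind.adenomas.empty() && ind.cancers.empty())
    pos = scr.unif() > sm.fobt_spec;
  if (pos && ind.fu_attender)
    return colonoscopy(ind, cx, scr_outer, nat, q, 3);
  return false;
}

static void natural_history_step(Individual &ind, Ctx &cx, Rng &nat, int q) {
  const NatParams &np = cx.np;
  double sexI = ind.sex ? np.sex_init : 1.0;
  double sexE = ind.sex ? np.sex_early : 1.0;
  double sexA = ind.sex ? np.sex_adv : 1.0;
  // (i) new adenoma
  double p_new = cx.sig_rate[q] * sexI * ind.risk;
  if (p_new > 1) { p_new = 1; cx.T.clip_warn += 1; }
  if (nat.unif() < p_new) {
    Adenoma a;
    a.stage = 1;
    a.seg = 1 + nat.categorical(np.loc_cum);
    // one aggressiveness quantile per adenoma: the early and advanced
    // multiplier CDFs are evaluated comonotonically, so a fast early lesion
    // is also a fast advanced lesion
    double u_les = nat.unif();
    a.multE = pwl(np.lesE_q, np.lesE_m, u_les);
    a.multA = pwl(np.lesA_q, np.lesA_m, u_les);
    a.birth_q = q;
    ind.adenomas.push_back(a);
    cx.T.aden_init += 1;
  }
  // (ii) per-adenoma events: at most one of progression / fast cancer / regression
  double bq = cx.b_rate[q], cq = cx.c_rate[q];
  for (int i = (int)ind.adenomas.size() - 1; i >= 0; --i) {
    Adenoma &a = ind.adenomas[i];
    bool rect = (a.seg == 1);
    double pProg, pCan = 0;
    if (a.stage <= 4) {
      pProg = bq * a.multE * np.stage_prog[a.stage - 1] * sexE * (rect ? np.rect_early : 1.0);
    } else {
      pProg = cq * a.multA * np.stage_prog[a.stage - 1] * sexA * (rect ? np.rect_adv : 1.0);
    }
    if (a.stage <= 5)
      pCan = cq * a.multA * np.stage_cancer[a.stage - 1] * sexA * (rect ? np.rect_adv : 1.0);
    double pReg = np.stage_regr[a.stage - 1];
    double tot = pProg + pCan + pReg;
    if (tot > 1) { pProg /= tot; pCan /= tot; pReg /= tot; cx.T.clip_warn += 1; }
    double u = nat.unif();
    if (u < pProg) {
      if (a.stage == 6) { // malignant transformation of a stage-VI adenoma
        int seg = a.seg, bq2 = a.birth_q;
        cx.T.aden_transform += 1;
        ind.adenomas.erase(ind.adenomas.begin() + i);
        new_cancer(ind, cx, nat, q, seg, 0, bq2);
      } else a.stage += 1;
    } else if (u < pProg + pCan) { // fast route to carcinoma from stages I-V
      int seg = a.seg, bq2 = a.birth_q;
      cx.T.aden_transform += 1;
      ind.adenomas.erase(ind.adenomas.begin() + i);
      new_cancer(ind, cx, nat, q, seg, 1, bq2);
    } else if (u < pProg + pCan + pReg) {
      if (a.stage == 1) { // disappearance of a stage-I adenoma
        cx.T.aden_disappear += 1;
        ind.adenomas.erase(ind.adenomas.begin() + i);
      } else a.stage -= 1;
    }
  }
  // (iii) direct carcinoma without adenomatous precursor
  if (np.direct_tot > 0) {
    double p_dir = np.direct_tot * ind.risk * sexI;
    if (p_dir > 1) { p_dir = 1; cx.T.clip_warn += 1; }
    if (nat.unif() < p_dir) {
      int seg = 1 + nat.categorical(np.direct_cum);
      new_cancer(ind, cx, nat, q, seg, 2, q);
    }
  }
  // (iv) cancer stage advance (predefined dwell schedule)
  for (Cancer &c : ind.cancers)
    for (int k = 0; k < 3; ++k)
      if (c.stage == k + 1 && q >= c.adv_q[k]) c.stage = k + 2;
}

static void simulate_one(Individual &ind, Ctx &cx, Rng &nat, Rng &scr) {
  const Plan &pl = cx.pl;
  Tally &T = cx.T;
  // natural (non-CRC) death quarter: one inverse-CDF draw
  {
    double u = nat.unif();
    int lo = 0, hi = HORIZON_Q - 1;
    while (lo < hi) { int mid = (lo + hi) / 2; if (cx.death_cdf[mid] >= u) hi = mid; else lo = mid + 1; }
    ind.nat_death_q = lo;
  }
  // screening-arm draws (made unconditionally: keeps arms paired)
  ind.attender = scr.unif() < pl.adherence;
  ind.fu_attender = scr.unif() < pl.fu_adherence;
  if (pl.trial_mode) {
    ind.trial_e_q = pl.trial_lo_q + (int)(scr.unif() * (pl.trial_hi_q - pl.trial_lo_q + 1));
    ind.trial_second = scr.unif() < pl.trial_second_frac;
    T.trial_n += 1;
  }
  for (int q = 0; q < HORIZON_Q; ++q) {
    int age = q / 4;
    if (q % 4 == 0) { // birthday tallies
      T.alive_at[age * 2 + ind.sex] += 1;
      bool e = false, ad = false; int nles = (int)ind.adenomas.size();
      for (const Adenoma &a : ind.adenomas) { if (a.stage <= 4) e = true; else ad = true; }
      if (e)  T.early_at[age * 2 + ind.sex] += 1;
      if (ad) T.adv_at[age * 2 + ind.sex] += 1;
      if (nles >= 1) T.carrier_at[age] += 1;
      if (nles >= 2) T.multi_at[age] += 1;
    }
    T.py[age] += 0.25;
    if (q >= 80) // lesions are not modelled before age 20
      natural_history_step(ind, cx, nat, q);
    // hypothetical perfect intervention: clear the colon silently
    if (pl.perfect_q > 0 && q == pl.perfect_q) {
      T.aden_resect += ind.adenomas.size();
      ind.adenomas.clear();
      ind.cancers.clear();
    }
    // --- interventions -----------------------------------------------------
    bool dead_proc = false;
    // symptomatic cancer triggers a diagnostic colonoscopy
    bool sympt = false;
    for (const Cancer &c : ind.cancers) if (q >= c.sym_q) sympt = true;
    if (sympt) {
      dead_proc = colonoscopy(ind, cx, scr, nat, q, 2);
    } else if (ind.next_surv_q > 0 && q == ind.next_surv_q) {
      ind.next_surv_q = 0;
      dead_proc = colonoscopy(ind, cx, scr, nat, q, 1);
    } else if (pl.modality != 0 && ind.attender && ind.next_surv_q == 0 && !ind.treat_on) {
      bool due = false;
      if (pl.trial_mode) {
        due = (q == ind.trial_e_q) ||
              (ind.trial_second && q == ind.trial_e_q + pl.trial_gap_q);
      } else {
        while (ind.next_scr < pl.scr_q.size() && pl.scr_q[ind.next_scr] < q) ind.next_scr++;
        due = (ind.next_scr < pl.scr_q.size() && pl.scr_q[ind.next_scr] == q);
      }
      if (due) {
        if (pl.modality == 1)      dead_proc = colonoscopy(ind, cx, scr, nat, q, 0);
        else if (pl.modality == 2) dead_proc = sigmoidoscopy(ind, cx, scr, nat, q);
        else if (pl.modality == 3) dead_proc = stool_test(ind, cx, scr, nat, q);
      }
    }
    if (dead_proc) break;
    // --- treatment costs ---------------------------------------------------
    if (ind.treat_on) {
      int k = q - ind.diag_q; // quarters since diagnosis
      if (k >= 20) ind.treat_on = false;
      else {
        int s = ind.treat_stage - 1;
        double cost;
        if (k == 0) cost = cx.co.treat_init[s];
        else if (ind.crc_death_q > 0 && q >= ind.crc_death_q - 4)
          cost = cx.co.treat_term[s] / 4.0;
        else cost = cx.co.treat_cont[s] / 4.0;
        T.cost_treat[age] += cost;
      }
    }
    // --- deaths ------------------------------------------------------------
    if (ind.crc_death_q == q) {
      ind.alive = false; ind.death_cause = 1;
      T.crc_death[age] += 1;
      T.years_lost += (ind.nat_death_q - q) / 4.0;
      if (ind.trial_e_q >= 0 && q > ind.trial_e_q && q <= ind.trial_e_q + pl.trial_fu_q)
        T.trial_deaths += 1;
      break;
    }
    if (q >= ind.nat_death_q) {
      ind.alive = false; ind.death_cause = 0;
      T.oth_death[age] += 1;
      break;
    }
  }
  T.aden_alive_end += ind.adenomas.size();
}

// ---------------------------------------------------------------------------
// Parameter unpacking
// ---------------------------------------------------------------------------

static NatParams unpack_params(List p) {
  NatParams np;
  np.a0 = p["a0"]; np.a1 = p["a1"]; np.a2 = p["a2"];
  np.b0 = p["b0"]; np.b1 = p["b1"]; np.b2 = p["b2"];
  np.c0 = p["c0"]; np.c1 = p["c1"]; np.c2 = p["c2"];
  NumericVector iq = p["indiv_q"], im = p["indiv_m"];
  np.indiv_q = as<std::vector<double>>(iq); np.indiv_m = as<std::vector<double>>(im);
  NumericVector eq = p["lesion_early_q"], em = p["lesion_early_m"];
  np.lesE_q = as<std::vector<double>>(eq); np.lesE_m = as<std::vector<double>>(em);
  NumericVector aq = p["lesion_adv_q"], am = p["lesion_adv_m"];
  np.lesA_q = as<std::vector<double>>(aq); np.lesA_m = as<std::vector<double>>(am);
  NumericVector sf = p["sex_factors"];
  np.sex_init = sf[0]; np.sex_early = sf[1]; np.sex_adv = sf[2];
  NumericVector rf = p["rectum_factors"];
  np.rect_early = rf[0]; np.rect_adv = rf[1];
  fill_arr(np.stage_prog, p["stage_progression"], 6);
  fill_arr(np.stage_regr, p["stage_regression"], 6);
  fill_arr(np.stage_cancer, p["stage_cancer_risk"], 5);
  fill_arr(np.direct_risk, p["direct_cancer_risk"], 13);
  np.sojourn_mean_y = p["sojourn_mean_y"]; np.sojourn_sd_y = p["sojourn_sd_y"];
  NumericVector loc = p["location_dist"];
  np.loc_cum = cumvec(loc);
  NumericVector dr = p["direct_cancer_risk"];
  np.direct_tot = 0; for (int i = 0; i < 13; ++i) np.direct_tot += dr[i];
  if (np.direct_tot > 0) np.direct_cum = cumvec(dr);
  else np.direct_cum.assign(13, 1.0);
  fill_arr(np.symp_stage, p["symptomatic_stage_dist"], 4);
  fill_arr(np.stage_time_w, p["stage_time_weights"], 4);
  fill_arr(np.surv5, p["survival_5y"], 4);
  np.male_fraction = p["male_fraction"];
  return np;
}

static ScreenModel unpack_screen(List s) {
  ScreenModel m;
  fill_arr(m.det_ad, s["detect_adenoma"], 6);
  m.det_ca = s["detect_cancer"];
  m.flex_pen = s["flexure_penalty"];
  IntegerVector fx = s["flexure_segments"];
  m.flex1 = fx[0]; m.flex2 = fx[1];
  m.reach_cecum = s["reach_cecum"];
  IntegerVector inc = s["incomplete_range"];
  m.inc_lo = inc[0]; m.inc_hi = inc[1];
  fill_arr(m.compl_p, s["complication_p"], 4);
  m.compl_poly_mult = s["complication_polyp_mult"];
  m.compl_death_p = s["perforation_fatality"];
  m.sig_compl_mult = s["sig_complication_mult"];
  NumericVector sr = s["sig_reach_p"];
  m.sig_reach_cum = cumvec(sr);
  m.sig_reach_lo = s["sig_reach_lo"];
  m.sig_pen_early = s["sig_penalty_early"]; m.sig_pen_adv = s["sig_penalty_adv"];
  m.fobt_sens_early = s["fobt_sens_early"]; m.fobt_sens_adv = s["fobt_sens_adv"];
  m.fobt_sens_ca = s["fobt_sens_cancer"]; m.fobt_spec = s["fobt_spec"];
  m.surv_int_crc = s["surv_interval_crc"];
  m.surv_int_adv = s["surv_interval_adv"];
  m.surv_int_small = s["surv_interval_small"];
  m.surv_stop_q = s["surv_stop_q"];
  return m;
}

static Plan unpack_plan(List p) {
  Plan pl;
  pl.modality = p["modality"];
  IntegerVector sq = p["screen_quarters"];
  pl.scr_q = as<std::vector<int>>(sq);
  pl.adherence = p["adherence"]; pl.fu_adherence = p["fu_adherence"];
  pl.surveillance_on = p["surveillance_on"];
  pl.trial_mode = p["trial_mode"];
  pl.trial_lo_q = p["trial_lo_q"]; pl.trial_hi_q = p["trial_hi_q"];
  pl.trial_fu_q = p["trial_fu_q"]; pl.trial_gap_q = p["trial_gap_q"];
  pl.trial_second_frac = p["trial_second_frac"];
  pl.perfect_q = p["perfect_q"];
  return pl;
}

static Costs unpack_costs(List c) {
  Costs co;
  co.colono = c["colonoscopy"]; co.polyp = c["polypectomy"];
  co.sig = c["sigmoidoscopy"]; co.fobt = c["fobt"];
  fill_arr(co.compl_c, c["complication_costs"], 4);
  fill_arr(co.treat_init, c["treat_initial"], 4);
  fill_arr(co.treat_cont, c["treat_continuing"], 4);
  fill_arr(co.treat_term, c["treat_terminal"], 4);
  return co;
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sim_population_cpp(List params, List screen, List plan, List costs,
                        NumericVector death_cdf, int n, int seed) {
  if (n < 1) stop("n must be >= 1");
  NatParams np = unpack_params(params);
  ScreenModel sm = unpack_screen(screen);
  Plan pl = unpack_plan(plan);
  Costs co = unpack_costs(costs);
  std::vector<double> cdf = as<std::vector<double>>(death_cdf);
  if ((int)cdf.size() != HORIZON_Q) stop("death_cdf must have 404 quarterly entries");
  Tally T;
  Ctx cx{np, sm, pl, co, cdf, T};
  cx.sig_rate.assign(HORIZON_Q, 0);
  cx.b_rate.assign(HORIZON_Q, 0);
  cx.c_rate.assign(HORIZON_Q, 0);
  for (int q = 0; q < HORIZON_Q; ++q) {
    double y = q / 4.0;
    cx.sig_rate[q] = np.a0 / (1.0 + std::exp(-(np.a1 * y - np.a2)));
    double db = np.b1 * y - np.b2, dc = np.c1 * y - np.c2;
    cx.b_rate[q] = np.b0 * std::exp(-db * db);
    cx.c_rate[q] = np.c0 * std::exp(-dc * dc);
  }
  uint64_t master = (uint64_t)(uint32_t)seed;
  for (int i = 0; i < n; ++i) {
    Rng nat, scr;
    uint64_t b1 = master * 0x9E3779B97F4A7C15ULL + (uint64_t)(2 * i + 1);
    uint64_t b2 = master * 0x9E3779B97F4A7C15ULL + (uint64_t)(2 * i + 2);
    nat.seed(splitmix64(b1));
    scr.seed(splitmix64(b2));
    Individual ind;
    ind.scr_key = splitmix64(b2) ^ 0xA5A5A5A5DEADBEEFULL;
    ind.sex = (nat.unif() < np.male_fraction) ? 1 : 0;
    ind.risk = pwl(np.indiv_q, np.indiv_m, nat.unif());
    simulate_one(ind, cx, nat, scr);
  }

  auto NV = [](std::vector<double> &v) { return NumericVector(v.begin(), v.end()); };
  NumericVector cn(4), cp(4), oi(3), od(3), tc(3);
  for (int i = 0; i < 4; ++i) { cn[i] = T.compl_nopoly[i]; cp[i] = T.compl_poly[i]; }
  for (int i = 0; i < 3; ++i) { oi[i] = T.origin_init[i]; od[i] = T.origin_diag[i]; tc[i] = T.trial_cases[i]; }
  NumericMatrix sm2(2, 4);
  for (int i = 0; i < 2; ++i) for (int j = 0; j < 4; ++j) sm2(i, j) = T.stage_mode[i][j];
  return List::create(
    _["n"] = n, _["seed"] = seed,
    _["py"] = NV(T.py),
    _["alive_at"] = NV(T.alive_at), _["early_at"] = NV(T.early_at),
    _["adv_at"] = NV(T.adv_at), _["carrier_at"] = NV(T.carrier_at),
    _["multi_at"] = NV(T.multi_at),
    _["inc_stage"] = NV(T.inc_stage), _["inc_sex"] = NV(T.inc_sex),
    _["inc_mode"] = NV(T.inc_mode),
    _["inc_side"] = NV(T.inc_side),
    _["crc_death"] = NV(T.crc_death), _["oth_death"] = NV(T.oth_death),
    _["compl_death"] = NV(T.compl_death_v),
    _["colono"] = NV(T.colono), _["sig"] = NV(T.sig), _["fobt"] = NV(T.fobt),
    _["polypectomy"] = NV(T.polyp),
    _["compl_nopoly"] = cn, _["compl_poly"] = cp,
    _["ncol_nopoly"] = T.ncol_nopoly, _["ncol_poly"] = T.ncol_poly,
    _["ncol_total"] = T.ncol_total, _["reach_cecum_n"] = T.reach_cecum_n,
    _["cost_proc"] = NV(T.cost_proc), _["cost_compl"] = NV(T.cost_compl),
    _["cost_treat"] = NV(T.cost_treat),
    _["origin_init"] = oi, _["origin_diag"] = od,
    _["sync_diag"] = T.sync_diag, _["total_diag"] = T.total_diag,
    _["dwell_hist"] = NV(T.dwell_hist),
    _["years_lost"] = T.years_lost,
    _["stage_mode"] = sm2,
    _["trial_cases"] = tc, _["trial_cases_tot"] = T.trial_cases_tot,
    _["trial_deaths"] = T.trial_deaths, _["trial_n"] = T.trial_n,
    _["aden_init"] = T.aden_init, _["aden_disappear"] = T.aden_disappear,
    _["aden_resect"] = T.aden_resect, _["aden_transform"] = T.aden_transform,
    _["aden_alive_end"] = T.aden_alive_end,
    _["clip_warnings"] = T.clip_warn);
}

// [[Rcpp::export]]
IntegerVector sample_sojourn_cpp(int n, double mean_y, double sd_y, int seed) {
  Rng r; uint64_t m = (uint64_t)(uint32_t)seed;
  r.seed(splitmix64(m));
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double t;
    do { t = r.normal(mean_y, sd_y); } while (t <= 0);
    int T = (int)std::lround(t * 4.0); if (T < 1) T = 1;
    out[i] = T;
  }
  return out;
}

// Stand-alone complication sampler exercising the same probability model as
// the in-engine colonoscopy (used for empirical rate checks at large n).
// [[Rcpp::export]]
NumericVector sample_complications_cpp(int n, NumericVector compl_p,
                                       double poly_mult, bool polypectomy,
                                       int seed) {
  if (compl_p.size() != 4) stop("complication_p must have 4 entries");
  Rng r; uint64_t m = ((uint64_t)(uint32_t)seed) ^ 0xC001D00DULL;
  r.seed(splitmix64(m));
  NumericVector counts(4);
  double mult = polypectomy ? poly_mult : 1.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 4; ++j)
      if (r.unif() < compl_p[j] * mult) counts[j] += 1;
  return counts;
}
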