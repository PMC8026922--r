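// Core microsimulation engine: latent adenoma-carcinoma natural history and
// screening overlay. All randomness is drawn from a counter-based hash RNG
// keyed by (seed, individual, purpose, k1, k2) so that every individual sees
// identical uniforms under every strategy and scenario (common random
// numbers), and so the per-person R reference implementation can reproduce
// the engine draw-for-draw.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// hashed RNG

static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline double u01(uint64_t seed, uint64_t id, uint64_t purpose,
                         uint64_t k1, uint64_t k2) {
  uint64_t h = mix64(seed ^ 0x5851f42d4c957f2dULL);
  h = mix64(h ^ id);
  h = mix64(h ^ purpose);
  h = mix64(h ^ k1);
  h = mix64(h ^ k2);
  // strictly inside (0,1)
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

// purpose codes (shared contract with the R reference implementation)
enum Purpose {
  P_FRAILTY = 1, P_OCD = 2, P_NADEN = 3, P_ONSET = 4, P_SEGMENT = 5,
  P_GROWTH = 6, P_TRANS = 7, P_SOJOURN = 8, P_STAGE = 9,
  P_SURVCURE = 10, P_SURVTIME = 11,
  P_STOOL = 12, P_DETECT = 13, P_REACH = 14, P_FP = 15, P_COMPL = 16
};

// [[Rcpp::export]]
NumericVector cpp_hash_u01(double seed, NumericVector id, NumericVector purpose,
                           NumericVector k1, NumericVector k2) {
  R_xlen_t n = std::max(std::max(id.size(), purpose.size()),
                        std::max(k1.size(), k2.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = u01((uint64_t)seed,
                 (uint64_t)id[i % id.size()],
                 (uint64_t)purpose[i % purpose.size()],
                 (uint64_t)k1[i % k1.size()],
                 (uint64_t)k2[i % k2.size()]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// parameters

static const int CAP = 64;      // max adenomas carried per person
static const double T_NONE = 1e9;

struct NHParams {
  std::vector<double> ob, orate;   // onset age breaks and rates (piecewise)
  double max_age;
  double fr_ml, fr_sd;
  double gr_ml, gr_sd;             // lognormal time from 1 mm to 10 mm
  double tr_rate10, tr_power;      // transformation hazard at/below 10 mm
  double sj_ml, sj_sd;             // lognormal preclinical sojourn
  double st_sympt[4], st_screen[4];   // stage CDFs
  double sv_cure[4], sv_mean[4];
  double seg_cum[4];
  std::vector<double> q;           // life table qx, ages 0..(length-1)
};

static NHParams parseNH(List nh) {
  NHParams p;
  p.ob = as<std::vector<double>>(nh["onset_breaks"]);
  p.orate = as<std::vector<double>>(nh["onset_rates"]);
  p.max_age = as<double>(nh["max_age"]);
  List fr = nh["frailty"];
  p.fr_ml = as<double>(fr["meanlog"]); p.fr_sd = as<double>(fr["sdlog"]);
  List gr = nh["growth"];
  p.gr_ml = as<double>(gr["meanlog"]); p.gr_sd = as<double>(gr["sdlog"]);
  List tr = nh["transition"];
  p.tr_rate10 = as<double>(tr["rate_at_10mm"]);
  p.tr_power = as<double>(tr["size_power"]);
  List sj = nh["sojourn"];
  p.sj_ml = as<double>(sj["meanlog"]); p.sj_sd = as<double>(sj["sdlog"]);
  NumericVector ss = nh["stage_symptomatic"], sc = nh["stage_screen"];
  double c1 = 0, c2 = 0;
  for (int s = 0; s < 4; ++s) {
    c1 += ss[s]; c2 += sc[s]; p.st_sympt[s] = c1; p.st_screen[s] = c2;
  }
  NumericVector cu = nh["survival_cure"], mn = nh["survival_mean"];
  for (int s = 0; s < 4; ++s) { p.sv_cure[s] = cu[s]; p.sv_mean[s] = mn[s]; }
  NumericVector sg = nh["segment_probs"];
  double cs = 0;
  for (int s = 0; s < 4; ++s) { cs += sg[s]; p.seg_cum[s] = cs; }
  p.q = as<std::vector<double>>(nh["life_table_qx"]);
  return p;
}

struct ScrParams {
  int modality;                    // 0 colonoscopy, 1 FIT, 2 mt-sDNA
  double start, stop, interval;
  double st_crc[4];                // stool CRC sensitivity by segment
  double st_aden[3][4];            // stool sensitivity by size class x segment
  std::vector<double> st_spec;     // stool specificity by single year of age
  double cs_screen[3], cs_fu[3];   // adenoma sensitivity small/medium/large
  double cs_crc, cs_spec, full_reach;
  double compl_base, compl_slope, compl_ref;
  double si_large, si_small, surv_stop, return_interval;
  int n_thresh; double size_thresh;
  bool fit_screening_arm;
};

static ScrParams parseScr(List sc) {
  ScrParams s;
  s.modality = as<int>(sc["modality"]);
  s.start = as<double>(sc["start_age"]);
  s.stop = as<double>(sc["stop_age"]);
  s.interval = as<double>(sc["interval"]);
  NumericVector scrc = sc["stool_sens_crc"];
  for (int i = 0; i < 4; ++i) s.st_crc[i] = scrc[i % scrc.size()];
  NumericMatrix sad = sc["stool_sens_adenoma"];   // 3 rows (size) x 4 cols
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 4; ++j) s.st_aden[i][j] = sad(i, j);
  s.st_spec = as<std::vector<double>>(sc["stool_spec"]);
  NumericVector a = sc["col_sens_screening"], b = sc["col_sens_followup"];
  for (int i = 0; i < 3; ++i) { s.cs_screen[i] = a[i]; s.cs_fu[i] = b[i]; }
  s.cs_crc = as<double>(sc["col_sens_crc"]);
  s.cs_spec = as<double>(sc["col_spec"]);
  s.full_reach = as<double>(sc["full_reach"]);
  s.compl_base = as<double>(sc["compl_base"]);
  s.compl_slope = as<double>(sc["compl_slope"]);
  s.compl_ref = as<double>(sc["compl_ref_age"]);
  s.si_large = as<double>(sc["surveillance_large"]);
  s.si_small = as<double>(sc["surveillance_small"]);
  s.surv_stop = as<double>(sc["surveillance_stop_age"]);
  s.return_interval = as<double>(sc["return_interval"]);
  s.n_thresh = as<int>(sc["count_threshold"]);
  s.size_thresh = as<double>(sc["size_threshold"]);
  s.fit_screening_arm = as<bool>(sc["fit_screening_arm"]);
  return s;
}

// ---------------------------------------------------------------------------
// natural-history sampling primitives (must match the R reference exactly)

static int pois_inv(double u, double lambda, int cap) {
  if (lambda <= 0) return 0;
  double p = std::exp(-lambda), cdf = p;
  int n = 0;
  while (u > cdf && n < cap) { ++n; p *= lambda / n; cdf += p; }
  return n;
}

static double onset_total(const NHParams& p) {
  double tot = 0;
  size_t m = p.ob.size();
  for (size_t i = 0; i < m; ++i) {
    double hi = (i + 1 < m) ? p.ob[i + 1] : p.max_age;
    tot += p.orate[i] * (hi - p.ob[i]);
  }
  return tot;
}

static double onset_invert(const NHParams& p, double target) {
  size_t m = p.ob.size();
  double acc = 0;
  for (size_t i = 0; i < m; ++i) {
    double hi = (i + 1 < m) ? p.ob[i + 1] : p.max_age;
    double seg = p.orate[i] * (hi - p.ob[i]);
    if (target <= acc + seg && p.orate[i] > 0)
      return p.ob[i] + (target - acc) / p.orate[i];
    acc += seg;
  }
  return p.max_age;
}

// time from onset (1 mm) to malignant transformation. Hazard
// h(d) = rate10 * (d/10)^power below 10 mm, constant rate10 above;
// diameter is log-linear in time: d(t) = 10^(t/t10).
static double trans_time(double E, double t10, const NHParams& p) {
  double L = std::log(10.0), A = p.tr_rate10, pw = p.tr_power;
  double H1 = A * t10 / (pw * L) * (1.0 - std::pow(10.0, -pw));
  double t;
  if (E <= H1) {
    double rhs = std::pow(10.0, -pw) + E * pw * L / (A * t10);
    t = t10 + t10 * std::log(rhs) / (pw * L);
  } else {
    t = t10 + (E - H1) / A;
  }
  return t;
}

static int stage_from_u(double u, const double* cdf) {
  int s = 0;
  while (s < 3 && u > cdf[s]) ++s;
  return s;                       // 0..3 == stages I..IV
}

struct Person {
  double frailty, ocd;
  int n;
  double onset[CAP], t10[CAP], trans[CAP], clin[CAP];
  int seg[CAP];
  bool removed[CAP];
};

static void gen_person(uint64_t seed, uint64_t id, const NHParams& p, Person& pr) {
  pr.frailty = std::exp(p.fr_ml + p.fr_sd *
                        R::qnorm(u01(seed, id, P_FRAILTY, 0, 0), 0, 1, 1, 0));
  // other-cause death from the life table, uniform within year
  double u1 = u01(seed, id, P_OCD, 0, 0), u2 = u01(seed, id, P_OCD, 1, 0);
  double cum = 1.0;
  pr.ocd = p.q.size() - 1;        // fallback (terminal q should be 1)
  for (size_t x = 0; x < p.q.size(); ++x) {
    cum *= (1.0 - p.q[x]);
    if (1.0 - cum >= u1) { pr.ocd = x + u2; break; }
  }
  double lam0 = onset_total(p);
  int N = pois_inv(u01(seed, id, P_NADEN, 0, 0), pr.frailty * lam0, CAP);
  pr.n = N;
  for (int k = 1; k <= N; ++k) {
    int i = k - 1;
    pr.onset[i] = onset_invert(p, u01(seed, id, P_ONSET, k, 0) * lam0);
    double useg = u01(seed, id, P_SEGMENT, k, 0);
    int sgm = 0;
    while (sgm < 3 && useg > p.seg_cum[sgm]) ++sgm;
    pr.seg[i] = sgm;
    pr.t10[i] = std::exp(p.gr_ml + p.gr_sd *
                         R::qnorm(u01(seed, id, P_GROWTH, k, 0), 0, 1, 1, 0));
    double E = -std::log(u01(seed, id, P_TRANS, k, 0));
    double tt = trans_time(E, pr.t10[i], p);
    if (tt > 150.0) { pr.trans[i] = T_NONE; pr.clin[i] = T_NONE; }
    else {
      pr.trans[i] = pr.onset[i] + tt;
      double sj = std::exp(p.sj_ml + p.sj_sd *
                           R::qnorm(u01(seed, id, P_SOJOURN, k, 0), 0, 1, 1, 0));
      pr.clin[i] = pr.trans[i] + sj;
    }
    pr.removed[i] = false;
  }
}

// survival after diagnosis of lesion k (1-based key), given stage
static double crc_death_age(uint64_t seed, uint64_t id, int k, int stage,
                            double dx_age, const NHParams& p) {
  double ucure = u01(seed, id, P_SURVCURE, k, 0);
  if (ucure < p.sv_cure[stage]) return T_NONE;   // cured, no CRC death
  double ut = u01(seed, id, P_SURVTIME, k, 0);
  return dx_age - p.sv_mean[stage] * std::log(ut);
}

// ---------------------------------------------------------------------------
// screening overlay

struct ScrOut {
  double dx_age, death_age;
  int dx_mode;                    // 0 none, 1 symptomatic, 2 screen-detected
  int stage;                      // -1 none, else 0..3
  int dx_k;                       // 1-based lesion key of the diagnosed cancer
  int n_stool, n_col, n_compl, n_det_total;
  double first_fu_age; int first_fu_det;   // stool strategies only
};

struct AmrAcc {
  std::vector<double> exams, present, missed;
  AmrAcc() : exams(101, 0.0), present(101, 0.0), missed(101, 0.0) {}
};

struct SessionRes {
  int n_det; double max_d; bool cancer_dx; int dx_k; int n_present;
};

static SessionRes col_session(uint64_t seed, uint64_t id, Person& pr, double a,
                              const double* sens, const ScrParams& s,
                              ScrOut& o, AmrAcc* amr, bool record_amr) {
  SessionRes r; r.n_det = 0; r.max_d = 0; r.cancer_dx = false; r.dx_k = -1;
  r.n_present = 0;
  uint64_t ak = (uint64_t)std::llround(a);
  bool full = u01(seed, id, P_REACH, ak, 0) < s.full_reach;
  o.n_col += full ? 1 : 2;        // partial reach: immediate completed repeat
  for (int i = 0; i < pr.n; ++i) {
    if (pr.removed[i] || pr.onset[i] > a) continue;
    int k = i + 1;
    if (pr.trans[i] > a) {        // still an adenoma
      ++r.n_present;
      double d = std::pow(10.0, (a - pr.onset[i]) / pr.t10[i]);
      int cls = d < 6.0 ? 0 : (d < 10.0 ? 1 : 2);
      if (u01(seed, id, P_DETECT, k, ak) < sens[cls]) {
        pr.removed[i] = true;
        ++r.n_det;
        if (d > r.max_d) r.max_d = d;
      }
    } else {                      // preclinical cancer (clinical age > a)
      if (u01(seed, id, P_DETECT, k, ak) < s.cs_crc && !r.cancer_dx) {
        r.cancer_dx = true; r.dx_k = k;
      }
    }
  }
  bool fp = u01(seed, id, P_FP, ak, 0) < (1.0 - s.cs_spec);
  bool polyp = (r.n_det > 0) || fp;
  double risk = s.compl_base * std::exp(s.compl_slope * (a - s.compl_ref));
  if (risk > 1) risk = 1;
  if (polyp && u01(seed, id, P_COMPL, ak, 0) < risk) ++o.n_compl;
  o.n_det_total += r.n_det;
  if (record_amr && amr) {
    int ai = (int)std::llround(a);
    if (ai >= 0 && ai <= 100) {
      amr->exams[ai] += 1;
      amr->present[ai] += r.n_present;
      amr->missed[ai] += r.n_present - r.n_det;
    }
  }
  return r;
}

static double min_clin(const Person& pr) {
  double m = T_NONE;
  for (int i = 0; i < pr.n; ++i)
    if (!pr.removed[i] && pr.clin[i] < m) m = pr.clin[i];
  return m;
}

// next-exam bookkeeping
enum Kind { K_NONE = 0, K_STOOL = 1, K_COLSCREEN = 2, K_SURVEIL = 3 };

static ScrOut screen_person(uint64_t seed, uint64_t id, Person& pr,
                            const NHParams& p, const ScrParams& s,
                            AmrAcc* amr, bool record_amr) {
  ScrOut o;
  o.dx_age = T_NONE; o.dx_mode = 0; o.stage = -1; o.dx_k = -1;
  o.n_stool = 0; o.n_col = 0; o.n_compl = 0; o.n_det_total = 0;
  o.first_fu_age = -1; o.first_fu_det = -1;

  double a = s.start;
  int kind = (s.modality == 0) ? K_COLSCREEN : K_STOOL;
  while (kind != K_NONE) {
    double tclin = min_clin(pr);
    if (tclin < a && tclin < pr.ocd) {     // symptomatic presentation first
      o.dx_age = tclin; o.dx_mode = 1; break;
    }
    if (a >= pr.ocd) break;                // dies of other causes before exam
    uint64_t ak = (uint64_t)std::llround(a);
    if (kind == K_STOOL) {
      ++o.n_stool;
      // per-person hierarchy: preclinical CRC > most advanced adenoma > none
      int crc_i = -1, best_i = -1;
      double best_d = 0;
      for (int i = 0; i < pr.n; ++i) {
        if (pr.removed[i] || pr.onset[i] > a) continue;
        if (pr.trans[i] <= a) { if (crc_i < 0) crc_i = i; }
        else {
          double d = std::pow(10.0, (a - pr.onset[i]) / pr.t10[i]);
          if (d > best_d) { best_d = d; best_i = i; }
        }
      }
      double prob;
      if (crc_i >= 0) prob = s.st_crc[pr.seg[crc_i]];
      else if (best_i >= 0) {
        int cls = best_d < 6.0 ? 0 : (best_d < 10.0 ? 1 : 2);
        prob = s.st_aden[cls][pr.seg[best_i]];
      } else {
        size_t ai = (size_t)std::min((int)ak, (int)s.st_spec.size() - 1);
        prob = 1.0 - s.st_spec[ai];
      }
      bool pos = u01(seed, id, P_STOOL, ak, 0) < prob;
      if (pos) {
        const double* arm = (s.fit_screening_arm && s.modality == 1)
                              ? s.cs_screen : s.cs_fu;
        SessionRes r = col_session(seed, id, pr, a, arm, s, o, amr, record_amr);
        if (o.first_fu_det < 0) {
          o.first_fu_age = a;
          o.first_fu_det = (r.n_det > 0) ? 1 : 0;
        }
        if (r.cancer_dx) {
          o.dx_age = a; o.dx_mode = 2; o.dx_k = r.dx_k;
          o.stage = stage_from_u(u01(seed, id, P_STAGE, r.dx_k, 0), p.st_screen);
          break;
        }
        if (r.n_det == 0) {                // negative follow-up: back to stool
          if (a + s.return_interval <= s.stop) { a += s.return_interval; }
          else kind = K_NONE;
        } else {
          double iv = (r.n_det >= s.n_thresh || r.max_d >= s.size_thresh)
                        ? s.si_large : s.si_small;
          if (a + iv <= s.surv_stop) { a += iv; kind = K_SURVEIL; }
          else kind = K_NONE;
        }
      } else {
        if (a + s.interval <= s.stop) a += s.interval;
        else kind = K_NONE;
      }
    } else {                               // colonoscopy exam
      const double* arm;
      if (kind == K_COLSCREEN) arm = s.cs_screen;
      else arm = (s.fit_screening_arm && s.modality == 1) ? s.cs_screen
                                                          : s.cs_fu;
      SessionRes r = col_session(seed, id, pr, a, arm, s, o, amr, record_amr);
      if (r.cancer_dx) {
        o.dx_age = a; o.dx_mode = 2; o.dx_k = r.dx_k;
        o.stage = stage_from_u(u01(seed, id, P_STAGE, r.dx_k, 0), p.st_screen);
        break;
      }
      if (r.n_det == 0) {                  // negative: return to screening
        if (a + s.return_interval <= s.stop) {
          a += s.return_interval;
          kind = (s.modality == 0) ? K_COLSCREEN : K_STOOL;
        } else kind = K_NONE;
      } else {
        double iv = (r.n_det >= s.n_thresh || r.max_d >= s.size_thresh)
                      ? s.si_large : s.si_small;
        if (a + iv <= s.surv_stop) { a += iv; kind = K_SURVEIL; }
        else kind = K_NONE;
      }
    }
  }

  // after the screening era: residual symptomatic presentation
  if (o.dx_mode == 0) {
    double tclin = min_clin(pr);
    if (tclin < pr.ocd) { o.dx_age = tclin; o.dx_mode = 1; }
  }
  double death = pr.ocd;
  if (o.dx_mode > 0) {
    if (o.dx_mode == 1) {                  // which lesion presented
      for (int i = 0; i < pr.n; ++i)
        if (!pr.removed[i] && pr.clin[i] == o.dx_age) { o.dx_k = i + 1; break; }
      o.stage = stage_from_u(u01(seed, id, P_STAGE, o.dx_k, 0), p.st_sympt);
    }
    double cd = crc_death_age(seed, id, o.dx_k, o.stage, o.dx_age, p);
    if (cd < death) death = cd;
  }
  o.death_age = death;
  return o;
}

// ---------------------------------------------------------------------------
// exported entry points

// [[Rcpp::export]]
DataFrame cpp_lesions(double seed, IntegerVector ids, List nh) {
  NHParams p = parseNH(nh);
  std::vector<int> vid, vk, vseg;
  std::vector<double> vonset, vt10, vtrans, vclin;
  Person pr;
  for (int j = 0; j < ids.size(); ++j) {
    gen_person((uint64_t)seed, (uint64_t)ids[j], p, pr);
    for (int i = 0; i < pr.n; ++i) {
      vid.push_back(ids[j]); vk.push_back(i + 1); vseg.push_back(pr.seg[i] + 1);
      vonset.push_back(pr.onset[i]); vt10.push_back(pr.t10[i]);
      vtrans.push_back(pr.trans[i] >= T_NONE ? NA_REAL : pr.trans[i]);
      vclin.push_back(pr.clin[i] >= T_NONE ? NA_REAL : pr.clin[i]);
    }
  }
  return DataFrame::create(_["id"] = vid, _["lesion"] = vk,
                           _["segment"] = vseg, _["onset_age"] = vonset,
                           _["time_to_10mm"] = vt10,
                           _["transition_age"] = vtrans,
                           _["clinical_age"] = vclin);
}

// [[Rcpp::export]]
List cpp_simulate_cohort(double seed, IntegerVector ids, List nh,
                         Nullable<List> screen) {
  NHParams p = parseNH(nh);
  bool do_scr = screen.isNotNull();
  ScrParams s;
  if (do_scr) s = parseScr(screen.get());

  int n = ids.size();
  NumericVector frailty(n), ocd(n), u_dx(n), u_death(n);
  IntegerVector n_aden(n), elig(n), u_dxmode(n), u_stage(n);
  NumericVector s_dx(n), s_death(n), first_fu_age(n);
  IntegerVector s_dxmode(n), s_stage(n), n_stool(n), n_col(n), n_compl(n),
      n_det(n), first_fu_det(n);
  AmrAcc amr;
  Person pr;

  for (int j = 0; j < n; ++j) {
    uint64_t id = (uint64_t)ids[j];
    gen_person((uint64_t)seed, id, p, pr);
    frailty[j] = pr.frailty; ocd[j] = pr.ocd; n_aden[j] = pr.n;

    // natural course (no screening)
    double dxa = T_NONE; int kk = -1;
    for (int i = 0; i < pr.n; ++i)
      if (pr.clin[i] < dxa) { dxa = pr.clin[i]; kk = i + 1; }
    bool dx = dxa < pr.ocd;
    double death = pr.ocd; int stg = -1;
    if (dx) {
      stg = stage_from_u(u01((uint64_t)seed, id, P_STAGE, kk, 0), p.st_sympt);
      double cd = crc_death_age((uint64_t)seed, id, kk, stg, dxa, p);
      if (cd < death) death = cd;
    }
    u_dx[j] = dx ? dxa : NA_REAL;
    u_dxmode[j] = dx ? 1 : 0;
    u_stage[j] = dx ? stg + 1 : NA_INTEGER;
    u_death[j] = death;
    bool eligible = (pr.ocd > 40.0) && !(dx && dxa <= 40.0);
    elig[j] = eligible ? 1 : 0;

    if (do_scr) {
      ScrOut o = screen_person((uint64_t)seed, id, pr, p, s, &amr, eligible);
      s_dx[j] = (o.dx_mode > 0) ? o.dx_age : NA_REAL;
      s_dxmode[j] = o.dx_mode;
      s_stage[j] = (o.dx_mode > 0) ? o.stage + 1 : NA_INTEGER;
      s_death[j] = o.death_age;
      n_stool[j] = o.n_stool; n_col[j] = o.n_col; n_compl[j] = o.n_compl;
      n_det[j] = o.n_det_total;
      first_fu_age[j] = (o.first_fu_det >= 0) ? o.first_fu_age : NA_REAL;
      first_fu_det[j] = (o.first_fu_det >= 0) ? o.first_fu_det : NA_INTEGER;
    }
  }

  DataFrame person;
  if (do_scr) {
    person = DataFrame::create(
      _["id"] = ids, _["eligible"] = elig, _["frailty"] = frailty,
      _["other_cause_death_age"] = ocd, _["n_adenomas"] = n_aden,
      _["dx_age_unscreened"] = u_dx, _["stage_unscreened"] = u_stage,
      _["death_age_unscreened"] = u_death,
      _["dx_age"] = s_dx, _["dx_mode"] = s_dxmode, _["stage"] = s_stage,
      _["death_age"] = s_death, _["n_stool_tests"] = n_stool,
      _["n_colonoscopies"] = n_col, _["n_complications"] = n_compl,
      _["n_adenomas_removed"] = n_det,
      _["first_followup_age"] = first_fu_age,
      _["first_followup_detected"] = first_fu_det);
  } else {
    person = DataFrame::create(
      _["id"] = ids, _["eligible"] = elig, _["frailty"] = frailty,
      _["other_cause_death_age"] = ocd, _["n_adenomas"] = n_aden,
      _["dx_age_unscreened"] = u_dx, _["stage_unscreened"] = u_stage,
      _["death_age_unscreened"] = u_death);
  }
  List out = List::create(
    _["person"] = person,
    _["amr_age"] = seq(0, 100),
    _["amr_exams"] = NumericVector(amr.exams.begin(), amr.exams.end()),
    _["amr_present"] = NumericVector(amr.present.begin(), amr.present.end()),
    _["amr_missed"] = NumericVector(amr.missed.begin(), amr.missed.end()));
  return out;
}
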