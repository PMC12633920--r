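// Yearly-cycle engine for the prosocial-equilibrium society simulator.
//
// The society is passed to and from R as a list of parallel vectors (one
// entry per living agent) plus a few scalars and an opaque RNG state, so
// every stage can also be driven one call at a time from R for testing.
// All randomness inside the engine comes from a xoshiro256++ generator whose
// state travels with the society; composing the exported stage functions in
// the documented order therefore reproduces cpp_run_years() bit for bit.

#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: xoshiro256++ seeded via splitmix64. State is carried in an R numeric
// vector of 8 doubles (each 64-bit word split into two exactly representable
// 32-bit halves) so that it survives list round-trips through R untouched.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];

  static uint64_t splitmix64(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }

  void seed(uint64_t sd) {
    uint64_t x = sd;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(x);
  }

  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }

  uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }

  // uniform in [0, 1)
  double runif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }

  // uniform integer in [0, n)
  uint64_t rint(uint64_t n) {
    // Lemire multiply-shift; bias is negligible for n << 2^64
    return (uint64_t)(((__uint128_t)next() * (__uint128_t)n) >> 64);
  }

  NumericVector pack() const {
    NumericVector out(8);
    for (int i = 0; i < 4; ++i) {
      out[2 * i]     = (double)(uint32_t)(s[i] >> 32);
      out[2 * i + 1] = (double)(uint32_t)(s[i] & 0xFFFFFFFFULL);
    }
    return out;
  }

  void unpack(const NumericVector &v) {
    if (v.size() != 8) stop("rng_state must have 8 elements");
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)v[2 * i];
      uint64_t lo = (uint64_t)v[2 * i + 1];
      s[i] = (hi << 32) | lo;
    }
  }
};

// [[Rcpp::export]]
NumericVector cpp_rng_init(double seed) {
  Xoshiro r;
  r.seed((uint64_t)seed);
  return r.pack();
}

// ---------------------------------------------------------------------------
// Parameters and society state
// ---------------------------------------------------------------------------

struct Params {
  // engine switches
  bool pb_enabled, threats_enabled, threat_stochastic, ci_enabled;
  bool rel_dec_additive, rel_dec_gated, wb_insec_printed;
  // behaviour
  double pb_threshold, pb_inc_rel_self, pb_inc_rel_neigh;
  double pb_dec_insec_self, pb_dec_insec_neigh, pb_wellbeing_cost;
  int num_neigh_benefited;
  double threat_value, rel_dec_perc, parochial_prosociality, radius;
  int pb_min_age, socialisation_max_age, rel_dec_min_age;
  // demography
  double rep_cost, rep_a, rep_b, imp_ins, imp_wb;
  double wb_age_threshold, wb_C, wb_exp1, wb_exp2;
  double wb_insec_th, wb_max_inc, wb_max_dec;
  double marriage_age_diff;
  int marriage_min_age, repro_min_age, repro_max_age;
  std::vector<double> mort_curve;
  // institutions
  double ci_benefit, ci_wb_cost;
  int ci_min_tax_age, ci_start_year;
  // schedule
  int rep_timing;   // 0 = before PB, 1 = after PB, 2 = random
  int ci_timing;    // 0 = before PB, 1 = after PB
  int threat_start_year, horizon, record_interval;
  double space_size, max_pop;
};

static double getd(const List &p, const char *nm) {
  return as<double>(p[nm]);
}
static int geti(const List &p, const char *nm) { return as<int>(p[nm]); }
static bool getb(const List &p, const char *nm) { return as<double>(p[nm]) != 0.0; }

static Params params_from_list(const List &p) {
  Params q;
  q.pb_enabled = getb(p, "pb_enabled");
  q.threats_enabled = getb(p, "threats_enabled");
  q.threat_stochastic = getb(p, "threat_stochastic");
  q.ci_enabled = getb(p, "ci_enabled");
  q.rel_dec_additive = getb(p, "rel_dec_additive");
  q.rel_dec_gated = getb(p, "rel_dec_gated");
  q.wb_insec_printed = getb(p, "wb_insec_printed");
  q.pb_threshold = getd(p, "pb_threshold");
  q.pb_inc_rel_self = getd(p, "pb_inc_rel_self");
  q.pb_inc_rel_neigh = getd(p, "pb_inc_rel_neigh");
  q.pb_dec_insec_self = getd(p, "pb_dec_insec_self");
  q.pb_dec_insec_neigh = getd(p, "pb_dec_insec_neigh");
  q.pb_wellbeing_cost = getd(p, "pb_wellbeing_cost");
  q.num_neigh_benefited = geti(p, "num_neigh_benefited");
  q.threat_value = getd(p, "threat_value");
  q.rel_dec_perc = getd(p, "rel_dec_perc");
  q.parochial_prosociality = getd(p, "parochial_prosociality");
  q.radius = getd(p, "radius_local_area");
  q.pb_min_age = geti(p, "pb_min_age");
  q.socialisation_max_age = geti(p, "socialisation_max_age");
  q.rel_dec_min_age = geti(p, "rel_dec_min_age");
  q.rep_cost = getd(p, "rep_cost");
  q.rep_a = getd(p, "rep_mid_threshold");
  q.rep_b = getd(p, "rep_curve_shape");
  q.imp_ins = getd(p, "importance_insec");
  q.imp_wb = getd(p, "importance_wb");
  q.wb_age_threshold = getd(p, "wb_age_threshold");
  q.wb_C = getd(p, "wb_intercept_C");
  q.wb_exp1 = getd(p, "wb_exp_gain");
  q.wb_exp2 = getd(p, "wb_exp_loss");
  q.wb_insec_th = getd(p, "wb_insec_threshold");
  q.wb_max_inc = getd(p, "wb_max_inc");
  q.wb_max_dec = getd(p, "wb_max_dec");
  q.marriage_age_diff = getd(p, "marriage_age_diff");
  q.marriage_min_age = geti(p, "marriage_min_age");
  q.repro_min_age = geti(p, "repro_min_age");
  q.repro_max_age = geti(p, "repro_max_age");
  q.mort_curve = as<std::vector<double> >(p["mortality_curve"]);
  q.ci_benefit = getd(p, "ci_benefit");
  q.ci_wb_cost = getd(p, "ci_wb_cost");
  q.ci_min_tax_age = geti(p, "ci_min_tax_age");
  q.ci_start_year = geti(p, "ci_start_year");
  q.rep_timing = geti(p, "rep_timing");
  q.ci_timing = geti(p, "ci_timing");
  q.threat_start_year = geti(p, "threat_start_year");
  q.horizon = geti(p, "horizon");
  q.record_interval = geti(p, "record_interval");
  q.space_size = getd(p, "space_size");
  q.max_pop = getd(p, "max_pop");
  return q;
}

struct Society {
  std::vector<int> id, age, partner;       // partner holds the partner's id, 0 = none
  std::vector<char> female, married;
  std::vector<double> rel, wb, ins, sens, anx, x, y;
  int year, next_id;
  double space_size;
  Xoshiro rng;

  size_t n() const { return id.size(); }
};

static Society soc_from_list(const List &s) {
  Society z;
  z.id = as<std::vector<int> >(s["id"]);
  z.age = as<std::vector<int> >(s["age"]);
  z.partner = as<std::vector<int> >(s["partner"]);
  IntegerVector fem = s["female"], mar = s["married"];
  z.female.assign(fem.begin(), fem.end());
  z.married.assign(mar.begin(), mar.end());
  z.rel = as<std::vector<double> >(s["religiosity"]);
  z.wb = as<std::vector<double> >(s["wellbeing"]);
  z.ins = as<std::vector<double> >(s["insecurity"]);
  z.sens = as<std::vector<double> >(s["sensitivity"]);
  z.anx = as<std::vector<double> >(s["anxiety"]);
  z.x = as<std::vector<double> >(s["x"]);
  z.y = as<std::vector<double> >(s["y"]);
  z.year = as<int>(s["year"]);
  z.next_id = as<int>(s["next_id"]);
  z.space_size = as<double>(s["space_size"]);
  z.rng.unpack(s["rng_state"]);
  size_t n = z.id.size();
  if (z.age.size() != n || z.rel.size() != n || z.wb.size() != n ||
      z.ins.size() != n || z.sens.size() != n || z.anx.size() != n ||
      z.x.size() != n || z.y.size() != n || z.partner.size() != n ||
      z.female.size() != n || z.married.size() != n)
    stop("society vectors have inconsistent lengths");
  return z;
}

static List soc_to_list(const Society &z) {
  return List::create(
    _["id"] = wrap(z.id), _["age"] = wrap(z.age),
    _["female"] = IntegerVector(z.female.begin(), z.female.end()),
    _["married"] = IntegerVector(z.married.begin(), z.married.end()),
    _["partner"] = wrap(z.partner),
    _["religiosity"] = wrap(z.rel), _["wellbeing"] = wrap(z.wb),
    _["insecurity"] = wrap(z.ins), _["sensitivity"] = wrap(z.sens),
    _["anxiety"] = wrap(z.anx),
    _["x"] = wrap(z.x), _["y"] = wrap(z.y),
    _["year"] = z.year, _["next_id"] = z.next_id,
    _["space_size"] = z.space_size,
    _["rng_state"] = z.rng.pack());
}

static inline double clamp01(double v) {
  return v < 0.0 ? 0.0 : (v > 1.0 ? 1.0 : v);
}

static double polyval(const std::vector<double> &c, double v) {
  double acc = 0.0;
  for (size_t k = c.size(); k-- > 0;) acc = acc * v + c[k];
  return acc;
}

// id -> index lookup (ids are dense, assigned sequentially from 1). Entries
// of dead ids go stale, but partner ids always reference living agents, so
// only entries written in the same pass are ever read back.
static void build_id_map(const Society &z, std::vector<int> &map) {
  if (map.size() < (size_t)z.next_id + 1) map.resize(z.next_id + 1, -1);
  for (size_t i = 0; i < z.n(); ++i) map[z.id[i]] = (int)i;
}

struct Scratch {
  std::vector<int> idmap;
};

// ---------------------------------------------------------------------------
// Stages
// ---------------------------------------------------------------------------

// Marriage formation. Eligible = single and age strictly above the minimum.
// Eligible agents are visited in shuffled order; each unmatched agent picks a
// partner uniformly among unmatched opposite-gender eligibles whose age
// differs by at most marriage_age_diff. Age-bucketed candidate lists keep the
// scan linear in the number of singles.
static void stage_marriage(Society &z, const Params &p) {
  const int AMAX = 220;
  size_t n = z.n();
  std::vector<int> elig;
  elig.reserve(n / 4);
  for (size_t i = 0; i < n; ++i)
    if (!z.married[i] && z.age[i] > p.marriage_min_age) elig.push_back((int)i);
  if (elig.size() < 2) return;

  // Fisher-Yates shuffle of the visiting order
  for (size_t i = elig.size() - 1; i > 0; --i) {
    size_t j = z.rng.rint(i + 1);
    std::swap(elig[i], elig[j]);
  }

  // per-gender, per-age buckets of unmatched candidates; pos[i] = index of
  // agent i inside its bucket, for O(1) swap-removal
  std::vector<std::vector<int> > bucket[2];
  bucket[0].assign(AMAX + 1, std::vector<int>());
  bucket[1].assign(AMAX + 1, std::vector<int>());
  std::vector<int> pos(n, -1);
  for (size_t k = 0; k < elig.size(); ++k) {
    int i = elig[k];
    int a = z.age[i] > AMAX ? AMAX : z.age[i];
    int g = z.female[i] ? 1 : 0;
    pos[i] = (int)bucket[g][a].size();
    bucket[g][a].push_back(i);
  }
  auto remove_from_bucket = [&](int i) {
    int a = z.age[i] > AMAX ? AMAX : z.age[i];
    int g = z.female[i] ? 1 : 0;
    std::vector<int> &b = bucket[g][a];
    int pi = pos[i];
    int last = b.back();
    b[pi] = last;
    pos[last] = pi;
    b.pop_back();
    pos[i] = -1;
  };

  int d = (int)std::floor(p.marriage_age_diff);
  for (size_t k = 0; k < elig.size(); ++k) {
    int i = elig[k];
    if (z.married[i]) continue;
    int g_other = z.female[i] ? 0 : 1;
    int a = z.age[i] > AMAX ? AMAX : z.age[i];
    int lo = a - d < 0 ? 0 : a - d;
    int hi = a + d > AMAX ? AMAX : a + d;
    size_t total = 0;
    for (int aa = lo; aa <= hi; ++aa) total += bucket[g_other][aa].size();
    if (total == 0) continue;
    size_t t = z.rng.rint(total);
    int j = -1;
    for (int aa = lo; aa <= hi; ++aa) {
      size_t m = bucket[g_other][aa].size();
      if (t < m) { j = bucket[g_other][aa][t]; break; }
      t -= m;
    }
    // marry i and j
    remove_from_bucket(i);
    remove_from_bucket(j);
    z.married[i] = 1; z.married[j] = 1;
    z.partner[i] = z.id[j]; z.partner[j] = z.id[i];
  }
}

static void stage_threats(Society &z, double value) {
  for (size_t i = 0; i < z.n(); ++i) {
    z.ins[i] = std::min(1.0, z.ins[i] + value);
    z.anx[i] = z.ins[i] * z.sens[i];
  }
}

static void stage_ci(Society &z, const Params &p) {
  for (size_t i = 0; i < z.n(); ++i) {
    z.ins[i] = std::max(0.0, z.ins[i] - p.ci_benefit);
    if (z.age[i] > p.ci_min_tax_age)
      z.wb[i] = std::max(0.0, z.wb[i] - p.ci_wb_cost);
    z.anx[i] = z.ins[i] * z.sens[i];
  }
}

// Reproduction: every married female of reproductive age gets one yearly
// opportunity; probability is a sigmoid of the weighted average of the two
// partners' wellbeing and insecurity. Both parents pay rep_cost of their own
// wellbeing; the offspring starts with the sum of the two losses and copies
// religiosity, insecurity and sensitivity from one parent chosen at random.
static int stage_reproduction(Society &z, const Params &p, Scratch &sc) {
  size_t n = z.n();
  std::vector<int> &idmap = sc.idmap;
  build_id_map(z, idmap);
  int births = 0;
  double wsum = p.imp_wb + p.imp_ins;
  for (size_t i = 0; i < n; ++i) {
    if (!z.female[i] || !z.married[i]) continue;
    if (z.age[i] < p.repro_min_age || z.age[i] > p.repro_max_age) continue;
    int j = idmap[z.partner[i]];
    if (j < 0) continue;
    double avg_wb = 0.5 * (z.wb[i] + z.wb[j]);
    double avg_ins = 0.5 * (z.ins[i] + z.ins[j]);
    double xx = (avg_wb * p.imp_wb + avg_ins * p.imp_ins) / wsum;
    double prob = 1.0 / (1.0 + std::exp(-p.rep_b * (xx - p.rep_a)));
    if (z.rng.runif() >= prob) continue;
    double loss_i = p.rep_cost * z.wb[i];
    double loss_j = p.rep_cost * z.wb[j];
    z.wb[i] -= loss_i;
    z.wb[j] -= loss_j;
    size_t par = (z.rng.runif() < 0.5) ? i : (size_t)j;
    z.id.push_back(z.next_id++);
    z.age.push_back(0);
    z.female.push_back(z.rng.runif() < 0.5 ? 1 : 0);
    z.married.push_back(0);
    z.partner.push_back(0);
    z.rel.push_back(z.rel[par]);
    z.wb.push_back(clamp01(loss_i + loss_j));
    z.ins.push_back(z.ins[par]);
    z.sens.push_back(z.sens[par]);
    z.anx.push_back(z.ins[par] * z.sens[par]);
    z.x.push_back(z.rng.runif() * z.space_size);
    z.y.push_back(z.rng.runif() * z.space_size);
    ++births;
  }
  return births;
}

// Spatial grid over the square, cell size = neighbourhood radius, CSR layout.
struct Grid {
  int ncell;
  double cell;
  std::vector<int> start, items, cellof;

  void build(const Society &z, double radius) {
    cell = radius;
    ncell = (int)std::ceil(z.space_size / cell);
    if (ncell < 1) ncell = 1;
    size_t n = z.n();
    cellof.resize(n);
    std::vector<int> cnt(ncell * ncell + 1, 0);
    for (size_t i = 0; i < n; ++i) {
      int cx = (int)(z.x[i] / cell); if (cx >= ncell) cx = ncell - 1; if (cx < 0) cx = 0;
      int cy = (int)(z.y[i] / cell); if (cy >= ncell) cy = ncell - 1; if (cy < 0) cy = 0;
      cellof[i] = cy * ncell + cx;
      ++cnt[cellof[i] + 1];
    }
    start.assign(ncell * ncell + 1, 0);
    for (int c = 0; c < ncell * ncell; ++c) start[c + 1] = start[c] + cnt[c + 1];
    items.resize(n);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (size_t i = 0; i < n; ++i) items[fill[cellof[i]]++] = (int)i;
  }
};

// Prosocial behaviour stage. Agents are visited in a freshly shuffled order;
// anxiety is recomputed on visit, so relief granted earlier in the year can
// prevent later acts. Beneficiaries are drawn uniformly without replacement
// from the eligible set (within radius, parochial religiosity rule) using
// rejection sampling over the 3x3 grid block, with a full enumeration
// fallback so uniformity holds even when eligibles are scarce.
static int stage_pb(Society &z, const Params &p) {
  size_t n = z.n();
  if (n == 0) return 0;
  // no agent can trigger while all insecurity (hence anxiety) is zero,
  // which holds exactly throughout the pre-threat stabilisation era
  bool any_ins = false;
  for (size_t i = 0; i < n; ++i) if (z.ins[i] > 0.0) { any_ins = true; break; }
  if (!any_ins) {
    for (size_t i = 0; i < n; ++i) z.anx[i] = 0.0;
    return 0;
  }
  std::vector<int> order(n);
  for (size_t i = 0; i < n; ++i) order[i] = (int)i;
  for (size_t i = n - 1; i > 0; --i) {
    size_t j = z.rng.rint(i + 1);
    std::swap(order[i], order[j]);
  }
  Grid grid;
  grid.build(z, p.radius);
  const double r2 = p.radius * p.radius;
  int pb_count = 0;
  std::vector<int> chosen;
  std::vector<int> pool_cells;
  std::vector<int> elig;
  chosen.reserve(p.num_neigh_benefited + 1);

  for (size_t oi = 0; oi < n; ++oi) {
    int i = order[oi];
    z.anx[i] = z.ins[i] * z.sens[i];
    if (z.age[i] < p.pb_min_age) continue;
    if (!(z.anx[i] * z.rel[i] > p.pb_threshold)) continue;
    ++pb_count;
    double rel_perf = z.rel[i];
    double rel_min = rel_perf - p.parochial_prosociality;
    // performer effects first
    z.ins[i] = std::max(0.0, z.ins[i] - p.pb_dec_insec_self);
    z.wb[i] = std::max(0.0, z.wb[i] - p.pb_wellbeing_cost);
    if (z.age[i] <= p.socialisation_max_age)
      z.rel[i] = std::min(1.0, z.rel[i] + p.pb_inc_rel_self);
    z.anx[i] = z.ins[i] * z.sens[i];
    int k = p.num_neigh_benefited;
    if (k <= 0) continue;

    // candidate pool: the 3x3 block of grid cells around the performer
    int cx = grid.cellof[i] % grid.ncell, cy = grid.cellof[i] / grid.ncell;
    pool_cells.clear();
    size_t pool_total = 0;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = cy + dy;
      if (yy < 0 || yy >= grid.ncell) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = cx + dx;
        if (xx < 0 || xx >= grid.ncell) continue;
        int c = yy * grid.ncell + xx;
        if (grid.start[c + 1] > grid.start[c]) {
          pool_cells.push_back(c);
          pool_total += grid.start[c + 1] - grid.start[c];
        }
      }
    }
    if (pool_total <= 1) continue;

    chosen.clear();
    auto eligible = [&](int j) {
      if (j == i) return false;
      double dx = z.x[j] - z.x[i], dy = z.y[j] - z.y[i];
      if (dx * dx + dy * dy > r2) return false;
      return z.rel[j] > rel_min;
    };
    auto already = [&](int j) {
      for (size_t t = 0; t < chosen.size(); ++t) if (chosen[t] == j) return true;
      return false;
    };

    int tries = 0, max_tries = 6 * k + 20;
    if ((int)pool_total <= max_tries) tries = max_tries;  // enumerate directly
    while ((int)chosen.size() < k && tries < max_tries) {
      ++tries;
      size_t t = z.rng.rint(pool_total);
      int j = -1;
      for (size_t c = 0; c < pool_cells.size(); ++c) {
        size_t m = grid.start[pool_cells[c] + 1] - grid.start[pool_cells[c]];
        if (t < m) { j = grid.items[grid.start[pool_cells[c]] + t]; break; }
        t -= m;
      }
      if (eligible(j) && !already(j)) chosen.push_back(j);
    }
    if ((int)chosen.size() < k) {
      // fallback: enumerate the remaining eligibles and draw exactly
      elig.clear();
      for (size_t c = 0; c < pool_cells.size(); ++c)
        for (int t = grid.start[pool_cells[c]]; t < grid.start[pool_cells[c] + 1]; ++t) {
          int j = grid.items[t];
          if (eligible(j) && !already(j)) elig.push_back(j);
        }
      int need = k - (int)chosen.size();
      int avail = (int)elig.size();
      for (int t = 0; t < need && t < avail; ++t) {
        size_t pick = t + z.rng.rint(avail - t);
        std::swap(elig[t], elig[pick]);
        chosen.push_back(elig[t]);
      }
    }
    for (size_t t = 0; t < chosen.size(); ++t) {
      int j = chosen[t];
      z.ins[j] = std::max(0.0, z.ins[j] - p.pb_dec_insec_neigh);
      if (z.age[j] <= p.socialisation_max_age)
        z.rel[j] = std::min(1.0, z.rel[j] + p.pb_inc_rel_neigh);
      z.anx[j] = z.ins[j] * z.sens[j];
    }
  }
  return pb_count;
}

static inline double wb_age_delta_one(double age, const Params &p) {
  double u = (age - p.wb_age_threshold) / (100.0 - p.wb_age_threshold);
  if (age >= p.wb_age_threshold)
    return p.wb_C - 4.0 * p.wb_C * std::pow(u, p.wb_exp2);
  return p.wb_C + 4.0 * p.wb_C * std::pow(-u, p.wb_exp1);
}

static inline double wb_insec_delta_one(double ins, const Params &p) {
  if (ins <= p.wb_insec_th) {
    if (p.wb_insec_printed)
      return p.wb_max_inc + ins * p.wb_max_inc / p.wb_insec_th;
    return p.wb_max_inc * (1.0 - ins / p.wb_insec_th);
  }
  return -p.wb_max_dec * (ins - p.wb_insec_th) / (1.0 - p.wb_insec_th);
}

static void stage_wb_age(Society &z, const Params &p) {
  // ages are small integers: tabulate the delta once per year instead of
  // paying two pow() calls per agent
  double table[201];
  for (int a = 0; a <= 200; ++a)
    table[a] = wb_age_delta_one((double)(a <= 100 ? a : 100), p);
  for (size_t i = 0; i < z.n(); ++i) {
    int a = z.age[i] < 0 ? 0 : (z.age[i] > 200 ? 200 : z.age[i]);
    z.wb[i] = clamp01(z.wb[i] + table[a]);
  }
}

static void stage_wb_insec(Society &z, const Params &p) {
  for (size_t i = 0; i < z.n(); ++i)
    z.wb[i] = clamp01(z.wb[i] + wb_insec_delta_one(z.ins[i], p));
}

static void stage_decay(Society &z, const Params &p) {
  for (size_t i = 0; i < z.n(); ++i) {
    if (z.age[i] >= 26 || z.age[i] < p.rel_dec_min_age) continue;
    if (p.rel_dec_additive)
      z.rel[i] = std::max(0.0, z.rel[i] - p.rel_dec_perc);
    else
      z.rel[i] = z.rel[i] * (1.0 - p.rel_dec_perc);
  }
}

static int stage_mortality(Society &z, const Params &p, Scratch &sc) {
  size_t n = z.n();
  if (n == 0) return 0;
  std::vector<char> dead(n, 0);
  int deaths = 0;
  for (size_t i = 0; i < n; ++i) {
    double prob = clamp01(polyval(p.mort_curve, clamp01(z.wb[i])));
    if (z.rng.runif() < prob) { dead[i] = 1; ++deaths; }
  }
  if (deaths == 0) return 0;
  std::vector<int> &idmap = sc.idmap;
  build_id_map(z, idmap);
  // widow survivors whose partner died
  for (size_t i = 0; i < n; ++i) {
    if (dead[i] || !z.married[i]) continue;
    int j = idmap[z.partner[i]];
    if (j >= 0 && dead[j]) { z.married[i] = 0; z.partner[i] = 0; }
  }
  size_t w = 0;
  for (size_t i = 0; i < n; ++i) {
    if (dead[i]) continue;
    if (w != i) {
      z.id[w] = z.id[i]; z.age[w] = z.age[i]; z.partner[w] = z.partner[i];
      z.female[w] = z.female[i]; z.married[w] = z.married[i];
      z.rel[w] = z.rel[i]; z.wb[w] = z.wb[i]; z.ins[w] = z.ins[i];
      z.sens[w] = z.sens[i]; z.anx[w] = z.anx[i];
      z.x[w] = z.x[i]; z.y[w] = z.y[i];
    }
    ++w;
  }
  z.id.resize(w); z.age.resize(w); z.partner.resize(w);
  z.female.resize(w); z.married.resize(w);
  z.rel.resize(w); z.wb.resize(w); z.ins.resize(w);
  z.sens.resize(w); z.anx.resize(w); z.x.resize(w); z.y.resize(w);
  return deaths;
}

// One full year. Returns (births, deaths, pb_count).
static void step_one_year(Society &z, const Params &p, Scratch &sc,
                          int &births, int &deaths, int &pb_count) {
  int y = z.year + 1;
  births = deaths = pb_count = 0;
  stage_marriage(z, p);
  if (p.threats_enabled && y >= p.threat_start_year) {
    double tv = p.threat_value;
    if (p.threat_stochastic) tv = z.rng.runif() * 2.0 * p.threat_value;
    stage_threats(z, tv);
  }
  bool ci_on = p.ci_enabled && y >= p.ci_start_year;
  if (ci_on && p.ci_timing == 0) stage_ci(z, p);
  int rep_now = p.rep_timing;
  if (rep_now == 2) rep_now = (z.rng.runif() < 0.5) ? 0 : 1;
  if (rep_now == 0) births += stage_reproduction(z, p, sc);
  if (p.pb_enabled) pb_count = stage_pb(z, p);
  if (ci_on && p.ci_timing == 1) stage_ci(z, p);
  if (rep_now == 1) births += stage_reproduction(z, p, sc);
  stage_wb_age(z, p);
  stage_wb_insec(z, p);
  // the decay of religiosity belongs to the sensitivity-analysis mechanism
  // set: by default it switches on with threats, not during stabilisation
  if (!p.rel_dec_gated || (p.threats_enabled && y >= p.threat_start_year))
    stage_decay(z, p);
  deaths = stage_mortality(z, p, sc);
  for (size_t i = 0; i < z.n(); ++i) ++z.age[i];
  z.year = y;
}

static void record_row(const Society &z, NumericMatrix &traj, int row,
                       int births, int deaths, int pb_count) {
  size_t n = z.n();
  double mr = NA_REAL, mi = NA_REAL, mw = NA_REAL;
  if (n > 0) {
    double sr = 0, si = 0, sw = 0;
    for (size_t i = 0; i < n; ++i) { sr += z.rel[i]; si += z.ins[i]; sw += z.wb[i]; }
    mr = sr / n; mi = si / n; mw = sw / n;
  }
  traj(row, 0) = z.year;
  traj(row, 1) = (double)n;
  traj(row, 2) = mr;
  traj(row, 3) = mi;
  traj(row, 4) = mw;
  traj(row, 5) = births;
  traj(row, 6) = deaths;
  traj(row, 7) = pb_count;
}

// [[Rcpp::export]]
List cpp_run_years(List society, List params, int n_years,
                   bool return_society = false) {
  Society z = soc_from_list(society);
  Params p = params_from_list(params);
  NumericMatrix traj(n_years, 8);
  Scratch sc;
  int start_year = z.year;
  bool halted = false;   // population cap reached
  int row = 0;
  for (; row < n_years; ++row) {
    if (z.n() == 0 || halted) break;
    int b, d, pb;
    step_one_year(z, p, sc, b, d, pb);
    record_row(z, traj, row, b, d, pb);
    if (p.max_pop > 0 && (double)z.n() > p.max_pop) halted = true;
  }
  // pad the remaining years: zeros after extinction, last values after a halt
  for (int r = row; r < n_years; ++r) {
    z.year = start_year + r + 1;
    if (halted && row > 0) {
      traj(r, 0) = z.year;
      for (int cch = 1; cch < 5; ++cch) traj(r, cch) = traj(row - 1, cch);
      traj(r, 5) = NA_REAL; traj(r, 6) = NA_REAL; traj(r, 7) = NA_REAL;
    } else {
      traj(r, 0) = z.year;
      traj(r, 1) = 0;
      traj(r, 2) = NA_REAL; traj(r, 3) = NA_REAL; traj(r, 4) = NA_REAL;
      traj(r, 5) = 0; traj(r, 6) = 0; traj(r, 7) = 0;
    }
  }
  colnames(traj) = CharacterVector::create(
    "year", "pop", "mean_rel", "mean_ins", "mean_wb", "births", "deaths",
    "pb_count");
  List out = List::create(_["trajectory"] = traj, _["capped"] = halted,
                          _["final_pop"] = (double)z.n());
  if (return_society) out["society"] = soc_to_list(z);
  return out;
}

// ---------------------------------------------------------------------------
// Exported single-stage wrappers (the R-level operation surface)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_form_marriages(List society, List params) {
  Society z = soc_from_list(society);
  Params p = params_from_list(params);
  stage_marriage(z, p);
  return soc_to_list(z);
}

// [[Rcpp::export]]
List cpp_apply_threats(List society, double threat_value) {
  Society z = soc_from_list(society);
  stage_threats(z, threat_value);
  return soc_to_list(z);
}

// [[Rcpp::export]]
List cpp_apply_ci(List society, List params) {
  Society z = soc_from_list(society);
  Params p = params_from_list(params);
  stage_ci(z, p);
  return soc_to_list(z);
}

// [[Rcpp::export]]
List cpp_reproduction(List society, List params) {
  Society z = soc_from_list(society);
  Params p = params_from_list(params);
  Scratch sc;
  int births = stage_reproduction(z, p, sc);
  List out = soc_to_list(z);
  out["births"] = births;
  return out;
}

// [[Rcpp::export]]
List cpp_pb_stage(List society, List params) {
  Society z = soc_from_list(society);
  Params p = params_from_list(params);
  int pb = stage_pb(z, p);
  List out = soc_to_list(z);
  out["pb_count"] = pb;
  return out;
}

// [[Rcpp::export]]
List cpp_wb_update(List society, List params) {
  Society z = soc_from_list(society);
  Params p = params_from_list(params);
  stage_wb_age(z, p);
  stage_wb_insec(z, p);
  return soc_to_list(z);
}

// [[Rcpp::export]]
List cpp_decay_religiosity(List society, List params) {
  Society z = soc_from_list(society);
  Params p = params_from_list(params);
  stage_decay(z, p);
  return soc_to_list(z);
}

// [[Rcpp::export]]
List cpp_apply_mortality(List society, List params) {
  Society z = soc_from_list(society);
  Params p = params_from_list(params);
  Scratch sc;
  int deaths = stage_mortality(z, p, sc);
  List out = soc_to_list(z);
  out["deaths"] = deaths;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_wb_age_delta(NumericVector age, List params) {
  Params p = params_from_list(params);
  NumericVector out(age.size());
  for (int i = 0; i < age.size(); ++i) out[i] = wb_age_delta_one(age[i], p);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_wb_insec_delta(NumericVector ins, List params) {
  Params p = params_from_list(params);
  NumericVector out(ins.size());
  for (int i = 0; i < ins.size(); ++i) out[i] = wb_insec_delta_one(ins[i], p);
  return out;
}
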