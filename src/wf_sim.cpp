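// Forward-time Wright-Fisher simulator with recombination, migration and
// optional additive selection on a single focal variant.
//
// Populations are vectors of haplotypes; a haplotype is the vector of
// mutation ids it carries, kept sorted by genomic position via an
// id -> position registry (ids are 16-bit, recycled when a mutation is lost
// or fixed, which bounds the number of simultaneously segregating mutations
// at 65,535 -- far above anything these models produce).  Mutation follows
// the infinite-sites model on the integer bp grid: a position already
// occupied by a segregating mutation is redrawn.  Fixed mutations are
// stripped periodically (they are invisible in a polymorphism sample).
//
// Per-generation crossover and mutation events are drawn once as
// Poisson(2 N rate L) totals and scattered uniformly over gametes, which is
// distributionally identical to per-gamete Poisson draws but far cheaper.
//
// All parameters arriving here are already rescaled (see R/simgen.R): the
// caller divides population sizes and times by lambda and multiplies
// mutation, recombination, migration and growth rates by lambda, which
// preserves theta = 4*N*mu, rho = 4*N*r and times in units of 2N
// generations.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
#include <cmath>

namespace {

// xoshiro256++ with splitmix64 seeding: fast, reproducible across platforms.
struct RNG {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t& x) {
    x += 0x9E3779B97F4A7C15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t v) {
    uint64_t x = v;
    for (int i = 0; i < 4; ++i) s[i] = splitmix(x);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int below(int n) {
    return (int)(((__uint128_t)next() * (uint64_t)n) >> 64);
  }
};

// Knuth Poisson sampler, split for large means to keep the uniform product
// away from underflow.
int rpois_mean(RNG& rng, double mean) {
  int k = 0;
  while (mean > 400.0) {
    double part = 200.0;
    double expm = std::exp(-part);
    double p = rng.unif();
    int kk = 0;
    while (p > expm) { ++kk; p *= rng.unif(); }
    k += kk;
    mean -= part;
  }
  double expm = std::exp(-mean);
  double p = rng.unif();
  while (p > expm) { ++k; p *= rng.unif(); }
  return k;
}

typedef uint16_t MutId;
typedef std::vector<MutId> Hap;
typedef std::vector<Hap> Pop;

const int MAXMUT = 65536;

struct State {
  std::vector<Pop> pops;        // slot 0 = AFR/ancestral, 1 = B/EUR, 2 = ASN
  std::vector<uint8_t> occ;     // position occupied by a live mutation
  std::vector<uint8_t> alive;   // id allocated
  std::vector<int> mut_pos;     // id -> bp position
  std::vector<MutId> free_ids;  // recycling stack
  RNG rng;

  int alloc_mut(int pos) {
    if (free_ids.empty())
      Rcpp::stop("too many segregating mutations; shrink the region or raise lambda");
    MutId id = free_ids.back();
    free_ids.pop_back();
    alive[id] = 1;
    mut_pos[id] = pos;
    occ[pos] = 1;
    return id;
  }
  void release_mut(MutId id) {
    occ[mut_pos[id]] = 0;
    alive[id] = 0;
    free_ids.push_back(id);
  }
};

struct Params {
  int L;
  int npop;
  int N_anc, N_af, N_b, N_eu0, N_as0;
  double g_eu, g_as;          // per-generation growth rates (rescaled)
  int T_af, T_b, T_euas;      // rescaled generations before present
  double m_af_b, m_af_eu, m_af_as, m_eu_as;  // rescaled per-gen fractions
  double mu, rec;             // per bp per rescaled generation
  int burnin;
  // sweep
  bool has_sweep;
  int sel_pop;                // 0/1/2
  int focal;                  // requested bp position (0-based)
  double target, band;
  int sweep_start, sweep_end; // rescaled generations ago
  double s_init;
  int max_attempts;
};

// scratch reused across generations
struct Scratch {
  std::vector<Pop> nxt;
  std::vector<uint8_t> ev_rec, ev_mut;  // per-gamete event counts
  std::vector<int> touched;
  std::vector<int> cnt;                 // per-id occurrence counts
  Scratch() : nxt(3), cnt(MAXMUT, 0) {}
};

inline void active_slots(const Params& P, int g, bool alive[3]) {
  alive[0] = true;
  if (P.npop == 1) {
    alive[1] = alive[2] = false;
  } else {
    alive[1] = (g <= P.T_b);          // B before the EU/AS split, then EUR
    alive[2] = (g <= P.T_euas);       // ASN
  }
}

inline int pop_size(const Params& P, int slot, int g) {
  if (P.npop == 1) return P.N_anc;
  if (slot == 0) return (g > P.T_af) ? P.N_anc : P.N_af;
  if (slot == 1) {
    if (g > P.T_euas) return P.N_b;
    return std::max(2, (int)std::lround(P.N_eu0 * std::exp(P.g_eu * (P.T_euas - g))));
  }
  return std::max(2, (int)std::lround(P.N_as0 * std::exp(P.g_as * (P.T_euas - g))));
}

// slot under selection at g generations ago (ancestor of the selected pop)
inline int sel_slot_at(const Params& P, int g) {
  if (P.sel_pop == 0) return 0;
  if (g > P.T_b) return 0;       // before the out-of-Africa split
  if (g > P.T_euas) return 1;    // Eurasian ancestor B
  return P.sel_pop;
}

struct PosLess {
  const std::vector<int>& mp;
  explicit PosLess(const std::vector<int>& m) : mp(m) {}
  bool operator()(MutId id, int pos) const { return mp[id] < pos; }
};

inline bool carries(const Hap& h, const std::vector<int>& mp, MutId id) {
  Hap::const_iterator it =
      std::lower_bound(h.begin(), h.end(), mp[id], PosLess(mp));
  return it != h.end() && *it == id;
}

inline void make_gamete(State& st, const Params& P, const Hap& a, const Hap& b,
                        int k, int m, bool first_a, Hap& out,
                        std::vector<int>& brk) {
  out.clear();
  if (k == 0) {
    const Hap& src = first_a ? a : b;
    out.assign(src.begin(), src.end());
  } else {
    brk.clear();
    for (int i = 0; i < k; ++i) brk.push_back(st.rng.below(P.L - 1) + 1);
    std::sort(brk.begin(), brk.end());
    const Hap* cur = first_a ? &a : &b;
    const Hap* oth = first_a ? &b : &a;
    PosLess less(st.mut_pos);
    int start = 0;
    for (int bi = 0; bi <= k; ++bi) {
      int hi = (bi < k) ? brk[bi] : P.L;
      Hap::const_iterator lo = std::lower_bound(cur->begin(), cur->end(), start, less);
      Hap::const_iterator up = std::lower_bound(lo, cur->end(), hi, less);
      out.insert(out.end(), lo, up);
      std::swap(cur, oth);
      start = hi;
    }
  }
  for (int i = 0; i < m; ++i) {
    int pos = -1;
    for (int tries = 0; tries < 1000000; ++tries) {
      int cand = st.rng.below(P.L);
      if (!st.occ[cand]) { pos = cand; break; }
    }
    if (pos < 0) Rcpp::stop("infinite-sites grid saturated; increase region_bp or lower mu");
    MutId id = (MutId)st.alloc_mut(pos);
    out.insert(std::lower_bound(out.begin(), out.end(), pos, PosLess(st.mut_pos)), id);
  }
}

// strip mutations fixed in every haplotype; release lost ids
void purge(State& st, const Params& P, Scratch& sc, int protect_id) {
  std::vector<int>& cnt = sc.cnt;
  size_t tot = 0;
  for (size_t p = 0; p < st.pops.size(); ++p)
    for (size_t h = 0; h < st.pops[p].size(); ++h) {
      const Hap& hap = st.pops[p][h];
      for (size_t i = 0; i < hap.size(); ++i) ++cnt[hap[i]];
      ++tot;
    }
  std::vector<uint8_t> drop(MAXMUT, 0);
  bool any_drop = false;
  for (int id = 0; id < MAXMUT; ++id) {
    if (!st.alive[id]) { cnt[id] = 0; continue; }
    if (cnt[id] == 0) {
      st.release_mut((MutId)id);
    } else if ((size_t)cnt[id] == tot && id != protect_id) {
      drop[id] = 1;
      st.release_mut((MutId)id);
      any_drop = true;
    }
    cnt[id] = 0;
  }
  if (any_drop) {
    for (size_t p = 0; p < st.pops.size(); ++p)
      for (size_t h = 0; h < st.pops[p].size(); ++h) {
        Hap& hap = st.pops[p][h];
        hap.erase(std::remove_if(hap.begin(), hap.end(),
                                 [&](MutId id) { return drop[id] != 0; }),
                  hap.end());
      }
  }
}

// advance one generation: build offspring for gens_ago = g_new from state at
// g_new + 1.  sel_active: additive selection with coefficient s in slot
// sel_slot (fitness 1, 1+s, 1+2s by focal genotype, focal mutation id
// focal_id).
void step(State& st, const Params& P, int g_new, bool sel_active, int sel_slot,
          double s, int focal_id, Scratch& sc, std::vector<int>& brk) {
  bool alive_old[3], alive_new[3];
  active_slots(P, g_new + 1, alive_old);
  active_slots(P, g_new, alive_new);

  // founder sources for slots that come alive this generation
  int source_of[3] = {0, 1, 2};
  if (alive_new[1] && !alive_old[1]) source_of[1] = 0;       // B founded from AFR
  if (alive_new[2] && !alive_old[2]) { source_of[1] = 1; source_of[2] = 1; }

  // migration: rows = destination slot, cols = source slot (old generation)
  double mig[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  if (P.npop == 3 && g_new < P.T_b) {
    if (g_new >= P.T_euas) {
      mig[0][1] = P.m_af_b; mig[1][0] = P.m_af_b;
    } else {
      mig[0][1] = P.m_af_eu; mig[1][0] = P.m_af_eu;
      mig[0][2] = P.m_af_as; mig[2][0] = P.m_af_as;
      mig[1][2] = P.m_eu_as; mig[2][1] = P.m_eu_as;
    }
  }

  // fitness lookup for the selected slot's previous generation
  std::vector<uint8_t> geno;
  double wmax = 1.0;
  if (sel_active) {
    const Pop& sp = st.pops[sel_slot];
    int N = (int)sp.size() / 2;
    geno.resize(N);
    for (int i = 0; i < N; ++i)
      geno[i] = (uint8_t)(carries(sp[2 * i], st.mut_pos, (MutId)focal_id) +
                          carries(sp[2 * i + 1], st.mut_pos, (MutId)focal_id));
    wmax = 1.0 + 2.0 * s;
  }

  for (int slot = 0; slot < 3; ++slot) {
    if (!alive_new[slot]) { sc.nxt[slot].clear(); continue; }
    int Nn = pop_size(P, slot, g_new);
    if ((int)sc.nxt[slot].size() != 2 * Nn) sc.nxt[slot].resize(2 * Nn);
    int n_gam = 2 * Nn;

    // scatter this generation's crossover and mutation events over gametes
    if ((int)sc.ev_rec.size() < n_gam) {
      sc.ev_rec.assign(n_gam, 0);
      sc.ev_mut.assign(n_gam, 0);
    }
    sc.touched.clear();
    int n_rec = rpois_mean(st.rng, (double)n_gam * P.rec * P.L);
    for (int e = 0; e < n_rec; ++e) {
      int g = st.rng.below(n_gam);
      if (!sc.ev_rec[g] && !sc.ev_mut[g]) sc.touched.push_back(g);
      ++sc.ev_rec[g];
    }
    int n_mut = rpois_mean(st.rng, (double)n_gam * P.mu * P.L);
    for (int e = 0; e < n_mut; ++e) {
      int g = st.rng.below(n_gam);
      if (!sc.ev_rec[g] && !sc.ev_mut[g]) sc.touched.push_back(g);
      ++sc.ev_mut[g];
    }

    bool founding = !alive_old[slot];
    int base_src = founding ? source_of[slot] : slot;
    double m1 = 0, m2 = 0;
    int o1 = -1, o2 = -1;
    if (!founding) {
      for (int j = 0; j < 3; ++j) {
        if (j == slot || mig[slot][j] <= 0 || !alive_old[j]) continue;
        if (o1 < 0) { o1 = j; m1 = mig[slot][j]; }
        else { o2 = j; m2 = mig[slot][j]; }
      }
    }
    for (int ind = 0; ind < Nn; ++ind) {
      int src = base_src;
      if (o1 >= 0) {
        double u = st.rng.unif();
        if (u < m1) src = o1;
        else if (u < m1 + m2) src = o2;
      }
      const Pop& parents = st.pops[src];
      int Np = (int)parents.size() / 2;
      bool use_fit = sel_active && src == sel_slot;
      for (int gamete = 0; gamete < 2; ++gamete) {
        int gidx = 2 * ind + gamete;
        uint64_t r = st.rng.next();
        int par;
        bool first_a = (r >> 32) & 1;
        if (use_fit) {
          for (;;) {
            par = st.rng.below(Np);
            double w = 1.0 + s * geno[par];
            if (st.rng.unif() * wmax <= w) break;
          }
        } else {
          par = (int)(((uint64_t)(uint32_t)r * (uint64_t)(uint32_t)Np) >> 32);
        }
        make_gamete(st, P, parents[2 * par], parents[2 * par + 1],
                    sc.ev_rec[gidx], sc.ev_mut[gidx], first_a,
                    sc.nxt[slot][gidx], brk);
      }
    }
    for (size_t t = 0; t < sc.touched.size(); ++t) {
      sc.ev_rec[sc.touched[t]] = 0;
      sc.ev_mut[sc.touched[t]] = 0;
    }
    std::swap(st.pops[slot], sc.nxt[slot]);
  }
}

inline long count_copies(const State& st, MutId id) {
  long n = 0;
  for (size_t p = 0; p < st.pops.size(); ++p)
    for (size_t h = 0; h < st.pops[p].size(); ++h)
      if (carries(st.pops[p][h], st.mut_pos, id)) ++n;
  return n;
}

inline long count_copies_pop(const State& st, int slot, MutId id) {
  long n = 0;
  for (size_t h = 0; h < st.pops[slot].size(); ++h)
    if (carries(st.pops[slot][h], st.mut_pos, id)) ++n;
  return n;
}

double logit(double p) { return std::log(p / (1.0 - p)); }

}  // namespace

// [[Rcpp::export(name = ".wf_simulate_cpp")]]
Rcpp::List wf_simulate_cpp(Rcpp::List par) {
  Params P;
  P.L = Rcpp::as<int>(par["L"]);
  P.npop = Rcpp::as<int>(par["npop"]);
  P.N_anc = Rcpp::as<int>(par["N_anc"]);
  P.N_af = Rcpp::as<int>(par["N_af"]);
  P.N_b = Rcpp::as<int>(par["N_b"]);
  P.N_eu0 = Rcpp::as<int>(par["N_eu0"]);
  P.N_as0 = Rcpp::as<int>(par["N_as0"]);
  P.g_eu = Rcpp::as<double>(par["g_eu"]);
  P.g_as = Rcpp::as<double>(par["g_as"]);
  P.T_af = Rcpp::as<int>(par["T_af"]);
  P.T_b = Rcpp::as<int>(par["T_b"]);
  P.T_euas = Rcpp::as<int>(par["T_euas"]);
  P.m_af_b = Rcpp::as<double>(par["m_af_b"]);
  P.m_af_eu = Rcpp::as<double>(par["m_af_eu"]);
  P.m_af_as = Rcpp::as<double>(par["m_af_as"]);
  P.m_eu_as = Rcpp::as<double>(par["m_eu_as"]);
  P.mu = Rcpp::as<double>(par["mu"]);
  P.rec = Rcpp::as<double>(par["rec"]);
  P.burnin = Rcpp::as<int>(par["burnin"]);
  P.has_sweep = Rcpp::as<bool>(par["has_sweep"]);
  P.sel_pop = Rcpp::as<int>(par["sel_pop"]);
  P.focal = Rcpp::as<int>(par["focal"]);
  P.target = Rcpp::as<double>(par["target"]);
  P.band = Rcpp::as<double>(par["band"]);
  P.sweep_start = Rcpp::as<int>(par["sweep_start"]);
  P.sweep_end = Rcpp::as<int>(par["sweep_end"]);
  P.s_init = Rcpp::as<double>(par["s_init"]);
  P.max_attempts = Rcpp::as<int>(par["max_attempts"]);
  int n_samp = Rcpp::as<int>(par["n_samp"]);
  uint64_t seed = (uint64_t)Rcpp::as<double>(par["seed"]);

  if (P.L < 2) Rcpp::stop("region too short");
  if (P.npop != 1 && P.npop != 3) Rcpp::stop("npop must be 1 or 3");

  int G0 = P.burnin + (P.npop == 3 ? P.T_af : 0);
  if (P.has_sweep && P.sweep_start >= G0)
    Rcpp::stop("sweep starts before the simulation does");

  State st;
  st.pops.resize(3);
  st.occ.assign(P.L, 0);
  st.alive.assign(MAXMUT, 0);
  st.mut_pos.assign(MAXMUT, 0);
  st.free_ids.resize(MAXMUT);
  for (int i = 0; i < MAXMUT; ++i) st.free_ids[i] = (MutId)(MAXMUT - 1 - i);
  st.rng.seed(seed);
  st.pops[0].assign(2 * pop_size(P, 0, G0), Hap());

  Scratch sc;
  std::vector<int> brk;

  double s = P.s_init;
  long attempts = 0;
  int focal_id = -1;
  int focal_pos = P.focal;

  int stop_at = (P.has_sweep) ? P.sweep_start : 0;
  for (int g = G0 - 1; g >= stop_at; --g) {
    step(st, P, g, false, 0, 0.0, -1, sc, brk);
    if ((G0 - g) % 128 == 0 || (int)st.free_ids.size() < 16384)
      purge(st, P, sc, -1);
  }

  if (P.has_sweep) {
    purge(st, P, sc, -1);
    // infinite sites: if the requested focal bp carries a standing neutral
    // mutation, nudge to the nearest free position
    for (int d = 0; st.occ[focal_pos]; ++d) {
      if (P.focal + d < P.L && !st.occ[P.focal + d]) { focal_pos = P.focal + d; break; }
      if (P.focal - d >= 0 && !st.occ[P.focal - d]) { focal_pos = P.focal - d; break; }
      if (d > P.L) Rcpp::stop("no free focal position");
    }
    State checkpoint = st;  // deep copy
    bool accepted = false;
    double f0 = 1.0 / (2.0 * pop_size(P, sel_slot_at(P, P.sweep_start), P.sweep_start));
    double tgt = std::min(P.target, 0.995);
    for (int att = 1; att <= P.max_attempts && !accepted; ++att) {
      ++attempts;
      st = checkpoint;
      uint64_t aseed = seed ^ (0x9E3779B97F4A7C15ULL * (uint64_t)att);
      st.rng.seed(aseed);
      // introduce the focal mutation on one random haplotype
      int slot0 = sel_slot_at(P, P.sweep_start);
      focal_id = st.alloc_mut(focal_pos);
      Hap& h0 = st.pops[slot0][st.rng.below((int)st.pops[slot0].size())];
      h0.insert(std::lower_bound(h0.begin(), h0.end(), focal_pos,
                                 PosLess(st.mut_pos)), (MutId)focal_id);
      bool lost = false;
      double freq_end_sel = 0.0;
      for (int g = P.sweep_start - 1; g >= 0; --g) {
        bool sel_active = (g >= P.sweep_end);
        int slot = sel_slot_at(P, g + 1);
        step(st, P, g, sel_active, slot, s, focal_id, sc, brk);
        long copies = count_copies(st, (MutId)focal_id);
        if (copies == 0) { lost = true; break; }
        if (g == P.sweep_end) {
          int cs = sel_slot_at(P, g);
          freq_end_sel = count_copies_pop(st, cs, (MutId)focal_id) /
                         (double)st.pops[cs].size();
        }
        if ((P.sweep_start - g) % 128 == 0 ||
            (int)st.free_ids.size() < 16384)
          purge(st, P, sc, focal_id);
      }
      if (lost) continue;
      double f = count_copies_pop(st, P.sel_pop, (MutId)focal_id) /
                 (double)st.pops[P.sel_pop].size();
      bool ok = (P.target >= 0.9999) ? (f >= P.target - P.band)
                                     : (std::fabs(f - P.target) <= P.band);
      if (ok) {
        accepted = true;
      } else if (freq_end_sel > 5.0 * f0 && freq_end_sel < 1.0) {
        // established but missed the band: rescale s on the logit path
        double fe = std::min(std::max(freq_end_sel, 2.0 * f0), 0.995);
        double ratio = (logit(tgt) - logit(f0)) / (logit(fe) - logit(f0));
        ratio = std::min(std::max(ratio, 0.25), 4.0);
        s = std::min(std::max(s * ratio, 1e-4), 10.0);
      }
    }
    if (!accepted)
      Rcpp::stop("sweep conditioning failed after %ld attempts (last s = %g)",
                 attempts, s);
  }

  purge(st, P, sc, P.has_sweep ? focal_id : -1);

  // ---- sample n_samp diploids per active population ----
  bool alive_now[3];
  active_slots(P, 0, alive_now);
  std::vector<int> pop_of;       // per sampled individual: slot
  std::vector<const Hap*> samp;  // sampled haplotypes, pop-major
  for (int slot = 0; slot < 3; ++slot) {
    if (!alive_now[slot]) continue;
    int N = (int)st.pops[slot].size() / 2;
    if (n_samp > N)
      Rcpp::stop("n_per_pop (%d) exceeds final population size (%d)", n_samp, N);
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int i = 0; i < n_samp; ++i) {
      int j = i + st.rng.below(N - i);
      std::swap(idx[i], idx[j]);
      pop_of.push_back(slot);
      samp.push_back(&st.pops[slot][2 * idx[i]]);
      samp.push_back(&st.pops[slot][2 * idx[i] + 1]);
    }
  }
  int nh = (int)samp.size();

  // polymorphic positions within the sample (focal always reported)
  std::vector<int>& cnt = sc.cnt;
  for (int i = 0; i < nh; ++i)
    for (size_t k = 0; k < samp[i]->size(); ++k) ++cnt[(*samp[i])[k]];
  std::vector<std::pair<int, int> > keep;  // (position, id)
  for (int id = 0; id < MAXMUT; ++id) {
    if (!st.alive[id]) continue;
    bool poly = cnt[id] > 0 && cnt[id] < nh;
    if (poly || (P.has_sweep && id == focal_id))
      keep.push_back(std::make_pair(st.mut_pos[id], id));
  }
  std::sort(keep.begin(), keep.end());
  std::vector<int> row_of(MAXMUT, -1);
  for (size_t r = 0; r < keep.size(); ++r) row_of[keep[r].second] = (int)r;
  Rcpp::IntegerMatrix H((int)keep.size(), nh);
  for (int i = 0; i < nh; ++i)
    for (size_t k = 0; k < samp[i]->size(); ++k) {
      int r = row_of[(*samp[i])[k]];
      if (r >= 0) H(r, i) = 1;
    }
  for (int id = 0; id < MAXMUT; ++id) cnt[id] = 0;

  int sel_index = NA_INTEGER;
  Rcpp::NumericVector pop_freq(3, NA_REAL);
  if (P.has_sweep) {
    sel_index = row_of[focal_id] + 1;  // 1-based for R
    for (int slot = 0; slot < 3; ++slot)
      if (alive_now[slot])
        pop_freq[slot] = count_copies_pop(st, slot, (MutId)focal_id) /
                         (double)st.pops[slot].size();
  }

  Rcpp::IntegerVector pos_out((int)keep.size());
  for (size_t r = 0; r < keep.size(); ++r) pos_out[(int)r] = keep[r].first + 1;

  return Rcpp::List::create(
      Rcpp::Named("positions") = pos_out,
      Rcpp::Named("H") = H,
      Rcpp::Named("pop_of") = Rcpp::IntegerVector(pop_of.begin(), pop_of.end()),
      Rcpp::Named("selected_index") = sel_index,
      Rcpp::Named("pop_freq") = pop_freq,
      Rcpp::Named("attempts") = (double)attempts,
      Rcpp::Named("s_used") = P.has_sweep ? s : NA_REAL);
}
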