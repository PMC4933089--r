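// Simulation engine: a dual-scale stochastic model of tissue homeostasis and
// tumour growth on a rectangular lattice. Each grid element holds a bounded
// population of cells that share a nutrient and per-gene growth factors by
// relative demand; cell ageing, division, mutation, migration and
// fitness-ranked competition are resolved once per generation (tick).
//
// Trait vector layout (length 2N+5 for an N-gene genome):
//   [0..N-1]   gene targets
//   [N..2N-1]  gene tolerances
//   [2N]       nutrient target
//   [2N+1]     nutrient rate
//   [2N+2]     lifetime (integer-valued, stored as double)
//   [2N+3]     mutation rate
//   [2N+4]     invasion rate
#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <cmath>
#include <algorithm>
#include <random>
#include <string>

using namespace Rcpp;

// cell states
static const int CS_HEALTHY = 0;
static const int CS_DIVIDING = 1;
static const int CS_APOPTOTIC = 2;
static const int CS_TBC = 3;

// element states
static const int ES_NORMAL = 0;
static const int ES_MAJ_NORMAL = 1;
static const int ES_MAJ_MALIGNANT = 2;
static const int ES_TUMOUR = 3;
static const int ES_NECROTIC = 4;

// ---------------------------------------------------------------------------
// closed-form model functions
// ---------------------------------------------------------------------------

static inline double expression_fn(double target, double factor) {
  return 1.0 - std::exp(-(target - factor));
}

static inline bool health_fn(double target, double tolerance, double received) {
  return (received < target + tolerance) && (received > target - tolerance);
}

static inline double fitness_fn(const double* targets, const double* received, int n) {
  double acc = 0.0;
  for (int g = 0; g < n; ++g)
    acc += std::exp(-std::fabs(targets[g] - received[g]) / targets[g]);
  return acc / n;
}

// element composition code from the Normal/Malignant head-count
static inline int composition_code(int n_normal, int n_malignant) {
  if (n_malignant == 0) return ES_NORMAL;              // incl. empty elements
  if (n_normal == 0) return ES_TUMOUR;
  if (n_malignant > n_normal) return ES_MAJ_MALIGNANT; // strict majority
  return ES_MAJ_NORMAL;                                // ties favour normal
}

// ---------------------------------------------------------------------------
// exported wrappers for the closed-form functions (shared with the engine)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector cpp_nutrient_shares(NumericVector targets, double supply) {
  if (targets.size() == 0) stop("no population: empty demand vector");
  double s = 0.0;
  for (double x : targets) s += x;
  if (s == 0.0) stop("degenerate demand: targets sum to zero");
  NumericVector out(targets.size());
  for (int i = 0; i < targets.size(); ++i) out[i] = supply * targets[i] / s;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_gene_factor_shares(NumericVector targets, double available) {
  if (targets.size() == 0) stop("no population: empty demand vector");
  double s = 0.0;
  for (double x : targets) s += x;
  if (s == 0.0) stop("degenerate demand: targets sum to zero");
  NumericVector out(targets.size());
  for (int i = 0; i < targets.size(); ++i) out[i] = available * targets[i] / s;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_gene_health(double target, double tolerance, NumericVector received) {
  LogicalVector out(received.size());
  for (int i = 0; i < received.size(); ++i)
    out[i] = health_fn(target, tolerance, received[i]);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_expression(NumericVector target, NumericVector factor) {
  int n = std::max(target.size(), factor.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = expression_fn(target[i % target.size()], factor[i % factor.size()]);
  return out;
}

// [[Rcpp::export]]
double cpp_fitness(NumericVector targets, NumericVector received) {
  if (targets.size() != received.size())
    stop("dimension error: genome has %d genes but %d received values supplied",
         (int)targets.size(), (int)received.size());
  return fitness_fn(REAL(targets), REAL(received), targets.size());
}

// Per-gene factor pipeline for one grid element: each cell evaluates its
// expression feedback against its demand-share of the exogenous supply; the
// available total (exogenous + sum of expressions) is then redistributed by
// relative demand.
// gene_targets: cells x N matrix. Returns available totals and the cells x N
// matrix of received shares.
// [[Rcpp::export]]
List cpp_distribute_factors(NumericMatrix gene_targets, NumericVector supply) {
  int ncell = gene_targets.nrow(), N = gene_targets.ncol();
  if (supply.size() != N) stop("dimension error: supply length must equal genome size");
  NumericVector available(N);
  NumericMatrix shares(ncell, N);
  for (int g = 0; g < N; ++g) {
    double gsum = 0.0;
    for (int i = 0; i < ncell; ++i) gsum += gene_targets(i, g);
    if (ncell > 0 && gsum == 0.0) stop("degenerate demand: targets sum to zero");
    double avail = supply[g];
    for (int i = 0; i < ncell; ++i) {
      double f = supply[g] * gene_targets(i, g) / gsum;   // per-cell exogenous share
      avail += expression_fn(gene_targets(i, g), f);
    }
    available[g] = avail;
    for (int i = 0; i < ncell; ++i)
      shares(i, g) = avail * gene_targets(i, g) / gsum;
  }
  return List::create(_["available"] = available, _["shares"] = shares);
}

// One healthy cell's ageing step. Returns the updated clock, store and state
// code (0 = HEALTHY, 1 = DIVIDING, 3 = TO_BE_CLEARED when intercepted by an
// active cytotoxic treatment).
// [[Rcpp::export]]
List cpp_step_cell(int clock, double store, double nutrient_share,
                   double nutrient_rate, int n_unhealthy, bool treated) {
  store += nutrient_share - nutrient_rate;
  if (store <= 0.0) {
    store = 0.0;
    clock = 0;                       // metabolic failure forces the transition
  } else {
    clock -= 1 + n_unhealthy;
    if (clock < 0) clock = 0;
  }
  int state = CS_HEALTHY;
  if (clock == 0) state = treated ? CS_TBC : CS_DIVIDING;
  return List::create(_["clock"] = clock, _["store"] = store, _["state"] = state);
}

// ---------------------------------------------------------------------------
// mutation
// ---------------------------------------------------------------------------

static void mutate_in_place(std::vector<double>& v, int N, double delta,
                            std::mt19937_64& rng,
                            std::uniform_real_distribution<double>& unif) {
  int k = 2 * N + 5;
  int idx = (int)std::floor(unif(rng) * k);
  if (idx >= k) idx = k - 1;
  double f = 1.0 - delta + 2.0 * delta * unif(rng);
  v[idx] *= f;
  if (idx >= N && idx < 2 * N && v[idx] < 0.0) v[idx] = 0.0;   // tolerance floor
  if (idx == 2 * N + 2) {                                      // lifetime: integer >= 1
    double L = std::round(v[idx]);
    v[idx] = (L < 1.0) ? 1.0 : L;
  }
  if (idx == 2 * N + 3 || idx == 2 * N + 4) {                  // probabilities clamp
    if (v[idx] < 0.0) v[idx] = 0.0;
    if (v[idx] > 1.0) v[idx] = 1.0;
  }
}

// [[Rcpp::export]]
NumericVector cpp_mutate_traits(NumericVector traits, int n_genes, double delta, int seed) {
  if (traits.size() != 2 * n_genes + 5) stop("trait vector has wrong length");
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<double> v(traits.begin(), traits.end());
  mutate_in_place(v, n_genes, delta, rng, unif);
  return wrap(v);
}

// ---------------------------------------------------------------------------
// ranked-selection removal (competition at carrying capacity)
// ---------------------------------------------------------------------------

struct RankKey { double fit; int clock; double tie; int idx; };
static bool rank_less(const RankKey& a, const RankKey& b) {
  if (a.fit != b.fit) return a.fit < b.fit;
  if (a.clock != b.clock) return a.clock < b.clock;  // older (lower clock) first
  return a.tie < b.tie;
}

// Indices (1-based) of the n_remove cells eliminated by fitness-ranked
// selection; ties broken by age then randomly.
// [[Rcpp::export]]
IntegerVector cpp_rank_removal(NumericVector fitness, IntegerVector clock,
                               int n_remove, int seed) {
  if (fitness.size() != clock.size()) stop("fitness and clock lengths differ");
  if (n_remove < 0 || n_remove > fitness.size()) stop("invalid removal count");
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<RankKey> keys(fitness.size());
  for (int i = 0; i < fitness.size(); ++i)
    keys[i] = RankKey{fitness[i], clock[i], unif(rng), i};
  std::sort(keys.begin(), keys.end(), rank_less);
  IntegerVector out(n_remove);
  for (int i = 0; i < n_remove; ++i) out[i] = keys[i].idx + 1;
  return out;
}

// [[Rcpp::export]]
int cpp_element_state(int n_normal, int n_malignant) {
  return composition_code(n_normal, n_malignant);
}

// Apply the necrosis rule to a matrix of composition codes: a TUMOUR element
// whose whole Moore neighbourhood of the given radius (truncated at edges)
// is TUMOUR or NECROTIC becomes NECROTIC; otherwise it keeps (or reverts to)
// its composition code.
// [[Rcpp::export]]
IntegerMatrix cpp_necrosis_update(IntegerMatrix comp, int radius) {
  int H = comp.nrow(), W = comp.ncol();
  IntegerMatrix out(H, W);
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      int code = comp(r, c);
      if (code == ES_NECROTIC) code = ES_TUMOUR;  // classify from composition
      if (code == ES_TUMOUR) {
        bool all_tumour = true;
        for (int dr = -radius; dr <= radius && all_tumour; ++dr) {
          for (int dc = -radius; dc <= radius; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
            int nb = comp(rr, cc);
            if (nb != ES_TUMOUR && nb != ES_NECROTIC) { all_tumour = false; break; }
          }
        }
        if (all_tumour) code = ES_NECROTIC;
      }
      out(r, c) = code;
    }
  }
  return out;
}

// Cytotoxic flagging: HEALTHY or DIVIDING cells with clock <= the cut-off for
// their type are marked TO_BE_CLEARED. A cut-off of -1 means the type is not
// targeted (magic-bullet mode for Normal cells).
// [[Rcpp::export]]
LogicalVector cpp_flag_cytotoxic(IntegerVector clock, IntegerVector type,
                                 IntegerVector state, int cutoff_normal,
                                 int cutoff_malignant) {
  int n = clock.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    int cut = (type[i] == 1) ? cutoff_malignant : cutoff_normal;
    out[i] = (cut >= 0) && (state[i] == CS_HEALTHY || state[i] == CS_DIVIDING) &&
             (clock[i] <= cut);
  }
  return out;
}

// ---------------------------------------------------------------------------
// full simulation
// ---------------------------------------------------------------------------

struct CellC {
  int type;        // 0 Normal, 1 Malignant
  int state;
  int gid;         // genotype id (0 = base Normal genotype)
  int clock;
  double store;
  int mutations;
  std::vector<double> lastA;  // latest received gene-factor shares
};

struct Sim {
  // configuration
  int W, H, N, opt, cap, lifetime;
  double nut_supply, nut_target, nut_rate, store0;
  std::vector<double> gtar, gtol, fsup;
  int seed_gen, seed_row, seed_col, seed_count;
  double m_mr, m_ir, mut_delta;
  bool parent_survives;
  int necro_r;
  bool has_treat;
  int trig_type;        // 0 = generation, 1 = malignant count
  double trig_val, duration;
  int cut_n, cut_m;     // -1 = type not targeted

  // state
  std::vector<std::vector<CellC>> elems;
  std::vector<int> estate;
  std::vector<std::vector<double>> genotypes;  // gid -> trait vector
  std::map<std::vector<double>, int> malig_registry;
  int gene_pool;
  int treat_start;
  long prev_malignant;
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif;

  Sim() : gene_pool(0), treat_start(-1), prev_malignant(0), unif(0.0, 1.0) {}

  int rint(int n) {  // uniform on 0..n-1
    int k = (int)std::floor(unif(rng) * n);
    return (k >= n) ? n - 1 : k;
  }

  double life_of(int gid) const { return genotypes[gid][2 * N + 2]; }
  double ntarget_of(int gid) const { return genotypes[gid][2 * N]; }
  double nrate_of(int gid) const { return genotypes[gid][2 * N + 1]; }
  double mr_of(int gid) const { return genotypes[gid][2 * N + 3]; }
  double ir_of(int gid) const { return genotypes[gid][2 * N + 4]; }
  double gt_of(int gid, int g) const { return genotypes[gid][g]; }
  double tol_of(int gid, int g) const { return genotypes[gid][N + g]; }

  int register_malignant(const std::vector<double>& tv) {
    auto it = malig_registry.find(tv);
    if (it != malig_registry.end()) return it->second;
    genotypes.push_back(tv);
    int gid = (int)genotypes.size() - 1;
    malig_registry[tv] = gid;
    gene_pool++;
    return gid;
  }

  void init(int seed) {
    rng.seed((uint64_t)seed);
    elems.assign((size_t)W * H, {});
    estate.assign((size_t)W * H, ES_NORMAL);
    std::vector<double> base(2 * N + 5);
    for (int g = 0; g < N; ++g) { base[g] = gtar[g]; base[N + g] = gtol[g]; }
    base[2 * N] = nut_target;
    base[2 * N + 1] = nut_rate;
    base[2 * N + 2] = lifetime;
    base[2 * N + 3] = 0.0;
    base[2 * N + 4] = 0.0;
    genotypes.clear();
    genotypes.push_back(base);
    malig_registry.clear();
    gene_pool = 0;
    treat_start = -1;
    prev_malignant = 0;
    for (auto& e : elems) {
      e.reserve(cap + 2);
      for (int i = 0; i < opt; ++i) {
        CellC c;
        c.type = 0; c.state = CS_HEALTHY; c.gid = 0;
        c.clock = rint(lifetime + 1);  // random start phase at instantiation
        c.store = store0; c.mutations = 0;
        c.lastA.assign(gtar.begin(), gtar.end());
        e.push_back(c);
      }
    }
  }

  void seed_malignant() {
    int r = (seed_row >= 0) ? seed_row : H / 2;
    int c = (seed_col >= 0) ? seed_col : W / 2;
    std::vector<double> tv = genotypes[0];
    tv[2 * N + 3] = m_mr;
    tv[2 * N + 4] = m_ir;
    int gid = register_malignant(tv);
    for (int i = 0; i < seed_count; ++i) {
      CellC cell;
      cell.type = 1; cell.state = CS_HEALTHY; cell.gid = gid;
      cell.clock = (int)life_of(gid);  // full clock, no inherited head start
      cell.store = store0; cell.mutations = 0;
      cell.lastA.assign(gtar.begin(), gtar.end());
      elems[(size_t)r * W + c].push_back(cell);
    }
  }

  bool active_now(int gen) {
    if (!has_treat) return false;
    if (treat_start < 0) {
      if (trig_type == 0) {
        if (gen >= (int)trig_val) treat_start = std::max((int)trig_val, 1);
      } else {
        if ((double)prev_malignant >= trig_val) treat_start = gen;
      }
    }
    return treat_start >= 0 && gen >= treat_start &&
           (double)(gen - treat_start) < duration;
  }

  // scratch buffers reused across elements
  std::vector<double> buf_nt, buf_nshare, buf_gsum;

  void distribute_element(std::vector<CellC>& cells) {
    // per-gene: per-cell exogenous share -> expression feedback -> available
    // total -> redistribution by demand; stored as each cell's lastA
    size_t n = cells.size();
    for (int g = 0; g < N; ++g) {
      double gsum = 0.0;
      for (size_t i = 0; i < n; ++i) gsum += gt_of(cells[i].gid, g);
      double avail = fsup[g];
      for (size_t i = 0; i < n; ++i) {
        double T = gt_of(cells[i].gid, g);
        double f = fsup[g] * T / gsum;
        avail += expression_fn(T, f);
      }
      for (size_t i = 0; i < n; ++i)
        cells[i].lastA[g] = avail * gt_of(cells[i].gid, g) / gsum;
    }
  }

  List run(int generations, IntegerVector snapshot_at) {
    int G = generations;
    // per-generation observables
    NumericVector m_total(G), m_healthy(G), m_dividing(G), m_apoptotic(G),
        m_tbc(G), m_normal(G), m_malignant(G), m_fit_n(G), m_fitmax_n(G),
        m_fit_m(G), m_fitmax_m(G), m_age(G), m_pool(G), m_clones(G),
        m_dom(G), m_mut(G), m_mrate(G), m_irate(G), m_born(G), m_cleared(G),
        m_migr(G), m_mutev(G), m_flag(G), m_maxelem(G), m_e0(G), m_e1(G),
        m_e2(G), m_e3(G), m_e4(G);
    std::map<int, IntegerMatrix> snaps;
    std::set<int> want(snapshot_at.begin(), snapshot_at.end());

    for (int gen = 1; gen <= G; ++gen) {
      if (seed_count > 0 && gen == seed_gen + 1) seed_malignant();
      bool active = active_now(gen);
      long flagged = 0, cleared = 0, born = 0, migr = 0, mutev = 0;

      // (1) cytotoxic strategy: flag standing cells at or below the cut-off
      if (active) {
        for (size_t e = 0; e < elems.size(); ++e) {
          if (estate[e] == ES_NECROTIC) continue;
          for (auto& cell : elems[e]) {
            int cut = (cell.type == 1) ? cut_m : cut_n;
            if (cut >= 0 &&
                (cell.state == CS_HEALTHY || cell.state == CS_DIVIDING) &&
                cell.clock <= cut) {
              cell.state = CS_TBC;
              flagged++;
            }
          }
        }
      }

      // (2) clearance: APOPTOTIC advances to TO_BE_CLEARED, then all
      //     TO_BE_CLEARED cells are removed
      for (size_t e = 0; e < elems.size(); ++e) {
        if (estate[e] == ES_NECROTIC) continue;
        auto& cells = elems[e];
        for (auto& cell : cells)
          if (cell.state == CS_APOPTOTIC) cell.state = CS_TBC;
        size_t before = cells.size();
        cells.erase(std::remove_if(cells.begin(), cells.end(),
                                   [](const CellC& c) { return c.state == CS_TBC; }),
                    cells.end());
        cleared += before - cells.size();
      }

      // (3) resource distribution and ageing of HEALTHY cells
      for (size_t e = 0; e < elems.size(); ++e) {
        if (estate[e] == ES_NECROTIC) continue;
        auto& cells = elems[e];
        size_t n = cells.size();
        if (n == 0) continue;
        double ntsum = 0.0;
        for (auto& cell : cells) ntsum += ntarget_of(cell.gid);
        distribute_element(cells);
        for (auto& cell : cells) {
          if (cell.state != CS_HEALTHY) continue;
          double nshare = nut_supply * ntarget_of(cell.gid) / ntsum;
          cell.store += nshare - nrate_of(cell.gid);
          if (cell.store <= 0.0) {
            cell.store = 0.0;
            cell.clock = 0;
          } else {
            int unhealthy = 0;
            for (int g = 0; g < N; ++g)
              if (!health_fn(gt_of(cell.gid, g), tol_of(cell.gid, g), cell.lastA[g]))
                unhealthy++;
            cell.clock -= 1 + unhealthy;
            if (cell.clock < 0) cell.clock = 0;
          }
          if (cell.clock == 0) {
            int cut = (cell.type == 1) ? cut_m : cut_n;
            cell.state = (active && cut >= 0) ? CS_TBC : CS_DIVIDING;
            if (cell.state == CS_TBC) flagged++;
          }
        }
      }

      // ---- census: the per-generation observables are read here, after
      // ageing has settled and before divisions resolve ----
      collect(gen - 1, m_total, m_healthy, m_dividing, m_apoptotic, m_tbc,
              m_normal, m_malignant, m_fit_n, m_fitmax_n, m_fit_m, m_fitmax_m,
              m_age, m_pool, m_clones, m_dom, m_mut, m_mrate, m_irate);

      // (4) division, elements row-major, within-element order randomised
      for (size_t e = 0; e < elems.size(); ++e) {
        if (estate[e] == ES_NECROTIC) continue;
        auto& cells = elems[e];
        std::vector<int> div_idx;
        for (size_t i = 0; i < cells.size(); ++i)
          if (cells[i].state == CS_DIVIDING) div_idx.push_back((int)i);
        if (div_idx.empty()) continue;
        for (int i = (int)div_idx.size() - 1; i > 0; --i)
          std::swap(div_idx[i], div_idx[rint(i + 1)]);
        cells.reserve(cells.size() + div_idx.size());
        for (int i : div_idx) {
          if (cells[i].store <= 0.0) {
            // metabolic failure: no fuel to clone, the cell dies instead
            cells[i].state = CS_APOPTOTIC;
            continue;
          }
          CellC d;
          d.type = cells[i].type;
          d.gid = cells[i].gid;
          d.mutations = cells[i].mutations;
          d.state = CS_HEALTHY;
          if (d.type == 1 && unif(rng) < mr_of(cells[i].gid)) {
            std::vector<double> tv = genotypes[cells[i].gid];
            mutate_in_place(tv, N, mut_delta, rng, unif);
            d.gid = register_malignant(tv);
            d.mutations++;
            mutev++;
          }
          d.clock = (int)life_of(d.gid);
          d.store = store0;
          d.lastA.assign(genotypes[d.gid].begin(), genotypes[d.gid].begin() + N);
          bool placed = false;
          if ((int)cells.size() >= cap && d.type == 1 &&
              unif(rng) < ir_of(cells[i].gid)) {
            int r = (int)(e / W), c = (int)(e % W);
            int cand[8]; int ncand = 0;
            for (int dr = -1; dr <= 1; ++dr)
              for (int dc = -1; dc <= 1; ++dc) {
                if (dr == 0 && dc == 0) continue;
                int rr = r + dr, cc = c + dc;
                if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
                int ne = rr * W + cc;
                if (estate[ne] == ES_NECROTIC) continue;
                cand[ncand++] = ne;
              }
            if (ncand > 0) {
              elems[cand[rint(ncand)]].push_back(d);
              placed = true;
              migr++;
            }
          }
          if (!placed) cells.push_back(d);
          born++;
          if (cells[i].type == 0 || !parent_survives) {
            cells[i].state = CS_APOPTOTIC;
          } else {
            cells[i].clock = (int)life_of(cells[i].gid);
            cells[i].state = CS_HEALTHY;
          }
        }
      }

      // (5) fitness-ranked competition wherever capacity is exceeded
      for (size_t e = 0; e < elems.size(); ++e) {
        if (estate[e] == ES_NECROTIC) continue;
        auto& cells = elems[e];
        int excess = (int)cells.size() - cap;
        if (excess <= 0) continue;
        distribute_element(cells);  // shares for the crowded population
        std::vector<RankKey> keys(cells.size());
        for (size_t i = 0; i < cells.size(); ++i) {
          double fit = fitness_fn(genotypes[cells[i].gid].data(),
                                  cells[i].lastA.data(), N);
          keys[i] = RankKey{fit, cells[i].clock, unif(rng), (int)i};
        }
        std::sort(keys.begin(), keys.end(), rank_less);
        std::vector<bool> drop(cells.size(), false);
        for (int i = 0; i < excess; ++i) drop[keys[i].idx] = true;
        std::vector<CellC> keep;
        keep.reserve(cap + 2);
        for (size_t i = 0; i < cells.size(); ++i)
          if (!drop[i]) keep.push_back(std::move(cells[i]));
        cells = std::move(keep);
        cleared += excess;
      }

      // (6) element state update with the necrosis rule
      {
        std::vector<int> comp((size_t)W * H);
        for (size_t e = 0; e < elems.size(); ++e) {
          int nn = 0, nm = 0;
          for (auto& cell : elems[e]) (cell.type == 1 ? nm : nn)++;
          comp[e] = composition_code(nn, nm);
        }
        for (int r = 0; r < H; ++r) {
          for (int c = 0; c < W; ++c) {
            int e = r * W + c;
            int code = comp[e];
            if (code == ES_TUMOUR) {
              bool all_tumour = true;
              for (int dr = -necro_r; dr <= necro_r && all_tumour; ++dr)
                for (int dc = -necro_r; dc <= necro_r; ++dc) {
                  if (dr == 0 && dc == 0) continue;
                  int rr = r + dr, cc = c + dc;
                  if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
                  if (comp[(size_t)rr * W + cc] != ES_TUMOUR) { all_tumour = false; break; }
                }
              if (all_tumour) code = ES_NECROTIC;
            }
            estate[e] = code;
          }
        }
      }

      // element census + tick counters + post-tick capacity check;
      // mean viable-cell age is read here so that newborn daughters (age 0)
      // and reset malignant parents are included
      {
        int cnt[5] = {0, 0, 0, 0, 0};
        size_t maxn = 0;
        double age_sum = 0;
        long n_viable = 0;
        for (size_t e = 0; e < elems.size(); ++e) {
          cnt[estate[e]]++;
          if (elems[e].size() > maxn) maxn = elems[e].size();
          for (auto& cell : elems[e]) {
            if (cell.state == CS_HEALTHY) {
              age_sum += life_of(cell.gid) - cell.clock;
              n_viable++;
            }
          }
        }
        m_age[gen - 1] = n_viable ? age_sum / n_viable : NA_REAL;
        int i = gen - 1;
        m_e0[i] = cnt[0]; m_e1[i] = cnt[1]; m_e2[i] = cnt[2];
        m_e3[i] = cnt[3]; m_e4[i] = cnt[4];
        m_born[i] = born; m_cleared[i] = cleared; m_migr[i] = migr;
        m_mutev[i] = mutev; m_flag[i] = flagged; m_maxelem[i] = (double)maxn;
      }
      prev_malignant = (long)m_malignant[gen - 1];

      if (want.count(gen)) snaps[gen] = snapshot_matrix();
      if (gen % 256 == 0) Rcpp::checkUserInterrupt();
    }

    const int NCOL = 30;
    List metrics(NCOL);
    CharacterVector colnames(NCOL);
    int ci = 0;
    IntegerVector gens = seq_len(G);
    metrics[ci] = gens; colnames[ci++] = "generation";
    metrics[ci] = m_total; colnames[ci++] = "total_cells";
    metrics[ci] = m_healthy; colnames[ci++] = "healthy_cells";
    metrics[ci] = m_dividing; colnames[ci++] = "dividing_cells";
    metrics[ci] = m_apoptotic; colnames[ci++] = "apoptotic_cells";
    metrics[ci] = m_tbc; colnames[ci++] = "to_be_cleared_cells";
    metrics[ci] = m_normal; colnames[ci++] = "normal_cells";
    metrics[ci] = m_malignant; colnames[ci++] = "malignant_cells";
    metrics[ci] = m_fit_n; colnames[ci++] = "mean_fitness_normal";
    metrics[ci] = m_fitmax_n; colnames[ci++] = "max_fitness_normal";
    metrics[ci] = m_fit_m; colnames[ci++] = "mean_fitness_malignant";
    metrics[ci] = m_fitmax_m; colnames[ci++] = "max_fitness_malignant";
    metrics[ci] = m_age; colnames[ci++] = "mean_age";
    metrics[ci] = m_pool; colnames[ci++] = "gene_pool";
    metrics[ci] = m_clones; colnames[ci++] = "active_clones";
    metrics[ci] = m_dom; colnames[ci++] = "dominance";
    metrics[ci] = m_mut; colnames[ci++] = "mean_mutations_malignant";
    metrics[ci] = m_mrate; colnames[ci++] = "mean_mutation_rate";
    metrics[ci] = m_irate; colnames[ci++] = "mean_invasion_rate";
    metrics[ci] = m_e0; colnames[ci++] = "elems_normal";
    metrics[ci] = m_e1; colnames[ci++] = "elems_majority_normal";
    metrics[ci] = m_e2; colnames[ci++] = "elems_majority_malignant";
    metrics[ci] = m_e3; colnames[ci++] = "elems_tumour";
    metrics[ci] = m_e4; colnames[ci++] = "elems_necrotic";
    metrics[ci] = m_born; colnames[ci++] = "cells_born";
    metrics[ci] = m_cleared; colnames[ci++] = "cells_cleared";
    metrics[ci] = m_migr; colnames[ci++] = "migration_events";
    metrics[ci] = m_mutev; colnames[ci++] = "mutation_events";
    metrics[ci] = m_flag; colnames[ci++] = "cells_flagged";
    metrics[ci] = m_maxelem; colnames[ci++] = "max_element_cells";
    metrics.attr("names") = colnames;
    metrics.attr("class") = "data.frame";
    metrics.attr("row.names") = gens;

    List snap_out;
    for (auto& kv : snaps) snap_out[std::to_string(kv.first)] = kv.second;

    // final genotype table and living clone counts
    NumericMatrix gmat((int)genotypes.size(), 2 * N + 5);
    for (size_t i = 0; i < genotypes.size(); ++i)
      for (int j = 0; j < 2 * N + 5; ++j) gmat((int)i, j) = genotypes[i][j];
    std::map<int, long> livecount;
    for (auto& e : elems)
      for (auto& cell : e)
        if (cell.type == 1) livecount[cell.gid]++;
    IntegerVector clone_gid((int)livecount.size());
    NumericVector clone_n((int)livecount.size());
    int k = 0;
    for (auto& kv : livecount) { clone_gid[k] = kv.first; clone_n[k] = (double)kv.second; k++; }

    return List::create(
        _["metrics"] = metrics, _["snapshots"] = snap_out,
        _["final_state"] = snapshot_matrix(), _["gene_pool"] = gene_pool,
        _["genotypes"] = gmat,
        _["final_clones"] = DataFrame::create(_["genotype_id"] = clone_gid,
                                              _["cells"] = clone_n));
  }

  IntegerMatrix snapshot_matrix() {
    IntegerMatrix m(H, W);
    for (int r = 0; r < H; ++r)
      for (int c = 0; c < W; ++c) m(r, c) = estate[(size_t)r * W + c];
    return m;
  }

  void collect(int i, NumericVector& m_total, NumericVector& m_healthy,
               NumericVector& m_dividing, NumericVector& m_apoptotic,
               NumericVector& m_tbc, NumericVector& m_normal,
               NumericVector& m_malignant, NumericVector& m_fit_n,
               NumericVector& m_fitmax_n, NumericVector& m_fit_m,
               NumericVector& m_fitmax_m, NumericVector& m_age,
               NumericVector& m_pool, NumericVector& m_clones,
               NumericVector& m_dom, NumericVector& m_mut,
               NumericVector& m_mrate, NumericVector& m_irate) {
    long total = 0, healthy = 0, dividing = 0, apoptotic = 0, tbc = 0;
    long nnorm = 0, nmal = 0, mutsum = 0;
    double fitn_sum = 0, fitm_sum = 0, fitn_max = NA_REAL, fitm_max = NA_REAL;
    double mr_sum = 0, ir_sum = 0;
    std::map<int, long> clones;
    for (auto& e : elems) {
      for (auto& cell : e) {
        total++;
        switch (cell.state) {
          case CS_HEALTHY: healthy++; break;
          case CS_DIVIDING: dividing++; break;
          case CS_APOPTOTIC: apoptotic++; break;
          case CS_TBC: tbc++; break;
        }
        double fit = fitness_fn(genotypes[cell.gid].data(), cell.lastA.data(), N);
        // viable-cell age is censused at end of tick, not here
        if (cell.type == 1) {
          nmal++;
          fitm_sum += fit;
          if (ISNA(fitm_max) || fit > fitm_max) fitm_max = fit;
          mutsum += cell.mutations;
          mr_sum += mr_of(cell.gid);
          ir_sum += ir_of(cell.gid);
          clones[cell.gid]++;
        } else {
          nnorm++;
          fitn_sum += fit;
          if (ISNA(fitn_max) || fit > fitn_max) fitn_max = fit;
        }
      }
    }
    long biggest = 0;
    for (auto& kv : clones) biggest = std::max(biggest, kv.second);
    m_total[i] = (double)total;
    m_healthy[i] = (double)healthy;
    m_dividing[i] = (double)dividing;
    m_apoptotic[i] = (double)apoptotic;
    m_tbc[i] = (double)tbc;
    m_normal[i] = (double)nnorm;
    m_malignant[i] = (double)nmal;
    m_fit_n[i] = nnorm ? fitn_sum / nnorm : NA_REAL;
    m_fitmax_n[i] = fitn_max;
    m_fit_m[i] = nmal ? fitm_sum / nmal : NA_REAL;
    m_fitmax_m[i] = fitm_max;
    // m_age is filled at end of tick (viable cells after division resolve)
    m_pool[i] = (double)gene_pool;
    m_clones[i] = (double)clones.size();
    m_dom[i] = nmal ? 100.0 * (double)biggest / (double)nmal : NA_REAL;
    m_mut[i] = nmal ? (double)mutsum / nmal : NA_REAL;
    m_mrate[i] = nmal ? mr_sum / nmal : NA_REAL;
    m_irate[i] = nmal ? ir_sum / nmal : NA_REAL;
  }
};

// [[Rcpp::export]]
List cpp_run_simulation(List cfg, int seed) {
  Sim s;
  s.W = as<int>(cfg["width"]);
  s.H = as<int>(cfg["height"]);
  s.opt = as<int>(cfg["optimum_count"]);
  s.cap = as<int>(cfg["carrying_capacity"]);
  s.nut_supply = as<double>(cfg["nutrient_supply"]);
  s.nut_target = as<double>(cfg["nutrient_target"]);
  s.nut_rate = as<double>(cfg["nutrient_rate"]);
  s.store0 = as<double>(cfg["initial_store"]);
  s.gtar = as<std::vector<double>>(cfg["gene_targets"]);
  s.gtol = as<std::vector<double>>(cfg["gene_tolerances"]);
  s.fsup = as<std::vector<double>>(cfg["factor_supply"]);
  s.N = (int)s.gtar.size();
  s.lifetime = as<int>(cfg["lifetime"]);
  s.seed_gen = as<int>(cfg["seed_generation"]);
  s.seed_row = as<int>(cfg["seed_row"]);
  s.seed_col = as<int>(cfg["seed_col"]);
  s.seed_count = as<int>(cfg["seed_count"]);
  s.m_mr = as<double>(cfg["mutation_rate"]);
  s.m_ir = as<double>(cfg["invasion_rate"]);
  s.mut_delta = as<double>(cfg["mutation_delta"]);
  s.parent_survives = as<bool>(cfg["malignant_parent_survives"]);
  s.necro_r = as<int>(cfg["necrosis_radius"]);
  int generations = as<int>(cfg["generations"]);
  IntegerVector snapshot_at = cfg.containsElementNamed("snapshot_at")
                                  ? as<IntegerVector>(cfg["snapshot_at"])
                                  : IntegerVector(0);
  s.has_treat = false;
  s.trig_type = 0; s.trig_val = 0; s.duration = 0; s.cut_n = -1; s.cut_m = -1;
  if (cfg.containsElementNamed("treatment") && !Rf_isNull(cfg["treatment"])) {
    List tr = cfg["treatment"];
    s.has_treat = true;
    std::string tt = as<std::string>(tr["trigger"]);
    s.trig_type = (tt == "malignant_count") ? 1 : 0;
    s.trig_val = as<double>(tr["trigger_value"]);
    s.duration = as<double>(tr["duration"]);
    // the R wrapper encodes an untargeted cell type as -1
    s.cut_n = as<int>(tr["cutoff_normal"]);
    s.cut_m = as<int>(tr["cutoff_malignant"]);
  }
  s.init(seed);
  return s.run(generations, snapshot_at);
}
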