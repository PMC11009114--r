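// Per-timestep eco-evolutionary automaton. One call runs a full simulation
// for one seed species: range tracking under a changing climate, stochastic
// jump-dispersal, niche evolution under one of ten scenarios, connected-
// component (population) tracking with isolation clocks, allopatric
// speciation, extinction, and phylogeny/event bookkeeping.
//
// Randomness: each species owns a splitmix64 substream keyed by
// (run_seed, species_id), so results do not depend on species iteration
// order and any species' draw sequence is replayable in isolation.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <queue>
using namespace Rcpp;

static inline uint64_t sm64_next(uint64_t &state) {
  state += 0x9E3779B97f4A7C15ULL;
  uint64_t z = state;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double sm64_unif(uint64_t &state) {
  return (sm64_next(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline uint64_t species_stream(uint64_t run_seed, int species_id) {
  uint64_t s = run_seed * 0x9E3779B97f4A7C15ULL +
               (uint64_t)species_id * 0xBF58476D1CE4E5B9ULL;
  sm64_next(s);  // warm-up
  return s;
}

struct Component {
  std::vector<int> cells;  // sorted 0-based cell ids
  int clock;               // consecutive steps isolated (>=2 comps present)
};

struct Species {
  int id;                // 1-based
  int parent;            // 0 = root
  int origin_step;
  int end_step;          // -1 while extant
  int status;            // 0 extant, 1 extinct, 2 split (pseudo-extinct)
  double env[6];         // tmax lo,hi; tmin lo,hi; prcp lo,hi
  double nb0_temp, nb0_prcp;
  std::vector<int> occ;  // sorted occupied cells, 0-based
  std::vector<Component> comps;
  uint64_t rng;
};

struct Recorder {
  std::vector<int> ev_step, ev_type, ev_species, ev_detail;
  std::vector<int> fr_step, fr_species, fr_ncomp;
  std::vector<int> oc_step, oc_species, oc_cell;
  std::vector<int> ni_step, ni_species;
  std::vector<double> ni_env;  // 6 per row
  std::vector<double> ni_delta;  // 6 per row: dv_t, dv_p, ce_t, ce_p, ed_t, ed_p
};

static inline bool suitable(const double *env, double tx, double tn, double pr) {
  if (ISNAN(tx) || ISNAN(tn) || ISNAN(pr)) return false;
  return tx >= env[0] && tx <= env[1] &&
         tn >= env[2] && tn <= env[3] &&
         pr >= env[4] && pr <= env[5];
}

// seed_cell is 1-based; scenario_kind codes: 0 conservatism, 1 dir-shift,
// 2 dir-expand, 3 omni-expand, 4 rand-shift, 5 rand-expand-reduce,
// 6 rand-change-shift; kernel_probs covers reach d = 0..max_d.
// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(int n_cells,
                 IntegerVector land,
                 IntegerVector ball_ptr,
                 IntegerVector ball_cells,
                 IntegerMatrix ball_cnt,
                 NumericMatrix tmax, NumericMatrix tmin, NumericMatrix prcp,
                 int seed_cell,
                 double temp_breadth, double prcp_breadth,
                 int scenario_kind,
                 double rate_x,
                 NumericVector kernel_probs,
                 int isolation_steps,
                 int max_species,
                 double run_seed,
                 bool record_components,
                 bool record_occupancy,
                 bool record_niche) {
  const int n_steps = tmax.ncol() - 1;  // slices 0..n_steps
  const int max_d = kernel_probs.size() - 1;
  const int sc = seed_cell - 1;
  if (sc < 0 || sc >= n_cells) stop("seed cell out of range");
  if (!land[sc]) stop("seed cell is not land");
  if (ball_cnt.ncol() < max_d && max_d > 0)
    stop("neighbour balls shallower than the kernel's maximum reach");

  // kernel CDF
  std::vector<double> cdf(max_d + 1);
  double acc = 0;
  for (int d = 0; d <= max_d; ++d) { acc += kernel_probs[d]; cdf[d] = acc; }

  std::vector<Species> pop;
  pop.reserve(64);
  {
    Species s0;
    s0.id = 1; s0.parent = 0; s0.origin_step = 0; s0.end_step = -1;
    s0.status = 0;
    double tx = tmax(sc, 0), tn = tmin(sc, 0), pr = prcp(sc, 0);
    if (ISNAN(tx) || ISNAN(tn) || ISNAN(pr))
      stop("seed cell has no climate at step 0");
    s0.env[0] = tx - temp_breadth / 2; s0.env[1] = tx + temp_breadth / 2;
    s0.env[2] = tn - temp_breadth / 2; s0.env[3] = tn + temp_breadth / 2;
    s0.env[4] = pr - prcp_breadth / 2; s0.env[5] = pr + prcp_breadth / 2;
    s0.nb0_temp = temp_breadth; s0.nb0_prcp = prcp_breadth;
    s0.occ.push_back(sc);
    Component c; c.cells.push_back(sc); c.clock = 0;
    s0.comps.push_back(c);
    s0.rng = species_stream((uint64_t)run_seed, 1);
    pop.push_back(s0);
  }
  int cumulative = 1;
  bool aborted = false;

  Recorder rec;
  std::vector<int> richness(n_steps + 1, 0);
  richness[0] = 1;

  // scratch arrays with stamp-based clearing
  std::vector<int> stamp_occ(n_cells, 0), stamp_cand(n_cells, 0),
                   comp_of(n_cells, -1), prev_of(n_cells, -1);
  int stamp = 0;

  if (record_components) {
    rec.fr_step.push_back(0); rec.fr_species.push_back(1);
    rec.fr_ncomp.push_back(1);
  }
  if (record_occupancy) {
    rec.oc_step.push_back(0); rec.oc_species.push_back(1);
    rec.oc_cell.push_back(sc + 1);
  }

  for (int step = 1; step <= n_steps && !aborted; ++step) {
    const size_t n_at_start = pop.size();
    for (size_t si = 0; si < n_at_start; ++si) {
      Species &sp = pop[si];
      if (sp.status != 0) continue;

      // (1) drop cells that became unsuitable under this step's climate
      {
        size_t keep = 0;
        for (size_t i = 0; i < sp.occ.size(); ++i) {
          int c = sp.occ[i];
          if (suitable(sp.env, tmax(c, step), tmin(c, step), prcp(c, step)))
            sp.occ[keep++] = c;
        }
        sp.occ.resize(keep);
      }

      // (2) dispersal: one reach draw per remaining occupied cell
      if (!sp.occ.empty() && max_d > 0) {
        ++stamp;
        for (size_t i = 0; i < sp.occ.size(); ++i) stamp_occ[sp.occ[i]] = stamp;
        std::vector<int> newcells;
        for (size_t i = 0; i < sp.occ.size(); ++i) {
          double u = sm64_unif(sp.rng);
          int d = 0;
          while (d < max_d && u >= cdf[d]) ++d;
          if (d == 0) continue;
          int c = sp.occ[i];
          int from = ball_ptr[c];
          int upto = from + ball_cnt(c, d - 1);
          for (int k = from; k < upto; ++k) {
            int cand = ball_cells[k];
            if (stamp_occ[cand] == stamp || stamp_cand[cand] == stamp) continue;
            stamp_cand[cand] = stamp;
            if (!land[cand]) continue;
            if (suitable(sp.env, tmax(cand, step), tmin(cand, step),
                         prcp(cand, step)))
              newcells.push_back(cand);
          }
        }
        if (!newcells.empty()) {
          std::sort(newcells.begin(), newcells.end());
          std::vector<int> merged;
          merged.reserve(sp.occ.size() + newcells.size());
          std::merge(sp.occ.begin(), sp.occ.end(),
                     newcells.begin(), newcells.end(),
                     std::back_inserter(merged));
          sp.occ.swap(merged);
        }
      }

      // (3) extinction: no suitable occupied habitat and no colonization
      if (sp.occ.empty()) {
        sp.status = 1;
        sp.end_step = step;
        sp.comps.clear();
        rec.ev_step.push_back(step); rec.ev_type.push_back(2);
        rec.ev_species.push_back(sp.id); rec.ev_detail.push_back(0);
        continue;
      }

      // (4) niche evolution on the current range
      double dv_t = 0, dv_p = 0, ce_t = 0, ce_p = 0, ed_t = 0, ed_p = 0;
      if (scenario_kind >= 1 && scenario_kind <= 3) {
        double s_t1 = 0, s_t0 = 0, s_p1 = 0, s_p0 = 0;
        for (size_t i = 0; i < sp.occ.size(); ++i) {
          int c = sp.occ[i];
          s_t1 += tmax(c, step); s_t0 += tmax(c, step - 1);
          s_p1 += prcp(c, step); s_p0 += prcp(c, step - 1);
        }
        double n = (double)sp.occ.size();
        dv_t = (s_t1 - s_t0) / n;
        dv_p = (s_p1 - s_p0) / n;
      } else if (scenario_kind >= 4) {
        ce_t = (2 * sm64_unif(sp.rng) - 1) * sp.nb0_temp * 0.01;
        ce_p = (2 * sm64_unif(sp.rng) - 1) * sp.nb0_prcp * 0.01;
        ed_t = (2 * sm64_unif(sp.rng) - 1) * sp.nb0_temp * 0.01;
        ed_p = (2 * sm64_unif(sp.rng) - 1) * sp.nb0_prcp * 0.01;
      }
      switch (scenario_kind) {
        case 0: break;
        case 1:  // directional shift
          sp.env[0] += rate_x * dv_t; sp.env[1] += rate_x * dv_t;
          sp.env[2] += rate_x * dv_t; sp.env[3] += rate_x * dv_t;
          sp.env[4] += rate_x * dv_p; sp.env[5] += rate_x * dv_p;
          break;
        case 2:  // directional expansion
          if (dv_t > 0) { sp.env[1] += rate_x * dv_t; sp.env[3] += rate_x * dv_t; }
          if (dv_t < 0) { sp.env[0] += rate_x * dv_t; sp.env[2] += rate_x * dv_t; }
          if (dv_p > 0) sp.env[5] += rate_x * dv_p;
          if (dv_p < 0) sp.env[4] += rate_x * dv_p;
          break;
        case 3:  // omnidirectional expansion
          sp.env[0] -= rate_x * std::abs(dv_t); sp.env[1] += rate_x * std::abs(dv_t);
          sp.env[2] -= rate_x * std::abs(dv_t); sp.env[3] += rate_x * std::abs(dv_t);
          sp.env[4] -= rate_x * std::abs(dv_p); sp.env[5] += rate_x * std::abs(dv_p);
          break;
        case 4:  // random shift
          sp.env[0] += ce_t; sp.env[1] += ce_t;
          sp.env[2] += ce_t; sp.env[3] += ce_t;
          sp.env[4] += ce_p; sp.env[5] += ce_p;
          break;
        case 5:  // random expansion/reduction
          sp.env[0] += ed_t; sp.env[1] -= ed_t;
          sp.env[2] += ed_t; sp.env[3] -= ed_t;
          sp.env[4] += ed_p; sp.env[5] -= ed_p;
          break;
        case 6:  // random change and shift
          sp.env[1] += ce_t + ed_t; sp.env[0] += ce_t - ed_t;
          sp.env[3] += ce_t + ed_t; sp.env[2] += ce_t - ed_t;
          sp.env[5] += ce_p + ed_p; sp.env[4] += ce_p - ed_p;
          break;
      }
      if (record_niche) {
        rec.ni_step.push_back(step); rec.ni_species.push_back(sp.id);
        for (int k = 0; k < 6; ++k) rec.ni_env.push_back(sp.env[k]);
        rec.ni_delta.push_back(dv_t); rec.ni_delta.push_back(dv_p);
        rec.ni_delta.push_back(ce_t); rec.ni_delta.push_back(ce_p);
        rec.ni_delta.push_back(ed_t); rec.ni_delta.push_back(ed_p);
      }

      // (5) connected components of the occupied set (BFS on adjacency,
      // i.e. the depth-1 prefix of each cell's neighbour ball)
      ++stamp;
      for (size_t i = 0; i < sp.occ.size(); ++i) stamp_occ[sp.occ[i]] = stamp;
      std::vector<std::vector<int> > cur;
      for (size_t i = 0; i < sp.occ.size(); ++i) {
        int c0 = sp.occ[i];
        if (comp_of[c0] >= 0 && stamp_cand[c0] == stamp) continue;
        // BFS from c0
        std::vector<int> cells;
        std::queue<int> q;
        q.push(c0);
        stamp_cand[c0] = stamp; comp_of[c0] = (int)cur.size();
        while (!q.empty()) {
          int c = q.front(); q.pop();
          cells.push_back(c);
          int from = ball_ptr[c];
          int upto = from + ball_cnt(c, 0);
          for (int k = from; k < upto; ++k) {
            int nb = ball_cells[k];
            if (stamp_occ[nb] == stamp &&
                !(stamp_cand[nb] == stamp)) {
              stamp_cand[nb] = stamp;
              comp_of[nb] = (int)cur.size();
              q.push(nb);
            }
          }
        }
        std::sort(cells.begin(), cells.end());
        cur.push_back(cells);
      }
      const int n_cur = (int)cur.size();
      const int n_prev = (int)sp.comps.size();

      // match previous components to current by maximal overlap
      std::vector<int> assigned_count(n_cur, 0), inherit_clock(n_cur, -1);
      bool merged_any = false;
      for (int p = 0; p < n_prev; ++p) {
        // count overlap of prev comp p with each current comp
        std::vector<int> ov(n_cur, 0);
        for (size_t i = 0; i < sp.comps[p].cells.size(); ++i) {
          int c = sp.comps[p].cells[i];
          if (stamp_cand[c] == stamp) ov[comp_of[c]]++;
        }
        int best = -1, bestov = 0;
        for (int q2 = 0; q2 < n_cur; ++q2) {
          if (ov[q2] > bestov) { bestov = ov[q2]; best = q2; }
        }
        if (best >= 0) {
          assigned_count[best]++;
          if (assigned_count[best] == 1) {
            inherit_clock[best] = sp.comps[p].clock;
          } else {
            merged_any = true;
          }
        }
      }
      // a clock ticks only if the component existed as one of >= 2
      // mutually isolated components over the whole step (n_prev >= 2)
      std::vector<Component> newcomps(n_cur);
      for (int q2 = 0; q2 < n_cur; ++q2) {
        newcomps[q2].cells.swap(cur[q2]);
        if (assigned_count[q2] == 1 && n_prev >= 2) {
          newcomps[q2].clock = inherit_clock[q2] + 1;
        } else {
          newcomps[q2].clock = 0;
        }
      }
      sp.comps.swap(newcomps);
      if (n_cur > n_prev) {
        rec.ev_step.push_back(step); rec.ev_type.push_back(3);
        rec.ev_species.push_back(sp.id); rec.ev_detail.push_back(n_cur);
      }
      if (merged_any) {
        rec.ev_step.push_back(step); rec.ev_type.push_back(4);
        rec.ev_species.push_back(sp.id); rec.ev_detail.push_back(n_cur);
      }

      // (6) speciation: some population has stayed isolated from the rest
      // of the species for >= threshold steps; the parent is replaced by
      // all of its current components (possibly multifurcating)
      if (n_cur >= 2) {
        int maxclock = sp.comps[0].clock;
        for (int q2 = 1; q2 < n_cur; ++q2)
          if (sp.comps[q2].clock > maxclock) maxclock = sp.comps[q2].clock;
        if (maxclock >= isolation_steps) {
          // copy parent state out first: appending daughters may reallocate
          // the population vector and invalidate the reference
          sp.status = 2;  // pseudo-extinct parent
          sp.end_step = step;
          const int parent_id = sp.id;
          double envc[6];
          for (int k = 0; k < 6; ++k) envc[k] = sp.env[k];
          const double nb0t = sp.nb0_temp, nb0p = sp.nb0_prcp;
          std::vector<Component> pcomps;
          pcomps.swap(sp.comps);
          sp.occ.clear();
          rec.ev_step.push_back(step); rec.ev_type.push_back(1);
          rec.ev_species.push_back(parent_id); rec.ev_detail.push_back(n_cur);
          for (int q2 = 0; q2 < n_cur; ++q2) {
            Species d;
            d.id = ++cumulative;
            d.parent = parent_id;
            d.origin_step = step;
            d.end_step = -1;
            d.status = 0;
            for (int k = 0; k < 6; ++k) d.env[k] = envc[k];
            d.nb0_temp = nb0t; d.nb0_prcp = nb0p;
            d.occ = pcomps[q2].cells;
            Component c; c.cells = pcomps[q2].cells; c.clock = 0;
            d.comps.push_back(c);
            d.rng = species_stream((uint64_t)run_seed, d.id);
            pop.push_back(d);
          }
          if (cumulative > max_species) aborted = true;
        }
      }
      if (aborted) break;
    }

    int extant = 0;
    for (size_t si = 0; si < pop.size(); ++si) {
      if (pop[si].status != 0) continue;
      ++extant;
      if (record_components) {
        rec.fr_step.push_back(step);
        rec.fr_species.push_back(pop[si].id);
        rec.fr_ncomp.push_back((int)pop[si].comps.size());
      }
      if (record_occupancy) {
        for (size_t i = 0; i < pop[si].occ.size(); ++i) {
          rec.oc_step.push_back(step);
          rec.oc_species.push_back(pop[si].id);
          rec.oc_cell.push_back(pop[si].occ[i] + 1);
        }
      }
    }
    richness[step] = extant;
    if (extant == 0) {
      for (int s2 = step + 1; s2 <= n_steps; ++s2) richness[s2] = 0;
      break;
    }
  }

  // species table and final occupancy
  int n_sp = (int)pop.size();
  IntegerVector sp_id(n_sp), sp_parent(n_sp), sp_origin(n_sp), sp_end(n_sp),
      sp_status(n_sp);
  NumericMatrix sp_env(n_sp, 6);
  List occupancy(n_sp);
  for (int i = 0; i < n_sp; ++i) {
    const Species &sp = pop[i];
    sp_id[i] = sp.id;
    sp_parent[i] = sp.parent == 0 ? NA_INTEGER : sp.parent;
    sp_origin[i] = sp.origin_step;
    sp_end[i] = sp.end_step < 0 ? NA_INTEGER : sp.end_step;
    sp_status[i] = sp.status;
    for (int k = 0; k < 6; ++k) sp_env(i, k) = sp.env[k];
    IntegerVector oc(sp.occ.size());
    for (size_t j = 0; j < sp.occ.size(); ++j) oc[j] = sp.occ[j] + 1;
    occupancy[i] = oc;
  }

  List out = List::create(
    _["species"] = List::create(
      _["species_id"] = sp_id, _["parent_id"] = sp_parent,
      _["origin_step"] = sp_origin, _["end_step"] = sp_end,
      _["status"] = sp_status),
    _["envelopes"] = sp_env,
    _["events"] = List::create(
      _["step"] = wrap(rec.ev_step), _["type"] = wrap(rec.ev_type),
      _["species_id"] = wrap(rec.ev_species),
      _["detail"] = wrap(rec.ev_detail)),
    _["richness"] = wrap(richness),
    _["occupancy"] = occupancy,
    _["cumulative"] = cumulative,
    _["aborted"] = aborted);
  if (record_components) {
    out["fragmentation"] = List::create(
      _["step"] = wrap(rec.fr_step), _["species_id"] = wrap(rec.fr_species),
      _["n_components"] = wrap(rec.fr_ncomp));
  }
  if (record_occupancy) {
    out["occupancy_steps"] = List::create(
      _["step"] = wrap(rec.oc_step), _["species_id"] = wrap(rec.oc_species),
      _["cell_id"] = wrap(rec.oc_cell));
  }
  if (record_niche) {
    int nr = (int)rec.ni_step.size();
    NumericMatrix env(nr, 6), del(nr, 6);
    for (int i = 0; i < nr; ++i) {
      for (int k = 0; k < 6; ++k) {
        env(i, k) = rec.ni_env[(size_t)i * 6 + k];
        del(i, k) = rec.ni_delta[(size_t)i * 6 + k];
      }
    }
    out["niche_trace"] = List::create(
      _["step"] = wrap(rec.ni_step), _["species_id"] = wrap(rec.ni_species),
      _["envelopes"] = env, _["deltas"] = del);
  }
  return out;
}
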