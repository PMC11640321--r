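// Compiled run engine for the huddling model.
//
// Semantics are defined by the R reference stepper in R/world.R; this
// engine replays them draw-for-draw on R's RNG stream (unif_rand), so a
// given seed yields the same trajectory in both engines. Spatial binning
// (cell width >= sensing radius, 3x3 neighbourhood scan) only changes
// which agents are examined, never the selected candidate.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Cluster {
  double ax, ay;
  std::vector<int> members; // 0-based agent indices, kept sorted
};

struct Params {
  int n, temperature, join_threshold, leave_threshold, step_cap;
  double w, h, radius;
};

// All trig goes through volatile function pointers: this stops the
// compiler fusing adjacent cos/sin pairs into sincos (whose results can
// differ in the last bit), so every call site — including the kernels
// exported to the R reference stepper — produces identical doubles.
double (*volatile cos_fn)(double) = ::cos;
double (*volatile sin_fn)(double) = ::sin;
inline double t_cos(double x) { return cos_fn(x); }
inline double t_sin(double x) { return sin_fn(x); }

inline double wrap_coord(double x, double width) {
  double v = x - std::floor(x / width) * width;
  if (v < 0) v += width;
  if (v >= width) v -= width;
  return v;
}

inline double torus_delta(double d, double width) {
  d = std::fabs(d);
  double a = width - d;
  return d < a ? d : a;
}

struct World {
  Params p;
  std::vector<double> x, y, heading;
  std::vector<int> cluster_id, huddle_time;
  std::map<int, Cluster> clusters;
  int next_cid = 0, tick = 0, n_lone = 0;
  int max_size = 0; // size of the largest active cluster

  void recompute_max_size() {
    max_size = 0;
    for (std::map<int, Cluster>::const_iterator it = clusters.begin();
         it != clusters.end(); ++it) {
      int m = (int)it->second.members.size();
      if (m > max_size) max_size = m;
    }
  }

  // spatial bins
  int ncx, ncy;
  double cellw, cellh;
  std::vector<std::vector<int> > cells;
  std::vector<int> cell_of;

  void init_bins() {
    ncx = std::max(1, (int)std::floor(p.w / p.radius));
    ncy = std::max(1, (int)std::floor(p.h / p.radius));
    cellw = p.w / ncx;
    cellh = p.h / ncy;
    cells.assign(ncx * ncy, std::vector<int>());
    cell_of.assign(p.n, -1);
    for (int i = 0; i < p.n; ++i) bin_insert(i);
  }
  int cell_index(double xi, double yi) const {
    int cx = (int)(xi / cellw);
    if (cx >= ncx) cx = ncx - 1;
    int cy = (int)(yi / cellh);
    if (cy >= ncy) cy = ncy - 1;
    return cy * ncx + cx;
  }
  void bin_insert(int i) {
    int c = cell_index(x[i], y[i]);
    cell_of[i] = c;
    cells[c].push_back(i);
  }
  void bin_remove(int i) {
    std::vector<int>& v = cells[cell_of[i]];
    v.erase(std::find(v.begin(), v.end(), i));
  }
  void move_agent_to(int i, double nx, double ny) {
    int c = cell_index(nx, ny);
    if (c != cell_of[i]) {
      bin_remove(i);
      x[i] = nx; y[i] = ny;
      cell_of[i] = c;
      cells[c].push_back(i);
    } else {
      x[i] = nx; y[i] = ny;
    }
  }

  double p_join(int n_ci) const {
    return ((double)n_ci / (double)p.n) * (1.0 / (double)p.temperature) *
           (1.0 / (double)p.join_threshold);
  }
  double p_leave(int n_ci) const {
    return ((double)(p.n - n_ci) / (double)p.n) *
           (1.0 / (double)p.leave_threshold);
  }

  void update_cluster_positions(int cid) {
    Cluster& c = clusters[cid];
    int m = (int)c.members.size();
    double r = std::min(1.0, p.radius / 2.0);
    for (int k = 0; k < m; ++k) {
      double theta = 2.0 * M_PI * (double)k / (double)m;
      int id = c.members[k];
      move_agent_to(id, wrap_coord(c.ax + r * t_cos(theta), p.w),
                    wrap_coord(c.ay + r * t_sin(theta), p.h));
    }
  }

  // Largest cluster in sensing range (ties: lowest id); else lone agent
  // with lowest id; else none. type: 0 none, 1 cluster, 2 lone.
  void find_candidate(int i, int& type, int& id, int& size) const {
    double r2 = p.radius * p.radius;
    int best_cid = -1, best_size = -1, best_lone = -1;
    int cx = cell_of[i] % ncx, cy = cell_of[i] / ncx;
    for (int dy = -1; dy <= 1; ++dy) {
      int yy = (cy + dy + ncy) % ncy;
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = (cx + dx + ncx) % ncx;
        const std::vector<int>& v = cells[yy * ncx + xx];
        for (size_t t = 0; t < v.size(); ++t) {
          int j = v[t];
          if (j == i) continue;
          double ddx = torus_delta(x[i] - x[j], p.w);
          double ddy = torus_delta(y[i] - y[j], p.h);
          if (ddx * ddx + ddy * ddy > r2) continue;
          int cj = cluster_id[j];
          if (cj >= 0) {
            int sz = (int)clusters.at(cj).members.size();
            if (sz > best_size || (sz == best_size && cj < best_cid)) {
              best_size = sz;
              best_cid = cj;
            }
          } else if (best_lone < 0 || j < best_lone) {
            best_lone = j;
          }
        }
      }
    }
    if (best_cid >= 0) {
      type = 1; id = best_cid; size = best_size;
    } else if (best_lone >= 0) {
      type = 2; id = best_lone; size = 1;
    } else {
      type = 0; id = -1; size = 0;
    }
  }

  void join_cluster(int i, int cid) {
    Cluster& c = clusters[cid];
    c.members.push_back(i);
    std::sort(c.members.begin(), c.members.end());
    cluster_id[i] = cid;
    huddle_time[i] = 0;
    --n_lone;
    if ((int)c.members.size() > max_size) max_size = (int)c.members.size();
    update_cluster_positions(cid);
  }

  void nucleate(int i, int partner) {
    int nid = next_cid++;
    Cluster c;
    c.ax = x[i];
    c.ay = y[i];
    c.members.push_back(std::min(i, partner));
    c.members.push_back(std::max(i, partner));
    clusters[nid] = c;
    cluster_id[i] = nid;
    cluster_id[partner] = nid;
    huddle_time[i] = 0;
    huddle_time[partner] = 0;
    n_lone -= 2;
    if (max_size < 2) max_size = 2;
    update_cluster_positions(nid);
  }

  void leave_cluster(int i) {
    int cid = cluster_id[i];
    Cluster& c = clusters[cid];
    int old_size = (int)c.members.size();
    cluster_id[i] = -1;
    huddle_time[i] = 0;
    ++n_lone;
    c.members.erase(std::find(c.members.begin(), c.members.end(), i));
    if (c.members.size() == 1) {
      int other = c.members[0];
      cluster_id[other] = -1;
      huddle_time[other] = 0;
      ++n_lone;
      clusters.erase(cid);
    } else {
      update_cluster_positions(cid);
    }
    if (old_size == max_size) recompute_max_size();
  }

  void do_tick(std::vector<int>& perm) {
    int n = p.n;
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n; i >= 2; --i) {
      int j = (int)std::floor(unif_rand() * (double)i);
      if (j > i - 1) j = i - 1;
      std::swap(perm[i - 1], perm[j]);
    }
    for (int k = 0; k < n; ++k) {
      int id = perm[k];
      if (cluster_id[id] == -1) {
        double hh = (unif_rand() * 2.0) * M_PI;
        heading[id] = hh;
        move_agent_to(id, wrap_coord(x[id] + t_cos(hh), p.w),
                      wrap_coord(y[id] + t_sin(hh), p.h));
        double u = unif_rand(); // decision draw, consumed unconditionally
        // The candidate search consumes no draws, so it can be skipped
        // whenever the draw already exceeds the best possible join
        // probability (bounded by the largest active cluster's size).
        if (u < p_join(max_size > 1 ? max_size : 1)) {
          int type, cid, size;
          find_candidate(id, type, cid, size);
          if (type != 0 && u < p_join(size)) {
            if (type == 1)
              join_cluster(id, cid);
            else
              nucleate(id, cid);
          }
        }
      } else {
        double u = unif_rand();
        int sz = (int)clusters.at(cluster_id[id]).members.size();
        if (u < p_leave(sz))
          leave_cluster(id);
        else
          ++huddle_time[id];
      }
    }
    ++tick;
  }
};

} // namespace

// Trig kernels shared with the R reference stepper, so both engines use
// bit-identical cos/sin (libm builds can differ by an ulp between
// compilation units, which would break trajectory equality).
// [[Rcpp::export(name = ".sim_cos")]]
NumericVector sim_cos(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = t_cos(x[i]);
  return out;
}

// [[Rcpp::export(name = ".sim_sin")]]
NumericVector sim_sin(NumericVector x) {
  NumericVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = t_sin(x[i]);
  return out;
}

// Run the simulation with the current R RNG state (caller set.seed()s).
// force_ticks >= 0 runs exactly that many ticks with no termination check
// (used by the R-vs-compiled equivalence tests); force_ticks < 0 runs to
// termination (all agents huddled, or tick == step_cap).
// [[Rcpp::export(name = ".sim_run_cpp")]]
List sim_run_cpp(List params, int force_ticks = -1,
                 bool return_state = false) {
  World w;
  w.p.n = as<int>(params["group_size"]);
  w.p.temperature = as<int>(params["temperature"]);
  w.p.join_threshold = as<int>(params["join_threshold"]);
  w.p.leave_threshold = as<int>(params["leave_threshold"]);
  w.p.w = (double)as<int>(params["grid_width"]);
  w.p.h = (double)as<int>(params["grid_height"]);
  w.p.radius = as<double>(params["sensing_radius"]);
  w.p.step_cap = as<int>(params["step_cap"]);

  int n = w.p.n;
  w.x.resize(n);
  w.y.resize(n);
  w.heading.resize(n);
  w.cluster_id.assign(n, -1);
  w.huddle_time.assign(n, 0);
  w.n_lone = n;

  // RNG scope is provided by the Rcpp attributes wrapper
  for (int i = 0; i < n; ++i) {
    w.x[i] = unif_rand() * w.p.w;
    w.y[i] = unif_rand() * w.p.h;
    w.heading[i] = (unif_rand() * 2.0) * M_PI;
  }
  w.init_bins();

  std::vector<int> perm(n);
  if (force_ticks >= 0) {
    for (int t = 0; t < force_ticks; ++t) w.do_tick(perm);
  } else {
    while (w.tick < w.p.step_cap && w.n_lone > 0) {
      w.do_tick(perm);
      if ((w.tick & 1023) == 0) Rcpp::checkUserInterrupt();
    }
  }

  int nc = (int)w.clusters.size();
  IntegerVector sizes(nc), cids(nc);
  int k = 0;
  for (std::map<int, Cluster>::const_iterator it = w.clusters.begin();
       it != w.clusters.end(); ++it, ++k) {
    cids[k] = it->first;
    sizes[k] = (int)it->second.members.size();
  }

  List out = List::create(
      _["steps_elapsed"] = w.tick, _["n_lone"] = w.n_lone,
      _["cluster_ids"] = cids, _["cluster_sizes"] = sizes);
  if (return_state) {
    NumericVector ax(nc), ay(nc);
    List members(nc);
    k = 0;
    for (std::map<int, Cluster>::const_iterator it = w.clusters.begin();
         it != w.clusters.end(); ++it, ++k) {
      ax[k] = it->second.ax;
      ay[k] = it->second.ay;
      IntegerVector mem(it->second.members.size());
      for (size_t t = 0; t < it->second.members.size(); ++t)
        mem[t] = it->second.members[t] + 1; // back to 1-based agent ids
      members[k] = mem;
    }
    out["agents"] = DataFrame::create(
        _["agent_id"] = seq_len(n), _["x"] = NumericVector(w.x.begin(), w.x.end()),
        _["y"] = NumericVector(w.y.begin(), w.y.end()),
        _["heading"] = NumericVector(w.heading.begin(), w.heading.end()),
        _["cluster_id"] = IntegerVector(w.cluster_id.begin(), w.cluster_id.end()),
        _["huddle_time"] = IntegerVector(w.huddle_time.begin(), w.huddle_time.end()));
    out["anchor_x"] = ax;
    out["anchor_y"] = ay;
    out["members"] = members;
    out["next_cluster_id"] = w.next_cid;
  }
  return out;
}
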