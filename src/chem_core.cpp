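// Four-kernel diffusion-reaction loop for the chemical stage.
//
// Kernel 1: candidate-pair search + contact reactions (d < R), greedy
//           conflict resolution by increasing distance, stable index ties.
// Kernel 2: dynamic time step dt = (d_min - R)^2 / (8 (sqrt(DA)+sqrt(DB))^2)
//           for the minimal-distance surviving pair, clamped below at dt_min
//           and capped at the next output time.
// Kernel 3: Gaussian diffusion, per-axis sd sqrt(2 D dt); molecules leaving
//           the box are removed permanently.
// Kernel 4: Brownian-bridge encounter check, run only when the step taken
//           exceeds the safe step: p = exp(-(d_i-R)(d_f-R)/((DA+DB) dt)).
//
// The pair search uses a hashed cell grid with cutoff `w1` (w1 covers the
// contact radii and every bridge pair whose acceptance probability exceeds
// p_floor); the global minimum pair distance is recovered exactly by
// widening the cutoff until a reactive pair is found or the implied
// time-step lower bound exceeds the checkpoint cap. RNG draws come from R's
// stream in a fixed order (diffusion in storage order, x/y/z per molecule;
// one uniform per bridge pair with p > p_floor, those pairs ordered by
// index), so the exhaustive reference implementation in R consumes an
// identical stream. Products created in a step join the search next step.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Pair {
  int i, j, rx;   // molecule indices, reaction row (0-based)
  double d2;
};

inline int64_t cell_key(int ix, int iy, int iz) {
  const int64_t B = 1 << 20;  // pack 21-bit offset coordinates
  return ((int64_t)(ix + B) << 42) | ((int64_t)(iy + B) << 21) | (int64_t)(iz + B);
}

// half neighborhood: self + 13 forward offsets, so each cell pair is
// visited exactly once
static const int HALF_OFF[14][3] = {
  {0, 0, 0},
  {1, 0, 0}, {-1, 1, 0}, {0, 1, 0}, {1, 1, 0},
  {-1, -1, 1}, {0, -1, 1}, {1, -1, 1},
  {-1, 0, 1}, {0, 0, 1}, {1, 0, 1},
  {-1, 1, 1}, {0, 1, 1}, {1, 1, 1}
};

typedef std::unordered_map<int64_t, std::vector<int> > CellMap;

struct Engine {
  std::vector<double> x, y, z;
  std::vector<int> spec;
  std::vector<char> alive;
  std::vector<int> pair_tab;   // S x S reaction row + 1, 0 = none
  int S;
  CellMap cells;

  void build(double h, int n_limit) {
    cells.clear();
    for (int i = 0; i < n_limit; ++i) {
      if (!alive[i]) continue;
      cells[cell_key((int)std::floor(x[i] / h), (int)std::floor(y[i] / h),
                     (int)std::floor(z[i] / h))].push_back(i);
    }
  }

  inline int rx_of(int a, int b) const { return pair_tab[spec[a] * S + spec[b]]; }

  inline double d2_of(int a, int b) const {
    double ddx = x[a] - x[b], ddy = y[a] - y[b], ddz = z[a] - z[b];
    return ddx * ddx + ddy * ddy + ddz * ddz;
  }

  // all reactive pairs within cutoff (grid must be built with h >= cutoff)
  void scan_pairs(double cutoff2, std::vector<Pair>& out) const {
    for (CellMap::const_iterator kv = cells.begin(); kv != cells.end(); ++kv) {
      int64_t key = kv->first;
      int ix = (int)((key >> 42) & 0x1FFFFF) - (1 << 20);
      int iy = (int)((key >> 21) & 0x1FFFFF) - (1 << 20);
      int iz = (int)(key & 0x1FFFFF) - (1 << 20);
      for (int o = 0; o < 14; ++o) {
        CellMap::const_iterator it =
          cells.find(cell_key(ix + HALF_OFF[o][0], iy + HALF_OFF[o][1],
                              iz + HALF_OFF[o][2]));
        if (it == cells.end()) continue;
        const std::vector<int>& A = kv->second;
        const std::vector<int>& B = it->second;
        const bool same = (o == 0);
        for (size_t ai = 0; ai < A.size(); ++ai) {
          int a = A[ai];
          for (size_t bi = same ? ai + 1 : 0; bi < B.size(); ++bi) {
            int b = B[bi];
            int rx = rx_of(a, b);
            if (!rx) continue;
            double d2 = d2_of(a, b);
            if (d2 <= cutoff2) {
              Pair p = {a < b ? a : b, a < b ? b : a, rx - 1, d2};
              out.push_back(p);
            }
          }
        }
      }
    }
  }
};

inline bool pair_lt(const Pair& u, const Pair& v) {
  if (u.d2 != v.d2) return u.d2 < v.d2;
  if (u.i != v.i) return u.i < v.i;
  return u.j < v.j;
}

}  // namespace

// [[Rcpp::export(name = ".chem_run_cpp")]]
List chem_run_cpp(NumericMatrix pos0, IntegerVector species0,
                  NumericVector D_nm2_ps, IntegerMatrix pair_table,
                  NumericVector radius_nm, NumericVector D_sum_nm2_ps,
                  IntegerMatrix prod_table, IntegerVector n_products,
                  IntegerVector react_a,
                  NumericVector box_lo, NumericVector box_hi,
                  double t0, double dt_min, NumericVector sample_times,
                  double p_floor, double w1, double max_iter,
                  bool use_grid) {
  const int S = D_nm2_ps.size();
  const int NR = radius_nm.size();
  const int n0 = pos0.nrow();
  Engine eng;
  eng.S = S;
  eng.pair_tab.resize(S * S);
  for (int a = 0; a < S; ++a)
    for (int b = 0; b < S; ++b) eng.pair_tab[a * S + b] = pair_table(a, b);
  eng.x.reserve(n0 * 2); eng.y.reserve(n0 * 2); eng.z.reserve(n0 * 2);
  eng.spec.reserve(n0 * 2); eng.alive.reserve(n0 * 2);
  for (int i = 0; i < n0; ++i) {
    eng.x.push_back(pos0(i, 0)); eng.y.push_back(pos0(i, 1));
    eng.z.push_back(pos0(i, 2));
    eng.spec.push_back(species0[i] - 1);
    eng.alive.push_back(1);
  }
  std::vector<double> Dsp(D_nm2_ps.begin(), D_nm2_ps.end());
  std::vector<double> sqrtD(S);
  for (int s = 0; s < S; ++s) sqrtD[s] = std::sqrt(Dsp[s]);
  double rmax = 0.0, dmax = 0.0, r2max = 0.0;
  for (int r = 0; r < NR; ++r) rmax = std::max(rmax, radius_nm[r]);
  r2max = rmax * rmax;
  for (int s = 0; s < S; ++s) dmax = std::max(dmax, Dsp[s]);

  const int NT = sample_times.size();
  NumericMatrix counts(S, NT);
  NumericMatrix reac_counts(NR, NT);  // events binned to the next sample time
  std::vector<double> pend_reac(NR, 0.0);
  double n_exited = 0.0, n_steps = 0.0;

  double t = t0;
  int next_sample = 0;
  std::vector<Pair> cand, sub;
  std::vector<double> px, py, pz;     // pre-diffusion snapshot

  auto record = [&](int k) {
    for (size_t i = 0; i < eng.spec.size(); ++i)
      if (eng.alive[i]) counts(eng.spec[i], k) += 1.0;
    for (int r = 0; r < NR; ++r) {
      reac_counts(r, k) = pend_reac[r]; pend_reac[r] = 0.0;
    }
  };
  while (next_sample < NT && sample_times[next_sample] <= t + 1e-9) {
    record(next_sample); ++next_sample;
  }

  // effective parent positions: ea belongs to the molecule matching the
  // reaction's first reactant (stable product assignment)
  auto apply_event = [&](int i, int j, int rx, double eax, double eay, double eaz,
                         double ebx, double eby, double ebz) {
    eng.alive[i] = 0; eng.alive[j] = 0;
    pend_reac[rx] += 1.0;
    const int np = n_products[rx];
    const double mx = 0.5 * (eax + ebx), my = 0.5 * (eay + eby),
                 mz = 0.5 * (eaz + ebz);
    for (int p = 0; p < np; ++p) {
      double qx, qy, qz;
      if (np == 1) { qx = mx; qy = my; qz = mz; }
      else if (p == 0) { qx = eax; qy = eay; qz = eaz; }
      else if (p == 1) { qx = ebx; qy = eby; qz = ebz; }
      else { qx = mx; qy = my; qz = mz; }
      eng.x.push_back(qx); eng.y.push_back(qy); eng.z.push_back(qz);
      eng.spec.push_back(prod_table(rx, p) - 1); eng.alive.push_back(1);
    }
  };

  const double t_end = sample_times[NT - 1];
  long iter = 0;
  const double w1sq = w1 * w1;
  while (next_sample < NT && t < t_end - 1e-12) {
    if (++iter > (long)max_iter)
      stop("chemical stage exceeded max_iter steps");
    const int n_pre = (int)eng.x.size();

    // ---- Kernel 1: candidate pairs + contact reactions -------------------
    cand.clear();
    if (use_grid) {
      eng.build(w1, n_pre);
      eng.scan_pairs(w1sq, cand);
    } else {
      for (int a = 0; a < n_pre; ++a) {
        if (!eng.alive[a]) continue;
        for (int b = a + 1; b < n_pre; ++b) {
          if (!eng.alive[b]) continue;
          int rx = eng.rx_of(a, b);
          if (!rx) continue;
          Pair p = {a, b, rx - 1, eng.d2_of(a, b)};
          cand.push_back(p);
        }
      }
    }
    // contacts: the (small) subset with d < R, greedy in increasing distance
    sub.clear();
    for (const Pair& p : cand) {
      if (p.d2 < r2max && p.d2 < radius_nm[p.rx] * radius_nm[p.rx])
        sub.push_back(p);
    }
    std::sort(sub.begin(), sub.end(), pair_lt);
    for (const Pair& p : sub) {
      if (!eng.alive[p.i] || !eng.alive[p.j]) continue;
      int i = p.i, j = p.j;
      if (eng.spec[i] != react_a[p.rx] - 1) std::swap(i, j);
      apply_event(i, j, p.rx, eng.x[i], eng.y[i], eng.z[i],
                  eng.x[j], eng.y[j], eng.z[j]);
    }

    // ---- Kernel 2: time step --------------------------------------------
    double cap = sample_times[next_sample] - t;
    double dt_raw = R_PosInf;
    {
      const Pair* best = NULL;
      for (const Pair& p : cand) {
        if (!eng.alive[p.i] || !eng.alive[p.j]) continue;
        if (best == NULL || pair_lt(p, *best)) best = &p;
      }
      if (best != NULL) {
        double R = radius_nm[best->rx];
        double d = std::sqrt(best->d2);
        double ss = sqrtD[eng.spec[best->i]] + sqrtD[eng.spec[best->j]];
        dt_raw = (d - R) * (d - R) / (8 * (ss * ss));
      }
    }
    if (dt_raw == R_PosInf && use_grid) {
      // no surviving pair within w1: widen until a reactive pair is found
      // or the implied lower bound on dt exceeds the cap
      double W = w1;
      std::vector<Pair> far;
      while (true) {
        double gap = W - rmax;
        if (gap > 0.0 && (gap * gap) / (32 * dmax) >= cap) break;
        W *= 4.0;
        eng.build(W, n_pre);
        far.clear();
        eng.scan_pairs(W * W, far);
        const Pair* best = NULL;
        for (const Pair& p : far) {
          if (!eng.alive[p.i] || !eng.alive[p.j]) continue;
          if (best == NULL || pair_lt(p, *best)) best = &p;
        }
        if (best != NULL) {
          double R = radius_nm[best->rx];
          double d = std::sqrt(best->d2);
          double ss = sqrtD[eng.spec[best->i]] + sqrtD[eng.spec[best->j]];
          dt_raw = (d - R) * (d - R) / (8 * (ss * ss));
          break;
        }
      }
    }
    double dt = dt_raw;
    if (dt < dt_min) dt = dt_min;
    if (dt > cap) dt = cap;
    const bool clamped = (dt > dt_raw);

    // ---- Kernel 3: diffusion --------------------------------------------
    if (clamped) {
      px.assign(eng.x.begin(), eng.x.end());
      py.assign(eng.y.begin(), eng.y.end());
      pz.assign(eng.z.begin(), eng.z.end());
    }
    const int n_now = (int)eng.x.size();
    for (int i = 0; i < n_now; ++i) {
      if (!eng.alive[i]) continue;
      double sd = std::sqrt(2 * Dsp[eng.spec[i]] * dt);
      eng.x[i] += norm_rand() * sd;
      eng.y[i] += norm_rand() * sd;
      eng.z[i] += norm_rand() * sd;
      if (eng.x[i] < box_lo[0] || eng.x[i] > box_hi[0] ||
          eng.y[i] < box_lo[1] || eng.y[i] > box_hi[1] ||
          eng.z[i] < box_lo[2] || eng.z[i] > box_hi[2]) {
        eng.alive[i] = 0; n_exited += 1.0;
      }
    }

    // ---- Kernel 4: Brownian bridge --------------------------------------
    if (clamped) {
      // qualifying pairs (p > p_floor) drawn in index order; the set is
      // RNG-free, so engines enumerating pairs differently still agree
      struct Qual { int i, j, rx; double prob, df; };
      std::vector<Qual> qual;
      for (const Pair& p : cand) {
        if (!eng.alive[p.i] || !eng.alive[p.j]) continue;
        double R = radius_nm[p.rx];
        double di = std::sqrt(p.d2);
        double df = std::sqrt(eng.d2_of(p.i, p.j));
        double prob;
        if (di <= R || df <= R) prob = 1.0;
        else prob = std::exp(-((di - R) * (df - R) / (D_sum_nm2_ps[p.rx] * dt)));
        if (prob > p_floor) { Qual q = {p.i, p.j, p.rx, prob, df}; qual.push_back(q); }
      }
      std::sort(qual.begin(), qual.end(), [](const Qual& u, const Qual& v) {
        if (u.i != v.i) return u.i < v.i;
        return u.j < v.j;
      });
      std::vector<Qual> acc;
      for (const Qual& q : qual)
        if (unif_rand() < q.prob) acc.push_back(q);
      std::sort(acc.begin(), acc.end(), [](const Qual& u, const Qual& v) {
        if (u.df != v.df) return u.df < v.df;
        if (u.i != v.i) return u.i < v.i;
        return u.j < v.j;
      });
      for (const Qual& a : acc) {
        if (!eng.alive[a.i] || !eng.alive[a.j]) continue;
        int i = a.i, j = a.j;
        if (eng.spec[i] != react_a[a.rx] - 1) std::swap(i, j);
        apply_event(i, j, a.rx,
                    0.5 * (px[i] + eng.x[i]), 0.5 * (py[i] + eng.y[i]),
                    0.5 * (pz[i] + eng.z[i]),
                    0.5 * (px[j] + eng.x[j]), 0.5 * (py[j] + eng.y[j]),
                    0.5 * (pz[j] + eng.z[j]));
      }
    }

    t += dt;
    n_steps += 1.0;
    while (next_sample < NT && sample_times[next_sample] <= t + 1e-9) {
      record(next_sample);
      ++next_sample;
    }
  }
  while (next_sample < NT) { record(next_sample); ++next_sample; }

  const int n = (int)eng.x.size();
  NumericMatrix fin(n, 3);
  IntegerVector fspec(n);
  LogicalVector fal(n);
  for (int i = 0; i < n; ++i) {
    fin(i, 0) = eng.x[i]; fin(i, 1) = eng.y[i]; fin(i, 2) = eng.z[i];
    fspec[i] = eng.spec[i] + 1; fal[i] = eng.alive[i] != 0;
  }
  return List::create(_["counts"] = counts,
                      _["reaction_events"] = reac_counts,
                      _["n_exited"] = n_exited,
                      _["n_steps"] = n_steps,
                      _["pos"] = fin, _["species"] = fspec, _["alive"] = fal);
}
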