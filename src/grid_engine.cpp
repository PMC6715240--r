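#include <Rcpp.h>
#include <unordered_map>
#include <cstdlib>
using namespace Rcpp;

// Occupancy is tracked in a hash map keyed by the packed (x, y) pair, so the
// plane never has to be materialized and coordinates may be arbitrary ints.
static inline long long pack_xy(int x, int y) {
  return (static_cast<long long>(x) << 32) ^ static_cast<unsigned int>(y);
}

// Scan order N, NE, E, SE, S, SW, W, NW with y pointing down (screen
// convention); the 4-neighbourhood keeps the N, E, S, W subsequence.
static const int DX8[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int DY8[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DX4[4] = {0, 1, 0, -1};
static const int DY4[4] = {-1, 0, 1, 0};

typedef std::unordered_map<long long, int> OccMap;

static OccMap build_occ(const IntegerMatrix& pos) {
  OccMap occ;
  for (int i = 0; i < pos.nrow(); ++i) {
    long long key = pack_xy(pos(i, 0), pos(i, 1));
    if (occ.count(key))
      stop("two entities occupy the same grid point");
    occ[key] = i;
  }
  return occ;
}

static double cost_impl(const IntegerMatrix& pos, const NumericMatrix& w) {
  const int n = pos.nrow();
  double c = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double wij = w(i, j);
      if (wij != 0.0)
        c += wij * (std::abs(pos(i, 0) - pos(j, 0)) +
                    std::abs(pos(i, 1) - pos(j, 1)));
    }
  return c;
}

// One sweep of steepest single-entity descent in entity order.  For each
// entity the vacant in-bounds neighbours are scored and the move with the
// largest strictly negative cost change is committed; ties go to the first
// direction in scan order.  Returns whether any entity moved.
static bool sweep_once(IntegerMatrix& pos, const NumericMatrix& w,
                       const IntegerMatrix& bounds, OccMap& occ, bool moore) {
  const int n = pos.nrow();
  const int ndir = moore ? 8 : 4;
  const int* DX = moore ? DX8 : DX4;
  const int* DY = moore ? DY8 : DY4;
  bool moved = false;
  for (int i = 0; i < n; ++i) {
    const int x = pos(i, 0), y = pos(i, 1);
    double best = -1e-9;  // strict improvement required
    int bx = 0, by = 0;
    bool found = false;
    for (int d = 0; d < ndir; ++d) {
      const int nx = x + DX[d], ny = y + DY[d];
      if (nx < bounds(i, 0) || nx > bounds(i, 1) ||
          ny < bounds(i, 2) || ny > bounds(i, 3))
        continue;
      if (occ.count(pack_xy(nx, ny)))
        continue;
      double delta = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double wij = w(i, j);
        if (wij == 0.0) continue;
        delta += wij *
          ((std::abs(nx - pos(j, 0)) + std::abs(ny - pos(j, 1))) -
           (std::abs(x - pos(j, 0)) + std::abs(y - pos(j, 1))));
      }
      if (delta < best) {
        best = delta;
        bx = nx;
        by = ny;
        found = true;
      }
    }
    if (found) {
      occ.erase(pack_xy(x, y));
      occ[pack_xy(bx, by)] = i;
      pos(i, 0) = bx;
      pos(i, 1) = by;
      moved = true;
    }
  }
  return moved;
}

static void partial_optimize_impl(IntegerMatrix& pos, const NumericMatrix& w,
                                  const IntegerMatrix& bounds, OccMap& occ,
                                  bool moore) {
  while (sweep_once(pos, w, bounds, occ, moore))
    ;
}

// Each entity independently, with probability prob, jumps to a uniformly
// chosen vacant in-bounds neighbour (no move when none is vacant).  Uses R's
// RNG stream so set.seed() governs the result.
static void perturb_impl(IntegerMatrix& pos, double prob,
                         const IntegerMatrix& bounds, OccMap& occ,
                         bool moore) {
  const int n = pos.nrow();
  const int ndir = moore ? 8 : 4;
  const int* DX = moore ? DX8 : DX4;
  const int* DY = moore ? DY8 : DY4;
  int cx[8], cy[8];
  for (int i = 0; i < n; ++i) {
    if (unif_rand() >= prob)
      continue;
    const int x = pos(i, 0), y = pos(i, 1);
    int k = 0;
    for (int d = 0; d < ndir; ++d) {
      const int nx = x + DX[d], ny = y + DY[d];
      if (nx < bounds(i, 0) || nx > bounds(i, 1) ||
          ny < bounds(i, 2) || ny > bounds(i, 3))
        continue;
      if (occ.count(pack_xy(nx, ny)))
        continue;
      cx[k] = nx;
      cy[k] = ny;
      ++k;
    }
    if (k == 0)
      continue;
    int pick = static_cast<int>(unif_rand() * k);
    if (pick >= k) pick = k - 1;
    occ.erase(pack_xy(x, y));
    occ[pack_xy(cx[pick], cy[pick])] = i;
    pos(i, 0) = cx[pick];
    pos(i, 1) = cy[pick];
  }
}

// [[Rcpp::export]]
double grid_cost_cpp(IntegerMatrix pos, NumericMatrix w) {
  return cost_impl(pos, w);
}

// [[Rcpp::export]]
IntegerMatrix grid_partial_optimize_cpp(IntegerMatrix pos, NumericMatrix w,
                                        IntegerMatrix bounds, bool moore) {
  IntegerMatrix p = clone(pos);
  OccMap occ = build_occ(p);
  partial_optimize_impl(p, w, bounds, occ, moore);
  return p;
}

// [[Rcpp::export]]
IntegerMatrix grid_perturb_cpp(IntegerMatrix pos, double prob,
                               IntegerMatrix bounds, bool moore) {
  IntegerMatrix p = clone(pos);
  OccMap occ = build_occ(p);
  perturb_impl(p, prob, bounds, occ, moore);
  return p;
}

// Reoptimization after perturbation: locally optimize, then repeatedly kick
// the incumbent and re-optimize, keeping the candidate only when its cost is
// strictly lower.
// [[Rcpp::export]]
IntegerMatrix grid_reoptimize_cpp(IntegerMatrix pos, NumericMatrix w,
                                  IntegerMatrix bounds, int niter,
                                  double prob, bool moore) {
  IntegerMatrix best = clone(pos);
  {
    OccMap occ = build_occ(best);
    partial_optimize_impl(best, w, bounds, occ, moore);
  }
  double best_cost = cost_impl(best, w);
  for (int it = 0; it < niter; ++it) {
    if (it % 64 == 0)
      Rcpp::checkUserInterrupt();
    IntegerMatrix cand = clone(best);
    OccMap occ = build_occ(cand);
    perturb_impl(cand, prob, bounds, occ, moore);
    partial_optimize_impl(cand, w, bounds, occ, moore);
    const double c = cost_impl(cand, w);
    if (c < best_cost - 1e-9) {
      best = cand;
      best_cost = c;
    }
  }
  return best;
}
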