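// Finite-horizon backward induction over the foraging decision tree.
//
// A state is (time remaining, per-area knowledge, location).  Knowledge is a
// richness code per area (0 unknown, 1 rich, 2 poor) plus the number of boxes
// already taken there; location is -1 for the central zone (pre-first-action
// only) or an area index 0..3.  Values are coins-to-go: terminal nodes are 0.
// Unknown areas branch stochastically on first entry; the posterior that the
// entered area is rich follows the urn of 2 rich + 2 poor areas, i.e.
// p = (2 - #revealed rich) / (4 - #revealed).  Forced inferences (two areas of
// the same type revealed) are applied before every lookup, so memo keys are
// canonical.  Time enters the memo key quantized at 1e-6 s for hashing only;
// all arithmetic is done in double precision.

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

class Solver {
public:
  double T1, T2, battery;
  bool mixedEnv;     // false: all four areas rich (label known via sensor)
  bool firstCostT1;  // cost of entering an area from the central zone
  std::vector<int> richSeq, poorSeq;
  int nBoxes;
  std::unordered_map<uint64_t, double> memo;

  Solver(double t1, double t2, double bat, bool mixed, bool fc1,
         std::vector<int> rs, std::vector<int> ps)
    : T1(t1), T2(t2), battery(bat), mixedEnv(mixed), firstCostT1(fc1),
      richSeq(rs), poorSeq(ps), nBoxes(static_cast<int>(rs.size())) {}

  void closure(int rz[4]) const {
    if (!mixedEnv) {
      for (int i = 0; i < 4; ++i) if (rz[i] == 0) rz[i] = 1;
      return;
    }
    int r = 0, p = 0;
    for (int i = 0; i < 4; ++i) { if (rz[i] == 1) ++r; else if (rz[i] == 2) ++p; }
    if (r >= 2) { for (int i = 0; i < 4; ++i) if (rz[i] == 0) rz[i] = 2; }
    else if (p >= 2) { for (int i = 0; i < 4; ++i) if (rz[i] == 0) rz[i] = 1; }
  }

  int coin(int rz, int b) const {
    return rz == 1 ? richSeq[b] : poorSeq[b];
  }

  uint64_t key(double t, const int rz[4], const int bx[4], int loc) const {
    uint64_t s = 0;
    for (int i = 0; i < 4; ++i)
      s = s * 32u + static_cast<uint64_t>(rz[i] * (nBoxes + 1) + bx[i]);
    s = s * 8u + static_cast<uint64_t>(loc + 1);
    int64_t q = llround(t * 1e6);
    if (q < 0) q = 0;
    return static_cast<uint64_t>(q) | (s << 28);
  }

  // Expected coins-to-go of taking action (stay: a == loc; move: a != loc or
  // from central).  Caller guarantees feasibility.
  double actValue(double t, const int rz[4], const int bx[4], int loc,
                  int a, double cost) {
    int nb[4]; std::copy(bx, bx + 4, nb); nb[a]++;
    if (rz[a] != 0) {
      return coin(rz[a], bx[a]) + value(t - cost, rz, nb, a);
    }
    int r = 0, p = 0;
    for (int i = 0; i < 4; ++i) { if (rz[i] == 1) ++r; else if (rz[i] == 2) ++p; }
    double pr = (2.0 - r) / (4.0 - r - p);
    int rr[4]; std::copy(rz, rz + 4, rr);
    rr[a] = 1;
    double vRich = richSeq[0] + value(t - cost, rr, nb, a);
    rr[a] = 2;
    double vPoor = poorSeq[0] + value(t - cost, rr, nb, a);
    return pr * vRich + (1.0 - pr) * vPoor;
  }

  double value(double t0, const int rz0[4], const int bx[4], int loc) {
    double t = t0 < 0 ? 0 : t0;
    int rz[4]; std::copy(rz0, rz0 + 4, rz);
    closure(rz);
    uint64_t k = key(t, rz, bx, loc);
    auto it = memo.find(k);
    if (it != memo.end()) return it->second;

    const double eps = 1e-9;
    double best = 0.0;
    if (loc >= 0 && bx[loc] < nBoxes && t >= T1 - eps) {
      double v = actValue(t, rz, bx, loc, loc, T1);
      if (v > best) best = v;
    }
    double moveCost = (loc == -1) ? (firstCostT1 ? T1 : T2) : T2;
    for (int a = 0; a < 4; ++a) {
      if (a == loc || bx[a] >= nBoxes) continue;
      if (t < moveCost - eps) continue;
      double v = actValue(t, rz, bx, loc, a, moveCost);
      if (v > best) best = v;
    }
    memo[k] = best;
    return best;
  }
};

Solver* getSolver(SEXP ptr) {
  Rcpp::XPtr<Solver> xp(ptr);
  return xp.get();
}

} // namespace

// [[Rcpp::export(name = ".solver_create")]]
SEXP solver_create(double t1, double t2, double battery, bool mixed,
                   bool first_cost_t1, IntegerVector rich_seq,
                   IntegerVector poor_seq) {
  std::vector<int> rs = as<std::vector<int> >(rich_seq);
  std::vector<int> ps = as<std::vector<int> >(poor_seq);
  Rcpp::XPtr<Solver> ptr(new Solver(t1, t2, battery, mixed, first_cost_t1,
                                    rs, ps), true);
  return ptr;
}

// [[Rcpp::export(name = ".solver_value")]]
double solver_value(SEXP ptr, double t, IntegerVector richness,
                    IntegerVector boxes, int loc) {
  Solver* s = getSolver(ptr);
  int rz[4], bx[4];
  for (int i = 0; i < 4; ++i) { rz[i] = richness[i]; bx[i] = boxes[i]; }
  return s->value(t, rz, bx, loc);
}

// Feasible actions and their expected coins-to-go, in canonical order:
// stay first, then moves by ascending area index.  kind: 0 stay, 1 move;
// target is 0-based area index.
// [[Rcpp::export(name = ".solver_actions")]]
List solver_actions(SEXP ptr, double t, IntegerVector richness,
                    IntegerVector boxes, int loc) {
  Solver* s = getSolver(ptr);
  int rz[4], bx[4];
  for (int i = 0; i < 4; ++i) { rz[i] = richness[i]; bx[i] = boxes[i]; }
  s->closure(rz);
  if (t < 0) t = 0;
  const double eps = 1e-9;
  std::vector<int> kind, target;
  std::vector<double> cost, val;
  if (loc >= 0 && bx[loc] < s->nBoxes && t >= s->T1 - eps) {
    kind.push_back(0); target.push_back(loc); cost.push_back(s->T1);
    val.push_back(s->actValue(t, rz, bx, loc, loc, s->T1));
  }
  double moveCost = (loc == -1) ? (s->firstCostT1 ? s->T1 : s->T2) : s->T2;
  for (int a = 0; a < 4; ++a) {
    if (a == loc || bx[a] >= s->nBoxes) continue;
    if (t < moveCost - eps) continue;
    kind.push_back(1); target.push_back(a); cost.push_back(moveCost);
    val.push_back(s->actValue(t, rz, bx, loc, a, moveCost));
  }
  return List::create(_["kind"] = wrap(kind), _["target"] = wrap(target),
                      _["cost"] = wrap(cost), _["value"] = wrap(val));
}

// [[Rcpp::export(name = ".solver_memo_size")]]
double solver_memo_size(SEXP ptr) {
  return static_cast<double>(getSolver(ptr)->memo.size());
}

// [[Rcpp::export(name = ".solver_clear")]]
void solver_clear(SEXP ptr) {
  getSolver(ptr)->memo.clear();
}
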