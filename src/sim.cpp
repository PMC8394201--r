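#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Self-contained counter-free PRNG (xoshiro256++ seeded via splitmix64).
// The engine draws one uniform per unreplicated candidate block per round,
// which is far too many calls for R's RNG API to be practical; the stream
// is seeded from R so runs remain reproducible under set.seed().
namespace {

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) {
      seed += 0x9E3779B97F4A7C15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t;    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  // uniform integer in [0, n)
  inline uint64_t below(uint64_t n) {
    uint64_t x, r;
    do { x = next(); r = x % n; } while (x - r > UINT64_MAX - (n - 1));
    return r;
  }
};

// Enumerate the ranks (0-based, ascending) of Bernoulli(p) successes
// among n trials by geometric skipping: cost O(successes + 1) instead of
// O(n). Exactly equivalent to n independent draws.
template <typename F>
static inline void bernoulli_ranks(long n, double p, Xoshiro& rng, F&& hit) {
  if (n <= 0 || p <= 0.0) return;
  if (p >= 1.0) {
    for (long r = 0; r < n; ++r) hit(r);
    return;
  }
  const double denom = std::log1p(-p);
  double r = -1.0;
  for (;;) {
    double u = rng.unif();
    if (u <= 0.0) u = 0x1.0p-53;
    r += 1.0 + std::floor(std::log(u) / denom);
    if (r >= (double)n) break;
    hit((long)r);
  }
}

struct Eye {
  long s, e;      // inclusive 0-based block range
  bool aL, aR;    // left / right fork still active (not terminated at an end)
};

} // namespace

// Run one complete S-phase on a lattice of L 1-kb blocks.
//
// Model conventions (see package documentation):
//  * one round = round_minutes of real time; a constant-speed fork advances
//    `speed_choices[0]` blocks per round (1 block at v = 0.5 kb/min, 2 min
//    rounds); with variable speed each active fork edge independently draws
//    its per-round displacement from `speed_choices`.
//  * candidates are unreplicated, origin-eligible blocks whose uniform draw
//    falls strictly below their reference probability (plocal inside the
//    fork-proximal zone when use_local, else pin/pout by the region mask).
//  * available factors: floor(N0 + J t) - Nb, Nb = active fork edges / 2
//    (a factor is sequestered at firing and released when its forks meet;
//    a fork terminating at a lattice end counts as half a release).
//
// [[Rcpp::export]]
List sim_run_cpp(int L, double n0, double j_rate,
                 double pout, double pin, double plocal,
                 bool use_local, int d,
                 IntegerVector speed_choices,
                 Nullable<LogicalVector> eligible_,
                 Nullable<LogicalVector> in_mask_,
                 double f_stop, int max_rounds,
                 NumericVector snapshot_f,
                 bool record_times, bool record_firings,
                 IntegerMatrix initial_eyes,
                 double seed_lo, double seed_hi,
                 double gen_spacing = 0, double gen_theta = -1) {
  if (L < 1) stop("L must be >= 1");
  uint64_t seed = (static_cast<uint64_t>(seed_hi) << 31) ^
                  static_cast<uint64_t>(seed_lo);
  Xoshiro rng(seed ^ 0xD1B54A32D192ED03ULL);

  // class membership per block; either supplied from R or generated
  // in-engine (fast path for optimisation loops)
  std::vector<uint8_t> eligv, maskv;
  bool have_elig = false, have_mask = false;
  if (eligible_.isNotNull()) {
    LogicalVector ev(eligible_.get());
    if (ev.size() != L) stop("origin map length does not match L");
    eligv.resize(L);
    for (long i = 0; i < L; ++i) eligv[i] = ev[i] ? 1 : 0;
    have_elig = true;
  } else if (gen_spacing > 1.0) {
    eligv.assign(L, 0);
    bernoulli_ranks(L, 1.0 / gen_spacing, rng,
                    [&](long r) { eligv[r] = 1; });
    have_elig = true;
  }
  if (in_mask_.isNotNull()) {
    LogicalVector mv(in_mask_.get());
    if (mv.size() != L) stop("region mask length does not match L");
    maskv.resize(L);
    for (long i = 0; i < L; ++i) maskv[i] = mv[i] ? 1 : 0;
    have_mask = true;
  } else if (gen_theta >= 0.0) {
    long k = (long)std::floor(gen_theta * L + 0.5);
    maskv.assign(L, 0);
    if (k > 0) {
      // uniform k-subset via partial Fisher-Yates
      std::vector<int> idx(L);
      for (long i = 0; i < L; ++i) idx[i] = (int)i;
      for (long i = 0; i < k; ++i) {
        long j = i + (long)rng.below((uint64_t)(L - i));
        std::swap(idx[i], idx[j]);
        maskv[idx[i]] = 1;
      }
    }
    have_mask = true;
  }
  const uint8_t* elig = have_elig ? eligv.data() : nullptr;
  const uint8_t* mask = have_mask ? maskv.data() : nullptr;

  std::vector<uint8_t> x(L, 0);
  std::vector<int> times;
  if (record_times) times.assign(L, NA_INTEGER);
  std::vector<int> fire_pos, fire_round;

  std::vector<Eye> eyes;
  long covered = 0;
  double fired_total = 0.0;

  // Optional pre-existing replicated intervals (e.g. a single seeded origin).
  for (int r = 0; r < initial_eyes.nrow(); ++r) {
    Eye ey;
    ey.s = initial_eyes(r, 0);
    ey.e = initial_eyes(r, 1);
    if (ey.s < 0 || ey.e >= L || ey.s > ey.e) stop("invalid initial eye");
    ey.aL = ey.s > 0;
    ey.aR = ey.e < L - 1;
    eyes.push_back(ey);
    for (long i = ey.s; i <= ey.e; ++i) {
      if (!x[i]) { x[i] = 1; ++covered; if (record_times) times[i] = 0; }
    }
    fired_total += 1.0;
  }
  std::sort(eyes.begin(), eyes.end(),
            [](const Eye& a, const Eye& b) { return a.s < b.s; });

  // prefix sums over block classes: cumE[i] = eligible blocks < i,
  // cumI[i] = eligible IN-mask blocks < i. Candidate draws then work on
  // contiguous gap segments in rank space (geometric skipping) with a
  // binary search mapping ranks back to block positions.
  std::vector<int> cumE(L + 1, 0), cumI(L + 1, 0);
  for (long i = 0; i < L; ++i) {
    int el = (!elig || elig[i]) ? 1 : 0;
    int in = (el && mask && mask[i]) ? 1 : 0;
    cumE[i + 1] = cumE[i] + el;
    cumI[i + 1] = cumI[i] + in;
  }
  // position of the (r+1)-th class member at or after block s
  auto pos_of_rank_E = [&](long s, long r) -> long {
    long lo = s, hi = L - 1;
    int base = cumE[s];
    while (lo < hi) {
      long mid = (lo + hi) / 2;
      if (cumE[mid + 1] - base >= r + 1) hi = mid; else lo = mid + 1;
    }
    return lo;
  };
  auto pos_of_rank_I = [&](long s, long r) -> long {
    long lo = s, hi = L - 1;
    int base = cumI[s];
    while (lo < hi) {
      long mid = (lo + hi) / 2;
      if (cumI[mid + 1] - base >= r + 1) hi = mid; else lo = mid + 1;
    }
    return lo;
  };
  auto pos_of_rank_O = [&](long s, long r) -> long {  // eligible, not IN
    long lo = s, hi = L - 1;
    int baseE = cumE[s], baseI = cumI[s];
    while (lo < hi) {
      long mid = (lo + hi) / 2;
      if ((cumE[mid + 1] - baseE) - (cumI[mid + 1] - baseI) >= r + 1)
        hi = mid;
      else
        lo = mid + 1;
    }
    return lo;
  };

  // snapshots: lattice just before and just after crossing each target f
  std::vector<double> targets(snapshot_f.begin(), snapshot_f.end());
  std::sort(targets.begin(), targets.end());
  size_t next_target = 0;
  while (next_target < targets.size() &&
         (double)covered / L >= targets[next_target]) {
    ++next_target;  // already at/above target before any round: snapshot now
  }
  List snapshots(targets.size());
  std::vector<uint8_t> prev_x;
  double prev_f = (double)covered / L;
  for (size_t k = 0; k < next_target; ++k) {
    IntegerVector xv(L);
    for (long i = 0; i < L; ++i) xv[i] = x[i];
    snapshots[k] = List::create(_["target"] = targets[k],
                                _["round_before"] = 0, _["round_at"] = 0,
                                _["f_before"] = prev_f, _["f_at"] = prev_f,
                                _["x_before"] = xv, _["x_at"] = xv);
  }

  const int n_speed = speed_choices.size();
  const int* speeds = INTEGER(speed_choices);

  // trajectory storage
  std::vector<double> tr_round, tr_f, tr_ninit, tr_nblocks, tr_forks,
      tr_nb, tr_avail;

  std::vector<long> cand;
  bool hit_cap = false;

  long edges = 0;
  for (const Eye& ey : eyes) edges += (ey.aL ? 1 : 0) + (ey.aR ? 1 : 0);

  int t = 0;
  while (t < max_rounds) {
    double f_now = (double)covered / L;
    if (f_now >= f_stop || covered == L) break;

    // ---- candidate blocks: per unreplicated gap, decompose into the
    // fork-proximal zones at its flanks (probability plocal, truncated
    // at d and at the gap itself) and the remaining middle (pin/pout by
    // class); draw successes by geometric skipping in rank space ----
    cand.clear();
    {
      auto draw_zone = [&](long s, long e) {  // eligible blocks, plocal
        if (s > e) return;
        long nn = cumE[e + 1] - cumE[s];
        bernoulli_ranks(nn, plocal, rng, [&](long r) {
          cand.push_back(pos_of_rank_E(s, r));
        });
      };
      auto draw_middle = [&](long s, long e) {
        if (s > e) return;
        if (mask) {
          long nI = cumI[e + 1] - cumI[s];
          bernoulli_ranks(nI, pin, rng, [&](long r) {
            cand.push_back(pos_of_rank_I(s, r));
          });
          long nO = (cumE[e + 1] - cumE[s]) - nI;
          bernoulli_ranks(nO, pout, rng, [&](long r) {
            cand.push_back(pos_of_rank_O(s, r));
          });
        } else {
          long nn = cumE[e + 1] - cumE[s];
          bernoulli_ranks(nn, pout, rng, [&](long r) {
            cand.push_back(pos_of_rank_E(s, r));
          });
        }
      };
      long g_start = 0;
      size_t ei = 0;
      bool left_active = false;           // fork entering the gap from the left
      while (g_start < L) {
        long g_end = (ei < eyes.size()) ? eyes[ei].s - 1 : L - 1;
        bool right_active = (ei < eyes.size()) && eyes[ei].aL;
        if (g_start <= g_end) {
          if (use_local && d > 0) {
            long zL = left_active ? std::min<long>(d, g_end - g_start + 1)
                                  : 0;
            long z1e = g_start + zL - 1;               // zone from the left
            long z2s = right_active
                           ? std::max<long>(g_end - d + 1, z1e + 1)
                           : g_end + 1;                // zone from the right
            if (zL > 0) draw_zone(g_start, z1e);
            if (z2s <= g_end) draw_zone(z2s, g_end);
            draw_middle(z1e + 1, z2s - 1);
          } else {
            draw_middle(g_start, g_end);
          }
        }
        if (ei >= eyes.size()) break;
        left_active = eyes[ei].aR;
        g_start = eyes[ei].e + 1;
        ++ei;
      }
      std::sort(cand.begin(), cand.end());
    }

    // ---- limiting-factor cap ----
    double n_total = std::floor(n0 + j_rate * t);
    double avail = n_total - edges / 2.0;
    long k_allowed = (long)std::floor(avail + 1e-9);
    if (k_allowed < 0) k_allowed = 0;
    long M = (long)cand.size();
    long n_fire = std::min<long>(M, k_allowed);
    if (n_fire < M) {  // uniform random subset (partial Fisher-Yates)
      for (long i = 0; i < n_fire; ++i) {
        long jdx = i + (long)rng.below((uint64_t)(M - i));
        std::swap(cand[i], cand[jdx]);
      }
      cand.resize(n_fire);
      std::sort(cand.begin(), cand.end());
    }

    // keep a copy of the pre-round lattice while snapshot targets pending
    if (next_target < targets.size()) prev_x = x;
    prev_f = f_now;

    // ---- fire new origins ----
    long new_blocks = 0;
    std::vector<Eye> born;
    born.reserve(cand.size());
    for (long i : cand) {
      Eye ey;
      ey.s = ey.e = i;
      ey.aL = i > 0;
      ey.aR = i < L - 1;
      born.push_back(ey);
      x[i] = 1; ++covered; ++new_blocks;
      if (record_times) times[i] = t + 1;
      if (record_firings) { fire_pos.push_back((int)i); fire_round.push_back(t + 1); }
    }
    fired_total += (double)cand.size();

    // ---- propagate pre-existing forks ----
    for (Eye& ey : eyes) {
      long sL = 0, sR = 0;
      if (ey.aL) sL = (n_speed == 1) ? speeds[0] : speeds[rng.below(n_speed)];
      if (ey.aR) sR = (n_speed == 1) ? speeds[0] : speeds[rng.below(n_speed)];
      long ns = ey.s - sL, ne = ey.e + sR;
      if (ns < 0) ns = 0;
      if (ne > L - 1) ne = L - 1;
      for (long i = ns; i < ey.s; ++i)
        if (!x[i]) { x[i] = 1; ++covered; ++new_blocks; if (record_times) times[i] = t + 1; }
      for (long i = ey.e + 1; i <= ne; ++i)
        if (!x[i]) { x[i] = 1; ++covered; ++new_blocks; if (record_times) times[i] = t + 1; }
      ey.s = ns; ey.e = ne;
      if (ey.s == 0) ey.aL = false;
      if (ey.e == L - 1) ey.aR = false;
    }

    // variable per-fork speeds can reorder eyes (a fast left fork
    // overtaking a slow short eye); the merge sweep needs sorted input
    if (n_speed > 1) {
      std::sort(eyes.begin(), eyes.end(),
                [](const Eye& a, const Eye& b) { return a.s < b.s; });
    }

    // ---- merge coalesced / adjacent eyes (old and newborn) ----
    std::vector<Eye> merged;
    merged.reserve(eyes.size() + born.size());
    {
      size_t ia = 0, ib = 0;
      auto take = [&]() -> Eye {
        if (ia < eyes.size() &&
            (ib >= born.size() || eyes[ia].s <= born[ib].s))
          return eyes[ia++];
        return born[ib++];
      };
      while (ia < eyes.size() || ib < born.size()) {
        Eye nx = take();
        if (!merged.empty() && nx.s <= merged.back().e + 1) {
          Eye& cur = merged.back();
          if (nx.e > cur.e) { cur.e = nx.e; cur.aR = nx.aR; }
          else if (nx.e == cur.e) { cur.aR = cur.aR || nx.aR; }
          // converging interior forks annihilate: drop them implicitly
        } else {
          merged.push_back(nx);
        }
      }
    }
    eyes.swap(merged);

    edges = 0;
    for (const Eye& ey : eyes) edges += (ey.aL ? 1 : 0) + (ey.aR ? 1 : 0);

    ++t;
    f_now = (double)covered / L;

    tr_round.push_back(t);
    tr_f.push_back(f_now);
    tr_ninit.push_back((double)cand.size());
    tr_nblocks.push_back((double)new_blocks);
    tr_forks.push_back((double)edges);
    tr_nb.push_back(edges / 2.0);
    tr_avail.push_back(avail);

    while (next_target < targets.size() && f_now >= targets[next_target]) {
      IntegerVector xb(L), xa(L);
      for (long i = 0; i < L; ++i) { xb[i] = prev_x[i]; xa[i] = x[i]; }
      snapshots[next_target] =
          List::create(_["target"] = targets[next_target],
                       _["round_before"] = t - 1, _["round_at"] = t,
                       _["f_before"] = prev_f, _["f_at"] = f_now,
                       _["x_before"] = xb, _["x_at"] = xa);
      ++next_target;
    }
  }
  if (t >= max_rounds && (double)covered / L < f_stop && covered < L)
    hit_cap = true;

  int n_rounds = (int)tr_round.size();
  NumericMatrix traj(n_rounds, 7);
  for (int i = 0; i < n_rounds; ++i) {
    traj(i, 0) = tr_round[i]; traj(i, 1) = tr_f[i];
    traj(i, 2) = tr_ninit[i]; traj(i, 3) = tr_nblocks[i];
    traj(i, 4) = tr_forks[i]; traj(i, 5) = tr_nb[i];
    traj(i, 6) = tr_avail[i];
  }

  IntegerVector xv(L);
  for (long i = 0; i < L; ++i) xv[i] = x[i];

  List out = List::create(
      _["trajectory"] = traj,
      _["x"] = xv,
      _["fired_total"] = fired_total,
      _["edges"] = (double)edges,
      _["released_total"] = fired_total - edges / 2.0,
      _["rounds"] = t,
      _["f"] = (double)covered / L,
      _["hit_round_cap"] = hit_cap,
      _["snapshots"] = snapshots);
  if (record_times) {
    IntegerVector tv(times.begin(), times.end());
    out["times"] = tv;
  }
  if (record_firings) {
    IntegerMatrix fm((int)fire_pos.size(), 2);
    for (int i = 0; i < (int)fire_pos.size(); ++i) {
      fm(i, 0) = fire_pos[i]; fm(i, 1) = fire_round[i];
    }
    colnames(fm) = CharacterVector::create("position", "round");
    out["firings"] = fm;
  }
  return out;
}
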