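#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Deterministic 64-bit mixing (splitmix64 finalizer). Used for the seeded
// STRAIGHT/CROSS draw at heterozygote-free junctions so that the outcome
// depends only on (seed, junction, individual), never on worker scheduling.
// ---------------------------------------------------------------------------
static inline uint64_t mix64(uint64_t z) {
  z += 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export]]
int cpp_case3_bit(int seed, int junction, int individual) {
  uint64_t h = mix64((uint64_t)(uint32_t)seed);
  h = mix64(h ^ (uint64_t)(uint32_t)junction);
  h = mix64(h ^ (uint64_t)(uint32_t)individual);
  return (int)(h & 1ULL);
}

// [[Rcpp::export]]
int cpp_derive_seed(int seed, int index) {
  uint64_t h = mix64(mix64((uint64_t)(uint32_t)seed) ^ (uint64_t)(uint32_t)index);
  return (int)(h % 2147483647ULL);
}

// ---------------------------------------------------------------------------
// Two-site unambiguous gamete counts. Codes: 0 hom-major, 1 hom-minor,
// 2 het, NA missing. Double-het or missing individuals contribute nothing;
// double-hom contributes 2 identical gametes; hom+het contributes one gamete
// to each cell compatible with the homozygote.
// ---------------------------------------------------------------------------
static void gcounts(const int* G, int n, int m, int s, int t, long out[4]) {
  out[0] = out[1] = out[2] = out[3] = 0;
  const int* cs = G + (size_t)s * n;  // column-major
  const int* ct = G + (size_t)t * n;
  for (int i = 0; i < n; i++) {
    int a = cs[i], b = ct[i];
    if (a == NA_INTEGER || b == NA_INTEGER) continue;
    if (a == 2 && b == 2) continue;
    if (a != 2 && b != 2) {
      out[a * 2 + b] += 2;
    } else if (a != 2) {
      out[a * 2 + 0] += 1;
      out[a * 2 + 1] += 1;
    } else {
      out[0 + b] += 1;
      out[2 + b] += 1;
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gamete_counts(IntegerMatrix G, int s, int t) {
  long c[4];
  gcounts(G.begin(), G.nrow(), G.ncol(), s, t, c);
  NumericVector out = NumericVector::create(
    _["n00"] = (double)c[0], _["n01"] = (double)c[1],
    _["n10"] = (double)c[2], _["n11"] = (double)c[3]);
  return out;
}

// ---------------------------------------------------------------------------
// Phase 1: initial phasing. Homozygotes copied, missing imputed to column
// major allele (a het call counts one of each), het sites chained left to
// right by the sign of the two-site LD statistic D = n00*n11 - n01*n10
// between consecutive het sites (D >= 0: alleles 0 co-reside).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_initial_phase(IntegerMatrix G) {
  int n = G.nrow(), m = G.ncol();
  IntegerMatrix h1(n, m), h2(n, m);
  LogicalMatrix imp(n, m);
  std::vector<int> major(m, 0);
  for (int j = 0; j < m; j++) {
    long c0 = 0, c1 = 0;
    for (int i = 0; i < n; i++) {
      int g = G(i, j);
      if (g == NA_INTEGER) continue;
      if (g == 0) c0 += 2;
      else if (g == 1) c1 += 2;
      else { c0 += 1; c1 += 1; }
    }
    major[j] = (c1 > c0) ? 1 : 0;
  }
  std::unordered_map<long long, int> cis_cache;
  for (int i = 0; i < n; i++) {
    int prev = -1, prev_a1 = 0;
    for (int j = 0; j < m; j++) {
      int g = G(i, j);
      if (g == NA_INTEGER) {
        h1(i, j) = major[j]; h2(i, j) = major[j]; imp(i, j) = 1;
      } else if (g == 0) {
        h1(i, j) = 0; h2(i, j) = 0;
      } else if (g == 1) {
        h1(i, j) = 1; h2(i, j) = 1;
      } else {
        int a1;
        if (prev < 0) {
          a1 = 0;  // canonical orientation at the first het site
        } else {
          long long key = (long long)prev * m + j;
          auto it = cis_cache.find(key);
          int cis;
          if (it == cis_cache.end()) {
            long c[4];
            gcounts(G.begin(), n, m, prev, j, c);
            double D = (double)c[0] * c[3] - (double)c[1] * c[2];
            cis = (D >= 0) ? 1 : 0;
            cis_cache.emplace(key, cis);
          } else {
            cis = it->second;
          }
          a1 = cis ? prev_a1 : 1 - prev_a1;
        }
        h1(i, j) = a1; h2(i, j) = 1 - a1;
        prev = j; prev_a1 = a1;
      }
    }
  }
  return List::create(_["h1"] = h1, _["h2"] = h2, _["imputed"] = imp);
}

// ---------------------------------------------------------------------------
// Polynomial (Rabin) fingerprints of haplotype fragments: prefix hashes per
// row allow O(1) substring and spliced-substring fingerprints. 64-bit
// fingerprints stand in for fragment identity in the hot loops; the exported
// R-level support operations are exact and serve as independent oracles.
// ---------------------------------------------------------------------------
static const uint64_t PBASE = 0x00000100000001B3ULL;

struct HapState {
  int n, m;                       // individuals, sites
  std::vector<uint8_t> hap;       // 2n rows * m, row r = i*2+which
  std::vector<uint64_t> pre;      // 2n rows * (m+1) prefix hashes
  std::vector<uint64_t> pw;       // powers of PBASE

  void init(const IntegerMatrix& H1, const IntegerMatrix& H2) {
    n = H1.nrow(); m = H1.ncol();
    hap.assign((size_t)2 * n * m, 0);
    for (int i = 0; i < n; i++)
      for (int j = 0; j < m; j++) {
        hap[(size_t)(2 * i) * m + j] = (uint8_t)H1(i, j);
        hap[(size_t)(2 * i + 1) * m + j] = (uint8_t)H2(i, j);
      }
    pw.resize(m + 1);
    pw[0] = 1;
    for (int j = 1; j <= m; j++) pw[j] = pw[j - 1] * PBASE;
    pre.assign((size_t)2 * n * (m + 1), 0);
    for (int r = 0; r < 2 * n; r++) rehash_row(r, 0);
  }
  void rehash_row(int r, int from) {
    uint64_t* p = &pre[(size_t)r * (m + 1)];
    const uint8_t* h = &hap[(size_t)r * m];
    for (int j = from; j < m; j++) p[j + 1] = p[j] * PBASE + (uint64_t)(h[j] + 1);
  }
  // fingerprint of row r restricted to [a, b)
  inline uint64_t sub(int r, int a, int b) const {
    const uint64_t* p = &pre[(size_t)r * (m + 1)];
    return p[b] - p[a] * pw[b - a];
  }
  // fingerprint of rowA[a,q) concatenated with rowB[q,b)
  inline uint64_t splice(int rA, int rB, int a, int q, int b) const {
    return sub(rA, a, q) * pw[b - q] + sub(rB, q, b);
  }
  // swap the [q, m) suffix of individual i's two rows and refresh hashes
  void flip_suffix(int i, int q) {
    uint8_t* a = &hap[(size_t)(2 * i) * m];
    uint8_t* b = &hap[(size_t)(2 * i + 1) * m];
    for (int j = q; j < m; j++) std::swap(a[j], b[j]);
    rehash_row(2 * i, q);
    rehash_row(2 * i + 1, q);
  }
  void export_to(IntegerMatrix& H1, IntegerMatrix& H2) const {
    for (int i = 0; i < n; i++)
      for (int j = 0; j < m; j++) {
        H1(i, j) = hap[(size_t)(2 * i) * m + j];
        H2(i, j) = hap[(size_t)(2 * i + 1) * m + j];
      }
  }
};

// Open-addressing fingerprint -> count table, reused across windows via a
// generation stamp so it never needs clearing.
struct CountTable {
  std::vector<uint64_t> key;
  std::vector<int> cnt;
  std::vector<uint32_t> stamp;
  uint32_t cur = 0;
  size_t mask = 0;
  void init(size_t want) {
    size_t sz = 8;
    while (sz < want) sz <<= 1;
    key.assign(sz, 0); cnt.assign(sz, 0); stamp.assign(sz, 0);
    mask = sz - 1; cur = 0;
  }
  inline void next_window() { cur++; }
  inline void insert(uint64_t h) {
    size_t s = (size_t)(mix64(h) & mask);
    for (;;) {
      if (stamp[s] != cur) { stamp[s] = cur; key[s] = h; cnt[s] = 1; return; }
      if (key[s] == h) { cnt[s]++; return; }
      s = (s + 1) & mask;
    }
  }
  inline int lookup(uint64_t h) const {
    size_t s = (size_t)(mix64(h) & mask);
    for (;;) {
      if (stamp[s] != cur) return 0;
      if (key[s] == h) return cnt[s];
      s = (s + 1) & mask;
    }
  }
  // decrement; the slot stays occupied (possibly at zero) so probe chains
  // remain intact within the current window
  inline void remove(uint64_t h) {
    size_t s = (size_t)(mix64(h) & mask);
    for (;;) {
      if (stamp[s] != cur) return;
      if (key[s] == h) { cnt[s]--; return; }
      s = (s + 1) & mask;
    }
  }
};

// Per-individual breakpoints: consecutive het-site pairs (p, q).
static void het_breakpoints(const IntegerMatrix& G,
                            std::vector<std::vector<int>>& P,
                            std::vector<std::vector<int>>& Q) {
  int n = G.nrow(), m = G.ncol();
  P.assign(n, {}); Q.assign(n, {});
  for (int i = 0; i < n; i++) {
    int prev = -1;
    for (int j = 0; j < m; j++) {
      if (G(i, j) == 2) {
        if (prev >= 0) { P[i].push_back(prev); Q[i].push_back(j); }
        prev = j;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Phase 2: scalable sliding-window orientation refinement. For every
// breakpoint (the gap between an individual's consecutive het sites) both
// relative orientations of the suffix are scored with the exact-match
// support weight: the number of other-individual haplotype fragments equal
// to each candidate fragment inside the window. Windows have length l_min,
// 2*l_min, ..., <= l_max and every placement keeping a het of the
// individual on both sides of the gap is visited.
//
// mode 0 ("argmax"): all decisions in a sweep are scored against the
//   sweep-start configuration and applied together; a breakpoint flips iff
//   the single best flip weight over all (length, placement) windows
//   strictly exceeds the single best keep weight.
// mode 1 ("consolidate"): progressive — windows slide left to right,
//   shortest length first; a placement preferring the flipped orientation
//   applies it immediately and updates the pool, so later windows always
//   score the corrected configuration. Suited to low-diversity panels,
//   where every true haplotype is common and an unsupported fragment is
//   almost surely a phase error.
// mode 2 ("repair"): progressive as above (longest length first) but a
//   flip is accepted only as a corroborated repair: the current pair must
//   contain a fragment with zero support and both flipped fragments must
//   have support, in addition to winning the weight comparison. Suited to
//   diverse panels, where unsupported fragments are often genuine rare
//   haplotypes.
//
// Sweeps repeat up to `passes` times, stopping early once nothing changes.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_refine(IntegerMatrix G, IntegerMatrix H1, IntegerMatrix H2,
                int lmin, int lmax, int passes, int mode = 2) {
  int n = G.nrow(), m = G.ncol();
  HapState st;
  st.init(H1, H2);
  std::vector<std::vector<int>> P, Q;
  het_breakpoints(G, P, Q);
  std::vector<int> off(n + 1, 0);
  for (int i = 0; i < n; i++) off[i + 1] = off[i] + (int)P[i].size();
  int nb = off[n];
  std::vector<int> lengths;
  for (int l = std::max(2, lmin); l <= lmax && l <= m; l *= 2)
    lengths.push_back(l);
  if (mode == 2) std::reverse(lengths.begin(), lengths.end());
  CountTable tab;
  tab.init((size_t)8 * n);
  std::vector<long long> bestKeep, bestFlip;
  if (mode == 0) { bestKeep.assign(nb, -1LL); bestFlip.assign(nb, -1LL); }
  std::vector<int> lo(n), hi(n);
  int sweeps = 0;
  for (int pass = 0; pass < passes && nb > 0; pass++) {
    bool changed = false;
    if (mode == 0) {
      std::fill(bestKeep.begin(), bestKeep.end(), -1LL);
      std::fill(bestFlip.begin(), bestFlip.end(), -1LL);
    }
    for (int l : lengths) {
      std::fill(lo.begin(), lo.end(), 0);
      std::fill(hi.begin(), hi.end(), 0);
      for (int a = 0; a + l <= m; a++) {
        int b = a + l;
        bool built = false;
        for (int i = 0; i < n; i++) {
          int nk = (int)P[i].size();
          while (lo[i] < nk && P[i][lo[i]] < a) lo[i]++;
          if (hi[i] < lo[i]) hi[i] = lo[i];
          while (hi[i] < nk && Q[i][hi[i]] <= b - 1) hi[i]++;
          if (lo[i] >= hi[i]) continue;
          if (!built) {
            tab.next_window();
            for (int r = 0; r < 2 * n; r++) tab.insert(st.sub(r, a, b));
            built = true;
          }
          for (int k = lo[i]; k < hi[i]; k++) {
            int q = Q[i][k];
            uint64_t hA = st.sub(2 * i, a, b), hB = st.sub(2 * i + 1, a, b);
            long long sA = tab.lookup(hA) - 1 - (hA == hB ? 1 : 0);
            long long sB = tab.lookup(hB) - 1 - (hA == hB ? 1 : 0);
            uint64_t fA = st.splice(2 * i, 2 * i + 1, a, q, b);
            uint64_t fB = st.splice(2 * i + 1, 2 * i, a, q, b);
            long long sFA =
              (long long)tab.lookup(fA) - (fA == hA) - (fA == hB);
            long long sFB =
              (long long)tab.lookup(fB) - (fB == hA) - (fB == hB);
            long long wKeep = sA + sB, wFlip = sFA + sFB;
            if (mode == 0) {
              int idx = off[i] + k;
              if (wKeep > bestKeep[idx]) bestKeep[idx] = wKeep;
              if (wFlip > bestFlip[idx]) bestFlip[idx] = wFlip;
            } else {
              bool go = wFlip > wKeep;
              if (mode == 2)
                go = go && std::min(sA, sB) == 0 && std::min(sFA, sFB) >= 1;
              if (go) {
                tab.remove(hA); tab.remove(hB);
                st.flip_suffix(i, q);
                tab.insert(st.sub(2 * i, a, b));
                tab.insert(st.sub(2 * i + 1, a, b));
                changed = true;
              }
            }
          }
        }
      }
    }
    if (mode == 0) {
      for (int i = 0; i < n; i++) {
        // a suffix flip at Q[i][k] toggles exactly the relative orientation
        // across breakpoint k (later breakpoints see both rows swapped
        // together, which preserves their relative orientation), so batch
        // application in any order is sound.
        int nk = (int)P[i].size();
        for (int k = 0; k < nk; k++) {
          int idx = off[i] + k;
          if (bestFlip[idx] > bestKeep[idx]) {
            st.flip_suffix(i, Q[i][k]);
            changed = true;
          }
        }
      }
    }
    sweeps++;
    if (!changed) break;
  }
  IntegerMatrix o1(n, m), o2(n, m);
  st.export_to(o1, o2);
  return List::create(_["h1"] = o1, _["h2"] = o2, _["sweeps"] = sweeps);
}

// ---------------------------------------------------------------------------
// Phase 3: maximum-parsimony hill climb. Moves are the same suffix flips;
// a move is accepted only if it strictly reduces the number of distinct
// haplotypes in the 2n-row pool, or keeps it equal while strictly raising
// the total support sum (sum over rows of the multiplicity of that row,
// i.e. the sum of squared multiplicities). Sequential sweeps, deterministic
// order, until a sweep accepts nothing or `passes` sweeps have run.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_parsimony(IntegerMatrix G, IntegerMatrix H1, IntegerMatrix H2,
                   int passes) {
  int n = G.nrow(), m = G.ncol();
  HapState st;
  st.init(H1, H2);
  std::vector<std::vector<int>> P, Q;
  het_breakpoints(G, P, Q);
  std::unordered_map<uint64_t, int> cnt;
  cnt.reserve((size_t)4 * n);
  for (int r = 0; r < 2 * n; r++) cnt[st.sub(r, 0, m)]++;
  for (int pass = 0; pass < passes; pass++) {
    bool changed = false;
    for (int i = 0; i < n; i++) {
      int nk = (int)P[i].size();
      for (int k = 0; k < nk; k++) {
        int q = Q[i][k];
        uint64_t hA = st.sub(2 * i, 0, m), hB = st.sub(2 * i + 1, 0, m);
        uint64_t nA = st.splice(2 * i, 2 * i + 1, 0, q, m);
        uint64_t nB = st.splice(2 * i + 1, 2 * i, 0, q, m);
        if ((nA == hA && nB == hB) || (nA == hB && nB == hA)) continue;
        // net delta over distinct keys
        uint64_t keys[4] = {hA, hB, nA, nB};
        int net[4] = {-1, -1, 1, 1};
        long long dS = 0;
        int dD = 0;
        for (int u = 0; u < 4; u++) {
          bool dup = false;
          for (int v = 0; v < u; v++)
            if (keys[v] == keys[u]) { net[v] += net[u]; dup = true; break; }
          if (dup) net[u] = 0;
        }
        for (int u = 0; u < 4; u++) {
          if (net[u] == 0) continue;
          auto it = cnt.find(keys[u]);
          long long c = (it == cnt.end()) ? 0 : it->second;
          long long nc = c + net[u];
          dS += nc * nc - c * c;
          dD += (nc > 0 ? 1 : 0) - (c > 0 ? 1 : 0);
        }
        if (dD < 0 || (dD == 0 && dS > 0)) {
          for (int u = 0; u < 4; u++) {
            if (net[u] == 0) continue;
            int& c = cnt[keys[u]];
            c += net[u];
            if (c == 0) cnt.erase(keys[u]);
          }
          st.flip_suffix(i, q);
          changed = true;
        }
      }
    }
    if (!changed) break;
  }
  IntegerMatrix o1(n, m), o2(n, m);
  st.export_to(o1, o2);
  return List::create(_["h1"] = o1, _["h2"] = o2);
}

// ---------------------------------------------------------------------------
// Neutral coalescent block without intra-block recombination (infinite
// sites). Exponential coalescence times at rate C(j,2) (units of 2N
// generations), Poisson(theta/2 * total branch length) mutations, each
// dropped uniformly on the extant lineages of its epoch. Columns are
// ordered by a uniform mutation position on [0,1]. Uses R's RNG.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_block(int n_hap, double theta) {
  if (n_hap < 2) stop("n_hap must be >= 2");
  std::vector<std::vector<int>> clusters(n_hap);
  for (int i = 0; i < n_hap; i++) clusters[i] = {i};
  std::vector<std::vector<int>> cols;
  for (int j = n_hap; j >= 2; j--) {
    double rate = (double)j * (j - 1) / 2.0;
    double t = R::rexp(1.0 / rate);
    int nm = (int)R::rpois(theta / 2.0 * j * t);
    for (int u = 0; u < nm; u++) {
      int c = (int)(R::unif_rand() * j);
      if (c >= j) c = j - 1;
      cols.push_back(clusters[c]);
    }
    int a = (int)(R::unif_rand() * j);
    if (a >= j) a = j - 1;
    int b = (int)(R::unif_rand() * (j - 1));
    if (b >= j - 1) b = j - 2;
    if (b >= a) b++;
    clusters[a].insert(clusters[a].end(), clusters[b].begin(), clusters[b].end());
    if (b != j - 1) clusters[b] = std::move(clusters[j - 1]);
    clusters.pop_back();
  }
  int S = (int)cols.size();
  std::vector<double> pos(S);
  for (int s = 0; s < S; s++) pos[s] = R::unif_rand();
  std::vector<int> ord(S);
  for (int s = 0; s < S; s++) ord[s] = s;
  std::sort(ord.begin(), ord.end(),
            [&](int x, int y) { return pos[x] < pos[y]; });
  IntegerMatrix H(n_hap, S);
  NumericVector opos(S);
  for (int s = 0; s < S; s++) {
    opos[s] = pos[ord[s]];
    for (int tip : cols[ord[s]]) H(tip, s) = 1;
  }
  H.attr("positions") = opos;
  return H;
}
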