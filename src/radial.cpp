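#include <Rcpp.h>
#include <cstdint>
#include <cstdio>
#include <algorithm>
#include <set>
#include <vector>

using namespace Rcpp;

// splitmix64 finalizer: well-mixed 64-bit avalanche, used both to seed and to
// combine invariants. All feature identifiers live in the full 2^64 space so
// collisions are negligible and never folded away.
static inline uint64_t mix64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}

static inline uint64_t hcombine(uint64_t h, uint64_t v) {
  return mix64(h ^ mix64(v));
}

static std::string hex64(uint64_t v) {
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)v);
  return std::string(buf);
}

// Radial (extended-connectivity) features for one molecule.
//
// atoms: n x k integer matrix of per-atom invariants (element, heavy degree,
//        formal charge, attached hydrogens, ring membership).
// bonds: m x 3 integer matrix (i, j, order), 1-based atom indices.
// n_iter: number of radial iterations; environments of radius 0..n_iter are
//        all emitted (cumulative, extended-connectivity convention).
//
// Returns the sorted set of distinct 64-bit feature identifiers as 16-digit
// lower-case hex strings.
// [[Rcpp::export]]
CharacterVector cpp_radial_features(IntegerMatrix atoms, IntegerMatrix bonds,
                                    int n_iter) {
  const int n = atoms.nrow();
  const int m = bonds.nrow();
  const int k = atoms.ncol();
  if (n == 0) return CharacterVector(0);

  // iteration-0 invariants: hash of the atom-invariant tuple
  std::vector<uint64_t> inv(n);
  for (int a = 0; a < n; ++a) {
    uint64_t h = 0x66726167646976ULL; // constant domain seed
    for (int c = 0; c < k; ++c) h = hcombine(h, (uint64_t)(int64_t)atoms(a, c));
    inv[a] = h;
  }

  // adjacency with bond orders
  std::vector<std::vector<std::pair<int, int> > > adj(n); // (neighbor, order)
  for (int b = 0; b < m; ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1, o = bonds(b, 2);
    adj[i].push_back(std::make_pair(j, o));
    adj[j].push_back(std::make_pair(i, o));
  }

  std::set<uint64_t> feats(inv.begin(), inv.end());
  std::vector<uint64_t> nxt(n);
  for (int it = 1; it <= n_iter; ++it) {
    for (int a = 0; a < n; ++a) {
      // neighbor contributions sorted by (bond order, invariant) so the hash
      // is independent of atom numbering
      std::vector<std::pair<int, uint64_t> > nb;
      nb.reserve(adj[a].size());
      for (size_t q = 0; q < adj[a].size(); ++q)
        nb.push_back(std::make_pair(adj[a][q].second, inv[adj[a][q].first]));
      std::sort(nb.begin(), nb.end());
      uint64_t h = mix64((uint64_t)it);
      h = hcombine(h, inv[a]);
      for (size_t q = 0; q < nb.size(); ++q) {
        h = hcombine(h, (uint64_t)nb[q].first);
        h = hcombine(h, nb[q].second);
      }
      nxt[a] = h;
    }
    inv = nxt;
    feats.insert(inv.begin(), inv.end());
  }

  CharacterVector out(feats.size());
  int p = 0;
  for (std::set<uint64_t>::const_iterator itf = feats.begin();
       itf != feats.end(); ++itf)
    out[p++] = hex64(*itf);
  return out;
}

// Deterministic 64-bit hash of strings, returned as doubles (top 53 bits)
// for use as a structure-decorrelated sort key. Platform-independent.
// [[Rcpp::export]]
NumericVector cpp_string_hash64(CharacterVector x) {
  NumericVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    const char* s = CHAR(STRING_ELT(x, i));
    uint64_t h = 0xcbf29ce484222325ULL;
    for (const char* p = s; *p; ++p) {
      h ^= (uint64_t)(unsigned char)*p;
      h *= 0x100000001b3ULL; // FNV-1a
    }
    h = mix64(h);
    out[i] = (double)(h >> 11); // exactly representable in a double
  }
  return out;
}

// ---- set-based Tanimoto kernels on integer-indexed feature sets ----
// Fingerprint sets are passed as a List of strictly increasing integer
// vectors (indices into a shared feature universe).

static inline int isect_size(const IntegerVector& a, const IntegerVector& b) {
  int i = 0, j = 0, c = 0;
  const int na = a.size(), nb = b.size();
  while (i < na && j < nb) {
    if (a[i] == b[j]) { ++c; ++i; ++j; }
    else if (a[i] < b[j]) ++i;
    else ++j;
  }
  return c;
}

static inline double tani(const IntegerVector& a, const IntegerVector& b) {
  int c = isect_size(a, b);
  int u = a.size() + b.size() - c;
  return u == 0 ? NA_REAL : (double)c / (double)u;
}

// Per-molecule maximum Tanimoto similarity to any other molecule (all pairs).
// [[Rcpp::export]]
NumericVector cpp_nn_max_sim(List fps) {
  const int n = fps.size();
  NumericVector best(n, 0.0);
  std::vector<IntegerVector> v(n);
  for (int i = 0; i < n; ++i) v[i] = fps[i];
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = tani(v[i], v[j]);
      if (s > best[i]) best[i] = s;
      if (s > best[j]) best[j] = s;
    }
  }
  return best;
}

// Directed sphere exclusion. Visits candidates in visit_order (1-based
// indices into fps); a candidate is kept iff its Tanimoto distance to every
// already-selected compound is >= radius, i.e. similarity <= 1 - radius
// (boundary counts as selectable). Stops at max_size.
// Returns 1-based indices of selected compounds in selection order.
// [[Rcpp::export]]
IntegerVector cpp_sphere_exclusion(List fps, IntegerVector visit_order,
                                   double radius, int max_size) {
  const int n = visit_order.size();
  std::vector<IntegerVector> v(fps.size());
  for (int i = 0; i < (int)fps.size(); ++i) v[i] = fps[i];
  const double max_sim = 1.0 - radius;
  std::vector<int> sel;
  for (int q = 0; q < n && (int)sel.size() < max_size; ++q) {
    int cand = visit_order[q] - 1;
    bool ok = true;
    for (size_t s = 0; s < sel.size(); ++s) {
      if (tani(v[cand], v[sel[s]]) > max_sim + 1e-12) { ok = false; break; }
    }
    if (ok) sel.push_back(cand);
  }
  IntegerVector out(sel.size());
  for (size_t s = 0; s < sel.size(); ++s) out[s] = sel[s] + 1;
  return out;
}

// Maximum similarity of each query fingerprint to any member of a reference
// index set (used for post-hoc sphere-exclusion audits).
// [[Rcpp::export]]
NumericVector cpp_max_sim_to_set(List fps, IntegerVector query,
                                 IntegerVector ref) {
  std::vector<IntegerVector> v(fps.size());
  for (int i = 0; i < (int)fps.size(); ++i) v[i] = fps[i];
  NumericVector out(query.size());
  for (int q = 0; q < query.size(); ++q) {
    double best = 0.0;
    const IntegerVector& fq = v[query[q] - 1];
    for (int r = 0; r < ref.size(); ++r) {
      if (ref[r] == query[q]) continue;
      double s = tani(fq, v[ref[r] - 1]);
      if (s > best) best = s;
    }
    out[q] = best;
  }
  return out;
}

// Maximum pairwise similarity within an index set (audit helper: the minimum
// pairwise Tanimoto distance is 1 minus this value).
// [[Rcpp::export]]
double cpp_max_pairwise_sim(List fps, IntegerVector idx) {
  std::vector<IntegerVector> v(fps.size());
  for (int i = 0; i < (int)fps.size(); ++i) v[i] = fps[i];
  double best = 0.0;
  for (int i = 0; i < idx.size(); ++i) {
    for (int j = i + 1; j < idx.size(); ++j) {
      double s = tani(v[idx[i] - 1], v[idx[j] - 1]);
      if (s > best) best = s;
    }
  }
  return best;
}
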