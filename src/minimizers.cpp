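#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include "kcsf_util.h"

using namespace Rcpp;

// Order on m-mers: 53 high bits of the seeded splitmix64 hash (so the same
// order is reproducible from R, where doubles hold 53 bits exactly).
// Ties between equal-hash windows are broken by leftmost occurrence.
static inline uint64_t order_hash(uint64_t mmer, uint64_t seed) {
  return kcsf_hash(mmer, seed) >> 11;
}

// [[Rcpp::export(name = ".minimizers_cpp")]]
CharacterVector minimizers_cpp(CharacterVector kmers, int m, int seed) {
  if (m < 1) stop("minimizer length m must be >= 1");
  uint64_t sd = (uint64_t)(int64_t)seed;
  const uint64_t mask = (1ULL << (2 * m)) - 1; // m <= 31
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  // cache distinct packed minimizers -> CHARSXP to avoid re-unpacking
  std::unordered_map<uint64_t, SEXP> cache;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(kmers, i));
    int k = LENGTH(STRING_ELT(kmers, i));
    if (m > k) stop("minimizer length m=%d exceeds k-mer length %d", m, k);
    uint64_t v = 0, best = 0, besth = ~0ULL;
    for (int j = 0; j < k; ++j) {
      int c = kcsf_base_code(s[j]);
      if (c < 0 || c > 3) stop("invalid base in k-mer '%s'", s);
      v = ((v << 2) | (uint64_t)c) & mask;
      if (j >= m - 1) {
        uint64_t h = order_hash(v, sd);
        if (h < besth) { // strict < keeps the leftmost window on ties
          besth = h;
          best = v;
        }
      }
    }
    auto it = cache.find(best);
    if (it == cache.end()) {
      SEXP ch = Rf_mkChar(kcsf_unpack(best, m).c_str());
      cache.emplace(best, ch);
      SET_STRING_ELT(out, i, ch);
    } else {
      SET_STRING_ELT(out, i, it->second);
    }
  }
  return out;
}

// Hash values defining the m-mer order, exposed for oracle-style tests.
// [[Rcpp::export(name = ".mmer_order_hash_cpp")]]
NumericVector mmer_order_hash_cpp(CharacterVector mmers, int seed) {
  uint64_t sd = (uint64_t)(int64_t)seed;
  NumericVector out(mmers.size());
  for (R_xlen_t i = 0; i < mmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(mmers, i));
    int m = LENGTH(STRING_ELT(mmers, i));
    uint64_t v;
    if (m > 31 || !kcsf_pack(s, m, v)) stop("invalid m-mer '%s'", s);
    out[i] = (double)order_hash(v, sd);
  }
  return out;
}

// Group identical strings (packed) and return per-group min/max/size plus a
// 1-based group index per element. Groups appear in first-occurrence order.
// [[Rcpp::export(name = ".bucket_stats_cpp")]]
List bucket_stats_cpp(CharacterVector mins, IntegerVector counts) {
  R_xlen_t n = mins.size();
  if (counts.size() != n) stop("length mismatch");
  std::unordered_map<uint64_t, int> idx;
  std::vector<uint64_t> packed;
  std::vector<int> mn, mx, sz, mlen;
  IntegerVector group(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(mins, i));
    int m = LENGTH(STRING_ELT(mins, i));
    uint64_t v;
    if (m > 31 || !kcsf_pack(s, m, v)) stop("invalid minimizer '%s'", s);
    auto it = idx.find(v);
    int g;
    if (it == idx.end()) {
      g = (int)packed.size();
      idx.emplace(v, g);
      packed.push_back(v);
      mn.push_back(counts[i]);
      mx.push_back(counts[i]);
      sz.push_back(0);
      mlen.push_back(m);
    } else {
      g = it->second;
      if (counts[i] < mn[(size_t)g]) mn[(size_t)g] = counts[i];
      if (counts[i] > mx[(size_t)g]) mx[(size_t)g] = counts[i];
    }
    sz[(size_t)g]++;
    group[i] = g + 1;
  }
  R_xlen_t ng = (R_xlen_t)packed.size();
  CharacterVector mm(ng);
  IntegerVector omn(ng), omx(ng), osz(ng);
  for (R_xlen_t g = 0; g < ng; ++g) {
    mm[g] = kcsf_unpack(packed[(size_t)g], mlen[(size_t)g]);
    omn[g] = mn[(size_t)g];
    omx[g] = mx[(size_t)g];
    osz[g] = sz[(size_t)g];
  }
  return List::create(_["minimizer"] = mm, _["min"] = omn, _["max"] = omx,
                      _["size"] = osz, _["group"] = group);
}

// Exact per-bucket modal value (two-pass histogram); ties broken toward the
// smallest value.
// [[Rcpp::export(name = ".bucket_majority_cpp")]]
List bucket_majority_cpp(CharacterVector mins, IntegerVector counts) {
  List st = bucket_stats_cpp(mins, counts);
  IntegerVector group = st["group"];
  CharacterVector mm = st["minimizer"];
  R_xlen_t ng = mm.size(), n = mins.size();
  std::vector<std::unordered_map<int, int> > hist((size_t)ng);
  for (R_xlen_t i = 0; i < n; ++i) hist[(size_t)(group[i] - 1)][counts[i]]++;
  IntegerVector maj(ng);
  for (R_xlen_t g = 0; g < ng; ++g) {
    int bestv = 0, bestc = -1;
    for (auto &kv : hist[(size_t)g]) {
      if (kv.second > bestc || (kv.second == bestc && kv.first < bestv)) {
        bestc = kv.second;
        bestv = kv.first;
      }
    }
    maj[g] = bestv;
  }
  return List::create(_["minimizer"] = mm, _["majority"] = maj,
                      _["group"] = group);
}
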