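#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
#include "kcsf_util.h"

using namespace Rcpp;

// Compressed static function core. Each key contributes, for every bit j of
// its codeword, one XOR equation over three hash-derived bit positions:
//   W[p1+j] ^ W[p2+j] ^ W[p3+j] = codeword bit j.
// Keys are partitioned into chunks by a top-level hash; per chunk the linear
// system over GF(2) is solved by hypergraph peeling with dense Gaussian
// elimination on the residual 2-core. On failure the chunk seed is bumped.

static inline uint64_t chunk_of(uint64_t key, uint64_t seed, uint64_t nchunks) {
  return kcsf_hash(key, seed ^ 0x1d2c3b4a59687766ULL) % nchunks;
}

static inline uint64_t chunk_seed(uint64_t seed, uint64_t chunk,
                                  uint64_t attempt) {
  return kcsf_hash((chunk << 8) | attempt, seed ^ 0xc0ffee5eed1234abULL);
}

static inline void key_positions(uint64_t key, uint64_t cs, uint64_t npos,
                                 uint64_t p[3]) {
  p[0] = kcsf_hash(key, cs) % npos;
  p[1] = kcsf_hash(key, cs ^ 0x5555555555555555ULL) % npos;
  p[2] = kcsf_hash(key, cs ^ 0x3333333333333333ULL) % npos;
}

struct Eq {
  int32_t v[3];
  int8_t nv;
  uint8_t rhs;
  uint8_t active;
};

// XOR-dedup a position triple: variables occurring an even number of times
// cancel. Result has 1 or 3 distinct variables.
static inline void dedup3(const uint64_t p[3], int j, Eq &e) {
  int64_t a = (int64_t)p[0] + j, b = (int64_t)p[1] + j, c = (int64_t)p[2] + j;
  if (a == b && b == c) {
    e.v[0] = (int32_t)a;
    e.nv = 1;
  } else if (a == b) {
    e.v[0] = (int32_t)c;
    e.nv = 1;
  } else if (a == c) {
    e.v[0] = (int32_t)b;
    e.nv = 1;
  } else if (b == c) {
    e.v[0] = (int32_t)a;
    e.nv = 1;
  } else {
    e.v[0] = (int32_t)a;
    e.v[1] = (int32_t)b;
    e.v[2] = (int32_t)c;
    e.nv = 3;
  }
}

// Dense GF(2) solver over ncols variables; rows carry an appended rhs bit.
// Returns false on inconsistency; free variables are set to 0.
static bool dense_solve(std::vector<std::vector<uint64_t> > &rows, int ncols,
                        std::vector<uint8_t> &sol) {
  int words = (ncols + 1 + 63) / 64; // last logical bit is the rhs
  int rhs_word = ncols / 64, rhs_off = ncols % 64;
  std::vector<int> pivot_col;
  std::vector<int> col_pivot((size_t)ncols, -1);
  std::vector<std::vector<uint64_t> > basis;
  for (size_t r = 0; r < rows.size(); ++r) {
    std::vector<uint64_t> &row = rows[r];
    for (;;) {
      int p = -1;
      for (int w = 0; w < words; ++w) {
        uint64_t x = row[(size_t)w];
        if (w == rhs_word) x &= (rhs_off ? ((1ULL << rhs_off) - 1) : 0ULL);
        if (x) {
          p = w * 64 + __builtin_ctzll(x);
          break;
        }
      }
      if (p < 0) { // all-zero LHS
        if ((row[(size_t)rhs_word] >> rhs_off) & 1ULL) return false;
        break;
      }
      if (col_pivot[(size_t)p] >= 0) {
        std::vector<uint64_t> &q = basis[(size_t)col_pivot[(size_t)p]];
        for (int w = 0; w < words; ++w) row[(size_t)w] ^= q[(size_t)w];
      } else {
        col_pivot[(size_t)p] = (int)basis.size();
        basis.push_back(row);
        pivot_col.push_back(p);
        break;
      }
    }
  }
  sol.assign((size_t)ncols, 0);
  // the pivot is each row's minimum set column, so substituting in
  // decreasing pivot order resolves all non-pivot columns first
  std::vector<int> idx(basis.size());
  for (size_t i = 0; i < basis.size(); ++i) idx[i] = (int)i;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) {
    return pivot_col[(size_t)a] > pivot_col[(size_t)b];
  });
  for (size_t ii = 0; ii < idx.size(); ++ii) {
    int i = idx[ii];
    std::vector<uint64_t> &row = basis[(size_t)i];
    int p = pivot_col[(size_t)i];
    uint8_t b = (uint8_t)((row[(size_t)rhs_word] >> rhs_off) & 1ULL);
    for (int w = 0; w < words; ++w) {
      uint64_t x = row[(size_t)w];
      if (w == rhs_word) x &= (rhs_off ? ((1ULL << rhs_off) - 1) : 0ULL);
      while (x) {
        int c = w * 64 + __builtin_ctzll(x);
        x &= x - 1;
        if (c != p) b ^= sol[(size_t)c];
      }
    }
    sol[(size_t)p] = b;
  }
  return true;
}

// Attempt to solve one chunk; on success fills `bits` (one byte per bit).
static bool build_chunk(const std::vector<uint64_t> &keys,
                        const std::vector<int> &lens,
                        const std::vector<uint64_t> &codes, uint64_t cs,
                        uint64_t array_bits, int max_len,
                        std::vector<uint8_t> &bits) {
  uint64_t npos = array_bits - (uint64_t)max_len + 1;
  std::vector<Eq> eqs;
  size_t total = 0;
  for (size_t i = 0; i < keys.size(); ++i) total += (size_t)lens[i];
  eqs.reserve(total);
  for (size_t i = 0; i < keys.size(); ++i) {
    uint64_t p[3];
    key_positions(keys[i], cs, npos, p);
    int len = lens[i];
    for (int j = 0; j < len; ++j) {
      Eq e;
      dedup3(p, j, e);
      e.rhs = (uint8_t)((codes[i] >> (len - 1 - j)) & 1ULL);
      e.active = 1;
      eqs.push_back(e);
    }
  }

  // peel degree-1 variables
  std::vector<int32_t> deg((size_t)array_bits, 0), xsum((size_t)array_bits, 0);
  for (size_t e = 0; e < eqs.size(); ++e)
    for (int t = 0; t < eqs[e].nv; ++t) {
      deg[(size_t)eqs[e].v[t]]++;
      xsum[(size_t)eqs[e].v[t]] ^= (int32_t)e;
    }
  std::vector<int32_t> stack;
  for (size_t v = 0; v < (size_t)array_bits; ++v)
    if (deg[v] == 1) stack.push_back((int32_t)v);
  std::vector<std::pair<int32_t, int32_t> > order; // (equation, pivot var)
  order.reserve(eqs.size());
  while (!stack.empty()) {
    int32_t v = stack.back();
    stack.pop_back();
    if (deg[(size_t)v] != 1) continue;
    int32_t e = xsum[(size_t)v];
    order.push_back(std::make_pair(e, v));
    eqs[(size_t)e].active = 0;
    for (int t = 0; t < eqs[(size_t)e].nv; ++t) {
      int32_t u = eqs[(size_t)e].v[t];
      deg[(size_t)u]--;
      xsum[(size_t)u] ^= e;
      if (deg[(size_t)u] == 1) stack.push_back(u);
    }
  }

  // dense elimination on the 2-core
  std::vector<int32_t> core_var; // core variable -> global position
  std::vector<int32_t> vmap((size_t)array_bits, -1);
  std::vector<size_t> core_eqs;
  for (size_t e = 0; e < eqs.size(); ++e) {
    if (!eqs[e].active) continue;
    core_eqs.push_back(e);
    for (int t = 0; t < eqs[e].nv; ++t) {
      int32_t u = eqs[e].v[t];
      if (vmap[(size_t)u] < 0) {
        vmap[(size_t)u] = (int32_t)core_var.size();
        core_var.push_back(u);
      }
    }
  }
  bits.assign((size_t)array_bits, 0);
  if (!core_eqs.empty()) {
    int ncols = (int)core_var.size();
    int words = (ncols + 1 + 63) / 64;
    std::vector<std::vector<uint64_t> > rows(core_eqs.size());
    for (size_t r = 0; r < core_eqs.size(); ++r) {
      rows[r].assign((size_t)words, 0ULL);
      Eq &e = eqs[core_eqs[r]];
      for (int t = 0; t < e.nv; ++t) {
        int c = vmap[(size_t)e.v[t]];
        rows[r][(size_t)(c / 64)] ^= (1ULL << (c % 64));
      }
      if (e.rhs) rows[r][(size_t)(ncols / 64)] ^= (1ULL << (ncols % 64));
    }
    std::vector<uint8_t> sol;
    if (!dense_solve(rows, ncols, sol)) return false;
    for (int c = 0; c < ncols; ++c) bits[(size_t)core_var[(size_t)c]] = sol[(size_t)c];
  }

  // back-substitute peeled equations in reverse order
  for (size_t i = order.size(); i-- > 0;) {
    Eq &e = eqs[(size_t)order[i].first];
    int32_t pv = order[i].second;
    uint8_t b = e.rhs;
    for (int t = 0; t < e.nv; ++t)
      if (e.v[t] != pv) b ^= bits[(size_t)e.v[t]];
    bits[(size_t)pv] = b;
  }

  // safety: verify every equation
  for (size_t e = 0; e < eqs.size(); ++e) {
    uint8_t b = 0;
    for (int t = 0; t < eqs[e].nv; ++t) b ^= bits[(size_t)eqs[e].v[t]];
    if (b != eqs[e].rhs) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".csf_build_cpp")]]
List csf_build_cpp(CharacterVector keys, IntegerVector lens,
                   NumericVector codes, double gamma, int chunk_target,
                   int eq_target, int seed, int max_len, int max_attempts) {
  R_xlen_t n = keys.size();
  uint64_t sd = (uint64_t)(int64_t)seed;
  std::vector<uint64_t> packed((size_t)n);
  double total_bits = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(keys, i));
    int k = LENGTH(STRING_ELT(keys, i));
    if (k > 31 || !kcsf_pack(s, k, packed[(size_t)i]))
      stop("invalid key '%s' (must be ACGT, length <= 31)", s);
    total_bits += lens[i];
  }
  uint64_t nchunks = 1;
  uint64_t by_keys = (uint64_t)((n + chunk_target - 1) / chunk_target);
  uint64_t by_eqs = (uint64_t)std::ceil(total_bits / (double)eq_target);
  if (by_keys > nchunks) nchunks = by_keys;
  if (by_eqs > nchunks) nchunks = by_eqs;

  // scatter keys to chunks
  std::vector<std::vector<size_t> > members((size_t)nchunks);
  for (R_xlen_t i = 0; i < n; ++i)
    members[(size_t)chunk_of(packed[(size_t)i], sd, nchunks)].push_back(
        (size_t)i);

  List arrays((R_xlen_t)nchunks);
  NumericVector array_bits_out((R_xlen_t)nchunks);
  IntegerVector attempts_out((R_xlen_t)nchunks);
  for (uint64_t c = 0; c < nchunks; ++c) {
    std::vector<size_t> &mem = members[(size_t)c];
    // sort member keys so the build is independent of input order
    std::sort(mem.begin(), mem.end(), [&](size_t a, size_t b) {
      return packed[a] < packed[b];
    });
    for (size_t i = 1; i < mem.size(); ++i)
      if (packed[mem[i]] == packed[mem[i - 1]])
        stop("duplicate key '%s' in CSF input",
             kcsf_unpack(packed[mem[i]], LENGTH(STRING_ELT(keys, (R_xlen_t)mem[i]))).c_str());
    std::vector<uint64_t> ck(mem.size()), cc(mem.size());
    std::vector<int> cl(mem.size());
    double chunk_len = 0;
    for (size_t i = 0; i < mem.size(); ++i) {
      ck[i] = packed[mem[i]];
      cl[i] = lens[(R_xlen_t)mem[i]];
      cc[i] = (uint64_t)codes[(R_xlen_t)mem[i]];
      chunk_len += cl[i];
    }
    if (chunk_len == 0) { // empty chunk (or all-zero-length codewords)
      arrays[(R_xlen_t)c] = RawVector(0);
      array_bits_out[(R_xlen_t)c] = 0;
      attempts_out[(R_xlen_t)c] = 0;
      continue;
    }
    bool ok = false;
    std::vector<uint8_t> bits;
    uint64_t ab = 0;
    int attempt = 0;
    for (; attempt < max_attempts; ++attempt) {
      // gamma sits near the 3-XOR solvability threshold, so small chunks
      // occasionally draw singular systems; late retries widen the array
      // by 4% per attempt (the realized size is stored per chunk)
      double g = gamma * (attempt > 3 ? 1.0 + 0.04 * (attempt - 3) : 1.0);
      ab = (uint64_t)std::ceil(g * chunk_len);
      if (ab < (uint64_t)max_len) ab = (uint64_t)max_len;
      if (build_chunk(ck, cl, cc, chunk_seed(sd, c, (uint64_t)attempt), ab,
                      max_len, bits)) {
        ok = true;
        break;
      }
    }
    if (!ok)
      stop("CSF chunk %d unsolvable after %d seed attempts; retry with a larger gamma",
           (int)c, max_attempts);
    RawVector rv((R_xlen_t)((ab + 7) / 8));
    for (uint64_t b = 0; b < ab; ++b)
      if (bits[(size_t)b]) rv[(R_xlen_t)(b >> 3)] |= (Rbyte)(1u << (b & 7));
    arrays[(R_xlen_t)c] = rv;
    array_bits_out[(R_xlen_t)c] = (double)ab;
    attempts_out[(R_xlen_t)c] = attempt;
  }
  return List::create(_["arrays"] = arrays, _["arrayBits"] = array_bits_out,
                      _["attempts"] = attempts_out,
                      _["nChunks"] = (double)nchunks);
}

// [[Rcpp::export(name = ".csf_query_cpp")]]
IntegerVector csf_query_cpp(CharacterVector keys, int seed, double nchunks_d,
                            List arrays, NumericVector array_bits,
                            IntegerVector attempts, int max_len,
                            IntegerVector len_count, NumericVector len_first,
                            IntegerVector len_offset) {
  uint64_t sd = (uint64_t)(int64_t)seed;
  uint64_t nchunks = (uint64_t)nchunks_d;
  R_xlen_t n = keys.size();
  IntegerVector out(n);
  std::vector<const Rbyte *> arr((size_t)nchunks);
  for (uint64_t c = 0; c < nchunks; ++c) {
    RawVector rv = arrays[(R_xlen_t)c];
    arr[(size_t)c] = rv.size() ? RAW(rv) : (const Rbyte *)0;
  }
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(keys, i));
    int k = LENGTH(STRING_ELT(keys, i));
    uint64_t key;
    if (k > 31 || !kcsf_pack(s, k, key)) stop("invalid key '%s'", s);
    uint64_t c = chunk_of(key, sd, nchunks);
    uint64_t ab = (uint64_t)array_bits[(R_xlen_t)c];
    int idx = 0; // arbitrary symbol for degenerate chunks / unbuilt keys
    if (ab > 0) {
      uint64_t cs = chunk_seed(sd, c, (uint64_t)attempts[(R_xlen_t)c]);
      uint64_t npos = ab - (uint64_t)max_len + 1;
      uint64_t p[3];
      key_positions(key, cs, npos, p);
      const Rbyte *w = arr[(size_t)c];
      uint64_t code = 0;
      idx = 0;
      for (int l = 1; l <= max_len; ++l) {
        uint64_t j = (uint64_t)(l - 1);
        uint64_t b = 0;
        for (int t = 0; t < 3; ++t) {
          uint64_t pos = p[t] + j;
          b ^= (uint64_t)((w[pos >> 3] >> (pos & 7)) & 1);
        }
        code = (code << 1) | b;
        if (len_count[l] > 0) {
          uint64_t first = (uint64_t)len_first[l];
          if (code >= first && code - first < (uint64_t)len_count[l]) {
            idx = len_offset[l] + (int)(code - first);
            break;
          }
        }
      }
    }
    out[i] = idx; // 0-based canonical symbol index
  }
  return out;
}

// Standalone GF(2) solver (positions are 0-based).
// [[Rcpp::export(name = ".gf2_solve_cpp")]]
SEXP gf2_solve_cpp(List positions, LogicalVector rhs, int nvars) {
  size_t m = (size_t)positions.size();
  int words = (nvars + 1 + 63) / 64;
  std::vector<std::vector<uint64_t> > rows(m);
  for (size_t r = 0; r < m; ++r) {
    IntegerVector ps = positions[(R_xlen_t)r];
    rows[r].assign((size_t)words, 0ULL);
    for (R_xlen_t t = 0; t < ps.size(); ++t) {
      int p = ps[t];
      if (p < 0 || p >= nvars) stop("position %d out of bounds", p);
      rows[r][(size_t)(p / 64)] ^= (1ULL << (p % 64));
    }
    if (rhs[(R_xlen_t)r]) rows[r][(size_t)(nvars / 64)] ^= (1ULL << (nvars % 64));
  }
  std::vector<uint8_t> sol;
  if (!dense_solve(rows, nvars, sol)) return R_NilValue;
  LogicalVector out(nvars);
  for (int v = 0; v < nvars; ++v) out[v] = sol[(size_t)v] != 0;
  return out;
}
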