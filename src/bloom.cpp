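#include <Rcpp.h>
#include "kcsf_util.h"

using namespace Rcpp;

// Double hashing (Kirsch-Mitzenmacher): probe i at h1 + i*h2 mod m_bits.
static inline void probe_bases(const char *s, int len, uint64_t seed,
                               uint64_t &h1, uint64_t &h2) {
  uint64_t v;
  if (len > 31 || !kcsf_pack(s, len, v)) stop("invalid key '%s'", s);
  h1 = kcsf_hash(v, seed);
  h2 = kcsf_hash(v, seed ^ 0xa5a5a5a5a5a5a5a5ULL) | 1ULL;
}

// [[Rcpp::export(name = ".bloom_build_cpp")]]
RawVector bloom_build_cpp(CharacterVector keys, double m_bits_d,
                          int num_hashes, int seed) {
  uint64_t m_bits = (uint64_t)m_bits_d;
  if (m_bits == 0) stop("Bloom filter must have at least 1 bit");
  RawVector bits((R_xlen_t)((m_bits + 7) / 8));
  uint64_t sd = (uint64_t)(int64_t)seed;
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    uint64_t h1, h2;
    probe_bases(CHAR(STRING_ELT(keys, i)), LENGTH(STRING_ELT(keys, i)), sd,
                h1, h2);
    for (int j = 0; j < num_hashes; ++j) {
      uint64_t pos = (h1 + (uint64_t)j * h2) % m_bits;
      bits[(R_xlen_t)(pos >> 3)] |= (Rbyte)(1u << (pos & 7));
    }
  }
  return bits;
}

// [[Rcpp::export(name = ".bloom_query_cpp")]]
LogicalVector bloom_query_cpp(RawVector bits, double m_bits_d, int num_hashes,
                              int seed, CharacterVector keys) {
  uint64_t m_bits = (uint64_t)m_bits_d;
  uint64_t sd = (uint64_t)(int64_t)seed;
  LogicalVector out(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); ++i) {
    uint64_t h1, h2;
    probe_bases(CHAR(STRING_ELT(keys, i)), LENGTH(STRING_ELT(keys, i)), sd,
                h1, h2);
    bool hit = true;
    for (int j = 0; j < num_hashes && hit; ++j) {
      uint64_t pos = (h1 + (uint64_t)j * h2) % m_bits;
      hit = (bits[(R_xlen_t)(pos >> 3)] >> (pos & 7)) & 1;
    }
    out[i] = hit;
  }
  return out;
}
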