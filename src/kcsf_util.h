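#ifndef KCSF_UTIL_H
#define KCSF_UTIL_H

#include <cstdint>
#include <string>

// splitmix64: statistically strong 64-bit mixer, used for every hash in the
// package (m-mer order, Bloom probes, CSF positions, chunk assignment).
static inline uint64_t kcsf_splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

static inline uint64_t kcsf_hash(uint64_t key, uint64_t seed) {
  return kcsf_splitmix64(key ^ kcsf_splitmix64(seed));
}

// A=0 C=1 G=2 T=3, N=4, anything else -1.
static inline int kcsf_base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case 'N': case 'n': return 4;
  default: return -1;
  }
}

// First base most significant, so numeric order on packed values equals
// lexicographic order on equal-length strings (ACGT alphabet order).
static inline bool kcsf_pack(const char *s, int k, uint64_t &out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = kcsf_base_code(s[i]);
    if (c < 0 || c > 3) return false;
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

static inline uint64_t kcsf_revcomp(uint64_t v, int k) {
  uint64_t r = 0;
  for (int i = 0; i < k; ++i) {
    r = (r << 2) | (3ULL - (v & 3ULL));
    v >>= 2;
  }
  return r;
}

static inline std::string kcsf_unpack(uint64_t v, int k) {
  static const char B[5] = "ACGT";
  std::string s((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t)i] = B[v & 3ULL];
    v >>= 2;
  }
  return s;
}

#endif
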