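#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include "kcsf_util.h"

using namespace Rcpp;

// Shared sliding-window scan: calls f(canonical_or_forward_packed_kmer) for
// every window of k consecutive ACGT bases (windows containing N are skipped).
template <typename F>
static void scan_sequence(const char *s, R_xlen_t len, int k, bool canonical,
                          F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t v = 0;
  int run = 0;
  for (R_xlen_t i = 0; i < len; ++i) {
    int c = kcsf_base_code(s[i]);
    if (c < 0)
      stop("invalid character '%c' at position %d (only A,C,G,T,N allowed)",
           s[i], (int)(i + 1));
    if (c == 4) { // N resets the window
      run = 0;
      v = 0;
      continue;
    }
    v = ((v << 2) | (uint64_t)c) & mask;
    if (++run >= k) {
      uint64_t key = v;
      if (canonical) {
        uint64_t rc = kcsf_revcomp(v, k);
        if (rc < key) key = rc;
      }
      f(key);
    }
  }
}

static List map_to_table(std::unordered_map<uint64_t, int64_t> &counts, int k) {
  std::vector<uint64_t> keys;
  keys.reserve(counts.size());
  for (auto &kv : counts) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  R_xlen_t n = (R_xlen_t)keys.size();
  CharacterVector km(n);
  IntegerVector ct(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    km[i] = kcsf_unpack(keys[(size_t)i], k);
    int64_t c = counts[keys[(size_t)i]];
    if (c > INT_MAX) stop("k-mer count overflows integer range");
    ct[i] = (int)c;
  }
  return List::create(_["kmer"] = km, _["count"] = ct);
}

// [[Rcpp::export(name = ".count_kmers_cpp")]]
List count_kmers_cpp(CharacterVector sequences, int k, bool canonical) {
  if (sequences.size() == 0) stop("no input sequences");
  std::unordered_map<uint64_t, int64_t> counts;
  for (R_xlen_t s = 0; s < sequences.size(); ++s) {
    const char *str = CHAR(STRING_ELT(sequences, s));
    R_xlen_t len = (R_xlen_t)LENGTH(STRING_ELT(sequences, s));
    scan_sequence(str, len, k, canonical, [&](uint64_t key) { counts[key]++; });
  }
  if (counts.empty())
    stop("no k-mers of length %d found: every sequence is shorter than k (or all windows contain N)",
         k);
  return map_to_table(counts, k);
}

// [[Rcpp::export(name = ".document_frequency_cpp")]]
List document_frequency_cpp(List genomes, int k, bool canonical) {
  if (genomes.size() == 0) stop("no input genomes");
  std::unordered_map<uint64_t, int64_t> df;
  bool any = false;
  for (R_xlen_t g = 0; g < genomes.size(); ++g) {
    CharacterVector seqs(genomes[g]);
    std::unordered_set<uint64_t> present;
    for (R_xlen_t s = 0; s < seqs.size(); ++s) {
      const char *str = CHAR(STRING_ELT(seqs, s));
      R_xlen_t len = (R_xlen_t)LENGTH(STRING_ELT(seqs, s));
      scan_sequence(str, len, k, canonical,
                    [&](uint64_t key) { present.insert(key); });
    }
    for (uint64_t key : present) df[key]++;
    if (!present.empty()) any = true;
  }
  if (!any) stop("no k-mers of length %d found in any genome", k);
  return map_to_table(df, k);
}

// Number of valid (N-free) k-windows, for the conservation invariant.
// [[Rcpp::export(name = ".count_windows_cpp")]]
double count_windows_cpp(CharacterVector sequences, int k) {
  double total = 0;
  for (R_xlen_t s = 0; s < sequences.size(); ++s) {
    const char *str = CHAR(STRING_ELT(sequences, s));
    R_xlen_t len = (R_xlen_t)LENGTH(STRING_ELT(sequences, s));
    scan_sequence(str, len, k, false, [&](uint64_t) { total += 1; });
  }
  return total;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const char *s = CHAR(STRING_ELT(x, i));
    int n = LENGTH(STRING_ELT(x, i));
    std::string r((size_t)n, 'A');
    for (int j = 0; j < n; ++j) {
      int c = kcsf_base_code(s[j]);
      if (c < 0) stop("invalid base in '%s'", s);
      static const char B[6] = "TGCAN"; // complement of ACGTN
      r[(size_t)(n - 1 - j)] = B[c];
    }
    out[i] = r;
  }
  return out;
}
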