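#include <Rcpp.h>
#include <cstdint>

using namespace Rcpp;

// CRC-32 (IEEE 802.3, reflected polynomial 0xEDB88320), table-driven.
static uint32_t crc_table[256];
static bool crc_init_done = false;

static void crc_init() {
  for (uint32_t i = 0; i < 256; ++i) {
    uint32_t c = i;
    for (int j = 0; j < 8; ++j)
      c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
    crc_table[i] = c;
  }
  crc_init_done = true;
}

// [[Rcpp::export(name = ".crc32_cpp")]]
double crc32_cpp(RawVector data) {
  if (!crc_init_done) crc_init();
  uint32_t c = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    c = crc_table[(c ^ data[i]) & 0xFFu] ^ (c >> 8);
  return (double)(c ^ 0xFFFFFFFFu);
}
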