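// Deterministic integer seed derivation (splitmix64-based hash), so that
// every replicate/purpose gets an independent stream derived from one root
// seed, reproducibly across platforms.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
int mix_seed_cpp(IntegerVector parts) {
  uint64_t h = 0x9E3779B97F4A7C15ULL;
  for (int i = 0; i < parts.size(); ++i) {
    uint64_t z = h ^ ((uint64_t)(uint32_t)parts[i] + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2));
    z += 0x9E3779B97F4A7C15ULL;
    z ^= z >> 30; z *= 0xBF58476D1CE4E5B9ULL;
    z ^= z >> 27; z *= 0x94D049BB133111EBULL;
    z ^= z >> 31;
    h = z;
  }
  return (int)(h % 2147483647ULL); // in [0, 2^31 - 2]
}
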