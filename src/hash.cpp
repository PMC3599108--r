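#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// 64-bit FNV-1a over the raw bytes of each string, returned as 16-char
// lowercase hex. Stable across platforms and sessions; collisions are
// accepted (negligible probability at corpus scale).

// [[Rcpp::export]]
CharacterVector fnv1a64_cpp(CharacterVector x) {
  const uint64_t prime = 1099511628211ULL;
  const int n = x.size();
  CharacterVector out(n);
  char buf[17];
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(x, i));
    uint64_t h = 14695981039346656037ULL;
    for (const char *p = s; *p; ++p) {
      h ^= (uint64_t)(unsigned char)(*p);
      h *= prime;
    }
    snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
    out[i] = buf;
  }
  return out;
}
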