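#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <set>

using namespace Rcpp;

// FNV-1a hash, as used for fastText-style subword bucket hashing.
static inline uint32_t fnv1a(const std::string &s) {
  uint32_t h = 2166136261u;
  for (size_t i = 0; i < s.size(); ++i) {
    h ^= (uint32_t)(unsigned char)s[i];
    h *= 16777619u;
  }
  return h;
}

// For each word, the sorted unique bucket ids (0-based, < buckets) of its
// character n-grams of length minn..maxn over "<word>".
// [[Rcpp::export(name = ".ngram_buckets_cpp")]]
List ngram_buckets_cpp(CharacterVector words, int minn, int maxn, int buckets) {
  int n = words.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    std::string w = "<" + std::string(words[i]) + ">";
    std::set<int> ids;
    int len = (int)w.size();
    for (int l = minn; l <= maxn && l <= len; ++l) {
      for (int s = 0; s + l <= len; ++s) {
        ids.insert((int)(fnv1a(w.substr(s, l)) % (uint32_t)buckets));
      }
    }
    out[i] = IntegerVector(ids.begin(), ids.end());
  }
  return out;
}
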