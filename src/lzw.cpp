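#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// Lempel-Ziv-Welch over the binary alphabet {'0','1'}.
//
// The parser repeatedly takes the longest dictionary word matching the
// remaining input, emits its code, and inserts that word extended by the
// next character. Because every inserted word is an existing word plus one
// character, the dictionary is prefix-closed and greedy longest-match is
// exact. An optional seed dictionary (e.g. the final dictionary of a prior
// pass over a reference corpus) replaces the default {"0","1"} start and is
// still extended during the pass.

static void init_dict(std::unordered_map<std::string, int>& dict,
                      std::vector<std::string>& words,
                      const std::vector<std::string>& seed) {
  if (seed.empty()) {
    words.push_back("0");
    words.push_back("1");
  } else {
    words = seed;
  }
  for (size_t i = 0; i < words.size(); ++i) dict[words[i]] = (int) i;
  if (dict.find("0") == dict.end() || dict.find("1") == dict.end())
    stop("seed dictionary must contain both single-symbol words \"0\" and \"1\"");
}

// [[Rcpp::export]]
List lzw_compress_cpp(const std::string& s,
                      const std::vector<std::string>& seed_words) {
  if (s.empty()) stop("cannot compress an empty string");
  for (size_t i = 0; i < s.size(); ++i)
    if (s[i] != '0' && s[i] != '1')
      stop("input contains a non-binary symbol at position %d", (int) (i + 1));

  std::unordered_map<std::string, int> dict;
  std::vector<std::string> words;
  init_dict(dict, words, seed_words);

  std::vector<int> codes;
  std::string w(1, s[0]);
  for (size_t i = 1; i < s.size(); ++i) {
    std::string wc = w + s[i];
    if (dict.find(wc) != dict.end()) {
      w.swap(wc);
    } else {
      codes.push_back(dict[w]);
      dict[wc] = (int) words.size();
      words.push_back(wc);
      w.assign(1, s[i]);
    }
  }
  codes.push_back(dict[w]);

  return List::create(_["codes"] = IntegerVector(codes.begin(), codes.end()),
                      _["n_codes"] = (int) codes.size(),
                      _["dict_words"] = CharacterVector(words.begin(), words.end()));
}

// [[Rcpp::export]]
std::string lzw_decompress_cpp(const IntegerVector& codes,
                               const std::vector<std::string>& seed_words) {
  if (codes.size() == 0) return "";
  std::unordered_map<std::string, int> dict;
  std::vector<std::string> words;
  init_dict(dict, words, seed_words);

  if (codes[0] < 0 || codes[0] >= (int) words.size())
    stop("invalid first code");
  std::string prev = words[codes[0]];
  std::string out = prev;
  for (int i = 1; i < codes.size(); ++i) {
    int c = codes[i];
    std::string entry;
    if (c >= 0 && c < (int) words.size()) {
      entry = words[c];
    } else if (c == (int) words.size()) {
      entry = prev + prev[0];        // the cScSc corner case
    } else {
      stop("invalid code %d at position %d", c, i + 1);
    }
    out += entry;
    words.push_back(prev + entry[0]);
    prev = entry;
  }
  return out;
}
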