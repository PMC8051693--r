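#include <Rcpp.h>
using namespace Rcpp;

// Lempel-Ziv 1976 exhaustive-history complexity of a binary sequence.
// Scans left to right; a new word is produced whenever the current
// phrase cannot be reproduced from the prior history plus the phrase's
// own proper prefix (the classic copy-with-extension rule). A final
// incomplete phrase counts as a word.
// [[Rcpp::export(name = ".lz76_cpp")]]
int lz76_cpp(IntegerVector b) {
  int n = b.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1;    // word count; the first symbol is always a word
  int i = 0;    // start of the history prefix that may be copied from
  int k = 1;    // current match length being tried
  int l = 1;    // start of the current phrase
  int k_max = 1;
  while (true) {
    if (b[i + k - 1] == b[l + k - 1]) {
      k++;
      if (l + k > n) {  // ran off the end mid-phrase: counts as a word
        c++;
        break;
      }
    } else {
      if (k > k_max) k_max = k;
      i++;
      if (i == l) {     // no prior position reproduces the phrase
        c++;
        l += k_max;
        if (l + 1 > n) break;
        i = 0;
        k = 1;
        k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
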