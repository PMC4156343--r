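#include <Rcpp.h>
using namespace Rcpp;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// motif is primitive iff it is not a whole number of copies of a shorter motif
static bool motif_primitive(const char* s, int m) {
  for (int d = 1; d < m; ++d) {
    if (m % d) continue;
    bool periodic = true;
    for (int i = d; i < m && periodic; ++i)
      if (s[i] != s[i - d]) periodic = false;
    if (periodic) return false;
  }
  return true;
}

// Perfect tandem-repeat scan for motif lengths 2..6.
// min_repeats: thresholds for motif lengths 2,3,4,5,6 (in that order).
// Returns 1-based inclusive [start, end] spanning exactly repeats * motif_len
// bases; runs are maximal and reported once, under the leftmost phase of
// their primitive motif.  Non-ACGT characters terminate runs.
// [[Rcpp::export]]
DataFrame ssr_scan_cpp(std::string seq, IntegerVector min_repeats) {
  const int n = (int) seq.size();
  const char* s = seq.c_str();
  std::vector<int> start, end, mlen, reps;
  std::vector<std::string> motifs;

  for (int m = 2; m <= 6; ++m) {
    const int thr = min_repeats[m - 2];
    int i = 0;
    const int lim = n - m;  // match[i] defined for i in [0, lim)
    while (i < lim) {
      if (!(is_acgt(s[i]) && s[i] == s[i + m])) { ++i; continue; }
      // maximal run of consecutive matches starting at i
      int j = i;
      while (j < lim && is_acgt(s[j]) && s[j] == s[j + m]) ++j;
      const int span = (j - i) + m;        // tandem region length
      const int count = span / m;
      if (count >= thr && motif_primitive(s + i, m)) {
        start.push_back(i + 1);
        end.push_back(i + count * m);
        mlen.push_back(m);
        reps.push_back(count);
        motifs.push_back(std::string(s + i, s + i + m));
      }
      i = j + 1;
    }
  }
  return DataFrame::create(
      _["start"] = start, _["end"] = end, _["motif"] = motifs,
      _["motif_length"] = mlen, _["repeats"] = reps,
      _["stringsAsFactors"] = false);
}
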