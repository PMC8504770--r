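#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Structural scan for TIR-bounded elements.  For every interval [i, j)
// whose length lies in [min_len, max_len], find the longest terminal
// inverted repeat t in [min_tir, max_tir] such that the prefix of length t
// matches the reverse complement of the suffix of length t with at most
// max_mismatch mismatches.  Positions containing 'N' always count as
// mismatches.  Returns one row per qualifying interval with its maximal
// TIR length; overlap resolution is done by the caller.

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

// [[Rcpp::export(name = ".tir_scan_cpp")]]
DataFrame tir_scan_cpp(std::string seq, int min_tir, int max_tir,
                       int min_len, int max_len, int max_mismatch) {
  const int n = (int)seq.size();
  if (min_tir < 1 || min_len < 2 * min_tir)
    stop("min_len must allow two non-overlapping TIRs of min_tir bases");
  std::vector<int> starts, ends, tirs, mms;
  for (int i = 0; i + min_len <= n; ++i) {
    const int jmax = std::min(n, i + max_len);
    for (int j = i + min_len; j <= jmax; ++j) {
      const int len = j - i;
      const int tcap = std::min(max_tir, len / 2);
      int mism = 0, best_t = 0, best_mm = 0;
      for (int k = 0; k < tcap; ++k) {
        const char a = seq[i + k];
        const char b = comp(seq[j - 1 - k]);
        if (a == 'N' || b == 'N' || a != b) ++mism;
        if (mism > max_mismatch) break;
        best_t = k + 1;
        best_mm = mism;
      }
      if (best_t >= min_tir) {
        starts.push_back(i);
        ends.push_back(j);
        tirs.push_back(best_t);
        mms.push_back(best_mm);
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends,
                           _["tir_length"] = tirs,
                           _["tir_mismatches"] = mms);
}
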