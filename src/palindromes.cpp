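#include <Rcpp.h>
using namespace Rcpp;

// Watson-Crick complement; anything non-ACGT (incl. N) never pairs.
static inline char comp(char b) {
  switch (b) {
    case 'A': return 'T';
    case 'T': return 'A';
    case 'G': return 'C';
    case 'C': return 'G';
    default: return 0;
  }
}

// Enumerate all maximal imperfect palindromes: for every (loop position, loop
// length) the arms are extended symmetrically outwards; a pair that does not
// complement costs one mismatch. Extension stops when the next pair would
// exceed max_mismatch or runs off the sequence; the call is emitted when the
// final arm length reaches min_arm. Coordinates are 1-based.
// [[Rcpp::export(name = ".scan_palindromes")]]
DataFrame scan_palindromes_cpp(std::string seq, int min_arm, int max_loop,
                               int max_mismatch) {
  int n = (int) seq.size();
  std::vector<int> center, arm, loop, mism, start, end;
  for (int g = 0; g <= max_loop; ++g) {
    // left arm ends at i (0-based), loop occupies i+1 .. i+g
    for (int i = 0; i + g + 1 < n; ++i) {
      int mm = 0, d = 0;
      while (true) {
        int li = i - d, ri = i + g + 1 + d;
        if (li < 0 || ri >= n) break;
        bool ok = comp(seq[li]) && comp(seq[li]) == seq[ri];
        if (!ok) {
          if (mm + 1 > max_mismatch) break;
          ++mm;
        }
        ++d;
      }
      if (d >= min_arm) {
        center.push_back(i + 1);
        arm.push_back(d);
        loop.push_back(g);
        mism.push_back(mm);
        start.push_back(i - d + 2);      // 1-based span start
        end.push_back(i + g + d + 1);    // 1-based span end
      }
    }
  }
  return DataFrame::create(_["center"] = center, _["arm_len"] = arm,
                           _["loop_len"] = loop, _["mismatches"] = mism,
                           _["start"] = start, _["end"] = end);
}

// Match vector for period u over a char sequence: m[i] = (s[i] == s[i+u]),
// with N never matching. Returned as logical, length n - u.
// [[Rcpp::export(name = ".period_match")]]
LogicalVector period_match_cpp(std::string seq, int u) {
  int n = (int) seq.size();
  if (u >= n) return LogicalVector(0);
  LogicalVector out(n - u);
  for (int i = 0; i + u < n; ++i) {
    char a = seq[i], b = seq[i + u];
    out[i] = (a == b) && (a == 'A' || a == 'C' || a == 'G' || a == 'T');
  }
  return out;
}
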