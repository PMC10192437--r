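#include <Rcpp.h>
using namespace Rcpp;

// Scan each read for every spacer at every offset on the given strand(s),
// tolerating up to max_mismatch Hamming mismatches ('N' never matches).
// Returns, per read: the index (1-based) of the unique matching spacer, 0 if
// none matched, -1 if more than one distinct spacer matched (ambiguous).
// [[Rcpp::export(name = ".match_spacers")]]
IntegerVector match_spacers(CharacterVector reads, CharacterVector spacers,
                            int max_mismatch) {
  const int n_reads = reads.size();
  const int n_sp = spacers.size();
  std::vector<std::string> sp(n_sp);
  for (int j = 0; j < n_sp; ++j) sp[j] = as<std::string>(spacers[j]);
  const int w = n_sp ? (int)sp[0].size() : 0;

  IntegerVector out(n_reads);
  for (int i = 0; i < n_reads; ++i) {
    const std::string rd = as<std::string>(reads[i]);
    const int L = (int)rd.size();
    int hit = 0;   // 0 = none, >0 index, -1 ambiguous
    for (int j = 0; j < n_sp && hit != -1; ++j) {
      const char* s = sp[j].c_str();
      bool matched = false;
      for (int off = 0; off + w <= L && !matched; ++off) {
        int mm = 0;
        const char* r = rd.c_str() + off;
        for (int k = 0; k < w; ++k) {
          if (r[k] != s[k] || r[k] == 'N') {
            if (++mm > max_mismatch) break;
          }
        }
        if (mm <= max_mismatch) matched = true;
      }
      if (matched) {
        if (hit == 0) hit = j + 1;
        else if (hit != j + 1) hit = -1;
      }
    }
    out[i] = hit;
  }
  return out;
}
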