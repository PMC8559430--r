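#include <Rcpp.h>
using namespace Rcpp;

// Overlap-merge of one read pair (r2 already reverse-complemented).
// Scans all overlap lengths >= minOverlap, keeps the one with the lowest
// mismatch fraction (ties: longest overlap); overlaps above maxMismFrac
// are rejected. Disagreeing overlap positions take the base from the mate
// whose flanking non-overlap segment is longer (the better-anchored call).

// [[Rcpp::export(name = ".mergePair")]]
List mergePair(std::string r1, std::string r2rc, int minOverlap,
               double maxMismFrac) {
  int n1 = r1.size(), n2 = r2rc.size();
  int maxOv = std::min(n1, n2);
  int bestOv = -1, bestMis = 0;
  double bestFrac = 1e9;
  for (int ov = minOverlap; ov <= maxOv; ++ov) {
    int mism = 0;
    const char* a = r1.data() + (n1 - ov);
    const char* b = r2rc.data();
    for (int k = 0; k < ov; ++k)
      if (a[k] != b[k]) ++mism;
    double frac = (double)mism / ov;
    if (frac <= maxMismFrac &&
        (frac < bestFrac || (frac == bestFrac && ov > bestOv))) {
      bestFrac = frac;
      bestOv = ov;
      bestMis = mism;
    }
  }
  if (bestOv < 0)
    return List::create(_["merged"] = CharacterVector::create(NA_STRING),
                        _["overlap"] = 0, _["mismatches"] = 0);
  std::string ovSeq(bestOv, 'N');
  for (int k = 0; k < bestOv; ++k) {
    char a = r1[n1 - bestOv + k], b = r2rc[k];
    if (a == b) ovSeq[k] = a;
    else ovSeq[k] = (n1 - bestOv >= n2 - bestOv) ? a : b;
  }
  std::string merged = r1.substr(0, n1 - bestOv) + ovSeq +
    r2rc.substr(bestOv);
  return List::create(_["merged"] = merged, _["overlap"] = bestOv,
                      _["mismatches"] = bestMis);
}
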