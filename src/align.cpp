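#include <Rcpp.h>
using namespace Rcpp;

// Token-level Smith-Waterman local alignment with optional repeated
// extraction: the best-scoring local alignment is found, its spans are
// masked in both sequences, and the search repeats while the best score
// stays at or above min_segment_score. Masked positions cannot take part
// in any later alignment (their DP cells are pinned to zero), so extracted
// segments never overlap within a sequence.
//
// Tokens are integer codes (>= 1). Traceback prefers diagonal over up
// (gap in b) over left (gap in a); the pure-R oracle in the test suite
// uses the same preference so matched-token counts are comparable.

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b,
                  double match, double mismatch, double gap,
                  double min_segment_score, bool repeated) {
  const int la = a.size(), lb = b.size();
  std::vector<bool> maskA(la, false), maskB(lb, false);
  std::vector<double> H((la + 1) * (lb + 1), 0.0);
  auto at = [&](int i, int j) -> double& { return H[i * (lb + 1) + j]; };

  int matched = 0;
  double total_score = 0.0;
  std::vector<int> seg_sa, seg_ea, seg_sb, seg_eb;

  for (int iter = 0;; ++iter) {
    double best = 0.0;
    int bi = -1, bj = -1;
    for (int i = 1; i <= la; ++i) {
      for (int j = 1; j <= lb; ++j) {
        double h;
        if (maskA[i - 1] || maskB[j - 1]) {
          h = 0.0;
        } else {
          double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
          h = at(i - 1, j - 1) + s;
          h = std::max(h, at(i - 1, j) + gap);
          h = std::max(h, at(i, j - 1) + gap);
          h = std::max(h, 0.0);
        }
        at(i, j) = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    bool accept = repeated ? (best >= min_segment_score) : (best > 0.0);
    if (!accept || bi < 0) break;

    // traceback
    int i = bi, j = bj, seg_matched = 0;
    while (i > 0 && j > 0 && at(i, j) > 0.0) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      if (!maskA[i - 1] && !maskB[j - 1] &&
          at(i, j) == at(i - 1, j - 1) + s) {
        if (a[i - 1] == b[j - 1]) ++seg_matched;
        --i; --j;
      } else if (at(i, j) == at(i - 1, j) + gap) {
        --i;
      } else {
        --j;
      }
    }
    // segment spans [i, bi) x [j, bj) in 0-based token coordinates
    for (int k = i; k < bi; ++k) maskA[k] = true;
    for (int k = j; k < bj; ++k) maskB[k] = true;
    seg_sa.push_back(i); seg_ea.push_back(bi);
    seg_sb.push_back(j); seg_eb.push_back(bj);
    matched += seg_matched;
    total_score += best;

    if (!repeated) break;
  }

  const int ns = seg_sa.size();
  IntegerMatrix segs(ns, 4);
  for (int k = 0; k < ns; ++k) {
    segs(k, 0) = seg_sa[k] + 1; segs(k, 1) = seg_ea[k] + 1;
    segs(k, 2) = seg_sb[k] + 1; segs(k, 3) = seg_eb[k] + 1;
  }
  colnames(segs) = CharacterVector::create("start_a", "end_a",
                                           "start_b", "end_b");
  return List::create(_["matched_tokens"] = matched,
                      _["score"] = total_score,
                      _["segments"] = segs);
}
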