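#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive window scan of one miRNA against one transcript.
//
// Bases are encoded A=0, C=1, G=2, U=3, N=4. `pen` is a 5x5 row-major
// per-pair penalty lookup indexed pen[mir*5 + tx]; `w` holds the
// positional multiplier for each miRNA position (seed doubling).
// The miRNA is read 5'->3' and pairs antiparallel with the transcript
// window, so miRNA position 1 sits on the window's 3'-most base.
//
// Three alignment shapes are enumerated per window start:
//   gap_type 0: gapless, window length L
//   gap_type 1: miRNA base j unpaired (gap in transcript), length L-1;
//               the gap is charged at miRNA position j
//   gap_type 2: one bulged transcript base between miRNA positions j
//               and j+1, length L+1; charged at miRNA position j+1
//
// Rows returned: start (1-based), gap_type, gap_pos, expectation, for
// every alignment with expectation <= cutoff.
// [[Rcpp::export]]
NumericMatrix scan_windows_cpp(IntegerVector mir, IntegerVector tx,
                               NumericVector pen, NumericVector w,
                               double gap_penalty, double cutoff,
                               int max_gaps) {
  const int L = mir.size(), N = tx.size();
  std::vector<double> hits;

  // gapless
  for (int s = 0; s + L <= N; ++s) {
    double e = 0.0;
    for (int i = 0; i < L; ++i) {
      e += pen[mir[i] * 5 + tx[s + L - 1 - i]] * w[i];
      if (e > cutoff) break;
    }
    if (e <= cutoff) {
      hits.push_back(s + 1); hits.push_back(0);
      hits.push_back(0); hits.push_back(e);
    }
  }

  if (max_gaps >= 1 && L >= 2) {
    // miRNA base j unpaired (1-based j)
    for (int j = 1; j <= L; ++j) {
      double gp = gap_penalty * w[j - 1];
      if (gp > cutoff) continue;
      for (int s = 0; s + L - 1 <= N; ++s) {
        double e = gp;
        for (int i = 1; i <= L && e <= cutoff; ++i) {
          if (i == j) continue;
          int widx = (i < j) ? (L - i - 1) : (L - i);  // 0-based in window
          e += pen[mir[i - 1] * 5 + tx[s + widx]] * w[i - 1];
        }
        if (e <= cutoff) {
          hits.push_back(s + 1); hits.push_back(1);
          hits.push_back(j); hits.push_back(e);
        }
      }
    }
    // bulged transcript base between miRNA positions j and j+1
    for (int j = 1; j <= L - 1; ++j) {
      double gp = gap_penalty * w[j];  // charged at position j+1
      if (gp > cutoff) continue;
      for (int s = 0; s + L + 1 <= N; ++s) {
        double e = gp;
        for (int i = 1; i <= L && e <= cutoff; ++i) {
          int widx = (i <= j) ? (L + 1 - i) : (L - i);  // 0-based in window
          e += pen[mir[i - 1] * 5 + tx[s + widx]] * w[i - 1];
        }
        if (e <= cutoff) {
          hits.push_back(s + 1); hits.push_back(2);
          hits.push_back(j); hits.push_back(e);
        }
      }
    }
  }

  const int nhit = hits.size() / 4;
  NumericMatrix out(nhit, 4);
  for (int k = 0; k < nhit; ++k)
    for (int c = 0; c < 4; ++c) out(k, c) = hits[4 * k + c];
  colnames(out) = CharacterVector::create("start", "gap_type", "gap_pos",
                                          "expectation");
  return out;
}
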