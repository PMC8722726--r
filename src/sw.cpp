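#include <Rcpp.h>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman).
//
// Scoring convention: a gap of length L costs gap_open + L * gap_extend
// (the Biostrings pairwiseAlignment convention), match/mismatch are the
// per-column substitution scores.  'N' never matches anything and is
// scored as a mismatch against every base, including another 'N'.
//
// The optimal end cell is the first cell (row-major scan, rows = a)
// attaining the maximal score; the start is recovered by aligning the
// reversed prefixes, and the aligned strings by a small traceback DP
// restricted to the [start, end) window.  All tie-breaks prefer
// diagonal over vertical over horizontal moves, so the result is fully
// deterministic.

static inline double subscore(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

struct SwEnd {
  double score;
  int i, j; // 1-based end cell (position counts consumed)
};

static SwEnd sw_best_end(const std::string &a, const std::string &b,
                         double match, double mismatch,
                         double go, double ge) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Fprev(m + 1, R_NegInf), Fcur(m + 1, R_NegInf);
  SwEnd best = {0.0, 0, 0};
  for (int i = 1; i <= n; ++i) {
    double E = R_NegInf;
    Hcur[0] = 0.0;
    Fcur[0] = R_NegInf;
    for (int j = 1; j <= m; ++j) {
      E = std::max(Hcur[j - 1] - go - ge, E - ge);
      double F = std::max(Hprev[j] - go - ge, Fprev[j] - ge);
      double diag = Hprev[j - 1] + subscore(a[i - 1], b[j - 1], match, mismatch);
      double h = std::max(0.0, std::max(diag, std::max(E, F)));
      Hcur[j] = h;
      Fcur[j] = F;
      if (h > best.score) {
        best.score = h;
        best.i = i;
        best.j = j;
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }
  return best;
}

// [[Rcpp::export(rng = false)]]
List sw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  SwEnd fwd = sw_best_end(a, b, match, mismatch, gap_open, gap_extend);
  if (fwd.score <= 0.0 || fwd.i == 0) {
    return List::create(_["score"] = 0.0,
                        _["a_start"] = 0, _["a_end"] = 0,
                        _["b_start"] = 0, _["b_end"] = 0,
                        _["aligned_a"] = "", _["aligned_b"] = "",
                        _["matches"] = 0, _["columns"] = 0);
  }
  // Locate the start of the optimal path by aligning reversed prefixes.
  std::string ar(a.begin(), a.begin() + fwd.i);
  std::string br(b.begin(), b.begin() + fwd.j);
  std::reverse(ar.begin(), ar.end());
  std::reverse(br.begin(), br.end());
  SwEnd rev = sw_best_end(ar, br, match, mismatch, gap_open, gap_extend);
  int a_start = fwd.i - rev.i; // 0-based inclusive
  int b_start = fwd.j - rev.j;

  // Traceback DP on the small [start, end) window.
  int wn = fwd.i - a_start, wm = fwd.j - b_start;
  std::vector<std::vector<double> > H(wn + 1, std::vector<double>(wm + 1, 0.0));
  std::vector<std::vector<double> > E(wn + 1, std::vector<double>(wm + 1, R_NegInf));
  std::vector<std::vector<double> > F(wn + 1, std::vector<double>(wm + 1, R_NegInf));
  for (int i = 1; i <= wn; ++i) {
    for (int j = 1; j <= wm; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gap_open - gap_extend, E[i][j - 1] - gap_extend);
      F[i][j] = std::max(H[i - 1][j] - gap_open - gap_extend, F[i - 1][j] - gap_extend);
      double diag = H[i - 1][j - 1] +
        subscore(a[a_start + i - 1], b[b_start + j - 1], match, mismatch);
      H[i][j] = std::max(0.0, std::max(diag, std::max(E[i][j], F[i][j])));
    }
  }
  std::string al_a, al_b;
  int i = wn, j = wm;
  char state = 'H';
  while (i > 0 || j > 0) {
    if (state == 'H') {
      if (H[i][j] == 0.0) break;
      double diag = (i > 0 && j > 0)
        ? H[i - 1][j - 1] + subscore(a[a_start + i - 1], b[b_start + j - 1], match, mismatch)
        : R_NegInf;
      if (i > 0 && j > 0 && H[i][j] == diag) {
        al_a.push_back(a[a_start + i - 1]);
        al_b.push_back(b[b_start + j - 1]);
        --i; --j;
      } else if (i > 0 && H[i][j] == F[i][j]) {
        state = 'F';
      } else {
        state = 'E';
      }
    } else if (state == 'F') { // gap in b, consume a
      al_a.push_back(a[a_start + i - 1]);
      al_b.push_back('-');
      bool opened = (F[i][j] == H[i - 1][j] - gap_open - gap_extend);
      --i;
      if (opened) state = 'H';
    } else { // 'E': gap in a, consume b
      al_a.push_back('-');
      al_b.push_back(b[b_start + j - 1]);
      bool opened = (E[i][j] == H[i][j - 1] - gap_open - gap_extend);
      --j;
      if (opened) state = 'H';
    }
  }
  std::reverse(al_a.begin(), al_a.end());
  std::reverse(al_b.begin(), al_b.end());
  int matches = 0;
  for (size_t k = 0; k < al_a.size(); ++k) {
    if (al_a[k] == al_b[k] && al_a[k] != '-' && al_a[k] != 'N') ++matches;
  }
  return List::create(_["score"] = fwd.score,
                      _["a_start"] = a_start, _["a_end"] = fwd.i,
                      _["b_start"] = b_start, _["b_end"] = fwd.j,
                      _["aligned_a"] = al_a, _["aligned_b"] = al_b,
                      _["matches"] = matches,
                      _["columns"] = (int)al_a.size());
}
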