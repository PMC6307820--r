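#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties (Gotoh, three-state DP).
// A gap of length L costs gap_open + L * gap_extend (both negative).
// Tie-breaking is deterministic: during traceback, at equal scores the
// B-insertion state (gap in A) is preferred, then the A-insertion state, then
// the match state, which places gaps as far right along parent A as possible.
//
// Returned `states` encode alignment columns left to right:
//   0 = both parents present (match or mismatch)
//   1 = gap in A, base only in B (B insertion)
//   2 = gap in B, base only in A (A insertion)

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List gotoh_align_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  const int n = a.size();
  const int m = b.size();

  // Traceback matrices store, per state, the predecessor state (0=M,1=Y,2=X).
  // Y consumes B only (gap in A); X consumes A only (gap in B).
  std::vector<uint8_t> tbM((size_t)(n + 1) * (m + 1));
  std::vector<uint8_t> tbX((size_t)(n + 1) * (m + 1));
  std::vector<uint8_t> tbY((size_t)(n + 1) * (m + 1));
  const size_t W = (size_t)m + 1;

  std::vector<double> prevM(m + 1), prevX(m + 1), prevY(m + 1);
  std::vector<double> curM(m + 1), curX(m + 1), curY(m + 1);

  prevM[0] = 0.0; prevX[0] = NEG_INF; prevY[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    prevM[j] = NEG_INF;
    prevX[j] = NEG_INF;
    prevY[j] = gap_open + j * gap_extend;
    tbY[(size_t)0 * W + j] = (j == 1) ? 0 : 1;  // open from M, then extend
  }

  for (int i = 1; i <= n; ++i) {
    curM[0] = NEG_INF;
    curY[0] = NEG_INF;
    curX[0] = gap_open + i * gap_extend;
    tbX[(size_t)i * W + 0] = (i == 1) ? 0 : 2;
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: diagonal from any state; prefer Y, then X, then M on ties.
      {
        double best = prevY[j - 1]; uint8_t st = 1;
        if (prevX[j - 1] > best) { best = prevX[j - 1]; st = 2; }
        if (prevM[j - 1] > best) { best = prevM[j - 1]; st = 0; }
        curM[j] = best + s;
        tbM[(size_t)i * W + j] = st;
      }
      // X: consume A base i (gap in B); extend preferred on ties.
      {
        double best = prevX[j] + gap_extend; uint8_t st = 2;
        double cand = prevY[j] + gap_open + gap_extend;
        if (cand > best) { best = cand; st = 1; }
        cand = prevM[j] + gap_open + gap_extend;
        if (cand > best) { best = cand; st = 0; }
        curX[j] = best;
        tbX[(size_t)i * W + j] = st;
      }
      // Y: consume B base j (gap in A); extend preferred on ties.
      {
        double best = curY[j - 1] + gap_extend; uint8_t st = 1;
        double cand = curX[j - 1] + gap_open + gap_extend;
        if (cand > best) { best = cand; st = 2; }
        cand = curM[j - 1] + gap_open + gap_extend;
        if (cand > best) { best = cand; st = 0; }
        curY[j] = best;
        tbY[(size_t)i * W + j] = st;
      }
    }
    std::swap(prevM, curM);
    std::swap(prevX, curX);
    std::swap(prevY, curY);
  }

  // Final state: prefer Y, then X, then M on ties.
  double score = prevY[m]; uint8_t state = 1;
  if (prevX[m] > score) { score = prevX[m]; state = 2; }
  if (prevM[m] > score) { score = prevM[m]; state = 0; }

  std::vector<int> states;
  states.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      states.push_back(0);
      state = tbM[(size_t)i * W + j];
      --i; --j;
    } else if (state == 1) {              // gap in A, B-only base
      states.push_back(1);
      state = tbY[(size_t)i * W + j];
      --j;
    } else {                              // gap in B, A-only base
      states.push_back(2);
      state = tbX[(size_t)i * W + j];
      --i;
    }
  }
  std::reverse(states.begin(), states.end());

  return List::create(_["score"] = score,
                      _["states"] = IntegerVector(states.begin(), states.end()));
}
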