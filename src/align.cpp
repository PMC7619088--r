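#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh, three-state DP).
//
// Gap scoring follows the open-scores-first-position convention: an internal
// gap of length k costs gap_open + (k-1) * gap_extend.  Terminal gaps (runs
// touching either end of either sequence) cost term_gap per position, i.e.
// they are scored at the extension-only rate.  Because a vertical gap run
// keeps j constant and a horizontal run keeps i constant, a run is terminal
// exactly when j is 0 or m (vertical) / i is 0 or n (horizontal), so the
// rate can be chosen cell-wise.
//
// Tie-break: highest-scoring path; on ties, diagonal over up over left
// (within a direction, predecessor state preference M > X > Y).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes: 0 = M (diagonal), 1 = X (up, gap in y), 2 = Y (left, gap in x)

// [[Rcpp::export]]
List gotoh_align_cpp(std::string x, std::string y,
                     double match, double mismatch,
                     double gap_open, double gap_extend, double term_gap) {
  int n = x.size(), m = y.size();
  int w = m + 1;
  std::vector<double> M((n + 1) * w, NEG_INF), X((n + 1) * w, NEG_INF),
      Y((n + 1) * w, NEG_INF);
  std::vector<signed char> pM((n + 1) * w, -1), pX((n + 1) * w, -1),
      pY((n + 1) * w, -1);
  M[0] = 0.0;

  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= m; ++j) {
      int id = i * w + j;
      if (i > 0) {  // X: x_i aligned to a gap (vertical move)
        bool terminal = (j == 0 || j == m);
        double open = terminal ? term_gap : gap_open;
        double ext = terminal ? term_gap : gap_extend;
        int up = (i - 1) * w + j;
        double cand[3] = {M[up] + open, X[up] + ext, Y[up] + open};
        int best = 0;
        for (int s = 1; s < 3; ++s)
          if (cand[s] > cand[best]) best = s;
        if (cand[best] > NEG_INF) {
          X[id] = cand[best];
          pX[id] = (signed char)best;
        }
      }
      if (j > 0) {  // Y: y_j aligned to a gap (horizontal move)
        bool terminal = (i == 0 || i == n);
        double open = terminal ? term_gap : gap_open;
        double ext = terminal ? term_gap : gap_extend;
        int left = i * w + (j - 1);
        double cand[3] = {M[left] + open, X[left] + open, Y[left] + ext};
        int best = 0;
        for (int s = 1; s < 3; ++s)
          if (cand[s] > cand[best]) best = s;
        if (cand[best] > NEG_INF) {
          Y[id] = cand[best];
          pY[id] = (signed char)best;
        }
      }
      if (i > 0 && j > 0) {  // M: x_i aligned to y_j
        double s = (x[i - 1] == y[j - 1]) ? match : mismatch;
        int dg = (i - 1) * w + (j - 1);
        double cand[3] = {M[dg], X[dg], Y[dg]};
        int best = 0;
        for (int k = 1; k < 3; ++k)
          if (cand[k] > cand[best]) best = k;
        if (cand[best] > NEG_INF) {
          M[id] = cand[best] + s;
          pM[id] = (signed char)best;
        }
      }
    }
  }

  int end = n * w + m;
  double fin[3] = {M[end], X[end], Y[end]};
  int state = 0;
  for (int s = 1; s < 3; ++s)
    if (fin[s] > fin[state]) state = s;
  double score = fin[state];

  std::string ax, ay;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int id = i * w + j;
    if (i == 0) state = 2;
    if (j == 0) state = 1;
    if (state == 0) {
      ax.push_back(x[i - 1]);
      ay.push_back(y[j - 1]);
      state = pM[id];
      --i;
      --j;
    } else if (state == 1) {
      ax.push_back(x[i - 1]);
      ay.push_back('-');
      state = pX[id];
      --i;
    } else {
      ax.push_back('-');
      ay.push_back(y[j - 1]);
      state = pY[id];
      --j;
    }
  }
  std::reverse(ax.begin(), ax.end());
  std::reverse(ay.begin(), ay.end());

  return List::create(_["score"] = score, _["aligned_x"] = ax,
                      _["aligned_y"] = ay);
}
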