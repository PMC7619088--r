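#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Weighted penalised changepoint detection for a piecewise-constant Gaussian
// mean model, solved exactly by optimal partitioning with functional
// candidate tracking: the cost of ending the current segment at observation
// i with mean mu is kept, per candidate changepoint tau, as a quadratic
// a*mu^2 + b*mu + c that is updated in O(1) per observation
// (adding w_i*(y_i - mu)^2).  Candidates whose unconstrained minimum exceeds
// F*_i + penalty can never be optimal again and are pruned.
//
// Objective: sum_j sum_{i in seg j} w_i (y_i - mu_j)^2 + penalty * (K - 1).
//
// Tie-break: among candidates of equal cost the largest tau (most recent
// changepoint) wins, so a zero penalty yields n singleton segments.

// [[Rcpp::export]]
List fpop_cpp(NumericVector y, NumericVector w, double penalty) {
  int n = y.size();
  std::vector<double> A, B, C;
  std::vector<int> Tau;
  A.reserve(64); B.reserve(64); C.reserve(64); Tau.reserve(64);
  std::vector<int> last(n + 1, 0);
  std::vector<double> Fstar(n + 1);
  Fstar[0] = -penalty;
  A.push_back(0.0);
  B.push_back(0.0);
  C.push_back(0.0);  // F_0 + penalty
  Tau.push_back(0);

  for (int i = 1; i <= n; ++i) {
    double yi = y[i - 1], wi = w[i - 1];
    double best = R_PosInf;
    int bestTau = -1;
    size_t k2 = 0;
    for (size_t k = 0; k < A.size(); ++k) {
      A[k] += wi;
      B[k] -= 2.0 * wi * yi;
      C[k] += wi * yi * yi;
      double mn = C[k] - (B[k] * B[k]) / (4.0 * A[k]);
      if (mn < best || (mn <= best && Tau[k] > bestTau)) {
        best = mn;
        bestTau = Tau[k];
      }
    }
    Fstar[i] = best;
    last[i] = bestTau;
    // prune candidates that can never beat restarting after i
    for (size_t k = 0; k < A.size(); ++k) {
      double mn = C[k] - (B[k] * B[k]) / (4.0 * A[k]);
      if (mn <= Fstar[i] + penalty) {
        A[k2] = A[k];
        B[k2] = B[k];
        C[k2] = C[k];
        Tau[k2] = Tau[k];
        ++k2;
      }
    }
    A.resize(k2); B.resize(k2); C.resize(k2); Tau.resize(k2);
    A.push_back(0.0);
    B.push_back(0.0);
    C.push_back(Fstar[i] + penalty);
    Tau.push_back(i);
  }

  std::vector<int> ends;
  for (int t = n; t > 0; t = last[t]) ends.push_back(t);
  std::reverse(ends.begin(), ends.end());

  return List::create(_["changepoints"] = IntegerVector(ends.begin(), ends.end()),
                      _["total_cost"] = Fstar[n]);
}
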