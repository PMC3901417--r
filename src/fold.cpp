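#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Base-pair stacking-free energy model: GC = -3, AU = -2, GU = -1 kcal/mol.
// Returns +1 (sentinel, "not pairable") for every other combination.
static inline double pairEnergy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0;
}

// Minimum-energy nested secondary structure (Nussinov-style recursion over
// pair energies, hairpin loop >= minLoop unpaired bases). Traceback is
// deterministic: whenever pairing the 3' base attains the optimum, the
// 5'-most admissible partner is chosen; otherwise the base is left unpaired.
// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(std::string seq, int minLoop = 3) {
  const int n = (int) seq.size();
  const double EPS = 1e-9;
  if (n == 0) stop("empty sequence");

  std::vector< std::vector<double> > E(n, std::vector<double>(n, 0.0));
  for (int len = minLoop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      double best = E[i][j - 1];  // j unpaired
      for (int k = i; k <= j - minLoop - 1; ++k) {
        double e = pairEnergy(seq[k], seq[j]);
        if (e > 0) continue;
        double cand = e + (k > i ? E[i][k - 1] : 0.0) + E[k + 1][j - 1];
        if (cand < best - EPS) best = cand;
      }
      E[i][j] = best;
    }
  }

  std::vector<int> partner(n, 0);  // 1-based partner, 0 = unpaired
  std::vector< std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (j - i < minLoop + 1) continue;
    int chosen = -1;
    for (int k = i; k <= j - minLoop - 1; ++k) {
      double e = pairEnergy(seq[k], seq[j]);
      if (e > 0) continue;
      double cand = e + (k > i ? E[i][k - 1] : 0.0) + E[k + 1][j - 1];
      if (std::fabs(cand - E[i][j]) < EPS) { chosen = k; break; }
    }
    if (chosen >= 0) {
      partner[chosen] = j + 1;
      partner[j] = chosen + 1;
      if (chosen > i) stack.push_back(std::make_pair(i, chosen - 1));
      stack.push_back(std::make_pair(chosen + 1, j - 1));
    } else {
      stack.push_back(std::make_pair(i, j - 1));
    }
  }

  std::string db(n, '.');
  std::vector<int> pi, pj;
  double esum = 0.0;
  for (int i = 0; i < n; ++i) {
    int p = partner[i];
    if (p > i + 1) {
      db[i] = '(';
      db[p - 1] = ')';
      pi.push_back(i + 1);
      pj.push_back(p);
      esum += pairEnergy(seq[i], seq[p - 1]);
    }
  }

  return List::create(
    _["structure"] = db,
    _["mfe"] = E[0][n - 1],
    _["pair_i"] = wrap(pi),
    _["pair_j"] = wrap(pj),
    _["energy_check"] = esum);
}
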