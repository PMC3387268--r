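#include <Rcpp.h>
using namespace Rcpp;

// Base codes: A=0, C=1, G=2, T/U=3, anything else >=4 (never pairs, always
// mismatches, scores as background).

static inline double pair_energy(int a, int b) {
  // simple per-pair stabilities (arbitrary kcal/mol-like units)
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3.0; // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2.0; // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1.0; // G:U wobble
  return 0.0;
}

// Maximum-stability secondary structure by a Nussinov-style dynamic program
// with a stacking bonus: a pair (i,j) lying directly on pair (i+1,j-1) gains
// `stack_bonus` on top of its intrinsic pair energy. Returns the dot-bracket
// string and a pseudo minimum free energy (negative total stability).
// [[Rcpp::export(name = ".fold_stack_cpp")]]
List fold_stack_cpp(IntegerVector seq, int min_loop = 3,
                    double stack_bonus = 1.0) {
  int n = seq.size();
  std::string db(n, '.');
  if (n == 0) return List::create(_["structure"] = db, _["energy"] = 0.0);

  // V[i][j]: best score with (i,j) paired; W[i][j]: best score on [i..j]
  std::vector<std::vector<double> > V(n, std::vector<double>(n, R_NegInf));
  std::vector<std::vector<double> > W(n, std::vector<double>(n, 0.0));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double pe = pair_energy(seq[i], seq[j]);
      if (pe > 0.0) {
        double best = 0.0; // hairpin loop closure
        if (j - i - 1 > min_loop) {
          double inner = W[i + 1][j - 1];
          if (inner > best) best = inner;
          if (V[i + 1][j - 1] > R_NegInf) {
            double stacked = V[i + 1][j - 1] + stack_bonus;
            if (stacked > best) best = stacked;
          }
        }
        V[i][j] = pe + best;
      }
      double w = W[i + 1][j];
      if (W[i][j - 1] > w) w = W[i][j - 1];
      if (V[i][j] > w) w = V[i][j];
      for (int k = i; k < j; ++k) {
        double split = W[i][k] + W[k + 1][j];
        if (split > w) w = split;
      }
      W[i][j] = w;
    }
  }

  // Iterative traceback; preference order fixed for determinism.
  std::vector<std::pair<std::pair<int, int>, bool> > stack; // ((i,j), inV)
  stack.push_back(std::make_pair(std::make_pair(0, n - 1), false));
  const double eps = 1e-9;
  while (!stack.empty()) {
    int i = stack.back().first.first;
    int j = stack.back().first.second;
    bool inV = stack.back().second;
    stack.pop_back();
    if (i >= j) continue;
    if (inV) {
      db[i] = '(';
      db[j] = ')';
      double pe = pair_energy(seq[i], seq[j]);
      double rest = V[i][j] - pe;
      if (rest <= eps) continue; // hairpin closure
      if (j - i - 1 > min_loop) {
        if (V[i + 1][j - 1] > R_NegInf &&
            std::fabs(V[i + 1][j - 1] + stack_bonus - rest) < eps) {
          stack.push_back(std::make_pair(std::make_pair(i + 1, j - 1), true));
          continue;
        }
        stack.push_back(std::make_pair(std::make_pair(i + 1, j - 1), false));
      }
      continue;
    }
    double w = W[i][j];
    if (w <= eps) continue;
    if (V[i][j] > R_NegInf && std::fabs(V[i][j] - w) < eps) {
      stack.push_back(std::make_pair(std::make_pair(i, j), true));
      continue;
    }
    if (std::fabs(W[i + 1][j] - w) < eps) {
      stack.push_back(std::make_pair(std::make_pair(i + 1, j), false));
      continue;
    }
    if (std::fabs(W[i][j - 1] - w) < eps) {
      stack.push_back(std::make_pair(std::make_pair(i, j - 1), false));
      continue;
    }
    bool done = false;
    for (int k = i; k < j && !done; ++k) {
      if (std::fabs(W[i][k] + W[k + 1][j] - w) < eps) {
        stack.push_back(std::make_pair(std::make_pair(i, k), false));
        stack.push_back(std::make_pair(std::make_pair(k + 1, j), false));
        done = true;
      }
    }
  }

  return List::create(_["structure"] = db,
                      _["energy"] = -W[0][n - 1]);
}

// Hamming distance of `pattern` against every window of `subject`.
// Codes >= 4 always count as mismatches.
// [[Rcpp::export(name = ".hamming_scan_cpp")]]
IntegerVector hamming_scan_cpp(IntegerVector subject, IntegerVector pattern) {
  int n = subject.size(), m = pattern.size();
  if (m == 0 || n < m) return IntegerVector(0);
  IntegerVector out(n - m + 1);
  for (int o = 0; o <= n - m; ++o) {
    int d = 0;
    for (int k = 0; k < m; ++k) {
      int s = subject[o + k], p = pattern[k];
      if (s != p || s >= 4) ++d;
    }
    out[o] = d;
  }
  return out;
}

// Log-odds PWM score at every window offset; rows of `lods` are A,C,G,T.
// Codes >= 4 (N) contribute 0 (background-equivalent).
// [[Rcpp::export(name = ".pwm_score_cpp")]]
NumericVector pwm_score_cpp(IntegerVector subject, NumericMatrix lods) {
  int n = subject.size(), L = lods.ncol();
  if (L == 0 || n < L) return NumericVector(0);
  NumericVector out(n - L + 1);
  for (int o = 0; o <= n - L; ++o) {
    double s = 0.0;
    for (int k = 0; k < L; ++k) {
      int b = subject[o + k];
      if (b < 4) s += lods(b, k);
    }
    out[o] = s;
  }
  return out;
}
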