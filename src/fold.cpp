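#include <Rcpp.h>
using namespace Rcpp;

static inline int bcode(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

// Simplified stem-loop folding estimator.  Enumerates all stem candidates:
// seq[i..i+l-1] paired with the reverse complement of seq[j..j+l-1]
// (j >= i+l+min_loop, l >= 2), scores each as the sum of nearest-neighbor
// stack terms over the i-side strand minus a loop penalty, and returns
// max(0, best score) per sequence.
// [[Rcpp::export]]
NumericVector fold_energy_cpp(CharacterVector seqs, NumericVector stack,
                              double loop_penalty, int min_loop) {
  const int ns = seqs.size();
  NumericVector out(ns);
  for (int s = 0; s < ns; ++s) {
    const std::string q = as<std::string>(seqs[s]);
    const int n = (int) q.size();
    std::vector<int> c(n);
    for (int i = 0; i < n; ++i) c[i] = bcode(q[i]);
    double best = 0.0;
    for (int i = 0; i + 1 < n; ++i) {
      for (int l = 2; i + l <= n; ++l) {
        for (int j = i + l + min_loop; j + l <= n; ++j) {
          bool ok = true;
          for (int t = 0; t < l && ok; ++t) {
            const int a = c[i + t], b = c[j + l - 1 - t];
            if (a < 0 || b < 0 || a + b != 3) ok = false;
          }
          if (!ok) continue;
          double sc = -loop_penalty;
          for (int t = 0; t + 1 < l; ++t) {
            sc += stack[c[i + t] * 4 + c[i + t + 1]];
          }
          if (sc > best) best = sc;
        }
      }
    }
    out[s] = best;
  }
  return out;
}
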