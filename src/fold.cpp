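#include <Rcpp.h>
using namespace Rcpp;

// pair kind codes: 0 = GC, 1 = AU, 2 = GU, -1 = not pairable
// base codes (1-based from R): A=1, C=2, G=3, U=4
static inline int pair_kind(int a, int b) {
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 0;
  if ((a == 1 && b == 4) || (a == 4 && b == 1)) return 1;
  if ((a == 3 && b == 4) || (a == 4 && b == 3)) return 2;
  return -1;
}

// Nested-structure fold MFE under the reduced model: energy is the sum of
// stack terms over stacked adjacent pairs; isolated pairs contribute 0; the
// empty structure (0) is always admissible. Minimum hairpin loop of
// `min_hairpin` unpaired nt.
//
// W(i,j): best energy on [i..j]. V(i,j): best energy given (i,j) paired.
// V(i,j) = min( W(i+1,j-1), V(i+1,j-1) + stack(kind(i,j), kind(i+1,j-1)) )
// W(i,j) = min( W(i+1,j), min_k { V(i,k) + W(k+1,j) : k >= i+min_hairpin+1 } )
// [[Rcpp::export]]
double fold_mfe_cpp(IntegerVector codes, NumericMatrix stack, int min_hairpin) {
  const int n = codes.size();
  if (n == 0) stop("empty sequence");
  if (n <= min_hairpin + 1) return 0.0;

  std::vector<double> W(n * n, 0.0), V(n * n, R_PosInf);
  auto idx = [n](int i, int j) { return i * n + j; };

  for (int span = min_hairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int k0 = pair_kind(codes[i], codes[j]);
      if (k0 >= 0) {
        double v = W[idx(i + 1, j - 1)];
        if (j - 1 - (i + 1) > min_hairpin) {
          int k1 = pair_kind(codes[i + 1], codes[j - 1]);
          if (k1 >= 0 && R_finite(V[idx(i + 1, j - 1)])) {
            double cand = V[idx(i + 1, j - 1)] + stack(k0, k1);
            if (cand < v) v = cand;
          }
        }
        V[idx(i, j)] = v;
      }
      double w = W[idx(i + 1, j)];
      for (int k = i + min_hairpin + 1; k <= j; ++k) {
        if (R_finite(V[idx(i, k)])) {
          double rest = (k + 1 <= j) ? W[idx(k + 1, j)] : 0.0;
          double cand = V[idx(i, k)] + rest;
          if (cand < w) w = cand;
        }
      }
      W[idx(i, j)] = w;
    }
  }
  double out = W[idx(0, n - 1)];
  return out < 0.0 ? out : 0.0;
}
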