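#include <Rcpp.h>
using namespace Rcpp;

// Score every length-w window of an integer-coded sequence (1..4 = ACGT,
// 0 = ambiguous) against a 4 x w log-odds matrix. Windows containing an
// ambiguous base get NA.
// [[Rcpp::export]]
NumericVector score_windows_cpp(IntegerVector seq, NumericMatrix lod) {
  int L = seq.size();
  int w = lod.ncol();
  if (L < w) return NumericVector(0);
  int n = L - w + 1;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      int b = seq[i + j];
      if (b == 0) { ok = false; break; }
      s += lod(b - 1, j);
    }
    out[i] = ok ? s : NA_REAL;
  }
  return out;
}

// Exact DP convolution of the PWM score distribution under an i.i.d.
// background, on an integer score grid. iscore: 4 x w integer-discretized
// scores; bg: background probabilities (length 4). Returns the
// probability vector over total scores offset by the sum of per-column
// minima (index 0 = minimal total score).
// [[Rcpp::export]]
NumericVector score_distribution_cpp(IntegerMatrix iscore, NumericVector bg) {
  int w = iscore.ncol();
  long long range = 0;
  std::vector<int> mins(w), maxs(w);
  for (int j = 0; j < w; ++j) {
    int mn = iscore(0, j), mx = iscore(0, j);
    for (int a = 1; a < 4; ++a) {
      mn = std::min(mn, iscore(a, j));
      mx = std::max(mx, iscore(a, j));
    }
    mins[j] = mn; maxs[j] = mx;
    range += (long long)(mx - mn);
  }
  std::vector<double> dist(1, 1.0);
  dist.reserve(range + 1);
  long long cur_len = 1;
  for (int j = 0; j < w; ++j) {
    long long new_len = cur_len + (maxs[j] - mins[j]);
    std::vector<double> nd(new_len, 0.0);
    for (long long k = 0; k < cur_len; ++k) {
      double p = dist[k];
      if (p == 0.0) continue;
      for (int a = 0; a < 4; ++a) {
        nd[k + (iscore(a, j) - mins[j])] += p * bg[a];
      }
    }
    dist.swap(nd);
    cur_len = new_len;
  }
  return NumericVector(dist.begin(), dist.end());
}
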