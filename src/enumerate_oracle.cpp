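#include <Rcpp.h>

// Exhaustive containment-probability oracle: iterates over every one of the
// 4^L length-L sequences (odometer order), checks naively whether the query
// occurs as a substring, and accumulates the product of per-base
// probabilities for the sequences that contain it.  Deliberately shares no
// logic with the recurrence it validates.

// [[Rcpp::export(rng = false)]]
double enumerate_containment(Rcpp::IntegerVector code,
                             Rcpp::NumericVector probs, int L) {
  const int m = code.size();
  if (L < m) return 0.0;
  std::vector<int> pat(m);
  for (int i = 0; i < m; ++i) pat[i] = code[i] - 1;  // 0-based base codes
  std::vector<int> seq(L, 0);
  double total = 0.0, comp = 0.0;  // Kahan-compensated sum of ~4^L terms
  const double p0 = probs[0], p1 = probs[1], p2 = probs[2], p3 = probs[3];
  const double pr[4] = {p0, p1, p2, p3};
  for (;;) {
    // containment check
    bool found = false;
    for (int start = 0; start + m <= L && !found; ++start) {
      int j = 0;
      while (j < m && seq[start + j] == pat[j]) ++j;
      found = (j == m);
    }
    if (found) {
      double w = 1.0;
      for (int i = 0; i < L; ++i) w *= pr[seq[i]];
      double y = w - comp;
      double t = total + y;
      comp = (t - total) - y;
      total = t;
    }
    // odometer increment
    int pos = L - 1;
    while (pos >= 0 && seq[pos] == 3) seq[pos--] = 0;
    if (pos < 0) break;
    ++seq[pos];
  }
  return total;
}
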