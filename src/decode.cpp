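#include <Rcpp.h>
using namespace Rcpp;

// Constrained Viterbi decoding of the two-motif-set promoter model.
//
// The path of the model is fully determined by the component choice and
// start of each motif set (or its skip path), so the most likely path is
// found by maximizing over legal placements:
//   rel_lp = ltau1[c1] + ltau2[c2] + G1(c1,s1) + G2(c2,s2) + placement prior
// where G(c,s) is the log-odds (motif emission vs background) of the
// window starting at s, and the placement prior is uniform over the legal
// configurations of the skip pattern. Constraints: the first present motif
// starts at or after `offset`; when both motifs are present,
// s2 >= s1 + motif_len + min_gap.
//
// Tie-breaking is by evaluation order with strict improvement: the skip
// path first, then set-1-only placements (start ascending, component
// ascending), then set-2-only, then pairs (s1 ascending, component 1,
// component 2 ascending, earliest maximizing s2). X codes: 0..3 = A,C,G,T,
// 4 = N (contributes zero log-odds and background log-probability).

// [[Rcpp::export]]
List decode_promoters_cpp(IntegerMatrix X, List D1, List D2,
                          NumericVector ltau1, NumericVector ltau2,
                          int offset, int min_gap, int motif_len,
                          double lp_single, double lp_pair) {
  const int n = X.nrow(), L = X.ncol(), m = motif_len;
  const int K1 = D1.size(), K2 = D2.size();
  const int smax = L - m;               // last legal 0-based start
  const int S = smax - offset + 1;      // single-motif start count
  if (S <= 0) stop("sequence shorter than the minimum motif footprint");

  IntegerVector c1(n), s1(n), c2(n), s2(n);
  NumericVector rel_lp(n), llr(n);

  std::vector<NumericMatrix> d1, d2;
  for (int k = 0; k < K1; ++k) d1.push_back(as<NumericMatrix>(D1[k]));
  for (int k = 0; k < K2; ++k) d2.push_back(as<NumericMatrix>(D2[k]));

  // gain matrices and suffix max/argmax for set 2, reused per sequence
  std::vector<std::vector<double> > G1(K1), G2(K2), M2(K2);
  std::vector<std::vector<int> > A2(K2);
  for (int k = 0; k < K1; ++k) G1[k].resize(S);
  for (int k = 0; k < K2; ++k) {
    G2[k].resize(S); M2[k].resize(S); A2[k].resize(S);
  }

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K1; ++k)
      for (int s = offset; s <= smax; ++s) {
        double g = 0.0;
        for (int j = 0; j < m; ++j) {
          int c = X(i, s + j);
          if (c < 4) g += d1[k](j, c);
        }
        G1[k][s - offset] = g;
      }
    for (int k = 0; k < K2; ++k) {
      for (int s = offset; s <= smax; ++s) {
        double g = 0.0;
        for (int j = 0; j < m; ++j) {
          int c = X(i, s + j);
          if (c < 4) g += d2[k](j, c);
        }
        G2[k][s - offset] = g;
      }
      // suffix maxima, keeping the earliest maximizer on ties
      M2[k][S - 1] = G2[k][S - 1];
      A2[k][S - 1] = S - 1;
      for (int s = S - 2; s >= 0; --s) {
        if (G2[k][s] >= M2[k][s + 1]) {  // >= : earlier start wins ties
          M2[k][s] = G2[k][s]; A2[k][s] = s;
        } else {
          M2[k][s] = M2[k][s + 1]; A2[k][s] = A2[k][s + 1];
        }
      }
    }

    // skip/skip incumbent
    double best = ltau1[0] + ltau2[0];
    int bc1 = -1, bs1 = -1, bc2 = -1, bs2 = -1;
    // set-1-only
    for (int s = 0; s < S; ++s)
      for (int k = 0; k < K1; ++k) {
        double v = ltau1[k + 1] + ltau2[0] + G1[k][s] + lp_single;
        if (v > best) { best = v; bc1 = k; bs1 = s + offset;
                        bc2 = -1; bs2 = -1; }
      }
    // set-2-only
    for (int s = 0; s < S; ++s)
      for (int k = 0; k < K2; ++k) {
        double v = ltau1[0] + ltau2[k + 1] + G2[k][s] + lp_single;
        if (v > best) { best = v; bc1 = -1; bs1 = -1;
                        bc2 = k; bs2 = s + offset; }
      }
    // both motifs
    for (int ss1 = 0; ss1 < S; ++ss1) {
      int smin2 = ss1 + offset + m + min_gap;   // absolute 0-based
      if (smin2 > smax) break;
      int idx2 = smin2 - offset;
      for (int k1 = 0; k1 < K1; ++k1)
        for (int k2 = 0; k2 < K2; ++k2) {
          double v = ltau1[k1 + 1] + ltau2[k2 + 1] +
            G1[k1][ss1] + M2[k2][idx2] + lp_pair;
          if (v > best) { best = v; bc1 = k1; bs1 = ss1 + offset;
                          bc2 = k2; bs2 = A2[k2][idx2] + offset; }
        }
    }

    c1[i] = bc1; s1[i] = bs1; c2[i] = bc2; s2[i] = bs2;
    rel_lp[i] = best;
    llr[i] = best - (ltau1[0] + ltau2[0]);
  }

  return List::create(_["c1"] = c1, _["s1"] = s1, _["c2"] = c2,
                      _["s2"] = s2, _["rel_lp"] = rel_lp, _["llr"] = llr);
}
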