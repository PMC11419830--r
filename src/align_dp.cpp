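#include <Rcpp.h>
using namespace Rcpp;

// Sparse dynamic programme over monotone label pairings, in the style of
// classical restriction-map / optical-map alignment. A state (i, j) means
// "reference label i is paired with molecule label j"; transitions skip up
// to max_skip labels on either side. Score of a pairing chain:
//   sum over pairs of match_score
//   - miss_ref  * (reference labels skipped between consecutive pairs)
//   - miss_qry  * (molecule labels skipped between consecutive pairs)
//   - size_cost * (ref_gap - qry_gap)^2 per consecutive pair interval,
// except that an interval straddling [free_lo, free_hi] on the reference
// (the declared repeat locus) pays no size cost, so arbitrarily expanded
// molecules still align. Ends are free on both sequences. Ties are broken
// toward more matched pairs, then toward the leftmost reference placement.

// [[Rcpp::export(name = ".dp_align")]]
List dp_align(NumericVector ref, NumericVector qry,
              double match_score, double miss_ref, double miss_qry,
              double size_cost, double free_lo, double free_hi,
              bool has_free, int max_skip) {
  const int R = ref.size(), Q = qry.size();
  if (R == 0 || Q == 0)
    return List::create(_["score"] = R_NegInf,
                        _["ref_idx"] = IntegerVector(0),
                        _["qry_idx"] = IntegerVector(0));
  NumericMatrix H(R, Q);
  IntegerMatrix NP(R, Q), Pi(R, Q), Pj(R, Q);
  for (int i = 0; i < R; ++i) {
    for (int j = 0; j < Q; ++j) {
      double best = match_score;   // start a fresh chain at (i, j)
      int bnp = 1, bpi = -1, bpj = -1;
      const int i0 = std::max(0, i - max_skip - 1);
      const int j0 = std::max(0, j - max_skip - 1);
      for (int ip = i0; ip < i; ++ip) {
        for (int jp = j0; jp < j; ++jp) {
          double dr = ref[i] - ref[ip];
          double dq = qry[j] - qry[jp];
          double cost;
          if (has_free && ref[ip] <= free_lo && ref[i] >= free_hi)
            cost = 0.0;
          else {
            double d = dr - dq;
            cost = size_cost * d * d;
          }
          double cand = H(ip, jp) + match_score
            - miss_ref * (i - ip - 1) - miss_qry * (j - jp - 1) - cost;
          int cnp = NP(ip, jp) + 1;
          if (cand > best + 1e-9 ||
              (cand > best - 1e-9 &&
               (cnp > bnp || (cnp == bnp && (bpi < 0 || ip < bpi))))) {
            best = cand; bnp = cnp; bpi = ip; bpj = jp;
          }
        }
      }
      H(i, j) = best; NP(i, j) = bnp; Pi(i, j) = bpi; Pj(i, j) = bpj;
    }
  }
  // best terminal cell: score, then pair count, then leftmost reference end
  int bi = 0, bj = 0;
  for (int i = 0; i < R; ++i)
    for (int j = 0; j < Q; ++j) {
      double d = H(i, j) - H(bi, bj);
      if (d > 1e-9 ||
          (d > -1e-9 && (NP(i, j) > NP(bi, bj) ||
                         (NP(i, j) == NP(bi, bj) && i < bi))))
        { bi = i; bj = j; }
    }
  std::vector<int> ri, qi;
  for (int i = bi, j = bj; i >= 0; ) {
    ri.push_back(i + 1); qi.push_back(j + 1);
    int ni = Pi(i, j), nj = Pj(i, j);
    i = ni; j = nj;
  }
  std::reverse(ri.begin(), ri.end());
  std::reverse(qi.begin(), qi.end());
  return List::create(_["score"] = H(bi, bj),
                      _["ref_idx"] = wrap(ri),
                      _["qry_idx"] = wrap(qi));
}
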