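#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman-style) alignment of a protein sequence against a
// position-specific scoring model with affine gap penalties.
//
// logodds: 20 x M matrix of per-column log-odds (bits); rows follow the
//   package's fixed amino-acid order.
// seq: residue indices (1..20), 0 for unknown residues (scored 0 bits).
// Returns the best local score (>= 0, the empty alignment scores 0), the
// aligned sequence span (0-based, half-open) and, per profile column, the
// 1-based sequence position aligned to it (0 = column deleted, -1 = column
// outside the aligned span). Insertions relative to the profile consume
// sequence positions but are not reported per column.
// [[Rcpp::export]]
List profile_align_local(NumericMatrix logodds, IntegerVector seq,
                         double gap_open, double gap_extend) {
  const int M = logodds.ncol();
  const int L = seq.size();
  const double NEG = -1e30;

  NumericMatrix Mm(M + 1, L + 1), Ix(M + 1, L + 1), Iy(M + 1, L + 1);
  IntegerMatrix tbM(M + 1, L + 1), tbX(M + 1, L + 1), tbY(M + 1, L + 1);
  for (int i = 0; i <= M; ++i)
    for (int j = 0; j <= L; ++j) {
      Mm(i, j) = NEG; Ix(i, j) = NEG; Iy(i, j) = NEG;
    }

  double best = 0.0;
  int bi = -1, bj = -1;
  for (int i = 1; i <= M; ++i) {
    for (int j = 1; j <= L; ++j) {
      const int a = seq[j - 1];
      const double s = (a > 0) ? logodds(a - 1, i - 1) : 0.0;
      double m0 = 0.0;  // fresh local start
      int t = 0;
      if (Mm(i - 1, j - 1) > m0) { m0 = Mm(i - 1, j - 1); t = 1; }
      if (Ix(i - 1, j - 1) > m0) { m0 = Ix(i - 1, j - 1); t = 2; }
      if (Iy(i - 1, j - 1) > m0) { m0 = Iy(i - 1, j - 1); t = 3; }
      Mm(i, j) = m0 + s; tbM(i, j) = t;

      const double x1 = Mm(i, j - 1) + gap_open;
      const double x2 = Ix(i, j - 1) + gap_extend;
      if (x1 >= x2) { Ix(i, j) = x1; tbX(i, j) = 1; }
      else          { Ix(i, j) = x2; tbX(i, j) = 2; }

      const double y1 = Mm(i - 1, j) + gap_open;
      const double y2 = Iy(i - 1, j) + gap_extend;
      if (y1 >= y2) { Iy(i, j) = y1; tbY(i, j) = 1; }
      else          { Iy(i, j) = y2; tbY(i, j) = 2; }

      if (Mm(i, j) > best) { best = Mm(i, j); bi = i; bj = j; }
    }
  }

  IntegerVector col_pos(M, -1);
  int start0 = 0, end0 = 0;
  if (bi > 0) {
    int i = bi, j = bj, state = 0;  // 0 = M, 1 = Ix, 2 = Iy
    end0 = bj;
    for (;;) {
      if (state == 0) {
        col_pos[i - 1] = j;
        const int t = tbM(i, j);
        --i; --j;
        if (t == 0) break;
        state = (t == 1) ? 0 : (t == 2 ? 1 : 2);
      } else if (state == 1) {
        const int t = tbX(i, j);
        --j;
        state = (t == 1) ? 0 : 1;
      } else {
        col_pos[i - 1] = 0;
        const int t = tbY(i, j);
        --i;
        state = (t == 1) ? 0 : 2;
      }
    }
    start0 = j;
  }

  return List::create(_["score"] = (bi > 0 ? best : 0.0),
                      _["start"] = start0,
                      _["end"] = end0,
                      _["col_pos"] = col_pos);
}
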