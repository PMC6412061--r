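#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Affine-gap Smith-Waterman returning the single best local alignment (one
// HSP) with deterministic tie handling:
//   * the end cell is the first score-maximal substitution cell in row-major
//     order (smallest query end, then smallest subject end);
//   * traceback prefers substitution over a query-consuming gap over a
//     subject-consuming gap, and prefers extending the alignment over
//     restarting when the local zero floor ties, which favours the longest
//     co-optimal alignment into that cell.
// Gap of length L costs gap_open + L * gap_extend (BLAST convention).
//
// State matrices: M ends in a substitution column; GQ ends in a gap column
// consuming the query (gap in subject); GS ends in a gap column consuming the
// subject (gap in query). Only M cells may start (floor at 0) or end the
// alignment, so an optimal HSP never begins or ends with a gap.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export(name = ".sw_align_cpp")]]
SEXP sw_align_cpp(std::string q, std::string s,
                  int match, int mismatch,
                  int gap_open, int gap_extend,
                  int min_score) {
  const int n = (int) q.size();
  const int m = (int) s.size();
  if (n == 0 || m == 0) return R_NilValue;

  std::vector<int> Mprev(m + 1, 0), Mcur(m + 1, 0);
  std::vector<int> Qprev(m + 1, NEG), Qcur(m + 1, NEG);
  std::vector<int> Sprev(m + 1, NEG), Scur(m + 1, NEG);
  // traceback: 2 bits per state per cell
  // tbM: 0 = fresh start, 1 = from M, 2 = from GQ, 3 = from GS (diagonal)
  // tbQ/tbS: 1 = from M, 2 = from GQ, 3 = from GS (vertical/horizontal)
  std::vector<unsigned char> tbM((size_t) n * m), tbQ((size_t) n * m), tbS((size_t) n * m);

  int best = 0, bi = -1, bj = -1;
  const int go = gap_open + gap_extend;   // cost of opening a length-1 gap

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = 0; Qcur[0] = NEG; Scur[0] = NEG;
    const char qa = q[i - 1];
    const size_t row = (size_t) (i - 1) * m;
    for (int j = 1; j <= m; ++j) {
      const char sb = s[j - 1];
      const bool ident = (qa == sb) && qa != 'N';
      const int sub = ident ? match : -mismatch;

      // substitution state: prefer M > GQ > GS, extension over restart at 0;
      // the matrix border is not an alignment cell, so border diagonals start
      int prev = 0; unsigned char pm = 0;
      if (i > 1 && j > 1) {
        prev = Mprev[j - 1]; pm = 1;
        if (Qprev[j - 1] > prev) { prev = Qprev[j - 1]; pm = 2; }
        if (Sprev[j - 1] > prev) { prev = Sprev[j - 1]; pm = 3; }
        if (prev < 0) { prev = 0; pm = 0; }
      }
      Mcur[j] = prev + sub;
      tbM[row + (j - 1)] = pm;

      // gap consuming the query (vertical, uses previous row at same j)
      int vq = Mprev[j] - go; unsigned char pq = 1;
      if (Qprev[j] - gap_extend > vq) { vq = Qprev[j] - gap_extend; pq = 2; }
      if (Sprev[j] - go > vq) { vq = Sprev[j] - go; pq = 3; }
      Qcur[j] = vq < NEG ? NEG : vq;
      tbQ[row + (j - 1)] = pq;

      // gap consuming the subject (horizontal, same row at j-1)
      int vs = Mcur[j - 1] - go; unsigned char ps = 1;
      if (Qcur[j - 1] - go > vs) { vs = Qcur[j - 1] - go; ps = 2; }
      if (Scur[j - 1] - gap_extend > vs) { vs = Scur[j - 1] - gap_extend; ps = 3; }
      Scur[j] = vs < NEG ? NEG : vs;
      tbS[row + (j - 1)] = ps;

      if (Mcur[j] > best) { best = Mcur[j]; bi = i; bj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Qprev, Qcur); std::swap(Sprev, Scur);
  }

  if (bi < 0 || best < min_score) return R_NilValue;

  // traceback using stored 2-bit decisions
  int i = bi, j = bj, state = 1;  // 1 = M, 2 = GQ, 3 = GS
  int nident = 0, nmis = 0, ngap = 0, alnlen = 0;
  int qend = bi, send = bj, qstart = bi, sstart = bj;
  for (;;) {
    const size_t idx = (size_t) (i - 1) * m + (j - 1);
    if (state == 1) {
      const bool ident = (q[i - 1] == s[j - 1]) && q[i - 1] != 'N';
      if (ident) ++nident; else ++nmis;
      ++alnlen; qstart = i; sstart = j;
      const unsigned char p = tbM[idx];
      --i; --j;
      if (p == 0) break;
      state = p;
    } else if (state == 2) {
      ++ngap; ++alnlen; qstart = i;
      state = tbQ[idx];
      --i;
    } else {
      ++ngap; ++alnlen; sstart = j;
      state = tbS[idx];
      --j;
    }
  }

  return List::create(
    _["score"] = best, _["nident"] = nident, _["mismatch"] = nmis,
    _["gaps"] = ngap, _["alnlen"] = alnlen,
    _["qstart"] = qstart, _["qend"] = qend,
    _["sstart"] = sstart, _["send"] = send);
}
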