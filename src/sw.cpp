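#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh three-state
// recursion). A gap of length L costs gap_open + L * gap_extend, both
// penalties negative. 'N' matches nothing: it scores as a mismatch against
// every base (including another N) and never counts as an identity, so
// N-padding cannot extend an alignment.
//
// Traceback directions are packed per cell into one byte:
//   bits 0-1: how H was achieved (0 stop, 1 diagonal, 2 from E, 3 from F)
//   bit  2  : E achieved by opening (1) vs extending (0)
//   bit  3  : F achieved by opening (1) vs extending (0)
// The best cell is the first maximal H in row-major order and the traceback
// prefers diagonal over vertical over horizontal, so results are
// deterministic (lowest alignment end, fixed path among ties).

static inline bool is_base(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0);

  const double NEG = -1e30;
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<double> Fcol(m + 1, NEG);
  std::vector<unsigned char> dir((size_t)(n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    Ecur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      unsigned char d = 0;
      // E: gap in query (consumes b_j), horizontal move
      double e_open = Hcur[j - 1] + gap_open + gap_extend;
      double e_ext  = Ecur[j - 1] + gap_extend;
      double E = (e_open >= e_ext) ? e_open : e_ext;
      if (e_open >= e_ext) d |= 4;
      Ecur[j] = E;
      // F: gap in subject (consumes a_i), vertical move
      double f_open = Hprev[j] + gap_open + gap_extend;
      double f_ext  = Fcol[j] + gap_extend;
      double F = (f_open >= f_ext) ? f_open : f_ext;
      if (f_open >= f_ext) d |= 8;
      Fcol[j] = F;
      // H
      char ca = a[i - 1], cb = b[j - 1];
      double s = (ca == cb && is_base(ca)) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double H = 0.0;
      unsigned char h = 0;
      if (diag > H) { H = diag; h = 1; }
      if (F > H)    { H = F;    h = 3; }
      if (E > H)    { H = E;    h = 2; }
      Hcur[j] = H;
      dir[(size_t)i * (m + 1) + j] = (unsigned char)(d | h);
      if (H > best) { best = H; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0);

  // traceback
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  int qend = bi, send = bj, qstart = bi, sstart = bj;
  int cols = 0, idents = 0;
  while (i > 0 && j > 0) {
    unsigned char d = dir[(size_t)i * (m + 1) + j];
    if (state == 0) {
      unsigned char h = d & 3;
      if (h == 0) break;
      if (h == 1) {
        ++cols;
        if (a[i - 1] == b[j - 1] && is_base(a[i - 1])) ++idents;
        qstart = i; sstart = j;
        --i; --j;
      } else if (h == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // E: column (-, b_j)
      ++cols;
      sstart = j;
      bool opened = (d & 4) != 0;
      --j;
      if (opened) state = 0;
    } else { // F: column (a_i, -)
      ++cols;
      qstart = i;
      bool opened = (d & 8) != 0;
      --i;
      if (opened) state = 0;
    }
  }

  return List::create(
    _["score"] = best,
    _["query_start"] = qstart, _["query_end"] = qend,
    _["subject_start"] = sstart, _["subject_end"] = send,
    _["aligned_length"] = cols, _["identities"] = idents);
}
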