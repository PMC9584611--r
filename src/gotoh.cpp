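#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
#include <algorithm>

using namespace Rcpp;

// Global affine-gap alignment (Gotoh three-state DP) of a read against a
// reference. A gap of length k costs gap_open + k * gap_ext. 'N' in the
// reference is a wildcard and scores as a match against any read base
// (the barcode slot of the amplicon reference is N12); 'N' in the read
// scores as a mismatch against any non-N reference base.
//
// Tie-break policy (deterministic): on equal scores the traceback prefers
// the substitution state over a reference-consuming gap (deletion from the
// read) over a read-consuming gap (insertion), and prefers extending an
// open gap over opening a new one. Indel placement is normalised
// downstream by left-alignment, so co-optimal gap placements collapse to a
// single variant record.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

inline double subst_score(char a, char b, double match, double mismatch) {
  // a = read base, b = reference base
  if (b == 'N') return match;
  if (a == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List gotoh_align_cpp(std::string read, std::string ref,
                     double match, double mismatch,
                     double gap_open, double gap_ext) {
  const int n = read.size();
  const int m = ref.size();
  // state 0 = M (diagonal), 1 = D (gap in read, ref base consumed),
  // state 2 = I (gap in ref, read base consumed)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> D((n + 1) * (m + 1), NEG_INF);
  std::vector<double> I((n + 1) * (m + 1), NEG_INF);
  // predecessor state for each cell/state (255 = none)
  std::vector<unsigned char> pM((n + 1) * (m + 1), 255);
  std::vector<unsigned char> pD((n + 1) * (m + 1), 255);
  std::vector<unsigned char> pI((n + 1) * (m + 1), 255);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) {
    D[at(0, j)] = gap_open + j * gap_ext;
    pD[at(0, j)] = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    I[at(i, 0)] = gap_open + i * gap_ext;
    pI[at(i, 0)] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = subst_score(read[i - 1], ref[j - 1], match, mismatch);
      // M: preference M > D > I on ties
      {
        double best = M[at(i - 1, j - 1)];
        unsigned char st = 0;
        if (D[at(i - 1, j - 1)] > best) { best = D[at(i - 1, j - 1)]; st = 1; }
        if (I[at(i - 1, j - 1)] > best) { best = I[at(i - 1, j - 1)]; st = 2; }
        M[at(i, j)] = (best == NEG_INF) ? NEG_INF : best + s;
        pM[at(i, j)] = st;
      }
      // D: prefer extension (D) over opening from M over opening from I
      {
        double best = D[at(i, j - 1)] + gap_ext;
        unsigned char st = 1;
        double opm = M[at(i, j - 1)] + gap_open + gap_ext;
        double opi = I[at(i, j - 1)] + gap_open + gap_ext;
        if (opm > best) { best = opm; st = 0; }
        if (opi > best) { best = opi; st = 2; }
        D[at(i, j)] = best;
        pD[at(i, j)] = st;
      }
      // I: prefer extension (I) over opening from M over opening from D
      {
        double best = I[at(i - 1, j)] + gap_ext;
        unsigned char st = 2;
        double opm = M[at(i - 1, j)] + gap_open + gap_ext;
        double opd = D[at(i - 1, j)] + gap_open + gap_ext;
        if (opm > best) { best = opm; st = 0; }
        if (opd > best) { best = opd; st = 1; }
        I[at(i, j)] = best;
        pI[at(i, j)] = st;
      }
    }
  }

  int i = n, j = m;
  unsigned char state = 0;
  double score = M[at(n, m)];
  if (D[at(n, m)] > score) { score = D[at(n, m)]; state = 1; }
  if (I[at(n, m)] > score) { score = I[at(n, m)]; state = 2; }

  std::string ar, af;  // aligned read / aligned ref, built reversed
  ar.reserve(n + m);
  af.reserve(n + m);
  while (i > 0 || j > 0) {
    if (state == 0) {
      ar.push_back(read[i - 1]);
      af.push_back(ref[j - 1]);
      state = pM[at(i, j)];
      --i; --j;
    } else if (state == 1) {
      ar.push_back('-');
      af.push_back(ref[j - 1]);
      state = pD[at(i, j)];
      --j;
    } else {
      ar.push_back(read[i - 1]);
      af.push_back('-');
      state = pI[at(i, j)];
      --i;
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(af.begin(), af.end());
  return List::create(_["score"] = score,
                      _["aligned_read"] = ar,
                      _["aligned_ref"] = af);
}
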