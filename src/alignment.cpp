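#include <Rcpp.h>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

// Residue -> row index lookup for a scoring matrix; unknown characters fall
// back to the 'X' row so non-standard residues never crash the DP.
static void make_lookup(const std::vector<std::string> &letters, int lut[256],
                        int &xi) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  xi = -1;
  for (size_t i = 0; i < letters.size(); ++i) {
    unsigned char c = (unsigned char)letters[i][0];
    lut[c] = (int)i;
    if (c == 'X') xi = (int)i;
  }
  if (xi < 0) stop("scoring matrix must contain an 'X' row");
}

static std::vector<int> encode(const std::string &s, const int lut[256],
                               int xi) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int k = lut[(unsigned char)s[i]];
    v[i] = (k < 0) ? xi : k;
  }
  return v;
}

// Smith-Waterman, affine gaps: a gap of length L costs open + ext * L
// (the BLAST / Biostrings convention for gapOpening=11, gapExtension=1).
// Returns the optimal local score; when traceback is requested also the
// identity (matches / alignment columns) and alignment length of the
// first-encountered optimal cell (row-major scan => deterministic).
struct SWOut {
  int score;
  double identity;
  int alen;
};

static SWOut sw_pair(const std::vector<int> &a, const std::vector<int> &b,
                     const std::string &sa, const std::string &sb,
                     const std::vector<int> &S, int L, int open, int ext,
                     bool traceback) {
  const int m = (int)a.size(), n = (int)b.size();
  const int go = open + ext;
  const int NEG = -1000000000;
  SWOut out{0, NA_REAL, NA_INTEGER};
  if (m == 0 || n == 0) return out;

  if (!traceback) {
    // Rolling-array score-only DP: O(n) memory, no traceback bookkeeping.
    std::vector<int> Hup(n + 1, 0);   // H[i-1][*], overwritten in place
    std::vector<int> Fup(n + 1, NEG); // F[i-1][*]
    int best = 0;
    for (int i = 1; i <= m; ++i) {
      const int *Srow = S.data() + (size_t)a[i - 1] * L;
      int Hdiag = Hup[0];  // H[i-1][j-1]
      int Hleft = 0;       // H[i][j-1] (H[i][0] = 0 for local alignment)
      int Eleft = NEG;     // E[i][j-1]
      for (int j = 1; j <= n; ++j) {
        const int e = std::max(Hleft - go, Eleft - ext);
        const int f = std::max(Hup[j] - go, Fup[j] - ext);
        int h = Hdiag + Srow[b[j - 1]];
        if (f > h) h = f;
        if (e > h) h = e;
        if (h < 0) h = 0;
        Hdiag = Hup[j];
        Hup[j] = h;
        Fup[j] = f;
        Hleft = h;
        Eleft = e;
        if (h > best) best = h;
      }
    }
    out.score = best;
    return out;
  }

  // Full-matrix DP with traceback (identity / alignment length needed).
  const size_t W = (size_t)(n + 1);
  std::vector<int> H((size_t)(m + 1) * W, 0), E((size_t)(m + 1) * W, NEG),
      F((size_t)(m + 1) * W, NEG);
  std::vector<unsigned char> tbH, tbE, tbF;
  if (traceback) {
    tbH.assign((size_t)(m + 1) * W, 0);
    tbE.assign((size_t)(m + 1) * W, 0);
    tbF.assign((size_t)(m + 1) * W, 0);
  }
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int *Srow = S.data() + (size_t)a[i - 1] * L;
    for (int j = 1; j <= n; ++j) {
      const size_t ij = (size_t)i * W + j;
      const int eOpen = H[ij - 1] - go, eExt = E[ij - 1] - ext;
      const int e = (eOpen >= eExt) ? eOpen : eExt;
      const int fOpen = H[ij - W] - go, fExt = F[ij - W] - ext;
      const int f = (fOpen >= fExt) ? fOpen : fExt;
      const int d = H[ij - W - 1] + Srow[b[j - 1]];
      int h = 0;
      unsigned char p = 0;
      if (d > h) { h = d; p = 1; }
      if (f > h) { h = f; p = 3; }
      if (e > h) { h = e; p = 2; }
      H[ij] = h;
      E[ij] = e;
      F[ij] = f;
      if (traceback) {
        tbH[ij] = p;
        tbE[ij] = (eOpen >= eExt) ? 1 : 0;
        tbF[ij] = (fOpen >= fExt) ? 1 : 0;
      }
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  out.score = best;
  if (traceback) {
    int i = bi, j = bj, state = 0;  // 0=H,1=E,2=F
    int cols = 0, matches = 0;
    while (i > 0 && j > 0) {
      const size_t ij = (size_t)i * W + j;
      if (state == 0) {
        unsigned char p = tbH[ij];
        if (p == 0) break;
        if (p == 1) {
          ++cols;
          if (sa[i - 1] == sb[j - 1]) ++matches;
          --i; --j;
        } else if (p == 2) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {  // E: gap in `a`, consume b[j-1]
        ++cols;
        state = tbE[ij] ? 0 : 1;
        --j;
      } else {  // F: gap in `b`, consume a[i-1]
        ++cols;
        state = tbF[ij] ? 0 : 2;
        --i;
      }
    }
    out.alen = cols;
    out.identity = (cols > 0) ? (double)matches / (double)cols
                              : (best > 0 ? 1.0 : 0.0);
    if (best == 0) { out.alen = 0; out.identity = 0.0; }
  }
  return out;
}

// [[Rcpp::export(name = ".sw_batch")]]
DataFrame sw_batch(std::string query, std::vector<std::string> subjects,
                   IntegerMatrix S, int gap_open, int gap_ext,
                   bool traceback) {
  List dn = S.attr("dimnames");
  CharacterVector rn = dn[0];
  std::vector<std::string> letters(rn.size());
  for (int i = 0; i < rn.size(); ++i) letters[i] = as<std::string>(rn[i]);
  int lut[256], xi;
  make_lookup(letters, lut, xi);
  const int L = (int)letters.size();
  std::vector<int> Sf((size_t)L * L);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) Sf[(size_t)i * L + j] = S(i, j);

  const std::vector<int> q = encode(query, lut, xi);
  const int nsub = (int)subjects.size();
  IntegerVector score(nsub), alen(nsub);
  NumericVector ident(nsub);
  for (int k = 0; k < nsub; ++k) {
    std::vector<int> s = encode(subjects[k], lut, xi);
    SWOut r = sw_pair(q, s, query, subjects[k], Sf, L, gap_open, gap_ext,
                      traceback);
    score[k] = r.score;
    ident[k] = r.identity;
    alen[k] = r.alen;
  }
  return DataFrame::create(_["score"] = score, _["identity"] = ident,
                           _["align_length"] = alen);
}

// Cross-family collision scan for the synthetic-genome self-test: among
// all sequence pairs belonging to different families, report those whose
// Smith-Waterman local score reaches the Karlin-Altschul E-value cut-off
// (E = K * m * n * exp(-lambda * S) <= max_evalue). Returns a two-column
// 1-based index matrix of colliding pairs (i < j).
// [[Rcpp::export(name = ".collision_pairs")]]
IntegerMatrix collision_pairs(std::vector<std::string> seqs,
                              IntegerVector fam, IntegerMatrix S,
                              int gap_open, int gap_ext, double lambda,
                              double K, double max_evalue) {
  List dn = S.attr("dimnames");
  CharacterVector rn = dn[0];
  std::vector<std::string> letters(rn.size());
  for (int i = 0; i < rn.size(); ++i) letters[i] = as<std::string>(rn[i]);
  int lut[256], xi;
  make_lookup(letters, lut, xi);
  const int L = (int)letters.size();
  std::vector<int> Sf((size_t)L * L);
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j) Sf[(size_t)i * L + j] = S(i, j);

  const int n = (int)seqs.size();
  std::vector<std::vector<int>> enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode(seqs[i], lut, xi);

  std::vector<int> ia, ja;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (fam[i] == fam[j]) continue;
      const double m1 = (double)enc[i].size(), n1 = (double)enc[j].size();
      // minimal integer score that reaches the E-value threshold
      const double st = std::log(K * m1 * n1 / max_evalue) / lambda;
      SWOut r = sw_pair(enc[i], enc[j], seqs[i], seqs[j], Sf, L, gap_open,
                        gap_ext, false);
      if ((double)r.score >= st) {
        ia.push_back(i + 1);
        ja.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out((int)ia.size(), 2);
  for (size_t k = 0; k < ia.size(); ++k) {
    out(k, 0) = ia[k];
    out(k, 1) = ja[k];
  }
  return out;
}

// Progressive profile alignment. Sequences are added in the order given;
// each new sequence is globally aligned (Needleman-Wunsch, affine gaps,
// gap length L costs open + ext*L) against the running profile. Profile
// column score for residue a = mean over rows of S[row_residue, a], gap
// rows contributing 0. Tie-breaks are fixed (diagonal > vertical >
// horizontal; gap-open > gap-extend) so the result is deterministic.
// [[Rcpp::export(name = ".progressive_align")]]
CharacterVector progressive_align_cpp(std::vector<std::string> seqs,
                                      IntegerMatrix S, double gap_open,
                                      double gap_ext) {
  const int nseq = (int)seqs.size();
  if (nseq == 0) return CharacterVector(0);
  List dn = S.attr("dimnames");
  CharacterVector rn = dn[0];
  std::vector<std::string> letters(rn.size());
  for (int i = 0; i < rn.size(); ++i) letters[i] = as<std::string>(rn[i]);
  int lut[256], xi;
  make_lookup(letters, lut, xi);
  const int L = (int)letters.size();
  const double go = gap_open + gap_ext;
  const double NEG = -1e30;

  std::vector<std::string> aln;
  aln.push_back(seqs[0]);

  for (int k = 1; k < nseq; ++k) {
    const std::string &s = seqs[k];
    const int m = (int)aln[0].size();  // profile columns
    const int n = (int)s.size();
    const int nrow = (int)aln.size();

    // per-column profile scores against every alphabet letter
    std::vector<double> ps((size_t)m * L, 0.0);
    for (int i = 0; i < m; ++i) {
      for (int r = 0; r < nrow; ++r) {
        char c = aln[r][i];
        if (c == '-') continue;
        int ci = lut[(unsigned char)c];
        if (ci < 0) ci = xi;
        for (int a = 0; a < L; ++a) ps[(size_t)i * L + a] += S(ci, a);
      }
      for (int a = 0; a < L; ++a) ps[(size_t)i * L + a] /= (double)nrow;
    }
    std::vector<int> sv = encode(s, lut, xi);

    const size_t W = (size_t)(n + 1);
    std::vector<double> H((size_t)(m + 1) * W, NEG), E((size_t)(m + 1) * W, NEG),
        F((size_t)(m + 1) * W, NEG);
    std::vector<unsigned char> tbH((size_t)(m + 1) * W, 0),
        tbE((size_t)(m + 1) * W, 0), tbF((size_t)(m + 1) * W, 0);
    H[0] = 0.0;
    for (int j = 1; j <= n; ++j) {
      E[j] = -(go + gap_ext * (j - 1));
      H[j] = E[j];
      tbH[j] = 2;
      tbE[j] = (j == 1) ? 1 : 0;
    }
    for (int i = 1; i <= m; ++i) {
      const size_t i0 = (size_t)i * W;
      F[i0] = -(go + gap_ext * (i - 1));
      H[i0] = F[i0];
      tbH[i0] = 3;
      tbF[i0] = (i == 1) ? 1 : 0;
    }
    for (int i = 1; i <= m; ++i) {
      for (int j = 1; j <= n; ++j) {
        const size_t ij = (size_t)i * W + j;
        const double eOpen = H[ij - 1] - go, eExt = E[ij - 1] - gap_ext;
        E[ij] = (eOpen >= eExt) ? eOpen : eExt;
        tbE[ij] = (eOpen >= eExt) ? 1 : 0;
        const double fOpen = H[ij - W] - go, fExt = F[ij - W] - gap_ext;
        F[ij] = (fOpen >= fExt) ? fOpen : fExt;
        tbF[ij] = (fOpen >= fExt) ? 1 : 0;
        const double d = H[ij - W - 1] + ps[(size_t)(i - 1) * L + sv[j - 1]];
        double h = d;
        unsigned char p = 1;
        if (F[ij] > h) { h = F[ij]; p = 3; }
        if (E[ij] > h) { h = E[ij]; p = 2; }
        H[ij] = h;
        tbH[ij] = p;
      }
    }

    // traceback -> sequence of ops (1 diag, 2 insert-gap-column, 3 gap-in-new)
    std::vector<unsigned char> ops;
    int i = m, j = n, state = 0;
    while (i > 0 || j > 0) {
      const size_t ij = (size_t)i * W + j;
      if (state == 0) {
        unsigned char p = tbH[ij];
        if (p == 1) { ops.push_back(1); --i; --j; }
        else if (p == 2) state = 1;
        else state = 2;
      } else if (state == 1) {  // gap in profile: new column
        ops.push_back(2);
        state = tbE[ij] ? 0 : 1;
        --j;
      } else {  // gap in new sequence
        ops.push_back(3);
        state = tbF[ij] ? 0 : 2;
        --i;
      }
    }
    std::reverse(ops.begin(), ops.end());

    std::vector<std::string> newAln(nrow + 1);
    int pi = 0, sj = 0;
    for (size_t t = 0; t < ops.size(); ++t) {
      if (ops[t] == 1) {
        for (int r = 0; r < nrow; ++r) newAln[r].push_back(aln[r][pi]);
        newAln[nrow].push_back(s[sj]);
        ++pi; ++sj;
      } else if (ops[t] == 2) {
        for (int r = 0; r < nrow; ++r) newAln[r].push_back('-');
        newAln[nrow].push_back(s[sj]);
        ++sj;
      } else {
        for (int r = 0; r < nrow; ++r) newAln[r].push_back(aln[r][pi]);
        newAln[nrow].push_back('-');
        ++pi;
      }
    }
    aln.swap(newAln);
  }

  CharacterVector out(nseq);
  for (int r = 0; r < nseq; ++r) out[r] = aln[r];
  return out;
}

// Pairwise comparable-column and mismatch counts over aligned rows
// (columns where both rows are non-gap). Feeds the Poisson-corrected
// distance used by the internal NJ backend.
// [[Rcpp::export(name = ".pairwise_mismatch")]]
List pairwise_mismatch_cpp(std::vector<std::string> rows) {
  const int n = (int)rows.size();
  IntegerMatrix comp(n, n), mism(n, n);
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      if (rows[a].size() != rows[b].size())
        stop("aligned rows differ in length");
      int c = 0, mm = 0;
      const std::string &x = rows[a], &y = rows[b];
      for (size_t i = 0; i < x.size(); ++i) {
        if (x[i] == '-' || y[i] == '-') continue;
        ++c;
        if (x[i] != y[i]) ++mm;
      }
      comp(a, b) = comp(b, a) = c;
      mism(a, b) = mism(b, a) = mm;
    }
  }
  return List::create(_["compared"] = comp, _["mismatch"] = mism);
}
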