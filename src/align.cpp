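#include <Rcpp.h>
#include <vector>
#include <cfloat>
using namespace Rcpp;

// Window scan of a log-odds PSSM over an integer-coded residue sequence.
// seq codes: 0..(ncol-1) residue index, -1 unknown (X), -2 stop (*).
// Returns positions (1-based window starts) and scores for windows >= threshold.
// [[Rcpp::export]]
List pssm_scan_cpp(IntegerVector seq, NumericMatrix pssm,
                   double threshold, double unknown_score, double stop_score) {
  int L = pssm.nrow();
  int m = seq.size();
  if (m < L) return List::create(_["pos"] = IntegerVector(0),
                                 _["score"] = NumericVector(0));
  int nw = m - L + 1;
  // shift codes to 0..21: 0 = stop (-2), 1 = unknown (-1), 2+a = residue a
  std::vector<int> code(m);
  for (int t = 0; t < m; ++t) code[t] = seq[t] + 2;
  std::vector<double> acc(nw, 0.0);
  double colvals[22];
  for (int i = 0; i < L; ++i) {
    colvals[0] = stop_score;
    colvals[1] = unknown_score;
    for (int a = 0; a < 20; ++a) colvals[2 + a] = pssm(i, a);
    const int* cp = code.data() + i;
    for (int p = 0; p < nw; ++p) acc[p] += colvals[cp[p]];
  }
  std::vector<int> pos;
  std::vector<double> sc;
  for (int p = 0; p < nw; ++p)
    if (acc[p] >= threshold) { pos.push_back(p + 1); sc.push_back(acc[p]); }
  return List::create(_["pos"] = wrap(pos), _["score"] = wrap(sc));
}

// Banded global (Needleman-Wunsch, affine gaps) alignment of two column
// profiles. A and B are S x L matrices of column counts; the last row is the
// gap state. Column-column score is occupancy-weighted expected match score.
// Band: row i admits columns j in [i + dmin, i + dmax].
// Returns merged path as 1-based column indices (0 = gap) plus the score.

static inline double col_score(const std::vector<double>& fa, double occa,
                               const std::vector<double>& fb, double occb,
                               int S1, double match, double mismatch) {
  if (occa <= 0.0 || occb <= 0.0) return 0.0;
  double pm = 0.0;
  for (int s = 0; s < S1; ++s) pm += fa[s] * fb[s];
  return occa * occb * (match * pm + mismatch * (1.0 - pm));
}

// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix A, NumericMatrix B,
                       double match, double mismatch,
                       double gap_open, double gap_ext, int band) {
  const double NEG = -1e30;
  int S = A.nrow();
  int S1 = S - 1; // residue states (last row = gap)
  int L1 = A.ncol(), L2 = B.ncol();
  int dmin = std::min(0, L2 - L1) - band;
  int dmax = std::max(0, L2 - L1) + band;
  int K = dmax - dmin + 1;

  // normalized non-gap frequencies + occupancy per column
  std::vector<std::vector<double> > fA(L1, std::vector<double>(S1, 0.0)),
      fB(L2, std::vector<double>(S1, 0.0));
  std::vector<double> occA(L1), occB(L2);
  for (int i = 0; i < L1; ++i) {
    double tot = 0.0, ng = 0.0;
    for (int s = 0; s < S; ++s) tot += A(s, i);
    for (int s = 0; s < S1; ++s) ng += A(s, i);
    occA[i] = tot > 0 ? ng / tot : 0.0;
    if (ng > 0) for (int s = 0; s < S1; ++s) fA[i][s] = A(s, i) / ng;
  }
  for (int j = 0; j < L2; ++j) {
    double tot = 0.0, ng = 0.0;
    for (int s = 0; s < S; ++s) tot += B(s, j);
    for (int s = 0; s < S1; ++s) ng += B(s, j);
    occB[j] = tot > 0 ? ng / tot : 0.0;
    if (ng > 0) for (int s = 0; s < S1; ++s) fB[j][s] = B(s, j) / ng;
  }

  // DP over rows 0..L1 with banded columns; k = j - i - dmin in [0, K)
  // traceback codes: for M, 0=from M,1=from X,2=from Y; for X/Y likewise.
  std::vector<double> Mprev(K, NEG), Xprev(K, NEG), Yprev(K, NEG);
  std::vector<double> Mcur(K, NEG), Xcur(K, NEG), Ycur(K, NEG);
  RawMatrix tbM(L1 + 1, K), tbX(L1 + 1, K), tbY(L1 + 1, K);

  // row 0
  for (int k = 0; k < K; ++k) {
    int j = 0 + dmin + k;
    if (j < 0 || j > L2) continue;
    if (j == 0) { Mprev[k] = 0.0; }
    else {
      // gap in A consuming B[0..j)
      Yprev[k] = gap_open + gap_ext * j;
      tbY(0, k) = (j == 1) ? 0 : 2;
    }
  }
  for (int i = 1; i <= L1; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG);
    std::fill(Xcur.begin(), Xcur.end(), NEG);
    std::fill(Ycur.begin(), Ycur.end(), NEG);
    for (int k = 0; k < K; ++k) {
      int j = i + dmin + k;
      if (j < 0 || j > L2) continue;
      // X: gap in B, consume A row i; from (i-1, j) which is k+1 in prev row
      if (k + 1 < K) {
        double m0 = Mprev[k + 1] + gap_open + gap_ext;
        double x0 = Xprev[k + 1] + gap_ext;
        double y0 = Yprev[k + 1] + gap_open + gap_ext;
        double best = m0; int c = 0;
        if (x0 > best) { best = x0; c = 1; }
        if (y0 > best) { best = y0; c = 2; }
        if (best > NEG / 2) { Xcur[k] = best; tbX(i, k) = (unsigned char)c; }
      }
      if (j >= 1) {
        // M: diagonal from (i-1, j-1) = same k in prev row
        double sc = col_score(fA[i - 1], occA[i - 1], fB[j - 1], occB[j - 1],
                              S1, match, mismatch);
        double m0 = Mprev[k], x0 = Xprev[k], y0 = Yprev[k];
        double best = m0; int c = 0;
        if (x0 > best) { best = x0; c = 1; }
        if (y0 > best) { best = y0; c = 2; }
        if (best > NEG / 2) { Mcur[k] = best + sc; tbM(i, k) = (unsigned char)c; }
        // Y: gap in A, consume B col j; from (i, j-1) = k-1 current row
        if (k - 1 >= 0) {
          double m1 = Mcur[k - 1] + gap_open + gap_ext;
          double x1 = Xcur[k - 1] + gap_open + gap_ext;
          double y1 = Ycur[k - 1] + gap_ext;
          double b2 = m1; int c2 = 0;
          if (x1 > b2) { b2 = x1; c2 = 1; }
          if (y1 > b2) { b2 = y1; c2 = 2; }
          if (b2 > NEG / 2) { Ycur[k] = b2; tbY(i, k) = (unsigned char)c2; }
        }
      }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    // store row in traceback only (scores already in tb decisions)
  }
  int kend = L2 - L1 - dmin;
  if (kend < 0 || kend >= K) stop("band too narrow for sequence lengths");
  double sM = Mprev[kend], sX = Xprev[kend], sY = Yprev[kend];
  int state = 0; double score = sM;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }

  // traceback
  std::vector<int> pa, pb;
  int i = L1, j = L2;
  while (i > 0 || j > 0) {
    if (i == 0) { pa.push_back(0); pb.push_back(j); --j; continue; }
    if (j == 0) { pa.push_back(i); pb.push_back(0); --i; continue; }
    int k = j - i - dmin;
    if (k < 0 || k >= K) stop("traceback left the band");
    if (state == 0) { // M consumed (i,j)
      pa.push_back(i); pb.push_back(j);
      int c = tbM(i, k); --i; --j; state = c;
    } else if (state == 1) { // X consumed A row i
      pa.push_back(i); pb.push_back(0);
      int c = tbX(i, k); --i; state = c;
    } else { // Y consumed B col j
      pa.push_back(0); pb.push_back(j);
      int c = tbY(i, k); --j; state = c;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["path_a"] = wrap(pa), _["path_b"] = wrap(pb),
                      _["score"] = score);
}

// Banded local (Smith-Waterman, affine gaps) alignment of two integer-coded
// sequences around a fixed diagonal (j - i ~= diag). Returns best local
// alignment coordinates (1-based inclusive), score, matches and alignment
// length (columns including gaps). Traceback-free: per-cell alignment
// statistics (matches, length, start) are propagated along the DP, using
// two rolling rows only.

struct CellStats { double score; int matches, alen, as, bs; };

// [[Rcpp::export]]
List banded_local_cpp(IntegerVector a, IntegerVector b, int diag, int band,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  const double NEG = -1e30;
  int L1 = a.size(), L2 = b.size();
  int dmin = diag - band, dmax = diag + band;
  int K = dmax - dmin + 1;
  std::vector<CellStats> Mp(K), Xp(K), Yp(K), Mc(K), Xc(K), Yc(K);
  const CellStats DEAD = {NEG, 0, 0, 0, 0};
  for (int k = 0; k < K; ++k) Mp[k] = Xp[k] = Yp[k] = DEAD;
  for (int k = 0; k < K; ++k) {
    int j = 0 + dmin + k;
    if (j >= 0 && j <= L2) { Mp[k].score = 0.0; }
  }
  CellStats best = DEAD; best.score = 0.0;
  int best_i = -1, best_j = -1;
  for (int i = 1; i <= L1; ++i) {
    for (int k = 0; k < K; ++k) Mc[k] = Xc[k] = Yc[k] = DEAD;
    for (int k = 0; k < K; ++k) {
      int j = i + dmin + k;
      if (j < 0 || j > L2) continue;
      if (k + 1 < K) { // X: gap in b, consume a[i]; from (i-1, j) = k+1 prev
        CellStats m0 = Mp[k + 1], x0 = Xp[k + 1];
        m0.score += gap_open + gap_ext;
        x0.score += gap_ext;
        CellStats bb = (x0.score > m0.score) ? x0 : m0;
        if (bb.score > NEG / 2) { bb.alen += 1; Xc[k] = bb; }
      }
      if (j >= 1) {
        bool is_m = (a[i - 1] >= 0 && a[i - 1] == b[j - 1]);
        double sc = is_m ? match : mismatch;
        CellStats pred = Mp[k];
        if (Xp[k].score > pred.score) pred = Xp[k];
        if (Yp[k].score > pred.score) pred = Yp[k];
        CellStats cur;
        if (pred.score > 0.0 && pred.score > NEG / 2) {
          cur = pred;
          cur.score += sc;
        } else { // local restart at (i, j)
          cur.score = sc; cur.matches = 0; cur.alen = 0;
          cur.as = i; cur.bs = j;
        }
        cur.alen += 1;
        if (is_m) cur.matches += 1;
        if (cur.score > 0) {
          Mc[k] = cur;
          if (cur.score > best.score) { best = cur; best_i = i; best_j = j; }
        }
        if (k - 1 >= 0) { // Y: gap in a, consume b[j]; from (i, j-1) = k-1 cur
          CellStats m1 = Mc[k - 1], y1 = Yc[k - 1];
          m1.score += gap_open + gap_ext;
          y1.score += gap_ext;
          CellStats b2 = (y1.score > m1.score) ? y1 : m1;
          if (b2.score > NEG / 2) { b2.alen += 1; Yc[k] = b2; }
        }
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  if (best_i < 0)
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1,
                        _["matches"] = 0, _["aln_len"] = 0);
  return List::create(_["score"] = best.score,
                      _["a_start"] = best.as, _["a_end"] = best_i,
                      _["b_start"] = best.bs, _["b_end"] = best_j,
                      _["matches"] = best.matches, _["aln_len"] = best.alen);
}
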