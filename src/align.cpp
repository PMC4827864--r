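// Affine-gap pairwise alignment engine.
//
// Conventions shared with the R layer:
//   * sequences arrive as 0-based integer codes into the package alphabet
//   * a gap of length g costs gapOpen + (g-1) * gapExtend (GCG convention:
//     the first gapped residue pays the creation penalty, later ones the
//     extension penalty)
//   * "global" penalizes end gaps unless freeEnds is set (semi-global)
//   * traceback tie-break: match state preferred over a gap in the second
//     sequence ("up"), preferred over a gap in the first ("left")

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <climits>

using namespace Rcpp;

namespace {

const int NEG = INT_MIN / 4;

struct Scoring {
  std::vector<int> mat;
  int n;
  int open;
  int ext;
  inline int s(int x, int y) const { return mat[x * n + y]; }
};

Scoring makeScoring(const IntegerMatrix& S, int open, int ext) {
  Scoring sc;
  sc.n = S.nrow();
  sc.open = open;
  sc.ext = ext;
  sc.mat.assign((size_t) sc.n * sc.n, 0);
  for (int i = 0; i < sc.n; ++i)
    for (int j = 0; j < sc.n; ++j)
      sc.mat[(size_t) i * sc.n + j] = S(i, j);
  return sc;
}

inline int max3(int a, int b, int c) { return std::max(a, std::max(b, c)); }

// Score-only Gotoh with three states; rolling rows.
int alignScore(const std::vector<int>& a, const std::vector<int>& b,
               const Scoring& sc, bool local, bool freeEnds) {
  const int na = (int) a.size(), nb = (int) b.size();
  std::vector<int> M(nb + 1), X(nb + 1), Y(nb + 1);

  M[0] = local ? 0 : 0;
  X[0] = NEG;
  Y[0] = NEG;
  for (int j = 1; j <= nb; ++j) {
    M[j] = local ? 0 : NEG;
    X[j] = NEG;
    Y[j] = local ? NEG
                 : (freeEnds ? 0 : -(sc.open + (j - 1) * sc.ext));
  }

  int best = local ? 0 : NEG;
  if (freeEnds) best = max3(M[nb], X[nb], Y[nb]);

  for (int i = 1; i <= na; ++i) {
    int diagM = M[0], diagX = X[0], diagY = Y[0];
    M[0] = local ? 0 : NEG;
    X[0] = local ? NEG : (freeEnds ? 0 : -(sc.open + (i - 1) * sc.ext));
    Y[0] = NEG;
    const int* srow = &sc.mat[(size_t) a[i - 1] * sc.n];
    for (int j = 1; j <= nb; ++j) {
      const int pm = M[j], px = X[j], py = Y[j];  // (i-1, j)

      int dbest = max3(diagM, diagX, diagY);
      if (local && dbest < 0) dbest = 0;
      int m = (dbest <= NEG / 2) ? NEG : dbest + srow[b[j - 1]];

      int x = std::max(std::max(pm, py) - sc.open, px - sc.ext);
      if (x < NEG / 2) x = NEG;

      int y = std::max(std::max(M[j - 1], X[j - 1]) - sc.open,
                       Y[j - 1] - sc.ext);
      if (y < NEG / 2) y = NEG;

      diagM = pm; diagX = px; diagY = py;
      M[j] = m; X[j] = x; Y[j] = y;

      if (local && m > best) best = m;
      if (freeEnds && (i == na || j == nb)) {
        const int h = max3(m, x, y);
        if (h > best) best = h;
      }
    }
  }
  if (local || freeEnds) return best;
  return max3(M[nb], X[nb], Y[nb]);
}

void fisherYates(std::vector<int>& v) {
  for (int i = (int) v.size() - 1; i > 0; --i) {
    int j = (int) (unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

}  // namespace

// [[Rcpp::export]]
double c_align_score(IntegerVector a, IntegerVector b, IntegerMatrix S,
                     int gapOpen, int gapExtend, bool local, bool freeEnds) {
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  Scoring sc = makeScoring(S, gapOpen, gapExtend);
  return (double) alignScore(av, bv, sc, local, freeEnds);
}

// Full traceback. States: 0 = M (match/mismatch), 1 = X (gap in b,
// consumes a, "up"), 2 = Y (gap in a, consumes b, "left").
// Predecessor codes stored per state; 3 marks a fresh local start / origin.
// [[Rcpp::export]]
List c_align_traceback(IntegerVector a, IntegerVector b, IntegerMatrix S,
                       int gapOpen, int gapExtend, bool local, bool freeEnds) {
  const int na = a.size(), nb = b.size();
  Scoring sc = makeScoring(S, gapOpen, gapExtend);

  const size_t ncell = (size_t) (na + 1) * (nb + 1);
  std::vector<int> M(ncell), X(ncell), Y(ncell);
  std::vector<unsigned char> pM(ncell, 3), pX(ncell, 3), pY(ncell, 3);
  auto at = [nb](int i, int j) { return (size_t) i * (nb + 1) + j; };

  M[at(0, 0)] = 0; X[at(0, 0)] = NEG; Y[at(0, 0)] = NEG;
  for (int j = 1; j <= nb; ++j) {
    const size_t c = at(0, j);
    M[c] = local ? 0 : NEG;
    X[c] = NEG;
    Y[c] = local ? NEG : (freeEnds ? 0 : -(sc.open + (j - 1) * sc.ext));
    pY[c] = (unsigned char) (j == 1 ? 0 : 2);  // from origin M or previous Y
  }
  for (int i = 1; i <= na; ++i) {
    const size_t c = at(i, 0);
    M[c] = local ? 0 : NEG;
    Y[c] = NEG;
    X[c] = local ? NEG : (freeEnds ? 0 : -(sc.open + (i - 1) * sc.ext));
    pX[c] = (unsigned char) (i == 1 ? 0 : 1);
  }

  int bestVal = local ? 0 : NEG;
  int bestI = 0, bestJ = 0, bestState = 0;

  for (int i = 1; i <= na; ++i) {
    const int* srow = &sc.mat[(size_t) a[i - 1] * sc.n];
    for (int j = 1; j <= nb; ++j) {
      const size_t c = at(i, j), cu = at(i - 1, j), cl = at(i, j - 1),
                   cd = at(i - 1, j - 1);

      // M: predecessor at (i-1, j-1), preference M > X > Y, local start last
      int dbest = M[cd]; unsigned char dp = 0;
      if (X[cd] > dbest) { dbest = X[cd]; dp = 1; }
      if (Y[cd] > dbest) { dbest = Y[cd]; dp = 2; }
      // local: a non-positive predecessor is a fresh start (standard SW
      // restart; also keeps the traceback from walking past the origin)
      if (local && dbest <= 0) { dbest = 0; dp = 3; }
      int m = (dbest <= NEG / 2) ? NEG : dbest + srow[b[j - 1]];
      M[c] = m; pM[c] = dp;

      // X: predecessor at (i-1, j), preference M (open) > X (extend) > Y
      int x = M[cu] - sc.open; unsigned char xp = 0;
      if (X[cu] - sc.ext > x) { x = X[cu] - sc.ext; xp = 1; }
      if (Y[cu] - sc.open > x) { x = Y[cu] - sc.open; xp = 2; }
      if (x < NEG / 2) x = NEG;
      X[c] = x; pX[c] = xp;

      // Y: predecessor at (i, j-1), preference M > X > Y
      int y = M[cl] - sc.open; unsigned char yp = 0;
      if (X[cl] - sc.open > y) { y = X[cl] - sc.open; yp = 1; }
      if (Y[cl] - sc.ext > y) { y = Y[cl] - sc.ext; yp = 2; }
      if (y < NEG / 2) y = NEG;
      Y[c] = y; pY[c] = yp;

      if (local) {
        if (m > bestVal) { bestVal = m; bestI = i; bestJ = j; bestState = 0; }
      } else if (freeEnds && (i == na || j == nb)) {
        if (m > bestVal) { bestVal = m; bestI = i; bestJ = j; bestState = 0; }
        if (x > bestVal) { bestVal = x; bestI = i; bestJ = j; bestState = 1; }
        if (y > bestVal) { bestVal = y; bestI = i; bestJ = j; bestState = 2; }
      }
    }
  }

  if (!local && !freeEnds) {
    const size_t c = at(na, nb);
    bestVal = M[c]; bestI = na; bestJ = nb; bestState = 0;
    if (X[c] > bestVal) { bestVal = X[c]; bestState = 1; }
    if (Y[c] > bestVal) { bestVal = Y[c]; bestState = 2; }
  }

  // Trace back; emit 1-based residue indices, NA for gaps.
  std::vector<int> ia, ib;
  if (!(local && bestVal <= 0)) {
    int i = bestI, j = bestJ, st = bestState;
    while (true) {
      if (!local && i == 0 && j == 0) break;
      const size_t c = at(i, j);
      if (st == 0) {
        const unsigned char p = pM[c];
        ia.push_back(i); ib.push_back(j);
        --i; --j;
        if (local && p == 3) break;
        st = p;
        if (!local && i == 0 && j == 0) break;
      } else if (st == 1) {
        ia.push_back(i); ib.push_back(NA_INTEGER);
        st = pX[c];
        --i;
      } else {
        ia.push_back(NA_INTEGER); ib.push_back(j);
        st = pY[c];
        --j;
      }
    }
    std::reverse(ia.begin(), ia.end());
    std::reverse(ib.begin(), ib.end());
  }

  return List::create(_["score"] = (double) bestVal,
                      _["ia"] = wrap(ia),
                      _["ib"] = wrap(ib));
}

// Null score distribution under residue shuffling (uses R's RNG so that
// set.seed() on the R side controls reproducibility).
// [[Rcpp::export]]
NumericVector c_shuffle_null(IntegerVector a, IntegerVector b, IntegerMatrix S,
                             int gapOpen, int gapExtend, int n, bool both,
                             bool local, bool freeEnds) {
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  Scoring sc = makeScoring(S, gapOpen, gapExtend);
  NumericVector out(n);
  std::vector<int> as = av, bs = bv;
  for (int r = 0; r < n; ++r) {
    fisherYates(as);
    if (both) fisherYates(bs);
    out[r] = (double) alignScore(as, both ? bs : bv, sc, local, freeEnds);
    if (r % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix c_allpairs_scores(List seqs, IntegerMatrix S, int gapOpen,
                                int gapExtend, bool local, bool freeEnds) {
  const int n = seqs.size();
  Scoring sc = makeScoring(S, gapOpen, gapExtend);
  std::vector<std::vector<int> > v(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector s = seqs[i];
    v[i].assign(s.begin(), s.end());
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double sc_ij = (double) alignScore(v[i], v[j], sc, local, freeEnds);
      out(i, j) = sc_ij;
      out(j, i) = sc_ij;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix c_cross_scores(List seqsA, List seqsB, IntegerMatrix S,
                             int gapOpen, int gapExtend, bool local,
                             bool freeEnds) {
  const int na = seqsA.size(), nb = seqsB.size();
  Scoring sc = makeScoring(S, gapOpen, gapExtend);
  std::vector<std::vector<int> > va(na), vb(nb);
  for (int i = 0; i < na; ++i) {
    IntegerVector s = seqsA[i];
    va[i].assign(s.begin(), s.end());
  }
  for (int j = 0; j < nb; ++j) {
    IntegerVector s = seqsB[j];
    vb[j].assign(s.begin(), s.end());
  }
  NumericMatrix out(na, nb);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j)
      out(i, j) = (double) alignScore(va[i], vb[j], sc, local, freeEnds);
    Rcpp::checkUserInterrupt();
  }
  return out;
}
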