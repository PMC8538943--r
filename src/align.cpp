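#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// 4-bit membership masks for the IUPAC nucleotide alphabet (A=1, C=2, G=4, T=8).
static int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'R': return 1 | 4;          case 'Y': return 2 | 8;
    case 'S': return 2 | 4;          case 'W': return 1 | 8;
    case 'K': return 4 | 8;          case 'M': return 1 | 2;
    case 'B': return 2 | 4 | 8;      case 'D': return 1 | 4 | 8;
    case 'H': return 1 | 2 | 8;     case 'V': return 1 | 2 | 4;
    case 'N': return 15;
    default:  return 0;              // '-' and anything else: no base content
  }
}

// [[Rcpp::export]]
IntegerVector iupac_masks_cpp(std::string s) {
  IntegerVector out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = iupac_mask(s[i]);
  return out;
}

static const double NEG_INF = -1e30;
enum { SM = 0, SU = 1, SL = 2 };  // match/mismatch, gap-in-b (up), gap-in-a (left)

// Needleman-Wunsch with gap run cost gap_open + (len-1) * gap_extend.
// mode: 0 = global, 1 = overlap (terminal gaps free).
// Ambiguity codes count as a match when their base sets intersect.
// Tie-breaking: diagonal, then up, then left (both for state choice and
// predecessor choice), giving a deterministic alignment.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend, int mode) {
  const int n = a.size(), m = b.size();
  const bool overlap = mode == 1;
  std::vector<double> M((n + 1) * (m + 1), NEG_INF),
                      U((n + 1) * (m + 1), NEG_INF),
                      L((n + 1) * (m + 1), NEG_INF);
  std::vector<int> amask(n), bmask(m);
  for (int i = 0; i < n; ++i) amask[i] = iupac_mask(a[i]);
  for (int j = 0; j < m; ++j) bmask[j] = iupac_mask(b[j]);
  #define IX(i, j) ((i) * (m + 1) + (j))

  M[IX(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j)
    L[IX(0, j)] = overlap ? 0.0 : gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i)
    U[IX(i, 0)] = overlap ? 0.0 : gap_open + (i - 1) * gap_extend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (amask[i - 1] & bmask[j - 1]) ? match : mismatch;
      double d = M[IX(i - 1, j - 1)];
      if (U[IX(i - 1, j - 1)] > d) d = U[IX(i - 1, j - 1)];
      if (L[IX(i - 1, j - 1)] > d) d = L[IX(i - 1, j - 1)];
      M[IX(i, j)] = d + s;
      double u = M[IX(i - 1, j)] + gap_open;
      if (U[IX(i - 1, j)] + gap_extend > u) u = U[IX(i - 1, j)] + gap_extend;
      if (L[IX(i - 1, j)] + gap_open > u) u = L[IX(i - 1, j)] + gap_open;
      U[IX(i, j)] = u;
      double l = M[IX(i, j - 1)] + gap_open;
      if (L[IX(i, j - 1)] + gap_extend > l) l = L[IX(i, j - 1)] + gap_extend;
      if (U[IX(i, j - 1)] + gap_open > l) l = U[IX(i, j - 1)] + gap_open;
      L[IX(i, j)] = l;
    }
  }

  auto cellmax = [&](int i, int j, int &state) {
    double best = M[IX(i, j)]; state = SM;
    if (U[IX(i, j)] > best) { best = U[IX(i, j)]; state = SU; }
    if (L[IX(i, j)] > best) { best = L[IX(i, j)]; state = SL; }
    return best;
  };

  int ei = n, ej = m, estate;
  double score = cellmax(n, m, estate);
  if (overlap) {
    // free terminal gaps: end anywhere on the last row or column
    for (int i = 0; i <= n; ++i) {
      int st; double v = cellmax(i, m, st);
      if (v > score) { score = v; ei = i; ej = m; estate = st; }
    }
    for (int j = 0; j < m; ++j) {
      int st; double v = cellmax(n, j, st);
      if (v > score) { score = v; ei = n; ej = j; estate = st; }
    }
  }

  std::string ra, rb;
  // terminal padding for overlap mode
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }

  int i = ei, j = ej, state = estate;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) { ra.push_back('-'); rb.push_back(b[--j]); state = SL; continue; }
    if (j == 0) { ra.push_back(a[--i]); rb.push_back('-'); state = SU; continue; }
    if (state == SM) {
      const double s = (amask[i - 1] & bmask[j - 1]) ? match : mismatch;
      const double need = M[IX(i, j)] - s;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
      if (M[IX(i, j)] >= need - eps) state = SM;
      else if (U[IX(i, j)] >= need - eps) state = SU;
      else state = SL;
    } else if (state == SU) {
      const double v = U[IX(i, j)];
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
      if (M[IX(i, j)] + gap_open >= v - eps) state = SM;
      else if (U[IX(i, j)] + gap_extend >= v - eps) state = SU;
      else state = SL;
    } else {
      const double v = L[IX(i, j)];
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
      if (M[IX(i, j)] + gap_open >= v - eps) state = SM;
      else if (L[IX(i, j)] + gap_extend >= v - eps) state = SL;
      else state = SU;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  #undef IX
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}

// Profile-profile global alignment for the progressive MSA.  Profiles are
// 5 x L frequency matrices (rows A, C, G, T, gap); ambiguity codes are
// spread fractionally over their base sets upstream.  Column score is the
// expected pairwise score; residue-vs-gap pairs score gap_extend, gap-gap 0.
// Returns the edit path as 0 = diagonal, 1 = gap in B (consume A column),
// 2 = gap in A (consume B column), in alignment order.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix pa, NumericMatrix pb,
                       double match, double mismatch,
                       double gap_open, double gap_extend) {
  const int n = pa.ncol(), m = pb.ncol();
  std::vector<double> M((n + 1) * (m + 1), NEG_INF),
                      U((n + 1) * (m + 1), NEG_INF),
                      L((n + 1) * (m + 1), NEG_INF);
  #define IX(i, j) ((i) * (m + 1) + (j))
  M[IX(0, 0)] = 0.0;
  for (int j = 1; j <= m; ++j) L[IX(0, j)] = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) U[IX(i, 0)] = gap_open + (i - 1) * gap_extend;

  auto colscore = [&](int i, int j) {
    double s = 0.0, ares = 0.0, bres = 0.0;
    for (int x = 0; x < 4; ++x) { ares += pa(x, i); bres += pb(x, j); }
    for (int x = 0; x < 4; ++x)
      for (int y = 0; y < 4; ++y)
        s += pa(x, i) * pb(y, j) * (x == y ? match : mismatch);
    s += (pa(4, i) * bres + pb(4, j) * ares) * gap_extend;
    return s;
  };

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = colscore(i - 1, j - 1);
      double d = M[IX(i - 1, j - 1)];
      if (U[IX(i - 1, j - 1)] > d) d = U[IX(i - 1, j - 1)];
      if (L[IX(i - 1, j - 1)] > d) d = L[IX(i - 1, j - 1)];
      M[IX(i, j)] = d + s;
      double u = M[IX(i - 1, j)] + gap_open;
      if (U[IX(i - 1, j)] + gap_extend > u) u = U[IX(i - 1, j)] + gap_extend;
      if (L[IX(i - 1, j)] + gap_open > u) u = L[IX(i - 1, j)] + gap_open;
      U[IX(i, j)] = u;
      double l = M[IX(i, j - 1)] + gap_open;
      if (L[IX(i, j - 1)] + gap_extend > l) l = L[IX(i, j - 1)] + gap_extend;
      if (U[IX(i, j - 1)] + gap_open > l) l = U[IX(i, j - 1)] + gap_open;
      L[IX(i, j)] = l;
    }
  }

  int i = n, j = m, state = SM;
  double score = M[IX(n, m)];
  if (U[IX(n, m)] > score) { score = U[IX(n, m)]; state = SU; }
  if (L[IX(n, m)] > score) { score = L[IX(n, m)]; state = SL; }

  std::vector<int> ops;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back(2); --j; continue; }
    if (j == 0) { ops.push_back(1); --i; continue; }
    if (state == SM) {
      const double need = M[IX(i, j)] - colscore(i - 1, j - 1);
      ops.push_back(0); --i; --j;
      if (M[IX(i, j)] >= need - eps) state = SM;
      else if (U[IX(i, j)] >= need - eps) state = SU;
      else state = SL;
    } else if (state == SU) {
      const double v = U[IX(i, j)];
      ops.push_back(1); --i;
      if (M[IX(i, j)] + gap_open >= v - eps) state = SM;
      else if (U[IX(i, j)] + gap_extend >= v - eps) state = SU;
      else state = SL;
    } else {
      const double v = L[IX(i, j)];
      ops.push_back(2); --j;
      if (M[IX(i, j)] + gap_open >= v - eps) state = SM;
      else if (L[IX(i, j)] + gap_extend >= v - eps) state = SL;
      else state = SU;
    }
  }
  std::reverse(ops.begin(), ops.end());
  #undef IX
  return List::create(_["ops"] = wrap(ops), _["score"] = score);
}

// Pairwise substitution counts over an integer-coded alignment
// (rows = sequences; 0=A, 1=C, 2=G, 3=T, negative = gap/ambiguity, excluded
// by pairwise deletion).  Transitions are A<->G and C<->T (same parity in
// this coding); every other differing pair is a transversion.
// [[Rcpp::export]]
List subst_count_cpp(IntegerMatrix seqs) {
  const int n = seqs.nrow(), Lc = seqs.ncol();
  IntegerMatrix sites(n, n), ts(n, n), tv(n, n);
  // column-major copy for cache-friendly row access
  std::vector<int> dat(n * Lc);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < Lc; ++k) dat[i * Lc + k] = seqs(i, k);
  for (int i = 0; i < n; ++i) {
    const int *ri = &dat[i * Lc];
    for (int j = i + 1; j < n; ++j) {
      const int *rj = &dat[j * Lc];
      int ns = 0, nts = 0, ntv = 0;
      for (int k = 0; k < Lc; ++k) {
        const int x = ri[k], y = rj[k];
        if (x < 0 || y < 0) continue;
        ++ns;
        if (x != y) {
          if ((x & 1) == (y & 1)) ++nts; else ++ntv;
        }
      }
      sites(i, j) = sites(j, i) = ns;
      ts(i, j) = ts(j, i) = nts;
      tv(i, j) = tv(j, i) = ntv;
    }
  }
  return List::create(_["sites"] = sites, _["transitions"] = ts,
                      _["transversions"] = tv);
}
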