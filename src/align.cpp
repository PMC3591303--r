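// Banded local alignment: three-state (M / query-gap / subject-gap) affine
// dynamic programming restricted to a diagonal band, with full traceback.
// Memory is proportional to band area (rows x band width), never to the
// full m x n rectangle.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const int NEG = INT32_MIN / 4;

// traceback codes
enum { TB_START = 0, TB_M = 1, TB_X = 2, TB_Y = 3 };

// [[Rcpp::export(name = ".banded_align_cpp")]]
SEXP banded_align_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sm,
                      int q_lo, int q_hi, int s_lo, int s_hi, int dlo,
                      int dhi, int gip, int gep) {
  if (q_lo < 0) q_lo = 0;
  if (s_lo < 0) s_lo = 0;
  if (q_hi > q.size() - 1) q_hi = q.size() - 1;
  if (s_hi > s.size() - 1) s_hi = s.size() - 1;
  if (q_hi < q_lo || s_hi < s_lo || dhi < dlo) return R_NilValue;
  // clip diagonal range to the rectangle's feasible diagonals
  if (dlo < q_lo - s_hi) dlo = q_lo - s_hi;
  if (dhi > q_hi - s_lo) dhi = q_hi - s_lo;
  if (dhi < dlo) return R_NilValue;

  const int R = q_hi - q_lo + 1;
  const int W = dhi - dlo + 1;
  const int A = sm.nrow(); // alphabet size (21 when a sentinel row is added)
  const int *smv = sm.begin();
  // cell (i,j): row r = i - q_lo, col c = j - (i - dhi); moves:
  //   diag (i-1,j-1) -> (r-1, c); up (i-1,j) -> (r-1, c+1); left -> (r, c-1)
  std::vector<int> M((size_t)R * W, NEG), X((size_t)R * W, NEG),
      Y((size_t)R * W, NEG);
  std::vector<unsigned char> tM((size_t)R * W, TB_START),
      tX((size_t)R * W, 0), tY((size_t)R * W, 0);

  int best = 0, best_r = -1, best_c = -1, best_i = -1, best_j = -1;
  const int go = gip + gep; // first gapped residue pays opening + extension
  for (int r = 0; r < R; ++r) {
    int i = q_lo + r;
    int jlo = i - dhi;
    if (jlo < s_lo) jlo = s_lo;
    int jhi = i - dlo;
    if (jhi > s_hi) jhi = s_hi;
    if (jhi < jlo) continue;
    size_t row = (size_t)r * W;
    size_t prow = (size_t)(r - 1) * W;
    for (int j = jlo; j <= jhi; ++j) {
      int c = j - (i - dhi);
      // gap states
      int xs = NEG;
      unsigned char xt = 0;
      if (r > 0 && c + 1 < W) { // (i-1, j) in band?
        int pj = j;
        int pi = i - 1;
        if (pi - pj >= dlo && pi - pj <= dhi && pj >= s_lo && pi >= q_lo) {
          int fromM = M[prow + c + 1] > 0 ? M[prow + c + 1] - go : NEG;
          int fromX = X[prow + c + 1] > NEG ? X[prow + c + 1] - gep : NEG;
          if (fromM >= fromX) { xs = fromM; xt = TB_M; }
          else { xs = fromX; xt = TB_X; }
        }
      }
      X[row + c] = xs;
      tX[row + c] = xt;
      int ys = NEG;
      unsigned char yt = 0;
      if (c > 0 && j > s_lo) { // (i, j-1) in band?
        int fromM = M[row + c - 1] > 0 ? M[row + c - 1] - go : NEG;
        int fromY = Y[row + c - 1] > NEG ? Y[row + c - 1] - gep : NEG;
        if (fromM >= fromY) { ys = fromM; yt = TB_M; }
        else { ys = fromY; yt = TB_Y; }
      }
      Y[row + c] = ys;
      tY[row + c] = yt;
      // match state
      int sub = smv[q[i] * A + s[j]];
      int prev = 0;
      unsigned char mt = TB_START;
      if (r > 0 && c < W && j > s_lo) { // (i-1, j-1): row r-1, col c
        int pi = i - 1, pj = j - 1;
        if (pi - pj >= dlo && pi - pj <= dhi && pi >= q_lo && pj >= s_lo) {
          int pm = M[prow + c], px = X[prow + c], py = Y[prow + c];
          // tie preference: match/mismatch, then query-gap, then subject-gap
          if (pm > 0 && pm >= px && pm >= py) { prev = pm; mt = TB_M; }
          else if (px > 0 && px >= py) { prev = px; mt = TB_X; }
          else if (py > 0) { prev = py; mt = TB_Y; }
        }
      }
      int ms = sub + prev;
      M[row + c] = ms;
      tM[row + c] = mt;
      // best end cell; ties prefer smallest subject then query coordinate
      if (ms > 0 &&
          (ms > best ||
           (ms == best && (j < best_j || (j == best_j && i < best_i))))) {
        best = ms;
        best_r = r;
        best_c = c;
        best_i = i;
        best_j = j;
      }
    }
  }
  if (best <= 0 || best_r < 0) return R_NilValue;

  // traceback from the best-scoring M cell
  std::vector<char> ops;
  int r = best_r, c = best_c, state = TB_M;
  int i = q_lo + r, j = i - dhi + c;
  int q_end = i + 1, s_end = j + 1; // half-open ends
  while (true) {
    size_t row = (size_t)r * W;
    if (state == TB_M) {
      ops.push_back('M');
      unsigned char t = tM[row + c];
      if (t == TB_START) break;
      state = t;
      --r; --i; --j; // diag: col stays
    } else if (state == TB_X) { // query residue over gap
      ops.push_back('D');
      unsigned char t = tX[row + c];
      state = t;
      --r; --i; ++c;
    } else { // TB_Y: subject residue over gap
      ops.push_back('I');
      unsigned char t = tY[row + c];
      state = t;
      --c; --j;
    }
  }
  int q_start = i, s_start = j;
  std::reverse(ops.begin(), ops.end());

  // run-length encode, count stats
  std::vector<char> run_op;
  std::vector<int> run_len;
  int identities = 0, mismatches = 0, gap_open = 0, alen = (int)ops.size();
  {
    int qi = q_start, sj = s_start;
    char prev = 0;
    for (char o : ops) {
      if (o != prev) {
        run_op.push_back(o);
        run_len.push_back(0);
        if (o != 'M') ++gap_open;
      }
      run_len.back()++;
      prev = o;
      if (o == 'M') {
        if (q[qi] == s[sj]) ++identities; else ++mismatches;
        ++qi; ++sj;
      } else if (o == 'D') ++qi;
      else ++sj;
    }
  }
  CharacterVector rop(run_op.size());
  for (size_t z = 0; z < run_op.size(); ++z) rop[z] = std::string(1, run_op[z]);
  return List::create(
      _["sw_score"] = best, _["q_start"] = q_start, _["q_end"] = q_end,
      _["s_start"] = s_start, _["s_end"] = s_end,
      _["path_op"] = rop, _["path_len"] = IntegerVector(run_len.begin(), run_len.end()),
      _["identities"] = identities, _["mismatches"] = mismatches,
      _["gap_openings"] = gap_open, _["aligned_length"] = alen);
}
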