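// Seeding stage: k-tuple codes, tuple diversification, lookup-table build.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const int ALPHA = 20;

static int64_t pow20(int k) {
  int64_t r = 1;
  for (int i = 0; i < k; ++i) r *= ALPHA;
  return r;
}

// [[Rcpp::export(name = ".encode_residues_cpp")]]
IntegerVector encode_residues_cpp(std::string seq, std::string symbols) {
  // residues not in `symbols` map to NA (excluded from any k-tuple window)
  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = NA_INTEGER;
  for (size_t i = 0; i < symbols.size(); ++i)
    idx[(unsigned char)symbols[i]] = (int)i;
  IntegerVector out(seq.size());
  for (size_t i = 0; i < seq.size(); ++i)
    out[i] = idx[(unsigned char)seq[i]];
  return out;
}

// Rolling k-tuple codes for a residue-index vector; windows containing an
// invalid residue (NA) get code NA.
// [[Rcpp::export(name = ".window_codes_cpp")]]
IntegerVector window_codes_cpp(IntegerVector res, int k) {
  int n = res.size();
  int nw = n - k + 1;
  if (nw < 1) return IntegerVector(0);
  IntegerVector out(nw);
  int64_t msd = pow20(k - 1);
  int64_t code = 0;
  int valid = 0; // length of current run of valid residues ending at i
  for (int i = 0; i < n; ++i) {
    int r = res[i];
    if (r == NA_INTEGER) {
      valid = 0;
      code = 0;
    } else {
      code = (code % msd) * ALPHA + r;
      if (valid < k) ++valid;
    }
    if (i >= k - 1)
      out[i - k + 1] = (valid >= k) ? (int)code : NA_INTEGER;
  }
  return out;
}

struct DivOut {
  std::vector<int> codes;
  std::vector<int> suffix; // k values per code (column-major, k fast)
};

// DFS over the 20-way k-level trie with prefix-score + best-possible-suffix
// pruning. `t` = digits of the original tuple, `S` = real-valued threshold.
// `self_suf[p]` = self score of t[p..k-1], self_suf[k] = 0.
static void div_dfs(const int *t, int k, const int *sm, const double S,
                    const int *self_suf, int depth, int prefix_score,
                    int *digits, DivOut &out) {
  for (int r = 0; r < ALPHA; ++r) {
    int sc = prefix_score + sm[t[depth] * ALPHA + r];
    if ((double)(sc + self_suf[depth + 1]) < S) continue; // prune sub-branch
    digits[depth] = r;
    if (depth == k - 1) {
      int code = 0;
      for (int p = 0; p < k; ++p) code = code * ALPHA + digits[p];
      out.codes.push_back(code);
      int acc = 0;
      size_t base = out.suffix.size();
      out.suffix.resize(base + k);
      for (int p = k - 1; p >= 0; --p) {
        acc += sm[t[p] * ALPHA + digits[p]];
        out.suffix[base + p] = acc;
      }
    } else {
      div_dfs(t, k, sm, S, self_suf, depth + 1, sc, digits, out);
    }
  }
}

static void self_suffixes(const int *t, int k, const int *sm, int *self_suf) {
  self_suf[k] = 0;
  for (int p = k - 1; p >= 0; --p)
    self_suf[p] = self_suf[p + 1] + sm[t[p] * ALPHA + t[p]];
}

// [[Rcpp::export(name = ".diversify_tuple_cpp")]]
List diversify_tuple_cpp(IntegerVector tuple, IntegerMatrix sm, double approx) {
  int k = tuple.size();
  std::vector<int> t(tuple.begin(), tuple.end());
  std::vector<int> smv(sm.begin(), sm.end()); // column-major 20x20, symmetric
  std::vector<int> self_suf(k + 1);
  self_suffixes(t.data(), k, smv.data(), self_suf.data());
  double S = (double)self_suf[0] * approx;
  DivOut out;
  std::vector<int> digits(k);
  div_dfs(t.data(), k, smv.data(), S, self_suf.data(), 0, 0, digits.data(), out);
  int n = (int)out.codes.size();
  IntegerMatrix suf(k, n);
  std::copy(out.suffix.begin(), out.suffix.end(), suf.begin());
  return List::create(_["codes"] = IntegerVector(out.codes.begin(), out.codes.end()),
                      _["suffix_scores"] = suf,
                      _["threshold"] = S);
}

// Two-pass lookup-table build over encoded query sequences.
// Pass 1 counts exact occurrences per code, diversifies each occurring code
// and adds its exact count to every neighbour's counter; one arena of
// sum(counts) entries is then laid out. Pass 2 re-runs diversification and
// copies the exact locations (with suffix scores of key-vs-query tuple)
// into each neighbour's region.
// [[Rcpp::export(name = ".build_lookup_cpp")]]
List build_lookup_cpp(List qres, int k, double approx, IntegerMatrix sm) {
  int64_t A = pow20(k);
  int nq = qres.size();
  std::vector<int> smv(sm.begin(), sm.end());

  std::vector<int> exact((size_t)A, 0);
  std::vector<int> occurring;
  for (int q = 0; q < nq; ++q) {
    IntegerVector res = qres[q];
    IntegerVector codes = window_codes_cpp(res, k);
    for (int i = 0; i < codes.size(); ++i) {
      int c = codes[i];
      if (c == NA_INTEGER) continue;
      if (exact[c] == 0) occurring.push_back(c);
      exact[c]++;
    }
  }
  std::sort(occurring.begin(), occurring.end());

  // pass 1: diversify occurring codes, accumulate total counters
  std::vector<int> total((size_t)A, 0);
  std::vector<int> self_suf(k + 1), digits(k), t(k);
  int64_t N = 0;
  for (int c : occurring) {
    int cc = c;
    for (int p = k - 1; p >= 0; --p) { t[p] = cc % ALPHA; cc /= ALPHA; }
    self_suffixes(t.data(), k, smv.data(), self_suf.data());
    double S = (double)self_suf[0] * approx;
    DivOut out;
    div_dfs(t.data(), k, smv.data(), S, self_suf.data(), 0, 0, digits.data(), out);
    for (int nb : out.codes) total[nb] += exact[c];
    N += (int64_t)out.codes.size() * exact[c];
  }
  if (N > INT32_MAX) stop("lookup table too large (>2^31 entries)");

  // arena layout: offsets[c] .. offsets[c+1]-1 is code c's region
  IntegerVector offsets((R_xlen_t)(A + 1));
  int64_t run = 0;
  for (int64_t c = 0; c < A; ++c) {
    offsets[c] = (int)run;
    run += total[c];
  }
  offsets[A] = (int)run;
  std::vector<int> cursor(total.size());
  for (int64_t c = 0; c < A; ++c) cursor[c] = offsets[c];

  IntegerVector e_q((int)N), e_off((int)N);
  IntegerMatrix e_suf(k, (int)N);
  int *sufp = e_suf.begin();

  // collect exact locations per occurring code (ordered by code for
  // deterministic region content)
  std::vector<std::vector<std::pair<int, int>>> occ_locs(occurring.size());
  {
    std::vector<int> rank((size_t)A, -1);
    for (size_t i = 0; i < occurring.size(); ++i) rank[occurring[i]] = (int)i;
    for (int q = 0; q < nq; ++q) {
      IntegerVector res = qres[q];
      IntegerVector codes = window_codes_cpp(res, k);
      for (int i = 0; i < codes.size(); ++i) {
        int c = codes[i];
        if (c == NA_INTEGER) continue;
        occ_locs[rank[c]].push_back(std::make_pair(q, i));
      }
    }
  }

  // pass 2: re-diversify and copy locations into neighbour regions
  for (size_t oi = 0; oi < occurring.size(); ++oi) {
    int c = occurring[oi];
    int cc = c;
    for (int p = k - 1; p >= 0; --p) { t[p] = cc % ALPHA; cc /= ALPHA; }
    self_suffixes(t.data(), k, smv.data(), self_suf.data());
    double S = (double)self_suf[0] * approx;
    DivOut out;
    div_dfs(t.data(), k, smv.data(), S, self_suf.data(), 0, 0, digits.data(), out);
    for (size_t j = 0; j < out.codes.size(); ++j) {
      int nb = out.codes[j];
      const int *sufsrc = out.suffix.data() + j * k;
      for (const auto &loc : occ_locs[oi]) {
        int pos = cursor[nb]++;
        e_q[pos] = loc.first;
        e_off[pos] = loc.second;
        std::copy(sufsrc, sufsrc + k, sufp + (size_t)pos * k);
      }
    }
  }
  for (int64_t c = 0; c < A; ++c)
    if (cursor[c] != offsets[c + 1]) stop("internal error: arena region not exactly filled");

  int64_t n_exact = 0;
  for (int c : occurring) n_exact += exact[c];

  return List::create(_["offsets"] = offsets, _["entry_query"] = e_q,
                      _["entry_offset"] = e_off, _["entry_suffix"] = e_suf,
                      _["total_entries"] = (double)N,
                      _["exact_entries"] = (double)n_exact);
}
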