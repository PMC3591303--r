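// Inner search loop: per-subject streaming of k-tuple hits into diagonal
// similarity zones, with lazy invalidation of diagonal state across
// subjects, lateral zone merging within mxshift diagonals, and a hits
// array of zones that ever crossed the detection threshold.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

struct Zone {
  int diag_lo, diag_hi;  // global diagonal bounds (inclusive)
  int subj_lo, subj_hi;  // subject-offset bounds (inclusive)
  int best;              // maximal cumulative match score achieved
  int query;             // query sequence index (0-based)
  bool skip;             // obsolete (merged away)
  int hit;               // index in hits array, -1 = sentinel
};

struct SearchContext {
  // lookup table (shared with R side; kept alive by the R wrapper object)
  IntegerVector offsets, e_q, e_off;
  IntegerMatrix e_suf;
  int k;
  // query catalog
  std::vector<int> qstart; // global start offset per query, + total at end
  std::vector<int> qlen;
  // parameters
  int msl, kthresh, mxshift, gip, gep;
  size_t max_zones, max_hits;
  // per-diagonal running state (lazy invalidation via d_subj)
  std::vector<int> d_last, d_score, d_zone, d_subj, d_query;
  std::vector<Zone> zones;
  std::vector<int> hits;
  bool zone_warned, hits_warned;
};

static inline int gap_pen(int len, int gip, int gep) {
  return len <= 0 ? 0 : gip + gep * len;
}

// [[Rcpp::export(name = ".new_search_context_cpp")]]
SEXP new_search_context_cpp(List table_core, IntegerVector qlens, int k,
                            int msl, int kthresh, int mxshift, int gip,
                            int gep, double max_zones, double max_hits) {
  SearchContext *ctx = new SearchContext();
  ctx->offsets = as<IntegerVector>(table_core["offsets"]);
  ctx->e_q = as<IntegerVector>(table_core["entry_query"]);
  ctx->e_off = as<IntegerVector>(table_core["entry_offset"]);
  ctx->e_suf = as<IntegerMatrix>(table_core["entry_suffix"]);
  ctx->k = k;
  ctx->msl = msl;
  ctx->kthresh = kthresh;
  ctx->mxshift = mxshift;
  ctx->gip = gip;
  ctx->gep = gep;
  ctx->max_zones = (size_t)max_zones;
  ctx->max_hits = (size_t)max_hits;
  int nq = qlens.size();
  ctx->qstart.resize(nq + 1);
  ctx->qlen.resize(nq);
  int run = 0;
  for (int q = 0; q < nq; ++q) {
    ctx->qstart[q] = run;
    ctx->qlen[q] = qlens[q];
    run += qlens[q];
  }
  ctx->qstart[nq] = run;
  size_t ndiag = (size_t)run + (size_t)msl;
  ctx->d_last.assign(ndiag, 0);
  ctx->d_score.assign(ndiag, 0);
  ctx->d_zone.assign(ndiag, -1);
  ctx->d_subj.assign(ndiag, -1);
  ctx->d_query.assign(ndiag, -1);
  ctx->zone_warned = ctx->hits_warned = false;
  XPtr<SearchContext> p(ctx, true);
  return p;
}

// distance between two closed integer intervals (0 if they overlap)
static inline int ivl_dist(int alo, int ahi, int blo, int bhi) {
  if (ahi < blo) return blo - ahi;
  if (bhi < alo) return alo - bhi;
  return 0;
}

static inline int ivl_overlap(int alo, int ahi, int blo, int bhi) {
  int lo = alo > blo ? alo : blo;
  int hi = ahi < bhi ? ahi : bhi;
  return hi >= lo ? hi - lo + 1 : 0;
}

// score of merging two zones: sum of best scores with the smaller zone
// prorated by its non-overlapping subject fraction, minus an affine gap
// penalty on the diagonal distance
static double merge_estimate(const Zone &a, const Zone &b, int gip, int gep) {
  int la = a.subj_hi - a.subj_lo + 1, lb = b.subj_hi - b.subj_lo + 1;
  int v = ivl_overlap(a.subj_lo, a.subj_hi, b.subj_lo, b.subj_hi);
  double sa = a.best, sb = b.best;
  if (la <= lb)
    sa *= (1.0 - (double)v / la);
  else
    sb *= (1.0 - (double)v / lb);
  int dg = ivl_dist(a.diag_lo, a.diag_hi, b.diag_lo, b.diag_hi);
  return sa + sb - gap_pen(dg, gip, gep);
}

static void record_hit(SearchContext *ctx, int zi, int score) {
  Zone &z = ctx->zones[zi];
  if (score < ctx->kthresh || z.hit >= 0) return;
  if (ctx->hits.size() >= ctx->max_hits) {
    if (!ctx->hits_warned) {
      Rf_warning("hits array exhausted; further hits not recorded");
      ctx->hits_warned = true;
    }
    return;
  }
  z.hit = (int)ctx->hits.size();
  ctx->hits.push_back(zi);
}

// [[Rcpp::export(name = ".scan_subject_cpp")]]
DataFrame scan_subject_cpp(SEXP ctxp, IntegerVector scodes, int subj_len,
                           int subj_idx) {
  XPtr<SearchContext> ctx(ctxp);
  const int k = ctx->k;
  if (subj_len > ctx->msl)
    stop("subject longer than max_subject_len (%d > %d)", subj_len, ctx->msl);
  const int msl = ctx->msl;
  const int *off = ctx->offsets.begin();
  const int *eq = ctx->e_q.begin();
  const int *eo = ctx->e_off.begin();
  const int *es = ctx->e_suf.begin();

  // per-subject reset of arena fill counters (diagonal state persists,
  // invalidated lazily through the stored subject index)
  ctx->zones.clear();
  ctx->hits.clear();

  for (int soff = 0; soff < scodes.size(); ++soff) {
    int code = scodes[soff];
    if (code == NA_INTEGER) continue;
    for (int ei = off[code]; ei < off[code + 1]; ++ei) {
      int q = eq[ei];
      int qoff = eo[ei];
      const int *suf = es + (size_t)ei * k;
      int64_t g64 = (int64_t)ctx->qstart[q] + qoff - soff + msl;
      int g = (int)g64;
      bool fresh = !(ctx->d_subj[g] == subj_idx && ctx->d_query[g] == q &&
                     ctx->d_zone[g] >= 0);
      int zi = -1, newscore = 0;
      if (!fresh) {
        // same query/subject pair, active zone on this diagonal
        zi = ctx->d_zone[g];
        Zone &z = ctx->zones[zi];
        int d = soff - ctx->d_last[g];
        int ext;
        if (d < k) // overlapping match: add pre-computed suffix score
          ext = ctx->d_score[g] + suf[k - d];
        else
          ext = ctx->d_score[g] + suf[0] - gap_pen(d - k, ctx->gip, ctx->gep);
        if (ext > 0) {
          if (soff < z.subj_lo) z.subj_lo = soff;
          if (soff + k - 1 > z.subj_hi) z.subj_hi = soff + k - 1;
          if (ext > z.best) z.best = ext;
          newscore = ext;
        } else {
          fresh = true; // previous zone stays active; start anew here
        }
      }
      if (fresh) {
        if (ctx->zones.size() >= ctx->max_zones) {
          if (!ctx->zone_warned) {
            Rf_warning("zone arena exhausted; further zones not recorded");
            ctx->zone_warned = true;
          }
          continue;
        }
        Zone z;
        z.diag_lo = z.diag_hi = g;
        z.subj_lo = soff;
        z.subj_hi = soff + k - 1;
        z.best = suf[0];
        z.query = q;
        z.skip = false;
        z.hit = -1;
        zi = (int)ctx->zones.size();
        ctx->zones.push_back(z);
        newscore = suf[0];
      }
      ctx->d_last[g] = soff;
      ctx->d_score[g] = newscore;
      ctx->d_zone[g] = zi;
      ctx->d_subj[g] = subj_idx;
      ctx->d_query[g] = q;
      record_hit(ctx, zi, newscore);

      // lateral merge across up to mxshift adjacent diagonals
      for (int dir = -1; dir <= 1; dir += 2) {
        for (int sh = 1; sh <= ctx->mxshift; ++sh) {
          int64_t gg = g64 + (int64_t)dir * sh;
          if (gg < 0 || gg >= (int64_t)ctx->d_zone.size()) break;
          if (ctx->d_subj[gg] != subj_idx || ctx->d_query[gg] != q) continue;
          int zj = ctx->d_zone[gg];
          if (zj < 0 || zj == zi) continue;
          Zone &za = ctx->zones[zi];
          Zone &zb = ctx->zones[zj];
          if (zb.skip) continue;
          double est = merge_estimate(za, zb, ctx->gip, ctx->gep);
          if (est <= 0) continue;
          int surv = zi < zj ? zi : zj, obs = zi < zj ? zj : zi;
          Zone &zs = ctx->zones[surv];
          Zone &zo = ctx->zones[obs];
          int olo = zo.diag_lo, ohi = zo.diag_hi;
          if (zo.diag_lo < zs.diag_lo) zs.diag_lo = zo.diag_lo;
          if (zo.diag_hi > zs.diag_hi) zs.diag_hi = zo.diag_hi;
          if (zo.subj_lo < zs.subj_lo) zs.subj_lo = zo.subj_lo;
          if (zo.subj_hi > zs.subj_hi) zs.subj_hi = zo.subj_hi;
          int iest = (int)est;
          if (zo.best > zs.best) zs.best = zo.best;
          if (iest > zs.best) zs.best = iest;
          zo.skip = true;
          // re-point diagonal entries of the obsolete zone to the survivor
          for (int d2 = olo; d2 <= ohi; ++d2) {
            if (ctx->d_subj[d2] == subj_idx && ctx->d_query[d2] == q &&
                ctx->d_zone[d2] == obs)
              ctx->d_zone[d2] = surv;
          }
          record_hit(ctx, surv, zs.best);
          zi = surv;
        }
      }
    }
  }

  // emit zones listed in the hits array whose skip flag is clear
  std::vector<int> out_zi;
  for (int zi : ctx->hits)
    if (!ctx->zones[zi].skip) out_zi.push_back(zi);
  int n = (int)out_zi.size();
  IntegerVector r_zone(n), r_query(n), r_dlo(n), r_dhi(n), r_slo(n), r_shi(n),
      r_qlo(n), r_qhi(n), r_score(n);
  for (int i = 0; i < n; ++i) {
    const Zone &z = ctx->zones[out_zi[i]];
    int qs = ctx->qstart[z.query], ql = ctx->qlen[z.query];
    // local query bounds implied by diagonal+subject bounds, clipped
    int qlo = z.diag_lo - msl + z.subj_lo - qs;
    int qhi = z.diag_hi - msl + z.subj_hi - qs;
    if (qlo < 0) qlo = 0;
    if (qhi > ql - 1) qhi = ql - 1;
    r_zone[i] = out_zi[i];
    r_query[i] = z.query + 1;
    r_dlo[i] = z.diag_lo - msl - qs; // local diagonal = qpos_local - soff
    r_dhi[i] = z.diag_hi - msl - qs;
    r_slo[i] = z.subj_lo;
    r_shi[i] = std::min(z.subj_hi, subj_len - 1);
    r_qlo[i] = qlo;
    r_qhi[i] = qhi;
    r_score[i] = z.best;
  }
  return DataFrame::create(
      _["zone_id"] = r_zone, _["query"] = r_query, _["diag_lo"] = r_dlo,
      _["diag_hi"] = r_dhi, _["s_lo"] = r_slo, _["s_hi"] = r_shi,
      _["q_lo"] = r_qlo, _["q_hi"] = r_qhi, _["score"] = r_score);
}
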