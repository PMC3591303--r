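# Post-processing of alignments: filters, remote-segment chaining, ranking.
#
# All stages operate on a "hits" data frame with one row per alignment:
# query_id, subject_id, sw_score, q_start, q_end, s_start, s_end (0-based
# half-open), identities, mismatches, gap_openings, aligned_length, qaln,
# saln, n_members; statistics add evalue and bit. Filter and merge stages
# never alter a member alignment's coordinates or score - they only group,
# drop or chain rows.

empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             sw_score = numeric(0), q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             identities = integer(0), mismatches = integer(0),
             gap_openings = integer(0), aligned_length = integer(0),
             qaln = character(0), saln = character(0),
             n_members = integer(0), stringsAsFactors = FALSE)
}

#' Alignment score filter
#'
#' Keeps alignments with `sw_score >= min_score`. Applied after accurate
#' Smith-Waterman scores are available, so it is more reliable than the
#' zone-score gates earlier in the pipeline.
#'
#' @param alignments Hits data frame.
#' @param min_score Minimal score kept.
#' @export
filter_by_score <- function(alignments, min_score) {
  alignments[alignments$sw_score >= min_score, , drop = FALSE]
}

#' Long-repeat filter
#'
#' Detects when multiple similarities between one query/subject pair are
#' caused by repeats: alignments whose query intervals mutually overlap by
#' at least half of the shorter interval while their subject intervals are
#' disjoint (or the symmetric case) form a conflict group, and only the
#' top-scoring member of each group survives. Alignments disjoint in both
#' sequences (e.g. the two domains of a fusion protein) are never grouped.
#'
#' @param alignments Hits data frame for one query/subject pair.
#' @export
filter_long_repeats <- function(alignments) {
  n <- nrow(alignments)
  if (n <= 1L) return(alignments)
  olap <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1))
  comp <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    qo <- olap(alignments$q_start[i], alignments$q_end[i],
               alignments$q_start[j], alignments$q_end[j])
    so <- olap(alignments$s_start[i], alignments$s_end[i],
               alignments$s_start[j], alignments$s_end[j])
    qlen <- min(alignments$q_end[i] - alignments$q_start[i],
                alignments$q_end[j] - alignments$q_start[j])
    slen <- min(alignments$s_end[i] - alignments$s_start[i],
                alignments$s_end[j] - alignments$s_start[j])
    conflict <- (qo >= 0.5 * qlen && so == 0L) || (so >= 0.5 * slen && qo == 0L)
    if (conflict) comp[comp == comp[j]] <- comp[i]
  }
  keep <- unlist(lapply(split(seq_len(n), comp), function(ix) {
    ix[order(-alignments$sw_score[ix], ix)][1L]
  }))
  alignments[sort(keep), , drop = FALSE]
}

#' Remote-segment merger
#'
#' Chains collinear alignment segments of one query/subject pair into
#' super-alignments by dynamic programming over segments sorted by query
#' start: segment j may follow i only when both its query and subject
#' intervals start at or after i's ends, and the bridge costs
#' `affine_gap_penalty(max(q_gap, s_gap))`. A link is taken only when it
#' improves on leaving the segments separate; the output chains partition
#' the input segments. Member coordinates and scores are never modified;
#' a chained row carries the combined score, the overall spans, summed
#' identity statistics and `n_members > 1`.
#'
#' @param alignments Hits data frame for one query/subject pair.
#' @param params A `zs_params` (gap penalties).
#' @export
merge_remote_segments <- function(alignments, params = search_params()) {
  n <- nrow(alignments)
  if (n <= 1L) return(alignments)
  a <- alignments[order(alignments$q_start, alignments$s_start), , drop = FALSE]
  used <- rep(FALSE, n)
  chains <- list()
  repeat {
    idx <- which(!used)
    if (!length(idx)) break
    dp <- a$sw_score[idx]
    back <- rep(NA_integer_, length(idx))
    for (jj in seq_along(idx)) {
      j <- idx[jj]
      for (ii in seq_len(jj - 1L)) {
        i <- idx[ii]
        if (a$q_start[j] < a$q_end[i] || a$s_start[j] < a$s_end[i]) next
        bridge <- affine_gap_penalty(max(a$q_start[j] - a$q_end[i],
                                         a$s_start[j] - a$s_end[i]), params)
        cand <- dp[ii] - bridge + a$sw_score[j]
        if (cand > dp[jj]) {
          dp[jj] <- cand
          back[jj] <- ii
        }
      }
    }
    best <- which.max(dp)
    chain <- best
    while (!is.na(back[chain[1L]])) chain <- c(back[chain[1L]], chain)
    chains[[length(chains) + 1L]] <- list(rows = idx[chain], score = dp[best])
    used[idx[chain]] <- TRUE
  }
  out <- lapply(chains, function(ch) {
    zz <- a[ch$rows, , drop = FALSE]
    if (nrow(zz) == 1L) return(zz)
    data.frame(query_id = zz$query_id[1L], subject_id = zz$subject_id[1L],
               sw_score = ch$score,
               q_start = min(zz$q_start), q_end = max(zz$q_end),
               s_start = min(zz$s_start), s_end = max(zz$s_end),
               identities = sum(zz$identities), mismatches = sum(zz$mismatches),
               gap_openings = sum(zz$gap_openings) + nrow(zz) - 1L,
               aligned_length = sum(zz$aligned_length),
               qaln = paste(zz$qaln, collapse = "----"),
               saln = paste(zz$saln, collapse = "----"),
               n_members = sum(zz$n_members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$q_start, out$s_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank hits and truncate per query
#'
#' Sorts each query's hits by ascending E-value (ties: descending score,
#' then subject id) and keeps at most `rpq` of them.
#'
#' @param hits Hits data frame with `evalue` present.
#' @param params A `zs_params` (uses `rpq`).
#' @export
rank_and_report <- function(hits, params = search_params()) {
  if (nrow(hits) == 0L) return(hits)
  grp <- factor(hits$query_id, levels = unique(hits$query_id))
  out <- do.call(rbind, lapply(split(hits, grp), function(h) {
    h <- h[order(h$evalue, -h$sw_score, h$subject_id), , drop = FALSE]
    head(h, params$rpq)
  }))
  rownames(out) <- NULL
  out
}
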