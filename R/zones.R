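# Similarity-zone search: streaming subjects against the lookup table.

#' Search parameters
#'
#' Bundles the tunable parameters of the search with validated defaults.
#'
#' @param k Tuple size (3..6).
#' @param approx Tuple diversification threshold, fraction of the
#'   occurring tuple's self-match score, in (0, 1].
#' @param kthresh Zone detection threshold (score units): minimal
#'   accumulated zone score that triggers downstream processing.
#' @param mxshift Maximum number of adjacent diagonals searched in each
#'   direction when merging zones laterally.
#' @param gip,gep Affine gap initiation and extension penalties (positive
#'   score units); a gap of length L costs `gip + gep * L`.
#' @param max_subject_len Longest subject sequence supported (residues);
#'   sets the size of the pre-allocated diagonal array.
#' @param band_extension Residues added around a finished zone before
#'   banded alignment.
#' @param rpq Maximum results reported per query.
#' @param min_score Alignment score filter threshold (0 disables).
#' @param evalue_cutoff Maximum E-value reported.
#' @param max_zones,max_hits Arena capacities for zones and hits per
#'   subject; exhaustion degrades gracefully with a warning.
#' @param repeat_filter,merge_remote Enable the long-repeat filter and the
#'   remote-segment merger in [run_search()].
#' @return A list of class `zs_params`.
#' @export
search_params <- function(k = 5L, approx = 0.85, kthresh = 18L, mxshift = 3L,
                          gip = 11L, gep = 1L, max_subject_len = 50000L,
                          band_extension = 16L, rpq = 100L, min_score = 0L,
                          evalue_cutoff = 10, max_zones = 2e6,
                          max_hits = 65536, repeat_filter = FALSE,
                          merge_remote = FALSE) {
  p <- list(k = as.integer(k), approx = approx, kthresh = as.integer(kthresh),
            mxshift = as.integer(mxshift), gip = as.integer(gip),
            gep = as.integer(gep), max_subject_len = as.integer(max_subject_len),
            band_extension = as.integer(band_extension), rpq = as.integer(rpq),
            min_score = as.integer(min_score), evalue_cutoff = evalue_cutoff,
            max_zones = max_zones, max_hits = max_hits,
            repeat_filter = isTRUE(repeat_filter),
            merge_remote = isTRUE(merge_remote))
  if (p$k < 3L || p$k > 6L) stop("k (ksize) must be in 3..6")
  if (!is.numeric(approx) || approx <= 0 || approx > 1)
    stop("approx must be in (0, 1]")
  if (p$kthresh <= 0L) stop("kthresh must be > 0")
  if (p$mxshift < 0L) stop("mxshift must be >= 0")
  if (p$gip < 0L || p$gep < 0L) stop("gap penalties must be >= 0")
  if (p$max_subject_len < 1L) stop("max_subject_len must be positive")
  if (p$rpq < 1L) stop("rpq must be >= 1")
  class(p) <- "zs_params"
  p
}

#' Diagonal index of a match
#'
#' All cells on one alignment diagonal share the index
#' `query_global_offset - subject_offset + max_subject_len`, where the
#' query offset is taken in the concatenation of all query sequences. The
#' diagonal array therefore has `total_query_length + max_subject_len`
#' entries.
#'
#' @param query_global_offset 0-based position in the concatenated queries.
#' @param subject_offset 0-based position in the subject.
#' @param max_subject_len Pre-allocated maximal subject length.
#' @return Integer diagonal index.
#' @export
diagonal_index <- function(query_global_offset, subject_offset,
                           max_subject_len = 50000L) {
  if (any(query_global_offset < 0) || any(subject_offset < 0))
    stop("offsets must be non-negative")
  if (any(subject_offset >= max_subject_len))
    stop("subject offset exceeds max_subject_len")
  as.integer(query_global_offset - subject_offset + max_subject_len)
}

#' Affine gap penalty
#'
#' Cost of a gap (or inter-zone separation): 0 for length 0, otherwise
#' `gip + gep * length`.
#'
#' @param length Gap length in residues or diagonals (>= 0).
#' @param params A `zs_params` (only `gip`, `gep` are used).
#' @export
affine_gap_penalty <- function(length, params = search_params()) {
  if (any(length < 0)) stop("gap length must be >= 0")
  ifelse(length == 0, 0L, params$gip + params$gep * as.integer(length))
}

#' Create a streaming search context
#'
#' Allocates the per-diagonal running state and the zone/hit arenas once,
#' for reuse across subject sequences. Diagonal entries are invalidated
#' lazily (by comparing their stored subject index with the current one),
#' so no per-subject clearing of the diagonal array is needed.
#'
#' @param table A `zs_lookup`.
#' @param params A `zs_params`; its `k` and `approx` must match the table.
#' @return A `zs_context` wrapping an external pointer.
#' @export
new_search_context <- function(table, params = search_params()) {
  stopifnot(inherits(table, "zs_lookup"))
  if (params$k != table$k)
    stop("params$k does not match the lookup table")
  ptr <- .new_search_context_cpp(table$core, table$query_lengths, table$k,
                                 params$max_subject_len, params$kthresh,
                                 params$mxshift, params$gip, params$gep,
                                 params$max_zones, params$max_hits)
  structure(list(ptr = ptr, table = table, params = params,
                 n_scanned = new.env(parent = emptyenv())),
            class = "zs_context")
}

#' Scan one subject sequence
#'
#' Runs the full inner loop for one subject: every subject k-tuple is
#' looked up, each entry updates its diagonal's similarity zone (new match,
#' overlap-corrected extension, or fresh zone), lateral merges across up to
#' `mxshift` adjacent diagonals are attempted after every update, and zones
#' crossing `kthresh` are recorded in the hits array. After the subject is
#' consumed, the surviving hit zones are clustered by single linkage
#' ([cluster_zones()]) and the merged zones are returned.
#'
#' @param subject A residue string (or single-row sequence set).
#' @param table A `zs_lookup`; ignored when `context` is given.
#' @param params A `zs_params`; ignored when `context` is given.
#' @param context Optional `zs_context` for streaming many subjects; when
#'   `NULL` a fresh context is created for this call.
#' @param subject_index Integer identity of the subject within the stream;
#'   distinct subjects must carry distinct indices (defaults to an
#'   auto-incremented counter of the context).
#' @param cluster Run [cluster_zones()] on the hit zones (default); set to
#'   `FALSE` to inspect the raw per-diagonal zones before single-linkage
#'   clustering.
#' @return A data frame of merged zones with columns `query` (1-based),
#'   `q_lo`, `q_hi`, `s_lo`, `s_hi` (0-based inclusive), `diag_lo`,
#'   `diag_hi` (query-local diagonals) and `score`, plus attribute
#'   `zones_created`.
#' @export
scan_subject <- function(subject, table = NULL, params = search_params(),
                         context = NULL, subject_index = NULL,
                         cluster = TRUE) {
  if (is.null(context)) context <- new_search_context(table, params)
  params <- context$params
  table <- context$table
  seq <- as_seqset(subject)$seq[1L]
  if (nchar(seq) > params$max_subject_len)
    stop("subject longer than max_subject_len")
  if (is.null(subject_index)) {
    n <- get0("n", envir = context$n_scanned, ifnotfound = 0L)
    subject_index <- n + 1L
    assign("n", subject_index, envir = context$n_scanned)
  }
  res <- encode_residues(seq, table$matrix$symbols)
  codes <- .window_codes_cpp(res, table$k)
  raw <- .scan_subject_cpp(context$ptr, codes, nchar(seq), as.integer(subject_index))
  zones_created <- nrow(raw)
  merged <- if (cluster) cluster_zones(raw, params) else raw
  attr(merged, "zones_created") <- zones_created
  merged
}

#' Single-linkage clustering of similarity zones
#'
#' Zones on the same query (and one subject) are linked when the sum of
#' their scores, prorated for overlapping fractions, exceeds the affine
#' gap penalty on the minimal diagonal distance between them by more than
#' the better member alone - i.e. when the merged zone is properly
#' arranged to yield a better single alignment than either zone by itself.
#' The proration scales the lower-scoring zone by its largest overlap
#' fraction across the query and subject projections, so alternative
#' placements of the same region (repeat copies) never satisfy the link.
#' Connected components are computed by transitive closure and each
#' component is merged into its first (lowest arena index) zone: bounds are
#' unioned and the combined score accumulates members in subject order,
#' each prorated for subject overlap with the zones already merged and
#' charged the gap penalty to its nearest predecessor.
#'
#' @param zones Data frame of zones as returned by the raw scan (columns
#'   `zone_id`, `query`, `diag_lo`, `diag_hi`, `s_lo`, `s_hi`, `q_lo`,
#'   `q_hi`, `score`).
#' @param params A `zs_params`.
#' @return Data frame of merged zones (same columns).
#' @export
cluster_zones <- function(zones, params = search_params()) {
  n <- nrow(zones)
  if (n <= 1L) return(zones)
  zones <- zones[order(zones$zone_id), , drop = FALSE]
  comp <- seq_len(n)
  dist_ivl <- function(alo, ahi, blo, bhi)
    pmax(0L, pmax(blo - ahi, alo - bhi))
  olap_ivl <- function(alo, ahi, blo, bhi)
    pmax(0L, pmin(ahi, bhi) - pmax(alo, blo) + 1L)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (zones$query[i] != zones$query[j]) next
    if (comp[i] == comp[j]) next
    dg <- dist_ivl(zones$diag_lo[i], zones$diag_hi[i],
                   zones$diag_lo[j], zones$diag_hi[j])
    vs <- olap_ivl(zones$s_lo[i], zones$s_hi[i], zones$s_lo[j], zones$s_hi[j])
    vq <- olap_ivl(zones$q_lo[i], zones$q_hi[i], zones$q_lo[j], zones$q_hi[j])
    si <- zones$score[i]; sj <- zones$score[j]
    # prorate the weaker zone by its largest overlap fraction
    w <- if (si <= sj) i else j
    frac <- max(vs / (zones$s_hi[w] - zones$s_lo[w] + 1L),
                vq / (zones$q_hi[w] - zones$q_lo[w] + 1L))
    adj <- min(si, sj) * (1 - frac)
    if (max(si, sj) + adj - affine_gap_penalty(dg, params) > max(si, sj)) {
      comp[comp == comp[j]] <- comp[i] # transitive closure of the link
    }
  }
  out <- lapply(split(seq_len(n), comp), function(ix) {
    zz <- zones[ix, , drop = FALSE]
    if (nrow(zz) == 1L) return(zz)
    zz_s <- zz[order(zz$s_lo, zz$zone_id), , drop = FALSE]
    # combined score: subject-ordered accumulation with overlap proration
    acc <- zz_s$score[1L]
    cov_lo <- zz_s$s_lo[1L]; cov_hi <- zz_s$s_hi[1L]
    for (r in 2L:nrow(zz_s)) {
      v <- olap_ivl(cov_lo, cov_hi, zz_s$s_lo[r], zz_s$s_hi[r])
      len <- zz_s$s_hi[r] - zz_s$s_lo[r] + 1L
      dg <- min(dist_ivl(zz_s$diag_lo[seq_len(r - 1L)], zz_s$diag_hi[seq_len(r - 1L)],
                         zz_s$diag_lo[r], zz_s$diag_hi[r]))
      acc <- acc + zz_s$score[r] * max(0, 1 - v / len) -
        affine_gap_penalty(dg, params)
      cov_lo <- min(cov_lo, zz_s$s_lo[r]); cov_hi <- max(cov_hi, zz_s$s_hi[r])
    }
    first <- which.min(zz$zone_id)
    data.frame(zone_id = zz$zone_id[first], query = zz$query[first],
               diag_lo = min(zz$diag_lo), diag_hi = max(zz$diag_hi),
               s_lo = min(zz$s_lo), s_hi = max(zz$s_hi),
               q_lo = min(zz$q_lo), q_hi = max(zz$q_hi),
               score = max(acc, max(zz$score)))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$zone_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
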