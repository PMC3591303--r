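# Direct-addressed query index over diversified k-tuples.

#' Diversify a k-tuple into its scoring neighbourhood
#'
#' Enumerates every k-tuple whose match score against `t` is at least
#' `approx * tuple_self_score(t)`, by depth-first traversal of the 20-way
#' k-level trie. A branch is abandoned as soon as the score of the prefix
#' seen so far plus the best possible (self-matching) remainder of the
#' original tuple drops below the threshold, which is safe because
#' self-match scores are row maxima. Ties at the threshold are included.
#'
#' @param t Tuple: residue string, or integer code together with `k`.
#' @param m A `zs_matrix` (or matrix name).
#' @param approx Diversification threshold, a fraction in (0, 1].
#' @param k Tuple length when `t` is a code.
#' @return A list with `codes` (integer vector of neighbour tuple codes,
#'   always containing `t` itself), `suffix_scores` (k x n integer matrix;
#'   column j holds the suffix match scores of neighbour j against `t`,
#'   row 1 being the full-tuple match score) and `threshold` (the
#'   real-valued score cutoff `S`).
#' @examples
#' nb <- diversify_tuple("ACDEF", load_matrix("BLOSUM62"), 0.9)
#' length(nb$codes)
#' @export
diversify_tuple <- function(t, m, approx, k = NULL) {
  m <- as_zs_matrix(m)
  if (!is.numeric(approx) || length(approx) != 1L || approx <= 0 || approx > 1)
    stop("approx must be a fraction in (0, 1]")
  if (is.null(k)) {
    if (!is.character(t)) stop("k is required when t is an integer code")
    k <- nchar(t)
  }
  d <- tuple_digits(t, k, m$symbols)
  .diversify_tuple_cpp(d, m$scores, approx)
}

#' Build the query lookup table
#'
#' Indexes a set of query sequences for the scan stage. The table is
#' direct-addressed: the base-20 code of a k-tuple is its offset, and each
#' code maps to a contiguous region of one shared entry arena holding the
#' query locations of all sufficiently similar tuples, each with the
#' pre-computed suffix match scores of the key tuple against the occurring
#' query tuple.
#'
#' The build runs in two passes over the queries: the first counts exact
#' occurrences per code and, after diversifying every occurring code, adds
#' its count to each neighbour's counter so a single arena of exactly the
#' right size can be allocated and partitioned; the second records the
#' locations and re-runs the diversification to copy them (with suffix
#' scores) into the neighbours' regions. Every region ends exactly full.
#'
#' Any k-tuple containing a residue outside the 20-letter alphabet (B, Z,
#' X, U, `*`, ...) contributes no entries and is never looked up.
#'
#' @param queries Query sequences: a character vector (optionally named by
#'   id), or a data frame with columns `id` and `seq` as returned by
#'   [read_fasta()].
#' @param m A `zs_matrix` or matrix name (default `"BLOSUM62"`).
#' @param k Tuple size, 3..6. Memory for the direct-addressed index grows
#'   as `20^k` (about 13 MB of counters at k = 5, 256 MB at k = 6).
#' @param approx Diversification threshold in (0, 1].
#' @return An object of class `zs_lookup`.
#' @examples
#' qs <- random_proteome(3, 80, seed = 1)
#' lt <- build_lookup_table(qs, "BLOSUM62", k = 5, approx = 0.9)
#' lt$total_entries
#' @export
build_lookup_table <- function(queries, m = "BLOSUM62", k = 5L, approx = 0.85) {
  m <- as_zs_matrix(m)
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k > 6L) stop("k must be in 3..6")
  if (!is.numeric(approx) || approx <= 0 || approx > 1)
    stop("approx must be a fraction in (0, 1]")
  seqs <- as_seqset(queries)
  if (nrow(seqs) == 0L) stop("empty query set")
  if (any(!nzchar(seqs$seq))) stop("empty query sequence")
  enc <- lapply(seqs$seq, encode_residues, symbols = m$symbols)
  core <- .build_lookup_cpp(enc, k, approx, m$scores)
  structure(list(
    k = k, approx = approx, matrix = m,
    query_ids = seqs$id,
    query_lengths = nchar(seqs$seq),
    query_seqs = seqs$seq,
    core = core,
    total_entries = core$total_entries,
    exact_entries = core$exact_entries
  ), class = "zs_lookup")
}

#' @export
print.zs_lookup <- function(x, ...) {
  cat("<zs_lookup> k =", x$k, " approx =", x$approx, " matrix =",
      x$matrix$name, "\n  ", length(x$query_ids), "queries,",
      format(x$total_entries, big.mark = ","), "entries (",
      format(x$exact_entries, big.mark = ","), "exact )\n")
  invisible(x)
}

#' Look up a k-tuple in the table
#'
#' Constant-time direct-addressed access to the entry region of a tuple
#' code. Entry order within a region is unspecified.
#'
#' @param table A `zs_lookup`.
#' @param t Residue string or integer code.
#' @return A list with `query` (1-based query index), `offset` (0-based
#'   tuple start in that query) and `suffix_scores` (k x n integer matrix,
#'   row 1 = full-tuple match score of the looked-up tuple against the
#'   stored query tuple). All vectors have length 0 for codes with no
#'   neighbours in the queries.
#' @export
lookup <- function(table, t) {
  stopifnot(inherits(table, "zs_lookup"))
  code <- if (is.character(t)) encode_tuple(t, table$matrix$symbols) else as.integer(t)
  if (is.na(code) || code < 0L || code >= 20^table$k)
    stop("tuple code out of range [0, 20^k)")
  lo <- table$core$offsets[code + 1L]
  hi <- table$core$offsets[code + 2L]
  idx <- if (hi > lo) (lo + 1L):hi else integer(0)
  list(query = table$core$entry_query[idx] + 1L,
       offset = table$core$entry_offset[idx],
       suffix_scores = table$core$entry_suffix[, idx, drop = FALSE])
}

# normalize sequence-set inputs to data.frame(id, desc, seq)
as_seqset <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "seq") %in% names(x)))
    if (is.null(x$desc)) x$desc <- ""
    return(data.frame(id = as.character(x$id), desc = as.character(x$desc),
                      seq = toupper(as.character(x$seq)),
                      stringsAsFactors = FALSE))
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq%d", seq_along(x))
    return(data.frame(id = ids, desc = rep("", length(x)),
                      seq = toupper(unname(x)), stringsAsFactors = FALSE))
  }
  stop("cannot interpret sequence set (need character vector or data frame)")
}
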