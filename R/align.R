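# Band extension and banded local alignment.

#' Extend a similarity zone into an alignment band
#'
#' Widens the diagonal span of a merged zone by half the band extension on
#' each side and lengthens it along the diagonal by the full extension each
#' way, clipping to the sequence ends.
#'
#' @param zone One merged zone: a one-row data frame or list with `q_lo`,
#'   `q_hi`, `s_lo`, `s_hi`, `diag_lo`, `diag_hi` (0-based inclusive,
#'   query-local diagonals).
#' @param params A `zs_params` (uses `band_extension`).
#' @param query_len,subject_len Sequence lengths for clipping.
#' @return A list with the extended, clipped `q_lo`, `q_hi`, `s_lo`,
#'   `s_hi`, `diag_lo`, `diag_hi`.
#' @export
extend_band <- function(zone, params, query_len, subject_len) {
  ext <- params$band_extension
  list(
    q_lo = max(0L, zone$q_lo - ext),
    q_hi = min(query_len - 1L, zone$q_hi + ext),
    s_lo = max(0L, zone$s_lo - ext),
    s_hi = min(subject_len - 1L, zone$s_hi + ext),
    diag_lo = zone$diag_lo - ext %/% 2L,
    diag_hi = zone$diag_hi + ext %/% 2L
  )
}

#' Banded local alignment with affine gaps
#'
#' Computes the optimal local (Smith-Waterman scored) alignment restricted
#' to the cells of a diagonal band, using three-state affine-gap dynamic
#' programming with full traceback. Memory and time are proportional to
#' the band area, never to the full rectangle. Traceback ties prefer
#' match/mismatch over a query-consuming gap over a subject-consuming gap,
#' and among equal-scoring end cells the smallest subject (then query)
#' coordinate wins, so output is deterministic.
#'
#' @param query,subject Residue strings.
#' @param band Band as returned by [extend_band()] (query-local diagonals
#'   `diag = q - s`).
#' @param m A `zs_matrix` or matrix name.
#' @param params A `zs_params` (uses `gip`, `gep`).
#' @return `NULL` when no cell scores positive (or the band is empty after
#'   clipping); otherwise a list of class `zs_alignment` with `sw_score`,
#'   0-based half-open `q_start`, `q_end`, `s_start`, `s_end`, a run-length
#'   edit path (`path_op` in M/D/I, `path_len`), `identities`,
#'   `mismatches`, `gap_openings`, `aligned_length` and the aligned strings
#'   `qaln`, `saln` (gaps as `-`).
#' @examples
#' p <- search_params()
#' b <- list(q_lo = 0, q_hi = 7, s_lo = 0, s_hi = 7, diag_lo = -8, diag_hi = 8)
#' banded_align("ACDEFGHI", "ACDEFGHI", b, "BLOSUM62", p)$sw_score
#' @export
banded_align <- function(query, subject, band, m, params = search_params()) {
  m <- as_zs_matrix(m)
  q <- encode_residues(as_seqset(query)$seq[1L], m$symbols)
  s <- encode_residues(as_seqset(subject)$seq[1L], m$symbols)
  sm <- m$scores
  # non-standard residues map to a sentinel row of strongly negative
  # weights: they can sit inside an alignment but never score
  if (anyNA(q) || anyNA(s)) {
    sm <- matrix(-1000L, 21L, 21L)
    sm[1:20, 1:20] <- m$scores
    q[is.na(q)] <- 20L
    s[is.na(s)] <- 20L
  }
  res <- .banded_align_cpp(q, s, sm, band$q_lo, band$q_hi, band$s_lo,
                           band$s_hi, band$diag_lo, band$diag_hi,
                           params$gip, params$gep)
  if (is.null(res)) return(NULL)
  aln <- render_alignment(res, as_seqset(query)$seq[1L], as_seqset(subject)$seq[1L])
  res$qaln <- aln$qaln
  res$saln <- aln$saln
  class(res) <- "zs_alignment"
  res
}

# build gapped alignment strings from the run-length path
render_alignment <- function(res, query, subject) {
  qi <- res$q_start + 1L
  sj <- res$s_start + 1L
  qparts <- character(0)
  sparts <- character(0)
  for (r in seq_along(res$path_op)) {
    len <- res$path_len[r]
    op <- res$path_op[r]
    if (op == "M") {
      qparts <- c(qparts, substr(query, qi, qi + len - 1L))
      sparts <- c(sparts, substr(subject, sj, sj + len - 1L))
      qi <- qi + len; sj <- sj + len
    } else if (op == "D") {
      qparts <- c(qparts, substr(query, qi, qi + len - 1L))
      sparts <- c(sparts, strrep("-", len))
      qi <- qi + len
    } else {
      qparts <- c(qparts, strrep("-", len))
      sparts <- c(sparts, substr(subject, sj, sj + len - 1L))
      sj <- sj + len
    }
  }
  list(qaln = paste(qparts, collapse = ""), saln = paste(sparts, collapse = ""))
}

#' @export
print.zs_alignment <- function(x, ...) {
  cat("<zs_alignment> score", x$sw_score, " q", x$q_start, "-", x$q_end,
      " s", x$s_start, "-", x$s_end, " id ", x$identities, "/",
      x$aligned_length, "\n", sep = "")
  invisible(x)
}
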