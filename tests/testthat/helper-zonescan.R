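# Shared fixtures and independent oracles used across the suite.

BL62 <- load_matrix("BLOSUM62")

# identity toy matrix in NCBI text form (diagonal 1, off-diagonal -1)
toy_matrix_file <- function(diag = 1L, off = -1L, tweak = NULL) {
  sc <- matrix(off, 20, 20, dimnames = list(STD_AA, STD_AA))
  diag(sc) <- diag
  if (!is.null(tweak)) sc[tweak[[1]], tweak[[2]]] <- sc[tweak[[2]], tweak[[1]]] <- tweak[[3]]
  path <- tempfile(fileext = ".mat")
  writeLines(c("# toy matrix",
               paste(" ", paste(STD_AA, collapse = "  ")),
               vapply(seq_len(20), function(i)
                 paste(STD_AA[i], paste(sprintf("%2d", sc[i, ]), collapse = " ")), "")),
             path)
  path
}

random_tuple <- function(k = 5L) paste(sample(STD_AA, k, replace = TRUE), collapse = "")

# brute-force match score straight off the matrix (independent of the
# suffix-array code path)
brute_match_score <- function(a, b, m = BL62) {
  da <- match(strsplit(a, "")[[1]], m$symbols)
  db <- match(strsplit(b, "")[[1]], m$symbols)
  sum(m$scores[cbind(da, db)])
}

# 0-based digit matrix of all 20^k codes (cached per k within a session)
all_code_digits <- local({
  cache <- list()
  function(k) {
    key <- as.character(k)
    if (is.null(cache[[key]])) {
      code <- 0:(20^k - 1)
      d <- matrix(0L, nrow = 20^k, ncol = k)
      for (p in k:1) {
        d[, p] <- code %% 20L
        code <- code %/% 20L
      }
      cache[[key]] <<- d
    }
    cache[[key]]
  }
})

# exhaustive diversification oracle: position-wise score of every code
# against the tuple, filtered at S = self * approx
oracle_neighborhood_scores <- function(tup, m = BL62) {
  d <- match(strsplit(tup, "")[[1]], m$symbols) - 1L
  k <- length(d)
  dg <- all_code_digits(k)
  tot <- numeric(nrow(dg))
  for (p in seq_len(k)) tot <- tot + unname(m$scores[d[p] + 1L, dg[, p] + 1L])
  tot
}

oracle_neighborhood <- function(tup, approx, m = BL62, scores = NULL) {
  if (is.null(scores)) scores <- oracle_neighborhood_scores(tup, m)
  S <- brute_match_score(tup, tup, m) * approx
  which(scores >= S) - 1L
}

# brute-force lookup index: every occurring query tuple scored against all
# 20^k codes (used at k = 3 where this is tractable)
oracle_index <- function(seqs, m, k, approx) {
  out <- list()
  for (qi in seq_along(seqs)) {
    chars <- strsplit(seqs[qi], "")[[1]]
    for (off in 0:(nchar(seqs[qi]) - k)) {
      tup <- paste(chars[(off + 1):(off + k)], collapse = "")
      nb <- oracle_neighborhood(tup, approx, m)
      out[[length(out) + 1L]] <- data.frame(code = nb, query = qi, offset = off)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$code, df$query, df$offset), , drop = FALSE]
}

# full-table dump of a built lookup table as (code, query, offset) rows
dump_table <- function(lt) {
  k <- lt$k
  off <- lt$core$offsets
  n <- lt$total_entries
  code <- rep.int(0:(20^k - 1), diff(off))
  df <- data.frame(code = code, query = lt$core$entry_query + 1L,
                   offset = lt$core$entry_offset)
  df <- df[order(df$code, df$query, df$offset), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# residue pools chosen so segments from different pools never share
# diversified tuples at approx = 1 (exact matching only)
pool_seq <- function(pool, n, seed) {
  with_seed(seed, paste(sample(pool, n, replace = TRUE), collapse = ""))
}

zone_row <- function(query = 1L, diag_lo = 0L, diag_hi = 0L, s_lo = 0L,
                     s_hi = 10L, q_lo = 0L, q_hi = 10L, score = 50L,
                     zone_id = 0L) {
  data.frame(zone_id = zone_id, query = query, diag_lo = diag_lo,
             diag_hi = diag_hi, s_lo = s_lo, s_hi = s_hi, q_lo = q_lo,
             q_hi = q_hi, score = score)
}

full_band <- function(qlen, slen) {
  list(q_lo = 0L, q_hi = qlen - 1L, s_lo = 0L, s_hi = slen - 1L,
       diag_lo = -(slen - 1L), diag_hi = qlen - 1L)
}

# independent full Smith-Waterman score (Biostrings dynamic programming)
biostrings_sw <- function(q, s, m = BL62, gip = 11, gep = 1) {
  as.numeric(Biostrings::score(Biostrings::pairwiseAlignment(
    q, s, type = "local", substitutionMatrix = m$scores,
    gapOpening = gip, gapExtension = gep)))
}

planted_trial <- function(seed, n_decoys = 50L, L = 300L,
                          substitution_rate = 0.2, n_indels = 2L) {
  qs <- random_proteome(1L, L, seed = seed)
  mut <- mutate_homolog(qs$seq, substitution_rate = substitution_rate,
                        n_indels = n_indels, seed = seed + 1L)
  decoys <- random_proteome(n_decoys, L, seed = seed + 2L)
  subjects <- rbind(data.frame(id = "PLANTED", desc = "", seq = mut$seq,
                               stringsAsFactors = FALSE), decoys)
  list(query = qs, subjects = subjects)
}
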