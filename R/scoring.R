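# Residue alphabet, substitution matrices, k-tuple codes and match scores.

# the 20 standard amino acids in NCBI matrix header order
STD_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Load a substitution matrix
#'
#' Reads an amino-acid substitution matrix in the NCBI text format
#' (`#` comment lines, a header row of symbols, one labelled row per
#' symbol) and restricts it to the 20 standard residues, in header order.
#' The matrix must be symmetric and every residue's self-match score must
#' be the row maximum; both are validated at load time because the
#' diversification trie pruning depends on them.
#'
#' @param source Path to an NCBI-format matrix file, or the name of a
#'   bundled matrix (currently `"BLOSUM62"`).
#' @return An object of class `zs_matrix`: a list with `name`, `symbols`
#'   (ordered 20-letter alphabet) and `scores` (20 x 20 integer matrix with
#'   residue dimnames).
#' @examples
#' m <- load_matrix("BLOSUM62")
#' m$scores["W", "W"]
#' @export
load_matrix <- function(source) {
  bundled <- c(BLOSUM62 = "BLOSUM62.txt")
  if (file.exists(source)) {
    path <- source
    name <- sub("\\.[^.]*$", "", basename(source))
  } else if (source %in% names(bundled)) {
    path <- system.file("extdata", bundled[[source]], package = "zonescan")
    name <- source
  } else {
    stop("unknown substitution matrix: '", source,
         "' (not a readable file, and not a bundled name)")
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("malformed matrix file: ", path)
  header <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  labels <- vapply(rows, `[`, "", 1L)
  vals <- lapply(rows, function(r) {
    v <- suppressWarnings(as.integer(r[-1L]))
    if (anyNA(v)) stop("malformed matrix row in ", path, ": ", paste(r, collapse = " "))
    v
  })
  if (any(lengths(vals) != length(header)))
    stop("malformed matrix file: row length does not match header (", path, ")")
  full <- do.call(rbind, vals)
  dimnames(full) <- list(labels, header)

  keep <- header[header %in% STD_AA]
  if (length(keep) != 20L)
    stop("matrix header does not contain the 20 standard residues (", path, ")")
  if (!all(keep %in% labels)) stop("matrix rows missing standard residues")
  sc <- full[keep, keep, drop = FALSE]
  storage.mode(sc) <- "integer"

  if (!identical(sc, t(sc))) stop("substitution matrix is not symmetric")
  for (i in seq_len(20L)) {
    j <- which(sc[i, ] > sc[i, i])
    if (length(j))
      stop("self-max violated: score(", keep[i], ",", keep[j[1L]], ") = ",
           sc[i, j[1L]], " > score(", keep[i], ",", keep[i], ") = ", sc[i, i])
  }
  structure(list(name = name, symbols = keep, scores = sc),
            class = "zs_matrix")
}

#' @export
print.zs_matrix <- function(x, ...) {
  cat("<zs_matrix>", x$name, "-", paste(x$symbols, collapse = ""), "\n")
  invisible(x)
}

as_zs_matrix <- function(m) {
  if (inherits(m, "zs_matrix")) return(m)
  if (is.character(m) && length(m) == 1L) return(load_matrix(m))
  stop("expected a zs_matrix or a matrix name/path")
}

# encode a residue string to 0-based alphabet indices (NA for non-standard)
encode_residues <- function(seq, symbols = STD_AA) {
  .encode_residues_cpp(toupper(seq), paste(symbols, collapse = ""))
}

tuple_digits <- function(t, k, symbols = STD_AA) {
  # accept a residue string or an integer code (with k)
  if (is.character(t)) {
    d <- encode_residues(t, symbols)
    if (anyNA(d)) stop("tuple contains a residue outside the 20-letter alphabet: ", t)
    d
  } else {
    t <- as.numeric(t)
    if (is.na(t) || t < 0 || t >= 20^k) stop("tuple code out of range [0, 20^k)")
    d <- integer(k)
    for (p in k:1) {
      d[p] <- t %% 20
      t <- t %/% 20
    }
    as.integer(d)
  }
}

#' Encode and decode k-tuple codes
#'
#' A k-tuple of residues is addressed by its base-20 positional code (most
#' significant digit first), so that the code is a direct offset into the
#' lookup table.
#'
#' @param residues Length-k residue string (e.g. `"ACDEF"`).
#' @param symbols Ordered alphabet (default: the 20 standard residues).
#' @return `encode_tuple()`: an integer code in `[0, 20^k)`;
#'   `decode_tuple()`: the residue string.
#' @examples
#' encode_tuple("RD") # 1*20 + 3
#' decode_tuple(23, 2)
#' @export
encode_tuple <- function(residues, symbols = STD_AA) {
  d <- encode_residues(residues, symbols)
  if (anyNA(d)) stop("cannot encode tuple '", residues,
                     "': residue outside the alphabet")
  if (length(d) < 1L) stop("k must be >= 1")
  as.integer(sum(d * 20^(rev(seq_along(d)) - 1L)))
}

#' @rdname encode_tuple
#' @param code Integer tuple code.
#' @param k Tuple length.
#' @export
decode_tuple <- function(code, k, symbols = STD_AA) {
  paste(symbols[tuple_digits(code, k, symbols) + 1L], collapse = "")
}

#' Tuple self- and match scores with suffix arrays
#'
#' `match_score()` sums substitution-matrix weights over the residue pairs
#' of two equal-length tuples; `tuple_self_score()` is the score of a tuple
#' against itself. The `suffix_*` variants return, for each position j, the
#' score of the suffix starting at j (1-based; element 1 is the full-tuple
#' score). These per-suffix partial scores are what the lookup table stores
#' so that overlapping diagonal matches are scored without touching the
#' substitution matrix in the inner loop.
#'
#' @param a,b,t Tuples: residue strings, or integer codes if `k` is given.
#' @param m A `zs_matrix` (or matrix name).
#' @param k Tuple length, required when tuples are given as codes.
#' @return An integer score, or an integer vector of k suffix scores.
#' @examples
#' m <- load_matrix("BLOSUM62")
#' tuple_self_score("ACDEF", m)
#' suffix_match_scores("ACDEF", "ACDEY", m)
#' @export
match_score <- function(a, b, m, k = NULL) {
  suffix_match_scores(a, b, m, k)[1L]
}

#' @rdname match_score
#' @export
suffix_match_scores <- function(a, b, m, k = NULL) {
  m <- as_zs_matrix(m)
  if (is.null(k)) {
    if (!is.character(a) || !is.character(b))
      stop("k is required when tuples are given as integer codes")
    if (nchar(a) != nchar(b)) stop("tuples have different lengths")
    k <- nchar(a)
  }
  da <- tuple_digits(a, k, m$symbols) + 1L
  db <- tuple_digits(b, k, m$symbols) + 1L
  if (length(da) != length(db)) stop("tuples have different lengths")
  per <- m$scores[cbind(da, db)]
  as.integer(rev(cumsum(rev(per))))
}

#' @rdname match_score
#' @export
tuple_self_score <- function(t, m, k = NULL) {
  suffix_self_scores(t, m, k)[1L]
}

#' @rdname match_score
#' @export
suffix_self_scores <- function(t, m, k = NULL) {
  suffix_match_scores(t, t, m, k)
}
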