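# Seeded synthetic protein data for tests and benchmarks.

# Robinson & Robinson (1991) background amino-acid frequencies, in the
# standard NCBI matrix symbol order (A R N D C Q E G H I L K M F P S T W Y V)
ROBINSON_FREQS <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Generate a random synthetic proteome
#'
#' Sequences of i.i.d. residues from a stated composition; deterministic
#' in the seed.
#'
#' @param n_seqs Number of sequences.
#' @param lengths Sequence length(s), recycled to `n_seqs`.
#' @param seed Integer seed.
#' @param composition `"uniform"` (default) or `"robinson"` (natural
#'   background frequencies).
#' @return Sequence set data frame (`id`, `desc`, `seq`).
#' @export
random_proteome <- function(n_seqs, lengths = 300L, seed = 1L,
                            composition = c("uniform", "robinson")) {
  stopifnot(n_seqs >= 1L)
  composition <- match.arg(composition)
  prob <- if (composition == "uniform") rep(1 / 20, 20) else unname(ROBINSON_FREQS)
  lengths <- rep_len(as.integer(lengths), n_seqs)
  with_seed(seed, {
    seqs <- vapply(lengths, function(L) {
      paste(sample(STD_AA, L, replace = TRUE, prob = prob), collapse = "")
    }, "")
    data.frame(id = sprintf("SYN%04d", seq_len(n_seqs)),
               desc = paste0("synthetic ", composition),
               seq = seqs, stringsAsFactors = FALSE)
  })
}

#' Mutate a sequence into a homolog with a known alignment
#'
#' Applies residue substitutions and insertions/deletions (geometric
#' length, mean `mean_indel_len`) and returns the mutant together with the
#' ground-truth edit path, enabling recall scoring of the search pipeline.
#' Indels can be given as per-residue rates or as an exact count
#' (`n_indels`, placed uniformly, type chosen at random).
#'
#' @param seq Residue string.
#' @param substitution_rate,insertion_rate,deletion_rate Per-residue event
#'   probabilities in `[0, 1)`.
#' @param mean_indel_len Mean indel length (geometric distribution).
#' @param n_indels Exact number of indels (overrides the indel rates).
#' @param seed Integer seed.
#' @return A list with `seq` (mutant) and `path` (data frame of run-length
#'   operations `op` in M/I/D, `len`), where M columns pair original and
#'   mutant residues, D consumes the original and I the mutant.
#' @export
mutate_homolog <- function(seq, substitution_rate = 0, insertion_rate = 0,
                           deletion_rate = 0, mean_indel_len = 3,
                           n_indels = NULL, seed = 1L) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  stopifnot(all(rates >= 0), all(rates < 1), mean_indel_len >= 1)
  res <- strsplit(toupper(seq), "")[[1L]]
  L <- length(res)
  with_seed(seed, {
    sub_at <- runif(L) < substitution_rate
    if (!is.null(n_indels)) {
      pos <- if (n_indels > 0) sort(sample.int(L, n_indels)) else integer(0)
      type <- sample(c("I", "D"), length(pos), replace = TRUE)
    } else {
      ins <- runif(L) < insertion_rate
      del <- runif(L) < deletion_rate
      pos <- sort(c(which(ins), which(del)))
      type <- c(rep("I", sum(ins)), rep("D", sum(del)))[order(c(which(ins), which(del)))]
    }
    len <- rgeom(length(pos), 1 / mean_indel_len) + 1L

    ops <- character(0)
    out <- character(0)
    i <- 1L
    ev <- 1L
    while (i <= L) {
      if (ev <= length(pos) && pos[ev] == i) {
        if (type[ev] == "D") {
          d <- min(len[ev], L - i + 1L)
          ops <- c(ops, rep("D", d))
          i <- i + d
        } else {
          ops <- c(ops, rep("I", len[ev]))
          out <- c(out, sample(STD_AA, len[ev], replace = TRUE))
        }
        ev <- ev + 1L
        # skip any events swallowed by a deletion
        while (ev <= length(pos) && pos[ev] < i) ev <- ev + 1L
        next
      }
      r <- res[i]
      if (sub_at[i]) r <- sample(setdiff(STD_AA, r), 1L)
      out <- c(out, r)
      ops <- c(ops, "M")
      i <- i + 1L
    }
    rl <- rle(ops)
    list(seq = paste(out, collapse = ""),
         path = data.frame(op = rl$values, len = rl$lengths,
                           stringsAsFactors = FALSE))
  })
}

#' Construct repeat and fusion proteins with known coordinates
#'
#' Deterministic constructs that exercise the long-repeat filter and the
#' remote-segment merger.
#'
#' @param unit Repeat unit (residue string).
#' @param copies Number of copies (>= 2).
#' @param spacer_len Random spacer length between copies.
#' @param seed Integer seed (spacers/linkers are random).
#' @return `make_repeat_protein()`: list with `seq` and `unit_starts`
#'   (1-based start of each copy); `make_fusion_protein()`: list with
#'   `seq` and 1-based `a_start`, `a_end`, `b_start`, `b_end`.
#' @export
make_repeat_protein <- function(unit, copies, spacer_len, seed = 1L) {
  stopifnot(copies >= 2L)
  with_seed(seed, {
    spacers <- vapply(seq_len(copies - 1L), function(i)
      paste(sample(STD_AA, spacer_len, replace = TRUE), collapse = ""), "")
    parts <- character(0)
    starts <- integer(copies)
    pos <- 1L
    for (i in seq_len(copies)) {
      starts[i] <- pos
      parts <- c(parts, unit)
      pos <- pos + nchar(unit)
      if (i < copies) {
        parts <- c(parts, spacers[i])
        pos <- pos + spacer_len
      }
    }
    list(seq = paste(parts, collapse = ""), unit_starts = starts)
  })
}

#' @rdname make_repeat_protein
#' @param domainA,domainB Domain residue strings.
#' @param linker_len Random linker length between the domains.
#' @export
make_fusion_protein <- function(domainA, domainB, linker_len, seed = 1L) {
  with_seed(seed, {
    linker <- paste(sample(STD_AA, linker_len, replace = TRUE), collapse = "")
    list(seq = paste0(domainA, linker, domainB),
         a_start = 1L, a_end = nchar(domainA),
         b_start = nchar(domainA) + linker_len + 1L,
         b_end = nchar(domainA) + linker_len + nchar(domainB))
  })
}
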