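# FASTA input and result writers (TEXT, TAB, TABX, NCBI m8/m9).

#' Read a FASTA protein file
#'
#' Wraps `Biostrings::readAAStringSet()`. Record ids are the first
#' whitespace-delimited token of the header, the rest is kept as the
#' description, residues are uppercased, and empty-sequence records are
#' skipped with a warning.
#'
#' @param path Readable FASTA file.
#' @param allow_empty Return a zero-row set instead of erroring when no
#'   parseable record remains.
#' @return Data frame with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path, allow_empty = FALSE) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  ss <- Biostrings::readAAStringSet(path)
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(ss))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    warning("skipping ", sum(empty), " empty FASTA record(s): ",
            paste(head(ids[empty], 3L), collapse = ", "))
    ids <- ids[!empty]; desc <- desc[!empty]; seqs <- seqs[!empty]
  }
  if (length(seqs) == 0L && !allow_empty)
    stop("no parseable sequence records in ", path)
  data.frame(id = ids, desc = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a sequence set as FASTA
#'
#' @param seqs Sequence set (data frame with `id`, optional `desc`, `seq`).
#' @param path Output file.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  seqs <- as_seqset(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    hdr <- if (nzchar(seqs$desc[i])) paste(seqs$id[i], seqs$desc[i]) else seqs$id[i]
    writeLines(paste0(">", hdr), con)
    s <- seqs$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

format_evalue <- function(e) {
  ifelse(e < 1e-180, "0.0", sprintf("%.3g", e))
}

m8_fields <- function(hits) {
  data.frame(
    qid = hits$query_id, sid = hits$subject_id,
    pident = sprintf("%.2f", 100 * hits$identities / hits$aligned_length),
    length = hits$aligned_length, mismatch = hits$mismatches,
    gapopen = hits$gap_openings,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = hits$s_start + 1L, send = hits$s_end,
    evalue = format_evalue(hits$evalue),
    bitscore = sprintf("%.1f", hits$bit),
    stringsAsFactors = FALSE)
}

#' Write search results
#'
#' Writers for the finalized hit table (E-values present). `NCBI_M8` is
#' the 12-column tab-separated BLAST tabular convention with 1-based
#' inclusive coordinates; `NCBI_M9` adds `#`-prefixed header lines per
#' query. `TAB` is qid, sid, sw_score, evalue, qstart, qend, sstart, send;
#' `TABX` appends identity %, aligned length and gap openings. `TEXT`
#' prints human-readable blocks with the rendered alignments.
#'
#' @param hits Hits data frame with statistics columns.
#' @param omode One of `"TEXT"`, `"TAB"`, `"TABX"`, `"NCBI_M8"`,
#'   `"NCBI_M9"`.
#' @param file Output path or connection (default: standard output).
#' @export
write_results <- function(hits, omode = "NCBI_M8", file = stdout()) {
  if (is.character(file)) {
    con <- file(file, "w")
    on.exit(close(con))
  } else con <- file
  omode <- toupper(omode)
  tab <- function(df) writeLines(do.call(paste, c(df, sep = "\t")), con)
  if (omode == "NCBI_M8") {
    if (nrow(hits)) tab(m8_fields(hits))
  } else if (omode == "NCBI_M9") {
    fields <- paste("# Fields: query id, subject id, % identity,",
                    "alignment length, mismatches, gap openings,",
                    "q. start, q. end, s. start, s. end, evalue, bit score")
    for (q in unique(hits$query_id)) {
      h <- hits[hits$query_id == q, , drop = FALSE]
      writeLines(c(paste0("# zonescan ", as.character(utils::packageVersion("zonescan"))),
                   paste0("# Query: ", q), fields,
                   paste0("# ", nrow(h), " hits found")), con)
      tab(m8_fields(h))
    }
  } else if (omode == "TAB") {
    if (nrow(hits))
      tab(data.frame(hits$query_id, hits$subject_id, hits$sw_score,
                     format_evalue(hits$evalue), hits$q_start + 1L,
                     hits$q_end, hits$s_start + 1L, hits$s_end))
  } else if (omode == "TABX") {
    if (nrow(hits))
      tab(data.frame(hits$query_id, hits$subject_id, hits$sw_score,
                     format_evalue(hits$evalue), hits$q_start + 1L,
                     hits$q_end, hits$s_start + 1L, hits$s_end,
                     sprintf("%.2f", 100 * hits$identities / hits$aligned_length),
                     hits$aligned_length, hits$gap_openings))
  } else if (omode == "TEXT") {
    for (i in seq_len(nrow(hits))) write_text_block(hits[i, ], con)
  } else stop("unknown output mode: ", omode)
  invisible(NULL)
}

write_text_block <- function(h, con) {
  writeLines(c(
    paste0("Query: ", h$query_id, "   Subject: ", h$subject_id),
    sprintf(" Score = %d (%.1f bits), Expect = %s", as.integer(h$sw_score),
            h$bit, format_evalue(h$evalue)),
    sprintf(" Identities = %d/%d (%.1f%%), Mismatches = %d, Gap openings = %d",
            h$identities, h$aligned_length,
            100 * h$identities / h$aligned_length, h$mismatches,
            h$gap_openings)), con)
  qa <- strsplit(h$qaln, "")[[1L]]
  sa <- strsplit(h$saln, "")[[1L]]
  mid <- ifelse(qa == sa & qa != "-", "|", ifelse(qa == "-" | sa == "-", " ", "."))
  qpos <- h$q_start + 1L
  spos <- h$s_start + 1L
  for (off in seq(1L, length(qa), by = 60L)) {
    j <- min(off + 59L, length(qa))
    qchunk <- qa[off:j]; schunk <- sa[off:j]
    writeLines(c(
      sprintf("Query  %5d  %s  %d", qpos, paste(qchunk, collapse = ""),
              qpos + sum(qchunk != "-") - 1L),
      sprintf("              %s", paste(mid[off:j], collapse = "")),
      sprintf("Sbjct  %5d  %s  %d", spos, paste(schunk, collapse = ""),
              spos + sum(schunk != "-") - 1L), ""), con)
    qpos <- qpos + sum(qchunk != "-")
    spos <- spos + sum(schunk != "-")
  }
  invisible(NULL)
}
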