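test_that("random proteomes are seed-deterministic with the stated shape", {
  a <- random_proteome(5L, 300L, seed = 81)
  b <- random_proteome(5L, 300L, seed = 81)
  expect_identical(a, b)
  expect_identical(nrow(a), 5L)
  expect_true(all(nchar(a$seq) == 300L))
  expect_false(identical(a, random_proteome(5L, 300L, seed = 82)))
  lens <- nchar(random_proteome(4L, c(100L, 200L), seed = 83)$seq)
  expect_identical(lens, c(100L, 200L, 100L, 200L))
})

test_that("residue composition stays within multinomial bounds", {
  # n*L = 1e5 residues; each uniform count ~ Bin(1e5, 1/20)
  big <- random_proteome(10L, 10000L, seed = 84)
  counts <- table(factor(strsplit(paste(big$seq, collapse = ""), "")[[1]],
                         levels = STD_AA))
  n <- 1e5
  expm <- n / 20
  sigma <- sqrt(n * (1 / 20) * (19 / 20))
  expect_true(all(abs(counts - expm) < 3.5 * sigma))

  rob <- random_proteome(10L, 10000L, seed = 85, composition = "robinson")
  rcounts <- table(factor(strsplit(paste(rob$seq, collapse = ""), "")[[1]],
                          levels = STD_AA))
  pf <- zonescan:::ROBINSON_FREQS
  expect_true(all(abs(rcounts - n * pf) < 3.5 * sqrt(n * pf * (1 - pf))))
})

test_that("zero-rate mutation is the identity with an all-match path", {
  q <- random_proteome(1L, 200L, seed = 86)$seq
  m <- mutate_homolog(q, seed = 87)
  expect_identical(m$seq, q)
  expect_identical(m$path, data.frame(op = "M", len = 200L,
                                      stringsAsFactors = FALSE))
})

test_that("substitution counts fall in binomial bounds and paths replay", {
  q <- random_proteome(1L, 300L, seed = 88)$seq
  m <- mutate_homolog(q, substitution_rate = 0.2, seed = 89)
  ndiff <- sum(strsplit(q, "")[[1]] != strsplit(m$seq, "")[[1]])
  expect_true(ndiff >= qbinom(0.005, 300, 0.2) &&
              ndiff <= qbinom(0.995, 300, 0.2))

  # replaying the truth path on the pair must reconstruct the mutant
  mi <- mutate_homolog(q, substitution_rate = 0.1, n_indels = 3L, seed = 90)
  qi <- 1L; si <- 1L; rebuilt <- character(0)
  for (r in seq_len(nrow(mi$path))) {
    op <- mi$path$op[r]; len <- mi$path$len[r]
    if (op == "M") {
      rebuilt <- c(rebuilt, substr(mi$seq, si, si + len - 1L))
      qi <- qi + len; si <- si + len
    } else if (op == "I") {
      rebuilt <- c(rebuilt, substr(mi$seq, si, si + len - 1L))
      si <- si + len
    } else qi <- qi + len
  }
  expect_identical(paste(rebuilt, collapse = ""), mi$seq)
  expect_identical(qi - 1L, nchar(q))
  expect_identical(si - 1L, nchar(mi$seq))
  expect_identical(mutate_homolog(q, substitution_rate = 0.2, seed = 89)$seq,
                   m$seq)
})

test_that("repeat and fusion constructs have the stated geometry", {
  unit <- random_proteome(1L, 40L, seed = 91)$seq
  rp <- make_repeat_protein(unit, copies = 3L, spacer_len = 10L, seed = 92)
  expect_identical(nchar(rp$seq), 3L * 40L + 2L * 10L)
  expect_identical(rp$unit_starts, c(1L, 51L, 101L))
  for (st in rp$unit_starts)
    expect_identical(substr(rp$seq, st, st + 39L), unit)

  a <- random_proteome(1L, 60L, seed = 93)$seq
  b <- random_proteome(1L, 70L, seed = 94)$seq
  fp <- make_fusion_protein(a, b, linker_len = 15L, seed = 95)
  expect_identical(nchar(fp$seq), 60L + 15L + 70L)
  expect_identical(substr(fp$seq, fp$a_start, fp$a_end), a)
  expect_identical(substr(fp$seq, fp$b_start, fp$b_end), b)
})

test_that("repeat proteins trigger the repeat filter end to end", {
  unit <- random_proteome(1L, 40L, seed = 96)$seq
  rp <- make_repeat_protein(unit, copies = 3L, spacer_len = 12L, seed = 97)
  p <- search_params(kthresh = 14L)
  lt <- build_lookup_table(unit, BL62, k = 5, approx = 0.85)
  zones <- scan_subject(rp$seq, lt, p)
  hits <- do.call(rbind, lapply(seq_len(nrow(zones)), function(i) {
    b <- extend_band(zones[i, ], p, nchar(unit), nchar(rp$seq))
    a <- banded_align(unit, rp$seq, b, BL62, p)
    data.frame(query_id = "u", subject_id = "rp", sw_score = a$sw_score,
               q_start = a$q_start, q_end = a$q_end, s_start = a$s_start,
               s_end = a$s_end, identities = a$identities,
               mismatches = a$mismatches, gap_openings = a$gap_openings,
               aligned_length = a$aligned_length, qaln = a$qaln,
               saln = a$saln, n_members = 1L, stringsAsFactors = FALSE)
  }))
  hits <- hits[!duplicated(hits[c("q_start", "q_end", "s_start", "s_end")]), ]
  expect_gte(nrow(hits), 2L) # one hit per repeat copy before filtering
  kept <- filter_long_repeats(hits)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$sw_score, max(hits$sw_score))
})

test_that("fusion proteins chain into one super-alignment end to end", {
  # diverged two-domain partner: the domains seed two well-separated
  # zones whose banded alignments are then chained by the merger
  a <- random_proteome(1L, 80L, seed = 98)$seq
  b <- random_proteome(1L, 80L, seed = 99)$seq
  query <- make_fusion_protein(a, b, linker_len = 5L, seed = 100)
  am <- mutate_homolog(a, substitution_rate = 0.25, seed = 200)$seq
  bm <- mutate_homolog(b, substitution_rate = 0.25, seed = 201)$seq
  subject <- make_fusion_protein(am, bm, linker_len = 65L, seed = 202)
  p <- search_params(kthresh = 14L, merge_remote = TRUE)
  lt <- build_lookup_table(query$seq, BL62, k = 5, approx = 0.85)
  zones <- scan_subject(subject$seq, lt, p)
  hits <- do.call(rbind, lapply(seq_len(nrow(zones)), function(i) {
    bd <- extend_band(zones[i, ], p, nchar(query$seq), nchar(subject$seq))
    al <- banded_align(query$seq, subject$seq, bd, BL62, p)
    data.frame(query_id = "f1", subject_id = "f2", sw_score = al$sw_score,
               q_start = al$q_start, q_end = al$q_end, s_start = al$s_start,
               s_end = al$s_end, identities = al$identities,
               mismatches = al$mismatches, gap_openings = al$gap_openings,
               aligned_length = al$aligned_length, qaln = al$qaln,
               saln = al$saln, n_members = 1L, stringsAsFactors = FALSE)
  }))
  hits <- hits[!duplicated(hits[c("q_start", "q_end", "s_start", "s_end")]), ]
  expect_gte(nrow(hits), 2L) # the two domains align separately
  sup <- merge_remote_segments(hits, p)
  expect_identical(nrow(sup), 1L)
  expect_identical(sup$n_members, 2L)
  expect_gt(sup$sw_score, max(hits$sw_score))
})
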