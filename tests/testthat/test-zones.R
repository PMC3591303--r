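test_that("diagonal index is constant on a diagonal and bounded", {
  expect_identical(diagonal_index(0L, 0L, 100L), 100L)
  expect_identical(diagonal_index(10L, 4L, 100L), diagonal_index(11L, 5L, 100L))
  expect_false(diagonal_index(10L, 4L, 100L) == diagonal_index(11L, 4L, 100L))
  expect_error(diagonal_index(0L, 100L, 100L), "max_subject_len")
})

test_that("affine gap penalty is gip + gep*L with a free zero gap", {
  p <- search_params(gip = 11, gep = 1)
  expect_identical(affine_gap_penalty(0, p), 0L)
  expect_equal(affine_gap_penalty(5, p), 16L)
  pens <- affine_gap_penalty(0:50, p)
  expect_true(all(diff(pens) >= 0))
})

test_that("a self-match forms one main-diagonal zone scoring the full self score", {
  qs <- random_proteome(1L, 300L, seed = 41)
  p <- search_params(approx = 1.0)
  lt <- build_lookup_table(qs, BL62, k = 5, approx = 1.0)
  z <- scan_subject(qs$seq, lt, p)
  expect_identical(nrow(z), 1L)
  expect_identical(z$diag_lo, 0L)
  expect_identical(z$diag_hi, 0L)
  expect_identical(c(z$s_lo, z$s_hi, z$q_lo, z$q_hi), c(0L, 299L, 0L, 299L))
  # independent running-sum oracle: ungapped diagonal score
  d <- match(strsplit(qs$seq, "")[[1]], BL62$symbols)
  expect_equal(z$score, sum(BL62$scores[cbind(d, d)]))
})

test_that("overlapping diagonal matches add suffix scores, not full rescans", {
  # 6-residue self-match: two 5-tuple seeds at distance 1
  with_seed(42, q <- random_tuple(6L))
  lt <- build_lookup_table(q, BL62, k = 5, approx = 1.0)
  z <- scan_subject(q, lt, search_params(approx = 1.0, kthresh = 1L))
  expect_identical(nrow(z), 1L)
  expect_equal(z$score, brute_match_score(q, q))
})

test_that("same-diagonal separation costs an affine penalty or splits the zone", {
  x1 <- pool_seq(c("W", "Y", "F", "H"), 25, 43)
  x2 <- pool_seq(c("C", "M", "I", "L"), 25, 44)
  p <- search_params(approx = 1.0, kthresh = 10L)
  for (g in c(8L, 400L)) {
    mid_q <- strrep("A", g)
    mid_s <- strrep("V", g) # A vs V never seed at approx 1
    query <- paste0(x1, mid_q, x2)
    subj <- paste0(x1, mid_s, x2)
    lt <- build_lookup_table(query, BL62, k = 5, approx = 1.0)
    z <- scan_subject(subj, lt, p, cluster = FALSE)
    s1 <- brute_match_score(x1, x1)
    s2 <- brute_match_score(x2, x2)
    if (g == 8L) {
      # extension wins: single zone, both segments, one affine gap charge
      expect_identical(nrow(z), 1L)
      expect_equal(z$score, s1 + s2 - affine_gap_penalty(g, p))
    } else {
      # the penalty exceeds running score + match score: the diagonal
      # restarts a fresh zone and the first one stays reported
      expect_identical(nrow(z), 2L)
      expect_equal(sort(z$score), sort(c(s1, s2)))
    }
  }
})

test_that("an insertion homolog merges laterally within mxshift but not at 0", {
  x1 <- pool_seq(c("W", "Y", "F", "H"), 25, 43)
  x2 <- pool_seq(c("C", "M", "I", "L"), 25, 44)
  query <- paste0(x1, x2)
  subj <- paste0(x1, "AA", x2) # 2-residue insertion => 2-diagonal shift
  s1 <- brute_match_score(x1, x1)
  s2 <- brute_match_score(x2, x2)
  lt <- build_lookup_table(query, BL62, k = 5, approx = 1.0)
  p2 <- search_params(approx = 1, mxshift = 2, kthresh = 10)
  z2 <- scan_subject(subj, lt, p2, cluster = FALSE)
  expect_identical(nrow(z2), 1L)
  expect_identical(c(z2$diag_lo, z2$diag_hi), c(-2L, 0L))
  expect_identical(c(z2$s_lo, z2$s_hi), c(0L, nchar(subj) - 1L))
  # merged score is bounded by its parts and never double-counted
  expect_true(z2$score >= max(s1, s2) && z2$score <= s1 + s2)
  z0 <- scan_subject(subj, lt, search_params(approx = 1, mxshift = 0, kthresh = 10),
                     cluster = FALSE)
  expect_identical(nrow(z0), 2L)
  expect_equal(sort(z0$score), sort(c(s1, s2)))
})

test_that("rescanning the same subject reproduces identical zones", {
  qs <- random_proteome(2L, 200L, seed = 47)
  mut <- mutate_homolog(qs$seq[1], substitution_rate = 0.15, n_indels = 1, seed = 48)
  lt <- build_lookup_table(qs, BL62, k = 5, approx = 0.85)
  p <- search_params()
  a <- scan_subject(mut$seq, lt, p)
  b <- scan_subject(mut$seq, lt, p)
  expect_identical(a, b)
})

test_that("lazy diagonal invalidation: streaming equals fresh contexts", {
  qs <- random_proteome(3L, 150L, seed = 49)
  subs <- c(mutate_homolog(qs$seq[2], substitution_rate = 0.1, seed = 50)$seq,
            random_proteome(2L, 150L, seed = 51)$seq,
            mutate_homolog(qs$seq[3], substitution_rate = 0.25, seed = 52)$seq)
  lt <- build_lookup_table(qs, BL62, k = 5, approx = 0.85)
  p <- search_params()
  ctx <- new_search_context(lt, p)
  streamed <- lapply(seq_along(subs), function(i)
    scan_subject(subs[i], context = ctx, subject_index = i))
  fresh <- lapply(seq_along(subs), function(i)
    scan_subject(subs[i], lt, p, subject_index = i))
  expect_identical(streamed, fresh)
})

test_that("zone invariants: query attribution, boundaries, threshold", {
  qs <- random_proteome(2L, 250L, seed = 53)
  mut <- mutate_homolog(qs$seq[2], substitution_rate = 0.2, n_indels = 2, seed = 54)
  p <- search_params()
  lt <- build_lookup_table(qs, BL62, k = 5, approx = 0.85)
  z <- scan_subject(mut$seq, lt, p)
  expect_true(all(z$query == 2L)) # similar to query 2 only
  expect_true(all(z$score >= p$kthresh))
  expect_true(all(z$q_lo >= 0 & z$q_hi < nchar(qs$seq[2])))
  expect_true(all(z$s_lo >= 0 & z$s_hi < nchar(mut$seq)))

  none <- scan_subject(strrep("A", 100), lt, p)
  expect_identical(nrow(none), 0L)
})

test_that("zones are invariant to entry order within lookup regions", {
  qs <- random_proteome(3L, 120L, seed = 55)
  mut <- mutate_homolog(qs$seq[1], substitution_rate = 0.15, seed = 56)
  lt <- build_lookup_table(qs, BL62, k = 5, approx = 0.85)
  p <- search_params()
  before <- scan_subject(mut$seq, lt, p)

  # shuffle every region of the entry arena in place
  shuffled <- lt
  off <- lt$core$offsets
  with_seed(57, {
    for (code in which(diff(off) > 1L)) {
      idx <- (off[code] + 1L):off[code + 1L]
      perm <- sample(idx)
      shuffled$core$entry_query[idx] <- lt$core$entry_query[perm]
      shuffled$core$entry_offset[idx] <- lt$core$entry_offset[perm]
      shuffled$core$entry_suffix[, idx] <- lt$core$entry_suffix[, perm]
    }
  })
  after <- scan_subject(mut$seq, shuffled, p)
  cols <- c("query", "diag_lo", "diag_hi", "s_lo", "s_hi", "q_lo", "q_hi", "score")
  ord <- function(z) {
    z <- z[do.call(order, z[cols]), cols]
    rownames(z) <- NULL
    z
  }
  expect_identical(ord(before), ord(after))
})

test_that("overlong subjects are rejected by name of the limit", {
  qs <- random_proteome(1L, 100L, seed = 58)
  lt <- build_lookup_table(qs, BL62, k = 5, approx = 1.0)
  p <- search_params(max_subject_len = 150L)
  expect_error(scan_subject(strrep("A", 200), lt, p), "max_subject_len")
})

test_that("single-linkage clustering merges compatible zones only", {
  p <- search_params(gip = 11, gep = 1)
  one <- zone_row(score = 40L)
  expect_identical(cluster_zones(one, p), one)

  # two strong collinear zones 20 diagonals apart: 100 + 100 > 31
  strong <- rbind(zone_row(zone_id = 0L, diag_lo = 0L, diag_hi = 0L,
                           s_lo = 0L, s_hi = 49L, q_lo = 0L, q_hi = 49L,
                           score = 100L),
                  zone_row(zone_id = 1L, diag_lo = 20L, diag_hi = 20L,
                           s_lo = 60L, s_hi = 109L, q_lo = 80L, q_hi = 129L,
                           score = 100L))
  m <- cluster_zones(strong, p)
  expect_identical(nrow(m), 1L)
  expect_identical(c(m$diag_lo, m$diag_hi), c(0L, 20L))
  expect_identical(c(m$s_lo, m$s_hi, m$q_lo, m$q_hi), c(0L, 109L, 0L, 129L))
  expect_equal(m$score, 100 + 100 - affine_gap_penalty(20, p))

  # weak pair: 12 + 12 <= penalty 31 -> two zones out
  weak <- strong
  weak$score <- c(12L, 12L)
  expect_identical(nrow(cluster_zones(weak, p)), 2L)

  # zones of different queries are never linked
  cross <- strong
  cross$query <- c(1L, 2L)
  expect_identical(nrow(cluster_zones(cross, p)), 2L)
})
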