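test_that("ungapped extension recovers identical sequences in full", {
  q <- "ACDEFGHIK"
  h <- ungapped_extend(q, q, 2, 2, k = 4)
  expect_equal(h$raw_score, 53)   # BLOSUM62 diagonal sum A+C+D+E+F+G+H+I+K
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(0, 9, 0, 9))
  expect_equal(h$identities, 9L)
  expect_equal(h$path, strrep("M", 9))
})

test_that("extension never scores below the bare seed", {
  m <- load_matrix()
  set.seed(31)
  for (i in 1:30) {
    q <- random_protein(60); s <- random_protein(60)
    mm <- helper_kmer_matches(q, s, 3)
    if (!nrow(mm)) next
    for (j in seq_len(nrow(mm))) {
      seed_score <- sum(vapply(0:2, function(t)
        m[substr(q, mm$q_pos[j] + 1 + t, mm$q_pos[j] + 1 + t),
          substr(s, mm$s_pos[j] + 1 + t, mm$s_pos[j] + 1 + t)], 0L))
      h <- ungapped_extend(q, s, mm$q_pos[j], mm$s_pos[j], k = 3)
      expect_gte(h$raw_score, seed_score)
    }
  }
})

test_that("X-drop confines an HSP between hostile flanks", {
  core <- "ACDEFGHIKLMNPQRS"
  q <- paste0(strrep("*", 8), core, strrep("*", 8))
  s <- paste0(random_protein(8), core, random_protein(8))
  set.seed(32)
  h <- ungapped_extend(q, s, 8 + 4, 8 + 4, k = 4, x_drop = 20)
  expect_equal(c(h$q_start, h$q_end), c(8, 8 + nchar(core)))
  expect_equal(c(h$s_start, h$s_end), c(8, 8 + nchar(core)))
})

test_that("gapped extension of identical sequences opens no gap", {
  set.seed(33)
  q <- random_protein(120)
  u <- ungapped_extend(q, q, 50, 50, k = 4)
  g <- gapped_extend(u, q, q)
  expect_equal(g$raw_score, u$raw_score)
  expect_equal(g$gap_opens, 0L)
})

test_that("a single deletion costs exactly one gap open", {
  set.seed(34)
  q <- random_protein(100)
  s <- paste0(substr(q, 1, 50), substr(q, 52, 100))   # residue 51 deleted
  u <- ungapped_extend(q, s, 10, 10, k = 4)
  g <- gapped_extend(u, q, s)
  expect_equal(g$raw_score, helper_sw_score(q, s))    # brute-force full DP
  expect_equal(g$gap_opens, 1L)
  rep <- replay_alignment(g$path, q, s, g$q_start, g$s_start)
  expect_equal(rep$score, g$raw_score)
})

test_that("widening the band never decreases the gapped score", {
  set.seed(35)
  q <- random_protein(150)
  s <- mutate_homolog(q, 0.75, 0.02)$residues
  u <- ungapped_extend(q, s, helper_kmer_matches(q, s, 4)$q_pos[1],
                       helper_kmer_matches(q, s, 4)$s_pos[1], k = 4)
  scores <- vapply(c(4, 8, 16, 32, 64, 128), function(bw)
    gapped_extend(u, q, s, band_width = bw)$raw_score, 0)
  expect_true(all(diff(scores) >= 0))
  expect_gte(gapped_extend(u, q, s)$raw_score, u$raw_score)
})

test_that("the Smith-Waterman oracle matches hand and brute-force scores", {
  h <- smith_waterman("ACDE", "ACDE")
  expect_equal(h$raw_score, 24)                       # 4 + 9 + 6 + 5
  expect_equal(h$path, "MMMM")
  set.seed(36)
  for (i in 1:25) {
    q <- random_protein(sample(5:30, 1))
    s <- random_protein(sample(5:30, 1))
    expect_equal(smith_waterman(q, s)$raw_score, helper_sw_score(q, s))
    expect_equal(smith_waterman(q, s)$raw_score,
                 smith_waterman(s, q)$raw_score)      # objective symmetry
  }
})

test_that("the oracle agrees with Biostrings local alignment", {
  skip_if_not_installed("Biostrings")
  m24 <- load_matrix()[1:24, 1:24]                    # drop U for Biostrings
  set.seed(37)
  for (i in 1:20) {
    q <- random_protein(sample(20:80, 1))
    s <- if (i %% 2) random_protein(sample(20:80, 1)) else
      mutate_homolog(random_protein(60), 0.7, 0.02)$residues
    bs <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(s),
      substitutionMatrix = m24, gapOpening = 10, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
    expect_equal(smith_waterman(q, s)$raw_score, max(bs, 0))
  }
})

test_that("every heuristic HSP is dominated by the oracle and replays exactly", {
  set.seed(38)
  for (i in 1:40) {
    q <- random_protein(sample(40:150, 1))
    s <- if (i %% 2) random_protein(sample(40:150, 1)) else
      mutate_homolog(q, runif(1, 0.5, 0.95), 0.02)$residues
    sw <- smith_waterman(q, s)$raw_score
    h <- helper_pair_best_hsp(q, s)
    if (is.null(h)) next
    expect_lte(h$raw_score, sw)
    rep <- replay_alignment(h$path, q, s, h$q_start, h$s_start)
    expect_identical(rep$score, h$raw_score)
    expect_equal(rep$q_len, h$q_end - h$q_start)
    expect_equal(rep$s_len, h$s_end - h$s_start)
  }
})

test_that("the heuristic ties the oracle on an exact self-copy", {
  set.seed(39)
  for (len in c(60, 150, 300)) {
    q <- random_protein(len)
    h <- helper_pair_best_hsp(q, q)
    expect_equal(h$raw_score, smith_waterman(q, q)$raw_score)
    expect_equal(h$identities, len)
  }
})
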