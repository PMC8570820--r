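test_that("an exact copy in the reference is the rank-1 hit", {
  set.seed(41)
  q <- aa_set("probe", random_protein(80))
  decoys <- vapply(rep(90, 30), random_protein, "")
  ref <- aa_set(c(sprintf("S1|d%02d", 1:30), "S2|copy"),
                c(decoys, q$residues[1]))
  res <- pzsearch(q, ref)
  expect_gte(nrow(res$hits), 1L)
  expect_equal(res$hits$subject_id[1], "S2|copy")
  expect_equal(res$hits$pct_identity[1], 100)
  expect_lte(res$hits$evalue[1], 1e-8)
  expect_equal(res$hits$q_start[1], 1L)
  expect_equal(res$hits$q_end[1], 80L)
})

test_that("a reference with no shared k-words yields no hits", {
  q <- aa_set("q", strrep("MKVLADE", 10))
  ref <- aa_set("S1|w", strrep("W", 100))
  res <- pzsearch(q, ref)
  expect_equal(nrow(res$hits), 0L)
})

test_that("an empty reference warns and returns empty results", {
  q <- aa_set("q", strrep("MKVLADE", 10))
  empty <- aa_set("x", "MK")[0, ]
  class(empty) <- c("aa_set", "data.frame")
  expect_warning(res <- pzsearch(q, empty), "empty reference")
  expect_equal(nrow(res$hits), 0L)
})

test_that("the query submission limit is enforced by search", {
  n <- 10001L
  big <- aa_set(sprintf("q%05d", seq_len(n)), rep("MKVLAMKVLA", n))
  ref <- aa_set("S|r", "MKVLAMKVLA")
  expect_error(pzsearch(big, ref), "maximum of 10000")
})

test_that("chunked search equals the exhaustive-pair heuristic", {
  sim <- fixture_small()
  q <- fixture_query300()
  res <- pzsearch(q, sim$reference)
  cfg <- search_config()
  params <- ka_params(cfg$lambda, cfg$K, TRUE, cfg$gap_open, cfg$gap_extend)
  n_total <- sum(sim$reference$length)
  # brute force: run the extension operators on every pair independently
  expected <- NULL
  for (r in seq_len(nrow(sim$reference))) {
    h <- helper_pair_best_hsp(q$residues[1], sim$reference$residues[r], cfg)
    if (is.null(h)) next
    ev <- evalue(h$raw_score, q$length[1], n_total, params)
    if (ev <= cfg$evalue_max)
      expected <- rbind(expected,
                        data.frame(subject_id = sim$reference$id[r],
                                   raw = h$raw_score, evalue = ev,
                                   stringsAsFactors = FALSE))
  }
  expected <- expected[order(expected$evalue, expected$subject_id), ]
  expect_equal(res$hits$subject_id, expected$subject_id)
  expect_equal(res$hits$evalue, expected$evalue)
})

test_that("merging one chunk is the identity", {
  sim <- fixture_small()
  q <- fixture_query300()
  cfg <- search_config()
  n_total <- sum(sim$reference$length)
  part <- search_chunk(q, sim$reference, cfg, n_total)
  merged <- merge_chunk_results(list(part), cfg)
  single <- pzsearch(q, sim$reference, cfg)
  expect_identical(pzsearch:::format_hit_lines(merged$hits),
                   pzsearch:::format_hit_lines(single$hits))
})

test_that("chunking and worker counts never change the hit table", {
  sim <- fixture_small()
  q <- fixture_query300()
  base <- pzsearch:::format_hit_lines(pzsearch(q, sim$reference)$hits)
  chunks <- as_chunks(sim$reference, 4)
  expect_identical(pzsearch:::format_hit_lines(pzsearch(q, chunks)$hits), base)
  for (w in c(2L, 4L)) {
    cfg <- search_config(workers = w)
    expect_identical(pzsearch:::format_hit_lines(pzsearch(q, chunks, cfg)$hits),
                     base)
  }
})

test_that("mismatched chunk configurations refuse to merge", {
  sim <- fixture_small()
  q <- fixture_query300()
  p1 <- search_chunk(q, sim$reference, search_config(), 1000)
  p2 <- search_chunk(q, sim$reference, search_config(evalue_max = 1e-4), 1000)
  expect_error(merge_chunk_results(list(p1, p2), search_config()),
               "different configurations")
  p3 <- search_chunk(q, sim$reference, search_config(), 2000)
  expect_error(merge_chunk_results(list(p1, p3), search_config()),
               "different configurations")
})

test_that("duplicate subject ids across chunks are a detected fixture error", {
  set.seed(42)
  q <- aa_set("q", random_protein(100))
  copy <- aa_set("S1|dup", q$residues[1])
  expect_error(pzsearch(q, list(copy, copy)), "duplicate subject id")
})

test_that("raising max_hits_per_query only appends hits", {
  sim <- fixture_small()
  q <- fixture_query300()
  h3 <- pzsearch(q, sim$reference, search_config(max_hits_per_query = 3))
  h10 <- pzsearch(q, sim$reference, search_config(max_hits_per_query = 10))
  expect_equal(nrow(h3$hits), 3L)
  expect_true(h3$truncated[["query300aa"]])
  expect_identical(pzsearch:::format_hit_lines(h3$hits),
                   pzsearch:::format_hit_lines(h10$hits)[1:3])
})

test_that("every reported E-value respects the cutoff, and cutoffs nest", {
  sim <- fixture_small()
  q <- fixture_query300()
  loose <- pzsearch(q, sim$reference, search_config(evalue_max = 1e-4))
  tight <- pzsearch(q, sim$reference, search_config(evalue_max = 1e-30))
  expect_true(all(loose$hits$evalue <= 1e-4))
  expect_true(all(tight$hits$evalue <= 1e-30))
  key <- function(h) paste(h$query_id, h$subject_id)
  expect_true(all(key(tight$hits) %in% key(loose$hits)))
})
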