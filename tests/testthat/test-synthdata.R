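test_that("generation is byte-identical under a fixed seed", {
  q <- fixture_query300()
  cfg <- sim_config(n_samples = 3L, seqs_per_sample = 10L,
                    planted = data.frame(query_id = "query300aa",
                                         n_copies = 4L, identity = 0.8,
                                         indel_rate = 0.01),
                    rng_seed = 99L)
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  r1 <- generate_reference(cfg, q, out_dir = d1, n_chunks = 2L)
  r2 <- generate_reference(cfg, q, out_dir = d2, n_chunks = 2L)
  for (i in seq_along(r1$paths$fasta))
    expect_identical(readLines(r1$paths$fasta[i]),
                     readLines(r2$paths$fasta[i]))
  expect_identical(readLines(r1$paths$metadata), readLines(r2$paths$metadata))
  expect_identical(readLines(r1$paths$planted_truth),
                   readLines(r2$paths$planted_truth))
  # a different seed changes the sequences
  cfg2 <- sim_config(n_samples = 3L, seqs_per_sample = 10L, rng_seed = 100L)
  r3 <- generate_reference(cfg2)
  expect_false(identical(r3$reference$residues[1], r1$reference$residues[1]))
})

test_that("output counts decompose into decoys plus planted copies", {
  q <- fixture_query300()
  cfg <- sim_config(n_samples = 20L, seqs_per_sample = 100L,
                    planted = data.frame(query_id = "query300aa",
                                         n_copies = 7L, identity = 1.0,
                                         indel_rate = 0))
  r <- generate_reference(cfg, q)
  expect_equal(nrow(r$reference), 20L * 100L + 7L)
  expect_equal(nrow(r$planted_truth), 7L)
  # identity 1, no indels: planted copies equal the query exactly
  planted_seqs <- r$reference$residues[match(r$planted_truth$subject_id,
                                             r$reference$id)]
  expect_true(all(planted_seqs == q$residues[1]))
  expect_true(all(r$planted_truth$realized_identity == 1))
})

test_that("planted truth ids resolve and identities recount correctly", {
  q <- fixture_query300()
  sim <- fixture_small()
  expect_true(all(sim$planted_truth$subject_id %in% sim$reference$id))
  # sample attribution embedded in the id matches the truth table
  expect_equal(sub("\\|.*$", "", sim$planted_truth$subject_id),
               sim$planted_truth$sample_id)
  # direct per-column recount of realized identity (no-indel homolog)
  set.seed(61)
  mut <- mutate_homolog(q$residues[1], 0.7, indel_rate = 0)
  a <- strsplit(q$residues[1], "")[[1]]
  b <- strsplit(mut$residues, "")[[1]]
  expect_equal(mut$realized_identity, mean(a == b))
  expect_equal(mut$n_substitutions, sum(a != b))
})

test_that("realized identity concentrates near its target", {
  q <- fixture_query300()
  set.seed(62)
  ids <- replicate(30, mutate_homolog(q$residues[1], 0.7,
                                      indel_rate = 0)$realized_identity)
  # binomial n = 300, p = 0.7: the 0.65-0.75 band holds w.p. > 0.99 per draw
  expect_true(mean(ids >= 0.65 & ids <= 0.75) >= 0.9)
  expect_true(abs(mean(ids) - 0.7) < 0.02)
})

test_that("mutation is reproducible under a fixed RNG state", {
  q <- fixture_query300()
  set.seed(63); m1 <- mutate_homolog(q$residues[1], 0.8, 0.05)
  set.seed(63); m2 <- mutate_homolog(q$residues[1], 0.8, 0.05)
  expect_identical(m1, m2)
  expect_error(mutate_homolog("MKVLA", 0.8), "nchar")
  expect_error(sim_config(planted = data.frame(query_id = "q", n_copies = 1,
                                               identity = 0, indel_rate = 0)),
               "identity")
})

test_that("metadata layout fits the summarization reader", {
  sim <- fixture_small()
  p <- helper_tmp()
  write.table(sim$metadata, p, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  md <- read_sample_metadata(p)
  expect_equal(md$sample_id, sim$metadata$sample_id)
  expect_true(all(grepl("\\|", md$env_class_ids)))
})

test_that("planted homologs at high identity are always recovered", {
  # sensitivity floor: realized identity >= 0.9 and length >= 100 implies
  # recovery at E <= 1e-8 under the default search configuration
  bench <- fixture_bench()
  strong <- bench$sim$planted_truth$subject_id[
    bench$sim$planted_truth$realized_identity >= 0.9]
  expect_gte(length(strong), 5L)   # realized identities scatter around 0.9
  expect_true(all(strong %in% bench$result$hits$subject_id))
})
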