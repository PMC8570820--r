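pairs_df <- function(q, s) data.frame(query_id = q, subject_id = s,
                                      stringsAsFactors = FALSE)

test_that("precision and recall use the floored two-decimal convention", {
  truth <- paste0("t", 1:303)
  expect_equal(precision_recall(truth, truth),
               list(precision_pct = 100, recall_pct = 100, tp = 303L,
                    n_predicted = 303L, n_truth = 303L))
  # all-true predictions of 215/221/224 pairs against 303 truth pairs
  expect_equal(precision_recall(truth[1:215], truth)$recall_pct, 70.95)
  expect_equal(precision_recall(truth[1:221], truth)$recall_pct, 72.93)
  expect_equal(precision_recall(truth[1:224], truth)$recall_pct, 73.92)
  # smaller truth set of 61 pairs
  t61 <- paste0("u", 1:61)
  expect_equal(precision_recall(t61[1:54], t61)$recall_pct, 88.52)
  pr <- precision_recall(c(t61[1:56], "fp1", "fp2"), t61)
  expect_equal(pr$precision_pct, 96.55)
  expect_equal(pr$recall_pct, 91.80)
  pr2 <- precision_recall(c(t61, paste0("fp", 1:6)), t61)
  expect_equal(pr2$precision_pct, 91.04)
  expect_equal(pr2$recall_pct, 100)
  # rounding would print 70.96/72.94/73.93 for the first three: flooring
  # is what reproduces the published convention
  expect_equal(round(100 * 215 / 303, 2), 70.96)
})

test_that("degenerate prediction/truth sets follow the stated conventions", {
  expect_equal(precision_recall(character(), character()),
               list(precision_pct = 100, recall_pct = 100, tp = 0L,
                    n_predicted = 0L, n_truth = 0L))
  pr <- precision_recall(character(), c("a", "b"))
  expect_true(is.na(pr$precision_pct))
  expect_equal(pr$recall_pct, 0)
})

test_that("precision_recall agrees with brute-force set intersection", {
  set.seed(51)
  for (i in 1:25) {
    universe <- paste0("p", 1:200)
    p <- sample(universe, sample(0:80, 1))
    t <- sample(universe, sample(1:80, 1))
    pr <- precision_recall(p, t)
    tp <- sum(p %in% t)
    expect_equal(pr$tp, tp)
    if (length(p))
      expect_equal(pr$precision_pct, floor(1e4 * tp / length(p) + 1e-9) / 100)
    expect_equal(pr$recall_pct, floor(1e4 * tp / length(t) + 1e-9) / 100)
  }
})

test_that("rates display with trailing zeros trimmed", {
  expect_equal(format_rate(c(91.80, 100, 96.55, NA)),
               c("91.8", "100", "96.55", "NA"))
})

test_that("ground truth contains the query copy and nests by threshold", {
  set.seed(52)
  q <- aa_set("q", random_protein(120))
  ref <- aa_set(c("S1|self", sprintf("S1|d%d", 1:25)),
                c(q$residues[1], vapply(rep(100, 25), random_protein, "")))
  t8 <- make_ground_truth(q, ref, threshold = 1e-8)
  expect_true("S1|self" %in% t8$pairs$subject_id)
  expect_true(all(t8$pairs$evalue <= 1e-8))
  # unrelated random pairs do not reach 1e-8
  expect_equal(nrow(t8$pairs), 1L)
  t10 <- make_ground_truth(q, ref, threshold = 1e-10)
  expect_true(all(t10$pairs$subject_id %in% t8$pairs$subject_id))
})

test_that("evaluate_tool deduplicates pairs and applies the threshold", {
  set.seed(53)
  q <- aa_set("q", random_protein(100))
  ref <- aa_set("S1|self", q$residues[1])
  truth <- make_ground_truth(q, ref)
  h <- data.frame(query_id = "q", subject_id = "S1|self",
                  pct_identity = 100, length = 100L, mismatches = 0L,
                  gap_opens = 0L, q_start = 1L, q_end = 100L,
                  s_start = 1L, s_end = 100L, evalue = 1e-40,
                  bit_score = 200, stringsAsFactors = FALSE)
  rep1 <- evaluate_tool(rbind(h, h), truth)   # duplicate HSP rows: one pair
  overall <- rep1[rep1$query_id == "overall", ]
  expect_equal(overall$predicted_hits, 1L)
  expect_equal(overall$precision_pct, 100)
  expect_equal(overall$recall_pct, 100)
  # empty predictions, non-empty truth
  rep2 <- evaluate_tool(h[0, ], truth)
  expect_equal(rep2$recall_pct[rep2$query_id == "overall"], 0)
  # above-threshold rows are excluded
  h$evalue <- 1e-4
  rep3 <- evaluate_tool(h, truth)
  expect_equal(rep3$predicted_hits[rep3$query_id == "overall"], 0L)
  # round-trip through the tabular format
  p <- helper_tmp()
  h$evalue <- 1e-40
  write_hits_tab(h, p)
  rep4 <- evaluate_tool(p, truth)
  expect_equal(rep4$true_positives[rep4$query_id == "overall"], 1L)
})
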