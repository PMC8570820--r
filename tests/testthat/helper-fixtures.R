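# Shared deterministic fixtures.  The benchmark fixture (20 samples x 250
# decoys, 60 planted homologs of a 300-residue query at identities
# 0.9/0.8/0.7/0.6, seed 42) is expensive, so it is built lazily once per
# test run and reused; the generator is deterministic so reuse is safe.

.fx_cache <- new.env(parent = emptyenv())

fixture_query300 <- function() {
  if (is.null(.fx_cache$q300)) {
    set.seed(7)
    .fx_cache$q300 <- aa_set("query300aa", random_protein(300))
  }
  .fx_cache$q300
}

fixture_planted_spec <- function() {
  data.frame(query_id = "query300aa", n_copies = 15L,
             identity = c(0.9, 0.8, 0.7, 0.6), indel_rate = 0.01)
}

# small variant for fast module tests
fixture_small <- function() {
  if (is.null(.fx_cache$small)) {
    q <- fixture_query300()
    cfg <- sim_config(n_samples = 5L, seqs_per_sample = 40L,
                      planted = fixture_planted_spec(), rng_seed = 42L)
    .fx_cache$small <- generate_reference(cfg, queries = q)
  }
  .fx_cache$small
}

# full benchmark fixture + its single-pass search result and ground truth
fixture_bench <- function() {
  if (is.null(.fx_cache$bench)) {
    q <- fixture_query300()
    cfg <- sim_config(planted = fixture_planted_spec(), rng_seed = 42L)
    sim <- generate_reference(cfg, queries = q)
    res <- pzsearch(q, sim$reference)
    .fx_cache$bench <- list(queries = q, sim = sim, result = res)
  }
  .fx_cache$bench
}

as_chunks <- function(ref, n) {
  idx <- rep(seq_len(n), length.out = nrow(ref))
  lapply(seq_len(n), function(i) {
    ch <- ref[idx == i, , drop = FALSE]
    class(ch) <- c("aa_set", "data.frame")
    ch
  })
}
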