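# Robinson-Robinson amino-acid background frequencies (the standard protein
# null model used with BLOSUM62 statistics), over the 20 canonical residues.
AA_BACKGROUND <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

#' Random protein sequence from the background model
#'
#' Residues are drawn i.i.d. from the Robinson-Robinson frequencies, the
#' null model under which the package's E-value statistics are calibrated.
#' Draws come from R's current RNG stream; call `set.seed()` for
#' reproducibility.
#'
#' @param length sequence length in residues.
#' @return A residue string.
#' @export
random_protein <- function(length) {
  paste(sample(names(AA_BACKGROUND), length, replace = TRUE,
               prob = AA_BACKGROUND), collapse = "")
}

#' Simulation configuration
#'
#' Describes a synthetic sample-annotated protein reference: `n_samples`
#' metagenome samples each contributing `seqs_per_sample` background decoy
#' sequences, plus planted homologs of chosen queries mutated to target
#' identities.  Defaults are the package's benchmark conditions: 20 samples
#' of 250 decoys (lengths uniform on 100-350 residues) and 60 planted
#' copies split evenly over identities 0.9/0.8/0.7/0.6 with indel rate 0.01.
#'
#' @param n_samples number of samples.
#' @param seqs_per_sample decoys per sample.
#' @param length_range decoy length bounds (uniform).
#' @param planted data frame with columns `query_id`, `n_copies`,
#'   `identity` (in (0, 1]) and `indel_rate` (in [0, 0.2]); `NULL` plants
#'   nothing.
#' @param class_pool character vector of `id|label` environment classes to
#'   sample from (with optional `weights` attribute).
#' @param body_pool `id|label` body-site classes attached to human-associated
#'   samples (first class of `class_pool`), or `NULL`.
#' @param coord_pool two-column matrix/data frame of latitude, longitude
#'   candidate locations; a row of `NA` leaves a sample unlocated.
#' @param multi_class when `TRUE`, samples may receive two environment
#'   classes (default `FALSE` so single-class invariants hold).
#' @param rng_seed integer seed; the same seed reproduces output files
#'   byte for byte.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 20L, seqs_per_sample = 250L,
                       length_range = c(100L, 350L), planted = NULL,
                       class_pool = default_class_pool(),
                       body_pool = default_body_pool(),
                       coord_pool = default_coord_pool(),
                       multi_class = FALSE, rng_seed = 42L) {
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("query_id", "n_copies", "identity", "indel_rate") %in%
                    names(planted)))
    if (any(planted$identity <= 0 | planted$identity > 1))
      stop("target identity must be in (0, 1]")
    if (any(planted$indel_rate < 0 | planted$indel_rate > 0.2))
      stop("indel_rate must be in [0, 0.2]")
  }
  structure(list(n_samples = as.integer(n_samples),
                 seqs_per_sample = as.integer(seqs_per_sample),
                 length_range = as.integer(length_range),
                 planted = planted, class_pool = class_pool,
                 body_pool = body_pool, coord_pool = coord_pool,
                 multi_class = isTRUE(multi_class),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

# Illustrative (synthetic) ontology classes and locations; identifiers are
# placeholders in the style of environment/body-site ontologies, not
# resolved terms.
default_class_pool <- function() {
  structure(c("ENV:0001|human gut", "ENV:0002|soil", "ENV:0003|marine water",
              "ENV:0004|freshwater", "ENV:0005|hot spring"),
            weights = c(0.35, 0.25, 0.2, 0.12, 0.08))
}
default_body_pool <- function() c("BODY:0001|colon", "BODY:0002|oral cavity")
default_coord_pool <- function() {
  data.frame(latitude = c(35.0, -23.5, 51.5, 64.1, NA),
             longitude = c(139.0, -46.6, -0.1, -21.9, NA))
}

#' Mutate a query into a planted homolog
#'
#' Each position is substituted with probability `1 - target_identity` to a
#' uniformly chosen different canonical residue; afterwards indel events
#' occur per column with probability `indel_rate`, with geometric lengths
#' (mean 1.5) and equal odds of insertion (background residues) or
#' deletion.  The realized identity is the fraction of unsubstituted
#' columns, recounted on the pre-indel sequence.  Uses R's current RNG
#' stream.
#'
#' @param query residue string of length >= 20.
#' @param target_identity in (0, 1].
#' @param indel_rate per-column indel probability, in [0, 0.2].
#' @return List with `residues`, `realized_identity`, `n_substitutions`,
#'   `n_insertions`, `n_deletions` and the pre-indel `substituted` string.
#' @export
mutate_homolog <- function(query, target_identity, indel_rate = 0) {
  stopifnot(nchar(query) >= 20, target_identity > 0, target_identity <= 1,
            indel_rate >= 0, indel_rate <= 0.2)
  chars <- strsplit(query, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  sub_at <- runif(n) < (1 - target_identity)
  for (i in which(sub_at)) {
    alt <- setdiff(AA_CANONICAL, chars[i])
    chars[i] <- alt[sample.int(length(alt), 1L)]
  }
  substituted <- paste(chars, collapse = "")
  realized <- sum(strsplit(substituted, "", fixed = TRUE)[[1L]] ==
                    strsplit(query, "", fixed = TRUE)[[1L]]) / n
  n_ins <- 0L; n_del <- 0L
  if (indel_rate > 0) {
    out <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      if (runif(1L) < indel_rate) {
        len <- 1L + rgeom(1L, 1 / 1.5)
        if (runif(1L) < 0.5) {
          ins <- sample(names(AA_BACKGROUND), len, replace = TRUE,
                        prob = AA_BACKGROUND)
          out <- c(out, ins, chars[i])
          n_ins <- n_ins + len
          i <- i + 1L
        } else {
          drop_to <- min(length(chars), i + len - 1L)
          n_del <- n_del + (drop_to - i + 1L)
          i <- drop_to + 1L
        }
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    chars <- out
  }
  list(residues = paste(chars, collapse = ""),
       realized_identity = realized,
       n_substitutions = sum(sub_at),
       n_insertions = n_ins, n_deletions = n_del,
       substituted = substituted)
}

#' Generate a synthetic sample-annotated reference
#'
#' Emulates the product of a large metagenome-derived protein collection at
#' desk scale: every sample contributes background decoy sequences and is
#' annotated with an environment class, an optional body-site class and
#' optional coordinates; planted homologs of the supplied queries are spread
#' over samples round-robin and recorded in a truth table.  Output is
#' deterministic (byte-identical files) for a fixed `rng_seed`.
#'
#' Sequence ids follow the `sampleID|sequenceID` convention that the rest of
#' the package uses for sample attribution.
#'
#' @param config a [sim_config()].
#' @param queries an [aa_set] providing the sequences named by
#'   `config$planted` (may be `NULL` when nothing is planted).
#' @param out_dir when non-`NULL`, FASTA chunk(s) `reference_###.faa`,
#'   `samples.tsv` and `planted_truth.tsv` are written there.
#' @param n_chunks number of FASTA chunks to split the reference over.
#' @return List with `reference` (an [aa_set]), `metadata`
#'   (sample_metadata), `planted_truth` (data frame `subject_id`,
#'   `query_id`, `target_identity`, `realized_identity`, `sample_id`) and
#'   `paths` (written files, or `NULL`).
#' @export
generate_reference <- function(config = sim_config(), queries = NULL,
                               out_dir = NULL, n_chunks = 1L) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$rng_seed)
  ns <- config$n_samples
  sample_ids <- sprintf("S%03d", seq_len(ns))
  # per-sample annotations
  w <- attr(config$class_pool, "weights")
  if (is.null(w)) w <- rep(1, length(config$class_pool))
  env1 <- sample(config$class_pool, ns, replace = TRUE, prob = w)
  env2 <- if (config$multi_class) {
    extra <- sample(config$class_pool, ns, replace = TRUE, prob = w)
    ifelse(runif(ns) < 0.3 & extra != env1, extra, NA_character_)
  } else rep(NA_character_, ns)
  env_col <- ifelse(is.na(env2), env1, paste(env1, env2, sep = ";"))
  body_col <- ifelse(env1 == config$class_pool[1L] &
                       !is.null(config$body_pool),
                     sample(config$body_pool, ns, replace = TRUE),
                     "")
  coord_idx <- sample.int(nrow(config$coord_pool), ns, replace = TRUE)
  metadata <- data.frame(sample_id = sample_ids,
                         env_class_ids = env_col,
                         body_class_ids = body_col,
                         latitude = config$coord_pool$latitude[coord_idx],
                         longitude = config$coord_pool$longitude[coord_idx],
                         stringsAsFactors = FALSE)
  class(metadata) <- c("sample_metadata", "data.frame")
  # decoys
  lens <- sample(seq(config$length_range[1L], config$length_range[2L]),
                 ns * config$seqs_per_sample, replace = TRUE)
  decoy_sample <- rep(sample_ids, each = config$seqs_per_sample)
  decoy_num <- rep(seq_len(config$seqs_per_sample), times = ns)
  decoy_ids <- sprintf("%s|d%04d", decoy_sample, decoy_num)
  decoy_seqs <- vapply(lens, random_protein, "")
  # planted homologs, spread round-robin over samples
  planted_ids <- character(0); planted_seqs <- character(0)
  truth <- data.frame(subject_id = character(), query_id = character(),
                      target_identity = numeric(),
                      realized_identity = numeric(),
                      sample_id = character(), stringsAsFactors = FALSE)
  if (!is.null(config$planted) && nrow(config$planted)) {
    stopifnot(inherits(queries, "aa_set"))
    counter <- 0L
    for (p in seq_len(nrow(config$planted))) {
      qrow <- match(config$planted$query_id[p], queries$id)
      if (is.na(qrow))
        stop("planted query '", config$planted$query_id[p],
             "' not found in queries")
      for (cp in seq_len(config$planted$n_copies[p])) {
        counter <- counter + 1L
        smp <- sample_ids[((counter - 1L) %% ns) + 1L]
        mut <- mutate_homolog(queries$residues[qrow],
                              config$planted$identity[p],
                              config$planted$indel_rate[p])
        sid <- sprintf("%s|p%04d", smp, counter)
        planted_ids <- c(planted_ids, sid)
        planted_seqs <- c(planted_seqs, mut$residues)
        truth <- rbind(truth, data.frame(
          subject_id = sid, query_id = queries$id[qrow],
          target_identity = config$planted$identity[p],
          realized_identity = mut$realized_identity,
          sample_id = smp, stringsAsFactors = FALSE))
      }
    }
  }
  reference <- aa_set(id = c(decoy_ids, planted_ids),
                      residues = c(decoy_seqs, planted_seqs),
                      sample_id = c(decoy_sample, truth$sample_id))
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    n_chunks <- max(1L, as.integer(n_chunks))
    idx <- split(seq_len(nrow(reference)),
                 rep(seq_len(n_chunks), length.out = nrow(reference)))
    fasta_paths <- character(n_chunks)
    for (ci in seq_len(n_chunks)) {
      fasta_paths[ci] <- file.path(out_dir,
                                   sprintf("reference_%03d.faa", ci))
      chunk <- reference[idx[[ci]], , drop = FALSE]
      class(chunk) <- c("aa_set", "data.frame")
      write_fasta(chunk, fasta_paths[ci])
    }
    md_path <- file.path(out_dir, "samples.tsv")
    write.table(metadata, md_path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    truth_path <- file.path(out_dir, "planted_truth.tsv")
    write.table(truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- list(fasta = fasta_paths, metadata = md_path,
                  planted_truth = truth_path)
  }
  list(reference = reference, metadata = metadata, planted_truth = truth,
       paths = paths)
}
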