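#' Search configuration
#'
#' Collects every tunable of the seed-and-extend search.  Defaults are the
#' package's declared operating point: BLOSUM62 with gap open 11 / extend 1,
#' exact 4-mer one-hit seeding, ungapped X-drop 20, gapped trigger 22 bits,
#' gapped X-drop 38 in a 64-diagonal band, E-value cutoff 1e-8, at most
#' 10000 hits reported per query and at most 10000 query sequences per
#' submission.
#'
#' @param k seed length (residues).
#' @param matrix_name built-in matrix name, see [load_matrix()].
#' @param gap_open,gap_extend affine gap costs.
#' @param x_drop_ungapped,x_drop_gapped raw-score drop-offs.
#' @param band_width diagonals explored around the gapped-extension anchor.
#' @param trigger_bits ungapped bit score required to trigger gapped
#'   extension.
#' @param evalue_max report hits with E-value at or below this cutoff.
#' @param max_hits_per_query per-query report truncation.
#' @param max_queries submission limit.
#' @param workers reference chunks are processed in this many parallel
#'   workers; results are independent of the worker count.
#' @param lambda,K Karlin-Altschul statistics, see [ka_params()].
#' @param total_reference_residues optional override of the search-space
#'   denominator (otherwise the grand total over all chunks is used).
#' @param mask_x skip seed words containing `X`.
#' @return A list of class `search_config`.
#' @export
search_config <- function(k = 4L, matrix_name = "BLOSUM62",
                          gap_open = 11L, gap_extend = 1L,
                          x_drop_ungapped = 20L, x_drop_gapped = 38L,
                          band_width = 64L, trigger_bits = 22,
                          evalue_max = 1e-8, max_hits_per_query = 10000L,
                          max_queries = 10000L, workers = 1L,
                          lambda = 0.267, K = 0.041,
                          total_reference_residues = NULL, mask_x = TRUE) {
  if (!(evalue_max > 0)) stop("evalue_max must be > 0")
  if (max_hits_per_query < 1L) stop("max_hits_per_query must be >= 1")
  if (workers < 1L) stop("workers must be >= 1")
  structure(list(k = as.integer(k), matrix_name = matrix_name,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 x_drop_ungapped = as.integer(x_drop_ungapped),
                 x_drop_gapped = as.integer(x_drop_gapped),
                 band_width = as.integer(band_width),
                 trigger_bits = trigger_bits,
                 evalue_max = evalue_max,
                 max_hits_per_query = as.integer(max_hits_per_query),
                 max_queries = as.integer(max_queries),
                 workers = as.integer(workers),
                 lambda = lambda, K = K,
                 total_reference_residues = total_reference_residues,
                 mask_x = isTRUE(mask_x)),
            class = "search_config")
}

config_params <- function(config) {
  ka_params(lambda = config$lambda, K = config$K, gapped = TRUE,
            gap_open = config$gap_open, gap_extend = config$gap_extend)
}

# fields that must agree for chunk results to be mergeable
config_digest <- function(config, n_total) {
  keep <- config[setdiff(names(config), c("workers",
                                          "total_reference_residues"))]
  paste(c(vapply(keep, function(v) paste(format(v, digits = 17),
                                         collapse = ","), ""),
          format(n_total)), collapse = ";")
}

as_chunk_list <- function(db) {
  if (inherits(db, "aa_set")) return(list(db))
  if (is.character(db)) {
    if (length(db) == 1L && dir.exists(db))
      db <- sort(list.files(db, pattern = "\\.(fa|faa|fasta)$",
                            full.names = TRUE))
    return(lapply(db, read_fasta, mode = "lenient"))
  }
  if (is.list(db) && all(vapply(db, inherits, TRUE, "aa_set"))) return(db)
  stop("'db' must be FASTA path(s), a directory, an aa_set, or a list of aa_sets")
}

#' Search queries against a chunked protein reference
#'
#' Builds a k-mer index over the queries, streams every reference chunk past
#' it, extends seeds into gapped HSPs, keeps the best HSP per
#' (query, subject) pair, converts raw scores to Karlin-Altschul E-values
#' against the grand-total reference residue count, and reports hits with
#' `E <= evalue_max`, ranked by (E-value, bit score, subject id) and
#' truncated to `max_hits_per_query`.  Results are identical regardless of
#' how the reference is chunked or how many workers are used.
#'
#' @param queries an [aa_set] or FASTA path.
#' @param db reference: FASTA path(s), a directory of FASTA chunks, an
#'   [aa_set], or a list of aa_sets (one per chunk).
#' @param config a [search_config()].
#' @return An object of class `pzsearch_result`: list with `hits` (the
#'   12-column hit table of [read_hits_tab()]), `n_candidates` (pairs that
#'   reached extension), `truncated` (per-query logical), `config` and
#'   `total_reference_residues`.
#' @export
pzsearch <- function(queries, db, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  if (is.character(queries)) queries <- read_fasta(queries)
  stopifnot(inherits(queries, "aa_set"))
  if (nrow(queries) > config$max_queries)
    stop("query set has ", nrow(queries),
         " sequences, exceeding the maximum of ", config$max_queries,
         " sequences per submission")
  chunks <- as_chunk_list(db)
  nref <- sum(vapply(chunks, nrow, 0L))
  if (nref == 0L) {
    warning("empty reference: no hits")
    return(finalize_result(list(), queries, config, 0))
  }
  all_subjects <- unlist(lapply(chunks, `[[`, "id"))
  if (anyDuplicated(all_subjects))
    stop("duplicate subject id(s) across reference chunks: ",
         paste(utils::head(unique(all_subjects[duplicated(all_subjects)]), 3L),
               collapse = ", "))
  n_total <- config$total_reference_residues
  if (is.null(n_total))
    n_total <- sum(vapply(chunks, function(ch) sum(ch$length), 0))
  index <- build_index(queries, k = config$k, mask_x = config$mask_x,
                       max_queries = config$max_queries)
  run_one <- function(chunk) search_chunk(queries, chunk, config,
                                          n_total, index = index)
  partials <- if (config$workers > 1L && length(chunks) > 1L) {
    parallel::mclapply(chunks, run_one, mc.cores = config$workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(chunks, run_one)
  }
  merge_chunk_results(partials, config)
}

#' Search one reference chunk
#'
#' The per-worker unit of the data-parallel contract: scans and extends one
#' chunk, scoring E-values against the grand-total residue count supplied by
#' the caller so that chunked and single-pass runs agree exactly.
#'
#' @param queries an [aa_set].
#' @param chunk an [aa_set] holding one reference chunk.
#' @param config a [search_config()].
#' @param total_reference_residues grand-total residue count over all chunks.
#' @param index optional prebuilt [build_index()] (rebuilt when `NULL`).
#' @return A `pzsearch_partial` list consumed by [merge_chunk_results()].
#' @export
search_chunk <- function(queries, chunk, config, total_reference_residues,
                         index = NULL) {
  stopifnot(inherits(queries, "aa_set"), inherits(chunk, "aa_set"))
  if (is.null(index))
    index <- build_index(queries, k = config$k, mask_x = config$mask_x,
                         max_queries = config$max_queries)
  matrix <- load_matrix(config$matrix_name)
  ab <- paste(rownames(matrix), collapse = "")
  params <- config_params(config)
  trigger_raw <- raw_for_bits(config$trigger_bits, params)
  rows <- vector("list", nrow(chunk))
  n_cand <- 0L
  for (r in seq_len(nrow(chunk))) {
    seeds <- scan_reference(index, chunk$residues[r])
    if (nrow(seeds) == 0L) next
    seeds <- collapse_seeds(seeds, config$k)
    hsps <- cpp_extend_seeds(queries$residues, chunk$residues[r],
                             seeds$q_ord, seeds$q_pos, seeds$s_pos,
                             config$k, matrix, ab,
                             config$gap_open, config$gap_extend,
                             config$x_drop_ungapped, config$x_drop_gapped,
                             config$band_width %/% 2L, trigger_raw)
    if (nrow(hsps) == 0L) next
    n_cand <- n_cand + length(unique(hsps$q_ord))
    # best HSP per query for this subject (deterministic tie-break)
    alen <- nchar(hsps$path)
    o <- order(hsps$q_ord, -hsps$raw_score, hsps$q_start, hsps$s_start,
               alen, method = "radix")
    hsps <- hsps[o[!duplicated(hsps$q_ord[o])], , drop = FALSE]
    ev <- evalue(hsps$raw_score, queries$length[hsps$q_ord],
                 total_reference_residues, params)
    keep <- ev <= config$evalue_max
    if (!any(keep)) next
    hsps <- hsps[keep, , drop = FALSE]
    alen <- nchar(hsps$path)
    rows[[r]] <- data.frame(
      query_id = queries$id[hsps$q_ord],
      subject_id = chunk$id[r],
      pct_identity = round(100 * hsps$identities / alen, 2L),
      length = alen,
      mismatches = hsps$match_cols - hsps$identities,
      gap_opens = hsps$gap_opens,
      q_start = hsps$q_start + 1L, q_end = hsps$q_end,
      s_start = hsps$s_start + 1L, s_end = hsps$s_end,
      evalue = ev[keep],
      bit_score = raw_to_bits(hsps$raw_score, params),
      stringsAsFactors = FALSE
    )
  }
  hits <- if (any(!vapply(rows, is.null, TRUE)))
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)]) else empty_hit_table()
  structure(list(hits = hits, n_candidates = n_cand,
                 digest = config_digest(config, total_reference_residues),
                 total_reference_residues = total_reference_residues,
                 query_ids = queries$id),
            class = "pzsearch_partial")
}

#' Merge per-chunk search results
#'
#' Produces a ranking identical to a single-pass search over the
#' concatenated reference.  Partials must have been computed with an
#' identical configuration and the same grand-total residue count.
#'
#' @param partials list of `pzsearch_partial` objects from [search_chunk()].
#' @param config the shared [search_config()].
#' @return A `pzsearch_result`, as for [pzsearch()].
#' @export
merge_chunk_results <- function(partials, config) {
  stopifnot(length(partials) >= 1L,
            all(vapply(partials, inherits, TRUE, "pzsearch_partial")))
  digests <- vapply(partials, `[[`, "", "digest")
  if (length(unique(digests)) != 1L)
    stop("chunk results were computed with different configurations ",
         "or reference totals and cannot be merged")
  hits <- do.call(rbind, lapply(partials, `[[`, "hits"))
  pair <- paste(hits$query_id, hits$subject_id, sep = "\r")
  if (anyDuplicated(pair))
    stop("the same (query, subject) pair appears in multiple chunks; ",
         "subject ids must be unique across chunks")
  res <- finalize_result(hits, NULL, config,
                         partials[[1L]]$total_reference_residues,
                         query_ids = partials[[1L]]$query_ids)
  res$n_candidates <- sum(vapply(partials, `[[`, 0L, "n_candidates"))
  res
}

finalize_result <- function(hits, queries, config, n_total,
                            query_ids = NULL) {
  if (is.null(query_ids) && !is.null(queries)) query_ids <- queries$id
  if (!is.data.frame(hits) || is.null(hits) || length(hits) == 0L ||
      nrow(hits) == 0L) {
    hits <- empty_hit_table()
    truncated <- setNames(logical(length(query_ids)), query_ids)
  } else {
    o <- order(hits$query_id, hits$evalue, -hits$bit_score, hits$subject_id,
               method = "radix")
    hits <- hits[o, , drop = FALSE]
    rank_in_query <- stats::ave(seq_len(nrow(hits)), hits$query_id,
                                FUN = seq_along)
    truncated_ids <- unique(hits$query_id[rank_in_query >
                                            config$max_hits_per_query])
    hits <- hits[rank_in_query <= config$max_hits_per_query, , drop = FALSE]
    rownames(hits) <- NULL
    truncated <- setNames(query_ids %in% truncated_ids, query_ids)
  }
  structure(list(hits = hits, n_candidates = 0L, truncated = truncated,
                 config = config, total_reference_residues = n_total),
            class = "pzsearch_result")
}

#' @export
print.pzsearch_result <- function(x, ...) {
  cat("pzsearch_result:", nrow(x$hits), "hit(s) for", length(x$truncated),
      if (length(x$truncated) == 1L) "query" else "queries", "\n")
  cat("  search space:", format(x$total_reference_residues, big.mark = ","),
      "reference residues | E <=", format(x$config$evalue_max), "\n")
  if (any(x$truncated))
    cat("  truncated at", x$config$max_hits_per_query, "hits:",
        paste(names(x$truncated)[x$truncated], collapse = ", "), "\n")
  if (nrow(x$hits)) {
    cat("  top hits:\n")
    top <- utils::head(x$hits, 5L)
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %s -> %s  id %.2f%%  E %.1e  bits %.1f\n",
                  top$query_id[i], top$subject_id[i], top$pct_identity[i],
                  top$evalue[i], top$bit_score[i]))
  }
  invisible(x)
}
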