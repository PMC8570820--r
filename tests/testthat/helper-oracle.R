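# Independent pure-R oracles, written separately from the package internals.

# Exhaustive affine-gap Smith-Waterman score (gap of length L costs
# open + (L-1)*ext).  O(mn) loops in plain R: test-scale only.
helper_sw_score <- function(q, s, mat = load_matrix(), open = 11, ext = 1) {
  qi <- strsplit(q, "", fixed = TRUE)[[1L]]
  si <- strsplit(s, "", fixed = TRUE)[[1L]]
  m <- length(qi); n <- length(si)
  H <- matrix(0, m + 1L, n + 1L)
  E <- matrix(-Inf, m + 1L, n + 1L)
  F <- matrix(-Inf, m + 1L, n + 1L)
  best <- 0
  for (i in seq_len(m) + 1L) {
    for (j in seq_len(n) + 1L) {
      E[i, j] <- max(H[i, j - 1L] - open, E[i, j - 1L] - ext)
      F[i, j] <- max(H[i - 1L, j] - open, F[i - 1L, j] - ext)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[qi[i - 1L], si[j - 1L]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Brute-force all-pairs k-word comparison between a query set and one
# reference string: the double-loop oracle for the seed scanner.
helper_kmer_matches <- function(queries, ref, k, mask_x = TRUE) {
  out <- NULL
  for (qi in seq_along(queries)) {
    q <- queries[qi]
    if (nchar(q) < k || nchar(ref) < k) next
    for (qp in seq_len(nchar(q) - k + 1L)) {
      w <- substr(q, qp, qp + k - 1L)
      if (grepl("*", w, fixed = TRUE)) next
      if (mask_x && grepl("X", w, fixed = TRUE)) next
      for (sp in seq_len(nchar(ref) - k + 1L)) {
        if (substr(ref, sp, sp + k - 1L) == w)
          out <- rbind(out, data.frame(q_ord = qi, q_pos = qp - 1L,
                                       s_pos = sp - 1L))
      }
    }
  }
  if (is.null(out))
    return(data.frame(q_ord = integer(), q_pos = integer(),
                      s_pos = integer()))
  out[order(out$q_ord, out$s_pos - out$q_pos, out$q_pos), , drop = FALSE]
}

# Heuristic best hit for one (query, subject) pair, driven by the
# brute-force seed finder but the package's extension operators: the
# exhaustive-pair route the chunked search must agree with.
helper_pair_best_hsp <- function(q, s, config = search_config(),
                                 mat = load_matrix(config$matrix_name)) {
  m <- helper_kmer_matches(q, s, config$k, config$mask_x)
  m$diagonal <- m$s_pos - m$q_pos
  m <- collapse_seeds(m, config$k)
  params <- ka_params(config$lambda, config$K, TRUE,
                      config$gap_open, config$gap_extend)
  trigger <- pzsearch:::raw_for_bits(config$trigger_bits, params)
  best <- NULL
  hsps <- list()
  if (nrow(m)) for (i in seq_len(nrow(m))) {
    k <- config$k
    contained <- any(vapply(hsps, function(h)
      m$q_pos[i] >= h$q_start && m$q_pos[i] + k <= h$q_end &&
        m$s_pos[i] >= h$s_start && m$s_pos[i] + k <= h$s_end, TRUE))
    if (contained) next    # same containment policy as the search driver
    u <- ungapped_extend(q, s, m$q_pos[i], m$s_pos[i], k, mat,
                         config$x_drop_ungapped)
    if (u$raw_score < trigger) next
    g <- gapped_extend(u, q, s, mat, config$gap_open, config$gap_extend,
                       config$x_drop_gapped, config$band_width)
    hsps[[length(hsps) + 1L]] <- g
    if (is.null(best) || g$raw_score > best$raw_score) best <- g
  }
  best
}

helper_tmp <- function(ext = ".tsv") tempfile(fileext = ext)
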