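#' Build a k-mer seed index over the query set
#'
#' The index is built over the (small) query set so that the (large)
#' reference can be streamed past it: each length-`k` residue word maps to
#' the postings list of (query ordinal, query offset) pairs at which it
#' occurs.  Words containing `*` are never indexed; words containing `X`
#' are skipped by default.  Queries shorter than `k` are excluded from
#' seeding with a warning (they remain reachable through the
#' Smith-Waterman oracle).
#'
#' @param queries an [aa_set] of query sequences.
#' @param k seed length in residues (>= 2), default 4.
#' @param mask_x skip words containing `X` (default `TRUE`).
#' @param max_queries submission limit; exceeding it is an error
#'   (default 10000).
#' @return An object of class `seed_index` with elements `k`, `postings`
#'   (hashed environment word -> integer matrix with rows `ord`, `off`),
#'   `query_ids`, `query_lengths`, `n_queries`, `total_postings`.
#' @export
build_index <- function(queries, k = 4L, mask_x = TRUE, max_queries = 10000L) {
  stopifnot(inherits(queries, "aa_set"))
  k <- as.integer(k)
  if (k < 2L) stop("seed length k must be >= 2")
  n <- nrow(queries)
  if (n < 1L) stop("no query sequences")
  if (n > max_queries)
    stop("query set has ", n, " sequences, exceeding the maximum of ",
         max_queries, " sequences per submission")
  short <- queries$length < k
  if (any(short))
    warning(sum(short), " quer", if (sum(short) == 1L) "y" else "ies",
            " shorter than k=", k, " excluded from seeding: ",
            paste(utils::head(queries$id[short], 5L), collapse = ", "))
  env <- new.env(hash = TRUE, parent = emptyenv())
  total <- 0L
  for (i in seq_len(n)) {
    L <- queries$length[i]
    if (L < k) next
    np <- L - k + 1L
    words <- substring(queries$residues[i], seq_len(np), seq_len(np) + k - 1L)
    keep <- !grepl("*", words, fixed = TRUE)
    if (mask_x) keep <- keep & !grepl("X", words, fixed = TRUE)
    offs <- which(keep) - 1L             # 0-based query offsets
    total <- total + length(offs)
    for (w in unique(words[keep])) {
      at <- offs[words[keep] == w]
      entry <- rbind(ord = rep.int(i, length(at)), off = at)
      prev <- env[[w]]
      env[[w]] <- if (is.null(prev)) entry else cbind(prev, entry)
    }
  }
  structure(list(k = k, postings = env,
                 query_ids = queries$id,
                 query_lengths = queries$length,
                 n_queries = n, total_postings = total,
                 mask_x = mask_x),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("seed_index: k =", x$k, "|", x$n_queries, "queries |",
      x$total_postings, "postings |",
      length(ls(x$postings)), "distinct words\n")
  invisible(x)
}

#' Scan one reference sequence against a seed index
#'
#' Reports every exact k-word shared between the reference and any indexed
#' query, one row per (query posting, reference position) pair, ordered by
#' (query ordinal, diagonal, query offset).  Postings scanned for a single
#' word within one reference sequence are capped at `max_postings_per_word`
#' (a guard against single-residue low-complexity words), with a warning on
#' truncation.
#'
#' @param index a `seed_index` from [build_index()].
#' @param ref a residue string, or a single-row [aa_set].
#' @param max_postings_per_word cap per word per reference sequence.
#' @return Data frame with columns `q_ord`, `q_pos`, `s_pos`, `diagonal`
#'   (all 0-based; `diagonal = s_pos - q_pos`).
#' @export
scan_reference <- function(index, ref, max_postings_per_word = 10000L) {
  stopifnot(inherits(index, "seed_index"))
  if (inherits(ref, "aa_set")) {
    stopifnot(nrow(ref) == 1L)
    ref <- ref$residues
  }
  k <- index$k
  L <- nchar(ref)
  empty <- data.frame(q_ord = integer(), q_pos = integer(),
                      s_pos = integer(), diagonal = integer())
  if (L < k) return(empty)
  np <- L - k + 1L
  words <- substring(ref, seq_len(np), seq_len(np) + k - 1L)
  posts <- mget(words, envir = index$postings, ifnotfound = list(NULL))
  hit <- !vapply(posts, is.null, logical(1L))
  if (!any(hit)) return(empty)
  rows <- vector("list", sum(hit))
  ri <- 0L
  for (p in which(hit)) {
    m <- posts[[p]]
    if (ncol(m) > max_postings_per_word) {
      warning("word '", words[p], "' truncated to ", max_postings_per_word,
              " postings in one reference sequence")
      m <- m[, seq_len(max_postings_per_word), drop = FALSE]
    }
    ri <- ri + 1L
    rows[[ri]] <- data.frame(q_ord = m["ord", ], q_pos = m["off", ],
                             s_pos = rep.int(p - 1L, ncol(m)))
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  out$diagonal <- out$s_pos - out$q_pos
  out[order(out$q_ord, out$diagonal, out$q_pos, method = "radix"), ,
      drop = FALSE]
}

#' Collapse clustered seeds before extension
#'
#' Within each (query, diagonal) group, seeds within `2 * k` residues of the
#' last kept seed collapse onto the leftmost, avoiding redundant extensions.
#'
#' @param matches seed-match data frame from [scan_reference()].
#' @param k seed length used to build the matches.
#' @return Filtered seed-match data frame (same columns, same ordering).
#' @export
collapse_seeds <- function(matches, k) {
  n <- nrow(matches)
  if (n <= 1L) return(matches)
  keep <- logical(n)
  last_ord <- -1L; last_diag <- NA_integer_; last_q <- -Inf
  for (i in seq_len(n)) {
    new_group <- matches$q_ord[i] != last_ord ||
      matches$diagonal[i] != last_diag
    if (new_group || matches$q_pos[i] >= last_q + 2L * k) {
      keep[i] <- TRUE
      last_ord <- matches$q_ord[i]
      last_diag <- matches$diagonal[i]
      last_q <- matches$q_pos[i]
    }
  }
  matches[keep, , drop = FALSE]
}
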