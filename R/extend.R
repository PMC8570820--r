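#' High-scoring segment pairs
#'
#' An `hsp` is a list with 0-based half-open coordinates `q_start`, `q_end`,
#' `s_start`, `s_end`, the integer `raw_score`, the edit `path` (a string
#' over `M` = aligned column, `I` = gap in subject consuming query, `D` =
#' gap in query consuming subject), and the path statistics `identities`,
#' `match_cols`, `gap_opens`.  `raw_score` always equals the score obtained
#' by replaying `path` against the two sequences (see [replay_alignment()]).
#'
#' @name hsp
NULL

as_hsp <- function(x, q_ord = 1L) {
  structure(list(q_ord = as.integer(q_ord),
                 q_start = x$q_start, q_end = x$q_end,
                 s_start = x$s_start, s_end = x$s_end,
                 raw_score = as.numeric(x$score),
                 path = x$path,
                 identities = x$identities,
                 match_cols = x$match_cols,
                 gap_opens = x$gap_opens),
            class = "hsp")
}

#' @export
print.hsp <- function(x, ...) {
  cat(sprintf("hsp: raw %g | q [%d,%d) s [%d,%d) | %d/%d identities | %d gap run(s)\n",
              x$raw_score, x$q_start, x$q_end, x$s_start, x$s_end,
              x$identities, nchar(x$path), x$gap_opens))
  invisible(x)
}

#' Replay an alignment path
#'
#' Recomputes score and column statistics of an edit path against the two
#' sequences under a matrix and affine gap costs (gap of length L costs
#' `gap_open + (L - 1) * gap_extend`).  Used to verify the path invariant
#' of every emitted HSP.
#'
#' @param path edit path over `M`/`I`/`D`.
#' @param qseq,sseq residue strings.
#' @param q_start,s_start 0-based alignment start coordinates.
#' @param matrix substitution matrix from [load_matrix()].
#' @param gap_open,gap_extend gap costs.
#' @return List with `score`, `identities`, `match_cols`, `gap_opens`,
#'   `q_len`, `s_len`.
#' @export
replay_alignment <- function(path, qseq, sseq, q_start, s_start,
                             matrix = load_matrix(), gap_open = 11L,
                             gap_extend = 1L) {
  cpp_replay(path, qseq, sseq, as.integer(q_start), as.integer(s_start),
             matrix, paste(rownames(matrix), collapse = ""),
             as.integer(gap_open), as.integer(gap_extend))
}

#' Ungapped X-drop extension through a seed
#'
#' Extends an exact seed in both directions along its diagonal, keeping the
#' best-scoring prefix/suffix; extension in a direction stops once the
#' running score falls more than `x_drop` below the best seen there.
#'
#' @param qseq,sseq residue strings.
#' @param q_pos,s_pos 0-based seed start offsets.
#' @param k seed length.
#' @param matrix substitution matrix.
#' @param x_drop raw-score drop-off (default 20).
#' @return A gap-free [hsp] (its `path` is all `M`).
#' @export
ungapped_extend <- function(qseq, sseq, q_pos, s_pos, k = 4L,
                            matrix = load_matrix(), x_drop = 20L) {
  r <- cpp_ungapped_extend(qseq, sseq, as.integer(q_pos), as.integer(s_pos),
                           as.integer(k), matrix,
                           paste(rownames(matrix), collapse = ""),
                           as.integer(x_drop))
  len <- r$q_end - r$q_start
  rep_stats <- replay_alignment(strrep("M", len), qseq, sseq,
                                r$q_start, r$s_start, matrix)
  as_hsp(list(q_start = r$q_start, q_end = r$q_end,
              s_start = r$s_start, s_end = r$s_end,
              score = r$score, path = strrep("M", len),
              identities = rep_stats$identities,
              match_cols = rep_stats$match_cols,
              gap_opens = 0L))
}

#' Banded gapped extension of an ungapped HSP
#'
#' Anchors at the midpoint column of the ungapped HSP and runs an exact
#' banded affine-gap extension to both sides (band of `band_width` diagonals
#' centred on the anchor diagonal; a side stops when every in-band cell of a
#' row falls more than `x_drop` below the running best).  The returned raw
#' score is the replay of the combined path and is never below the ungapped
#' score.
#'
#' @param hsp_seed gap-free [hsp] from [ungapped_extend()].
#' @param qseq,sseq residue strings.
#' @param matrix substitution matrix.
#' @param gap_open,gap_extend affine gap costs.
#' @param x_drop raw-score drop-off (default 38).
#' @param band_width number of diagonals explored around the anchor
#'   (default 64).
#' @return An [hsp].
#' @export
gapped_extend <- function(hsp_seed, qseq, sseq, matrix = load_matrix(),
                          gap_open = 11L, gap_extend = 1L, x_drop = 38L,
                          band_width = 64L) {
  stopifnot(inherits(hsp_seed, "hsp"))
  r <- cpp_gapped_extend(qseq, sseq,
                         hsp_seed$q_start, hsp_seed$q_end,
                         hsp_seed$s_start, hsp_seed$s_end,
                         matrix, paste(rownames(matrix), collapse = ""),
                         as.integer(gap_open), as.integer(gap_extend),
                         as.integer(band_width) %/% 2L, as.integer(x_drop))
  as_hsp(r, q_ord = hsp_seed$q_ord)
}

#' Exact Smith-Waterman local alignment
#'
#' Full affine-gap dynamic programming over the whole pair (no band, no
#' drop-off): the rigorous optimum that plays the role of an SSEARCH-style
#' ground truth.  Ties between equal-scoring alignments resolve to the
#' smallest query end, then subject end, with a fixed traceback operator
#' preference, so results are bit-reproducible.  Memory is O(m*n) bytes.
#'
#' @param qseq,sseq non-empty residue strings.
#' @param matrix substitution matrix.
#' @param gap_open,gap_extend affine gap costs (gap of length L costs
#'   `gap_open + (L - 1) * gap_extend`).
#' @return An [hsp] with the optimal `raw_score`.
#' @export
smith_waterman <- function(qseq, sseq, matrix = load_matrix(),
                           gap_open = 11L, gap_extend = 1L) {
  r <- cpp_sw_pair(qseq, sseq, matrix,
                   paste(rownames(matrix), collapse = ""),
                   as.integer(gap_open), as.integer(gap_extend))
  stopifnot(r$score == r$replay_score)   # path invariant, bit-exact
  as_hsp(r)
}

#' Smith-Waterman scores of one query against many subjects
#'
#' Score-only variant of [smith_waterman()] (linear memory), used to build
#' ground-truth hit sets over all query-subject pairs.
#'
#' @param qseq residue string.
#' @param sseqs character vector of subject residue strings.
#' @param matrix substitution matrix.
#' @param gap_open,gap_extend affine gap costs.
#' @return Integer vector of optimal raw scores.
#' @export
smith_waterman_scores <- function(qseq, sseqs, matrix = load_matrix(),
                                  gap_open = 11L, gap_extend = 1L) {
  cpp_sw_score_many(qseq, sseqs, matrix,
                    paste(rownames(matrix), collapse = ""),
                    as.integer(gap_open), as.integer(gap_extend))
}
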