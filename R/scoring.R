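#' Load a built-in substitution matrix
#'
#' Returns the NCBI BLOSUM62 or BLOSUM50 matrix over the package's 25-symbol
#' alphabet (20 canonical residues, the ambiguity codes B/Z/X, selenocysteine
#' U and the terminator `*`).  `U` is scored with the `X` rows, following the
#' rule that ambiguity residues score through the matrix's ambiguity entries.
#'
#' @param name `"BLOSUM62"` (default) or `"BLOSUM50"`.
#' @return Integer matrix with identical row/column names, symmetric.
#' @export
load_matrix <- function(name = "BLOSUM62") {
  if (!name %in% c("BLOSUM62", "BLOSUM50"))
    stop("unknown substitution matrix '", name,
         "'; built-ins are BLOSUM62 and BLOSUM50")
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- e[[name]]
  base <- c(AA_CANONICAL, "B", "Z", "X", "*")
  m <- m[base, base]
  full <- matrix(0L, 25L, 25L, dimnames = list(AA_ALLOWED, AA_ALLOWED))
  full[base, base] <- m
  full["U", ] <- full["X", AA_ALLOWED]
  full[, "U"] <- full[AA_ALLOWED, "X"]
  full["U", "U"] <- full["X", "X"]
  storage.mode(full) <- "integer"
  attr(full, "name") <- name
  full
}

#' Read an NCBI-format substitution matrix file
#'
#' Parses the plain-text matrix format used by NCBI (header row of symbols,
#' one labelled row per symbol, `#` comments).  Symbols outside the package
#' alphabet are dropped; absent package symbols score as `X` (or as the
#' minimum off-diagonal score when `X` itself is absent).
#'
#' @param path matrix text file.
#' @return Integer matrix as in [load_matrix()].
#' @export
read_score_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not an NCBI matrix file: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  syms <- vapply(rows, `[[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.integer(r[-1L]),
                   integer(length(header))))
  dimnames(vals) <- list(syms, header)
  if (!isTRUE(all.equal(vals[syms, syms], t(vals[syms, syms]))))
    stop("matrix in '", path, "' is not symmetric")
  keep <- intersect(AA_ALLOWED, syms)
  fallback <- if ("X" %in% syms) "X" else NULL
  full <- matrix(if (is.null(fallback)) min(vals) else 0L,
                 25L, 25L, dimnames = list(AA_ALLOWED, AA_ALLOWED))
  if (!is.null(fallback)) {
    full[, ] <- vals[fallback, fallback]
    full[keep, ] <- vals[keep, fallback]
    full[, keep] <- vals[fallback, keep]
  }
  full[keep, keep] <- vals[keep, keep]
  miss <- setdiff(AA_ALLOWED, syms)
  for (s in miss) {
    src <- if (!is.null(fallback)) fallback else keep[1L]
    full[s, keep] <- vals[src, keep]
    full[keep, s] <- vals[keep, src]
  }
  storage.mode(full) <- "integer"
  attr(full, "name") <- basename(path)
  full
}

#' Karlin-Altschul statistical parameters
#'
#' Parameters of the extreme-value statistics for local alignment scores:
#' `lambda` (nats per raw-score unit) and `K` scale raw scores into bit
#' scores and E-values.  The defaults are the standard published constants
#' for gapped BLOSUM62 alignments with gap open 11, gap extend 1.
#'
#' @param lambda positive scale, nats per raw-score unit.
#' @param K positive dimensionless constant.
#' @param gapped logical flag recording whether the parameters describe
#'   gapped alignment statistics.
#' @param gap_open,gap_extend non-negative gap costs; a gap of length L
#'   costs `gap_open + (L - 1) * gap_extend`.
#' @return A list of class `ka_params`.
#' @export
ka_params <- function(lambda = 0.267, K = 0.041, gapped = TRUE,
                      gap_open = 11L, gap_extend = 1L) {
  if (!(lambda > 0)) stop("lambda must be > 0")
  if (!(K > 0)) stop("K must be > 0")
  if (gap_open < 0 || gap_extend < 0) stop("gap costs must be >= 0")
  if (gap_extend > gap_open) stop("gap_extend must be <= gap_open")
  structure(list(lambda = lambda, K = K, gapped = isTRUE(gapped),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "ka_params")
}

#' Convert a raw alignment score to bits
#'
#' `bits = (lambda * S - ln K) / ln 2`.
#'
#' @param S raw score(s).
#' @param params a [ka_params] object.
#' @return Numeric bit score(s).
#' @export
raw_to_bits <- function(S, params = ka_params()) {
  stopifnot(inherits(params, "ka_params"))
  (params$lambda * S - log(params$K)) / log(2)
}

#' Karlin-Altschul E-value
#'
#' Expected number of chance local alignments scoring at least `S` in a
#' search space of `m * n` residue pairs: `E = K * m * n * exp(-lambda * S)`.
#' The search space is the raw product of query length and total reference
#' residues (no finite-size length adjustment).
#'
#' @param S raw score(s).
#' @param m query length in residues.
#' @param n total reference residues searched.
#' @param params a [ka_params] object.
#' @return Numeric expectation(s), >= 0.
#' @export
evalue <- function(S, m, n, params = ka_params()) {
  stopifnot(inherits(params, "ka_params"))
  if (any(m < 1) || any(n < 1)) stop("m and n must be >= 1")
  params$K * as.numeric(m) * as.numeric(n) * exp(-params$lambda * S)
}

# smallest integer raw score whose bit score reaches `bits`
raw_for_bits <- function(bits, params) {
  ceiling((bits * log(2) + log(params$K)) / params$lambda)
}
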