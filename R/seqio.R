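#' Protein sequence sets
#'
#' An `aa_set` is a plain data frame with one row per sequence and columns
#' `id`, `description`, `sample_id`, `residues` and `length`.  Residues are
#' uppercase over the 20 canonical amino acids plus the ambiguity symbols
#' `B`, `Z`, `X`, `U` and the terminator `*`.
#'
#' @param id character vector of unique record identifiers.
#' @param residues character vector of residue strings (same length as `id`).
#' @param description optional free-text descriptions.
#' @param sample_id optional per-record sample identifiers (`NA` when the
#'   record carries no sample attribution).
#' @param mode `"strict"` rejects residues outside the allowed alphabet;
#'   `"lenient"` maps them to `X`.
#' @return A data frame of class `aa_set`.
#' @export
aa_set <- function(id, residues, description = "", sample_id = NA_character_,
                   mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(residues) != length(id))
    stop("'id' and 'residues' must have the same length")
  if (anyDuplicated(id))
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(residues)))
    stop("empty residue string for record(s): ",
         paste(id[!nzchar(residues)], collapse = ", "))
  residues <- normalize_residues(residues, id, mode)
  out <- data.frame(
    id = id,
    description = rep_len(as.character(description), length(id)),
    sample_id = rep_len(as.character(sample_id), length(id)),
    residues = residues,
    length = nchar(residues),
    stringsAsFactors = FALSE
  )
  class(out) <- c("aa_set", "data.frame")
  out
}

normalize_residues <- function(residues, id, mode) {
  bad <- gsub(paste0("[", gsub("\\*", "\\\\*", paste(AA_ALLOWED, collapse = "")), "]"),
              "", residues)
  if (any(nzchar(bad))) {
    offenders <- which(nzchar(bad))
    if (mode == "strict") {
      stop("disallowed residue(s) '", substr(bad[offenders[1L]], 1, 1),
           "' in record '", id[offenders[1L]], "' (strict mode)")
    }
    for (i in offenders) {
      chars <- strsplit(residues[i], "", fixed = TRUE)[[1L]]
      chars[!chars %in% AA_ALLOWED] <- "X"
      residues[i] <- paste(chars, collapse = "")
    }
  }
  residues
}

#' @export
print.aa_set <- function(x, ...) {
  cat("aa_set with", nrow(x), "sequence(s),",
      sum(x$length), "residues\n")
  if (nrow(x)) {
    show <- utils::head(x, 5L)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  %s (%d aa)%s\n", show$id[i], show$length[i],
                  if (!is.na(show$sample_id[i]))
                    paste0(" [sample ", show$sample_id[i], "]") else ""))
    if (nrow(x) > 5L) cat("  ...\n")
  }
  invisible(x)
}

#' Read protein FASTA
#'
#' Reads a (possibly wrapped) multi-record amino-acid FASTA file.  When a
#' record header follows the `sampleID|sequenceID` convention the part before
#' the first `|` is taken as the sample of origin; an explicit two-column
#' `sample_map` (sequence id, sample id) overrides the convention.
#'
#' @param path FASTA file.
#' @param mode `"strict"` (default) errors on residues outside the alphabet;
#'   `"lenient"` maps them to `X`.
#' @param sample_map optional data frame (or TSV path) with columns
#'   `id`, `sample_id` overriding header-derived sample attribution.
#' @return An [aa_set].
#' @export
read_fasta <- function(path, mode = c("strict", "lenient"), sample_map = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  pre <- readLines(path, n = 50L, warn = FALSE)
  nonblank <- which(nzchar(trimws(pre)))
  if (length(nonblank) && !startsWith(trimws(pre[nonblank[1L]]), ">"))
    stop("malformed FASTA in '", path, "': line ", nonblank[1L],
         " precedes the first '>' header")
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("malformed FASTA in '", path, "': no records")
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  sample_id <- ifelse(grepl("|", id, fixed = TRUE),
                      sub("\\|.*$", "", id), NA_character_)
  out <- aa_set(id = id, residues = as.character(set),
                description = description, sample_id = sample_id, mode = mode)
  if (!is.null(sample_map)) {
    if (is.character(sample_map))
      sample_map <- read.table(sample_map, sep = "\t", header = FALSE,
                               col.names = c("id", "sample_id"),
                               stringsAsFactors = FALSE, quote = "",
                               comment.char = "")
    m <- match(out$id, sample_map$id)
    out$sample_id[!is.na(m)] <- sample_map$sample_id[m[!is.na(m)]]
  }
  out
}

#' Write protein FASTA
#'
#' @param x an [aa_set].
#' @param path output file.
#' @param width line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(inherits(x, "aa_set"))
  hdr <- ifelse(nzchar(x$description), paste(x$id, x$description), x$id)
  set <- Biostrings::BStringSet(setNames(x$residues, hdr))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

# 12 canonical BLAST tabular columns (outfmt 6)
HIT_COLUMNS <- c("query_id", "subject_id", "pct_identity", "length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bit_score")

empty_hit_table <- function() {
  out <- data.frame(query_id = character(), subject_id = character(),
                    pct_identity = numeric(), length = integer(),
                    mismatches = integer(), gap_opens = integer(),
                    q_start = integer(), q_end = integer(),
                    s_start = integer(), s_end = integer(),
                    evalue = numeric(), bit_score = numeric(),
                    stringsAsFactors = FALSE)
  out
}

#' Write a BLAST-style 12-column hit table
#'
#' Columns, in order: query id, subject id, percent identity (2 decimals),
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end (1-based inclusive), E-value (scientific, 2 significant
#' digits) and bit score (1 decimal).  Tab-separated, no header.
#'
#' @param hits data frame with the columns of [read_hits_tab()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits_tab <- function(hits, path) {
  lines <- format_hit_lines(hits)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  invisible(path)
}

format_hit_lines <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return(character())
  missing <- setdiff(HIT_COLUMNS, names(hits))
  if (length(missing))
    stop("hit table lacks column(s): ", paste(missing, collapse = ", "))
  sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
          hits$query_id, hits$subject_id, hits$pct_identity,
          as.integer(hits$length), as.integer(hits$mismatches),
          as.integer(hits$gap_opens), as.integer(hits$q_start),
          as.integer(hits$q_end), as.integer(hits$s_start),
          as.integer(hits$s_end), sprintf("%.1e", hits$evalue),
          hits$bit_score)
}

#' Read a BLAST-style tabular hit file
#'
#' Accepts 12 or more tab-separated columns (extra trailing columns are
#' ignored).  Rows with fewer than 12 columns raise a format error naming
#' the offending row.
#'
#' @param path tab-separated hit file (BLAST `outfmt 6` compatible).
#' @return Data frame with columns `query_id`, `subject_id`, `pct_identity`,
#'   `length`, `mismatches`, `gap_opens`, `q_start`, `q_end`, `s_start`,
#'   `s_end`, `evalue`, `bit_score`.
#' @export
read_hits_tab <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("hit table '", path, "': row ", which(nf < 12L)[1L],
         " has ", nf[which(nf < 12L)[1L]], " column(s), expected >= 12")
  get <- function(i) vapply(fields, `[[`, "", i)
  out <- data.frame(
    query_id = get(1L), subject_id = get(2L),
    pct_identity = as.numeric(get(3L)), length = as.integer(get(4L)),
    mismatches = as.integer(get(5L)), gap_opens = as.integer(get(6L)),
    q_start = as.integer(get(7L)), q_end = as.integer(get(8L)),
    s_start = as.integer(get(9L)), s_end = as.integer(get(10L)),
    evalue = as.numeric(get(11L)), bit_score = as.numeric(get(12L)),
    stringsAsFactors = FALSE
  )
  bad <- which(is.na(out$evalue) | is.na(out$q_start) | is.na(out$pct_identity))
  if (length(bad))
    stop("hit table '", path, "': row ", bad[1L], " has non-numeric fields")
  if (any(out$q_start > out$q_end | out$s_start > out$s_end))
    stop("hit table '", path, "': start > end coordinates")
  out
}
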