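#' Read a per-sample metadata table
#'
#' Tab-separated with header columns `sample_id`, `env_class_ids`,
#' `body_class_ids`, `latitude`, `longitude`.  Class columns hold
#' semicolon-separated `id|label` pairs (empty allowed for body classes);
#' coordinates may be empty.
#'
#' @param path metadata TSV.
#' @return Data frame of class `sample_metadata` (one row per sample).
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  md <- read.table(path, sep = "\t", header = TRUE, quote = "",
                   comment.char = "", stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character",
                                  env_class_ids = "character",
                                  body_class_ids = "character",
                                  latitude = "numeric",
                                  longitude = "numeric"))
  needed <- c("sample_id", "env_class_ids", "body_class_ids",
              "latitude", "longitude")
  miss <- setdiff(needed, names(md))
  if (length(miss))
    stop("metadata '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id(s) in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  ok_lat <- is.na(md$latitude) | (md$latitude >= -90 & md$latitude <= 90)
  ok_lon <- is.na(md$longitude) | (md$longitude >= -180 & md$longitude <= 180)
  if (!all(ok_lat & ok_lon))
    stop("coordinates out of range for sample(s): ",
         paste(md$sample_id[!(ok_lat & ok_lon)], collapse = ", "))
  class(md) <- c("sample_metadata", "data.frame")
  md
}

# "id|label;id|label" -> data.frame(class_id, class_label)
parse_classes <- function(s) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(class_id = character(), class_label = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(s, ";", fixed = TRUE)[[1L]]
  id <- sub("\\|.*$", "", parts)
  label <- ifelse(grepl("|", parts, fixed = TRUE),
                  sub("^[^|]*\\|", "", parts), parts)
  data.frame(class_id = id, class_label = label, stringsAsFactors = FALSE)
}

hit_sample_ids <- function(hits) {
  ifelse(grepl("|", hits$subject_id, fixed = TRUE),
         sub("\\|.*$", "", hits$subject_id), NA_character_)
}

#' Summarize hits by ontology class
#'
#' Attributes each hit to the sample its subject sequence came from and
#' counts hits per annotation class in the chosen namespace
#' (environment-ontology or body-site).  A hit whose sample carries several
#' classes contributes one count to each, so fractions can sum above 1 for
#' multi-class metadata; with one class per sample the fractions sum to 1
#' exactly.  Hits whose sample has no metadata row (or no class in the
#' namespace) are attributed to the reserved class `unclassified`.
#'
#' @param hits a 12-column hit table ([read_hits_tab()]) or
#'   `pzsearch_result`.
#' @param metadata a [read_sample_metadata()] table.
#' @param namespace `"env"` or `"body"`.
#' @return Data frame with columns `class_id`, `class_label`, `hit_count`,
#'   `hit_fraction` (of all input hits) and `distinct_samples`, sorted by
#'   `hit_count` descending then `class_id`.
#' @export
summarize_by_class <- function(hits, metadata, namespace = c("env", "body")) {
  if (inherits(hits, "pzsearch_result")) hits <- hits$hits
  namespace <- tryCatch(match.arg(namespace),
                        error = function(e) stop("unknown namespace; use 'env' or 'body'"))
  col <- if (namespace == "env") "env_class_ids" else "body_class_ids"
  samples <- hit_sample_ids(hits)
  n_hits <- nrow(hits)
  recs <- vector("list", n_hits)
  for (i in seq_len(n_hits)) {
    row <- match(samples[i], metadata$sample_id)
    cls <- if (is.na(row)) parse_classes("") else
      parse_classes(metadata[[col]][row])
    if (nrow(cls) == 0L)
      cls <- data.frame(class_id = "unclassified",
                        class_label = "unclassified",
                        stringsAsFactors = FALSE)
    cls$sample <- if (is.na(samples[i])) "<none>" else samples[i]
    recs[[i]] <- cls
  }
  long <- if (n_hits) do.call(rbind, recs) else
    data.frame(class_id = character(), class_label = character(),
               sample = character(), stringsAsFactors = FALSE)
  key <- paste(long$class_id, long$class_label, sep = "\r")
  agg <- if (nrow(long)) {
    cnt <- tapply(rep(1L, nrow(long)), key, sum)
    ds <- tapply(long$sample, key, function(s) length(unique(s)))
    ids <- strsplit(names(cnt), "\r", fixed = TRUE)
    data.frame(class_id = vapply(ids, `[[`, "", 1L),
               class_label = vapply(ids, `[[`, "", 2L),
               hit_count = as.integer(cnt),
               hit_fraction = as.numeric(cnt) / n_hits,
               distinct_samples = as.integer(ds),
               stringsAsFactors = FALSE)
  } else {
    data.frame(class_id = character(), class_label = character(),
               hit_count = integer(), hit_fraction = numeric(),
               distinct_samples = integer(), stringsAsFactors = FALSE)
  }
  agg <- agg[order(-agg$hit_count, agg$class_id, method = "radix"), ,
             drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "namespace") <- namespace
  attr(agg, "n_hits") <- n_hits
  agg
}

#' Summarize hits by sampling location
#'
#' Groups hits by their sample's exact (latitude, longitude) pair; hits from
#' samples without coordinates (or without metadata) aggregate under a
#' single no-location row.
#'
#' @param hits a 12-column hit table or `pzsearch_result`.
#' @param metadata a [read_sample_metadata()] table.
#' @return Data frame with columns `latitude`, `longitude` (`NA` for the
#'   no-location row), `hit_count`, `distinct_samples`, sorted by
#'   `hit_count` descending.
#' @export
summarize_geography <- function(hits, metadata) {
  if (inherits(hits, "pzsearch_result")) hits <- hits$hits
  samples <- hit_sample_ids(hits)
  row <- match(samples, metadata$sample_id)
  lat <- metadata$latitude[row]
  lon <- metadata$longitude[row]
  noloc <- is.na(lat) | is.na(lon)
  key <- ifelse(noloc, "no-location", paste(lat, lon, sep = "\r"))
  sample_key <- ifelse(is.na(samples), "<none>", samples)
  if (!length(key))
    return(data.frame(latitude = numeric(), longitude = numeric(),
                      hit_count = integer(), distinct_samples = integer(),
                      stringsAsFactors = FALSE))
  cnt <- tapply(rep(1L, length(key)), key, sum)
  ds <- tapply(sample_key, key, function(s) length(unique(s)))
  parts <- strsplit(names(cnt), "\r", fixed = TRUE)
  out <- data.frame(
    latitude = vapply(parts, function(p)
      if (length(p) == 2L) as.numeric(p[1L]) else NA_real_, 0),
    longitude = vapply(parts, function(p)
      if (length(p) == 2L) as.numeric(p[2L]) else NA_real_, 0),
    hit_count = as.integer(cnt),
    distinct_samples = as.integer(ds),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$hit_count, out$latitude, out$longitude,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
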