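.readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = NA, quote = "")
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Parse a feature table (ASV/OTU counts per sample)
#'
#' Accepts the plain TSV export of a QIIME2-style feature table: first
#' column holds feature ids (header "feature-id", "#OTU ID" or similar),
#' remaining columns one per sample. Counts may be fractional (some
#' upstream tools emit non-integer counts) but never negative.
#'
#' @param path TSV file path.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts` (features x samples).
#' @export
parseFeatureTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- .readTsv(path)
  if (ncol(df) < 2) stop("parse error: feature table needs an id column and at least one sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("schema error: duplicated feature id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop("parse error: non-numeric count at feature '", ids[bad[1]],
         "', sample '", colnames(m)[bad[2]], "'")
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("parse error: negative count at feature '", ids[bad[1]],
         "', sample '", colnames(m)[bad[2]], "'")
  }
  rownames(m) <- ids
  SummarizedExperiment::SummarizedExperiment(assays = list(counts = m))
}

#' Parse a taxonomy assignment table
#'
#' Two dialects are supported and auto-detected: `silva-strings` — columns
#' "Feature ID" and "Taxon" holding a semicolon-delimited lineage with or
#' without `d__`-style rank prefixes (optional "Confidence" column kept);
#' `rank-columns` — a feature id column followed by explicit rank columns
#' (domain...species). Lineages are stored with prefixes stripped, missing
#' ranks as empty strings.
#'
#' @param path TSV file path.
#' @param dialect "auto" (default), "silva-strings" or "rank-columns".
#' @return a [S4Vectors::DataFrame] with rownames = feature ids, the seven
#'   rank columns, and `confidence` when present.
#' @export
parseTaxonomy <- function(path, dialect = c("auto", "silva-strings", "rank-columns")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- .readTsv(path)
  nm <- tolower(gsub("[ _-]", "", names(df)))
  if (dialect == "auto") {
    dialect <- if ("taxon" %in% nm) "silva-strings" else "rank-columns"
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("schema error: feature listed twice in taxonomy: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (dialect == "silva-strings") {
    tcol <- which(nm == "taxon")[1]
    if (is.na(tcol)) stop("schema error: no 'Taxon' column found")
    ranks <- t(vapply(as.character(df[[tcol]]), .splitLineage, character(7)))
  } else {
    have <- intersect(.RANKS, tolower(names(df)))
    if (!length(have)) stop("schema error: no rank columns found")
    ranks <- matrix("", nrow(df), 7, dimnames = list(NULL, .RANKS))
    for (rk in have) {
      v <- as.character(df[[which(tolower(names(df)) == rk)[1]]])
      v[is.na(v)] <- ""
      ranks[, rk] <- sub("^[a-zA-Z]__", "", v)
    }
  }
  out <- DataFrame(ranks, row.names = ids)
  colnames(out) <- .RANKS
  ccol <- which(nm == "confidence")[1]
  if (!is.na(ccol)) out$confidence <- as.numeric(df[[ccol]])
  out
}

.splitLineage <- function(s) {
  parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  parts <- sub("^[a-zA-Z]__", "", parts)
  length(parts) <- 7
  parts[is.na(parts)] <- ""
  parts
}

#' Parse sample metadata (QIIME2 dialect)
#'
#' First column is the sample id (header "#SampleID", "sample-id" or
#' similar); an optional second header row of QIIME2 column types
#' (`#q2:types`) is skipped.
#'
#' @param path TSV file path.
#' @return a [S4Vectors::DataFrame] with rownames = sample ids.
#' @export
parseSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- .readTsv(path)
  if (nrow(df) && grepl("^#q2:types", as.character(df[[1]][1]))) {
    df <- df[-1, , drop = FALSE]
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("schema error: duplicated sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- DataFrame(df[, -1, drop = FALSE], row.names = ids)
  out
}

#' Write / read an activity-score matrix as TSV
#'
#' Scores are written with fixed 6-decimal formatting (rows = reactions or
#' subsystems, first column `feature_id`, one column per sample), the
#' on-disk contract used by the command-line interface.
#'
#' @param scores a matrix or SummarizedExperiment of scores.
#' @param path output TSV path.
#' @return `writeScoresTsv`: invisibly, `path`. `readScoresTsv`: a numeric
#'   matrix with feature rownames and sample colnames.
#' @export
writeScoresTsv <- function(scores, path) {
  m <- .asScoreMatrix(scores)
  df <- data.frame(feature_id = rownames(m), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- sprintf("%.6f", m[, j])
  .writeTsv(df, path)
  invisible(path)
}

#' @rdname writeScoresTsv
#' @export
readScoresTsv <- function(path) {
  df <- .readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

.asScoreMatrix <- function(scores) {
  if (methods::is(scores, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(scores)
  } else {
    m <- as.matrix(scores)
  }
  storage.mode(m) <- "double"
  m
}
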