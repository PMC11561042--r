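#' Ambiguity markers for taxonomic names
#'
#' A feature only enters the analysis when its assignment at the chosen
#' rank is unambiguous: the rank name must be non-empty and free of the
#' placeholder tokens that 16S classifiers emit for unresolved taxa.
#'
#' @export
defaultAmbiguityMarkers <- function() {
  c("uncultured", "metagenome", "sp.", "unidentified")
}

.nameAtLevel <- function(taxonomy, level) {
  if (level == "genus") {
    gsub("_", " ", trimws(taxonomy$genus))
  } else {
    .speciesKeyDisplay(taxonomy$genus, taxonomy$species)
  }
}

.isAmbiguous <- function(name, markers) {
  if (!nzchar(name)) return(TRUE)
  low <- tolower(name)
  any(vapply(markers, function(m) grepl(m, low, fixed = TRUE), logical(1)))
}

#' Collapse a feature table to an unambiguous taxonomic level
#'
#' Features whose lineage is empty or ambiguous at `level` are dropped and
#' logged with reason "ambiguous assignation"; features resolving to the
#' same taxon name at `level` are merged by summing their counts. At
#' species level the taxon name is the binomial "Genus epithet".
#'
#' @param table SummarizedExperiment from [parseFeatureTable()].
#' @param taxonomy DataFrame from [parseTaxonomy()]. Features absent from
#'   the taxonomy are treated as ambiguous.
#' @param level "species" (default) or "genus".
#' @param ambiguityMarkers tokens marking an unresolved name; see
#'   [defaultAmbiguityMarkers()].
#' @return a SummarizedExperiment with assay `counts`, rownames = taxon
#'   names at `level`; dropped features in
#'   `S4Vectors::metadata(.)$discard_log`.
#' @export
collapseToLevel <- function(table, taxonomy, level = c("species", "genus"),
                            ambiguityMarkers = defaultAmbiguityMarkers()) {
  level <- match.arg(level)
  counts <- SummarizedExperiment::assay(table, "counts")
  fids <- rownames(counts)
  tx <- taxonomy[match(fids, rownames(taxonomy)), , drop = FALSE]
  names4 <- .nameAtLevel(tx, level)
  names4[is.na(names4)] <- ""
  ambiguous <- vapply(names4, .isAmbiguous, logical(1),
                      markers = ambiguityMarkers) |
    is.na(match(fids, rownames(taxonomy)))
  discard <- data.frame(item = fids[ambiguous],
                        reason = rep("ambiguous assignation", sum(ambiguous)),
                        stringsAsFactors = FALSE)
  kept <- counts[!ambiguous, , drop = FALSE]
  keptNames <- names4[!ambiguous]
  if (nrow(kept)) {
    merged <- rowsum(kept, group = keptNames, reorder = FALSE)
  } else {
    merged <- kept
  }
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = merged))
  metadata(out)$discard_log <- discard
  metadata(out)$level <- level
  out
}

#' Build the relative-abundance matrix X
#'
#' Per sample, counts are divided by that sample's total count over *all*
#' collapsed taxa, so columns sum to 1 before any deletion. Taxa with no
#' match in the reconstruction are then deleted (logged with reason "no
#' reconstruction match"), which can leave column sums below 1; set
#' `renormalizeAfterMatch = TRUE` to rescale the surviving columns back to
#' sum 1 over matched taxa.
#'
#' @param collapsed SummarizedExperiment from [collapseToLevel()].
#' @param bundle a [ReconstructionBundle-class].
#' @param level "species" or "genus"; defaults to the level recorded by
#'   [collapseToLevel()].
#' @param renormalizeAfterMatch logical, default `FALSE`.
#' @return a SummarizedExperiment with assay `relabund` (matched taxa x
#'   samples, values in \[0,1\]), rowData columns `taxon_name` and
#'   `strain_ids` ([IRanges::CharacterList]), and the accumulated discard
#'   log in `S4Vectors::metadata(.)$discard_log`.
#' @export
buildAbundanceMatrix <- function(collapsed, bundle, level = NULL,
                                 renormalizeAfterMatch = FALSE) {
  counts <- SummarizedExperiment::assay(collapsed, "counts")
  if (!nrow(counts)) stop("collapsed table is empty")
  if (is.null(level)) level <- metadata(collapsed)$level
  if (is.null(level)) level <- "species"
  totals <- colSums(counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[totals == 0], collapse = ", "))
  }
  rel <- sweep(counts, 2, totals, "/")
  matches <- matchTaxa(bundle, rownames(rel), level = level)
  keep <- match(matches$taxon_name, rownames(rel))
  X <- rel[keep, , drop = FALSE]
  if (renormalizeAfterMatch && nrow(X)) {
    cs <- colSums(X)
    if (any(cs == 0)) {
      stop("sample(s) with no matched taxa cannot be renormalized: ",
           paste(colnames(X)[cs == 0], collapse = ", "))
    }
    X <- sweep(X, 2, cs, "/")
  }
  rd <- DataFrame(taxon_name = matches$taxon_name,
                  strain_ids = matches$strain_ids)
  out <- SummarizedExperiment::SummarizedExperiment(
    assays = list(relabund = X), rowData = rd)
  prior <- metadata(collapsed)$discard_log
  if (is.null(prior)) prior <- data.frame(item = character(), reason = character())
  metadata(out)$discard_log <- rbind(prior, metadata(matches)$discard_log)
  metadata(out)$level <- level
  metadata(out)$renormalized <- renormalizeAfterMatch
  out
}
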