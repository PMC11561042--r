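#' Construct a ReconstructionBundle from in-memory tables
#'
#' Strains and reactions are sorted lexicographically by id; the presence
#' matrix is re-indexed accordingly. Reactions found in no strain are
#' rejected: such an all-zero column of the reaction matrix would be
#' indistinguishable from genuine absence downstream.
#'
#' @param strains data.frame with `strain_id` and the seven rank columns
#'   (`domain` ... `species`); missing ranks as empty strings.
#' @param reactions data.frame with `reaction_id` and `subsystem`
#'   (empty string allowed).
#' @param presence 0/1 matrix (strains x reactions, dimnames set) or a long
#'   data.frame with columns `strain_id`, `reaction_id`.
#' @param ceMap optional data.frame with columns `reaction_id`,
#'   `ce_subsystem`, assigning exchange reactions to compound-exchange
#'   subsystems.
#' @param name bundle label.
#' @return a validated [ReconstructionBundle-class] object.
#' @export
newReconstructionBundle <- function(strains, reactions, presence,
                                    ceMap = NULL, name = "bundle") {
  strains <- as.data.frame(strains, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  for (rk in .RANKS) {
    if (is.null(strains[[rk]])) strains[[rk]] <- ""
    strains[[rk]][is.na(strains[[rk]])] <- ""
  }
  strains$strain_id <- as.character(strains$strain_id)
  reactions$reaction_id <- as.character(reactions$reaction_id)
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""

  if (is.data.frame(presence)) {
    presence <- .presenceFromLong(presence, strains$strain_id, reactions$reaction_id)
  }
  if (!is.matrix(presence)) stop("presence must be a matrix or a long data.frame")
  if (is.null(rownames(presence)) || is.null(colnames(presence))) {
    stop("presence matrix must carry strain and reaction dimnames")
  }
  if (!setequal(rownames(presence), strains$strain_id) ||
      !setequal(colnames(presence), reactions$reaction_id)) {
    stop("schema error: presence matrix dimensions/names do not match the ",
         "strain and reaction tables")
  }

  so <- order(strains$strain_id)
  ro <- order(reactions$reaction_id)
  strains <- strains[so, c("strain_id", .RANKS), drop = FALSE]
  reactions <- reactions[ro, , drop = FALSE]
  rownames(strains) <- NULL
  rownames(reactions) <- NULL
  presence <- presence[strains$strain_id, reactions$reaction_id, drop = FALSE]
  storage.mode(presence) <- "double"

  reactions$ce_subsystem <- NA_character_
  if (!is.null(ceMap) && nrow(ceMap)) {
    ceMap <- as.data.frame(ceMap, stringsAsFactors = FALSE)
    unknown <- setdiff(ceMap$reaction_id, reactions$reaction_id)
    if (length(unknown)) {
      stop("schema error: CE map names unknown reaction(s): ",
           paste(unknown, collapse = ", "))
    }
    idx <- match(ceMap$reaction_id, reactions$reaction_id)
    reactions$ce_subsystem[idx] <- as.character(ceMap$ce_subsystem)
  }
  reactions$is_exchange <- !is.na(reactions$ce_subsystem) |
    grepl("^EX_", reactions$reaction_id)

  new("ReconstructionBundle", name = name, strains = strains,
      reactions = reactions, presence = presence)
}

.presenceFromLong <- function(long, strainIds, reactionIds) {
  if (!all(c("strain_id", "reaction_id") %in% names(long))) {
    stop("long presence table needs columns strain_id, reaction_id")
  }
  m <- matrix(0, length(strainIds), length(reactionIds),
              dimnames = list(strainIds, reactionIds))
  si <- match(as.character(long$strain_id), strainIds)
  ri <- match(as.character(long$reaction_id), reactionIds)
  if (anyNA(si)) {
    stop("schema error: presence names unknown strain(s): ",
         paste(unique(long$strain_id[is.na(si)]), collapse = ", "))
  }
  if (anyNA(ri)) {
    stop("schema error: presence names unknown reaction(s): ",
         paste(unique(long$reaction_id[is.na(ri)]), collapse = ", "))
  }
  m[cbind(si, ri)] <- 1
  m
}

#' Load a reconstruction bundle from its TSV file set
#'
#' Reads the four-file bundle schema: `strains.tsv` (strain_id + seven rank
#' columns), `reactions.tsv` (reaction_id, subsystem), `presence.tsv`
#' (either long format with columns strain_id/reaction_id, or a dense 0/1
#' matrix whose first column is strain_id), and an optional `ce_map.tsv`
#' (reaction_id, ce_subsystem) assigning exchange reactions to
#' compound-exchange subsystems.
#'
#' @param strainsPath,reactionsPath,presencePath,ceMapPath file paths;
#'   `ceMapPath` may be `NULL`.
#' @param name bundle label.
#' @return a [ReconstructionBundle-class].
#' @export
loadBundle <- function(strainsPath, reactionsPath, presencePath,
                       ceMapPath = NULL, name = "bundle") {
  for (p in c(strainsPath, reactionsPath, presencePath, ceMapPath)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  strains <- .readTsv(strainsPath)
  reactions <- .readTsv(reactionsPath)
  praw <- .readTsv(presencePath)
  ceMap <- if (!is.null(ceMapPath)) .readTsv(ceMapPath) else NULL

  if (all(c("strain_id", "reaction_id") %in% names(praw)) && ncol(praw) == 2) {
    presence <- praw
  } else {
    # dense form: first column strain ids, remaining columns reactions
    m <- as.matrix(praw[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- as.character(praw[[1]])
    if (anyNA(m) || !all(m %in% c(0, 1))) {
      stop("schema error: dense presence matrix must contain only 0/1")
    }
    presence <- m
  }
  newReconstructionBundle(strains, reactions, presence, ceMap, name)
}

#' Write a bundle back to the TSV file set
#'
#' Emits `strains.tsv`, `reactions.tsv`, `presence.tsv` (long format) and,
#' when any reaction carries a CE subsystem, `ce_map.tsv`. Re-loading the
#' emitted files reproduces the bundle exactly.
#'
#' @param bundle a [ReconstructionBundle-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- strainTable(bundle)
  rx <- reactionTable(bundle)
  pm <- presenceMatrix(bundle)
  paths <- file.path(dir, c("strains.tsv", "reactions.tsv", "presence.tsv", "ce_map.tsv"))
  .writeTsv(st, paths[1])
  .writeTsv(rx[, c("reaction_id", "subsystem")], paths[2])
  idx <- which(pm == 1, arr.ind = TRUE)
  long <- data.frame(strain_id = rownames(pm)[idx[, 1]],
                     reaction_id = colnames(pm)[idx[, 2]],
                     stringsAsFactors = FALSE)
  long <- long[order(long$strain_id, long$reaction_id), , drop = FALSE]
  .writeTsv(long, paths[3])
  ce <- rx[!is.na(rx$ce_subsystem), c("reaction_id", "ce_subsystem"), drop = FALSE]
  if (nrow(ce)) .writeTsv(ce, paths[4]) else paths <- paths[1:3]
  invisible(paths)
}

#' Normalize a taxon name for matching
#'
#' Matching between lineage strings from 16S classifiers (Silva-style) and
#' reconstruction strain names must be robust to decoration: rank prefixes
#' (`g__`, `s__`, ...), underscores vs spaces, repeated whitespace and
#' letter case. This helper strips all of these.
#'
#' @param x character vector of names.
#' @return normalized lower-case names.
#' @export
normalizeTaxonName <- function(x) {
  x <- sub("^[a-zA-Z]__", "", trimws(x))
  x <- gsub("_", " ", x, fixed = TRUE)
  x <- gsub("[[:space:]]+", " ", x)
  tolower(trimws(x))
}

# Display form of the species key: "Genus epithet" unless the species field
# already repeats the genus.
.speciesKeyDisplay <- function(genus, species) {
  genus[is.na(genus)] <- ""
  species[is.na(species)] <- ""
  g <- gsub("_", " ", trimws(genus))
  s <- gsub("_", " ", trimws(species))
  out <- character(length(g))
  hasBoth <- nzchar(g) & nzchar(s)
  pre <- startsWith(tolower(s), paste0(tolower(g), " ")) | tolower(s) == tolower(g)
  out[hasBoth & pre] <- s[hasBoth & pre]
  out[hasBoth & !pre] <- paste(g[hasBoth & !pre], s[hasBoth & !pre])
  out
}

.strainKeys <- function(bundle, level) {
  st <- strainTable(bundle)
  if (level == "genus") {
    normalizeTaxonName(st$genus)
  } else {
    normalizeTaxonName(.speciesKeyDisplay(st$genus, st$species))
  }
}

#' Match taxon names against the strains of a bundle
#'
#' Each input name is compared, after [normalizeTaxonName()], against the
#' strain lineages at the chosen rank. At species level the match key is
#' the binomial "genus species" (epithets alone are not unique across
#' genera). Names matching no strain are omitted from the result and
#' recorded on the discard log with reason "no reconstruction match", since
#' only reconstruction-covered taxa can be scored.
#'
#' @param bundle a [ReconstructionBundle-class].
#' @param taxonNames character vector of names at rank `level`.
#' @param level "species" (default) or "genus".
#' @return a [S4Vectors::DataFrame] with columns `taxon_name` and
#'   `strain_ids` (a [IRanges::CharacterList]); the discard log is stored
#'   in `S4Vectors::metadata(.)$discard_log` as a data.frame with columns
#'   `item`, `reason`.
#' @export
matchTaxa <- function(bundle, taxonNames, level = c("species", "genus")) {
  level <- match.arg(level)
  keys <- .strainKeys(bundle, level)
  ids <- strainTable(bundle)$strain_id
  qn <- normalizeTaxonName(taxonNames)
  hits <- lapply(qn, function(q) {
    if (!nzchar(q)) character() else ids[keys == q]
  })
  matched <- lengths(hits) > 0
  res <- DataFrame(
    taxon_name = as.character(taxonNames)[matched],
    strain_ids = CharacterList(hits[matched])
  )
  discard <- data.frame(
    item = as.character(taxonNames)[!matched],
    reason = rep("no reconstruction match", sum(!matched)),
    stringsAsFactors = FALSE
  )
  metadata(res)$discard_log <- discard
  res
}

#' The ordered subsystem universe of a bundle
#'
#' The deterministic (lexicographically sorted) union of the annotated
#' subsystems and the compound-exchange subsystems. A reaction carrying
#' both an annotated subsystem and a CE assignment contributes to both; a
#' reaction with neither belongs to no subsystem.
#'
#' @param bundle a [ReconstructionBundle-class].
#' @return character vector of subsystem names (possibly empty).
#' @export
subsystemUniverse <- function(bundle) {
  rx <- reactionTable(bundle)
  ann <- unique(rx$subsystem[nzchar(rx$subsystem)])
  ce <- unique(rx$ce_subsystem[!is.na(rx$ce_subsystem)])
  sort(unique(c(ann, ce)))
}

# subsystem -> member reaction ids (annotated membership plus CE membership)
.subsystemMembers <- function(bundle) {
  rx <- reactionTable(bundle)
  subs <- subsystemUniverse(bundle)
  members <- lapply(subs, function(z) {
    rx$reaction_id[(nzchar(rx$subsystem) & rx$subsystem == z) |
                   (!is.na(rx$ce_subsystem) & rx$ce_subsystem == z)]
  })
  names(members) <- subs
  members
}
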