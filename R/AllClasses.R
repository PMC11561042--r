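#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges CharacterList
NULL

#' ReconstructionBundle: a collection of strain-level metabolic models
#'
#' A bundle holds the content of a gut-microbiota metabolic reconstruction
#' (AGORA/AGREDA-style) needed for activity scoring: the strains with their
#' taxonomic lineages, the reactions with their subsystem annotation
#' (including compound-exchange, "CE", subsystems for exchange reactions),
#' and the binary strain-by-reaction presence matrix.
#'
#' Strains and reactions are sorted lexicographically by id at construction
#' so that all derived matrices have a reproducible order.
#'
#' @slot name        character(1) label for the bundle (e.g. "AGREDA-like").
#' @slot strains     data.frame with columns `strain_id`, `domain`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species` (empty string = missing
#'   rank; `species` holds the epithet or the full binomial).
#' @slot reactions   data.frame with columns `reaction_id`, `subsystem`
#'   (empty allowed), `is_exchange` (logical) and `ce_subsystem`
#'   (NA when absent; only exchange reactions may carry one).
#' @slot presence    numeric 0/1 matrix, strains x reactions, dimnames set.
#'
#' @seealso [loadBundle()], [matchTaxa()], [subsystemUniverse()]
#' @export
setClass("ReconstructionBundle",
  representation(
    name = "character",
    strains = "data.frame",
    reactions = "data.frame",
    presence = "matrix"
  )
)

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

setValidity("ReconstructionBundle", function(object) {
  msg <- character()
  st <- object@strains
  rx <- object@reactions
  pm <- object@presence
  need.st <- c("strain_id", .RANKS)
  if (!all(need.st %in% names(st))) {
    msg <- c(msg, paste("strains must have columns:", paste(need.st, collapse = ", ")))
  } else {
    if (anyDuplicated(st$strain_id)) msg <- c(msg, "duplicated strain_id")
    if (any(!nzchar(st$strain_id))) msg <- c(msg, "empty strain_id")
    bad <- nzchar(st$species) & !nzchar(st$genus)
    if (any(bad)) msg <- c(msg, "strain with species but empty genus")
  }
  need.rx <- c("reaction_id", "subsystem", "is_exchange", "ce_subsystem")
  if (!all(need.rx %in% names(rx))) {
    msg <- c(msg, paste("reactions must have columns:", paste(need.rx, collapse = ", ")))
  } else {
    if (anyDuplicated(rx$reaction_id)) msg <- c(msg, "duplicated reaction_id")
    bad <- !is.na(rx$ce_subsystem) & !rx$is_exchange
    if (any(bad)) msg <- c(msg, "ce_subsystem set on non-exchange reaction")
  }
  if (!identical(rownames(pm), st$strain_id)) {
    msg <- c(msg, "presence rownames must equal strain ids")
  }
  if (!identical(colnames(pm), rx$reaction_id)) {
    msg <- c(msg, "presence colnames must equal reaction ids")
  }
  if (length(pm) && !all(pm %in% c(0, 1))) msg <- c(msg, "presence entries must be 0 or 1")
  if (length(pm) && any(colSums(pm) == 0)) {
    orphan <- colnames(pm)[colSums(pm) == 0]
    msg <- c(msg, paste("reaction(s) present in zero strains:", paste(orphan, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Subsystem normalization weights (matrix S)
#'
#' Relative contribution of each reaction to each subsystem. In `global`
#' mode a single matrix applies to all samples: member reactions of a
#' subsystem with `m` annotated reactions get weight `1/m`, so each row sums
#' to 1. In `contextualized` mode (the mgPipe-style contrast) the weights
#' are recomputed per sample over the member reactions with nonzero reaction
#' activity in that sample, and one matrix is stored per sample.
#'
#' @slot mode           "global" or "contextualized".
#' @slot subsystemNames ordered subsystem names (rows).
#' @slot reactionIds    ordered reaction ids (columns).
#' @slot global         the s x r weight matrix (global mode; empty otherwise).
#' @slot perSample      named list of s x r matrices, one per sample
#'   (contextualized mode; empty otherwise).
#' @slot members        named list: subsystem -> member reaction ids.
#' @export
setClass("SubsystemWeights",
  representation(
    mode = "character",
    subsystemNames = "character",
    reactionIds = "character",
    global = "matrix",
    perSample = "list",
    members = "list"
  )
)

setValidity("SubsystemWeights", function(object) {
  if (!object@mode %in% c("global", "contextualized")) {
    return("mode must be 'global' or 'contextualized'")
  }
  if (object@mode == "global") {
    if (!identical(rownames(object@global), object@subsystemNames)) {
      return("global matrix rows must match subsystemNames")
    }
    if (!identical(colnames(object@global), object@reactionIds)) {
      return("global matrix columns must match reactionIds")
    }
  }
  TRUE
})

#' Principal component analysis of activity scores
#'
#' Samples are the observations, reactions/subsystems the variables. A
#' deterministic sign convention is applied: within each component the
#' loading with the largest magnitude is made positive.
#'
#' @slot sampleIds sample identifiers (rows of `coordinates`).
#' @slot coordinates n x K matrix of component scores.
#' @slot explainedVarianceRatio fraction of total variance per component,
#'   non-increasing, each in \[0, 1\].
#' @slot loadings feature x K matrix of loadings.
#' @export
setClass("PcaResult",
  representation(
    sampleIds = "character",
    coordinates = "matrix",
    explainedVarianceRatio = "numeric",
    loadings = "matrix"
  )
)

setValidity("PcaResult", function(object) {
  evr <- object@explainedVarianceRatio
  if (length(evr)) {
    if (any(evr < -1e-12 | evr > 1 + 1e-12)) return("explainedVarianceRatio outside [0,1]")
    if (any(diff(evr) > 1e-12)) return("explainedVarianceRatio must be non-increasing")
    if (sum(evr) > 1 + 1e-9) return("explainedVarianceRatio sums to more than 1")
  }
  if (nrow(object@coordinates) != length(object@sampleIds)) {
    return("coordinates rows must match sampleIds")
  }
  TRUE
})

#' Hierarchical clustering order for heatmap display
#'
#' Row and column leaf orders from independent agglomerative clusterings,
#' plus the merge heights of each dendrogram.
#'
#' @slot rowOrder,colOrder integer permutations of row/column indices.
#' @slot rowHeights,colHeights merge heights (non-decreasing for average
#'   linkage).
#' @slot rowLabels,colLabels the row/column identifiers being permuted.
#' @export
setClass("ClusterOrder",
  representation(
    rowOrder = "integer",
    colOrder = "integer",
    rowHeights = "numeric",
    colHeights = "numeric",
    rowLabels = "character",
    colLabels = "character"
  )
)

setValidity("ClusterOrder", function(object) {
  if (!identical(sort(object@rowOrder), seq_along(object@rowOrder))) {
    return("rowOrder is not a permutation")
  }
  if (!identical(sort(object@colOrder), seq_along(object@colOrder))) {
    return("colOrder is not a permutation")
  }
  TRUE
})
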