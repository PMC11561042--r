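#' Build the reaction-by-taxon presence-ratio matrix R
#'
#' Entry `R[k, i]` is the fraction of the strains matched to taxon `i`
#' whose model contains reaction `k`: a reaction carried by every strain
#' of the taxon gets full weight 1, one carried by a subset gets a
#' proportionally lower weight (3 of 4 strains gives 0.75). The
#' `weightMode = "full"` contrast reproduces the mgPipe rule of granting
#' full weight whenever *any* strain of the taxon carries the reaction.
#'
#' @param bundle a [ReconstructionBundle-class].
#' @param matches the DataFrame returned by [matchTaxa()] (or the rowData
#'   of an abundance matrix): columns `taxon_name`, `strain_ids`.
#' @param weightMode "ratio" (default) or "full".
#' @return numeric matrix, reactions x taxa, entries in \[0, 1\].
#' @export
buildReactionMatrix <- function(bundle, matches, weightMode = c("ratio", "full")) {
  weightMode <- match.arg(weightMode)
  if (!nrow(matches)) stop("matches is empty")
  pm <- presenceMatrix(bundle)
  allIds <- rownames(pm)
  cols <- lapply(seq_len(nrow(matches)), function(i) {
    ids <- matches$strain_ids[[i]]
    if (!length(ids)) {
      stop("taxon '", matches$taxon_name[i], "' has zero associated strains")
    }
    missing <- setdiff(ids, allIds)
    if (length(missing)) {
      stop("unknown strain id(s) for taxon '", matches$taxon_name[i], "': ",
           paste(missing, collapse = ", "))
    }
    colMeans(pm[ids, , drop = FALSE])
  })
  R <- do.call(cbind, cols)
  colnames(R) <- as.character(matches$taxon_name)
  if (weightMode == "full") R[R > 0] <- 1
  R
}

#' Reaction activity scores W = R X
#'
#' The matrix product of the reaction presence-ratio matrix with the
#' relative-abundance matrix: `W[k, j]` is the presence ratio of reaction
#' `k` in sample `j`, weighting each matched taxon by its relative
#' frequency. With column sums of X at most 1 and R at most 1, every score
#' lies in \[0, 1\].
#'
#' @param R reaction x taxon matrix from [buildReactionMatrix()].
#' @param X abundance SummarizedExperiment from [buildAbundanceMatrix()]
#'   (or a plain taxon x sample matrix). Taxon order must agree with `R`.
#' @return a SummarizedExperiment with assay `activity` (reactions x
#'   samples).
#' @export
computeReactionScores <- function(R, X) {
  Xm <- if (methods::is(X, "SummarizedExperiment")) {
    SummarizedExperiment::assay(X)
  } else {
    as.matrix(X)
  }
  if (!identical(colnames(R), rownames(Xm))) {
    stop("taxon order mismatch between R columns and X rows")
  }
  W <- R %*% Xm
  SummarizedExperiment::SummarizedExperiment(assays = list(activity = W))
}

#' Build the subsystem normalization matrix S
#'
#' In `global` mode `S[z, k] = 1/m_z` for each of the `m_z` reactions
#' annotated to subsystem `z` (annotated subsystem or CE subsystem), else
#' 0, so each subsystem row sums to 1. In `contextualized` mode (the
#' mgPipe-style contrast) the denominator is recomputed per sample as the
#' number of member reactions with nonzero activity in that sample; a
#' subsystem with no active member reaction in a sample gets an all-zero
#' row there (its score is 0). Subsystems with zero annotated reactions in
#' the whole bundle are excluded with a warning.
#'
#' @param bundle a [ReconstructionBundle-class].
#' @param reactionIds reaction ordering for the columns of S; defaults to
#'   the bundle's reactions.
#' @param mode "global" (default) or "contextualized".
#' @param W reaction activity (SummarizedExperiment or matrix); required
#'   in contextualized mode.
#' @param epsilon presence threshold for the contextualized mode; a
#'   reaction counts as present in a sample when its activity exceeds
#'   this value (default 0, an exact test, since W is built from exact
#'   ratios).
#' @return a [SubsystemWeights-class].
#' @export
buildSubsystemMatrix <- function(bundle, reactionIds = NULL,
                                 mode = c("global", "contextualized"),
                                 W = NULL, epsilon = 0) {
  mode <- match.arg(mode)
  if (is.null(reactionIds)) reactionIds <- reactionTable(bundle)$reaction_id
  members <- .subsystemMembers(bundle)
  members <- lapply(members, intersect, y = reactionIds)
  empty <- lengths(members) == 0
  if (any(empty)) {
    warning("subsystem(s) with zero annotated reactions excluded: ",
            paste(names(members)[empty], collapse = ", "))
    members <- members[!empty]
  }
  subs <- names(members)
  if (mode == "global") {
    S <- matrix(0, length(subs), length(reactionIds),
                dimnames = list(subs, reactionIds))
    for (z in subs) S[z, members[[z]]] <- 1 / length(members[[z]])
    new("SubsystemWeights", mode = "global", subsystemNames = subs,
        reactionIds = reactionIds, global = S, perSample = list(),
        members = members)
  } else {
    if (is.null(W)) stop("contextualized mode requires the reaction activity W")
    Wm <- .asScoreMatrix(W)
    if (!identical(rownames(Wm), reactionIds)) {
      stop("reaction order mismatch between W and reactionIds")
    }
    perSample <- lapply(colnames(Wm), function(j) {
      S <- matrix(0, length(subs), length(reactionIds),
                  dimnames = list(subs, reactionIds))
      active <- reactionIds[Wm[, j] > epsilon]
      for (z in subs) {
        mem <- intersect(members[[z]], active)
        if (length(mem)) S[z, mem] <- 1 / length(mem)
      }
      S
    })
    names(perSample) <- colnames(Wm)
    new("SubsystemWeights", mode = "contextualized", subsystemNames = subs,
        reactionIds = reactionIds, global = matrix(0, 0, 0), perSample = perSample,
        members = members)
  }
}

#' Subsystem activity scores Y = S W
#'
#' In global mode a single matrix product; in contextualized mode each
#' sample's column of W is multiplied by that sample's own S.
#'
#' @param S a [SubsystemWeights-class].
#' @param W reaction activity (SummarizedExperiment or matrix), reaction
#'   order aligned with `S`.
#' @return a SummarizedExperiment with assay `activity` (subsystems x
#'   samples).
#' @export
computeSubsystemScores <- function(S, W) {
  Wm <- .asScoreMatrix(W)
  if (!identical(rownames(Wm), S@reactionIds)) {
    stop("reaction order mismatch between S and W")
  }
  if (S@mode == "global") {
    Y <- S@global %*% Wm
  } else {
    if (!identical(names(S@perSample), colnames(Wm))) {
      stop("sample mismatch between contextualized S and W")
    }
    Y <- vapply(colnames(Wm),
                function(j) drop(S@perSample[[j]] %*% Wm[, j]),
                numeric(length(S@subsystemNames)))
    Y <- matrix(Y, nrow = length(S@subsystemNames),
                dimnames = list(S@subsystemNames, colnames(Wm)))
  }
  SummarizedExperiment::SummarizedExperiment(assays = list(activity = Y))
}

#' End-to-end activity scoring
#'
#' Orchestrates the full pipeline: collapse the feature table to the
#' chosen rank, normalize to relative frequencies and keep the
#' reconstruction-matched taxa (X), build the reaction presence-ratio
#' matrix (R), compute reaction scores W = R X, build the subsystem
#' weights (S) and compute subsystem scores Y = S W. Defaults are species
#' level, ratio weights, global subsystem mode and no renormalization
#' after matching.
#'
#' @param featureTable SummarizedExperiment from [parseFeatureTable()].
#' @param taxonomy DataFrame from [parseTaxonomy()].
#' @param bundle a [ReconstructionBundle-class].
#' @param level "species" (default) or "genus".
#' @param weightMode "ratio" (default) or "full".
#' @param subsystemMode "global" (default) or "contextualized".
#' @param renormalizeAfterMatch logical, default FALSE.
#' @param ambiguityMarkers see [collapseToLevel()].
#' @return a list with elements `reactionScores` and `subsystemScores`
#'   (SummarizedExperiments with assay `activity`), `abundance` (the X
#'   object), `discardLog` (data.frame item/stage/reason: taxa dropped as
#'   ambiguous or unmatched, plus reactions belonging to no subsystem,
#'   reported as "unannotated reaction") and `params` (the parameter
#'   record of the run).
#' @export
generateFeatures <- function(featureTable, taxonomy, bundle,
                             level = c("species", "genus"),
                             weightMode = c("ratio", "full"),
                             subsystemMode = c("global", "contextualized"),
                             renormalizeAfterMatch = FALSE,
                             ambiguityMarkers = defaultAmbiguityMarkers()) {
  level <- match.arg(level)
  weightMode <- match.arg(weightMode)
  subsystemMode <- match.arg(subsystemMode)

  collapsed <- tryCatch(
    collapseToLevel(featureTable, taxonomy, level, ambiguityMarkers),
    error = function(e) stop("collapse stage: ", conditionMessage(e), call. = FALSE))
  X <- tryCatch(
    buildAbundanceMatrix(collapsed, bundle, level, renormalizeAfterMatch),
    error = function(e) stop("abundance stage: ", conditionMessage(e), call. = FALSE))
  if (!nrow(X)) stop("scoring stage: no taxa matched the reconstruction")
  matches <- SummarizedExperiment::rowData(X)
  R <- tryCatch(
    buildReactionMatrix(bundle, matches, weightMode),
    error = function(e) stop("reaction-matrix stage: ", conditionMessage(e), call. = FALSE))
  W <- computeReactionScores(R, X)
  S <- tryCatch(
    buildSubsystemMatrix(bundle, rownames(W), subsystemMode, W = W),
    error = function(e) stop("subsystem-matrix stage: ", conditionMessage(e), call. = FALSE))
  Y <- computeSubsystemScores(S, W)

  rx <- reactionTable(bundle)
  unann <- rx$reaction_id[!nzchar(rx$subsystem) & is.na(rx$ce_subsystem)]
  dl <- metadata(X)$discard_log
  log <- rbind(
    data.frame(item = dl$item, stage = rep("features", nrow(dl)),
               reason = dl$reason, stringsAsFactors = FALSE),
    data.frame(item = unann, stage = rep("scoring", length(unann)),
               reason = rep("unannotated reaction", length(unann)),
               stringsAsFactors = FALSE)
  )
  params <- list(level = level, weight_mode = weightMode,
                 subsystem_mode = subsystemMode,
                 renormalize_after_match = renormalizeAfterMatch,
                 bundle = bundleName(bundle))
  list(reactionScores = W, subsystemScores = Y, abundance = X,
       discardLog = log, params = params)
}
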