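#' @rdname ReconstructionBundle-class
#' @param x a `ReconstructionBundle`.
#' @export
setGeneric("bundleName", function(x) standardGeneric("bundleName"))

#' @rdname ReconstructionBundle-class
#' @export
setGeneric("strainTable", function(x) standardGeneric("strainTable"))

#' @rdname ReconstructionBundle-class
#' @export
setGeneric("reactionTable", function(x) standardGeneric("reactionTable"))

#' @rdname ReconstructionBundle-class
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname ReconstructionBundle-class
#' @export
setMethod("bundleName", "ReconstructionBundle", function(x) x@name)

#' @rdname ReconstructionBundle-class
#' @export
setMethod("strainTable", "ReconstructionBundle", function(x) x@strains)

#' @rdname ReconstructionBundle-class
#' @export
setMethod("reactionTable", "ReconstructionBundle", function(x) x@reactions)

#' @rdname ReconstructionBundle-class
#' @export
setMethod("presenceMatrix", "ReconstructionBundle", function(x) x@presence)

setMethod("show", "ReconstructionBundle", function(object) {
  rx <- object@reactions
  cat("ReconstructionBundle \"", object@name, "\"\n", sep = "")
  cat("  strains:   ", nrow(object@strains), "\n", sep = "")
  cat("  reactions: ", nrow(rx), " (", sum(rx$is_exchange), " exchange)\n", sep = "")
  nsub <- length(subsystemUniverse(object))
  cat("  subsystems:", nsub, "(annotated + CE)\n")
})

#' @rdname PcaResult-class
#' @param x a `PcaResult`.
#' @export
setGeneric("pcaCoordinates", function(x) standardGeneric("pcaCoordinates"))

#' @rdname PcaResult-class
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname PcaResult-class
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' @rdname PcaResult-class
#' @export
setMethod("pcaCoordinates", "PcaResult", function(x) x@coordinates)

#' @rdname PcaResult-class
#' @export
setMethod("explainedVariance", "PcaResult", function(x) x@explainedVarianceRatio)

#' @rdname PcaResult-class
#' @export
setMethod("pcaLoadings", "PcaResult", function(x) x@loadings)

setMethod("show", "PcaResult", function(object) {
  k <- ncol(object@coordinates)
  cat("PcaResult:", length(object@sampleIds), "samples,", k, "components\n")
  cat("  explained variance ratio:",
      paste(sprintf("%.3f", object@explainedVarianceRatio), collapse = ", "), "\n")
})

setMethod("show", "SubsystemWeights", function(object) {
  cat("SubsystemWeights (", object@mode, " mode): ",
      length(object@subsystemNames), " subsystems x ",
      length(object@reactionIds), " reactions\n", sep = "")
  if (object@mode == "contextualized") {
    cat("  per-sample matrices:", length(object@perSample), "\n")
  }
})

setMethod("show", "ClusterOrder", function(object) {
  cat("ClusterOrder:", length(object@rowOrder), "rows x",
      length(object@colOrder), "columns\n")
})
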