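#' PCA of samples in activity-score space
#'
#' Samples are the observations and features (reactions or subsystems) the
#' variables. Mean-centering is on and variance-scaling off by default:
#' the scores already share the \[0,1\] scale, and scaling would inflate
#' near-constant features. A deterministic sign convention makes the
#' largest-magnitude loading of each component positive.
#'
#' @param scores SummarizedExperiment or matrix (features x samples).
#' @param nComponents number of components to keep (default 2).
#' @param center,scale passed to [stats::prcomp()].
#' @return a [PcaResult-class].
#' @export
pcaScores <- function(scores, nComponents = 2, center = TRUE, scale = FALSE) {
  m <- .asScoreMatrix(scores)
  x <- t(m)  # samples x features
  if (nrow(x) < 2) stop("PCA needs at least 2 samples")
  if (nComponents > min(dim(x))) {
    stop("nComponents exceeds min(features, samples)")
  }
  if (all(apply(x, 2, function(v) max(v) == min(v)))) {
    stop("constant score matrix: no variance to decompose")
  }
  if (scale) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0)) stop("cannot scale: constant feature(s) present")
  }
  pc <- stats::prcomp(x, center = center, scale. = scale)
  k <- min(nComponents, ncol(pc$rotation))
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- pc$x[, seq_len(k), drop = FALSE]
  loads <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(loads[, j]))
    if (loads[top, j] < 0) {
      loads[, j] <- -loads[, j]
      coords[, j] <- -coords[, j]
    }
  }
  new("PcaResult",
      sampleIds = rownames(x),
      coordinates = coords,
      explainedVarianceRatio = evr[seq_len(k)],
      loadings = loads)
}

#' Silhouette score of metadata groups in PCA space
#'
#' Mean silhouette coefficient over samples, with Euclidean distance on
#' the first `nComponents` PCA coordinates and the metadata group column
#' as labels. Values near 1 indicate tight, well-separated groups; values
#' near 0 indicate overlap. Samples in singleton groups take silhouette
#' width 0 (the standard convention).
#'
#' @param pca a [PcaResult-class].
#' @param metadata DataFrame/data.frame with rownames = sample ids.
#' @param groupColumn metadata column with group labels.
#' @param nComponents number of leading coordinates to use (default 2).
#' @return numeric scalar in \[-1, 1\].
#' @export
silhouetteOfGroups <- function(pca, metadata, groupColumn, nComponents = 2) {
  coords <- pcaCoordinates(pca)
  k <- min(nComponents, ncol(coords))
  coords <- coords[, seq_len(k), drop = FALSE]
  if (!(groupColumn %in% colnames(metadata))) {
    stop("group column '", groupColumn, "' not found in metadata")
  }
  labels <- as.character(metadata[[groupColumn]])
  names(labels) <- rownames(metadata)
  labels <- labels[pca@sampleIds]
  if (anyNA(labels)) stop("metadata missing for sample(s): ",
                          paste(pca@sampleIds[is.na(labels)], collapse = ", "))
  if (length(unique(labels)) < 2) {
    stop("silhouette needs at least 2 groups")
  }
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             stats::dist(coords))
  mean(sil[, "sil_width"])
}

#' Hierarchical clustering order for heatmap display
#'
#' Rows and columns are clustered independently with agglomerative
#' (average-linkage, Euclidean by default) clustering; the returned leaf
#' orders are deterministic for fixed input.
#'
#' @param scores SummarizedExperiment or matrix (features x samples).
#' @param metric distance metric (only "euclidean" supported).
#' @param linkage agglomeration method (only "average" supported).
#' @return a [ClusterOrder-class].
#' @export
hierarchicalOrder <- function(scores, metric = "euclidean", linkage = "average") {
  metric <- match.arg(metric, "euclidean")
  linkage <- match.arg(linkage, "average")
  m <- .asScoreMatrix(scores)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need at least 2 rows and 2 columns")
  if (any(!is.finite(m))) stop("non-finite values in score matrix")
  hr <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  hc <- stats::hclust(stats::dist(t(m), method = metric), method = linkage)
  new("ClusterOrder",
      rowOrder = as.integer(hr$order), colOrder = as.integer(hc$order),
      rowHeights = hr$height, colHeights = hc$height,
      rowLabels = rownames(m), colLabels = colnames(m))
}

#' 1-SD covariance ellipse parameters per group
#'
#' For 2-D PCA plots: per group, the mean and the covariance of the first
#' two coordinates, summarized as ellipse center, semi-axes (square roots
#' of the covariance eigenvalues, i.e. 1 standard deviation along each
#' principal direction) and orientation angle. Rendering is left to the
#' caller; groups with fewer than 3 samples have no defined ellipse and
#' are skipped.
#'
#' @inheritParams silhouetteOfGroups
#' @return data.frame with columns `group`, `center_x`, `center_y`,
#'   `semi_major`, `semi_minor`, `angle_rad`, `n`.
#' @export
groupEllipses <- function(pca, metadata, groupColumn) {
  coords <- pcaCoordinates(pca)[, 1:2, drop = FALSE]
  labels <- as.character(metadata[[groupColumn]])
  names(labels) <- rownames(metadata)
  labels <- labels[pca@sampleIds]
  out <- lapply(unique(labels), function(g) {
    xy <- coords[labels == g, , drop = FALSE]
    if (nrow(xy) < 3) return(NULL)
    cv <- stats::cov(xy)
    eg <- eigen(cv, symmetric = TRUE)
    data.frame(group = g,
               center_x = mean(xy[, 1]), center_y = mean(xy[, 2]),
               semi_major = sqrt(max(eg$values[1], 0)),
               semi_minor = sqrt(max(eg$values[2], 0)),
               angle_rad = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
               n = nrow(xy), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
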