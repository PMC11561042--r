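#' Differential activity analysis between two sample groups
#'
#' For every row of a reaction or subsystem score matrix, compares the two
#' groups with an unpaired two-sided Wilcoxon rank-sum (Mann-Whitney)
#' test: exact when both groups have at most 8 samples and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' corrections. P-values are adjusted across all rows of the given table
#' with the Benjamini-Hochberg step-up. The effect size `delta_psi` is the
#' difference of group mean scores, `mean(groupA) - mean(groupB)`. A row
#' is flagged significant when `q_value <= alpha` and
#' `|delta_psi| >= minEffect`. Rows constant across all samples (including
#' all-zero rows) are kept with p = 1 so the multiple-testing denominator
#' stays reproducible; they are listed in `attr(., "log")`.
#'
#' @param scores SummarizedExperiment or matrix (features x samples).
#' @param metadata DataFrame/data.frame with rownames = sample ids (see
#'   [parseSampleMetadata()]).
#' @param groupColumn metadata column holding the group labels.
#' @param groupA,groupB the two labels to compare.
#' @param alpha FDR threshold (default 0.05).
#' @param minEffect minimum |delta_psi| (default 0.1).
#' @param exactMax largest per-group size for which the exact test is used
#'   (default 8).
#' @return data.frame with columns `feature_id`, `mean_a`, `mean_b`,
#'   `delta_psi`, `p_value`, `q_value`, `significant`, ordered as the
#'   input rows; constant rows noted in `attr(., "log")`.
#' @export
differentialActivity <- function(scores, metadata, groupColumn,
                                 groupA, groupB,
                                 alpha = 0.05, minEffect = 0.1,
                                 exactMax = 8) {
  m <- .asScoreMatrix(scores)
  if (!(groupColumn %in% colnames(metadata))) {
    stop("group column '", groupColumn, "' not found in metadata")
  }
  labels <- as.character(metadata[[groupColumn]])
  names(labels) <- rownames(metadata)
  common <- intersect(colnames(m), names(labels))
  sa <- common[labels[common] %in% groupA]
  sb <- common[labels[common] %in% groupB]
  if (length(sa) < 2 || length(sb) < 2) {
    stop("each group needs at least 2 samples (", groupA, ": ", length(sa),
         ", ", groupB, ": ", length(sb), ")")
  }
  A <- m[, sa, drop = FALSE]
  B <- m[, sb, drop = FALSE]
  nr <- nrow(m)
  p <- numeric(nr)
  constant <- logical(nr)
  for (i in seq_len(nr)) {
    a <- A[i, ]
    b <- B[i, ]
    vals <- c(a, b)
    if (max(vals) == min(vals)) {
      p[i] <- 1
      constant[i] <- TRUE
      next
    }
    ties <- anyDuplicated(vals) > 0
    exact <- length(a) <= exactMax && length(b) <= exactMax && !ties
    p[i] <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = exact, correct = TRUE)$p.value)
  }
  delta <- rowMeans(A) - rowMeans(B)
  q <- stats::p.adjust(p, method = "BH")
  res <- data.frame(
    feature_id = rownames(m),
    mean_a = rowMeans(A),
    mean_b = rowMeans(B),
    delta_psi = delta,
    p_value = p,
    q_value = q,
    significant = q <= alpha & abs(delta) >= minEffect,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  if (any(constant)) {
    attr(res, "log") <- paste0("constant row, p set to 1: ",
                               rownames(m)[constant])
  }
  res
}

#' Long-format score records for boxplots
#'
#' Projects selected features of a score matrix into tidy records
#' (feature, sample, group, score) ready for plotting. Samples whose
#' group value is missing are excluded and reported in `attr(., "log")`.
#'
#' @inheritParams differentialActivity
#' @param featureIds features (rows) to extract.
#' @return data.frame with columns `feature`, `sample`, `group`, `score`.
#' @export
boxplotData <- function(scores, metadata, featureIds, groupColumn) {
  m <- .asScoreMatrix(scores)
  unknown <- setdiff(featureIds, rownames(m))
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  }
  if (!(groupColumn %in% colnames(metadata))) {
    stop("group column '", groupColumn, "' not found in metadata")
  }
  labels <- as.character(metadata[[groupColumn]])
  names(labels) <- rownames(metadata)
  samples <- intersect(colnames(m), names(labels))
  grp <- labels[samples]
  missing <- samples[is.na(grp) | !nzchar(grp)]
  samples <- setdiff(samples, missing)
  recs <- expand.grid(feature = featureIds, sample = samples,
                      stringsAsFactors = FALSE)
  recs$group <- labels[recs$sample]
  recs$score <- m[cbind(recs$feature, recs$sample)]
  if (length(missing)) {
    attr(recs, "log") <- paste0("sample excluded (missing group value): ",
                                missing)
  }
  recs
}
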