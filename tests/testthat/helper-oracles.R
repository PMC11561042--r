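# Independent oracles used across test files. These deliberately avoid the
# package's own code paths (naive loops, exhaustive enumeration).

# naive triple-loop matrix product
naiveProduct <- function(A, B) {
  C <- matrix(0, nrow(A), ncol(B), dimnames = list(rownames(A), colnames(B)))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(B))) {
      acc <- 0
      for (k in seq_len(ncol(A))) acc <- acc + A[i, k] * B[k, j]
      C[i, j] <- acc
    }
  }
  C
}

# exact two-sided rank-sum p-value by enumeration of all rank assignments
# (no-ties case); mirrors the 2*min(lower tail, upper tail) convention
enumRankSumP <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  uObs <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  combos <- utils::combn(n, length(a))
  uAll <- apply(combos, 2, function(idx) {
    sum(seq_len(n)[idx]) - length(a) * (length(a) + 1) / 2
  })
  p <- 2 * min(mean(uAll <= uObs), mean(uAll >= uObs))
  min(1, p)
}

# Benjamini-Hochberg step-up, written directly from its definition
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# a small hand-assembled bundle: one taxon, four strains, one reaction in
# three of them plus a ubiquitous second reaction
fourStrainBundle <- function() {
  strains <- data.frame(
    strain_id = paste0("st", 1:4),
    domain = "Bacteria", phylum = "P", class = "C", order = "O",
    family = "F", genus = "Quadrigenus", species = "exemplaris",
    stringsAsFactors = FALSE)
  reactions <- data.frame(reaction_id = c("rA", "rB"),
                          subsystem = c("Sub1", "Sub1"),
                          stringsAsFactors = FALSE)
  presence <- matrix(c(1, 1, 1, 0,   # rA in 3 of 4 strains
                       1, 1, 1, 1),  # rB in all
                     nrow = 4,
                     dimnames = list(strains$strain_id, reactions$reaction_id))
  newReconstructionBundle(strains, reactions, presence, name = "four-strain")
}

seAssay <- function(x) SummarizedExperiment::assay(x)
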