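#' The worked toy example: 3 taxa, 6 reactions, 2 subsystems, 6 samples
#'
#' A fully determined miniature dataset used throughout the tests and
#' documentation. Three species-level taxa (a1, a2, a3) are matched to a
#' tiny reconstruction of four strains and six reactions (v1...v6) grouped
#' into two subsystems: p1 = \{v1, v2, v3\} and p2 = \{v4, v5, v6\}. Every
#' reaction carried by a taxon is carried by all its strains, except v4
#' which is present in only one of a3's two strains, so the presence-ratio
#' matrix is 0/1 everywhere except R\[v4, a3\] = 0.5. Six samples form two
#' conditions (control m1-m3, test m4-m6); the counts of sample m1 are in
#' ratio 7:3:0 across a1, a2, a3, so its relative abundances are
#' (0.7, 0.3, 0).
#'
#' @return list with elements `bundle` ([ReconstructionBundle-class]),
#'   `featureTable` (SummarizedExperiment of counts), `taxonomy`
#'   (DataFrame) and `metadata` (DataFrame with a `condition` column).
#' @export
makeToyExample <- function() {
  lineage <- function(ph, cl, or, fa, ge, sp) {
    c(domain = "Bacteria", phylum = ph, class = cl, order = or,
      family = fa, genus = ge, species = sp)
  }
  strains <- rbind(
    data.frame(strain_id = "BU_1", t(lineage("Bacteroidota", "Bacteroidia",
      "Bacteroidales", "Bacteroidaceae", "Bacteroides", "uniformis"))),
    data.frame(strain_id = "FP_1", t(lineage("Bacillota", "Clostridia",
      "Eubacteriales", "Oscillospiraceae", "Faecalibacterium", "prausnitzii"))),
    data.frame(strain_id = "EC_1", t(lineage("Pseudomonadota", "Gammaproteobacteria",
      "Enterobacterales", "Enterobacteriaceae", "Escherichia", "coli"))),
    data.frame(strain_id = "EC_2", t(lineage("Pseudomonadota", "Gammaproteobacteria",
      "Enterobacterales", "Enterobacteriaceae", "Escherichia", "coli")))
  )
  reactions <- data.frame(
    reaction_id = paste0("v", 1:6),
    subsystem = c("p1", "p1", "p1", "p2", "p2", "p2"),
    stringsAsFactors = FALSE
  )
  presence <- matrix(0, 4, 6,
                     dimnames = list(strains$strain_id, reactions$reaction_id))
  presence["BU_1", c("v1", "v2", "v3", "v4")] <- 1  # taxon a1
  presence["FP_1", c("v2", "v3", "v5", "v6")] <- 1  # taxon a2
  presence["EC_1", c("v1", "v4", "v5", "v6")] <- 1  # taxon a3, strain with v4
  presence["EC_2", c("v1", "v5", "v6")] <- 1        # taxon a3, strain without v4
  bundle <- newReconstructionBundle(strains, reactions, presence, name = "TOY")

  # counts: m1 fixed at ratio 7:3:0 (a1, a2, a3); the remaining columns are
  # free choices frozen here, with the test condition shifted towards a3
  counts <- matrix(
    c(70, 60, 65, 10, 15, 5,
      30, 35, 30, 20, 15, 25,
       0,  5,  5, 70, 70, 70),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("asv1", "asv2", "asv3"), paste0("m", 1:6)))
  featureTable <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts))

  taxonomy <- DataFrame(
    domain = rep("Bacteria", 3),
    phylum = c("Bacteroidota", "Bacillota", "Pseudomonadota"),
    class = c("Bacteroidia", "Clostridia", "Gammaproteobacteria"),
    order = c("Bacteroidales", "Eubacteriales", "Enterobacterales"),
    family = c("Bacteroidaceae", "Oscillospiraceae", "Enterobacteriaceae"),
    genus = c("Bacteroides", "Faecalibacterium", "Escherichia"),
    species = c("Bacteroides_uniformis", "prausnitzii", "Escherichia_coli"),
    row.names = c("asv1", "asv2", "asv3"))

  metadata <- DataFrame(
    condition = rep(c("control", "test"), each = 3),
    row.names = paste0("m", 1:6))

  list(bundle = bundle, featureTable = featureTable,
       taxonomy = taxonomy, metadata = metadata)
}

#' Write the toy example as the TSV file set consumed by the CLI
#'
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeToyExample <- function(dir) {
  toy <- makeToyExample()
  .writeFixture(toy, dir)
}

.writeFixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeBundle(fx$bundle, dir)
  counts <- SummarizedExperiment::assay(fx$featureTable, "counts")
  ft <- data.frame(`feature-id` = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(ft, file.path(dir, "feature_table.tsv"))
  taxStrings <- apply(as.data.frame(fx$taxonomy[, .RANKS]), 1, function(rk) {
    pre <- c("d__", "p__", "c__", "o__", "f__", "g__", "s__")
    paste0(pre, rk, collapse = "; ")
  })
  tx <- data.frame(`Feature ID` = rownames(fx$taxonomy), Taxon = taxStrings,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(tx, file.path(dir, "taxonomy.tsv"))
  md <- data.frame(`sample-id` = rownames(fx$metadata),
                   as.data.frame(fx$metadata),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .writeTsv(md, file.path(dir, "metadata.tsv"))
  invisible(dir)
}

#' Generate a seeded synthetic dataset with known structure
#'
#' Builds a random reconstruction bundle plus a matching feature table,
#' taxonomy and metadata, for property tests and power/type-I
#' simulations. Strain reaction sets are drawn independently at
#' `reactionDensity`; counts follow a Dirichlet-multinomial (overdispersed
#' and compositional, the common working model for 16S counts): per-taxon
#' Dirichlet weights are drawn once, per-sample gamma draws are normalized
#' to proportions, and samples in the second group have designated taxa
#' shifted by `groupEffect` on the log scale. Taxonomy is emitted in the
#' Silva string dialect.
#'
#' @param nTaxa,strainsPerTaxon,nReactions,nSubsystems,nSamples dataset
#'   dimensions. `nSamples` is split evenly into groups "control" and
#'   "case".
#' @param reactionDensity probability a strain carries a reaction, in
#'   (0, 1\].
#' @param abundanceConcentration Dirichlet concentration scale; smaller
#'   values give more overdispersed compositions.
#' @param groupEffect scalar or per-taxon vector of log-fold shifts
#'   applied to the "case" group.
#' @param nCeSubsystems number of compound-exchange subsystems; when
#'   positive, `2*nCeSubsystems` reactions are renamed `EX_*` and mapped
#'   to CE subsystems.
#' @param reserveFirstTaxon when TRUE, five extra reactions carried only
#'   by the strains of taxon 1 are added under a dedicated subsystem
#'   "Reserved pathway" (useful to design a subsystem whose activity
#'   tracks one taxon exclusively).
#' @param libSize multinomial library size per sample.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `bundle`, `featureTable`, `taxonomy`, `metadata`,
#'   and `spec` (the arguments as a record).
#' @export
makeSynthetic <- function(nTaxa = 20, strainsPerTaxon = 3, nReactions = 100,
                          nSubsystems = 8, nSamples = 12,
                          reactionDensity = 0.3,
                          abundanceConcentration = 50,
                          groupEffect = 0, nCeSubsystems = 0,
                          reserveFirstTaxon = FALSE,
                          libSize = 20000, seed = 1) {
  if (nReactions < 1) stop("infeasible spec: need at least one reaction")
  if (nTaxa < 1 || nSamples < 2) stop("infeasible spec: need taxa and >=2 samples")
  if (reactionDensity <= 0 || reactionDensity > 1) {
    stop("infeasible spec: reactionDensity must be in (0, 1]")
  }
  if (length(groupEffect) == 1) groupEffect <- rep(groupEffect, nTaxa)
  if (length(groupEffect) != nTaxa) stop("groupEffect must be scalar or length nTaxa")

  old <- .Random.seed.exists()
  set.seed(seed)

  genus <- sprintf("Syngenus%02d", seq_len(nTaxa))
  epithet <- sprintf("species%02d", seq_len(nTaxa))
  strains <- do.call(rbind, lapply(seq_len(nTaxa), function(i) {
    data.frame(
      strain_id = sprintf("T%02d_S%d", i, seq_len(strainsPerTaxon)),
      domain = "Bacteria", phylum = "Synphylum", class = "Synclass",
      order = "Synorder", family = "Synfamily",
      genus = genus[i], species = epithet[i],
      stringsAsFactors = FALSE)
  }))

  rxn <- sprintf("rxn%04d", seq_len(nReactions))
  if (nCeSubsystems > 0) {
    nEx <- min(2 * nCeSubsystems, nReactions)
    rxn[seq_len(nEx)] <- sprintf("EX_met%03d(e)", seq_len(nEx))
  }
  subsystem <- sprintf("Subsystem %02d",
                       1 + (seq_len(nReactions) - 1) %% nSubsystems)
  presence <- matrix(
    as.numeric(stats::runif(nrow(strains) * nReactions) < reactionDensity),
    nrow(strains), nReactions, dimnames = list(strains$strain_id, rxn))
  # every reaction must live in at least one strain
  orphan <- which(colSums(presence) == 0)
  if (length(orphan)) {
    presence[cbind(sample.int(nrow(strains), length(orphan), replace = TRUE),
                   orphan)] <- 1
  }
  reactions <- data.frame(reaction_id = rxn, subsystem = subsystem,
                          stringsAsFactors = FALSE)
  ceMap <- NULL
  if (nCeSubsystems > 0) {
    nEx <- sum(startsWith(rxn, "EX_"))
    ceMap <- data.frame(
      reaction_id = rxn[seq_len(nEx)],
      ce_subsystem = sprintf("CE family %02d", 1 + (seq_len(nEx) - 1) %% nCeSubsystems),
      stringsAsFactors = FALSE)
    reactions$subsystem[seq_len(nEx)] <- ""  # exchanges carry CE annotation only
  }
  if (reserveFirstTaxon) {
    resIds <- sprintf("rsv%02d", 1:5)
    reactions <- rbind(reactions,
                       data.frame(reaction_id = resIds,
                                  subsystem = "Reserved pathway",
                                  stringsAsFactors = FALSE))
    resM <- matrix(0, nrow(strains), 5,
                   dimnames = list(strains$strain_id, resIds))
    resM[strains$genus == genus[1], ] <- 1
    presence <- cbind(presence, resM)
  }
  bundle <- newReconstructionBundle(strains, reactions, presence, ceMap,
                                    name = sprintf("SYNTH-seed%d", seed))

  # Dirichlet-multinomial counts
  base <- as.numeric(stats::rgamma(nTaxa, shape = 1))
  base <- base / sum(base)
  nA <- ceiling(nSamples / 2)
  group <- rep(c("control", "case"), c(nA, nSamples - nA))
  samples <- sprintf("S%03d", seq_len(nSamples))
  counts <- vapply(seq_len(nSamples), function(j) {
    w <- base * if (group[j] == "case") exp(groupEffect) else 1
    alpha <- abundanceConcentration * w / sum(w)
    g <- stats::rgamma(nTaxa, shape = alpha)
    if (sum(g) == 0) g <- rep(1, nTaxa)
    drop(stats::rmultinom(1, size = libSize, prob = g / sum(g)))
  }, numeric(nTaxa))
  asv <- sprintf("asv%03d", seq_len(nTaxa))
  dimnames(counts) <- list(asv, samples)
  featureTable <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts))

  taxonomy <- DataFrame(
    domain = rep("Bacteria", nTaxa), phylum = rep("Synphylum", nTaxa),
    class = rep("Synclass", nTaxa), order = rep("Synorder", nTaxa),
    family = rep("Synfamily", nTaxa), genus = genus, species = epithet,
    row.names = asv)
  metadata <- DataFrame(condition = group, row.names = samples)

  .restoreSeed(old)
  list(bundle = bundle, featureTable = featureTable, taxonomy = taxonomy,
       metadata = metadata,
       spec = list(nTaxa = nTaxa, strainsPerTaxon = strainsPerTaxon,
                   nReactions = nReactions, nSubsystems = nSubsystems,
                   nSamples = nSamples, reactionDensity = reactionDensity,
                   abundanceConcentration = abundanceConcentration,
                   groupEffect = groupEffect, nCeSubsystems = nCeSubsystems,
                   reserveFirstTaxon = reserveFirstTaxon,
                   libSize = libSize, seed = seed))
}

.Random.seed.exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restoreSeed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Write a synthetic dataset as the TSV file set consumed by the CLI
#'
#' @param dir output directory.
#' @param ... passed to [makeSynthetic()].
#' @return invisibly, the directory.
#' @export
writeSyntheticFixture <- function(dir, ...) {
  fx <- makeSynthetic(...)
  .writeFixture(fx, dir)
}
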