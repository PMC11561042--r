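writeLines2 <- function(lines, path) writeLines(lines, path)

test_that("feature table parser handles both header dialects and rejects bad counts", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "ft.tsv")
  writeLines2(c("feature-id\ts1\ts2\ts3\ts4\ts5\ts6",
                "f1\t1\t2\t3\t4\t5\t6",
                "f2\t0\t0\t1\t1\t2\t2",
                "f3\t9\t8\t7\t6\t5\t4"), p1)
  ft <- parseFeatureTable(p1)
  expect_equal(dim(seAssay(ft)), c(3L, 6L))
  expect_identical(rownames(ft), c("f1", "f2", "f3"))

  p2 <- file.path(dir, "otu.tsv")
  writeLines2(c("#OTU ID\tsampleA\tsampleB", "o1\t5\t0", "o2\t1\t1"), p2)
  ft2 <- parseFeatureTable(p2)
  expect_identical(rownames(ft2), c("o1", "o2"))
  expect_identical(colnames(ft2), c("sampleA", "sampleB"))

  p3 <- file.path(dir, "neg.tsv")
  writeLines2(c("feature-id\ts1", "f1\t-3"), p3)
  expect_error(parseFeatureTable(p3), "negative count")

  p4 <- file.path(dir, "dup.tsv")
  writeLines2(c("feature-id\ts1", "f1\t1", "f1\t2"), p4)
  expect_error(parseFeatureTable(p4), "duplicated feature")

  p5 <- file.path(dir, "txt.tsv")
  writeLines2(c("feature-id\ts1", "f1\tabc"), p5)
  expect_error(parseFeatureTable(p5), "non-numeric")
})

test_that("taxonomy parser strips prefixes and the two dialects agree", {
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "tax.tsv")
  writeLines2(c("Feature ID\tTaxon\tConfidence",
                paste0("f1\td__Bacteria; p__Bacteroidota; c__Bacteroidia; ",
                       "o__Bacteroidales; f__Bacteroidaceae; g__Bacteroides; ",
                       "s__uniformis\t0.99"),
                "f2\td__Bacteria; p__Bacillota; c__Clostridia; o__Eubacteriales; f__Lachnospiraceae\t0.80"),
              p1)
  tx <- parseTaxonomy(p1)
  expect_identical(tx["f1", "genus"], "Bacteroides")
  expect_identical(tx["f1", "species"], "uniformis")
  # truncated lineage: genus and species empty
  expect_identical(tx["f2", "genus"], "")
  expect_identical(tx["f2", "species"], "")
  expect_equal(tx$confidence, c(0.99, 0.80))

  # rank-columns dialect round-trips to the same lineage
  p2 <- file.path(dir, "tax2.tsv")
  writeLines2(c("feature_id\tdomain\tphylum\tclass\torder\tfamily\tgenus\tspecies",
                "f1\tBacteria\tBacteroidota\tBacteroidia\tBacteroidales\tBacteroidaceae\tBacteroides\tuniformis",
                "f2\tBacteria\tBacillota\tClostridia\tEubacteriales\tLachnospiraceae\t\t"),
              p2)
  tx2 <- parseTaxonomy(p2, dialect = "rank-columns")
  expect_identical(as.data.frame(tx[, 1:7]), as.data.frame(tx2[, 1:7]))

  p3 <- file.path(dir, "dup.tsv")
  writeLines2(c("Feature ID\tTaxon", "f1\td__Bacteria", "f1\td__Bacteria"), p3)
  expect_error(parseTaxonomy(p3), "twice")
})

test_that("sample metadata parser handles the QIIME2 dialect", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "md.tsv")
  writeLines2(c("#SampleID\tcondition\tage",
                "#q2:types\tcategorical\tnumeric",
                "m1\tcontrol\t4", "m2\ttest\t5"), p)
  md <- parseSampleMetadata(p)
  expect_identical(rownames(md), c("m1", "m2"))
  expect_identical(as.character(md$condition), c("control", "test"))
})

test_that("collapse drops ambiguous assignments, merges duplicates, conserves mass", {
  counts <- matrix(c(4, 1, 6, 2, 3, 9, 5, 7),
                   nrow = 4, byrow = TRUE,
                   dimnames = list(c("f1", "f2", "f3", "f4"), c("s1", "s2")))
  ft <- SummarizedExperiment::SummarizedExperiment(assays = list(counts = counts))
  tax <- S4Vectors::DataFrame(
    domain = "Bacteria", phylum = "P", class = "C", order = "O", family = "F",
    genus = c("Bacteroides", "Bacteroides", "Escherichia", "Blautia"),
    species = c("uniformis", "uniformis", "", "sp. nova"),
    row.names = c("f1", "f2", "f3", "f4"))

  sp <- collapseToLevel(ft, tax, "species")
  # f1 + f2 merge (same binomial); f3 empty species and f4 "sp." marker drop
  expect_identical(rownames(sp), "Bacteroides uniformis")
  expect_equal(unname(seAssay(sp)["Bacteroides uniformis", ]), c(4 + 6, 1 + 2))
  dl <- S4Vectors::metadata(sp)$discard_log
  expect_setequal(dl$item, c("f3", "f4"))
  expect_true(all(dl$reason == "ambiguous assignation"))

  # at genus level f3 and f4 survive: their genus names are non-empty and
  # clean (the "sp." marker sits in the species epithet only)
  ge <- collapseToLevel(ft, tax, "genus")
  expect_setequal(rownames(ge), c("Bacteroides", "Escherichia", "Blautia"))

  # mass conservation: merged totals equal kept input totals per sample
  keptTotals <- colSums(counts[c("f1", "f2"), ])
  expect_equal(colSums(seAssay(sp)), keptTotals)

  # feature missing from taxonomy is treated as ambiguous
  tax2 <- tax[c("f1", "f2", "f3"), ]
  sp2 <- collapseToLevel(ft, tax2, "species")
  expect_true("f4" %in% S4Vectors::metadata(sp2)$discard_log$item)
})

test_that("abundance matrix normalizes before deletion and bounds hold", {
  toy <- makeToyExample()
  collapsed <- collapseToLevel(toy$featureTable, toy$taxonomy, "species")
  X <- buildAbundanceMatrix(collapsed, toy$bundle)
  Xm <- seAssay(X)
  # every toy taxon matches, so columns sum to exactly 1
  expect_equal(unname(colSums(Xm)), rep(1, 6))
  expect_equal(unname(Xm[, "m1"]), c(0.7, 0.3, 0))
  expect_true(all(Xm >= 0 & Xm <= 1))

  # unmatched taxon: pre-deletion normalization leaves column sums < 1
  counts <- matrix(c(5, 5), 2, 1, dimnames = list(c("fA", "fB"), "s1"))
  ft <- SummarizedExperiment::SummarizedExperiment(assays = list(counts = counts))
  tax <- S4Vectors::DataFrame(
    domain = "Bacteria", phylum = "P", class = "C", order = "O", family = "F",
    genus = c("Escherichia", "Nulligenus"),
    species = c("coli", "vacua"), row.names = c("fA", "fB"))
  coll <- collapseToLevel(ft, tax, "species")
  X2 <- buildAbundanceMatrix(coll, toy$bundle)
  expect_equal(unname(colSums(seAssay(X2))), 0.5)
  expect_true("Nulligenus vacua" %in% S4Vectors::metadata(X2)$discard_log$item)

  # renormalization restores column sums to 1 over matched taxa
  X3 <- buildAbundanceMatrix(coll, toy$bundle, renormalizeAfterMatch = TRUE)
  expect_equal(unname(colSums(seAssay(X3))), 1)

  # zero-count sample is a loud error naming the sample
  counts0 <- matrix(c(1, 0), 1, 2, dimnames = list("fA", c("ok", "empty")))
  ft0 <- SummarizedExperiment::SummarizedExperiment(assays = list(counts = counts0))
  coll0 <- collapseToLevel(ft0, tax, "species")
  expect_error(buildAbundanceMatrix(coll0, toy$bundle), "empty")
})

test_that("deleting an all-zero taxon leaves the nonzero content of X unchanged", {
  toy <- makeToyExample()
  counts <- seAssay(toy$featureTable)
  aug <- rbind(counts, asv4 = 0)
  ftAug <- SummarizedExperiment::SummarizedExperiment(assays = list(counts = aug))
  taxAug <- rbind(toy$taxonomy,
                  S4Vectors::DataFrame(domain = "Bacteria", phylum = "P",
                                       class = "C", order = "O", family = "F",
                                       genus = "Nulligenus", species = "vacua",
                                       row.names = "asv4"))
  X1 <- buildAbundanceMatrix(collapseToLevel(toy$featureTable, toy$taxonomy, "species"),
                             toy$bundle)
  X2 <- buildAbundanceMatrix(collapseToLevel(ftAug, taxAug, "species"), toy$bundle)
  expect_equal(seAssay(X1), seAssay(X2))
})
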