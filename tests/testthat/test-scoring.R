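test_that("reaction matrix entries are strain-presence ratios; full mode saturates", {
  b <- fourStrainBundle()
  m <- matchTaxa(b, "Quadrigenus exemplaris")
  R <- buildReactionMatrix(b, m, weightMode = "ratio")
  expect_equal(R["rA", "Quadrigenus exemplaris"], 0.75)
  expect_equal(R["rB", "Quadrigenus exemplaris"], 1)
  Rfull <- buildReactionMatrix(b, m, weightMode = "full")
  expect_equal(Rfull["rA", "Quadrigenus exemplaris"], 1)
  expect_true(all(Rfull >= R))
})

test_that("toy reaction matrix is 0/1 except the half-present reaction", {
  toy <- makeToyExample()
  m <- matchTaxa(toy$bundle, c("Bacteroides uniformis",
                               "Faecalibacterium prausnitzii",
                               "Escherichia coli"))
  R <- buildReactionMatrix(toy$bundle, m)
  expect_equal(R["v4", "Escherichia coli"], 0.5)
  rest <- R
  rest["v4", "Escherichia coli"] <- NA
  expect_true(all(rest[!is.na(rest)] %in% c(0, 1)))
})

test_that("W = R X matches the naive loop oracle and simple identities", {
  toy <- makeToyExample()
  res <- generateFeatures(toy$featureTable, toy$taxonomy, toy$bundle)
  X <- res$abundance
  R <- buildReactionMatrix(toy$bundle, SummarizedExperiment::rowData(X))
  W <- computeReactionScores(R, X)
  expect_equal(seAssay(W), naiveProduct(R, seAssay(X)), tolerance = 1e-12)

  # single taxon with abundance 1 reproduces the R column
  oneT <- matchTaxa(toy$bundle, "Escherichia coli")
  R1 <- buildReactionMatrix(toy$bundle, oneT)
  X1 <- matrix(1, 1, 1, dimnames = list("Escherichia coli", "s"))
  expect_equal(unname(seAssay(computeReactionScores(R1, X1))[, 1]),
               unname(R1[, 1]))

  # zero abundance -> zero scores
  X0 <- X1 * 0
  expect_true(all(seAssay(computeReactionScores(R1, X0)) == 0))

  # taxon order mismatch is an error
  Xs <- seAssay(X)[c(2, 1, 3), ]
  expect_error(computeReactionScores(R, Xs), "mismatch")
})

test_that("global S rows are 1/members and the worked 1/10 vs 1/6 contrast holds", {
  # subsystem with 10 member reactions
  strains <- data.frame(strain_id = c("sA", "sB"), domain = "Bacteria",
                        phylum = "P", class = "C", order = "O", family = "F",
                        genus = c("Ga", "Gb"), species = c("one", "two"))
  rxn <- sprintf("r%02d", 1:10)
  reactions <- data.frame(reaction_id = rxn, subsystem = "BigSub")
  # strain sA carries 6 of the 10 reactions, sB the other 4
  presence <- matrix(0, 2, 10, dimnames = list(strains$strain_id, rxn))
  presence["sA", 1:6] <- 1
  presence["sB", 7:10] <- 1
  b <- newReconstructionBundle(strains, reactions, presence)

  Sg <- buildSubsystemMatrix(b, mode = "global")
  expect_equal(unname(Sg@global["BigSub", ]), rep(1 / 10, 10))
  expect_equal(sum(Sg@global["BigSub", ]), 1)

  # a sample containing only taxon Ga has 6 of 10 reactions present:
  # contextualized weights become 1/6
  m <- matchTaxa(b, "Ga one")
  R <- buildReactionMatrix(b, m)
  X <- matrix(1, 1, 1, dimnames = list("Ga one", "samp"))
  W <- computeReactionScores(R, X)
  Sc <- buildSubsystemMatrix(b, mode = "contextualized", W = W)
  wv <- Sc@perSample[["samp"]]["BigSub", ]
  expect_equal(unname(wv[1:6]), rep(1 / 6, 6))
  expect_equal(unname(wv[7:10]), rep(0, 4))

  # global vs contextualized differ by the predicted 10/6 factor when the
  # present reactions share one activity value
  Yg <- seAssay(computeSubsystemScores(Sg, W))["BigSub", "samp"]
  Yc <- seAssay(computeSubsystemScores(Sc, W))["BigSub", "samp"]
  expect_equal(Yc / Yg, 10 / 6)
})

test_that("toy subsystem weights: p1 row is 1/3 on its three members", {
  toy <- makeToyExample()
  S <- buildSubsystemMatrix(toy$bundle, mode = "global")
  expect_equal(unname(S@global["p1", ]), c(1/3, 1/3, 1/3, 0, 0, 0))
})

test_that("Y = S W matches the loop oracle; contextualized zero rows stay zero", {
  syn <- makeSynthetic(nTaxa = 6, nReactions = 30, nSubsystems = 5, seed = 42)
  res <- generateFeatures(syn$featureTable, syn$taxonomy, syn$bundle)
  W <- res$reactionScores
  S <- buildSubsystemMatrix(syn$bundle, rownames(W), mode = "global")
  Y <- computeSubsystemScores(S, W)
  expect_equal(seAssay(Y), naiveProduct(S@global, seAssay(W)), tolerance = 1e-12)

  # constant-activity members: global-mode Y equals that constant (convexity)
  toy <- makeToyExample()
  rtoy <- generateFeatures(toy$featureTable, toy$taxonomy, toy$bundle)
  Wt <- seAssay(rtoy$reactionScores)
  # v5 and v6 always share a value and with v4 form p2; craft a W where all
  # of p2 shares one value
  Wc <- Wt
  Wc[c("v4", "v5", "v6"), ] <- 0.4
  St <- buildSubsystemMatrix(toy$bundle, rownames(Wc), mode = "global")
  Yc <- St@global %*% Wc
  expect_equal(unname(Yc["p2", ]), rep(0.4, 6))

  # a subsystem with no active member in a sample scores 0 there
  W0 <- Wt
  W0[c("v1", "v2", "v3"), "m1"] <- 0
  Sc <- buildSubsystemMatrix(toy$bundle, rownames(W0), mode = "contextualized",
                             W = W0)
  Y0 <- seAssay(computeSubsystemScores(Sc, W0))
  expect_equal(Y0["p1", "m1"], 0)
})

test_that("random fixtures: oracle equality, bounds, monotonicity, mode dominance", {
  for (seed in 1:6) {
    syn <- makeSynthetic(nTaxa = 5, strainsPerTaxon = 2, nReactions = 25,
                         nSubsystems = 4, nSamples = 6, seed = seed)
    res <- generateFeatures(syn$featureTable, syn$taxonomy, syn$bundle)
    X <- res$abundance
    Xm <- seAssay(X)
    R <- buildReactionMatrix(syn$bundle, SummarizedExperiment::rowData(X))
    W <- seAssay(res$reactionScores)
    Y <- seAssay(res$subsystemScores)

    expect_equal(W, naiveProduct(R, Xm), tolerance = 1e-12)
    expect_true(all(R >= 0 & R <= 1))
    expect_true(all(W >= -1e-15 & W <= 1 + 1e-15))
    expect_true(all(Y >= -1e-15 & Y <= 1 + 1e-15))

    # Y bounded by the max member activity
    S <- buildSubsystemMatrix(syn$bundle, rownames(W), mode = "global")
    for (z in S@subsystemNames) {
      mem <- S@members[[z]]
      expect_true(all(Y[z, ] <= apply(W[mem, , drop = FALSE], 2, max) + 1e-12))
    }

    # full-weight dominance
    Rf <- buildReactionMatrix(syn$bundle, SummarizedExperiment::rowData(X),
                              weightMode = "full")
    expect_true(all(Rf >= R))
    expect_true(all(Rf %*% Xm >= W - 1e-15))

    # monotonicity: raising one taxon's abundance never lowers scores of
    # reactions that taxon carries
    X2 <- Xm
    X2[1, ] <- pmin(1, X2[1, ] + 0.1)
    W2 <- R %*% X2
    carried <- R[, 1] > 0
    expect_true(all(W2[carried, ] >= W[carried, ] - 1e-15))
  }
})

test_that("generateFeatures orchestrates with the documented defaults", {
  toy <- makeToyExample()
  res <- generateFeatures(toy$featureTable, toy$taxonomy, toy$bundle)
  expect_equal(dim(seAssay(res$reactionScores)), c(6L, 6L))
  expect_equal(dim(seAssay(res$subsystemScores)), c(2L, 6L))
  expect_identical(res$params[c("level", "weight_mode", "subsystem_mode",
                                "renormalize_after_match")],
                   list(level = "species", weight_mode = "ratio",
                        subsystem_mode = "global",
                        renormalize_after_match = FALSE))
  expect_true(all(seAssay(res$reactionScores) >= 0 &
                  seAssay(res$reactionScores) <= 1))
  expect_true(all(seAssay(res$subsystemScores) >= 0 &
                  seAssay(res$subsystemScores) <= 1))
  # stage-tagged errors
  expect_error(generateFeatures(toy$featureTable, toy$taxonomy[0, ], toy$bundle),
               "stage")
})
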