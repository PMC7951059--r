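test_that("module regulator inference matches the hypergeometric tail", {
  universe <- paste0("g", 1:2000)
  asg <- setNames(rep(0L, 2000), universe)
  asg[1:50] <- 1L
  prior <- list(TFgood = c(universe[1:30], universe[100:109]),
                TFempty = c("zz1", "zz2"))
  res <- inferModuleRegulators(asg, prior)
  expect_false("TFempty" %in% res$tf)       # no targets in universe
  pHand <- phyper(29, 40, 1960, 50, lower.tail = FALSE)
  expect_equal(res$p[res$tf == "TFgood"], pHand)
  expect_lt(res$q[res$tf == "TFgood"], 1e-6)
  expect_true("TFgood" %in% attr(res, "selected"))
  expect_error(inferModuleRegulators(asg, list()), "empty")
})

test_that("decoy TFs with uniform targets are rejected", {
  labels <- setNames(c(rep(1L, 60), rep(2L, 50), rep(0L, 1890)),
                     paste0("g", 1:2000))
  hits <- vapply(1:40, function(i) {
    prior <- simulateRegulonPrior(labels, targetsPerTF = 40,
                                  purity = 0.9, nDecoys = 1, seed = i)
    res <- inferModuleRegulators(labels, prior)
    "decoyTF1" %in% attr(res, "selected")
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("regulon activity follows its z-score identities", {
  set.seed(5)
  expr <- matrix(rnorm(200), 10, 20,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
  # a regulon of copies of one gene has that gene's z-score profile
  expr[2, ] <- expr[1, ]; expr[3, ] <- expr[1, ]
  act <- regulonActivity(expr, list(tf = c("g1", "g2", "g3")))
  expect_equal(unname(act["tf", ]), as.numeric(scale(expr[1, ])),
               tolerance = 1e-12)
  expect_equal(unname(rowMeans(act)), 0, tolerance = 1e-12)
  expect_equal(unname(apply(act, 1, sd)), 1, tolerance = 1e-12)

  # invariant to adding a constant to one target gene
  shifted <- expr; shifted["g5", ] <- shifted["g5", ] + 100
  a1 <- regulonActivity(expr, list(tf = paste0("g", 4:8)))
  a2 <- regulonActivity(shifted, list(tf = paste0("g", 4:8)))
  expect_equal(a1, a2, tolerance = 1e-10)

  expect_message(
    regulonActivity(expr, list(ok = paste0("g", 1:5),
                               thin = c("g1", "nope"))),
    "dropped")
  expect_error(regulonActivity(expr, list(thin = "nope")), "no regulon")
})

test_that("planted module TFs have eigengene-like activity", {
  sim <- simulateCohort(cohortConfig(
    nSamples = 200, nGenes = 200,
    moduleSpec = data.frame(size = c(50, 40), loading = 0.8),
    noiseSd = 0.5, seed = 21))
  expr <- exprsMatrix(sim$cohort)
  lab <- sim$truth@moduleLabels
  prior <- simulateRegulonPrior(lab, targetsPerTF = 30, purity = 1,
                                nDecoys = 0, seed = 2)
  act <- regulonActivity(expr, prior)
  eig <- moduleEigengenes(expr, lab)
  expect_gte(abs(cor(act["TF1", ], eig["ME1", ])), 0.8)
  expect_gte(abs(cor(act["TF2", ], eig["ME2", ])), 0.8)
})

test_that("regulon clustering recovers activity archetypes", {
  skip_if_not_installed("mclust")
  set.seed(9)
  arch <- matrix(rnorm(3 * 60), 3, 60)
  act <- arch[rep(1:3, each = 6), ] + matrix(rnorm(18 * 60, sd = 0.3),
                                             18, 60)
  rownames(act) <- paste0("tf", 1:18)
  cl <- clusterRegulons(act, k = 3)
  expect_gte(mclust::adjustedRandIndex(cl, rep(1:3, each = 6)), 0.8)

  # duplicated rows land together; k = 1 collapses everything
  act2 <- rbind(act, tf19 = act[1, ])
  cl2 <- clusterRegulons(act2, k = 3)
  expect_equal(unname(cl2["tf19"]), unname(cl2["tf1"]))
  expect_equal(length(unique(clusterRegulons(act, k = 1))), 1L)
  expect_error(clusterRegulons(act[1:2, ], k = 3), "fewer regulons")
})

test_that("consensus regulons intersect cohort selections", {
  expect_length(consensusRegulons(c("A", "B"), c("C", "D")), 0)
  expect_setequal(consensusRegulons(c("A", "B"), c("B", "A")),
                  c("A", "B"))

  # two cohorts simulated from one truth recover the planted TFs
  hits <- vapply(1:10, function(i) {
    cfgArgs <- list(nSamples = 150, nGenes = 400,
                    moduleSpec = data.frame(size = c(50, 40),
                                            loading = 0.8),
                    noiseSd = 0.5)
    simA <- simulateCohort(do.call(cohortConfig, c(cfgArgs,
                                                   seed = 100 + i)))
    simB <- simulateCohort(do.call(cohortConfig, c(cfgArgs,
                                                   seed = 200 + i)))
    prior <- simulateRegulonPrior(simA$truth@moduleLabels,
                                  targetsPerTF = 30, purity = 0.9,
                                  nDecoys = 3, seed = i)
    asgA <- suppressWarnings(detectModules(topologicalOverlap(
      signedAdjacency(exprsMatrix(simA$cohort)))))
    asgB <- suppressWarnings(detectModules(topologicalOverlap(
      signedAdjacency(exprsMatrix(simB$cohort)))))
    common <- consensusRegulons(inferModuleRegulators(asgA, prior),
                                inferModuleRegulators(asgB, prior))
    all(c("TF1", "TF2") %in% common)
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("patient clustering is order-invariant and deterministic", {
  skip_if_not_installed("mclust")
  set.seed(12)
  a1 <- matrix(rnorm(5 * 30), 5, 30)
  a2 <- a1 + 3  # second archetype
  act <- cbind(a1, a2)
  colnames(act) <- paste0("s", 1:60)
  rownames(act) <- paste0("tf", 1:5)
  res <- clusterPatientsByRegulon(act, k = 2)
  truth <- rep(1:2, each = 30)
  expect_gte(mclust::adjustedRandIndex(res$labels, truth), 0.8)

  # same partition regardless of input column order
  perm <- sample(60)
  res2 <- clusterPatientsByRegulon(act[, perm], k = 2)
  agree <- table(res$labels[colnames(act)], res2$labels[colnames(act)])
  expect_equal(sum(apply(agree, 1, max)), 60)
  expect_identical(clusterPatientsByRegulon(act, k = 2)$labels,
                   res$labels)
})
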