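test_that("signed adjacency matches its closed forms", {
  s <- seq_len(6)
  e <- rbind(a = s, b = s, c = -s)                 # cor 1 and -1
  e <- e + 0                                        # numeric
  rownames(e) <- c("a", "b", "c"); colnames(e) <- paste0("s", 1:6)
  adj <- signedAdjacency(e, beta = 8)
  expect_equal(adj["a", "b"], 1)
  expect_equal(adj["a", "c"], 0)
  # orthogonal profiles: cor 0 -> 0.5^8
  e2 <- rbind(x = c(1, 1, -1, -1), y = c(1, -1, 1, -1))
  colnames(e2) <- paste0("s", 1:4)
  expect_equal(signedAdjacency(e2, 8)["x", "y"], 0.5^8)
  expect_equal(0.5^8, 0.00390625)
  bad <- rbind(e, flat = rep(1, 6))
  expect_error(signedAdjacency(bad), "flat")
})

test_that("topological overlap matches the formula on printed toys", {
  # two genes connected only to each other with a = 1
  a2 <- matrix(c(1, 1, 1, 1), 2, 2)
  d2 <- topologicalOverlap(a2)
  expect_equal(d2[1, 2], 0)
  # 4-node toy: recompute the formula by hand, entry by entry
  a <- matrix(c(1, .8, .2, .1,
                .8, 1, .3, .2,
                .2, .3, 1, .7,
                .1, .2, .7, 1), 4, 4)
  d <- topologicalOverlap(a)
  a0 <- a; diag(a0) <- 0
  k <- rowSums(a0)
  for (i in 1:3) for (j in (i + 1):4) {
    l <- sum(a0[i, -c(i, j)] * a0[-c(i, j), j])
    omega <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
    expect_equal(d[i, j], 1 - omega, tolerance = 1e-12)
  }
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("adjacency and TOM are equivariant under gene reordering", {
  set.seed(2)
  e <- matrix(rnorm(20 * 10), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  perm <- sample(20)
  a1 <- signedAdjacency(e)[perm, perm]
  a2 <- signedAdjacency(e[perm, ])
  expect_equal(a1, a2)
  expect_equal(topologicalOverlap(a1), topologicalOverlap(a2))
})

test_that("planted factor modules are recovered and noise left out", {
  skip_if_not_installed("mclust")
  sim <- simulateCohort(cohortConfig(
    nSamples = 300, nGenes = 280,
    moduleSpec = data.frame(size = c(60, 50, 40, 30), loading = 0.8),
    noiseSd = 0.5, seed = 13))
  expr <- exprsMatrix(sim$cohort)
  lab <- sim$truth@moduleLabels
  asg <- detectModules(topologicalOverlap(signedAdjacency(expr)))
  ok <- asg > 0
  ari <- mclust::adjustedRandIndex(asg[ok], lab[names(asg)[ok]])
  expect_gte(ari, 0.9)

  # eigengenes track the planted factors and beat single members
  eig <- moduleEigengenes(expr, asg)
  for (m in 1:4) {
    genes <- names(asg)[asg == m]
    trueMod <- unique(lab[genes])
    trueMod <- trueMod[trueMod > 0][1]
    factorProxy <- colMeans(expr[names(lab)[lab == trueMod], ])
    r <- abs(cor(eig[paste0("ME", m), ], factorProxy))
    expect_gte(r, 0.9)
    bestSingle <- max(abs(cor(t(expr[genes, ]), eig[paste0("ME", m), ])))
    varByEig <- mean(cor(t(expr[genes, ]), eig[paste0("ME", m), ])^2)
    varBySingle <- max(vapply(genes, function(g)
      mean(cor(t(expr[genes, ]), expr[g, ])^2), numeric(1)))
    expect_gte(varByEig + 1e-8, varBySingle * 0.95)
  }
})

test_that("noise-only input and sub-minimum clusters stay unassigned", {
  sim <- simulateCohort(cohortConfig(nSamples = 300, nGenes = 150,
                                     noiseSd = 0.5, seed = 14))
  d <- topologicalOverlap(signedAdjacency(exprsMatrix(sim$cohort)))
  asg <- suppressWarnings(detectModules(d))
  expect_gte(mean(asg == 0), 0.8)

  sim2 <- simulateCohort(cohortConfig(
    nSamples = 300, nGenes = 120,
    moduleSpec = data.frame(size = 10, loading = 0.9),
    noiseSd = 0.5, seed = 15))
  lab2 <- sim2$truth@moduleLabels
  asg2 <- suppressWarnings(detectModules(
    topologicalOverlap(signedAdjacency(exprsMatrix(sim2$cohort)))))
  expect_true(all(asg2[names(lab2)[lab2 == 1]] == 0))
})

test_that("eigengene conventions: unit variance, orientation, degenerate", {
  set.seed(4)
  f <- rnorm(50)
  expr <- rbind(t(replicate(5, f)),                  # perfect module
                matrix(rnorm(100), 2, 50))
  rownames(expr) <- paste0("g", 1:7)
  colnames(expr) <- paste0("s", 1:50)
  asg <- setNames(c(rep(1L, 5), 0L, 0L), rownames(expr))
  eig <- moduleEigengenes(expr, asg)
  expect_equal(sd(eig["ME1", ]), 1)
  expect_equal(abs(cor(eig["ME1", ], f)), 1, tolerance = 1e-10)
  z <- colMeans((expr[1:5, ] - rowMeans(expr[1:5, ])) /
                  apply(expr[1:5, ], 1, sd))
  expect_gte(cor(eig["ME1", ], z), 0)
  # single-gene module equals that gene's z-scores
  asg2 <- setNames(c(rep(1L, 5), 2L, 0L), rownames(expr))
  eig2 <- moduleEigengenes(expr, asg2)
  expect_equal(unname(eig2["ME2", ]),
               as.numeric(scale(expr[6, ])), tolerance = 1e-12)
})

test_that("module similarity and trait profiles follow their identities", {
  sim <- simulateCohort(cohortConfig(
    nSamples = 200, nGenes = 120, nPosGenes = 0,
    moduleSpec = data.frame(size = c(40, 30), loading = 0.8),
    noiseSd = 0.5, seed = 16))
  expr <- exprsMatrix(sim$cohort)
  lab <- sim$truth@moduleLabels
  eig <- moduleEigengenes(expr, lab)
  ms <- moduleSimilarity(eig)
  expect_equal(unname(diag(ms$correlation)), rep(1, 2))
  expect_equal(ms$correlation, t(ms$correlation))

  # a dominant shared latent factor couples the two module eigengenes
  # (loading 2.5 vs own-factor loading 0.8: expected |r| ~ 6.25/7.25)
  expr2 <- expr
  shared <- rnorm(200)
  expr2[names(lab)[lab > 0], ] <- expr2[names(lab)[lab > 0], ] +
    matrix(shared, sum(lab > 0), 200, byrow = TRUE) * 2.5
  eig2 <- moduleEigengenes(expr2, lab)
  expect_gte(abs(moduleSimilarity(eig2)$correlation[1, 2]), 0.8)

  # trait profile: two groups give +/- z pairs with zero row means
  groups <- clinicalData(sim$cohort)$mna_status
  tp <- moduleTraitProfile(eig, groups)
  expect_true(all(abs(rowMeans(tp)) < 1e-12))
  expect_equal(tp[, 1], -tp[, 2], ignore_attr = TRUE)

  # an MNA-driven module scores positive z in the MNA group
  expr3 <- expr
  expr3[names(lab)[lab == 1], groups == 1] <-
    expr3[names(lab)[lab == 1], groups == 1] + 2
  tp3 <- moduleTraitProfile(moduleEigengenes(expr3, lab), groups)
  expect_gt(tp3["ME1", "1"], 0)
})

test_that("population composition counts tally and degrade gracefully", {
  asg <- setNames(c(1L, 1L, 2L, 2L, 2L, 0L), paste0("g", 1:6))
  pops <- list(NK = c("g1", "g3", "g4"), B = c("g6"), empty = "gX")
  suppressWarnings(comp <- modulePopulationComposition(asg, pops))
  expect_equal(unname(comp$counts["NK", ]), c(1L, 2L))
  expect_equal(unname(comp$counts["B", ]), c(0L, 0L))
  expect_true(all(comp$z["empty", ] == 0))
  expect_true(all(colSums(comp$counts) <= c(2L, 3L) * length(pops)))
})

test_that("module enrichment equals the hypergeometric tail", {
  asg <- setNames(c(rep(1L, 5), rep(0L, 15)), paste0("g", 1:20))
  sets <- list(hit = c("g1", "g2", "g3", "g21"),
               none = c("gX", "gY"))
  res <- moduleEnrichment(asg, sets)
  # module 5 genes, set 3 present, overlap 3, background 20
  expect_equal(res$p[res$set == "hit"],
               phyper(2, 3, 17, 5, lower.tail = FALSE))
  expect_false("none" %in% res$set)  # zero-overlap set skipped

  # a module identical to a set attains the minimal p among all sets
  asg2 <- setNames(c(rep(1L, 6), rep(0L, 24)), paste0("g", 1:30))
  sets2 <- list(exact = paste0("g", 1:6),
                other = paste0("g", 10:20),
                rnd = paste0("g", c(2, 8, 14, 25)))
  res2 <- moduleEnrichment(asg2, sets2)
  expect_equal(res2$set[which.min(res2$p)], "exact")
})
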