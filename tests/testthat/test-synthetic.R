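test_that("zero-noise cohorts reproduce planted effects exactly", {
  sim <- simulateCohort(cohortConfig(nSamples = 20, nGenes = 50,
                                     nPosGenes = 5, posEffect = 1.5,
                                     nNegGenes = 3, negEffect = 0.7,
                                     noiseSd = 0, seed = 1))
  e <- exprsMatrix(sim$cohort)
  m <- clinicalData(sim$cohort)$mna_status
  for (g in sim$truth@posSignature$gene)
    expect_equal(mean(e[g, m == 1]) - mean(e[g, m == 0]), 1.5)
  for (g in sim$truth@negSignature$gene)
    expect_equal(mean(e[g, m == 1]) - mean(e[g, m == 0]), -0.7)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- cohortConfig(nSamples = 30, nGenes = 80, nPosGenes = 4,
                      moduleSpec = data.frame(size = 20, loading = 0.8),
                      hazardBetas = list(pos = 0.5), seed = 42)
  a <- simulateCohort(cfg); b <- simulateCohort(cfg)
  expect_identical(exprsMatrix(a$cohort), exprsMatrix(b$cohort))
  expect_identical(clinicalData(a$cohort), clinicalData(b$cohort))
  p1 <- simulateRegulonPrior(a$truth@moduleLabels, seed = 7)
  p2 <- simulateRegulonPrior(a$truth@moduleLabels, seed = 7)
  expect_identical(p1, p2)
  m1 <- simulateReferenceMixtures(seed = 5)
  m2 <- simulateReferenceMixtures(seed = 5)
  expect_identical(m1$mixtures, m2$mixtures)
})

test_that("noisy group-mean difference stays within the CLT bound", {
  sim <- simulateCohort(cohortConfig(nSamples = 600, mnaFraction = 0.5,
                                     nGenes = 20, nPosGenes = 5,
                                     posEffect = 1.5, noiseSd = 1,
                                     seed = 2))
  e <- exprsMatrix(sim$cohort)
  m <- clinicalData(sim$cohort)$mna_status
  bound <- 3 * (1 / sqrt(300) + 1 / sqrt(300))
  for (g in sim$truth@posSignature$gene) {
    d <- mean(e[g, m == 1]) - mean(e[g, m == 0])
    expect_lt(abs(d - 1.5), bound)
  }
})

test_that("contradictory cohort configs are rejected with a message", {
  expect_error(cohortConfig(nGenes = 10, nPosGenes = 20),
               "exceed nGenes")
  expect_error(cohortConfig(mnaFraction = 1.2), "mnaFraction")
  expect_error(cohortConfig(noiseSd = -1), "noiseSd")
})

test_that("null survival generator is log-rank calibrated across groups", {
  ps <- vapply(1:200, function(i) {
    sim <- simulateCohort(cohortConfig(nSamples = 80, mnaFraction = 0.5,
                                       nGenes = 5, censorRate = 0.03,
                                       noiseSd = 1, seed = 1000 + i))
    cl <- clinicalData(sim$cohort)
    kaplanMeierLogrank(cl$mna_status, cl$surv_time, cl$surv_event)$p
  }, numeric(1))
  phat <- mean(ps < 0.05)
  expect_lt(abs(phat - 0.05), 1.96 * sqrt(0.05 * 0.95 / 200) + 1e-9)
})

test_that("reference mixtures respect the linear mixing model", {
  # pure one-hot sample at zero noise equals the mean reference profile
  mx <- simulateReferenceMixtures(nTypes = 3, markersPerType = 5,
                                  nOtherGenes = 0, nSamples = 1,
                                  noiseSd = 0, seed = 3)
  expect_true(all(abs(rowSums(mx$trueFractions) - 1) < 1e-12))
  f <- mx$trueFractions[1, ]
  expect_equal(unname(mx$mixtures[, 1]),
               unname(as.numeric(mx$meanProfile %*% f)))
  # simplex invariant at many samples
  mx2 <- simulateReferenceMixtures(nSamples = 100, seed = 4)
  expect_true(all(abs(rowSums(mx2$trueFractions) - 1) < 1e-12))
  expect_true(all(mx2$trueFractions >= 0))
  # marker value within 3x the relative noise of the noiseless mix
  mx3 <- simulateReferenceMixtures(nTypes = 5, markersPerType = 40,
                                   nSamples = 10, noiseSd = 0.05,
                                   seed = 5)
  clean <- mx3$meanProfile %*% t(mx3$trueFractions)
  dev <- abs(mx3$mixtures - clean) / (0.05 * pmax(abs(clean), 1e-9))
  expect_gt(mean(dev <= 3), 0.99)
  expect_error(simulateReferenceMixtures(nTypes = 1), "2 cell types")
})

test_that("interactome fixture straddles its thresholds and plants decoys", {
  fx <- simulateInteractome(seed = 6)
  expect_true(any(fx$annotation$score == 1.5))
  expect_true(any(fx$edges$combined_score == 400L))
  expect_true(any(fx$edges$protein1 == fx$edges$protein2))
  # a protein annotated only intracellularly never enters the expected net
  surfaceless <- fx$annotation$protein[
    !grepl("plasma membrane|cell junctions|focal adhesion",
           fx$annotation$locations)]
  ed <- networkEdges(fx$expected)
  expect_false(any(surfaceless %in% c(ed$tumorGene, ed$immuneProtein)))
  # a score-400 edge never survives (strict inequality)
  expect_true(all(ed$score > 400))
})

test_that("regulon prior honors purity and rejects module-free input", {
  labels <- setNames(c(rep(1L, 50), rep(2L, 40), rep(0L, 110)),
                     paste0("g", 1:200))
  pure <- simulateRegulonPrior(labels, targetsPerTF = 30, purity = 1,
                               nDecoys = 0, seed = 1)
  expect_true(all(pure$TF1 %in% names(labels)[labels == 1L]))
  expect_error(simulateRegulonPrior(setNames(rep(0L, 10),
                                             paste0("g", 1:10))),
               "no modules")
  # decoy targets are uniform across the universe (chi-square over the
  # three strata at large n)
  many <- simulateRegulonPrior(labels, targetsPerTF = 150, purity = 0.8,
                               nDecoys = 30, seed = 2)
  decoys <- many[grep("^decoy", names(many))]
  counts <- table(factor(labels[unlist(decoys)], levels = c(0, 1, 2)))
  expected <- length(unlist(decoys)) * c(110, 50, 40) / 200
  chi <- sum((as.numeric(counts) - expected)^2 / expected)
  expect_lt(chi, qchisq(0.999, df = 2))
})
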