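test_that("min-max normalization maps printed toys exactly", {
  expect_equal(minmaxNormalize(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(minmaxNormalize(c(-3, -1)), c(0, 1))
  w <- rnorm(10)
  nw <- minmaxNormalize(w)
  expect_equal(nw[which.min(w)], 0)
  expect_equal(nw[which.max(w)], 1)
  expect_true(all(nw >= 0 & nw <= 1))
  expect_error(minmaxNormalize(c(2, 2, 2)), "zero range")
})

test_that("weight fusion keeps only common genes and sums weights", {
  wl <- c(a = 0.4, b = 1, c = 0)
  wc <- c(a = 0.3, d = 0.8)
  comb <- combineWeights(wl, wc)
  expect_equal(unname(comb["a"]), 0.7)
  expect_false("b" %in% names(comb))   # only in the logistic vector
  expect_false("d" %in% names(comb))
  expect_true(all(comb >= 0 & comb <= 2))
  expect_error(combineWeights(c(x = 1), c(y = 1)), "in common")
})

test_that("score formula matches hand arithmetic on the 2-gene toy", {
  expr <- toyMatrix(c(2, 2, 4, 4, 3, 3, 5, 5), c("g1", "g2", "h1", "h2"),
                    c("p1", "p2"))
  model <- new("ImmuneScoreModel",
               weights = data.frame(),
               positiveSignature = c(g1 = 1.0, g2 = 0.5),
               negativeSignature = c(h1 = 1.0, h2 = 0.5),
               metadata = list())
  sc <- computeScores(expr, model)
  # immP = (1/2)(2*1.0 + 4*0.5) = 2.0 for both patients
  expect_equal(sc$immP, c(2, 2))
  expect_equal(sc$immN, c(2.75, 2.75))
  expect_equal(sc$score, c(2 / 2.75, 2 / 2.75))

  # identical signatures on both sides give score 1 for every patient
  model1 <- new("ImmuneScoreModel", weights = data.frame(),
                positiveSignature = c(g1 = 1.0, g2 = 0.5),
                negativeSignature = c(g1 = 1.0, g2 = 0.5),
                metadata = list())
  expect_true(all(computeScores(expr, model1)$score == 1))

  # doubling log2 values doubles immP/immN but not the ratio
  sc2 <- computeScores(expr * 2, model)
  expect_equal(sc2$immP, 2 * sc$immP)
  expect_equal(sc2$score, sc$score)
})

test_that("stratification boundaries follow the z cutoffs", {
  z <- c(-0.6, -0.5, 0, 1, 1.2)
  s <- stratifyScores(z)
  expect_equal(as.character(s),
               c("low", "medium", "medium", "medium", "high"))
  expect_equal(sum(table(s)), length(z))
})

test_that("Bonferroni screen arithmetic and selection behave", {
  sim <- simulateCohort(cohortConfig(
    nSamples = 500, mnaFraction = 0.5, nGenes = 100, nPosGenes = 1,
    posEffect = 0, hazardBetas = c(g1 = 0.8), baselineHazard = 0.1,
    censorRate = 0.04, noiseSd = 1, seed = 30))
  cl <- clinicalData(sim$cohort)
  xz <- t(scale(t(exprsMatrix(sim$cohort))))
  scr <- univariateCoxScreen(xz, cl$surv_time, cl$surv_event)
  expect_equal(attr(scr, "threshold"), 0.05 / 100)  # m = 100
  expect_true("g1" %in% attr(scr, "selected"))
  expect_gt(scr$beta[scr$gene == "g1"], 0)
  expect_error(univariateCoxScreen(xz, -cl$surv_time, cl$surv_event),
               "> 0")
})

test_that("L1 logistic selects planted genes and is seed-deterministic", {
  sim <- simulateCohort(cohortConfig(
    nSamples = 400, mnaFraction = 0.4, nGenes = 300, nPosGenes = 20,
    posEffect = 1.5, noiseSd = 1, seed = 31))
  cl <- clinicalData(sim$cohort)
  xz <- t(scale(t(exprsMatrix(sim$cohort))))
  fit <- fitMNALogistic(xz, cl$mna_status, nRounds = 20, seed = 5)
  planted <- sim$truth@posSignature$gene
  expect_gte(mean(planted %in% names(fit$WPM)), 0.8)
  noise <- setdiff(rownames(xz), planted)
  expect_gte(mean(fit$meanWeights[noise] == 0), 0.9)
  expect_gt(mean(fit$auc), 0.9)

  fit2 <- fitMNALogistic(xz, cl$mna_status, nRounds = 20, seed = 5)
  expect_identical(fit$meanWeights, fit2$meanWeights)
  expect_error(fitMNALogistic(xz, rep(1, ncol(xz))), "both MNA classes")
  expect_error(fitMNALogistic(xz, cl$mna_status, nRounds = 1), ">= 2")
})

test_that("penalized Cox matches the unpenalized fit in the zero limit", {
  sim <- simulateCohort(cohortConfig(
    nSamples = 250, nGenes = 3, hazardBetas = c(g1 = 0.7, g2 = -0.5),
    baselineHazard = 0.1, censorRate = 0.03, noiseSd = 1, seed = 32))
  cl <- clinicalData(sim$cohort)
  xz <- t(scale(t(exprsMatrix(sim$cohort))))
  pc <- penalizedCox(xz, cl$surv_time, cl$surv_event, lambda1 = 0)
  ref <- survival::coxph(
    survival::Surv(cl$surv_time, cl$surv_event) ~ t(xz))
  expect_equal(unname(pc$coefficients), unname(coef(ref)),
               tolerance = 1e-4)
  # sign recovery at the working penalty
  pc2 <- penalizedCox(xz, cl$surv_time, cl$surv_event, lambda1 = 0.25)
  expect_true("g1" %in% names(pc2$WPC))
  expect_true("g2" %in% names(pc2$WNC))
  # an overwhelming penalty empties the model
  expect_error(penalizedCox(xz, cl$surv_time, cl$surv_event,
                            lambda1 = 1e6), "smaller lambda1")
})

test_that("signature coverage below 80% is refused when scoring", {
  expr <- toyMatrix(c(2, 2, 3, 3), c("g1", "h1"), c("p1", "p2"))
  model <- new("ImmuneScoreModel", weights = data.frame(),
               positiveSignature = c(g1 = 1, gMissing1 = 1,
                                     gMissing2 = 1),
               negativeSignature = c(h1 = 1),
               metadata = list())
  expect_error(computeScores(expr, model), "coverage")
})
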