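#' L1-penalized logistic MNA classification with Monte-Carlo resampling
#'
#' Fits, over \code{nRounds} random 80/20 splits, an L1-penalized logistic
#' regression of MNA status on the immune-gene expression (inverse
#' regularization strength \code{C}; the penalty is applied as
#' \code{lambda = 1/(C * nTrain)}). Per-gene weights are averaged over the
#' rounds and genes with zero average are dropped; positive averages form
#' the MNA-associated vector \code{WPM}, negative averages the
#' non-MNA-associated vector \code{WNM}. The held-out AUC of each round is
#' reported.
#'
#' @param exprImmune numeric matrix (immune genes x samples), gene-scaled.
#' @param mnaLabels binary vector over samples (1 = MNA).
#' @param C inverse regularization strength (default 0.1).
#' @param nRounds resampling rounds (default 50, >= 2).
#' @param trainFrac training fraction per round (default 0.8).
#' @param seed integer seed.
#' @return list with \code{WPM}, \code{WNM} (named numeric), \code{auc}
#'   (per-round held-out AUC), \code{meanWeights}.
#' @export
fitMNALogistic <- function(exprImmune, mnaLabels, C = 0.1, nRounds = 50L,
                           trainFrac = 0.8, seed = 1L) {
  y <- as.integer(mnaLabels)
  if (length(unique(y)) != 2L) stop("both MNA classes must be present")
  if (nRounds < 2L) stop("nRounds must be >= 2")
  X <- t(exprImmune)
  n <- nrow(X)
  nTrain <- floor(trainFrac * n)
  W <- matrix(0, ncol(X), nRounds, dimnames = list(colnames(X), NULL))
  auc <- numeric(nRounds)
  withSeed(deriveSeed(seed, "logistic"), {
    for (r in seq_len(nRounds)) {
      repeat {
        tr <- sample.int(n, nTrain)
        if (length(unique(y[tr])) == 2L && length(unique(y[-tr])) == 2L)
          break
      }
      lam <- 1 / (C * length(tr))
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], factor(y[tr]),
                            family = "binomial", alpha = 1,
                            lambda = lam * c(16, 8, 4, 2, 1),
                            standardize = FALSE)
      W[, r] <- as.numeric(stats::coef(fit, s = lam))[-1]
      pred <- as.numeric(stats::predict(fit, X[-tr, , drop = FALSE],
                                        s = lam))
      auc[r] <- rankAUC(pred, y[-tr])
    }
  })
  w <- rowMeans(W)
  list(WPM = w[w > 0], WNM = w[w < 0], auc = auc, meanWeights = w)
}

#' Univariate Cox screen with Bonferroni correction
#'
#' Per gene, a single-covariate Cox proportional-hazards fit; genes whose
#' Wald p is at most \code{alpha / m} (m = genes tested) are kept.
#'
#' @param exprImmune numeric matrix, genes x samples.
#' @param survTime,survEvent survival time (> 0) and event indicator.
#' @param alpha family-wise error target (default 0.05).
#' @return data.frame (gene, beta, p, selected); attribute
#'   \code{selected} carries the selected gene labels, attribute
#'   \code{threshold} the effective per-test threshold.
#' @export
univariateCoxScreen <- function(exprImmune, survTime, survEvent,
                                alpha = 0.05) {
  if (any(survTime <= 0)) stop("survival times must be > 0")
  if (sum(survEvent) < 20L) stop("need >= 20 events for the Cox screen")
  s <- apply(exprImmune, 1L, sd)
  if (any(s == 0))
    message(sum(s == 0), " zero-variance gene(s) skipped")
  genes <- rownames(exprImmune)[s > 0]
  y <- survival::Surv(survTime, survEvent)
  ctrl <- survival::coxph.control()
  res <- vapply(genes, function(g) {
    x <- matrix(exprImmune[g, ], ncol = 1)
    fit <- survival::coxph.fit(x, y, strata = NULL, offset = NULL,
                               init = 0, control = ctrl, weights = NULL,
                               method = "efron", rownames = NULL)
    beta <- fit$coefficients[1]
    z <- beta / sqrt(fit$var[1, 1])
    c(beta = unname(beta), p = 2 * stats::pnorm(-abs(z)))
  }, numeric(2))
  m <- length(genes)
  thr <- alpha / m
  out <- data.frame(gene = genes, beta = res["beta", ], p = res["p", ],
                    selected = res["p", ] <= thr,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p), ]
  attr(out, "selected") <- out$gene[out$selected]
  attr(out, "threshold") <- thr
  out
}

#' Lasso-penalized multivariate Cox regression at a fixed penalty
#'
#' Multivariate Cox with L1 penalty \code{lambda1} on the sum of absolute
#' coefficients (no internal tuning; internally mapped to the per-sample
#' scale of the solver as \code{lambda1 / n}). Nonzero positive
#' coefficients form the hazard-associated vector \code{WPC}, negative
#' the protective vector \code{WNC}.
#'
#' @param exprScreened numeric matrix (screened genes x samples).
#' @param survTime,survEvent survival time and event indicator.
#' @param lambda1 L1 penalty on the unnormalized partial likelihood scale
#'   (default 0.25).
#' @return list with \code{WPC}, \code{WNC} (named numeric) and
#'   \code{coefficients}.
#' @export
penalizedCox <- function(exprScreened, survTime, survEvent,
                         lambda1 = 0.25) {
  if (!nrow(exprScreened)) stop("no screened genes")
  if (sum(survEvent) < 20L) stop("need >= 20 events")
  X <- t(exprScreened)
  n <- nrow(X)
  y <- survival::Surv(survTime, survEvent)
  lam <- lambda1 / n
  path <- if (lam > 0) lam * c(16, 8, 4, 2, 1) else {
    l0 <- 0.5 / n
    c(l0 * c(64, 16, 4, 1), 0)
  }
  fit <- glmnet::glmnet(X, y, family = "cox", alpha = 1, lambda = path,
                        standardize = FALSE,
                        thresh = if (lam > 0) 1e-9 else 1e-12,
                        maxit = 3e5)
  b <- as.numeric(stats::coef(fit, s = lam))
  names(b) <- colnames(X)
  if (all(b == 0))
    stop("no nonzero coefficient at this penalty; try a smaller lambda1")
  list(WPC = b[b > 0], WNC = b[b < 0], coefficients = b)
}

#' Min-max normalize a weight vector to [0, 1]
#'
#' \eqn{\hat W_i = (W_i - \min W) / (\max W - \min W)}.
#'
#' @param w numeric vector with at least 2 distinct values.
#' @return normalized vector (min maps to 0, max to 1).
#' @examples minmaxNormalize(c(2, 4, 6))
#' @export
minmaxNormalize <- function(w) {
  rng <- range(w)
  if (diff(rng) == 0) stop("constant weight vector (zero range)")
  (w - rng[1]) / diff(rng)
}

#' Fuse normalized logistic and Cox weights into one signature
#'
#' Keeps the genes shared by the two normalized vectors of one side and
#' sums their weights (positive side: MNA-logistic + hazard-Cox; negative
#' side: non-MNA-logistic + protective-Cox).
#'
#' @param wLogistic,wCox normalized (in [0, 1]) named weight vectors of
#'   the same side.
#' @return named numeric vector of combined weights in [0, 2] over the
#'   common genes; an empty intersection is an error.
#' @export
combineWeights <- function(wLogistic, wCox) {
  common <- intersect(names(wLogistic), names(wCox))
  if (!length(common))
    stop("no genes in common between the logistic and Cox vectors")
  sort(wLogistic[common] + wCox[common], decreasing = TRUE)
}

#' Derive the full MYCN immune signature from a cohort
#'
#' End-to-end weight derivation: L1 logistic MNA model over the immune
#' gene universe (\code{\link{fitMNALogistic}}), Bonferroni-corrected
#' univariate Cox screen on the same genes, lasso Cox on the screened
#' genes (\code{\link{penalizedCox}}), min-max normalization of the four
#' weight vectors, and weight fusion over the common genes
#' (\code{\link{combineWeights}}). The two negative-side vectors are
#' magnitude-oriented (negated) before normalization so that the
#' strongest non-MNA / protective gene maps to 1; set
#' \code{negateNegative = FALSE} for the literal alternative.
#'
#' @param cohort an \linkS4class{ExpressionCohort} with
#'   \code{mna_status}, \code{surv_time}, \code{surv_event} in its
#'   clinical table.
#' @param immuneGenes character vector, the immune gene universe.
#' @param C,nRounds,seed passed to \code{\link{fitMNALogistic}}.
#' @param coxAlpha screen level (default 0.05, Bonferroni-corrected).
#' @param lambda1 lasso Cox penalty (default 0.25).
#' @param negateNegative magnitude-orient negative vectors before
#'   normalization (default TRUE).
#' @return an \linkS4class{ImmuneScoreModel}.
#' @export
deriveImmuneSignature <- function(cohort, immuneGenes, C = 0.1,
                                  nRounds = 50L, seed = 1L,
                                  coxAlpha = 0.05, lambda1 = 0.25,
                                  negateNegative = TRUE) {
  cl <- clinicalData(cohort)
  need <- c("mna_status", "surv_time", "surv_event")
  if (!all(need %in% colnames(cl)))
    stop("cohort clinical table needs: ", paste(need, collapse = ", "))
  genes <- intersect(immuneGenes, rownames(exprsMatrix(cohort)))
  if (length(genes) < 2L) stop("immune gene universe not in cohort")
  xz <- zscoreRows(exprsMatrix(cohort)[genes, , drop = FALSE],
                   warnConstant = FALSE)

  logit <- fitMNALogistic(xz, cl$mna_status, C = C, nRounds = nRounds,
                          seed = seed)
  screen <- univariateCoxScreen(xz, cl$surv_time, cl$surv_event,
                                alpha = coxAlpha)
  screened <- attr(screen, "selected")
  if (!length(screened))
    stop("Cox screen selected no gene; relax coxAlpha")
  cox <- penalizedCox(xz[screened, , drop = FALSE], cl$surv_time,
                      cl$surv_event, lambda1 = lambda1)

  orient <- function(w) if (negateNegative) -w else w
  normPM <- minmaxNormalize(logit$WPM)
  normNM <- minmaxNormalize(orient(logit$WNM))
  normPC <- minmaxNormalize(cox$WPC)
  normNC <- minmaxNormalize(orient(cox$WNC))

  pos <- combineWeights(normPM, normPC)
  neg <- combineWeights(normNM, normNC)

  wtab <- rbind(
    data.frame(gene = names(logit$WPM), vector = "PM",
               raw = unname(logit$WPM), normalized = unname(normPM)),
    data.frame(gene = names(logit$WNM), vector = "NM",
               raw = unname(logit$WNM), normalized = unname(normNM)),
    data.frame(gene = names(cox$WPC), vector = "PC",
               raw = unname(cox$WPC), normalized = unname(normPC)),
    data.frame(gene = names(cox$WNC), vector = "NC",
               raw = unname(cox$WNC), normalized = unname(normNC)))
  new("ImmuneScoreModel", weights = wtab, positiveSignature = pos,
      negativeSignature = neg,
      metadata = list(C = C, nRounds = nRounds, lambda1 = lambda1,
                      coxAlpha = coxAlpha, seed = seed, auc = logit$auc,
                      nScreened = length(screened),
                      negateNegative = negateNegative))
}

#' Compute per-patient MYCN immune scores
#'
#' \eqn{immP = (1/n_P) \sum_i x_i \hat W_i} over the positive signature
#' genes and likewise \eqn{immN} over the negative signature, with
#' \eqn{x_i} the log2 expression (non-negative scale); the MYCN immune
#' score is the ratio \eqn{immP / immN}, z-scored within the cohort and
#' stratified at the z cutoffs -0.5 and 1. Signature genes missing from
#' the cohort reduce n, with the coverage fraction reported; coverage
#' below \code{minCoverage} on either side is an error.
#'
#' @param expr log2 expression matrix (genes x samples, values >= 0) or
#'   an \linkS4class{ExpressionCohort}.
#' @param model an \linkS4class{ImmuneScoreModel}.
#' @param minCoverage minimum fraction of signature genes that must be
#'   present (default 0.8).
#' @return data.frame (sample, immP, immN, score, z, stratum) with
#'   attribute \code{coverage}.
#' @export
computeScores <- function(expr, model, minCoverage = 0.8) {
  if (is(expr, "ExpressionCohort")) expr <- exprsMatrix(expr)
  useSide <- function(w) {
    present <- intersect(names(w), rownames(expr))
    cov <- length(present) / length(w)
    if (cov < minCoverage)
      stop("signature coverage ", round(cov, 2), " below ", minCoverage)
    list(w = w[present], coverage = cov)
  }
  pos <- useSide(model@positiveSignature)
  neg <- useSide(model@negativeSignature)
  immP <- as.numeric(crossprod(expr[names(pos$w), , drop = FALSE],
                               pos$w)) / length(pos$w)
  immN <- as.numeric(crossprod(expr[names(neg$w), , drop = FALSE],
                               neg$w)) / length(neg$w)
  if (any(immN <= 0))
    stop("immN <= 0 for some patient; expression must be non-negative ",
         "log2 scale")
  score <- immP / immN
  z <- as.numeric(scale(score))
  out <- data.frame(sample = colnames(expr), immP = immP, immN = immN,
                    score = score, z = z, stratum = stratifyScores(z),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "coverage") <- c(positive = pos$coverage,
                             negative = neg$coverage)
  out
}

#' Stratify cohort z-scores into low / medium / high
#'
#' Low: z < -0.5; medium: -0.5 <= z <= 1; high: z > 1 (both boundaries
#' belong to medium).
#'
#' @param z numeric vector of cohort-normalized scores.
#' @return factor with levels low, medium, high.
#' @export
stratifyScores <- function(z) {
  factor(ifelse(z < -0.5, "low", ifelse(z > 1, "high", "medium")),
         levels = c("low", "medium", "high"))
}
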