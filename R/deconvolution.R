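#' Build a cell-type signature matrix from reference profiles
#'
#' For each cell type a one-vs-rest two-sample t-test is run over the
#' reference samples; genes passing \code{q < qThreshold} (BH within type)
#' are ranked by linear-scale fold change and the top \code{topG} kept. The
#' signature is the per-type mean reference expression over the union of
#' selected genes.
#'
#' @param refs list with \code{profiles} (genes x reference samples,
#'   linear scale, non-negative) and \code{typeMap} (named character,
#'   reference sample -> cell type).
#' @param topG genes kept per type (default 50).
#' @param qThreshold BH q cutoff for the one-vs-rest test (default 0.3).
#' @return a \linkS4class{SignatureMatrix}.
#' @export
buildSignatureMatrix <- function(refs, topG = 50L, qThreshold = 0.3) {
  profiles <- refs$profiles
  typeMap <- refs$typeMap[colnames(profiles)]
  types <- unique(typeMap)
  if (length(types) < 2L) stop("need >= 2 cell types")
  selected <- character(0)
  for (ty in types) {
    inTy <- typeMap == ty
    if (sum(inTy) < 2L || sum(!inTy) < 2L)
      stop("each type needs >= 2 reference samples for the one-vs-rest test")
    m1 <- rowMeans(profiles[, inTy, drop = FALSE])
    m0 <- rowMeans(profiles[, !inTy, drop = FALSE])
    v1 <- apply(profiles[, inTy, drop = FALSE], 1L, var)
    v0 <- apply(profiles[, !inTy, drop = FALSE], 1L, var)
    n1 <- sum(inTy); n0 <- sum(!inTy)
    sp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n0))
    tt <- ifelse(se > 0, (m1 - m0) / se, 0)
    p <- 2 * pt(-abs(tt), df = n1 + n0 - 2)
    q <- p.adjust(p, "BH")
    fc <- (m1 + 1e-9) / (m0 + 1e-9)
    cand <- which(q < qThreshold & fc > 1)
    if (!length(cand))
      stop("no discriminating genes for type '", ty,
           "'; increase topG or relax qThreshold")
    cand <- cand[order(-fc[cand])]
    selected <- union(selected,
                      rownames(profiles)[head(cand, topG)])
  }
  sig <- vapply(types, function(ty)
    rowMeans(profiles[selected, typeMap == ty, drop = FALSE]),
    numeric(length(selected)))
  rownames(sig) <- selected
  kap <- {
    d <- svd(sig, nu = 0, nv = 0)$d
    d[1] / d[length(d)]
  }
  new("SignatureMatrix", profiles = sig, conditionNumber = kap)
}

# z-score a vector and canonicalize to 8 significant digits, so inputs
# that differ only by floating-point noise (e.g. a rescaled mixture) reach
# the solver bitwise-identically and fractions are rescaling-invariant
zvec <- function(y) {
  s <- sd(y)
  if (s == 0) stop("constant (degenerate) mixture sample")
  signif((y - mean(y)) / s, 8)
}

# One-sample deconvolution: nu-SVR over a small nu grid, keeping the model
# whose fitted mixture best correlates with the observation; or NNLS.
solveSample <- function(Xz, yz, method, nuGrid) {
  if (method == "svr") {
    best <- NULL; bestCor <- -Inf
    for (nu in nuGrid) {
      fit <- e1071::svm(x = Xz, y = yz, type = "nu-regression",
                        kernel = "linear", nu = nu, scale = FALSE)
      w <- as.numeric(crossprod(fit$coefs, fit$SV))
      fc <- suppressWarnings(cor(as.numeric(Xz %*% w), yz))
      if (!is.na(fc) && fc > bestCor) {
        bestCor <- fc; best <- w
      }
    }
    w <- best
  } else {
    # signed intercept via a +/- 1 column pair, dropped afterwards
    Xi <- cbind(Xz, 1, -1)
    w <- pracma::lsqnonneg(Xi, yz)$x[seq_len(ncol(Xz))]
  }
  w[w < 0] <- 0
  fitCor <- if (sum(w) > 0)
    suppressWarnings(cor(as.numeric(Xz %*% w), yz)) else NA_real_
  frac <- if (sum(w) > 0) w / sum(w) else rep(1 / ncol(Xz), ncol(Xz))
  list(fractions = frac, fitCor = fitCor)
}

#' Estimate immune cell fractions by reference-based deconvolution
#'
#' Solves \code{mixture ~ signature \%*\% fractions} per sample with linear
#' nu-support-vector regression over a small nu grid (best-fit model kept;
#' negative coefficients clipped to zero, fractions renormalized to sum 1),
#' or non-negative least squares as fallback engine. Mixture samples and
#' the signature matrix are z-scored before regression, which makes the
#' estimated fractions invariant to positive rescaling of a sample.
#' Significance: a shared null of \code{nPerm} pseudo-samples (genes drawn
#' at random from the mixture matrix) gives, per sample, the fraction of
#' null fits whose goodness-of-fit correlation reaches the observed one.
#'
#' @param mixtures numeric matrix, genes x samples, linear (anti-logged)
#'   scale; or log2 values with \code{isLog2 = TRUE}.
#' @param sig a \linkS4class{SignatureMatrix}.
#' @param nPerm permutations for the null (>= 100).
#' @param seed integer seed.
#' @param method \code{"svr"} (default) or \code{"nnls"}.
#' @param nuGrid nu grid for the SVR engine.
#' @param isLog2 anti-log the mixtures with \code{2^x} first.
#' @return list with \code{fractions} (samples x cell types, rows sum to
#'   1), \code{pValue} and \code{fitCor} (named per sample).
#' @export
estimateFractions <- function(mixtures, sig, nPerm = 200L, seed = 1L,
                              method = c("svr", "nnls"),
                              nuGrid = c(0.25, 0.5, 0.75),
                              isLog2 = FALSE) {
  method <- match.arg(method)
  if (nPerm < 100L) stop("nPerm must be >= 100")
  if (is(sig, "SignatureMatrix")) sig <- signatureProfiles(sig)
  if (isLog2) mixtures <- 2^mixtures
  genes <- intersect(rownames(sig), rownames(mixtures))
  if (length(genes) < 0.3 * nrow(sig))
    stop("fewer than 30% of signature genes present in the mixtures")
  X <- sig[genes, , drop = FALSE]
  Xz <- (X - mean(X)) / sd(X)
  M <- mixtures[genes, , drop = FALSE]
  if (any(colSums(abs(M)) == 0)) stop("all-zero mixture sample")

  res <- lapply(seq_len(ncol(M)), function(j)
    solveSample(Xz, zvec(M[, j]), method, nuGrid))
  fractions <- t(vapply(res, `[[`, numeric(ncol(X)), "fractions"))
  dimnames(fractions) <- list(colnames(M), colnames(X))
  fitCor <- setNames(vapply(res, `[[`, numeric(1), "fitCor"),
                     colnames(M))

  nullCor <- withSeed(deriveSeed(seed, "deconv"), {
    pool <- as.numeric(mixtures)
    vapply(seq_len(nPerm), function(i) {
      y <- sample(pool, length(genes))
      if (sd(y) == 0) return(NA_real_)
      solveSample(Xz, zvec(y), method, nuGrid)$fitCor
    }, numeric(1))
  })
  nullCor <- nullCor[!is.na(nullCor)]
  # a sample with no usable fit (all coefficients clipped) cannot beat the
  # null, so its p is 1
  pValue <- vapply(fitCor, function(r)
    if (is.na(r)) 1 else mean(nullCor >= r), numeric(1))
  list(fractions = fractions, pValue = pValue, fitCor = fitCor)
}

#' Compare estimated cell fractions between two sample groups
#'
#' Per cell type: group means and medians, Wilcoxon rank-sum statistic and
#' p, and the direction of enrichment. (The groups are independent MNA /
#' non-MNA patient sets, so a rank-sum rather than a paired test is used.)
#'
#' @param fractions samples x cell types matrix (e.g. from
#'   \code{\link{estimateFractions}}).
#' @param groups binary vector over samples (1 = MNA).
#' @return data.frame, one row per cell type.
#' @export
compareFractions <- function(fractions, groups) {
  g <- as.integer(factor(groups)) - 1L
  if (length(unique(g)) != 2L || min(table(g)) < 3L)
    stop("two groups with >= 3 samples each required")
  rows <- lapply(colnames(fractions), function(ty) {
    x1 <- fractions[g == 1L, ty]
    x0 <- fractions[g == 0L, ty]
    if (sd(c(x1, x0)) == 0) {
      warning("constant fractions for ", ty, "; p set to 1")
      p <- 1; W <- NA_real_
    } else {
      wt <- suppressWarnings(wilcox.test(x1, x0))
      p <- wt$p.value; W <- unname(wt$statistic)
    }
    data.frame(cellType = ty, meanMNA = mean(x1), meanNonMNA = mean(x0),
               medianMNA = median(x1), medianNonMNA = median(x0),
               W = W, p = p,
               direction = if (mean(x1) > mean(x0)) "MNA" else "non-MNA",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  out
}
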