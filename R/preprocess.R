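#' Preprocess a raw expression matrix
#'
#' Quantile-normalizes columns, averages duplicate gene-label rows
#' (replicate probes), drops genes with any missing value (logged), and
#' optionally z-scales each gene across samples. Zero-variance genes scale
#' to 0 with a warning.
#'
#' @param x numeric matrix, genes x samples, possibly with duplicated row
#'   names and missing values.
#' @param scaleGenes z-scale rows after normalization (default TRUE).
#' @return numeric matrix with unique gene row names.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 2, 4, 6, 8), 4, 2,
#'             dimnames = list(c("a", "b", "b", "c"), c("s1", "s2")))
#' preprocessExpression(m, scaleGenes = FALSE)
#' @export
preprocessExpression <- function(x, scaleGenes = TRUE) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("gene row names required")
  nBad <- sum(!complete.cases(x))
  if (nBad > 0) {
    message("dropping ", nBad, " gene row(s) with missing values")
    x <- x[complete.cases(x), , drop = FALSE]
  }
  if (!nrow(x)) stop("no complete gene rows left")
  x <- limma::normalizeQuantiles(x)
  if (anyDuplicated(rownames(x))) {
    x <- rowsum(x, group = rownames(x), reorder = FALSE) /
      as.vector(table(rownames(x))[unique(rownames(x))])
    # rowsum reorders groups by first occurrence; fix the divisor alignment
  }
  if (scaleGenes) x <- zscoreRows(x)
  x
}

#' Rank genes by Pearson correlation with a driver gene
#'
#' @param expr numeric matrix, genes x samples (>= 3 samples).
#' @param driver driver gene label present in \code{expr} (e.g.
#'   \code{"MYCN"}).
#' @return named numeric vector of Pearson r for every other gene, sorted
#'   decreasingly; ties broken by gene label for determinism. Zero-variance
#'   genes are excluded with a warning.
#' @export
correlateWithGene <- function(expr, driver) {
  if (!driver %in% rownames(expr)) stop("driver gene '", driver,
                                        "' not found")
  if (ncol(expr) < 3L) stop("need >= 3 samples")
  d <- expr[driver, ]
  if (sd(d) == 0) stop("driver gene has zero variance")
  others <- setdiff(rownames(expr), driver)
  s <- apply(expr[others, , drop = FALSE], 1L, sd)
  if (any(s == 0)) {
    warning(sum(s == 0), " zero-variance gene(s) excluded from ranking")
    others <- others[s > 0]
  }
  r <- as.vector(cor(t(expr[others, , drop = FALSE]), d))
  names(r) <- others
  r[order(-r, names(r))]
}

#' Two-group differential expression with empirical-Bayes moderated t
#'
#' Fits a per-gene two-group comparison (logFC = group1 minus group0),
#' shrinks the per-gene variance toward a pooled prior via the standard
#' empirical-Bayes update
#' \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)}, and tests the
#' moderated t on \eqn{d + d_0} degrees of freedom. The prior
#' \eqn{(d_0, s_0^2)} is estimated by moment matching on the log variances.
#' P-values are Benjamini-Hochberg adjusted.
#'
#' @param expr numeric matrix, genes x samples.
#' @param groups binary vector (0/1 or two-level factor) over samples; the
#'   second level / 1 is the "MNA" group whose mean enters positively.
#' @param priorDf override for the prior degrees of freedom; \code{0}
#'   disables shrinkage (ordinary two-sample t with pooled variance),
#'   \code{NULL} (default) estimates it from the data.
#' @return data.frame (gene, logFC, t, df, p, q) sorted by p.
#' @export
moderatedDE <- function(expr, groups, priorDf = NULL) {
  g <- as.integer(factor(groups)) - 1L
  if (length(unique(g)) != 2L) stop("exactly two groups required")
  n1 <- sum(g == 1L); n0 <- sum(g == 0L)
  if (n1 < 2L || n0 < 2L) stop("each group needs >= 2 samples")
  m1 <- rowMeans(expr[, g == 1L, drop = FALSE])
  m0 <- rowMeans(expr[, g == 0L, drop = FALSE])
  logFC <- m1 - m0
  df <- n1 + n0 - 2L
  ss <- (rowSums((expr[, g == 1L, drop = FALSE] - m1)^2) +
           rowSums((expr[, g == 0L, drop = FALSE] - m0)^2)) / df

  if (is.null(priorDf)) {
    fit <- fitVarPrior(ss, df)
    d0 <- fit$df; s02 <- fit$s02
  } else if (priorDf == 0) {
    d0 <- 0; s02 <- 0
  } else {
    d0 <- priorDf; s02 <- mean(ss)
  }
  sTilde2 <- if (is.finite(d0)) (d0 * s02 + df * ss) / (d0 + df) else
    rep(s02, length(ss))
  se <- sqrt(sTilde2 * (1 / n1 + 1 / n0))
  tt <- ifelse(se > 0, logFC / se, 0)
  # total df capped at the pooled residual df across genes, so an
  # infinite prior yields a large-but-finite reference distribution
  dfTotal <- min(df + d0, df * length(ss))
  p <- 2 * pt(-abs(tt), df = dfTotal)
  out <- data.frame(gene = rownames(expr), logFC = logFC, t = tt,
                    df = dfTotal, p = p, q = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p, out$gene), ]
}

# Moment estimator of the scaled inverse-chi-square variance prior from
# log sample variances: matches mean/variance of log(s^2) against the
# log-F moments implied by s^2 ~ s0^2 * F(df, d0).
fitVarPrior <- function(s2, df) {
  ok <- s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0)        # no excess spread beyond sampling
    return(list(df = Inf, s02 = mean(s2[ok])))
  d0 <- 2 * trigammaInverse(evar)
  s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(df = d0, s02 = s02)
}

# Invert trigamma by Newton iteration (monotone decreasing on (0, Inf)).
trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Assign differential genes to the MNA / non-MNA sides
#'
#' Genes with logFC at or above \code{+lfcThreshold} go to the MNA set,
#' at or below \code{-lfcThreshold} to the non-MNA set; others are
#' unassigned. The permissive default of 0.5 log2 units is meant to also
#' capture weak surface interactions.
#'
#' @param de data.frame from \code{\link{moderatedDE}} (columns gene,
#'   logFC).
#' @param lfcThreshold absolute log2 fold-change threshold (default 0.5).
#' @return list with character vectors \code{mna} and \code{nonMna}.
#' @export
groupDEGenes <- function(de, lfcThreshold = 0.5) {
  list(mna = de$gene[de$logFC >= lfcThreshold],
       nonMna = de$gene[de$logFC <= -lfcThreshold])
}
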