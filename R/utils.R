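#' @importFrom stats cor sd var quantile rnorm rexp runif rbinom pt phyper
#'   p.adjust hclust cutree as.dist dist wilcox.test pchisq qnorm setNames
#'   complete.cases prcomp t.test aggregate median coef predict cor.test
#' @importFrom methods new validObject is slot
#' @importFrom utils head tail read.delim write.table
NULL

# Derive a reproducible sub-stream seed from one global integer seed, so each
# generator draws from its own stream without cross-stage coupling.
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(as.integer(seed)) * 1009L + h) %% 2147483647L)
}

# Evaluate expr under a local RNG state; the caller's .Random.seed is restored.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Rank-based AUC of scores for binary labels (1 = positive class).
rankAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Row-wise z-scoring; zero-variance rows become 0 with a warning.
zscoreRows <- function(x, warnConstant = TRUE) {
  m <- rowMeans(x)
  s <- apply(x, 1L, sd)
  bad <- !is.finite(s) | s == 0
  if (any(bad)) {
    if (warnConstant)
      warning(sum(bad), " zero-variance row(s) set to 0 after scaling")
    s[bad] <- 1
  }
  z <- (x - m) / s
  z[bad, ] <- 0
  z
}

`%||%` <- function(a, b) if (is.null(a)) b else a
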