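#' Kaplan-Meier curves with a k-sample log-rank test
#'
#' Product-limit estimate per stratum plus the log-rank chi-square test
#' across strata. Empty strata are dropped with a warning.
#'
#' @param strata stratum label per sample (factor or character).
#' @param survTime,survEvent survival time and event indicator.
#' @return list with \code{km} (data.frame: stratum, time, surv, nRisk,
#'   nEvent), \code{chisq}, \code{df} and \code{p} (NA when only one
#'   stratum remains).
#' @export
kaplanMeierLogrank <- function(strata, survTime, survEvent) {
  strata <- as.factor(strata)
  empty <- levels(strata)[table(strata) == 0L]
  if (length(empty)) {
    warning("dropping empty stratum(s): ", paste(empty, collapse = ", "))
    strata <- droplevels(strata)
  }
  y <- survival::Surv(survTime, survEvent)
  fit <- survival::survfit(y ~ strata)
  lab <- if (is.null(fit$strata)) rep(levels(strata), length(fit$time))
  else rep(sub("^strata=", "", names(fit$strata)), fit$strata)
  km <- data.frame(stratum = lab, time = fit$time, surv = fit$surv,
                   nRisk = fit$n.risk, nEvent = fit$n.event,
                   stringsAsFactors = FALSE)
  if (nlevels(strata) >= 2L) {
    lr <- survival::survdiff(y ~ strata)
    chisq <- lr$chisq
    df <- length(lr$n) - 1L
    p <- pchisq(chisq, df, lower.tail = FALSE)
  } else {
    chisq <- NA_real_; df <- NA_integer_; p <- NA_real_
  }
  list(km = km, chisq = chisq, df = df, p = p)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Fits all supplied covariates jointly (Efron tie handling) and reports
#' hazard ratios with 95\% confidence intervals and Wald p per covariate.
#'
#' @param covariates data.frame of covariates (e.g. score z plus clinical
#'   factors), one row per sample.
#' @param survTime,survEvent survival time and event indicator.
#' @return data.frame (term, hr, lo95, hi95, p).
#' @export
coxMultivariate <- function(covariates, survTime, survEvent) {
  if (sum(survEvent) < 20L) stop("need >= 20 events")
  dat <- cbind(covariates,
               .time = survTime, .event = as.integer(survEvent))
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(.time, .event) ~ .,
                    data = dat, ties = "efron"),
    warning = function(w) {
      # iteration-limit failures are fatal; monotone-likelihood warnings
      # (a coefficient running to infinity) are reported but tolerated
      if (grepl("Ran out of iterations", conditionMessage(w)))
        stop("Cox fit did not converge: ", conditionMessage(w))
      warning(w); invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  ci <- sm$conf.int
  data.frame(term = rownames(sm$coefficients),
             hr = sm$coefficients[, "exp(coef)"],
             lo95 = ci[, "lower .95"], hi95 = ci[, "upper .95"],
             p = sm$coefficients[, "Pr(>|z|)"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate the immune score with a gene panel
#'
#' Per panel gene present in the expression matrix: Pearson r against the
#' score, its p-value and BH-adjusted q, and the direction. Missing panel
#' genes are reported.
#'
#' @param scoreZ numeric vector of per-sample scores (e.g. cohort
#'   z-scores), aligned with the columns of \code{expr}.
#' @param expr numeric matrix, genes x samples.
#' @param genePanel character vector of panel genes (e.g. checkpoints,
#'   MHC, TLRs, cytokines).
#' @return data.frame (gene, r, p, q, direction), one row per present
#'   panel gene.
#' @export
panelCorrelation <- function(scoreZ, expr, genePanel) {
  present <- intersect(genePanel, rownames(expr))
  missing <- setdiff(genePanel, present)
  if (length(missing))
    message(length(missing), " panel gene(s) absent: ",
            paste(head(missing, 5), collapse = ", "))
  if (!length(present)) stop("no panel gene present in expr")
  res <- t(vapply(present, function(g) {
    ct <- suppressWarnings(stats::cor.test(expr[g, ], scoreZ))
    c(r = unname(ct$estimate), p = ct$p.value)
  }, numeric(2)))
  out <- data.frame(gene = present, r = res[, "r"], p = res[, "p"],
                    q = p.adjust(res[, "p"], "BH"),
                    direction = ifelse(res[, "r"] >= 0, "positive",
                                       "negative"),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p), ]
}
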