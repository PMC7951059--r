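#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' ExpressionCohort: a log2 expression cohort with clinical annotations
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding one assay
#' \code{"exprs"} (log2-scale expression, genes x samples) and per-sample
#' clinical covariates in \code{colData} (canonically \code{mna_status},
#' \code{surv_time}, \code{surv_event}, \code{stage}). It is the universal
#' input of the pipeline.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @export
setClass("ExpressionCohort", contains = "SummarizedExperiment")

setValidity("ExpressionCohort", function(object) {
  msg <- character()
  if (!"exprs" %in% names(assays(object)))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    e <- assay(object, "exprs")
    if (!is.numeric(e)) msg <- c(msg, "'exprs' must be numeric")
    if (anyNA(e) || any(!is.finite(e)))
      msg <- c(msg, "'exprs' must be finite (drop or impute missing values first)")
    if (anyDuplicated(rownames(e)))
      msg <- c(msg, "duplicate gene ids (average replicate probes first)")
    if (anyDuplicated(colnames(e)))
      msg <- c(msg, "duplicate sample ids")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionCohort
#'
#' @param exprs numeric matrix of log2 expression, genes x samples, with
#'   unique row (gene) and column (sample) names.
#' @param clinical data.frame of per-sample annotations, one row per column
#'   of \code{exprs} (matched by row name when present, else by order).
#' @return An \linkS4class{ExpressionCohort}.
#' @examples
#' m <- matrix(rnorm(6, 7), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionCohort(m, data.frame(mna_status = c(1, 0)))
#' @export
ExpressionCohort <- function(exprs, clinical = NULL) {
  exprs <- as.matrix(exprs)
  if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
    stop("exprs needs gene row names and sample column names")
  if (is.null(clinical))
    clinical <- data.frame(row.names = colnames(exprs))
  if (!is.null(rownames(clinical)) &&
      all(colnames(exprs) %in% rownames(clinical)))
    clinical <- clinical[colnames(exprs), , drop = FALSE]
  if (nrow(clinical) != ncol(exprs))
    stop("clinical rows must align 1:1 with samples")
  rownames(clinical) <- colnames(exprs)
  se <- SummarizedExperiment(assays = list(exprs = exprs),
                             colData = DataFrame(clinical))
  new("ExpressionCohort", se)
}

#' @describeIn ExpressionCohort expression matrix accessor.
#' @param object,x an ExpressionCohort.
#' @export
exprsMatrix <- function(x) assay(x, "exprs")

#' @describeIn ExpressionCohort clinical table accessor (base data.frame).
#' @export
clinicalData <- function(x) as.data.frame(colData(x))

#' GroundTruth: planted structure emitted by the cohort simulator
#'
#' Records every quantity the simulator planted so downstream stages can be
#' scored against a known answer: signature genes and their effects, per-gene
#' log-hazard coefficients, module labels, mixing fractions and regulons.
#'
#' @slot posSignature data.frame (gene, effect): genes upregulated in the
#'   MNA group, with the planted log2 effect.
#' @slot negSignature data.frame (gene, effect): genes upregulated in the
#'   non-MNA group.
#' @slot hazardCoefficients named numeric, per-gene log-hazard betas.
#' @slot moduleLabels named integer, gene -> planted module (0 = none).
#' @slot trueFractions samples x cell-types matrix, rows summing to 1
#'   (empty matrix when not applicable).
#' @slot trueRegulons named list, TF -> character vector of targets.
#' @export
setClass("GroundTruth",
         representation(posSignature = "data.frame",
                        negSignature = "data.frame",
                        hazardCoefficients = "numeric",
                        moduleLabels = "integer",
                        trueFractions = "matrix",
                        trueRegulons = "list"))

setValidity("GroundTruth", function(object) {
  tf <- object@trueFractions
  if (length(tf) && any(abs(rowSums(tf) - 1) > 1e-8))
    return("trueFractions rows must sum to 1")
  TRUE
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:",
      nrow(object@posSignature), "MNA-positive /",
      nrow(object@negSignature), "MNA-negative planted genes;",
      sum(object@hazardCoefficients != 0), "hazard genes;",
      length(unique(object@moduleLabels[object@moduleLabels > 0])),
      "planted modules;",
      length(object@trueRegulons), "regulons\n")
})

#' SignatureMatrix: cell-type signature profiles for deconvolution
#'
#' @slot profiles selected genes x cell types matrix of mean reference
#'   expression (linear scale).
#' @slot conditionNumber 2-norm condition number of the profile matrix, a
#'   collinearity diagnostic.
#' @export
setClass("SignatureMatrix",
         representation(profiles = "matrix", conditionNumber = "numeric"))

setValidity("SignatureMatrix", function(object) {
  p <- object@profiles
  if (ncol(p) < 2L) return("need >= 2 cell types")
  if (any(p < 0)) return("reference profiles must be non-negative")
  TRUE
})

setMethod("show", "SignatureMatrix", function(object) {
  cat("SignatureMatrix:", nrow(object@profiles), "genes x",
      ncol(object@profiles), "cell types; condition number",
      signif(object@conditionNumber, 4), "\n")
})

#' @describeIn SignatureMatrix profile matrix accessor.
#' @param object,x a SignatureMatrix.
#' @export
signatureProfiles <- function(x) x@profiles

#' ImmuneNetwork: bipartite tumor-gene / immune-population surface network
#'
#' Edges surviving the filter cascade (surface localization, per-population
#' expression score, interaction score), annotated with the immune
#' population and its activation status.
#'
#' @slot edges data.frame with columns tumorGene, immuneProtein, population,
#'   activationStatus, score.
#' @slot populationCounts named integer, edges per immune population.
#' @export
setClass("ImmuneNetwork",
         representation(edges = "data.frame", populationCounts = "integer"))

setValidity("ImmuneNetwork", function(object) {
  req <- c("tumorGene", "immuneProtein", "population", "activationStatus",
           "score")
  if (!all(req %in% colnames(object@edges)))
    return(paste("edges must have columns:", paste(req, collapse = ", ")))
  if (nrow(object@edges) &&
      any(object@edges$tumorGene == object@edges$immuneProtein))
    return("self-loops are not allowed")
  TRUE
})

setMethod("show", "ImmuneNetwork", function(object) {
  cat("ImmuneNetwork:", nrow(object@edges), "edges across",
      length(object@populationCounts), "immune populations\n")
})

#' @describeIn ImmuneNetwork edge table accessor.
#' @param object,x an ImmuneNetwork.
#' @export
networkEdges <- function(x) x@edges

#' ImmuneScoreModel: fused signature weights of the MYCN immune score
#'
#' Holds the four raw weight vectors (logistic MNA-positive/negative, Cox
#' hazard-positive/negative), their min-max normalized forms, and the fused
#' positive / negative signatures (sum of normalized logistic and Cox weight
#' over the genes the two models share).
#'
#' @slot weights data.frame (gene, vector, raw, normalized) for the four
#'   vectors PM, NM, PC, NC.
#' @slot positiveSignature named numeric, combined weight per positive
#'   signature gene (in [0, 2]).
#' @slot negativeSignature named numeric, combined weight per negative
#'   signature gene.
#' @slot metadata list of fitting metadata (penalties, rounds, seed, AUC per
#'   round, screened gene count).
#' @export
setClass("ImmuneScoreModel",
         representation(weights = "data.frame",
                        positiveSignature = "numeric",
                        negativeSignature = "numeric",
                        metadata = "list"))

setValidity("ImmuneScoreModel", function(object) {
  if (length(object@positiveSignature) == 0L ||
      length(object@negativeSignature) == 0L)
    return("both fused signatures must be non-empty")
  w <- c(object@positiveSignature, object@negativeSignature)
  if (any(w < 0 | w > 2)) return("combined weights must lie in [0, 2]")
  TRUE
})

setMethod("show", "ImmuneScoreModel", function(object) {
  auc <- object@metadata$auc
  cat("ImmuneScoreModel:", length(object@positiveSignature),
      "positive /", length(object@negativeSignature),
      "negative signature genes",
      if (!is.null(auc)) sprintf("; mean held-out AUC %.3f", mean(auc)),
      "\n", sep = "")
})

#' @describeIn ImmuneScoreModel fused signature accessor.
#' @param object,x an ImmuneScoreModel.
#' @param side \code{"positive"} or \code{"negative"}.
#' @export
signatureWeights <- function(x, side = c("positive", "negative")) {
  side <- match.arg(side)
  if (side == "positive") x@positiveSignature else x@negativeSignature
}
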