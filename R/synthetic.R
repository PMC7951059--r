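#' Configure a synthetic two-group expression cohort
#'
#' Defines the study conditions for \code{\link{simulateCohort}}: a two-group
#' (MNA vs non-MNA) log-normal expression cohort with planted signature
#' genes, proportional-hazards survival structure, and latent-factor
#' co-expression modules. Gene ids are \code{g1..gN}; the first
#' \code{nPosGenes} genes carry the MNA effect, the next \code{nNegGenes}
#' the non-MNA effect, and module blocks follow immediately after.
#'
#' @param nSamples number of samples.
#' @param mnaFraction proportion of MNA samples, in (0, 1).
#' @param nGenes number of genes.
#' @param nPosGenes,posEffect count of genes upregulated in the MNA group
#'   and the log2 units added there.
#' @param nNegGenes,negEffect count of genes upregulated in the non-MNA
#'   group and the log2 units added there.
#' @param hazardBetas per-gene log-hazard coefficients: either a named
#'   numeric vector over gene ids, or \code{list(pos =, neg =)} applying one
#'   coefficient to every planted positive / negative gene, or \code{NULL}
#'   (no survival signal).
#' @param baselineHazard exponential baseline hazard rate (1/time units).
#' @param censorRate independent exponential censoring rate.
#' @param moduleSpec data.frame with columns \code{size} and \code{loading}
#'   (one latent Gaussian factor per module, loading added on the log2
#'   scale), or \code{NULL}.
#' @param noiseSd per-gene Gaussian noise sd, log2 units.
#' @param seed integer seed feeding a hierarchical stream per generator.
#' @return A validated list of class \code{"CohortConfig"}.
#' @export
cohortConfig <- function(nSamples = 200L, mnaFraction = 0.25,
                         nGenes = 1000L, nPosGenes = 0L, posEffect = 1.5,
                         nNegGenes = 0L, negEffect = 1.5,
                         hazardBetas = NULL, baselineHazard = 0.1,
                         censorRate = 0.05, moduleSpec = NULL,
                         noiseSd = 1, seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples), mnaFraction = mnaFraction,
              nGenes = as.integer(nGenes), nPosGenes = as.integer(nPosGenes),
              posEffect = posEffect, nNegGenes = as.integer(nNegGenes),
              negEffect = negEffect, hazardBetas = hazardBetas,
              baselineHazard = baselineHazard, censorRate = censorRate,
              moduleSpec = moduleSpec, noiseSd = noiseSd,
              seed = as.integer(seed))
  class(cfg) <- "CohortConfig"
  validateCohortConfig(cfg)
  cfg
}

validateCohortConfig <- function(cfg) {
  with(cfg, {
    if (nSamples < 2L || nGenes < 1L)
      stop("counts must be positive (nSamples >= 2, nGenes >= 1)")
    if (mnaFraction <= 0 || mnaFraction >= 1)
      stop("mnaFraction must lie in (0, 1)")
    if (noiseSd < 0) stop("noiseSd must be >= 0")
    nModGenes <- if (is.null(moduleSpec)) 0L else sum(moduleSpec$size)
    if (nPosGenes + nNegGenes + nModGenes > nGenes)
      stop("planted genes (signature + modules) exceed nGenes")
    if (!is.null(moduleSpec) &&
        !all(c("size", "loading") %in% colnames(moduleSpec)))
      stop("moduleSpec needs columns 'size' and 'loading'")
    if (baselineHazard <= 0 || censorRate < 0)
      stop("baselineHazard must be > 0, censorRate >= 0")
  })
  invisible(cfg)
}

resolveHazardBetas <- function(cfg, genes) {
  hb <- cfg$hazardBetas
  betas <- setNames(numeric(length(genes)), genes)
  if (is.null(hb)) return(betas)
  if (is.list(hb)) {
    if (cfg$nPosGenes > 0L && !is.null(hb$pos))
      betas[seq_len(cfg$nPosGenes)] <- hb$pos
    if (cfg$nNegGenes > 0L && !is.null(hb$neg))
      betas[cfg$nPosGenes + seq_len(cfg$nNegGenes)] <- hb$neg
  } else {
    if (is.null(names(hb)) || !all(names(hb) %in% genes))
      stop("named hazardBetas must refer to existing gene ids")
    betas[names(hb)] <- hb
  }
  betas
}

#' Simulate a two-group expression cohort with planted ground truth
#'
#' Expression is baseline + group effect (planted signature genes) + latent
#' factor structure (one Gaussian factor per configured module) + Gaussian
#' noise, all on the log2 scale. Survival times follow an exponential
#' proportional-hazards model with linear predictor
#' \eqn{\sum_g \beta_g z_g} over centered, unit-scaled expression of the
#' hazard genes, with independent exponential censoring.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return list with \code{cohort} (\linkS4class{ExpressionCohort}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' sim <- simulateCohort(cohortConfig(nSamples = 40, nGenes = 100,
#'                                    nPosGenes = 5, seed = 7))
#' dim(exprsMatrix(sim$cohort))
#' @export
simulateCohort <- function(config) {
  validateCohortConfig(config)
  genes <- paste0("g", seq_len(config$nGenes))
  samples <- paste0("s", seq_len(config$nSamples))
  nMNA <- round(config$nSamples * config$mnaFraction)
  if (nMNA < 1L || nMNA >= config$nSamples)
    stop("mnaFraction leaves a group empty at this nSamples")
  mna <- c(rep(1L, nMNA), rep(0L, config$nSamples - nMNA))

  expr <- withSeed(deriveSeed(config$seed, "expression"), {
    baseline <- runif(config$nGenes, 5, 10)
    e <- matrix(baseline, config$nGenes, config$nSamples)
    if (config$nPosGenes > 0L)
      e[seq_len(config$nPosGenes), mna == 1L] <-
        e[seq_len(config$nPosGenes), mna == 1L] + config$posEffect
    if (config$nNegGenes > 0L)
      e[config$nPosGenes + seq_len(config$nNegGenes), mna == 0L] <-
        e[config$nPosGenes + seq_len(config$nNegGenes), mna == 0L] +
        config$negEffect
    e
  })

  moduleLabels <- setNames(rep(0L, config$nGenes), genes)
  if (!is.null(config$moduleSpec)) {
    expr <- withSeed(deriveSeed(config$seed, "modules"), {
      offset <- config$nPosGenes + config$nNegGenes
      for (m in seq_len(nrow(config$moduleSpec))) {
        sz <- config$moduleSpec$size[m]
        idx <- offset + seq_len(sz)
        f <- rnorm(config$nSamples)
        expr[idx, ] <- expr[idx, ] +
          config$moduleSpec$loading[m] * matrix(f, sz, config$nSamples,
                                                byrow = TRUE)
        moduleLabels[idx] <- m
        offset <- offset + sz
      }
      expr
    })
  }

  if (config$noiseSd > 0)
    expr <- expr + withSeed(deriveSeed(config$seed, "noise"),
      matrix(rnorm(length(expr), sd = config$noiseSd),
             config$nGenes, config$nSamples))
  dimnames(expr) <- list(genes, samples)

  betas <- resolveHazardBetas(config, genes)
  hz <- betas[betas != 0]
  lp <- rep(0, config$nSamples)
  if (length(hz)) {
    z <- t(scale(t(expr[names(hz), , drop = FALSE])))
    lp <- as.numeric(crossprod(z, hz))
  }
  surv <- withSeed(deriveSeed(config$seed, "survival"), {
    tEvent <- rexp(config$nSamples,
                   rate = config$baselineHazard * exp(lp))
    tCens <- if (config$censorRate > 0)
      rexp(config$nSamples, rate = config$censorRate)
    else rep(Inf, config$nSamples)
    data.frame(surv_time = pmax(pmin(tEvent, tCens), 1e-8),
               surv_event = as.integer(tEvent <= tCens))
  })

  clinical <- data.frame(mna_status = mna, surv, row.names = samples)
  clinical$stage <- withSeed(deriveSeed(config$seed, "stage"),
    factor(ifelse(mna == 1L, "stage4",
                  sample(paste0("stage", 1:4), config$nSamples,
                         replace = TRUE))))

  nPos <- config$nPosGenes; nNeg <- config$nNegGenes
  truth <- new("GroundTruth",
    posSignature = data.frame(gene = genes[seq_len(nPos)],
                              effect = rep(config$posEffect, nPos)),
    negSignature = data.frame(gene = genes[nPos + seq_len(nNeg)],
                              effect = rep(config$negEffect, nNeg)),
    hazardCoefficients = betas,
    moduleLabels = moduleLabels,
    trueFractions = matrix(numeric(0), 0, 0),
    trueRegulons = list())
  list(cohort = ExpressionCohort(expr, clinical), truth = truth,
       linearPredictor = setNames(lp, samples))
}

#' Simulate reference cell-type profiles and bulk mixtures
#'
#' Builds linear-scale reference profiles with disjoint marker-gene blocks
#' (one block per cell type), replicate reference samples, and bulk mixtures
#' \code{mixture = reference \%*\% fractions + noise} with mixing fractions
#' drawn uniformly on the simplex by stick-breaking.
#'
#' @param nTypes number of cell types (>= 2).
#' @param markersPerType marker genes per type.
#' @param nOtherGenes additional non-marker genes.
#' @param nRefsPerType replicate reference samples per type.
#' @param nSamples number of bulk mixture samples.
#' @param noiseSd mixture noise sd as a fraction of each gene's signal.
#' @param markerHigh,markerLow linear-scale expression of a marker in its
#'   own type vs elsewhere.
#' @param seed integer seed.
#' @return list with \code{refs} (list: \code{profiles} genes x reference
#'   samples, \code{typeMap} reference sample -> type), \code{mixtures}
#'   (linear-scale genes x samples matrix), \code{trueFractions}
#'   (samples x types, rows sum to 1).
#' @export
simulateReferenceMixtures <- function(nTypes = 5L, markersPerType = 40L,
                                      nOtherGenes = 100L, nRefsPerType = 3L,
                                      nSamples = 50L, noiseSd = 0.05,
                                      markerHigh = 500, markerLow = 20,
                                      seed = 1L) {
  if (nTypes < 2L) stop("need at least 2 cell types")
  if (markersPerType < 1L) stop("each type needs >= 1 marker gene")
  types <- paste0("type", seq_len(nTypes))
  nGenes <- nTypes * markersPerType + nOtherGenes
  genes <- paste0("m", seq_len(nGenes))

  meanProfile <- matrix(markerLow, nGenes, nTypes,
                        dimnames = list(genes, types))
  for (t in seq_len(nTypes))
    meanProfile[(t - 1L) * markersPerType + seq_len(markersPerType), t] <-
      markerHigh
  if (nOtherGenes > 0L)
    meanProfile[nTypes * markersPerType + seq_len(nOtherGenes), ] <- 50

  refSamples <- paste0(rep(types, each = nRefsPerType), "_r",
                       rep(seq_len(nRefsPerType), nTypes))
  typeMap <- setNames(rep(types, each = nRefsPerType), refSamples)
  profiles <- withSeed(deriveSeed(seed, "refs"), {
    p <- meanProfile[, typeMap, drop = FALSE]
    p <- pmax(p + matrix(rnorm(length(p), sd = 0.02 * p), nrow(p)), 0)
    colnames(p) <- refSamples
    p
  })

  fractions <- withSeed(deriveSeed(seed, "fractions"),
    t(vapply(seq_len(nSamples), function(i) stickBreak(nTypes),
             numeric(nTypes))))
  dimnames(fractions) <- list(paste0("mix", seq_len(nSamples)), types)

  mixtures <- meanProfile %*% t(fractions)
  if (noiseSd > 0)
    mixtures <- withSeed(deriveSeed(seed, "mixnoise"),
      pmax(mixtures + matrix(rnorm(length(mixtures),
                                   sd = noiseSd * abs(mixtures)),
                             nrow(mixtures)), 0))
  list(refs = list(profiles = profiles, typeMap = typeMap),
       mixtures = mixtures, trueFractions = fractions,
       meanProfile = meanProfile)
}

# Uniform-simplex draw by stick-breaking: v_i ~ Beta(1, K - i).
stickBreak <- function(k) {
  f <- numeric(k)
  rest <- 1
  for (i in seq_len(k - 1L)) {
    v <- stats::rbeta(1, 1, k - i)
    f[i] <- v * rest
    rest <- rest - f[i]
  }
  f[k] <- rest
  f
}

#' Simulate an annotated interactome fixture with a hand-derivable network
#'
#' Emits a protein annotation table (subcellular locations with reliability
#' status, per-immune-population normalized expression scores straddling the
#' 1.5 threshold), a STRING-style scored edge table straddling the 400
#' threshold (including exact-boundary rows and a self-loop), a tumor-side
#' gene set, and the expected filtered network computed by an exhaustive
#' reference loop independent of the network module.
#'
#' @param nProteins number of proteins.
#' @param nEdges number of candidate interaction edges.
#' @param populations character vector of immune population labels.
#' @param seed integer seed.
#' @return list with \code{annotation} (data.frame: protein, locations,
#'   population, score, activation_status), \code{edges} (data.frame:
#'   protein1, protein2, combined_score), \code{tumorSet}, and
#'   \code{expected} (\linkS4class{ImmuneNetwork}).
#' @export
simulateInteractome <- function(nProteins = 60L, nEdges = 150L,
                                populations = c("CD8_Tcell", "CD4_Tcell",
                                                "NK", "Bcell", "Monocyte"),
                                seed = 1L) {
  proteins <- sprintf("P%02d", seq_len(nProteins))
  surfaceTerms <- c("plasma membrane", "cell junctions",
                    "focal adhesion sites")
  otherTerms <- c("cytosol", "nucleoplasm", "mitochondria", "vesicles")

  ann <- withSeed(deriveSeed(seed, "annotation"), {
    locs <- vapply(seq_along(proteins), function(i) {
      kind <- i %% 4L
      if (kind == 0L)            # surface, reliable
        paste0(sample(surfaceTerms, 1), "|approved;",
               sample(otherTerms, 1), "|supported")
      else if (kind == 1L)       # surface term at non-reliable status only
        paste0(sample(surfaceTerms, 1), "|uncertain;",
               sample(otherTerms, 1), "|approved")
      else if (kind == 2L)       # surface, supported
        paste0(sample(surfaceTerms, 1), "|supported")
      else                       # intracellular only
        paste0(sample(otherTerms, 2), "|approved", collapse = ";")
    }, character(1))
    scores <- round(runif(nProteins * length(populations), 0, 3), 2)
    # plant exact-boundary and clearly straddling values
    scores[seq_len(length(populations))] <- 1.5
    data.frame(
      protein = rep(proteins, times = length(populations)),
      locations = rep(locs, times = length(populations)),
      population = rep(populations, each = nProteins),
      score = scores,
      activation_status = rep(sample(c("resting", "activated"),
                                     length(populations), replace = TRUE),
                              each = nProteins),
      stringsAsFactors = FALSE)
  })

  edges <- withSeed(deriveSeed(seed, "edges"), {
    a <- sample(proteins, nEdges, replace = TRUE)
    b <- sample(proteins, nEdges, replace = TRUE)
    s <- sample(0:1000, nEdges, replace = TRUE)
    s[1:3] <- c(400L, 401L, 399L)      # boundary plants
    b[4] <- a[4]                       # self-loop plant
    data.frame(protein1 = a, protein2 = b, combined_score = as.integer(s),
               stringsAsFactors = FALSE)
  })

  tumorSet <- withSeed(deriveSeed(seed, "tumor"),
                       sample(proteins, max(5L, nProteins %/% 4L)))

  expected <- referenceNetwork(ann, edges, tumorSet)
  list(annotation = ann, edges = edges, tumorSet = tumorSet,
       expected = expected)
}

# Exhaustive reference application of the filter cascade, written as plain
# loops so it can serve as an oracle for the vectorized network builder.
referenceNetwork <- function(ann, edges, tumorSet, minScore = 400,
                             scoreThreshold = 1.5) {
  isReliableSurface <- function(locString) {
    parts <- strsplit(strsplit(locString, ";")[[1]], "\\|")
    any(vapply(parts, function(p)
      p[1] %in% c("plasma membrane", "cell junctions",
                  "focal adhesion sites") &&
        p[2] %in% c("approved", "supported"), logical(1)))
  }
  locByProtein <- ann[!duplicated(ann$protein),
                      c("protein", "locations")]
  surface <- locByProtein$protein[vapply(locByProtein$locations,
                                         isReliableSurface, logical(1))]
  # naive undirected dedupe (keep max score per unordered pair), mirroring
  # the edge-reader contract, written independently of dedupeEdges()
  best <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(edges))) {
    p1 <- edges$protein1[i]; p2 <- edges$protein2[i]
    if (p1 == p2) next
    key <- paste(sort(c(p1, p2)), collapse = "\r")
    prev <- if (!is.null(best[[key]])) best[[key]] else -1L
    if (edges$combined_score[i] > prev)
      best[[key]] <- edges$combined_score[i]
  }
  keys <- ls(best)
  edges <- data.frame(
    protein1 = vapply(strsplit(keys, "\r"), `[`, character(1), 1L),
    protein2 = vapply(strsplit(keys, "\r"), `[`, character(1), 2L),
    combined_score = vapply(keys, function(k) best[[k]], integer(1)),
    stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(edges))) {
    p1 <- edges$protein1[i]; p2 <- edges$protein2[i]
    sc <- edges$combined_score[i]
    if (p1 == p2 || sc <= minScore) next
    for (orient in list(c(p1, p2), c(p2, p1))) {
      tg <- orient[1]; ip <- orient[2]
      if (!(tg %in% tumorSet) || !(tg %in% surface)) next
      if (!(ip %in% surface)) next
      rows <- ann[ann$protein == ip & ann$score > scoreThreshold, ,
                  drop = FALSE]
      for (j in seq_len(nrow(rows)))
        out[[length(out) + 1L]] <- data.frame(
          tumorGene = tg, immuneProtein = ip,
          population = rows$population[j],
          activationStatus = rows$activation_status[j],
          score = sc, stringsAsFactors = FALSE)
    }
  }
  edgesDF <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(tumorGene = character(), immuneProtein = character(),
               population = character(), activationStatus = character(),
               score = integer(), stringsAsFactors = FALSE)
  edgesDF <- edgesDF[order(edgesDF$tumorGene, edgesDF$immuneProtein,
                           edgesDF$population), , drop = FALSE]
  rownames(edgesDF) <- NULL
  counts <- table(factor(edgesDF$population))
  new("ImmuneNetwork", edges = edgesDF,
      populationCounts = setNames(as.integer(counts), names(counts)))
}

#' Simulate a TF-to-target regulon prior aligned with planted modules
#'
#' Each planted TF draws a configurable fraction (\code{purity}) of its
#' targets from one planted module and the rest uniformly from the gene
#' universe; decoy TFs draw all targets uniformly.
#'
#' @param moduleLabels named integer vector, gene -> module id (0 = none),
#'   e.g. from a \linkS4class{GroundTruth}.
#' @param targetsPerTF targets drawn per TF.
#' @param purity fraction of a planted TF's targets inside its module.
#' @param nDecoys number of decoy TFs with uniform targets.
#' @param seed integer seed.
#' @return named list TF -> character vector of targets, with attribute
#'   \code{plantedModule} (named integer; 0 for decoys).
#' @export
simulateRegulonPrior <- function(moduleLabels, targetsPerTF = 40L,
                                 purity = 0.8, nDecoys = 5L, seed = 1L) {
  mods <- sort(unique(moduleLabels[moduleLabels > 0L]))
  if (!length(mods)) stop("no modules configured in moduleLabels")
  universe <- names(moduleLabels)
  withSeed(deriveSeed(seed, "regulons"), {
    prior <- list()
    planted <- integer(0)
    for (m in mods) {
      inMod <- universe[moduleLabels == m]
      nIn <- min(round(purity * targetsPerTF), length(inMod))
      tf <- paste0("TF", m)
      prior[[tf]] <- unique(c(sample(inMod, nIn),
                              sample(universe, targetsPerTF - nIn)))
      planted[tf] <- m
    }
    for (d in seq_len(nDecoys)) {
      tf <- paste0("decoyTF", d)
      prior[[tf]] <- sample(universe, targetsPerTF)
      planted[tf] <- 0L
    }
    attr(prior, "plantedModule") <- planted
    prior
  })
}
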