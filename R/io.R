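#' Read a gene expression table
#'
#' Tab- (or comma-) delimited text, first column gene labels, header line of
#' sample labels. Duplicate gene rows are retained so the preprocessing
#' stage can average them; \code{"NA"} cells are parsed as missing and their
#' count reported.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return numeric matrix (genes x samples) with possibly duplicated row
#'   names; attributes \code{duplicatedGenes} (labels occurring more than
#'   once) and \code{nMissing}.
#' @export
readExpressionTable <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed expression table: ", path)
  genes <- trimws(as.character(df[[1]]))
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) &
                   toupper(trimws(vals[[j]])) != "NA")
    if (length(bad))
      stop("non-numeric value in row '", genes[bad[1]], "', column '",
           colnames(vals)[j], "'")
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  nMissing <- sum(is.na(m))
  if (nMissing > 0)
    message(nMissing, " missing value(s) in ", basename(path))
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    message(length(dup), " duplicated gene label(s) retained for averaging")
  structure(m, duplicatedGenes = dup, nMissing = nMissing)
}

#' Write an expression table (inverse of \code{readExpressionTable})
#' @param x numeric matrix with gene row names and sample column names.
#' @param path output path.
#' @export
writeExpressionTable <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' \code{name}, \code{description}, then member genes. Member order is
#' preserved; duplicate members within a set are dropped with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors; each element carries a
#'   \code{description} attribute.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    members <- trimws(f[-(1:2)])
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[1], "' deduplicated")
      members <- unique(members)
    }
    if (!length(members)) stop("GMT line ", i, ": set has no members")
    if (f[1] %in% names(sets)) stop("duplicate set name '", f[1], "'")
    sets[[f[1]]] <- structure(members, description = f[2])
  }
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors (optional
#'   \code{description} attributes).
#' @param path output path.
#' @export
writeGMT <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, attr(sets[[nm]], "description") %||% "", sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' Requires columns \code{sample}, \code{mna_status}, \code{surv_time},
#' \code{surv_event}; unknown columns are preserved as extras.
#' \code{surv_event} is coerced to \{0, 1\}; non-positive survival times are
#' rejected.
#'
#' @param path TSV path.
#' @return data.frame with row names = sample ids.
#' @export
readClinicalTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample", "mna_status", "surv_time", "surv_event")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("clinical table missing required column(s): ",
         paste(miss, collapse = ", "))
  if (any(df$surv_time <= 0, na.rm = TRUE))
    stop("survival times must be > 0")
  ev <- df$surv_event
  if (is.logical(ev)) ev <- as.integer(ev)
  if (is.character(ev))
    ev <- as.integer(tolower(ev) %in% c("1", "true", "yes", "dead",
                                        "event"))
  if (!all(ev %in% c(0L, 1L)))
    stop("surv_event must be codeable as {0, 1}")
  df$surv_event <- as.integer(ev)
  df$mna_status <- as.integer(df$mna_status)
  rownames(df) <- trimws(as.character(df$sample))
  df
}

#' Read a protein annotation table
#'
#' One row per (protein, population) with columns \code{protein},
#' \code{locations} (semicolon-separated \code{term|status} pairs, status
#' one of approved/supported/other), \code{population}, \code{score}
#' (normalized per-population expression) and optionally
#' \code{activation_status}. Rows with non-reliable statuses are retained;
#' reliability is evaluated by the network filters.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
readAnnotationTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("protein", "locations", "population", "score")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("annotation table missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!nrow(df)) stop("empty annotation table")
  if (any(!is.finite(df$score))) stop("annotation scores must be finite")
  if (is.null(df$activation_status)) df$activation_status <- "unknown"
  df$protein <- trimws(df$protein)
  df
}

#' Read a STRING-style interaction edge table
#'
#' Columns \code{protein1}, \code{protein2}, \code{combined_score}
#' (integer, 0-1000). The table is made undirected on load: self-loops are
#' dropped and bidirectional duplicates collapsed (keeping the maximum
#' score) before any score filtering.
#'
#' @param path TSV path.
#' @return data.frame (protein1, protein2, combined_score).
#' @export
readEdgeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("protein1", "protein2", "combined_score")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("edge table missing required column(s): ",
         paste(miss, collapse = ", "))
  df$combined_score <- as.integer(df$combined_score)
  if (any(df$combined_score < 0 | df$combined_score > 1000, na.rm = TRUE))
    stop("combined_score must lie in [0, 1000]")
  dedupeEdges(df)
}

# Undirected deduplication: drop self-loops, collapse A-B / B-A rows to one
# edge keeping the maximum combined score.
dedupeEdges <- function(df) {
  df$protein1 <- trimws(df$protein1)
  df$protein2 <- trimws(df$protein2)
  df <- df[df$protein1 != df$protein2, , drop = FALSE]
  a <- pmin(df$protein1, df$protein2)
  b <- pmax(df$protein1, df$protein2)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -df$combined_score)
  df <- data.frame(protein1 = a, protein2 = b,
                   combined_score = df$combined_score,
                   stringsAsFactors = FALSE)[o, , drop = FALSE]
  df <- df[!duplicated(key[o]), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a one-gene-per-line list (e.g. the immune gene universe)
#' @param path text file, one gene label per line.
#' @return character vector, trimmed, empty lines dropped.
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Write an ExpressionCohort to disk as expression + clinical TSV
#' @param cohort an \linkS4class{ExpressionCohort}.
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ep <- file.path(dir, "expression.tsv")
  cp <- file.path(dir, "clinical.tsv")
  writeExpressionTable(exprsMatrix(cohort), ep)
  cl <- clinicalData(cohort)
  cl <- data.frame(sample = rownames(cl), cl, stringsAsFactors = FALSE)
  write.table(cl, cp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(expression = ep, clinical = cp))
}

#' Read an ExpressionCohort from expression + clinical TSV
#' @param expressionPath,clinicalPath paths as written by
#'   \code{\link{writeCohort}}.
#' @return an \linkS4class{ExpressionCohort}.
#' @export
readCohort <- function(expressionPath, clinicalPath) {
  m <- readExpressionTable(expressionPath)
  cl <- readClinicalTable(clinicalPath)
  ExpressionCohort(m, cl)
}
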