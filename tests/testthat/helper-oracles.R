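# Independent oracles and small fixture builders shared across tests.

# Brute-force GSEA running sum: walks every position of the ranked list and
# accumulates P_hit - P_miss explicitly. Independent of the package's
# closed-form hit-position implementation.
bruteForceES <- function(ranked, geneSet, exponent = 1) {
  N <- length(ranked)
  hit <- names(ranked) %in% geneSet
  w <- abs(ranked)^exponent
  tot <- sum(w[hit])
  run <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    cur <- if (hit[i]) cur + w[i] / tot else cur - 1 / (N - sum(hit))
    run[i] <- cur
  }
  m1 <- max(run); m2 <- min(run)
  if (m1 >= -m2 - 1e-12) m1 else m2
}

# Hand-computable two-group cohort: genes x samples with explicit values.
toyMatrix <- function(values, genes, samples) {
  matrix(values, nrow = length(genes), byrow = TRUE,
         dimnames = list(genes, samples))
}

# Small annotation row constructor for network tests.
annRow <- function(protein, locations, population, score,
                   activation = "resting") {
  data.frame(protein = protein, locations = locations,
             population = population, score = score,
             activation_status = activation, stringsAsFactors = FALSE)
}

# Two-sample log-rank statistic computed from first principles (observed
# minus expected events in group 1 at each distinct event time, over the
# hypergeometric variance), as the chi-square cross-check.
handLogrank <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in ts) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}
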