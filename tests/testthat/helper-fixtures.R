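## Fixtures are built in code; nothing is read from disk except the
## reference count tables under inst/extdata.

.cells <- c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")

## A tiny hand-built cohort: 4 probes x 6 samples (3 like-sex pairs).
tinyCohort <- function(withDetP = TRUE) {
  set.seed(402)
  beta <- matrix(round(runif(24, 0.05, 0.95), 4), 4, 6,
                 dimnames = list(paste0("cg000000", 1:4), paste0("s", 1:6)))
  dp <- matrix(0.001, 4, 6, dimnames = dimnames(beta))
  cp <- matrix(1 / 6, 6, 6, dimnames = list(NULL, .cells))
  samples <- data.frame(
    sample_id = paste0("s", 1:6),
    sex = rep(c("male", "male", "female"), each = 2),
    age = rep(c(60, 70, 65), each = 2),
    twin_pair_id = rep(c("p1", "p2", "p3"), each = 2),
    zygosity = "MZ",
    sentrix_id = rep(c("A", "B", "A"), each = 2),
    sentrix_position = rep(c("R01C01", "R02C01"), 3),
    cp, stringsAsFactors = FALSE)
  probes <- data.frame(
    probe_id = rownames(beta), chromosome = "X",
    position = c(100L, 200L, 300L, 400L),
    gene_region = c("TSS200", "Body", "1stExon", "Intergenic"),
    is_cross_reactive = FALSE, is_polymorphic = FALSE,
    stringsAsFactors = FALSE)
  MethylationCohort(beta, samples, probes,
                    detectionP = if (withDetP) dp, cohortLabel = "tiny")
}

## Zero-matrix of per-pattern age slopes, for null configurations.
zeroSlopes <- function() {
  matrix(0, 6, 2, dimnames = list(c("A", "B", "C", "D", "ONE_COHORT", "REST"),
                                  c("male", "female")))
}

## Global-null configuration: no sex effect, no age slope.
nullConfig <- function(nPairs = 30, nCpgs = 100, seed = 1,
                       detectionFailRate = 0, ...) {
  SimulationConfig(nPairsPerSex = nPairs,
                   nCpgsPerPattern = c(REST = nCpgs),
                   ageSlope = zeroSlopes(),
                   detectionFailRate = detectionFailRate, seed = seed, ...)
}

## Brute-force BH step-up, straight from the definition.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- sapply(seq_len(m), function(i) min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

## Brute-force Pearson chi-squared.
bruteForceChisq <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
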