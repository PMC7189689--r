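#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

## Canonical column sets used throughout the package.
.CELL_TYPES <- c("CD8T", "CD4T", "NK", "Bcell", "Mono", "Gran")
.GENE_REGIONS <- c("1stExon", "3'UTR", "5'UTR", "Body", "Intergenic",
                   "TSS1500", "TSS200")
.SAMPLE_COLS <- c("sample_id", "sex", "age", "twin_pair_id", "zygosity",
                  "sentrix_id", "sentrix_position", .CELL_TYPES)
.PROBE_COLS <- c("probe_id", "chromosome", "position", "gene_region",
                 "is_cross_reactive", "is_polymorphic")
.PATTERNS <- c("A", "B", "C", "D", "ONE_COHORT", "REST")

#' MethylationCohort: one cohort's methylation data
#'
#' A \linkS4class{SummarizedExperiment} holding a CpG-by-sample beta-value
#' matrix (assay \code{"beta"}, values in \eqn{[0,1]} or \code{NA}), an
#' optional same-shaped detection-p matrix (assay \code{"detection_p"}),
#' the sample sheet as \code{colData} (sex, age, twin pairing, zygosity,
#' sentrix ID/position, six blood cell-type proportions) and the probe
#' annotation as \code{rowData} (chromosome, position, gene-region category,
#' cross-reactive/polymorphic flags). The cohort label lives in
#' \code{metadata(x)$cohort_label}.
#'
#' Twin pairs are like-sex: sex must be constant within \code{twin_pair_id}
#' and no pair may exceed two members. Cell-type proportions, when present,
#' must be non-negative and sum to one within 1e-6 per sample.
#'
#' @seealso \code{\link{MethylationCohort}} (constructor),
#'   \code{\link{betaValues}}, \code{\link{applyQC}}
#' @export
setClass("MethylationCohort", contains = "SummarizedExperiment")

setValidity("MethylationCohort", function(object) {
  msg <- character()
  anames <- SummarizedExperiment::assayNames(object)
  if (!"beta" %in% anames)
    return("assay 'beta' is required")
  beta <- SummarizedExperiment::assay(object, "beta")
  if (is.null(rownames(object)) || is.null(colnames(object)))
    msg <- c(msg, "probe and sample ids (dimnames) are required")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate probe ids")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  rng <- suppressWarnings(range(beta, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1))
    msg <- c(msg, "beta values must lie in [0, 1]")
  cd <- SummarizedExperiment::colData(object)
  if ("detection_p" %in% anames) {
    dp <- SummarizedExperiment::assay(object, "detection_p")
    drng <- suppressWarnings(range(dp, na.rm = TRUE))
    if (is.finite(drng[1]) && (drng[1] < 0 || drng[2] > 1))
      msg <- c(msg, "detection p-values must lie in [0, 1]")
  }
  if (all(c("sex", "twin_pair_id") %in% colnames(cd))) {
    sex <- as.character(cd$sex)
    if (!all(sex %in% c("male", "female")))
      msg <- c(msg, "sex must be 'male' or 'female'")
    pair <- as.character(cd$twin_pair_id)
    nsex <- tapply(sex, pair, function(s) length(unique(s)))
    if (any(nsex > 1))
      msg <- c(msg, "sex must be constant within a twin pair (like-sex pairs)")
    if (any(table(pair) > 2))
      msg <- c(msg, "a twin pair cannot have more than two members")
  }
  if (all(.CELL_TYPES %in% colnames(cd))) {
    cp <- as.matrix(as.data.frame(cd[, .CELL_TYPES]))
    if (any(cp < 0, na.rm = TRUE))
      msg <- c(msg, "cell-type proportions must be non-negative")
    s <- rowSums(cp)
    if (any(abs(s - 1) > 1e-6, na.rm = TRUE))
      msg <- c(msg, "cell-type proportions must sum to 1 (tolerance 1e-6)")
  }
  gr <- SummarizedExperiment::rowData(object)$gene_region
  if (!is.null(gr) && !all(as.character(gr) %in% .GENE_REGIONS))
    msg <- c(msg, sprintf("gene_region must be one of: %s",
                          paste(.GENE_REGIONS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' QC report for a methylation cohort
#'
#' Tallies of the quality-control actions taken by \code{\link{applyQC}}:
#' probes in, calls masked for detection failure, probes dropped for the
#' blacklist (cross-reactive or polymorphic) and for excess missingness,
#' and probes out. Drops are disjoint; the blacklist is applied first, so
#' \code{nProbesOut = nProbesIn - nDroppedBlacklist - nDroppedMissingness}.
#'
#' @export
setClass("QCReport",
  representation(nProbesIn = "integer", nMaskedCalls = "integer",
                 nDroppedMissingness = "integer", nDroppedBlacklist = "integer",
                 nProbesOut = "integer"))

setValidity("QCReport", function(object) {
  if (object@nProbesOut !=
      object@nProbesIn - object@nDroppedMissingness - object@nDroppedBlacklist)
    return("probes out must equal probes in minus disjoint drops")
  TRUE
})

#' Simulation configuration for a synthetic twin cohort
#'
#' Defines the generating model of \code{\link{generateCohort}}: a
#' twin-pair design (like-sex pairs, co-twins sharing age), per-pattern
#' baseline methylation and age slopes on the M scale, twin-pair, sentrix-ID
#' and sentrix-position random intercepts, Dirichlet blood cell compositions
#' with per-CpG cell-composition effects, Gaussian residual noise, and
#' missing-completely-at-random detection failures.
#'
#' @slot nPairsPerSex twin pairs per sex.
#' @slot mzFraction proportion of pairs that are monozygotic.
#' @slot ageRange min and max age (years); ages drawn uniformly per pair.
#' @slot nCpgsPerPattern named integer vector over pattern labels
#'   (subset of \code{A, B, C, D, ONE_COHORT, REST}).
#' @slot patternBaseBeta pattern-by-sex matrix of baseline beta levels
#'   (columns \code{male}, \code{female}), values in (0,1).
#' @slot ageSlope pattern-by-sex matrix of age slopes, M units per year.
#' @slot pairInterceptSd,batchSd,positionSd,residualSd M-scale standard
#'   deviations of the twin-pair, sentrix-ID and sentrix-position random
#'   intercepts and of the residual noise.
#' @slot batchCount number of sentrix IDs.
#' @slot cellDirichletAlpha 6-vector of Dirichlet concentrations
#'   (CD8T, CD4T, NK, Bcell, Mono, Gran).
#' @slot cellEffectSd SD of per-CpG cell-composition coefficients (M scale).
#' @slot detectionFailRate proportion of calls with detection p > 0.01.
#' @slot singletonPairs if \code{TRUE} each "pair" is a single unrelated
#'   individual (validation-cohort design).
#' @slot oneCohortActive whether ONE_COHORT sites express their sex effect
#'   in this cohort's generating model.
#' @slot seed integer root seed; all draws flow from it.
#' @seealso \code{\link{SimulationConfig}} (constructor with study defaults)
#' @export
setClass("SimulationConfig",
  representation(nPairsPerSex = "integer", mzFraction = "numeric",
                 ageRange = "numeric", nCpgsPerPattern = "integer",
                 patternBaseBeta = "matrix", ageSlope = "matrix",
                 pairInterceptSd = "numeric", batchCount = "integer",
                 batchSd = "numeric", positionSd = "numeric",
                 residualSd = "numeric", cellDirichletAlpha = "numeric",
                 cellEffectSd = "numeric", detectionFailRate = "numeric",
                 singletonPairs = "logical", oneCohortActive = "logical",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nPairsPerSex <= 0L)
    msg <- c(msg, "nPairsPerSex must be positive")
  if (object@mzFraction < 0 || object@mzFraction > 1)
    msg <- c(msg, "mzFraction must be in [0, 1]")
  if (length(object@ageRange) != 2L || diff(object@ageRange) < 0)
    msg <- c(msg, "ageRange must be (min, max) with min <= max")
  if (any(object@nCpgsPerPattern < 0L) || sum(object@nCpgsPerPattern) <= 0L)
    msg <- c(msg, "CpG counts must be non-negative with a positive total")
  if (!all(names(object@nCpgsPerPattern) %in% .PATTERNS))
    msg <- c(msg, "pattern labels must be among A, B, C, D, ONE_COHORT, REST")
  bb <- object@patternBaseBeta
  if (!all(c("male", "female") %in% colnames(bb)))
    msg <- c(msg, "patternBaseBeta needs 'male' and 'female' columns")
  else {
    if (any(bb <= 0 | bb >= 1))
      msg <- c(msg, "patternBaseBeta values must lie in (0, 1)")
    pats <- rownames(bb)
    if ("A" %in% pats && bb["A", "female"] <= bb["A", "male"])
      msg <- c(msg, "pattern A requires female mean > male mean")
    if ("D" %in% pats && bb["D", "male"] <= bb["D", "female"])
      msg <- c(msg, "pattern D requires male mean > female mean")
    if ("B" %in% pats && any(bb["B", ] >= 0.25))
      msg <- c(msg, "pattern B baselines must be < 0.25 in both sexes")
    if ("C" %in% pats && any(bb["C", ] <= 0.75))
      msg <- c(msg, "pattern C baselines must be > 0.75 in both sexes")
  }
  sds <- c(object@pairInterceptSd, object@batchSd, object@positionSd,
           object@residualSd, object@cellEffectSd)
  if (any(sds < 0)) msg <- c(msg, "standard deviations must be >= 0")
  if (object@batchCount < 1L) msg <- c(msg, "batchCount must be >= 1")
  if (length(object@cellDirichletAlpha) != 6L ||
      any(object@cellDirichletAlpha <= 0))
    msg <- c(msg, "cellDirichletAlpha must be 6 positive concentrations")
  if (object@detectionFailRate < 0 || object@detectionFailRate > 1)
    msg <- c(msg, "detectionFailRate must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
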