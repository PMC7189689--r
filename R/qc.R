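#' Quality control for a methylation cohort
#'
#' Applies, in order: (1) blacklist removal — probes flagged cross-reactive
#' or polymorphic in the annotation are dropped; (2) detection-p masking —
#' calls with detection p above \code{detectionThreshold} are set missing;
#' (3) missingness filtering — probes whose missing fraction exceeds
#' \code{maxMissingFraction} (strict \code{>}: "more than") are dropped.
#' The returned report tallies every action. Re-applying QC to its own
#' output changes nothing.
#'
#' @param cohort a \linkS4class{MethylationCohort}.
#' @param detectionThreshold detection p-value above which a call is
#'   treated as missing (default 0.01); ignored with a message when the
#'   cohort has no detection-p assay.
#' @param maxMissingFraction maximum tolerated per-probe missing fraction
#'   (default 0.05).
#' @return a list with components \code{cohort} (the filtered
#'   \linkS4class{MethylationCohort}) and \code{report} (a
#'   \linkS4class{QCReport}).
#' @examples
#' study <- generateStudy(defaultStudyConfigs(seed = 1, scale = 0.05))
#' qc <- applyQC(study$cohorts$cohort2)
#' qc$report
#' @export
applyQC <- function(cohort, detectionThreshold = 0.01,
                    maxMissingFraction = 0.05) {
  nIn <- nrow(cohort)
  pr <- probeInfo(cohort)
  black <- pr$is_cross_reactive | pr$is_polymorphic
  black[is.na(black)] <- FALSE
  cohort <- cohort[!black, ]

  beta <- betaValues(cohort)
  dp <- detectionP(cohort)
  nMasked <- 0L
  if (!is.null(dp)) {
    mask <- !is.na(beta) & !is.na(dp) & dp > detectionThreshold
    nMasked <- sum(mask)
    beta[mask] <- NA_real_
    SummarizedExperiment::assay(cohort, "beta") <- beta
  } else if (!missing(detectionThreshold)) {
    message("no detection-p assay; detection masking skipped")
  }

  missFrac <- rowMeans(is.na(beta))
  dropMiss <- missFrac > maxMissingFraction
  cohort <- cohort[!dropMiss, ]
  if (nrow(cohort) == 0L)
    stop("all probes removed by QC: empty analysis set")

  report <- new("QCReport", nProbesIn = nIn, nMaskedCalls = as.integer(nMasked),
                nDroppedMissingness = as.integer(sum(dropMiss)),
                nDroppedBlacklist = as.integer(sum(black)),
                nProbesOut = nrow(cohort))
  S4Vectors::metadata(cohort)$qc <- report
  list(cohort = cohort, report = report)
}

#' Within-sex quantile normalization
#'
#' Full quantile normalization of the beta matrix applied separately within
#' male columns and within female columns, so the two sexes' X-chromosome
#' distributions are never forced onto a common shape. Ranks are preserved
#' within each sample and output stays in \eqn{[0,1]}. This is a simple
#' stand-in for probe-subset normalizers applied within sex; cohorts already
#' normalized upstream can skip it.
#'
#' @param cohort a \linkS4class{MethylationCohort} with at least two
#'   samples of each sex.
#' @return the cohort with normalized beta values.
#' @export
normalizeWithinSex <- function(cohort) {
  sex <- sampleInfo(cohort)$sex
  for (s in c("male", "female"))
    if (sum(sex == s) < 2L)
      stop("fewer than 2 ", s, " samples; skip normalization for this cohort")
  beta <- betaValues(cohort)
  for (s in c("male", "female")) {
    idx <- which(sex == s)
    beta[, idx] <- limma::normalizeQuantiles(beta[, idx, drop = FALSE],
                                             ties = TRUE)
  }
  SummarizedExperiment::assay(cohort, "beta") <- beta
  S4Vectors::metadata(cohort)$log <-
    c(S4Vectors::metadata(cohort)$log, "within-sex quantile normalization")
  cohort
}
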