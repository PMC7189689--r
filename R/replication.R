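#' Upper-tail hypergeometric overlap probability
#'
#' The probability of observing an overlap at least as large as \code{k}
#' between two significant-CpG lists of sizes \code{m} and \code{n} drawn
#' from a universe of \code{N} CpGs: \eqn{P(X \ge k)} with
#' \eqn{X \sim \mathrm{Hypergeometric}(N, m, n)}. Evaluated in log space,
#' so magnitudes around 1e-300 remain exact.
#'
#' @param N universe size (CpGs analysed).
#' @param m,n sizes of the two significant sets.
#' @param k observed overlap; must satisfy \code{0 <= k <= min(m, n)}.
#' @param log if \code{TRUE} return the natural-log probability.
#' @return the tail probability in \eqn{(0, 1]} (or its log).
#' @examples
#' hypergeometricTail(10096, 159, 415, 55)
#' hypergeometricTail(10096, 159, 415, 0)  # 1
#' @export
hypergeometricTail <- function(N, m, n, k, log = FALSE) {
  if (any(c(N, m, n, k) < 0) || m > N || n > N)
    stop("require 0 <= m, n <= N and k >= 0")
  if (k > min(m, n))
    stop("overlap k cannot exceed min(m, n)")
  lp <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE, log.p = TRUE)
  if (log) lp else exp(lp)
}

#' Replication of age-associated CpGs across two cohorts
#'
#' For each age-association class (\code{both}, \code{male_only},
#' \code{female_only}) intersects the two discovery cohorts' significant
#' sets, computes the hypergeometric tail probability of the overlap over
#' the shared post-QC universe, and reports per-cohort replication
#' percentages \eqn{100 k / m} and \eqn{100 k / n}.
#'
#' @param classC1,classC2 data.frames from \code{\link{classifyAgeSites}}
#'   for the two cohorts (shared probe universe).
#' @param universeSize number of CpGs analysed, N (the post-QC universe of
#'   the discovery analysis).
#' @return a list with \code{summary} (one row per class: m, n, k,
#'   \code{pct_c1}, \code{pct_c2}, \code{p_value}) and \code{replicated}
#'   (named list of replicated probe-id vectors).
#' @export
replicateAcrossCohorts <- function(classC1, classC2, universeSize) {
  if (!setequal(classC1$probe_id, classC2$probe_id))
    stop("inconsistent probe universes between the two cohorts")
  if (nrow(classC1) > universeSize)
    stop("universe size smaller than the tested probe set")
  classes <- c("both", "male_only", "female_only")
  replicated <- stats::setNames(vector("list", length(classes)), classes)
  rows <- lapply(classes, function(cl) {
    set1 <- classC1$probe_id[classC1$class == cl]
    set2 <- classC2$probe_id[classC2$class == cl]
    k <- length(intersect(set1, set2))
    replicated[[cl]] <<- intersect(set1, set2)
    data.frame(class = cl, m = length(set1), n = length(set2), k = k,
               pct_c1 = if (length(set1)) 100 * k / length(set1) else NA_real_,
               pct_c2 = if (length(set2)) 100 * k / length(set2) else NA_real_,
               p_value = hypergeometricTail(universeSize, length(set1),
                                            length(set2), k),
               stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), replicated = replicated)
}

#' Validation of replicated CpGs in a third cohort
#'
#' Checks which replicated CpGs reach \code{q < alpha} in an independent
#' third cohort, where the third cohort's q-values must have been computed
#' over ALL its tested chromosome CpGs (not just the replicated subset).
#' Sex-specific classes are validated in the matching sex stratum; the
#' sex-independent class requires significance in both sexes (or either,
#' via \code{bothRule}). Sign consistency — the third cohort's slope
#' agreeing in direction with both discovery cohorts — is reported as a
#' subset of the validated set. Replicated probes absent from the third
#' cohort are excluded from the denominator with a message.
#'
#' @param replication result of \code{\link{replicateAcrossCohorts}}.
#' @param classC1,classC2 the discovery cohorts'
#'   \code{\link{classifyAgeSites}} tables (for discovery directions).
#' @param thirdMale,thirdFemale the third cohort's \code{\link{fitAgeModel}}
#'   results per sex with \code{q_value} filled over all tested CpGs.
#' @param alpha FDR cut-off in the third cohort (default 0.05).
#' @param bothRule for the sex-independent class: require \code{q < alpha}
#'   in \code{"both"} sexes (default) or in \code{"either"}.
#' @return a list per class: \code{replicated}, \code{validated} and
#'   \code{sign_consistent} probe ids, and \code{rate} (percent validated,
#'   NA for an empty replicated list).
#' @export
validateInThirdCohort <- function(replication, classC1, classC2,
                                  thirdMale, thirdFemale, alpha = 0.05,
                                  bothRule = c("both", "either")) {
  bothRule <- match.arg(bothRule)
  qM <- stats::setNames(thirdMale$q_value, thirdMale$probe_id)
  qF <- stats::setNames(thirdFemale$q_value, thirdFemale$probe_id)
  dM <- stats::setNames(thirdMale$direction, thirdMale$probe_id)
  dF <- stats::setNames(thirdFemale$direction, thirdFemale$probe_id)
  d1M <- stats::setNames(classC1$direction_male, classC1$probe_id)
  d1F <- stats::setNames(classC1$direction_female, classC1$probe_id)
  d2M <- stats::setNames(classC2$direction_male, classC2$probe_id)
  d2F <- stats::setNames(classC2$direction_female, classC2$probe_id)

  out <- list()
  for (cl in names(replication$replicated)) {
    rep_ids <- replication$replicated[[cl]]
    present <- rep_ids[rep_ids %in% names(qM) & rep_ids %in% names(qF)]
    if (length(present) < length(rep_ids))
      message(length(rep_ids) - length(present), " replicated ", cl,
              " probe(s) absent from the third cohort excluded")
    sigM <- !is.na(qM[present]) & qM[present] < alpha
    sigF <- !is.na(qF[present]) & qF[present] < alpha
    validated <- switch(cl,
      male_only = present[sigM],
      female_only = present[sigF],
      both = if (bothRule == "both") present[sigM & sigF]
             else present[sigM | sigF])
    consistent <- switch(cl,
      male_only = validated[dM[validated] == d1M[validated] &
                            dM[validated] == d2M[validated]],
      female_only = validated[dF[validated] == d1F[validated] &
                              dF[validated] == d2F[validated]],
      both = validated[dM[validated] == d1M[validated] &
                       dM[validated] == d2M[validated] &
                       dF[validated] == d1F[validated] &
                       dF[validated] == d2F[validated]])
    out[[cl]] <- list(
      replicated = present, validated = validated,
      sign_consistent = consistent,
      rate = if (length(present)) 100 * length(validated) / length(present)
             else NA_real_)
  }
  out
}
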