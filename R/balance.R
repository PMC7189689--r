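#' Age-matched sex balancing at twin-pair granularity
#'
#' Reduces the larger sex to the smaller sex's sample count by repeatedly
#' selecting, among the larger sex's twin pairs, the pair whose mean age is
#' closest to the smaller sex's mean age (ties broken by lexicographically
#' smaller pair id). Whole pairs are always kept or dropped together; the
#' smaller sex is retained in full. Cohorts of unrelated individuals carry
#' singleton "pairs", so selection degenerates to sample level. A pair that
#' would overshoot the target count is skipped in favour of the next
#' closest that fits.
#'
#' @param x a \linkS4class{MethylationCohort} or a sample-sheet data.frame
#'   (columns \code{sample_id}, \code{sex}, \code{age}, \code{twin_pair_id}).
#' @param ... unused.
#' @return for a data.frame, the retained sample ids (character); for a
#'   cohort, the cohort subset to the retained samples.
#' @examples
#' sheet <- data.frame(sample_id = paste0("s", 1:5),
#'                     sex = c("male", "male", "male", "female", "female"),
#'                     age = c(60, 70, 80, 65, 66),
#'                     twin_pair_id = paste0("p", 1:5))
#' balanceSexes(sheet)  # males aged 70 and 60 retained
#' @name balanceSexes
NULL

#' @rdname balanceSexes
#' @export
setMethod("balanceSexes", "data.frame", function(x, ...) {
  stopifnot(all(c("sample_id", "sex", "age", "twin_pair_id") %in% colnames(x)))
  nBySex <- table(factor(x$sex, levels = c("male", "female")))
  if (any(nBySex == 0L)) stop("both sexes must be present")
  if (nBySex["male"] == nBySex["female"]) return(x$sample_id)
  larger <- names(nBySex)[which.max(nBySex)]
  smaller <- setdiff(c("male", "female"), larger)
  target <- min(nBySex)
  targetAge <- mean(x$age[x$sex == smaller])

  big <- x[x$sex == larger, , drop = FALSE]
  pairAge <- tapply(big$age, big$twin_pair_id, mean)
  pairSize <- table(big$twin_pair_id)[names(pairAge)]
  ord <- order(abs(pairAge - targetAge), names(pairAge))
  keptPairs <- character()
  n <- 0L
  for (p in names(pairAge)[ord]) {
    sz <- as.integer(pairSize[[p]])
    if (n + sz > target) next
    keptPairs <- c(keptPairs, p)
    n <- n + sz
    if (n == target) break
  }
  if (n < target)
    warning("could not reach the smaller sex's count exactly without ",
            "splitting a pair; retained ", n, " of ", target)
  keep <- x$sex == smaller | (x$sex == larger & x$twin_pair_id %in% keptPairs)
  x$sample_id[keep]
})

#' @rdname balanceSexes
#' @export
setMethod("balanceSexes", "MethylationCohort", function(x, ...) {
  ids <- balanceSexes(sampleInfo(x))
  x[, colnames(x) %in% ids]
})
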