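## Per-CpG sex-difference testing under the random-intercept-per-pair model
##   M_ij = b0 + b1 * sex(pair j) + u_j + e_ij,  u_j ~ N(0, su2), e ~ N(0, se2).
##
## Because sex is constant within a like-sex pair, the model decomposes into
## within-pair contrasts (informing se2 only) and a between-pair regression
## of pair means on sex. With equal pair sizes this yields the exact REML
## fit in closed form: the sex test is the two-sample t-test on pair means
## (df = pairs - 2) unless the between-pair mean square falls below the
## within-pair bound, in which case the pair variance is truncated at zero
## and the residual variance pooled. Probes with per-probe missingness get
## a 1-D profiled REML over the variance ratio. The same engine is used for
## the observed fit and for every permutation replicate.

.sexdiffPrecompute <- function(M, pairId) {
  pid <- as.character(pairId)
  obs <- !is.na(M)
  S <- t(rowsum(t(ifelse(obs, M, 0)), pid))
  CNT <- t(rowsum(t(obs + 0), pid))
  PM <- S / CNT                              # NaN where a pair is all-missing
  SSQ <- t(rowsum(t(ifelse(obs, M^2, 0)), pid))
  SSWmat <- SSQ - CNT * ifelse(CNT > 0, PM, 0)^2
  SSW <- rowSums(SSWmat)
  dfW <- rowSums(pmax(CNT - 1L, 0L))
  sizes <- table(pid)[colnames(PM)]
  s <- as.integer(sizes[1])
  balanced <- all(sizes == s)
  rowComplete <- balanced & rowSums(CNT != s) == 0L
  list(M = M, pairId = pid, pairs = colnames(PM), PM = PM, CNT = CNT,
       SSW = SSW, dfW = dfW, s = s, rowComplete = rowComplete)
}

## Closed-form REML sex test for rows with complete, equal-size pairs.
.sexdiffFast <- function(pre, pairSex) {
  idxM <- which(pairSex == "male")
  idxF <- which(pairSex == "female")
  GM <- length(idxM); GF <- length(idxF); G <- GM + GF
  mM <- rowMeans(pre$PM[, idxM, drop = FALSE])
  mF <- rowMeans(pre$PM[, idxF, drop = FALSE])
  b <- mF - mM
  SSB <- rowSums((pre$PM[, idxM, drop = FALSE] - mM)^2) +
         rowSums((pre$PM[, idxF, drop = FALSE] - mF)^2)
  dfB <- G - 2L
  MSB <- SSB / dfB
  s <- pre$s
  if (s > 1L) {
    MSW <- pre$SSW / pre$dfW
    keepPair <- MSB >= MSW / s
    Vpm <- ifelse(keepPair, MSB, (pre$SSW + s * SSB) / (pre$dfW + dfB) / s)
    df <- ifelse(keepPair, dfB, pre$dfW + dfB)
  } else {
    Vpm <- MSB
    df <- rep(dfB, length(b))
  }
  se <- sqrt(Vpm * (1 / GM + 1 / GF))
  t <- b / se
  p <- 2 * stats::pt(-abs(t), df)
  data.frame(sex_effect = b, p_obs = p, se = se, df = df)
}

## 1-D profiled REML for one probe with unequal observed pair sizes.
.sexdiffREML <- function(y, pairId, pairSexTab) {
  ok <- !is.na(y)
  y <- y[ok]; g <- as.character(pairId)[ok]
  nj <- tapply(y, g, length)
  ybar <- tapply(y, g, mean)
  sexg <- pairSexTab[names(nj)]
  if (length(unique(sexg)) < 2L || length(nj) < 3L)
    return(c(effect = NA_real_, p = NA_real_))
  SSW <- sum((y - ybar[g])^2)
  N <- length(y)
  fit <- function(lam) {
    w <- nj / (1 + lam * nj)
    wM <- sum(w[sexg == "male"]); wF <- sum(w[sexg == "female"])
    mM <- sum((w * ybar)[sexg == "male"]) / wM
    mF <- sum((w * ybar)[sexg == "female"]) / wF
    SSB <- sum(w * (ybar - ifelse(sexg == "male", mM, mF))^2)
    Q <- SSW + SSB
    crit <- (N - 2) * log(Q) + sum(log(1 + lam * nj)) + log(wM) + log(wF)
    list(crit = crit, b = mF - mM, Vb = Q / (N - 2) * (1 / wM + 1 / wF))
  }
  opt <- stats::optimize(function(l) fit(l)$crit, c(0, 1e3))
  best <- if (fit(0)$crit <= opt$objective) fit(0) else fit(opt$minimum)
  df <- length(nj) - 2
  tval <- best$b / sqrt(best$Vb)
  c(effect = best$b, p = 2 * stats::pt(-abs(tval), df))
}

.sexdiffTest <- function(pre, pairSex) {
  out <- .sexdiffFast(pre, pairSex)
  out$method <- "reml_closed_form"
  bad <- !is.finite(out$p_obs) & pre$rowComplete
  if (any(bad)) {
    out$p_obs[bad] <- NA_real_
    out$method[bad] <- "degenerate"
  }
  slow <- which(!pre$rowComplete)
  if (length(slow)) {
    tab <- stats::setNames(pairSex, pre$pairs)
    for (i in slow) {
      r <- .sexdiffREML(pre$M[i, ], pre$pairId, tab)
      out$sex_effect[i] <- r["effect"]
      out$p_obs[i] <- r["p"]
      out$method[i] <- "reml_profiled"
    }
  }
  out
}

.pairSexOf <- function(cohort) {
  si <- sampleInfo(cohort)
  pairSex <- tapply(as.character(si$sex), as.character(si$twin_pair_id),
                    function(s) s[1])
  pairSex
}

#' Per-CpG mixed-model sex-difference test
#'
#' For every CpG, fits the random-intercept-per-twin-pair model of the
#' methylation M-value on sex (female minus male) by REML and reports the
#' sex coefficient with its two-sided p-value, together with the per-sex
#' mean beta values. Probes with degenerate fits (zero variance at every
#' level) are flagged and get a missing p-value.
#'
#' @param cohort a QC'd \linkS4class{MethylationCohort} with both sexes
#'   present and at least two pairs per sex.
#' @return a data.frame with one row per probe: \code{probe_id},
#'   \code{sex_effect} (M-scale, female − male), \code{p_obs},
#'   \code{fwer} (filled by \code{\link{permutationFWER}}),
#'   \code{mean_beta_male}, \code{mean_beta_female}, \code{method}.
#' @seealso \code{\link{permutationFWER}}, \code{\link{classifyPatterns}},
#'   \code{\link{sexDifferenceAnalysis}}
#' @export
fitSexDifference <- function(cohort) {
  si <- sampleInfo(cohort)
  pairSexTab <- .pairSexOf(cohort)
  if (sum(pairSexTab == "male") < 2L || sum(pairSexTab == "female") < 2L)
    stop("need at least 2 twin pairs per sex")
  M <- mValues(cohort)
  pre <- .sexdiffPrecompute(M, si$twin_pair_id)
  res <- .sexdiffTest(pre, as.character(pairSexTab[pre$pairs]))
  beta <- betaValues(cohort)
  data.frame(
    probe_id = rownames(cohort),
    sex_effect = res$sex_effect,
    p_obs = res$p_obs,
    fwer = NA_real_,
    mean_beta_male = rowMeans(beta[, si$sex == "male", drop = FALSE],
                              na.rm = TRUE),
    mean_beta_female = rowMeans(beta[, si$sex == "female", drop = FALSE],
                                na.rm = TRUE),
    method = res$method,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Twin-pair permutation family-wise error rate
#'
#' Permutes sex labels across twin pairs (preserving the observed
#' male:female pair ratio; for cohorts without twin structure the pairs are
#' singletons, so sample-level labels are shuffled), reruns the full
#' per-CpG sex-difference test for each of \code{K} replicates, and records
#' each replicate's minimum p-value. A probe's FWER is the fraction of
#' replicate minima strictly below its observed p-value,
#' \eqn{\mathrm{FWER}(c) = \sum_i I[p_{min}(i) < p_{obs}(c)] / K}.
#'
#' @param cohort the \linkS4class{MethylationCohort} the observed p-values
#'   came from.
#' @param pObs numeric vector of observed per-CpG p-values (or the
#'   data.frame from \code{\link{fitSexDifference}}).
#' @param K number of permutation replicates (default 10000).
#' @param seed integer seed; output is deterministic given it.
#' @return numeric vector of per-CpG FWER values in \eqn{[0,1]}, with the
#'   sorted replicate minima attached as attribute \code{"minima"}.
#' @export
permutationFWER <- function(cohort, pObs, K = 10000L, seed = 1L) {
  if (is.data.frame(pObs)) pObs <- pObs$p_obs
  if (K < 1L) stop("K must be >= 1")
  si <- sampleInfo(cohort)
  pairSexTab <- .pairSexOf(cohort)
  if (all(table(si$twin_pair_id) == 1L))
    message("no twin structure: permuting sample-level sex labels")
  M <- mValues(cohort)
  pre <- .sexdiffPrecompute(M, si$twin_pair_id)
  labels <- as.character(pairSexTab[pre$pairs])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  minima <- vapply(seq_len(K), function(k) {
    perm <- sample(labels)
    min(.sexdiffTest(pre, perm)$p_obs, na.rm = TRUE)
  }, numeric(1))
  fwer <- vapply(pObs, function(p)
    if (is.na(p)) NA_real_ else sum(minima < p) / K, numeric(1))
  attr(fwer, "minima") <- sort(minima)
  fwer
}

#' One-call sex-difference analysis
#'
#' Runs \code{\link{fitSexDifference}} and \code{\link{permutationFWER}}
#' and returns the results table with the FWER column filled.
#'
#' @inheritParams permutationFWER
#' @return the \code{\link{fitSexDifference}} data.frame with \code{fwer}
#'   set.
#' @export
sexDifferenceAnalysis <- function(cohort, K = 10000L, seed = 1L) {
  res <- fitSexDifference(cohort)
  res$fwer <- as.numeric(permutationFWER(cohort, res$p_obs, K = K,
                                         seed = seed))
  res
}
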