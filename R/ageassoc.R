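## Per-sex, per-CpG age-association models:
##   M = b0 + b1 age + b2..b7 cell proportions
##       + (1 | sentrix_id) + (1 | sentrix_position) [+ (1 | twin_pair_id)]
## fitted by REML with lme4. The fixed design is identical across CpGs, so
## after one full fit each remaining probe is a refit() with a new
## response. Grouping factors with a single level (or no twin structure)
## are dropped; probes whose mixed fit fails fall back to ordinary least
## squares with a flag. Age is centred before fitting; the slope is
## unaffected.

.olsAgeFit <- function(y, X) {
  ok <- !is.na(y)
  fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
  rdf <- sum(ok) - fit$rank
  s2 <- sum(fit$residuals^2) / rdf
  XtXinv <- chol2inv(chol(crossprod(X[ok, , drop = FALSE])))
  se <- sqrt(s2 * XtXinv[2L, 2L])
  c(slope = unname(fit$coefficients["age_c"]), se = se, df = rdf,
    n = sum(ok))
}

#' Per-CpG age-association mixed model for one sex
#'
#' For each CpG in the given sex's samples, regresses the methylation
#' M-value on age (centred) and the six blood cell-type proportions, with
#' random intercepts for sentrix ID, sentrix position and — when the
#' cohort has twin structure — twin pair. Reports the age slope, its
#' standard error, a two-sided p-value, and the direction of change
#' (\code{hyper} for a non-negative slope, \code{hypo} otherwise).
#' Grouping factors with a single level are dropped from the random
#' structure; a probe whose mixed fit fails falls back to ordinary least
#' squares with a flag; probes are fitted complete-case.
#'
#' Because the six cell proportions are compositional (they sum to one,
#' aliasing the intercept), granulocytes serve as the reference and the
#' other five proportions enter the fixed design; the age slope is
#' unaffected by this reparameterization.
#'
#' @param cohort a \linkS4class{MethylationCohort} with cell-type
#'   proportion columns.
#' @param sex \code{"male"} or \code{"female"}.
#' @return a data.frame: \code{probe_id}, \code{sex}, \code{slope} (M per
#'   year), \code{se}, \code{p_value}, \code{q_value} (NA until
#'   \code{\link{bhFDR}}), \code{direction}, \code{n_used}, \code{method}.
#' @seealso \code{\link{bhFDR}}, \code{\link{classifyAgeSites}}
#' @export
fitAgeModel <- function(cohort, sex = c("male", "female")) {
  sex <- match.arg(sex)
  keep <- sampleInfo(cohort)$sex == sex
  if (sum(keep) < 10L) stop("need at least 10 ", sex, " samples")
  cohort <- cohort[, keep]
  si <- sampleInfo(cohort)
  missCov <- setdiff(.CELL_TYPES, colnames(si))
  if (length(missCov))
    stop("missing covariate columns: ", paste(missCov, collapse = ", "))

  cellCovs <- setdiff(.CELL_TYPES, "Gran")   # compositional reference
  dat <- data.frame(age_c = si$age - mean(si$age),
                    si[, cellCovs, drop = FALSE],
                    sentrix_id = factor(si$sentrix_id),
                    sentrix_position = factor(si$sentrix_position),
                    twin_pair_id = factor(si$twin_pair_id))
  ranTerms <- character()
  if (nlevels(dat$sentrix_id) > 1L)
    ranTerms <- c(ranTerms, "(1 | sentrix_id)")
  if (nlevels(dat$sentrix_position) > 1L)
    ranTerms <- c(ranTerms, "(1 | sentrix_position)")
  if (any(table(dat$twin_pair_id) > 1L) && nlevels(dat$twin_pair_id) > 1L)
    ranTerms <- c(ranTerms, "(1 | twin_pair_id)")
  fixedStr <- paste("y ~ age_c +", paste(cellCovs, collapse = " + "))
  X <- stats::model.matrix(
    stats::as.formula(paste("~ age_c +", paste(cellCovs, collapse = "+"))),
    dat)
  M <- mValues(cohort)
  nC <- nrow(M)
  slope <- se <- df <- rep(NA_real_, nC)
  nUsed <- integer(nC)
  method <- rep(if (length(ranTerms)) "lmm" else "ols", nC)

  if (!length(ranTerms)) {
    for (i in seq_len(nC)) {
      f <- .olsAgeFit(M[i, ], X)
      slope[i] <- f["slope"]; se[i] <- f["se"]; df[i] <- f["df"]
      nUsed[i] <- f["n"]
    }
  } else {
    form <- stats::as.formula(paste(fixedStr, "+",
                                    paste(ranTerms, collapse = " + ")))
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    base <- NULL
    extract <- function(fit, n) {
      ## all variance components at the REML boundary: the model IS OLS
      if (max(lme4::getME(fit, "theta")) < 1e-7)
        stop("degenerate mixed fit: zero variance everywhere")
      b <- lme4::fixef(fit)["age_c"]
      v <- as.matrix(stats::vcov(fit))
      list(slope = unname(b), se = sqrt(v["age_c", "age_c"]),
           df = n - ncol(X), n = n)
    }
    for (i in seq_len(nC)) {
      y <- M[i, ]
      ok <- !is.na(y)
      res <- tryCatch({
        if (all(ok)) {
          dat$y <- y
          fit <- if (is.null(base)) {
            dat$y <- y
            base <- suppressMessages(
              lme4::lmer(form, data = dat, REML = TRUE, control = ctrl))
          } else suppressMessages(lme4::refit(base, newresp = y))
          extract(fit, length(y))
        } else {
          d2 <- dat[ok, , drop = FALSE]
          d2$y <- y[ok]
          fit <- suppressMessages(
            lme4::lmer(form, data = d2, REML = TRUE, control = ctrl))
          extract(fit, sum(ok))
        }
      }, error = function(e) NULL)
      if (is.null(res)) {
        f <- .olsAgeFit(y, X)
        slope[i] <- f["slope"]; se[i] <- f["se"]; df[i] <- f["df"]
        nUsed[i] <- f["n"]; method[i] <- "ols_fallback"
      } else {
        slope[i] <- res$slope; se[i] <- res$se; df[i] <- res$df
        nUsed[i] <- res$n
      }
    }
  }
  p <- 2 * stats::pt(-abs(slope / se), df)
  if (any(slope == 0, na.rm = TRUE))
    message(sum(slope == 0, na.rm = TRUE),
            " zero slope(s) counted as hypermethylated")
  data.frame(probe_id = rownames(cohort), sex = sex, slope = slope, se = se,
             p_value = p, q_value = NA_real_,
             direction = ifelse(slope >= 0, "hyper", "hypo"),
             n_used = nUsed, method = method,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR
#'
#' Computes BH q-values, \eqn{q_{(i)} = \min_{j \ge i} (m \, p_{(j)} / j)}
#' over the sorted p-values with the original order restored. Missing
#' p-values propagate missing q-values; the number of tests m is the
#' number of non-missing p-values.
#'
#' @param pValues numeric vector of p-values in \eqn{[0,1]} (NAs allowed).
#' @return numeric vector of q-values, same length and order.
#' @export
bhFDR <- function(pValues) {
  ok <- !is.na(pValues)
  if (any(pValues[ok] < 0 | pValues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(pValues))
  q[ok] <- stats::p.adjust(pValues[ok], method = "BH")
  q
}

#' Classify CpGs by which sexes show an age association
#'
#' Given the two sexes' age-association results (with q-values), assigns
#' each probe to \code{both}, \code{male_only}, \code{female_only} or
#' \code{neither} according to which sexes pass \code{q < alpha}, keeping
#' each sex's direction of change.
#'
#' @param maleResults,femaleResults data.frames from
#'   \code{\link{fitAgeModel}} with \code{q_value} filled (same probe
#'   universe).
#' @param alpha FDR significance cut-off (default 0.05, strict \code{<}).
#' @return a data.frame: \code{probe_id}, \code{class},
#'   \code{direction_male}, \code{direction_female}, \code{q_male},
#'   \code{q_female}.
#' @export
classifyAgeSites <- function(maleResults, femaleResults, alpha = 0.05) {
  if (!setequal(maleResults$probe_id, femaleResults$probe_id) ||
      nrow(maleResults) != nrow(femaleResults))
    stop("probe ids mismatch between the two sexes' results")
  f <- femaleResults[match(maleResults$probe_id, femaleResults$probe_id), ]
  sigM <- !is.na(maleResults$q_value) & maleResults$q_value < alpha
  sigF <- !is.na(f$q_value) & f$q_value < alpha
  cls <- ifelse(sigM & sigF, "both",
         ifelse(sigM, "male_only",
         ifelse(sigF, "female_only", "neither")))
  data.frame(probe_id = maleResults$probe_id, class = cls,
             direction_male = maleResults$direction,
             direction_female = f$direction,
             q_male = maleResults$q_value, q_female = f$q_value,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Percentage of hypermethylated sites
#'
#' Among a set of age-associated CpGs, the percentage whose methylation
#' increases with age: \eqn{100 \cdot \#\{slope > 0\} / (\#\{slope > 0\} +
#' \#\{slope < 0\})}. Exactly-zero slopes (measure-zero in practice) are
#' counted as hypermethylated with a message. An empty subset yields
#' \code{NA} with a warning.
#'
#' @param results a (significant) subset of a \code{\link{fitAgeModel}}
#'   data.frame.
#' @return a percentage, or \code{NA} for an empty subset.
#' @examples
#' percentHypermethylated(data.frame(slope = c(rep(1, 149), rep(-1, 10))))
#' @export
percentHypermethylated <- function(results) {
  slope <- results$slope[!is.na(results$slope)]
  if (!length(slope)) {
    warning("empty subset: percentage undefined")
    return(NA_real_)
  }
  nzero <- sum(slope == 0)
  if (nzero > 0)
    message(nzero, " zero slope(s) counted as hypermethylated")
  100 * sum(slope >= 0) / length(slope)
}

#' Age-association enrichment across XCI patterns
#'
#' Cross-tabulates age-association significance (\code{q <= alpha};
#' boundary inclusive) against the five methylation patterns (ONE_COHORT
#' merged into REST) and tests the 2 x 5 table with a Pearson chi-squared
#' (df = 4), reporting each pattern's percentage of significant CpGs.
#'
#' @param calls data.frame from \code{\link{classifyPatterns}}.
#' @param results data.frame from \code{\link{fitAgeModel}} with
#'   \code{q_value} filled, same probe universe.
#' @param alpha FDR cut-off (default 0.05, inclusive).
#' @return a list: \code{table} (2 x 5 counts), \code{percent_significant}
#'   (per pattern), \code{statistic}, \code{df}, \code{p.value}.
#' @export
patternAgeEnrichment <- function(calls, results, alpha = 0.05) {
  idx <- match(results$probe_id, calls$probe_id)
  if (anyNA(idx)) stop("pattern calls missing for some probes")
  pat <- calls$pattern[idx]
  pat[pat == "ONE_COHORT"] <- "REST"
  sig <- factor(ifelse(results$q_value <= alpha, "significant",
                       "insignificant"),
                levels = c("insignificant", "significant"))
  tab <- table(sig, factor(pat, levels = c("A", "B", "C", "D", "REST")))
  if (any(colSums(tab) == 0))
    warning("empty pattern column; df left unadjusted")
  cs <- .chisqTable(tab)
  pct <- 100 * tab["significant", ] / colSums(tab)
  list(table = tab, percent_significant = pct, statistic = cs$statistic,
       df = cs$df, p.value = cs$p.value)
}
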