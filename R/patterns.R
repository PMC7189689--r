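#' Two-cohort XCI methylation pattern classification
#'
#' Assigns each CpG the first matching pattern, in this order:
#' \describe{
#'   \item{A}{sex-differentially methylated (FWER < \code{alphaFwer}) in
#'     both cohorts with females the more methylated in both — sites
#'     inferred subject to XCI;}
#'   \item{D}{significant in both cohorts with males the more methylated
#'     in both;}
#'   \item{ONE_COHORT}{significant in exactly one cohort;}
#'   \item{B}{not significant in either cohort and all four per-sex,
#'     per-cohort mean beta values below \code{lowCut} — sites escaping
#'     XCI;}
#'   \item{C}{not significant in either cohort and all four means above
#'     \code{highCut} — constitutively highly methylated sites;}
#'   \item{REST}{everything else. Probes significant in both cohorts with
#'     discordant directions land here (counted in a message).}
#' }
#'
#' @param resultsC1,resultsC2 data.frames from
#'   \code{\link{sexDifferenceAnalysis}} (or \code{\link{fitSexDifference}}
#'   plus \code{\link{permutationFWER}}) for the two cohorts; they must
#'   cover the same probe ids.
#' @param alphaFwer FWER significance cut-off (default 0.05).
#' @param lowCut,highCut beta cut-offs for patterns B and C (defaults 0.25
#'   and 0.75).
#' @return a data.frame with one row per probe: \code{probe_id},
#'   \code{pattern}, and per-cohort \code{fwer}, effect \code{sign} and
#'   per-sex mean betas.
#' @export
classifyPatterns <- function(resultsC1, resultsC2, alphaFwer = 0.05,
                             lowCut = 0.25, highCut = 0.75) {
  if (!setequal(resultsC1$probe_id, resultsC2$probe_id) ||
      nrow(resultsC1) != nrow(resultsC2))
    stop("probe ids mismatch between the two cohorts' results")
  r2 <- resultsC2[match(resultsC1$probe_id, resultsC2$probe_id), ]
  r1 <- resultsC1
  sig1 <- r1$fwer < alphaFwer
  sig2 <- r2$fwer < alphaFwer
  up1 <- r1$sex_effect > 0
  up2 <- r2$sex_effect > 0
  means <- cbind(r1$mean_beta_male, r1$mean_beta_female,
                 r2$mean_beta_male, r2$mean_beta_female)
  pattern <- rep("REST", nrow(r1))
  isA <- sig1 & sig2 & up1 & up2
  isD <- sig1 & sig2 & !up1 & !up2
  isOne <- xor(sig1, sig2)
  nonsig <- !sig1 & !sig2
  isB <- nonsig & rowSums(means < lowCut) == 4L
  isC <- nonsig & rowSums(means > highCut) == 4L
  pattern[isC] <- "C"
  pattern[isB] <- "B"
  pattern[isOne] <- "ONE_COHORT"
  pattern[isD] <- "D"
  pattern[isA] <- "A"
  discordant <- sum(sig1 & sig2 & (up1 != up2), na.rm = TRUE)
  if (discordant > 0)
    message(discordant,
            " probe(s) significant in both cohorts with discordant",
            " directions assigned to REST")
  data.frame(probe_id = r1$probe_id, pattern = pattern,
             fwer_c1 = r1$fwer, fwer_c2 = r2$fwer,
             sign_c1 = sign(r1$sex_effect), sign_c2 = sign(r2$sex_effect),
             mean_beta_male_c1 = r1$mean_beta_male,
             mean_beta_female_c1 = r1$mean_beta_female,
             mean_beta_male_c2 = r2$mean_beta_male,
             mean_beta_female_c2 = r2$mean_beta_female,
             row.names = NULL, stringsAsFactors = FALSE)
}

## Pearson chi-squared computed from the textbook formula so that
## zero-margin tables can still be evaluated with the nominal df (cells
## with zero expectation are skipped with a warning).
.chisqTable <- function(tab) {
  tab <- as.matrix(tab)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    warning("zero row/column in contingency table; df left unadjusted")
  ok <- E > 0
  stat <- sum((tab[ok] - E[ok])^2 / E[ok])
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Gene-region by methylation-pattern contingency
#'
#' Cross-tabulates pattern calls against the seven gene-region categories
#' (1stExon, 3'UTR, 5'UTR, Body, Intergenic, TSS1500, TSS200) and tests
#' independence with a Pearson chi-squared on the 7 x 5 table
#' (df = 24). ONE_COHORT calls are merged into REST so the table has
#' exactly the five pattern columns A, B, C, D, REST.
#'
#' @param calls data.frame from \code{\link{classifyPatterns}}.
#' @param probes probe annotation data.frame (\code{probe_id},
#'   \code{gene_region}); every called probe must be annotated.
#' @return a list with \code{table} (counts with margins),
#'   \code{statistic}, \code{df} and \code{p.value}.
#' @export
regionContingency <- function(calls, probes) {
  idx <- match(calls$probe_id, probes$probe_id)
  if (anyNA(idx))
    stop("unannotated probes: ",
         paste(utils::head(calls$probe_id[is.na(idx)]), collapse = ", "))
  pat <- calls$pattern
  pat[pat == "ONE_COHORT"] <- "REST"
  tab <- table(factor(probes$gene_region[idx], levels = .GENE_REGIONS),
               factor(pat, levels = c("A", "B", "C", "D", "REST")))
  cs <- .chisqTable(tab)
  list(table = stats::addmargins(tab), statistic = cs$statistic,
       df = cs$df, p.value = cs$p.value)
}
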