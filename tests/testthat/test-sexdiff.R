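test_that("the mixed-model sex test agrees with the pair-means oracle", {
  cfg <- SimulationConfig(nPairsPerSex = 50,
                          nCpgsPerPattern = c(A = 10, REST = 30),
                          ageSlope = zeroSlopes(), detectionFailRate = 0,
                          seed = 23)
  co <- generateCohort(cfg, "pm")$cohort
  res <- fitSexDifference(co)
  M <- mValues(co)
  si <- sampleInfo(co)
  pair <- si$twin_pair_id
  pairSex <- tapply(si$sex, pair, `[`, 1)
  for (i in seq_len(nrow(M))) {
    pm <- tapply(M[i, ], pair, mean)
    tt <- t.test(pm[pairSex[names(pm)] == "female"],
                 pm[pairSex[names(pm)] == "male"], var.equal = TRUE)
    expect_lt(abs(res$p_obs[i] - tt$p.value) / tt$p.value, 0.10)
    expect_equal(res$sex_effect[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-8)
  }
})

test_that("the engine reproduces lme4 REML fits, including under missingness", {
  skip_if_not_installed("lmerTest")
  cfg <- SimulationConfig(nPairsPerSex = 20,
                          nCpgsPerPattern = c(A = 3, D = 3, REST = 3),
                          detectionFailRate = 0, seed = 31)
  co <- generateCohort(cfg, "xv")$cohort
  M <- mValues(co)
  M[1, c(2, 7)] <- NA            # force the profiled-REML path for probe 1
  SummarizedExperiment::assay(co, "beta") <- mToBeta(M)
  res <- fitSexDifference(co)
  expect_equal(res$method[1], "reml_profiled")
  si <- sampleInfo(co)
  for (i in seq_len(nrow(M))) {
    d <- data.frame(y = M[i, ], sex = factor(si$sex, c("male", "female")),
                    pair = si$twin_pair_id)
    f <- suppressMessages(lmerTest::lmer(y ~ sex + (1 | pair), data = d))
    cs <- coef(summary(f))
    expect_equal(res$sex_effect[i], unname(cs[2, 1]), tolerance = 1e-6)
    expect_equal(res$p_obs[i], unname(cs[2, 5]), tolerance = 0.02)
  }
})

test_that("the sex test holds its size on null CpGs", {
  cfg <- SimulationConfig(nPairsPerSex = 50, nCpgsPerPattern = c(B = 200),
                          ageSlope = zeroSlopes(), detectionFailRate = 0,
                          seed = 41)
  co <- generateCohort(cfg, "nullsex")$cohort
  res <- fitSexDifference(co)
  rate <- mean(res$p_obs < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.08)
})

test_that("a known sex effect of 3 M units is recovered", {
  ## female base M 1 (beta 2/3), male base M -2 (beta 0.2)
  bb <- .defaultBaseBeta()
  bb["A", ] <- c(0.2, 2 / 3)
  cfg <- SimulationConfig(nPairsPerSex = 50, nCpgsPerPattern = c(A = 60),
                          patternBaseBeta = bb, ageSlope = zeroSlopes(),
                          residualSd = 0.5, detectionFailRate = 0, seed = 47)
  co <- generateCohort(cfg, "eff")$cohort
  res <- fitSexDifference(co)
  expect_lt(abs(mean(res$sex_effect) - 3), 0.1)
})

test_that("FWER is the fraction of replicate minima below the observed p", {
  co <- generateCohort(SimulationConfig(nPairsPerSex = 10,
    nCpgsPerPattern = c(A = 5, REST = 15), detectionFailRate = 0,
    seed = 53), "fw")$cohort
  res <- fitSexDifference(co)
  fw <- permutationFWER(co, res$p_obs, K = 50, seed = 9)
  minima <- attr(fw, "minima")
  expect_length(minima, 50L)
  expect_equal(as.numeric(fw),
               sapply(res$p_obs, function(p) sum(minima < p) / 50))
  ## boundaries: a p below all minima -> 0; above all -> 1
  probe <- permutationFWER(co, c(0, 1), K = 50, seed = 9)
  expect_equal(as.numeric(probe), c(0, 1))
  ## deterministic given the seed, and monotone in p_obs
  fw2 <- permutationFWER(co, res$p_obs, K = 50, seed = 9)
  expect_identical(as.numeric(fw), as.numeric(fw2))
  o <- order(res$p_obs)
  expect_true(all(diff(as.numeric(fw)[o]) >= 0))
  expect_error(permutationFWER(co, res$p_obs, K = 0), "K must be")
})

test_that("the permutation FWER controls family-wise false positives under the null", {
  rates <- sapply(1:10, function(s) {
    co <- generateCohort(nullConfig(nPairs = 30, nCpgs = 100,
                                    seed = 60 + s), "fwnull")$cohort
    res <- sexDifferenceAnalysis(co, K = 200, seed = s)
    mean(res$fwer < 0.05)
  })
  expect_lte(mean(rates), 0.05)
})

test_that("pattern rules are applied in order on constructed cases", {
  mk <- function(fwer, eff, bm, bf) {
    data.frame(probe_id = paste0("cg", seq_along(fwer)), sex_effect = eff,
               p_obs = 0.5, fwer = fwer, mean_beta_male = bm,
               mean_beta_female = bf, stringsAsFactors = FALSE)
  }
  r1 <- mk(c(0.001, 0.5, 0.5, 0.01, 0.02, 0.5),
           c(1.2, -0.1, 0.1, -1.0, 0.8, 0.2),
           c(0.50, 0.08, 0.91, 0.70, 0.50, 0.40),
           c(0.60, 0.11, 0.93, 0.40, 0.60, 0.45))
  r2 <- mk(c(0.004, 0.7, 0.6, 0.04, 0.70, 0.5),
           c(0.9, -0.2, 0.1, -0.8, 0.7, 0.1),
           c(0.55, 0.06, 0.88, 0.72, 0.52, 0.42),
           c(0.65, 0.09, 0.90, 0.42, 0.62, 0.47))
  calls <- classifyPatterns(r1, r2)
  expect_equal(calls$pattern, c("A", "B", "C", "D", "ONE_COHORT", "REST"))
  ## discordant significant directions land in REST, with a message
  rd1 <- mk(0.01, 1.0, 0.5, 0.6)
  rd2 <- mk(0.01, -1.0, 0.6, 0.5)
  expect_message(cd <- classifyPatterns(rd1, rd2), "discordant")
  expect_equal(cd$pattern, "REST")
  ## probe mismatch errors
  r2bad <- r2
  r2bad$probe_id[1] <- "cgX"
  expect_error(classifyPatterns(r1, r2bad), "mismatch")
})

test_that("patterns partition the probe set; alpha 0 leaves only B/C/REST", {
  study <- generateStudy(defaultStudyConfigs(seed = 6, scale = 0.1))
  res1 <- sexDifferenceAnalysis(study$cohorts$cohort1, K = 60, seed = 1)
  res2 <- sexDifferenceAnalysis(study$cohorts$cohort2, K = 60, seed = 2)
  calls <- classifyPatterns(res1, res2)
  expect_equal(nrow(calls), nrow(study$cohorts$cohort1))
  expect_true(all(calls$pattern %in%
                    c("A", "B", "C", "D", "ONE_COHORT", "REST")))
  calls0 <- classifyPatterns(res1, res2, alphaFwer = 0)
  expect_true(all(calls0$pattern %in% c("B", "C", "REST")))
})

test_that("the region contingency matches a brute-force chi-squared", {
  set.seed(71)
  for (r in 1:5) {
    tab <- matrix(rpois(35, 40) + 1, 7, 5)
    probes <- data.frame(
      probe_id = sprintf("cg%04d", seq_len(sum(tab))),
      gene_region = rep(rep(c("1stExon", "3'UTR", "5'UTR", "Body",
                              "Intergenic", "TSS1500", "TSS200"),
                            rowSums(tab)), 1),
      stringsAsFactors = FALSE)
    pat <- unlist(lapply(seq_len(7), function(i)
      rep(c("A", "B", "C", "D", "REST"), tab[i, ])))
    calls <- data.frame(probe_id = probes$probe_id, pattern = pat,
                        stringsAsFactors = FALSE)
    rc <- regionContingency(calls, probes)
    expect_equal(rc$statistic, bruteForceChisq(tab), tolerance = 1e-10)
    expect_equal(rc$df, 24L)
    ## transpose symmetry of the statistic
    expect_equal(bruteForceChisq(t(tab)), bruteForceChisq(tab))
  }
  ## proportional rows mean independence: statistic 0
  tabInd <- outer(c(10, 20, 30, 10, 5, 15, 10), c(1, 2, 3, 4, 5))
  probesI <- data.frame(
    probe_id = sprintf("p%04d", seq_len(sum(tabInd))),
    gene_region = rep(c("1stExon", "3'UTR", "5'UTR", "Body", "Intergenic",
                        "TSS1500", "TSS200"), rowSums(tabInd)),
    stringsAsFactors = FALSE)
  patI <- unlist(lapply(seq_len(7), function(i)
    rep(c("A", "B", "C", "D", "REST"), tabInd[i, ])))
  rcI <- regionContingency(data.frame(probe_id = probesI$probe_id,
                                      pattern = patI), probesI)
  expect_equal(rcI$statistic, 0, tolerance = 1e-10)
})
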