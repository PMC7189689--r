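test_that("with zero simulated random-effect variances the fit collapses to OLS", {
  cfg <- nullConfig(nPairs = 25, nCpgs = 60, seed = 81,
                    pairInterceptSd = 0, batchSd = 0, positionSd = 0,
                    cellEffectSd = 0)
  co <- generateCohort(cfg, "flatre")$cohort
  res <- fitAgeModel(co, "male")
  sub <- co[, sampleInfo(co)$sex == "male"]
  si <- sampleInfo(sub)
  M <- mValues(sub)
  cells <- setdiff(.cells, "Gran")
  d <- data.frame(age_c = si$age - mean(si$age), si[, cells])
  ols <- t(sapply(seq_len(nrow(M)), function(i) {
    s <- summary(lm(M[i, ] ~ ., data = d))$coefficients["age_c", ]
    c(slope = s[1], p = s[4])
  }))
  ## probes flagged as degenerate match OLS to machine precision
  deg <- res$method == "ols_fallback"
  expect_gt(sum(deg), 0)
  expect_equal(res$slope[deg], unname(ols[deg, 1]), tolerance = 1e-10)
  expect_equal(res$p_value[deg], unname(ols[deg, 2]), tolerance = 1e-10)
  ## and all probes converge on the OLS solution
  expect_equal(res$slope, unname(ols[, 1]), tolerance = 1e-2)
  expect_lt(median(abs(res$p_value - ols[, 2])), 0.05)
  expect_gt(cor(res$p_value, ols[, 2]), 0.9)
})

test_that("known age slopes are recovered without material bias at n = 100", {
  ## 25 pairs/sex -> 100 samples; constitutively-high sites drift +0.02 M/yr
  cfg <- SimulationConfig(nPairsPerSex = 25, nCpgsPerPattern = c(C = 200),
                          detectionFailRate = 0, seed = 2)
  co <- generateCohort(cfg, "recov")$cohort
  resM <- fitAgeModel(co, "male")
  bias <- mean(resM$slope) - 0.02
  expect_lt(abs(bias), 0.005)             # < 25% of the true slope
})

test_that("age-model p-values hold their size on null CpGs", {
  ps <- unlist(lapply(1:5, function(s) {
    co <- generateCohort(nullConfig(nPairs = 25, nCpgs = 100,
                                    seed = 200 + s), "t1")$cohort
    fitAgeModel(co, "female")$p_value
  }))
  rate <- mean(ps < 0.05)                 # 500 null CpGs
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("null age-association p-values are uniform across seeds", {
  ksp <- sapply(1:10, function(s) {
    co <- generateCohort(nullConfig(nPairs = 20, nCpgs = 60,
                                    seed = 300 + s), "ks")$cohort
    suppressWarnings(ks.test(fitAgeModel(co, "male")$p_value, "punif")$p.value)
  })
  expect_gte(sum(ksp > 0.01), 9L)
})

test_that("missing covariates and undersized cohorts are errors", {
  co <- generateCohort(nullConfig(nPairs = 12, nCpgs = 5, seed = 7), "e")$cohort
  cd <- SummarizedExperiment::colData(co)
  cd$CD8T <- NULL
  SummarizedExperiment::colData(co) <- cd
  expect_error(fitAgeModel(co, "male"), "CD8T")
  co2 <- generateCohort(nullConfig(nPairs = 12, nCpgs = 5, seed = 7),
                        "e2")$cohort
  expect_error(fitAgeModel(co2[, 1:8], "male"), "at least 10")
})

test_that("BH q-values follow the step-up definition", {
  expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFDR(rep(0.2, 7)), rep(0.2, 7))
  set.seed(91)
  for (r in 1:20) {
    p <- runif(sample(5:200, 1))^sample(1:3, 1)
    expect_equal(bhFDR(p), bruteForceBH(p), tolerance = 1e-12)
  }
  ## NA propagation and monotonicity
  p <- c(0.01, NA, 0.5, 0.002)
  q <- bhFDR(p)
  expect_true(is.na(q[2]))
  expect_equal(q[-2], bruteForceBH(p[-2]))
  ps <- sort(runif(50))
  expect_true(all(diff(bhFDR(ps)) >= 0))
  expect_error(bhFDR(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("sex-specific significance classes follow q-value set algebra", {
  mk <- function(q, dir) data.frame(
    probe_id = paste0("cg", seq_along(q)), slope = ifelse(dir == "hyper", 1, -1),
    q_value = q, direction = dir, stringsAsFactors = FALSE)
  male <- mk(c(0.01, 0.01, 0.20, 0.30), c("hyper", "hyper", "hypo", "hyper"))
  female <- mk(c(0.20, 0.04, 0.01, 0.30), c("hyper", "hyper", "hypo", "hypo"))
  cls <- classifyAgeSites(male, female)
  expect_equal(cls$class, c("male_only", "both", "female_only", "neither"))
  expect_equal(cls$direction_male[2], "hyper")
  expect_equal(cls$direction_female[2], "hyper")
  ## both <=> membership in both sexes' significant sets
  sigM <- male$probe_id[male$q_value < 0.05]
  sigF <- female$probe_id[female$q_value < 0.05]
  expect_setequal(cls$probe_id[cls$class == "both"], intersect(sigM, sigF))
  expect_error(classifyAgeSites(male, female[1:3, ]), "mismatch")
})

test_that("truly sex-specific sites are classified to the right class", {
  slopes <- zeroSlopes()
  slopes["B", ] <- c(-0.05, 0)        # male-only signal
  slopes["C", ] <- c(0, 0.05)         # female-only signal
  slopes["D", ] <- c(0.05, 0.05)      # shared signal
  cfg <- SimulationConfig(nPairsPerSex = 50,
                          nCpgsPerPattern = c(B = 40, C = 40, D = 40,
                                              REST = 60),
                          ageSlope = slopes, detectionFailRate = 0, seed = 19)
  sim <- generateCohort(cfg, "cls")
  co <- sim$cohort
  resM <- fitAgeModel(co, "male");  resM$q_value <- bhFDR(resM$p_value)
  resF <- fitAgeModel(co, "female"); resF$q_value <- bhFDR(resF$p_value)
  cls <- classifyAgeSites(resM, resF)
  truth <- sim$truth$probes$pattern
  expect_gt(mean(cls$class[truth == "B"] == "male_only"), 0.9)
  expect_gt(mean(cls$class[truth == "C"] == "female_only"), 0.9)
  expect_gt(mean(cls$class[truth == "D"] == "both"), 0.9)
})

test_that("hypermethylation percentages and edge cases are exact", {
  expect_equal(round(percentHypermethylated(
    data.frame(slope = c(rep(1, 149), rep(-1, 10)))), 2), 93.71)
  expect_equal(round(percentHypermethylated(
    data.frame(slope = c(rep(1, 466), rep(-1, 886)))), 2), 34.47)
  expect_equal(percentHypermethylated(data.frame(slope = rep(2, 5))), 100)
  expect_message(z <- percentHypermethylated(data.frame(slope = c(0, 1, -1))),
                 "zero slope")
  expect_equal(z, 100 * 2 / 3)
  expect_warning(e <- percentHypermethylated(data.frame(slope = numeric())),
                 "empty")
  expect_true(is.na(e))
})

test_that("pattern enrichment gives a zero statistic under equal rates", {
  calls <- data.frame(probe_id = sprintf("cg%03d", 1:100),
                      pattern = rep(c("A", "B", "C", "D", "REST"), each = 20),
                      stringsAsFactors = FALSE)
  q <- rep(c(0.01, 0.5), 50)            # 50% significant in every pattern
  res <- data.frame(probe_id = calls$probe_id, q_value = q,
                    stringsAsFactors = FALSE)
  enr <- patternAgeEnrichment(calls, res)
  expect_equal(enr$statistic, 0, tolerance = 1e-12)
  expect_equal(enr$df, 4L)
  expect_equal(unname(enr$percent_significant), rep(50, 5))
})
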