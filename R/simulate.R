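## Twin-cohort simulator. The generating model is the exact inverse of the
## fitted analysis models: M-values are built additively on the logit scale
## (baseline by pattern and sex, age slope, twin-pair / sentrix-ID /
## sentrix-position random intercepts, cell-composition term, Gaussian
## residual) and mapped to beta with the inverse logit.

.defaultBaseBeta <- function() {
  m <- rbind(A = c(0.05, 0.45), B = c(0.10, 0.10), C = c(0.85, 0.85),
             D = c(0.65, 0.35), ONE_COHORT = c(0.35, 0.55),
             REST = c(0.50, 0.50))
  colnames(m) <- c("male", "female")
  m
}

.defaultAgeSlope <- function() {
  ## escaping-XCI sites drift down with age, constitutively high sites up
  m <- rbind(A = c(0, 0), B = c(-0.02, -0.02), C = c(0.02, 0.02),
             D = c(0, 0), ONE_COHORT = c(0, 0), REST = c(0, 0))
  colnames(m) <- c("male", "female")
  m
}

#' Construct a simulation configuration
#'
#' All arguments have defaults describing a middle-aged Danish-twin-like
#' cohort; see \linkS4class{SimulationConfig} for the meaning of each
#' parameter and \code{\link{defaultStudyConfigs}} for the three-cohort
#' study design.
#'
#' @param nPairsPerSex twin pairs per sex (each complete pair contributes
#'   two samples, so a cohort has \code{4 * nPairsPerSex} samples).
#' @param mzFraction,ageRange,nCpgsPerPattern,patternBaseBeta,ageSlope
#'   see \linkS4class{SimulationConfig}.
#' @param pairInterceptSd,batchCount,batchSd,positionSd,residualSd
#'   see \linkS4class{SimulationConfig}; \code{positionSd} defaults to
#'   \code{batchSd / 2}.
#' @param cellDirichletAlpha,cellEffectSd,detectionFailRate,singletonPairs
#'   see \linkS4class{SimulationConfig}.
#' @param oneCohortActive,seed see \linkS4class{SimulationConfig}.
#' @return a validated \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(nPairsPerSex = 113L,
                             mzFraction = 0.95,
                             ageRange = c(56, 79),
                             nCpgsPerPattern = c(A = 215L, B = 32L, C = 147L,
                                                 D = 8L, REST = 103L),
                             patternBaseBeta = .defaultBaseBeta(),
                             ageSlope = .defaultAgeSlope(),
                             pairInterceptSd = 0.3,
                             batchCount = 8L,
                             batchSd = 0.15,
                             positionSd = batchSd / 2,
                             residualSd = 0.4,
                             cellDirichletAlpha = c(CD8T = 4, CD4T = 7,
                                                    NK = 2.5, Bcell = 2.5,
                                                    Mono = 3.5, Gran = 30.5),
                             cellEffectSd = 0.5,
                             detectionFailRate = 0.002,
                             singletonPairs = FALSE,
                             oneCohortActive = TRUE,
                             seed = 1L) {
  if (length(nPairsPerSex) != 1L || nPairsPerSex <= 0)
    stop("configuration error: nPairsPerSex must be a positive count")
  if (sum(nCpgsPerPattern) <= 0)
    stop("configuration error: total CpG count must be positive")
  new("SimulationConfig",
      nPairsPerSex = as.integer(nPairsPerSex), mzFraction = mzFraction,
      ageRange = as.numeric(ageRange),
      nCpgsPerPattern = stats::setNames(as.integer(nCpgsPerPattern),
                                        names(nCpgsPerPattern)),
      patternBaseBeta = patternBaseBeta, ageSlope = ageSlope,
      pairInterceptSd = pairInterceptSd, batchCount = as.integer(batchCount),
      batchSd = batchSd, positionSd = positionSd, residualSd = residualSd,
      cellDirichletAlpha = cellDirichletAlpha, cellEffectSd = cellEffectSd,
      detectionFailRate = detectionFailRate,
      singletonPairs = singletonPairs, oneCohortActive = oneCohortActive,
      seed = as.integer(seed))
}

#' Default three-cohort study configurations
#'
#' Returns configurations for two discovery twin cohorts and one
#' validation cohort of unrelated individuals, sharing one CpG universe:
#' cohort 1 with 113 pairs per sex aged 56-79 (the larger, younger twin
#' cohort), cohort 2 with 36 pairs per sex aged 74-88 (the smaller, older
#' one), and a validation cohort of 190 singletons per sex aged 78-91.
#' Pattern CpG counts default to one twentieth of the published
#' X-chromosome pattern sizes.
#'
#' @param seed integer root seed shared by the three configurations.
#' @param scale optional factor scaling both sample and CpG counts down
#'   for quick examples (default 1 = the full design).
#' @param ... further arguments passed to every \code{\link{SimulationConfig}}
#'   call (e.g. \code{ageSlope}).
#' @return a named list of three \linkS4class{SimulationConfig} objects
#'   (\code{cohort1}, \code{cohort2}, \code{validation}).
#' @export
defaultStudyConfigs <- function(seed = 1L, scale = 1, ...) {
  ncp <- c(A = 215L, B = 32L, C = 147L, D = 8L, REST = 103L)
  ncp <- stats::setNames(as.integer(pmax(2, round(ncp * scale))), names(ncp))
  np <- function(n) max(3L, as.integer(round(n * scale)))
  list(
    cohort1 = SimulationConfig(nPairsPerSex = np(113), ageRange = c(56, 79),
                               nCpgsPerPattern = ncp, seed = seed, ...),
    cohort2 = SimulationConfig(nPairsPerSex = np(36), ageRange = c(74, 88),
                               nCpgsPerPattern = ncp, seed = seed, ...),
    validation = SimulationConfig(nPairsPerSex = np(190),
                                  ageRange = c(78, 91),
                                  nCpgsPerPattern = ncp,
                                  singletonPairs = TRUE, seed = seed, ...))
}

## Deterministic sub-seed: one root integer, split per purpose/cohort.
.subSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

## Probe universe shared across cohorts of one study: ids, annotation,
## pattern assignment and per-CpG cell-composition coefficients.
.makeProbeTemplate <- function(config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.subSeed(config@seed, "probe-universe"))
  ncp <- config@nCpgsPerPattern[config@nCpgsPerPattern > 0L]
  pattern <- rep(names(ncp), ncp)
  n <- length(pattern)
  regionFreq <- c(790, 399, 1389, 2103, 1504, 2062, 1849) / 10096
  probes <- data.frame(
    probe_id = sprintf("cg%07d", seq_len(n)),
    chromosome = "X",
    position = sort(sample.int(155e6, n)),
    gene_region = sample(.GENE_REGIONS, n, TRUE, prob = regionFreq),
    is_cross_reactive = FALSE, is_polymorphic = FALSE,
    stringsAsFactors = FALSE)
  cellCoef <- matrix(stats::rnorm(n * 6, 0, config@cellEffectSd), n, 6,
                     dimnames = list(probes$probe_id, .CELL_TYPES))
  list(probes = probes, pattern = pattern, cellCoef = cellCoef,
       key = ncp)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a synthetic twin cohort with ground truth
#'
#' Simulates like-sex twin pairs (pair-level sex and age), draws blood
#' cell compositions from a Dirichlet, builds M-values additively from the
#' pattern-and-sex baseline, the per-pattern age slope applied to
#' age centred at the cohort mean, twin-pair, sentrix-ID and
#' sentrix-position random intercepts, a per-CpG cell-composition term and
#' Gaussian residual noise, and returns beta values via the inverse logit
#' together with a missing-completely-at-random detection-p matrix.
#' Identical configuration and label give bit-identical output.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param cohortLabel label for the cohort (also enters the sub-seed, so
#'   different labels give independent cohorts from one root seed).
#' @param .template internal: shared probe universe from
#'   \code{\link{generateStudy}}.
#' @return a list with components \code{cohort} (a
#'   \linkS4class{MethylationCohort}) and \code{truth} (list of two
#'   data.frames: \code{probes} with the true pattern, per-sex age slope
#'   and M-scale sex effect per CpG; \code{samples} with each sample's
#'   pair intercept and batch).
#' @examples
#' sim <- generateCohort(SimulationConfig(nPairsPerSex = 10,
#'          nCpgsPerPattern = c(A = 50, B = 50, C = 50, D = 50, REST = 50),
#'          seed = 7), "demo")
#' dim(sim$cohort)  # 250 CpGs x 40 samples
#' @export
generateCohort <- function(config, cohortLabel = "cohort", .template = NULL) {
  validObject(config)
  tpl <- if (is.null(.template)) .makeProbeTemplate(config) else .template
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.subSeed(config@seed, paste0("cohort:", cohortLabel)))

  perPair <- if (config@singletonPairs) 1L else 2L
  nPairs <- 2L * config@nPairsPerSex
  pairSex <- rep(c("male", "female"), each = config@nPairsPerSex)
  pairId <- sprintf("%s_%s_p%03d", cohortLabel,
                    ifelse(pairSex == "male", "m", "f"),
                    rep(seq_len(config@nPairsPerSex), 2L))
  pairAge <- stats::runif(nPairs, config@ageRange[1], config@ageRange[2])
  pairZyg <- if (config@singletonPairs) rep(NA_character_, nPairs) else
    sample(c("MZ", "DZ"), nPairs, TRUE,
           prob = c(config@mzFraction, 1 - config@mzFraction))

  sIdx <- rep(seq_len(nPairs), each = perPair)
  nS <- length(sIdx)
  sampleId <- paste0(pairId[sIdx], "_", rep(seq_len(perPair), nPairs))
  sex <- pairSex[sIdx]
  age <- pairAge[sIdx]

  batchIdx <- sample.int(config@batchCount, nS, TRUE)
  sentrix <- sprintf("chip%02d", batchIdx)
  posLevels <- sprintf("R%02dC%02d", rep(1:6, 2), rep(1:2, each = 6))
  posIdx <- sample.int(12L, nS, TRUE)
  position <- posLevels[posIdx]

  props <- .rdirichlet(nS, config@cellDirichletAlpha)
  expProps <- config@cellDirichletAlpha / sum(config@cellDirichletAlpha)
  propsC <- sweep(props, 2, expProps)

  ## pattern-by-sex baselines on the M scale; ONE_COHORT sites carry their
  ## sex effect only where the config activates it
  baseBeta <- config@patternBaseBeta
  if (!config@oneCohortActive && "ONE_COHORT" %in% rownames(baseBeta))
    baseBeta["ONE_COHORT", "female"] <- baseBeta["ONE_COHORT", "male"]
  baseM <- betaToM(baseBeta)
  pat <- tpl$pattern
  nC <- length(pat)
  sexCol <- ifelse(sex == "male", 1L, 2L)
  ageC <- age - mean(age)

  ## random intercepts are realizations of the per-CpG mixed model, so
  ## each CpG gets its own draw per pair / chip / position
  pairInt <- matrix(stats::rnorm(nC * nPairs, 0, config@pairInterceptSd),
                    nC, nPairs)
  batchInt <- matrix(stats::rnorm(nC * config@batchCount, 0, config@batchSd),
                     nC, config@batchCount)
  posInt <- matrix(stats::rnorm(nC * 12L, 0, config@positionSd), nC, 12L)
  M <- baseM[pat, , drop = FALSE][, sexCol, drop = FALSE] +
    config@ageSlope[pat, , drop = FALSE][, sexCol, drop = FALSE] *
      matrix(ageC, nC, nS, byrow = TRUE)
  M <- M + pairInt[, sIdx, drop = FALSE] + batchInt[, batchIdx, drop = FALSE] +
    posInt[, posIdx, drop = FALSE]
  M <- M + tpl$cellCoef %*% t(propsC)
  if (config@residualSd > 0)
    M <- M + matrix(stats::rnorm(nC * nS, 0, config@residualSd), nC, nS)
  beta <- mToBeta(M)
  dimnames(beta) <- list(tpl$probes$probe_id, sampleId)

  fail <- matrix(stats::runif(nC * nS) < config@detectionFailRate, nC, nS)
  dp <- matrix(stats::runif(nC * nS, 0, 0.01), nC, nS)
  dp[fail] <- stats::runif(sum(fail), 0.0101, 1)
  dimnames(dp) <- dimnames(beta)

  samples <- data.frame(
    sample_id = sampleId, sex = sex, age = age,
    twin_pair_id = pairId[sIdx], zygosity = pairZyg[sIdx],
    sentrix_id = sentrix, sentrix_position = position,
    props, stringsAsFactors = FALSE)
  cohort <- MethylationCohort(beta, samples, tpl$probes, detectionP = dp,
                              cohortLabel = cohortLabel)
  truth <- list(
    probes = data.frame(
      probe_id = tpl$probes$probe_id, pattern = pat,
      slope_male = config@ageSlope[pat, "male"],
      slope_female = config@ageSlope[pat, "female"],
      sex_effect = baseM[pat, "female"] - baseM[pat, "male"],
      stringsAsFactors = FALSE),
    samples = data.frame(
      sample_id = sampleId,
      pair_intercept = colMeans(pairInt)[sIdx],  # averaged over CpGs
      batch = sentrix, stringsAsFactors = FALSE))
  list(cohort = cohort, truth = truth)
}

#' Generate a two-discovery-plus-validation synthetic study
#'
#' Builds three cohorts over one shared CpG universe (identical probe ids,
#' annotation, pattern assignment and cell-composition coefficients): two
#' twin discovery cohorts and a validation cohort of unrelated individuals
#' (singleton pair ids, no twin structure). ONE_COHORT sites, when
#' configured, express their sex effect in cohort 1's generating model
#' only.
#'
#' @param configs a named list of three \linkS4class{SimulationConfig}
#'   objects (\code{cohort1}, \code{cohort2}, \code{validation}), e.g. from
#'   \code{\link{defaultStudyConfigs}}. All three must share the same
#'   per-pattern CpG counts.
#' @return a list with \code{cohorts} (named list of three
#'   \linkS4class{MethylationCohort}s) and \code{truth} (the matching
#'   ground-truth lists; the probe-level truth is shared).
#' @export
generateStudy <- function(configs) {
  stopifnot(all(c("cohort1", "cohort2", "validation") %in% names(configs)))
  key <- lapply(configs, function(cf) cf@nCpgsPerPattern)
  if (!all(vapply(key, identical, logical(1), y = key[[1]])))
    stop("configuration error: mismatched CpG universes across cohorts")
  tpl <- .makeProbeTemplate(configs$cohort1)
  cfg1 <- configs$cohort1; cfg1@oneCohortActive <- TRUE
  cfg2 <- configs$cohort2; cfg2@oneCohortActive <- FALSE
  cfgV <- configs$validation
  cfgV@oneCohortActive <- FALSE
  cfgV@singletonPairs <- TRUE
  sims <- list(cohort1 = generateCohort(cfg1, "cohort1", .template = tpl),
               cohort2 = generateCohort(cfg2, "cohort2", .template = tpl),
               validation = generateCohort(cfgV, "validation",
                                           .template = tpl))
  list(cohorts = lapply(sims, `[[`, "cohort"),
       truth = lapply(sims, `[[`, "truth"))
}
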