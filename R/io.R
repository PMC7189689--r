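## Delimited-text I/O. All files are TSV with a header row; matrices carry
## the probe id in the first column and sample ids as the remaining column
## names. Writers and readers share one dialect so cohorts round-trip.

.readMatrix <- function(path, what) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop(what, " matrix needs a probe-id column plus sample columns: ", path)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate probe ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  nbad <- sum(is.na(vals) & !(is.na(raw) | raw %in% c("NA", "NaN", "")))
  if (nbad > 0L)
    warning(nbad, " unparseable numeric cell(s) in ", basename(path),
            " set to missing")
  dimnames(vals) <- list(ids, colnames(raw))
  vals
}

#' Read a methylation cohort from delimited text files
#'
#' Reads the beta matrix, optional detection-p matrix, sample sheet and
#' probe annotation written by \code{\link{writeCohort}} (TSV; matrices have
#' the probe id as first column and sample ids as header). Unparseable
#' numeric cells become missing with a warning reporting the count; sample
#' ids mismatched between matrix and sheet, or duplicate probe ids, are
#' hard errors naming the offenders.
#'
#' @param betaPath,samplePath,annotPath paths to the beta matrix, sample
#'   sheet and probe annotation TSVs.
#' @param detectionPath optional path to the detection-p matrix TSV.
#' @param cohortLabel label for the cohort.
#' @return a \linkS4class{MethylationCohort}.
#' @seealso \code{\link{writeCohort}}
#' @export
readCohort <- function(betaPath, samplePath, annotPath, detectionPath = NULL,
                       cohortLabel = "cohort") {
  beta <- .readMatrix(betaPath, "beta")
  detp <- if (!is.null(detectionPath)) .readMatrix(detectionPath, "detection-p")
  samples <- utils::read.delim(samplePath, check.names = FALSE,
                               stringsAsFactors = FALSE)
  probes <- utils::read.delim(annotPath, check.names = FALSE,
                              stringsAsFactors = FALSE)
  MethylationCohort(beta, samples, probes, detectionP = detp,
                    cohortLabel = cohortLabel)
}

.writeMatrix <- function(m, path) {
  df <- data.frame(probe_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a methylation cohort as delimited text
#'
#' Emits \code{beta.tsv}, \code{detection_p.tsv} (when present),
#' \code{samples.tsv} and \code{probes.tsv} into \code{dir}, in the dialect
#' \code{\link{readCohort}} reads.
#'
#' @param cohort a \linkS4class{MethylationCohort}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             samples = file.path(dir, "samples.tsv"),
             probes = file.path(dir, "probes.tsv"))
  .writeMatrix(betaValues(cohort), paths["beta"])
  dp <- detectionP(cohort)
  if (!is.null(dp)) {
    paths["detection_p"] <- file.path(dir, "detection_p.tsv")
    .writeMatrix(dp, paths["detection_p"])
  }
  utils::write.table(sampleInfo(cohort), paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(probeInfo(cohort), paths["probes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write or read a simulation ground-truth table
#'
#' The per-CpG truth (pattern label, per-sex age slope, sex effect) and the
#' per-sample truth (pair intercept, batch) are written as two TSVs.
#'
#' @param truth a ground-truth list as returned by
#'   \code{\link{generateCohort}} (components \code{probes}, \code{samples}).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
writeGroundTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(probes = file.path(dir, "truth_probes.tsv"),
             samples = file.path(dir, "truth_samples.tsv"))
  utils::write.table(truth$probes, paths["probes"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write or read a simulation configuration as YAML
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param path file path.
#' @return \code{readSimConfig} returns a \linkS4class{SimulationConfig};
#'   \code{writeSimConfig} invisibly returns \code{path}.
#' @export
writeSimConfig <- function(config, path) {
  x <- list(
    n_pairs_per_sex = config@nPairsPerSex,
    mz_fraction = config@mzFraction,
    age_range = as.numeric(config@ageRange),
    n_cpgs_per_pattern = as.list(config@nCpgsPerPattern),
    pattern_base_beta = apply(config@patternBaseBeta, 1, as.list,
                              simplify = FALSE),
    age_slope = apply(config@ageSlope, 1, as.list, simplify = FALSE),
    pair_intercept_sd = config@pairInterceptSd,
    batch_count = config@batchCount,
    batch_sd = config@batchSd,
    position_sd = config@positionSd,
    residual_sd = config@residualSd,
    cell_dirichlet_alpha = as.numeric(config@cellDirichletAlpha),
    cell_effect_sd = config@cellEffectSd,
    detection_fail_rate = config@detectionFailRate,
    singleton_pairs = config@singletonPairs,
    one_cohort_active = config@oneCohortActive,
    seed = config@seed)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
  x <- yaml::read_yaml(path)
  toMat <- function(l) {
    m <- do.call(rbind, lapply(l, function(r) c(male = r$male,
                                                female = r$female)))
    rownames(m) <- names(l)
    m
  }
  SimulationConfig(
    nPairsPerSex = x$n_pairs_per_sex, mzFraction = x$mz_fraction,
    ageRange = unlist(x$age_range),
    nCpgsPerPattern = unlist(x$n_cpgs_per_pattern),
    patternBaseBeta = toMat(x$pattern_base_beta),
    ageSlope = toMat(x$age_slope),
    pairInterceptSd = x$pair_intercept_sd, batchCount = x$batch_count,
    batchSd = x$batch_sd, positionSd = x$position_sd,
    residualSd = x$residual_sd,
    cellDirichletAlpha = unlist(x$cell_dirichlet_alpha),
    cellEffectSd = x$cell_effect_sd,
    detectionFailRate = x$detection_fail_rate,
    singletonPairs = x$singleton_pairs,
    oneCohortActive = x$one_cohort_active, seed = x$seed)
}
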