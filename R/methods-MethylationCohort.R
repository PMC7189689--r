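#' Construct a MethylationCohort
#'
#' Assembles a \linkS4class{MethylationCohort} from a beta matrix, an
#' optional detection-p matrix, a sample sheet and a probe annotation
#' table. Sample ids must match the beta column names and probe ids the
#' row names; mismatches are hard errors naming the offenders.
#'
#' @param beta numeric CpG-by-sample matrix, values in \eqn{[0,1]} or NA;
#'   rownames are probe ids, colnames sample ids.
#' @param samples data.frame with columns \code{sample_id}, \code{sex}
#'   (\code{"male"}/\code{"female"}), \code{age}, \code{twin_pair_id},
#'   \code{zygosity}, \code{sentrix_id}, \code{sentrix_position} and the
#'   six cell-type proportion columns \code{CD8T, CD4T, NK, Bcell, Mono,
#'   Gran} (cell proportions optional).
#' @param probes data.frame with columns \code{probe_id},
#'   \code{chromosome}, \code{position}, \code{gene_region},
#'   \code{is_cross_reactive}, \code{is_polymorphic}.
#' @param detectionP optional detection p-value matrix, same shape and
#'   dimnames as \code{beta}.
#' @param cohortLabel character label for the cohort.
#' @return A \linkS4class{MethylationCohort}.
#' @examples
#' beta <- matrix(runif(8), 4, 2,
#'                dimnames = list(paste0("cg", 1:4), c("s1", "s2")))
#' samples <- data.frame(sample_id = c("s1", "s2"), sex = "female",
#'                       age = c(60, 60), twin_pair_id = "p1",
#'                       zygosity = "MZ", sentrix_id = "S01",
#'                       sentrix_position = "R01C01")
#' probes <- data.frame(probe_id = paste0("cg", 1:4), chromosome = "X",
#'                      position = 1:4 * 1000L, gene_region = "TSS200",
#'                      is_cross_reactive = FALSE, is_polymorphic = FALSE)
#' MethylationCohort(beta, samples, probes, cohortLabel = "demo")
#' @export
MethylationCohort <- function(beta, samples, probes, detectionP = NULL,
                              cohortLabel = "cohort") {
  beta <- as.matrix(beta)
  samples <- as.data.frame(samples)
  probes <- as.data.frame(probes)
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe ids in annotation: ",
         paste(unique(probes$probe_id[duplicated(probes$probe_id)]),
               collapse = ", "))
  .checkIds(colnames(beta), samples$sample_id, "sample")
  .checkIds(rownames(beta), probes$probe_id, "probe")
  samples <- samples[match(colnames(beta), samples$sample_id), , drop = FALSE]
  probes <- probes[match(rownames(beta), probes$probe_id), , drop = FALSE]
  assays <- list(beta = beta)
  if (!is.null(detectionP)) {
    detectionP <- as.matrix(detectionP)
    if (!identical(dim(detectionP), dim(beta)))
      stop("detection-p matrix must have the same shape as the beta matrix")
    dimnames(detectionP) <- dimnames(beta)
    assays$detection_p <- detectionP
  }
  cd <- S4Vectors::DataFrame(samples, row.names = samples$sample_id)
  rd <- S4Vectors::DataFrame(probes, row.names = probes$probe_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = cd, rowData = rd,
    metadata = list(cohort_label = cohortLabel, log = character()))
  new("MethylationCohort", se)
}

.checkIds <- function(matrixIds, sheetIds, what) {
  miss <- setdiff(matrixIds, sheetIds)
  extra <- setdiff(sheetIds, matrixIds)
  if (length(miss) || length(extra))
    stop(sprintf("%s ids mismatched between matrix and table;", what),
         if (length(miss)) paste0(" absent from table: ",
                                  paste(miss, collapse = ", ")),
         if (length(extra)) paste0(" absent from matrix: ",
                                   paste(extra, collapse = ", ")))
  if (anyDuplicated(matrixIds))
    stop("duplicate ", what, " ids: ",
         paste(unique(matrixIds[duplicated(matrixIds)]), collapse = ", "))
  invisible(TRUE)
}

#' Assay and annotation accessors
#'
#' \code{betaValues} returns the beta matrix, \code{mValues} its logit
#' (base-2) transform via \code{\link{betaToM}}, and \code{detectionP} the
#' detection p-value matrix (\code{NULL} when absent).
#'
#' @param x a \linkS4class{MethylationCohort}.
#' @return a numeric matrix (or \code{NULL} for a missing detection-p assay).
#' @name betaValues
#' @aliases betaValues,MethylationCohort-method
#'   mValues,MethylationCohort-method detectionP,MethylationCohort-method
NULL

#' @rdname betaValues
#' @export
setMethod("betaValues", "MethylationCohort", function(x)
  SummarizedExperiment::assay(x, "beta"))

#' @rdname betaValues
#' @export
setMethod("mValues", "MethylationCohort", function(x)
  betaToM(SummarizedExperiment::assay(x, "beta")))

#' @rdname betaValues
#' @export
setMethod("detectionP", "MethylationCohort", function(x) {
  if ("detection_p" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "detection_p") else NULL
})

#' Sample sheet, probe annotation and cohort label
#'
#' \code{sampleInfo} and \code{probeInfo} return the sample sheet and probe
#' annotation as plain data.frames; \code{cohortLabel} gets or sets the
#' cohort's label.
#'
#' @param x a \linkS4class{MethylationCohort}.
#' @param value replacement label.
#' @return a data.frame, or a character label.
#' @name sampleInfo
NULL

#' @rdname sampleInfo
#' @export
setMethod("sampleInfo", "MethylationCohort", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname sampleInfo
#' @export
setMethod("probeInfo", "MethylationCohort", function(x)
  as.data.frame(SummarizedExperiment::rowData(x)))

#' @rdname sampleInfo
#' @export
setMethod("cohortLabel", "MethylationCohort", function(x)
  S4Vectors::metadata(x)$cohort_label)

#' @rdname sampleInfo
#' @export
setMethod("cohortLabel<-", "MethylationCohort", function(x, value) {
  S4Vectors::metadata(x)$cohort_label <- value
  x
})

#' @export
#' @describeIn MethylationCohort-class compact display
setMethod("show", "MethylationCohort", function(object) {
  si <- sampleInfo(object)
  cat("MethylationCohort '", cohortLabel(object), "': ",
      nrow(object), " probes x ", ncol(object), " samples\n", sep = "")
  if (nrow(si)) {
    cat("  sex: ", sum(si$sex == "male"), " male / ",
        sum(si$sex == "female"), " female;  pairs: ",
        length(unique(si$twin_pair_id)), "\n", sep = "")
    cat("  age range: ", paste(round(range(si$age), 1), collapse = "-"),
        " years\n", sep = "")
  }
  cat("  assays: ",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "),
      "\n", sep = "")
  qc <- S4Vectors::metadata(object)$qc
  if (!is.null(qc))
    cat("  QC: ", qc@nProbesIn, " probes in -> ", qc@nProbesOut,
        " out\n", sep = "")
  invisible(NULL)
})

#' @export
#' @describeIn QCReport-class display QC tallies
setMethod("show", "QCReport", function(object) {
  cat("QCReport:\n",
      "  probes in:            ", object@nProbesIn, "\n",
      "  calls masked (det-p): ", object@nMaskedCalls, "\n",
      "  dropped blacklist:    ", object@nDroppedBlacklist, "\n",
      "  dropped missingness:  ", object@nDroppedMissingness, "\n",
      "  probes out:           ", object@nProbesOut, "\n", sep = "")
  invisible(NULL)
})

#' Restrict a cohort to one chromosome
#'
#' Chromosome selection (X-chromosome analysis versus an autosomal
#' comparison chromosome) is a plain filter on the probe annotation.
#'
#' @param cohort a \linkS4class{MethylationCohort}.
#' @param chromosome chromosome name(s) to keep, e.g. \code{"X"}.
#' @return the filtered cohort.
#' @export
filterChromosome <- function(cohort, chromosome) {
  keep <- probeInfo(cohort)$chromosome %in% chromosome
  if (!any(keep))
    stop("no probes on chromosome(s) ", paste(chromosome, collapse = ", "))
  cohort[keep, ]
}
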