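#' @rdname betaValues
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname betaValues
#' @export
setGeneric("mValues", function(x) standardGeneric("mValues"))

#' @rdname betaValues
#' @export
setGeneric("detectionP", function(x) standardGeneric("detectionP"))

#' @rdname sampleInfo
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname sampleInfo
#' @export
setGeneric("probeInfo", function(x) standardGeneric("probeInfo"))

#' @rdname sampleInfo
#' @export
setGeneric("cohortLabel", function(x) standardGeneric("cohortLabel"))

#' @rdname sampleInfo
#' @export
setGeneric("cohortLabel<-", function(x, value) standardGeneric("cohortLabel<-"))

#' @rdname balanceSexes
#' @export
setGeneric("balanceSexes", function(x, ...) standardGeneric("balanceSexes"))
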