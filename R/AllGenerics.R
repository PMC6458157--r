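#' @rdname MirnaExperiment-class
#' @param object,x a package object.
#' @export
setGeneric("expressionScale", function(x) standardGeneric("expressionScale"))

#' @rdname MirnaExperiment-class
#' @export
setGeneric("probeClass", function(x) standardGeneric("probeClass"))

#' @rdname CtSet-class
#' @export
setGeneric("ctRecords", function(x) standardGeneric("ctRecords"))

#' @rdname CtSet-class
#' @export
setGeneric("calibratorAssay", function(x) standardGeneric("calibratorAssay"))

#' @rdname CtSet-class
#' @export
setGeneric("spikeInAssays", function(x) standardGeneric("spikeInAssays"))

#' @rdname RocCurve-class
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname RocCurve-class
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname LatentModel-class
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname LatentModel-class
#' @export
setGeneric("loadings", function(x) standardGeneric("loadings"))

#' @rdname LatentModel-class
#' @export
setGeneric("r2x", function(x) standardGeneric("r2x"))

#' @rdname LatentModel-class
#' @export
setGeneric("r2y", function(x) standardGeneric("r2y"))

#' @rdname LatentModel-class
#' @export
setGeneric("q2y", function(x) standardGeneric("q2y"))

#' @rdname ScreenThreshold-class
#' @export
setGeneric("specificity", function(x) standardGeneric("specificity"))

#' @rdname QcReport-class
#' @export
setGeneric("flaggedSamples", function(x) standardGeneric("flaggedSamples"))
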