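#' @rdname buildModel
#' @export
setGeneric("buildModel", function(spec, NS, ...) standardGeneric("buildModel"))

#' @rdname initialState
#' @export
setGeneric("initialState", function(spec, NS, ...)
  standardGeneric("initialState"))

#' @rdname sampleEndpoints
#' @export
setGeneric("sampleEndpoints", function(system, initFactory, config, ...)
  standardGeneric("sampleEndpoints"))

#' @rdname mutualInformation
#' @export
setGeneric("mutualInformation", function(ensemble, ...)
  standardGeneric("mutualInformation"))

#' @rdname averageFano
#' @export
setGeneric("averageFano", function(ensemble, ...)
  standardGeneric("averageFano"))

#' @rdname outputRange
#' @export
setGeneric("outputRange", function(ensemble, ...)
  standardGeneric("outputRange"))

#' @rdname ensembleMetrics
#' @export
setGeneric("ensembleMetrics", function(ensemble, ...)
  standardGeneric("ensembleMetrics"))

#' @rdname findOptimum
#' @export
setGeneric("findOptimum", function(sweep, ...) standardGeneric("findOptimum"))

#' Extract the result table of a sweep
#'
#' @param x a [SweepResult-class].
#' @rdname sweepTable
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' Signal levels of a response ensemble
#'
#' @rdname signalLevels
#' @export
setGeneric("signalLevels", function(x) standardGeneric("signalLevels"))

#' @rdname writeSweep
#' @export
setGeneric("writeSweep", function(x, path, ...) standardGeneric("writeSweep"))
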