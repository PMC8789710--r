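#' Accessors for pvloop classes
#'
#' @param x An object of one of the package classes.
#' @param ... Unused.
#' @return \code{pressure}, \code{volume}: numeric vectors; \code{sampleTimes}:
#'   time of each sample in seconds; \code{samplingRate}: Hz;
#'   \code{recordingMetadata}: named list; \code{beats}, \code{loopPoints},
#'   \code{perBeat}: data frames; \code{indices}: named numeric vector;
#'   \code{truthValues}: named numeric vector of derived ground truth.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pressure", function(x, ...) standardGeneric("pressure"))
#' @rdname accessors
#' @export
setGeneric("volume", function(x, ...) standardGeneric("volume"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x, ...) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x, ...) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setGeneric("recordingMetadata", function(x, ...)
  standardGeneric("recordingMetadata"))
#' @rdname accessors
#' @export
setGeneric("beats", function(x, ...) standardGeneric("beats"))
#' @rdname accessors
#' @export
setGeneric("indices", function(x, ...) standardGeneric("indices"))
#' @rdname accessors
#' @export
setGeneric("perBeat", function(x, ...) standardGeneric("perBeat"))
#' @rdname accessors
#' @export
setGeneric("loopPoints", function(x, ...) standardGeneric("loopPoints"))
#' @rdname accessors
#' @export
setGeneric("truthValues", function(x, ...) standardGeneric("truthValues"))
#' @rdname accessors
#' @export
setGeneric("beatLog", function(x, ...) standardGeneric("beatLog"))

#' @rdname accessors
#' @export
setMethod("pressure", "PVRecording", function(x, ...) x@pressure)
#' @rdname accessors
#' @export
setMethod("volume", "PVRecording", function(x, ...) x@volume)
#' @rdname accessors
#' @export
setMethod("samplingRate", "PVRecording", function(x, ...) x@fs)
#' @rdname accessors
#' @export
setMethod("sampleTimes", "PVRecording", function(x, ...)
  (seq_along(x@pressure) - 1) / x@fs)
#' @rdname accessors
#' @export
setMethod("recordingMetadata", "PVRecording", function(x, ...) x@metadata)
#' @rdname accessors
#' @export
setMethod("beats", "BeatTable", function(x, ...) x@beats)
#' @rdname accessors
#' @export
setMethod("samplingRate", "BeatTable", function(x, ...) x@fs)
#' @rdname accessors
#' @export
setMethod("indices", "IndexReport", function(x, ...) x@indices)
#' @rdname accessors
#' @export
setMethod("perBeat", "IndexReport", function(x, ...) x@perBeat)
#' @rdname accessors
#' @export
setMethod("loopPoints", "CanonicalLoop", function(x, ...) x@points)
#' @rdname accessors
#' @export
setMethod("truthValues", "SimTruth", function(x, ...) x@derived)
#' @rdname accessors
#' @export
setMethod("beatLog", "SimTruth", function(x, ...) x@beatLog)
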