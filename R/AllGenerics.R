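#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the core classes: \linkS4class{Signal},
#' \linkS4class{FrameStack}, \linkS4class{Recording},
#' \linkS4class{AreaWaveform}, \linkS4class{FoTrack},
#' \linkS4class{Spectrogram} and \linkS4class{PSSeries}.
#'
#' @param x object
#' @param ... further arguments for methods
#' @return The slot content documented for each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x, ...) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x, ...) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x, ...) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x, ...) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("channelLabel", function(x, ...) standardGeneric("channelLabel"))

#' @rdname accessors
#' @export
setGeneric("channels", function(x, ...) standardGeneric("channels"))

#' @rdname accessors
#' @export
setGeneric("frames", function(x, ...) standardGeneric("frames"))

#' @rdname accessors
#' @export
setGeneric("fps", function(x, ...) standardGeneric("fps"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("areas", function(x, ...) standardGeneric("areas"))

#' @rdname accessors
#' @export
setGeneric("foValues", function(x, ...) standardGeneric("foValues"))

#' @rdname accessors
#' @export
setGeneric("foTimes", function(x, ...) standardGeneric("foTimes"))

#' @rdname accessors
#' @export
setGeneric("voicingConfidence", function(x, ...)
  standardGeneric("voicingConfidence"))

#' @rdname accessors
#' @export
setGeneric("windowCenters", function(x, ...) standardGeneric("windowCenters"))

#' @rdname accessors
#' @export
setGeneric("psMedian", function(x, ...) standardGeneric("psMedian"))

#' @rdname accessors
#' @export
setGeneric("psQ25", function(x, ...) standardGeneric("psQ25"))

#' @rdname accessors
#' @export
setGeneric("psQ75", function(x, ...) standardGeneric("psQ75"))

#' @rdname accessors
#' @export
setGeneric("psIQR", function(x, ...) standardGeneric("psIQR"))

#' @rdname accessors
#' @export
setGeneric("asSignal", function(x, ...) standardGeneric("asSignal"))
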