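#' @include AllClasses.R
NULL

#' @rdname accessors
#' @aliases samples,Signal-method
#' @export
setMethod("samples", "Signal", function(x, ...) x@samples)

#' @rdname accessors
#' @export
setMethod("samplingRate", "Signal", function(x, ...) x@Fs)

#' @rdname accessors
#' @export
setMethod("nSamples", "Signal", function(x, ...) length(x@samples))

#' @rdname accessors
#' @export
setMethod("duration", "Signal", function(x, ...) length(x@samples) / x@Fs)

#' @rdname accessors
#' @export
setMethod("channelLabel", "Signal", function(x, ...) x@label)

setMethod("show", "Signal", function(object) {
  cat(sprintf("Signal [%s]: %d samples @ %g Hz (%.4g s), t0 = %g s\n",
              object@label, length(object@samples), object@Fs,
              length(object@samples) / object@Fs, object@t0))
  if (length(object@samples))
    cat(sprintf("  range [%.4g, %.4g]\n", min(object@samples),
                max(object@samples)))
})

#' @rdname accessors
#' @export
setMethod("channels", "Recording", function(x, ...) x@channels)

#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(x, ...) x@Fs)

#' @rdname accessors
#' @export
setMethod("frames", "Recording", function(x, ...) x@frames)

#' @rdname accessors
#' @export
setMethod("duration", "Recording", function(x, ...) {
  if (!length(x@channels)) return(0)
  nSamples(x@channels[[1L]]) / x@Fs
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channel(s) @ %g Hz, %.4g s\n",
              length(object@channels), object@Fs, duration(object)))
  if (length(object@channels))
    cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
  if (!is.null(object@frames))
    cat(sprintf("  frames: %d @ %g fps\n", length(object@frames@frames),
                object@frames@fps))
})

#' Extract one channel of a Recording
#'
#' @param x a \linkS4class{Recording}
#' @param i channel name or index
#' @return the \linkS4class{Signal}
#' @export
setMethod("[[", "Recording", function(x, i) x@channels[[i]])

#' @rdname accessors
#' @export
setMethod("frames", "FrameStack", function(x, ...) x@frames)

#' @rdname accessors
#' @export
setMethod("fps", "FrameStack", function(x, ...) x@fps)

#' @rdname accessors
#' @export
setMethod("nFrames", "FrameStack", function(x, ...) length(x@frames))

setMethod("show", "FrameStack", function(object) {
  d <- if (length(object@frames)) dim(object@frames[[1L]]) else c(0, 0)
  cat(sprintf("FrameStack: %d frame(s) of %d x %d px @ %g fps\n",
              length(object@frames), d[1L], d[2L], object@fps))
})

#' @rdname accessors
#' @export
setMethod("areas", "AreaWaveform", function(x, ...) x@areas)

#' @rdname accessors
#' @export
setMethod("fps", "AreaWaveform", function(x, ...) x@fps)

#' @rdname accessors
#' @export
setMethod("duration", "AreaWaveform", function(x, ...)
  length(x@areas) / x@fps)

#' Convert an AreaWaveform to a Signal
#'
#' The per-frame areas become samples at the frame rate; the label follows
#' the segmentation target (GAW for glottal, SAW for supraglottic).
#'
#' @param x an \linkS4class{AreaWaveform}
#' @param ... unused
#' @return a \linkS4class{Signal}
#' @export
setMethod("asSignal", "AreaWaveform", function(x, ...) {
  Signal(x@areas, Fs = x@fps,
         label = if (x@target == "glottal") "GAW" else "SAW")
})

setMethod("show", "AreaWaveform", function(object) {
  cat(sprintf("AreaWaveform [%s]: %d frame(s) @ %g fps, area range [%g, %g] px^2\n",
              object@target, length(object@areas), object@fps,
              if (length(object@areas)) min(object@areas) else NA,
              if (length(object@areas)) max(object@areas) else NA))
})

#' @rdname accessors
#' @export
setMethod("foTimes", "FoTrack", function(x, ...) x@times)

#' @rdname accessors
#' @export
setMethod("foValues", "FoTrack", function(x, ...) x@fo)

#' @rdname accessors
#' @export
setMethod("voicingConfidence", "FoTrack", function(x, ...) x@voicing)

setMethod("show", "FoTrack", function(object) {
  nv <- sum(!is.na(object@fo))
  cat(sprintf("FoTrack [%s]: %d frame(s), %d voiced", object@channel,
              length(object@times), nv))
  if (nv)
    cat(sprintf(", fo %.4g +/- %.2g Hz", mean(object@fo, na.rm = TRUE),
                stats::sd(object@fo, na.rm = TRUE)))
  cat("\n")
})

setMethod("show", "Spectrogram", function(object) {
  cat(sprintf(
    "Spectrogram: %d bins x %d frames (window %d, hop %d @ %g Hz)\n",
    nrow(object@mag), ncol(object@mag), object@windowLength, object@hop,
    object@Fs))
})

#' @rdname accessors
#' @export
setMethod("windowCenters", "PSSeries", function(x, ...) x@centers)

#' @rdname accessors
#' @export
setMethod("psMedian", "PSSeries", function(x, ...) x@med)

#' @rdname accessors
#' @export
setMethod("psQ25", "PSSeries", function(x, ...) x@q25)

#' @rdname accessors
#' @export
setMethod("psQ75", "PSSeries", function(x, ...) x@q75)

#' @rdname accessors
#' @export
setMethod("psIQR", "PSSeries", function(x, ...) x@q75 - x@q25)

setMethod("show", "PSSeries", function(object) {
  ok <- !is.na(object@med)
  cat(sprintf("PSSeries: %d window(s), %d valid\n", length(object@centers),
              sum(ok)))
  if (any(ok))
    cat(sprintf("  median PS range [%.3f, %.3f]\n", min(object@med[ok]),
                max(object@med[ok])))
})

#' Convert a PSSeries to a data.frame
#'
#' @param x a \linkS4class{PSSeries}
#' @param ... unused
#' @return data.frame with columns t_center, median, q25, q75, IQR, n_valid
#' @export
setMethod("as.data.frame", "PSSeries", function(x, ...) {
  data.frame(t_center = x@centers, median = x@med, q25 = x@q25,
             q75 = x@q75, IQR = x@q75 - x@q25, n_valid = x@nValid)
})

#' Convert an FoTrack to a data.frame
#'
#' @param x an \linkS4class{FoTrack}
#' @param ... unused
#' @return data.frame with columns time, fo, voicing
#' @export
setMethod("as.data.frame", "FoTrack", function(x, ...) {
  data.frame(time = x@times, fo = x@fo, voicing = x@voicing)
})

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %.3g s @ %g Hz, regime '%s', ratio %d:1, seed %d\n",
    object@duration, object@Fs, object@coupling@regime,
    as.integer(object@coupling@ratioN), as.integer(object@seed)))
  cat(sprintf("  glottal: %s fo trajectory (%s Hz), %s\n",
              object@glottal@trajType,
              paste(object@glottal@trajPar, collapse = ", "),
              object@glottal@pulseShape))
  if (!is.null(object@supraglottic))
    cat(sprintf("  supraglottic: explicit %s trajectory (%s Hz)\n",
                object@supraglottic@trajType,
                paste(object@supraglottic@trajPar, collapse = ", ")))
  else
    cat("  supraglottic: derived from glottal / ratio\n")
  if (!is.null(object@render)) cat("  rendering: enabled\n")
})
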