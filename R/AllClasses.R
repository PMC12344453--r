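#' @include AllGenerics.R
NULL

.SIGNAL_LABELS <- c("audio", "EGG", "iEGG", "GAW", "SAW", "other")

#' Signal: a single uniformly sampled channel
#'
#' A one-dimensional, uniformly sampled time series with a sampling rate,
#' a time origin and a channel label. Signals hold acoustic pressure,
#' electroglottogram (EGG), sign-inverted EGG (iEGG) or glottal /
#' supraglottic area-waveform data; all downstream analysis (fo tracking,
#' spectrograms, phase synchrony) operates on this class.
#'
#' @slot samples numeric vector, finite
#' @slot Fs sampling rate in Hz, positive
#' @slot t0 time of the first sample in seconds
#' @slot label one of \code{"audio"}, \code{"EGG"}, \code{"iEGG"},
#'   \code{"GAW"}, \code{"SAW"}, \code{"other"}
#' @aliases Signal-class
#' @exportClass Signal
setClass("Signal",
  representation(samples = "numeric", Fs = "numeric", t0 = "numeric",
                 label = "character"),
  prototype(samples = numeric(0), Fs = 20000, t0 = 0, label = "other"))

setValidity("Signal", function(object) {
  msg <- character(0)
  if (length(object@Fs) != 1L || !is.finite(object@Fs) || object@Fs <= 0)
    msg <- c(msg, "'Fs' must be a single positive finite number")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "'t0' must be a single finite number")
  if (anyNA(object@samples) || any(!is.finite(object@samples)))
    msg <- c(msg, "'samples' must be finite and non-missing")
  if (length(object@label) != 1L || !object@label %in% .SIGNAL_LABELS)
    msg <- c(msg, paste0("'label' must be one of: ",
                         paste(.SIGNAL_LABELS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a Signal
#'
#' @param samples numeric sample vector
#' @param Fs sampling rate (Hz)
#' @param t0 time of first sample (s); all channels of a simultaneously
#'   triggered recording share \code{t0 = 0}
#' @param label channel label
#' @return a \linkS4class{Signal}
#' @examples
#' s <- Signal(sin(2 * pi * 100 * (0:1999) / 20000), Fs = 20000,
#'             label = "audio")
#' duration(s)
#' @export
Signal <- function(samples, Fs, t0 = 0, label = "other") {
  new("Signal", samples = as.numeric(samples), Fs = as.numeric(Fs),
      t0 = as.numeric(t0), label = as.character(label))
}

#' FrameStack: a grayscale high-speed image sequence
#'
#' An ordered list of equally sized grayscale frames (matrices with values
#' in [0, 1]) together with the frame rate. High-speed laryngeal imaging is
#' acquired at the signal sampling rate (nominally 20000 fps, 386 x 320 px),
#' so a stack is sample-aligned with the signal channels of a
#' \linkS4class{Recording}.
#'
#' @slot frames list of numeric matrices, all the same dimension
#' @slot fps frame rate in Hz
#' @slot bitDepth nominal storage bit depth (8 or 16); frames are held as
#'   doubles in [0, 1] regardless
#' @aliases FrameStack-class
#' @exportClass FrameStack
setClass("FrameStack",
  representation(frames = "list", fps = "numeric", bitDepth = "numeric"),
  prototype(frames = list(), fps = 20000, bitDepth = 8))

setValidity("FrameStack", function(object) {
  msg <- character(0)
  if (length(object@fps) != 1L || !is.finite(object@fps) || object@fps <= 0)
    msg <- c(msg, "'fps' must be a single positive number")
  if (length(object@frames)) {
    if (!all(vapply(object@frames, is.matrix, logical(1))))
      msg <- c(msg, "all frames must be matrices")
    else {
      d <- dim(object@frames[[1L]])
      same <- vapply(object@frames, function(f) identical(dim(f), d),
                     logical(1))
      if (!all(same)) msg <- c(msg, "all frames must have the same size")
    }
  }
  if (!object@bitDepth %in% c(8, 16))
    msg <- c(msg, "'bitDepth' must be 8 or 16")
  if (length(msg)) msg else TRUE
})

#' Construct a FrameStack
#'
#' @param frames list of grayscale matrices in [0, 1]
#' @param fps frame rate (Hz)
#' @param bitDepth nominal bit depth
#' @return a \linkS4class{FrameStack}
#' @export
FrameStack <- function(frames, fps, bitDepth = 8) {
  new("FrameStack", frames = frames, fps = as.numeric(fps),
      bitDepth = as.numeric(bitDepth))
}

#' Recording: aligned multi-channel container
#'
#' Holds the simultaneously acquired channels of one phonation task --
#' audio, EGG/iEGG and area waveforms -- at a common sampling rate,
#' optionally together with the high-speed frame stack. After alignment all
#' channels have the same length and time origin.
#'
#' @slot channels named list of \linkS4class{Signal}
#' @slot frames a \linkS4class{FrameStack} or \code{NULL}
#' @slot Fs common sampling rate (Hz)
#' @aliases Recording-class
#' @exportClass Recording
setClass("Recording",
  representation(channels = "list", frames = "ANY", Fs = "numeric"),
  prototype(channels = list(), frames = NULL, Fs = 20000))

setValidity("Recording", function(object) {
  msg <- character(0)
  if (length(object@channels)) {
    if (is.null(names(object@channels)) || any(names(object@channels) == ""))
      msg <- c(msg, "'channels' must be a named list")
    ok <- vapply(object@channels, function(ch) methods::is(ch, "Signal"),
                 logical(1))
    if (!all(ok)) msg <- c(msg, "all channels must be Signal objects")
    else {
      n <- vapply(object@channels, function(ch) length(ch@samples), integer(1))
      if (length(unique(n)) > 1L)
        msg <- c(msg, "all channels must have the same length")
      fs <- vapply(object@channels, function(ch) ch@Fs, numeric(1))
      if (any(abs(fs - object@Fs) > 1e-9))
        msg <- c(msg, "all channels must share the common 'Fs'")
      t0 <- vapply(object@channels, function(ch) ch@t0, numeric(1))
      if (any(abs(t0 - t0[1L]) > 1e-12))
        msg <- c(msg, "all channels must share the same 't0'")
    }
  }
  if (!is.null(object@frames) && !methods::is(object@frames, "FrameStack"))
    msg <- c(msg, "'frames' must be NULL or a FrameStack")
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param channels named list of \linkS4class{Signal} objects, all at the
#'   same sampling rate, length and time origin
#' @param frames optional \linkS4class{FrameStack}
#' @param Fs common sampling rate; defaults to the rate of the first channel
#' @return a \linkS4class{Recording}
#' @export
Recording <- function(channels, frames = NULL, Fs = NULL) {
  if (is.null(Fs)) {
    if (!length(channels)) stop("need 'Fs' for an empty Recording")
    Fs <- channels[[1L]]@Fs
  }
  new("Recording", channels = channels, frames = frames, Fs = as.numeric(Fs))
}

#' AreaWaveform: per-frame segmented region area
#'
#' The glottal (GAW) or supraglottic (SAW) area waveform: one uncalibrated
#' pixel area per frame. Area waveforms carry no contact-area semantics --
#' the minimum of a SAW need not coincide with maximal supraglottic contact,
#' since it derives from a two-dimensional projection.
#'
#' @slot areas numeric vector of non-negative pixel areas, one per frame
#' @slot fps frame rate (Hz)
#' @slot target \code{"glottal"} or \code{"supraglottic"}
#' @slot profile the \linkS4class{SegmentationProfile} used (or a list for
#'   synthetic ground truth)
#' @aliases AreaWaveform-class
#' @exportClass AreaWaveform
setClass("AreaWaveform",
  representation(areas = "numeric", fps = "numeric", target = "character",
                 profile = "ANY"),
  prototype(areas = numeric(0), fps = 20000, target = "glottal",
            profile = NULL))

setValidity("AreaWaveform", function(object) {
  msg <- character(0)
  if (any(!is.finite(object@areas)) || any(object@areas < 0))
    msg <- c(msg, "'areas' must be finite and non-negative")
  if (length(object@fps) != 1L || object@fps <= 0)
    msg <- c(msg, "'fps' must be a single positive number")
  if (!object@target %in% c("glottal", "supraglottic"))
    msg <- c(msg, "'target' must be 'glottal' or 'supraglottic'")
  if (length(msg)) msg else TRUE
})

#' Construct an AreaWaveform
#'
#' @param areas non-negative per-frame areas (px^2)
#' @param fps frame rate (Hz)
#' @param target \code{"glottal"} or \code{"supraglottic"}
#' @param profile segmentation profile used, if any
#' @return an \linkS4class{AreaWaveform}
#' @export
AreaWaveform <- function(areas, fps, target = "glottal", profile = NULL) {
  new("AreaWaveform", areas = as.numeric(areas), fps = as.numeric(fps),
      target = target, profile = profile)
}

#' FoTrack: time-stamped fundamental-frequency estimates
#'
#' Frame-wise fo estimates for one channel. Unvoiced frames carry
#' \code{NA} fo; each frame has a voicing confidence in [0, 1].
#'
#' @slot times frame centre times (s), strictly increasing
#' @slot fo fo in Hz, \code{NA} where unvoiced, positive where present
#' @slot voicing voicing confidence in [0, 1]
#' @slot channel label of the analysed channel
#' @slot settings list of estimator settings (fmin, fmax, threshold, ...)
#' @aliases FoTrack-class
#' @exportClass FoTrack
setClass("FoTrack",
  representation(times = "numeric", fo = "numeric", voicing = "numeric",
                 channel = "character", settings = "list"),
  prototype(times = numeric(0), fo = numeric(0), voicing = numeric(0),
            channel = "other", settings = list()))

setValidity("FoTrack", function(object) {
  msg <- character(0)
  n <- length(object@times)
  if (length(object@fo) != n || length(object@voicing) != n)
    msg <- c(msg, "'times', 'fo' and 'voicing' must have equal length")
  if (n > 1L && any(diff(object@times) <= 0))
    msg <- c(msg, "'times' must be strictly increasing")
  if (any(!is.na(object@fo) & object@fo <= 0))
    msg <- c(msg, "voiced 'fo' values must be positive")
  if (any(object@voicing < 0 | object@voicing > 1, na.rm = TRUE))
    msg <- c(msg, "'voicing' must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an FoTrack
#'
#' @param times frame centre times (s)
#' @param fo fo estimates in Hz (\code{NA} = unvoiced)
#' @param voicing voicing confidence in [0, 1]
#' @param channel channel label
#' @param settings estimator settings list
#' @return an \linkS4class{FoTrack}
#' @export
FoTrack <- function(times, fo, voicing = rep(1, length(times)),
                    channel = "other", settings = list()) {
  new("FoTrack", times = as.numeric(times), fo = as.numeric(fo),
      voicing = as.numeric(voicing), channel = channel, settings = settings)
}

#' Spectrogram: short-term Fourier magnitude array
#'
#' Magnitudes of a Hann-windowed STFT, with frequency-bin and frame-time
#' axes. The magnitude is \code{Mod} of the one-sided STFT without further
#' scaling, so per-frame energy obeys Parseval up to the constant
#' \code{sum(hann^2)}.
#'
#' @slot mag magnitude matrix, frequency bins x frames
#' @slot freq bin centre frequencies (Hz)
#' @slot time frame centre times (s)
#' @slot Fs sampling rate (Hz)
#' @slot windowLength window length (samples)
#' @slot hop hop size (samples)
#' @aliases Spectrogram-class
#' @exportClass Spectrogram
setClass("Spectrogram",
  representation(mag = "matrix", freq = "numeric", time = "numeric",
                 Fs = "numeric", windowLength = "numeric", hop = "numeric"))

setValidity("Spectrogram", function(object) {
  msg <- character(0)
  if (nrow(object@mag) != length(object@freq))
    msg <- c(msg, "nrow(mag) must equal length(freq)")
  if (ncol(object@mag) != length(object@time))
    msg <- c(msg, "ncol(mag) must equal length(time)")
  if (object@hop <= 0 || object@hop > object@windowLength)
    msg <- c(msg, "'hop' must satisfy 0 < hop <= windowLength")
  if (length(msg)) msg else TRUE
})

#' PSSeries: windowed phase-synchrony summary
#'
#' Per-window median, 25% and 75% quantiles of the pointwise phase
#' synchrony between two channels. Windows where either channel is silent
#' are reported as missing (\code{NA}), not as zero. The interquartile
#' range (IQR) is \code{q75 - q25}.
#'
#' @slot centers window centre times (s)
#' @slot med per-window median PS in [-1, 1]
#' @slot q25 per-window 25% quantile
#' @slot q75 per-window 75% quantile
#' @slot nValid number of valid samples per window
#' @slot options the \linkS4class{PSOptions} used
#' @aliases PSSeries-class
#' @exportClass PSSeries
setClass("PSSeries",
  representation(centers = "numeric", med = "numeric", q25 = "numeric",
                 q75 = "numeric", nValid = "numeric", options = "ANY"))

setValidity("PSSeries", function(object) {
  msg <- character(0)
  n <- length(object@centers)
  if (length(object@med) != n || length(object@q25) != n ||
      length(object@q75) != n || length(object@nValid) != n)
    msg <- c(msg, "all per-window slots must have equal length")
  ok <- !is.na(object@med)
  if (any(object@med[ok] < -1 - 1e-9 | object@med[ok] > 1 + 1e-9))
    msg <- c(msg, "'med' must lie in [-1, 1]")
  if (any(object@q25[ok] > object@med[ok] + 1e-9) ||
      any(object@med[ok] > object@q75[ok] + 1e-9))
    msg <- c(msg, "must satisfy q25 <= median <= q75")
  if (length(msg)) msg else TRUE
})

## ---- synthetic-scene specification classes ----------------------------

#' OscillatorSpec: one quasi-periodic pulse-train oscillator
#'
#' Parametric description of a glottal or supraglottic oscillator: an fo
#' trajectory (constant, linear glissando or step), a pulse shape, an open
#' quotient and an amplitude.
#'
#' @slot trajType \code{"constant"}, \code{"glissando"} or \code{"step"}
#' @slot trajPar numeric parameters: constant \code{c(fo)}; glissando
#'   \code{c(f0, f1, tStart, tEnd)} (linear in between, constant outside);
#'   step \code{c(f0, f1, tStep)}
#' @slot pulseShape \code{"raised_cosine_pulse"}, \code{"impulse_train"} or
#'   \code{"sinusoid"}
#' @slot openQuotient open-phase fraction of the cycle, in (0, 1]
#' @slot amplitude dimensionless amplitude
#' @aliases OscillatorSpec-class
#' @exportClass OscillatorSpec
setClass("OscillatorSpec",
  representation(trajType = "character", trajPar = "numeric",
                 pulseShape = "character", openQuotient = "numeric",
                 amplitude = "numeric"),
  prototype(trajType = "constant", trajPar = 136,
            pulseShape = "raised_cosine_pulse", openQuotient = 0.5,
            amplitude = 1))

setValidity("OscillatorSpec", function(object) {
  msg <- character(0)
  if (!object@trajType %in% c("constant", "glissando", "step"))
    msg <- c(msg, "'trajType' must be constant, glissando or step")
  need <- c(constant = 1L, glissando = 4L, step = 3L)[object@trajType]
  if (!is.na(need) && length(object@trajPar) != need)
    msg <- c(msg, sprintf("'trajPar' needs %d values for type '%s'",
                          need, object@trajType))
  fo <- object@trajPar[seq_len(min(2L, length(object@trajPar)))]
  if (any(fo <= 0)) msg <- c(msg, "fo trajectory must be positive everywhere")
  if (!object@pulseShape %in%
      c("raised_cosine_pulse", "impulse_train", "sinusoid"))
    msg <- c(msg, "unknown 'pulseShape'")
  if (object@openQuotient <= 0 || object@openQuotient > 1)
    msg <- c(msg, "'openQuotient' must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an OscillatorSpec
#'
#' @param fo constant fo in Hz (ignored when \code{glissando} or
#'   \code{step} is given)
#' @param glissando \code{c(f0, f1, tStart, tEnd)}: linear glide from
#'   \code{f0} to \code{f1} between the two times, constant outside
#' @param step \code{c(f0, f1, tStep)}: discrete fo jump at \code{tStep}
#' @param pulseShape pulse shape
#' @param openQuotient open-phase fraction in (0, 1]
#' @param amplitude amplitude
#' @return an \linkS4class{OscillatorSpec}
#' @export
oscillatorSpec <- function(fo = 136, glissando = NULL, step = NULL,
                           pulseShape = "raised_cosine_pulse",
                           openQuotient = 0.5, amplitude = 1) {
  if (!is.null(glissando) && !is.null(step))
    stop("give at most one of 'glissando' and 'step'")
  if (!is.null(glissando)) {
    trajType <- "glissando"; trajPar <- as.numeric(glissando)
  } else if (!is.null(step)) {
    trajType <- "step"; trajPar <- as.numeric(step)
  } else {
    trajType <- "constant"; trajPar <- as.numeric(fo)
  }
  new("OscillatorSpec", trajType = trajType, trajPar = trajPar,
      pulseShape = pulseShape, openQuotient = as.numeric(openQuotient),
      amplitude = as.numeric(amplitude))
}

#' CouplingSpec: how the supraglottic oscillator relates to the glottal one
#'
#' @slot ratioN integer >= 1: glottal cycles per supraglottic cycle
#' @slot phaseOffset fixed phase offset (radians) of the supraglottic
#'   oscillator in the locked regime
#' @slot regime \code{"locked"}, \code{"drifting"}, \code{"biphonation"} or
#'   \code{"chaotic"}
#' @slot subharmonicDepth in [0, 1]: amplitude reduction of glottal pulses
#'   on cycles coinciding with supraglottic contact (period-doubling-style
#'   alternation at ratio 2)
#' @slot noiseSnrDb additive-noise SNR in dB; \code{Inf} = no noise
#' @aliases CouplingSpec-class
#' @exportClass CouplingSpec
setClass("CouplingSpec",
  representation(ratioN = "numeric", phaseOffset = "numeric",
                 regime = "character", subharmonicDepth = "numeric",
                 noiseSnrDb = "numeric"),
  prototype(ratioN = 2, phaseOffset = 0, regime = "locked",
            subharmonicDepth = 0, noiseSnrDb = Inf))

setValidity("CouplingSpec", function(object) {
  msg <- character(0)
  if (object@ratioN < 1 || object@ratioN != round(object@ratioN))
    msg <- c(msg, "'ratioN' must be a positive integer")
  if (!object@regime %in% c("locked", "drifting", "biphonation", "chaotic"))
    msg <- c(msg, "unknown 'regime'")
  if (object@subharmonicDepth < 0 || object@subharmonicDepth > 1)
    msg <- c(msg, "'subharmonicDepth' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a CouplingSpec
#'
#' @param ratioN glottal cycles per supraglottic cycle (integer >= 1)
#' @param phaseOffset supraglottic phase offset (radians)
#' @param regime coupling regime
#' @param subharmonicDepth amplitude-alternation depth in [0, 1]
#' @param noiseSnrDb additive-noise SNR (dB), \code{Inf} for none
#' @return a \linkS4class{CouplingSpec}
#' @export
couplingSpec <- function(ratioN = 2, phaseOffset = 0, regime = "locked",
                         subharmonicDepth = 0, noiseSnrDb = Inf) {
  new("CouplingSpec", ratioN = as.numeric(ratioN),
      phaseOffset = as.numeric(phaseOffset), regime = regime,
      subharmonicDepth = as.numeric(subharmonicDepth),
      noiseSnrDb = as.numeric(noiseSnrDb))
}

#' RenderSpec: how a scene is rasterized into grayscale frames
#'
#' Frames contain a central elliptical glottal region surrounded by an
#' annular supraglottic region; the pixel area of each region follows its
#' area waveform. The three brightness levels (background, supraglottic,
#' glottal) are configurable but must be distinct.
#'
#' @slot frameSize \code{c(width, height)} in pixels (default 386 x 320)
#' @slot fps frame rate (Hz); frames are rendered at the signal rate
#' @slot glottalMaxArea glottal region capacity (px^2)
#' @slot supraMaxArea supraglottic annulus capacity (px^2)
#' @slot glottalAspect width/height ratio of the glottal ellipse
#' @slot brightness \code{c(background, supraglottic, glottal)} grey levels
#' @slot rotation in-plane rotation of the region axes (degrees, CCW)
#' @aliases RenderSpec-class
#' @exportClass RenderSpec
setClass("RenderSpec",
  representation(frameSize = "numeric", fps = "numeric",
                 glottalMaxArea = "numeric", supraMaxArea = "numeric",
                 glottalAspect = "numeric", brightness = "numeric",
                 rotation = "numeric"),
  prototype(frameSize = c(386, 320), fps = 20000, glottalMaxArea = 600,
            supraMaxArea = 4000, glottalAspect = 3,
            brightness = c(0.05, 0.55, 0.95), rotation = 0))

setValidity("RenderSpec", function(object) {
  msg <- character(0)
  if (length(object@frameSize) != 2L || any(object@frameSize < 8))
    msg <- c(msg, "'frameSize' must be c(width, height), each >= 8 px")
  if (length(object@brightness) != 3L ||
      any(object@brightness < 0 | object@brightness > 1))
    msg <- c(msg, "'brightness' must be 3 grey levels in [0, 1]")
  if (length(unique(object@brightness)) != 3L)
    msg <- c(msg, "brightness levels must be distinct")
  if (object@glottalMaxArea <= 0 || object@supraMaxArea <= 0)
    msg <- c(msg, "region capacities must be positive")
  cap <- prod(object@frameSize)
  if (object@glottalMaxArea * 1.3 + object@supraMaxArea > 0.8 * cap)
    msg <- c(msg, "regions do not fit inside the frame")
  if (length(msg)) msg else TRUE
})

#' Construct a RenderSpec
#'
#' @param frameSize \code{c(width, height)} px
#' @param fps frame rate (Hz)
#' @param glottalMaxArea glottal capacity (px^2)
#' @param supraMaxArea supraglottic capacity (px^2)
#' @param glottalAspect glottal ellipse aspect ratio
#' @param brightness grey levels \code{c(background, supraglottic, glottal)}
#' @param rotation region rotation (degrees CCW)
#' @return a \linkS4class{RenderSpec}
#' @export
renderSpec <- function(frameSize = c(386, 320), fps = 20000,
                       glottalMaxArea = 600, supraMaxArea = 4000,
                       glottalAspect = 3,
                       brightness = c(0.05, 0.55, 0.95), rotation = 0) {
  new("RenderSpec", frameSize = as.numeric(frameSize), fps = as.numeric(fps),
      glottalMaxArea = as.numeric(glottalMaxArea),
      supraMaxArea = as.numeric(supraMaxArea),
      glottalAspect = as.numeric(glottalAspect),
      brightness = as.numeric(brightness), rotation = as.numeric(rotation))
}

#' SceneSpec: full parametric description of a synthetic phonation scene
#'
#' @slot glottal \linkS4class{OscillatorSpec} of the glottal oscillator
#' @slot supraglottic \linkS4class{OscillatorSpec} or \code{NULL}; when
#'   \code{NULL} the supraglottic fo is derived from the glottal trajectory
#'   and the coupling ratio (tight entrainment)
#' @slot coupling \linkS4class{CouplingSpec}
#' @slot duration scene duration (s)
#' @slot Fs sampling rate (Hz)
#' @slot events data.frame with columns \code{time}, \code{kind}
#'   (\code{frequency_jump}, \code{glissando_start}, \code{regime_switch})
#'   and \code{value}; sorted by time, all within [0, duration]
#' @slot render \linkS4class{RenderSpec} or \code{NULL}
#' @slot seed integer seed for every stochastic component
#' @aliases SceneSpec-class
#' @exportClass SceneSpec
setClass("SceneSpec",
  representation(glottal = "OscillatorSpec", supraglottic = "ANY",
                 coupling = "CouplingSpec", duration = "numeric",
                 Fs = "numeric", events = "data.frame", render = "ANY",
                 seed = "numeric"),
  prototype(duration = 1, Fs = 20000,
            events = data.frame(time = numeric(0), kind = character(0),
                                value = numeric(0)),
            render = NULL, seed = 1))

setValidity("SceneSpec", function(object) {
  msg <- character(0)
  if (object@duration <= 0) msg <- c(msg, "'duration' must be positive")
  if (!is.null(object@supraglottic) &&
      !methods::is(object@supraglottic, "OscillatorSpec"))
    msg <- c(msg, "'supraglottic' must be NULL or an OscillatorSpec")
  if (!is.null(object@render) && !methods::is(object@render, "RenderSpec"))
    msg <- c(msg, "'render' must be NULL or a RenderSpec")
  ev <- object@events
  if (nrow(ev)) {
    if (!all(c("time", "kind", "value") %in% names(ev)))
      msg <- c(msg, "'events' needs columns time, kind, value")
    else {
      if (is.unsorted(ev$time)) msg <- c(msg, "'events' must be sorted by time")
      if (any(ev$time < 0 | ev$time > object@duration))
        msg <- c(msg, "events outside [0, duration]")
      if (!all(ev$kind %in% c("frequency_jump", "glissando_start",
                              "regime_switch")))
        msg <- c(msg, "unknown event kind")
    }
  }
  ## Nyquist guard: Fs must exceed twice the highest glottal harmonic of
  ## interest (taken as 10 * max fo of the trajectory)
  fmax <- max(object@glottal@trajPar[seq_len(
    min(2L, length(object@glottal@trajPar)))])
  if (nrow(ev)) {
    jump <- ev$kind == "frequency_jump"
    if (any(jump)) fmax <- max(fmax, as.numeric(ev$value[jump]))
  }
  if (object@Fs <= 2 * 10 * fmax)
    msg <- c(msg, "'Fs' must exceed twice the highest harmonic of interest")
  if (!is.null(object@render) &&
      abs(object@render@fps - object@Fs) > 1e-9)
    msg <- c(msg, "render fps must equal the scene Fs (frame = sample)")
  if (length(msg)) msg else TRUE
})

#' Construct a SceneSpec
#'
#' @param glottal glottal \linkS4class{OscillatorSpec}
#' @param coupling \linkS4class{CouplingSpec}
#' @param supraglottic explicit supraglottic \linkS4class{OscillatorSpec},
#'   or \code{NULL} to derive it from the glottal trajectory and
#'   \code{ratioN}
#' @param duration scene duration (s)
#' @param Fs sampling rate (Hz)
#' @param events event data.frame (time, kind, value)
#' @param render optional \linkS4class{RenderSpec}
#' @param seed integer seed
#' @return a \linkS4class{SceneSpec}
#' @examples
#' spec <- sceneSpec(oscillatorSpec(fo = 136), couplingSpec(ratioN = 2),
#'                   duration = 0.5)
#' sc <- makeCoupledScene(spec)
#' names(channels(sc$recording))
#' @export
sceneSpec <- function(glottal = oscillatorSpec(),
                      coupling = couplingSpec(),
                      supraglottic = NULL, duration = 1, Fs = 20000,
                      events = data.frame(time = numeric(0),
                                          kind = character(0),
                                          value = numeric(0)),
                      render = NULL, seed = 1) {
  new("SceneSpec", glottal = glottal, supraglottic = supraglottic,
      coupling = coupling, duration = as.numeric(duration),
      Fs = as.numeric(Fs), events = events, render = render,
      seed = as.numeric(seed))
}

#' SegmentationProfile: contrast/threshold recipe for area segmentation
#'
#' @slot contrastGain multiplicative contrast gain
#' @slot contrastOffset additive contrast offset
#' @slot greyThreshold lower grey threshold in [0, 1]
#' @slot greyCeiling upper grey bound in [0, 1] (default 1); a supraglottic
#'   profile can set it below the glottal brightness to suppress the
#'   glottal region
#' @slot roi \code{c(x0, x1, y0, y1)} pixel rectangle or \code{NULL} (full
#'   frame)
#' @slot target \code{"glottal"} or \code{"supraglottic"}
#' @slot minRegionPx smallest connected region kept (despeckle)
#' @aliases SegmentationProfile-class
#' @exportClass SegmentationProfile
setClass("SegmentationProfile",
  representation(contrastGain = "numeric", contrastOffset = "numeric",
                 greyThreshold = "numeric", greyCeiling = "numeric",
                 roi = "ANY", target = "character", minRegionPx = "numeric"),
  prototype(contrastGain = 1, contrastOffset = 0, greyThreshold = 0.5,
            greyCeiling = 1, roi = NULL, target = "glottal",
            minRegionPx = 5))

setValidity("SegmentationProfile", function(object) {
  msg <- character(0)
  if (object@greyThreshold < 0 || object@greyThreshold > 1)
    msg <- c(msg, "'greyThreshold' must be in [0, 1]")
  if (object@greyCeiling < object@greyThreshold || object@greyCeiling > 1)
    msg <- c(msg, "'greyCeiling' must be in [greyThreshold, 1]")
  if (!is.finite(object@contrastGain))
    msg <- c(msg, "'contrastGain' must be finite")
  if (!is.null(object@roi) &&
      (length(object@roi) != 4L || any(object@roi < 1) ||
       object@roi[1] > object@roi[2] || object@roi[3] > object@roi[4]))
    msg <- c(msg, "'roi' must be c(x0, x1, y0, y1) with x0<=x1, y0<=y1")
  if (!object@target %in% c("glottal", "supraglottic"))
    msg <- c(msg, "'target' must be 'glottal' or 'supraglottic'")
  if (object@minRegionPx < 1)
    msg <- c(msg, "'minRegionPx' must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentationProfile
#'
#' @param greyThreshold lower grey threshold in [0, 1]
#' @param target \code{"glottal"} or \code{"supraglottic"}
#' @param contrastGain contrast gain
#' @param contrastOffset contrast offset
#' @param greyCeiling upper grey bound (set below the glottal brightness in
#'   a supraglottic profile to suppress the glottal region)
#' @param roi pixel rectangle \code{c(x0, x1, y0, y1)} or \code{NULL}
#' @param minRegionPx despeckle size (px)
#' @return a \linkS4class{SegmentationProfile}
#' @export
segmentationProfile <- function(greyThreshold = 0.5, target = "glottal",
                                contrastGain = 1, contrastOffset = 0,
                                greyCeiling = 1, roi = NULL,
                                minRegionPx = 5) {
  new("SegmentationProfile", contrastGain = as.numeric(contrastGain),
      contrastOffset = as.numeric(contrastOffset),
      greyThreshold = as.numeric(greyThreshold),
      greyCeiling = as.numeric(greyCeiling), roi = roi, target = target,
      minRegionPx = as.numeric(minRegionPx))
}

#' PSOptions: windowing and filtering options for phase synchrony
#'
#' The window length follows the variable-window rule
#' \code{Nwin = floor(Fs / foMin)} with \code{foMin = 0.2 * min(foIEGG,
#' foAudio)} for quasi-periodic (group-1) material and \code{foMin = 20 Hz}
#' for irregular (group-2) material.
#'
#' @slot group \code{"group1"} or \code{"group2"}
#' @slot foIEGG task-mean fo of the iEGG channel (Hz; group 1 only)
#' @slot foAudio task-mean fo of the audio channel (Hz; group 1 only)
#' @slot foMin derived minimum frequency (Hz)
#' @slot Fs sampling rate (Hz)
#' @slot Nwin window length (samples), \code{floor(Fs / foMin)}
#' @slot bandLow band-pass lower corner (Hz), \code{NA} = no filtering
#' @slot bandHigh band-pass upper corner (Hz), \code{NA} = no filtering
#' @slot hop hop between windows (samples); default \code{Nwin}
#'   (non-overlapping)
#' @slot edgeFraction fraction of samples excluded at each end
#' @aliases PSOptions-class
#' @exportClass PSOptions
setClass("PSOptions",
  representation(group = "character", foIEGG = "numeric", foAudio = "numeric",
                 foMin = "numeric", Fs = "numeric", Nwin = "numeric",
                 bandLow = "numeric", bandHigh = "numeric", hop = "numeric",
                 edgeFraction = "numeric"))

setValidity("PSOptions", function(object) {
  msg <- character(0)
  if (!object@group %in% c("group1", "group2"))
    msg <- c(msg, "'group' must be 'group1' or 'group2'")
  if (object@foMin <= 0) msg <- c(msg, "'foMin' must be positive")
  if (object@Nwin < 2) msg <- c(msg, "'Nwin' must be >= 2")
  if (object@hop <= 0) msg <- c(msg, "'hop' must be positive")
  if (!is.na(object@bandLow)) {
    if (!(object@bandLow < object@bandHigh &&
          object@bandHigh < object@Fs / 2))
      msg <- c(msg, "need bandLow < bandHigh < Fs/2")
  }
  if (object@edgeFraction < 0 || object@edgeFraction >= 0.5)
    msg <- c(msg, "'edgeFraction' must be in [0, 0.5)")
  if (length(msg)) msg else TRUE
})
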