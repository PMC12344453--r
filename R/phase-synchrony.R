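#' @include AllClasses.R
NULL

## analytic signal via the frequency-domain method: zero the negative
## frequencies, double the positive ones, keep DC (and Nyquist for even n)
.analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a signal
#'
#' The angle of the analytic signal x + jH(x), where H is the Hilbert
#' transform; the mean is removed first. Phases are returned wrapped to
#' (-pi, pi]; unwrapping is unnecessary for phase-synchrony computation
#' since only differences modulo 2 pi matter.
#'
#' @param s a \linkS4class{Signal} or numeric vector
#' @return numeric vector of phases (radians)
#' @export
instantaneousPhase <- function(s) {
  x <- asSamples(s)
  stopifnot2(length(x) > 1L, "signal too short")
  x <- x - mean(x)
  if (all(x == 0)) stop("all-zero signal has no phase", call. = FALSE)
  Arg(.analytic(x))
}

#' Pointwise phase synchrony of two signals
#'
#' The cosine of the absolute instantaneous phase difference,
#' \code{cos(|phi_a - phi_b|)}, per sample: +1 in-phase, -1 anti-phase
#' (180 degrees), 0 at quadrature (90 degrees) or when the prominent
#' frequencies stand in an integer ratio. Bounded in [-1, 1], exactly
#' symmetric under swapping the inputs, and invariant under positive
#' rescaling of either input (only phases enter).
#'
#' @param a,b \linkS4class{Signal}s (or numeric vectors) of equal length
#'   and sampling rate
#' @return numeric vector in [-1, 1]
#' @export
pointwisePS <- function(a, b) {
  if (methods::is(a, "Signal") && methods::is(b, "Signal"))
    stopifnot2(abs(a@Fs - b@Fs) < 1e-9, "sampling rates differ")
  xa <- asSamples(a); xb <- asSamples(b)
  stopifnot2(length(xa) == length(xb), "length mismatch")
  cos(abs(instantaneousPhase(xa) - instantaneousPhase(xb)))
}

#' Phase-synchrony options
#'
#' Builds a \linkS4class{PSOptions} with the variable-window rule
#' \code{Nwin = floor(Fs / foMin)}: \code{foMin = 0.2 * min(foIEGG,
#' foAudio)} for quasi-periodic group-1 material (so a window spans about
#' five periods of the slower fo) and \code{foMin = 20} Hz for irregular
#' group-2 material (1000 samples at 20 kHz).
#'
#' @param group \code{"group1"} or \code{"group2"}
#' @param Fs sampling rate (Hz)
#' @param foIEGG,foAudio task-mean fo of the iEGG and audio channels (Hz);
#'   required for group 1
#' @param bandpass \code{c(low, high)} corner frequencies in Hz, \code{NA}
#'   for no filtering, or \code{NULL} (default) for the automatic band
#'   \code{[0.5 * foMin, min(10 * foRef, 0.45 * Fs)]} with \code{foRef}
#'   the larger given fo (group 1) or \code{0.45 * Fs} as upper corner
#'   (group 2)
#' @param hop window hop in samples; default \code{Nwin} (non-overlapping)
#' @param edgeFraction fraction of samples dropped at each end to avoid
#'   Hilbert edge artefacts (default 0.02)
#' @return a \linkS4class{PSOptions}
#' @examples
#' psOptions("group2", Fs = 20000)@Nwin          # 1000
#' psOptions("group1", Fs = 20000, foIEGG = 68, foAudio = 68)@Nwin  # 1470
#' @export
psOptions <- function(group = c("group2", "group1"), Fs = 20000,
                      foIEGG = NULL, foAudio = NULL, bandpass = NULL,
                      hop = NULL, edgeFraction = 0.02) {
  group <- match.arg(group)
  if (group == "group1") {
    stopifnot2(!is.null(foIEGG) && !is.null(foAudio),
               "group 1 requires foIEGG and foAudio")
    foMin <- 0.2 * min(foIEGG, foAudio)
  } else {
    foMin <- 20
    if (is.null(foIEGG)) foIEGG <- NA_real_
    if (is.null(foAudio)) foAudio <- NA_real_
  }
  Nwin <- floor(Fs / foMin)
  if (is.null(bandpass)) {
    hi <- if (group == "group1") min(10 * max(foIEGG, foAudio), 0.45 * Fs)
          else 0.45 * Fs
    bandpass <- c(0.5 * foMin, hi)
  }
  if (anyNA(bandpass)) bandpass <- c(NA_real_, NA_real_)
  if (is.null(hop)) hop <- Nwin
  new("PSOptions", group = group, foIEGG = as.numeric(foIEGG),
      foAudio = as.numeric(foAudio), foMin = foMin, Fs = as.numeric(Fs),
      Nwin = Nwin, bandLow = bandpass[1L], bandHigh = bandpass[2L],
      hop = hop, edgeFraction = edgeFraction)
}

.bandpassZeroPhase <- function(x, low, high, Fs) {
  bf <- signal::butter(4, c(low, high) / (Fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

#' Windowed phase synchrony of two channels
#'
#' Optionally band-pass filters both inputs (zero-phase forward-backward
#' 4th-order Butterworth), computes the pointwise phase synchrony, and
#' summarizes consecutive windows of \code{Nwin} samples by their median,
#' 25% and 75% quantiles. The first and last \code{edgeFraction} of
#' samples are excluded from the statistics (Hilbert edge artefacts).
#' Windows where either channel is essentially silent are reported as
#' missing, not zero: a zero area waveform has no phase.
#'
#' @param a,b \linkS4class{Signal}s of equal length and sampling rate
#' @param opts a \linkS4class{PSOptions}
#' @return a \linkS4class{PSSeries}
#' @examples
#' t <- (0:39999) / 20000
#' a <- Signal(sin(2 * pi * 100 * t), 20000)
#' b <- Signal(sin(2 * pi * 100 * t - pi / 2), 20000)
#' ps <- windowedPS(a, b, psOptions("group2", Fs = 20000))
#' round(stats::median(psMedian(ps), na.rm = TRUE), 2)   # ~0: quadrature
#' @export
windowedPS <- function(a, b, opts) {
  methods::validObject(opts)
  xa <- asSamples(a); xb <- asSamples(b)
  stopifnot2(length(xa) == length(xb), "length mismatch")
  n <- length(xa)
  stopifnot2(opts@Nwin <= n, "Nwin exceeds the signal length")
  if (!is.na(opts@bandLow)) {
    xa <- .bandpassZeroPhase(xa, opts@bandLow, opts@bandHigh, opts@Fs)
    xb <- .bandpassZeroPhase(xb, opts@bandLow, opts@bandHigh, opts@Fs)
  }
  ps <- cos(abs(instantaneousPhase(xa) - instantaneousPhase(xb)))
  margin <- ceiling(opts@edgeFraction * n)
  lo <- margin + 1L
  hi <- n - margin
  starts <- seq(lo, hi - opts@Nwin + 1L, by = opts@hop)
  stopifnot2(length(starts) > 0L, "no complete window inside the edges")
  silTol <- 1e-9 * max(max(abs(xa)), max(abs(xb)))
  med <- q25 <- q75 <- cent <- nv <- numeric(length(starts))
  for (j in seq_along(starts)) {
    ii <- starts[j]:(starts[j] + opts@Nwin - 1L)
    cent[j] <- (stats::median(ii) - 1) / opts@Fs
    silent <- max(abs(xa[ii])) <= silTol || max(abs(xb[ii])) <= silTol
    if (silent) {
      med[j] <- q25[j] <- q75[j] <- NA_real_; nv[j] <- 0
    } else {
      w <- ps[ii]
      med[j] <- stats::median(w)
      q25[j] <- q7(w, 0.25)
      q75[j] <- q7(w, 0.75)
      nv[j] <- length(w)
    }
  }
  new("PSSeries", centers = cent, med = med, q25 = q25, q75 = q75,
      nValid = nv, options = opts)
}
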