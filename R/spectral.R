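#' @include AllClasses.R
NULL

#' Hann-windowed short-term Fourier spectrogram
#'
#' One-sided STFT magnitudes. The default 2048-sample window at 20 kHz
#' gives a bin spacing of about 9.8 Hz, enough to separate a fundamental
#' near 136 Hz from its half-frequency subharmonic and to inspect
#' frequency jumps. Magnitudes are unscaled \code{Mod} values, so
#' per-frame energy relates to signal energy through the window constant
#' \code{sum(hann^2)} (Parseval).
#'
#' @param s a \linkS4class{Signal}
#' @param windowLength Hann window length in samples (default 2048)
#' @param hop hop in samples (default \code{windowLength / 4})
#' @return a \linkS4class{Spectrogram}
#' @export
stftSpectrogram <- function(s, windowLength = 2048,
                            hop = windowLength %/% 4) {
  stopifnot2(methods::is(s, "Signal"), "'s' must be a Signal")
  stopifnot2(hop > 0 && hop <= windowLength, "need 0 < hop <= windowLength")
  x <- s@samples; Fs <- s@Fs
  stopifnot2(length(x) >= windowLength, "window longer than signal")
  w <- signal::hanning(windowLength)
  starts <- seq(1L, length(x) - windowLength + 1L, by = hop)
  nb <- windowLength %/% 2 + 1L
  mag <- matrix(0, nrow = nb, ncol = length(starts))
  for (j in seq_along(starts)) {
    seg <- x[starts[j]:(starts[j] + windowLength - 1L)] * w
    mag[, j] <- Mod(stats::fft(seg))[seq_len(nb)]
  }
  new("Spectrogram", mag = mag,
      freq = (seq_len(nb) - 1L) * Fs / windowLength,
      time = (starts - 1L + windowLength / 2) / Fs + s@t0,
      Fs = Fs, windowLength = windowLength, hop = hop)
}

.emptyEvents <- function() {
  data.frame(kind = character(0), tStart = numeric(0), tEnd = numeric(0),
             order = numeric(0), f1 = numeric(0), f2 = numeric(0),
             strength = numeric(0))
}

## merge runs of flagged spectrogram frames into events
.mergeRuns <- function(flag, times, minFrames) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minFrames
  data.frame(iStart = starts[keep], iEnd = ends[keep])
}

#' Detect subharmonic components
#'
#' For every spectrogram frame with a voiced fo estimate, tests whether a
#' spectral peak near fo/k (k = 2..maxOrder) exceeds a relative-magnitude
#' threshold against the fo peak; consecutive detections of the same order
#' merge into one event. Subharmonics at fo/2 are the spectral signature
#' of period-doubling (amplitude-alternating cycles).
#'
#' @param s the \linkS4class{Signal} to analyse
#' @param foTrack \linkS4class{FoTrack} giving the reference fo
#' @param maxOrder largest subharmonic order tested (default 4)
#' @param threshold minimum magnitude of the fo/k peak relative to the fo
#'   peak (default 0.05)
#' @param windowLength STFT window (default 2048)
#' @param minFrames shortest run of consecutive detections kept
#' @return data.frame of events: kind, tStart, tEnd, order, f1 (the
#'   subharmonic frequency), f2 (the reference fo), strength (mean
#'   relative magnitude)
#' @export
detectSubharmonics <- function(s, foTrack, maxOrder = 4, threshold = 0.05,
                               windowLength = 2048, minFrames = 2) {
  sg <- stftSpectrogram(s, windowLength = windowLength,
                        hop = windowLength %/% 2)
  df <- sg@freq[2L] - sg@freq[1L]
  foAt <- stats::approx(foTrack@times, foTrack@fo, xout = sg@time,
                        rule = 2)$y
  nT <- ncol(sg@mag)
  hit <- matrix(FALSE, nrow = maxOrder, ncol = nT)
  rel <- matrix(0, nrow = maxOrder, ncol = nT)
  ## magnitude of a genuine local spectral maximum near f0; the skirt of a
  ## neighbouring strong component is monotone, hence rejected
  peakMag <- function(m, f0, tol) {
    sel <- which(abs(sg@freq - f0) <= tol)
    sel <- sel[sel > 1L & sel < length(m)]
    sel <- sel[m[sel] >= m[sel - 1L] & m[sel] >= m[sel + 1L]]
    if (!length(sel)) return(0)
    max(m[sel])
  }
  for (j in seq_len(nT)) {
    f0 <- foAt[j]
    if (is.na(f0) || f0 <= 0) next
    m <- sg@mag[, j]
    tol0 <- max(2 * df, 0.04 * f0)
    mF0 <- peakMag(m, f0, tol0)
    if (mF0 <= 0) next
    for (k in 2:maxOrder) {
      fk <- f0 / k
      if (fk < 1.5 * df) next
      tolK <- max(1.5 * df, 0.04 * fk)
      mk <- peakMag(m, fk, tolK)
      if (mk >= threshold * mF0) {
        hit[k, j] <- TRUE
        rel[k, j] <- mk / mF0
      }
    }
  }
  out <- .emptyEvents()
  for (k in 2:maxOrder) {
    runs <- .mergeRuns(hit[k, ], sg@time, minFrames)
    for (i in seq_len(nrow(runs))) {
      jj <- runs$iStart[i]:runs$iEnd[i]
      out <- rbind(out, data.frame(
        kind = "subharmonic", tStart = sg@time[runs$iStart[i]],
        tEnd = sg@time[runs$iEnd[i]], order = k,
        f1 = mean(foAt[jj]) / k, f2 = mean(foAt[jj]),
        strength = mean(rel[k, jj])))
    }
  }
  out
}

#' Detect discrete frequency jumps in an fo track
#'
#' Change-point detection: a jump at time t requires the medians of two
#' flanking windows (each \code{flank} seconds long, separated by
#' \code{maxGap}) to differ by at least \code{minStep}, with both flanks
#' stable (their internal spread small relative to the step), so that a
#' continuous glissando does not trigger.
#'
#' @param foTrack an \linkS4class{FoTrack}
#' @param minStep smallest step reported (Hz, default 5)
#' @param flank flanking-window length (s, default 0.1)
#' @param maxGap longest admissible transition (s, default 0.05)
#' @return data.frame of events: kind, tStart, tEnd, f1 (pre fo), f2
#'   (post fo), strength (step size in Hz)
#' @export
detectFrequencyJump <- function(foTrack, minStep = 5, flank = 0.1,
                                maxGap = 0.05) {
  tt <- foTrack@times; fo <- foTrack@fo
  if (all(is.na(fo))) stop("fo track is fully unvoiced", call. = FALSE)
  nT <- length(tt)
  cand <- logical(nT); step <- pre <- post <- rep(NA_real_, nT)
  for (j in seq_len(nT)) {
    lSel <- which(tt >= tt[j] - maxGap / 2 - flank &
                  tt < tt[j] - maxGap / 2 & !is.na(fo))
    rSel <- which(tt > tt[j] + maxGap / 2 &
                  tt <= tt[j] + maxGap / 2 + flank & !is.na(fo))
    if (length(lSel) < 3L || length(rSel) < 3L) next
    pm <- stats::median(fo[lSel]); qm <- stats::median(fo[rSel])
    st <- qm - pm
    if (abs(st) < minStep) next
    spreadOK <- stats::IQR(fo[lSel]) <= max(1, 0.25 * abs(st)) &&
      stats::IQR(fo[rSel]) <= max(1, 0.25 * abs(st))
    if (!spreadOK) next
    cand[j] <- TRUE; step[j] <- st; pre[j] <- pm; post[j] <- qm
  }
  out <- .emptyEvents()
  if (!any(cand)) return(out)
  r <- rle(cand)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    jj <- starts[i]:ends[i]
    jBest <- jj[which.max(abs(step[jj]))]
    out <- rbind(out, data.frame(
      kind = "frequency_jump", tStart = tt[jBest], tEnd = tt[jBest],
      order = NA_real_, f1 = pre[jBest], f2 = post[jBest],
      strength = abs(step[jBest])))
  }
  out
}

## classify the spectral peaks of one frame into harmonic families
.frameBiphonic <- function(freq, m, peakRel, maxOrder, ratioTol, df) {
  pk <- which(diff(sign(diff(m))) == -2) + 1L
  pk <- pk[m[pk] >= peakRel * max(m) & freq[pk] >= 20]
  if (length(pk) < 2L) return(FALSE)
  f <- freq[pk]
  near <- function(f, base) {
    mm <- round(f / base)
    mm >= 1 & abs(f - mm * base) <= pmax(2 * df, 0.035 * f)
  }
  f1 <- f[1L]
  un <- f[!near(f, f1)]
  if (!length(un)) return(FALSE)            # one harmonic family
  f2 <- un[1L]
  left <- un[!near(un, f2)]
  if (length(left)) return(FALSE)           # >2 families: broadband, not
                                            # two-component biphonation
  r <- f2 / f1
  for (q in 1:maxOrder) for (p in 1:maxOrder)
    if (abs(r - p / q) <= ratioTol / q^2) return(FALSE)
  TRUE
}

#' Detect biphonation (two incommensurate components)
#'
#' Frames whose spectral peaks form exactly two harmonic families with a
#' frequency ratio not close to any small-integer ratio p/q are flagged;
#' runs of flagged frames merge into events. The integer-ratio tolerance
#' shrinks as 1/q^2, the natural noise scale for rational approximation,
#' so an 8:5 near-miss (e.g. the golden ratio) is still biphonic while a
#' noisy 2:1 is not. Broadband (chaotic) frames, whose peaks cannot be
#' explained by two families, are not flagged.
#'
#' @param s a \linkS4class{Signal}
#' @param windowLength STFT window (default 2048)
#' @param maxOrder largest integer in the harmonic-ratio test (default 8)
#' @param ratioTol base tolerance of the p/q test (default 0.05)
#' @param peakRel relative magnitude floor for peaks (default 0.1)
#' @param minFrames shortest run kept (default 3)
#' @return data.frame of events: kind, tStart, tEnd, f1, f2, strength
#' @export
detectBiphonation <- function(s, windowLength = 2048, maxOrder = 8,
                              ratioTol = 0.05, peakRel = 0.1,
                              minFrames = 3) {
  sg <- stftSpectrogram(s, windowLength = windowLength,
                        hop = windowLength %/% 2)
  df <- sg@freq[2L] - sg@freq[1L]
  nT <- ncol(sg@mag)
  flag <- logical(nT)
  for (j in seq_len(nT)) {
    m <- sg@mag[, j]
    if (max(m) <= 0) next
    flag[j] <- .frameBiphonic(sg@freq, m, peakRel, maxOrder, ratioTol, df)
  }
  runs <- .mergeRuns(flag, sg@time, minFrames)
  out <- .emptyEvents()
  for (i in seq_len(nrow(runs))) {
    out <- rbind(out, data.frame(
      kind = "biphonation", tStart = sg@time[runs$iStart[i]],
      tEnd = sg@time[runs$iEnd[i]], order = NA_real_, f1 = NA_real_,
      f2 = NA_real_, strength = (runs$iEnd[i] - runs$iStart[i] + 1) / nT))
  }
  out
}

#' Windowed periodicity index
#'
#' Per non-overlapping window, the maximum of the normalized (bias
#' corrected) autocorrelation over lags of at least one expected period.
#' Near 1 for periodic oscillation, small for noise or chaos; used to
#' separate quasi-periodic from irregular regimes.
#'
#' @param s a \linkS4class{Signal}
#' @param window window length in seconds (must cover >= 2 expected
#'   periods when \code{foExpected} is given)
#' @param foExpected expected fo (Hz); sets the minimum lag to about one
#'   period. Default searches lags from 1/600 s.
#' @return data.frame with columns \code{time} (window centres) and
#'   \code{index} in [0, 1] (\code{NA} for silent windows)
#' @export
periodicityIndex <- function(s, window, foExpected = NULL) {
  stopifnot2(methods::is(s, "Signal"), "'s' must be a Signal")
  Fs <- s@Fs
  Nw <- round(window * Fs)
  stopifnot2(Nw <= nSamples(s), "window longer than signal")
  if (!is.null(foExpected))
    stopifnot2(window >= 2 / foExpected, "window must cover >= 2 periods")
  minLag <- if (is.null(foExpected)) max(2L, round(Fs / 600))
            else max(2L, round(0.8 * Fs / foExpected))
  maxLag <- Nw %/% 2L
  stopifnot2(minLag < maxLag, "window too short for the expected period")
  starts <- seq(1L, nSamples(s) - Nw + 1L, by = Nw)
  idx <- times <- numeric(length(starts))
  for (j in seq_along(starts)) {
    xw <- s@samples[starts[j]:(starts[j] + Nw - 1L)]
    xw <- xw - mean(xw)
    times[j] <- (starts[j] - 1L + Nw / 2) / Fs + s@t0
    v <- sum(xw^2)
    if (v <= 0) { idx[j] <- NA; next }
    N2 <- .nextPow2(2L * Nw)
    ac <- Re(stats::fft(Mod(stats::fft(c(xw, rep(0, N2 - Nw))))^2,
                        inverse = TRUE))[seq_len(maxLag + 1L)] / N2
    lags <- minLag:maxLag
    r <- (ac[lags + 1L] / ac[1L]) * (Nw / (Nw - lags))
    idx[j] <- min(1, max(r))
  }
  data.frame(time = times, index = pmax(0, idx))
}
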