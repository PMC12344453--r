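#' @include AllClasses.R
NULL

.nextPow2 <- function(n) 2^ceiling(log2(n))

## YIN per-frame analysis: difference function via FFT cross-correlation,
## cumulative-mean-normalized difference (CMNDF), absolute-threshold
## candidate pick with parabolic interpolation.
.yinFrame <- function(xf, W, tauMin, tauMax, threshold) {
  L <- length(xf)
  N2 <- .nextPow2(L + W)
  A <- stats::fft(c(xf, rep(0, N2 - L)))
  B <- stats::fft(c(xf[seq_len(W)], rep(0, N2 - W)))
  cc <- Re(stats::fft(A * Conj(B), inverse = TRUE)) / N2
  cs <- cumsum(c(0, xf^2))
  taus <- 0:tauMax
  powW <- cs[taus + W + 1L] - cs[taus + 1L]
  d <- powW[1L] + powW - 2 * cc[taus + 1L]
  d[d < 0] <- 0                                   # numerical guard
  ## CMNDF
  dp <- rep(1, tauMax + 1L)
  run <- cumsum(d[-1L])
  dp[-1L] <- d[-1L] * (1:tauMax) / pmax(run, .Machine$double.eps)
  rng <- (tauMin + 1L):(tauMax + 1L)
  below <- which(dp[rng] < threshold)
  if (length(below)) {
    i <- rng[below[1L]]
    while (i < tauMax + 1L && dp[i + 1L] < dp[i]) i <- i + 1L
  } else {
    i <- rng[which.min(dp[rng])]
  }
  ## parabolic interpolation of the minimum
  tau <- i - 1L
  if (i > 2L && i < tauMax + 1L) {
    a <- dp[i - 1L]; b <- dp[i]; c <- dp[i + 1L]
    den <- a - 2 * b + c
    if (abs(den) > .Machine$double.eps) {
      off <- 0.5 * (a - c) / den
      if (abs(off) < 1) tau <- tau + off
    }
  }
  c(tau = tau, aperiodicity = dp[i])
}

#' Track the fundamental frequency of a signal
#'
#' A YIN-family estimator: per frame, the difference function is computed
#' by FFT cross-correlation, normalized by its cumulative mean (CMNDF),
#' and the first dip below the absolute threshold (refined by parabolic
#' interpolation) gives the period candidate. Frames whose CMNDF minimum
#' exceeds \code{voicingThreshold}, or whose energy is negligible relative
#' to the signal, are flagged unvoiced. Voiced estimates are median
#' smoothed across frames to suppress octave errors.
#'
#' @param s a \linkS4class{Signal}
#' @param fmin,fmax search band in Hz (\code{fmin < fmax < Fs/2})
#' @param hop frame hop in samples (default 10 ms)
#' @param threshold CMNDF absolute threshold (default 0.15)
#' @param voicingThreshold CMNDF minimum above which a frame is unvoiced
#' @param medianK median-smoothing length (odd; 1 disables)
#' @return an \linkS4class{FoTrack}
#' @examples
#' s <- Signal(sin(2 * pi * 100 * (0:19999) / 20000), 20000, label = "audio")
#' tr <- estimateFo(s, fmin = 60, fmax = 400)
#' mean(foValues(tr), na.rm = TRUE)
#' @export
estimateFo <- function(s, fmin = 50, fmax = 600, hop = NULL,
                       threshold = 0.15, voicingThreshold = 0.35,
                       medianK = 5) {
  stopifnot2(methods::is(s, "Signal"), "'s' must be a Signal")
  stopifnot2(fmin > 0, "degenerate fmin <= 0")
  stopifnot2(fmin < fmax && fmax < s@Fs / 2, "need fmin < fmax < Fs/2")
  x <- s@samples; Fs <- s@Fs
  stopifnot2(length(x) >= ceiling(2 * Fs / fmin),
             "signal shorter than 2/fmin")
  tauMin <- max(2L, floor(Fs / fmax))
  tauMax <- ceiling(Fs / fmin)
  W <- tauMax
  L <- 2L * tauMax
  if (is.null(hop)) hop <- max(1L, round(0.010 * Fs))
  starts <- seq(1L, length(x) - L + 1L, by = hop)
  rmsAll <- sqrt(mean(x^2))
  times <- fo <- voi <- numeric(length(starts))
  for (j in seq_along(starts)) {
    xf <- x[starts[j]:(starts[j] + L - 1L)]
    times[j] <- (starts[j] - 1L + L / 2) / Fs + s@t0
    frms <- sqrt(mean(xf^2))
    if (frms == 0 || frms < 1e-6 * rmsAll) {
      fo[j] <- NA; voi[j] <- 0; next
    }
    r <- .yinFrame(xf, W, tauMin, tauMax, threshold)
    voi[j] <- max(0, 1 - r["aperiodicity"])
    if (r["aperiodicity"] > voicingThreshold || r["tau"] <= 0) {
      fo[j] <- NA
    } else {
      fo[j] <- Fs / r["tau"]
    }
  }
  if (medianK > 1) {
    v <- which(!is.na(fo))
    if (length(v) >= 3) {
      k <- min(medianK, length(v) - (1 - length(v) %% 2))
      if (k >= 3) fo[v] <- stats::runmed(fo[v], k)
    }
  }
  FoTrack(times, fo, voi, channel = s@label,
          settings = list(fmin = fmin, fmax = fmax, hop = hop,
                          threshold = threshold,
                          voicingThreshold = voicingThreshold,
                          medianK = medianK))
}

#' Segment mean and standard deviation of an fo track
#'
#' The conventional per-segment summary (mean +/- SD over voiced frames of
#' a sustained interval).
#'
#' @param track an \linkS4class{FoTrack}
#' @param tStart,tEnd segment bounds in seconds (defaults: whole track)
#' @return list with \code{mean}, \code{sd} and \code{nVoiced}
#' @export
foSegmentStats <- function(track, tStart = -Inf, tEnd = Inf) {
  sel <- track@times >= tStart & track@times <= tEnd & !is.na(track@fo)
  vals <- track@fo[sel]
  list(mean = if (length(vals)) mean(vals) else NA_real_,
       sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
       nVoiced = length(vals))
}
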