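#' @include utils.R
NULL

## fo trajectory of an oscillator at times t, with scene events applied
## (frequency_jump overrides fo from the event time on; glissando_start
## glides from the current fo to the event value by the end of the scene).
.foTrajectory <- function(osc, t, events = NULL, duration = max(t)) {
  p <- osc@trajPar
  fo <- switch(osc@trajType,
    constant = rep(p[1L], length(t)),
    glissando = {
      f0 <- p[1L]; f1 <- p[2L]; ta <- p[3L]; tb <- p[4L]
      u <- pmin(1, pmax(0, (t - ta) / max(tb - ta, 1e-12)))
      f0 + (f1 - f0) * u
    },
    step = ifelse(t < p[3L], p[1L], p[2L]))
  if (!is.null(events) && nrow(events)) {
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      if (ev$kind == "frequency_jump") {
        fo[t >= ev$time] <- as.numeric(ev$value)
      } else if (ev$kind == "glissando_start") {
        sel <- t >= ev$time
        if (any(sel)) {
          f0 <- fo[which(sel)[1L]]
          u <- (t[sel] - ev$time) / max(duration - ev$time, 1e-12)
          fo[sel] <- f0 + (as.numeric(ev$value) - f0) * u
        }
      }
    }
  }
  fo
}

## waveform value from instantaneous phase (radians); cycleAmp: optional
## per-cycle amplitude factors indexed by floor(phi / 2pi) + 1
.pulseFromPhase <- function(phi, shape, oq, cycleAmp = NULL) {
  u <- (phi / (2 * pi)) %% 1
  w <- switch(shape,
    raised_cosine_pulse = ifelse(u < oq, 0.5 * (1 - cos(2 * pi * u / oq)), 0),
    impulse_train = as.numeric(u < 0.05),
    sinusoid = 0.5 * (1 - cos(phi)))
  if (!is.null(cycleAmp)) {
    idx <- pmax(1L, pmin(length(cycleAmp), floor(phi / (2 * pi)) + 1L))
    w <- w * cycleAmp[idx]
  }
  w
}

## chaotic supraglottic cycles: lengths driven by a logistic map at r = 4
## scaled to +/-20% jitter around the nominal period; per-cycle amplitude
## and pulse width (open quotient) are driven by two further logistic
## streams, since an aperiodic regime is irregular in all three.
.chaoticCycles <- function(t, foNominal, duration) {
  x <- stats::runif(1, 0.1, 0.9)
  y <- stats::runif(1, 0.1, 0.9)
  z <- stats::runif(1, 0.1, 0.9)
  bounds <- 0; amps <- oqs <- numeric(0)
  while (bounds[length(bounds)] < duration) {
    tk <- bounds[length(bounds)]
    f <- foNominal[min(length(foNominal),
                       max(1L, findInterval(tk, t)))]
    x <- 4 * x * (1 - x)
    y <- 4 * y * (1 - y)
    z <- 4 * z * (1 - z)
    L <- (1 / f) * (1 + 0.4 * (x - 0.5))
    bounds <- c(bounds, tk + L)
    amps <- c(amps, 0.2 + y)
    oqs <- c(oqs, 0.3 + 0.4 * z)
  }
  list(bounds = bounds, amps = amps, oqs = oqs)
}

#' Generate a synthetic coupled-oscillator phonation scene
#'
#' Synthesizes a multi-channel \linkS4class{Recording} from a
#' \linkS4class{SceneSpec}: a glottal pulse-train oscillator and a
#' supraglottic oscillator that is either tightly entrained (locked at an
#' integer ratio n:1 with a fixed phase offset), slowly drifting,
#' biphonic (irrational frequency ratio) or chaotic (logistic-map cycle
#' jitter). Channels:
#' \describe{
#'   \item{GAW}{glottal area waveform (non-negative pulse train)}
#'   \item{SAW}{supraglottic area waveform}
#'   \item{iEGG}{glottal pulse train whose pulse amplitudes are reduced by
#'     \code{subharmonicDepth} on cycles coinciding with supraglottic
#'     contact, mimicking period-doubling amplitude alternation}
#'   \item{audio}{weighted mix of the (modulated) glottal train and the
#'     supraglottic waveform derivative, each max-abs normalized before
#'     weighting}
#' }
#' Additive Gaussian noise at \code{noiseSnrDb} is applied independently
#' per channel. Everything is deterministic given \code{spec@seed}.
#'
#' @param spec a valid \linkS4class{SceneSpec}
#' @param audioWeights \code{c(glottal, supraglotticDerivative)} mixing
#'   weights for the audio-like channel
#' @return list with elements \code{recording} (a
#'   \linkS4class{Recording}, including rendered frames when
#'   \code{spec@render} is set), \code{truth} (data.frame: time,
#'   foGlottal, foSupraglottic, ratio; attributes \code{events} and
#'   \code{phaseOffset}) and, when rendered, \code{trueAreas} (per-frame
#'   pixel areas)
#' @examples
#' sc <- makeCoupledScene(sceneSpec(oscillatorSpec(fo = 136),
#'                                  couplingSpec(ratioN = 2),
#'                                  duration = 0.25))
#' mean(sc$truth$ratio)
#' @export
makeCoupledScene <- function(spec, audioWeights = c(0.7, 0.3)) {
  methods::validObject(spec)
  Fs <- spec@Fs
  n <- round(spec@duration * Fs)
  t <- (seq_len(n) - 1L) / Fs
  cpl <- spec@coupling
  ratio <- cpl@ratioN

  foG <- .foTrajectory(spec@glottal, t, spec@events, spec@duration)
  phiG <- 2 * pi * cumsum(c(0, foG[-n])) / Fs

  ## regime timeline (regime_switch events change it mid-scene)
  regimes <- rep(cpl@regime, n)
  if (nrow(spec@events)) {
    sw <- spec@events[spec@events$kind == "regime_switch", , drop = FALSE]
    for (i in seq_len(nrow(sw)))
      regimes[t >= sw$time[i]] <- as.character(sw$value[i])
  }

  out <- localSeed(spec@seed, {
    ## supraglottic phase / waveform
    foSnom <- if (!is.null(spec@supraglottic))
      .foTrajectory(spec@supraglottic, t, NULL, spec@duration)
    else foG / ratio

    sWave <- numeric(n); foS <- numeric(n)
    segStart <- c(1L, which(regimes[-1L] != regimes[-n]) + 1L)
    segEnd <- c(segStart[-1L] - 1L, n)
    phiCarry <- cpl@phaseOffset
    for (k in seq_along(segStart)) {
      idx <- segStart[k]:segEnd[k]
      reg <- regimes[idx[1L]]
      if (reg == "locked" && is.null(spec@supraglottic)) {
        ## tight entrainment: supraglottic phase is the glottal phase
        ## divided by n, plus a fixed offset -- locking survives glissandi
        phiS <- phiG[idx] / ratio + cpl@phaseOffset
        foS[idx] <- foG[idx] / ratio
        sWave[idx] <- .pulseFromPhase(phiS, "raised_cosine_pulse", 0.5)
      } else if (reg == "chaotic") {
        cyc <- .chaoticCycles(t[idx], foSnom[idx], t[idx[length(idx)]] + 1 / Fs)
        ci <- findInterval(t[idx], cyc$bounds + t[idx[1L]] - cyc$bounds[1L])
        ci <- pmax(1L, pmin(length(cyc$amps), ci))
        lo <- cyc$bounds[ci] + t[idx[1L]] - cyc$bounds[1L]
        len <- cyc$bounds[ci + 1L] - cyc$bounds[ci]
        u <- (t[idx] - lo) / len
        foS[idx] <- 1 / len
        oqv <- cyc$oqs[ci]
        sWave[idx] <- ifelse(u < oqv,
                             0.5 * (1 - cos(2 * pi * u / oqv)), 0) *
          cyc$amps[ci]
      } else {
        f <- switch(reg,
          locked = foSnom[idx],
          drifting = foSnom[idx] * (1 + 0.03 * sin(2 * pi * 0.7 * t[idx])),
          biphonation = if (is.null(spec@supraglottic))
            foG[idx] / (ratio + 0.6180339887) else
            foSnom[idx] / 1.6180339887 * 1.0)
        foS[idx] <- f
        dphi <- 2 * pi * f / Fs
        phiS <- phiCarry + cumsum(c(0, dphi[-length(dphi)]))
        phiCarry <- phiS[length(phiS)] + dphi[length(dphi)]
        shape <- if (!is.null(spec@supraglottic))
          spec@supraglottic@pulseShape else "raised_cosine_pulse"
        oq <- if (!is.null(spec@supraglottic))
          spec@supraglottic@openQuotient else 0.5
        sWave[idx] <- .pulseFromPhase(phiS, shape, oq)
      }
    }
    sAmp <- if (!is.null(spec@supraglottic)) spec@supraglottic@amplitude else 1
    sWave <- sWave * sAmp

    ## glottal waveforms: clean area (GAW) and amplitude-modulated train
    ## (iEGG); modulation reduces every cycle not aligned with the
    ## supraglottic cycle start by (1 - depth)
    gWave <- spec@glottal@amplitude *
      .pulseFromPhase(phiG, spec@glottal@pulseShape,
                      spec@glottal@openQuotient)
    depth <- cpl@subharmonicDepth
    if (depth > 0 && ratio >= 2) {
      nc <- floor(max(phiG) / (2 * pi)) + 2L
      cycAmp <- ifelse((seq_len(nc) - 1L) %% ratio == 0L, 1, 1 - depth)
      gMod <- spec@glottal@amplitude *
        .pulseFromPhase(phiG, spec@glottal@pulseShape,
                        spec@glottal@openQuotient, cycleAmp = cycAmp)
    } else gMod <- gWave

    dS <- c(0, diff(sWave)) * Fs
    nrm <- function(x) if (max(abs(x)) > 0) x / max(abs(x)) else x
    audio <- audioWeights[1L] * nrm(gMod) + audioWeights[2L] * nrm(dS)

    addCh <- function(x) {
      if (is.finite(cpl@noiseSnrDb) && max(abs(x)) > 0) {
        p <- mean(x^2)
        x + stats::rnorm(n, sd = sqrt(p / 10^(cpl@noiseSnrDb / 10)))
      } else x
    }
    list(audio = addCh(audio), iEGG = addCh(gMod), GAW = addCh(gWave),
         SAW = addCh(sWave), foS = foS, sClean = sWave, gClean = gWave)
  })

  chans <- list(
    audio = Signal(out$audio, Fs, label = "audio"),
    iEGG = Signal(out$iEGG, Fs, label = "iEGG"),
    GAW = Signal(out$GAW, Fs, label = "GAW"),
    SAW = Signal(out$SAW, Fs, label = "SAW"))

  truth <- data.frame(time = t, foGlottal = foG, foSupraglottic = out$foS,
                      ratio = foG / out$foS)
  attr(truth, "events") <- spec@events
  attr(truth, "phaseOffset") <- cpl@phaseOffset

  res <- list(recording = Recording(chans, Fs = Fs), truth = truth)

  if (!is.null(spec@render)) {
    rs <- spec@render
    gw <- out$gClean; sw <- out$sClean
    aG <- if (max(gw) > 0) gw / max(gw) * rs@glottalMaxArea else gw
    aS <- if (max(sw) > 0) sw / max(sw) * rs@supraMaxArea else sw
    rend <- renderFrames(
      AreaWaveform(aG, fps = rs@fps, target = "glottal"),
      AreaWaveform(aS, fps = rs@fps, target = "supraglottic"), rs)
    res$recording@frames <- rend$stack
    res$trueAreas <- rend$trueAreas
  }
  res
}

#' Add Gaussian noise at a prescribed SNR
#'
#' @param signal a \linkS4class{Signal}
#' @param snrDb signal-to-noise ratio in dB; \code{Inf} returns the input
#'   unchanged
#' @param seed integer seed; the caller's RNG state is untouched
#' @return the noisy \linkS4class{Signal}
#' @export
addNoise <- function(signal, snrDb, seed = 1) {
  stopifnot2(methods::is(signal, "Signal"), "'signal' must be a Signal")
  stopifnot2(is.finite(snrDb) || is.infinite(snrDb) && snrDb > 0,
             "'snrDb' must be a real number or Inf")
  if (is.infinite(snrDb)) return(signal)
  p <- mean(signal@samples^2)
  if (p == 0)
    stop("cannot set a finite SNR on a zero-power signal", call. = FALSE)
  noisy <- localSeed(seed, {
    signal@samples + stats::rnorm(nSamples(signal),
                                  sd = sqrt(p / 10^(snrDb / 10)))
  })
  Signal(noisy, Fs = signal@Fs, t0 = signal@t0, label = signal@label)
}
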