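# shared fixtures, built in code

FS <- 20000

sinusoidSignal <- function(f, dur = 2, Fs = FS, phase = 0, amp = 1,
                           label = "other") {
  t <- (seq_len(round(dur * Fs)) - 1) / Fs
  Signal(amp * sin(2 * pi * f * t + phase), Fs, label = label)
}

# a locked n:1 scene with sensible defaults for quick tests
quickScene <- function(fo = 136, n = 2, dur = 0.5, seed = 1, depth = 0,
                       regime = "locked", snr = Inf, ...) {
  makeCoupledScene(sceneSpec(
    oscillatorSpec(fo = fo),
    couplingSpec(ratioN = n, regime = regime, subharmonicDepth = depth,
                 noiseSnrDb = snr),
    duration = dur, seed = seed, ...))
}

smallRender <- function(frameSize = c(128, 128), fps = 1000,
                        glottalMaxArea = 600, supraMaxArea = 1500) {
  renderSpec(frameSize = frameSize, fps = fps,
             glottalMaxArea = glottalMaxArea, supraMaxArea = supraMaxArea)
}

# dominant DFT frequency of a vector
fftPeakHz <- function(x, Fs) {
  x <- x - mean(x)
  m <- Mod(stats::fft(x))[seq_len(floor(length(x) / 2))]
  (which.max(m) - 1) * Fs / length(x)
}

# brute-force normalized autocorrelation (unbiased) at a set of lags
acfOracle <- function(x, lags) {
  x <- x - mean(x)
  n <- length(x)
  v <- sum(x^2) / n
  vapply(lags, function(k) {
    mean(x[seq_len(n - k)] * x[(k + 1):n]) / v
  }, numeric(1))
}
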