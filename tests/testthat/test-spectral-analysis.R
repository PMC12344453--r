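test_that("fo tracking recovers a clean tone within 1% and stays voiced", {
  for (f in c(100, 236.5, 440)) {
    tr <- estimateFo(sinusoidSignal(f, dur = 1), fmin = 60, fmax = 600)
    expect_true(all(!is.na(foValues(tr))))
    expect_lt(abs(mean(foValues(tr)) - f) / f, 0.01)
  }
})

test_that("silence (tiny noise) is fully unvoiced", {
  set.seed(5)
  s <- Signal(rnorm(20000, sd = 1e-6), FS)
  tr <- estimateFo(s, 60, 400)
  expect_true(all(is.na(foValues(tr))))
  expect_true(all(voicingConfidence(tr) < 0.65))
})

test_that("fo estimation avoids octave errors on clean input at SNR >= 30 dB", {
  for (seed in 1:6) {
    set.seed(seed)
    f <- runif(1, 90, 260)
    sc <- quickScene(fo = f, n = 1, dur = 0.5, seed = seed, snr = 30)
    tr <- estimateFo(sc$recording[["GAW"]], 50, 600)
    v <- foValues(tr)[!is.na(foValues(tr))]
    expect_gt(length(v), 0)
    expect_true(all(abs(v - f) / f < 0.25))   # never at f/2 or 2f
  }
})

test_that("degenerate fo-tracking inputs are rejected", {
  s <- sinusoidSignal(100, dur = 0.02)
  expect_error(estimateFo(s, fmin = 50, fmax = 400), "shorter")
  expect_error(estimateFo(sinusoidSignal(100, 1), fmin = 0, fmax = 400),
               "fmin")
  expect_error(estimateFo(sinusoidSignal(100, 1), fmin = 50, fmax = 2e4),
               "Fs/2")
})

test_that("spectrogram localizes tones and respects linearity bounds", {
  s <- sinusoidSignal(1000, dur = 0.5)
  sg <- stftSpectrogram(s)
  binHz <- sg@freq[2] - sg@freq[1]
  peaks <- sg@freq[apply(sg@mag, 2, which.max)]
  expect_true(all(abs(peaks - 1000) <= binHz))
  # 68 + 136 Hz resolve into two distinct peaks with the 2048 window
  s2 <- Signal(sin(2 * pi * 68 * (0:19999) / FS) +
               sin(2 * pi * 136 * (0:19999) / FS), FS)
  sg2 <- stftSpectrogram(s2, 2048)
  m <- sg2@mag[, 3]
  loc <- which(diff(sign(diff(m))) == -2) + 1
  loc <- loc[m[loc] > 0.1 * max(m)]
  expect_equal(sort(sg2@freq[loc]), c(68, 136), tolerance = binHz)
  # all-zero signal: all-zero magnitudes
  expect_true(all(stftSpectrogram(Signal(numeric(4096), FS))@mag == 0))
  expect_error(stftSpectrogram(Signal(numeric(100), FS)), "longer")
  # triangle inequality per bin
  a <- samples(quickScene(fo = 120, dur = 0.3)$recording[["iEGG"]])
  b <- samples(quickScene(fo = 190, dur = 0.3, seed = 2)$recording[["iEGG"]])
  ma <- stftSpectrogram(Signal(a, FS))@mag
  mb <- stftSpectrogram(Signal(b, FS))@mag
  mab <- stftSpectrogram(Signal(a + b, FS))@mag
  expect_true(all(mab <= ma + mb + 1e-9))
})

test_that("subharmonic detector flags a constructed fo/2 component and nothing on a pure tone", {
  t <- (0:39999) / FS
  f <- 150
  s <- Signal(sin(2 * pi * f * t) + 0.3 * sin(2 * pi * f / 2 * t), FS)
  track <- FoTrack(seq(0.05, 1.95, 0.05), rep(f, 39))
  ev <- detectSubharmonics(s, track)
  expect_gt(nrow(ev), 0)
  expect_true(all(ev$order == 2))
  pure <- detectSubharmonics(Signal(sin(2 * pi * f * t), FS), track)
  expect_identical(nrow(pure), 0L)
})

test_that("period-doubled pulse trains show an fo/2 subharmonic (FFT oracle agrees)", {
  sc <- quickScene(fo = 136, n = 2, dur = 0.8, depth = 0.4, seed = 7)
  x <- samples(sc$recording[["iEGG"]])
  # oracle: the DFT has a genuine component at 68 Hz
  m <- Mod(stats::fft(x - mean(x)))[seq_len(length(x) / 2)]
  fHz <- (seq_along(m) - 1) * FS / length(x)
  i68 <- which.min(abs(fHz - 68)); i136 <- which.min(abs(fHz - 136))
  relOracle <- max(m[(i68 - 2):(i68 + 2)]) / max(m[(i136 - 2):(i136 + 2)])
  expect_gt(relOracle, 0.05)
  track <- estimateFo(sc$recording[["GAW"]], 60, 400)
  ev <- detectSubharmonics(sc$recording[["iEGG"]], track)
  expect_true(2 %in% ev$order)
  expect_equal(ev$f1[ev$order == 2][1], 68, tolerance = 1)
})

test_that("frequency jumps are found with correct pre/post fo; constants and glissandi are not", {
  sc <- makeCoupledScene(sceneSpec(oscillatorSpec(step = c(100, 120, 1)),
                                   couplingSpec(ratioN = 1), duration = 2))
  tr <- estimateFo(sc$recording[["GAW"]], 50, 400)
  ev <- detectFrequencyJump(tr)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$f1, 100, tolerance = 1)
  expect_equal(ev$f2, 120, tolerance = 1)
  expect_equal(ev$tStart, 1, tolerance = 0.1)

  const <- estimateFo(quickScene(fo = 140, n = 1, dur = 2)$recording[["GAW"]],
                      50, 400)
  expect_identical(nrow(detectFrequencyJump(const)), 0L)

  gl <- makeCoupledScene(sceneSpec(oscillatorSpec(
    glissando = c(100, 200, 0, 2)), couplingSpec(ratioN = 1), duration = 2))
  trg <- estimateFo(gl$recording[["GAW"]], 50, 400)
  # brute-force flanking-median oracle: no 100 ms plateau pair separated by
  # 50 ms differs by >= 5 Hz while both flanks are stable
  expect_identical(nrow(detectFrequencyJump(trg)), 0L)

  unv <- FoTrack(1:10 / 10, rep(NA_real_, 10), rep(0, 10))
  expect_error(detectFrequencyJump(unv), "unvoiced")
})

test_that("biphonation fires on incommensurate pairs only", {
  t <- (0:39999) / FS
  gold <- Signal(sin(2 * pi * 100 * t) + sin(2 * pi * 161.8 * t), FS)
  expect_gt(nrow(detectBiphonation(gold)), 0)
  harm <- Signal(sin(2 * pi * 100 * t) + sin(2 * pi * 200 * t), FS)
  expect_identical(nrow(detectBiphonation(harm)), 0L)
  # chaotic channel is broadband, not two-component
  sc <- quickScene(fo = 136, n = 2, dur = 2, regime = "chaotic", seed = 5)
  expect_identical(nrow(detectBiphonation(sc$recording[["SAW"]])), 0L)
})

test_that("periodicity index separates periodic, noise and chaos", {
  sc <- quickScene(fo = 136, n = 2, dur = 1)
  pi1 <- periodicityIndex(sc$recording[["SAW"]], 0.2, foExpected = 68)
  expect_true(all(pi1$index > 0.9))

  set.seed(8)
  noise <- Signal(rnorm(20000), FS)
  expect_lt(max(periodicityIndex(noise, 1)$index), 0.3)

  # paired comparison over seeds: chaotic always below locked
  for (seed in 1:8) {
    ch <- quickScene(fo = 136, n = 2, dur = 1, regime = "chaotic",
                     seed = seed)
    lk <- quickScene(fo = 136, n = 2, dur = 1, seed = seed)
    mCh <- mean(periodicityIndex(ch$recording[["SAW"]], 0.2)$index)
    mLk <- mean(periodicityIndex(lk$recording[["SAW"]], 0.2)$index)
    expect_lt(mCh, mLk)
  }
  expect_error(periodicityIndex(sinusoidSignal(100, 0.1), 1), "longer")
})
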