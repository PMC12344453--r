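test_that("WAV round trips are exact at matching bit depth", {
  set.seed(1)
  x <- round(runif(5000, -0.9, 0.9) * 32768) / 32768
  for (bd in c(16, 24, 32)) {
    p <- withr::local_tempfile(fileext = ".wav")
    writeWav(x, FS, p, bitDepth = bd)
    r <- readWav(p)
    expect_equal(as.numeric(r$samples[, 1]), x, tolerance = 0,
                 info = paste("bit depth", bd))
    expect_equal(r$Fs, FS, tolerance = 0)
    expect_identical(r$bitDepth, as.integer(bd))
  }
})

test_that("stereo WAV keeps channels separate", {
  p <- withr::local_tempfile(fileext = ".wav")
  m <- cbind(sin(2 * pi * 100 * (0:999) / FS),
             sin(2 * pi * 200 * (0:999) / FS))
  m <- pmin(round(m * 32768), 32767) / 32768
  writeWav(m, FS, p, 16)
  r <- readWav(p)
  expect_equal(dim(r$samples), c(1000L, 2L))
  expect_equal(r$samples, m, tolerance = 1e-12)
})

test_that("delimited-table round trip preserves values to 1e-9 relative", {
  sc <- quickScene(dur = 0.1)
  p <- withr::local_tempfile(fileext = ".csv")
  writeSignalTable(channels(sc$recording), p)
  back <- readSignalTable(p)
  expect_named(back, names(channels(sc$recording)))
  for (nm in names(back)) {
    orig <- samples(sc$recording[[nm]])
    scl <- max(abs(orig))
    expect_lt(max(abs(samples(back[[nm]]) - orig)) / scl, 1e-9)
  }
  expect_equal(samplingRate(back[[1]]), FS, tolerance = 1e-6)
})

test_that("WAV at 44.1 kHz resampled to 20 kHz has round(1 s * 20000) samples", {
  p <- withr::local_tempfile(fileext = ".wav")
  writeWav(sin(2 * pi * 440 * (0:44099) / 44100), 44100, p, 16)
  rec <- readRecording(wav = c(audio = p), targetFs = 20000)
  expect_identical(nSamples(rec[["audio"]]), 20000L)
  expect_equal(samplingRate(rec), 20000)
  # tone survives resampling
  expect_equal(fftPeakHz(samples(rec[["audio"]]), 20000), 440,
               tolerance = 2)
})

test_that("an image sequence becomes a FrameStack with the declared fps", {
  dir <- withr::local_tempdir()
  for (i in 1:7)
    png::writePNG(matrix(runif(64), 8, 8),
                  file.path(dir, sprintf("f%02d.png", i)))
  fs <- readFrameStack(Sys.glob(file.path(dir, "*.png")), fps = 100)
  expect_identical(nFrames(fs), 7L)
  expect_identical(fps(fs), 100)
  expect_identical(dim(frames(fs)[[1]]), c(8L, 8L))
})

test_that("multi-page TIFF round trips a frame stack", {
  sc <- quickScene(dur = 0.002, render = smallRender(frameSize = c(48, 48),
                                                     fps = FS,
                                                     glottalMaxArea = 80,
                                                     supraMaxArea = 300))
  st <- frames(sc$recording)
  p <- withr::local_tempfile(fileext = ".tif")
  writeFrameStack(st, p)
  back <- readFrameStack(p, fps = FS)
  expect_identical(nFrames(back), nFrames(st))
  # 8-bit storage quantizes to 1/255
  expect_lt(max(abs(frames(back)[[1]] -
                    frames(frames(sc$recording))[[1]])), 1 / 254)
})

test_that("writeRecording/readRecording round trips channels", {
  sc <- quickScene(dur = 0.05)
  dir <- withr::local_tempdir()
  writeRecording(sc$recording, dir)
  back <- readRecording(table = file.path(dir, "channels.csv"))
  expect_setequal(names(channels(back)), names(channels(sc$recording)))
  expect_equal(samples(back[["SAW"]]), samples(sc$recording[["SAW"]]),
               tolerance = 1e-9)
})

test_that("mismatched channel lengths error unless alignment is on", {
  p1 <- withr::local_tempfile(fileext = ".wav")
  p2 <- withr::local_tempfile(fileext = ".wav")
  writeWav(rnorm(1000) / 10, FS, p1, 16)
  writeWav(rnorm(1500) / 10, FS, p2, 16)
  expect_error(readRecording(wav = c(audio = p1, EGG = p2), align = FALSE),
               "mismatched")
  rec <- readRecording(wav = c(audio = p1, EGG = p2), align = TRUE)
  expect_identical(nSamples(rec[["audio"]]), 1000L)
  expect_identical(nSamples(rec[["EGG"]]), 1000L)
})

test_that("invertEGG negates, toggles the label and is an involution", {
  egg <- Signal(c(0.5, -0.25, 0), FS, label = "EGG")
  iegg <- invertEGG(egg)
  expect_equal(samples(iegg), c(-0.5, 0.25, 0))
  expect_identical(channelLabel(iegg), "iEGG")
  expect_identical(which.max(samples(iegg)), which.min(samples(egg)))
  back <- invertEGG(iegg)
  expect_identical(samples(back), samples(egg))
  expect_identical(channelLabel(back), "EGG")
  expect_error(invertEGG(Signal(1:3, FS, label = "audio")), "EGG")
})

test_that("normalizeMaxAbs scales to unit max, idempotently and scale-invariantly", {
  s <- Signal(c(0, -2, 1), FS)
  n1 <- normalizeMaxAbs(s)
  expect_equal(samples(n1), c(0, -1, 0.5))
  expect_equal(max(abs(samples(n1))), 1)
  expect_equal(samples(normalizeMaxAbs(n1)), samples(n1))
  for (k in c(0.001, 3.7, 1e6)) {
    sk <- Signal(k * samples(s), FS)
    expect_equal(samples(normalizeMaxAbs(sk)), samples(n1),
                 tolerance = 1e-12)
  }
  expect_error(normalizeMaxAbs(Signal(numeric(10), FS)), "all-zero")
})

test_that("non-monotone timestamps in a table are rejected", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,audio", "0,0.1", "0.0002,0.2", "0.0001,0.3"), p)
  expect_error(readSignalTable(p), "monotone")
})
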