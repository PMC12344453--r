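test_that("rendering realizes requested areas exactly (pixel-count oracle)", {
  rs <- smallRender()
  out <- renderFrames(AreaWaveform(rep(500, 4), 1000, "glottal"),
                      AreaWaveform(rep(0, 4), 1000, "supraglottic"), rs)
  expect_true(all(abs(out$trueAreas$glottal - 500) <= 1))
  # brute-force count at the glottal brightness level
  counts <- vapply(frames(out$stack), function(m) sum(m > 0.9), numeric(1))
  expect_true(all(abs(counts - 500) <= 1))
})

test_that("both areas zero renders uniform background", {
  rs <- smallRender()
  out <- renderFrames(AreaWaveform(rep(0, 3), 1000, "glottal"),
                      AreaWaveform(rep(0, 3), 1000, "supraglottic"), rs)
  for (m in frames(out$stack))
    expect_true(all(m == rs@brightness[1]))
})

test_that("sinusoidal requested areas are rendered within 2% RMS", {
  rs <- smallRender(glottalMaxArea = 1000, supraMaxArea = 2000)
  req <- 500 + 500 * sin(2 * pi * (1:80) / 25)
  out <- renderFrames(AreaWaveform(req, 1000, "glottal"),
                      AreaWaveform(rep(0, 80), 1000, "supraglottic"), rs)
  rel <- (out$trueAreas$glottal - req) / pmax(req, 100)
  expect_lt(sqrt(mean(rel^2)), 0.02)
})

test_that("requested area above the region capacity errors", {
  rs <- smallRender(glottalMaxArea = 200)
  expect_error(
    renderFrames(AreaWaveform(300, 1000, "glottal"),
                 AreaWaveform(0, 1000, "supraglottic"), rs),
    "capacity")
})

test_that("segmentation recovers rendered ground truth within 2% RMS", {
  rs <- smallRender()
  n <- 60
  gA <- 300 + 280 * sin(2 * pi * (1:n) / 20)
  sA <- 800 + 600 * sin(2 * pi * (1:n) / 30 + 1)
  out <- renderFrames(AreaWaveform(gA, 1000, "glottal"),
                      AreaWaveform(sA, 1000, "supraglottic"), rs)
  ag <- segmentArea(out$stack, segmentationProfile(greyThreshold = 0.75,
                                                   target = "glottal"))
  as <- segmentArea(out$stack,
                    segmentationProfile(greyThreshold = 0.3,
                                        greyCeiling = 0.75,
                                        target = "supraglottic"))
  relG <- (areas(ag) - out$trueAreas$glottal) / pmax(out$trueAreas$glottal, 100)
  relS <- (areas(as) - out$trueAreas$supraglottic) /
    pmax(out$trueAreas$supraglottic, 100)
  expect_lt(sqrt(mean(relG^2)), 0.02)
  expect_lt(sqrt(mean(relS^2)), 0.02)
})

test_that("segmented area equals the brute-force pixel count (oracle equivalence)", {
  rs <- smallRender()
  out <- renderFrames(AreaWaveform(c(150, 400), 1000, "glottal"),
                      AreaWaveform(c(900, 200), 1000, "supraglottic"), rs)
  prof <- segmentationProfile(greyThreshold = 0.5, minRegionPx = 1)
  aw <- segmentArea(out$stack, prof)
  oracle <- vapply(frames(out$stack),
                   function(m) sum(m >= 0.5), numeric(1))
  expect_identical(areas(aw), oracle)
})

test_that("an all-background stack yields a zero waveform with a warning", {
  st <- FrameStack(replicate(4, matrix(0.05, 32, 32), simplify = FALSE),
                   fps = 100)
  expect_warning(aw <- segmentArea(st, segmentationProfile(0.5)),
                 "no regions")
  expect_true(all(areas(aw) == 0))
})

test_that("nested fixture: high threshold isolates the glottal ellipse, supraglottic profile the annulus", {
  rs <- smallRender()
  out <- renderFrames(AreaWaveform(rep(300, 3), 1000, "glottal"),
                      AreaWaveform(rep(1000, 3), 1000, "supraglottic"), rs)
  inner <- segmentArea(out$stack, segmentationProfile(greyThreshold = 0.75,
                                                      target = "glottal"))
  expect_true(all(areas(inner) == 300))
  annul <- segmentArea(out$stack,
                       segmentationProfile(greyThreshold = 0.3,
                                           greyCeiling = 0.75,
                                           target = "supraglottic"))
  expect_true(all(areas(annul) == 1000))
  # without the ceiling both levels binarize and the areas sum
  both <- segmentArea(out$stack, segmentationProfile(greyThreshold = 0.3))
  expect_true(all(areas(both) == 1300))
})

test_that("lowering the threshold never decreases the segmented area", {
  sc <- quickScene(dur = 0.004,
                   render = smallRender(frameSize = c(64, 64), fps = FS,
                                        glottalMaxArea = 150,
                                        supraMaxArea = 600))
  st <- frames(sc$recording)
  thrs <- c(0.9, 0.7, 0.5, 0.3, 0.1)
  prev <- areas(segmentArea(st, segmentationProfile(thrs[1])))
  for (thr in thrs[-1]) {
    a <- areas(segmentArea(st, segmentationProfile(thr)))
    expect_true(all(a >= prev))
    prev <- a
  }
})

test_that("SAW recovery correlates with the true supraglottic area when it dominates", {
  sc <- quickScene(fo = 170, n = 2, dur = 0.01,
                   render = smallRender(frameSize = c(96, 96), fps = FS,
                                        glottalMaxArea = 150,
                                        supraMaxArea = 1200))
  st <- frames(sc$recording)
  recS <- areas(segmentArea(st, segmentationProfile(
    greyThreshold = 0.3, greyCeiling = 0.75, target = "supraglottic")))
  trueS <- sc$trueAreas$supraglottic
  trueG <- sc$trueAreas$glottal
  expect_gt(cor(recS, trueS), 0.95)
  expect_gt(cor(recS, trueS), cor(recS, trueG))
})

test_that("preprocessing: identity transform returns identical frames", {
  sc <- quickScene(dur = 0.002, render = smallRender(frameSize = c(48, 48),
                                                     fps = FS,
                                                     glottalMaxArea = 80,
                                                     supraMaxArea = 300))
  st <- frames(sc$recording)
  out <- preprocessFrames(st, rotation = 0, crop = NULL, gain = 1,
                          offset = 0)
  expect_identical(frames(out), frames(st))
})

test_that("90-degree rotation follows the CCW index-mapping oracle on a labelled 3x3 frame", {
  m <- matrix((1:9) / 10, 3, 3, byrow = TRUE)
  r <- frames(preprocessFrames(FrameStack(list(m), fps = 1),
                               rotation = 90))[[1]]
  # CCW: new[i, j] = old[j, nrow - i + 1]
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) oracle[i, j] <- m[j, 3 - i + 1]
  expect_equal(r, oracle)
  # four quarter turns = identity
  r4 <- preprocessFrames(FrameStack(list(m), fps = 1), rotation = 360)
  expect_equal(frames(r4)[[1]], m)
})

test_that("contrast gain clips at the valid range", {
  st <- FrameStack(list(matrix(0.6, 4, 4)), fps = 1)
  out <- frames(preprocessFrames(st, gain = 2))[[1]]
  expect_true(all(out == 1))
  expect_error(preprocessFrames(st, gain = Inf), "gain")
  expect_error(preprocessFrames(st, crop = c(2, 1, 1, 4)), "crop")
})

test_that("a ROI outside the frame is rejected", {
  st <- FrameStack(list(matrix(0.5, 16, 16)), fps = 1)
  expect_error(
    segmentArea(st, segmentationProfile(0.4, roi = c(1, 20, 1, 8))),
    "roi")
})
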