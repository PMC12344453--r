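mkTrack <- function(fo, jitter = 0, n = 101) {
  set.seed(1)
  FoTrack(seq(0, 1, length.out = n), fo + rnorm(n, sd = jitter))
}

test_that("integer ratios are recovered from mean fo pairs", {
  expect_identical(estimateRatio(mkTrack(136), mkTrack(68))$n, 2L)
  expect_identical(estimateRatio(mkTrack(100), mkTrack(100))$n, 1L)
  expect_identical(estimateRatio(mkTrack(231), mkTrack(77))$n, 3L)
  e <- estimateRatio(mkTrack(136, 1), mkTrack(68, 0.5))
  expect_gt(e$confidence, 0.8)
})

test_that("swapping the tracks reports the reciprocal orientation with the same n", {
  fwd <- estimateRatio(mkTrack(210), mkTrack(70))
  rev <- estimateRatio(mkTrack(70), mkTrack(210))
  expect_identical(fwd$n, rev$n)
  expect_identical(fwd$orientation, "glottal:supraglottic")
  expect_identical(rev$orientation, "inverted")
  expect_equal(rev$ratio, 1 / fwd$ratio, tolerance = 1e-12)
})

test_that("degenerate ratio inputs error", {
  expect_error(estimateRatio(mkTrack(100), mkTrack(5)), "outside")
  unv <- FoTrack(seq(0, 1, 0.01), rep(NA_real_, 101), rep(0, 101))
  expect_error(estimateRatio(mkTrack(100), unv), "voiced")
})

test_that("ratio recovery works from estimated tracks at 20 dB SNR (spot check)", {
  for (n in c(2, 5)) for (seed in 1:5) {
    sc <- quickScene(fo = 200, n = n, dur = 0.6, seed = seed, snr = 20)
    trG <- estimateFo(sc$recording[["GAW"]], 60, 400)
    trS <- estimateFo(sc$recording[["SAW"]], 15, 400)
    expect_identical(estimateRatio(trG, trS)$n, as.integer(n))
  }
})

test_that("a glissando against a fixed supraglottic fo yields a 2 -> 3 ratio transition", {
  sc <- makeCoupledScene(sceneSpec(
    oscillatorSpec(glissando = c(154, 231, 0.25, 1.25)),
    couplingSpec(ratioN = 2), supraglottic = oscillatorSpec(fo = 77),
    duration = 1.5, seed = 2))
  trG <- estimateFo(sc$recording[["GAW"]], 80, 500)
  trS <- estimateFo(sc$recording[["SAW"]], 40, 300)
  tw <- trackRatio(trG, trS, 0.25)
  nn <- tw$n[!is.na(tw$n)]
  expect_identical(nn[1], 2L)
  expect_identical(nn[length(nn)], 3L)
  cp <- attr(tw, "changePoints")
  expect_identical(nrow(cp), 1L)
  expect_identical(cp$from, 2L)
  expect_identical(cp$to, 3L)
})

test_that("a locked scene keeps a constant ratio with no change-points", {
  sc <- quickScene(fo = 160, n = 2, dur = 1.5)
  trG <- estimateFo(sc$recording[["GAW"]], 60, 400)
  trS <- estimateFo(sc$recording[["SAW"]], 40, 300)
  tw <- trackRatio(trG, trS, 0.25)
  expect_true(all(tw$n == 2L, na.rm = TRUE))
  expect_identical(nrow(attr(tw, "changePoints")), 0L)
})

test_that("biphonation (incommensurate) scenes give low ratio confidence everywhere", {
  sc <- quickScene(fo = 136, n = 2, dur = 1, regime = "biphonation",
                   seed = 5)
  trG <- estimateFo(sc$recording[["GAW"]], 60, 400)
  trS <- estimateFo(sc$recording[["SAW"]], 30, 300)
  tw <- trackRatio(trG, trS, 0.25)
  expect_true(all(tw$confidence < 0.5))
  # oracle: 136 / (136 / 2.618) = 2.618, residual to n = 3 is 12.7% > tol
  expect_gt(min(abs(2.618 - 2), abs(2.618 - 3)) / 3, 0.08)
})

test_that("regime classification follows the documented rule", {
  expect_identical(classifyGroup(0.95, 0.9, TRUE)$group, "group1")
  expect_identical(classifyGroup(0.4, 0.2, TRUE)$group, "group2a")
  expect_identical(classifyGroup(0.4, 0.2, FALSE)$group, "group2b")
  # high periodicity alone is not enough
  expect_identical(classifyGroup(0.9, 0.1, TRUE)$group, "group2a")
  # determinism: identical features, identical label
  a <- classifyGroup(0.71, 0.61, FALSE)
  b <- classifyGroup(0.71, 0.61, FALSE)
  expect_identical(a, b)
  expect_error(classifyGroup(NA, 0.5, TRUE), "features")
})

test_that("end-to-end features classify locked vs chaotic scenes correctly", {
  lk <- quickScene(fo = 136, n = 2, dur = 1)
  ch <- quickScene(fo = 136, n = 2, dur = 1, regime = "chaotic", seed = 4)
  feat <- function(sc) {
    trG <- estimateFo(sc$recording[["GAW"]], 60, 400)
    trS <- estimateFo(sc$recording[["SAW"]], 30, 400)
    pidx <- mean(periodicityIndex(sc$recording[["SAW"]], 0.2)$index,
                 na.rm = TRUE)
    conf <- tryCatch(estimateRatio(trG, trS)$confidence,
                     error = function(e) 0)
    c(pidx, conf)
  }
  fl <- feat(lk); fc <- feat(ch)
  expect_identical(classifyGroup(fl[1], fl[2], TRUE)$group, "group1")
  expect_identical(classifyGroup(fc[1], fc[2], TRUE)$group, "group2a")
  expect_identical(classifyGroup(fc[1], fc[2], FALSE)$group, "group2b")
})
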