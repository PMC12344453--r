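interior <- function(n, frac = 0.1) seq(ceiling(n * frac), floor(n * (1 - frac)))

test_that("instantaneous phase of a cosine advances by 2 pi f dt per sample", {
  f <- 100
  t <- (0:9999) / FS
  ph <- instantaneousPhase(Signal(cos(2 * pi * f * t), FS))
  ii <- interior(length(ph))
  dph <- diff(ph[ii]) %% (2 * pi)
  expect_true(all(abs(dph - 2 * pi * f / FS) < 1e-3))
})

test_that("sin lags cos by pi/2 in the interior", {
  t <- (0:9999) / FS
  pc <- instantaneousPhase(cos(2 * pi * 100 * t))
  ps <- instantaneousPhase(sin(2 * pi * 100 * t))
  ii <- interior(length(t))
  d <- (pc[ii] - ps[ii]) %% (2 * pi)
  expect_true(all(abs(d - pi / 2) < 1e-2))
})

test_that("a slow amplitude envelope leaves the phase unchanged (Bedrosian)", {
  t <- (0:19999) / FS
  carrier <- cos(2 * pi * 150 * t)
  am <- (1 + 0.5 * sin(2 * pi * 3 * t)) * carrier
  p0 <- instantaneousPhase(carrier)
  p1 <- instantaneousPhase(am)
  ii <- interior(length(t))
  d <- abs((p1[ii] - p0[ii] + pi) %% (2 * pi) - pi)
  expect_lt(max(d), 1e-2)
})

test_that("all-zero input has no phase", {
  expect_error(instantaneousPhase(numeric(100)), "all-zero")
})

test_that("pointwise PS hits the analytic anchors: +1, -1, 0", {
  t <- (0:39999) / FS
  a <- Signal(sin(2 * pi * 100 * t), FS)
  ii <- interior(length(t))
  expect_true(all(pointwisePS(a, a)[ii] == 1))
  anti <- Signal(sin(2 * pi * 100 * (t - 0.005)), FS)    # half period
  expect_true(all(abs(pointwisePS(a, anti)[ii] + 1) < 1e-3))
  quad <- Signal(sin(2 * pi * 100 * (t - 0.0025)), FS)   # quarter period
  expect_true(all(abs(pointwisePS(a, quad)[ii]) < 1e-2))
  expect_error(pointwisePS(a, Signal(1:10 / 10, FS)), "length")
})

test_that("the variable-window rule gives the documented window lengths", {
  expect_identical(psOptions("group2", Fs = 20000)@Nwin, 1000)
  o1 <- psOptions("group1", Fs = 20000, foIEGG = 68, foAudio = 68)
  expect_equal(o1@foMin, 13.6)
  expect_identical(o1@Nwin, floor(20000 / 13.6))
  expect_identical(o1@Nwin, 1470)
  expect_error(psOptions("group1", Fs = 20000), "foIEGG")
})

test_that("windowed PS: quadrature pair gives median ~0 with IQR ~0", {
  t <- (0:39999) / FS
  a <- Signal(sin(2 * pi * 100 * t), FS)
  b <- Signal(sin(2 * pi * 100 * t - pi / 2), FS)
  ps <- windowedPS(a, b, psOptions("group2", Fs = FS))
  expect_true(all(abs(psMedian(ps)) < 0.02))
  expect_true(all(psIQR(ps) < 0.02))
})

test_that("windowed PS: integer-ratio pairs give median ~0 over whole-period windows", {
  t <- (0:39999) / FS
  base <- Signal(sin(2 * pi * 40 * t), FS)   # period 500; Nwin = 1000
  for (n in 2:5) {
    hi <- Signal(sin(2 * pi * 40 * n * t), FS)
    ps <- windowedPS(base, hi, psOptions("group2", Fs = FS))
    expect_true(all(abs(psMedian(ps)) < 0.05), info = paste("n =", n))
  }
})

test_that("PS bounds and quartile ordering hold for arbitrary signal pairs", {
  set.seed(11)
  for (i in 1:5) {
    a <- Signal(rnorm(8000), FS)
    b <- Signal(rnorm(8000), FS)
    ps <- windowedPS(a, b, psOptions("group2", Fs = FS))
    ok <- !is.na(psMedian(ps))
    expect_true(all(psMedian(ps)[ok] >= -1 & psMedian(ps)[ok] <= 1))
    expect_true(all(psQ25(ps)[ok] <= psMedian(ps)[ok]))
    expect_true(all(psMedian(ps)[ok] <= psQ75(ps)[ok]))
    raw <- pointwisePS(a, b)
    expect_true(all(raw >= -1 & raw <= 1))
  }
})

test_that("windowed PS is exactly symmetric in its inputs", {
  sc <- quickScene(fo = 136, dur = 1, depth = 0.3)
  a <- sc$recording[["iEGG"]]; b <- sc$recording[["SAW"]]
  o <- psOptions("group2", Fs = FS)
  ab <- windowedPS(a, b, o); ba <- windowedPS(b, a, o)
  expect_identical(psMedian(ab), psMedian(ba))
  expect_identical(psQ25(ab), psQ25(ba))
  expect_identical(psQ75(ab), psQ75(ba))
})

test_that("PS is invariant under positive rescaling of either input", {
  sc <- quickScene(fo = 136, dur = 0.5, depth = 0.3)
  a <- sc$recording[["iEGG"]]; b <- sc$recording[["SAW"]]
  o <- psOptions("group2", Fs = FS)
  ref <- psMedian(windowedPS(a, b, o))
  # power-of-two scalings commute exactly with every float operation
  for (k in c(0.5, 4)) {
    ak <- Signal(k * samples(a), FS)
    expect_identical(psMedian(windowedPS(ak, b, o)), ref)
  }
  a37 <- Signal(3.7 * samples(a), FS)
  # arbitrary scalings agree to floating-point accumulation error
  expect_equal(psMedian(windowedPS(a37, b, o)), ref, tolerance = 1e-6)
})

test_that("silent windows are reported as missing, not zero", {
  t <- (0:39999) / FS
  x <- sin(2 * pi * 120 * t)
  y <- x
  y[15000:25000] <- 0                     # SAW drop-out
  ps <- windowedPS(Signal(x, FS), Signal(y, FS),
                   psOptions("group2", Fs = FS, bandpass = NA))
  mid <- which(windowCenters(ps) > 0.8 & windowCenters(ps) < 1.2)
  expect_true(any(is.na(psMedian(ps)[mid])))
  expect_true(all(ps@nValid[is.na(psMedian(ps))] == 0))
})

test_that("windows longer than the signal are rejected", {
  a <- sinusoidSignal(100, dur = 0.04)
  expect_error(windowedPS(a, a, psOptions("group2", Fs = FS)), "Nwin")
})
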