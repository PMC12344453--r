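#' @include AllClasses.R
NULL

#' Estimate the integer glottal:supraglottic oscillation ratio
#'
#' Takes the mean fo of each track over the interval, forms the ratio
#' (documented orientation: glottal over supraglottic) and reports its
#' best small-integer approximation n together with a confidence that
#' decreases with the relative residual |ratio - n| / n and with the
#' within-track fo variability. Ratios below 1 (swapped inputs) are
#' reported with n computed from the reciprocal and
#' \code{orientation = "inverted"}.
#'
#' @param foGlottal,foSupraglottic \linkS4class{FoTrack}s
#' @param tStart,tEnd analysis interval (s); defaults to the overlap
#' @param nMax largest admissible integer ratio (default 8)
#' @param tol relative tolerance for accepting n (default 0.08)
#' @return one-row data.frame: n, ratio, confidence, orientation, tStart,
#'   tEnd
#' @examples
#' tg <- FoTrack(seq(0, 1, 0.01), rep(136, 101))
#' ts <- FoTrack(seq(0, 1, 0.01), rep(68, 101))
#' estimateRatio(tg, ts)$n   # 2
#' @export
estimateRatio <- function(foGlottal, foSupraglottic, tStart = -Inf,
                          tEnd = Inf, nMax = 8, tol = 0.08) {
  selG <- foGlottal@times >= tStart & foGlottal@times <= tEnd
  selS <- foSupraglottic@times >= tStart & foSupraglottic@times <= tEnd
  stopifnot2(any(selG) && any(selS), "interval covers no frames")
  vG <- foGlottal@fo[selG]; vS <- foSupraglottic@fo[selS]
  if (mean(!is.na(vG)) < 0.5 || mean(!is.na(vS)) < 0.5)
    stop("tracks must be voiced over at least 50% of the interval",
         call. = FALSE)
  mG <- mean(vG, na.rm = TRUE); mS <- mean(vS, na.rm = TRUE)
  r <- mG / mS
  if (r > nMax || r < 1 / nMax)
    stop(sprintf("ratio %.3g outside [1/%d, %d]", r, nMax, nMax),
         call. = FALSE)
  orientation <- "glottal:supraglottic"
  rEff <- r
  if (r < 1) { rEff <- 1 / r; orientation <- "inverted" }
  n <- max(1L, min(as.integer(nMax), as.integer(round(rEff))))
  resid <- abs(rEff - n) / n
  cvG <- stats::sd(vG, na.rm = TRUE) / mG
  cvS <- stats::sd(vS, na.rm = TRUE) / mS
  if (is.na(cvG)) cvG <- 0
  if (is.na(cvS)) cvS <- 0
  stability <- 1 / (1 + 5 * (cvG + cvS))
  confidence <- max(0, 1 - resid / tol) * stability
  data.frame(n = n, ratio = r, confidence = confidence,
             orientation = orientation,
             tStart = max(min(foGlottal@times[selG]),
                          min(foSupraglottic@times[selS])),
             tEnd = min(max(foGlottal@times[selG]),
                        max(foSupraglottic@times[selS])))
}

#' Track the oscillation ratio through time
#'
#' Applies \code{\link{estimateRatio}} in consecutive windows and reports
#' the per-window estimates plus the change-points where the integer
#' ratio switches (as during a glissando where the supraglottic natural
#' frequency stays fixed while the glottal fo rises).
#'
#' @param foGlottal,foSupraglottic \linkS4class{FoTrack}s
#' @param window window length (s)
#' @param ... passed to \code{\link{estimateRatio}}
#' @return data.frame with one row per window (n, ratio, confidence,
#'   orientation, tStart, tEnd; \code{NA} rows where a window was
#'   unvoiced); attribute \code{"changePoints"} holds a data.frame (time,
#'   from, to)
#' @export
trackRatio <- function(foGlottal, foSupraglottic, window, ...) {
  t0 <- max(min(foGlottal@times), min(foSupraglottic@times))
  t1 <- min(max(foGlottal@times), max(foSupraglottic@times))
  stopifnot2(t1 - t0 >= window, "window longer than the track overlap")
  starts <- seq(t0, t1 - window, by = window)
  rows <- lapply(starts, function(ws) {
    est <- tryCatch(
      estimateRatio(foGlottal, foSupraglottic, ws, ws + window, ...),
      error = function(e) data.frame(
        n = NA_integer_, ratio = NA_real_, confidence = 0,
        orientation = NA_character_, tStart = ws, tEnd = ws + window))
    est
  })
  out <- do.call(rbind, rows)
  nn <- out$n
  valid <- which(!is.na(nn))
  cp <- data.frame(time = numeric(0), from = integer(0), to = integer(0))
  if (length(valid) > 1L) {
    ch <- which(diff(nn[valid]) != 0)
    if (length(ch))
      cp <- data.frame(time = out$tStart[valid[ch + 1L]],
                       from = nn[valid[ch]], to = nn[valid[ch + 1L]])
  }
  attr(out, "changePoints") <- cp
  out
}

#' Classify a phonation regime
#'
#' Quasi-periodic phonation with a stable integer oscillation ratio is
#' labelled group 1; irregular phonation is group 2, split into 2a
#' (glottis visible on imaging) and 2b (glottis hidden by supraglottic
#' constriction). Visibility is a visual judgement and therefore an
#' explicit input flag, never inferred from the data.
#'
#' @param periodicity mean periodicity index of the analysis interval
#' @param ratioConfidence ratio-estimate confidence on the interval
#' @param glottisVisible logical flag from endoscopic judgement
#' @param thetaP periodicity threshold for group 1 (default 0.7)
#' @param thetaR ratio-confidence threshold for group 1 (default 0.6)
#' @return one-row data.frame: group (\code{"group1"}, \code{"group2a"} or
#'   \code{"group2b"}), periodicity, ratioConfidence, glottisVisible
#' @examples
#' classifyGroup(0.95, 0.9, TRUE)$group    # "group1"
#' classifyGroup(0.3, 0.2, FALSE)$group    # "group2b"
#' @export
classifyGroup <- function(periodicity, ratioConfidence, glottisVisible,
                          thetaP = 0.7, thetaR = 0.6) {
  stopifnot2(is.finite(periodicity) && is.finite(ratioConfidence),
             "missing features")
  stopifnot2(is.logical(glottisVisible) && length(glottisVisible) == 1L,
             "'glottisVisible' must be a single logical")
  group <- if (periodicity >= thetaP && ratioConfidence >= thetaR) "group1"
           else if (glottisVisible) "group2a" else "group2b"
  data.frame(group = group, periodicity = periodicity,
             ratioConfidence = ratioConfidence,
             glottisVisible = glottisVisible)
}
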