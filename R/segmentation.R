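#' @include AllClasses.R
NULL

## exact 90-degree rotations, counter-clockwise positive
.rot90 <- function(m, k) {
  k <- ((k %% 4) + 4) %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

#' Geometric and intensity preprocessing of a frame stack
#'
#' Applies, in order: in-plane rotation (exact for multiples of 90
#' degrees, bilinear resampling otherwise), rectangular cropping and an
#' affine contrast adjustment \code{clip(gain * I + offset)} to [0, 1].
#'
#' @param stack a \linkS4class{FrameStack}
#' @param rotation degrees, counter-clockwise positive
#' @param crop \code{c(x0, x1, y0, y1)} in pixel coordinates of the
#'   rotated frame (x = column, y = row), or \code{NULL} for no crop
#' @param gain contrast gain (finite)
#' @param offset contrast offset
#' @return the transformed \linkS4class{FrameStack}
#' @export
preprocessFrames <- function(stack, rotation = 0, crop = NULL, gain = 1,
                             offset = 0) {
  stopifnot2(methods::is(stack, "FrameStack"), "'stack' must be a FrameStack")
  stopifnot2(is.finite(gain), "non-finite gain")
  fr <- frames(stack)
  if (rotation != 0) {
    if (abs(rotation %% 90) < 1e-9) {
      k <- round(rotation / 90)
      fr <- lapply(fr, .rot90, k = k)
    } else {
      ## EBImage::rotate matches the CCW-positive matrix convention used
      ## by the exact 90-degree path
      fr <- lapply(fr, function(m) {
        as.matrix(EBImage::rotate(m, rotation, output.dim = dim(m),
                                  bg.col = 0))
      })
    }
  }
  if (!is.null(crop)) {
    stopifnot2(length(crop) == 4L, "'crop' must be c(x0, x1, y0, y1)")
    d <- dim(fr[[1L]])
    x0 <- crop[1L]; x1 <- crop[2L]; y0 <- crop[3L]; y1 <- crop[4L]
    stopifnot2(x0 >= 1 && y0 >= 1 && x1 <= d[2L] && y1 <= d[1L] &&
               x0 <= x1 && y0 <= y1, "empty crop or crop outside frame")
    fr <- lapply(fr, function(m) m[y0:y1, x0:x1, drop = FALSE])
  }
  if (gain != 1 || offset != 0)
    fr <- lapply(fr, function(m) clip01(gain * m + offset))
  FrameStack(fr, fps = fps(stack), bitDepth = stack@bitDepth)
}

#' Segment an area waveform from a frame stack
#'
#' Per frame: apply the profile's affine contrast adjustment, binarize all
#' pixels whose grey value lies in \code{[greyThreshold, greyCeiling]}
#' within the ROI, label 4-connected regions, discard regions smaller than
#' \code{minRegionPx}, and record the total retained pixel count. Multiple
#' retained regions are summed: the supraglottic waveform aggregates all
#' vibrating areas without distinguishing them.
#'
#' @param stack a \linkS4class{FrameStack}
#' @param profile a \linkS4class{SegmentationProfile}
#' @return an \linkS4class{AreaWaveform} (one area per frame)
#' @examples
#' rs <- renderSpec(frameSize = c(64, 64), fps = 1000,
#'                  glottalMaxArea = 120, supraMaxArea = 600)
#' out <- renderFrames(
#'   AreaWaveform(rep(100, 3), 1000, "glottal"),
#'   AreaWaveform(rep(300, 3), 1000, "supraglottic"), rs)
#' aw <- segmentArea(out$stack, segmentationProfile(greyThreshold = 0.75))
#' areas(aw)
#' @export
segmentArea <- function(stack, profile) {
  stopifnot2(methods::is(stack, "FrameStack"), "'stack' must be a FrameStack")
  methods::validObject(profile)
  fr <- frames(stack)
  stopifnot2(length(fr) > 0L, "empty frame stack")
  d <- dim(fr[[1L]])
  roi <- profile@roi
  if (!is.null(roi))
    stopifnot2(roi[2L] <= d[2L] && roi[4L] <= d[1L],
               "roi outside frame")
  areas <- vapply(fr, function(m) {
    img <- clip01(profile@contrastGain * m + profile@contrastOffset)
    mask <- img >= profile@greyThreshold & img <= profile@greyCeiling
    if (!is.null(roi)) {
      keep <- matrix(FALSE, d[1L], d[2L])
      keep[roi[3L]:roi[4L], roi[1L]:roi[2L]] <- TRUE
      mask <- mask & keep
    }
    if (!any(mask)) return(0)
    lab <- EBImage::bwlabel(mask + 0)
    cnt <- tabulate(lab[lab > 0])
    sum(cnt[cnt >= profile@minRegionPx])
  }, numeric(1))
  if (all(areas == 0))
    warning("segmentation produced no regions in any frame; ",
            "check threshold/contrast", call. = FALSE)
  AreaWaveform(areas, fps = fps(stack), target = profile@target,
               profile = profile)
}
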