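#' @include AllClasses.R
NULL

## Pixel machinery for exact-area rasterization.
##
## For a fixed ellipse shape (centre, aspect, rotation), a pixel lies
## inside the ellipse scaled by s iff its normalized elliptical radius^2
## is <= s^2. Sorting pixels by that radius therefore yields, for any
## requested integer area A, the exact A-pixel region: the A pixels of
## smallest radius. The centre is offset from the pixel grid by an
## irrational-ish amount so radii are generically distinct and the region
## grows one pixel at a time.
.regionOrders <- function(rs) {
  W <- rs@frameSize[1L]; H <- rs@frameSize[2L]
  cx <- W / 2 + 0.2371; cy <- H / 2 + 0.4113
  x <- matrix(rep(seq_len(W), each = H), nrow = H)
  y <- matrix(rep(seq_len(H), times = W), nrow = H)
  th <- rs@rotation * pi / 180
  xr <- (x - cx) * cos(th) + (y - cy) * sin(th)
  yr <- -(x - cx) * sin(th) + (y - cy) * cos(th)
  r2g <- (xr / rs@glottalAspect)^2 + yr^2      # glottal ellipse metric
  r2s <- (xr / 1.2)^2 + yr^2                   # annulus (outer) metric
  ordAll <- order(r2g)
  nHole <- ceiling(1.3 * rs@glottalMaxArea)    # fixed inner hole
  holeIdx <- ordAll[seq_len(nHole)]
  inHole <- logical(H * W); inHole[holeIdx] <- TRUE
  outIdx <- which(!inHole)
  ordG <- holeIdx                               # already sorted by r2g
  ordS <- outIdx[order(r2s[outIdx])]
  list(ordG = ordG, ordS = ordS, H = H, W = W)
}

#' Render area waveforms into a synthetic grayscale frame stack
#'
#' Draws, for every frame, a central elliptical glottal region and a
#' surrounding annular supraglottic region whose pixel areas follow the
#' two waveforms exactly (integer pixel counts; the rasterizer picks, per
#' frame, the requested number of pixels closest to the region centre in
#' the elliptical metric). Brightness levels are taken from the
#' \linkS4class{RenderSpec}.
#'
#' @param glottalWave non-negative \linkS4class{AreaWaveform} (px^2)
#' @param supraglotticWave non-negative \linkS4class{AreaWaveform}, same
#'   length and frame rate
#' @param render a \linkS4class{RenderSpec}
#' @return list with \code{stack} (a \linkS4class{FrameStack}) and
#'   \code{trueAreas} (data.frame: frame, glottal, supraglottic -- the
#'   exact rendered pixel counts)
#' @examples
#' rs <- renderSpec(frameSize = c(64, 64), fps = 1000,
#'                  glottalMaxArea = 120, supraMaxArea = 600)
#' gw <- AreaWaveform(rep(100, 5), fps = 1000, target = "glottal")
#' sw <- AreaWaveform(rep(400, 5), fps = 1000, target = "supraglottic")
#' out <- renderFrames(gw, sw, rs)
#' out$trueAreas$glottal
#' @export
renderFrames <- function(glottalWave, supraglotticWave, render) {
  methods::validObject(render)
  g <- areas(glottalWave); s <- areas(supraglotticWave)
  stopifnot2(length(g) == length(s),
             "glottal and supraglottic waveforms must have equal length")
  stopifnot2(all(g >= 0) && all(s >= 0), "waveforms must be non-negative")
  stopifnot2(abs(fps(glottalWave) - render@fps) < 1e-9 &&
             abs(fps(supraglotticWave) - render@fps) < 1e-9,
             "waveform fps must match the render fps")
  kG <- round(g); kS <- round(s)
  if (any(kG > render@glottalMaxArea + 0.5))
    stop("requested glottal area exceeds region capacity", call. = FALSE)
  if (any(kS > render@supraMaxArea + 0.5))
    stop("requested supraglottic area exceeds region capacity",
         call. = FALSE)
  ord <- .regionOrders(render)
  stopifnot2(length(ord$ordS) >= max(kS),
             "supraglottic region does not fit inside the frame")
  bg <- render@brightness[1L]; bs <- render@brightness[2L]
  bgl <- render@brightness[3L]
  frames <- vector("list", length(kG))
  for (i in seq_along(kG)) {
    m <- matrix(bg, nrow = ord$H, ncol = ord$W)
    if (kS[i] > 0) m[ord$ordS[seq_len(kS[i])]] <- bs
    if (kG[i] > 0) m[ord$ordG[seq_len(kG[i])]] <- bgl
    frames[[i]] <- m
  }
  list(stack = FrameStack(frames, fps = render@fps),
       trueAreas = data.frame(frame = seq_along(kG), glottal = kG,
                              supraglottic = kS))
}
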