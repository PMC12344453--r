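#' @include utils.R
NULL

## ---- WAV ---------------------------------------------------------------
## Minimal RIFF/WAVE support (PCM 16/24-bit and IEEE float32, little
## endian). The installed stack carries no audio package, so this is kept
## deliberately small: plain mono/multichannel read and write, no cue or
## metadata chunks.

#' Read a WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float 32-bit, mono or
#' multichannel. Samples are returned as doubles in [-1, 1) (PCM scaled by
#' 2^(bits-1)).
#'
#' @param path file path
#' @return list with \code{samples} (matrix, one column per channel),
#'   \code{Fs} and \code{bitDepth} (16, 24 or 32)
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  stopifnot2(identical(riff, "RIFF"), "not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  stopifnot2(identical(wave, "WAVE"), "not a WAVE file")
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audioFormat = readBin(con, "integer", 1, 2, endian = "little",
                              signed = FALSE),
        nChannels = readBin(con, "integer", 1, 2, endian = "little"),
        Fs = readBin(con, "integer", 1, 4, endian = "little"),
        byteRate = readBin(con, "integer", 1, 4, endian = "little"),
        blockAlign = readBin(con, "integer", 1, 2, endian = "little"),
        bits = readBin(con, "integer", 1, 2, endian = "little"))
      if (sz > 16) invisible(readBin(con, "raw", sz - 16))
    } else if (identical(id, "data")) {
      dat <- readBin(con, "raw", sz)
      if (sz %% 2L == 1L) invisible(readBin(con, "raw", 1))
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  stopifnot2(!is.null(fmt) && !is.null(dat), "missing fmt or data chunk")
  nch <- fmt$nChannels
  if (fmt$audioFormat == 3L && fmt$bits == 32L) {
    x <- readBin(dat, "double", length(dat) / 4L, size = 4,
                 endian = "little")
    bd <- 32L
  } else if (fmt$audioFormat == 1L && fmt$bits == 16L) {
    x <- readBin(dat, "integer", length(dat) / 2L, size = 2,
                 endian = "little", signed = TRUE) / 32768
    bd <- 16L
  } else if (fmt$audioFormat == 1L && fmt$bits == 24L) {
    b <- as.integer(dat)
    n <- length(b) %/% 3L
    idx <- 3L * seq_len(n)
    v <- b[idx - 2L] + 256L * b[idx - 1L] + 65536L * b[idx]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
    bd <- 24L
  } else {
    stop("unsupported WAV encoding (format ", fmt$audioFormat, ", ",
         fmt$bits, " bit)")
  }
  list(samples = matrix(x, ncol = nch, byrow = TRUE), Fs = fmt$Fs,
       bitDepth = bd)
}

#' Write a WAV file
#'
#' @param samples numeric vector or matrix (columns = channels) in [-1, 1]
#' @param Fs sampling rate (Hz)
#' @param path output path
#' @param bitDepth 16, 24 (PCM) or 32 (IEEE float)
#' @return the path, invisibly
#' @export
writeWav <- function(samples, Fs, path, bitDepth = 16) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  x <- as.numeric(t(samples))               # interleave channels
  nch <- ncol(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  bytes <- c(`16` = 2L, `24` = 3L, `32` = 4L)[as.character(bitDepth)]
  stopifnot2(!is.na(bytes), "bitDepth must be 16, 24 or 32")
  fmtCode <- if (bitDepth == 32) 3L else 1L
  dataSize <- length(x) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + dataSize), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmtCode, con, size = 2, endian = "little")
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(as.integer(Fs), con, size = 4, endian = "little")
  writeBin(as.integer(Fs * nch * bytes), con, size = 4, endian = "little")
  writeBin(as.integer(nch * bytes), con, size = 2, endian = "little")
  writeBin(as.integer(bitDepth), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (bitDepth == 32) {
    writeBin(x, con, size = 4, endian = "little")
  } else if (bitDepth == 16) {
    v <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    v <- round(pmax(-8388608, pmin(8388607, x * 8388608)))
    v <- ifelse(v < 0, v + 16777216, v)
    b <- integer(3L * length(v))
    b[seq(1, length(b), 3)] <- v %% 256
    b[seq(2, length(b), 3)] <- (v %/% 256) %% 256
    b[seq(3, length(b), 3)] <- (v %/% 65536) %% 256
    writeBin(as.raw(b), con)
  }
  invisible(path)
}

## ---- delimited tables --------------------------------------------------

#' Read signal channels from a delimited table
#'
#' Dialect: comma-separated, header row, one column per channel, first
#' column optionally time in seconds (named \code{time} or \code{t}).
#'
#' @param path CSV path
#' @param Fs sampling rate; required when the table has no time column
#' @return named list of \linkS4class{Signal} objects
#' @export
readSignalTable <- function(path, Fs = NULL) {
  tab <- utils::read.csv(path, check.names = FALSE)
  nms <- names(tab)
  hasTime <- tolower(nms[1L]) %in% c("time", "t", "time_s")
  t0 <- 0
  if (hasTime) {
    tt <- tab[[1L]]
    if (length(tt) > 1L) {
      dt <- diff(tt)
      stopifnot2(all(dt > 0), "non-monotone timestamps")
      Fs <- 1 / stats::median(dt)
    } else stopifnot2(!is.null(Fs), "need 'Fs' for a 1-row table")
    t0 <- tt[1L]
    tab <- tab[-1L]
  } else {
    stopifnot2(!is.null(Fs), "table has no time column; give 'Fs'")
  }
  out <- lapply(names(tab), function(nm) {
    lab <- if (nm %in% .SIGNAL_LABELS) nm else "other"
    Signal(tab[[nm]], Fs = Fs, t0 = t0, label = lab)
  })
  names(out) <- names(tab)
  out
}

#' Write signal channels to a delimited table
#'
#' @param channels named list of \linkS4class{Signal} (equal length and Fs)
#' @param path output CSV path
#' @param writeTime prepend a time column (default TRUE)
#' @return the path, invisibly
#' @export
writeSignalTable <- function(channels, path, writeTime = TRUE) {
  n <- vapply(channels, nSamples, integer(1))
  stopifnot2(length(unique(n)) == 1L, "channels differ in length")
  tab <- lapply(channels, samples)
  if (writeTime) {
    s1 <- channels[[1L]]
    tab <- c(list(time = s1@t0 + (seq_len(n[1L]) - 1L) / s1@Fs), tab)
  }
  df <- as.data.frame(tab, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## ---- frame stacks ------------------------------------------------------

.toGrey <- function(img) {
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                               drop = FALSE], c(1, 2), mean)
  as.matrix(img)
}

#' Read a frame stack
#'
#' Accepts a multi-page TIFF path or a character vector of image paths
#' (PNG or TIFF), read in the given order. Colour images are averaged to
#' grayscale.
#'
#' @param paths one multi-page TIFF path or several image paths
#' @param fps declared frame rate (Hz)
#' @param bitDepth nominal bit depth
#' @return a \linkS4class{FrameStack}
#' @export
readFrameStack <- function(paths, fps, bitDepth = 8) {
  if (length(paths) == 1L && grepl("\\.tiff?$", paths, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(paths, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    fr <- lapply(pages, .toGrey)
  } else {
    fr <- lapply(paths, function(p) {
      if (grepl("\\.png$", p, ignore.case = TRUE))
        .toGrey(png::readPNG(p))
      else if (grepl("\\.tiff?$", p, ignore.case = TRUE))
        .toGrey(tiff::readTIFF(p))
      else stop("unknown frame format: ", p)
    })
  }
  FrameStack(fr, fps = fps, bitDepth = bitDepth)
}

#' Write a frame stack to a multi-page TIFF
#'
#' @param stack a \linkS4class{FrameStack}
#' @param path output path
#' @return the path, invisibly
#' @export
writeFrameStack <- function(stack, path) {
  tiff::writeTIFF(frames(stack), path,
                  bits.per.sample = if (stack@bitDepth == 16) 16L else 8L)
  invisible(path)
}

## ---- recordings --------------------------------------------------------

#' Read an aligned multi-channel recording
#'
#' Channels can come from mono WAV files and/or a delimited table; frames
#' from a multi-page TIFF or an image sequence. All channels are resampled
#' to \code{targetFs} (polyphase rational resampling with anti-alias
#' filtering) and truncated to a common length when \code{align = TRUE}.
#'
#' @param wav named character vector of WAV paths (names become channel
#'   names), or NULL
#' @param table CSV path in the \code{\link{readSignalTable}} dialect, or
#'   NULL
#' @param frames frame paths for \code{\link{readFrameStack}}, or NULL
#' @param targetFs common sampling rate; default: rate of the first channel
#' @param Fs fallback rate for tables without a time column
#' @param fps frame rate of the image data; default \code{targetFs}
#' @param align truncate channels to a common length (default TRUE); with
#'   \code{align = FALSE} mismatched lengths are an error
#' @return a \linkS4class{Recording}
#' @export
readRecording <- function(wav = NULL, table = NULL, frames = NULL,
                          targetFs = NULL, Fs = NULL, fps = NULL,
                          align = TRUE) {
  chans <- list()
  if (!is.null(wav)) {
    nms <- names(wav)
    if (is.null(nms)) nms <- rep("audio", length(wav))
    for (i in seq_along(wav)) {
      w <- readWav(wav[[i]])
      lab <- if (nms[i] %in% .SIGNAL_LABELS) nms[i] else "other"
      chans[[nms[i]]] <- Signal(w$samples[, 1L], Fs = w$Fs, label = lab)
    }
  }
  if (!is.null(table)) chans <- c(chans, readSignalTable(table, Fs = Fs))
  stopifnot2(length(chans) > 0L || !is.null(frames),
             "no channels or frames given")
  if (is.null(targetFs) && length(chans)) targetFs <- chans[[1L]]@Fs
  chans <- lapply(chans, resampleSignal, targetFs = targetFs)
  if (length(chans) > 1L) {
    n <- vapply(chans, nSamples, integer(1))
    if (length(unique(n)) > 1L) {
      if (!align) stop("mismatched channel lengths; set align = TRUE")
      chans <- lapply(chans, function(ch) {
        ch@samples <- ch@samples[seq_len(min(n))]; ch
      })
    }
  }
  fstack <- NULL
  if (!is.null(frames)) {
    if (is.null(fps)) fps <- if (!is.null(targetFs)) targetFs else 20000
    fstack <- readFrameStack(frames, fps = fps)
  }
  Recording(chans, frames = fstack,
            Fs = if (length(chans)) targetFs else fps)
}

#' Write a Recording to a directory
#'
#' Channels go to \code{channels.csv} (time column + one column per
#' channel); frames, if present, to \code{frames.tif}.
#'
#' @param rec a \linkS4class{Recording}
#' @param dir output directory (created if needed)
#' @return named character vector of written paths, invisibly
#' @export
writeRecording <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (length(channels(rec))) {
    p <- file.path(dir, "channels.csv")
    writeSignalTable(channels(rec), p)
    paths["channels"] <- p
  }
  if (!is.null(frames(rec))) {
    p <- file.path(dir, "frames.tif")
    writeFrameStack(frames(rec), p)
    paths["frames"] <- p
  }
  invisible(paths)
}

## ---- conventions: sign inversion, normalization, resampling ------------

#' Sign-invert an electroglottogram
#'
#' Multiplies an EGG signal by -1 so that the result (iEGG) is oriented
#' like the area waveforms: a positive iEGG corresponds to a positive
#' glottal or supraglottic area, peaking at minimal vocal-fold contact.
#' Applying it to an iEGG maps back to EGG, so the operation is an
#' involution.
#'
#' @param egg a \linkS4class{Signal} labelled \code{"EGG"} (or
#'   \code{"iEGG"} to invert back)
#' @return the negated \linkS4class{Signal} with the toggled label
#' @export
invertEGG <- function(egg) {
  stopifnot2(methods::is(egg, "Signal"), "'egg' must be a Signal")
  stopifnot2(egg@label %in% c("EGG", "iEGG"),
             "invertEGG needs a signal labelled 'EGG' (or 'iEGG')")
  Signal(-egg@samples, Fs = egg@Fs, t0 = egg@t0,
         label = if (egg@label == "EGG") "iEGG" else "EGG")
}

#' Normalize a signal by its maximum absolute value
#'
#' After normalization \code{max(abs(samples)) == 1}; the waveform shape is
#' preserved exactly, so the operation is idempotent and invariant under
#' positive scaling of the input.
#'
#' @param s a \linkS4class{Signal}
#' @return the normalized \linkS4class{Signal}
#' @export
normalizeMaxAbs <- function(s) {
  stopifnot2(methods::is(s, "Signal"), "'s' must be a Signal")
  m <- max(abs(s@samples))
  if (!is.finite(m) || m == 0)
    stop("cannot normalize an all-zero signal", call. = FALSE)
  Signal(s@samples / m, Fs = s@Fs, t0 = s@t0, label = s@label)
}

#' Resample a signal to a new rate
#'
#' Polyphase rational resampling with anti-alias filtering
#' (\code{signal::resample}); the rational factor is the best
#' approximation of \code{targetFs/Fs} with denominator <= 2^10.
#'
#' @param s a \linkS4class{Signal}
#' @param targetFs new sampling rate (Hz)
#' @return the resampled \linkS4class{Signal}
#' @export
resampleSignal <- function(s, targetFs) {
  if (is.null(targetFs) || abs(targetFs - s@Fs) < 1e-9) return(s)
  r <- targetFs / s@Fs
  ## continued-fraction rational approximation
  pq <- .ratApprox(r, maxDen = 1024L)
  y <- signal::resample(s@samples, pq[1L], pq[2L])
  nOut <- round(nSamples(s) * r)
  y <- y[seq_len(min(length(y), nOut))]
  if (length(y) < nOut) y <- c(y, rep(0, nOut - length(y)))
  Signal(y, Fs = targetFs, t0 = s@t0, label = s@label)
}

.ratApprox <- function(x, maxDen = 1024L) {
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L; r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0; q2 <- a * q1 + q0
    if (q2 > maxDen) break
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
    if (abs(p1 / q1 - x) < 1e-12) break
    if (r == a) break
    r <- 1 / (r - a)
  }
  c(as.integer(p1), as.integer(q1))
}
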