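#' @include AllClasses.R
NULL

#' Read a flat key-value pipeline configuration
#'
#' One `section.key = value` pair per line; `#` starts a comment. Values
#' are parsed as numbers where possible, `true`/`false` as logicals.
#' Sections used by \code{\link{runPipeline}}: \code{scene.*} (synthetic
#' input), \code{input.*} (file input), \code{segment.*}, \code{analyze.*},
#' \code{ps.*}, \code{classify.*}, \code{intervals.*}.
#'
#' @param path config file path
#' @return nested named list: \code{cfg$section$key}
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    stopifnot2(length(kv) >= 2L, paste("malformed config line:", ln))
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    else if (tolower(val) %in% c("true", "false"))
      val <- tolower(val) == "true"
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    stopifnot2(length(parts) == 2L,
               paste("config keys must be 'section.key':", key))
    cfg[[parts[1L]]][[parts[2L]]] <- val
  }
  cfg
}

.cfgGet <- function(cfg, section, key, default = NULL) {
  v <- cfg[[section]][[key]]
  if (is.null(v)) default else v
}

.sceneFromConfig <- function(cfg, seed) {
  sc <- cfg$scene
  gliss <- NULL
  if (!is.null(sc$glissando))
    gliss <- as.numeric(strsplit(as.character(sc$glissando), ":")[[1L]])
  glottal <- oscillatorSpec(fo = .cfgGet(cfg, "scene", "glottal_fo", 136),
                            glissando = gliss)
  supra <- NULL
  if (!is.null(sc$supraglottic_fo))
    supra <- oscillatorSpec(fo = sc$supraglottic_fo)
  cpl <- couplingSpec(
    ratioN = .cfgGet(cfg, "scene", "ratio_n", 2),
    phaseOffset = .cfgGet(cfg, "scene", "phase_offset", 0),
    regime = .cfgGet(cfg, "scene", "regime", "locked"),
    subharmonicDepth = .cfgGet(cfg, "scene", "subharmonic_depth", 0),
    noiseSnrDb = .cfgGet(cfg, "scene", "noise_snr", Inf))
  events <- data.frame(time = numeric(0), kind = character(0),
                       value = numeric(0))
  if (!is.null(sc$jump_time))
    events <- data.frame(time = sc$jump_time, kind = "frequency_jump",
                         value = sc$jump_fo)
  render <- NULL
  if (isTRUE(sc$render))
    render <- renderSpec(
      frameSize = c(.cfgGet(cfg, "scene", "frame_width", 96),
                    .cfgGet(cfg, "scene", "frame_height", 80)),
      fps = .cfgGet(cfg, "scene", "fs", 20000),
      glottalMaxArea = .cfgGet(cfg, "scene", "glottal_max_area", 300),
      supraMaxArea = .cfgGet(cfg, "scene", "supra_max_area", 1500))
  sceneSpec(glottal = glottal, coupling = cpl, supraglottic = supra,
            duration = .cfgGet(cfg, "scene", "duration", 1),
            Fs = .cfgGet(cfg, "scene", "fs", 20000),
            events = events, render = render,
            seed = if (is.null(seed)) .cfgGet(cfg, "scene", "seed", 1)
                   else seed)
}

.psLog <- function(level, stage, msg, logLevel) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[logLevel]])
    message(sprintf("[%s] %s: %s", level, stage, msg))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> segment -> analyze -> phase
#' synchrony -> classify, writing every stage output as plain text plus a
#' run manifest with checksums. Reruns with the same configuration and
#' seed are byte-identical. Stage failures surface with the stage name;
#' configuration problems (e.g. an analysis interval beyond the recording
#' duration) are caught before any computation.
#'
#' @param config path to a config file (see
#'   \code{\link{readPipelineConfig}}) or an equivalent nested list
#' @param outDir output directory (created)
#' @param seed overrides the scene seed
#' @param logLevel \code{"debug"}, \code{"info"} or \code{"warn"}
#' @return invisibly, a list with the recording, fo tracks, events, PS
#'   series, label and the manifest path
#' @export
runPipeline <- function(config, outDir, seed = NULL, logLevel = "info") {
  cfg <- if (is.character(config)) readPipelineConfig(config) else config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(name, writer) {
    p <- file.path(outDir, name)
    writer(p)
    written <<- c(written, p)
    p
  }

  hasScene <- !is.null(cfg$scene)
  hasInput <- !is.null(cfg$input)
  stopifnot2(xor(hasScene, hasInput),
             "exactly one input source: 'scene.*' or 'input.*'")

  ## ---- validate intervals before any compute --------------------------
  dur <- if (hasScene) .cfgGet(cfg, "scene", "duration", 1) else Inf
  intervals <- lapply(cfg$intervals, function(v)
    as.numeric(strsplit(as.character(v), ":")[[1L]]))
  for (nm in names(intervals)) {
    iv <- intervals[[nm]]
    stopifnot2(length(iv) == 2L && iv[1L] >= 0 && iv[2L] <= dur &&
               iv[1L] < iv[2L],
               sprintf("interval '%s' invalid or beyond duration", nm))
  }

  ## ---- stage: input ----------------------------------------------------
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  scene <- NULL
  rec <- stage("simulate", {
    if (hasScene) {
      spec <- .sceneFromConfig(cfg, seed)
      .psLog("info", "simulate", sprintf("scene: %s, ratio %d:1",
             spec@coupling@regime, as.integer(spec@coupling@ratioN)),
             logLevel)
      scene <- makeCoupledScene(spec)
      emit("ground_truth.csv", function(p)
        utils::write.csv(scene$truth, p, row.names = FALSE))
      emit("channels.csv", function(p)
        writeSignalTable(channels(scene$recording), p))
      if (!is.null(frames(scene$recording)))
        emit("frames.tif", function(p)
          writeFrameStack(frames(scene$recording), p))
      scene$recording
    } else {
      readRecording(wav = cfg$input$wav, table = cfg$input$table,
                    frames = cfg$input$frames,
                    targetFs = cfg$input$target_fs, Fs = cfg$input$fs)
    }
  })

  if (isTRUE(.cfgGet(cfg, "scene", "simulate_only", FALSE))) {
    manifest <- .writeManifest(cfg, seed, written, outDir)
    return(invisible(list(recording = rec, manifest = manifest)))
  }

  ## ---- stage: segment --------------------------------------------------
  if (!is.null(frames(rec))) {
    stage("segment", {
      for (tgt in c("glottal", "supraglottic")) {
        thr <- .cfgGet(cfg, "segment", paste0(tgt, "_threshold"),
                       if (tgt == "glottal") 0.75 else 0.3)
        ceil <- .cfgGet(cfg, "segment", paste0(tgt, "_ceiling"),
                        if (tgt == "glottal") 1 else 0.75)
        prof <- segmentationProfile(greyThreshold = thr, target = tgt,
                                    greyCeiling = ceil)
        aw <- segmentArea(frames(rec), prof)
        lab <- if (tgt == "glottal") "GAW" else "SAW"
        emit(paste0(tolower(lab), "_segmented.csv"), function(p)
          utils::write.csv(data.frame(
            frame_index = seq_along(areas(aw)),
            time_s = (seq_along(areas(aw)) - 1) / fps(aw),
            area_px2 = areas(aw)), p, row.names = FALSE))
      }
    })
  }

  ## ---- stage: analyze --------------------------------------------------
  fmin <- .cfgGet(cfg, "analyze", "fmin", 40)
  fmax <- .cfgGet(cfg, "analyze", "fmax", 600)
  tracks <- stage("analyze", {
    tr <- list()
    for (nm in names(channels(rec))) {
      tr[[nm]] <- estimateFo(rec[[nm]], fmin = fmin, fmax = fmax)
      emit(paste0("fo_", nm, ".csv"), function(p)
        utils::write.csv(as.data.frame(tr[[nm]]), p, row.names = FALSE))
    }
    tr
  })

  events <- stage("analyze", {
    detCh <- .cfgGet(cfg, "analyze", "detect_channel", "iEGG")
    refTrack <- if (!is.null(tracks$GAW)) tracks$GAW else tracks[[detCh]]
    ev <- rbind(
      detectSubharmonics(rec[[detCh]], refTrack),
      detectFrequencyJump(tracks[[detCh]]),
      detectBiphonation(rec[[detCh]]))
    emit("events.csv", function(p)
      utils::write.csv(ev, p, row.names = FALSE))
    ev
  })

  ## ---- stage: ps -------------------------------------------------------
  psSeries <- stage("ps", {
    aName <- .cfgGet(cfg, "ps", "a", "iEGG")
    bName <- .cfgGet(cfg, "ps", "b", "SAW")
    grp <- .cfgGet(cfg, "ps", "group", "group2")
    if (grp == "group1") {
      foI <- foSegmentStats(tracks[[aName]])$mean
      foA <- foSegmentStats(if (!is.null(tracks$audio)) tracks$audio
                            else tracks[[bName]])$mean
      opts <- psOptions("group1", Fs = samplingRate(rec), foIEGG = foI,
                        foAudio = foA)
    } else {
      opts <- psOptions("group2", Fs = samplingRate(rec))
    }
    ps <- windowedPS(rec[[aName]], rec[[bName]], opts)
    nMissing <- sum(is.na(psMedian(ps)))
    if (nMissing > 0)
      .psLog("warn", "ps", sprintf("%d window(s) silent; PS missing",
                                   nMissing), logLevel)
    emit("ps_series.csv", function(p)
      utils::write.csv(as.data.frame(ps), p, row.names = FALSE))
    ps
  })

  ## ---- stage: classify -------------------------------------------------
  label <- stage("classify", {
    glotName <- if (!is.null(tracks$GAW)) "GAW" else "iEGG"
    supName <- if (!is.null(tracks$SAW)) "SAW" else "audio"
    piWin <- .cfgGet(cfg, "classify", "pi_window", 0.1)
    pidx <- periodicityIndex(rec[[supName]], piWin)
    est <- tryCatch(
      estimateRatio(tracks[[glotName]], tracks[[supName]]),
      error = function(e) data.frame(n = NA, ratio = NA, confidence = 0))
    lab <- classifyGroup(mean(pidx$index, na.rm = TRUE), est$confidence,
                         isTRUE(.cfgGet(cfg, "classify",
                                        "glottis_visible", TRUE)))
    lab$ratioN <- est$n
    emit("label.json", function(p)
      jsonlite::write_json(as.list(lab), p, auto_unbox = TRUE,
                           digits = NA))
    lab
  })

  manifest <- .writeManifest(cfg, seed, written, outDir)
  invisible(list(recording = rec, tracks = tracks, events = events,
                 ps = psSeries, label = label, manifest = manifest))
}

.writeManifest <- function(cfg, seed, written, outDir) {
  files <- lapply(written, function(p)
    list(name = basename(p), md5 = unname(tools::md5sum(p))))
  manifest <- list(
    package = "phonosync",
    version = as.character(utils::packageVersion("phonosync")),
    seed = if (is.null(seed)) NA else seed,
    configHash = unname(.hashConfig(cfg)),
    outputs = files)
  p <- file.path(outDir, "run_manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       null = "null")
  p
}

.hashConfig <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(cfg, file = tmp)
  tools::md5sum(tmp)
}
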