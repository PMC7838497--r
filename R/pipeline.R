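#' Run the full sEPSC analysis for one cell
#'
#' Noise estimation -> event detection -> 10-s binning -> baseline
#' normalisation -> maximal-effect window -> burst detection ->
#' responsiveness, with every parameter echoed in the returned report.
#'
#' @param trace a [CurrentTrace-class] with its protocol attached.
#' @param binWidth bin width, seconds.
#' @param kThreshold event detection threshold in noise SDs.
#' @param refractoryMs event refractory period, ms.
#' @param windowMin maximal-effect window width, minutes.
#' @param alpha significance level for responsiveness.
#' @param postMin responsiveness comparison span after onset, minutes.
#' @return An `ExperimentReport` list with components `cellId`, `noiseSd`,
#'   `events` (times/amplitudes/epochs), `frequency` and `amplitude`
#'   summaries (baseline mean, effect window, percent of baseline, percent
#'   increase), `bursts`, `responsive`, and `params`.
#' @export
runEpscPipeline <- function(trace, binWidth = 10, kThreshold = 3,
                            refractoryMs = 2, windowMin = 5, alpha = 0.05,
                            postMin = 10) {
  prot <- trace@protocol
  ep <- prot@epochs
  ctrl <- ep[ep$label == "control", , drop = FALSE]
  noiseWin <- if (nrow(ctrl)) as.numeric(ctrl[1L, c("start", "end")]) else NULL
  noise <- estimateNoise(trace, noiseWin)
  train <- detectEvents(trace, noise, kThreshold = kThreshold,
                        refractoryMs = refractoryMs)

  freq <- binFrequency(train, binWidth)
  freqN <- normalizeToBaseline(freq, prot)
  hasDrug <- !is.na(drugOnset(prot))

  win <- percentIncrease <- percentOfBaseline <- NULL
  ampPercentIncrease <- NA_real_
  resp <- list(responsive = NA, pValue = NA_real_)
  if (hasDrug) {
    win <- selectEffectWindow(freqN, prot, windowMin)
    lo <- freqN@binEdges[-length(freqN@binEdges)]
    inWin <- lo >= win[1L] - 1e-9 & lo < win[2L] - 1e-9
    percentOfBaseline <- mean(freqN@values[inWin], na.rm = TRUE)
    percentIncrease <- percentOfBaseline - 100
    resp <- responsiveCell(freq, prot, alpha = alpha, postMin = postMin)
  }

  amp <- binAmplitude(train, binWidth)
  ampN <- tryCatch(normalizeToBaseline(amp, prot), error = function(e) NULL)
  ampBase <- if (!is.null(ampN)) ampN@baselineMean else NA_real_
  if (hasDrug && !is.null(ampN)) {
    lo <- ampN@binEdges[-length(ampN@binEdges)]
    inWin <- lo >= win[1L] - 1e-9 & lo < win[2L] - 1e-9
    ampPercentIncrease <- mean(ampN@values[inWin], na.rm = TRUE) - 100
  }

  baselineFreq <- freq@baselineMean
  if (is.na(baselineFreq)) baselineFreq <- freqN@baselineMean
  bursts <- if (baselineFreq > 0)
    detectBursts(train, baselineFreq)
  else data.frame()

  list(
    kind = "epsc",
    cellId = trace@cellId,
    noiseSd = noise@sd,
    nEvents = length(train@times),
    events = data.frame(time_s = train@times,
                        amplitude_pA = train@amplitudes,
                        epoch = epochOf(prot, train@times)),
    frequency = list(
      binEdges = freq@binEdges, valuesHz = freq@values,
      normalized = freqN@values, baselineHz = freqN@baselineMean,
      effectWindow = win, percentOfBaseline = percentOfBaseline,
      percentIncrease = percentIncrease),
    amplitude = list(
      binEdges = amp@binEdges, valuesPa = amp@values,
      baselinePa = ampBase, percentIncrease = ampPercentIncrease),
    bursts = bursts,
    responsive = list(flag = resp$responsive, pValue = resp$pValue),
    params = list(binWidth = binWidth, kThreshold = kThreshold,
                  refractoryMs = refractoryMs, windowMin = windowMin,
                  alpha = alpha, postMin = postMin,
                  protocol = prot@epochs)
  )
}

#' Run the population calcium-imaging analysis
#'
#' (Movie -> ROIs ->) dF/F -> transient detection -> binary raster ->
#' coactivity histogram with Monte Carlo surrogate threshold -> per-cell
#' activity per condition -> cross-condition tests.
#'
#' @param input a [Movie-class], [FluorTraces-class] or [DffTraces-class].
#' @param protocol a [DrugProtocol-class] used to label frames; NULL treats
#'   the whole recording as a single "control" condition.
#' @param kAmp,kDeriv transient detection thresholds (see
#'   [detectTransients()]).
#' @param nSurrogates,alpha,seed Monte Carlo settings (see
#'   [monteCarloThreshold()]).
#' @param diameterRange ROI diameters for movie input, um.
#' @return An `ExperimentReport` list with components `nCells`, `raster`,
#'   `coactivity` (counts, threshold, significant frames), `activity`
#'   (per-cell table), `tests` (KS and Friedman results, when >= 3
#'   conditions), and `params`.
#' @export
runCalciumPipeline <- function(input, protocol = NULL, kAmp = 2.5,
                               kDeriv = 2.5, nSurrogates = 1000,
                               alpha = 0.05, seed = 1L,
                               diameterRange = c(4, 30)) {
  roiMap <- NULL
  if (is(input, "Movie")) {
    roiMap <- extractRois(input, diameterRange = diameterRange)
    raw <- roiTraces(input, roiMap)
    dff <- computeDff(raw)
  } else if (is(input, "FluorTraces")) {
    dff <- computeDff(input)
  } else if (is(input, "DffTraces")) {
    dff <- input
  } else stop("input must be a Movie, FluorTraces or DffTraces object")

  nC <- nrow(dff@traces)
  if (nC == 0L) {
    return(list(kind = "calcium", nCells = 0L, raster = matrix(0, 0, 0),
                coactivity = list(counts = integer(0), threshold = NA_real_,
                                  significantFrames = integer(0),
                                  nSurrogates = 0L),
                activity = data.frame(), tests = NULL,
                params = list(kAmp = kAmp, kDeriv = kDeriv,
                              nSurrogates = nSurrogates, alpha = alpha,
                              seed = seed)))
  }

  tset <- detectTransients(dff, kAmp = kAmp, kDeriv = kDeriv)
  raster <- binarize(tset, protocol = protocol)
  if (is.null(protocol))
    raster@conditionOfFrame <- rep("control", ncol(raster@mat))
  co <- monteCarloThreshold(raster, nSurrogates = nSurrogates,
                            alpha = alpha, seed = seed)
  act <- cellActivity(raster)
  nConds <- length(unique(act@table$condition))
  tests <- NULL
  if (nConds >= 3L && nC >= 5L) {
    cmp <- compareActivity(act)
    tests <- list(
      ks = lapply(cmp$ks, function(t)
        list(statistic = t@statistic, pValue = t@pValue)),
      friedman = list(statistic = cmp$friedman@statistic,
                      pValue = cmp$friedman@pValue))
  }

  list(
    kind = "calcium",
    nCells = nC,
    roiMap = if (!is.null(roiMap)) roiMap@rois else NULL,
    noiseSd = tset@noiseSd,
    ampThreshold = tset@ampThreshold,
    raster = raster@mat,
    conditionOfFrame = raster@conditionOfFrame,
    frameRate = raster@frameRate,
    coactivity = list(counts = co@coactivity, threshold = co@threshold,
                      significantFrames = co@significantFrames,
                      nSurrogates = co@nSurrogates, alpha = co@alpha,
                      seed = co@seed),
    activity = act@table,
    tests = tests,
    params = list(kAmp = kAmp, kDeriv = kDeriv, nSurrogates = nSurrogates,
                  alpha = alpha, seed = seed)
  )
}

#' Run a config-driven experiment
#'
#' Reads a YAML (or list) configuration describing the protocol, the arm to
#' run (`epsc`, `calcium`, or both), simulation or input-file settings and
#' analysis parameters; runs the corresponding pipelines; and, when
#' `outDir` is given, serialises the reports as JSON alongside CSV event
#' tables. All seeds and parameters are echoed into the reports.
#'
#' @param config path to a YAML file or an equivalent nested list. Top-level
#'   fields: `protocol` (`control`/`drug`/`wash` durations plus effect
#'   parameters), `epsc` and/or `calcium` blocks, each with either a
#'   `simulate` sub-block (generator parameters) or an `input` path, plus
#'   analysis parameters matching the pipeline arguments.
#' @param outDir optional output directory.
#' @return Named list of reports (`epsc`, `calcium` as configured).
#' @export
runExperiment <- function(config, outDir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  pc <- config$protocol
  if (is.null(pc)) stop("config must contain a protocol block")
  prot <- drugProtocol(
    control = pc$control %||% 600, drug = pc$drug %||% 600,
    wash = pc$wash %||% 600,
    drugRateRatio = pc$drugRateRatio %||% 2.72,
    drugAmpRatio = pc$drugAmpRatio %||% 2.403,
    onsetTau = pc$onsetTau %||% 60,
    washoutPersistence = pc$washoutPersistence %||% 0.8)

  reports <- list()
  if (!is.null(config$epsc)) {
    ec <- config$epsc
    trace <- if (!is.null(ec$input)) {
      readCurrentTrace(ec$input, samplingRate = ec$samplingRate %||% 5000,
                       protocol = prot)
    } else {
      sp <- ec$simulate %||% list()
      params <- epscSimParams(
        baseRate = sp$baseRate %||% 3.5, noiseSd = sp$noiseSd %||% 2,
        burstRate = sp$burstRate %||% 0, seed = sp$seed %||% 1L)
      simulateEpscTrace(params, prot)$trace
    }
    reports$epsc <- runEpscPipeline(
      trace, binWidth = ec$binWidth %||% 10,
      kThreshold = ec$kThreshold %||% 3, alpha = ec$alpha %||% 0.05)
  }
  if (!is.null(config$calcium)) {
    cc <- config$calcium
    input <- if (!is.null(cc$input)) {
      readMovieTiff(cc$input, frameRate = cc$frameRate %||% 4,
                    pixelSize = cc$pixelSize %||% 1)
    } else {
      sp <- cc$simulate %||% list()
      params <- calciumSimParams(
        nCells = sp$nCells %||% 30, bgEventRate = sp$bgEventRate %||% 0.1,
        ensembleRate = sp$ensembleRate %||% 0.02, seed = sp$seed %||% 1L)
      simulateCalciumTraces(params, prot)$traces
    }
    reports$calcium <- runCalciumPipeline(
      input, prot, kAmp = cc$kAmp %||% 2.5, kDeriv = cc$kDeriv %||% 2.5,
      nSurrogates = cc$nSurrogates %||% 1000, alpha = cc$alpha %||% 0.05,
      seed = cc$seed %||% 1L)
  }

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(reports)) {
      writeReportJson(reports[[nm]], file.path(outDir, paste0(nm, "-report.json")))
      if (nm == "epsc")
        utils::write.csv(reports$epsc$events,
                         file.path(outDir, "epsc-events.csv"),
                         row.names = FALSE)
      if (nm == "calcium")
        utils::write.csv(as.data.frame(reports$calcium$raster),
                         file.path(outDir, "calcium-raster.csv"),
                         row.names = FALSE)
    }
  }
  reports
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
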