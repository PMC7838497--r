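## Generics and accessors. Accessor functions are the supported way to reach
## slot contents; slot layout is not part of the API.

#' @name accessors
#' @title Accessors for episcope classes
#' @param object an episcope S4 object.
#' @param x an episcope S4 object.
#' @return The slot contents documented per method.
NULL

#' @rdname accessors
#' @export
setGeneric("epochs", function(object) standardGeneric("epochs"))

#' @rdname accessors
#' @export
setMethod("epochs", "DrugProtocol", function(object) object@epochs)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setMethod("samplingRate", "CurrentTrace", function(object) object@samplingRate)

#' @rdname accessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname accessors
#' @export
setMethod("frameRate", "FluorTraces", function(object) object@frameRate)

#' @rdname accessors
#' @export
setMethod("frameRate", "DffTraces", function(object) object@frameRate)

#' @rdname accessors
#' @export
setMethod("frameRate", "Movie", function(object) object@frameRate)

#' @rdname accessors
#' @export
setMethod("frameRate", "BinaryRaster", function(object) object@frameRate)

#' @rdname accessors
#' @export
setGeneric("traceSamples", function(object) standardGeneric("traceSamples"))

#' @rdname accessors
#' @export
setMethod("traceSamples", "CurrentTrace", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("protocol", function(object) standardGeneric("protocol"))

#' @rdname accessors
#' @export
setMethod("protocol", "CurrentTrace", function(object) object@protocol)

#' @rdname accessors
#' @export
setGeneric("eventTimes", function(object) standardGeneric("eventTimes"))

#' @rdname accessors
#' @export
setMethod("eventTimes", "EventTrain", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("eventAmplitudes", function(object) standardGeneric("eventAmplitudes"))

#' @rdname accessors
#' @export
setMethod("eventAmplitudes", "EventTrain", function(object) object@amplitudes)

#' @rdname accessors
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))

#' @rdname accessors
#' @export
setMethod("binEdges", "BinnedSeries", function(object) object@binEdges)

#' @rdname accessors
#' @export
setGeneric("binValues", function(object) standardGeneric("binValues"))

#' @rdname accessors
#' @export
setMethod("binValues", "BinnedSeries", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("traceMatrix", function(object) standardGeneric("traceMatrix"))

#' @rdname accessors
#' @export
setMethod("traceMatrix", "FluorTraces", function(object) object@traces)

#' @rdname accessors
#' @export
setMethod("traceMatrix", "DffTraces", function(object) object@traces)

#' @rdname accessors
#' @export
setGeneric("rasterMatrix", function(object) standardGeneric("rasterMatrix"))

#' @rdname accessors
#' @export
setMethod("rasterMatrix", "BinaryRaster", function(object) object@mat)

#' @rdname accessors
#' @export
setGeneric("conditionOfFrame", function(object) standardGeneric("conditionOfFrame"))

#' @rdname accessors
#' @export
setMethod("conditionOfFrame", "BinaryRaster", function(object) object@conditionOfFrame)

#' @rdname accessors
#' @export
setGeneric("rois", function(object) standardGeneric("rois"))

#' @rdname accessors
#' @export
setMethod("rois", "RoiMap", function(object) object@rois)

#' @rdname accessors
#' @export
setGeneric("transientOnsets", function(object) standardGeneric("transientOnsets"))

#' @rdname accessors
#' @export
setMethod("transientOnsets", "TransientSet", function(object) object@onsets)

#' @rdname accessors
#' @export
setGeneric("noiseSd", function(object) standardGeneric("noiseSd"))

#' @rdname accessors
#' @export
setMethod("noiseSd", "NoiseModel", function(object) object@sd)

#' @rdname accessors
#' @export
setMethod("noiseSd", "TransientSet", function(object) object@noiseSd)

#' @rdname accessors
#' @export
setGeneric("ampThreshold", function(object) standardGeneric("ampThreshold"))

#' @rdname accessors
#' @export
setMethod("ampThreshold", "TransientSet", function(object) object@ampThreshold)

#' @rdname accessors
#' @export
setGeneric("coactivityCounts", function(object) standardGeneric("coactivityCounts"))

#' @rdname accessors
#' @export
setMethod("coactivityCounts", "CoactivityResult", function(object) object@coactivity)

#' @rdname accessors
#' @export
setGeneric("coactivityThreshold", function(object) standardGeneric("coactivityThreshold"))

#' @rdname accessors
#' @export
setMethod("coactivityThreshold", "CoactivityResult", function(object) object@threshold)

#' @rdname accessors
#' @export
setGeneric("significantFrames", function(object) standardGeneric("significantFrames"))

#' @rdname accessors
#' @export
setMethod("significantFrames", "CoactivityResult", function(object) object@significantFrames)

#' @rdname accessors
#' @export
setGeneric("nSurrogates", function(object) standardGeneric("nSurrogates"))

#' @rdname accessors
#' @export
setMethod("nSurrogates", "CoactivityResult", function(object) object@nSurrogates)

#' @rdname accessors
#' @export
setGeneric("activityTable", function(object) standardGeneric("activityTable"))

#' @rdname accessors
#' @export
setMethod("activityTable", "CellActivitySummary", function(object) object@table)

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setMethod("pValue", "TestResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setGeneric("testStatistic", function(object) standardGeneric("testStatistic"))

#' @rdname accessors
#' @export
setMethod("testStatistic", "TestResult", function(object) object@statistic)

#' @rdname accessors
#' @export
setGeneric("truthEvents", function(object) standardGeneric("truthEvents"))

#' @rdname accessors
#' @export
setMethod("truthEvents", "SimTruth", function(object) object@events)

#' @rdname accessors
#' @export
setGeneric("truthCellFrames", function(object) standardGeneric("truthCellFrames"))

#' @rdname accessors
#' @export
setMethod("truthCellFrames", "SimTruth", function(object) object@cellEventFrames)

#' @rdname accessors
#' @export
setGeneric("truthEnsembleFrames", function(object) standardGeneric("truthEnsembleFrames"))

#' @rdname accessors
#' @export
setMethod("truthEnsembleFrames", "SimTruth", function(object) object@ensembleFrames)

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setMethod("nCells", "BinaryRaster", function(x) nrow(x@mat))

#' @rdname accessors
#' @export
setMethod("nCells", "FluorTraces", function(x) nrow(x@traces))

#' @rdname accessors
#' @export
setMethod("nCells", "DffTraces", function(x) nrow(x@traces))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setMethod("nFrames", "BinaryRaster", function(x) ncol(x@mat))

#' @rdname accessors
#' @export
setMethod("nFrames", "FluorTraces", function(x) ncol(x@traces))

#' @rdname accessors
#' @export
setMethod("nFrames", "DffTraces", function(x) ncol(x@traces))

#' @rdname accessors
#' @export
setMethod("nFrames", "Movie", function(x) dim(x@frames)[3L])

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "DrugProtocol", function(object) {
  ep <- object@epochs
  cat("DrugProtocol:", nrow(ep), "epoch(s),",
      sprintf("rate ratio %.3g, amp ratio %.3g, onset tau %.3g s, persistence %.3g\n",
              object@drugRateRatio, object@drugAmpRatio,
              object@onsetTau, object@washoutPersistence))
  for (i in seq_len(nrow(ep)))
    cat(sprintf("  %-8s %8.1f - %8.1f s\n", ep$label[i], ep$start[i], ep$end[i]))
  invisible(NULL)
})

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf(
    "CurrentTrace '%s': %.1f s at %g Hz, holding %g mV\n",
    object@cellId, length(object@samples) / object@samplingRate,
    object@samplingRate, object@holdingPotential))
  invisible(NULL)
})

setMethod("show", "EventTrain", function(object) {
  n <- length(object@times)
  cat(sprintf("EventTrain '%s': %d events over %.1f s (%.3g Hz)\n",
              object@cellId, n, object@duration,
              if (object@duration > 0) n / object@duration else NA_real_))
  invisible(NULL)
})

setMethod("show", "BinnedSeries", function(object) {
  cat(sprintf("BinnedSeries: %d bins of %.3g s [%s]%s\n",
              length(object@values),
              if (length(object@binEdges) > 1) diff(object@binEdges[1:2]) else NA,
              object@units,
              if (isTRUE(object@normalized)) " (normalised to baseline)" else ""))
  invisible(NULL)
})

setMethod("show", "FluorTraces", function(object) {
  cat(sprintf("FluorTraces: %d cell(s) x %d frame(s) at %g frames/s\n",
              nrow(object@traces), ncol(object@traces), object@frameRate))
  invisible(NULL)
})

setMethod("show", "DffTraces", function(object) {
  cat(sprintf("DffTraces: %d cell(s) x %d frame(s) at %g frames/s\n",
              nrow(object@traces), ncol(object@traces), object@frameRate))
  invisible(NULL)
})

setMethod("show", "Movie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Movie: %d x %d px, %d frames at %g frames/s (%g um/px)\n",
              d[1L], d[2L], d[3L], object@frameRate, object@pixelSize))
  invisible(NULL)
})

setMethod("show", "RoiMap", function(object) {
  cat(sprintf("RoiMap: %d ROI(s) on a %d x %d summary image\n",
              nrow(object@rois), nrow(object@summaryImage),
              ncol(object@summaryImage)))
  invisible(NULL)
})

setMethod("show", "TransientSet", function(object) {
  cat(sprintf("TransientSet: %d cell(s), %d transient(s) over %d frames\n",
              length(object@onsets), sum(lengths(object@onsets)),
              object@nFrames))
  invisible(NULL)
})

setMethod("show", "BinaryRaster", function(object) {
  cat(sprintf("BinaryRaster: %d cell(s) x %d frame(s), %d active entr%s\n",
              nrow(object@mat), ncol(object@mat), sum(object@mat),
              if (sum(object@mat) == 1) "y" else "ies"))
  invisible(NULL)
})

setMethod("show", "CoactivityResult", function(object) {
  cat(sprintf(
    "CoactivityResult: threshold %s (%d surrogates, alpha %.3g), %d significant frame(s)\n",
    format(object@threshold), object@nSurrogates, object@alpha,
    length(object@significantFrames)))
  invisible(NULL)
})

setMethod("show", "CellActivitySummary", function(object) {
  cat(sprintf("CellActivitySummary: %d cell(s) x %d condition(s)\n",
              length(unique(object@table$cell)),
              length(unique(object@table$condition))))
  invisible(NULL)
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g%s\n", object@method,
              object@statistic, object@pValue,
              if (isTRUE(object@exact)) " (exact)" else ""))
  invisible(NULL)
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %d event(s), %d cell frame list(s), %d ensemble frame(s)\n",
              nrow(object@events), length(object@cellEventFrames),
              length(object@ensembleFrames)))
  invisible(NULL)
})
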