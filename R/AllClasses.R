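#' @import methods
NULL

## ---------------------------------------------------------------------------
## Drug protocol
## ---------------------------------------------------------------------------

#' Drug administration protocol
#'
#' Describes the condition structure of a slice experiment: a control
#' (baseline) recording period, a drug administration epoch, and an optional
#' washout period, together with the modelled drug effect sizes. The drug
#' effect on event rate and amplitude rises exponentially after drug onset
#' with time constant `onsetTau` and is retained at a fraction
#' `washoutPersistence` of its asymptotic size after the drug is washed out.
#'
#' @slot epochs data.frame with columns `label` (one of "control", "drug",
#'   "wash"), `start` and `end` (seconds). Epochs must be non-overlapping and
#'   strictly increasing, with exactly one control epoch preceding any drug
#'   epoch.
#' @slot drugRateRatio asymptotic multiplicative effect of the drug on event
#'   rate (dimensionless, > 0).
#' @slot drugAmpRatio asymptotic multiplicative effect on event amplitude
#'   (dimensionless, > 0).
#' @slot onsetTau exponential onset time constant, seconds.
#' @slot washoutPersistence fraction of the asymptotic drug effect retained
#'   after washout, in \[0, 1\].
#'
#' @seealso [drugProtocol()]
#' @export
setClass("DrugProtocol",
  representation(
    epochs = "data.frame",
    drugRateRatio = "numeric",
    drugAmpRatio = "numeric",
    onsetTau = "numeric",
    washoutPersistence = "numeric"
  )
)

setValidity("DrugProtocol", function(object) {
  ep <- object@epochs
  msgs <- character(0)
  if (!all(c("label", "start", "end") %in% names(ep)))
    return("epochs must have columns label, start, end")
  if (nrow(ep) < 1L) return("at least one epoch is required")
  if (!all(ep$label %in% c("control", "drug", "wash")))
    msgs <- c(msgs, "epoch labels must be control, drug or wash")
  if (any(ep$end <= ep$start))
    msgs <- c(msgs, "each epoch must have end > start")
  if (nrow(ep) > 1L) {
    if (is.unsorted(ep$start, strictly = TRUE))
      msgs <- c(msgs, "epochs must be strictly increasing")
    if (any(ep$start[-1L] < ep$end[-nrow(ep)]))
      msgs <- c(msgs, "epochs must not overlap")
  }
  if (any(ep$label == "drug")) {
    firstDrug <- min(which(ep$label == "drug"))
    ctrl <- which(ep$label == "control")
    if (length(ctrl) != 1L || ctrl >= firstDrug)
      msgs <- c(msgs, "exactly one control epoch must precede any drug epoch")
  }
  if (length(object@drugRateRatio) != 1L || object@drugRateRatio <= 0)
    msgs <- c(msgs, "drugRateRatio must be a positive scalar")
  if (length(object@drugAmpRatio) != 1L || object@drugAmpRatio <= 0)
    msgs <- c(msgs, "drugAmpRatio must be a positive scalar")
  if (length(object@onsetTau) != 1L || object@onsetTau <= 0)
    msgs <- c(msgs, "onsetTau must be a positive scalar (seconds)")
  wp <- object@washoutPersistence
  if (length(wp) != 1L || is.na(wp) || wp < 0 || wp > 1)
    msgs <- c(msgs, "washoutPersistence must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

## ---------------------------------------------------------------------------
## Simulation parameter containers
## ---------------------------------------------------------------------------

#' Parameters for the synthetic sEPSC trace generator
#'
#' @slot samplingRate sampling rate in Hz (acquisition default 5000).
#' @slot duration trace duration in seconds; `NA` means "span the protocol".
#' @slot baseRate baseline spontaneous event rate, Hz.
#' @slot ampMedian median event amplitude, pA (inward events are rendered as
#'   negative deflections; amplitudes are stored as positive magnitudes).
#' @slot ampSigmaLog log-scale SD of the lognormal amplitude distribution.
#' @slot kernelRiseTau,kernelDecayTau biexponential kernel time constants, ms.
#' @slot noiseSd Gaussian baseline noise SD, pA.
#' @slot burstRate rate of burst insertions at full drug effect, Hz.
#' @slot burstSizeRange integer pair, events per burst (minimum >= 3).
#' @slot intraBurstMs numeric pair, uniform range of intra-burst intervals, ms.
#' @slot refractoryMs minimum separation imposed on background events, ms.
#' @slot seed integer seed; generation is bit-reproducible given params + seed.
#' @export
setClass("EpscSimParams",
  representation(
    samplingRate = "numeric", duration = "numeric", baseRate = "numeric",
    ampMedian = "numeric", ampSigmaLog = "numeric",
    kernelRiseTau = "numeric", kernelDecayTau = "numeric",
    noiseSd = "numeric", burstRate = "numeric",
    burstSizeRange = "integer", intraBurstMs = "numeric",
    refractoryMs = "numeric", seed = "integer"
  )
)

setValidity("EpscSimParams", function(object) {
  msgs <- character(0)
  if (object@samplingRate <= 0) msgs <- c(msgs, "samplingRate must be > 0")
  if (object@baseRate < 0) msgs <- c(msgs, "baseRate must be >= 0")
  if (object@burstRate < 0) msgs <- c(msgs, "burstRate must be >= 0")
  if (object@kernelRiseTau <= 0 || object@kernelDecayTau <= 0)
    msgs <- c(msgs, "kernel time constants must be > 0")
  if (object@kernelRiseTau >= object@kernelDecayTau)
    msgs <- c(msgs, "kernelRiseTau must be smaller than kernelDecayTau")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (length(object@burstSizeRange) != 2L || object@burstSizeRange[1L] < 3L)
    msgs <- c(msgs, "burstSizeRange must be an integer pair with minimum >= 3")
  if (length(object@intraBurstMs) != 2L || any(object@intraBurstMs <= 0))
    msgs <- c(msgs, "intraBurstMs must be a positive pair (ms)")
  if (object@refractoryMs < 0) msgs <- c(msgs, "refractoryMs must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Parameters for the synthetic calcium-imaging generator
#'
#' Defaults mirror the acquisition: 4 frames/s, 6-min videos (1,440 frames),
#' a 280 x 260 um field and circular cells of 4-30 um diameter.
#'
#' @slot nCells number of cells.
#' @slot frameRate acquisition rate, frames/s.
#' @slot nFrames number of frames; `NA` derives it from the protocol span
#'   (`round(frameRate * total duration)`).
#' @slot fieldSize field of view, um (width, height).
#' @slot pixelSize um per pixel.
#' @slot cellDiameterRange cell diameter range, um, within \[4, 30\].
#' @slot bgEventRate per-cell background calcium-event rate, Hz.
#' @slot ensembleRate rate of population (ensemble) events, Hz.
#' @slot participationP probability that a cell joins an ensemble event.
#' @slot transientAmp transient amplitude, dF/F units (instantaneous rise).
#' @slot decayTau transient exponential decay time constant, seconds.
#' @slot noiseSd additive Gaussian noise SD, dF/F units.
#' @slot conditionRateRatios named per-epoch rate multipliers
#'   (e.g. `c(control = 1, drug = 2, wash = 2)`), applied to both the
#'   background and ensemble event rates.
#' @slot seed integer seed.
#' @export
setClass("CalciumSimParams",
  representation(
    nCells = "integer", frameRate = "numeric", nFrames = "integer",
    fieldSize = "numeric", pixelSize = "numeric",
    cellDiameterRange = "numeric", bgEventRate = "numeric",
    ensembleRate = "numeric", participationP = "numeric",
    transientAmp = "numeric", decayTau = "numeric", noiseSd = "numeric",
    conditionRateRatios = "numeric", seed = "integer"
  )
)

setValidity("CalciumSimParams", function(object) {
  msgs <- character(0)
  if (object@nCells < 0L) msgs <- c(msgs, "nCells must be >= 0")
  if (object@frameRate <= 0) msgs <- c(msgs, "frameRate must be > 0")
  if (object@participationP < 0 || object@participationP > 1)
    msgs <- c(msgs, "participationP must lie in [0, 1]")
  dr <- object@cellDiameterRange
  if (length(dr) != 2L || dr[1L] < 4 || dr[2L] > 30 || dr[1L] > dr[2L])
    msgs <- c(msgs, "cellDiameterRange must lie within [4, 30] um")
  if (object@bgEventRate < 0 || object@ensembleRate < 0)
    msgs <- c(msgs, "event rates must be >= 0")
  if (object@decayTau <= 0) msgs <- c(msgs, "decayTau must be > 0")
  if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
  if (object@pixelSize <= 0) msgs <- c(msgs, "pixelSize must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' Ground truth emitted by the synthetic generators
#'
#' @slot events data.frame of sEPSC ground truth (`time`, `amplitude`,
#'   `burst`, `epoch`); empty for calcium simulations.
#' @slot cellEventFrames list of integer vectors, per-cell calcium event
#'   frames; empty for sEPSC simulations.
#' @slot ensembleFrames integer vector of planted ensemble frames (frames in
#'   which at least one cell participated).
#' @slot params echo of the generator parameters as a plain list.
#' @export
setClass("SimTruth",
  representation(
    events = "data.frame",
    cellEventFrames = "list",
    ensembleFrames = "integer",
    params = "list"
  )
)

## ---------------------------------------------------------------------------
## Electrophysiology containers
## ---------------------------------------------------------------------------

#' Voltage-clamp current trace
#'
#' A sampled holding-current record (pA) with acquisition metadata and the
#' condition protocol attached. Spontaneous synaptic events appear as inward
#' (negative) deflections at the -70 mV holding potential.
#'
#' @slot samples current samples, pA.
#' @slot samplingRate Hz.
#' @slot holdingPotential mV.
#' @slot protocol a [DrugProtocol-class] describing the condition epochs.
#' @slot cellId identifier used in tables and reports.
#' @export
setClass("CurrentTrace",
  representation(
    samples = "numeric", samplingRate = "numeric",
    holdingPotential = "numeric", protocol = "DrugProtocol",
    cellId = "character"
  )
)

setValidity("CurrentTrace", function(object) {
  if (object@samplingRate <= 0) return("samplingRate must be > 0")
  if (length(object@samples) < object@samplingRate)
    return("at least 1 s of samples is required")
  TRUE
})

#' Baseline noise model of a current trace
#'
#' @slot sd robust noise SD, pA.
#' @slot method description of the estimator.
#' @slot window seconds pair over which the noise was estimated.
#' @export
setClass("NoiseModel",
  representation(sd = "numeric", method = "character", window = "numeric")
)

setValidity("NoiseModel", function(object) {
  if (length(object@sd) != 1L || is.na(object@sd) || object@sd < 0)
    return("sd must be a single non-negative number")
  TRUE
})

#' Detected synaptic event train
#'
#' @slot times event peak times, seconds, strictly increasing.
#' @slot amplitudes positive magnitudes of the inward deflections, pA.
#' @slot duration recording duration, seconds (defines bin coverage).
#' @slot cellId identifier.
#' @export
setClass("EventTrain",
  representation(
    times = "numeric", amplitudes = "numeric",
    duration = "numeric", cellId = "character"
  )
)

setValidity("EventTrain", function(object) {
  msgs <- character(0)
  if (length(object@times) != length(object@amplitudes))
    msgs <- c(msgs, "times and amplitudes must have the same length")
  if (length(object@times) > 1L && any(diff(object@times) <= 0))
    msgs <- c(msgs, "times must be strictly increasing")
  if (any(object@amplitudes <= 0))
    msgs <- c(msgs, "amplitudes must be positive magnitudes")
  if (length(object@times) && any(object@times < 0 | object@times > object@duration))
    msgs <- c(msgs, "all event times must lie within [0, duration]")
  if (length(msgs)) msgs else TRUE
})

#' Binned time series of event frequency or amplitude
#'
#' @slot binEdges bin edges, seconds (length = number of bins + 1).
#' @slot values per-bin values: Hz, pA, or percent of baseline when normalised.
#' @slot units unit label.
#' @slot normalized TRUE after [normalizeToBaseline()].
#' @slot baselineMean control-epoch mean on the original scale (NA before
#'   normalisation).
#' @export
setClass("BinnedSeries",
  representation(
    binEdges = "numeric", values = "numeric", units = "character",
    normalized = "logical", baselineMean = "numeric"
  )
)

setValidity("BinnedSeries", function(object) {
  if (length(object@values) != length(object@binEdges) - 1L)
    return("length(values) must equal length(binEdges) - 1")
  if (length(object@binEdges) > 1L && any(diff(object@binEdges) <= 0))
    return("binEdges must be strictly increasing")
  TRUE
})

## ---------------------------------------------------------------------------
## Calcium-imaging containers
## ---------------------------------------------------------------------------

#' Fluorescence movie
#'
#' @slot frames 3-D intensity array (row, col, frame), non-negative.
#' @slot frameRate frames/s.
#' @slot pixelSize um per pixel.
#' @export
setClass("Movie",
  representation(frames = "array", frameRate = "numeric", pixelSize = "numeric")
)

setValidity("Movie", function(object) {
  if (length(dim(object@frames)) != 3L)
    return("frames must be a 3-D array (row, col, frame)")
  if (object@frameRate <= 0) return("frameRate must be > 0")
  if (any(object@frames < 0)) return("intensities must be non-negative")
  TRUE
})

#' Map of circular regions of interest
#'
#' @slot rois data.frame with columns `id`, `x`, `y` (pixel centres) and
#'   `diameterUm` (4-30 um).
#' @slot summaryImage the per-pixel temporal-SD image the ROIs were picked on.
#' @slot pixelSize um per pixel.
#' @export
setClass("RoiMap",
  representation(rois = "data.frame", summaryImage = "matrix",
                 pixelSize = "numeric")
)

setValidity("RoiMap", function(object) {
  r <- object@rois
  if (!all(c("id", "x", "y", "diameterUm") %in% names(r)))
    return("rois must have columns id, x, y, diameterUm")
  if (nrow(r) && (any(r$diameterUm < 4) || any(r$diameterUm > 30)))
    return("ROI diameters must lie within [4, 30] um")
  TRUE
})

#' Raw per-cell fluorescence traces
#'
#' Cells x frames matrix of mean ROI intensities (arbitrary units) or, for
#' synthetic data, fluorescence relative to a resting level of 1.0.
#'
#' @slot traces cells x frames numeric matrix.
#' @slot frameRate frames/s.
#' @export
setClass("FluorTraces",
  representation(traces = "matrix", frameRate = "numeric")
)

#' dF/F trace set
#'
#' Per-cell fluorescence change normalised to resting fluorescence:
#' (F_t - F0) / F0, dimensionless, with F0 estimated per cell.
#'
#' @slot traces cells x frames dF/F matrix.
#' @slot f0 per-cell resting fluorescence (original units).
#' @slot frameRate frames/s.
#' @export
setClass("DffTraces",
  representation(traces = "matrix", f0 = "numeric", frameRate = "numeric")
)

setValidity("DffTraces", function(object) {
  if (!all(is.finite(object@traces))) return("dF/F values must be finite")
  if (length(object@f0) != nrow(object@traces))
    return("f0 must have one entry per cell")
  TRUE
})

#' Detected calcium transients
#'
#' Per-cell transient onsets with the noise model and thresholds that
#' produced them. The amplitude threshold is `kAmp x noiseSd` per cell
#' (acquisition criterion: transients 2.5x above the noise SD).
#'
#' @slot onsets list of integer vectors, onset frames per cell.
#' @slot peakAmplitudes list of numeric vectors, dF/F peak per transient.
#' @slot noiseSd per-cell robust noise SD of the dF/F trace.
#' @slot ampThreshold per-cell amplitude acceptance threshold (dF/F).
#' @slot derivThreshold per-cell derivative candidate threshold.
#' @slot frameRate frames/s.
#' @slot nFrames trace length.
#' @export
setClass("TransientSet",
  representation(
    onsets = "list", peakAmplitudes = "list", noiseSd = "numeric",
    ampThreshold = "numeric", derivThreshold = "numeric",
    frameRate = "numeric", nFrames = "integer"
  )
)

#' Binary activity raster
#'
#' Cells x frames matrix of ones and zeros, where 1 marks a transient onset
#' (an active frame) and 0 an inactive frame for each neuron.
#'
#' @slot mat cells x frames 0/1 matrix.
#' @slot frameRate frames/s.
#' @slot conditionOfFrame per-frame epoch label (may contain NA for frames
#'   outside any epoch).
#' @export
setClass("BinaryRaster",
  representation(mat = "matrix", frameRate = "numeric",
                 conditionOfFrame = "character")
)

setValidity("BinaryRaster", function(object) {
  if (!all(object@mat %in% c(0, 1)))
    return("raster entries must be 0 or 1")
  if (length(object@conditionOfFrame) != ncol(object@mat))
    return("conditionOfFrame must have one label per frame")
  TRUE
})

#' Coactivity significance result
#'
#' Per-frame counts of simultaneously active cells plus the Monte Carlo
#' surrogate threshold: each surrogate circularly shifts every row of the
#' raster by an independent uniform offset (preserving per-cell event counts
#' and within-cell timing structure) and records its maximum per-frame
#' coactivity.
#'
#' @slot coactivity per-frame count of active cells.
#' @slot threshold smallest count reached by fewer than `alpha * nSurrogates`
#'   surrogate maxima (NA when undefined, e.g. a single cell).
#' @slot nSurrogates number of surrogates (default 1000).
#' @slot significantFrames frames with coactivity >= threshold.
#' @slot surrogateMax the surrogate null distribution of maximum coactivity.
#' @slot surrogateScheme description of the shuffle.
#' @slot alpha family-wise significance level.
#' @slot seed RNG seed used.
#' @export
setClass("CoactivityResult",
  representation(
    coactivity = "integer", threshold = "numeric", nSurrogates = "integer",
    significantFrames = "integer", surrogateMax = "integer",
    surrogateScheme = "character", alpha = "numeric", seed = "integer"
  )
)

#' Per-cell activity summary across conditions
#'
#' @slot table data.frame with columns `cell`, `condition`, `nActive`,
#'   `nFrames`, `fraction` (active frames / frames in condition).
#' @export
setClass("CellActivitySummary", representation(table = "data.frame"))

setValidity("CellActivitySummary", function(object) {
  tb <- object@table
  if (!all(c("cell", "condition", "nActive", "nFrames", "fraction") %in% names(tb)))
    return("table must have columns cell, condition, nActive, nFrames, fraction")
  if (nrow(tb) && (any(tb$fraction < 0) || any(tb$fraction > 1)))
    return("fractions must lie in [0, 1]")
  TRUE
})

## ---------------------------------------------------------------------------
## Statistics
## ---------------------------------------------------------------------------

#' Nonparametric test result
#'
#' @slot statistic test statistic (U, D, or Friedman chi-square).
#' @slot pValue p-value in \[0, 1\].
#' @slot method description.
#' @slot n sample sizes.
#' @slot exact TRUE when the p-value came from exhaustive enumeration.
#' @export
setClass("TestResult",
  representation(
    statistic = "numeric", pValue = "numeric", method = "character",
    n = "integer", exact = "logical"
  )
)

setValidity("TestResult", function(object) {
  p <- object@pValue
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
    return("pValue must lie in [0, 1]")
  TRUE
})
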