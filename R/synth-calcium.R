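#' Parameters for synthetic calcium-imaging data
#'
#' Constructor for [CalciumSimParams-class]. Defaults emulate the
#' acquisition: 4 frames/s, a 280 x 260 um field at 1 um/px, and cells of
#' 10-20 um diameter. Background transients occur at 0.1 Hz per cell with a
#' 0.3 dF/F instantaneous rise decaying with a 1.5 s time constant over
#' 0.03 dF/F noise; population (ensemble) events recruit each cell with
#' probability 0.6. Per-epoch rate ratios default to a doubling of activity
#' in drug and wash conditions.
#'
#' @param nCells number of cells.
#' @param frameRate frames/s.
#' @param nFrames number of frames; NA derives `round(frameRate * span)` from
#'   the protocol (a 6-min single-epoch protocol gives 1,440 frames).
#' @param fieldSize field of view (width, height), um.
#' @param pixelSize um per pixel.
#' @param cellDiameterRange cell diameters, um, within \[4, 30\].
#' @param bgEventRate per-cell background event rate, Hz.
#' @param ensembleRate ensemble event rate, Hz.
#' @param participationP per-cell ensemble participation probability.
#' @param transientAmp transient amplitude, dF/F units.
#' @param decayTau transient decay time constant, seconds.
#' @param noiseSd additive Gaussian noise SD, dF/F units.
#' @param conditionRateRatios named per-epoch rate multipliers.
#' @param seed integer seed.
#' @return A [CalciumSimParams-class] object.
#' @export
calciumSimParams <- function(nCells = 30, frameRate = 4, nFrames = NA_integer_,
                             fieldSize = c(280, 260), pixelSize = 1,
                             cellDiameterRange = c(10, 20),
                             bgEventRate = 0.1, ensembleRate = 0.02,
                             participationP = 0.6, transientAmp = 0.3,
                             decayTau = 1.5, noiseSd = 0.03,
                             conditionRateRatios = c(control = 1, drug = 2, wash = 2),
                             seed = 1L) {
  new("CalciumSimParams", nCells = as.integer(nCells), frameRate = frameRate,
      nFrames = as.integer(nFrames), fieldSize = fieldSize,
      pixelSize = pixelSize, cellDiameterRange = cellDiameterRange,
      bgEventRate = bgEventRate, ensembleRate = ensembleRate,
      participationP = participationP, transientAmp = transientAmp,
      decayTau = decayTau, noiseSd = noiseSd,
      conditionRateRatios = conditionRateRatios, seed = as.integer(seed))
}

#' Simulate per-cell fluorescence traces
#'
#' Builds per-cell fluorescence traces as a resting level of 1.0 plus
#' calcium transients (instantaneous rise of `transientAmp`, exponential
#' decay `decayTau`) at background Poisson event frames and at ensemble
#' frames (each cell participating with probability `participationP`), with
#' additive Gaussian noise. Per-epoch rate ratios from
#' `conditionRateRatios` scale both the background and ensemble rates.
#' Apply [computeDff()] to obtain dF/F traces for transient detection.
#'
#' @param params a [CalciumSimParams-class].
#' @param protocol a [DrugProtocol-class]; its span defines the recording
#'   length.
#' @param ensembleFrames optional integer vector of frames at which ensemble
#'   events are planted deterministically instead of being drawn at
#'   `ensembleRate` (participation is still random per cell).
#' @return A list with elements `traces` ([FluorTraces-class], cells x
#'   frames, resting level 1.0) and `truth` ([SimTruth-class]) whose
#'   `cellEventFrames` lists every event frame per cell and whose
#'   `ensembleFrames` lists the ensemble frames in which at least one cell
#'   participated.
#' @examples
#' prot <- drugProtocol(control = 360, drug = 0, wash = 0)
#' sim <- simulateCalciumTraces(calciumSimParams(nCells = 5), prot)
#' sim$traces
#' @export
simulateCalciumTraces <- function(params, protocol, ensembleFrames = NULL) {
  validObject(params); validObject(protocol)
  span <- protocolEnd(protocol)
  nF <- if (is.na(params@nFrames)) as.integer(round(params@frameRate * span))
        else params@nFrames
  if (nF != round(params@frameRate * span))
    stop("nFrames (", nF, ") must equal round(frameRate * protocol span) = ",
         round(params@frameRate * span))
  nC <- params@nCells
  if (nC < 1L) stop("nCells must be >= 1")
  set.seed(params@seed)

  frameTimes <- (seq_len(nF) - 0.5) / params@frameRate
  lab <- epochOf(protocol, frameTimes)
  ratio <- params@conditionRateRatios[lab]
  ratio[is.na(ratio)] <- 1

  dt <- 1 / params@frameRate
  pBg <- pmin(1, params@bgEventRate * ratio * dt)
  eventsMat <- matrix(stats::runif(nC * nF), nC, nF) <
    matrix(rep(pBg, each = nC), nC, nF)

  if (is.null(ensembleFrames)) {
    pEns <- pmin(1, params@ensembleRate * ratio * dt)
    ensembleFrames <- which(stats::runif(nF) < pEns)
  } else {
    ensembleFrames <- as.integer(ensembleFrames)
    if (any(ensembleFrames < 1L | ensembleFrames > nF))
      stop("ensembleFrames must lie in [1, nFrames]")
  }
  realized <- integer(0)
  for (f in ensembleFrames) {
    part <- stats::runif(nC) < params@participationP
    if (any(part)) {
      eventsMat[part, f] <- TRUE
      realized <- c(realized, f)
    }
  }

  a <- exp(-dt / params@decayTau)
  traces <- matrix(0, nC, nF)
  for (i in seq_len(nC)) {
    imp <- params@transientAmp * as.numeric(eventsMat[i, ])
    traces[i, ] <- as.numeric(stats::filter(imp, a, method = "recursive"))
  }
  traces <- 1 + traces
  if (params@noiseSd > 0)
    traces <- traces + matrix(stats::rnorm(nC * nF, 0, params@noiseSd), nC, nF)

  truth <- new("SimTruth", events = data.frame(),
               cellEventFrames = lapply(seq_len(nC),
                                        function(i) which(eventsMat[i, ])),
               ensembleFrames = as.integer(realized),
               params = c(paramsAsList(params),
                          list(nFramesUsed = nF, frameLabels = list(lab))))
  list(traces = new("FluorTraces", traces = traces,
                    frameRate = params@frameRate),
       truth = truth)
}

#' Render fluorescence traces into a movie
#'
#' Places each cell as a circular disk at a random non-overlapping position
#' in the field and renders a multi-page-TIFF-compatible intensity stack in
#' which disk pixels follow `bgLevel + cellGain * trace` and background
#' pixels sit at `bgLevel`, optionally with per-pixel Gaussian noise. Lets
#' the ROI-extraction stage be tested end to end against known cell
#' positions.
#'
#' @param traces a [FluorTraces-class] (one row per cell).
#' @param params a [CalciumSimParams-class] providing field geometry.
#' @param cellGain intensity scale of the cell fluorescence.
#' @param bgLevel background intensity.
#' @param pixelNoiseSd per-pixel Gaussian noise SD (intensity units).
#' @param seed RNG seed for placement and pixel noise.
#' @return A list with elements `movie` ([Movie-class]) and `cells`
#'   (data.frame of ground-truth `id`, `x`, `y` pixel centres and
#'   `diameterUm`).
#' @export
renderMovie <- function(traces, params, cellGain = 100, bgLevel = 10,
                        pixelNoiseSd = 0, seed = params@seed) {
  validObject(params)
  tr <- traces@traces
  nC <- nrow(tr); nF <- ncol(tr)
  px <- params@pixelSize
  nx <- round(params@fieldSize[1L] / px)
  ny <- round(params@fieldSize[2L] / px)
  set.seed(seed)

  xs <- ys <- ds <- numeric(0)
  tries <- 0L
  while (length(xs) < nC && tries < 500L * max(1L, nC)) {
    tries <- tries + 1L
    d <- stats::runif(1, params@cellDiameterRange[1L], params@cellDiameterRange[2L])
    r <- d / 2 / px
    x <- stats::runif(1, r + 1, nx - r)
    y <- stats::runif(1, r + 1, ny - r)
    if (length(xs)) {
      dist2 <- (xs - x)^2 + (ys - y)^2
      if (any(dist2 < ((ds + d) / 2 / px)^2)) next
    }
    xs <- c(xs, x); ys <- c(ys, y); ds <- c(ds, d)
  }
  if (length(xs) < nC)
    stop("field too small to place ", nC, " non-overlapping cells (placed ",
         length(xs), ")")

  M <- matrix(bgLevel, ny * nx, nF)
  for (i in seq_len(nC)) {
    r <- ds[i] / 2 / px
    cols <- pmax(1L, floor(xs[i] - r)):pmin(nx, ceiling(xs[i] + r))
    rows <- pmax(1L, floor(ys[i] - r)):pmin(ny, ceiling(ys[i] + r))
    gx <- rep(cols, each = length(rows))
    gy <- rep(rows, times = length(cols))
    inDisk <- (gx - xs[i])^2 + (gy - ys[i])^2 <= r^2
    pix <- (gx[inDisk] - 1L) * ny + gy[inDisk]
    M[pix, ] <- M[pix, ] +
      cellGain * matrix(tr[i, ], length(pix), nF, byrow = TRUE)
  }
  if (pixelNoiseSd > 0)
    M <- pmax(0, M + matrix(stats::rnorm(length(M), 0, pixelNoiseSd), nrow(M)))

  list(movie = new("Movie", frames = array(M, c(ny, nx, nF)),
                   frameRate = traces@frameRate, pixelSize = px),
       cells = data.frame(id = seq_len(nC), x = xs, y = ys, diameterUm = ds))
}
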