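#' Compute dF/F from raw fluorescence traces
#'
#' Per cell, `(F_t - F0) / F0`, with the resting fluorescence F0 estimated
#' as a low percentile of the trace (default the 10th), which resists
#' contamination by the transients themselves. The ratio makes the signal
#' invariant to multiplicative illumination gain.
#'
#' @param ft a [FluorTraces-class].
#' @param f0Quantile percentile (as a probability) used for F0.
#' @return A [DffTraces-class].
#' @examples
#' ft <- new("FluorTraces", traces = rbind(c(1, 1, 2, 1)), frameRate = 4)
#' traceMatrix(computeDff(ft))
#' @export
computeDff <- function(ft, f0Quantile = 0.1) {
  tr <- ft@traces
  if (!nrow(tr))
    return(new("DffTraces", traces = tr, f0 = numeric(0),
               frameRate = ft@frameRate))
  f0 <- apply(tr, 1L, stats::quantile, probs = f0Quantile, names = FALSE)
  bad <- which(f0 <= 0)
  if (length(bad))
    stop("resting fluorescence F0 <= 0 for cell(s) ",
         paste(bad, collapse = ", "),
         "; dF/F is undefined for non-positive F0")
  dff <- sweep(sweep(tr, 1L, f0, "-"), 1L, f0, "/")
  new("DffTraces", traces = dff, f0 = f0, frameRate = ft@frameRate)
}

## Robust per-cell noise SD of a dF/F trace: MAD after masking provisional
## supra-threshold frames, iterated once.
#' @noRd
robustNoiseSd <- function(v, k = 2.5) {
  s0 <- stats::mad(v)
  if (s0 == 0) return(0)
  keep <- v <= stats::median(v) + k * s0
  stats::mad(v[keep])
}

#' Detect calcium transients in dF/F traces
#'
#' Transients and their first derivative are the indicators of cell firing.
#' Candidate onsets are frames where the rise statistic -- the first
#' difference of the 2-frame boxcar-smoothed trace, whose noise SD equals
#' the per-frame noise SD -- exceeds `kDeriv` times its own robust noise SD;
#' a candidate is accepted when the following dF/F peak reaches `kAmp`
#' times the per-cell noise SD (amplitude criterion: transients 2.5x above
#' the noise SD). Noise SDs are robust MADs computed after masking
#' provisional supra-threshold frames.
#'
#' @param dff a [DffTraces-class] with at least 8 frames.
#' @param kAmp amplitude acceptance threshold, in noise SDs.
#' @param kDeriv derivative candidate threshold, in noise SDs of the rise
#'   statistic.
#' @param peakWinS window after onset searched for the peak, seconds.
#' @return A [TransientSet-class]; `ampThreshold(x)` exposes the per-cell
#'   acceptance threshold `kAmp * noiseSd`.
#' @export
detectTransients <- function(dff, kAmp = 2.5, kDeriv = 2.5, peakWinS = 1.25) {
  tr <- dff@traces
  nC <- nrow(tr); nF <- ncol(tr)
  if (nF < 8L) stop("traces must have at least 8 frames")
  pk <- max(2L, round(peakWinS * dff@frameRate))

  onsets <- vector("list", nC)
  amps <- vector("list", nC)
  nsd <- dth <- numeric(nC)
  for (i in seq_len(nC)) {
    v <- tr[i, ]
    s <- robustNoiseSd(v, kAmp)
    nsd[i] <- s

    if (s == 0) {
      ## noise-free trace: every strict rise is an onset, exactly
      dth[i] <- 0
      on <- which(c(0, diff(v)) > 1e-12)
      onsets[[i]] <- as.integer(on)
      amps[[i]] <- vapply(on, function(f) max(v[f:min(nF, f + pk)]), 0)
      next
    }

    ## rise statistic on the 2-frame forward mean
    w <- (v + c(v[-1L], v[nF])) / 2
    u <- c(0, 0, w[3:nF] - w[seq_len(nF - 2L)])
    su0 <- stats::mad(u)
    su <- if (su0 > 0) stats::mad(u[abs(u) <= kDeriv * su0]) else 0
    dth[i] <- kDeriv * su

    cand <- which(u > dth[i])
    if (su == 0) cand <- which(u > 1e-12)
    if (!length(cand)) { onsets[[i]] <- integer(0); amps[[i]] <- numeric(0); next }

    ## single-frame rise, used to split runs holding more than one event
    d1 <- c(0, diff(v))
    sd10 <- stats::mad(d1)
    sd1 <- if (sd10 > 0) stats::mad(d1[abs(d1) <= kDeriv * sd10]) else 0
    d1th <- if (sd1 > 0) kDeriv * sd1 else 1e-12

    ## candidate runs: each holds one onset per strong single-frame rise,
    ## or the frame of maximal smoothed rise when none stands out
    runs <- split(cand, cumsum(c(1L, diff(cand) > 1L)))
    on <- unlist(lapply(runs, function(r) {
      strong <- r[d1[r] > d1th]
      if (length(strong)) strong else r[which.max(u[r])]
    }), use.names = FALSE)
    on <- sort(unique(on))

    peak <- vapply(on, function(f) max(v[f:min(nF, f + pk)]), 0)
    ok <- peak >= kAmp * s
    onsets[[i]] <- as.integer(on[ok])
    amps[[i]] <- peak[ok]
  }
  new("TransientSet", onsets = onsets, peakAmplitudes = amps,
      noiseSd = nsd, ampThreshold = kAmp * nsd, derivThreshold = dth,
      frameRate = dff@frameRate, nFrames = as.integer(nF))
}

#' Build the binary activity raster
#'
#' Builds the cells x frames matrix of ones and zeros in which 1 marks an
#' active frame (a transient onset) and 0 an inactive frame for each
#' neuron. Onset-only marking is used: the first derivative localises
#' firing onsets, and marking whole transient durations would inflate
#' coactivity.
#'
#' @param transients a [TransientSet-class], or a list of per-cell onset
#'   frame vectors.
#' @param nFrames number of frames (taken from the TransientSet when
#'   available).
#' @param frameRate frames/s (likewise).
#' @param protocol optional [DrugProtocol-class] used to label each frame
#'   with its condition.
#' @param conditionOfFrame optional explicit per-frame labels (overrides
#'   `protocol`).
#' @return A [BinaryRaster-class].
#' @export
binarize <- function(transients, nFrames = NULL, frameRate = NULL,
                     protocol = NULL, conditionOfFrame = NULL) {
  if (is(transients, "TransientSet")) {
    on <- transients@onsets
    if (is.null(nFrames)) nFrames <- transients@nFrames
    if (is.null(frameRate)) frameRate <- transients@frameRate
  } else {
    on <- transients
    if (is.null(nFrames) || is.null(frameRate))
      stop("nFrames and frameRate are required with a plain onset list")
  }
  nC <- length(on)
  m <- matrix(0, nC, nFrames)
  for (i in seq_len(nC)) {
    f <- on[[i]]
    if (any(f < 1L | f > nFrames))
      stop("onset frames must lie in [1, nFrames]")
    if (anyDuplicated(f)) {
      warning("duplicate onsets collapsed for cell ", i)
      f <- unique(f)
    }
    m[i, f] <- 1
  }
  if (is.null(conditionOfFrame)) {
    conditionOfFrame <- if (!is.null(protocol)) {
      epochOf(protocol, (seq_len(nFrames) - 0.5) / frameRate)
    } else rep(NA_character_, nFrames)
  }
  new("BinaryRaster", mat = m, frameRate = frameRate,
      conditionOfFrame = conditionOfFrame)
}
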