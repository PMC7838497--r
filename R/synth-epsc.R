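#' Parameters for synthetic sEPSC traces
#'
#' Constructor for [EpscSimParams-class]. Defaults describe a typical
#' voltage-clamp recording from a brainstem slice: 5 kHz sampling, a 3.5 Hz
#' baseline sEPSC rate, lognormal amplitudes with a 20 pA median over 2 pA
#' baseline noise, and AMPA-like biexponential kinetics (0.5 ms rise, 3 ms
#' decay). Bursts are clusters of 4-8 events at 15-25 ms spacing, i.e. an
#' in-burst frequency of roughly 50 Hz, inserted in proportion to the drug
#' envelope.
#'
#' @param samplingRate Hz.
#' @param duration seconds; NA spans the protocol passed to
#'   [simulateEpscTrace()].
#' @param baseRate baseline event rate, Hz.
#' @param ampMedian median amplitude, pA.
#' @param ampSigmaLog lognormal log-scale SD (right-skewed amplitudes).
#' @param kernelRiseTau,kernelDecayTau kernel time constants, ms.
#' @param noiseSd baseline noise SD, pA.
#' @param burstRate burst-insertion rate at full drug effect, Hz.
#' @param burstSizeRange integer pair, events per burst (min >= 3).
#' @param intraBurstMs uniform range of intra-burst intervals, ms.
#' @param refractoryMs minimum separation of background events, ms.
#' @param seed integer seed.
#' @return An [EpscSimParams-class] object.
#' @export
epscSimParams <- function(samplingRate = 5000, duration = NA_real_,
                          baseRate = 3.5, ampMedian = 20, ampSigmaLog = 0.45,
                          kernelRiseTau = 0.5, kernelDecayTau = 3,
                          noiseSd = 2, burstRate = 0,
                          burstSizeRange = c(4L, 8L),
                          intraBurstMs = c(15, 25), refractoryMs = 2,
                          seed = 1L) {
  new("EpscSimParams", samplingRate = samplingRate, duration = duration,
      baseRate = baseRate, ampMedian = ampMedian, ampSigmaLog = ampSigmaLog,
      kernelRiseTau = kernelRiseTau, kernelDecayTau = kernelDecayTau,
      noiseSd = noiseSd, burstRate = burstRate,
      burstSizeRange = as.integer(burstSizeRange),
      intraBurstMs = as.numeric(intraBurstMs), refractoryMs = refractoryMs,
      seed = as.integer(seed))
}

## Inhomogeneous Poisson sampling by thinning. rateFun(t) must be bounded by
## rateMax on [0, duration].
#' @noRd
thinPoisson <- function(duration, rateFun, rateMax) {
  if (rateMax <= 0 || duration <= 0) return(numeric(0))
  n <- stats::rpois(1L, rateMax * duration)
  if (n == 0L) return(numeric(0))
  cand <- sort(stats::runif(n, 0, duration))
  keep <- stats::runif(n) < rateFun(cand) / rateMax
  cand[keep]
}

#' Draw ground-truth sEPSC event times for a protocol
#'
#' Samples the event process alone (no trace rendering): background events
#' from an inhomogeneous Poisson process whose rate is
#' `baseRate * rateModulation(protocol, t)`, plus burst clusters inserted at
#' rate `burstRate * e(t)` where `e(t)` is the drug envelope. Event
#' amplitudes are lognormal, scaled by the amplitude modulation at the event
#' time. Useful on its own for distributional checks; [simulateEpscTrace()]
#' renders the same events into a sampled current trace.
#'
#' @param params an [EpscSimParams-class].
#' @param protocol a [DrugProtocol-class].
#' @return A [SimTruth-class] whose `events` table has columns `time`
#'   (seconds), `amplitude` (pA, positive magnitude), `burst` (logical) and
#'   `epoch`.
#' @export
simulateEpscEvents <- function(params, protocol) {
  validObject(params); validObject(protocol)
  duration <- if (is.na(params@duration)) protocolEnd(protocol) else params@duration
  if (duration < protocolEnd(protocol))
    stop("duration (", duration, " s) is shorter than the protocol span (",
         protocolEnd(protocol), " s)")
  set.seed(params@seed)

  grid <- seq(0, duration, by = 1)
  mMax <- max(rateModulation(protocol, c(grid, protocol@epochs$end)))

  bg <- thinPoisson(duration,
                    function(t) params@baseRate * rateModulation(protocol, t),
                    params@baseRate * mMax)
  if (length(bg) > 1L && params@refractoryMs > 0) {
    refr <- params@refractoryMs / 1000
    keep <- c(TRUE, diff(bg) >= refr)
    ## one pass is enough at physiological rates; repeat until stable
    while (!all(keep)) {
      bg <- bg[keep]
      keep <- c(TRUE, diff(bg) >= refr)
    }
  }

  burstTimes <- numeric(0)
  burstId <- integer(0)
  if (params@burstRate > 0) {
    eMax <- max(drugEnvelope(protocol, c(grid, protocol@epochs$end)))
    starts <- thinPoisson(duration,
                          function(t) params@burstRate * drugEnvelope(protocol, t),
                          params@burstRate * max(eMax, 1e-12))
    for (k in seq_along(starts)) {
      sz <- sample(seq(params@burstSizeRange[1L], params@burstSizeRange[2L]), 1L)
      gaps <- stats::runif(sz - 1L, params@intraBurstMs[1L],
                           params@intraBurstMs[2L]) / 1000
      tt <- starts[k] + c(0, cumsum(gaps))
      tt <- tt[tt <= duration]
      burstTimes <- c(burstTimes, tt)
      burstId <- c(burstId, rep(k, length(tt)))
    }
  }

  times <- c(bg, burstTimes)
  burst <- c(rep(FALSE, length(bg)), rep(TRUE, length(burstTimes)))
  o <- order(times)
  times <- times[o]; burst <- burst[o]

  amps <- stats::rlnorm(length(times), log(params@ampMedian), params@ampSigmaLog) *
    ampModulation(protocol, times)

  pl <- paramsAsList(params)
  pl$duration <- duration
  new("SimTruth",
      events = data.frame(time = times, amplitude = amps, burst = burst,
                          epoch = epochOf(protocol, times),
                          stringsAsFactors = FALSE),
      cellEventFrames = list(), ensembleFrames = integer(0),
      params = pl)
}

#' @noRd
paramsAsList <- function(p) {
  nm <- slotNames(class(p))
  stats::setNames(lapply(nm, function(s) slot(p, s)), nm)
}

## Biexponential kernel sampled at fs, unit peak, with the peak at index
## `peakIdx` so that ground-truth event times coincide with rendered peaks.
#' @noRd
epscKernel <- function(riseTauMs, decayTauMs, fs) {
  dt <- 1000 / fs                       # ms per sample
  tEnd <- 8 * decayTauMs
  t <- seq(0, tEnd, by = dt)
  k <- exp(-t / decayTauMs) - exp(-t / riseTauMs)
  k <- k / max(k)
  list(k = k, peakIdx = which.max(k))
}

#' Simulate a voltage-clamp sEPSC trace
#'
#' Generates a sampled holding-current record (pA) in which spontaneous
#' events appear as negative (inward) biexponential deflections on a noisy
#' baseline. Event rate and amplitude are multiplied by the protocol's
#' `drugRateRatio` / `drugAmpRatio` during the drug epoch with exponential
#' onset, and retain `washoutPersistence` of the asymptotic effect during
#' washout. Bursts are inserted as clusters of events at intra-burst spacing.
#' The returned [SimTruth-class] lists every inserted event.
#'
#' @param params an [EpscSimParams-class].
#' @param protocol a [DrugProtocol-class]; the trace must span all epochs.
#' @param cellId identifier stored on the trace.
#' @return A list with elements `trace` ([CurrentTrace-class]) and `truth`
#'   ([SimTruth-class]).
#' @examples
#' p <- epscSimParams(duration = 60, seed = 7)
#' prot <- drugProtocol(control = 60, drug = 0, wash = 0)
#' sim <- simulateEpscTrace(p, prot)
#' sim$trace
#' nrow(truthEvents(sim$truth))
#' @export
simulateEpscTrace <- function(params, protocol, cellId = "sim") {
  truth <- simulateEpscEvents(params, protocol)
  duration <- truth@params$duration
  fs <- params@samplingRate
  n <- round(duration * fs)

  ## noise is drawn after the event draw inside the same seeded stream,
  ## so identical params + seed give identical traces bit-for-bit
  x <- stats::rnorm(n, 0, params@noiseSd)

  ev <- truth@events
  if (nrow(ev)) {
    kern <- epscKernel(params@kernelRiseTau, params@kernelDecayTau, fs)
    k <- kern$k; kl <- length(k)
    for (i in seq_len(nrow(ev))) {
      pk <- round(ev$time[i] * fs) + 1L
      i0 <- pk - kern$peakIdx + 1L
      j0 <- max(1L, i0); j1 <- min(n, i0 + kl - 1L)
      if (j1 < j0) next
      seg <- (j0 - i0 + 1L):(j1 - i0 + 1L)
      x[j0:j1] <- x[j0:j1] - ev$amplitude[i] * k[seg]
    }
  }

  trace <- new("CurrentTrace", samples = x, samplingRate = fs,
               holdingPotential = -70, protocol = protocol, cellId = cellId)
  list(trace = trace, truth = truth)
}
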