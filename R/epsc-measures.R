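#' Bin event frequency over time
#'
#' Builds the 10-s-bin frequency histogram used for drug time courses:
#' per-bin event count divided by the bin width, in Hz. The last partial bin
#' is dropped so that every bin has equal exposure.
#'
#' @param train an [EventTrain-class].
#' @param binWidth bin width, seconds.
#' @return A [BinnedSeries-class] in Hz.
#' @examples
#' tr <- new("EventTrain", times = seq(0.5, 99.5, 1),
#'           amplitudes = rep(10, 100), duration = 100, cellId = "c")
#' binValues(binFrequency(tr))
#' @export
binFrequency <- function(train, binWidth = 10) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  nb <- floor(train@duration / binWidth)
  if (nb < 1L)
    stop("recording shorter than one bin (", binWidth, " s)")
  edges <- seq(0, nb * binWidth, by = binWidth)
  counts <- graphics::hist(train@times[train@times < edges[nb + 1L]],
                           breaks = edges, plot = FALSE, right = FALSE)$counts
  new("BinnedSeries", binEdges = edges, values = counts / binWidth,
      units = "Hz", normalized = FALSE, baselineMean = NA_real_)
}

#' Bin mean event amplitude over time
#'
#' Companion to [binFrequency()]: per-bin mean amplitude in pA, `NA` for
#' bins without events. The last partial bin is dropped.
#'
#' @inheritParams binFrequency
#' @return A [BinnedSeries-class] in pA.
#' @export
binAmplitude <- function(train, binWidth = 10) {
  if (binWidth <= 0) stop("binWidth must be > 0")
  nb <- floor(train@duration / binWidth)
  if (nb < 1L)
    stop("recording shorter than one bin (", binWidth, " s)")
  edges <- seq(0, nb * binWidth, by = binWidth)
  idx <- findInterval(train@times, edges, rightmost.closed = FALSE)
  ok <- idx >= 1L & idx <= nb
  vals <- rep(NA_real_, nb)
  if (any(ok)) {
    m <- tapply(train@amplitudes[ok], factor(idx[ok], levels = seq_len(nb)), mean)
    vals <- as.numeric(m)
  }
  new("BinnedSeries", binEdges = edges, values = vals,
      units = "pA", normalized = FALSE, baselineMean = NA_real_)
}

#' @noRd
controlBins <- function(series, protocol) {
  ep <- protocol@epochs
  ctrl <- ep[ep$label == "control", , drop = FALSE]
  if (!nrow(ctrl)) stop("protocol has no control epoch")
  lo <- series@binEdges[-length(series@binEdges)]
  hi <- series@binEdges[-1L]
  which(lo >= ctrl$start[1L] - 1e-9 & hi <= ctrl$end[1L] + 1e-9)
}

#' Normalise a binned series to its baseline
#'
#' Divides every bin by the control-epoch mean and expresses the result as
#' percent of baseline (the baseline mean maps to 100%; a value of 272%
#' corresponds to a +172% increase).
#'
#' @param series a [BinnedSeries-class].
#' @param protocol a [DrugProtocol-class] identifying the control epoch,
#'   which must contain at least 3 bins.
#' @return A normalised [BinnedSeries-class] (units "% baseline") with the
#'   control-epoch mean recorded in `baselineMean`.
#' @export
normalizeToBaseline <- function(series, protocol) {
  cb <- controlBins(series, protocol)
  if (length(cb) < 3L)
    stop("control epoch must contain at least 3 bins (has ", length(cb), ")")
  base <- mean(series@values[cb], na.rm = TRUE)
  if (!is.finite(base) || base == 0)
    stop("control-epoch mean is ", base,
         "; cannot normalise to an empty baseline")
  new("BinnedSeries", binEdges = series@binEdges,
      values = series@values / base * 100, units = "% baseline",
      normalized = TRUE, baselineMean = base)
}

#' Select the maximal-effect window
#'
#' Finds the contiguous window of the given width (default 5 min), aligned
#' to bin edges and starting at or after drug onset, that maximises the mean
#' bin value; ties go to the earliest window. This is the window used for
#' statistical comparison of the drug effect.
#'
#' @param series a [BinnedSeries-class] (raw or normalised).
#' @param protocol a [DrugProtocol-class] with a drug epoch.
#' @param widthMin window width in minutes.
#' @return Numeric pair `c(start, end)` in seconds.
#' @export
selectEffectWindow <- function(series, protocol, widthMin = 5) {
  onset <- drugOnset(protocol)
  if (is.na(onset)) stop("protocol has no drug epoch")
  width <- widthMin * 60
  edges <- series@binEdges
  bw <- diff(edges[1:2])
  nwin <- round(width / bw)
  if (abs(nwin * bw - width) > 1e-9)
    stop("window width must be a multiple of the bin width")
  starts <- which(edges >= onset - 1e-9)
  starts <- starts[starts + nwin <= length(edges)]
  if (!length(starts))
    stop("insufficient post-onset data for a ", widthMin, "-min window")
  means <- vapply(starts, function(i)
    mean(series@values[i:(i + nwin - 1L)], na.rm = TRUE), 0)
  best <- starts[which.max(means)]     # which.max takes the earliest tie
  c(edges[best], edges[best] + width)
}

#' Detect bursts of synaptic events
#'
#' A burst is a short cluster of events: at least 3 consecutive events
#' spanning 50-150 ms whose within-cluster frequency
#' `(n_events - 1) / span` is at least 1.5x the baseline frequency.
#' Overlapping candidates are resolved by a greedy left-to-right scan that
#' extends each burst to the maximal run of events within the 150 ms span.
#'
#' @param train an [EventTrain-class].
#' @param baselineFreq baseline event frequency, Hz (> 0).
#' @param spanRange allowed burst span, seconds.
#' @param minEvents minimum events per burst.
#' @param freqFactor required multiple of the baseline frequency.
#' @return data.frame with columns `start`, `end` (s), `nEvents`,
#'   `withinFreq` (Hz); zero rows when no burst is found.
#' @examples
#' tr <- new("EventTrain", times = 1 + (0:5) * 0.02,
#'           amplitudes = rep(20, 6), duration = 10, cellId = "c")
#' detectBursts(tr, baselineFreq = 3.5)
#' @export
detectBursts <- function(train, baselineFreq, spanRange = c(0.05, 0.15),
                         minEvents = 3L, freqFactor = 1.5) {
  if (baselineFreq <= 0) stop("baselineFreq must be > 0")
  t <- train@times
  n <- length(t)
  out <- data.frame(start = numeric(0), end = numeric(0),
                    nEvents = integer(0), withinFreq = numeric(0))
  i <- 1L
  while (i <= n - minEvents + 1L) {
    j <- i
    while (j < n && t[j + 1L] - t[i] <= spanRange[2L]) j <- j + 1L
    span <- t[j] - t[i]
    nev <- j - i + 1L
    if (nev >= minEvents && span >= spanRange[1L] &&
        (nev - 1L) / span >= freqFactor * baselineFreq) {
      out <- rbind(out, data.frame(start = t[i], end = t[j], nEvents = nev,
                                   withinFreq = (nev - 1L) / span))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Classify a cell as drug-responsive
#'
#' A cell is responsive when its binned frequency (or amplitude) shows a
#' statistically significant change relative to baseline within the first
#' 10 minutes after drug administration: a two-sided Mann-Whitney U test
#' between the control-epoch bins and the post-onset bins.
#'
#' @param series a [BinnedSeries-class].
#' @param protocol a [DrugProtocol-class] with a drug epoch.
#' @param alpha significance level.
#' @param postMin length of the post-onset comparison span, minutes.
#' @return A list with elements `responsive` (logical), `pValue`, and
#'   `test` (the [TestResult-class]).
#' @export
responsiveCell <- function(series, protocol, alpha = 0.05, postMin = 10) {
  onset <- drugOnset(protocol)
  if (is.na(onset)) stop("protocol has no drug epoch")
  cb <- controlBins(series, protocol)
  lo <- series@binEdges[-length(series@binEdges)]
  hi <- series@binEdges[-1L]
  pb <- which(lo >= onset - 1e-9 & hi <= onset + postMin * 60 + 1e-9)
  x <- series@values[cb]; x <- x[!is.na(x)]
  y <- series@values[pb]; y <- y[!is.na(y)]
  if (length(x) < 3L || length(y) < 3L)
    stop("need at least 3 control and 3 post-onset bins (have ",
         length(x), " and ", length(y), ")")
  tst <- mannWhitneyU(y, x)
  list(responsive = tst@pValue < alpha, pValue = tst@pValue, test = tst)
}

#' Empirical cumulative fraction
#'
#' The empirical CDF as plotted for inter-event intervals and amplitudes:
#' sorted values against cumulative fractions ending at 1.
#'
#' @param values non-empty numeric vector.
#' @return data.frame with columns `value` (sorted) and `fraction`.
#' @export
cumulativeFraction <- function(values) {
  if (!length(values)) stop("values must be non-empty")
  s <- sort(values)
  data.frame(value = s, fraction = seq_along(s) / length(s))
}
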