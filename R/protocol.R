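#' Build a drug administration protocol
#'
#' Convenience constructor for [DrugProtocol-class]. Either supply an
#' `epochs` data.frame directly, or give epoch durations and contiguous
#' control/drug/wash epochs are laid out from time zero.
#'
#' @param epochs data.frame with columns `label`, `start`, `end` (seconds),
#'   or NULL to build from durations.
#' @param control,drug,wash epoch durations in seconds (used when `epochs`
#'   is NULL); set `drug` or `wash` to 0 to omit them.
#' @param drugRateRatio asymptotic multiplicative drug effect on event rate.
#'   The default 2.72 corresponds to a +172% frequency increase.
#' @param drugAmpRatio asymptotic multiplicative drug effect on amplitude.
#'   The default 2.403 corresponds to a +140.3% amplitude increase.
#' @param onsetTau exponential onset time constant, seconds.
#' @param washoutPersistence fraction of the asymptotic effect retained after
#'   washout, in \[0, 1\].
#' @return A [DrugProtocol-class] object.
#' @examples
#' p <- drugProtocol(control = 600, drug = 600, wash = 600)
#' epochs(p)
#' @export
drugProtocol <- function(epochs = NULL, control = 600, drug = 600, wash = 600,
                         drugRateRatio = 2.72, drugAmpRatio = 2.403,
                         onsetTau = 60, washoutPersistence = 0.8) {
  if (is.null(epochs)) {
    labels <- c("control", "drug", "wash")
    durs <- c(control, drug, wash)
    keep <- durs > 0
    labels <- labels[keep]; durs <- durs[keep]
    ends <- cumsum(durs)
    epochs <- data.frame(label = labels, start = c(0, ends[-length(ends)]),
                         end = ends, stringsAsFactors = FALSE)
  }
  new("DrugProtocol", epochs = epochs,
      drugRateRatio = drugRateRatio, drugAmpRatio = drugAmpRatio,
      onsetTau = onsetTau, washoutPersistence = washoutPersistence)
}

#' Epoch membership of time points
#'
#' @param protocol a [DrugProtocol-class].
#' @param times numeric vector of times, seconds.
#' @return Character vector of epoch labels; NA for times outside all epochs.
#'   The end of the final epoch is inclusive.
#' @export
epochOf <- function(protocol, times) {
  ep <- protocol@epochs
  out <- rep(NA_character_, length(times))
  for (i in seq_len(nrow(ep))) {
    inEp <- times >= ep$start[i] &
      (times < ep$end[i] | (i == nrow(ep) & times <= ep$end[i]))
    out[inEp] <- ep$label[i]
  }
  out
}

#' Drug onset time
#'
#' @param protocol a [DrugProtocol-class].
#' @return Start time (seconds) of the first drug epoch, or NA when the
#'   protocol has none.
#' @export
drugOnset <- function(protocol) {
  ep <- protocol@epochs
  i <- which(ep$label == "drug")
  if (!length(i)) NA_real_ else ep$start[min(i)]
}

#' Total protocol span in seconds
#' @noRd
protocolEnd <- function(protocol) max(protocol@epochs$end)

## Drug-effect envelope e(t) in [0, 1]:
##   0 before drug onset;
##   1 - exp(-(t - t0)/tau) during the drug epoch;
##   washoutPersistence after the drug epoch ends (fraction of the
##   asymptotic effect retained; with persistence = 1 the washout rate equals
##   the drug-epoch asymptotic rate).
#' @noRd
drugEnvelope <- function(protocol, times) {
  ep <- protocol@epochs
  i <- which(ep$label == "drug")
  e <- numeric(length(times))
  if (!length(i)) return(e)
  t0 <- ep$start[min(i)]; t1 <- ep$end[min(i)]
  inDrug <- times >= t0 & times < t1
  e[inDrug] <- 1 - exp(-(times[inDrug] - t0) / protocol@onsetTau)
  e[times >= t1] <- protocol@washoutPersistence
  e
}

#' Time-varying drug modulation factors
#'
#' `rateModulation()` and `ampModulation()` return the multiplicative factor
#' applied to the baseline event rate / amplitude at each time:
#' `1 + (ratio - 1) * e(t)` where `e(t)` is the exponential-onset envelope
#' (0 in control, rising with `onsetTau` during drug, held at
#' `washoutPersistence` after washout).
#'
#' @param protocol a [DrugProtocol-class].
#' @param times numeric vector of times, seconds.
#' @return Numeric vector of modulation factors.
#' @export
rateModulation <- function(protocol, times) {
  1 + (protocol@drugRateRatio - 1) * drugEnvelope(protocol, times)
}

#' @rdname rateModulation
#' @export
ampModulation <- function(protocol, times) {
  1 + (protocol@drugAmpRatio - 1) * drugEnvelope(protocol, times)
}
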