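## Independent brute-force oracles, deliberately written with different
## formulas than the package implementations they check.

## Mann-Whitney U of x by direct pair counting (ties count 1/2).
bruteU <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

## Exact two-sided Mann-Whitney p by enumerating every labelling of the
## pooled sample, recomputing U by pair counting for each.
bruteMwPValue <- function(x, y) {
  n <- length(x)
  pool <- c(x, y)
  N <- length(pool)
  U <- bruteU(x, y)
  idx <- utils::combn(N, n)
  Us <- apply(idx, 2L, function(i) bruteU(pool[i], pool[-i]))
  p1 <- min(mean(Us <= U + 1e-9), mean(Us >= U - 1e-9))
  min(1, 2 * p1)
}

## KS D via the classic pooled-sort running-sum sweep.
bruteKsD <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  lab <- c(rep(1 / n, n), rep(-1 / m, m))
  o <- order(pooled)
  v <- pooled[o]; lab <- lab[o]
  cs <- cumsum(lab)
  ## at ties, only the cumulative value after the full tie group counts
  last <- c(v[-1] != v[-length(v)], TRUE)
  max(abs(cs[last]))
}

bruteKsPValue <- function(x, y) {
  n <- length(x)
  pool <- c(x, y)
  D <- bruteKsD(x, y)
  idx <- utils::combn(length(pool), n)
  Ds <- apply(idx, 2L, function(i) bruteKsD(pool[i], pool[-i]))
  mean(Ds >= D - 1e-12)
}

## Friedman statistic straight from the untied rank formula
## 12/(nk(k+1)) * sum((Rj - n(k+1)/2)^2); valid when rows have no ties.
bruteFriedmanStat <- function(m) {
  n <- nrow(m); k <- ncol(m)
  Rj <- colSums(t(apply(m, 1, rank)))
  12 / (n * k * (k + 1)) * sum((Rj - n * (k + 1) / 2)^2)
}

## Reference burst scan, written index-first rather than while-loop-first:
## from each unconsumed event, take the largest run within the 150 ms span
## and keep it when it meets the burst definition.
bruteBursts <- function(t, baseline, lo = 0.05, hi = 0.15, minN = 3L,
                        mult = 1.5) {
  out <- data.frame(start = numeric(0), end = numeric(0),
                    nEvents = integer(0), withinFreq = numeric(0))
  n <- length(t)
  consumedUpTo <- 0L
  for (i in seq_len(n)) {
    if (i <= consumedUpTo) next
    inSpan <- which(t - t[i] <= hi & seq_len(n) >= i)
    j <- max(inSpan)
    span <- t[j] - t[i]
    nev <- j - i + 1L
    if (nev >= minN && span >= lo && span <= hi &&
        (nev - 1) / span >= mult * baseline) {
      out <- rbind(out, data.frame(start = t[i], end = t[j], nEvents = nev,
                                   withinFreq = (nev - 1) / span))
      consumedUpTo <- j
    }
  }
  out
}

## Build an EventTrain without going through detection.
makeTrain <- function(times, amplitudes = rep(10, length(times)),
                      duration = max(times, 1) + 1, cellId = "t") {
  new("EventTrain", times = times, amplitudes = amplitudes,
      duration = duration, cellId = cellId)
}

## Inject biexponential kernels of known amplitude into Gaussian noise.
injectedTrace <- function(times, amp, noiseSd = 2, duration = 60, fs = 5000,
                          riseMs = 0.5, decayMs = 3, seed = 1,
                          protocol = drugProtocol(control = duration,
                                                  drug = 0, wash = 0)) {
  set.seed(seed)
  n <- round(duration * fs)
  x <- rnorm(n, 0, noiseSd)
  dt <- 1000 / fs
  t <- seq(0, 8 * decayMs, by = dt)
  k <- exp(-t / decayMs) - exp(-t / riseMs)
  k <- k / max(k)
  pkoff <- which.max(k) - 1L
  amp <- rep_len(amp, length(times))
  for (j in seq_along(times)) {
    i0 <- round(times[j] * fs) + 1L - pkoff
    seg <- i0:(i0 + length(k) - 1L)
    ok <- seg >= 1 & seg <= n
    x[seg[ok]] <- x[seg[ok]] - amp[j] * k[ok]
  }
  new("CurrentTrace", samples = x, samplingRate = fs,
      holdingPotential = -70, protocol = protocol, cellId = "inj")
}

## dF/F traces with planted isolated transients (instant rise, exp decay).
plantedDff <- function(onsets, amp, nFrames = 1440, frameRate = 4,
                       decayTau = 1.5, noiseSd = 0.03, nCells = 1,
                       seed = 1) {
  set.seed(seed)
  tr <- matrix(0, nCells, nFrames)
  a <- exp(-1 / (frameRate * decayTau))
  for (i in seq_len(nCells)) {
    imp <- numeric(nFrames)
    imp[onsets[[min(i, length(onsets))]]] <- amp
    tr[i, ] <- as.numeric(stats::filter(imp, a, method = "recursive")) +
      rnorm(nFrames, 0, noiseSd)
  }
  new("DffTraces", traces = tr, f0 = rep(1, nCells), frameRate = frameRate)
}

## Match detected to true items within a tolerance; returns recall/precision.
matchRate <- function(truth, detected, tol) {
  hit <- vapply(truth, function(x) any(abs(detected - x) <= tol), TRUE)
  used <- vapply(detected, function(x) any(abs(truth - x) <= tol), TRUE)
  c(recall = mean(hit), precision = mean(used))
}
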