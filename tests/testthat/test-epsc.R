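flatTrace <- function(value = 0, dur = 10, fs = 5000) {
  new("CurrentTrace", samples = rep(value, dur * fs), samplingRate = fs,
      holdingPotential = -70,
      protocol = drugProtocol(control = dur, drug = 0, wash = 0),
      cellId = "flat")
}

test_that("noise estimate is zero for flat traces and offsets, accurate for Gaussian noise", {
  expect_equal(noiseSd(estimateNoise(flatTrace(0))), 0)
  expect_equal(noiseSd(estimateNoise(flatTrace(-12.5))), 0)

  set.seed(4)
  tr <- flatTrace(0, dur = 50)
  tr@samples <- rnorm(length(tr@samples), 0, 2)
  expect_equal(noiseSd(estimateNoise(tr)), 2, tolerance = 0.02)

  expect_error(estimateNoise(flatTrace(0, dur = 10), c(5, 20)), "outside")
})

test_that("pure noise yields no detections at a 5-SD threshold", {
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    tr <- flatTrace(0, dur = 20)
    tr@samples <- rnorm(length(tr@samples), 0, 2)
    length(eventTimes(detectEvents(tr, estimateNoise(tr), kThreshold = 5)))
  }, 0)
  expect_gte(mean(hits == 0), 0.99)
})

test_that("flat traces yield an empty event train and bad thresholds are rejected", {
  tr <- flatTrace(0)
  expect_length(eventTimes(detectEvents(tr, estimateNoise(tr))), 0)
  expect_error(detectEvents(tr, estimateNoise(tr), kThreshold = 0), "kThreshold")
})

test_that("injected 10-SD kernels are recovered with accurate times and amplitudes", {
  tt <- seq(2, 58, length.out = 20)
  tr <- injectedTrace(tt, amp = 20, noiseSd = 2, seed = 9)
  ev <- detectEvents(tr, estimateNoise(tr))
  expect_equal(length(eventTimes(ev)), 20)
  m <- vapply(tt, function(x) which.min(abs(eventTimes(ev) - x)), 1L)
  expect_true(all(abs(eventTimes(ev)[m] - tt) <= 0.002))
  expect_true(all(abs(eventAmplitudes(ev)[m] / 20 - 1) <= 0.2))
})

test_that("detection is invariant to a constant offset", {
  tt <- seq(1, 19, by = 1.5)
  tr <- injectedTrace(tt, amp = 15, duration = 20, seed = 3)
  shifted <- tr
  shifted@samples <- tr@samples + 43.7
  n1 <- estimateNoise(tr); n2 <- estimateNoise(shifted)
  expect_equal(noiseSd(n1), noiseSd(n2))
  e1 <- detectEvents(tr, n1); e2 <- detectEvents(shifted, n2)
  expect_identical(eventTimes(e1), eventTimes(e2))
  expect_equal(eventAmplitudes(e1), eventAmplitudes(e2))
})

test_that("binned frequency counts events per bin width", {
  tr <- makeTrain(seq(0.5, 99.5, by = 1), duration = 100)
  b <- binFrequency(tr, 10)
  expect_length(binValues(b), 10)
  expect_true(all(binValues(b) == 1))

  empty <- makeTrain(numeric(0), amplitudes = numeric(0), duration = 60)
  b0 <- binFrequency(empty, 10)
  expect_equal(binValues(b0), rep(0, 6))

  ## partial last bin is dropped, not rescaled
  tr2 <- makeTrain(c(1, 12, 25), duration = 35)
  expect_length(binValues(binFrequency(tr2, 10)), 3)

  expect_error(binFrequency(makeTrain(numeric(0), numeric(0), duration = 5), 10),
               "shorter than one bin")
})

test_that("binned frequency of a Poisson train estimates its rate", {
  sim <- simulateEpscEvents(
    epscSimParams(duration = 600, baseRate = 3.5, refractoryMs = 0, seed = 13),
    drugProtocol(control = 600, drug = 0, wash = 0))
  tr <- makeTrain(truthEvents(sim)$time,
                  truthEvents(sim)$amplitude, duration = 600)
  b <- binFrequency(tr, 10)
  se <- sqrt(3.5 / 600)        # SE of the mean rate over the full record
  expect_lt(abs(mean(binValues(b)) - 3.5), 3 * se)
})

test_that("baseline normalisation maps the control mean to 100%", {
  prot <- drugProtocol(control = 50, drug = 50, wash = 0)
  b <- new("BinnedSeries", binEdges = seq(0, 100, 10),
           values = rep(2, 10), units = "Hz", normalized = FALSE,
           baselineMean = NA_real_)
  bn <- normalizeToBaseline(b, prot)
  expect_true(all(binValues(bn) == 100))

  b2 <- b
  b2@values <- c(rep(3.5, 5), rep(9.52, 5))
  bn2 <- normalizeToBaseline(b2, prot)
  expect_equal(binValues(bn2)[6:10], rep(272, 5))   # +172% increase

  b3 <- b
  b3@values <- rep(0, 10)
  expect_error(normalizeToBaseline(b3, prot), "baseline")

  shortProt <- drugProtocol(control = 20, drug = 80, wash = 0)
  b4 <- new("BinnedSeries", binEdges = seq(0, 100, 10), values = rep(1, 10),
            units = "Hz", normalized = FALSE, baselineMean = NA_real_)
  bShort <- new("BinnedSeries", binEdges = seq(0, 100, 50), values = 1:2,
                units = "Hz", normalized = FALSE, baselineMean = NA_real_)
  expect_error(normalizeToBaseline(bShort, prot), "at least 3 bins")
})

test_that("the maximal-effect window scans all post-onset positions", {
  prot <- drugProtocol(control = 600, drug = 600, wash = 600)
  edges <- seq(0, 1800, 10)
  ## constant series: tie broken to the earliest window = drug onset
  b <- new("BinnedSeries", binEdges = edges, values = rep(5, 180),
           units = "Hz", normalized = FALSE, baselineMean = NA_real_)
  expect_equal(selectEffectWindow(b, prot), c(600, 900))

  ## step increase at t = 600: exhaustive scan oracle
  v <- ifelse(edges[-1] <= 600, 2, 6)
  b2 <- new("BinnedSeries", binEdges = edges, values = v, units = "Hz",
            normalized = FALSE, baselineMean = NA_real_)
  starts <- which(edges >= 600); starts <- starts[starts + 30 <= length(edges)]
  means <- vapply(starts, function(i) mean(v[i:(i + 29)]), 0)
  bestStart <- edges[starts[which.max(means)]]
  w <- selectEffectWindow(b2, prot)
  expect_equal(w[1], bestStart)
  expect_equal(w, c(600, 900))

  ## a late peak is found even inside the wash epoch
  v3 <- rep(2, 180); v3[150:179] <- 10
  b3 <- new("BinnedSeries", binEdges = edges, values = v3, units = "Hz",
            normalized = FALSE, baselineMean = NA_real_)
  expect_equal(selectEffectWindow(b3, prot), c(1490, 1790))

  shortProt <- drugProtocol(control = 600, drug = 240, wash = 0)
  bShort <- new("BinnedSeries", binEdges = seq(0, 840, 10),
                values = rep(1, 84), units = "Hz", normalized = FALSE,
                baselineMean = NA_real_)
  expect_error(selectEffectWindow(bShort, shortProt), "insufficient")
})

test_that("burst detection applies the 50-150 ms cluster definition", {
  expect_equal(nrow(detectBursts(makeTrain(numeric(0), numeric(0), 10), 3.5)), 0)

  ## uniform 1 Hz train: spacing exceeds the 150 ms window
  expect_equal(nrow(detectBursts(makeTrain(seq(1, 60), duration = 61), 1)), 0)

  ## 6 events spaced 20 ms: one burst at (6-1)/0.1 = 50 Hz
  b <- detectBursts(makeTrain(1 + (0:5) * 0.02, duration = 10), 3.5)
  expect_equal(nrow(b), 1)
  expect_equal(b$nEvents, 6)
  expect_equal(b$withinFreq, 50)
  expect_equal(b$end - b$start, 0.1)

  ## a cluster tighter than 50 ms does not qualify
  tight <- detectBursts(makeTrain(1 + (0:3) * 0.01, duration = 10), 3.5)
  expect_equal(nrow(tight), 0)

  ## a slow cluster below 1.5x baseline does not qualify
  slow <- detectBursts(makeTrain(1 + (0:2) * 0.07, duration = 10), 100)
  expect_equal(nrow(slow), 0)

  expect_error(detectBursts(makeTrain(1:3, duration = 5), 0), "baselineFreq")
})

test_that("burst detection matches an independent scan on random trains", {
  for (s in 1:10) {
    sim <- simulateEpscEvents(
      epscSimParams(duration = 120, baseRate = 4, refractoryMs = 0,
                    seed = 700 + s),
      drugProtocol(control = 120, drug = 0, wash = 0))
    tr <- makeTrain(truthEvents(sim)$time, truthEvents(sim)$amplitude, 120)
    got <- detectBursts(tr, baselineFreq = 3.5)
    ref <- bruteBursts(eventTimes(tr), 3.5)
    expect_equal(got$start, ref$start)
    expect_equal(got$nEvents, ref$nEvents)
    expect_equal(got$withinFreq, ref$withinFreq)
    ## every reported burst satisfies the definition
    if (nrow(got)) {
      expect_true(all(got$end - got$start >= 0.05 & got$end - got$start <= 0.15))
      expect_true(all(got$nEvents >= 3))
      expect_true(all(got$withinFreq >= 1.5 * 3.5))
    }
  }
})

test_that("planted burst clusters are recovered on a quiet background", {
  prot <- drugProtocol(control = 10, drug = 590, wash = 0, onsetTau = 1e-6,
                       washoutPersistence = 1)
  sim <- simulateEpscEvents(
    epscSimParams(duration = 600, baseRate = 0, burstRate = 0.05,
                  burstSizeRange = c(5L, 7L), intraBurstMs = c(18, 24),
                  seed = 12), prot)
  ev <- truthEvents(sim)
  tr <- makeTrain(ev$time, ev$amplitude, 600)
  got <- detectBursts(tr, baselineFreq = 3.5)
  ## planted clusters: 5-7 events at 18-24 ms spacing span 72-144 ms,
  ## always inside the 50-150 ms definition when not overlapping another
  starts <- ev$time[c(TRUE, diff(ev$time) > 0.3)]
  covered <- vapply(starts, function(s0)
    any(got$start <= s0 + 0.01 & got$end >= s0), TRUE)
  expect_gte(mean(covered), 0.9)
})

test_that("responsiveness uses the exact Mann-Whitney comparison of bins", {
  prot <- drugProtocol(control = 50, drug = 600, wash = 0)
  edges <- seq(0, 100, 10)
  b <- new("BinnedSeries", binEdges = edges,
           values = c(3, 3, 4, 3, 4, 9, 10, 9, 10, 9), units = "Hz",
           normalized = FALSE, baselineMean = NA_real_)
  r <- responsiveCell(b, prot)
  expect_true(r$responsive)
  expect_equal(r$pValue,
               bruteMwPValue(c(9, 10, 9, 10, 9), c(3, 3, 4, 3, 4)),
               tolerance = 1e-12)

  bConst <- new("BinnedSeries", binEdges = edges, values = rep(3, 10),
                units = "Hz", normalized = FALSE, baselineMean = NA_real_)
  rc <- responsiveCell(bConst, prot)
  expect_false(rc$responsive)
  expect_equal(rc$pValue, 1)

  prot2 <- drugProtocol(control = 20, drug = 600, wash = 0)
  bFew <- new("BinnedSeries", binEdges = seq(0, 40, 10), values = rep(1, 4),
              units = "Hz", normalized = FALSE, baselineMean = NA_real_)
  expect_error(responsiveCell(bFew, prot2), "at least 3")
})

test_that("cumulative fraction is the translation-invariant empirical CDF", {
  cf <- cumulativeFraction(5)
  expect_equal(cf$value, 5)
  expect_equal(cf$fraction, 1)

  cf4 <- cumulativeFraction(c(3, 1, 4, 2))
  expect_equal(cf4$fraction, c(0.25, 0.5, 0.75, 1))
  expect_equal(cf4$value, 1:4)

  x <- rnorm(20)
  expect_equal(cumulativeFraction(x + 2.5)$fraction,
               cumulativeFraction(x)$fraction)
  expect_equal(cumulativeFraction(x + 2.5)$value,
               cumulativeFraction(x)$value + 2.5)

  expect_error(cumulativeFraction(numeric(0)), "non-empty")
})

test_that("binned frequency is a consistent estimator on long synthetic records", {
  errs <- vapply(1:20, function(s) {
    sim <- simulateEpscEvents(
      epscSimParams(duration = 600, baseRate = 3.5, refractoryMs = 0,
                    seed = 500 + s),
      drugProtocol(control = 600, drug = 0, wash = 0))
    tr <- makeTrain(truthEvents(sim)$time, truthEvents(sim)$amplitude, 600)
    abs(mean(binValues(binFrequency(tr))) - 3.5) / 3.5
  }, 0)
  expect_lt(mean(errs), 0.05)
})
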