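test_that("dF/F is zero for constant traces, 1.0 for a doubling step, and gain-invariant", {
  ft <- new("FluorTraces", traces = rbind(rep(5, 20)), frameRate = 4)
  expect_true(all(traceMatrix(computeDff(ft)) == 0))

  step <- c(rep(10, 18), 20, 20)
  ft2 <- new("FluorTraces", traces = rbind(step), frameRate = 4)
  expect_equal(max(traceMatrix(computeDff(ft2))), 1.0)

  set.seed(2)
  raw <- rbind(1 + abs(rnorm(50, 0, 0.1)))
  g1 <- computeDff(new("FluorTraces", traces = raw, frameRate = 4))
  g2 <- computeDff(new("FluorTraces", traces = raw * 7.3, frameRate = 4))
  expect_equal(traceMatrix(g1), traceMatrix(g2), tolerance = 1e-12)

  bad <- new("FluorTraces", traces = rbind(c(rep(0, 19), 1)), frameRate = 4)
  expect_error(computeDff(bad), "F0 <= 0")
})

test_that("transient detection: flat traces give none, amplitude threshold is 2.5x the noise SD", {
  flat <- new("DffTraces", traces = matrix(0, 2, 100), f0 = c(1, 1),
              frameRate = 4)
  ts <- detectTransients(flat)
  expect_true(all(lengths(transientOnsets(ts)) == 0))

  set.seed(5)
  noise <- new("DffTraces", traces = matrix(rnorm(3 * 1440, 0, 0.03), 3),
               f0 = rep(1, 3), frameRate = 4)
  tsn <- detectTransients(noise)
  expect_equal(ampThreshold(tsn) / noiseSd(tsn), rep(2.5, 3))

  expect_error(detectTransients(
    new("DffTraces", traces = matrix(0, 1, 5), f0 = 1, frameRate = 4)),
    "at least 8 frames")
})

test_that("isolated 5-SD transients are recovered with onsets within one frame", {
  tp <- fn <- fp <- 0
  for (s in 1:3) {
    onsets <- seq(12 + 3 * s, 1420, by = 40)
    dff <- plantedDff(list(onsets), amp = 0.15, noiseSd = 0.03, seed = s)
    got <- transientOnsets(detectTransients(dff))[[1]]
    r <- matchRate(onsets, got, tol = 1)
    tp <- tp + r["recall"] * length(onsets)
    fn <- fn + (1 - r["recall"]) * length(onsets)
    fp <- fp + (1 - r["precision"]) * length(got)
  }
  expect_gte(tp / (tp + fn), 0.95)
  expect_gte(tp / (tp + fp), 0.95)
})

test_that("false-event rate on pure noise stays below the Gaussian tail bound", {
  set.seed(31)
  counts <- vapply(1:30, function(i) {
    dff <- new("DffTraces", traces = rbind(rnorm(1440, 0, 0.05)), f0 = 1,
               frameRate = 4)
    length(transientOnsets(detectTransients(dff))[[1]])
  }, 0)
  bound <- 1440 * pnorm(-2.5)       # one-sided tail at the 2.5-SD criterion
  expect_lt(mean(counts), bound)
})

test_that("binarize marks exactly the onset frames and collapses duplicates with a warning", {
  r0 <- binarize(list(integer(0), integer(0)), nFrames = 50, frameRate = 4)
  expect_true(all(rasterMatrix(r0) == 0))

  r1 <- binarize(list(c(3L, 10L)), nFrames = 20, frameRate = 4)
  expect_equal(sum(rasterMatrix(r1)), 2)
  expect_equal(which(rasterMatrix(r1)[1, ] == 1), c(3, 10))

  expect_warning(r2 <- binarize(list(c(4L, 4L)), nFrames = 10, frameRate = 4),
                 "duplicate")
  expect_equal(sum(rasterMatrix(r2)), 1)

  expect_error(binarize(list(c(30L)), nFrames = 10, frameRate = 4),
               "must lie in")
})

test_that("noiseless simulated traces binarize back to the ground-truth raster", {
  prot <- drugProtocol(control = 360, drug = 0, wash = 0)
  sim <- simulateCalciumTraces(
    calciumSimParams(nCells = 8, noiseSd = 0, bgEventRate = 0.05, seed = 6),
    prot)
  dff <- computeDff(sim$traces)
  ts <- detectTransients(dff)
  raster <- binarize(ts, protocol = prot)
  truthRaster <- binarize(truthCellFrames(sim$truth), nFrames = 1440,
                          frameRate = 4)
  expect_equal(rasterMatrix(raster), rasterMatrix(truthRaster))
})

test_that("coactivity equals brute-force column sums", {
  m <- matrix(0, 3, 12)
  m[, 7] <- 1
  r <- new("BinaryRaster", mat = m, frameRate = 4,
           conditionOfFrame = rep("control", 12))
  co <- coactivity(r)
  expect_equal(co[7], 3)
  expect_equal(sum(co), 3)

  set.seed(8)
  m2 <- matrix(rbinom(10 * 50, 1, 0.2), 10, 50)
  r2 <- new("BinaryRaster", mat = m2, frameRate = 4,
            conditionOfFrame = rep("control", 50))
  expect_equal(coactivity(r2),
               as.integer(apply(m2, 2, sum)))

  z <- new("BinaryRaster", mat = matrix(0, 4, 20), frameRate = 4,
           conditionOfFrame = rep("control", 20))
  expect_true(all(coactivity(z) == 0))
})

test_that("circular row shifts preserve row sums and within-row structure", {
  set.seed(14)
  m <- matrix(rbinom(6 * 30, 1, 0.3), 6, 30)
  offs <- sample.int(30, 6) - 1L
  sm <- circularShiftRows(m, offs)
  expect_equal(rowSums(sm), rowSums(m))
  ## shifting back restores the original
  expect_equal(circularShiftRows(sm, (30 - offs) %% 30), m)
})

test_that("Monte Carlo flags planted ensembles and nothing else", {
  set.seed(3)
  m <- matrix(rbinom(30 * 1440, 1, 0.005), 30, 1440)
  planted <- c(200, 500, 800, 1100, 1400)
  for (f in planted) m[runif(30) < 0.6, f] <- 1
  r <- new("BinaryRaster", mat = m, frameRate = 4,
           conditionOfFrame = rep("control", 1440))
  mc <- monteCarloThreshold(r, seed = 11)
  expect_equal(nSurrogates(mc), 1000L)
  expect_equal(significantFrames(mc), as.integer(planted))
  ## reproducibility given the seed
  mc2 <- monteCarloThreshold(r, seed = 11)
  expect_identical(mc@surrogateMax, mc2@surrogateMax)
  expect_identical(coactivityThreshold(mc), coactivityThreshold(mc2))
})

test_that("Monte Carlo edge cases: empty raster, single cell, degenerate alpha", {
  z <- new("BinaryRaster", mat = matrix(0, 5, 40), frameRate = 4,
           conditionOfFrame = rep("control", 40))
  expect_length(significantFrames(monteCarloThreshold(z, seed = 1)), 0)

  one <- new("BinaryRaster", mat = matrix(rbinom(40, 1, 0.3), 1), frameRate = 4,
             conditionOfFrame = rep("control", 40))
  r1 <- monteCarloThreshold(one, seed = 1)
  expect_true(is.na(coactivityThreshold(r1)))
  expect_length(significantFrames(r1), 0)

  set.seed(2)
  m <- matrix(rbinom(4 * 40, 1, 0.2), 4, 40)
  r <- new("BinaryRaster", mat = m, frameRate = 4,
           conditionOfFrame = rep("control", 40))
  rAll <- monteCarloThreshold(r, alpha = 1, seed = 1)
  expect_equal(significantFrames(rAll), which(colSums(m) >= 1))

  expect_warning(monteCarloThreshold(r, nSurrogates = 50, seed = 1),
                 "unreliable")
})

test_that("the surrogate threshold is monotone under added activity (fixed seed)", {
  set.seed(21)
  a <- matrix(rbinom(15 * 300, 1, 0.05), 15, 300)
  b <- a
  extra <- which(a == 0)
  b[sample(extra, 400)] <- 1
  ra <- new("BinaryRaster", mat = a, frameRate = 4,
            conditionOfFrame = rep("control", 300))
  rb <- new("BinaryRaster", mat = b, frameRate = 4,
            conditionOfFrame = rep("control", 300))
  ta <- monteCarloThreshold(ra, nSurrogates = 400, seed = 5)
  tb <- monteCarloThreshold(rb, nSurrogates = 400, seed = 5)
  expect_gte(coactivityThreshold(tb), coactivityThreshold(ta))
  ## at a fixed count threshold, added activity never removes significant frames
  thr <- coactivityThreshold(ta)
  expect_true(all(which(coactivity(ra) >= thr) %in% which(coactivity(rb) >= thr)))
})

test_that("per-cell activity fractions split correctly by condition", {
  z <- new("BinaryRaster", mat = matrix(0, 3, 30), frameRate = 4,
           conditionOfFrame = rep(c("control", "drug", "wash"), each = 10))
  tz <- activityTable(cellActivity(z))
  expect_true(all(tz$fraction == 0))

  m <- matrix(1, 1, 30)
  r <- new("BinaryRaster", mat = m, frameRate = 4,
           conditionOfFrame = rep(c("control", "drug", "wash"), each = 10))
  tr <- activityTable(cellActivity(r))
  expect_true(all(tr$fraction == 1))
  expect_equal(tr$nFrames, rep(10, 3))

  bad <- new("BinaryRaster", mat = m, frameRate = 4,
             conditionOfFrame = c(rep("control", 29), NA))
  expect_error(cellActivity(bad), "condition label")
})

test_that("doubled generator rates double the recovered activity fractions", {
  prot <- drugProtocol(control = 360, drug = 360, wash = 360)
  ratios <- vapply(1:5, function(s) {
    sim <- simulateCalciumTraces(calciumSimParams(seed = 200 + s), prot)
    dff <- computeDff(sim$traces)
    raster <- binarize(detectTransients(dff), protocol = prot)
    tb <- activityTable(cellActivity(raster))
    med <- tapply(tb$fraction, tb$condition, median)
    med[["drug"]] / med[["control"]]
  }, 0)
  expect_lt(abs(mean(ratios) - 2), 0.4)   # within 20% of the planted ratio 2
})

test_that("condition comparisons: identical conditions give null statistics", {
  tb <- do.call(rbind, lapply(c("control", "drug", "wash"), function(cc)
    data.frame(cell = 1:6, condition = cc, nActive = c(1, 2, 3, 4, 5, 6),
               nFrames = 20, fraction = c(1, 2, 3, 4, 5, 6) / 20)))
  s <- new("CellActivitySummary", table = tb)
  cmp <- compareActivity(s)
  expect_equal(testStatistic(cmp$friedman), 0)
  expect_equal(pValue(cmp$friedman), 1)
  for (k in cmp$ks) expect_equal(testStatistic(k), 0)

  ## disjoint supports give D = 1
  tb2 <- tb
  tb2$fraction[tb2$condition == "drug"] <-
    tb2$fraction[tb2$condition == "drug"] + 0.5
  cmp2 <- compareActivity(new("CellActivitySummary", table = tb2))
  expect_equal(testStatistic(cmp2$ks[["control vs drug"]]), 1)

  expect_error(compareActivity(new("CellActivitySummary",
                                   table = tb[tb$condition != "wash", ])),
               "at least 3 conditions")
})

test_that("ROI extraction finds rendered cells and ignores inactive fields", {
  prot <- drugProtocol(control = 150, drug = 0, wash = 0)
  p <- calciumSimParams(nCells = 5, fieldSize = c(120, 120), noiseSd = 0,
                        bgEventRate = 0.15, seed = 4)
  sim <- simulateCalciumTraces(p, prot)
  rm <- renderMovie(sim$traces, p, pixelNoiseSd = 0)
  roim <- extractRois(rm$movie)
  expect_equal(nrow(rois(roim)), 5)
  for (i in seq_len(5)) {
    d <- sqrt((rm$cells$x - rois(roim)$x[i])^2 +
              (rm$cells$y - rois(roim)$y[i])^2)
    expect_lt(min(d), 2)
  }

  set.seed(5)
  noiseMovie <- new("Movie",
                    frames = array(abs(rnorm(60 * 60 * 40, 100, 2)),
                                   c(60, 60, 40)),
                    frameRate = 4, pixelSize = 1)
  expect_equal(nrow(rois(extractRois(noiseMovie))), 0)

  arrS <- array(10, c(60, 60, 40)); arrS[20:30, 20:30, ] <- 200
  static <- new("Movie", frames = arrS, frameRate = 4, pixelSize = 1)
  expect_equal(nrow(rois(extractRois(static))), 0)

  expect_error(extractRois(rm$movie, diameterRange = c(2, 10)), "4, 30")
})

test_that("ROI traces reproduce uniform movies and empty maps", {
  uni <- new("Movie", frames = array(3.2, c(30, 30, 15)), frameRate = 4,
             pixelSize = 1)
  roim <- new("RoiMap", rois = data.frame(id = 1, x = 15, y = 15,
                                          diameterUm = 8),
              summaryImage = matrix(0, 1, 1), pixelSize = 1)
  tr <- roiTraces(uni, roim)
  expect_true(all(abs(traceMatrix(tr) - 3.2) < 1e-12))

  empty <- new("RoiMap", rois = data.frame(id = integer(0), x = numeric(0),
                                           y = numeric(0),
                                           diameterUm = numeric(0)),
               summaryImage = matrix(0, 1, 1), pixelSize = 1)
  expect_equal(nrow(traceMatrix(roiTraces(uni, empty))), 0)

  out <- new("RoiMap", rois = data.frame(id = 1, x = 2, y = 2,
                                         diameterUm = 20),
             summaryImage = matrix(0, 1, 1), pixelSize = 1)
  expect_error(roiTraces(uni, out), "outside the field")
})

test_that("movie-to-raster recovery reproduces at least 90% of true event frames", {
  prot <- drugProtocol(control = 150, drug = 0, wash = 0)
  p <- calciumSimParams(nCells = 6, fieldSize = c(120, 120), noiseSd = 0.03,
                        bgEventRate = 0.15, transientAmp = 0.3, seed = 17)
  sim <- simulateCalciumTraces(p, prot)
  rm <- renderMovie(sim$traces, p, pixelNoiseSd = 0.5)
  roim <- extractRois(rm$movie)
  expect_equal(nrow(rois(roim)), 6)
  dff <- computeDff(roiTraces(rm$movie, roim))
  ts <- detectTransients(dff)
  ## match extracted ROIs back to true cells by position
  hits <- total <- 0
  for (i in seq_len(nrow(rois(roim)))) {
    d <- sqrt((rm$cells$x - rois(roim)$x[i])^2 +
              (rm$cells$y - rois(roim)$y[i])^2)
    truthFrames <- truthCellFrames(sim$truth)[[which.min(d)]]
    got <- transientOnsets(ts)[[i]]
    hits <- hits + sum(vapply(truthFrames,
                              function(f) any(abs(got - f) <= 1), TRUE))
    total <- total + length(truthFrames)
  }
  expect_gte(hits / total, 0.9)
})
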