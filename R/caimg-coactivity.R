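#' Coactivity histogram
#'
#' Per-frame count of simultaneously active cells: the column sums of the
#' binary raster, as graphed below a raster plot.
#'
#' @param raster a non-empty [BinaryRaster-class].
#' @return Integer vector, one count per frame.
#' @export
coactivity <- function(raster) {
  if (!nrow(raster@mat)) stop("raster has no cells")
  as.integer(colSums(raster@mat))
}

#' Circularly shift every row of a matrix
#'
#' The surrogate operation behind [monteCarloThreshold()]: row `i` is
#' rotated by `offsets[i]` columns, wrapping around, so its row sum and
#' within-row timing structure are preserved exactly.
#'
#' @param mat numeric matrix.
#' @param offsets integer vector of per-row shifts (0 to `ncol(mat) - 1`).
#' @return The shifted matrix.
#' @export
circularShiftRows <- function(mat, offsets) {
  nF <- ncol(mat)
  idx <- seq_len(nF)
  out <- mat
  for (i in seq_len(nrow(mat))) {
    sh <- ((idx - 1L + offsets[i]) %% nF) + 1L
    out[i, ] <- mat[i, sh]
  }
  out
}

#' Monte Carlo significance threshold for coactivity peaks
#'
#' Assesses the significance of neurons being active together. Each of
#' `nSurrogates` (default 1,000) surrogate rasters independently circularly
#' shifts every cell's row by a uniform random offset, preserving per-cell
#' event counts and within-cell timing structure while destroying
#' cross-cell alignment, and records its maximum per-frame coactivity. The
#' threshold is the smallest integer count reached by fewer than
#' `alpha * nSurrogates` surrogate maxima (family-wise control over
#' frames); observed frames at or above it are flagged significant.
#'
#' With a single cell the threshold is undefined and no frame is flagged.
#' `alpha >= 1` is the degenerate bound: every frame with coactivity >= 1
#' is flagged.
#'
#' @param raster a [BinaryRaster-class] with >= 2 cells and >= 10 frames.
#' @param nSurrogates number of surrogates (a warning is issued below 100).
#' @param alpha family-wise significance level.
#' @param seed RNG seed; results are reproducible given the seed.
#' @return A [CoactivityResult-class].
#' @export
monteCarloThreshold <- function(raster, nSurrogates = 1000, alpha = 0.05,
                                seed = 1L) {
  m <- raster@mat
  nC <- nrow(m); nF <- ncol(m)
  obs <- as.integer(colSums(m))
  if (nC < 2L) {
    return(new("CoactivityResult", coactivity = obs, threshold = NA_real_,
               nSurrogates = 0L, significantFrames = integer(0),
               surrogateMax = integer(0),
               surrogateScheme = "per-cell circular shift",
               alpha = alpha, seed = as.integer(seed)))
  }
  if (nF < 10L) stop("raster must have at least 10 frames")
  if (nSurrogates < 100) warning("fewer than 100 surrogates is unreliable")
  set.seed(seed)

  maxs <- integer(nSurrogates)
  for (s in seq_len(nSurrogates)) {
    offs <- sample.int(nF, nC, replace = TRUE) - 1L
    maxs[s] <- as.integer(max(colSums(circularShiftRows(m, offs))))
  }

  if (alpha >= 1) {
    thr <- 1
  } else {
    thr <- NA_real_
    for (c in 1:(nC + 1L)) {
      if (sum(maxs >= c) < alpha * nSurrogates) { thr <- c; break }
    }
  }
  sig <- if (is.na(thr)) integer(0) else which(obs >= thr)
  new("CoactivityResult", coactivity = obs, threshold = thr,
      nSurrogates = as.integer(nSurrogates),
      significantFrames = as.integer(sig), surrogateMax = maxs,
      surrogateScheme = "per-cell circular shift", alpha = alpha,
      seed = as.integer(seed))
}

#' Per-cell activity per condition
#'
#' Active-frame counts and activity fractions (active frames / frames in
#' condition) for each cell in each condition of the recording.
#'
#' @param raster a [BinaryRaster-class] whose frames are all labelled with a
#'   condition.
#' @return A [CellActivitySummary-class].
#' @export
cellActivity <- function(raster) {
  lab <- raster@conditionOfFrame
  if (anyNA(lab)) stop("all frames must carry a condition label")
  conds <- unique(lab)
  m <- raster@mat
  nC <- nrow(m)
  rows <- lapply(conds, function(cc) {
    f <- lab == cc
    data.frame(cell = seq_len(nC), condition = cc,
               nActive = as.integer(rowSums(m[, f, drop = FALSE])),
               nFrames = sum(f),
               fraction = rowSums(m[, f, drop = FALSE]) / sum(f),
               stringsAsFactors = FALSE)
  })
  new("CellActivitySummary", table = do.call(rbind, rows))
}

#' Compare per-cell activity across conditions
#'
#' Pairwise two-sample Kolmogorov-Smirnov tests of the activity
#' distributions against the control condition, and a Friedman rank test
#' across the paired per-cell condition triplets.
#'
#' @param summary a [CellActivitySummary-class] with at least 3 conditions
#'   and at least 5 cells.
#' @param measure compare activity `"fraction"`s (default) or `"count"`s.
#' @return A list with elements `ks` (named list of [TestResult-class],
#'   one per non-control condition), `friedman` (a [TestResult-class]) and
#'   `wide` (the cells x conditions matrix compared).
#' @export
compareActivity <- function(summary, measure = c("fraction", "count")) {
  measure <- match.arg(measure)
  tb <- summary@table
  conds <- unique(tb$condition)
  cells <- sort(unique(tb$cell))
  if (length(conds) < 3L) stop("need at least 3 conditions")
  if (length(cells) < 5L) stop("need at least 5 cells")
  col <- if (measure == "fraction") "fraction" else "nActive"
  wide <- sapply(conds, function(cc)
    tb[[col]][tb$condition == cc][order(tb$cell[tb$condition == cc])])
  rownames(wide) <- cells
  ref <- if ("control" %in% conds) "control" else conds[1L]
  others <- setdiff(conds, ref)
  ks <- lapply(others, function(cc) ksTwoSample(wide[, ref], wide[, cc]))
  names(ks) <- paste(ref, "vs", others)
  list(ks = ks, friedman = friedmanTest(wide), wide = wide)
}
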