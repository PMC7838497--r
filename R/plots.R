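#' Time-frequency histogram with drug-epoch band
#'
#' Bar plot of a binned series with the drug epoch shaded and, optionally,
#' the maximal-effect window outlined.
#'
#' @param series a [BinnedSeries-class].
#' @param protocol a [DrugProtocol-class].
#' @param effectWindow optional `c(start, end)` seconds pair.
#' @param ... passed to [graphics::plot()].
#' @return NULL, invisibly.
#' @export
plotTimeFrequency <- function(series, protocol = NULL, effectWindow = NULL,
                              ...) {
  edges <- series@binEdges
  mids <- (edges[-1L] + edges[-length(edges)]) / 2
  v <- series@values
  graphics::plot(mids / 60, v, type = "h", lwd = 3, col = "grey40",
                 xlab = "Time (min)", ylab = series@units, ...)
  if (!is.null(protocol)) {
    ep <- protocol@epochs
    dr <- ep[ep$label == "drug", , drop = FALSE]
    if (nrow(dr)) {
      usr <- graphics::par("usr")
      graphics::rect(dr$start[1L] / 60, usr[3L], dr$end[1L] / 60, usr[4L],
                     col = grDevices::adjustcolor("red", 0.15), border = NA)
    }
  }
  if (!is.null(effectWindow))
    graphics::abline(v = effectWindow / 60, lty = 2, col = "blue")
  invisible(NULL)
}

#' Raster plot with coactivity histogram
#'
#' The activity of all cells over time: one row per cell with dots at
#' active frames, and the summed coactivity histogram below with the Monte
#' Carlo threshold line and significant peaks marked.
#'
#' @param raster a [BinaryRaster-class].
#' @param coactivityResult optional [CoactivityResult-class].
#' @return NULL, invisibly.
#' @export
plotRaster <- function(raster, coactivityResult = NULL) {
  m <- raster@mat
  nC <- nrow(m); nF <- ncol(m)
  if (nF == 0L) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
    on.exit(graphics::par(op))
    graphics::plot(NA, xlim = 0:1, ylim = 0:1, xlab = "", ylab = "Cell")
    graphics::plot(NA, xlim = 0:1, ylim = 0:1, xlab = "Time (min)",
                   ylab = "Coactive cells")
    return(invisible(NULL))
  }
  tmin <- (seq_len(nF) - 0.5) / raster@frameRate / 60
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = range(tmin, 0), ylim = c(0.5, max(nC, 1) + 0.5),
                 xlab = "", ylab = "Cell", xaxs = "i")
  if (nC) {
    act <- which(m == 1, arr.ind = TRUE)
    if (nrow(act))
      graphics::points(tmin[act[, 2L]], act[, 1L], pch = 15, cex = 0.3)
  }
  co <- if (!is.null(coactivityResult)) coactivityResult@coactivity
        else if (nC) as.integer(colSums(m)) else integer(nF)
  graphics::par(mar = c(4, 4, 0.5, 1))
  graphics::plot(tmin, co, type = "h", xlab = "Time (min)",
                 ylab = "Coactive cells", xaxs = "i")
  if (!is.null(coactivityResult) && !is.na(coactivityResult@threshold)) {
    graphics::abline(h = coactivityResult@threshold, col = "red", lty = 2)
    sf <- coactivityResult@significantFrames
    if (length(sf))
      graphics::points(tmin[sf], co[sf], pch = 8, col = "red")
  }
  invisible(NULL)
}

#' Cumulative fraction plot
#'
#' @param ... named numeric vectors to compare (e.g. control vs drug
#'   inter-event intervals or amplitudes).
#' @param xlab x-axis label.
#' @return NULL, invisibly.
#' @export
plotCumulativeFraction <- function(..., xlab = "Value") {
  sets <- list(...)
  if (!length(sets) || !any(lengths(sets))) {
    graphics::plot(NA, xlim = 0:1, ylim = 0:1, xlab = xlab,
                   ylab = "Cumulative fraction")
    return(invisible(NULL))
  }
  cols <- grDevices::hcl.colors(max(2L, length(sets)), "Dark 3")
  rng <- range(unlist(sets))
  graphics::plot(NA, xlim = rng, ylim = c(0, 1), xlab = xlab,
                 ylab = "Cumulative fraction")
  for (i in seq_along(sets)) {
    if (!length(sets[[i]])) next
    cf <- cumulativeFraction(sets[[i]])
    graphics::lines(cf$value, cf$fraction, type = "s", col = cols[i], lwd = 2)
  }
  if (!is.null(names(sets)))
    graphics::legend("bottomright", legend = names(sets),
                     col = cols[seq_along(sets)], lwd = 2, bty = "n")
  invisible(NULL)
}

#' Render the figures for a pipeline report
#'
#' Best-effort rendering of the standard figures into PDF files: the
#' time-frequency histogram with drug band and effect window plus the
#' amplitude cumulative fractions for an sEPSC report; the raster plot
#' with coactivity histogram and threshold line for a calcium report.
#' Empty reports produce empty axes without error.
#'
#' @param report an `ExperimentReport` list.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Character vector of files written, invisibly.
#' @export
plotReport <- function(report, dir = ".", prefix = report$kind %||% "report") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  if (identical(report$kind, "epsc")) {
    f <- file.path(dir, paste0(prefix, "-time-frequency.pdf"))
    grDevices::pdf(f, width = 7, height = 4)
    series <- new("BinnedSeries", binEdges = report$frequency$binEdges,
                  values = report$frequency$normalized,
                  units = "% baseline", normalized = TRUE,
                  baselineMean = report$frequency$baselineHz)
    plotTimeFrequency(series, effectWindow = report$frequency$effectWindow)
    grDevices::dev.off()
    files <- c(files, f)

    f <- file.path(dir, paste0(prefix, "-cumulative-amplitude.pdf"))
    grDevices::pdf(f, width = 5, height = 5)
    ev <- report$events
    byEpoch <- split(ev$amplitude_pA, ev$epoch)
    do.call(plotCumulativeFraction, c(byEpoch, list(xlab = "Amplitude (pA)")))
    grDevices::dev.off()
    files <- c(files, f)
  } else if (identical(report$kind, "calcium")) {
    f <- file.path(dir, paste0(prefix, "-raster.pdf"))
    grDevices::pdf(f, width = 7, height = 6)
    nF <- if (length(report$raster)) ncol(report$raster) else 0L
    raster <- new("BinaryRaster",
                  mat = if (length(report$raster)) report$raster
                        else matrix(0, 0, 0),
                  frameRate = report$frameRate %||% 4,
                  conditionOfFrame = report$conditionOfFrame %||%
                    rep(NA_character_, nF))
    co <- NULL
    if (!is.null(report$coactivity$counts) &&
        length(report$coactivity$counts)) {
      co <- new("CoactivityResult",
                coactivity = as.integer(report$coactivity$counts),
                threshold = as.numeric(report$coactivity$threshold %||% NA),
                nSurrogates = as.integer(report$coactivity$nSurrogates %||% 0),
                significantFrames =
                  as.integer(report$coactivity$significantFrames %||% integer(0)),
                surrogateMax = integer(0),
                surrogateScheme = "per-cell circular shift",
                alpha = as.numeric(report$coactivity$alpha %||% 0.05),
                seed = 0L)
    }
    plotRaster(raster, co)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
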