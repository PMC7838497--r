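#' Read a current trace from a columnar time-series file
#'
#' Expects a CSV/TSV with `time` (seconds) and `current` (pA) columns; the
#' sampling rate is inferred from the time column when not given.
#'
#' @param path file path.
#' @param samplingRate Hz; NULL infers `1 / median(diff(time))`.
#' @param protocol a [DrugProtocol-class] to attach.
#' @param holdingPotential mV.
#' @param cellId identifier.
#' @return A [CurrentTrace-class].
#' @export
readCurrentTrace <- function(path, samplingRate = NULL,
                             protocol = drugProtocol(),
                             holdingPotential = -70, cellId = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("time", "current") %in% names(df)))
    stop("expected columns 'time' and 'current' in ", path)
  if (is.null(samplingRate))
    samplingRate <- 1 / stats::median(diff(df$time))
  new("CurrentTrace", samples = df$current, samplingRate = samplingRate,
      holdingPotential = holdingPotential, protocol = protocol,
      cellId = cellId %||% basename(path))
}

#' Write a detected event table
#'
#' CSV with columns `time_s`, `amplitude_pA` and `epoch`.
#'
#' @param train an [EventTrain-class].
#' @param path output path.
#' @param protocol optional [DrugProtocol-class] for the epoch column.
#' @return The path, invisibly.
#' @export
writeEventTable <- function(train, path, protocol = NULL) {
  df <- data.frame(time_s = train@times, amplitude_pA = train@amplitudes)
  df$epoch <- if (!is.null(protocol)) epochOf(protocol, train@times)
              else NA_character_
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Raster CSV round trip
#'
#' Writes/reads the cells x frames 0/1 matrix as CSV with a leading
#' `condition` header row encoded as a commented first line.
#'
#' @param raster a [BinaryRaster-class].
#' @param path file path.
#' @return `writeRasterCsv` the path invisibly; `readRasterCsv` a
#'   [BinaryRaster-class].
#' @export
writeRasterCsv <- function(raster, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#condition,", paste(raster@conditionOfFrame, collapse = ",")),
             con)
  writeLines(paste0("#frameRate,", raster@frameRate), con)
  utils::write.table(raster@mat, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeRasterCsv
#' @export
readRasterCsv <- function(path) {
  hdr <- readLines(path, n = 2L)
  cond <- strsplit(sub("^#condition,", "", hdr[1L]), ",")[[1L]]
  cond[cond == "NA"] <- NA_character_
  fr <- as.numeric(sub("^#frameRate,", "", hdr[2L]))
  m <- as.matrix(utils::read.table(path, sep = ",", skip = 2L, header = FALSE))
  dimnames(m) <- NULL
  new("BinaryRaster", mat = m, frameRate = fr, conditionOfFrame = cond)
}

#' Multi-page TIFF movie I/O
#'
#' Writes a movie as a multi-page TIFF (intensities rescaled to \[0, 1\] by
#' the stack maximum; dF/F is invariant to this gain) and reads one back.
#'
#' @param movie a [Movie-class].
#' @param path file path.
#' @param frameRate,pixelSize metadata to attach on read.
#' @return `writeMovieTiff` the path invisibly; `readMovieTiff` a
#'   [Movie-class].
#' @export
writeMovieTiff <- function(movie, path) {
  mx <- max(movie@frames)
  if (mx <= 0) mx <- 1
  pages <- lapply(seq_len(dim(movie@frames)[3L]),
                  function(f) movie@frames[, , f] / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(path, frameRate = 4, pixelSize = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(unlist(pages), c(dim(pages[[1L]])[1:2], length(pages)))
  new("Movie", frames = arr, frameRate = frameRate, pixelSize = pixelSize)
}

#' Report JSON round trip
#'
#' Serialises a pipeline report to JSON (full double precision) and parses
#' it back.
#'
#' @param report an `ExperimentReport` list from [runEpscPipeline()] or
#'   [runCalciumPipeline()].
#' @param path file path.
#' @return `writeReportJson` the path invisibly; `readReportJson` the
#'   parsed list.
#' @export
writeReportJson <- function(report, path) {
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           null = "null", dataframe = "columns")
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeReportJson
#' @export
readReportJson <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
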