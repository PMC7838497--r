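#' Extract circular ROIs from a fluorescence movie
#'
#' Selects active cells with a circular template of variable size (4-30 um).
#' The summary image is the per-pixel temporal SD, which highlights pixels
#' whose intensity fluctuates (active cells) and is flat for static
#' structures and background. ROI centres are local maxima of the
#' Gaussian-smoothed summary image above a robust prominence floor; each is
#' fitted with the disk diameter maximising the disk-vs-annulus contrast and
#' accepted greedily in decreasing peak order with no overlap.
#'
#' @param movie a [Movie-class] with at least 10 frames.
#' @param diameterRange allowed ROI diameters, um, within \[4, 30\].
#' @param smoothSigmaPx Gaussian smoothing sigma for the summary image, px.
#' @param prominence floor in robust SDs of the smoothed summary image.
#' @return A [RoiMap-class].
#' @export
extractRois <- function(movie, diameterRange = c(4, 30), smoothSigmaPx = 2,
                        prominence = 5) {
  d <- dim(movie@frames)
  if (d[3L] < 10L) stop("movie must have at least 10 frames")
  if (diameterRange[1L] < 4 || diameterRange[2L] > 30 ||
      diameterRange[1L] > diameterRange[2L])
    stop("diameterRange must lie within [4, 30] um")
  ny <- d[1L]; nx <- d[2L]; nf <- d[3L]
  px <- movie@pixelSize

  M <- matrix(movie@frames, ny * nx, nf)
  mu <- rowMeans(M)
  S <- matrix(sqrt(pmax(0, rowMeans(M * M) - mu * mu)), ny, nx)

  Sb <- EBImage::imageData(EBImage::gblur(EBImage::Image(S),
                                          sigma = smoothSigmaPx))
  Sb <- matrix(as.numeric(Sb), ny, nx)

  floorVal <- stats::median(Sb) + prominence * stats::mad(Sb)

  ## strict local maxima over the 8-neighbourhood
  isMax <- matrix(TRUE, ny, nx)
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  shifts <- shifts[!(shifts$dy == 0 & shifts$dx == 0), ]
  core <- function(m) m[2:(ny - 1L), 2:(nx - 1L)]
  cm <- core(Sb)
  for (s in seq_len(nrow(shifts))) {
    nb <- Sb[2:(ny - 1L) + shifts$dy[s], 2:(nx - 1L) + shifts$dx[s]]
    isMax[2:(ny - 1L), 2:(nx - 1L)] <-
      isMax[2:(ny - 1L), 2:(nx - 1L)] & (cm > nb)
  }
  isMax[c(1L, ny), ] <- FALSE
  isMax[, c(1L, nx)] <- FALSE
  isMax <- isMax & (Sb > floorVal)

  peaks <- which(isMax, arr.ind = TRUE)
  roiDf <- data.frame(id = integer(0), x = numeric(0), y = numeric(0),
                      diameterUm = numeric(0))
  if (nrow(peaks)) {
    vals <- Sb[peaks]
    peaks <- peaks[order(vals, decreasing = TRUE), , drop = FALSE]
    diams <- seq(diameterRange[1L], diameterRange[2L], by = max(1, px))
    gx <- matrix(rep(seq_len(nx), each = ny), ny, nx)
    gy <- matrix(rep(seq_len(ny), times = nx), ny, nx)
    accepted <- list()
    for (i in seq_len(nrow(peaks))) {
      cy <- peaks[i, 1L]; cx <- peaks[i, 2L]
      dist2 <- (gx - cx)^2 + (gy - cy)^2
      best <- NULL; bestScore <- -Inf
      for (dd in diams) {
        r <- dd / 2 / px
        if (cx - r < 1 || cx + r > nx || cy - r < 1 || cy + r > ny) next
        disk <- dist2 <= r^2
        ring <- dist2 > r^2 & dist2 <= (r + 3)^2
        if (!any(disk) || !any(ring)) next
        score <- mean(Sb[disk]) - mean(Sb[ring])
        if (score > bestScore) { bestScore <- score; best <- dd }
      }
      if (is.null(best)) next
      rpx <- best / 2 / px
      clash <- FALSE
      for (a in accepted) {
        if ((a$x - cx)^2 + (a$y - cy)^2 < (rpx + a$r)^2) { clash <- TRUE; break }
      }
      if (clash) next
      accepted[[length(accepted) + 1L]] <-
        list(x = cx, y = cy, r = rpx, d = best)
    }
    if (length(accepted)) {
      roiDf <- data.frame(
        id = seq_along(accepted),
        x = vapply(accepted, `[[`, 0, "x"),
        y = vapply(accepted, `[[`, 0, "y"),
        diameterUm = vapply(accepted, `[[`, 0, "d"))
    }
  }
  new("RoiMap", rois = roiDf, summaryImage = S, pixelSize = px)
}

#' Collect per-ROI fluorescence traces
#'
#' Mean pixel intensity per frame over each circular ROI.
#'
#' @param movie a [Movie-class].
#' @param roiMap a [RoiMap-class] whose disks lie within the field.
#' @return A [FluorTraces-class] with one row per ROI (zero rows for an
#'   empty map).
#' @export
roiTraces <- function(movie, roiMap) {
  d <- dim(movie@frames)
  ny <- d[1L]; nx <- d[2L]; nf <- d[3L]
  px <- movie@pixelSize
  r <- roiMap@rois
  out <- matrix(numeric(0), 0L, nf)
  if (nrow(r)) {
    M <- matrix(movie@frames, ny * nx, nf)
    out <- matrix(0, nrow(r), nf)
    for (i in seq_len(nrow(r))) {
      rad <- r$diameterUm[i] / 2 / px
      if (r$x[i] - rad < 0.5 || r$x[i] + rad > nx + 0.5 ||
          r$y[i] - rad < 0.5 || r$y[i] + rad > ny + 0.5)
        stop("ROI ", r$id[i], " extends outside the field")
      cols <- max(1L, floor(r$x[i] - rad)):min(nx, ceiling(r$x[i] + rad))
      rows <- max(1L, floor(r$y[i] - rad)):min(ny, ceiling(r$y[i] + rad))
      gx <- rep(cols, each = length(rows))
      gy <- rep(rows, times = length(cols))
      inDisk <- (gx - r$x[i])^2 + (gy - r$y[i])^2 <= rad^2
      pix <- (gx[inDisk] - 1L) * ny + gy[inDisk]
      out[i, ] <- colMeans(M[pix, , drop = FALSE])
    }
  }
  new("FluorTraces", traces = out, frameRate = movie@frameRate)
}
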