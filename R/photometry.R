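#' Pixels belonging to a circular ROI
#'
#' @param x,y ROI center, 0-based pixel coordinates.
#' @param radius radius, pixels.
#' @param dim frame dimensions `c(nrow, ncol)`; pixels outside the frame
#'   are excluded.
#' @return two-column integer matrix of 0-based `(x, y)` pixel coordinates.
#' @keywords internal
roi_pixels <- function(x, y, radius, dim) {
  x0 <- max(0L, floor(x - radius)); x1 <- min(dim[2L] - 1L, ceiling(x + radius))
  y0 <- max(0L, floor(y - radius)); y1 <- min(dim[1L] - 1L, ceiling(y + radius))
  if (x0 > x1 || y0 > y1) return(cbind(x = integer(0), y = integer(0)))
  g <- expand.grid(x = x0:x1, y = y0:y1)
  keep <- (g$x - x)^2 + (g$y - y)^2 <= radius^2
  cbind(x = g$x[keep], y = g$y[keep])
}

.pix_index <- function(px, dim) px[, 2L] + 1L + px[, 1L] * dim[1L]

#' Estimate the local background around an ROI
#'
#' Median pixel value in the annulus between `radius` and `2 * radius`
#' around the ROI center, excluding any pixel that lies inside another
#' track's ROI in the same frame (so one individual's flash cannot inflate
#' a neighbour's background). When clipping at the frame border and the
#' exclusions leave the annulus empty, the whole-frame median is used and
#' the result is flagged with attribute `fallback = TRUE`.
#'
#' @param frame numeric matrix.
#' @param x,y ROI center.
#' @param radius ROI radius, pixels.
#' @param exclude optional data frame / list with fields `x`, `y`,
#'   `radius`: other ROIs whose pixels must not enter the annulus.
#' @return background level in sensor units per pixel.
#' @export
estimate_background <- function(frame, x, y, radius, exclude = NULL) {
  dimf <- dim(frame)
  outer_px <- roi_pixels(x, y, 2 * radius, dimf)
  if (nrow(outer_px) > 0L) {
    d2 <- (outer_px[, 1L] - x)^2 + (outer_px[, 2L] - y)^2
    ann <- outer_px[d2 > radius^2, , drop = FALSE]
  } else ann <- outer_px
  if (!is.null(exclude) && nrow(ann) > 0L) {
    n_ex <- length(exclude$x)
    for (k in seq_len(n_ex)) {
      if (nrow(ann) == 0L) break
      d2 <- (ann[, 1L] - exclude$x[k])^2 + (ann[, 2L] - exclude$y[k])^2
      ann <- ann[d2 > exclude$radius[k]^2, , drop = FALSE]
    }
  }
  if (nrow(ann) == 0L) {
    bg <- stats::median(frame)
    attr(bg, "fallback") <- TRUE
    return(bg)
  }
  stats::median(frame[.pix_index(ann, dimf)])
}

#' Measure an individual's intensity trace
#'
#' For every frame the track covers (gaps use the interpolated centers),
#' sums the background-subtracted pixel values inside the circular ROI.
#' The per-frame background is the annulus median from
#' [estimate_background()]; a negative post-subtraction sum is clipped to
#' zero since emitted intensity is physically nonnegative. ROI pixels
#' falling outside the frame are excluded from the sum. Photometry always
#' reads the raw frames — display adjustment never enters here.
#'
#' @param seq a `frame_sequence`.
#' @param track a `track` whose frame range lies within the sequence.
#' @param aggregate `"sum"` (default; total flux is robust to the radius
#'   choice for an enclosed point source) or `"mean"`.
#' @param background `"annulus"` (default) or `"none"`.
#' @param others optional list of other `track` objects whose ROIs are
#'   excluded from the background annulus.
#' @return an object of class `intensity_trace`: fields `track_id`,
#'   `frames`, `times`, `values`, `background`, `is_gap`, `frame_rate`,
#'   plus the track centers `x`, `y`.
#' @export
measure_intensity <- function(seq, track, aggregate = c("sum", "mean"),
                              background = c("annulus", "none"),
                              others = list()) {
  stopifnot(inherits(seq, "frame_sequence"), inherits(track, "track"))
  aggregate <- match.arg(aggregate)
  background <- match.arg(background)
  n <- n_frames(seq)
  if (track$frames[1L] < 0L || track$frames[length(track$frames)] >= n)
    stop("track frame range lies outside the sequence", call. = FALSE)
  times <- seq$t0 + track$frames / seq$frame_rate
  m <- length(track$frames)
  values <- numeric(m); bgs <- numeric(m)
  for (i in seq_len(m)) {
    f <- track$frames[i]
    frame <- seq$frames[[f + 1L]]
    excl <- NULL
    if (length(others) > 0L) {
      ox <- numeric(0); oy <- numeric(0); orad <- numeric(0)
      for (ot in others) {
        j <- match(f, ot$frames)
        if (!is.na(j)) {
          ox <- c(ox, ot$x[j]); oy <- c(oy, ot$y[j])
          orad <- c(orad, ot$radius)
        }
      }
      if (length(ox) > 0L) excl <- list(x = ox, y = oy, radius = orad)
    }
    bg <- if (background == "annulus")
      estimate_background(frame, track$x[i], track$y[i], track$radius,
                          exclude = excl) else 0
    px <- roi_pixels(track$x[i], track$y[i], track$radius, dim(frame))
    v <- if (nrow(px) == 0L) 0 else
      sum(frame[.pix_index(px, dim(frame))] - bg)
    if (aggregate == "mean" && nrow(px) > 0L) v <- v / nrow(px)
    values[i] <- max(v, 0)
    bgs[i] <- as.numeric(bg)
  }
  structure(
    list(track_id = track$track_id, frames = track$frames, times = times,
         values = values, background = bgs, is_gap = track$is_gap,
         frame_rate = seq$frame_rate, x = track$x, y = track$y),
    class = "intensity_trace")
}

#' Construct an intensity trace directly from values
#'
#' Useful for analysing externally produced photometry or for tests.
#'
#' @param values intensity values, sensor units.
#' @param frame_rate frames per second.
#' @param t0 time of the first sample, seconds.
#' @param track_id label.
#' @return an `intensity_trace`.
#' @export
intensity_trace <- function(values, frame_rate, t0 = 0, track_id = "trace") {
  stopifnot(is.numeric(values), length(values) >= 1L, frame_rate > 0)
  n <- length(values)
  structure(
    list(track_id = track_id, frames = 0:(n - 1L),
         times = t0 + (0:(n - 1L)) / frame_rate, values = values,
         background = rep(0, n), is_gap = rep(FALSE, n),
         frame_rate = frame_rate,
         x = rep(NA_real_, n), y = rep(NA_real_, n)),
    class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf(
    "intensity_trace '%s': %d samples at %.6g fps, t %.3f-%.3f s, peak %.4g\n",
    x$track_id, length(x$values), x$frame_rate, x$times[1L],
    x$times[length(x$times)], max(x$values)))
  invisible(x)
}

#' Measure all tracks of a scene
#'
#' Convenience wrapper applying [measure_intensity()] to each track with
#' the remaining tracks excluded from its background annulus.
#'
#' @inheritParams measure_intensity
#' @param tracks list of `track` objects.
#' @return list of `intensity_trace` objects, one per track.
#' @export
measure_all <- function(seq, tracks, aggregate = "sum",
                        background = "annulus") {
  lapply(seq_along(tracks), function(i)
    measure_intensity(seq, tracks[[i]], aggregate = aggregate,
                      background = background, others = tracks[-i]))
}
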