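#' Detect flash peaks in an intensity trace
#'
#' Finds local maxima whose topographic prominence is at least
#' `min_prominence_frac` times the trace's full range. Prominence of a
#' peak is its height minus the higher of the two lowest points one must
#' descend to before reaching higher ground (or the trace edge) on either
#' side — the standard definition. A plateau maximum (a run of equal
#' values higher than both neighbours) reports its center time, which can
#' fall between samples.
#'
#' @param trace an `intensity_trace` (length >= 3), or a numeric vector
#'   together with `frame_rate`.
#' @param min_prominence_frac fraction of `max - min` of the trace a peak
#'   must rise above its surroundings. Default 0.05.
#' @param smooth odd boxcar width in samples applied before peak finding
#'   (1 = no smoothing). Smoothing suppresses shot-noise maxima when
#'   counting sub-pulses; reported times refer to the smoothed trace.
#' @param frame_rate used when `trace` is a bare numeric vector.
#' @return data frame with columns `time`, `value`, `prominence`, `index`
#'   (fractional sample index, 1-based). Zero rows for a constant trace.
#' @export
detect_peaks <- function(trace, min_prominence_frac = 0.05, smooth = 1L,
                         frame_rate = NULL) {
  if (inherits(trace, "intensity_trace")) {
    v <- trace$values; t0 <- trace$times[1L]; fr <- trace$frame_rate
  } else {
    if (is.null(frame_rate))
      stop("`frame_rate` required for a bare numeric trace", call. = FALSE)
    v <- as.numeric(trace); t0 <- 0; fr <- frame_rate
  }
  n <- length(v)
  if (n < 3L) stop("trace must have >= 3 samples", call. = FALSE)
  if (smooth > 1L) {
    k <- as.integer(smooth); if (k %% 2L == 0L) k <- k + 1L
    v <- as.vector(stats::filter(v, rep(1 / k, k), sides = 2))
    # boxcar undefined at the ends; hold edge values
    h <- (k - 1L) %/% 2L
    v[seq_len(h)] <- v[h + 1L]
    v[(n - h + 1L):n] <- v[n - h]
  }
  rng <- max(v) - min(v)
  empty <- data.frame(time = numeric(0), value = numeric(0),
                      prominence = numeric(0), index = numeric(0))
  if (rng == 0) return(empty)

  # candidate maxima with plateau handling
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  cand_idx <- numeric(0); cand_val <- numeric(0)
  for (j in seq_len(nr)) {
    left_ok <- j == 1L || r$values[j - 1L] < r$values[j]
    right_ok <- j == nr || r$values[j + 1L] < r$values[j]
    interior <- j > 1L && j < nr     # edge runs are not peaks
    if (left_ok && right_ok && interior) {
      cand_idx <- c(cand_idx, (starts[j] + ends[j]) / 2)
      cand_val <- c(cand_val, r$values[j])
    }
  }
  if (length(cand_idx) == 0L) return(empty)

  prom <- vapply(seq_along(cand_idx), function(k) {
    i0 <- floor(cand_idx[k]); pv <- cand_val[k]
    lmin <- pv; i <- i0
    while (i >= 1L && v[i] <= pv) { lmin <- min(lmin, v[i]); i <- i - 1L }
    rmin <- pv; i <- ceiling(cand_idx[k])
    while (i <= n && v[i] <= pv) { rmin <- min(rmin, v[i]); i <- i + 1L }
    pv - max(lmin, rmin)
  }, numeric(1))

  keep <- prom >= min_prominence_frac * rng
  data.frame(time = t0 + (cand_idx[keep] - 1) / fr,
             value = cand_val[keep], prominence = prom[keep],
             index = cand_idx[keep])
}

# linear-interpolated crossing time of `thr`, walking outward from sample
# `from` in direction `dir` (-1 left, +1 right); v strictly above thr at
# `from`
.crossing <- function(v, times, from, dir, thr) {
  i <- from
  while (i + dir >= 1L && i + dir <= length(v) && v[i + dir] > thr) i <- i + dir
  j <- i + dir
  if (j < 1L || j > length(v)) return(times[i])        # runs off the edge
  frac <- (v[i] - thr) / (v[i] - v[j])                 # v[j] <= thr < v[i]
  times[i] + frac * (times[j] - times[i])
}

#' Segment an intensity trace into flash events
#'
#' Two-pass threshold segmentation. The baseline is the 10th-percentile
#' trace value (robust to isolated dark-noise samples). A coarse pass
#' marks runs above `baseline + onset_frac * (global max - baseline)`;
#' each run is then refined with its own threshold
#' `baseline + onset_frac * (run peak - baseline)` so flashes of unequal
#' amplitude get comparable boundaries, with onset/offset located by
#' linear interpolation between samples. Runs whose dark gap is shorter
#' than `merge_gap` are merged into a single flash event (a twinkling
#' flash with minor blinks counts as one flash); an event's peaks are all
#' detected peaks falling inside it, or the event's maximum sample when
#' prominence filtering leaves none.
#'
#' @param trace an `intensity_trace`.
#' @param onset_frac threshold fraction of peak-above-baseline defining
#'   onset and offset (0 < onset_frac < 1). Default 0.1 (10% of peak);
#'   0.5 gives half-max boundaries.
#' @param merge_gap dark gaps shorter than this many seconds are merged,
#'   default 0.3 s.
#' @param min_prominence_frac passed to [detect_peaks()].
#' @param smooth passed to [detect_peaks()] (peak counting only;
#'   boundaries always use the raw trace).
#' @param drop_truncated drop events whose above-threshold run touches
#'   the first or last trace sample: such flashes are cut off by the
#'   recording window and their durations are not measurable. Default
#'   `TRUE`.
#' @return list of `flash_event` objects (fields `onset`, `offset`,
#'   `duration`, `peak_times`, `peak_values`); empty list when the trace
#'   never exceeds threshold.
#' @export
segment_flashes <- function(trace, onset_frac = 0.1, merge_gap = 0.3,
                            min_prominence_frac = 0.05, smooth = 1L,
                            drop_truncated = TRUE) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (onset_frac <= 0 || onset_frac >= 1)
    stop("`onset_frac` must be in (0, 1)", call. = FALSE)
  v <- trace$values; tt <- trace$times
  baseline <- stats::quantile(v, 0.10, names = FALSE)
  vmax <- max(v)
  if (vmax <= baseline) return(list())
  thr_g <- baseline + onset_frac * (vmax - baseline)
  above <- v > thr_g
  if (!any(above)) return(list())

  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  seg <- cbind(starts[r$values], ends[r$values])
  if (drop_truncated) {
    whole <- seg[, 1L] > 1L & seg[, 2L] < length(v)
    seg <- seg[whole, , drop = FALSE]
    if (nrow(seg) == 0L) return(list())
  }

  bounds <- matrix(NA_real_, nrow(seg), 2L)
  for (k in seq_len(nrow(seg))) {
    i0 <- seg[k, 1L]; i1 <- seg[k, 2L]
    pk <- i0 - 1L + which.max(v[i0:i1])
    thr_s <- baseline + onset_frac * (v[pk] - baseline)
    bounds[k, 1L] <- .crossing(v, tt, pk, -1L, thr_s)
    bounds[k, 2L] <- .crossing(v, tt, pk, +1L, thr_s)
  }
  # refinement can make neighbours overlap; clip to midpoints
  if (nrow(bounds) > 1L) for (k in 2:nrow(bounds)) {
    if (bounds[k, 1L] < bounds[k - 1L, 2L]) {
      mid <- (tt[seg[k - 1L, 2L]] + tt[seg[k, 1L]]) / 2
      bounds[k - 1L, 2L] <- min(bounds[k - 1L, 2L], mid)
      bounds[k, 1L] <- max(bounds[k, 1L], mid)
    }
  }
  # merge events separated by a short dark gap
  merged <- bounds[1L, , drop = FALSE]
  if (nrow(bounds) > 1L) for (k in 2:nrow(bounds)) {
    gap <- bounds[k, 1L] - merged[nrow(merged), 2L]
    if (gap < merge_gap) merged[nrow(merged), 2L] <- bounds[k, 2L]
    else merged <- rbind(merged, bounds[k, , drop = FALSE])
  }

  pk <- detect_peaks(trace, min_prominence_frac = min_prominence_frac,
                     smooth = smooth)
  events <- vector("list", nrow(merged))
  for (k in seq_len(nrow(merged))) {
    on <- merged[k, 1L]; off <- merged[k, 2L]
    inside <- pk$time >= on & pk$time <= off
    if (any(inside)) {
      ptimes <- pk$time[inside]; pvals <- pk$value[inside]
    } else {
      sel <- which(tt >= on & tt <= off)
      if (length(sel) == 0L) sel <- which.min(abs(tt - (on + off) / 2))
      j <- sel[which.max(v[sel])]
      ptimes <- tt[j]; pvals <- v[j]
    }
    events[[k]] <- structure(
      list(onset = on, offset = off, duration = off - on,
           peak_times = ptimes, peak_values = pvals),
      class = "flash_event")
  }
  events
}

#' @export
print.flash_event <- function(x, ...) {
  cat(sprintf("flash_event: %.4f-%.4f s (%.0f ms), %d peak(s)\n",
              x$onset, x$offset, 1000 * x$duration, length(x$peak_times)))
  invisible(x)
}

#' Events as a data frame
#' @param events list of `flash_event` objects.
#' @param track_id label recorded in the table.
#' @return one row per event: onset_s, offset_s, duration_s, n_peaks,
#'   `;`-joined peak times and values.
#' @export
events_to_df <- function(events, track_id = "trace") {
  if (length(events) == 0L)
    return(data.frame(track_id = character(0), onset_s = numeric(0),
                      offset_s = numeric(0), duration_s = numeric(0),
                      n_peaks = integer(0), peak_times_s = character(0),
                      peak_values = character(0)))
  data.frame(
    track_id = track_id,
    onset_s = vapply(events, `[[`, 0, "onset"),
    offset_s = vapply(events, `[[`, 0, "offset"),
    duration_s = vapply(events, `[[`, 0, "duration"),
    n_peaks = vapply(events, function(e) length(e$peak_times), 0L),
    peak_times_s = vapply(events, function(e)
      paste(format(e$peak_times, digits = 17, trim = TRUE,
                   scientific = FALSE), collapse = ";"), ""),
    peak_values = vapply(events, function(e)
      paste(format(e$peak_values, digits = 17, trim = TRUE,
                   scientific = FALSE), collapse = ";"), ""))
}

#' Summarize flash events into pattern metrics
#'
#' The metrics that characterise a species' flash pattern:
#' \describe{
#'   \item{n_flashes}{number of flash events.}
#'   \item{mean_duration}{mean onset-to-offset time, seconds.}
#'   \item{mean_peak_interval}{mean time between the first peaks of
#'     successive flashes.}
#'   \item{mean_interflash_interval}{mean dark gap — one flash's offset to
#'     the next flash's onset. The peak-to-peak reading is also reported
#'     as `mean_peak_to_peak`.}
#'   \item{mean_subpulse_interval}{mean spacing of successive peaks
#'     *within* a flash (`NA` when every flash has a single peak).}
#'   \item{pulses_per_flash}{integer peak count of each flash, in order.}
#' }
#' Interval means are `NA` with fewer than two flashes.
#'
#' @param events list of `flash_event` objects from [segment_flashes()].
#' @param track_id label carried into the summary.
#' @return an object of class `flash_summary`.
#' @export
summarize_flashes <- function(events, track_id = "trace") {
  n <- length(events)
  pulses <- if (n) vapply(events, function(e) length(e$peak_times), 0L)
            else integer(0)
  mean_or_na <- function(x) if (length(x) >= 1L) mean(x) else NA_real_
  if (n >= 2L) {
    first_peaks <- vapply(events, function(e) e$peak_times[1L], 0)
    onsets <- vapply(events, `[[`, 0, "onset")
    offsets <- vapply(events, `[[`, 0, "offset")
    peak_int <- mean(diff(first_peaks))
    inter <- mean(onsets[-1L] - offsets[-n])
    p2p <- peak_int
  } else peak_int <- inter <- p2p <- NA_real_
  sub <- unlist(lapply(events, function(e)
    if (length(e$peak_times) > 1L) diff(e$peak_times) else NULL))
  structure(
    list(track_id = track_id, n_flashes = n,
         mean_duration = if (n) mean(vapply(events, `[[`, 0, "duration"))
                         else NA_real_,
         mean_peak_interval = peak_int,
         mean_interflash_interval = inter,
         mean_peak_to_peak = p2p,
         mean_subpulse_interval = mean_or_na(sub),
         pulses_per_flash = pulses),
    class = "flash_summary")
}

#' @export
print.flash_summary <- function(x, ...) {
  cat(sprintf("flash_summary '%s': %d flashes\n", x$track_id, x$n_flashes))
  cat(sprintf("  mean duration        %8.1f ms\n", 1000 * x$mean_duration))
  cat(sprintf("  mean peak interval   %8.1f ms\n",
              1000 * x$mean_peak_interval))
  cat(sprintf("  mean interflash gap  %8.1f ms\n",
              1000 * x$mean_interflash_interval))
  cat(sprintf("  mean subpulse gap    %8.1f ms\n",
              1000 * x$mean_subpulse_interval))
  if (x$n_flashes)
    cat("  pulses per flash    ",
        paste(x$pulses_per_flash, collapse = " "), "\n")
  invisible(x)
}

#' Summaries as a one-row-per-track data frame
#' @param summaries list of `flash_summary` objects (or a single one).
#' @return data frame, one row per summary.
#' @export
summaries_to_df <- function(summaries) {
  if (inherits(summaries, "flash_summary")) summaries <- list(summaries)
  do.call(rbind, lapply(summaries, function(s) data.frame(
    track_id = s$track_id, n_flashes = s$n_flashes,
    mean_duration_s = s$mean_duration,
    mean_peak_interval_s = s$mean_peak_interval,
    mean_interflash_interval_s = s$mean_interflash_interval,
    mean_peak_to_peak_s = s$mean_peak_to_peak,
    mean_subpulse_interval_s = s$mean_subpulse_interval,
    pulses_per_flash = paste(s$pulses_per_flash, collapse = ";"))))
}
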