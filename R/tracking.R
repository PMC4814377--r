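#' Circular region of interest
#'
#' A pixel `(px, py)` belongs to the ROI iff the Euclidean distance from
#' `(px, py)` to the center is at most `radius`.
#'
#' @param x,y center coordinates, pixels (0-based, may be fractional).
#' @param radius ROI radius in pixels, >= 1.
#' @param frame 0-based frame index the ROI refers to.
#' @return an object of class `roi`.
#' @export
roi <- function(x, y, radius, frame = 0L) {
  if (radius < 1) stop("`radius` must be >= 1 pixel", call. = FALSE)
  structure(list(x = x, y = y, radius = radius,
                 frame = as.integer(frame)), class = "roi")
}

#' Construct a track (one individual's flight path)
#'
#' A track holds one circular ROI center per frame over a contiguous frame
#' range. Frames with no observation are gaps: their centers are linearly
#' interpolated between the neighbouring observations (so photometry stays
#' aligned to the frame clock) and flagged in `is_gap`. Two tracks may
#' occupy overlapping pixels in the same frame — coinciding paths are
#' traced superpositionally, though their light is then not separable.
#'
#' @param track_id label for the individual.
#' @param frames strictly increasing 0-based frame indices of the
#'   observations.
#' @param x,y observed center coordinates, one per element of `frames`.
#' @param radius constant ROI radius for the whole track, pixels.
#' @return an object of class `track` with per-frame fields covering the
#'   full range `min(frames):max(frames)`.
#' @export
track <- function(track_id, frames, x, y, radius = 5) {
  frames <- as.integer(frames)
  if (length(frames) < 1L) stop("track needs >= 1 observation", call. = FALSE)
  if (length(x) != length(frames) || length(y) != length(frames))
    stop("`frames`, `x`, `y` must have equal length", call. = FALSE)
  if (any(diff(frames) <= 0L))
    stop("frame indices must be strictly increasing", call. = FALSE)
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  full <- frames[1L]:frames[length(frames)]
  is_gap <- !(full %in% frames)
  xi <- if (length(frames) > 1L)
    stats::approx(frames, x, xout = full)$y else x
  yi <- if (length(frames) > 1L)
    stats::approx(frames, y, xout = full)$y else y
  structure(list(track_id = track_id, frames = full, x = xi, y = yi,
                 is_gap = is_gap, radius = radius), class = "track")
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("track '%s': frames %d-%d (%d gaps), radius %.3g px\n",
              x$track_id, x$frames[1L], x$frames[length(x$frames)],
              sum(x$is_gap), x$radius))
  invisible(x)
}

#' Tracks as a data frame
#' @param x a `track`.
#' @param ... unused.
#' @return data frame with columns track_id, frame, x, y, is_gap.
#' @export
as.data.frame.track <- function(x, ...) {
  data.frame(track_id = x$track_id, frame = x$frames, x = x$x, y = x$y,
             is_gap = x$is_gap)
}

#' Import a manually traced flight path from CSV
#'
#' The CSV dialect replaces the mouse tracing of interactive tools: a
#' header row and columns `frame,x,y` (0-based frames, pixel units),
#' optionally `track_id` for a multi-individual file. Frames must be
#' strictly increasing within an individual; frames missing between the
#' first and last become gaps.
#'
#' @param path CSV file.
#' @param radius ROI radius assigned to the trace, pixels.
#' @return a `track`, or a list of tracks when the file has a `track_id`
#'   column with several individuals.
#' @export
load_manual_track <- function(path, radius = 5) {
  df <- try(utils::read.csv(path), silent = TRUE)
  if (inherits(df, "try-error"))
    stop("cannot read trace CSV: ", path, call. = FALSE)
  need <- c("frame", "x", "y")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns frame,x,y (found: ",
         paste(names(df), collapse = ","), ")", call. = FALSE)
  for (col in need)
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column `", col, "`", call. = FALSE)
  build <- function(d, id) {
    if (any(diff(d$frame) <= 0))
      stop("frame indices must be strictly increasing (track ", id, ")",
           call. = FALSE)
    track(id, d$frame, d$x, d$y, radius = radius)
  }
  if ("track_id" %in% names(df) && length(unique(df$track_id)) > 1L) {
    ids <- unique(df$track_id)
    return(lapply(ids, function(id) build(df[df$track_id == id, ], id)))
  }
  id <- if ("track_id" %in% names(df)) df$track_id[1L] else
    sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  build(df, id)
}

#' Detect bright spots in one frame
#'
#' Thresholds the frame, labels connected components (8-connectivity, via
#' EBImage), discards components smaller than `min_area`, and reports each
#' surviving component's brightness-weighted centroid, summed brightness,
#' and pixel area, sorted by descending total brightness.
#'
#' @param frame numeric matrix. Choosing `threshold` above the background
#'   level is the caller's responsibility (see [suggest_threshold()]).
#' @param threshold sensor units; pixels strictly above it are foreground.
#' @param min_area minimum component size in pixels.
#' @return data frame with columns `x`, `y` (sub-pixel centroid),
#'   `total_brightness`, `area`; zero rows for a blank frame.
#' @export
detect_spots <- function(frame, threshold, min_area = 1L) {
  stopifnot(is.matrix(frame))
  mask <- frame > threshold
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      total_brightness = numeric(0), area = integer(0))
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(mask * 1)
  idx <- which(lab > 0)
  labs <- as.integer(lab[idx])
  vals <- frame[idx]
  ys <- ((idx - 1L) %% nrow(frame))        # 0-based row = y
  xs <- ((idx - 1L) %/% nrow(frame))       # 0-based col = x
  area <- tabulate(labs)
  wsum <- rowsum(vals, labs)[, 1L]
  cx <- rowsum(vals * xs, labs)[, 1L] / wsum
  cy <- rowsum(vals * ys, labs)[, 1L] / wsum
  keep <- area >= min_area
  if (!any(keep)) return(empty)
  out <- data.frame(x = cx[keep], y = cy[keep],
                    total_brightness = wsum[keep], area = area[keep])
  out <- out[order(-out$total_brightness, out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Suggest a detection threshold for a scene
#'
#' Robust dark-background heuristic: median plus `k` times the median
#' absolute deviation of pixel values, pooled over up to `n_sample` frames.
#'
#' @param seq a `frame_sequence`.
#' @param k multiplier on the MAD (default 8).
#' @param n_sample frames sampled evenly across the sequence.
#' @return threshold in sensor units.
#' @export
suggest_threshold <- function(seq, k = 8, n_sample = 16L) {
  stopifnot(inherits(seq, "frame_sequence"))
  pick <- unique(round(seq(1L, n_frames(seq), length.out = n_sample)))
  v <- unlist(lapply(seq$frames[pick], as.vector), use.names = FALSE)
  stats::median(v) + k * max(stats::mad(v), 1)
}

#' Link per-frame detections into tracks
#'
#' Greedy nearest-neighbour linking: at each frame, live tracks claim
#' detections in order of increasing distance; a pairing farther than
#' `max_jump` pixels is refused. Detections claimed by no track start new
#' tracks; a track unmatched for more than `max_gap` consecutive frames is
#' closed. Ties (equal distance) are broken toward the older (lower-id)
#' track, then the earlier detection — never iteration order — so linking
#' is fully deterministic. Interior unmatched frames become gaps with
#' linearly interpolated centers. A warning is issued when two live track
#' centers come within one ROI radius, since overlapping sources cannot be
#' photometered separately.
#'
#' @param detections_per_frame list (one element per frame, in frame order)
#'   of data frames as returned by [detect_spots()].
#' @param max_jump maximum allowed center displacement between a track's
#'   last known position and a new detection, pixels.
#' @param max_gap frames a track may go unobserved before it is closed.
#' @param radius ROI radius given to the resulting tracks.
#' @param frame_offset 0-based index of the first element of
#'   `detections_per_frame` within the parent sequence.
#' @param min_length discard final tracks with fewer observations.
#' @return list of `track` objects, ordered by first frame then creation.
#' @export
link_tracks <- function(detections_per_frame, max_jump, max_gap = 2L,
                        radius = 5, frame_offset = 0L, min_length = 1L) {
  live <- list()     # each: id, last_x, last_y, last_frame, frames, x, y
  done <- list()
  next_id <- 1L
  overlap_warned <- FALSE

  for (fi in seq_along(detections_per_frame)) {
    f <- frame_offset + fi - 1L
    det <- detections_per_frame[[fi]]
    nd <- if (is.null(det)) 0L else nrow(det)
    nt <- length(live)
    assigned_det <- rep(FALSE, nd)
    matched_track <- rep(FALSE, nt)

    if (nt > 0L && nd > 0L) {
      dx <- outer(vapply(live, `[[`, 0, "last_x"), det$x, `-`)
      dy <- outer(vapply(live, `[[`, 0, "last_y"), det$y, `-`)
      dist <- sqrt(dx^2 + dy^2)
      dist[dist > max_jump] <- NA
      ids <- vapply(live, `[[`, 0L, "id")
      repeat {
        if (all(is.na(dist))) break
        best <- min(dist, na.rm = TRUE)
        cand <- which(dist == best, arr.ind = TRUE)
        # ties: lowest track id wins, then earliest detection
        cand <- cand[order(ids[cand[, 1L]], cand[, 2L]), , drop = FALSE]
        ti <- cand[1L, 1L]; di <- cand[1L, 2L]
        live[[ti]]$frames <- c(live[[ti]]$frames, f)
        live[[ti]]$x <- c(live[[ti]]$x, det$x[di])
        live[[ti]]$y <- c(live[[ti]]$y, det$y[di])
        live[[ti]]$last_x <- det$x[di]; live[[ti]]$last_y <- det$y[di]
        live[[ti]]$last_frame <- f
        matched_track[ti] <- TRUE; assigned_det[di] <- TRUE
        dist[ti, ] <- NA; dist[, di] <- NA
      }
    }
    # births
    if (nd > 0L) for (di in which(!assigned_det)) {
      live[[length(live) + 1L]] <- list(
        id = next_id, last_x = det$x[di], last_y = det$y[di],
        last_frame = f, frames = f, x = det$x[di], y = det$y[di])
      next_id <- next_id + 1L
    }
    # deaths
    if (length(live) > 0L) {
      stale <- vapply(live, function(tr) f - tr$last_frame > max_gap,
                      logical(1))
      done <- c(done, live[stale])
      live <- live[!stale]
    }
    if (!overlap_warned && length(live) > 1L) {
      xs <- vapply(live, `[[`, 0, "last_x")
      ys <- vapply(live, `[[`, 0, "last_y")
      dmin <- min(stats::dist(cbind(xs, ys)))
      if (dmin <= radius) {
        warning("two track centers within one ROI radius; ",
                "their intensities are not separable", call. = FALSE)
        overlap_warned <- TRUE
      }
    }
  }
  done <- c(done, live)
  done <- done[vapply(done, function(tr) length(tr$frames), 0L) >= min_length]
  done <- done[order(vapply(done, function(tr) tr$frames[1L], 0L),
                     vapply(done, `[[`, 0L, "id"))]
  lapply(done, function(tr)
    track(tr$id, tr$frames, tr$x, tr$y, radius = radius))
}

#' Run spot detection over a whole sequence
#'
#' @param seq a `frame_sequence`.
#' @param threshold sensor units (default from [suggest_threshold()]).
#' @param min_area minimum component area, pixels.
#' @return list of per-frame detection data frames (see [detect_spots()]).
#' @export
detect_all <- function(seq, threshold = suggest_threshold(seq),
                       min_area = 2L) {
  lapply(seq$frames, detect_spots, threshold = threshold,
         min_area = min_area)
}
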