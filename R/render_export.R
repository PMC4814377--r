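#' Ordinal step scale for intensity circles
#'
#' Maps an intensity series onto `n_steps` ordinal levels rendered as
#' circles of increasing radius along the orbit line (seven steps by
#' default). Radii default to `radius_min + (step - 1) * radius_increment`.
#'
#' @param n_steps number of levels, >= 2 (default 7).
#' @param radius_min radius of step 1, pixels.
#' @param radius_increment radius increase per step, pixels.
#' @param radii explicit strictly increasing radii (overrides the linear
#'   ramp).
#' @return object of class `step_scale`.
#' @export
step_scale <- function(n_steps = 7L, radius_min = 2, radius_increment = 2,
                       radii = NULL) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("`n_steps` must be >= 2", call. = FALSE)
  if (is.null(radii))
    radii <- radius_min + (seq_len(n_steps) - 1L) * radius_increment
  if (length(radii) != n_steps || any(diff(radii) <= 0))
    stop("`radii` must be strictly increasing with one entry per step",
         call. = FALSE)
  structure(list(n_steps = n_steps, radii = radii), class = "step_scale")
}

#' Quantize an intensity series into ordinal steps
#'
#' Equal-width bins spanning `[min, max]` of the series, half-open and
#' closed at the top: the minimum maps to step 1, the maximum to step
#' `n_steps`, and a constant series maps wholly to step 1. An
#' equal-quantile allocation is available via `method = "quantile"`.
#' Quantization is monotone: `v1 <= v2` implies `step(v1) <= step(v2)`.
#'
#' @param values numeric intensity series (non-empty).
#' @param n_steps number of steps, >= 2 (default 7).
#' @param method `"width"` (default) or `"quantile"`.
#' @return integer vector of steps in `1..n_steps`.
#' @export
quantize_intensity <- function(values, n_steps = 7L,
                               method = c("width", "quantile")) {
  method <- match.arg(method)
  if (length(values) == 0L) stop("empty series", call. = FALSE)
  n_steps <- as.integer(n_steps)
  if (n_steps < 2L) stop("`n_steps` must be >= 2", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (hi == lo) return(rep(1L, length(values)))
  if (method == "width") {
    w <- (hi - lo) / n_steps
    s <- ceiling((values - lo) / w)
    s[s < 1L] <- 1L; s[s > n_steps] <- n_steps
    as.integer(s)
  } else {
    edges <- unique(stats::quantile(values, seq(0, 1, length.out =
                                                  n_steps + 1L)))
    as.integer(cut(values, breaks = edges, include.lowest = TRUE,
                   labels = FALSE))
  }
}

# draw a filled disk of `value` into matrix `img` (0-based center coords)
.draw_disk <- function(img, x, y, r, value) {
  px <- roi_pixels(x, y, r, dim(img))
  if (nrow(px) > 0L) img[.pix_index(px, dim(img))] <- value
  img
}

# draw a 1-px polyline; `dashed` skips every other interpolated dot
.draw_polyline <- function(img, xs, ys, value, dashed = FALSE) {
  dimi <- dim(img)
  for (i in seq_len(length(xs) - 1L)) {
    n <- max(2L, ceiling(max(abs(xs[i + 1L] - xs[i]),
                             abs(ys[i + 1L] - ys[i]))) + 1L)
    f <- seq(0, 1, length.out = n)
    if (dashed) f <- f[seq_along(f) %% 2L == 1L]
    px <- round(xs[i] + f * (xs[i + 1L] - xs[i]))
    py <- round(ys[i] + f * (ys[i + 1L] - ys[i]))
    keep <- px >= 0 & px < dimi[2L] & py >= 0 & py < dimi[1L]
    if (any(keep))
      img[.pix_index(cbind(px[keep], py[keep]), dimi)] <- value
  }
  img
}

# 1-px circle outline
.draw_circle <- function(img, x, y, r, value, dashed = FALSE) {
  th <- seq(0, 2 * pi, length.out = max(16L, ceiling(2 * pi * r)))
  if (dashed) th <- th[seq_along(th) %% 2L == 1L]
  px <- round(x + r * cos(th)); py <- round(y + r * sin(th))
  dimi <- dim(img)
  keep <- px >= 0 & px < dimi[2L] & py >= 0 & py < dimi[1L]
  if (any(keep)) img[.pix_index(cbind(px[keep], py[keep]), dimi)] <- value
  img
}

#' Render a flight path with stepped intensity circles
#'
#' Draws the orbit line (polyline through the track's per-frame centers)
#' and, at every sample, a filled circle whose radius encodes the
#' quantized intensity step — the classic flight-path figure with circle
#' size allocated at `n_steps` (default seven) steps on the orbit line.
#'
#' @param track a `track`.
#' @param trace the matching `intensity_trace` (equal length).
#' @param scale a [step_scale()].
#' @param canvas output image dimensions `c(width, height)` in pixels.
#' @param suppress_min if `TRUE`, step-1 (dark-phase) circles are not
#'   drawn, de-cluttering the dark portions of the path. Default `FALSE`.
#' @param method binning method for [quantize_intensity()].
#' @return numeric matrix (`height x width`, values in `[0, 1]`):
#'   background 0, orbit line 0.1, circles at `step / n_steps` (always
#'   above the line value). Larger steps are drawn last, so the brightest
#'   value marks the strongest flash.
#' @export
render_path <- function(track, trace, scale = step_scale(),
                        canvas = c(256L, 256L), suppress_min = FALSE,
                        method = "width") {
  stopifnot(inherits(track, "track"), inherits(trace, "intensity_trace"),
            inherits(scale, "step_scale"))
  if (length(track$frames) == 0L)
    stop("empty track", call. = FALSE)
  if (length(track$frames) != length(trace$values))
    stop("track and trace lengths differ", call. = FALSE)
  img <- matrix(0, nrow = canvas[2L], ncol = canvas[1L])
  img <- .draw_polyline(img, track$x, track$y, 0.1)
  steps <- quantize_intensity(trace$values, scale$n_steps, method = method)
  for (s in sort(unique(steps))) {
    if (suppress_min && s == 1L) next
    for (i in which(steps == s))
      img <- .draw_disk(img, track$x[i], track$y[i], scale$radii[s],
                        s / scale$n_steps)
  }
  img
}

#' Plot intensity time courses with an optional frame cursor
#'
#' One coloured series per trace on a shared time axis, using the
#' conventional palette order red, brown, green, purple, blue (cycling
#' beyond five traces), with a red vertical cursor line marking the time
#' of `cursor_frame` when given.
#'
#' @param traces non-empty list of `intensity_trace` objects.
#' @param cursor_frame optional 0-based frame index to mark.
#' @param palette colour order for the series.
#' @return a `ggplot` object.
#' @export
render_timecourse <- function(traces, cursor_frame = NULL,
                              palette = c("red", "brown", "green",
                                          "purple", "blue")) {
  if (inherits(traces, "intensity_trace")) traces <- list(traces)
  if (length(traces) == 0L) stop("no traces to plot", call. = FALSE)
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(track_id = as.character(tr$track_id), time = tr$times,
               intensity = tr$values)))
  ids <- unique(df$track_id)
  cols <- rep_len(palette, length(ids))
  names(cols) <- ids
  df$track_id <- factor(df$track_id, levels = ids)
  p <- ggplot2::ggplot(df, ggplot2::aes(
         x = time, y = intensity, colour = track_id)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = cols, name = "track") +
    ggplot2::labs(x = "time (s)", y = "ROI intensity (ADU)") +
    ggplot2::theme_minimal()
  if (!is.null(cursor_frame)) {
    tcur <- traces[[1L]]$times[1L] +
      (cursor_frame - traces[[1L]]$frames[1L]) / traces[[1L]]$frame_rate
    p <- p + ggplot2::geom_vline(xintercept = tcur, colour = "red")
  }
  p
}

# tiny 3x5 bitmap font for the burned-in timer (digits, dot, colon)
.glyphs <- local({
  g <- list(
    "0" = c(7,5,5,5,7), "1" = c(2,6,2,2,7), "2" = c(7,1,7,4,7),
    "3" = c(7,1,7,1,7), "4" = c(5,5,7,1,1), "5" = c(7,4,7,1,7),
    "6" = c(7,4,7,5,7), "7" = c(7,1,1,1,1), "8" = c(7,5,7,5,7),
    "9" = c(7,5,7,1,7), "." = c(0,0,0,0,2), ":" = c(0,2,0,2,0),
    " " = c(0,0,0,0,0))
  lapply(g, function(rows)
    t(vapply(rows, function(r)
      as.integer(bitwAnd(r, c(4L, 2L, 1L)) > 0L), integer(3))))
})

.stamp_text <- function(img, text, x, y, value, scale = 1L) {
  for (ch in strsplit(text, "")[[1L]]) {
    gl <- .glyphs[[ch]]
    if (!is.null(gl)) {
      for (gy in 1:5) for (gx in 1:3) if (gl[gy, gx] > 0L) {
        yy <- y + (gy - 1L) * scale + seq_len(scale) - 1L
        xx <- x + (gx - 1L) * scale + seq_len(scale) - 1L
        yy <- yy[yy >= 1L & yy <= nrow(img)]
        xx <- xx[xx >= 1L & xx <= ncol(img)]
        if (length(yy) && length(xx)) img[yy, xx] <- value
      }
    }
    x <- x + 4L * scale
  }
  img
}

#' Burn tracking overlays into a video
#'
#' Re-encodes the sequence with, for each track, the ROI circle at the
#' current frame and the trailing path polyline burned in at the
#' sequence's maximum representable value. At a gap frame the
#' (interpolated-position) ROI is drawn dashed. Frame count, dimensions
#' and rate are preserved. Optionally stamps a `sec.msec` timer in the
#' top-left corner.
#'
#' @param seq a `frame_sequence`.
#' @param tracks list of `track` objects within the sequence range (may be
#'   empty: the video is then re-encoded unchanged).
#' @param out output AVI path.
#' @param trail number of past positions included in the trailing
#'   polyline; `Inf` keeps the whole history.
#' @param timer stamp the frame time as `sec.msec`. Default `FALSE`.
#' @return `out`, invisibly.
#' @export
write_overlay_video <- function(seq, tracks, out, trail = Inf,
                                timer = FALSE) {
  stopifnot(inherits(seq, "frame_sequence"))
  top <- 2^seq$bits - 1
  n <- n_frames(seq)
  for (tr in tracks)
    if (tr$frames[1L] < 0L || tr$frames[length(tr$frames)] >= n)
      stop("track outside sequence range", call. = FALSE)
  frames <- vector("list", n)
  times <- frame_times(seq)
  for (f0 in 0:(n - 1L)) {
    img <- seq$frames[[f0 + 1L]]
    for (tr in tracks) {
      j <- match(f0, tr$frames)
      upto <- if (is.na(j)) sum(tr$frames < f0) else j
      if (upto >= 2L) {
        from <- max(1L, upto - if (is.finite(trail)) as.integer(trail) else upto)
        img <- .draw_polyline(img, tr$x[from:upto], tr$y[from:upto], top)
      }
      if (!is.na(j))
        img <- .draw_circle(img, tr$x[j], tr$y[j], tr$radius, top,
                            dashed = tr$is_gap[j])
    }
    if (timer)
      img <- .stamp_text(img, sprintf("%.3f", times[f0 + 1L]), 3L, 3L, top)
    frames[[f0 + 1L]] <- img
  }
  write_avi(frame_sequence(frames, seq$frame_rate, seq$t0, seq$bits), out)
  invisible(out)
}

#' Save a raster matrix as a PNG file
#' @param img numeric matrix in `[0, 1]` (or any range; rescaled).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(img, path) {
  rng <- range(img)
  if (diff(rng) > 0) img <- (img - rng[1L]) / diff(rng)
  png::writePNG(img, path)
  invisible(path)
}

#' Export the full analysis bundle
#'
#' Writes every text and graphical output of a run into `out_dir`: the
#' track, trace, event and summary CSVs, a rendered orbit-line figure per
#' track, the shared time-course figure, optionally the overlay video, and
#' a JSON manifest listing each file with its row or frame count.
#'
#' @param out_dir output directory (created if needed).
#' @param tracks list of `track` objects.
#' @param traces list of matching `intensity_trace` objects.
#' @param events_list list (per track) of flash-event lists.
#' @param summaries list of `flash_summary` objects.
#' @param seq optional `frame_sequence`; when given the overlay video is
#'   written.
#' @param scale a [step_scale()] for the path figures.
#' @param canvas path-figure dimensions `c(width, height)`; defaults to
#'   the sequence's frame size or 256 x 256.
#' @param figures write PNG figures (requires a working png device for
#'   the time-course plot). Default `TRUE`.
#' @return the manifest (named list), invisibly written as
#'   `manifest.json`.
#' @export
export_bundle <- function(out_dir, tracks, traces, events_list, summaries,
                          seq = NULL, scale = step_scale(), canvas = NULL,
                          figures = TRUE) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  add <- function(name, path, count) {
    if (!file.exists(path))
      stop("failed to write output artifact: ", path, call. = FALSE)
    manifest[[name]] <<- list(file = basename(path), count = count)
  }

  tr_df <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    d <- as.data.frame(tracks[[i]])
    d$time_s <- traces[[i]]$times
    d[, c("track_id", "frame", "time_s", "x", "y", "is_gap")]
  }))
  p <- file.path(out_dir, "tracks.csv")
  readr::write_csv(tr_df, p)
  add("tracks_csv", p, nrow(tr_df))

  trace_df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(track_id = tr$track_id, frame = tr$frames,
               time_s = tr$times, x = tr$x, y = tr$y,
               intensity = tr$values, background = tr$background,
               is_gap = tr$is_gap)))
  p <- file.path(out_dir, "traces.csv")
  readr::write_csv(trace_df, p)
  add("traces_csv", p, nrow(trace_df))

  ev_df <- do.call(rbind, lapply(seq_along(events_list), function(i)
    events_to_df(events_list[[i]], track_id = tracks[[i]]$track_id)))
  p <- file.path(out_dir, "events.csv")
  readr::write_csv(ev_df, p)
  add("events_csv", p, nrow(ev_df))

  sum_df <- summaries_to_df(summaries)
  p <- file.path(out_dir, "summary.csv")
  readr::write_csv(sum_df, p)
  add("summary_csv", p, nrow(sum_df))

  if (figures) {
    if (is.null(canvas))
      canvas <- if (!is.null(seq)) rev(dim(seq$frames[[1L]]))
                else c(256L, 256L)
    for (i in seq_along(tracks)) {
      img <- render_path(tracks[[i]], traces[[i]], scale = scale,
                         canvas = canvas)
      p <- file.path(out_dir,
                     sprintf("path_%s.png", tracks[[i]]$track_id))
      write_raster_png(img, p)
      add(paste0("path_png_", tracks[[i]]$track_id), p, 1L)
    }
    gg <- render_timecourse(traces)
    p <- file.path(out_dir, "timecourse.png")
    grDevices::png(p, width = 900, height = 500)
    print(gg)
    grDevices::dev.off()
    add("timecourse_png", p, 1L)
  }

  if (!is.null(seq)) {
    p <- file.path(out_dir, "overlay.avi")
    write_overlay_video(seq, tracks, p)
    add("overlay_avi", p, n_frames(seq))
  }

  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  manifest
}
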