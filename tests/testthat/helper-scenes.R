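# Shared fixtures and independent oracles, all built in code.

# frame with one (or more) Gaussian spots on a flat background;
# spots: data.frame(x, y, flux)
gaussian_frame <- function(w, h, spots, sigma = 1.5, background = 0) {
  img <- matrix(background, h, w)
  for (i in seq_len(nrow(spots))) {
    gx <- exp(-((0:(w - 1)) - spots$x[i])^2 / (2 * sigma^2))
    gy <- exp(-((0:(h - 1)) - spots$y[i])^2 / (2 * sigma^2))
    k <- outer(gy, gx)
    img <- img + spots$flux[i] * k / sum(k)
  }
  img
}

# brute-force brightness-weighted centroid over all above-threshold pixels
bf_centroid <- function(frame, threshold) {
  idx <- which(frame > threshold)
  v <- frame[idx]
  y <- (idx - 1) %% nrow(frame)
  x <- (idx - 1) %/% nrow(frame)
  c(x = sum(v * x) / sum(v), y = sum(v * y) / sum(v))
}

# brute-force ROI sum of (pixel - bg) over in-frame pixels within radius
bf_roi_sum <- function(frame, cx, cy, r, bg = 0) {
  s <- 0
  for (px in 0:(ncol(frame) - 1)) for (py in 0:(nrow(frame) - 1))
    if ((px - cx)^2 + (py - cy)^2 <= r^2)
      s <- s + frame[py + 1, px + 1] - bg
  s
}

# exhaustive frame-to-frame minimum-total-displacement matching.
# prev: matrix of track positions (k x 2); det: data.frame(x, y).
# returns for each prev row the matched detection index (NA if > max_jump)
bf_match <- function(prev, det, max_jump) {
  k <- nrow(prev); m <- nrow(det)
  if (m == 0 || k == 0) return(rep(NA_integer_, k))
  best <- NULL; best_cost <- Inf
  # choose which tracks get matched and to which detections, exhaustively
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  subsets <- function(n, r) utils::combn(n, r, simplify = FALSE)
  for (r in seq(min(k, m), 0)) {
    for (ts in (if (r > 0) subsets(k, r) else list(integer(0)))) {
      for (ds in (if (r > 0) subsets(m, r) else list(integer(0)))) {
        for (p in (if (r > 0) perms(ds) else list(integer(0)))) {
          d <- if (r > 0) sqrt((prev[ts, 1] - det$x[p])^2 +
                               (prev[ts, 2] - det$y[p])^2) else numeric(0)
          if (any(d > max_jump)) next
          cost <- sum(d) + 1e6 * (k - r)    # unmatched penalized
          if (cost < best_cost) {
            best_cost <- cost
            a <- rep(NA_integer_, k); a[ts] <- p
            best <- a
          }
        }
      }
    }
  }
  best
}

# brute-force above-threshold run segmentation of a trace (no merging,
# sample-resolution boundaries)
bf_segments <- function(values, thr) {
  above <- values > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

# direct lagged Pearson correlation
bf_lag_cor <- function(a, b, k) {
  n_a <- length(a); n_b <- length(b)
  if (k >= 0) { ia <- seq_len(min(n_a, n_b - k)); ib <- ia + k }
  else { ib <- seq_len(min(n_b, n_a + k)); ia <- ib - k }
  stats::cor(a[ia], b[ib])
}

# brute-force box counting over a fixed point set
bf_box_count <- function(p, s, x0, y0, ex, ey) {
  ix <- floor(pmin((p[, 1] - x0) / s, ex / s - 1e-9)); ix[ix < 0] <- 0
  iy <- floor(pmin((p[, 2] - y0) / s, ey / s - 1e-9)); iy[iy < 0] <- 0
  nrow(unique(cbind(ix, iy)))
}

# a small flashing scene with automated tracking, through the pipeline
# stages, returning summaries and the scene truth
run_auto_metrics <- function(spec, max_jump = 15, max_gap = 30L,
                             radius = 6, min_length = 5L, ...) {
  scene <- make_scene(spec)
  det <- detect_all(scene$seq)
  trks <- link_tracks(det, max_jump = max_jump, max_gap = max_gap,
                      radius = radius, min_length = min_length)
  traces <- measure_all(scene$seq, trks)
  events <- lapply(traces, segment_flashes, ...)
  summaries <- lapply(seq_along(events), function(i)
    summarize_flashes(events[[i]], trks[[i]]$track_id))
  list(scene = scene, tracks = trks, traces = traces, events = events,
       summaries = summaries, truth = truth_summary(scene$truth))
}

# match each recovered track to its ground-truth individual by median
# distance; returns per-track fraction of frames within `tol` px
track_position_accuracy <- function(tracks, truth_positions, tol = 2) {
  vapply(tracks, function(tr) {
    tdf <- as.data.frame(tr)
    best <- -Inf
    for (ind in unique(truth_positions$individual)) {
      p <- truth_positions[truth_positions$individual == ind, ]
      m <- merge(tdf, p, by = "frame")
      if (nrow(m) == 0) next
      e <- sqrt((m$x.x - m$x.y)^2 + (m$y.x - m$y.y)^2)
      best <- max(best, mean(e <= tol))
    }
    best
  }, numeric(1))
}
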