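#' Cross-correlation synchrony between two intensity traces
#'
#' Pearson correlation of the two traces at every integer-frame lag in
#' `[-max_lag, +max_lag]`, each computed over the overlapping window after
#' mean removal and unit-variance normalisation (i.e. `stats::cor` of the
#' overlapping samples). Positive `best_lag` means `b` trails `a`: the
#' correlation at lag `k` pairs `a[t]` with `b[t + k]`. On ties the lag of
#' smallest magnitude (then the more negative) wins, so `corr_at_best_lag
#' >= corr_zero_lag` always holds.
#'
#' @param a,b `intensity_trace` objects sharing one frame rate.
#' @param max_lag largest lag examined, seconds.
#' @return an object of class `synchrony_result`: `track_pair`, `lags`
#'   (seconds), `correlogram`, `corr_zero_lag`, `best_lag`,
#'   `corr_at_best_lag`.
#' @export
cross_correlate <- function(a, b, max_lag = 2) {
  stopifnot(inherits(a, "intensity_trace"), inherits(b, "intensity_trace"))
  if (abs(a$frame_rate - b$frame_rate) > 1e-9)
    stop("traces must share one frame rate", call. = FALSE)
  fr <- a$frame_rate
  va <- a$values; vb <- b$values
  if (stats::var(va) == 0 || stats::var(vb) == 0)
    stop("correlation undefined for a zero-variance trace", call. = FALSE)
  L <- as.integer(round(max_lag * fr))
  lags <- (-L):L
  n_a <- length(va); n_b <- length(vb)
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      ia <- seq_len(min(n_a, n_b - k)); ib <- ia + k
    } else {
      ib <- seq_len(min(n_b, n_a + k)); ia <- ib - k
    }
    if (length(ia) < 3L)
      stop("fewer than 3 overlapping samples at lag ", k, call. = FALSE)
    if (stats::sd(va[ia]) == 0 || stats::sd(vb[ib]) == 0) return(NA_real_)
    stats::cor(va[ia], vb[ib])
  }, numeric(1))
  ord <- order(-cc, abs(lags), lags)
  best <- ord[1L]
  structure(
    list(track_pair = c(a$track_id, b$track_id), lags = lags / fr,
         correlogram = cc, corr_zero_lag = cc[lags == 0L],
         best_lag = lags[best] / fr, corr_at_best_lag = cc[best]),
    class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf(
    "synchrony %s ~ %s: r(0) = %.3f, best r = %.3f at lag %+.3f s\n",
    x$track_pair[1L], x$track_pair[2L], x$corr_zero_lag,
    x$corr_at_best_lag, x$best_lag))
  invisible(x)
}

#' Group synchrony index
#'
#' Pairwise [cross_correlate()] over all trace pairs plus the mean
#' pairwise zero-lag correlation as a single group synchrony index.
#'
#' @param traces list of >= 2 `intensity_trace` objects.
#' @param max_lag passed to [cross_correlate()].
#' @return list with `pairs` (list of `synchrony_result`) and
#'   `mean_corr_zero_lag`.
#' @export
synchrony_index <- function(traces, max_lag = 2) {
  stopifnot(length(traces) >= 2L)
  pairs <- list()
  for (i in seq_len(length(traces) - 1L))
    for (j in (i + 1L):length(traces))
      pairs[[length(pairs) + 1L]] <-
        cross_correlate(traces[[i]], traces[[j]], max_lag = max_lag)
  list(pairs = pairs,
       mean_corr_zero_lag =
         mean(vapply(pairs, `[[`, 0, "corr_zero_lag")))
}

#' One-sided periodogram of a flash train
#'
#' Discrete Fourier periodogram of the mean-removed trace. The `power`
#' column is per-bin and one-sided (interior bins doubled), normalised so
#' that `sum(power)` equals the mean square of the mean-removed trace —
#' Parseval's identity holds by construction. The spectral density per Hz
#' is `power / df` with `df = frame_rate / n`.
#'
#' @param trace an `intensity_trace` of length >= 8, or numeric vector
#'   with `frame_rate`.
#' @param taper `"none"` (default) or `"hann"`.
#' @param frame_rate used for a bare numeric trace.
#' @return object of class `spectrum_result`: `frequencies` (Hz, 0 to the
#'   Nyquist frequency), `power`, `density`, `df`.
#' @export
power_spectrum <- function(trace, taper = c("none", "hann"),
                           frame_rate = NULL) {
  taper <- match.arg(taper)
  if (inherits(trace, "intensity_trace")) {
    v <- trace$values; fr <- trace$frame_rate
  } else {
    if (is.null(frame_rate))
      stop("`frame_rate` required for a bare numeric trace", call. = FALSE)
    v <- as.numeric(trace); fr <- frame_rate
  }
  n <- length(v)
  if (n < 8L) stop("trace must have >= 8 samples", call. = FALSE)
  x <- v - mean(v)
  if (taper == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
    x <- x * w / sqrt(mean(w^2))     # preserve total power
  }
  X <- stats::fft(x)
  p2 <- Mod(X)^2 / n^2               # two-sided, sums to mean(x^2)
  half <- n %/% 2L + 1L
  p1 <- p2[seq_len(half)]
  if (n %% 2L == 0L) {
    if (half > 2L) p1[2:(half - 1L)] <- 2 * p1[2:(half - 1L)]
  } else if (half > 1L) p1[2:half] <- 2 * p1[2:half]
  freqs <- (seq_len(half) - 1L) * fr / n
  structure(list(frequencies = freqs, power = p1,
                 density = p1 / (fr / n), df = fr / n),
            class = "spectrum_result")
}

#' @export
print.spectrum_result <- function(x, ...) {
  i <- which.max(x$power)
  cat(sprintf(
    "spectrum_result: %d bins, df = %.5g Hz, dominant %.5g Hz\n",
    length(x$frequencies), x$df, x$frequencies[i]))
  invisible(x)
}

#' Box-counting fractal dimension of a flight path
#'
#' The path is densified by linear interpolation between consecutive
#' centers (at most `step` px between samples) so that sparse sampling
#' cannot starve small boxes, then covered by square boxes on a grid
#' anchored at the path's bounding-box corner. Box sizes form a dyadic
#' ladder from the bounding box's larger side down `n_scales` halvings
#' (never below `min_box` px). The dimension is the least-squares slope of
#' `log(count)` versus `log(1/size)`; a straight line has dimension 1, a
#' plane-filling path 2.
#'
#' @param path a `track`, or a two-column matrix/data frame of `(x, y)`
#'   coordinates with at least two distinct positions.
#' @param n_scales number of halvings of the box size, default 6.
#' @param min_box smallest box size considered, pixels.
#' @param step densification spacing, pixels.
#' @return object of class `path_metrics`: `box_sizes` (descending),
#'   `box_counts`, `dimension`, `fit_r2`.
#' @export
fractal_dimension <- function(path, n_scales = 6L, min_box = 2, step = 0.5) {
  if (inherits(path, "track")) xy <- cbind(path$x, path$y)
  else xy <- as.matrix(path)[, 1:2, drop = FALSE]
  xy <- xy[stats::complete.cases(xy), , drop = FALSE]
  if (nrow(xy) < 2L || nrow(unique(xy)) < 2L)
    stop("path needs >= 2 distinct positions", call. = FALSE)

  # densify segments longer than `step`
  dx <- diff(xy[, 1L]); dy <- diff(xy[, 2L])
  seglen <- sqrt(dx^2 + dy^2)
  pts <- lapply(seq_along(seglen), function(i) {
    m <- max(1L, ceiling(seglen[i] / step))
    f <- seq(0, 1, length.out = m + 1L)[-(m + 1L)]
    cbind(xy[i, 1L] + f * dx[i], xy[i, 2L] + f * dy[i])
  })
  p <- rbind(do.call(rbind, pts), xy[nrow(xy), , drop = FALSE])

  x0 <- min(p[, 1L]); y0 <- min(p[, 2L])
  ex <- max(p[, 1L]) - x0; ey <- max(p[, 2L]) - y0
  s0 <- max(ex, ey)
  if (s0 <= 0) stop("degenerate path extent", call. = FALSE)
  sizes <- s0 / 2^(0:n_scales)
  sizes <- sizes[sizes >= min_box]
  if (length(sizes) < 2L) sizes <- s0 / 2^(0:1)
  counts <- vapply(sizes, function(s) {
    ix <- floor(pmin((p[, 1L] - x0) / s, ex / s - 1e-9))
    iy <- floor(pmin((p[, 2L] - y0) / s, ey / s - 1e-9))
    ix[ix < 0] <- 0; iy[iy < 0] <- 0
    length(unique(ix * 2^26 + iy))
  }, numeric(1))
  fit <- stats::lm(log(counts) ~ log(1 / sizes))
  lc <- log(counts)
  ss_tot <- sum((lc - mean(lc))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(box_sizes = sizes, box_counts = counts,
         dimension = unname(stats::coef(fit)[2L]), fit_r2 = r2),
    class = "path_metrics")
}

#' @export
print.path_metrics <- function(x, ...) {
  cat(sprintf(
    "path_metrics: D = %.3f (r^2 = %.4f) over %d scales (%.3g-%.3g px)\n",
    x$dimension, x$fit_r2, length(x$box_sizes),
    min(x$box_sizes), max(x$box_sizes)))
  invisible(x)
}

#' Binarized flash train of a trace
#'
#' 0/1 indicator of flash activity: 1 inside every [segment_flashes()]
#' event window, 0 elsewhere. An alternative input to [cross_correlate()]
#' when raw-amplitude correlation is not wanted.
#'
#' @param trace an `intensity_trace`.
#' @param ... passed to [segment_flashes()].
#' @return an `intensity_trace` of 0/1 values on the same clock.
#' @export
binarize_trace <- function(trace, ...) {
  ev <- segment_flashes(trace, ...)
  v <- numeric(length(trace$values))
  for (e in ev) v[trace$times >= e$onset & trace$times <= e$offset] <- 1
  out <- trace
  out$values <- v
  out
}
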