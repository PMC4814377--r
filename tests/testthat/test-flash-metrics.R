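test_that("peak detection: constant, triangle, pulse train, prominence", {
  fr <- 10
  expect_equal(nrow(detect_peaks(rep(5, 30), frame_rate = fr)), 0L)
  expect_error(detect_peaks(c(1, 2), frame_rate = fr), ">= 3")

  # triangular pulse peaking at exactly t = 2.0 s
  t <- (0:60) / fr
  tri <- pmax(0, 1 - abs(t - 2))
  pk <- detect_peaks(tri, frame_rate = fr)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$time, 2.0)

  # 4-peak train at 0, 1.9, 3.8, 5.7 s (30 fps)
  fr <- 30
  tt <- (0:210) / fr
  v <- rowSums(vapply(c(0.25, 2.15, 4.05, 5.95), function(c0)
    pmax(0, 1 - (abs(tt - c0) / 0.3)^2), numeric(length(tt))))
  pk <- detect_peaks(v, frame_rate = fr)
  expect_equal(nrow(pk), 4L)
  expect_true(all(abs(pk$time - c(0.25, 2.15, 4.05, 5.95)) <= 0.5 / fr))
  # independent cross-check: pracma finds the same peaks (its plateau
  # convention reports the first sample of a tie, ours the center)
  pp <- pracma::findpeaks(v, minpeakheight = 0.5, zero = "+")
  expect_equal(nrow(pp), 4L)
  expect_true(all(abs(sort(pp[, 2]) - pk$index) <= 1))

  # prominence agrees with a direct computation for every local max
  set.seed(3)
  x <- stats::filter(stats::rnorm(200), rep(1 / 5, 5), sides = 2)
  x <- as.numeric(x[!is.na(x)])
  pk <- detect_peaks(x, min_prominence_frac = 0, frame_rate = 1)
  direct_prom <- function(i) {
    lmin <- x[i]; j <- i
    while (j >= 1 && x[j] <= x[i]) { lmin <- min(lmin, x[j]); j <- j - 1 }
    rmin <- x[i]; j <- i
    while (j <= length(x) && x[j] <= x[i]) {
      rmin <- min(rmin, x[j]); j <- j + 1
    }
    x[i] - max(lmin, rmin)
  }
  for (r in seq_len(nrow(pk))) {
    i <- pk$index[r]
    if (i == round(i))   # skip plateau centers
      expect_equal(pk$prominence[r], direct_prom(i))
  }
})

test_that("plateau maxima report their center time", {
  v <- c(0, 0, 5, 5, 5, 0, 0)
  pk <- detect_peaks(v, frame_rate = 1)
  expect_equal(pk$time, 3)      # samples 3..5 (1-based), center index 4
})

test_that("flash segmentation: boundaries, merging, sub-pulse counting", {
  fr <- 50
  t <- (0:249) / fr
  # rectangular pulse on [1.0, 2.0)
  v <- as.numeric(t >= 1 & t < 2) * 100
  ev <- segment_flashes(intensity_trace(v, fr))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$duration, 1.0, tolerance = 1 / fr)
  expect_length(ev[[1]]$peak_times, 1L)

  # two rectangular sub-pulses with a 0.14 s dark gap
  v2 <- as.numeric((t >= 1 & t < 1.3) | (t >= 1.44 & t < 1.74)) * 100
  tr2 <- intensity_trace(v2, fr)
  one <- segment_flashes(tr2, merge_gap = 0.3)
  expect_length(one, 1L)
  expect_length(one[[1]]$peak_times, 2L)
  expect_equal(diff(one[[1]]$peak_times), 0.44, tolerance = 1 / fr)
  two <- segment_flashes(tr2, merge_gap = 0.05)
  expect_length(two, 2L)

  # merge_gap = 0 equals plain above-threshold segmentation
  set.seed(9)
  v3 <- rep(0, 300)
  for (s in c(30, 120, 200)) v3[s:(s + 20)] <- 80 + stats::rnorm(21, 0, 2)
  tr3 <- intensity_trace(v3, fr)
  ev3 <- segment_flashes(tr3, merge_gap = 0)
  base <- stats::quantile(v3, 0.1, names = FALSE)
  oracle <- bf_segments(v3, base + 0.1 * (max(v3) - base))
  expect_equal(length(ev3), nrow(oracle))
  for (k in seq_along(ev3)) {
    expect_lt(abs(ev3[[k]]$onset - (oracle[k, "start"] - 1) / fr),
              1.5 / fr)
    expect_lt(abs(ev3[[k]]$offset - (oracle[k, "end"] - 1) / fr),
              1.5 / fr)
  }

  # sub-threshold trace: no events, not an error
  expect_length(segment_flashes(intensity_trace(rep(1, 60), fr)), 0L)
  expect_error(segment_flashes(tr2, onset_frac = 1.2), "onset_frac")
})

test_that("summary arithmetic over constructed events", {
  mk <- function(onset, peaks, duration = 1.3)
    structure(list(onset = onset, offset = onset + duration,
                   duration = duration, peak_times = peaks,
                   peak_values = rep(1, length(peaks))),
              class = "flash_event")
  # four single-peak flashes, peaks 1.9 s apart, each 1.3 s long
  ev <- lapply(0:3, function(k) mk(1.9 * k - 0.65, 1.9 * k))
  s <- summarize_flashes(ev)
  expect_equal(s$n_flashes, 4L)
  expect_equal(s$mean_duration, 1.3)
  expect_equal(s$mean_peak_interval, 1.9)
  expect_equal(s$mean_interflash_interval, 1.9 - 1.3)
  expect_true(is.na(s$mean_subpulse_interval))

  s0 <- summarize_flashes(list())
  expect_equal(s0$n_flashes, 0L)
  expect_true(is.na(s0$mean_duration))
  expect_true(is.na(s0$mean_peak_interval))

  ev2 <- list(mk(0, c(0.2, 0.34), 0.566), mk(1.19, c(1.39, 1.53), 0.566))
  s2 <- summarize_flashes(ev2)
  expect_equal(s2$mean_subpulse_interval, 0.14)
  expect_equal(s2$pulses_per_flash, c(2L, 2L))
})

test_that("time metrics are shift-equivariant and scale-invariant", {
  fr <- 30
  spec <- scene_spec(1L, duration = 10, frame_rate = fr,
                     flash = list(envelope = "raised_cosine",
                                  flash_duration = 0.8, period = 1.6,
                                  amplitude = 500, phase = 0.3),
                     noise_sd = 0, seed = 2L)
  flux <- make_scene(spec)$truth$flux[, 1]
  base <- segment_flashes(intensity_trace(flux, fr))

  shifted <- segment_flashes(intensity_trace(flux, fr, t0 = 4.25))
  expect_equal(vapply(shifted, `[[`, 0, "onset"),
               vapply(base, `[[`, 0, "onset") + 4.25)
  expect_equal(vapply(shifted, `[[`, 0, "duration"),
               vapply(base, `[[`, 0, "duration"))

  scaled <- segment_flashes(intensity_trace(flux * 7.5, fr))
  expect_equal(vapply(scaled, `[[`, 0, "onset"),
               vapply(base, `[[`, 0, "onset"))
  expect_equal(vapply(scaled, `[[`, 0, "duration"),
               vapply(base, `[[`, 0, "duration"))
  expect_equal(lapply(scaled, `[[`, "peak_times"),
               lapply(base, `[[`, "peak_times"))
})

test_that("ground-truth metrics are recovered over >= 20 flashes", {
  fr <- 30
  for (env in c("rect", "raised_cosine")) {
    spec <- scene_spec(1L, duration = 45, frame_rate = fr,
                       flash = list(envelope = env, flash_duration = 0.9,
                                    period = 2.1, amplitude = 700,
                                    phase = 0.37),
                       noise_sd = 0, seed = 6L)
    flux <- make_scene(spec)$truth$flux[, 1]
    ev <- segment_flashes(intensity_trace(flux, fr))
    s <- summarize_flashes(ev)
    expect_gte(s$n_flashes, 20L)
    expect_lt(abs(s$mean_duration - 0.9), 1 / fr)
    expect_lt(abs(s$mean_peak_interval - 2.1), 1 / fr)
  }
  # sub-pulse spacing (bimodal raised-cosine male-type flash)
  spec <- scene_spec(1L, duration = 30, frame_rate = fr,
                     flash = list(envelope = "raised_cosine",
                                  flash_duration = 0.566, period = 1.19,
                                  n_subpulses = 2L,
                                  subpulse_interval = 0.14,
                                  amplitude = 700, phase = 0.2),
                     noise_sd = 0, seed = 6L)
  flux <- make_scene(spec)$truth$flux[, 1]
  s <- summarize_flashes(segment_flashes(intensity_trace(flux, fr)))
  expect_gte(s$n_flashes, 20L)
  expect_lt(abs(s$mean_subpulse_interval - 0.14), 1 / fr)
})

test_that("event and summary tables round-trip through CSV exactly", {
  fr <- 25
  v <- rep(0, 100); v[20:30] <- 50; v[60:72] <- 80
  ev <- segment_flashes(intensity_trace(v, fr))
  df <- events_to_df(ev, "t1")
  p <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df, p)
  back <- as.data.frame(readr::read_csv(p, show_col_types = FALSE))
  expect_equal(back$onset_s, df$onset_s)
  expect_equal(back$duration_s, df$duration_s)
  pt <- as.numeric(strsplit(as.character(back$peak_times_s[1]), ";")[[1]])
  expect_identical(pt, ev[[1]]$peak_times)
})
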