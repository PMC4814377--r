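test_that("intensity quantization follows the declared binning rules", {
  expect_equal(quantize_intensity(seq(0, 70, by = 10), 7),
               c(1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L))
  v <- c(0, 35, 70)
  q <- quantize_intensity(v, 7)
  expect_equal(q[1], 1L)                 # min -> 1
  expect_equal(q[3], 7L)                 # max -> n_steps
  expect_equal(quantize_intensity(rep(3, 5), 7), rep(1L, 5))
  expect_error(quantize_intensity(numeric(0)), "empty")
  expect_error(quantize_intensity(1:5, 1), ">= 2")

  # monotone: v1 <= v2 => step(v1) <= step(v2)
  set.seed(1)
  v <- stats::runif(200, -5, 12)
  q <- quantize_intensity(v, 7)
  o <- order(v)
  expect_true(all(diff(q[o]) >= 0))

  # quantile binning also covers 1..n and stays monotone
  q2 <- quantize_intensity(v, 5, method = "quantile")
  expect_equal(range(q2), c(1L, 5L))
  expect_true(all(diff(q2[o]) >= 0))
})

test_that("path rendering places stepped circles on the orbit line", {
  # two-point track, constant trace: a segment and two step-1 circles
  tk <- track("a", 0:1, c(10, 40), c(20, 20), radius = 3)
  tr <- intensity_trace(c(5, 5), 30)
  img <- render_path(tk, tr, canvas = c(64, 48))
  expect_equal(dim(img), c(48L, 64L))
  expect_true(any(img == 0.1))                # orbit line present
  expect_equal(max(img), 1 / 7)               # only minimum-step circles
  expect_gt(sum(img == 1 / 7), 2 * 10)        # two filled disks

  # straight path with one flash mid-way: largest circle at the flash
  n <- 21
  tk2 <- track("b", 0:(n - 1), seq(10, 90, length.out = n), rep(30, n),
               radius = 3)
  v <- rep(2, n); v[11] <- 100
  img2 <- render_path(tk2, intensity_trace(v, 30), canvas = c(100, 60))
  hot <- which(img2 == max(img2), arr.ind = TRUE)
  cx <- mean(hot[, 2] - 1); cy <- mean(hot[, 1] - 1)
  expect_lt(abs(cx - tk2$x[11]), 1)
  expect_lt(abs(cy - tk2$y[11]), 1)
  expect_equal(max(img2), 1)                  # step 7 of 7

  expect_error(render_path(tk, intensity_trace(c(1, 2, 3), 30),
                           canvas = c(64, 48)), "lengths differ")
})

test_that("timecourse figure colors series in the conventional order", {
  traces <- lapply(1:5, function(i)
    intensity_trace(stats::runif(50), 25, track_id = paste0("t", i)))
  p <- render_timecourse(traces, cursor_frame = 0)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  line_cols <- unique(built$data[[1]]$colour)
  expect_length(line_cols, 5L)
  expect_setequal(line_cols, c("red", "brown", "green", "purple", "blue"))
  # red cursor line at t0
  vline <- built$data[[2]]
  expect_equal(vline$xintercept[1], traces[[1]]$times[1])
  expect_error(render_timecourse(list()), "no traces")
})

test_that("overlay video preserves geometry, rate and frame count", {
  set.seed(2)
  frames <- lapply(1:10, function(i) matrix(sample(0:40, 48 * 48, TRUE),
                                            48, 48))
  s <- frame_sequence(frames, 15)
  tk <- track("a", c(0:3, 5:9), seq(10, 40, length.out = 9),
              rep(24, 9), radius = 4)    # frame 4 is a gap
  out <- withr::local_tempfile(fileext = ".avi")
  write_overlay_video(s, list(tk), out, timer = TRUE)
  r <- read_video(out)
  expect_equal(n_frames(r), 10L)
  expect_equal(dim(r$frames[[1]]), c(48L, 48L))
  expect_equal(r$frame_rate, 15)
  # overlay pixels burned at the maximum value
  expect_true(any(r$frames[[6]] == 255))

  # zero tracks: pure re-encode is pixel-identical for 8-bit input
  out2 <- withr::local_tempfile(fileext = ".avi")
  write_overlay_video(s, list(), out2)
  r2 <- read_video(out2)
  for (i in 1:10) expect_equal(r2$frames[[i]], frames[[i]])

  expect_error(write_overlay_video(s, list(track("x", 12, 1, 1))),
               "outside")
})

test_that("export bundle writes every artifact with correct counts", {
  spec <- scene_spec(2L, duration = 100 / 20, frame_rate = 20,
                     frame_size = c(64L, 64L),
                     trajectory = list(model = "stationary",
                                       positions = rbind(c(20, 32),
                                                         c(44, 32))),
                     flash = list(envelope = "rect", flash_duration = 0.5,
                                  period = 1, amplitude = 500),
                     seed = 3L)
  scene <- make_scene(spec)
  pos <- scene$truth$positions
  tks <- lapply(1:2, function(i) {
    p <- pos[pos$individual == i, ]
    track(i, p$frame, p$x, p$y, radius = 5)
  })
  trs <- measure_all(scene$seq, tks)
  evs <- lapply(trs, segment_flashes)
  sms <- lapply(seq_along(evs), function(i) summarize_flashes(evs[[i]], i))
  dir <- withr::local_tempdir()
  man <- export_bundle(dir, tks, trs, evs, sms, seq = scene$seq)

  expect_equal(man$traces_csv$count, 200L)   # 2 tracks x 100 frames
  expect_true(file.exists(file.path(dir, "manifest.json")))
  for (entry in man)
    expect_true(file.exists(file.path(dir, entry$file)))
  # stated row counts match the files
  tcsv <- readr::read_csv(file.path(dir, "traces.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(tcsv), man$traces_csv$count)
  # CSV round trip is value-exact
  expect_identical(tcsv$intensity, unlist(lapply(trs, `[[`, "values"),
                                          use.names = FALSE))
  expect_identical(tcsv$x, unlist(lapply(tks, `[[`, "x"),
                                  use.names = FALSE))

  # empty event list: header-only CSV
  dir2 <- withr::local_tempdir()
  man2 <- export_bundle(dir2, tks[1], trs[1], list(list()),
                        sms[1], figures = FALSE)
  expect_equal(man2$events_csv$count, 0L)
  expect_equal(length(readLines(file.path(dir2, "events.csv"))), 1L)
})
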