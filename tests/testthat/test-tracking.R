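test_that("manual trace CSV import handles gaps and bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("frame,x,y\n0,10,10\n1,12,11\n2,14,12", path)
  tk <- load_manual_track(path, radius = 5)
  expect_s3_class(tk, "track")
  expect_equal(length(tk$frames), 3L)
  expect_false(any(tk$is_gap))
  expect_equal(tk$radius, 5)

  writeLines("frame,x,y\n0,10,10\n2,14,12", path)
  tk <- load_manual_track(path, radius = 5)
  expect_equal(tk$frames, 0:2)
  expect_equal(tk$is_gap, c(FALSE, TRUE, FALSE))
  expect_equal(tk$x[2], 12)       # linear interpolation across the gap

  writeLines("frame,x,y\n1,12,11\n0,10,10", path)
  expect_error(load_manual_track(path), "strictly increasing")
  writeLines("frame,x\n0,10", path)
  expect_error(load_manual_track(path), "columns frame,x,y")
})

test_that("multi-individual trace CSVs split by track_id", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("frame,x,y,track_id\n0,1,1,a\n1,2,2,a\n0,9,9,b\n1,8,8,b",
             path)
  tks <- load_manual_track(path, radius = 3)
  expect_length(tks, 2L)
  expect_equal(vapply(tks, `[[`, "", "track_id"), c("a", "b"))
})

test_that("detect_spots matches a brute-force weighted centroid", {
  blank <- matrix(0, 48, 48)
  expect_equal(nrow(detect_spots(blank, threshold = 10)), 0L)

  f1 <- gaussian_frame(48, 48, data.frame(x = 20, y = 30, flux = 2000),
                       sigma = 1.5)
  d <- detect_spots(f1, threshold = 5)
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$x - 20), 0.5)
  expect_lt(abs(d$y - 30), 0.5)
  oracle <- bf_centroid(f1, 5)
  expect_equal(d$x, unname(oracle["x"]), tolerance = 1e-12)
  expect_equal(d$y, unname(oracle["y"]), tolerance = 1e-12)

  f2 <- gaussian_frame(64, 64, data.frame(x = c(15, 35), y = c(20, 20),
                                          flux = c(2000, 1500)))
  d2 <- detect_spots(f2, threshold = 5)
  expect_equal(nrow(d2), 2L)
  # sorted by descending total brightness
  expect_gt(d2$total_brightness[1], d2$total_brightness[2])
  expect_lt(abs(d2$x[1] - 15), 0.5)
})

test_that("min_area filters small components", {
  f <- matrix(0, 10, 10)
  f[5, 5] <- 100                       # single-pixel speck
  f[2:3, 2:3] <- 100                   # 4-pixel blob
  d <- detect_spots(f, threshold = 50, min_area = 2)
  expect_equal(nrow(d), 1L)
  expect_equal(d$area, 4L)
})

test_that("link_tracks follows, splits and stays deterministic", {
  # two stationary spots over 5 frames
  det <- replicate(5, data.frame(x = c(10, 40), y = c(10, 40),
                                 total_brightness = c(2, 1), area = 5L),
                   simplify = FALSE)
  tks <- link_tracks(det, max_jump = 5)
  expect_length(tks, 2L)
  expect_equal(vapply(tks, function(t) length(t$frames), 0L), c(5L, 5L))

  # one spot moving 2 px/frame
  det <- lapply(0:5, function(i)
    data.frame(x = 10 + 2 * i, y = 10, total_brightness = 1, area = 4L))
  tks <- link_tracks(det, max_jump = 5)
  expect_length(tks, 1L)
  expect_equal(tks[[1]]$x, 10 + 2 * (0:5))

  # teleport beyond max_jump closes the track and starts a new one
  det <- lapply(0:5, function(i) {
    x <- if (i < 3) 10 + i else 60 + i
    data.frame(x = x, y = 10, total_brightness = 1, area = 4L)
  })
  tks <- link_tracks(det, max_jump = 5, max_gap = 1)
  expect_length(tks, 2L)
  expect_equal(tks[[1]]$frames, 0:2)
  expect_equal(tks[[2]]$frames, 3:5)

  # determinism: identical input, identical output
  expect_identical(link_tracks(det, max_jump = 5, max_gap = 1), tks)
})

test_that("greedy linking agrees with exhaustive matching on small scenes", {
  set.seed(11)
  for (rep in 1:8) {
    k <- sample(1:3, 1)
    nf <- sample(4:10, 1)
    # well-separated starts, small per-frame steps (< max_jump / 2)
    start <- cbind(x = sample(seq(10, 90, by = 25), k),
                   y = sample(seq(10, 90, by = 25), k))
    steps_x <- matrix(stats::runif(k * nf, -1.5, 1.5), nf, k)
    steps_y <- matrix(stats::runif(k * nf, -1.5, 1.5), nf, k)
    X <- sweep(apply(steps_x, 2, cumsum), 2, start[, 1], `+`)
    Y <- sweep(apply(steps_y, 2, cumsum), 2, start[, 2], `+`)
    det <- lapply(seq_len(nf), function(f)
      data.frame(x = X[f, ], y = Y[f, ],
                 total_brightness = rev(seq_len(k)), area = 5L))
    tks <- link_tracks(det, max_jump = 5)
    expect_length(tks, k)
    # oracle: exhaustive min-total-displacement matching frame by frame
    prev <- cbind(X[1, ], Y[1, ])
    paths <- lapply(seq_len(k), function(i) prev[i, , drop = FALSE])
    for (f in 2:nf) {
      a <- bf_match(prev, det[[f]], max_jump = 5)
      for (i in seq_len(k)) if (!is.na(a[i])) {
        prev[i, ] <- c(det[[f]]$x[a[i]], det[[f]]$y[a[i]])
        paths[[i]] <- rbind(paths[[i]], prev[i, ])
      }
    }
    got <- lapply(tks, function(t) cbind(t$x, t$y))
    # same set of paths regardless of ordering
    for (p in paths) {
      hit <- any(vapply(got, function(g)
        nrow(g) == nrow(p) && max(abs(g - p)) < 1e-9, logical(1)))
      expect_true(hit)
    }
  }
})

test_that("simulated non-crossing trajectories are recovered within 2 px", {
  spec <- scene_spec(
    n_individuals = 5L, duration = 4, frame_rate = 30,
    frame_size = c(160L, 160L),
    trajectory = list(model = "weave", speed = 12, weave_amp = 6,
                      weave_period = 4, margin = 10),
    flash = list(envelope = "rect", flash_duration = 1, period = 1,
                 amplitude = 800),     # always on: pure tracking test
    noise_sd = 1.5, seed = 21L)
  scene <- make_scene(spec)
  det <- detect_all(scene$seq)
  tks <- link_tracks(det, max_jump = 6, max_gap = 2, min_length = 10)
  expect_length(tks, 5L)
  acc <- track_position_accuracy(tks, scene$truth$positions, tol = 2)
  expect_true(all(acc >= 0.95))
})

test_that("coinciding track centers trigger the superposition warning", {
  det <- replicate(4, data.frame(x = c(10, 12), y = c(10, 10),
                                 total_brightness = c(2, 1), area = 4L),
                   simplify = FALSE)
  expect_warning(link_tracks(det, max_jump = 5, radius = 5),
                 "not separable")
})
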