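#' Construct a frame sequence
#'
#' A `frame_sequence` is the raw observable of the pipeline: an ordered list
#' of single-channel intensity rasters sharing one shape, sampled at a
#' constant frame rate. Pixel values are in arbitrary sensor units (ADU).
#'
#' Coordinate convention, used everywhere in the package: pixel indices are
#' 0-based, origin at the top-left corner, x increases rightward (matrix
#' columns), y increases downward (matrix rows), and pixel centers sit at
#' integer coordinates. Pixel `(x, y)` is matrix element `[y + 1, x + 1]`.
#'
#' @param frames list of numeric matrices, all with identical dimensions.
#' @param frame_rate frames per second (> 0).
#' @param t0 time of the first frame, seconds. Default 0.
#' @param bits nominal sensor bit depth (8 or 16); sets the representable
#'   range `[0, 2^bits - 1]` used by display adjustment and file export.
#' @return an object of class `frame_sequence` with fields `frames`,
#'   `frame_rate`, `t0`, `bits`.
#' @seealso [read_video()], [trim()], [export_frames()]
#' @export
frame_sequence <- function(frames, frame_rate, t0 = 0, bits = 8L) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop("every frame must be a matrix", call. = FALSE)
  d <- dim(frames[[1L]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same))
    stop("all frames must share one height x width", call. = FALSE)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("`frame_rate` must be a single positive number", call. = FALSE)
  if (!bits %in% c(8L, 16L))
    stop("`bits` must be 8 or 16", call. = FALSE)
  structure(
    list(frames = frames, frame_rate = as.numeric(frame_rate),
         t0 = as.numeric(t0), bits = as.integer(bits)),
    class = "frame_sequence")
}

#' Number of frames in a sequence
#' @param seq a `frame_sequence`.
#' @return integer frame count.
#' @export
n_frames <- function(seq) length(seq$frames)

#' Frame timestamps
#'
#' Timestamps are derived from the constant frame rate, not per-frame
#' container metadata: time of frame `i` (0-based) is `t0 + i / frame_rate`.
#'
#' @param seq a `frame_sequence`.
#' @return numeric vector of times in seconds, strictly increasing.
#' @export
frame_times <- function(seq) {
  seq$t0 + (seq_len(n_frames(seq)) - 1L) / seq$frame_rate
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf(
    "frame_sequence: %d frames of %d x %d px, %.6g fps, t0 = %.6g s, %d-bit\n",
    n_frames(x), d[2L], d[1L], x$frame_rate, x$t0, x$bits))
  invisible(x)
}

#' Trim a sequence to a scene
#'
#' Selects the half-open frame interval `[start_frame, end_frame)` (0-based)
#' and advances `t0` accordingly, so trimmed timestamps agree with the
#' original clock.
#'
#' @param seq a `frame_sequence`.
#' @param start_frame first frame kept, 0-based.
#' @param end_frame one past the last frame kept; must exceed `start_frame`.
#' @return a `frame_sequence` with `end_frame - start_frame` frames.
#' @export
trim <- function(seq, start_frame, end_frame) {
  stopifnot(inherits(seq, "frame_sequence"))
  n <- n_frames(seq)
  if (start_frame < 0 || end_frame > n || start_frame >= end_frame)
    stop(sprintf("invalid trim bounds [%s, %s) for %d frames",
                 start_frame, end_frame, n), call. = FALSE)
  frame_sequence(seq$frames[(start_frame + 1L):end_frame], seq$frame_rate,
                 t0 = seq$t0 + start_frame / seq$frame_rate, bits = seq$bits)
}

#' Display adjustment (brightness / contrast)
#'
#' A non-destructive linear remap used only for rendering; photometry always
#' reads the unadjusted frames. The identity adjustment is gain 1, offset 0.
#'
#' @param gain unitless multiplier (contrast).
#' @param offset additive term in sensor units (brightness).
#' @return an object of class `display_adjustment`.
#' @export
display_adjustment <- function(gain = 1, offset = 0) {
  stopifnot(is.numeric(gain), is.numeric(offset))
  structure(list(gain = gain, offset = offset), class = "display_adjustment")
}

#' Apply a display adjustment to one frame
#'
#' Computes `clip(gain * value + offset)` to the raster's representable
#' range. The input frame is never modified.
#'
#' @param frame numeric matrix.
#' @param adj a [display_adjustment()].
#' @param max_value top of the representable range; default `2^bits - 1`
#'   for `bits = 8`.
#' @param bits convenience alternative to `max_value`.
#' @return adjusted matrix, same dimensions.
#' @export
adjust_display <- function(frame, adj = display_adjustment(),
                           bits = 8L, max_value = 2^bits - 1) {
  stopifnot(is.matrix(frame), inherits(adj, "display_adjustment"))
  out <- adj$gain * frame + adj$offset
  out[out < 0] <- 0
  out[out > max_value] <- max_value
  out
}

# Rec. 601 luminance; exact pass-through when the three channels are equal
# so grayscale video round-trips without fp drift.
.luminance <- function(r, g, b) {
  y <- 0.299 * r + 0.587 * g + 0.114 * b
  eq <- (r == g) & (g == b)
  y[eq] <- r[eq]
  y
}

# 3-d array (h x w x 3, any scale) -> luminance matrix
.rgb_to_luma <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  if (dim(arr)[3L] >= 3L)
    return(.luminance(arr[, , 1L], arr[, , 2L], arr[, , 3L]))
  arr[, , 1L]
}

#' Read video into a frame sequence
#'
#' Accepts either an uncompressed AVI file or a frame-stack directory of
#' numbered TIFF/PNG images (the two interchangeable input dialects). Color
#' input is converted to luminance with Rec. 601 weights at load; frames of
#' a stack are ordered by file name.
#'
#' @param path AVI file or directory of numbered `.tif`/`.tiff`/`.png`
#'   frames.
#' @param frame_rate frames per second. Required for frame stacks; for AVI
#'   it overrides the container metadata when given.
#' @param bits nominal bit depth for frame stacks (AVI carries its own).
#' @return a `frame_sequence`.
#' @export
read_video <- function(path, frame_rate = NULL, bits = 8L) {
  if (!file.exists(path))
    stop("input does not exist: ", path, call. = FALSE)
  if (dir.exists(path))
    return(read_frame_stack(path, frame_rate = frame_rate, bits = bits))
  avi <- read_avi(path)
  fr <- if (is.null(frame_rate)) avi$frame_rate else frame_rate
  frame_sequence(avi$frames, frame_rate = fr, bits = avi$bits)
}

#' @rdname read_video
#' @export
read_frame_stack <- function(path, frame_rate = NULL, bits = 8L) {
  if (is.null(frame_rate))
    stop("`frame_rate` must be given for a frame-stack directory",
         call. = FALSE)
  files <- list.files(path, pattern = "\\.(tif|tiff|png)$",
                      ignore.case = TRUE, full.names = TRUE)
  if (length(files) == 0L)
    stop("no TIFF/PNG frames found in ", path, call. = FALSE)
  files <- files[order(basename(files))]
  scale <- 2^bits - 1
  frames <- lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE))
      png::readPNG(f) else tiff::readTIFF(f)
    round(.rgb_to_luma(img) * scale)
  })
  frame_sequence(frames, frame_rate = frame_rate, bits = bits)
}

#' Export each frame as a TIFF file
#'
#' Writes one uncompressed TIFF per frame, named `frame_000000.tif`,
#' `frame_000001.tif`, ... Re-reading the directory with [read_video()]
#' yields pixel-identical frames.
#'
#' @param seq a `frame_sequence`; pixel values must lie in the sequence's
#'   representable range.
#' @param out_dir output directory (created if missing).
#' @return character vector of written file paths, in frame order.
#' @export
export_frames <- function(seq, out_dir) {
  stopifnot(inherits(seq, "frame_sequence"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  scale <- 2^seq$bits - 1
  paths <- character(n_frames(seq))
  for (i in seq_len(n_frames(seq))) {
    p <- file.path(out_dir, sprintf("frame_%06d.tif", i - 1L))
    ok <- try(tiff::writeTIFF(pmin(pmax(seq$frames[[i]], 0), scale) / scale,
                              p, bits.per.sample = seq$bits,
                              compression = "none"), silent = TRUE)
    if (inherits(ok, "try-error") || !file.exists(p))
      stop("failed to write frame: ", p, call. = FALSE)
    paths[i] <- p
  }
  paths
}
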