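#' Minimal uncompressed AVI reader and writer
#'
#' The package speaks the plainest dialect of the AVI container: a RIFF
#' `AVI ` file with a single `vids` stream of uncompressed bottom-up DIB
#' frames (`BI_RGB`, 8-bit palettized or 24-bit). This covers the files the
#' package itself writes and uncompressed exports from common editors;
#' codec-compressed AVIs are rejected with a clear error, and a frame-stack
#' directory can always be used instead (see [read_video()]).
#'
#' @name avi_io
NULL

.u32 <- function(r, pos) {
  readBin(r[pos:(pos + 3L)], "integer", size = 4L, endian = "little")
}
.u16 <- function(r, pos) {
  readBin(r[pos:(pos + 1L)], "integer", size = 2L, endian = "little",
          signed = FALSE)
}
.fourcc <- function(r, pos) rawToChar(r[pos:(pos + 3L)])

#' @rdname avi_io
#' @param path AVI file path.
#' @return `read_avi()`: a list with `frames` (luminance matrices),
#'   `frame_rate` and `bits`.
#' @export
read_avi <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 12L || .fourcc(r, 1L) != "RIFF" || .fourcc(r, 9L) != "AVI ")
    stop("not a RIFF/AVI file: ", path, call. = FALSE)

  scale <- 0L; rate <- 0L; usec <- 0L
  width <- 0L; height <- 0L; bitcount <- 0L; compression <- 0L
  palette <- NULL
  frames <- list()

  walk <- function(pos, end) {
    while (pos + 8L <= end) {
      id <- .fourcc(r, pos)
      sz <- .u32(r, pos + 4L)
      body <- pos + 8L
      if (id == "LIST") {
        walk(body + 4L, body + sz)
      } else if (id == "avih") {
        usec <<- .u32(r, body)
      } else if (id == "strh") {
        if (.fourcc(r, body) == "vids") {
          scale <<- .u32(r, body + 20L)
          rate <<- .u32(r, body + 24L)
        }
      } else if (id == "strf" && width == 0L) {
        width <<- .u32(r, body + 4L)
        height <<- .u32(r, body + 8L)
        bitcount <<- .u16(r, body + 14L)
        compression <<- .u32(r, body + 16L)
        if (bitcount == 8L && sz >= 40L + 1024L)
          palette <<- r[(body + 40L):(body + 40L + 1023L)]
      } else if (id %in% c("00db", "00dc") && sz > 0L) {
        frames[[length(frames) + 1L]] <<- r[body:(body + sz - 1L)]
      }
      pos <- body + sz + (sz %% 2L)   # chunks are word-aligned
    }
  }
  walk(13L, length(r))

  if (width <= 0L || height <= 0L)
    stop("AVI stream format header not found in ", path, call. = FALSE)
  if (compression != 0L)
    stop("only uncompressed (BI_RGB) AVI is supported; found compression ",
         compression, call. = FALSE)
  if (!bitcount %in% c(8L, 24L))
    stop("unsupported DIB bit depth: ", bitcount, call. = FALSE)
  if (length(frames) == 0L)
    stop("AVI contains zero frames: ", path, call. = FALSE)

  fr <- if (scale > 0L && rate > 0L) rate / scale
        else if (usec > 0L) 1e6 / usec else 30

  decode <- function(buf) {
    if (bitcount == 24L) {
      stride <- ((width * 3L + 3L) %/% 4L) * 4L
      m <- matrix(as.integer(buf[seq_len(stride * height)]), nrow = stride)
      px <- m[seq_len(width * 3L), , drop = FALSE]   # drop row padding
      b <- px[seq(1L, by = 3L, length.out = width), , drop = FALSE]
      g <- px[seq(2L, by = 3L, length.out = width), , drop = FALSE]
      rr <- px[seq(3L, by = 3L, length.out = width), , drop = FALSE]
      # columns are bottom-up image rows -> transpose and flip to top-down
      .luminance(t(rr)[height:1L, , drop = FALSE],
                 t(g)[height:1L, , drop = FALSE],
                 t(b)[height:1L, , drop = FALSE])
    } else {
      stride <- ((width + 3L) %/% 4L) * 4L
      m <- matrix(as.integer(buf[seq_len(stride * height)]), nrow = stride)
      idx <- m[seq_len(width), , drop = FALSE]
      img <- t(idx)[height:1L, , drop = FALSE]
      if (is.null(palette)) img else {
        pal <- matrix(as.integer(palette), nrow = 4L)  # B,G,R,0 per entry
        lum <- .luminance(pal[3L, ], pal[2L, ], pal[1L, ])
        matrix(lum[img + 1L], nrow = height)
      }
    }
  }
  list(frames = lapply(frames, decode), frame_rate = fr, bits = 8L)
}

#' @rdname avi_io
#' @param seq a `frame_sequence`; 16-bit sequences are rescaled to 8-bit
#'   for the container.
#' @return `write_avi()`: `path`, invisibly.
#' @export
write_avi <- function(seq, path) {
  stopifnot(inherits(seq, "frame_sequence"))
  d <- dim(seq$frames[[1L]])
  h <- d[1L]; w <- d[2L]; n <- n_frames(seq)
  stride <- ((w * 3L + 3L) %/% 4L) * 4L
  fsize <- stride * h
  top <- 2^seq$bits - 1

  con <- try(file(path, "wb"), silent = TRUE)
  if (inherits(con, "try-error"))
    stop("cannot open for writing: ", path, call. = FALSE)
  on.exit(close(con))
  put4 <- function(x) writeBin(as.integer(x), con, size = 4L,
                               endian = "little")
  put2 <- function(x) writeBin(as.integer(x), con, size = 2L,
                               endian = "little")
  tag <- function(s) writeBin(charToRaw(s), con)

  rate_scale <- 1000L
  rate <- as.integer(round(seq$frame_rate * rate_scale))
  movi_size <- 4L + n * (8L + fsize)
  hdrl_size <- 4L + (8L + 56L) + (8L + 116L)
  riff_size <- 4L + (8L + hdrl_size) + (8L + movi_size) + (8L + 16L * n)

  tag("RIFF"); put4(riff_size); tag("AVI ")
  tag("LIST"); put4(hdrl_size); tag("hdrl")
  tag("avih"); put4(56L)
  put4(round(1e6 / seq$frame_rate))       # dwMicroSecPerFrame
  put4(fsize * ceiling(seq$frame_rate))   # dwMaxBytesPerSec
  put4(0L); put4(16L)                     # padding; AVIF_HASINDEX
  put4(n); put4(0L); put4(1L); put4(fsize)
  put4(w); put4(h); put4(rep(0L, 4L))
  tag("LIST"); put4(116L); tag("strl")
  tag("strh"); put4(56L)
  tag("vids"); tag("DIB ")
  put4(0L); put2(0L); put2(0L); put4(0L)
  put4(rate_scale); put4(rate)
  put4(0L); put4(n); put4(fsize); put4(-1L); put4(0L)
  put2(c(0L, 0L, w, h))                   # rcFrame
  tag("strf"); put4(40L)
  put4(40L); put4(w); put4(h); put2(1L); put2(24L)
  put4(0L); put4(fsize); put4(0L); put4(0L); put4(0L); put4(0L)

  tag("LIST"); put4(movi_size); tag("movi")
  for (i in seq_len(n)) {
    v <- seq$frames[[i]]
    v <- pmin(pmax(round(v / top * 255), 0), 255)
    bytes <- rep(as.raw(as.vector(t(v[h:1L, , drop = FALSE]))), each = 3L)
    buf <- matrix(as.raw(0L), nrow = stride, ncol = h)
    buf[seq_len(3L * w), ] <- matrix(bytes, nrow = 3L * w)
    tag("00db"); put4(fsize); writeBin(as.vector(buf), con)
  }
  tag("idx1"); put4(16L * n)
  off <- 4L
  for (i in seq_len(n)) {
    tag("00db"); put4(16L); put4(off); put4(fsize)
    off <- off + 8L + fsize
  }
  invisible(path)
}
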