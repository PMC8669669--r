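## Minimal uncompressed AVI (RIFF 'AVI ', DIB 'vids' stream) support.
## Scope: reading 8-bit palettized / 24-bit RGB uncompressed frames and
## writing 8-bit grayscale frames. Enough for lossless video round trips;
## compressed AVIs are rejected with a clear error.

u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
fourcc <- function(s) charToRaw(s)

read_u32 <- function(raw, off) {  # off: 0-based byte offset
  sum(as.integer(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
}

#' Write a grayscale stack as an uncompressed 8-bit AVI
#'
#' Frames are clamped to `[0, 255]` and rounded; the stream is a standard
#' palettized DIB 'vids' stream readable by common players and by
#' [read_avi_stack()].
#'
#' @param stack a [frame_stack()] (intensities on a 0-255 scale).
#' @param path output file.
#' @param fps frames per second written to the header.
#' @return `path`, invisibly.
#' @export
write_avi_stack <- function(stack, path, fps = 50) {
  f <- stack$frames
  H <- dim(f)[1]; W <- dim(f)[2]; TT <- dim(f)[3]
  stride <- ((W + 3) %/% 4) * 4
  framebytes <- stride * H

  frame_raw <- function(t) {
    m <- pmin(pmax(round(f[, , t]), 0), 255)
    # DIB rows are bottom-up
    buf <- matrix(as.raw(0), nrow = stride, ncol = H)
    buf[seq_len(W), ] <- as.raw(t(m[H:1, , drop = FALSE]))
    as.vector(buf)
  }

  usec <- round(1e6 / fps)
  avih <- c(u32(usec), u32(framebytes * fps), u32(0), u32(0x10),  # AVIF_HASINDEX
            u32(TT), u32(0), u32(1), u32(framebytes),
            u32(W), u32(H), u32(0), u32(0), u32(0), u32(0))
  strh <- c(fourcc("vids"), fourcc("DIB "), u32(0), u16(0), u16(0),
            u32(0), u32(1), u32(round(fps)), u32(0), u32(TT),
            u32(framebytes), u32(0), u32(0),
            u16(0), u16(0), u16(W), u16(H))
  pal <- as.raw(as.vector(rbind(0:255, 0:255, 0:255, 0)))  # grayscale BGR0 quads
  strf <- c(u32(40), u32(W), u32(H), u16(1), u16(8), u32(0),
            u32(framebytes), u32(0), u32(0), u32(256), u32(0), pal)

  chunk <- function(id, payload) c(fourcc(id), u32(length(payload)), payload,
                                   if (length(payload) %% 2) as.raw(0))
  list_chunk <- function(type, payload) chunk("LIST", c(fourcc(type), payload))

  strl <- list_chunk("strl", c(chunk("strh", strh), chunk("strf", strf)))
  hdrl <- list_chunk("hdrl", c(chunk("avih", avih), strl))

  movi_frames <- lapply(seq_len(TT), function(t) chunk("00db", frame_raw(t)))
  movi <- list_chunk("movi", do.call(c, movi_frames))

  # idx1: one entry per frame; offsets relative to start of 'movi' list data
  offs <- cumsum(c(4, head(vapply(movi_frames, length, integer(1)), -1)))
  idx <- do.call(c, lapply(seq_len(TT), function(t)
    c(fourcc("00db"), u32(0x10), u32(offs[t]), u32(framebytes))))
  idx1 <- chunk("idx1", idx)

  body <- c(fourcc("AVI "), hdrl, movi, idx1)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(fourcc("RIFF"), u32(length(body)), body), con)
  invisible(path)
}

#' Read an uncompressed AVI into a FrameStack
#'
#' Supports uncompressed 8-bit palettized and 24-bit RGB DIB streams; RGB is
#' converted to luminance with Rec. 601 weights. Compressed streams raise an
#' input error.
#'
#' @param path AVI file.
#' @return a [frame_stack()].
#' @export
read_avi_stack <- function(path) {
  if (!file.exists(path)) cm_input_error(paste("cannot read video:", path))
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 12 || rawToChar(raw[1:4]) != "RIFF" ||
      rawToChar(raw[9:12]) != "AVI ")
    cm_input_error(paste("not a RIFF/AVI file:", path))

  state <- new.env(parent = emptyenv())
  state$frames <- list()
  state$W <- NA_integer_; state$H <- NA_integer_
  state$bits <- NA_integer_; state$comp <- NA_integer_
  state$fps <- NULL

  walk <- function(off, end) {
    while (off + 8 <= end) {
      id <- rawToChar(raw[off + 1:4])
      sz <- read_u32(raw, off + 4)
      data0 <- off + 8
      if (id == "LIST") {
        walk(data0 + 4, data0 + sz)
      } else if (id == "strf" && is.na(state$W)) {
        state$W <- read_u32(raw, data0 + 4)
        state$H <- read_u32(raw, data0 + 8)
        state$bits <- read_u32(raw, data0 + 14) %% 65536
        state$comp <- read_u32(raw, data0 + 16)
      } else if (id == "strh" && is.null(state$fps)) {
        scale <- read_u32(raw, data0 + 20); rate <- read_u32(raw, data0 + 24)
        if (scale > 0) state$fps <- rate / scale
      } else if (grepl("^..(db|dc)$", id) && sz > 0) {
        state$frames[[length(state$frames) + 1]] <- raw[data0 + seq_len(sz)]
      }
      off <- data0 + sz + (sz %% 2)
    }
  }
  walk(12, length(raw))

  if (is.na(state$W) || length(state$frames) == 0)
    cm_input_error(paste("no decodable video stream in:", path))
  if (!is.na(state$comp) && state$comp != 0)
    cm_input_error("compressed AVI streams are not supported; use an uncompressed DIB AVI or TIFF")
  if (!state$bits %in% c(8, 24))
    cm_input_error(sprintf("unsupported AVI bit depth: %d", state$bits))

  W <- state$W; H <- state$H
  decode <- function(buf) {
    if (state$bits == 8) {
      stride <- ((W + 3) %/% 4) * 4
      m <- matrix(as.integer(buf[seq_len(stride * H)]), nrow = stride)[seq_len(W), , drop = FALSE]
      t(m)[H:1, , drop = FALSE]
    } else {
      stride <- ((3 * W + 3) %/% 4) * 4
      m <- matrix(as.integer(buf[seq_len(stride * H)]), nrow = stride)
      b <- t(m[seq(1, 3 * W, by = 3), , drop = FALSE])[H:1, , drop = FALSE]
      g <- t(m[seq(2, 3 * W, by = 3), , drop = FALSE])[H:1, , drop = FALSE]
      r <- t(m[seq(3, 3 * W, by = 3), , drop = FALSE])[H:1, , drop = FALSE]
      rgb_to_luminance(r, g, b)
    }
  }
  frames <- lapply(state$frames, decode)
  if (length(frames) < 2)
    cm_validation_error(paste("video has fewer than 2 frames:", path))
  frame_stack(frames, frame_rate_hz = state$fps)
}

## Rec. 601 luma weights; deterministic RGB -> grayscale.
rgb_to_luminance <- function(r, g, b) 0.299 * r + 0.587 * g + 0.114 * b
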