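#' Select the registration reference square
#'
#' Picks the square used for movement correction on the first frame. In
#' `"manual"` mode the configured corner is returned unchanged; in `"auto"`
#' mode a stride-searched grid of candidate corners is scanned and the square
#' with the highest intensity standard deviation (i.e. most contrast) wins.
#'
#' @param frame0 2-D intensity matrix (first frame).
#' @param size side length in pixels.
#' @param mode `"manual"` or `"auto"`.
#' @param corner 0-based `c(row, col)` corner, required in manual mode.
#' @param stride grid step for the auto search (pixels).
#' @return integer `c(row, col, size)`, 0-based corner.
#' @export
select_reference_square <- function(frame0, size = 256L,
                                    mode = c("auto", "manual"),
                                    corner = NULL, stride = NULL) {
  mode <- match.arg(mode)
  H <- nrow(frame0); W <- ncol(frame0); size <- as.integer(size)
  if (size > H || size > W)
    cm_validation_error(sprintf("frame (%d x %d) smaller than reference square (%d)",
                                H, W, size))
  if (mode == "manual") {
    if (is.null(corner)) cm_validation_error("manual mode needs a corner")
    sq <- as.integer(c(corner[1], corner[2], size))
    validate_reference_square(sq, c(H, W))
    return(sq)
  }
  if (is.null(stride)) stride <- max(1L, size %/% 4L)
  # square variance for every candidate corner via integral images
  s1 <- apply(apply(frame0, 2, cumsum), 1, cumsum)      # transposed cumsums
  s1 <- t(s1); s2 <- apply(apply(frame0^2, 2, cumsum), 1, cumsum); s2 <- t(s2)
  box <- function(S, r0, c0) {  # 1-based inclusive corners of size x size box
    r1 <- r0 + size - 1L; c1 <- c0 + size - 1L
    S[r1, c1] -
      (if (r0 > 1) S[r0 - 1, c1] else 0) -
      (if (c0 > 1) S[r1, c0 - 1] else 0) +
      (if (r0 > 1 && c0 > 1) S[r0 - 1, c0 - 1] else 0)
  }
  rows <- unique(c(seq(1L, H - size + 1L, by = stride), H - size + 1L))
  cols <- unique(c(seq(1L, W - size + 1L, by = stride), W - size + 1L))
  n <- as.numeric(size)^2
  best <- c(-Inf, 1L, 1L)
  for (r in rows) for (cc in cols) {
    v <- box(s2, r, cc) / n - (box(s1, r, cc) / n)^2
    if (v > best[1]) best <- c(v, r, cc)
  }
  if (best[1] <= 0)
    warning("reference square search found no contrast (constant image)")
  as.integer(c(best[2] - 1L, best[3] - 1L, size))
}

#' Estimate the displacement of one frame
#'
#' Finds the integer shift maximizing the zero-normalized cross-correlation
#' between the reference patch (cut from frame 0 at `pos`) and the like-sized
#' window of `frame`, searched in a square window of radius `max_shift_px`
#' centered on `prev_shift` and capped at `max_shift_px` absolute
#' displacement. Ties are broken by smallest `|d_row| + |d_col|`, then
#' lexicographically.
#'
#' @param ref_patch 2-D matrix, the reference square content from frame 0.
#' @param frame 2-D matrix to register.
#' @param pos 0-based `c(row, col)` corner of the patch in frame-0 coordinates.
#' @param prev_shift integer `c(d_row, d_col)` search center.
#' @param max_shift_px search radius and absolute displacement cap.
#' @return list with `shift` (integer `c(d_row, d_col)`) and `peak_corr`.
#' @export
estimate_displacement <- function(ref_patch, frame, pos = c(0L, 0L),
                                  prev_shift = c(0L, 0L), max_shift_px = 4L) {
  m <- as.integer(max_shift_px)
  dr_rng <- c(max(prev_shift[1] - m, -m), min(prev_shift[1] + m, m))
  dc_rng <- c(max(prev_shift[2] - m, -m), min(prev_shift[2] + m, m))
  if (dr_rng[1] > dr_rng[2] || dc_rng[1] > dc_rng[2])
    cm_registration_error("empty displacement search window")
  scores <- .zncc_scan_cpp(ref_patch, frame,
                           as.integer(pos[1]), as.integer(pos[2]),
                           dr_rng[1], dr_rng[2], dc_rng[1], dc_rng[2])
  if (all(is.na(scores)))
    cm_registration_error("no valid shift keeps the reference square in frame")
  peak <- max(scores, na.rm = TRUE)
  hits <- which(scores >= peak - 1e-12, arr.ind = TRUE)
  drs <- dr_rng[1] + hits[, 1] - 1L
  dcs <- dc_rng[1] + hits[, 2] - 1L
  ord <- order(abs(drs) + abs(dcs), drs, dcs)
  list(shift = as.integer(c(drs[[ord[1]]], dcs[[ord[1]]])), peak_corr = peak)
}

#' Align a stack to its first frame
#'
#' Corrects in-plane movement: the displacement of the high-contrast
#' reference square is tracked by two-dimensional image correlation of
#' consecutive frames (frame t is matched against the reference square's
#' content in frame t-1 at its last known position, so the correlation is
#' dominated by structure that persists over one frame interval rather than
#' by moving red cells) and expressed relative to frame 0. Every frame is
#' then shifted by the negative of its displacement and the stack is cropped
#' to the maximal rectangle covered by all shifted frames, so temporal
#' statistics never mix in padding values.
#'
#' @param stack a [frame_stack()].
#' @param config an [analysis_config()]; if `config$reference_square` is
#'   `NULL` the square is auto-selected by contrast.
#' @return list with `aligned` (cropped [frame_stack()]), `trace` (data frame
#'   `frame`, `d_row`, `d_col`, `peak_corr`), `valid_region` (0-based
#'   half-open `c(row0, row1, col0, col1)`), and `reference_square`.
#' @export
align_stack <- function(stack, config = analysis_config()) {
  f <- stack$frames
  H <- dim(f)[1]; W <- dim(f)[2]; TT <- dim(f)[3]
  sq <- if (is.null(config$reference_square)) {
    select_reference_square(f[, , 1], size = min(config$reference_size, H, W),
                            mode = "auto")
  } else {
    validate_reference_square(config$reference_square, c(H, W))
  }
  shifts <- matrix(0L, TT, 2)
  peaks <- numeric(TT); peaks[1] <- 1
  for (t in seq_len(TT)[-1]) {
    # reference square content from the previous frame at its tracked position
    pr <- sq[1] + shifts[t - 1, 1]; pc <- sq[2] + shifts[t - 1, 2]
    if (pr < 0 || pc < 0 || pr + sq[3] > H || pc + sq[3] > W)
      cm_registration_error(sprintf(
        "frame %d: reference square drifted out of frame", t - 1L))
    patch <- f[pr + seq_len(sq[3]), pc + seq_len(sq[3]), t - 1]
    est <- tryCatch(
      estimate_displacement(patch, f[, , t], pos = sq[1:2],
                            prev_shift = shifts[t - 1, ],
                            max_shift_px = config$max_shift_px),
      cammesh_registration_error = function(e)
        cm_registration_error(sprintf("frame %d: %s", t - 1L, conditionMessage(e))))
    if (est$peak_corr < config$min_peak_corr)
      cm_registration_error(sprintf(
        "frame %d: best correlation %.3f below min_peak_corr %.2f (drift beyond max_shift_px, or reference lost)",
        t - 1L, est$peak_corr, config$min_peak_corr))
    shifts[t, ] <- est$shift
    peaks[t] <- est$peak_corr
  }
  # maximal rectangle covered by every frame shifted by -shift (0-based, half-open)
  r0 <- max(0L, max(-shifts[, 1])); r1 <- min(H, min(H - shifts[, 1]))
  c0 <- max(0L, max(-shifts[, 2])); c1 <- min(W, min(W - shifts[, 2]))
  if (r1 <= r0 || c1 <= c0)
    cm_registration_error("displacements leave no common valid region")
  aligned <- array(0, dim = c(r1 - r0, c1 - c0, TT))
  for (t in seq_len(TT)) {
    aligned[, , t] <- f[(r0 + shifts[t, 1] + 1):(r1 + shifts[t, 1]),
                        (c0 + shifts[t, 2] + 1):(c1 + shifts[t, 2]), t]
  }
  list(aligned = frame_stack(aligned, pixel_size_um = stack$pixel_size_um,
                             frame_rate_hz = stack$frame_rate_hz),
       trace = data.frame(frame = 0:(TT - 1), d_row = shifts[, 1],
                          d_col = shifts[, 2], peak_corr = peaks),
       valid_region = c(r0, r1, c0, c1),
       reference_square = sq)
}
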