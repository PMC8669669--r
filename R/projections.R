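#' Projection images
#'
#' A `ProjectionImage` is a per-pixel temporal statistic map computed from an
#' aligned video: either the standard-deviation "vessel image" (high where
#' passing red cells modulate absorbance, i.e. in perfused lumen) or the
#' cumulative intensity-change "perfusion image" (sensitive to amplitude
#' times frequency of change, a semi-quantitative relative flow map).
#'
#' @param values 2-D numeric matrix.
#' @param kind `"vessel_sd"` or `"perfusion_cumchange"`.
#' @param norm `"raw"` or `"unit"`.
#' @return a `ProjectionImage`.
#' @export
projection_image <- function(values, kind = c("vessel_sd", "perfusion_cumchange"),
                             norm = c("raw", "unit")) {
  kind <- match.arg(kind); norm <- match.arg(norm)
  if (!is.matrix(values) || !is.numeric(values))
    cm_validation_error("projection values must be a numeric matrix")
  if (norm == "unit") {
    mx <- max(values)
    if (min(values) < 0 || (mx != 0 && abs(mx - 1) > 1e-12))
      cm_validation_error("unit-normalized image must lie in [0,1] with max 1 (or be all zero)")
  }
  structure(list(values = values, kind = kind, norm = norm),
            class = "ProjectionImage")
}

#' @export
print.ProjectionImage <- function(x, ...) {
  cat(sprintf("ProjectionImage (%s, %s): %d x %d px, range [%g, %g]\n",
              x$kind, x$norm, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Temporal standard-deviation vessel image
#'
#' Per-pixel population standard deviation of intensity over all frames of an
#' aligned stack. The SD reflects only the extent of intensity change, not
#' its frequency, so the result is invariant to reordering frames; perfused
#' lumen scores high, avascular tissue low.
#'
#' @param aligned an aligned [frame_stack()].
#' @return `ProjectionImage(kind = "vessel_sd", norm = "raw")`.
#' @export
sd_image <- function(aligned) {
  f <- aligned$frames
  TT <- dim(f)[3]
  if (TT < 2) cm_validation_error("sd_image needs at least 2 frames")
  m <- rowMeans(f, dims = 2)
  v <- rowMeans(f^2, dims = 2) - m^2
  v[v < 0] <- 0  # numerical guard
  projection_image(sqrt(v), kind = "vessel_sd", norm = "raw")
}

#' Cumulative intensity-change perfusion image
#'
#' Per-pixel sum over time of `|I(t+1) - I(t)|`. Unlike the SD image this
#' grows with both the amplitude and the frequency of intensity changes
#' (related to the number of passing red cells per unit time), so it is not
#' invariant to frame reordering.
#'
#' @param aligned an aligned [frame_stack()].
#' @return `ProjectionImage(kind = "perfusion_cumchange", norm = "raw")`.
#' @export
cumulative_change_image <- function(aligned) {
  f <- aligned$frames
  TT <- dim(f)[3]
  if (TT < 2) cm_validation_error("cumulative_change_image needs at least 2 frames")
  acc <- matrix(0, dim(f)[1], dim(f)[2])
  for (t in seq_len(TT - 1)) acc <- acc + abs(f[, , t + 1] - f[, , t])
  projection_image(acc, kind = "perfusion_cumchange", norm = "raw")
}

#' Normalize a projection image to the available dynamic range
#'
#' Divides by the image maximum so the maximum maps to full range. The
#' minimum is deliberately not subtracted: both statistics have a natural
#' zero ("no change"), which is preserved. Normalized products show only
#' relative levels for a given video sequence. An all-zero image is returned
#' unchanged with a warning.
#'
#' @param img a raw `ProjectionImage`.
#' @param quiet suppress the all-zero warning.
#' @return `ProjectionImage` with `norm = "unit"`.
#' @export
normalize_to_dynamic_range <- function(img, quiet = FALSE) {
  stopifnot(inherits(img, "ProjectionImage"))
  if (!all(is.finite(img$values)))
    cm_validation_error("projection image has non-finite values")
  mx <- max(img$values)
  if (mx == 0) {
    if (!quiet) warning("all-zero projection image; normalization is a no-op")
    return(projection_image(img$values, img$kind, "unit"))
  }
  projection_image(img$values / mx, img$kind, "unit")
}

## Fixed perceptually-ordered look-up table (dark blue -> yellow), 256
## entries; deterministic across runs.
perfusion_lut <- function() {
  cols <- grDevices::hcl.colors(256, "viridis")
  t(grDevices::col2rgb(cols)) / 255
}

#' Pseudo-color rendering of a perfusion image
#'
#' Maps a unit-normalized perfusion image through a fixed
#' perceptually-ordered colormap (dark blue = low, yellow = high). Because
#' each image is normalized to span the full range, colors encode relative
#' flow within one recording only.
#'
#' @param img `ProjectionImage(norm = "unit")`.
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
pseudocolor <- function(img) {
  stopifnot(inherits(img, "ProjectionImage"))
  if (img$norm != "unit")
    cm_validation_error("pseudocolor needs a unit-normalized image")
  lut <- perfusion_lut()
  idx <- pmin(255L, pmax(0L, as.integer(floor(img$values * 255 + 0.5)))) + 1L
  H <- nrow(img$values); W <- ncol(img$values)
  array(lut[idx, ], dim = c(H, W, 3))
}
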