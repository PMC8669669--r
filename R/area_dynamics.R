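#' Landmark quadrilateral
#'
#' Four user-identified landmarks (vessel junctions or branch points) marking
#' the corners of a CAM test region, given as 0-based `(row, col)` real
#' coordinates in traversal order. The polygon must be simple.
#'
#' @param points 4 x 2 matrix of `(row, col)` coordinates, in order.
#' @param timepoint_h hours since the first observation.
#' @return a `LandmarkQuad`.
#' @export
landmark_quad <- function(points, timepoint_h = 0) {
  points <- as.matrix(points)
  if (nrow(points) != 4 || ncol(points) != 2 || !all(is.finite(points)))
    cm_validation_error("a LandmarkQuad needs exactly 4 finite (row, col) points")
  if (quad_self_intersects(points))
    cm_validation_error(
      "landmark polygon self-intersects; reorder the points along the boundary")
  structure(list(points = points, timepoint_h = timepoint_h),
            class = "LandmarkQuad")
}

## Do the two pairs of opposite edges of the ordered quad cross?
quad_self_intersects <- function(p) {
  seg_cross <- function(a, b, c, d) {
    orient <- function(o, a, b)
      sign((a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1]))
    o1 <- orient(a, b, c); o2 <- orient(a, b, d)
    o3 <- orient(c, d, a); o4 <- orient(c, d, b)
    (o1 != o2 && o3 != o4) && all(c(o1, o2, o3, o4) != 0)
  }
  seg_cross(p[1, ], p[2, ], p[3, ], p[4, ]) ||
    seg_cross(p[2, ], p[3, ], p[4, ], p[1, ])
}

#' Polygon area of a landmark quad
#'
#' Shoelace formula on the ordered corners; orientation-independent.
#'
#' @param quad a [landmark_quad()] (or 4 x 2 coordinate matrix).
#' @param pixel_size_um optional micrometers per pixel; when given the area
#'   is returned in um^2 instead of px^2.
#' @return scalar area.
#' @export
quad_area <- function(quad, pixel_size_um = NULL) {
  p <- if (inherits(quad, "LandmarkQuad")) quad$points
       else landmark_quad(quad)$points
  i <- 1:4; j <- c(2:4, 1)
  a <- abs(sum(p[i, 1] * p[j, 2] - p[j, 1] * p[i, 2])) / 2
  if (!is.null(pixel_size_um)) a <- a * pixel_size_um^2
  a
}

#' Relative-area trace over timepoints
#'
#' Tracks CAM area change from the same four landmarks re-identified at each
#' timepoint: `rel_area[t] = area(t) / area(t0)`, starting at exactly 1.
#'
#' @param quads list of [landmark_quad()] in time order (>= 2 timepoints).
#' @return data frame with columns `timepoint_h`, `rel_area`.
#' @export
area_series <- function(quads) {
  if (length(quads) < 2)
    cm_validation_error("area_series needs at least 2 timepoints")
  ok <- vapply(quads, inherits, logical(1), what = "LandmarkQuad")
  if (!all(ok)) cm_validation_error("all elements must be LandmarkQuads")
  areas <- vapply(quads, quad_area, numeric(1))
  tps <- vapply(quads, function(q) q$timepoint_h, numeric(1))
  rel <- areas / areas[1]
  rel[1] <- 1.0
  data.frame(timepoint_h = tps, rel_area = rel)
}

#' Rasterize a quad interior
#'
#' Pixel-center-inside test (even-odd rule, half-open on edges so that quads
#' tiling a region partition its pixels).
#'
#' @param quad a [landmark_quad()].
#' @param dim image `c(H, W)`.
#' @return logical matrix, `TRUE` inside the quad.
#' @export
rasterize_quad <- function(quad, dim) {
  rasterize_polygon(quad$points, dim)
}

## General even-odd polygon rasterizer, pixel-center-inside, half-open on
## edges (shared edges between tiling polygons assign each pixel once).
rasterize_polygon <- function(p, dim) {
  H <- dim[1]; W <- dim[2]
  out <- matrix(FALSE, H, W)
  ys <- p[, 1]; xs <- p[, 2]
  n <- nrow(p)
  j <- c(2:n, 1)
  for (r in 0:(H - 1)) {
    cross <- (ys > r) != (ys[j] > r)
    if (!any(cross)) next
    xint <- xs[cross] + (r - ys[cross]) * (xs[j][cross] - xs[cross]) /
      (ys[j][cross] - ys[cross])
    xint <- sort(xint)
    if (length(xint) %% 2 == 1) next  # numerically degenerate scanline
    for (k in seq(1, length(xint) - 1, by = 2)) {
      c0 <- ceiling(xint[k]); c1 <- ceiling(xint[k + 1]) - 1
      c0 <- max(c0, 0); c1 <- min(c1, W - 1)
      if (c1 >= c0) out[r + 1, (c0 + 1):(c1 + 1)] <- TRUE
    }
  }
  out
}

#' Capillary density inside a landmark quad
#'
#' Restricts the segmentation to the rasterized quad interior and reports
#' skeleton length per unit area and vessel area fraction there.
#'
#' @param seg a [network_segmentation()].
#' @param quad a [landmark_quad()] lying within the image bounds.
#' @param pixel_size_um optional micrometers per pixel (density per um).
#' @return data frame with `skel_len_density`, `area_fraction`, `n_px`.
#' @export
capillary_density <- function(seg, quad, pixel_size_um = NULL) {
  stopifnot(inherits(seg, "NetworkSegmentation"))
  d <- dim(seg$vessel_mask)
  p <- quad$points
  if (any(p[, 1] < -0.5) || any(p[, 2] < -0.5) ||
      any(p[, 1] > d[1] - 0.5) || any(p[, 2] > d[2] - 0.5))
    cm_validation_error("landmark quad lies outside the image")
  inside <- rasterize_quad(quad, d)
  n <- sum(inside)
  if (n == 0)
    return(data.frame(skel_len_density = 0, area_fraction = 0, n_px = 0L))
  dens <- sum(seg$skeleton[inside]) / n
  if (!is.null(pixel_size_um)) dens <- dens / pixel_size_um
  data.frame(skel_len_density = dens,
             area_fraction = mean(seg$vessel_mask[inside]),
             n_px = n)
}
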