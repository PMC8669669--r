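#' Gaussian vessel enhancement
#'
#' Smooths an SD vessel image with a Gaussian kernel (separable convolution,
#' reflective boundaries) to enhance the intensity difference between vessels
#' (bright, elongated) and tissue islands (dark, roundish) before
#' thresholding.
#'
#' @param sd_img a `ProjectionImage` or plain numeric matrix.
#' @param gaussian_sigma_px Gaussian sigma in pixels (> 0).
#' @return numeric matrix, same shape.
#' @export
enhance <- function(sd_img, gaussian_sigma_px = 2) {
  if (gaussian_sigma_px <= 0) cm_validation_error("gaussian sigma must be > 0")
  img <- if (inherits(sd_img, "ProjectionImage")) sd_img$values else sd_img
  sep_convolve(img, gaussian_kernel_1d(gaussian_sigma_px))
}

#' Double-threshold vessel segmentation
#'
#' Combines a global Otsu threshold (main vessels) with a local mean
#' threshold (small and secondary vessels): `pixel > local_mean - offset`
#' over an odd window. The final mask is the union of the two, with specks
#' below `min_speckle_px` pruned (8-connectivity). The union is always a
#' pixelwise superset of the global-only mask under the same pruning.
#'
#' @param enhanced numeric matrix (enhanced SD image).
#' @param local_window_px odd window size, >= 3.
#' @param local_offset subtracted from the local mean (negative values place
#'   the threshold above the local mean).
#' @param min_speckle_px prune foreground components smaller than this.
#' @param use_local include the local threshold (set `FALSE` for the
#'   global-only mask).
#' @return logical vessel mask.
#' @export
double_threshold <- function(enhanced, local_window_px = 51L,
                             local_offset = -0.02, min_speckle_px = 20L,
                             use_local = TRUE) {
  if (local_window_px < 3 || local_window_px %% 2 == 0)
    cm_validation_error("local_window_px must be odd and >= 3")
  rng <- range(enhanced)
  if (diff(rng) == 0) {
    warning("flat image: global threshold undefined, returning empty mask")
    return(matrix(FALSE, nrow(enhanced), ncol(enhanced)))
  }
  th_global <- EBImage::otsu(enhanced, range = rng, levels = 256L)
  mask <- enhanced > th_global
  if (use_local) {
    lm <- local_mean(enhanced, local_window_px)
    mask <- mask | (enhanced > lm - local_offset)
  }
  prune_speckles(mask, min_speckle_px)
}

## Remove 8-connected foreground components smaller than min_px.
prune_speckles <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- label_components(mask, 8)
  sizes <- tabulate(lab[lab > 0], nbins = attr(lab, "n"))
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Topology-preserving skeletonization
#'
#' Thins a binary vessel mask to 1-px centerlines by sequential removal of
#' simple points (8-connected foreground, 4-connected background) in four
#' directional subpasses, protecting curve endpoints. Because only simple
#' points are ever deleted, the connected-component count and Euler number of
#' the mask are preserved exactly, and the skeleton is a subset of the mask.
#'
#' @param vessel_mask logical (or 0/1) matrix.
#' @return logical skeleton matrix.
#' @export
skeletonize_mask <- function(vessel_mask) {
  .thin_cpp(mask_logical(vessel_mask))
}

#' Extract tissue islands from a vessel mask
#'
#' Tissue islands are the avascular regions fully enclosed by vessel
#' foreground, i.e. the holes of the mask (4-connected background not
#' touching the border); background reaching the border is not an island
#' since enclosure cannot be established. Two morphological passes with the
#' same disk clean the result: a closing (dilation-erosion) of the vessel
#' mask first seals hairline breaks in thin capillary walls that would
#' spuriously merge neighboring islands, then an opening (erosion-dilation)
#' of the holes removes ragged hole edges; islands below the minimum area
#' are dropped.
#'
#' @param vessel_mask logical matrix.
#' @param morph_radius_px disk radius of the opening (>= 1).
#' @param min_island_area_px minimum island area kept (pixels).
#' @return integer label matrix (0 = background) with attribute `n` = number
#'   of islands.
#' @export
extract_tissue_islands <- function(vessel_mask, morph_radius_px = 2L,
                                   min_island_area_px = 25L) {
  if (morph_radius_px < 1) cm_validation_error("morph_radius_px must be >= 1")
  vessel_mask <- mask_logical(vessel_mask)
  brush <- EBImage::makeBrush(2L * as.integer(morph_radius_px) + 1L, "disc")
  closed <- EBImage::closing(vessel_mask * 1, brush) > 0
  holes <- EBImage::fillHull(closed * 1) > 0 & !closed
  if (any(holes)) holes <- EBImage::opening(holes * 1, brush) > 0
  lab <- label_components(holes, 4)
  n <- attr(lab, "n")
  if (n == 0) return(structure(lab, n = 0L))
  sizes <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(sizes >= min_island_area_px)
  out <- matrix(match(lab, keep, nomatch = 0L), nrow(lab), ncol(lab))
  structure(out, n = length(keep))
}

#' Assemble a network segmentation
#'
#' Bundles the vessel mask, skeleton and island labels for one field of view
#' and verifies the structural invariants (skeleton inside mask, topology
#' preserved, islands disjoint from vessels).
#'
#' @param vessel_mask logical matrix.
#' @param skeleton logical matrix (defaults to [skeletonize_mask()] output).
#' @param islands integer label matrix (defaults to
#'   [extract_tissue_islands()] output).
#' @param params_used optional [analysis_config()] echo.
#' @param check verify invariants (small cost; disable for huge masks).
#' @return a `NetworkSegmentation`.
#' @export
network_segmentation <- function(vessel_mask, skeleton = NULL, islands = NULL,
                                 params_used = NULL, check = TRUE) {
  vessel_mask <- mask_logical(vessel_mask)
  if (is.null(skeleton)) skeleton <- skeletonize_mask(vessel_mask)
  if (is.null(islands)) {
    islands <- if (is.null(params_used))
      extract_tissue_islands(vessel_mask)
    else
      extract_tissue_islands(vessel_mask, params_used$morph_radius_px,
                             params_used$min_island_area_px)
  }
  if (check) {
    if (any(skeleton & !vessel_mask))
      cm_validation_error("skeleton must be a subset of the vessel mask")
    if (any(islands > 0 & vessel_mask))
      cm_validation_error("islands must be disjoint from the vessel mask")
    if (attr(label_components(skeleton, 8), "n") !=
        attr(label_components(vessel_mask, 8), "n") ||
        euler_number(skeleton) != euler_number(vessel_mask))
      cm_validation_error("skeletonization broke topology (components or Euler number)")
  }
  structure(list(vessel_mask = vessel_mask, skeleton = skeleton,
                 islands = islands, params_used = params_used),
            class = "NetworkSegmentation")
}

#' @export
print.NetworkSegmentation <- function(x, ...) {
  cat(sprintf("NetworkSegmentation: %d x %d px, vessel fraction %.3f, %d islands\n",
              nrow(x$vessel_mask), ncol(x$vessel_mask), mean(x$vessel_mask),
              attr(x$islands, "n")))
  invisible(x)
}

#' Morphometry of a segmented network
#'
#' Computes per-ROI descriptors of the capillary mesh: vessel area fraction,
#' skeleton length density (skeleton pixels per pixel^2; per um when the
#' pixel size is known), island count and island-area mean/CV, vessel
#' diameter mean/CV sampled along the skeleton (diameter = 2 x Euclidean
#' distance transform - 1 at skeleton pixels, excluding pixels within one
#' local radius of branch points to reduce junction bias), and perfusion
#' heterogeneity (CV of perfusion values over vessel pixels).
#'
#' @param seg a [network_segmentation()].
#' @param perf optional perfusion `ProjectionImage` (any `norm`; CV is
#'   scale-invariant).
#' @param pixel_size_um optional micrometers per pixel.
#' @param roi_id identifier copied to the record.
#' @param timepoint_h optional hours since first observation.
#' @return one-row data frame (`MorphometryRecord`).
#' @export
measure_network <- function(seg, perf = NULL, pixel_size_um = NULL,
                            roi_id = "roi", timepoint_h = NA_real_) {
  stopifnot(inherits(seg, "NetworkSegmentation"))
  mask <- seg$vessel_mask; skel <- seg$skeleton
  npx <- length(mask)
  area_fraction <- mean(mask)
  skel_len_density <- sum(skel) / npx
  if (!is.null(pixel_size_um)) skel_len_density <- skel_len_density / pixel_size_um

  n_islands <- attr(seg$islands, "n")
  if (is.null(n_islands)) n_islands <- max(seg$islands)
  if (n_islands > 0) {
    areas <- tabulate(seg$islands[seg$islands > 0], nbins = n_islands)
    island_area_mean <- mean(areas)
    island_area_cv <- cv(areas)
  } else {
    island_area_mean <- NA_real_; island_area_cv <- NA_real_
  }

  if (!any(skel)) {
    warning("empty skeleton: diameter statistics unavailable")
    diam_mean_px <- 0; diam_cv <- NA_real_
  } else {
    edt <- as.matrix(EBImage::distmap(mask * 1))
    diams <- sample_diameters(skel, edt)
    diam_mean_px <- mean(diams)
    diam_cv <- cv(diams)
  }

  perf_cv <- NA_real_
  if (!is.null(perf)) {
    pv <- (if (inherits(perf, "ProjectionImage")) perf$values else perf)[mask]
    perf_cv <- cv(pv)
  }

  structure(data.frame(roi_id = roi_id, area_fraction = area_fraction,
                       skel_len_density = skel_len_density,
                       n_islands = n_islands,
                       island_area_mean = island_area_mean,
                       island_area_cv = island_area_cv,
                       diam_mean_px = diam_mean_px, diam_cv = diam_cv,
                       perf_cv = perf_cv, timepoint_h = timepoint_h,
                       stringsAsFactors = FALSE),
            class = c("MorphometryRecord", "data.frame"))
}

## Diameters (2 * EDT - 1) at skeleton pixels, excluding pixels within one
## local radius of any skeleton branch point (junction bias).
sample_diameters <- function(skel, edt) {
  idx <- which(skel, arr.ind = TRUE)
  nb <- neighbor_count(skel)
  branch <- which(skel & nb > 2, arr.ind = TRUE)
  keep <- rep(TRUE, nrow(idx))
  if (nrow(branch) > 0) {
    for (b in seq_len(nrow(branch))) {
      r <- edt[branch[b, 1], branch[b, 2]]
      d2 <- (idx[, 1] - branch[b, 1])^2 + (idx[, 2] - branch[b, 2])^2
      keep <- keep & d2 > r^2
    }
  }
  if (!any(keep)) keep[] <- TRUE  # tiny/junction-dominated skeletons: keep all
  2 * edt[idx[keep, , drop = FALSE]] - 1
}

## Number of 8-neighbors that are foreground, for every pixel.
neighbor_count <- function(mask) {
  m <- mask_logical(mask) * 1L
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  out <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + p[2:(H + 1) + dr, 2:(W + 1) + dc]
  }
  out
}
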