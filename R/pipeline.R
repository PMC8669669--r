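#' Run the full analysis pipeline
#'
#' Composes the stages end to end: read (when given a path), align to frame
#' 0, compute the SD vessel image and cumulative-change perfusion image,
#' normalize both to the dynamic range, enhance and double-threshold the SD
#' image into a vessel mask, skeletonize, extract tissue islands, and
#' measure the network. The run is fully deterministic given the inputs and
#' the config. A QC report records the displacement trace, the parameters
#' used, and the fraction of total perfusion signal lying outside the vessel
#' mask — the indicator of the perfusion algorithm's known artifact (tissue
#' flicker produces small positive perfusion values in avascular areas).
#'
#' @param video a file path (TIFF/AVI) or a [frame_stack()].
#' @param config an [analysis_config()].
#' @param landmarks optional list of [landmark_quad()]s (or a landmarks CSV
#'   path) for area dynamics within the field of view.
#' @param out_dir optional output directory; when given, all products are
#'   written and the manifest is included in the result.
#' @param roi_id identifier attached to the morphometry record.
#' @return list with `vessel_image`, `perfusion_image` (unit-normalized
#'   `ProjectionImage`s), `perfusion_rgb`, `segmentation`, `morphometry`,
#'   `trace`, `valid_region`, `qc`, and (with `out_dir`) `manifest`.
#' @export
run_pipeline <- function(video, config = analysis_config(), landmarks = NULL,
                         out_dir = NULL, roi_id = "roi") {
  stack <- if (inherits(video, "FrameStack")) video else read_stack(video)
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)

  al <- align_stack(stack, config)
  sd_raw <- sd_image(al$aligned)
  perf_raw <- cumulative_change_image(al$aligned)
  vessel_img <- normalize_to_dynamic_range(sd_raw, quiet = TRUE)
  perf_img <- normalize_to_dynamic_range(perf_raw, quiet = TRUE)

  enh <- enhance(vessel_img, config$gaussian_sigma_px)
  mask <- double_threshold(enh, config$local_window_px, config$local_offset,
                           config$min_speckle_px)
  seg <- network_segmentation(mask, params_used = config, check = FALSE)
  morph <- measure_network(seg, perf = perf_img,
                           pixel_size_um = stack$pixel_size_um,
                           roi_id = roi_id)

  total_perf <- sum(perf_raw$values)
  outside <- if (total_perf == 0) 0 else sum(perf_raw$values[!mask]) / total_perf

  qc <- list(displacement_trace = al$trace,
             reference_square = al$reference_square,
             valid_region = al$valid_region,
             perfusion_outside_mask_fraction = outside,
             params = unclass(config))

  area <- NULL
  if (!is.null(landmarks)) {
    area <- area_series(landmarks)
    dens <- lapply(landmarks, function(q) capillary_density(seg, q,
                                                            stack$pixel_size_um))
    dens <- do.call(rbind, dens)
    area$skel_len_density <- dens$skel_len_density
    area$area_fraction <- dens$area_fraction
  }

  res <- list(vessel_image = vessel_img, perfusion_image = perf_img,
              perfusion_rgb = pseudocolor(perf_img),
              segmentation = seg, morphometry = morph,
              trace = al$trace, valid_region = al$valid_region,
              area_dynamics = area, qc = qc)

  if (!is.null(out_dir)) {
    products <- list(vessel_image = vessel_img,
                     perfusion_image = perf_img,
                     perfusion_rgb = res$perfusion_rgb,
                     vessel_mask = seg$vessel_mask,
                     skeleton = seg$skeleton,
                     islands = seg$islands * 1.0,
                     morphometry = morph,
                     displacement_trace = al$trace)
    if (!is.null(area)) products$area_dynamics <- area
    res$manifest <- write_products(out_dir, products)
    jsonlite::write_json(
      list(perfusion_outside_mask_fraction = outside,
           reference_square = al$reference_square,
           valid_region = al$valid_region,
           params = unclass(config)),
      file.path(out_dir, "qc.json"), auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Compare morphometry records across timepoints
#'
#' Per-ROI differences and ratios of every numeric metric between two sets of
#' [measure_network()] records matched by `roi_id`. No inferential
#' statistics; ratios with a zero baseline are reported as missing values.
#'
#' @param records_t0,records_t1 data frames of morphometry records.
#' @return long data frame: `roi_id`, `metric`, `t0`, `t1`, `delta`, `ratio`.
#' @export
compare_timepoints <- function(records_t0, records_t1) {
  ids0 <- records_t0$roi_id; ids1 <- records_t1$roi_id
  un <- c(setdiff(ids0, ids1), setdiff(ids1, ids0))
  if (length(un))
    cm_validation_error(paste("unmatched roi_ids:", paste(un, collapse = ", ")))
  metrics <- setdiff(names(records_t0)[vapply(records_t0, is.numeric, logical(1))],
                     "timepoint_h")
  rows <- list()
  for (id in ids0) {
    r0 <- records_t0[records_t0$roi_id == id, , drop = FALSE]
    r1 <- records_t1[records_t1$roi_id == id, , drop = FALSE]
    for (mname in metrics) {
      v0 <- r0[[mname]][1]; v1 <- r1[[mname]][1]
      rows[[length(rows) + 1]] <- data.frame(
        roi_id = id, metric = mname, t0 = v0, t1 = v1,
        delta = v1 - v0,
        ratio = if (isTRUE(v0 == 0)) NA_real_ else v1 / v0,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
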