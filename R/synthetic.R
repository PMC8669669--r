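#' Synthetic CAM mesh scenes
#'
#' Generates a ground-truthed synthetic chorioallantoic-membrane scene: a
#' jittered polygonal capillary mesh enclosing avascular tissue islands, with
#' phase presets that mimic the four stages of coalescent remodeling observed
#' in vivo:
#'
#' * `"I"` (isotropic mesh): near-uniform capillary diameters and flows,
#'   polygonal islands of even size.
#' * `"II"` (preferential pathway): one horizontal chain of capillaries with
#'   increased diameter and flow; islands along it shrink.
#' * `"III"` (emergent vessel): the pathway merges into a single wide
#'   channel; islands along it are eliminated except two residual "pillar"
#'   islands inside the channel.
#' * `"IV"` (established vessel): a wider channel with no residual islands
#'   and enlarged islands in adjacent regions.
#'
#' @param frame_shape `c(H, W)` in pixels.
#' @param mean_island_diameter_px target island diameter (>= 4).
#' @param phase_preset `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param seed integer; scenes are deterministic given the seed.
#' @param capillary_diameter_px base capillary diameter.
#' @param margin blank border kept free of scene content (accommodates
#'   drift during rendering).
#' @return a `SyntheticScene`: `segments` (list of `poly` 2-column
#'   `(row, col)` polyline, `diameter_px`, `flow_au`), `islands` (list of
#'   polygon matrices), `frame_shape`, `background_intensity`,
#'   `vessel_absorbance`, `main_band` (0-based row interval containing the
#'   pathway/channel, used for perfusion-share summaries), `path_zone` (the
#'   narrower row interval of the two cell rows the pathway eliminates),
#'   `phase`, `seed`.
#' @export
generate_mesh_scene <- function(frame_shape = c(512L, 512L),
                                mean_island_diameter_px = 24,
                                phase_preset = c("I", "II", "III", "IV"),
                                seed = 1L,
                                capillary_diameter_px = 4,
                                margin = 16L) {
  phase_preset <- match.arg(phase_preset)
  H <- frame_shape[1]; W <- frame_shape[2]
  if (mean_island_diameter_px < 4)
    cm_validation_error("mean_island_diameter_px must be >= 4")
  gap <- 1.5
  d0 <- capillary_diameter_px
  pitch <- mean_island_diameter_px + d0 + 2 * gap
  nr <- floor((H - 2 * margin) / pitch)
  nc <- floor((W - 2 * margin) / pitch)
  if (nr < 4 || nc < 4)
    cm_validation_error("island diameter too large for the frame (need a >= 4 x 4 cell mesh)")

  with_seed(seed, {
    # jittered lattice vertices (0-based real coordinates)
    VR <- outer(0:nr, rep(1, nc + 1)) * pitch + margin +
      matrix(runif((nr + 1) * (nc + 1), -0.12, 0.12) * pitch, nr + 1)
    VC <- outer(rep(1, nr + 1), 0:nc) * pitch + margin +
      matrix(runif((nr + 1) * (nc + 1), -0.12, 0.12) * pitch, nr + 1)

    mi <- ceiling((nr + 1) / 2)  # vertex row of the preferential pathway
    segments <- list()
    add_seg <- function(p1, p2, diameter, flow, on_path = FALSE) {
      segments[[length(segments) + 1]] <<- list(
        poly = rbind(p1, p2), diameter_px = diameter, flow_au = flow,
        on_path = on_path)
    }
    # capillary flow declines as flow concentrates in the maturing vessel
    cap_flow <- c(I = 1, II = 1, III = 0.7, IV = 0.4)[[phase_preset]]
    for (i in 1:(nr + 1)) for (j in 1:nc) {   # horizontal edges
      on_path <- (i == mi)
      if (on_path && phase_preset %in% c("III", "IV")) next  # merged into channel
      dj <- d0 * runif(1, 0.95, 1.05); fl <- cap_flow * runif(1, 0.9, 1.1)
      if (on_path && phase_preset == "II") { dj <- dj * 1.8; fl <- fl * 3 }
      add_seg(c(VR[i, j], VC[i, j]), c(VR[i, j + 1], VC[i, j + 1]), dj, fl, on_path)
    }
    # phase IV: pairs of islands in the rows flanking the vessel merge as the
    # capillary wall between them regresses ("enlarged in adjacent regions")
    merged_rows <- if (phase_preset == "IV") c(mi - 2, mi + 1) else integer(0)
    merged_walls <- function(i, j)  # vertical wall between cells (i, j-1) and (i, j)
      i %in% merged_rows && j %% 2 == 0 && j <= nc
    for (i in 1:nr) for (j in 1:(nc + 1)) {   # vertical edges
      if (merged_walls(i, j)) next
      dj <- d0 * runif(1, 0.95, 1.05); fl <- cap_flow * runif(1, 0.9, 1.1)
      add_seg(c(VR[i, j], VC[i, j]), c(VR[i + 1, j], VC[i + 1, j]), dj, fl)
    }
    if (phase_preset %in% c("III", "IV")) {   # coalesced channel along row mi
      chan_d <- if (phase_preset == "III") 2 * pitch + d0 else 2 * pitch + 3 * d0
      chan_flow <- if (phase_preset == "III") 6 else 10
      chain <- cbind(VR[mi, ], VC[mi, ])
      segments[[length(segments) + 1]] <- list(
        poly = chain, diameter_px = chan_d, flow_au = chan_flow, on_path = TRUE)
    }

    # islands: one shrunken polygon per lattice cell
    islands <- list()
    in_band <- function(i) i %in% c(mi - 1, mi)  # cell rows adjacent to row mi
    shrink_poly <- function(poly, shrink) {
      ctr <- colMeans(poly)
      dirs <- sweep(poly, 2, ctr)
      lens <- sqrt(rowSums(dirs^2))
      sweep(dirs * pmax(0, 1 - shrink / lens), 2, ctr, "+")
    }
    for (i in 1:nr) {
      j <- 1
      while (j <= nc) {
        if (in_band(i) && phase_preset %in% c("III", "IV")) { j <- j + 1; next }
        if (i %in% merged_rows && j %% 2 == 1 && j + 1 <= nc) {
          # double-width island spanning the merged cell pair
          poly <- rbind(c(VR[i, j], VC[i, j]),
                        c(VR[i, j + 2], VC[i, j + 2]),
                        c(VR[i + 1, j + 2], VC[i + 1, j + 2]),
                        c(VR[i + 1, j], VC[i + 1, j]))
          islands[[length(islands) + 1]] <- shrink_poly(poly, d0 / 2 + gap)
          j <- j + 2
          next
        }
        poly <- rbind(c(VR[i, j], VC[i, j]),
                      c(VR[i, j + 1], VC[i, j + 1]),
                      c(VR[i + 1, j + 1], VC[i + 1, j + 1]),
                      c(VR[i + 1, j], VC[i + 1, j]))
        shrink <- d0 / 2 + gap
        if (phase_preset == "II" && in_band(i)) shrink <- shrink + 0.15 * pitch
        islands[[length(islands) + 1]] <- shrink_poly(poly, shrink)
        j <- j + 1
      }
    }
    if (phase_preset == "III") {              # two residual pillar islands
      band_r <- mean(VR[mi, ])
      for (jc in round(c(nc / 3, 2 * nc / 3))) {
        cc <- mean(VC[, jc + 1])
        s <- mean_island_diameter_px / 4
        islands[[length(islands) + 1]] <-
          rbind(c(band_r - s, cc), c(band_r, cc + s),
                c(band_r + s, cc), c(band_r, cc - s))
      }
    }

    center <- margin + (mi - 1) * pitch
    band_half <- 1.5 * pitch     # covers the widest (phase IV) channel + jitter
    band0 <- center - band_half
    band1 <- center + band_half
    # the pathway zone proper: the two cell rows whose islands the emerging
    # vessel eliminates (narrower than the perfusion band)
    path_zone <- c(center - pitch, center + pitch)
    structure(list(segments = segments, islands = islands,
                   frame_shape = as.integer(c(H, W)),
                   background_intensity = 200,
                   vessel_absorbance = 160,
                   capillary_diameter_px = d0,
                   main_band = c(max(0, band0), min(H, band1)),
                   path_zone = c(max(0, path_zone[1]), min(H, path_zone[2])),
                   phase = phase_preset, seed = as.integer(seed),
                   pitch = pitch, margin = as.integer(margin)),
              class = "SyntheticScene")
  })
}

#' @export
print.SyntheticScene <- function(x, ...) {
  cat(sprintf("SyntheticScene (phase %s): %d x %d px, %d segments, %d islands\n",
              x$phase, x$frame_shape[1], x$frame_shape[2],
              length(x$segments), length(x$islands)))
  invisible(x)
}

#' Rendering parameters for synthetic videos
#'
#' Defaults emulate the recording protocol the pipeline targets: 4 s at
#' 50 fps (200 frames), red cells as dark absorbance particles whose contrast
#' is inversely related to vessel diameter, low-amplitude Gaussian intensity
#' flicker restricted to avascular tissue, additive sensor noise, and
#' scripted global in-plane drift.
#'
#' @param n_frames number of frames (>= 2).
#' @param rbc_density_per_px particles per px^3 of lumen volume (length x
#'   diameter^2, the blood column being roughly as deep as the vessel is
#'   wide); with per-particle contrast inversely related to diameter this
#'   keeps mean absorbance consistent across calibers while the smallest
#'   vessels fluctuate most.
#' @param rbc_speed_px_per_frame base particle speed; scaled per segment by
#'   its flow.
#' @param drift_script `n_frames x 2` integer `(d_row, d_col)` per-frame
#'   scene displacement, or `NULL` for none.
#' @param tissue_flicker_sd SD of tissue flicker (intensity units).
#' @param sensor_noise_sd SD of sensor noise (intensity units).
#' @param static_texture_sd SD of the static spatial texture (smoothed random
#'   field emulating tissue structure and uneven illumination; constant over
#'   time, so it anchors registration without affecting any temporal
#'   statistic).
#' @param seed integer seed; renders are bit-identical given scene + params.
#' @return a `RenderParams` list.
#' @export
render_params <- function(n_frames = 200L, rbc_density_per_px = 0.025,
                          rbc_speed_px_per_frame = 1.5, drift_script = NULL,
                          tissue_flicker_sd = 1.5, sensor_noise_sd = 2,
                          static_texture_sd = 8, seed = 1L) {
  if (n_frames < 2) cm_validation_error("n_frames must be >= 2")
  if (tissue_flicker_sd < 0 || sensor_noise_sd < 0 || rbc_density_per_px < 0)
    cm_validation_error("noise and density parameters must be non-negative")
  if (!is.null(drift_script)) {
    drift_script <- matrix(as.integer(round(drift_script)), ncol = 2)
    if (nrow(drift_script) != n_frames)
      cm_validation_error("drift_script must have one (d_row, d_col) row per frame")
  }
  structure(list(n_frames = as.integer(n_frames),
                 rbc_density_per_px = rbc_density_per_px,
                 rbc_speed_px_per_frame = rbc_speed_px_per_frame,
                 drift_script = drift_script,
                 tissue_flicker_sd = tissue_flicker_sd,
                 sensor_noise_sd = sensor_noise_sd,
                 static_texture_sd = static_texture_sd,
                 seed = as.integer(seed)),
            class = "RenderParams")
}

## Rasterize the true lumen of a scene onto a canvas of dims `d`, with an
## optional coordinate offset; residual island polygons are carved out.
render_truth_lumen <- function(scene, d, offset = 0) {
  lum <- matrix(FALSE, d[1], d[2])
  for (s in scene$segments) {
    lum <- .stroke_segment_cpp(lum, s$poly + offset, s$diameter_px / 2)
  }
  for (poly in scene$islands) {
    lum[rasterize_polygon(poly + offset, d)] <- FALSE
  }
  lum
}

## Label raster of ground-truth islands (frame coordinates).
render_truth_islands <- function(scene) {
  d <- scene$frame_shape
  lab <- matrix(0L, d[1], d[2])
  for (k in seq_along(scene$islands)) {
    lab[rasterize_polygon(scene$islands[[k]], d)] <- k
  }
  structure(lab, n = length(scene$islands))
}

#' Render a synthetic CAM video
#'
#' Renders the scene as a bright-background absorbance video: discrete dark
#' particles are advected along each segment at flow-scaled speed with
#' per-particle contrast inversely related to the segment diameter (so the
#' smallest vessels fluctuate most, as red cells do), global integer drift is
#' applied per frame from the script, zero-mean Gaussian flicker is added in
#' avascular tissue, and sensor noise everywhere. Intensities are quantized
#' to the 8-bit range `[0, 255]`.
#'
#' @param scene a [generate_mesh_scene()] scene.
#' @param params a [render_params()].
#' @return list with `stack` (a [frame_stack()]), and `truth`: `vessel_mask`
#'   and `islands` rasters in pre-drift frame coordinates, `drift_script`,
#'   and the `scene`.
#' @export
render_video <- function(scene, params = render_params()) {
  stopifnot(inherits(scene, "SyntheticScene"), inherits(params, "RenderParams"))
  H <- scene$frame_shape[1]; W <- scene$frame_shape[2]
  TT <- params$n_frames
  drift <- params$drift_script
  if (is.null(drift)) drift <- matrix(0L, TT, 2)
  m <- max(abs(drift), 0L)
  if (m > scene$margin)
    cm_validation_error(sprintf(
      "drift (max %d px) exceeds the scene margin (%d px): scene would leave the frame",
      m, scene$margin))

  wd <- c(H + 2 * m, W + 2 * m)
  world_lumen <- render_truth_lumen(scene, wd, offset = m)
  truth_mask <- world_lumen[m + seq_len(H), m + seq_len(W)]
  truth_islands <- render_truth_islands(scene)

  # static absorbance of the blood column: faint in capillaries, clearly
  # visible in wide vessels (still frames show mainly the largest vessels)
  base <- matrix(scene$background_intensity, wd[1], wd[2])
  for (s in scene$segments) {
    sl <- .stroke_segment_cpp(matrix(FALSE, wd[1], wd[2]), s$poly + m,
                              s$diameter_px / 2)
    base[sl] <- scene$background_intensity - min(6 + s$diameter_px / 2, 25)
  }
  base[!world_lumen] <- scene$background_intensity  # carved islands are tissue

  frames <- array(0, dim = c(H, W, TT))
  with_seed(params$seed, {
    if (params$static_texture_sd > 0) {
      tex <- sep_convolve(matrix(rnorm(wd[1] * wd[2]), wd[1], wd[2]),
                          gaussian_kernel_1d(3))
      base <- base + tex * (params$static_texture_sd / stats::sd(tex))
    }
    # particle populations, fixed at t = 0
    pl <- list(ar = numeric(0), ac = numeric(0), ur = numeric(0), uc = numeric(0),
               s0 = numeric(0), sp = numeric(0), len = numeric(0),
               off = numeric(0), rad = numeric(0), amp = numeric(0))
    for (s in scene$segments) {
      poly <- s$poly
      dir <- sample(c(-1, 1), 1)  # flow direction alternates across the mesh
      for (e in seq_len(nrow(poly) - 1)) {
        a <- poly[e, ]; b <- poly[e + 1, ]
        len <- sqrt(sum((b - a)^2))
        if (len == 0) next
        # particle count scales sub-quadratically with caliber: the optical
        # column saturates (Beer-Lambert), so very wide vessels contribute
        # fewer *resolvable* absorbance particles per unit volume
        d0 <- scene$capillary_diameter_px
        lambda <- params$rbc_density_per_px * len * s$diameter_px^1.75 * d0^0.25
        np <- rpois(1, lambda)
        # every rendered segment is perfused (fields of view are chosen so):
        # floor the count to avoid transiently empty capillaries
        if (lambda > 0) np <- max(np, min(3L, ceiling(lambda)))
        if (np == 0) next
        u <- (b - a) / len
        nv <- c(-u[2], u[1])
        rad <- min(s$diameter_px / 2, 1.6)
        pl$ar <- c(pl$ar, rep(a[1], np)); pl$ac <- c(pl$ac, rep(a[2], np))
        pl$ur <- c(pl$ur, rep(u[1], np)); pl$uc <- c(pl$uc, rep(u[2], np))
        pl$s0 <- c(pl$s0, runif(np, 0, len))
        pl$sp <- c(pl$sp, rep(dir * params$rbc_speed_px_per_frame * s$flow_au, np))
        pl$len <- c(pl$len, rep(len, np))
        lat <- runif(np, -1, 1) * max(0, s$diameter_px / 2 - rad / 2)
        pl$off <- c(pl$off, lat)
        # lateral offsets are fixed per particle; store offset vector parts
        pl$ar[length(pl$ar) - np + seq_len(np)] <-
          a[1] + lat * nv[1]
        pl$ac[length(pl$ac) - np + seq_len(np)] <-
          a[2] + lat * nv[2]
        pl$rad <- c(pl$rad, rep(rad, np))
        # contrast inversely related to diameter (sub-linearly, so wide
        # vessels keep a net perfusion signal despite weaker fluctuation)
        d0 <- scene$capillary_diameter_px
        amp <- (scene$vessel_absorbance / d0) * (d0 / s$diameter_px)^0.4
        pl$amp <- c(pl$amp, rep(min(amp, 60), np))
      }
    }
    for (t in seq_len(TT)) {
      img <- base
      if (length(pl$s0)) {
        s <- (pl$s0 + (t - 1) * pl$sp) %% pl$len
        pr <- pl$ar + s * pl$ur + m
        pc <- pl$ac + s * pl$uc + m
        img <- .stamp_particles_cpp(img, pr, pc, pl$rad, pl$amp)
      }
      # content displaced by +drift[t] relative to frame 0 = window at -drift
      fr <- img[m - drift[t, 1] + seq_len(H), m - drift[t, 2] + seq_len(W)]
      if (params$tissue_flicker_sd > 0) {
        tis <- !world_lumen[m - drift[t, 1] + seq_len(H),
                            m - drift[t, 2] + seq_len(W)]
        fr[tis] <- fr[tis] + rnorm(sum(tis), 0, params$tissue_flicker_sd)
      }
      if (params$sensor_noise_sd > 0)
        fr <- fr + rnorm(H * W, 0, params$sensor_noise_sd)
      frames[, , t] <- pmin(pmax(round(fr), 0), 255)
    }
  })
  list(stack = frame_stack(frames, frame_rate_hz = 50),
       truth = list(vessel_mask = truth_mask, islands = truth_islands,
                    drift_script = drift, scene = scene))
}

#' Recovery scores of a segmentation against simulator ground truth
#'
#' @param truth the `truth` element returned by [render_video()].
#' @param seg a [network_segmentation()] on the same (or cropped) grid; if
#'   `valid_region` is given the truth rasters are cropped to it first.
#' @param trace optional displacement trace (data frame with `d_row`,
#'   `d_col`) to score against the drift script.
#' @param valid_region 0-based half-open `c(row0, row1, col0, col1)` crop.
#' @return list: `dice` of the vessel mask, `island_count_error`
#'   (recovered - true), `island_jaccard` (per true island, best-match), and
#'   `displacement_rmse` (NA without a trace).
#' @export
truth_metrics <- function(truth, seg, trace = NULL, valid_region = NULL) {
  tmask <- truth$vessel_mask
  tisl <- truth$islands
  if (!is.null(valid_region)) {
    vr <- valid_region
    tmask <- tmask[(vr[1] + 1):vr[2], (vr[3] + 1):vr[4]]
    tisl <- tisl[(vr[1] + 1):vr[2], (vr[3] + 1):vr[4]]
  }
  smask <- seg$vessel_mask
  if (!all(dim(smask) == dim(tmask)))
    cm_validation_error("segmentation and truth shapes disagree")
  inter <- sum(smask & tmask)
  denom <- sum(smask) + sum(tmask)
  dice <- if (denom == 0) 1 else 2 * inter / denom

  tl <- sort(unique(tisl[tisl > 0]))
  jac <- vapply(tl, function(k) {
    tk <- tisl == k
    cand <- seg$islands[tk]
    cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    best <- as.integer(names(which.max(table(cand))))
    sk <- seg$islands == best
    sum(tk & sk) / sum(tk | sk)
  }, numeric(1))

  n_seg <- attr(seg$islands, "n")
  if (is.null(n_seg)) n_seg <- length(unique(seg$islands[seg$islands > 0]))
  rmse <- NA_real_
  if (!is.null(trace)) {
    d <- cbind(trace$d_row, trace$d_col) - truth$drift_script
    rmse <- sqrt(mean(d^2))
  }
  list(dice = dice,
       island_count_error = n_seg - length(tl),
       island_jaccard = jac,
       displacement_rmse = rmse)
}

#' Ground-truth summary of a scene
#'
#' Descriptors computed from the generated geometry (no rendering):
#' segment-diameter CV, island count and island-area CV (polygon areas via
#' the shoelace formula), and the number of islands intersecting the
#' pathway/channel band.
#'
#' @param scene a [generate_mesh_scene()] scene.
#' @return one-row data frame.
#' @export
scene_summary <- function(scene) {
  diams <- vapply(scene$segments, function(s) s$diameter_px, numeric(1))
  poly_area <- function(p) {
    n <- nrow(p); j <- c(2:n, 1)
    abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  }
  areas <- vapply(scene$islands, poly_area, numeric(1))
  ctr_r <- vapply(scene$islands, function(p) mean(p[, 1]), numeric(1))
  band <- scene$path_zone
  data.frame(phase = scene$phase,
             diam_cv = cv(diams),
             n_islands = length(areas),
             island_area_cv = cv(areas),
             n_islands_in_band = sum(ctr_r >= band[1] & ctr_r < band[2]),
             stringsAsFactors = FALSE)
}
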