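#' Read a video into a FrameStack
#'
#' Reads a multi-page TIFF or an uncompressed AVI. Integer data are promoted
#' to double on their native scale (an 8-bit TIFF yields values 0-255, not
#' 0-1); RGB frames are converted to luminance with Rec. 601 weights.
#'
#' @param path video file.
#' @param fmt `"tiff"`, `"avi"`, or `"auto"` (by file extension, falling back
#'   to content sniffing).
#' @param pixel_size_um,frame_rate_hz optional metadata attached to the stack.
#' @return a [frame_stack()].
#' @export
read_stack <- function(path, fmt = c("auto", "tiff", "avi"),
                       pixel_size_um = NULL, frame_rate_hz = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) cm_input_error(paste("cannot read video:", path))
  if (fmt == "auto") {
    ext <- tolower(tools::file_ext(path))
    fmt <- if (ext %in% c("tif", "tiff")) "tiff"
           else if (ext == "avi") "avi"
           else {
             magic <- readBin(path, "raw", 4)
             if (identical(rawToChar(magic), "RIFF")) "avi" else "tiff"
           }
  }
  if (fmt == "avi") {
    st <- read_avi_stack(path)
    if (!is.null(pixel_size_um)) st$pixel_size_um <- pixel_size_um
    if (!is.null(frame_rate_hz)) st$frame_rate_hz <- frame_rate_hz
    return(st)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e)
                      cm_input_error(paste("cannot decode TIFF:", path)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2)
    cm_validation_error(paste("video has fewer than 2 frames:", path))
  dims <- lapply(pages, function(p) dim(p)[1:2])
  if (length(unique(dims)) != 1)
    cm_validation_error(paste("inconsistent frame sizes in:", path))
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) {
      if (dim(p)[3] < 3) p[, , 1]
      else rgb_to_luminance(p[, , 1], p[, , 2], p[, , 3])
    } else p
  })
  frame_stack(frames, pixel_size_um = pixel_size_um, frame_rate_hz = frame_rate_hz)
}

## Quantize a [0,1] image to 16 bits and write a lossless TIFF.
write_tiff16 <- function(img, path) {
  img <- pmin(pmax(img, 0), 1)
  tiff::writeTIFF(round(img * 65535) / 65535, path, bits.per.sample = 16,
                  compression = "none")
  path
}

read_tiff16 <- function(path) {
  tiff::readTIFF(path, as.is = TRUE)
}

write_png8 <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  path
}

#' Write pipeline products to a directory
#'
#' Accepts a named list mixing `ProjectionImage`s (written as 8-bit PNG plus
#' lossless 16-bit TIFF; raw-scale images are unit-normalized first and the
#' scale factor recorded), logical masks and integer label images (TIFF),
#' data frames (CSV with header), and RGB arrays (PNG).
#'
#' @param out_dir output directory, created if needed.
#' @param products named list of products.
#' @return data frame manifest (`name`, `type`, `path`, `scale_max`), also
#'   written to `manifest.csv` in `out_dir`.
#' @export
write_products <- function(out_dir, products = list()) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    cm_io_error(paste("cannot write to directory:", out_dir))
  rows <- list()
  add <- function(name, type, path, scale_max = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, type = type, path = path, scale_max = scale_max,
      stringsAsFactors = FALSE)
  }
  for (name in names(products)) {
    p <- products[[name]]
    if (inherits(p, "ProjectionImage")) {
      scale_max <- NA_real_
      if (p$norm == "raw") {
        scale_max <- max(p$values)
        p <- normalize_to_dynamic_range(p, quiet = TRUE)
      }
      tp <- file.path(out_dir, paste0(name, ".tif"))
      pp <- file.path(out_dir, paste0(name, ".png"))
      write_tiff16(p$values, tp)
      write_png8(p$values, pp)
      add(name, paste0("projection_", p$kind), tp, scale_max)
      add(name, paste0("projection_", p$kind, "_png"), pp, scale_max)
    } else if (is.data.frame(p)) {
      cp <- file.path(out_dir, paste0(name, ".csv"))
      write.csv(p, cp, row.names = FALSE)
      add(name, "table", cp)
    } else if (is.logical(p) && is.matrix(p)) {
      tp <- file.path(out_dir, paste0(name, ".tif"))
      write_tiff16(p * 1.0, tp)
      add(name, "mask", tp)
    } else if (is.matrix(p) && is.numeric(p)) {
      tp <- file.path(out_dir, paste0(name, ".tif"))
      write_tiff16(p / 65535, tp)  # integer labels stored verbatim in 16 bits
      add(name, "labels", tp)
    } else if (is.array(p) && length(dim(p)) == 3) {
      pp <- file.path(out_dir, paste0(name, ".png"))
      png::writePNG(pmin(pmax(p, 0), 1), pp)
      add(name, "rgb", pp)
    } else {
      cm_validation_error(paste("unrecognized product type for:", name))
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows)
    else data.frame(name = character(), type = character(),
                    path = character(), scale_max = numeric())
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a landmark CSV into LandmarkQuads
#'
#' Expected columns: `timepoint_h`, `point_index` (0-3), `row`, `col`
#' (0-based pixel coordinates).
#'
#' @param path CSV file.
#' @return list of [landmark_quad()] ordered by timepoint.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) cm_input_error(paste("landmark file not found:", path))
  df <- read.csv(path)
  need <- c("timepoint_h", "point_index", "row", "col")
  if (!all(need %in% names(df)))
    cm_validation_error(paste("landmark CSV must have columns:",
                              paste(need, collapse = ", ")))
  tps <- sort(unique(df$timepoint_h))
  lapply(tps, function(tp) {
    sub <- df[df$timepoint_h == tp, ]
    sub <- sub[order(sub$point_index), ]
    if (nrow(sub) != 4 || !identical(as.integer(sub$point_index), 0:3))
      cm_validation_error(sprintf(
        "timepoint %g must have exactly point_index 0..3", tp))
    landmark_quad(cbind(sub$row, sub$col), timepoint_h = tp)
  })
}
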