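#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline. All coordinates are
#' 0-based `(row, col)`; `reference_square` is `c(row, col, size)` naming the
#' top-left corner and side length of the registration reference square
#' (256 and 512 are the conventional sizes for full-resolution recordings;
#' any size that fits the frame is accepted).
#'
#' @param reference_square integer `c(row, col, size)`, or `NULL` to select
#'   the highest-contrast square automatically during alignment.
#' @param reference_size side length used when `reference_square` is `NULL`.
#' @param max_shift_px search radius (pixels) around the previous frame's
#'   displacement; also bounds the absolute per-frame displacement.
#' @param gaussian_sigma_px Gaussian enhancement sigma in pixels.
#' @param local_window_px odd window (pixels) of the local mean threshold.
#' @param local_offset subtracted from the local mean to form the local
#'   threshold (`pixel > local_mean - local_offset`); on unit-normalized
#'   images a small negative value places the threshold just above the
#'   local mean.
#' @param min_island_area_px smallest tissue island kept, in pixels.
#' @param morph_radius_px disk radius of the island-cleaning opening.
#' @param min_speckle_px vessel-mask specks smaller than this are pruned.
#' @param min_peak_corr registration fails on a frame whose best correlation
#'   falls below this (catches drift beyond `max_shift_px` or lost focus).
#' @param seed integer seed for any randomized steps.
#' @return an `AnalysisConfig` list.
#' @export
analysis_config <- function(reference_square = NULL,
                            reference_size = 256L,
                            max_shift_px = 4L,
                            gaussian_sigma_px = 1,
                            local_window_px = 51L,
                            local_offset = -0.02,
                            min_island_area_px = 25L,
                            morph_radius_px = 2L,
                            min_speckle_px = 20L,
                            min_peak_corr = 0.3,
                            seed = 1L) {
  if (local_window_px < 3 || local_window_px %% 2 == 0)
    cm_validation_error("local_window_px must be odd and >= 3")
  if (gaussian_sigma_px <= 0) cm_validation_error("gaussian_sigma_px must be > 0")
  if (max_shift_px < 0) cm_validation_error("max_shift_px must be >= 0")
  if (min_island_area_px < 1) cm_validation_error("min_island_area_px must be >= 1")
  if (morph_radius_px < 1) cm_validation_error("morph_radius_px must be >= 1")
  if (!is.null(reference_square)) {
    reference_square <- as.integer(reference_square)
    if (length(reference_square) != 3 || any(reference_square < 0) ||
        reference_square[3] < 2)
      cm_validation_error("reference_square must be c(row, col, size), 0-based")
  }
  structure(list(reference_square = reference_square,
                 reference_size = as.integer(reference_size),
                 max_shift_px = as.integer(max_shift_px),
                 gaussian_sigma_px = gaussian_sigma_px,
                 local_window_px = as.integer(local_window_px),
                 local_offset = local_offset,
                 min_island_area_px = as.integer(min_island_area_px),
                 morph_radius_px = as.integer(morph_radius_px),
                 min_speckle_px = as.integer(min_speckle_px),
                 min_peak_corr = min_peak_corr,
                 seed = as.integer(seed)),
            class = "AnalysisConfig")
}

## Check the reference square against a frame; errors if out of bounds.
validate_reference_square <- function(sq, frame_dim) {
  if (sq[1] < 0 || sq[2] < 0 ||
      sq[1] + sq[3] > frame_dim[1] || sq[2] + sq[3] > frame_dim[2])
    cm_validation_error(sprintf(
      "reference square (%d, %d, size %d) does not fit a %d x %d frame",
      sq[1], sq[2], sq[3], frame_dim[1], frame_dim[2]))
  invisible(sq)
}

#' Read a flat TOML-style key/value config file
#'
#' Supports the flat subset of TOML used by the package: `key = value` lines,
#' `#` comments, quoted strings, numbers, booleans, and bracketed numeric
#' arrays like `reference_square = [10, 20, 256]`.
#'
#' @param path config file path.
#' @return named list of parsed values.
#' @export
read_config_file <- function(path) {
  if (!file.exists(path)) cm_input_error(paste("config file not found:", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3)
      cm_input_error(paste("cannot parse config line:", ln))
    key <- m[2]; val <- trimws(m[3])
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (grepl("^\\[.*\\]$", val)) {
    inner <- trimws(strsplit(substr(val, 2, nchar(val) - 1), ",")[[1]])
    return(vapply(inner, function(v) as.numeric(v), numeric(1), USE.NAMES = FALSE))
  }
  if (grepl('^".*"$', val)) return(substr(val, 2, nchar(val) - 1))
  if (val %in% c("true", "false")) return(val == "true")
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

#' Build an AnalysisConfig from a config file plus overrides
#'
#' @param path optional config file (see [read_config_file()]).
#' @param ... individual [analysis_config()] arguments overriding file keys.
#' @return an `AnalysisConfig`.
#' @export
load_analysis_config <- function(path = NULL, ...) {
  vals <- if (is.null(path)) list() else read_config_file(path)
  dots <- list(...)
  vals[names(dots)] <- dots
  keep <- intersect(names(vals), names(formals(analysis_config)))
  do.call(analysis_config, vals[keep])
}
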