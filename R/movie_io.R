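#' Construct a movie stack
#'
#' A `movie_stack` holds an ordered single-channel time-lapse movie as a
#' 3-D array of camera counts together with its acquisition calibration.
#' Frame index `k` (0-based) maps to time `t = origin_time + k * frame_interval`.
#'
#' @param frames numeric or integer array with dimensions
#'   `(n_frames, height, width)`; camera counts, non-negative.
#' @param frame_interval time between consecutive frames in seconds (> 0).
#' @param pixel_size optional pixel size in micrometres.
#' @param origin_time acquisition time of frame 0 in seconds.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(frames, frame_interval, pixel_size = NULL,
                        origin_time = 0) {
  if (length(dim(frames)) != 3L)
    stop("`frames` must be a 3-D array (frame, row, col)")
  if (dim(frames)[1] < 2L)
    stop("a movie stack needs at least 2 frames")
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("`frame_interval` must be a single positive number of seconds")
  structure(
    list(frames = frames, frame_interval = as.numeric(frame_interval),
         pixel_size = pixel_size, origin_time = as.numeric(origin_time)),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack: %d frames of %d x %d px, dt = %g s, span %g s\n",
              d[1], d[2], d[3], x$frame_interval, frame_time(x, d[1] - 1L)))
  invisible(x)
}

#' Number of frames in a stack
#' @param stack a `movie_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[1]

#' Acquisition time of a frame
#' @param stack a `movie_stack`.
#' @param frame 0-based frame index (vectorized).
#' @return time in seconds.
#' @export
frame_time <- function(stack, frame) stack$origin_time + frame * stack$frame_interval

#' Read a multi-page TIFF into a movie stack
#'
#' Pages are taken in file order as consecutive frames. 16-bit (and 8-bit)
#' unsigned grayscale input is preserved losslessly as integer counts.
#'
#' @param path path to a multi-page grayscale TIFF.
#' @param frame_interval frame interval in seconds.
#' @param pixel_size optional pixel size in micrometres.
#' @return a `movie_stack`.
#' @export
read_stack <- function(path, frame_interval, pixel_size = NULL) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("stack at ", path, " has a single frame; a movie needs >= 2")
  shp <- dim(pages[[1]])
  if (length(shp) != 2L)
    stop("expected single-channel grayscale pages in ", path)
  ok <- vapply(pages, function(p) identical(dim(p), shp), logical(1))
  if (!all(ok))
    stop("inconsistent page shapes in ", path, " (first bad page: ",
         which(!ok)[1], ")")
  frames <- array(0L, dim = c(length(pages), shp[1], shp[2]))
  for (k in seq_along(pages)) frames[k, , ] <- pages[[k]]
  movie_stack(frames, frame_interval, pixel_size = pixel_size)
}

#' Write a movie stack as a multi-page 16-bit TIFF
#'
#' Page `k` of the file is frame `k` of the stack. Values must already be
#' integers representable in 16 bits; out-of-range values are an error, not
#' clipped, so that a written file always round-trips exactly.
#'
#' @param stack a `movie_stack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "movie_stack"))
  fr <- stack$frames
  if (any(fr < 0) || any(fr > 65535))
    stop("frame values outside the unsigned 16-bit range [0, 65535]")
  pages <- lapply(seq_len(dim(fr)[1]), function(k) round(fr[k, , ]) / 65535)
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                        compression = "none")
  if (ok != length(pages)) stop("failed writing all pages to ", path)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

#' Default analysis configuration
#'
#' Central container for every tunable of the analysis pipeline. The
#' defaults encode the standard operating point: responders must show a
#' >500 % fold-increase of intensity over their post-landing baseline
#' (`response_threshold = 5`), only cells landing within the first 300 s
#' are analyzed, and aligned time zero is placed 2 s after landing.
#'
#' @param response_threshold responder classification threshold on
#'   dI/I0 = (Imax - I0)/I0 (dimensionless fold-increase, > 0).
#' @param threshold_mode `"fold_over_baseline"` tests dI/I0 >
#'   `response_threshold`; the alternative reading `"ratio"` tests
#'   Imax/I0 > `response_threshold`.
#' @param landing_window latest admissible landing time, seconds.
#' @param align_offset seconds after landing that define aligned time 0.
#' @param edge_margin_diameters minimum distance of a cell centroid from
#'   the image border, in units of that cell's own diameter.
#' @param window_frames Savitzky-Golay window length in frames (odd).
#' @param poly_order Savitzky-Golay polynomial order (< `window_frames`).
#' @param motion_stop_threshold maximum per-frame centroid displacement
#'   (pixels) still counted as stationary.
#' @param motion_stop_frames number of consecutive stationary frames that
#'   define a landing.
#' @param peak_min_prominence minimum prominence of the triggering peak in
#'   dR/dt (1/s); `NA` selects an adaptive per-cell value of 3 robust
#'   standard deviations of the pre-landing derivative.
#' @param decrease_fraction fraction of the above-baseline excursion that
#'   R(t) must shed after its maximum for a "subsequent decrease".
#' @param baseline_window_s seconds after landing used for the baseline
#'   intensity I0 (median); converted to samples at the trace's own
#'   sampling interval (at least one sample), so coarse re-sampled
#'   traces keep a short baseline instead of swallowing the transient.
#' @param refine_masks logical; refine each landed cell's mask once with
#'   distance-regularized level-set evolution and reuse it for all
#'   post-landing frames.
#' @param mean_r_responders_only average the aligned R(t) over responders
#'   only (default) or over all included cells.
#' @param dispersion `"sdm"` (standard deviation of the mean, SD/sqrt(n))
#'   or `"sd"` for population error bars.
#' @return an object of class `run_config` (a named list).
#' @export
run_config <- function(response_threshold = 5.0,
                       threshold_mode = c("fold_over_baseline", "ratio"),
                       landing_window = 300,
                       align_offset = 2,
                       edge_margin_diameters = 1,
                       window_frames = 7L,
                       poly_order = 2L,
                       motion_stop_threshold = 0.25,
                       motion_stop_frames = 8L,
                       peak_min_prominence = NA_real_,
                       decrease_fraction = 0.2,
                       baseline_window_s = 5,
                       refine_masks = TRUE,
                       mean_r_responders_only = TRUE,
                       dispersion = c("sdm", "sd")) {
  threshold_mode <- match.arg(threshold_mode)
  dispersion <- match.arg(dispersion)
  cfg <- list(
    response_threshold = response_threshold,
    threshold_mode = threshold_mode,
    landing_window = landing_window,
    align_offset = align_offset,
    edge_margin_diameters = edge_margin_diameters,
    window_frames = as.integer(window_frames),
    poly_order = as.integer(poly_order),
    motion_stop_threshold = motion_stop_threshold,
    motion_stop_frames = as.integer(motion_stop_frames),
    peak_min_prominence = peak_min_prominence,
    decrease_fraction = decrease_fraction,
    baseline_window_s = baseline_window_s,
    refine_masks = isTRUE(refine_masks),
    mean_r_responders_only = isTRUE(mean_r_responders_only),
    dispersion = dispersion)
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  if (cfg$response_threshold <= 0)
    stop("response_threshold must be > 0")
  if (cfg$window_frames %% 2L != 1L)
    stop("window_frames must be odd, got ", cfg$window_frames)
  if (cfg$window_frames <= cfg$poly_order)
    stop("window_frames must exceed poly_order")
  if (cfg$landing_window <= 0 || cfg$align_offset < 0)
    stop("landing_window must be > 0 and align_offset >= 0")
  if (cfg$motion_stop_frames < 1L || cfg$motion_stop_threshold <= 0)
    stop("motion_stop_frames >= 1 and motion_stop_threshold > 0 required")
  invisible(cfg)
}

#' Load an analysis configuration from YAML
#'
#' Flat keys mirror the arguments of [run_config()]. Unknown keys are an
#' error so that typos cannot silently fall back to a default. An empty
#' file yields the defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a `run_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("malformed config file: ", path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, raw)
}

#' Baseline window length in samples
#'
#' Converts the configured baseline duration (seconds after landing used
#' for the I0 median) into a sample count for a trace sampled at
#' interval `dt`, never fewer than one sample.
#'
#' @param config a [run_config()].
#' @param dt sampling interval of the trace, seconds.
#' @return integer sample count.
#' @export
baseline_samples <- function(config, dt) {
  max(1L, as.integer(round(config$baseline_window_s / dt)))
}
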