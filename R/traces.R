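# Per-cell intensity time courses: extraction, smoothing, resampling,
# normalization to R(t) = I(t)/Imax.

#' Construct a raw per-cell intensity trace
#'
#' @param cell_id cell identifier.
#' @param times sample times, seconds, strictly increasing.
#' @param intensities mean camera counts over the cell's mask per frame
#'   (non-negative).
#' @param n_pixels pixels contributing per frame.
#' @return an object of class `raw_trace`.
#' @export
raw_trace <- function(cell_id, times, intensities,
                      n_pixels = rep(NA_integer_, length(times))) {
  if (length(times) != length(intensities))
    stop("times and intensities must have equal length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(intensities < 0, na.rm = TRUE)) stop("intensities must be >= 0")
  structure(list(cell_id = cell_id, times = as.numeric(times),
                 intensities = as.numeric(intensities),
                 n_pixels = n_pixels),
            class = "raw_trace")
}

#' Extract a cell's mean-intensity trace from a movie
#'
#' Per frame, the intensity is the arithmetic mean of the movie values
#' over the cell's mask pixels. Frames where tracking coasted without a
#' mask are filled by linear interpolation of the intensity and flagged
#' with `n_pixels = 0`.
#'
#' @param stack a [movie_stack()].
#' @param record a `cell_record` with masks for its spanned frames.
#' @return a [raw_trace()].
#' @export
extract_trace <- function(stack, record) {
  frames <- record$frames
  nfr <- length(frames)
  nf <- dim(stack$frames)[1]
  ints <- rep(NA_real_, nfr)
  npx <- integer(nfr)
  for (j in seq_len(nfr)) {
    m <- record$masks[[j]]
    if (is.null(m) || length(m) == 0L) next
    # (frame, row, col) of array dims (nf, H, W): 3-D linear index is
    # frame + nf * (2-D frame index - 1)
    ints[j] <- mean(stack$frames[frames[j] + 1L + nf * (m - 1L)])
    npx[j] <- length(m)
  }
  if (all(is.na(ints)))
    stop("cell ", record$cell_id, " has no mask on any spanned frame")
  if (anyNA(ints)) {
    if (is.na(ints[1]) || is.na(ints[nfr])) {
      bad <- frames[c(which(is.na(ints)))][1]
      if (is.na(ints[1]) && is.na(ints[nfr]))
        stop("cell ", record$cell_id, ": empty mask at boundary frame ", bad)
    }
    ints <- stats::approx(seq_len(nfr)[!is.na(ints)], ints[!is.na(ints)],
                          xout = seq_len(nfr), rule = 2)$y
  }
  raw_trace(record$cell_id, frame_time(stack, frames), ints, npx)
}

#' Savitzky-Golay smoothing of a trace
#'
#' Each sample is replaced by the value, at its own position, of the
#' least-squares polynomial of degree `poly_order` fitted over the
#' centered window of `window_frames` samples; window ends are handled by
#' the boundary polynomial fits, so polynomials of degree up to
#' `poly_order` pass through unchanged everywhere, including the edges.
#'
#' @param trace a [raw_trace()].
#' @param window_frames odd window length, greater than `poly_order`.
#' @param poly_order polynomial degree.
#' @return a smoothed [raw_trace()].
#' @export
smooth_trace <- function(trace, window_frames = 7L, poly_order = 2L) {
  n <- length(trace$times)
  if (window_frames %% 2L != 1L) stop("window_frames must be odd")
  if (window_frames <= poly_order) stop("window_frames must exceed poly_order")
  if (n < window_frames)
    stop("trace of length ", n, " is shorter than the smoothing window ",
         window_frames)
  sm <- signal::sgolayfilt(trace$intensities, p = poly_order, n = window_frames)
  raw_trace(trace$cell_id, trace$times, pmax(sm, 0), trace$n_pixels)
}

#' Resample a trace to a different time resolution
#'
#' For a target interval that is an integer multiple `k` of the native
#' one, every `k`-th sample starting at the first is kept (decimation,
#' simulating a slower acquisition). For non-integer ratios the trace is
#' linearly interpolated onto a uniform grid spanning the original range.
#'
#' @param trace a [raw_trace()].
#' @param target_interval desired sampling interval, seconds.
#' @return a [raw_trace()] on the new grid.
#' @export
resample_trace <- function(trace, target_interval) {
  if (target_interval <= 0) stop("target_interval must be > 0")
  dt <- stats::median(diff(trace$times))
  k <- target_interval / dt
  if (abs(k - round(k)) < 1e-9) {
    k <- as.integer(round(k))
    sel <- seq(1L, length(trace$times), by = k)
    if (length(sel) < 4L)
      stop("resampled grid would have ", length(sel), " samples (< 4)")
    return(raw_trace(trace$cell_id, trace$times[sel], trace$intensities[sel],
                     trace$n_pixels[sel]))
  }
  grid <- seq(trace$times[1], trace$times[length(trace$times)],
              by = target_interval)
  if (length(grid) < 4L)
    stop("resampled grid would have ", length(grid), " samples (< 4)")
  y <- stats::approx(trace$times, trace$intensities, xout = grid)$y
  raw_trace(trace$cell_id, grid, y,
            rep(NA_integer_, length(grid)))
}

#' Normalize a trace to the relative response R(t) = I(t)/Imax
#'
#' `Imax` is the maximum of the trace; the baseline `I0` is the median
#' intensity over the `baseline_window` samples immediately after landing
#' (post-landing, pre-trigger: the cell is in focus but not yet
#' signaling), and `dI = Imax - I0`.
#'
#' @param trace a [raw_trace()] (typically smoothed).
#' @param baseline_window number of samples for the baseline median.
#' @param landing_time landing time in seconds; the baseline window
#'   starts at the first sample at or after it. `NULL` uses the trace
#'   start.
#' @return an object of class `normalized_trace` with fields `cell_id`,
#'   `times`, `R`, `I0`, `Imax`, `dI`.
#' @export
normalize_trace <- function(trace, baseline_window = 10L,
                            landing_time = NULL) {
  n <- length(trace$times)
  if (n == 0L) stop("empty trace")
  Imax <- max(trace$intensities)
  if (Imax <= 0) stop("Imax = 0; cannot normalize")
  start <- if (is.null(landing_time)) 1L
           else which(trace$times >= landing_time)[1]
  if (is.na(start)) start <- 1L
  win <- start:min(start + baseline_window - 1L, n)
  I0 <- stats::median(trace$intensities[win])
  structure(list(cell_id = trace$cell_id, times = trace$times,
                 R = trace$intensities / Imax,
                 I0 = I0, Imax = Imax, dI = Imax - I0),
            class = "normalized_trace")
}

#' Long-format table of processed traces
#'
#' @param raw,smoothed,normalized parallel lists of [raw_trace()]s and
#'   `normalized_trace`s (same cells, same grids).
#' @param frame_interval seconds per frame, to recover frame indices.
#' @return data.frame matching the `traces.csv` schema: `cell_id`,
#'   `frame`, `time_s`, `intensity_raw`, `intensity_smoothed`, `R`,
#'   `n_pixels`.
#' @export
traces_table <- function(raw, smoothed, normalized, frame_interval) {
  do.call(rbind, lapply(seq_along(raw), function(i) {
    tr <- raw[[i]]
    data.frame(cell_id = tr$cell_id,
               frame = as.integer(round(tr$times / frame_interval)),
               time_s = tr$times,
               intensity_raw = tr$intensities,
               intensity_smoothed = smoothed[[i]]$intensities,
               R = normalized[[i]]$R,
               n_pixels = tr$n_pixels)
  }))
}
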