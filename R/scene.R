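#' Configuration of a synthetic calcium-imaging scene
#'
#' Describes a ground-truth-annotated synthetic movie emulating
#' indicator-loaded non-excitable cells in suspension that land on a
#' stimulating surface and, with probability `responder_fraction`, fire a
#' single global calcium transient. Cells perform a random walk before
#' landing, stop dead at landing, and appear dimmer before landing (they
#' are out of the focal plane at the surface) by `landing_step_factor`.
#' A responder's mean intensity follows
#' `I0 + dI * g(t - t_trigger)` with `dI = amplitude_ratio * I0` and
#' `g(t) = (1 - exp(-t/rise_time)) * exp(-t/decay_time)`, normalized so
#' `max g = 1` (saturating-exponential rise, exponential decay).
#'
#' Distribution specs are lists: `list(dist = "uniform", min, max)` or
#' `list(dist = "constant", value)`.
#'
#' The defaults describe the reference acquisition regime: a 512 x 512 px
#' field recorded for 600 frames at 2 Hz with ~200 cells, 60 % of them
#' responders with fold-amplitudes dI/I0 uniform on [5.5, 20], landing
#' within the first 50 s and triggering 50-200 s after landing. The cell
#' density, radius and pre-landing mobility are set so that mask-overlap
#' events (excluded downstream) stay rare, emulating an experiment run at
#' a suitable cell density.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param n_frames number of frames.
#' @param frame_interval seconds between frames.
#' @param n_cells number of cells to place.
#' @param cell_radius_px `c(mean, sd)` of cell radii in pixels.
#' @param responder_fraction probability a cell is a responder, in [0,1].
#' @param landing_time_dist distribution of landing times (seconds).
#' @param trigger_delay_dist distribution of the delay between landing and
#'   triggering (seconds).
#' @param baseline_intensity post-landing baseline counts I0.
#' @param landing_step_factor pre-landing intensity = I0 / this (> 1).
#' @param amplitude_ratio_dist distribution of dI/I0.
#' @param rise_time transient rise time constant, seconds.
#' @param decay_time transient decay time constant, seconds
#'   (must exceed `rise_time`).
#' @param diffusion_step_px mean per-frame step length of the pre-landing
#'   random walk, pixels.
#' @param noise_model `list(gaussian_sd = counts, poisson = flag)`.
#' @param background_intensity constant background counts.
#' @param edge_blur_px Gaussian sigma for optional cell-edge blur
#'   (0 = sharp disks).
#' @param seed integer RNG seed; equal seeds give bit-identical output.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_size = c(512L, 512L),
                         n_frames = 600L,
                         frame_interval = 0.5,
                         n_cells = 200L,
                         cell_radius_px = c(5, 0.6),
                         responder_fraction = 0.6,
                         landing_time_dist = list(dist = "uniform", min = 5, max = 50),
                         trigger_delay_dist = list(dist = "uniform", min = 50, max = 200),
                         baseline_intensity = 100,
                         landing_step_factor = 1.3,
                         amplitude_ratio_dist = list(dist = "uniform", min = 5.5, max = 20),
                         rise_time = 3,
                         decay_time = 40,
                         diffusion_step_px = 0.8,
                         noise_model = list(gaussian_sd = 10, poisson = FALSE),
                         background_intensity = 20,
                         edge_blur_px = 0,
                         seed = 1L) {
  cfg <- list(image_size = as.integer(image_size), n_frames = as.integer(n_frames),
              frame_interval = frame_interval, n_cells = as.integer(n_cells),
              cell_radius_px = cell_radius_px,
              responder_fraction = responder_fraction,
              landing_time_dist = landing_time_dist,
              trigger_delay_dist = trigger_delay_dist,
              baseline_intensity = baseline_intensity,
              landing_step_factor = landing_step_factor,
              amplitude_ratio_dist = amplitude_ratio_dist,
              rise_time = rise_time, decay_time = decay_time,
              diffusion_step_px = diffusion_step_px,
              noise_model = noise_model,
              background_intensity = background_intensity,
              edge_blur_px = edge_blur_px,
              seed = as.integer(seed))
  validate_scene_config(cfg)
  structure(cfg, class = "scene_config")
}

validate_scene_config <- function(cfg) {
  if (cfg$responder_fraction < 0 || cfg$responder_fraction > 1)
    stop("responder_fraction must lie in [0, 1]")
  if (cfg$rise_time <= 0 || cfg$decay_time <= cfg$rise_time)
    stop("need decay_time > rise_time > 0")
  if (cfg$frame_interval <= 0) stop("frame_interval must be > 0")
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2")
  if (cfg$landing_step_factor <= 1)
    stop("landing_step_factor must be > 1 (pre-landing cells are dimmer)")
  if (cfg$baseline_intensity <= 0) stop("baseline_intensity must be > 0")
  invisible(cfg)
}

draw_dist <- function(spec, n) {
  switch(spec$dist,
         uniform = stats::runif(n, spec$min, spec$max),
         constant = rep(spec$value, n),
         exponential = stats::rexp(n, rate = spec$rate),
         stop("unknown distribution spec: ", spec$dist))
}

#' Normalized single-transient shape
#'
#' `g(t) = (1 - exp(-t/rise)) * exp(-t/decay) / M` for `t >= 0`, 0 before,
#' with `M` the analytic maximum, attained at `t* = rise * log((rise+decay)/rise)`.
#'
#' @param t seconds since transient onset (vectorized).
#' @param rise_time,decay_time time constants, seconds.
#' @return dimensionless values in [0, 1] with maximum 1.
#' @export
transient_shape <- function(t, rise_time, decay_time) {
  tstar <- rise_time * log((rise_time + decay_time) / rise_time)
  M <- (1 - exp(-tstar / rise_time)) * exp(-tstar / decay_time)
  out <- ifelse(t < 0, 0,
                (1 - exp(-t / rise_time)) * exp(-t / decay_time) / M)
  out
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so simulation never perturbs user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic movie with ground truth
#'
#' Renders the scene described by a [scene_config()] as a 16-bit movie
#' stack and returns it with a per-cell ground-truth table and the exact
#' trajectories used. Cells are uniform-intensity disks; before their
#' landing frame they random-walk (steps with mean length
#' `diffusion_step_px`, reflected at the borders) and appear dimmed by
#' `landing_step_factor`; from the landing frame on they are strictly
#' stationary. Responders whose transient would start beyond the movie end
#' are recorded as non-responders, since no observable response exists.
#'
#' @param config a [scene_config()].
#' @return a list with elements `stack` (a [movie_stack()]) and
#'   `ground_truth` (class `ground_truth`: `$cells` per-cell table,
#'   `$trajectories` long table of true centroids, `$config`).
#' @export
generate_movie <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, generate_movie_impl(config))
}

generate_movie_impl <- function(cfg) {
  H <- cfg$image_size[1]; W <- cfg$image_size[2]
  nf <- cfg$n_frames; dt <- cfg$frame_interval; nc <- cfg$n_cells

  radii <- pmax(2, stats::rnorm(nc, cfg$cell_radius_px[1], cfg$cell_radius_px[2]))

  # initial placement: rejection-sample centroids at least one cell
  # diameter apart (pairwise max), keeping whole disks inside the frame
  pos <- matrix(NA_real_, nc, 2)
  max_attempts <- 2000L * nc
  attempts <- 0L
  placed <- 0L
  while (placed < nc) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("cell count infeasible: could not place ", nc,
           " cells with one-diameter separation in a ", H, " x ", W, " frame")
    r <- radii[placed + 1L]
    cand <- c(stats::runif(1, r + 2, H - r - 1),
              stats::runif(1, r + 2, W - r - 1))
    if (placed > 0L) {
      d <- sqrt(rowSums((pos[seq_len(placed), , drop = FALSE] -
                           matrix(cand, placed, 2, byrow = TRUE))^2))
      minsep <- 2 * pmax(radii[seq_len(placed)], r)
      if (any(d < minsep)) next
    }
    placed <- placed + 1L
    pos[placed, ] <- cand
  }

  landing_t <- draw_dist(cfg$landing_time_dist, nc)
  landing_frame <- as.integer(round(landing_t / dt))
  landing_frame[landing_frame >= nf] <- NA_integer_   # never lands on screen

  is_resp <- stats::runif(nc) < cfg$responder_fraction
  delay <- draw_dist(cfg$trigger_delay_dist, nc)
  trigger_frame <- landing_frame + as.integer(round(delay / dt))
  trigger_frame[!is_resp] <- NA_integer_
  # a transient starting beyond the movie is unobservable
  unobs <- is_resp & (is.na(landing_frame) | is.na(trigger_frame) |
                        trigger_frame >= nf)
  is_resp[unobs] <- FALSE
  trigger_frame[unobs] <- NA_integer_

  amp <- draw_dist(cfg$amplitude_ratio_dist, nc)
  amp[!is_resp] <- NA_real_

  # trajectories: random walk before landing, frozen afterwards
  step_sd <- cfg$diffusion_step_px / sqrt(pi / 2)  # mean |step| = diffusion_step_px
  traj <- array(NA_real_, dim = c(nf, nc, 2))
  for (i in seq_len(nc)) {
    lf <- landing_frame[i]
    stop_at <- if (is.na(lf)) nf else min(lf, nf - 1L)
    p <- pos[i, ]
    r <- radii[i]
    for (k in seq_len(nf) - 1L) {
      traj[k + 1L, i, ] <- p
      if (k < stop_at) {
        p <- p + stats::rnorm(2, 0, step_sd)
        # reflect to keep the disk inside the frame
        p[1] <- min(max(p[1], r + 2), H - r - 1)
        p[2] <- min(max(p[2], r + 2), W - r - 1)
      }
    }
  }

  I0 <- cfg$baseline_intensity
  pre_I <- I0 / cfg$landing_step_factor
  times <- (seq_len(nf) - 1L) * dt

  # per-cell mean-intensity trace (noise-free truth)
  level <- matrix(pre_I, nf, nc)
  for (i in seq_len(nc)) {
    lf <- landing_frame[i]
    if (is.na(lf)) next
    level[(lf + 1L):nf, i] <- I0
    if (is_resp[i]) {
      tf <- trigger_frame[i]
      post <- (tf + 1L):nf
      level[post, i] <- I0 + amp[i] * I0 *
        transient_shape(times[post] - times[tf + 1L], cfg$rise_time, cfg$decay_time)
    }
  }

  gsd <- cfg$noise_model$gaussian_sd %||% 0
  pois <- isTRUE(cfg$noise_model$poisson)
  frames <- array(0L, dim = c(nf, H, W))
  boxr <- ceiling(max(radii)) + 1L
  off <- expand.grid(dr = -boxr:boxr, dc = -boxr:boxr)
  for (k in seq_len(nf)) {
    fr <- matrix(cfg$background_intensity, H, W)
    for (i in seq_len(nc)) {
      ctr <- traj[k, i, ]
      rr <- round(ctr[1]) + off$dr
      cc <- round(ctr[2]) + off$dc
      keep <- (rr - ctr[1])^2 + (cc - ctr[2])^2 <= radii[i]^2 &
        rr >= 1 & rr <= H & cc >= 1 & cc <= W
      idx <- rr[keep] + (cc[keep] - 1L) * H
      fr[idx] <- pmax(fr[idx], level[k, i])
    }
    if (cfg$edge_blur_px > 0)
      fr <- EBImage::gblur(fr, sigma = cfg$edge_blur_px)
    if (pois) fr <- stats::rpois(length(fr), pmax(fr, 0))
    if (gsd > 0) fr <- fr + stats::rnorm(length(fr), 0, gsd)
    frames[k, , ] <- as.integer(pmin(pmax(round(fr), 0), 65535))
  }

  cells <- data.frame(
    cell_id = seq_len(nc),
    true_landing_frame = landing_frame,
    is_responder = is_resp,
    true_trigger_frame = trigger_frame,
    true_amplitude_ratio = amp,
    radius_px = radii,
    baseline_intensity = I0)
  trajectories <- data.frame(
    cell_id = rep(seq_len(nc), each = nf),
    frame = rep(seq_len(nf) - 1L, nc),
    row = as.vector(traj[, , 1]),
    col = as.vector(traj[, , 2]))

  gt <- structure(list(cells = cells, trajectories = trajectories,
                       config = cfg),
                  class = "ground_truth")
  list(stack = movie_stack(frames, dt), ground_truth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' True noise-free mean-intensity trace of a synthetic cell
#'
#' Closed-form per-frame mean intensity implied by the ground truth, for
#' parameter-recovery comparisons.
#'
#' @param gt a `ground_truth`.
#' @param cell_id cell identifier.
#' @return data.frame with `frame`, `time_s`, `intensity`.
#' @export
true_trace <- function(gt, cell_id) {
  cfg <- gt$config
  row <- gt$cells[gt$cells$cell_id == cell_id, ]
  if (nrow(row) != 1L) stop("unknown cell_id ", cell_id)
  nf <- cfg$n_frames; dt <- cfg$frame_interval
  times <- (seq_len(nf) - 1L) * dt
  I0 <- cfg$baseline_intensity
  v <- rep(I0 / cfg$landing_step_factor, nf)
  lf <- row$true_landing_frame
  if (!is.na(lf)) {
    v[(lf + 1L):nf] <- I0
    if (isTRUE(row$is_responder)) {
      tf <- row$true_trigger_frame
      post <- (tf + 1L):nf
      v[post] <- I0 + row$true_amplitude_ratio * I0 *
        transient_shape(times[post] - times[tf + 1L], cfg$rise_time, cfg$decay_time)
    }
  }
  data.frame(frame = seq_len(nf) - 1L, time_s = times, intensity = v)
}

#' Write a ground-truth table to CSV
#'
#' One row per cell, frame indices 0-based, header
#' `cell_id,true_landing_frame,is_responder,true_trigger_frame,true_amplitude_ratio`.
#'
#' @param gt a `ground_truth` (or its `$cells` data.frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  cells <- if (inherits(gt, "ground_truth")) gt$cells else gt
  if (is.null(cells) || nrow(cells) == 0L)
    stop("ground truth is empty; nothing to write")
  cols <- c("cell_id", "true_landing_frame", "is_responder",
            "true_trigger_frame", "true_amplitude_ratio")
  utils::write.csv(cells[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a ground-truth CSV written by [write_ground_truth()]
#' @param path CSV path.
#' @return data.frame with the canonical ground-truth columns.
#' @export
read_ground_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
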